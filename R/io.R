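#' Write / read a label volume as a multi-page TIFF stack
#'
#' One 8-bit page per z-slice (labels 0/1/2), with a JSON sidecar
#' (`<path>.json`) carrying resolution and provenance metadata.
#'
#' @param volume A [label_volume()].
#' @param path Output TIFF path.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns the `label_volume`.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  pages <- lapply(seq_len(d[3]), function(j) volume$labels[, , j] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- volume$meta
  meta$params <- NULL  # params are not JSON-stable; store traits only
  p <- volume$meta$params
  if (!is.null(p)) {
    meta$traits <- unclass(p)[c("CD", "TH", "SL", "SW", "CH", "SS", "SPL",
                                "SPW", "CSC", "CSM")]
  }
  sidecar <- list(kind = "label_volume", resolution_mm = volume$resolution,
                  dims = d, labels = list(water = 0, tissue = 1, skeleton = 2),
                  meta = meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  labels <- array(0L, dim = d)
  for (j in seq_len(d[3])) labels[, , j] <- as.integer(round(pages[[j]] * 255))
  label_volume(labels, side$resolution_mm,
               meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Write a fluence volume as a 32-bit float TIFF stack
#'
#' Pages are stored normalized to the volume maximum (TIFF float pages hold
#' values in `[0, 1]`); the sidecar JSON records `phi_max`, the escape and
#' absorption ledger, photon count and seed so the volume can be restored
#' exactly on read.
#'
#' @param fluence A `fluence_volume` from [run_mc()].
#' @param path Output TIFF path.
#' @return `path`, invisibly; `read_fluence_volume()` returns a list with
#'   `phi` and the ledger fields.
#' @export
write_fluence_volume <- function(fluence, path) {
  stopifnot(inherits(fluence, "fluence_volume"))
  d <- dim(fluence$phi)
  mx <- max(fluence$phi, 1e-300)
  pages <- lapply(seq_len(d[3]), function(j) fluence$phi[, , j] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(kind = "fluence_volume", resolution_mm = fluence$resolution,
                  dims = d, phi_max = mx,
                  escaped_top = fluence$escaped_top,
                  escaped_other = fluence$escaped_other,
                  absorbed = as.list(fluence$absorbed),
                  roulette_net = fluence$roulette_net,
                  n_photons = fluence$config$n_photons,
                  seed = fluence$config$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fluence_volume
#' @export
read_fluence_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  phi <- array(0, dim = d)
  for (j in seq_len(d[3])) phi[, , j] <- pages[[j]] * side$phi_max
  c(list(phi = phi), side[setdiff(names(side), c("kind", "dims", "phi_max"))])
}

#' Write scenario results to CSV
#'
#' @param results A `scenario_results` tibble from [run_scenario_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a morphotype blueprint as YAML
#'
#' Plain key-value YAML so blueprints can be versioned and edited outside R.
#'
#' @param params A [morphotype_params()] object.
#' @param path Output `.yaml` path.
#' @return `write_morphotype_params()` returns `path` invisibly;
#'   `read_morphotype_params()` returns the validated blueprint.
#' @export
write_morphotype_params <- function(params, path) {
  stopifnot(inherits(params, "morphotype_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_morphotype_params
#' @export
read_morphotype_params <- function(path) {
  x <- yaml::read_yaml(path)
  morphotype_params(
    CD = x$CD, TH = x$TH, SL = x$SL, SW = x$SW, CH = x$CH, SS = x$SS,
    SPL = x$SPL, SPW = x$SPW, CSC = x$CSC, CSM = x$CSM,
    n_septa = x$n_septa %||% 6L,
    tissue_thickness = x$tissue_thickness %||% "max_spine_length",
    polyp_recess = x$polyp_recess %||% 0.5,
    columella_diameter = x$columella_diameter,
    allow_protruding_columella = isTRUE(x$allow_protruding_columella),
    label = x$label %||% NA_character_
  )
}
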