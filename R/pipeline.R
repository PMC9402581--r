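STRUCTURAL_VARIANTS <- c("default", "knockout:corallite", "knockout:columella",
                         "knockout:spines", "exchange:spacing", "exchange:height")

#' Expand a scenario configuration into an ordered run matrix
#'
#' Full factorial expansion of the enabled factor levels, deterministically
#' ordered and de-duplicated. One row per simulation spec.
#'
#' @param morphotypes Subset of `c("shallow", "mesophotic")`.
#' @param irradiances Named numeric vector of incident irradiances,
#'   umol photons m^-2 s^-1 (defaults `c(high = 750, low = 45)`).
#' @param optical_scenarios Integer subset of 1..6.
#' @param pe_sets Subset of `c("shallow", "mesophotic")`.
#' @param structural_variants Subset of `"default"`, `"knockout:corallite"`,
#'   `"knockout:columella"`, `"knockout:spines"`, `"exchange:spacing"`,
#'   `"exchange:height"`; must be non-empty.
#' @param seeds Integer vector of replicate seeds.
#' @return A tibble of scenario specs, one row per run, with attribute
#'   `n_documented` equal to its row count.
#' @export
expand_scenario_matrix <- function(morphotypes = c("shallow", "mesophotic"),
                                   irradiances = c(high = 750, low = 45),
                                   optical_scenarios = 1:6,
                                   pe_sets = c("shallow", "mesophotic"),
                                   structural_variants = "default",
                                   seeds = 1L) {
  morphotypes <- match.arg(morphotypes, several.ok = TRUE)
  pe_sets <- match.arg(pe_sets, c("shallow", "mesophotic"), several.ok = TRUE)
  if (length(structural_variants) == 0) {
    abort("structural_variants must not be empty")
  }
  bad <- setdiff(structural_variants, STRUCTURAL_VARIANTS)
  if (length(bad) > 0) {
    abort(paste("unknown structural variant(s):", paste(bad, collapse = ", ")))
  }
  if (!all(optical_scenarios %in% 1:6)) abort("optical scenarios must be in 1..6")
  if (is.null(names(irradiances))) {
    names(irradiances) <- paste0("E", irradiances)
  }
  specs <- tidyr::expand_grid(
    morphotype = morphotypes,
    irradiance_label = names(irradiances),
    optical_scenario = as.integer(optical_scenarios),
    pe_set = pe_sets,
    structural_variant = structural_variants,
    replicate_seed = as.integer(seeds)
  ) |>
    dplyr::mutate(irradiance = unname(irradiances[.data$irradiance_label])) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$morphotype, .data$irradiance_label,
                   .data$optical_scenario, .data$pe_set,
                   .data$structural_variant, .data$replicate_seed)
  attr(specs, "n_documented") <- nrow(specs)
  specs
}

#' The shipped default scenario ledger
#'
#' The six bio-optical scenarios under default structure, plus the five
#' structural variants (three knock-outs, two trait exchanges) under default
#' optics, crossed with both morphotypes, both irradiances and both P-E sets:
#' 2 x 2 x 2 x (6 + 5) = 88 runs per seed. The composition is configurable;
#' the total is carried as the `n_documented` attribute, not hard-coded.
#'
#' @param seeds Integer vector of replicate seeds.
#' @return A scenario spec tibble (see [expand_scenario_matrix()]).
#' @export
default_scenario_ledger <- function(seeds = 1L) {
  optical <- expand_scenario_matrix(optical_scenarios = 1:6,
                                    structural_variants = "default",
                                    seeds = seeds)
  structural <- expand_scenario_matrix(
    optical_scenarios = 1L,
    structural_variants = setdiff(STRUCTURAL_VARIANTS, "default"),
    seeds = seeds)
  out <- dplyr::bind_rows(optical, structural) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$morphotype, .data$irradiance_label,
                   .data$optical_scenario, .data$pe_set,
                   .data$structural_variant, .data$replicate_seed)
  attr(out, "n_documented") <- nrow(out)
  out
}

variant_params <- function(variant, own, other) {
  switch(variant,
    "default" = own,
    "knockout:corallite" = knockout(own, "corallite"),
    "knockout:columella" = knockout(own, "columella"),
    "knockout:spines" = knockout(own, "spines"),
    "exchange:spacing" = exchange_traits(own, other, "spacing"),
    "exchange:height" = exchange_traits(own, other, "height"),
    abort(paste("unknown structural variant:", variant))
  )
}

#' Run a scenario matrix
#'
#' Executes every spec row: builds (or reuses) the variant geometry, runs
#' photon transport once per distinct (morphotype, variant, optical scenario,
#' seed) combination, scores photosynthesis for each irradiance and P-E set
#' sharing that fluence field, and attaches surface metrics and the escape
#' ledger. A failing run is recorded in the `error` column; the matrix
#' continues.
#'
#' @param specs A spec tibble from [expand_scenario_matrix()] or
#'   [default_scenario_ledger()].
#' @param params Named list of [morphotype_params()] (defaults: the shipped
#'   shallow/mesophotic blueprints).
#' @param pe Named list of [pe_params()] (defaults: [pe_defaults()]).
#' @param base_optics Scenario-1 [optical_properties()].
#' @param transport A [transport_config()]; its seed is replaced per-run by
#'   `replicate_seed`.
#' @param resolution,tile_corallites,water_mm,slab_mm Passed to [build_tile()].
#' @param verbose Print one line per transport run.
#' @return A `scenario_results` tibble: the spec columns plus `score`
#'   (tissue-normalized photosynthetic score), `mean_tissue_phi`,
#'   `surface_area`, `rugosity`, `tissue_volume`, `escaped_top`,
#'   `escaped_other`, `absorbed_total`, `n_tissue`, `error`.
#' @export
run_scenario_matrix <- function(specs,
                                params = list(shallow = shallow_params(),
                                              mesophotic = mesophotic_params()),
                                pe = pe_defaults(),
                                base_optics = optical_properties(),
                                transport = transport_config(),
                                resolution = 0.02, tile_corallites = 2L,
                                water_mm = 0.3, slab_mm = 1.0,
                                verbose = FALSE) {
  stopifnot(all(c("morphotype", "irradiance", "optical_scenario", "pe_set",
                  "structural_variant", "replicate_seed") %in% names(specs)))

  geom_cache <- new.env(parent = emptyenv())
  metrics_cache <- new.env(parent = emptyenv())
  get_geom <- function(morph, variant) {
    key <- paste(morph, variant, sep = "|")
    if (!is.null(geom_cache[[key]])) return(geom_cache[[key]])
    own <- params[[morph]]
    other <- params[[setdiff(c("shallow", "mesophotic"), morph)]]
    vol <- build_tile(variant_params(variant, own, other),
                      resolution = resolution,
                      tile_corallites = tile_corallites,
                      water_mm = water_mm, slab_mm = slab_mm)
    geom_cache[[key]] <- vol
    metrics_cache[[key]] <- surface_metrics(vol)
    vol
  }

  fluence_cache <- new.env(parent = emptyenv())
  get_fluence <- function(morph, variant, scen, seed) {
    key <- paste(morph, variant, scen, seed, sep = "|")
    if (!is.null(fluence_cache[[key]])) return(fluence_cache[[key]])
    vol <- get_geom(morph, variant)
    cfg <- transport
    cfg$seed <- as.numeric(seed)
    if (verbose) {
      message(sprintf("transport: %s %s scenario %d seed %d (%g photons)",
                      morph, variant, scen, seed, cfg$n_photons))
    }
    fl <- run_mc(vol, optics_for_scenario(scen, base = base_optics), cfg)
    fluence_cache[[key]] <- fl
    fl
  }

  rows <- purrr::pmap(specs, function(morphotype, irradiance, optical_scenario,
                                      pe_set, structural_variant,
                                      replicate_seed, ...) {
    tryCatch({
      vol <- get_geom(morphotype, structural_variant)
      fl <- get_fluence(morphotype, structural_variant, optical_scenario,
                        replicate_seed)
      field <- score_volume(fl, vol, pe[[pe_set]], irradiance)
      sm <- metrics_cache[[paste(morphotype, structural_variant, sep = "|")]]
      tibble::tibble(
        score = field$summary,
        mean_tissue_phi = mean_tissue_phi(fl, vol),
        surface_area = sm$surface_area,
        rugosity = sm$rugosity,
        tissue_volume = sm$tissue_volume,
        escaped_top = fl$escaped_top,
        escaped_other = fl$escaped_other,
        absorbed_total = sum(fl$absorbed),
        n_tissue = field$n_tissue,
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(score = NA_real_, mean_tissue_phi = NA_real_,
                     surface_area = NA_real_, rugosity = NA_real_,
                     tissue_volume = NA_real_, escaped_top = NA_real_,
                     escaped_other = NA_real_, absorbed_total = NA_real_,
                     n_tissue = NA_integer_, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_cols(specs, dplyr::bind_rows(rows))
  class(out) <- c("scenario_results", class(out))
  out
}
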