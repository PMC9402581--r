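#' Corallite trait blueprint for a morphotype
#'
#' Bundles the ten corallite/coenosteum skeletal traits (all in mm) plus the
#' tissue-thickness rule into the blueprint a geometry tile is built from.
#' Trait symbols follow standard coral morphometrics: calyx diameter (CD),
#' theca height (TH), septal length/width (SL/SW), columella height (CH),
#' coenosteal spine spacing/length/width (SS/SPL/SPW), corallite
#' center-to-center spacing (CSC) and minimal margin spacing (CSM).
#'
#' @param CD Calyx diameter, mm.
#' @param TH Theca (corallite wall) height, i.e. calyx recess depth, mm.
#' @param SL Septal length (radial extent inward from the theca wall), mm.
#' @param SW Septal width, mm.
#' @param CH Columella height above the calyx floor, mm. Must not exceed `TH`
#'   unless `allow_protruding_columella = TRUE`.
#' @param SS Coenosteal spine spacing (square-lattice pitch), mm.
#' @param SPL Coenosteal spine length (height above the coenosteum), mm.
#' @param SPW Coenosteal spine basal width, mm.
#' @param CSC Corallite center-to-center spacing (square-lattice pitch), mm.
#' @param CSM Minimal spacing between corallite margins, mm. Must satisfy
#'   `CSM <= CSC - CD` up to a small tolerance.
#' @param n_septa Number of radial septa (default 6, the number this
#'   pocilloporid develops).
#' @param tissue_thickness Tissue thickness over the coenosteum, mm, or the
#'   string `"max_spine_length"` (default) to tie it to `SPL` — contracted
#'   tissue drapes the coenosteum up to the spine tips.
#' @param polyp_recess Fraction of `TH` left unfilled by the contracted polyp:
#'   0 fills the calyx to the rim, 1 leaves only a conformal wall coat. The
#'   default 0.5 gives the tissue surface a corallite-scale dimple.
#' @param columella_diameter Columella diameter, mm; default `0.25 * CD`.
#' @param allow_protruding_columella Permit `CH > TH`.
#' @param label Optional morphotype label (e.g. `"shallow"`).
#'
#' @return An object of class `morphotype_params` (a named list).
#' @seealso [shallow_params()], [mesophotic_params()], [build_tile()]
#' @export
morphotype_params <- function(CD, TH, SL, SW, CH, SS, SPL, SPW, CSC, CSM,
                              n_septa = 6L,
                              tissue_thickness = "max_spine_length",
                              polyp_recess = 0.5,
                              columella_diameter = NULL,
                              allow_protruding_columella = FALSE,
                              label = NA_character_) {
  lengths <- c(CD = CD, TH = TH, SL = SL, SW = SW, CH = CH, SS = SS,
               SPL = SPL, SPW = SPW, CSC = CSC, CSM = CSM)
  bad <- names(lengths)[!is.finite(lengths) | lengths < 0]
  if (length(bad) > 0) {
    abort(paste0("trait(s) must be finite and >= 0: ", paste(bad, collapse = ", ")),
          class = "corallux_invalid_params")
  }
  if (CD > CSC) {
    abort("CD must not exceed CSC: corallites would overlap at their centers",
          class = "corallux_invalid_params")
  }
  tol <- 1e-8 + 0.05 * CSC
  if (CSM > CSC - CD + tol) {
    abort("CSM must not exceed CSC - CD (margins inconsistent with centers)",
          class = "corallux_invalid_params")
  }
  if (!allow_protruding_columella && CH > TH + 1e-12) {
    abort("CH must not exceed TH (columella would protrude above the rim)",
          class = "corallux_invalid_params")
  }
  if (!identical(tissue_thickness, "max_spine_length")) {
    stopifnot(is.numeric(tissue_thickness), tissue_thickness >= 0)
  }
  stopifnot(polyp_recess >= 0, polyp_recess <= 1, n_septa >= 0)
  if (is.null(columella_diameter)) columella_diameter <- 0.25 * CD
  structure(
    list(CD = CD, TH = TH, SL = SL, SW = SW, CH = CH, SS = SS, SPL = SPL,
         SPW = SPW, CSC = CSC, CSM = CSM, n_septa = as.integer(n_septa),
         tissue_thickness = tissue_thickness, polyp_recess = polyp_recess,
         columella_diameter = columella_diameter,
         allow_protruding_columella = allow_protruding_columella,
         label = label),
    class = "morphotype_params"
  )
}

#' @export
print.morphotype_params <- function(x, ...) {
  cat("<morphotype_params>", if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n",
      sep = "")
  tr <- unlist(x[c("CD", "TH", "SL", "SW", "CH", "SS", "SPL", "SPW", "CSC", "CSM")])
  print(round(tr, 4))
  cat("n_septa:", x$n_septa, " tissue_thickness:",
      if (identical(x$tissue_thickness, "max_spine_length")) "max spine length"
      else format(x$tissue_thickness), " polyp_recess:", x$polyp_recess, "\n")
  invisible(x)
}

#' Default morphotype trait means
#'
#' Per-trait group means used as the shipped blueprint for the two
#' depth-specific morphotypes of *Stylophora pistillata*. Calyx diameter uses
#' the midpoints of the ranges reported for each depth group (0.848–1.191 mm
#' shallow, 0.533–0.719 mm mesophotic); corallite margin spacing encodes the
#' reported ~58% wider spacing at mesophotic depth; porosity and branch
#' thickness use the reported group values. No reported values exist for the
#' remaining traits, so their defaults are plausible values for this species
#' and are tagged `"assumed"` — override them freely.
#'
#' @return A tibble with columns `trait`, `shallow`, `mesophotic`, `units`,
#'   `provenance` (`"reported"` or `"assumed"`).
#' @export
trait_defaults <- function() {
  tibble::tribble(
    ~trait,              ~shallow, ~mesophotic, ~units,     ~provenance,
    "CD",                 1.02,     0.63,       "mm",       "reported",
    "TH",                 0.50,     0.28,       "mm",       "assumed",
    "SL",                 0.20,     0.13,       "mm",       "assumed",
    "SW",                 0.06,     0.05,       "mm",       "assumed",
    "CH",                 0.15,     0.12,       "mm",       "assumed",
    "SS",                 0.18,     0.14,       "mm",       "assumed",
    "SPL",                0.12,     0.08,       "mm",       "assumed",
    "SPW",                0.06,     0.05,       "mm",       "assumed",
    "CSC",                1.55,     1.45,       "mm",       "assumed",
    "CSM",                0.50,     0.79,       "mm",       "reported",
    "branch_thickness",   6.0,      4.2,        "mm",       "reported",
    "porosity",           0.0828,   0.1557,     "fraction", "reported"
  )
}

params_from_defaults <- function(group) {
  d <- trait_defaults()
  v <- setNames(d[[group]], d$trait)
  morphotype_params(CD = v[["CD"]], TH = v[["TH"]], SL = v[["SL"]],
                    SW = v[["SW"]], CH = v[["CH"]], SS = v[["SS"]],
                    SPL = v[["SPL"]], SPW = v[["SPW"]], CSC = v[["CSC"]],
                    CSM = v[["CSM"]], label = group)
}

#' Shipped morphotype blueprints
#'
#' Convenience constructors returning [morphotype_params()] filled with the
#' default trait means of [trait_defaults()].
#'
#' @return A `morphotype_params` object.
#' @export
shallow_params <- function() params_from_defaults("shallow")

#' @rdname shallow_params
#' @export
mesophotic_params <- function() params_from_defaults("mesophotic")

#' Swap trait values between two morphotype blueprints
#'
#' Returns `a` with the named trait groups replaced by `b`'s values:
#' `"spacing"` swaps the corallite margin spacing `CSM` and re-derives the
#' lattice pitch as `CSC = CD + CSM + w`, where `w` is `a`'s original wall
#' allowance (`CSC - CD - CSM`), so the swapped margins actually move the
#' corallites; `"height"` swaps the theca height `TH` (the columella is
#' clipped to the new rim if it would protrude). Used for the trait-exchange
#' simulation scenarios.
#'
#' @param a,b `morphotype_params` objects.
#' @param traits Character subset of `c("spacing", "height")`.
#' @return A `morphotype_params` object (validated after the swap).
#' @export
exchange_traits <- function(a, b, traits) {
  stopifnot(inherits(a, "morphotype_params"), inherits(b, "morphotype_params"))
  traits <- match.arg(traits, c("spacing", "height"), several.ok = TRUE)
  out <- unclass(a)
  if ("spacing" %in% traits) {
    wall <- max(0, a$CSC - a$CD - a$CSM)
    out$CSM <- b$CSM
    out$CSC <- out$CD + out$CSM + wall
  }
  if ("height" %in% traits) {
    out$TH <- b$TH
    out$CH <- min(out$CH, out$TH)
  }
  morphotype_params(CD = out$CD, TH = out$TH, SL = out$SL, SW = out$SW,
                    CH = out$CH, SS = out$SS, SPL = out$SPL, SPW = out$SPW,
                    CSC = out$CSC, CSM = out$CSM, n_septa = out$n_septa,
                    tissue_thickness = out$tissue_thickness,
                    polyp_recess = out$polyp_recess,
                    columella_diameter = out$columella_diameter,
                    allow_protruding_columella = out$allow_protruding_columella,
                    label = paste0(a$label, "+", paste(traits, collapse = "/"),
                                   "<-", b$label))
}
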