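#' Specification for the synthetic trait-table generator
#'
#' Describes the sampling design the generator emulates: two depth groups of
#' colonies, per-trait group means, a between-colony random effect
#' (additive normal truncated at zero — traits are positive lengths), and
#' within-colony replicate measurement noise (multiplicative lognormal with a
#' stated coefficient of variation).
#'
#' @param group_means A tibble/data frame with columns `trait`, `shallow`,
#'   `mesophotic` (and optionally `units`); defaults to [trait_defaults()].
#' @param colony_sd Between-colony SD, either a single fraction of the group
#'   mean (default 0.10) or a named numeric vector of absolute SDs per trait.
#' @param replicate_cv Within-colony replicate coefficient of variation,
#'   in (0, 1); default 0.08.
#' @param n_colonies_per_group Colonies per depth group (>= 2); default 15.
#' @param n_replicates Measurements per colony per trait (>= 1); default 10.
#' @param seed Integer seed. Per-colony random streams are derived by
#'   counter-based splitting, so increasing the colony count does not
#'   reshuffle earlier colonies.
#' @return A `trait_generator_spec` object.
#' @export
trait_generator_spec <- function(group_means = trait_defaults(),
                                 colony_sd = 0.10,
                                 replicate_cv = 0.08,
                                 n_colonies_per_group = 15L,
                                 n_replicates = 10L,
                                 seed = 1L) {
  gm <- tibble::as_tibble(group_means)
  need <- c("trait", "shallow", "mesophotic")
  if (!all(need %in% names(gm))) {
    abort(paste("group_means must have columns:", paste(need, collapse = ", ")),
          class = "corallux_invalid_spec")
  }
  if (!all(is.finite(gm$shallow)) || any(gm$shallow <= 0) ||
      !all(is.finite(gm$mesophotic)) || any(gm$mesophotic <= 0)) {
    abort("group_means: all means must be strictly positive",
          class = "corallux_invalid_spec")
  }
  if (!"units" %in% names(gm)) gm$units <- "mm"
  if (is.null(names(colony_sd))) {
    if (length(colony_sd) != 1 || colony_sd < 0 || colony_sd >= 1) {
      abort("colony_sd: fractional form must be a single value in [0, 1)",
            class = "corallux_invalid_spec")
    }
  } else {
    if (any(colony_sd < 0)) {
      abort("colony_sd: absolute SDs must be >= 0", class = "corallux_invalid_spec")
    }
  }
  if (replicate_cv < 0 || replicate_cv >= 1) {
    abort("replicate_cv must lie in [0, 1)", class = "corallux_invalid_spec")
  }
  if (n_colonies_per_group < 2) {
    abort("n_colonies_per_group must be >= 2", class = "corallux_invalid_spec")
  }
  if (n_replicates < 1) {
    abort("n_replicates must be >= 1", class = "corallux_invalid_spec")
  }
  structure(list(group_means = gm, colony_sd = colony_sd,
                 replicate_cv = replicate_cv,
                 n_colonies_per_group = as.integer(n_colonies_per_group),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "trait_generator_spec")
}

# deterministic 31-bit stream seed for colony `i` under master seed `s`
colony_seed <- function(s, i) {
  x <- (as.double(s) * 2654435761 + as.double(i) * 97531) %% 2147483647
  as.integer(x) + 1L
}

#' Generate a synthetic morphometric trait table
#'
#' Draws colony-level trait values from a zero-truncated normal around the
#' group mean, then replicate measurements from a lognormal centred on the
#' colony value with the specified CV. Deterministic under a fixed seed.
#'
#' @param spec A [trait_generator_spec()].
#' @return A tidy tibble: `sample_id`, `depth_group`, `trait`,
#'   `replicate_index`, `value`, `units`.
#' @export
generate_trait_table <- function(spec) {
  stopifnot(inherits(spec, "trait_generator_spec"))
  gm <- spec$group_means
  traits <- gm$trait
  units <- setNames(gm$units, gm$trait)
  groups <- c("shallow", "mesophotic")

  sdlog <- sqrt(log(1 + spec$replicate_cv^2))
  rows <- vector("list", 2L * spec$n_colonies_per_group)
  ci <- 0L
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    means <- setNames(gm[[grp]], gm$trait)
    for (col in seq_len(spec$n_colonies_per_group)) {
      ci <- ci + 1L
      id <- sprintf("%s%02d", if (grp == "shallow") "sh" else "ms", col)
      set.seed(colony_seed(spec$seed, (gi - 1L) * 100000L + col))
      vals <- lapply(traits, function(tr) {
        mu <- means[[tr]]
        sdv <- if (is.null(names(spec$colony_sd))) spec$colony_sd * mu
               else unname(spec$colony_sd[tr])
        if (is.na(sdv)) sdv <- 0
        cval <- if (sdv > 0) {
          p0 <- stats::pnorm(0, mu, sdv)  # truncate at zero
          qnorm(p0 + runif(1) * (1 - p0), mu, sdv)
        } else mu
        reps <- if (spec$replicate_cv > 0) {
          stats::rlnorm(spec$n_replicates,
                        meanlog = log(cval) - sdlog^2 / 2, sdlog = sdlog)
        } else rep(cval, spec$n_replicates)
        tibble::tibble(trait = tr, replicate_index = seq_len(spec$n_replicates),
                       value = reps, units = units[[tr]])
      })
      rows[[ci]] <- dplyr::bind_rows(vals) |>
        dplyr::mutate(sample_id = id, depth_group = grp, .before = 1)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a trait table as tidy CSV
#'
#' @param table A trait table tibble.
#' @param path File path.
#' @return `read_trait_table()` returns the tibble; `write_trait_table()`
#'   returns `path` invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
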