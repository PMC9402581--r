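#' Collapse a trait table to colony means
#'
#' Colonies are the experimental unit: all statistics operate on per-colony
#' trait means, never on raw replicates.
#'
#' @param table A tidy trait table (`sample_id`, `depth_group`, `trait`,
#'   `value`).
#' @return A tibble with one row per colony x trait: `sample_id`,
#'   `depth_group`, `trait`, `value` (the colony mean).
#' @export
colony_means <- function(table) {
  check_trait_table(table)
  table |>
    dplyr::group_by(.data$sample_id, .data$depth_group, .data$trait) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

check_trait_table <- function(table) {
  need <- c("sample_id", "depth_group", "trait", "value")
  if (!all(need %in% names(table))) {
    abort(paste("trait table must have columns:", paste(need, collapse = ", ")))
  }
  map <- unique(table[, c("sample_id", "depth_group")])
  if (anyDuplicated(map$sample_id)) {
    abort("each sample_id must map to exactly one depth_group")
  }
  invisible(table)
}

# wide colony x trait matrix of colony means, plus the group factor
colony_matrix <- function(table) {
  cm <- colony_means(table)
  wide <- tidyr::pivot_wider(cm, names_from = "trait", values_from = "value")
  X <- as.matrix(wide[, setdiff(names(wide), c("sample_id", "depth_group"))])
  rownames(X) <- wide$sample_id
  list(X = X, group = wide$depth_group, sample_id = wide$sample_id)
}

# standardize to pooled zero mean / unit variance, dropping constant traits
standardize_traits <- function(X) {
  sds <- apply(X, 2, sd)
  drop <- names(which(sds == 0 | is.na(sds)))
  if (length(drop) > 0) {
    warn(paste("dropping zero-variance trait(s):", paste(drop, collapse = ", ")))
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  scale(X)
}

pick_reference <- function(groups) {
  lv <- sort(unique(groups))
  if (setequal(lv, c("shallow", "mesophotic"))) c("shallow", "mesophotic")
  else lv
}

#' Per-group trait summaries and percent differences
#'
#' Colony means are computed first; group mean and standard error are then
#' taken over colonies. The percent difference is ratio-based,
#' `100 * (mean_first / mean_second - 1)`, with the shallow group first when
#' the groups are shallow/mesophotic (so "+60" reads "60% larger in shallow").
#'
#' @param table A tidy trait table.
#' @return A tibble with one row per trait: per-group `mean_*`, `se_*`, `n_*`
#'   and `percent_diff`.
#' @export
summarize_by_group <- function(table) {
  cm <- colony_means(table)
  groups <- pick_reference(cm$depth_group)
  if (length(groups) != 2) abort("expected exactly two depth groups")
  for (g in groups) {
    if (!any(cm$depth_group == g)) abort(paste("group has no records:", g))
  }
  stats <- cm |>
    dplyr::group_by(.data$trait, .data$depth_group) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(stats, names_from = "depth_group",
                             values_from = c("mean", "se", "n"))
  g1 <- groups[1]; g2 <- groups[2]
  wide$percent_diff <- 100 * (wide[[paste0("mean_", g1)]] /
                                wide[[paste0("mean_", g2)]] - 1)
  attr(wide, "comparison") <- paste(g1, "relative to", g2)
  wide
}

#' Colony-blocked permutation test of a group difference
#'
#' Replicates are collapsed to colony means and whole colonies are permuted
#' across the two depth groups (the colony, not the replicate, is the
#' exchangeable unit — the permutation analogue of a mixed model with colony
#' as random effect). The statistic is the difference of group means; the
#' p-value uses the add-one correction
#' `p = (1 + #{|d_perm| >= |d_obs|}) / (1 + n_perm)`.
#'
#' @param table A tidy trait table.
#' @param trait Trait to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `corallux_permtest` object with [tidy()] and [glance()] methods.
#' @export
blocked_permutation_test <- function(table, trait, n_perm = 999, seed = 1L) {
  check_trait_table(table)
  if (n_perm < 99) abort("n_perm must be at least 99")
  cm <- colony_means(table)
  cm <- cm[cm$trait == trait, ]
  if (nrow(cm) == 0) abort(paste("trait not present in table:", trait))
  groups <- pick_reference(cm$depth_group)
  if (length(groups) != 2) abort("expected exactly two depth groups")
  v <- cm$value
  is1 <- cm$depth_group == groups[1]
  n1 <- sum(is1)
  obs <- mean(v[is1]) - mean(v[!is1])

  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- length(v)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    mean(v[idx]) - mean(v[-idx])
  }, 1)
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  structure(list(trait = trait, estimate = obs, p_value = p,
                 n_perm = n_perm, n_colonies = n,
                 groups = groups, seed = seed),
            class = "corallux_permtest")
}

#' @export
print.corallux_permtest <- function(x, ...) {
  cat(sprintf("Colony-blocked permutation test: %s\n", x$trait))
  cat(sprintf("  mean difference (%s - %s) = %.4g, p = %.4g (%d permutations, %d colonies)\n",
              x$groups[1], x$groups[2], x$estimate, x$p_value, x$n_perm, x$n_colonies))
  invisible(x)
}

#' @export
tidy.corallux_permtest <- function(x, ...) {
  tibble::tibble(trait = x$trait, estimate = x$estimate, p.value = x$p_value,
                 n.perm = x$n_perm, n.colonies = x$n_colonies)
}

#' Principal coordinates analysis of colony trait means
#'
#' Classical scaling on Euclidean distances of pooled-standardized colony
#' means (equivalent to PCA of the standardized matrix). Constant traits are
#' dropped with a warning; negative eigenvalues — impossible for Euclidean
#' input — would be clamped to zero with a warning if user-supplied distances
#' ever produced them.
#'
#' @param table A tidy trait table (>= 3 colonies).
#' @return A `corallux_pcoa`: `scores` tibble (sample, group, Axis columns),
#'   `explained` per-axis fraction of variance, `loadings` trait-axis Pearson
#'   correlations with an `above_null_contribution` flag (axis share of
#'   absolute loading exceeding 1/n_traits, a reporting convention only).
#' @export
trait_pcoa <- function(table) {
  mt <- colony_matrix(table)
  if (nrow(mt$X) < 3) abort("PCoA needs at least 3 colonies")
  Z <- standardize_traits(mt$X)
  D <- dist(Z)
  k <- min(nrow(Z) - 1L, ncol(Z))
  fit <- cmdscale(D, k = k, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warn("negative PCoA eigenvalues clamped to zero")
  }
  eig <- pmax(eig, 0)
  pos <- eig[eig > 0]
  explained <- eig[seq_len(ncol(fit$points))] / sum(pos)
  scores <- fit$points
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  loadings <- cor(Z, scores)
  share <- abs(loadings)
  share <- sweep(share, 2, colSums(share), "/")
  structure(list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = mt$sample_id, depth_group = mt$group),
      tibble::as_tibble(scores)),
    explained = explained,
    loadings = loadings,
    loading_share = share,
    above_null_contribution = share > 1 / ncol(Z),
    eig = eig
  ), class = "corallux_pcoa")
}

#' @export
print.corallux_pcoa <- function(x, ...) {
  cat("<corallux_pcoa>\n  explained fractions:",
      paste(sprintf("%.3f", head(x$explained, 4)), collapse = " "), "\n")
  invisible(x)
}

#' @export
glance.corallux_pcoa <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$explained),
                 explained_fraction = x$explained,
                 cumulative = cumsum(x$explained))
}

#' PERMANOVA of depth-group effect on colony trait means
#'
#' Pseudo-F from the among/within partition of squared Euclidean distances on
#' pooled-standardized colony means; the p-value permutes whole colony labels
#' with the add-one correction, or enumerates all label assignments when
#' `n_perm = "exhaustive"`.
#'
#' @param table A tidy trait table.
#' @param n_perm Number of permutations (>= 99), or `"exhaustive"`.
#' @param seed Integer seed (ignored for exhaustive enumeration).
#' @return A `corallux_permanova` object with [tidy()].
#' @export
trait_permanova <- function(table, n_perm = 999, seed = 1L) {
  mt <- colony_matrix(table)
  groups <- mt$group
  lv <- unique(groups)
  if (length(lv) != 2) abort("expected exactly two depth groups")
  for (g in lv) if (sum(groups == g) == 0) abort(paste("group has no colonies:", g))
  Z <- standardize_traits(mt$X)
  D2 <- as.matrix(dist(Z))^2
  n <- nrow(Z)

  pseudo_f <- function(grp) {
    ss_t <- sum(D2[upper.tri(D2)]) / n
    ss_w <- 0
    for (g in lv) {
      sel <- grp == g
      ng <- sum(sel)
      if (ng > 1) ss_w <- ss_w + sum(D2[sel, sel][upper.tri(D2[sel, sel])]) / ng
    }
    ss_a <- ss_t - ss_w
    list(F = (ss_a / (length(lv) - 1)) / (ss_w / (n - length(lv))),
         ss_total = ss_t, ss_among = ss_a, ss_within = ss_w)
  }
  obs <- pseudo_f(groups)

  if (identical(n_perm, "exhaustive")) {
    n1 <- sum(groups == lv[1])
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      grp <- rep(lv[2], n); grp[idx] <- lv[1]
      pseudo_f(grp)$F
    })
    p <- mean(fs >= obs$F - 1e-12)
    n_used <- ncol(combos)
  } else {
    if (n_perm < 99) abort("n_perm must be at least 99")
    set.seed(as.integer(seed %% .Machine$integer.max))
    fs <- vapply(seq_len(n_perm), function(i) {
      pseudo_f(sample(groups))$F
    }, 1)
    p <- (1 + sum(fs >= obs$F - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = obs$F, p_value = p,
                 ss_among = obs$ss_among, ss_within = obs$ss_within,
                 ss_total = obs$ss_total,
                 df_among = length(lv) - 1, df_within = n - length(lv),
                 n_perm = n_used,
                 exhaustive = identical(n_perm, "exhaustive")),
            class = "corallux_permanova")
}

#' @export
print.corallux_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%s%d permutations)\n",
              x$pseudo_F, x$p_value, if (x$exhaustive) "exhaustive, " else "",
              x$n_perm))
  invisible(x)
}

#' @export
tidy.corallux_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("depth_group", "residual", "total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    sum_of_squares = c(x$ss_among, x$ss_within, x$ss_total),
    pseudo_F = c(x$pseudo_F, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
}

#' SIMPER: per-trait contribution to between-group dissimilarity
#'
#' Decomposes the average squared Euclidean distance between colonies of
#' different depth groups (on pooled-standardized colony means) into per-trait
#' components; contributions are reported as percentages summing to 100.
#'
#' @param table A tidy trait table.
#' @return A tibble sorted by contribution: `trait`, `contribution_pct`,
#'   `cumulative_pct`.
#' @export
trait_simper <- function(table) {
  mt <- colony_matrix(table)
  lv <- unique(mt$group)
  if (length(lv) != 2) abort("expected exactly two depth groups")
  Z <- standardize_traits(mt$X)
  A <- Z[mt$group == lv[1], , drop = FALSE]
  B <- Z[mt$group == lv[2], , drop = FALSE]
  contrib <- vapply(seq_len(ncol(Z)), function(j) {
    mean(outer(A[, j], B[, j], "-")^2)
  }, 1)
  pct <- 100 * contrib / sum(contrib)
  out <- tibble::tibble(trait = colnames(Z), contribution_pct = pct) |>
    dplyr::arrange(dplyr::desc(.data$contribution_pct)) |>
    dplyr::mutate(cumulative_pct = cumsum(.data$contribution_pct))
  out
}

#' Pearson correlation matrix of colony trait means
#'
#' @param table A tidy trait table (>= 3 colonies).
#' @return A symmetric trait x trait correlation matrix; zero-variance traits
#'   give `NA` entries with a warning.
#' @export
pearson_matrix <- function(table) {
  mt <- colony_matrix(table)
  if (nrow(mt$X) < 3) abort("correlations need at least 3 colonies")
  sds <- apply(mt$X, 2, sd)
  if (any(sds == 0, na.rm = TRUE)) {
    warn(paste("zero-variance trait(s) give NA correlations:",
               paste(names(which(sds == 0)), collapse = ", ")))
  }
  suppressWarnings(cor(mt$X))
}
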