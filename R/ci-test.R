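#' Likelihood-ratio test of (conditional) independence between a discrete
#' factor and a functional dynamic target
#'
#' Tests `X _||_ Y | A` where `Y` is a curve-valued target. Under the null
#' the mean-curve parameters depend only on the configuration of the
#' conditioning set `A` (a single pooled fit when `A` is empty); under the
#' alternative they depend on the configuration of `A` and `X` jointly. With
#' iid Gaussian errors and profiled variance the statistic is
#' `LR = nq * (log RSS0 - log RSS1)`, asymptotically chi-squared with degrees
#' of freedom equal to the difference in free-parameter counts, i.e.
#' `arity * (#configs(A, X) - #configs(A))`.
#'
#' Configurations are the *observed* joint levels, so empty cells drop out of
#' both fits symmetrically. A configuration cell with fewer samples than
#' `min_cell` is treated as too sparse to support a parameter set of its own
#' and its samples are dropped from *both* fits (the same symmetric
#' treatment as an empty cell; the count is reported as `n_dropped`). If
#' after dropping, the factor adds no grouping information at all, the test
#' is degenerate: it returns `lr = 0`, `p = 1` and `insufficient = TRUE`,
#' which call sites treat as a non-rejection — a conservative choice that
#' avoids fabricating causes from unfittable strata.
#'
#' The alternative optimisation always includes the null's fitted parameters
#' among its starting points, which guarantees `LR >= 0` numerically.
#'
#' @param factors data frame of discrete factor columns (one row per sample).
#' @param x name of the factor column under test.
#' @param a character vector of conditioning column names (may be empty).
#' @param target a [functional_target()].
#' @param family a [growth_family()].
#' @param control a [growth_control()].
#' @param min_cell smallest fittable cell size; defaults to `family$arity`.
#' @param fit_cache optional environment memoising fits by grouping columns
#'   (used by [data_tester()] so repeated groupings across tests are fitted
#'   once); only exact-data fits (no dropped cells) are cached.
#' @return a list of class `lr_result`: `lr`, `df`, `p_value`,
#'   `n_params_null`, `n_params_alt`, `insufficient`, plus the two fits.
#' @export
lr_conditional_test <- function(factors, x, a = character(0), target, family,
                                control = growth_control(), min_cell = NULL,
                                fit_cache = NULL) {
  if (x %in% a) stop("x must not be part of the conditioning set")
  n <- nrow(target$curves)
  q <- length(target$times)
  stopifnot(nrow(factors) == n)
  min_cell <- min_cell %||% family$arity
  g_alt_all <- config_labels(factors, c(a, x))
  cells <- table(g_alt_all)
  keep_cells <- names(cells)[cells >= min_cell]
  keep <- g_alt_all %in% keep_cells
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    factors <- factors[keep, , drop = FALSE]
    target <- functional_target(target$curves[keep, , drop = FALSE], target$times)
    n <- nrow(target$curves)
  }
  g_null <- config_labels(factors, a)
  g_alt <- config_labels(factors, c(a, x))
  cacheable <- !is.null(fit_cache) && n_dropped == 0
  cache_get <- function(cols) {
    if (cacheable) fit_cache[[paste0("k:", paste(sort(cols), collapse = "\r"))]] else NULL
  }
  cache_put <- function(cols, fit) {
    if (cacheable) fit_cache[[paste0("k:", paste(sort(cols), collapse = "\r"))]] <- fit
    invisible(NULL)
  }
  if (n == 0 || length(unique(g_alt)) == length(unique(g_null))) {
    # degenerate: X adds no grouping information (constant X, X determined
    # by A, or every extra cell was too sparse)
    if (n == 0) {
      np <- family$arity + 1L
      return(new_lr_result(0, 0L, 1, np, np, TRUE, NULL, NULL, x, a, n_dropped))
    }
    fit0 <- cache_get(a)
    if (is.null(fit0)) {
      fit0 <- fit_curve(target, family, g_null, control)
      cache_put(a, fit0)
    }
    return(new_lr_result(0, 0L, 1, fit0$n_params, fit0$n_params, n_dropped > 0,
                         fit0, fit0, x, a, n_dropped))
  }
  insufficient <- FALSE
  ctl0 <- control
  ctl0$n_starts <- 0L  # refinement passes: warm starts only
  fit0 <- cache_get(a)
  if (is.null(fit0)) {
    fit0 <- fit_curve(target, family, g_null, control)
    cache_put(a, fit0)
  }
  # warm-start every alternative cell from its null parent's estimate
  warm <- lapply(unique(g_alt), function(gl) {
    parent <- g_null[match(gl, g_alt)]
    fit0$theta_by_group[[parent]]
  })
  names(warm) <- unique(g_alt)
  fit1_cached <- cache_get(c(a, x))
  if (is.null(fit1_cached)) {
    fit1 <- fit_curve(target, family, g_alt, control, warm_starts = warm)
  } else {
    # refine the cached alternative with the current null's solutions
    warm1 <- lapply(unique(g_alt), function(gl) {
      c(list(fit1_cached$theta_by_group[[gl]]), warm[gl])
    })
    names(warm1) <- unique(g_alt)
    fit1 <- fit_curve(target, family, g_alt, ctl0, warm_starts = warm1)
    if (fit1_cached$rss < fit1$rss) fit1 <- fit1_cached
  }
  cache_put(c(a, x), fit1)
  # symmetric warm start: offer the alternative's solutions back to the null,
  # so a deeper optimum found by one side cannot masquerade as a group effect
  warm0 <- lapply(unique(g_null), function(gl) {
    kids <- unique(g_alt[g_null == gl])
    c(list(fit0$theta_by_group[[gl]]), unname(fit1$theta_by_group[kids]))
  })
  names(warm0) <- unique(g_null)
  fit0b <- fit_curve(target, family, g_null, ctl0, warm_starts = warm0)
  if (fit0b$rss < fit0$rss) fit0 <- fit0b
  cache_put(a, fit0)
  lr <- (n * q) * (log(fit0$rss) - log(fit1$rss))
  if (lr < 0) {
    if (lr < -1e-3) warning("negative LR statistic clamped to zero (optimizer tolerance)")
    lr <- 0
  }
  df <- fit1$n_params - fit0$n_params
  p <- if (df > 0) pchisq(lr, df, lower.tail = FALSE) else 1
  new_lr_result(lr, df, p, fit0$n_params, fit1$n_params, insufficient,
                fit0, fit1, x, a, n_dropped)
}

#' @rdname lr_conditional_test
#' @export
lr_independence_test <- function(factors, x, target, family,
                                 control = growth_control(), min_cell = NULL,
                                 fit_cache = NULL) {
  lr_conditional_test(factors, x, character(0), target, family, control,
                      min_cell, fit_cache)
}

new_lr_result <- function(lr, df, p, np0, np1, insufficient, fit0, fit1, x, a,
                          n_dropped = 0L) {
  structure(list(lr = lr, df = as.integer(df), p_value = p,
                 n_params_null = np0, n_params_alt = np1,
                 insufficient = insufficient, n_dropped = as.integer(n_dropped),
                 x = x, a = a, fit_null = fit0, fit_alt = fit1),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cond <- if (length(x$a) > 0) paste(" |", paste(x$a, collapse = ", ")) else ""
  cat("<lr_result> ", x$x, " vs target", cond, ": LR = ", signif(x$lr, 5),
      ", df = ", x$df, ", p = ", signif(x$p_value, 4),
      if (x$insufficient) " [insufficient data]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.lr_result <- function(x, ...) {
  tibble::tibble(x = x$x, conditioning = paste(x$a, collapse = ","),
                 lr = x$lr, df = x$df, p_value = x$p_value,
                 n_params_null = x$n_params_null, n_params_alt = x$n_params_alt,
                 insufficient = x$insufficient, n_dropped = x$n_dropped)
}

# joint configuration label per sample, using observed levels only; the
# empty set gets a constant (non-empty: empty strings cannot be matched as
# list names) label
config_labels <- function(factors, cols) {
  if (length(cols) == 0) return(rep("all", nrow(factors)))
  do.call(paste, c(lapply(cols, function(cl) as.character(factors[[cl]])), sep = "\r"))
}

#' Stratified G-squared test of conditional independence between two
#' discrete factors
#'
#' A likelihood-ratio test on the contingency table of `xi` and `xj`
#' stratified by the joint configurations of `z`. Zero-count rows and
#' columns are dropped per stratum, and each observed stratum contributes
#' `(K_i - 1)(K_j - 1)` degrees of freedom with the stratum's observed level
#' counts.
#'
#' @param factors data frame of discrete factor columns.
#' @param xi,xj names of the two factor columns.
#' @param z character vector of stratifying column names (may be empty).
#' @return a list with `statistic`, `df`, `p_value`.
#' @export
discrete_ci_test <- function(factors, xi, xj, z = character(0)) {
  strata <- config_labels(factors, z)
  xiv <- as.character(factors[[xi]])
  xjv <- as.character(factors[[xj]])
  g2 <- 0
  df <- 0L
  for (s in unique(strata)) {
    rows <- strata == s
    tab <- table(xiv[rows], xjv[rows])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    g2 <- g2 + 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
    df <- df + (nrow(tab) - 1L) * (ncol(tab) - 1L)
  }
  p <- if (df > 0) pchisq(g2, df, lower.tail = FALSE) else 1
  list(statistic = g2, df = df, p_value = p)
}
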