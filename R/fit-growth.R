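#' Control settings for grouped growth-curve fits
#'
#' @param n_starts number of quasi-random multi-start points per group fit
#'   (drawn deterministically from a Halton sequence over the data-driven
#'   parameter box); the box midpoint and any warm starts are always added.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param aic_variant `"printed"` puts `RSS/q` inside the AIC log term;
#'   `"per_observation"` uses `RSS/(nq)`.
#' @param error_model `"iid"` treats the residuals at all time points as
#'   independent Gaussians with a pooled variance; `"random_walk"` assumes
#'   the error curve is a Gaussian random walk started at zero, in which
#'   case fitting and likelihood evaluation work on the first-differenced
#'   curves (whose errors are exactly iid), leaving parameter counts,
#'   degrees of freedom and all test statistics' formulas unchanged.
#' @param seed integer seed controlling any tie-breaking; the optimiser
#'   itself is deterministic.
#' @return a list of class `growth_control`.
#' @export
growth_control <- function(n_starts = 10L, max_iter = 100L,
                           aic_variant = c("printed", "per_observation"),
                           error_model = c("iid", "random_walk"),
                           seed = 1L) {
  structure(list(n_starts = as.integer(n_starts), max_iter = as.integer(max_iter),
                 aic_variant = match.arg(aic_variant),
                 error_model = match.arg(error_model), seed = as.integer(seed)),
            class = "growth_control")
}

# working response under the error model: identity for iid, first
# differences (keeping the first observation) for the random walk
transform_curves <- function(curves, error_model) {
  if (error_model == "iid") return(curves)
  cbind(curves[, 1, drop = FALSE], t(diff(t(curves))))
}

# least-squares fit of one mean profile: minimises sum_t w_t (zbar_t - m_t)^2
# where zbar is the (possibly differenced) group mean and m the model mean on
# the same scale; the parameter box comes from the raw-scale profile.
# Multi-start Levenberg-Marquardt within bounds.
fit_mean_profile <- function(times, ybar, zbar, w, family, control, warm = NULL) {
  box <- family$start_box(times, ybar)
  lower <- box$lower; upper <- box$upper
  d <- family$arity
  sw <- sqrt(w)
  em <- control$error_model %||% "iid"
  q <- length(times)
  model_mean <- if (em == "iid") {
    function(theta) family$mean(times, theta)
  } else {
    function(theta) {
      mu <- family$mean(times, theta)
      mu - c(0, mu[-q])
    }
  }
  resid_fn <- function(theta) sw * (zbar - model_mean(theta))
  jac_fn <- NULL
  if (!is.null(family$jac)) {
    jac_fn <- if (em == "iid") {
      function(theta) -sw * family$jac(times, theta)
    } else {
      function(theta) {
        j <- family$jac(times, theta)
        jd <- j
        jd[-1, ] <- j[-1, , drop = FALSE] - j[-q, , drop = FALSE]
        -sw * jd
      }
    }
  }
  starts <- list((lower + upper) / 2)
  if (control$n_starts > 0) {
    h <- halton_matrix(control$n_starts, d)
    for (i in seq_len(control$n_starts)) {
      starts[[length(starts) + 1]] <- lower + h[i, ] * (upper - lower)
    }
  }
  if (!is.null(warm)) {
    for (th in warm) starts[[length(starts) + 1]] <- pmin(pmax(th, lower), upper)
  }
  best <- NULL
  best_ss <- Inf
  converged <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = th0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = control$max_iter))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) {
      best_ss <- ss
      best <- fit$par
      converged <- fit$info %in% 1:4
    }
  }
  # warm starts must never be beaten by their own objective value
  if (!is.null(warm)) {
    for (th in warm) {
      if (length(th) != d || anyNA(th)) next
      ss <- sum(resid_fn(pmin(pmax(th, lower), upper))^2)
      if (is.finite(ss) && ss < best_ss) {
        best_ss <- ss
        best <- pmin(pmax(th, lower), upper)
        converged <- TRUE
      }
    }
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, d), ss = Inf, converged = FALSE))
  }
  names(best) <- family$params
  list(theta = best, ss = best_ss, converged = converged)
}

#' Fit a growth family to grouped curve data
#'
#' Estimates one parameter vector per group by nonlinear least squares,
#' pooling all samples of a group. The objective is the total residual sum
#' of squares over samples and time points; because every curve in a group
#' shares a mean profile, each group is fitted to its pointwise mean curve
#' weighted by group size, and the (fixed) within-group scatter is added back
#' to the reported RSS — algebraically identical to the full objective.
#'
#' The error model is iid Gaussian across all residuals with a single pooled
#' variance, so `n_params = n_groups * arity + 1` — e.g. 13 free parameters
#' for one binary grouping variable under the Double-Logistic family.
#'
#' @param target a [functional_target()].
#' @param family a [growth_family()].
#' @param groups vector of group labels, one per sample (a single group when
#'   `NULL`).
#' @param control a [growth_control()].
#' @param warm_starts optional named list (group level -> numeric theta, or a
#'   list of thetas) of additional starting values; used by the nested
#'   likelihood-ratio tests so an alternative fit never falls below its null.
#' @return an object of class `growth_fit` with components `family`,
#'   `theta_by_group`, `n_by_group`, `rss`, `sigma2`, `loglik`, `n_params`,
#'   `aic` and per-group `converged` flags.
#' @export
fit_curve <- function(target, family, groups = NULL, control = growth_control(),
                      warm_starts = NULL) {
  stopifnot(inherits(target, "functional_target"), inherits(family, "growth_family"))
  n <- nrow(target$curves)
  q <- length(target$times)
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("groups must have one label per sample")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  em <- control$error_model %||% "iid"
  zcurves <- transform_curves(target$curves, em)
  theta_by_group <- list()
  converged <- logical(0)
  n_by_group <- integer(0)
  rss <- 0
  for (g in lev) {
    rows <- which(groups == g)
    ng <- length(rows)
    sub <- target$curves[rows, , drop = FALSE]
    zsub <- zcurves[rows, , drop = FALSE]
    ybar <- colMeans(sub)
    zbar <- colMeans(zsub)
    ssw <- sum(sweep(zsub, 2, zbar)^2)
    warm <- NULL
    if (!is.null(warm_starts)) {
      wg <- warm_starts[[g]]
      if (!is.null(wg)) warm <- if (is.list(wg)) wg else list(wg)
    }
    f <- fit_mean_profile(target$times, ybar, zbar, rep(ng, q), family, control, warm = warm)
    theta_by_group[[g]] <- f$theta
    converged[g] <- f$converged
    n_by_group[g] <- ng
    rss <- rss + f$ss + ssw
  }
  nq <- n * q
  n_params <- length(lev) * family$arity + 1L
  sigma2 <- rss / nq
  loglik <- -nq / 2 * (log(2 * pi * sigma2) + 1)
  aic <- growth_aic(rss, n, q, n_params, control$aic_variant)
  structure(list(
    family = family, theta_by_group = theta_by_group, group_levels = lev,
    n_by_group = n_by_group, times = target$times, rss = rss, sigma2 = sigma2,
    loglik = loglik, n_params = n_params, aic = aic,
    aic_variant = control$aic_variant, error_model = em,
    converged = converged, n = n, q = q
  ), class = "growth_fit")
}

growth_aic <- function(rss, n, q, n_params, variant = "printed") {
  nq <- n * q
  denom <- if (variant == "printed") q else nq
  nq + nq * log(2 * pi) + nq * log(rss / denom) + 2 * n_params
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> family ", x$family$name, ", ", length(x$group_levels),
      " group(s), RSS = ", signif(x$rss, 5), ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  if (!all(x$converged)) {
    cat("  warning: optimiser flagged non-convergence for group(s): ",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, groups = NULL, times = NULL, ...) {
  times <- times %||% object$times
  if (is.null(groups)) groups <- object$group_levels
  groups <- as.character(groups)
  out <- matrix(NA_real_, length(groups), length(times))
  for (i in seq_along(groups)) {
    th <- object$theta_by_group[[groups[i]]]
    if (is.null(th)) next
    out[i, ] <- growth_mean(object$family, times, th)
  }
  rownames(out) <- NULL
  out
}

#' Broom-style accessors for growth fits
#'
#' `tidy()` returns one row per group and parameter; `glance()` returns the
#' one-row model summary.
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  rows <- purrr::map_dfr(x$group_levels, function(g) {
    tibble::tibble(group = g, term = x$family$params,
                   estimate = as.numeric(x$theta_by_group[[g]]))
  })
  rows
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(family = x$family$name, n_groups = length(x$group_levels),
                 n_params = x$n_params, rss = x$rss, sigma2 = x$sigma2,
                 logLik = x$loglik, AIC = x$aic,
                 converged = all(x$converged))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Serialize a growth fit to JSON
#'
#' Writes the family, per-group parameter estimates and the fit summary
#' (RSS, variance, log-likelihood, parameter count, AIC) as plain JSON.
#'
#' @param fit a `growth_fit`.
#' @param path file path.
#' @export
write_growth_fit_json <- function(fit, path) {
  obj <- list(
    family = fit$family$name,
    params = fit$family$params,
    theta_by_group = lapply(fit$theta_by_group, as.numeric),
    n_by_group = as.list(fit$n_by_group),
    rss = fit$rss, sigma2 = fit$sigma2, loglik = fit$loglik,
    n_params = fit$n_params, aic = fit$aic,
    aic_variant = fit$aic_variant, error_model = fit$error_model,
    converged = as.list(fit$converged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select a growth family by AIC
#'
#' Fits each candidate family and returns the one minimising the AIC
#' criterion `nq + nq log(2*pi) + nq log(RSS/q) + 2 |Theta|` (with
#' `|Theta|` counting all free parameters including the error variance).
#' Ties are broken by fewest parameters, then family name.
#'
#' @inheritParams fit_curve
#' @param candidates list of [growth_family()] objects (or family names).
#' @return the selected `growth_family`, with the comparison table in
#'   attribute `"selection"`.
#' @export
select_family <- function(target, candidates, groups = NULL, control = growth_control()) {
  if (length(candidates) == 0) stop("at least one candidate family is required")
  candidates <- lapply(candidates, function(f) {
    if (inherits(f, "growth_family")) f else growth_family(f)
  })
  rows <- purrr::map_dfr(candidates, function(fam) {
    fit <- tryCatch(fit_curve(target, fam, groups, control), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$aic)) {
      tibble::tibble(family = fam$name, n_params = NA_integer_, rss = NA_real_, aic = NA_real_)
    } else {
      tibble::tibble(family = fam$name, n_params = fit$n_params, rss = fit$rss, aic = fit$aic)
    }
  })
  ok <- which(is.finite(rows$aic))
  if (length(ok) == 0) stop("all candidate families failed to fit")
  ord <- ok[order(rows$aic[ok], rows$n_params[ok], rows$family[ok])]
  sel <- candidates[[ord[1]]]
  attr(sel, "selection") <- rows
  sel
}

#' Plot a fitted growth model over the observed curves
#'
#' @param object a `growth_fit`.
#' @param target optional [functional_target()] with the observed curves.
#' @param groups optional per-sample group labels matching `target`.
#' @param ... unused.
#' @export
autoplot.growth_fit <- function(object, target = NULL, groups = NULL, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()")
  }
  tgrid <- seq(min(object$times), max(object$times), length.out = 100)
  fitted <- purrr::map_dfr(object$group_levels, function(g) {
    tibble::tibble(group = g, time = tgrid,
                   mean = growth_mean(object$family, tgrid, object$theta_by_group[[g]]))
  })
  pl <- ggplot2::ggplot()
  if (!is.null(target)) {
    n <- nrow(target$curves)
    if (is.null(groups)) groups <- rep(object$group_levels[1], n)
    obs <- tibble::tibble(
      sample = rep(seq_len(n), each = length(target$times)),
      group = rep(as.character(groups), each = length(target$times)),
      time = rep(target$times, times = n),
      value = as.numeric(t(target$curves))
    )
    pl <- pl + ggplot2::geom_line(
      data = obs,
      ggplot2::aes(x = .data$time, y = .data$value,
                   group = .data$sample, colour = .data$group),
      alpha = 0.25, linewidth = 0.3)
  }
  pl +
    ggplot2::geom_line(
      data = fitted,
      ggplot2::aes(x = .data$time, y = .data$mean, colour = .data$group),
      linewidth = 1) +
    ggplot2::labs(x = "time", y = "target",
                  title = paste0("fitted ", object$family$name, " mean curves"))
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
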