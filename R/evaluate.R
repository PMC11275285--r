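#' Structure-recovery metrics
#'
#' Compares a learned cause set with the true one over `p` candidate
#' factors: `TP = |learned ∩ truth|`, `FP = |learned \ truth|`,
#' `FN = |truth \ learned|`, with `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)` (both 1 when their denominator is 0, so an
#' empty-vs-empty comparison scores perfect) and
#' `accuracy = (p - FP - FN) / p` — the fraction of factors classified
#' correctly as cause / non-cause.
#'
#' @param learned character vector of learned cause ids.
#' @param truth character vector of true cause ids.
#' @param p total number of candidate factors.
#' @return a one-row tibble with `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `accuracy`, `p`.
#' @examples
#' confusion_metrics(c("X1", "X2"), c("X2", "X3"), p = 10)
#' @export
confusion_metrics <- function(learned, truth, p) {
  learned <- unique(as.character(learned))
  truth <- unique(as.character(truth))
  stopifnot(p >= length(union(learned, truth)))
  tp <- length(intersect(learned, truth))
  fp <- length(setdiff(learned, truth))
  fn <- length(setdiff(truth, learned))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    accuracy = (p - fp - fn) / p,
    p = as.integer(p)
  )
}

#' Held-out prediction error of a fitted curve model
#'
#' Predicts each held-out sample's curve by the fitted mean of its group
#' and returns the mean squared error over samples and time points. Samples
#' whose configuration was never seen in the fit fall back to the pooled
#' (single-group) fit; their count is reported in attribute `"n_unseen"`.
#'
#' @param fit a `growth_fit` (grouped by the learned causes).
#' @param heldout a [functional_target()] of held-out curves.
#' @param configurations per-sample group labels for `heldout`, matching the
#'   groups used in `fit`.
#' @param fallback optional `growth_fit` with a single pooled group used for
#'   unseen configurations.
#' @return mean squared prediction error (numeric scalar).
#' @export
prediction_mse <- function(fit, heldout, configurations, fallback = NULL) {
  n <- nrow(heldout$curves)
  stopifnot(length(configurations) == n)
  configurations <- as.character(configurations)
  unseen <- !(configurations %in% fit$group_levels)
  pred <- matrix(NA_real_, n, length(heldout$times))
  if (any(!unseen)) {
    pred[!unseen, ] <- predict(fit, configurations[!unseen], heldout$times)
  }
  if (any(unseen)) {
    if (is.null(fallback)) stop("unseen configurations but no fallback fit supplied")
    pred[unseen, ] <- matrix(predict(fallback, fallback$group_levels[1], heldout$times),
                             sum(unseen), length(heldout$times), byrow = TRUE)
  }
  out <- mean((heldout$curves - pred)^2)
  attr(out, "n_unseen") <- sum(unseen)
  out
}

# one simulated replicate: generate, screen, run the requested methods,
# score direct causes (DC) and all causes (AC)
run_replicate <- function(config, rep_seed, methods = c("s_local", "ssl"),
                          alpha = NULL, family = growth_family("double_logistic"),
                          control = growth_control(error_model = "random_walk"), m = NULL,
                          heldout_n = 0L) {
  truth_seed <- derive_seed(rep_seed, 1)
  data_seed <- derive_seed(rep_seed, 2)
  cfg <- config
  cfg$seed <- truth_seed
  truth <- random_truth(cfg)
  dat <- sim_generate(truth, config$n, data_seed)
  alpha <- alpha %||% adaptive_alpha(config$p)
  tester <- data_tester(dat$factors, dat$target, family, alpha, control)
  scr <- screen_factors(dat$factors, dat$target, family, alpha, control = control)
  true_dc <- truth$parents
  true_ac <- ancestors(truth$dag, truth$target)
  m <- m %||% config$p
  rows <- list()
  learned_dc <- list()
  for (method in methods) {
    if (method == "s_local") {
      dc <- learn_direct_causes(scr, tester)
      loc <- pc_by_pc(tester, dc, m = m, target_name = "Y")
      ac <- loc$expanded
    } else if (method == "ssl") {
      res <- ssl(scr, tester, target_name = "Y")
      dc <- res$direct_causes
      ac <- res$all_causes
    } else {
      stop("unknown method: ", method)
    }
    learned_dc[[method]] <- dc
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(method = method, cause = "DC"),
      confusion_metrics(dc, true_dc, config$p)
    )
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(method = method, cause = "AC"),
      confusion_metrics(ac, true_ac, config$p)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_factors <- config$p
  out$n <- config$n
  mse <- NULL
  if (heldout_n > 0 && "s_local" %in% methods) {
    dc <- learned_dc[["s_local"]]
    test_dat <- sim_generate(truth, heldout_n, derive_seed(rep_seed, 3))
    fit_groups <- config_labels(dat$factors, sort(dc))
    fit <- fit_curve(dat$target, family, fit_groups, control)
    pooled <- fit_curve(dat$target, family, NULL, control)
    ho_groups <- config_labels(test_dat$factors, sort(dc))
    mse <- prediction_mse(fit, test_dat$target, ho_groups, fallback = pooled)
    correct <- setequal(dc, true_dc)
    mse <- tibble::tibble(mse = as.numeric(mse), dc_correct = correct,
                          n_unseen = attr(mse, "n_unseen"))
  }
  list(metrics = out, mse = mse, truth = truth, learned_dc = learned_dc)
}

#' Run a simulation experiment grid
#'
#' Replicates the synthetic-data study: for each configuration and
#' replicate, draw a ground truth and data set, screen, run the requested
#' methods, and score direct causes (DC) and all causes (AC) by
#' [confusion_metrics()]. For the local method the learned all-cause set is
#' the union of identified and possible causes of the target in the learned
#' local graph; for SSL it is the target's ancestor set in the learned
#' graph. Per-replicate records are kept in attribute `"replicates"`.
#'
#' @param grid list of [sim_config()] objects (or a single one).
#' @param reps replicates per configuration.
#' @param methods subset of `c("s_local", "ssl")`.
#' @param alpha significance level; default [adaptive_alpha()] per
#'   configuration.
#' @param seed master seed; every replicate seed derives from it.
#' @param family,control model family and fit control.
#' @param heldout_n if positive, also compute held-out prediction MSE for
#'   the local method's learned direct causes (attribute `"mse"`).
#' @return a tibble with mean `recall`, `precision`, `accuracy` per
#'   (p, n, method, cause-type).
#' @export
run_experiment <- function(grid, reps, methods = c("s_local", "ssl"),
                           alpha = NULL, seed = 1L,
                           family = growth_family("double_logistic"),
                           control = growth_control(error_model = "random_walk"),
                           heldout_n = 0L) {
  if (inherits(grid, "sim_config")) grid <- list(grid)
  stopifnot(reps >= 1)
  all_rows <- list()
  all_mse <- list()
  for (ci in seq_along(grid)) {
    config <- grid[[ci]]
    for (r in seq_len(reps)) {
      rep_seed <- derive_seed(seed, ci, r)
      res <- run_replicate(config, rep_seed, methods, alpha, family, control,
                           heldout_n = heldout_n)
      res$metrics$rep <- r
      all_rows[[length(all_rows) + 1]] <- res$metrics
      if (!is.null(res$mse)) {
        res$mse$rep <- r
        res$mse$p_factors <- config$p
        res$mse$n <- config$n
        all_mse[[length(all_mse) + 1]] <- res$mse
      }
    }
  }
  records <- dplyr::bind_rows(all_rows)
  summary <- records |>
    dplyr::group_by(.data$p_factors, .data$n, .data$method, .data$cause) |>
    dplyr::summarise(recall = mean(.data$recall), precision = mean(.data$precision),
                     accuracy = mean(.data$accuracy), .groups = "drop")
  attr(summary, "replicates") <- records
  if (length(all_mse) > 0) attr(summary, "mse") <- dplyr::bind_rows(all_mse)
  summary
}

#' Plot experiment metrics against sample size
#'
#' @param results the summary tibble from [run_experiment()].
#' @param cause `"DC"` or `"AC"`.
#' @export
plot_experiment <- function(results, cause = "DC") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_experiment()")
  }
  df <- results[results$cause == cause, , drop = FALSE]
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = cause, x = "sample size n")
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  parts <- lapply(c("recall", "precision", "accuracy"), function(mt) {
    tibble::tibble(p_factors = df$p_factors, n = df$n, method = df$method,
                   metric = mt, value = df[[mt]])
  })
  dplyr::bind_rows(parts)
}
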