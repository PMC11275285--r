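#' Adaptive significance level for high-dimensional screening
#'
#' The level shrinks with the number of potential factors so that the
#' screening stage gets stricter as the search space grows:
#' `alpha(p) = min(0.05, 5 / p)`, which gives 0.05 at p = 100 and 0.0005 at
#' p = 10,000, with the cap applying for small p.
#'
#' @param p number of potential factors (`p >= 1`).
#' @return the significance level.
#' @examples
#' adaptive_alpha(100)    # 0.05
#' adaptive_alpha(10000)  # 5e-4
#' @export
adaptive_alpha <- function(p) {
  stopifnot(p >= 1)
  min(0.05, 5 / p)
}

#' Stage-1 screening of factors marginally associated with the target
#'
#' Runs one marginal likelihood-ratio test per factor against the
#' curve-valued target and keeps the factors with `p < alpha` (the set
#' `X_sig`). Under faithfulness this set consists of all causes of the
#' target together with the descendants of those causes. No multiplicity
#' correction is applied; the adaptive level ([adaptive_alpha()]) plays that
#' role. Tests are independent of each other, so the result does not depend
#' on execution order.
#'
#' Either supply `factors` + `target` (data screening) or a `tester`
#' (e.g. the d-separation oracle), in which case the tester's surrogate
#' p-values are used.
#'
#' @param factors data frame of discrete factor columns.
#' @param target a [functional_target()].
#' @param family a [growth_family()].
#' @param alpha significance level; defaults to [adaptive_alpha()] at the
#'   number of factors.
#' @param tester optional `ci_tester` used instead of direct data tests.
#' @param control a [growth_control()].
#' @param min_cell smallest fittable level size (default `family$arity`);
#'   unfittable factors are flagged and excluded.
#' @return a `screen_result`: a tibble with columns `factor`, `p_value`,
#'   `significant`, `insufficient`, carrying `alpha` and the ordered
#'   significant set `xsig` as attributes.
#' @export
screen_factors <- function(factors = NULL, target = NULL,
                           family = growth_family("double_logistic"),
                           alpha = NULL, tester = NULL,
                           control = growth_control(), min_cell = NULL) {
  if (is.null(tester)) {
    stopifnot(!is.null(factors), !is.null(target))
    ids <- names(factors)
    alpha <- alpha %||% adaptive_alpha(length(ids))
    fit_cache <- new.env(parent = emptyenv())  # the pooled null is fitted once
    rows <- purrr::map_dfr(ids, function(x) {
      res <- lr_independence_test(factors, x, target, family, control, min_cell,
                                  fit_cache)
      tibble::tibble(factor = x, p_value = res$p_value,
                     insufficient = res$insufficient)
    })
  } else {
    ids <- tester$factor_ids
    alpha <- alpha %||% tester$alpha
    rows <- purrr::map_dfr(ids, function(x) {
      tibble::tibble(factor = x, p_value = tester$target_pvalue(x, character(0)),
                     insufficient = FALSE)
    })
  }
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(factor = character(0), p_value = numeric(0),
                           insufficient = logical(0))
  }
  rows$significant <- rows$p_value < alpha
  out <- rows[, c("factor", "p_value", "significant", "insufficient")]
  class(out) <- c("screen_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "xsig") <- out$factor[out$significant]
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> alpha = ", attr(x, "alpha"), "; ",
      sum(x$significant), " of ", nrow(x), " factors significant\n", sep = "")
  NextMethod()
}

#' Significant factor set of a screening result
#' @param screen a `screen_result`.
#' @return character vector of factor ids with `p < alpha`.
#' @export
xsig <- function(screen) attr(screen, "xsig")

# screened factors ordered by ascending association (descending p-value,
# ties by factor id) -- "weakest first", the order used to initialise DC
screen_order_weakest_first <- function(screen) {
  sig <- screen[screen$significant, , drop = FALSE]
  sig$factor[order(-sig$p_value, sig$factor)]
}

screen_pvalues <- function(screen) {
  setNames(screen$p_value, screen$factor)
}
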