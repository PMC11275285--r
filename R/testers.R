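#' Conditional-independence tester contract
#'
#' Discovery algorithms consult a tester for two kinds of queries: is factor
#' `X` independent of the curve-valued target given a factor set `A`
#' (`target` queries), and is factor `Xi` independent of factor `Xj` given
#' `Z` (`factor` queries). Two backends implement the contract:
#'
#' * [data_tester()] answers from data, via the likelihood-ratio tests
#'   ([lr_conditional_test()]) and the stratified G-squared test
#'   ([discrete_ci_test()]); a query is "independent" when `p >= alpha`.
#' * [oracle_tester()] answers exactly by d-separation on a known true DAG
#'   (the faithfulness idealisation), reporting p = 0 for dependence and
#'   p = 1 for independence.
#'
#' Both backends memoise queries and keep an ordered audit log
#' ([audit_log()]), so identical inputs yield identical query sequences.
#'
#' @name ci_tester
NULL

new_ci_tester <- function(type, alpha, factor_ids, target_pvalue, factor_pvalue) {
  structure(list(
    type = type, alpha = alpha, factor_ids = factor_ids,
    target_pvalue = target_pvalue, factor_pvalue = factor_pvalue,
    audit = new.env(parent = emptyenv())
  ), class = "ci_tester")
}

#' @export
print.ci_tester <- function(x, ...) {
  cat("<ci_tester> backend = ", x$type, ", alpha = ", x$alpha, ", ",
      length(x$factor_ids), " factors\n", sep = "")
  invisible(x)
}

audit_push <- function(tester, kind, x, other, cond, p, note = "") {
  log <- tester$audit$log %||% list()
  log[[length(log) + 1]] <- list(kind = kind, x = x, other = other,
                                 cond = sort(cond), p = p, note = note)
  tester$audit$log <- log
  invisible(NULL)
}

#' Ordered log of CI queries issued to a tester
#'
#' @param tester a `ci_tester`.
#' @return a tibble with one row per query: `kind`, `x`, `other`,
#'   `conditioning`, `p_value`, `independent`, `note`.
#' @export
audit_log <- function(tester) {
  log <- tester$audit$log %||% list()
  purrr::map_dfr(log, function(r) {
    tibble::tibble(kind = r$kind, x = r$x, other = r$other,
                   conditioning = paste(r$cond, collapse = ","),
                   p_value = r$p, independent = r$p >= tester$alpha,
                   note = r$note)
  })
}

# independence decisions used by the algorithms
tester_target_indep <- function(tester, x, a = character(0)) {
  tester$target_pvalue(x, a) >= tester$alpha
}

tester_factor_indep <- function(tester, xi, xj, z = character(0)) {
  tester$factor_pvalue(xi, xj, z) >= tester$alpha
}

#' d-separation oracle tester
#'
#' Answers every CI query exactly by d-separation on the true DAG, the
#' idealisation under which the identifiability theorems for the discovery
#' algorithms are exact. Requires the target vertex to have no children
#' (the functional dynamic target is a sink by assumption).
#'
#' @param g a `mixed_graph` DAG over the factors and the target (or a
#'   `ground_truth` from [random_truth()], whose DAG is used).
#' @param target the target vertex id (defaults to a `ground_truth`'s
#'   target).
#' @param alpha nominal level stored for interface compatibility (decisions
#'   are deterministic).
#' @return a `ci_tester`.
#' @export
oracle_tester <- function(g, target = NULL, alpha = 0.05) {
  if (inherits(g, "ground_truth")) {
    target <- target %||% g$target
    g <- g$dag
  }
  if (is.null(target)) stop("target vertex id is required")
  if (!is_dag(g)) stop("the oracle requires a DAG")
  if (length(children_of(g, target)) > 0) {
    stop("the target must have no children in the true DAG")
  }
  adj <- directed_adjacency(g)
  verts <- g$vertices
  factor_ids <- setdiff(verts, target)
  cache <- new.env(parent = emptyenv())
  ti <- match(target, verts)
  query <- function(xi, yi, zi) {
    key <- paste(xi, yi, paste(sort(zi), collapse = "."), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- dsep_engine(adj, xi, yi, zi)
    cache[[key]] <- val
    val
  }
  tester <- NULL
  target_pvalue <- function(x, a = character(0)) {
    indep <- query(match(x, verts), ti, match(a, verts))
    p <- if (indep) 1 else 0
    audit_push(tester, "target", x, target, a, p)
    p
  }
  factor_pvalue <- function(xi, xj, z = character(0)) {
    indep <- query(match(xi, verts), match(xj, verts), match(z, verts))
    p <- if (indep) 1 else 0
    audit_push(tester, "factor", xi, xj, z, p)
    p
  }
  tester <- new_ci_tester("oracle", alpha, factor_ids, target_pvalue, factor_pvalue)
  tester
}

#' Data-backed tester
#'
#' Wraps a factor table and a functional target; target queries run the
#' likelihood-ratio test under `family`, factor queries run the stratified
#' G-squared test. Queries flagged "insufficient data" (an unfittable
#' configuration cell) report `p = 1`, i.e. a non-rejection, and are marked
#' in the audit log.
#'
#' @param factors data frame of discrete factor columns.
#' @param target a [functional_target()].
#' @param family a [growth_family()].
#' @param alpha significance level for independence decisions.
#' @param control a [growth_control()].
#' @param min_cell smallest fittable configuration cell (default
#'   `family$arity`).
#' @return a `ci_tester`.
#' @export
data_tester <- function(factors, target, family = growth_family("double_logistic"),
                        alpha = adaptive_alpha(ncol(factors)),
                        control = growth_control(), min_cell = NULL) {
  stopifnot(nrow(factors) == nrow(target$curves))
  cache <- new.env(parent = emptyenv())
  fit_cache <- new.env(parent = emptyenv())
  tester <- NULL
  target_pvalue <- function(x, a = character(0)) {
    key <- paste("T", x, paste(sort(a), collapse = "."), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- lr_conditional_test(factors, x, sort(a), target, family, control,
                               min_cell, fit_cache = fit_cache)
    p <- res$p_value
    note <- if (res$insufficient) "insufficient data"
            else if (res$n_dropped > 0) paste0("dropped ", res$n_dropped, " samples in sparse cells")
            else ""
    audit_push(tester, "target", x, "Y", a, p, note)
    cache[[key]] <- p
    p
  }
  factor_pvalue <- function(xi, xj, z = character(0)) {
    key <- paste("F", pair_key(xi, xj), paste(sort(z), collapse = "."), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- discrete_ci_test(factors, xi, xj, sort(z))
    audit_push(tester, "factor", xi, xj, z, res$p_value)
    cache[[key]] <- res$p_value
    res$p_value
  }
  tester <- new_ci_tester("data", alpha, names(factors), target_pvalue, factor_pvalue)
  tester
}
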