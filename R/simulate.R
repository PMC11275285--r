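#' Simulation configuration
#'
#' Describes one synthetic study condition: a random DAG over `p` discrete
#' factors (each forward edge included with probability
#' `expected_degree / (p - 1)` under a random vertex order), conditional
#' probability tables drawn from a flat Dirichlet, one or two direct causes
#' of the curve-valued target chosen uniformly, and a Double-Logistic mean
#' curve per parent configuration observed at `q` equally spaced time points
#' with random-walk noise of step standard deviation `noise_sd`.
#'
#' Per-configuration curve parameters are drawn as a common base curve plus
#' configuration-specific perturbations (genotype-like modulation of a
#' shared growth pattern); the pairwise root-mean-square distance between
#' configuration mean curves is forced to be at least `effect_separation`
#' so that distinct parent configurations are in principle detectable.
#'
#' @param p number of potential factors.
#' @param n default sample size for [sim_generate()].
#' @param q number of time points (default 24).
#' @param max_levels factor levels are drawn uniformly from `2:max_levels`.
#' @param expected_degree expected vertex degree of the factor DAG.
#' @param noise_sd step standard deviation of the random-walk noise.
#' @param effect_separation minimal RMS distance between the mean curves of
#'   two parent configurations.
#' @param n_parents candidate counts of direct causes (drawn uniformly).
#' @param seed integer seed; every draw is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(p, n, q = 24L, max_levels = 3L, expected_degree = 2,
                       noise_sd = 0.02, effect_separation = 0.05,
                       n_parents = c(1L, 2L), seed = 1L) {
  stopifnot(p >= 1, n >= 1, q >= 2, max_levels >= 2)
  structure(list(p = as.integer(p), n = as.integer(n), q = as.integer(q),
                 max_levels = as.integer(max_levels),
                 expected_degree = expected_degree, noise_sd = noise_sd,
                 effect_separation = effect_separation,
                 n_parents = as.integer(n_parents), seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a random ground truth
#'
#' Generates the full causal model: factor DAG, conditional probability
#' tables, the target's direct causes and one Double-Logistic parameter
#' vector per parent configuration. CPTs whose rows are (numerically)
#' identical across parent configurations are rejected and resampled, since
#' such a mechanism would make an edge exactly unfaithful.
#'
#' @param config a [sim_config()].
#' @return an object of class `ground_truth` with fields `dag` (a
#'   `mixed_graph` DAG over the factors and `"Y"`), `levels`, `cpts`,
#'   `parents` (direct causes of the target), `theta_map` (parent
#'   configuration -> Double-Logistic parameters), `noise_sd`, `times`.
#' @export
random_truth <- function(config) {
  with_local_seed(config$seed, {
    p <- config$p
    ids <- paste0("X", seq_len(p))
    ord <- sample(ids)  # topological order of the factor DAG
    pe <- if (p > 1) min(1, config$expected_degree / (p - 1)) else 0
    edges <- NULL
    if (p > 1) {
      tails <- character(0); heads <- character(0)
      for (i in seq_len(p - 1)) {
        picks <- which(runif(p - i) < pe)
        if (length(picks) > 0) {
          tails <- c(tails, rep(ord[i], length(picks)))
          heads <- c(heads, ord[i + picks])
        }
      }
      edges <- data.frame(tail = tails, head = heads, mark = "dir")
    }
    npar <- sample(rep(config$n_parents, 2), 1)
    parents <- sort(sample(ids, min(npar, p)))
    yedges <- data.frame(tail = parents, head = "Y", mark = "dir")
    alledges <- if (is.null(edges) || nrow(edges) == 0) yedges else rbind(edges, yedges)
    dag <- mixed_graph(c(ids, "Y"), alledges)
    lvl_choices <- seq.int(2L, config$max_levels)
    levels <- setNames(lvl_choices[sample.int(length(lvl_choices), p, replace = TRUE)], ids)
    cpts <- lapply(ids, function(v) draw_cpt(dag, v, levels))
    names(cpts) <- ids
    theta_map <- draw_theta_map(parents, levels, config)
    structure(list(dag = dag, target = "Y", order = ord, levels = levels,
                   cpts = cpts, parents = parents, theta_map = theta_map,
                   noise_sd = config$noise_sd, times = seq_len(config$q),
                   config = config),
              class = "ground_truth")
  })
}

# CPT for one factor: one Dirichlet(1) row per parent configuration;
# resampled if any two rows coincide numerically (exact unfaithfulness)
draw_cpt <- function(dag, v, levels) {
  pa <- sort(parents_of(dag, v))
  k <- levels[[v]]
  ncfg <- if (length(pa) == 0) 1L else prod(levels[pa])
  for (try in 1:100) {
    rows <- matrix(rgamma(ncfg * k, 1), ncfg, k)
    rows <- rows / rowSums(rows)
    if (ncfg == 1) break
    d <- as.matrix(stats::dist(rows, method = "manhattan"))
    if (min(d[upper.tri(d)]) > 1e-9) break
  }
  list(parents = pa, prob = rows)
}

dl_base_ranges <- list(
  a1 = c(0.5, 1.5), r1 = c(0.4, 1.2), c1 = c(0.2, 0.4),   # c as fraction of span
  a2 = c(0.5, 1.5), r2 = c(0.4, 1.2), c2 = c(0.6, 0.8)
)

dl_offset_scale <- c(a1 = 0.15, r1 = 0.15, c1 = 1.5, a2 = 0.15, r2 = 0.15, c2 = 1.5)

draw_theta_map <- function(parents, levels, config) {
  times <- seq_len(config$q)
  fam <- growth_family("double_logistic")
  cfgs <- parent_configs(parents, levels)
  span <- config$q
  for (try in 1:100) {
    base <- c(
      runif(1, dl_base_ranges$a1[1], dl_base_ranges$a1[2]),
      runif(1, dl_base_ranges$r1[1], dl_base_ranges$r1[2]),
      runif(1, dl_base_ranges$c1[1] * span, dl_base_ranges$c1[2] * span),
      runif(1, dl_base_ranges$a2[1], dl_base_ranges$a2[2]),
      runif(1, dl_base_ranges$r2[1], dl_base_ranges$r2[2]),
      runif(1, dl_base_ranges$c2[1] * span, dl_base_ranges$c2[2] * span)
    )
    thetas <- lapply(cfgs, function(cfg) {
      off <- runif(6, -1, 1) * dl_offset_scale
      th <- base + off
      th[c(1, 4)] <- pmax(th[c(1, 4)], 0.05)  # keep amplitudes positive
      th[c(2, 5)] <- pmax(th[c(2, 5)], 0.05)  # and rates
      setNames(th, fam$params)
    })
    names(thetas) <- cfgs
    if (length(cfgs) == 1) return(thetas)
    curves <- vapply(thetas, function(th) growth_mean(fam, times, th), numeric(length(times)))
    ok <- TRUE
    for (i in seq_len(ncol(curves) - 1)) for (j in (i + 1):ncol(curves)) {
      if (sqrt(mean((curves[, i] - curves[, j])^2)) < config$effect_separation) ok <- FALSE
    }
    if (ok) return(thetas)
  }
  stop("could not achieve the requested effect separation; lower effect_separation")
}

# all joint parent configurations as labels "l1\rl2\r..."
parent_configs <- function(parents, levels) {
  if (length(parents) == 0) return("")
  grids <- lapply(parents, function(p) seq_len(levels[[p]]))
  grid <- expand.grid(rev(grids))
  grid <- grid[, rev(seq_along(parents)), drop = FALSE]
  apply(grid, 1, function(r) paste(r, collapse = "\r"))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$levels), " factors, direct causes of Y: ",
      paste(x$parents, collapse = ", "), " (", length(x$theta_map),
      " parent configurations)\n", sep = "")
  invisible(x)
}

#' Generate data from a ground truth
#'
#' Samples the factors ancestrally from the conditional probability tables,
#' then builds each sample's curve as its parent configuration's
#' Double-Logistic mean plus an independent random walk started at zero
#' with Gaussian steps of standard deviation `truth$noise_sd`.
#'
#' @param truth a `ground_truth` from [random_truth()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return a list with `factors` (tibble of integer-coded factor columns),
#'   `target` (a [functional_target()]) and `configs` (the per-sample parent
#'   configuration labels of the target).
#' @export
sim_generate <- function(truth, n, seed = 1L) {
  with_local_seed(seed, {
    ids <- names(truth$levels)
    fac <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
    for (v in truth$order) {
      cpt <- truth$cpts[[v]]
      k <- truth$levels[[v]]
      if (length(cpt$parents) == 0) {
        fac[, v] <- sample.int(k, n, replace = TRUE, prob = cpt$prob[1, ])
      } else {
        cfg_idx <- config_row_index(fac[, cpt$parents, drop = FALSE], truth$levels[cpt$parents])
        u <- runif(n)
        cum <- t(apply(cpt$prob, 1, cumsum))
        fac[, v] <- vapply(seq_len(n), function(i) {
          sum(u[i] > cum[cfg_idx[i], ]) + 1L
        }, 1L)
      }
    }
    cfg <- if (length(truth$parents) == 0) rep("", n) else {
      apply(fac[, truth$parents, drop = FALSE], 1, function(r) paste(r, collapse = "\r"))
    }
    fam <- growth_family("double_logistic")
    q <- length(truth$times)
    mu <- vapply(truth$theta_map, function(th) growth_mean(fam, truth$times, th),
                 numeric(q))
    curves <- t(vapply(seq_len(n), function(i) {
      mu[, cfg[i]] + cumsum(rnorm(q, 0, truth$noise_sd))
    }, numeric(q)))
    list(factors = tibble::as_tibble(as.data.frame(fac)),
         target = functional_target(curves, truth$times),
         configs = cfg)
  })
}

# row index into a CPT's configuration grid (first parent varies slowest,
# matching parent_configs())
config_row_index <- function(values, levels) {
  ncfg <- prod(levels)
  idx <- rep(1L, nrow(values))
  mult <- ncfg
  for (j in seq_along(levels)) {
    mult <- mult / levels[[j]]
    idx <- idx + (values[, j] - 1L) * mult
  }
  as.integer(idx)
}

#' Serialize / restore a ground truth as JSON
#'
#' Plain-text round trip of the DAG edge list, levels, CPTs and curve
#' parameters.
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    vertices = truth$dag$vertices,
    edges = graph_edges(truth$dag),
    target = truth$target,
    order = truth$order,
    levels = as.list(truth$levels),
    parents = truth$parents,
    cpts = lapply(truth$cpts, function(c) list(parents = c$parents, prob = c$prob)),
    theta_map = lapply(truth$theta_map, as.numeric),
    theta_configs = names(truth$theta_map),
    noise_sd = truth$noise_sd,
    times = truth$times
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dag <- mixed_graph(obj$vertices, obj$edges)
  fam <- growth_family("double_logistic")
  theta_map <- lapply(seq_along(obj$theta_configs), function(i) {
    setNames(as.numeric(obj$theta_map[[i]]), fam$params)
  })
  names(theta_map) <- obj$theta_configs
  structure(list(dag = dag, target = obj$target, order = obj$order,
                 levels = setNames(unlist(obj$levels), names(obj$levels)),
                 cpts = setNames(lapply(obj$cpts, function(c) {
                   list(parents = as.character(unlist(c$parents)),
                        prob = as.matrix(c$prob))
                 }), names(obj$cpts)),
                 parents = as.character(obj$parents), theta_map = theta_map,
                 noise_sd = obj$noise_sd, times = as.numeric(obj$times)),
            class = "ground_truth")
}
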