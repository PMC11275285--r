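#' Discovery results
#'
#' Container returned by [ssl()] and [pc_by_pc()]: the learned mixed graph
#' over the involved vertices plus the target, the direct causes, the
#' identifiable causes (`all_causes`: ancestors of the target in the learned
#' graph) and the `possible_causes` (vertices reaching the target only
#' through partially directed paths).
#'
#' @name discovery_result
NULL

new_discovery_result <- function(method, graph, target, direct_causes, extra = list()) {
  res <- list(
    method = method, graph = graph, target = target,
    direct_causes = sort(direct_causes),
    all_causes = ancestors(graph, target),
    possible_causes = possible_ancestors(graph, target)
  )
  structure(c(res, extra), class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result> method = ", x$method, "\n",
      "  direct causes:   ", paste(x$direct_causes, collapse = ", "), "\n",
      "  all causes:      ", paste(x$all_causes, collapse = ", "), "\n",
      "  possible causes: ", paste(x$possible_causes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.discovery_result <- function(x, ...) {
  verts <- setdiff(x$graph$vertices, x$target)
  tibble::tibble(
    vertex = verts,
    direct_cause = verts %in% x$direct_causes,
    cause = verts %in% x$all_causes,
    possible_cause = verts %in% x$possible_causes
  )
}

# PC-style skeleton learning over a vertex set: start complete, remove edges
# by testing conditioning sets of growing size drawn from the current
# adjacencies of either endpoint, recording the first separating set found.
pc_skeleton <- function(tester, vertices) {
  vertices <- sort(vertices)
  g <- mixed_graph(vertices)
  p <- length(vertices)
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      g <- add_edge(g, vertices[i], vertices[j], "undir")
    }
  }
  store <- separation_store()
  l <- 0
  repeat {
    any_big_enough <- FALSE
    for (x in vertices) {
      for (y in vertices) {
        if (x >= y && l == 0) next  # unordered at l = 0 (empty set symmetric)
        if (x == y || !has_edge(g, x, y)) next
        adjx <- setdiff(neighbours_of(g, x), y)
        if (length(adjx) < l) next
        any_big_enough <- TRUE
        for (a in subsets_of_size(adjx, l)) {
          if (tester_factor_indep(tester, x, y, a)) {
            g <- remove_edge(g, x, y)
            sep_record(store, x, y, a)
            break
          }
        }
      }
    }
    l <- l + 1
    if (!any_big_enough) break
  }
  list(skeleton = g, store = store)
}

#' Screening and structural learning (SSL)
#'
#' Learns the causes of the functional dynamic target by full structural
#' learning over the screened factor set: a PC-style skeleton with
#' separation sets, v-structure orientation tolerant of bidirected edges,
#' deletion of bidirected edges followed by Meek closure, then a target
#' pruning loop. Every screened factor starts with a directed edge into the
#' target; an edge `X -> Y` is removed as soon as some conditioning set
#' `A` of the current direct-cause candidates (searched in growing size,
#' candidates ordered weakest-association-first) renders `X` independent of
#' the target.
#'
#' @param screen a `screen_result` from [screen_factors()].
#' @param tester a `ci_tester` ([data_tester()] or [oracle_tester()]).
#' @param target_name vertex id used for the target node in the learned
#'   graph.
#' @return a `discovery_result`; the element `cpdag_xsig` holds the learned
#'   graph over the screened factors before the target was attached.
#' @export
ssl <- function(screen, tester, target_name = "Y") {
  xs <- xsig(screen)
  if (length(xs) == 0) {
    g <- mixed_graph(target_name)
    return(new_discovery_result("ssl", g, target_name, character(0),
                                list(cpdag_xsig = mixed_graph(character(0)))))
  }
  if (target_name %in% xs) stop("target_name collides with a factor id")
  sk <- pc_skeleton(tester, xs)
  g <- orient_v_structures(sk$skeleton, sk$store)
  # delete all bidirected edges (screening artifacts), then Meek closure
  e <- graph_edges(g)
  bid <- e[e$mark == "bidir", , drop = FALSE]
  for (i in seq_len(nrow(bid))) g <- remove_edge(g, bid$tail[i], bid$head[i])
  g <- apply_meek_rules(g)
  cpdag_xsig <- g
  # attach the target with an edge from every screened factor, then prune
  gy <- mixed_graph(c(g$vertices, target_name), graph_edges(g))
  dc <- screen_order_weakest_first(screen)
  for (x in xs) gy <- add_edge(gy, x, target_name, "dir")
  k <- 1
  while (k < length(dc)) {
    for (x in dc) {
      if (!(x %in% dc)) next
      cand <- setdiff(dc, x)
      if (length(cand) < k) next
      for (a in subsets_of_size(cand, k)) {
        if (tester_target_indep(tester, x, a)) {
          gy <- remove_edge(gy, x, target_name)
          dc <- setdiff(dc, x)
          break
        }
      }
    }
    k <- k + 1
  }
  new_discovery_result("ssl", gy, target_name, dc, list(cpdag_xsig = cpdag_xsig))
}

#' Screening-based learning of direct causes
#'
#' Starts from the screened factors ordered weakest-association-first and
#' removes each factor `X` for which some conditioning set renders it
#' independent of the target. Candidate sets of size `k` are drawn from the
#' remaining candidates excluding `X` and excluding `N_X` — the factors that
#' `X` is known not to separate-with (whenever `A` separates `X` from the
#' target, `X` is added to `N_V` for every `V` in `A`, since `X` cannot in
#' turn belong to a separating set for those variables). Candidate sets are
#' searched strongest-association-first (a set scored by the smallest
#' screening p-value of its members, ties by member ids).
#'
#' @inheritParams ssl
#' @return sorted character vector of direct causes, with the per-variable
#'   exclusion sets in attribute `"exclusions"`.
#' @export
learn_direct_causes <- function(screen, tester) {
  dc <- screen_order_weakest_first(screen)
  pv <- screen_pvalues(screen)
  n_excl <- setNames(vector("list", length(dc)), dc)
  k <- 1
  while (k < length(dc)) {
    for (x in dc) {
      if (!(x %in% dc)) next
      cand <- setdiff(dc, c(x, n_excl[[x]]))
      if (length(cand) < k) next
      subs <- subsets_of_size(cand, k)
      score <- vapply(subs, function(a) min(pv[a]), 0)
      tie <- vapply(subs, paste, "", collapse = "|")
      subs <- subs[order(score, tie)]
      for (a in subs) {
        if (tester_target_indep(tester, x, a)) {
          dc <- setdiff(dc, x)
          for (v in a) n_excl[[v]] <- union(n_excl[[v]], x)
          break
        }
      }
    }
    k <- k + 1
  }
  out <- sort(dc)
  attr(out, "exclusions") <- n_excl
  out
}

#' Local parents-children-descendants (LPC) learning
#'
#' Learns the PCD set of a factor `t`: initialise with the factors outside
#' `u` marginally dependent on `t`, then repeatedly remove any member with a
#' separating subset of the current set (growing subset size), recording
#' each separation. The result contains `t`'s parents and children plus
#' possibly some non-child descendants (removed later by the symmetric
#' check in [pc_by_pc()]).
#'
#' @param tester a `ci_tester`.
#' @param t the factor id whose local set is learned.
#' @param u factor ids excluded from consideration.
#' @param store a [separation_store()] to extend (a fresh one by default).
#' @return a list with elements `pc` (sorted character vector) and `store`.
#' @export
lpc <- function(tester, t, u = character(0), store = separation_store()) {
  cand <- sort(setdiff(tester$factor_ids, c(t, u)))
  dep <- vapply(cand, function(x) !tester_factor_indep(tester, t, x), TRUE)
  pcd <- cand[dep]
  # a pair screened out marginally is separated by the empty set; the
  # orientation step needs that fact recorded just like any other separator
  for (x in cand[!dep]) sep_record(store, t, x, character(0))
  k <- 1
  while (k < length(pcd)) {
    for (x in pcd) {
      if (!(x %in% pcd)) next
      rest <- setdiff(pcd, x)
      if (length(rest) < k) next
      for (a in subsets_of_size(rest, k)) {
        if (tester_factor_indep(tester, t, x, a)) {
          pcd <- setdiff(pcd, x)
          sep_record(store, t, x, a)
          break
        }
      }
    }
    k <- k + 1
  }
  list(pc = pcd, store = store)
}

# single-pass orientation of the triples incident to a newly processed
# vertex x: for an unshielded triple whose end pair has a recorded
# separation set missing the middle vertex, arrowheads are placed into the
# middle. Already-directed edges are never re-oriented.
orient_local_triples <- function(g, x, store) {
  nb <- sort(neighbours_of(g, x))
  # V1 - x - V2  =>  V1 -> x <- V2
  if (length(nb) >= 2) {
    for (v1 in nb) for (v2 in nb) {
      if (v1 >= v2 || has_edge(g, v1, v2)) next
      s <- sep_set(store, v1, v2)
      if (!is.null(s) && !(x %in% s)) {
        if (edge_mark(g, v1, x) == "undir") { g <- remove_edge(g, v1, x); g <- add_edge(g, v1, x, "dir") }
        if (edge_mark(g, v2, x) == "undir") { g <- remove_edge(g, v2, x); g <- add_edge(g, v2, x, "dir") }
      }
    }
  }
  # x - V1 - V2 and x - V1 <- V2  =>  x -> V1 <- V2
  for (v1 in sort(neighbours_of(g, x))) {
    others <- sort(setdiff(adjacent_of(g, v1), x))
    for (v2 in others) {
      if (has_edge(g, x, v2)) next
      mk <- edge_mark(g, v2, v1)
      if (!(mk %in% c("undir", "dir"))) next  # need V1 - V2 or V2 -> V1
      s <- sep_set(store, x, v2)
      if (!is.null(s) && !(v1 %in% s)) {
        if (edge_mark(g, x, v1) == "undir") { g <- remove_edge(g, x, v1); g <- add_edge(g, x, v1, "dir") }
        if (mk == "undir") { g <- remove_edge(g, v2, v1); g <- add_edge(g, v2, v1, "dir") }
      }
    }
  }
  g
}

#' PC-by-PC: all causes of a target set within a given distance
#'
#' Expands outwards from the target's direct causes. An auxiliary node `L`
#' (the target) receives a directed edge from every member of `t`. Each
#' queued candidate has its PC set learned by [lpc()] (excluding the
#' already-processed vertices whose PC sets exclude it), asymmetric pairs
#' are deleted by the symmetric check, local triples are oriented, and when
#' the current frontier is exhausted a Meek closure runs and each frontier
#' vertex `V` enqueues its PC set — but only while the shortest path from
#' `V` to `L` is shorter than `m` edges, or the `m`-th edge nearest `L` on
#' that path is still undirected. The path length counts the edge into `L`,
#' so with `t` the direct causes of a target `Y` the procedure reaches all
#' causes of `Y` up to distance `m + 1`.
#'
#' @param tester a `ci_tester`.
#' @param t character vector: the target set (for a functional target, its
#'   direct causes from [learn_direct_causes()]).
#' @param m maximum distance (`>= 1`).
#' @param target_name vertex id for the auxiliary target node.
#' @return a `discovery_result`; element `expanded` lists every vertex that
#'   entered the queue and `store` the accumulated separation sets.
#' @export
pc_by_pc <- function(tester, t, m, target_name = "Y") {
  stopifnot(m >= 1)
  t <- sort(as.character(t))
  if (target_name %in% tester$factor_ids) stop("target_name collides with a factor id")
  if (length(t) == 0) {
    g <- mixed_graph(target_name)
    return(new_discovery_result("pc_by_pc", g, target_name, character(0),
                                list(expanded = character(0), store = separation_store())))
  }
  g <- mixed_graph(c(tester$factor_ids, target_name))
  for (ti in t) g <- add_edge(g, ti, target_name, "dir")
  store <- separation_store()
  pc <- list()
  canc <- t
  n <- 1L
  nprime <- 0L
  while (n <= length(canc)) {
    x <- canc[n]
    prev <- canc[seq_len(n - 1L)]
    u <- prev[!vapply(prev, function(v) x %in% pc[[v]], TRUE)]
    res <- lpc(tester, x, u, store)
    pcx <- res$pc
    for (v in intersect(pcx, prev)) {
      if (x %in% pc[[v]]) {
        if (!has_edge(g, x, v)) g <- add_edge(g, x, v, "undir")
      } else {
        pcx <- setdiff(pcx, v)
        pc[[v]] <- setdiff(pc[[v]], x)
      }
    }
    pc[[x]] <- pcx
    g <- orient_local_triples(g, x, store)
    if (n == length(canc)) {
      g <- apply_meek_rules(g)
      ring <- canc[(nprime + 1L):n]
      for (v in ring) {
        sp <- shortest_path(g, v, target_name)
        expand <- FALSE
        if (is.finite(sp$length)) {
          if (sp$length < m) {
            expand <- TRUE
          } else {
            pth <- sp$path
            len <- length(pth)
            expand <- edge_mark(g, pth[len - m], pth[len - m + 1]) == "undir"
          }
        }
        if (expand) canc <- c(canc, sort(setdiff(pc[[v]], canc)))
      }
      nprime <- n
    }
    n <- n + 1L
  }
  gi <- induced_subgraph(g, c(canc, target_name))
  new_discovery_result("pc_by_pc", gi, target_name, t,
                       list(expanded = canc, store = store))
}
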