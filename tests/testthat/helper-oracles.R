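# independent oracles used to validate the graph machinery:
# brute-force path enumeration for d-separation and exhaustive DAG-extension
# enumeration for CPDAG invariance. Deliberately naive implementations.

subsets_of_size_test <- function(x, k) curvecause:::subsets_of_size(x, k)

# random DAG as a mixed_graph: vertices V1..Vp in random topological order,
# each forward edge with probability prob
random_test_dag <- function(p, prob = 0.35) {
  ids <- paste0("V", seq_len(p))
  ord <- sample(ids)
  tails <- character(0); heads <- character(0)
  if (p >= 2) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < prob) { tails <- c(tails, ord[i]); heads <- c(heads, ord[j]) }
    }
  }
  if (length(tails) == 0) return(mixed_graph(ids))
  mixed_graph(ids, data.frame(tail = tails, head = heads, mark = "dir"))
}

# all simple paths between a and b on the skeleton (list of vertex vectors)
enumerate_paths <- function(g, a, b) {
  amat <- g$amat
  adj <- amat != 0L | t(amat) != 0L
  v <- g$vertices
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nx in v[adj[match(last, v), ]]) {
      if (!(nx %in% path)) walk(c(path, nx))
    }
  }
  walk(a)
  out
}

# textbook blocking definition applied to one path
path_blocked <- function(g, path, z) {
  if (length(path) <= 2) return(FALSE)
  for (k in 2:(length(path) - 1)) {
    mid <- path[k]
    into_mid <- edge_mark(g, path[k - 1], mid) == "dir"
    out_of_mid <- edge_mark(g, mid, path[k + 1]) == "dir"
    collider <- into_mid && !out_of_mid
    if (collider) {
      de <- descendants(g, mid, include_self = TRUE)
      if (length(intersect(de, z)) == 0) return(TRUE)
    } else {
      if (mid %in% z) return(TRUE)
    }
  }
  FALSE
}

# brute-force d-separation: every path between every x, y pair blocked
dsep_brute <- function(g, x, y, z) {
  for (a in x) for (b in y) {
    for (p in enumerate_paths(g, a, b)) {
      if (!path_blocked(g, p, z)) return(FALSE)
    }
  }
  TRUE
}

# all DAGs sharing g's skeleton and v-structures (g a DAG); returns list of
# mixed_graph DAGs. Exhaustive over edge orientations - small graphs only.
dag_equivalence_class <- function(g) {
  e <- graph_edges(g)
  m <- nrow(e)
  vstr <- v_structure_key(g)
  out <- list()
  if (m == 0) return(list(g))
  for (mask in 0:(2^m - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    tails <- ifelse(bits, e$head, e$tail)
    heads <- ifelse(bits, e$tail, e$head)
    cand <- mixed_graph(g$vertices, data.frame(tail = tails, head = heads, mark = "dir"))
    if (!is_dag(cand)) next
    if (identical(v_structure_key(cand), vstr)) out[[length(out) + 1]] <- cand
  }
  out
}

v_structure_key <- function(g) {
  vs <- curvecause:::v_structures_of(g)
  sort(vapply(vs, paste, "", collapse = "|"))
}

# compelled edges: identically oriented across the whole equivalence class
compelled_edges <- function(class) {
  e0 <- graph_edges(class[[1]])
  keep <- rep(TRUE, nrow(e0))
  for (h in class[-1]) {
    eh <- graph_edges(h)
    key <- paste(eh$tail, eh$head)
    keep <- keep & paste(e0$tail, e0$head) %in% key
  }
  e0[keep, , drop = FALSE]
}

# maximally oriented graph of a DAG given that the target's in-edges are
# known: CPDAG plus forced target edges plus Meek closure
bg_cpdag <- function(dag, target) {
  cp <- cpdag_of(dag)
  for (pa in parents_of(dag, target)) {
    if (edge_mark(cp, pa, target) == "undir") {
      cp <- remove_edge(cp, pa, target)
      cp <- add_edge(cp, pa, target, "dir")
    }
  }
  apply_meek_rules(cp)
}
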