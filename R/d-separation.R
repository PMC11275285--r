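#' d-separation in a DAG
#'
#' Tests whether every path between `x` and `y` is blocked by `z` under the
#' usual chain/fork/collider rules: a path is blocked if it contains a chain
#' or fork whose middle vertex is in `z`, or a collider none of whose
#' descendants (itself included) is in `z`.
#'
#' The implementation uses the classical reduction: `x` and `y` are
#' d-separated by `z` iff they are separated in the moralized induced
#' subgraph over the ancestral closure of `x`, `y` and `z`, with `z` removed.
#'
#' @param g a `mixed_graph` that is a DAG.
#' @param x,y,z character vectors of vertex ids; `x`, `y`, `z` must be
#'   pairwise disjoint and `x`, `y` non-empty.
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @examples
#' chain <- mixed_graph(c("A", "B", "C"),
#'                      data.frame(tail = c("A", "B"), head = c("B", "C")))
#' d_separated(chain, "A", "C", "B")  # TRUE
#' d_separated(chain, "A", "C", character(0))  # FALSE
#' @export
d_separated <- function(g, x, y, z = character(0)) {
  if (!is_dag(g)) stop("d_separated requires a DAG")
  xi <- vertex_index(g, x); yi <- vertex_index(g, y)
  zi <- if (length(z) > 0) vertex_index(g, z) else integer(0)
  if (length(intersect(xi, yi)) || length(intersect(xi, zi)) || length(intersect(yi, zi))) {
    stop("x, y, z must be pairwise disjoint")
  }
  dsep_engine(directed_adjacency(g), xi, yi, zi)
}

# adj[i, j] TRUE iff i -> j; xi, yi, zi integer index vectors
dsep_engine <- function(adj, xi, yi, zi) {
  p <- nrow(adj)
  # ancestral closure of x, y, z
  inset <- rep(FALSE, p)
  inset[c(xi, yi, zi)] <- TRUE
  frontier <- which(inset)
  while (length(frontier) > 0) {
    pa <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & !inset)
    inset[pa] <- TRUE
    frontier <- pa
  }
  keep <- which(inset)
  a <- adj[keep, keep, drop = FALSE]
  # moralize: connect co-parents, drop directions
  m <- a | t(a)
  if (nrow(a) > 1) {
    shared_child <- (a %*% t(a)) > 0
    m <- m | shared_child
  }
  diag(m) <- FALSE
  # remove conditioning vertices, then test connectivity x -> y
  zk <- match(zi, keep)
  if (length(zk) > 0) {
    m[zk, ] <- FALSE
    m[, zk] <- FALSE
  }
  xs <- match(xi, keep); ys <- match(yi, keep)
  reach <- rep(FALSE, nrow(m))
  reach[xs] <- TRUE
  frontier <- xs
  while (length(frontier) > 0) {
    nxt <- which(colSums(m[frontier, , drop = FALSE]) > 0 & !reach)
    if (any(nxt %in% ys)) return(FALSE)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  !any(reach[ys])
}
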