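#' Mixed graphs with directed, undirected and bidirected edges
#'
#' A `mixed_graph` stores a vertex set and at most one edge per unordered
#' vertex pair, each edge marked `"dir"` (tail -> head), `"undir"` or
#' `"bidir"`. The one structure serves as DAG, skeleton, PDAG and CPDAG;
#' bidirected edges arise when v-structure orientation places arrowheads at
#' both ends of an edge (a signature of a screened-out common cause) and are
#' deleted before Meek closure.
#'
#' Internally the graph is an integer mark matrix `amat` with
#' `amat[i, j] == 2` for `i -> j`, `1` on both sides for `i - j`, and `3` on
#' both sides for `i <-> j`.
#'
#' @param vertices character vector of vertex ids (insertion order is kept).
#' @param edges `NULL` or a data frame with columns `tail`, `head`, `mark`
#'   (`mark` in `c("dir", "undir", "bidir")`; missing `mark` defaults to
#'   `"dir"`).
#' @return an object of class `mixed_graph`.
#' @examples
#' g <- mixed_graph(c("A", "B", "C"),
#'                  data.frame(tail = c("A", "B"), head = c("B", "C"),
#'                             mark = c("dir", "undir")))
#' graph_edges(g)
#' @export
mixed_graph <- function(vertices, edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate vertex ids")
  p <- length(vertices)
  amat <- matrix(0L, p, p, dimnames = list(vertices, vertices))
  g <- structure(list(vertices = vertices, amat = amat), class = "mixed_graph")
  if (!is.null(edges) && nrow(edges) > 0) {
    mark <- if ("mark" %in% names(edges)) as.character(edges$mark) else rep("dir", nrow(edges))
    for (i in seq_len(nrow(edges))) {
      g <- add_edge(g, as.character(edges$tail[i]), as.character(edges$head[i]), mark[i])
    }
  }
  g
}

vertex_index <- function(g, v) {
  idx <- match(v, g$vertices)
  if (anyNA(idx)) stop("unknown vertex id: ", paste(v[is.na(idx)], collapse = ", "))
  idx
}

#' @rdname mixed_graph
#' @param g a `mixed_graph`.
#' @param tail,head vertex ids.
#' @param mark edge mark, one of `"dir"`, `"undir"`, `"bidir"`.
#' @export
add_edge <- function(g, tail, head, mark = "dir") {
  i <- vertex_index(g, tail); j <- vertex_index(g, head)
  if (i == j) stop("self-loops are not allowed")
  if (g$amat[i, j] != 0L || g$amat[j, i] != 0L) stop("pair already has an edge: ", tail, ", ", head)
  switch(mark,
    dir = { g$amat[i, j] <- 2L },
    undir = { g$amat[i, j] <- 1L; g$amat[j, i] <- 1L },
    bidir = { g$amat[i, j] <- 3L; g$amat[j, i] <- 3L },
    stop("unknown edge mark: ", mark)
  )
  g
}

#' @rdname mixed_graph
#' @export
remove_edge <- function(g, tail, head) {
  i <- vertex_index(g, tail); j <- vertex_index(g, head)
  g$amat[i, j] <- 0L
  g$amat[j, i] <- 0L
  g
}

#' @rdname mixed_graph
#' @export
has_edge <- function(g, tail, head) {
  i <- vertex_index(g, tail); j <- vertex_index(g, head)
  g$amat[i, j] != 0L || g$amat[j, i] != 0L
}

#' Mark of the edge between two vertices
#'
#' @param g a `mixed_graph`.
#' @param tail,head vertex ids.
#' @return `"dir"` (tail -> head), `"dir_rev"` (head -> tail), `"undir"`,
#'   `"bidir"`, or `"none"`.
#' @export
edge_mark <- function(g, tail, head) {
  i <- vertex_index(g, tail); j <- vertex_index(g, head)
  if (g$amat[i, j] == 2L) return("dir")
  if (g$amat[j, i] == 2L) return("dir_rev")
  if (g$amat[i, j] == 1L) return("undir")
  if (g$amat[i, j] == 3L) return("bidir")
  "none"
}

#' Edge list of a mixed graph
#'
#' Symmetric (undirected/bidirected) edges are reported once, with
#' `tail < head` in vertex-insertion order. Rows are sorted for determinism.
#'
#' @param g a `mixed_graph`.
#' @return a tibble with columns `tail`, `head`, `mark`.
#' @export
graph_edges <- function(g) {
  a <- g$amat
  v <- g$vertices
  tails <- character(0); heads <- character(0); marks <- character(0)
  p <- length(v)
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (a[i, j] == 2L) { tails <- c(tails, v[i]); heads <- c(heads, v[j]); marks <- c(marks, "dir") }
        else if (a[j, i] == 2L) { tails <- c(tails, v[j]); heads <- c(heads, v[i]); marks <- c(marks, "dir") }
        else if (a[i, j] == 1L) { tails <- c(tails, v[i]); heads <- c(heads, v[j]); marks <- c(marks, "undir") }
        else if (a[i, j] == 3L) { tails <- c(tails, v[i]); heads <- c(heads, v[j]); marks <- c(marks, "bidir") }
      }
    }
  }
  out <- tibble::tibble(tail = tails, head = heads, mark = marks)
  out[order(out$tail, out$head, out$mark), , drop = FALSE]
}

#' @method as_tibble mixed_graph
#' @export
as_tibble.mixed_graph <- function(x, ...) graph_edges(x)

#' @export
print.mixed_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat("<mixed_graph> ", length(x$vertices), " vertices, ", nrow(e), " edges\n", sep = "")
  if (nrow(e) > 0) {
    sym <- c(dir = "->", undir = "--", bidir = "<->")
    cat(paste0("  ", e$tail, " ", sym[e$mark], " ", e$head, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

# ---- structural queries ----------------------------------------------------

#' Parents, children, neighbours and adjacent vertices
#'
#' `parents_of()`/`children_of()` follow directed edges, `neighbours_of()`
#' returns undirected neighbours, `adjacent_of()` all adjacent vertices
#' regardless of mark.
#'
#' @param g a `mixed_graph`.
#' @param v a vertex id.
#' @return character vector of vertex ids.
#' @export
parents_of <- function(g, v) {
  j <- vertex_index(g, v)
  g$vertices[g$amat[, j] == 2L]
}

#' @rdname parents_of
#' @export
children_of <- function(g, v) {
  i <- vertex_index(g, v)
  g$vertices[g$amat[i, ] == 2L]
}

#' @rdname parents_of
#' @export
neighbours_of <- function(g, v) {
  i <- vertex_index(g, v)
  g$vertices[g$amat[i, ] == 1L]
}

#' @rdname parents_of
#' @export
adjacent_of <- function(g, v) {
  i <- vertex_index(g, v)
  g$vertices[g$amat[i, ] != 0L | g$amat[, i] != 0L]
}

directed_adjacency <- function(g) g$amat == 2L

#' Is the graph a DAG?
#'
#' True when all edges are directed and there is no directed cycle.
#' @param g a `mixed_graph`.
#' @export
is_dag <- function(g) {
  a <- g$amat
  if (any(a == 1L | a == 3L)) return(FALSE)
  acyclic_directed(a == 2L)
}

# no directed cycle among the TRUE entries of a boolean adjacency matrix
acyclic_directed <- function(adj) {
  p <- nrow(adj)
  if (p == 0) return(TRUE)
  indeg <- colSums(adj)
  alive <- rep(TRUE, p)
  repeat {
    free <- which(alive & indeg == 0)
    if (length(free) == 0) break
    for (f in free) {
      indeg <- indeg - adj[f, ]
      alive[f] <- FALSE
    }
  }
  !any(alive)
}

# PDAG validity: no bidirected edges and no cycle among the directed edges
is_pdag <- function(g) {
  if (any(g$amat == 3L)) return(FALSE)
  acyclic_directed(g$amat == 2L)
}

#' Ancestors and possible ancestors
#'
#' `ancestors()` returns the vertices with a directed path to `v`
#' (`include_self = TRUE` adds `v` itself, the closure convention used when
#' stating identifiability results). `possible_ancestors()` returns the
#' vertices with a partially directed path to `v` (no edge on the path is
#' traversed against its arrowhead) that are *not* plain ancestors; this
#' "strictly possible" convention mirrors how learned graphs report causes
#' whose edges could not all be oriented.
#'
#' @param g a `mixed_graph`.
#' @param v a vertex id.
#' @param include_self include `v` in the returned set (ancestors only).
#' @return a sorted character vector of vertex ids.
#' @export
ancestors <- function(g, v, include_self = FALSE) {
  adj <- directed_adjacency(g)
  idx <- vertex_index(g, v)
  seen <- rep(FALSE, length(g$vertices))
  frontier <- idx
  while (length(frontier) > 0) {
    pa <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & !seen)
    seen[pa] <- TRUE
    frontier <- pa
  }
  out <- g$vertices[seen]
  out <- setdiff(out, v)
  if (include_self) out <- c(out, v)
  sort(out)
}

#' @rdname ancestors
#' @export
possible_ancestors <- function(g, v) {
  # u may precede w on a partially directed path iff u -> w or u -- w
  trav <- g$amat == 2L | g$amat == 1L
  idx <- vertex_index(g, v)
  seen <- rep(FALSE, length(g$vertices))
  frontier <- idx
  while (length(frontier) > 0) {
    pre <- which(rowSums(trav[, frontier, drop = FALSE]) > 0 & !seen)
    seen[pre] <- TRUE
    frontier <- pre
  }
  out <- setdiff(g$vertices[seen], v)
  sort(setdiff(out, ancestors(g, v)))
}

#' Descendants via directed paths
#' @inheritParams ancestors
#' @export
descendants <- function(g, v, include_self = FALSE) {
  adj <- directed_adjacency(g)
  idx <- vertex_index(g, v)
  seen <- rep(FALSE, length(g$vertices))
  frontier <- idx
  while (length(frontier) > 0) {
    ch <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[ch] <- TRUE
    frontier <- ch
  }
  out <- setdiff(g$vertices[seen], v)
  if (include_self) out <- c(out, v)
  sort(out)
}

#' Shortest path between two vertices, ignoring edge marks
#'
#' Breadth-first search on the skeleton. Returns the number of edges and one
#' shortest path; a disconnected pair is reported as `length = Inf` with a
#' `NULL` path.
#'
#' @param g a `mixed_graph`.
#' @param from,to vertex ids.
#' @return a list with elements `length` and `path` (character vector from
#'   `from` to `to`, or `NULL`).
#' @export
shortest_path <- function(g, from, to) {
  s <- vertex_index(g, from); t <- vertex_index(g, to)
  if (s == t) return(list(length = 0L, path = g$vertices[s]))
  adj <- g$amat != 0L | t(g$amat) != 0L
  p <- length(g$vertices)
  prev <- rep(NA_integer_, p)
  seen <- rep(FALSE, p); seen[s] <- TRUE
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(adj[u, ] & !seen)) {
        seen[w] <- TRUE
        prev[w] <- u
        if (w == t) {
          path <- w
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(list(length = length(path) - 1L, path = g$vertices[path]))
        }
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  list(length = Inf, path = NULL)
}

#' Induced subgraph over a vertex subset
#'
#' @param g a `mixed_graph`.
#' @param vertices vertex ids to keep (in the given order).
#' @return a `mixed_graph` with only the edges between kept vertices.
#' @export
induced_subgraph <- function(g, vertices) {
  idx <- vertex_index(g, vertices)
  out <- structure(list(vertices = g$vertices[idx],
                        amat = g$amat[idx, idx, drop = FALSE]),
                   class = "mixed_graph")
  out
}

# ---- serialization ---------------------------------------------------------

#' Read / write a mixed graph as a plain-text edge list
#'
#' The format is one edge per line, `tail<TAB>head<TAB>mark` with mark in
#' `dir`, `undir`, `bidir`, preceded by a header line `# vertices: ...`
#' listing all vertex ids (so isolated vertices survive the round trip).
#'
#' @param g a `mixed_graph`.
#' @param path file path.
#' @export
write_graph_tsv <- function(g, path) {
  e <- graph_edges(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# vertices: ", paste(g$vertices, collapse = ",")), con)
  if (nrow(e) > 0) {
    writeLines(paste(e$tail, e$head, e$mark, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# vertices:", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing '# vertices:' header")
  vertices <- strsplit(sub("^# vertices: *", "", hdr), ",")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) return(mixed_graph(vertices))
  parts <- strsplit(body, "\t", fixed = TRUE)
  edges <- data.frame(
    tail = vapply(parts, `[`, "", 1),
    head = vapply(parts, `[`, "", 2),
    mark = vapply(parts, `[`, "", 3)
  )
  mixed_graph(vertices, edges)
}
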