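#' Separation-set store
#'
#' Records, for non-adjacent vertex pairs, the conditioning set that separated
#' them during skeleton learning. Pairs are unordered.
#'
#' @return an object of class `separation_store`.
#' @export
separation_store <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "separation_store")
}

#' @rdname separation_store
#' @param store a `separation_store`.
#' @param a,b vertex ids (unordered pair).
#' @param set character vector: the separating set.
#' @export
sep_set <- function(store, a, b) {
  key <- pair_key(a, b)
  if (!exists(key, envir = store$env, inherits = FALSE)) return(NULL)
  get(key, envir = store$env)
}

#' @rdname separation_store
#' @export
sep_record <- function(store, a, b, set) {
  assign(pair_key(a, b), sort(as.character(set)), envir = store$env)
  invisible(store)
}

sep_pairs <- function(store) {
  keys <- ls(store$env)
  lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
}

#' @export
print.separation_store <- function(x, ...) {
  cat("<separation_store> ", length(ls(x$env)), " pairs\n", sep = "")
  invisible(x)
}

#' Orient v-structures on a skeleton, tolerating conflicting arrowheads
#'
#' Scans unshielded triples `X - Y - Z` (in lexicographic order over
#' `(X, Y, Z)`) and, when the recorded separation set of `X` and `Z` does not
#' contain `Y`, places arrowheads into `Y` on both edges. Arrowheads
#' accumulate: an edge that receives an arrowhead at each end becomes
#' bidirected rather than being overwritten. Such edges are expected when a
#' common cause of two retained variables was screened out, and are deleted
#' by the caller before Meek closure.
#'
#' @param skeleton a `mixed_graph` with only undirected edges.
#' @param store a `separation_store` covering the non-adjacent pairs tested.
#' @return a `mixed_graph` with the same adjacencies and updated marks.
#' @export
orient_v_structures <- function(skeleton, store) {
  if (any(skeleton$amat == 2L | skeleton$amat == 3L)) {
    stop("skeleton must contain only undirected edges")
  }
  v <- skeleton$vertices
  p <- length(v)
  adj <- skeleton$amat != 0L
  # head[i, j] TRUE: arrowhead at j on edge i - j
  head <- matrix(FALSE, p, p)
  ord <- order(v)
  for (xi in ord) {
    for (yi in ord) {
      if (xi == yi || !adj[xi, yi]) next
      for (zi in ord) {
        if (zi == xi || zi == yi || !adj[yi, zi] || adj[xi, zi]) next
        s <- sep_set(store, v[xi], v[zi])
        if (is.null(s)) next
        if (!(v[yi] %in% s)) {
          head[xi, yi] <- TRUE
          head[zi, yi] <- TRUE
        }
      }
    }
  }
  out <- skeleton
  a <- out$amat
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j && adj[i, j]) {
        if (head[i, j] && head[j, i]) { a[i, j] <- 3L; a[j, i] <- 3L }
        else if (head[i, j]) { a[i, j] <- 2L; a[j, i] <- 0L }
        else if (head[j, i]) { a[j, i] <- 2L; a[i, j] <- 0L }
      }
    }
  }
  out$amat <- a
  out
}

#' Meek's orientation rules to a fixed point
#'
#' Applies the four sound orientation rules for PDAGs until no rule fires.
#' Never adds or removes adjacencies and never reverses an existing directed
#' edge; the set of directed edges only grows, so the operation is monotone
#' and idempotent.
#'
#' @param g a `mixed_graph` without bidirected edges (delete them first).
#' @return the maximally oriented `mixed_graph`.
#' @export
apply_meek_rules <- function(g) {
  if (any(g$amat == 3L)) stop("bidirected edges present; delete them before Meek closure")
  a <- g$amat
  p <- nrow(a)
  if (p < 2) return(g)
  repeat {
    changed <- FALSE
    adj <- a != 0L | t(a) != 0L
    und <- a == 1L        # symmetric
    dir <- a == 2L        # dir[i, j]: i -> j
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (!und[i, j] || i == j) next
        orient <- FALSE
        # R1: some k -> i with k, j non-adjacent  =>  i -> j
        ks <- which(dir[, i])
        if (any(!adj[ks, j])) orient <- TRUE
        # R2: directed path i -> k -> j  =>  i -> j
        if (!orient) {
          ks <- which(dir[i, ] & dir[, j])
          if (length(ks) > 0) orient <- TRUE
        }
        # R3: i - k, i - l, k -> j, l -> j, k and l non-adjacent  =>  i -> j
        if (!orient) {
          ks <- which(und[i, ] & dir[, j])
          if (length(ks) >= 2) {
            for (k in ks) {
              if (any(!adj[k, setdiff(ks, k)])) { orient <- TRUE; break }
            }
          }
        }
        # R4: i - d, d -> c, c -> j, d and j non-adjacent, i adjacent to c  =>  i -> j
        if (!orient) {
          ds <- which(und[i, ])
          for (d in ds) {
            cs <- which(dir[d, ] & dir[, j] & adj[i, ])
            if (length(cs) > 0 && !adj[d, j]) { orient <- TRUE; break }
          }
        }
        if (orient) {
          a[i, j] <- 2L
          a[j, i] <- 0L
          und[i, j] <- und[j, i] <- FALSE
          dir[i, j] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  g$amat <- a
  g
}

#' CPDAG of a DAG
#'
#' Returns the completed partially directed acyclic graph representing the
#' Markov equivalence class of `g`: same skeleton, with exactly the
#' orientation-invariant edges directed (v-structures plus Meek closure).
#'
#' @param g a `mixed_graph` that is a DAG.
#' @return a `mixed_graph` (the CPDAG).
#' @export
cpdag_of <- function(g) {
  if (!is_dag(g)) stop("cpdag_of requires a DAG")
  v <- g$vertices
  adjd <- directed_adjacency(g)
  adj <- adjd | t(adjd)
  p <- length(v)
  a <- matrix(0L, p, p, dimnames = dimnames(g$amat))
  a[adj] <- 1L
  # orient the DAG's v-structures
  for (j in seq_len(p)) {
    pa <- which(adjd[, j])
    if (length(pa) >= 2) {
      for (u in pa) for (w in pa) {
        if (u < w && !adj[u, w]) {
          a[u, j] <- 2L; a[j, u] <- 0L
          a[w, j] <- 2L; a[j, w] <- 0L
        }
      }
    }
  }
  out <- g
  out$amat <- a
  apply_meek_rules(out)
}

v_structures_of <- function(g) {
  # list of sorted (u, j, w) triples u -> j <- w with u, w non-adjacent
  a <- g$amat
  adj <- a != 0L | t(a) != 0L
  v <- g$vertices
  out <- list()
  for (j in seq_along(v)) {
    pa <- which(a[, j] == 2L)
    if (length(pa) >= 2) {
      for (u in pa) for (w in pa) {
        if (u < w && !adj[u, w]) out[[length(out) + 1]] <- c(min(v[u], v[w]), v[j], max(v[u], v[w]))
      }
    }
  }
  out
}
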