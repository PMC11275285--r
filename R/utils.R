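# internal helpers shared across modules

# run code with a private RNG stream; restores the caller's .Random.seed
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# derive a reproducible child seed from a master seed; stays below 2^31
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(x)
}

# van der Corput / Halton quasi-random sequence in [0,1]^d, deterministic
halton_matrix <- function(n, d) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (d > length(bases)) stop("halton_matrix supports at most ", length(bases), " dimensions")
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    b <- bases[j]
    for (i in seq_len(n)) {
      f <- 1
      r <- 0
      k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, j] <- r
    }
  }
  out
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  if (a <= b) paste0(a, "\r", b) else paste0(b, "\r", a)
}

# all subsets of a character vector with exactly k elements, in lexicographic
# order of the (sorted) member ids; returns a list of character vectors
subsets_of_size <- function(x, k) {
  x <- sort(x)
  if (k == 0L) return(list(character(0)))
  if (length(x) < k) return(list())
  cmb <- utils::combn(x, k, simplify = FALSE)
  cmb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
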