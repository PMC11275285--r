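#' Growth-curve mean-function families
#'
#' The classical S-shaped families used to model functional dynamic targets:
#'
#' * `logistic`: \eqn{\mu(t) = a / (1 + e^{-r(t - c)})}, parameters `(a, r, c)`
#' * `gompertz`: \eqn{\mu(t) = a e^{-b e^{-c t}}}, parameters `(a, b, c)`
#' * `richards`: \eqn{\mu(t) = a / (1 + b e^{-c t})^d}, parameters `(a, b, c, d)`
#' * `hossfeld`: \eqn{\mu(t) = a t^k / (c + t^k)}, parameters `(a, k, c)`
#' * `double_logistic`: the sum of two logistic terms, parameters
#'   `(a1, r1, c1, a2, r2, c2)` — the family used for two-phase growth.
#'
#' @param name one of `"logistic"`, `"gompertz"`, `"richards"`, `"hossfeld"`,
#'   `"double_logistic"`.
#' @return an object of class `growth_family` with fields `name`, `arity`,
#'   `params` (parameter names), `mean` (function of `t` and `theta`) and
#'   `start_box` (data-driven parameter box for multi-start optimisation).
#' @examples
#' fam <- growth_family("logistic")
#' growth_mean(fam, t = 5, theta = c(a = 2, r = 1, c = 5))  # a / 2
#' @export
growth_family <- function(name = c("logistic", "gompertz", "richards",
                                   "hossfeld", "double_logistic")) {
  name <- match.arg(name)
  fam <- switch(name,
    logistic = list(
      arity = 3L,
      params = c("a", "r", "c"),
      mean = function(t, theta) theta[1] / (1 + exp(-theta[2] * (t - theta[3]))),
      jac = function(t, theta) {
        s <- 1 / (1 + exp(-theta[2] * (t - theta[3])))
        cbind(s, theta[1] * (t - theta[3]) * s * (1 - s),
              -theta[1] * theta[2] * s * (1 - s))
      },
      start_box = function(times, y) {
        ry <- max(max(y) - min(y), max(abs(y)), 1e-3)
        span <- max(diff(range(times)), 1e-3)
        list(lower = c(1e-3, 0.01, min(times) - span),
             upper = c(3 * ry, 5, max(times) + span))
      }
    ),
    gompertz = list(
      arity = 3L,
      params = c("a", "b", "c"),
      mean = function(t, theta) theta[1] * exp(-theta[2] * exp(-theta[3] * t)),
      jac = function(t, theta) {
        e <- exp(-theta[3] * t)
        f <- exp(-theta[2] * e)
        cbind(f, -theta[1] * f * e, theta[1] * f * theta[2] * t * e)
      },
      start_box = function(times, y) {
        ry <- max(max(y) - min(y), max(abs(y)), 1e-3)
        list(lower = c(1e-3, 0.01, 0.01),
             upper = c(3 * ry, 50, 5))
      }
    ),
    richards = list(
      arity = 4L,
      params = c("a", "b", "c", "d"),
      mean = function(t, theta) theta[1] / (1 + theta[2] * exp(-theta[3] * t))^theta[4],
      jac = function(t, theta) {
        e <- exp(-theta[3] * t)
        u <- 1 + theta[2] * e
        cbind(u^(-theta[4]),
              -theta[1] * theta[4] * u^(-theta[4] - 1) * e,
              theta[1] * theta[4] * theta[2] * t * e * u^(-theta[4] - 1),
              -theta[1] * u^(-theta[4]) * log(u))
      },
      start_box = function(times, y) {
        ry <- max(max(y) - min(y), max(abs(y)), 1e-3)
        list(lower = c(1e-3, 0.01, 0.01, 0.05),
             upper = c(3 * ry, 50, 5, 10))
      }
    ),
    hossfeld = list(
      arity = 3L,
      params = c("a", "k", "c"),
      mean = function(t, theta) theta[1] * t^theta[2] / (theta[3] + t^theta[2]),
      jac = function(t, theta) {
        tk <- t^theta[2]
        d <- theta[3] + tk
        cbind(tk / d,
              theta[1] * theta[3] * tk * log(t) / d^2,
              -theta[1] * tk / d^2)
      },
      start_box = function(times, y) {
        ry <- max(max(y) - min(y), max(abs(y)), 1e-3)
        list(lower = c(1e-3, 0.2, 1e-3),
             upper = c(3 * ry, 8, 1e4))
      }
    ),
    double_logistic = list(
      arity = 6L,
      params = c("a1", "r1", "c1", "a2", "r2", "c2"),
      mean = function(t, theta) {
        theta[1] / (1 + exp(-theta[2] * (t - theta[3]))) +
          theta[4] / (1 + exp(-theta[5] * (t - theta[6])))
      },
      jac = function(t, theta) {
        s1 <- 1 / (1 + exp(-theta[2] * (t - theta[3])))
        s2 <- 1 / (1 + exp(-theta[5] * (t - theta[6])))
        d1 <- s1 * (1 - s1)
        d2 <- s2 * (1 - s2)
        out <- matrix(0, length(t), 6L)
        out[, 1] <- s1
        out[, 2] <- theta[1] * (t - theta[3]) * d1
        out[, 3] <- -theta[1] * theta[2] * d1
        out[, 4] <- s2
        out[, 5] <- theta[4] * (t - theta[6]) * d2
        out[, 6] <- -theta[4] * theta[5] * d2
        out
      },
      start_box = function(times, y) {
        ry <- max(max(y) - min(y), max(abs(y)), 1e-3)
        span <- max(diff(range(times)), 1e-3)
        list(lower = c(0, 0.01, min(times) - span / 2,
                       0, 0.01, min(times) - span / 2),
             upper = c(2 * ry, 5, max(times) + span / 2,
                       2 * ry, 5, max(times) + span / 2))
      }
    )
  )
  fam$name <- name
  structure(fam, class = "growth_family")
}

#' @export
print.growth_family <- function(x, ...) {
  cat("<growth_family> ", x$name, " (", x$arity, " parameters: ",
      paste(x$params, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a growth-family mean function
#'
#' @param family a `growth_family`.
#' @param t numeric vector of times.
#' @param theta numeric parameter vector of length `family$arity`.
#' @return numeric vector of mean values.
#' @export
growth_mean <- function(family, t, theta) {
  if (length(theta) != family$arity) {
    stop("theta must have length ", family$arity, " for family ", family$name)
  }
  family$mean(t, as.numeric(theta))
}

#' Functional dynamic target container
#'
#' An `n x q` matrix of curve observations sharing one grid of `q` time
#' points: row `i` is sample `i`'s trajectory.
#'
#' @param curves numeric matrix (`n x q`) of observations.
#' @param times numeric vector of length `q >= 2`, strictly increasing.
#' @return an object of class `functional_target`.
#' @export
functional_target <- function(curves, times) {
  curves <- as.matrix(curves)
  times <- as.numeric(times)
  if (length(times) < 2) stop("at least two time points are required")
  if (ncol(curves) != length(times)) stop("ncol(curves) must equal length(times)")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(curves = unname(curves), times = times), class = "functional_target")
}

#' @export
print.functional_target <- function(x, ...) {
  cat("<functional_target> ", nrow(x$curves), " curves at ", length(x$times),
      " time points [", min(x$times), ", ", max(x$times), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.functional_target <- function(x) dim(x$curves)

#' Read / write a functional target as wide CSV plus a JSON time sidecar
#'
#' The CSV has a `sample` column followed by one column per time point
#' (`t_<value>`); the sidecar `<path>.json` stores the numeric time grid.
#'
#' @param x a `functional_target`.
#' @param path CSV file path.
#' @export
write_functional_target <- function(x, path) {
  df <- data.frame(sample = seq_len(nrow(x$curves)), x$curves)
  names(df) <- c("sample", paste0("t_", x$times))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(times = x$times), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_functional_target
#' @export
read_functional_target <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  times <- if (file.exists(sidecar)) {
    as.numeric(jsonlite::read_json(sidecar, simplifyVector = TRUE)$times)
  } else {
    as.numeric(sub("^t_", "", setdiff(names(df), "sample")))
  }
  functional_target(as.matrix(df[setdiff(names(df), "sample")]), times)
}
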