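# Exact hypergeometric intersection distribution.
#
# Model: two subsets of sizes a and b are drawn independently, uniformly
# and without replacement from a universe of n distinct protein-coding
# genes; V = |A intersect B|. Conditioning on the first draw reduces the
# both-sets-random formulation to the classical fixed-set hypergeometric,
#   P(V = v) = C(a, v) C(n - a, b - v) / C(n, b),
# which is what is implemented (in log-space). The reduction itself is
# validated empirically by the Monte Carlo module's literal two-subset
# sampler.

check_hyperg_params <- function(n, a, b) {
  if (length(n) != 1 || length(a) != 1 || length(b) != 1 ||
      anyNA(c(n, a, b))) stop("n, a, b must be single non-NA numbers")
  if (n != floor(n) || a != floor(a) || b != floor(b) ||
      n < 0 || a < 0 || b < 0) stop("n, a, b must be non-negative integers")
  if (a > n || b > n) {
    stop("draw sizes exceed the universe: a=", a, ", b=", b, ", n=", n)
  }
  invisible(TRUE)
}

#' Probability mass of the intersection size
#'
#' `P(V = v)` for the intersection of two independent uniform draws
#' without replacement of sizes `a` and `b` from `n` distinct genes.
#' Computed from log binomial coefficients; values of `v` outside the
#' support (`v < max(0, a + b - n)` or `v > min(a, b)`) return 0.
#'
#' @param n universe size (distinct protein-coding genes).
#' @param a,b sizes of the two draws.
#' @param v intersection size(s); vectorized.
#' @return numeric vector of probabilities.
#' @export
intersection_pmf <- function(n, a, b, v) {
  check_hyperg_params(n, a, b)
  v <- as.numeric(v)
  out <- numeric(length(v))
  ok <- !is.na(v) & v == floor(v) & v >= max(0, a + b - n) & v <= min(a, b)
  if (any(ok)) {
    k <- v[ok]
    out[ok] <- exp(lchoose(a, k) + lchoose(n - a, b - k) - lchoose(n, b))
  }
  out
}

#' Upper-tail probability of the intersection size
#'
#' `P(V >= v)`: the probability, under the null of independent uniform
#' draws, of an intersection at least as large as observed. The tail
#' convention is "greater than or equal", matching how overlap
#' significance is reported; the strict tail is not exposed to avoid
#' off-by-one misuse. The smaller of the two tails is summed directly and
#' the result clamped to [0, 1].
#'
#' @inheritParams intersection_pmf
#' @param v observed intersection size.
#' @return a single probability.
#' @examples
#' intersection_tail_ge(19500, 691, 742, 41)  # ~0.0034
#' @export
intersection_tail_ge <- function(n, a, b, v) {
  check_hyperg_params(n, a, b)
  stopifnot(length(v) == 1, !is.na(v))
  lo <- max(0, a + b - n)
  hi <- min(a, b)
  if (v <= lo) return(1)
  if (v > hi) return(0)
  upper <- v:hi
  lower <- lo:(v - 1)
  p <- if (length(upper) <= length(lower)) {
    sum(intersection_pmf(n, a, b, upper))
  } else {
    1 - sum(intersection_pmf(n, a, b, lower))
  }
  min(max(p, 0), 1)
}

#' Mean and variance of the intersection size
#'
#' Closed forms under the null: `mean = a b / n` and
#' `variance = (a b / n) (1 - a/n) (n - b)/(n - 1)`.
#'
#' @inheritParams intersection_pmf
#' @return list with `mean` and `variance`.
#' @export
intersection_moments <- function(n, a, b) {
  check_hyperg_params(n, a, b)
  if (n < 2 && (a > 0 || b > 0)) {
    stop("moments need a universe of at least 2 when draws are non-empty")
  }
  m <- a * b / n
  v <- if (n < 2) 0 else m * (1 - a / n) * (n - b) / (n - 1)
  list(mean = m, variance = v)
}

#' Exact intersection test
#'
#' Convenience wrapper bundling the observed parameters, the upper-tail
#' probability and the null moments, analogous to the result object of a
#' classical test function.
#'
#' @inheritParams intersection_tail_ge
#' @return a `hyperg_result`: list with `n`, `a`, `b`, `v`, `p_tail`,
#'   `mean`, `variance`.
#' @export
intersection_test <- function(n, a, b, v) {
  mom <- intersection_moments(n, a, b)
  structure(
    list(n = n, a = a, b = b, v = v,
         p_tail = intersection_tail_ge(n, a, b, v),
         mean = mom$mean, variance = mom$variance),
    class = "hyperg_result"
  )
}

#' @export
print.hyperg_result <- function(x, ...) {
  cat("Hypergeometric intersection test\n",
      "  n = ", x$n, ", a = ", x$a, ", b = ", x$b, ", observed v = ", x$v, "\n",
      "  null mean = ", format(x$mean, digits = 6),
      ", sd = ", format(sqrt(x$variance), digits = 6), "\n",
      "  P(V >= v) = ", format(x$p_tail, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Brute-force intersection pmf by subset enumeration (test oracle)
#'
#' Enumerates every pair of subsets `(A, B)` with `|A| = a`, `|B| = b`
#' from a universe of `n` elements and tallies intersection sizes. Cost is
#' `C(n,a) * C(n,b)` pairs, so `n` is capped at 14. This is the
#' independent oracle for [intersection_pmf()]; it shares no code with it.
#'
#' @inheritParams intersection_pmf
#' @return numeric vector of probabilities named by intersection size
#'   `0..min(a,b)`.
#' @export
brute_force_intersection_pmf <- function(n, a, b) {
  check_hyperg_params(n, a, b)
  if (n > 14) stop("enumeration capped at n <= 14 (got n = ", n, ")")
  ind <- function(k) {
    if (k == 0) return(matrix(0, nrow = 1, ncol = n))
    sets <- utils::combn(n, k)
    m <- matrix(0, nrow = ncol(sets), ncol = n)
    for (i in seq_len(ncol(sets))) m[i, sets[, i]] <- 1
    m
  }
  counts <- ind(a) %*% t(ind(b))          # |A ∩ B| for every pair
  tal <- tabulate(as.vector(counts) + 1L, nbins = min(a, b) + 1L)
  stats::setNames(tal / sum(tal), 0:min(a, b))
}
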