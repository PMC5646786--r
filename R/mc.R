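# Monte Carlo null for the intersection size.

#' Sample intersection sizes under the null
#'
#' Each trial draws two independent uniform subsets of sizes `a` and `b`
#' (without replacement within each subset) from a universe of `n` genes
#' and records the intersection cardinality.
#'
#' Two samplers are provided. The default (`method = "conditional"`)
#' exploits the conditional equivalence of the null: by symmetry the
#' distribution of the intersection is unchanged if the first subset is
#' held fixed at `{1..a}`, so a trial reduces to drawing `b` indices from
#' `{1..n}` and counting how many fall at or below `a` — which makes
#' 1,000,000 trials routine. `method = "two_subset"` performs the literal
#' two-subset draw; it exists to validate that equivalence empirically.
#'
#' @param n universe size; `a`, `b` draw sizes.
#' @param a,b sizes of the two draws.
#' @param reps number of trials (>= 1).
#' @param seed integer RNG seed (Mersenne-Twister via [set.seed()]).
#' @param method `"conditional"` (default) or `"two_subset"`.
#' @return integer vector of `reps` intersection sizes.
#' @export
sample_intersection_sizes <- function(n, a, b, reps, seed,
                                      method = c("conditional", "two_subset")) {
  check_hyperg_params(n, a, b)
  method <- match.arg(method)
  if (length(reps) != 1 || is.na(reps) || reps < 1 || reps != floor(reps)) {
    stop("reps must be a positive integer")
  }
  reps <- as.integer(reps)
  set.seed(as.integer(seed))
  if (method == "conditional") {
    if (b == 0) return(integer(reps))
    vapply(seq_len(reps),
           function(i) sum(sample.int(n, b) <= a),
           integer(1))
  } else {
    vapply(seq_len(reps), function(i) {
      A <- sample.int(n, a)
      B <- sample.int(n, b)
      length(intersect(A, B))
    }, integer(1))
  }
}

#' Monte Carlo estimate of the intersection tail
#'
#' Estimates `P(V >= v)` as the fraction of seeded trials whose
#' intersection size reaches `v`, with a normal-approximation 95%
#' confidence interval (reported even when the count is small).
#'
#' @inheritParams sample_intersection_sizes
#' @param v tail threshold.
#' @return an `mc_result`: list with `n`, `a`, `b`, `v`, `reps`, `seed`,
#'   `method`, `count_ge_v`, `fraction`, `ci95` (length-2 vector).
#' @examples
#' estimate_tail(100, 20, 20, 6, reps = 1000, seed = 1)
#' @export
estimate_tail <- function(n, a, b, v, reps = 1e6, seed,
                          method = c("conditional", "two_subset")) {
  method <- match.arg(method)
  sizes <- sample_intersection_sizes(n, a, b, reps, seed, method)
  k <- sum(sizes >= v)
  f <- k / reps
  half <- 1.96 * sqrt(f * (1 - f) / reps)
  structure(
    list(n = n, a = a, b = b, v = v, reps = as.integer(reps),
         seed = as.integer(seed), method = method,
         count_ge_v = k, fraction = f,
         ci95 = c(max(0, f - half), min(1, f + half))),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo intersection null (", x$method, " sampler)\n",
      "  n = ", x$n, ", a = ", x$a, ", b = ", x$b, ", v = ", x$v, "\n",
      "  ", x$count_ge_v, "/", x$reps, " trials with V >= v  (seed ",
      x$seed, ")\n",
      "  fraction = ", format(x$fraction, digits = 4),
      "  95% CI [", format(x$ci95[1], digits = 4), ", ",
      format(x$ci95[2], digits = 4), "]\n", sep = "")
  invisible(x)
}
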