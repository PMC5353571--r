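# Bootstrap standard errors and confidence intervals for diversity
# estimates, via the coverage-adjusted bootstrap assemblage.

#' Coverage-adjusted bootstrap assemblage
#'
#' Constructs the probability distribution from which bootstrap samples are
#' drawn: observed relative abundances are shrunk so their total equals the
#' estimated coverage, \eqn{\tilde p_i = \hat p_i [1 - \lambda (1 -
#' \hat p_i)^n]} with \eqn{\lambda = (1 - \hat C) / \sum_i \hat p_i (1 -
#' \hat p_i)^n}, and the undetected mass \eqn{1 - \hat C} is spread equally
#' over \eqn{\hat f_0 = \lceil \mathrm{Chao1} - S_{obs} \rceil} augmented
#' unseen classes. The full vector sums to one.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return An object of class `bootstrap_assemblage`: list with `p_adjusted`
#'   (length S_obs), `f0` (augmented unseen classes), `p_unseen` (shared
#'   unseen-class probability), `lambda`, `c_hat` and `n`.
#' @export
bootstrap_assemblage <- function(x) {
  av <- if (inherits(x, "freq_counts")) counts_from_fc(x) else abundance_vector(x)
  n <- sum(av)
  if (n < 2) stop("bootstrap assemblage needs n >= 2")
  p_hat <- as.numeric(av) / n
  c_hat <- sample_coverage(av)$c_hat
  f0 <- ceiling(chao1(av) - length(av))
  if (c_hat >= 1 || f0 == 0) {
    return(structure(list(p_adjusted = p_hat, f0 = 0L, p_unseen = 0,
                          lambda = 0, c_hat = c_hat, n = n),
                     class = "bootstrap_assemblage"))
  }
  lambda <- (1 - c_hat) / sum(p_hat * (1 - p_hat)^n)
  p_adj <- p_hat * (1 - lambda * (1 - p_hat)^n)
  structure(list(p_adjusted = p_adj, f0 = as.integer(f0),
                 p_unseen = (1 - c_hat) / f0, lambda = lambda,
                 c_hat = c_hat, n = n),
            class = "bootstrap_assemblage")
}

#' @export
print.bootstrap_assemblage <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap assemblage> n = %d, observed classes = %d",
                     " (mass %.4f), unseen classes = %d (mass %.4f)\n"),
              x$n, length(x$p_adjusted), sum(x$p_adjusted), x$f0,
              x$f0 * x$p_unseen))
  invisible(x)
}

#' Bootstrap standard error of a diversity statistic
#'
#' Draws `B` multinomial resamples of size n from the coverage-adjusted
#' bootstrap assemblage, evaluates `statistic` on each replicate's class
#' counts, and reports the across-replicate standard deviation as the
#' standard error with symmetric normal 95% intervals (estimate +/- 1.96
#' s.e.). `statistic` may be vector-valued (e.g. a whole curve), in which
#' case `se` is computed per element. Identical seeds give identical
#' results; the caller's random-number state is left untouched.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param statistic Function taking a vector of class counts (zero-count
#'   classes dropped) and returning a numeric scalar or vector.
#' @param B Number of replicates (default 200).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `bootstrap_result`: list with `estimate`,
#'   `se`, `ci_low`, `ci_high`, `B`, `seed`.
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' bootstrap_se(fc$East, shannon_asymptotic, B = 50, seed = 1)
bootstrap_se <- function(x, statistic, B = 200, seed = NULL) {
  if (B < 2) stop("need at least B = 2 bootstrap replicates")
  ba <- bootstrap_assemblage(x)
  av <- if (inherits(x, "freq_counts")) counts_from_fc(x) else abundance_vector(x)
  p_full <- c(ba$p_adjusted, rep(ba$p_unseen, ba$f0))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  draws <- stats::rmultinom(B, size = ba$n, prob = p_full)
  reps <- apply(draws, 2, function(cnt) statistic(cnt[cnt > 0]))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  est <- statistic(as.numeric(av))
  se <- apply(reps, 1, stats::sd)
  structure(list(estimate = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 B = B, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap result> B = %d\n", x$B))
  print(data.frame(estimate = x$estimate, se = x$se,
                   ci_low = x$ci_low, ci_high = x$ci_high))
  invisible(x)
}
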