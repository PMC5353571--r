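# Observed and asymptotic Hill numbers of orders q = 0, 1, 2.

#' Observed Hill number of order q
#'
#' The effective number of equally abundant classes in the sample: class
#' richness for q = 0, the exponential of Shannon entropy for q = 1, and
#' inverse Simpson concentration for q = 2, all computed from the empirical
#' relative abundances.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param q Diversity order: 0, 1 or 2.
#' @return The observed diversity in effective classes.
#' @export
#' @examples
#' observed_hill(c(4, 4, 4), q = 1)  # 3 equally abundant classes -> 3
observed_hill <- function(x, q) {
  fc <- as_freq_counts(x)
  if (fc$n < 1) stop("empty sample")
  if (!q %in% c(0, 1, 2)) stop("only diversity orders 0, 1, 2 are supported")
  k <- fc_k(fc); f <- fc$f; n <- fc$n
  if (q == 0) return(as.numeric(fc$S_obs))
  p <- k / n
  if (q == 1) return(exp(-sum(f * p * log(p))))
  1 / sum(f * p^2)
}

# observed Shannon entropy (nats), shared by q = 1 estimators
observed_entropy <- function(fc) {
  k <- fc_k(fc); p <- k / fc$n
  -sum(fc$f * p * log(p))
}

#' Chao1 asymptotic class richness
#'
#' Nonparametric lower-bound estimate of total class richness (detected plus
#' undetected), driven by singletons and doubletons:
#' \deqn{\hat S = S_{obs} + \frac{n-1}{n}\frac{f_1^2}{2 f_2}} (bias-corrected
#' form \eqn{S_{obs} + \frac{n-1}{n} f_1 (f_1 - 1)/2} when \eqn{f_2 = 0}).
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return Estimated asymptotic class richness.
#' @export
chao1 <- function(x) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (n < 1) stop("empty sample")
  f1 <- fk(fc, 1); f2 <- fk(fc, 2)
  if (f2 > 0) fc$S_obs + ((n - 1) / n) * f1^2 / (2 * f2)
  else fc$S_obs + ((n - 1) / n) * f1 * (f1 - 1) / 2
}

#' Asymptotic Shannon diversity (low-bias nonparametric estimator)
#'
#' Estimates the Shannon entropy of the complete assemblage with the
#' harmonic-sum estimator plus a singleton correction, then exponentiates to
#' effective classes:
#' \deqn{\hat H = \sum_{1 \le X_i \le n-1} \frac{X_i}{n}
#'   \sum_{k=X_i}^{n-1} \frac{1}{k} \; + \; \frac{f_1}{n} (1-A)^{1-n}
#'   \left[-\log A - \sum_{r=1}^{n-1} \frac{(1-A)^r}{r}\right]}
#' with \eqn{A = 2 f_2 / [(n-1) f_1 + 2 f_2]} when \eqn{f_2 > 0},
#' \eqn{A = 2 / [(n-1)(f_1 - 1) + 2]} when \eqn{f_2 = 0, f_1 > 1}, and
#' \eqn{A = 1} (no correction) when \eqn{f_1 \le 1, f_2 = 0}. The first sum
#' only needs the frequency counts: classes with equal X_i contribute
#' identically, and the inner harmonic tails come from one cumulative sum.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return Estimated asymptotic Shannon diversity, `exp(H_hat)`.
#' @export
shannon_asymptotic <- function(x) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (n < 2) stop("Shannon asymptote needs n >= 2")
  f1 <- fk(fc, 1); f2 <- fk(fc, 2)
  # harm_tail[j] = sum_{r=j}^{n-1} 1/r
  harm_tail <- rev(cumsum(1 / rev(seq_len(n - 1))))
  k <- fc_k(fc)
  in_range <- k <= n - 1
  part1 <- sum(fc$f[in_range] * (k[in_range] / n) * harm_tail[k[in_range]])
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  part2 <- 0
  if (A < 1) {
    r <- seq_len(n - 1)
    part2 <- (f1 / n) * (1 - A)^(1 - n) *
      (-log(A) - sum((1 - A)^r / r))
  }
  exp(part1 + part2)
}

#' Asymptotic Simpson diversity (unbiased estimator)
#'
#' The inverse of the minimum-variance unbiased estimator of the Simpson
#' repeat rate: \deqn{\hat D = \frac{n (n-1)}{\sum_i X_i (X_i - 1)}.}
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return Estimated asymptotic Simpson diversity in effective classes.
#' @export
simpson_asymptotic <- function(x) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (n < 2) stop("Simpson asymptote needs n >= 2")
  denom <- sum_kk1(fc)
  if (denom == 0)
    stop("all classes are singletons: the unbiased Simpson estimator is ",
         "undefined; report the observed Simpson diversity instead")
  n * (n - 1) / denom
}

#' Observed and asymptotic diversity profile (orders 0, 1, 2)
#'
#' Aggregates the observed Hill numbers and their asymptotic estimates into
#' one summary table per assemblage, the shape in which diversity panels are
#' conventionally reported.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return Data frame with columns `q`, `measure`, `observed`, `asymptote`.
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' asymptotic_profile(fc$East)
asymptotic_profile <- function(x) {
  fc <- as_freq_counts(x)
  data.frame(
    q = c(0, 1, 2),
    measure = c("Class richness", "Shannon diversity", "Simpson diversity"),
    observed = vapply(c(0, 1, 2), function(q) observed_hill(fc, q), 1),
    asymptote = c(chao1(fc), shannon_asymptotic(fc), simpson_asymptotic(fc)),
    stringsAsFactors = FALSE)
}
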