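# Coefficient of variation of class abundances: the heterogeneity measure
# contrasting even with skewed class-frequency distributions.

#' True coefficient of variation of class abundances
#'
#' The ratio of the population standard deviation (divide-by-S) of the class
#' abundances to their mean. Zero for a perfectly even assemblage; invariant
#' to rescaling, so it applies equally to counts and probabilities.
#'
#' @param x Numeric vector of class abundances or probabilities (length S).
#' @return The CV, a non-negative scalar.
#' @export
#' @examples
#' true_cv(c(3, 1))  # population sd 1, mean 2 -> 0.5
true_cv <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty abundance set")
  mu <- mean(x)
  if (mu == 0) stop("mean abundance is zero; CV undefined")
  sqrt(mean((x - mu)^2)) / mu
}

#' Estimated coefficient of variation of class abundances
#'
#' Nonparametric estimator of the CV of the complete assemblage's class
#' abundances, driven by the Good-Turing sample coverage
#' \eqn{\hat C = 1 - f_1 / n}:
#' \deqn{\hat\gamma^2 = \max\left\{\frac{S_{obs}}{\hat C}
#'   \frac{\sum_k k (k-1) f_k}{n (n-1)} - 1,\; 0\right\}, \qquad
#'   \widehat{CV} = \sqrt{\hat\gamma^2}.}
#' On a complete, perfectly even sample the bracket is non-positive and the
#' estimate is exactly 0.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return An object of class `heterogeneity_estimate`: list with `cv_hat`,
#'   `gamma_sq`, and the inputs digest (`n`, `S_obs`, `c_hat`, `sum_kk1`).
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' estimated_cv(fc$West)$cv_hat  # 1.387
estimated_cv <- function(x) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (n < 2) stop("CV estimation needs n >= 2")
  f1 <- fk(fc, 1)
  c_hat <- 1 - f1 / n
  if (c_hat <= 0)
    stop("estimated coverage is zero (all singletons); CV not estimable")
  kk1 <- sum_kk1(fc)
  gamma_sq <- max((fc$S_obs / c_hat) * kk1 / (n * (n - 1)) - 1, 0)
  structure(list(cv_hat = sqrt(gamma_sq), gamma_sq = gamma_sq,
                 n = n, S_obs = fc$S_obs, c_hat = c_hat, sum_kk1 = kk1),
            class = "heterogeneity_estimate")
}

#' @export
print.heterogeneity_estimate <- function(x, ...) {
  cat(sprintf("<heterogeneity> CV_hat = %.3f (gamma^2 = %.4f, n = %d, S_obs = %d)\n",
              x$cv_hat, x$gamma_sq, x$n, x$S_obs))
  invisible(x)
}
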