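# Seamless size- and coverage-based rarefaction / extrapolation for
# Hill numbers of orders 0, 1, 2.

# log-scale binomial ratio C(a, b) / C(n, m), with C(a, b) = 0 when a < b.
# lchoose() returns -Inf for a < b, so exp() yields the right 0.
choose_ratio <- function(a, b, n, m) exp(lchoose(a, b) - lchoose(n, m))

#' Expected frequency counts of a rarefied subsample
#'
#' Under without-replacement subsampling of m individuals from the observed
#' n, the expected number of classes represented exactly j times is the
#' hypergeometric expectation
#' \deqn{E[f_j(m)] = \sum_i \binom{X_i}{j} \binom{n - X_i}{m - j} /
#'   \binom{n}{m}.}
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param m Subsample size, 1 <= m <= n.
#' @return Numeric vector `E[f_j(m)]` for j = 1..min(m, max X_i).
#' @export
#' @examples
#' expected_freq_counts(c(2, 1), m = 2)  # c(4/3, 1/3)
expected_freq_counts <- function(x, m) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (m < 1 || m > n) stop("need 1 <= m <= n; use extrapolation beyond n")
  k <- fc_k(fc)
  jmax <- min(m, max(k))
  # C(k, j) * C(n - k, m - j) / C(n, m), summed over classes grouped by k
  vapply(seq_len(jmax), function(j) {
    sum(fc$f * exp(lchoose(k, j) + lchoose(n - k, m - j) - lchoose(n, m)))
  }, 1)
}

#' Rarefied Hill number at subsample size m
#'
#' Expected diversity of a without-replacement subsample of size m <= n:
#' richness via the hypergeometric non-detection probabilities, Shannon via
#' the exponential of the expected subsample entropy, Simpson via the
#' unbiased repeat-rate estimator.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param m Subsample size, 1 <= m <= n.
#' @param q Diversity order: 0, 1 or 2.
#' @return Expected diversity at size m.
#' @export
#' @examples
#' rarefied_hill(c(2, 1), m = 2, q = 0)  # 5/3
rarefied_hill <- function(x, m, q) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (m < 1 || m > n) stop("need 1 <= m <= n; use extrapolation beyond n")
  if (!q %in% c(0, 1, 2)) stop("only diversity orders 0, 1, 2 are supported")
  k <- fc_k(fc)
  if (q == 0)
    return(fc$S_obs - sum(fc$f * choose_ratio(n - k, m, n, m)))
  if (q == 1) {
    if (m == 1) return(1)
    ef <- expected_freq_counts(fc, m)
    j <- seq_along(ef)
    return(exp(-sum(ef * (j / m) * log(j / m))))
  }
  # q = 2
  lambda <- sum_kk1(fc) / (n * (n - 1))
  1 / (1 / m + ((m - 1) / m) * lambda)
}

#' Extrapolated class richness at size n + m*
#'
#' Extends the richness curve beyond the observed sample using the Chao1
#' estimate of undetected richness \eqn{\hat f_0}:
#' \deqn{S(n + m^*) = S_{obs} + \hat f_0 \left[1 - \left(1 -
#'   \frac{f_1}{n \hat f_0 + f_1}\right)^{m^*}\right].}
#' At \eqn{m^* = 0} this is the observed richness; as \eqn{m^* \to \infty}
#' it approaches the Chao1 asymptote.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param m_star Additional individuals beyond n (>= 0).
#' @return Expected richness of a sample of size n + m_star.
#' @export
extrapolated_richness <- function(x, m_star) {
  fc <- as_freq_counts(x)
  if (m_star < 0) stop("m_star must be >= 0")
  f0 <- chao1(fc) - fc$S_obs
  if (f0 <= 0) return(as.numeric(fc$S_obs))
  f1 <- fk(fc, 1)
  fc$S_obs + f0 * (1 - (1 - f1 / (fc$n * f0 + f1))^m_star)
}

#' Extrapolated Shannon or Simpson diversity at size n + m*
#'
#' For q = 1 the extrapolated entropy is the size-weighted blend of the
#' observed entropy and the asymptotic entropy estimate,
#' \eqn{\frac{n}{n+m^*} \hat H_{obs} + \frac{m^*}{n+m^*} \hat H_{asy}},
#' exponentiated. For q = 2 the unbiased repeat-rate form evaluated at
#' \eqn{n + m^*} is used. Both tend to the corresponding asymptotic
#' estimators as \eqn{m^* \to \infty}.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param m_star Additional individuals beyond n (>= 0).
#' @param q Diversity order: 1 or 2.
#' @return Expected diversity of a sample of size n + m_star.
#' @export
extrapolated_hill <- function(x, m_star, q) {
  fc <- as_freq_counts(x)
  if (m_star < 0) stop("m_star must be >= 0")
  n <- fc$n
  if (q == 1) {
    h_obs <- observed_entropy(fc)
    h_asy <- log(shannon_asymptotic(fc))
    w <- n / (n + m_star)
    return(exp(w * h_obs + (1 - w) * h_asy))
  }
  if (q == 2) {
    m_tot <- n + m_star
    lambda <- sum_kk1(fc) / (n * (n - 1))
    return(1 / (1 / m_tot + ((m_tot - 1) / m_tot) * lambda))
  }
  stop("extrapolated_hill handles q = 1 or 2 (use extrapolated_richness for q = 0)")
}

#' Estimated sample coverage at an arbitrary sample size
#'
#' For rarefied sizes m < n the analytic expectation
#' \deqn{\hat C(m) = 1 - \sum_i \frac{X_i}{n}
#'   \binom{n - X_i}{m} / \binom{n - 1}{m}} is used; for extrapolated sizes
#' n + m* the geometric decay of the undetected mass,
#' \deqn{\hat C(n + m^*) = 1 - \frac{f_1}{n}\left[\frac{(n-1) f_1}
#'   {(n-1) f_1 + 2 f_2}\right]^{m^* + 1}.}
#' At m = n the second form reduces exactly to [sample_coverage()], so the
#' curve is seamless across the observed point.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param m Total sample size (may exceed n).
#' @return Estimated coverage in `[0, 1]`.
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' coverage_at_size(fc$East, 300)  # 0.760
coverage_at_size <- function(x, m) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (m < 1) stop("m must be >= 1")
  if (m < n) {
    k <- fc_k(fc)
    return(1 - sum(fc$f * (k / n) * choose_ratio(n - k, m, n - 1, m)))
  }
  # at m = n the extrapolation form reduces exactly to sample_coverage()
  f1 <- fk(fc, 1); f2 <- fk(fc, 2)
  if (f1 == 0) return(1)
  adj <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  1 - (f1 / n) * adj^(m - n + 1)
}

#' Smallest sample size reaching a target coverage
#'
#' Inverts [coverage_at_size()] by monotone bisection on integer m, returning
#' the smallest m whose estimated coverage is at least `target`. Used to put
#' coverage-based curves of different assemblages on a common coverage grid.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param target Coverage in (0, 1); must be attainable at a finite size.
#' @param m_max Upper bound for the search (default 100 * n).
#' @return Integer sample size.
#' @export
size_for_coverage <- function(x, target, m_max = NULL) {
  fc <- as_freq_counts(x)
  if (is.null(m_max)) m_max <- 100L * fc$n
  if (coverage_at_size(fc, m_max) < target)
    stop("target coverage not attainable below m_max")
  lo <- 1L; hi <- as.integer(m_max)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (coverage_at_size(fc, mid) >= target) hi <- mid else lo <- mid + 1L
  }
  lo
}

# diversity at an arbitrary total size, dispatching on segment
diversity_at_size <- function(fc, m, q) {
  n <- fc$n
  if (m < n) rarefied_hill(fc, m, q)
  else if (m == n) observed_hill(fc, q)
  else if (q == 0) extrapolated_richness(fc, m - n)
  else extrapolated_hill(fc, m - n, q)
}

#' Seamless rarefaction/extrapolation curve
#'
#' Builds the interpolated/observed/extrapolated diversity curve of order q
#' over a grid of sample sizes from 1 up to `base_size` (default 300 for
#' richness, 600 for Shannon and Simpson), always including the observed
#' size n. With `basis = "coverage"` the same points are indexed by their
#' estimated coverage. Optional bootstrap confidence bands resample `B`
#' assemblages from the coverage-adjusted bootstrap distribution and
#' recompute the whole curve for each replicate.
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @param q Diversity order: 0, 1 or 2.
#' @param basis `"size"` or `"coverage"` (x-axis of the curve).
#' @param base_size Maximum total sample size (default 300 if q = 0 else
#'   600); must be at least n.
#' @param grid_points Number of knots (default 40).
#' @param B Bootstrap replicates for 95% confidence bands (0 = none).
#' @param seed Seed for the bootstrap.
#' @return A data frame of class `div_curve` with columns `q`, `basis`, `m`,
#'   `m_star`, `coverage`, `qD`, `ci_low`, `ci_high`, `segment`.
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' head(build_curve(fc$East, q = 0, base_size = 300))
build_curve <- function(x, q, basis = c("size", "coverage"),
                        base_size = NULL, grid_points = 40, B = 0,
                        seed = NULL) {
  basis <- match.arg(basis)
  fc <- as_freq_counts(x)
  n <- fc$n
  if (is.null(base_size)) base_size <- if (q == 0) 300 else 600
  if (base_size < n) stop("base_size must be at least the observed size n")
  if (grid_points < 1) stop("empty curve grid")
  m_grid <- sort(unique(c(
    round(seq(1, base_size, length.out = grid_points)), n)))
  qD <- vapply(m_grid, function(m) diversity_at_size(fc, m, q), 1)
  cov <- vapply(m_grid, function(m) coverage_at_size(fc, m), 1)
  seg <- ifelse(m_grid < n, "rarefied",
                ifelse(m_grid == n, "observed", "extrapolated"))
  out <- data.frame(q = q, basis = basis, m = m_grid,
                    m_star = pmax(m_grid - n, 0),
                    coverage = cov, qD = qD,
                    ci_low = NA_real_, ci_high = NA_real_,
                    segment = seg, stringsAsFactors = FALSE)
  if (B > 0) {
    stat <- function(counts) {
      fcb <- as_freq_counts(counts)
      vapply(m_grid, function(m) diversity_at_size(fcb, m, q), 1)
    }
    br <- bootstrap_se(counts_from_fc(fc), stat, B = B, seed = seed)
    out$ci_low <- qD - 1.96 * br$se
    out$ci_high <- qD + 1.96 * br$se
  }
  class(out) <- c("div_curve", class(out))
  out
}
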