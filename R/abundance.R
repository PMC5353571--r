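# Class-abundance containers: abundance vectors X_i, sparse frequency
# counts f_k, and Good-Turing sample coverage.

#' Class-abundance vector
#'
#' A validated vector of per-class specimen counts X_i (all >= 1), the basic
#' input to every diversity estimator. The total n is `sum(x)` and the
#' observed class richness S_obs is `length(x)`.
#'
#' @param counts Positive integer counts, one per observed class.
#' @param codes Optional class-code labels (names).
#' @return An integer vector of class `abundance_vector`.
#' @export
#' @examples
#' av <- abundance_vector(c(2, 1), c("1-1-1-1-1-1-1", "1-2-1-1-2-2-1"))
#' sum(av); length(av)
abundance_vector <- function(counts, codes = NULL) {
  counts <- as.integer(counts)
  if (!length(counts)) stop("abundance vector is empty")
  if (any(is.na(counts) | counts < 1L))
    stop("all class abundances must be integers >= 1")
  if (!is.null(codes)) {
    if (length(codes) != length(counts))
      stop("codes and counts differ in length")
    if (anyDuplicated(codes)) stop("duplicate class codes")
    names(counts) <- codes
  }
  structure(counts, class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("<abundance vector> n =", sum(x), " S_obs =", length(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Frequency counts f_k
#'
#' The frequency-of-frequencies representation of a sample: `f[k]` is the
#' number of classes observed exactly k times. Stored sparsely (only k with
#' f_k > 0) since empirical tallies have long zero tails. The identities
#' `sum(f_k) = S_obs` and `sum(k * f_k) = n` always hold.
#'
#' @param k Integer multiplicities.
#' @param f_k Number of classes with each multiplicity (same length as `k`).
#' @return An object of class `freq_counts`: list with `n`, `S_obs` and the
#'   sparse named vector `f`.
#' @export
#' @examples
#' fc <- freq_counts(k = c(1, 2), f_k = c(1, 1))  # one singleton, one doubleton
#' fc$n; fc$S_obs
freq_counts <- function(k, f_k) {
  k <- as.integer(k); f_k <- as.integer(f_k)
  if (length(k) != length(f_k)) stop("k and f_k differ in length")
  if (any(f_k < 0L) || any(k < 1L)) stop("need k >= 1 and f_k >= 0")
  keep <- f_k > 0L
  k <- k[keep]; f_k <- f_k[keep]
  if (anyDuplicated(k)) stop("duplicated k")
  o <- order(k)
  f <- stats::setNames(f_k[o], k[o])
  structure(list(n = sum(k * f_k), S_obs = sum(f_k), f = f),
            class = "freq_counts")
}

#' @export
print.freq_counts <- function(x, ...) {
  cat("<frequency counts> n =", x$n, " S_obs =", x$S_obs, "\n")
  print(x$f)
  invisible(x)
}

#' Convert counts to frequency counts
#'
#' @param x An `abundance_vector` (or bare counts), or already a
#'   `freq_counts` object (returned unchanged).
#' @param ... Unused.
#' @return A `freq_counts` object.
#' @export
as_freq_counts <- function(x, ...) UseMethod("as_freq_counts")

#' @export
as_freq_counts.freq_counts <- function(x, ...) x

#' @export
as_freq_counts.default <- function(x, ...) {
  x <- abundance_vector(x)
  tab <- table(unclass(x))
  freq_counts(as.integer(names(tab)), as.integer(tab))
}

# f_k for a specific k (0 if absent)
fk <- function(fc, k) {
  v <- unname(fc$f[as.character(k)])
  ifelse(is.na(v), 0, as.numeric(v))
}

# multiplicities as integer vector aligned with fc$f
fc_k <- function(fc) as.integer(names(fc$f))

# reconstruct a per-class count vector from frequency counts
counts_from_fc <- function(fc) {
  abundance_vector(rep(fc_k(fc), fc$f))
}

# sum over classes of X_i (X_i - 1), computable from f_k alone
sum_kk1 <- function(fc) {
  k <- fc_k(fc)
  sum(k * (k - 1) * fc$f)
}

#' Improved Good-Turing sample coverage
#'
#' Estimates sample completeness -- the probability-weighted fraction of the
#' assemblage represented in the sample -- from singletons and doubletons:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.}
#' With no singletons the sample is judged complete (\eqn{\hat C = 1}).
#'
#' @param x Counts, `abundance_vector`, or `freq_counts`.
#' @return An object of class `coverage_estimate`: list with `c_hat`,
#'   `f1_share` (f1/n) and `adjustment` (the Good-Turing modification
#'   factor).
#' @export
#' @examples
#' fc <- freq_counts(k = c(1, 2), f_k = c(60, 15))  # plus heavier classes
#' sample_coverage(freq_counts(c(1, 2, 3, 4, 5, 6), c(60, 15, 7, 4, 1, 1)))
sample_coverage <- function(x) {
  fc <- as_freq_counts(x)
  n <- fc$n
  if (n < 1) stop("coverage undefined for an empty sample")
  f1 <- fk(fc, 1); f2 <- fk(fc, 2)
  if (f1 == 0) {
    adj <- 1
    c_hat <- 1
  } else {
    adj <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
    c_hat <- 1 - (f1 / n) * adj
  }
  structure(list(c_hat = c_hat, f1_share = f1 / n, adjustment = adj, n = n),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("<sample coverage> C_hat = %.4f (f1/n = %.4f, adjustment = %.4f)\n",
              x$c_hat, x$f1_share, x$adjustment))
  invisible(x)
}

#' Read abundance or frequency-count tables
#'
#' `read_abundances()` reads a CSV with columns `class_code`, `count` and
#' optionally `region`; `read_freq_counts()` reads columns `k`, `f_k` and
#' optionally `region` (the dialect in which a published frequency tally can
#' be entered directly). With a `region` column a named list is returned.
#'
#' @param path CSV file path.
#' @return An `abundance_vector` / `freq_counts`, or a named list of them.
#' @export
read_abundances <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class_code", "count") %in% names(d)))
    stop("abundance CSV needs columns class_code, count")
  build <- function(dd) abundance_vector(dd$count, dd$class_code)
  if ("region" %in% names(d)) lapply(split(d, d$region), build) else build(d)
}

#' @rdname read_abundances
#' @export
read_freq_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("k", "f_k") %in% names(d)))
    stop("frequency-count CSV needs columns k, f_k")
  build <- function(dd) freq_counts(dd$k, dd$f_k)
  if ("region" %in% names(d)) lapply(split(d, d$region), build) else build(d)
}

#' Published frequency tallies of Early Paleoindian point classes
#'
#' The class frequency counts of the continent-wide fluted-point sample
#' analysed by region: 154 points in 71 classes West of the Mississippi and
#' 138 points in 88 classes East of it. These tallies are the published
#' inputs from which every deterministic summary statistic of the study can
#' be recomputed.
#'
#' @return A named list with `East` and `West` [freq_counts()] objects.
#' @export
#' @examples
#' fc <- clovis_freq_counts()
#' sample_coverage(fc$East)$c_hat  # 0.567
clovis_freq_counts <- function() {
  path <- system.file("extdata", "clovis_freq_counts.csv",
                      package = "paleodiv", mustWork = TRUE)
  read_freq_counts(path)
}
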