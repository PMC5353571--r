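# Ground-truth-known synthetic data emulating the two-region fluted-point
# study structure, so every pipeline stage can be validated end to end.

#' Configuration for the synthetic-data generator
#'
#' Describes the regional sampling design to emulate. The defaults mirror
#' the study conditions: two regions split by a continental divide, a
#' West-like region of 154 specimens in 26 assemblages drawn from a strongly
#' skewed (geometric) class-abundance distribution with true CV near 1.4,
#' and an East-like region of 138 specimens in 23 assemblages drawn from a
#' nearly even (lognormal-noise) distribution with true CV near 0.65, with
#' 26 classes planted as shared between the regions.
#'
#' Abundance families: `uniform` (perfectly even, CV = 0),
#' `geometric` (`param` = decay ratio in (0,1)), `zipf` (`param` = exponent
#' s > 0), `lognormal` ("uniform plus noise": weights `exp(N(0, param))`).
#'
#' @param regions Named list; each element a list with `n_specimens`,
#'   `n_assemblages`, `S_true`, `family`, `param`.
#' @param shared_classes Number of classes planted in both regions.
#' @param seed Integer seed governing every draw.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    regions = list(
      West = list(n_specimens = 154, n_assemblages = 26, S_true = 200,
                  family = "geometric", param = 0.97),
      East = list(n_specimens = 138, n_assemblages = 23, S_true = 160,
                  family = "lognormal", param = 0.6)),
    shared_classes = 26,
    seed = 1) {
  for (r in regions) {
    stopifnot(r$S_true >= 1, r$n_specimens >= 1, r$n_assemblages >= 1)
    if (r$family == "geometric" && (r$param <= 0 || r$param >= 1))
      stop("geometric decay must lie in (0, 1)")
  }
  if (shared_classes > min(vapply(regions, `[[`, 1, "S_true")))
    stop("shared_classes exceeds a region's true class count")
  structure(list(regions = regions, shared_classes = shared_classes,
                 seed = seed),
            class = "synthetic_config")
}

# true class-probability vector for one region (may consume RNG for the
# lognormal family)
class_probabilities <- function(family, param, S) {
  w <- switch(family,
    uniform   = rep(1, S),
    geometric = param^(seq_len(S) - 1),
    zipf      = seq_len(S)^(-param),
    lognormal = exp(stats::rnorm(S, 0, param)),
    stop("unknown abundance family: ", family))
  sort(w / sum(w), decreasing = TRUE)
}

# true Hill numbers of a probability vector
true_hill <- function(p, q) {
  if (q == 0) length(p)
  else if (q == 1) exp(-sum(p * log(p)))
  else 1 / sum(p^2)
}

#' Draw regional class abundances with known truth
#'
#' For each configured region, builds the true class-probability vector,
#' draws a multinomial sample of the configured size, and records the exact
#' ground truth: the probabilities, the true CV, the true Hill numbers of
#' orders 0-2, and the realized true coverage of the draw (one minus the
#' summed probability of unseen classes).
#'
#' @param config A [synthetic_config()].
#' @return List with `abundances` (named list of [abundance_vector()]s,
#'   classes labelled by rank) and `truth` (per-region list with `p`,
#'   `true_cv`, `true_hill` (q = 0, 1, 2), `true_coverage`).
#' @export
sample_abundances <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  out <- list(abundances = list(), truth = list())
  for (rn in names(config$regions)) {
    r <- config$regions[[rn]]
    p <- class_probabilities(r$family, r$param, r$S_true)
    x <- as.vector(stats::rmultinom(1, r$n_specimens, p))
    seen <- x > 0
    out$abundances[[rn]] <- abundance_vector(
      x[seen], paste0(rn, "_class", which(seen)))
    out$truth[[rn]] <- list(
      p = p,
      true_cv = true_cv(p),
      true_hill = stats::setNames(vapply(0:2, function(q) true_hill(p, q), 1),
                                  paste0("q", 0:2)),
      true_coverage = sum(p[seen]))
  }
  out
}

#' Generate a measurement record that classifies into a given class
#'
#' Inverts the classification: samples raw morphometric measurements whose
#' derived character values fall strictly inside the target code's state
#' intervals, keeping a margin of 0.002 from every interval boundary so that
#' 3-decimal rounding cannot flip the state. Used both to build synthetic
#' specimen tables and to round-trip-test the classifier.
#'
#' @param code A [class_code()] (or integer state indices) for `scheme`.
#' @param scheme A `point_scheme`.
#' @param specimen_id,assemblage_id,region Label fields for the record.
#' @return A one-row data frame with the full measurement fields.
#' @export
measurements_for_class <- function(code, scheme = point_scheme(),
                                   specimen_id = "s1",
                                   assemblage_id = "a1", region = "East") {
  if (!inherits(code, "class_code")) code <- class_code(code, scheme)
  margin <- 0.002
  pick <- function(id) {
    spec <- scheme[[id]]
    i <- unclass(code)[[id]]
    b <- spec$states[i, ]
    stats::runif(1, b$lower + margin, b$upper - margin)
  }
  curv <- pick("II"); indent <- pick("III"); constr <- pick("IV")
  # for the broad state, floor the ratio at 1.2 to keep blade width plausible
  b7 <- scheme[["VII"]]$states[unclass(code)[["VII"]], ]
  lw <- stats::runif(1, max(b7$lower + margin, 1.2), b7$upper - margin)
  max_len <- 60
  max_w <- max_len / lw
  angles <- switch(unclass(code)[["V"]],
    stats::runif(2, 92.5, 130),   # diverging
    stats::runif(2, 88.1, 91.9),  # parallel
    stats::runif(2, 45, 87.5),    # converging
    c(stats::runif(1, 93, 120), stats::runif(1, 60, 87)))  # multistate
  flags <- switch(unclass(code)[["VI"]],
    c(TRUE, TRUE), c(FALSE, FALSE), c(TRUE, FALSE))
  data.frame(
    specimen_id = specimen_id, assemblage_id = assemblage_id,
    region = region,
    max_width_half = c("proximal", "distal")[unclass(code)[["I"]]],
    ear_span_a = 30,
    basal_depth_b = curv * 30,
    medial_length = max_len * (1 - indent),
    maximum_length = max_len,
    min_blade_width_proximal = max_w * (1 - constr),
    maximum_blade_width = max_w,
    left_tang_angle = angles[1], right_tang_angle = angles[2],
    left_ear_pointed = flags[1], right_ear_pointed = flags[2],
    stringsAsFactors = FALSE)
}

# all possible codes of a scheme as an integer matrix (rows = codes)
all_codes <- function(scheme) {
  as.matrix(expand.grid(lapply(scheme, function(s) seq_len(n_states(s)))))
}

#' Assemble a full synthetic specimen dataset with ground truth
#'
#' Builds, for each region, a pool of distinct class codes (the requested
#' number of cross-region shared codes occupy the highest-probability ranks
#' of both regions and the remaining pools are disjoint), draws specimen
#' class memberships from the regional abundance distribution, guarantees
#' every planted shared code at least one specimen in each region, spreads
#' specimens uniformly across assemblages, and generates a raw measurement
#' row per specimen via [measurements_for_class()].
#'
#' @param config A [synthetic_config()].
#' @param scheme A `point_scheme`.
#' @return List with `specimens` (measurement table readable by
#'   [classify_points()]), and `truth`: per-region `p`, `codes` (class code
#'   per rank), `abundances` (realized counts named by code), `true_cv`,
#'   `true_hill`, `true_coverage`, plus `shared_codes` and `profiles` (the
#'   generator's own record of each assemblage's class set, the oracle for
#'   the network module).
#' @export
assemble_dataset <- function(config, scheme = point_scheme()) {
  stopifnot(inherits(config, "synthetic_config"))
  space <- all_codes(scheme)
  total_distinct <- sum(vapply(config$regions, `[[`, 1, "S_true")) -
    config$shared_classes
  if (total_distinct > nrow(space))
    stop("infeasible: requested more distinct classes than the class space holds")
  set.seed(config$seed)
  pool_idx <- sample.int(nrow(space), total_distinct)
  shared_idx <- pool_idx[seq_len(config$shared_classes)]
  rest <- if (config$shared_classes > 0)
    pool_idx[-seq_len(config$shared_classes)] else pool_idx
  code_txt <- function(i) apply(space[i, , drop = FALSE], 1, paste, collapse = "-")

  specimens <- list(); truth <- list(); membership <- list()
  offset <- 0
  for (rn in names(config$regions)) {
    r <- config$regions[[rn]]
    own <- rest[offset + seq_len(r$S_true - config$shared_classes)]
    offset <- offset + r$S_true - config$shared_classes
    codes <- code_txt(c(shared_idx, own))  # shared codes get the top ranks
    p <- class_probabilities(r$family, r$param, r$S_true)
    x <- as.vector(stats::rmultinom(1, r$n_specimens, p))
    # guarantee every planted shared code is observed: move one specimen
    # from the largest class to each empty shared slot
    for (j in seq_len(config$shared_classes)) {
      if (x[j] == 0) {
        donor <- which.max(x)
        x[donor] <- x[donor] - 1L
        x[j] <- 1L
      }
    }
    seen <- x > 0
    assem_ids <- sprintf("%s_%02d", rn, seq_len(r$n_assemblages))
    class_of_spec <- rep(codes[seen], x[seen])
    assem_of_spec <- sample(assem_ids, length(class_of_spec), replace = TRUE)
    rows <- lapply(seq_along(class_of_spec), function(i) {
      idx <- as.integer(strsplit(class_of_spec[i], "-")[[1]])
      measurements_for_class(
        class_code(idx, scheme), scheme,
        specimen_id = sprintf("%s_s%03d", rn, i),
        assemblage_id = assem_of_spec[i], region = rn)
    })
    specimens[[rn]] <- do.call(rbind, rows)
    membership[[rn]] <- data.frame(assemblage_id = assem_of_spec,
                                   class_code = class_of_spec,
                                   stringsAsFactors = FALSE)
    truth[[rn]] <- list(
      p = p, codes = codes,
      abundances = stats::setNames(x[seen], codes[seen]),
      true_cv = true_cv(p),
      true_hill = stats::setNames(vapply(0:2, function(q) true_hill(p, q), 1),
                                  paste0("q", 0:2)),
      true_coverage = sum(p[seen]))
  }
  spec_tab <- do.call(rbind, specimens)
  rownames(spec_tab) <- NULL
  # generator-side bookkeeping of per-assemblage class sets (independent of
  # the classifier: recorded from the planted memberships themselves)
  memb <- do.call(rbind, membership)
  prof <- lapply(split(memb$class_code, memb$assemblage_id), unique)
  list(specimens = spec_tab,
       truth = c(truth, list(shared_codes = code_txt(shared_idx),
                             profiles = prof)))
}

#' Write a synthetic dataset to disk
#'
#' Emits the specimen measurement CSV (the dialect [read_specimens()]
#' reads), a per-region abundance CSV, and the ground truth as JSON.
#'
#' @param ds Output of [assemble_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  regions <- setdiff(names(ds$truth), c("shared_codes", "profiles"))
  ab <- do.call(rbind, lapply(regions, function(rn) {
    a <- ds$truth[[rn]]$abundances
    data.frame(class_code = names(a), count = as.integer(a), region = rn,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ab, file.path(dir, "abundances.csv"), row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
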