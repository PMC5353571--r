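# Specimen-level classification: raw measurements -> character values ->
# state indices -> class code.

measurement_fields <- c(
  "specimen_id", "assemblage_id", "region", "max_width_half",
  "ear_span_a", "basal_depth_b", "medial_length", "maximum_length",
  "min_blade_width_proximal", "maximum_blade_width",
  "left_tang_angle", "right_tang_angle",
  "left_ear_pointed", "right_ear_pointed")

check_record <- function(rec) {
  pos <- c("ear_span_a", "medial_length", "maximum_length",
           "min_blade_width_proximal", "maximum_blade_width")
  for (f in pos)
    if (!is.finite(rec[[f]]) || rec[[f]] <= 0)
      stop("invalid measurement: ", f, " must be positive (got ",
           rec[[f]], ")")
  if (!is.finite(rec$basal_depth_b) || rec$basal_depth_b < 0)
    stop("invalid measurement: basal_depth_b must be non-negative")
  if (rec$medial_length > rec$maximum_length)
    stop("invalid measurement: medial_length exceeds maximum_length")
  if (rec$min_blade_width_proximal > rec$maximum_blade_width)
    stop("invalid measurement: min_blade_width_proximal exceeds maximum_blade_width")
  for (f in c("left_tang_angle", "right_tang_angle"))
    if (!is.finite(rec[[f]]) || rec[[f]] <= 0 || rec[[f]] >= 180)
      stop("invalid measurement: ", f, " must lie in (0, 180)")
  if (!rec$max_width_half %in% c("proximal", "distal"))
    stop("invalid measurement: max_width_half must be 'proximal' or 'distal'")
  invisible(rec)
}

#' Derive the seven character values from one specimen's measurements
#'
#' Computes, from a single morphometric record, the value of each character
#' the classification scheme scores: the half holding the maximum blade
#' width (I), the basal curvature index -- perpendicular basal depth divided
#' by the span between the basal ears (II), the basal-indentation ratio --
#' indented fraction of maximum length (III), the constriction ratio --
#' waisted fraction of maximum blade width (IV), the pair of outer tang
#' angles (V), the pair of ear-pointedness flags (VI), and the length/width
#' ratio (VII). Ratios are returned at full precision; rounding happens only
#' at state assignment.
#'
#' @param rec A list or one-row data frame with the measurement fields
#'   `specimen_id`, `assemblage_id`, `region`, `max_width_half`
#'   (`"proximal"`/`"distal"`), `ear_span_a`, `basal_depth_b`,
#'   `medial_length`, `maximum_length`, `min_blade_width_proximal`,
#'   `maximum_blade_width`, `left_tang_angle`, `right_tang_angle`,
#'   `left_ear_pointed`, `right_ear_pointed` (lengths in mm, angles in
#'   degrees, pointedness logical).
#' @return A named list of character values `I` (character), `II`, `III`,
#'   `IV`, `VII` (numeric ratios), `V` (numeric length-2 angle pair), `VI`
#'   (logical length-2 flag pair).
#' @export
#' @examples
#' rec <- list(specimen_id = "s1", assemblage_id = "a1", region = "East",
#'             max_width_half = "proximal", ear_span_a = 30,
#'             basal_depth_b = 6, medial_length = 55, maximum_length = 60,
#'             min_blade_width_proximal = 20, maximum_blade_width = 25,
#'             left_tang_angle = 90, right_tang_angle = 91,
#'             left_ear_pointed = TRUE, right_ear_pointed = TRUE)
#' derive_characters(rec)
derive_characters <- function(rec) {
  rec <- as.list(rec)
  check_record(rec)
  list(
    I   = rec$max_width_half,
    II  = rec$basal_depth_b / rec$ear_span_a,
    III = (rec$maximum_length - rec$medial_length) / rec$maximum_length,
    IV  = (rec$maximum_blade_width - rec$min_blade_width_proximal) /
          rec$maximum_blade_width,
    V   = c(rec$left_tang_angle, rec$right_tang_angle),
    VI  = c(isTRUE(as.logical(rec$left_ear_pointed)),
            isTRUE(as.logical(rec$right_ear_pointed))),
    VII = rec$maximum_length / rec$maximum_blade_width
  )
}

match_interval <- function(value, spec) {
  v <- round(value, 3)
  hit <- which(spec$states$lower <= v & v <= spec$states$upper)
  if (length(hit) != 1L)
    stop(sprintf("character %s: value %.3f outside every state interval",
                 spec$id, v))
  hit
}

match_angles <- function(angles, spec) {
  lo <- spec$parallel_low; hi <- spec$parallel_high
  if (all(angles > hi)) 1L
  else if (all(angles >= lo & angles <= hi)) 2L
  else if (all(angles < lo)) 3L
  else 4L
}

match_flags <- function(flags) {
  if (all(flags)) 1L else if (all(!flags)) 2L else 3L
}

#' Assign character states and form the class code
#'
#' Maps derived character values to state indices: interval characters are
#' rounded to 3 decimals and matched to the unique inclusive interval; the
#' tang-angle pair is Diverging / Parallel / Converging / Multistate; the
#' pointedness pair is Both pointed / Both round / Multistate. The class
#' code is the dash-joined 1-based state indices in character order, e.g.
#' `"1-2-1-1-2-2-1"`.
#'
#' @param values Output of [derive_characters()] (entries for the scheme's
#'   characters).
#' @param scheme A `point_scheme` (default [point_scheme()]).
#' @return A `class_code` object: the integer state indices with the text
#'   form as `format()`/`as.character()`.
#' @export
assign_states <- function(values, scheme = point_scheme()) {
  stopifnot(inherits(scheme, "point_scheme"))
  idx <- vapply(scheme, function(spec) {
    v <- values[[spec$id]]
    if (is.null(v)) stop("no value supplied for character ", spec$id)
    switch(spec$type,
      categorical = {
        i <- if (identical(v, "proximal")) 1L
             else if (identical(v, "distal")) 2L
             else match(v, spec$states)
        if (is.na(i)) stop("character ", spec$id, ": unknown state ", v)
        as.integer(i)
      },
      interval   = match_interval(v, spec),
      angle_pair = match_angles(v, spec),
      flag_pair  = match_flags(v),
      stop("unknown character type ", spec$type))
  }, 1L)
  class_code(idx, scheme)
}

#' Construct a class code from state indices
#'
#' @param idx Integer vector of 1-based state indices, one per character of
#'   `scheme`, in scheme order.
#' @param scheme The `point_scheme` the indices refer to.
#' @return A `class_code` object.
#' @export
class_code <- function(idx, scheme = point_scheme()) {
  counts <- vapply(scheme, n_states, 1L)
  idx <- as.integer(idx)
  if (length(idx) != length(scheme))
    stop("class code needs one state index per character")
  if (any(idx < 1L | idx > counts))
    stop("state index out of range for its character")
  structure(idx, names = names(scheme), class = "class_code")
}

#' @export
format.class_code <- function(x, ...) paste(unclass(x), collapse = "-")

#' @export
as.character.class_code <- function(x, ...) format(x)

#' @export
print.class_code <- function(x, ...) {
  cat("<class code>", format(x), "\n")
  invisible(x)
}

#' Classify a table of specimens into paradigmatic classes
#'
#' Applies [derive_characters()] and [assign_states()] to every row of a
#' specimen measurement table. Rows failing the measurement invariants are
#' reported together in a single error.
#'
#' @param specimens Data frame with one row per specimen and the measurement
#'   fields (see [derive_characters()]).
#' @param scheme A `point_scheme`.
#' @return Data frame with columns `specimen_id`, `assemblage_id`, `region`,
#'   `class_code` (text codes).
#' @export
classify_points <- function(specimens, scheme = point_scheme()) {
  missing_cols <- setdiff(measurement_fields, names(specimens))
  if (length(missing_cols))
    stop("specimen table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(specimens$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(specimens$specimen_id[duplicated(specimens$specimen_id)]),
               collapse = ", "))
  codes <- character(nrow(specimens))
  bad <- character(0)
  for (i in seq_len(nrow(specimens))) {
    res <- tryCatch(
      format(assign_states(derive_characters(specimens[i, ]), scheme)),
      error = function(e) e)
    if (inherits(res, "error")) {
      bad <- c(bad, sprintf("row %d (%s): %s", i, specimens$specimen_id[i],
                            conditionMessage(res)))
    } else codes[i] <- res
  }
  if (length(bad))
    stop("malformed specimen rows:\n  ", paste(bad, collapse = "\n  "))
  data.frame(specimen_id = specimens$specimen_id,
             assemblage_id = specimens$assemblage_id,
             region = specimens$region,
             class_code = codes,
             stringsAsFactors = FALSE)
}

#' Tabulate classified specimens into class-abundance vectors
#'
#' Counts specimens per distinct class code within each level of a grouping
#' column (region by default). Totals equal specimen counts and the number
#' of distinct codes is the observed class richness.
#'
#' @param classified Data frame with columns `specimen_id`, `class_code` and
#'   the grouping column.
#' @param by Grouping column name (`"region"` or `"assemblage_id"`), or
#'   `NULL` to pool everything.
#' @return A named list of [abundance_vector()] objects (or a single one if
#'   `by` is `NULL`).
#' @export
tabulate_classes <- function(classified, by = "region") {
  if (anyDuplicated(classified$specimen_id))
    stop("duplicate specimen_id in classified table")
  if (is.null(by)) {
    tab <- table(classified$class_code)
    return(abundance_vector(as.integer(tab), names(tab)))
  }
  if (!by %in% names(classified)) stop("no such grouping column: ", by)
  lapply(split(classified, classified[[by]]), function(d) {
    tab <- table(d$class_code)
    abundance_vector(as.integer(tab), names(tab))
  })
}

#' Read specimen measurement or pre-classified tables
#'
#' `read_specimens()` reads a CSV with one row per specimen and the
#' measurement fields; `read_classified()` reads the pre-classified dialect
#' with columns `specimen_id`, `assemblage_id`, `region`, `class_code`.
#' Both validate column presence; `read_specimens()` additionally validates
#' every row's measurement invariants and reports all offending rows.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_specimens <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(measurement_fields, names(d))
  if (length(missing_cols))
    stop("specimen CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  d$left_ear_pointed <- as.logical(d$left_ear_pointed)
  d$right_ear_pointed <- as.logical(d$right_ear_pointed)
  bad <- character(0)
  for (i in seq_len(nrow(d))) {
    res <- tryCatch(check_record(as.list(d[i, ])), error = function(e) e)
    if (inherits(res, "error"))
      bad <- c(bad, sprintf("row %d: %s", i, conditionMessage(res)))
  }
  if (length(bad))
    stop("malformed specimen rows:\n  ", paste(bad, collapse = "\n  "))
  d
}

#' @rdname read_specimens
#' @export
read_classified <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "assemblage_id", "region", "class_code")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("classified CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  d
}
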