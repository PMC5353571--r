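#' The seven-character paradigmatic classification scheme for fluted points
#'
#' Returns the default classification scheme: seven morphometric characters,
#' each with a small set of mutually exclusive states. A class is the
#' intersection of one state per character, so the scheme spans
#' `prod(state counts)` = 2 x 3 x 3 x 3 x 4 x 3 x 3 = 1944 possible classes.
#'
#' Characters and states:
#' \describe{
#'   \item{I}{Location of maximum blade width: proximal (base) half or
#'     distal (tip) half.}
#'   \item{II}{Base shape, measured by the index of basal-edge curvature
#'     (maximum perpendicular depth of the basal concavity divided by the
#'     straight-line span between the basal ears): Flat (0.000-0.162),
#'     Concave (0.163-0.323), Very concave (0.324-0.486).}
#'   \item{III}{Basal-indentation ratio, the indented fraction of maximum
#'     length, (maximum length - medial length) / maximum length:
#'     Shallow (0.0000-0.0952), Deep (0.0953-0.1904),
#'     Very deep (0.1905-0.2856).}
#'   \item{IV}{Constriction ratio, the waisted fraction of maximum blade
#'     width, (maximum width - minimum proximal width) / maximum width:
#'     Little or no waist (0.000-0.131), Waist (0.132-0.262),
#'     Prominent waist (0.263-0.394).}
#'   \item{V}{Outer tang (basal ear) angle: Diverging (both tangs > 92
#'     degrees), Parallel (both within 88-92), Converging (both < 88),
#'     Multistate otherwise.}
#'   \item{VI}{Tang tip shape: Both pointed, Both round, Multistate.}
#'   \item{VII}{Length/width ratio, maximum length / maximum blade width:
#'     Broad (0.000-2.437), Narrow (2.438-3.354), Very narrow (3.355-4.795).}
#' }
#'
#' Continuous characters are matched to a state by rounding the derived value
#' to 3 decimals and testing inclusive interval bounds, so the printed
#' adjacent bounds (e.g. 0.162 / 0.163) can never both match. Values falling
#' outside every interval raise an error rather than being clamped: the state
#' ranges describe the sampled population and silently extending them would
#' change the class space.
#'
#' @return An object of class `point_scheme`: a list of seven character
#'   specifications, each with elements `id`, `name`, `type` (one of
#'   `"categorical"`, `"interval"`, `"angle_pair"`, `"flag_pair"`) and
#'   `states` (a character vector of labels, or for interval characters a
#'   data frame with columns `label`, `lower`, `upper`).
#' @seealso [assign_states()], [enumerate_class_space()], [read_scheme()]
#' @export
#' @examples
#' sch <- point_scheme()
#' enumerate_class_space(sch)  # 1944
point_scheme <- function() {
  iv <- function(labels, lower, upper)
    data.frame(label = labels, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  scheme <- list(
    list(id = "I", name = "Location of maximum blade width",
         type = "categorical", states = c("Proximal half", "Distal half")),
    list(id = "II", name = "Base shape (curvature index)",
         type = "interval",
         states = iv(c("Flat", "Concave", "Very concave"),
                     c(0.000, 0.163, 0.324), c(0.162, 0.323, 0.486))),
    list(id = "III", name = "Basal-indentation ratio",
         type = "interval",
         states = iv(c("Shallow", "Deep", "Very deep"),
                     c(0.0000, 0.0953, 0.1905), c(0.0952, 0.1904, 0.2856))),
    list(id = "IV", name = "Constriction ratio",
         type = "interval",
         states = iv(c("Little or no waist", "Waist", "Prominent waist"),
                     c(0.000, 0.132, 0.263), c(0.131, 0.262, 0.394))),
    list(id = "V", name = "Outer tang angle",
         type = "angle_pair",
         states = c("Diverging", "Parallel", "Converging", "Multistate"),
         parallel_low = 88, parallel_high = 92),
    list(id = "VI", name = "Tang tip shape",
         type = "flag_pair",
         states = c("Both pointed", "Both round", "Multistate")),
    list(id = "VII", name = "Length/width ratio",
         type = "interval",
         states = iv(c("Broad", "Narrow", "Very narrow"),
                     c(0.000, 2.438, 3.355), c(2.437, 3.354, 4.795)))
  )
  names(scheme) <- vapply(scheme, `[[`, "", "id")
  class(scheme) <- "point_scheme"
  scheme
}

n_states <- function(spec) {
  if (is.data.frame(spec$states)) nrow(spec$states) else length(spec$states)
}

state_labels <- function(spec) {
  if (is.data.frame(spec$states)) spec$states$label else spec$states
}

#' Number of possible classes spanned by a classification scheme
#'
#' The class space of a paradigmatic classification is the Cartesian product
#' of the character-state sets, so its size is the product of the per-
#' character state counts.
#'
#' @param scheme A `point_scheme`, e.g. [point_scheme()].
#' @return Integer count of possible classes (1944 for the default scheme).
#' @export
enumerate_class_space <- function(scheme) {
  stopifnot(inherits(scheme, "point_scheme"))
  prod(vapply(scheme, n_states, 1L))
}

#' Drop characters from a classification scheme
#'
#' Used for robustness runs that iteratively remove one character at a time.
#' At least one character must remain.
#'
#' @param scheme A `point_scheme`.
#' @param exclude Character ids to drop (e.g. `"V"` or `c("II", "VII")`).
#' @return A reduced `point_scheme`.
#' @export
subset_scheme <- function(scheme, exclude) {
  stopifnot(inherits(scheme, "point_scheme"))
  bad <- setdiff(exclude, names(scheme))
  if (length(bad))
    stop("unknown character id(s): ", paste(bad, collapse = ", "))
  keep <- setdiff(names(scheme), exclude)
  if (!length(keep)) stop("cannot exclude every character")
  out <- scheme[keep]
  class(out) <- "point_scheme"
  out
}

#' @export
print.point_scheme <- function(x, ...) {
  cat("Paradigmatic classification scheme:", length(x), "characters,",
      enumerate_class_space(x), "possible classes\n")
  for (spec in x) {
    cat(sprintf("  %-4s %s [%s]: %s\n", spec$id, spec$name, spec$type,
                paste(state_labels(spec), collapse = " | ")))
  }
  invisible(x)
}

#' Read or write a classification scheme as YAML
#'
#' The on-disk form lists, for each character, its id, name, type and states
#' (labels, plus inclusive lower/upper bounds for interval characters). This
#' lets robustness analyses rerun the pipeline under altered state breadths
#' without touching code.
#'
#' @param path File path (YAML).
#' @param scheme A `point_scheme` to serialize.
#' @return `read_scheme()` returns a `point_scheme`; `write_scheme()` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  scheme <- lapply(raw, function(ch) {
    if (identical(ch$type, "interval")) {
      ch$states <- data.frame(
        label = vapply(ch$states, `[[`, "", "label"),
        lower = vapply(ch$states, function(s) as.numeric(s$lower), 1),
        upper = vapply(ch$states, function(s) as.numeric(s$upper), 1),
        stringsAsFactors = FALSE)
    } else {
      ch$states <- unlist(ch$states)
    }
    ch
  })
  names(scheme) <- vapply(scheme, `[[`, "", "id")
  class(scheme) <- "point_scheme"
  scheme
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "point_scheme"))
  raw <- lapply(unclass(scheme), function(ch) {
    if (is.data.frame(ch$states)) {
      ch$states <- lapply(seq_len(nrow(ch$states)), function(i)
        list(label = ch$states$label[i], lower = ch$states$lower[i],
             upper = ch$states$upper[i]))
    } else {
      ch$states <- as.list(ch$states)
    }
    ch
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
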