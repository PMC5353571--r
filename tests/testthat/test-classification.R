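test_that("derived character values follow their geometric definitions", {
  # zero basal depth forces zero curvature; equal medial/max length means
  # no indentation
  v <- derive_characters(template_record(basal_depth_b = 0,
                                         medial_length = 60))
  expect_equal(v$II, 0)
  expect_equal(v$III, 0)
  # length/width 70/25 = 2.8 falls in the "Narrow" interval
  v <- derive_characters(template_record(maximum_length = 70,
                                         medial_length = 65,
                                         maximum_blade_width = 25))
  expect_equal(v$VII, 2.8)
  code <- assign_states(v)
  expect_equal(unclass(code)[["VII"]], 2L)
})

test_that("invalid measurements raise errors naming the offending field", {
  expect_error(derive_characters(template_record(ear_span_a = 0)),
               "ear_span_a")
  expect_error(derive_characters(template_record(maximum_blade_width = -1)),
               "maximum_blade_width")
  expect_error(derive_characters(template_record(medial_length = 61)),
               "medial_length")
  expect_error(derive_characters(template_record(left_tang_angle = 190)),
               "left_tang_angle")
})

test_that("tang-angle and pointedness pairs map to the right categorical states", {
  sch <- point_scheme()
  base <- derive_characters(template_record())
  cases <- list(
    list(angles = c(90, 90), state = 2L),    # parallel
    list(angles = c(95, 110), state = 1L),   # diverging
    list(angles = c(80, 85), state = 3L),    # converging
    list(angles = c(95, 85), state = 4L),    # mixed -> multistate
    list(angles = c(92, 88), state = 2L))    # inclusive bounds
  for (cs in cases) {
    v <- base; v$V <- cs$angles
    expect_identical(unclass(assign_states(v, sch))[["V"]], cs$state)
  }
  v <- base; v$VI <- c(FALSE, FALSE)
  expect_identical(unclass(assign_states(v, sch))[["VI"]], 2L)
  v$VI <- c(TRUE, FALSE)
  expect_identical(unclass(assign_states(v, sch))[["VI"]], 3L)
})

test_that("interval matching rounds to 3 decimals then matches inclusively", {
  sch <- point_scheme()
  base <- derive_characters(template_record())
  # curvature 0.2 sits in the middle concavity interval
  v <- base; v$II <- 0.2
  expect_identical(unclass(assign_states(v, sch))[["II"]], 2L)
  # 0.1625 rounds to 0.162 (bottom interval); 0.1626 rounds to 0.163 (next)
  v$II <- 0.16249
  expect_identical(unclass(assign_states(v, sch))[["II"]], 1L)
  v$II <- 0.1626
  expect_identical(unclass(assign_states(v, sch))[["II"]], 2L)
  # values above the top interval are errors, not clamped
  v$II <- 0.6
  expect_error(assign_states(v, sch), "outside every state interval")
})

test_that("class space size is the product of state counts", {
  expect_equal(enumerate_class_space(point_scheme()), 1944)
  # brute-force enumeration on a reduced scheme agrees with the product
  sch <- subset_scheme(point_scheme(), c("I", "V"))
  combos <- expand.grid(lapply(sch, function(s)
    seq_len(if (is.data.frame(s$states)) nrow(s$states) else length(s$states))))
  expect_equal(enumerate_class_space(sch), nrow(unique(combos)))
  # dropping the 4-state character divides the space by 4
  expect_equal(enumerate_class_space(subset_scheme(point_scheme(), "V")),
               1944 / 4)
})

test_that("tabulation counts classes and preserves totals", {
  cl <- data.frame(specimen_id = c("a", "b", "c"),
                   assemblage_id = "x", region = "East",
                   class_code = c("A", "A", "B"), stringsAsFactors = FALSE)
  av <- tabulate_classes(cl, by = NULL)
  expect_equal(sum(av), 3)
  expect_equal(length(av), 2)
  expect_equal(as.integer(av[c("A", "B")]), c(2L, 1L))
  cl$specimen_id <- c("a", "a", "c")
  expect_error(tabulate_classes(cl, by = NULL), "duplicate specimen_id")
})

test_that("scheme YAML serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(point_scheme(), path)
  sch2 <- read_scheme(path)
  expect_equal(enumerate_class_space(sch2), 1944)
  v <- derive_characters(template_record())
  expect_identical(format(assign_states(v, sch2)),
                   format(assign_states(v, point_scheme())))
})

test_that("classification round-trips measurements generated inside a class", {
  sch <- point_scheme()
  set.seed(11)
  counts <- vapply(sch, function(s)
    if (is.data.frame(s$states)) nrow(s$states) else length(s$states), 1L)
  for (i in 1:50) {
    idx <- vapply(counts, function(k) sample.int(k, 1), 1L)
    code <- class_code(idx, sch)
    rec <- measurements_for_class(code, sch)
    expect_identical(format(assign_states(derive_characters(rec), sch)),
                     format(code))
  }
})
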