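test_that("abundance sampling is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  a <- sample_abundances(cfg)
  b <- sample_abundances(cfg)
  expect_identical(a, b)
  c2 <- sample_abundances(synthetic_config(seed = 8))
  expect_false(identical(a$abundances, c2$abundances))
})

test_that("truth records exact probabilities and derived quantities", {
  cfg <- synthetic_config(
    regions = list(U = list(n_specimens = 200, n_assemblages = 4,
                            S_true = 25, family = "uniform", param = NULL),
                   G = list(n_specimens = 200, n_assemblages = 4,
                            S_true = 30, family = "geometric", param = 0.5)),
    shared_classes = 5, seed = 3)
  out <- sample_abundances(cfg)
  # uniform family: true CV is exactly 0, true Hill numbers all S_true
  expect_equal(out$truth$U$true_cv, 0)
  expect_equal(unname(out$truth$U$true_hill), rep(25, 3))
  # geometric family: direct formula on the explicit probability vector
  p <- out$truth$G$p
  expect_equal(out$truth$G$true_cv, sqrt(mean((p - mean(p))^2)) / mean(p))
  expect_equal(sum(p), 1)
  # totals and realized coverage bookkeeping
  expect_equal(sum(out$abundances$G), 200)
  seen_mass <- out$truth$G$true_coverage
  expect_gte(seen_mass, 0); expect_lte(seen_mass, 1)
})

test_that("generated measurement records stay inside their class intervals", {
  sch <- point_scheme()
  set.seed(41)
  # a code with the flat-base state: curvature index must sit in (0, 0.162)
  code <- class_code(c(1, 1, 1, 1, 2, 2, 1), sch)
  rec <- measurements_for_class(code, sch)
  expect_gt(rec$basal_depth_b / rec$ear_span_a, 0)
  expect_lt(rec$basal_depth_b / rec$ear_span_a, 0.162)
  # a multistate tang code straddles the 88/92 boundaries
  code <- class_code(c(1, 1, 1, 1, 4, 3, 1), sch)
  rec <- measurements_for_class(code, sch)
  a <- sort(c(rec$left_tang_angle, rec$right_tang_angle))
  expect_lt(a[1], 88); expect_gt(a[2], 92)
  expect_false(rec$left_ear_pointed && rec$right_ear_pointed)
})

test_that("assembled datasets honour their planted bookkeeping", {
  cfg <- synthetic_config(seed = 5)
  ds <- assemble_dataset(cfg)
  expect_equal(nrow(ds$specimens), 154 + 138)
  expect_equal(sum(ds$specimens$region == "West"), 154)
  # every emitted row is accepted by the classification reader
  cl <- classify_points(ds$specimens)
  expect_equal(nrow(cl), nrow(ds$specimens))
  # tabulated abundances equal the generator's ground-truth counts
  tab <- tabulate_classes(cl, by = "region")
  for (rn in c("West", "East")) {
    truth <- ds$truth[[rn]]$abundances
    got <- unclass(tab[[rn]])
    expect_equal(sort(names(got)), sort(names(truth)))
    expect_equal(got[sort(names(got))],
                 as.integer(truth)[order(names(truth))],
                 ignore_attr = TRUE)
  }
  # the planted cross-region sharing is recovered exactly
  expect_equal(cross_region_shared_classes(cl), cfg$shared_classes)
  # network against the generator's own profile bookkeeping
  profs <- assemblage_profiles(cl)
  for (a in names(profs$class_sets))
    expect_setequal(profs$class_sets[[a]], ds$truth$profiles[[a]])
})

test_that("infeasible sharing requests are rejected", {
  expect_error(synthetic_config(shared_classes = 1000), "exceeds")
})

test_that("single assemblage per region yields no within-region edges", {
  cfg <- synthetic_config(
    regions = list(W = list(n_specimens = 30, n_assemblages = 1,
                            S_true = 20, family = "uniform", param = NULL),
                   E = list(n_specimens = 30, n_assemblages = 1,
                            S_true = 20, family = "uniform", param = NULL)),
    shared_classes = 0, seed = 2)
  ds <- assemble_dataset(cfg)
  cl <- classify_points(ds$specimens)
  net <- build_class_network(assemblage_profiles(cl))
  expect_equal(igraph::ecount(net), 0)
})

test_that("written synthetic bundles read back through the pipeline readers", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- synthetic_config(
    regions = list(W = list(n_specimens = 40, n_assemblages = 3,
                            S_true = 25, family = "geometric", param = 0.8),
                   E = list(n_specimens = 40, n_assemblages = 3,
                            S_true = 25, family = "uniform", param = NULL)),
    shared_classes = 4, seed = 9)
  write_synthetic(assemble_dataset(cfg), dir)
  sp <- read_specimens(file.path(dir, "specimens.csv"))
  expect_equal(nrow(sp), 80)
  avs <- read_abundances(file.path(dir, "abundances.csv"))
  expect_equal(sum(avs$W), 40)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$shared_codes), 4)
})
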