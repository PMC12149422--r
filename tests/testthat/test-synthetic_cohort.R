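test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(habitat_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(cohort_spec(intensity_sds = c(0, 5)), "positive")
  expect_error(cohort_spec(prevalence_high_grade = 1), "strictly between")
  expect_error(cohort_spec(module_sizes = c(150, 99)), ">= 100")
  expect_error(cohort_spec(module_trait_cor = 1), "inside \\(-1, 1\\)")
  expect_error(cohort_spec(survival_baseline_hazard = 0), "positive")
  expect_error(cohort_spec(n_genes = 300, module_sizes = c(150, 120, 100)),
               "at most n_genes")
})

test_that("tumor volumes carry a bimodal two-habitat intensity mixture", {
  spec <- cohort_spec(image_shape = c(24L, 24L, 24L), radius_range = c(6, 8),
                      mean_jitter_sd = 0, sd_jitter = 0, texture_jitter = 0,
                      fraction_jitter = 0)
  set.seed(1)
  v <- generate_tumor_volume(spec, data.frame(patient_id = "P1", grade = "low"))
  x1 <- v$image[v$habitat_truth == 1]
  x2 <- v$image[v$habitat_truth == 2]
  expect_equal(mean(x1), spec$intensity_means[1], tolerance = 0.1)
  expect_equal(mean(x2), spec$intensity_means[2], tolerance = 0.1)
  # both habitats populated at roughly the configured fraction
  expect_equal(length(x1) / sum(v$mask), 0.5, tolerance = 0.05)
  # masks attached: primary plus two repeats, all non-empty and overlapping
  expect_true(all(vapply(v$repeat_masks, sum, 1) > 0))
  expect_gt(sum(v$mask * v$repeat_masks$intra) / sum(v$mask), 0.7)
})

test_that("oversized tumors raise an error naming the offending dimensions", {
  spec <- small_spec()
  spec$radius_range <- c(30, 30)
  set.seed(1)
  expect_error(generate_tumor_volume(spec, data.frame(grade = "low")),
               "exceeds image bounds.*x.*y.*z")
  expect_error(generate_tumor_volume(spec, data.frame(grade = NULL)),
               "grade")
})

test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- generate_cohort(small_spec(n = 4))
  c2 <- generate_cohort(small_spec(n = 4))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$volumes[[3]]$image, c2$volumes[[3]]$image)
  expect_identical(c1$volumes[[2]]$repeat_masks, c2$volumes[[2]]$repeat_masks)
})

test_that("zero grade effect leaves low-density-habitat texture grade-free", {
  spec <- cohort_spec(n_patients = 1, image_shape = c(22L, 22L, 22L),
                      radius_range = c(5, 7), grade_effect = 0,
                      mean_jitter_sd = 0, sd_jitter = 0, texture_jitter = 0)
  stat <- function(grade, seed) {
    set.seed(seed)
    v <- generate_tumor_volume(spec, data.frame(patient_id = "P", grade = grade))
    stats::sd(v$image[v$habitat_truth == 1])
  }
  lo <- vapply(1:12, function(s) stat("low", s), numeric(1))
  hi <- vapply(1:12, function(s) stat("high", 100 + s), numeric(1))
  expect_gt(stats::wilcox.test(lo, hi)$p.value, 0.01)
})

test_that("survival times follow the exponential risk model", {
  spec <- cohort_spec(censoring_max = Inf, survival_risk_coef = 0.8)
  set.seed(3)
  risk <- c(rep(0, 1000), rep(1, 1000))
  sv <- generate_survival(spec, risk)
  expect_true(all(sv$os_event == 1))   # no censoring
  expect_true(all(sv$os_time > 0))
  # closed-form exponential medians: log(2)/h0 and log(2)/(h0 e^coef)
  med0 <- log(2) / spec$survival_baseline_hazard
  med1 <- log(2) / (spec$survival_baseline_hazard * exp(0.8))
  expect_equal(median(sv$os_time[risk == 0]), med0, tolerance = 0.15)
  expect_equal(median(sv$os_time[risk == 1]), med1, tolerance = 0.15)
  expect_lt(median(sv$os_time[risk == 1]), median(sv$os_time[risk == 0]))
  expect_error(generate_survival(spec, c(1, NA)), "finite")
  # with censoring enabled, both outcomes occur
  spec2 <- cohort_spec(censoring_max = 30)
  set.seed(4)
  sv2 <- generate_survival(spec2, rnorm(300))
  expect_true(all(c(0, 1) %in% sv2$os_event))
})

test_that("expression generator plants modules with the target trait link", {
  spec <- cohort_spec()
  set.seed(11)
  trait <- rnorm(100)
  ge <- generate_expression(spec, trait)
  expect_equal(dim(ge$expr), c(600L, 100L))
  expect_true(all(apply(ge$expr, 1, stats::sd) > 0))
  # planted factor of module 1 hits the target correlation exactly
  expect_equal(cor(ge$factors[, 1], trait), spec$module_trait_cor,
               tolerance = 1e-10)
  # other factors near-orthogonal to the trait
  expect_lt(max(abs(cor(ge$factors[, -1], trait))), 0.2)
  # average within-module correlation exceeds between-module correlation
  cm <- cor(t(ge$expr))
  lab <- ge$module_truth
  within <- mean(abs(cm[lab == "planted1", lab == "planted1"]))
  between <- mean(abs(cm[lab == "planted1", lab == "planted2"]))
  expect_gt(within, between)
  expect_error(generate_expression(cohort_spec(module_trait_cor = 0.999999999),
                                   trait), NA)
})

test_that("zero loading removes within-module correlation", {
  spec <- cohort_spec(module_loading = 0)
  set.seed(12)
  ge <- generate_expression(spec, rnorm(80))
  cm <- cor(t(ge$expr[ge$module_truth == "planted1", ]))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.12)
})

test_that("zero target correlation leaves all factors unlinked to the trait", {
  spec <- cohort_spec(module_trait_cor = 0)
  set.seed(13)
  trait <- rnorm(100)
  ge <- generate_expression(spec, trait)
  expect_lt(max(abs(cor(ge$factors, trait))), 0.2)
})

test_that("annotation generator covers planted modules and the enrichment layout", {
  spec <- cohort_spec()
  set.seed(14)
  ge <- generate_expression(spec, rnorm(50))
  ann <- generate_annotation(ge$module_truth)
  expect_named(ann, c("term_id", "term_name", "gene"))
  expect_true("T_planted1" %in% ann$term_id)
  planted_term <- ann$gene[ann$term_id == "T_planted1"]
  expect_true(all(ge$module_truth[planted_term] == "planted1"))
})

test_that("generated cohorts satisfy downstream preconditions", {
  coh <- small_cohort()
  expect_s3_class(coh, "synthetic_cohort")
  expect_true(all(vapply(coh$volumes, function(v) sum(v$mask) > 0, logical(1))))
  expect_true(all(coh$clinical$os_time > 0))
  expect_true(all(coh$clinical$grade %in% c("high", "low")))
  expect_true(all(coh$clinical$tnm %in% c("high", "low")))
})
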