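# ANOVA -> Gaussian weighting -> normalised pattern.

test_that("two-group ANOVA reduces to the equal-variance t-test (F = t^2)", {
  set.seed(1)
  df <- data.frame(subject_id = sprintf("s%02d", 1:20),
                   diagnosis = rep(c("NC", "AD"), each = 10),
                   view = "V1",
                   roi_1 = rnorm(20), roi_2 = rnorm(20) + rep(c(0, 1), each = 10),
                   stringsAsFactors = FALSE)
  tab <- cohort_table(df, roi_atlas(1:2))
  p <- anova_pvalues(tab, "V1")
  for (i in 1:2) {
    x <- view_matrix(tab, "V1")[, i]
    tt <- t.test(x[1:10], x[11:20], var.equal = TRUE)
    expect_equal(p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("a strongly graded ROI is overwhelmingly significant", {
  set.seed(2)
  n <- 30
  df <- data.frame(subject_id = sprintf("s%03d", 1:(3 * n)),
                   diagnosis = rep(c("NC", "MCI", "AD"), each = n),
                   view = "V1",
                   roi_1 = rep(c(0, 1, 2), each = n) + rnorm(3 * n, sd = 0.1),
                   roi_2 = rnorm(3 * n),
                   stringsAsFactors = FALSE)
  tab <- cohort_table(df, roi_atlas(1:2))
  p <- anova_pvalues(tab, "V1")
  expect_lt(p[1], 1e-10)
  expect_gt(p[2], 1e-4)
})

test_that("null features give calibrated (uniform-ish) p-values", {
  null <- generate_cohort(cohort_spec(n_per_group = c(50, 50, 50), K = 200,
                                      effect_sizes = c(NC = 0, MCI = 0, AD = 0),
                                      view_assignment = c(V1 = 1L),
                                      archetypes = {
                                        m <- matrix(0, 1, 200); m[1, 1:10] <- 0.1; m
                                      }),
                          seed = 77)
  p <- anova_pvalues(null$table, "V1")
  expect_gt(median(p), 0.3); expect_lt(median(p), 0.7)
})

test_that("degenerate group structures are rejected or flagged", {
  df <- tiny_table_df() # one subject per group
  tab <- cohort_table(df, roi_atlas(1:2))
  expect_error(anova_pvalues(tab, "GMV"), "fewer than 2")
  set.seed(3)
  df2 <- data.frame(subject_id = sprintf("s%02d", 1:12),
                    diagnosis = rep(c("NC", "AD"), each = 6), view = "V1",
                    roi_1 = 1, roi_2 = rnorm(12), stringsAsFactors = FALSE)
  tab2 <- cohort_table(df2, roi_atlas(1:2))
  expect_warning(p <- anova_pvalues(tab2, "V1"), "constant")
  expect_equal(p[1], 1)
})

test_that("the Gaussian weight transform matches its closed form", {
  cfg <- crossview_config()
  expect_identical(gaussian_weights(0, cfg), 1)
  expect_equal(gaussian_weights(0.05, cfg), exp(-1 / 2))
  expect_equal(gaussian_weights(1, cfg), exp(-200)) # underflows to 0
  p <- seq(0, 1, by = 0.01)
  w <- gaussian_weights(p, cfg)
  expect_equal(w, exp(-p^2 / (2 * 0.05^2)))
  expect_true(all(diff(w) < 0)) # strictly decreasing on [0, 1]
})

test_that("pattern normalisation yields a floored probability vector", {
  cfg <- crossview_config()
  expect_equal(normalize_pattern(rep(2, 5), cfg), rep(1 / 5, 5))
  out <- normalize_pattern(c(1, 0, 0), cfg)
  expect_equal(out, c(1, 1e-12, 1e-12) / (1 + 2e-12))
  set.seed(4)
  for (i in 1:1000) {
    w <- runif(sample(3:50, 1), 0, 10) * rbinom(1, 1, 0.95)
    out <- normalize_pattern(w, cfg)
    expect_true(abs(sum(out) - 1) < 1e-9)
    expect_true(all(out > 0))
  }
})

test_that("compute_pattern composes the three steps and recovers planted
           structure", {
  cohort <- make_simple_cohort(n = 40, K = 10, delta = c(0, 0.75, 1.5))
  pat <- compute_pattern(cohort$table, "V1")
  p <- anova_pvalues(cohort$table, "V1")
  expect_equal(pat$weights, gaussian_weights(p))
  expect_equal(pat$normalized, normalize_pattern(gaussian_weights(p)))
  planted <- cohort$truth$planted_by_view$V1
  top5 <- order(pat$normalized, decreasing = TRUE)[1:5]
  expect_true(all(top5 %in% planted))
  # tidy() exposes all three stages
  td <- tidy(pat)
  expect_equal(nrow(td), 10)
  expect_named(td, c("view", "roi_id", "p_value", "weight", "normalized"))
})

test_that("a pure-noise view yields a near-uniform pattern", {
  null <- generate_cohort(cohort_spec(n_per_group = c(60, 60, 60), K = 50,
                                      effect_sizes = c(NC = 0, MCI = 0, AD = 0),
                                      view_assignment = c(V1 = 1L),
                                      archetypes = {
                                        m <- matrix(0, 1, 50); m[1, 1:5] <- 0.2; m
                                      }),
                          seed = 11)
  pat <- compute_pattern(null$table, "V1")
  # aggregate flatness: a single null ROI can still draw a small p-value and
  # carry visible mass, so the check is on the mean deviation
  expect_lt(mean(abs(pat$normalized - 1 / 50)), 2 / 50)
  expect_gt(sum(pat$normalized[1:5]), 0) # planted set carries no special mass
  expect_lt(sum(pat$normalized[1:5]), 0.5)
})

test_that("planted ROIs absorb >= 80% of pattern mass at d = 1.5,
           n = 100 per group", {
  arch <- matrix(0, 1, 83); arch[1, 1:30] <- 1 / 30
  cohort <- generate_cohort(
    cohort_spec(n_per_group = c(100, 100, 100), K = 83, archetypes = arch,
                view_assignment = c(V1 = 1L),
                effect_sizes = c(NC = 0, MCI = 0.75, AD = 1.5)),
    seed = 5)
  pat <- compute_pattern(cohort$table, "V1")
  expect_gte(sum(pat$normalized[1:30]), 0.80)
})

test_that("ROI consistency typing follows the threshold rules", {
  mk <- function(w) structure(list(view_name = "v", p_values = 1 - w,
                                   weights = w, normalized = w / sum(w),
                                   roi_ids = seq_along(w)),
                              class = "view_pattern")
  # ROI 1 high everywhere, ROI 2 low everywhere, ROI 3 high in half the views
  pats <- list(mk(c(1, 0, 1)), mk(c(1, 0, 1)), mk(c(1, 0, 0)), mk(c(1, 0, 0)))
  types <- classify_roi_types(pats)
  expect_equal(types$type,
               c("disease-affected", "disease-spared", "view-specific"))
})
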