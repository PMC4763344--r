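# Kernels, cascade routing, tuning and cross-validation.

test_that("Gram matrices behave like convex RBF combinations", {
  cohort <- make_simple_cohort(n = 10, K = 4, seed = 2)
  tab <- cohort$table
  tab$views$V2 <- tab$views$V1[, c(2, 1, 3, 4)] * 2
  n <- nrow(tab$subjects)
  spec1 <- kernel_spec("V1", gamma = 0.5)
  k1 <- compute_kernel(tab, spec1, seq_len(n))
  expect_equal(unname(diag(k1)), rep(1, n)) # ||x - x|| = 0
  expect_true(isSymmetric(k1, tol = 1e-12))
  # degenerate combination weights collapse to the single-view kernel
  spec10 <- kernel_spec(c("V1", "V2"), gamma = c(0.5, 0.2), weights = c(1, 0))
  expect_equal(compute_kernel(tab, spec10, seq_len(n)), k1, tolerance = 1e-12)
  # uniform weights average the single-view kernels
  specu <- kernel_spec(c("V1", "V2"), gamma = c(0.5, 0.2))
  k2 <- compute_kernel(tab, kernel_spec("V2", gamma = 0.2), seq_len(n))
  expect_equal(compute_kernel(tab, specu, seq_len(n)), (k1 + k2) / 2,
               tolerance = 1e-12)
  # PSD on a 50-subject Gram
  big <- make_simple_cohort(n = 17, K = 5, seed = 3) # 51 subjects
  kb <- compute_kernel(big$table, kernel_spec("V1", gamma = 1),
                       seq_len(50))
  expect_gte(min(eigen(kb, symmetric = TRUE)$values), -1e-8)
})

test_that("cascade routing is the deterministic function of stage outputs", {
  # constant-stage mocks exercise all 2 x 2 x 3 output combinations
  for (s1 in c("NC", "REST")) for (s2 in c("AD", "NONAD"))
    for (s3 in c("NC", "MCI", "AD")) {
      models <- list(stage1 = list(constant = s1),
                     stage2 = list(constant = s2),
                     stage3 = list(list(fit = list(constant = s3),
                                        sel = 1L, pair = c("x", "y")),
                                   list(fit = list(constant = s3),
                                        sel = 1L, pair = c("x", "y")),
                                   list(fit = list(constant = s3),
                                        sel = 1L, pair = c("x", "y"))))
      got <- as.character(crossview:::cascade_predict_kernel(
        models, matrix(0, 1, 1)))
      want <- if (s1 == "NC") "NC" else if (s2 == "AD") "AD" else s3
      expect_identical(got, want)
      # restrict-to-MCI toggle
      got_r <- as.character(crossview:::cascade_predict_kernel(
        models, matrix(0, 1, 1), restrict_mci = TRUE))
      want_r <- if (s1 == "NC") "NC" else if (s2 == "AD") "AD" else "MCI"
      expect_identical(got_r, want_r)
    }
})

test_that("a separable cohort is fit perfectly on its training data", {
  cohort <- make_simple_cohort(n = 12, K = 6, delta = c(0, 3, 6), sd = 0.3,
                               seed = 4)
  spec <- kernel_spec("V1", gamma = 0.5)
  model <- train_cascade(cohort$table, spec,
                         hyperparams = list(C1 = 1000, C2 = 1000, C3 = 1000))
  pred <- predict_cascade(model, cohort$table)
  expect_equal(as.character(pred),
               as.character(cohort$table$subjects$diagnosis))
})

test_that("stage 1 coincides with a binary machine on relabelled data", {
  cohort <- make_simple_cohort(n = 12, K = 6, delta = c(0, 1, 2), seed = 5)
  tab <- cohort$table
  spec <- kernel_spec("V1", gamma = 0.3)
  model <- train_cascade(tab, spec, list(C1 = 10, C2 = 10, C3 = 10))
  n <- nrow(tab$subjects)
  ktr <- compute_kernel(tab, spec, seq_len(n))
  y1 <- factor(ifelse(tab$subjects$diagnosis == "NC", "NC", "REST"))
  direct <- kernlab::ksvm(kernlab::as.kernelMatrix(ktr), y1, type = "C-svc",
                          C = 10)
  sv <- kernlab::SVindex(direct)
  direct_pred <- kernlab::predict(
    direct, kernlab::as.kernelMatrix(ktr[, sv, drop = FALSE]))
  p1 <- crossview:::predict_binary(model$models$stage1, ktr)
  expect_equal(p1$label, as.character(direct_pred))
})

test_that("a missing class in training is an error", {
  cohort <- make_simple_cohort(n = 8, K = 4, seed = 6)
  no_ad <- which(cohort$table$subjects$diagnosis != "AD")
  expect_error(train_cascade(cohort$table, kernel_spec("V1"),
                             subjects = no_ad),
               "all three classes")
})

test_that("staging metrics follow the paper's conventions", {
  perfect <- compute_metrics(rep(c("NC", "MCI", "AD"), 4),
                             rep(c("NC", "MCI", "AD"), 4))
  expect_true(all(unlist(perfect$metrics) == 100))
  # all predicted MCI on a 2/2/2 cohort
  m <- compute_metrics(rep(c("NC", "MCI", "AD"), each = 2), rep("MCI", 6))
  expect_equal(m$metrics$accuracy, 100 / 3, tolerance = 1e-9)
  expect_equal(m$metrics$sensitivity, 100)
  expect_equal(m$metrics$specificity, 0)
  expect_equal(m$metrics$precision_MCI, 100 / 3, tolerance = 1e-9)
  expect_true(is.na(m$metrics$precision_NC)) # never predicted
  expect_true(is.na(m$metrics$precision_AD))
  expect_equal(unname(rowSums(m$confusion)), c(2, 2, 2))
})

test_that("random search is reproducible, honours budget 1, and never gets
           worse with more candidates", {
  cohort <- make_simple_cohort(n = 10, K = 4, seed = 7)
  cfg <- crossview_config(staging = list(inner_folds = 2))
  r1 <- random_search(cohort$table, "V1", budget = 1, seed = 3, config = cfg)
  expect_equal(nrow(r1$trace), 1)
  expect_equal(r1$score, r1$trace$score[1])
  r1b <- random_search(cohort$table, "V1", budget = 1, seed = 3, config = cfg)
  expect_identical(r1$hyperparams, r1b$hyperparams)
  expect_identical(r1$spec$gamma, r1b$spec$gamma)
  # the candidate stream is a prefix sequence: larger budgets only add
  r3 <- random_search(cohort$table, "V1", budget = 3, seed = 3, config = cfg)
  r12 <- random_search(cohort$table, "V1", budget = 12, seed = 3, config = cfg)
  expect_equal(r3$trace$score, r12$trace$score[1:3])
  expect_gte(r12$score, r3$score)
})

test_that("cross-validation partitions subjects and is seed-deterministic", {
  cohort <- make_simple_cohort(n = 10, K = 4, delta = c(0, 1.5, 3), seed = 8)
  cfg <- crossview_config(staging = list(folds = 3, budget = 2,
                                         inner_folds = 2))
  res <- cross_validate(cohort$table, "V1", cfg, seed = 2)
  expect_equal(sort(unique(res$folds)), 1:3)
  expect_equal(length(res$folds), 30)
  expect_equal(sum(res$confusion), 30) # every subject predicted once
  res2 <- cross_validate(cohort$table, "V1", cfg, seed = 2)
  expect_identical(res$fold_metrics, res2$fold_metrics)
  expect_identical(res$confusion, res2$confusion)
  # result surfaces
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$views, "V1")
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 100))
})
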