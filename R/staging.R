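# Disease staging with a cascade of kernel SVMs.
#
# Stage 1 separates NC from {MCI, AD}; predicted NC are final. Stage 2
# separates AD from non-AD among the rest; predicted AD are final. Stage 3
# is a three-class machine (one-vs-one voting) labelling the remainder.
# Single views use an RBF kernel; view combinations use a convex combination
# of per-view RBF kernels (multi-kernel SVM). The cascade exists because the
# cohort the design targets is heavily MCI-skewed, which biases any single
# three-class machine.

#' Kernel specification
#'
#' Describes the (multi-)kernel used by the cascade: one RBF width per view
#' and convex combination weights. A single view gets weight 1.
#'
#' @param view_names Character vector of one or more view names.
#' @param gamma Positive RBF width(s), recycled to the number of views.
#' @param weights Nonnegative combination weights summing to 1; default
#'   uniform.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(view_names, gamma = 1, weights = NULL) {
  m <- length(view_names)
  assert_that(m >= 1, "need at least one view")
  gamma <- rep_len(as.numeric(gamma), m)
  assert_that(all(gamma > 0), "gamma must be positive")
  if (is.null(weights)) weights <- rep(1 / m, m)
  assert_that(length(weights) == m, "one weight per view required")
  assert_that(all(weights >= 0) && abs(sum(weights) - 1) < 1e-8,
              "weights must be nonnegative and sum to 1")
  structure(list(view_names = view_names, gamma = gamma,
                 weights = as.numeric(weights)),
            class = "kernel_spec")
}

std_stats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_std <- function(x, st) sweep(sweep(x, 2, st$center), 2, st$scale, "/")

sqdist <- function(a, b = a) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

kernel_from_d2 <- function(d2_list, gamma, weights) {
  k <- 0
  for (v in seq_along(d2_list)) k <- k + weights[v] * exp(-gamma[v] * d2_list[[v]])
  k
}

#' Compute a (multi-view) Gram matrix
#'
#' `K(x, y) = sum_v w_v exp(-gamma_v ||x_v - y_v||^2)` over the selected
#' views, with each view z-standardised using statistics estimated from the
#' `rows` subjects (the training fold), so kernels stay comparable across
#' views of different scales. Symmetric positive semi-definite whenever
#' `rows == cols`.
#'
#' @param table A [cohort_table()].
#' @param spec A [kernel_spec()].
#' @param rows,cols Integer subject indices for the Gram rows and columns;
#'   `cols` defaults to `rows`.
#' @param stats Optional list of per-view standardisation statistics; by
#'   default estimated from `rows`.
#' @return A `length(rows) x length(cols)` matrix.
#' @export
compute_kernel <- function(table, spec, rows, cols = rows, stats = NULL) {
  xs <- lapply(seq_along(spec$view_names), function(v) {
    x <- view_matrix(table, spec$view_names[v])
    st <- if (is.null(stats)) std_stats(x[rows, , drop = FALSE]) else stats[[v]]
    list(r = apply_std(x[rows, , drop = FALSE], st),
         c = apply_std(x[cols, , drop = FALSE], st))
  })
  d2 <- lapply(xs, function(p) sqdist(p$r, p$c))
  kernel_from_d2(d2, spec$gamma, spec$weights)
}

# ---- cascade internals on precomputed kernels ---------------------------

fit_binary <- function(ktr, y, cost) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) return(list(constant = levels(y)[1]))
  m <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(ktr), y, type = "C-svc",
                  C = cost, prob.model = FALSE),
    error = function(e) NULL)
  if (is.null(m)) {
    tab <- table(y)
    return(list(constant = names(tab)[which.max(tab)]))
  }
  list(model = m, levels = levels(y))
}

predict_binary <- function(fit, kte) {
  n <- nrow(kte)
  if (!is.null(fit$constant))
    return(list(label = rep(fit$constant, n), margin = rep(Inf, n)))
  sv <- kernlab::SVindex(fit$model)
  km <- kernlab::as.kernelMatrix(kte[, sv, drop = FALSE])
  lab <- as.character(kernlab::predict(fit$model, km))
  dec <- tryCatch(as.numeric(kernlab::predict(fit$model, km, type = "decision")),
                  error = function(e) rep(NA_real_, n))
  list(label = lab, margin = abs(dec))
}

cascade_fit_kernel <- function(ktr, y, costs) {
  y <- factor(y, levels = DIAGNOSIS_LEVELS)
  assert_that(all(DIAGNOSIS_LEVELS %in% y),
              "training set must contain all three classes (NC, MCI, AD)")
  y1 <- factor(ifelse(y == "NC", "NC", "REST"), levels = c("NC", "REST"))
  y2 <- factor(ifelse(y == "AD", "AD", "NONAD"), levels = c("AD", "NONAD"))
  pairs <- list(c("NC", "MCI"), c("NC", "AD"), c("MCI", "AD"))
  s3 <- lapply(pairs, function(pr) {
    sel <- which(y %in% pr)
    list(fit = fit_binary(ktr[sel, sel, drop = FALSE], y[sel], costs$C3),
         sel = sel, pair = pr)
  })
  list(stage1 = fit_binary(ktr, y1, costs$C1),
       stage2 = fit_binary(ktr, y2, costs$C2),
       stage3 = s3)
}

# One-vs-one vote over the three pairwise machines; ties broken by summed
# decision magnitudes, then by factor order.
predict_stage3 <- function(s3, kte) {
  n <- nrow(kte)
  votes <- matrix(0, n, 3, dimnames = list(NULL, DIAGNOSIS_LEVELS))
  score <- matrix(0, n, 3, dimnames = list(NULL, DIAGNOSIS_LEVELS))
  for (mp in s3) {
    pr <- predict_binary(mp$fit, kte[, mp$sel, drop = FALSE])
    for (i in seq_len(n)) {
      lab <- pr$label[i]
      votes[i, lab] <- votes[i, lab] + 1
      sc <- pr$margin[i]
      score[i, lab] <- score[i, lab] + (if (is.finite(sc)) sc else 0)
    }
  }
  vapply(seq_len(n), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) {
      sc <- score[i, best]
      best <- best[which.max(sc)]
    }
    DIAGNOSIS_LEVELS[best[1]]
  }, character(1))
}

cascade_predict_kernel <- function(models, kte, restrict_mci = FALSE) {
  n <- nrow(kte)
  out <- rep(NA_character_, n)
  p1 <- predict_binary(models$stage1, kte)
  is_nc <- p1$label == "NC"
  out[is_nc] <- "NC"
  rest <- which(!is_nc)
  if (length(rest) > 0) {
    p2 <- predict_binary(models$stage2, kte[rest, , drop = FALSE])
    is_ad <- p2$label == "AD"
    out[rest[is_ad]] <- "AD"
    rest3 <- rest[!is_ad]
    if (length(rest3) > 0) {
      out[rest3] <- if (restrict_mci) "MCI"
      else predict_stage3(models$stage3, kte[rest3, , drop = FALSE])
    }
  }
  factor(out, levels = DIAGNOSIS_LEVELS)
}

# ---- exported cascade API ------------------------------------------------

#' Train the staging cascade
#'
#' Trains the three cascade stages on the same training subjects and the
#' same (multi-)kernel: stage 1 (NC vs rest), stage 2 (AD vs non-AD) and
#' stage 3 (three-class, one-vs-one).
#'
#' @param table A [cohort_table()].
#' @param spec A [kernel_spec()].
#' @param hyperparams List with per-stage soft-margin costs `C1`, `C2`, `C3`
#'   (defaults 1).
#' @param subjects Integer indices of the training subjects (default: all).
#' @param config A [crossview_config()] (uses
#'   `staging$stage3_restrict_mci`).
#' @return A `cascade_model`.
#' @export
train_cascade <- function(table, spec, hyperparams = list(C1 = 1, C2 = 1, C3 = 1),
                          subjects = seq_len(nrow(table$subjects)),
                          config = crossview_config()) {
  stats <- lapply(spec$view_names, function(v)
    std_stats(view_matrix(table, v)[subjects, , drop = FALSE]))
  ktr <- compute_kernel(table, spec, subjects, subjects, stats = stats)
  models <- cascade_fit_kernel(ktr, table$subjects$diagnosis[subjects],
                               hyperparams)
  structure(list(spec = spec, hyperparams = hyperparams,
                 train_idx = subjects, stats = stats, models = models,
                 restrict_mci = isTRUE(config$staging$stage3_restrict_mci)),
            class = "cascade_model")
}

#' Predict diagnoses with a trained cascade
#'
#' Routing is sequential: subjects the first stage calls NC are final;
#' remaining subjects the second stage calls AD are final; the third stage
#' labels the rest, and its verdict is accepted verbatim (including NC or
#' AD) unless the model was trained with `stage3_restrict_mci = TRUE`.
#'
#' @param model A [train_cascade()] result.
#' @param table A [cohort_table()] (same atlas/views as training).
#' @param subjects Integer indices of the subjects to predict (default all).
#' @return Factor of predicted labels (`NC`, `MCI`, `AD`).
#' @export
predict_cascade <- function(model, table,
                            subjects = seq_len(nrow(table$subjects))) {
  kte <- compute_kernel(table, model$spec, subjects, model$train_idx,
                        stats = model$stats)
  cascade_predict_kernel(model$models, kte, model$restrict_mci)
}

#' Staging performance metrics
#'
#' Per-class precision plus overall accuracy, specificity and sensitivity,
#' all in percent. NC is the negative class; MCI and AD together form the
#' positive class, so sensitivity is the fraction of patients (MCI or AD)
#' not labelled NC, and specificity the fraction of NC labelled NC. A class
#' never predicted yields an undefined (NA) precision, which fold averaging
#' skips.
#'
#' @param true,predicted Vectors/factors of labels in `{NC, MCI, AD}`.
#' @return List with `metrics` (one-row tibble) and `confusion`
#'   (3x3 table, rows = truth).
#' @examples
#' compute_metrics(rep(c("NC","MCI","AD"), 2), rep("MCI", 6))
#' @export
compute_metrics <- function(true, predicted) {
  true <- factor(true, levels = DIAGNOSIS_LEVELS)
  predicted <- factor(predicted, levels = DIAGNOSIS_LEVELS)
  cm <- table(true = true, predicted = predicted)
  prec <- vapply(DIAGNOSIS_LEVELS, function(cl) {
    denom <- sum(cm[, cl])
    if (denom == 0) NA_real_ else 100 * cm[cl, cl] / denom
  }, numeric(1))
  n <- length(true)
  pos <- true %in% c("MCI", "AD")
  metrics <- tibble::tibble(
    precision_NC = unname(prec["NC"]), precision_MCI = unname(prec["MCI"]),
    precision_AD = unname(prec["AD"]),
    accuracy = 100 * mean(true == predicted),
    specificity = if (any(!pos)) 100 * mean(predicted[!pos] == "NC") else NA_real_,
    sensitivity = if (any(pos)) 100 * mean(predicted[pos] != "NC") else NA_real_)
  list(metrics = metrics, confusion = cm)
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Random-search hyperparameter tuning for the cascade
#'
#' Samples `budget` configurations — per-view RBF widths log-uniform over
#' `gamma_range`, per-stage costs log-uniform over `cost_range`, and
#' Dirichlet(1) kernel weights for multi-view specs — and scores each by the
#' cascade's overall accuracy under stratified inner cross-validation on the
#' training subjects. The three stages are tuned jointly on the cascade
#' output ("trained together"). Ties keep the first-sampled configuration.
#'
#' @param table A [cohort_table()].
#' @param view_names Views entering the kernel.
#' @param budget Number of sampled configurations.
#' @param seed Integer seed (sampling and inner folds).
#' @param subjects Training subject indices (default all).
#' @param config A [crossview_config()] (`staging$inner_folds`,
#'   `staging$cost_range`, `staging$gamma_range`).
#' @return List with `spec` ([kernel_spec()]), `hyperparams`, `score`
#'   (inner-CV accuracy, %), and the search `trace` tibble.
#' @export
random_search <- function(table, view_names, budget = 60, seed = 20160223,
                          subjects = seq_len(nrow(table$subjects)),
                          config = crossview_config()) {
  assert_that(budget >= 1, "budget must be >= 1")
  st <- config$staging
  nv <- length(view_names)
  y <- table$subjects$diagnosis[subjects]
  seeds <- child_seeds(seed, 2)
  inner <- stratified_folds(as.character(y), st$inner_folds, seeds[1])
  # precompute standardized squared distances per inner fold and view
  fold_data <- lapply(seq_len(st$inner_folds), function(f) {
    tr <- subjects[inner != f]; te <- subjects[inner == f]
    d2 <- lapply(view_names, function(v) {
      x <- view_matrix(table, v)
      stt <- std_stats(x[tr, , drop = FALSE])
      xtr <- apply_std(x[tr, , drop = FALSE], stt)
      xte <- apply_std(x[te, , drop = FALSE], stt)
      list(tr = sqdist(xtr), te = sqdist(xte, xtr))
    })
    list(d2 = d2, ytr = y[inner != f], yte = y[inner == f])
  })
  usable <- vapply(fold_data, function(fd)
    all(DIAGNOSIS_LEVELS %in% fd$ytr) && length(fd$yte) > 0, logical(1))
  assert_that(any(usable), "no inner fold contains all three classes")
  fold_data <- fold_data[usable]
  cands <- local_seed(seeds[2], {
    lapply(seq_len(budget), function(i) {
      w <- if (nv == 1) 1 else { e <- rexp(nv); e / sum(e) }
      list(gamma = exp(runif(nv, log(st$gamma_range[1]), log(st$gamma_range[2]))),
           weights = w,
           costs = list(C1 = exp(runif(1, log(st$cost_range[1]), log(st$cost_range[2]))),
                        C2 = exp(runif(1, log(st$cost_range[1]), log(st$cost_range[2]))),
                        C3 = exp(runif(1, log(st$cost_range[1]), log(st$cost_range[2])))))
    })
  })
  scores <- vapply(cands, function(cand) {
    accs <- vapply(fold_data, function(fd) {
      ktr <- kernel_from_d2(lapply(fd$d2, `[[`, "tr"), cand$gamma, cand$weights)
      kte <- kernel_from_d2(lapply(fd$d2, `[[`, "te"), cand$gamma, cand$weights)
      models <- cascade_fit_kernel(ktr, fd$ytr, cand$costs)
      pred <- cascade_predict_kernel(models, kte,
                                     isTRUE(st$stage3_restrict_mci))
      100 * mean(pred == fd$yte)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(scores) # which.max returns the first maximum: tie rule
  cand <- cands[[best]]
  list(spec = kernel_spec(view_names, cand$gamma, cand$weights),
       hyperparams = cand$costs, score = scores[best],
       trace = tibble::tibble(
         candidate = seq_len(budget), score = scores,
         C1 = vapply(cands, function(c) c$costs$C1, numeric(1)),
         C2 = vapply(cands, function(c) c$costs$C2, numeric(1)),
         C3 = vapply(cands, function(c) c$costs$C3, numeric(1))))
}

#' Cross-validated staging of a cohort
#'
#' Stratified k-fold cross-validation of the cascade on one view or a view
#' combination: per fold, hyperparameters are tuned by [random_search()] on
#' the training subjects, the cascade is retrained on the whole training
#' fold with the selected configuration, and the held-out fold is predicted.
#' Metrics are computed per fold and summarised as mean and standard
#' deviation, alongside the pooled confusion matrix.
#'
#' @param table A [cohort_table()].
#' @param view_names Views entering the kernel (1 = RBF-SVM, 2+ = MK-SVM).
#' @param config A [crossview_config()] (`staging$folds`, `staging$budget`,
#'   ...).
#' @param seed Integer seed controlling folds and search.
#' @return A `staging_result` with per-fold metrics, their summary, the
#'   pooled confusion matrix and the fold assignment.
#' @examples
#' \donttest{
#' bench <- default_benchmark(seed = 1, n_scale = 0.2)
#' cfg <- crossview_config(staging = list(folds = 3, budget = 4,
#'                                        inner_folds = 2))
#' res <- cross_validate(bench$table, "GMV", cfg, seed = 1)
#' glance(res)
#' }
#' @export
cross_validate <- function(table, view_names, config = crossview_config(),
                           seed = config$seed) {
  st <- config$staging
  y <- table$subjects$diagnosis
  n <- length(y)
  seeds <- child_seeds(seed, st$folds + 1)
  fold <- stratified_folds(as.character(y), st$folds, seeds[st$folds + 1])
  fold_rows <- vector("list", st$folds)
  preds <- factor(rep(NA_character_, n), levels = DIAGNOSIS_LEVELS)
  configs <- vector("list", st$folds)
  for (f in seq_len(st$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    rs <- random_search(table, view_names, budget = st$budget,
                        seed = seeds[f], subjects = tr, config = config)
    model <- train_cascade(table, rs$spec, rs$hyperparams, subjects = tr,
                           config = config)
    preds[te] <- predict_cascade(model, table, te)
    configs[[f]] <- rs
    fold_rows[[f]] <- compute_metrics(y[te], preds[te])$metrics
  }
  fold_metrics <- dplyr::bind_cols(tibble::tibble(fold = seq_len(st$folds)),
                                   dplyr::bind_rows(fold_rows))
  summary <- fold_metrics |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     n_folds = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(view_names = view_names, fold_metrics = fold_metrics,
                 summary = summary,
                 confusion = table(true = y, predicted = preds),
                 folds = fold, configs = configs, seed = seed),
            class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat("<staging_result>", paste(x$view_names, collapse = " + "), "-",
      max(x$fold_metrics$fold), "fold CV\n")
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  accuracy %.2f +/- %.2f %%\n", acc$mean, acc$sd))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.staging_result <- function(x, ...) {
  dplyr::mutate(x$summary, views = paste(x$view_names, collapse = "|"),
                .before = 1)
}

#' @exportS3Method generics::glance
glance.staging_result <- function(x, ...) {
  wide <- stats::setNames(x$summary$mean, x$summary$metric)
  dplyr::bind_cols(tibble::tibble(views = paste(x$view_names, collapse = "|")),
                   tibble::as_tibble(as.list(wide)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.staging_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "% (mean +/- sd over folds)",
                  title = paste("Staging:",
                                paste(object$view_names, collapse = " + "))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
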