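noise_cohort <- function(n_a, n_b, p = 4, seed = 1, shift_b = 0) {
  nm <- paste0("f", seq_len(p))
  generate_cohort(cohort_spec(
    n = c(A = n_a, B = n_b),
    feature_mean = list(A = stats::setNames(rep(0, p), nm),
                        B = stats::setNames(rep(shift_b, p), nm)),
    feature_sd = list(A = stats::setNames(rep(1, p), nm),
                      B = stats::setNames(rep(1, p), nm)),
    seed = seed))
}

test_that("PCA keeps the fewest components covering the variance target", {
  set.seed(21)
  X <- tibble::tibble(f1 = rnorm(40), f2 = rnorm(40), f3 = rnorm(40),
                      label = factor(rep(c("A", "B"), 20)))
  # isotropic features: all 3 components needed at 95 %
  expect_identical(pca_select(X)$n_components, 3L)
  # duplicating every column must not change the count (rank argument)
  Xd <- dplyr::mutate(X, g1 = f1, g2 = f2, g3 = f3)
  expect_identical(pca_select(Xd)$n_components, 3L)
  # one dominant direction: 1 component at a loose target
  Y <- tibble::tibble(f1 = rnorm(40), label = X$label)
  Y$f2 <- Y$f1 + rnorm(40, 0, 1e-4)
  expect_identical(pca_select(Y, variance = 0.9)$n_components, 1L)
})

test_that("PCA eigenvalues match a direct eigendecomposition oracle", {
  set.seed(31)
  X <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30))
  p <- pca_select(X, label_col = "none")
  ev <- eigen(cor(as.matrix(X)))$values
  expect_equal(p$sdev^2, ev, tolerance = 1e-9)
})

test_that("zero-variance features are dropped with a warning", {
  X <- tibble::tibble(f1 = rnorm(20), f2 = rep(1, 20),
                      label = factor(rep(c("A", "B"), 10)))
  expect_warning(p <- pca_select(X), "zero-variance")
  expect_false("f2" %in% p$features)
})

test_that("projection of training data reproduces the fitted scores", {
  coh <- noise_cohort(10, 10, seed = 5)
  p <- pca_select(coh)
  proj <- predict(p, coh)
  expect_equal(as.matrix(proj),
               as.matrix(p$scores[, seq_len(p$n_components)]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ADASYN balances to the G = (n_maj - n_min) * beta equation", {
  coh <- noise_cohort(10, 40, seed = 7)
  bal <- balance_training(coh, seed = 1)
  counts <- table(bal$label)
  expect_identical(as.integer(counts[["A"]]), 40L)  # 10 + G, G = 30
  expect_identical(as.integer(counts[["B"]]), 40L)
  # already balanced: untouched
  cohb <- noise_cohort(15, 15, seed = 8)
  expect_identical(balance_training(cohb, seed = 1), cohb)
})

test_that("ADASYN synthetic points interpolate minority neighbours", {
  coh <- noise_cohort(12, 30, seed = 9)
  bal <- balance_training(coh, seed = 2)
  synth <- bal[(nrow(coh) + 1):nrow(bal), ]
  expect_true(all(synth$label == "A"))
  feats <- paste0("f", 1:4)
  mins <- dplyr::filter(coh, label == "A")
  for (f in feats) {
    expect_gte(min(synth[[f]]), min(mins[[f]]) - 1e-9)
    expect_lte(max(synth[[f]]), max(mins[[f]]) + 1e-9)
  }
})

test_that("a tiny minority class falls back to duplication with a warning", {
  coh <- noise_cohort(3, 20, seed = 10)
  expect_warning(bal <- balance_training(coh, seed = 3), "duplicating")
  expect_identical(as.integer(table(bal$label)[["A"]]), 20L)
})

test_that("classification metrics follow their defining formulas", {
  m <- classification_metrics(tp = 8, fp = 1, fn = 2, tn = 9)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$SENS, 0.8)
  expect_equal(m$SPEC, 0.9)
  expect_equal(m$PREC, 8 / 9)
  expect_equal(m$NPV, 9 / 11)
  expect_equal(m$F1SC, 16 / 19)
  # F1 consistency: F1 = 2 PREC SENS / (PREC + SENS)
  expect_equal(m$F1SC, 2 * m$PREC * m$SENS / (m$PREC + m$SENS))
})

test_that("LOOCV separates a separable cohort perfectly and leaks nothing", {
  fm <- list(A = c(f1 = 0, f2 = 1), B = c(f1 = 1, f2 = 0))
  fsd <- list(A = c(f1 = 0.02, f2 = 0.02), B = c(f1 = 0.02, f2 = 0.02))
  coh <- generate_cohort(cohort_spec(n = c(A = 6, B = 6), feature_mean = fm,
                                     feature_sd = fsd, seed = 12))
  ev <- suppressWarnings(evaluate_loocv(coh, seed = 4))
  expect_identical(ev$metrics$ACC, 1)
  expect_identical(ev$metrics$AUC, 1)
  expect_identical(nrow(ev$predictions), nrow(coh))
  # fold fingerprints exclude the held-out row
  for (i in seq_along(ev$settings$fold_rows)) {
    expect_false(i %in% ev$settings$fold_rows[[i]])
    expect_identical(length(ev$settings$fold_rows[[i]]), nrow(coh) - 1L)
  }
})

test_that("the tuned grid search also solves the separable cohort", {
  fm <- list(A = c(f1 = 0, f2 = 1), B = c(f1 = 1, f2 = 0))
  fsd <- list(A = c(f1 = 0.02, f2 = 0.02), B = c(f1 = 0.02, f2 = 0.02))
  coh <- generate_cohort(cohort_spec(n = c(A = 5, B = 5), feature_mean = fm,
                                     feature_sd = fsd, seed = 13))
  ev <- suppressWarnings(evaluate_loocv(coh, seed = 6, tune = TRUE,
                       tune_trees = c(100, 300), inner_folds = 5))
  expect_identical(ev$metrics$AUC, 1)
  expect_true(all(ev$predictions$num_trees %in% c(100, 300)))
})

test_that("AUC is invariant to monotone transformations of the scores", {
  coh <- noise_cohort(8, 12, seed = 14, shift_b = 1)
  ev <- suppressWarnings(evaluate_loocv(coh, seed = 8))
  roc1 <- pROC::roc(ev$predictions$label, ev$predictions$score,
                    levels = c("A", "B"), direction = "<", quiet = TRUE)
  roc2 <- pROC::roc(ev$predictions$label, stats::qlogis(ev$predictions$score / 1.0001 + 1e-6),
                    levels = c("A", "B"), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(roc1$auc), as.numeric(roc2$auc), tolerance = 1e-12)
})

test_that("Wilcoxon comparison matches exact enumeration on small groups", {
  res <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12))
  # exact two-sided p for complete separation of 3 vs 3: 2 / choose(6, 3)
  expect_equal(res$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  expect_false(res$significant)  # 0.1 > 0.05 despite complete separation
  # identical groups are not significant
  set.seed(15)
  v <- rnorm(20)
  expect_false(wilcoxon_compare(v, v)$significant)
  # a p-value exactly at the threshold counts as significant (inclusive)
  expect_true(wilcoxon_compare(1:3, c(10, 11, 12), alpha = 2 / 20)$significant)
  # all tied -> warning and p = 1
  expect_warning(res_t <- wilcoxon_compare(rep(1, 5), rep(1, 5)), "tied")
  expect_identical(res_t$p_value, 1)
  expect_error(wilcoxon_compare(numeric(0), 1:3), class = "empty_input")
})

test_that("per-feature comparison flags only the separated feature", {
  set.seed(18)
  coh <- tibble::tibble(
    label = factor(rep(c("A", "B"), each = 20)),
    f_sep = c(rnorm(20, 0), rnorm(20, 3)),
    f_null = rnorm(40))
  res <- compare_features(coh)
  expect_true(dplyr::filter(res, feature == "f_sep")$significant)
  expect_false(dplyr::filter(res, feature == "f_null")$significant)
})

test_that("an offset of zero reproduces the original features exactly", {
  m <- motion_model(top_bottom_delay = 0.2, fundamental_freq = 1,
                    duration = 4.5, seed = 41)
  ph <- generate_image_sequence(m, phantom_geometry(n_cols = 120))
  ph$contours <- thin_contours(ph$contours)
  res <- suppressWarnings(
    variability_experiment(ph, offsets = 0, n_trim = 8))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})
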