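feature_columns <- function(table, label_col = "label") {
  nm <- names(table)[vapply(table, is.numeric, TRUE)]
  setdiff(nm, c(label_col, "plaque", "true_delay"))
}

#' PCA feature selection at a variance-coverage criterion
#'
#' Standardises the feature columns and retains the fewest principal
#' components whose cumulative explained variance reaches the requested
#' coverage (95 percent by default). Zero-variance features are dropped with
#' a warning.
#'
#' @param table Cohort tibble: numeric feature columns plus a label column.
#' @param variance Target fraction of variance to cover.
#' @param label_col Name of the label column (kept alongside the scores).
#' @return A `plq_pca` object with `scores` (tibble of retained components
#'   plus the label), `rotation`, `center`, `scale`, `sdev`,
#'   `n_components`, `explained_variance`.
#' @export
pca_select <- function(table, variance = 0.95, label_col = "label") {
  feats <- feature_columns(table, label_col)
  if (length(feats) == 0) {
    stop_plq("no numeric feature columns found", "invalid_cohort")
  }
  X <- as.matrix(table[feats])
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warn(sprintf("dropping zero-variance feature(s): %s",
                 paste(feats[sds < 1e-12], collapse = ", ")))
    feats <- feats[sds >= 1e-12]
    X <- X[, feats, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance - 1e-12)[1]
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  if (label_col %in% names(table)) scores[[label_col]] <- table[[label_col]]
  structure(list(scores = scores, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, scale = pc$scale, sdev = pc$sdev,
                 n_components = k, explained_variance = expl,
                 features = feats, label_col = label_col),
            class = "plq_pca")
}

#' @export
print.plq_pca <- function(x, ...) {
  cat(sprintf("<plq_pca: %d of %d components cover %.1f%% of variance>\n",
              x$n_components, length(x$sdev),
              100 * sum(x$explained_variance[seq_len(x$n_components)])))
  invisible(x)
}

#' Project new data onto a fitted PCA
#' @param object A `plq_pca`.
#' @param newdata Tibble containing the original feature columns.
#' @param ... Unused.
#' @return Tibble of component scores.
#' @export
predict.plq_pca <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as_tibble(Xs %*% object$rotation)
}

#' @export
tidy.plq_pca <- function(x, ...) {
  as_tibble(x$rotation, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component", values_to = "loading")
}

#' @export
glance.plq_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         variance_covered = sum(x$explained_variance[seq_len(x$n_components)]),
         n_features = length(x$features))
}

#' Balance a training set with adaptive synthetic oversampling (ADASYN)
#'
#' Appends density-adaptive synthetic minority samples until the classes are
#' (near) balanced: more synthetic points are generated around minority
#' samples whose neighbourhoods are dominated by the majority class. Applied
#' only inside training folds; test data are never resampled.
#'
#' @param train Training tibble (numeric features plus label column).
#' @param label_col Name of the binary label column.
#' @param k Number of nearest neighbours.
#' @param beta Target balance level: `G = (n_maj - n_min) * beta` synthetic
#'   samples are generated.
#' @param seed Optional seed.
#' @return The training tibble with synthetic minority rows appended.
#' @export
balance_training <- function(train, label_col = "label", k = 5, beta = 1,
                             seed = NULL) {
  y <- factor(train[[label_col]])
  if (nlevels(droplevels(y)) != 2) {
    stop_plq("training data must contain exactly two classes", "invalid_cohort")
  }
  y <- droplevels(y)
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  G <- round((n_maj - n_min) * beta)
  if (G == 0) return(train)
  feats <- feature_columns(train, label_col)
  X <- as.matrix(train[feats])
  min_idx <- which(y == minority)

  with_rng(seed, {
    if (n_min <= k) {
      warn("minority class too small for ADASYN neighbourhoods; duplicating instead")
      dup <- train[sample(min_idx, G, replace = TRUE), ]
      return(bind_rows(train, dup))
    }
    # neighbour search in standardised space
    sds <- apply(X, 2, stats::sd); sds[sds < 1e-12] <- 1
    Z <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
    D <- as.matrix(stats::dist(Z))
    diag(D) <- Inf
    r <- vapply(min_idx, function(i) {
      nb <- order(D[i, ])[seq_len(k)]
      sum(y[nb] != minority) / k
    }, 0)
    rhat <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
    g <- as.vector(stats::rmultinom(1, G, rhat))
    synth <- purrr::map(seq_along(min_idx), function(ii) {
      if (g[ii] == 0) return(NULL)
      i <- min_idx[ii]
      nb_min <- min_idx[order(D[i, min_idx])][seq_len(min(k, n_min - 1))]
      purrr::map(seq_len(g[ii]), function(s) {
        z <- if (length(nb_min) > 0) sample(nb_min, 1) else i
        lam <- runif(1)
        as_tibble(as.list(setNames(X[i, ] + lam * (X[z, ] - X[i, ]), feats)))
      }) |> list_rbind()
    }) |> purrr::compact() |> list_rbind()
    synth[[label_col]] <- factor(minority, levels = levels(y))
    bind_rows(train, synth)
  })
}

#' Confusion-matrix evaluation metrics
#'
#' @param tp,fp,fn,tn Confusion counts (positive class convention as in the
#'   returned metrics).
#' @return One-row tibble: `ACC, SENS, SPEC, PREC, NPV, F1SC`.
#' @examples
#' classification_metrics(tp = 8, fp = 1, fn = 2, tn = 9)
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tibble(ACC = (tp + tn) / (tp + fp + fn + tn),
         SENS = sens,
         SPEC = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         PREC = prec,
         NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         F1SC = if (isTRUE(prec + sens > 0)) 2 * prec * sens / (prec + sens) else NA_real_)
}

rf_fit <- function(scores, label_col, num_trees, mtry, seed) {
  ranger::ranger(
    dependent.variable.name = label_col, data = as.data.frame(scores),
    num.trees = num_trees, mtry = mtry, probability = TRUE,
    min.node.size = 1,  # grow full trees, the classification convention
    seed = seed, num.threads = 1)
}

rf_score <- function(fit, newdata, positive) {
  predict(fit, data = as.data.frame(newdata), num.threads = 1)$predictions[, positive]
}

# Inner k-fold CV accuracy over the (num_trees x mtry) grid; ties go to the
# cheaper model (fewer trees, then smaller mtry).
tune_rf <- function(scores, label_col, positive, tune_trees, tune_mtry,
                    inner_folds, seed) {
  y <- scores[[label_col]]
  n <- nrow(scores)
  folds <- with_rng(seed, {
    repeat {
      f <- sample(rep(seq_len(inner_folds), length.out = n))
      ok <- all(vapply(seq_len(inner_folds), function(k) {
        length(unique(y[f != k])) == 2
      }, TRUE))
      if (ok) break
    }
    f
  })
  grid <- tidyr::expand_grid(num_trees = tune_trees, mtry = tune_mtry)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    correct <- 0
    for (k in sort(unique(folds))) {
      tr <- scores[folds != k, ]; te <- scores[folds == k, ]
      fit <- rf_fit(tr, label_col, grid$num_trees[gi], grid$mtry[gi], seed + gi)
      sc <- rf_score(fit, te, positive)
      pred <- ifelse(sc >= 0.5, positive, setdiff(levels(y), positive))
      correct <- correct + sum(pred == te[[label_col]])
    }
    correct / n
  }, 0)
  best <- order(-acc, grid$num_trees, grid$mtry)[1]
  list(num_trees = grid$num_trees[best], mtry = grid$mtry[best], acc = acc[best])
}

#' Leave-one-out evaluation of the phenotype classifier
#'
#' For every held-out plaque: PCA feature selection (95 percent variance) is
#' fitted on the remaining plaques, ADASYN balances the training scores, a
#' probability Random Forest is trained (optionally tuned on the grid of
#' 100-900 trees in steps of 200 and mtry from 2 to the number of retained
#' components, by inner 10-fold cross-validation), and the held-out plaque
#' is scored. Metrics and the ROC AUC are computed from the pooled held-out
#' scores. PCA and ADASYN are fitted strictly inside each training fold, so
#' the held-out plaque never leaks into feature selection or resampling.
#'
#' @param table Cohort tibble: feature columns plus a binary label column.
#' @param label_col Name of the label column.
#' @param positive Positive-class label; defaults to the majority class.
#' @param seed Master seed (per-fold seeds are derived from it).
#' @param pca_variance Variance coverage for [pca_select()].
#' @param balance Apply ADASYN inside each fold?
#' @param tune If `TRUE`, tune trees/mtry per fold by inner
#'   `inner_folds`-fold CV; if `FALSE`, use `num_trees` and `mtry`.
#' @param num_trees,mtry Forest size and features per split when
#'   `tune = FALSE` (`mtry = NULL` uses `floor(sqrt(p))`).
#' @param tune_trees Tree-count grid for tuning.
#' @param inner_folds Inner CV folds for tuning.
#' @return A `plq_eval` object: `metrics` (one-row tibble with ACC, SENS,
#'   SPEC, PREC, NPV, F1SC, AUC), `predictions` (per-plaque held-out
#'   scores), `settings`.
#' @export
evaluate_loocv <- function(table, label_col = "label", positive = NULL,
                           seed = 1, pca_variance = 0.95, balance = TRUE,
                           tune = FALSE, num_trees = 500, mtry = NULL,
                           tune_trees = seq(100, 900, by = 200),
                           inner_folds = 10) {
  y <- factor(table[[label_col]])
  if (nlevels(droplevels(y)) != 2) {
    stop_plq("the label column must be binary", "invalid_cohort")
  }
  y <- droplevels(y)
  n <- nrow(table)
  if (n < 10) {
    stop_plq("leave-one-out evaluation needs at least 10 plaques", "invalid_cohort")
  }
  if (is.null(positive)) {
    positive <- names(which.max(table(y)))
  }
  negative <- setdiff(levels(y), positive)
  fold_seeds <- derive_seeds(seed, n)

  fold_rows <- vector("list", n)
  preds <- purrr::map(seq_len(n), function(i) {
    train <- table[-i, , drop = FALSE]
    test <- table[i, , drop = FALSE]
    fold_rows[[i]] <<- setdiff(seq_len(n), i)
    pca <- suppressWarnings(pca_select(train, variance = pca_variance,
                                       label_col = label_col))
    tr_scores <- pca$scores
    tr_scores[[label_col]] <- droplevels(factor(train[[label_col]]))
    te_scores <- predict(pca, test)
    if (balance) {
      tr_scores <- balance_training(tr_scores, label_col = label_col,
                                    seed = fold_seeds[i])
    }
    p <- ncol(tr_scores) - 1L
    if (tune) {
      mtry_grid <- unique(pmin(seq(2, max(2, p)), p))
      tn <- tune_rf(tr_scores, label_col, positive,
                    tune_trees = tune_trees, tune_mtry = mtry_grid,
                    inner_folds = min(inner_folds, nrow(tr_scores)),
                    seed = fold_seeds[i])
      nt <- tn$num_trees; mt <- min(tn$mtry, p)
    } else {
      nt <- num_trees
      mt <- if (is.null(mtry)) max(1, floor(sqrt(p))) else min(mtry, p)
    }
    fit <- rf_fit(tr_scores, label_col, nt, mt, fold_seeds[i])
    tibble(plaque = i, label = y[i],
           score = rf_score(fit, te_scores, positive),
           num_trees = nt, mtry = mt)
  }) |> list_rbind()

  preds <- mutate(preds,
                  predicted = factor(ifelse(.data$score >= 0.5, positive, negative),
                                     levels = levels(y)))
  tp <- sum(preds$label == positive & preds$predicted == positive)
  fp <- sum(preds$label == negative & preds$predicted == positive)
  fn <- sum(preds$label == positive & preds$predicted == negative)
  tn <- sum(preds$label == negative & preds$predicted == negative)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = preds$label, predictor = preds$score,
    levels = c(negative, positive), direction = "<", quiet = TRUE)))
  metrics <- mutate(classification_metrics(tp, fp, fn, tn), AUC = auc)
  structure(list(metrics = metrics, predictions = preds,
                 settings = list(positive = positive, seed = seed,
                                 pca_variance = pca_variance, balance = balance,
                                 tune = tune, fold_rows = fold_rows)),
            class = "plq_eval")
}

#' @export
print.plq_eval <- function(x, ...) {
  cat("<plq_eval: leave-one-out evaluation>\n")
  print(as.data.frame(round(x$metrics, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.plq_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.plq_eval <- function(x, ...) {
  mutate(x$metrics, n = nrow(x$predictions), positive = x$settings$positive)
}

#' @export
autoplot.plq_eval <- function(object, ...) {
  roc <- pROC::roc(response = object$predictions$label,
                   predictor = object$predictions$score,
                   levels = c(setdiff(levels(object$predictions$label),
                                      object$settings$positive),
                              object$settings$positive),
                   direction = "<", quiet = TRUE)
  df <- tibble(fpr = 1 - roc$specificities, tpr = roc$sensitivities) |>
    arrange(.data$fpr, .data$tpr)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC, AUC = %.2f", object$metrics$AUC)) +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test; significance is declared for p-values equal to
#' or lower than 0.05. Completely tied data (every value identical across
#' both groups) yield p = 1 with a warning.
#'
#' @param group_a,group_b Numeric vectors of feature values.
#' @param alpha Significance threshold (inclusive).
#' @return One-row tibble: `p_value`, `significant`.
#' @export
wilcoxon_compare <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_plq("both groups must be non-empty", "empty_input")
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    warn("all values tied across both groups; p = 1")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(group_a, group_b)$p.value)
  }
  tibble(p_value = p, significant = p <= alpha)
}

#' Per-feature Wilcoxon comparison of a labelled cohort
#'
#' @param table Cohort tibble with feature columns and a binary label.
#' @param label_col Name of the label column.
#' @param alpha Significance threshold (inclusive).
#' @return Tibble `feature, p_value, significant`, one row per feature.
#' @export
compare_features <- function(table, label_col = "label", alpha = 0.05) {
  y <- factor(table[[label_col]])
  if (nlevels(droplevels(y)) != 2) {
    stop_plq("the label column must be binary", "invalid_cohort")
  }
  lv <- levels(droplevels(y))
  purrr::map(feature_columns(table, label_col), function(f) {
    res <- wilcoxon_compare(table[[f]][y == lv[1]], table[[f]][y == lv[2]],
                            alpha = alpha)
    mutate(res, feature = f, .before = 1)
  }) |> list_rbind()
}

#' Extract the 24-feature signature from an image sequence
#'
#' Convenience wrapper running the full image pipeline for one plaque:
#' tracking of the four ROI contours, wall-diameter selection, edge
#' trimming, filtering/windowing and the per-pair cross-correlation
#' features.
#'
#' @param seq An [image_sequence()].
#' @param contours Tibble of all four ROI contours (`roi, pixel, row, col`).
#' @param cfg A [tracker_config()].
#' @param n_trim Edge pixels trimmed from PTS/PBS.
#' @return One-row tibble of the 24 features.
#' @export
extract_features <- function(seq, contours, cfg = tracker_config(), n_trim = 25) {
  traj <- track_rois(seq, contours, cfg)
  roi_traj <- function(nm) filter(traj, .data$roi == nm)
  wall <- wall_diameter(roi_traj("AWL"), roi_traj("PWL"),
                        frame_rate = seq$frame_rate, spacing = seq$spacing)
  plaque_features(wall,
                  trim_plaque_edges(roi_traj("PTS"), n_trim),
                  trim_plaque_edges(roi_traj("PBS"), n_trim),
                  spacing = seq$spacing)
}

#' Contour-placement variability experiment
#'
#' Emulates inter/intra-observer annotation variability: for each of a set
#' of repeated phantom recordings, the plaque contours (PTS and PBS) are
#' displaced radially by 0-2 pixels and the full feature pipeline is
#' re-run. Per offset and per feature, the per-phantom feature values of
#' the displaced version are compared against the originals with the
#' Wilcoxon rank-sum test, mirroring the across-plaque comparison of mean
#' phase shifts used in observer-variability studies.
#'
#' @param phantoms A list of phantoms, each a list with elements `seq` (an
#'   [image_sequence()]) and `contours` (the four ROI contours), as
#'   returned by [generate_image_sequence()]; a single phantom is accepted.
#' @param offsets Radial offsets in pixels to test.
#' @param cfg A [tracker_config()].
#' @param n_trim Edge pixels trimmed from PTS/PBS.
#' @param features Feature columns compared (default: the mean phase shifts
#'   of the three cross-correlation types).
#' @param alpha Significance threshold (inclusive).
#' @return Tibble `offset, feature, p_value, significant`.
#' @export
variability_experiment <- function(phantoms, offsets = c(0, 0.5, 1, 1.5, 2),
                                   cfg = tracker_config(), n_trim = 25,
                                   features = c("mean_CC1", "mean_CC2", "mean_CC3"),
                                   alpha = 0.05) {
  if (!is.null(phantoms$seq)) phantoms <- list(phantoms)
  run <- function(ph, off) {
    ctrs <- if (off == 0) ph$contours else bind_rows(
      filter(ph$contours, !.data$roi %in% c("PTS", "PBS")),
      displace_contour(filter(ph$contours, .data$roi %in% c("PTS", "PBS")), off))
    extract_features(ph$seq, ctrs, cfg = cfg, n_trim = n_trim)
  }
  original <- purrr::map(phantoms, run, off = 0) |> list_rbind()
  purrr::map(offsets, function(off) {
    displaced <- purrr::map(phantoms, run, off = off) |> list_rbind()
    purrr::map(features, function(f) {
      res <- suppressWarnings(wilcoxon_compare(original[[f]], displaced[[f]],
                                               alpha = alpha))
      mutate(res, offset = off, feature = f, .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
}
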