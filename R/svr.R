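#' Extract edge features from a cohort of connectivity matrices
#'
#' Vectorizes the strictly-below-diagonal part of each subject's
#' symmetric connectivity matrix in a fixed, documented order: rows of
#' the lower triangle, i.e. pairs `(i, j)` with `i > j`, ordered by `i`
#' then `j` (row-major). For an `m`-node network this yields
#' `m (m - 1) / 2` features per subject.
#'
#' @param matrices list of [connectivity_matrix()] objects sharing
#'   region labels (and band).
#' @param subject_ids optional subject labels (default `S001`, ...).
#' @return object of class `feature_table`: list with `subject_ids`,
#'   `edge_labels` (`"A--B"`), and `values` (subjects x edges matrix).
#' @export
extract_edge_features <- function(matrices, subject_ids = NULL) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "connectivity_matrix")))
  labs <- matrices[[1]]$region_labels
  for (m in matrices)
    if (!identical(m$region_labels, labs))
      stop("connectivity matrices do not share region labels")
  n <- length(labs)
  idx <- do.call(rbind, lapply(seq_len(n)[-1], function(i)
    cbind(i = i, j = seq_len(i - 1))))
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_along(matrices))
  values <- t(vapply(matrices, function(m) m$values[idx], numeric(nrow(idx))))
  edge_labels <- paste(labs[idx[, "i"]], labs[idx[, "j"]], sep = "--")
  colnames(values) <- edge_labels
  rownames(values) <- subject_ids
  structure(list(subject_ids = subject_ids, edge_labels = edge_labels,
                 values = values),
            class = "feature_table")
}

#' Configuration for leave-one-subject-out SVR
#'
#' Linear epsilon-insensitive support-vector regression on standardized
#' features and target. When `cost` or `epsilon` is `NULL` they default
#' to `iqr(y_train) / 1.349` and `iqr(y_train) / 13.49` respectively
#' (computed on the standardized training target), a robust-scale
#' convention for SVR defaults on z-scored data.
#'
#' @param cost box constraint, or `NULL` for the IQR default.
#' @param epsilon insensitivity-tube half-width, or `NULL` for the IQR
#'   default.
#' @param kappa prior width for the Bayesian-correlation accuracy.
#' @param side sidedness of the accuracy test; prediction accuracy is
#'   one-sided positive (a negative observed-predicted correlation is a
#'   failed fit, not anti-prediction).
#' @param leakage_compat if `TRUE`, standardize target and features on
#'   the full cohort before the cross-validation split (a literal
#'   reading of pipelines that z-score once); default `FALSE`
#'   standardizes inside each training fold, which avoids information
#'   leakage into the held-out subject.
#' @return list of class `svr_config`.
#' @export
svr_config <- function(cost = NULL, epsilon = NULL, kappa = 0.5,
                       side = "positive", leakage_compat = FALSE) {
  structure(list(cost = cost, epsilon = epsilon, kappa = kappa,
                 side = side, leakage_compat = leakage_compat),
            class = "svr_config")
}

#' Leave-one-subject-out SVR prediction of a scalar index
#'
#' For each held-out subject: the target and each feature column are
#' z-scored on the training fold; a linear epsilon-SVR is fitted on the
#' training subjects; the held-out subject is predicted from its
#' features scaled with the training-fold statistics, and the
#' prediction is mapped back to raw target units. Observed and
#' predicted values are concatenated across the folds and the accuracy
#' is the one-sided Bayesian correlation between them.
#'
#' @param features a `feature_table` from [extract_edge_features()].
#' @param target numeric vector of per-subject scalars, one per row of
#'   `features` (must have nonzero variance).
#' @param config an [svr_config()].
#' @param band,network,target_name labels carried into the result.
#' @return object of class `prediction_result`: `observed`, `predicted`
#'   (run order = subject order), `accuracy` (a `bayes_cor_result`),
#'   `rmse`, plus the labels.
#' @export
loso_predict <- function(features, target, config = svr_config(),
                         band = NA_character_, network = NA_character_,
                         target_name = NA_character_) {
  stopifnot(inherits(features, "feature_table"), is.numeric(target),
            length(target) == length(features$subject_ids),
            all(is.finite(target)))
  n <- length(target)
  if (n < 3) stop("need at least 3 subjects for leave-one-out")
  if (stats::sd(target) == 0) stop("zero-variance target")
  X <- features$values
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature column(s) dropped")
    X <- X[, keep, drop = FALSE]
  }
  if (isTRUE(config$leakage_compat)) {
    X <- scale(X)
    target_s <- as.numeric(scale(target))
  }
  predicted <- numeric(n)
  for (h in seq_len(n)) {
    tr <- setdiff(seq_len(n), h)
    if (isTRUE(config$leakage_compat)) {
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[h, , drop = FALSE]
      ytr <- target_s[tr]
      mu_y <- mean(target); sd_y <- stats::sd(target)
    } else {
      mu_x <- colMeans(X[tr, , drop = FALSE])
      sd_x <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_x[sd_x == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu_x), 2, sd_x, "/")
      Xte <- matrix((X[h, ] - mu_x) / sd_x, nrow = 1)
      mu_y <- mean(target[tr]); sd_y <- stats::sd(target[tr])
      ytr <- (target[tr] - mu_y) / sd_y
    }
    iqr_y <- stats::IQR(ytr)
    cost <- if (is.null(config$cost)) max(iqr_y / 1.349, 1e-3) else config$cost
    eps <- if (is.null(config$epsilon)) iqr_y / 13.49 else config$epsilon
    fit <- e1071::svm(x = Xtr, y = ytr, type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = eps,
                      scale = FALSE)
    predicted[h] <- as.numeric(stats::predict(fit, Xte)) * sd_y + mu_y
  }
  r <- stats::cor(target, predicted)
  acc <- bayes_cor_test(r, n, kappa = config$kappa, side = config$side)
  structure(list(observed = target, predicted = predicted,
                 subject_ids = features$subject_ids,
                 accuracy = acc,
                 rmse = sqrt(mean((target - predicted)^2)),
                 band = band, network = network, target_name = target_name),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s / %s -> %s: r = %.3f, BF10 = %.4g\n",
              x$band, x$network, x$target_name,
              x$accuracy$r, x$accuracy$bf10))
  invisible(x)
}

#' Run LOSO SVR over a band x network x target grid
#'
#' @param cohorts nested named list: `cohorts[[band]][[network]]` is a
#'   list of per-subject [connectivity_matrix()] objects restricted to
#'   that network.
#' @param targets data frame with a `subject` column plus one numeric
#'   column per target index.
#' @param config an [svr_config()].
#' @return list of `prediction_result`, one per band x network x target
#'   combination, each with a logical `reported` flag set by
#'   [significance_gate()] (BF10 > sqrt(10) and r > 0).
#' @export
prediction_grid <- function(cohorts, targets, config = svr_config()) {
  target_names <- setdiff(names(targets), "subject")
  results <- list()
  for (band in names(cohorts)) {
    for (net in names(cohorts[[band]])) {
      feats <- extract_edge_features(cohorts[[band]][[net]],
                                     subject_ids = targets$subject)
      for (tn in target_names) {
        res <- loso_predict(feats, targets[[tn]], config,
                            band = band, network = net, target_name = tn)
        results[[paste(band, net, tn, sep = ".")]] <- res
      }
    }
  }
  gated <- vapply(results, function(x)
    length(significance_gate(list(x$accuracy))) == 1L, logical(1))
  for (k in seq_along(results)) results[[k]]$reported <- gated[[k]]
  results
}
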