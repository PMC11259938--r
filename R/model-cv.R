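# Stratified fold assignment; errors when a class is too small to stratify.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("cannot build ", k, " stratified folds: smallest class has only ",
         min(table(y)), " observations")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Default lambda grid
#'
#' 100 log-spaced values descending from `lambda_max` over four orders of
#' magnitude. Because the ridge penalty never sends coefficients exactly to
#' zero, `lambda_max` follows the usual elastic-net convention for the
#' ridge end of the path: the smallest lambda that annihilates the
#' (standardized, class-weighted) score at beta = 0, divided by 0.001.
#'
#' @param X Variants x tissues score matrix.
#' @param y Binary labels.
#' @param n_lambda Grid length (default 100).
#' @param ratio Ratio of smallest to largest grid value (default 1e-4).
#' @param class_weights Optional weights; defaults to balanced.
#' @return Decreasing numeric vector of penalty values.
#' @export
default_lambda_grid <- function(X, y, n_lambda = 100, ratio = 1e-4,
                                class_weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(class_weights)) class_weights <- balanced_class_weights(y)
  std <- standardize_columns(X)
  ybar <- sum(class_weights * y) / sum(class_weights)
  score <- abs(drop(crossprod(std$Z, class_weights * (y - ybar)))) / nrow(X)
  lam_max <- max(score) / 1e-3
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max * ratio), length.out = n_lambda))
}

# Ridge path over the model design (tissue-mean column unpenalized, bounded
# at zero) fitted with glmnet on pre-standardized features, so that its
# lambda axis matches fit_penalized_logistic's parametrization (glmnet
# rescales penalty factors to sum to the number of variables, hence the
# d/(d+1) correction).
glmnet_ridge_path <- function(X_train, y_train, w_train, lambda_grid) {
  d <- ncol(X_train)
  std <- standardize_columns(cbind(xbar = rowMeans(X_train), X_train))
  fit <- glmnet::glmnet(
    std$Z, y_train, family = "binomial", weights = w_train,
    alpha = 0, lambda = lambda_grid * d / (d + 1),
    penalty.factor = c(0, rep(1, d)),
    lower.limits = c(0, rep(-Inf, d)), upper.limits = Inf,
    standardize = FALSE, thresh = 1e-9
  )
  list(fit = fit, std = std)
}

predict_ridge_path <- function(path, X_new) {
  Znew <- sweep(sweep(cbind(rowMeans(X_new), X_new), 2L, path$std$center),
                2L, path$std$scale, "/")
  predict(path$fit, Znew, type = "link")
}

#' Select the ridge penalty by cross-validated AUROC
#'
#' Stratified k-fold cross-validation over a lambda grid; the value with the
#' highest mean held-out AUROC is returned, with ties broken toward the
#' larger penalty (stronger regularization).
#'
#' @param X Variants x tissues score matrix (training data).
#' @param y Binary labels.
#' @param folds Number of folds (default 5).
#' @param lambda_grid Decreasing penalty grid; defaults to
#'   [default_lambda_grid()].
#' @param seed Integer seed for the fold assignment.
#' @param class_weights Optional weights; defaults to balanced.
#' @return Selected lambda, with the mean AUROC profile attached as
#'   attribute `"cv_auroc"`.
#' @export
select_lambda <- function(X, y, folds = 5, lambda_grid = NULL, seed = 1L,
                          class_weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(class_weights)) class_weights <- balanced_class_weights(y)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  if (length(lambda_grid) == 1L) return(lambda_grid)
  assignment <- stratified_folds(y, folds, seed)
  aucs <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
  for (k in seq_len(folds)) {
    tr <- assignment != k
    path <- glmnet_ridge_path(X[tr, , drop = FALSE], y[tr],
                              class_weights[tr], lambda_grid)
    eta <- predict_ridge_path(path, X[!tr, , drop = FALSE])
    aucs[k, ] <- apply(eta, 2L, auroc, labels = y[!tr])
  }
  profile <- colMeans(aucs)
  best <- which(profile == max(profile))[1L] # grid is decreasing: first = largest
  out <- lambda_grid[best]
  attr(out, "cv_auroc") <- stats::setNames(profile, format(lambda_grid))
  out
}

#' Nested cross-validation scores
#'
#' Outer stratified folds provide untouched held-out variants; within each
#' outer training set an inner cross-validation (via [select_lambda()])
#' picks the ridge penalty, a model is fitted at that penalty on the full
#' outer training set, and the outer held-out variants are scored. Every
#' variant receives exactly one held-out predicted probability.
#'
#' @param X Variants x tissues score matrix.
#' @param y Binary labels.
#' @param outer_folds,inner_folds Fold counts (default 5 each).
#' @param seed Integer seed.
#' @param lambda_grid Optional penalty grid shared across folds; defaults to
#'   a per-outer-training-set [default_lambda_grid()].
#' @return List of class `nested_cv` with `scores` (held-out probabilities in
#'   input order), `fold` (outer fold of each variant), `fits` (per-fold
#'   `model_fit`s) and `lambdas`.
#' @export
nested_cv_scores <- function(X, y, outer_folds = 5, inner_folds = 5,
                             seed = 1L, lambda_grid = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- balanced_class_weights(y)
  assignment <- stratified_folds(y, outer_folds, seed)
  inner_seeds <- derive_seeds(seed, outer_folds)
  scores <- rep(NA_real_, length(y))
  fits <- vector("list", outer_folds)
  lambdas <- numeric(outer_folds)
  for (k in seq_len(outer_folds)) {
    tr <- assignment != k
    lam <- select_lambda(X[tr, , drop = FALSE], y[tr], folds = inner_folds,
                         lambda_grid = lambda_grid, seed = inner_seeds[k])
    fit <- fit_penalized_logistic(X[tr, , drop = FALSE], y[tr], lam = lam)
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    fits[[k]] <- fit
    lambdas[k] <- lam
  }
  structure(list(scores = scores, fold = assignment, fits = fits,
                 lambdas = lambdas, seed = seed),
            class = "nested_cv")
}

#' Repeated nested cross-validation performance
#'
#' Runs [nested_cv_scores()] `repeats` times with distinct fold seeds and
#' records AUROC and average precision of the held-out scores for each
#' repeat. The mean over repeats summarizes a method's performance; the
#' spread reflects fold-assignment variability.
#'
#' @param X Variants x tissues score matrix.
#' @param y Binary labels.
#' @param repeats Number of repeats (default 30).
#' @param seed Master seed; per-repeat fold seeds are derived from it.
#' @param ... Passed to [nested_cv_scores()].
#' @return Data frame with one row per repeat (`repeat_idx`, `seed`,
#'   `auroc`, `avg_precision`) and the column means attached as attribute
#'   `"summary"`.
#' @export
repeated_cv_performance <- function(X, y, repeats = 30, seed = 1L, ...) {
  seeds <- derive_seeds(seed, repeats)
  records <- lapply(seq_len(repeats), function(r) {
    cv <- nested_cv_scores(X, y, seed = seeds[r], ...)
    perf <- compute_metrics(cv$scores, y, label = paste0("repeat_", r))
    data.frame(repeat_idx = r, seed = seeds[r], auroc = perf$auroc,
               avg_precision = perf$avg_precision)
  })
  out <- do.call(rbind, records)
  attr(out, "summary") <- c(auroc = mean(out$auroc),
                            avg_precision = mean(out$avg_precision))
  out
}

#' Coefficient estimates from repeated cross-validation
#'
#' Repeats stratified k-fold splitting `repeats` times; for each of the
#' `folds * repeats` training splits the penalty is selected by
#' [select_lambda()] on that split and a model is fitted, yielding one
#' coefficient vector per split (50 at the defaults of 5 folds x 10
#' repeats). Elementwise mean and standard deviation over the archived
#' vectors estimate each tissue coefficient and its variability.
#'
#' @param X Variants x tissues score matrix.
#' @param y Binary labels.
#' @param folds,repeats Split design (defaults 5 and 10).
#' @param seed Master seed.
#' @param inner_folds Folds used inside [select_lambda()] (default 5).
#' @param lambda_grid Optional fixed penalty grid.
#' @return Object of class `coefficient_estimate` with `beta_mean`,
#'   `beta_sd`, `n_fits`, `archive` (n_fits x d matrix), plus the
#'   corresponding baseline-coefficient and lambda archives.
#' @export
estimate_coefficients <- function(X, y, folds = 5, repeats = 10, seed = 1L,
                                  inner_folds = 5, lambda_grid = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n_fits <- as.integer(folds * repeats)
  archive <- matrix(NA_real_, nrow = n_fits, ncol = ncol(X),
                    dimnames = list(NULL, colnames(X)))
  baseline <- numeric(n_fits)
  lambdas <- numeric(n_fits)
  repeat_seeds <- derive_seeds(seed, repeats)
  # inner-selection seeds depend on the fold index only, so identical
  # training splits (e.g., the degenerate folds = 1 mode) give identical fits
  split_seeds <- derive_seeds(seed + 1L, folds)
  i <- 0L
  for (r in seq_len(repeats)) {
    assignment <- if (folds == 1L) rep(0L, length(y)) else
      stratified_folds(y, folds, repeat_seeds[r])
    for (k in seq_len(folds)) {
      tr <- assignment != k
      lam <- select_lambda(X[tr, , drop = FALSE], y[tr], folds = inner_folds,
                           lambda_grid = lambda_grid, seed = split_seeds[k])
      fit <- fit_penalized_logistic(X[tr, , drop = FALSE], y[tr], lam = lam)
      i <- i + 1L
      archive[i, ] <- fit$tissue_coefs
      baseline[i] <- fit$baseline_coef
      lambdas[i] <- lam
    }
  }
  structure(list(
    beta_mean = colMeans(archive),
    beta_sd = if (n_fits > 1L) apply(archive, 2L, sd) else
      stats::setNames(rep(0, ncol(archive)), colnames(archive)),
    n_fits = n_fits,
    archive = archive,
    baseline_coefs = baseline,
    lambdas = lambdas,
    folds = folds, repeats = repeats, seed = seed
  ), class = "coefficient_estimate")
}

#' @export
print.coefficient_estimate <- function(x, ...) {
  cat("Coefficient estimate over ", x$n_fits, " cross-validation fits (",
      x$folds, " folds x ", x$repeats, " repeats)\n", sep = "")
  top <- head(order(-abs(x$beta_mean)), 5L)
  cat("  top |beta_mean| tissues: ",
      paste0(names(x$beta_mean)[top], " (", signif(x$beta_mean[top], 3), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}
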