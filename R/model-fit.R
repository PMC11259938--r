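#' Validate a variants x tissues score matrix
#'
#' @param X Numeric matrix of non-negative tissue scores; rows are variants,
#'   columns are tissue/cell-type contexts. Row and column names are kept.
#' @return `X` with class `tissue_score_matrix` prepended.
#' @export
tissue_score_matrix <- function(X) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), ncol(X) >= 1L)
  if (anyNA(X)) stop("score matrix contains missing entries")
  if (any(X < 0)) stop("tissue scores must be non-negative")
  if (is.null(colnames(X))) colnames(X) <- paste0("tissue_", seq_len(ncol(X)))
  class(X) <- c("tissue_score_matrix", class(X))
  X
}

#' Disease-agnostic baseline: mean score across tissues
#'
#' @param X Variants x tissues score matrix.
#' @return Numeric vector of per-variant means over tissue contexts.
#' @export
tissue_mean_score <- function(X) {
  rowMeans(as.matrix(X))
}

#' Balanced class weights
#'
#' Per-observation weights `n / (2 * n_class)`, so the total weight of
#' positives equals the total weight of controls and weights average to one.
#'
#' @param y Binary label vector.
#' @return Numeric weight vector.
#' @export
balanced_class_weights <- function(y) {
  y <- as.integer(y)
  n <- length(y)
  tab <- c(`0` = sum(y == 0L), `1` = sum(y == 1L))
  if (any(tab == 0L)) stop("both classes must be present")
  n / (2 * tab[as.character(y)])
}

# population (1/n) column standardization, matching the glmnet convention
standardize_columns <- function(Z) {
  center <- colMeans(Z)
  scale <- sqrt(colMeans(sweep(Z, 2L, center)^2))
  scale[scale == 0] <- 1
  list(Z = sweep(sweep(Z, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# Newton solver with backtracking for the weighted penalized logistic
# objective  (1/n) sum_i w_i [log(1 + e^{eta_i}) - y_i eta_i]
#            + (lam/2) ||theta[pen]||^2
# columns of Z include the intercept; `pen` marks penalized columns.
newton_logistic <- function(Z, y, w, lam, pen, maxit = 200, grad_tol = 1e-6) {
  n <- nrow(Z)
  theta <- numeric(ncol(Z))
  pen_vec <- lam * pen
  obj <- function(theta) {
    eta <- drop(Z %*% theta)
    mean(w * (log1pexp(eta) - y * eta)) + sum(pen_vec * theta^2) / 2
  }
  f <- obj(theta)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% theta)
    p <- plogis(eta)
    grad <- drop(crossprod(Z, w * (p - y))) / n + pen_vec * theta
    if (max(abs(grad)) <= grad_tol) {
      return(list(theta = theta, converged = TRUE, n_iter = it - 1L,
                  objective = f, grad_norm = max(abs(grad))))
    }
    s <- w * p * (1 - p) / n
    H <- crossprod(Z * sqrt(s)) + diag(pen_vec, ncol(Z))
    step <- tryCatch(solve(H, grad), error = function(e) grad) # fall back to gradient
    t_ls <- 1
    repeat {
      theta_new <- theta - t_ls * step
      f_new <- obj(theta_new)
      if (is.finite(f_new) &&
          f_new <= f - 1e-4 * t_ls * sum(grad * step)) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-12) break
    }
    theta <- theta - t_ls * step
    f <- obj(theta)
  }
  eta <- drop(Z %*% theta)
  grad <- drop(crossprod(Z, w * (plogis(eta) - y))) / n + pen_vec * theta
  list(theta = theta, converged = max(abs(grad)) <= grad_tol,
       n_iter = maxit, objective = f, grad_norm = max(abs(grad)))
}

#' Fit the constrained, ridge-penalized logistic model
#'
#' Fits `logit(p_i) = a0 + a * xbar_i + beta' x_i` subject to `a >= 0`,
#' minimizing the class-weighted mean negative log-likelihood plus
#' `(lam / 2) * ||beta||^2`. The intercept `a0` and the baseline coefficient
#' `a` (on the tissue-mean column) are not penalized; the non-negativity
#' bound on `a` guarantees that, for large `lam`, the model degrades
#' gracefully to (a scaled version of) the tissue-mean baseline rather than
#' inverting it.
#'
#' Features (including the tissue-mean column) are internally centered and
#' scaled by their population standard deviation before penalization;
#' reported coefficients are back-transformed to the original scale. The
#' single bound constraint is handled by an exact active-set step: the
#' unconstrained optimum is accepted when its baseline coefficient is
#' non-negative, otherwise the model is refit with the baseline term pinned
#' at zero (the boundary optimum of this convex problem).
#'
#' @param X Variants x tissues score matrix.
#' @param y Binary labels (1 = disease-associated, 0 = control).
#' @param lam Ridge penalty `lambda >= 0` on the tissue coefficients.
#' @param class_weights Optional per-observation weights; defaults to
#'   [balanced_class_weights()].
#' @param standardize Standardize features internally (default `TRUE`).
#' @param maxit,grad_tol Newton iteration cap and gradient-norm convergence
#'   tolerance (on the standardized scale).
#' @return Object of class `model_fit` with elements `intercept`,
#'   `baseline_coef`, `tissue_coefs` (original scale), `lam`,
#'   `class_weights`, `feature_scaling`, `objective`, `converged`, `n_iter`.
#' @export
fit_penalized_logistic <- function(X, y, lam, class_weights = NULL,
                                   standardize = TRUE,
                                   maxit = 200, grad_tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(lam >= 0, nrow(X) == length(y), all(is.finite(X)))
  if (is.null(class_weights)) class_weights <- balanced_class_weights(y)
  d <- ncol(X)
  xbar <- rowMeans(X)
  Zraw <- cbind(xbar = xbar, X)
  if (standardize) {
    std <- standardize_columns(Zraw)
  } else {
    std <- list(Z = Zraw, center = rep(0, d + 1L), scale = rep(1, d + 1L))
  }
  Z <- cbind(1, std$Z)
  pen <- c(0, 0, rep(1, d)) # intercept and baseline term unpenalized

  fit <- newton_logistic(Z, y, class_weights, lam, pen,
                         maxit = maxit, grad_tol = grad_tol)
  alpha_at_zero <- FALSE
  if (fit$theta[2L] < 0) {
    # bound active: boundary optimum with the baseline column removed
    fit0 <- newton_logistic(Z[, -2L, drop = FALSE], y, class_weights, lam,
                            pen[-2L], maxit = maxit, grad_tol = grad_tol)
    fit0$theta <- append(fit0$theta, 0, after = 1L)
    fit <- fit0
    alpha_at_zero <- TRUE
  }
  if (!fit$converged) {
    stop("penalized logistic fit did not converge: gradient norm ",
         format(fit$grad_norm), " after ", fit$n_iter,
         " iterations (lam = ", format(lam), ", n = ", length(y), ")")
  }
  theta_std <- unname(fit$theta[-1L] / std$scale)
  intercept <- unname(fit$theta[1L] -
                        sum(fit$theta[-1L] * std$center / std$scale))
  tissue_coefs <- theta_std[-1L]
  names(tissue_coefs) <- colnames(X)
  structure(list(
    intercept = intercept,
    baseline_coef = theta_std[1L],
    tissue_coefs = tissue_coefs,
    lam = lam,
    class_weights = class_weights,
    feature_scaling = list(center = std$center, scale = std$scale),
    objective = fit$objective,
    converged = fit$converged,
    n_iter = fit$n_iter,
    baseline_at_bound = alpha_at_zero
  ), class = "model_fit")
}

#' Predicted disease-association probability
#'
#' @param object A `model_fit`.
#' @param newdata Variants x tissues score matrix on the original scale.
#' @param ... Unused.
#' @return Vector of predicted probabilities.
#' @export
predict.model_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  eta <- object$intercept + object$baseline_coef * rowMeans(X) +
    drop(X %*% object$tissue_coefs)
  plogis(eta)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Constrained ridge logistic fit (lambda = ", format(x$lam), ")\n",
      "  baseline coefficient: ", format(x$baseline_coef),
      if (x$baseline_at_bound) "  [at bound]" else "", "\n",
      "  tissue coefficients: ", length(x$tissue_coefs),
      " (||beta||_inf = ", format(max(abs(x$tissue_coefs))), ")\n", sep = "")
  invisible(x)
}

# full penalized objective for coefficients expressed on the same scale as
# X (pair with standardize = FALSE fits when verifying optimality)
penalized_objective <- function(X, y, intercept, baseline_coef, tissue_coefs,
                                lam, class_weights = NULL) {
  if (is.null(class_weights)) class_weights <- balanced_class_weights(y)
  eta <- intercept + baseline_coef * rowMeans(X) + drop(X %*% tissue_coefs)
  mean(class_weights * (log1pexp(eta) - y * eta)) + lam / 2 * sum(tissue_coefs^2)
}
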