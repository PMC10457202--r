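#' Cross-validation folds stratified by day value
#'
#' Samples are ordered by the response and dealt into folds cyclically after
#' a seeded shuffle within ties, so every fold spans the time gradient
#' (a fold containing only one day would make the CV fit degenerate).
#'
#' @param days numeric response values.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold assignment, same length as `days`.
#' @export
make_cv_folds <- function(days, n_folds, seed = 1L) {
  withr::with_seed(seed, {
    ord <- order(days, stats::runif(length(days)))
    fold <- integer(length(days))
    fold[ord] <- rep_len(sample(n_folds), length(days))
    fold
  })
}

#' Train a penalized epigenetic clock for days in culture
#'
#' Fits a penalized linear regression of days in culture on beta values at
#' candidate CpGs, minimising
#' `(1/2n) sum (y - b0 - x'b)^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`
#' along a log-spaced lambda path (glmnet; the response is standardized
#' internally, so on the original day scale the L1 weight is exactly
#' `lambda * alpha` while the ridge weight carries an extra factor
#' `1 / sd_n(y)` — the usual glmnet convention). `alpha = 0.5` gives the
#' elastic-net clock, `alpha = 0` the ridge predictor. When `lambda` is
#' `NULL` (default) it is chosen by n-fold cross-validation with folds
#' stratified by day; `lambda_choice = "min"` takes the CV-error minimiser,
#' `"1se"` the one-standard-error rule. Predictors are standardized
#' internally and coefficients reported on the original beta scale.
#'
#' @param beta_cand beta matrix restricted to candidate CpGs.
#' @param days numeric days in culture per sample (column order or named).
#' @param alpha elastic-net mixing parameter in \[0,1\] (default 0.5).
#' @param n_folds CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param lambda optional fixed penalty; skips CV.
#' @param lambda_choice "min" (default) or "1se".
#' @param standardize standardize predictors internally (default TRUE).
#' @return a `clock_model`: intercept (days), named non-zero coefficients
#'   (days per unit beta), hyperparameters, training r-squared.
#' @export
train_penalized_clock <- function(beta_cand, days, alpha = 0.5, n_folds = 10L,
                                  seed = 1L, lambda = NULL,
                                  lambda_choice = c("min", "1se"),
                                  standardize = TRUE) {
  beta_cand <- beta_matrix(beta_cand)
  lambda_choice <- match.arg(lambda_choice)
  if (!is.null(names(days))) days <- days[colnames(beta_cand)]
  days <- as.numeric(days)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]", call. = FALSE)
  if (length(unique(days)) < 2L) stop("need >= 2 distinct day values", call. = FALSE)
  x <- t(beta_cand)
  if (is.null(lambda)) {
    if (ncol(x) < 2L) stop("need >= 2 candidate CpGs for the penalized path", call. = FALSE)
    if (nrow(x) < n_folds) stop("fewer samples than CV folds", call. = FALSE)
    foldid <- make_cv_folds(days, n_folds, seed)
    cv <- glmnet::cv.glmnet(x, days, alpha = alpha, foldid = foldid,
                            standardize = standardize)
    lam <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
    cf <- stats::coef(fit, s = lam)
  } else {
    # fit a decreasing path ending at the requested lambda: glmnet's warm
    # starts make the terminal solution much more accurate than a cold
    # single-lambda fit (matters for the lambda = 0 OLS limit)
    yc <- days - mean(days)
    xs <- scale(x, center = TRUE, scale = standardize)
    lam_max <- max(abs(crossprod(xs, yc))) / nrow(x) / max(alpha, 1e-3)
    lam_max <- max(lam_max, lambda * 1.01, 1e-3)
    path <- sort(unique(c(exp(seq(log(lam_max), log(max(lambda, lam_max * 1e-7)),
                                  length.out = 100L)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, days, alpha = alpha, standardize = standardize,
                          lambda = path, thresh = 1e-16, maxit = 1e7)
    lam <- lambda
    k <- which.min(abs(fit$lambda - lambda))   # exact path point, no interpolation
    cf <- rbind(fit$a0[k], fit$beta[, k, drop = FALSE])
  }
  cf <- drop(as.matrix(cf))
  intercept <- cf[1L]
  coefs <- cf[-1L]
  coefs <- coefs[coefs != 0]
  model <- structure(list(
    intercept = unname(intercept),
    coefficients = coefs,
    hyperparameters = list(alpha = alpha, lambda = unname(lam),
                           n_folds = if (is.null(lambda)) n_folds else NA_integer_,
                           seed = seed, lambda_choice = lambda_choice),
    n_training = nrow(x)
  ), class = "clock_model")
  pred <- predict_days(model, beta_cand)
  model$training_r2 <- evaluate_clock(pred$predicted_days, days)$r_squared
  model
}

#' Construct a clock model by hand
#'
#' Builds a `clock_model` from an intercept and a named coefficient vector,
#' e.g. to apply a published signature whose coefficients are known.
#'
#' @param intercept intercept in days.
#' @param coefficients named numeric vector, days per unit beta per CpG.
#' @param alpha,lambda hyperparameters to record (informational).
#' @return a `clock_model`.
#' @export
clock_model <- function(intercept, coefficients = stats::setNames(numeric(), character()),
                        alpha = NA_real_, lambda = NA_real_) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("coefficients must be named by CpG id", call. = FALSE)
  }
  structure(list(
    intercept = unname(intercept),
    coefficients = coefficients[coefficients != 0],
    hyperparameters = list(alpha = alpha, lambda = lambda,
                           n_folds = NA_integer_, seed = NA_integer_,
                           lambda_choice = NA_character_),
    n_training = NA_integer_, training_r2 = NA_real_
  ), class = "clock_model")
}

#' Predict days in culture from beta values
#'
#' Applies a trained clock: `yhat = b0 + x'b` over the model CpGs. No
#' clipping: negative predictions are reported as-is.
#'
#' @param model a `clock_model`.
#' @param beta beta matrix containing all model CpGs (any row order).
#' @param impute_missing if `TRUE`, a CpG absent from `beta` contributes its
#'   grand-mean beta of 0.5; default `FALSE` (missing CpG is an error).
#' @return tibble with `sample_id`, `predicted_days`.
#' @export
predict_days <- function(model, beta, impute_missing = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  beta <- beta_matrix(beta)
  need <- names(model$coefficients)
  missing_cpg <- setdiff(need, rownames(beta))
  if (length(missing_cpg) && !impute_missing) {
    stop("beta matrix lacks model CpG(s): ",
         paste(utils::head(missing_cpg, 10L), collapse = ", "), call. = FALSE)
  }
  x <- matrix(0.5, nrow = length(need), ncol = ncol(beta),
              dimnames = list(need, colnames(beta)))
  have <- intersect(need, rownames(beta))
  x[have, ] <- beta[have, , drop = FALSE]
  yhat <- model$intercept + drop(crossprod(x, model$coefficients))
  if (length(need) == 0L) yhat <- rep(model$intercept, ncol(beta))
  tibble::tibble(sample_id = colnames(beta), predicted_days = unname(yhat))
}

#' Evaluate clock predictions against true days
#'
#' `r_squared` is the squared Pearson correlation between predicted and true
#' days (the scatter-plot convention); `r2_cod` is the coefficient of
#' determination `1 - SS_res/SS_tot`, which unlike squared Pearson penalises
#' bias. Constant predictions get `r_squared = 0` by convention and are
#' flagged; an anti-correlated fit is flagged `negative_slope`.
#'
#' @param predicted,truth numeric vectors of equal length (>= 2).
#' @return one-row tibble: `r_squared`, `r2_cod`, `rmse`, `n`, `flag`.
#' @export
evaluate_clock <- function(predicted, truth) {
  predicted <- as.numeric(predicted)
  truth <- as.numeric(truth)
  if (length(predicted) != length(truth) || length(truth) < 2L) {
    stop("predicted and truth must be equal length >= 2", call. = FALSE)
  }
  rmse <- sqrt(mean((predicted - truth)^2))
  flag <- "ok"
  if (stats::sd(predicted) == 0 || stats::sd(truth) == 0) {
    r2 <- 0
    flag <- "constant_predictions"
  } else {
    rr <- stats::cor(predicted, truth)
    r2 <- rr^2
    if (rr < 0) flag <- "negative_slope"
  }
  r2_cod <- 1 - sum((truth - predicted)^2) / sum((truth - mean(truth))^2)
  tibble::tibble(r_squared = r2, r2_cod = r2_cod, rmse = rmse,
                 n = length(truth), flag = flag)
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock: %d CpG(s), alpha = %g, lambda = %.4g\n",
              length(x$coefficients), x$hyperparameters$alpha,
              x$hyperparameters$lambda))
  cat(sprintf("  intercept %.3f days; training r2 %.3f (n = %d)\n",
              x$intercept, x$training_r2 %||% NA_real_, x$n_training))
  invisible(x)
}

#' Tidy a clock model into a coefficient table
#' @param x a `clock_model`.
#' @param ... unused.
#' @return tibble with `term` (CpG id or "(Intercept)") and `estimate`.
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a clock model
#' @param x a `clock_model`.
#' @param ... unused.
#' @return tibble with alpha, lambda, number of CpGs, training r2, n.
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$hyperparameters$alpha,
    lambda = x$hyperparameters$lambda,
    n_cpgs = length(x$coefficients),
    training_r2 = x$training_r2 %||% NA_real_,
    n = x$n_training
  )
}

#' Serialize a clock model to JSON
#' @param model a `clock_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  jsonlite::write_json(list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    hyperparameters = model$hyperparameters,
    n_training = model$n_training,
    training_r2 = model$training_r2
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a clock model from JSON
#' @param path path written by [write_clock_model()].
#' @return a `clock_model`.
#' @export
read_clock_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = x$intercept,
    coefficients = unlist(x$coefficients) %||% stats::setNames(numeric(), character()),
    hyperparameters = x$hyperparameters,
    n_training = x$n_training,
    training_r2 = x$training_r2
  ), class = "clock_model")
}
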