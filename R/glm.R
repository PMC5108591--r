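# In-repo GLM machinery: iteratively reweighted least squares for the
# logistic and log-link models the assay statistics rely on, with the
# covariance and dispersion conventions documented in the vignette.

.irls_solve <- function(X, W, z) {
  xw <- X * W
  chol2inv_safe <- function(A) {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) abort("weighted cross-product is singular during IRLS")
    chol2inv(ch)
  }
  V <- chol2inv_safe(crossprod(xw, X))
  list(beta = drop(V %*% crossprod(xw, z)), V = V)
}

new_glm_fit <- function(class, coefficients, vcov, dispersion, loglik,
                        link, n_obs, df_residual, iter, converged,
                        spec = NULL, extra = list()) {
  structure(c(list(coefficients = coefficients, vcov = vcov,
                   dispersion = dispersion, loglik = loglik, link = link,
                   n_obs = n_obs, df_residual = df_residual, iter = iter,
                   converged = converged, spec = spec), extra),
            class = c(class, "myo_fit"))
}

#' Fit a binomial logistic model by maximum likelihood
#'
#' Iteratively reweighted least squares on the logit link, run to
#' `max |delta beta| < 1e-10` (at most 100 iterations). The response may be
#' grouped (successes/trials matrix) or fully expanded Bernoulli 0/1 rows;
#' both parameterise the same likelihood and return identical
#' coefficients. The coefficient covariance is the inverse Fisher
#' information; dispersion is fixed at 1.
#'
#' @param X design matrix with named columns (see [build_design()]).
#' @param y two-column matrix `(successes, trials)` or a 0/1 vector.
#' @param spec optional [model_spec()] carried along for reporting.
#' @return A `myo_glm` fit object (see also [tidy.myo_glm()]).
#' @export
fit_binomial_glm <- function(X, y, spec = NULL) {
  if (is.matrix(y) && ncol(y) == 2) {
    s <- y[, 1]; trials <- y[, 2]
  } else {
    if (any(!y %in% c(0, 1))) abort("Bernoulli response must be 0/1")
    s <- as.numeric(y); trials <- rep(1, length(y))
  }
  if (any(trials <= 0)) abort("every cell needs trials >= 1")
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- trials * mu * (1 - mu)
    if (any(W < 1e-12)) W <- pmax(W, 1e-12)
    z <- eta + (s - trials * mu) / W
    sol <- .irls_solve(X, W, z)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    trace <- c(trace, delta)
    if (max(abs(beta)) > 30) {
      abort("complete separation detected: coefficients diverging beyond |30| on the logit scale")
    }
    if (delta < 1e-10) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("IRLS did not converge in 100 iterations; last steps: %s",
                  paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(dbinom(s, trials, mu, log = TRUE))
  names(beta) <- colnames(X)
  V <- .irls_solve(X, trials * mu * (1 - mu), eta)$V
  dimnames(V) <- list(colnames(X), colnames(X))
  new_glm_fit("myo_glm", beta, V, dispersion = 1, loglik = ll,
              link = "logit", n_obs = length(s),
              df_residual = length(s) - p, iter = it, converged = TRUE,
              spec = spec, extra = list(family = "binomial"))
}

#' Fit a quasi-Poisson count model
#'
#' Log-link IRLS with Poisson working weights; after convergence the
#' dispersion is estimated by the Pearson statistic
#' `phi = sum((y - mu)^2 / mu) / (n - p)` and standard errors are scaled
#' by `sqrt(phi)`. Coefficient tests downstream use the t distribution on
#' `n - p` degrees of freedom.
#'
#' @param X design matrix with named columns.
#' @param y non-negative counts.
#' @param spec optional [model_spec()].
#' @return A `myo_quasipoisson` fit object.
#' @export
fit_quasipoisson_glm <- function(X, y, spec = NULL) {
  if (any(y < 0)) abort("counts must be non-negative")
  if (all(y == 0)) abort("all-zero response: no count model to fit")
  p <- ncol(X)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(100)) {
    W <- mu
    z <- eta + (y - mu) / mu
    sol <- .irls_solve(X, W, z)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (delta < 1e-10) { converged <- TRUE; break }
  }
  if (!converged) abort("IRLS did not converge in 100 iterations")
  phi <- sum((y - mu)^2 / mu) / (length(y) - p)
  V <- .irls_solve(X, mu, eta)$V * phi
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  qdev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  new_glm_fit("myo_quasipoisson", beta, V, dispersion = phi,
              loglik = -qdev / 2, link = "log", n_obs = length(y),
              df_residual = length(y) - p, iter = it, converged = TRUE,
              spec = spec, extra = list(family = "quasipoisson",
                                        quasi_deviance = qdev))
}

#' Fit an ordinary linear model
#'
#' Least squares with per-coefficient t statistics and two-sided p-values
#' on `n - p` residual degrees of freedom (the approximate-t convention
#' used for the eccentricity dose models).
#'
#' @param X design matrix with named columns.
#' @param y continuous response.
#' @param spec optional [model_spec()].
#' @return A `myo_lm` fit object.
#' @export
fit_linear_model <- function(X, y, spec = NULL) {
  n <- length(y); p <- ncol(X)
  if (n <= p) abort("need more observations than coefficients")
  qx <- qr(X)
  if (qx$rank < p) abort("design is rank deficient")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - p)
  V <- chol2inv(qr.R(qx)) * sigma2
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- -n / 2 * (log(2 * pi * max(sigma2, .Machine$double.eps)) + 1)
  new_glm_fit("myo_lm", beta, V, dispersion = sigma2, loglik = ll,
              link = "identity", n_obs = n, df_residual = n - p,
              iter = 1L, converged = TRUE, spec = spec,
              extra = list(family = "gaussian", sigma = sqrt(sigma2)))
}

#' Fit the model described by a spec to a data table
#'
#' Tidy entry point: builds the design with [build_design()] and
#' dispatches to the matching fitter, including the random-intercept
#' logistic model when `random_intercept` is set.
#'
#' @param data tibble with the model columns.
#' @param spec a [model_spec()].
#' @param ... passed to the underlying fitter (e.g. `n_quad` for the
#'   mixed model).
#' @return A fitted `myo_fit` object.
#' @export
#' @examples
#' d <- generate_outcomes(outcome_spec(factors = "treated", mu = -0.5,
#'                                     beta = c(treated = 1), seed = 2))
#' fit <- fit_model(d, model_spec("binomial_bernoulli", "outcome",
#'                                factors = "treated"))
#' tidy(fit)
fit_model <- function(data, spec, ...) {
  d <- build_design(data, spec)
  if (!is.null(spec$random_intercept)) {
    if (spec$response_kind != "binomial_bernoulli" &&
        spec$response_kind != "binomial_grouped") {
      abort("random intercepts are supported for binomial responses only")
    }
    return(fit_binomial_glmm(d$X, d$y, d$groups, spec = spec, ...))
  }
  switch(spec$response_kind,
         binomial_grouped = ,
         binomial_bernoulli = fit_binomial_glm(d$X, d$y, spec = spec),
         count = fit_quasipoisson_glm(d$X, d$y, spec = spec),
         continuous = fit_linear_model(d$X, d$y, spec = spec))
}

#' @export
print.myo_fit <- function(x, ...) {
  cat(sprintf("<%s> %d obs, %d coefficients%s\n", class(x)[1], x$n_obs,
              length(x$coefficients),
              if (!is.null(x$sigma_g)) sprintf(", sigma_g = %.3f", x$sigma_g)
              else ""))
  print(tidy(x))
  invisible(x)
}
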