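#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Wald tests: z for ML binomial fits, t on the residual df for
# dispersion-estimated fits (quasi-Poisson, linear).
.term_table <- function(x, use_t = FALSE) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  p <- if (use_t) 2 * pt(-abs(stat), df = x$df_residual) else
    2 * pnorm(-abs(stat))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(stat),
                 p.value = unname(p))
}

#' Tidy a fitted model
#'
#' One row per coefficient with estimate, standard error, Wald statistic
#' and two-sided p-value: a z test for maximum-likelihood logistic fits
#' (plain and mixed), a t test on the residual degrees of freedom for
#' quasi-Poisson and linear fits.
#'
#' @param x a fitted `myo_*` model.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.myo_glm <- function(x, ...) .term_table(x, use_t = FALSE)

#' @rdname tidy.myo_glm
#' @export
tidy.myo_glmm <- function(x, ...) .term_table(x, use_t = FALSE)

#' @rdname tidy.myo_glm
#' @export
tidy.myo_quasipoisson <- function(x, ...) .term_table(x, use_t = TRUE)

#' @rdname tidy.myo_glm
#' @export
tidy.myo_lm <- function(x, ...) .term_table(x, use_t = TRUE)

#' One-row model summary
#'
#' @param x a fitted `myo_*` model.
#' @param ... unused.
#' @return A tibble with fit-level quantities (observations, residual df,
#'   dispersion, log-likelihood, convergence; random-effect SD for mixed
#'   fits).
#' @export
glance.myo_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, df_residual = x$df_residual,
                 dispersion = x$dispersion, loglik = x$loglik,
                 sigma_g = x$sigma_g %||% NA_real_,
                 iter = x$iter, converged = x$converged)
}

#' Effect report with odds/rate ratios and per-condition fitted values
#'
#' Reproduces the reporting convention of the model tables this package is
#' built around. Per term: the exponentiated estimate (odds ratio under the
#' logit link, rate ratio under the log link) with a 95% Wald interval
#' `exp(estimate +/- 1.96 SE)`. Per condition (every combination of the
#' model's binary factors, at dose 0 and reference batch): the fitted
#' response-scale value from the summed coefficients with a Wald interval
#' on the linear predictor. When `omit_intercept_error` is set, the
#' variance contribution of the intercept (its variance and covariances)
#' is excluded from non-baseline condition intervals, matching the
#' source-table convention that baseline error is not propagated into
#' treatment intervals.
#'
#' @param fit a fitted logit- or log-link `myo_*` model.
#' @param omit_intercept_error logical flag (default TRUE, the reported
#'   convention; set FALSE for full delta-method intervals).
#' @param conf_level confidence level for the Wald intervals.
#' @return Object of class `myo_effect_report`: list of tibbles `terms`
#'   and `conditions` plus the flag.
#' @export
effect_report <- function(fit, omit_intercept_error = TRUE,
                          conf_level = 0.95) {
  if (fit$link == "identity") {
    abort("odds/rate ratios are undefined for an identity-link fit")
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  use_t <- inherits(fit, "myo_quasipoisson")
  terms <- .term_table(fit, use_t = use_t)
  ratio_name <- if (fit$link == "logit") "odds_ratio" else "rate_ratio"
  terms[[ratio_name]] <- exp(terms$estimate)
  terms$ratio_low <- exp(terms$estimate - zq * terms$std.error)
  terms$ratio_high <- exp(terms$estimate + zq * terms$std.error)

  conditions <- .condition_table(fit, zq, omit_intercept_error)
  structure(list(terms = terms, conditions = conditions,
                 omit_intercept_error = omit_intercept_error,
                 link = fit$link, conf_level = conf_level),
            class = "myo_effect_report")
}

# Fitted response-scale values over the factorial conditions implied by
# the coefficient names: for each subset S of binary main effects, the
# condition uses the intercept, the members of S and every interaction
# whose members all lie in S. Dose and batch columns are held at zero /
# reference.
.condition_table <- function(fit, zq, omit_intercept_error) {
  cn <- names(fit$coefficients)
  spec <- fit$spec
  mains <- if (!is.null(spec)) intersect(cn, spec$factors) else
    cn[!grepl(":", cn) & cn != "(Intercept)"]
  extra <- if (!is.null(spec)) c(spec$dose, spec$batch) else character()
  mains <- setdiff(mains, extra)
  if (!length(mains)) {
    combos <- list(character(0))
  } else {
    combos <- unlist(lapply(0:length(mains), function(k)
      utils::combn(mains, k, simplify = FALSE)), recursive = FALSE)
  }
  linkinv <- if (fit$link == "logit") plogis else exp
  V <- fit$vcov
  rows <- lapply(combos, function(set) {
    l <- setNames(numeric(length(cn)), cn)
    l["(Intercept)"] <- 1
    l[set] <- 1
    for (term in cn[grepl(":", cn)]) {
      members <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (all(members %in% set)) l[term] <- 1
    }
    eta <- sum(l * fit$coefficients)
    lv <- l
    if (omit_intercept_error && length(set) > 0) lv["(Intercept)"] <- 0
    se <- sqrt(drop(t(lv) %*% V %*% lv))
    tibble::tibble(
      condition = if (length(set)) paste(set, collapse = " + ") else
        "baseline",
      linear_predictor = eta, se = se,
      fitted = linkinv(eta),
      conf_low = linkinv(eta - zq * se),
      conf_high = linkinv(eta + zq * se))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.myo_effect_report <- function(x, ...) {
  cat(sprintf("<myo_effect_report> link = %s, intercept error %s in condition CIs\n",
              x$link,
              if (x$omit_intercept_error) "omitted" else "included"))
  cat("Terms:\n"); print(x$terms)
  cat("Conditions:\n"); print(x$conditions)
  invisible(x)
}

#' @export
tidy.myo_effect_report <- function(x, ...) x$terms
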