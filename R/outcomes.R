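#' Specification of a simulated per-cell binary-outcome experiment
#'
#' Describes the data-generating process assumed by the logistic models in
#' this package: each cell's binary outcome (e.g. "this nucleus sits in a
#' MyHC-positive myotube") is Bernoulli with success probability
#' `plogis(mu + sum(beta * delta) + c * dose + u_g)`, where `delta` are 0/1
#' factor indicators (including products for interactions), `c` an optional
#' log-odds-per-unit-dose slope, and `u_g ~ N(0, random_sd^2)` a random
#' intercept drawn once per group (mouse or experiment).
#'
#' @param factors character vector of binary factor names.
#' @param mu intercept, log-odds at the reference condition.
#' @param beta named numeric vector of log-odds effects; names are factor
#'   names or interactions written `"A:B"`.
#' @param dose_coefficient optional log-odds change per unit dose.
#' @param doses numeric vector of dose levels crossed with the factorial
#'   design (default a single level, 0).
#' @param group_label name of the random-effect grouping, e.g. `"mouse"`.
#' @param n_groups number of groups (>= 1).
#' @param random_sd standard deviation of the group intercepts, log-odds.
#' @param cells_per_group_per_condition cells drawn per group in each
#'   factor-by-dose condition.
#' @param seed integer seed.
#' @return A validated `outcome_spec` list.
#' @export
outcome_spec <- function(factors = character(),
                         mu = 0,
                         beta = NULL,
                         dose_coefficient = NULL,
                         doses = 0,
                         group_label = "mouse",
                         n_groups = 1L,
                         random_sd = 0,
                         cells_per_group_per_condition = 100L,
                         seed = 1L) {
  if (n_groups < 1) abort("`n_groups` must be >= 1")
  if (cells_per_group_per_condition < 1) {
    abort("`cells_per_group_per_condition` must be >= 1")
  }
  if (random_sd < 0) abort("`random_sd` must be >= 0")
  beta <- beta %||% setNames(numeric(0), character(0))
  bad <- setdiff(unlist(strsplit(names(beta), ":", fixed = TRUE)), factors)
  if (length(bad)) {
    abort(sprintf("`beta` names refer to unknown factors: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(factors = factors, mu = mu, beta = beta,
                 dose_coefficient = dose_coefficient, doses = doses,
                 group_label = group_label, n_groups = as.integer(n_groups),
                 random_sd = random_sd,
                 cells_per_group_per_condition =
                   as.integer(cells_per_group_per_condition),
                 seed = as.integer(seed)),
            class = "outcome_spec")
}

#' Simulate a per-cell binary outcome table
#'
#' Draws one Bernoulli outcome per cell under the logistic model described
#' by an [outcome_spec()]: full factorial over the binary factors, crossed
#' with the dose levels, replicated in every group with a group-level
#' random intercept drawn once per group.
#'
#' @param spec an [outcome_spec()].
#' @return Tibble with one row per cell: the 0/1 factor columns, `dose`,
#'   the grouping column (named after `spec$group_label`), the latent
#'   success probability `prob`, and the binary `outcome`.
#' @export
#' @examples
#' spec <- outcome_spec(factors = "treated", mu = -1,
#'                      beta = c(treated = 1.5), n_groups = 3,
#'                      random_sd = 0.5, seed = 42)
#' generate_outcomes(spec)
generate_outcomes <- function(spec) {
  stopifnot(inherits(spec, "outcome_spec"))
  with_seed(spec$seed, {
    grid <- expand.grid(
      c(setNames(rep(list(0:1), length(spec$factors)), spec$factors),
        list(dose = spec$doses)),
      KEEP.OUT.ATTRS = FALSE)
    u <- rnorm(spec$n_groups, 0, spec$random_sd)
    rows <- tidyr::expand_grid(
      grid,
      .group = seq_len(spec$n_groups),
      .cell = seq_len(spec$cells_per_group_per_condition))
    eta <- rep(spec$mu, nrow(rows)) + u[rows$.group]
    for (term in names(spec$beta)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      delta <- Reduce(`*`, lapply(parts, function(f) rows[[f]]))
      eta <- eta + spec$beta[[term]] * delta
    }
    if (!is.null(spec$dose_coefficient)) {
      eta <- eta + spec$dose_coefficient * rows$dose
    }
    if (any(!is.finite(eta))) abort("non-finite linear predictor")
    p <- plogis(eta)
    out <- tibble::as_tibble(rows[spec$factors])
    out$dose <- rows$dose
    out[[spec$group_label]] <- paste0(spec$group_label, rows$.group)
    out$prob <- p
    out$outcome <- as.integer(runif(nrow(rows)) < p)
    out
  })
}

#' Simulate replicate count data with controlled overdispersion
#'
#' Counts with mean `m` and variance `dispersion * m`: Poisson when
#' `dispersion = 1`, otherwise a gamma-Poisson mixture (negative binomial
#' with size `m / (dispersion - 1)`), the variance structure the
#' quasi-Poisson model assumes.
#'
#' @param condition_means positive numeric vector, one mean per condition.
#' @param dispersion variance-to-mean ratio, >= 1.
#' @param n_replicates replicate draws (batches) per condition.
#' @param seed integer seed.
#' @return Tibble with `condition`, `replicate` and `count`.
#' @export
generate_counts <- function(condition_means, dispersion = 1,
                            n_replicates = 1L, seed = 1L) {
  if (any(condition_means <= 0)) abort("`condition_means` must be > 0")
  if (dispersion < 1) abort("`dispersion` must be >= 1")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  conds <- names(condition_means) %||%
    paste0("cond", seq_along(condition_means))
  with_seed(seed, {
    out <- tidyr::expand_grid(condition = factor(conds, levels = conds),
                              replicate = seq_len(n_replicates))
    m <- condition_means[as.integer(out$condition)]
    out$count <- if (dispersion == 1) {
      rpois(nrow(out), m)
    } else {
      rnbinom(nrow(out), size = m / (dispersion - 1), mu = m)
    }
    out
  })
}
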