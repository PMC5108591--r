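#' Specify a factorial / dose-gradient model
#'
#' Describes one member of the model family used for assay data: a
#' treatment-coded design with an intercept (the reference condition),
#' binary or multi-level factors, optional factor interactions, an
#' optional linear-in-concentration dose term, an optional batch
#' (replicate) factor and an optional random intercept grouping. The link
#' is tied to the response kind: logit for binomial, log for counts,
#' identity for continuous.
#'
#' @param response_kind one of `"binomial_grouped"` (successes/trials
#'   columns), `"binomial_bernoulli"` (0/1 column), `"count"`,
#'   `"continuous"`.
#' @param response for `binomial_grouped`, `c(successes = , trials = )`
#'   column names; otherwise a single column name.
#' @param factors character vector of factor column names. Numeric 0/1
#'   columns are used as-is; character/factor/logical columns are
#'   treatment-coded against their first level.
#' @param interactions list of character vectors, each naming >= 2 factors.
#' @param dose optional name of a numeric concentration column.
#' @param batch optional name of a replicate factor column.
#' @param random_intercept optional name of a grouping column (e.g.
#'   `"mouse"`); only meaningful for Bernoulli responses.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response_kind = c("binomial_grouped",
                                         "binomial_bernoulli",
                                         "count", "continuous"),
                       response,
                       factors = character(),
                       interactions = list(),
                       dose = NULL,
                       batch = NULL,
                       random_intercept = NULL) {
  response_kind <- match.arg(response_kind)
  if (response_kind == "binomial_grouped") {
    if (length(response) != 2 ||
        !all(c("successes", "trials") %in% names(response))) {
      abort("grouped binomial response must be c(successes = , trials = )")
    }
  } else if (length(response) != 1) {
    abort("response must name a single column")
  }
  for (ia in interactions) {
    bad <- setdiff(ia, c(factors, dose))
    if (length(bad)) {
      abort(sprintf("interaction members not among factors or dose: %s",
                    paste(bad, collapse = ", ")))
    }
    if (length(ia) < 2) abort("an interaction needs >= 2 factors")
  }
  link <- switch(response_kind, binomial_grouped = , binomial_bernoulli =
                   "logit", count = "log", continuous = "identity")
  structure(list(response_kind = response_kind, response = response,
                 factors = factors, interactions = interactions,
                 dose = dose, batch = batch,
                 random_intercept = random_intercept, link = link),
            class = "model_spec")
}

# Treatment-coded dummy columns for one factor column. Numeric columns are
# used as a single column under their own name.
.factor_columns <- function(data, name) {
  x <- data[[name]]
  if (is.null(x)) abort(sprintf("column '%s' not found", name))
  if (is.numeric(x)) {
    m <- matrix(x, ncol = 1, dimnames = list(NULL, name))
    return(m)
  }
  f <- if (is.factor(x)) x else factor(x)
  levs <- levels(f)
  if (length(levs) < 2) {
    abort(sprintf("factor '%s' has a single level", name))
  }
  m <- vapply(levs[-1], function(l) as.numeric(f == l),
              numeric(length(f)))
  colnames(m) <- paste0(name, levs[-1])
  m
}

#' Build a design matrix and response from a model spec
#'
#' Columns are ordered deterministically: intercept first, then main
#' effects in the order of `spec$factors`, then interactions in the order
#' given (each as the element-wise product of its members' columns), then
#' the dose column, then batch dummies. The design is checked for full
#' rank; aliased columns are named in the error.
#'
#' @param data tibble/data frame with the model columns.
#' @param spec a [model_spec()].
#' @return List with `X` (design matrix), `y` (numeric vector, or 2-column
#'   successes/trials matrix for grouped binomial responses) and `groups`
#'   (random-intercept labels or NULL).
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(data)
  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  main <- lapply(spec$factors, .factor_columns, data = data)
  names(main) <- spec$factors
  blocks <- c(blocks, main)
  # interaction members may also reference the dose column
  members <- main
  if (!is.null(spec$dose)) {
    members[[spec$dose]] <- .factor_columns(data, spec$dose)
  }
  for (ia in spec$interactions) {
    combos <- expand.grid(lapply(ia, function(f) colnames(members[[f]])),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cols <- apply(combos, 1, function(nm) {
      Reduce(`*`, lapply(seq_along(ia),
                         function(i) members[[ia[i]]][, nm[i]]))
    })
    cols <- matrix(cols, nrow = n)
    colnames(cols) <- apply(combos, 1, paste, collapse = ":")
    blocks[[paste(ia, collapse = ":")]] <- cols
  }
  if (!is.null(spec$dose)) {
    if (!spec$dose %in% names(data)) {
      abort(sprintf("dose column '%s' not found", spec$dose))
    }
    blocks[[spec$dose]] <- matrix(data[[spec$dose]], ncol = 1,
                                  dimnames = list(NULL, spec$dose))
  }
  if (!is.null(spec$batch)) {
    blocks[[spec$batch]] <- .factor_columns(data, spec$batch)
  }
  X <- do.call(cbind, unname(blocks))

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("design is rank deficient; aliased columns: %s",
                  paste(aliased, collapse = ", ")))
  }

  y <- if (spec$response_kind == "binomial_grouped") {
    s <- data[[spec$response[["successes"]]]]
    t <- data[[spec$response[["trials"]]]]
    if (any(t <= 0)) abort("grouped binomial data has a cell with trials = 0")
    if (any(s < 0) || any(s > t)) {
      abort("binomial data must satisfy 0 <= successes <= trials")
    }
    cbind(successes = s, trials = t)
  } else {
    data[[spec$response]]
  }
  groups <- if (!is.null(spec$random_intercept)) {
    as.character(data[[spec$random_intercept]])
  }
  list(X = X, y = y, groups = groups, spec = spec)
}
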