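saturated_2x2 <- function(s, n = rep(100, 4)) {
  tibble::tibble(A = c(0, 1, 0, 1), B = c(0, 0, 1, 1), s = s, n = n)
}

fit_2x2 <- function(d) {
  de <- build_design(d, model_spec("binomial_grouped",
                                   c(successes = "s", trials = "n"),
                                   factors = c("A", "B"),
                                   interactions = list(c("A", "B"))))
  fit_binomial_glm(de$X, de$y)
}

test_that("saturated binomial fits equal closed-form log-odds contrasts", {
  f <- fit_2x2(saturated_2x2(c(50, 25, 50, 75)))
  lo <- qlogis(c(0.5, 0.25, 0.5, 0.75))
  expected <- c(lo[1], lo[2] - lo[1], lo[3] - lo[1],
                lo[4] - lo[3] - lo[2] + lo[1])
  expect_lt(max(abs(unname(f$coefficients) - expected)), 1e-8)
})

test_that("a flat table fits to the null model", {
  f <- fit_2x2(saturated_2x2(rep(50, 4)))
  expect_lt(max(abs(f$coefficients)), 1e-10)
})

test_that("complete separation raises an explicit error", {
  expect_error(fit_2x2(saturated_2x2(c(50, 25, 50, 100))), "separation")
})

test_that("grouped and expanded Bernoulli data give identical coefficients", {
  d <- saturated_2x2(c(30, 55, 12, 71))
  fg <- fit_2x2(d)
  long <- tidyr::uncount(d, weights = d$n)
  long$y <- unlist(mapply(function(s, n) rep(c(1, 0), c(s, n - s)),
                          d$s, d$n, SIMPLIFY = FALSE))
  de <- build_design(long, model_spec("binomial_bernoulli", "y",
                                      factors = c("A", "B"),
                                      interactions = list(c("A", "B"))))
  fb <- fit_binomial_glm(de$X, de$y)
  expect_lt(max(abs(fg$coefficients - fb$coefficients)), 1e-10)
})

test_that("binomial fits agree with the reference implementation", {
  d <- saturated_2x2(c(33, 48, 61, 22))
  f <- fit_2x2(d)
  g <- glm(cbind(s, n - s) ~ A * B, data = d, family = binomial,
           control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(f$coefficients - coef(g))), 1e-8)
  expect_lt(max(abs(sqrt(diag(f$vcov)) - sqrt(diag(vcov(g))))), 1e-8)
})

test_that("quasi-Poisson cell means hit the log-link closed form", {
  d <- generate_counts(c(a = 10, b = 20), dispersion = 1,
                       n_replicates = 10000, seed = 3)
  de <- build_design(d, model_spec("count", "count", factors = "condition"))
  f <- fit_quasipoisson_glm(de$X, de$y)
  m <- tapply(d$count, d$condition, mean)
  expect_lt(abs(f$coefficients[1] - log(m[["a"]])), 1e-8)
  expect_lt(abs(f$coefficients[2] - log(m[["b"]] / m[["a"]])), 1e-8)
  expect_lt(abs(f$coefficients[1] - log(10)), 0.05)
  expect_lt(abs(f$coefficients[2] - log(2)), 0.05)
  expect_gt(f$dispersion, 0.9); expect_lt(f$dispersion, 1.1)
})

test_that("a single-condition count fit returns the log sample mean", {
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_quasipoisson_glm(X, c(4, 6))
  expect_equal(unname(f$coefficients), log(5), tolerance = 1e-10)
  expect_error(fit_quasipoisson_glm(X, c(0, 0)), "all-zero")
})

test_that("linear fits reproduce exact lines and sample means", {
  x <- 1:10
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_linear_model(X, 2 * x + 1)
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(f$dispersion, 1e-20)
  y <- c(4.2, 5.1, 4.8, 5.6, 5.0, 4.4, 5.3, 4.9, 5.2, 4.7)
  fm <- fit_linear_model(matrix(1, 10, 1, dimnames = list(NULL, "mu")), y)
  expect_equal(unname(fm$coefficients), mean(y), tolerance = 1e-12)
})

test_that("an eccentricity-style line-by-dose interaction is recovered", {
  set.seed(31)
  n <- 400
  d <- tibble::tibble(
    line = rep(c(0, 1), each = n / 2),
    dose = rep(c(0, 0.125, 0.25, 0.5), n / 4))
  d$ecc <- 0.55 + 0.1 * d$line + 0 * d$dose - 0.05 * d$line * d$dose +
    rnorm(n, 0, 0.08)
  de <- build_design(d, model_spec("continuous", "ecc", factors = "line",
                                   interactions = list(c("line", "dose")),
                                   dose = "dose"))
  f <- fit_linear_model(de$X, de$y)
  est <- f$coefficients[["line:dose"]]
  se <- sqrt(diag(f$vcov))[["line:dose"]]
  expect_lt(abs(est - (-0.05)), 2 * se)
  td <- tidy(f)
  expect_true(all(c("estimate", "std.error", "statistic", "p.value") %in%
                    names(td)))
})

test_that("quasi-Poisson matches the reference implementation", {
  d <- generate_counts(c(a = 7, b = 19, c = 11), dispersion = 2.5,
                       n_replicates = 40, seed = 8)
  de <- build_design(d, model_spec("count", "count", factors = "condition"))
  f <- fit_quasipoisson_glm(de$X, de$y)
  g <- glm(count ~ condition, data = d, family = quasipoisson,
           control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(f$coefficients - coef(g))), 1e-8)
  expect_lt(max(abs(sqrt(diag(f$vcov)) - sqrt(diag(vcov(g))))), 1e-8)
})
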