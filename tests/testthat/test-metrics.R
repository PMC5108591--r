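cells_fixture <- function() {
  tibble::tibble(
    n_nuclei = c(12L, rep(1L, 8)),
    marker_MyHC = c(TRUE, rep(FALSE, 8)),
    marker_GFP = c(TRUE, rep(c(TRUE, FALSE), 4)))
}

test_that("fusion index counts nuclei in MyHC-positive multinucleate cells", {
  fi <- fusion_index(cells_fixture())
  expect_equal(fi$fused_nuclei, 12L)
  expect_equal(fi$total_nuclei, 20L)
  expect_equal(fi$fusion_index, 0.6)
})

test_that("mononucleate MyHC-positive cells never enter the numerator", {
  cells <- tibble::tibble(n_nuclei = c(1L, 1L, 2L),
                          marker_MyHC = c(TRUE, FALSE, TRUE))
  fi <- fusion_index(cells)
  expect_equal(fi$fused_nuclei, 2L)
  expect_equal(fi$total_nuclei, 4L)
})

test_that("gated fusion index keeps the all-nuclei denominator by default", {
  cells <- cells_fixture()
  cells$marker_GFP[1] <- FALSE
  fi <- fusion_index(cells, gate_marker = "GFP")
  expect_equal(fi$fused_nuclei, 0L)       # myotube is GFP-negative
  expect_equal(fi$total_nuclei, 20L)      # denominator still the whole field
  fi2 <- fusion_index(cells_fixture(), gate_marker = "GFP",
                      denominator = "gated")
  expect_equal(fi2$total_nuclei, 12L + 4L)
})

test_that("fusion index on generated truth equals the direct tally", {
  sc <- generate_scene(scene_params(n_cells = 80, myotube_fraction = 0.2,
                                    seed = 12))
  fi <- fusion_index(sc$cells)
  tube_nuclei <- sum(sc$cells$n_nuclei[sc$cells$is_myotube])
  expect_equal(fi$fused_nuclei, tube_nuclei)
  expect_equal(fi$total_nuclei, sum(sc$cells$n_nuclei))
})

test_that("zero total nuclei is an explicit error naming the frame", {
  cells <- tibble::tibble(n_nuclei = integer(), marker_MyHC = logical(),
                          frame_id = character())
  expect_error(fusion_index(cells), "zero total nuclei")
})

test_that("size classes use the inclusive class bounds", {
  expect_equal(as.character(classify_myotube_size(c(2, 4, 5, 9, 10, 24, 25, 80))),
               c("small", "small", "medium", "medium", "large", "large",
                 "very_large", "very_large"))
  expect_error(classify_myotube_size(1), ">= 2")
})

test_that("size classes partition every admissible nucleus count", {
  cls <- classify_myotube_size(2:100)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 99)
  hist <- size_class_histogram(tibble::tibble(n_nuclei = 2:100))
  expect_equal(sum(hist$n), 99L)
  expect_equal(sum(hist$proportion), 1, tolerance = 1e-9)
})

test_that("marker fractions count gated cells correctly", {
  cells <- tibble::tibble(
    marker_EdU = rep(c(TRUE, FALSE), c(44, 56)),
    marker_GFP = TRUE)
  mf <- marker_fraction(cells, "EdU")
  expect_equal(mf$ratio, 0.44)
  mf2 <- marker_fraction(cells, "EdU", gate = "GFP")
  expect_equal(mf2$n, 100L)
  cells$marker_GFP <- FALSE
  expect_warning(mf3 <- marker_fraction(cells, "EdU", gate = "GFP"),
                 "no cells in gate")
  expect_true(is.na(mf3$ratio))
})

test_that("generated marker states recover the programmed probability", {
  d <- generate_outcomes(outcome_spec(mu = qlogis(0.25),
                                      cells_per_group_per_condition = 10000,
                                      seed = 6))
  cells <- tibble::tibble(marker_EdU = d$outcome == 1)
  mf <- marker_fraction(cells, "EdU")
  expect_gte(mf$k, qbinom(0.005, 10000, 0.25))
  expect_lte(mf$k, qbinom(0.995, 10000, 0.25))
})

test_that("moving a nucleus into a myotube raises the fusion index", {
  base <- tibble::tibble(n_nuclei = c(5L, rep(1L, 10)),
                         marker_MyHC = c(TRUE, rep(FALSE, 10)))
  moved <- tibble::tibble(n_nuclei = c(6L, rep(1L, 9)),
                          marker_MyHC = c(TRUE, rep(FALSE, 9)))
  expect_gt(fusion_index(moved)$fusion_index,
            fusion_index(base)$fusion_index)
  expect_equal(fusion_index(base), fusion_index(base))  # purity
})

test_that("engraftment summaries aggregate sections per muscle", {
  one <- tibble::tibble(mouse = "m1", section_position = 1,
                        laminAC_in_fibre = 10, laminAC_interstitial = 5,
                        spectrin_fibres = 3)
  es <- engraftment_summary(one)
  expect_equal(es$per_muscle$laminAC_total, 15)
  expect_equal(es$per_muscle$in_fibre_fraction, 2 / 3)

  three <- tibble::tibble(mouse = "m1", section_position = 1:3,
                          laminAC_in_fibre = 0, laminAC_interstitial = 0,
                          spectrin_fibres = c(4, 6, 8))
  es3 <- engraftment_summary(three)
  expect_equal(es3$per_muscle$spectrin_fibres, 18)
  expect_equal(es3$per_muscle$spectrin_per_section, 6)

  expect_error(engraftment_summary(one[, -3]), "missing columns")
})

test_that("simulated engraftment effect is recovered through the stats layer", {
  # 8 mice, treatment doubles the odds that a donor nucleus sits in a fibre
  set.seed(42)
  mice <- sprintf("m%d", 1:8)
  treated <- rep(c(0, 1), each = 4)
  rows <- lapply(1:8, function(i) {
    p <- plogis(-0.5 + 1 * treated[i] + rnorm(1, 0, 0.2))
    total <- rpois(6, 40)
    infib <- rbinom(6, total, p)
    tibble::tibble(mouse = mice[i], treated = treated[i],
                   section_position = 1:6,
                   laminAC_in_fibre = infib,
                   laminAC_interstitial = total - infib,
                   spectrin_fibres = rpois(6, 20))
  })
  sections <- dplyr::bind_rows(rows)
  es <- engraftment_summary(dplyr::mutate(sections, condition = treated))
  per <- dplyr::rename(es$per_muscle, treated = "condition")
  fit <- fit_model(per, model_spec(
    "binomial_grouped",
    c(successes = "laminAC_in_fibre", trials = "laminAC_total"),
    factors = "treated"))
  est <- tidy(fit)
  expect_gt(est$estimate[est$term == "treated"], 0)
})
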