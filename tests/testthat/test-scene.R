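test_that("empty scene yields a pure background frame and empty truth", {
  sc <- generate_scene(scene_params(n_cells = 0, field_size = c(64, 64),
                                    seed = 1))
  expect_equal(nrow(sc$cells), 0)
  expect_equal(nrow(sc$nuclei), 0)
  expect_true(all(sc$truth_cell_labels == 0))
  expect_true(all(sc$frame$channels$cyto == 0))
})

test_that("degenerate eccentricity distribution is reproduced exactly", {
  sc <- generate_scene(scene_params(n_cells = 50, eccentricity_sd = 0,
                                    eccentricity_mean = 0.8,
                                    myotube_fraction = 0, seed = 1))
  expect_equal(nrow(sc$cells), 50)
  expect_true(all(abs(sc$cells$eccentricity - 0.8) < 1e-12))
})

test_that("myotube count follows the programmed fraction", {
  sc <- generate_scene(scene_params(n_cells = 200, myotube_fraction = 0.2,
                                    field_size = c(1100, 1100), seed = 7))
  k <- sum(sc$cells$is_myotube)
  # binomial 99% interval around n * p, independent tally of the truth table
  expect_gte(k, qbinom(0.005, 200, 0.2))
  expect_lte(k, qbinom(0.995, 200, 0.2))
})

test_that("scene truth satisfies its geometric invariants", {
  sc <- generate_scene(scene_params(n_cells = 60, myotube_fraction = 0.25,
                                    seed = 5))
  expect_true(all(abs(sc$cells$eccentricity -
                        sqrt(1 - (sc$cells$b / sc$cells$a)^2)) < 1e-12))
  expect_true(all(sc$cells$n_nuclei[!sc$cells$is_myotube] == 1L))
  expect_true(all(sc$cells$n_nuclei[sc$cells$is_myotube] >= 2L))
  # every nucleus centre lies inside its cell's ellipse
  joined <- dplyr::left_join(sc$nuclei, sc$cells, by = "cell_id")
  u <- (joined$col - joined$cx) * cos(joined$theta) +
    (joined$row - joined$cy) * sin(joined$theta)
  v <- -(joined$col - joined$cx) * sin(joined$theta) +
    (joined$row - joined$cy) * cos(joined$theta)
  expect_true(all((u / joined$a)^2 + (v / joined$b)^2 <= 1))
})

test_that("rasterised truth ellipses reproduce analytic eccentricity", {
  sc <- generate_scene(scene_params(n_cells = 30, myotube_fraction = 0,
                                    seed = 11))
  for (i in seq_len(nrow(sc$cells))) {
    row <- sc$cells[i, ]
    if (row$b < 10) next
    px <- which(sc$truth_cell_labels == row$cell_id, arr.ind = TRUE)
    expect_lt(abs(compute_eccentricity(px) - row$eccentricity), 0.02)
  }
})

test_that("marker frequencies converge to the programmed probabilities", {
  scenes <- lapply(1:4, function(s)
    generate_scene(scene_params(n_cells = 260, myotube_fraction = 0,
                                field_size = c(1100, 1100),
                                marker_probs = c(EdU = 0.3), seed = s)))
  k <- sum(vapply(scenes, function(sc) sum(sc$cells$marker_EdU), 0))
  n <- sum(vapply(scenes, function(sc) nrow(sc$cells), 0))
  expect_gte(k, qbinom(0.005, n, 0.3))
  expect_lte(k, qbinom(0.995, n, 0.3))
})

test_that("noise sub-stream does not perturb geometry or marker states", {
  p1 <- scene_params(n_cells = 25, seed = 9, noise_sd = 0)
  p2 <- scene_params(n_cells = 25, seed = 9, noise_sd = 800,
                     background_amplitude = 0.4, speckle_density = 10)
  s1 <- generate_scene(p1); s2 <- generate_scene(p2)
  expect_equal(s1$cells, s2$cells)
  expect_equal(s1$nuclei, s2$nuclei)
  expect_false(isTRUE(all.equal(s1$frame$channels$cyto,
                                s2$frame$channels$cyto)))
})

test_that("scene generation is reproducible under a fixed seed", {
  p <- scene_params(n_cells = 20, seed = 4, noise_sd = 300,
                    speckle_density = 5)
  s1 <- generate_scene(p); s2 <- generate_scene(p)
  expect_identical(s1$frame$channels, s2$frame$channels)
  expect_identical(s1$cells, s2$cells)
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(eccentricity_mean = 1.2), "eccentricity_mean")
  expect_error(scene_params(myotube_fraction = 1.5), "probability")
  expect_error(scene_params(nuclei_count_weights = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  # field too small for any cell placement
  expect_error(generate_scene(scene_params(n_cells = 200,
                                           field_size = c(64, 64),
                                           seed = 1)))
})

test_that("fusion design helper inverts the expected fusion index", {
  ek <- expected_nuclei_per_myotube()
  f <- myotube_fraction_for_fusion(0.5)
  expect_equal(f * ek / (f * ek + (1 - f)), 0.5, tolerance = 1e-12)
  # Monte-Carlo confirmation on generated scenes
  cfg <- scene_params(n_cells = 150, field_size = c(1100, 1100),
                      myotube_fraction = myotube_fraction_for_fusion(0.4),
                      seed = 21)
  fis <- vapply(1:4, function(s) {
    cfg$seed <- 20 + s
    fusion_index(generate_scene(cfg)$cells)$fusion_index
  }, 0)
  expect_lt(abs(mean(fis) - 0.4), 0.08)
})
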