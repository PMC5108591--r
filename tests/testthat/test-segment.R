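test_that("a blank frame yields zero nuclei with a warning", {
  expect_warning(res <- detect_nuclei(matrix(0, 64, 64)), "no foreground")
  expect_equal(nrow(res$centroids), 0)
  expect_true(all(res$labels == 0))
})

test_that("well-separated nuclei are all detected near their true centres", {
  sc <- generate_scene(scene_params(n_cells = 50, myotube_fraction = 0,
                                    noise_sd = 0, seed = 2))
  pre <- bandpass_preprocess(sc$frame$channels$dapi)
  res <- detect_nuclei(pre)
  expect_equal(nrow(res$centroids), 50)
  for (i in seq_len(nrow(res$centroids))) {
    d <- sqrt((sc$nuclei$row - res$centroids$row[i])^2 +
                (sc$nuclei$col - res$centroids$col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("watershed splits overlapping nuclei", {
  img <- matrix(0, 80, 80)
  img[disk_mask(40, 32, 10, c(80, 80))] <- 1000
  img[disk_mask(40, 49, 10, c(80, 80))] <- 1000  # centres 17 px apart
  res <- detect_nuclei(img, min_area = 20)
  expect_equal(nrow(res$centroids), 2)
})

test_that("a single cell with one nucleus keeps its full pixel set", {
  dim <- c(100, 100)
  ell <- raster_ellipse(50, 50, 30, 18, 0.4, dim)
  seeds <- matrix(0L, dim[1], dim[2])
  seeds[disk_mask(50, 50, 4, dim)] <- 1L
  labs <- voronoi_segment_cells(ell, seeds)
  expect_true(all(labs[ell] == 1))
  expect_true(all(labs[!ell] == 0))
})

test_that("symmetric overlap splits along the perpendicular bisector", {
  dim <- c(200, 200)
  # odd centre separation puts the bisector between pixel columns, so no
  # pixel is exactly equidistant and the tie-break does not bias the split
  m <- disk_mask(100, 80, 30, dim) | disk_mask(100, 121, 30, dim)
  seeds <- matrix(0L, dim[1], dim[2])
  seeds[disk_mask(100, 80, 3, dim)] <- 1L
  seeds[disk_mask(100, 121, 3, dim)] <- 2L
  labs <- voronoi_segment_cells(m, seeds)
  n1 <- sum(labs == 1); n2 <- sum(labs == 2)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.01)
  expect_true(all(labs[, 1:99][m[, 1:99]] == 1))
  expect_true(all(labs[, 103:200][m[, 103:200]] == 2))
})

test_that("assignment follows geodesic not Euclidean distance", {
  # C-shaped mask: pixels at the tip of one arm are Euclidean-close to the
  # nucleus across the gap but geodesically far around the bend
  dim <- c(90, 90)
  m <- matrix(FALSE, dim[1], dim[2])
  m[10:20, 10:80] <- TRUE   # top arm
  m[70:80, 10:80] <- TRUE   # bottom arm
  m[10:80, 10:20] <- TRUE   # spine
  seeds <- matrix(0L, dim[1], dim[2])
  seeds[disk_mask(15, 75, 3, dim)] <- 1L   # top-arm tip
  seeds[disk_mask(75, 75, 3, dim)] <- 2L   # bottom-arm tip
  labs <- voronoi_segment_cells(m, seeds)
  d1 <- bf_geodesic_dist(m, seeds == 1)
  d2 <- bf_geodesic_dist(m, seeds == 2)
  decided <- m & abs(d1 - d2) > 1e-9
  oracle <- ifelse(d1 < d2, 1L, 2L)
  expect_true(all(labs[decided] == oracle[decided]))
  # the bottom-arm tip region belongs to seed 2 even though seed 1 is
  # Euclidean-nearer across the concavity
  expect_true(all(labs[70:80, 70:80][m[70:80, 70:80]] == 2))
})

test_that("voronoi segmentation validates its inputs", {
  expect_error(voronoi_segment_cells(matrix(TRUE, 4, 4), matrix(0L, 5, 5)),
               "dimensions")
  expect_error(voronoi_segment_cells(matrix(TRUE, 4, 4), matrix(0L, 4, 4)),
               "at least one nucleus")
})

test_that("eccentricity matches analytic values and is rotation invariant", {
  expect_lt(compute_eccentricity(disk_mask(60, 60, 30, c(120, 120))), 0.05)
  e1 <- compute_eccentricity(raster_ellipse(100, 100, 50, 30, 0, c(200, 200)))
  expect_lt(abs(e1 - 0.8), 0.02)
  angles <- (0:7) * pi / 8
  es <- vapply(angles, function(th)
    compute_eccentricity(raster_ellipse(100, 100, 40, 20, th, c(200, 200))),
    0)
  expect_true(all(abs(es - sqrt(1 - 0.25)) < 0.02))
  expect_lt(max(es) - min(es), 0.02)
})

test_that("degenerate regions are rejected", {
  expect_error(compute_eccentricity(matrix(c(1, 1), 1)), "at least 5")
  line <- matrix(FALSE, 20, 20); line[10, 3:17] <- TRUE
  expect_error(compute_eccentricity(line), "collinear")
})

test_that("nucleus-cell assignment conserves nuclei and counts myotubes", {
  sc <- generate_scene(scene_params(n_cells = 40, myotube_fraction = 0.3,
                                    noise_sd = 0, seed = 8))
  asg <- assign_nuclei_to_cells(sc$truth_nucleus_labels,
                                sc$truth_cell_labels)
  expect_equal(sum(asg$counts$n_nuclei) + asg$n_unassigned,
               nrow(sc$nuclei))
  merged <- dplyr::inner_join(asg$counts, sc$cells, by = "cell_id")
  expect_equal(merged$n_nuclei.x, merged$n_nuclei.y)
})

test_that("nuclei outside all cells are flagged unassigned", {
  cells <- matrix(0L, 60, 60); cells[disk_mask(20, 20, 10, c(60, 60))] <- 1L
  nucs <- matrix(0L, 60, 60)
  nucs[disk_mask(20, 20, 3, c(60, 60))] <- 1L
  nucs[disk_mask(50, 50, 3, c(60, 60))] <- 2L
  asg <- assign_nuclei_to_cells(nucs, cells)
  expect_equal(asg$n_unassigned, 1L)
  expect_equal(asg$counts$n_nuclei[asg$counts$cell_id == 1], 1L)
})

test_that("marker classification matches truth on a noiseless render", {
  sc <- generate_scene(scene_params(n_cells = 40, myotube_fraction = 0.2,
                                    marker_probs = c(MyHC = 0.15),
                                    noise_sd = 0, seed = 10))
  cl <- classify_marker(sc$truth_cell_labels, sc$frame$channels$MyHC)
  expect_equal(cl$positive, sc$cells$marker_MyHC)
})

test_that("frame summaries average eccentricity over retained cells", {
  seg <- structure(list(
    cells = tibble::tibble(
      cell_id = 1:3, area = 500L, centroid_row = 1, centroid_col = 1,
      eccentricity = c(0.2, 0.4, 0.6), n_nuclei = 1L,
      touches_border = FALSE, retained = TRUE),
    nucleus_labels = matrix(0L, 2, 2), cell_labels = matrix(0L, 2, 2),
    n_nuclei_total = 3L, n_unassigned = 0L,
    metadata = tibble::tibble(frame_id = "f")), class = "myo_segmentation")
  expect_equal(summarise_frame(seg)$mean_eccentricity, 0.4)
  seg$cells <- seg$cells[1, ]
  expect_equal(summarise_frame(seg)$mean_eccentricity, 0.2)
  seg$cells$retained <- FALSE
  expect_warning(s <- summarise_frame(seg), "no retained")
  expect_true(is.na(s$mean_eccentricity))
})

test_that("segmentation is deterministic and conserves nuclei end to end", {
  sc <- generate_scene(scene_params(n_cells = 30, seed = 6, noise_sd = 300,
                                    background_amplitude = 0.2))
  s1 <- segment_frame(sc$frame)
  s2 <- segment_frame(sc$frame)
  expect_identical(s1$cell_labels, s2$cell_labels)
  expect_identical(s1$cells, s2$cells)
  expect_equal(sum(s1$cells$n_nuclei) + s1$n_unassigned, s1$n_nuclei_total)
})

test_that("programmed frame mean eccentricity is recovered", {
  sc <- generate_scene(scene_params(n_cells = 100, eccentricity_mean = 0.8,
                                    eccentricity_sd = 0.05,
                                    myotube_fraction = 0, noise_sd = 300,
                                    seed = 5))
  seg <- segment_frame(sc$frame)
  expect_lt(abs(summarise_frame(seg)$mean_eccentricity - 0.8), 0.03)
})

test_that("pipeline frame means order scenes by programmed cell shape", {
  mean_of <- function(em, seed) {
    sc <- generate_scene(scene_params(
      n_cells = 30, eccentricity_mean = em, eccentricity_sd = 0.1,
      myotube_fraction = 0, field_size = c(512, 512), noise_sd = 300,
      background_amplitude = 0.2, seed = seed))
    summarise_frame(segment_frame(sc$frame))$mean_eccentricity
  }
  for (s in 1:10) {
    expect_lt(mean_of(0.3, s), mean_of(0.8, 100 + s))
  }
})
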