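# Independent oracles and small fixture builders used across the suite.

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

# Filled disk mask.
disk_mask <- function(cy, cx, r, dim) {
  raster_ellipse(cy, cx, r, r, 0, dim)
}

# Brute-force geodesic distance field from a seed label by iterative
# relaxation over the 8-connected in-mask graph (Bellman-Ford style; only
# viable on small rasters, which is the point: it shares no code with the
# package's Dijkstra).
bf_geodesic_dist <- function(mask, seed_mask) {
  h <- nrow(mask); w <- ncol(mask)
  d <- matrix(Inf, h, w)
  d[seed_mask & mask] <- 0
  moves <- cbind(
    di = c(-1, 1, 0, 0, -1, -1, 1, 1),
    dj = c(0, 0, -1, 1, -1, 1, -1, 1),
    wt = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2)))
  repeat {
    changed <- FALSE
    for (m in seq_len(nrow(moves))) {
      di <- moves[m, 1]; dj <- moves[m, 2]; wt <- moves[m, 3]
      src_r <- max(1, 1 - di):min(h, h - di)
      src_c <- max(1, 1 - dj):min(w, w - dj)
      cand <- d[src_r, src_c, drop = FALSE] + wt
      dst <- d[src_r + di, src_c + dj, drop = FALSE]
      ok <- mask[src_r + di, src_c + dj, drop = FALSE] & (cand < dst - 1e-12)
      if (any(ok)) {
        dst[ok] <- cand[ok]
        d[src_r + di, src_c + dj] <- dst
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# Score a segmentation against scene ground truth: detected-nucleus count,
# the fraction of detected nuclei grouped consistently with the truth
# cells, and the pipeline-vs-truth fusion index gap.
score_scene_recovery <- function(scene, seg) {
  truth_n <- nrow(scene$nuclei)
  det_n <- seg$n_nuclei_total
  cents <- centroids_of(seg$nucleus_labels)
  truth_cell <- scene$truth_cell_labels[cbind(round(cents$row) + 1,
                                              round(cents$col) + 1)]
  asg <- assign_nuclei_to_cells(seg$nucleus_labels, seg$cell_labels)
  pred_cell <- asg$assignment$cell_id
  # majority map: segmented cell -> truth cell
  ok <- !is.na(pred_cell) & truth_cell > 0
  maj <- tapply(truth_cell[ok], pred_cell[ok],
                function(v) as.integer(names(which.max(table(v)))))
  agree <- ok & truth_cell == unname(maj[as.character(pred_cell)])
  fi_truth <- fusion_index(scene$cells)$fusion_index
  fi_pipe <- fusion_index(dplyr::filter(seg$cells, retained))$fusion_index
  list(count_error = abs(det_n - truth_n) / truth_n,
       assignment_accuracy = sum(agree) / length(pred_cell),
       fusion_gap = abs(fi_truth - fi_pipe))
}

# Scene parameters used for the truth-recovery benchmark (the study
# conditions: dense field, strong background gradient, speckles, noise).
recovery_scene <- function(seed) {
  scene_params(n_cells = 100, seed = seed, background_amplitude = 0.3,
               speckle_density = 5, noise_sd = 300)
}

# A small saturated 2x2 binomial fit reused by the report tests.
report_fixture <- function() {
  d <- tibble::tibble(A = c(0, 1, 0, 1), B = c(0, 0, 1, 1),
                      s = c(40, 25, 50, 75), n = rep(100, 4))
  fit_model(d, model_spec("binomial_grouped",
                          c(successes = "s", trials = "n"),
                          factors = c("A", "B"),
                          interactions = list(c("A", "B"))))
}

# Dose-response study design: per-nucleus fusion probability
# plogis(mu + c * dose + u_g), realised through the myotube fraction, with
# `n_rep` replicate frames per dose-by-group cell.
dose_experiment_params <- function(doses, groups, mu, dose_coef, u_by_group,
                                   seed_base, n_cells = 120, n_rep = 3) {
  cfgs <- list()
  i <- 0
  for (g in seq_along(groups)) {
    for (d in doses) {
      for (r in seq_len(n_rep)) {
        i <- i + 1
        p <- plogis(mu + dose_coef * d + u_by_group[g])
        cfgs[[i]] <- scene_params(
          n_cells = n_cells,
          myotube_fraction = myotube_fraction_for_fusion(p),
          dose = d, group = groups[g],
          frame_id = sprintf("d%g_%s_r%d", d, groups[g], r),
          background_amplitude = 0.3, speckle_density = 5, noise_sd = 300,
          seed = seed_base + i)
      }
    }
  }
  cfgs
}

# Fit the dose-gradient mixed model to per-frame fusion counts: nuclei are
# clustered into myotubes, so the per-frame binomial is overdispersed; a
# frame-level ("experiment") random intercept absorbs that extra variance.
fit_dose_model <- function(frame_counts) {
  de <- build_design(frame_counts, model_spec(
    "binomial_grouped", c(successes = "fused", trials = "total"),
    dose = "dose", random_intercept = "frame_id"))
  fit_binomial_glmm(de$X, de$y, de$groups)
}
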