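#' Parameters for a synthetic fluorescence field of view
#'
#' Bundles and validates every knob of the scene simulator. The defaults
#' describe a typical differentiation-assay field: a few hundred pixels on a
#' side, mostly mononucleate myoblasts with a minority of elongated
#' multinucleated myotubes, a smooth low-frequency illumination gradient and
#' sparse saturated speckle artifacts on top of additive Gaussian noise.
#'
#' @param field_size integer vector `c(height, width)` in pixels.
#' @param n_cells number of cells to place.
#' @param eccentricity_mean,eccentricity_sd mean and spread of the true
#'   moments-based eccentricity of mononucleate cells, each in `[0, 1)`
#'   (0 = disk, towards 1 = line). Draws are truncated to `[0, 0.95]`.
#' @param myotube_fraction probability that a cell is a multinucleated
#'   myotube rather than a mononucleate myoblast.
#' @param nuclei_count_weights probability vector over the four myotube size
#'   classes `small` (2-4 nuclei), `medium` (5-9), `large` (10-24) and
#'   `very_large` (25+; capped at 40 in the simulator). Must sum to 1.
#' @param marker_probs named numeric vector of Bernoulli positivity
#'   probabilities, one per marker channel (e.g. `c(MyHC = 0.1, EdU = 0.4)`).
#'   A marker named `"MyHC"` is additionally forced positive on myotubes,
#'   which are MyHC-positive by definition; the stated probability applies
#'   to mononucleate cells.
#' @param background_amplitude amplitude of the smooth 2-D cosine background
#'   gradient, as a fraction of the cytoplasm staining level.
#' @param speckle_density expected number of small saturated artifacts per
#'   megapixel.
#' @param noise_sd standard deviation of additive Gaussian noise, in 16-bit
#'   intensity units (full scale 65535).
#' @param condition,dose,group,frame_id acquisition metadata carried through
#'   to the truth table and frame.
#' @param seed integer seed. Geometry, marker states and noise are drawn
#'   from three sub-streams derived from it, so changing the noise does not
#'   move the cells.
#'
#' @return A validated `scene_params` list.
#' @export
#' @examples
#' p <- scene_params(n_cells = 20, seed = 1)
#' sc <- generate_scene(p)
#' sc$cells
scene_params <- function(field_size = c(640L, 640L),
                         n_cells = 100L,
                         eccentricity_mean = 0.6,
                         eccentricity_sd = 0.15,
                         myotube_fraction = 0.15,
                         nuclei_count_weights = c(small = 0.50, medium = 0.30,
                                                  large = 0.15, very_large = 0.05),
                         marker_probs = c(MyHC = 0.05),
                         background_amplitude = 0,
                         speckle_density = 0,
                         noise_sd = 0,
                         condition = "control",
                         dose = 0,
                         group = "g1",
                         frame_id = "frame_1",
                         seed = 1L) {
  if (length(field_size) != 2 || any(field_size < 32)) {
    abort("`field_size` must be c(height, width) with both >= 32")
  }
  if (n_cells < 0) abort("`n_cells` must be >= 0")
  check_prob(myotube_fraction, "myotube_fraction")
  check_prob(marker_probs, "marker_probs")
  if (length(marker_probs) && is.null(names(marker_probs))) {
    abort("`marker_probs` must be named by marker")
  }
  if (eccentricity_mean < 0 || eccentricity_mean >= 1) {
    abort("`eccentricity_mean` must be in [0, 1)")
  }
  if (eccentricity_sd < 0) abort("`eccentricity_sd` must be >= 0")
  if (length(nuclei_count_weights) != 4) {
    abort("`nuclei_count_weights` must have 4 entries (small, medium, large, very_large)")
  }
  if (any(nuclei_count_weights < 0) ||
      abs(sum(nuclei_count_weights) - 1) > 1e-9) {
    abort("`nuclei_count_weights` must be non-negative and sum to 1 (tol 1e-9)")
  }
  if (background_amplitude < 0) abort("`background_amplitude` must be >= 0")
  if (speckle_density < 0) abort("`speckle_density` must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(
    field_size = as.integer(field_size), n_cells = as.integer(n_cells),
    eccentricity_mean = eccentricity_mean, eccentricity_sd = eccentricity_sd,
    myotube_fraction = myotube_fraction,
    nuclei_count_weights = nuclei_count_weights,
    marker_probs = marker_probs,
    background_amplitude = background_amplitude,
    speckle_density = speckle_density, noise_sd = noise_sd,
    condition = condition, dose = dose, group = group, frame_id = frame_id,
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Intensity levels of the 16-bit render (full scale 65535).
.render_levels <- list(cyto = 18000, nucleus = 32000, marker = 22000,
                       full_scale = 65535, nucleus_radius = 4)

# Size-class nucleus-count ranges; very_large capped at 40 for placement.
.size_class_ranges <- list(small = 2:4, medium = 5:9, large = 10:24,
                           very_large = 25:40)

#' Rasterize a filled ellipse
#'
#' Pixel-set of the ellipse with centre `(cy, cx)` (1-based row/col), semi
#' axes `a >= b` and orientation `theta` (radians from the column axis),
#' on an `dim[1] x dim[2]` grid. Used both by the scene renderer and as an
#' analytic fixture for shape tests.
#'
#' @param cy,cx centre, 1-based row and column.
#' @param a,b semi-major and semi-minor axes in pixels.
#' @param theta orientation in radians.
#' @param dim `c(height, width)` of the raster.
#' @return Logical matrix mask.
#' @export
raster_ellipse <- function(cy, cx, a, b, theta, dim) {
  rr <- floor(max(1, cy - a - 1)):ceiling(min(dim[1], cy + a + 1))
  cc <- floor(max(1, cx - a - 1)):ceiling(min(dim[2], cx + a + 1))
  dr <- outer(rr - cy, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - cx)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m <- matrix(FALSE, dim[1], dim[2])
  m[rr, cc] <- inside
  m
}

# Draw the geometry of one cell (no placement yet).
.draw_cell_geometry <- function(is_myotube, params) {
  if (!is_myotube) {
    e <- rnorm(1, params$eccentricity_mean, params$eccentricity_sd)
    e <- min(max(e, 0), 0.95)
    b <- runif(1, 10, 16)
    a <- b / sqrt(1 - e^2)
    if (a > 60) {
      a <- 60
      e <- sqrt(1 - (b / a)^2)
    }
    list(a = a, b = b, ecc = e, n_nuclei = 1L, is_myotube = FALSE,
         nuc_offsets = cbind(0, 0))
  } else {
    cls <- sample(names(.size_class_ranges), 1,
                  prob = params$nuclei_count_weights)
    rng <- .size_class_ranges[[cls]]
    k <- if (length(rng) == 1) rng else sample(rng, 1)
    rows <- if (k <= 6) 1L else 2L
    per_row <- ceiling(k / rows)
    b <- if (rows == 1) 10 else 15
    rn <- .render_levels$nucleus_radius
    yoff <- if (rows == 1) 0 else 4.5
    span <- (per_row - 1) * 11 / 2
    # semi-major axis long enough that every nucleus disk sits inside the
    # ellipse with margin, and elongated (a/b >= 4) regardless
    shrink <- sqrt(1 - (yoff / (b - rn - 2))^2)
    a <- max((span + rn + 4) / shrink, 4 * b)
    xs <- seq(-span, span, length.out = per_row)
    offs <- if (rows == 1) {
      cbind(xs, 0)
    } else {
      rbind(cbind(xs, yoff), cbind(xs + 5.5, -yoff))[seq_len(k), , drop = FALSE]
    }
    list(a = a, b = b, ecc = sqrt(1 - (b / a)^2), n_nuclei = as.integer(k),
         is_myotube = TRUE, nuc_offsets = offs)
  }
}

#' Generate a synthetic multi-channel field of view with ground truth
#'
#' Places non-overlapping elliptical cells (mononucleate myoblasts and
#' elongated multinucleated myotubes) on a blank field, renders a nuclear
#' channel (one disk per nucleus), a cytoplasm channel (filled ellipses) and
#' one channel per marker (cytoplasm intensity present only on
#' marker-positive cells), then corrupts the render with a smooth cosine
#' background gradient, saturated speckle artifacts and additive Gaussian
#' noise. Every cell's geometry, nucleus positions and marker states are
#' recorded in a truth table, and truth label rasters are kept so that
#' segmentation output can be scored exactly.
#'
#' @param params a [scene_params()] object.
#' @return An object of class `myo_scene`: a list with `frame` (a
#'   `myo_frame`: named channel matrices in `[0, 65535]` plus metadata),
#'   `cells` (truth tibble: one row per cell with centre, axes, orientation,
#'   eccentricity, nucleus count, size class and marker states), `nuclei`
#'   (tibble of nucleus centres), `truth_cell_labels`,
#'   `truth_nucleus_labels` and `speckle_mask` rasters, and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$field_size[1]; w <- params$field_size[2]
  lv <- .render_levels

  geometry <- with_seed(sub_seed(params$seed, 0), {
    n <- params$n_cells
    if (n == 0) {
      list(cells = list(), centres = NULL)
    } else {
      is_tube <- runif(n) < params$myotube_fraction
      cells <- lapply(is_tube, .draw_cell_geometry, params = params)
      thetas <- runif(n, 0, pi)
      for (i in seq_len(n)) cells[[i]]$theta <- thetas[i]
      # place largest first so long myotubes always find room
      ord <- order(vapply(cells, function(g) g$a * g$b, 0), decreasing = TRUE)
      cells <- cells[ord]
      occupied <- matrix(FALSE, h, w)
      placed <- vector("list", n)
      for (i in seq_len(n)) {
        g <- cells[[i]]
        margin <- g$a + 3
        if (margin >= h - margin || margin >= w - margin) {
          abort(sprintf(
            "cell of extent %.0f px cannot fit the %dx%d field; placed %d of %d",
            g$a, h, w, i - 1L, n))
        }
        ok <- FALSE
        for (try in seq_len(1000)) {
          cy <- runif(1, margin, h - margin)
          cx <- runif(1, margin, w - margin)
          # collision mask padded by 2 px so neighbouring cells never touch
          pad <- raster_ellipse(cy, cx, g$a + 2, g$b + 2, g$theta, c(h, w))
          if (!any(occupied & pad)) {
            occupied <- occupied | pad
            g$cy <- cy; g$cx <- cx
            placed[[i]] <- g
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "could not place cell %d of %d after 1000 attempts (field too crowded)",
            i, n))
        }
      }
      list(cells = placed)
    }
  })

  cells <- geometry$cells
  n <- length(cells)
  marker_names <- names(params$marker_probs)

  marker_states <- with_seed(sub_seed(params$seed, 1), {
    st <- matrix(FALSE, n, length(marker_names),
                 dimnames = list(NULL, marker_names))
    for (m in marker_names) st[, m] <- runif(n) < params$marker_probs[[m]]
    if ("MyHC" %in% marker_names && n > 0) {
      st[vapply(cells, `[[`, TRUE, "is_myotube"), "MyHC"] <- TRUE
    }
    st
  })

  # --- render noiseless truth ---------------------------------------------
  cell_labels <- matrix(0L, h, w)
  nuc_labels <- matrix(0L, h, w)
  cyto <- matrix(0, h, w)
  dapi <- matrix(0, h, w)
  marker_ch <- lapply(marker_names, function(m) matrix(0, h, w))
  names(marker_ch) <- marker_names

  jitters <- with_seed(sub_seed(params$seed, 2),
                       if (n > 0) runif(n, 0.85, 1.15) else numeric())

  nuc_rows <- list()
  nuc_id <- 0L
  for (i in seq_len(n)) {
    g <- cells[[i]]
    mask <- raster_ellipse(g$cy, g$cx, g$a, g$b, g$theta, c(h, w))
    cell_labels[mask] <- i
    cyto[mask] <- lv$cyto * jitters[i]
    for (m in marker_names) {
      if (marker_states[i, m]) marker_ch[[m]][mask] <- lv$marker * jitters[i]
    }
    # nuclei: offsets along the major axis, rotated into frame coordinates
    off <- g$nuc_offsets
    nr <- off[, 1] * sin(g$theta) + off[, 2] * cos(g$theta) + g$cy
    nc <- off[, 1] * cos(g$theta) - off[, 2] * sin(g$theta) + g$cx
    for (j in seq_len(nrow(off))) {
      nuc_id <- nuc_id + 1L
      nmask <- raster_ellipse(nr[j], nc[j], lv$nucleus_radius,
                              lv$nucleus_radius, 0, c(h, w))
      dapi[nmask] <- lv$nucleus
      nuc_labels[nmask] <- nuc_id
      nuc_rows[[nuc_id]] <- tibble::tibble(
        nucleus_id = nuc_id, cell_id = i, row = nr[j], col = nc[j])
    }
  }

  # --- corrupt: background gradient, speckles, noise ----------------------
  speckle_mask <- matrix(FALSE, h, w)
  channels <- c(list(dapi = dapi, cyto = cyto), marker_ch)
  channels <- with_seed(sub_seed(params$seed, 2), {
    # burn the jitter draws again so the stream position matches the render
    if (n > 0) runif(n)
    if (params$background_amplitude > 0) {
      ph <- runif(4, 0, 2 * pi)
      fr <- runif(2, 0.5, 1.5)
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      bg <- (0.5 + 0.25 * cos(2 * pi * fr[1] * rr / h + ph[1]) +
               0.25 * cos(2 * pi * fr[2] * cc / w + ph[2]))
      bg <- params$background_amplitude * lv$cyto * bg
      channels <- lapply(channels, function(ch) ch + bg)
    }
    n_speck <- rpois(1, params$speckle_density * h * w / 1e6)
    if (n_speck > 0) {
      for (s in seq_len(n_speck)) {
        sr <- runif(1, 3, h - 3); sc <- runif(1, 3, w - 3)
        rad <- runif(1, 0.9, 1.6)  # disk of ~3-9 px
        sm <- raster_ellipse(sr, sc, rad, rad, 0, c(h, w))
        speckle_mask <- speckle_mask | sm
        channels <- lapply(channels, function(ch) { ch[sm] <- lv$full_scale; ch })
      }
    }
    if (params$noise_sd > 0) {
      channels <- lapply(channels, function(ch)
        ch + matrix(rnorm(h * w, 0, params$noise_sd), h, w))
    }
    lapply(channels, function(ch) pmin(pmax(ch, 0), lv$full_scale))
  })

  truth <- if (n == 0) {
    tibble::tibble(cell_id = integer(), cx = numeric(), cy = numeric(),
                   a = numeric(), b = numeric(), theta = numeric(),
                   eccentricity = numeric(), n_nuclei = integer(),
                   is_myotube = logical())
  } else {
    tibble::tibble(
      cell_id = seq_len(n),
      cx = vapply(cells, `[[`, 0, "cx") - 1,  # 0-based, (row, col) = (cy, cx)
      cy = vapply(cells, `[[`, 0, "cy") - 1,
      a = vapply(cells, `[[`, 0, "a"),
      b = vapply(cells, `[[`, 0, "b"),
      theta = vapply(cells, `[[`, 0, "theta"),
      eccentricity = vapply(cells, `[[`, 0, "ecc"),
      n_nuclei = vapply(cells, `[[`, 1L, "n_nuclei"),
      is_myotube = vapply(cells, `[[`, TRUE, "is_myotube")
    )
  }
  for (m in marker_names) truth[[paste0("marker_", m)]] <- marker_states[, m]
  truth$condition <- params$condition
  truth$dose <- params$dose
  truth$group <- params$group

  nuclei <- if (length(nuc_rows)) dplyr::bind_rows(nuc_rows) else
    tibble::tibble(nucleus_id = integer(), cell_id = integer(),
                   row = numeric(), col = numeric())

  frame <- structure(list(
    channels = channels,
    pixel_size = NA_real_,
    metadata = tibble::tibble(condition = params$condition,
                              dose = params$dose, group = params$group,
                              frame_id = params$frame_id)
  ), class = "myo_frame")

  structure(list(frame = frame, cells = truth, nuclei = nuclei,
                 truth_cell_labels = cell_labels,
                 truth_nucleus_labels = nuc_labels,
                 speckle_mask = speckle_mask, params = params),
            class = "myo_scene")
}

#' Expected nuclei per myotube under the size-class weights
#'
#' Myotube nucleus counts are drawn by first picking a size class with the
#' given weights, then uniformly within the class range (2-4, 5-9, 10-24,
#' 25-40). The expectation is the weight-averaged class mean.
#'
#' @param nuclei_count_weights probability vector over the four classes.
#' @return Expected nucleus count per myotube.
#' @export
expected_nuclei_per_myotube <- function(nuclei_count_weights =
                                          formals(scene_params)$nuclei_count_weights) {
  w <- eval(nuclei_count_weights)
  sum(w * vapply(.size_class_ranges, function(r) mean(r), 0))
}

#' Myotube fraction that yields a target fusion probability
#'
#' Inverse design helper for dose-response simulations: given a target
#' per-nucleus fusion probability `p` (the expected fusion index), returns
#' the myotube fraction `f` such that `f E[k] / (f E[k] + (1 - f)) = p`,
#' with `E[k]` the expected nuclei per myotube under the class weights.
#' Programming `p = plogis(mu + c * dose)` therefore makes the logit of
#' the expected fusion index exactly linear in dose.
#'
#' @param p target fusion probability in (0, 1).
#' @param nuclei_count_weights probability vector over the four classes.
#' @return Myotube fraction in (0, 1).
#' @export
myotube_fraction_for_fusion <- function(p, nuclei_count_weights =
                                          formals(scene_params)$nuclei_count_weights) {
  stopifnot(all(p > 0), all(p < 1))
  ek <- expected_nuclei_per_myotube(nuclei_count_weights)
  p / (p + (1 - p) * ek)
}

#' @export
print.myo_scene <- function(x, ...) {
  cat(sprintf("<myo_scene> %dx%d px, %d cells (%d myotubes), %d nuclei, channels: %s\n",
              x$params$field_size[1], x$params$field_size[2],
              nrow(x$cells), sum(x$cells$is_myotube), nrow(x$nuclei),
              paste(names(x$frame$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.myo_frame <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<myo_frame> %dx%d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
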