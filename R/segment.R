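#' Band-pass pre-processing of a fluorescence channel
#'
#' Removes the two nuisance components the simulator (and real microscopy)
#' puts on top of the signal: (1) low-frequency background staining,
#' estimated by a Gaussian blur at a scale `low_sigma` much larger than a
#' cell and subtracted (clipped at zero); (2) small, compact, near-saturated
#' artifacts ("speckles"), identified as connected components above the
#' `artifact_min_intensity` quantile that are both smaller than
#' `artifact_max_area` and blob-like (solidity > 0.9), and zeroed.
#'
#' Candidate pixels are those above the intensity quantile; the unit that
#' is kept or zeroed is the containing foreground object (connected
#' component of the background-subtracted foreground), so that a bright
#' noise pixel inside a genuine nucleus never punches a hole in it, while
#' an isolated saturated speckle is removed whole.
#'
#' @param image 2-D numeric matrix of non-negative intensities.
#' @param low_sigma background scale in pixels (> 0).
#' @param artifact_max_area maximum artifact area in px^2; must be below
#'   the area of the smallest genuine structure (default 30, under a
#'   typical nucleus cross-section).
#' @param artifact_min_intensity intensity quantile in (0, 1] above which a
#'   pixel marks a candidate artifact.
#' @return Non-negative matrix of the same shape.
#' @export
bandpass_preprocess <- function(image, low_sigma = 50,
                                artifact_max_area = 30,
                                artifact_min_intensity = 0.999) {
  check_raster(image)
  if (low_sigma <= 0) abort("`low_sigma` must be > 0")
  if (artifact_min_intensity <= 0 || artifact_min_intensity > 1) {
    abort("`artifact_min_intensity` must be in (0, 1]")
  }
  bg <- .background_estimate(image, low_sigma)
  out <- pmax(image - bg, 0)
  thr <- quantile(image, artifact_min_intensity, names = FALSE)
  cand <- image > thr
  if (any(cand)) {
    fg <- out > .otsu(out) | cand
    labs <- EBImage::bwlabel(fg)
    hit <- unique(labs[cand & labs > 0])
    areas <- tabulate(labs[labs > 0])
    for (k in hit[areas[hit] <= artifact_max_area]) {
      px <- which(labs == k, arr.ind = TRUE)
      if (.solidity(px) > 0.9) out[labs == k] <- 0
    }
  }
  out
}

# Gaussian background estimate at scale sigma. Images smaller than the
# filter support are edge-replicate padded so the estimate is defined on
# any frame size.
.background_estimate <- function(image, sigma) {
  kern <- 2 * ceiling(3 * sigma) + 1
  h <- nrow(image); w <- ncol(image)
  p <- ceiling(3 * sigma) + 1
  if (min(h, w) > kern) {
    return(as.matrix(EBImage::gblur(image, sigma = sigma)))
  }
  ri <- pmin(pmax(seq(1 - p, h + p), 1), h)
  ci <- pmin(pmax(seq(1 - p, w + p), 1), w)
  padded <- image[ri, ci]
  blurred <- as.matrix(EBImage::gblur(padded, sigma = sigma))
  blurred[p + seq_len(h), p + seq_len(w)]
}

# Solidity = area / convex-hull area of a pixel set. Components of < 3
# distinct points are maximally compact by convention.
.solidity <- function(px) {
  if (nrow(px) < 3) return(1)
  hull <- grDevices::chull(px[, 2], px[, 1])
  if (length(hull) < 3) return(1)
  hx <- px[hull, 2]; hy <- px[hull, 1]
  # shoelace, padded by half-pixel border so single-row sets don't divide by 0
  area_hull <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  min(nrow(px) / max(area_hull, nrow(px) * 0.5), 1)
}

# Otsu threshold over a numeric vector or matrix on its own range.
.otsu <- function(x, levels = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(floor((x - r[1]) / diff(r) * levels) + 1, levels),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / levels * diff(r)
}

#' Detect nuclei in a pre-processed nuclear channel
#'
#' Global Otsu threshold, hole filling, watershed on the distance transform
#' to split touching nuclei, and a minimum-area filter. Labels are assigned
#' in raster-scan (row-major) order of each component's first pixel.
#'
#' @param nuclear_channel pre-processed 2-D matrix (see
#'   [bandpass_preprocess()]).
#' @param min_area minimum nucleus area in px^2.
#' @return List with `labels` (integer raster) and `centroids` (tibble
#'   `nucleus_id`, `row`, `col`; 0-based pixel coordinates). An empty mask
#'   yields zero labels with a warning, not an error.
#' @export
detect_nuclei <- function(nuclear_channel, min_area = 20) {
  check_raster(nuclear_channel, "nuclear_channel")
  thr <- .otsu(nuclear_channel)
  mask <- nuclear_channel > thr
  if (!any(mask)) {
    warn("no foreground found in nuclear channel; returning zero labels")
    return(list(labels = matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel)),
                centroids = tibble::tibble(nucleus_id = integer(),
                                           row = numeric(), col = numeric())))
  }
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  dm <- EBImage::distmap(mask)
  labs <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  areas <- tabulate(labs[labs > 0])
  small <- which(areas < min_area)
  if (length(small)) labs[labs %in% small] <- 0L
  labs <- if (any(labs > 0)) relabel_raster_scan(labs) else
    matrix(0L, nrow(labs), ncol(labs))
  cents <- centroids_of(labs)
  list(labels = labs, centroids = cents)
}

#' Centroids of a label raster
#'
#' @param labels integer label raster.
#' @return Tibble `nucleus_id`, `row`, `col` (0-based centroid
#'   coordinates), one row per positive label.
#' @export
centroids_of <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(tibble::tibble(nucleus_id = integer(), row = numeric(),
                          col = numeric()))
  }
  px <- which(labels > 0, arr.ind = TRUE)
  vals <- labels[labels > 0]
  tibble::tibble(
    nucleus_id = ids,
    row = as.numeric(tapply(px[, 1], vals, mean)) - 1,
    col = as.numeric(tapply(px[, 2], vals, mean)) - 1)
}

#' Segregate overlapping cytoplasm by nucleus-anchored geodesic Voronoi
#'
#' Every cytoplasm pixel is assigned the label of the nearest nucleus,
#' where distance is geodesic -- measured along 8-connected paths that stay
#' inside the cytoplasm mask -- so touching cells split along the
#' equidistant ridge but disconnected cytoplasm is never bridged across
#' background. Cytoplasm components containing no nucleus are dropped
#' (label 0). Ties go to the lower nucleus label.
#'
#' @param cytoplasm_mask logical (or 0/1) raster of cytoplasm foreground.
#' @param nucleus_labels integer label raster of seed nuclei, same shape.
#' @return Integer cell-label raster (labels are the nucleus labels).
#' @export
voronoi_segment_cells <- function(cytoplasm_mask, nucleus_labels) {
  if (!is.matrix(cytoplasm_mask)) abort("`cytoplasm_mask` must be a matrix")
  check_same_shape(cytoplasm_mask, nucleus_labels,
                   "cytoplasm_mask", "nucleus_labels")
  if (!any(nucleus_labels > 0)) abort("need at least one nucleus label")
  mask <- cytoplasm_mask > 0
  # nuclei are valid cell territory even where the cytoplasm stain is dim
  mask <- mask | (nucleus_labels > 0)
  geodesic_voronoi_cpp(mask, matrix(as.integer(nucleus_labels),
                                    nrow(nucleus_labels)))
}

#' Moments-based eccentricity of a pixel region
#'
#' With `lambda1 >= lambda2` the eigenvalues of the covariance matrix of
#' the region's pixel coordinates, eccentricity is
#' `sqrt(1 - lambda2 / lambda1)`: 0 for a disk, approaching 1 for a line.
#' Invariant to translation, rotation and uniform intensity scaling (the
#' computation uses only the binary pixel set).
#'
#' @param pixels either a logical/0-1 matrix mask or a 2-column matrix of
#'   (row, col) pixel coordinates; at least 5 pixels.
#' @return Eccentricity in `[0, 1)`.
#' @export
compute_eccentricity <- function(pixels) {
  px <- if (is.matrix(pixels) && ncol(pixels) == 2 && !is.logical(pixels) &&
            !all(pixels %in% c(0, 1))) {
    pixels
  } else {
    which(pixels > 0, arr.ind = TRUE)
  }
  if (nrow(px) < 5) abort("eccentricity needs at least 5 pixels")
  cv <- stats::cov(px) * (nrow(px) - 1) / nrow(px)  # population moments
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] <= .Machine$double.eps * ev[1]) {
    abort("degenerate (collinear) region: eccentricity undefined")
  }
  sqrt(1 - ev[2] / ev[1])
}

#' Count nuclei per cell
#'
#' A nucleus belongs to the cell label occupying its centroid pixel; if the
#' centroid falls on background, the majority cell label over the nucleus
#' mask is used; a nucleus overlapping no cell is flagged unassigned.
#'
#' @param nucleus_labels,cell_labels aligned label rasters.
#' @return List with `counts` (tibble `cell_id`, `n_nuclei` for every cell
#'   label present), `assignment` (tibble `nucleus_id`, `cell_id`, NA when
#'   unassigned) and `n_unassigned`.
#' @export
assign_nuclei_to_cells <- function(nucleus_labels, cell_labels) {
  check_same_shape(nucleus_labels, cell_labels,
                   "nucleus_labels", "cell_labels")
  nuc_ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  cents <- centroids_of(nucleus_labels)
  assigned <- integer(length(nuc_ids))
  for (i in seq_along(nuc_ids)) {
    r <- round(cents$row[i]) + 1; c <- round(cents$col[i]) + 1
    lab <- cell_labels[r, c]
    if (lab == 0) {
      over <- cell_labels[nucleus_labels == nuc_ids[i]]
      over <- over[over > 0]
      lab <- if (length(over)) as.integer(names(which.max(table(over)))) else 0L
    }
    assigned[i] <- lab
  }
  cell_ids <- sort(unique(cell_labels[cell_labels > 0]))
  counts <- tibble::tibble(
    cell_id = cell_ids,
    n_nuclei = vapply(cell_ids, function(id) sum(assigned == id), 0L))
  list(counts = counts,
       assignment = tibble::tibble(
         nucleus_id = nuc_ids,
         cell_id = ifelse(assigned == 0, NA_integer_, assigned)),
       n_unassigned = sum(assigned == 0))
}

#' Classify per-cell marker positivity
#'
#' A cell is marker-positive when its mean in-cell intensity in the
#' (pre-processed) marker channel exceeds a threshold: either Otsu over the
#' per-cell means (default) or a fixed numeric value.
#'
#' @param cell_labels integer cell label raster.
#' @param marker_channel matrix of marker intensities, same shape.
#' @param threshold `"otsu"` or a fixed numeric intensity.
#' @return Tibble `cell_id`, `mean_intensity`, `positive`.
#' @export
classify_marker <- function(cell_labels, marker_channel, threshold = "otsu") {
  check_same_shape(cell_labels, marker_channel,
                   "cell_labels", "marker_channel")
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  means <- vapply(ids, function(id) mean(marker_channel[cell_labels == id]), 0)
  thr <- if (identical(threshold, "otsu")) .otsu(means) else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  tibble::tibble(cell_id = ids, mean_intensity = means,
                 positive = means > thr)
}

#' Segment one multi-channel frame end to end
#'
#' Runs the full image-analysis procedure on a frame: band-pass
#' pre-processing of every channel, nucleus detection on the nuclear
#' channel, Otsu cytoplasm masking, geodesic Voronoi segregation anchored
#' on the nuclei, nucleus-to-cell assignment, marker classification and
#' per-cell shape measurement.
#'
#' Multinucleated myotubes must stay single objects for fusion counting,
#' while touching mononucleate cells must be segregated for shape
#' measurement. When `myotube_marker` names a marker channel present in
#' the frame, each connected cytoplasm component is classified on that
#' marker: positive components (differentiated, MyHC-expressing) are kept
#' whole as one multinucleate cell, negative components are split into
#' per-nucleus cells by the Voronoi rule. With `myotube_marker = NULL`
#' every component is Voronoi-split (pure shape-assay behaviour).
#'
#' @param frame a `myo_frame` (see [generate_scene()]) or a named list of
#'   channel matrices.
#' @param nuclear_channel,cytoplasm_channel channel names.
#' @param marker_channels channel names to classify; defaults to every
#'   other channel.
#' @param low_sigma,artifact_max_area,artifact_min_intensity see
#'   [bandpass_preprocess()].
#' @param min_nucleus_area minimum nucleus size in px^2.
#' @param min_cell_area cells smaller than this are flagged and excluded
#'   from frame statistics.
#' @param marker_threshold see [classify_marker()].
#' @param myotube_marker marker whose positive cytoplasm components are
#'   kept as single multinucleate objects (default `"MyHC"`; ignored when
#'   that channel is absent).
#' @return Object of class `myo_segmentation`: list with `cells` (per-cell
#'   tibble: `cell_id`, `area`, `centroid_row`, `centroid_col` (0-based),
#'   `eccentricity`, `n_nuclei`, `touches_border`, `retained`, one logical
#'   `marker_*` column per marker), `nucleus_labels`, `cell_labels`,
#'   `n_nuclei_total`, `n_unassigned` and `metadata`.
#' @export
segment_frame <- function(frame,
                          nuclear_channel = "dapi",
                          cytoplasm_channel = "cyto",
                          marker_channels = NULL,
                          low_sigma = 50,
                          artifact_max_area = 30,
                          artifact_min_intensity = 0.999,
                          min_nucleus_area = 20,
                          min_cell_area = 100,
                          marker_threshold = "otsu",
                          myotube_marker = "MyHC") {
  channels <- if (inherits(frame, "myo_frame")) frame$channels else frame
  metadata <- if (inherits(frame, "myo_frame")) frame$metadata else
    tibble::tibble(frame_id = "frame_1")
  if (!nuclear_channel %in% names(channels)) {
    abort(sprintf("nuclear channel '%s' not found", nuclear_channel))
  }
  if (!cytoplasm_channel %in% names(channels)) {
    abort(sprintf("cytoplasm channel '%s' not found", cytoplasm_channel))
  }
  marker_channels <- marker_channels %||%
    setdiff(names(channels), c(nuclear_channel, cytoplasm_channel))

  pre <- lapply(channels, bandpass_preprocess, low_sigma = low_sigma,
                artifact_max_area = artifact_max_area,
                artifact_min_intensity = artifact_min_intensity)

  nuc <- detect_nuclei(pre[[nuclear_channel]], min_area = min_nucleus_area)
  cyto <- pre[[cytoplasm_channel]]
  cmask <- cyto > .otsu(cyto)
  cmask <- as.matrix(EBImage::fillHull(EBImage::Image(cmask))) > 0

  if (!any(nuc$labels > 0)) {
    warn("no nuclei detected; returning empty segmentation")
    cells <- tibble::tibble(cell_id = integer(), area = integer(),
                            centroid_row = numeric(), centroid_col = numeric(),
                            eccentricity = numeric(), n_nuclei = integer(),
                            touches_border = logical(), retained = logical())
    return(structure(list(cells = cells, nucleus_labels = nuc$labels,
                          cell_labels = matrix(0L, nrow(cyto), ncol(cyto)),
                          n_nuclei_total = 0L, n_unassigned = 0L,
                          metadata = metadata),
                     class = "myo_segmentation"))
  }

  vlabs <- voronoi_segment_cells(cmask, nuc$labels)
  clabs <- vlabs
  if (!is.null(myotube_marker) && myotube_marker %in% names(pre)) {
    comp <- EBImage::bwlabel(cmask | nuc$labels > 0)
    # only components that received at least one nucleus can form cells
    with_nuc <- unique(comp[nuc$labels > 0 & comp > 0])
    cls <- classify_marker(comp, pre[[myotube_marker]],
                           threshold = marker_threshold)
    pos <- intersect(cls$cell_id[cls$positive], with_nuc)
    if (length(pos)) {
      keep_whole <- matrix(comp %in% pos, nrow(comp))
      clabs[keep_whole] <- max(vlabs) + comp[keep_whole]
    }
  }
  clabs <- if (any(clabs > 0)) relabel_raster_scan(clabs) else clabs
  asg <- assign_nuclei_to_cells(nuc$labels, clabs)

  ids <- sort(unique(clabs[clabs > 0]))
  h <- nrow(clabs); w <- ncol(clabs)
  border <- vapply(ids, function(id) {
    any(clabs[1, ] == id) || any(clabs[h, ] == id) ||
      any(clabs[, 1] == id) || any(clabs[, w] == id)
  }, TRUE)
  px_by_id <- split(which(clabs > 0, arr.ind = TRUE),
                    rep(clabs[clabs > 0], 2))
  cells <- tibble::tibble(
    cell_id = ids,
    area = vapply(ids, function(id) sum(clabs == id), 0L),
    centroid_row = NA_real_, centroid_col = NA_real_,
    eccentricity = NA_real_,
    touches_border = border)
  for (i in seq_along(ids)) {
    px <- matrix(px_by_id[[as.character(ids[i])]], ncol = 2)
    cells$centroid_row[i] <- mean(px[, 1]) - 1
    cells$centroid_col[i] <- mean(px[, 2]) - 1
    cells$eccentricity[i] <- if (nrow(px) >= 5) {
      tryCatch(compute_eccentricity(px), error = function(e) NA_real_)
    } else NA_real_
  }
  cells <- dplyr::left_join(cells, asg$counts, by = "cell_id")
  cells$n_nuclei[is.na(cells$n_nuclei)] <- 0L
  for (m in marker_channels) {
    cl <- classify_marker(clabs, pre[[m]], threshold = marker_threshold)
    cells[[paste0("marker_", m)]] <-
      cl$positive[match(cells$cell_id, cl$cell_id)]
  }
  cells$retained <- !cells$touches_border & cells$area >= min_cell_area

  structure(list(cells = cells, nucleus_labels = nuc$labels,
                 cell_labels = clabs,
                 n_nuclei_total = nrow(nuc$centroids),
                 n_unassigned = asg$n_unassigned,
                 metadata = metadata),
            class = "myo_segmentation")
}

#' @export
print.myo_segmentation <- function(x, ...) {
  cat(sprintf("<myo_segmentation> %d cells (%d retained), %d nuclei (%d unassigned)\n",
              nrow(x$cells), sum(x$cells$retained), x$n_nuclei_total,
              x$n_unassigned))
  invisible(x)
}

#' Per-frame summary of a segmentation
#'
#' The frame-level quantity carried into the shape statistics is the
#' unweighted mean eccentricity over retained cells (non-border,
#' area-filtered). Zero retained cells yields an `NA` summary with a
#' warning rather than an error.
#'
#' @param segmentation a `myo_segmentation` from [segment_frame()].
#' @return One-row tibble: frame metadata, `n_cells`, `n_retained`,
#'   `n_nuclei`, `mean_eccentricity`.
#' @export
summarise_frame <- function(segmentation) {
  stopifnot(inherits(segmentation, "myo_segmentation"))
  cells <- dplyr::filter(segmentation$cells, .data$retained,
                         !is.na(.data$eccentricity))
  if (nrow(cells) == 0) {
    warn("no retained cells in frame; mean eccentricity is NA")
  }
  dplyr::bind_cols(
    segmentation$metadata,
    tibble::tibble(
      n_cells = nrow(segmentation$cells),
      n_retained = nrow(cells),
      n_nuclei = segmentation$n_nuclei_total,
      mean_eccentricity = if (nrow(cells)) mean(cells$eccentricity) else
        NA_real_))
}
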