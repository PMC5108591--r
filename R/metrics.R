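#' Fusion index of a per-cell table
#'
#' The fusion index is the ratio of the number of nuclei incorporated into
#' MyHC-positive multinucleate cells (>= 2 nuclei) to the total number of
#' nuclei in the field of view. With a gate marker (e.g. GFP to restrict
#' to transduced cells), the numerator additionally requires
#' gate-positivity; the denominator stays all nuclei in the field (the
#' convention of the gated counts this package models), unless
#' `denominator = "gated"`.
#'
#' @param cells per-cell tibble with `n_nuclei` and logical `marker_*`
#'   columns (from [segment_frame()] or a scene truth table).
#' @param myhc_marker name of the differentiation marker column (without
#'   the `marker_` prefix).
#' @param gate_marker optional gate marker name.
#' @param denominator `"all"` (default) or `"gated"` (nuclei of
#'   gate-positive cells only).
#' @return One-row tibble: `fused_nuclei`, `total_nuclei`, `fusion_index`.
#' @export
#' @examples
#' cells <- tibble::tibble(n_nuclei = c(12, rep(1, 8)),
#'                         marker_MyHC = c(TRUE, rep(FALSE, 8)))
#' fusion_index(cells)  # 12 of 20 nuclei
fusion_index <- function(cells, myhc_marker = "MyHC", gate_marker = NULL,
                         denominator = c("all", "gated")) {
  denominator <- match.arg(denominator)
  mcol <- paste0("marker_", myhc_marker)
  if (!mcol %in% names(cells)) {
    abort(sprintf("column '%s' not found in cell table", mcol))
  }
  pos <- isTRUE_vec(cells[[mcol]])
  gated <- if (!is.null(gate_marker)) {
    gcol <- paste0("marker_", gate_marker)
    if (!gcol %in% names(cells)) {
      abort(sprintf("column '%s' not found in cell table", gcol))
    }
    isTRUE_vec(cells[[gcol]])
  } else rep(TRUE, nrow(cells))
  denom_cells <- if (denominator == "gated") gated else rep(TRUE, nrow(cells))
  total <- sum(cells$n_nuclei[denom_cells])
  if (total < 1) {
    fid <- if ("frame_id" %in% names(cells)) cells$frame_id[1] else "<frame>"
    abort(sprintf("zero total nuclei in frame %s: fusion index undefined", fid))
  }
  fused <- sum(cells$n_nuclei[pos & gated & cells$n_nuclei >= 2])
  tibble::tibble(fused_nuclei = fused, total_nuclei = total,
                 fusion_index = fused / total)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Myotube size class from nucleus count
#'
#' Myotubes are binned by nuclei per myotube into inclusive classes:
#' small (2-4), medium (5-9), large (10-24) and very large (25+).
#'
#' @param n_nuclei integer vector of nucleus counts, each >= 2.
#' @return Factor with levels `small`, `medium`, `large`, `very_large`.
#' @export
classify_myotube_size <- function(n_nuclei) {
  if (any(n_nuclei < 2)) {
    abort("a myotube has >= 2 nuclei; got a count below 2")
  }
  cut(n_nuclei, breaks = c(2, 5, 10, 25, Inf), right = FALSE,
      labels = c("small", "medium", "large", "very_large"))
}

#' Myotube size-class histogram of a per-cell table
#'
#' @param cells per-cell tibble with `n_nuclei` (and optionally a
#'   `marker_*` column to restrict to marker-positive cells).
#' @param myhc_marker optional marker restricting which cells count as
#'   myotubes (default: any cell with >= 2 nuclei).
#' @return Tibble `size_class`, `n`, `proportion` over the four classes.
#' @export
size_class_histogram <- function(cells, myhc_marker = NULL) {
  keep <- cells$n_nuclei >= 2
  if (!is.null(myhc_marker)) {
    keep <- keep & isTRUE_vec(cells[[paste0("marker_", myhc_marker)]])
  }
  cls <- classify_myotube_size(cells$n_nuclei[keep])
  tab <- table(cls)
  tibble::tibble(size_class = factor(names(tab), levels = names(tab)),
                 n = as.integer(tab),
                 proportion = if (sum(tab) > 0) as.integer(tab) / sum(tab)
                 else rep(NA_real_, length(tab)))
}

#' Marker-positive fraction of a per-cell table
#'
#' `k` = cells positive for `marker` (and for `gate`, if given); `n` =
#' cells positive for `gate` (or all cells); ratio `k/n`. Counts are
#' retained so the fraction can feed a binomial model directly.
#'
#' @param cells per-cell tibble with logical `marker_*` columns.
#' @param marker marker name (without prefix).
#' @param gate optional gate marker name defining the denominator.
#' @return One-row tibble `k`, `n`, `ratio`. An empty gate set yields an
#'   `NA` ratio with a warning.
#' @export
marker_fraction <- function(cells, marker, gate = NULL) {
  pos <- isTRUE_vec(cells[[paste0("marker_", marker)]])
  ingate <- if (!is.null(gate)) {
    isTRUE_vec(cells[[paste0("marker_", gate)]])
  } else rep(TRUE, nrow(cells))
  n <- sum(ingate)
  if (n == 0) {
    warn(sprintf("no cells in gate '%s'; marker fraction is NA",
                 gate %||% "<all>"))
    return(tibble::tibble(k = 0L, n = 0L, ratio = NA_real_))
  }
  k <- sum(pos & ingate)
  tibble::tibble(k = k, n = n, ratio = k / n)
}

#' Summarise engraftment section counts
#'
#' Aggregates per-section counts of donor-derived nuclei and fibres from
#' serially sectioned grafted muscles: human LAMIN A/C-positive nuclei
#' inside or outside myofibres and human SPECTRIN-positive fibres, counted
#' on sections at known positions along the muscle. Returns totals per
#' muscle (all sections combined), per-section means, and the mean profile
#' along the muscle.
#'
#' @param sections tibble/data frame with columns `mouse`,
#'   `section_position` (ordered position index or micrometre offset),
#'   `laminAC_in_fibre`, `laminAC_interstitial`, `spectrin_fibres` and
#'   optionally `spectrin_fibres_with_laminAC` plus metadata columns such
#'   as `condition`.
#' @return List of class `myo_engraftment` with tibbles `per_muscle`
#'   (totals and per-section means per mouse) and `profile` (mean per
#'   position across mice, by condition if present).
#' @export
engraftment_summary <- function(sections) {
  req <- c("mouse", "section_position", "laminAC_in_fibre",
           "laminAC_interstitial", "spectrin_fibres")
  missing_cols <- setdiff(req, names(sections))
  if (length(missing_cols)) {
    abort(sprintf("section table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(sections$laminAC_in_fibre < 0) ||
      any(sections$laminAC_interstitial < 0)) {
    abort("engraftment counts must be non-negative")
  }
  sections <- dplyr::mutate(
    sections, laminAC_total = .data$laminAC_in_fibre +
      .data$laminAC_interstitial)
  group_cols <- intersect(c("condition", "mouse"), names(sections))
  per_muscle <- sections |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      laminAC_total = sum(.data$laminAC_total),
      laminAC_in_fibre = sum(.data$laminAC_in_fibre),
      laminAC_interstitial = sum(.data$laminAC_interstitial),
      spectrin_fibres = sum(.data$spectrin_fibres),
      laminAC_per_section = .data$laminAC_total / .data$n_sections,
      spectrin_per_section = .data$spectrin_fibres / .data$n_sections,
      in_fibre_fraction = .data$laminAC_in_fibre /
        pmax(.data$laminAC_total, 1L),
      .groups = "drop")
  prof_cols <- intersect(c("condition", "section_position"), names(sections))
  profile <- sections |>
    dplyr::group_by(dplyr::across(dplyr::all_of(prof_cols))) |>
    dplyr::summarise(
      laminAC_total = mean(.data$laminAC_total),
      laminAC_in_fibre = mean(.data$laminAC_in_fibre),
      spectrin_fibres = mean(.data$spectrin_fibres),
      n_mice = dplyr::n(),
      .groups = "drop")
  structure(list(per_muscle = per_muscle, profile = profile),
            class = "myo_engraftment")
}

#' @export
print.myo_engraftment <- function(x, ...) {
  cat(sprintf("<myo_engraftment> %d muscles, %d profile positions\n",
              nrow(x$per_muscle), nrow(x$profile)))
  print(x$per_muscle)
  invisible(x)
}

#' Full assay summary of one per-cell table
#'
#' Convenience wrapper combining [fusion_index()],
#' [size_class_histogram()] and [marker_fraction()] for each marker
#' column present.
#'
#' @param cells per-cell tibble.
#' @param myhc_marker differentiation marker name.
#' @param gate_marker optional gate for the fusion index.
#' @return One-row tibble with frame metadata (if present), fusion-index
#'   counts, per-class myotube proportions and per-marker fractions.
#' @export
assay_summary <- function(cells, myhc_marker = "MyHC", gate_marker = NULL) {
  fi <- fusion_index(cells, myhc_marker, gate_marker)
  hist <- size_class_histogram(cells, myhc_marker)
  wide_hist <- setNames(as.list(hist$proportion),
                        paste0("prop_", hist$size_class))
  markers <- sub("^marker_", "", grep("^marker_", names(cells), value = TRUE))
  fracs <- list()
  for (m in markers) {
    fracs[[paste0("frac_", m)]] <- marker_fraction(cells, m)$ratio
  }
  meta <- intersect(c("frame_id", "condition", "dose", "group"), names(cells))
  dplyr::bind_cols(
    if (length(meta)) dplyr::distinct(cells[meta])[1, ] else NULL,
    fi, tibble::as_tibble(wide_hist), tibble::as_tibble(fracs))
}
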