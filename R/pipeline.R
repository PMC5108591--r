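#' Validate a set of frames against a channel map
#'
#' Reporting operation (never errors): checks that every frame carries the
#' required channels, that all channels within a frame share dimensions,
#' that frame sizes are consistent across the batch, and that metadata is
#' complete.
#'
#' @param frames list of `myo_frame` objects.
#' @param required_channels channel names every frame must contain.
#' @return Tibble of issues (`frame_id`, `issue`); zero rows when clean.
#' @export
validate_inputs <- function(frames,
                            required_channels = c("dapi", "cyto")) {
  issues <- list()
  note <- function(fid, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(frame_id = fid,
                                                    issue = msg)
  }
  ref_dim <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    fid <- tryCatch(fr$metadata$frame_id[1], error = function(e) NA)
    fid <- if (is.null(fid) || is.na(fid)) paste0("frame_", i) else fid
    missing_ch <- setdiff(required_channels, names(fr$channels))
    for (m in missing_ch) note(fid, sprintf("missing channel '%s'", m))
    dims <- lapply(fr$channels, dim)
    if (length(unique(dims)) > 1) {
      note(fid, "channels within the frame have inconsistent dimensions")
    }
    if (length(dims)) {
      if (is.null(ref_dim)) {
        ref_dim <- dims[[1]]
      } else if (!identical(dims[[1]], ref_dim)) {
        note(fid, sprintf("frame size %s differs from batch size %s",
                          paste(dims[[1]], collapse = "x"),
                          paste(ref_dim, collapse = "x")))
      }
    }
    meta_req <- c("condition", "dose", "group", "frame_id")
    missing_meta <- setdiff(meta_req, names(fr$metadata))
    if (length(missing_meta)) {
      note(fid, sprintf("metadata incomplete: missing %s",
                        paste(missing_meta, collapse = ", ")))
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(frame_id = character(), issue = character())
}

#' Run the simulate - segment - metrics - fit pipeline
#'
#' Executes the enabled stages in order on a configuration (an R list or a
#' YAML file path), writes all stage outputs and a manifest to `out_dir`,
#' and returns the results. Every source of randomness is derived from the
#' single `seed`, so a rerun with the same configuration reproduces the
#' run bit for bit. Any stage error aborts with the stage name; partial
#' outputs are retained next to a `FAILED` marker file.
#'
#' Configuration fields: `seed`; `out_dir`; `stages` (subset of
#' `"simulate"`, `"segment"`, `"metrics"`, `"fit"`); `frames` (list, one
#' entry per frame, each a list of [scene_params()] overrides such as
#' `condition`, `dose`, `group`, `myotube_fraction`); `segment` (list of
#' [segment_frame()] arguments); `metrics` (list: `myhc_marker`,
#' `gate_marker`, `denominator`); `fit` (list of [model_spec()] arguments).
#'
#' @param config list or path to a YAML file.
#' @return Invisibly, a list with `manifest`, `scenes`, `segmentations`,
#'   `summaries` (per-frame assay tibble), `fit` and `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("myoquant_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "segment", "metrics", "fit")
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  res <- list(manifest = list(
    seed = seed, stages = stages,
    config_hash = rlang::hash(config),
    version = as.character(utils::packageVersion("myoquant")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = list()))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), failed_marker)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      frame_cfgs <- config$frames %||% list(list())
      scenes <- vector("list", length(frame_cfgs))
      for (i in seq_along(frame_cfgs)) {
        ov <- frame_cfgs[[i]]
        ov$seed <- ov$seed %||% (seed + i - 1L)
        ov$frame_id <- ov$frame_id %||% sprintf("frame_%03d", i)
        scenes[[i]] <- generate_scene(do.call(scene_params, ov))
        write_truth_csv(scenes[[i]],
                        file.path(out_dir, paste0(ov$frame_id, "_truth.csv")))
        write_frame_tiff(scenes[[i]]$frame,
                         file.path(out_dir, paste0(ov$frame_id, ".tif")))
      }
      res$scenes <<- scenes
      res$manifest$outputs$simulate <<-
        sprintf("%d frames + truth tables", length(scenes))
      invisible(NULL)
    })
  }

  if ("segment" %in% stages) {
    run_stage("segment", function() {
      if (is.null(res$scenes)) abort("segment stage needs simulated frames")
      seg_args <- config$segment %||% list()
      segs <- lapply(res$scenes, function(sc) {
        do.call(segment_frame, c(list(frame = sc$frame), seg_args))
      })
      cells <- dplyr::bind_rows(lapply(seq_along(segs), function(i) {
        dplyr::bind_cols(segs[[i]]$cells, segs[[i]]$metadata)
      }))
      readr::write_csv(cells, file.path(out_dir, "cells.csv"))
      res$segmentations <<- segs
      res$manifest$outputs$segment <<-
        sprintf("%d frames, %d cells", length(segs), nrow(cells))
      invisible(NULL)
    })
  }

  if ("metrics" %in% stages) {
    run_stage("metrics", function() {
      if (is.null(res$segmentations)) abort("metrics stage needs segmentations")
      m <- config$metrics %||% list()
      summaries <- dplyr::bind_rows(lapply(res$segmentations, function(sg) {
        cells <- dplyr::bind_cols(sg$cells, sg$metadata)
        fi <- fusion_index(dplyr::filter(cells, .data$retained),
                           myhc_marker = m$myhc_marker %||% "MyHC",
                           gate_marker = m$gate_marker,
                           denominator = m$denominator %||% "all")
        dplyr::bind_cols(summarise_frame(sg), fi)
      }))
      readr::write_csv(summaries, file.path(out_dir, "frame_summaries.csv"))
      res$summaries <<- summaries
      res$manifest$outputs$metrics <<-
        sprintf("%d frame summaries", nrow(summaries))
      invisible(NULL)
    })
  }

  if ("fit" %in% stages) {
    run_stage("fit", function() {
      if (is.null(res$summaries)) abort("fit stage needs frame metrics")
      fit_cfg <- config$fit %||%
        list(response_kind = "binomial_grouped",
             response = c(successes = "fused_nuclei",
                          trials = "total_nuclei"),
             factors = "condition")
      if (!is.null(names(fit_cfg$response))) {
        fit_cfg$response <- unlist(fit_cfg$response)
      }
      spec <- do.call(model_spec, fit_cfg)
      fit <- fit_model(res$summaries, spec)
      report <- effect_report(fit)
      readr::write_csv(tidy(fit), file.path(out_dir, "coefficients.csv"))
      jsonlite::write_json(
        list(terms = report$terms, conditions = report$conditions),
        file.path(out_dir, "effect_report.json"),
        dataframe = "rows", digits = NA)
      res$fit <<- fit
      res$report <<- report
      res$manifest$outputs$fit <<-
        sprintf("%s with %d coefficients", class(fit)[1],
                length(fit$coefficients))
      invisible(NULL)
    })
  }

  res$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$out_dir <- out_dir
  invisible(res)
}
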