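#' Pipeline configuration
#'
#' Bundles every tunable of the per-subject analysis so a run is fully
#' described by (inputs, config, seed). Round-trips losslessly through
#' JSON via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param threshold_factor relative-median defect threshold (default 0.70).
#' @param bands respiratory/cardiac search bands, see [default_bands()].
#' @param pencil_L,order,sv_tol,max_order matrix-pencil parameters (see
#'   [matrix_pencil_decompose()]); `pencil_L = NULL` selects the
#'   per-signal default.
#' @param freq_tol component-matching half-width in Hz.
#' @param ddi_radius defect distribution index radius in voxels.
#' @param register logical; run translation-based motion compensation.
#' @param seed integer seed covering all randomness of a run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_factor = 0.70, bands = default_bands(),
                            pencil_L = NULL, order = NULL, sv_tol = 1e-3,
                            max_order = 16, freq_tol = 0.1, ddi_radius = 3,
                            register = TRUE, seed = 1L) {
  if (threshold_factor <= 0 || threshold_factor > 1)
    stop_config("threshold_factor", "must lie in (0, 1]")
  if (bands$resp[2] > bands$card[1])
    stop_config("bands", "respiratory band must end at or below the cardiac band")
  assert_positive(freq_tol, "freq_tol")
  assert_positive(ddi_radius, "ddi_radius")
  assert_positive(sv_tol, "sv_tol")
  structure(list(threshold_factor = threshold_factor, bands = bands,
                 pencil_L = pencil_L, order = order, sv_tol = sv_tol,
                 max_order = as.integer(max_order),
                 freq_tol = freq_tol, ddi_radius = ddi_radius,
                 register = isTRUE(register), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(threshold_factor = x$threshold_factor,
                  bands = lapply(x$bands, as.numeric),
                  pencil_L = x$pencil_L, order = x$order,
                  sv_tol = x$sv_tol, max_order = x$max_order,
                  freq_tol = x$freq_tol,
                  ddi_radius = x$ddi_radius, register = x$register,
                  seed = x$seed)
}

#' Content hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every output
#' file so results from different configurations cannot be mixed
#' silently.
#' @param config a [pipeline_config()].
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a phantom to disk
#'
#' Emits the series as 4D NIfTI `(x, y, slice, time)` with a JSON sidecar
#' (`frame_rate_hz`, `voxel_size_mm`, `f_resp_true`, `f_card_true`), the
#' side-labelled mask as NIfTI (0 = background, 1 = right lung, 2 = left
#' lung, 3 = heart), the scalar ground truth as JSON, and the true
#' amplitude fields and planted defect masks as NIfTI.
#'
#' @param phantom result of [generate_phantom_series()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of written paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  pix <- c(phantom$series$voxel_size, 1 / phantom$series$frame_rate)
  RNifti::writeNifti(RNifti::asNifti(phantom$series$data, pixdim = pix),
                     p("series.nii.gz"))
  jsonlite::write_json(list(frame_rate_hz = phantom$series$frame_rate,
                            voxel_size_mm = phantom$series$voxel_size,
                            f_resp_true = phantom$truth$f_resp,
                            f_card_true = phantom$truth$f_card),
                       p("series.json"), auto_unbox = TRUE, digits = NA)
  RNifti::writeNifti(RNifti::asNifti(phantom$mask$labels,
                                     pixdim = phantom$series$voxel_size),
                     p("mask.nii.gz"))
  tr <- phantom$truth
  jsonlite::write_json(
    list(true_defect_fraction_by_side = tr$true_defect_fraction_by_side,
         f_resp = tr$f_resp, f_card = tr$f_card, phases = as.list(tr$phases),
         s0 = tr$s0, shifts_dy = tr$shifts[, 1]),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  for (nm in c("resp_amplitude", "card_amplitude")) {
    x <- tr[[nm]]; x[is.na(x)] <- 0
    RNifti::writeNifti(RNifti::asNifti(x), p(paste0("truth_", nm, ".nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(tr$defect_mask_v + 0L),
                     p("truth_defect_v.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(tr$defect_mask_q + 0L),
                     p("truth_defect_q.nii.gz"))
  invisible(list(series = p("series.nii.gz"), sidecar = p("series.json"),
                 mask = p("mask.nii.gz"), truth = p("truth.json")))
}

#' Read a dynamic series from NIfTI (+ JSON sidecar)
#'
#' @param path 4D NIfTI file `(x, y, slice, time)`.
#' @param sidecar JSON sidecar path carrying `frame_rate_hz` and
#'   `voxel_size_mm`; defaults to `<path minus .nii(.gz)>.json`.
#' @return a [dynamic_series()].
#' @export
read_dynamic_series <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("series file not found: %s", path))
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("series NIfTI must be 4D")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fr <- meta$frame_rate_hz
    vs <- as.numeric(meta$voxel_size_mm)
  } else {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4 || pd[4] <= 0)
      stop("no JSON sidecar and no usable time step in the NIfTI header")
    fr <- 1 / pd[4]
    vs <- pd[1:3]
  }
  dynamic_series(array(as.numeric(img), dim(img)), frame_rate = fr,
                 voxel_size = vs)
}

#' Read a side-labelled lung mask from NIfTI
#'
#' @param path mask NIfTI (labels 0/1/2/3).
#' @return a [lung_mask()].
#' @export
read_lung_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  lung_mask(array(as.integer(round(img)), dim(img)))
}

flatten_metrics <- function(metrics, id = "subject", group = NA_character_) {
  m <- metrics
  row <- data.frame(id = id, group = group, hernia_side = m$hernia_side,
                    vdp_pct = m$vdp, qdp_pct = m$qdp, vqd_pct = m$vqd_match,
                    ddi_v = m$ddi_v, ddi_q = m$ddi_q,
                    stringsAsFactors = FALSE)
  nm <- names(m$vdp_side)
  suffix <- if (identical(nm, c("affected", "non_affected")))
    c("_aff", "_nonaff") else c("_left", "_right")
  for (i in 1:2) {
    row[[paste0("vdp", suffix[i])]] <- m$vdp_side[[i]]
    row[[paste0("qdp", suffix[i])]] <- m$qdp_side[[i]]
    row[[paste0("vqd", suffix[i])]] <- m$vqd_side[[i]]
    row[[paste0("ddi_v", suffix[i])]] <- m$ddi_v_side[[i]]
    row[[paste0("ddi_q", suffix[i])]] <- m$ddi_q_side[[i]]
  }
  row$n_lung_voxels <- m$counts$lung
  row$n_v_defect <- m$counts$v_defect
  row$n_q_defect <- m$counts$q_defect
  row
}

#' Run the per-subject analysis pipeline
#'
#' Executes the full chain on one subject: baseline selection and
#' translation-based motion compensation, cardinal-frequency estimation,
#' voxel-wise matrix-pencil mapping, slice-wise relative-median defect
#' masking, and defect quantification. Inputs may be in-memory objects
#' or file paths (NIfTI series + sidecar, NIfTI mask, JSON metadata).
#' When no mask is given the fallback intensity segmentation is used.
#'
#' @param series a [dynamic_series()] or NIfTI path.
#' @param mask a [lung_mask()], NIfTI path, or `NULL` for the fallback
#'   segmentation.
#' @param meta list (or JSON path) with optional `id`, `group`,
#'   `hernia_side`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes the
#'   functional maps and defect masks (NIfTI), the metrics (CSV + JSON)
#'   and a provenance manifest (JSON with the config hash).
#' @return list with `metrics` ([compute_defect_metrics()] result),
#'   `maps`, `freqs`, `v_defect`, `q_defect`, `baseline`, `series`
#'   (registered) and `mask`.
#' @export
run_subject <- function(series, mask = NULL, meta = list(),
                        config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(series)) series <- read_dynamic_series(series)
  if (is.character(mask)) mask <- read_lung_mask(mask)
  if (is.character(meta)) meta <- jsonlite::read_json(meta,
                                                      simplifyVector = TRUE)
  hernia_side <- meta$hernia_side %||% "none"
  if (is.na(hernia_side)) hernia_side <- "none"
  if (is.null(mask)) {
    message("no mask supplied; running fallback lung segmentation")
    mask <- segment_lungs_fallback(series_mean_image(series))
  }
  if (!identical(dim(series$data)[1:3], dim(mask$labels)))
    stop("[preprocess] mask grid does not match the series grid")

  baseline <- select_baseline_frame(series, mask)
  if (config$register && !series$registered) {
    series <- register_translation(series, baseline)
  } else if (!series$registered) {
    series$registered <- TRUE  # caller vouches for pre-registered input
  }
  freqs <- tryCatch(
    estimate_cardinal_frequencies(series, mask, config$bands,
                                  config$pencil_L, config$order,
                                  config$sv_tol, config$max_order),
    error = function(e) stop("[mp_spectral] ", conditionMessage(e),
                             call. = FALSE))
  maps <- compute_functional_maps(series, mask, freqs, config$freq_tol,
                                  config$pencil_L, config$order,
                                  config$sv_tol, config$max_order)
  v_defect <- defect_mask(maps$fv, mask, config$threshold_factor)
  q_defect <- defect_mask(maps$q, mask, config$threshold_factor)
  metrics <- compute_defect_metrics(v_defect, q_defect, mask, hernia_side,
                                    config$ddi_radius)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    for (nm in c("fv", "q")) {
      x <- maps[[nm]]; x[is.na(x)] <- 0
      RNifti::writeNifti(RNifti::asNifti(x), p(paste0("map_", nm, ".nii.gz")))
    }
    RNifti::writeNifti(RNifti::asNifti(v_defect + 0L), p("defect_v.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(q_defect + 0L), p("defect_q.nii.gz"))
    hash <- config_hash(config)
    row <- flatten_metrics(metrics, meta$id %||% "subject",
                           meta$group %||% NA_character_)
    row$config_hash <- hash
    write.csv(row, p("metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(metrics = unclass(metrics)[c("vdp", "qdp", "vqd_match",
                                        "vdp_side", "qdp_side", "vqd_side",
                                        "ddi_v", "ddi_q", "ddi_v_side",
                                        "ddi_q_side", "counts")],
           f_resp = freqs$f_resp, f_card = freqs$f_card,
           baseline_frame = baseline, config = unclass(config),
           config_hash = hash,
           software_version = as.character(packageVersion("mplung"))),
      p("metrics.json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(metrics = metrics, maps = maps, freqs = freqs, v_defect = v_defect,
       q_defect = q_defect, baseline = baseline, series = series,
       mask = mask)
}

known_side_outcomes <- c("vdp", "qdp", "vqd", "ddi_v", "ddi_q")

#' Run the cohort statistics stage
#'
#' Reproduces the group-level analysis design on a cohort table: per
#' whole-lung outcome a one-way ANOVA with the configured post-hoc
#' procedure; per per-side outcome a mixed repeated-measures ANOVA
#' (group x side) with Bonferroni-adjusted paired side contrasts; and a
#' Spearman/Benjamini-Hochberg correlation screen of lung-function
#' against affected-side imaging outcomes. In summary mode the input is
#' a `(group, outcome, mean, sd, n)` table of printed group summaries
#' and only the between-group stage runs.
#'
#' @param table cohort data frame or CSV path (one row per subject), or
#'   in summary mode a long summary data frame / CSV.
#' @param summary_mode logical.
#' @param methods named character vector mapping outcome to post-hoc
#'   method (default [default_posthoc_methods()]).
#' @param out_dir optional directory for result CSVs.
#' @return list with `overall` (per outcome: `anova`, `posthoc`), `side`
#'   (per outcome: `anova`, `posthoc`) and `correlations`.
#' @export
run_cohort <- function(table, summary_mode = FALSE,
                       methods = default_posthoc_methods(),
                       out_dir = NULL) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  if ("config_hash" %in% names(table) &&
      length(unique(table$config_hash)) > 1L)
    stop("refusing to mix metrics produced under different pipeline configs")

  overall <- list()
  if (summary_mode) {
    need <- c("group", "outcome", "mean", "sd", "n")
    miss <- setdiff(need, names(table))
    if (length(miss))
      stop("summary table lacks columns: ", paste(miss, collapse = ", "))
    for (oc in unique(table$outcome)) {
      sub <- table[table$outcome == oc, , drop = FALSE]
      gs <- group_summary(sub$group, sub$mean, sub$sd, sub$n)
      if (nrow(gs) < 2) stop("between-group analysis needs at least 2 groups")
      overall[[oc]] <- list(
        anova = one_way_anova(gs),
        posthoc = posthoc_all_pairs(gs, methods[[oc]] %||% "tukey_kramer"))
    }
    res <- list(overall = overall, side = NULL, correlations = NULL)
  } else {
    if (!"group" %in% names(table))
      stop("cohort table lacks columns: group")
    if (length(unique(as.character(table$group))) < 2)
      stop("between-group analysis needs at least 2 groups")
    outcomes <- intersect(names(methods), names(table))
    if (length(outcomes) == 0)
      stop("cohort table lacks columns: ",
           paste(names(methods), collapse = ", "))
    for (oc in outcomes) {
      gs <- summarize_groups(table, oc)
      overall[[oc]] <- list(anova = one_way_anova(table, oc),
                            posthoc = posthoc_all_pairs(gs, methods[[oc]]))
    }
    side <- list()
    for (oc in known_side_outcomes) {
      if (!all(side_cols(oc) %in% names(table))) next
      side[[oc]] <- list(anova = mixed_anova_group_side(table, oc),
                         posthoc = bonferroni_side_posthoc(table, oc))
    }
    lf <- intersect(c("fev1_z", "fvc_z", "rv_tlc_pct", "lci2_5_TO"),
                    names(table))
    im <- intersect(c("vdp_aff", "qdp_aff", "vqd_aff"), names(table))
    correlations <- if (length(lf) && length(im)) {
      patients <- table[as.character(table$group) != "control", ,
                        drop = FALSE]
      spearman_bh(patients, lf, im)
    } else NULL
    res <- list(overall = overall, side = if (length(side)) side else NULL,
                correlations = correlations)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ov <- do.call(rbind, lapply(names(res$overall), function(oc)
      cbind(outcome = oc, res$overall[[oc]]$posthoc)))
    write.csv(ov, file.path(out_dir, "overall_posthoc.csv"),
              row.names = FALSE)
    if (!is.null(res$side)) {
      sd_tab <- do.call(rbind, lapply(names(res$side), function(oc)
        cbind(outcome = oc, res$side[[oc]]$posthoc)))
      write.csv(sd_tab, file.path(out_dir, "side_posthoc.csv"),
                row.names = FALSE)
    }
    if (!is.null(res$correlations))
      write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
  }
  res
}
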