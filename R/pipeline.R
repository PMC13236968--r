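#' Pipeline configuration
#'
#' Central home for all tunables, echoed into every report for provenance.
#' Ratios are relative to the eyebrow height `h` measured from the baseline
#' landmarks.
#'
#' @param margin ROI margin (px, in the resized detection frame).
#' @param resized_width detector frame width (px).
#' @param delta_ratio trimap vertical-expansion ratio (default 0.30).
#' @param trimap_dilate_ratio trimap safety-dilation ratio (default 0.10).
#' @param fg_core_ratio optional definite-foreground erosion ratio
#'   (default 0: whole hull is "unknown").
#' @param tau binarization threshold on the 8-bit probability map.
#' @param kernel_open_ratio,kernel_dilate_ratio morphological kernel ratios.
#' @param tau_dist_ratio,tau_area_ratio component-retention ratios
#'   (distance vs `h`, area vs `h^2`).
#' @param backend matting backend id or plugin function.
#' @param robust enable consensus outlier rejection in fine registration.
#' @param regenerate_trimaps regenerate the trimap from each capture's own
#'   landmarks and propagate it through the registration chain (ablation of
#'   the default baseline-referenced strategy).
#' @param icc_stack how sessions are stacked into the ICC subject dimension:
#'   `"timepoint_eye"` (default, pooled) or `"timepoint"` (combined eyes).
#' @param seed RNG seed for the consensus sampling.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(margin = 10, resized_width = 600,
                            delta_ratio = 0.30, trimap_dilate_ratio = 0.10,
                            fg_core_ratio = 0, tau = 1,
                            kernel_open_ratio = 0.05,
                            kernel_dilate_ratio = 0.07,
                            tau_dist_ratio = 0.50, tau_area_ratio = 0.01,
                            backend = "baseline", robust = TRUE,
                            regenerate_trimaps = FALSE,
                            icc_stack = c("timepoint_eye", "timepoint"),
                            seed = 1) {
  icc_stack <- match.arg(icc_stack)
  structure(as.list(environment()), class = "pipeline_config")
}

retention_params_cfg <- function(h, config) {
  p <- retention_params(h)
  p$tau_dist <- config$tau_dist_ratio * h
  p$tau_area <- config$tau_area_ratio * h^2
  p$kernel_open <- odd_size(config$kernel_open_ratio * h)
  p$kernel_dilate <- odd_size(config$kernel_dilate_ratio * h)
  p
}

#' Run the full quantification pipeline on a session
#'
#' End-to-end per capture and eye: landmarks -> margin-expanded ROI ->
#' baseline-referenced luminance normalization -> two-stage registration to
#' the baseline capture -> trimap-guided segmentation in the shared baseline
#' frame -> morphological post-processing and component retention ->
#' foreground pixel area. Densities are expressed as percent of the mean
#' baseline (T1) area; repeatability statistics (intra-session Std,
#' ICC(2,1), SEM, MDC) are computed over the replicate captures.
#' Deterministic for a fixed config and seed.
#'
#' @param session a `synthetic_session`, or a session directory path laid
#'   out as described in [write_session()].
#' @param config a [pipeline_config()].
#' @param keep_intermediates if a directory path, per-stage intermediates
#'   (registered ROIs, trimaps, probability maps, masks, homography chains)
#'   are written under it.
#' @return a `session_report` list; see [write_report()].
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         keep_intermediates = NULL) {
  if (is.character(session)) session <- read_session(session)
  set.seed(config$seed)
  topo <- session$topology
  tps <- session$timepoints
  if (!"T1" %in% names(tps)) stop("missing baseline timepoint T1")
  ref_cap <- tps[["T1"]]$captures[[1]]
  warnings_log <- character(0)

  eye_results <- vector("list", 2)
  for (eye in 1:2) {
    m_eff <- effective_margin(ref_cap$landmarks, config)
    ref_roi <- extract_roi(ref_cap$landmarks, eye, m_eff, ref_cap$image, topo)
    geom <- eyebrow_geometry(ref_cap$landmarks, eye, topo)
    h <- geom$height
    photo_ref <- compute_reference(ref_roi$raster)
    ref_norm <- normalize_luminance(ref_roi$raster, photo_ref)
    brow_local <- to_local(geom$polygon, ref_roi$box)
    tm_base <- make_trimap(brow_local, h, dim(ref_norm)[1:2],
                           delta_ratio = config$delta_ratio,
                           dilate_ratio = config$trimap_dilate_ratio,
                           fg_core_ratio = config$fg_core_ratio)
    params <- retention_params_cfg(h, config)
    ref_lm_local <- to_local(lm_subset(ref_cap$landmarks,
                                       topo$periocular[[eye]]), ref_roi$box)

    rows <- list()
    for (tn in names(tps)) {
      for (ci in seq_along(tps[[tn]]$captures)) {
        cap <- tps[[tn]]$captures[[ci]]
        is_ref <- identical(tn, "T1") && ci == 1L
        res <- tryCatch(
          process_capture(cap, eye, topo, config, m_eff, ref_roi, ref_norm,
                          ref_lm_local, photo_ref, tm_base, params, is_ref,
                          keep_intermediates, tn, ci),
          error = function(e) e)
        if (inherits(res, "error")) {
          warnings_log <- c(warnings_log, sprintf(
            "eye %d %s capture %d failed: %s", eye, tn, ci,
            conditionMessage(res)))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          eye = eye, timepoint = tn, capture = ci, area = res$area,
          rmse_coarse = res$rmse_coarse, rmse_fine = res$rmse_fine,
          fine_fallback = res$fine_fallback, offset = res$offset)
      }
    }
    eye_results[[eye]] <- do.call(rbind, rows)
  }
  measurements <- do.call(rbind, eye_results)
  report <- build_report(measurements, config, session, warnings_log)
  report
}

effective_margin <- function(lms, config) {
  if (lms$frame == "resized") config$margin
  else config$margin * (lms$width / config$resized_width)
}

process_capture <- function(cap, eye, topo, config, m_eff, ref_roi, ref_norm,
                            ref_lm_local, photo_ref, tm_base, params, is_ref,
                            keep_intermediates, tn, ci) {
  roi <- extract_roi(cap$landmarks, eye, m_eff, cap$image, topo)
  norm <- normalize_luminance(roi$raster, photo_ref)
  offset <- attr(norm, "offset")
  if (is_ref) {
    registered <- ref_norm
    rmse_coarse <- 0; rmse_fine <- 0; fine_fallback <- FALSE
    chain <- NULL
    tm <- tm_base
  } else {
    lm_local <- to_local(lm_subset(cap$landmarks, topo$periocular[[eye]]),
                         roi$box)
    chain <- register_two_stage(norm, ref_norm, lm_local, ref_lm_local,
                                robust = config$robust)
    registered <- chain$registered
    rmse_coarse <- chain$rmse_coarse
    rmse_fine <- chain$rmse_fine
    fine_fallback <- chain$fine_fallback
    if (config$regenerate_trimaps) {
      geom_t <- eyebrow_geometry(cap$landmarks, eye, topo)
      tm_t <- make_trimap(to_local(geom_t$polygon, roi$box), geom_t$height,
                          dim(norm)[1:2],
                          delta_ratio = config$delta_ratio,
                          dilate_ratio = config$trimap_dilate_ratio,
                          fg_core_ratio = config$fg_core_ratio)
      tm <- propagate_trimap(tm_t, chain$H_total, dim(ref_norm)[1:2])
    } else {
      # baseline-referenced strategy: segmentation happens in the baseline
      # frame, where the T1 trimap applies directly
      tm <- trimap(tm_base$mask, delta = tm_base$delta,
                   provenance = "propagated")
    }
    # restrict the trimap to pixels observed in this capture's ROI
    msk <- tm$mask; msk[!chain$valid] <- TRIMAP_BG
    tm <- trimap(msk, delta = tm$delta, provenance = "propagated")
  }
  p <- segment_hair(registered, tm, backend = config$backend)
  post <- postprocess_mask(prob_to_gray8(p), params, tau = config$tau)
  if (is.character(keep_intermediates)) {
    d <- file.path(keep_intermediates, sprintf("eye%d_%s_cap%d", eye, tn, ci))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_image(registered, file.path(d, "registered.png"))
    write_trimap(tm, file.path(d, "trimap.png"))
    write_probability_map(p, file.path(d, "probability.png"))
    png::writePNG(post$mask, file.path(d, "mask_opt.png"))
    write_component_table(post$table, file.path(d, "components.csv"))
    if (!is.null(chain)) write_homography_chain(chain, file.path(d, "homography.json"))
  }
  list(area = pixel_area(post$mask), offset = offset,
       rmse_coarse = rmse_coarse, rmse_fine = rmse_fine,
       fine_fallback = fine_fallback)
}

build_report <- function(meas, config, session, warnings_log) {
  tp_names <- names(session$timepoints)
  # per-eye and combined retained series, baseline = mean of T1 captures
  series <- list()
  for (eye in 1:2) {
    sub <- meas[meas$eye == eye, ]
    a_ref <- mean(sub$area[sub$timepoint == "T1"])
    sub$retained <- 100 * sub$area / a_ref
    sub$delta <- 100 - sub$retained
    series[[paste0("eye", eye)]] <- sub
  }
  comb <- merge(series$eye1[, c("timepoint", "capture", "area")],
                series$eye2[, c("timepoint", "capture", "area")],
                by = c("timepoint", "capture"), suffixes = c("_e1", "_e2"))
  comb$area <- comb$area_e1 + comb$area_e2
  a_ref_c <- mean(comb$area[comb$timepoint == "T1"])
  comb$retained <- 100 * comb$area / a_ref_c
  comb$delta <- 100 - comb$retained
  comb <- comb[order(match(comb$timepoint, tp_names), comb$capture), ]

  summarize <- function(df) {
    out <- lapply(tp_names, function(tn) {
      r <- df$retained[df$timepoint == tn]
      list(timepoint = tn, n = length(r),
           retained_mean = mean(r), delta_mean = 100 - mean(r),
           std = if (length(r) >= 2) intra_session_std(r) else NULL)
    })
    names(out) <- tp_names
    out
  }

  stack <- if (config$icc_stack == "timepoint_eye") {
    rows <- list()
    for (eye in 1:2) for (tn in tp_names) {
      r <- series[[paste0("eye", eye)]]
      rows[[paste0("e", eye, "_", tn)]] <-
        r$retained[r$timepoint == tn][order(r$capture[r$timepoint == tn])]
    }
    rows
  } else {
    lapply(stats::setNames(tp_names, tp_names),
           function(tn) comb$retained[comb$timepoint == tn])
  }
  k <- min(lengths(stack))
  repeatability <- if (length(stack) >= 2 && k >= 2) {
    mstack <- do.call(rbind, lapply(stack, function(x) x[seq_len(k)]))
    tryCatch(repeatability_stats(mstack), error = function(e) NULL)
  } else NULL

  structure(list(
    patient = session$patient,
    config = unclass(config)[!vapply(unclass(config), is.function, logical(1))],
    timepoints = tp_names,
    measurements = list(eye1 = series$eye1, eye2 = series$eye2,
                        combined = comb),
    summary = list(eye1 = summarize(series$eye1),
                   eye2 = summarize(series$eye2),
                   combined = summarize(comb)),
    repeatability = if (is.null(repeatability)) NULL else list(
      stacking = config$icc_stack,
      std_per_row = as.list(repeatability$std),
      std_pooled = repeatability$std_pooled,
      icc = repeatability$icc, sem = repeatability$sem,
      mdc = repeatability$mdc),
    registration = list(
      rmse_coarse_mean = mean(meas$rmse_coarse[meas$rmse_coarse > 0]),
      rmse_coarse_max = max(meas$rmse_coarse),
      rmse_fine_mean = mean(meas$rmse_fine[meas$rmse_coarse > 0], na.rm = TRUE),
      rmse_fine_max = if (all(is.na(meas$rmse_fine))) NA_real_
                      else max(meas$rmse_fine, na.rm = TRUE),
      n_fine_fallbacks = sum(meas$fine_fallback)),
    warnings = warnings_log
  ), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report: patient %s, %d timepoints>\n",
              x$patient, length(x$timepoints)))
  for (tn in x$timepoints) {
    s <- x$summary$combined[[tn]]
    cat(sprintf("  %s: retained %.2f%% (Std %s, n=%d)\n", tn, s$retained_mean,
                if (is.null(s$std)) "NA" else sprintf("%.2f", s$std), s$n))
  }
  if (!is.null(x$repeatability))
    cat(sprintf("  ICC(2,1)=%.3f  SEM=%.2f%%  MDC=%.2f%%\n",
                x$repeatability$icc, x$repeatability$sem, x$repeatability$mdc))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Write the machine-readable session report
#'
#' JSON at full precision (plus CSV mirrors of the per-capture tables when
#' `csv = TRUE`). Contains no timestamps, so identical runs produce
#' byte-identical files.
#'
#' @param report a `session_report`.
#' @param path output JSON path.
#' @param csv also write `<path>_measurements.csv`.
#' @export
write_report <- function(report, path, csv = FALSE) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (csv) {
    base <- sub("\\.json$", "", path)
    utils::write.csv(do.call(rbind, report$measurements[c("eye1", "eye2")]),
                     paste0(base, "_measurements.csv"), row.names = FALSE)
  }
  invisible(path)
}
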