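# Variant letter <-> (DN, CL, GSR) toggle mapping for the seven standard
# processing variants; the fixed stages (slice timing, smoothing,
# high-pass) are always on.
variant_table <- data.frame(
  variant = LETTERS[1:7],
  dn  = c(FALSE, FALSE, FALSE, TRUE,  TRUE,  TRUE,  TRUE),
  cl  = c(FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, TRUE),
  gsr = c(FALSE, TRUE,  TRUE,  FALSE, FALSE, TRUE,  TRUE),
  stringsAsFactors = FALSE
)

#' Pipeline variant toggles
#'
#' Maps a variant letter A-G to its (denoise, clean, GSR) toggle triple
#' and back. A is the baseline (slice timing + smoothing + high-pass
#' only); G enables all three optional stages.
#'
#' @param variant Letter in `A`..`G`.
#' @return Named logical vector `c(dn, cl, gsr)`.
#' @export
variant_toggles <- function(variant) {
  row <- variant_table[variant_table$variant == toupper(variant), ]
  if (nrow(row) != 1) stop("unknown pipeline variant: ", variant)
  c(dn = row$dn, cl = row$cl, gsr = row$gsr)
}

#' @rdname variant_toggles
#' @param dn,cl,gsr Logical stage toggles.
#' @export
variant_letter <- function(dn, cl, gsr) {
  hit <- variant_table$dn == dn & variant_table$cl == cl &
    variant_table$gsr == gsr
  variant_table$variant[hit]
}

#' Pipeline configuration
#'
#' @param dn,cl,gsr Optional-stage toggles (MP-PCA denoising, ICA-based
#'   cleaning, global-signal partial correlation).
#' @param kernel MP-PCA kernel width.
#' @param slice_order,ref_slice Slice-timing parameters (defaults:
#'   ascending order, middle reference slice).
#' @param fwhm Smoothing FWHM in mm per axis.
#' @param cutoff High-pass cutoff in Hz.
#' @param n_components ICA model order (used when `cl` is on).
#' @param fix_threshold Classifier threshold for automatic cleaning.
#' @param clean_mode `"aggressive"` or `"soft"`.
#' @param seed Integer seed (ICA initialization).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dn = TRUE, cl = TRUE, gsr = TRUE, kernel = 5,
                            slice_order = NULL, ref_slice = NULL,
                            fwhm = c(0.36, 0.36, 1.0), cutoff = 0.01,
                            n_components = 40, fix_threshold = 45,
                            clean_mode = "aggressive", seed = 1L) {
  structure(list(dn = dn, cl = cl, gsr = gsr, kernel = kernel,
                 slice_order = slice_order, ref_slice = ref_slice,
                 fwhm = fwhm, cutoff = cutoff, n_components = n_components,
                 fix_threshold = fix_threshold, clean_mode = clean_mode,
                 seed = as.integer(seed),
                 variant = variant_letter(dn, cl, gsr)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return A [pipeline_config()] (read) or `path` (write).
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config,
          raw[intersect(names(raw), setdiff(names(formals(pipeline_config)),
                                            ""))])
}

#' @rdname read_pipeline_config
#' @param cfg A [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null,
                                            logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full processing pipeline on one subject scan
#'
#' Stage order: optional MP-PCA denoising, slice-timing correction,
#' spatial smoothing, high-pass filtering, then (when cleaning is on)
#' spatial ICA + classifier-driven artifact regression, ROI extraction,
#' FC (global-signal partial correlation when GSR is on, full correlation
#' otherwise) and the Fisher z-transform. The global signal is computed
#' from the cleaned series.
#'
#' @param scan A [subject_scan()] (or bare [bold_series()]).
#' @param labels A [label_volume()].
#' @param mask A [brain_mask()].
#' @param cfg A [pipeline_config()].
#' @param classifier A trained [train_classifier()] model; required when
#'   `cfg$cl` is on.
#' @return List with `z` (z-space `fc_matrix`), `qc` (per-stage log:
#'   variant, sigma/tSNR summaries, artifact indices, clip counts).
#' @export
run_subject <- function(scan, labels, mask, cfg, classifier = NULL) {
  series <- if (inherits(scan, "subject_scan")) scan$series else scan
  stopifnot(inherits(series, "bold_series"), inherits(cfg, "pipeline_config"))
  if (cfg$cl && is.null(classifier))
    stop("cleaning (CL) is enabled but no classifier model was given")
  qc <- list(variant = cfg$variant, seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (cfg$dn) {
    dn <- stage("denoise", mppca_denoise(series, mask, kernel = cfg$kernel))
    qc$sigma_median <- stats::median(dn$sigma_map, na.rm = TRUE)
    qc$tsnr_before <- tsnr(series, mask)$mean_tsnr
    qc$tsnr_after <- tsnr(dn$denoised, mask)$mean_tsnr
    series <- dn$denoised
  }
  series <- stage("slice_timing",
                  slice_timing_correct(series, cfg$slice_order, cfg$ref_slice))
  series <- stage("smooth", smooth_series(series, cfg$fwhm))
  series <- stage("highpass", highpass(series, cfg$cutoff))
  if (cfg$cl) {
    cs <- stage("ica", spatial_ica(series, mask,
                                   n_components = min(cfg$n_components,
                                                      series$n_frames - 1L),
                                   seed = cfg$seed))
    feats <- stage("features", extract_features(cs, mask, tr_vol = series$tr_vol))
    cls <- stage("classify",
                 classify_components(classifier, feats, cfg$fix_threshold))
    qc$artifact_idx <- cls$artifact_idx
    qc$n_components <- cs$n_components
    qc$explained_variance <- cs$explained_variance
    series <- stage("clean",
                    clean_series(series, cs, cls$artifact_idx, cfg$clean_mode))
  }
  ts <- stage("roi_extract", extract_roi_timeseries(series, labels, mask))
  fc <- if (cfg$gsr) {
    gs <- stage("global_signal", global_signal(series, mask))
    stage("fc", fc_partial_gsr(ts, gs))
  } else {
    stage("fc", fc_full(ts))
  }
  z <- fisher_z(fc)
  qc$n_clipped <- z$n_clipped
  qc$dropped_rois <- ts$dropped
  list(z = z, qc = qc)
}

#' Evaluate processing variants on a cohort
#'
#' Runs each requested variant on every scan, then reports the
#' within-group variability of the control group per timepoint and,
#' when both groups are present, the NBS comparison per timepoint.
#' Runs belonging to the same subject and timepoint are averaged in
#' z-space before group statistics.
#'
#' @param cohort List of [subject_scan()].
#' @param labels,mask Shared [label_volume()] / [brain_mask()].
#' @param variants Character vector of variant letters (subset of A-G).
#' @param cfg Base [pipeline_config()] supplying stage parameters.
#' @param classifier Trained classifier (needed for variants with CL).
#' @param nbs_threshold,nbs_n_perm NBS parameters used when both groups
#'   are present.
#' @return An object of class `variant_report`: `variability`
#'   (data.frame: variant, timepoint, ctl_variability), `nbs` (nested
#'   list), `z` (per-variant list of subject z matrices).
#' @export
evaluate_variants <- function(cohort, labels, mask, variants, cfg,
                              classifier = NULL, nbs_threshold = 2.2,
                              nbs_n_perm = 1000) {
  bad <- setdiff(toupper(variants), variant_table$variant)
  if (length(bad)) stop("unknown pipeline variant: ", paste(bad, collapse = ", "))
  groups <- vapply(cohort, `[[`, character(1), "group")
  tps <- vapply(cohort, function(s) s$timepoint, numeric(1))
  subj <- vapply(cohort, `[[`, character(1), "subject_id")
  if (sum(groups == "CTL") < 2) stop("need >= 2 control subjects")
  var_rows <- list()
  nbs_out <- list()
  z_out <- list()
  want <- toupper(variants)
  toggles <- lapply(want, variant_toggles)
  names(toggles) <- want
  need_dn <- any(vapply(toggles, `[[`, logical(1), "dn"))
  need_raw <- any(!vapply(toggles, `[[`, logical(1), "dn"))
  # shared-stage cache: denoising and ICA are computed once per subject and
  # reused by every variant that needs them
  prep <- lapply(cohort, function(s) {
    out <- list()
    fixed <- function(x) highpass(smooth_series(
      slice_timing_correct(x, cfg$slice_order, cfg$ref_slice), cfg$fwhm),
      cfg$cutoff)
    if (need_dn)
      out$dn <- fixed(mppca_denoise(s$series, mask, cfg$kernel)$denoised)
    if (need_raw) out$raw <- fixed(s$series)
    for (nm in names(out)) {
      if (any(vapply(toggles, function(t) t[["cl"]] == TRUE &&
                       t[["dn"]] == (nm == "dn"), logical(1)))) {
        cs <- spatial_ica(out[[nm]], mask,
                          n_components = min(cfg$n_components,
                                             out[[nm]]$n_frames - 1L),
                          seed = cfg$seed)
        feats <- extract_features(cs, mask, tr_vol = out[[nm]]$tr_vol)
        art <- classify_components(classifier, feats,
                                   cfg$fix_threshold)$artifact_idx
        out[[paste0(nm, "_clean")]] <-
          clean_series(out[[nm]], cs, art, cfg$clean_mode)
      }
    }
    out
  })
  fc_of <- function(series, gsr) {
    ts <- suppressWarnings(extract_roi_timeseries(series, labels, mask))
    fc <- if (gsr) fc_partial_gsr(ts, global_signal(series, mask))
          else fc_full(ts)
    fisher_z(fc)$m
  }
  for (v in want) {
    tg <- toggles[[v]]
    if (tg[["cl"]] && is.null(classifier))
      stop("cleaning (CL) is enabled but no classifier model was given")
    key <- paste0(if (tg[["dn"]]) "dn" else "raw",
                  if (tg[["cl"]]) "_clean" else "")
    zs <- lapply(prep, function(p) fc_of(p[[key]], tg[["gsr"]]))
    # average runs of one subject-timepoint in z-space
    key <- paste(subj, tps)
    agg_keys <- unique(key)
    zagg <- lapply(agg_keys, function(k)
      Reduce(`+`, zs[key == k]) / sum(key == k))
    g_agg <- groups[match(agg_keys, key)]
    t_agg <- tps[match(agg_keys, key)]
    z_out[[v]] <- stats::setNames(zagg, agg_keys)
    for (tp in sort(unique(t_agg))) {
      ctl <- zagg[g_agg == "CTL" & t_agg == tp]
      if (length(ctl) >= 2) {
        var_rows[[length(var_rows) + 1]] <-
          data.frame(variant = v, timepoint = tp,
                     ctl_variability = within_group_variability(ctl)$summary)
      }
      stz <- zagg[g_agg == "STZ" & t_agg == tp]
      if (length(ctl) >= 2 && length(stz) >= 2) {
        nbs_out[[v]][[as.character(tp)]] <-
          nbs_test(stz, ctl, threshold = nbs_threshold,
                   n_perm = nbs_n_perm, seed = cfg$seed)
      }
    }
  }
  structure(list(variability = do.call(rbind, var_rows), nbs = nbs_out,
                 z = z_out),
            class = "variant_report")
}
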