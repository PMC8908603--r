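#' Normalise a study to the canonical reference frame
#'
#' Computes the normalisation transform from the mid short-axis slice and
#' the two long-axis planes (see [build_normalization]; the apex-most SAx
#' slice anchors the z-sign, assuming apex-to-base stack ordering),
#' resamples every slice in-plane to `target_spacing` mm pixels aligned with
#' the canonical axes, and expresses the resulting plane geometry in the
#' canonical frame (anchor at the origin, SAx normal along z) — so
#' normalising an already-normalised study is the identity. Long-axis
#' landmark annotations are re-indexed onto the new grids through patient
#' space.
#'
#' @param study a `cine_study`.
#' @param target_spacing canonical in-plane pixel size, mm (default 1).
#' @param resample_pixels interpolate the pixel data onto the new grids
#'   (default). Set FALSE to regrid the geometry only — sufficient for
#'   segmenters that rasterise analytically, e.g. [oracle_segmenter].
#' @param canonical_geometry express the output plane geometry in the
#'   canonical frame (default). With FALSE the regridded planes keep their
#'   patient-space coordinates — the grids and pixel values are identical,
#'   only the frame labelling differs.
#' @return list with `study` (normalised `cine_study`, pixels as nested
#'   lists `[[slice]][[phase]]`) and `transform`.
#' @export
normalize_study <- function(study, target_spacing = 1.0,
                            resample_pixels = TRUE,
                            canonical_geometry = TRUE) {
  n_sl <- length(study$sax$planes)
  mid <- study$sax$planes[[n_sl %/% 2L + 1L]]
  apex_pl <- study$sax$planes[[1L]]
  apex_ref <- pixel_to_patient(apex_pl, (apex_pl$n_rows - 1) / 2,
                               (apex_pl$n_cols - 1) / 2)
  transform <- build_normalization(mid, study$ch2$plane, study$ch4$plane,
                                   apex_reference = apex_ref,
                                   target_spacing = target_spacing)

  resample_series <- function(plane, get_img, n_ph) {
    if (!resample_pixels)
      return(list(plane = resampled_plane_geometry(plane, transform),
                  images = NULL))
    first <- resample_plane(get_img(1L), plane, transform, "linear")
    out <- vector("list", n_ph)
    out[[1L]] <- first$image
    if (n_ph > 1L) {
      # the grid mapping is shared across phases; only pixel values change
      np <- first$plane
      grid <- expand.grid(row = 0:(np$n_rows - 1L), col = 0:(np$n_cols - 1L))
      pts <- pixel_to_patient(np, grid$row, grid$col)
      px <- patient_to_pixel(plane, pts)
      for (p in 2:n_ph) {
        out[[p]] <- matrix(sample_bilinear(get_img(p), px$row, px$col),
                           np$n_rows, np$n_cols)
      }
    }
    list(plane = first$plane, images = out)
  }

  n_ph <- study$n_phases
  sax_planes <- vector("list", n_sl)
  sax_px <- vector("list", n_sl)
  for (k in seq_len(n_sl)) {
    rs <- resample_series(study$sax$planes[[k]],
                          function(p) study$sax$pixels[, , k, p], n_ph)
    sax_planes[[k]] <- rs$plane
    sax_px[k] <- list(rs$images)
  }
  if (!resample_pixels) sax_px <- NULL
  fix_lax <- function(lax) {
    rs <- resample_series(lax$plane, function(p) lax$pixels[, , p], n_ph)
    mv_px <- lax$mv_px
    if (!is.null(mv_px)) {
      for (p in seq_len(n_ph)) for (j in 1:2) {
        pt <- pixel_to_patient(lax$plane, mv_px[p, j, "row"],
                               mv_px[p, j, "col"])
        px <- patient_to_pixel(rs$plane, pt)
        mv_px[p, j, "row"] <- px$row
        mv_px[p, j, "col"] <- px$col
      }
    }
    list(plane = rs$plane, pixels = rs$images, mv_px = mv_px)
  }
  # relabel all geometry into the canonical frame (pixel data and pixel
  # indices are unaffected; this is a rigid re-expression)
  to_canonical <- if (canonical_geometry) {
    function(pl) transform_plane(pl, transform$rotation,
                                 transform$translation)
  } else identity
  canon_lax <- function(lax) {
    if (is.null(lax)) return(NULL)
    lax$plane <- to_canonical(lax$plane)
    lax
  }
  out <- structure(list(
    sax = list(planes = lapply(sax_planes, to_canonical), pixels = sax_px),
    ch2 = canon_lax(if (is.null(study$ch2)) NULL else fix_lax(study$ch2)),
    ch4 = canon_lax(if (is.null(study$ch4)) NULL else fix_lax(study$ch4)),
    n_phases = n_ph, phase_times = study$phase_times
  ), class = "cine_study")
  list(study = out, transform = transform)
}

#' @noRd
#' Detect the two mitral annulus points of one long-axis view at one phase
#' by the distance-map encode/decode round trip (emulating the landmark
#' U-net head on annotated content), returning patient-space points.
detect_mv_points <- function(lax, phase, sigma_mm) {
  pts <- matrix(NA_real_, 2L, 3L)
  for (j in 1:2) {
    p3 <- pixel_to_patient(lax$plane, lax$mv_px[phase, j, "row"],
                           lax$mv_px[phase, j, "col"])
    map <- encode_landmark(lax$plane, p3, sigma = sigma_mm)
    pts[j, ] <- decode_landmark(map, lax$plane)
  }
  pts
}

#' Run the full analysis pipeline on one study
#'
#' Executes the automated analysis end to end: spatial normalisation,
#' slice-wise segmentation, mitral annulus landmark detection on the
#' long-axis views, least-squares mitral valve plane fitting, basal volume
#' trimming, phase selection and LV metric derivation, plus automated
#' plausibility checks. The pipeline is deterministic: repeated runs on
#' identical input yield identical metrics.
#'
#' When a long-axis view is missing the mitral plane cannot be fitted;
#' volumes are then computed untrimmed and the report carries an
#' `mv_plane_skipped` flag.
#'
#' @param study a `cine_study`.
#' @param segmenter segmenter function (see [oracle_segmenter],
#'   [unet_segmenter]).
#' @param sigma_mm landmark map Gaussian width, mm.
#' @param density_g_per_ml myocardial density for mass.
#' @param mv_plane_per_phase fit a mitral plane per phase (default); when
#'   FALSE the ED-phase plane is reused for every phase.
#' @param qc_volume_threshold plausibility-flag volume fraction threshold.
#' @param normalize spatially normalise before segmentation (default TRUE).
#' @return object of class `study_report`: `metrics` (an `lv_metrics`),
#'   `blood_ml` per phase, `qc` flag data.frame, `mv_residual_mm`,
#'   `mv_plane_skipped`, and `provenance`.
#' @export
run_study <- function(study, segmenter, sigma_mm = 5,
                      density_g_per_ml = 1.05, mv_plane_per_phase = TRUE,
                      qc_volume_threshold = 0.05, normalize = TRUE) {
  if (length(study$sax$planes) < 3L)
    cmr_stop("data_error", "need at least 3 SAx slices")
  have_lax <- !is.null(study$ch2) && !is.null(study$ch4) &&
    !is.null(study$ch2$mv_px) && !is.null(study$ch4$mv_px)
  # analytic segmenters never read pixel data; skip the interpolation
  needs_pixels <- !inherits(segmenter, "oracle_segmenter")
  # normalisation needs both long-axis views to define the canonical frame
  # analysis stays in the patient frame (volumes are rigid-invariant and
  # the oracle segmenter rasterises in patient coordinates); the canonical
  # relabelling is only needed when exporting normalised studies
  norm <- if (normalize && have_lax) {
    normalize_study(study, resample_pixels = needs_pixels,
                    canonical_geometry = FALSE)
  } else list(study = study, transform = NULL)
  st <- norm$study
  seg <- segment_study(st, segmenter, myocardium_at_ed_only = TRUE)
  n_ph <- st$n_phases
  n_sl <- length(st$sax$planes)
  apex_pl <- st$sax$planes[[1L]]
  apex_ref <- pixel_to_patient(apex_pl, (apex_pl$n_rows - 1) / 2,
                               (apex_pl$n_cols - 1) / 2)

  mv_planes <- vector("list", n_ph)
  mv_residual <- NA_real_
  if (have_lax) {
    fit_phase <- function(p) {
      pts <- rbind(detect_mv_points(st$ch2, p, sigma_mm),
                   detect_mv_points(st$ch4, p, sigma_mm))
      fit_mv_plane(pts, ventricular_reference = apex_ref)
    }
    if (mv_plane_per_phase) {
      mv_planes <- lapply(seq_len(n_ph), fit_phase)
    } else {
      ed_plane <- fit_phase(seg$ed_index)
      mv_planes <- rep(list(ed_plane), n_ph)
    }
    mv_residual <- mv_planes[[seg$ed_index]]$fit_residual_mm
  }

  blood_ml <- vapply(seq_len(n_ph), function(p) {
    stack_volume(lapply(seq_len(n_sl), function(k) seg$masks[[k]][[p]]),
                 st$sax$planes, label = 1L, mv_plane = mv_planes[[p]])
  }, numeric(1))
  myo_ml <- stack_volume(
    lapply(seq_len(n_sl), function(k) seg$masks[[k]][[seg$ed_index]]),
    st$sax$planes, label = 2L, mv_plane = mv_planes[[seg$ed_index]])
  metrics <- compute_metrics(blood_ml, myo_ml,
                             density_g_per_ml = density_g_per_ml)

  qc <- plausibility_flags(
    lapply(seq_len(n_sl), function(k) seg$masks[[k]][[seg$ed_index]]),
    st$sax$planes, volume_threshold = qc_volume_threshold,
    mv_fit_residual = if (have_lax) mv_residual else NULL)
  if (!have_lax)
    qc <- rbind(qc, data.frame(flag = "mv_plane_skipped", slice = NA_integer_,
                               fraction = NA_real_))

  config <- list(sigma_mm = sigma_mm, density_g_per_ml = density_g_per_ml,
                 mv_plane_per_phase = mv_plane_per_phase,
                 qc_volume_threshold = qc_volume_threshold,
                 normalize = normalize)
  structure(list(
    metrics = metrics, blood_ml = blood_ml, myo_ml_ed = myo_ml,
    qc = qc, mv_residual_mm = mv_residual,
    mv_plane_skipped = !have_lax,
    provenance = list(
      package = as.character(utils::packageVersion("cmrlv")),
      config = config, config_hash = config_hash(config),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "study_report")
}

#' @noRd
#' Tiny stable FNV-1a hash of a deparsed object (provenance fingerprint;
#' timestamps are not part of it).
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (ch in s) h <- (bitwXor(as.integer(h %% 2^31), ch) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.study_report <- function(x, ...) {
  print(x$metrics)
  if (nrow(x$qc)) {
    cat("QC flags:\n")
    print(x$qc)
  } else cat("QC: no flags\n")
  invisible(x)
}

#' Scan-rescan precision evaluation
#'
#' Runs the full pipeline on each subject's scan and rescan and summarises
#' scan-rescan agreement per LV metric: within-subject CoV (root-mean-square
#' method) with bootstrap confidence interval, SEM, minimal detectable
#' change, Lin's CCC, Bland-Altman limits and mean absolute difference.
#'
#' @param subjects list of subjects, each a list with `scan` and `rescan`
#'   (`cine_study`) and `truth` (used by the oracle segmenter).
#' @param segmenter `"oracle"`, or a function `(truth)` returning a
#'   segmenter, or a fixed segmenter function used for all subjects.
#' @param metrics which LV metric fields to evaluate.
#' @param n_boot,seed bootstrap settings.
#' @param ... passed to [run_study].
#' @return list with `reports` (one `precision_report` per metric) and
#'   `values` (data.frame of per-subject metric values).
#' @export
run_precision <- function(subjects,
                          segmenter = "oracle",
                          metrics = c("edv_ml", "esv_ml", "sv_ml", "ef_pct",
                                      "lvm_g"),
                          n_boot = 1000L, seed = 1L, ...) {
  if (length(subjects) < 2L)
    cmr_stop("data_error", "need at least two subjects")
  get_seg <- function(subj) {
    if (is.function(segmenter) && !inherits(segmenter, "oracle_segmenter"))
      return(segmenter)
    if (identical(segmenter, "oracle")) {
      if (is.null(subj$truth))
        cmr_stop("data_error", "oracle segmenter requires per-subject truth")
      return(oracle_segmenter(subj$truth))
    }
    segmenter
  }
  rows <- list()
  for (i in seq_along(subjects)) {
    subj <- subjects[[i]]
    seg <- get_seg(subj)
    for (session in c("scan", "rescan")) {
      rp <- run_study(subj[[session]], seg, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, session = session,
        edv_ml = rp$metrics$edv_ml, esv_ml = rp$metrics$esv_ml,
        sv_ml = rp$metrics$sv_ml, ef_pct = rp$metrics$ef_pct,
        lvm_g = rp$metrics$lvm_g)
    }
  }
  values <- do.call(rbind, rows)
  reports <- lapply(metrics, function(m) {
    x1 <- values[values$session == "scan", m]
    x2 <- values[values$session == "rescan", m]
    precision_report(paired_measurements(x1, x2), metric = m,
                     n_boot = n_boot, seed = seed)
  })
  names(reports) <- metrics
  list(reports = reports, values = values)
}

#' Format precision reports as a summary table
#'
#' One row per metric: CoV% with its confidence interval in brackets, SEM,
#' MDC, CCC, bias and mean absolute difference.
#'
#' @param reports list of `precision_report` objects.
#' @return data.frame.
#' @export
format_precision_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      metric = r$metric,
      cov = sprintf("%.1f%% (%.1f-%.1f)", r$cov_pct, r$cov_ci_low,
                    r$cov_ci_high),
      sem = round(r$sem, 3), mdc = round(r$mdc, 3),
      ccc = round(r$ccc, 4),
      bias = round(r$bland_altman$bias, 3),
      mean_abs_diff = round(r$mean_abs_diff, 3),
      n = r$n_subjects)
  }))
}
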