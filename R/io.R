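#' @noRd
plane_to_list <- function(pl) {
  list(origin = pl$origin, row_dir = pl$row_dir, col_dir = pl$col_dir,
       row_spacing = pl$row_spacing, col_spacing = pl$col_spacing,
       slab_thickness = pl$slab_thickness, n_rows = pl$n_rows,
       n_cols = pl$n_cols)
}

#' @noRd
plane_from_list <- function(x) {
  image_plane(x$origin, x$row_dir, x$col_dir, x$row_spacing, x$col_spacing,
              x$slab_thickness, x$n_rows, x$n_cols)
}

#' Write a cine study as NIfTI volumes with a JSON geometry sidecar
#'
#' The short-axis stack is stored as a 4D NIfTI (rows x cols x slices x
#' phases) and each long-axis cine as a 3D NIfTI; the exact plane geometry
#' (DICOM-convention origins, direction cosines, spacings) and any landmark
#' annotations go to `study.json`. Pixel geometry in the NIfTI headers is
#' nominal — the sidecar is authoritative, which keeps the round trip exact.
#'
#' @param study a `cine_study` (with array pixel storage, i.e. as generated;
#'   normalised studies with per-slice grids are an in-memory form only).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (is.list(study$sax$pixels))
    cmr_stop("data_error",
             "only studies with uniform array storage can be written")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(study$sax$pixels),
                     file.path(dir, "sax.nii"))
  RNifti::writeNifti(RNifti::asNifti(study$ch2$pixels),
                     file.path(dir, "ch2.nii"))
  RNifti::writeNifti(RNifti::asNifti(study$ch4$pixels),
                     file.path(dir, "ch4.nii"))
  meta <- list(
    n_phases = study$n_phases,
    phase_times = study$phase_times,
    sax_planes = lapply(study$sax$planes, plane_to_list),
    ch2 = list(plane = plane_to_list(study$ch2$plane),
               mv_px = study$ch2$mv_px),
    ch4 = list(plane = plane_to_list(study$ch4$plane),
               mv_px = study$ch4$mv_px)
  )
  jsonlite::write_json(meta, file.path(dir, "study.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cine study written by [write_study]
#'
#' @param dir study directory.
#' @return a `cine_study`.
#' @export
read_study <- function(dir) {
  jf <- file.path(dir, "study.json")
  if (!file.exists(jf))
    cmr_stop("data_error", sprintf("no study found in '%s'", dir))
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  arr <- function(f) {
    a <- RNifti::readNifti(file.path(dir, f))
    array(as.numeric(a), dim = dim(a))
  }
  mv_arr <- function(x) {
    if (is.null(x)) return(NULL)
    a <- x
    if (!is.array(a)) a <- simplify2array(a)
    dimnames(a) <- list(NULL, NULL, c("row", "col"))
    a
  }
  structure(list(
    sax = list(planes = lapply(meta$sax_planes, plane_from_list),
               pixels = arr("sax.nii")),
    ch2 = list(plane = plane_from_list(meta$ch2$plane), pixels = arr("ch2.nii"),
               mv_px = mv_arr(meta$ch2$mv_px)),
    ch4 = list(plane = plane_from_list(meta$ch4$plane), pixels = arr("ch4.nii"),
               mv_px = mv_arr(meta$ch4$mv_px)),
    n_phases = as.integer(meta$n_phases),
    phase_times = meta$phase_times
  ), class = "cine_study")
}

#' Write a study report as JSON
#'
#' @param report a `study_report` from [run_study].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    metrics = unclass(report$metrics),
    blood_ml = report$blood_ml,
    myo_ml_ed = report$myo_ml_ed,
    mv_residual_mm = report$mv_residual_mm,
    mv_plane_skipped = report$mv_plane_skipped,
    qc = report$qc,
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}
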