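#' Read and write BOLD runs and 3D maps as NIfTI
#'
#' Volumes are written as NIfTI-1 with the voxel size in the header and a
#' JSON sidecar holding the repetition time and provenance (stage,
#' parameters, seed), enough to re-derive the file.
#'
#' @param run a [bold_run()].
#' @param path output `.nii` / `.nii.gz` path (the mask is written alongside
#'   with suffix `_mask`, the sidecar with `.json`).
#' @param voxel_size_mm voxel dimensions.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path, voxel_size_mm = c(4, 4, 4)) {
  img <- RNifti::asNifti(run$data, pixdim = c(voxel_size_mm, run$tr_seconds))
  RNifti::writeNifti(img, path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(run$brain_mask),
                                           dim(run$brain_mask)),
                                     pixdim = voxel_size_mm),
                     sidecar_path(path, "_mask"))
  jsonlite::write_json(list(tr_seconds = run$tr_seconds, meta = run$meta),
                       sidecar_path(path, ext = ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path, ext = ".json"),
                              simplifyVector = TRUE)
  mask <- RNifti::readNifti(sidecar_path(path, "_mask")) > 0
  bold_run(array(as.numeric(img), dim(img)), side$tr_seconds, mask,
           meta = side$meta)
}

sidecar_path <- function(path, suffix = "", ext = NULL) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, suffix, if (is.null(ext)) ".nii" else ext)
}

#' Write and read a lag map as NIfTI plus JSON sidecar
#'
#' The sidecar records method, polarity, the shift grid and TR; the validity
#' mask is stored as a companion volume.
#'
#' @param map a [lag_map()].
#' @param path output path.
#' @param voxel_size_mm voxel dimensions.
#' @return `path` (write) / a [lag_map()] (read).
#' @export
write_lag_map <- function(map, path, voxel_size_mm = c(4, 4, 4)) {
  RNifti::writeNifti(RNifti::asNifti(map$values, pixdim = voxel_size_mm), path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map$valid_mask),
                                           dim(map$valid_mask)),
                                     pixdim = voxel_size_mm),
                     sidecar_path(path, "_valid"))
  jsonlite::write_json(
    list(method = map$method, polarity = map$polarity,
         tr_seconds = map$tr_seconds, shift_range_s = map$shift_range_s),
    sidecar_path(path, ext = ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lag_map
#' @export
read_lag_map <- function(path) {
  vals <- RNifti::readNifti(path)
  valid <- RNifti::readNifti(sidecar_path(path, "_valid")) > 0
  side <- jsonlite::read_json(sidecar_path(path, ext = ".json"),
                              simplifyVector = TRUE)
  lag_map(array(as.numeric(vals), dim(vals)), valid, side$method,
          side$tr_seconds, side$shift_range_s)
}

#' Write / read event timing tables as TSV
#'
#' Three columns: onset, duration, kind (seconds).
#'
#' @param events an [event_list()].
#' @param path TSV path.
#' @return `path` (write) / an [event_list()] (read).
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_list(df$onset, df$duration, df$kind)
}

#' Write a phantom (runs, truth sidecars) to a directory
#'
#' Runs are written as 4D NIfTI, tissue and ROI maps as 3D NIfTI, events as
#' TSV, and the planted truth as a lag-field NIfTI plus a JSON sidecar with
#' the configuration and component classes.
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory (created if missing).
#' @param events optional [event_list()] written alongside.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, events = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$truth$config$voxel_size_mm
  for (r in seq_along(phantom$runs))
    write_bold_run(phantom$runs[[r]],
                   file.path(dir, sprintf("run-%02d.nii", r)), vs)
  tis <- phantom$truth$tissue
  for (nm in names(tis))
    RNifti::writeNifti(RNifti::asNifti(tis[[nm]], pixdim = vs),
                       file.path(dir, paste0(nm, ".nii")))
  for (roi in phantom$truth$rois)
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(roi$mask),
                                             dim(roi$mask)), pixdim = vs),
                       file.path(dir, paste0("roi_", roi$name, ".nii")))
  lf <- phantom$truth$lag_field
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(lf), dim(lf)),
                                     pixdim = vs),
                     file.path(dir, "truth_lag_field.nii"))
  if (!is.null(events)) write_events_tsv(events, file.path(dir, "events.tsv"))
  jsonlite::write_json(
    list(config = unclass(phantom$truth$config),
         session_seed = phantom$truth$session_seed,
         component_classes = vapply(phantom$truth$component_truth,
                                    `[[`, "", "class"),
         positive_lag_fraction = attr(lf, "positive_fraction")),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
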