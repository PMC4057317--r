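# NIfTI volume and tabular IO. Volumes (maps, masks, label images) are
# written as NIfTI-1; masks and labels as 32-bit integers (bit-exact round
# trip), parameter maps as 32-bit floats. Tables are RFC-4180 CSV with a
# header row.

#' Write a volume as NIfTI-1
#'
#' Integer volumes (masks, labels) are stored as `int32` and round-trip
#' bit-exactly; floating-point maps are stored as `float32`.
#'
#' @param volume 3-D numeric or logical array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param pixdim voxel size in mm, length 3.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, pixdim = c(1, 1, 1)) {
  int_like <- is.logical(volume) ||
    (is.numeric(volume) && !anyNA(volume) &&
       all(volume == round(volume)) && max(abs(volume)) < 2^31)
  dat <- if (int_like) array(as.integer(volume), dim(volume)) else volume
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path,
                     datatype = if (int_like) "int32" else "float")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file path.
#' @return The data array with attribute `"pixdim"` (voxel size in mm).
#' @export
read_volume <- function(path) {
  img <- tryCatch(
    withCallingHandlers(RNifti::readNifti(path),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e)
      stop(sprintf("cannot read '%s' as NIfTI: %s", path,
                   conditionMessage(e)), call. = FALSE))
  out <- array(as.vector(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

write_table_csv <- function(df, path, checksum = NULL) {
  if (!is.null(checksum)) {
    con <- file(path, "w")
    writeLines(sprintf("# config_checksum=%s", checksum), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Export a synthetic cohort to disk
#'
#' Writes per scan the ground-truth parameter maps, tissue label volume and
#' tumor mask as NIfTI, plus a cohort manifest CSV and the generator settings
#' as YAML.
#'
#' @param cohort an `mpmri_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest `data.frame`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- cohort$protocol$pixdim
  rows <- list()
  for (key in names(cohort$scans)) {
    sc <- cohort$scans[[key]]
    paths <- c(vapply(c("T1", "T2", "ADC", "MTR"), function(p) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", key, p))
      write_volume(sc$maps[[p]], f, pix)
      f
    }, ""), labels = {
      f <- file.path(dir, sprintf("%s_labels.nii.gz", key))
      write_volume(sc$labels, f, pix)
      f
    }, mask = {
      f <- file.path(dir, sprintf("%s_mask.nii.gz", key))
      write_volume(sc$tumor_mask, f, pix)
      f
    })
    rows[[key]] <- data.frame(animal = sc$animal, group = sc$group,
                              timepoint = sc$timepoint,
                              sacrifice = sc$sacrifice,
                              true_nonviable_fraction =
                                sc$true_nonviable_fraction,
                              t(paths), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_table_csv(manifest, file.path(dir, "manifest.csv"))
  settings <- list(
    design = list(n_treated = cohort$design$n_treated,
                  n_treated_72h = cohort$design$n_treated_72h,
                  n_control = cohort$design$n_control),
    protocol = cohort$protocol[c("matrix_size", "n_slices", "fov_mm",
                                 "slice_mm", "s0", "noise_sd")],
    lesion = unclass(cohort$lesion),
    seed = cohort$seed)
  yaml::write_yaml(settings, file.path(dir, "generator_settings.yaml"))
  invisible(manifest)
}
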