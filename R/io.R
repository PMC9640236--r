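# Reading and writing: NIfTI case volumes with ACDC-style `_gt` label
# companions, and PNG + CSV-manifest layout for phantom datasets.

#' Case volume
#'
#' One case's image stack: `voxels` is (H, W, S) with S slices, `labels`
#' (same shape) is optional.
#'
#' @param voxels 3D numeric array (H, W, S).
#' @param labels Optional 3D integer array of the same shape.
#' @param case_id Case identifier.
#' @param pixel_spacing Optional (mm, mm) in-plane spacing.
#' @return A `case_volume`.
#' @export
case_volume <- function(voxels, labels = NULL, case_id = "case",
                        pixel_spacing = NULL) {
  if (length(dim(voxels)) == 2L) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.null(labels)) {
    if (length(dim(labels)) == 2L) labels <- array(labels, c(dim(labels), 1L))
    if (!identical(dim(labels), dim(voxels)))
      stop("labels shape ", paste(dim(labels), collapse = "x"),
           " does not match voxels ", paste(dim(voxels), collapse = "x"),
           " for case ", case_id)
  }
  structure(list(voxels = voxels, labels = labels, case_id = case_id,
                 pixel_spacing = pixel_spacing), class = "case_volume")
}

label_companion <- function(path) {
  for (ext in c("\\.nii\\.gz$", "\\.nii$")) {
    if (grepl(ext, path)) {
      cand <- sub(ext, paste0("_gt", sub("\\$", "", sub("\\\\", "", ext))),
                  path)
      if (file.exists(cand)) return(cand)
    }
  }
  NULL
}

#' Read a case volume
#'
#' `path` may be a NIfTI file (a label volume is picked up automatically
#' from the `_gt` companion, e.g. `patient001.nii.gz` +
#' `patient001_gt.nii.gz`) or a phantom dataset directory containing a
#' `manifest.csv` written by [write_dataset()], in which case `case_id`
#' selects the case (default: the only/first case).
#'
#' @param path NIfTI file or manifest directory.
#' @param case_id Case to load from a manifest directory.
#' @return A [case_volume()].
#' @export
read_volume <- function(path, case_id = NULL) {
  if (dir.exists(path)) return(read_manifest_case(path, case_id))
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  if (length(dim(vox)) == 4L) vox <- vox[, , , 1L]
  labels <- NULL
  lp <- label_companion(path)
  if (!is.null(lp)) {
    lab <- as.array(RNifti::readNifti(lp))
    if (length(dim(lab)) == 2L) lab <- array(lab, c(dim(lab), 1L))
    storage.mode(lab) <- "integer"
    labels <- lab
  }
  pd <- tryCatch(RNifti::pixdim(img)[1:2], error = function(e) NULL)
  case_volume(vox, labels,
              case_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
              pixel_spacing = pd)
}

read_manifest_case <- function(dir, case_id = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (is.null(case_id)) case_id <- man$case_id[1]
  man <- man[man$case_id == case_id, , drop = FALSE]
  if (nrow(man) == 0L) stop("case ", case_id, " not present in ", mf)
  man <- man[order(man$slice_index), , drop = FALSE]
  imgs <- lapply(file.path(dir, man$image), function(p) png::readPNG(p))
  masks <- lapply(file.path(dir, man$mask), function(p) {
    m <- png::readPNG(p)
    matrix(as.integer(round(m * 255)), nrow = nrow(m))
  })
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  vox <- array(unlist(imgs), c(H, W, length(imgs)))
  lab <- array(unlist(masks), c(H, W, length(masks)))
  storage.mode(lab) <- "integer"
  case_volume(vox, lab, case_id = case_id)
}

#' Write a phantom dataset as PNG pairs + manifest
#'
#' Images go to 8-bit grayscale PNGs, masks to PNGs storing the class id
#' directly (value/255), plus a `manifest.csv` with columns case_id,
#' slice_index, image, mask.
#'
#' @param samples List of `slice_sample`s.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    stem <- sprintf("%s_slice%02d", s$case_id, s$slice_index)
    png::writePNG(s$image, file.path(dir, paste0(stem, ".png")))
    png::writePNG(s$mask / 255, file.path(dir, paste0(stem, "_mask.png")))
    data.frame(case_id = s$case_id, slice_index = s$slice_index,
               image = paste0(stem, ".png"),
               mask = paste0(stem, "_mask.png"))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Convert a case volume to slice samples
#'
#' @param volume A [case_volume()] with labels.
#' @return List of `slice_sample`s.
#' @export
volume_to_samples <- function(volume) {
  stopifnot(inherits(volume, "case_volume"))
  S <- dim(volume$voxels)[3]
  lapply(seq_len(S), function(i) {
    new_slice_sample(volume$voxels[, , i],
                     if (is.null(volume$labels)) matrix(0L, dim(volume$voxels)[1], dim(volume$voxels)[2])
                     else volume$labels[, , i],
                     volume$case_id, i)
  })
}

#' Load every case of a manifest directory as slice samples
#'
#' @param dir Dataset directory with `manifest.csv`.
#' @return List of `slice_sample`s across all cases.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  unlist(lapply(unique(man$case_id), function(cid)
    volume_to_samples(read_manifest_case(dir, cid))), recursive = FALSE)
}
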