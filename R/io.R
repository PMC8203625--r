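# Dataset reading and writing: NIfTI-1 volumes (float32) + phenotype CSV +
# ground-truth JSON and masks. Disk format is float32; computation is
# float64.

write_volume <- function(vec, shape, voxel_size, file) {
  img <- RNifti::asNifti(array(vec, dim = shape))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, file, datatype = "float")
}

#' Write a dataset (volumes, phenotype table, ground truth) to a directory
#'
#' One 3-D NIfTI per stack row (`layout = "per_subject"`, files named by row
#' id) or a single 4-D stack (`layout = "4d"`), plus `pheno.csv` with a
#' `volume_file` column and, when `truth` is given, `truth.json` with
#' baseline and pattern masks as NIfTI volumes.
#'
#' @param stack a [gm_stack()].
#' @param pheno matching phenotype table.
#' @param dir output directory (created if missing).
#' @param truth optional [make_ground_truth()] object.
#' @param layout `"per_subject"` or `"4d"`.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(stack, pheno, dir, truth = NULL,
                          layout = c("per_subject", "4d")) {
  layout <- match.arg(layout)
  stopifnot(nrow(stack$data) == nrow(pheno))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  shape <- stack$grid_shape
  vs <- stack$voxel_size_mm
  if (layout == "per_subject") {
    files <- paste0(stack$subject_ids, ".nii.gz")
    for (i in seq_len(nrow(stack$data)))
      write_volume(stack$data[i, ], shape, vs, file.path(dir, files[i]))
    pheno$volume_file <- files
  } else {
    arr <- array(t(stack$data), dim = c(shape, nrow(stack$data)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vs, 1)
    RNifti::writeNifti(img, file.path(dir, "stack4d.nii.gz"),
                       datatype = "float")
    pheno$volume_file <- "stack4d.nii.gz"
  }
  pheno$row_id <- stack$subject_ids
  utils::write.csv(pheno, file.path(dir, "pheno.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(grid_shape = shape, voxel_size_mm = vs, layout = layout),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    write_volume(truth$baseline, shape, vs, file.path(dir, "baseline.nii.gz"))
    write_volume(truth$disorder_pattern, shape, vs,
                 file.path(dir, "disorder_pattern.nii.gz"))
    write_volume(truth$aging_pattern, shape, vs,
                 file.path(dir, "aging_pattern.nii.gz"))
    jsonlite::write_json(
      list(disorder_idx = truth$disorder_idx, aging_idx = truth$aging_idx,
           config_seed = truth$config_seed),
      file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Volumes are matched to phenotype rows by the `row_id` / `volume_file`
#' columns; a phenotype row whose volume is missing is an error naming the
#' id. Per-subject 3-D and 4-D layouts load identically.
#'
#' @param dir dataset directory.
#' @return list with `stack`, `pheno`, and `truth` (NULL when absent;
#'   otherwise baseline and pattern vectors plus index sets).
#' @export
read_dataset <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "pheno.csv"),
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "grid.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$grid_shape)
  if (identical(meta$layout, "4d")) {
    arr <- RNifti::readNifti(file.path(dir, "stack4d.nii.gz"))
    data <- t(matrix(as.numeric(arr), nrow = prod(shape)))
  } else {
    files <- file.path(dir, pheno$volume_file)
    missing <- !file.exists(files)
    if (any(missing))
      stop("missing volume for: ",
           paste(pheno$row_id[missing], collapse = ", "))
    data <- t(vapply(files, function(f) {
      img <- RNifti::readNifti(f)
      if (!identical(as.integer(dim(img)), shape))
        stop("grid mismatch in ", f)
      as.numeric(img)
    }, numeric(prod(shape))))
  }
  stack <- gm_stack(data, shape, as.numeric(meta$voxel_size_mm),
                    subject_ids = pheno$row_id)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tl <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- structure(
      list(baseline = as.numeric(RNifti::readNifti(
             file.path(dir, "baseline.nii.gz"))),
           disorder_pattern = as.numeric(RNifti::readNifti(
             file.path(dir, "disorder_pattern.nii.gz"))),
           aging_pattern = as.numeric(RNifti::readNifti(
             file.path(dir, "aging_pattern.nii.gz"))),
           disorder_idx = as.integer(tl$disorder_idx),
           aging_idx = as.integer(tl$aging_idx),
           grid_shape = shape, voxel_size_mm = as.numeric(meta$voxel_size_mm),
           config_seed = tl$config_seed),
      class = "ground_truth")
  }
  list(stack = stack, pheno = pheno, truth = truth)
}
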