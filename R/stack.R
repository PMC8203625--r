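#' Gray-matter stack container
#'
#' A `gm_stack` holds per-subject gray-matter density maps as a
#' subjects-by-voxels matrix tied to a 3-D grid geometry. Voxels are stored
#' in x-fastest order, i.e. the column-major vectorisation of an
#' `array(dim = grid_shape)` volume: voxel `(x, y, z)` sits at flat index
#' `x + nx*(y-1) + nx*ny*(z-1)`.
#'
#' @param data numeric matrix, subjects in rows, voxels in columns.
#' @param grid_shape integer vector of length 3, voxel extents per axis.
#' @param voxel_size_mm numeric length 3, voxel edge lengths in mm.
#' @param subject_ids character vector of row identifiers; defaults to
#'   `rownames(data)` or `"S001"...`.
#' @return An object of class `gm_stack` with elements `data`, `grid_shape`,
#'   `voxel_size_mm`, `subject_ids`.
#' @export
gm_stack <- function(data, grid_shape, voxel_size_mm = c(2, 2, 2),
                     subject_ids = NULL) {
  data <- as.matrix(data)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (ncol(data) != prod(grid_shape))
    stop("ncol(data) must equal prod(grid_shape)")
  if (!all(is.finite(data)))
    stop("gm_stack data must be finite")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(data)
    if (is.null(subject_ids))
      subject_ids <- sprintf("S%03d", seq_len(nrow(data)))
  }
  if (length(subject_ids) != nrow(data))
    stop("subject_ids length must match row count")
  rownames(data) <- subject_ids
  structure(
    list(data = data, grid_shape = grid_shape,
         voxel_size_mm = as.numeric(voxel_size_mm),
         subject_ids = as.character(subject_ids)),
    class = "gm_stack"
  )
}

#' @export
print.gm_stack <- function(x, ...) {
  cat(sprintf("gm_stack: %d subjects x %d voxels (grid %s, voxel %s mm)\n",
              nrow(x$data), ncol(x$data),
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Subset a gm_stack by rows
#'
#' @param stack a [gm_stack()].
#' @param idx integer or logical row index.
#' @return a `gm_stack` with the selected rows.
#' @export
subset_stack <- function(stack, idx) {
  gm_stack(stack$data[idx, , drop = FALSE], stack$grid_shape,
           stack$voxel_size_mm, stack$subject_ids[idx])
}

#' Extract one subject's map as a 3-D volume
#'
#' @param stack a [gm_stack()].
#' @param i row index or subject id.
#' @return 3-D array of dimension `grid_shape`.
#' @export
stack_volume <- function(stack, i) {
  if (is.character(i)) i <- match(i, stack$subject_ids)
  array(stack$data[i, ], dim = stack$grid_shape)
}

# Flatten a 3-D volume into the documented x-fastest voxel order.
flatten_volume <- function(vol) as.vector(vol)
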