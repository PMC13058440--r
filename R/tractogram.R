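#' Voxel grid: shape plus world-from-voxel affine
#'
#' The spatial reference for density maps and masks. World coordinates are
#' RAS millimetres; voxel indices are 0-based; a world point `p` lies in voxel
#' `v` iff `floor(solve(affine) %*% p) == v` (half-open voxel cells, so the
#' affine maps voxel *corners* to world space and the centre of voxel `v` is
#' `affine %*% (v + 0.5)`).
#'
#' @param shape Integer vector of length 3, all positive.
#' @param affine 4x4 world-from-voxel transform (mm). Default: identity,
#'   i.e. a 1 mm isotropic grid anchored at the world origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(90, 110, 90))
#' @export
voxel_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("shape must be 3 positive integers", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("affine must be invertible", call. = FALSE)
  structure(list(shape = shape, affine = affine), class = "voxel_grid")
}

#' Default synthetic-study grid
#'
#' 90 x 110 x 90 voxels at 1 mm isotropic, matching the resampled resolution
#' the analysis assumes.
#' @return A [voxel_grid()].
#' @export
default_grid <- function() voxel_grid(c(90L, 110L, 90L))

.grid_voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Construct a bundle of streamlines
#'
#' A bundle is the set of streamlines connecting one area pair: a list of
#' n-by-3 matrices of world-mm points (each with >= 2 rows, finite, no
#' repeated consecutive points), a [voxel_grid()] reference, and a label.
#' Bundles may be empty (an absent connection).
#'
#' @param streamlines List of numeric matrices with 3 columns.
#' @param grid A [voxel_grid()].
#' @param label Free-text or pair label.
#' @return An object of class `bundle`.
#' @export
bundle <- function(streamlines = list(), grid = default_grid(), label = "") {
  if (!inherits(grid, "voxel_grid")) stop("grid must be a voxel_grid", call. = FALSE)
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline needs >= 2 points with 3 coordinates", call. = FALSE)
    if (!all(is.finite(s))) stop("streamline coordinates must be finite", call. = FALSE)
    step <- diff(s)
    if (any(rowSums(step^2) == 0))
      stop("consecutive streamline points must be distinct", call. = FALSE)
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, grid = grid, label = label),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("bundle '%s': %d streamlines on %s grid\n",
              x$label, length(x$streamlines),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Number of streamlines in a bundle
#' @param b A [bundle()].
#' @return Integer count.
#' @export
n_streamlines <- function(b) length(b$streamlines)

#' Apply a 4x4 affine transform to every streamline point
#'
#' Stand-in for applying a (pre-computed) registration to streamlines rather
#' than to density maps; rigid transforms preserve arc lengths.
#'
#' @param b A [bundle()].
#' @param transform Invertible 4x4 matrix (world-from-world, mm).
#' @return The transformed bundle (same grid reference).
#' @export
apply_affine <- function(b, transform) {
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L)) || abs(det(transform)) < 1e-12)
    stop("transform must be an invertible 4x4 matrix", call. = FALSE)
  R <- transform[1:3, 1:3]; t3 <- transform[1:3, 4L]
  b$streamlines <- lapply(b$streamlines, function(s)
    sweep(s %*% t(R), 2L, t3, "+"))
  b
}

.world_to_voxel <- function(points, grid) {
  inv <- solve(grid$affine)
  sweep(points %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")
}

.voxel_to_world <- function(vox, grid) {
  sweep(vox %*% t(grid$affine[1:3, 1:3]), 2L, grid$affine[1:3, 4L], "+")
}

#' Read or write a tractogram
#'
#' Dispatches on format: TrackVis `.trk` (carries its own grid header) or
#' MRtrix `.tck` (world-mm only; a `reference` volume or grid is required
#' when the grid matters downstream). All streamlines are normalized to world
#' RAS mm on read.
#'
#' @param path File path.
#' @param format `"trk"` or `"tck"`; default guessed from the extension.
#' @param reference For TCK: a [voxel_grid()] or NIfTI path supplying the
#'   grid; mandatory.
#' @param label Bundle label to attach.
#' @return A [bundle()].
#' @export
read_tractogram <- function(path, format = tools::file_ext(path),
                            reference = NULL, label = "") {
  format <- tolower(format)
  switch(format,
         trk = read_trk(path, label = label),
         tck = read_tck(path, reference = reference, label = label),
         stop("unknown tractogram format: ", format, call. = FALSE))
}

#' @rdname read_tractogram
#' @param b A [bundle()] to write.
#' @export
write_tractogram <- function(b, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  switch(format,
         trk = write_trk(b, path),
         tck = write_tck(b, path),
         stop("unknown tractogram format: ", format, call. = FALSE))
  invisible(path)
}

#' Read a binary region-of-interest mask from NIfTI
#'
#' @param path NIfTI file.
#' @param grid Optional [voxel_grid()] the mask must match (shape and affine
#'   within 1e-4); mismatch is an error.
#' @return A list with `mask` (logical 3D array) and `grid`.
#' @export
read_mask <- function(path, grid = NULL) {
  v <- read_volume(path, grid = grid)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask is not binary: values other than 0/1 found in ", path,
         call. = FALSE)
  list(mask = array(v$data > 0, dim = dim(v$data)), grid = v$grid)
}

#' Read a scalar volume from NIfTI
#' @inheritParams read_mask
#' @return A list with `data` (3D array) and `grid`.
#' @export
read_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  dat <- array(as.vector(img), dim = dim(img))
  g <- voxel_grid(dim(dat), matrix(aff, 4L, 4L))
  if (!is.null(grid)) {
    if (!all(g$shape == grid$shape) ||
        max(abs(g$affine - grid$affine)) > 1e-4)
      stop("volume shape/affine does not match the expected grid: ", path,
           call. = FALSE)
  }
  list(data = dat, grid = g)
}

#' Write a scalar volume (or density map) to NIfTI
#'
#' @param data 3D array matching `grid$shape`.
#' @param grid A [voxel_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  data <- as.array(data)
  if (!all(dim(data) == grid$shape))
    stop("data dimensions do not match grid shape", call. = FALSE)
  img <- RNifti::asNifti(data, pixdim = .grid_voxel_size(grid))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
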