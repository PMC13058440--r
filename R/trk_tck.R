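# TrackVis (.trk) and MRtrix (.tck) tractogram I/O.
#
# No R package on CRAN/Bioconductor reads these formats, so they are
# implemented here directly. Both readers normalize streamlines to world RAS
# mm. TRK stores points in "voxmm" (voxel coordinates scaled by voxel size,
# shifted half a voxel); the conversion used here matches the reference
# implementations: rasmm = vox_to_ras %*% (voxmm / voxel_size - 0.5).

.TRK_HDR_SIZE <- 1000L

.axcodes <- function(affine) {
  letters_pos <- c("R", "A", "S"); letters_neg <- c("L", "P", "I")
  out <- character(3L)
  for (j in 1:3) {
    col <- affine[1:3, j]
    i <- which.max(abs(col))
    out[j] <- if (col[i] >= 0) letters_pos[i] else letters_neg[i]
  }
  paste(out, collapse = "")
}

#' Write a bundle as a TrackVis TRK file
#'
#' @param b A [bundle()]; the grid affine is stored in the header
#'   (`vox_to_ras`), so the file is self-describing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trk <- function(b, path) {
  if (!inherits(b, "bundle")) stop("b must be a bundle", call. = FALSE)
  grid <- b$grid
  vs <- .grid_voxel_size(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(as.raw(0L), con)
  writeBin(as.integer(grid$shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")     # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)                                     # scalar names
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)                                     # property names
  writeBin(as.numeric(t(grid$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                     # reserved
  vo <- charToRaw(.axcodes(grid$affine))
  writeBin(c(vo, raw(4L - length(vo))), con)                   # voxel_order
  writeBin(raw(4L), con)                                       # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")     # orientation
  writeBin(raw(2L), con)                                       # pad1
  writeBin(raw(6L), con)                                       # invert/swap
  writeBin(length(b$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(.TRK_HDR_SIZE, con, size = 4L, endian = "little")
  inv <- solve(grid$affine)
  for (s in b$streamlines) {
    vox <- sweep(s %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4L], "+")
    voxmm <- sweep(vox + 0.5, 2L, vs, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' @param path File path.
#' @param label Bundle label to attach.
#' @return A [bundle()] with streamlines in world RAS mm and the grid taken
#'   from the header.
#' @export
read_trk <- function(path, label = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("malformed TRK header at offset 0: missing TRACK magic in ", path,
         call. = FALSE)
  shape <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")    # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, .TRK_HDR_SIZE))
    stop("malformed TRK header at offset 996: hdr_size = ", hdr_size,
         " (expected 1000) in ", path, call. = FALSE)
  if (all(aff == 0))
    stop("TRK header (offset 440) has no vox_to_ras transform (version ",
         version, "); cannot map to world mm", call. = FALSE)
  aff[4L, ] <- c(0, 0, 0, 1)
  grid <- voxel_grid(pmax(shape, 1L), aff)
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L,
                              endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, vs, "/") - 0.5
    i <- i + 1L
    streamlines[[i]] <- sweep(vox %*% t(aff[1:3, 1:3]), 2L, aff[1:3, 4L], "+")
    if (n_count > 0L && i == n_count) break
  }
  length(streamlines) <- i
  bundle(streamlines, grid = grid, label = label)
}

#' Write a bundle as an MRtrix TCK file
#'
#' TCK stores world-mm coordinates only; the grid is not serialized, so a
#' reference volume is needed when reading the file back for voxel work.
#'
#' @param b A [bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(b, path) {
  if (!inherits(b, "bundle")) stop("b must be a bundle", call. = FALSE)
  body <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                 length(b$streamlines), "\nfile: . ")
  # the offset field includes its own digits; iterate to a fixed point
  offset <- nchar(body) + nchar("END\n") + 2L
  repeat {
    hdr <- paste0(body, offset, "\nEND\n")
    if (nchar(hdr) == offset) break
    offset <- nchar(hdr)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in b$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#'
#' @param path File path.
#' @param reference A [voxel_grid()] or a NIfTI file path providing the voxel
#'   grid; required (TCK carries no grid of its own).
#' @param label Bundle label to attach.
#' @return A [bundle()].
#' @export
read_tck <- function(path, reference = NULL, label = "") {
  if (is.null(reference))
    stop("TCK files carry no voxel grid; supply a reference volume or ",
         "voxel_grid", call. = FALSE)
  grid <- if (inherits(reference, "voxel_grid")) reference
          else read_volume(reference)$grid
  raw_all <- readBin(path, "raw", file.size(path))
  hdr_end <- .find_tck_end(raw_all)
  hdr <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\n", fixed = TRUE)[[1L]]
  if (!identical(hdr[1L], "mrtrix tracks"))
    stop("malformed TCK header at offset 0: missing 'mrtrix tracks' magic in ",
         path, call. = FALSE)
  fields <- hdr[grepl(":", hdr, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(fields, ":", fixed = TRUE))
  keys <- trimws(kv[, 1L]); vals <- trimws(kv[, 2L])
  dtype <- vals[match("datatype", keys)]
  endian <- switch(dtype,
                   Float32LE = "little", Float32BE = "big",
                   stop("unsupported TCK datatype: ", dtype, call. = FALSE))
  fileline <- vals[match("file", keys)]
  offset <- as.integer(sub("^\\.\\s+", "", fileline))
  n <- (length(raw_all) - offset) %/% 4L
  vals32 <- readBin(raw_all[(offset + 1L):length(raw_all)], "numeric", n,
                    size = 4L, endian = endian)
  pts <- matrix(vals32[seq_len((length(vals32) %/% 3L) * 3L)],
                ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(pts)) == 3L
  is_inf <- is.infinite(pts[, 1L]) & is.infinite(pts[, 2L]) &
            is.infinite(pts[, 3L])
  stop_at <- which(is_inf)
  if (length(stop_at) > 0L) pts <- pts[seq_len(stop_at[1L] - 1L), , drop = FALSE]
  is_nan <- rowSums(is.na(pts)) == 3L
  grp <- cumsum(c(TRUE, utils::head(is_nan, -1L)))
  keep <- !is_nan
  streamlines <- if (nrow(pts) == 0L) list() else
    lapply(split.data.frame(pts[keep, , drop = FALSE], grp[keep]), as.matrix)
  names(streamlines) <- NULL
  bundle(streamlines, grid = grid, label = label)
}

.find_tck_end <- function(raw_all) {
  marker <- charToRaw("END\n")
  limit <- min(length(raw_all), 4096L)
  for (i in seq_len(limit - 3L)) {
    if (identical(raw_all[i:(i + 3L)], marker)) return(i + 3L)
  }
  stop("malformed TCK header: END marker not found in first ", limit,
       " bytes", call. = FALSE)
}
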