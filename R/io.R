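# File formats: NIfTI images via RNifti, or delimited text grids with a
# sidecar spacing declaration.

isNiftiPath <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read a 2D image slice
#'
#' NIfTI files carry their pixel spacing in the header; a volume needs a
#' `slice` index (or a single-slice third dimension). Delimited text grids
#' (whitespace or comma separated) carry no metadata, so the spacing must
#' come either from the `spacing` argument or from a sidecar file
#' `<path>.spacing` holding `dx dy` in mm.
#'
#' @param path image file.
#' @param spacing optional `c(dx, dy)` in mm, overriding any sidecar.
#' @param slice optional 1-based slice index into a NIfTI volume.
#' @return A [PETSlice-class].
#' @export
readImageSlice <- function(path, spacing = NULL, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (isNiftiPath(path)) {
    img <- RNifti::readNifti(path)
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    arr <- array(as.vector(img), dim = dim(img))
    if (length(dim(arr)) == 3L) {
      if (is.null(slice)) {
        if (dim(arr)[3] != 1L)
          stop("volume has ", dim(arr)[3], " slices; pass a slice index")
        slice <- 1L
      }
      arr <- arr[, , slice]
    }
    if (length(dim(arr)) != 2L) stop("not a 2D slice")
    if (is.null(spacing)) spacing <- pd[1:2]
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
    arr <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                       comment.char = "#"))
    dimnames(arr) <- NULL
    if (!is.null(slice) && slice != 1L)
      stop("text grids hold a single slice")
    if (is.null(spacing)) {
      sidecar <- paste0(path, ".spacing")
      if (!file.exists(sidecar))
        stop("missing pixel spacing for text grid: pass spacing= or ",
             "provide the sidecar file ", sidecar)
      spacing <- scan(sidecar, quiet = TRUE)
    }
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  petSlice(arr, dx = spacing[1], dy = spacing[2])
}

#' Write a 2D image slice
#'
#' NIfTI output stores the spacing in the header; text output writes a
#' whitespace-delimited grid plus a `<path>.spacing` sidecar so the file
#' round-trips through [readImageSlice()].
#'
#' @param image a [PETSlice-class].
#' @param path destination; format chosen by extension (`.nii`/`.nii.gz`
#'   versus anything else as text).
#' @return `path`, invisibly.
#' @export
writeImageSlice <- function(image, path) {
  stopifnot(is(image, "PETSlice"))
  sp <- pixelSpacing(image)
  if (isNiftiPath(path)) {
    img <- RNifti::asNifti(intensityValues(image))
    RNifti::pixdim(img) <- c(sp[["dx"]], sp[["dy"]])
    RNifti::writeNifti(img, path)
  } else {
    utils::write.table(intensityValues(image), path, row.names = FALSE,
                       col.names = FALSE)
    writeLines(paste(sp[["dx"]], sp[["dy"]]),
               paste0(path, ".spacing"))
  }
  invisible(path)
}

#' Read / write a binary mask slice
#'
#' Masks use the same formats as images with values 0/1.
#'
#' @inheritParams readImageSlice
#' @return `readMaskSlice`: a logical matrix.
#' @export
readMaskSlice <- function(path, spacing = c(1, 1), slice = NULL) {
  intensityValues(readImageSlice(path, spacing = spacing, slice = slice)) != 0
}

#' @rdname readMaskSlice
#' @param mask logical matrix.
#' @param dx,dy spacing recorded in the output, mm.
#' @export
writeMaskSlice <- function(mask, path, dx = 4, dy = dx) {
  writeImageSlice(petSlice(asMask(mask) * 1, dx = dx, dy = dy), path)
}
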