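#' Read a label map configuration file
#'
#' The label map assigns a positive integer label value to each structure
#' name. YAML (`.yaml`/`.yml`) and JSON (`.json`) are supported; the file is
#' a flat mapping, e.g. `tumor: 1`, `SMA: 4`. All six required structures
#' (see [requiredStructures()]) must be declared; additional structures
#' (pancreas, aorta, ...) are allowed.
#'
#' @param path path to a YAML or JSON mapping file.
#' @return Named integer vector.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("label map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported label map format: .", ext, " (use YAML or JSON)"))
  if (!length(raw) || is.null(names(raw)))
    stop("label map must be a named mapping of structure -> integer")
  vals <- unlist(raw)
  if (any(vals != round(vals))) stop("label values must be integers")
  lm <- structure(as.integer(vals), names = names(raw))
  msg <- .validLabelMap(lm)
  if (length(msg)) stop(paste(msg, collapse = "; "))
  lm
}

#' Write a label map to YAML
#'
#' @param labelMap named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labelMap, path) {
  msg <- .validLabelMap(labelMap)
  if (length(msg)) stop(paste(msg, collapse = "; "))
  yaml::write_yaml(as.list(structure(as.integer(labelMap),
                                     names = names(labelMap))), path)
  invisible(path)
}

#' Load a 3D label volume from a NIfTI file
#'
#' Reads an integer-valued NIfTI-1 volume (`.nii` or `.nii.gz`), takes the
#' absolute per-axis spacing from the header, and keeps the voxel grid in the
#' file's native axis order (no reorientation). Every nonzero voxel value
#' must be declared in `labelMap`.
#'
#' @param path path to the NIfTI file.
#' @param labelMap named integer vector (see [readLabelMap()]), or a path to
#'   a label map file.
#' @return A [LabelVolume-class].
#' @examples
#' ph <- makeWrapPhantom(90, shape = c(32, 32, 32))
#' f <- tempfile(fileext = ".nii.gz")
#' writeLabelVolume(ph$volume, f)
#' vol <- readLabelVolume(f, labelMap(ph$volume))
#' identical(voxels(vol), voxels(ph$volume))
#' @export
readLabelVolume <- function(path, labelMap) {
  if (is.character(labelMap) && length(labelMap) == 1L &&
      file.exists(labelMap))
    labelMap <- readLabelMap(labelMap)
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop niftiImage attributes
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- arr[, , , 1L, drop = TRUE]
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("expected a 3D label volume, got ", length(d), " dimensions")
  if (is.double(arr) && any(arr != round(arr)))
    stop("non-integer voxel values: not a label volume")
  storage.mode(arr) <- "integer"
  sp <- abs(RNifti::pixdim(img)[1:3])
  vals <- unique(as.integer(arr))
  vals <- vals[vals != 0L]
  unknown <- setdiff(vals, unname(as.integer(labelMap)))
  if (length(unknown))
    stop("voxel value(s) not declared in label map: ",
         paste(sort(unknown), collapse = ", "))
  LabelVolume(arr, sp, labelMap)
}

#' Write a LabelVolume to NIfTI
#'
#' @param volume a [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; the default 16-bit integer fits any
#'   label mask.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(volume, path, datatype = "int16") {
  stopifnot(is(volume, "LabelVolume"))
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Extract one 2D slice from a label volume
#'
#' The plane orthogonal to `axis` at slice `index` (1-based). The in-plane
#' spacing is the pair of remaining spacing components in ascending axis
#' order, matching the matrix dimensions of the returned plane.
#'
#' @param volume a [LabelVolume-class].
#' @param axis 1, 2 or 3.
#' @param index 1-based slice position along `axis`.
#' @return A [LabelPlane-class].
#' @export
extractPlane <- function(volume, axis, index) {
  stopifnot(is(volume, "LabelVolume"))
  axis <- as.integer(axis)
  index <- as.integer(index)
  if (length(axis) != 1L || !(axis %in% 1:3)) stop("axis must be 1, 2 or 3")
  n <- dim(volume@voxels)[axis]
  if (length(index) != 1L || is.na(index) || index < 1L || index > n)
    stop("slice index ", index, " out of range [1, ", n, "] for axis ", axis)
  pix <- switch(axis,
    volume@voxels[index, , , drop = TRUE],
    volume@voxels[, index, , drop = TRUE],
    volume@voxels[, , index, drop = TRUE])
  new("LabelPlane", pixels = pix, spacing = volume@spacing[-axis],
      axis = axis, index = index)
}

.resolveLabel <- function(volume, label) {
  lm <- volume@labelMap
  if (is.character(label)) {
    if (!(label %in% names(lm)))
      stop("unknown structure name: ", label)
    return(unname(lm[label]))
  }
  label <- as.integer(label)
  if (!(label %in% lm))
    stop("label value ", label, " not declared in label map")
  label
}

## Per-axis slice presence of a logical 3D mask, without copying slices.
.presenceByAxis <- function(mask) {
  d <- dim(mask)
  list(
    rowSums(matrix(mask, d[1], d[2] * d[3])) > 0,
    colSums(matrix(aperm(mask, c(1, 3, 2)), d[1] * d[3], d[2])) > 0,
    colSums(matrix(mask, d[1] * d[2], d[3])) > 0)
}

#' Find all planes containing two labels simultaneously
#'
#' Sweeps all three grid axes and returns every (axis, index) pair whose
#' slice contains at least one voxel of each label. This is the plane set
#' the involvement quantifier measures ("all x, y and z planes containing
#' both the vessel and the tumor").
#'
#' @param volume a [LabelVolume-class].
#' @param labelA,labelB structure names or label values.
#' @return data.frame with columns `axis` and `index` (1-based).
#' @export
planesContaining <- function(volume, labelA, labelB) {
  stopifnot(is(volume, "LabelVolume"))
  la <- .resolveLabel(volume, labelA)
  lb <- .resolveLabel(volume, labelB)
  pa <- .presenceByAxis(volume@voxels == la)
  pb <- .presenceByAxis(volume@voxels == lb)
  out <- lapply(1:3, function(ax) {
    idx <- which(pa[[ax]] & pb[[ax]])
    if (length(idx)) data.frame(axis = ax, index = idx) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(axis = integer(), index = integer()) else out
}
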