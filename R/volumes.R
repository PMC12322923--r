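#' Voxel grid geometry
#'
#' A `voxel_grid` describes the geometry shared by all volumes in an
#' analysis: the array shape, the physical voxel spacing in millimetres,
#' and the physical position (mm) of the centre of voxel index (1,1,1).
#' All distances in the package are physical distances in mm derived from
#' the spacing, so results are resolution-independent.
#'
#' @param shape Integer vector of length 3, array dimensions (each >= 1).
#' @param spacing Numeric vector of length 3, mm per voxel along each axis
#'   (each > 0). Defaults to 0.45 mm isotropic, a typical high-resolution
#'   7 T acquisition.
#' @param origin Numeric vector of length 3, mm position of the first
#'   voxel centre.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(64, 64, 64))
voxel_grid <- function(shape, spacing = c(0.45, 0.45, 0.45), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  if (any(spacing <= 0)) stop("voxel spacing components must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Physical coordinates of voxel centres
#'
#' @param grid A [voxel_grid()].
#' @param index Integer matrix (n x 3) of 1-based voxel indices; if `NULL`,
#'   all voxel centres are returned in array (column-major) order.
#' @return Numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_centers <- function(grid, index = NULL) {
  if (is.null(index)) {
    index <- as.matrix(expand.grid(
      i = seq_len(grid$shape[1]),
      j = seq_len(grid$shape[2]),
      k = seq_len(grid$shape[3])
    ))
  }
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep(sweep(index - 1, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Labeled vessel volume
#'
#' A `labeled_volume` bundles a 3D integer array of vessel labels with its
#' grid geometry and a label map (vessel name -> integer id). Background is
#' 0. Label names must be drawn from the five canonical vessels, see
#' [vessel_labels()].
#'
#' @param voxels 3D integer array; 0 is background.
#' @param grid A [voxel_grid()] matching `dim(voxels)`.
#' @param labels Named integer vector mapping vessel name -> label id.
#'   Defaults to the canonical map restricted to ids present in `voxels`
#'   when all of those ids are canonical.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, grid, labels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop("voxel array shape does not match grid shape")
  if (is.double(voxels)) {
    if (any(voxels != round(voxels))) stop("label volume must contain integer data")
    storage.mode(voxels) <- "integer"
  }
  present <- sort(unique(as.vector(voxels)))
  present <- present[present != 0L]
  if (is.null(labels)) {
    if (!all(present %in% .CANONICAL_VESSELS))
      stop("voxel values outside the canonical label map; supply `labels`")
    labels <- .CANONICAL_VESSELS[.CANONICAL_VESSELS %in% present]
  }
  labels <- validate_label_map(labels)
  missing <- setdiff(present, labels)
  if (length(missing))
    stop("voxel value(s) ", paste(missing, collapse = ", "),
         " absent from label map")
  structure(list(voxels = voxels, grid = grid, labels = labels),
            class = "labeled_volume")
}

validate_label_map <- function(labels) {
  labels <- setNames(as.integer(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("label map must be a named integer vector (name -> id)")
  if (anyDuplicated(labels)) stop("duplicate ids in label map")
  if (anyDuplicated(names(labels))) stop("duplicate names in label map")
  if (any(labels == 0L)) stop("label id 0 is reserved for background")
  unknown <- setdiff(names(labels), names(.CANONICAL_VESSELS))
  if (length(unknown))
    stop("unknown vessel name(s): ", paste(unknown, collapse = ", "))
  labels
}

#' @export
print.labeled_volume <- function(x, ...) {
  print(x$grid)
  counts <- vapply(x$labels, function(id) sum(x$voxels == id), integer(1))
  cat("labels:\n")
  for (nm in names(x$labels))
    cat(sprintf("  %d = %-18s %d voxel(s)\n", x$labels[[nm]], nm, counts[[nm]]))
  invisible(x)
}

sform_matrix <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$spacing[1]
  m[2, 2] <- grid$spacing[2]
  m[3, 3] <- grid$spacing[3]
  m[1:3, 4] <- grid$origin
  m
}

grid_from_xform <- function(xf, shape) {
  # NIfTI-1 headers store geometry in single precision; snap to 6
  # significant digits so that e.g. a 0.45 mm spacing written as float32
  # reads back as exactly 0.45
  spacing <- signif(sqrt(colSums(xf[1:3, 1:3]^2)), 6)
  origin <- xf[1:3, 4]
  origin[origin != 0] <- signif(origin[origin != 0], 6)
  voxel_grid(shape, spacing = spacing, origin = origin)
}

label_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.json", path)
}

# plain 3D array (no image attributes); volumes with trailing singleton
# dimensions dropped by the reader are padded back to 3D
read_nifti_array <- function(img) {
  arr <- as.array(img)
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  array(as.vector(arr), dim = d)
}

#' Read a labeled volume from a NIfTI-1 file
#'
#' Voxel data must be integer-valued. The label map is taken from a JSON
#' sidecar file (`<stem>.labels.json`, an object of name -> id pairs) or
#' from the `labels` argument; `labels` wins when both are given.
#'
#' @param path Path to a `.nii` / `.nii.gz` file with integer data.
#' @param labels Optional named integer vector (vessel name -> id).
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, labels = NULL) {
  img <- RNifti::readNifti(path)
  arr <- read_nifti_array(img)
  if (any(arr != round(arr)))
    stop("file does not contain integer label data: ", path)
  storage.mode(arr) <- "integer"
  grid <- grid_from_xform(structure(RNifti::xform(img), dim = c(4, 4)),
                          dim(arr))
  if (is.null(labels)) {
    sidecar <- label_sidecar_path(path)
    if (file.exists(sidecar)) {
      labels <- unlist(jsonlite::read_json(sidecar))
    }
  }
  labeled_volume(arr, grid, labels = labels)
}

#' Write a labeled volume to a NIfTI-1 file
#'
#' Writes int32 voxel data with spacing and origin encoded in the sform,
#' plus a JSON label-map sidecar (`<stem>.labels.json`). A written volume
#' reads back identically (voxels, spacing, origin, labels).
#'
#' @param volume A [labeled_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(volume$voxels, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(sform_matrix(volume$grid), code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(volume$labels), label_sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read or write a binary mask volume
#'
#' Convenience wrappers around the labeled-volume I/O for region-of-
#' interest masks (0/1 volumes). The mask is returned as a logical array
#' with a `grid` attribute.
#'
#' @param path NIfTI path.
#' @return `read_mask_volume`: logical 3D array with attribute `grid`.
#' @export
read_mask_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- read_nifti_array(img)
  if (!all(arr %in% c(0, 1))) stop("mask volume must be binary: ", path)
  grid <- grid_from_xform(structure(RNifti::xform(img), dim = c(4, 4)),
                          dim(arr))
  structure(arr != 0, grid = grid)
}

#' @param mask Logical or 0/1 3D array.
#' @param grid A [voxel_grid()]; defaults to the mask's `grid` attribute.
#' @rdname read_mask_volume
#' @export
write_mask_volume <- function(mask, path, grid = attr(mask, "grid")) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- array(as.integer(mask != 0), dim = dim(mask))
  img <- RNifti::asNifti(arr, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(sform_matrix(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write hemisphere covariate tables
#'
#' Per-hemisphere records used by the thickness statistics: one row per
#' hemisphere and region with columns `subject`, `hemisphere` (left/right),
#' `age` (years), `sex` (female/male), `region`, `thickness_mm`.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_hemisphere_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "hemisphere", "age", "sex", "region", "thickness_mm")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("hemisphere table missing column(s): ", paste(missing, collapse = ", "))
  if (any(tab$age <= 0)) stop("ages must be positive")
  if (any(tab$thickness_mm <= 0)) stop("thickness values must be positive")
  tab
}

#' @param table Data frame as returned by [read_hemisphere_table()].
#' @rdname read_hemisphere_table
#' @export
write_hemisphere_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
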