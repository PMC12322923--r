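#' Left-right flip of a volume
#'
#' Mirrors a volume along the first (left-right) axis, the convention used
#' to bring right hemispheres onto a left-hemisphere template before label
#' fusion. The operation is involutive and preserves the voxel-count
#' histogram of every label, hence all supply fractions.
#'
#' @param volume A [labeled_volume()], or a plain 3D array.
#' @return The mirrored object, same class as the input.
#' @export
flip_lr <- function(volume) {
  if (inherits(volume, "labeled_volume")) {
    volume$voxels <- volume$voxels[rev(seq_len(dim(volume$voxels)[1])), , ,
                                   drop = FALSE]
    return(volume)
  }
  if (length(dim(volume)) != 3L) stop("expected a 3D array or labeled_volume")
  volume[rev(seq_len(dim(volume)[1])), , , drop = FALSE]
}

#' Assemble an aligned stack of parcellations
#'
#' Bundles hemisphere label volumes that already share one common grid into
#' a stack for fusion, flipping right-hemisphere volumes onto the
#' left-hemisphere convention.
#'
#' @param volumes List of [labeled_volume()] on an identical grid.
#' @param laterality Character vector (`"left"` / `"right"`), one per
#'   volume; right volumes are flipped with [flip_lr()].
#' @param pattern Optional `vessel_pattern` key for bookkeeping.
#' @return An object of class `aligned_stack`.
#' @export
align_stack <- function(volumes, laterality = rep("left", length(volumes)),
                        pattern = NULL) {
  if (length(volumes) < 1L) stop("empty stack")
  stopifnot(length(laterality) == length(volumes),
            all(laterality %in% c("left", "right")))
  g <- volumes[[1]]$grid
  for (v in volumes) {
    stopifnot(inherits(v, "labeled_volume"))
    if (!same_grid(v$grid, g)) stop("stack volumes are not on a common grid")
  }
  volumes <- mapply(function(v, lat) if (lat == "right") flip_lr(v) else v,
                    volumes, laterality, SIMPLIFY = FALSE)
  structure(list(volumes = volumes, pattern = pattern, grid = g),
            class = "aligned_stack")
}

#' Majority-vote label fusion
#'
#' Fuses a stack of co-registered territory parcellations into one atlas by
#' assigning each voxel the most frequent non-zero label across the stack.
#' Background never outvotes a present label: a voxel is labelled whenever
#' at least one volume labels it. Vote ties resolve to the smallest label
#' id, the package-wide tie convention.
#'
#' @param stack An [align_stack()] object, or a plain list of
#'   [labeled_volume()] on one grid.
#' @return An object of class `fused_atlas`: list with `volume` (a
#'   [labeled_volume()]), `votes` (4D array: label x grid, vote counts) and
#'   `support` (logical array, voxels with >= 1 vote).
#' @export
majority_vote <- function(stack) {
  if (!inherits(stack, "aligned_stack")) stack <- align_stack(stack)
  vols <- stack$volumes
  grid <- stack$grid
  ids <- sort(unique(unlist(lapply(vols, function(v) unname(v$labels)))))
  votes <- array(0L, dim = c(length(ids), grid$shape))
  for (v in vols) {
    for (k in seq_along(ids)) {
      votes[k, , , ] <- votes[k, , , ] + (v$voxels == ids[k])
    }
  }
  # winner: first (smallest) id attaining the per-voxel maximum vote count
  max_votes <- apply(votes, 2:4, max)
  fused <- array(0L, dim = grid$shape)
  for (k in rev(seq_along(ids))) {
    win <- votes[k, , , ] == max_votes & max_votes > 0L
    fused[win] <- ids[k]
  }
  support <- max_votes > 0L
  label_map <- .CANONICAL_VESSELS[.CANONICAL_VESSELS %in% ids]
  structure(list(volume = labeled_volume(fused, grid, labels = label_map),
                 votes = votes, vote_ids = ids, support = support),
            class = "fused_atlas")
}

#' @export
print.fused_atlas <- function(x, ...) {
  cat("<fused_atlas>\n")
  print(x$volume)
  cat(sprintf("support: %d voxel(s)\n", sum(x$support)))
  invisible(x)
}

#' Voxel-wise mean distance atlas
#'
#' Averages co-registered vessel distance maps voxel by voxel. Maps flagged
#' empty (absent vessel) are excluded, with per-voxel count bookkeeping, so
#' the average at each voxel is over the hemispheres in which the vessel
#' exists.
#'
#' @param maps List of `distance_map` objects on one common grid.
#' @return A `distance_map` whose `values` are the voxel-wise means (`NaN`
#'   where no valid map contributes), with an extra `n_maps` field giving
#'   the per-voxel contributing count.
#' @export
mean_distance_atlas <- function(maps) {
  if (length(maps) < 1L) stop("no distance maps supplied")
  g <- maps[[1]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "distance_map"))
    if (!same_grid(m$grid, g)) stop("distance maps are not on a common grid")
  }
  valid <- maps[!vapply(maps, `[[`, logical(1), "empty")]
  if (length(valid) == 0L) stop("all distance maps are empty")
  acc <- array(0, dim = g$shape)
  n <- array(0L, dim = g$shape)
  for (m in valid) {
    ok <- is.finite(m$values)
    acc[ok] <- acc[ok] + m$values[ok]
    n <- n + ok
  }
  values <- acc / n
  structure(list(values = values, grid = g, vessel = maps[[1]]$vessel,
                 vessel_name = maps[[1]]$vessel_name, empty = FALSE,
                 n_maps = n),
            class = "distance_map")
}

#' Fuse ROI masks by voting
#'
#' Merges co-registered binary ROI masks into one representative mask: a
#' voxel belongs to the fused ROI when at least half of the input masks
#' contain it (exact 50% included).
#'
#' @param masks List of logical / 0-1 3D arrays of identical shape.
#' @return Logical 3D array.
#' @export
fuse_roi_masks <- function(masks) {
  if (length(masks) < 1L) stop("no masks supplied")
  d <- dim(masks[[1]])
  acc <- array(0L, dim = d)
  for (m in masks) {
    if (!identical(dim(m), d)) stop("masks are not on a common grid")
    acc <- acc + (m != 0)
  }
  acc >= length(masks) / 2
}
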