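#' Phantom configuration
#'
#' Describes a synthetic hemisphere: a curved cortical sheet (a section of
#' a cylindrical shell, mimicking a gyrus-like ribbon of gray matter) plus
#' up to five vessel centreline curves (ordered 3D control points in mm,
#' treated as polylines) running just outside the sheet, mimicking pial
#' arteries. Each vessel can be marked absent to produce 3- to 5-vessel
#' supply patterns.
#'
#' @param grid A [voxel_grid()].
#' @param cortex List with `center` (mm, 3-vector: cylinder axis position
#'   in the x-y plane; the axis runs along z), `radius` (inner radius, mm),
#'   `thickness` (mm, > 0), `angle_start` and `angle_extent` (radians), and
#'   `z_range` (mm, length 2).
#' @param vessels Named list: for each canonical vessel name, a list with
#'   `points` (3 x m matrix of mm control points, m >= 2) and `present`
#'   (logical).
#' @param raster_radius Rasterisation radius in mm: voxels whose centres
#'   lie within this distance of a present vessel's polyline receive the
#'   vessel's label. Default: one voxel (first-axis spacing), emulating
#'   voxelised manual centreline delineations.
#' @param seed Integer seed (reserved for randomised configs).
#' @return An object of class `phantom_config`.
#' @seealso [default_phantom_config()] for a ready-made geometry.
#' @export
phantom_config <- function(grid, cortex, vessels,
                           raster_radius = grid$spacing[1], seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  need <- c("center", "radius", "thickness", "angle_start", "angle_extent",
            "z_range")
  missing <- setdiff(need, names(cortex))
  if (length(missing))
    stop("cortex spec missing: ", paste(missing, collapse = ", "))
  if (cortex$thickness <= 0) stop("cortex thickness must be > 0")
  unknown <- setdiff(names(vessels), names(.CANONICAL_VESSELS))
  if (length(unknown))
    stop("unknown vessel name(s): ", paste(unknown, collapse = ", "))
  present <- vapply(vessels, function(v) isTRUE(v$present), logical(1))
  if (!any(present)) stop("at least one vessel must be present")
  for (nm in names(vessels)) {
    p <- vessels[[nm]]$points
    if (!is.matrix(p) || nrow(p) != 3L || ncol(p) < 2L)
      stop("vessel '", nm, "' needs a 3 x m control-point matrix with m >= 2")
  }
  structure(list(grid = grid, cortex = cortex, vessels = vessels,
                 raster_radius = raster_radius, seed = as.integer(seed)),
            class = "phantom_config")
}

arc_points <- function(center, radius, angle, z, n = 33) {
  # polyline along the cylinder axis at a fixed angle (a "longitudinal"
  # pial artery course); slight sinusoidal angular wobble keeps the
  # geometry non-degenerate without moving the mean course
  t <- seq(0, 1, length.out = n)
  a <- angle + 0.015 * sin(2 * pi * t)
  rbind(center[1] + radius * cos(a),
        center[2] + radius * sin(a),
        z[1] + t * (z[2] - z[1]))
}

#' Default phantom geometry
#'
#' A ready-made [phantom_config()]: a 120-degree cylindrical-shell cortex
#' section with the five canonical vessels as parallel longitudinal curves
#' offset 2 mm outside the sheet, spread over the angular extent in
#' canonical order. With all five present each vessel owns an angular wedge
#' of the cortex; marking vessels absent lets the neighbours absorb the
#' wedge, emulating the 3- to 5-vessel patterns seen in real hemispheres.
#'
#' @param present Named logical vector over the canonical vessel names (or
#'   a character vector of present vessel names).
#' @param n Grid size per axis (default 64).
#' @param spacing Isotropic voxel spacing in mm (default 0.45).
#' @param seed Integer seed.
#' @param angles Optional numeric vector (radians, length 5) of vessel
#'   angular positions; defaults to equally spaced positions inside the
#'   sheet's angular extent.
#' @return A `phantom_config`.
#' @export
#' @examples
#' cfg <- default_phantom_config(c("pericallosa", "precentral", "central"))
default_phantom_config <- function(present = names(vessel_labels()),
                                   n = 64, spacing = 0.45, seed = 1L,
                                   angles = NULL) {
  if (is.character(present)) {
    unknown <- setdiff(present, names(.CANONICAL_VESSELS))
    if (length(unknown))
      stop("unknown vessel name(s): ", paste(unknown, collapse = ", "))
    present <- setNames(names(.CANONICAL_VESSELS) %in% present,
                        names(.CANONICAL_VESSELS))
  }
  grid <- voxel_grid(c(n, n, n), spacing = rep(spacing, 3))
  extent_mm <- (n - 1) * spacing
  center <- c(extent_mm / 2, 0, 0)
  radius <- 0.38 * extent_mm
  thickness <- 2.5                      # gray-matter-like sheet, mm
  angle_start <- pi / 2 - pi / 3        # 120 degrees, centred on +y
  angle_extent <- 2 * pi / 3
  z_range <- c(0.15, 0.85) * extent_mm
  cortex <- list(center = center, radius = radius, thickness = thickness,
                 angle_start = angle_start, angle_extent = angle_extent,
                 z_range = z_range)
  if (is.null(angles)) {
    angles <- angle_start + angle_extent * seq(0.1, 0.9, length.out = 5)
  }
  vessel_radius <- radius + thickness + 2  # 2 mm outside the pial surface
  vessels <- list()
  for (i in seq_along(.CANONICAL_VESSELS)) {
    nm <- names(.CANONICAL_VESSELS)[i]
    vessels[[nm]] <- list(
      points = arc_points(center, vessel_radius, angles[i], z_range),
      present = isTRUE(present[[nm]])
    )
  }
  phantom_config(grid, cortex, vessels, seed = seed)
}

cortex_mask <- function(grid, cortex) {
  xyz <- voxel_centers(grid)
  dx <- xyz[, 1] - cortex$center[1]
  dy <- xyz[, 2] - cortex$center[2]
  r <- sqrt(dx^2 + dy^2)
  a <- atan2(dy, dx) %% (2 * pi)
  a0 <- cortex$angle_start %% (2 * pi)
  rel <- (a - a0) %% (2 * pi)
  inside <- r >= cortex$radius & r <= cortex$radius + cortex$thickness &
    rel <= cortex$angle_extent &
    xyz[, 3] >= cortex$z_range[1] & xyz[, 3] <= cortex$z_range[2]
  array(inside, dim = grid$shape)
}

#' Generate a synthetic hemisphere phantom
#'
#' Rasterises the configured vessel polylines onto the grid (a voxel
#' carries a vessel's label when its centre lies within the rasterisation
#' radius of the curve; overlaps resolve to the smallest label id),
#' computes the cortical ROI mask, and derives the analytic ground truth:
#' each ROI voxel centre is assigned the present vessel whose continuous
#' polyline is nearest (exact point-to-segment distances, independent of
#' any voxel distance transform), giving expected supply fractions.
#'
#' @param config A [phantom_config()].
#' @return List with components `volume` (a [labeled_volume()] of the
#'   rasterised vessels), `roi` (logical array), and `truth` (class
#'   `phantom_truth`: `territory` label array over the ROI, `fractions`
#'   — a [supply_record()] — and `present` vessel names).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  roi <- cortex_mask(grid, config$cortex)
  if (!any(roi)) stop("cortex sheet does not intersect the grid")

  present <- names(config$vessels)[
    vapply(config$vessels, function(v) isTRUE(v$present), logical(1))]
  present <- intersect(names(.CANONICAL_VESSELS), present)  # canonical order

  voxels <- array(0L, dim = grid$shape)
  # descending id so overlaps end up with the smallest id
  for (nm in rev(present)) {
    pts <- config$vessels[[nm]]$points
    # only voxels inside the curve's bounding box (+ radius) can be hit
    lo <- pmax(1L, ceiling((apply(pts, 1, min) - config$raster_radius -
                              grid$origin) / grid$spacing) + 1L)
    hi <- pmin(grid$shape, floor((apply(pts, 1, max) + config$raster_radius -
                                    grid$origin) / grid$spacing) + 1L)
    if (any(lo > hi)) {
      warning("vessel '", nm, "' rasterises to zero voxels (outside grid?)")
      next
    }
    idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                 k = lo[3]:hi[3]))
    d <- .polyline_dist(voxel_centers(grid, idx), pts)
    hit <- idx[d <= config$raster_radius, , drop = FALSE]
    if (nrow(hit) == 0L) {
      warning("vessel '", nm, "' rasterises to zero voxels (outside grid?)")
      next
    }
    voxels[hit] <- .CANONICAL_VESSELS[[nm]]
  }
  labels <- .CANONICAL_VESSELS[present]
  volume <- labeled_volume(voxels, grid, labels = labels)

  # analytic truth: nearest continuous polyline per ROI voxel centre
  roi_idx <- which(roi)
  roi_xyz <- voxel_centers(grid, arrayInd(roi_idx, grid$shape))
  dmat <- vapply(present, function(nm)
    .polyline_dist(roi_xyz, config$vessels[[nm]]$points),
    numeric(length(roi_idx)))
  dmat <- matrix(dmat, ncol = length(present))
  winner <- present[max.col(-dmat, ties.method = "first")]
  territory <- array(0L, dim = grid$shape)
  territory[roi_idx] <- .CANONICAL_VESSELS[winner]
  counts <- vapply(present, function(nm) sum(winner == nm), numeric(1))
  truth <- structure(
    list(territory = territory,
         fractions = supply_record(counts / length(roi_idx),
                                   roi_voxels = length(roi_idx),
                                   roi_volume_mm3 = length(roi_idx) *
                                     prod(grid$spacing)),
         present = present),
    class = "phantom_truth")
  list(volume = volume, roi = roi, truth = truth)
}

#' Cohort configuration
#'
#' Specifies a synthetic cohort of hemispheres: how many, which vessel
#' patterns (a map from pattern to count), and a linear model for mean
#' cortical thickness with known sex and age effects plus Gaussian noise.
#'
#' @param pattern_mix Named integer vector mapping pattern -> count. Names
#'   are either vessel counts (`"3"`, `"4"`, `"5"`, resolved to canonical
#'   compositions: one ACA branch + precentral + central for 3;
#'   both ACA branches + precentral + central for 4; all five for 5) or
#'   explicit compositions such as `"pericallosa+precentral+central"`.
#' @param thickness List with `intercept` (mm), `sex_effect` (mm, added for
#'   males), `age_slope` (mm/year), `noise_sd` (mm, >= 0). The defaults
#'   emulate a young healthy cohort: baseline near 2.7 mm, a strong sex
#'   difference, a weak negative age slope, and residual scatter of
#'   0.055 mm.
#' @param age_range Years, uniform sampling range for ages.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param grid_n,spacing Phantom grid size and spacing passed to
#'   [default_phantom_config()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(pattern_mix = c(`3` = 10L, `4` = 19L, `5` = 9L),
                          thickness = list(intercept = 2.75,
                                           sex_effect = -0.09,
                                           age_slope = -0.005,
                                           noise_sd = 0.055),
                          age_range = c(22, 45), seed = 1L,
                          grid_n = 64, spacing = 0.45) {
  if (is.null(names(pattern_mix)) || any(!nzchar(names(pattern_mix))))
    stop("pattern_mix must be a named vector (pattern -> count)")
  if (any(pattern_mix < 0) || sum(pattern_mix) < 1)
    stop("pattern counts must be non-negative and sum to >= 1")
  if (thickness$noise_sd < 0) stop("noise_sd must be >= 0")
  # resolve and validate compositions now so infeasible patterns fail fast
  comps <- lapply(seq_along(pattern_mix), function(i)
    resolve_pattern_composition(names(pattern_mix)[i], i))
  structure(list(pattern_mix = pattern_mix, compositions = comps,
                 thickness = thickness, age_range = age_range,
                 seed = as.integer(seed), grid_n = grid_n,
                 spacing = spacing),
            class = "cohort_config")
}

resolve_pattern_composition <- function(key, alt = 1L) {
  if (grepl("^[0-9]+$", key)) {
    count <- as.integer(key)
    if (count < 1L || count > 5L)
      stop("pattern count must be between 1 and 5: ", key)
    return(switch(as.character(count),
      `1` = c("central"),
      `2` = c("precentral", "central"),
      # alternate the ACA branch for 3-vessel patterns across mix entries
      `3` = c(if (alt %% 2 == 1L) "pericallosa" else "callosomarginalis",
              "precentral", "central"),
      `4` = c("pericallosa", "callosomarginalis", "precentral", "central"),
      `5` = names(.CANONICAL_VESSELS)))
  }
  comp <- strsplit(key, "+", fixed = TRUE)[[1]]
  unknown <- setdiff(comp, names(.CANONICAL_VESSELS))
  if (length(unknown))
    stop("infeasible pattern '", key, "': unknown vessel(s) ",
         paste(unknown, collapse = ", "))
  if (length(comp) == 0L) stop("infeasible pattern: empty composition")
  intersect(names(.CANONICAL_VESSELS), comp)
}

#' Simulate a cohort covariate table
#'
#' Draws the per-hemisphere covariates (age, sex, laterality) and mean
#' thickness values for a [cohort_config()] without generating any image
#' volumes — useful when only the statistics are under study. Thickness is
#' linear in the covariates: `intercept + sex_effect * male +
#' age_slope * age + N(0, noise_sd)`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per hemisphere: `subject`, `hemisphere`,
#'   `age`, `sex`, `region`, `thickness_mm`, `pattern` (vessel count) and
#'   `composition`.
#' @export
simulate_cohort_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- sum(config$pattern_mix)
  set.seed(config$seed)
  comp_per_hemi <- rep(seq_along(config$pattern_mix), config$pattern_mix)
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("female", "male"), n, replace = TRUE)
  hemi <- rep(c("left", "right"), length.out = n)
  th <- config$thickness
  thickness <- th$intercept + th$sex_effect * (sex == "male") +
    th$age_slope * age +
    if (th$noise_sd > 0) rnorm(n, 0, th$noise_sd) else 0
  comps <- config$compositions[comp_per_hemi]
  data.frame(
    subject = sprintf("phantom%02d", seq_len(n)),
    hemisphere = hemi,
    age = age,
    sex = sex,
    region = "motor",
    thickness_mm = thickness,
    pattern = vapply(comps, length, integer(1)),
    composition = vapply(comps, paste, character(1), collapse = "+"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort of hemisphere phantoms
#'
#' Generates one phantom per hemisphere following the configured pattern
#' mix, together with the index-aligned covariate table from
#' [simulate_cohort_table()]. Deterministic for a given seed.
#'
#' @param config A [cohort_config()].
#' @return List with `phantoms` (list of [generate_phantom()] results) and
#'   `table` (data frame, rows aligned with `phantoms`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  table <- simulate_cohort_table(config)
  comp_per_hemi <- rep(seq_along(config$pattern_mix), config$pattern_mix)
  phantoms <- lapply(seq_len(nrow(table)), function(i) {
    comp <- config$compositions[[comp_per_hemi[i]]]
    cfg <- default_phantom_config(comp, n = config$grid_n,
                                  spacing = config$spacing,
                                  seed = config$seed + i)
    generate_phantom(cfg)
  })
  list(phantoms = phantoms, table = table)
}
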