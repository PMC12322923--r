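# Independent brute-force oracles used across the suite. These deliberately
# avoid every code path of the implementation they check: plain R loops over
# voxel centres and pairwise distances.

# minimum pairwise Euclidean distance (mm) from every voxel centre to the
# voxels carrying `id`
bf_distance <- function(volume, id) {
  g <- volume$grid
  src_idx <- which(volume$voxels == id, arr.ind = TRUE)
  if (nrow(src_idx) == 0L) return(array(Inf, dim = g$shape))
  src <- t(sweep(sweep(src_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+"))
  all_idx <- as.matrix(expand.grid(i = seq_len(g$shape[1]),
                                   j = seq_len(g$shape[2]),
                                   k = seq_len(g$shape[3])))
  xyz <- sweep(sweep(all_idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  d <- apply(xyz, 1, function(p) min(sqrt(colSums((src - p)^2))))
  array(d, dim = g$shape)
}

# TRUE when a parcellation agrees with the brute-force winner-takes-all
# rule: wherever a unique nearest vessel exists (distance gap > tol) the
# labels must be identical; at (near-)ties the assigned label only has to
# be one of the near-minimal vessels, since a tie at floating-point
# precision is not reproducibly ordered by any algorithm.
bf_parcellation_ok <- function(volume, roi, parc, tol = 1e-9) {
  ids <- sort(unname(volume$labels))
  maps <- lapply(ids, function(id) bf_distance(volume, id))
  roi_lin <- which(roi != 0)
  d <- vapply(maps, function(m) m[roi_lin], numeric(length(roi_lin)))
  d <- matrix(d, ncol = length(ids))
  dmin <- do.call(pmin, as.data.frame(d))
  near <- d <= dmin + tol
  lab <- parc$labels[roi_lin]
  unique_win <- rowSums(near) == 1L
  ok_unique <- lab[unique_win] ==
    ids[apply(near[unique_win, , drop = FALSE], 1, which)]
  ok_tie <- vapply(which(!unique_win), function(r)
    lab[r] %in% ids[near[r, ]], logical(1))
  all(ok_unique) && all(ok_tie) && all(parc$labels[-roi_lin] == 0L)
}

# per-voxel mode of non-zero labels; ties -> smallest label
bf_mode_fusion <- function(arrays) {
  d <- dim(arrays[[1]])
  out <- array(0L, dim = d)
  for (lin in seq_len(prod(d))) {
    vals <- vapply(arrays, function(a) a[lin], integer(1))
    vals <- vals[vals != 0L]
    if (length(vals) == 0L) next
    tab <- table(vals)
    best <- as.integer(names(tab)[tab == max(tab)])
    out[lin] <- min(best)
  }
  out
}

# a small labeled volume with random sparse vessels (guaranteed non-empty)
random_sparse_volume <- function(shape, spacing, n_vessels = 3,
                                 density = 0.04) {
  v <- array(0L, dim = shape)
  n <- prod(shape)
  for (id in seq_len(n_vessels)) {
    k <- max(1L, round(density * n / n_vessels))
    v[sample(n, k)] <- id
  }
  labels <- vessel_labels()[seq_len(n_vessels)]
  labeled_volume(v, voxel_grid(shape, spacing = spacing), labels = labels)
}

# straight-line two-vessel phantom, exactly mirror-symmetric about the
# mid-plane of the grid along x
symmetric_two_vessel_config <- function(n = 64, spacing = 0.45) {
  grid <- voxel_grid(c(n, n, n), spacing = rep(spacing, 3))
  L <- (n - 1) * spacing
  mid <- L / 2
  off <- 0.3 * L
  line <- function(x) rbind(c(x, x), c(0.85 * L, 0.85 * L), c(0.1 * L, 0.9 * L))
  cortex <- list(center = c(mid, 0, 0), radius = 0.38 * L, thickness = 2.5,
                 angle_start = pi / 2 - pi / 3, angle_extent = 2 * pi / 3,
                 z_range = c(0.15, 0.85) * L)
  phantom_config(grid, cortex, vessels = list(
    pericallosa = list(points = line(mid - off), present = TRUE),
    callosomarginalis = list(points = line(mid + off), present = TRUE)
  ))
}
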