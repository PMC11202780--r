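# Shared fixture machinery: cohorts are generated once per test session in
# tempdir() and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, spec) {
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("ctsurv-", key))
    man <- if (dir.exists(dir)) read_manifest(dir) else make_cohort(spec, dir)
    .fixture_cache[[key]] <- list(dir = dir, manifest = man)
  }
  .fixture_cache[[key]]
}

# a tumor_mask built from an axis-aligned square (uses the package's own
# constructor so area/bbox/centroid stay consistent)
mk_square_mask <- function(uid, side, dim = 64L, at = c(10L, 10L)) {
  m <- matrix(FALSE, dim, dim)
  if (side > 0)
    m[at[1]:(at[1] + side - 1L), at[2]:(at[2] + side - 1L)] <- TRUE
  ctsurv:::.new_tumor_mask(uid, m)
}

disk_mask <- function(dim, r, cx = dim / 2, cy = dim / 2) {
  g <- expand.grid(row = seq_len(dim), col = seq_len(dim))
  m <- matrix((g$row - cx)^2 + (g$col - cy)^2 <= r^2, dim, dim)
  ctsurv:::.new_tumor_mask(NA_character_, m)
}

mask_stack <- function(masks, patient_id = "TEST") {
  structure(list(patient_id = patient_id, masks = masks),
            class = "tumor_mask_stack")
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force even-odd point-in-polygon oracle: per-pixel scalar test,
# independent of the vectorized production rasterizer.
pip_naive_mask <- function(px, py, nrow, ncol, eps = 1e-9) {
  n <- length(px)
  seg_d2 <- function(x, y, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 == 0) return((x - x1)^2 + (y - y1)^2)
    t <- min(1, max(0, ((x - x1) * dx + (y - y1) * dy) / L2))
    (x - x1 - t * dx)^2 + (y - y1 - t * dy)^2
  }
  mask <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    for (cc in seq_len(ncol)) {
      x <- cc - 1; y <- r - 1
      crossings <- 0L; boundary <- FALSE
      for (j in seq_len(n)) {
        jn <- if (j == n) 1L else j + 1L
        x1 <- px[j]; y1 <- py[j]; x2 <- px[jn]; y2 <- py[jn]
        if ((y1 > y) != (y2 > y)) {
          xi <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
          if (x < xi) crossings <- crossings + 1L
        }
        if (seg_d2(x, y, x1, y1, x2, y2) <= eps * eps) boundary <- TRUE
      }
      mask[r, cc] <- (crossings %% 2L == 1L) || boundary
    }
  }
  mask
}

random_polygon <- function(n_vertices, lim) {
  # star-shaped random polygon: random radii around a random centre
  cx <- runif(1, lim * 0.3, lim * 0.7)
  cy <- runif(1, lim * 0.3, lim * 0.7)
  t <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, lim * 0.05, lim * 0.4)
  list(x = cx + r * cos(t), y = cy + r * sin(t))
}

# an in-memory ct_series with synthetic pixel content (bypasses disk I/O
# for geometry-only tests)
mk_series <- function(pixel_arrays, z = seq_along(pixel_arrays) * 3,
                      spacing = 1, thickness = 3, origin = c(0, 0),
                      patient_id = "TEST") {
  slices <- lapply(seq_along(pixel_arrays), function(i) {
    structure(list(
      sop_instance_uid = paste0("uid.", i),
      z_position = z[i], rescale_slope = 1, rescale_intercept = 0,
      slice_thickness = thickness, pixel_spacing = c(spacing, spacing),
      image_position = c(origin[1], origin[2], z[i]),
      pixel_array = pixel_arrays[[i]]
    ), class = "slice_meta")
  })
  structure(list(patient_id = patient_id, slices = slices),
            class = "ct_series")
}

separable_task <- function(n = 80L, dim = 32L, depth = 5L, seed = 1L) {
  set.seed(seed)
  labs <- rep(c(0, 1), each = n / 2)
  xs <- lapply(labs, function(y) {
    v <- array(runif(dim * dim * depth, 0, 0.3), c(dim, dim, depth))
    if (y == 1) v[12:20, 12:20, 2:4] <- v[12:20, 12:20, 2:4] + 0.6
    v
  })
  list(stacks = xs, labels = labs)
}
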