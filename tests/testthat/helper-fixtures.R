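# programmatic fixtures shared across tests

# label volume of an analytic solid digitized at voxel centers placed at
# half-offsets so shapes with even mm extents digitize symmetrically
digitize_solid <- function(inside_fun, extent, spacing) {
  n <- as.integer(round(2 * extent / spacing))
  ax <- ((seq_len(n) - 1) + 0.5) * spacing - extent
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  label_volume(array(as.integer(inside_fun(X, Y, Z)), dim = c(n, n, n)),
               rep(spacing, 3))
}

ball_volume <- function(r, spacing, extent = r + 6 * spacing) {
  digitize_solid(function(X, Y, Z) X^2 + Y^2 + Z^2 <= r^2, extent, spacing)
}

cuboid_volume <- function(side, spacing, extent = side / 2 + 6 * spacing) {
  digitize_solid(function(X, Y, Z) {
    abs(X) < side / 2 & abs(Y) < side / 2 & abs(Z) < side / 2
  }, extent, spacing)
}

# a small closed toy mesh: regular octahedron (6 vertices, 8 faces)
octahedron_mesh <- function(scale = 1) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1)) * scale
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  surface_mesh(v, f)
}

# deterministic GEE fixture; statsmodels oracle values frozen in test-gee.R
gee_fixture <- function() {
  set.seed(42)
  n_sub <- 30
  sub <- sprintf("s%02d", 1:n_sub)
  two <- rep(c(TRUE, FALSE), length.out = n_sub)
  df <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    k <- if (two[i]) 2 else 1
    data.frame(subject_id = sub[i], ga = round(runif(k, 20, 38), 3),
               sex = sample(c(0, 1), k, replace = TRUE),
               cohort = as.numeric(i > n_sub / 2))
  }))
  re <- rnorm(n_sub)[match(df$subject_id, sub)]
  df$y <- round(5 + 0.8 * df$ga - 2 * df$cohort + 0.5 * df$sex + 2 * re +
                  rnorm(nrow(df)), 4)
  df
}

# brute-force BH step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[ord[i]] <- min(sorted[i:m] * m / (i:m), 1)
  }
  q
}

small_phantom_spec <- function(A, r = 20, spacing = 1.25, freq = 6) {
  phantom_spec(wm_radius = r, fold_amplitude = A, fold_frequency = freq,
               cgm_thickness = 2.5, spacing = rep(spacing, 3))
}

junction_labels <- function() {
  segmentation_labels()[c("wm", "dgm", "hippocampus", "ventricles")]
}
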