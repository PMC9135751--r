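test_that("vertex areas partition the mesh area", {
  mesh <- octahedron_mesh(3)
  expect_equal(sum(vertex_areas(mesh)), mesh_area(mesh))
  ph_mesh <- extract_junction_mesh(ball_volume(10, 1.25), 1L)
  expect_equal(sum(vertex_areas(ph_mesh)), mesh_area(ph_mesh))
})

test_that("lobe areas follow the triangle-majority rule and conserve area", {
  # cuboid bisected by a coordinate plane into two regions
  seg <- cuboid_volume(16, 1)
  mesh <- extract_junction_mesh(seg, 1L)
  d <- dim(seg$data)
  parc <- array(0L, dim = d)
  half <- seq_len(d[1]) <= d[1] / 2
  parc[half, , ] <- 1L   # frontal (left)
  parc[!half, , ] <- 2L  # parietal (left)
  mesh <- assign_regions(mesh, label_volume(parc, seg$spacing))
  mesh$hemisphere <- rep("left", nrow(mesh$vertices))
  la <- lobe_surface_area(mesh)
  tot <- mesh_area(mesh)
  expect_equal(sum(la$area_mm2), tot)
  # each half of a bisected cuboid carries half the area (one extra face each)
  expect_equal(la$area_mm2[la$lobe == "frontal"], tot / 2, tolerance = 0.02)

  # uniform single-lobe mesh: lobe area equals total area
  mesh1 <- mesh
  mesh1$region <- rep(3L, nrow(mesh$vertices))  # temporal
  la1 <- lobe_surface_area(mesh1)
  expect_equal(la1$area_mm2[la1$lobe == "temporal"], tot)
  expect_true(all(la1$area_mm2[la1$lobe != "temporal"] == 0))

  expect_error(lobe_surface_area(octahedron_mesh()), "no regions")
})

test_that("sphere split into hemispheric regions yields equal halves", {
  seg <- ball_volume(15, 1)
  mesh <- extract_junction_mesh(seg, 1L)
  d <- dim(seg$data)
  parc <- array(0L, dim = d)
  parc[seq_len(d[1]) <= d[1] / 2, , ] <- 1L
  parc[seq_len(d[1]) > d[1] / 2, , ] <- 11L  # same lobe, right hemisphere
  mesh <- assign_regions(mesh, label_volume(parc, seg$spacing))
  la <- lobe_surface_area(mesh)
  fr <- la$area_mm2[la$lobe == "frontal"]
  expect_equal(fr[1], mesh_area(mesh) / 2, tolerance = 0.02)
  expect_equal(fr[2], mesh_area(mesh) / 2, tolerance = 0.02)
})

test_that("geodesic patch areas match an exhaustive shortest-path oracle", {
  mesh <- extract_junction_mesh(ball_volume(8, 2), 1L)
  radius <- 6
  g <- mesh_geodesic_graph(mesh, chord_ring = 3)
  got <- geodesic_patch_areas(mesh, radius, graph = g)
  # independent oracle: igraph all-pairs shortest paths over the same graph
  ig <- igraph::graph_from_edgelist(cbind(g$i, g$j), directed = FALSE)
  igraph::E(ig)$weight <- g$w
  dmat <- igraph::distances(ig)
  va <- vertex_areas(mesh)
  want <- vapply(seq_len(nrow(mesh$vertices)), function(v) {
    sum(va[dmat[v, ] <= radius])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("LGI is ~1 on a convex surface and increases with folding", {
  mesh <- extract_junction_mesh(ball_volume(18, 1), 1L)
  hull <- convex_hull_mesh(mesh, "all")
  lg <- local_gyrification_index(mesh, hull, lgi_params(patch_radius = 8))
  expect_true(all(lg$lgi > 0.95 & lg$lgi < 1.05))
  expect_true(all(lg$lgi > 0))

  # radius below 3x mean edge length is rejected
  expect_error(
    local_gyrification_index(mesh, hull, lgi_params(patch_radius = 0.6)),
    "patch_radius"
  )
})

test_that("sulcal depth is zero on hull vertices and exact for a planar lid", {
  mesh <- extract_junction_mesh(ball_volume(15, 1.25), 1L)
  hull <- convex_hull_mesh(mesh, "left")
  dp <- sulcal_depth(mesh, hull)
  expect_true(all(dp$depth >= 0))
  # vertices that are themselves hull vertices sit at depth ~0
  hv <- do.call(paste, as.data.frame(hull$vertices))
  mv <- do.call(paste, as.data.frame(mesh$vertices[dp$vertex, , drop = FALSE]))
  expect_gt(sum(mv %in% hv), 0)
  expect_lt(max(dp$depth[mv %in% hv]), 1e-9)

  # hemisphere mismatch errors
  mesh_r <- mesh
  mesh_r$hemisphere <- rep("right", nrow(mesh$vertices))
  hull_l <- hull
  expect_error(sulcal_depth(mesh_r, hull_l), "hemisphere")
})

test_that("a radial pit's depth matches its construction ground truth", {
  # cos^2 pit with an exact planar rim: expected hull distance of the pit
  # bottom is depth - R (1 - cos(angular_radius))
  R <- 22; d <- 10; sig <- 0.45
  spec <- phantom_spec(wm_radius = R, fold_amplitude = 0, cgm_thickness = 2.5,
                       spacing = c(1, 1, 1),
                       pit = list(depth = d, angular_radius = sig,
                                  direction = c(1, 0, 0)))
  ph <- make_phantom(spec)
  mesh <- extract_junction_mesh(ph$segmentation, junction_labels())
  hull <- convex_hull_mesh(mesh, "right")
  dp <- sulcal_depth(mesh, hull)
  expected <- d - R * (1 - cos(sig))
  expect_equal(max(dp$depth), expected, tolerance = 0.05)
})

test_that("feature aggregation weights by associated area and conserves area", {
  # 3-triangle toy mesh with hand-assigned values and weights
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0), c(4, 0, 0))
  f <- rbind(c(1, 2, 3), c(2, 4, 3), c(2, 5, 4))
  mesh <- surface_mesh(v, f, region = c(1L, 1L, 1L, 2L, 2L),
                       hemisphere = rep("left", 5))
  va <- vertex_areas(mesh)
  feats <- tibble::tibble(vertex = 1:5, lgi = c(1, 2, 3, 4, 5))
  agg <- aggregate_features(mesh, feats)
  # hand computation: area-weighted means over lobe vertices
  for (lobe in c("frontal", "parietal")) {
    ids <- which(mesh$region == parcellation_regions()[[lobe]])
    want <- sum(feats$lgi[ids] * va[ids]) / sum(va[ids])
    expect_equal(agg$lgi[agg$lobe == lobe], want)
  }
  # constant field: every lobe mean equals the constant
  aggc <- aggregate_features(mesh, tibble::tibble(vertex = 1:5, lgi = rep(7, 5)))
  expect_equal(aggc$lgi[aggc$lobe %in% c("frontal", "parietal", "global")],
               rep(7, 3))
  expect_true(all(is.na(aggc$lgi[aggc$lobe %in% c("temporal", "occipital")])))
  # global area equals the sum of the lobe areas
  expect_equal(agg$area_mm2[agg$lobe == "global"],
               sum(agg$area_mm2[agg$lobe != "global"]))
  # lobes with no vertices are flagged missing, not zero
  expect_true(all(is.na(agg$lgi[agg$lobe %in% c("temporal", "occipital")])))
})

test_that("scaling the mesh leaves LGI invariant and scales depth and area", {
  ph <- make_phantom(small_phantom_spec(0.12, r = 14, spacing = 1.25))
  mesh <- extract_junction_mesh(ph$segmentation, junction_labels())
  k <- 2
  mesh2 <- mesh
  mesh2$vertices <- mesh$vertices * k
  hull <- convex_hull_mesh(mesh, "all")
  hull2 <- convex_hull_mesh(mesh2, "all")
  p1 <- lgi_params(patch_radius = 7)
  p2 <- lgi_params(patch_radius = 7 * k, hull_sample_edge = 1 * k)
  lg1 <- local_gyrification_index(mesh, hull, p1)
  lg2 <- local_gyrification_index(mesh2, hull2, p2)
  expect_equal(lg2$lgi, lg1$lgi, tolerance = 1e-6)
  expect_equal(mesh_area(mesh2), mesh_area(mesh) * k^2)
  d1 <- sulcal_depth(mesh, convex_hull_mesh(mesh, "left"))
  d2 <- sulcal_depth(mesh2, convex_hull_mesh(mesh2, "left"))
  expect_equal(d2$depth, d1$depth * k, tolerance = 1e-9)
})

test_that("perturbing one hemisphere leaves the other's features unchanged", {
  ph <- make_phantom(small_phantom_spec(0.1, r = 14, spacing = 1.25))
  mesh <- extract_junction_mesh(ph$segmentation, junction_labels())
  right <- mesh$hemisphere == "right"
  mesh_pert <- mesh
  mesh_pert$vertices[right, ] <- mesh$vertices[right, , drop = FALSE] +
    matrix(runif(sum(right) * 3, 0, 0.4), ncol = 3)
  d_l1 <- sulcal_depth(mesh, convex_hull_mesh(mesh, "left"))
  d_l2 <- sulcal_depth(mesh_pert, convex_hull_mesh(mesh_pert, "left"))
  expect_identical(d_l1$depth, d_l2$depth)
})
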