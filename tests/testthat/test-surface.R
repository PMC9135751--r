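test_that("cuboid junction mesh is closed with near-analytic area", {
  seg <- cuboid_volume(20, 1)
  mesh <- extract_junction_mesh(seg, 1L)
  # closedness is asserted during extraction; re-check the edge pairing here
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  expect_equal(mesh_area(mesh), 2400, tolerance = 0.03)
})

test_that("sphere junction mesh area approaches the closed form", {
  mesh <- extract_junction_mesh(ball_volume(20, 1), 1L)
  expect_equal(mesh_area(mesh), 4 * pi * 400, tolerance = 0.03)
})

test_that("empty or overlapping label sets are rejected", {
  seg <- ball_volume(8, 2)
  expect_error(extract_junction_mesh(seg, integer(0)), "empty inner label set")
  expect_error(extract_junction_mesh(seg, 2L), "no voxels")
  expect_error(extract_junction_mesh(seg, 1L, outer_labels = 1L), "overlap")
})

test_that("region assignment takes the nearest labeled voxel", {
  seg <- ball_volume(10, 1)
  mesh <- extract_junction_mesh(seg, 1L)
  # single-region parcellation: every vertex gets that region
  parc1 <- label_volume(array(7L, dim = dim(seg$data)), seg$spacing)
  m1 <- assign_regions(mesh, parc1)
  expect_true(all(m1$region == 7L))
  # vertex coincident with a labeled voxel center gets that label
  d <- dim(seg$data)
  parc <- array(0L, dim = d)
  parc[3, 4, 5] <- 9L
  pv <- label_volume(parc, c(1, 1, 1))
  probe <- surface_mesh(rbind(c(2, 3, 4)), matrix(integer(0), 0, 3))
  expect_equal(fetalfold:::.cpp_nearest_label(probe$vertices, pv$data,
                                              dim(pv$data), pv$spacing), 9L)
  # all-background parcellation errors
  expect_error(assign_regions(mesh, label_volume(array(0L, dim = d),
                                                 seg$spacing)),
               "background")
})

test_that("phantom vertices recover their generating angular sector", {
  ph <- make_phantom(small_phantom_spec(0, r = 18))
  mesh <- extract_junction_mesh(ph$segmentation, junction_labels())
  mesh <- assign_regions(mesh, ph$parcellation)
  spec <- small_phantom_spec(0, r = 18)
  cen <- spec$center
  v <- sweep(mesh$vertices, 2, cen)
  # recompute the construction sector from each vertex position
  r <- sqrt(rowSums(v^2))
  theta <- acos(pmax(-1, pmin(1, v[, 3] / r)))
  alpha <- atan2(abs(v[, 1]), v[, 2])
  regs <- parcellation_regions()
  want <- regs[["frontal"]] + pmin(3L, as.integer(floor(alpha / (pi / 4))))
  top <- theta < pi / 8
  bot <- theta > 7 * pi / 8
  want[top] <- ifelse(v[top, 2] >= 0, regs[["ant_cingulate"]],
                      regs[["post_cingulate"]])
  want[bot] <- ifelse(v[bot, 2] >= 0, regs[["insula"]],
                      regs[["corpus_callosum"]])
  want <- want + ifelse(v[, 1] > 0, hemisphere_offset(), 0L)
  # agreement away from sector borders (>= 2 mm from any boundary plane)
  phi_a <- alpha %% (pi / 4)
  away <- pmin(phi_a, pi / 4 - phi_a) * r > 2 &
    pmin(abs(theta - pi / 8), abs(theta - 7 * pi / 8)) * r > 2 &
    abs(v[, 1]) > 2
  expect_gt(mean(mesh$region[away] == want[away]), 0.99)
})

test_that("convex hulls are convex, tight on convex input, exact on cubes", {
  mesh <- extract_junction_mesh(ball_volume(15, 1), 1L)
  hull <- convex_hull_mesh(mesh, "all")
  # hull vertices are a subset of mesh vertices
  expect_true(all(hull$vertices %in% mesh$vertices))
  # containment: all mesh vertices inside or on the hull
  expect_lt(max(hull_signed_distance(hull, mesh$vertices)), 1e-6)
  # convex input: hull area within 1% of mesh area, and never larger than it
  expect_equal(mesh_area(hull), mesh_area(mesh), tolerance = 0.01)
  expect_lte(mesh_area(hull), mesh_area(mesh) * (1 + 1e-9))

  # 8 cube corners: hull area exactly 6 s^2
  s <- 7
  corners <- as.matrix(expand.grid(c(0, s), c(0, s), c(0, s)))
  cube_mesh <- surface_mesh(corners, matrix(integer(0), 0, 3),
                            hemisphere = rep("left", 8))
  hull_c <- convex_hull_mesh(cube_mesh, "all")
  expect_equal(mesh_area(hull_c), 6 * s^2)

  # degenerate (coplanar) input errors
  flat <- surface_mesh(cbind(runif(10), runif(10), 0), matrix(integer(0), 0, 3))
  expect_error(convex_hull_mesh(flat, "all"), "coplanar|degenerate")
})

test_that("hull area never exceeds the area of a folded enclosing surface", {
  ph <- make_phantom(small_phantom_spec(0.15, r = 15))
  mesh <- extract_junction_mesh(ph$segmentation, junction_labels())
  for (h in c("left", "right")) {
    hull <- convex_hull_mesh(mesh, h)
    verts <- mesh$vertices[mesh$hemisphere == h, , drop = FALSE]
    expect_lt(max(hull_signed_distance(hull, verts)), 1e-6)
  }
  hull_all <- convex_hull_mesh(mesh, "all")
  expect_lt(mesh_area(hull_all), mesh_area(mesh))
})

test_that("surface area errors shrink as the grid is refined", {
  errs <- vapply(c(2, 1), function(sp) {
    abs(mesh_area(extract_junction_mesh(ball_volume(15, sp), 1L)) /
          (4 * pi * 225) - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
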