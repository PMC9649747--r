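test_that("the estimated axis of a helical tube hugs the true axis", {
  tube <- default_tube()
  ax <- estimate_axis(tube$model)
  # true axis is the z axis: radial deviation everywhere small
  expect_lt(max(sqrt(ax$x^2 + ax$y^2)), 0.5)
  # arclength strictly increasing, resampled near-uniformly
  expect_true(all(diff(ax$s) > 0))
  expect_lte(max(diff(ax$s)), 2 * attr(ax, "step"))
  expect_false(attr(ax, "flagged"))
})

test_that("a straight CA rod yields an axis on the rod line and a degenerate order is flagged", {
  line <- line_model(150)
  ax <- estimate_axis(line)
  expect_lt(max(sqrt(ax$x^2 + ax$y^2)), 1e-9)
  expect_error(estimate_axis(line_model(60)), "too few")

  # same atoms in random spatial order with sequential numbering: centerline
  # collapses and is flagged
  tube <- default_tube()$model
  shuf <- tube
  set.seed(6)
  perm <- sample(nrow(shuf$atoms))
  xyz <- megastitch:::atom_coords(shuf)[perm, ]
  shuf <- megastitch:::set_coords(shuf, xyz)
  expect_warning(ax2 <- estimate_axis(shuf), "degenerate")
  expect_true(attr(ax2, "flagged"))
})

test_that("radius profile on an ideal cylinder equals wall radius minus vdW", {
  cyl <- cylinder_model(wall_r = 7.7, length = 100)
  axis_true <- data.frame(s = seq(0, 100, 2), x = 0, y = 0, z = seq(0, 100, 2))
  prof <- radius_profile(cyl, axis_true)
  interior <- prof$s >= 5 & prof$s <= 95
  expect_true(all(abs(prof$radius[interior] - 6.0) < 0.1))
  # Leu walls: lining hydropathy is the Leu scale value at every station
  expect_true(all(abs(prof$mean_hydropathy[interior] - 3.8) < 1e-9))
})

test_that("profile radii equal the brute-force all-atom minimum exactly", {
  tube <- make_tube(n_res = 120, length = 40, seed = 2)$model
  ax <- estimate_axis(tube, window = 30)
  prof <- radius_profile(tube, ax)
  a <- tube$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  for (k in seq(1, nrow(prof), by = 3)) {
    d <- sqrt(colSums((t(X) - c(prof$x[k], prof$y[k], prof$z[k]))^2)) - a$vdw_radius
    expect_equal(prof$radius[k], max(min(d), 0), tolerance = 1e-12)
  }
})

test_that("the benchmark tube reads as a continuous hydrophobic tunnel of known lumen", {
  tube <- default_tube()
  ax <- estimate_axis(tube$model)
  prof <- radius_profile(tube$model, ax)
  ts <- tunnel_summary(prof)
  expect_true(ts$continuous)
  expect_true(ts$hydrophobic)
  expect_lt(abs(ts$min_radius - tube$truth$lumen_radius), 0.5)
  expect_gt(ts$mean_lining_hydropathy, 3)
  # interior mean hydropathy is high at every station, not just on average
  interior <- prof$s >= 0.05 * max(prof$s) & prof$s <= 0.95 * max(prof$s)
  expect_true(all(prof$mean_hydropathy[interior] > 3))
})

test_that("blocked and solid geometries are not continuous tunnels", {
  cyl <- cylinder_model(wall_r = 7.7, length = 100)
  axis_true <- data.frame(s = seq(0, 100, 2), x = 0, y = 0, z = seq(0, 100, 2))
  # an atom dropped onto the axis mid-tunnel blocks it there
  blocker <- cyl$atoms[1, ]
  blocker$serial <- max(cyl$atoms$serial) + 1L
  blocker$residue_number <- max(cyl$atoms$residue_number) + 10L
  blocker$x <- 0; blocker$y <- 0; blocker$z <- 50
  blocked <- structure_model(rbind(cyl$atoms, blocker))
  # the blocking atom sits on the axis, so the clamp warning is expected
  ts <- tunnel_summary(suppressWarnings(radius_profile(blocked, axis_true)))
  expect_false(ts$continuous)
  expect_equal(ts$argmin_s, 50)
  expect_equal(ts$verdict, "no continuous tunnel")

  # probe wider than the lumen: not continuous either
  ts2 <- tunnel_summary(radius_profile(cyl, axis_true), probe = 8)
  expect_false(ts2$continuous)

  # solid rod: atoms on the axis itself, radii clamp to zero
  solid <- line_model(150, spacing = 1.5)
  axis_solid <- data.frame(s = seq(0, 220, 2), x = 0, y = 0, z = seq(0, 220, 2))
  expect_warning(prof_s <- radius_profile(solid, axis_solid), "clamped")
  ts3 <- tunnel_summary(prof_s)
  expect_false(ts3$continuous)
  expect_equal(ts3$min_radius, 0)
})

test_that("rod_length measures principal-axis extent and is rotation invariant", {
  two <- quick_model(c(1, 5), c(0, 0), c(0, 0), c(0, 300))
  rl <- rod_length(two)
  expect_equal(rl$angstrom, 300)
  expect_equal(rl$nm, 30)

  tube <- default_tube()
  rl_t <- rod_length(tube$model)
  expect_lt(abs(rl_t$angstrom - tube$truth$length) / tube$truth$length, 0.02)

  set.seed(13)
  for (k in 1:3) {
    xfm <- rigid_transform(random_proper_rotation(), runif(3, -80, 80))
    moved <- apply_transform(xfm, tube$model)
    expect_equal(rod_length(moved)$angstrom, rl_t$angstrom, tolerance = 1e-9)
  }
})

test_that("tunnel statistics are invariant under rigid motions of the model", {
  tube <- default_tube()
  ts0 <- tunnel_summary(radius_profile(tube$model, estimate_axis(tube$model)))
  set.seed(29)
  xfm <- rigid_transform(random_proper_rotation(), runif(3, -80, 80))
  moved <- apply_transform(xfm, tube$model)
  ts1 <- tunnel_summary(radius_profile(moved, estimate_axis(moved)))
  expect_equal(ts1$continuous, ts0$continuous)
  expect_equal(ts1$min_radius, ts0$min_radius, tolerance = 0.05)
  expect_equal(ts1$mean_lining_hydropathy, ts0$mean_lining_hydropathy,
               tolerance = 0.05)
})

test_that("mutation blockage: identity is a no-op, lumen-facing Gly->Glu blocks, outward-facing does not", {
  tg <- make_tube(lumen_aa = "G", seed = 3)
  ax <- estimate_axis(tg$model)
  lumen_res <- 451L  # odd residues face the lumen
  mb_id <- mutation_blockage(tg$model, paste0("G", lumen_res, "G"), ax)
  expect_true(all(mb_id$delta_radius == 0))

  mb <- mutation_blockage(tg$model, paste0("G", lumen_res, "E"), ax)
  expect_lt(min(mb$delta_radius), 0)
  # the dip is adjacent to the residue, within the recomputed arc window
  expect_lte(abs(mb$s[which.min(mb$delta_radius)] - attr(mb, "nearest_station_s")), 15)
  expect_true(all(mb$delta_radius <= 0))

  to <- make_tube(outer_aa = "G", seed = 3)
  axo <- estimate_axis(to$model)
  mbo <- mutation_blockage(to$model, "G450E", axo)  # even residues face out
  expect_true(all(abs(mbo$delta_radius) < 1e-9))

  expect_error(mutation_blockage(tg$model, paste0("A", lumen_res, "E"), ax),
               "mismatch")
  expect_error(mutation_spec("GxE"), "parse")
})
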