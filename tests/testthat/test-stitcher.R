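test_that("kabsch_superpose recovers exact rigid motions and rejects degenerate input", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$transform$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$t, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(fit$rmsd, 1e-12)

  # Q is P rotated 90 deg about z then translated: the fit inverts it
  R90 <- rot_z(pi / 2)
  Q <- sweep(P %*% t(R90), 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transform$R, t(R90), tolerance = 1e-9)
  back <- apply_transform(fit$transform, Q)
  expect_lt(max(abs(back - P)), 1e-9)

  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "insufficient")
  lin <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_warning(kabsch_superpose(lin, lin), "collinear")
})

test_that("kabsch rmsd matches the independent quaternion oracle on random noisy instances", {
  set.seed(99)
  worst <- 0
  for (k in 1:200) {
    n <- sample(4:40, 1)
    P <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
    Q <- sweep(P %*% t(random_proper_rotation()), 2, runif(3, -50, 50), "+") +
      matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    worst <- max(worst, abs(kabsch_superpose(P, Q)$rmsd - oracle_rmsd_quaternion(P, Q)))
  }
  expect_lt(worst, 1e-8)
})

test_that("kabsch rmsd agrees with bio3d's fitting as a second external check", {
  set.seed(5)
  for (k in 1:5) {
    n <- 25
    P <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
    Q <- sweep(P %*% t(random_proper_rotation()), 2, runif(3, -10, 10), "+") +
      matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    r_b <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)),
                       fit = TRUE, a.inds = 1:(3 * n), b.inds = 1:(3 * n))
    # bio3d prints/rounds its RMSD to 3 decimals
    expect_lt(abs(kabsch_superpose(P, Q)$rmsd - r_b), 6e-4)
  }
})

test_that("rigid_transform enforces proper orthonormal rotations and composes correctly", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper|reflection")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  set.seed(3)
  a <- rigid_transform(random_proper_rotation(), rnorm(3))
  b <- rigid_transform(random_proper_rotation(), rnorm(3))
  X <- matrix(rnorm(15), ncol = 3)
  expect_equal(apply_transform(compose_transform(a, b), X),
               apply_transform(a, apply_transform(b, X)), tolerance = 1e-12)
  expect_equal(apply_transform(invert_transform(a), apply_transform(a, X)),
               X, tolerance = 1e-10)
})

test_that("superpose_on_overlap fits shared CA residues and guards sequence identity", {
  tube <- default_tube()$model
  mov <- megastitch:::subset_residues(tube, 251, 650)
  set.seed(8)
  xfm <- rigid_transform(random_proper_rotation(), runif(3, -50, 50))
  mov <- apply_transform(xfm, mov)
  sup <- superpose_on_overlap(tube, mov, c(251, 400))
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$n_atoms, 150)
  back <- apply_transform(sup$transform, mov)
  expect_lt(max(abs(megastitch:::atom_coords(back) -
                      megastitch:::atom_coords(megastitch:::subset_residues(tube, 251, 650)))),
            1e-8)

  # shifted numbering puts outer-facing letters at lumen positions -> mismatch
  shifted <- mov
  shifted$atoms$residue_number <- shifted$atoms$residue_number + 1L
  expect_error(superpose_on_overlap(tube, shifted, c(252, 400)), "mismatch")
  expect_error(superpose_on_overlap(tube, mov, c(251, 252)), "fewer than 3")
})

test_that("overlap rmsd of two noisy fragment copies follows sigma * sqrt(6)", {
  tube <- default_tube()$model
  plan <- tube_plan_900()
  sigma <- 0.5
  set.seed(17)
  vals <- replicate(30, {
    fp <- fragment_and_perturb(tube, plan, sigma = sigma, seed = sample.int(1e6, 1))
    asm <- assemble(fp$fragments, plan)
    mean(asm$report$junctions$rmsd)
  })
  expect_true(all(vals > 0.5 & vals < 1.3))
  expect_equal(mean(vals), sigma * sqrt(6), tolerance = 0.1)
})

test_that("noiseless fragmented tubes are reassembled to machine precision", {
  tube <- default_tube()
  plan <- tube_plan_900()
  for (seed in c(11, 23, 31)) {
    fp <- fragment_and_perturb(tube$model, plan, sigma = 0, seed = seed)
    asm <- assemble(fp$fragments, plan)
    expect_lt(rmsd_to_reference(asm$model, tube$model), 1e-6)
    expect_equal(asm$report$total_residues, 900)
    expect_identical(residue_numbers(asm$model), 1:900)
  }
})

test_that("single-fragment plans return the fragment unchanged", {
  tube <- make_tube(n_res = 120, length = 40, seed = 2)$model
  plan <- plan_fragments(120, target_len = 200, min_overlap = 50)
  asm <- assemble(list(tube), plan)
  expect_equal(asm$model$atoms, tube$atoms)
  expect_null(asm$report$junctions)
})

test_that("noisy assembly stays within tolerance with clash-free junctions, monotone in noise", {
  tube <- default_tube()
  plan <- tube_plan_900()
  fp <- fragment_and_perturb(tube$model, plan, sigma = 0.5, seed = 4242)
  asm <- assemble(fp$fragments, plan)
  expect_lt(rmsd_to_reference(asm$model, tube$model, atoms = "CA"), 1.5)
  expect_equal(asm$report$clash_count, 0L)

  mean_junction_rmsd <- function(sigma, seeds) {
    mean(vapply(seeds, function(s) {
      f <- fragment_and_perturb(tube$model, plan, sigma = sigma, seed = s)
      mean(assemble(f$fragments, plan)$report$junctions$rmsd)
    }, numeric(1)))
  }
  seeds <- c(101, 202, 303)
  curve <- vapply(c(0, 0.25, 0.5, 1.0), mean_junction_rmsd, numeric(1), seeds = seeds)
  expect_true(all(diff(curve) > 0))
})

test_that("max_confidence splicing picks the crossover an exhaustive search picks", {
  tube <- default_tube()
  plan <- tube_plan_900()
  fp <- fragment_and_perturb(tube$model, plan, sigma = 0.2, seed = 77)
  asm <- assemble(fp$fragments, plan, splice_rule = "max_confidence")
  for (j in seq_len(nrow(asm$report$junctions))) {
    ov <- c(asm$report$junctions$overlap_start[j], asm$report$junctions$overlap_end[j])
    left <- fp$fragments[[j]]; right <- fp$fragments[[j + 1]]
    conf_of <- function(m) {
      a <- m$atoms[m$atoms$residue_number >= ov[1] & m$atoms$residue_number <= ov[2], ]
      tapply(a$confidence, a$residue_number, mean)
    }
    lc <- conf_of(left); rc <- conf_of(right)
    res <- sort(as.integer(names(lc)))
    cand <- res[res < ov[2]]
    score <- vapply(cand, function(cc) {
      min(mean(lc[as.integer(names(lc)) <= cc]),
          mean(rc[as.integer(names(rc)) > cc]))
    }, numeric(1))
    expect_equal(asm$report$junctions$crossover[j], cand[which.max(score)])
  }
  # confidence decays toward fragment ends, so the best crossover is interior
  expect_true(all(asm$report$junctions$crossover > asm$report$junctions$overlap_start))
  expect_true(all(asm$report$junctions$crossover < asm$report$junctions$overlap_end))
})

test_that("assembly contract errors: missing fragments and uncovered intervals", {
  tube <- default_tube()$model
  plan <- tube_plan_900()
  fp <- fragment_and_perturb(tube, plan, sigma = 0, seed = 1)
  expect_error(assemble(fp$fragments[1:2], plan), "missing fragment")
  expect_error(assemble(fp$fragments[c(1, 1, 3)], plan), "does not cover")
})

test_that("clash_report matches the all-pairs oracle and applies bonded exclusion", {
  two <- quick_model(c(1, 11), c(0, 1), 0, 0)
  hits <- clash_report(two, cutoff = 2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$distance, 1)
  near <- quick_model(c(1, 2), c(0, 1), 0, 0)
  expect_equal(nrow(clash_report(near, cutoff = 2)), 0)

  tube <- make_tube(n_res = 120, length = 40, seed = 2)$model
  expect_equal(nrow(clash_report(tube, cutoff = 2)), 0)
  expect_identical(oracle_clash_pairs(tube, 2), character(0))

  # jostled tube has real clashes; grid search must equal brute force
  set.seed(12)
  jost <- megastitch:::set_coords(tube, megastitch:::atom_coords(tube) +
                                    matrix(rnorm(nrow(tube$atoms) * 3, sd = 1.2), ncol = 3))
  hits <- clash_report(jost, cutoff = 2.5)
  expect_gt(nrow(hits), 0)
  expect_identical(sort(paste(hits$i, hits$j, sep = "-")),
                   oracle_clash_pairs(jost, 2.5))
})
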