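# Superposition, ensemble alignment, sampling clouds, step parameters.

test_that("superpose recovers applied rigid motions and excludes reflections", {
  set.seed(41)
  A <- matrix(rnorm(36, sd = 10), ncol = 3)
  idt <- superpose(A, A)
  expect_lt(idt$rmsd, 1e-9)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-9)
  for (i in 1:10) {
    R <- random_rotation(); tv <- rnorm(3, 0, 20)
    mob <- A %*% t(R) + matrix(tv, nrow(A), 3, byrow = TRUE)
    tr <- superpose(A, mob)
    expect_equal(tr$rotation %*% R, diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(tr$rmsd, 1e-9)
  }
  # mirror image: proper rotation enforced, residual stays positive
  mir <- A %*% diag(c(-1, 1, 1))
  tr <- superpose(A, mir)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_gt(tr$rmsd, 0.1)
  expect_error(superpose(A, A[-1, ]), "pairing error")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose(line, line), "degenerate")
})

test_that("superpose agrees with the bio3d Kabsch implementation", {
  set.seed(42)
  A <- matrix(rnorm(60, sd = 8), ncol = 3)
  B <- A %*% t(random_rotation()) +
    matrix(rnorm(3, 0, 10), nrow(A), 3, byrow = TRUE) +
    matrix(rnorm(60, 0, 0.5), ncol = 3)
  ours <- superpose(A, B)
  moved <- apply_transform(B, ours)
  ref_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(A)), mobile = as.numeric(t(B)),
                   fixed.inds = seq_len(3 * nrow(A)),
                   mobile.inds = seq_len(3 * nrow(A))))
  theirs <- matrix(as.numeric(ref_fit), ncol = 3, byrow = TRUE)
  expect_equal(moved, theirs, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ours$rmsd,
               sqrt(mean(rowSums((theirs - A)^2))), tolerance = 1e-6)
})

test_that("aligning an ensemble of rotated copies collapses it; alignment is idempotent", {
  set.seed(43)
  st <- build_stack(stack_spec(n_factors = 1))
  xyz0 <- model_coords(st$structure)
  frames <- lapply(1:6, function(i) {
    R <- random_rotation(); tv <- rnorm(3, 0, 30)
    xyz0 %*% t(R) + matrix(tv, nrow(xyz0), 3, byrow = TRUE)
  })
  ens <- trajectory_ensemble(structure_model(st$structure$atom, frames),
                             topology = st)
  al <- align_ensemble(ens, "nuc1")
  for (f in 2:6)
    expect_lt(max(abs(al$frames[[f]] - al$frames[[1]])), 1e-6)
  al2 <- align_ensemble(al, "nuc1")
  for (f in 1:6)
    expect_lt(max(abs(al2$frames[[f]] - al$frames[[f]])), 1e-9)
  # per-frame residual is the minimal superposition RMSD
  rows <- nucstack:::.ref_c1_rows(st, "nuc1")
  direct <- superpose(ens$frames[[1]][rows, ], ens$frames[[3]][rows, ])
  expect_equal(attr(al, "alignment_rmsd")[3], direct$rmsd,
               tolerance = 1e-9)
})

test_that("sampling clouds: zero dispersion collapses, translation sigma gives sigma*sqrt(3)", {
  st <- build_stack(stack_spec(n_factors = 1))
  const <- sample_ensemble(st, dispersion_spec(n_frames = 10, seed = 5))
  cl0 <- sampling_cloud(align_ensemble(const, "nuc1"), "nuc2")
  expect_lt(max(cl0$dispersion), 1e-9)
  expect_error(sampling_cloud(const, "nuc2"), "state error")

  iso <- sample_ensemble(st, dispersion_spec(n_frames = 500, seed = 6,
                                             sd_rise = 1, sd_shift = 1))
  cl <- sampling_cloud(align_ensemble(iso, "nuc1"), "nuc2")
  expect_equal(unname(cl$dispersion["dyad"]), sqrt(3), tolerance = 0.1)
  expect_equal(unname(cl$dispersion["anti_dyad"]), sqrt(3),
               tolerance = 0.1)
  expect_identical(nrow(cl$points), 1000L)
})

test_that("step parameters: constructed translations and rotations decompose exactly", {
  f1 <- nucleosome_frame(build_nucleosome())
  same <- step_parameters(f1, f1)
  expect_equal(as.numeric(same[1, 1:5]), rep(0, 5), tolerance = 1e-9)

  f2 <- f1; f2$origin <- f1$origin + 60 * f1$z
  s <- step_parameters(f1, f2)
  expect_equal(s$rise, 60, tolerance = 1e-9)
  expect_equal(abs(s$shift_x) + abs(s$shift_y) + s$tilt + abs(s$twist), 0,
               tolerance = 1e-9)

  R20 <- nucstack:::.rot_axis(f1$z, 20 * pi / 180)
  f3 <- rigid_move_frame(f1, R20, as.numeric(f1$origin - R20 %*% f1$origin))
  s3 <- step_parameters(f1, f3)
  expect_equal(s3$twist, 20, tolerance = 1e-9)
  expect_equal(s3$tilt, 0, tolerance = 1e-9)
  expect_equal(s3$rise, 0, tolerance = 1e-9)
})

test_that("step parameters are rigid-motion invariant, antisymmetric, and satisfy the distance identity", {
  set.seed(44)
  f1 <- nucleosome_frame(build_nucleosome())
  for (i in 1:10) {
    spec <- random_step()
    f2 <- frame_from_step(f1, spec$step)
    s <- step_parameters(f1, f2)
    expect_equal(s$center_distance^2,
                 s$rise^2 + s$shift_x^2 + s$shift_y^2, tolerance = 1e-6)
    R <- random_rotation(); tv <- rnorm(3, 0, 40)
    sm <- step_parameters(rigid_move_frame(f1, R, tv),
                          rigid_move_frame(f2, R, tv))
    expect_equal(as.numeric(sm[1, ]), as.numeric(s[1, ]),
                 tolerance = 1e-9)
    rev <- step_parameters(f2, f1)
    expect_equal(rev$twist, -s$twist, tolerance = 1e-9)
    expect_equal(rev$rise, -s$rise, tolerance = 1e-9)
    expect_equal(rev$tilt, s$tilt, tolerance = 1e-9)
    expect_true(s$tilt >= 0 && s$tilt <= 180)
    expect_true(s$twist > -180 && s$twist <= 180)
  }
  bad <- f1; bad$x <- f1$x * 2
  expect_error(step_parameters(bad, f1), "orthonormal")
})

test_that("frame_from_step inverts step_parameters at nonzero bend azimuth too", {
  set.seed(45)
  f1 <- nucleosome_frame(build_nucleosome())
  for (az in c(-120, 45, 170)) {
    spec <- random_step()
    f2 <- frame_from_step(f1, spec$step, azimuth = az)
    s <- step_parameters(f1, f2)
    expect_equal(s$tilt, spec$step$tilt, tolerance = 1e-6)
    expect_equal(s$twist, spec$step$twist, tolerance = 1e-6)
    expect_equal(s$rise, spec$step$rise, tolerance = 1e-6)
  }
})

test_that("ensemble step stats recover generator dispersion and means", {
  st <- build_stack(stack_spec(n_factors = 1))
  const <- sample_ensemble(st, dispersion_spec(n_frames = 8, seed = 9))
  s0 <- ensemble_step_stats(const, "nuc1", "nuc2")
  expect_identical(nrow(s0$series), 8L)
  expect_lt(max(s0$summary$sd), 1e-9)

  ens <- sample_ensemble(st, dispersion_spec(n_frames = 300, seed = 10,
                                             sd_twist = 3))
  ss <- ensemble_step_stats(ens, "nuc1", "nuc2")
  tw <- ss$summary[ss$summary$parameter == "twist", ]
  expect_equal(tw$mean, 20, tolerance = 3 * 3 / sqrt(300))
  expect_equal(tw$sd, 3, tolerance = 0.25 * 3)
  # summary is recomputable from the series
  expect_equal(tw$sd, sd(ss$series$twist), tolerance = 1e-12)

  # two presets differing only in dispersion: comparable means, ordered sd
  narrow <- ensemble_step_stats(
    sample_ensemble(st, dispersion_spec(300, seed = 12, sd_twist = 1)),
    "nuc1", "nuc2")
  wide <- ensemble_step_stats(
    sample_ensemble(st, dispersion_spec(300, seed = 12, sd_twist = 6)),
    "nuc1", "nuc2")
  nt <- narrow$summary[narrow$summary$parameter == "twist", ]
  wt <- wide$summary[wide$summary$parameter == "twist", ]
  expect_lt(nt$sd, wt$sd)
  expect_lt(abs(nt$mean - wt$mean), 6 * 3 / sqrt(300) + 1)
})
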