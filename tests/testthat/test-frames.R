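# Base-pair pairing, nucleosome frames, SHL mapping, dyad points.

test_that("pairing a canonical nucleosome gives 147 pairs spanning -73..73", {
  nuc <- build_nucleosome()
  s <- pair_base_steps(nuc, "nuc1")
  expect_identical(nrow(s), 147L)
  expect_identical(range(s$index), c(-73L, 73L))
  expect_true(all(diff(s$index) == 1L))
  # bp centers are the midpoints of their two C1' atoms by construction
  expect_equal(s$cx, (s$x1 + s$x2) / 2, tolerance = 1e-12)
  expect_true(all(s$stably_bound))
  # strand pairing is antiparallel in residue numbers
  expect_identical(s$resno2, rev(s$resno1))
})

test_that("unequal strands and missing C1' atoms are rejected", {
  nuc <- build_nucleosome()
  atom <- nuc$structure$atom
  xyz <- model_coords(nuc$structure)
  drop <- which(atom$chain_id == "J")[1]          # terminal residue
  m <- structure_model(atom[-drop, ], list(xyz[-drop, ]))
  cx <- assign_roles(m, nuc$role_map)
  expect_error(pair_base_steps(cx, "nuc1"), "pairing error")
  # equal strand lengths but an interior hole on one strand
  drop2 <- c(which(atom$chain_id == "J" & atom$residue_index == 70),
             which(atom$chain_id == "I" & atom$residue_index == 147))
  m2 <- structure_model(atom[-drop2, ], list(xyz[-drop2, ]))
  cx2 <- assign_roles(m2, nuc$role_map)
  expect_error(pair_base_steps(cx2, "nuc1"), "gap error")
})

test_that("the frame of an ideal planar circle is the global frame", {
  s <- circle_series()
  f <- compute_frame(s)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f$x, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(f$y, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(f$z, c(0, 0, 1), tolerance = 1e-9)
})

test_that("compute_frame is equivariant under rigid motion and always right-handed", {
  set.seed(31)
  nuc <- build_nucleosome()
  s0 <- pair_base_steps(nuc, "nuc1")
  f0 <- compute_frame(s0)
  for (i in 1:10) {
    R <- random_rotation(); tv <- rnorm(3, 0, 50)
    moved <- rigid_move_complex(nuc, R, tv)
    f <- nucleosome_frame(moved)
    expect_equal(f$origin, as.numeric(R %*% f0$origin) + tv,
                 tolerance = 1e-9)
    for (ax in c("x", "y", "z"))
      expect_equal(f[[ax]], as.numeric(R %*% f0[[ax]]), tolerance = 1e-9)
    B <- cbind(f$x, f$y, f$z)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(det(B), 1, tolerance = 1e-9)
  }
})

test_that("degenerate or truncated series are rejected", {
  s <- circle_series()
  flat <- s
  flat$cx <- seq_len(nrow(s)); flat$cy <- 2 * flat$cx; flat$cz <- 0
  expect_error(compute_frame(flat), "collinear")
  few <- s[s$index >= -5 & s$index <= 5, ]
  class(few) <- class(s)
  expect_error(compute_frame(few), "at least")
  one_side <- s[s$index >= 0, ]
  class(one_side) <- class(s)
  expect_error(compute_frame(one_side, min_bp = 20), "span the dyad")
})

test_that("SHL mapping follows bp / 10.4 and is antisymmetric and bounded", {
  expect_identical(shl_of(0), 0)
  expect_equal(shl_of(52), 5.0)
  expect_equal(shl_of(65), 6.25)
  expect_equal(shl_of(73), 7.019231, tolerance = 1e-6)
  expect_lte(abs(shl_of(73)), 7.3)
  idx <- -73:73
  expect_equal(shl_of(-idx), -shl_of(idx))
  expect_error(shl_of(74), "out of range")
  expect_identical(shl_bin(c(4.23, 4.81, 6.25)), c(4L, 4L, 6L))
})

test_that("dyad and anti-dyad points are C1' centroids of the stated pairs", {
  nuc <- build_nucleosome()
  s <- pair_base_steps(nuc, "nuc1")
  pts <- dyad_points(s)
  rows <- s[s$index %in% -1:1, ]
  direct <- colMeans(rbind(as.matrix(rows[, c("x1", "y1", "z1")]),
                           as.matrix(rows[, c("x2", "y2", "z2")])))
  expect_equal(pts$dyad_point, direct, tolerance = 1e-12,
               ignore_attr = TRUE)
  rows2 <- s[s$index %in% c(-37, -36, 36, 37), ]
  direct2 <- colMeans(rbind(as.matrix(rows2[, c("x1", "y1", "z1")]),
                            as.matrix(rows2[, c("x2", "y2", "z2")])))
  expect_equal(pts$anti_dyad_point, direct2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # single-bp degenerate case: midpoint of the two C1'
  one <- s[s$index == 0, ]
  class(one) <- class(s)
  p <- dyad_points(one, dyad_indices = 0, anti_dyad_indices = 0)
  expect_equal(p$dyad_point,
               as.numeric((one[, c("x1", "y1", "z1")] +
                             one[, c("x2", "y2", "z2")]) / 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing required bp -> gap error
  trunc <- s[s$index <= 36, ]
  class(trunc) <- class(s)
  expect_error(dyad_points(trunc), "gap error")
})

test_that("CENP-A-style flexible ends are flagged and excluded from the fit", {
  cen <- build_nucleosome(cenpa_nucleosome_spec())
  s <- pair_base_steps(cen, "nuc1")
  expect_identical(sum(s$stably_bound), 121L)
  expect_identical(range(s$index[s$stably_bound]), c(-60L, 60L))
  # the 121-bp-core frame is a valid, nearby frame: the superhelical axis
  # of the shorter arc tilts only modestly against the full-wrap axis
  f_cen <- compute_frame(s)
  f_can <- nucleosome_frame(build_nucleosome())
  ang <- acos(sum(f_cen$z * f_can$z)) * 180 / pi
  expect_lt(ang, 15)
  B <- cbind(f_cen$x, f_cen$y, f_cen$z)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})
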