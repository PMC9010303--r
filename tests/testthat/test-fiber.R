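# Array ordering, fiber steps, start number, helical fit, linker accounting.

test_that("a 12-mer with two flexible nucleosomes per end has 8 ordered members", {
  fib <- build_fiber(fiber_spec(n_nucleosomes = 12,
                                terminal_flexible_count = 2,
                                preset = "cenpn_like"))
  ord <- order_nucleosomes(fib)
  expect_identical(sum(ord$ordered_flag), 8L)
  expect_identical(nrow(ord), 12L)
  expect_false(any(ord$ordered_flag[c(1, 2, 11, 12)]))

  full <- build_fiber(fiber_spec(n_nucleosomes = 6,
                                 terminal_flexible_count = 0,
                                 factor_copies = 0))
  expect_identical(sum(order_nucleosomes(full)$ordered_flag), 6L)

  all_flex <- build_fiber(fiber_spec(n_nucleosomes = 6,
                                     terminal_flexible_count = 3,
                                     factor_copies = 0))
  expect_error(order_nucleosomes(all_flex), "insufficient")
})

test_that("fiber step series have the right lengths and preset geometry", {
  fib <- build_fiber(fiber_spec(n_nucleosomes = 5,
                                terminal_flexible_count = 0,
                                factor_copies = 0, rise = 30,
                                twist = 170, tilt_out = 18))
  steps <- fiber_steps(order_nucleosomes(fib))
  expect_identical(sum(steps$offset == 1), 4L)
  expect_identical(sum(steps$offset == 2), 3L)
  # two-start: (n, n+2) pairs nearly parallel, (n, n+1) pairs across
  expect_lt(max(steps$tilt[steps$offset == 2]), 15)
  expect_gt(min(steps$center_distance[steps$offset == 1]),
            max(steps$center_distance[steps$offset == 2]))

  lad <- build_fiber(fiber_spec(n_nucleosomes = 6, preset = "ladder",
                                terminal_flexible_count = 0))
  lord <- order_nucleosomes(lad)
  lsteps <- fiber_steps(lord)
  expect_lt(max(abs(lsteps$twist[lsteps$offset == 2])), 1e-9)
  lfit <- fiber_helix_fit(lord)
  expect_equal(lfit$twist_per_nucleosome, 0, tolerance = 1e-9)
  expect_gt(lfit$rise_per_nucleosome, 0)

  three <- build_fiber(fiber_spec(n_nucleosomes = 3,
                                  terminal_flexible_count = 0,
                                  factor_copies = 0))
  s3 <- fiber_steps(order_nucleosomes(three))
  expect_identical(nrow(s3), 3L)   # 2 + 1 steps
})

test_that("start-number classification: two-start, one-start, and degenerate input", {
  two <- build_fiber(fiber_spec(preset = "cenpn_like"))
  cls <- classify_start_number(fiber_steps(order_nucleosomes(two)))
  expect_identical(cls$start_number, 2L)
  expect_identical(cls$partner_offset, 2L)

  # solenoid-like: consecutive nucleosomes stack (small twist, short rise)
  sol <- build_fiber(fiber_spec(n_nucleosomes = 8, rise = 40, twist = 30,
                                tilt_out = 5, radius = 45,
                                terminal_flexible_count = 0,
                                factor_copies = 0))
  scls <- classify_start_number(fiber_steps(order_nucleosomes(sol)))
  expect_identical(scls$start_number, 1L)

  pair <- build_fiber(fiber_spec(n_nucleosomes = 2,
                                 terminal_flexible_count = 0,
                                 factor_copies = 0))
  expect_error(fiber_steps(order_nucleosomes(pair)), ">= 3")

  tie <- data.frame(offset = c(1, 2), center_distance = c(50, 50.2))
  expect_identical(classify_start_number(tie)$status, "ambiguous")
})

test_that("helix fit recovers generator rise/twist exactly (noiseless) and within 5% under jitter", {
  fib <- build_fiber(fiber_spec(n_nucleosomes = 12, rise = 30,
                                twist = 160, tilt_out = 10,
                                terminal_flexible_count = 0,
                                factor_copies = 0))
  fit <- fiber_helix_fit(order_nucleosomes(fib))
  expect_equal(fit$rise_per_nucleosome, 30, tolerance = 1e-6)
  expect_equal(fit$twist_per_nucleosome, 160, tolerance = 1e-6)
  expect_identical(fit$n_ordered, 12L)

  # 0.5 A coordinate jitter, fixed seed
  xyz <- model_coords(fib$structure)
  jit <- nucstack:::.with_seed(77,
    xyz + matrix(rnorm(length(xyz), 0, 0.5), nrow(xyz), 3))
  fitj <- fiber_helix_fit(order_nucleosomes(set_coords(fib, jit)))
  expect_equal(fitj$rise_per_nucleosome, 30, tolerance = 0.05 * 30)
  expect_equal(fitj$twist_per_nucleosome, 160, tolerance = 0.05 * 160)
})

test_that("helix fit is invariant under rigid motion and order reversal", {
  set.seed(61)
  fib <- build_fiber(fiber_spec(n_nucleosomes = 8, rise = 25, twist = 165,
                                tilt_out = 12, terminal_flexible_count = 0,
                                factor_copies = 0))
  fit <- fiber_helix_fit(order_nucleosomes(fib))
  moved <- rigid_move_complex(fib, random_rotation(), rnorm(3, 0, 100))
  fitm <- fiber_helix_fit(order_nucleosomes(moved))
  expect_equal(fitm$rise_per_nucleosome, fit$rise_per_nucleosome,
               tolerance = 1e-6)
  expect_equal(fitm$twist_per_nucleosome, fit$twist_per_nucleosome,
               tolerance = 1e-6)
  expect_equal(fitm$stacked_pair_distance, fit$stacked_pair_distance,
               tolerance = 1e-6)

  rev_cx <- fib
  rev_cx$nucleosomes <- rev(fib$nucleosomes)
  frev <- fiber_helix_fit(order_nucleosomes(rev_cx))
  expect_equal(abs(frev$rise_per_nucleosome), fit$rise_per_nucleosome,
               tolerance = 1e-6)
  expect_equal(abs(frev$twist_per_nucleosome),
               abs(fit$twist_per_nucleosome), tolerance = 1e-6)
  crev <- classify_start_number(fiber_steps(order_nucleosomes(rev_cx)))
  expect_identical(crev$start_number, 2L)
})

test_that("bridging-factor preset orderings distinguish the fiber types", {
  cen <- fiber_helix_fit(order_nucleosomes(
    build_fiber(fiber_spec(preset = "cenpn_like"))))
  h1 <- fiber_helix_fit(order_nucleosomes(
    build_fiber(fiber_spec(preset = "h1_like"))))
  expect_gt(cen$stacked_pair_distance, h1$stacked_pair_distance)
  expect_gt(cen$stacked_pair_angle, h1$stacked_pair_angle)
  expect_gt(abs(cen$twist_per_nucleosome), abs(h1$twist_per_nucleosome))
  expect_identical(cen$start_number, 2L)
  expect_identical(h1$start_number, 2L)
})

test_that("linker accounting is exact integer arithmetic", {
  expect_identical(linker_accounting(array_definition(12, 167)), 20L)
  expect_identical(linker_accounting(array_definition(12, 207)), 60L)
  expect_identical(linker_accounting(array_definition(1, 147)), 0L)
  a <- array_definition(12, 167)
  expect_identical(a$wrapped_length + linker_accounting(a),
                   a$repeat_length)
  expect_error(array_definition(12, 100), ">= wrapped_length")
})
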