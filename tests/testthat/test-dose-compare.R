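dvh_of <- function(volumes, bin_width = 1)
  structure(list(bin_width = bin_width, volumes = volumes,
                 structure = "test"), class = "dvh")

test_that("compute_dvh reproduces enumerable step functions", {
  dims <- c(3, 3, 1)
  uniform <- dose_grid(array(2, dims), spacing_cm = c(1, 1, 1))
  dvh <- compute_dvh(uniform, full_mask(dims), bin_width = 1)
  expect_equal(dvh$volumes, c(100, 100, 100, 0))

  two <- dose_grid(array(c(1, 3), c(2, 1, 1)), spacing_cm = c(1, 1, 1))
  dvh2 <- compute_dvh(two, full_mask(c(2, 1, 1)), bin_width = 1)
  expect_equal(dvh2$volumes, c(100, 100, 50, 50, 0))

  empty <- structure_mask("none", array(FALSE, dims))
  expect_error(compute_dvh(uniform, empty, 1), "empty")
})

test_that("DVH invariants hold on random grids", {
  for (seed in 1:5) {
    g <- random_dose_grid(c(7, 6, 5), seed = seed)
    dvh <- compute_dvh(g, full_mask(c(7, 6, 5)), bin_width = max(g$values) / 50)
    expect_equal(dvh$volumes[1], 100)
    expect_true(all(diff(dvh$volumes) <= 0))
    expect_equal(dvh$volumes[length(dvh$volumes)], 0)
  }
})

test_that("percentage of agreement matches the hand-worked example", {
  expect_equal(
    percentage_of_agreement(dvh_of(c(100, 50, 0)), dvh_of(c(100, 40, 0))),
    100 * (1 - 10 / 150), tolerance = 1e-12)
})

test_that("PA limit cases: identity, zero histogram, symmetry, bounds", {
  h <- dvh_of(c(100, 80, 30, 0))
  expect_identical(percentage_of_agreement(h, h), 100)
  expect_identical(percentage_of_agreement(h, dvh_of(c(0, 0, 0, 0))), 0)
  set.seed(2)
  for (i in 1:10) {
    v1 <- c(100, sort(runif(5, 0, 100), decreasing = TRUE), 0)
    v2 <- c(100, sort(runif(5, 0, 100), decreasing = TRUE), 0)
    pa12 <- percentage_of_agreement(dvh_of(v1), dvh_of(v2))
    expect_equal(pa12, percentage_of_agreement(dvh_of(v2), dvh_of(v1)))
    expect_gte(pa12, 0); expect_lte(pa12, 100)
  }
  # unequal lengths: shorter histogram is zero-padded
  expect_equal(
    percentage_of_agreement(dvh_of(c(100, 50, 0, 0)), dvh_of(c(100, 50))),
    100)
  expect_error(percentage_of_agreement(dvh_of(c(0, 0)), dvh_of(c(0, 0))),
               "undefined")
  expect_error(percentage_of_agreement(dvh_of(c(100, 0)),
                                       dvh_of(c(100, 0), bin_width = 2)),
               "bin width")
})

test_that("widening a single bin difference never increases PA", {
  base <- c(100, 70, 40, 0)
  pa_prev <- 100
  for (drop in seq(0, 40, by = 10)) {
    v2 <- base; v2[3] <- base[3] - drop
    pa <- percentage_of_agreement(dvh_of(base), dvh_of(v2))
    expect_lte(pa, pa_prev + 1e-12)
    pa_prev <- pa
  }
})

test_that("gamma is 0 for identical grids and tolerant to bounded offsets", {
  g <- random_dose_grid(c(8, 8, 4), seed = 3)
  crit <- gamma_criteria(2, 2)
  expect_identical(gamma_pass_rate(g, g, crit), 100)
  shifted <- dose_grid(g$values * 1.01, g$spacing_cm, g$origin_cm)
  expect_identical(gamma_pass_rate(g, shifted, crit), 100)
})

test_that("a single hot voxel fails gamma exactly as enumerated", {
  dims <- c(5, 5, 1)
  ref <- dose_grid(array(1, dims), spacing_cm = c(1, 1, 1))
  ev_vals <- array(1, dims); ev_vals[3, 3, 1] <- 1.05
  ev <- dose_grid(ev_vals, spacing_cm = c(1, 1, 1))
  crit <- gamma_criteria(3, 0.0001)   # vanishing DTA: pure dose comparison
  expect_equal(gamma_pass_rate(ref, ev, crit), 100 * 24 / 25)
})

test_that("optimized gamma equals the exhaustive oracle on small grids", {
  crit <- gamma_criteria(3, 3, search_step_fraction = 0.25,
                         search_radius_factor = 1.5)
  for (seed in 1:4) {
    ref <- random_dose_grid(c(6, 5, 4), seed = seed)
    ev_vals <- ref$values * (1 + 0.04 * sin(seed + seq_along(ref$values)))
    ev <- dose_grid(array(ev_vals, dim = dim(ref$values)), ref$spacing_cm)
    opt <- gamma_pass_rate(ref, ev, crit, return_gamma = TRUE)
    brute <- gamma_brute(ref, ev, crit)
    expect_equal(opt$gamma, unname(brute$gamma), tolerance = 1e-12)
    expect_equal(opt$pass_rate, brute$pass_rate, tolerance = 1e-12)
  }
})

test_that("GPR never decreases when criteria are loosened", {
  ref <- random_dose_grid(c(7, 7, 3), seed = 5)
  ev <- dose_grid(ref$values * (1 + 0.03 * cos(seq_along(ref$values))),
                  ref$spacing_cm)
  g21 <- gamma_pass_rate(ref, ev, gamma_criteria(2, 1))
  g22 <- gamma_pass_rate(ref, ev, gamma_criteria(2, 2))
  g31 <- gamma_pass_rate(ref, ev, gamma_criteria(3, 1))
  g33 <- gamma_pass_rate(ref, ev, gamma_criteria(3, 3))
  expect_gte(g22, g21); expect_gte(g31, g21); expect_gte(g33, g22)
  expect_gte(g33, g31)
})

test_that("systematic differences separate offsets from noise", {
  dims <- c(8, 8, 4)
  zero_sig <- array(0, dims)
  g <- random_dose_grid(dims, seed = 6, sigma = zero_sig)
  m <- full_mask(dims)
  # identical grids: alpha = 0 for every positive delta
  sd0 <- systematic_differences(g, g, m)
  expect_true(all(sd0$alpha_percent == 0))
  # constant offset of 2% of max: step response at delta = 2 (uniform grids
  # keep the voxel difference bit-identical across the whole domain)
  ref_u <- dose_grid(array(1, dims), g$spacing_cm, sigma = zero_sig)
  off <- dose_grid(array(0.98, dims), g$spacing_cm, sigma = zero_sig)
  sd2 <- systematic_differences(ref_u, off, m,
                                delta_grid_percent = c(0.5, 1, 1.5, 2, 2.5, 3))
  expect_true(all(sd2$alpha_percent[sd2$delta_percent <= 2] == 100))
  expect_true(all(sd2$alpha_percent[sd2$delta_percent > 2] == 0))
  # alpha is non-increasing in delta by construction
  expect_true(all(diff(sd0$alpha_percent) <= 0))
  # sigma is mandatory
  g2 <- random_dose_grid(dims, seed = 6)
  expect_error(systematic_differences(g2, g2, m), "sigma")
})

test_that("pure noise is suppressed by the quadrature subtraction", {
  ph <- make_phantom(shape = c(21, 21, 11))
  plan <- make_vmat_plan(cp_count = 10)
  d1 <- compute_dose(plan, ph, noise_relative = 0.003, seed = 100)
  d2 <- compute_dose(plan, ph, noise_relative = 0.003, seed = 200)
  sd <- systematic_differences(d1, d2, phantom_masks(ph)$body,
                               delta_grid_percent = 1)
  expect_lt(sd$alpha_percent, 5)
})

test_that("alpha is symmetric under swapping when sigmas match and norm is fixed", {
  dims <- c(6, 6, 3)
  sig <- array(0.005, dims)
  a <- random_dose_grid(dims, seed = 8, sigma = sig)
  b_vals <- a$values * (1 + 0.02 * sin(seq_along(a$values)))
  b <- dose_grid(array(b_vals, dims), a$spacing_cm, sigma = sig)
  m <- full_mask(dims)
  norm <- max(pmax(a$values, b$values))
  # low domain threshold so both orderings analyze the same voxel set
  expect_equal(
    systematic_differences(a, b, m, dose_threshold_percent = 1,
                           norm_dose = norm)$alpha_percent,
    systematic_differences(b, a, m, dose_threshold_percent = 1,
                           norm_dose = norm)$alpha_percent)
})

test_that("compare_doses aggregates consistently and round trips", {
  ph <- make_phantom(shape = c(17, 17, 9))
  masks <- phantom_masks(ph)
  plan <- make_vmat_plan(cp_count = 8)
  ref <- compute_dose(plan, ph)
  report <- compare_doses(ref, ref, masks, criteria = list(c(2, 2)))
  for (row in report$structures) {
    expect_equal(row$pa, 100)
    expect_equal(row$gpr_2_2, 100)
  }
  # per-structure PA equals calling the primitive directly
  ev <- dose_grid(ref$values * 0.97, ref$spacing_cm, ref$origin_cm)
  rep2 <- compare_doses(ref, ev, masks, criteria = list(c(2, 2)))
  direct <- percentage_of_agreement(
    compute_dvh(ref, masks$ptv, rep2$bin_width),
    compute_dvh(ev, masks$ptv, rep2$bin_width))
  ptv_row <- Filter(function(r) r$structure == "ptv", rep2$structures)[[1]]
  expect_equal(ptv_row$pa, direct)
  # serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep2, path)
  back <- read_report(path)
  expect_equal(back$structures, rep2$structures, tolerance = 1e-12)
  expect_equal(back$bin_width, rep2$bin_width, tolerance = 1e-12)
})
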