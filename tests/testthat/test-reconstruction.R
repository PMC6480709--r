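test_that("UR at the native tick selects every record", {
  field <- random_field(n = 17)
  idx <- selected_indices(field, reconstruction_config("ur"))
  expect_identical(idx, 1:17)
})

test_that("UR with a coarser interval subsamples and keeps the last record", {
  field <- random_field(n = 10)
  idx <- selected_indices(field,
                          reconstruction_config("ur", interval_ms = 100L))
  expect_identical(idx, c(1L, 3L, 5L, 7L, 9L, 10L))
  expect_error(
    selected_indices(field, reconstruction_config("ur", interval_ms = 75L)),
    "multiple")
})

test_that("PSR picks the first record of each segment plus the endpoints", {
  field <- random_field(n = 6)
  field$segment <- c(0L, 0L, 1L, 1L, 2L, 2L)
  idx <- selected_indices(field, reconstruction_config("psr"))
  expect_identical(idx, c(1L, 3L, 5L, 6L))
})

test_that("PSR control-point count equals the original plan's on simulated deliveries", {
  for (cp in c(11, 40)) {
    plan <- make_vmat_plan(cp_count = cp)
    pair <- simulate_delivery(plan, leaf_error_model("gaussian"),
                              records_per_segment = 4, seed = 5)
    field <- merge_banks(pair$a, pair$b)
    beam <- reconstruct(field, reconstruction_config("psr"))
    expect_identical(length(beam$cumulative_weight), as.integer(cp))
  }
})

test_that("PSR-ED limits: zero tolerance keeps all, large tolerance reduces to PSR", {
  pair <- simulate_delivery(make_vmat_plan(cp_count = 11),
                            leaf_error_model("gaussian", sigma_mm = 0.5),
                            records_per_segment = 4, seed = 6)
  field <- merge_banks(pair$a, pair$b)
  n <- length(field$time_ms)
  mle <- max_leaf_error(field)
  all_idx <- selected_indices(field,
                              reconstruction_config("psr_ed",
                                                    tolerance_mm = 0))
  expect_identical(all_idx, seq_len(n))
  psr <- selected_indices(field, reconstruction_config("psr"))
  for (tol in c(mle, mle * 2))
    expect_identical(
      selected_indices(field,
                       reconstruction_config("psr_ed", tolerance_mm = tol)),
      psr)
})

test_that("PSR-ED selection equals a brute-force union oracle", {
  pair <- simulate_delivery(make_vmat_plan(cp_count = 9),
                            leaf_error_model("gaussian", sigma_mm = 0.4),
                            records_per_segment = 5, seed = 8)
  field <- merge_banks(pair$a, pair$b)
  for (tol in c(0, 0.2, 0.5, 0.9, 1.5))
    expect_identical(
      selected_indices(field,
                       reconstruction_config("psr_ed", tolerance_mm = tol)),
      psr_ed_brute(field, tol))
})

test_that("selection is monotone: PSR within PSR-ED within all records", {
  pair <- simulate_delivery(make_vmat_plan(cp_count = 13),
                            leaf_error_model("gaussian", sigma_mm = 0.6),
                            records_per_segment = 4, seed = 10)
  field <- merge_banks(pair$a, pair$b)
  psr <- selected_indices(field, reconstruction_config("psr"))
  n <- length(field$time_ms)
  set.seed(3)
  tols <- sort(runif(8, 0.01, max_leaf_error(field) * 1.1),
               decreasing = TRUE)
  prev <- psr
  for (tol in tols) {
    cur <- selected_indices(field,
                            reconstruction_config("psr_ed",
                                                  tolerance_mm = tol))
    expect_true(all(psr %in% cur))
    expect_true(all(prev %in% cur))   # non-increasing tolerance adds records
    expect_true(all(cur %in% seq_len(n)))
    prev <- cur
  }
})

test_that("expected and actual reconstructions differ only in leaf positions", {
  pair <- simulate_delivery(make_vmat_plan(cp_count = 11),
                            leaf_error_model("gaussian", sigma_mm = 0.5),
                            records_per_segment = 3, seed = 4)
  field <- merge_banks(pair$a, pair$b)
  be <- reconstruct(field, reconstruction_config("psr", source = "expected"))
  ba <- reconstruct(field, reconstruction_config("psr", source = "actual"))
  expect_identical(be$cumulative_weight, ba$cumulative_weight)
  expect_identical(be$gantry_deg, ba$gantry_deg)
  expect_identical(be$jaws_cm, ba$jaws_cm)
  expect_false(identical(be$mlc_cm, ba$mlc_cm))
  expect_identical(be$provenance, "reconstructed_expected")
  expect_identical(ba$provenance, "reconstructed_actual")
  expect_true(all(diff(be$cumulative_weight) >= 0))
  expect_equal(be$cumulative_weight[length(be$cumulative_weight)], 1)
})

test_that("beam-hold records are excluded from PSR and flagged under UR", {
  field <- random_field(n = 12)
  field$segment <- rep(0:3, each = 3)
  field$beam_hold <- rep(FALSE, 12)
  field$beam_hold[c(4, 10)] <- TRUE   # holds at two segment transitions
  idx <- selected_indices(field, reconstruction_config("psr"))
  expect_false(any(field$beam_hold[idx]))
  expect_warning(selected_indices(field, reconstruction_config("ur")),
                 "hold")
})

test_that("degenerate streams are rejected", {
  field <- random_field(n = 8)
  field$beam_on <- rep(FALSE, 8)
  expect_error(selected_indices(field, reconstruction_config("ur")),
               "beam-on")
  field2 <- random_field(n = 8)
  field2$dose_fraction <- rep(0, 8)
  expect_error(reconstruct(field2, reconstruction_config("psr")), "dose")
})
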