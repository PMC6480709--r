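test_that("native dialect write/parse round trip is exact for arbitrary values", {
  field <- random_field(n = 10, seed = 42)
  # perturb off the quantization grid: the native dialect must still be exact
  field$expected_cm <- field$expected_cm + pi * 1e-5
  field$actual_cm <- field$actual_cm + exp(1) * 1e-5
  pair <- split_field(field)
  d <- dynalog_dialect("native")
  for (bank in pair) {
    path <- withr::local_tempfile()
    write_bank_file(bank, path, d)
    back <- parse_bank_file(path, d)
    expect_identical(back$expected_cm, bank$expected_cm)
    expect_identical(back$actual_cm, bank$actual_cm)
    expect_identical(back$dose_fraction, bank$dose_fraction)
    expect_identical(back$segment, bank$segment)
    expect_identical(back$bank_id, bank$bank_id)
  }
})

test_that("clinac dialect round trips quantized banks and is byte-stable", {
  pair <- split_field(random_field(n = 15, seed = 7))
  d <- dynalog_dialect("clinac")
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bank_file(pair$a, p1, d)
  write_bank_file(pair$a, p2, d)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  back <- parse_bank_file(p1, d)
  for (fld in c("time_ms", "segment", "gantry_deg", "dose_fraction",
                "expected_cm", "actual_cm", "jaws_cm"))
    expect_equal(back[[fld]], pair$a[[fld]], tolerance = 1e-12)
})

test_that("clinac positions are integers in hundredths of a millimetre", {
  # in-memory 5 cm must be stored as raw 5000 and read back as 5 cm
  expected <- matrix(5, 3, 4)
  field <- make_field(expected)
  pair <- split_field(field)
  path <- withr::local_tempfile()
  write_bank_file(pair$a, path, dynalog_dialect("clinac"))
  rec <- strsplit(readLines(path)[2], ",")[[1]]
  expect_identical(rec[11], "5000")
  back <- parse_bank_file(path, dynalog_dialect("clinac"))
  expect_equal(back$expected_cm[1, 1], 5)
})

test_that("a missing tick produces a warning and the gap is preserved", {
  pair <- split_field(random_field(n = 10))
  bank <- pair$a
  keep <- setdiff(seq_len(10), 5)
  for (fld in c("time_ms", "beam_on", "beam_hold", "segment", "gantry_deg",
                "dose_fraction"))
    bank[[fld]] <- bank[[fld]][keep]
  for (fld in c("jaws_cm", "expected_cm", "actual_cm"))
    bank[[fld]] <- bank[[fld]][keep, , drop = FALSE]
  path <- withr::local_tempfile()
  expect_warning(write_bank_file(bank, path), "gap")
  back <- NULL
  expect_warning(back <- parse_bank_file(path), "gap")
  expect_identical(diff(back$time_ms)[4], 100L)
})

test_that("malformed records are rejected with their line number", {
  pair <- split_field(random_field(n = 5))
  path <- withr::local_tempfile()
  write_bank_file(pair$a, path)
  lines <- readLines(path)
  lines[4] <- paste(lines[4], "999", sep = ",")  # extra field on record 3
  writeLines(lines, path)
  expect_error(parse_bank_file(path), "line 4")
  lines <- readLines(path)
  expect_error(parse_bank_file(withr::local_tempfile(lines = "bogus")),
               "signature")
})

test_that("merge_banks concatenates leaves and checks consistency", {
  pair <- split_field(random_field(n = 20, leaves_per_bank = 60))
  field <- merge_banks(pair$a, pair$b)
  expect_identical(dim(field$expected_cm), c(20L, 120L))
  expect_identical(field$leaf_count_per_bank, 60L)

  # record-count mismatch
  short <- pair$b
  for (fld in c("time_ms", "beam_on", "beam_hold", "segment", "gantry_deg",
                "dose_fraction"))
    short[[fld]] <- short[[fld]][-20]
  for (fld in c("jaws_cm", "expected_cm", "actual_cm"))
    short[[fld]] <- short[[fld]][-20, , drop = FALSE]
  expect_error(merge_banks(pair$a, short), "mismatch")

  # gantry disagreement is reported with its record index
  off <- pair$b
  off$gantry_deg[7] <- off$gantry_deg[7] + 5
  expect_error(merge_banks(pair$a, off), "record 7")

  # bank order is enforced
  expect_error(merge_banks(pair$b, pair$a), "bank A then bank B")
})

test_that("leaf errors are expected minus actual", {
  expected <- matrix(5.00, 2, 4)
  actual <- matrix(4.98, 2, 4)
  field <- make_field(expected, actual)
  eps <- leaf_errors(field)
  expect_equal(eps, matrix(0.02, 2, 4), tolerance = 1e-12)
  expect_equal(eps + field$actual_cm, field$expected_cm)

  same <- make_field(expected)
  expect_true(all(leaf_errors(same) == 0))
})

test_that("rms_error matches hand-worked values and a plain-loop oracle", {
  # errors of 0.3 mm and 0.4 mm on each record -> sqrt((0.09 + 0.16)/2)
  field <- make_field(rbind(c(2, 3), c(2, 3)),
                      rbind(c(2 - 0.03, 3 - 0.04), c(2 - 0.03, 3 - 0.04)))
  expect_equal(rms_error(field), sqrt((0.09 + 0.16) / 2), tolerance = 1e-12)

  rf <- random_field(n = 25, leaves_per_bank = 8, seed = 3)
  expect_equal(rms_error(rf), rms_brute(rf), tolerance = 1e-12)
  expect_true(rms_error(rf) <= max_leaf_error(rf))

  zero <- make_field(matrix(1, 3, 4))
  expect_identical(rms_error(zero), 0)
})

test_that("rms_error is invariant under record/leaf permutation", {
  rf <- random_field(n = 30, leaves_per_bank = 6, seed = 9)
  perm <- random_field(n = 30, leaves_per_bank = 6, seed = 9)
  set.seed(11)
  ri <- sample(30); li <- sample(12)
  perm$expected_cm <- perm$expected_cm[ri, li]
  perm$actual_cm <- perm$actual_cm[ri, li]
  expect_equal(rms_error(perm), rms_error(rf), tolerance = 1e-12)
})

test_that("rms beam_on filter errors when nothing is eligible", {
  field <- make_field(matrix(1, 4, 4), beam_on = rep(FALSE, 4))
  expect_error(rms_error(field, beam_on_only = TRUE), "eligible")
})

test_that("max_leaf_error is the max absolute error in mm", {
  expected <- rbind(c(3, 3, 3), c(3, 3, 3))
  actual <- expected - rbind(c(0.01, -0.05, 0.03), c(0, 0, 0))
  field <- make_field(expected, actual)
  expect_equal(max_leaf_error(field), 0.5, tolerance = 1e-12)
  expect_identical(max_leaf_error(make_field(expected)), 0)
})
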