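# In-code fixtures: small dynalog fields and dose grids built from scratch.

# Build a merged dynalog field directly from expected/actual matrices
# (columns: 2 * leaves_per_bank, bank A first).
make_field <- function(expected_cm, actual_cm = expected_cm,
                       segment = NULL, dose_fraction = NULL,
                       gantry_deg = NULL, beam_on = NULL, beam_hold = NULL,
                       tick_ms = 50) {
  n <- nrow(expected_cm)
  L <- ncol(expected_cm) / 2
  if (is.null(segment)) segment <- rep(0L, n)
  if (is.null(dose_fraction)) dose_fraction <- seq(0, 1, length.out = n)
  if (is.null(gantry_deg)) gantry_deg <- rep(180, n)
  if (is.null(beam_on)) beam_on <- rep(TRUE, n)
  if (is.null(beam_hold)) beam_hold <- rep(FALSE, n)
  jaws <- matrix(rep(c(-10, 10, -10, 10), each = n), n, 4)
  mk <- function(id, cols) dynalog_bank(
    bank_id = id, linac_type = if (tick_ms == 50) "clinac" else "truebeam",
    time_ms = (seq_len(n) - 1L) * tick_ms, beam_on = beam_on,
    beam_hold = beam_hold, segment = segment, gantry_deg = gantry_deg,
    jaws_cm = jaws, dose_fraction = dose_fraction,
    expected_cm = expected_cm[, cols, drop = FALSE],
    actual_cm = actual_cm[, cols, drop = FALSE])
  suppressWarnings(merge_banks(mk("A", seq_len(L)), mk("B", L + seq_len(L))))
}

# A small random field with quantized (0.01 mm) positions, valid in the
# clinac dialect.
random_field <- function(n = 12, leaves_per_bank = 5, err_sd_cm = 0.05,
                         seed = 1) {
  set.seed(seed)
  L2 <- 2 * leaves_per_bank
  expected <- round(matrix(runif(n * L2, 1, 6), n, L2), 3)
  actual <- round(expected + matrix(rnorm(n * L2, 0, err_sd_cm), n, L2), 3)
  make_field(expected, actual,
             segment = sort(sample(0:3, n, replace = TRUE)),
             dose_fraction = round(seq(0, 1, length.out = n) * 25000) / 25000)
}

# A smooth positive random dose grid.
random_dose_grid <- function(dims, spacing = c(0.25, 0.25, 0.25), seed = 1,
                             sigma = NULL) {
  set.seed(seed)
  ax <- lapply(dims, function(n) seq(0, 1, length.out = n))
  base <- outer(outer(sin(pi * ax[[1]]) + 1.2, sin(pi * ax[[2]]) + 1.1),
                cos(pi * ax[[3]] / 2) + 1.05)
  vals <- array(base, dim = dims) * (1 + 0.05 * array(runif(prod(dims)),
                                                      dim = dims))
  dose_grid(vals, spacing_cm = spacing, sigma = sigma)
}

full_mask <- function(dims) structure_mask("all", array(TRUE, dims))
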