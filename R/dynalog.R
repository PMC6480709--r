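#' @useDynLib dynaverify, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm approx
NULL

# -- dialects -----------------------------------------------------------------

#' Dynalog file dialects
#'
#' A dialect descriptor fixes how a dynalog bank file is laid out on disk:
#' the field separator, the integer scale of leaf/jaw positions, the full-scale
#' value of the cumulative dose counter and the unit of the gantry column.
#' Two dialects ship with the package:
#' \describe{
#'   \item{\code{"clinac"}}{Integer columns in the style of a Clinac
#'     Millennium-120 controller log: positions and jaws in hundredths of a
#'     millimetre (1000 counts per cm), gantry in tenths of a degree,
#'     cumulative dose on a 0--25000 counter, comma separated.}
#'   \item{\code{"native"}}{A self-describing tab-separated dialect used for
#'     synthetic data: all quantities in their in-memory units (cm, degrees,
#'     dose fraction in [0,1]) printed with full double precision, so a
#'     write/parse round trip is exact for arbitrary values.}
#' }
#'
#' @param name dialect name, \code{"clinac"} or \code{"native"}.
#' @return a list with components \code{name}, \code{sep},
#'   \code{pos_counts_per_cm}, \code{gantry_counts_per_deg},
#'   \code{dose_full_scale} and \code{integer_cols}.
#' @export
dynalog_dialect <- function(name = c("clinac", "native")) {
  name <- match.arg(name)
  switch(name,
    clinac = list(name = "clinac", sep = ",",
                  pos_counts_per_cm = 1000,   # hundredths of a millimetre
                  gantry_counts_per_deg = 10, # tenths of a degree
                  dose_full_scale = 25000,
                  integer_cols = TRUE),
    native = list(name = "native", sep = "\t",
                  pos_counts_per_cm = 1,
                  gantry_counts_per_deg = 1,
                  dose_full_scale = 1,
                  integer_cols = FALSE))
}

linac_tick_ms <- function(linac_type) {
  switch(linac_type, clinac = 50L, truebeam = 20L,
         stop("unknown linac type: ", linac_type))
}

# -- dynalog bank -------------------------------------------------------------

#' Construct a dynalog bank
#'
#' One bank file corresponds to one MLC carriage (A or B) and holds the record
#' stream written by the controller every 50 ms (20 ms on TrueBeam): beam
#' status, hold-off flag, segment index, gantry angle, jaw positions, the
#' cumulative fraction of delivered dose, and the expected and actual position
#' of every leaf of that bank, in cm at the isocenter plane. Leaf coordinates
#' increase in the leaf's opening direction, so subtracting a positive error
#' from a position always shrinks the aperture.
#'
#' @param bank_id \code{"A"} or \code{"B"}.
#' @param linac_type \code{"clinac"} (50 ms tick) or \code{"truebeam"} (20 ms).
#' @param time_ms integer vector, milliseconds since field start.
#' @param beam_on,beam_hold logical vectors.
#' @param segment non-decreasing integer vector; index of the transition
#'   interval between two original control points.
#' @param gantry_deg gantry angle in degrees, wrapped to [0, 360).
#' @param jaws_cm n x 4 matrix (x1, x2, y1, y2) in cm at isocenter.
#' @param dose_fraction non-decreasing cumulative dose fraction in [0, 1].
#' @param expected_cm,actual_cm n x L matrices of leaf positions, cm.
#' @param header named list of free-form metadata.
#' @return an object of class \code{dynalog_bank}.
#' @export
dynalog_bank <- function(bank_id, linac_type = "clinac", time_ms, beam_on,
                         beam_hold, segment, gantry_deg, jaws_cm,
                         dose_fraction, expected_cm, actual_cm,
                         header = list()) {
  stopifnot(bank_id %in% c("A", "B"))
  expected_cm <- as.matrix(expected_cm)
  actual_cm <- as.matrix(actual_cm)
  jaws_cm <- as.matrix(jaws_cm)
  n <- length(time_ms)
  bank <- structure(list(
    bank_id = bank_id, linac_type = linac_type,
    tick_ms = linac_tick_ms(linac_type), header = header,
    time_ms = as.integer(time_ms), beam_on = as.logical(beam_on),
    beam_hold = as.logical(beam_hold), segment = as.integer(segment),
    gantry_deg = as.numeric(gantry_deg), jaws_cm = jaws_cm,
    dose_fraction = as.numeric(dose_fraction),
    expected_cm = expected_cm, actual_cm = actual_cm),
    class = "dynalog_bank")
  validate_dynalog_bank(bank)
  bank
}

validate_dynalog_bank <- function(bank) {
  n <- length(bank$time_ms)
  if (n < 2L)
    stop("dynalog bank must contain at least 2 records, got ", n)
  lens <- c(length(bank$beam_on), length(bank$beam_hold),
            length(bank$segment), length(bank$gantry_deg),
            length(bank$dose_fraction), nrow(bank$jaws_cm),
            nrow(bank$expected_cm), nrow(bank$actual_cm))
  if (any(lens != n))
    stop("inconsistent record count across dynalog bank fields")
  if (ncol(bank$expected_cm) != ncol(bank$actual_cm))
    stop("expected and actual leaf matrices differ in leaf count")
  if (ncol(bank$jaws_cm) != 4L)
    stop("jaws_cm must have four columns (x1, x2, y1, y2)")
  if (any(diff(bank$segment) < 0L))
    stop("segment index must be non-decreasing")
  if (any(diff(bank$dose_fraction) < -1e-9))
    stop("dose_fraction must be non-decreasing")
  if (any(bank$dose_fraction < -1e-9 | bank$dose_fraction > 1 + 1e-9))
    stop("dose_fraction must lie in [0, 1]")
  dt <- diff(bank$time_ms)
  if (any(dt <= 0))
    stop("time_ms must be strictly increasing")
  if (any(dt != bank$tick_ms))
    warning("dynalog bank has ", sum(dt != bank$tick_ms),
            " record gap(s) not equal to the ", bank$tick_ms, " ms tick")
  invisible(bank)
}

n_leaves <- function(x) ncol(x$expected_cm)
n_records <- function(x) length(x$time_ms)

#' @export
print.dynalog_bank <- function(x, ...) {
  cat(sprintf("Dynalog bank %s (%s, %d ms tick): %d records x %d leaves\n",
              x$bank_id, x$linac_type, x$tick_ms, n_records(x), n_leaves(x)))
  invisible(x)
}

# -- bank file I/O ------------------------------------------------------------

fmt_num <- function(x, dialect, scale) {
  if (dialect$integer_cols) sprintf("%d", as.integer(round(x * scale)))
  else sprintf("%.17g", x)
}

#' Write a dynalog bank file
#'
#' Serializes a bank under a given dialect. Writing is deterministic: two
#' writes of the same bank produce byte-identical files. Under the
#' \code{"native"} dialect the emitted file re-parses to an exactly equal
#' bank for arbitrary values; under \code{"clinac"} exactness holds for
#' values already quantized to the dialect's integer resolution (0.01 mm
#' positions, 0.1 degree gantry, 1/25000 dose counts), which is what the
#' controller -- and the synthetic generator -- produce.
#'
#' @param bank a \code{dynalog_bank}.
#' @param path output file path.
#' @param dialect a descriptor from [dynalog_dialect()].
#' @return invisibly, \code{path}.
#' @seealso [parse_bank_file()]
#' @export
write_bank_file <- function(bank, path, dialect = dynalog_dialect("clinac")) {
  validate_dynalog_bank(bank)
  d <- dialect
  n <- n_records(bank)
  L <- n_leaves(bank)
  head_lines <- c(
    sprintf("dynaverify-dynalog\t%s\t%s\t%s\t%d", d$name, bank$bank_id,
            bank$linac_type, L),
    if (length(bank$header))
      sprintf("# %s=%s", names(bank$header), unlist(bank$header)))
  pos <- function(m) {
    cols <- apply(m, 2, fmt_num, dialect = d, scale = d$pos_counts_per_cm)
    matrix(cols, nrow = n)
  }
  body <- cbind(
    sprintf("%d", bank$time_ms),
    sprintf("%d", as.integer(bank$beam_on)),
    sprintf("%d", as.integer(bank$beam_hold)),
    sprintf("%d", bank$segment),
    fmt_num(bank$gantry_deg, d, d$gantry_counts_per_deg),
    pos(bank$jaws_cm),
    fmt_num(bank$dose_fraction, d, d$dose_full_scale),
    pos(bank$expected_cm), pos(bank$actual_cm))
  lines <- c(head_lines, apply(body, 1, paste, collapse = d$sep))
  con <- file(path, "wb")  # binary mode: byte-stable newlines on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Parse a dynalog bank file
#'
#' Reads one bank file, converting raw positions to cm at isocenter, the
#' gantry column to degrees, beam status flags to logicals, and the
#' cumulative dose counter to a fraction in [0, 1], according to the dialect.
#' A record gap (missing tick) is preserved in \code{time_ms} and reported
#' as a warning.
#'
#' @inheritParams write_bank_file
#' @param path path to the bank file.
#' @return a \code{dynalog_bank}.
#' @export
parse_bank_file <- function(path, dialect = dynalog_dialect("clinac")) {
  if (!file.exists(path)) stop("dynalog file not found: ", path)
  d <- dialect
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "dynaverify-dynalog"))
    stop("not a dynalog bank file (missing signature line): ", path)
  sig <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(sig) != 5L)
    stop("malformed dynalog signature line in ", path)
  if (sig[2L] != d$name)
    stop("file declares dialect '", sig[2L], "' but parse requested '",
         d$name, "'")
  bank_id <- sig[3L]; linac <- sig[4L]; L <- as.integer(sig[5L])
  rest <- lines[-1L]
  is_hdr <- startsWith(rest, "# ")
  header <- list()
  if (any(is_hdr)) {
    kv <- sub("^# ", "", rest[is_hdr])
    eq <- regexpr("=", kv, fixed = TRUE)
    header <- as.list(substring(kv, eq + 1L))
    names(header) <- substring(kv, 1L, eq - 1L)
  }
  data_lines <- rest[!is_hdr]
  file_line <- 1L + which(!is_hdr)  # original line number of each data line
  ncol_exp <- 10L + 2L * L
  parts <- strsplit(data_lines, d$sep, fixed = TRUE)
  bad <- which(lengths(parts) != ncol_exp)
  if (length(bad))
    stop("malformed dynalog record at line ", file_line[bad[1L]], " of ",
         path, ": expected ", ncol_exp, " fields, found ",
         lengths(parts)[bad[1L]])
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = ncol_exp, byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1, any))[1L]
    stop("non-numeric field in dynalog record at line ", file_line[bad_row],
         " of ", path)
  }
  jaw_cols <- 6:9
  exp_cols <- 10L + seq_len(L)
  act_cols <- 10L + L + seq_len(L)
  dynalog_bank(
    bank_id = bank_id, linac_type = linac, header = header,
    time_ms = m[, 1L], beam_on = m[, 2L] != 0, beam_hold = m[, 3L] != 0,
    segment = m[, 4L], gantry_deg = m[, 5L] / d$gantry_counts_per_deg,
    jaws_cm = m[, jaw_cols, drop = FALSE] / d$pos_counts_per_cm,
    dose_fraction = m[, 10L] / d$dose_full_scale,
    expected_cm = m[, exp_cols, drop = FALSE] / d$pos_counts_per_cm,
    actual_cm = m[, act_cols, drop = FALSE] / d$pos_counts_per_cm)
}

# -- merging ------------------------------------------------------------------

#' Merge an A/B bank pair into a per-field record stream
#'
#' The controller writes two files per treatment field, one per MLC carriage.
#' \code{merge_banks} checks that the two streams describe the same delivery
#' (equal record counts and time stamps; gantry, segment, jaw and dose streams
#' in agreement within tolerance) and concatenates the per-record leaf vectors
#' (bank A first) into a single \code{dynalog_field}.
#'
#' @param a,b \code{dynalog_bank} objects with \code{bank_id} "A" and "B".
#' @param gantry_tol_deg,dose_tol,jaw_tol_cm agreement tolerances for the
#'   shared scalar streams (taken from bank A after the check).
#' @return an object of class \code{dynalog_field}.
#' @export
merge_banks <- function(a, b, gantry_tol_deg = 0.2, dose_tol = 1e-3,
                        jaw_tol_cm = 1e-3) {
  if (a$bank_id != "A" || b$bank_id != "B")
    stop("merge_banks expects bank A then bank B (got ",
         a$bank_id, ", ", b$bank_id, ")")
  if (n_records(a) != n_records(b))
    stop("record-count mismatch between banks (truncated acquisition?): A has ",
         n_records(a), ", B has ", n_records(b))
  if (a$tick_ms != b$tick_ms)
    stop("banks declare different linac ticks")
  if (any(a$time_ms != b$time_ms))
    stop("bank time stamps disagree at record ",
         which(a$time_ms != b$time_ms)[1L])
  check_stream <- function(what, da, tol) {
    bad <- which(abs(da) > tol)
    if (length(bad))
      stop("banks disagree in ", what, " at record ", bad[1L],
           " (|diff| = ", format(max(abs(da[bad]))), " > ", tol, ")")
  }
  check_stream("gantry angle", a$gantry_deg - b$gantry_deg, gantry_tol_deg)
  check_stream("dose fraction", a$dose_fraction - b$dose_fraction, dose_tol)
  check_stream("segment index", as.numeric(a$segment - b$segment), 0)
  check_stream("jaw positions", as.numeric(a$jaws_cm - b$jaws_cm), jaw_tol_cm)
  if (n_leaves(a) != n_leaves(b))
    stop("banks have different leaf counts")
  structure(list(
    leaf_count_per_bank = n_leaves(a), tick_ms = a$tick_ms,
    linac_type = a$linac_type,
    time_ms = a$time_ms, beam_on = a$beam_on & b$beam_on,
    beam_hold = a$beam_hold | b$beam_hold, segment = a$segment,
    gantry_deg = a$gantry_deg, jaws_cm = a$jaws_cm,
    dose_fraction = a$dose_fraction,
    expected_cm = cbind(a$expected_cm, b$expected_cm),
    actual_cm = cbind(a$actual_cm, b$actual_cm)),
    class = "dynalog_field")
}

#' Split a field back into its A/B bank pair
#'
#' Inverse of [merge_banks()]; used when a modified field (e.g. after
#' [magnify_errors()]) must be written back as a dynalog file pair.
#'
#' @param field a \code{dynalog_field}.
#' @param header named list of free-form metadata copied into both banks.
#' @return list with components \code{a} and \code{b}.
#' @export
split_field <- function(field, header = list()) {
  L <- field$leaf_count_per_bank
  mk <- function(id, cols) dynalog_bank(
    bank_id = id, linac_type = field$linac_type, header = header,
    time_ms = field$time_ms, beam_on = field$beam_on,
    beam_hold = field$beam_hold, segment = field$segment,
    gantry_deg = field$gantry_deg, jaws_cm = field$jaws_cm,
    dose_fraction = field$dose_fraction,
    expected_cm = field$expected_cm[, cols, drop = FALSE],
    actual_cm = field$actual_cm[, cols, drop = FALSE])
  list(a = mk("A", seq_len(L)), b = mk("B", L + seq_len(L)))
}

#' @export
print.dynalog_field <- function(x, ...) {
  cat(sprintf(
    "Dynalog field: %d records x %d leaves (%d per bank), tick %d ms\n",
    length(x$time_ms), 2L * x$leaf_count_per_bank, x$leaf_count_per_bank,
    x$tick_ms))
  cat(sprintf("  RMS %.4f mm, MLE %.4f mm, delivered dose fraction %.3f\n",
              rms_error(x), max_leaf_error(x),
              x$dose_fraction[length(x$dose_fraction)]))
  invisible(x)
}

# -- leaf-error statistics ----------------------------------------------------

#' Per-record, per-leaf position errors
#'
#' The leaf error is \eqn{\epsilon = P_e - P_a}, the expected minus the actual
#' position. Because leaf coordinates increase in the opening direction, a
#' positive error means the leaf fell short of its planned opening.
#'
#' @param field a \code{dynalog_field}.
#' @return matrix (records x leaves) of errors in cm.
#' @export
leaf_errors <- function(field) field$expected_cm - field$actual_cm

#' Root-mean-square leaf position error
#'
#' \eqn{RMS = \sqrt{\frac{1}{N}\sum_{i=1}^{N}(P_{e,i}-P_{a,i})^2}} over all
#' leaf-position pairs in the selected records, in mm. The controller logs
#' leaf pairs also while the beam is held; whether those pairs enter the
#' statistic is controlled by \code{beam_on_only}.
#'
#' @param field a \code{dynalog_field}.
#' @param beam_on_only if \code{TRUE}, restrict to records with the beam on
#'   and not held. Default \code{FALSE}: all pairs present in the files.
#' @return RMS in mm.
#' @export
rms_error <- function(field, beam_on_only = FALSE) {
  e <- leaf_errors(field)
  if (beam_on_only) {
    keep <- field$beam_on & !field$beam_hold
    e <- e[keep, , drop = FALSE]
  }
  if (length(e) == 0L)
    stop("no eligible leaf-position pairs for RMS")
  sqrt(mean((e * 10)^2))
}

#' Maximum leaf error
#'
#' The largest absolute expected-minus-actual leaf position over all records
#' and leaves, in mm. This is the MLE used to scale errors in
#' [magnify_errors()].
#'
#' @param field a \code{dynalog_field}.
#' @return MLE in mm.
#' @export
max_leaf_error <- function(field) max(abs(leaf_errors(field))) * 10
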