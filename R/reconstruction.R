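# Plan reconstruction from a dynalog record stream.

#' Reconstruction configuration
#'
#' Three sampling strategies turn a dynalog record stream into control points:
#' \describe{
#'   \item{UR (uniform reconstruction)}{records taken at a fixed time
#'     interval, minimum one tick (50 ms Clinac / 20 ms TrueBeam), in which
#'     case every record becomes a control point.}
#'   \item{PSR (per-segment reconstruction)}{only records at which the stored
#'     segment number changes, which yields the same number of control points
#'     as the original plan whenever every original transition was logged.}
#'   \item{PSR-ED (PSR with error detection)}{the PSR records plus every
#'     record where at least one leaf has a position error above
#'     \code{tolerance_mm}. Tolerance 0 selects all records; a tolerance at
#'     or above the maximum leaf error reduces to plain PSR.}
#' }
#' Control points can be built from the expected or the actual leaf
#' positions; the two reconstructions differ only in the MLC matrix.
#'
#' @param mode \code{"ur"}, \code{"psr"} or \code{"psr_ed"}.
#' @param source \code{"expected"} or \code{"actual"}.
#' @param interval_ms UR sampling interval, a multiple of the dynalog tick.
#' @param tolerance_mm PSR-ED leaf-error tolerance, finite and >= 0.
#' @return an object of class \code{reconstruction_config}.
#' @export
reconstruction_config <- function(mode = c("ur", "psr", "psr_ed"),
                                  source = c("expected", "actual"),
                                  interval_ms = NULL, tolerance_mm = NULL) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  if (mode == "ur") {
    if (is.null(interval_ms)) interval_ms <- 0L  # resolved to tick later
  }
  if (mode == "psr_ed") {
    if (is.null(tolerance_mm)) stop("psr_ed requires tolerance_mm")
    if (!is.finite(tolerance_mm) || tolerance_mm < 0)
      stop("tolerance_mm must be finite and >= 0")
  }
  structure(list(mode = mode, source = source, interval_ms = interval_ms,
                 tolerance_mm = tolerance_mm),
            class = "reconstruction_config")
}

#' Record indices a reconstruction will use
#'
#' Exposes the sampling decision of [reconstruct()]: the exact (1-based)
#' record indices that become control points, in time order. The first and
#' last eligible records are always included so the reconstructed beam has
#' well-defined weight-0 and weight-1 endpoints.
#'
#' @param field a \code{dynalog_field}.
#' @param cfg a [reconstruction_config()].
#' @return sorted integer vector of record indices.
#' @export
selected_indices <- function(field, cfg) {
  n <- length(field$time_ms)
  on_idx <- which(field$beam_on)
  if (length(on_idx) == 0L)
    stop("reconstruction error: no beam-on records in the field")
  if (cfg$mode == "ur") {
    interval <- cfg$interval_ms
    if (is.null(interval) || interval == 0L) interval <- field$tick_ms
    if (interval %% field$tick_ms != 0L || interval < field$tick_ms)
      stop("UR interval must be a multiple of the ", field$tick_ms, " ms tick")
    step <- interval %/% field$tick_ms
    idx <- sort(unique(c(seq(1L, n, by = step), n)))
    if (any(field$beam_hold[idx]))
      warning("UR selection includes ", sum(field$beam_hold[idx]),
              " beam-hold record(s)")
    return(idx)
  }
  # PSR / PSR-ED operate on the non-hold stream; holds deliver no dose.
  eligible <- which(!field$beam_hold)
  if (length(eligible) < 2L)
    stop("reconstruction error: fewer than 2 non-hold records")
  seg <- field$segment[eligible]
  psr <- eligible[c(1L, which(diff(seg) != 0L) + 1L, length(eligible))]
  idx <- sort(unique(psr))
  if (cfg$mode == "psr_ed") {
    tol <- cfg$tolerance_mm
    if (tol == 0) {
      idx <- eligible  # stated convention: zero tolerance keeps every record
    } else {
      err_mm <- abs(leaf_errors(field)) * 10
      over <- eligible[apply(err_mm[eligible, , drop = FALSE], 1,
                             max) > tol]
      idx <- sort(unique(c(idx, over)))
    }
  }
  if (length(idx) < 2L)
    stop("reconstruction error: selection yields fewer than 2 records")
  idx
}

#' Reconstruct a deliverable beam from a dynalog field
#'
#' Builds an [rt_beam()] whose control points are the records chosen by
#' [selected_indices()], with MLC positions taken from the expected or the
#' actual stream, gantry and jaws copied per record, and cumulative meterset
#' weight taken from the recorded dose fraction, renormalized so the last
#' selected record has weight 1.
#'
#' @inheritParams selected_indices
#' @param meterset_mu meterset assigned to the reconstructed beam.
#' @param leaf_boundaries_cm optional leaf boundaries (defaults to uniform
#'   0.5 cm leaves).
#' @return an \code{rt_beam} with provenance
#'   \code{"reconstructed_expected"} or \code{"reconstructed_actual"}.
#' @export
reconstruct <- function(field, cfg, meterset_mu = 100,
                        leaf_boundaries_cm = NULL) {
  idx <- selected_indices(field, cfg)
  dose <- field$dose_fraction[idx]
  if (dose[length(dose)] <= 0)
    stop("reconstruction error: no dose delivered by the last selected record")
  w <- dose / dose[length(dose)]
  mlc <- switch(cfg$source,
                expected = field$expected_cm,
                actual = field$actual_cm)[idx, , drop = FALSE]
  rt_beam(cumulative_weight = w,
          gantry_deg = field$gantry_deg[idx],
          jaws_cm = field$jaws_cm[idx, , drop = FALSE],
          mlc_cm = mlc, meterset_mu = meterset_mu,
          leaf_boundaries_cm = leaf_boundaries_cm,
          provenance = paste0("reconstructed_", cfg$source),
          name = paste0("recon_", cfg$mode, "_", cfg$source))
}
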