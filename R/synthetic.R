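# Synthetic plans, phantoms and dynalog deliveries with controlled errors.

#' Synthetic leaf-error models
#'
#' Describes how the actual leaf positions of a simulated delivery deviate
#' from the expected ones:
#' \describe{
#'   \item{none}{error-free delivery (actual == expected).}
#'   \item{gaussian}{independent zero-mean Gaussian errors in both
#'     directions (\code{sigma_mm}).}
#'   \item{unidirectional}{errors all of one sign in the opening-direction
#'     convention, i.e. every misplaced leaf shrinks the aperture
#'     (\code{|N(mean_mm, sigma_mm)|}) -- the signature of e.g. a failing
#'     MLC carriage.}
#'   \item{drift}{error growing linearly with time at \code{rate_mm_per_s},
#'     aperture-shrinking.}
#' }
#'
#' @param kind one of \code{"none"}, \code{"gaussian"},
#'   \code{"unidirectional"}, \code{"drift"}.
#' @param sigma_mm Gaussian standard deviation, mm.
#' @param mean_mm mean error for the unidirectional model, mm.
#' @param rate_mm_per_s drift rate, mm per second.
#' @return an object of class \code{leaf_error_model}.
#' @export
leaf_error_model <- function(kind = c("none", "gaussian", "unidirectional",
                                      "drift"),
                             sigma_mm = 0.5, mean_mm = 1,
                             rate_mm_per_s = 0.05) {
  kind <- match.arg(kind)
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  structure(list(kind = kind, sigma_mm = sigma_mm, mean_mm = mean_mm,
                 rate_mm_per_s = rate_mm_per_s),
            class = "leaf_error_model")
}

realize_errors_cm <- function(model, n_rec, n_leaves, time_s) {
  switch(model$kind,
    none = matrix(0, n_rec, n_leaves),
    gaussian = matrix(rnorm(n_rec * n_leaves, 0, model$sigma_mm / 10),
                      n_rec, n_leaves),
    unidirectional = matrix(
      abs(rnorm(n_rec * n_leaves, model$mean_mm / 10,
                model$sigma_mm / 10)), n_rec, n_leaves),
    drift = matrix(rep(time_s * model$rate_mm_per_s / 10, n_leaves),
                   n_rec, n_leaves))
}

#' Generate a deterministic voxel phantom
#'
#' Body = ellipsoid, PTV = sphere at the isocenter, OAR = lateral box; the
#' PTV is always inside the body and disjoint from the OAR.
#'
#' @param shape grid dimensions; default 41 x 41 x 21.
#' @param spacing_cm voxel size; default 0.5 cm isotropic.
#' @param body_semiaxes_cm ellipsoid semi-axes of the body.
#' @param ptv_radius_cm radius of the PTV sphere.
#' @param oar_center_cm,oar_size_cm center and edge lengths of the OAR box.
#' @return a [phantom()] with masks \code{body}, \code{ptv}, \code{oar}.
#' @export
make_phantom <- function(shape = c(41, 41, 21), spacing_cm = c(0.5, 0.5, 0.5),
                         body_semiaxes_cm = c(9.5, 9.5, 5),
                         ptv_radius_cm = 2.5,
                         oar_center_cm = c(4.5, 0, 0),
                         oar_size_cm = c(3, 3, 3)) {
  shape <- as.integer(shape)
  origin <- -(shape - 1) / 2 * spacing_cm
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) *
                 spacing_cm[a])
  xg <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  yg <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
              dim = shape)
  zg <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  body <- (xg / body_semiaxes_cm[1])^2 + (yg / body_semiaxes_cm[2])^2 +
    (zg / body_semiaxes_cm[3])^2 <= 1
  ptv <- xg^2 + yg^2 + zg^2 <= ptv_radius_cm^2
  oar <- abs(xg - oar_center_cm[1]) <= oar_size_cm[1] / 2 &
    abs(yg - oar_center_cm[2]) <= oar_size_cm[2] / 2 &
    abs(zg - oar_center_cm[3]) <= oar_size_cm[3] / 2
  phantom(shape, spacing_cm, origin,
          masks = list(body = body, ptv = ptv & body, oar = oar & body))
}

#' Generate a synthetic single-arc VMAT plan
#'
#' A deterministic plan with smoothly varying apertures: a window of
#' breathing half-width sliding across the field while the gantry sweeps a
#' full arc (crossing 0 degrees), with a circular row envelope so the open
#' field is roughly round. Cumulative weights are uniform.
#'
#' @param cp_count number of control points (default 178).
#' @param arc_start_deg,arc_span_deg gantry arc (degrees; the default spans
#'   358 degrees crossing the 0/360 wrap).
#' @param leaf_count_per_bank leaves per bank (default 60, 0.5 cm wide).
#' @param mu beam meterset.
#' @param field_half_v_cm half-extent of the open field across leaf rows.
#' @return an [rt_plan()] with one beam.
#' @export
make_vmat_plan <- function(cp_count = 178, arc_start_deg = 181,
                           arc_span_deg = 358, leaf_count_per_bank = 60,
                           mu = 400, field_half_v_cm = 3) {
  L <- leaf_count_per_bank
  boundaries <- seq(-L / 4, L / 4, by = 0.5)
  v_centers <- (boundaries[-1] + boundaries[-(L + 1)]) / 2
  w <- seq(0, 1, length.out = cp_count)
  centers <- -3 + 6 * w
  open_rows <- abs(v_centers) < field_half_v_cm
  rowscale <- sqrt(pmax(0, 1 - (v_centers / (field_half_v_cm + 0.5))^2))
  mlc <- matrix(0, cp_count, 2 * L)
  for (ci in seq_len(cp_count)) {
    h <- rowscale * (2.5 + 1.2 * sin(2 * pi * (2 * w[ci] + v_centers / 10)))
    pos_a <- ifelse(open_rows, h - centers[ci], -centers[ci])
    pos_b <- ifelse(open_rows, h + centers[ci], centers[ci])
    mlc[ci, ] <- c(pos_a, pos_b)
  }
  left <- -mlc[, 1:L, drop = FALSE]
  right <- mlc[, L + 1:L, drop = FALSE]
  jaws <- cbind(apply(left, 1, min) - 0.5, apply(right, 1, max) + 0.5,
                -field_half_v_cm - 0.5, field_half_v_cm + 0.5)
  rt_plan(rt_beam(
    cumulative_weight = w,
    gantry_deg = (arc_start_deg + arc_span_deg * w) %% 360,
    jaws_cm = jaws, mlc_cm = mlc, meterset_mu = mu,
    leaf_boundaries_cm = boundaries,
    provenance = "original", name = "arc1"),
    patient_id = "SYNTH", plan_label = "synthetic_vmat")
}

#' Simulate a dynalog delivery of a plan
#'
#' Emulates the MLC controller writing one record per tick: expected leaf
#' positions are the plan apertures linearly interpolated in cumulative
#' weight (dose fraction is linear in time), the gantry is interpolated
#' circularly, the segment field indexes the bracketing original
#' control-point interval, and actual positions deviate from expected
#' according to the error model. All recorded quantities are quantized to
#' the controller's resolution (0.01 mm positions, 0.1 degree gantry,
#' 1/25000 dose counts), so a write/parse round trip in the clinac dialect
#' is exact. The record grid contains \code{records_per_segment} ticks per
#' control-point interval, aligned with the segment boundaries.
#'
#' @param plan an [rt_plan()] (first beam is delivered) or an [rt_beam()].
#' @param error_model a [leaf_error_model()].
#' @param tick_ms controller tick: 50 (clinac) or 20 (truebeam).
#' @param records_per_segment ticks per control-point interval (default 9,
#'   which for a 178-point plan gives 1594 records, the usual regime of a
#'   clinical arc).
#' @param seed RNG seed for the error realization.
#' @return list with \code{dynalog_bank} components \code{a} and \code{b}.
#' @export
simulate_delivery <- function(plan, error_model = leaf_error_model("none"),
                              tick_ms = 50, records_per_segment = 9,
                              seed = 1) {
  beam <- if (inherits(plan, "rt_plan")) plan$beams[[1L]] else plan
  linac <- switch(as.character(tick_ms), "50" = "clinac", "20" = "truebeam",
                  stop("tick_ms must be 50 (clinac) or 20 (truebeam)"))
  C <- n_control_points(beam)
  n_seg <- C - 1L
  n_rec <- n_seg * records_per_segment + 1L
  tgrid <- seq_len(n_rec) - 1L
  time_ms <- tgrid * tick_ms
  w <- tgrid / (n_rec - 1L)
  # plan weights are a general non-decreasing grid; map time-uniform w
  # through the plan's cumulative weight for interpolation positions
  expected <- interp_matrix(beam$cumulative_weight, beam$mlc_cm, w)
  jaws <- interp_matrix(beam$cumulative_weight, beam$jaws_cm, w)
  gantry <- interp_gantry(beam$cumulative_weight, beam$gantry_deg, w)
  segment <- pmin(findInterval(w, beam$cumulative_weight,
                               rightmost.closed = TRUE) - 1L, n_seg - 1L)
  eps <- with_seed(seed, realize_errors_cm(error_model, n_rec,
                                           ncol(beam$mlc_cm),
                                           time_ms / 1000))
  q <- function(m, res) round(m / res) * res
  expected <- q(expected, 1e-3)
  actual <- q(expected - eps, 1e-3)
  jaws <- q(jaws, 1e-3)
  gantry <- q(gantry, 0.1) %% 360
  dose <- q(w, 1 / 25000)
  L <- beam$leaf_count_per_bank
  mk <- function(id, cols) dynalog_bank(
    bank_id = id, linac_type = linac,
    header = list(plan = beam$name),
    time_ms = time_ms, beam_on = rep(TRUE, n_rec),
    beam_hold = rep(FALSE, n_rec), segment = segment,
    gantry_deg = gantry, jaws_cm = jaws, dose_fraction = dose,
    expected_cm = expected[, cols, drop = FALSE],
    actual_cm = actual[, cols, drop = FALSE])
  list(a = mk("A", seq_len(L)), b = mk("B", L + seq_len(L)))
}
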