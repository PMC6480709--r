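# TPS-style deliverable plan model: beams as vectorized control-point tables.

#' Construct a beam
#'
#' A beam is an ordered sequence of control points, each a snapshot of the
#' machine state: cumulative meterset weight in [0, 1], gantry angle, the four
#' jaw positions and the positions of every MLC leaf (bank A columns first,
#' then bank B), in cm at the isocenter plane. Leaf coordinates increase in
#' the opening direction of the leaf; the physical bank-A edge is at
#' \code{-posA} and the bank-B edge at \code{+posB}, so the aperture width of
#' an opposed pair is \code{posA + posB}.
#'
#' @param cumulative_weight numeric vector, non-decreasing, from 0 to 1.
#' @param gantry_deg gantry angle per control point, degrees.
#' @param jaws_cm C x 4 matrix (x1, x2, y1, y2), physical cm.
#' @param mlc_cm C x 2L matrix of leaf positions, opening-direction cm.
#' @param meterset_mu total beam meterset in monitor units.
#' @param leaf_boundaries_cm length L+1 vector of leaf-side edges along the
#'   direction orthogonal to leaf travel (default: uniform 0.5 cm leaves
#'   centered on the axis).
#' @param provenance one of \code{"original"}, \code{"reconstructed_expected"},
#'   \code{"reconstructed_actual"}, \code{"densified"}, \code{"magnified"}.
#' @param name beam label.
#' @return an object of class \code{rt_beam}.
#' @export
rt_beam <- function(cumulative_weight, gantry_deg, jaws_cm, mlc_cm,
                    meterset_mu = 100, leaf_boundaries_cm = NULL,
                    provenance = "original", name = "beam") {
  mlc_cm <- as.matrix(mlc_cm)
  jaws_cm <- as.matrix(jaws_cm)
  L <- ncol(mlc_cm) / 2
  if (is.null(leaf_boundaries_cm))
    leaf_boundaries_cm <- seq(-L / 4, L / 4, by = 0.5)  # 0.5 cm leaves
  beam <- structure(list(
    cumulative_weight = as.numeric(cumulative_weight),
    gantry_deg = as.numeric(gantry_deg), jaws_cm = jaws_cm, mlc_cm = mlc_cm,
    meterset_mu = meterset_mu, leaf_count_per_bank = as.integer(L),
    leaf_boundaries_cm = leaf_boundaries_cm,
    provenance = provenance, name = name), class = "rt_beam")
  validate_rt_beam(beam)
  beam
}

validate_rt_beam <- function(beam) {
  C <- length(beam$cumulative_weight)
  if (C < 2L) stop("beam needs at least 2 control points")
  if (length(beam$gantry_deg) != C || nrow(beam$jaws_cm) != C ||
      nrow(beam$mlc_cm) != C)
    stop("control-point fields have inconsistent lengths")
  w <- beam$cumulative_weight
  if (abs(w[1L]) > 1e-6 || abs(w[C] - 1) > 1e-6)
    stop("cumulative weights must run from 0 to 1 (got ",
         format(w[1L]), " .. ", format(w[C]), ")")
  if (any(diff(w) < -1e-9))
    stop("cumulative weights must be non-decreasing")
  if (ncol(beam$mlc_cm) != 2L * beam$leaf_count_per_bank)
    stop("mlc_cm must have 2 x leaf_count_per_bank columns")
  if (length(beam$leaf_boundaries_cm) != beam$leaf_count_per_bank + 1L)
    stop("leaf_boundaries_cm must have leaf_count_per_bank + 1 entries")
  invisible(beam)
}

#' Construct a plan
#'
#' @param beams list of [rt_beam()] objects.
#' @param patient_id,plan_label identifiers.
#' @return an object of class \code{rt_plan}.
#' @export
rt_plan <- function(beams, patient_id = "SYNTH", plan_label = "plan") {
  if (inherits(beams, "rt_beam")) beams <- list(beams)
  if (length(beams) < 1L) stop("plan needs at least one beam")
  lapply(beams, validate_rt_beam)
  structure(list(beams = beams, patient_id = patient_id,
                 plan_label = plan_label), class = "rt_plan")
}

n_control_points <- function(beam) length(beam$cumulative_weight)

#' @export
print.rt_beam <- function(x, ...) {
  cat(sprintf("Beam '%s' (%s): %d control points, %d leaf pairs, %.1f MU\n",
              x$name, x$provenance, n_control_points(x),
              x$leaf_count_per_bank, x$meterset_mu))
  invisible(x)
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("Plan '%s' (patient %s): %d beam(s)\n", x$plan_label,
              x$patient_id, length(x$beams)))
  for (b in x$beams) print(b)
  invisible(x)
}

# -- circular gantry interpolation -------------------------------------------

# Unwrap a gantry-angle sequence to a continuous curve (shortest-arc steps),
# so linear interpolation crosses the 359->1 degree wrap correctly.
unwrap_deg <- function(deg) {
  d <- diff(deg)
  d <- (d + 180) %% 360 - 180
  cumsum(c(deg[1L], d))
}

wrap_deg <- function(deg) deg %% 360

# Interpolate angles circularly at query positions xq given knots x/deg.
interp_gantry <- function(x, deg, xq) {
  wrap_deg(approx(x, unwrap_deg(deg), xout = xq, rule = 2)$y)
}

# Piecewise-linear interpolation of each column of a matrix at query weights.
interp_matrix <- function(x, m, xq) {
  apply(m, 2, function(col) approx(x, col, xout = xq, rule = 2)$y)
}

# -- densification ------------------------------------------------------------

#' Densify a beam by control-point interpolation
#'
#' Inserts new control points at uniformly spaced cumulative-weight values,
#' computing leaf and jaw positions by linear interpolation in cumulative
#' weight and gantry angle by circular (shortest-arc) interpolation. All
#' original control points are preserved; the returned beam therefore has at
#' least \code{target_cp_count} control points (more when the uniform grid
#' does not contain all original weights).
#'
#' @param beam an [rt_beam()].
#' @param target_cp_count requested number of control points, at least the
#'   current count.
#' @return a new \code{rt_beam} with provenance \code{"densified"}.
#' @export
densify_plan <- function(beam, target_cp_count) {
  C <- n_control_points(beam)
  if (target_cp_count < C)
    stop("target control-point count (", target_cp_count,
         ") is smaller than the current count (", C, ")")
  if (target_cp_count == C) return(beam)
  w0 <- beam$cumulative_weight
  grid <- seq(0, 1, length.out = target_cp_count)
  w <- sort(c(w0, grid))
  w <- w[c(TRUE, diff(w) > 1e-12)]  # dedupe within tolerance
  rt_beam(
    cumulative_weight = w,
    gantry_deg = interp_gantry(w0, beam$gantry_deg, w),
    jaws_cm = interp_matrix(w0, beam$jaws_cm, w),
    mlc_cm = interp_matrix(w0, beam$mlc_cm, w),
    meterset_mu = beam$meterset_mu,
    leaf_boundaries_cm = beam$leaf_boundaries_cm,
    provenance = "densified", name = beam$name)
}

# -- JSON dump ----------------------------------------------------------------

#' Write / read a plan as JSON
#'
#' A complete, documented plain-text serialization of an [rt_plan()] used for
#' debugging and as an interchange format. Matrices are stored row-major as
#' nested arrays; all positions in cm, angles in degrees.
#'
#' @param plan an \code{rt_plan}.
#' @param path file path.
#' @return \code{write_plan_json}: invisibly, \code{path};
#'   \code{read_plan_json}: an \code{rt_plan}.
#' @export
write_plan_json <- function(plan, path) {
  ser <- list(
    format = "dynaverify-plan", version = 1L,
    patient_id = plan$patient_id, plan_label = plan$plan_label,
    beams = lapply(plan$beams, function(b) list(
      name = b$name, provenance = b$provenance, meterset_mu = b$meterset_mu,
      leaf_count_per_bank = b$leaf_count_per_bank,
      leaf_boundaries_cm = b$leaf_boundaries_cm,
      cumulative_weight = b$cumulative_weight, gantry_deg = b$gantry_deg,
      jaws_cm = b$jaws_cm, mlc_cm = b$mlc_cm)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(ser$format, "dynaverify-plan"))
    stop("not a dynaverify plan JSON file: ", path)
  rt_plan(lapply(ser$beams, function(b) {
    n <- length(b$cumulative_weight)
    rt_beam(cumulative_weight = b$cumulative_weight,
            gantry_deg = b$gantry_deg,
            jaws_cm = matrix(unlist(b$jaws_cm), nrow = n, ncol = 4),
            mlc_cm = matrix(unlist(b$mlc_cm), nrow = n),
            meterset_mu = b$meterset_mu,
            leaf_boundaries_cm = b$leaf_boundaries_cm,
            provenance = b$provenance, name = b$name)
  }), patient_id = ser$patient_id, plan_label = ser$plan_label)
}
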