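# Controlled magnification of recorded leaf-position errors.

#' Magnify the leaf-position errors of a dynalog field
#'
#' Rescales the recorded errors \eqn{\epsilon = P_e - P_a} so that the
#' largest absolute error becomes a chosen target \eqn{\Sigma}: each actual
#' position is replaced by
#' \deqn{P'_a = P_e - f\,\epsilon, \qquad f = \Sigma / MLE,}
#' where MLE is the maximum leaf error of the input field. In
#' \code{"signed"} mode the sign of each error is conserved; in
#' \code{"absolute"} mode \eqn{\epsilon} is replaced by \eqn{|\epsilon|}, so
#' every altered leaf defines a smaller aperture than its expected position
#' (errors are forced to one direction, emulating e.g. a failing carriage).
#' Errors at or below \code{floor_mm} (default 0.01 mm, the controller's
#' position resolution) are left untouched. Expected positions are never
#' modified, so the magnified field has a maximum leaf error of exactly
#' \eqn{\Sigma}.
#'
#' Magnified positions are clipped to the physical leaf travel range;
#' the number of clipped values is available as \code{attr(x, "clipped")}.
#' Opposed-leaf crossing is not repaired here: the dose engine treats a
#' crossed pair as a closed aperture.
#'
#' @param field a \code{dynalog_field} with \code{max_leaf_error(field)}
#'   above \code{floor_mm}.
#' @param sigma_mm target maximum error \eqn{\Sigma} in mm, > 0.
#' @param mode \code{"signed"} or \code{"absolute"}.
#' @param floor_mm magnification floor in mm; errors with
#'   \eqn{|\epsilon| \le} \code{floor_mm} are not magnified.
#' @param travel_limit_cm two-element leaf travel range in opening-direction
#'   cm.
#' @return a new \code{dynalog_field} with replaced actual positions.
#' @export
magnify_errors <- function(field, sigma_mm, mode = c("signed", "absolute"),
                           floor_mm = 0.01, travel_limit_cm = c(-20, 20)) {
  mode <- match.arg(mode)
  if (!is.finite(sigma_mm) || sigma_mm <= 0)
    stop("sigma_mm must be a positive number")
  if (floor_mm < 0) stop("floor_mm must be >= 0")
  eps <- leaf_errors(field)            # cm
  mle_mm <- max(abs(eps)) * 10
  if (mle_mm <= floor_mm)
    stop("cannot scale: maximum leaf error (", format(mle_mm),
         " mm) does not exceed the magnification floor (", floor_mm, " mm)")
  f <- sigma_mm / mle_mm
  scale_eps <- if (mode == "absolute") abs(eps) else eps
  magnify <- abs(eps) * 10 > floor_mm
  new_actual <- field$actual_cm
  new_actual[magnify] <- field$expected_cm[magnify] - f * scale_eps[magnify]
  clipped <- sum(new_actual < travel_limit_cm[1L] |
                 new_actual > travel_limit_cm[2L])
  new_actual <- pmin(pmax(new_actual, travel_limit_cm[1L]),
                     travel_limit_cm[2L])
  out <- field
  out$actual_cm <- new_actual
  out$magnified <- list(sigma_mm = sigma_mm, mode = mode, f = f,
                        source_mle_mm = mle_mm, floor_mm = floor_mm)
  attr(out, "clipped") <- clipped
  out
}

#' Default magnification sweep
#'
#' The set of target maximum errors (mm) used for the standard sensitivity
#' sweep.
#' @export
default_sigma_grid_mm <- function() c(2, 3, 4, 5, 10, 30)
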