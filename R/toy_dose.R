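# Deterministic toy dose engine.
#
# This engine is NOT a radiation transport code: it exists so that plan
# reconstruction and dose-comparison pipelines can be exercised end to end,
# with dose responding to aperture changes in the physically sensible
# direction. Each control-point interval contributes an aperture fluence
# (binary MLC/jaw opening at the isocenter plane blurred by a Gaussian
# penumbra), projected through the phantom as a diverging cone along the
# interval's mean gantry direction with exponential depth attenuation.
# It is linear in meterset, additive over beams, and pointwise monotone in
# the aperture: shrinking any leaf opening never increases dose anywhere.

#' Toy dose engine configuration
#'
#' @param sad_cm source-axis distance (cone divergence), cm.
#' @param mu_attenuation_per_cm exponential depth-attenuation coefficient
#'   (roughly the percent-depth-dose falloff of a 6 MV beam).
#' @param penumbra_sigma_cm Gaussian penumbra sigma at the isocenter plane.
#' @param fluence_spacing_cm resolution of the aperture fluence grid.
#' @param fluence_extent_cm half-size of the fluence grid.
#' @param inverse_square include the inverse-square divergence factor.
#' @param dose_per_mu output scaling, dose units per monitor unit.
#' @return a list of engine parameters.
#' @export
toy_dose_config <- function(sad_cm = 100, mu_attenuation_per_cm = 0.04,
                            penumbra_sigma_cm = 0.3,
                            fluence_spacing_cm = 0.25,
                            fluence_extent_cm = 12,
                            inverse_square = TRUE, dose_per_mu = 0.01) {
  list(sad_cm = sad_cm, mu_attenuation_per_cm = mu_attenuation_per_cm,
       penumbra_sigma_cm = penumbra_sigma_cm,
       fluence_spacing_cm = fluence_spacing_cm,
       fluence_extent_cm = fluence_extent_cm,
       inverse_square = inverse_square, dose_per_mu = dose_per_mu)
}

#' Construct a voxel phantom
#'
#' @param shape grid dimensions (nx, ny, nz).
#' @param spacing_cm voxel dimensions.
#' @param origin_cm first voxel center; default centers the grid on the
#'   isocenter.
#' @param masks named list of logical arrays congruent with the grid (by
#'   convention the first is the body).
#' @param isocenter_cm isocenter position, cm.
#' @return an object of class \code{phantom}.
#' @export
phantom <- function(shape, spacing_cm, origin_cm = NULL, masks = list(),
                    isocenter_cm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (is.null(origin_cm)) origin_cm <- -(shape - 1) / 2 * spacing_cm
  for (m in masks)
    if (!identical(dim(m), shape)) stop("phantom masks must match the grid")
  lo <- origin_cm; hi <- origin_cm + (shape - 1) * spacing_cm
  if (any(isocenter_cm < lo) || any(isocenter_cm > hi))
    stop("isocenter lies outside the phantom grid")
  structure(list(shape = shape, spacing_cm = as.numeric(spacing_cm),
                 origin_cm = as.numeric(origin_cm), masks = masks,
                 isocenter_cm = as.numeric(isocenter_cm)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %d x %d x %d @ (%.2f, %.2f, %.2f) cm; masks: %s\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing_cm[1],
              x$spacing_cm[2], x$spacing_cm[3],
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Structure masks of a phantom
#'
#' @param ph a [phantom()].
#' @return named list of [structure_mask()] objects.
#' @export
phantom_masks <- function(ph) {
  out <- lapply(names(ph$masks), function(nm)
    structure_mask(nm, ph$masks[[nm]]))
  names(out) <- names(ph$masks)
  out
}

# 1D Gaussian blur matrix on a uniform grid (zero padding at the edges),
# normalized by the untruncated kernel sum so blurring is monotone and
# never amplifies.
blur_matrix <- function(n, spacing, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- ceiling(4 * sigma / spacing)
  w <- exp(-((-k:k) * spacing)^2 / (2 * sigma^2))
  w <- w / sum(w)
  m <- matrix(0, n, n)
  for (d in -k:k) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- w[d + k + 1L]
  }
  m
}

# Vectorized bilinear sampling of matrix F (grid start u0, step sp in both
# dims); zero outside the grid.
bilinear_sample <- function(f, ui, vi, u0, sp) {
  ng <- nrow(f)
  fi <- (ui - u0) / sp
  fj <- (vi - u0) / sp
  i0 <- floor(fi); j0 <- floor(fj)
  ok <- i0 >= 0 & j0 >= 0 & i0 <= ng - 2 & j0 <= ng - 2
  out <- numeric(length(ui))
  if (!any(ok)) return(out)
  ti <- fi[ok] - i0[ok]; tj <- fj[ok] - j0[ok]
  id <- j0[ok] * ng + i0[ok] + 1L
  fv <- as.vector(f)
  out[ok] <- fv[id] * (1 - ti) * (1 - tj) + fv[id + 1L] * ti * (1 - tj) +
    fv[id + ng] * (1 - ti) * tj + fv[id + ng + 1L] * ti * tj
  out
}

# Aperture fluence of one machine state on the (u, v) isocenter-plane grid:
# binary opening from MLC + jaws, then separable Gaussian penumbra blur.
# A crossed leaf pair (negative gap) is a closed row.
aperture_fluence <- function(mlc, jaws, boundaries, ugrid, blur) {
  L <- length(mlc) / 2L
  pos_a <- mlc[seq_len(L)]; pos_b <- mlc[L + seq_len(L)]
  leaf_of_row <- findInterval(ugrid, boundaries,
                              rightmost.closed = TRUE)
  in_rows <- leaf_of_row >= 1L & leaf_of_row <= L
  lo <- hi <- rep(1, length(ugrid))  # empty interval by default (lo > hi)
  lo[in_rows] <- pmax(-pos_a[leaf_of_row[in_rows]], jaws[1L])
  hi[in_rows] <- pmin(pos_b[leaf_of_row[in_rows]], jaws[2L])
  lo[!in_rows] <- 1; hi[!in_rows] <- 0
  v_open <- ugrid >= jaws[3L] & ugrid <= jaws[4L]
  hi[!v_open] <- -Inf
  # strict bounds so a zero-gap (parked or crossed) pair is truly closed
  ind <- outer(ugrid, lo, `>`) & outer(ugrid, hi, `<`)
  blur %*% ind %*% blur
}

#' Compute a 3D dose distribution with the toy engine
#'
#' Accumulates, per control-point interval, the penumbra-blurred aperture
#' fluence projected through the phantom along the interval's mean gantry
#' direction (diverging from a point source at \code{sad_cm}), attenuated
#' exponentially with depth past the isocenter plane, weighted by the
#' interval's meterset fraction, and scaled by the beam meterset. With
#' \code{noise_relative > 0}, seeded Gaussian noise emulating Monte Carlo
#' statistical fluctuation is added and the grid carries the corresponding
#' per-voxel \code{sigma}.
#'
#' @param x an [rt_beam()] or [rt_plan()] (beams are additive).
#' @param ph a [phantom()].
#' @param config a [toy_dose_config()].
#' @param noise_relative standard deviation of added noise as a fraction of
#'   the maximum dose (0 = deterministic).
#' @param seed RNG seed, required when \code{noise_relative > 0}.
#' @return a [dose_grid()] in the phantom geometry.
#' @export
compute_dose <- function(x, ph, config = toy_dose_config(),
                         noise_relative = 0, seed = NULL) {
  values <- if (inherits(x, "rt_plan")) {
    Reduce(`+`, lapply(x$beams, beam_dose_values, ph = ph, config = config))
  } else {
    beam_dose_values(x, ph, config)
  }
  sigma <- NULL
  if (noise_relative > 0) {
    if (is.null(seed)) stop("noisy dose requires a seed")
    sig <- noise_relative * max(values)
    values <- values + with_seed(seed, array(
      rnorm(length(values), 0, sig), dim = dim(values)))
    values <- pmax(values, 0)
    sigma <- array(sig, dim = dim(values))
  }
  dose_grid(values, spacing_cm = ph$spacing_cm, origin_cm = ph$origin_cm,
            sigma = sigma)
}

beam_dose_values <- function(beam, ph, config) {
  validate_rt_beam(beam)
  cfg <- config
  ug <- seq(-cfg$fluence_extent_cm, cfg$fluence_extent_cm,
            by = cfg$fluence_spacing_cm)
  blur <- blur_matrix(length(ug), cfg$fluence_spacing_cm,
                      cfg$penumbra_sigma_cm)
  # voxel center coordinates relative to isocenter
  ax <- lapply(1:3, function(a)
    ph$origin_cm[a] + (seq_len(ph$shape[a]) - 1) * ph$spacing_cm[a] -
      ph$isocenter_cm[a])
  xg <- rep(ax[[1L]], times = ph$shape[2L] * ph$shape[3L])
  yg <- rep(rep(ax[[2L]], each = ph$shape[1L]), times = ph$shape[3L])
  zg <- rep(ax[[3L]], each = ph$shape[1L] * ph$shape[2L])
  acc <- numeric(length(xg))
  C <- n_control_points(beam)
  dw <- diff(beam$cumulative_weight)
  gantry_u <- unwrap_deg(beam$gantry_deg)
  for (i in seq_len(C - 1L)) {
    if (dw[i] <= 0) next
    theta <- (gantry_u[i] + gantry_u[i + 1L]) / 2 * pi / 180
    mlc <- (beam$mlc_cm[i, ] + beam$mlc_cm[i + 1L, ]) / 2
    jaws <- (beam$jaws_cm[i, ] + beam$jaws_cm[i + 1L, ]) / 2
    flu <- aperture_fluence(mlc, jaws, beam$leaf_boundaries_cm, ug, blur)
    st <- sin(theta); ct <- cos(theta)
    s <- st * xg - ct * zg                 # depth past isocenter plane
    u <- ct * xg + st * zg                 # lateral beam's-eye-view coords
    mag <- cfg$sad_cm / (cfg$sad_cm + s)
    fl <- bilinear_sample(flu, u * mag, yg * mag, ug[1L],
                          cfg$fluence_spacing_cm)
    w <- dw[i] * exp(-cfg$mu_attenuation_per_cm * s)
    if (cfg$inverse_square) w <- w * mag^2
    acc <- acc + fl * w
  }
  array(acc * beam$meterset_mu * cfg$dose_per_mu, dim = ph$shape)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}
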