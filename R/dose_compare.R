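# Dose containers and agreement statistics: DVH, PA, gamma, alpha/delta.

#' Construct a 3D dose grid
#'
#' @param values 3D numeric array of dose, finite and non-negative.
#' @param spacing_cm voxel dimensions (dx, dy, dz) in cm.
#' @param origin_cm position of the first voxel center in cm.
#' @param sigma optional per-voxel standard statistical uncertainty, same
#'   shape and unit as \code{values}.
#' @return an object of class \code{dose_grid}.
#' @export
dose_grid <- function(values, spacing_cm, origin_cm = c(0, 0, 0),
                      sigma = NULL) {
  if (length(dim(values)) != 3L) stop("dose values must be a 3D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0")
  if (!is.null(sigma)) {
    if (!identical(dim(sigma), dim(values)))
      stop("sigma must have the same shape as values")
    if (any(sigma < 0)) stop("sigma must be >= 0")
  }
  structure(list(values = values, spacing_cm = as.numeric(spacing_cm),
                 origin_cm = as.numeric(origin_cm), sigma = sigma),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dose grid %d x %d x %d, spacing (%.2f, %.2f, %.2f) cm, max %.4g%s\n",
              d[1], d[2], d[3], x$spacing_cm[1], x$spacing_cm[2],
              x$spacing_cm[3], max(x$values),
              if (is.null(x$sigma)) "" else ", with uncertainty"))
  invisible(x)
}

#' Construct a structure mask
#'
#' @param name structure name (e.g. "body", "ptv", "oar").
#' @param voxels logical 3D array congruent with the associated dose grid.
#' @return an object of class \code{structure_mask}.
#' @export
structure_mask <- function(name, voxels) {
  if (length(dim(voxels)) != 3L) stop("mask must be a 3D array")
  structure(list(name = name, voxels = voxels,
                 n_voxels = sum(voxels)), class = "structure_mask")
}

mask_volume_cm3 <- function(mask, spacing_cm)
  mask$n_voxels * prod(spacing_cm)

check_congruent <- function(dose, mask) {
  if (!identical(dim(dose$values), dim(mask$voxels)))
    stop("mask '", mask$name, "' is not congruent with the dose grid")
}

# -- DVH ----------------------------------------------------------------------

#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a structure on a fixed dose-bin grid:
#' \code{volumes[i]} is the percentage of the structure volume receiving a
#' dose of at least \code{(i-1) * bin_width}. The first bin is always 100,
#' volumes are non-increasing, and the grid extends one bin beyond the
#' maximum dose so the histogram ends at 0.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] congruent with \code{dose}.
#' @param bin_width dose bin width \eqn{\Delta d} (same unit as the grid).
#' @return an object of class \code{dvh} with fields \code{bin_width},
#'   \code{volumes} and \code{structure}.
#' @export
compute_dvh <- function(dose, mask, bin_width) {
  check_congruent(dose, mask)
  if (mask$n_voxels == 0L) stop("empty structure mask: ", mask$name)
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- dose$values[mask$voxels]
  n_bins <- floor(max(d) / bin_width) + 2L
  edges <- (seq_len(n_bins) - 1L) * bin_width
  counts <- vapply(edges, function(e) sum(d >= e), numeric(1))
  structure(list(bin_width = bin_width,
                 volumes = 100 * counts / length(d),
                 structure = mask$name), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("DVH of '%s': %d bins of width %.4g\n", x$structure,
              length(x$volumes), x$bin_width))
  invisible(x)
}

#' Percentage of agreement between two DVHs
#'
#' An area-based similarity index for cumulative DVHs:
#' \deqn{PA = 100\,[1 - \delta_A / \max(A_1, A_2)],}
#' where \eqn{A_k = \Delta d \sum_i V_{k,i}} is the area under histogram
#' \eqn{k} and \eqn{\delta_A = \Delta d \sum_i |V_{1,i} - V_{2,i}|} the area
#' between the two histograms. Identical histograms give 100; a histogram
#' compared against an all-zero one gives 0. The shorter histogram is
#' zero-padded to the longer before the sums.
#'
#' @param dvh1,dvh2 [compute_dvh()] objects with equal bin width.
#' @return PA in percent, in [0, 100].
#' @export
percentage_of_agreement <- function(dvh1, dvh2) {
  if (abs(dvh1$bin_width - dvh2$bin_width) > 1e-12 * dvh1$bin_width)
    stop("DVHs have different bin widths")
  dd <- dvh1$bin_width
  n <- max(length(dvh1$volumes), length(dvh2$volumes))
  v1 <- c(dvh1$volumes, numeric(n - length(dvh1$volumes)))
  v2 <- c(dvh2$volumes, numeric(n - length(dvh2$volumes)))
  a1 <- dd * sum(v1)
  a2 <- dd * sum(v2)
  if (a1 == 0 && a2 == 0)
    stop("undefined PA: both DVH areas are zero")
  delta_a <- dd * sum(abs(v1 - v2))
  min(100, max(0, 100 * (1 - delta_a / max(a1, a2))))
}

# -- gamma --------------------------------------------------------------------

#' Gamma-analysis criteria
#'
#' @param dose_percent dose-difference criterion, percent of the global
#'   normalization dose (the reference maximum).
#' @param dta_mm distance-to-agreement criterion in mm.
#' @param low_dose_cutoff_percent reference voxels below this percentage of
#'   the normalization dose are excluded from the analysis.
#' @param search_step_fraction spatial search step as a fraction of
#'   \code{dta_mm} (the evaluated grid is tri-linearly interpolated on this
#'   sub-grid).
#' @param search_radius_factor search radius as a multiple of \code{dta_mm}.
#' @return an object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dose_percent, dta_mm, low_dose_cutoff_percent = 10,
                           search_step_fraction = 0.1,
                           search_radius_factor = 3) {
  stopifnot(dose_percent > 0, dta_mm > 0, low_dose_cutoff_percent > 0,
            search_step_fraction > 0, search_radius_factor > 0)
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 low_dose_cutoff_percent = low_dose_cutoff_percent,
                 search_step_fraction = search_step_fraction,
                 search_radius_factor = search_radius_factor),
            class = "gamma_criteria")
}

# Offsets of the gamma search lattice, sorted by radial distance (cm).
gamma_offsets <- function(criteria) {
  dta_cm <- criteria$dta_mm / 10
  step <- dta_cm * criteria$search_step_fraction
  radius <- dta_cm * criteria$search_radius_factor
  k <- floor(radius / step)
  g <- seq(-k, k) * step
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  r2 <- rowSums(off^2)
  keep <- r2 <= radius^2 + 1e-12
  off <- off[keep, , drop = FALSE]
  r2 <- r2[keep]
  ord <- order(r2)
  list(offsets = off[ord, , drop = FALSE], dist2 = r2[ord])
}

#' Gamma pass rate between two dose grids
#'
#' For every masked reference voxel above the low-dose cutoff, the gamma
#' index is the minimum over evaluated positions within the search radius of
#' \deqn{\gamma = \sqrt{\left(\frac{\Delta D}{\%D \cdot D_{max}/100}\right)^2
#'   + \left(\frac{r}{DTA}\right)^2},}
#' with global normalization to the reference maximum \eqn{D_{max}} (or an
#' explicit \code{norm_dose}). The evaluated distribution is tri-linearly
#' interpolated on a sub-grid of step \code{search_step_fraction * dta}
#' within \code{search_radius_factor * dta}. The pass rate is the percentage
#' of analyzed voxels with \eqn{\gamma \le 1}.
#'
#' @param reference,evaluated congruent [dose_grid()]s.
#' @param criteria a [gamma_criteria()].
#' @param mask optional [structure_mask()]; default: all voxels.
#' @param norm_dose global normalization dose; default the maximum of the
#'   reference grid (over the mask if given).
#' @param return_gamma if \code{TRUE}, also return the per-voxel gamma values.
#' @return the pass rate in percent, or (with \code{return_gamma}) a list
#'   with \code{pass_rate}, \code{gamma} and \code{n}.
#' @export
gamma_pass_rate <- function(reference, evaluated, criteria, mask = NULL,
                            norm_dose = NULL, return_gamma = FALSE) {
  if (!identical(dim(reference$values), dim(evaluated$values)))
    stop("reference and evaluated grids are not congruent")
  dims <- dim(reference$values)
  sel <- if (is.null(mask)) array(TRUE, dims) else {
    check_congruent(reference, mask)
    mask$voxels
  }
  dmax <- if (is.null(norm_dose)) max(reference$values[sel]) else norm_dose
  if (dmax <= 0) stop("normalization dose must be positive")
  eligible <- sel & reference$values >= criteria$low_dose_cutoff_percent /
    100 * dmax
  idx <- which(eligible) - 1L            # 0-based linear indices for C++
  if (length(idx) == 0L)
    stop("no eligible voxels for gamma analysis")
  off <- gamma_offsets(criteria)
  g2 <- gamma_min_cpp(
    ref = reference$values, ev = evaluated$values,
    idx = idx, dims = as.integer(dims),
    spacing = reference$spacing_cm,
    offsets = off$offsets, dist2 = off$dist2,
    dose_tol = criteria$dose_percent / 100 * dmax,
    dta_cm = criteria$dta_mm / 10)
  gam <- sqrt(g2)
  rate <- 100 * mean(gam <= 1)
  if (return_gamma) list(pass_rate = rate, gamma = gam, n = length(gam))
  else rate
}

# -- systematic differences ---------------------------------------------------

#' Systematic dose differences separated from statistical noise
#'
#' For two dose distributions that carry per-voxel statistical uncertainty,
#' the per-voxel systematic difference magnitude is estimated by quadrature
#' subtraction of the noise variances from the observed squared difference:
#' \deqn{s_i = \sqrt{\max(0,\; d_i^2 - \sigma_{ref,i}^2 -
#'   \sigma_{eval,i}^2)},}
#' with \eqn{d_i} the voxel dose difference. The result is reported as
#' \eqn{\alpha/\Delta} pairs: \eqn{\alpha} is the percentage of analyzed
#' voxels whose systematic deviation is at least \eqn{\Delta} percent of the
#' reference maximum dose. The analysis domain is the masked region with
#' reference dose above \code{dose_threshold_percent} of the maximum.
#'
#' @param reference,evaluated congruent [dose_grid()]s, both with
#'   \code{sigma}.
#' @param mask a [structure_mask()] (typically the body contour).
#' @param dose_threshold_percent analysis domain threshold, percent of the
#'   reference maximum (default 30).
#' @param delta_grid_percent the \eqn{\Delta} values, percent of the
#'   reference maximum.
#' @param norm_dose reference maximum override; default max of the reference
#'   grid over the mask.
#' @return an object of class \code{systematic_diff}: a data frame with
#'   columns \code{delta_percent} and \code{alpha_percent}.
#' @export
systematic_differences <- function(reference, evaluated, mask,
                                   dose_threshold_percent = 30,
                                   delta_grid_percent =
                                     c(0.5, 1, 1.2, 1.5, 2, 3, 4, 5),
                                   norm_dose = NULL) {
  if (is.null(reference$sigma) || is.null(evaluated$sigma))
    stop("systematic_differences requires per-voxel uncertainty (sigma) ",
         "on both dose grids")
  check_congruent(reference, mask)
  check_congruent(evaluated, mask)
  if (mask$n_voxels == 0L) stop("empty structure mask")
  dmax <- if (is.null(norm_dose)) max(reference$values[mask$voxels])
          else norm_dose
  domain <- mask$voxels & reference$values >
    dose_threshold_percent / 100 * dmax
  if (!any(domain)) stop("no voxels above the dose threshold")
  d <- reference$values[domain] - evaluated$values[domain]
  var_noise <- reference$sigma[domain]^2 + evaluated$sigma[domain]^2
  s <- sqrt(pmax(0, d^2 - var_noise))
  alpha <- vapply(delta_grid_percent,
                  function(dl) 100 * mean(s >= dl / 100 * dmax), numeric(1))
  structure(data.frame(delta_percent = delta_grid_percent,
                       alpha_percent = alpha),
            class = c("systematic_diff", "data.frame"))
}

# -- aggregate comparison -----------------------------------------------------

#' Full agreement report between two dose grids
#'
#' Computes, per structure, the DVH percentage of agreement and the gamma
#' pass rate for every requested criteria pair, and optionally the
#' systematic-difference \eqn{\alpha/\Delta} table on the first mask (the
#' body, by convention) and the leaf RMS/MLE statistics of an associated
#' dynalog field. The normalization dose for gamma and \eqn{\Delta} is the
#' reference maximum over the first mask.
#'
#' @param reference,evaluated congruent [dose_grid()]s.
#' @param masks named list of [structure_mask()]s; the first is used for
#'   dose normalization.
#' @param criteria list of [gamma_criteria()] (or two-element numeric vectors
#'   \code{c(dose_percent, dta_mm)}).
#' @param field optional \code{dynalog_field} whose RMS and MLE are reported.
#' @param bin_width DVH bin width; default reference-maximum / 1000.
#' @param alpha_delta compute the \eqn{\alpha/\Delta} table (requires sigma
#'   on both grids).
#' @return an object of class \code{comparison_report}.
#' @export
compare_doses <- function(reference, evaluated, masks,
                          criteria = list(c(2, 1), c(2, 2), c(3, 3)),
                          field = NULL, bin_width = NULL,
                          alpha_delta = FALSE) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    names(masks) <- vapply(masks, `[[`, "", "name")
  criteria <- lapply(criteria, function(cr)
    if (inherits(cr, "gamma_criteria")) cr else gamma_criteria(cr[1], cr[2]))
  norm <- max(reference$values[masks[[1L]]$voxels])
  if (is.null(bin_width)) bin_width <- norm / 1000
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    pa <- percentage_of_agreement(
      compute_dvh(reference, m, bin_width),
      compute_dvh(evaluated, m, bin_width))
    gprs <- vapply(criteria, function(cr)
      gamma_pass_rate(reference, evaluated, cr, mask = m,
                      norm_dose = norm), numeric(1))
    names(gprs) <- vapply(criteria, function(cr)
      sprintf("gpr_%g_%g", cr$dose_percent, cr$dta_mm), "")
    c(list(structure = nm,
           volume_cm3 = mask_volume_cm3(m, reference$spacing_cm),
           pa = pa), as.list(gprs))
  })
  report <- list(
    version = 1L,
    bin_width = bin_width, norm_dose = norm,
    structures = rows,
    rms_mm = if (!is.null(field)) rms_error(field) else NULL,
    mle_mm = if (!is.null(field)) max_leaf_error(field) else NULL,
    alpha_delta = if (alpha_delta)
      as.data.frame(systematic_differences(reference, evaluated,
                                           masks[[1L]], norm_dose = norm))
      else NULL)
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Dose comparison report\n")
  if (!is.null(x$rms_mm))
    cat(sprintf("  leaf errors: RMS %.3f mm, MLE %.3f mm\n",
                x$rms_mm, x$mle_mm))
  df <- do.call(rbind, lapply(x$structures, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  print(df, row.names = FALSE, digits = 5)
  if (!is.null(x$alpha_delta)) {
    cat("  systematic differences (alpha % of voxels >= delta % of max):\n")
    print(x$alpha_delta, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize / restore a comparison report
#'
#' @param report a \code{comparison_report}.
#' @param path JSON file path.
#' @return \code{write_report}: invisibly, \code{path};
#'   \code{read_report}: a \code{comparison_report}.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!is.null(rep$alpha_delta))
    rep$alpha_delta <- as.data.frame(rep$alpha_delta)
  class(rep) <- "comparison_report"
  rep
}
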