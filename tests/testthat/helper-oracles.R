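# Independent oracles: plain-loop or exhaustive reference implementations
# used to check the package's optimized paths.

# Trilinear interpolation at many points (rows of `pts`, cm); NA outside.
trilinear_many <- function(arr, spacing, pts) {
  dims <- dim(arr)
  f <- sweep(pts, 2, spacing, `/`)
  inside <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= dims[1] - 1 & f[, 2] <= dims[2] - 1 & f[, 3] <= dims[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(inside)) return(out)
  f <- f[inside, , drop = FALSE]
  i0 <- pmin(floor(f), matrix(dims - 2, nrow(f), 3, byrow = TRUE))
  t <- f - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
      (if (dy) t[, 2] else 1 - t[, 2]) *
      (if (dz) t[, 3] else 1 - t[, 3])
    lin <- (i0[, 1] + dx + 1) + (i0[, 2] + dy) * dims[1] +
      (i0[, 3] + dz) * dims[1] * dims[2]
    v <- v + w * arr[lin]
  }
  out[inside] <- v
  out
}

# Exhaustive gamma: for every analyzed voxel, evaluate the full search
# lattice with no pruning, and take the minimum.
gamma_brute <- function(reference, evaluated, criteria, mask = NULL,
                        norm_dose = NULL) {
  dims <- dim(reference$values)
  sel <- if (is.null(mask)) array(TRUE, dims) else mask$voxels
  dmax <- if (is.null(norm_dose)) max(reference$values[sel]) else norm_dose
  dose_tol <- criteria$dose_percent / 100 * dmax
  dta_cm <- criteria$dta_mm / 10
  step <- dta_cm * criteria$search_step_fraction
  radius <- dta_cm * criteria$search_radius_factor
  k <- floor(radius / step)
  g <- seq(-k, k) * step
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  off <- off[rowSums(off^2) <= radius^2 + 1e-12, , drop = FALSE]
  dist2 <- rowSums(off^2)
  eligible <- which(sel & reference$values >=
                      criteria$low_dose_cutoff_percent / 100 * dmax,
                    arr.ind = TRUE)
  spacing <- reference$spacing_cm
  gam <- apply(eligible, 1, function(ijk) {
    p0 <- (ijk - 1) * spacing
    dref <- reference$values[ijk[1], ijk[2], ijk[3]]
    de <- trilinear_many(evaluated$values, spacing,
                         sweep(off, 2, p0, `+`))
    g2 <- ((dref - de) / dose_tol)^2 + dist2 / dta_cm^2
    sqrt(min(g2, na.rm = TRUE))
  })
  list(pass_rate = 100 * mean(gam <= 1), gamma = gam)
}

# Plain-loop RMS over all leaf-position pairs, in mm.
rms_brute <- function(field) {
  total <- 0; n <- 0
  for (i in seq_len(nrow(field$expected_cm)))
    for (l in seq_len(ncol(field$expected_cm))) {
      d_mm <- (field$expected_cm[i, l] - field$actual_cm[i, l]) * 10
      total <- total + d_mm^2
      n <- n + 1
    }
  sqrt(total / n)
}

# Brute-force PSR-ED selection: segment-change records plus records with any
# leaf error above tolerance, first/last always included, holds excluded.
psr_ed_brute <- function(field, tol_mm) {
  elig <- which(!field$beam_hold)
  sel <- logical(length(field$time_ms))
  sel[elig[1]] <- TRUE
  sel[elig[length(elig)]] <- TRUE
  prev_seg <- field$segment[elig[1]]
  for (i in elig[-1]) {
    if (field$segment[i] != prev_seg) sel[i] <- TRUE
    prev_seg <- field$segment[i]
  }
  if (tol_mm == 0) sel[elig] <- TRUE
  else for (i in elig)
    if (max(abs(field$expected_cm[i, ] - field$actual_cm[i, ])) * 10 > tol_mm)
      sel[i] <- TRUE
  which(sel)
}
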