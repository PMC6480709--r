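# Minimal DICOM codec (explicit VR, little endian) for RT Plan / RT Dose.
# Covers exactly the attributes this package produces and consumes; sequences
# are written with defined lengths, and both defined and undefined lengths
# are accepted on read.

UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPL_CLASS <- "2.25.848509745793200430284929867214953784"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid_new <- function() {
  # Fresh UID in the 2.25 (UUID-derived) root; not cryptographic, just unique.
  paste0("2.25.", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

r_u16 <- function(x) {
  x <- as.integer(x)
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}
r_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_tag <- function(group, element) c(r_u16(group), r_u16(element))

pad_even <- function(payload, pad = as.raw(0L)) {
  if (length(payload) %% 2L) c(payload, pad) else payload
}

dcm_elem <- function(group, element, vr, payload) {
  payload <- pad_even(payload,
                      if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" "))
  hdr <- if (vr %in% LONG_VRS)
    c(charToRaw(vr), raw(2L), r_u32(length(payload)))
  else
    c(charToRaw(vr), r_u16(length(payload)))
  c(dcm_tag(group, element), hdr, payload)
}

dcm_str <- function(group, element, vr, value)
  dcm_elem(group, element, vr, charToRaw(paste(value, collapse = "\\")))

dcm_ds <- function(group, element, value)
  dcm_str(group, element, "DS", sprintf("%.10g", value))

dcm_is <- function(group, element, value)
  dcm_str(group, element, "IS", sprintf("%d", as.integer(value)))

dcm_us <- function(group, element, value)
  dcm_elem(group, element, "US", r_u16(value))

dcm_item <- function(content) c(dcm_tag(0xFFFE, 0xE000), r_u32(length(content)),
                                content)

dcm_sq <- function(group, element, items)
  dcm_elem(group, element, "SQ", do.call(c, items))

dcm_file <- function(sop_class, sop_instance, dataset) {
  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", sop_class),
    dcm_str(0x0002, 0x0003, "UI", sop_instance),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", UID_IMPL_CLASS))
  c(raw(128L), charToRaw("DICM"),
    dcm_elem(0x0002, 0x0000, "UL", r_u32(length(meta_body))),
    meta_body, dataset)
}

# -- reader -------------------------------------------------------------------

p_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
p_u32 <- function(r, i) p_u16(r, i) + 65536 * p_u16(r, i + 2L)

# Parse a dataset from raw bytes r starting at i (1-based), stopping at `end`
# or at an item/sequence delimiter. Returns list(elements = named list,
# pos = next position). Element names are "GGGG,EEEE" uppercase hex.
dcm_parse_ds <- function(r, i, end) {
  out <- list()
  while (i + 7L <= end && i + 7L <= length(r)) {
    group <- p_u16(r, i); element <- p_u16(r, i + 2L)
    if (group == 0xFFFE) {            # item/sequence delimiter
      if (element %in% c(0xE00D, 0xE0DD)) return(list(elements = out,
                                                      pos = i + 8L))
      stop("unexpected item tag in dataset")
    }
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% LONG_VRS) {
      len <- p_u32(r, i + 8L); data0 <- i + 12L
    } else {
      len <- p_u16(r, i + 6L); data0 <- i + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      if (len == 4294967295) {
        items <- list(); j <- data0
        repeat {
          if (p_u16(r, j) != 0xFFFE) stop("malformed sequence")
          el <- p_u16(r, j + 2L)
          if (el == 0xE0DD) { j <- j + 8L; break }
          ilen <- p_u32(r, j + 4L)
          iend <- if (ilen == 4294967295) length(r) else j + 8L + ilen - 1L
          it <- dcm_parse_ds(r, j + 8L, iend)
          items[[length(items) + 1L]] <- it$elements
          j <- it$pos
        }
        out[[key]] <- items; i <- j
      } else {
        items <- list(); j <- data0; sq_end <- data0 + len - 1L
        while (j <= sq_end) {
          ilen <- p_u32(r, j + 4L)
          iend <- if (ilen == 4294967295) sq_end else j + 8L + ilen - 1L
          it <- dcm_parse_ds(r, j + 8L, iend)
          items[[length(items) + 1L]] <- it$elements
          j <- it$pos
        }
        out[[key]] <- items; i <- sq_end + 1L
      }
      next
    }
    payload <- if (len > 0) r[data0:(data0 + len - 1L)] else raw(0L)
    out[[key]] <- dcm_decode(vr, payload)
    i <- data0 + len
  }
  list(elements = out, pos = i)
}

dcm_decode <- function(vr, payload) {
  txt <- function() sub(" +$", "", rawToChar(payload[payload != as.raw(0L)]))
  switch(vr,
    DS = as.numeric(strsplit(txt(), "\\", fixed = TRUE)[[1L]]),
    IS = as.integer(strsplit(txt(), "\\", fixed = TRUE)[[1L]]),
    US = readBin(payload, integer(), n = length(payload) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(payload, integer(), n = length(payload) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(payload, double(), n = length(payload) / 8L, size = 8L,
                 endian = "little"),
    OW = payload,
    OB = payload,
    txt())
}

dcm_read_file <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  meta <- dcm_parse_ds(r, 133L, 133L + 11L)   # just the group length element
  glen <- meta$elements[["0002,0000"]]
  body0 <- meta$pos + glen
  meta_full <- dcm_parse_ds(r, meta$pos, body0 - 1L)
  ts <- meta_full$elements[["0002,0010"]]
  if (!is.null(ts) && ts != UID_EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax: ", ts)
  dcm_parse_ds(r, body0, length(r))$elements
}

sq_items <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) list() else v
}

# -- RT Plan ------------------------------------------------------------------

#' Write a plan as a DICOM RT Plan file
#'
#' Emits an explicit-VR little-endian RT Plan with one dynamic photon beam per
#' [rt_beam()]: beam limiting device definitions (ASYMX/ASYMY jaws and an
#' MLCX with the beam's leaf boundaries), a full control-point sequence
#' (gantry angle, jaw and MLC positions, cumulative meterset weight), and a
#' fraction group carrying the beam meterset. Leaf positions are converted
#' from the package's opening-direction cm convention to the DICOM bank-A /
#' bank-B millimetre convention. SOP instance UIDs are freshly generated on
#' every write; all other content is deterministic.
#'
#' @param plan an [rt_plan()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso [read_rtplan()]
#' @export
write_rtplan <- function(plan, path) {
  if (length(plan$beams) == 0L) stop("plan has no beams")
  sop <- dcm_uid_new()
  beam_items <- lapply(seq_along(plan$beams), function(bi) {
    b <- plan$beams[[bi]]
    L <- b$leaf_count_per_bank
    cps <- lapply(seq_len(n_control_points(b)), function(ci) {
      mlc_mm <- c(-b$mlc_cm[ci, seq_len(L)],
                  b$mlc_cm[ci, L + seq_len(L)]) * 10
      dcm_item(c(
        dcm_is(0x300A, 0x0112, ci - 1L),
        dcm_ds(0x300A, 0x011E, b$gantry_deg[ci]),
        dcm_sq(0x300A, 0x011A, list(
          dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
                     dcm_ds(0x300A, 0x011C, b$jaws_cm[ci, 1:2] * 10))),
          dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
                     dcm_ds(0x300A, 0x011C, b$jaws_cm[ci, 3:4] * 10))),
          dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
                     dcm_ds(0x300A, 0x011C, mlc_mm))))),
        dcm_ds(0x300A, 0x0134, b$cumulative_weight[ci])))
    })
    dcm_item(c(
      dcm_is(0x300A, 0x00C0, bi),
      dcm_str(0x300A, 0x00C2, "LO", b$name),
      dcm_str(0x300A, 0x00C4, "CS", "DYNAMIC"),
      dcm_str(0x300A, 0x00C6, "CS", "PHOTON"),
      dcm_sq(0x300A, 0x00B6, list(
        dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "ASYMX"),
                   dcm_is(0x300A, 0x00BC, 1L))),
        dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "ASYMY"),
                   dcm_is(0x300A, 0x00BC, 1L))),
        dcm_item(c(dcm_str(0x300A, 0x00B8, "CS", "MLCX"),
                   dcm_is(0x300A, 0x00BC, L),
                   dcm_ds(0x300A, 0x00BE, b$leaf_boundaries_cm * 10))))),
      dcm_ds(0x300A, 0x010E, 1),
      dcm_is(0x300A, 0x0110, n_control_points(b)),
      dcm_sq(0x300A, 0x0111, cps)))
  })
  ref_items <- lapply(seq_along(plan$beams), function(bi) dcm_item(c(
    dcm_ds(0x300A, 0x0086, plan$beams[[bi]]$meterset_mu),
    dcm_is(0x300C, 0x0006, bi))))
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTPLAN),
    dcm_str(0x0008, 0x0018, "UI", sop),
    dcm_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_str(0x0010, 0x0010, "PN", plan$patient_id),
    dcm_str(0x0010, 0x0020, "LO", plan$patient_id),
    dcm_str(0x300A, 0x0002, "SH", plan$plan_label),
    dcm_sq(0x300A, 0x0070, list(dcm_item(c(
      dcm_is(0x300A, 0x0071, 1L),
      dcm_is(0x300A, 0x0078, 1L),
      dcm_is(0x300A, 0x0080, length(plan$beams)),
      dcm_sq(0x300C, 0x0004, ref_items))))),
    dcm_sq(0x300A, 0x00B0, beam_items))
  writeBin(dcm_file(UID_RTPLAN, sop, dataset), path)
  invisible(path)
}

#' Read a DICOM RT Plan file
#'
#' Reads a dynamic-MLC RT Plan into an [rt_plan()]. Cumulative meterset
#' weights are normalized to [0, 1] by the final cumulative weight. DICOM
#' attributes that the standard allows to be omitted after the first control
#' point (gantry angle, jaw and MLC positions) are carried forward from the
#' previous control point. A plan whose beams carry no MLC position sequence
#' is rejected as unsupported.
#'
#' @param path path to an RT Plan file.
#' @return an [rt_plan()].
#' @export
read_rtplan <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(ds[["0008,0016"]], UID_RTPLAN))
    stop("not an RT Plan DICOM file: ", path)
  beams_sq <- sq_items(ds, "300A,00B0")
  if (length(beams_sq) == 0L) stop("RT Plan contains no beams")
  metersets <- rep(100, length(beams_sq))
  for (fg in sq_items(ds, "300A,0070"))
    for (rb in sq_items(fg, "300C,0004")) {
      bn <- rb[["300C,0006"]]
      if (!is.null(bn) && !is.null(rb[["300A,0086"]]))
        metersets[bn] <- rb[["300A,0086"]]
    }
  beams <- lapply(seq_along(beams_sq), function(bi) {
    bd <- beams_sq[[bi]]
    boundaries <- NULL; L <- NULL
    for (bld in sq_items(bd, "300A,00B6"))
      if (identical(bld[["300A,00B8"]], "MLCX")) {
        boundaries <- bld[["300A,00BE"]] / 10
        L <- bld[["300A,00BC"]]
      }
    cps <- sq_items(bd, "300A,0111")
    if (length(cps) < 2L) stop("beam ", bi, " has fewer than 2 control points")
    gantry <- jx <- jy <- mlc <- NULL
    weights <- numeric(length(cps))
    gantry_v <- numeric(length(cps))
    jaws_m <- matrix(NA_real_, length(cps), 4L)
    mlc_m <- NULL
    for (ci in seq_along(cps)) {
      cp <- cps[[ci]]
      weights[ci] <- cp[["300A,0134"]]
      if (!is.null(cp[["300A,011E"]])) gantry <- cp[["300A,011E"]]
      for (bldp in sq_items(cp, "300A,011A")) {
        pos <- bldp[["300A,011C"]]
        switch(bldp[["300A,00B8"]],
               ASYMX = { jx <- pos / 10 }, X = { jx <- pos / 10 },
               ASYMY = { jy <- pos / 10 }, Y = { jy <- pos / 10 },
               MLCX = { mlc <- pos / 10 })
      }
      if (is.null(gantry)) stop("control point ", ci, " lacks a gantry angle")
      gantry_v[ci] <- gantry
      jaws_m[ci, ] <- c(if (is.null(jx)) c(-20, 20) else jx,
                        if (is.null(jy)) c(-20, 20) else jy)
      if (is.null(mlc))
        stop("unsupported plan: beam ", bi,
             " has no MLC position sequence (static beam?)")
      if (is.null(mlc_m)) mlc_m <- matrix(NA_real_, length(cps), length(mlc))
      n2 <- length(mlc) / 2L
      mlc_m[ci, ] <- c(-mlc[seq_len(n2)], mlc[n2 + seq_len(n2)])
    }
    final_w <- bd[["300A,010E"]]
    if (is.null(final_w) || final_w <= 0) final_w <- weights[length(weights)]
    rt_beam(cumulative_weight = weights / final_w, gantry_deg = gantry_v,
            jaws_cm = jaws_m, mlc_cm = mlc_m, meterset_mu = metersets[bi],
            leaf_boundaries_cm = boundaries,
            provenance = "original",
            name = if (is.null(bd[["300A,00C2"]])) paste0("beam", bi)
                   else bd[["300A,00C2"]])
  })
  rt_plan(beams, patient_id = if (is.null(ds[["0010,0020"]])) "UNKNOWN"
                              else ds[["0010,0020"]],
          plan_label = if (is.null(ds[["300A,0002"]])) "plan"
                       else ds[["300A,0002"]])
}

# -- RT Dose ------------------------------------------------------------------

#' Write / read a dose grid as DICOM RT Dose
#'
#' The dose array is stored as 32-bit scaled integers (DoseGridScaling chosen
#' so the grid maximum maps near the top of the integer range), frames along
#' the third array dimension, rows along the second, columns along the first.
#' Per-voxel statistical uncertainty, when present on the grid, is not part
#' of the RT Dose object; use [write_dose_pair()] to preserve it.
#'
#' @param dose a [dose_grid()].
#' @param path file path.
#' @return \code{write_rtdose}: invisibly, \code{path};
#'   \code{read_rtdose}: a [dose_grid()].
#' @export
write_rtdose <- function(dose, path) {
  dims <- dim(dose$values)
  sop <- dcm_uid_new()
  mx <- max(dose$values)
  scaling <- if (mx > 0) mx / (2^31 - 1) else 1
  px <- as.integer(round(as.vector(dose$values) / scaling))
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_str(0x0008, 0x0018, "UI", sop),
    dcm_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_str(0x0020, 0x0032, "DS",
            sprintf("%.10g", dose$origin_cm * 10)),
    dcm_str(0x0020, 0x0037, "DS",
            sprintf("%.10g", c(1, 0, 0, 0, 1, 0))),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_is(0x0028, 0x0008, dims[3L]),
    dcm_us(0x0028, 0x0010, dims[2L]),
    dcm_us(0x0028, 0x0011, dims[1L]),
    dcm_ds(0x0028, 0x0030, dose$spacing_cm[c(2L, 1L)] * 10),
    dcm_us(0x0028, 0x0100, 32L),
    dcm_us(0x0028, 0x0101, 32L),
    dcm_us(0x0028, 0x0102, 31L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_str(0x3004, 0x0002, "CS", "GY"),
    dcm_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_str(0x3004, 0x000A, "CS", "PLAN"),
    dcm_ds(0x3004, 0x000C, (seq_len(dims[3L]) - 1L) * dose$spacing_cm[3L] * 10),
    dcm_ds(0x3004, 0x000E, scaling),
    dcm_elem(0x7FE0, 0x0010, "OW", writeBin(px, raw(), size = 4L,
                                            endian = "little")))
  writeBin(dcm_file(UID_RTDOSE, sop, dataset), path)
  invisible(path)
}

#' @rdname write_rtdose
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(ds[["0008,0016"]], UID_RTDOSE))
    stop("not an RT Dose DICOM file: ", path)
  nx <- as.integer(ds[["0028,0011"]]); ny <- as.integer(ds[["0028,0010"]])
  nz <- as.integer(ds[["0028,0008"]])
  scaling <- ds[["3004,000E"]]
  px <- readBin(ds[["7FE0,0010"]], integer(), n = nx * ny * nz, size = 4L,
                endian = "little")
  values <- array(px * scaling, dim = c(nx, ny, nz))
  spacing_xy <- ds[["0028,0030"]][c(2L, 1L)] / 10
  offsets <- ds[["3004,000C"]]
  dz <- if (length(offsets) > 1L) (offsets[2L] - offsets[1L]) / 10 else 1
  dose_grid(values, spacing_cm = c(spacing_xy, dz),
            origin_cm = ds[["0020,0032"]] / 10)
}

# -- plain dose pair ----------------------------------------------------------

#' Write / read a dose grid as a JSON + raw-binary pair
#'
#' A documented two-file format for dose grids: \code{<path>.json} holds the
#' geometry (dimensions, spacing and origin in cm, element order) and
#' \code{<path>.bin} the voxel values as little-endian float64 in R array
#' order (first dimension fastest), followed by the per-voxel uncertainty
#' array when present.
#'
#' @param dose a [dose_grid()].
#' @param path base path (extensions are appended).
#' @return \code{write_dose_pair}: invisibly, \code{path};
#'   \code{read_dose_pair}: a [dose_grid()].
#' @export
write_dose_pair <- function(dose, path) {
  meta <- list(format = "dynaverify-dose", version = 1L,
               dim = dim(dose$values), spacing_cm = dose$spacing_cm,
               origin_cm = dose$origin_cm, has_sigma = !is.null(dose$sigma),
               dtype = "float64-le")
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(dose$values), con, size = 8L, endian = "little")
  if (!is.null(dose$sigma))
    writeBin(as.vector(dose$sigma), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_dose_pair
#' @export
read_dose_pair <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "dynaverify-dose"))
    stop("not a dynaverify dose pair: ", path)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  values <- array(readBin(con, double(), n = n, size = 8L,
                          endian = "little"), dim = meta$dim)
  sigma <- NULL
  if (isTRUE(meta$has_sigma))
    sigma <- array(readBin(con, double(), n = n, size = 8L,
                           endian = "little"), dim = meta$dim)
  dose_grid(values, spacing_cm = meta$spacing_cm, origin_cm = meta$origin_cm,
            sigma = sigma)
}
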