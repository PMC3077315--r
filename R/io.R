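# File interchange: minimal NIfTI-1 image I/O (no NIfTI package exists in
# the installed R stack, and only a small, fixed subset of the format is
# needed: single-file .nii, little-endian, 2D-4D, uint8/int16/float32/
# float64), JSON sidecars and budget reports via jsonlite, and plain CSV
# for waveforms and sensor traces.

SCHEMA_VERSION <- "1.0"

nifti_datatypes <- c(`2` = "integer", `4` = "integer", `16` = "double",
                     `64` = "double")
nifti_sizes <- c(`2` = 1L, `4` = 2L, `16` = 4L, `64` = 8L)

#' Minimal NIfTI-1 image writer/reader
#'
#' Writes/reads single-file uncompressed `.nii` volumes, little-endian,
#' supporting uint8, int16, float32 and float64. Arrays are `[ny, nx]` or
#' `[ny, nx, nt]` in R (row = y); on disk they follow the NIfTI convention
#' (x fastest, a 4D file has z = 1). Round trips at float64 are
#' bit-identical.
#'
#' @param img numeric/logical matrix or 3D array `[ny, nx, nt]`.
#' @param path output path (`.nii`).
#' @param pixdim voxel dimensions `c(dx, dy, dz, dt)` (cm, cm, cm, s).
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 16 (float32),
#'   64 (float64, default).
#' @return `write_nifti()`: the path, invisibly. `read_nifti()`: a list with
#'   `img` (array `[ny, nx, nt]`, `nt` dropped if 1) and `pixdim`.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1, 1), datatype = 64L) {
  if (is.logical(img)) img <- img + 0L
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  stopifnot(length(dim(img)) == 3)
  dt_key <- as.character(datatype)
  if (!dt_key %in% names(nifti_sizes))
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  d <- dim(img)
  nt <- d[3]
  ndim <- if (nt > 1) 4L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wint(348L, 4)                                   # sizeof_hdr
  wraw(35)                                        # data_type..regular
  wraw(1)                                         # dim_info
  wint(c(ndim, d[2], d[1], 1L, nt, 1L, 1L, 1L), 2)  # dim[8]
  wflt(c(0, 0, 0))                                # intent_p1..3
  wint(0L, 2)                                     # intent_code
  wint(datatype, 2)                               # datatype
  wint(8L * nifti_sizes[[dt_key]], 2)             # bitpix
  wint(0L, 2)                                     # slice_start
  wflt(c(1, pixdim[1], pixdim[2], pixdim[3], pixdim[4], 0, 0, 0))  # pixdim
  wflt(352)                                       # vox_offset
  wflt(c(0, 0))                                   # scl_slope, scl_inter
  wint(0L, 2); wraw(2)                            # slice_end, slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                             # cal_max..toffset
  wint(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw("cvmr minimal NIfTI-1")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip
  wraw(24)                                        # aux_file
  wint(c(0L, 0L), 2)                              # qform_code, sform_code
  wflt(rep(0, 6))                                 # quatern/qoffset
  wflt(c(pixdim[1], 0, 0, 0)); wflt(c(0, pixdim[2], 0, 0))
  wflt(c(0, 0, pixdim[3], 0))                     # srow
  wraw(16)                                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  wraw(4)                                         # extension flag
  dat <- aperm(img, c(2, 1, 3))                   # x fastest on disk
  if (nifti_datatypes[[dt_key]] == "integer") {
    writeBin(as.integer(dat), con, size = nifti_sizes[[dt_key]],
             endian = "little")
  } else {
    writeBin(as.numeric(dat), con, size = nifti_sizes[[dt_key]],
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  rint <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rflt <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rint(0, 4) != 348L || rawToChar(hdr[345:347]) != "n+1")
    stop("not a single-file NIfTI-1 image: ", path, call. = FALSE)
  dim8 <- rint(40, 2, 8)
  datatype <- rint(70, 2)
  dt_key <- as.character(datatype)
  if (!dt_key %in% names(nifti_sizes))
    stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- rflt(76, 8)[2:5]
  vox_offset <- rflt(108)
  nx <- dim8[2]; ny <- dim8[3]; nz <- max(dim8[4], 1L)
  nt <- if (dim8[1] >= 4) max(dim8[5], 1L) else 1L
  seek(con, vox_offset)
  n_vox <- nx * ny * nz * nt
  dat <- readBin(con, nifti_datatypes[[dt_key]], n = n_vox,
                 size = nifti_sizes[[dt_key]], endian = "little",
                 signed = datatype != 2L)
  img <- aperm(array(dat, c(nx, ny, nz * nt)), c(2, 1, 3))
  if (dim(img)[3] == 1) img <- img[, , 1]
  list(img = img, pixdim = pixdim)
}

#' Write/read a velocity series as NIfTI + JSON sidecar
#'
#' `write_velocity_series()` writes `<base>_vel.nii` and `<base>_mag.nii`
#' (float64, 4D with z = 1) plus a `<base>.json` sidecar carrying the
#' acquisition metadata (venc_cm_s, pixel_spacing_cm, period_s, n_phases,
#' seed, ...). `read_velocity_series()` reconstructs the
#' [velocity_series()]; a missing sidecar key raises a schema error naming
#' the key.
#'
#' @param series a [velocity_series()].
#' @param base path prefix (no extension).
#' @return `write_velocity_series()`: `base`, invisibly;
#'   `read_velocity_series()`: a [velocity_series()].
#' @export
write_velocity_series <- function(series, base) {
  stopifnot(inherits(series, "velocity_series"))
  acq <- series$acquisition
  pd <- c(acq$pixel_spacing, acq$pixel_spacing, acq$slice_thickness,
          acq$cycle_period / acq$n_phases)
  write_nifti(series$velocity, paste0(base, "_vel.nii"), pd)
  write_nifti(series$magnitude, paste0(base, "_mag.nii"), pd)
  side <- list(schema_version = SCHEMA_VERSION,
               venc_cm_s = acq$venc,
               pixel_spacing_cm = acq$pixel_spacing,
               field_of_view_cm = acq$field_of_view,
               matrix_size = acq$matrix_size,
               slice_thickness_cm = acq$slice_thickness,
               period_s = acq$cycle_period,
               n_phases = acq$n_phases,
               timestamps_s = series$timestamps,
               seed = series$seed,
               lumen = series$lumen)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(base)
}

#' @rdname write_velocity_series
#' @export
read_velocity_series <- function(base) {
  side_path <- paste0(base, ".json")
  if (!file.exists(side_path))
    stop("schema error: sidecar not found: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  required <- c("venc_cm_s", "pixel_spacing_cm", "field_of_view_cm",
                "matrix_size", "slice_thickness_cm", "period_s", "n_phases",
                "timestamps_s")
  missing <- setdiff(required, names(side))
  if (length(missing))
    stop("schema error: sidecar missing key '", missing[1], "'",
         call. = FALSE)
  vel <- read_nifti(paste0(base, "_vel.nii"))$img
  mag <- read_nifti(paste0(base, "_mag.nii"))$img
  acq <- acquisition_geometry(side$field_of_view_cm, side$matrix_size,
                              side$slice_thickness_cm, side$n_phases,
                              side$period_s, side$venc_cm_s)
  seed <- if (is.null(side$seed) || is.na(side$seed)) NA_integer_
          else as.integer(side$seed)
  velocity_series(vel, mag, acq, side$timestamps_s,
                  lumen = side$lumen, seed = seed)
}

#' Write/read an ROI mask as NIfTI (0/1)
#'
#' @param mask an [roi_mask()].
#' @param path output `.nii` path.
#' @return `write_mask_nifti()`: path, invisibly; `read_mask_nifti()`: an
#'   [roi_mask()] (pixel spacing taken from the NIfTI header).
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_nifti(mask$mask, path,
              pixdim = c(mask$pixel_spacing, mask$pixel_spacing, 1, 1),
              datatype = 2L)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  nii <- read_nifti(path)
  roi_mask(nii$img != 0, pixel_spacing = nii$pixdim[1])
}

#' Waveform and sensor-trace CSV I/O
#'
#' Waveform files have one header line `time_s,value,units`; sensor traces
#' `time_s,dp_pa`. Values round-trip at full double precision.
#'
#' @param wf a [waveform()].
#' @param path CSV path.
#' @return writers return the path invisibly; `read_waveform_csv()` a
#'   [waveform()], `read_sensor_csv()` a `sensor_trace`.
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  utils::write.csv(format(as.data.frame(wf), digits = 17, trim = TRUE,
                          scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value", "units") %in% names(df)))
    stop("schema error: waveform CSV needs time_s,value,units", call. = FALSE)
  if (nrow(df) == 0)
    stop("insufficient data: empty waveform CSV", call. = FALSE)
  dt <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else df$time_s[1]
  waveform(df$value, period = dt * nrow(df), units = df$units[1])
}

#' @rdname write_waveform_csv
#' @param trace a `sensor_trace` (data.frame `time_s`, `dp_pa`).
#' @export
write_sensor_csv <- function(trace, path) {
  utils::write.csv(format(as.data.frame(trace)[c("time_s", "dp_pa")],
                          digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "dp_pa") %in% names(df)))
    stop("schema error: sensor CSV needs time_s,dp_pa", call. = FALSE)
  if (nrow(df) < 2)
    stop("insufficient data: sensor CSV has fewer than 2 samples",
         call. = FALSE)
  structure(df, class = c("sensor_trace", "data.frame"),
            period = NA_real_)
}

# waveform <-> plain list for JSON
wf_to_list <- function(wf) {
  if (is.null(wf)) return(NULL)
  list(values = wf$values, period_s = wf$period, units = wf$units)
}
wf_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  waveform(unlist(x$values), x$period_s, x$units)
}

#' Budget report JSON I/O
#'
#' Serializes a [momentum_budget()] (all waveforms, geometry, fluid,
#' uncertainty and scheme choices) to JSON at full float precision, with a
#' `schema_version` field, and reads it back.
#'
#' @param budget a [momentum_budget()].
#' @param path JSON path.
#' @return `write_budget_json()`: path, invisibly; `read_budget_json()`: a
#'   list mirroring the budget with `waveform` objects restored.
#' @export
write_budget_json <- function(budget, path) {
  stopifnot(inherits(budget, "momentum_budget"))
  rep <- list(
    schema_version = SCHEMA_VERSION,
    mode = budget$mode, scheme = budget$scheme,
    geometry = unclass(budget$geometry),
    fluid = unclass(budget$fluid),
    body_force_dyne = budget$body_force,
    flow = wf_to_list(budget$flow),
    inertial_force = wf_to_list(budget$inertial_force),
    momentum_inflow = wf_to_list(budget$momentum_inflow),
    viscous_force = wf_to_list(budget$viscous_force),
    pressure_force_cv = wf_to_list(budget$pressure_force_cv),
    pressure_gradient = wf_to_list(budget$pressure_gradient),
    up = list(gradient = wf_to_list(budget$up$gradient),
              inertial_part = wf_to_list(budget$up$inertial_part),
              viscous_part = wf_to_list(budget$up$viscous_part),
              force = wf_to_list(budget$up$force),
              n_stencil_pixels = budget$up$n_stencil_pixels),
    uncertainty = if (!is.null(budget$uncertainty))
      unclass(budget$uncertainty))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_budget_json
#' @export
read_budget_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("flow", "inertial_force", "momentum_inflow", "viscous_force",
              "pressure_force_cv", "pressure_gradient"))
    rep[[f]] <- wf_from_list(rep[[f]])
  for (f in c("gradient", "inertial_part", "viscous_part", "force"))
    rep$up[[f]] <- wf_from_list(rep$up[[f]])
  rep
}
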