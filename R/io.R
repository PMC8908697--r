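#' Load a 4D dynamic series from NIfTI-1
#'
#' Reads a 4D (x, y, z, t) signal-intensity volume. Frame times default to
#' a uniform grid `(0:(nt-1)) * protocol$dt_s` anchored at the first
#' dynamic frame; an explicit per-frame time table overrides the grid.
#' A frame count differing from `protocol$n_dynamic` is reported as a
#' warning, not an error, so truncated acquisitions remain loadable.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`)
#' @param protocol `acquisition_protocol` supplying `dt_s` and the expected
#'   frame count
#' @param frame_times_s optional explicit per-frame times (s), strictly
#'   increasing, one per frame
#' @return object of class `dynamic_series`: list with `data` (4D array),
#'   `frame_times_s`, `voxel_dims_mm`
#' @export
load_dynamic_series <- function(path, protocol, frame_times_s = NULL) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-dimensional dynamic series, got %d dimensions",
                 length(dim(arr))))
  if (any(!is.finite(arr)) || any(arr < 0, na.rm = TRUE))
    stop("dynamic series must be finite and non-negative")
  nt <- dim(arr)[4]
  if (nt != protocol$n_dynamic)
    warning(sprintf("frame count %d differs from protocol n_dynamic %d",
                    nt, protocol$n_dynamic))
  if (is.null(frame_times_s)) {
    frame_times_s <- (seq_len(nt) - 1) * protocol$dt_s
  } else {
    if (length(frame_times_s) != nt)
      stop("frame_times_s length must equal the number of frames")
    if (any(diff(frame_times_s) <= 0))
      stop("frame_times_s must be strictly increasing")
  }
  pd <- RNifti::pixdim(img)
  dynamic_series(arr, frame_times_s, voxel_dims_mm = pd[seq_len(min(3, length(pd)))])
}

#' Construct a dynamic series from an in-memory array
#'
#' @param data 4D (x, y, z, t) array, finite and non-negative
#' @param frame_times_s strictly increasing frame times (s)
#' @param voxel_dims_mm spatial voxel spacing (mm)
#' @return `dynamic_series`
#' @export
dynamic_series <- function(data, frame_times_s, voxel_dims_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4L,
            length(frame_times_s) == dim(data)[4])
  if (any(diff(frame_times_s) <= 0))
    stop("frame_times_s must be strictly increasing")
  structure(list(data = data,
                 frame_times_s = as.numeric(frame_times_s),
                 voxel_dims_mm = as.numeric(voxel_dims_mm)),
            class = "dynamic_series")
}

#' Load an ROI mask from NIfTI-1
#'
#' Nonzero voxels are selected. The mask must share the spatial grid of the
#' series it indexes; no resampling is performed, so voxel (i, j, k) of the
#' mask addresses voxel (i, j, k) of the series.
#'
#' @param path NIfTI-1 file with integer or boolean voxels
#' @param series `dynamic_series` (or 3D/4D array) defining the expected
#'   spatial shape
#' @param label mask role, `"tumor"` or `"artery"`
#' @return object of class `voxel_mask`: list with logical 3D `data`, `label`
#' @export
load_mask <- function(path, series, label = c("tumor", "artery")) {
  label <- match.arg(label)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("mask must be a 3-dimensional volume")
  voxel_mask(arr != 0, series, label = label)
}

#' Construct a voxel mask from a logical array
#'
#' @param data logical 3D array
#' @param series `dynamic_series` or array whose spatial shape must match
#' @param label `"tumor"` or `"artery"`
#' @return `voxel_mask`
#' @export
voxel_mask <- function(data, series = NULL, label = c("tumor", "artery")) {
  label <- match.arg(label)
  stopifnot(is.logical(data) || all(data %in% c(0, 1)))
  data <- array(as.logical(data), dim(data))
  if (!is.null(series)) {
    shape <- if (inherits(series, "dynamic_series")) dim(series$data)[1:3]
             else dim(series)[1:3]
    if (!identical(as.integer(dim(data)), as.integer(shape)))
      stop(sprintf("mask shape (%s) does not match series spatial shape (%s)",
                   paste(dim(data), collapse = "x"),
                   paste(shape, collapse = "x")))
  }
  if (!any(data))
    stop("empty ROI: mask selects no voxels")
  structure(list(data = data, label = label), class = "voxel_mask")
}

# Allowed tokens for the clinical table.
.subtype_tokens <- c("endometrioid", "nonendometrioid")

#' Read a per-patient clinical table
#'
#' Expects a CSV (RFC-4180, header row) with at least `id` and `subtype`;
#' recognised columns are `id, subtype, grade, dmi, csi, lvsi, lnm,
#' reader_dmi, reader_csi, reader_lnm, mvd` plus any per-parameter median
#' columns. Pathology/reader flags are coerced to logical; `grade` must be
#' 1-3 and is required for endometrioid tumors. Missing optional columns
#' are left absent (never silently zero-filled).
#'
#' @param path CSV file path
#' @return `data.frame` of class `cohort_table`
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("cohort table must have an 'id' column")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate patient id(s): ", paste(dup, collapse = ", "))
  if ("subtype" %in% names(df)) {
    bad <- setdiff(unique(df$subtype), .subtype_tokens)
    if (length(bad))
      stop("unknown subtype token(s): ", paste(bad, collapse = ", "))
    if ("grade" %in% names(df)) {
      g <- df$grade[df$subtype == "endometrioid"]
      if (any(!is.na(g) & !g %in% 1:3))
        stop("endometrioid grade must be 1, 2 or 3")
    }
  }
  for (fl in c("dmi", "csi", "lvsi", "lnm",
               "reader_dmi", "reader_csi", "reader_lnm"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  if ("risk" %in% names(df) &&
      any(!df$risk %in% c("low", "high", NA)))
    stop("risk labels must be 'low' or 'high'")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a 3D parameter map to NIfTI-1
#'
#' Failed-fit voxels are encoded as NaN and survive the round trip
#' bit-exactly (maps are written as doubles). The parameter name and units
#' are recorded in the NIfTI `descrip` header field as `"name [units]"`.
#'
#' @param map 3D numeric array (NaN allowed at failed voxels)
#' @param path output file path (`.nii` or `.nii.gz`)
#' @param name parameter name (e.g. `"Ktrans"`)
#' @param units unit string (e.g. `"min^-1"`)
#' @param voxel_dims_mm voxel spacing recorded in the header
#' @return `path`, invisibly
#' @export
write_parameter_map <- function(map, path, name = "param", units = "",
                                voxel_dims_mm = c(1, 1, 1)) {
  if (length(dim(map)) != 3L)
    stop(sprintf("parameter map must be 3-dimensional, got %d dimensions",
                 length(dim(map))))
  img <- RNifti::asNifti(map, datatype = "double")
  img <- RNifti::updateNifti(img, list(
    descrip = substr(sprintf("%s [%s]", name, units), 1, 79),
    pixdim = c(1, voxel_dims_mm, rep(1, 4))))   # qfac + 7 dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read back a parameter map written by [write_parameter_map()]
#'
#' @param path NIfTI file
#' @return list with `map` (3D array), `name`, `units`
#' @export
read_parameter_map <- function(path) {
  img <- RNifti::readNifti(path)
  descrip <- RNifti::niftiHeader(img)$descrip
  m <- regmatches(descrip, regexec("^(.*) \\[(.*)\\]$", descrip))[[1]]
  list(map = as.array(img),
       name = if (length(m) == 3) m[2] else descrip,
       units = if (length(m) == 3) m[3] else "")
}

#' Write a 3D or 4D volume to NIfTI-1 (bit-exact doubles)
#'
#' @param arr 3D/4D numeric array
#' @param path output path
#' @return `path`, invisibly
#' @export
write_volume <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}
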