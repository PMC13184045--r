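#' Voxel volume container
#'
#' A `voxel_volume` is a 3D scalar grid with isotropic-or-not voxel spacing and
#' a unit tag. It is the common currency of the phantom generator, the
#' attenuation-map utilities and the VOI extraction functions. Conventions:
#' 0-based voxel indices in world-coordinate formulas, world coordinate of a
#' voxel center = index * spacing, axis order (x, y, z), identity orientation.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm along (x, y, z).
#' @param unit one of `"suv"` (SUV g/mL), `"mu"` (cm^-1), `"hu"` (Hounsfield
#'   units) or `"label"` (integer organ/lesion labels).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(4, 4, 4), unit = c("suv", "mu", "hu", "label")) {
  unit <- match.arg(unit)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), unit = unit),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, unit '%s'\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit
  ))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

#' Voxel volume in cubic centimetres
#' @param vol a `voxel_volume`.
#' @return scalar, volume of one voxel in ccm (mL).
#' @export
voxel_ccm <- function(vol) {
  stopifnot(is_voxel_volume(vol))
  prod(vol$spacing) / 1000
}

#' Check two volumes share the same grid
#'
#' Same array dimensions and same spacing (to within a strict numerical
#' tolerance). Registration is out of scope: volumes are contractually
#' co-registered, and this identity check is what enforces the contract.
#'
#' @param a,b `voxel_volume` objects.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
assert_same_grid <- function(a, b) {
  stopifnot(is_voxel_volume(a), is_voxel_volume(b))
  if (!identical(dim(a$data), dim(b$data))) {
    stop("grid mismatch: array dimensions differ", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop("grid mismatch: voxel spacing differs", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a voxel volume as headered plain text
#'
#' Simple ASCII serialization used in place of NIfTI (no NIfTI I/O package is
#' assumed): a header line `dims dx dy dz spacing sx sy sz unit u`, then the
#' values in column-major order, one per line, full precision.
#'
#' @param vol a `voxel_volume`.
#' @param path file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` the volume.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_voxel_volume(vol))
  d <- dim(vol$data)
  header <- sprintf(
    "dims %d %d %d spacing %.17g %.17g %.17g unit %s",
    d[1], d[2], d[3], vol$spacing[1], vol$spacing[2], vol$spacing[3], vol$unit
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17g", as.vector(vol$data)), con)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  lines <- readLines(path)
  h <- strsplit(lines[[1]], " ", fixed = TRUE)[[1]]
  if (length(h) != 10L || h[1] != "dims" || h[5] != "spacing" || h[9] != "unit") {
    stop("not a voxel_volume text file: bad header", call. = FALSE)
  }
  d <- as.integer(h[2:4])
  spacing <- as.numeric(h[6:8])
  unit <- h[10]
  vals <- as.numeric(lines[-1])
  if (length(vals) != prod(d)) stop("value count does not match header dims", call. = FALSE)
  voxel_volume(array(vals, dim = d), spacing = spacing, unit = unit)
}
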