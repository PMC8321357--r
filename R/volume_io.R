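#' Construct a Volume
#'
#' A `Volume` is the package's uniform container for 2D MR slices and 3D MR
#' volumes: a finite real intensity array with per-axis voxel spacing (mm)
#' and a recorded nominal peak intensity. The peak anchors the package's
#' percent-noise convention (n% noise means a noise standard deviation of
#' `n/100 * peak`) and the PSNR peak; it is recorded once and never silently
#' recomputed from the data, so noisy data may exceed it.
#'
#' @param data numeric array with 2 or 3 axes; all values must be finite.
#' @param spacing numeric vector of physical voxel sizes per axis (mm);
#'   recycled to the number of axes. Default 1.
#' @param peak nominal maximum intensity (default 255, the 8-bit convention
#'   used for percent noise levels).
#' @return an object of class `mrisr_volume` with fields `data`, `spacing`,
#'   `peak`.
#' @examples
#' v <- volume(matrix(0, 8, 8))
#' dim(v$data)
#' @export
volume <- function(data, spacing = NULL, peak = 255) {
  data <- as.array(data)
  if (is.null(dim(data))) stop("data must be an array")
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) {
    stop("Volume data must have 2 or 3 axes, got ", nd)
  }
  if (!all(is.finite(data))) stop("Volume intensities must all be finite")
  if (!is.numeric(peak) || length(peak) != 1L || peak <= 0) {
    stop("peak must be a single positive number")
  }
  if (is.null(spacing)) spacing <- rep(1, nd)
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing, peak = peak),
            class = "mrisr_volume")
}

#' @export
print.mrisr_volume <- function(x, ...) {
  cat("mrisr Volume:", paste(dim(x$data), collapse = " x "),
      "| spacing (mm):", paste(signif(x$spacing, 4), collapse = " x "),
      "| peak:", x$peak,
      "| intensity range:", paste(signif(range(x$data), 5), collapse = " .. "),
      "\n")
  invisible(x)
}

# Coerce a bare matrix/array to Volume; pass Volumes through.
as_volume <- function(x, peak = 255) {
  if (inherits(x, "mrisr_volume")) x else volume(x, peak = peak)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read an image volume
#'
#' Reads a NIfTI-1 file (`.nii`, `.nii.gz`) or a plain-text array file
#' written by [write_volume()] and returns a [volume()]. Intensities are
#' kept at their native scale (no rescaling); spacing comes from the NIfTI
#' header (1 mm per axis if absent). The recorded `peak` defaults to 255 and
#' can be overridden, matching the 8-bit percent-noise convention.
#'
#' @param path path to a `.nii`/`.nii.gz` file or a `.tsv` array file.
#' @param peak nominal peak intensity to record (default 255).
#' @return a `mrisr_volume`.
#' @export
read_volume <- function(path, peak = 255) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    # squeeze trailing singleton axes (e.g. 3D files holding a single slice)
    while (length(d) > 2L && d[length(d)] == 1L) d <- d[-length(d)]
    if (length(d) < 2L || length(d) > 3L) {
      stop("volume in ", path, " has ", length(d), " spatial axes; need 2 or 3")
    }
    sp <- tryCatch(RNifti::pixdim(img), error = function(e) NULL)
    if (is.null(sp) || !length(sp)) sp <- rep(1, length(d))
    sp <- rep_len(abs(as.numeric(sp)), length(d))
    sp[!is.finite(sp) | sp <= 0] <- 1
    arr <- array(as.numeric(img), dim = d)
    return(volume(arr, spacing = sp, peak = peak))
  }
  # plain-text array container: header line "# dim: a b [c] spacing: ..."
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  if (!startsWith(hdr, "# mrisr-array")) {
    stop("not a NIfTI or mrisr plain array file: ", path)
  }
  toks <- strsplit(sub("^# mrisr-array ", "", hdr), "\\s+")[[1]]
  nd <- as.integer(toks[1])
  d <- as.integer(toks[2:(1 + nd)])
  sp <- as.numeric(toks[(2 + nd):(1 + 2 * nd)])
  pk <- as.numeric(toks[2 + 2 * nd])
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != prod(d)) stop("corrupt array file: ", path)
  volume(array(vals, dim = d), spacing = sp, peak = pk)
}

#' Write an image volume
#'
#' Writes a [volume()] to disk; the format is inferred from the extension
#' (`.nii`/`.nii.gz` for NIfTI-1, anything else is the package's plain-text
#' array container used for small fixtures). Data and spacing round-trip
#' exactly through [read_volume()] at stored precision.
#'
#' @param vol a `mrisr_volume` (or bare array).
#' @param path output path; the parent directory must exist.
#' @return `invisible(path)`.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (is_nifti_path(path)) {
    dat <- vol$data
    attr(dat, "pixdim") <- vol$spacing
    RNifti::writeNifti(RNifti::asNifti(dat, datatype = "double"), path)
  } else {
    d <- dim(vol$data)
    hdr <- paste("# mrisr-array", length(d), paste(d, collapse = " "),
                 paste(format(vol$spacing, digits = 17), collapse = " "),
                 format(vol$peak, digits = 17))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(format(as.vector(vol$data), digits = 17), con)
  }
  invisible(path)
}
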