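CATEGORIES <- c("dark", "bright", "reference", "sample")
HARMONIC_LABELS <- {
  g <- expand.grid(m = -1:1, n = -1:1)
  lapply(seq_len(nrow(g)), function(i) c(g$m[i], g$n[i]))
}

label_key <- function(label) sprintf("%+d%+d", label[1], label[2])

parse_label <- function(key) {
  m <- regmatches(key, regexec("^([+-]\\d+)([+-]\\d+)$", key))[[1]]
  if (length(m) != 3L) stop("bad harmonic label key: ", key, call. = FALSE)
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Initialize a measurement project directory
#'
#' Creates the on-disk layout used by the whole pipeline: one subdirectory
#' per frame category plus `out/` for processed maps. In CT mode, `out/`
#' additionally contains one `harmonic_{label}/` directory per harmonic
#' order so that per-angle, per-harmonic contrast images can be organised
#' for reconstruction. Re-running on an existing project is a no-op (no
#' data are clobbered).
#'
#' @param root Project root directory (created if absent).
#' @param mode `"projection"` for single-view imaging, `"ct"` for scans.
#' @return An object of class `shi_project` with fields `root`, `mode`,
#'   and named category/output paths.
#' @export
init_project <- function(root, mode = c("projection", "ct")) {
  mode <- match.arg(mode)
  dirs <- c(file.path(root, CATEGORIES), file.path(root, "out"))
  if (identical(mode, "ct")) {
    dirs <- c(dirs, file.path(root, "out",
                              paste0("harmonic_", vapply(HARMONIC_LABELS, label_key, ""))))
  }
  for (d in dirs) {
    ok <- dir.exists(d) || dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(d)) {
      stop("cannot create project directory: ", d, call. = FALSE)
    }
  }
  structure(
    list(root = normalizePath(root), mode = mode,
         categories = stats::setNames(file.path(normalizePath(root), CATEGORIES), CATEGORIES),
         out = file.path(normalizePath(root), "out")),
    class = "shi_project"
  )
}

#' @export
print.shi_project <- function(x, ...) {
  cat(sprintf("<shi_project> mode=%s root=%s\n", x$mode, x$root))
  invisible(x)
}

#' Output path for a per-angle, per-harmonic CT contrast image
#'
#' Pure function of (angle index, harmonic label, contrast kind); this is
#' the directory contract that [assemble_sinogram()] reads back.
#'
#' @param project A `shi_project` in `"ct"` mode.
#' @param angle_index 1-based projection index.
#' @param label Integer pair `c(m, n)`.
#' @param kind Contrast kind: `"absorption"`, `"dpc"` or `"scattering"`.
#' @return File path (character).
#' @export
ct_output_path <- function(project, angle_index, label, kind) {
  stopifnot(inherits(project, "shi_project"))
  file.path(project$out, paste0("harmonic_", label_key(label)), kind,
            sprintf("angle_%05d.tif", as.integer(angle_index)))
}

#' Write an image to TIFF
#'
#' Raw detector frames are stored as single-page 16-bit unsigned grayscale
#' (values 0..65535). Processed real-valued maps are stored as 32-bit
#' float after an affine map to \[0, 1\], with the original `(vmin, vmax)`
#' recorded in a JSON sidecar `<path>.json` which [read_image()] inverts;
#' this keeps the files portable baseline TIFF while preserving the full
#' value range.
#'
#' @param pixels Numeric matrix.
#' @param path Output file path.
#' @param bits 16 (raw counts) or 32 (float map with sidecar).
#' @export
write_image <- function(pixels, path, bits = 16L) {
  pixels <- as_pixel_matrix(pixels)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (bits == 16L) {
    if (min(pixels) < 0 || max(pixels) > 65535) {
      stop("16-bit output requires values in [0, 65535]", call. = FALSE)
    }
    tiff::writeTIFF(round(pixels) / 65535, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
  } else if (bits == 32L) {
    vmin <- min(pixels); vmax <- max(pixels)
    scaled <- if (vmax > vmin) (pixels - vmin) / (vmax - vmin) else pixels * 0
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(vmin = vmin, vmax = vmax),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop("bits must be 16 or 32", call. = FALSE)
  }
  invisible(path)
}

#' Read a TIFF image written by this package
#'
#' @param path TIFF file path.
#' @return Numeric matrix in double precision. 16-bit integer data are
#'   promoted to double; 32-bit float data are rescaled through the JSON
#'   sidecar if one is present.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x <- matrix(as.numeric(x), nrow(x), ncol(x))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    # 32-bit float reads come back in [0,1]; undo the affine storage map
    x <- tiff::readTIFF(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x <- x * (meta$vmax - meta$vmin) + meta$vmin
  }
  x
}

#' Save a frame stack as numbered TIFF files
#'
#' Filenames are zero-padded (`frame_00001.tif`, ...) so lexicographic
#' order equals acquisition order.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
save_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "shi_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%05d.tif", i))
    write_image(stack$frames[[i]]$pixels, paths[i], bits = 16L)
  }
  invisible(paths)
}

#' Load a frame stack from a directory of TIFF files
#'
#' Frames are sorted by filename (zero-padded names sort in acquisition
#' order); 16-bit integer data are promoted to double. A single TIFF is
#' accepted (single-shot mode). All frames must share one shape.
#'
#' @param dir Directory containing at least one `.tif`/`.tiff` file.
#' @param category Frame category to tag the stack with.
#' @param angle_deg Optional projection angle applied to every frame.
#' @return A [frame_stack()].
#' @export
load_stack <- function(dir, category = c("dark", "bright", "reference", "sample"),
                       angle_deg = NULL) {
  category <- match.arg(category)
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF files found in ", dir, call. = FALSE)
  frames <- vector("list", length(files))
  shp <- NULL
  for (i in seq_along(files)) {
    px <- read_image(files[i])
    if (is.null(shp)) shp <- dim(px)
    if (!identical(dim(px), shp)) {
      stop(sprintf("shape mismatch in %s: %s, expected %s",
                   basename(files[i]), paste(dim(px), collapse = "x"),
                   paste(shp, collapse = "x")), call. = FALSE)
    }
    frames[[i]] <- frame(px, category = category, angle_deg = angle_deg,
                         index = i)
  }
  frame_stack(frames)
}
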