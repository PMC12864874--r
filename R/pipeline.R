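FIRST_ORDER_KEYS <- c("+1+0", "-1+0", "+0+1", "+0-1")
DIAGONAL_KEYS <- c("+1+1", "-1-1", "+1-1", "-1+1")

#' Retrieve all contrast maps from a corrected reference/sample pair
#'
#' Core single-projection retrieval: Fourier-transforms both corrected
#' images, locates the harmonic lattice on the reference (or reuses
#' supplied metadata), extracts the nine band-limited harmonics of each,
#' reference-corrects harmonic by harmonic, and evaluates absorption
#' (fundamental), scattering and differential phase (first and second
#' order). Directional first-order maps are also combined into
#' bidirectional means; each symmetric harmonic pair is averaged (with
#' the sign flipped for the antisymmetric phase maps).
#'
#' @param ref_corr,sample_corr `shi_corrected` images of one shape (from
#'   [flat_field()]).
#' @param meta Optional `shi_harmonic_meta` to reuse; computed from the
#'   reference when `NULL`.
#' @param expected_period_px Optional projected mask period passed to
#'   [detect_peaks()].
#' @param guard Reference-modulus guard for [reference_correct()].
#' @param unwrap_method Phase unwrapping method applied to the
#'   directional and bidirectional phase maps (default `"none"`).
#' @return An object of class `shi_contrasts`: list with `absorption`
#'   (map + valid), named lists `scattering` and `dpc` (one entry per
#'   non-fundamental label), `directional` (`S_h`, `S_v`, `P_h`, `P_v`),
#'   `bidirectional` (`S`, `P`), and the harmonic `meta` used.
#' @export
retrieve_contrasts <- function(ref_corr, sample_corr, meta = NULL,
                               expected_period_px = NULL, guard = 1e-3,
                               unwrap_method = "none") {
  stopifnot(inherits(ref_corr, "shi_corrected"),
            inherits(sample_corr, "shi_corrected"))
  ref_spec <- forward_spectrum(ref_corr)
  sample_spec <- forward_spectrum(sample_corr)
  if (is.null(meta)) {
    meta <- detect_peaks(ref_spec, expected_period_px = expected_period_px)
  }
  ref_h <- apply_metadata(ref_spec, meta)
  sample_h <- apply_metadata(sample_spec, meta)

  ratios <- lapply(names(ref_h), function(k) {
    reference_correct(sample_h[[k]], ref_h[[k]], guard = guard)
  })
  names(ratios) <- names(ref_h)

  ab <- absorption(ratios[["+0+0"]])
  other <- setdiff(names(ratios), "+0+0")
  sc <- lapply(ratios[other], scattering,
               sample00 = sample_h[["+0+0"]], ref00 = ref_h[["+0+0"]])
  ph <- lapply(ratios[other], function(r) {
    out <- dpc(r)
    out$map <- unwrap(out$map, unwrap_method)
    out
  })

  pair_mean <- function(maps, a, b, antisym = FALSE) {
    s <- if (antisym) -1 else 1
    combine_directions(maps[[a]]$map, s * maps[[b]]$map)
  }
  directional <- list(
    S_h = pair_mean(sc, "+1+0", "-1+0"),
    S_v = pair_mean(sc, "+0+1", "+0-1"),
    P_h = pair_mean(ph, "+1+0", "-1+0", antisym = TRUE),
    P_v = pair_mean(ph, "+0+1", "+0-1", antisym = TRUE))
  bidirectional <- list(
    S = combine_directions(directional$S_h, directional$S_v),
    P = combine_directions(directional$P_h, directional$P_v))

  structure(list(absorption = ab, scattering = sc, dpc = ph,
                 directional = directional, bidirectional = bidirectional,
                 meta = meta),
            class = "shi_contrasts")
}

#' @export
print.shi_contrasts <- function(x, ...) {
  cat(sprintf("<shi_contrasts> %d x %d maps, period %.2f px, band_limit %d\n",
              nrow(x$absorption$map), ncol(x$absorption$map),
              x$meta$d, x$meta$band_limit))
  cat(sprintf("  absorption mean %.4g; bidirectional S mean %.4g; P mean %.4g rad\n",
              mean(x$absorption$map), mean(x$bidirectional$S),
              mean(x$bidirectional$P)))
  invisible(x)
}

#' Export contrast maps as 32-bit float TIFFs
#'
#' One directory per contrast modality under `out_dir`: `absorption/`,
#' `dpc_{label}/`, `scattering_{label}/` plus `bidirectional/`; filenames
#' carry the harmonic and contrast identifiers. Harmonic metadata is
#' saved alongside as `harmonics.json`.
#'
#' @param contrasts A `shi_contrasts`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_contrasts <- function(contrasts, out_dir) {
  stopifnot(inherits(contrasts, "shi_contrasts"))
  paths <- character(0)
  put <- function(map, subdir, name) {
    p <- file.path(out_dir, subdir, name)
    write_image(map, p, bits = 32L)
    paths <<- c(paths, p)
  }
  put(contrasts$absorption$map, "absorption", "absorption_+0+0.tif")
  for (k in names(contrasts$scattering)) {
    put(contrasts$scattering[[k]]$map, paste0("scattering_", k),
        paste0("scattering_", k, ".tif"))
    put(contrasts$dpc[[k]]$map, paste0("dpc_", k), paste0("dpc_", k, ".tif"))
  }
  put(contrasts$bidirectional$S, "bidirectional", "scattering_bidir.tif")
  put(contrasts$bidirectional$P, "bidirectional", "dpc_bidir.tif")
  save_harmonic_meta(contrasts$meta, file.path(out_dir, "harmonics.json"))
  invisible(paths)
}

load_and_average <- function(project, category, region = NULL,
                             screen_threshold = NULL, subdir = NULL) {
  dir <- if (is.null(subdir)) project$categories[[category]]
         else file.path(project$categories[[category]], subdir)
  stack <- load_stack(dir, category)
  if (!is.null(screen_threshold) && length(stack) > 2L) {
    stack <- screen_corrupted(stack, screen_threshold)$stack
  }
  avg <- average_stack(stack)
  if (!is.null(region)) crop(avg, region) else avg
}

#' Process one projection measurement from a project directory
#'
#' Disk-level orchestration of the full retrieval: loads the four
#' category stacks, optionally screens corrupted frames, averages,
#' crops to the ROI, flat-field-corrects reference and sample, and runs
#' [retrieve_contrasts()]; results are exported under `out/` unless
#' `export = FALSE`.
#'
#' @param project A `shi_project` (or root path).
#' @param region Optional [roi()]; `roi.yml` in the project root is used
#'   when present.
#' @param expected_period_px,guard,unwrap_method Passed through to
#'   [retrieve_contrasts()].
#' @param screen_threshold Optional relative threshold for
#'   [screen_corrupted()]; `NULL` disables screening.
#' @param export Write maps under `out/` (default `TRUE`).
#' @return The `shi_contrasts`, invisibly.
#' @export
shi_process <- function(project, region = NULL, expected_period_px = NULL,
                        guard = 1e-3, unwrap_method = "none",
                        screen_threshold = NULL, export = TRUE) {
  if (!inherits(project, "shi_project")) project <- init_project(project, "projection")
  roi_file <- file.path(project$root, "roi.yml")
  if (is.null(region) && file.exists(roi_file)) region <- load_roi(roi_file)

  dark <- load_and_average(project, "dark", region, screen_threshold)
  bright <- load_and_average(project, "bright", region, screen_threshold)
  ref <- load_and_average(project, "reference", region, screen_threshold)
  sample <- load_and_average(project, "sample", region, screen_threshold)

  ref_corr <- flat_field(ref, dark, bright)
  sample_corr <- flat_field(sample, dark, bright)
  contrasts <- retrieve_contrasts(ref_corr, sample_corr,
                                  expected_period_px = expected_period_px,
                                  guard = guard, unwrap_method = unwrap_method)
  if (export) export_contrasts(contrasts, project$out)
  invisible(contrasts)
}

#' Prepare per-angle, per-harmonic contrast images for CT reconstruction
#'
#' Runs the projection retrieval once per scan angle, reusing the
#' harmonic metadata detected on the single shared reference image, and
#' writes each contrast into the per-harmonic CT directory layout read
#' by [assemble_sinogram()].
#'
#' @inheritParams shi_process
#' @return The harmonic metadata used, invisibly.
#' @export
shi_ct_prep <- function(project, region = NULL, expected_period_px = NULL,
                        guard = 1e-3, unwrap_method = "none",
                        screen_threshold = NULL) {
  if (!inherits(project, "shi_project")) project <- init_project(project, "ct")
  dark <- load_and_average(project, "dark", region, screen_threshold)
  bright <- load_and_average(project, "bright", region, screen_threshold)
  ref <- load_and_average(project, "reference", region, screen_threshold)
  ref_corr <- flat_field(ref, dark, bright)
  meta <- detect_peaks(forward_spectrum(ref_corr),
                       expected_period_px = expected_period_px)

  angle_dirs <- sort(list.dirs(project$categories[["sample"]], recursive = FALSE))
  if (length(angle_dirs) == 0L) stop("no per-angle sample directories found", call. = FALSE)
  for (dir in angle_dirs) {
    i <- as.integer(sub("^angle_", "", basename(dir)))
    sample <- load_and_average(project, "sample", region, screen_threshold,
                               subdir = basename(dir))
    cs <- retrieve_contrasts(ref_corr, flat_field(sample, dark, bright),
                             meta = meta, guard = guard,
                             unwrap_method = unwrap_method)
    write_image(cs$absorption$map,
                ct_output_path(project, i, c(0L, 0L), "absorption"), bits = 32L)
    for (k in names(cs$scattering)) {
      lab <- parse_label(k)
      write_image(cs$scattering[[k]]$map,
                  ct_output_path(project, i, lab, "scattering"), bits = 32L)
      write_image(cs$dpc[[k]]$map,
                  ct_output_path(project, i, lab, "dpc"), bits = 32L)
    }
  }
  save_harmonic_meta(meta, file.path(project$out, "harmonics.json"))
  invisible(meta)
}
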