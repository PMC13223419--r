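# Image reading/writing and the benchmark runner.

#' Read an image file as a grayscale matrix
#'
#' PNG, TIFF and JPEG are supported.  Multi-channel images are converted
#' to luminance with weights (0.299, 0.587, 0.114); an alpha channel, if
#' present, is dropped.  Intensities are returned on the integer scale of
#' the source bit depth (0-255 for 8-bit, 0-65535 for 16-bit), with the
#' peak recorded in the `"peak"` attribute.
#'
#' @param path path to a `.png`, `.tif(f)`, `.jpg`/`.jpeg` file.
#' @return numeric matrix with attribute `peak`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (supported: png, tiff, jpeg)")
  )
  # readers return values in [0,1]; 8-bit data are exact multiples of
  # 1/255, anything finer is treated as 16-bit
  peak <- 255
  if (ext %in% c("tif", "tiff", "png")) {
    v <- as.numeric(arr) * 255
    if (max(abs(v - round(v))) > 1e-6) peak <- 65535
  }
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    w <- c(0.299, 0.587, 0.114)
    if (nch >= 3) {
      arr <- arr[, , 1] * w[1] + arr[, , 2] * w[2] + arr[, , 3] * w[3]
    } else {
      arr <- arr[, , 1]
    }
  }
  out <- arr * peak
  attr(out, "peak") <- peak
  out
}

#' Write a grayscale matrix as PNG or TIFF
#'
#' Values are clipped to `[0, peak]` and quantized to the requested bit
#' depth.
#'
#' @param image numeric matrix.
#' @param path output path ending in `.png` or `.tif(f)`.
#' @param peak intensity that maps to full scale (default 255).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, peak = 255, bits = 8L) {
  stopifnot(is.matrix(image), bits %in% c(8L, 16L))
  x <- pmin(pmax(image / peak, 0), 1)
  levels <- 2^bits - 1
  x <- round(x * levels) / levels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported output format '", ext, "' (supported: png, tiff)")
  }
  invisible(path)
}

.benchmark_methods <- list(
  proposed = function(img, config) denoise_proposed(img, config),
  swt = function(img, config) denoise_swt2d(img, config),
  dt_soft = function(img, config) denoise_dt_soft(img, config),
  nlm = function(img, config) denoise_nlm(img)
)

#' Run a denoising benchmark sweep
#'
#' For every combination of image, noise model, seed and method: corrupt
#' the clean image, denoise it, and score the result against the clean
#' image with all four metrics.  Mirrors the table layout of wavelet
#' denoising studies: a long-format results table plus a mean-aggregated
#' summary in which the best method per (image, noise) cell is marked.
#'
#' @param images named list of clean grayscale matrices.
#' @param methods character subset of
#'   `c("proposed", "swt", "dt_soft", "nlm")`.
#' @param noise list of [noise_spec()] objects (their `seed` field is
#'   overridden by `seeds`).
#' @param seeds integer vector of corruption seeds.
#' @param config a [denoise_config()] shared by the wavelet methods.
#' @param metrics which metrics to compute; dropping `"fsim"` speeds up
#'   large sweeps.
#' @return list with `results` (one row per image/noise/seed/method) and
#'   `summary` (seed-averaged, with a logical `best` column marking the
#'   highest mean PSNR per cell).
#' @export
run_benchmark <- function(images, methods = c("proposed", "swt", "dt_soft"),
                          noise = list(noise_spec("gaussian", sigma = 20)),
                          seeds = 1:3,
                          config = denoise_config(),
                          metrics = c("psnr", "ssim", "nmse", "fsim")) {
  stopifnot(length(images) > 0, length(methods) > 0, length(noise) > 0,
            length(seeds) > 0)
  if (is.null(names(images))) {
    names(images) <- paste0("image", seq_along(images))
  }
  unknown <- setdiff(methods, names(.benchmark_methods))
  if (length(unknown) > 0) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(.benchmark_methods), collapse = ", "))
  }
  rows <- list()
  for (img_name in names(images)) {
    clean <- images[[img_name]]
    for (ns in noise) {
      level <- switch(ns$kind, gaussian = ns$sigma,
                      salt_pepper = ns$density, poisson = ns$scale)
      for (seed in seeds) {
        spec <- ns; spec$seed <- as.integer(seed)
        noisy <- corrupt(clean, spec)
        for (method in methods) {
          den <- .benchmark_methods[[method]](noisy, config)
          row <- list(image = img_name, kind = ns$kind, level = level,
                      seed = seed, method = method)
          if ("psnr" %in% metrics) row$psnr <- psnr(clean, den)
          if ("ssim" %in% metrics) row$ssim <- ssim(clean, den)
          if ("nmse" %in% metrics) row$nmse <- nmse(clean, den)
          if ("fsim" %in% metrics) row$fsim <- fsim(clean, den)
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  metric_cols <- intersect(c("psnr", "ssim", "nmse", "fsim"),
                           names(results))
  agg <- stats::aggregate(
    results[metric_cols],
    by = results[c("image", "kind", "level", "method")],
    FUN = mean
  )
  # mark the best method per (image, kind, level) cell by mean PSNR
  if ("psnr" %in% metric_cols) {
    cell <- interaction(agg$image, agg$kind, agg$level, drop = TRUE)
    best <- stats::ave(agg$psnr, cell, FUN = max)
    agg$best <- agg$psnr == best
  }
  list(results = results, summary = agg)
}

#' Write benchmark output to CSV and JSON
#'
#' @param bench result of [run_benchmark()].
#' @param path_csv,path_json output paths (`NULL` to skip one format).
#' @return invisibly, the list of paths written.
#' @export
write_benchmark <- function(bench, path_csv = NULL, path_json = NULL) {
  written <- character(0)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 4))
    df
  }
  if (!is.null(path_csv)) {
    utils::write.csv(fmt(bench$results), path_csv, row.names = FALSE)
    written <- c(written, path_csv)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(results = fmt(bench$results), summary = fmt(bench$summary)),
      path_json, auto_unbox = TRUE, digits = NA
    )
    written <- c(written, path_json)
  }
  invisible(written)
}
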