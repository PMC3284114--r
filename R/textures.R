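#' Generate a synthetic textured-patch dataset
#'
#' Emulates a pool of small grayscale tissue regions in which the two classes
#' differ in second-order statistics: minority ("textured") patches are an
#' oriented sinusoidal grating plus Gaussian noise, majority patches are pure
#' Gaussian noise at the same mean intensity. Gabor magnitude at the grating
#' frequency/orientation and Haralick statistics separate the classes by
#' construction. Patches are tiled into sheet images with a region table, the
#' on-disk layout a patch featurizer consumes.
#'
#' @param n_regions number of square regions to generate.
#' @param patch_size side of each region in pixels (>= 8; default 30, a
#'   typical region size for downsampled biopsy images).
#' @param minority_fraction fraction of textured (class 1) regions; exactly
#'   `round(n_regions * minority_fraction)` are generated.
#' @param texture_params list with elements `frequency` (cycles/pixel of the
#'   minority grating), `orientation` (radians), `amplitude` (grating contrast
#'   on the \[0,1\] intensity scale) and `noise_sd` (shared Gaussian noise sd).
#' @param seed integer seed; same seed, identical pixel arrays.
#' @param regions_per_sheet how many patches are tiled into one sheet image.
#' @return list with `images` (named list of numeric matrices in \[0,1\]),
#'   `regions` (data.frame `image_id,x,y,size,label`; x/y 0-based top-left,
#'   half-open extents) and `labels` (integer vector, 1 = textured minority).
#' @export
make_texture_dataset <- function(n_regions, patch_size = 30,
                                 minority_fraction = 0.04,
                                 texture_params = list(frequency = 0.2,
                                                       orientation = pi / 4,
                                                       amplitude = 0.35,
                                                       noise_sd = 0.08),
                                 seed = 1L, regions_per_sheet = 64L) {
  check_number(n_regions, "n_regions", lower = 1, integer = TRUE)
  check_number(patch_size, "patch_size", lower = 8, integer = TRUE)
  check_number(minority_fraction, "minority_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  tp <- utils::modifyList(list(frequency = 0.2, orientation = pi / 4,
                               amplitude = 0.35, noise_sd = 0.08),
                          texture_params %||% list())
  if (tp$amplitude <= 0)
    warning("degenerate texture_params: zero grating contrast; classes are ",
            "distributionally identical", call. = FALSE)

  n1 <- as.integer(round(n_regions * minority_fraction))
  labels <- c(rep(1L, n1), rep(0L, n_regions - n1))
  with_seed(seed, {
    labels <- sample(labels)
    patches <- lapply(seq_len(n_regions), function(i) {
      noise <- matrix(stats::rnorm(patch_size^2, sd = tp$noise_sd),
                      patch_size, patch_size)
      base <- 0.5 + noise
      if (labels[i] == 1L) {
        cc <- matrix(rep(seq_len(patch_size) - 1L, each = patch_size),
                     patch_size, patch_size)       # x = column index
        rr <- matrix(rep(seq_len(patch_size) - 1L, patch_size),
                     patch_size, patch_size)       # y = row index
        phase <- 2 * pi * tp$frequency *
          (cc * cos(tp$orientation) + rr * sin(tp$orientation))
        base <- base + tp$amplitude * sin(phase)
      }
      pmin(pmax(base, 0), 1)
    })
    # tile patches into sheets, row-major
    per <- as.integer(regions_per_sheet)
    n_sheets <- ceiling(n_regions / per)
    grid <- ceiling(sqrt(per))
    images <- vector("list", n_sheets)
    rows <- vector("list", n_regions)
    for (i in seq_len(n_regions)) {
      sheet <- (i - 1L) %/% per + 1L
      k <- (i - 1L) %% per
      gx <- (k %% grid) * patch_size
      gy <- (k %/% grid) * patch_size
      if (is.null(images[[sheet]]))
        images[[sheet]] <- matrix(0, grid * patch_size, grid * patch_size)
      images[[sheet]][gy + seq_len(patch_size), gx + seq_len(patch_size)] <-
        patches[[i]]
      rows[[i]] <- data.frame(image_id = sprintf("sheet%03d", sheet),
                              x = gx, y = gy, size = patch_size,
                              label = labels[i])
    }
    names(images) <- sprintf("sheet%03d", seq_len(n_sheets))
    list(images = images, regions = do.call(rbind, rows), labels = labels)
  })
}

#' Write a texture dataset to disk
#'
#' Sheets become 8-bit grayscale PNGs, the region table a CSV
#' (`image_id,x,y,size,label`).
#'
#' @param dataset result of [make_texture_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_texture_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_paths <- vapply(names(dataset$images), function(id) {
    p <- file.path(dir, paste0(id, ".png"))
    png::writePNG(dataset$images[[id]], p)
    p
  }, character(1))
  csv <- file.path(dir, "regions.csv")
  utils::write.csv(dataset$regions, csv, row.names = FALSE, quote = FALSE)
  invisible(c(img_paths, csv))
}
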