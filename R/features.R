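#' Patch texture features
#'
#' Patch-level descriptors for small grayscale image regions, in three
#' families: first-order intensity statistics, second-order Haralick
#' statistics of the gray-level co-occurrence matrix, and mean magnitudes of
#' a steerable Gabor filter bank. Each region is summarised by the average of
#' the pixel-wise feature over the region, so a region yields one value per
#' feature.
#'
#' @name patch_features
NULL

as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] >= 3L)
    return(0.2989 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  stop("image must be a 2-D matrix or an RGB array", call. = FALSE)
}

check_patch <- function(patch) {
  if (!is.matrix(patch) && !(is.array(patch) && length(dim(patch)) == 3L))
    stop("patch must be a 2-D numeric matrix (or RGB array)", call. = FALSE)
  p <- as_gray(patch)
  if (!length(p) || !all(is.finite(p)))
    stop("patch must be non-empty with finite values", call. = FALSE)
  p
}

sobel_gradients <- function(patch) {
  if (any(dim(patch) < 3L))
    return(list(gx = matrix(0, nrow(patch), ncol(patch)),
                gy = matrix(0, nrow(patch), ncol(patch))))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  list(gx = EBImage::filter2(patch, kx, boundary = "replicate"),
       gy = EBImage::filter2(patch, t(kx), boundary = "replicate"))
}

#' First-order statistical features of a patch
#'
#' Intensity statistics computed directly from pixel values: mean, median,
#' standard deviation (population form, i.e. divisor N), range, mean Sobel
#' gradient magnitude, and mean absolute directional gradients. The
#' discriminative subset used by the shipped 14-feature selection is
#' `std` and `range`.
#'
#' @param patch numeric matrix (grayscale) or RGB array.
#' @return named numeric vector: `mean, median, std, range, sobel, grad_x,
#'   grad_y`.
#' @examples
#' first_order_features(matrix(100, 5, 5))  # std = 0, range = 0
#' @export
first_order_features <- function(patch) {
  p <- check_patch(patch)
  g <- sobel_gradients(p)
  c(mean   = mean(p),
    median = stats::median(p),
    std    = sqrt(mean((p - mean(p))^2)),
    range  = max(p) - min(p),
    sobel  = mean(sqrt(g$gx^2 + g$gy^2)),
    grad_x = mean(abs(g$gx)),
    grad_y = mean(abs(g$gy)))
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes a patch to `levels` equal-width gray bins and accumulates
#' symmetric pixel-pair counts at the given `distance` for each of the four
#' standard directions (0, 45, 90, 135 degrees). The four normalized
#' matrices are averaged, so entries sum to 1.
#'
#' @param patch numeric matrix.
#' @param levels number of gray levels (>= 2).
#' @param distance pixel offset between pair members.
#' @return `levels x levels` matrix summing to 1.
#' @export
cooccurrence_matrix <- function(patch, levels = 64, distance = 1) {
  p <- check_patch(patch)
  check_number(levels, "levels", lower = 2, integer = TRUE)
  check_number(distance, "distance", lower = 1, integer = TRUE)
  if (min(dim(p)) <= distance)
    stop("patch must be larger than `distance`", call. = FALSE)
  L <- as.integer(levels)
  rng <- range(p)
  q <- if (rng[1] == rng[2]) matrix(1L, nrow(p), ncol(p))
       else matrix(pmin(L, 1L + as.integer(floor((p - rng[1]) /
                      (rng[2] - rng[1]) * L))), nrow(p), ncol(p))
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)) # 0,45,90,135 deg
  nr <- nrow(q); nc <- ncol(q)
  acc <- matrix(0, L, L)
  for (off in offsets) {
    dr <- off[1] * distance; dc <- off[2] * distance
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- matrix(tabulate((a - 1L) * L + b, nbins = L * L), L, L,
                     byrow = TRUE)
    counts <- counts + t(counts)                       # symmetric pairs
    acc <- acc + counts / sum(counts)
  }
  acc / length(offsets)
}

haralick_names <- c("har_energy", "har_contrast", "har_correlation",
                    "har_variance", "har_homogeneity", "har_sum_average",
                    "har_sum_variance", "har_sum_entropy", "har_entropy",
                    "har_diff_variance", "har_diff_entropy", "har_imc1",
                    "har_imc2")

#' The thirteen Haralick co-occurrence features
#'
#' Classical second-order texture statistics of the direction-averaged
#' symmetric co-occurrence matrix: energy (angular second moment), contrast,
#' correlation, variance (sum of squares), homogeneity (inverse difference
#' moment), sum average, sum variance (about the sum average), sum entropy,
#' entropy, difference variance, difference entropy, and the two information
#' measures of correlation. Natural logarithms; `0 log 0 = 0`; correlation
#' and IMC1 are defined as 0 on degenerate (zero-variance) matrices so that
#' every feature is finite on any input. The discriminative subset shipped in
#' the default selection is information measure (IMC1), correlation, energy,
#' contrast, and entropy.
#'
#' @inheritParams cooccurrence_matrix
#' @return named numeric vector of length 13.
#' @examples
#' f <- haralick_features(matrix(5, 10, 10))
#' f["har_energy"]; f["har_entropy"]  # 1 and 0 for a constant patch
#' @export
haralick_features <- function(patch, levels = 64, distance = 1) {
  P <- cooccurrence_matrix(patch, levels, distance)
  L <- nrow(P)
  i <- seq_len(L)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  II <- matrix(i, L, L); JJ <- t(II)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # distributions of i+j and |i-j|
  psum  <- vapply(2:(2 * L), function(k) sum(P[II + JJ == k]), numeric(1))
  ks    <- 2:(2 * L)
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(II - JJ) == k]), numeric(1))
  kd    <- 0:(L - 1)
  f6 <- sum(ks * psum)
  hxy  <- -sum(xlogx(P))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  dmean <- sum(kd * pdiff)
  out <- c(
    sum(P^2),
    sum((II - JJ)^2 * P),
    if (sx * sy > 0) (sum(II * JJ * P) - mux * muy) / (sx * sy) else 0,
    sum((i - mux)^2 * px),
    sum(P / (1 + (II - JJ)^2)),
    f6,
    sum((ks - f6)^2 * psum),
    -sum(xlogx(psum)),
    hxy,
    sum((kd - dmean)^2 * pdiff),
    -sum(xlogx(pdiff)),
    if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  )
  names(out) <- haralick_names
  out
}

#' Gabor filter bank specification
#'
#' A steerable bank parameterized by spatial frequency (cycles/pixel) and
#' orientation (radians). The default 5 frequencies x 8 orientations gives
#' the 40-filter bank.
#'
#' @param frequencies frequencies in (0, 0.5].
#' @param orientations orientations in radians.
#' @return object of class `gabor_bank`: data.frame with columns `name`,
#'   `frequency`, `orientation`.
#' @export
gabor_bank <- function(frequencies = c(0.05, 0.1, 0.2, 0.3, 0.4),
                       orientations = (0:7) * pi / 8) {
  if (!length(frequencies) || any(frequencies <= 0 | frequencies > 0.5))
    stop("frequencies must lie in (0, 0.5]", call. = FALSE)
  g <- expand.grid(oi = seq_along(orientations), frequency = frequencies)
  bank <- data.frame(
    name = sprintf("gabor_f%.3f_o%d", g$frequency, g$oi),
    frequency = g$frequency,
    orientation = orientations[g$oi])
  class(bank) <- c("gabor_bank", "data.frame")
  bank
}

# complex Gabor kernel, DC-free (mean subtracted) so constant inputs give 0.
# Envelope sd tied to wavelength (~1 octave bandwidth); support truncated at
# 3 sd and capped so the kernel fits inside the image.
gabor_kernel <- function(frequency, orientation, max_half = Inf) {
  sigma <- 0.56 / frequency
  h <- max(1L, min(ceiling(3 * sigma), floor(max_half)))
  xs <- -h:h
  X <- matrix(rep(xs, each = 2 * h + 1), 2 * h + 1)   # column offset
  Y <- matrix(rep(xs, 2 * h + 1), 2 * h + 1)          # row offset
  xr <- X * cos(orientation) + Y * sin(orientation)
  yr <- -X * sin(orientation) + Y * cos(orientation)
  k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * exp(2i * pi * frequency * xr)
  k <- k - mean(k)                 # DC-free: zero response to constants
  k / sqrt(sum(Mod(k)^2))          # unit energy: comparable across filters
}

gabor_response <- function(img, frequency, orientation) {
  half <- (min(dim(img)) - 1) / 2
  k <- gabor_kernel(frequency, orientation, max_half = half)
  re <- EBImage::filter2(img, Re(k), boundary = "replicate")
  im <- EBImage::filter2(img, Im(k), boundary = "replicate")
  sqrt(re^2 + im^2)
}

#' Gabor filter-bank features of a patch
#'
#' Mean magnitude of the zero-DC complex Gabor response, one value per
#' (frequency, orientation) filter in the bank.
#'
#' @param patch numeric matrix (grayscale) or RGB array.
#' @param bank a [gabor_bank()].
#' @return named numeric vector, one entry per filter.
#' @export
gabor_features <- function(patch, bank = gabor_bank()) {
  p <- check_patch(patch)
  stopifnot(inherits(bank, "gabor_bank"))
  out <- vapply(seq_len(nrow(bank)), function(i)
    mean(gabor_response(p, bank$frequency[i], bank$orientation[i])),
    numeric(1))
  names(out) <- bank$name
  out
}

#' Feature registry and default selection
#'
#' `feature_registry()` lists every implemented patch feature name (7
#' first-order + 13 Haralick + one per bank filter, 40 by default).
#' `default_feature_selection()` is the shipped 14-feature selection
#' standing in for the discriminative subset used for patch classification:
#' 2 first-order (std, range), 5 Haralick (information measure, correlation,
#' energy, contrast, entropy) and 7 Gabor filters.
#'
#' @param bank a [gabor_bank()].
#' @return character vector of feature names.
#' @export
feature_registry <- function(bank = gabor_bank()) {
  c("mean", "median", "std", "range", "sobel", "grad_x", "grad_y",
    haralick_names, bank$name)
}

#' @rdname feature_registry
#' @export
default_feature_selection <- function() {
  c("std", "range",
    "har_imc1", "har_correlation", "har_energy", "har_contrast",
    "har_entropy",
    "gabor_f0.100_o1", "gabor_f0.100_o5", "gabor_f0.200_o1",
    "gabor_f0.200_o3", "gabor_f0.200_o5", "gabor_f0.200_o7",
    "gabor_f0.400_o1")
}

first_order_names <- c("mean", "median", "std", "range", "sobel",
                       "grad_x", "grad_y")

#' Compute feature vectors for regions of an image
#'
#' First-order and Haralick features are computed on the region patch (one
#' window the size of the region); Gabor responses are computed by
#' convolution over the full image and averaged over the region's pixels.
#' Regions use 0-based top-left origin and half-open extents, so a region
#' `(x, y, size)` covers columns `x .. x+size-1` and rows `y .. y+size-1`.
#'
#' @param image numeric matrix (grayscale, values in any range) or RGB array.
#' @param regions data.frame with columns `x`, `y`, `size` (and optionally
#'   `label`), or a single numeric vector `c(x, y, size)`.
#' @param selection character vector of feature names (see
#'   [feature_registry()]); defaults to the 14-feature selection.
#' @param bank Gabor bank to draw any selected `gabor_*` features from.
#' @param levels,distance co-occurrence parameters for Haralick features.
#' @return matrix with one row per region and one named column per selected
#'   feature.
#' @export
featurize_regions <- function(image, regions,
                              selection = default_feature_selection(),
                              bank = gabor_bank(), levels = 64, distance = 1) {
  img <- as_gray(image)
  if (is.numeric(regions) && is.null(dim(regions)))
    regions <- data.frame(x = regions[1], y = regions[2], size = regions[3])
  stopifnot(all(c("x", "y", "size") %in% names(regions)))
  bad <- regions$x < 0 | regions$y < 0 |
    regions$x + regions$size > ncol(img) | regions$y + regions$size > nrow(img)
  if (any(bad))
    stop("region(s) out of image bounds: rows ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  unknown <- setdiff(selection, feature_registry(bank))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  need_fo  <- intersect(selection, first_order_names)
  need_har <- intersect(selection, haralick_names)
  need_gab <- intersect(selection, bank$name)

  gab_maps <- lapply(need_gab, function(nm) {
    i <- match(nm, bank$name)
    gabor_response(img, bank$frequency[i], bank$orientation[i])
  })
  names(gab_maps) <- need_gab

  out <- matrix(NA_real_, nrow(regions), length(selection),
                dimnames = list(NULL, selection))
  for (r in seq_len(nrow(regions))) {
    rows <- regions$y[r] + seq_len(regions$size[r])
    cols <- regions$x[r] + seq_len(regions$size[r])
    patch <- img[rows, cols, drop = FALSE]
    if (length(need_fo))
      out[r, need_fo] <- first_order_features(patch)[need_fo]
    if (length(need_har))
      out[r, need_har] <- haralick_features(patch, levels, distance)[need_har]
    for (nm in need_gab)
      out[r, nm] <- mean(gab_maps[[nm]][rows, cols])
  }
  out
}

#' @rdname featurize_regions
#' @param region a single region, `c(x, y, size)` or one-row data.frame.
#' @return `patch_feature_vector` returns one named numeric vector.
#' @export
patch_feature_vector <- function(image, region,
                                 selection = default_feature_selection(),
                                 bank = gabor_bank(), levels = 64,
                                 distance = 1) {
  drop(featurize_regions(image, region, selection, bank, levels, distance)[1, ])
}

#' Build a feature pool from a texture dataset on disk or in memory
#'
#' Applies [featurize_regions()] to every region of a texture dataset and
#' returns a `sample_pool` whose hidden labels come from the region table.
#'
#' @param dataset result of [make_texture_dataset()], or a directory written
#'   by [write_texture_dataset()].
#' @inheritParams featurize_regions
#' @return a `sample_pool`.
#' @export
featurize_dataset <- function(dataset,
                              selection = default_feature_selection(),
                              bank = gabor_bank(), levels = 64,
                              distance = 1) {
  if (is.character(dataset)) {
    regions <- utils::read.csv(file.path(dataset, "regions.csv"))
    images <- lapply(unique(regions$image_id), function(id)
      png::readPNG(file.path(dataset, paste0(id, ".png"))))
    names(images) <- unique(regions$image_id)
    dataset <- list(images = images, regions = regions,
                    labels = regions$label)
  }
  regions <- dataset$regions
  idx <- unlist(lapply(names(dataset$images), function(id)
    which(regions$image_id == id)))
  feats <- do.call(rbind, lapply(names(dataset$images), function(id) {
    sub <- regions[regions$image_id == id, , drop = FALSE]
    featurize_regions(dataset$images[[id]], sub, selection, bank, levels,
                      distance)
  }))
  regions <- regions[idx, , drop = FALSE]
  new_pool(sprintf("r%05d", seq_len(nrow(regions))), feats, regions$label)
}
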