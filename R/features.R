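# The 12-feature morpho-textural-phase descriptor computed from each
# segmented phase crop: 3 morphological features from the binary mask,
# 5 texture features from the grey-level co-occurrence matrix (GLCM)
# and the in-mask value distribution, and 4 quantitative-phase
# statistics measured directly on the phase map.

#' Feature column names, in canonical order
#'
#' @return character vector of the 12 feature names.
#' @export
feature_names <- function() {
  c("area_px", "eccentricity", "perimeter_px",
    "homogeneity", "energy", "kurtosis", "skewness", "entropy",
    "phase_max", "phase_min", "phase_mean", "phase_std")
}

#' Feature-group membership
#'
#' @return named list mapping group (`morphological`, `texture`, `QPI`)
#'   to feature names.
#' @export
feature_groups <- function() {
  list(
    morphological = c("area_px", "eccentricity", "perimeter_px"),
    texture = c("homogeneity", "energy", "kurtosis", "skewness", "entropy"),
    QPI = c("phase_max", "phase_min", "phase_mean", "phase_std")
  )
}

#' Morphological features of a binary mask
#'
#' Area is the foreground pixel count. Eccentricity comes from the
#' second-central-moment equivalent ellipse,
#' `sqrt(1 - (minor/major)^2)`, in `[0, 1)`. Perimeter is the length of
#' the 8-connected outer boundary contour polygon through the boundary
#' pixel centres (axial steps count 1, diagonal steps `sqrt(2)`); for a
#' `k x k` filled square this convention gives `4 (k - 1)`.
#'
#' @param mask logical (or 0/1) matrix with exactly one connected
#'   foreground component.
#' @return named numeric: `area_px`, `eccentricity`, `perimeter_px`.
#' @export
morph_features <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu_yy <- mean((y - mean(y))^2) + 1 / 12
  mu_xx <- mean((x - mean(x))^2) + 1 / 12
  mu_xy <- mean((y - mean(y)) * (x - mean(x)))
  # eigenvalues of the covariance matrix -> equivalent-ellipse axes
  tr <- mu_xx + mu_yy
  dt <- sqrt((mu_xx - mu_yy)^2 + 4 * mu_xy^2)
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  ecc <- sqrt(pmax(0, 1 - l2 / l1))
  per <- EBImage::computeFeatures.shape(
    EBImage::bwlabel(EBImage::Image(mask * 1)))[1, "s.perimeter"]
  c(area_px = area, eccentricity = unname(ecc), perimeter_px = unname(per))
}

#' Grey-level co-occurrence matrix of in-mask values
#'
#' Quantises the in-mask values linearly into `n_levels` bins over the
#' in-mask min-max range, counts ordered pairs of levels for each pixel
#' offset, keeps only pairs with both pixels inside the mask,
#' symmetrises, and normalises to sum 1. A constant in-mask region
#' yields the single-entry matrix `P[1, 1] = 1`.
#'
#' @param values numeric matrix.
#' @param mask logical matrix, same size.
#' @param n_levels number of grey levels (>= 2).
#' @param offsets list of integer `c(dy, dx)` neighbour offsets;
#'   default horizontal distance-1.
#' @return `n_levels x n_levels` matrix summing to 1.
#' @export
glcm <- function(values, mask = NULL, n_levels = 8,
                 offsets = list(c(0, 1))) {
  stopifnot(is.matrix(values), n_levels >= 2)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  v <- values[mask]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev <- matrix(1L, nrow(values), ncol(values))
  } else {
    lev <- matrix(pmin(n_levels, 1L + floor(
      (values - rng[1]) / (rng[2] - rng[1]) * n_levels)),
      nrow(values), ncol(values))
  }
  P <- matrix(0, n_levels, n_levels)
  ny <- nrow(values); nx <- ncol(values)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    ys <- seq_len(ny); xs <- seq_len(nx)
    y1 <- ys[ys + dy >= 1 & ys + dy <= ny]
    x1 <- xs[xs + dx >= 1 & xs + dx <= nx]
    ok <- mask[y1, x1, drop = FALSE] &
      mask[y1 + dy, x1 + dx, drop = FALSE]
    a <- lev[y1, x1, drop = FALSE][ok]
    b <- lev[y1 + dy, x1 + dx, drop = FALSE][ok]
    if (length(a))
      P <- P + stats::xtabs(~factor(a, 1:n_levels) + factor(b, 1:n_levels))
  }
  P <- P + t(P)  # symmetrise
  s <- sum(P)
  if (s == 0) stop("no valid pixel pairs inside the mask")
  matrix(as.numeric(P / s), n_levels, n_levels)
}

#' Texture features from a GLCM and the in-mask values
#'
#' GLCM statistics: homogeneity `sum P/(1+|i-j|)`, energy `sum P^2`,
#' entropy `-sum P log2 P` (bits, `0 log 0 = 0`). Distribution
#' statistics of the in-mask values: skewness (standardised third
#' central moment) and kurtosis (standardised fourth central moment,
#' non-excess: a Gaussian gives 3). A zero-variance distribution gets
#' skewness and kurtosis 0 with a `zero_variance` attribute flag.
#'
#' @param P normalised GLCM from [glcm()].
#' @param in_mask_values numeric vector of the in-mask values (>= 4).
#' @return named numeric: `homogeneity`, `energy`, `kurtosis`,
#'   `skewness`, `entropy`.
#' @export
texture_features <- function(P, in_mask_values) {
  stopifnot(abs(sum(P) - 1) < 1e-8, length(in_mask_values) >= 4)
  i <- row(P); j <- col(P)
  hom <- sum(P / (1 + abs(i - j)))
  ene <- sum(P^2)
  ent <- -sum(ifelse(P > 0, P * log2(P), 0))
  v <- in_mask_values
  m <- mean(v); s2 <- mean((v - m)^2)
  zero_var <- s2 == 0
  skew <- if (zero_var) 0 else mean((v - m)^3) / s2^1.5
  kurt <- if (zero_var) 0 else mean((v - m)^4) / s2^2
  out <- c(homogeneity = hom, energy = ene, kurtosis = kurt,
           skewness = skew, entropy = ent)
  attr(out, "zero_variance") <- zero_var
  out
}

#' Quantitative-phase statistics over the mask
#'
#' Maximum, minimum, mean and (population) standard deviation of the
#' phase values inside the mask, radians.
#'
#' @param qpm phase matrix (radians).
#' @param mask logical matrix, same size, non-empty.
#' @return named numeric: `phase_max`, `phase_min`, `phase_mean`,
#'   `phase_std`.
#' @export
qpi_features <- function(qpm, mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  v <- qpm[mask]
  c(phase_max = max(v), phase_min = min(v), phase_mean = mean(v),
    phase_std = sqrt(mean((v - mean(v))^2)))
}

#' Extract the full 12-feature descriptor from a cell crop
#'
#' @param crop a `cell_crop` from [segment_crop()] (or any list with
#'   `qpm` and `mask` matrices).
#' @param n_levels,offsets GLCM parameters, see [glcm()].
#' @param texture_on `"values"` (default) computes skewness/kurtosis on
#'   the in-mask phase distribution and entropy on the GLCM;
#'   `"glcm"` computes all five texture statistics from the GLCM
#'   (skewness/kurtosis of the co-occurrence distribution).
#' @return named numeric vector of length 12 in [feature_names()]
#'   order.
#' @export
extract_features <- function(crop, n_levels = 8, offsets = list(c(0, 1)),
                             texture_on = c("values", "glcm")) {
  texture_on <- match.arg(texture_on)
  stopifnot(is.matrix(crop$qpm), is.matrix(crop$mask))
  mo <- morph_features(crop$mask)
  P <- glcm(crop$qpm, crop$mask, n_levels = n_levels, offsets = offsets)
  if (texture_on == "values") {
    tx <- texture_features(P, crop$qpm[crop$mask > 0])
  } else {
    # moments of the GLCM marginal level distribution
    pm <- rowSums(P)
    lv <- seq_along(pm)
    m <- sum(lv * pm); s2 <- sum((lv - m)^2 * pm)
    skew <- if (s2 == 0) 0 else sum((lv - m)^3 * pm) / s2^1.5
    kurt <- if (s2 == 0) 0 else sum((lv - m)^4 * pm) / s2^2
    i <- row(P); j <- col(P)
    tx <- c(homogeneity = sum(P / (1 + abs(i - j))), energy = sum(P^2),
            kurtosis = kurt, skewness = skew,
            entropy = -sum(ifelse(P > 0, P * log2(P), 0)))
  }
  qp <- qpi_features(crop$qpm, crop$mask)
  out <- c(mo, tx, qp)[feature_names()]
  stopifnot(all(is.finite(out)))
  out
}

#' Build a feature table from a list of cell crops
#'
#' @param crops list of `cell_crop` objects.
#' @param ... passed to [extract_features()].
#' @return data frame of class `feature_table`: columns `cell_id`,
#'   `frame_id`, `class_label`, then the 12 features in canonical
#'   order.
#' @export
feature_table <- function(crops, ...) {
  stopifnot(length(crops) >= 1)
  feats <- t(vapply(crops, extract_features, numeric(12), ...))
  df <- data.frame(
    cell_id = vapply(crops, function(cr) as.integer(cr$cell_id %||% NA), 1L),
    frame_id = vapply(crops, function(cr) as.integer(cr$frame_id %||% NA), 1L),
    class_label = vapply(crops, function(cr) as.character(cr$label %||% NA), ""),
    feats, stringsAsFactors = FALSE
  )
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Numeric feature matrix of a feature table
#'
#' @param table a `feature_table` (or data frame with the 12 feature
#'   columns).
#' @param features which feature columns to keep.
#' @return numeric matrix.
#' @export
feature_matrix <- function(table, features = feature_names()) {
  as.matrix(as.data.frame(table)[, features, drop = FALSE])
}
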