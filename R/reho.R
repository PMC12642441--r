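#' Kendall's coefficient of concordance
#'
#' Concordance W across m time series over T time points, with mid-ranks
#' for ties and the standard tie correction:
#' \deqn{W = \frac{12 \sum_t (R_t - \bar R)^2}{m^2 (T^3 - T) - m \sum_i C_i}}
#' where \eqn{R_t} is the across-series rank sum at time t and
#' \eqn{C_i = \sum_g (t_g^3 - t_g)} over tied groups of series i.
#'
#' @param block m x T numeric matrix; rows are series, columns time points.
#' @return W in [0, 1]; NA if the tie-corrected denominator is not positive
#'   (e.g. all series constant).
#' @export
kendalls_w <- function(block) {
  block <- as.matrix(block)
  m <- nrow(block); Tn <- ncol(block)
  if (m < 2L) stop("need at least 2 series")
  if (Tn < 3L) stop("length error: need at least 3 time points")
  if (any(!is.finite(block))) stop("series must be finite")
  ranks <- t(apply(block, 1, rank))
  Ct <- vapply(seq_len(m), function(i) {
    x <- block[i, ]
    if (anyDuplicated(x) == 0L) return(0)
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  }, numeric(1))
  Rt <- colSums(ranks)
  S <- sum((Rt - m * (Tn + 1) / 2)^2)
  denom <- m^2 * (Tn^3 - Tn) - m * sum(Ct)
  if (denom <= 0) return(NA_real_)
  min(12 * S / denom, 1)
}

# neighbor offsets for the 7 (face), 19 (face+edge) and 27 (full cube)
# stencils; includes the center voxel
stencil_offsets <- function(cluster_size) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  switch(as.character(cluster_size),
         "7"  = g[d <= 1, , drop = FALSE],
         "19" = g[d <= 2, , drop = FALSE],
         "27" = g,
         stop("cluster_size must be one of 7, 19, 27"))
}

#' Regional homogeneity map
#'
#' Computes Kendall's W over each in-mask voxel and its in-mask neighbors
#' within the chosen stencil. Boundary voxels use their shrunken in-mask
#' neighborhood; voxels with fewer than \code{min_neighbors} in-mask
#' neighbors are set to missing.
#'
#' @param image 4D \code{\link{voxel_image}}.
#' @param cluster_size neighborhood size: 7 (faces), 19 (faces+edges) or
#'   27 (full 3x3x3 cube).
#' @param min_neighbors minimum in-mask neighbors (excluding the center)
#'   required to score a voxel; default 4.
#' @return A \code{reho_map} (stage "raw"): W in [0,1] inside the mask,
#'   NaN outside or where the neighborhood is too small.
#' @export
compute_reho <- function(image, cluster_size = 27, min_neighbors = 4) {
  stopifnot(inherits(image, "voxel_image"))
  dims <- dim(image$data)
  if (length(dims) != 4L) stop("dimension error: a 4D image is required")
  Tn <- dims[4]
  if (Tn < 3L) stop("length error: need at least 3 time points")
  mask <- image$mask
  if (!any(mask)) stop("mask is empty")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  # per-voxel time ranks and tie corrections (zero outside mask)
  nvox <- nx * ny * nz
  mat <- matrix(image$data, nrow = nvox, ncol = Tn)
  midx <- which(mask)
  ranks_flat <- matrix(0, nrow = nvox, ncol = Tn)
  ranks_flat[midx, ] <- t(apply(mat[midx, , drop = FALSE], 1, rank))
  Cvox <- numeric(nvox)
  for (i in midx) {
    x <- mat[i, ]
    if (anyDuplicated(x)) {
      tt <- tabulate(match(x, unique(x)))
      Cvox[i] <- sum(tt^3 - tt)
    }
  }
  Rk <- array(ranks_flat, dim = dims)
  Cv <- array(Cvox, dim = dims[1:3])
  Mnum <- array(as.numeric(mask), dim = dims[1:3])

  RS <- array(0, dim = dims)       # neighborhood rank sums per time point
  Msum <- array(0, dim = dims[1:3]) # in-mask member count
  Csum <- array(0, dim = dims[1:3]) # summed tie corrections
  for (o in seq_len(nrow(off <- stencil_offsets(cluster_size)))) {
    dx <- off[o, 1]; dy <- off[o, 2]; dz <- off[o, 3]
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    zs <- max(1, 1 - dz):min(nz, nz - dz)
    RS[xs, ys, zs, ] <- RS[xs, ys, zs, , drop = FALSE] +
      Rk[xs + dx, ys + dy, zs + dz, , drop = FALSE]
    Msum[xs, ys, zs] <- Msum[xs, ys, zs] + Mnum[xs + dx, ys + dy, zs + dz]
    Csum[xs, ys, zs] <- Csum[xs, ys, zs] + Cv[xs + dx, ys + dy, zs + dz]
  }

  m <- Msum
  Rbar <- m * (Tn + 1) / 2
  S <- apply(sweep(RS, 1:3, Rbar, "-")^2, 1:3, sum)
  denom <- m^2 * (Tn^3 - Tn) - m * Csum
  W <- array(NaN, dim = dims[1:3])
  ok <- mask & (m >= (min_neighbors + 1)) & denom > 0
  W[ok] <- pmin(12 * S[ok] / denom[ok], 1)
  reho_map(W, mask, stage = "raw")
}

#' ReHo map container
#'
#' @param values 3D array; NaN outside the mask.
#' @param mask logical 3D array.
#' @param stage one of "raw", "zscored", "smoothed".
#' @return An object of class \code{reho_map}.
#' @export
reho_map <- function(values, mask, stage = c("raw", "zscored", "smoothed")) {
  stage <- match.arg(stage)
  values <- as.array(values)
  if (!identical(dim(values), dim(mask))) stop("alignment error: values/mask shapes differ")
  values[!mask] <- NaN
  structure(list(values = values, mask = mask, stage = stage), class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  v <- x$values[x$mask & is.finite(x$values)]
  cat("<reho_map> stage=", x$stage, ", ", sum(x$mask), " in-mask voxels, ",
      "mean=", format(mean(v), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Standardize a map to zero mean and unit SD inside the mask
#'
#' @param map a \code{reho_map}.
#' @return A \code{reho_map} with stage "zscored"; in-mask mean 0 and SD 1
#'   (n-1 denominator).
#' @export
zscore_map <- function(map) {
  stopifnot(inherits(map, "reho_map"))
  v <- map$values
  idx <- map$mask & is.finite(v)
  x <- v[idx]
  if (length(x) < 2L || stats::sd(x) == 0)
    stop("value error: need >= 2 in-mask values with nonzero variance")
  v[idx] <- (x - mean(x)) / stats::sd(x)
  reho_map(v, map$mask, stage = "zscored")
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# shift-and-add separable convolution of a 3D array along one axis
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  out <- array(0, dim = d)
  r <- (length(kernel) - 1L) / 2L
  for (j in seq_along(kernel)) {
    s <- j - r - 1L  # offset
    src <- list(1:d[1], 1:d[2], 1:d[3])
    dst <- src
    n <- d[axis]
    dst[[axis]] <- max(1, 1 - s):min(n, n - s)
    src[[axis]] <- dst[[axis]] + s
    out[dst[[1]], dst[[2]], dst[[3]]] <- out[dst[[1]], dst[[2]], dst[[3]]] +
      kernel[j] * arr[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Gaussian smoothing of a map, mask-aware
#'
#' Separable Gaussian smoothing with sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis in voxel units, truncated at 4 sigma. Smoothing is normalized by
#' the smoothed mask so out-of-mask voxels neither bleed in nor attenuate
#' edge values.
#'
#' @param map a \code{reho_map}.
#' @param fwhm_mm kernel full width at half maximum, in mm.
#' @param voxel_size mm per axis (length 3).
#' @return A \code{reho_map} with stage "smoothed".
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(map, "reho_map"))
  if (fwhm_mm < 0) stop("value error: fwhm must be >= 0")
  if (fwhm_mm == 0) return(reho_map(map$values, map$mask, stage = "smoothed"))
  valid <- map$mask & is.finite(map$values)
  num <- map$values
  num[!valid] <- 0
  den <- array(as.numeric(valid), dim = dim(valid))
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size[axis]
    if (sigma <= 0) next
    k <- gaussian_kernel_1d(sigma)
    if (length(k) == 1L) next
    num <- convolve_axis(num, k, axis)
    den <- convolve_axis(den, k, axis)
  }
  out <- array(NaN, dim = dim(num))
  ok <- valid & den > 0
  out[ok] <- num[ok] / den[ok]
  reho_map(out, map$mask, stage = "smoothed")
}

#' Average a map within parcels
#'
#' @param map a \code{reho_map} (any stage).
#' @param parc a \code{\link{parcellation}} aligned with the map.
#' @return Named numeric vector of per-parcel means over in-mask,
#'   non-missing voxels; NA for parcels with no valid voxel.
#' @export
parcel_average <- function(map, parc) {
  stopifnot(inherits(map, "reho_map"), inherits(parc, "parcellation"))
  if (!identical(dim(map$values), dim(parc$labels)))
    stop("alignment error: map and parcellation shapes differ")
  valid <- map$mask & is.finite(map$values) & parc$labels > 0
  means <- tapply(map$values[valid], parc$labels[valid], mean)
  out <- stats::setNames(rep(NA_real_, length(parc$ids)), parc$names[as.character(parc$ids)])
  hit <- match(as.integer(names(means)), parc$ids)
  out[hit] <- as.numeric(means)
  out
}
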