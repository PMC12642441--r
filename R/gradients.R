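#' Parcel-by-time series container
#'
#' @param mat parcel x time numeric matrix.
#' @param ids parcel identifiers (default rownames or 1..P).
#' @param condition optional condition tag.
#' @return An object of class \code{parcel_series}.
#' @export
parcel_series <- function(mat, ids = NULL, condition = NA_character_) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 time points")
  if (is.null(ids)) ids <- if (!is.null(rownames(mat))) rownames(mat) else as.character(seq_len(nrow(mat)))
  dropped <- which(apply(mat, 1, function(r) any(!is.finite(r))))
  if (length(dropped)) {
    warning("dropping ", length(dropped), " parcels with missing data: ",
            paste(ids[dropped], collapse = ", "))
    mat <- mat[-dropped, , drop = FALSE]
    ids <- ids[-dropped]
  }
  structure(list(mat = mat, ids = ids, condition = condition,
                 dropped = if (length(dropped)) ids else character(0)),
            class = "parcel_series")
}

#' Functional connectivity matrix
#'
#' Pearson correlation between all pairs of parcel time series.
#'
#' @param series a \code{parcel_series} or parcel x time matrix.
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   parcels are dropped with a warning (their ids recorded in attribute
#'   \code{"dropped"}).
#' @export
functional_connectivity <- function(series) {
  if (inherits(series, "parcel_series")) {
    mat <- series$mat; ids <- series$ids
  } else {
    mat <- as.matrix(series)
    ids <- if (!is.null(rownames(mat))) rownames(mat) else as.character(seq_len(nrow(mat)))
  }
  v <- apply(mat, 1, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad)) {
    warning("dropping zero-variance parcels: ", paste(ids[bad], collapse = ", "))
    mat <- mat[-bad, , drop = FALSE]
    ids <- ids[-bad]
  }
  C <- stats::cor(t(mat))
  dimnames(C) <- list(ids, ids)
  attr(C, "dropped") <- if (length(bad)) ids[bad] else character(0)
  C
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Per row, retains the top (1 - sparsity) fraction of off-diagonal
#' entries by value (ties at the cutoff all kept), zeroes everything else
#' including negatives among the kept entries, and zeroes the diagonal.
#'
#' @param mat square numeric matrix.
#' @param sparsity fraction of off-diagonal entries to discard per row,
#'   in [0, 1); default 0.90.
#' @return Nonnegative row-sparsified matrix (not necessarily symmetric).
#' @export
sparsify <- function(mat, sparsity = 0.90) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n != ncol(mat)) stop("matrix must be square")
  if (sparsity < 0 || sparsity >= 1) stop("value error: sparsity must be in [0, 1)")
  keep_n <- ceiling((1 - sparsity) * (n - 1))
  out <- matrix(0, n, n, dimnames = dimnames(mat))
  for (i in seq_len(n)) {
    row <- mat[i, ]
    row[i] <- -Inf
    thr <- sort(row, decreasing = TRUE)[keep_n]
    kept <- row >= thr
    vals <- pmax(row, 0)
    out[i, kept] <- vals[kept]
  }
  if (all(out == 0)) warning("all retained entries were negative; sparsified matrix is zero")
  out
}

#' Cosine-similarity affinity between connectivity profiles
#'
#' @param mat nonnegative (row-sparsified) connectivity matrix; rows are
#'   connectivity profiles.
#' @return Symmetric affinity matrix in [0, 1] (negative cosines clipped
#'   to 0) with unit diagonal. All-zero rows are an error if universal,
#'   otherwise dropped with a warning.
#' @export
cosine_affinity <- function(mat) {
  mat <- as.matrix(mat)
  nrm <- sqrt(rowSums(mat^2))
  if (all(nrm == 0)) stop("degenerate input: all rows are zero")
  zero <- which(nrm == 0)
  if (length(zero)) {
    warning("dropping all-zero rows: ", paste(zero, collapse = ", "))
    mat <- mat[-zero, -zero, drop = FALSE]
    nrm <- nrm[-zero]
  }
  A <- tcrossprod(mat / nrm)
  A <- pmax(A, 0)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization \eqn{W' = D^{-\alpha} W D^{-\alpha}}, Markov
#' normalization \eqn{P = D'^{-1} W'}, eigendecomposition of P (via the
#' symmetric conjugate), removal of the trivial constant eigenvector, and
#' coordinate scaling by \eqn{\lambda / (1 - \lambda)} (diffusion_time 0)
#' or \eqn{\lambda^t} otherwise.
#'
#' @param affinity symmetric nonnegative matrix, connected as a graph.
#' @param n_components number of embedding components to return.
#' @param alpha anisotropic diffusion exponent (default 0.5).
#' @param diffusion_time diffusion time t; 0 selects the
#'   \eqn{\lambda/(1-\lambda)} convention.
#' @return A \code{gradient_set} (alignment "unaligned") with components
#'   ordered by descending eigenvalue. Near-equal leading eigenvalues are
#'   flagged degenerate in attribute \code{"degenerate"}.
#' @export
diffusion_map_embed <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0) {
  A <- as.matrix(affinity)
  n <- nrow(A)
  if (n != ncol(A)) stop("affinity must be square")
  if (max(abs(A - t(A))) > 1e-10) stop("affinity must be symmetric")
  if (min(A) < 0) stop("affinity must be nonnegative")
  comp <- graph_components(A)
  if (max(comp) > 1L)
    stop("component error: affinity graph is disconnected (blocks: ",
         paste(tabulate(comp), collapse = ", "), ")")
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dp <- rowSums(W)
  # symmetric conjugate of the Markov matrix
  S <- W / outer(sqrt(dp), sqrt(dp))
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  vec <- e$vectors / sqrt(dp)   # eigenvectors of P = D'^-1 W'
  # drop the trivial stationary eigenvector (lambda ~ 1, constant)
  keep <- 2:min(n, n_components + 1L)
  lam_k <- lam[keep]
  vec_k <- vec[, keep, drop = FALSE]
  # normalize eigenvectors to unit norm, fix sign (largest-|.| entry positive)
  for (j in seq_len(ncol(vec_k))) {
    vec_k[, j] <- vec_k[, j] / sqrt(sum(vec_k[, j]^2))
    i0 <- which.max(abs(vec_k[, j]))
    if (vec_k[i0, j] < 0) vec_k[, j] <- -vec_k[, j]
  }
  scale_f <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  coords <- sweep(vec_k, 2, scale_f, "*")
  rownames(coords) <- rownames(A)
  degenerate <- any(abs(diff(lam_k)) < 1e-10)
  gs <- gradient_set(coords, lam_k, alignment = "unaligned")
  attr(gs, "degenerate") <- degenerate
  gs
}

#' Gradient set container
#'
#' @param coordinates parcel x component matrix.
#' @param eigenvalues per-component eigenvalues (descending).
#' @param alignment "unaligned" or "aligned".
#' @param template_id optional identifier of the alignment template.
#' @return An object of class \code{gradient_set}.
#' @export
gradient_set <- function(coordinates, eigenvalues,
                         alignment = c("unaligned", "aligned"),
                         template_id = NA_character_) {
  alignment <- match.arg(alignment)
  coordinates <- as.matrix(coordinates)
  if (length(eigenvalues) != ncol(coordinates))
    stop("one eigenvalue per component required")
  if (is.unsorted(rev(eigenvalues), strictly = FALSE) && any(diff(eigenvalues) > 1e-12))
    stop("components must be ordered by descending eigenvalue")
  structure(list(coordinates = coordinates, eigenvalues = as.numeric(eigenvalues),
                 alignment = alignment, template_id = template_id),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("<gradient_set> ", nrow(x$coordinates), " parcels x ",
      ncol(x$coordinates), " components (", x$alignment, ")\n", sep = "")
  invisible(x)
}

#' Template gradient from a set of connectivity matrices
#'
#' Averages the matrices element-wise, then applies the standard pipeline
#' (sparsify, cosine affinity, diffusion map embedding).
#'
#' @param matrices list of equal-dimension connectivity matrices.
#' @param n_components components to embed.
#' @param sparsity,alpha,diffusion_time pipeline parameters.
#' @return A \code{gradient_set} serving as alignment template.
#' @export
compute_template <- function(matrices, n_components = 10, sparsity = 0.90,
                             alpha = 0.5, diffusion_time = 0) {
  if (!length(matrices)) stop("need at least one matrix")
  dims <- lapply(matrices, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("alignment error: matrices have mismatched dimensions")
  M <- Reduce(`+`, matrices) / length(matrices)
  g <- diffusion_map_embed(cosine_affinity(sparsify(M, sparsity)),
                           n_components, alpha, diffusion_time)
  g$template_id <- "template"
  g
}

#' Procrustes alignment of a gradient set to a template
#'
#' Orthogonal (rotation/reflection, no scaling) Procrustes transform of
#' the column-centered source coordinates minimizing Frobenius distance
#' to the template, re-estimated \code{n_iter} times against the
#' reference.
#'
#' @param source,template \code{gradient_set}s with equal parcel and
#'   component counts.
#' @param n_iter number of re-estimation passes (default 10).
#' @return Aligned \code{gradient_set}; the final Frobenius disparity is
#'   in attribute \code{"disparity"}.
#' @export
procrustes_align <- function(source, template, n_iter = 10) {
  X <- source$coordinates
  Yt <- template$coordinates
  if (!all(dim(X) == dim(Yt))) stop("source and template dimensions must match")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Yt, center = TRUE, scale = FALSE)
  aligned <- Xc
  for (i in seq_len(n_iter)) {
    sv <- svd(crossprod(aligned, Yc))
    if (min(sv$d) < 1e-12 * max(sv$d))
      warning("rank-deficient source; returning best-fit alignment")
    Q <- sv$u %*% t(sv$v)
    aligned <- aligned %*% Q
  }
  disparity <- sqrt(sum((aligned - Yc)^2))
  out <- gradient_set(aligned, source$eigenvalues, alignment = "aligned",
                      template_id = template$template_id)
  attr(out, "disparity") <- disparity
  out
}

#' Network-averaged gradient coordinates
#'
#' @param g a \code{gradient_set}.
#' @param networks vector of network labels, one per parcel.
#' @return network x component matrix of mean coordinates.
#' @export
network_average <- function(g, networks) {
  if (length(networks) != nrow(g$coordinates))
    stop("labels must cover all parcels")
  nets <- sort(unique(networks))
  out <- t(vapply(nets, function(nw)
    colMeans(g$coordinates[networks == nw, , drop = FALSE]),
    numeric(ncol(g$coordinates))))
  rownames(out) <- as.character(nets)
  out
}

#' Dispersion of one gradient component
#'
#' Range (max - min) and SD of a component across parcels; quantifies
#' compression/flattening of the hierarchy spanned by that gradient.
#'
#' @param g a \code{gradient_set}.
#' @param component component index (default 1, the principal gradient).
#' @return list(range =, sd =).
#' @export
gradient_dispersion <- function(g, component = 1) {
  x <- g$coordinates[, component]
  list(range = max(x) - min(x), sd = stats::sd(x))
}
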