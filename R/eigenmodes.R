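#' Laplace-Beltrami operator matrices for a triangle mesh
#'
#' Cotangent-weight stiffness matrix (symmetric positive semidefinite,
#' zero row sums) and lumped (diagonal) mass matrix whose total mass
#' equals the surface area (one third of incident face area per vertex).
#'
#' @param mesh a \code{\link{triangle_mesh}}.
#' @return list(stiffness = sparse V x V, mass = sparse diagonal V x V).
#' @export
assemble_lbo <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  areas <- face_areas(mesh)
  if (any(areas <= 1e-14))
    stop("mesh error: degenerate triangle at face ", which(areas <= 1e-14)[1])
  nV <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  # cotangent of the angle at vertex `a` opposite edge (b, c)
  for (corner in 1:3) {
    a <- f[, corner]
    b <- f[, corner %% 3 + 1]
    c_ <- f[, (corner + 1) %% 3 + 1]
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c_, , drop = FALSE] - v[a, , drop = FALSE]
    dotp <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    crs <- sqrt(cx^2 + cy^2 + cz^2)
    cot <- dotp / crs
    ii <- c(ii, b, c_); jj <- c(jj, c_, b); ww <- c(ww, cot / 2, cot / 2)
  }
  Wm <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nV, nV))
  S <- Matrix::Diagonal(x = Matrix::rowSums(Wm)) - Wm
  S <- (S + Matrix::t(S)) / 2
  mvec <- numeric(nV)
  for (corner in 1:3)
    mvec <- mvec + unname(tapply(areas / 3, factor(f[, corner], levels = seq_len(nV)), sum, default = 0))
  mvec[is.na(mvec)] <- 0
  list(stiffness = S, mass = Matrix::Diagonal(x = mvec))
}

#' Solve for the geometric eigenmode basis
#'
#' Smallest-K generalized eigenpairs of (stiffness, mass), returned in
#' ascending eigenvalue order with mass-orthonormal modes and a
#' deterministic sign convention (first entry of magnitude > 1e-10
#' positive).
#'
#' @param stiffness,mass matrices from \code{\link{assemble_lbo}}.
#' @param K number of modes (K < V); default 200.
#' @param mesh_id optional identifier recorded on the basis.
#' @return An \code{eigenmode_basis}: eigenvalues, modes (V x K), mass.
#' @export
solve_eigenmodes <- function(stiffness, mass, K = 200, mesh_id = NA_character_) {
  mvec <- Matrix::diag(mass)
  nV <- length(mvec)
  if (K > nV) stop("K cannot exceed the vertex count")
  s <- 1 / sqrt(mvec)
  B <- as.matrix(stiffness) * outer(s, s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  if (any(!is.finite(e$values))) stop("numerical error: eigensolve failed")
  idx <- order(e$values)[seq_len(K)]
  lam <- pmax(e$values[idx], 0)
  modes <- e$vectors[, idx, drop = FALSE] * s
  for (j in seq_len(K)) {
    nz <- which(abs(modes[, j]) > 1e-10)[1]
    if (!is.na(nz) && modes[nz, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(eigenvalues = lam, modes = modes, mass = mass,
                 mesh_id = mesh_id),
            class = "eigenmode_basis")
}

#' @export
print.eigenmode_basis <- function(x, ...) {
  cat("<eigenmode_basis> ", length(x$eigenvalues), " modes on ",
      nrow(x$modes), " vertices; lambda in [",
      format(min(x$eigenvalues), digits = 3), ", ",
      format(max(x$eigenvalues), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Project vertex time series onto an eigenmode basis
#'
#' With mass-orthonormal modes the mass-weighted least-squares solution
#' is the closed form \eqn{\omega = \psi^T M y}. With a vertex mask (or
#' the pseudoinverse method) a general least-squares problem restricted
#' to the included vertices is solved instead.
#'
#' @param data V x T matrix of vertex time series.
#' @param basis an \code{eigenmode_basis}.
#' @param vertex_mask optional logical vector of vertices to include.
#' @param method "mass" (default, mass-weighted inner product) or
#'   "pseudoinverse" (plain least squares).
#' @return A \code{spectral_activation} with coefficients K x T.
#' @export
project_timeseries <- function(data, basis, vertex_mask = NULL,
                               method = c("mass", "pseudoinverse")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (nrow(data) != nrow(basis$modes))
    stop("alignment error: data has ", nrow(data), " vertices, basis ",
         nrow(basis$modes))
  if (any(!is.finite(data))) stop("data must be finite")
  if (is.null(vertex_mask) && method == "mass") {
    mvec <- Matrix::diag(basis$mass)
    omega <- crossprod(basis$modes, data * mvec)
  } else {
    keep <- if (is.null(vertex_mask)) rep(TRUE, nrow(data)) else vertex_mask
    A <- basis$modes[keep, , drop = FALSE]
    if (method == "mass") {
      w <- sqrt(Matrix::diag(basis$mass)[keep])
      omega <- qr.coef(qr(A * w), data[keep, , drop = FALSE] * w)
    } else {
      omega <- qr.coef(qr(A), data[keep, , drop = FALSE])
    }
  }
  structure(list(coefficients = unname(as.matrix(omega))),
            class = "spectral_activation")
}

#' Power and energy spectra of eigenmode activations
#'
#' Power is the activation strength |omega_k(t)|; energy is the
#' eigenvalue-weighted square |omega_k(t)|^2 lambda_k^2. Totals sum each
#' over modes per time point.
#'
#' @param activation a \code{spectral_activation} with coefficients.
#' @param basis the \code{eigenmode_basis} used for projection.
#' @return The activation augmented with \code{power}, \code{energy}
#'   (K x T) and \code{total_power}, \code{total_energy} (length T).
#' @export
spectra <- function(activation, basis) {
  om <- activation$coefficients
  lam <- basis$eigenvalues
  if (nrow(om) != length(lam)) stop("coefficient/basis mode mismatch")
  power <- abs(om)
  energy <- om^2 * lam^2
  activation$power <- power
  activation$energy <- energy
  activation$total_power <- colSums(power)
  activation$total_energy <- colSums(energy)
  activation
}

#' Per-mode segment summaries of power and energy
#'
#' Mean and maximum over time per mode, log-transformed after temporal
#' averaging (floor applied before the log), plus segment totals (sum
#' over modes per time point, averaged over the segment).
#'
#' @param sa a \code{spectral_activation} with power/energy.
#' @param log_base base of the log transform (default 10).
#' @param floor values below this are floored before the log.
#' @return list with per-mode \code{mean_power}, \code{max_power},
#'   \code{mean_energy}, \code{max_energy} (log scale), the linear-scale
#'   versions (suffix \code{_lin}), segment totals, and a
#'   \code{floored} flag matrix.
#' @export
segment_summary <- function(sa, log_base = 10, floor = 1e-12) {
  if (is.null(sa$power)) stop("call spectra() first")
  lg <- function(x) log(pmax(x, floor), base = log_base)
  mp <- rowMeans(sa$power);  xp <- apply(sa$power, 1, max)
  me <- rowMeans(sa$energy); xe <- apply(sa$energy, 1, max)
  list(mean_power = lg(mp), max_power = lg(xp),
       mean_energy = lg(me), max_energy = lg(xe),
       mean_power_lin = mp, max_power_lin = xp,
       mean_energy_lin = me, max_energy_lin = xe,
       total_power = mean(sa$total_power),
       total_energy = mean(sa$total_energy),
       floored = cbind(mean_power = mp < floor, max_power = xp < floor,
                       mean_energy = me < floor, max_energy = xe < floor))
}

#' Default eigengroup partition (spherical-harmonic multiplicities)
#'
#' Mode 1 alone, then consecutive blocks of size 3, 5, 7, ... (2l+1);
#' the final group may be truncated at K.
#'
#' @param K number of modes.
#' @return integer vector of group indices, length K.
#' @export
eigengroup_partition <- function(K) {
  g <- integer(0); l <- 0L
  while (length(g) < K) {
    g <- c(g, rep(l + 1L, 2L * l + 1L))
    l <- l + 1L
  }
  g[seq_len(K)]
}

#' Group-level summary of per-mode values
#'
#' @param values numeric vector of per-mode summaries (length K).
#' @param grouping integer group index per mode; default the
#'   spherical-harmonic partition from \code{\link{eigengroup_partition}}.
#' @return named numeric vector of group means.
#' @export
eigengroup_summary <- function(values, grouping = NULL) {
  K <- length(values)
  if (is.null(grouping)) grouping <- eigengroup_partition(K)
  if (length(grouping) != K || anyNA(grouping))
    stop("value error: grouping must assign every mode 1..K to a group")
  out <- tapply(values, grouping, mean)
  stats::setNames(as.numeric(out), paste0("group_", names(out)))
}
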