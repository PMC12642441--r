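#' Triangle mesh container
#'
#' @param vertices V x 3 numeric matrix of coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param validate check manifoldness and triangle areas (default TRUE).
#' @return An object of class \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be V x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces index vertices outside 1..V")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (validate) {
    a <- face_areas(m)
    if (any(a <= 1e-14))
      stop("mesh error: degenerate (zero-area) triangle at face ",
           which(a <= 1e-14)[1])
    ec <- edge_face_counts(m)
    if (any(ec > 2L)) stop("mesh error: non-manifold edge present")
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> V=", nrow(x$vertices), " F=", nrow(x$faces),
      " E=", n_edges(x), " (Euler ", nrow(x$vertices) - n_edges(x) + nrow(x$faces),
      ")\n", sep = "")
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_face_counts <- function(mesh) {
  e <- mesh_edges(mesh)
  table(paste(e[, 1], e[, 2]))
}

n_edges <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  nrow(e)
}

#' Surface area of a triangle mesh
#' @param mesh a \code{triangle_mesh}.
#' @return total area.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Unit icosphere mesh
#'
#' Builds a closed genus-0 triangle mesh of unit radius by midpoint
#' subdivision of a regular icosahedron; each subdivision level quadruples
#' the face count, giving 10 * 4^n + 2 vertices.
#'
#' @param subdivisions integer in 1..6.
#' @return A \code{triangle_mesh}.
#' @export
icosphere <- function(subdivisions = 2) {
  if (!(subdivisions %in% 1:6)) stop("subdivisions must be in 1..6")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    extra <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midcache[[key]]
      if (!is.null(idx)) return(idx)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      extra[[length(extra) + 1L]] <<- p
      idx <- nv + length(extra)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
  }
  triangle_mesh(v, f, validate = FALSE)
}

#' Read an ASCII OFF mesh file
#' @param path path to an OFF file.
#' @return A \code{triangle_mesh}.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("format error: not an OFF file")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    xs <- as.integer(strsplit(l, "\\s+")[[1]])
    if (xs[1] != 3L) stop("format error: only triangle faces are supported")
    xs[2:4] + 1L
  }))
  triangle_mesh(vtx, fc)
}

#' Write an ASCII OFF mesh file
#' @param mesh a \code{triangle_mesh}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
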