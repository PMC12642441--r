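#' Psychobehavioral term-map library
#'
#' @param maps term x location numeric matrix (rows are maps on a common
#'   grid or parcel set).
#' @param terms character vector of term names (default rownames).
#' @return An object of class \code{term_map_library}.
#' @export
term_map_library <- function(maps, terms = rownames(maps)) {
  maps <- as.matrix(maps)
  if (is.null(terms)) terms <- paste0("term_", seq_len(nrow(maps)))
  if (length(terms) != nrow(maps)) stop("one term name per map required")
  const <- apply(maps, 1, function(r) stats::sd(r, na.rm = TRUE) == 0)
  if (any(const)) stop("all-constant term map: ", paste(terms[const], collapse = ", "))
  structure(list(maps = maps, terms = terms), class = "term_map_library")
}

#' @export
print.term_map_library <- function(x, ...) {
  cat("<term_map_library> ", length(x$terms), " terms x ", ncol(x$maps),
      " locations\n", sep = "")
  invisible(x)
}

#' State-minus-control difference map
#'
#' @param state_map,control_map numeric vectors/arrays on the same grid;
#'   unthresholded difference, missing where either input is missing.
#' @return element-wise state - control.
#' @export
delta_map <- function(state_map, control_map) {
  if (!identical(dim(state_map) %||% length(state_map),
                 dim(control_map) %||% length(control_map)))
    stop("alignment error: maps must share the grid")
  state_map - control_map
}

#' Correlation decoding of a map against a term library
#'
#' Pearson correlation between the (unthresholded) input map and each
#' term map over jointly non-missing locations, a descending rank over
#' terms, and top-k most-positive / most-negative term lists.
#'
#' @param map numeric vector on the library's grid.
#' @param library a \code{\link{term_map_library}}.
#' @param top_k size of the top lists (default 10).
#' @param min_locations minimum joint non-missing locations per term.
#' @return A \code{decoding_result}: data.frame (term, r, rank) plus
#'   \code{top_positive} and \code{top_negative}.
#' @export
correlation_decode <- function(map, library, top_k = 10, min_locations = 10) {
  map <- as.numeric(map)
  if (length(map) != ncol(library$maps))
    stop("alignment error: map length differs from library grid")
  if (stats::sd(map, na.rm = TRUE) == 0) stop("constant map: correlations undefined")
  r <- apply(library$maps, 1, function(tm) {
    ok <- is.finite(map) & is.finite(tm)
    if (sum(ok) < min_locations)
      stop("fewer than ", min_locations, " joint non-missing locations")
    stats::cor(map[ok], tm[ok])
  })
  ord <- order(r, decreasing = TRUE)
  rank <- integer(length(r)); rank[ord] <- seq_along(r)
  k <- min(top_k, length(r))
  structure(list(table = data.frame(term = library$terms, r = r, rank = rank,
                                    row.names = NULL),
                 top_positive = library$terms[ord[seq_len(k)]],
                 top_negative = library$terms[rev(ord)[seq_len(k)]]),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", nrow(x$table), " terms; top positive: ",
      paste(utils::head(x$top_positive, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subgroup spatial similarity with permutation inference
#'
#' Per-state Pearson correlation between two subgroups' maps, with a
#' two-sided permutation p obtained by shuffling one map's locations.
#'
#' @param mapsA,mapsB lists (or matrices state x location) of per-state
#'   maps on the same support.
#' @param n_perm permutation iterations (default 10000).
#' @param seed integer seed.
#' @return data.frame per state: r, p.
#' @export
subgroup_similarity <- function(mapsA, mapsB, n_perm = 10000, seed = 1) {
  tomat <- function(m) if (is.list(m)) do.call(rbind, lapply(m, as.numeric)) else as.matrix(m)
  A <- tomat(mapsA); B <- tomat(mapsB)
  if (!all(dim(A) == dim(B))) stop("map sets must share support and state count")
  res <- data.frame(state = seq_len(nrow(A)), r = NA_real_, p = NA_real_)
  set.seed(derive_seed(seed, 303L))
  for (s in seq_len(nrow(A))) {
    a <- A[s, ]; b <- B[s, ]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 10) stop("fewer than 10 joint locations for state ", s)
    a <- a[ok]; b <- b[ok]
    r_obs <- stats::cor(a, b)
    cnt <- 0L
    for (i in seq_len(n_perm))
      cnt <- cnt + (abs(stats::cor(a, b[sample.int(length(b))])) >= abs(r_obs))
    res$r[s] <- r_obs
    res$p[s] <- (1 + cnt) / (n_perm + 1)
  }
  res
}

#' Linear trend of subgroup similarity across ordered states
#'
#' Ordinary least squares of the per-state similarity r on the state
#' index, with a two-sided slope test.
#'
#' @param r numeric vector of per-state correlations (state index
#'   1..length(r)); NAs dropped.
#' @return list(slope =, p =, intercept =).
#' @export
similarity_trend <- function(r) {
  idx <- seq_along(r)
  ok <- is.finite(r)
  if (sum(ok) < 3) stop("need >= 3 states with defined r")
  fit <- stats::lm(r[ok] ~ idx[ok])
  # summary() warns on exact fits; an exact line is a legitimate input here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), p = unname(sm[2, 4]),
       intercept = unname(sm[1, 1]))
}
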