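#' Volumetric image container
#'
#' Bundles a 3D map or 4D time series with its voxel geometry and an
#' analysis mask. The mask defaults to voxels that are finite everywhere
#' (3D) or finite with nonzero temporal variance (4D).
#'
#' @param data 3D or 4D numeric array.
#' @param voxel_size numeric vector of mm per spatial axis (length 3).
#' @param mask logical 3D array aligned with the spatial grid, or NULL to
#'   derive the default mask from the data.
#' @return An object of class \code{voxel_image} with elements \code{data},
#'   \code{voxel_size} and \code{mask}.
#' @export
voxel_image <- function(data, voxel_size = c(1, 1, 1), mask = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3L && nd != 4L)
    stop("dimension error: data must be a 3D or 4D array, got ", nd, "D")
  if (nd == 4L && dim(data)[4] < 2L)
    stop("dimension error: 4D data must have at least 2 time points")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (mm)")
  sdim <- dim(data)[1:3]
  if (is.null(mask)) {
    if (nd == 3L) {
      mask <- array(is.finite(data), dim = sdim)
    } else {
      finite_all <- apply(is.finite(data), 1:3, all)
      v <- apply(data, 1:3, stats::var)
      mask <- finite_all & is.finite(v) & v > 0
    }
  } else {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(as.integer(dim(mask)), as.integer(sdim)))
      stop("alignment error: mask shape must equal the spatial shape of data")
  }
  structure(list(data = data, voxel_size = voxel_size, mask = mask),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<voxel_image> ", paste(d, collapse = " x "),
      if (length(d) == 4L) " (4D time series)" else " (3D map)", "\n", sep = "")
  cat("  voxel size (mm): ", paste(format(x$voxel_size), collapse = " x "), "\n", sep = "")
  cat("  in-mask voxels: ", sum(x$mask), "/", prod(d[1:3]), "\n", sep = "")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a \code{\link{voxel_image}}, taking voxel
#' sizes from the header pixdim.
#'
#' @param path path to a NIfTI file (.nii or .nii.gz).
#' @param mask optional logical 3D array; default derived from the data.
#' @return A \code{voxel_image}.
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error: not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e), ")"))
  arr <- array(as.numeric(img), dim = dim(img))  # strip header attributes
  nd <- length(dim(arr))
  if (nd != 3L && nd != 4L)
    stop("dimension error: expected a 3D or 4D volume, got ", nd, "D")
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(1, 1, 1)
  voxel_image(arr, voxel_size = vs, mask = mask)
}

#' Write a NIfTI volume
#'
#' @param image a \code{voxel_image}.
#' @param path output path (.nii or .nii.gz); the parent directory must exist.
#' @param datatype storage type passed to RNifti (default "double" keeps
#'   round-trips exact; "float" matches common fMRI storage).
#' @return Invisibly, the path.
#' @export
write_volume <- function(image, path, datatype = "double") {
  stopifnot(inherits(image, "voxel_image"))
  if (!dir.exists(dirname(path))) stop("I/O error: parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(image$data)
  nd <- length(dim(image$data))
  RNifti::pixdim(img) <- c(image$voxel_size, rep(1, nd - 3L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a delimited table
#'
#' Reads a CSV or TSV file with a header row into a data.frame; empty
#' cells become NA. The delimiter is taken from the file extension, or
#' sniffed from the header line.
#'
#' @param path path to the delimited file.
#' @return data.frame with typed columns.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t"
         else if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
         else if (lengths(regmatches(first, gregexpr("\t", first))) >
                  lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  header_fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header_fields))
    stop("schema error: duplicate column names: ",
         paste(unique(header_fields[duplicated(header_fields)]), collapse = ", "))
  numeric_like <- grepl("^\\s*-?[0-9.]+([eE][+-]?[0-9]+)?\\s*$", header_fields)
  if (all(numeric_like) && length(header_fields) > 0L)
    stop("schema error: file appears to have no header row")
  utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Condition vocabulary for segment tables
#' @export
condition_levels <- function() c(paste0("J", 1:8), "counting", "memory", "afterglow")

#' Validate a segment table
#'
#' A segment table has one row per (participant, session, condition) with
#' 0-based half-open volume bounds \code{[start, end)} into the parent run.
#'
#' @param df data.frame with columns participant, session, condition,
#'   start, end.
#' @return The validated data.frame, classed \code{segment_table}.
#' @export
segment_table <- function(df) {
  need <- c("participant", "session", "condition", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$condition %in% condition_levels()))
    stop("condition must be one of {", paste(condition_levels(), collapse = ", "), "}")
  if (any(df$start >= df$end)) stop("segment bounds must satisfy start < end")
  if (any(df$start < 0)) stop("segment start must be >= 0")
  # non-overlap within each run
  sp <- split(df, interaction(df$participant, df$session, drop = TRUE))
  for (run in sp) {
    o <- order(run$start)
    if (nrow(run) > 1L && any(run$start[o][-1] < run$end[o][-nrow(run)]))
      stop("segments within a run must not overlap")
  }
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Slice a 4D run into per-segment images
#'
#' Uses 0-based half-open \code{[start, end)} time indices.
#'
#' @param image 4D \code{voxel_image}.
#' @param segments a \code{segment_table} (or compatible data.frame).
#' @param min_length minimum analyzable segment length in volumes
#'   (default 20); shorter rows are an error.
#' @param warn_below warn for segments shorter than this many volumes
#'   (default 60, roughly 3 minutes at typical repetition times).
#' @return A list of 4D \code{voxel_image}s, one per row, in row order.
#' @export
extract_segments <- function(image, segments, min_length = 20, warn_below = 60) {
  stopifnot(inherits(image, "voxel_image"))
  if (length(dim(image$data)) != 4L) stop("dimension error: a 4D image is required")
  Tn <- dim(image$data)[4]
  if (any(segments$end > Tn) || any(segments$start < 0))
    stop("index error: segment bounds [", min(segments$start), ", ",
         max(segments$end), ") outside run of length ", Tn)
  len <- segments$end - segments$start
  if (any(len < min_length))
    stop("segment shorter than the minimum analyzable length (", min_length, ")")
  if (any(len < warn_below))
    warning(sum(len < warn_below), " segment(s) shorter than ", warn_below, " volumes")
  lapply(seq_len(nrow(segments)), function(i) {
    idx <- (segments$start[i] + 1L):segments$end[i]
    voxel_image(image$data[, , , idx, drop = FALSE],
                voxel_size = image$voxel_size, mask = image$mask)
  })
}

#' Parcellation container
#'
#' @param labels integer 3D array; 0 is background.
#' @param names named character vector mapping label -> region name; if
#'   NULL, names are generated as "parcel_<label>".
#' @param networks optional named vector mapping label -> network id.
#' @return An object of class \code{parcellation}.
#' @export
parcellation <- function(labels, names = NULL, networks = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("dimension error: labels must be 3D")
  if (any(labels < 0)) stop("labels must be nonnegative")
  ids <- sort(unique(labels[labels > 0]))
  if (is.null(names)) {
    names <- stats::setNames(paste0("parcel_", ids), as.character(ids))
  } else if (!all(as.character(ids) %in% base::names(names))) {
    stop("every nonzero label needs a name")
  }
  structure(list(labels = labels, names = names, networks = networks,
                 ids = as.integer(ids)),
            class = "parcellation")
}
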