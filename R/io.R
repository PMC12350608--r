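# File formats: UTF-8 comma-separated text with a header row and '.' as
# the decimal mark.  Matrix files may start with '#' provenance comments.

check_numeric_csv <- function(df, path, cols) {
  for (cl in cols) {
    v <- as.character(df[[cl]])
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v) & v != "" & toupper(v) != "NA")
    if (length(bad)) {
      if (grepl(",", v[bad[1]], fixed = TRUE))
        stop(sprintf("%s: column '%s' uses decimal commas (line %d); use '.' as decimal mark",
                     path, cl, bad[1] + 1L))
      stop(sprintf("%s: column '%s' is not numeric (line %d)", path, cl, bad[1] + 1L))
    }
  }
  invisible(df)
}

#' Read and write contour CSV files
#'
#' A contour file holds one vertex per row in two numeric columns `x`,
#' `y` with a header row.  Writing then reading a contour round-trips the
#' vertices exactly (full double precision).
#'
#' @param path file path.
#' @param contour an [oto_contour] (for writing).
#' @param ... passed to [oto_contour()] when reading (`side`, `units`).
#' @return `read_contour_csv()` returns an [oto_contour];
#'   `write_contour_csv()` returns `path` invisibly.
#' @export
read_contour_csv <- function(path, ...) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("x", "y") %in% names(df)))
    stop(sprintf("%s: expected columns 'x' and 'y'", path))
  check_numeric_csv(df, path, c("x", "y"))
  oto_contour(cbind(as.numeric(df$x), as.numeric(df$y)), ...)
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(contour, path) {
  contour <- as_contour(contour)
  df <- data.frame(x = sprintf("%.17g", contour$vertices[, 1]),
                   y = sprintf("%.17g", contour$vertices[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest lists one specimen per row with columns `sample_id`,
#' `population`, `TL_mm` (total fish length), `OL_mm` (otolith length),
#' `side` (left/right) and `path` (contour CSV or mask image, relative
#' to the manifest's directory).  Sample ids must be unique, otolith
#' lengths positive, and every referenced file must exist.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that the referenced files exist.
#' @return Data frame of class `oto_manifest` (paths resolved).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("sample_id", "population", "TL_mm", "OL_mm", "side", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("%s: missing column(s): %s", path,
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    stop(sprintf("%s: duplicate sample_id '%s'", path, dup))
  }
  check_numeric_csv(df, path, c("TL_mm", "OL_mm"))
  df$TL_mm <- as.numeric(df$TL_mm); df$OL_mm <- as.numeric(df$OL_mm)
  bad <- which(!is.na(df$OL_mm) & df$OL_mm <= 0)
  if (length(bad)) stop(sprintf("%s: OL_mm must be positive (line %d)", path, bad[1] + 1L))
  df$path <- file.path(dirname(path), df$path)
  if (check_paths) {
    gone <- which(!file.exists(df$path))
    if (length(gone))
      stop(sprintf("%s: file for sample '%s' not found: %s", path,
                   df$sample_id[gone[1]], df$path[gone[1]]))
  }
  class(df) <- c("oto_manifest", "data.frame")
  df
}

#' Write a dataset to disk as manifest + contour files
#'
#' Materialises an `oto_dataset` (e.g. from
#' [generate_metapopulation()]) as one contour CSV per individual plus a
#' manifest CSV, the on-disk exchange format of the pipeline.
#'
#' @param dataset an `oto_dataset`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oto_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$contours)
  ids <- sprintf("%s_%03d", dataset$labels, stats::ave(seq_len(n), dataset$labels,
                                                       FUN = seq_along))
  rel <- paste0(ids, ".csv")
  for (i in seq_len(n)) write_contour_csv(dataset$contours[[i]], file.path(dir, rel[i]))
  man <- data.frame(sample_id = ids, population = dataset$labels,
                    TL_mm = NA_real_, OL_mm = dataset$sizes,
                    side = "left", path = rel)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

# Load contours referenced by a manifest (CSV polygons or PNG/TIFF masks).
load_manifest_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "oto_manifest"))
  contours <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    side <- manifest$side[i]
    ext <- tolower(tools::file_ext(p))
    if (ext == "csv") {
      read_contour_csv(p, side = side)
    } else if (ext %in% c("png", "tif", "tiff")) {
      img <- if (ext == "png") png::readPNG(p) else {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF masks requires the 'tiff' package")
        tiff::readTIFF(p)
      }
      if (length(dim(img)) == 3) img <- img[, , 1]
      # image rows run top-to-bottom; transpose to mask[x, y] convention
      m <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
      ct <- extract_contour(round(m))
      ct$side <- side
      ct
    } else stop(sprintf("sample '%s': unsupported file type '%s'",
                        manifest$sample_id[i], ext))
  })
  structure(list(contours = contours, sizes = manifest$OL_mm,
                 labels = manifest$population,
                 true_morphotype = rep(NA_character_, nrow(manifest)),
                 params = NULL),
            class = "oto_dataset")
}

#' Write a matrix as CSV with an id column and provenance header
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param ids row identifiers (first column).
#' @param comment optional provenance comment written as a leading
#'   `#` line.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path, ids = rownames(mat), comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(id = ids %||% seq_len(nrow(mat)), as.data.frame(mat))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a machine-readable run report
#'
#' @param report named list (parameters, seeds, metrics, file inventory).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
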