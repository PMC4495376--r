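#' Construct and validate a peak matrix
#'
#' A peak matrix is the standard container for pre-processed metabolomics
#' data: a numeric matrix of peak intensities with one row per sample and
#' one column per metabolite (VOC). Missing intensities are `NA`; all other
#' values must be finite. Row and column names are the sample and
#' metabolite identifiers and must be unique and non-empty.
#'
#' @param values numeric matrix, rows = samples, columns = metabolites,
#'   with complete `dimnames`.
#' @return the validated matrix (invisibly unchanged).
#' @examples
#' m <- matrix(c(1, 3, 2, 4), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' peak_matrix(m)
#' @export
peak_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("peak matrix must be a numeric matrix")
  }
  ids <- dimnames(values)
  if (is.null(ids) || is.null(ids[[1L]]) || is.null(ids[[2L]])) {
    stop_data("peak matrix must carry sample (row) and metabolite (column) names")
  }
  check_axis_ids(rownames(values), "sample")
  check_axis_ids(colnames(values), "metabolite")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_data("non-finite intensity at sample '", rownames(values)[idx[1L]],
              "', metabolite '", colnames(values)[idx[2L]], "'")
  }
  values
}

check_axis_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop_data("empty ", what, " identifier")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_data("duplicate ", what, " identifier: '", dup[1L], "'")
  }
  invisible(ids)
}

#' Construct and validate a sample annotation table
#'
#' Annotations hold one or more categorical labels per sample (for
#' example disease status, smoking, nutrition). Each label column becomes
#' a factor; every sample must have a value for every label.
#'
#' @param x data frame with row names = sample identifiers and one column
#'   per label.
#' @return a data frame of factors with the same row names.
#' @export
sample_annotations <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 1L) {
    stop_data("annotations must be a data frame with at least one label column")
  }
  check_axis_ids(rownames(x), "sample")
  check_axis_ids(colnames(x), "label")
  for (j in seq_along(x)) {
    v <- as.character(x[[j]])
    if (anyNA(v) || any(!nzchar(v))) {
      i <- which(is.na(v) | !nzchar(v))[1L]
      stop_data("sample '", rownames(x)[i], "' has no value for label '",
                colnames(x)[j], "'")
    }
    x[[j]] <- factor(v)
  }
  x
}

num_fmt <- function(x) {
  # >= 12 significant digits so write/read round-trips are lossless at 1e-9
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1L) stop_data("no content in ", path)
  # sentinel keeps trailing empty fields, which strsplit would drop
  cells <- strsplit(paste0(body, "\x01"), "\t", fixed = TRUE)
  cells <- lapply(cells, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  widths <- lengths(cells)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop_data("ragged row ", bad, " in ", path, ": expected ",
              widths[1L], " fields, found ", widths[bad])
  }
  meta <- character(0)
  for (ml in meta_lines) {
    kv <- regmatches(ml, gregexpr("[A-Za-z_]+=[^ \t]+", ml))[[1L]]
    for (pair in kv) {
      eq <- regexpr("=", pair, fixed = TRUE)
      meta[substr(pair, 1L, eq - 1L)] <- substring(pair, eq + 1L)
    }
  }
  list(cells = cells, meta = meta)
}

parse_numeric_cells <- function(cells, row_ids, col_ids, path, missing_token = "NA") {
  n <- length(row_ids)
  m <- length(col_ids)
  out <- matrix(NA_real_, n, m, dimnames = list(row_ids, col_ids))
  for (i in seq_len(n)) {
    raw <- cells[[i]]
    is_missing <- raw == missing_token
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !is_missing
    if (any(bad)) {
      j <- which(bad)[1L]
      stop_data("non-numeric cell at row '", row_ids[i], "', column '",
                col_ids[j], "' in ", path, ": '", raw[j], "'")
    }
    out[i, ] <- val
  }
  out
}

#' Read a peak matrix from tab-separated text
#'
#' The file must have a header row and a header column; the body holds
#' intensities with `NA` as the missing-value token and a period decimal
#' separator. Files with metabolites in rows are transposed on read so
#' that the returned matrix always has samples in rows.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"samples_in_columns"`, describing the file on disk.
#' @return a validated [peak_matrix()].
#' @export
read_peak_matrix <- function(path,
                             orientation = c("samples_in_rows", "samples_in_columns")) {
  orientation <- match.arg(orientation)
  tab <- read_tsv_table(path)
  cells <- tab$cells
  if (length(cells) < 2L) stop_data("peak matrix file needs a header and a body: ", path)
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  row_ids <- vapply(body, `[`, character(1L), 1L)
  body <- lapply(body, `[`, -1L)
  values <- parse_numeric_cells(body, row_ids, header, path)
  if (orientation == "samples_in_columns") values <- t(values)
  peak_matrix(values)
}

#' Write a peak matrix as tab-separated text
#'
#' @param x a [peak_matrix()].
#' @param path destination path.
#' @export
write_peak_matrix <- function(x, path) {
  x <- peak_matrix(x)
  write_matrix_tsv(x, path, corner = "sample")
}

write_matrix_tsv <- function(x, path, corner, meta = NULL) {
  lines <- character(0)
  if (!is.null(meta)) lines <- paste0("# ", meta)
  lines <- c(lines, paste(c(corner, colnames(x)), collapse = "\t"))
  for (i in seq_len(nrow(x))) {
    lines <- c(lines, paste(c(rownames(x)[i], num_fmt(x[i, ])), collapse = "\t"))
  }
  write_lines_checked(lines, path)
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_data("cannot write '", path, "': ", conditionMessage(ok))
  invisible(NULL)
}

#' Read a sample annotation table
#'
#' Expects a header row declaring label names; the first column holds
#' sample identifiers.
#'
#' @param path path to a TSV file.
#' @return a [sample_annotations()] data frame.
#' @export
read_annotations <- function(path) {
  tab <- read_tsv_table(path)
  cells <- tab$cells
  if (length(cells) < 2L) stop_data("annotation file needs a header and a body: ", path)
  labels <- cells[[1L]][-1L]
  body <- cells[-1L]
  ids <- vapply(body, `[`, character(1L), 1L)
  df <- as.data.frame(
    lapply(seq_along(labels), function(j) {
      vapply(body, `[`, character(1L), j + 1L)
    }),
    col.names = labels, stringsAsFactors = FALSE
  )
  rownames(df) <- ids
  sample_annotations(df)
}

#' Write a sample annotation table
#'
#' @param ann a [sample_annotations()] data frame.
#' @param path destination path.
#' @export
write_annotations <- function(ann, path) {
  ann <- sample_annotations(ann)
  lines <- paste(c("sample", colnames(ann)), collapse = "\t")
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines, paste(c(rownames(ann)[i],
                              vapply(ann[i, , drop = FALSE], as.character, character(1L))),
                            collapse = "\t"))
  }
  write_lines_checked(lines, path)
}

#' Write a relation matrix
#'
#' Serializes a square similarity or dissimilarity matrix with a comment
#' header recording its kind, measure and absolute flag, so the reader can
#' restore the full object.
#'
#' @param rel a [relation_matrix] object.
#' @param path destination path.
#' @export
write_relation_matrix <- function(rel, path) {
  stopifnot(inherits(rel, "relation_matrix"))
  meta <- sprintf("kind=%s measure=%s absolute=%s",
                  attr(rel, "kind"), attr(rel, "measure"),
                  tolower(as.character(attr(rel, "absolute"))))
  write_matrix_tsv(unclass_relation(rel), path, corner = "object", meta = meta)
}

#' Read a relation matrix written by [write_relation_matrix()]
#'
#' @param path path to a TSV file.
#' @return a [relation_matrix] object.
#' @export
read_relation_matrix <- function(path) {
  tab <- read_tsv_table(path)
  cells <- tab$cells
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  ids <- vapply(body, `[`, character(1L), 1L)
  values <- parse_numeric_cells(lapply(body, `[`, -1L), ids, header, path)
  if (!identical(rownames(values), colnames(values))) {
    stop_data("relation matrix row/column identifiers disagree in ", path)
  }
  meta <- tab$meta
  new_relation_matrix(values,
                      kind = if (is.na(meta["kind"])) "similarity" else unname(meta["kind"]),
                      measure = if (is.na(meta["measure"])) "converted" else unname(meta["measure"]),
                      absolute = identical(unname(meta["absolute"]), "true"))
}

#' Write a clustering (partition) as two-column TSV
#'
#' One data line per object: `object_id<TAB>cluster_id`, preceded by a
#' comment line recording the clustering method and its threshold or cut
#' parameter.
#'
#' @param cl a [clustering] object.
#' @param path destination path.
#' @export
write_clustering <- function(cl, path) {
  stopifnot(inherits(cl, "clustering"))
  meta <- sprintf("method=%s parameter=%s", attr(cl, "method"),
                  num_fmt(attr(cl, "parameter")))
  lines <- c(paste0("# ", meta), "object_id\tcluster_id",
             paste(names(cl), unclass(cl), sep = "\t"))
  write_lines_checked(lines, path)
}

#' Read a clustering written by [write_clustering()]
#'
#' @param path path to a TSV file.
#' @return a [clustering] object.
#' @export
read_clustering <- function(path) {
  tab <- read_tsv_table(path)
  body <- tab$cells[-1L]
  ids <- vapply(body, `[`, character(1L), 1L)
  assign <- as.integer(vapply(body, `[`, character(1L), 2L))
  meta <- tab$meta
  clustering(stats::setNames(assign, ids),
             method = if (is.na(meta["method"])) "unknown" else unname(meta["method"]),
             parameter = unname(suppressWarnings(as.numeric(meta["parameter"]))))
}

#' Write a quality curve as two-column TSV
#'
#' One data line per swept parameter, sorted by parameter, preceded by a
#' comment line recording the measure and (for the F-measure) the
#' annotation label.
#'
#' @param curve a [quality_curve] object.
#' @param path destination path.
#' @export
write_quality_curve <- function(curve, path) {
  stopifnot(inherits(curve, "quality_curve"))
  meta <- sprintf("measure=%s label=%s subject=%s",
                  attr(curve, "measure"),
                  if (is.null(attr(curve, "label"))) "-" else attr(curve, "label"),
                  if (is.null(attr(curve, "subject"))) "-" else attr(curve, "subject"))
  o <- order(curve$parameter)
  lines <- c(paste0("# ", meta), "parameter\tvalue",
             paste(num_fmt(curve$parameter[o]), num_fmt(curve$value[o]), sep = "\t"))
  write_lines_checked(lines, path)
}

#' Read a quality curve written by [write_quality_curve()]
#'
#' @param path path to a TSV file.
#' @return a [quality_curve] object.
#' @export
read_quality_curve <- function(path) {
  tab <- read_tsv_table(path)
  body <- tab$cells[-1L]
  param <- as.numeric(vapply(body, `[`, character(1L), 1L))
  value <- as.numeric(vapply(body, `[`, character(1L), 2L))
  meta <- tab$meta
  lab <- unname(meta["label"])
  subj <- unname(meta["subject"])
  quality_curve_points(param, value,
                       measure = if (is.na(meta["measure"])) "unknown" else unname(meta["measure"]),
                       label = if (is.na(lab) || identical(lab, "-")) NULL else lab,
                       subject = if (is.na(subj) || identical(subj, "-")) NULL else subj)
}
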