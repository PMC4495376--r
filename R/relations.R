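#' Pairwise relation matrices
#'
#' A `relation_matrix` is a symmetric numeric matrix of pairwise relations
#' over the objects of one axis of a peak matrix, tagged with its `kind`
#' (`"similarity"` or `"dissimilarity"`), the `measure` that produced it
#' (`"pearson"`, `"spearman"`, `"euclidean"` or `"converted"`) and whether
#' absolute correlation values were taken.
#'
#' @name relation_matrix-class
NULL

new_relation_matrix <- function(values, kind, measure, absolute = FALSE) {
  kind <- match.arg(kind, c("similarity", "dissimilarity"))
  if (!isTRUE(all(is.finite(values)))) stop_data("relation matrix has non-finite entries")
  if (nrow(values) != ncol(values)) stop_data("relation matrix must be square")
  if (max(abs(values - t(values))) > 0) stop_data("relation matrix must be symmetric")
  if (kind == "dissimilarity") {
    if (any(values < 0)) stop_data("dissimilarities must be non-negative")
    if (any(diag(values) != 0)) stop_data("dissimilarity diagonal must be zero")
  }
  structure(values, class = "relation_matrix", kind = kind,
            measure = measure, absolute = isTRUE(absolute))
}

unclass_relation <- function(rel) {
  attributes(rel) <- attributes(rel)[c("dim", "dimnames")]
  rel
}

#' @export
print.relation_matrix <- function(x, ...) {
  cat(sprintf("%s matrix (%s%s) over %d objects\n",
              attr(x, "kind"), attr(x, "measure"),
              if (isTRUE(attr(x, "absolute"))) ", absolute" else "",
              nrow(x)))
  print(unclass_relation(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

#' Scalar relation measures
#'
#' `pearson()` is the product-moment correlation of two observation
#' vectors; `spearman()` is the same correlation computed on average
#' ranks; `euclidean()` is the root of summed squared coordinate
#' differences. Correlations lie in \[-1, 1\]; the Euclidean distance is
#' non-negative and zero only for identical vectors.
#'
#' Correlation of a zero-variance vector is undefined: these functions
#' return `NA` with a warning, and the matrix builder maps that case to
#' zero similarity (see [relation_matrix()]).
#'
#' @param x,y numeric vectors of equal length (at least 2 for the
#'   correlations).
#' @return a single numeric value.
#' @examples
#' euclidean(c(0, 0), c(3, 4))   # 5
#' pearson(1:4, c(2, 1, 4, 6))
#' @export
pearson <- function(x, y) {
  check_pair(x, y, min_len = 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson
#' @export
spearman <- function(x, y) {
  check_pair(x, y, min_len = 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' @rdname pearson
#' @export
euclidean <- function(x, y) {
  check_pair(x, y, min_len = 1L)
  sqrt(sum((x - y)^2))
}

check_pair <- function(x, y, min_len) {
  if (length(x) != length(y)) {
    stop_data("vectors differ in length (", length(x), " vs ", length(y), ")")
  }
  if (length(x) < min_len) stop_data("vectors too short (need >= ", min_len, ")")
  invisible(NULL)
}

#' Compute a pairwise relation matrix over one axis of a peak matrix
#'
#' For correlation measures the result is a similarity matrix with unit
#' diagonal (absolute values taken by default, so entries lie in \[0, 1\]);
#' for the Euclidean measure it is a dissimilarity matrix with zero
#' diagonal. Objects are the rows (samples) or columns (metabolites) of
#' the peak matrix, as selected by `axis`.
#'
#' Missing intensities are rejected unless `pairwise_complete = TRUE`, in
#' which case each pair is computed over its co-observed positions (at
#' least `min_overlap`). An object with zero variance has no defined
#' correlation; its off-diagonal similarities are set to 0 with a warning
#' naming the object.
#'
#' @param data a [peak_matrix()].
#' @param axis `"metabolites"` or `"samples"`.
#' @param measure `"pearson"`, `"spearman"` or `"euclidean"`.
#' @param absolute take absolute correlation values (default `TRUE`;
#'   ignored for the Euclidean measure).
#' @param pairwise_complete allow missing values, computing each pair over
#'   co-observed positions.
#' @param min_overlap minimum number of co-observed positions per pair
#'   under `pairwise_complete`.
#' @return a [relation_matrix-class] object.
#' @export
relation_matrix <- function(data,
                            axis = c("metabolites", "samples"),
                            measure = c("pearson", "spearman", "euclidean"),
                            absolute = TRUE,
                            pairwise_complete = FALSE,
                            min_overlap = 3L) {
  axis <- match.arg(axis)
  measure <- match.arg(measure)
  data <- peak_matrix(data)
  vecs <- if (axis == "metabolites") data else t(data)   # objects in columns
  n <- ncol(vecs)
  if (n < 2L) stop_data("axis '", axis, "' has fewer than 2 objects")
  if (anyNA(vecs) && !pairwise_complete) {
    stop_data("peak matrix contains missing values; enable pairwise_complete ",
              "or impute upstream")
  }

  if (measure == "euclidean") {
    if (anyNA(vecs)) stop_data("euclidean relation does not support missing values")
    d <- as.matrix(stats::dist(t(vecs), method = "euclidean"))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    return(new_relation_matrix(d, "dissimilarity", "euclidean"))
  }

  use <- if (pairwise_complete) "pairwise.complete.obs" else "everything"
  if (pairwise_complete) {
    obs <- crossprod(!is.na(vecs))
    if (any(obs < min_overlap)) {
      ij <- which(obs < min_overlap, arr.ind = TRUE)[1L, ]
      stop_data("pair ('", colnames(vecs)[ij[1L]], "', '", colnames(vecs)[ij[2L]],
                "') has fewer than ", min_overlap, " co-observed values")
    }
  }
  s <- suppressWarnings(stats::cor(vecs, method = measure, use = use))
  if (any(is.na(s))) {
    flat <- colnames(vecs)[vapply(seq_len(n), function(j) {
      anyNA(s[-j, j])
    }, logical(1L))]
    if (length(flat)) {
      warning("zero-variance object(s) assigned zero similarity: ",
              paste(flat, collapse = ", "), call. = FALSE)
    }
    s[is.na(s)] <- 0
  }
  if (absolute) s <- abs(s)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  new_relation_matrix(s, "similarity", measure, absolute = absolute)
}

#' Convert between similarity and dissimilarity
#'
#' Flips the representation of a relation matrix using the magnitude
#' complement: every entry becomes `M - |value|`, where `M` is the maximum
#' absolute entry of the whole input matrix (diagonal included). For an
#' absolute correlation matrix `M = 1`, giving the familiar
#' `d = 1 - |r|`. The conversion reverses the ordering of magnitudes, so
#' the most similar pair becomes the least dissimilar one and vice versa.
#' When the converted kind is a dissimilarity, the diagonal is forced to
#' zero afterwards (with a warning if it was not already), as required by
#' downstream clustering and silhouette computation.
#'
#' @param rel a [relation_matrix-class] object.
#' @return a [relation_matrix-class] of the opposite kind, with
#'   `measure = "converted"`.
#' @export
convert_relation <- function(rel) {
  stopifnot(inherits(rel, "relation_matrix"))
  if (length(rel) == 0L) stop_data("cannot convert an empty relation matrix")
  values <- unclass_relation(rel)
  M <- max(abs(values))
  out <- M - abs(values)
  to <- if (attr(rel, "kind") == "similarity") "dissimilarity" else "similarity"
  if (to == "dissimilarity" && any(diag(out) != 0)) {
    warning("forcing converted dissimilarity diagonal to zero", call. = FALSE)
    diag(out) <- 0
  }
  new_relation_matrix(out, to, "converted")
}
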