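#' Overall silhouette value of a clustering
#'
#' For each object i, `a_i` is the mean dissimilarity to the other
#' members of its own cluster and `b_i` the smallest mean dissimilarity
#' to any other cluster (the "neighbour" cluster). The object silhouette
#' is `(b_i - a_i) / max(a_i, b_i)`; members of singleton clusters score
#' 0 by convention. The overall value is the mean over all objects and
#' lies in \[-1, 1\]; tightly separated clusters approach 1.
#'
#' A clustering with a single cluster has no between-cluster term: the
#' function returns `NA` with a warning, and sweep curves record the
#' point as skipped.
#'
#' @param cl a [clustering()].
#' @param dissim a [relation_matrix-class] of kind `"dissimilarity"` over
#'   the same objects.
#' @return a single numeric value in \[-1, 1\], or `NA` for a
#'   single-cluster partition. The per-object values are attached as
#'   attribute `"widths"`.
#' @export
silhouette_value <- function(cl, dissim) {
  stopifnot(inherits(cl, "clustering"))
  check_dissimilarity(dissim, "silhouette_value")
  d <- align_relation(dissim, names(cl))
  a <- as.integer(cl)
  ks <- sort(unique(a))
  if (length(ks) < 2L) {
    warning("silhouette undefined for a single-cluster partition", call. = FALSE)
    return(NA_real_)
  }
  sizes <- tabulate(a)
  n <- length(a)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- a[i]
    if (sizes[own] == 1L) {
      s[i] <- 0
      next
    }
    ai <- mean(d[i, a == own & seq_len(n) != i])
    bi <- min(vapply(ks[ks != own], function(k) mean(d[i, a == k]), numeric(1L)))
    s[i] <- if (max(ai, bi) == 0) 0 else (bi - ai) / max(ai, bi)
  }
  structure(mean(s), widths = stats::setNames(s, names(cl)))
}

align_relation <- function(rel, ids) {
  m <- unclass_relation(rel)
  miss <- setdiff(ids, rownames(m))
  extra <- setdiff(rownames(m), ids)
  if (length(miss) || length(extra)) {
    stop_data("object sets disagree (missing from matrix: ",
              paste(utils::head(miss, 3L), collapse = ", "),
              "; extra in matrix: ",
              paste(utils::head(extra, 3L), collapse = ", "), ")")
  }
  m[ids, ids, drop = FALSE]
}

#' External F-measure of a clustering against a gold standard
#'
#' Compares a clustering C to a known grouping K (here built from one
#' annotation label): with `t[i, j]` the number of objects shared by
#' class `K_i` and cluster `C_j`,
#' `F = (1 / sum_i |K_i|) * sum_i |K_i| * max_j 2 t[i, j] / (|C_j| + |K_i|)`.
#' The value lies in \[0, 1\] and equals 1 exactly when the two
#' partitions are identical.
#'
#' @param cl a [clustering()].
#' @param gold the gold-standard grouping: a named factor/character
#'   vector over the identical object set, or a [clustering()].
#' @return a single numeric value in \[0, 1\].
#' @export
f_measure <- function(cl, gold) {
  stopifnot(inherits(cl, "clustering"))
  ids <- names(cl)
  gold_ids <- names(gold)
  if (is.null(gold_ids)) stop_data("gold standard must be named by object id")
  miss <- setdiff(ids, gold_ids)
  extra <- setdiff(gold_ids, ids)
  if (length(miss) || length(extra)) {
    stop_data("object sets disagree (unannotated: ",
              paste(utils::head(miss, 3L), collapse = ", "),
              "; not clustered: ",
              paste(utils::head(extra, 3L), collapse = ", "), ")")
  }
  k <- factor(as.character(gold)[match(ids, gold_ids)])
  cj <- factor(as.integer(cl))
  t_ij <- table(k, cj)
  k_sizes <- rowSums(t_ij)
  c_sizes <- colSums(t_ij)
  per_class <- apply(2 * t_ij / outer(k_sizes, c_sizes, "+"), 1L, max)
  sum(k_sizes * per_class) / sum(k_sizes)
}

#' Build a gold-standard grouping from one annotation label
#'
#' Each distinct value of the label becomes one class.
#'
#' @param ann a [sample_annotations()] data frame.
#' @param label name of the annotation column.
#' @param ids optional subset/order of sample ids.
#' @return a named factor usable as the `gold` argument of
#'   [f_measure()].
#' @export
gold_standard <- function(ann, label, ids = rownames(ann)) {
  if (!label %in% colnames(ann)) {
    stop_data("unknown annotation label '", label, "'")
  }
  missing_ids <- setdiff(ids, rownames(ann))
  if (length(missing_ids)) {
    stop_data("samples without annotations: ",
              paste(utils::head(missing_ids, 3L), collapse = ", "))
  }
  stats::setNames(factor(ann[ids, label]), ids)
}

#' Quality curves over a clustering sweep
#'
#' Evaluates one quality measure for every clustering of a sweep and
#' returns the (parameter, value) series. Undefined points (silhouette of
#' a single-cluster partition) are omitted rather than coerced to a
#' number, so [best_parameter()] is not corrupted.
#'
#' @param result a [clustering_result()].
#' @param measure `"silhouette"` or `"fmeasure"`.
#' @param dissim dissimilarity [relation_matrix-class] (silhouette only).
#' @param gold gold-standard grouping from [gold_standard()] (F-measure
#'   only).
#' @param label annotation label name recorded on the curve (F-measure).
#' @param subject identifier of the clustered object set, recorded on the
#'   curve (e.g. `"samples|subset_1"`).
#' @return a `"quality_curve"`: data frame with columns `parameter` and
#'   `value` plus attributes `measure`, `label`, `subject`.
#' @export
quality_curve <- function(result, measure = c("silhouette", "fmeasure"),
                          dissim = NULL, gold = NULL, label = NULL,
                          subject = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(result, "clustering_result"))
  if (measure == "silhouette" && is.null(dissim)) {
    stop_data("silhouette curves need a dissimilarity matrix")
  }
  if (measure == "fmeasure" && is.null(gold)) {
    stop_data("F-measure curves need a gold standard")
  }
  vals <- vapply(result$clusterings, function(cl) {
    if (measure == "silhouette") {
      suppressWarnings(as.numeric(silhouette_value(cl, dissim)))
    } else {
      f_measure(cl, gold)
    }
  }, numeric(1L))
  keep <- !is.na(vals)
  if (any(!keep)) {
    message(sum(!keep), " sweep point(s) skipped (measure undefined)")
  }
  quality_curve_points(result$parameters[keep], vals[keep],
                       measure = measure, label = label, subject = subject)
}

quality_curve_points <- function(parameter, value, measure, label = NULL,
                                 subject = NULL) {
  if (length(parameter) && any(diff(parameter) <= 0)) {
    stop_data("curve parameters must be strictly increasing")
  }
  structure(data.frame(parameter = parameter, value = value),
            class = c("quality_curve", "data.frame"),
            measure = measure, label = label, subject = subject)
}

#' @export
print.quality_curve <- function(x, ...) {
  cat(sprintf("%s curve%s%s: %d points\n", attr(x, "measure"),
              if (is.null(attr(x, "label"))) "" else paste0(" [", attr(x, "label"), "]"),
              if (is.null(attr(x, "subject"))) "" else paste0(" on ", attr(x, "subject")),
              nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Parameter with the best quality value
#'
#' Returns the sweep parameter maximizing the curve; ties are broken
#' toward the smaller parameter (fewer clusters / lower threshold).
#'
#' @param curve a [quality_curve()].
#' @return the winning parameter value.
#' @export
best_parameter <- function(curve) {
  stopifnot(inherits(curve, "quality_curve"))
  if (nrow(curve) == 0L) stop_data("cannot select a parameter from an empty curve")
  o <- order(curve$parameter)
  p <- curve$parameter[o]
  v <- curve$value[o]
  p[which.max(v)]
}

#' Peak of a quality curve
#'
#' @param curve a [quality_curve()].
#' @return list with `parameter` and `value` at the maximum (ties toward
#'   the smaller parameter).
#' @export
curve_peak <- function(curve) {
  p <- best_parameter(curve)
  list(parameter = p, value = curve$value[match(p, curve$parameter)])
}
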