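#' Partition containers
#'
#' A `clustering` is one partition of a fixed object set: a named integer
#' vector mapping each object id to a cluster id, with cluster ids
#' contiguous from 1. A `clustering_result` is the ordered family of
#' clusterings produced by sweeping a method parameter (the cut level k
#' for hierarchical clustering, the similarity threshold for transitivity
#' clustering).
#'
#' @param assignment named integer vector, one entry per object.
#' @param method name of the producing method.
#' @param parameter the threshold / cut parameter that produced the
#'   partition.
#' @return `clustering()` returns the validated, canonically relabelled
#'   named integer vector of class `"clustering"`.
#' @export
clustering <- function(assignment, method = "manual", parameter = NA_real_) {
  ids <- names(assignment)
  if (is.null(ids)) stop_data("clustering assignment must be named by object id")
  check_axis_ids(ids, "object")
  a <- as.integer(assignment)
  if (anyNA(a)) stop_data("clustering assignment contains NA")
  # canonical labels: clusters numbered 1.. in order of first appearance
  a <- match(a, unique(a))
  structure(stats::setNames(a, ids), class = "clustering",
            method = method, parameter = parameter)
}

n_clusters <- function(cl) length(unique(as.integer(cl)))

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("clustering of %d objects into %d clusters (%s, parameter %s)\n",
              length(x), n_clusters(x), attr(x, "method"),
              format(attr(x, "parameter"))))
  invisible(x)
}

#' Split a clustering into member-id lists
#'
#' @param cl a [clustering()].
#' @return list of character vectors, one per cluster.
#' @export
cluster_members <- function(cl) {
  split(names(cl), as.integer(cl))
}

#' @rdname clustering
#' @param clusterings list of [clustering()] objects over the identical
#'   object set.
#' @param parameters strictly increasing numeric vector, one per
#'   clustering.
#' @return `clustering_result()` returns a list of class
#'   `"clustering_result"` with elements `clusterings`, `parameters`,
#'   `method`.
#' @export
clustering_result <- function(clusterings, parameters, method) {
  if (length(clusterings) != length(parameters)) {
    stop_data("one parameter per clustering required")
  }
  if (length(parameters) == 0L) stop_data("empty clustering result")
  if (any(diff(parameters) <= 0)) stop_data("sweep parameters must be strictly increasing")
  ids <- names(clusterings[[1L]])
  for (cl in clusterings) {
    if (!identical(sort(names(cl)), sort(ids))) {
      stop_data("all clusterings in a result must cover the identical object set")
    }
  }
  structure(list(clusterings = clusterings, parameters = parameters,
                 method = method),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering result (%s): %d partitions over %d objects, parameters %s..%s\n",
              x$method, length(x$clusterings), length(x$clusterings[[1L]]),
              format(min(x$parameters)), format(max(x$parameters))))
  invisible(x)
}
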