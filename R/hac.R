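#' Hierarchical agglomerative clustering of a dissimilarity matrix
#'
#' Starts from singletons and iteratively merges the pair of clusters at
#' the smallest inter-cluster dissimilarity, where the inter-cluster
#' dissimilarity is the minimum (`single`), maximum (`complete`) or mean
#' (`average`) of all cross-pair object dissimilarities. These three
#' linkages are monotone, so merge heights never decrease along the
#' sequence. When several pairs tie at the minimal distance, the pair that
#' is lexicographically smallest by (smallest member id, then the other
#' cluster's smallest member id) is merged, which makes the tree
#' deterministic and independent of input order.
#'
#' @param dissim a [relation_matrix-class] of kind `"dissimilarity"`.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return an object of class `"hac_tree"`: list with `merge` and
#'   `height` in [stats::hclust()] layout, `labels` and `linkage`.
#'   Use [as.hclust()] for plotting.
#' @seealso [cut_tree()], [sweep_hac()]
#' @export
hac <- function(dissim, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  check_dissimilarity(dissim, "hac")
  values <- unclass_relation(dissim)
  n <- nrow(values)
  if (n < 2L) stop_data("need at least 2 objects to cluster")
  labels <- rownames(values)
  rank <- id_rank(labels)

  D <- values
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minrank <- rank                    # smallest member-id rank per cluster
  code <- -seq_len(n)                # hclust merge coding
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    dmin <- Inf
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]
      dij <- D[i, idx[(a + 1L):length(idx)]]
      m <- min(dij)
      if (m < dmin) dmin <- m
    }
    # collect exact ties and break them by member-id ranks
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]
      for (b in (a + 1L):length(idx)) {
        j <- idx[b]
        if (D[i, j] == dmin) {
          key <- c(min(minrank[i], minrank[j]), max(minrank[i], minrank[j]))
          if (is.null(best) || key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])) {
            best <- list(i = i, j = j, key = key)
          }
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- dmin

    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- switch(linkage,
        single   = min(D[i, k], D[j, k]),
        complete = max(D[i, k], D[j, k]),
        average  = (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
      )
      D[k, i] <- D[i, k]
    }
    size[i] <- size[i] + size[j]
    minrank[i] <- min(minrank[i], minrank[j])
    code[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "hac_tree")
}

check_dissimilarity <- function(rel, caller) {
  if (!inherits(rel, "relation_matrix")) {
    stop_data(caller, " expects a relation_matrix")
  }
  if (attr(rel, "kind") != "dissimilarity") {
    stop_data(caller, " needs a dissimilarity matrix; convert a similarity ",
              "with convert_relation() first")
  }
  invisible(rel)
}

#' @export
print.hac_tree <- function(x, ...) {
  cat(sprintf("hierarchical agglomeration (%s linkage) of %d objects; merge heights %s..%s\n",
              x$linkage, length(x$labels),
              format(min(x$height)), format(max(x$height))))
  invisible(x)
}

#' @export
as.hclust.hac_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = tree_leaf_order(x$merge, length(x$labels)),
                 labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "user-supplied"),
            class = "hclust")
}

tree_leaf_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0L) return(-node)
    c(leaves(merge[node, 1L]), leaves(merge[node, 2L]))
  }
  leaves(n - 1L)
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges, i.e. applies the first `n - k` merges
#' of the tree, yielding exactly `k` clusters.
#'
#' @param tree an `"hac_tree"` from [hac()].
#' @param k number of clusters, between 1 and the number of objects.
#' @return a [clustering()] with `parameter = k`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hac_tree"))
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n || k != round(k)) {
    stop_data("k must be an integer in [1, ", n, "]")
  }
  assign <- seq_len(n)
  cluster_of_merge <- integer(n - 1L)
  steps <- n - as.integer(k)
  for (s in seq_len(steps)) {
    left <- tree$merge[s, 1L]
    right <- tree$merge[s, 2L]
    lc <- if (left < 0L) assign[-left] else cluster_of_merge[left]
    rc <- if (right < 0L) assign[-right] else cluster_of_merge[right]
    keep <- min(lc, rc)
    assign[assign == lc | assign == rc] <- keep
    cluster_of_merge[s] <- keep
  }
  clustering(stats::setNames(assign, tree$labels),
             method = paste0("hac_", tree$linkage), parameter = as.numeric(k))
}

#' Sweep all cuts of a hierarchical clustering
#'
#' Produces one clustering per cluster count k = 1..n, the full family of
#' partitions encoded by the merge tree.
#'
#' @inheritParams hac
#' @return a [clustering_result()] with `parameters = 1:n`.
#' @export
sweep_hac <- function(dissim, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  tree <- hac(dissim, linkage)
  n <- length(tree$labels)
  ks <- seq_len(n)
  clustering_result(lapply(ks, function(k) cut_tree(tree, k)),
                    parameters = as.numeric(ks),
                    method = paste0("hac_", linkage))
}
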