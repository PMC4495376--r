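#' Multidimensional scaling by stress majorization
#'
#' Embeds the objects of a dissimilarity matrix into 2 or 3 dimensions so
#' that the embedded pairwise distances reproduce the input distances as
#' closely as possible, minimizing the raw stress
#' `S(z_1, ..., z_N) = sum_{i != j} (d_ij - ||z_i - z_j||)^2`.
#' The configuration is initialized by classical scaling (double-centred
#' eigendecomposition) and refined by SMACOF majorization (the Guttman
#' transform), which guarantees a non-increasing stress sequence. The
#' seed is only consulted when classical scaling is degenerate (fewer
#' positive eigenvalues than requested dimensions) and the missing
#' coordinates must be jittered.
#'
#' Coordinates are determined only up to rotation, reflection and
#' translation; compare embedded distance matrices, never raw
#' coordinates.
#'
#' @param dissim a [relation_matrix-class] of kind `"dissimilarity"`.
#' @param dim 2 or 3.
#' @param seed integer seed (used only for degenerate initialization).
#' @param max_iter maximum majorization iterations.
#' @param tol stop when the relative stress improvement falls below this.
#' @return object of class `"mds_embedding"`: list with `points`
#'   (N x dim matrix, rownames = object ids), `stress` (final raw
#'   stress), `stress_trace` (per-iteration values, starting with the
#'   initial configuration) and `iterations`.
#' @export
mds_embed <- function(dissim, dim = 2L, seed = 1L, max_iter = 300L,
                      tol = 1e-6) {
  check_dissimilarity(dissim, "mds_embed")
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop_data("dim must be 2 or 3")
  D <- unclass_relation(dissim)
  n <- nrow(D)
  if (n < dim + 1L) stop_data("need at least dim + 1 objects to embed")

  Z <- classical_init(D, dim, seed)
  stress <- raw_stress(D, Z)
  trace <- stress
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    Z <- guttman_transform(D, Z)
    new_stress <- raw_stress(D, Z)
    trace <- c(trace, new_stress)
    iterations <- it
    if (stress > 0 && (stress - new_stress) / stress < tol) {
      stress <- new_stress
      break
    }
    stress <- new_stress
    if (stress == 0) break
  }
  rownames(Z) <- rownames(D)
  structure(list(points = Z, stress = stress, stress_trace = trace,
                 iterations = iterations),
            class = "mds_embedding")
}

classical_init <- function(D, dim, seed) {
  n <- nrow(D)
  cm <- suppressWarnings(stats::cmdscale(D, k = dim))
  Z <- matrix(0, n, dim)
  if (ncol(cm) > 0L) Z[, seq_len(ncol(cm))] <- cm
  if (ncol(cm) < dim) {
    scale <- max(D) / 1000
    if (scale == 0) scale <- 1e-6
    Z[, (ncol(cm) + 1L):dim] <- with_seed(seed, {
      matrix(stats::runif(n * (dim - ncol(cm)), -scale, scale),
             n, dim - ncol(cm))
    })
  }
  Z
}

# Raw stress of Eq.-style objective: sum over ordered pairs i != j.
raw_stress <- function(D, Z) {
  E <- as.matrix(stats::dist(Z))
  sum((D - E)^2)
}

guttman_transform <- function(D, Z) {
  n <- nrow(D)
  E <- as.matrix(stats::dist(Z))
  B <- matrix(0, n, n)
  pos <- E > 0
  B[pos] <- -D[pos] / E[pos]
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  (B %*% Z) / n
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("MDS embedding of %d objects in %d dimensions; raw stress %.6g after %d iterations\n",
              nrow(x$points), ncol(x$points), x$stress, x$iterations))
  invisible(x)
}

#' Write MDS coordinates as TSV
#'
#' One line per object: `object_id`, the coordinates, and optionally the
#' cluster id from a clustering (for downstream colour-coding).
#'
#' @param embedding an [mds_embed()] result.
#' @param path destination path.
#' @param cl optional [clustering()] over the same objects.
#' @export
write_embedding <- function(embedding, path, cl = NULL) {
  stopifnot(inherits(embedding, "mds_embedding"))
  Z <- embedding$points
  header <- c("object_id", paste0("z", seq_len(ncol(Z))))
  rows <- cbind(rownames(Z), apply(Z, 2L, num_fmt))
  if (!is.null(cl)) {
    stopifnot(inherits(cl, "clustering"))
    header <- c(header, "cluster_id")
    rows <- cbind(rows, as.character(as.integer(cl)[match(rownames(Z), names(cl))]))
  }
  lines <- c(paste(header, collapse = "\t"),
             apply(rows, 1L, paste, collapse = "\t"))
  write_lines_checked(lines, path)
}
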