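# Independent oracles: literal transcriptions of the defining formulas and
# naive brute-force procedures, kept deliberately separate from the package's
# implementation paths.

# Product-moment correlation, written out term by term.
pearson_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  num <- sum((x - xb) * (y - yb))
  num / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# Euclidean distance, written out term by term.
euclidean_oracle <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  sqrt(acc)
}

# Naive hierarchical agglomeration: keeps explicit member lists and
# recomputes every cross-pair linkage distance from the original matrix at
# every step (no Lance-Williams updates). Same deterministic tie rule as
# the implementation: lexicographically smallest (min member id, other
# cluster's min member id).
naive_hac_heights <- function(D, linkage) {
  ids <- rownames(D)
  clusters <- as.list(ids)
  heights <- numeric(0)
  link <- function(A, B) {
    d <- as.vector(D[A, B])
    switch(linkage, single = min(d), complete = max(d), average = mean(d))
  }
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        h <- link(clusters[[a]], clusters[[b]])
        ra <- min(clusters[[a]])
        rb <- min(clusters[[b]])
        lo <- min(ra, rb)
        hi <- max(ra, rb)
        if (is.null(best) || h < best$h ||
            (h == best$h && (lo < best$lo ||
                             (lo == best$lo && hi < best$hi)))) {
          best <- list(a = a, b = b, h = h, lo = lo, hi = hi)
        }
      }
    }
    heights <- c(heights, best$h)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  heights
}

# All set partitions of n labelled objects, as restricted-growth assignment
# vectors (cluster of object 1 is always 1).
all_partitions <- function(n) {
  out <- list()
  grow <- function(assign, maxc) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (c in seq_len(maxc + 1L)) grow(c(assign, c), max(maxc, c))
  }
  grow(integer(0), 0L)
  out
}

# Edit cost of a partition on a cost matrix, written as an explicit loop:
# separated pairs with positive cost pay the cost, joined pairs with
# negative cost pay the magnitude.
edit_cost_oracle <- function(C, assign) {
  total <- 0
  n <- length(assign)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (assign[i] == assign[j]) {
        if (C[i, j] < 0) total <- total - C[i, j]
      } else {
        if (C[i, j] > 0) total <- total + C[i, j]
      }
    }
  }
  total
}

min_edit_cost_by_enumeration <- function(C) {
  min(vapply(all_partitions(nrow(C)), function(p) edit_cost_oracle(C, p),
             numeric(1L)))
}

# Per-object silhouette transcription: a_i = mean dissimilarity within the
# own cluster, b_i = smallest mean dissimilarity to another cluster,
# singletons score 0.
silhouette_oracle <- function(D, assign) {
  n <- length(assign)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i] & seq_len(n) != i)
    if (length(own) == 0L) {
      s[i] <- 0
      next
    }
    a_i <- mean(D[i, own])
    b_i <- Inf
    for (k in setdiff(unique(assign), assign[i])) {
      b_i <- min(b_i, mean(D[i, assign == k]))
    }
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Contingency-table transcription of the clustering F-measure.
fmeasure_oracle <- function(assign_c, assign_k) {
  ks <- unique(assign_k)
  cs <- unique(assign_c)
  total <- 0
  for (ki in ks) {
    Ki <- which(assign_k == ki)
    best <- 0
    for (cj in cs) {
      Cj <- which(assign_c == cj)
      t_ij <- length(intersect(Ki, Cj))
      best <- max(best, 2 * t_ij / (length(Cj) + length(Ki)))
    }
    total <- total + length(Ki) * best
  }
  total / length(assign_k)
}

# --- random-instance generators --------------------------------------

random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(runif(n * 3), n)
  ids <- sprintf("o%02d", seq_len(n))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(ids, ids)
  breathclust:::new_relation_matrix(d, "dissimilarity", "euclidean")
}

random_similarity <- function(n, seed) {
  set.seed(seed)
  s <- matrix(runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  ids <- sprintf("v%02d", seq_len(n))
  dimnames(s) <- list(ids, ids)
  breathclust:::new_relation_matrix(s, "similarity", "pearson", absolute = TRUE)
}

random_peak_matrix <- function(n_samples, n_metabolites, seed) {
  set.seed(seed)
  peak_matrix(matrix(rnorm(n_samples * n_metabolites), n_samples,
                     dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                     sprintf("m%02d", seq_len(n_metabolites)))))
}

named_clustering <- function(assign, ids = sprintf("o%02d", seq_along(assign))) {
  clustering(setNames(as.integer(assign), ids))
}

# Which subset of a workflow result holds exactly the metabolites of one
# planted group; NA if no subset matches.
subset_of_group <- function(result, groups, group_name) {
  target <- names(groups)[groups == group_name]
  for (nm in names(result$subsets)) {
    if (setequal(colnames(result$subsets[[nm]]), target)) return(nm)
  }
  NA_character_
}

peak_f <- function(result, subset_name, label) {
  r <- result$ranking
  r$peak_f[r$subset == subset_name & r$label == label]
}
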