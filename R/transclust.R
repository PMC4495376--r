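#' Transitivity clustering by weighted cluster editing
#'
#' A similarity matrix and a threshold T define a cost graph: every
#' unordered object pair carries cost `s(u, v) - T`, and pairs with
#' strictly positive cost are the edges of the thresholded similarity
#' graph. Transitivity clustering edits this graph into a disjoint union
#' of cliques at minimal total cost, where deleting a positive-cost edge
#' costs its cost and inserting a missing edge (negative cost) costs its
#' magnitude; zero-cost pairs are free. Each connected component of the
#' thresholded graph is solved independently — exactly by
#' branch-and-bound up to `exact_cap` vertices, otherwise by a seeded
#' randomized pivot heuristic with greedy relocation.
#'
#' @name transclust-module
NULL

#' Build the cost graph for one threshold
#'
#' @param sim a [relation_matrix-class] of kind `"similarity"`.
#' @param threshold similarity threshold T.
#' @return object of class `"cost_graph"`: list with `ids`, `costs`
#'   (symmetric matrix `s - T`, diagonal zeroed) and `threshold`.
#' @export
build_cost_graph <- function(sim, threshold) {
  if (!inherits(sim, "relation_matrix") || attr(sim, "kind") != "similarity") {
    stop_data("build_cost_graph needs a similarity matrix; convert a ",
              "dissimilarity with convert_relation() first")
  }
  if (!is.finite(threshold)) stop_data("threshold must be finite")
  costs <- unclass_relation(sim) - threshold
  diag(costs) <- 0
  structure(list(ids = rownames(costs), costs = costs, threshold = threshold),
            class = "cost_graph")
}

# Edit cost of a partition: separated positive-cost pairs pay their cost,
# joined negative-cost pairs pay the magnitude.
partition_edit_cost <- function(costs, assign) {
  n <- length(assign)
  if (n < 2L) return(0)
  same <- outer(assign, assign, "==")
  up <- upper.tri(costs)
  sum(pmax(0, costs[up & !same])) + sum(pmax(0, -costs[up & same]))
}

# Connected components over strictly positive-cost pairs.
positive_components <- function(costs) {
  n <- nrow(costs)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(costs[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Exact cluster editing of one component by branch-and-bound
#'
#' Searches vertex-to-cluster assignments in canonical order, pruning with
#' an admissible lower bound (incurred cost plus, for every unplaced
#' vertex, the cheapest way to attach it to the clusters formed so far).
#' The search is warm-started with the pivot heuristic, so the returned
#' cost never exceeds the heuristic's. Guaranteed optimal.
#'
#' @param g a [build_cost_graph()] result.
#' @param component character vector of vertex ids to solve (default: all
#'   vertices of `g`).
#' @param exact_cap refuse components larger than this (the search is
#'   exponential in the worst case).
#' @return object of class `"editing_solution"`: list with `clustering`
#'   (a [clustering()] of the component), `total_cost` and `exact`.
#' @export
solve_exact <- function(g, component = NULL, exact_cap = 13L) {
  stopifnot(inherits(g, "cost_graph"))
  if (is.null(component)) component <- g$ids
  idx <- match(component, g$ids)
  if (anyNA(idx)) stop_data("unknown vertex id: '", component[which(is.na(idx))[1L]], "'")
  k <- length(idx)
  if (k > exact_cap) {
    stop_data("component of size ", k, " exceeds the exact-size cap (",
              exact_cap, "); use solve_heuristic()")
  }
  C <- g$costs[idx, idx, drop = FALSE]
  if (k == 1L) {
    return(editing_solution(stats::setNames(1L, component), 0, TRUE, g$threshold))
  }

  warm <- heuristic_partition(C, restarts = 5L, seed = 1L)
  best_assign <- warm$assign
  best_cost <- warm$cost

  assign <- integer(k)

  recurse <- function(pos, nclust, partial) {
    if (pos > k) {
      if (partial < best_cost) {
        best_cost <<- partial
        best_assign <<- assign[seq_len(k)]
      }
      return(invisible(NULL))
    }
    placed <- seq_len(pos - 1L)
    # attachment sums of vertex u to each existing cluster
    attach_sums <- function(u) {
      if (pos == 1L) return(numeric(0))
      cu <- C[u, placed]
      vapply(seq_len(nclust), function(c) sum(cu[assign[placed] == c]), numeric(1L))
    }
    # admissible bound: every unplaced vertex pays at least its cheapest
    # attachment cost against the vertices already placed
    bound <- partial
    for (u in pos:k) {
      cu <- C[u, placed]
      base <- sum(pmax(0, cu))
      s <- if (pos == 1L) numeric(0) else
        vapply(seq_len(nclust), function(c) sum(cu[assign[placed] == c]), numeric(1L))
      bound <- bound + base - max(0, if (length(s)) max(s) else 0)
      if (bound >= best_cost) return(invisible(NULL))
    }
    cu <- C[pos, placed]
    base <- sum(pmax(0, cu))
    s <- attach_sums(pos)
    order_c <- order(-s)
    for (c in c(order_c, nclust + 1L)) {
      inc <- if (c <= nclust) base - s[c] else base
      if (partial + inc >= best_cost) next
      assign[pos] <<- c
      recurse(pos + 1L, max(nclust, c), partial + inc)
    }
    assign[pos] <<- 0L
    invisible(NULL)
  }
  recurse(1L, 0L, 0)

  editing_solution(stats::setNames(best_assign, component), best_cost, TRUE,
                   g$threshold)
}

editing_solution <- function(assign, cost, exact, threshold) {
  structure(list(clustering = clustering(assign, method = "transclust",
                                         parameter = threshold),
                 total_cost = cost, exact = exact),
            class = "editing_solution")
}

#' @export
print.editing_solution <- function(x, ...) {
  cat(sprintf("cluster editing solution (%s): %d clusters, edit cost %.6g\n",
              if (x$exact) "exact" else "heuristic",
              n_clusters(x$clustering), x$total_cost))
  invisible(x)
}

# Randomized pivot partition + greedy single-vertex relocation, best of
# `restarts` seeded restarts. Returns list(assign, cost).
heuristic_partition <- function(C, restarts, seed) {
  k <- nrow(C)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      ord <- sample.int(k)
      assign <- integer(k)
      nclust <- 0L
      for (v in ord) {
        if (assign[v] != 0L) next
        nclust <- nclust + 1L
        assign[v] <- nclust
        free <- which(assign == 0L)
        grab <- free[C[v, free] > 0]
        assign[grab] <- nclust
      }
      assign <- relocate_to_local_min(C, assign)
      cost <- partition_edit_cost(C, assign)
      if (is.null(best) || cost < best$cost) best <- list(assign = assign, cost = cost)
    }
  })
  best$assign <- match(best$assign, unique(best$assign))
  best
}

relocate_to_local_min <- function(C, assign, max_rounds = 100L) {
  k <- length(assign)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (u in seq_len(k)) {
      others <- setdiff(seq_len(k), u)
      cu <- C[u, others]
      cl <- assign[others]
      ids <- unique(assign)
      s <- vapply(ids, function(c) sum(cu[cl == c]), numeric(1L))
      own <- s[match(assign[u], ids)]
      cand <- c(s, 0)                      # 0 = open a new singleton cluster
      best_c <- which.max(cand)
      if (cand[best_c] > own + 1e-12) {
        assign[u] <- if (best_c <= length(ids)) ids[best_c] else max(ids) + 1L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  assign
}

#' Heuristic cluster editing of one component
#'
#' Randomized pivot clustering (pick a pivot, absorb its positive-cost
#' neighbours) followed by greedy single-vertex relocation to a local
#' cost minimum; the best of `restarts` seeded restarts is returned.
#' Deterministic for a fixed seed.
#'
#' @inheritParams solve_exact
#' @param seed integer seed for the randomized restarts.
#' @param restarts number of restarts.
#' @return an `"editing_solution"` with `exact = FALSE`.
#' @export
solve_heuristic <- function(g, component = NULL, seed = 1L, restarts = 25L) {
  stopifnot(inherits(g, "cost_graph"))
  if (is.null(component)) component <- g$ids
  idx <- match(component, g$ids)
  if (anyNA(idx)) stop_data("unknown vertex id: '", component[which(is.na(idx))[1L]], "'")
  C <- g$costs[idx, idx, drop = FALSE]
  if (length(idx) == 1L) {
    return(editing_solution(stats::setNames(1L, component), 0, FALSE, g$threshold))
  }
  h <- heuristic_partition(C, restarts = restarts, seed = seed)
  editing_solution(stats::setNames(h$assign, component), h$cost, FALSE,
                   g$threshold)
}

#' Transitivity clustering over a threshold sweep
#'
#' For each threshold, thresholds the similarity into a cost graph,
#' decomposes it into connected components over positive-cost pairs
#' (loss-free, since no positive pair crosses components) and solves each
#' component exactly when it has at most `exact_cap` vertices, otherwise
#' heuristically. High thresholds give many small clusters, low
#' thresholds few large ones.
#'
#' @param sim a [relation_matrix-class] of kind `"similarity"`.
#' @param thresholds strictly increasing numeric vector of similarity
#'   thresholds.
#' @param seed integer seed controlling the heuristic restarts.
#' @param exact_cap largest component size solved exactly.
#' @param restarts heuristic restarts per component.
#' @return a [clustering_result()]; each clustering carries attributes
#'   `total_cost` and `all_exact`.
#' @export
transclust <- function(sim, thresholds, seed = 1L, exact_cap = 13L,
                       restarts = 25L) {
  if (!inherits(sim, "relation_matrix") || attr(sim, "kind") != "similarity") {
    stop_data("transclust needs a similarity matrix; convert a dissimilarity ",
              "with convert_relation() first")
  }
  if (length(thresholds) < 1L) stop_data("at least one threshold required")
  thresholds <- sort(unique(as.numeric(thresholds)))
  clusterings <- vector("list", length(thresholds))
  for (t in seq_along(thresholds)) {
    g <- build_cost_graph(sim, thresholds[t])
    comp <- positive_components(g$costs)
    assign <- integer(length(g$ids))
    total_cost <- 0
    all_exact <- TRUE
    offset <- 0L
    for (c in seq_len(max(comp))) {
      members <- g$ids[comp == c]
      sol <- if (length(members) <= exact_cap) {
        solve_exact(g, members, exact_cap = exact_cap)
      } else {
        all_exact <- FALSE
        solve_heuristic(g, members, seed = derive_seed(seed, t * 1000L + c),
                        restarts = restarts)
      }
      assign[comp == c] <- as.integer(sol$clustering)[match(members, names(sol$clustering))] + offset
      offset <- offset + n_clusters(sol$clustering)
      total_cost <- total_cost + sol$total_cost
    }
    cl <- clustering(stats::setNames(assign, g$ids), method = "transclust",
                     parameter = thresholds[t])
    attr(cl, "total_cost") <- total_cost
    attr(cl, "all_exact") <- all_exact
    clusterings[[t]] <- cl
  }
  clustering_result(clusterings, thresholds, method = "transclust")
}
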