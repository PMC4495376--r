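#' Configuration of the layered cross-clustering workflow
#'
#' Controls every stage of [cross_cluster()]: how metabolite relations
#' are computed and clustered, how the metabolite cut is selected, the
#' minimum subset size, how samples are re-clustered inside each subset,
#' and which annotation labels are scored.
#'
#' @param metabolite_measure relation measure over metabolites
#'   (`"pearson"`, `"spearman"` or `"euclidean"`).
#' @param metabolite_absolute take absolute correlations (default TRUE).
#' @param metabolite_method `"hac"` or `"transclust"`.
#' @param metabolite_linkage HAC linkage for the metabolite stage.
#' @param metabolite_cut `"silhouette"` (pick the cut maximizing the
#'   silhouette curve) or a fixed numeric parameter (cluster count for
#'   HAC, threshold for transitivity clustering).
#' @param transclust_thresholds threshold sweep when
#'   `metabolite_method = "transclust"`.
#' @param min_subset_size discard metabolite clusters smaller than this
#'   (default 3).
#' @param sample_measure relation measure over samples (default
#'   `"euclidean"`).
#' @param sample_linkage HAC linkage for the sample stage.
#' @param labels annotation labels to score; `NULL` = all labels in the
#'   annotation table.
#' @param seed integer seed for all randomized stages.
#' @return object of class `"workflow_config"`.
#' @export
workflow_config <- function(metabolite_measure = "pearson",
                            metabolite_absolute = TRUE,
                            metabolite_method = c("hac", "transclust"),
                            metabolite_linkage = "average",
                            metabolite_cut = "silhouette",
                            transclust_thresholds = seq(0.1, 0.95, by = 0.05),
                            min_subset_size = 3L,
                            sample_measure = "euclidean",
                            sample_linkage = "average",
                            labels = NULL,
                            seed = 1L) {
  metabolite_method <- match.arg(metabolite_method)
  if (min_subset_size < 1L) stop_data("min_subset_size must be >= 1")
  if (!(identical(metabolite_cut, "silhouette") ||
        (is.numeric(metabolite_cut) && length(metabolite_cut) == 1L))) {
    stop_data("metabolite_cut must be \"silhouette\" or a single number")
  }
  structure(list(metabolite_measure = metabolite_measure,
                 metabolite_absolute = metabolite_absolute,
                 metabolite_method = metabolite_method,
                 metabolite_linkage = metabolite_linkage,
                 metabolite_cut = metabolite_cut,
                 transclust_thresholds = transclust_thresholds,
                 min_subset_size = as.integer(min_subset_size),
                 sample_measure = sample_measure,
                 sample_linkage = sample_linkage,
                 labels = labels,
                 seed = as.integer(seed)),
            class = "workflow_config")
}

#' Split a peak matrix by a metabolite clustering
#'
#' Produces one sub-matrix per metabolite cluster of at least `min_size`
#' members (all samples retained, columns restricted to the cluster).
#' Smaller clusters are discarded with a message — in a confounder
#' screen, tiny clusters carry too little signal to re-cluster samples
#' on.
#'
#' @param data a [peak_matrix()].
#' @param metab_clustering a [clustering()] over the metabolite axis of
#'   `data`.
#' @param min_size minimum cluster size to keep.
#' @return named list of peak matrices (`subset_<cluster id>`).
#' @export
split_by_clusters <- function(data, metab_clustering, min_size = 3L) {
  data <- peak_matrix(data)
  stopifnot(inherits(metab_clustering, "clustering"))
  if (!setequal(names(metab_clustering), colnames(data))) {
    stop_data("clustering is not over the metabolite axis of the matrix")
  }
  members <- cluster_members(metab_clustering)
  keep <- lengths(members) >= min_size
  if (any(!keep)) {
    message("discarding ", sum(!keep), " metabolite cluster(s) smaller than ",
            min_size)
  }
  out <- lapply(members[keep], function(ids) data[, ids, drop = FALSE])
  names(out) <- if (length(out)) paste0("subset_", names(members)[keep]) else character(0)
  out
}

#' Layered cross-clustering of metabolites and samples
#'
#' The confounder screen: (1) compute the metabolite relation matrix and
#' (2) cluster the metabolites; (3) select the cut — silhouette-optimal
#' or fixed; (4) split the matrix into one subset per surviving
#' metabolite cluster; (5) inside each subset, and on the full matrix as
#' the baseline, compute the sample dissimilarity (Euclidean by
#' default, separately per subset), sweep a sample clustering, and score
#' it against every annotation label with an F-measure curve; (6) rank
#' the subsets by peak F-measure per label. A subset whose curve peaks
#' high for a confounder label (smoking, nutrition) but not for the
#' disease label carries confounder signal — and masking metabolites can
#' be excluded from downstream disease analysis. Deterministic given
#' `cfg$seed`.
#'
#' @param data a [peak_matrix()].
#' @param ann a [sample_annotations()] covering the samples of `data`.
#' @param cfg a [workflow_config()].
#' @return object of class `"workflow_result"`: list with
#'   `metabolite_clustering`, `metabolite_curve` (silhouette curve when
#'   the cut rule is silhouette), `subsets`, `sample_results` (one
#'   [clustering_result()] per subset and for `"full_matrix"`), `curves`
#'   (subset -> label -> [quality_curve()]) and `ranking` (data frame:
#'   subset, label, peak F-measure, parameter at peak).
#' @export
cross_cluster <- function(data, ann, cfg = workflow_config()) {
  data <- peak_matrix(data)
  ann <- sample_annotations(ann)
  stopifnot(inherits(cfg, "workflow_config"))
  missing_samples <- setdiff(rownames(data), rownames(ann))
  if (length(missing_samples)) {
    stop_data("stage annotations: samples without annotations: ",
              paste(utils::head(missing_samples, 3L), collapse = ", "))
  }
  labels <- if (is.null(cfg$labels)) colnames(ann) else cfg$labels
  unknown <- setdiff(labels, colnames(ann))
  if (length(unknown)) {
    stop_data("stage annotations: unknown label(s): ",
              paste(unknown, collapse = ", "))
  }

  # --- stage 1-3: metabolite clustering and cut selection -------------
  met_rel <- relation_matrix(data, axis = "metabolites",
                             measure = cfg$metabolite_measure,
                             absolute = cfg$metabolite_absolute)
  met_dissim <- if (attr(met_rel, "kind") == "similarity") {
    convert_relation(met_rel)
  } else {
    met_rel
  }
  if (cfg$metabolite_method == "hac") {
    met_sweep <- sweep_hac(met_dissim, cfg$metabolite_linkage)
  } else {
    met_sim <- if (attr(met_rel, "kind") == "similarity") met_rel else convert_relation(met_rel)
    met_sweep <- transclust(met_sim, cfg$transclust_thresholds,
                            seed = derive_seed(cfg$seed, 1L))
  }
  met_curve <- NULL
  if (identical(cfg$metabolite_cut, "silhouette")) {
    met_curve <- quality_curve(met_sweep, "silhouette", dissim = met_dissim,
                               subject = "metabolites")
    cut_at <- best_parameter(met_curve)
  } else {
    cut_at <- as.numeric(cfg$metabolite_cut)
  }
  sel <- which(met_sweep$parameters == cut_at)
  if (length(sel) != 1L) {
    stop_data("stage metabolite_cut: parameter ", cut_at, " not in the sweep")
  }
  met_clustering <- met_sweep$clusterings[[sel]]

  # --- stage 4: split -------------------------------------------------
  subsets <- split_by_clusters(data, met_clustering, cfg$min_subset_size)
  if (length(subsets) == 0L) {
    warning("no metabolite cluster reached min_subset_size = ",
            cfg$min_subset_size, "; only the full-matrix baseline is scored",
            call. = FALSE)
  }

  # --- stage 5: per-subset sample clustering and scoring --------------
  units <- c(subsets, list(full_matrix = data))
  sample_results <- list()
  curves <- list()
  for (nm in names(units)) {
    sub <- units[[nm]]
    samp_rel <- relation_matrix(sub, axis = "samples",
                                measure = cfg$sample_measure,
                                absolute = cfg$metabolite_absolute)
    samp_dissim <- if (attr(samp_rel, "kind") == "dissimilarity") {
      samp_rel
    } else {
      convert_relation(samp_rel)
    }
    sweep <- sweep_hac(samp_dissim, cfg$sample_linkage)
    sample_results[[nm]] <- sweep
    curves[[nm]] <- lapply(labels, function(lab) {
      quality_curve(sweep, "fmeasure",
                    gold = gold_standard(ann, lab, rownames(sub)),
                    label = lab, subject = paste0("samples|", nm))
    })
    names(curves[[nm]]) <- labels
  }

  # --- stage 6: ranking -----------------------------------------------
  ranking <- do.call(rbind, lapply(names(curves), function(nm) {
    do.call(rbind, lapply(labels, function(lab) {
      pk <- curve_peak(curves[[nm]][[lab]])
      data.frame(subset = nm, label = lab, peak_f = pk$value,
                 parameter = pk$parameter, stringsAsFactors = FALSE)
    }))
  }))
  rownames(ranking) <- NULL

  structure(list(metabolite_clustering = met_clustering,
                 metabolite_curve = met_curve,
                 subsets = subsets,
                 sample_results = sample_results,
                 curves = curves,
                 ranking = ranking,
                 config = cfg),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("cross-clustering result: %d metabolite clusters, %d subset(s) scored (+ baseline)\n",
              n_clusters(x$metabolite_clustering), length(x$subsets)))
  print(x$ranking, ...)
  invisible(x)
}

#' Rank metabolite subsets by peak F-measure for one label
#'
#' Orders the subsets by how well their sample clusterings recover the
#' given annotation label, descending; ties break by subset name. The
#' full-matrix baseline is appended as the last row for comparison, with
#' the rank it would take among the subsets.
#'
#' @param result a [cross_cluster()] result.
#' @param label annotation label evaluated in the result.
#' @return the ranking data frame rows for `label`, best subset first,
#'   baseline last.
#' @export
rank_subsets <- function(result, label) {
  stopifnot(inherits(result, "workflow_result"))
  r <- result$ranking[result$ranking$label == label, , drop = FALSE]
  if (nrow(r) == 0L) stop_data("label '", label, "' was not evaluated")
  base <- r[r$subset == "full_matrix", , drop = FALSE]
  r <- r[r$subset != "full_matrix", , drop = FALSE]
  r <- r[order(-r$peak_f, r$subset, method = "radix"), , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  base$rank <- sum(r$peak_f > base$peak_f) + 1L
  r <- rbind(r, base)
  rownames(r) <- NULL
  r
}

#' Select one representative object per cluster
#'
#' Returns the medoid of each cluster: the member with the maximal mean
#' similarity to its co-members (singletons represent themselves). Ties
#' break toward the object id that sorts first.
#'
#' @param cl a [clustering()].
#' @param sim a [relation_matrix-class] of kind `"similarity"` over the
#'   same objects.
#' @return named character vector: cluster id -> representative object
#'   id.
#' @export
select_representatives <- function(cl, sim) {
  stopifnot(inherits(cl, "clustering"))
  if (!inherits(sim, "relation_matrix") || attr(sim, "kind") != "similarity") {
    stop_data("select_representatives needs a similarity matrix")
  }
  s <- align_relation(sim, names(cl))
  members <- cluster_members(cl)
  reps <- vapply(members, function(ids) {
    if (length(ids) == 1L) return(ids)
    ord <- ids[order(id_rank(ids))]
    means <- vapply(ord, function(i) mean(s[i, setdiff(ids, i)]), numeric(1L))
    ord[which.max(means)]
  }, character(1L))
  reps
}
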