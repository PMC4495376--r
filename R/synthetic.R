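#' Configuration for the planted-group synthetic dataset
#'
#' Describes an idealized breathomics study: a small cohort annotated
#' with categorical labels, and groups of metabolites whose intensities
#' depend on exactly one label each. The defaults reproduce the standard
#' demonstration design — 16 samples, three labels ("health" with value
#' counts 5/5/6, "smoking" 9/7, "nutrition" 4/4/4/4) and three metabolite
#' groups of 4 metabolites, one group per label. Intensities are drawn
#' from per-(group, label value) normal distributions.
#'
#' Default signal geometry: unit standard deviation, baseline mean 10 and
#' a `level_step` of 6 between consecutive label values, i.e. adjacent
#' value means sit 6 SDs apart — comfortably separated, as befits a
#' proof-of-concept dataset. The smoking group is the planted confounder:
#' its two value means are separated by `confounder_dominance` (default
#' 2) times the *total* spread of the health group's means, so that a
#' clustering of samples over the full metabolite set is dominated by
#' smoking status rather than by the disease label.
#'
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @param metabolites_per_group metabolites in each planted group.
#' @param sd standard deviation of every intensity distribution
#'   (intensity units).
#' @param baseline_mean mean of the first level of every group.
#' @param level_step mean separation between consecutive label values, in
#'   SD units of the intensity noise.
#' @param confounder_dominance multiplier applied to the health group's
#'   total mean spread to obtain the smoking group's separation.
#' @param labels named list: label name -> named integer vector of
#'   per-value sample counts. All labels must sum to the same total.
#' @param groups optional named list overriding the generated group
#'   definitions; each entry needs `label`, `means` (named by label
#'   value) and `sd`.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             metabolites_per_group = 4L,
                             sd = 1,
                             baseline_mean = 10,
                             level_step = 6,
                             confounder_dominance = 2,
                             labels = NULL,
                             groups = NULL) {
  if (is.null(labels)) {
    labels <- list(
      health    = c(healthy = 5L, subtype1 = 5L, subtype2 = 6L),
      smoking   = c(smoker = 9L, non_smoker = 7L),
      nutrition = c(apple_juice = 4L, tea = 4L, orange_juice = 4L, coffee = 4L)
    )
  }
  totals <- vapply(labels, sum, numeric(1L))
  if (length(unique(totals)) != 1L) {
    stop_data("per-label sample counts must sum to the same total (got ",
              paste(totals, collapse = ", "), ")")
  }
  if (metabolites_per_group < 1L) stop_data("metabolites_per_group must be >= 1")
  if (sd <= 0) stop_data("sd must be positive")
  if (is.null(groups)) {
    level_means <- function(values, step) {
      stats::setNames(baseline_mean + step * (seq_along(values) - 1L), values)
    }
    groups <- lapply(names(labels), function(lab) {
      values <- names(labels[[lab]])
      step <- level_step
      if (lab == "smoking" && "health" %in% names(labels)) {
        health_spread <- level_step * (length(labels$health) - 1L)
        step <- confounder_dominance * health_spread
      }
      list(label = lab, means = level_means(values, step), sd = sd)
    })
    names(groups) <- names(labels)
  }
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (!grp$label %in% names(labels)) {
      stop_data("group '", g, "' references unknown label '", grp$label, "'")
    }
    if (!setequal(names(grp$means), names(labels[[grp$label]]))) {
      stop_data("group '", g, "' must define one mean per value of label '",
                grp$label, "'")
    }
  }
  structure(list(seed = as.integer(seed),
                 metabolites_per_group = as.integer(metabolites_per_group),
                 labels = labels, groups = groups),
            class = "synthetic_config")
}

#' Generate the planted-group artificial dataset
#'
#' Assigns each sample one value per label by an independent random
#' permutation honouring the exact per-value counts (so the labels are
#' approximately independent of each other), then draws every intensity
#' from the normal distribution of its metabolite's group at the sample's
#' value of the group's label. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `data` (a [peak_matrix()], default 16 x 12),
#'   `annotations` (a [sample_annotations()] data frame) and `groups`
#'   (named factor: metabolite id -> planted group).
#' @export
generate_artificial <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- sum(cfg$labels[[1L]])
  sample_ids <- sprintf("s%02d", seq_len(n))
  n_met <- length(cfg$groups) * cfg$metabolites_per_group
  met_ids <- sprintf("m%02d", seq_len(n_met))
  group_of <- factor(rep(names(cfg$groups), each = cfg$metabolites_per_group),
                     levels = names(cfg$groups))
  names(group_of) <- met_ids

  with_seed(cfg$seed, {
    ann <- as.data.frame(
      lapply(cfg$labels, function(counts) {
        sample(rep(names(counts), counts))
      }),
      col.names = names(cfg$labels)
    )
    rownames(ann) <- sample_ids
    ann <- sample_annotations(ann)

    values <- matrix(NA_real_, n, n_met, dimnames = list(sample_ids, met_ids))
    for (j in seq_len(n_met)) {
      grp <- cfg$groups[[as.character(group_of[j])]]
      mu <- grp$means[as.character(ann[[grp$label]])]
      values[, j] <- stats::rnorm(n, mean = mu, sd = grp$sd)
    }
    list(data = peak_matrix(values), annotations = ann, groups = group_of)
  })
}

#' Write the synthetic fixture to disk
#'
#' Writes the peak matrix, the annotation table, the planted group map
#' and the generating configuration (as JSON) into a directory. Two runs
#' with the same config produce byte-identical files.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir destination directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gen <- generate_artificial(cfg)
  paths <- file.path(out_dir, c("matrix.tsv", "annotations.tsv",
                                "groups.tsv", "config.json"))
  write_peak_matrix(gen$data, paths[1L])
  write_annotations(gen$annotations, paths[2L])
  write_lines_checked(
    c("metabolite_id\tgroup",
      paste(names(gen$groups), as.character(gen$groups), sep = "\t")),
    paths[3L])
  jsonlite::write_json(
    list(seed = cfg$seed,
         metabolites_per_group = cfg$metabolites_per_group,
         labels = cfg$labels,
         groups = lapply(cfg$groups, function(g)
           list(label = g$label, means = as.list(g$means), sd = g$sd))),
    paths[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
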