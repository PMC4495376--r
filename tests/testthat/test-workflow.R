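test_that("splitting by metabolite clusters filters small clusters", {
  gen <- generate_artificial(synthetic_config(seed = 1))
  truth <- clustering(setNames(as.integer(gen$groups), names(gen$groups)))
  subsets <- split_by_clusters(gen$data, truth, min_size = 3)
  expect_length(subsets, 3L)
  for (s in subsets) {
    expect_equal(dim(s), c(16L, 4L))
  }
  expect_length(split_by_clusters(gen$data, truth, min_size = 1), 3L)

  sizes <- c(rep(1L, 4), rep(2L, 2), rep(3L, 6))  # clusters of 4, 2, 6
  cl <- clustering(setNames(sizes, colnames(gen$data)))
  expect_message(kept <- split_by_clusters(gen$data, cl, min_size = 3),
                 "discarding 1")
  expect_equal(sort(vapply(kept, ncol, integer(1L))), c(4L, 6L),
               ignore_attr = TRUE)

  wrong <- clustering(setNames(rep(1L, 16), rownames(gen$data)))
  expect_error(split_by_clusters(gen$data, wrong, 3), "metabolite axis")
})

test_that("cross-clustering separates disease signal from confounders", {
  gen <- generate_artificial(synthetic_config(seed = 11))
  res <- cross_cluster(gen$data, gen$annotations,
                       workflow_config(seed = 11))
  expect_length(res$subsets, 3L)

  smoking_sub <- subset_of_group(res, gen$groups, "smoking")
  nutrition_sub <- subset_of_group(res, gen$groups, "nutrition")
  health_sub <- subset_of_group(res, gen$groups, "health")
  expect_false(anyNA(c(smoking_sub, nutrition_sub, health_sub)))

  # each confounder subset explains its own label perfectly
  expect_equal(peak_f(res, smoking_sub, "smoking"), 1)
  expect_equal(peak_f(res, nutrition_sub, "nutrition"), 1)

  # the confounder dominates the full-matrix baseline ...
  expect_gt(peak_f(res, "full_matrix", "smoking"),
            peak_f(res, "full_matrix", "health"))
  # ... while the disease subset beats the baseline on the disease label
  expect_gt(peak_f(res, health_sub, "health"),
            peak_f(res, "full_matrix", "health"))

  # ranking: the smoking subset explains "smoking" best
  r <- rank_subsets(res, "smoking")
  expect_identical(r$subset[1], smoking_sub)
  expect_true("full_matrix" %in% r$subset)
  expect_error(rank_subsets(res, "altitude"), "not evaluated")
})

test_that("workflow runs are deterministic and degrade gracefully", {
  gen <- generate_artificial(synthetic_config(seed = 3))
  cfg <- workflow_config(seed = 99)
  a <- cross_cluster(gen$data, gen$annotations, cfg)
  b <- cross_cluster(gen$data, gen$annotations, cfg)
  expect_identical(a$ranking, b$ranking)

  expect_warning(
    empty <- cross_cluster(gen$data, gen$annotations,
                           workflow_config(min_subset_size = 13L)),
    "min_subset_size")
  expect_length(empty$subsets, 0L)
  expect_identical(unique(empty$ranking$subset), "full_matrix")

  # the transitivity-clustering route with a fixed threshold also works
  sim <- relation_matrix(gen$data, "metabolites", "pearson")
  res_tc <- cross_cluster(gen$data, gen$annotations,
                          workflow_config(metabolite_method = "transclust",
                                          transclust_thresholds = c(0.4, 0.6),
                                          metabolite_cut = 0.6, seed = 1))
  expect_true(nrow(res_tc$ranking) > 0)
})

test_that("cluster representatives are the medoids", {
  sim <- random_similarity(9, seed = 14)
  cl <- named_clustering(c(1, 1, 1, 2, 2, 2, 2, 3, 3), rownames(sim))
  reps <- select_representatives(cl, sim)
  expect_length(reps, 3L)
  # brute force: maximal mean within-cluster similarity
  for (k in names(cluster_members(cl))) {
    ids <- cluster_members(cl)[[k]]
    means <- vapply(ids, function(i) {
      mean(sim[i, setdiff(ids, i)])
    }, numeric(1L))
    expect_equal(unname(means[reps[k]]), max(means))
  }
  single <- named_clustering(c(1, 2, 2, 2, 2, 2, 2, 2, 2), rownames(sim))
  expect_identical(unname(select_representatives(single, sim)["1"]),
                   rownames(sim)[1])
})
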