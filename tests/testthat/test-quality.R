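test_that("silhouette hits its defining extremes and conventions", {
  # two zero-diameter clusters, well separated -> overall value 1
  d <- matrix(5, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  ids <- letters[1:6]
  dimnames(d) <- list(ids, ids)
  rel <- breathclust:::new_relation_matrix(d, "dissimilarity", "euclidean")
  cl <- clustering(setNames(c(1, 1, 1, 2, 2, 2), ids))
  expect_equal(as.numeric(silhouette_value(cl, rel)), 1)

  # all singletons score 0 by convention
  singles <- clustering(setNames(1:6, ids))
  expect_equal(as.numeric(silhouette_value(singles, rel)), 0)

  # a single cluster has no between term
  expect_warning(v <- silhouette_value(clustering(setNames(rep(1, 6), ids)), rel),
                 "undefined")
  expect_true(is.na(v))

  # invariant under positive rescaling of the dissimilarities
  dd <- random_dissimilarity(8, seed = 6)
  part <- named_clustering(c(1, 2, 3, 1, 2, 3, 1, 2), rownames(dd))
  scaled <- breathclust:::new_relation_matrix(
    breathclust:::unclass_relation(dd) * 7.3, "dissimilarity", "euclidean")
  expect_equal(as.numeric(silhouette_value(part, dd)),
               as.numeric(silhouette_value(part, scaled)))
})

test_that("silhouette agrees with the cluster package on random instances", {
  for (seed in c(2, 13, 31)) {
    d <- random_dissimilarity(9, seed = seed)
    set.seed(seed)
    assign <- sample(1:3, 9, replace = TRUE)
    assign <- match(assign, unique(assign))
    cl <- named_clustering(assign, rownames(d))
    ref <- cluster::silhouette(as.integer(cl),
                               dmatrix = breathclust:::unclass_relation(d))
    expect_equal(as.numeric(silhouette_value(cl, d)),
                 mean(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("F-measure matches its contingency definition and invariances", {
  ids <- letters[1:4]
  gold <- setNames(factor(c("g1", "g1", "g2", "g2")), ids)
  cross <- clustering(setNames(c(1, 2, 1, 2), ids))
  expect_equal(f_measure(cross, gold), fmeasure_oracle(c(1, 2, 1, 2), c(1, 1, 2, 2)))

  # identity and the degenerate one-class case
  same <- clustering(setNames(c(1, 1, 2, 2), ids))
  expect_identical(f_measure(same, gold), 1)
  one <- clustering(setNames(rep(1, 4), ids))
  expect_identical(f_measure(one, setNames(factor(rep("g", 4)), ids)), 1)

  # invariance to relabeling of cluster and class ids
  relab <- clustering(setNames(c(2, 2, 1, 1), ids))
  gold_relab <- setNames(factor(c("zz", "zz", "aa", "aa")), ids)
  expect_equal(f_measure(relab, gold_relab), f_measure(same, gold))

  expect_error(f_measure(same, gold[1:3]), "object sets disagree")
})

test_that("F-measure equals 1 exactly when the partitions are identical", {
  parts <- all_partitions(5)
  ids <- letters[1:5]
  for (a in seq_along(parts)) {
    cl <- clustering(setNames(parts[[a]], ids))
    for (b in seq_along(parts)) {
      gold <- setNames(factor(parts[[b]]), ids)
      f <- f_measure(cl, gold)
      if (a == b) {
        expect_identical(f, 1)
      } else {
        expect_lt(f, 1)
      }
    }
  }
})

test_that("curves skip undefined points and select the best parameter", {
  gen <- generate_artificial(synthetic_config(seed = 1))
  d <- convert_relation(relation_matrix(gen$data, "metabolites", "pearson"))
  sweep <- sweep_hac(d, "average")
  expect_message(curve <- quality_curve(sweep, "silhouette", dissim = d),
                 "skipped")
  expect_equal(nrow(curve), 11L)            # k = 1 is undefined, 12 - 1 points
  expect_equal(best_parameter(curve), 3)

  # an F-measure curve peaks at 1 where the sweep matches the gold standard
  gold <- gold_standard(gen$annotations, "nutrition")
  sub <- gen$data[, names(gen$groups)[gen$groups == "nutrition"]]
  ssweep <- sweep_hac(relation_matrix(sub, "samples", "euclidean"), "average")
  fcurve <- quality_curve(ssweep, "fmeasure", gold = gold, label = "nutrition")
  expect_equal(fcurve$value[fcurve$parameter == 4], 1)

  tied <- breathclust:::quality_curve_points(c(2, 3, 4), c(0.3, 0.9, 0.5),
                                             measure = "silhouette")
  expect_equal(best_parameter(tied), 3)
  flat <- breathclust:::quality_curve_points(c(2, 3, 4), rep(0.5, 3),
                                             measure = "silhouette")
  expect_equal(best_parameter(flat), 2)     # ties break toward fewer clusters
  expect_error(best_parameter(breathclust:::quality_curve_points(
    numeric(0), numeric(0), "silhouette")), "empty curve")
})
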