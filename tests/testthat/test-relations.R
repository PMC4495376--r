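test_that("scalar measures match their defining formulas", {
  expect_equal(pearson(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1)
  expect_equal(pearson(c(1, 2, 3, 5), -c(1, 2, 3, 5)), -1)
  expect_equal(pearson(c(1, 2, 3, 5), c(2, 1, 4, 6)),
               pearson_oracle(c(1, 2, 3, 5), c(2, 1, 4, 6)))

  # monotone invariance and rank definition (ties get average ranks)
  x <- c(0.3, 1.1, 2.7, 3.2)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, rev(sort(x))), -1)
  expect_equal(spearman(c(1, 2, 2, 4), c(3, 1, 5, 2)),
               pearson_oracle(rank(c(1, 2, 2, 4)), rank(c(3, 1, 5, 2))))

  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean(1:4, 1:4), 0)
  set.seed(42)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(euclidean(a, b), euclidean_oracle(a, b))
  expect_error(euclidean(1:3, 1:4), "differ in length")
  expect_warning(p <- pearson(rep(1, 4), 1:4), "zero-variance")
  expect_true(is.na(p))
})

test_that("relation_matrix matches the scalar measures elementwise", {
  data <- random_peak_matrix(4, 3, seed = 5)
  for (measure in c("pearson", "spearman")) {
    rel <- relation_matrix(data, "metabolites", measure, absolute = FALSE)
    expect_identical(attr(rel, "kind"), "similarity")
    for (i in 1:3) for (j in 1:3) {
      scalar <- if (measure == "pearson") pearson else spearman
      expect_equal(rel[i, j], if (i == j) 1 else scalar(data[, i], data[, j]))
    }
  }
  d <- relation_matrix(data, "samples", measure = "euclidean")
  expect_identical(attr(d, "kind"), "dissimilarity")
  expect_true(all(diag(d) == 0) && all(d >= 0))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d[i, j], euclidean(data[i, ], data[j, ]))
  }
})

test_that("absolute flag, zero variance and missing values are handled", {
  gen <- generate_artificial(synthetic_config(seed = 2))
  rel <- relation_matrix(gen$data, "metabolites", "pearson", absolute = TRUE)
  expect_equal(dim(rel), c(12L, 12L))
  expect_true(all(diag(rel) == 1))
  expect_true(all(rel >= 0 & rel <= 1))

  flat <- gen$data
  flat[, "m03"] <- 7
  expect_warning(r2 <- relation_matrix(flat, "metabolites", "pearson"),
                 "m03")
  expect_equal(unname(r2["m03", "m01"]), 0)
  expect_equal(unname(r2["m03", "m03"]), 1)

  holey <- gen$data
  holey[1, 2] <- NA
  expect_error(relation_matrix(holey, "metabolites", "pearson"),
               "missing values")
  r3 <- relation_matrix(holey, "metabolites", "pearson",
                        pairwise_complete = TRUE)
  expect_true(all(is.finite(r3)))
  mostly_na <- gen$data
  mostly_na[3:16, 1] <- NA
  expect_error(relation_matrix(mostly_na, "metabolites", "pearson",
                               pairwise_complete = TRUE),
               "co-observed")
})

test_that("similarity/dissimilarity conversion follows the magnitude complement", {
  rel <- random_similarity(6, seed = 9)
  rel[2, 3] <- rel[3, 2] <- 0.4
  d <- convert_relation(rel)
  expect_identical(attr(d, "kind"), "dissimilarity")
  expect_equal(unname(d[2, 3]), 0.6)        # M = 1 on the diagonal
  expect_true(all(diag(d) == 0))

  # endpoints of converting a euclidean dissimilarity
  dd <- random_dissimilarity(5, seed = 4)
  M <- max(abs(dd))
  s <- convert_relation(dd)
  at_max <- which(unclass(dd) == M, arr.ind = TRUE)[1L, ]
  expect_equal(unname(s[at_max[1L], at_max[2L]]), 0)
  expect_equal(unname(diag(s)), rep(M, 5))

  # order reversal, checked pairwise over all entry pairs
  v_in <- abs(as.vector(unclass(rel)))
  v_out <- as.vector(unclass(d))
  for (a in seq_along(v_in)) {
    expect_true(all(v_out[v_in >= v_in[a]] <= v_out[a] + 1e-12))
  }

  # double conversion of an absolute similarity with unit diagonal is the
  # identity off the diagonal when the intermediate maximum is also 1
  # (arrange one fully dissimilar pair so the converted maximum is 1)
  rel[1, 4] <- rel[4, 1] <- 0
  d <- convert_relation(rel)
  back <- convert_relation(d)
  off <- upper.tri(back)
  expect_equal(back[off], rel[off], tolerance = 1e-12)
})
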