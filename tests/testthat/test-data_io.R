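test_that("peak matrix files parse, normalize orientation, and round-trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.tsv")
  writeLines(c("sample\tm1\tm2", "s1\t1\t2", "s2\t3\t4"), p)
  m <- read_peak_matrix(p)
  expect_equal(dim(m), c(2L, 2L))
  expect_identical(rownames(m), c("s1", "s2"))
  expect_equal(m["s2", "m2"], 4)

  # same file declared as metabolites-in-rows: transposed result
  t_m <- read_peak_matrix(p, orientation = "samples_in_columns")
  expect_identical(rownames(t_m), c("m1", "m2"))
  expect_equal(unname(t_m), unname(t(m)))

  # orientation flag is an involution through a write/read cycle
  p2 <- file.path(dir, "t.tsv")
  write_peak_matrix(m, p2)
  expect_identical(read_peak_matrix(p2), m)

  # generator fixture round-trips to 12+ decimal places, NA included
  gen <- generate_artificial(synthetic_config(seed = 3))
  withNA <- gen$data
  withNA[2, 5] <- NA
  p3 <- file.path(dir, "fix.tsv")
  write_peak_matrix(withNA, p3)
  back <- read_peak_matrix(p3)
  expect_identical(dimnames(back), dimnames(withNA))
  expect_true(is.na(back[2, 5]))
  expect_lt(max(abs(back - withNA), na.rm = TRUE), 1e-12)
})

test_that("malformed peak matrices fail with located errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("sample\tm1\tm2", "s1\t1\t2", "s1\t3\t4"), p)
  expect_error(read_peak_matrix(p), "duplicate sample identifier: 's1'")
  writeLines(c("sample\tm1\tm2", "s1\t1\t2", "s2\t3"), p)
  expect_error(read_peak_matrix(p), "ragged row 3")
  writeLines(c("sample\tm1\tm2", "s1\t1\tx", "s2\t3\t4"), p)
  expect_error(read_peak_matrix(p), "row 's1', column 'm2'")
})

test_that("annotation tables parse, validate, and round-trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ann.tsv")
  writeLines(c("sample\tsmoking", "s1\tsmoker", "s2\tnon-smoker"), p)
  ann <- read_annotations(p)
  expect_identical(colnames(ann), "smoking")
  expect_equal(nrow(ann), 2L)

  gen <- generate_artificial(synthetic_config(seed = 1))
  expect_equal(nlevels(gen$annotations$nutrition), 4L)
  p2 <- file.path(dir, "ann2.tsv")
  write_annotations(gen$annotations, p2)
  back <- read_annotations(p2)
  expect_identical(rownames(back), rownames(gen$annotations))
  expect_equal(lapply(back, as.character), lapply(gen$annotations, as.character))

  writeLines(c("sample\tsmoking", "s1\tsmoker", "s2\t"), p)
  expect_error(read_annotations(p), "no value for label 'smoking'")
})

test_that("relation matrices, clusterings and curves round-trip losslessly", {
  dir <- withr::local_tempdir()
  rel <- random_similarity(3, seed = 11)
  p <- file.path(dir, "rel.tsv")
  write_relation_matrix(rel, p)
  back <- read_relation_matrix(p)
  expect_lt(max(abs(back - rel)), 1e-9)
  expect_identical(attr(back, "kind"), "similarity")
  expect_identical(attr(back, "measure"), "pearson")
  expect_true(attr(back, "absolute"))

  cl <- named_clustering(c(1, 1, 2, 3, 2))
  pc <- file.path(dir, "cl.tsv")
  write_clustering(cl, pc)
  lines <- readLines(pc)
  expect_length(grep("^[^#]", lines), 6L)   # header + 5 object lines
  expect_identical(read_clustering(pc), cl)

  curve <- breathclust:::quality_curve_points(1:10 / 2, runif(10),
                                              measure = "fmeasure",
                                              label = "smoking")
  pq <- file.path(dir, "curve.tsv")
  write_quality_curve(curve, pq)
  back_c <- read_quality_curve(pq)
  expect_equal(back_c$parameter, curve$parameter)
  expect_equal(back_c$value, curve$value, tolerance = 1e-12)
  expect_identical(attr(back_c, "label"), "smoking")
  expect_equal(sum(!startsWith(readLines(pq), "#")), 11L)
})
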