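test_that("vectorize and unvectorize are exact inverses", {
  m <- unvectorize(c(0.5, -0.2, 0), 3)
  expect_equal(m, matrix(c(1, .5, -.2, .5, 1, 0, -.2, 0, 1), 3, 3))
  expect_identical(vectorize(m), c(0.5, -0.2, 0))
  expect_identical(unvectorize(rep(0, 3), 3), diag(3))

  set.seed(42)
  for (R in sample(3:20, 8)) {
    v <- stats::runif(n_edges(R), -1, 1)
    expect_identical(vectorize(unvectorize(v, R)), v)
    m2 <- unvectorize(v, R)
    expect_identical(unvectorize(vectorize(m2), R), m2)
  }
  expect_equal(n_edges(4), 6L)
  expect_error(unvectorize(rep(0, 5), 4), "length")
})

test_that("edge order is the row-major strict upper triangle", {
  # R = 4: edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 0  # fill explicitly by pair
  vals <- c("12" = 1, "13" = 2, "14" = 3, "23" = 4, "24" = 5, "34" = 6)
  for (nm in names(vals)) {
    i <- as.integer(substr(nm, 1, 1)); j <- as.integer(substr(nm, 2, 2))
    m[i, j] <- vals[[nm]]; m[j, i] <- vals[[nm]]
  }
  diag(m) <- 1
  expect_equal(vectorize(m), unname(vals))
})

test_that("edge index <-> ROI pair mapping is a bijection at R = 116", {
  labels <- aal116_labels()
  expect_length(labels, 116)
  expect_false(anyDuplicated(labels) > 0)
  E <- n_edges(116)
  expect_equal(E, 6670L)
  tab <- edge_to_roi_pair(seq_len(E), 116, labels)
  expect_false(anyDuplicated(paste(tab$roi_i, tab$roi_j)) > 0)
  # first row-major cell, end of first row, last cell
  expect_equal(unlist(tab[1, c("roi_i", "roi_j")], use.names = FALSE),
               labels[c(1, 2)])
  expect_equal(unlist(tab[115, c("roi_i", "roi_j")], use.names = FALSE),
               labels[c(1, 116)])
  expect_equal(unlist(tab[6670, c("roi_i", "roi_j")], use.names = FALSE),
               labels[c(115, 116)])
  expect_error(edge_to_roi_pair(6671, 116), "out of range")
  expect_error(edge_to_roi_pair(0, 116), "out of range")
})

test_that("connectome files round-trip and are validated on read", {
  m <- matrix(c(1, .5, -.2, .5, 1, 0, -.2, 0, 1), 3, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write.table(m, f, sep = ",", row.names = FALSE, col.names = FALSE)
  got <- read_connectome(f)
  expect_equal(got, m)
  expect_equal(nrow(got), 3)
  expect_error(read_connectome(f, expect_rois = 5), "expected 5")

  # last-digit asymmetry is symmetrized by averaging
  m2 <- m
  m2[1, 2] <- 0.5
  m2[2, 1] <- 0.5000000001
  write.table(m2, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_connectome(f)[1, 2], 0.50000000005, tolerance = 1e-15)

  # gross asymmetry is an error naming the worst cell
  m3 <- m
  m3[1, 3] <- m3[1, 3] + 1e-3
  write.table(m3, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(f), "asymmetric.*\\[3,1\\]|asymmetric.*\\[1,3\\]")

  # missing values and non-square shapes are rejected
  m4 <- m
  m4[2, 2] <- NA
  write.table(m4, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(f), "missing|non-finite")
  write.table(m[1:2, ], f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_connectome(f), "square")
})

test_that("cohort manifests round-trip, exclude missing scores, keep order", {
  g <- generate_cohort(synthetic_spec(n_subjects = 10, n_rois = 6, seed = 7))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(g$cohort, dir, truth = g$truth)
  back <- read_cohort(manifest, target = "fiq")
  expect_identical(back$phenotype$subject_id, g$cohort$phenotype$subject_id)
  expect_equal(back$scores, g$cohort$scores, tolerance = 1e-12)
  expect_equal(back$edges, g$cohort$edges, tolerance = 1e-12,
               ignore_attr = TRUE)
  # the simulated score is recorded under both IQ columns
  viq <- read_cohort(manifest, target = "viq")
  expect_equal(viq$scores, g$cohort$scores, tolerance = 1e-12)

  # a subject missing the target score is dropped, others keep their order
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  man$fiq[3] <- NA
  f2 <- file.path(dir, "manifest2.tsv")
  write.table(man, f2, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  expect_message(coh2 <- read_cohort(f2, target = "fiq"), "excluding 1")
  expect_equal(nrow(coh2$edges), 9)
  expect_identical(coh2$phenotype$subject_id, man$subject_id[-3])

  # duplicate ids and mixed groups are rejected
  man_dup <- rbind(man, man[1, ])
  write.table(man_dup, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  expect_error(read_cohort(f2), "duplicate")
  man_mix <- man
  man_mix$group[1] <- "ASD"
  write.table(man_mix, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  expect_error(read_cohort(f2), "mixes groups")
  expect_equal(nrow(read_cohort(f2, group = "NT")$edges), 8)

  # all target scores missing -> empty cohort error
  man_empty <- man
  man_empty$fiq <- NA
  write.table(man_empty, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  expect_error(suppressMessages(read_cohort(f2, target = "fiq")), "empty")
})
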