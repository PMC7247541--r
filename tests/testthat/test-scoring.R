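test_that("truth table is exhaustive and matches the dual-enzyme logic", {
  # every (hpa, msp) pair maps to exactly one state
  expect_identical(score_condition(c(1, 0, 1, 0), c(1, 1, 0, 0)),
                   c("100", "010", "001", "000"))
  # vectorized over matrices, shape preserved by caller
  m <- score_condition(matrix(c(1, 0), 2, 3), matrix(c(1, 1), 2, 3))
  expect_true(all(m %in% c("100", "010")))
  expect_error(score_condition(2, 1), "binary")
  expect_error(score_condition(c(1, 0), 1), "length")
})

test_that("size filter is inclusive at both bounds and preserves order", {
  p <- fragment_panel("HpaII", c("a", "b"),
                      c(99, 100, 600, 601),
                      matrix(1, 2, 4, dimnames = list(NULL, paste0("L", 1:4))))
  kept <- filter_size_range(p, 100, 600)
  expect_identical(kept$locus_ids, c("L2", "L3"))
  expect_identical(filter_size_range(p, 1, 1000)$locus_ids, p$locus_ids)
  p2 <- fragment_panel("HpaII", "a", c(50, 700), matrix(1, 1, 2))
  expect_warning(empty <- filter_size_range(p2, 100, 600), "no loci")
  expect_identical(ncol(empty$presence), 0L)
  expect_error(filter_size_range(p, 600, 100))
})

test_that("reproducibility filter counts discordances and drops loci", {
  pp <- random_panel_pair(10, 10, seed = 11)
  # identical replicates: everything retained, error rate 0
  res <- filter_reproducibility(pp$hpa, pp$hpa)
  expect_identical(res$report$n_loci_retained, 10L)
  expect_identical(res$report$error_rate, 0)

  # plant 5 discordant calls over 3 loci: strict keeps 7, rate 5/100
  rep2 <- pp$hpa
  flips <- cbind(sample = c(1, 2, 3, 4, 5), locus = c(2, 2, 5, 5, 9))
  rep2$presence[flips] <- 1L - rep2$presence[flips]
  res <- filter_reproducibility(pp$hpa, rep2, mode = "strict")
  expect_identical(res$report$n_loci_retained, 7L)
  expect_equal(res$report$error_rate, 0.05)
  expect_setequal(res$panel$locus_ids,
                  pp$hpa$locus_ids[-c(2, 5, 9)])

  # tolerance mode keeps loci under the threshold (locus 9: 1/10 mismatch)
  tol <- filter_reproducibility(pp$hpa, rep2, mode = "tolerance",
                                max_mismatch_fraction = 0.1)
  expect_identical(tol$report$n_loci_retained, 8L)

  expect_error(
    filter_reproducibility(pp$hpa, random_panel_pair(10, 9, 1)$hpa),
    "mismatched")
})

test_that("strict retention is a subset of tolerance retention", {
  for (seed in 1:5) {
    pp <- random_panel_pair(8, 20, seed)
    set.seed(seed + 100)
    rep2 <- pp$hpa
    f <- matrix(runif(length(rep2$presence)) < 0.05, 8)
    rep2$presence[f] <- 1L - rep2$presence[f]
    strict <- filter_reproducibility(pp$hpa, rep2, "strict")$panel$locus_ids
    for (thr in c(0, 0.1, 0.3)) {
      tol <- filter_reproducibility(pp$hpa, rep2, "tolerance",
                                    max_mismatch_fraction = thr)
      expect_true(all(strict %in% tol$panel$locus_ids))
    }
  }
})

test_that("epilocus expansion follows Mixed Scoring 2", {
  ids <- "s1"
  hpa <- fragment_panel("HpaII", ids, c(150, 200, 250, 300),
                        matrix(c(1, 0, 1, 0), 1))
  msp <- fragment_panel("MspI", ids, c(150, 200, 250, 300),
                        matrix(c(1, 1, 0, 0), 1))
  em <- build_epilocus_matrix(hpa, msp)
  expect_identical(as.vector(em$states), c("100", "010", "001", "000"))
  expect_identical(as.integer(em$expanded[1, ]),
                   c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))

  # all-(1,1) input: only nonmethylated subcolumns light up
  pp <- random_panel_pair(4, 6, 2)
  pp$hpa$presence[] <- 1L; pp$msp$presence[] <- 1L
  em2 <- build_epilocus_matrix(pp$hpa, pp$msp)
  expect_true(all(em2$expanded[, grepl("\\.n$", colnames(em2$expanded))] == 1))
  expect_true(all(em2$expanded[, !grepl("\\.n$", colnames(em2$expanded))] == 0))

  expect_error(build_epilocus_matrix(pp$hpa, pp$hpa), "enzyme")
})

test_that("state counts match a brute-force recount on random panels", {
  pp <- random_panel_pair(20, 50, seed = 42)
  em <- build_epilocus_matrix(pp$hpa, pp$msp)
  h <- pp$hpa$presence; m <- pp$msp$presence
  expect_identical(sum(em$states == "100"), sum(h == 1 & m == 1))
  expect_identical(sum(em$states == "010"), sum(h == 0 & m == 1))
  expect_identical(sum(em$states == "001"), sum(h == 1 & m == 0))
  expect_identical(sum(em$states == "000"), sum(h == 0 & m == 0))
})

test_that("expanded view has at most one presence per locus triple", {
  pp <- random_panel_pair(15, 30, seed = 9)
  em <- build_epilocus_matrix(pp$hpa, pp$msp)
  for (l in seq_along(em$locus_ids)) {
    triple <- em$expanded[, (3 * l - 2):(3 * l)]
    expect_true(all(rowSums(triple) %in% c(0L, 1L)))
  }
})

test_that("panel IO round-trips through TSV including sizes", {
  pp <- random_panel_pair(6, 12, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_fragment_panel(pp$hpa, path)
  back <- read_fragment_panel(path, "HpaII")
  expect_identical(back$presence, pp$hpa$presence)
  expect_equal(back$fragment_sizes, pp$hpa$fragment_sizes)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tL1\tL2", "s1\t0\t2"), bad)
  expect_error(read_fragment_panel(bad, "HpaII"), "non-binary")
})
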