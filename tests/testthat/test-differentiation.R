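test_that("one-factor ANOVA matches the classical decomposition", {
  # hand-computable 2x3 design
  y <- c(1, 2, 3, 7, 8, 9)
  f <- rep(c("a", "b"), each = 3)
  res <- one_factor_anova(y, f)
  # MSB = 6*(3-5)^2... grand mean 5, group means 2 and 8:
  # SSB = 3*(2-5)^2 + 3*(8-5)^2 = 54, SSW = 2+2 = 4
  expect_equal(res$ms_between, 54)
  expect_equal(res$ms_within, 1)
  expect_equal(res$F, 54)
  expect_identical(c(res$df_between, res$df_within), c(1L, 4L))
  # agreement with the stats::lm oracle on random data
  for (seed in 1:3) {
    set.seed(seed)
    y <- rnorm(30)
    f <- sample(letters[1:3], 30, replace = TRUE)
    ours <- one_factor_anova(y, f)
    ref <- anova(lm(y ~ f))
    expect_equal(ours$F, ref$`F value`[1])
    expect_equal(ours$p, ref$`Pr(>F)`[1])
  }
  # degenerate cases
  expect_error(one_factor_anova(1:4, rep("a", 4)), "single level")
  sep <- one_factor_anova(c(0, 0, 10, 10), c("a", "a", "b", "b"))
  expect_identical(sep$F, Inf)
  expect_equal(sep$p, 0)
})

test_that("pairwise group comparisons adjust p within panel families", {
  st <- simulate_study(simulation_config(
    group_sizes = c("2xS" = 10L, "2xM" = 6L, "4xM" = 10L, "4xA" = 10L),
    panel_sizes = c(nonmethylated = 30L, internal = 30L, external = 30L),
    n_populations = 8L, candidate_loci = default_candidate_loci()[0, ],
    seed = 6))
  v <- analysis_view(st$epiloci)
  pw <- pairwise_group_anova(v, st$metadata$group)
  expect_identical(nrow(pw), 18L)  # 6 pairs x 3 panels
  expect_true(all(pw$p_adjusted >= pw$p - 1e-12))
  # identical groups: copy one group's rows onto another
  x <- v$x
  g <- st$metadata$group
  x[g == "2xM", ] <- x[g == "2xS", ][seq_len(sum(g == "2xM")), ]
  pw2 <- pairwise_group_anova(list(x = x, panel = v$panel), g)
  same <- pw2[pw2$group1 == "2xS" & pw2$group2 == "2xM", ]
  expect_true(all(same$p > 0.2))
})

test_that("a large planted 4xA shift dominates the pairwise comparisons", {
  set.seed(77)
  g <- rep(c("2xS", "2xM", "4xM", "4xA"), times = c(15, 6, 15, 15))
  n <- length(g)
  x <- matrix(rbinom(n * 90, 1, 0.5), n, 90)
  x[g == "4xA", seq_len(60)] <- rbinom(sum(g == "4xA") * 60, 1, 0.05)
  pw <- pairwise_group_anova(list(x = x, panel = rep(c("nonmethylated",
                                                       "internal",
                                                       "external"),
                                                     each = 30)), g)
  has_4xa <- pw$group1 == "4xA" | pw$group2 == "4xA"
  expect_true(all(pw$p_adjusted[has_4xa & pw$panel != "external"] < 0.001))
  expect_true(all(pw$p_adjusted[!has_4xa] > 0.001))
})

test_that("one-level AMOVA equals the brute-force distance-algebra oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rbinom(6 * 8, 1, 0.5), 6, 8)
    f <- c("a", "a", "a", "b", "b", "b")
    ours <- amova_phist(x, f, n_perm = 100, seed = seed)
    ref <- oracle_amova1(x, f)
    expect_equal(ours$table$SSD[1], ref$ss_among)
    expect_equal(ours$table$SSD[2], ref$ss_within)
    expect_equal(ours$table$SSD[3], ref$ss_total)
    expect_equal(ours$table$sigma2[1], ref$sigma_a)
    expect_equal(ours$table$sigma2[2], ref$sigma_w)
    expect_equal(ours$phi_st, ref$phi)
    # additivity and MSD = SSD/df
    expect_equal(ours$table$SSD[1] + ours$table$SSD[2], ours$table$SSD[3])
    expect_equal(ours$table$MSD[1:2],
                 ours$table$SSD[1:2] / ours$table$df[1:2])
  }
})

test_that("hierarchical AMOVA equals the nested brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed + 50)
    x <- matrix(rbinom(6 * 10, 1, 0.5), 6, 10)
    l1 <- c("G1", "G1", "G1", "G2", "G2", "G2")
    l2 <- c("p1", "p1", "p2", "p3", "p3", "p4")
    ours <- hierarchical_amova(x, l1, l2, n_perm = 50, seed = seed)
    ref <- oracle_amova2(x, l1, l2)
    expect_equal(ours$table$SSD, c(ref$ss_a, ref$ss_b, ref$ss_c,
                                   ref$ss_total))
    expect_equal(ours$table$sigma2[1:3],
                 c(ref$sigma_a, ref$sigma_b, ref$sigma_c))
    expect_equal(sum(ours$table$SSD[1:3]), ours$table$SSD[4])
  }
})

test_that("Phi_ST hits the boundary cases", {
  # two maximally distinct monomorphic groups
  x <- rbind(matrix(0L, 4, 10), matrix(1L, 4, 10))
  f <- rep(c("a", "b"), each = 4)
  res <- suppressWarnings(amova_phist(x, f, n_perm = 99, seed = 1))
  expect_equal(res$phi_st, 1)
  expect_lt(res$p, 0.05)
  # all samples identical: zero SSD everywhere, Phi undefined and flagged
  same <- matrix(1L, 8, 10)
  res2 <- suppressWarnings(amova_phist(same, f, n_perm = 99, seed = 1))
  expect_true(is.na(res2$phi_st))
  # homogeneous data with arbitrary labels: Phi near zero
  set.seed(2)
  hom <- matrix(rbinom(40 * 60, 1, 0.5), 40, 60)
  res3 <- amova_phist(hom, rep(c("a", "b"), 20), n_perm = 199, seed = 3)
  expect_lt(abs(res3$phi_st), 0.1)
  expect_warning(amova_phist(hom, rep(c("a", "b"), 20), n_perm = 50),
                 "n_perm")
})

test_that("locus-by-locus AMOVA finds planted loci and controls the null", {
  set.seed(12)
  n <- 60
  f <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rbinom(n * 200, 1, 0.5), n, 200)
  planted <- seq(10, 100, by = 10)
  for (j in planted) {
    x[f == "a", j] <- rbinom(n / 2, 1, 0.05)
    x[f == "b", j] <- rbinom(n / 2, 1, 0.95)
  }
  res <- locus_by_locus_amova(x, f, alpha = 0.05, n_perm = 199, seed = 5)
  found <- which(res$per_locus$significant)
  expect_gte(length(intersect(found, planted)), 9)
  # false positive rate over the 190 null loci stays near alpha
  fp <- setdiff(found, planted)
  expect_lte(length(fp), ceiling(3 * 0.05 * 190))
  # monomorphic loci are noted and kept in the denominator
  x[, 1] <- 0
  res2 <- locus_by_locus_amova(x, f, n_perm = 99, seed = 5)
  expect_true(res2$per_locus$monomorphic[1])
  expect_identical(res2$n_loci, 200L)
})

test_that("Jaccard distances behave like a metric on binary data", {
  set.seed(9)
  x <- matrix(rbinom(12 * 30, 1, 0.4), 12, 30)
  x[x[, 1] == x[, 1], 1] <- 1  # avoid an all-zero row pathologies guard
  d <- as.matrix(jaccard_distances(x))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (k in 1:20) {
    ijk <- sample(12, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("NMDS separates simulated clusters and is seed-stable", {
  set.seed(15)
  n <- 20
  # two clusters with complementary band profiles (Jaccard-separable)
  pa <- rep(c(0.9, 0.1), each = 30)
  x <- rbind(t(replicate(n / 2, rbinom(60, 1, pa))),
             t(replicate(n / 2, rbinom(60, 1, rev(pa)))))
  labels <- rep(c("a", "b"), each = n / 2)
  ord <- suppressWarnings(nmds(x, seed = 3, restarts = 5))
  expect_gte(ord$stress, 0)
  expect_gt(oracle_silhouette(ord$points, labels), 0.5)
  ord2 <- suppressWarnings(nmds(x, seed = 3, restarts = 5))
  expect_identical(ord$points, ord2$points)
  # a duplicated sample lands on (essentially) the same spot
  xd <- rbind(x, x[1, ])
  ordd <- suppressWarnings(nmds(xd, seed = 4, restarts = 5))
  dup <- sqrt(sum((ordd$points[1, ] - ordd$points[n + 1, ])^2))
  spread <- mean(dist(ordd$points))
  expect_lt(dup, 0.05 * spread)
})
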