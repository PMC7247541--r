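# small config reused across tests: full group structure, few loci
small_config <- function(...,
                         panel_sizes = c(nonmethylated = 20L,
                                         internal = 30L,
                                         external = 25L)) {
  simulation_config(
    group_sizes = c("2xS" = 10L, "2xM" = 6L, "4xM" = 10L, "4xA" = 8L),
    panel_sizes = panel_sizes,
    n_populations = 12L,
    candidate_loci = default_candidate_loci()[0, ],
    ...)
}

test_that("metadata honours the sampling design", {
  md <- simulate_metadata(simulation_config(seed = 3))
  counts <- table(md$group)
  expect_equal(unname(counts[c("2xS", "2xM", "4xM", "4xA")]),
               c(41, 6, 45, 31), ignore_attr = TRUE)
  expect_identical(length(unique(md$population)), 48L)
  per_pop <- table(md$population)
  expect_true(all(per_pop >= 1 & per_pop <= 6))
  # populations are single-group
  expect_true(all(tapply(md$group, md$population,
                         function(g) length(unique(g))) == 1))
  expect_identical(unique(md$ploidy[md$group == "4xA"]), 4L)
  expect_identical(unique(md$reproduction_mode[md$group == "2xM"]), "mixed")
})

test_that("temperature follows the lapse-rate model exactly at zero noise", {
  cfg <- small_config(seed = 5, amt_noise_sd = 0, lapse_rate = 0.0065,
                      amt_intercept = 14)
  md <- simulate_metadata(cfg)
  # AMT + lapse * elevation is constant at the intercept
  expect_equal(md$amt + 0.0065 * md$elevation, rep(14, nrow(md)),
               tolerance = 1e-10)
  # 1000 m of extra elevation costs 6.5 degrees
  i <- order(md$elevation)
  d_amt <- diff(md$amt[i]); d_el <- diff(md$elevation[i])
  expect_equal(d_amt, -0.0065 * d_el, tolerance = 1e-10)
})

test_that("simulation is byte-deterministic under a fixed seed", {
  s1 <- simulate_study(small_config(seed = 99, noise_rate = 0.03,
                                    replicate_discordance_rate = 0.02))
  s2 <- simulate_study(small_config(seed = 99, noise_rate = 0.03,
                                    replicate_discordance_rate = 0.02))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$epiloci$states, s2$epiloci$states)
  expect_identical(s1$panels$hpa[[2]]$presence, s2$panels$hpa[[2]]$presence)
  s3 <- simulate_study(small_config(seed = 100))
  expect_false(identical(s1$epiloci$states, s3$epiloci$states))
})

test_that("empirical state frequencies converge to the generating truth", {
  # one big group so n x loci >= 1e4 calls per panel
  cfg <- simulation_config(
    group_sizes = c("2xS" = 5L, "2xM" = 5L, "4xM" = 5L, "4xA" = 200L),
    panel_sizes = c(nonmethylated = 60L, internal = 60L, external = 60L),
    n_populations = 20L, candidate_loci = default_candidate_loci()[0, ],
    seed = 21)
  st <- simulate_study(cfg)
  v <- analysis_view(st$epiloci)
  rows <- st$metadata$group == "4xA"
  emp <- colMeans(v$x[rows, ])
  types <- c("nonmethylated", "internal", "external")
  truth <- unlist(lapply(types, function(p) st$truth$freq[[p]][, "4xA"]))
  n <- sum(rows)
  z_ok <- abs(emp - truth) <= 3 * sqrt(truth * (1 - truth) / n) + 1e-12
  expect_gte(mean(z_ok), 0.98)
})

test_that("panel conversion round-trips at zero noise and obeys noise rates", {
  st <- simulate_study(small_config(seed = 13))
  em <- build_epilocus_matrix(st$panels$hpa[[1]], st$panels$msp[[1]])
  expect_identical(em$states, st$epiloci$states)
  # replicates identical when discordance rate is zero
  strict <- filter_reproducibility(st$panels$hpa[[1]], st$panels$hpa[[2]])
  expect_identical(strict$report$n_loci_retained,
                   length(st$panels$hpa[[1]]$locus_ids))

  # 5% bit flips on >= 1e4 calls: discordance within 3 binomial sd
  cfg <- small_config(seed = 14, noise_rate = 0.05,
                      panel_sizes = c(nonmethylated = 60L, internal = 60L,
                                      external = 60L))
  stn <- simulate_study(cfg)
  clean <- states_to_panels(stn$epiloci$states, noise_rate = 0,
                            seed = cfg$seed)
  n_calls <- length(clean$hpa[[1]]$presence) + length(clean$msp[[1]]$presence)
  n_flip <- sum(clean$hpa[[1]]$presence != stn$panels$hpa[[1]]$presence) +
    sum(clean$msp[[1]]$presence != stn$panels$msp[[1]]$presence)
  expect_gt(n_calls, 1e4)
  expect_lt(abs(n_flip / n_calls - 0.05),
            3 * sqrt(0.05 * 0.95 / n_calls))
})

test_that("planted group contrasts show up in the simulated data", {
  st <- simulate_study(simulation_config(seed = 8))
  v <- analysis_view(st$epiloci)
  g <- st$metadata$group
  frac_poly <- function(grp, panel) {
    cols <- which(v$panel == panel)
    length(polymorphic_markers(v$x[g == grp, cols])) / length(cols)
  }
  # the apomict signature: internal diversity up, nonmethylated/external down
  for (other in c("2xS", "2xM", "4xM")) {
    expect_gt(frac_poly("4xA", "internal"), frac_poly(other, "internal"))
    expect_lt(frac_poly("4xA", "nonmethylated"),
              frac_poly(other, "nonmethylated"))
  }
})

test_that("config validation catches bad candidate variables", {
  bad <- data.frame(panel = "internal", index = 1, variable = "slope",
                    beta0 = 0, beta1 = 1)
  expect_error(simulation_config(candidate_loci = bad), "unknown variable")
})
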