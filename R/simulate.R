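# Synthetic MSAP study generator.
#
# The generator emulates the sampling design the analysis assumes: four
# combined cytotype x reproduction-mode groups (2xS/2xM/4xM/4xA, default
# sizes 41/6/45/31), three epilocus panels (268 nonmethylated, 378
# externally and 442 internally methylated markers), alpine population
# coordinates with elevation-dependent temperature, and a handful of
# epiloci whose presence probability follows a logistic function of an
# environmental variable. Presence/absence is simulated directly at the
# epilocus level: dominant markers carry no dosage information, so an
# allele-level model would add nothing testable.

#' Configuration for the synthetic MSAP study
#'
#' Defaults encode the emulated study design; see the methods vignette for
#' the rationale behind every default.
#'
#' @param group_sizes Named integer vector of samples per combined group.
#' @param panel_sizes Named integer vector of epiloci per panel
#'   (`nonmethylated`, `internal`, `external`).
#' @param poly_prob Group x panel matrix: probability that an epilocus is
#'   polymorphic (frequency strictly inside (0,1)) within the group.
#'   Defaults are the published per-group polymorphic fractions.
#' @param presence_freq_range Range of the uniform within-group presence
#'   frequency given a locus is polymorphic in that group.
#' @param fixed_present_prob Probability that a non-polymorphic locus is
#'   fixed present (rather than fixed absent); shared across groups so that
#'   monomorphic bands are concordant between groups, as for real fragments.
#' @param n_populations Number of sampled populations (1-6 individuals
#'   each).
#' @param lon_range,lat_range Sampling-area bounding box (degrees).
#' @param elevation_mean_2x,elevation_mean_4x,elevation_sd Per-cytotype
#'   population elevation model (metres); tetraploids sit higher.
#' @param lapse_rate Temperature lapse rate (degC per metre, default
#'   0.0065).
#' @param amt_intercept Sea-level annual mean temperature (degC).
#' @param amt_noise_sd Residual s.d. of annual mean temperature (degC).
#' @param ap_mean,ap_sd Annual precipitation model (mm), independent of
#'   elevation.
#' @param candidate_loci Data frame with columns `panel`, `index`,
#'   `variable`, `beta0`, `beta1`: epiloci whose presence follows
#'   `plogis(beta0 + beta1 * z(variable))`. Default
#'   [default_candidate_loci()] mirrors the published candidate breakdown.
#' @param noise_rate Per-call bit-flip probability applied to both enzyme
#'   panels.
#' @param replicate_discordance_rate Per-call probability that replicate 2
#'   differs from replicate 1.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    group_sizes = c("2xS" = 41L, "2xM" = 6L, "4xM" = 45L, "4xA" = 31L),
    panel_sizes = c(nonmethylated = 268L, internal = 442L, external = 378L),
    poly_prob = default_poly_prob(),
    presence_freq_range = c(0.2, 0.8),
    fixed_present_prob = 0.5,
    n_populations = 48L,
    lon_range = c(5.5, 16), lat_range = c(43.5, 47.5),
    elevation_mean_2x = 1700, elevation_mean_4x = 2200, elevation_sd = 250,
    lapse_rate = 0.0065, amt_intercept = 14, amt_noise_sd = 0.5,
    ap_mean = 1200, ap_sd = 200,
    candidate_loci = default_candidate_loci(),
    noise_rate = 0, replicate_discordance_rate = 0,
    seed = 1L) {
  # JSON configs deliver named lists; coerce to the native vector forms
  if (is.list(group_sizes)) group_sizes <- unlist(group_sizes)
  if (is.list(panel_sizes)) panel_sizes <- unlist(panel_sizes)
  if (!is.data.frame(candidate_loci)) candidate_loci <-
      as.data.frame(candidate_loci)
  group_sizes <- round(group_sizes)
  panel_sizes <- round(panel_sizes)
  stopifnot(all(group_sizes >= 1), all(panel_sizes >= 1),
            all(poly_prob >= 0 & poly_prob <= 1),
            presence_freq_range[1] > 0, presence_freq_range[2] < 1,
            presence_freq_range[1] < presence_freq_range[2],
            noise_rate >= 0, noise_rate <= 1,
            replicate_discordance_rate >= 0, replicate_discordance_rate <= 1)
  if (!setequal(colnames(poly_prob), EPILOCUS_TYPES) ||
      !setequal(rownames(poly_prob), names(group_sizes)))
    stop("poly_prob must be a group x panel matrix matching group_sizes ",
         "and the three epilocus types")
  if (nrow(candidate_loci) > 0) {
    bad <- !candidate_loci$variable %in% c("elevation", "amt", "ap")
    if (any(bad))
      stop("candidate locus references unknown variable: ",
           paste(unique(candidate_loci$variable[bad]), collapse = ", "))
    if (!all(candidate_loci$panel %in% EPILOCUS_TYPES))
      stop("candidate locus references unknown panel")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Default per-group polymorphism probabilities
#'
#' The published per-group polymorphic-marker fractions, used as the
#' probability that a simulated epilocus is polymorphic within each group.
#' They encode the apomict signature: depleted nonmethylated/external
#' diversity, elevated internal diversity in 4xA.
#'
#' @return A 4 x 3 matrix (groups x epilocus types).
#' @export
default_poly_prob <- function() {
  m <- rbind("2xS" = c(0.605, 0.5882, 0.6878),
             "2xM" = c(0.317, 0.3145, 0.4762),
             "4xM" = c(0.709, 0.4457, 0.6402),
             "4xA" = c(0.179, 0.6991, 0.1640))
  colnames(m) <- c("nonmethylated", "internal", "external")
  m
}

#' Default environmentally associated candidate epiloci
#'
#' Mirrors the published candidate breakdown: 22 elevation-associated
#' epiloci (6 nonmethylated, 1 internal, 15 external) and 36 temperature-
#' associated ones (9/4/23), none for precipitation. Effect sizes are not
#' published; beta1 = 2 on the standardized variable gives effects
#' detectable at n = 123 under Bonferroni correction.
#'
#' @param beta1 Logistic slope on the standardized variable.
#' @return Data frame with columns `panel`, `index`, `variable`, `beta0`,
#'   `beta1`.
#' @export
default_candidate_loci <- function(beta1 = 2) {
  counts <- list(elevation = c(nonmethylated = 6, internal = 1, external = 15),
                 amt = c(nonmethylated = 9, internal = 4, external = 23))
  out <- list()
  offset <- c(nonmethylated = 0, internal = 0, external = 0)
  for (v in names(counts)) {
    for (p in EPILOCUS_TYPES) {
      k <- counts[[v]][[p]]
      if (k == 0) next
      out[[paste(v, p)]] <- data.frame(
        panel = p, index = offset[[p]] + seq_len(k), variable = v,
        beta0 = 0, beta1 = beta1)
      offset[[p]] <- offset[[p]] + k
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate sample metadata
#'
#' Samples are assigned to single-group populations (1-6 individuals each)
#' with random coordinates in the sampling box; population elevation is
#' normal around a cytotype-specific mean; annual mean temperature is
#' `amt_intercept - lapse_rate * elevation + noise` (so elevation and
#' temperature are strongly negatively correlated, as in alpine data);
#' annual precipitation is an independent draw.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `sample_id`, `population`, `group`,
#'   `ploidy`, `reproduction_mode`, `lon`, `lat`, `elevation`, `amt`, `ap`.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "metadata"))
  gs <- config$group_sizes
  n <- sum(gs)
  # populations per group, proportional to group size, at least one
  npop <- pmax(1L, round(config$n_populations * gs / n))
  while (sum(npop) != config$n_populations) {
    if (sum(npop) < config$n_populations) {
      i <- which.max(gs / npop)
      npop[i] <- npop[i] + 1L
    } else {
      cand <- which(npop > 1)  # never starve a group of populations
      i <- cand[which.min((gs / npop)[cand])]
      npop[i] <- npop[i] - 1L
    }
  }
  pop_group <- rep(names(gs), times = npop)
  pop_id <- sprintf("P%02d", seq_along(pop_group))
  # spread each group's samples as evenly as possible over its populations
  sample_pop <- unlist(lapply(names(gs), function(g) {
    pops <- pop_id[pop_group == g]
    sort(rep_len(pops, gs[[g]]))
  }))
  group <- rep(names(gs), times = gs)
  ploidy <- ifelse(startsWith(group, "2x"), 2L, 4L)
  mode <- c(S = "sexual", M = "mixed", A = "apomictic")[substr(group, 3, 3)]
  lon <- stats::runif(length(pop_id), config$lon_range[1], config$lon_range[2])
  lat <- stats::runif(length(pop_id), config$lat_range[1], config$lat_range[2])
  elev_mean <- ifelse(startsWith(pop_group, "2x"),
                      config$elevation_mean_2x, config$elevation_mean_4x)
  elev <- stats::rnorm(length(pop_id), elev_mean, config$elevation_sd)
  i <- match(sample_pop, pop_id)
  elevation <- elev[i]
  amt <- config$amt_intercept - config$lapse_rate * elevation +
    stats::rnorm(length(i), 0, config$amt_noise_sd)
  ap <- stats::rnorm(length(i), config$ap_mean, config$ap_sd)
  data.frame(
    sample_id = sprintf("I%03d", seq_along(group)),
    population = sample_pop, group = group, ploidy = ploidy,
    reproduction_mode = unname(mode),
    lon = lon[i], lat = lat[i],
    elevation = elevation, amt = amt, ap = ap,
    stringsAsFactors = FALSE)
}

#' Simulate the epilocus state matrix
#'
#' Each epilocus has one focal methylation state; a present band is that
#' state, an absent band is the ambiguous "000" condition (no fragment in
#' either enzyme panel). Non-candidate loci draw presence from group-
#' specific frequencies; candidate loci draw presence from a logistic model
#' on a standardized environmental variable (independent across samples
#' given covariates, so there is no residual spatial autocorrelation).
#'
#' @param config A [simulation_config()].
#' @param metadata Output of [simulate_metadata()].
#' @return List with `states` (sample x locus state-code matrix), `focal`
#'   (epilocus type per locus) and `truth` (generating frequencies and
#'   candidate effects, sufficient to compute expected values downstream).
#' @export
simulate_states <- function(config, metadata) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "states"))
  groups <- names(config$group_sizes)
  gidx <- match(metadata$group, groups)
  n <- nrow(metadata)
  prefix <- c(nonmethylated = "n", internal = "i", external = "e")
  code <- c(nonmethylated = "100", internal = "010", external = "001")
  env_z <- list(elevation = standardize(metadata$elevation, "elevation"),
                amt = standardize(metadata$amt, "amt"),
                ap = standardize(metadata$ap, "ap"))
  states <- list(); focal <- list(); freqs <- list(); cand_tab <- list()
  for (p in EPILOCUS_TYPES) {
    L <- config$panel_sizes[[p]]
    fr <- config$presence_freq_range
    b <- stats::rbinom(L, 1, config$fixed_present_prob)
    freq <- matrix(rep(b, length(groups)), L, length(groups),
                   dimnames = list(NULL, groups))
    for (g in seq_along(groups)) {
      variable <- stats::runif(L) < config$poly_prob[groups[g], p]
      freq[variable, g] <- stats::runif(sum(variable), fr[1], fr[2])
    }
    # per-sample presence probability
    pm <- t(freq)[gidx, , drop = FALSE]              # n x L
    cand <- config$candidate_loci
    cand <- cand[cand$panel == p, , drop = FALSE]
    if (nrow(cand) > 0) {
      if (any(cand$index > L)) stop("candidate index beyond panel size")
      for (k in seq_len(nrow(cand)))
        pm[, cand$index[k]] <- stats::plogis(
          cand$beta0[k] + cand$beta1[k] * env_z[[cand$variable[k]]])
    }
    x <- matrix(stats::rbinom(n * L, 1, pm), n, L)
    st <- matrix(ifelse(x == 1, code[[p]], "000"), n, L)
    ids <- sprintf("%s%03d", prefix[[p]], seq_len(L))
    colnames(st) <- ids
    states[[p]] <- st
    focal[[p]] <- rep(p, L)
    freqs[[p]] <- freq
    if (nrow(cand) > 0) {
      cand$locus_id <- ids[cand$index]
      cand_tab[[p]] <- cand
    }
  }
  states <- do.call(cbind, states)
  rownames(states) <- metadata$sample_id
  list(states = states,
       focal = unlist(focal, use.names = FALSE),
       truth = list(freq = freqs,
                    candidates = do.call(rbind,
                                         c(cand_tab, make.row.names = FALSE)),
                    env_z = env_z))
}

#' Convert a state matrix to duplicate HpaII/MspI fragment panels
#'
#' Inverts the scoring truth table (`"100"` -> both enzymes cut, `"010"` ->
#' MspI only, `"001"` -> HpaII only, `"000"` -> neither), then applies
#' independent per-call bit flips at `noise_rate` and builds a second
#' replicate differing from the first at `replicate_discordance_rate`.
#' Fragment sizes are drawn uniformly in 100-600 bp and shared between
#' enzymes.
#'
#' @param states Sample x locus state-code matrix.
#' @param noise_rate,replicate_discordance_rate Per-call probabilities.
#' @param seed Integer seed.
#' @return List with `hpa` and `msp`, each a list of two replicate
#'   [fragment_panel()]s.
#' @export
states_to_panels <- function(states, noise_rate = 0,
                             replicate_discordance_rate = 0, seed = 1L) {
  if (!all(states %in% STATE_CODES)) stop("invalid state codes")
  set.seed(derive_seed(seed, "panels"))
  n <- nrow(states); L <- ncol(states)
  hpa <- (states == "100" | states == "001") + 0L
  msp <- (states == "100" | states == "010") + 0L
  flip <- function(m, rate) {
    if (rate > 0) {
      f <- matrix(stats::runif(length(m)) < rate, nrow(m))
      m[f] <- 1L - m[f]
    }
    m
  }
  hpa1 <- flip(hpa, noise_rate); msp1 <- flip(msp, noise_rate)
  hpa2 <- flip(hpa1, replicate_discordance_rate)
  msp2 <- flip(msp1, replicate_discordance_rate)
  sizes <- round(stats::runif(L, 100, 600))
  ids <- colnames(states) %||% paste0("L", seq_len(L))
  mk <- function(m, enz) {
    colnames(m) <- ids
    rownames(m) <- rownames(states)
    fragment_panel(enz, rownames(m), sizes, m)
  }
  list(hpa = list(mk(hpa1, "HpaII"), mk(hpa2, "HpaII")),
       msp = list(mk(msp1, "MspI"), mk(msp2, "MspI")))
}

#' Simulate a complete MSAP study
#'
#' Runs [simulate_metadata()], [simulate_states()] and [states_to_panels()]
#' under one seed and assembles the pieces, including the scored
#' `epilocus_matrix` of the noise-free truth states.
#'
#' @param config A [simulation_config()].
#' @return List of class `msap_simulation` with fields `metadata`,
#'   `epiloci` (truth `epilocus_matrix` with focal panel labels), `panels`
#'   (duplicate fragment panels per enzyme), `truth`, and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  metadata <- simulate_metadata(config)
  sim <- simulate_states(config, metadata)
  panels <- states_to_panels(sim$states, config$noise_rate,
                             config$replicate_discordance_rate, config$seed)
  em <- epilocus_matrix(sim$states, panel = sim$focal)
  structure(list(metadata = metadata, epiloci = em, panels = panels,
                 truth = sim$truth, config = config),
            class = "msap_simulation")
}

#' @export
print.msap_simulation <- function(x, ...) {
  cat("msap_simulation:", nrow(x$metadata), "samples,",
      length(x$epiloci$locus_ids), "epiloci, seed", x$config$seed, "\n")
  invisible(x)
}
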