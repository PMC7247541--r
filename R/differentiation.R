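# Differentiation statistics: ANOVA on presence summaries, distance-based
# (Excoffier-style) AMOVA with permutation Phi-ST, and NMDS ordination.
#
# AMOVA distance convention: pairwise mismatch counts on the expanded
# binary view, i.e. squared Euclidean distance on 0/1 data ("haplotypic
# data, gamma 0.0" in the source tooling's terms: plain band-pattern
# mismatches, no distance correction).

# squared (mismatch-count) distance matrix of a binary matrix
squared_mismatch <- function(x) {
  x <- as.matrix(x)
  rs <- rowSums(x * x)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

#' Proportional mismatch distances
#'
#' `d(i, j)` = fraction of epiloci at which samples i and j differ; the
#' dominant-marker dissimilarity used for Mantel tests.
#'
#' @param x Binary sample x marker matrix.
#' @return An n x n symmetric matrix with zero diagonal.
#' @export
mismatch_distances <- function(x) {
  squared_mismatch(x) / ncol(x)
}

#' Jaccard distances on presence/absence data
#'
#' Thin wrapper over [vegan::vegdist()] with `binary = TRUE`, the distance
#' used for NMDS ordination.
#'
#' @param x Binary sample x marker matrix.
#' @return A `dist` object.
#' @export
jaccard_distances <- function(x) {
  vegan::vegdist(as.matrix(x), method = "jaccard", binary = TRUE)
}

#' One-factor analysis of variance
#'
#' Classical between/within decomposition of a numeric response over a
#' grouping factor.
#'
#' @param response Numeric vector.
#' @param labels Factor with at least two levels, two observations each.
#' @return List with `F`, `df_between`, `df_within`, `p`, and the
#'   between/within mean squares.
#' @export
one_factor_anova <- function(response, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("factor has a single level")
  labels <- droplevels(labels)
  if (any(table(labels) < 2)) stop("need >= 2 observations per level")
  n <- length(response)
  gm <- mean(response)
  means <- tapply(response, labels, mean)
  sizes <- tapply(response, labels, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((response - means[labels])^2)
  dfb <- nlevels(labels) - 1L
  dfw <- n - nlevels(labels)
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- if (msw == 0) Inf else msb / msw
  list(F = f, df_between = dfb, df_within = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       ms_between = msb, ms_within = msw)
}

#' Pairwise group comparisons of per-sample panel summaries
#'
#' For each epilocus panel, the per-sample response (presence count, or
#' arcsine-square-root transformed presence percentage) is compared between
#' every pair of groups with a pooled-variance two-sample test; p-values
#' are adjusted within each panel's comparison family.
#'
#' @param em An `epilocus_matrix` or [analysis_view()] list.
#' @param groups Group label per sample.
#' @param adjust_method `"holm"` (default), `"bonferroni"` or `"BH"`.
#' @param arcsine Transform per-sample presence percentages by
#'   `asin(sqrt(p/100))` before testing.
#' @return Data frame with columns `panel`, `group1`, `group2`, `EST`
#'   (mean difference), `SE`, `t`, `df`, `p`, `p_adjusted`.
#' @export
pairwise_group_anova <- function(em, groups,
                                 adjust_method = c("holm", "bonferroni",
                                                   "BH"),
                                 arcsine = FALSE) {
  adjust_method <- match.arg(adjust_method)
  v <- if (inherits(em, "epilocus_matrix")) analysis_view(em) else em
  glev <- unique(groups)
  if (length(glev) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(glev, 2)
  out <- list()
  for (p in EPILOCUS_TYPES) {
    cols <- which(v$panel == p)
    if (!length(cols)) next
    resp <- rowSums(v$x[, cols, drop = FALSE])
    if (arcsine) resp <- asin(sqrt(resp / length(cols)))
    res <- apply(pairs, 2, function(pr) {
      r1 <- resp[groups == pr[1]]; r2 <- resp[groups == pr[2]]
      n1 <- length(r1); n2 <- length(r2)
      sp2 <- (sum((r1 - mean(r1))^2) + sum((r2 - mean(r2))^2)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      est <- mean(r1) - mean(r2)
      t <- if (se == 0) sign(est) * Inf else est / se
      c(est = est, se = se, t = t, df = n1 + n2 - 2,
        p = 2 * stats::pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
    })
    out[[p]] <- data.frame(panel = p, group1 = pairs[1, ],
                           group2 = pairs[2, ], EST = res["est", ],
                           SE = res["se", ], t = res["t", ],
                           df = res["df", ], p = res["p", ],
                           p_adjusted = stats::p.adjust(res["p", ],
                                                        adjust_method),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# one-level AMOVA components from a squared-distance matrix
amova_components <- function(d2, f) {
  f <- as.factor(f)
  n <- nrow(d2)
  sizes <- table(f)
  g <- nlevels(f)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(levels(f), function(l) {
    idx <- which(f == l)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  df_among <- g - 1L
  df_within <- n - g
  msd_among <- ss_among / df_among
  msd_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_w <- msd_within
  sigma_a <- (msd_among - msd_within) / n0
  total <- sigma_a + sigma_w
  phi <- if (total <= 0) NA_real_ else sigma_a / total
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       msd_among = msd_among, msd_within = msd_within,
       sigma_a = sigma_a, sigma_w = sigma_w, phi = phi,
       negative_component = sigma_a < 0)
}

#' One-level AMOVA with permutation Phi-ST
#'
#' Partitions mismatch-distance sums of squares among and within groups
#' (Excoffier's ANOVA-on-distances algebra), estimates variance components
#' by equating observed mean squares to their expectations, and obtains a
#' permutation p-value for `Phi_ST = sigma2_among / sigma2_total` by random
#' relabeling of individuals.
#'
#' @param x Binary sample x marker matrix (a panel subset or all epiloci).
#' @param grouping Group label per sample.
#' @param n_perm Number of permutations (default 50000; values below 100
#'   trigger a warning).
#' @param seed Integer seed for the permutations.
#' @return List of class `amova_result`: `table` (stratum rows with SSD,
#'   MSD, df, sigma2 and variance percentages), `phi_st`, `p`, `n_perm`,
#'   and a `negative_component` flag.
#' @export
amova_phist <- function(x, grouping, n_perm = 50000, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(grouping)) < 2) stop("need >= 2 groups")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p")
  d2 <- squared_mismatch(x)
  obs <- amova_components(d2, grouping)
  set.seed(derive_seed(seed, "amova"))
  phi_perm <- vapply(seq_len(n_perm), function(i) {
    amova_components(d2, sample(grouping))$phi
  }, numeric(1))
  p <- (1 + sum(phi_perm >= obs$phi, na.rm = TRUE)) / (1 + n_perm)
  tot_sigma <- obs$sigma_a + obs$sigma_w
  tab <- data.frame(
    stratum = c("Among groups", "Within groups", "Total"),
    SSD = c(obs$ss_among, obs$ss_within, obs$ss_total),
    MSD = c(obs$msd_among, obs$msd_within,
            obs$ss_total / (obs$df_among + obs$df_within)),
    df = c(obs$df_among, obs$df_within, obs$df_among + obs$df_within),
    sigma2 = c(obs$sigma_a, obs$sigma_w, tot_sigma),
    variance_pct = c(100 * obs$sigma_a / tot_sigma,
                     100 * obs$sigma_w / tot_sigma, 100),
    stringsAsFactors = FALSE)
  structure(list(table = tab, phi_st = obs$phi, p = p, n_perm = n_perm,
                 negative_component = obs$negative_component),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f, permutation p = %.4g (%d permutations)\n",
              x$phi_st, x$p, x$n_perm))
  invisible(x)
}

#' Two-level hierarchical AMOVA
#'
#' Nested decomposition with a first grouping level (e.g. cytotype) and a
#' second level nested within it (e.g. combined cytotype x reproduction
#' groups). Variance components follow the standard nested expected mean
#' squares with unequal-size coefficients; permutation p-values permute
#' whole second-level units among first-level strata for the top component
#' and individuals among second-level units within strata for the nested
#' component.
#'
#' @param x Binary sample x marker matrix.
#' @param level1 First-level stratum label per sample.
#' @param level2 Second-level unit label per sample (nested in `level1`).
#' @param n_perm Number of permutations per component.
#' @param seed Integer seed.
#' @return List of class `amova_result` with a four-row `table` (among
#'   level 1, among level 2 within level 1, error, total), `phi`
#'   (`phi_ct`, `phi_sc`, `phi_st`), permutation p-values and flags.
#' @export
hierarchical_amova <- function(x, level1, level2, n_perm = 50000,
                               seed = 1L) {
  x <- as.matrix(x)
  d2 <- squared_mismatch(x)
  obs <- nested_components(d2, level1, level2)
  set.seed(derive_seed(seed, "hamova"))
  sub <- interaction(level1, level2, drop = TRUE)
  sub_l1 <- tapply(as.character(level1), sub, `[`, 1)
  # top component: permute whole subgroups among level-1 strata
  perm_a <- vapply(seq_len(n_perm), function(i) {
    new_l1 <- sample(sub_l1)
    nested_components(d2, new_l1[as.character(sub)], level2)$sigma_a
  }, numeric(1))
  # nested component: permute individuals within level-1 strata
  perm_b <- vapply(seq_len(n_perm), function(i) {
    idx <- seq_along(level1)
    for (l in unique(level1)) {
      w <- which(level1 == l)
      idx[w] <- w[sample.int(length(w))]
    }
    nested_components(d2, level1, level2[idx])$sigma_b
  }, numeric(1))
  p_a <- (1 + sum(perm_a >= obs$sigma_a)) / (1 + n_perm)
  p_b <- (1 + sum(perm_b >= obs$sigma_b)) / (1 + n_perm)
  tot <- obs$sigma_a + obs$sigma_b + obs$sigma_c
  tab <- data.frame(
    stratum = c("Among level 1", "Among level 2 within level 1", "Error",
                "Total"),
    SSD = c(obs$ss_a, obs$ss_b, obs$ss_c, obs$ss_total),
    MSD = c(obs$msd_a, obs$msd_b, obs$msd_c,
            obs$ss_total / (nrow(d2) - 1)),
    df = c(obs$df_a, obs$df_b, obs$df_c, nrow(d2) - 1L),
    sigma2 = c(obs$sigma_a, obs$sigma_b, obs$sigma_c, tot),
    variance_pct = 100 * c(obs$sigma_a, obs$sigma_b, obs$sigma_c, tot) / tot,
    p = c(p_a, p_b, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 phi = c(phi_ct = obs$sigma_a / tot,
                         phi_sc = obs$sigma_b / (obs$sigma_b + obs$sigma_c),
                         phi_st = (obs$sigma_a + obs$sigma_b) / tot),
                 p = c(level1 = p_a, level2 = p_b), n_perm = n_perm,
                 negative_component = any(c(obs$sigma_a, obs$sigma_b) < 0)),
            class = "amova_result")
}

nested_components <- function(d2, level1, level2) {
  level1 <- as.character(level1)
  sub <- paste(level1, as.character(level2), sep = "||")
  n <- nrow(d2)
  grp_levels <- unique(level1)
  sub_levels <- unique(sub)
  G <- length(grp_levels); S <- length(sub_levels)
  if (S <= G) stop("second level must subdivide the first")
  pair_ss <- function(idx) sum(d2[idx, idx]) / (2 * length(idx))
  ss_total <- sum(d2) / (2 * n)
  w_grp <- sum(vapply(grp_levels, function(l) pair_ss(which(level1 == l)),
                      numeric(1)))
  w_sub <- sum(vapply(sub_levels, function(l) pair_ss(which(sub == l)),
                      numeric(1)))
  ss_a <- ss_total - w_grp       # among level-1 strata
  ss_b <- w_grp - w_sub          # among subgroups within strata
  ss_c <- w_sub                  # within subgroups (error)
  df_a <- G - 1L; df_b <- S - G; df_c <- n - S
  msd_a <- ss_a / df_a; msd_b <- ss_b / df_b; msd_c <- ss_c / df_c
  n_sub <- table(sub)
  n_grp <- table(level1)
  sub_grp <- vapply(strsplit(sub_levels, "||", fixed = TRUE), `[`, "", 1)
  sum_ns2_over_ng <- sum(vapply(grp_levels, function(l) {
    s <- n_sub[sub_levels[sub_grp == l]]
    sum(s^2) / n_grp[[l]]
  }, numeric(1)))
  n1 <- (n - sum_ns2_over_ng) / df_b
  n2 <- (sum_ns2_over_ng - sum(n_sub^2) / n) / df_a
  n3 <- (n - sum(n_grp^2) / n) / df_a
  sigma_c <- msd_c
  sigma_b <- (msd_b - sigma_c) / n1
  sigma_a <- (msd_a - sigma_c - n2 * sigma_b) / n3
  list(ss_total = ss_total, ss_a = ss_a, ss_b = ss_b, ss_c = ss_c,
       df_a = df_a, df_b = df_b, df_c = df_c,
       msd_a = msd_a, msd_b = msd_b, msd_c = msd_c,
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c)
}

#' Locus-by-locus AMOVA
#'
#' Per-epilocus Phi-ST with a shared-permutation p-value, and the fraction
#' of significantly differentiated epiloci. Monomorphic epiloci are skipped
#' (noted) but remain in the denominator of the overall fraction, since the
#' fraction is reported over all epiloci.
#'
#' @param x Binary sample x marker matrix.
#' @param grouping Group label per sample.
#' @param alpha Significance level for the per-locus permutation p.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `per_locus` (locus, phi_st, p; NA for monomorphic),
#'   `fraction_significant`, `n_significant`, `n_loci`, `n_monomorphic`.
#' @export
locus_by_locus_amova <- function(x, grouping, alpha = 0.05, n_perm = 50000,
                                 seed = 1L) {
  x <- as.matrix(x)
  grouping <- as.factor(grouping)
  n <- nrow(x)
  sizes <- as.vector(table(grouping))
  g <- nlevels(grouping)
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  phi_cols <- function(xm, f) {
    # per-column one-level AMOVA on a binary locus via group presence counts
    n1g <- rowsum(xm, f)                       # g x L presence counts
    ng <- as.vector(table(f))
    ss_w <- colSums(n1g * (ng - n1g) / ng)
    n1 <- colSums(xm)
    ss_t <- n1 * (n - n1) / n
    ss_a <- ss_t - ss_w
    msd_a <- ss_a / (g - 1)
    msd_w <- ss_w / (n - g)
    sigma_a <- (msd_a - msd_w) / n0
    tot <- sigma_a + msd_w
    ifelse(tot <= 0, NA_real_, sigma_a / tot)
  }
  mono <- colMeans(x) %in% c(0, 1)
  phi_obs <- phi_cols(x, grouping)
  phi_obs[mono] <- NA_real_
  set.seed(derive_seed(seed, "lbl"))
  exceed <- numeric(ncol(x))
  for (i in seq_len(n_perm)) {
    phi_p <- phi_cols(x, sample(grouping))
    exceed <- exceed + (!is.na(phi_p) & !is.na(phi_obs) & phi_p >= phi_obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[mono] <- NA_real_
  sig <- !is.na(p) & p < alpha
  list(per_locus = data.frame(locus = colnames(x) %||% seq_len(ncol(x)),
                              phi_st = phi_obs, p = p,
                              significant = sig, monomorphic = mono,
                              stringsAsFactors = FALSE),
       fraction_significant = sum(sig) / ncol(x),
       n_significant = sum(sig), n_loci = ncol(x),
       n_monomorphic = sum(mono), alpha = alpha)
}

#' NMDS ordination of epilocus profiles
#'
#' Non-metric multidimensional scaling of Jaccard distances via
#' [vegan::metaMDS()] (iterative stress majorization with isotonic
#' regression), with multiple random restarts keeping the best stress;
#' deterministic under the seed. Coordinates are defined up to
#' rotation/reflection.
#'
#' @param x Binary sample x marker matrix.
#' @param k Embedding dimension (default 2).
#' @param seed Integer seed.
#' @param restarts Number of random restarts (default 20).
#' @return List of class `ordination_result` with `points` (n x k),
#'   `stress`, and `distance`.
#' @export
nmds <- function(x, k = 2, seed = 1L, restarts = 20) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 samples")
  d <- jaccard_distances(x)
  set.seed(derive_seed(seed, "nmds"))
  fit <- vegan::metaMDS(d, k = k, trymax = restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  pts <- fit$points
  rownames(pts) <- rownames(x)
  structure(list(points = pts, stress = fit$stress, distance = "jaccard"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("NMDS (", x$distance, "):", nrow(x$points), "samples, stress",
      round(x$stress, 4), "\n")
  invisible(x)
}
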