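# Spatial statistics: great-circle distances, spatial weights, stratified
# Mantel tests, global Moran's I and local Geary's C.

EARTH_RADIUS_KM <- 6371

#' Great-circle distances from longitude/latitude
#'
#' Haversine distances in kilometres; samples from the same population
#' (identical centroid coordinates) get distance zero.
#'
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return An n x n symmetric distance matrix (km).
#' @export
geographic_distances <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 360)) stop("implausible longitude")
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  n <- length(lon)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a[a > 1] <- 1
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Spatial or environmental weight matrices
#'
#' `inverse_geographic`: inverse geographic distance `1 / (d + eps_km)`
#' restricted, per row, to samples of the `k` nearest other populations
#' (ties kept); `env_similarity`: inverse environmental distance
#' `1 / (eps + |e_i - e_j|)` over all pairs. Both are zero on the diagonal
#' and optionally row-standardized (rows summing to 1).
#'
#' @param dist_km Geographic distance matrix (for `inverse_geographic`).
#' @param env Numeric environmental values (for `env_similarity`).
#' @param scheme Weighting scheme.
#' @param k Number of nearest distinct distances (population ring) kept per
#'   row.
#' @param eps_km Distance offset avoiding division by zero for co-located
#'   samples (km).
#' @param eps Environmental distance offset.
#' @param row_standardize Standardize rows to sum to 1.
#' @return List of class `spatial_weights` with `w`, `scheme`,
#'   `row_standardized`.
#' @export
spatial_weights <- function(dist_km = NULL, env = NULL,
                            scheme = c("inverse_geographic",
                                       "env_similarity"),
                            k = 10, eps_km = 1, eps = 1e-6,
                            row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "inverse_geographic") {
    stopifnot(!is.null(dist_km))
    d <- as.matrix(dist_km)
    w <- 1 / (d + eps_km)
    diag(w) <- 0
    # keep, per row, neighbours within the k nearest distinct distances
    # (distinct distances ~ populations when samples share centroids)
    for (i in seq_len(nrow(d))) {
      dv <- d[i, -i]
      cut <- sort(unique(dv))[min(k, length(unique(dv)))]
      w[i, d[i, ] > cut] <- 0
    }
  } else {
    stopifnot(!is.null(env), is.numeric(env))
    w <- 1 / (eps + abs(outer(env, env, "-")))
    diag(w) <- 0
  }
  w <- (w + t(w)) / 2  # keep symmetry after neighbour truncation
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  structure(list(w = w, scheme = scheme, row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Environmental-space weights
#'
#' Convenience wrapper building inverse environmental-distance weights;
#' feeding them to [morans_i()] yields a "Moran's I versus environment"
#' statistic (an explicit, documented stand-in for association-tool local-I
#' output).
#'
#' @param env Numeric environmental values per sample.
#' @param eps Distance offset (default 1e-6).
#' @param row_standardize Standardize rows to sum to 1.
#' @return A `spatial_weights` object.
#' @export
env_space_weights <- function(env, eps = 1e-6, row_standardize = TRUE) {
  spatial_weights(env = env, scheme = "env_similarity", eps = eps,
                  row_standardize = row_standardize)
}

#' Stratified Mantel test
#'
#' Pearson correlation of the upper triangles of two distance matrices,
#' with a permutation null that relabels samples only within the given
#' strata. One-sided (positive association) by default.
#'
#' @param d1,d2 Symmetric distance matrices of equal dimension.
#' @param strata Stratum label per sample (a single level reduces to the
#'   unstratified test).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List of class `mantel_result` with `r`, `p`, `n_perm`,
#'   `strata`.
#' @export
stratified_mantel <- function(d1, d2, strata = NULL, n_perm = 999,
                              seed = 1L,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(all(dim(d1) == dim(d2)))
  n <- nrow(d1)
  strata <- strata %||% rep(1L, n)
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance matrix; Mantel r undefined")
  r_obs <- stats::cor(v1, v2)
  set.seed(derive_seed(seed, "mantel"))
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- seq_len(n)
    for (s in unique(strata)) {
      w <- which(strata == s)
      idx[w] <- w[sample.int(length(w))]
    }
    stats::cor(d1[idx, idx][ut], v2)
  }, numeric(1))
  p <- if (alternative == "greater")
    (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  else
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n_perm = n_perm,
                 strata = unique(as.character(strata)),
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.3f (%d permutations, %s)\n",
              x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

# Moran's I for every column of a value matrix under one weight matrix;
# returns per-column I (NA for constant columns)
moran_columns <- function(x, w) {
  x <- as.matrix(x)
  n <- nrow(x)
  z <- sweep(x, 2, colMeans(x))
  denom <- colSums(z^2)
  num <- colSums(z * (w %*% z))
  i <- (n / sum(w)) * num / denom
  i[denom == 0] <- NA_real_
  i
}

#' Global Moran's I of epilocus values
#'
#' Per-locus Moran's I under a spatial weight matrix, summarized as the
#' mean over polymorphic (non-constant) loci; constant loci are excluded.
#' The closed-form null expectation is `-1/(n-1)`; the permutation p
#' relabels samples (the same permutation across loci) and is one-sided for
#' positive autocorrelation.
#'
#' @param x Binary (or numeric) sample x locus matrix; a vector is treated
#'   as one locus.
#' @param weights A `spatial_weights` object or plain weight matrix.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Integer seed.
#' @return List of class `moran_result` with `per_locus`, `I_obs` (mean
#'   over non-constant loci), `I_est` (`-1/(n-1)`), `p`, `n_excluded`.
#' @export
morans_i <- function(x, weights, n_perm = 199, seed = 1L) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else weights
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need >= 3 samples")
  stopifnot(all(dim(w) == n))
  i_loc <- moran_columns(x, w)
  if (all(is.na(i_loc))) stop("all loci constant; Moran's I undefined")
  i_obs <- mean(i_loc, na.rm = TRUE)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(derive_seed(seed, "moran"))
    i_perm <- vapply(seq_len(n_perm), function(k) {
      mean(moran_columns(x[sample.int(n), , drop = FALSE], w), na.rm = TRUE)
    }, numeric(1))
    p <- (1 + sum(i_perm >= i_obs)) / (1 + n_perm)
  }
  structure(list(per_locus = i_loc, I_obs = i_obs, I_est = -1 / (n - 1),
                 p = p, n_perm = n_perm, n_excluded = sum(is.na(i_loc))),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I: I_obs = %.3f, I_est = %.3f, p = %.3f\n",
              x$I_obs, x$I_est, x$p))
  invisible(x)
}

#' Local Geary's C per individual
#'
#' Anselin's local Geary `c_i = sum_j w_ij (x_i - x_j)^2 / (2 m2)` with
#' `m2 = sum_i (x_i - xbar)^2 / (n - 1)`, computed per locus and averaged
#' over non-constant loci per individual. Values above the threshold
#' (default 1) indicate negative local spatial autocorrelation (local
#' dissimilarity); all values are nonnegative.
#'
#' @param x Binary (or numeric) sample x locus matrix.
#' @param weights A `spatial_weights` object or plain weight matrix.
#' @param threshold Flagging threshold (default 1).
#' @return List of class `geary_result` with `c_local` (per individual,
#'   averaged over loci), `flagged` (indices above threshold),
#'   `threshold`.
#' @export
local_gearys_c <- function(x, weights, threshold = 1) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else weights
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(all(dim(w) == n))
  z2 <- x^2
  # sum_j w_ij (x_i - x_j)^2 = x_i^2 * rowSums(w) - 2 x_i (W x)_i + (W x^2)_i
  num <- z2 * rowSums(w) - 2 * x * (w %*% x) + (w %*% z2)
  m2 <- colSums(sweep(x, 2, colMeans(x))^2) / (n - 1)
  keep <- m2 > 0
  if (!any(keep)) stop("all loci constant; local Geary undefined")
  c_mat <- sweep(num[, keep, drop = FALSE], 2, 2 * m2[keep], "/")
  c_i <- rowMeans(c_mat)
  structure(list(c_local = c_i, flagged = which(c_i > threshold),
                 threshold = threshold, n_loci_used = sum(keep)),
            class = "geary_result")
}

#' @export
print.geary_result <- function(x, ...) {
  cat(sprintf(
    "local Geary's C: %d individuals, range %.3f-%.3f, %d above %.2f\n",
    length(x$c_local), min(x$c_local), max(x$c_local), length(x$flagged),
    x$threshold))
  invisible(x)
}
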