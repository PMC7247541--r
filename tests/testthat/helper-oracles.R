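# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops. They deliberately share no code with the
# package implementations they check.

# one-level AMOVA from first principles: explicit pair sums and the
# classical expected-mean-square equations
oracle_amova1 <- function(x, f) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  f <- as.character(f)
  lev <- unique(f)
  ss_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (l in lev) {
    idx <- which(f == l)
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) ss_w <- ss_w + d2[idx[a], idx[b]] / length(idx)
  }
  ss_a <- ss_tot - ss_w
  g <- length(lev)
  msd_a <- ss_a / (g - 1)
  msd_w <- ss_w / (n - g)
  sizes <- sapply(lev, function(l) sum(f == l))
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sig_w <- msd_w
  sig_a <- (msd_a - msd_w) / n0
  list(ss_total = ss_tot, ss_among = ss_a, ss_within = ss_w,
       sigma_a = sig_a, sigma_w = sig_w,
       phi = sig_a / (sig_a + sig_w))
}

# nested two-level AMOVA oracle (groups / subgroups / individuals)
oracle_amova2 <- function(x, g1, g2) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  g1 <- as.character(g1)
  sub <- paste(g1, as.character(g2))
  pair_sum <- function(idx) {
    s <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) s <- s + d2[idx[a], idx[b]]
    s
  }
  ss_tot <- pair_sum(seq_len(n)) / n
  w_grp <- 0
  for (l in unique(g1)) {
    idx <- which(g1 == l)
    w_grp <- w_grp + pair_sum(idx) / length(idx)
  }
  w_sub <- 0
  for (l in unique(sub)) {
    idx <- which(sub == l)
    w_sub <- w_sub + pair_sum(idx) / length(idx)
  }
  G <- length(unique(g1)); S <- length(unique(sub))
  ss_a <- ss_tot - w_grp
  ss_b <- w_grp - w_sub
  ss_c <- w_sub
  msd_a <- ss_a / (G - 1); msd_b <- ss_b / (S - G); msd_c <- ss_c / (n - S)
  n_sub <- table(sub); n_grp <- table(g1)
  sub_of_grp <- function(l) names(n_sub)[startsWith(names(n_sub),
                                                    paste0(l, " "))]
  sum_ns2_ng <- sum(sapply(unique(g1), function(l)
    sum(n_sub[sub_of_grp(l)]^2) / n_grp[[l]]))
  c1 <- (n - sum_ns2_ng) / (S - G)
  c2 <- (sum_ns2_ng - sum(n_sub^2) / n) / (G - 1)
  c3 <- (n - sum(n_grp^2) / n) / (G - 1)
  sig_c <- msd_c
  sig_b <- (msd_b - sig_c) / c1
  sig_a <- (msd_a - sig_c - c2 * sig_b) / c3
  list(ss_total = ss_tot, ss_a = ss_a, ss_b = ss_b, ss_c = ss_c,
       sigma_a = sig_a, sigma_b = sig_b, sigma_c = sig_c)
}

# Moran's I from the textbook double sum
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Anselin's local Geary from the definition
oracle_local_geary <- function(x, w) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / (n - 1)
  sapply(seq_len(n), function(i)
    sum(w[i, ] * (x[i] - x)^2) / (2 * m2))
}

# mean silhouette width on euclidean coordinates, from the definition
oracle_silhouette <- function(pts, labels) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    a <- if (length(own) > 1) mean(d[i, setdiff(own, i)]) else 0
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small random binary study used by several tests
random_panel_pair <- function(n, L, seed) {
  set.seed(seed)
  hpa <- matrix(rbinom(n * L, 1, 0.5), n)
  msp <- matrix(rbinom(n * L, 1, 0.5), n)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(hpa) <- rownames(msp) <- ids
  colnames(hpa) <- colnames(msp) <- sprintf("L%03d", seq_len(L))
  sizes <- sample(100:600, L, replace = TRUE)
  list(hpa = fragment_panel("HpaII", ids, sizes, hpa),
       msp = fragment_panel("MspI", ids, sizes, msp))
}
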