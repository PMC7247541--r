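# Per-group, per-panel diversity statistics for dominant epilocus data.

#' Polymorphic markers within a group
#'
#' A marker is polymorphic in a group when its presence frequency within the
#' group is strictly between 0 and 1 (any-variation criterion; a band-
#' frequency threshold would be degenerate for groups as small as n = 6).
#'
#' @param x Binary sample x marker matrix restricted to one group.
#' @return Integer indices of polymorphic columns.
#' @export
polymorphic_markers <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty group")
  p <- colMeans(x)
  which(p > 0 & p < 1)
}

#' Private polymorphic markers of a group
#'
#' A marker is private to group `g` when it is present in at least one
#' individual of `g` and absent from every individual of every other group.
#'
#' @param x Binary sample x marker matrix over all samples.
#' @param groups Group label per row.
#' @param group The focal group.
#' @return Integer indices of markers private to `group`.
#' @export
private_markers <- function(x, groups, group) {
  x <- as.matrix(x)
  stopifnot(length(groups) == nrow(x))
  if (length(unique(groups)) < 2) stop("need at least two groups")
  inside <- groups == group
  if (!any(inside)) stop("unknown group: ", group)
  present_in <- colSums(x[inside, , drop = FALSE]) > 0
  present_out <- colSums(x[!inside, , drop = FALSE]) > 0
  which(present_in & !present_out)
}

#' Shannon diversity of dominant markers
#'
#' Per marker with presence frequency p, `H = -p log p - (1-p) log(1-p)`
#' (natural log, `0 log 0 := 0`); the panel summary is the unweighted mean
#' over all markers of the panel. Combine panels with
#' [weighted_mean_shannon()].
#'
#' @param x Binary sample x marker matrix.
#' @return List with `per_locus` (H per marker) and `mean`.
#' @export
shannon_index <- function(x) {
  x <- as.matrix(x)
  p <- colMeans(x)
  term <- function(q) ifelse(q > 0, -q * log(q), 0)
  h <- term(p) + term(1 - p)
  list(per_locus = h, mean = mean(h))
}

#' Per-individual polymorphic-epilocus counts
#'
#' For each individual, the number of epiloci that are polymorphic within
#' the individual's own group and present in that individual (the quantity
#' summarized in per-group boxplots).
#'
#' @param x Binary sample x marker matrix.
#' @param groups Group label per row.
#' @return Integer vector, one count per individual.
#' @export
per_individual_polymorphic_counts <- function(x, groups) {
  x <- as.matrix(x)
  stopifnot(length(groups) == nrow(x))
  counts <- integer(nrow(x))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    poly <- polymorphic_markers(x[rows, , drop = FALSE])
    counts[rows] <- as.integer(rowSums(x[rows, poly, drop = FALSE]))
  }
  counts
}

#' Pearson chi-squared goodness-of-fit test
#'
#' @param observed Nonnegative observed counts.
#' @param expected_prop Expected proportions summing to 1.
#' @return List with `chisq`, `df` (k - 1) and `p`.
#' @export
chi_square_gof <- function(observed, expected_prop) {
  stopifnot(length(observed) == length(expected_prop), all(observed >= 0))
  if (abs(sum(expected_prop) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_prop <= 0)) stop("zero expected cell")
  e <- sum(observed) * expected_prop
  chisq <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Group x panel diversity summary table
#'
#' One row per combined group and epilocus panel: marker totals, polymorphic
#' and private counts with percentages (private percentage relative to
#' polymorphic markers), and the panel-mean Shannon index; plus a
#' panel-size-weighted overall Shannon value per group.
#'
#' @param em An `epilocus_matrix` (or the list returned by
#'   [analysis_view()]).
#' @param groups Group label per sample.
#' @return List with `table` (group x panel rows) and `overall` (group,
#'   weighted mean Shannon, summed polymorphic count).
#' @export
diversity_summary <- function(em, groups) {
  v <- if (inherits(em, "epilocus_matrix")) analysis_view(em) else em
  x <- v$x; panel <- v$panel
  stopifnot(length(groups) == nrow(x))
  glev <- unique(groups)
  rows <- list()
  for (g in glev) {
    inside <- groups == g
    for (p in EPILOCUS_TYPES) {
      cols <- which(panel == p)
      if (!length(cols)) next
      xg <- x[inside, cols, drop = FALSE]
      poly <- polymorphic_markers(xg)
      priv_all <- private_markers(x[, cols, drop = FALSE], groups, g)
      # private markers are reported among the group's polymorphic ones
      priv <- intersect(priv_all, poly)
      sh <- shannon_index(xg)
      rows[[paste(g, p)]] <- data.frame(
        group = g, panel = p, n_samples = sum(inside),
        n_total = length(cols), n_polymorphic = length(poly),
        pct_polymorphic = pct(length(poly), length(cols)),
        n_private = length(priv),
        pct_private = if (length(poly)) pct(length(priv), length(poly))
                      else NA_real_,
        shannon_mean = sh$mean, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  overall <- do.call(rbind, lapply(glev, function(g) {
    sub <- tab[tab$group == g, ]
    data.frame(group = g,
               n_polymorphic = sum(sub$n_polymorphic),
               shannon_weighted = weighted_mean_shannon(sub$shannon_mean,
                                                        sub$n_total),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, overall = overall)
}
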