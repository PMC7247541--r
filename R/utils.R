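#' @keywords internal
"_PACKAGE"

# canonical epilocus panels, in locus-expansion order
EPILOCUS_TYPES <- c("nonmethylated", "internal", "external")

# state codes: HpaII bit, MspI bit -> Mixed Scoring 2 code
STATE_CODES <- c(NONMETH = "100", INTERNAL = "010", EXTERNAL = "001",
                 AMBIG = "000")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean square from a sum of squares
#'
#' @param ssd Sum of squared deviations.
#' @param df Degrees of freedom (> 0).
#' @return `ssd / df`.
#' @export
msd <- function(ssd, df) {
  stopifnot(is.numeric(ssd), is.numeric(df), all(df > 0))
  ssd / df
}

#' Percentage helper used by the diversity tables
#'
#' @param numerator,denominator Nonnegative counts.
#' @return `100 * numerator / denominator`.
#' @export
pct <- function(numerator, denominator) {
  stopifnot(all(denominator > 0))
  100 * numerator / denominator
}

#' Panel-size-weighted mean Shannon index
#'
#' Combines per-panel mean Shannon indices into one per-group value, each
#' panel weighted by its marker count.
#'
#' @param h Per-panel mean Shannon indices.
#' @param n Per-panel marker counts (same length as `h`).
#' @return Weighted mean `sum(n * h) / sum(n)`.
#' @export
weighted_mean_shannon <- function(h, n) {
  stopifnot(length(h) == length(n), all(n >= 0), sum(n) > 0)
  sum(n * h) / sum(n)
}

#' Published per-group, per-panel diversity summary used for arithmetic checks
#'
#' Returns the printed group x panel summary (marker totals, polymorphic and
#' private counts, per-panel mean Shannon indices) bundled under
#' `inst/extdata/`. These are study-level summary statistics taken as inputs;
#' the package's own statistics are computed from sample x locus matrices.
#'
#' @return A data.frame with columns `group`, `panel`, `n_total`,
#'   `n_polymorphic`, `n_private`, `shannon_mean`.
#' @export
reference_diversity_table <- function() {
  path <- system.file("extdata", "published_diversity_summary.tsv",
                      package = "epimsap")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# standardize to z-scores; constant vectors -> error with the variable name
standardize <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("variable '", name, "' is constant; cannot standardize")
  (x - mean(x)) / s
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}
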