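# Mixed Scoring 2: dual-enzyme epilocus scoring.
#
# HpaII and MspI are isoschizomers of 5'-CCGG-3' with different methylation
# sensitivity. Comparing their dominant fragment calls at one locus
# distinguishes four conditions, three of which are informative:
#   HpaII=1, MspI=1 -> no methylation               code "100"
#   HpaII=0, MspI=1 -> internal cytosine methylated code "010"
#   HpaII=1, MspI=0 -> external cytosine hemimeth.  code "001"
#   HpaII=0, MspI=0 -> ambiguous (holomethylation   code "000"
#                      or mutation), not scored as a marker type.

#' Score one HpaII/MspI call pair into a methylation state
#'
#' Vectorized truth-table scoring. The "000" condition is kept in state
#' matrices but expands to absence at all three epiloci; it is never scored
#' as a marker type of its own.
#'
#' @param hpa,msp Binary (0/1) vectors of equal length.
#' @return Character vector of state codes `"100"`, `"010"`, `"001"`, `"000"`.
#' @examples
#' score_condition(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
score_condition <- function(hpa, msp) {
  if (!all(hpa %in% c(0, 1)) || !all(msp %in% c(0, 1)))
    stop("score_condition: inputs must be binary 0/1")
  if (length(hpa) != length(msp))
    stop("score_condition: inputs must have equal length")
  # index truth table by 2*hpa + msp: 0->(0,0), 1->(0,1), 2->(1,0), 3->(1,1)
  table <- c("000", "010", "001", "100")
  table[2L * hpa + msp + 1L]
}

#' Filter panel loci by fragment size
#'
#' Retains loci whose fragment length lies in `[min_bp, max_bp]`, both ends
#' inclusive (the common scoring-software convention for a "between" range).
#' Locus order is preserved.
#'
#' @param panel A [fragment_panel()].
#' @param min_bp,max_bp Size bounds in base pairs, `min_bp < max_bp`.
#' @return A filtered [fragment_panel()]; warns when no locus survives.
#' @export
filter_size_range <- function(panel, min_bp = 100, max_bp = 600) {
  stopifnot(inherits(panel, "fragment_panel"), min_bp < max_bp)
  keep <- panel$fragment_sizes >= min_bp & panel$fragment_sizes <= max_bp
  if (!any(keep))
    warning("size filter [", min_bp, ", ", max_bp, "] retained no loci")
  subset_panel(panel, keep)
}

subset_panel <- function(panel, keep) {
  fragment_panel(panel$enzyme, panel$sample_ids,
                 panel$fragment_sizes[keep],
                 panel$presence[, keep, drop = FALSE])
}

#' Filter loci by replicate reproducibility
#'
#' Every sample is run in duplicate from restriction to selective PCR; a
#' locus whose calls disagree between replicates is unreliable. `"strict"`
#' mode (the default, matching a 100%-reproducibility requirement) drops any
#' locus with at least one discordant call; `"tolerance"` mode drops loci
#' whose discordant-call fraction exceeds `max_mismatch_fraction`.
#'
#' @param panel_rep1,panel_rep2 Replicate [fragment_panel()]s with identical
#'   samples and loci.
#' @param mode `"strict"` or `"tolerance"`.
#' @param max_mismatch_fraction Per-locus discordance threshold for
#'   `"tolerance"` mode.
#' @return A list with `panel` (replicate 1 restricted to retained loci) and
#'   `report`, a `reproducibility_report` carrying `n_loci_in`,
#'   `n_loci_retained`, per-locus mismatch counts and the overall
#'   `error_rate` (fraction of discordant sample x locus calls).
#' @export
filter_reproducibility <- function(panel_rep1, panel_rep2,
                                   mode = c("strict", "tolerance"),
                                   max_mismatch_fraction = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel_rep1, "fragment_panel"),
            inherits(panel_rep2, "fragment_panel"))
  check_aligned_panels(panel_rep1, panel_rep2, "replicate panels")
  mism <- colSums(panel_rep1$presence != panel_rep2$presence)
  n_samples <- nrow(panel_rep1$presence)
  keep <- if (mode == "strict") mism == 0 else
    mism / n_samples <= max_mismatch_fraction
  report <- structure(list(
    n_loci_in = length(mism),
    n_loci_retained = sum(keep),
    mismatches_per_locus = mism,
    error_rate = sum(mism) / (n_samples * length(mism)),
    mode = mode), class = "reproducibility_report")
  list(panel = subset_panel(panel_rep1, keep), report = report)
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("reproducibility (%s): %d/%d loci retained, error rate %.4f\n",
              x$mode, x$n_loci_retained, x$n_loci_in, x$error_rate))
  invisible(x)
}

#' Build the three-state epilocus matrix from paired enzyme panels
#'
#' Applies [score_condition()] element-wise, and expands every locus into
#' three binary epiloci (nonmethylated / internally methylated / externally
#' methylated; subcolumn suffixes `.n`, `.i`, `.e`). The ambiguous "000"
#' condition expands to `(0, 0, 0)`.
#'
#' @param hpa_panel,msp_panel Aligned [fragment_panel()]s for HpaII and MspI.
#' @return An object of class `epilocus_matrix` with fields `sample_ids`,
#'   `locus_ids`, `states` (sample x locus state codes), `expanded`
#'   (sample x 3-loci binary), and `panel` (epilocus type per expanded
#'   column).
#' @export
build_epilocus_matrix <- function(hpa_panel, msp_panel) {
  stopifnot(inherits(hpa_panel, "fragment_panel"),
            inherits(msp_panel, "fragment_panel"))
  if (hpa_panel$enzyme == msp_panel$enzyme)
    stop("both panels claim enzyme ", hpa_panel$enzyme)
  check_aligned_panels(hpa_panel, msp_panel, "HpaII/MspI panels")
  states <- matrix(score_condition(hpa_panel$presence, msp_panel$presence),
                   nrow = nrow(hpa_panel$presence),
                   dimnames = dimnames(hpa_panel$presence))
  epilocus_matrix(states)
}

#' Construct an epilocus matrix from a state-code matrix
#'
#' @param states Character matrix of `"100"/"010"/"001"/"000"` codes,
#'   samples in rows.
#' @param panel Optional epilocus type per column for one-epilocus-per-locus
#'   matrices (as produced by the simulator); default expands every locus
#'   into all three subcolumns.
#' @return An `epilocus_matrix`.
#' @export
epilocus_matrix <- function(states, panel = NULL) {
  if (!all(states %in% STATE_CODES))
    stop("invalid state codes: ",
         paste(utils::head(setdiff(unique(as.vector(states)), STATE_CODES)),
               collapse = ", "))
  sample_ids <- rownames(states) %||% paste0("S", seq_len(nrow(states)))
  locus_ids <- colnames(states) %||% paste0("L", seq_len(ncol(states)))
  dimnames(states) <- list(sample_ids, locus_ids)
  n <- nrow(states); L <- ncol(states)
  # expanded view: one binary subcolumn per epilocus type per locus
  exp_mat <- matrix(0L, n, 3L * L)
  exp_mat[, seq(1L, 3L * L, by = 3L)] <- (states == "100") + 0L
  exp_mat[, seq(2L, 3L * L, by = 3L)] <- (states == "010") + 0L
  exp_mat[, seq(3L, 3L * L, by = 3L)] <- (states == "001") + 0L
  suffix <- c("n", "i", "e")
  colnames(exp_mat) <- paste(rep(locus_ids, each = 3L), suffix, sep = ".")
  rownames(exp_mat) <- sample_ids
  structure(list(sample_ids = sample_ids,
                 locus_ids = locus_ids,
                 states = states,
                 expanded = exp_mat,
                 panel = rep(EPILOCUS_TYPES, times = L),
                 focal = panel),
            class = "epilocus_matrix")
}

#' Extract the analysis matrix of an epilocus matrix
#'
#' The binary sample x epilocus view that all statistics consume. For
#' simulator-produced objects with one focal epilocus per locus, only the
#' focal subcolumns are returned (the others are structurally zero);
#' otherwise the full expanded view.
#'
#' @param em An `epilocus_matrix`.
#' @return List with `x` (binary matrix) and `panel` (epilocus type per
#'   column).
#' @export
analysis_view <- function(em) {
  stopifnot(inherits(em, "epilocus_matrix"))
  if (is.null(em$focal))
    return(list(x = em$expanded, panel = em$panel))
  suffix <- c(nonmethylated = "n", internal = "i", external = "e")[em$focal]
  cols <- paste(em$locus_ids, suffix, sep = ".")
  list(x = em$expanded[, cols, drop = FALSE], panel = unname(em$focal))
}

#' @export
print.epilocus_matrix <- function(x, ...) {
  cat("epilocus_matrix:", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci (", ncol(x$expanded), "epilocus columns )\n")
  tab <- table(factor(x$states, levels = STATE_CODES))
  cat("  state counts:", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Write epilocus matrices as TSV
#'
#' Writes both the expanded binary view (`<stem>_expanded.tsv`, subcolumn
#' suffixes `.n`, `.i`, `.e`) and the state-code view (`<stem>_states.tsv`).
#'
#' @param em An `epilocus_matrix`.
#' @param stem Output path stem.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return The two paths, invisibly.
#' @export
write_epilocus_matrix <- function(em, stem, header = character()) {
  p1 <- paste0(stem, "_expanded.tsv")
  p2 <- paste0(stem, "_states.tsv")
  write_tsv_with_header(
    data.frame(sample = em$sample_ids, em$expanded, check.names = FALSE),
    p1, header)
  write_tsv_with_header(
    data.frame(sample = em$sample_ids, em$states, check.names = FALSE),
    p2, header)
  invisible(c(p1, p2))
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
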