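# FragmentPanel: one enzyme's dominant presence/absence matrix.

#' Construct a fragment panel
#'
#' A fragment panel holds the dominant (presence/absence) scores of one
#' restriction enzyme (HpaII or MspI) over a set of samples and sized
#' fragments. The two panels of one experiment must share sample order and
#' locus order; epilocus scoring pairs them element-wise.
#'
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param sample_ids Character vector of sample identifiers.
#' @param fragment_sizes Numeric vector of fragment lengths (bp), one per
#'   locus; strictly positive.
#' @param presence Binary (0/1) matrix, samples in rows, loci in columns.
#'   Column names are taken as locus ids (generated when absent).
#' @return An object of class `fragment_panel`.
#' @export
fragment_panel <- function(enzyme, sample_ids, fragment_sizes, presence) {
  enzyme <- match.arg(enzyme, c("HpaII", "MspI"))
  presence <- as.matrix(presence)
  if (!all(presence %in% c(0, 1)))
    stop("presence matrix must contain only 0/1 values")
  storage.mode(presence) <- "integer"
  if (length(sample_ids) != nrow(presence))
    stop("sample_ids length (", length(sample_ids),
         ") does not match presence rows (", nrow(presence), ")")
  if (length(fragment_sizes) != ncol(presence))
    stop("fragment_sizes length does not match presence columns")
  if (any(fragment_sizes <= 0)) stop("fragment_sizes must be positive")
  if (anyDuplicated(sample_ids)) stop("duplicated sample_ids")
  locus_ids <- colnames(presence) %||% paste0("L", seq_len(ncol(presence)))
  rownames(presence) <- sample_ids
  if (ncol(presence) > 0) colnames(presence) <- locus_ids
  structure(list(enzyme = enzyme,
                 sample_ids = as.character(sample_ids),
                 locus_ids = locus_ids,
                 fragment_sizes = as.numeric(fragment_sizes),
                 presence = presence),
            class = "fragment_panel")
}

#' @export
print.fragment_panel <- function(x, ...) {
  cat("fragment_panel:", x$enzyme, "-", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci\n")
  invisible(x)
}

#' @export
dim.fragment_panel <- function(x) dim(x$presence)

# shared-shape check used by scoring and reproducibility filtering
check_aligned_panels <- function(a, b, what = "panels") {
  if (!identical(a$sample_ids, b$sample_ids))
    stop(what, " have mismatched sample_ids")
  if (!identical(a$locus_ids, b$locus_ids))
    stop(what, " have mismatched locus ids/ordering")
  invisible(TRUE)
}

#' Read a fragment panel from delimited text
#'
#' Expected layout: header row of locus ids (optionally `"locus:size"` to
#' carry the fragment size in bp), first column sample ids, remaining cells
#' 0/1. Separator is inferred from the file extension (`.csv` vs tab).
#'
#' @param path File path.
#' @param enzyme `"HpaII"` or `"MspI"`.
#' @param sep Field separator; default inferred.
#' @return A [fragment_panel()].
#' @export
read_fragment_panel <- function(path, enzyme, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  if (!all(m %in% c(0, 1)))
    stop("non-binary values in ", path, ": ",
         paste(utils::head(setdiff(unique(as.vector(m)), c(0, 1))),
               collapse = ", "))
  ids <- colnames(m)
  sizes <- rep(NA_real_, length(ids))
  has_size <- grepl(":", ids, fixed = TRUE)
  sizes[has_size] <- as.numeric(sub("^.*:", "", ids[has_size]))
  ids <- sub(":.*$", "", ids)
  if (anyNA(sizes)) {
    if (any(has_size)) stop("unparseable size annotation in ", path)
    sizes <- rep(1, length(ids))  # unsized input: size filter is a no-op
  }
  colnames(m) <- ids
  fragment_panel(enzyme, rownames(m), sizes, m)
}

#' Write a fragment panel as TSV
#'
#' Column headers are `locus:size`; first column is the sample id.
#'
#' @param panel A [fragment_panel()].
#' @param path Output path.
#' @export
write_fragment_panel <- function(panel, path) {
  m <- panel$presence
  colnames(m) <- paste0(panel$locus_ids, ":", panel$fragment_sizes)
  df <- data.frame(sample = panel$sample_ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
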