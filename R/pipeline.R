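# Config-driven end-to-end pipeline and a small CLI front end.

#' Read a sample metadata table
#'
#' TSV/CSV with at least `sample_id`, `group`, `lon`, `lat`, `elevation`,
#' `amt`, `ap`; `population`, `ploidy`, `reproduction_mode` are carried
#' through when present.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "group", "lon", "lat", "elevation", "amt", "ap")
  miss <- setdiff(required, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  md
}

#' Build a pipeline configuration
#'
#' Either from a JSON file or from a named list. Defaults are filled for
#' every unset field; the result is validated before any stage runs.
#' Precedence when used from the CLI: explicit flags override the config
#' file, which overrides defaults.
#'
#' @param config Path to a JSON config file, or a named list.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L, outdir = "msap_out",
    simulate = NULL, inputs = NULL,
    filters = list(min_bp = 100, max_bp = 600, reproducibility = "strict",
                   max_mismatch_fraction = 0.05),
    grouping = "group",
    n_perm = list(amova = 999, mantel = 999, moran = 199, locus = 199),
    alpha = 0.05, correction = "bonferroni",
    nmds_restarts = 20)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' block")
  if (!is.null(cfg$inputs)) {
    need <- c("hpa_rep1", "hpa_rep2", "msp_rep1", "msp_rep2", "metadata")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop("inputs block is missing: ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate panels and metadata jointly
#'
#' Collects all problems (sample-ID concordance across the four panels and
#' the metadata, coordinate ranges, group vocabulary) and reports them
#' together.
#'
#' @param panels List with `hpa` and `msp`, each a list of two replicate
#'   [fragment_panel()]s.
#' @param metadata Metadata data frame.
#' @param allowed_groups Group label vocabulary (`NULL` accepts any).
#' @return Invisibly `TRUE`; stops with the collected messages otherwise.
#' @export
validate_inputs <- function(panels, metadata,
                            allowed_groups = c("2xS", "2xM", "4xM", "4xA")) {
  errs <- character()
  ids <- panels$hpa[[1]]$sample_ids
  for (nm in c("hpa", "msp")) for (r in 1:2) {
    p <- panels[[nm]][[r]]
    if (!identical(p$sample_ids, ids))
      errs <- c(errs, sprintf("%s replicate %d: sample ids differ from %s replicate 1",
                              nm, r, "hpa"))
  }
  missing_md <- setdiff(ids, metadata$sample_id)
  if (length(missing_md))
    errs <- c(errs, paste("samples missing from metadata:",
                          paste(missing_md, collapse = ", ")))
  extra_md <- setdiff(metadata$sample_id, ids)
  if (length(extra_md))
    errs <- c(errs, paste("metadata samples absent from panels:",
                          paste(extra_md, collapse = ", ")))
  if (any(abs(metadata$lat) > 90)) errs <- c(errs, "latitude outside [-90, 90]")
  if (any(abs(metadata$lon) > 360)) errs <- c(errs, "implausible longitude")
  if (!is.null(allowed_groups)) {
    bad <- setdiff(unique(metadata$group), allowed_groups)
    if (length(bad))
      errs <- c(errs, paste("unknown group label(s):",
                            paste(bad, collapse = ", ")))
  }
  if (length(errs)) stop("input validation failed:\n  - ",
                         paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # where results land is not analysis provenance
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full MSAP analysis pipeline
#'
#' Executes scoring, diversity, differentiation (hierarchical and per-panel
#' AMOVA, locus-by-locus AMOVA, pairwise ANOVA, NMDS), spatial statistics
#' (stratified Mantel, Moran's I, local Geary's C) and the environmental
#' association screen, writing one TSV per result into the output
#' directory. Every output carries the package version and a hash of the
#' fully resolved configuration in `#` header lines, and the run is
#' byte-reproducible under a fixed seed.
#'
#' @param config A [pipeline_config()], config list, or JSON path.
#' @return Invisibly, a list with the in-memory results and the vector of
#'   written files.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- c(paste("epimsap", as.character(utils::packageVersion("epimsap"))),
           paste("config_hash:", hash))
  files <- character()
  emit <- function(df, name, extra = character()) {
    path <- file.path(cfg$outdir, paste0(name, ".tsv"))
    write_tsv_with_header(df, path, c(hdr, extra))
    files <<- c(files, path)
    path
  }

  # ---- stage: inputs -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    stage_log("simulate", "generating synthetic study")
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- do.call(simulation_config, sim_args)
    study <- simulate_study(sim)
    metadata <- study$metadata
    panels <- study$panels
  } else {
    stage_log("input", "reading panels and metadata")
    panels <- list(
      hpa = list(read_fragment_panel(cfg$inputs$hpa_rep1, "HpaII"),
                 read_fragment_panel(cfg$inputs$hpa_rep2, "HpaII")),
      msp = list(read_fragment_panel(cfg$inputs$msp_rep1, "MspI"),
                 read_fragment_panel(cfg$inputs$msp_rep2, "MspI")))
    metadata <- read_metadata(cfg$inputs$metadata)
  }
  validate_inputs(panels, metadata,
                  allowed_groups = cfg$allowed_groups %||%
                    unique(metadata$group))
  metadata <- metadata[match(panels$hpa[[1]]$sample_ids,
                             metadata$sample_id), ]
  groups <- metadata[[cfg$grouping]]

  # ---- stage: scoring ------------------------------------------------
  f <- cfg$filters
  score_enzyme <- function(reps) {
    p <- filter_size_range(reps[[1]], f$min_bp, f$max_bp)
    p2 <- filter_size_range(reps[[2]], f$min_bp, f$max_bp)
    rr <- filter_reproducibility(p, p2, f$reproducibility,
                                 f$max_mismatch_fraction)
    stage_log("score", sprintf("%s: %d -> %d loci (error rate %.4f)",
                               p$enzyme, rr$report$n_loci_in,
                               rr$report$n_loci_retained,
                               rr$report$error_rate))
    rr
  }
  hpa <- score_enzyme(panels$hpa)
  msp <- score_enzyme(panels$msp)
  shared <- intersect(hpa$panel$locus_ids, msp$panel$locus_ids)
  stage_log("score", length(shared), " loci shared between enzymes")
  keep_h <- hpa$panel$locus_ids %in% shared
  keep_m <- msp$panel$locus_ids %in% shared
  em <- build_epilocus_matrix(subset_panel(hpa$panel, keep_h),
                              subset_panel(msp$panel, keep_m))
  if (!is.null(cfg$simulate)) {
    # focal panel labels are known for simulated loci
    em$focal <- study$epiloci$focal[match(em$locus_ids,
                                          study$epiloci$locus_ids)]
  }
  write_epilocus_matrix(em, file.path(cfg$outdir, "epiloci"), hdr)
  files <- c(files, file.path(cfg$outdir,
                              c("epiloci_expanded.tsv", "epiloci_states.tsv")))
  v <- analysis_view(em)

  # ---- stage: diversity ----------------------------------------------
  stage_log("diversity", "group x panel summaries")
  div <- diversity_summary(v, groups)
  emit(div$table, "diversity")
  emit(div$overall, "diversity_overall")

  # ---- stage: differentiation ----------------------------------------
  stage_log("anova", "one-factor ANOVAs on stacked panel presence counts")
  counts <- lapply(EPILOCUS_TYPES, function(p)
    rowSums(v$x[, v$panel == p, drop = FALSE]))
  resp <- unlist(counts)
  anova_rows <- lapply(
    c(cytotype = "cytotype", reproduction_mode = "reproduction_mode",
      panel = "panel"),
    function(fac) {
      labels <- switch(fac,
        cytotype = rep(substr(groups, 1, 2), times = 3),
        reproduction_mode = rep(metadata$reproduction_mode %||%
                                  substr(groups, 3, 3), times = 3),
        panel = rep(EPILOCUS_TYPES, each = nrow(v$x)))
      a <- one_factor_anova(resp, labels)
      data.frame(factor = fac, F = a$F, df_between = a$df_between,
                 df_within = a$df_within, p = a$p)
    })
  emit(do.call(rbind, c(anova_rows, make.row.names = FALSE)), "anova")
  stage_log("amova", "hierarchical + per-panel Phi_ST")
  ham <- hierarchical_amova(v$x, substr(groups, 1, 2), groups,
                            n_perm = cfg$n_perm$amova, seed = cfg$seed)
  emit(cbind(ham$table,
             phi = c(ham$phi[["phi_ct"]], ham$phi[["phi_sc"]], NA,
                     ham$phi[["phi_st"]])),
       "amova_hierarchical")
  phist_rows <- lapply(c(list(all = seq_along(v$panel)),
                         split(seq_along(v$panel), v$panel)),
                       function(cols) {
    a <- amova_phist(v$x[, cols, drop = FALSE], groups,
                     n_perm = cfg$n_perm$amova, seed = cfg$seed)
    data.frame(phi_st = a$phi_st, p = a$p, n_loci = length(cols))
  })
  phist <- do.call(rbind, phist_rows)
  phist <- cbind(panel = rownames(phist), phist)
  emit(phist, "amova_phist")
  lbl <- locus_by_locus_amova(v$x, groups, alpha = cfg$alpha,
                              n_perm = cfg$n_perm$locus, seed = cfg$seed)
  emit(data.frame(fraction_significant = lbl$fraction_significant,
                  n_significant = lbl$n_significant,
                  n_loci = lbl$n_loci, alpha = lbl$alpha),
       "amova_locus_summary")
  pw <- pairwise_group_anova(v, groups)
  emit(pw, "anova_pairwise")
  stage_log("nmds", "ordination")
  ord <- nmds(v$x, seed = cfg$seed, restarts = cfg$nmds_restarts)
  emit(data.frame(sample = rownames(ord$points), ord$points,
                  check.names = FALSE),
       "nmds", extra = paste("stress:", format(ord$stress)))

  # ---- stage: spatial -------------------------------------------------
  stage_log("spatial", "Mantel, Moran's I, local Geary's C")
  dgeo <- geographic_distances(metadata$lon, metadata$lat)
  depi <- mismatch_distances(v$x)
  cyto <- substr(groups, 1, 2)
  man <- stratified_mantel(depi, dgeo, strata = cyto,
                           n_perm = cfg$n_perm$mantel, seed = cfg$seed)
  emit(data.frame(strata = "cytotype", r = man$r, p = man$p,
                  n_perm = man$n_perm),
       "mantel")
  w <- spatial_weights(dist_km = dgeo)
  moran_rows <- list()
  geary_rows <- list()
  for (g in unique(groups)) {
    rows_g <- which(groups == g)
    wg <- spatial_weights(dist_km = dgeo[rows_g, rows_g])
    for (p in EPILOCUS_TYPES) {
      cols <- which(v$panel == p)
      xg <- v$x[rows_g, cols, drop = FALSE]
      poly <- polymorphic_markers(xg)
      if (length(poly) < 2) next
      mi <- morans_i(xg[, poly, drop = FALSE], wg,
                     n_perm = cfg$n_perm$moran, seed = cfg$seed)
      moran_rows[[paste(g, p)]] <- data.frame(
        group = g, panel = p, I_obs = mi$I_obs, I_est = mi$I_est, p = mi$p)
      gc <- local_gearys_c(xg[, poly, drop = FALSE], wg)
      geary_rows[[paste(g, p)]] <- data.frame(
        group = g, panel = p, sample = metadata$sample_id[rows_g],
        c_local = gc$c_local, flagged = seq_along(rows_g) %in% gc$flagged)
    }
  }
  moran <- do.call(rbind, c(moran_rows, make.row.names = FALSE))
  # adjust across the three panels within each group
  moran$p_adjusted <- stats::ave(moran$p, moran$group,
                                 FUN = function(p) stats::p.adjust(p, "holm"))
  emit(moran, "moran")
  emit(do.call(rbind, c(geary_rows, make.row.names = FALSE)), "geary")

  # ---- stage: environmental association -------------------------------
  stage_log("envassoc", "logistic screen")
  scr <- screen_all(v, metadata, alpha = cfg$alpha,
                    correction = cfg$correction)
  emit(scr$tests, "envassoc_tests")
  emit(scr$counts, "envassoc_counts")

  # provenance: fully resolved config
  cfg_path <- file.path(cfg$outdir, "config.json")
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), cfg_path)
  files <- c(files, cfg_path)
  stage_log("done", length(files), " files in ", cfg$outdir)
  invisible(list(epiloci = em, metadata = metadata, diversity = div,
                 amova = list(hierarchical = ham, phist = phist,
                              locus = lbl),
                 pairwise = pw, nmds = ord, mantel = man, moran = moran,
                 screen = scr, files = files))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `score`, `diversity`, `amova`, `spatial`,
#' `envassoc`, `run`. All read a JSON config (`--config`); `--seed` and
#' `--out` flags override the config file. `run` executes every stage; the
#' other subcommands run the pipeline up to and including the named stage's
#' outputs (stages are cheap relative to I/O, so earlier stages are reused
#' rather than cached).
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Invisibly, the pipeline result (or simulation for `simulate`).
#' @export
msap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: msap <simulate|score|diversity|amova|spatial|envassoc|run>",
    "--config FILE [--seed N] [--out DIR]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg_path <- opt("--config")
  cfg <- pipeline_config(if (is.null(cfg_path)) list(simulate = list())
                         else cfg_path)
  seed <- opt("--seed"); out <- opt("--out")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$outdir <- out
  if (cmd == "simulate") {
    sim_args <- cfg$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% cfg$seed
    study <- simulate_study(do.call(simulation_config, sim_args))
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    write_fragment_panel(study$panels$hpa[[1]],
                         file.path(cfg$outdir, "hpa_rep1.tsv"))
    write_fragment_panel(study$panels$hpa[[2]],
                         file.path(cfg$outdir, "hpa_rep2.tsv"))
    write_fragment_panel(study$panels$msp[[1]],
                         file.path(cfg$outdir, "msp_rep1.tsv"))
    write_fragment_panel(study$panels$msp[[2]],
                         file.path(cfg$outdir, "msp_rep2.tsv"))
    write_tsv_with_header(study$metadata,
                          file.path(cfg$outdir, "metadata.tsv"))
    writeLines(jsonlite::toJSON(study$truth[c("candidates")],
                                auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(cfg$outdir, "truth.json"))
    return(invisible(study))
  }
  if (!cmd %in% c("score", "diversity", "amova", "spatial", "envassoc",
                  "run"))
    stop(usage, call. = FALSE)
  invisible(run_pipeline(cfg))
}
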