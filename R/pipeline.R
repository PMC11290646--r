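pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,               # NULL = return results only, write nothing
    sim = list(),                # overrides merged into sim_config()
    xr_genotypes = c("WT", "csb-1", "xpc-1"),
    xr_replicates = 2L,
    timepoints = xr_timepoints(),
    timecourse_genotype = "xpc-1",
    bin_width = 200L,
    upstream = 2000L,
    qc = list(min_mapq = 20, len_range = c(19L, 24L)),
    dynamics = list(n_perm = 50L, quantile = 0.95),
    run_discovery = TRUE,
    run_chromatin = TRUE,
    run_dynamics = TRUE
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills defaults, and enforces
#' the semantic constraints the stages rely on: unknown keys are rejected;
#' the intergenic-discovery call rules need exactly two XR replicates; the
#' time course must be an ordered subset of the canonical timepoints.
#' Normalisation is idempotent: validating an already-normalised config
#' returns it unchanged.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return Normalised config list of class `"pipeline_config"`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  class(config) <- NULL
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modify_defaults(defaults, config)
  if (isTRUE(cfg$run_discovery) && cfg$xr_replicates != 2L)
    stop("intergenic discovery requires exactly 2 XR replicates ",
         "(non-zero counts in both replicates); got ", cfg$xr_replicates)
  if (!all(cfg$timepoints %in% xr_timepoints()))
    stop("timepoints must be drawn from: ",
         paste(xr_timepoints(), collapse = ", "))
  if (is.unsorted(match(cfg$timepoints, xr_timepoints())))
    stop("timepoints must be in chronological order")
  if (length(cfg$timepoints) < 4L && isTRUE(cfg$run_dynamics))
    stop("dynamic-repair analysis needs at least 4 timepoints")
  cfg$seed <- as.integer(cfg$seed)
  cfg$bin_width <- as.integer(cfg$bin_width)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full synthetic XR-seq analysis pipeline
#'
#' Simulates a genome, annotations and all assay read sets, then runs the
#' downstream stages in dependency order: read QC, strand-resolved TCR
#' quantification (per-gene summaries and metagene profile), intergenic
#' transcription discovery (bin calls, Venn partition, classification,
#' detection metrics against capped RNA-seq truth), chromatin-state and
#' epigenomic-track comparisons, and time-course dynamic-repair detection.
#' All randomness derives from `config$seed`; the same config and seed
#' reproduce identical results.
#'
#' @param config a [validate_config()] result, YAML path, or override list.
#' @param quiet suppress progress messages.
#' @return A `RunReport`: named list of per-stage results plus
#'   `elapsed_s` and the normalised `config`. When `config$outdir` is set,
#'   stage tables are also written there as TSV/JSON.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message("[xrtcr] ", ...)
  set.seed(config$seed)
  report <- list(config = config)

  ## stage: simulate -----------------------------------------------------------
  say("simulate: genome, annotations, assays")
  scfg <- do.call(sim_config, config$sim)
  gen <- simulate_genome(scfg)
  ann <- simulate_annotations(scfg, gen$genome)
  tt_map <- build_tt_map(gen$seq, gen$genome)

  xr <- list()
  for (gt in config$xr_genotypes) {
    tps <- if (gt == config$timecourse_genotype) config$timepoints else "1h"
    for (tp in tps)
      for (rep in seq_len(config$xr_replicates)) {
        id <- sprintf("%s_%s_rep%d", gt, tp, rep)
        xr[[id]] <- suppressWarnings(simulate_xrseq(
          scfg, gen$genome, gen$seq, ann$genes, ann$truth,
          genotype = gt, timepoint = tp, replicate = rep, tt_map = tt_map
        ))
      }
  }
  rna_counts <- simulate_rnaseq(scfg, ann$genes, ann$truth)
  rna_reads <- list(
    WT = simulate_rna_reads(scfg, ann$genes, ann$truth, "WT"),
    xpc = simulate_rna_reads(scfg, ann$genes, ann$truth, "xpc-1")
  )
  capped <- simulate_capped(scfg, gen$genome, ann$genes, ann$annotations,
                            ann$truth)
  tracks <- simulate_tracks(scfg, gen$genome, ann$genes, ann$annotations,
                            ann$truth)
  report$simulate <- list(
    n_genes = length(ann$genes),
    n_ncrna = length(ann$annotations),
    n_xr_samples = length(xr),
    genome_bp = sum(chrom_lengths(gen$genome))
  )

  ## stage: qc -----------------------------------------------------------------
  say("qc: ", length(xr), " XR samples")
  qc_reports <- list()
  for (id in names(xr)) {
    res <- qc_filter(xr[[id]], min_mapq = config$qc$min_mapq,
                     allowed_chroms = names(chrom_lengths(gen$genome)),
                     len_range = config$qc$len_range)
    xr[[id]] <- res$reads
    qc_reports[[id]] <- res$report
  }
  report$qc <- qc_reports

  ## stage: tcr ----------------------------------------------------------------
  say("tcr: strand-resolved quantification")
  prof_genes <- select_profile_genes(ann$genes)
  tcr_tables <- list()
  for (gt in config$xr_genotypes) {
    id <- sprintf("%s_1h_rep1", gt)
    if (!id %in% names(xr)) next
    tcr_tables[[gt]] <- repair_strand_summary(ann$genes, xr[[id]])
  }
  mg_id <- sprintf("%s_1h_rep1", config$timecourse_genotype)
  metagene <- list(
    TS = metagene_profile(prof_genes, xr[[mg_id]], "TS"),
    NTS = metagene_profile(prof_genes, xr[[mg_id]], "NTS")
  )
  report$tcr <- list(
    n_profile_genes = length(prof_genes),
    summaries = tcr_tables,
    metagene_mean = data.frame(bin = 1:100, ts = metagene$TS$mean,
                               nts = metagene$NTS$mean),
    mean_ts_fraction = vapply(tcr_tables, function(t)
      mean(t$ts_fraction, na.rm = TRUE), numeric(1))
  )

  ## stage: discovery ----------------------------------------------------------
  if (isTRUE(config$run_discovery)) {
    say("discovery: intergenic bins and calls")
    grid <- tile_genome(gen$genome, config$bin_width)
    bins <- intergenic_bins(grid, ann$genes, upstream = config$upstream,
                            blacklist = ann$blacklist)
    tc_gt <- config$timecourse_genotype
    comb <- lapply(seq_len(config$xr_replicates), function(rep) {
      per_tp <- vapply(config$timepoints, function(tp) {
        rs <- xr[[sprintf("%s_%s_rep%d", tc_gt, tp, rep)]]
        adjust_library_size(bin_counts(bins, rs), library_size(rs))
      }, numeric(length(bins)))
      combine_timepoints(per_tp)
    })
    cnt <- function(rs) adjust_library_size(bin_counts(bins, rs),
                                            library_size(rs))
    calls <- call_detected(comb[[1]], comb[[2]],
                           cnt(rna_reads$WT), cnt(rna_reads$xpc),
                           cnt(capped$shortcap), cnt(capped$longcap))
    venn <- venn_partition(calls)
    xr_unique <- bins[calls$xr & !calls$rna & !calls$capped]
    classification <- classify_unique_bins(xr_unique, ann$annotations)
    metrics <- list(
      xr = detection_metrics(calls$xr, calls$capped),
      rna = detection_metrics(calls$rna, calls$capped)
    )
    report$discovery <- list(
      n_bins_total = length(grid),
      n_bins_intergenic = length(bins),
      venn = venn,
      n_xr_unique = length(xr_unique),
      classification = classification$fractions,
      metrics = metrics,
      calls = calls,
      bins = bins
    )
  }

  ## stage: chromatin ----------------------------------------------------------
  if (isTRUE(config$run_chromatin)) {
    say("chromatin: state profiles and track comparison")
    state_profiles <- list(
      xr = state_read_proportions(xr[[mg_id]], tracks$states),
      shortcap = state_read_proportions(capped$shortcap, tracks$states),
      longcap = state_read_proportions(capped$longcap, tracks$states),
      rna = state_read_proportions(rna_reads$WT, tracks$states)
    )
    cmp <- NULL
    if (isTRUE(config$run_discovery) && report$discovery$n_xr_unique >= 10) {
      cmp <- compare_to_random(
        report$discovery$bins[report$discovery$calls$xr &
                                !report$discovery$calls$rna],
        tracks$tracks, gen$genome
      )
    }
    report$chromatin <- list(state_profiles = state_profiles,
                             track_comparison = cmp)
  }

  ## stage: dynamics ------------------------------------------------------------
  if (isTRUE(config$run_dynamics)) {
    say("dynamics: time-course trend detection")
    qc_genes <- gene_qc(ann$genes, tt_map, xr)
    tc_gt <- config$timecourse_genotype
    tc <- lapply(seq_len(config$xr_replicates), function(rep) {
      m <- vapply(config$timepoints, function(tp) {
        rs <- xr[[sprintf("%s_%s_rep%d", tc_gt, tp, rep)]]
        cnt <- ts_nts_counts(qc_genes, rs)
        rpkm(cnt$ts, GenomicRanges::width(qc_genes), library_size(rs))
      }, numeric(length(qc_genes)))
      rownames(m) <- S4Vectors::mcols(qc_genes)$gene_id
      m
    })
    thr <- permutation_threshold(tc[[1]], n_perm = config$dynamics$n_perm,
                                 quantile = config$dynamics$quantile)
    r2 <- lapply(tc, segmented_rsq)
    clades <- classify_dynamic_genes(
      r2[[1]]$r_squared, r2[[2]]$r_squared, thr,
      (tc[[1]] + tc[[2]]) / 2,
      gene_ids = S4Vectors::mcols(qc_genes)$gene_id
    )
    report$dynamics <- list(
      n_qc_genes = length(qc_genes),
      threshold = as.numeric(thr),
      n_significant = sum(clades$significant),
      clades = table(clades$clade),
      flag = clades$flag
    )
  }

  report$elapsed_s <- proc.time()[["elapsed"]] - t0
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  say(sprintf("done in %.1f s", report$elapsed_s))
  invisible(report)
}

# Persist the text-format outputs of a pipeline run.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (gt in names(report$tcr$summaries))
    w(report$tcr$summaries[[gt]], sprintf("tcr_summary_%s.tsv", gt))
  w(report$tcr$metagene_mean, "metagene_mean.tsv")
  summary <- list(
    seed = report$config$seed,
    simulate = report$simulate,
    tcr_mean_ts_fraction = as.list(report$tcr$mean_ts_fraction),
    elapsed_s = report$elapsed_s
  )
  if (!is.null(report$discovery))
    summary$discovery <- list(
      n_bins_total = report$discovery$n_bins_total,
      n_bins_intergenic = report$discovery$n_bins_intergenic,
      venn = as.list(report$discovery$venn),
      n_xr_unique = report$discovery$n_xr_unique,
      metrics = report$discovery$metrics
    )
  if (!is.null(report$dynamics))
    summary$dynamics <- report$dynamics[c("n_qc_genes", "threshold",
                                          "n_significant", "flag")]
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
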