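#' Simulate epigenomic tracks and a chromatin-state segmentation
#'
#' Produces bedGraph-style tracks in fixed windows across the genome with
#' log-normal noise around a baseline and fold-enrichment at the regions
#' each mark decorates: chromatin accessibility (ATAC, DNase) and H3K4me3
#' at promoters, H3K4me1 at enhancers (eRNA loci), accessibility also at
#' enhancers, and H3K27me3 over broad randomly placed repressed domains.
#' A chromatin-state segmentation with `n_states` labels is derived from
#' the same features: state 1 = promoter, 2 = gene body 5' half,
#' 3 = gene body 3' half, 4 = enhancer, 5 = piRNA domain, 6 = lincRNA,
#' 7 = repressed domain, and the remaining states partition the background
#' at random.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_build()].
#' @param genes gene `GRanges`.
#' @param annotations ncRNA `GRanges` (with `class`).
#' @param truth truth list (for the piRNA cluster span).
#' @param seed optional integer seed.
#'
#' @return List with `tracks` (named list of window `GRanges` with `score`:
#'   ATAC, DNase, H3K4me1, H3K4me3, H3K27me3), `states` (window `GRanges`
#'   with integer `state`), `repressed` (the repressed domains).
#' @export
simulate_tracks <- function(config = sim_config(), genome, genes,
                            annotations, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tcfg <- config$tracks
  win <- tile_genome(genome, tcfg$window)
  lens <- chrom_lengths(genome)

  promoters <- GenomicRanges::trim(suppressWarnings(GenomicRanges::promoters(
    genes, upstream = tcfg$promoter_halfwidth,
    downstream = tcfg$promoter_halfwidth)))
  cls <- as.character(S4Vectors::mcols(annotations)$class)
  enhancers <- annotations[cls == "eRNA"]
  lincs <- annotations[cls == "lincRNA"]

  dw <- tcfg$repressed_domain_width
  dchr <- sample(names(lens), tcfg$repressed_domain_n, replace = TRUE,
                 prob = pmax(0, lens - dw))
  dstart <- vapply(dchr, function(ch) sample.int(lens[[ch]] - dw, 1L),
                   integer(1))
  repressed <- GenomicRanges::GRanges(
    seqnames = dchr, ranges = IRanges::IRanges(dstart, width = dw),
    seqinfo = genome$seqinfo
  )

  at_prom <- IRanges::overlapsAny(win, promoters, ignore.strand = TRUE)
  at_enh <- IRanges::overlapsAny(win, enhancers, ignore.strand = TRUE)
  at_rep <- IRanges::overlapsAny(win, repressed, ignore.strand = TRUE)

  noisy <- function(fold_mask_list) {
    base <- tcfg$baseline *
      exp(stats::rnorm(length(win), 0, tcfg$noise_sd))
    for (fm in fold_mask_list) base[fm$mask] <- base[fm$mask] * fm$fold
    out <- GenomicRanges::granges(win)
    S4Vectors::mcols(out)$score <- base
    out
  }
  tracks <- list(
    ATAC = noisy(list(list(mask = at_prom, fold = tcfg$promoter_fold),
                      list(mask = at_enh, fold = tcfg$enhancer_fold))),
    DNase = noisy(list(list(mask = at_prom, fold = tcfg$promoter_fold),
                       list(mask = at_enh, fold = tcfg$enhancer_fold))),
    H3K4me1 = noisy(list(list(mask = at_enh, fold = tcfg$enhancer_fold))),
    H3K4me3 = noisy(list(list(mask = at_prom, fold = tcfg$promoter_fold))),
    H3K27me3 = noisy(list(list(mask = at_rep, fold = tcfg$repressed_fold)))
  )

  ## chromatin states by priority over the same windows
  state <- rep(NA_integer_, length(win))
  assign_state <- function(state, regions, id) {
    hit <- IRanges::overlapsAny(win, regions, ignore.strand = TRUE)
    state[is.na(state) & hit] <- id
    state
  }
  gene5 <- GenomicRanges::resize(
    genes, pmax(1L, GenomicRanges::width(genes) %/% 2L), fix = "start")
  gene3 <- GenomicRanges::resize(
    genes, pmax(1L, GenomicRanges::width(genes) %/% 2L), fix = "end")
  state <- assign_state(state, promoters, 1L)
  state <- assign_state(state, gene5, 2L)
  state <- assign_state(state, gene3, 3L)
  state <- assign_state(state, enhancers, 4L)
  state <- assign_state(state, truth$pirna_cluster, 5L)
  state <- assign_state(state, lincs, 6L)
  state <- assign_state(state, repressed, 7L)
  bg <- is.na(state)
  if (tcfg$n_states > 7L)
    state[bg] <- sample(8:tcfg$n_states, sum(bg), replace = TRUE)
  else
    state[bg] <- tcfg$n_states
  states <- GenomicRanges::granges(win)
  S4Vectors::mcols(states)$state <- state

  list(tracks = tracks, states = states, repressed = repressed)
}
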