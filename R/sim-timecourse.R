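#' Simulate per-gene repair time courses with planted dynamic trends
#'
#' Generates a genes x timepoints matrix (optionally several replicates
#' sharing the same truth) in which a configured fraction of genes carries
#' a planted dynamic-repair trend drawn from two archetypes — `"early"`
#' (repair peaking at the second timepoint, then declining) and `"late"`
#' (repair rising to a peak at the second-to-last timepoint) — while the
#' remaining genes are flat. Gaussian noise is added at `noise_sd` times
#' each gene's dynamic range (or its level, for flat genes); the default
#' 0.02 corresponds to the counting noise of per-gene totals of a few
#' thousand reads.
#'
#' @param n_genes number of genes.
#' @param frac_dynamic fraction of genes given a planted trend
#'   (default 0.1).
#' @param archetype_probs named probabilities for the `early`/`late`
#'   archetypes among dynamic genes.
#' @param noise_sd noise level relative to each gene's range (default
#'   0.02).
#' @param n_timepoints number of ordered timepoints (default 6).
#' @param replicates number of replicate matrices sharing the truth.
#' @param seed optional integer seed.
#'
#' @return List with `matrices` (list of `replicates` matrices, genes x
#'   timepoints) and `truth` (`data.frame`: `gene`, `dynamic`, `class`
#'   (`early`/`late`/`flat`)).
#' @export
simulate_timecourse <- function(n_genes = 100, frac_dynamic = 0.1,
                                archetype_probs = c(early = 0.9, late = 0.1),
                                noise_sd = 0.02, n_timepoints = 6L,
                                replicates = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- n_timepoints
  u <- seq(0, 1, length.out = T)
  # archetype shapes: smooth unimodal profiles peaking early / late
  early_shape <- exp(-((u - u[2]) / 0.3)^2)
  late_shape <- exp(-((u - u[T - 1]) / 0.3)^2)
  n_dyn <- round(frac_dynamic * n_genes)
  cls <- rep("flat", n_genes)
  if (n_dyn > 0)
    cls[seq_len(n_dyn)] <- sample(names(archetype_probs), n_dyn,
                                  replace = TRUE, prob = archetype_probs)
  level <- stats::rlnorm(n_genes, log(10), 0.5)
  amp <- stats::rlnorm(n_genes, log(5), 0.3)
  base_profile <- function(g) {
    switch(cls[g],
           early = level[g] + amp[g] * early_shape,
           late = level[g] + amp[g] * late_shape,
           flat = rep(level[g], T))
  }
  signal <- t(vapply(seq_len(n_genes), base_profile, numeric(T)))
  scale <- apply(signal, 1L, function(y) {
    r <- diff(range(y)); if (r > 0) r else mean(y)
  })
  matrices <- lapply(seq_len(replicates), function(r) {
    m <- signal + matrix(stats::rnorm(n_genes * T, 0, noise_sd * scale),
                         nrow = n_genes)
    rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
    colnames(m) <- if (T == 6L) xr_timepoints() else paste0("t", seq_len(T))
    m
  })
  list(
    matrices = matrices,
    truth = data.frame(
      gene = sprintf("gene%04d", seq_len(n_genes)),
      dynamic = cls != "flat",
      class = cls,
      stringsAsFactors = FALSE
    )
  )
}
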