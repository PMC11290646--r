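# -- segmented-trend engine ---------------------------------------------------
# Continuous piecewise-linear least squares over ordered sample indices
# x = 0..T-1, with 0..2 breakpoints placed exhaustively at the midpoints
# between consecutive samples (so every segment keeps at least one sample).
# For a placement b the design is [1, x, (x-b1)+, (x-b2)+]; hat matrices are
# precomputed per series length so repeated fits (permutations) reduce to
# small matrix products.

segmented_engine <- local({
  cache <- list()
  function(T, max_breakpoints = 2L) {
    key <- paste(T, max_breakpoints)
    if (!is.null(cache[[key]])) return(cache[[key]])
    x <- seq_len(T) - 1
    mids <- x[-T] + 0.5
    placements <- list(list(k = 0L, b = numeric(0)))
    if (max_breakpoints >= 1L)
      for (b1 in mids)
        placements[[length(placements) + 1L]] <- list(k = 1L, b = b1)
    if (max_breakpoints >= 2L)
      for (i in seq_along(mids))
        for (j in seq_along(mids))
          if (j > i)
            placements[[length(placements) + 1L]] <-
              list(k = 2L, b = c(mids[i], mids[j]))
    for (p in seq_along(placements)) {
      b <- placements[[p]]$b
      X <- cbind(1, x)
      for (bb in b) X <- cbind(X, pmax(x - bb, 0))
      pinv <- solve(crossprod(X), t(X))
      placements[[p]]$X <- X
      placements[[p]]$pinv <- pinv
      placements[[p]]$hat <- X %*% pinv
    }
    out <- list(T = T, x = x, mids = mids, placements = placements,
                k_of = vapply(placements, `[[`, integer(1), "k"))
    cache[[key]] <<- out
    out
  }
})

# Per-gene RSS minimised within each breakpoint count, then BIC selection.
# Y: T x G matrix. Returns list(r_squared, k, best_placement) vectors.
segmented_select <- function(Y, max_breakpoints = 2L) {
  T <- nrow(Y)
  eng <- segmented_engine(T, max_breakpoints)
  G <- ncol(Y)
  n_pl <- length(eng$placements)
  rss <- matrix(Inf, nrow = n_pl, ncol = G)
  for (p in seq_len(n_pl)) {
    R <- Y - eng$placements[[p]]$hat %*% Y
    rss[p, ] <- colSums(R * R)
  }
  ks <- sort(unique(eng$k_of))
  best_rss <- matrix(Inf, nrow = length(ks), ncol = G)
  best_pl <- matrix(NA_integer_, nrow = length(ks), ncol = G)
  for (ki in seq_along(ks)) {
    rows <- which(eng$k_of == ks[ki])
    sub <- rss[rows, , drop = FALSE]
    w <- apply(sub, 2L, which.min)
    best_pl[ki, ] <- rows[w]
    best_rss[ki, ] <- sub[cbind(w, seq_len(G))]
  }
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  # BIC with 2 + 2k parameters (intercept, slope, plus slope change and
  # location per breakpoint); ties and near-ties resolved toward smaller k.
  # RSS is floored relative to the series' total variation so that exact
  # fits compare as ties instead of amplifying rounding noise.
  floor_rss <- matrix(rep(pmax(tss, .Machine$double.eps) * 1e-10,
                          each = length(ks)), nrow = length(ks))
  bic <- T * log(pmax(best_rss, floor_rss) / T) +
    outer(n_par <- 2 + 2 * ks, rep(log(T), G))
  sel <- apply(bic, 2L, function(col) which(col < min(col) + 1e-9)[1])
  sel_rss <- best_rss[cbind(sel, seq_len(G))]
  r2 <- ifelse(tss <= .Machine$double.eps, 0,
               pmax(0, 1 - sel_rss / tss))
  list(
    r_squared = r2,
    k = ks[sel],
    placement = best_pl[cbind(sel, seq_len(G))],
    engine = eng
  )
}

#' Fit a segmented linear trend to one repair time course
#'
#' Exhaustively searches continuous piecewise-linear models with up to
#' `max_breakpoints` breakpoints (so up to three segments, each containing
#' at least one sample) over the ordered sample index 0..T-1, choosing the
#' breakpoint count by BIC and reporting the selected model's R^2. Time is
#' encoded as ordered index, not clock hours: the experimental timepoints
#' span three orders of magnitude and only their order is modelled.
#'
#' @param y numeric vector of per-timepoint values (length >= 4).
#' @param max_breakpoints 0, 1 or 2 (default 2).
#' @return List of class `"TrendFit"`: `k` (selected breakpoint count),
#'   `breakpoints` (1-based index of the last timepoint before each break),
#'   `slopes` (one per segment), `r_squared`, `fitted`.
#' @examples
#' fit_segmented_trend(c(0, 1, 2, 3, 2, 1))$k
#' @export
fit_segmented_trend <- function(y, max_breakpoints = 2L) {
  y <- as.numeric(y)
  T <- length(y)
  if (T < 4L) stop("need at least 4 timepoints")
  if (any(!is.finite(y))) stop("non-finite values in y")
  if (stats::var(y) <= .Machine$double.eps) {
    out <- list(k = 0L, breakpoints = integer(0), slopes = 0,
                r_squared = 0, fitted = rep(mean(y), T))
    class(out) <- "TrendFit"
    return(out)
  }
  sel <- segmented_select(matrix(y, ncol = 1), max_breakpoints)
  pl <- sel$engine$placements[[sel$placement[1]]]
  beta <- as.vector(pl$pinv %*% y)
  slopes <- cumsum(beta[-1])       # slope per segment
  out <- list(
    k = sel$k[1],
    breakpoints = if (pl$k > 0) as.integer(floor(pl$b) + 1L) else integer(0),
    slopes = slopes,
    r_squared = sel$r_squared[1],
    fitted = as.vector(pl$X %*% beta)
  )
  class(out) <- "TrendFit"
  out
}

#' @export
print.TrendFit <- function(x, ...) {
  cat(sprintf("TrendFit: k=%d%s, R^2=%.3f\n", x$k,
              if (x$k > 0) paste0(" after t", paste(x$breakpoints,
                                                    collapse = ",t")) else "",
              x$r_squared))
  invisible(x)
}

#' Permutation-derived R^2 significance threshold
#'
#' Shuffles the timepoint labels — one shared shuffle per permutation,
#' applied identically to every gene — refits the segmented trend for each
#' gene, and records the BIC-selected model's R^2 (the same statistic used
#' to score observed genes, so null and observed values are exchangeable).
#' The threshold is the requested quantile of the pooled permuted R^2
#' distribution.
#'
#' @param mat numeric matrix, genes x ordered timepoints.
#' @param n_perm number of permutations (>= 20; default 100).
#' @param quantile pooled quantile defining the threshold (default 0.95).
#' @param max_breakpoints passed to the fitter (default 2).
#' @param seed optional integer seed.
#' @return Numeric threshold with attributes `n_perm`, `quantile`,
#'   `n_values`.
#' @export
permutation_threshold <- function(mat, n_perm = 100L, quantile = 0.95,
                                  max_breakpoints = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 20L) stop("n_perm must be at least 20")
  mat <- as.matrix(mat)
  T <- ncol(mat)
  Y <- t(mat)                       # T x G
  vals <- numeric(0)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(T)
    r2 <- segmented_select(Y[perm, , drop = FALSE], max_breakpoints)$r_squared
    vals <- c(vals, r2)
  }
  thr <- stats::quantile(vals, quantile, names = FALSE, type = 7)
  attr(thr, "n_perm") <- n_perm
  attr(thr, "quantile") <- quantile
  attr(thr, "n_values") <- length(vals)
  thr
}

#' R^2 of the selected segmented model for every gene
#'
#' Vectorised version of [fit_segmented_trend()] returning only the
#' selected-model R^2 and breakpoint count per gene.
#'
#' @inheritParams permutation_threshold
#' @return `data.frame` with `r_squared` and `k`, one row per gene.
#' @export
segmented_rsq <- function(mat, max_breakpoints = 2L) {
  mat <- as.matrix(mat)
  Y <- t(mat)
  const <- apply(Y, 2L, function(col) stats::var(col) <= .Machine$double.eps)
  sel <- segmented_select(Y, max_breakpoints)
  data.frame(
    r_squared = ifelse(const, 0, sel$r_squared),
    k = ifelse(const, 0L, sel$k)
  )
}

#' Classify significantly dynamic genes into early and late clades
#'
#' A gene is significant iff its selected-model R^2 exceeds `threshold` in
#' both replicates. Significant genes' profiles (replicate mean,
#' row-standardised) are clustered hierarchically with correlation distance
#' and average linkage; the tree is cut at two clades and the clade whose
#' mean profile peaks earlier is labelled `"early"`. Fewer than two
#' significant genes, or fully degenerate profiles, skip the clustering
#' with a flag.
#'
#' @param r2_rep1,r2_rep2 per-gene selected-model R^2 for the two
#'   replicates (e.g. from [segmented_rsq()]).
#' @param threshold R^2 significance threshold
#'   (from [permutation_threshold()]).
#' @param profiles numeric matrix, genes x timepoints, used for clustering
#'   (typically the replicate-mean RPKM).
#' @param gene_ids optional gene identifiers.
#' @return List with `significant` (logical per gene), `clade` (factor
#'   `early`/`late`, `NA` for non-significant genes), `flag`
#'   (`""`, `"too_few"`, or `"degenerate"`).
#' @export
classify_dynamic_genes <- function(r2_rep1, r2_rep2, threshold, profiles,
                                   gene_ids = NULL) {
  stopifnot(length(r2_rep1) == length(r2_rep2),
            nrow(profiles) == length(r2_rep1))
  sig <- r2_rep1 > threshold & r2_rep2 > threshold
  n <- length(sig)
  clade <- factor(rep(NA_character_, n), levels = c("early", "late"))
  flag <- ""
  if (sum(sig) < 2L) {
    if (sum(sig) == 1L) clade[sig] <- "early"
    flag <- "too_few"
  } else {
    P <- profiles[sig, , drop = FALSE]
    sds <- apply(P, 1L, stats::sd)
    Z <- sweep(P, 1L, rowMeans(P))
    Z <- sweep(Z, 1L, ifelse(sds > 0, sds, 1), "/")
    cm <- suppressWarnings(stats::cor(t(Z)))
    cm[!is.finite(cm)] <- 0
    d <- stats::as.dist(1 - cm)
    if (max(d) < 1e-12) {
      clade[sig] <- "early"
      flag <- "degenerate"
    } else {
      hc <- stats::hclust(d, method = "average")
      grp <- stats::cutree(hc, k = 2L)
      peak <- vapply(1:2, function(g) {
        if (!any(grp == g)) return(Inf)
        mean_profile <- colMeans(Z[grp == g, , drop = FALSE])
        which.max(mean_profile)
      }, numeric(1))
      early_grp <- which.min(peak)
      lab <- ifelse(grp == early_grp, "early", "late")
      clade[sig] <- lab
    }
  }
  if (!is.null(gene_ids)) names(clade) <- gene_ids
  list(significant = sig, clade = clade, flag = flag)
}
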