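#' Build the bin-level gold standard for TU evaluation
#'
#' A bin is actively transcribed (AT = 1) iff both the binarized RNA
#' polymerase II ChIP-seq enrichment and the nascent-RNA evidence are 1 in
#' that bin. Bins overlapping exclusion intervals (e.g. assembly gaps) are
#' removed from all downstream tallies but keep their indices.
#'
#' @param polII_calls 0/1 vector of binarized Pol II enrichment per bin.
#' @param nascent_calls 0/1 vector of nascent-RNA presence per bin (see
#'   [intervals_to_bin_mask()] over nascent transcripts).
#' @param grid a [bin_grid()].
#' @param exclusion optional `genomic_intervals` of regions to drop.
#' @return list of class `gold_standard`: `at` (0/1 vector), `keep` (logical
#'   evaluation mask), `grid`.
#' @export
build_gold_standard <- function(polII_calls, nascent_calls, grid,
                                exclusion = NULL) {
  stopifnot_grid(grid)
  if (length(polII_calls) != grid$n_total || length(nascent_calls) != grid$n_total)
    stop("call vectors must match the grid")
  keep <- rep(TRUE, grid$n_total)
  if (!is.null(exclusion))
    keep <- intervals_to_bin_mask(exclusion, grid) == 0L
  if (!any(keep)) stop("all bins excluded; empty evaluation set")
  at <- as.integer(polII_calls == 1L & nascent_calls == 1L)
  structure(list(at = at, keep = keep, grid = grid), class = "gold_standard")
}

#' Bin-level contingency counts and derived rates
#'
#' @param gold a [build_gold_standard()] result.
#' @param pred 0/1 prediction vector per bin (e.g. from
#'   [intervals_to_bin_mask()] over TU predictions).
#' @return list with TP/FP/FN/TN, precision (0 when nothing is called),
#'   recall and specificity.
#' @export
contingency <- function(gold, pred) {
  if (length(pred) != length(gold$at)) stop("prediction length mismatch")
  at <- gold$at[gold$keep]; pt <- as.integer(pred)[gold$keep]
  tp <- sum(at == 1L & pt == 1L); fp <- sum(at == 0L & pt == 1L)
  fn <- sum(at == 1L & pt == 0L); tn <- sum(at == 0L & pt == 0L)
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0)
}

# ROC and PRC points from labels and scores; ties grouped at one threshold
curve_points <- function(labels, scores) {
  ord <- order(-scores)
  labels <- labels[ord]; scores <- scores[ord]
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(labels == 1L); fp <- cumsum(labels == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  data.frame(threshold = scores[last], TP = tp[last], FP = fp[last],
             tpr = if (P > 0) tp[last] / P else NA_real_,
             fpr = if (N > 0) fp[last] / N else NA_real_,
             precision = tp[last] / (tp[last] + fp[last]),
             recall = if (P > 0) tp[last] / P else NA_real_)
}

trapezoid <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
}

#' ROC and precision-recall curves with trapezoidal AUCs
#'
#' Thresholds sweep the scores in decreasing order with ties grouped. For a
#' binary (score-less) prediction the curve degenerates to its single
#' operating point plus the endpoints, which keeps cross-method AUCs
#' interpretable.
#'
#' @param gold a [build_gold_standard()] result.
#' @param scores per-bin ranking score (higher = more confidently
#'   transcribed), e.g. the TU posterior from [decode_genome()].
#' @return list with `roc` and `prc` point data frames, `auc_roc`, `auc_prc`.
#'   All-positive or all-negative gold standards are an error for the ROC and
#'   a warning (NA AUC) for the PRC.
#' @export
roc_prc <- function(gold, scores) {
  if (length(scores) != length(gold$at)) stop("score length mismatch")
  labels <- gold$at[gold$keep]; sc <- scores[gold$keep]
  if (any(!is.finite(sc))) stop("scores must be finite")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("gold standard is all-", if (P == 0L) "negative" else "positive",
         "; ROC is undefined")
  pts <- curve_points(labels, sc)
  roc <- rbind(data.frame(threshold = Inf, TP = 0L, FP = 0L, tpr = 0, fpr = 0,
                          precision = NA_real_, recall = 0), pts)
  auc_roc <- trapezoid(roc$fpr, roc$tpr)
  prc <- rbind(data.frame(threshold = Inf, TP = 0L, FP = 0L, tpr = 0, fpr = 0,
                          precision = pts$precision[1], recall = 0), pts)
  auc_prc <- trapezoid(prc$recall, prc$precision)
  list(roc = roc[, c("threshold", "fpr", "tpr")],
       prc = prc[, c("threshold", "recall", "precision")],
       auc_roc = auc_roc, auc_prc = auc_prc)
}

auc_only <- function(labels, scores, curve = c("roc", "prc")) {
  curve <- match.arg(curve)
  pts <- curve_points(labels, scores)
  if (curve == "roc")
    trapezoid(c(0, pts$fpr), c(0, pts$tpr))
  else
    trapezoid(c(0, pts$recall), c(pts$precision[1], pts$precision))
}

#' Subsampled AUC estimator for class-imbalanced genomes
#'
#' Transcribed bins are a small minority of the genome, so full-genome AUCs
#' are dominated by the negative class. Each iteration keeps positive bins
#' (all of them, or `sample_size` of them) plus an equal number of sampled
#' negative bins, computes the AUC on this balanced subset, and the final
#' estimate is \code{mean(L_AUC) - stdDev(L_AUC) / sqrt(n)} over the n
#' iterations (sample standard deviation) — a mean shrunk by its standard
#' error, i.e. a conservative lower estimate.
#'
#' @param gold a [build_gold_standard()] result.
#' @param scores per-bin ranking score.
#' @param n_iterations number of sampling iterations n (>= 2; default 100).
#' @param sample_size positives per iteration (default NULL: all positives).
#' @param seed RNG seed for the bin sampling.
#' @param curve "roc" or "prc".
#' @return list of class `auc_estimate`: `estimate`, `L_auc`, `n`, `curve`.
#' @export
sampled_auc <- function(gold, scores, n_iterations = 100, sample_size = NULL,
                        seed = 17, curve = c("roc", "prc")) {
  curve <- match.arg(curve)
  if (n_iterations < 2) stop("n_iterations must be >= 2 for a defined stdDev")
  labels <- gold$at[gold$keep]; sc <- scores[gold$keep]
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  npos <- if (is.null(sample_size)) length(pos) else sample_size
  if (length(pos) < npos || npos < 1L)
    stop("fewer positive bins (", length(pos), ") than required (", npos, ")")
  if (length(neg) < 1L) stop("no negative bins to sample")
  L <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vapply(seq_len(n_iterations), function(i) {
      p <- if (npos < length(pos)) sample(pos, npos) else pos
      n <- sample(neg, min(npos, length(neg)), replace = length(neg) < npos)
      idx <- c(p, n)
      auc_only(labels[idx], sc[idx], curve)
    }, numeric(1))
  })
  structure(list(estimate = auc_from_samples(L),
                 L_auc = L, n = n_iterations, curve = curve),
            class = "auc_estimate")
}

#' Combine per-sample AUCs into the subsampled estimate
#'
#' \code{mean(L_AUC) - stdDev(L_AUC) / sqrt(n)} with the sample (n - 1)
#' standard deviation and n = length(L_AUC).
#'
#' @param L_auc numeric vector of per-iteration AUCs.
#' @return the combined estimate.
#' @export
auc_from_samples <- function(L_auc) {
  mean(L_auc) - stats::sd(L_auc) / sqrt(length(L_auc))
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("sampled AUC-%s: %.4f (n = %d, mean = %.4f, sd = %.4f)\n",
              toupper(x$curve), x$estimate, x$n, mean(x$L_auc), stats::sd(x$L_auc)))
  invisible(x)
}

#' Re-derive a bin mask at a different resolution
#'
#' Masks are recomputed from intervals at the new bin width when intervals
#' are given (the exact definition of the evaluation masks). A plain vector
#' can only be coarsened to an integer multiple of its own width (a coarse
#' bin is set iff any of its fine bins is set); anything else requires the
#' intervals.
#'
#' @param x a `genomic_intervals` data frame, or a 0/1 vector.
#' @param grid the [bin_grid()] the input lives on (its `bin_width` is the
#'   source resolution).
#' @param to_width target bin width in bp (e.g. 50, 100, 200, 500).
#' @return list with `grid` (the new [bin_grid()]) and `mask` (0/1 vector).
#' @export
rebin <- function(x, grid, to_width) {
  stopifnot_grid(grid)
  if (to_width <= 0) stop("to_width must be positive")
  new_grid <- bin_grid(grid$lengths, to_width)
  if (is.data.frame(x))
    return(list(grid = new_grid, mask = intervals_to_bin_mask(x, new_grid)))
  if (length(x) != grid$n_total) stop("vector length does not match grid")
  if (to_width %% grid$bin_width != 0)
    stop("cannot rebin a vector from ", grid$bin_width, " to ", to_width,
         " bp; supply the source intervals instead")
  mask <- integer(new_grid$n_total)
  set <- which(x == 1L) - 1L
  if (length(set)) {
    bc <- bin_coords(grid, set)
    for (i in seq_len(nrow(bc))) {
      idx <- bin_span(new_grid, bc$contig[i], bc$start[i], bc$end[i])
      mask[idx + 1L] <- 1L
    }
  }
  list(grid = new_grid, mask = mask)
}
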