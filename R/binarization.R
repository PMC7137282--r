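#' Fit a binomial-mixture enrichment model to ChIP vs control counts
#'
#' Per bin i, the ChIP count s_i is modelled as binomial with t_i = chip_i +
#' control_i trials and a success probability drawn from a K-component
#' mixture. The background component sits near the genome-wide ChIP fraction;
#' the component with the largest success probability is labelled "enriched".
#' Bins with t_i = 0 carry no information and are excluded from the fit and
#' from calling (the `binFilter = "zero"` convention of enrichment callers).
#'
#' EM is initialised deterministically: the background success probability at
#' the median per-bin ChIP fraction, the enriched one at the 90th percentile;
#' the log-likelihood is non-decreasing across iterations.
#'
#' @param chip,control per-bin non-negative integer count vectors of equal
#'   length (see [count_reads_midpoint()] or [read_bin_table()]).
#' @param n_components number of mixture components (>= 2; default 2).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return an `enrichment_fit` object: `posterior` (P(enriched | bin), NA for
#'   excluded bins), `qvalue`, mixture `proportions` and success
#'   probabilities `p`, `loglik_trace`, `converged`, and `excluded` mask.
#' @export
fit_enrichment <- function(chip, control, n_components = 2,
                           max_iter = 1000, tol = 1e-8) {
  if (length(chip) != length(control)) stop("chip and control lengths differ")
  if (any(chip < 0) || any(control < 0)) stop("counts must be non-negative")
  if (n_components < 2) stop("n_components must be >= 2")
  s <- as.numeric(chip)
  t <- as.numeric(chip) + as.numeric(control)
  excluded <- t == 0
  if (all(excluded)) stop("all bins have zero counts; nothing to fit")
  si <- s[!excluded]; ti <- t[!excluded]
  frac <- si / ti

  qs <- stats::quantile(frac, probs = seq(0.5, 0.9, length.out = n_components),
                        names = FALSE)
  p <- pmin(pmax(qs, 1e-4), 1 - 1e-4)
  # spread collapsed initial values
  for (c in 2:n_components) if (p[c] <= p[c - 1]) p[c] <- min(p[c - 1] + 0.05, 1 - 1e-4)
  prop <- c(0.9, rep(0.1 / (n_components - 1), n_components - 1))

  loglik_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  lchoose_const <- lchoose(ti, si)   # constant in EM, kept for a proper loglik
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(n_components), function(c)
      log(prop[c]) + si * log(p[c]) + (ti - si) * log1p(-p[c]), numeric(length(si)))
    m <- apply(lp, 1, max)
    w <- exp(lp - m)
    denom <- rowSums(w)
    r <- w / denom
    ll <- sum(m + log(denom) + lchoose_const)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol && ll - ll_prev > -1e-8) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    prop <- colMeans(r)
    p <- colSums(r * si) / colSums(r * ti)
    p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  }
  if (!converged) warning("enrichment EM did not converge after ", max_iter,
                          " iterations; returning best fit")

  # ties (e.g. chip identical to control, all components collapsed) resolve
  # to the highest-index component — the one initialised at the top quantile —
  # whose posterior then equals its minority proportion and nothing is called
  enr <- max(which(p >= max(p) - 1e-9))
  posterior <- rep(NA_real_, length(s))
  posterior[!excluded] <- r[, enr]
  structure(list(posterior = posterior, qvalue = qvalue_from_posterior(posterior),
                 proportions = prop, p = p, enriched_component = enr,
                 loglik_trace = loglik_trace, converged = converged,
                 excluded = excluded), class = "enrichment_fit")
}

# q-value per bin: running mean of (1 - posterior) over bins sorted by
# decreasing posterior; a bin's q estimates the FDR incurred by calling
# everything at least as confident. Bins with tied posteriors share the
# running mean at the end of their tie group, so the output is invariant
# under bin permutation.
qvalue_from_posterior <- function(posterior) {
  q <- rep(NA_real_, length(posterior))
  ok <- which(!is.na(posterior))
  if (!length(ok)) return(q)
  ord <- ok[order(-posterior[ok], ok)]
  run <- cumsum(1 - posterior[ord]) / seq_along(ord)
  grp <- cumsum(!duplicated(posterior[ord]))
  run <- stats::ave(run, grp, FUN = function(x) x[length(x)])
  q[ord] <- run
  q
}

#' Binary enrichment calls at a target FDR
#'
#' Calls bins whose q-value (running mean of 1 - posterior along decreasing
#' posterior order) is at or below `fdr`. Excluded (zero-count) bins are never
#' called.
#'
#' @param fit an [fit_enrichment()] result.
#' @param fdr target false discovery rate in (0, 1); default 0.2.
#' @return integer 0/1 vector, one entry per bin.
#' @export
call_enriched <- function(fit, fdr = 0.2) {
  if (!inherits(fit, "enrichment_fit")) stop("fit must be an enrichment_fit")
  if (length(fdr) != 1 || !is.finite(fdr) || fdr <= 0 || fdr >= 1)
    stop("fdr must be in (0, 1)")
  calls <- integer(length(fit$posterior))
  ok <- !is.na(fit$qvalue)
  calls[ok] <- as.integer(fit$qvalue[ok] <= fdr)
  calls
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("enrichment_fit: %d bins (%d excluded), p = [%s], proportions = [%s]\n",
              length(x$posterior), sum(x$excluded),
              paste(sprintf("%.3f", x$p), collapse = ", "),
              paste(sprintf("%.3f", x$proportions), collapse = ", ")))
  invisible(x)
}

#' Assemble a class matrix from per-mark binary call vectors
#'
#' The class matrix C is the m bins x n marks binary observation matrix the
#' transcription-unit HMM operates on; C[i, j] is the binarized enrichment of
#' mark j in bin i. Column order is recorded and enforced at prediction time.
#'
#' @param calls named list of 0/1 vectors (one per mark), each of length
#'   `grid$n_total`.
#' @param grid a [bin_grid()].
#' @param mark_order character vector naming exactly the marks in `calls`, in
#'   the column order to use (default: names of `calls`).
#' @return integer matrix (bins x marks) with `colnames = mark_order`.
#' @export
build_class_matrix <- function(calls, grid, mark_order = names(calls)) {
  stopifnot_grid(grid)
  if (is.null(names(calls)) || !setequal(mark_order, names(calls)) ||
      length(mark_order) != length(calls))
    stop("mark_order must cover exactly the provided marks")
  lens <- lengths(calls)
  if (any(lens != grid$n_total))
    stop("call vector length mismatch with grid for: ",
         paste(names(calls)[lens != grid$n_total], collapse = ", "))
  if (length(calls) == 1L)
    warning("single-mark class matrix: the model degenerates to one emission column")
  m <- do.call(cbind, lapply(calls[mark_order], as.integer))
  if (any(!m %in% c(0L, 1L))) stop("calls must be binary")
  colnames(m) <- mark_order
  m
}
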