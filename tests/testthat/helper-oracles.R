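# Brute-force HMM oracles: enumerate all k^T paths. Independent of the
# forward/Viterbi implementation under test.
enum_paths <- function(params, obs) {
  k <- params$k
  T <- nrow(obs)
  le <- emission_loglik(params, obs)
  lt <- suppressWarnings(log(params$transition))
  li <- suppressWarnings(log(params$initial))
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), T)))
  lp <- li[paths[, 1]] + le[cbind(1, paths[, 1])]
  if (T > 1)
    for (t in 2:T)
      lp <- lp + lt[cbind(paths[, t - 1], paths[, t])] + le[cbind(t, paths[, t])]
  lp
}

enum_loglik <- function(params, obs) {
  lp <- enum_paths(params, obs)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

enum_best <- function(params, obs) max(enum_paths(params, obs))

# random row-stochastic HMM, optionally with a structural-zero mask
rand_hmm <- function(k, n, zero_mask = NULL) {
  A <- matrix(stats::rgamma(k * k, 1), k)
  if (!is.null(zero_mask)) A[zero_mask] <- 0
  A <- A / rowSums(A)
  E <- matrix(stats::runif(k * n), k)
  init <- stats::rgamma(k, 1)
  hmm_params(E, A, init / sum(init), zero_mask = if (is.null(zero_mask)) A == 0 else zero_mask)
}

rand_obs <- function(T, n) matrix(stats::rbinom(T * n, 1, 0.5), T)

# per-bp overlap oracle for intervals_to_bin_mask
bp_mask_oracle <- function(intervals, grid) {
  mask <- integer(grid$n_total)
  bc <- bin_coords(grid)
  for (b in seq_len(nrow(bc))) {
    for (i in seq_len(nrow(intervals))) {
      if (intervals$contig[i] != bc$contig[b]) next
      if (max(intervals$start[i], bc$start[b]) < min(intervals$end[i], bc$end[b])) {
        mask[b] <- 1L
        break
      }
    }
  }
  mask
}

# hand-built bin-label object (bypasses annotation machinery)
make_labels <- function(...) {
  structure(list(...), class = "bin_labels")
}

label_entry <- function(id, strand, bins, roles, contig = "chr") {
  list(id = id, strand = strand, contig = contig,
       bins = data.frame(bin = bins, role = roles, stringsAsFactors = FALSE))
}

# ground-truth 17-state model with distinct background states, built from a
# simulated annotation's supervised entries and the default role emissions
make_truth_model <- function(seed = 11, contig_bp = 2e6) {
  cfg <- sim_config(seed = seed, contigs = c(simT = contig_bp), n_tus = 20)
  ann <- simulate_annotation(cfg)
  grid <- bin_grid(cfg$contigs, cfg$bin_width)
  labels <- suppressWarnings(label_annotation_bins(ann, grid))
  trans <- suppressWarnings(estimate_tu_transitions(labels))
  emis <- cfg$role_emissions[chromTU:::TU_ROLES, ]
  dummy <- matrix(0L, grid$n_total, ncol(emis),
                  dimnames = list(NULL, colnames(emis)))
  base <- assemble_model(trans, emis, dummy, grid, fit = FALSE)$params
  bg <- which(base$state_meta$role == "background")
  base$emission[bg, ] <- rbind(
    c(0.02, 0.05, 0.02, 0.02, 0.03, 0.03),   # quiescent
    c(0.03, 0.10, 0.05, 0.03, 0.80, 0.10),   # polycomb-like
    c(0.02, 0.05, 0.02, 0.02, 0.10, 0.80))   # heterochromatin-like
  # plausible free transitions: sticky backgrounds, occasional TU entry
  nm <- base$state_meta$name
  dimnames(base$transition) <- list(nm, nm)
  for (b in c("B1", "B2", "B3")) {
    row <- numeric(17); names(row) <- nm
    row[b] <- 0.95
    row[setdiff(c("B1", "B2", "B3"), b)] <- 0.017
    row[c("TSS", "TTS")] <- 0.008
    base$transition[b, ] <- row
  }
  base$transition["TSS", ] <- 0
  base$transition["TSS", c("exon1+", "TTS", "B1", "B2", "B3")] <-
    c(0.55, 0.01, 0.44 / 3, 0.44 / 3, 0.44 / 3)
  base$transition["TTS", ] <- 0
  base$transition["TTS", c("exonL-", "exon1-", "TSS", "B1", "B2", "B3")] <-
    c(0.45, 0.10, 0.01, 0.44 / 3, 0.44 / 3, 0.44 / 3)
  base$initial <- rep(0, 17)
  base$initial[bg] <- 1 / 3
  validate_hmm_params(base)
  list(params = base, trans = trans, emis = emis, grid = grid, config = cfg)
}

# run the full synthetic pipeline once; returns everything needed to score it
run_pipeline_once <- function(seed = 17, max_iter = 300, tol = 1e-4) {
  sim <- simulate_dataset(sim_config(seed = seed))
  calls <- lapply(sim$counts, function(cc)
    call_enriched(fit_enrichment(cc$chip, cc$control), fdr = 0.2))
  cm <- build_class_matrix(calls, sim$grid, names(sim$counts))
  polii <- call_enriched(fit_enrichment(sim$polii_counts$chip,
                                        sim$polii_counts$control), fdr = 0.2)
  fit <- suppressWarnings(train_tu_model(sim$annotation, cm, polii, sim$grid,
                                         max_iter = max_iter, tol = tol))
  dec <- decode_genome(fit$params, cm, sim$grid)
  tus <- suppressMessages(refine_to_tus(dec, sim$grid))
  pred <- intervals_to_bin_mask(tus, sim$grid)
  truth <- as.integer(sim$roles$role != "background")
  tp <- sum(pred == 1L & truth == 1L)
  list(sim = sim, classes = cm, polii = polii, fit = fit, decoded = dec,
       tus = tus, pred_mask = pred, truth_mask = truth,
       precision = if (sum(pred)) tp / sum(pred) else 0,
       recall = tp / sum(truth))
}
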