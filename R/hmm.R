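#' Construct and validate multivariate Bernoulli HMM parameters
#'
#' The model has k hidden states and n binary marks. Each state emits each
#' mark independently with its own Bernoulli success probability; transitions
#' form a row-stochastic k x k matrix with structural zeros (topology-
#' forbidden edges fixed at exactly 0). Free/clamped masks implement
#' semi-supervised training: entries with `free_* = FALSE` are clamped and
#' bit-identical before and after Baum-Welch.
#'
#' @param emission k x n matrix of Bernoulli success probabilities.
#' @param transition k x k row-stochastic matrix.
#' @param initial length-k initial state distribution.
#' @param zero_mask k x k logical; TRUE marks a structural zero (transition
#'   forced to exactly 0, never trainable).
#' @param free_transition,free_emission,free_initial logical masks of the
#'   trainable entries; defaults: everything not a structural zero is free.
#' @param state_meta data frame with one row per state: `name`, `role` (one of
#'   TSS, TTS, exon1, intron1, exonI, intronI, exonL, intronL, background) and
#'   `strand` ("+", "-", or "." for unstranded states).
#' @param marks character vector of mark (column) names.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(emission, transition, initial,
                       zero_mask = NULL,
                       free_transition = NULL, free_emission = NULL,
                       free_initial = NULL,
                       state_meta = NULL, marks = colnames(emission)) {
  emission <- as.matrix(emission); transition <- as.matrix(transition)
  k <- nrow(emission); n <- ncol(emission)
  if (is.null(zero_mask)) zero_mask <- transition == 0
  if (is.null(free_transition)) free_transition <- !zero_mask
  if (is.null(free_emission)) free_emission <- matrix(TRUE, k, n)
  if (is.null(free_initial)) free_initial <- rep(TRUE, k)
  if (is.null(marks)) marks <- paste0("mark", seq_len(n))
  if (is.null(state_meta))
    state_meta <- data.frame(name = paste0("S", seq_len(k)),
                             role = "background", strand = ".",
                             stringsAsFactors = FALSE)
  obj <- structure(list(k = k, n = n, marks = marks,
                        emission = emission, transition = transition,
                        initial = as.numeric(initial),
                        zero_mask = zero_mask,
                        free_transition = free_transition,
                        free_emission = free_emission,
                        free_initial = free_initial,
                        state_meta = state_meta),
                   class = "hmm_params")
  validate_hmm_params(obj)
  obj
}

#' @rdname hmm_params
#' @param params an `hmm_params` object.
#' @export
validate_hmm_params <- function(params) {
  p <- params
  if (nrow(p$transition) != p$k || ncol(p$transition) != p$k)
    stop("transition must be k x k")
  if (length(p$initial) != p$k) stop("initial must have length k")
  if (nrow(p$state_meta) != p$k) stop("state_meta must have k rows")
  if (length(p$marks) != p$n) stop("marks must have length n")
  if (any(p$emission < 0 | p$emission > 1)) stop("emission probabilities outside [0,1]")
  rs <- rowSums(p$transition)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition rows must sum to 1 (row ", which(abs(rs - 1) > 1e-9)[1], ")")
  if (abs(sum(p$initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  if (any(p$transition[p$zero_mask] != 0))
    stop("structural-zero entries must be exactly 0")
  if (any(p$free_transition & p$zero_mask))
    stop("a structural zero cannot be free")
  # a clamped row with free entries must leave trainable mass
  for (s in seq_len(p$k)) {
    f <- p$free_transition[s, ]
    if (any(f)) {
      clamped_mass <- sum(p$transition[s, !f])
      if (clamped_mass >= 1 - 1e-12)
        stop("transition row ", s, ": clamped mass >= 1 but free entries exist")
    }
  }
  invisible(params)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d states x %d marks (%d structural zeros, %d free transition entries)\n",
              x$k, x$n, sum(x$zero_mask), sum(x$free_transition)))
  invisible(x)
}

#' Per-position emission log-likelihoods
#'
#' log P(o_t | state s) = sum_j o_tj log e_sj + (1 - o_tj) log(1 - e_sj),
#' the log of the product of independent Bernoullis across marks. Emission
#' probabilities are clipped into [1e-12, 1 - 1e-12] for the computation so
#' values stay finite.
#'
#' @param params an [hmm_params()] object.
#' @param obs T x n binary observation matrix; column order must match
#'   `params$marks` if column names are present.
#' @return T x k matrix of log-likelihoods.
#' @export
emission_loglik <- function(params, obs) {
  obs <- as.matrix(obs)
  if (ncol(obs) != params$n) stop("observation has ", ncol(obs),
                                  " marks; model expects ", params$n)
  if (!is.null(colnames(obs)) && !identical(colnames(obs), params$marks))
    stop("mark order mismatch: model expects [",
         paste(params$marks, collapse = ", "), "]")
  e <- pmin(pmax(params$emission, 1e-12), 1 - 1e-12)
  obs %*% t(log(e)) + (1 - obs) %*% t(log1p(-e))
}

#' Forward-backward pass
#'
#' Scaled-probability implementation (numerically safe for sequences of
#' millions of bins). Returns the observation log-likelihood and per-bin
#' posterior state probabilities; posterior rows sum to 1.
#'
#' @inheritParams emission_loglik
#' @return list with `loglik`, `posterior` (T x k), and the EM sufficient
#'   statistics `xi_sum` (k x k expected transition counts) and `gamma1`
#'   (posterior at the first position).
#' @export
forward_backward <- function(params, obs) {
  le <- emission_loglik(params, obs)
  res <- fb_kernel(le, params$transition, params$initial)
  names(res)[names(res) == "gamma"] <- "posterior"
  colnames(res$posterior) <- params$state_meta$name
  res
}

#' Viterbi decoding
#'
#' Most probable state path given the observations; structural zeros are
#' respected exactly and ties break toward the lowest state index.
#'
#' @inheritParams emission_loglik
#' @return list with `path` (integer states, 1-based), `states` (state names)
#'   and `logprob` (log joint probability of path and observations).
#' @export
viterbi <- function(params, obs) {
  le <- emission_loglik(params, obs)
  res <- viterbi_kernel(le, params$transition, params$initial)
  res$states <- params$state_meta$name[res$path]
  res
}

#' Constrained (semi-supervised) Baum-Welch
#'
#' Expectation-maximisation over a list of observation sequences (typically
#' one per contig; sufficient statistics are pooled). Entries whose free mask
#' is FALSE are clamped: they are bit-identical before and after training.
#' Structural zeros remain exactly 0. Within each transition row, clamped
#' entries keep their values and the free entries share the remaining mass in
#' proportion to their expected transition counts — the M-step maximiser under
#' the row-sum constraint, so the total log-likelihood is non-decreasing at
#' every iteration (asserted to 1e-8).
#'
#' @param params an [hmm_params()] object.
#' @param sequences a single T x n binary matrix or a list of them.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @return list with `params` (fitted), `loglik_trace` and `converged`.
#' @export
baum_welch <- function(params, sequences, max_iter = 100, tol = 1e-6) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop("at least one observation sequence is required")
  validate_hmm_params(params)
  k <- params$k; n <- params$n
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi <- matrix(0, k, k)
    g1 <- numeric(k)
    em_num <- matrix(0, k, n)
    em_den <- numeric(k)
    for (obs in sequences) {
      fb <- forward_backward(params, obs)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi_sum
      g1 <- g1 + fb$gamma1
      em_num <- em_num + t(fb$posterior) %*% obs
      em_den <- em_den + colSums(fb$posterior)
    }
    if (length(trace) && ll < trace[length(trace)] - 1e-8)
      stop("log-likelihood decreased during EM (", trace[length(trace)],
           " -> ", ll, ")")
    improved <- length(trace) && (ll - trace[length(trace)] < tol)
    trace <- c(trace, ll)
    if (improved) { converged <- TRUE; break }

    # M-step: transitions, row-wise partial renormalization
    for (s in seq_len(k)) {
      f <- params$free_transition[s, ]
      if (!any(f)) next
      free_mass <- 1 - sum(params$transition[s, !f])
      tot <- sum(xi[s, f])
      if (tot > 0)
        params$transition[s, f] <- free_mass * xi[s, f] / tot
      # else: keep previous free values (they already sum to free_mass)
    }
    # emissions
    fe <- params$free_emission
    upd <- fe & (em_den > 0)
    params$emission[upd] <- (em_num / em_den)[upd]
    params$emission[fe] <- pmin(pmax(params$emission[fe], 1e-6), 1 - 1e-6)
    # initial distribution
    fi <- params$free_initial
    if (any(fi)) {
      free_mass <- 1 - sum(params$initial[!fi])
      tot <- sum(g1[fi])
      if (tot > 0) params$initial[fi] <- free_mass * g1[fi] / tot
    }
  }
  list(params = params, loglik_trace = trace, converged = converged)
}

#' Serialize model parameters to versioned JSON
#'
#' A trained model (matrices, masks, mark order, state metadata) written this
#' way can be re-applied to class matrices from other cell lines without
#' retraining.
#'
#' @param params an [hmm_params()] object.
#' @param path output path.
#' @export
hmm_write_json <- function(params, path) {
  doc <- list(format = "chromTU-hmm", version = 1L,
              k = params$k, n = params$n, marks = params$marks,
              emission = params$emission, transition = params$transition,
              initial = params$initial,
              zero_mask = params$zero_mask,
              free_transition = params$free_transition,
              free_emission = params$free_emission,
              free_initial = params$free_initial,
              state_meta = params$state_meta)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname hmm_write_json
#' @export
hmm_read_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "chromTU-hmm")
    stop(path, " is not a chromTU model file")
  hmm_params(emission = matrix(as.numeric(doc$emission), doc$k, doc$n),
             transition = matrix(as.numeric(doc$transition), doc$k, doc$k),
             initial = as.numeric(doc$initial),
             zero_mask = matrix(as.logical(doc$zero_mask), doc$k, doc$k),
             free_transition = matrix(as.logical(doc$free_transition), doc$k, doc$k),
             free_emission = matrix(as.logical(doc$free_emission), doc$k, doc$n),
             free_initial = as.logical(doc$free_initial),
             state_meta = as.data.frame(doc$state_meta, stringsAsFactors = FALSE),
             marks = as.character(doc$marks))
}
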