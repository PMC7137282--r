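#' Decode the genome into per-bin states and TU posteriors
#'
#' Runs one Viterbi pass per contig to obtain the most probable state path,
#' and one forward-backward pass to obtain a per-bin TU posterior (the summed
#' posterior probability over all 14 TU states), used as the ranking score in
#' evaluation.
#'
#' @param model an [hmm_params()] object (17-state TU model).
#' @param class_matrix bins x marks binary matrix; column names must match
#'   the model's mark order.
#' @param grid a [bin_grid()].
#' @return list with `states` (per-bin state names, genome order),
#'   `tu_posterior` (per-bin score in [0, 1]) and `path_logprob` (named per
#'   contig).
#' @export
decode_genome <- function(model, class_matrix, grid) {
  stopifnot_grid(grid)
  cm <- as.matrix(class_matrix)
  if (nrow(cm) != grid$n_total) stop("class matrix does not match grid")
  if (!is.null(colnames(cm)) && !identical(colnames(cm), model$marks))
    stop("mark order mismatch: model expects [",
         paste(model$marks, collapse = ", "), "]")
  tu_states <- model$state_meta$role != "background"
  states <- character(grid$n_total)
  tu_post <- numeric(grid$n_total)
  lp <- stats::setNames(numeric(length(grid$contigs)), grid$contigs)
  for (cg in grid$contigs) {
    nb <- grid$n_bins[[cg]]
    if (nb < 1L) next
    rows <- grid$offsets[[cg]] + seq_len(nb)
    obs <- cm[rows, , drop = FALSE]
    vit <- viterbi(model, obs)
    fb <- forward_backward(model, obs)
    states[rows] <- vit$states
    tu_post[rows] <- rowSums(fb$posterior[, tu_states, drop = FALSE])
    lp[cg] <- vit$logprob
  }
  list(states = states, tu_posterior = tu_post, path_logprob = lp)
}

#' Refine a decoded state vector into transcription-unit records
#'
#' Each maximal stretch of gene-body bins on one strand chain becomes a TU
#' iff it is flanked by the correct boundary bins in genome order: TSS before
#' and TTS after for the forward chain ("+"), TTS before and TSS after for
#' the reverse chain ("-"). The TU spans boundary bins inclusive, so its
#' first bin has role TSS and its last TTS for "+" (reversed for "-").
#' Because TSS and TTS states are shared between the strand chains, adjacent
#' opposite-strand TUs can share a boundary bin (e.g. one TTS bin ending a
#' "+" TU and opening a "-" TU); both records then include it. Body segments
#' without proper boundaries (e.g. truncated at a contig end) are dropped
#' with a message, as are isolated TSS/TTS bins.
#'
#' @param decoded a [decode_genome()] result (or a list with `states` and
#'   `tu_posterior`).
#' @param grid a [bin_grid()].
#' @return data frame of class `tu_records`: contig, start, end (bp,
#'   bin-aligned, 0-based half-open), strand, score (mean TU posterior),
#'   label, n_bins, first_bin, and a `states` list-column of member state
#'   names.
#' @export
refine_to_tus <- function(decoded, grid) {
  stopifnot_grid(grid)
  states <- decoded$states
  post <- decoded$tu_posterior
  role_of <- function(s) {
    ifelse(s %in% c("TSS", "TTS"), s,
           ifelse(grepl("^B", s), "background", sub("[+-]$", "", s)))
  }
  chain_of <- function(s) ifelse(grepl("\\+$", s), "+",
                                 ifelse(grepl("-$", s), "-", "."))
  recs <- list()
  dropped <- 0L
  for (cg in grid$contigs) {
    nb <- grid$n_bins[[cg]]
    off <- grid$offsets[[cg]]
    st <- states[off + seq_len(nb)]
    roles <- role_of(st)
    chain <- chain_of(st)
    body <- chain != "."                     # gene-body bins carry the strand
    if (!any(body)) next
    r <- rle(paste0(body, chain))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values %in% c("TRUE+", "TRUE-"))) {
      i <- starts[ri]; j <- ends[ri]
      strand <- chain[i]
      before <- if (i > 1L) roles[i - 1L] else NA_character_
      after <- if (j < nb) roles[j + 1L] else NA_character_
      valid <- if (strand == "+") identical(before, "TSS") && identical(after, "TTS")
               else identical(before, "TTS") && identical(after, "TSS")
      if (!isTRUE(valid)) { dropped <- dropped + 1L; next }
      piece <- (i - 1L):(j + 1L)             # boundary bins inclusive
      gbins <- off + piece - 1L              # 0-based global bin indices
      bc <- bin_coords(grid, c(gbins[1], gbins[length(gbins)]))
      recs[[length(recs) + 1L]] <- data.frame(
        contig = cg, start = bc$start[1], end = bc$end[2], strand = strand,
        score = mean(post[off + piece]), n_bins = length(piece),
        first_bin = gbins[1], stringsAsFactors = FALSE)
      recs[[length(recs)]]$states <- I(list(st[piece]))
    }
  }
  if (dropped) message(dropped, " body segment(s) without TSS/TTS boundaries dropped")
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), score = numeric(0), n_bins = integer(0),
               first_bin = integer(0), states = I(list()))
  out$label <- if (nrow(out)) sprintf("TU%05d", seq_len(nrow(out))) else character(0)
  class(out) <- c("tu_records", "data.frame")
  out
}

#' Write TU records as BED6
#'
#' Score is the mean TU-state posterior scaled to 0-1000.
#'
#' @param tus a `tu_records` data frame (see [refine_to_tus()]).
#' @param path output path.
#' @param header optional `#` comment lines.
#' @export
write_tu_bed <- function(tus, path, header = NULL) {
  iv <- genomic_intervals(tus$contig, tus$start, tus$end, tus$strand, tus$label)
  iv$score <- pmin(pmax(round(1000 * tus$score), 0), 1000)
  write_bed(iv, path, header = header)
}
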