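TU_ROLES <- c("TSS", "exon1", "intron1", "exonI", "intronI", "exonL", "intronL", "TTS")
BODY_ROLES <- c("exon1", "intron1", "exonI", "intronI", "exonL", "intronL")

# gene-body grammar in transcript orientation (source -> target), body states
# only; edges into/out of TSS/TTS are free (trained unsupervised) and listed
# separately in build_tu_topology().
BODY_EDGES <- rbind(
  c("exon1", "exon1"), c("exon1", "intron1"),
  c("intron1", "intron1"), c("intron1", "exonI"), c("intron1", "exonL"),
  c("exonI", "exonI"), c("exonI", "intronI"), c("exonI", "intronL"),
  c("intronI", "intronI"), c("intronI", "exonI"),
  c("intronL", "intronL"), c("intronL", "exonL"),
  c("exonL", "exonL"))

#' The 17-state transcription-unit model topology
#'
#' Fourteen TU states — shared TSS and TTS plus six gene-body states
#' (first/internal/last exon and intron) duplicated for the forward and
#' reverse strand — and three background states. In genome order the forward
#' chain runs TSS -> exon1+ -> ... -> TTS and the reverse chain
#' TTS -> exonL- -> ... -> exon1- -> TSS, so transcripts on both strands are
#' decodable from strand-less bins. Gene-body-internal edges are supervised
#' (estimated from an annotation and clamped); every edge whose source or
#' target is TSS, TTS or a background state is free (trained by Baum-Welch);
#' all other edges are structural zeros.
#'
#' @param n_background number of background states (default 3).
#' @return list with `state_meta` (name/role/strand per state), `allowed`
#'   (k x k logical edge set), `free` (trainable edges) and `supervised`
#'   (clamped edges); `allowed = free | supervised`.
#' @export
build_tu_topology <- function(n_background = 3) {
  fwd <- paste0(BODY_ROLES, "+")
  rev <- paste0(BODY_ROLES, "-")
  bg <- paste0("B", seq_len(n_background))
  nm <- c("TSS", fwd, "TTS", rev, bg)
  k <- length(nm)
  role <- c("TSS", BODY_ROLES, "TTS", BODY_ROLES, rep("background", n_background))
  strand <- c(".", rep("+", 6), ".", rep("-", 6), rep(".", n_background))
  meta <- data.frame(name = nm, role = role, strand = strand,
                     stringsAsFactors = FALSE)
  sup <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  free <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  # supervised: body-internal, forward chain a+ -> b+, reverse mirror b- -> a-
  for (i in seq_len(nrow(BODY_EDGES))) {
    a <- BODY_EDGES[i, 1]; b <- BODY_EDGES[i, 2]
    sup[paste0(a, "+"), paste0(b, "+")] <- TRUE
    sup[paste0(b, "-"), paste0(a, "-")] <- TRUE
  }
  # free: everything touching TSS/TTS along the chains, TSS<->TTS, and all
  # background edges
  free["TSS", "exon1+"] <- TRUE
  free["exon1+", "TTS"] <- TRUE   # single-exon forward exit
  free["exonL+", "TTS"] <- TRUE
  free["TTS", "exonL-"] <- TRUE
  free["TTS", "exon1-"] <- TRUE   # single-exon reverse entry
  free["exon1-", "TSS"] <- TRUE
  free["TSS", "TTS"] <- TRUE
  free["TTS", "TSS"] <- TRUE
  free[bg, bg] <- TRUE
  free[bg, c("TSS", "TTS")] <- TRUE
  free[c("TSS", "TTS"), bg] <- TRUE
  list(state_meta = meta, allowed = sup | free, free = free, supervised = sup)
}
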