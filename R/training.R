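#' Label annotation bins by transcription-unit component
#'
#' For each transcript, the bin containing the 5' end (strand-aware) is the
#' TSS bin, the bin containing the 3' end is the TTS bin, and every bin
#' strictly between them is labelled by the exon/intron component covering
#' the majority of the bin. Components are numbered in transcript
#' orientation: exon1 is the 5'-most exon, exonL the 3'-most (when there are
#' at least two), exonI any internal one; introns likewise (a single intron
#' is intron1; the last of two or more is intronL). Single-exon transcripts
#' yield TSS -> exon1 -> TTS. Bins are reported in genome order, so a
#' reverse-strand transcript starts with its TTS bin.
#'
#' @param annotation an `annotation` object (see [read_gtf()]).
#' @param grid a [bin_grid()].
#' @return list of class `bin_labels`; one element per usable transcript with
#'   `id`, `strand`, `contig` and `bins` (data frame: bin index, role).
#'   Transcripts spanning fewer than 3 bins are skipped with a warning.
#' @export
label_annotation_bins <- function(annotation, grid) {
  stopifnot_grid(grid)
  tr <- annotation$transcripts
  exons <- annotation$exons
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(tr))) {
    id <- tr$label[i]; strand <- tr$strand[i]; contig <- tr$contig[i]
    if (!strand %in% c("+", "-")) stop("transcript ", id, " must be stranded")
    bins <- bin_span(grid, contig, tr$start[i], tr$end[i])
    if (length(bins) < 3L) { skipped <- skipped + 1L; next }
    ex <- exons[exons$transcript_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    segs <- component_segments(ex, strand)
    roles <- character(length(bins))
    roles[1] <- if (strand == "+") "TSS" else "TTS"
    roles[length(bins)] <- if (strand == "+") "TTS" else "TSS"
    if (length(bins) > 2L) {
      bc <- bin_coords(grid, bins[seq(2, length(bins) - 1L)])
      for (j in seq_len(nrow(bc))) {
        ov <- pmin(segs$end, bc$end[j]) - pmax(segs$start, bc$start[j])
        roles[j + 1L] <- segs$role[which.max(ov)]
      }
    }
    out[[length(out) + 1L]] <- list(id = id, strand = strand, contig = contig,
                                    bins = data.frame(bin = bins, role = roles,
                                                      stringsAsFactors = FALSE))
  }
  if (skipped) warning(skipped, " transcript(s) shorter than 3 bins skipped")
  structure(out, class = "bin_labels")
}

# exon/intron segments of one transcript in genome order, with roles assigned
# in transcript orientation
component_segments <- function(ex, strand) {
  ne <- nrow(ex)
  tidx <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
  exon_role <- function(t) {
    if (t == 1L) "exon1" else if (t == ne && ne >= 2L) "exonL" else "exonI"
  }
  segs <- data.frame(start = ex$start, end = ex$end,
                     role = vapply(tidx, exon_role, character(1)),
                     stringsAsFactors = FALSE)
  if (ne >= 2L) {
    istart <- ex$end[-ne]; iend <- ex$start[-1]
    ni <- ne - 1L
    it <- if (strand == "+") seq_len(ni) else rev(seq_len(ni))
    intron_role <- function(t) {
      if (t == 1L) "intron1" else if (t == ni && ni >= 2L) "intronL" else "intronI"
    }
    keep <- istart < iend   # zero-length introns (abutting exons) dropped
    segs <- rbind(segs, data.frame(start = istart[keep], end = iend[keep],
                                   role = vapply(it, intron_role, character(1))[keep],
                                   stringsAsFactors = FALSE))
  }
  segs[order(segs$start), , drop = FALSE]
}

#' Supervised transition estimates from labelled bins
#'
#' Counts bin-to-bin role transitions along every transcript's label sequence
#' in transcript orientation (reverse-strand sequences are reversed first) and
#' normalises per source role — the maximum-likelihood estimate of the
#' forward-chain transitions. Reverse-chain entries are the strand-mirrored
#' copy: transposed counts, row-normalised.
#'
#' @param labels a `bin_labels` list (see [label_annotation_bins()]).
#' @return object of class `tu_transitions` with `counts` (8 x 8 role
#'   transition counts, transcript orientation) and `probs` (row-normalised;
#'   rows of never-observed roles are NA and trigger a warning).
#' @export
estimate_tu_transitions <- function(labels) {
  if (!length(labels)) stop("at least one labelled transcript is required")
  counts <- matrix(0, length(TU_ROLES), length(TU_ROLES),
                   dimnames = list(TU_ROLES, TU_ROLES))
  for (lab in labels) {
    roles <- lab$bins$role
    if (lab$strand == "-") roles <- rev(roles)
    if (length(roles) < 2L) next
    from <- roles[-length(roles)]; to <- roles[-1]
    for (j in seq_along(from)) counts[from[j], to[j]] <- counts[from[j], to[j]] + 1
  }
  rs <- rowSums(counts)
  probs <- counts / rs
  unseen <- setdiff(TU_ROLES[rs == 0], "TTS")  # TTS has no supervised exits
  if (length(unseen)) {
    warning("role(s) never observed as transition source: ",
            paste(unseen, collapse = ", "),
            "; their rows fall back to uniform over allowed edges")
    probs[unseen, ] <- NA_real_
  }
  probs["TTS", ] <- NA_real_
  structure(list(counts = counts, probs = probs), class = "tu_transitions")
}

#' Filter training transcripts by RNA polymerase II enrichment
#'
#' Each transcript is summarised by the mean binarized Pol II enrichment over
#' its TSS and TTS bins (averaged across antibodies when `pool = TRUE`,
#' otherwise one feature per antibody). Transcripts are 2-means clustered on
#' this feature and the cluster with the higher mean is retained — the
#' "actively transcribed" training set.
#'
#' @param labels a `bin_labels` list.
#' @param polII a 0/1 vector, a named list of them, or a bins x antibodies
#'   0/1 matrix of binarized Pol II enrichment.
#' @param pool average antibodies into a single feature (default TRUE).
#' @param seed RNG seed for k-means initialisation (default 17).
#' @return the retained subset of `labels` (class `bin_labels`), with
#'   attribute `features` (the per-transcript feature matrix).
#' @export
filter_polII_transcripts <- function(labels, polII, pool = TRUE, seed = 17) {
  if (length(labels) < 2L) stop("need at least 2 transcripts to cluster")
  if (is.list(polII) && !is.data.frame(polII)) polII <- do.call(cbind, polII)
  polII <- as.matrix(polII)
  fv <- vapply(labels, function(lab) {
    ends <- lab$bins$bin[lab$bins$role %in% c("TSS", "TTS")]
    colMeans(polII[ends + 1L, , drop = FALSE])
  }, numeric(ncol(polII)))
  feats <- if (is.matrix(fv)) t(fv) else matrix(fv, ncol = 1)
  if (pool) feats <- matrix(rowMeans(feats), ncol = 1)
  if (nrow(unique(feats)) < 2L) {
    warning("all Pol II features identical; retaining all transcripts")
    attr(labels, "features") <- feats
    return(labels)
  }
  km <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    stats::kmeans(feats, centers = 2, nstart = 10)
  })
  high <- which.max(rowMeans(km$centers))
  keep <- km$cluster == high
  out <- labels[keep]
  class(out) <- "bin_labels"
  attr(out, "features") <- feats
  out
}

#' Supervised emission estimates for TU states
#'
#' For each TU component role, the emission probability of mark j is the
#' fraction of bins carrying that role in which mark j is enriched, clipped
#' into [eps, 1 - eps]. By default forward- and reverse-strand gene-body
#' states share emission rows (a gene body looks the same in histone marks
#' regardless of strand); `tie_strands = FALSE` estimates them separately.
#'
#' @param labels a `bin_labels` list (usually Pol II-filtered).
#' @param class_matrix bins x marks binary matrix (see
#'   [build_class_matrix()]).
#' @param tie_strands share body-state emissions across strands (default
#'   TRUE).
#' @param eps clipping constant (default 1e-6).
#' @return matrix of emission rows: rownames are roles (tied) or
#'   "role|strand" for body roles (untied). Roles with zero bins fall back to
#'   a flat 0.5 row with a warning.
#' @export
estimate_tu_emissions <- function(labels, class_matrix, tie_strands = TRUE,
                                  eps = 1e-6) {
  if (!length(labels)) stop("filtered training set is empty")
  cm <- as.matrix(class_matrix)
  rows <- if (tie_strands) TU_ROLES
          else c("TSS", "TTS", paste(rep(BODY_ROLES, each = 2), c("+", "-"), sep = "|"))
  out <- matrix(NA_real_, length(rows), ncol(cm),
                dimnames = list(rows, colnames(cm)))
  key_of <- function(role, strand) {
    if (tie_strands || role %in% c("TSS", "TTS")) role
    else paste(role, strand, sep = "|")
  }
  bins_by_key <- new.env(parent = emptyenv())
  for (lab in labels)
    for (j in seq_len(nrow(lab$bins))) {
      key <- key_of(lab$bins$role[j], lab$strand)
      assign(key, c(get0(key, bins_by_key, ifnotfound = integer(0)),
                    lab$bins$bin[j]), bins_by_key)
    }
  empty <- character(0)
  for (key in rows) {
    b <- get0(key, bins_by_key, ifnotfound = integer(0))
    if (!length(b)) { out[key, ] <- 0.5; empty <- c(empty, key); next }
    out[key, ] <- pmin(pmax(colMeans(cm[b + 1L, , drop = FALSE]), eps), 1 - eps)
  }
  if (length(empty))
    warning("no bins for role(s) ", paste(empty, collapse = ", "),
            "; using flat 0.5 emission rows")
  out
}

#' Assemble the 17-state model and train its free parameters
#'
#' Installs supervised transition and emission entries (clamped), initialises
#' the free parameters — background emission rows from genome-wide mark
#' frequencies (scaled by 0.5/1.0/1.5 to break symmetry), free transition
#' entries sharing each row's remaining mass uniformly, a uniform initial
#' distribution — sets the structural zeros, and (by default) runs
#' constrained Baum-Welch on the class matrix, one observation sequence per
#' contig.
#'
#' Rows whose clamped mass would leave free entries less than `free_floor`
#' have their clamped entries rescaled so every free edge keeps trainable
#' mass (e.g. the exon1 -> TTS exit when no single-exon transcript was
#' observed).
#'
#' @param transitions a [estimate_tu_transitions()] result.
#' @param emissions a [estimate_tu_emissions()] result.
#' @param class_matrix bins x marks binary matrix.
#' @param grid a [bin_grid()] (defines the per-contig sequence boundaries).
#' @param topology a [build_tu_topology()] result.
#' @param free_floor minimum total free mass per transition row (default
#'   1e-3).
#' @param fit run [baum_welch()] after assembly (default TRUE).
#' @param max_iter,tol Baum-Welch controls.
#' @return list with `params` (an [hmm_params()]), `loglik_trace` and
#'   `converged` (NA when `fit = FALSE`).
#' @export
assemble_model <- function(transitions, emissions, class_matrix, grid,
                           topology = build_tu_topology(),
                           free_floor = 1e-3, fit = TRUE,
                           max_iter = 300, tol = 1e-4) {
  stopifnot_grid(grid)
  cm <- as.matrix(class_matrix)
  if (nrow(cm) != grid$n_total) stop("class matrix does not match grid")
  marks <- colnames(cm)
  if (is.null(marks)) stop("class matrix must have mark column names")
  meta <- topology$state_meta
  k <- nrow(meta)
  nm <- meta$name

  A <- matrix(0, k, k, dimnames = list(nm, nm))
  sup <- topology$supervised
  cnt <- transitions$counts
  # Clamped forward rows: counts restricted to topology-allowed targets
  # (grammar-violating transitions from majority-overlap labelling carry no
  # supervised mass), normalised together with the free chain exit so the
  # free entry later absorbs exactly the observed exit fraction. Reverse rows
  # mirror the forward counts: transposed (incoming) counts, row-normalised.
  for (a in BODY_ROLES) {
    af <- paste0(a, "+")
    sup_t <- BODY_ROLES[sup[af, paste0(BODY_ROLES, "+")]]
    tgt <- c(sup_t, if (topology$free[af, "TTS"]) "TTS")
    tot <- sum(cnt[a, tgt])
    A[af, paste0(sup_t, "+")] <-
      if (tot > 0) cnt[a, sup_t] / tot else 1 / length(tgt)

    ar <- paste0(a, "-")
    sup_s <- BODY_ROLES[sup[ar, paste0(BODY_ROLES, "-")]]
    src <- c(sup_s, if (topology$free[ar, "TSS"]) "TSS")
    tot <- sum(cnt[src, a])
    A[ar, paste0(sup_s, "-")] <-
      if (tot > 0) cnt[sup_s, a] / tot else 1 / length(src)
  }
  # free entries share each row's remaining mass uniformly, with a floor
  free <- topology$free
  for (s in nm) {
    fe <- free[s, ]
    if (!any(fe)) next
    clamped <- sum(A[s, sup[s, ]])
    if (clamped > 1 - free_floor) {
      A[s, sup[s, ]] <- A[s, sup[s, ]] * (1 - free_floor) / clamped
      clamped <- 1 - free_floor
    }
    A[s, fe] <- (1 - clamped) / sum(fe)
  }

  E <- matrix(NA_real_, k, ncol(cm), dimnames = list(nm, marks))
  tied <- !any(grepl("|", rownames(emissions), fixed = TRUE))
  for (i in seq_len(k)) {
    if (meta$role[i] == "background") next
    key <- if (tied || meta$role[i] %in% c("TSS", "TTS")) meta$role[i]
           else paste(meta$role[i], meta$strand[i], sep = "|")
    if (!key %in% rownames(emissions)) stop("missing emission row for ", key)
    E[i, ] <- emissions[key, ]
  }
  bg_states <- which(meta$role == "background")
  base <- colMeans(cm)
  scales <- seq(0.5, 1.5, length.out = length(bg_states))
  for (j in seq_along(bg_states))
    E[bg_states[j], ] <- pmin(pmax(base * scales[j], 1e-3), 1 - 1e-3)

  free_em <- matrix(FALSE, k, ncol(cm))
  free_em[bg_states, ] <- TRUE
  params <- hmm_params(emission = E, transition = A,
                       initial = rep(1 / k, k),
                       zero_mask = !topology$allowed,
                       free_transition = free,
                       free_emission = free_em,
                       free_initial = rep(TRUE, k),
                       state_meta = meta, marks = marks)
  if (!fit)
    return(list(params = params, loglik_trace = numeric(0), converged = NA))
  seqs <- split_by_contig(cm, grid)
  fitres <- baum_welch(params, seqs, max_iter = max_iter, tol = tol)
  fitres
}

split_by_contig <- function(class_matrix, grid) {
  lapply(grid$contigs, function(cg) {
    off <- grid$offsets[[cg]]
    class_matrix[off + seq_len(grid$n_bins[[cg]]), , drop = FALSE]
  })
}

#' Train the full transcription-unit model from an annotation
#'
#' Convenience wrapper: label annotation bins, filter transcripts by Pol II
#' enrichment, estimate supervised transitions and emissions, assemble the
#' 17-state model and train its free parameters by constrained Baum-Welch.
#'
#' @inheritParams assemble_model
#' @inheritParams filter_polII_transcripts
#' @param annotation an `annotation` object.
#' @param tie_strands see [estimate_tu_emissions()].
#' @return as [assemble_model()], plus `labels` (the filtered training set).
#' @export
train_tu_model <- function(annotation, class_matrix, polII, grid,
                           pool = TRUE, seed = 17, tie_strands = TRUE,
                           free_floor = 1e-3, max_iter = 300, tol = 1e-4,
                           fit = TRUE) {
  labels <- label_annotation_bins(annotation, grid)
  trans <- estimate_tu_transitions(labels)
  kept <- filter_polII_transcripts(labels, polII, pool = pool, seed = seed)
  emis <- estimate_tu_emissions(kept, class_matrix, tie_strands = tie_strands)
  res <- assemble_model(trans, emis, class_matrix, grid,
                        free_floor = free_floor, fit = fit,
                        max_iter = max_iter, tol = tol)
  res$labels <- kept
  res
}
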