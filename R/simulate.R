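with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

DEFAULT_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K36me3", "H3K27me3", "H3K9me3")

# well-separated per-role mark enrichment probabilities: promoter marks at the
# TSS, elongation mark over the body, repressive marks confined to background
default_role_emissions <- function() {
  e <- rbind(
    TSS        = c(0.90, 0.50, 0.95, 0.10, 0.02, 0.02),
    exon1      = c(0.60, 0.30, 0.40, 0.70, 0.02, 0.02),
    intron1    = c(0.30, 0.40, 0.15, 0.60, 0.02, 0.02),
    exonI      = c(0.30, 0.20, 0.10, 0.90, 0.02, 0.02),
    intronI    = c(0.20, 0.30, 0.08, 0.70, 0.02, 0.02),
    exonL      = c(0.25, 0.20, 0.08, 0.90, 0.02, 0.02),
    intronL    = c(0.20, 0.30, 0.08, 0.70, 0.02, 0.02),
    TTS        = c(0.30, 0.20, 0.10, 0.85, 0.05, 0.02),
    background = c(0.05, 0.08, 0.04, 0.05, 0.15, 0.12))
  colnames(e) <- DEFAULT_MARKS
  e
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: a toy genome, a
#' transcript landscape, per-role mark enrichment probabilities, and the
#' count model that turns enrichment masks into ChIP/control read counts.
#' All generators are pure functions of (config, seed).
#'
#' @param seed base RNG seed; sub-generators derive their own seeds from it.
#' @param contigs named vector of contig lengths in bp.
#' @param bin_width bin width in bp.
#' @param n_tus number of transcripts to place.
#' @param exon_bp_mean,intron_bp_mean mean exon/intron lengths in bp
#'   (exponential with a 200 bp floor).
#' @param n_exons_lambda Poisson rate for extra exons (exon count = 1 +
#'   Poisson).
#' @param gap_bp_mean mean intergenic gap in bp (exponential with a 1000 bp
#'   floor).
#' @param role_emissions matrix of per-role mark probabilities (rows: the 8
#'   TU component roles plus "background").
#' @param trials_min,trials_max per-bin total count (chip + control) range.
#' @param p_background,p_enriched binomial success probability of a ChIP read
#'   (vs chip + control) in background and enriched bins.
#' @param polii_p_tu,polii_p_bg Pol II enrichment probability in TU and
#'   background bins.
#' @param rna_dropout fraction of TUs withheld from the nascent-RNA evidence
#'   (emulating Pol II-positive transcripts without RNA-seq support).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 17,
                       contigs = c(simA = 4e5, simB = 3e5),
                       bin_width = 200,
                       n_tus = 30,
                       exon_bp_mean = 600,
                       intron_bp_mean = 1200,
                       n_exons_lambda = 2,
                       gap_bp_mean = 6000,
                       role_emissions = default_role_emissions(),
                       trials_min = 20, trials_max = 100,
                       p_background = 0.5, p_enriched = 0.9,
                       polii_p_tu = 0.9, polii_p_bg = 0.02,
                       rna_dropout = 0.1) {
  stopifnot(all(role_emissions >= 0 & role_emissions <= 1),
            p_background >= 0, p_background <= 1,
            p_enriched >= 0, p_enriched <= 1,
            rna_dropout >= 0, rna_dropout <= 1,
            trials_min >= 1, trials_max >= trials_min)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-transcript annotation
#'
#' Places non-overlapping multi-exon transcripts with a strand mix along the
#' configured genome: alternating exponential gaps and transcripts whose
#' exon/intron lengths are drawn from the config. Deterministic given
#' (config, seed): rewriting the same annotation yields a byte-identical GTF.
#'
#' @param config a [sim_config()].
#' @return an `annotation` object (see [read_gtf()]); its transcript
#'   intervals are the truth TU set.
#' @export
simulate_annotation <- function(config) {
  with_seed(config$seed, {
    exons <- list(); trs <- list()
    ci <- 1L; cursor <- 0
    placed <- 0L
    while (placed < config$n_tus) {
      if (ci > length(config$contigs))
        stop("genome too small for ", config$n_tus, " transcripts (placed ",
             placed, ")")
      gap <- 1000 + stats::rexp(1, 1 / config$gap_bp_mean)
      ne <- 1L + stats::rpois(1, config$n_exons_lambda)
      elen <- 200 + stats::rexp(ne, 1 / config$exon_bp_mean)
      ilen <- if (ne > 1L) 200 + stats::rexp(ne - 1L, 1 / config$intron_bp_mean) else numeric(0)
      total <- sum(elen) + sum(ilen)
      start <- round(cursor + gap)
      if (start + total > config$contigs[ci]) { ci <- ci + 1L; cursor <- 0; next }
      placed <- placed + 1L
      id <- sprintf("TU%05d", placed)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      estart <- start + cumsum(c(0, head(elen, -1) + ilen))
      exons[[placed]] <- data.frame(
        transcript_id = id, contig = names(config$contigs)[ci],
        start = round(estart), end = round(estart + elen),
        strand = strand, stringsAsFactors = FALSE)
      cursor <- start + total
    }
    annotation_from_exons(do.call(rbind, exons))
  })
}

#' Per-bin component roles implied by an annotation
#'
#' Background everywhere except annotated transcripts, whose bins carry the
#' TSS/TTS/exon/intron roles from [label_annotation_bins()]. Overlapping
#' transcripts (none in simulated annotations) would be resolved
#' last-writer-wins.
#'
#' @param annotation an `annotation` object.
#' @param grid a [bin_grid()].
#' @return list with `role` (character per bin) and `strand` (character per
#'   bin, "." for background).
#' @export
truth_bin_roles <- function(annotation, grid) {
  role <- rep("background", grid$n_total)
  strand <- rep(".", grid$n_total)
  labels <- label_annotation_bins(annotation, grid)
  for (lab in labels) {
    role[lab$bins$bin + 1L] <- lab$bins$role
    strand[lab$bins$bin + 1L] <- lab$strand
  }
  list(role = role, strand = strand)
}

#' Sample a class matrix from a known model
#'
#' Ancestral sampling: a state path per contig from the initial/transition
#' distributions, then independent Bernoulli marks from the state's emission
#' row — the exact generative counterpart of the HMM, used for parameter
#' recovery tests.
#'
#' @param model an [hmm_params()] object.
#' @param grid a [bin_grid()].
#' @param seed RNG seed.
#' @return list with `classes` (bins x marks 0/1 matrix) and `states`
#'   (true state indices per bin).
#' @export
simulate_class_matrix <- function(model, grid, seed = 17) {
  stopifnot_grid(grid)
  with_seed(seed, {
    states <- integer(grid$n_total)
    for (cg in grid$contigs) {
      nb <- grid$n_bins[[cg]]
      rows <- grid$offsets[[cg]] + seq_len(nb)
      states[rows] <- sample_path_kernel(model$transition, model$initial,
                                         stats::runif(nb))
    }
    p <- model$emission[states, , drop = FALSE]
    classes <- matrix(as.integer(stats::runif(length(p)) < p),
                      nrow = grid$n_total, dimnames = list(NULL, model$marks))
    list(classes = classes, states = states)
  })
}

#' Simulate ChIP and control counts from an enrichment mask
#'
#' Per bin, total trials are uniform on [trials_min, trials_max]; the ChIP
#' count is binomial with the enriched or background success probability
#' according to the mask, and the control count is the remainder.
#'
#' @param mask 0/1 truth enrichment vector.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `chip` and `control` integer vectors.
#' @export
simulate_counts <- function(mask, config, seed = 17) {
  with_seed(seed, {
    m <- length(mask)
    trials <- sample(config$trials_min:config$trials_max, m, replace = TRUE)
    p <- ifelse(mask == 1L, config$p_enriched, config$p_background)
    chip <- stats::rbinom(m, trials, p)
    list(chip = chip, control = trials - chip)
  })
}

#' Simulate a complete synthetic study
#'
#' Generates everything the pipeline consumes: genome and grid, annotation
#' (the truth TU set), per-bin component roles, per-mark truth enrichment
#' masks drawn from the role emission table, ChIP/control counts for the six
#' histone marks and for Pol II, and nascent-RNA transcript intervals (the
#' truth TUs minus a dropout fraction).
#'
#' @param config a [sim_config()].
#' @return list with `config`, `grid`, `annotation`, `truth_tus`
#'   (`genomic_intervals`), `roles`, `mark_masks`, `counts` (per mark:
#'   chip/control), `polii_mask`, `polii_counts`, `nascent`
#'   (`genomic_intervals`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  grid <- bin_grid(config$contigs, config$bin_width)
  annotation <- simulate_annotation(config)
  roles <- truth_bin_roles(annotation, grid)
  marks <- colnames(config$role_emissions)
  mark_masks <- with_seed(config$seed + 1L, {
    p <- config$role_emissions[roles$role, , drop = FALSE]
    m <- matrix(as.integer(stats::runif(length(p)) < p),
                nrow = grid$n_total, dimnames = list(NULL, marks))
    m
  })
  counts <- lapply(seq_along(marks), function(j)
    simulate_counts(mark_masks[, j], config, seed = config$seed + 1L + j))
  names(counts) <- marks
  tu_bin <- roles$role != "background"
  polii_mask <- with_seed(config$seed + 100L, {
    p <- ifelse(tu_bin, config$polii_p_tu, config$polii_p_bg)
    as.integer(stats::runif(grid$n_total) < p)
  })
  polii_counts <- simulate_counts(polii_mask, config, seed = config$seed + 101L)
  tr <- annotation$transcripts
  truth_tus <- genomic_intervals(tr$contig, tr$start, tr$end, tr$strand, tr$label)
  nascent <- with_seed(config$seed + 102L, {
    n_drop <- floor(config$rna_dropout * nrow(truth_tus))
    drop <- if (n_drop > 0) sample(nrow(truth_tus), n_drop) else integer(0)
    if (length(drop)) truth_tus[-drop, , drop = FALSE] else truth_tus
  })
  list(config = config, grid = grid, annotation = annotation,
       truth_tus = truth_tus, roles = roles, mark_masks = mark_masks,
       counts = counts, polii_mask = polii_mask, polii_counts = polii_counts,
       nascent = nascent)
}
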