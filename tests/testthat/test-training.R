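make_ann <- function(exons_df) chromTU:::annotation_from_exons(exons_df)

test_that("annotation bins are labelled TSS/body/TTS strand-aware", {
  g <- bin_grid(c(chr = 2000), 200)
  ann <- make_ann(data.frame(transcript_id = "t1", contig = "chr",
                             start = 100, end = 1100, strand = "+",
                             stringsAsFactors = FALSE))
  labs <- label_annotation_bins(ann, g)
  expect_length(labs, 1)
  expect_equal(labs[[1]]$bins$bin, 0:5)
  expect_equal(labs[[1]]$bins$role,
               c("TSS", "exon1", "exon1", "exon1", "exon1", "TTS"))

  # reverse strand: TSS is the rightmost transcript bin
  ann_m <- make_ann(data.frame(transcript_id = "t2", contig = "chr",
                               start = 100, end = 1100, strand = "-",
                               stringsAsFactors = FALSE))
  labs_m <- label_annotation_bins(ann_m, g)
  expect_equal(labs_m[[1]]$bins$role[1], "TTS")
  expect_equal(labs_m[[1]]$bins$role[6], "TSS")
  expect_equal(labs_m[[1]]$bins$role[2:5], rep("exon1", 4))

  # two-exon transcript: exon1, intron1, exonL and no internal states
  ann2 <- make_ann(data.frame(transcript_id = "t3", contig = "chr",
                              start = c(0, 1200), end = c(400, 1800),
                              strand = "+", stringsAsFactors = FALSE))
  labs2 <- label_annotation_bins(ann2, g)
  roles <- labs2[[1]]$bins$role
  expect_equal(roles[1], "TSS")
  expect_equal(roles[length(roles)], "TTS")
  expect_setequal(setdiff(roles, c("TSS", "TTS")),
                  c("exon1", "intron1", "exonL"))

  short <- make_ann(data.frame(transcript_id = "t4", contig = "chr",
                               start = 0, end = 300, strand = "+",
                               stringsAsFactors = FALSE))
  expect_warning(ls <- label_annotation_bins(short, g), "shorter than 3 bins")
  expect_length(ls, 0)
})

test_that("supervised transitions are ML counts along the label sequence", {
  labs <- make_labels(label_entry("t1", "+", 0:5,
                                  c("TSS", "exon1", "exon1", "exon1",
                                    "intron1", "TTS")))
  tr <- suppressWarnings(estimate_tu_transitions(labs))
  expect_equal(tr$probs["exon1", "exon1"], 2/3)
  expect_equal(tr$probs["exon1", "intron1"], 1/3)
  expect_equal(tr$counts["TSS", "exon1"], 1)

  # all transcripts single-exon: the exon1 -> intron1 event is never observed
  labs2 <- make_labels(
    label_entry("a", "+", 0:3, c("TSS", "exon1", "exon1", "TTS")),
    label_entry("b", "+", 10:13, c("TSS", "exon1", "exon1", "TTS")))
  tr2 <- suppressWarnings(estimate_tu_transitions(labs2))
  expect_equal(tr2$counts["exon1", "intron1"], 0)

  # reverse-strand label sequences are counted in transcript orientation
  labs3 <- make_labels(label_entry("m", "-", 0:5,
                                   c("TTS", "intron1", "exon1", "exon1",
                                     "exon1", "TSS")))
  tr3 <- suppressWarnings(estimate_tu_transitions(labs3))
  expect_equal(tr3$probs["exon1", "exon1"], 2/3)
  expect_equal(tr3$probs["exon1", "intron1"], 1/3)
})

test_that("constant-length components give geometric self-transitions", {
  # every exon1 exactly 4 bins: self-transition 3/4 by run-length counting
  labs <- make_labels(
    label_entry("a", "+", 0:5, c("TSS", rep("exon1", 4), "TTS")),
    label_entry("b", "+", 10:15, c("TSS", rep("exon1", 4), "TTS")))
  tr <- suppressWarnings(estimate_tu_transitions(labs))
  expect_equal(tr$probs["exon1", "exon1"], 3/4)
  expect_equal(tr$probs["exon1", "TTS"], 1/4)
})

test_that("Pol II clustering retains the high-enrichment transcripts", {
  mk <- function(i, pol) label_entry(paste0("t", i), "+", c(10*i, 10*i + 1, 10*i + 2),
                                     c("TSS", "exon1", "TTS"))
  labs <- make_labels(mk(1), mk(2), mk(3), mk(4), mk(5))
  pol <- integer(60)
  # transcripts 1-3: Pol II present at TSS and TTS bins; 4-5 absent
  for (i in 1:3) pol[c(10*i, 10*i + 2) + 1L] <- 1L
  kept <- filter_polII_transcripts(labs, pol, seed = 17)
  expect_setequal(vapply(kept, `[[`, "", "id"), c("t1", "t2", "t3"))

  # degenerate: identical features retain everything with a warning
  pol_all <- rep(1L, 60)
  expect_warning(kept_all <- filter_polII_transcripts(labs, pol_all),
                 "identical")
  expect_length(kept_all, 5)

  # two antibodies, clearly separated
  pol2 <- cbind(a1 = pol, a2 = pol)
  kept2 <- filter_polII_transcripts(labs, pol2, pool = FALSE, seed = 17)
  expect_setequal(vapply(kept2, `[[`, "", "id"), c("t1", "t2", "t3"))
})

test_that("supervised emissions are per-role mark frequencies with clipping", {
  labs <- make_labels(label_entry("t", "+", 0:5,
                                  c("TSS", "exon1", "exon1", "exon1",
                                    "exon1", "TTS")))
  cm <- matrix(0L, 10, 2, dimnames = list(NULL, c("m1", "m2")))
  cm[2:5, 1] <- c(1L, 1L, 0L, 1L)   # exon1 bins 1-4
  cm[2:5, 2] <- 1L
  em <- suppressWarnings(estimate_tu_emissions(labs, cm))
  expect_equal(em["exon1", "m1"], 0.75)
  expect_equal(em["exon1", "m2"], 1 - 1e-6)   # all-ones column is clipped
  # roles with no bins fall back to 0.5
  expect_warning(estimate_tu_emissions(labs, cm), "exonI")
  expect_equal(unname(em["exonI", ]), c(0.5, 0.5))
})

test_that("assembled models have 17 states, exact zeros and a clean grammar", {
  tm <- make_truth_model(seed = 9, contig_bp = 6e5)
  p <- tm$params
  expect_equal(p$k, 17L)
  expect_equal(sum(p$state_meta$role == "background"), 3L)
  expect_equal(sum(p$state_meta$role != "background"), 14L)
  expect_lt(max(abs(rowSums(p$transition) - 1)), 1e-9)
  expect_true(all(p$transition[p$zero_mask] == 0))
  # supervised mass only on grammar edges; no body edge crosses strands
  topo <- build_tu_topology()
  sup_idx <- which(topo$supervised, arr.ind = TRUE)
  st <- p$state_meta$strand
  expect_true(all(st[sup_idx[, 1]] == st[sup_idx[, 2]]))
  expect_true(all(p$transition[!topo$allowed] == 0))
})

test_that("clamped supervised entries survive full training runs", {
  tm <- make_truth_model(seed = 13, contig_bp = 6e5)
  sim <- simulate_class_matrix(tm$params, tm$grid, seed = 29)
  start <- assemble_model(tm$trans, tm$emis, sim$classes, tm$grid, fit = FALSE)
  fit <- baum_welch(start$params, list(sim$classes), max_iter = 40, tol = 1e-6)
  clamped_t <- !start$params$free_transition
  clamped_e <- !start$params$free_emission
  expect_identical(fit$params$transition[clamped_t],
                   start$params$transition[clamped_t])
  expect_identical(fit$params$emission[clamped_e],
                   start$params$emission[clamped_e])
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})
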