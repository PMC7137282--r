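#' @useDynLib chromTU, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

provenance_header <- function(params = list()) {
  c(sprintf("# chromTU %s", as.character(utils::packageVersion("chromTU"))),
    if (length(params))
      sprintf("# %s", paste(names(params), unlist(lapply(params, format)),
                            sep = "=", collapse = " ")))
}

#' Read a chrom.sizes table
#'
#' Two-column TSV (contig, length in bp), as distributed with genome
#' assemblies.
#'
#' @param path file path.
#' @return named numeric vector of contig lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "length"),
                          colClasses = c("character", "numeric"),
                          comment.char = "#")
  if (anyDuplicated(df$contig)) stop("duplicate contig in ", path)
  stats::setNames(df$length, df$contig)
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector of contig lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), format(sizes, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write BED files
#'
#' BED intervals are 0-based half-open on disk and kept that way internally.
#' BED3 and BED6 are supported; `#`-comment and `track` lines are skipped.
#' Malformed lines are rejected with their line number.
#'
#' @param path file path.
#' @return a `genomic_intervals` data frame with a `score` column (NA when
#'   absent from the file).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(cbind(genomic_intervals(character(0), numeric(0), numeric(0)),
                 score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("malformed BED line ", lineno[which(nf < 3)[1]],
                        " in ", path, ": fewer than 3 fields")
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  start <- suppressWarnings(as.numeric(get(1 + 1)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) stop("malformed BED line ", lineno[bad[1]], " in ", path,
                        ": invalid coordinates (start must be < end)")
  strand <- get(6, ".")
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  out <- genomic_intervals(get(1), start, end, strand, get(4, ""))
  out$label[is.na(out$label)] <- ""
  out$score <- suppressWarnings(as.numeric(get(5)))
  out
}

#' @rdname read_bed
#' @param intervals a `genomic_intervals` data frame; optional `score` column
#'   (defaults to 0).
#' @param header optional character vector of `#` comment lines to prepend.
#' @export
write_bed <- function(intervals, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(intervals) == 0L) return(invisible(path))
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  score[is.na(score)] <- 0
  name <- intervals$label
  name[is.na(name) | !nzchar(name)] <- "."
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                     intervals$contig,
                     format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE),
                     name,
                     format(score, scientific = FALSE, trim = TRUE),
                     intervals$strand), con)
  invisible(path)
}

#' Read a transcript annotation (GTF/GFF)
#'
#' Exon records are grouped by transcript id; transcript extents are the exon
#' spans. GTF/GFF coordinates (1-based inclusive) are converted to the
#' package-internal 0-based half-open convention on ingest.
#'
#' @param path GTF/GFF file path.
#' @return an `annotation` list with elements `transcripts` (a
#'   `genomic_intervals` data frame, label = transcript id) and `exons`
#'   (data frame: transcript_id, contig, start, end, strand, in genome order).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) stop("no feature type column in ", path)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("no exon records in ", path)
  tid <- as.character(ex$transcript_id)
  if (any(is.na(tid))) stop("exon without transcript_id in ", path)
  exons <- data.frame(transcript_id = tid,
                      contig = as.character(ex$seqnames),
                      start = ex$start - 1, end = as.numeric(ex$end),
                      strand = as.character(ex$strand),
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  annotation_from_exons(exons)
}

annotation_from_exons <- function(exons) {
  sp <- split(exons, exons$transcript_id)
  tr <- do.call(rbind, lapply(sp, function(e) {
    if (length(unique(e$contig)) != 1L || length(unique(e$strand)) != 1L)
      stop("transcript ", e$transcript_id[1], " spans contigs or strands")
    data.frame(contig = e$contig[1], start = min(e$start), end = max(e$end),
               strand = e$strand[1], label = e$transcript_id[1],
               stringsAsFactors = FALSE)
  }))
  rownames(tr) <- NULL
  tr <- tr[order(tr$contig, tr$start), , drop = FALSE]
  transcripts <- genomic_intervals(tr$contig, tr$start, tr$end, tr$strand, tr$label)
  structure(list(transcripts = transcripts, exons = exons), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation: %d transcript(s), %d exon record(s)\n",
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' @rdname read_gtf
#' @param annotation an `annotation` object.
#' @param source source field for the GTF records.
#' @export
write_gtf <- function(annotation, path, source = "chromTU") {
  ex <- annotation$exons
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  lines <- sprintf(
    '%s\t%s\texon\t%s\t%s\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$contig, source,
    format(ex$start + 1, scientific = FALSE, trim = TRUE),
    format(ex$end, scientific = FALSE, trim = TRUE),
    ex$strand, ex$transcript_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-bin tables (counts or binary classes)
#'
#' One row per bin: global 0-based index, contig, start, end, then one column
#' per track/mark. `#` comment lines carry provenance and are skipped on read.
#'
#' @param path file path.
#' @param grid optional [bin_grid()]; when given, the table is checked against
#'   it.
#' @return list with `grid_cols` (idx/contig/start/end data frame) and `values`
#'   (numeric matrix, one column per mark).
#' @export
read_bin_table <- function(path, grid = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("idx", "contig", "start", "end")
  if (!all(need %in% names(df))) stop("missing columns in ", path, ": ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  marks <- setdiff(names(df), need)
  vals <- as.matrix(df[, marks, drop = FALSE])
  if (!is.null(grid)) {
    stopifnot_grid(grid)
    if (nrow(df) != grid$n_total) stop("row count does not match grid")
    if (!identical(as.integer(df$idx), seq_len(grid$n_total) - 1L))
      stop("bin indices do not match grid")
  }
  list(grid_cols = df[, need], values = vals)
}

#' @rdname read_bin_table
#' @param values matrix (bins x tracks) with column names.
#' @param header optional `#` comment lines.
#' @export
write_bin_table <- function(values, grid, path, header = NULL) {
  stopifnot_grid(grid)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_total) stop("values do not match grid")
  if (is.null(colnames(values))) stop("values must have column names")
  bc <- bin_coords(grid)
  df <- data.frame(idx = bc$idx, contig = bc$contig,
                   start = format(bc$start, scientific = FALSE, trim = TRUE),
                   end = format(bc$end, scientific = FALSE, trim = TRUE),
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count fragment midpoints per bin from a BAM file
#'
#' Each retained fragment contributes exactly one count, to the bin containing
#' its midpoint. For a properly paired fragment the midpoint is
#' `floor((leftmost start + rightmost end) / 2)`; single-end reads (if any)
#' use the midpoint of the read itself and trigger a warning. Reads with
#' MAPQ below `min_mapq` or with any bit of `exclude_flag` set are dropped;
#' the defaults keep only uniquely mapped (MAPQ 255 as emitted by STAR),
#' non-duplicate (flag 1024) reads.
#'
#' @param bam_path indexed BAM file.
#' @param grid a [bin_grid()].
#' @param min_mapq minimum mapping quality (default 255).
#' @param exclude_flag SAM flag bits that disqualify a read (default 1024,
#'   PCR/optical duplicates).
#' @param on_missing_contig "warn" (skip reads on contigs absent from the
#'   grid, with a warning) or "error".
#' @return integer vector of per-bin counts (length `grid$n_total`).
#' @export
count_reads_midpoint <- function(bam_path, grid, min_mapq = 255,
                                 exclude_flag = 1024,
                                 on_missing_contig = c("warn", "error")) {
  stopifnot_grid(grid)
  on_missing_contig <- match.arg(on_missing_contig)
  what <- c("rname", "pos", "mapq", "flag", "isize", "qwidth")
  res <- Rsamtools::scanBam(bam_path,
    param = Rsamtools::ScanBamParam(
      what = what,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  rname <- as.character(res$rname)
  keep <- !is.na(res$pos) & !is.na(res$mapq) & res$mapq >= min_mapq &
    bitwAnd(res$flag, as.integer(exclude_flag)) == 0L
  missing <- keep & !rname %in% grid$contigs
  if (any(missing)) {
    if (on_missing_contig == "error")
      stop("reads on contigs absent from grid: ",
           paste(unique(rname[missing]), collapse = ", "))
    warning(sum(missing), " read(s) on contigs absent from grid skipped")
    keep <- keep & !missing
  }
  flag <- res$flag[keep]
  pos0 <- res$pos[keep] - 1          # SAM POS is 1-based
  isize <- res$isize[keep]
  qwidth <- res$qwidth[keep]
  rname <- rname[keep]

  paired <- bitwAnd(flag, 1L) > 0L
  if (any(!paired))
    warning(sum(!paired), " single-end read(s): using read midpoint")
  # one count per fragment: the leftmost mate (isize > 0) represents a pair
  rep_pair <- paired & !is.na(isize) & isize > 0L
  use <- rep_pair | !paired
  mid <- ifelse(paired[use],
                pos0[use] + abs(isize[use]) %/% 2,
                pos0[use] + qwidth[use] %/% 2)
  rname <- rname[use]
  mid <- pmin(pmax(mid, 0), grid$lengths[rname] - 1)
  counts <- integer(grid$n_total)
  if (length(mid)) {
    idx <- bin_index(grid, rname, mid)
    tab <- tabulate(idx + 1L, nbins = grid$n_total)
    counts <- as.integer(tab)
  }
  counts
}
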