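#' Partition a genome into fixed-width bins
#'
#' Tiles every contig with non-overlapping, strand-less bins of `bin_width`
#' base pairs. The last bin of a contig may be shorter than `bin_width`. All
#' coordinates are 0-based half-open; global bin indices are 0-based and run
#' contig by contig in the order given.
#'
#' @param chrom_sizes named numeric vector of contig lengths in bp, or a
#'   two-column data frame (contig, length) as read by [read_chrom_sizes()].
#' @param bin_width bin width in bp (default 200, roughly one nucleosome plus
#'   spacer).
#' @return an object of class `bin_grid`: contig names, lengths, per-contig
#'   bin counts, per-contig global-index offsets and the total bin count.
#' @examples
#' g <- bin_grid(c(chrA = 1000), bin_width = 200)
#' g$n_total  # 5
#' @export
bin_grid <- function(chrom_sizes, bin_width = 200) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chrom_sizes must be named by contig")
  if (anyDuplicated(names(sizes)))
    stop("duplicate contig names: ", paste(unique(names(sizes)[duplicated(names(sizes))]), collapse = ", "))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all contig lengths must be positive")
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a single positive number")
  bin_width <- as.integer(bin_width)
  nb <- as.integer(ceiling(sizes / bin_width))
  offsets <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offsets) <- names(sizes)
  structure(list(
    contigs   = names(sizes),
    lengths   = stats::setNames(as.numeric(sizes), names(sizes)),
    bin_width = bin_width,
    n_bins    = stats::setNames(nb, names(sizes)),
    offsets   = offsets,
    n_total   = sum(nb)
  ), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d contig(s), %d bp bins, %d bins total\n",
              length(x$contigs), x$bin_width, x$n_total))
  invisible(x)
}

#' @rdname bin_grid
#' @param chrom_sizes_table see `chrom_sizes`
#' @export
partition_genome <- function(chrom_sizes_table, bin_width = 200) {
  bin_grid(chrom_sizes_table, bin_width)
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "bin_grid")) stop("not a bin_grid")
  invisible(grid)
}

#' Map base-pair positions to global bin indices
#'
#' @param grid a [bin_grid()].
#' @param contig contig name (recycled against `pos`).
#' @param pos 0-based bp position(s) on the contig.
#' @return 0-based global bin index/indices.
#' @export
bin_index <- function(grid, contig, pos) {
  stopifnot_grid(grid)
  if (any(!contig %in% grid$contigs)) stop("unknown contig: ",
      paste(setdiff(contig, grid$contigs), collapse = ", "))
  if (any(pos < 0 | pos >= grid$lengths[contig]))
    stop("position out of contig range")
  as.integer(grid$offsets[contig] + pos %/% grid$bin_width)
}

#' Genomic coordinates of bins
#'
#' @param grid a [bin_grid()].
#' @param idx 0-based global bin indices (default: all bins).
#' @return data frame with contig, start, end (0-based half-open) per bin.
#' @export
bin_coords <- function(grid, idx = NULL) {
  stopifnot_grid(grid)
  if (is.null(idx)) idx <- seq_len(grid$n_total) - 1L
  idx <- as.integer(idx)
  if (any(idx < 0L | idx >= grid$n_total)) stop("bin index out of range")
  ci <- findInterval(idx, grid$offsets)          # contig number per bin
  contig <- grid$contigs[ci]
  local <- idx - grid$offsets[ci]
  start <- as.numeric(local) * grid$bin_width
  end <- pmin(start + grid$bin_width, grid$lengths[contig])
  data.frame(contig = contig, start = start, end = end, idx = idx,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global bin indices overlapped by a bp interval
#'
#' @param grid a [bin_grid()].
#' @param contig contig name.
#' @param start,end 0-based half-open interval; parts outside the contig are
#'   truncated.
#' @return integer vector of 0-based global bin indices (possibly empty).
#' @export
bin_span <- function(grid, contig, start, end) {
  stopifnot_grid(grid)
  if (!contig %in% grid$contigs) stop("unknown contig: ", contig)
  len <- grid$lengths[[contig]]
  start <- max(0, start); end <- min(len, end)
  if (start >= end) return(integer(0))
  first <- start %/% grid$bin_width
  last <- (end - 1) %/% grid$bin_width
  as.integer(grid$offsets[[contig]] + first:last)
}

#' Build an internal interval table
#'
#' Plain-data representation of genomic intervals (0-based half-open) used
#' throughout the package: annotation transcripts, BED predictions, nascent
#' transcripts.
#'
#' @param contig,start,end,strand,label parallel vectors; strand in
#'   `c("+", "-", ".")`, label free text.
#' @return data frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(contig, start, end, strand = ".", label = "") {
  n <- length(contig)
  df <- data.frame(contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end))
    stop("interval start must be < end (row ",
         which(df$start >= df$end)[1], ")")
  if (nrow(df) && any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Per-bin overlap mask of a set of intervals
#'
#' A bin is set to 1 iff at least one bp of any interval overlaps it
#' (the O(bin, .) >= 1 rule used for nascent-RNA and prediction masks).
#' Interval parts outside the grid are truncated; unknown contigs are dropped.
#'
#' @param intervals a `genomic_intervals` data frame (or any data frame with
#'   contig/start/end columns).
#' @param grid a [bin_grid()].
#' @param strand optional strand filter ("+" or "-"); default uses all
#'   intervals regardless of strand.
#' @return integer 0/1 vector of length `grid$n_total`.
#' @export
intervals_to_bin_mask <- function(intervals, grid, strand = NULL) {
  stopifnot_grid(grid)
  mask <- integer(grid$n_total)
  if (is.null(intervals) || nrow(intervals) == 0L) return(mask)
  if (!is.null(strand)) intervals <- intervals[intervals$strand == strand, , drop = FALSE]
  intervals <- intervals[intervals$contig %in% grid$contigs, , drop = FALSE]
  for (i in seq_len(nrow(intervals))) {
    idx <- bin_span(grid, intervals$contig[i], intervals$start[i], intervals$end[i])
    if (length(idx)) mask[idx + 1L] <- 1L
  }
  mask
}
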