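#' Aggregate reads into per-cell barcode counts
#'
#' Discards reads below the quality threshold, truncates barcodes to
#' `read_length` bases, and counts occurrences per (cell, truncated
#' barcode). Reads with `cell_label == 0` (unassigned) are dropped.
#'
#' @param reads ReadTable from [callBases()] with a `cell_label` column.
#' @param read_length Number of leading bases used (1..barcode length).
#' @param quality_min Minimum spot quality retained (default 0 keeps all).
#' @return Named list: per cell label (as character), a named integer vector
#'   of barcode counts.
#' @seealso [dominantBarcodes()], [genotypeCells()]
#' @export
aggregateReads <- function(reads, read_length = 12L, quality_min = 0) {
  stopifnot(read_length >= 1L)
  keep <- reads$spot_quality >= quality_min & reads$cell_label > 0L
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r)) return(structure(list(), names = character()))
  bc <- substr(r$barcode, 1L, read_length)
  tapply(bc, r$cell_label, function(b) {
    tb <- table(b)
    stats::setNames(as.integer(tb), names(tb))
  }, simplify = FALSE)
}

#' Select the two dominant barcodes of a cell
#'
#' Orders barcodes by decreasing count, breaking count ties
#' lexicographically (and flagging the cell ambiguous when the top count is
#' tied). The second barcode is the next distinct barcode in the same
#' order.
#'
#' @param counts Named integer vector of barcode counts (may be empty).
#' @return list(top, top_count, second, second_count, ambiguous); an empty
#'   input gives the all-null record.
#' @export
dominantBarcodes <- function(counts) {
  if (!length(counts))
    return(list(top = NA_character_, top_count = 0L,
                second = NA_character_, second_count = 0L,
                ambiguous = FALSE))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  top <- names(counts)[1]
  ambiguous <- length(counts) > 1L && counts[2] == counts[1]
  list(top = top, top_count = as.integer(counts[1]),
       second = if (length(counts) > 1L) names(counts)[2] else NA_character_,
       second_count = if (length(counts) > 1L) as.integer(counts[2]) else 0L,
       ambiguous = ambiguous)
}

#' Map a barcode to the codebook
#'
#' At `max_distance = 0` this is exact prefix lookup (set membership over
#' the codebook prefixes of `read_length` bases). For `max_distance > 0`
#' the unique entry within that Levenshtein distance wins; distance ties
#' give `"unmapped"`. Truncation that makes two codebook prefixes collide
#' is an error, not a silent merge.
#'
#' @param barcode Barcode string (length `read_length`).
#' @param codebook A [Codebook-class].
#' @param read_length Prefix length used for matching.
#' @param max_distance Maximum Levenshtein distance (default 0 = exact).
#' @return The matching sgrna_id, or `"unmapped"`.
#' @export
mapToCodebook <- function(barcode, codebook, read_length = 12L,
                          max_distance = 0L) {
  pre <- substr(barcodes(codebook), 1L, read_length)
  if (anyDuplicated(pre))
    stop(sprintf("codebook ambiguous at length %d", read_length))
  ids <- codebookTable(codebook)$sgrna_id
  if (max_distance == 0L) {
    hit <- match(barcode, pre)
    return(if (is.na(hit)) "unmapped" else ids[hit])
  }
  d <- utils::adist(barcode, pre)[1, ]
  best <- min(d)
  if (best > max_distance || sum(d == best) > 1L) return("unmapped")
  ids[which.min(d)]
}

#' Genotype every cell from its reads
#'
#' Aggregates reads per cell body, selects the dominant barcode pair, maps
#' the top barcode to the codebook, and reports a summary in the exact
#' definitions used for screen bookkeeping: fraction of cells with at least
#' one read, mean reads over all cells, and fraction of reads that mapped.
#'
#' @param reads ReadTable with `cell_label`.
#' @param cell_labels Integer vector of all cell labels present (e.g.
#'   `sort(unique(cells[cells > 0]))`), so zero-read cells are reported.
#' @param codebook A [Codebook-class].
#' @param read_length,quality_min,max_distance As in [aggregateReads()] and
#'   [mapToCodebook()].
#' @return list(genotypes, summary). `genotypes`: one row per cell with
#'   cell_label, n_reads, top/second barcode and counts, mapped_sgrna_id,
#'   gene, ambiguous. `summary`: fraction_cells_with_reads,
#'   reads_per_cell_mean, fraction_reads_mapped (0 with `no_reads = TRUE`
#'   flag when there are no reads at all).
#' @export
genotypeCells <- function(reads, cell_labels, codebook, read_length = 12L,
                          quality_min = 0, max_distance = 0L) {
  cb <- codebookTable(codebook)
  pre <- substr(cb$barcode, 1L, read_length)
  if (anyDuplicated(pre))
    stop(sprintf("codebook ambiguous at length %d", read_length))
  counts <- aggregateReads(reads, read_length, quality_min)
  cell_labels <- sort(unique(as.integer(cell_labels)))
  n <- length(cell_labels)
  gt <- data.frame(cell_label = cell_labels, n_reads = 0L,
                   top_barcode = NA_character_, top_count = 0L,
                   second_barcode = NA_character_, second_count = 0L,
                   mapped_sgrna_id = "unmapped", gene = NA_character_,
                   ambiguous = FALSE)
  for (i in seq_len(n)) {
    cc <- counts[[as.character(cell_labels[i])]]
    if (is.null(cc)) next
    gt$n_reads[i] <- sum(cc)
    dom <- dominantBarcodes(cc)
    gt$top_barcode[i] <- dom$top
    gt$top_count[i] <- dom$top_count
    gt$second_barcode[i] <- dom$second
    gt$second_count[i] <- dom$second_count
    gt$ambiguous[i] <- dom$ambiguous
    hit <- if (max_distance == 0L) {
      m <- match(dom$top, pre)
      if (is.na(m)) "unmapped" else cb$sgrna_id[m]
    } else mapToCodebook(dom$top, codebook, read_length, max_distance)
    gt$mapped_sgrna_id[i] <- hit
    if (hit != "unmapped") gt$gene[i] <- cb$gene[match(hit, cb$sgrna_id)]
  }
  total_reads <- sum(reads$cell_label > 0L &
                       reads$spot_quality >= quality_min)
  mapped_reads <- if (total_reads) {
    rbc <- substr(reads$barcode[reads$cell_label > 0L &
                                  reads$spot_quality >= quality_min],
                  1L, read_length)
    sum(rbc %in% pre)
  } else 0L
  summary <- list(
    fraction_cells_with_reads = if (n) mean(gt$n_reads > 0L) else 0,
    reads_per_cell_mean = if (n) mean(gt$n_reads) else 0,
    fraction_reads_mapped = if (total_reads) mapped_reads / total_reads else 0,
    no_reads = total_reads == 0L
  )
  list(genotypes = gt, summary = summary)
}
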