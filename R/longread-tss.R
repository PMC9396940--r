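#' Filter long reads supporting chimeric transcription
#'
#' Retains alignments with MapQ at least `min_mapq` that overlap an
#' LCT-producing L1 element, run antisense to it, and extend beyond the
#' element's 5' boundary into unique flanking sequence (the geometry of
#' an ASP-driven chimera). Reads may qualify for more than one element;
#' each qualifying (read, element) pair is returned.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand`,
#'   `mapq` (0-based half-open; a missing `mapq` column is an error) and
#'   optionally `read_id`.
#' @param lct_elements element table restricted to LCT-producing
#'   elements.
#' @param min_mapq minimum mapping quality (default 30, inclusive).
#' @return the qualifying alignments with an `element_id` column.
#' @export
filter_chimeric_longreads <- function(alignments, lct_elements,
                                      min_mapq = 30L) {
  .assert_cols(alignments, c("chrom", "start", "end", "strand"),
               "long-read alignment table")
  if (!"mapq" %in% names(alignments))
    stop("long-read alignment table has no 'mapq' column", call. = FALSE)
  if (!"read_id" %in% names(alignments))
    alignments$read_id <- sprintf("lr_%06d", seq_len(nrow(alignments)))
  ok <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  if (!nrow(ok) || !nrow(lct_elements)) {
    out <- ok[integer(0), , drop = FALSE]
    out$element_id <- character(0)
    return(out)
  }
  ov <- GenomicRanges::findOverlaps(.gr0(ok), .gr0(lct_elements),
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  anti <- ok$strand[q] != lct_elements$strand[s]
  beyond <- ifelse(lct_elements$strand[s] == "+",
                   ok$start[q] < lct_elements$start[s],
                   ok$end[q] > lct_elements$end[s])
  keep <- anti & beyond
  out <- ok[q[keep], , drop = FALSE]
  out$element_id <- lct_elements$id[s[keep]]
  rownames(out) <- NULL
  out
}

#' Reposition a read 5' end into L1-internal coordinates
#'
#' The read's 5' end is its transcription start (the read is antisense to
#' the element); the offset is the genomic distance from the element's
#' strand-aware 5' boundary. For a plus-strand element the 5' end of an
#' antisense (minus-strand) read is its highest coordinate; mirrored for
#' minus-strand elements. Negative offsets flag reads whose observed 5'
#' end lies outside the element (initiation beyond its boundary).
#'
#' @param read one-row data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param element one-row element data.frame.
#' @return list with `offset` (bp from the element 5' end) and
#'   `outside_element` flag.
#' @export
reposition_tss <- function(read, element) {
  read5 <- if (read$strand == "+") read$start else read$end - 1L
  offset <- if (element$strand == "+") read5 - element$start
            else element$end - 1L - read5
  list(offset = as.integer(offset), outside_element = offset < 0L)
}

# vectorised internal version over a filtered alignment table
.tss_offsets <- function(filtered, elements) {
  el <- elements[match(filtered$element_id, elements$id), ]
  read5 <- ifelse(filtered$strand == "+", filtered$start,
                  filtered$end - 1L)
  as.integer(ifelse(el$strand == "+", read5 - el$start,
                    el$end - 1L - read5))
}

#' Build per-element TSS profiles from filtered long reads
#'
#' @param filtered output of [filter_chimeric_longreads()].
#' @param elements element table.
#' @return data.frame with `element_id`, `read_id`, `offset`,
#'   `outside_element`.
#' @export
tss_profiles <- function(filtered, elements) {
  if (!nrow(filtered))
    return(data.frame(element_id = character(), read_id = character(),
                      offset = integer(), outside_element = logical(),
                      stringsAsFactors = FALSE))
  off <- .tss_offsets(filtered, elements)
  data.frame(element_id = filtered$element_id,
             read_id = filtered$read_id, offset = off,
             outside_element = off < 0L, stringsAsFactors = FALSE)
}

#' Summarise TSS usage over the L1 5' UTR
#'
#' Fractions of detected elements with at least one TSS in the first
#' 500 bp (the two described ASP regions) and the first 900 bp (the
#' whole 5' UTR) of the element, both windows inclusive at their upper
#' bound, plus a read-percentage heatmap matrix along element positions.
#' Elements in `all_elements` without any profiled read are reported as
#' undetected (rather than entering the denominators).
#'
#' @param profiles output of [tss_profiles()].
#' @param all_elements optional character vector of the element ids
#'   assayed (detected + undetected).
#' @param windows upper bounds of the two summary windows (bp).
#' @param bin heatmap bin width (bp).
#' @param max_pos heatmap extent in bp from the element 5' end.
#' @return list with `fractions` (named: `asp_0_500`, `utr_0_900`),
#'   `n_detected`, `undetected` (ids), `per_element` (indicator table)
#'   and `heatmap` (elements x bins matrix of read percentages; rows sum
#'   to 100).
#' @export
tss_summary <- function(profiles, all_elements = NULL,
                        windows = c(500L, 900L), bin = 50L,
                        max_pos = 6000L) {
  if (!nrow(profiles)) stop("no TSS profiles to summarise", call. = FALSE)
  det <- sort(unique(profiles$element_id))
  ind <- t(vapply(det, function(e) {
    off <- profiles$offset[profiles$element_id == e]
    c(asp_0_500 = any(off >= 0L & off <= windows[1]),
      utr_0_900 = any(off >= 0L & off <= windows[2]))
  }, logical(2)))
  breaks <- seq(0L, max_pos, by = bin)
  hm <- t(vapply(det, function(e) {
    off <- profiles$offset[profiles$element_id == e]
    off <- pmin(pmax(off, 0L), max_pos - 1L)
    h <- tabulate(findInterval(off, breaks), nbins = length(breaks) - 1L)
    100 * h / sum(h)
  }, numeric(length(breaks) - 1L)))
  colnames(hm) <- sprintf("%d-%d", breaks[-length(breaks)], breaks[-1L])
  undetected <- if (is.null(all_elements)) character()
                else setdiff(all_elements, det)
  list(fractions = colMeans(ind), n_detected = length(det),
       undetected = undetected, per_element = ind, heatmap = hm)
}
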