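#' Recent L1 subfamily names recognised as ASP-competent
#'
#' RepeatMasker repeat names for the evolutionarily recent L1 subfamilies
#' whose 5' UTR carries the antisense promoter. `L1HS` and `L1P1` are the
#' two RepeatMasker aliases of the youngest subfamily (L1PA1).
#'
#' @export
ASP_SUBFAMILIES <- c("L1P1", "L1HS", paste0("L1PA", 2:8))

# map RepeatMasker repNames onto canonical subfamily labels
.canon_subfamily <- function(rep_name) {
  ifelse(rep_name %in% c("L1HS", "L1P1"), "L1PA1", rep_name)
}

#' Read a UCSC-schema RepeatMasker table
#'
#' Parses an rmsk TSV in the UCSC Table Browser dialect and normalises the
#' strand-dependent consensus fields. On the plus strand `repStart` holds
#' the consensus start and `repLeft` the (negative) remainder past the
#' match end; on the minus strand the two fields swap roles, so the
#' consensus 5' offset is read from `repStart` on `+` and from the absolute
#' value of `repLeft` on `-`. `repEnd` is the consensus end on both
#' strands. Genomic coordinates are 0-based half-open.
#'
#' Malformed rows (non-numeric coordinates, start >= end, unknown strand)
#' are skipped with a warning naming the offending row numbers.
#'
#' @param path path to a TSV with UCSC rmsk columns. A header naming at
#'   least `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`,
#'   `repStart`, `repEnd`, `repLeft` is used when present; otherwise the
#'   standard headerless 17-column UCSC order is assumed.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class`, `consensus_5p_offset`, `consensus_end`.
#' @export
read_rmsk <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("genoName", first, fixed = TRUE)
  if (has_header) {
    raw <- read.delim(path, header = TRUE, comment.char = "",
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(raw) <- sub("^#", "", names(raw))
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    ucsc <- c("bin", "swScore", "milliDiv", "milliDel", "milliIns",
              "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
              "repName", "repClass", "repFamily", "repStart", "repEnd",
              "repLeft", "id")
    if (ncol(raw) == 16L) ucsc <- ucsc[-1L]  # no bin column
    if (ncol(raw) < 16L)
      stop("headerless rmsk table must have 16 or 17 UCSC columns, got ",
           ncol(raw), call. = FALSE)
    names(raw)[seq_along(ucsc)] <- ucsc
  }
  .assert_cols(raw, c("genoName", "genoStart", "genoEnd", "strand",
                      "repName", "repStart", "repEnd", "repLeft"),
               "rmsk table")
  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  gs <- num(raw$genoStart); ge <- num(raw$genoEnd)
  rs <- num(raw$repStart); re <- num(raw$repEnd); rl <- num(raw$repLeft)
  bad <- is.na(gs) | is.na(ge) | is.na(rs) | is.na(re) | is.na(rl) |
    !(raw$strand %in% c("+", "-")) | gs >= ge
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed rmsk row(s): ",
            paste(head(which(bad), 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", call. = FALSE)
  }
  keep <- !bad
  rc <- if ("repClass" %in% names(raw)) as.character(raw$repClass)[keep]
        else rep(NA_character_, sum(keep))
  data.frame(
    chrom = as.character(raw$genoName)[keep],
    start = as.integer(gs[keep]),
    end = as.integer(ge[keep]),
    strand = as.character(raw$strand)[keep],
    rep_name = as.character(raw$repName)[keep],
    rep_class = rc,
    consensus_5p_offset = as.integer(
      ifelse(raw$strand[keep] == "+", rs[keep], abs(rl[keep]))),
    consensus_end = as.integer(re[keep]),
    stringsAsFactors = FALSE)
}

#' Select ASP-competent L1 elements from a repeat table
#'
#' Retains repeats whose name belongs to the recent L1 subfamilies and
#' whose aligned consensus interval both starts before position 400 and
#' ends past position 600 of the L1 consensus, i.e. elements that still
#' carry the promoter-bearing portion of the 5' UTR (the antisense
#' promoter hotspots lie around +200 and +450). Both bounds are strict.
#' Input order is preserved and the operation is idempotent.
#'
#' @param records data.frame as returned by [read_rmsk()] (or any table
#'   with `chrom`, `start`, `end`, `strand`, `rep_name`,
#'   `consensus_5p_offset`, `consensus_end`).
#' @param subfamilies character vector of repNames to keep
#'   (default [ASP_SUBFAMILIES]).
#' @param max_5p_offset,min_consensus_end filter bounds in consensus bp.
#' @return data.frame of L1 elements with columns `id`, `chrom`, `start`,
#'   `end`, `strand`, `subfamily`, `consensus_5p_offset`, `consensus_end`,
#'   `has_asp` (all `TRUE` by construction) and `length`.
#' @export
select_asp_l1 <- function(records, subfamilies = ASP_SUBFAMILIES,
                          max_5p_offset = 400L, min_consensus_end = 600L) {
  .assert_cols(records, c("chrom", "start", "end", "strand", "rep_name",
                          "consensus_5p_offset", "consensus_end"),
               "repeat record table")
  keep <- records$rep_name %in% subfamilies &
    records$consensus_5p_offset < max_5p_offset &
    records$consensus_end > min_consensus_end
  out <- records[keep, , drop = FALSE]
  id <- if ("id" %in% names(out)) out$id else
    sprintf("L1_%05d", which(keep))
  res <- data.frame(
    id = id,
    chrom = out$chrom, start = out$start, end = out$end,
    strand = out$strand,
    subfamily = .canon_subfamily(out$rep_name),
    consensus_5p_offset = out$consensus_5p_offset,
    consensus_end = out$consensus_end,
    has_asp = rep(TRUE, nrow(out)),
    length = out$end - out$start,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Extract the 5'-most sequence of an L1 element
#'
#' Returns the first `L` bases of the element read in element orientation:
#' `genome[start, start+L)` for plus-strand elements and the reverse
#' complement of `genome[end-L, end)` for minus-strand elements. Elements
#' shorter than `L` yield the whole (truncated) element with a
#' `truncated` flag; elements extending outside the chromosome are an
#' error.
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or a FASTA path.
#' @param element one-row data.frame with `id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param L number of bases to extract (default 500).
#' @return [Biostrings::DNAStringSet] of length 1 named by the element id,
#'   with `metadata(x)$truncated` set accordingly.
#' @export
extract_5p_sequence <- function(genome, element, L = 500L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  .assert_cols(element, c("id", "chrom", "start", "end", "strand"),
               "element")
  len <- element$end - element$start
  take <- min(L, len)
  s <- if (element$strand == "+") {
    .subseq0(genome, element$chrom, element$start, element$start + take)
  } else {
    Biostrings::reverseComplement(
      .subseq0(genome, element$chrom, element$end - take, element$end))
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- element$id
  S4Vectors::metadata(out)$truncated <- len < L
  out
}

#' Build the L1 reference set (element table + 5' sequences)
#'
#' Convenience wrapper: filters a repeat table with [select_asp_l1()] and
#' extracts the 5'-most `L` bp of every retained element.
#'
#' @inheritParams select_asp_l1
#' @inheritParams extract_5p_sequence
#' @param out_fasta,out_table optional output paths (reference FASTA and
#'   element table TSV).
#' @return list with `elements` (data.frame) and `sequences`
#'   ([Biostrings::DNAStringSet] named by element id, same order).
#' @export
build_l1_reference <- function(records, genome,
                               subfamilies = ASP_SUBFAMILIES, L = 500L,
                               out_fasta = NULL, out_table = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  elements <- select_asp_l1(records, subfamilies)
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(elements)),
    function(i) extract_5p_sequence(genome, elements[i, ], L)[[1L]]))
  names(seqs) <- elements$id
  if (!is.null(out_fasta)) Biostrings::writeXStringSet(seqs, out_fasta)
  if (!is.null(out_table))
    write.table(elements, out_table, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(elements = elements, sequences = seqs)
}

#' Count elements per L1 subfamily
#'
#' @param elements data.frame with a `subfamily` column.
#' @return data.frame with `subfamily` and `count`; counts partition the
#'   input.
#' @export
subfamily_counts <- function(elements) {
  if (nrow(elements) == 0L)
    return(data.frame(subfamily = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(elements$subfamily)
  data.frame(subfamily = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
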