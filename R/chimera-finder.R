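#' Match reads against the L1 5' reference set
#'
#' Finds, for each read, the best contiguous gapless match of length at
#' least `min_len` with at most `max_mm` substitutions against any
#' reference sequence, on both strands. Ties are broken deterministically:
#' longest match, then fewest mismatches, then lexicographically lowest
#' element id, then sense before antisense. Matching is gapless with
#' substitutions only — the selection criterion is a mismatch budget, not
#' an alignment score.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector) of read
#'   sequences, named by read id.
#' @param reference [Biostrings::DNAStringSet] of L1 5' sequences named by
#'   element id (see [build_l1_reference()]).
#' @param min_len minimum match length in bp (default 50).
#' @param max_mm maximum substitutions tolerated (default 1).
#' @return data.frame with one row per read: `read_id`, `element_id` (NA
#'   when no qualifying match), `match_length`, `mismatches`,
#'   `orientation` (`sense` when the read matches the reference as given,
#'   `antisense` when it matches the reverse complement) and
#'   `offset_in_element` (0-based match start in the reference).
#' @export
match_read_to_l1 <- function(reads, reference, min_len = 50L,
                             max_mm = 1L) {
  if (length(reference) == 0L)
    stop("empty L1 reference set", call. = FALSE)
  if (is.null(names(reference)))
    stop("reference sequences must be named by element id", call. = FALSE)
  ord <- order(names(reference))  # lowest-id tie-break = lowest index
  refs <- reference[ord]
  rd <- as.character(reads)
  ids <- names(rd)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(rd))
  hit <- .cpp_match_reads(unname(rd), unname(as.character(refs)),
                          as.integer(min_len), as.integer(max_mm))
  data.frame(
    read_id = ids,
    element_id = names(refs)[hit$ref_index],
    match_length = hit$match_length,
    mismatches = hit$mismatches,
    orientation = ifelse(hit$antisense, "antisense", "sense"),
    offset_in_element = hit$ref_offset,
    stringsAsFactors = FALSE)
}

#' Longest repeat-free sub-interval of a mate alignment
#'
#' Subtracts the repeat annotation from the genomic interval covered by
#' the unique-side mate and returns the longest remaining piece, provided
#' it reaches `min_unique` bp.
#'
#' @param mate one-row data.frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open); `NA` chrom means unaligned.
#' @param repeats repeat annotation: a data.frame with `chrom`, `start`,
#'   `end` or a [GenomicRanges::GRanges].
#' @param min_unique minimum unique length in bp (default 30).
#' @return one-row data.frame `chrom`, `start`, `end`, `width`, or `NULL`
#'   when no repeat-free piece of `min_unique` bp exists (or the mate is
#'   unaligned).
#' @export
find_unique_segment <- function(mate, repeats, min_unique = 30L) {
  if (is.na(mate$chrom) || is.na(mate$start)) return(NULL)
  gr <- GenomicRanges::GRanges(mate$chrom,
                               IRanges::IRanges(mate$start + 1L, mate$end))
  rep_gr <- if (is(repeats, "GRanges")) repeats else .gr0(repeats)
  GenomicRanges::strand(rep_gr) <- "*"
  left <- GenomicRanges::setdiff(gr, rep_gr, ignore.strand = TRUE)
  if (!length(left)) return(NULL)
  best <- left[which.max(GenomicRanges::width(left))]
  if (GenomicRanges::width(best) < min_unique) return(NULL)
  data.frame(chrom = as.character(GenomicRanges::seqnames(best)),
             start = GenomicRanges::start(best) - 1L,
             end = GenomicRanges::end(best),
             width = GenomicRanges::width(best),
             stringsAsFactors = FALSE)
}

# vectorised unique-segment computation: longest repeat-free piece per
# mate interval (NA start when none reaches min_unique)
.unique_segments <- function(mates, rep_gr, min_unique = 30L) {
  n <- nrow(mates)
  out <- data.frame(chrom = mates$chrom,
                    start = rep(NA_integer_, n),
                    end = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  gr <- .gr0(mates)
  ov <- GenomicRanges::findOverlaps(gr, rep_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  clean <- setdiff(seq_len(n), unique(q))
  w <- mates$end[clean] - mates$start[clean]
  keep <- w >= min_unique
  out$start[clean[keep]] <- mates$start[clean[keep]]
  out$end[clean[keep]] <- mates$end[clean[keep]]
  for (i in unique(q)) {   # minority: mates touching annotated repeats
    cut <- IRanges::reduce(IRanges::ranges(rep_gr)[
      S4Vectors::subjectHits(ov)[q == i]])
    left <- IRanges::setdiff(IRanges::IRanges(mates$start[i] + 1L,
                                              mates$end[i]), cut)
    if (!length(left)) next
    b <- which.max(IRanges::width(left))
    if (IRanges::width(left)[b] >= min_unique) {
      out$start[i] <- IRanges::start(left)[b] - 1L
      out$end[i] <- IRanges::end(left)[b]
    }
  }
  out
}

# interval gap in bp (0 when touching/overlapping), half-open coordinates
.gap0 <- function(s1, e1, s2, e2) max(0L, max(s2 - e1, s1 - e2))

#' Filter a chimeric read pair into a candidate
#'
#' Applies the pair-level selection: the transcript must run antisense to
#' the matched element, the element must carry an ASP-competent 5' UTR,
#' and the genomic gap between the two mates must not exceed `max_insert`
#' (inclusive; large inserts are tolerated to keep spliced chimeras).
#' Mates on different chromosomes have no defined insert and are
#' rejected. The first failed check is recorded as the rejection reason
#' (`same_orientation`, `no_5utr`, `insert_undefined`,
#' `insert_too_large`).
#'
#' @param l1_match one-row data.frame from [match_read_to_l1()] plus an
#'   `orientation` relative to the element of record.
#' @param unique_interval one-row data.frame from
#'   [find_unique_segment()].
#' @param element one-row element data.frame (`id`, `chrom`, `start`,
#'   `end`, `strand`, `has_asp`).
#' @param max_insert maximum mate gap in bp (default 50000, inclusive).
#' @return list with `accepted` (logical), `reason` (NA when accepted)
#'   and, when accepted, `candidate` (element id, unique interval and
#'   transcript strand).
#' @export
pair_to_candidate <- function(l1_match, unique_interval, element,
                              max_insert = 50000L) {
  reason <- NA_character_
  if (l1_match$orientation == "sense") {
    reason <- "same_orientation"
  } else if (!isTRUE(element$has_asp)) {
    reason <- "no_5utr"
  } else if (unique_interval$chrom != element$chrom) {
    reason <- "insert_undefined"
  } else if (.gap0(element$start, element$end, unique_interval$start,
                   unique_interval$end) > max_insert) {
    reason <- "insert_too_large"
  }
  if (!is.na(reason)) return(list(accepted = FALSE, reason = reason))
  list(accepted = TRUE, reason = NA_character_,
       candidate = data.frame(
         element_id = element$id, chrom = element$chrom,
         unique_start = unique_interval$start,
         unique_end = unique_interval$end,
         transcript_strand = if (element$strand == "+") "-" else "+",
         stringsAsFactors = FALSE))
}

#' Cluster chimeric candidates into LCT loci
#'
#' Per element and transcript strand, merges unique-side intervals that
#' overlap or lie within `merge_gap` bp of each other (union span),
#' accumulates supporting reads per sample and derives the strand-aware
#' locus geometry: `r1r2_distance`, the gap along the transcription
#' direction between the 5'-most end of the L1-side alignments and the
#' start of the merged unique interval (negative or zero means overlap or
#' juxtaposition), and `total_size`, the outermost genomic span of the
#' locus.
#'
#' @param candidates data.frame with `element_id`, `chrom`,
#'   `unique_start`, `unique_end`, `transcript_strand` and optionally
#'   `sample`, `read_id`, `r1_start`, `r1_end`.
#' @param elements element table (used for element spans; only ids
#'   present in `candidates` are needed).
#' @param merge_gap merge distance in bp (default 300, about the upper
#'   bound of the library insert).
#' @return list with `loci` (one row per locus) and `counts` (locus x
#'   sample matrix of supporting reads).
#' @export
cluster_candidates <- function(candidates, elements, merge_gap = 300L) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(loci = data.frame(), counts = matrix(0L, 0, 0)))
  }
  if (!"sample" %in% names(candidates)) candidates$sample <- "pooled"
  has_r1 <- all(c("r1_start", "r1_end") %in% names(candidates))
  samples <- sort(unique(candidates$sample))
  key <- paste(candidates$element_id, candidates$transcript_strand)
  loci <- list(); counts <- list()
  for (k in unique(key)) {
    sub <- candidates[key == k, , drop = FALSE]
    el <- elements[match(sub$element_id[1], elements$id), ]
    ir <- IRanges::IRanges(sub$unique_start + 1L, sub$unique_end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    # every input interval is contained in exactly one reduced span
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in seq_along(red)) {
      mem <- sub[grp == g, , drop = FALSE]
      us <- IRanges::start(red)[g] - 1L; ue <- IRanges::end(red)[g]
      tstrand <- mem$transcript_strand[1]
      if (has_r1 && !all(is.na(mem$r1_start))) {
        l1_lo <- min(mem$r1_start, na.rm = TRUE)
        l1_hi <- max(mem$r1_end, na.rm = TRUE)
      } else {
        l1_lo <- el$start; l1_hi <- el$end
      }
      # along transcription: minus-strand transcripts exit the element
      # leftwards into the upstream flank, plus-strand rightwards
      d <- if (tstrand == "-") l1_lo - ue else us - l1_hi
      tot <- max(ue, l1_hi) - min(us, l1_lo)
      cnt <- table(factor(mem$sample, levels = samples))
      loci[[length(loci) + 1L]] <- data.frame(
        element_id = el$id, chrom = el$chrom,
        start = min(us, l1_lo), end = max(ue, l1_hi),
        transcript_strand = tstrand,
        unique_start = us, unique_end = ue, unique_length = ue - us,
        r1r2_distance = d, total_size = tot,
        n_reads = nrow(mem), stringsAsFactors = FALSE)
      counts[[length(counts) + 1L]] <- as.integer(cnt)
    }
  }
  loci <- do.call(rbind, loci)
  cm <- do.call(rbind, counts)
  colnames(cm) <- samples
  ord <- order(loci$chrom, loci$start, loci$element_id)
  loci <- loci[ord, , drop = FALSE]
  cm <- cm[ord, , drop = FALSE]
  loci <- cbind(id = sprintf("LCTloc_%04d", seq_len(nrow(loci))), loci,
                stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  rownames(cm) <- loci$id
  list(loci = loci, counts = cm)
}

#' Detect L1 chimeric read pairs and assemble LCT loci
#'
#' The tested reference path of the finder. Read pairs are consumed as a
#' normalised alignment table (mate 1 = transcript-sense read, mate 2 =
#' its partner) plus the mate-1 sequences. A pair becomes a chimeric
#' candidate when (i) mate 1 aligns over an annotated L1 element and its
#' sequence carries a gapless match of at least `min_l1` bp with at most
#' `max_mm` substitutions against the L1 5' reference set, and (ii) mate
#' 2 contains a repeat-free stretch of at least `min_unique` bp.
#' Candidates then pass the orientation / 5' UTR / insert filters of
#' [pair_to_candidate()] and are clustered into loci with
#' [cluster_candidates()]. The element of record is the element
#' overlapping the mate-1 alignment (ties by largest overlap), which
#' resolves multi-mapping between near-identical L1 copies; the sequence
#' matcher acts as the L1-evidence gate.
#'
#' @param r1_seqs mate-1 sequences, a [Biostrings::DNAStringSet] named by
#'   read id (per-sample list entries are combined by name).
#' @param alignments data.frame with `sample`, `read_id`, `mate`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @param elements full element table ([select_asp_l1()] schema, but
#'   including non-ASP rows when available so 5' UTR rejections can be
#'   recorded).
#' @param reference L1 5' reference [Biostrings::DNAStringSet].
#' @param repeats repeat annotation for the unique-side subtraction
#'   (data.frame or GRanges).
#' @param min_l1,max_mm,min_unique,max_insert,merge_gap selection
#'   thresholds; defaults 50 bp, 1 mismatch, 30 bp, 50 kb, 300 bp.
#' @return list with `loci` and `counts` (see [cluster_candidates()]),
#'   `candidates` (accepted pair table), `rejects` (rejected candidates
#'   with `reason`) and `summary` (filter accounting: total candidates,
#'   rejections by reason, retained).
#' @export
find_chimeras <- function(r1_seqs, alignments, elements, reference,
                          repeats, min_l1 = 50L, max_mm = 1L,
                          min_unique = 30L, max_insert = 50000L,
                          merge_gap = 300L) {
  .assert_cols(alignments, c("sample", "read_id", "mate", "chrom",
                             "start", "end", "strand"),
               "alignment table")
  if (is.list(r1_seqs) && !is(r1_seqs, "DNAStringSet"))
    r1_seqs <- do.call(c, unname(r1_seqs))
  a1 <- alignments[alignments$mate == 1L, , drop = FALSE]
  a2 <- alignments[alignments$mate == 2L, , drop = FALSE]
  a2 <- a2[match(a1$read_id, a2$read_id), , drop = FALSE]

  # element of record: the element overlapping the mate-1 alignment
  el_gr <- .gr0(elements)
  r1_gr <- .gr0(a1)
  ov <- GenomicRanges::findOverlaps(r1_gr, el_gr, ignore.strand = TRUE)
  if (length(ov)) {
    ovw <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(r1_gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(el_gr)[S4Vectors::subjectHits(ov)]))
    best <- tapply(seq_along(ovw), S4Vectors::queryHits(ov),
                   function(i) i[which.max(ovw[i])])
    ov <- ov[unlist(best)]
  }
  el_of <- rep(NA_integer_, nrow(a1))
  el_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  on_l1 <- which(!is.na(el_of))
  if (!length(on_l1)) {
    return(list(loci = data.frame(), counts = matrix(0L, 0, 0),
                candidates = data.frame(), rejects = data.frame(),
                summary = list(pairs_on_l1 = 0L, candidates = 0L,
                               rejected = c(), retained = 0L)))
  }

  # L1-evidence gate: sequence match against the 5' reference set
  seqs <- r1_seqs[a1$read_id[on_l1]]
  m <- match_read_to_l1(seqs, reference, min_len = min_l1,
                        max_mm = max_mm)
  gated <- on_l1[!is.na(m$element_id)]

  rep_gr <- if (is(repeats, "GRanges")) repeats else .gr0(repeats)
  uniq <- .unique_segments(a2[gated, , drop = FALSE], rep_gr,
                           min_unique = min_unique)
  has_uniq <- !is.na(uniq$start)
  idx <- gated[has_uniq]          # chimeric candidates
  uniq <- uniq[has_uniq, , drop = FALSE]
  el <- elements[el_of[idx], , drop = FALSE]
  orient <- ifelse(a1$strand[idx] == el$strand, "sense", "antisense")
  gap <- pmax(0L, pmax(uniq$start - el$end, el$start - uniq$end))
  reason <- rep(NA_character_, length(idx))
  reason[orient == "sense"] <- "same_orientation"
  r <- is.na(reason) & !el$has_asp
  reason[r] <- "no_5utr"
  r <- is.na(reason) & uniq$chrom != el$chrom
  reason[r] <- "insert_undefined"
  r <- is.na(reason) & gap > max_insert
  reason[r] <- "insert_too_large"
  ok <- is.na(reason)
  candidates <- data.frame(
    element_id = el$id[ok], chrom = el$chrom[ok],
    unique_start = uniq$start[ok], unique_end = uniq$end[ok],
    transcript_strand = ifelse(el$strand[ok] == "+", "-", "+"),
    sample = a1$sample[idx[ok]], read_id = a1$read_id[idx[ok]],
    r1_start = a1$start[idx[ok]], r1_end = a1$end[idx[ok]],
    stringsAsFactors = FALSE)
  rejects <- data.frame(
    sample = a1$sample[idx[!ok]], read_id = a1$read_id[idx[!ok]],
    element_id = el$id[!ok], reason = reason[!ok],
    stringsAsFactors = FALSE)
  cl <- cluster_candidates(candidates, elements, merge_gap = merge_gap)
  n_cand <- nrow(candidates) + nrow(rejects)
  list(loci = cl$loci, counts = cl$counts, candidates = candidates,
       rejects = rejects,
       summary = list(
         pairs_on_l1 = length(on_l1), candidates = n_cand,
         rejected = table(rejects$reason),
         retained = nrow(candidates)))
}

#' Pool per-sample locus sets
#'
#' Union of LCT loci across samples, keyed by element and merged unique
#' interval: the per-sample loci are re-clustered jointly, so pooling is
#' associative and commutative.
#'
#' @param locus_sets list of [cluster_candidates()] results (one per
#'   sample or per-sample subset).
#' @param elements element table.
#' @param merge_gap merge distance in bp.
#' @return a [cluster_candidates()]-shaped list for the pooled set.
#' @export
pool_samples <- function(locus_sets, elements, merge_gap = 300L) {
  cand <- do.call(rbind, lapply(locus_sets, function(x) {
    if (is.null(x$loci) || nrow(x$loci) == 0L) return(NULL)
    cnt <- x$counts
    do.call(rbind, lapply(colnames(cnt), function(sm) {
      keep <- cnt[, sm] > 0L
      if (!any(keep)) return(NULL)
      lo <- x$loci[keep, , drop = FALSE]
      lo <- lo[rep(seq_len(nrow(lo)), cnt[keep, sm]), , drop = FALSE]
      data.frame(element_id = lo$element_id, chrom = lo$chrom,
                 unique_start = lo$unique_start,
                 unique_end = lo$unique_end,
                 transcript_strand = lo$transcript_strand, sample = sm,
                 stringsAsFactors = FALSE)
    }))
  }))
  cluster_candidates(cand, elements, merge_gap = merge_gap)
}

#' LCT saturation curve over pooled samples
#'
#' Mean number of distinct LCT loci recovered when pooling the first `k`
#' samples, averaged over random sample orderings. The expected curve is
#' non-decreasing in `k`.
#'
#' @param locus_sets named list of per-sample [cluster_candidates()]
#'   results.
#' @param elements element table.
#' @param n_perm number of random orderings.
#' @param seed RNG seed.
#' @param merge_gap merge distance in bp.
#' @return data.frame with `k` and `mean_loci`.
#' @export
saturation_curve <- function(locus_sets, elements, n_perm = 20L,
                             seed = 1L, merge_gap = 300L) {
  K <- length(locus_sets)
  set.seed(seed)
  acc <- matrix(0, n_perm, K)
  for (p in seq_len(n_perm)) {
    ord <- sample(K)
    for (k in seq_len(K)) {
      pooled <- pool_samples(locus_sets[ord[seq_len(k)]], elements,
                             merge_gap = merge_gap)
      acc[p, k] <- if (is.null(pooled$loci)) 0L else nrow(pooled$loci)
    }
  }
  data.frame(k = seq_len(K), mean_loci = colMeans(acc))
}

#' Overlap LCT-producing elements with known loci
#'
#' @param loci locus table (needs `element_id`).
#' @param elements element table with genomic spans.
#' @param known known loci: a BED path, data.frame (`chrom`, `start`,
#'   `end`, 0-based) or [GenomicRanges::GRanges].
#' @return list with `count` (number of LCT-producing elements whose span
#'   intersects a known locus) and `matched_ids`.
#' @export
compare_to_known_loci <- function(loci, elements, known) {
  if (is.character(known)) known <- rtracklayer::import(known)
  known_gr <- if (is(known, "GRanges")) known else .gr0(known)
  ids <- unique(loci$element_id)
  el <- elements[elements$id %in% ids, , drop = FALSE]
  if (!nrow(el) || !length(known_gr))
    return(list(count = 0L, matched_ids = character()))
  hit <- GenomicRanges::countOverlaps(.gr0(el), known_gr,
                                      ignore.strand = TRUE) > 0L
  list(count = sum(hit), matched_ids = el$id[hit])
}
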