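#' Classify the 5' splice status of LCT loci
#'
#' Applies the three-rule classifier. A locus is called `spliced` when any
#' single rule fires: (1) distance — the strand-aware gap between the L1
#' side and the unique sequence exceeds 500 bp; (2) size — the locus
#' spans more than 1000 bp and its unique sequence is very large
#' (> 700 bp, the signature of concatenated reads bridging a splice);
#' (3) junction — a splice junction falls within 200 bp of the L1 element
#' start. Loci with a distance of 200-499 bp and a size of 600-999 bp are
#' `undetermined`; everything else is `unspliced`. Rule evaluation is
#' order-independent; precedence is spliced > undetermined > unspliced.
#' Loci with a distance of 1-199 bp and a size of 600-999 bp fall outside
#' the stated rules; they are called `unspliced` and flagged in the
#' `gray_zone` column.
#'
#' @param loci locus table with `r1r2_distance`, `total_size`,
#'   `unique_length`, `chrom`, `element_id`, `transcript_strand`.
#' @param elements element table (for the L1 start positions used by the
#'   junction rule); the element "start" is its strand-aware 5' end.
#' @param junctions splice junction table: data.frame with `chrom`,
#'   `start`, `end` (0-based; each endpoint is a junction boundary), a
#'   BED path, or `NULL`/empty for no junction evidence.
#' @param distance_cutoff,size_cutoff,unique_cutoff,junction_window rule
#'   parameters (defaults 500, 1000, 700, 200 bp).
#' @return `loci` with added columns `splice_status`
#'   (`spliced`/`undetermined`/`unspliced`), `splice_rules`
#'   (comma-separated fired rules among `distance`, `size`, `junction`)
#'   and `gray_zone`.
#' @export
splice_status <- function(loci, elements, junctions = NULL,
                          distance_cutoff = 500L, size_cutoff = 1000L,
                          unique_cutoff = 700L, junction_window = 200L) {
  .assert_cols(loci, c("r1r2_distance", "total_size", "unique_length",
                       "chrom", "element_id"), "locus table")
  if (any(is.na(loci$r1r2_distance)) || any(is.na(loci$total_size)))
    stop("locus table has missing r1r2_distance/total_size values",
         call. = FALSE)
  if (is.character(junctions)) {
    junctions <- .df0(as(rtracklayer::import(junctions), "GRanges"))
  }
  el <- elements[match(loci$element_id, elements$id), ]
  l1_start <- ifelse(el$strand == "+", el$start, el$end - 1L)

  r_dist <- loci$r1r2_distance > distance_cutoff
  r_size <- loci$total_size > size_cutoff &
    loci$unique_length > unique_cutoff
  r_junc <- rep(FALSE, nrow(loci))
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    jpos <- data.frame(chrom = rep(junctions$chrom, 2L),
                       pos = c(junctions$start, junctions$end))
    for (i in seq_len(nrow(loci))) {
      r_junc[i] <- any(jpos$chrom == loci$chrom[i] &
                         abs(jpos$pos - l1_start[i]) <= junction_window)
    }
  }
  spliced <- r_dist | r_size | r_junc
  undet <- !spliced &
    loci$r1r2_distance >= 200L & loci$r1r2_distance <= 499L &
    loci$total_size >= 600L & loci$total_size <= 999L
  gray <- !spliced & !undet &
    loci$r1r2_distance >= 1L & loci$r1r2_distance <= 199L &
    loci$total_size >= 600L & loci$total_size <= 999L
  loci$splice_status <- ifelse(spliced, "spliced",
                               ifelse(undet, "undetermined", "unspliced"))
  rules <- cbind(distance = r_dist, size = r_size, junction = r_junc)
  loci$splice_rules <- apply(rules, 1L, function(x)
    paste(colnames(rules)[x], collapse = ","))
  loci$gray_zone <- gray
  loci
}

#' Annotate LCT loci with their genic context
#'
#' A locus is intragenic when its L1 element overlaps a gene body
#' (transcript span, not exons). Orientation compares the LCT transcript
#' strand with the host gene strand; when several genes overlap, all
#' hosts are recorded and the summary orientation is taken from the gene
#' with the largest overlap.
#'
#' @param loci locus table with `element_id`, `transcript_strand`.
#' @param elements element table.
#' @param genes gene models: a GTF path, a data.frame (`gene_id`,
#'   `chrom`, `start`, `end`, `strand`, 0-based half-open) or a
#'   [GenomicRanges::GRanges] with a `gene_id` column. Strandless gene
#'   rows are an error.
#' @return list with `loci` (adds `genic_context` =
#'   `intragenic_sense`/`intragenic_antisense`/`intergenic`, `host_genes`
#'   comma-separated), and `summary` (`fraction_intragenic`,
#'   `fraction_antisense_intragenic`, `genes_per_lct` histogram of
#'   LCT-producing elements per host gene).
#' @export
genic_context <- function(loci, elements, genes) {
  if (is.character(genes)) {
    g <- rtracklayer::import(genes)
    g <- g[g$type == "gene"]
    genes <- cbind(.df0(g), gene_id = g$gene_id)
  } else if (is(genes, "GRanges")) {
    genes <- cbind(.df0(genes), gene_id = genes$gene_id)
  }
  .assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"),
               "gene table")
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene rows must be stranded (+/-)", call. = FALSE)
  el <- elements[match(loci$element_id, elements$id), ]
  el_gr <- .gr0(el)
  gene_gr <- .gr0(genes)
  ov <- GenomicRanges::findOverlaps(el_gr, gene_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  ovw <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(el_gr)[q], IRanges::ranges(gene_gr)[s]))

  ctx <- rep("intergenic", nrow(loci))
  hosts <- rep("", nrow(loci))
  for (i in unique(q)) {
    hits <- which(q == i)
    hosts[i] <- paste(genes$gene_id[s[hits]], collapse = ",")
    primary <- s[hits[which.max(ovw[hits])]]
    same <- loci$transcript_strand[i] == genes$strand[primary]
    ctx[i] <- if (same) "intragenic_sense" else "intragenic_antisense"
  }
  loci$genic_context <- ctx
  loci$host_genes <- hosts
  intra <- ctx != "intergenic"
  per_gene <- if (any(intra)) {
    pairs <- unique(do.call(rbind, lapply(which(intra), function(i)
      data.frame(gene = strsplit(hosts[i], ",")[[1L]],
                 element = loci$element_id[i],
                 stringsAsFactors = FALSE))))
    table(table(pairs$gene))
  } else table(integer())
  list(loci = loci,
       summary = list(
         fraction_intragenic = mean(intra),
         fraction_antisense_intragenic =
           if (any(intra)) mean(ctx[intra] == "intragenic_antisense")
           else NA_real_,
         genes_per_lct = per_gene))
}

#' Exact two-sided binomial enrichment test
#'
#' Tests whether `k` successes out of `n` depart from a background
#' fraction `p0`, summing the probabilities of all outcomes no more
#' likely than the observed one.
#'
#' @param k,n observed count and total.
#' @param p0 background fraction in (0, 1).
#' @return two-sided p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 1 || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("background fraction p0 must lie in (0, 1)", call. = FALSE)
  binom.test(k, n, p = p0)$p.value
}

#' Classify 5' walking-PCR amplification patterns
#'
#' Interprets the three-primer walking assay over the L1 5' UTR: a
#' common primer downstream of both ASP regions, a primer between the
#' +200 and +450 regions ("downstream") and a primer upstream of +450
#' ("upstream"), each combined with the LCT-specific unique-sequence
#' primer. Amplification with the common and downstream primers but not
#' the upstream primer places the TSS in the classical +450 ASP region;
#' amplification with the common primer only places it in the +200
#' region; amplification with all three means the transcript initiates
#' upstream of both ASP regions and is not an LCT. Any upstream-primer
#' amplification is read as initiation beyond the ASP regions. Patterns
#' with no common-primer amplification are unevaluable and flagged.
#'
#' @param patterns data.frame with logical columns `common`,
#'   `downstream`, `upstream` (and optionally `id`, `subfamily`).
#' @return `patterns` with added `status` (`ASP450`, `ASP200`, `NO_LCT`,
#'   `undetermined`) and `is_lct`.
#' @export
walking_classify <- function(patterns) {
  .assert_cols(patterns, c("common", "downstream", "upstream"),
               "walking pattern table")
  st <- with(patterns, ifelse(!common, "undetermined",
             ifelse(upstream, "NO_LCT",
             ifelse(downstream, "ASP450", "ASP200"))))
  patterns$status <- st
  patterns$is_lct <- st %in% c("ASP450", "ASP200")
  if (any(st == "undetermined"))
    warning(sum(st == "undetermined"),
            " pattern(s) without common-primer amplification are ",
            "unevaluable", call. = FALSE)
  patterns
}

#' Summarise walking-PCR calls by subfamily
#'
#' @param classified output of [walking_classify()] with a `subfamily`
#'   column.
#' @param exclude subfamilies excluded from the percentage (default
#'   `L1PA8`, whose chimeras initiate upstream of the ASP).
#' @return list with `by_status` (status x subfamily table) and
#'   `pct_lct` (percentage of LCT calls among non-excluded, evaluable
#'   chimeras).
#' @export
walking_summary <- function(classified, exclude = "L1PA8") {
  keep <- !(classified$subfamily %in% exclude) &
    classified$status != "undetermined"
  list(by_status = table(classified$status, classified$subfamily),
       pct_lct = 100 * sum(classified$is_lct[keep]) / sum(keep))
}

#' Classify LCT polyadenylation status from RT-condition amplification
#'
#' Each LCT is tested for amplification in cDNA primed three ways:
#' random hexamers (detection control), oligo-dT (polyA-dependent), and
#' oligo-dA after polyU tailing (polyA-independent). An LCT amplifying
#' with oligo-dT is polyadenylated; one failing oligo-dT but amplifying
#' after polyU tailing is non-polyadenylated; one failing both tailing
#' conditions is undetermined (the oligo-dT failure may reflect
#' inefficient long-range reverse transcription). The bounds on the
#' number of non-polyA transcripts are `min_nonpolyA` (confirmed
#' non-polyA) and `max_nonpolyA` (all oligo-dT failures). LCTs without
#' random-hexamer amplification are unevaluable and excluded from the
#' denominators.
#'
#' @param patterns data.frame with logical columns `random_hexamer`,
#'   `oligodT`, `polyU_oligodA` (and optionally `id`).
#' @return list with `patterns` (adds `polya_status`), `min_nonpolyA`,
#'   `max_nonpolyA`, `n_evaluable`.
#' @export
polya_classify <- function(patterns) {
  .assert_cols(patterns, c("random_hexamer", "oligodT", "polyU_oligodA"),
               "polyA pattern table")
  ev <- patterns$random_hexamer
  if (any(!ev))
    warning(sum(!ev), " pattern(s) without random-hexamer amplification ",
            "excluded from the denominators", call. = FALSE)
  st <- ifelse(!ev, "unevaluable",
        ifelse(patterns$oligodT, "polyA",
        ifelse(patterns$polyU_oligodA, "non_polyA", "undetermined")))
  patterns$polya_status <- st
  list(patterns = patterns,
       min_nonpolyA = sum(st == "non_polyA"),
       max_nonpolyA = sum(ev & !patterns$oligodT),
       n_evaluable = sum(ev))
}
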