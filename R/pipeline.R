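#' Run the full LCT pipeline on a simulated study
#'
#' Orchestrates the stages end to end on a synthetic study: genome and
#' truth generation, L1 reference construction, chimera detection and
#' clustering, locus annotation (splice status, genic context), long-read
#' TSS mapping, read-count deregulation prediction (Hedges' g), qAMP
#' methylation indices with expression correlation, and the chromatin
#' metaprofile contrast. Every stage writes TSV outputs plus a JSON
#' summary with the filter accounting (candidates, rejections by reason,
#' retained), and reruns with the same configuration are byte-identical.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param outdir output directory (created); `NULL` keeps everything in
#'   memory.
#' @param stages subset of
#'   `c("annotate", "tss", "diffexpr", "methylation", "chromatin",
#'   "report")` to run after the core simulate/reference/chimeras stages;
#'   default all.
#' @param thresholds named list overriding detection thresholds
#'   (`min_l1`, `max_mm`, `min_unique`, `max_insert`, `merge_gap`,
#'   `g_cutoff`, `min_mapq`).
#' @return list of class `lct_run` with the per-stage results and the
#'   resolved parameter set.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         stages = c("annotate", "tss", "diffexpr",
                                    "methylation", "chromatin",
                                    "report"),
                         thresholds = list()) {
  par <- utils::modifyList(list(min_l1 = 50L, max_mm = 1L,
                                min_unique = 30L, max_insert = 50000L,
                                merge_gap = 300L, g_cutoff = 1,
                                min_mapq = 30L), thresholds)
  tsv <- function(df, f) if (!is.null(outdir))
    write.table(df, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- simulate_genome(config, outdir = outdir)
  reads <- simulate_reads(truth, config)
  ref <- build_l1_reference(
    read_rmsk_df(truth$rmsk), truth$genome,
    out_fasta = if (!is.null(outdir)) file.path(outdir, "l1_ref.fa"),
    out_table = if (!is.null(outdir)) file.path(outdir,
                                                "l1_elements.tsv"))
  r1 <- do.call(c, unname(lapply(reads$reads, `[[`, "R1")))
  fc <- find_chimeras(r1, reads$alignments, truth$elements,
                      ref$sequences, .rmsk_to_records(truth$rmsk),
                      min_l1 = par$min_l1, max_mm = par$max_mm,
                      min_unique = par$min_unique,
                      max_insert = par$max_insert,
                      merge_gap = par$merge_gap)
  tsv(fc$loci, "lct_loci.tsv")
  tsv(fc$rejects, "rejected_candidates.tsv")
  if (!is.null(outdir) && nrow(fc$loci))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t0\t%s", fc$loci$chrom,
                       fc$loci$start, fc$loci$end, fc$loci$id,
                       fc$loci$n_reads, fc$loci$transcript_strand),
               file.path(outdir, "lct_loci.bed"))

  res <- list(config = config, parameters = par, truth = truth,
              reference = ref, chimeras = fc)

  if ("annotate" %in% stages && nrow(fc$loci)) {
    junc <- .sim_junctions(truth)
    ann <- splice_status(fc$loci, truth$elements, junc)
    gc <- genic_context(ann, truth$elements, truth$genes)
    res$annotation <- gc
    tsv(gc$loci, "lct_annotated.tsv")
  }
  if ("tss" %in% stages && nrow(fc$loci)) {
    lr <- simulate_longreads(truth, config)
    lct_el <- truth$elements[truth$elements$id %in% fc$loci$element_id, ]
    filt <- filter_chimeric_longreads(lr$alignments, lct_el,
                                      min_mapq = par$min_mapq)
    prof <- tss_profiles(filt, truth$elements)
    res$tss <- if (nrow(prof))
      tss_summary(prof, all_elements = lct_el$id) else NULL
    tsv(prof, "tss_offsets.tsv")
  }
  if ("diffexpr" %in% stages && nrow(fc$loci)) {
    grp <- setNames(truth$samples$group, truth$samples$sample)
    cm <- fc$counts
    miss <- setdiff(names(grp), colnames(cm))
    if (length(miss)) {
      cm <- cbind(cm, matrix(0L, nrow(cm), length(miss),
                             dimnames = list(NULL, miss)))
    }
    g <- apply(cm, 1L, function(v)
      hedges_g(v[grp[colnames(cm)] == "control"],
               v[grp[colnames(cm)] == "tumor"]))
    de <- data.frame(id = rownames(cm), g = g,
                     call = classify_deregulation(g, par$g_cutoff),
                     stringsAsFactors = FALSE)
    res$diffexpr <- de
    tsv(de, "deregulation.tsv")
  }
  if ("methylation" %in% stages && nrow(truth$lcts)) {
    qa <- simulate_qamp(truth, config)
    qi <- qamp_index(qa)
    res$methylation <- qi
    tsv(qi, "methylation_index.tsv")
  }
  if ("chromatin" %in% stages && nrow(fc$loci)) {
    track <- simulate_coverage(truth, config,
                               outfile = if (!is.null(outdir))
                                 file.path(outdir, "h3k36me3.bedgraph"))
    pos <- truth$elements[truth$elements$id %in%
                            truth$lcts$element_id, ]
    neg <- truth$elements[!truth$elements$id %in%
                            truth$lcts$element_id, ]
    if (nrow(pos) && nrow(neg))
      res$chromatin <- profile_contrast(track, pos, neg)
  }

  res$summary <- list(
    seed = config$seed, parameters = par,
    n_elements = nrow(truth$elements),
    n_asp_elements = sum(truth$elements$has_asp),
    n_planted_lcts = nrow(truth$lcts),
    candidates = fc$summary$candidates,
    rejected = as.list(fc$summary$rejected),
    retained = fc$summary$retained,
    n_loci = if (is.null(fc$loci) || !nrow(fc$loci)) 0L
             else nrow(fc$loci))
  if (!is.null(outdir))
    jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  class(res) <- "lct_run"
  if ("report" %in% stages) {
    res$report <- make_report(res)
    if (!is.null(outdir))
      writeLines(res$report, file.path(outdir, "report.md"))
  }
  res
}

# splice-junction table from the planted spliced LCTs (intron endpoints)
.sim_junctions <- function(truth) {
  sp <- truth$lcts[truth$lcts$spliced, , drop = FALSE]
  if (!nrow(sp)) return(NULL)
  js <- ifelse(sp$element_strand == "+", sp$unique_end,
               sp$element_end)
  je <- ifelse(sp$element_strand == "+", sp$element_start,
               sp$unique_start)
  data.frame(chrom = sp$chrom, start = pmin(js, je),
             end = pmax(js, je), stringsAsFactors = FALSE)
}

# convert simulator rmsk rows into the normalised record schema that
# select_asp_l1 consumes (same normalisation as read_rmsk)
.rmsk_to_records <- function(rmsk) {
  data.frame(
    chrom = rmsk$genoName, start = rmsk$genoStart, end = rmsk$genoEnd,
    strand = rmsk$strand, rep_name = rmsk$repName,
    rep_class = rmsk$repClass,
    consensus_5p_offset = as.integer(
      ifelse(rmsk$strand == "+", rmsk$repStart, abs(rmsk$repLeft))),
    consensus_end = as.integer(rmsk$repEnd),
    stringsAsFactors = FALSE)
}

#' Normalise an in-memory UCSC rmsk data.frame
#'
#' Same normalisation as [read_rmsk()] for tables already loaded (e.g.
#' the simulator's `truth$rmsk`).
#'
#' @param rmsk data.frame with UCSC rmsk columns.
#' @return normalised record data.frame (see [read_rmsk()]).
#' @export
read_rmsk_df <- function(rmsk) .rmsk_to_records(rmsk)

#' Render a run report
#'
#' Markdown summary of a pipeline run: detection accounting, subfamily
#' breakdown, splice/polyA/genic summaries, deregulation calls and the
#' TSS window fractions. Deterministic given the run object.
#'
#' @param run an `lct_run` from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
make_report <- function(run) {
  s <- run$summary
  lines <- c("# LCT pipeline report", "",
             sprintf("- seed: %d", s$seed),
             sprintf("- L1 elements: %d (ASP-competent: %d)",
                     s$n_elements, s$n_asp_elements),
             sprintf("- planted LCTs: %d", s$n_planted_lcts),
             sprintf("- chimeric candidates: %d", s$candidates),
             sprintf("- retained after filters: %d", s$retained),
             sprintf("- LCT loci: %d", s$n_loci), "")
  if (length(s$rejected))
    lines <- c(lines, "## Rejections",
               sprintf("- %s: %d", names(s$rejected),
                       unlist(s$rejected)), "")
  loci <- run$chimeras$loci
  if (!is.null(loci) && nrow(loci)) {
    el <- run$truth$elements
    sf <- subfamily_counts(el[match(unique(loci$element_id), el$id), ])
    lines <- c(lines, "## LCT loci by subfamily",
               sprintf("- %s: %d", sf$subfamily, sf$count), "")
  }
  if (!is.null(run$annotation)) {
    a <- run$annotation
    lines <- c(lines, "## Annotation",
               sprintf("- intragenic fraction: %.3f",
                       a$summary$fraction_intragenic),
               sprintf("- spliced: %d / %d",
                       sum(a$loci$splice_status == "spliced"),
                       nrow(a$loci)), "")
  }
  if (!is.null(run$diffexpr)) {
    tb <- table(run$diffexpr$call)
    lines <- c(lines, "## Deregulation calls",
               sprintf("- %s: %d", names(tb), as.integer(tb)), "")
  }
  if (!is.null(run$tss)) {
    fr <- run$tss$fractions
    lines <- c(lines, "## TSS windows",
               sprintf("- elements with a TSS in 0-500 bp: %.1f%%",
                       100 * fr[["asp_0_500"]]),
               sprintf("- elements with a TSS in 0-900 bp: %.1f%%",
                       100 * fr[["utr_0_900"]]), "")
  }
  lines
}
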