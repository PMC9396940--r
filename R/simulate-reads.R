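# outer genomic span of a transcript-coordinate interval (long reads span
# introns in a single alignment record)
.map_span <- function(tx, a, b) {
  widths <- tx$blocks$end - tx$blocks$start
  offs <- cumsum(c(0, widths))
  gs <- Inf; ge <- -Inf
  for (i in seq_len(nrow(tx$blocks))) {
    lo <- max(a, offs[i]); hi <- min(b, offs[i + 1])
    if (lo >= hi) next
    if (tx$strand == "+") {
      s <- tx$blocks$start[i] + (lo - offs[i]); e <- s + (hi - lo)
    } else {
      e <- tx$blocks$end[i] - (lo - offs[i]); s <- e - (hi - lo)
    }
    gs <- min(gs, s); ge <- max(ge, e)
  }
  c(gs, ge)
}

#' Simulate stranded paired-end reads
#'
#' Draws sequencing fragments from every planted transcript (LCTs and
#' host genes) with group-specific abundances, uniform insert lengths on
#' the configured range, and per-base substitution errors. Read 1 carries
#' the fragment end nearer the transcript 5' end (the strandedness
#' convention of the library; read 1 is transcript-sense). Alongside the
#' read sequences an error-free truth alignment table records the primary
#' genomic placement of each mate, which downstream stages consume in
#' place of a spliced aligner.
#'
#' @param truth a [simulate_genome()] result.
#' @param config the [sim_config()] used for the genome (defaults to
#'   `truth$config`).
#' @param outdir optional directory for per-sample FASTQ pairs
#'   (`<sample>_R1.fastq`/`_R2.fastq`) and `alignments.tsv`.
#' @return list of class `lct_sim_reads` with `reads` (per sample, `R1`
#'   and `R2` [Biostrings::DNAStringSet]s named by read id), `alignments`
#'   (data.frame: `sample`, `read_id`, `mate`, `chrom`, `start`, `end`,
#'   `strand`, `origin`) and `counts` (planted fragment-count matrix,
#'   transcripts x samples, LCT rows first).
#' @export
simulate_reads <- function(truth, config = truth$config, outdir = NULL) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 1000L)
  txs <- .sim_transcripts(truth)
  seqs <- lapply(txs, .transcript_seq, genome = truth$genome)
  rl <- config$read_length
  lct_ids <- truth$lcts$lct_id
  ids <- names(txs)
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(truth$samples),
                   dimnames = list(ids, truth$samples$sample))
  reads <- list(); aln <- list()
  for (si in seq_len(nrow(truth$samples))) {
    sm <- truth$samples$sample[si]; grp <- truth$samples$group[si]
    r1 <- list(); r2 <- list(); nm <- list()
    arows <- list(); k <- 0L
    for (tx_id in ids) {
      tx <- txs[[tx_id]]
      lam <- if (tx$type == "lct") {
        row <- match(tx_id, lct_ids)
        if (grp == "tumor") truth$lcts$lambda_tumor[row]
        else truth$lcts$lambda_control[row]
      } else config$base_gene_frags
      n <- rpois(1L, lam)
      counts[tx_id, sm] <- n
      if (n == 0L) next
      s <- seqs[[tx_id]]; tlen <- nchar(s)
      for (f in seq_len(n)) {
        k <- k + 1L
        ins <- sample(config$insert_range[1]:config$insert_range[2], 1L)
        if (ins >= tlen) { ins <- tlen; a <- 0L }
        else a <- sample(0:(tlen - ins), 1L)
        r1len <- min(rl, ins); r2len <- min(rl, ins)
        sq1 <- substr(s, a + 1L, a + r1len)
        sq2 <- .revcomp_chr(substr(s, a + ins - r2len + 1L, a + ins))
        if (config$error_rate > 0) {
          sq1 <- .mutate_dna(sq1, config$error_rate)
          sq2 <- .mutate_dna(sq2, config$error_rate)
        }
        rid <- sprintf("%s_f%06d", sm, k)
        r1[[k]] <- sq1; r2[[k]] <- sq2; nm[[k]] <- rid
        g1 <- .map_to_genome(tx, a, a + r1len)
        g2 <- .map_to_genome(tx, a + ins - r2len, a + ins)
        arows[[length(arows) + 1L]] <- data.frame(
          sample = sm, read_id = rid, mate = c(1L, 2L),
          chrom = tx$chrom,
          start = c(g1[1], g2[1]), end = c(g1[2], g2[2]),
          strand = c(tx$strand, if (tx$strand == "+") "-" else "+"),
          origin = tx_id, stringsAsFactors = FALSE)
      }
    }
    r1 <- unlist(r1); r2 <- unlist(r2); nm <- unlist(nm)
    R1 <- Biostrings::DNAStringSet(r1); names(R1) <- nm
    R2 <- Biostrings::DNAStringSet(r2); names(R2) <- nm
    reads[[sm]] <- list(R1 = R1, R2 = R2)
    aln[[sm]] <- do.call(rbind, arows)
  }
  alignments <- do.call(rbind, aln)
  rownames(alignments) <- NULL
  out <- list(reads = reads, alignments = alignments, counts = counts)
  class(out) <- "lct_sim_reads"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sm in names(reads)) {
      for (m in c("R1", "R2")) {
        x <- reads[[sm]][[m]]
        q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
          paste(rep("I", w), collapse = ""), character(1)))
        Biostrings::writeXStringSet(
          x, file.path(outdir, sprintf("%s_%s.fastq", sm, m)),
          format = "fastq", qualities = q)
      }
    }
    write.table(alignments, file.path(outdir, "alignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate long-read alignments over LCT transcripts
#'
#' Emulates the post-alignment product of full-length cDNA long-read
#' sequencing: one genomic record per read (`chrom`, `start`, `end`,
#' `strand`, `mapq`), spanning the transcript from its TSS (with optional
#' 5' loss) to its 3' end. A configurable fraction of reads receives
#' MapQ < 30 and a configurable fraction of LCTs is absent altogether.
#'
#' @inheritParams simulate_reads
#' @return list with `alignments` (`chrom`, `start`, `end`, `strand`,
#'   `mapq`, `read_id`) and `truth` (adds `lct_id`, `element_id`,
#'   `loss_5p` and the per-read `true_tss_offset` after loss).
#' @export
simulate_longreads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 2000L)
  txs <- .sim_transcripts(truth)
  lc <- truth$lcts
  n_lct <- nrow(lc)
  missing <- if (n_lct)
    runif(n_lct) < config$lr_missing_frac else logical(0)
  rows <- list()
  for (j in seq_len(n_lct)) {
    if (missing[j]) next
    n <- rpois(1L, config$lr_per_lct)
    if (n == 0L) next
    tx <- txs[[lc$lct_id[j]]]
    tlen <- sum(tx$blocks$end - tx$blocks$start)
    for (r in seq_len(n)) {
      loss <- if (runif(1) < config$lr_5p_loss_prob)
        min(round(rexp(1, 1 / config$lr_5p_loss_mean)), tlen - 50L) else 0L
      g <- .map_span(tx, loss, tlen)
      mapq <- if (runif(1) < config$lr_low_mapq_frac) sample(0:29, 1L)
              else sample(30:60, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = g[1], end = g[2], strand = tx$strand,
        mapq = mapq,
        read_id = sprintf("lr_%s_%03d", lc$lct_id[j], r),
        lct_id = lc$lct_id[j], element_id = lc$element_id[j],
        loss_5p = loss, true_tss_offset = lc$tss_offset[j] - loss,
        stringsAsFactors = FALSE)
    }
  }
  full <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mapq = integer(),
               read_id = character(), lct_id = character(),
               element_id = character(), loss_5p = integer(),
               true_tss_offset = integer(), stringsAsFactors = FALSE)
  rownames(full) <- NULL
  list(alignments = full[, c("chrom", "start", "end", "strand", "mapq",
                             "read_id")],
       truth = full, missing_lcts = lc$lct_id[missing])
}

# one reported Ct: mean of n technical wells; Inf encodes no amplification
.ct_measure <- function(true_ct, sd, nrep) {
  if (is.infinite(true_ct)) return(Inf)
  mean(true_ct + rnorm(nrep, 0, sd))
}

#' Simulate qPCR cycle-threshold tables
#'
#' Ct values follow `Ct = baseline - log_E(abundance) + noise`, with the
#' reported Ct the mean of `n_tech_rep` technical wells and two
#' independent reverse-transcription replicates per sample. Housekeeping
#' targets (TBP, RPL13A, PPIA) have unit abundance in every sample; LCT
#' targets scale with the planted group means plus biological log-normal
#' variation.
#'
#' @inheritParams simulate_reads
#' @return list with `ct` (data.frame: `sample`, `group`, `target`,
#'   `replicate`, `Ct`), `efficiencies` (named vector) and `housekeeping`
#'   (target names).
#' @export
simulate_qpcr <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 3000L)
  hk <- c("TBP", "RPL13A", "PPIA")
  targets <- c(truth$lcts$lct_id, hk)
  E <- setNames(runif(length(targets), config$efficiency_range[1],
                      config$efficiency_range[2]), targets)
  rows <- list()
  for (si in seq_len(nrow(truth$samples))) {
    sm <- truth$samples$sample[si]; grp <- truth$samples$group[si]
    for (tg in targets) {
      a <- if (tg %in% hk) 1 else {
        j <- match(tg, truth$lcts$lct_id)
        lam <- if (grp == "tumor") truth$lcts$lambda_tumor[j]
               else truth$lcts$lambda_control[j]
        max(0.01, lam / config$base_lct_frags * exp(rnorm(1, 0, 0.3)))
      }
      ct_true <- config$ct_baseline - log(a) / log(E[[tg]])
      for (rep_i in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sm, group = grp, target = tg, replicate = rep_i,
          Ct = .ct_measure(ct_true, config$ct_noise_sd,
                           config$n_tech_rep),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ct = do.call(rbind, rows), efficiencies = E, housekeeping = hk)
}

#' Simulate one qAMP enzyme-digest assay
#'
#' Encodes a methylation fraction `m` into the four cycle thresholds of a
#' qAMP assay. Methylation-sensitive enzymes (HhaI, HpaII) leave a
#' template fraction `m` intact, so `2^(-dCt) = m`; the
#' methylation-dependent McrBC leaves `1 - m`, so `2^(-dCt) = 1 - m`.
#' Zero surviving template never amplifies and is encoded as `Ct = Inf`.
#' Each reported Ct is the mean of `n_tech_rep` technical wells.
#'
#' @param m methylation fraction in `[0, 1]`.
#' @param ct_noise_sd per-well Ct noise (cycles).
#' @param n_tech_rep technical wells averaged per reported Ct.
#' @param baseline sham Ct level.
#' @return one-row data.frame with `Ct_sham`, `Ct_HhaI`, `Ct_HpaII`,
#'   `Ct_McrBC`.
#' @export
simulate_qamp_assay <- function(m, ct_noise_sd = 0, n_tech_rep = 3L,
                                baseline = 22) {
  if (!is.finite(m) || m < 0 || m > 1)
    stop("methylation fraction must lie in [0, 1], got ", m,
         call. = FALSE)
  d_sens <- if (m == 0) Inf else -log2(m)
  d_mcr <- if (m == 1) Inf else -log2(1 - m)
  data.frame(
    Ct_sham = .ct_measure(baseline, ct_noise_sd, n_tech_rep),
    Ct_HhaI = .ct_measure(baseline + d_sens, ct_noise_sd, n_tech_rep),
    Ct_HpaII = .ct_measure(baseline + d_sens, ct_noise_sd, n_tech_rep),
    Ct_McrBC = .ct_measure(baseline + d_mcr, ct_noise_sd, n_tech_rep))
}

#' Simulate qAMP Ct quadruples for every LCT locus and sample
#'
#' @inheritParams simulate_reads
#' @return data.frame with `locus`, `sample`, `group`, `m_true` and the
#'   four Ct columns of [simulate_qamp_assay()].
#' @export
simulate_qamp <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 4000L)
  rows <- list()
  for (j in seq_len(nrow(truth$lcts))) {
    for (si in seq_len(nrow(truth$samples))) {
      grp <- truth$samples$group[si]
      m <- if (grp == "tumor") truth$lcts$m_tumor[j]
           else truth$lcts$m_control[j]
      q <- simulate_qamp_assay(m, config$ct_noise_sd, config$n_tech_rep,
                               config$ct_baseline)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(locus = truth$lcts$lct_id[j],
                   sample = truth$samples$sample[si], group = grp,
                   m_true = m, stringsAsFactors = FALSE), q)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a CNV mean-log2-ratio table
#'
#' Copy number is diploid in expectation for every locus; per-sample
#' values carry measurement noise only, giving a null coupling between
#' CNV and expression unless the caller plants one.
#'
#' @inheritParams simulate_reads
#' @return data.frame with `locus`, `sample`, `group`, `log2_ratio`.
#' @export
simulate_cnv <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 5000L)
  grid <- expand.grid(locus = truth$lcts$lct_id,
                      sample = truth$samples$sample,
                      stringsAsFactors = FALSE)
  grid$group <- truth$samples$group[match(grid$sample,
                                          truth$samples$sample)]
  grid$log2_ratio <- rnorm(nrow(grid), 0, config$cnv_sd)
  grid
}

#' Simulate an H3K36me3-like coverage track
#'
#' Piecewise-constant bedGraph bins with background noise, elevated over
#' the bodies of LCT-producing elements (the mark of transcribed
#' chromatin).
#'
#' @inheritParams simulate_reads
#' @param outfile optional bedGraph output path.
#' @return data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open).
#' @export
simulate_coverage <- function(truth, config = truth$config,
                              outfile = NULL) {
  stopifnot(inherits(truth, "lct_sim_truth"))
  set.seed(config$seed + 6000L)
  bin <- config$coverage_bin
  rows <- list()
  pos <- truth$elements[truth$elements$id %in% truth$lcts$element_id, ]
  for (ch in names(truth$genome)) {
    n <- length(truth$genome[[ch]])
    starts <- seq(0L, n - 1L, by = bin)
    ends <- pmin(starts + bin, n)
    val <- pmax(0, rnorm(length(starts), config$h3k36_baseline,
                         config$coverage_noise_sd))
    el <- pos[pos$chrom == ch, ]
    for (i in seq_len(nrow(el))) {
      hit <- starts < el$end[i] & ends > el$start[i]
      val[hit] <- val[hit] + config$h3k36_gain
    }
    rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                             value = round(val, 4),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outfile)) {
    writeLines(sprintf("%s\t%d\t%d\t%g", out$chrom, out$start, out$end,
                       out$value), outfile)
  }
  out
}
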