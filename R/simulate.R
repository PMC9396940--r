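#' Configuration for the synthetic LCT study
#'
#' Builds the parameter set for the toy study emulated by the simulator:
#' a small genome with planted L1 elements (subfamilies L1PA1-L1PA8 with a
#' divergence ladder, variable 5' truncation), host genes whose exons
#' splice around the planted repeats, antisense chimeric transcripts
#' initiating at consensus positions +450/+200 of the L1 5' UTR, a
#' control and a tumor group with planted standardized effect sizes,
#' stranded 280-340 bp paired-end libraries, long reads with optional 5'
#' loss, qPCR/qAMP cycle-threshold assays, per-locus methylation
#' fractions, CNV ratios and an H3K36me3-like coverage track.
#'
#' All fractions must lie in `[0, 1]`; with a fixed `seed` every simulator
#' output is byte-identical across runs.
#'
#' @param seed integer seed; all simulator stages derive their RNG streams
#'   from it.
#' @param genome_length total genome size in bp, split evenly across
#'   `n_chrom` chromosomes.
#' @param n_chrom number of chromosomes.
#' @param n_genes number of host genes.
#' @param gene_length_range min/max gene length (bp).
#' @param n_l1_per_subfamily named integer vector, planted copies per
#'   subfamily (names `L1PA1`..`L1PA8`).
#' @param l1_cons_length length of the synthetic L1 consensus (bp).
#' @param frac_truncated fraction of L1 copies with a 5' truncation that
#'   removes the ASP (consensus start in `[400, 3000]`).
#' @param frac_short3p fraction of copies whose consensus end falls at or
#'   before 600 bp (fails the ASP filter on the 3' condition).
#' @param l1_intragenic_frac fraction of L1 copies placed inside gene
#'   bodies (introns).
#' @param frac_lct fraction of ASP-competent elements that produce an LCT.
#' @param tss_mix weights over the consensus +450 and +200 ASP regions.
#' @param frac_spliced fraction of LCTs with a single donor-acceptor gap
#'   (> 500 bp) between the L1 exit and the unique exon.
#' @param frac_nonpolyA fraction of LCTs without a polyA tail.
#' @param unique_len_range min/max length of the unique flanking exon (bp).
#' @param intron_range min/max intron size for spliced LCTs (bp).
#' @param groups named vector, samples per group (`control`, `tumor`).
#' @param effect_probs probabilities that an LCT is unchanged, down- or
#'   up-regulated in tumors.
#' @param effect_size magnitude of the planted standardized mean
#'   difference for deregulated loci.
#' @param base_lct_frags mean fragments per LCT per sample (control).
#' @param base_gene_frags mean fragments per gene transcript per sample.
#' @param insert_range library insert size bounds (bp), uniform.
#' @param read_length read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param lr_per_lct mean long reads per detected LCT.
#' @param lr_5p_loss_prob,lr_5p_loss_mean probability and mean (bp,
#'   exponential) of long-read 5' loss.
#' @param lr_low_mapq_frac fraction of long reads with MapQ < 30.
#' @param lr_missing_frac fraction of LCTs absent from the long-read set.
#' @param meth_control_range per-locus control methylation fraction range.
#' @param meth_tumor_drop range of the tumor methylation decrease.
#' @param ct_noise_sd per-well Ct measurement noise (cycles); reported Ct
#'   values are means of `n_tech_rep` technical wells.
#' @param n_tech_rep technical qPCR replicates averaged per reported Ct.
#' @param ct_baseline sham/reference Ct level (cycles).
#' @param efficiency_range PCR efficiency range (E per primer pair).
#' @param cnv_sd per-sample noise of the mean log2 CNV ratio.
#' @param coverage_bin bedGraph bin size (bp).
#' @param h3k36_baseline,h3k36_gain,coverage_noise_sd background level,
#'   gain over transcribed (LCT-producing) elements, and bin noise of the
#'   H3K36me3-like track.
#' @return a list of class `lct_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6, n_chrom = 2L,
                       n_genes = 50L, gene_length_range = c(8000, 25000),
                       n_l1_per_subfamily = setNames(rep(15L, 8L),
                                                     paste0("L1PA", 1:8)),
                       l1_cons_length = 6000L,
                       frac_truncated = 0.35, frac_short3p = 0.05,
                       l1_intragenic_frac = 0.55,
                       frac_lct = 0.5,
                       tss_mix = c("450" = 0.6, "200" = 0.4),
                       frac_spliced = 0.029, frac_nonpolyA = 0.5,
                       unique_len_range = c(250, 800),
                       intron_range = c(600, 2000),
                       groups = c(control = 3L, tumor = 8L),
                       effect_probs = c(unchanged = 0.78, down = 0.162,
                                        up = 0.058),
                       effect_size = 2,
                       base_lct_frags = 20, base_gene_frags = 12,
                       insert_range = c(280L, 340L), read_length = 100L,
                       error_rate = 0.001,
                       lr_per_lct = 8, lr_5p_loss_prob = 0.3,
                       lr_5p_loss_mean = 100, lr_low_mapq_frac = 0.1,
                       lr_missing_frac = 0.1,
                       meth_control_range = c(0.6, 0.9),
                       meth_tumor_drop = c(0.2, 0.4),
                       ct_noise_sd = 0.1, n_tech_rep = 3L,
                       ct_baseline = 22, efficiency_range = c(1.86, 2.0),
                       cnv_sd = 0.15,
                       coverage_bin = 100L, h3k36_baseline = 1,
                       h3k36_gain = 3, coverage_noise_sd = 0.2) {
  cfg <- as.list(environment())
  fr <- c(frac_truncated = frac_truncated, frac_short3p = frac_short3p,
          l1_intragenic_frac = l1_intragenic_frac, frac_lct = frac_lct,
          frac_spliced = frac_spliced, frac_nonpolyA = frac_nonpolyA,
          error_rate = error_rate, lr_5p_loss_prob = lr_5p_loss_prob,
          lr_low_mapq_frac = lr_low_mapq_frac,
          lr_missing_frac = lr_missing_frac)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "), call. = FALSE)
  if (insert_range[1] > insert_range[2])
    stop("insert_range min must be <= max", call. = FALSE)
  if (abs(sum(effect_probs) - 1) > 1e-8)
    stop("effect_probs must sum to 1", call. = FALSE)
  if (abs(sum(tss_mix) - 1) > 1e-8) cfg$tss_mix <- tss_mix / sum(tss_mix)
  class(cfg) <- "lct_sim_config"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random substitutions at a fixed per-base rate (kept transition-free for
# simplicity; the matcher only counts mismatches)
.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    repl <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# upstream room reserved ahead of each L1 5' end so the planted unique
# flank (and spliced intron) never collides with a neighbouring feature
.FLANK_RESERVE <- 3200L

#' Simulate the toy genome, repeats, genes and LCT truth
#'
#' Generates the genome FASTA, a UCSC-dialect rmsk table, gene models and
#' the machine-readable truth table of planted LCTs. L1 5' UTRs are copies
#' of seeded per-subfamily consensus stubs with per-copy divergence
#' increasing with subfamily age (L1PA1 lowest); genes and L1 placements
#' do not overlap except for deliberately intronic L1 copies, and host
#' gene exons splice around planted repeats.
#'
#' @param config a [sim_config()] list.
#' @param outdir optional directory; when given, writes `genome.fa`,
#'   `rmsk.tsv`, `genes.gtf`, `elements.tsv`, `lct_truth.tsv` and
#'   `samples.tsv`.
#' @return a list of class `lct_sim_truth` with `genome`
#'   ([Biostrings::DNAStringSet]), `rmsk`, `elements`, `genes`, `exons`,
#'   `lcts`, `samples` data.frames and the `config`.
#' @export
simulate_genome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "lct_sim_config"))
  set.seed(config$seed)
  subfams <- names(config$n_l1_per_subfamily)
  consensus_len <- config$l1_cons_length

  # divergence ladder: one ancestral stub, per-subfamily consensus, and
  # per-copy divergence growing with subfamily age
  ancestral <- .rand_dna(consensus_len)
  subfam_cons <- setNames(vector("list", length(subfams)), subfams)
  copy_div <- setNames(numeric(length(subfams)), subfams)
  for (i in seq_along(subfams)) {
    subfam_cons[[i]] <- .mutate_dna(ancestral, 0.005 * (i - 1))
    copy_div[i] <- 0.01 * i
  }

  # draw per-copy consensus intervals (5' truncation ladder)
  n_l1 <- sum(config$n_l1_per_subfamily)
  l1 <- data.frame(
    subfamily = rep(subfams, config$n_l1_per_subfamily),
    stringsAsFactors = FALSE)
  l1 <- l1[sample(nrow(l1)), , drop = FALSE]
  u <- runif(n_l1)
  off <- integer(n_l1)
  full <- u >= config$frac_truncated
  off[full] <- sample(0:99, sum(full), replace = TRUE)
  off[!full] <- sample(400:3000, sum(!full), replace = TRUE)
  cend <- rep(consensus_len, n_l1)
  short3 <- runif(n_l1) < config$frac_short3p & off < 400
  cend[short3] <- sample(450:600, sum(short3), replace = TRUE)
  l1$consensus_5p_offset <- off
  l1$consensus_end <- cend
  l1$length <- cend - off
  l1$strand <- sample(c("+", "-"), n_l1, replace = TRUE)
  l1$intragenic <- runif(n_l1) < config$l1_intragenic_frac

  # gene scaffold
  gene_len <- round(runif(config$n_genes, config$gene_length_range[1],
                          config$gene_length_range[2]))
  host_of <- rep(NA_integer_, n_l1)
  intra <- which(l1$intragenic)
  if (length(intra))
    host_of[intra] <- sample(config$n_genes, length(intra), replace = TRUE)

  # left-to-right layout per chromosome
  chrom_len <- floor(config$genome_length / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  units <- c(paste0("G", seq_len(config$n_genes)),
             paste0("I", which(!l1$intragenic)))
  units <- sample(units)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_,
                      strand = sample(c("+", "-"), config$n_genes, TRUE),
                      stringsAsFactors = FALSE)
  l1$chrom <- NA_character_; l1$start <- NA_integer_; l1$end <- NA_integer_
  free_gaps <- list()
  ci <- 1L; cursor <- 5000L
  place_len <- function(len) {
    if (cursor + len + 5000L > chrom_len) {
      ci <<- ci + 1L
      cursor <<- 5000L
      if (ci > config$n_chrom)
        stop("genome_length too small for the requested genes and L1 ",
             "elements; increase genome_length or reduce feature counts",
             call. = FALSE)
    }
  }
  for (u in units) {
    gap <- round(runif(1, 2000, 5000))
    if (startsWith(u, "G")) {
      gi <- as.integer(sub("G", "", u))
      members <- which(host_of == gi)
      need <- .FLANK_RESERVE * length(members) +
        sum(l1$length[members]) + .FLANK_RESERVE
      len <- max(gene_len[gi], need)
      place_len(len + gap)
      genes$chrom[gi] <- chroms[ci]
      genes$start[gi] <- cursor
      genes$end[gi] <- cursor + len
      inner <- cursor + .FLANK_RESERVE
      for (m in members) {
        l1$chrom[m] <- chroms[ci]
        l1$start[m] <- inner
        l1$end[m] <- inner + l1$length[m]
        inner <- inner + l1$length[m] + .FLANK_RESERVE
      }
      cursor <- cursor + len
    } else {
      m <- as.integer(sub("I", "", u))
      len <- .FLANK_RESERVE + l1$length[m]
      place_len(len + gap)
      l1$chrom[m] <- chroms[ci]
      l1$start[m] <- cursor + .FLANK_RESERVE
      l1$end[m] <- cursor + len
      cursor <- cursor + len
    }
    free_gaps[[length(free_gaps) + 1L]] <-
      list(chrom = chroms[ci], start = cursor + 500L,
           end = cursor + gap - 500L)
    cursor <- cursor + gap
  }
  l1$id <- sprintf("L1_%04d", seq_len(n_l1))
  l1$has_asp <- l1$consensus_5p_offset < 400L & l1$consensus_end > 600L

  # scattered short SINE-like repeats in free gaps (exercise the unique
  # segment subtraction); never inside the reserved LCT flanks
  alu <- do.call(rbind, lapply(free_gaps, function(g) {
    if (g$end - g$start < 400L || runif(1) > 0.5) return(NULL)
    s <- round(runif(1, g$start, g$end - 300L))
    data.frame(chrom = g$chrom, start = s, end = s + 300L,
               strand = sample(c("+", "-"), 1L),
               stringsAsFactors = FALSE)
  }))

  # genome sequence: random background, L1 copies written over it
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    .rand_dna(chrom_len), character(1)))
  names(genome) <- chroms
  for (i in seq_len(n_l1)) {
    cseq <- substr(.mutate_dna(subfam_cons[[l1$subfamily[i]]],
                               copy_div[l1$subfamily[i]]),
                   l1$consensus_5p_offset[i] + 1L, l1$consensus_end[i])
    if (l1$strand[i] == "-") cseq <- .revcomp_chr(cseq)
    Biostrings::subseq(genome[[l1$chrom[i]]], l1$start[i] + 1L,
                       l1$end[i]) <- Biostrings::DNAString(cseq)
  }

  # gene exons: gene body minus planted L1 copies (with a small buffer)
  exons <- do.call(rbind, lapply(seq_len(config$n_genes), function(gi) {
    g <- genes[gi, ]
    members <- which(host_of == gi)
    gr <- IRanges::IRanges(g$start + 1L, g$end)
    if (length(members)) {
      cut <- IRanges::IRanges(l1$start[members] + 1L - 200L,
                              l1$end[members] + 200L)
      gr <- IRanges::setdiff(gr, cut)
    }
    gr <- gr[IRanges::width(gr) >= 300L]
    if (!length(gr)) return(NULL)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = IRanges::start(gr) - 1L, end = IRanges::end(gr),
               strand = g$strand, stringsAsFactors = FALSE)
  }))

  # plant LCTs on a sample of ASP-competent elements
  asp_idx <- which(l1$has_asp)
  n_lct <- round(config$frac_lct * length(asp_idx))
  lct_idx <- sort(sample(asp_idx, n_lct))
  lcts <- NULL
  if (n_lct > 0) {
    tssc <- as.integer(sample(names(config$tss_mix), n_lct, replace = TRUE,
                              prob = config$tss_mix))
    # consensus TSS must lie inside the copy; fall back to +450 if +200
    # was truncated away
    bad <- tssc <= l1$consensus_5p_offset[lct_idx] + 50L
    tssc[bad] <- 450L
    tss_off <- tssc - l1$consensus_5p_offset[lct_idx]
    spliced <- runif(n_lct) < config$frac_spliced
    ulen <- round(runif(n_lct, config$unique_len_range[1],
                        config$unique_len_range[2]))
    ilen <- ifelse(spliced,
                   round(runif(n_lct, config$intron_range[1],
                               config$intron_range[2])), 0L)
    dirn <- sample(names(config$effect_probs), n_lct, replace = TRUE,
                   prob = config$effect_probs)
    delta <- ifelse(dirn == "up", config$effect_size,
                    ifelse(dirn == "down", -config$effect_size, 0))
    lam_c <- rep(config$base_lct_frags, n_lct)
    lam_t <- pmax(1, lam_c + delta * sqrt(lam_c))
    m_c <- runif(n_lct, config$meth_control_range[1],
                 config$meth_control_range[2])
    m_t <- pmin(1, pmax(0, m_c - runif(n_lct, config$meth_tumor_drop[1],
                                       config$meth_tumor_drop[2])))
    el <- l1[lct_idx, ]
    # ASP transcription exits the element 5' end into the upstream flank
    us <- ue <- tssg <- integer(n_lct)
    for (j in seq_len(n_lct)) {
      if (el$strand[j] == "+") {
        tssg[j] <- el$start[j] + tss_off[j]
        ue[j] <- el$start[j] - ilen[j]
        us[j] <- ue[j] - ulen[j]
      } else {
        tssg[j] <- el$end[j] - 1L - tss_off[j]
        us[j] <- el$end[j] + ilen[j]
        ue[j] <- us[j] + ulen[j]
      }
    }
    lcts <- data.frame(
      lct_id = sprintf("LCT_%04d", seq_len(n_lct)),
      element_id = el$id, chrom = el$chrom,
      element_start = el$start, element_end = el$end,
      element_strand = el$strand,
      transcript_strand = ifelse(el$strand == "+", "-", "+"),
      subfamily = el$subfamily,
      tss_consensus = tssc, tss_offset = tss_off, tss_genomic = tssg,
      spliced = spliced, intron_length = ilen,
      unique_start = us, unique_end = ue, unique_length = ulen,
      polya = runif(n_lct) >= config$frac_nonpolyA,
      direction = dirn, delta_std = delta,
      lambda_control = lam_c, lambda_tumor = lam_t,
      m_control = m_c, m_tumor = m_t,
      stringsAsFactors = FALSE)
  } else {
    lcts <- data.frame(lct_id = character(), element_id = character(),
                       chrom = character(), element_start = integer(),
                       element_end = integer(), element_strand = character(),
                       transcript_strand = character(),
                       subfamily = character(), tss_consensus = integer(),
                       tss_offset = integer(), tss_genomic = integer(),
                       spliced = logical(), intron_length = integer(),
                       unique_start = integer(), unique_end = integer(),
                       unique_length = integer(), polya = logical(),
                       direction = character(), delta_std = numeric(),
                       lambda_control = numeric(), lambda_tumor = numeric(),
                       m_control = numeric(), m_tumor = numeric(),
                       stringsAsFactors = FALSE)
  }

  samples <- data.frame(
    sample = c(sprintf("ctrl%02d", seq_len(config$groups[["control"]])),
               sprintf("tumor%02d", seq_len(config$groups[["tumor"]]))),
    group = rep(c("control", "tumor"), config$groups),
    stringsAsFactors = FALSE)

  elements <- data.frame(
    id = l1$id, chrom = l1$chrom, start = l1$start, end = l1$end,
    strand = l1$strand, subfamily = l1$subfamily,
    consensus_5p_offset = l1$consensus_5p_offset,
    consensus_end = l1$consensus_end, has_asp = l1$has_asp,
    length = l1$length, stringsAsFactors = FALSE)

  # UCSC-dialect rmsk rows (L1 copies + SINE decoys)
  rmsk_l1 <- data.frame(
    genoName = l1$chrom, genoStart = l1$start, genoEnd = l1$end,
    strand = l1$strand, repName = ifelse(l1$subfamily == "L1PA1", "L1HS",
                                         l1$subfamily),
    repClass = "LINE", repFamily = "L1",
    repStart = ifelse(l1$strand == "+", l1$consensus_5p_offset,
                      -(consensus_len - l1$consensus_end)),
    repEnd = l1$consensus_end,
    repLeft = ifelse(l1$strand == "+",
                     -(consensus_len - l1$consensus_end),
                     l1$consensus_5p_offset),
    stringsAsFactors = FALSE)
  rmsk <- rmsk_l1
  if (!is.null(alu) && nrow(alu)) {
    rmsk <- rbind(rmsk, data.frame(
      genoName = alu$chrom, genoStart = alu$start, genoEnd = alu$end,
      strand = alu$strand, repName = "AluY", repClass = "SINE",
      repFamily = "Alu", repStart = 0L, repEnd = 300L, repLeft = 0L,
      stringsAsFactors = FALSE))
  }
  rmsk <- rmsk[order(rmsk$genoName, rmsk$genoStart), ]
  rownames(rmsk) <- NULL

  truth <- list(genome = genome, rmsk = rmsk, elements = elements,
                genes = genes, exons = exons, lcts = lcts,
                samples = samples, config = config)
  class(truth) <- "lct_sim_truth"
  if (!is.null(outdir)) write_sim_truth(truth, outdir)
  truth
}

#' Write simulator outputs to disk
#'
#' @param truth a [simulate_genome()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_truth <- function(truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(truth$genome, file.path(outdir, "genome.fa"))
  tsv <- function(df, f) write.table(df, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(truth$rmsk, "rmsk.tsv")
  tsv(truth$elements, "elements.tsv")
  tsv(truth$lcts, "lct_truth.tsv")
  tsv(truth$samples, "samples.tsv")
  write_gtf(truth$genes, truth$exons, file.path(outdir, "genes.gtf"))
  invisible(outdir)
}

#' Write gene models as GTF
#'
#' Converts the internal 0-based half-open gene/exon tables to 1-based
#' closed GTF records.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param exons data.frame with the same columns per exon.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, exons, path) {
  fmt <- function(df, feat, attr) {
    sprintf("%s\tlctscape_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, feat, df$start + 1L, df$end, df$strand, attr)
  }
  lines <- c(
    fmt(genes, "gene", sprintf('gene_id "%s";', genes$gene_id)),
    fmt(exons, "exon",
        sprintf('gene_id "%s"; transcript_id "%s.t1";',
                exons$gene_id, exons$gene_id)))
  writeLines(lines, path)
  invisible(path)
}

# transcript block models (exon intervals in transcription order, 0-based
# half-open genomic coordinates) for every LCT and host gene
.sim_transcripts <- function(truth) {
  out <- list()
  lc <- truth$lcts
  for (j in seq_len(nrow(lc))) {
    el5 <- if (lc$element_strand[j] == "+") lc$element_start[j]
           else lc$element_end[j]
    if (lc$element_strand[j] == "+") {
      l1_block <- c(lc$element_start[j], lc$tss_genomic[j] + 1L)
    } else {
      l1_block <- c(lc$tss_genomic[j], lc$element_end[j])
    }
    blocks <- rbind(l1_block, c(lc$unique_start[j], lc$unique_end[j]))
    out[[lc$lct_id[j]]] <- list(
      id = lc$lct_id[j], type = "lct", chrom = lc$chrom[j],
      strand = lc$transcript_strand[j],
      blocks = data.frame(start = blocks[, 1], end = blocks[, 2]))
  }
  for (g in unique(truth$exons$gene_id)) {
    ex <- truth$exons[truth$exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    out[[g]] <- list(id = g, type = "gene", chrom = ex$chrom[1],
                     strand = ex$strand[1],
                     blocks = data.frame(start = ex$start, end = ex$end))
  }
  out
}

# spliced transcript sequence from genomic blocks (transcription order)
.transcript_seq <- function(genome, tx) {
  pieces <- vapply(seq_len(nrow(tx$blocks)), function(i) {
    s <- as.character(.subseq0(genome, tx$chrom, tx$blocks$start[i],
                               tx$blocks$end[i]))
    if (tx$strand == "-") .revcomp_chr(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

# map a transcript-coordinate interval [a, b) onto genomic blocks and
# return the longest genomic piece (primary alignment of a fragment end)
.map_to_genome <- function(tx, a, b) {
  widths <- tx$blocks$end - tx$blocks$start
  offs <- cumsum(c(0, widths))
  hits <- NULL
  for (i in seq_len(nrow(tx$blocks))) {
    lo <- max(a, offs[i]); hi <- min(b, offs[i + 1])
    if (lo >= hi) next
    if (tx$strand == "+") {
      gs <- tx$blocks$start[i] + (lo - offs[i]); ge <- gs + (hi - lo)
    } else {
      ge <- tx$blocks$end[i] - (lo - offs[i]); gs <- ge - (hi - lo)
    }
    hits <- rbind(hits, c(gs, ge))
  }
  hits[which.max(hits[, 2] - hits[, 1]), ]
}
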