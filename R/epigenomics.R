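#' qAMP methylation index from enzyme-digest cycle thresholds
#'
#' Converts the four Ct values of a qAMP assay (sham plus HhaI, HpaII,
#' McrBC digests) into per-enzyme methylation estimates and their mean.
#' The surviving template fraction after digestion is `2^(-dCt)` with
#' `dCt = Ct_enzyme - Ct_sham` (clamped at 0: small negative values are
#' measurement noise). Methylation protects against the
#' methylation-sensitive enzymes, so `M = 100 * 2^(-dCt)` for HhaI and
#' HpaII; the methylation-dependent McrBC cuts methylated templates, so
#' `M = 100 * (1 - 2^(-dCt))`. `Ct = Inf` encodes no amplification
#' (zero surviving template). The index is the arithmetic mean of the
#' available per-enzyme estimates, clamped to [0, 100]; assays with a
#' missing enzyme are flagged.
#'
#' @param assays data.frame with columns `Ct_sham`, `Ct_HhaI`,
#'   `Ct_HpaII`, `Ct_McrBC` (NA = enzyme not measured) and any id
#'   columns, which are carried through.
#' @return `assays` with added `M_HhaI`, `M_HpaII`, `M_McrBC`, `index`
#'   and `incomplete`.
#' @export
qamp_index <- function(assays) {
  .assert_cols(assays, c("Ct_sham", "Ct_HhaI", "Ct_HpaII", "Ct_McrBC"),
               "qAMP assay table")
  if (any(assays$Ct_sham <= 0, na.rm = TRUE))
    stop("non-positive sham Ct", call. = FALSE)
  dct <- function(ct) pmax(ct - assays$Ct_sham, 0)
  surv <- function(ct) 2^(-dct(ct))  # 2^-Inf = 0: no amplification
  assays$M_HhaI <- pmin(100, 100 * surv(assays$Ct_HhaI))
  assays$M_HpaII <- pmin(100, 100 * surv(assays$Ct_HpaII))
  assays$M_McrBC <- pmax(0, 100 * (1 - surv(assays$Ct_McrBC)))
  est <- cbind(assays$M_HhaI, assays$M_HpaII, assays$M_McrBC)
  assays$incomplete <- rowSums(is.na(est)) > 0L
  assays$index <- pmin(100, pmax(0, rowMeans(est, na.rm = TRUE)))
  if (any(assays$incomplete))
    warning(sum(assays$incomplete),
            " assay(s) with a missing enzyme: index from the available ",
            "enzymes", call. = FALSE)
  assays
}

# per-locus Spearman correlation between a paired covariate table and an
# expression matrix, with Bonferroni correction over loci
.paired_correlation <- function(tab, value_col, expression,
                                min_pairs = 3L) {
  loci <- intersect(unique(tab$locus), rownames(expression))
  rows <- lapply(loci, function(lo) {
    sub <- tab[tab$locus == lo, ]
    sm <- intersect(sub$sample, colnames(expression))
    if (length(sm) < min_pairs) {
      message("locus ", lo, ": fewer than ", min_pairs,
              " paired samples, skipped")
      return(NULL)
    }
    v <- sub[[value_col]][match(sm, sub$sample)]
    sp <- spearman_rho(v, expression[lo, sm])
    data.frame(locus = lo, rho = sp$rho, p = sp$p, n = sp$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}

#' Correlate methylation indices with expression
#'
#' Per-locus Spearman correlation between the qAMP methylation index and
#' relative expression across paired samples, Bonferroni-corrected over
#' loci. Loci with fewer than three paired samples are skipped with a
#' message.
#'
#' @param indices data.frame with `locus`, `sample`, `index` (e.g. from
#'   [qamp_index()]).
#' @param expression matrix loci x samples of relative expression.
#' @return data.frame with `locus`, `rho`, `p`, `n`, `p_bonf`.
#' @export
methylation_expression_correlation <- function(indices, expression) {
  .assert_cols(indices, c("locus", "sample", "index"),
               "methylation index table")
  .paired_correlation(indices, "index", expression)
}

#' Correlate CNV mean log2 ratios with expression
#'
#' @param cnv data.frame with `locus`, `sample`, `log2_ratio`.
#' @param expression matrix loci x samples.
#' @return data.frame as in [methylation_expression_correlation()].
#' @export
cnv_expression_correlation <- function(cnv, expression) {
  .assert_cols(cnv, c("locus", "sample", "log2_ratio"), "CNV table")
  .paired_correlation(cnv, "log2_ratio", expression)
}

# piecewise-constant track -> per-chromosome RleList of per-base values
.track_rle <- function(track) {
  gr <- if (is.character(track)) rtracklayer::import(track,
                                                     format = "bedGraph")
        else if (is(track, "GRanges")) track
        else {
    .assert_cols(track, c("chrom", "start", "end", "value"),
                 "coverage track")
    g <- .gr0(track); g$score <- track$value; g
  }
  GenomicRanges::coverage(gr, weight = gr$score)
}

# per-base values over [start, end) (0-based); positions without track
# coverage are 0
.track_values <- function(cov, chrom, start, end) {
  n <- end - start
  if (!chrom %in% names(cov)) return(numeric(n))
  r <- cov[[chrom]]
  lo <- max(start, 0L); hi <- min(end, length(r))
  v <- numeric(n)
  if (hi > lo)
    v[(lo - start + 1L):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo + 1L, hi))
  v
}

.binmeans <- function(v, bin) colMeans(matrix(v, nrow = bin))

#' Scale-regions chromatin metaprofile
#'
#' Computes the mean signal around a set of stranded elements: `before`
#' bp of 5' flank taken as-is, the element body rescaled to `body` bp by
#' nearest-neighbour per-base resampling, and `after` bp of 3' flank,
#' everything oriented 5' to 3' of the element (minus-strand rows are
#' reversed, flanks swapped). The signal is averaged within consecutive
#' `bin`-bp bins; positions not covered by the track count as 0. With
#' `skip_zeros`, elements whose entire row is zero are dropped from the
#' mean.
#'
#' @param track a bedGraph path, a [GenomicRanges::GRanges] with a
#'   `score` column, or a data.frame with `chrom`, `start`, `end`,
#'   `value` (0-based half-open, non-overlapping).
#' @param elements data.frame with `chrom`, `start`, `end`, `strand`
#'   (and optionally `id` for row names).
#' @param before,body,after window sizes in bp (defaults 1000 each);
#'   `bin` must divide all three.
#' @param bin bin width in bp (default 10).
#' @param skip_zeros drop all-zero rows (default TRUE).
#' @return list with `mean` (length `(before+body+after)/bin`),
#'   `matrix` (kept elements x bins), `position` (bin start relative to
#'   the element start, body bins spanning `[0, body)`), and
#'   `n_skipped`.
#' @export
metaprofile <- function(track, elements, before = 1000L, body = 1000L,
                        after = 1000L, bin = 10L, skip_zeros = TRUE) {
  if (before %% bin || body %% bin || after %% bin)
    stop("bin must divide before, body and after", call. = FALSE)
  if (!nrow(elements)) stop("no elements", call. = FALSE)
  cov <- .track_rle(track)
  nb <- (before + body + after) / bin
  rows <- matrix(0, nrow(elements), nb)
  for (i in seq_len(nrow(elements))) {
    v <- .track_values(cov, elements$chrom[i],
                       elements$start[i] - before,
                       elements$end[i] + after)
    if (elements$strand[i] == "-") v <- rev(v)
    w <- elements$end[i] - elements$start[i]
    vb <- v[(before + 1L):(before + w)]
    vb <- vb[floor((0:(body - 1L)) * w / body) + 1L]  # rescale body
    row <- c(v[seq_len(before)], vb, v[(before + w + 1L):length(v)])
    rows[i, ] <- .binmeans(row, bin)
  }
  rn <- if ("id" %in% names(elements)) elements$id
        else sprintf("el_%04d", seq_len(nrow(elements)))
  rownames(rows) <- rn
  keep <- if (skip_zeros) rowSums(rows != 0) > 0L
          else rep(TRUE, nrow(rows))
  kept <- rows[keep, , drop = FALSE]
  if (!nrow(kept))
    warning("all rows are zero; mean profile undefined", call. = FALSE)
  list(mean = if (nrow(kept)) colMeans(kept) else rep(NA_real_, nb),
       matrix = kept,
       position = seq(-before, body + after - bin, by = bin),
       n_skipped = sum(!keep))
}

#' Paired metaprofiles for LCT-producing vs silent elements
#'
#' @param track as in [metaprofile()].
#' @param elements_pos,elements_neg two disjoint element sets (genomic
#'   overlap between the sets is an error; both must be non-empty).
#' @param ... passed to [metaprofile()].
#' @return list with `pos` and `neg` metaprofiles.
#' @export
profile_contrast <- function(track, elements_pos, elements_neg, ...) {
  if (!nrow(elements_pos) || !nrow(elements_neg))
    stop("both element sets must be non-empty", call. = FALSE)
  ov <- GenomicRanges::findOverlaps(.gr0(elements_pos),
                                    .gr0(elements_neg),
                                    ignore.strand = TRUE)
  if (length(ov))
    stop("element sets overlap; they must be disjoint", call. = FALSE)
  list(pos = metaprofile(track, elements_pos, ...),
       neg = metaprofile(track, elements_neg, ...))
}
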