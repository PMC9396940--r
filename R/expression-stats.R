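#' Relative expression from qPCR cycle thresholds
#'
#' Efficiency-corrected relative quantity of a transcript of interest
#' normalised to the geometric mean of the housekeeping genes:
#' `R = E_TOI^(-Ct_TOI) / geomean_k(E_HKk^(-Ct_HKk))`. Replicate Ct
#' values are averaged on the Ct scale before the transformation.
#'
#' @param ct data.frame with `sample`, `target`, `Ct` (and optionally
#'   `replicate`).
#' @param sample,target the sample and transcript of interest.
#' @param efficiencies named vector of PCR efficiencies `E` in (1, 2]
#'   per target; a missing efficiency is an error.
#' @param housekeeping housekeeping target names (default TBP, RPL13A,
#'   PPIA); all must be measured in `sample`.
#' @return the relative expression `R` (strictly positive).
#' @export
relative_expression <- function(ct, sample, target, efficiencies,
                                housekeeping = c("TBP", "RPL13A",
                                                 "PPIA")) {
  .assert_cols(ct, c("sample", "target", "Ct"), "Ct table")
  mean_ct <- function(tg) {
    v <- ct$Ct[ct$sample == sample & ct$target == tg]
    if (!length(v))
      stop("target '", tg, "' not measured in sample '", sample, "'",
           call. = FALSE)
    mean(v)
  }
  eff <- function(tg) {
    if (!tg %in% names(efficiencies))
      stop("no PCR efficiency for target '", tg, "'", call. = FALSE)
    efficiencies[[tg]]
  }
  toi <- eff(target)^(-mean_ct(target))
  hk <- vapply(housekeeping, function(h) eff(h)^(-mean_ct(h)),
               numeric(1))
  toi / exp(mean(log(hk)))
}

#' Relative expression for every (sample, target) pair
#'
#' @inheritParams relative_expression
#' @param targets targets to quantify (default: all non-housekeeping
#'   targets in the table).
#' @return matrix targets x samples of relative expression values.
#' @export
relative_expression_matrix <- function(ct, efficiencies,
                                       housekeeping = c("TBP", "RPL13A",
                                                        "PPIA"),
                                       targets = NULL) {
  if (is.null(targets))
    targets <- setdiff(unique(ct$target), housekeeping)
  samples <- unique(ct$sample)
  out <- matrix(NA_real_, length(targets), length(samples),
                dimnames = list(targets, samples))
  for (s in samples) for (tg in targets)
    out[tg, s] <- relative_expression(ct, s, tg, efficiencies,
                                      housekeeping)
  out
}

#' Mann-Whitney tests with Holm correction across loci
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per locus between the
#' two groups, exact by enumeration when both group sizes are at most 8
#' and there are no ties, otherwise the tie-corrected normal
#' approximation; Holm step-down adjustment over the locus family.
#' Degenerate loci (a single distinct value across both groups) get
#' p = 1.
#'
#' @param values matrix loci x samples (or data.frame) of expression
#'   values.
#' @param groups named character vector (or factor) mapping samples to
#'   `control`/`tumor` (any two levels).
#' @param exact_max largest per-group n for exact enumeration.
#' @return data.frame with `locus`, `U`, `p`, `p_holm`.
#' @export
mw_holm <- function(values, groups, exact_max = 8L) {
  values <- as.matrix(values)
  g <- factor(groups[colnames(values)])
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  lv <- levels(g)
  res <- t(apply(values, 1L, function(v) {
    x <- v[g == lv[1]]; y <- v[g == lv[2]]
    if (length(unique(c(x, y))) == 1L) return(c(U = length(x) *
                                                  length(y) / 2, p = 1))
    ties <- any(duplicated(c(x, y)))
    ex <- !ties && length(x) <= exact_max && length(y) <= exact_max
    w <- suppressWarnings(wilcox.test(x, y, exact = ex, correct = !ex))
    c(U = unname(w$statistic), p = w$p.value)
  }))
  data.frame(locus = rownames(values), U = res[, "U"], p = res[, "p"],
             p_holm = p.adjust(res[, "p"], method = "holm"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hedges' g standardized mean difference
#'
#' Small-sample corrected standardized difference
#' `g = J * (mean(control) - mean(tumor)) / s_pooled` with
#' `J = 1 - 3 / (4 (n1 + n2) - 9)`. The orientation is fixed so that
#' overexpression in the tumor group gives g < 0 (hence the `up` call of
#' [classify_deregulation()] at g < -cutoff). A pooled SD of zero gives
#' g = 0 when the means are equal and a flagged infinity otherwise.
#'
#' @param control,tumor numeric vectors (each of length at least 2).
#' @return Hedges' g.
#' @export
hedges_g <- function(control, tumor) {
  n1 <- length(control); n2 <- length(tumor)
  if (n1 < 2L || n2 < 2L)
    stop("need at least two observations per group", call. = FALSE)
  sp <- sqrt(((n1 - 1) * var(control) + (n2 - 1) * var(tumor)) /
               (n1 + n2 - 2))
  d <- mean(control) - mean(tumor)
  if (sp == 0) {
    if (d == 0) return(0)
    warning("zero pooled SD with unequal means: unbounded effect size",
            call. = FALSE)
    return(sign(d) * Inf)
  }
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * d / sp
}

#' Call expression deregulation from an effect size
#'
#' `up` (overexpressed in tumors) when g < -cutoff, `down` when
#' g > +cutoff, otherwise `unchanged`; the cutoff is strict on both
#' sides.
#'
#' @param g Hedges' g value(s).
#' @param cutoff effect-size cutoff (default 1).
#' @return character vector of calls.
#' @export
classify_deregulation <- function(g, cutoff = 1) {
  ifelse(g < -cutoff, "up", ifelse(g > cutoff, "down", "unchanged"))
}

#' Calibrate the effect-size cutoff against assay-derived truth
#'
#' For each candidate cutoff, sensitivity is the fraction of truly
#' deregulated loci called with the matching direction at |g| > cutoff,
#' and specificity the fraction of truly unchanged loci called
#' unchanged. The chosen cutoff maximises Youden's J
#' (sensitivity + specificity - 1), ties resolved toward the smaller
#' cutoff; the full table is returned so a cutoff can also be chosen by
#' eye.
#'
#' @param g named vector of effect sizes computed from read counts.
#' @param truth named character vector over the same loci with values
#'   `deregulated_up`, `deregulated_down`, `unchanged` (typically from
#'   [mw_holm()] on an orthogonal qPCR dataset).
#' @param cutoffs candidate cutoffs (default `seq(0.25, 3, 0.25)`).
#' @return list with `table` (cutoff, sensitivity, specificity, youden)
#'   and `chosen` cutoff.
#' @export
calibrate_cutoff <- function(g, truth,
                             cutoffs = seq(0.25, 3, by = 0.25)) {
  truth <- truth[names(g)]
  dereg <- truth %in% c("deregulated_up", "deregulated_down")
  if (!any(dereg))
    stop("no deregulated loci in the truth set: sensitivity undefined",
         call. = FALSE)
  tab <- do.call(rbind, lapply(cutoffs, function(co) {
    call <- classify_deregulation(g, co)
    hit <- (truth == "deregulated_up" & call == "up") |
      (truth == "deregulated_down" & call == "down")
    data.frame(cutoff = co,
               sensitivity = sum(hit[dereg]) / sum(dereg),
               specificity = mean(call[!dereg] == "unchanged"))
  }))
  tab$youden <- tab$sensitivity + tab$specificity - 1
  chosen <- tab$cutoff[which.max(tab$youden)]  # ties: first = smallest
  list(table = tab, chosen = chosen)
}

#' Tie-corrected Spearman correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation. Constant vectors have no defined correlation and are
#' flagged.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `rho`, `p`, `n` and `defined`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || length(unique(x)) == 1L ||
      length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                defined = FALSE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Compare host-gene expression between two gene sets
#'
#' Reports the raw-scale group medians and a Welch t-test on the
#' variance-stabilising transform (default `log2(fpkm + 1)`).
#'
#' @param set_a,set_b numeric vectors of per-gene expression (fpkm).
#' @param transform function applied before the t-test.
#' @return list with `median_a`, `median_b`, `p` and the group sizes.
#' @export
compare_host_gene_expression <- function(set_a, set_b,
                                         transform = function(x)
                                           log2(x + 1)) {
  if (!length(set_a) || !length(set_b))
    stop("empty gene set", call. = FALSE)
  tt <- t.test(transform(set_a), transform(set_b))
  list(median_a = median(set_a), median_b = median(set_b),
       p = tt$p.value, n_a = length(set_a), n_b = length(set_b))
}
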