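test_that("qAMP index converts delta-Ct values as the survival model dictates", {
  # dCt = 1 for all three enzymes -> estimates (50, 50, 50)
  a <- qamp_index(data.frame(Ct_sham = 22, Ct_HhaI = 23, Ct_HpaII = 23,
                             Ct_McrBC = 23))
  expect_equal(c(a$M_HhaI, a$M_HpaII, a$M_McrBC), c(50, 50, 50))
  expect_equal(a$index, 50)
  # fully methylated limit: sensitive enzymes do not cut, McrBC cuts all
  b <- qamp_index(data.frame(Ct_sham = 22, Ct_HhaI = 22, Ct_HpaII = 22,
                             Ct_McrBC = Inf))
  expect_equal(b$index, 100)
  # negative dCt is measurement noise, clamped at zero
  cl <- qamp_index(data.frame(Ct_sham = 22, Ct_HhaI = 21.8,
                              Ct_HpaII = 22, Ct_McrBC = Inf))
  expect_equal(cl$index, 100)
  # missing enzyme: mean of the available estimates, flagged
  expect_warning(
    m <- qamp_index(data.frame(Ct_sham = 22, Ct_HhaI = 23,
                               Ct_HpaII = NA, Ct_McrBC = 23)),
    "missing enzyme")
  expect_equal(m$index, 50)
  expect_true(m$incomplete)
  expect_error(qamp_index(data.frame(Ct_sham = 0, Ct_HhaI = 1,
                                     Ct_HpaII = 1, Ct_McrBC = 1)),
               "sham")
})

test_that("qAMP inversion is exact at zero noise and robust at 0.1-cycle noise", {
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    q <- simulate_qamp_assay(m, ct_noise_sd = 0)
    expect_equal(qamp_index(q)$index, 100 * m)
  }
  set.seed(61)
  ms <- runif(1000)
  err <- vapply(ms, function(m)
    abs(qamp_index(simulate_qamp_assay(m, ct_noise_sd = 0.1))$index -
          100 * m), numeric(1))
  expect_gte(mean(err <= 5), 0.95)
})

test_that("methylation/CNV correlations delegate to Spearman with Bonferroni", {
  expr <- matrix(1:8, nrow = 2, byrow = TRUE,
                 dimnames = list(c("L1", "L2"), sprintf("s%d", 1:4)))
  idx <- data.frame(locus = rep(c("L1", "L2"), each = 4),
                    sample = rep(sprintf("s%d", 1:4), 2),
                    index = c(4, 3, 2, 1, 1, 2, 3, 4))
  out <- methylation_expression_correlation(idx, expr)
  expect_equal(out$rho, c(-1, 1))
  expect_equal(out$p_bonf, pmin(1, out$p * 2))
  cnv <- data.frame(locus = rep("L1", 4),
                    sample = sprintf("s%d", 1:4),
                    log2_ratio = c(0.1, 0.4, 0.2, 0.8))
  out2 <- cnv_expression_correlation(cnv, expr)
  expect_equal(out2$rho, spearman_rho(cnv$log2_ratio, expr["L1", ])$rho)
  # fewer than three paired samples: skipped with a message
  expect_message(
    skipped <- methylation_expression_correlation(idx[1:2, ], expr),
    "skipped")
  expect_equal(nrow(skipped), 0L)
})

test_that("independent pairs show no systematic methylation-expression correlation", {
  set.seed(62)
  rhos <- replicate(50, spearman_rho(rnorm(10), rnorm(10))$rho)
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("metaprofile: constant tracks, linearity, strand mirroring", {
  el <- data.frame(id = "e1", chrom = "chr1", start = 1000L,
                   end = 1200L, strand = "+", stringsAsFactors = FALSE)
  const <- data.frame(chrom = "chr1", start = 0L, end = 5000L,
                      value = 3)
  mp <- metaprofile(const, el, before = 100L, body = 100L,
                    after = 100L, bin = 10L)
  expect_equal(mp$mean, rep(3, 30))
  expect_equal(metaprofile(transform(const, value = 6), el, 100L, 100L,
                           100L, 10L)$mean, 2 * mp$mean)
  expect_error(metaprofile(const, el, before = 105L), "divide")

  # asymmetric track: a mirrored minus-strand element reproduces the
  # plus-strand profile
  set.seed(63)
  track <- data.frame(chrom = "chr1",
                      start = seq(0L, 4990L, by = 10L))
  track$end <- track$start + 10L
  track$value <- round(runif(nrow(track), 0, 5), 2)
  p_plus <- metaprofile(track, el, 100L, 100L, 100L, 10L)
  L <- 5000L
  track_m <- data.frame(chrom = "chr1", start = L - track$end,
                        end = L - track$start, value = track$value)
  el_m <- data.frame(id = "e1", chrom = "chr1", start = L - el$end,
                     end = L - el$start, strand = "-",
                     stringsAsFactors = FALSE)
  p_minus <- metaprofile(track_m, el_m, 100L, 100L, 100L, 10L)
  expect_equal(p_minus$mean, p_plus$mean)
})

test_that("metaprofile agrees exactly with the per-base resampling oracle", {
  set.seed(64)
  track <- data.frame(chrom = "chr1", start = seq(0L, 3980L, by = 20L))
  track$end <- track$start + 20L
  track$value <- round(runif(nrow(track), 0, 4), 2)
  el <- data.frame(id = sprintf("e%d", 1:5), chrom = "chr1",
                   start = c(500L, 900L, 1500L, 2200L, 3000L),
                   strand = c("+", "-", "+", "-", "+"),
                   stringsAsFactors = FALSE)
  el$end <- el$start + c(130L, 250L, 60L, 400L, 175L)
  got <- metaprofile(track, el, before = 100L, body = 100L,
                     after = 100L, bin = 10L, skip_zeros = FALSE)
  want <- bf_metaprofile(track, el, 100L, 100L, 100L, 10L)
  expect_equal(unname(got$matrix), unname(want))
  expect_equal(got$mean, colMeans(want))
})

test_that("skip_zeros drops silent rows and contrast rejects overlapping sets", {
  track <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                      value = 2)
  el <- data.frame(id = c("on", "off"), chrom = "chr1",
                   start = c(1100L, 3000L), end = c(1300L, 3200L),
                   strand = "+", stringsAsFactors = FALSE)
  mp <- metaprofile(track, el, 100L, 100L, 100L, 10L,
                    skip_zeros = TRUE)
  expect_equal(rownames(mp$matrix), "on")
  expect_equal(mp$n_skipped, 1L)

  expect_error(profile_contrast(track, el, el[1, ], before = 100L),
               "disjoint")
  expect_error(profile_contrast(track, el[0, ], el), "non-empty")
  # disjoint copies of identical geometry give identical profiles
  el2 <- transform(el, start = start + 10000L, end = end + 10000L,
                   id = paste0(id, "_b"))
  track2 <- rbind(track, transform(track, start = start + 10000L,
                                   end = end + 10000L))
  pc <- profile_contrast(track2, el, el2, before = 100L, body = 100L,
                         after = 100L, bin = 10L, skip_zeros = FALSE)
  expect_equal(pc$pos$mean, pc$neg$mean)
})

test_that("the planted H3K36me3 signal separates LCT-positive from silent elements", {
  sim <- shared_sim()
  track <- simulate_coverage(sim$truth, sim$cfg)
  el <- sim$truth$elements
  pos <- el[el$id %in% sim$truth$lcts$element_id, ]
  neg <- el[!el$id %in% sim$truth$lcts$element_id, ]
  pc <- profile_contrast(track, pos, neg, before = 1000L, body = 1000L,
                         after = 1000L, bin = 10L)
  body_bins <- 101:200
  expect_gt(mean(pc$pos$mean[body_bins]),
            mean(pc$neg$mean[body_bins]) + 1)
})
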