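mk_loci <- function(d, size, uniq = 200L, chrom = "chr1",
                    element_id = "L1_A", strand = "-") {
  data.frame(id = sprintf("loc%02d", seq_along(d)),
             element_id = element_id, chrom = chrom,
             r1r2_distance = d, total_size = size,
             unique_length = uniq, transcript_strand = strand,
             stringsAsFactors = FALSE)
}

test_that("splice rules reproduce the three-parameter classifier", {
  el <- toy_elements()
  # distance/size grid: (d, size, unique) -> expected status
  cases <- data.frame(
    d = c(-10L, 600L, 300L, 501L, 500L, -50L, -50L, 250L, 100L, 0L),
    size = c(350L, 2000L, 800L, 700L, 700L, 1100L, 1100L, 1000L, 800L,
             400L),
    uniq = c(200L, 300L, 300L, 300L, 300L, 800L, 700L, 300L, 300L,
             100L),
    want = c("unspliced",          # small contiguous locus
             "spliced",            # distance rule (> 500)
             "undetermined",       # 200-499 and 600-999
             "spliced",            # distance boundary: 501 fires
             "unspliced",          # 500 does not fire
             "spliced",            # size rule: >1000 with unique >700
             "unspliced",          # unique exactly 700 does not fire
             "unspliced",          # size 1000 outside the 600-999 band
             "unspliced",          # gray zone: d 1-199, size 600-999
             "unspliced"),
    stringsAsFactors = FALSE)
  got <- splice_status(mk_loci(cases$d, cases$size, cases$uniq), el,
                       junctions = NULL)
  expect_equal(got$splice_status, cases$want)
  expect_true(got$gray_zone[9])
  expect_equal(sum(got$gray_zone), 1L)

  # junction rule: a junction within 200 bp of the L1 start rescues an
  # otherwise unspliced locus
  j_in <- data.frame(chrom = "chr1", start = 9900L, end = 12000L)
  j_out <- data.frame(chrom = "chr1", start = 9000L, end = 9799L)
  base <- mk_loci(-10L, 350L)
  expect_equal(splice_status(base, el, j_in)$splice_status, "spliced")
  expect_equal(splice_status(base, el, j_in)$splice_rules, "junction")
  expect_equal(splice_status(base, el, j_out)$splice_status,
               "unspliced")
  # minus-strand element: the L1 "start" is its 5' end (right edge)
  b2 <- mk_loci(-10L, 350L, chrom = "chr2", element_id = "L1_C",
                strand = "+")
  j2 <- data.frame(chrom = "chr2", start = 15850L, end = 17000L)
  expect_equal(splice_status(b2, el, j2)$splice_status, "spliced")
  expect_error(splice_status(transform(base, r1r2_distance = NA), el),
               "missing")
})

test_that("splice calls are invariant to junction table order", {
  el <- toy_elements()
  j <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(9900L, 500L, 100L),
                  end = c(12000L, 700L, 300L))
  a <- splice_status(mk_loci(c(-10L, 600L), c(350L, 800L)), el, j)
  b <- splice_status(mk_loci(c(-10L, 600L), c(350L, 800L)), el,
                     j[c(3, 1, 2), ])
  expect_equal(a$splice_status, b$splice_status)
})

test_that("genic context classifies orientation against the host gene", {
  el <- toy_elements()
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                      start = c(5000L, 9000L), end = c(20000L, 20000L),
                      strand = c("-", "-"), stringsAsFactors = FALSE)
  loci <- data.frame(id = c("l1", "l2", "l3"),
                     element_id = c("L1_A", "L1_B", "L1_C"),
                     transcript_strand = c("-", "-", "+"),
                     stringsAsFactors = FALSE)
  out <- genic_context(loci, el, genes)
  # L1_A inside GA, transcript '-' on a '-' gene -> sense
  expect_equal(out$loci$genic_context,
               c("intragenic_sense", "intergenic",
                 "intragenic_antisense"))
  expect_equal(out$summary$fraction_intragenic, 2 / 3)
  expect_equal(out$summary$fraction_antisense_intragenic, 1 / 2)
  expect_error(genic_context(loci, el,
                             transform(genes, strand = "*")),
               "stranded")
})

test_that("genic context matches a brute-force overlap oracle and is translation invariant", {
  set.seed(31)
  n <- 50L
  el <- data.frame(id = sprintf("E%02d", 1:n), chrom = "chr1",
                   start = sample(0:90000, n), strand = "+",
                   stringsAsFactors = FALSE)
  el$end <- el$start + 6000L
  el$has_asp <- TRUE; el$subfamily <- "L1PA1"
  genes <- data.frame(gene_id = sprintf("G%02d", 1:12), chrom = "chr1",
                      start = sample(0:80000, 12),
                      strand = sample(c("+", "-"), 12, TRUE),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(5000:20000, 12)
  loci <- data.frame(id = el$id, element_id = el$id,
                     transcript_strand = "-", stringsAsFactors = FALSE)
  out <- genic_context(loci, el, genes)
  want_intra <- vapply(seq_len(n), function(i)
    any(genes$start < el$end[i] & genes$end > el$start[i]), logical(1))
  expect_equal(out$loci$genic_context != "intergenic", want_intra)
  shift <- function(df) transform(df, start = start + 12345L,
                                  end = end + 12345L)
  out2 <- genic_context(loci, shift(el), shift(genes))
  expect_equal(out2$summary$fraction_intragenic,
               out$summary$fraction_intragenic)
  expect_equal(out2$summary$fraction_antisense_intragenic,
               out$summary$fraction_antisense_intragenic)
})

test_that("binomial enrichment equals the exact two-sided tail sum", {
  expect_gt(binomial_enrichment(5, 10, 0.5), 0.99)  # symmetric centre
  expect_equal(binomial_enrichment(5, 10, 0.5), 1)
  # enumeration oracle for k = 9, n = 10, p0 = 0.5
  pm <- dbinom(0:10, 10, 0.5)
  want <- sum(pm[pm <= dbinom(9, 10, 0.5) + 1e-12])
  expect_equal(binomial_enrichment(9, 10, 0.5), want)
  expect_error(binomial_enrichment(11, 10, 0.5), "k <= n")
  expect_error(binomial_enrichment(2, 10, 0), "p0")
})

test_that("walking classifier covers the full amplification truth table", {
  grid <- expand.grid(common = c(TRUE, FALSE),
                      downstream = c(TRUE, FALSE),
                      upstream = c(TRUE, FALSE))
  grid$subfamily <- "L1PA2"
  out <- suppressWarnings(walking_classify(grid))
  want <- with(grid, ifelse(!common, "undetermined",
               ifelse(upstream, "NO_LCT",
               ifelse(downstream, "ASP450", "ASP200"))))
  expect_equal(out$status, want)
  expect_equal(out$is_lct, want %in% c("ASP450", "ASP200"))
  # the documented example patterns
  ex <- data.frame(common = c(TRUE, TRUE, TRUE),
                   downstream = c(TRUE, TRUE, FALSE),
                   upstream = c(FALSE, TRUE, FALSE))
  expect_equal(walking_classify(ex)$status,
               c("ASP450", "NO_LCT", "ASP200"))
  expect_warning(walking_classify(data.frame(common = FALSE,
                                             downstream = FALSE,
                                             upstream = FALSE)),
                 "unevaluable")
})

test_that("polyA classifier covers its truth table and reports bounds", {
  grid <- expand.grid(random_hexamer = c(TRUE, FALSE),
                      oligodT = c(TRUE, FALSE),
                      polyU_oligodA = c(TRUE, FALSE))
  out <- suppressWarnings(polya_classify(grid))
  want <- with(grid, ifelse(!random_hexamer, "unevaluable",
               ifelse(oligodT, "polyA",
               ifelse(polyU_oligodA, "non_polyA", "undetermined"))))
  expect_equal(out$patterns$polya_status, want)
  expect_equal(out$n_evaluable, 4L)
  expect_equal(out$min_nonpolyA, sum(want == "non_polyA"))
  expect_equal(out$max_nonpolyA, 2L)  # evaluable oligo-dT failures
  simple <- polya_classify(data.frame(random_hexamer = TRUE,
                                      oligodT = FALSE,
                                      polyU_oligodA = TRUE))
  expect_equal(simple$patterns$polya_status, "non_polyA")
})
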