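test_that("matcher boundaries: 50 bp exact accepts, 49 bp rejects, mismatch budget is 1", {
  set.seed(21)
  ref <- Biostrings::DNAStringSet(c(L1_X = random_dna(500)))
  window50 <- substr(as.character(ref[[1]]), 101, 150)
  pad <- random_dna(40)
  hit <- match_read_to_l1(c(r = paste0(pad, window50)), ref)
  expect_equal(hit$element_id, "L1_X")
  expect_gte(hit$match_length, 50L)

  # a bare 49 bp exact copy cannot host a 50 bp window
  miss <- match_read_to_l1(c(r = substr(window50, 1, 49)), ref)
  expect_true(is.na(miss$element_id))
  # padded, the 49 bp stretch extends one base using the mismatch budget
  padded <- match_read_to_l1(c(r = paste0(pad, substr(window50, 1, 49))),
                             ref)
  expect_false(is.na(padded$element_id))
  expect_true(is.na(match_read_to_l1(
    c(r = paste0(pad, substr(window50, 1, 49))), ref,
    max_mm = 0L)$element_id))

  # 60 bp copy: 1 substitution tolerated, 2 rejected
  w60 <- strsplit(substr(as.character(ref[[1]]), 201, 260), "")[[1]]
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  one <- w60; one[15] <- flip(one[15])
  two <- one; two[45] <- flip(two[45])
  expect_equal(match_read_to_l1(
    setNames(paste(one, collapse = ""), "r"), ref)$element_id, "L1_X")
  expect_true(is.na(match_read_to_l1(
    setNames(paste(two, collapse = ""), "r"), ref)$element_id))

  # antisense reads are found on the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window50)))
  anti <- match_read_to_l1(c(r = paste0(rc, pad)), ref)
  expect_equal(anti$orientation, "antisense")

  expect_error(match_read_to_l1(c(r = "ACGT"),
                                Biostrings::DNAStringSet()), "empty")
})

test_that("matcher agrees with the brute-force oracle on planted cases", {
  set.seed(22)
  refs <- setNames(lapply(1:3, function(i) random_dna(160)),
                   c("L1_a", "L1_b", "L1_c"))
  refset <- Biostrings::DNAStringSet(unlist(refs))
  for (case in 1:25) {
    read <- strsplit(random_dna(80), "")[[1]]
    rid <- sample(names(refs), 1)
    mlen <- sample(45:70, 1)
    roff <- sample(1:(160 - mlen), 1)
    core <- strsplit(substr(refs[[rid]], roff, roff + mlen - 1), "")[[1]]
    nmm <- sample(0:2, 1)
    if (nmm > 0) for (p in sample(mlen, nmm))
      core[p] <- setdiff(c("A", "C", "G", "T"), core[p])[1]
    at <- sample(1:(80 - mlen), 1)
    read[at:(at + mlen - 1)] <- core
    if (runif(1) < 0.5)
      read <- rev(chartr("ACGT", "TGCA", read))
    read <- paste(read, collapse = "")
    got <- match_read_to_l1(c(q = read), refset, min_len = 50L,
                            max_mm = 1L)
    want <- bf_best_match(read, refs, min_len = 50L, max_mm = 1L)
    if (is.null(want)) {
      expect_true(is.na(got$element_id))
    } else {
      expect_equal(got$element_id, want$id)
      expect_equal(got$match_length, want$len)
      expect_equal(got$mismatches, want$mm)
      expect_equal(got$orientation, want$orient)
    }
  }
})

test_that("relaxing matcher thresholds never shrinks the matched read set", {
  set.seed(23)
  refs <- Biostrings::DNAStringSet(c(L1_a = random_dna(300)))
  reads <- vapply(1:40, function(i) {
    n <- sample(40:60, 1)
    o <- sample(1:(300 - n), 1)
    core <- strsplit(substr(as.character(refs[[1]]), o, o + n - 1),
                     "")[[1]]
    for (p in sample(n, sample(0:2, 1)))
      core[p] <- setdiff(c("A", "C", "G", "T"), core[p])[1]
    paste0(random_dna(10), paste(core, collapse = ""), random_dna(10))
  }, character(1))
  names(reads) <- sprintf("r%02d", 1:40)
  hit <- function(min_len, max_mm)
    which(!is.na(match_read_to_l1(reads, refs, min_len,
                                  max_mm)$element_id))
  expect_true(all(hit(50, 1) %in% hit(45, 1)))
  expect_true(all(hit(50, 1) %in% hit(50, 2)))
})

test_that("unique segment extraction honours the 30 bp bound and matches per-base subtraction", {
  rep_df <- data.frame(chrom = "chr1",
                       start = c(1000L, 2000L, 2300L),
                       end = c(1500L, 2120L, 2600L))
  # fully repeat-free mate
  free <- find_unique_segment(list(chrom = "chr1", start = 5000L,
                                   end = 5100L), rep_df)
  expect_equal(free$start, 5000L); expect_equal(free$width, 100L)
  # only 29 repeat-free bp -> none; 30 -> accepted
  expect_null(find_unique_segment(list(chrom = "chr1", start = 1971L,
                                       end = 2120L), rep_df))
  expect_equal(find_unique_segment(list(chrom = "chr1", start = 1970L,
                                        end = 2120L), rep_df)$width, 30L)
  expect_null(find_unique_segment(list(chrom = "chr1", start = NA,
                                       end = NA), rep_df))
  # oracle agreement on random mates
  set.seed(24)
  for (i in 1:50) {
    m <- list(chrom = "chr1", start = sample(500:2600, 1))
    m$end <- m$start + sample(40:200, 1)
    got <- find_unique_segment(m, rep_df)
    want <- bf_unique(m, rep_df, 30L)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("pair filter boundaries: insert inclusive at 50 kb, orientation and 5' UTR checks", {
  el <- toy_elements()[1, ]  # + strand, [10000, 16000)
  m_anti <- list(orientation = "antisense")
  u_at <- function(gap) data.frame(chrom = "chr1",
                                   start = 16000L + gap,
                                   end = 16100L + gap)
  expect_true(pair_to_candidate(m_anti, u_at(50000L - 100L), el)$accepted)
  ok <- pair_to_candidate(m_anti,
                          data.frame(chrom = "chr1", start = 66000L,
                                     end = 66100L), el)  # gap 50000
  expect_true(ok$accepted)
  too_far <- pair_to_candidate(m_anti,
                               data.frame(chrom = "chr1",
                                          start = 66001L,
                                          end = 66101L), el)  # 50001
  expect_false(too_far$accepted)
  expect_equal(too_far$reason, "insert_too_large")

  sense <- pair_to_candidate(list(orientation = "sense"), u_at(0L), el)
  expect_equal(sense$reason, "same_orientation")

  no_utr <- pair_to_candidate(m_anti, u_at(0L),
                              transform(el, has_asp = FALSE))
  expect_equal(no_utr$reason, "no_5utr")

  cross <- pair_to_candidate(m_anti,
                             data.frame(chrom = "chr9", start = 0L,
                                        end = 100L), el)
  expect_equal(cross$reason, "insert_undefined")
  # accepted candidates run antisense to the element
  expect_equal(ok$candidate$transcript_strand, "-")
})

test_that("clustering merges within the gap and matches a union-find oracle", {
  el <- toy_elements()
  two <- data.frame(element_id = "L1_A", chrom = "chr1",
                    unique_start = c(9000L, 8000L),
                    unique_end = c(9400L, 8600L),   # gap 400 > 300
                    transcript_strand = "-",
                    stringsAsFactors = FALSE)
  cl2 <- cluster_candidates(two, el)
  expect_equal(nrow(cl2$loci), 2L)
  two$unique_start[2] <- 9100L; two$unique_end[2] <- 9500L
  cl1 <- cluster_candidates(two, el)
  expect_equal(nrow(cl1$loci), 1L)
  expect_equal(cl1$loci$n_reads, 2L)
  expect_equal(cl1$loci$unique_start, 9000L)
  expect_equal(cl1$loci$unique_end, 9500L)

  set.seed(25)
  rnd <- data.frame(
    element_id = sample(c("L1_A", "L1_B"), 200L, replace = TRUE),
    chrom = "chr1",
    unique_start = sample(0:20000, 200L, replace = TRUE),
    transcript_strand = "-", stringsAsFactors = FALSE)
  rnd$unique_end <- rnd$unique_start + sample(50:400, 200L,
                                              replace = TRUE)
  got <- cluster_candidates(rnd, el)
  want <- bf_cluster_partition(rnd, 300L)
  expect_equal(nrow(got$loci), length(want))
  # same partition: compare the sorted member spans
  got_spans <- sort(paste(got$loci$element_id, got$loci$unique_start,
                          got$loci$unique_end))
  want_spans <- sort(vapply(want, function(ix)
    paste(rnd$element_id[ix[1]], min(rnd$unique_start[ix]),
          max(rnd$unique_end[ix])), character(1)))
  expect_equal(got_spans, want_spans)
})

test_that("locus geometry follows the transcription direction", {
  el <- toy_elements()
  # minus transcript (plus element): unique abuts the element start
  juxt <- data.frame(element_id = "L1_A", chrom = "chr1",
                     unique_start = 9600L, unique_end = 10000L,
                     transcript_strand = "-",
                     r1_start = 10000L, r1_end = 10100L,
                     stringsAsFactors = FALSE)
  expect_equal(cluster_candidates(juxt, el)$loci$r1r2_distance, 0L)
  # overlap -> negative
  juxt$unique_end <- 10050L
  expect_lt(cluster_candidates(juxt, el)$loci$r1r2_distance, 0L)
  # spliced-like gap -> large positive
  far <- transform(juxt, unique_start = 8600L, unique_end = 9000L)
  expect_equal(cluster_candidates(far, el)$loci$r1r2_distance, 1000L)
  # plus transcript (minus element, chr2 [10000,16000)): flank is right
  plus <- data.frame(element_id = "L1_C", chrom = "chr2",
                     unique_start = 16000L, unique_end = 16400L,
                     transcript_strand = "+",
                     r1_start = 15900L, r1_end = 16000L,
                     stringsAsFactors = FALSE)
  expect_equal(cluster_candidates(plus, el)$loci$r1r2_distance, 0L)
  cl <- cluster_candidates(plus, el)
  expect_equal(cl$loci$total_size, 500L)
})

test_that("pooling is a union keyed by locus and commutative; saturation is sensible", {
  sim <- shared_sim()
  cand <- sim$fc$candidates
  el <- sim$truth$elements
  per_sample <- lapply(split(cand, cand$sample), cluster_candidates,
                       elements = el)
  pooled <- pool_samples(per_sample, el)
  expect_gte(nrow(pooled$loci),
             max(vapply(per_sample, function(x) nrow(x$loci),
                        integer(1))))
  pooled_rev <- pool_samples(rev(per_sample), el)
  expect_equal(sort(paste(pooled$loci$element_id,
                          pooled$loci$unique_start)),
               sort(paste(pooled_rev$loci$element_id,
                          pooled_rev$loci$unique_start)))
  # single sample: curve equals its own locus count
  one <- saturation_curve(per_sample[1], el, n_perm = 3L, seed = 2L)
  expect_equal(one$mean_loci, nrow(per_sample[[1]]$loci))
  curve <- saturation_curve(per_sample, el, n_perm = 5L, seed = 2L)
  expect_true(all(diff(curve$mean_loci) >= 0))
  expect_equal(curve$mean_loci[length(curve$mean_loci)],
               nrow(pooled$loci))
})

test_that("known-locus comparison counts intersecting elements", {
  sim <- shared_sim()
  loci <- sim$fc$loci
  el <- sim$truth$elements
  empty <- GenomicRanges::GRanges()
  expect_equal(compare_to_known_loci(loci, el, empty)$count, 0L)
  # self-comparison: all LCT-producing elements match
  self_bed <- el[el$id %in% loci$element_id,
                 c("chrom", "start", "end")]
  got <- compare_to_known_loci(loci, el, self_bed)
  expect_equal(got$count, length(unique(loci$element_id)))
  # toy oracle: only the first element's span is known
  one <- el[el$id == loci$element_id[1], c("chrom", "start", "end")]
  expect_equal(compare_to_known_loci(loci, el, one)$count, 1L)
})

test_that("the finder recovers the planted LCT set exactly on the shared error-free study", {
  sim <- shared_sim()
  found <- unique(sim$fc$loci$element_id)
  planted <- unique(sim$truth$lcts$element_id)
  expect_setequal(found, planted)
  expect_equal(nrow(sim$fc$loci), nrow(sim$truth$lcts))
  # accounting conservation at the pair-filter stage
  s <- sim$fc$summary
  expect_equal(s$candidates, s$retained + sum(s$rejected))
})
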