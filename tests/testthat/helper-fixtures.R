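# Shared medium-size simulated study, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (!is.null(.fixture_env$sim)) return(.fixture_env$sim)
  cfg <- sim_config(
    seed = 303L, genome_length = 1.2e6, n_chrom = 2L, n_genes = 18L,
    n_l1_per_subfamily = setNames(rep(6L, 8L), paste0("L1PA", 1:8)),
    error_rate = 0, frac_spliced = 0.15,
    groups = c(control = 2L, tumor = 2L))
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, cfg)
  ref <- build_l1_reference(read_rmsk_df(truth$rmsk), truth$genome)
  fc <- find_chimeras(lapply(reads$reads, `[[`, "R1"), reads$alignments,
                      truth$elements, ref$sequences,
                      read_rmsk_df(truth$rmsk))
  .fixture_env$sim <- list(cfg = cfg, truth = truth, reads = reads,
                           ref = ref, fc = fc)
  .fixture_env$sim
}

# small hand-built element table
toy_elements <- function() {
  data.frame(
    id = c("L1_A", "L1_B", "L1_C"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 40000L, 10000L),
    end = c(16000L, 46000L, 16000L),
    strand = c("+", "+", "-"),
    subfamily = c("L1PA1", "L1PA3", "L1PA2"),
    consensus_5p_offset = c(0L, 10L, 5L),
    consensus_end = c(6000L, 6000L, 6000L),
    has_asp = c(TRUE, TRUE, TRUE),
    length = c(6000L, 6000L, 6000L),
    stringsAsFactors = FALSE)
}
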