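# The standard synthetic benchmark: one function that runs the whole
# simulate -> build -> align -> call -> annotate -> evaluate pipeline under
# fixed study conditions, so tests and reproduction scripts exercise exactly
# the same configuration.

#' Run the standard repeat-genome benchmark
#'
#' Study conditions: a 100-kb genome carrying three repeat families of five
#' copies each (3 kb per copy, 1% pairwise divergence), SNVs planted at one
#' event per kilobase, error-free single-end 100-bp reads at regular-interval
#' 10x coverage, alignment with the built-in primary-placement aligner
#' (random tie-breaking), and naive pileup calling across mapping-quality
#' thresholds. Calling uses a sensitive variant-fraction threshold of 0.2
#' (the default minimum variant frequency of widely used pileup callers),
#' mirroring benchmark practice of maximizing candidates at low
#' mapping-quality thresholds and letting annotation sort them out.
#'
#' @param seed integer master seed; all stochastic stages derive their seeds
#'   from it.
#' @param genome_length,n_families,copies_per_family,repeat_length,divergence
#'   genome composition (defaults are the study conditions).
#' @param rate_per_kb planted SNV rate.
#' @param coverage,error_rate read sampling parameters.
#' @param thresholds mapping-quality thresholds for the sweep.
#' @param min_reads,min_fraction caller support thresholds.
#' @return list with the simulated inputs (`genome`, `repeats`, `truth`,
#'   `aln`, `thesaurus`), the sweep result (`sweep`), and `genome_length`.
#' @export
run_benchmark <- function(seed = 1L, genome_length = 1e5, n_families = 3L,
                          copies_per_family = 5L, repeat_length = 3000L,
                          divergence = 0.01, rate_per_kb = 1.0,
                          coverage = 10, error_rate = 0,
                          thresholds = c(0L, 1L, 30L),
                          min_reads = 2L, min_fraction = 0.2) {
  seed <- as.integer(seed)
  spec <- repeat_genome_spec(genome_length = genome_length,
                             n_families = n_families,
                             copies_per_family = copies_per_family,
                             repeat_length = repeat_length,
                             divergence = divergence, seed = seed)
  ref <- make_repeat_genome(spec)
  thesaurus <- build_thesaurus(ref$genome)
  planted <- plant_variants(ref$genome, rate_per_kb = rate_per_kb,
                            seed = seed + 1L)
  reads <- sample_reads(planted$genome, coverage = coverage,
                        error_rate = error_rate, seed = seed + 2L)
  aln <- align_reads(reads, ref$genome, seed = seed + 3L)
  sweep <- sweep_thresholds(aln, ref$genome, thesaurus, planted$truth,
                            thresholds = thresholds, min_reads = min_reads,
                            min_fraction = min_fraction)
  list(spec = spec, genome = ref$genome, repeats = ref$repeats,
       truth = planted$truth, reads = reads, aln = aln,
       thesaurus = thesaurus, sweep = sweep,
       genome_length = sum(genome_lengths(ref$genome)))
}
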