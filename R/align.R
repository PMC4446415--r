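# Primary-placement alignment of simulated reads.
#
# The benchmark needs a conventional alignment (one placement per read with a
# mapping quality) as input to calling and annotation. This aligner reuses
# the thesaurus all-mapper to enumerate placements and then reports a single
# primary one, mimicking how short-read aligners handle multi-mapping reads:
# the placement with the fewest mismatches wins, ties are broken uniformly at
# random (seeded), and the mapping quality reflects placement confidence.

MQ_UNIQUE <- 40L      # only one placement exists at all
MQ_BEST <- 23L        # several placements, but a unique best
MQ_AMBIGUOUS <- 0L    # tied best placements, position chosen at random

#' Align reads to a genome, reporting one primary placement per read
#'
#' @param reads data frame with columns `read_id` and `seq` (e.g. from
#'   [sample_reads()]).
#' @param genome named character vector (the reference).
#' @param index optional precomputed [build_seed_index()] over `genome`.
#' @param max_mm,protected all-mapper constraints.
#' @param seed seed for random tie-breaking among equally good placements.
#' @return alignment data frame in the [read_alignments()] layout, with an
#'   extra `n_mismatch` column; unmapped reads are dropped and counted in
#'   attribute `n_unmapped`.
#' @export
align_reads <- function(reads, genome, index = NULL, max_mm = 4L,
                        protected = 5L, seed = 1L) {
  if (is.null(index)) index <- build_seed_index(genome, protected)
  graw <- genome_as_raw(genome)
  n <- nrow(reads)
  qname <- character(n); chrom <- character(n); pos <- integer(n)
  mapq <- integer(n); strand <- character(n); seqs <- character(n)
  nmm <- integer(n)
  kept <- logical(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      hits <- all_map_core(reads$seq[i], index, graw, max_mm = max_mm,
                           protected = protected)
      if (is.null(hits) || length(hits$start) == 0) next
      n_hits <- length(hits$start)
      best <- which(hits$n_mismatch == min(hits$n_mismatch))
      pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
      mq <- if (n_hits == 1) MQ_UNIQUE else if (length(best) == 1) MQ_BEST
            else MQ_AMBIGUOUS
      kept[i] <- TRUE
      qname[i] <- reads$read_id[i]
      chrom[i] <- hits$chrom[pick]
      pos[i] <- hits$start[pick]
      mapq[i] <- mq
      strand[i] <- hits$strand[pick]
      seqs[i] <- if (hits$strand[pick] == "-") revcomp(reads$seq[i]) else reads$seq[i]
      nmm[i] <- hits$n_mismatch[pick]
    }
  })
  L <- nchar(reads$seq)
  aln <- data.frame(
    qname = qname[kept],
    flag = ifelse(strand[kept] == "-", 16L, 0L),
    chrom = chrom[kept], pos = pos[kept], mapq = mapq[kept],
    cigar = sprintf("%dM", L[kept]), strand = strand[kept], seq = seqs[kept],
    n_mismatch = nmm[kept], stringsAsFactors = FALSE)
  aln <- aln[order(aln$chrom, aln$pos), ]
  rownames(aln) <- NULL
  attr(aln, "n_unmapped") <- sum(!kept)
  aln
}
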