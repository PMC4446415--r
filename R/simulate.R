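# Synthetic data: repeat-family genomes, planted SNVs, tiled and shotgun
# reads, and the small worked example used to illustrate thesaurus-aware
# accounting.

#' Specification for a synthetic repeat-family genome
#'
#' @param genome_length total genome length in bp (one chromosome, `chr1`).
#' @param n_families number of independent repeat families.
#' @param copies_per_family copies of each family inserted into the genome.
#' @param repeat_length length of each repeat copy in bp.
#' @param divergence expected pairwise substitution fraction between two
#'   copies of the same family (each copy is mutated from the family master
#'   at half this rate). Must stay within 0.04 so 100-bp reads from one copy
#'   remain within the all-mapper's four-mismatch reach of the others.
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return object of class `repeat_genome_spec`.
#' @export
repeat_genome_spec <- function(genome_length = 1e5, n_families = 3,
                               copies_per_family = 5, repeat_length = 3000,
                               divergence = 0.01, seed = 1) {
  spec <- list(genome_length = as.integer(genome_length),
               n_families = as.integer(n_families),
               copies_per_family = as.integer(copies_per_family),
               repeat_length = as.integer(repeat_length),
               divergence = divergence, seed = as.integer(seed))
  if (spec$divergence < 0 || spec$divergence > 0.04) {
    stop("divergence must lie in [0, 0.04]", call. = FALSE)
  }
  if (spec$repeat_length * spec$copies_per_family * spec$n_families >
      spec$genome_length) {
    stop("repeat copies exceed genome capacity", call. = FALSE)
  }
  structure(spec, class = "repeat_genome_spec")
}

#' Generate a repeat-family genome
#'
#' The background is i.i.d. uniform A/C/G/T. Each family has a random master
#' sequence; copies are the master with per-base substitutions at half the
#' divergence rate (so two copies differ pairwise by about
#' `divergence * repeat_length` bases). Copies are placed at random
#' non-overlapping positions.
#'
#' @param spec a [repeat_genome_spec()].
#' @return list with `genome` (named character vector) and `repeats` (data
#'   frame: family, copy, chrom, start, end).
#' @export
make_repeat_genome <- function(spec) {
  stopifnot(inherits(spec, "repeat_genome_spec"))
  with_seed(spec$seed, {
    n_copies <- spec$n_families * spec$copies_per_family
    chars <- sample(BASES, spec$genome_length, replace = TRUE)
    # Non-overlapping placement: distribute the free space into random gaps
    # before each copy (stars and bars).
    free <- spec$genome_length - n_copies * spec$repeat_length
    cuts <- sort(stats::runif(n_copies))
    gaps <- floor(diff(c(0, cuts)) * free)
    starts <- cumsum(gaps + spec$repeat_length) - spec$repeat_length + 1L
    fam <- rep(seq_len(spec$n_families), each = spec$copies_per_family)
    # Shuffle which slot belongs to which family so copies interleave.
    fam <- sample(fam)
    masters <- vapply(seq_len(spec$n_families),
                      function(i) random_dna(spec$repeat_length), character(1))
    copy_idx <- integer(spec$n_families)
    rep_rows <- vector("list", n_copies)
    for (i in seq_len(n_copies)) {
      f <- fam[i]
      copy_idx[f] <- copy_idx[f] + 1L
      mut <- mutate_sequence(masters[f], spec$divergence / 2)
      chars[starts[i]:(starts[i] + spec$repeat_length - 1L)] <-
        strsplit(mut$seq, "", fixed = TRUE)[[1]]
      rep_rows[[i]] <- data.frame(family = f, copy = copy_idx[f], chrom = "chr1",
                                  start = starts[i],
                                  end = starts[i] + spec$repeat_length - 1L)
    }
    repeats <- do.call(rbind, rep_rows)
    repeats <- repeats[order(repeats$start), ]
    rownames(repeats) <- NULL
    list(genome = c(chr1 = paste(chars, collapse = "")), repeats = repeats)
  })
}

#' Plant single-nucleotide variants into a genome
#'
#' Every base mutates independently with probability `rate_per_kb / 1000`,
#' modelling a constant event rate per kilobase rather than a fixed count.
#'
#' @param genome named character vector (the reference).
#' @param rate_per_kb expected SNVs per kilobase.
#' @param seed integer seed.
#' @return list with `genome` (the sample genome) and `truth` (data frame:
#'   chrom, pos, ref, alt).
#' @export
plant_variants <- function(genome, rate_per_kb = 1.0, seed = 1) {
  stopifnot(rate_per_kb >= 0)
  with_seed(seed, {
    truth <- list()
    out <- genome
    for (chrom in names(genome)) {
      mut <- mutate_sequence(genome[[chrom]], rate_per_kb / 1000)
      out[[chrom]] <- mut$seq
      if (length(mut$pos) > 0) {
        truth[[chrom]] <- data.frame(chrom = chrom, pos = mut$pos,
                                     ref = mut$ref, alt = mut$alt,
                                     stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(genome = out, truth = truth)
  })
}

#' Tile error-free reads across a genome
#'
#' Reads of length `read_len` start every `step` bases, so interior positions
#' are covered by exactly `read_len / step` reads. Chromosomes shorter than
#' `read_len` are skipped with a warning.
#'
#' @param genome named character vector.
#' @param read_len read length in bp.
#' @param step distance between consecutive read starts in bp.
#' @return data frame: read_id, chrom, start, seq.
#' @export
tile_reads <- function(genome, read_len = 100L, step = 10L) {
  stopifnot(read_len >= 1, step >= 1)
  out <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    if (n < read_len) {
      warning("chromosome ", chrom, " shorter than read length; skipped")
      next
    }
    starts <- seq.int(1L, n - read_len + 1L, by = step)
    out[[chrom]] <- data.frame(
      read_id = sprintf("%s_%d", chrom, starts),
      chrom = chrom, start = starts,
      seq = substring(genome[[chrom]], starts, starts + read_len - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample shotgun reads from a genome
#'
#' Substitution errors only; no indels and no quality model. In `regular`
#' mode read starts are spaced `read_len / coverage` apart so every interior
#' base is covered by exactly `coverage` reads; `random` mode draws uniform
#' start positions. Strands alternate deterministically in regular mode and
#' are random in random mode. Optional paired-end output uses a fixed insert
#' size with both mates under the same error model.
#'
#' @param genome named character vector (the sample genome).
#' @param coverage target mean depth.
#' @param error_rate per-base substitution error probability (< 0.1).
#' @param read_len read length in bp.
#' @param seed integer seed.
#' @param mode `"regular"` or `"random"` start placement.
#' @param paired generate read pairs instead of single-end reads.
#' @param insert_size outer fragment length for paired mode.
#' @return data frame: read_id, chrom, start, end, strand, mate, seq. The
#'   chrom/start/end/strand columns record the true origin (the sidecar);
#'   `seq` is in sequencing orientation.
#' @export
sample_reads <- function(genome, coverage = 10, error_rate = 0,
                         read_len = 100L, seed = 1,
                         mode = c("regular", "random"),
                         paired = FALSE, insert_size = 300L) {
  mode <- match.arg(mode)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.1)
  read_len <- as.integer(read_len)
  insert_size <- as.integer(insert_size)
  with_seed(seed, {
    out <- list()
    for (chrom in names(genome)) {
      n <- nchar(genome[[chrom]])
      if (n < read_len || (paired && n < insert_size)) next
      if (paired) {
        span <- insert_size
        stride <- max(1L, as.integer(round(2 * read_len / coverage)))
      } else {
        span <- read_len
        stride <- max(1L, as.integer(round(read_len / coverage)))
      }
      frag_starts <- if (mode == "regular") {
        seq.int(1L, n - span + 1L, by = stride)
      } else {
        sort(sample.int(n - span + 1L,
                        size = max(1L, as.integer(round(coverage * n / span / (if (paired) 2 else 1)))),
                        replace = TRUE))
      }
      if (paired) {
        s1 <- frag_starts
        s2 <- frag_starts + span - read_len
        r1 <- substring(genome[[chrom]], s1, s1 + read_len - 1L)
        r2 <- revcomp(substring(genome[[chrom]], s2, s2 + read_len - 1L))
        ids <- sprintf("%s_f%d", chrom, frag_starts)
        out[[chrom]] <- data.frame(
          read_id = c(ids, ids), chrom = chrom,
          start = c(s1, s2), end = c(s1, s2) + read_len - 1L,
          strand = rep(c("+", "-"), each = length(s1)),
          mate = rep(1:2, each = length(s1)),
          seq = c(r1, r2), stringsAsFactors = FALSE)
      } else {
        strand <- if (mode == "regular") {
          rep_len(c("+", "-"), length(frag_starts))
        } else {
          sample(c("+", "-"), length(frag_starts), replace = TRUE)
        }
        sq <- substring(genome[[chrom]], frag_starts, frag_starts + read_len - 1L)
        sq[strand == "-"] <- revcomp(sq[strand == "-"])
        out[[chrom]] <- data.frame(
          read_id = sprintf("%s_r%d%s", chrom, frag_starts, ifelse(strand == "-", "m", "p")),
          chrom = chrom, start = frag_starts, end = frag_starts + read_len - 1L,
          strand = strand, mate = 1L, seq = sq, stringsAsFactors = FALSE)
      }
    }
    reads <- if (length(out) > 0) do.call(rbind, out) else
      data.frame(read_id = character(0), chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0), mate = integer(0),
                 seq = character(0), stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    if (error_rate > 0 && nrow(reads) > 0) {
      reads$seq <- vapply(reads$seq, function(s) mutate_sequence(s, error_rate)$seq,
                          character(1), USE.NAMES = FALSE)
    }
    reads
  })
}

#' The worked example: three truths, five calls, and their links
#'
#' A 1-kb illustrative genome with three true variants and five candidate
#' calls arranged in three scenarios: a mutual pair where one true variant is
#' called at both similar loci; a call reported only at the wrong locus with
#' a link back to the true (uncalled) site; and a true variant called at its
#' own locus plus one alternate, the alternate also linking to a third,
#' uncalled site. Local accounting gives TP=2, FP=3, FN=1; thesaurus-aware
#' accounting turns every wrongly placed call into a thesaurus true positive
#' and leaves no false positives or negatives.
#'
#' @return list with `truth`, `calls`, `links` data frames and
#'   `genome_length = 1000`.
#' @export
worked_example_fixture <- function() {
  chrom <- "chrW"
  truth <- data.frame(chrom = chrom, pos = c(100L, 400L, 700L),
                      ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(chrom = chrom, pos = c(100L, 150L, 420L, 700L, 750L),
                      id = ".", ref = c("A", "A", "C", "G", "G"),
                      alt = c("G", "G", "T", "A", "A"),
                      qual = ".", filter = "PASS", info = ".",
                      stringsAsFactors = FALSE)
  links <- data.frame(
    from_chrom = chrom, from_pos = c(100L, 150L, 420L, 700L, 750L, 750L),
    to_chrom = chrom, to_pos = c(150L, 100L, 400L, 750L, 700L, 800L),
    strand = "+",
    proj_ref = c("A", "A", "C", "G", "G", "G"),
    proj_alt = c("G", "G", "T", "A", "A", "A"),
    stringsAsFactors = FALSE)
  list(truth = truth, calls = calls, links = links, genome_length = 1000L)
}
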