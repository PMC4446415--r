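# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Byte-level complement lookup (A<->T, C<->G, case preserved, N fixed,
# everything else unchanged) for fast reverse complements without string-set
# overhead in the mapper's inner loop.
COMP_TABLE <- local({
  tab <- as.raw(0:255)
  from <- utf8ToInt("ACGTacgt")
  to <- utf8ToInt("TGCAtgca")
  tab[from + 1L] <- as.raw(to)
  tab
})

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) rawToChar(rev(COMP_TABLE[as.integer(charToRaw(s)) + 1L])),
         character(1), USE.NAMES = FALSE)
}

# Complement without reversing (single bases or strings).
complement_bases <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Random DNA string(s) of given length.
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Substitute each base with probability p by a uniformly chosen *other* base.
# Returns list(seq = mutated string, pos = 1-based substituted positions,
# ref = original bases, alt = new bases).
mutate_sequence <- function(seq, p) {
  n <- nchar(seq)
  if (n == 0 || p <= 0) {
    return(list(seq = seq, pos = integer(0), ref = character(0), alt = character(0)))
  }
  hit <- which(stats::runif(n) < p)
  if (length(hit) == 0) {
    return(list(seq = seq, pos = integer(0), ref = character(0), alt = character(0)))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- chars[hit]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                USE.NAMES = FALSE)
  chars[hit] <- alt
  list(seq = paste(chars, collapse = ""), pos = hit, ref = ref, alt = alt)
}

# Genome as a list of raw byte vectors (one per chromosome) for fast
# vectorized comparison.
genome_as_raw <- function(genome) {
  lapply(genome, charToRaw)
}

# Named integer vector of chromosome lengths.
genome_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

# Stop unless all chromosomes named in `chroms` exist in `genome`.
check_chroms <- function(chroms, genome) {
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) absent from the reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Key strings for (chrom, pos) pairs, used for set logic on genomic sites.
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
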