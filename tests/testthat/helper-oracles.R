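# Independent oracles and random-fixture generators used across tests.

rand_genome <- function(len, seed, chroms = "chr1") {
  set.seed(seed)
  stats::setNames(
    vapply(seq_along(chroms),
           function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                             collapse = ""),
           character(1)),
    chroms)
}

# Exhaustive all-mapper oracle: slide the read over every position of every
# chromosome and strand, apply the three constraints (ungapped; at most
# max_mm mismatches; clean protected terminals) directly.
oracle_all_map <- function(read, genome, max_mm = 4L, protected = 5L) {
  L <- nchar(read)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    qc <- strsplit(q, "")[[1]]
    for (chrom in names(genome)) {
      gc <- strsplit(genome[[chrom]], "")[[1]]
      n <- length(gc)
      for (s in seq_len(max(0L, n - L + 1L))) {
        neq <- gc[s:(s + L - 1L)] != qc
        if (sum(neq) > max_mm) next
        if (any(neq[c(1:protected, (L - protected + 1L):L)])) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s + L - 1L, strand = strand,
          n_mismatch = sum(neq), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), ]
}

# Plain union-find, the independent connectivity oracle for clustering.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Random valid thesaurus entries (canonical order not enforced; sortedness
# applied by the caller when required).
rand_entries <- function(n, seed, chroms = c("chr1", "chr2"), chrom_len = 10000L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(50:400, 1)
    os <- sample.int(chrom_len - len, 1)
    as_ <- sample.int(chrom_len - len, 1)
    strand <- sample(c("+", "-"), 1)
    n_mm <- sample(0:3, 1)
    mm <- if (n_mm == 0) "." else {
      pos <- sort(sample(os:(os + len - 1L), n_mm))
      bases <- c("A", "C", "G", "T")
      paste(sprintf("%d:%s:%s", pos, sample(bases, n_mm, TRUE),
                    sample(bases, n_mm, TRUE)), collapse = ";")
    }
    data.frame(origin_chrom = sample(chroms, 1), origin_start = os,
               origin_end = os + len - 1L, alt_chrom = sample(chroms, 1),
               alt_start = as_, alt_end = as_ + len - 1L, strand = strand,
               mismatches = mm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Two-copy repeat genome built by hand: background plus two copies of one
# repeat sequence with `n_diff` planted differences between the copies.
two_copy_genome <- function(seed, bg_len = 4000L, rep_len = 500L,
                            pos1 = 1001L, pos2 = 3001L, n_diff = 0L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  bg <- sample(bases, bg_len, replace = TRUE)
  rep1 <- sample(bases, rep_len, replace = TRUE)
  rep2 <- rep1
  diff_pos <- integer(0)
  if (n_diff > 0) {
    diff_pos <- sort(sample(seq(20L, rep_len - 20L), n_diff))
    for (p in diff_pos) rep2[p] <- sample(setdiff(bases, rep2[p]), 1)
  }
  g <- bg
  g[pos1:(pos1 + rep_len - 1L)] <- rep1
  g[pos2:(pos2 + rep_len - 1L)] <- rep2
  list(genome = c(chr1 = paste(g, collapse = "")),
       pos1 = pos1, pos2 = pos2, rep_len = rep_len, diff_pos = diff_pos)
}
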