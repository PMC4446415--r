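# Thesaurus construction: a terminal-seed ungapped all-mapper over tiled
# reads, conversion of alternate placements to region-pair entries, and
# merging/extension into the final sorted table.

#' Build a k-mer seed index over a genome
#'
#' Indexes every forward-strand k-mer occurrence; minus-strand lookups are
#' served by querying the reverse complement of a seed. The default k equals
#' the protected terminal length of the all-mapper, because those terminal
#' bases are the only seeds used for alignment.
#'
#' @param genome named character vector.
#' @param k seed length.
#' @return object of class `seed_index`.
#' @export
build_seed_index <- function(genome, k = 5L) {
  stopifnot(k >= 1)
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    stop("cannot index an empty genome", call. = FALSE)
  }
  if (k > min(nchar(genome))) {
    stop("seed length k exceeds the shortest chromosome", call. = FALSE)
  }
  idx <- lapply(genome, function(seq) {
    n <- nchar(seq)
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    split(starts, kmers)
  })
  structure(list(k = as.integer(k), index = idx, chroms = names(genome)),
            class = "seed_index")
}

#' Look up the occurrences of a k-mer in a seed index
#'
#' @param index a `seed_index`.
#' @param kmer seed sequence of length `index$k`.
#' @return data frame chrom, pos, strand: forward matches of `kmer` as "+",
#'   forward matches of its reverse complement as "-".
#' @export
seed_hits <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"), nchar(kmer) == index$k)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") kmer else revcomp(kmer)
    for (chrom in index$chroms) {
      pos <- index$index[[chrom]][[q]]
      if (!is.null(pos)) {
        rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                                strand = strand,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Core of the all-mapper: candidate start positions for query `q` (already in
# the orientation to be compared against the forward genome).
candidate_starts <- function(q, index, chrom, L) {
  k <- index$k
  s1 <- index$index[[chrom]][[substr(q, 1L, k)]]
  s2 <- index$index[[chrom]][[substr(q, L - k + 1L, L)]]
  out <- c(if (!is.null(s1)) s1, if (!is.null(s2)) s2 - (L - k))
  if (is.null(out)) integer(0) else sort(unique(out))
}

#' Enumerate all ungapped placements of a read
#'
#' Seed-and-extend all-mapper: candidate placements are anchored by exact
#' matches of the first or last `protected` bases (both strands), then the
#' whole read is compared without gaps. A placement is reported when it has
#' at most `max_mm` mismatches in total and none within the protected
#' terminal bases. Reads containing non-ACGT characters yield no placements
#' (ambiguity codes carry no linkage information); such reads are flagged via
#' the `skipped` attribute.
#'
#' @param read read sequence (plain string).
#' @param index a `seed_index` built over `genome`.
#' @param genome named character vector.
#' @param max_mm maximum mismatches per placement.
#' @param protected terminal bases that must match exactly.
#' @param graw optional precomputed `genome_as_raw(genome)` for repeated calls.
#' @return data frame: chrom, start, end, strand, n_mismatch, mismatches.
#'   Mismatches are "offset:read_base:genome_base" triples in read
#'   coordinates and read orientation, joined by ";" ("." if none).
#' @export
all_map_read <- function(read, index, genome, max_mm = 4L, protected = 5L,
                         graw = NULL) {
  if (is.null(graw)) graw <- genome_as_raw(genome)
  core <- all_map_core(read, index, graw, max_mm, protected)
  if (is.null(core)) {
    out <- empty_placements()
    attr(out, "skipped") <- 1L
    return(out)
  }
  out <- as.data.frame(core, stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(empty_placements())
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Inner loop of the all-mapper, free of data-frame overhead: returns a list
# of parallel vectors (chrom, start, end, strand, n_mismatch, mismatches),
# or NULL for reads containing non-ACGT characters.
all_map_core <- function(read, index, graw, max_mm = 4L, protected = 5L) {
  L <- nchar(read)
  stopifnot(L > 2L * protected)
  if (grepl("[^ACGT]", read)) return(NULL)
  prot_idx <- c(seq_len(protected), (L - protected + 1L):L)
  chrom_v <- character(0); start_v <- integer(0); strand_v <- character(0)
  nmm_v <- integer(0); mm_v <- character(0)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    qraw <- charToRaw(q)
    for (chrom in index$chroms) {
      g <- graw[[chrom]]
      starts <- candidate_starts(q, index, chrom, L)
      starts <- starts[starts >= 1L & starts <= length(g) - L + 1L]
      if (length(starts) == 0) next
      m <- matrix(g[rep(starts - 1L, each = L) + seq_len(L)], nrow = L)
      neq <- m != qraw
      mmc <- colSums(neq)
      ok <- mmc <= max_mm & colSums(neq[prot_idx, , drop = FALSE]) == 0L
      if (!any(ok)) next
      mm_str <- vapply(which(ok), function(j) {
        offs_q <- which(neq[, j])
        if (length(offs_q) == 0) return(".")
        gb <- rawToChar(m[offs_q, j], multiple = TRUE)
        if (strand == "+") {
          offs_r <- offs_q
          rb <- rawToChar(qraw[offs_q], multiple = TRUE)
        } else {
          offs_r <- L + 1L - offs_q
          rb <- complement_bases(rawToChar(qraw[offs_q], multiple = TRUE))
          gb <- complement_bases(gb)
        }
        o <- order(offs_r)
        paste(sprintf("%d:%s:%s", offs_r[o], rb[o], gb[o]), collapse = ";")
      }, character(1))
      n_ok <- sum(ok)
      chrom_v <- c(chrom_v, rep(chrom, n_ok))
      start_v <- c(start_v, starts[ok])
      strand_v <- c(strand_v, rep(strand, n_ok))
      nmm_v <- c(nmm_v, as.integer(mmc[ok]))
      mm_v <- c(mm_v, mm_str)
    }
  }
  list(chrom = chrom_v, start = start_v, end = start_v + L - 1L,
       strand = strand_v, n_mismatch = nmm_v, mismatches = mm_v)
}

empty_placements <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), n_mismatch = integer(0),
             mismatches = character(0), stringsAsFactors = FALSE)
}

#' Convert tiled-read placements to thesaurus entries
#'
#' Each non-trivial placement of a tiled read (whose true origin is known)
#' becomes one region-pair entry. The trivial self-placement is dropped, as
#' are placements with more than `max_entry_mm` mismatches. Mismatches are
#' re-expressed in origin coordinates; entries are canonicalized so the
#' lexicographically smaller interval is the origin side.
#'
#' @param placements data frame from the all-mapper with added columns
#'   `origin_chrom` and `origin_start` (true origin of each read).
#' @param max_entry_mm maximum recorded mismatches per entry.
#' @return entry data frame (see [thesaurus_table()]).
#' @export
alignments_to_entries <- function(placements, max_entry_mm = 3L) {
  if (nrow(placements) == 0) return(empty_entries())
  L <- placements$end - placements$start + 1L
  self <- placements$strand == "+" &
    placements$chrom == placements$origin_chrom &
    placements$start == placements$origin_start
  keep <- !self & placements$n_mismatch <= max_entry_mm
  p <- placements[keep, , drop = FALSE]
  if (nrow(p) == 0) return(empty_entries())
  L <- L[keep]
  # Re-express read-coordinate mismatches in origin coordinates. The read is
  # an exact copy of its origin, so read bases are origin bases and the
  # genome base (already in read orientation) is the strand-normalized alt.
  mm <- vapply(seq_len(nrow(p)), function(i) {
    s <- p$mismatches[i]
    if (s == ".") return(".")
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    off <- as.integer(vapply(parts, `[[`, character(1), 1L))
    paste(sprintf("%d:%s:%s", p$origin_start[i] + off - 1L,
                  vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 3L)), collapse = ";")
  }, character(1))
  entries <- data.frame(
    origin_chrom = p$origin_chrom, origin_start = p$origin_start,
    origin_end = p$origin_start + L - 1L,
    alt_chrom = p$chrom, alt_start = p$start, alt_end = p$end,
    strand = p$strand, mismatches = mm, stringsAsFactors = FALSE)
  canonicalize_entries(entries)
}

# Put each entry in canonical order: origin side lexicographically <= alt side.
canonicalize_entries <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  flip <- entries$alt_chrom < entries$origin_chrom |
    (entries$alt_chrom == entries$origin_chrom &
       entries$alt_start < entries$origin_start)
  if (any(flip)) {
    entries[flip, ] <- mirror_entries(entries[flip, , drop = FALSE])
  }
  entries
}

#' Merge and extend thesaurus entries
#'
#' Entries sharing chromosome pair, orientation and diagonal offset whose
#' origin intervals overlap or abut are merged into a single entry covering
#' their union, with mismatch lists unioned. Merged regions are then extended
#' `extend` bp in both directions (clipped at chromosome ends) to account for
#' incomplete read sampling and for alignments lost to mismatched seeds.
#'
#' @param entries entry data frame.
#' @param extend extension in bp applied after merging (0 disables).
#' @param chrom_lengths named integer vector used for clipping; without it no
#'   extension is applied beyond coordinate 1 clipping.
#' @param apply_extension set to `FALSE` to merge without extending.
#' @return sorted, merged entry data frame.
#' @export
merge_entries <- function(entries, extend = 10L, chrom_lengths = NULL,
                          apply_extension = TRUE) {
  entries <- unique(entries)
  if (nrow(entries) == 0) return(entries)
  diag <- ifelse(entries$strand == "+",
                 entries$alt_start - entries$origin_start,
                 entries$alt_end + entries$origin_start)
  key <- paste(entries$origin_chrom, entries$alt_chrom, entries$strand, diag,
               sep = "\r")
  out <- list()
  for (grp in split(seq_len(nrow(entries)), key)) {
    e <- entries[grp, , drop = FALSE]
    e <- e[order(e$origin_start), , drop = FALSE]
    run_end <- cummax(e$origin_end)
    new_run <- c(TRUE, e$origin_start[-1] > run_end[-nrow(e)] + 1L)
    run_id <- cumsum(new_run)
    for (r in split(seq_len(nrow(e)), run_id)) {
      os <- min(e$origin_start[r]); oe <- max(e$origin_end[r])
      strand <- e$strand[r[1]]
      d <- if (strand == "+") e$alt_start[r[1]] - e$origin_start[r[1]] else
        e$alt_end[r[1]] + e$origin_start[r[1]]
      mmdf <- do.call(rbind, parse_mismatch_strings(e$mismatches[r]))
      mmdf <- unique(mmdf)
      out[[length(out) + 1L]] <- data.frame(
        origin_chrom = e$origin_chrom[r[1]], origin_start = os, origin_end = oe,
        alt_chrom = e$alt_chrom[r[1]],
        alt_start = if (strand == "+") os + d else d - oe,
        alt_end = if (strand == "+") oe + d else d - os,
        strand = strand, mismatches = format_mismatch_df(mmdf),
        stringsAsFactors = FALSE)
    }
  }
  merged <- do.call(rbind, out)
  if (apply_extension && extend > 0) {
    len_of <- function(chrom) {
      if (is.null(chrom_lengths)) rep(.Machine$integer.max, length(chrom))
      else unname(chrom_lengths[chrom])
    }
    lo <- len_of(merged$origin_chrom); la <- len_of(merged$alt_chrom)
    plus <- merged$strand == "+"
    ext_l <- pmin(extend, merged$origin_start - 1L,
                  ifelse(plus, merged$alt_start - 1L, la - merged$alt_end))
    ext_r <- pmin(extend, lo - merged$origin_end,
                  ifelse(plus, la - merged$alt_end, merged$alt_start - 1L))
    merged$origin_start <- merged$origin_start - ext_l
    merged$origin_end <- merged$origin_end + ext_r
    merged$alt_start <- merged$alt_start - ifelse(plus, ext_l, ext_r)
    merged$alt_end <- merged$alt_end + ifelse(plus, ext_r, ext_l)
  }
  # Drop degenerate self-links (an interval linked to itself without any
  # recorded difference carries no information).
  degenerate <- merged$strand == "+" &
    merged$origin_chrom == merged$alt_chrom &
    merged$origin_start == merged$alt_start &
    merged$mismatches == "."
  merged <- merged[!degenerate, , drop = FALSE]
  sort_entries(merged)
}

#' Build a thesaurus table for a genome
#'
#' Composition of the full pipeline: tile error-free reads across the
#' genome, enumerate all their ungapped placements, convert non-trivial
#' placements to region-pair entries, then merge, extend and sort them. The
#' result records every pair of genome regions similar enough for reads to
#' migrate between them.
#'
#' @param genome named character vector.
#' @param read_len,step tiling parameters.
#' @param max_mm all-mapper mismatch cap per placement.
#' @param entry_mm recorded-mismatch cap per entry.
#' @param seed_len seed length (also the protected terminal length).
#' @param extend post-merge extension in bp.
#' @param progress print a line per chromosome.
#' @return a `thesaurus_table` with the build parameters in its header.
#' @export
build_thesaurus <- function(genome, read_len = 100L, step = 10L, max_mm = 4L,
                            entry_mm = 3L, seed_len = 5L, extend = 10L,
                            progress = FALSE) {
  reads <- tile_reads(genome, read_len, step)
  index <- build_seed_index(genome, seed_len)
  graw <- genome_as_raw(genome)
  parts <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    hits <- all_map_core(reads$seq[i], index, graw, max_mm = max_mm,
                         protected = seed_len)
    if (is.null(hits) || length(hits$start) == 0) next
    nontrivial <- !(hits$strand == "+" & hits$chrom == reads$chrom[i] &
                      hits$start == reads$start[i])
    if (!any(nontrivial)) next
    hits <- lapply(hits, `[`, nontrivial)
    hits$origin_chrom <- rep(reads$chrom[i], length(hits$start))
    hits$origin_start <- rep(reads$start[i], length(hits$start))
    parts[[i]] <- hits
    if (progress && i %% 2000 == 0) {
      message("  mapped ", i, "/", nrow(reads), " tiled reads")
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  entries <- if (length(parts) > 0) {
    placements <- as.data.frame(
      lapply(stats::setNames(nm = names(parts[[1]])),
             function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)),
      stringsAsFactors = FALSE)
    alignments_to_entries(placements, max_entry_mm = entry_mm)
  } else {
    empty_entries()
  }
  merged <- merge_entries(entries, extend = extend,
                          chrom_lengths = genome_lengths(genome))
  thesaurus_table(merged, header = list(read_len = read_len, step = step,
                                        max_mm = max_mm, entry_mm = entry_mm,
                                        seed_len = seed_len, extend = extend))
}
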