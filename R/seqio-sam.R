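# Plain-text SAM input/output for aligned reads.
#
# The package exchanges alignments as data frames with columns
# qname, flag, chrom, pos (1-based leftmost), mapq, cigar, strand ("+"/"-")
# and seq (read bases in reference orientation, as stored in SAM).

SAM_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar", "strand", "seq")

#' Read aligned reads from a SAM file
#'
#' Only mapped records are returned; the number of unmapped records skipped
#' is attached as attribute `n_unmapped`. CIGAR strings are preserved
#' verbatim so that downstream steps can detect insertions, deletions and
#' splice junctions.
#'
#' @param path path to a plain-text SAM file.
#' @return data frame of mapped reads (see module description for columns).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0) {
    aln <- empty_alignments()
    attr(aln, "n_unmapped") <- 0L
    return(aln)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0) {
    stop("truncated SAM record at line ", body_idx[bad[1]], call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  aln <- data.frame(
    qname = vapply(fields, `[[`, character(1), 1L),
    flag = flag,
    chrom = vapply(fields, `[[`, character(1), 3L),
    pos = as.integer(vapply(fields, `[[`, character(1), 4L)),
    mapq = as.integer(vapply(fields, `[[`, character(1), 5L)),
    cigar = vapply(fields, `[[`, character(1), 6L),
    seq = toupper(vapply(fields, `[[`, character(1), 10L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(aln$pos) || anyNA(aln$mapq)) {
    stop("malformed SAM record: non-numeric POS or MAPQ", call. = FALSE)
  }
  aln$strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
  out <- aln[mapped, SAM_COLS]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Write aligned reads to a SAM file
#'
#' @param aln alignment data frame (see [read_alignments()]).
#' @param chrom_lengths named integer vector of reference sequence lengths,
#'   used for the `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(aln) > 0) {
    ord <- order(match(aln$chrom, names(chrom_lengths)), aln$pos)
    aln <- aln[ord, ]
    flag <- if ("flag" %in% names(aln)) aln$flag else ifelse(aln$strand == "-", 16L, 0L)
    quals <- vapply(nchar(aln$seq), function(n) strrep("I", n), character(1))
    writeLines(paste(aln$qname, flag, aln$chrom, aln$pos, aln$mapq, aln$cigar,
                     "*", 0L, 0L, aln$seq, quals, sep = "\t"), con)
  }
  invisible(path)
}

empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), chrom = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             strand = character(0), seq = character(0), stringsAsFactors = FALSE)
}

# Length of the reference span consumed by a CIGAR string.
cigar_ref_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    if (length(m) == 0) return(NA_integer_)
    len <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- sub("\\d+", "", m)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

has_indel_or_splice <- function(cigar) {
  grepl("[0-9]+[IDN]", cigar)
}

# Per-read mismatches versus the reference, walking the CIGAR. Returns a data
# frame (row index into aln, chrom, gpos, read_base). Insertions and clips are
# skipped; deleted/skipped reference bases are not counted as mismatches (the
# has_indel flag covers them).
alignment_mismatches <- function(aln, genome) {
  if (nrow(aln) == 0) {
    return(data.frame(row = integer(0), chrom = character(0), gpos = integer(0),
                      read_base = character(0), stringsAsFactors = FALSE))
  }
  check_chroms(aln$chrom, genome)
  graw <- genome_as_raw(genome)
  simple <- grepl("^[0-9]+M$", aln$cigar)
  out <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    chrom <- aln$chrom[i]
    g <- graw[[chrom]]
    if (simple[i]) {
      r <- charToRaw(aln$seq[i])
      span <- length(r)
      if (aln$pos[i] + span - 1L > length(g)) next
      gseg <- g[aln$pos[i]:(aln$pos[i] + span - 1L)]
      mm <- which(gseg != r)
      if (length(mm) > 0) {
        out[[i]] <- data.frame(row = i, chrom = chrom,
                               gpos = aln$pos[i] + mm - 1L,
                               read_base = rawToChar(r[mm], multiple = TRUE),
                               stringsAsFactors = FALSE)
      }
    } else {
      m <- regmatches(aln$cigar[i], gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
      len <- as.integer(sub("[MIDNSHP=X]", "", m))
      op <- sub("\\d+", "", m)
      rpos <- 1L; gpos <- aln$pos[i]
      r <- charToRaw(aln$seq[i])
      acc <- list()
      for (j in seq_along(op)) {
        if (op[j] %in% c("M", "=", "X")) {
          idx <- seq_len(len[j])
          if (gpos + len[j] - 1L <= length(g)) {
            gseg <- g[gpos + idx - 1L]
            rseg <- r[rpos + idx - 1L]
            mm <- which(gseg != rseg)
            if (length(mm) > 0) {
              acc[[length(acc) + 1L]] <- data.frame(
                row = i, chrom = chrom, gpos = gpos + mm - 1L,
                read_base = rawToChar(rseg[mm], multiple = TRUE),
                stringsAsFactors = FALSE)
            }
          }
          rpos <- rpos + len[j]; gpos <- gpos + len[j]
        } else if (op[j] %in% c("I", "S")) {
          rpos <- rpos + len[j]
        } else if (op[j] %in% c("D", "N")) {
          gpos <- gpos + len[j]
        }
      }
      if (length(acc) > 0) out[[i]] <- do.call(rbind, acc)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(row = integer(0), chrom = character(0), gpos = integer(0),
                      read_base = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
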