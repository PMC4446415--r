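# FASTA and FASTQ input/output.

#' Read a FASTA file into a named character vector
#'
#' Sequence names are truncated at the first whitespace and sequences are
#' folded to uppercase, so downstream coordinate arithmetic can assume a
#' single canonical alphabet.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record: ",
         paste(nm[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Qualities are constant (the simulator does not model quality scores).
#'
#' @param reads data frame with columns `read_id` and `seq`.
#' @param path output path.
#' @param qual_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    quals <- vapply(nchar(reads$seq), function(n) strrep(qual_char, n), character(1))
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", quals), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return data frame with columns `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ: number of lines not a multiple of 4", call. = FALSE)
  }
  idx <- seq(1, length(lines), by = 4)
  data.frame(
    read_id = sub("\\s.*$", "", sub("^@", "", lines[idx])),
    seq = toupper(lines[idx + 1]),
    stringsAsFactors = FALSE
  )
}
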