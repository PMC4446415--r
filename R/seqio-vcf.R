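# VCF input/output.
#
# Variant calls travel as data frames with columns
# chrom, pos (integer), id, ref, alt, qual, filter, info.

VCF_COLS <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "info")

#' Read a VCF file into a call data frame
#'
#' @param path path to a VCF 4.x file.
#' @return data frame with columns chrom, pos, id, ref, alt, qual, filter,
#'   info; the meta header lines are attached as attribute `meta`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!any(startsWith(lines, "#CHROM"))) {
    stop("malformed VCF: missing #CHROM header line in ", path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  calls <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = as.character(fix[, "QUAL"]),
    filter = as.character(fix[, "FILTER"]),
    info = as.character(fix[, "INFO"]),
    stringsAsFactors = FALSE
  )
  for (col in c("id", "qual", "filter", "info")) {
    calls[[col]][is.na(calls[[col]])] <- "."
  }
  attr(calls, "meta") <- v@meta
  calls
}

#' Write a call data frame to a VCF file
#'
#' The header declares the `TS_ALT` and `TS_CLUSTER` INFO keys and the
#' `TS_MANY`, `TS_INDEL` and `TS_ERRORS` FILTER codes used by thesaurus
#' annotation, plus contig lines when chromosome lengths are supplied.
#'
#' @param calls call data frame (see [read_vcf()]).
#' @param path output path.
#' @param chrom_lengths optional named integer vector for ##contig lines.
#' @param extra_meta optional extra `##` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, chrom_lengths = NULL, extra_meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=varthesaurus-%s", as.character(utils::packageVersion("varthesaurus"))),
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##INFO=<ID=TS_ALT,Number=.,Type=String,Description=\"Thesaurus alternate sites (chrom:pos:strand)\">",
    "##INFO=<ID=TS_CLUSTER,Number=1,Type=Integer,Description=\"Thesaurus cluster identifier\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Qualifying read depth\">",
    "##INFO=<ID=VC,Number=1,Type=Integer,Description=\"Reads supporting the variant allele\">",
    "##FILTER=<ID=TS_MANY,Description=\"Linked to an excessive number of alternative sites\">",
    "##FILTER=<ID=TS_INDEL,Description=\"Variant supported by reads with insertions, deletions or splice junctions\">",
    "##FILTER=<ID=TS_ERRORS,Description=\"Variant supported by reads with a large number of mismatches\">",
    extra_meta
  )
  writeLines(meta, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                   collapse = "\t"), con)
  if (nrow(calls) > 0) {
    writeLines(paste(calls$chrom, calls$pos, calls$id, calls$ref, calls$alt,
                     calls$qual, calls$filter, calls$info, sep = "\t"), con)
  }
  invisible(path)
}

empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), id = character(0),
             ref = character(0), alt = character(0), qual = character(0),
             filter = character(0), info = character(0), stringsAsFactors = FALSE)
}

# TRUE for rows that are single-nucleotide substitutions.
is_snv <- function(calls) {
  nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
    calls$ref %in% BASES & calls$alt %in% BASES
}

# Extract one INFO key's value ("." records and absent keys give NA).
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

# Append key=value to INFO strings, handling "." placeholders.
info_append <- function(info, kv) {
  ifelse(is.na(info) | info == "." | info == "", kv, paste(info, kv, sep = ";"))
}

#' Parse TS_ALT INFO annotations into a link table
#'
#' @param calls an annotated call data frame.
#' @return data frame with columns from_chrom, from_pos, to_chrom, to_pos,
#'   strand (one row per alternate-site link).
#' @export
parse_ts_alt <- function(calls) {
  out <- list()
  vals <- info_field(calls$info, "TS_ALT")
  for (i in which(!is.na(vals))) {
    parts <- strsplit(strsplit(vals[i], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      from_chrom = calls$chrom[i], from_pos = calls$pos[i],
      to_chrom = vapply(parts, `[[`, character(1), 1L),
      to_pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
      strand = vapply(parts, `[[`, character(1), 3L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(from_chrom = character(0), from_pos = integer(0),
                      to_chrom = character(0), to_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
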