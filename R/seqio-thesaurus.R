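# The thesaurus table: a sorted collection of region-pair entries.
#
# An entry links an origin interval to an alternate interval of equal length,
# with an orientation ("+" or "-") and up to three recorded mismatches.
# Mismatches are stored in origin coordinates as "pos:origin_base:alt_base"
# triples joined by ";" ("." when the regions are identical); for "-" entries
# the alt base is reverse-complemented into the origin reading frame, so a
# single canonical frame serves both orientations.
#
# On disk the table is tab-delimited with '#'-prefixed "key=value" header
# lines carrying the build parameters, one entry per line:
# origin_chrom origin_start origin_end alt_chrom alt_start alt_end strand mismatches
# Each region pair is written once in canonical order (origin <= alt);
# queries resolve the symmetric direction by mirroring entries on the fly.

THESAURUS_COLS <- c("origin_chrom", "origin_start", "origin_end",
                    "alt_chrom", "alt_start", "alt_end", "strand", "mismatches")

empty_entries <- function() {
  data.frame(origin_chrom = character(0), origin_start = integer(0),
             origin_end = integer(0), alt_chrom = character(0),
             alt_start = integer(0), alt_end = integer(0),
             strand = character(0), mismatches = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a thesaurus table
#'
#' @param entries entry data frame (columns `origin_chrom`, `origin_start`,
#'   `origin_end`, `alt_chrom`, `alt_start`, `alt_end`, `strand`,
#'   `mismatches`).
#' @param header named list of build parameters stored with the table.
#' @return object of class `thesaurus_table`.
#' @export
thesaurus_table <- function(entries = empty_entries(), header = list()) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(THESAURUS_COLS %in% names(entries)))
  entries <- entries[, THESAURUS_COLS]
  validate_entries(entries)
  rownames(entries) <- NULL
  structure(list(entries = entries, header = header), class = "thesaurus_table")
}

#' @export
print.thesaurus_table <- function(x, ...) {
  cat("Thesaurus table with", nrow(x$entries), "entries\n")
  if (length(x$header) > 0) {
    cat("Build parameters:",
        paste(names(x$header), unlist(x$header), sep = "=", collapse = " "), "\n")
  }
  if (nrow(x$entries) > 0) print(utils::head(x$entries, 5))
  invisible(x)
}

validate_entries <- function(entries) {
  if (nrow(entries) == 0) return(invisible(TRUE))
  len_o <- entries$origin_end - entries$origin_start
  len_a <- entries$alt_end - entries$alt_start
  if (any(len_o != len_a)) {
    stop("ungapped entries require equal origin and alt lengths", call. = FALSE)
  }
  if (any(entries$origin_start < 1L) || any(entries$alt_start < 1L)) {
    stop("entry coordinates must be >= 1", call. = FALSE)
  }
  if (any(len_o < 0)) stop("entry end precedes start", call. = FALSE)
  if (!all(entries$strand %in% c("+", "-"))) {
    stop("entry strand must be '+' or '-'", call. = FALSE)
  }
  mm <- parse_mismatch_strings(entries$mismatches)
  n_mm <- vapply(mm, nrow, integer(1))
  for (i in which(n_mm > 0L)) {
    p <- mm[[i]]$pos
    if (any(p < entries$origin_start[i] | p > entries$origin_end[i])) {
      stop("mismatch position outside origin interval in entry ", i, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# "pos:ob:ab;..." -> list of data frames (pos, origin_base, alt_base).
parse_mismatch_strings <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "." || s == "") {
      return(data.frame(pos = integer(0), origin_base = character(0),
                        alt_base = character(0), stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    if (any(lengths(parts) != 3L)) stop("malformed mismatch field: ", s, call. = FALSE)
    data.frame(pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
               origin_base = vapply(parts, `[[`, character(1), 2L),
               alt_base = vapply(parts, `[[`, character(1), 3L),
               stringsAsFactors = FALSE)
  })
}

format_mismatch_df <- function(df) {
  if (nrow(df) == 0) return(".")
  df <- df[order(df$pos), , drop = FALSE]
  paste(sprintf("%d:%s:%s", df$pos, df$origin_base, df$alt_base), collapse = ";")
}

entries_sorted <- function(entries) {
  if (nrow(entries) < 2) return(TRUE)
  o <- order(entries$origin_chrom, entries$origin_start, entries$origin_end,
             entries$alt_chrom, entries$alt_start, entries$strand)
  identical(o, seq_len(nrow(entries)))
}

sort_entries <- function(entries) {
  entries <- unique(entries)
  o <- order(entries$origin_chrom, entries$origin_start, entries$origin_end,
             entries$alt_chrom, entries$alt_start, entries$strand)
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

#' Write a thesaurus table to a tab-delimited file
#'
#' The writer refuses unsorted entries: the on-disk format is defined to be
#' sorted by origin coordinate so it can be scanned in a single streaming
#' pass. A `.gz` suffix triggers gzip compression.
#'
#' @param table a `thesaurus_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(table, path) {
  stopifnot(inherits(table, "thesaurus_table"))
  entries <- table$entries
  if (!entries_sorted(entries)) {
    stop("thesaurus entries must be sorted by origin coordinate before writing",
         call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("#thesaurus_format=1", con)
  if (length(table$header) > 0) {
    writeLines(sprintf("#%s=%s", names(table$header),
                       vapply(table$header, as.character, character(1))), con)
  }
  if (nrow(entries) > 0) {
    writeLines(paste(entries$origin_chrom, entries$origin_start, entries$origin_end,
                     entries$alt_chrom, entries$alt_start, entries$alt_end,
                     entries$strand, entries$mismatches, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a thesaurus table from disk
#'
#' @param path path written by [write_thesaurus()].
#' @return a `thesaurus_table`.
#' @export
read_thesaurus <- function(path) {
  if (!file.exists(path)) stop("thesaurus file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr_idx <- which(startsWith(lines, "#"))
  header <- list()
  for (h in lines[hdr_idx]) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] != "thesaurus_format") header[[kv[1]]] <- kv[2]
  }
  body_idx <- setdiff(seq_along(lines), hdr_idx)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0) return(thesaurus_table(empty_entries(), header))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 8L)
  if (length(bad) > 0) {
    stop("malformed thesaurus line ", body_idx[bad[1]], " in ", path, call. = FALSE)
  }
  entries <- data.frame(
    origin_chrom = vapply(fields, `[[`, character(1), 1L),
    origin_start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    origin_end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    alt_chrom = vapply(fields, `[[`, character(1), 4L),
    alt_start = as.integer(vapply(fields, `[[`, character(1), 5L)),
    alt_end = as.integer(vapply(fields, `[[`, character(1), 6L)),
    strand = vapply(fields, `[[`, character(1), 7L),
    mismatches = vapply(fields, `[[`, character(1), 8L),
    stringsAsFactors = FALSE
  )
  if (anyNA(entries$origin_start) || anyNA(entries$alt_start) ||
      anyNA(entries$origin_end) || anyNA(entries$alt_end)) {
    stop("malformed thesaurus coordinates in ", path, call. = FALSE)
  }
  if (!entries_sorted(entries)) {
    stop("thesaurus file is not sorted by origin coordinate: ", path, call. = FALSE)
  }
  thesaurus_table(entries, header)
}

#' Mirror entries so the alt side becomes the origin side
#'
#' Swaps the two intervals of each entry and re-expresses the recorded
#' mismatches in the new origin frame (projected positions; bases swapped,
#' and complemented for "-" entries).
#'
#' @param entries entry data frame.
#' @return entry data frame of the same size.
#' @export
mirror_entries <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  mm <- parse_mismatch_strings(entries$mismatches)
  new_mm <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    df <- mm[[i]]
    if (nrow(df) == 0) {
      new_mm[i] <- "."
    } else if (entries$strand[i] == "+") {
      new_mm[i] <- format_mismatch_df(data.frame(
        pos = entries$alt_start[i] + (df$pos - entries$origin_start[i]),
        origin_base = df$alt_base, alt_base = df$origin_base,
        stringsAsFactors = FALSE))
    } else {
      new_mm[i] <- format_mismatch_df(data.frame(
        pos = entries$alt_end[i] - (df$pos - entries$origin_start[i]),
        origin_base = complement_bases(df$alt_base),
        alt_base = complement_bases(df$origin_base),
        stringsAsFactors = FALSE))
    }
  }
  data.frame(origin_chrom = entries$alt_chrom, origin_start = entries$alt_start,
             origin_end = entries$alt_end, alt_chrom = entries$origin_chrom,
             alt_start = entries$origin_start, alt_end = entries$origin_end,
             strand = entries$strand, mismatches = new_mm,
             stringsAsFactors = FALSE)
}

#' Query a thesaurus table for entries overlapping an interval
#'
#' Entries overlapping on the origin side are returned as stored; entries
#' overlapping on the alt side are returned mirrored, so in the result the
#' query interval always overlaps the origin side. Unknown chromosomes give
#' an empty result.
#'
#' @param table a `thesaurus_table`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive query interval (`end` defaults to
#'   `start`).
#' @return entry data frame.
#' @export
query_thesaurus <- function(table, chrom, start, end = start) {
  stopifnot(inherits(table, "thesaurus_table"))
  stopifnot(start >= 1, end >= start)
  e <- table$entries
  if (nrow(e) == 0) return(empty_entries())
  fwd <- e[e$origin_chrom == chrom & e$origin_start <= end & e$origin_end >= start, ,
           drop = FALSE]
  rev_hit <- e[e$alt_chrom == chrom & e$alt_start <= end & e$alt_end >= start, ,
               drop = FALSE]
  out <- rbind(fwd, mirror_entries(rev_hit))
  out <- unique(out)
  rownames(out) <- NULL
  out
}
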