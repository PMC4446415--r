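# Variant annotation: attach alternate-site links and marks to called
# variants by confronting their read support with the thesaurus, then group
# linked calls into clusters.

LINK_COLS <- c("from_chrom", "from_pos", "to_chrom", "to_pos", "strand",
               "proj_ref", "proj_alt", "reads", "fraction")

empty_links <- function() {
  data.frame(from_chrom = character(0), from_pos = integer(0),
             to_chrom = character(0), to_pos = integer(0),
             strand = character(0), proj_ref = character(0),
             proj_alt = character(0), reads = integer(0),
             fraction = numeric(0), stringsAsFactors = FALSE)
}

# Precompute per-read mismatch tables once per alignment set so that
# per-variant work stays proportional to local depth.
prepare_alignments <- function(aln, genome) {
  mm <- alignment_mismatches(aln, genome)
  list(aln = aln,
       span_end = aln$pos + cigar_ref_span(aln$cigar) - 1L,
       mm_by_row = split(mm[, c("gpos", "read_base")], factor(mm$row, levels = seq_len(nrow(aln)))),
       indel = has_indel_or_splice(aln$cigar))
}

# Aligned read base at reference position pos (NA if in a deletion/skip).
aligned_base <- function(aln_row, pos) {
  if (grepl("^[0-9]+M$", aln_row$cigar)) {
    return(substr(aln_row$seq, pos - aln_row$pos + 1L, pos - aln_row$pos + 1L))
  }
  m <- regmatches(aln_row$cigar, gregexpr("\\d+[MIDNSHP=X]", aln_row$cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]", "", m))
  op <- sub("\\d+", "", m)
  rpos <- 1L; gpos <- aln_row$pos
  for (j in seq_along(op)) {
    if (op[j] %in% c("M", "=", "X")) {
      if (pos >= gpos && pos < gpos + len[j]) {
        return(substr(aln_row$seq, rpos + (pos - gpos), rpos + (pos - gpos)))
      }
      rpos <- rpos + len[j]; gpos <- gpos + len[j]
    } else if (op[j] %in% c("I", "S")) {
      rpos <- rpos + len[j]
    } else if (op[j] %in% c("D", "N")) {
      if (pos >= gpos && pos < gpos + len[j]) return(NA_character_)
      gpos <- gpos + len[j]
    }
  }
  NA_character_
}

#' Collect read observations at a variant position
#'
#' Every aligned read overlapping the position yields one observation
#' recording whether it carries the variant allele, how many other
#' mismatches it shows against the reference, and whether its alignment
#' contains insertions, deletions or splice junctions.
#'
#' @param aln alignment data frame (see [read_alignments()]).
#' @param genome named character vector (the reference).
#' @param chrom,pos variant position.
#' @param alt variant allele (single base).
#' @param prep optional precomputed [prepare_alignments()] result (internal
#'   speed-up for batch annotation).
#' @return data frame: row (index into `aln`), start, end, strand, mapq,
#'   carries_variant, n_errors, has_indel; per-read mismatch tables are
#'   attached as attribute `mm` (list parallel to rows).
#' @export
collect_variant_reads <- function(aln, genome, chrom, pos, alt, prep = NULL) {
  if (is.null(prep)) prep <- prepare_alignments(aln, genome)
  idx <- which(prep$aln$chrom == chrom & prep$aln$pos <= pos & prep$span_end >= pos)
  if (length(idx) == 0) {
    out <- data.frame(row = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      carries_variant = logical(0), n_errors = integer(0),
                      has_indel = logical(0), stringsAsFactors = FALSE)
    attr(out, "mm") <- list()
    return(out)
  }
  base <- vapply(idx, function(i) aligned_base(prep$aln[i, ], pos), character(1))
  carries <- !is.na(base) & base == alt
  mm_list <- prep$mm_by_row[idx]
  n_err <- vapply(seq_along(idx), function(k) {
    m <- mm_list[[k]]
    if (is.null(m) || nrow(m) == 0) return(0L)
    sum(m$gpos != pos)
  }, integer(1))
  out <- data.frame(row = idx, start = prep$aln$pos[idx], end = prep$span_end[idx],
                    strand = prep$aln$strand[idx], mapq = prep$aln$mapq[idx],
                    carries_variant = carries, n_errors = n_err,
                    has_indel = prep$indel[idx], stringsAsFactors = FALSE)
  attr(out, "mm") <- mm_list
  out
}

#' Project a position through a thesaurus entry
#'
#' Affine map onto the alternate interval: for "+" entries
#' `alt_pos = alt_start + (pos - origin_start)`, for "-" entries the mirror
#' `alt_pos = alt_end - (pos - origin_start)`. Projecting the image through
#' the mirrored entry returns the original position (involution).
#'
#' @param entry one-row entry data frame.
#' @param pos position inside the entry's origin interval.
#' @return list with `chrom`, `pos` and `strand` of the projected site.
#' @export
project_position <- function(entry, pos) {
  if (pos < entry$origin_start || pos > entry$origin_end) {
    stop("position ", pos, " outside entry origin interval", call. = FALSE)
  }
  list(chrom = entry$alt_chrom,
       pos = if (entry$strand == "+") entry$alt_start + (pos - entry$origin_start)
             else entry$alt_end - (pos - entry$origin_start),
       strand = entry$strand)
}

# Lookup environment of called variants keyed by chrom:pos -> alt allele.
calls_env <- function(calls) {
  env <- new.env(parent = emptyenv(), size = max(2L, nrow(calls)))
  for (i in seq_len(nrow(calls))) {
    assign(site_key(calls$chrom[i], calls$pos[i]), calls$alt[i], envir = env)
  }
  env
}

#' Is a read's mismatch pattern consistent with a thesaurus entry?
#'
#' A read aligned at the origin locus may truly originate from the entry's
#' alternate locus. Its mismatches against the reference are then explained
#' by (a) the entry's recorded inter-region differences, (b) called variants
#' at the mismatch position itself or at its projection onto the alternate
#' side, or (c) a small residual budget of `max_extra_mm` mismatches
#' tolerated for sequencing errors and unannotated nearby variation.
#'
#' @param read_mm data frame of the read's mismatches (columns `gpos`,
#'   `read_base`), in reference coordinates on the entry's origin chromosome.
#' @param entry one-row entry data frame.
#' @param calls called-variant lookup: a call data frame or the environment
#'   from `calls_env()`.
#' @param max_extra_mm residual mismatch budget.
#' @return logical flag.
#' @export
read_consistent_with_entry <- function(read_mm, entry, calls, max_extra_mm = 2L) {
  if (is.null(read_mm) || nrow(read_mm) == 0) return(TRUE)
  env <- if (is.environment(calls)) calls else calls_env(calls)
  entry_mm <- parse_mismatch_strings(entry$mismatches)[[1]]
  residual <- 0L
  for (i in seq_len(nrow(read_mm))) {
    gpos <- read_mm$gpos[i]; base <- read_mm$read_base[i]
    hit <- entry_mm$pos == gpos & entry_mm$alt_base == base
    if (any(hit)) next
    called <- get0(site_key(entry$origin_chrom, gpos), envir = env)
    if (!is.null(called) && called == base) next
    if (gpos >= entry$origin_start && gpos <= entry$origin_end) {
      proj <- project_position(entry, gpos)
      proj_base <- if (entry$strand == "+") base else complement_bases(base)
      called <- get0(site_key(proj$chrom, proj$pos), envir = env)
      if (!is.null(called) && called == proj_base) next
    }
    residual <- residual + 1L
    if (residual > max_extra_mm) return(FALSE)
  }
  TRUE
}

#' Link one variant to its alternate sites
#'
#' For each thesaurus entry covering the variant, the variant-carrying reads
#' consistent with the entry are counted; a link to the projected alternate
#' site is emitted when both the read count and the fraction of carrying
#' reads pass their thresholds. Pathological support is marked instead:
#' `TS_INDEL` when carrying reads contain alignment gaps, `TS_ERRORS` when a
#' carrying read shows more mismatches than the thesaurus mapper itself
#' tolerates, and `TS_MANY` (links suppressed) when the variant links to an
#' excessive number of alternative sites.
#'
#' @param variant list or one-row data frame with chrom, pos, ref, alt.
#' @param obs observations from [collect_variant_reads()].
#' @param entries entry data frame from [query_thesaurus()] at the locus.
#' @param calls call data frame (or `calls_env()` environment) used to
#'   explain mismatches.
#' @param min_reads,min_fraction link support thresholds.
#' @param max_links threshold above which `TS_MANY` replaces the links.
#' @param error_cap `TS_ERRORS` threshold on per-read non-variant mismatches.
#' @param max_extra_mm residual budget for [read_consistent_with_entry()].
#' @return list with `links` (data frame) and `marks` (character vector).
#' @export
link_variant <- function(variant, obs, entries, calls, min_reads = 2L,
                         min_fraction = 0.5, max_links = 100L, error_cap = 4L,
                         max_extra_mm = 2L) {
  links <- empty_links()
  # a variant outside every thesaurus region is left entirely unannotated
  if (nrow(entries) == 0) return(list(links = links, marks = character(0)))
  marks <- character(0)
  carrying <- which(obs$carries_variant)
  if (length(carrying) > 0) {
    if (any(obs$has_indel[carrying])) marks <- c(marks, "TS_INDEL")
    if (any(obs$n_errors[carrying] > error_cap)) marks <- c(marks, "TS_ERRORS")
  }
  if (length(carrying) == 0) {
    return(list(links = links, marks = marks))
  }
  env <- if (is.environment(calls)) calls else calls_env(calls)
  mm_list <- attr(obs, "mm")
  rows <- list()
  for (j in seq_len(nrow(entries))) {
    entry <- entries[j, , drop = FALSE]
    n_ok <- 0L
    for (k in carrying) {
      if (read_consistent_with_entry(mm_list[[k]], entry, env, max_extra_mm)) {
        n_ok <- n_ok + 1L
      }
    }
    frac <- n_ok / length(carrying)
    if (n_ok >= min_reads && frac >= min_fraction) {
      proj <- project_position(entry, variant$pos)
      if (proj$chrom == variant$chrom && proj$pos == variant$pos) next
      flipped <- entry$strand == "-"
      rows[[length(rows) + 1L]] <- data.frame(
        from_chrom = variant$chrom, from_pos = variant$pos,
        to_chrom = proj$chrom, to_pos = proj$pos, strand = entry$strand,
        proj_ref = if (flipped) complement_bases(variant$ref) else variant$ref,
        proj_alt = if (flipped) complement_bases(variant$alt) else variant$alt,
        reads = n_ok, fraction = frac, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) > 0) {
    links <- do.call(rbind, rows)
    # Several merged entries can project onto the same site; keep the best
    # supported record per target.
    links <- links[order(links$to_chrom, links$to_pos, -links$reads), ]
    links <- links[!duplicated(links[, c("to_chrom", "to_pos")]), ]
    rownames(links) <- NULL
  }
  if (nrow(links) > max_links) {
    marks <- c(marks, "TS_MANY")
    links <- empty_links()
  }
  list(links = links, marks = marks)
}

#' Group linked variants into clusters
#'
#' Called variants are nodes; an edge joins two calls when a link of one
#' lands within `merge_tol` bases of the other's position. Clusters are the
#' connected components of this graph; link targets that coincide with no
#' call attach to their source's cluster as peripheral sites. Every call,
#' linked or not, belongs to exactly one cluster.
#'
#' @param calls call data frame.
#' @param links link data frame (from annotation).
#' @param merge_tol positional tolerance for matching a link target to a
#'   call.
#' @return list with `members` (chrom, pos, cluster_id) and `peripheral`
#'   (cluster_id, chrom, pos, proj_ref, proj_alt).
#' @export
cluster_variants <- function(calls, links, merge_tol = 0L) {
  n <- nrow(calls)
  members <- data.frame(chrom = calls$chrom, pos = calls$pos,
                        cluster_id = NA_integer_, stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(members = members,
                peripheral = data.frame(cluster_id = integer(0),
                                        chrom = character(0), pos = integer(0),
                                        proj_ref = character(0),
                                        proj_alt = character(0),
                                        stringsAsFactors = FALSE)))
  }
  key <- site_key(calls$chrom, calls$pos)
  edges <- NULL
  target_call <- integer(0)
  if (!is.null(links) && nrow(links) > 0) {
    from_idx <- match(site_key(links$from_chrom, links$from_pos), key)
    to_idx <- if (merge_tol == 0) {
      match(site_key(links$to_chrom, links$to_pos), key)
    } else {
      vapply(seq_len(nrow(links)), function(i) {
        hit <- which(calls$chrom == links$to_chrom[i] &
                       abs(calls$pos - links$to_pos[i]) <= merge_tol)
        if (length(hit) > 0) hit[1] else NA_integer_
      }, integer(1))
    }
    ok <- !is.na(from_idx) & !is.na(to_idx)
    edges <- cbind(from_idx[ok], to_idx[ok])
    target_call <- to_idx
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  members$cluster_id <- as.integer(comp)
  peripheral <- data.frame(cluster_id = integer(0), chrom = character(0),
                           pos = integer(0), proj_ref = character(0),
                           proj_alt = character(0), stringsAsFactors = FALSE)
  if (!is.null(links) && nrow(links) > 0) {
    from_idx <- match(site_key(links$from_chrom, links$from_pos), key)
    periph <- which(is.na(target_call) & !is.na(from_idx))
    if (length(periph) > 0) {
      peripheral <- data.frame(cluster_id = as.integer(comp[from_idx[periph]]),
                               chrom = links$to_chrom[periph],
                               pos = links$to_pos[periph],
                               proj_ref = links$proj_ref[periph],
                               proj_alt = links$proj_alt[periph],
                               stringsAsFactors = FALSE)
      peripheral <- unique(peripheral)
      rownames(peripheral) <- NULL
    }
  }
  list(members = members, peripheral = peripheral)
}

#' Annotate a set of called variants with thesaurus links
#'
#' The in-memory core of [annotate_vcf()]: every SNV call is confronted with
#' the thesaurus entries covering its locus and the reads overlapping it;
#' qualifying alternate sites become `TS_ALT` links, pathological support
#' becomes `TS_MANY`/`TS_INDEL`/`TS_ERRORS` FILTER marks, and linked calls
#' are grouped into clusters (`TS_CLUSTER`). Records are never reordered,
#' removed or otherwise modified: annotation is a pure decoration.
#'
#' @param calls call data frame (see [read_vcf()]).
#' @param aln alignment data frame.
#' @param thesaurus a `thesaurus_table`.
#' @param genome named character vector (the reference).
#' @param min_reads,min_fraction,max_links,error_cap,max_extra_mm see
#'   [link_variant()].
#' @param merge_tol see [cluster_variants()].
#' @return list with `calls` (annotated), `links` (with cluster ids) and
#'   `clusters` (members + peripheral sites).
#' @export
annotate_variants <- function(calls, aln, thesaurus, genome,
                              min_reads = 2L, min_fraction = 0.5,
                              max_links = 100L, error_cap = 4L,
                              max_extra_mm = 2L, merge_tol = 0L) {
  check_chroms(calls$chrom, genome)
  snv <- which(is_snv(calls))
  prep <- prepare_alignments(aln, genome)
  env <- calls_env(calls[snv, , drop = FALSE])
  all_links <- list()
  marks_by_call <- vector("list", nrow(calls))
  links_by_call <- vector("list", nrow(calls))
  for (i in snv) {
    entries <- query_thesaurus(thesaurus, calls$chrom[i], calls$pos[i])
    if (nrow(entries) == 0) next
    obs <- collect_variant_reads(aln, genome, calls$chrom[i], calls$pos[i],
                                 calls$alt[i], prep = prep)
    res <- link_variant(list(chrom = calls$chrom[i], pos = calls$pos[i],
                             ref = calls$ref[i], alt = calls$alt[i]),
                        obs, entries, env,
                        min_reads = min_reads, min_fraction = min_fraction,
                        max_links = max_links, error_cap = error_cap,
                        max_extra_mm = max_extra_mm)
    marks_by_call[[i]] <- res$marks
    if (nrow(res$links) > 0) {
      links_by_call[[i]] <- res$links
      all_links[[length(all_links) + 1L]] <- res$links
    }
  }
  links <- if (length(all_links) > 0) do.call(rbind, all_links) else empty_links()
  clusters <- cluster_variants(calls, links, merge_tol = merge_tol)
  cl_of_call <- clusters$members$cluster_id
  if (nrow(links) > 0) {
    links$cluster_id <- cl_of_call[match(site_key(links$from_chrom, links$from_pos),
                                         site_key(calls$chrom, calls$pos))]
  } else {
    links$cluster_id <- integer(0)
  }
  # Decorate the call records.
  annotated <- calls
  linked_to <- unique(site_key(links$to_chrom, links$to_pos))
  for (i in seq_len(nrow(calls))) {
    lk <- links_by_call[[i]]
    if (!is.null(lk) && nrow(lk) > 0) {
      ts_alt <- paste(sprintf("%s:%d:%s", lk$to_chrom, lk$to_pos, lk$strand),
                      collapse = ",")
      annotated$info[i] <- info_append(annotated$info[i],
                                       paste0("TS_ALT=", ts_alt))
    }
    in_cluster <- !is.null(lk) && nrow(lk) > 0 ||
      site_key(calls$chrom[i], calls$pos[i]) %in% linked_to
    if (in_cluster) {
      annotated$info[i] <- info_append(annotated$info[i],
                                       sprintf("TS_CLUSTER=%d", cl_of_call[i]))
    }
    mk <- marks_by_call[[i]]
    if (!is.null(mk) && length(mk) > 0) {
      old <- annotated$filter[i]
      keep <- if (is.na(old) || old %in% c(".", "PASS", "")) character(0) else
        strsplit(old, ";", fixed = TRUE)[[1]]
      annotated$filter[i] <- paste(unique(c(keep, mk)), collapse = ";")
    }
  }
  list(calls = annotated, links = links, clusters = clusters)
}

#' Annotate a VCF file with thesaurus links (file-level wrapper)
#'
#' @param vcf_path input VCF of called variants.
#' @param sam_path alignment file (plain-text SAM).
#' @param thesaurus_path thesaurus table file.
#' @param fasta_path reference genome FASTA.
#' @param out_vcf annotated VCF output path.
#' @param out_links link-table TSV output path (columns: from_chrom,
#'   from_pos, to_chrom, to_pos, strand, proj_ref, proj_alt, reads, fraction,
#'   cluster_id).
#' @param ... annotation parameters passed to [annotate_variants()].
#' @return the [annotate_variants()] result, invisibly.
#' @export
annotate_vcf <- function(vcf_path, sam_path, thesaurus_path, fasta_path,
                         out_vcf, out_links = NULL, ...) {
  calls <- read_vcf(vcf_path)
  aln <- read_alignments(sam_path)
  thesaurus <- read_thesaurus(thesaurus_path)
  genome <- read_fasta(fasta_path)
  res <- annotate_variants(calls, aln, thesaurus, genome, ...)
  write_vcf(res$calls, out_vcf, chrom_lengths = genome_lengths(genome))
  if (!is.null(out_links)) {
    utils::write.table(res$links, out_links, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(res)
}

#' Pooled B-allele frequencies over variant clusters
#'
#' A variant whose read evidence is scattered across similar loci shows a
#' deflated allele frequency at its called site. Pooling restores it:
#' variant-supporting reads are summed over every member and peripheral site
#' of the cluster (alleles projected per strand) and compared against the
#' depth expected at a single locus (the mean depth over the cluster's
#' covered sites), because the cluster represents one variant whose evidence
#' was spread out. The raw ratio against summed depth is also reported.
#'
#' @param annotation result of [annotate_variants()].
#' @param aln alignment data frame.
#' @param genome named character vector.
#' @return data frame, one row per cluster: cluster_id, n_members (called
#'   member sites), n_sites (covered sites), var_reads, depth_total,
#'   depth_mean, baf_pooled
#'   (`var_reads / depth_mean`), baf_pooled_ratio (`var_reads /
#'   depth_total`), baf_site_mean (mean per-called-site BAF). Clusters whose
#'   sites have no coverage are reported with NA frequencies.
#' @export
pooled_baf <- function(annotation, aln, genome) {
  prep <- prepare_alignments(aln, genome)
  members <- annotation$clusters$members
  calls <- annotation$calls
  members$alt <- calls$alt[match(site_key(members$chrom, members$pos),
                                 site_key(calls$chrom, calls$pos))]
  peripheral <- annotation$clusters$peripheral
  out <- list()
  for (cl in sort(unique(members$cluster_id))) {
    mem <- members[members$cluster_id == cl & !is.na(members$alt) &
                     members$alt %in% BASES, , drop = FALSE]
    per <- peripheral[peripheral$cluster_id == cl, , drop = FALSE]
    sites <- rbind(
      if (nrow(mem) > 0) data.frame(chrom = mem$chrom, pos = mem$pos,
                                    alt = mem$alt, member = TRUE,
                                    stringsAsFactors = FALSE),
      if (nrow(per) > 0) data.frame(chrom = per$chrom, pos = per$pos,
                                    alt = per$proj_alt, member = FALSE,
                                    stringsAsFactors = FALSE))
    if (is.null(sites) || nrow(sites) == 0) next
    sites <- unique(sites)
    depth <- integer(nrow(sites)); var <- integer(nrow(sites))
    for (s in seq_len(nrow(sites))) {
      obs <- collect_variant_reads(aln, genome, sites$chrom[s], sites$pos[s],
                                   sites$alt[s], prep = prep)
      depth[s] <- nrow(obs)
      var[s] <- sum(obs$carries_variant)
    }
    covered <- depth > 0
    site_baf <- ifelse(covered, var / depth, NA_real_)
    member_baf <- site_baf[sites$member & covered]
    out[[length(out) + 1L]] <- data.frame(
      cluster_id = cl,
      n_members = sum(sites$member),
      n_sites = sum(covered),
      var_reads = sum(var[covered]),
      depth_total = sum(depth[covered]),
      depth_mean = if (any(covered)) mean(depth[covered]) else NA_real_,
      baf_pooled = if (any(covered)) sum(var[covered]) / mean(depth[covered]) else NA_real_,
      baf_pooled_ratio = if (any(covered)) sum(var[covered]) / sum(depth[covered]) else NA_real_,
      baf_site_mean = if (length(member_baf) > 0) mean(member_baf) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(cluster_id = integer(0), n_members = integer(0),
                      n_sites = integer(0), var_reads = integer(0),
                      depth_total = integer(0), depth_mean = numeric(0),
                      baf_pooled = numeric(0), baf_pooled_ratio = numeric(0),
                      baf_site_mean = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
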