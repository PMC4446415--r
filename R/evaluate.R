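# Benchmark layer: a minimal pileup caller, local and thesaurus-aware
# confusion counting, rate computations, the mapping-quality threshold
# sweep, the random-link control and apparent-error-rate estimation.

#' Confusion counts under local or thesaurus-aware accounting
#'
#' @param TP,FP,FN,TN,TTP non-negative counts.
#' @param mode `"local"` or `"thesaurus"`.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0L, FP = 0L, FN = 0L, TN = 0L, TTP = 0L,
                             mode = c("local", "thesaurus")) {
  mode <- match.arg(mode)
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0, TTP >= 0)
  if (mode == "local" && TTP != 0) stop("local mode has no TTP", call. = FALSE)
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP), FN = as.numeric(FN),
                 TN = as.numeric(TN), TTP = as.numeric(TTP), mode = mode),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (%s): TP=%g FP=%g FN=%g TN=%g TTP=%g\n",
              x$mode, x$TP, x$FP, x$FN, x$TN, x$TTP))
  invisible(x)
}

truth_key <- function(truth, position_only) {
  if (position_only) site_key(truth$chrom, truth$pos)
  else paste(truth$chrom, truth$pos, truth$alt, sep = ":")
}

#' Classify calls against truth using local information only
#'
#' A call is a true positive when position and alternate allele match a
#' truth site; anything else called is a false positive and any uncalled
#' truth site a false negative. The number of true negatives is fixed by
#' convention to the genome length.
#'
#' @param calls call data frame.
#' @param truth truth data frame (chrom, pos, ref, alt).
#' @param genome_length true-negative convention.
#' @param position_only match on position alone, ignoring alleles.
#' @return a `confusion_counts` in local mode.
#' @export
classify_local <- function(calls, truth, genome_length, position_only = FALSE) {
  tk <- truth_key(truth, position_only)
  ck <- truth_key(calls, position_only)
  tp <- sum(ck %in% tk)
  confusion_counts(TP = tp, FP = nrow(calls) - tp,
                   FN = sum(!(tk %in% ck)), TN = genome_length, mode = "local")
}

#' Classify calls against truth using thesaurus links
#'
#' True positives are unchanged. A called site that is not itself a truth
#' site but whose links reach a truth site (with matching projected allele)
#' is a thesaurus true positive; a call reaching no truth site at all is a
#' false positive. A truth site is a false negative only when it is neither
#' called nor the link target of any call.
#'
#' @param calls call data frame.
#' @param links link data frame for those calls.
#' @param truth truth data frame.
#' @param genome_length true-negative convention.
#' @param position_only match on position alone.
#' @return a `confusion_counts` in thesaurus mode.
#' @export
classify_thesaurus <- function(calls, links, truth, genome_length,
                               position_only = FALSE) {
  tk <- truth_key(truth, position_only)
  ck <- truth_key(calls, position_only)
  link_key_to <- if (position_only) site_key(links$to_chrom, links$to_pos)
                 else paste(links$to_chrom, links$to_pos, links$proj_alt, sep = ":")
  link_from <- site_key(links$from_chrom, links$from_pos)
  call_site <- site_key(calls$chrom, calls$pos)
  tp <- ck %in% tk
  ttp <- logical(nrow(calls))
  for (i in which(!tp)) {
    mine <- link_key_to[link_from == call_site[i]]
    ttp[i] <- any(mine %in% tk)
  }
  fn <- sum(!(tk %in% ck) & !(tk %in% link_key_to))
  confusion_counts(TP = sum(tp), FP = sum(!tp & !ttp), FN = fn,
                   TN = genome_length, TTP = sum(ttp), mode = "thesaurus")
}

#' Performance rates from confusion counts
#'
#' `fpr = FP / (FP + TN)`, `tpr = TP / (TP + FN)` and
#' `ttpr = (TP + TTP) / (TP + TTP + FN)`; the thesaurus true positive rate
#' reduces to the conventional TPR when TTP is zero. Zero denominators give
#' `NA` rather than an error.
#'
#' @param c a `confusion_counts`.
#' @return rate in `[0, 1]`, or `NA`.
#' @export
fpr <- function(c) {
  d <- c$FP + c$TN
  if (d == 0) NA_real_ else c$FP / d
}

#' @rdname fpr
#' @export
tpr <- function(c) {
  d <- c$TP + c$FN
  if (d == 0) NA_real_ else c$TP / d
}

#' @rdname fpr
#' @export
ttpr <- function(c) {
  d <- c$TP + c$TTP + c$FN
  if (d == 0) NA_real_ else (c$TP + c$TTP) / d
}

# Reference-consuming M segments of reads, as intervals; used for depth.
m_segments <- function(aln) {
  simple <- grepl("^[0-9]+M$", aln$cigar)
  segs <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    if (simple[i]) {
      segs[[i]] <- data.frame(chrom = aln$chrom[i], start = aln$pos[i],
                              end = aln$pos[i] + nchar(aln$seq[i]) - 1L,
                              stringsAsFactors = FALSE)
    } else {
      m <- regmatches(aln$cigar[i], gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
      len <- as.integer(sub("[MIDNSHP=X]", "", m))
      op <- sub("\\d+", "", m)
      gpos <- aln$pos[i]
      acc <- list()
      for (j in seq_along(op)) {
        if (op[j] %in% c("M", "=", "X")) {
          acc[[length(acc) + 1L]] <- data.frame(chrom = aln$chrom[i],
                                                start = gpos,
                                                end = gpos + len[j] - 1L,
                                                stringsAsFactors = FALSE)
          gpos <- gpos + len[j]
        } else if (op[j] %in% c("D", "N")) {
          gpos <- gpos + len[j]
        }
      }
      segs[[i]] <- do.call(rbind, acc)
    }
  }
  do.call(rbind, segs)
}

# Per-position depth and mismatch counts over the whole genome.
pileup_profile <- function(aln, genome) {
  lens <- genome_lengths(genome)
  depth <- lapply(lens, function(n) integer(n))
  mmc <- lapply(lens, function(n) integer(n))
  if (nrow(aln) > 0) {
    segs <- m_segments(aln)
    for (chrom in unique(segs$chrom)) {
      s <- segs[segs$chrom == chrom, , drop = FALSE]
      n <- lens[[chrom]]
      delta <- integer(n + 1L)
      starts <- tabulate(s$start, nbins = n)
      ends <- tabulate(pmin(s$end, n) + 1L, nbins = n + 1L)
      delta[seq_len(n)] <- starts
      delta <- delta - ends
      depth[[chrom]] <- cumsum(delta[seq_len(n)])
    }
    mm <- alignment_mismatches(aln, genome)
    if (nrow(mm) > 0) {
      for (chrom in unique(mm$chrom)) {
        mmc[[chrom]] <- tabulate(mm$gpos[mm$chrom == chrom], nbins = lens[[chrom]])
      }
    }
  }
  list(depth = depth, mismatch = mmc)
}

#' A minimal deterministic pileup variant caller
#'
#' Emits an SNV wherever at least `min_reads` reads with mapping quality at
#' or above `min_mq` support the same non-reference base, making up at least
#' `min_fraction` of the qualifying depth. A deliberately simple stand-in
#' for production callers, sufficient for benchmarking mappability effects;
#' all evaluation functions also accept externally produced call sets.
#'
#' @param aln alignment data frame.
#' @param genome named character vector (the reference).
#' @param min_mq mapping-quality threshold.
#' @param min_reads,min_fraction support thresholds.
#' @return call data frame (see [read_vcf()]).
#' @export
naive_pileup_caller <- function(aln, genome, min_mq = 0L, min_reads = 2L,
                                min_fraction = 0.5) {
  aln <- aln[aln$mapq >= min_mq, , drop = FALSE]
  if (nrow(aln) == 0) return(empty_calls())
  prof <- pileup_profile(aln, genome)
  mm <- alignment_mismatches(aln, genome)
  if (nrow(mm) == 0) return(empty_calls())
  agg <- stats::aggregate(list(count = rep(1L, nrow(mm))),
                          by = list(chrom = mm$chrom, pos = mm$gpos,
                                    base = mm$read_base), FUN = sum)
  # Best-supported non-reference base per site, ties resolved alphabetically.
  agg <- agg[order(agg$chrom, agg$pos, -agg$count, agg$base), ]
  agg <- agg[!duplicated(agg[, c("chrom", "pos")]), , drop = FALSE]
  depth <- mapply(function(chrom, pos) prof$depth[[chrom]][pos],
                  agg$chrom, agg$pos)
  ok <- agg$count >= min_reads & agg$count / depth >= min_fraction &
    agg$base %in% BASES
  agg <- agg[ok, , drop = FALSE]
  depth <- depth[ok]
  if (nrow(agg) == 0) return(empty_calls())
  calls <- data.frame(
    chrom = agg$chrom, pos = as.integer(agg$pos), id = ".",
    ref = substring(genome[agg$chrom], agg$pos, agg$pos),
    alt = agg$base, qual = ".", filter = "PASS",
    info = sprintf("DP=%d;VC=%d", as.integer(depth), agg$count),
    stringsAsFactors = FALSE)
  calls <- calls[calls$ref != calls$alt & calls$ref %in% BASES, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos), ]
  rownames(calls) <- NULL
  calls
}

#' Call, annotate and classify across mapping-quality thresholds
#'
#' For each threshold the naive caller produces a call set, the thesaurus
#' annotates it, and both local and thesaurus-aware confusion counts and
#' rates are computed. Annotation always uses the full alignment (the
#' thesaurus exists precisely to interpret low-quality placements).
#'
#' @param aln alignment data frame.
#' @param genome named character vector.
#' @param thesaurus a `thesaurus_table`.
#' @param truth truth data frame.
#' @param thresholds increasing mapping-quality thresholds.
#' @param min_reads,min_fraction caller support thresholds.
#' @param ... annotation parameters passed to [annotate_variants()].
#' @return list with `points` (one row per threshold: counts and rates) and
#'   `runs` (per threshold: calls, annotation result).
#' @export
sweep_thresholds <- function(aln, genome, thesaurus, truth,
                             thresholds = c(0L, 1L, 30L),
                             min_reads = 2L, min_fraction = 0.5, ...) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  glen <- sum(genome_lengths(genome))
  runs <- list()
  rows <- list()
  for (th in thresholds) {
    calls <- naive_pileup_caller(aln, genome, min_mq = th,
                                 min_reads = min_reads,
                                 min_fraction = min_fraction)
    ann <- annotate_variants(calls, aln, thesaurus, genome, ...)
    loc <- classify_local(calls, truth, glen)
    thes <- classify_thesaurus(calls, ann$links, truth, glen)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = th, n_calls = nrow(calls),
      tp = loc$TP, fp_local = loc$FP, fn_local = loc$FN,
      fpr_local = fpr(loc), tpr_local = tpr(loc),
      fp_thesaurus = thes$FP, ttp = thes$TTP, fn_thesaurus = thes$FN,
      fpr_thesaurus = fpr(thes), ttpr = ttpr(thes))
    runs[[as.character(th)]] <- list(calls = calls, annotation = ann,
                                     local = loc, thesaurus = thes)
  }
  list(points = do.call(rbind, rows), runs = runs)
}

#' Random-link control
#'
#' Replaces every link target with a uniformly random genomic position while
#' keeping the per-variant link counts (and projected alleles) unchanged.
#' Random links should rescue essentially nothing, confirming that the
#' performance gain of real annotation comes from genuine sequence
#' similarity.
#'
#' @param links link data frame from a real annotation run.
#' @param genome named character vector.
#' @param seed integer seed.
#' @return link data frame of identical shape with randomized targets.
#' @export
random_link_control <- function(links, genome, seed = 1L) {
  if (nrow(links) == 0) return(links)
  lens <- genome_lengths(genome)
  with_seed(seed, {
    chrom <- sample(names(lens), nrow(links), replace = TRUE,
                    prob = lens / sum(lens))
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1L), integer(1),
                  USE.NAMES = FALSE)
    out <- links
    out$to_chrom <- chrom
    out$to_pos <- pos
    out
  })
}

#' Genome mask of thesaurus-covered positions
#'
#' @param thesaurus a `thesaurus_table`.
#' @param genome named character vector.
#' @return named list of logical vectors, TRUE where some entry (origin or
#'   alt side) covers the position.
#' @export
thesaurus_coverage <- function(thesaurus, genome) {
  lens <- genome_lengths(genome)
  mask <- lapply(lens, function(n) logical(n))
  e <- thesaurus$entries
  add <- function(chrom, start, end) {
    if (chrom %in% names(mask)) {
      mask[[chrom]][start:min(end, lens[[chrom]])] <<- TRUE
    }
  }
  for (i in seq_len(nrow(e))) {
    add(e$origin_chrom[i], e$origin_start[i], e$origin_end[i])
    add(e$alt_chrom[i], e$alt_start[i], e$alt_end[i])
  }
  mask
}

#' Apparent sequencing error rate over a region class
#'
#' Counts mismatched aligned bases relative to total aligned bases over the
#' positions selected by `mask`, after removing variant-labelled sites and
#' any explicitly excluded sites.
#'
#' @param aln alignment data frame.
#' @param genome named character vector.
#' @param mask named list of logical vectors selecting the region class, or
#'   `NULL` for the whole genome.
#' @param variant_sites data frame (chrom, pos) of sites labelled as
#'   variants, removed from the tally.
#' @param exclude_sites optional data frame (chrom, pos) of additional sites
#'   to exclude.
#' @param profile optional precomputed pileup profile (internal speed-up).
#' @return list with `mismatch_bases`, `total_bases` and `rate` (`NA` when
#'   the class is empty of aligned bases).
#' @export
error_rate <- function(aln, genome, mask = NULL, variant_sites = NULL,
                       exclude_sites = NULL, profile = NULL) {
  if (is.null(profile)) profile <- pileup_profile(aln, genome)
  lens <- genome_lengths(genome)
  if (is.null(mask)) mask <- lapply(lens, function(n) rep(TRUE, n))
  drop_sites <- function(mask, sites) {
    if (is.null(sites) || nrow(sites) == 0) return(mask)
    for (i in seq_len(nrow(sites))) {
      ch <- sites$chrom[i]
      if (ch %in% names(mask) && sites$pos[i] <= length(mask[[ch]])) {
        mask[[ch]][sites$pos[i]] <- FALSE
      }
    }
    mask
  }
  mask <- drop_sites(mask, variant_sites)
  mask <- drop_sites(mask, exclude_sites)
  mm <- 0; tot <- 0
  for (chrom in names(mask)) {
    sel <- mask[[chrom]]
    mm <- mm + sum(profile$mismatch[[chrom]][sel])
    tot <- tot + sum(profile$depth[[chrom]][sel])
  }
  list(mismatch_bases = mm, total_bases = tot,
       rate = if (tot > 0) mm / tot else NA_real_)
}

#' Error-rate comparison across exclusion policies
#'
#' Reproduces, at toy scale, the comparison of apparent error rates between
#' thesaurus-covered and non-covered regions, and the effect of excluding
#' the alternate sites linked to called variants versus excluding an equal
#' number of randomly selected covered sites (the random control is repeated
#' and summarized as mean and standard deviation).
#'
#' @param aln alignment data frame.
#' @param genome named character vector.
#' @param thesaurus a `thesaurus_table`.
#' @param calls call data frame (variant-labelled sites).
#' @param links link data frame (linked alternate sites to exclude).
#' @param repeats number of random-exclusion repetitions.
#' @param seed integer seed for the random draws.
#' @return list with elements `covered`, `covered_excl_linked`,
#'   `noncovered` (each as from [error_rate()]) and `covered_excl_random`
#'   (rates vector, mean and sd).
#' @export
error_rate_analysis <- function(aln, genome, thesaurus, calls, links,
                                repeats = 5L, seed = 1L) {
  profile <- pileup_profile(aln, genome)
  covered <- thesaurus_coverage(thesaurus, genome)
  noncovered <- lapply(covered, `!`)
  variant_sites <- calls[, c("chrom", "pos")]
  linked_sites <- unique(data.frame(chrom = links$to_chrom, pos = links$to_pos,
                                    stringsAsFactors = FALSE))
  res_cov <- error_rate(aln, genome, covered, variant_sites, profile = profile)
  res_link <- error_rate(aln, genome, covered, variant_sites,
                         exclude_sites = linked_sites, profile = profile)
  res_non <- error_rate(aln, genome, noncovered, variant_sites, profile = profile)
  # Random-matched exclusion: draw as many covered, non-variant sites as
  # there are linked alternate sites.
  pool <- list()
  for (chrom in names(covered)) {
    sel <- which(covered[[chrom]])
    if (length(sel) > 0) {
      pool[[chrom]] <- data.frame(chrom = chrom, pos = sel,
                                  stringsAsFactors = FALSE)
    }
  }
  pool <- if (length(pool) > 0) do.call(rbind, pool) else
    data.frame(chrom = character(0), pos = integer(0))
  vk <- site_key(variant_sites$chrom, variant_sites$pos)
  pool <- pool[!(site_key(pool$chrom, pool$pos) %in% vk), , drop = FALSE]
  rates <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      n_draw <- min(nrow(linked_sites), nrow(pool))
      draw <- pool[sample.int(nrow(pool), n_draw), , drop = FALSE]
      rates[r] <- error_rate(aln, genome, covered, variant_sites,
                             exclude_sites = draw, profile = profile)$rate
    }
  })
  list(covered = res_cov, covered_excl_linked = res_link, noncovered = res_non,
       covered_excl_random = list(rates = rates, mean = mean(rates),
                                  sd = stats::sd(rates)))
}
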