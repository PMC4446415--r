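# Projection, read consistency, linking, clustering, pooled BAF.

test_that("position projection is affine, mirrored on minus, and involutive", {
  e <- data.frame(origin_chrom = "A", origin_start = 1L, origin_end = 100L,
                  alt_chrom = "B", alt_start = 501L, alt_end = 600L,
                  strand = "+", mismatches = ".", stringsAsFactors = FALSE)
  expect_identical(project_position(e, 1L)$pos, 501L)
  e$strand <- "-"
  expect_identical(project_position(e, 1L)$pos, 600L)
  expect_error(project_position(e, 400L), "outside")

  entries <- rand_entries(100, seed = 201)
  set.seed(202)
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    pos <- sample(e$origin_start:e$origin_end, 1)
    fwd <- project_position(e, pos)
    back <- project_position(mirror_entries(e), fwd$pos)
    expect_identical(back$pos, pos)
    expect_identical(back$chrom, e$origin_chrom)
  }
})

test_that("variant read collection reports alleles, errors and indels", {
  g <- c(chr1 = strrep("ACGT", 250))
  ref50 <- substring(g[["chr1"]], 101, 150)
  alt_read <- ref50
  substr(alt_read, 25, 25) <- "T"   # variant A->T at position 125
  aln <- data.frame(
    qname = sprintf("r%d", 1:12),
    flag = 0L, chrom = "chr1", pos = 101L, mapq = 40L, cigar = "50M",
    strand = "+", seq = c(rep(alt_read, 10), ref50, ref50),
    stringsAsFactors = FALSE)
  # one reference read gains a deletion; one gains two extra errors
  aln$cigar[11] <- "20M1D30M"
  aln$seq[11] <- substring(paste0(substring(ref50, 1, 20), substring(g[["chr1"]], 122, 151)), 1, 50)
  err_read <- ref50
  substr(err_read, 2, 2) <- "T"; substr(err_read, 40, 40) <- "A"
  aln$seq[12] <- err_read

  obs <- collect_variant_reads(aln, g, "chr1", 125L, "T")
  expect_identical(nrow(obs), 12L)
  expect_identical(sum(obs$carries_variant), 10L)
  expect_true(obs$has_indel[11])
  expect_identical(obs$n_errors[12], 2L)
  expect_identical(obs$n_errors[1], 0L)

  expect_identical(nrow(collect_variant_reads(aln, g, "chr1", 900L, "A")), 0L)
})

test_that("read consistency tolerates explained mismatches and caps residuals", {
  e <- data.frame(origin_chrom = "chr1", origin_start = 100L, origin_end = 299L,
                  alt_chrom = "chr1", alt_start = 1100L, alt_end = 1299L,
                  strand = "+", mismatches = "150:A:G;220:C:T",
                  stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", pos = 180L, ref = "T", alt = "C",
                      stringsAsFactors = FALSE)
  # entry-recorded differences -> consistent
  mm <- data.frame(gpos = c(150L, 220L), read_base = c("G", "T"))
  expect_true(read_consistent_with_entry(mm, e, calls))
  # called variant at the origin -> consistent
  mm2 <- rbind(mm, data.frame(gpos = 180L, read_base = "C"))
  expect_true(read_consistent_with_entry(mm2, e, calls))
  # a called variant whose projection explains the mismatch
  calls_proj <- data.frame(chrom = "chr1", pos = 1250L, ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
  mm3 <- data.frame(gpos = 250L, read_base = "G")
  expect_true(read_consistent_with_entry(mm3, e, calls_proj))
  # residual budget: two unexplained pass, three fail
  mm4 <- data.frame(gpos = c(130L, 160L), read_base = c("T", "T"))
  expect_true(read_consistent_with_entry(mm4, e, calls))
  mm5 <- rbind(mm4, data.frame(gpos = 190L, read_base = "G"))
  expect_false(read_consistent_with_entry(mm5, e, calls))
})

test_that("minus-strand projection complements alleles", {
  e <- data.frame(origin_chrom = "chr1", origin_start = 100L, origin_end = 199L,
                  alt_chrom = "chr1", alt_start = 900L, alt_end = 999L,
                  strand = "-", mismatches = ".", stringsAsFactors = FALSE)
  calls_proj <- data.frame(chrom = "chr1", pos = 999L, ref = "T", alt = "C",
                           stringsAsFactors = FALSE)
  # read mismatch G at origin 100 projects to alt 999 as complement C
  mm <- data.frame(gpos = 100L, read_base = "G")
  expect_true(read_consistent_with_entry(mm, e, calls_proj))
  calls_wrong <- data.frame(chrom = "chr1", pos = 999L, ref = "T", alt = "G",
                            stringsAsFactors = FALSE)
  expect_false(read_consistent_with_entry(mm, e, calls_wrong,
                                          max_extra_mm = 0L))
})

test_that("a planted variant in a two-copy repeat links both called sites", {
  tc <- two_copy_genome(211)
  tab <- build_thesaurus(tc$genome)
  vpos <- tc$pos1 + 250L
  sample_g <- tc$genome
  ref_base <- substring(sample_g[["chr1"]], vpos, vpos)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  chars <- strsplit(sample_g[["chr1"]], "")[[1]]
  chars[vpos] <- alt_base
  sample_g[["chr1"]] <- paste(chars, collapse = "")
  reads <- sample_reads(sample_g, coverage = 10, seed = 212)
  aln <- align_reads(reads, tc$genome, seed = 213)
  calls <- naive_pileup_caller(aln, tc$genome, min_mq = 0, min_fraction = 0.2)
  ann <- annotate_variants(calls, aln, tab, tc$genome)

  vpos2 <- tc$pos2 + 250L
  called_sites <- calls$pos
  expect_true(vpos %in% called_sites)
  # evidence was split: the homologous site is called too, and both calls
  # link to each other's locus (mutual pair, one cluster)
  expect_true(vpos2 %in% called_sites)
  lk <- ann$links
  expect_true(any(lk$from_pos == vpos & lk$to_pos == vpos2))
  expect_true(any(lk$from_pos == vpos2 & lk$to_pos == vpos))
  ids <- ann$clusters$members
  expect_identical(ids$cluster_id[ids$pos == vpos],
                   ids$cluster_id[ids$pos == vpos2])

  # pooled BAF of that cluster recovers the haploid frequency better than
  # the per-site estimates diluted by read splitting
  baf <- pooled_baf(ann, aln, tc$genome)
  cl <- ids$cluster_id[ids$pos == vpos]
  row <- baf[baf$cluster_id == cl, ]
  expect_gte(row$n_members, 2L)
  expect_lt(row$baf_site_mean, 0.95)
  expect_gt(row$baf_pooled, row$baf_site_mean)
  expect_gt(row$baf_pooled, 0.8)
})

test_that("link thresholds, marks and TS_MANY behave as specified", {
  obs <- data.frame(row = 1:6, start = 1L, end = 100L, strand = "+",
                    mapq = 40L, carries_variant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    n_errors = 0L, has_indel = FALSE, stringsAsFactors = FALSE)
  attr(obs, "mm") <- rep(list(NULL), 6)
  variant <- list(chrom = "chr1", pos = 150L, ref = "A", alt = "G")
  calls <- data.frame(chrom = "chr1", pos = 150L, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  entries <- data.frame(origin_chrom = "chr1", origin_start = 101L,
                        origin_end = 200L, alt_chrom = "chr1",
                        alt_start = c(301L, 501L, 701L),
                        alt_end = c(400L, 600L, 800L), strand = "+",
                        mismatches = ".", stringsAsFactors = FALSE)
  res <- link_variant(variant, obs, entries, calls)
  expect_identical(nrow(res$links), 3L)
  expect_identical(res$links$reads, rep(3L, 3))
  expect_length(res$marks, 0L)

  res_many <- link_variant(variant, obs, entries, calls, max_links = 2L)
  expect_identical(nrow(res_many$links), 0L)
  expect_identical(res_many$marks, "TS_MANY")

  obs$has_indel[1] <- TRUE
  obs$n_errors[2] <- 7L
  res_marked <- link_variant(variant, obs, entries, calls)
  expect_setequal(res_marked$marks, c("TS_INDEL", "TS_ERRORS"))

  # no thesaurus entries -> nothing at all
  none <- link_variant(variant, obs, entries[0, ], calls)
  expect_identical(nrow(none$links), 0L)
  expect_length(none$marks, 0L)
})

test_that("clustering equals a union-find oracle on random link graphs", {
  empty <- cluster_variants(
    data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "G",
               stringsAsFactors = FALSE), empty_links())
  expect_identical(empty$members$cluster_id, c(1L, 2L))

  set.seed(221)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    calls <- data.frame(chrom = "chr1", pos = sort(sample.int(10000L, n)),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
    n_links <- sample(0:15, 1)
    links <- if (n_links == 0) empty_links() else {
      from <- sample(n, n_links, TRUE)
      # half the targets hit other calls, half are uncalled sites
      to_call <- sample(n, n_links, TRUE)
      to_pos <- ifelse(stats::runif(n_links) < 0.5, calls$pos[to_call],
                       sample.int(10000L, n_links, TRUE) + 20000L)
      data.frame(from_chrom = "chr1", from_pos = calls$pos[from],
                 to_chrom = "chr1", to_pos = to_pos, strand = "+",
                 proj_ref = "A", proj_alt = "G", reads = 2L, fraction = 1,
                 stringsAsFactors = FALSE)
    }
    got <- cluster_variants(calls, links)$members$cluster_id
    edge_idx <- cbind(match(links$from_pos, calls$pos),
                      match(links$to_pos, calls$pos))
    edge_idx <- edge_idx[stats::complete.cases(edge_idx), , drop = FALSE]
    want <- uf_components(n, edge_idx)
    # same partition up to relabeling
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
  }
})

test_that("annotation decorates records without reordering or dropping any", {
  tc <- two_copy_genome(231)
  tab <- build_thesaurus(tc$genome)
  reads <- sample_reads(tc$genome, coverage = 6, seed = 232)
  aln <- align_reads(reads, tc$genome, seed = 233)
  calls <- data.frame(
    chrom = "chr1", pos = c(50L, tc$pos1 + 100L, 3800L),
    id = ".", ref = c("A", "C", "AT"), alt = c("G", "T", "A"),
    qual = ".", filter = "PASS", info = ".", stringsAsFactors = FALSE)
  calls$ref[2] <- substring(tc$genome[["chr1"]], calls$pos[2], calls$pos[2])
  ann <- annotate_variants(calls, aln, tab, tc$genome)
  expect_identical(ann$calls[, c("chrom", "pos", "ref", "alt")],
                   calls[, c("chrom", "pos", "ref", "alt")])
  # the non-SNV record is untouched
  expect_identical(ann$calls$info[3], ".")
  expect_identical(ann$calls$filter[3], "PASS")
  expect_error(
    annotate_variants(data.frame(chrom = "chrZ", pos = 1L, id = ".", ref = "A",
                                 alt = "G", qual = ".", filter = ".", info = ".",
                                 stringsAsFactors = FALSE),
                      aln, tab, tc$genome),
    "chrZ")
})

test_that("annotate_vcf round-trips files and writes the link sidecar", {
  tc <- two_copy_genome(241)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); write_fasta(tc$genome, fa)
  tab <- build_thesaurus(tc$genome)
  thf <- file.path(dir, "g.thesaurus.tsv"); write_thesaurus(tab, thf)
  vpos <- tc$pos1 + 200L
  sample_g <- tc$genome
  chars <- strsplit(sample_g[["chr1"]], "")[[1]]
  ref_base <- chars[vpos]
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  chars[vpos] <- alt_base
  sample_g[["chr1"]] <- paste(chars, collapse = "")
  reads <- sample_reads(sample_g, coverage = 10, seed = 242)
  aln <- align_reads(reads, tc$genome, seed = 243)
  samf <- file.path(dir, "a.sam"); write_sam(aln, genome_lengths(tc$genome), samf)
  calls <- naive_pileup_caller(aln, tc$genome, min_mq = 0, min_fraction = 0.2)
  vcf <- file.path(dir, "calls.vcf"); write_vcf(calls, vcf)

  out_vcf <- file.path(dir, "out.vcf"); out_links <- file.path(dir, "links.tsv")
  res <- annotate_vcf(vcf, samf, thf, fa, out_vcf, out_links)
  back <- read_vcf(out_vcf)
  expect_identical(back[, c("chrom", "pos", "ref", "alt")],
                   calls[, c("chrom", "pos", "ref", "alt")])
  expect_true(any(!is.na(info_field(back$info, "TS_ALT"))))
  sidecar <- utils::read.table(out_links, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  expect_identical(nrow(sidecar), nrow(res$links))
  # link symmetry on the called mutual pair
  ts <- parse_ts_alt(back)
  for (i in seq_len(nrow(ts))) {
    mutual <- any(ts$from_chrom == ts$to_chrom[i] & ts$from_pos == ts$to_pos[i] &
                    ts$to_pos == ts$from_pos[i])
    called_there <- any(back$chrom == ts$to_chrom[i] & back$pos == ts$to_pos[i])
    if (called_there) expect_true(mutual)
  }
})

test_that("pooled BAF handles trivial and degenerate clusters", {
  g <- c(chr1 = strrep("ACGT", 100))
  read <- substring(g[["chr1"]], 101, 150)
  substr(read, 25, 25) <- "T"
  aln <- data.frame(qname = sprintf("r%d", 1:10), flag = 0L, chrom = "chr1",
                    pos = 101L, mapq = 40L, cigar = "50M", strand = "+",
                    seq = read, stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", pos = 125L, id = ".", ref = "A",
                      alt = "T", qual = ".", filter = "PASS", info = ".",
                      stringsAsFactors = FALSE)
  ann <- list(calls = calls,
              links = empty_links(),
              clusters = list(
                members = data.frame(chrom = "chr1", pos = 125L,
                                     cluster_id = 1L, stringsAsFactors = FALSE),
                peripheral = data.frame(cluster_id = 1L, chrom = "chr1",
                                        pos = 350L, proj_ref = "A",
                                        proj_alt = "T", stringsAsFactors = FALSE)))
  baf <- pooled_baf(ann, aln, g)
  expect_identical(baf$var_reads, 10L)
  expect_identical(baf$baf_pooled, 1.0)
  # the uncovered peripheral site contributed 0/0 and was skipped
  expect_identical(baf$n_sites, 1L)
})
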