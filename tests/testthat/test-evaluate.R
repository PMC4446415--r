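# Caller, confusion accounting, rates, sweep, controls, error rates.

test_that("the naive caller emits exactly the well-supported SNVs", {
  g <- rand_genome(2000, 301)
  reads <- sample_reads(g, coverage = 10, seed = 302)
  aln <- align_reads(reads, g, seed = 303)
  expect_identical(nrow(naive_pileup_caller(aln, g)), 0L)

  planted <- plant_variants(g, rate_per_kb = 3, seed = 304)
  reads2 <- sample_reads(planted$genome, coverage = 10, seed = 305)
  aln2 <- align_reads(reads2, g, seed = 306)
  calls <- naive_pileup_caller(aln2, g, min_mq = 0)
  # unique genome, error-free reads: calls = truth (up to read-edge losses)
  expect_true(all(paste(calls$pos, calls$alt) %in%
                    paste(planted$truth$pos, planted$truth$alt)))
  expect_gt(nrow(calls), 0)
})

test_that("caller counts agree with the Rsamtools pileup oracle", {
  g <- rand_genome(3000, 311)
  planted <- plant_variants(g, rate_per_kb = 2, seed = 312)
  reads <- sample_reads(planted$genome, coverage = 8, seed = 313)
  aln <- align_reads(reads, g, seed = 314)
  dir <- withr::local_tempdir()
  samf <- file.path(dir, "a.sam")
  write_sam(aln, genome_lengths(g), samf)
  faf <- file.path(dir, "g.fa")
  write_fasta(g, faf)
  bam <- Rsamtools::asBam(samf, file.path(dir, "a"), overwrite = TRUE)
  pp <- Rsamtools::pileup(
    bam, pileupParam = Rsamtools::PileupParam(distinguish_strands = FALSE,
                                              min_base_quality = 0L,
                                              min_mapq = 0L,
                                              max_depth = 1000L))
  calls <- naive_pileup_caller(aln, g, min_mq = 0)
  for (i in seq_len(nrow(calls))) {
    alt_count <- sum(pp$count[pp$pos == calls$pos[i] &
                                pp$nucleotide == calls$alt[i]])
    expect_identical(alt_count, as.integer(info_field(calls$info[i], "VC")))
    depth <- sum(pp$count[pp$pos == calls$pos[i]])
    expect_identical(depth, as.integer(info_field(calls$info[i], "DP")))
  }
})

test_that("local classification matches the worked example and edge cases", {
  wx <- worked_example_fixture()
  cc <- classify_local(wx$calls, wx$truth, wx$genome_length)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(2, 3, 1, 1000))
  # FP / (FP + TN) with the genome-length TN convention: around 3/1000
  expect_equal(fpr(cc), 3 / 1000, tolerance = 0.01)
  expect_equal(tpr(cc), 2 / 3)

  all_called <- classify_local(
    data.frame(chrom = wx$truth$chrom, pos = wx$truth$pos, ref = wx$truth$ref,
               alt = wx$truth$alt, stringsAsFactors = FALSE),
    wx$truth, wx$genome_length)
  expect_identical(c(all_called$FP, all_called$FN), c(0, 0))

  none <- classify_local(wx$calls[0, ], wx$truth, wx$genome_length)
  expect_identical(c(none$TP, none$FP, none$FN), c(0, 0, 3))
})

test_that("thesaurus classification rescues linked calls in the worked example", {
  wx <- worked_example_fixture()
  cc <- classify_thesaurus(wx$calls, wx$links, wx$truth, wx$genome_length)
  expect_identical(cc$TP, 2)
  expect_identical(cc$FP, 0)
  expect_identical(cc$FN, 0)
  expect_identical(cc$TTP, 3)  # every formerly false-positive call is linked
  expect_equal(fpr(cc), 0)
  expect_equal(ttpr(cc), 1.0)
})

test_that("with no links thesaurus classification reduces to local", {
  set.seed(321)
  mk_sites <- function(n) {
    data.frame(chrom = rep("chr1", n), pos = sample.int(5000L, n),
               ref = rep("A", n), alt = sample(c("C", "G", "T"), n, TRUE),
               stringsAsFactors = FALSE)
  }
  for (rep in 1:10) {
    truth <- mk_sites(sample(0:20, 1))
    calls <- mk_sites(sample(0:20, 1))
    loc <- classify_local(calls, truth, 5000)
    thes <- classify_thesaurus(calls, empty_links(), truth, 5000)
    expect_identical(c(thes$TP, thes$FP, thes$FN, thes$TTP),
                     c(loc$TP, loc$FP, loc$FN, 0))
  }
})

test_that("thesaurus counts equal an exhaustive set-logic oracle", {
  set.seed(331)
  for (rep in 1:15) {
    pool <- 1:40
    truth <- data.frame(chrom = "c", pos = sample(pool, 8), ref = "A",
                        alt = sample(c("C", "G", "T"), 8, TRUE),
                        stringsAsFactors = FALSE)
    calls <- data.frame(chrom = "c", pos = sample(pool, 10), ref = "A",
                        alt = sample(c("C", "G", "T"), 10, TRUE),
                        stringsAsFactors = FALSE)
    n_l <- sample(0:12, 1)
    links <- if (n_l == 0) empty_links() else data.frame(
      from_chrom = "c", from_pos = sample(calls$pos, n_l, TRUE),
      to_chrom = "c", to_pos = sample(pool, n_l, TRUE), strand = "+",
      proj_ref = "A", proj_alt = sample(c("C", "G", "T"), n_l, TRUE),
      reads = 2L, fraction = 1, stringsAsFactors = FALSE)
    got <- classify_thesaurus(calls, links, truth, 1000)

    tkey <- paste(truth$pos, truth$alt)
    ckey <- paste(calls$pos, calls$alt)
    lkey <- paste(links$to_pos, links$proj_alt)
    tp <- fp <- ttp <- 0
    for (i in seq_len(nrow(calls))) {
      if (ckey[i] %in% tkey) { tp <- tp + 1; next }
      reach <- lkey[links$from_pos == calls$pos[i]]
      if (any(reach %in% tkey)) ttp <- ttp + 1 else fp <- fp + 1
    }
    fn <- sum(!(tkey %in% ckey) & !(tkey %in% lkey))
    expect_identical(c(got$TP, got$FP, got$TTP, got$FN),
                     as.numeric(c(tp, fp, ttp, fn)))
  }
})

test_that("rates handle zero denominators and the TTP=0 reduction", {
  cc0 <- confusion_counts(TP = 0, FP = 0, FN = 0, TN = 0, mode = "local")
  expect_true(is.na(fpr(cc0)))
  expect_true(is.na(tpr(cc0)))
  expect_true(is.na(ttpr(cc0)))
  set.seed(341)
  for (rep in 1:20) {
    cc <- confusion_counts(TP = sample(0:50, 1), FP = sample(0:50, 1),
                           FN = sample(1:50, 1), TN = sample(1:1000, 1),
                           TTP = 0, mode = "thesaurus")
    expect_identical(ttpr(cc), tpr(cc))
    cc2 <- confusion_counts(TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
                            TTP = sample(1:20, 1), mode = "thesaurus")
    expect_gte(ttpr(cc2), tpr(cc2))
    expect_true(fpr(cc2) >= 0 && fpr(cc2) <= 1)
    expect_true(ttpr(cc2) >= 0 && ttpr(cc2) <= 1)
  }
})

test_that("threshold sweeps are flat on unique genomes, monotone on repeats", {
  g <- rand_genome(5000, 351)
  planted <- plant_variants(g, rate_per_kb = 2, seed = 352)
  reads <- sample_reads(planted$genome, coverage = 10, seed = 353)
  aln <- align_reads(reads, g, seed = 354)
  tab <- build_thesaurus(g)   # empty: unique genome
  sw <- sweep_thresholds(aln, g, tab, planted$truth, c(0L, 1L, 30L))
  expect_true(all(sw$points$n_calls == sw$points$n_calls[1]))
  expect_true(all(sw$points$ttpr == sw$points$tpr_local))

  tc <- two_copy_genome(361)
  tab2 <- build_thesaurus(tc$genome)
  planted2 <- plant_variants(tc$genome, rate_per_kb = 2, seed = 362)
  reads2 <- sample_reads(planted2$genome, coverage = 10, seed = 363)
  aln2 <- align_reads(reads2, tc$genome, seed = 364)
  sw2 <- sweep_thresholds(aln2, tc$genome, tab2, planted2$truth, c(0L, 1L, 30L),
                          min_fraction = 0.2)
  expect_true(all(diff(sw2$points$n_calls) <= 0))
})

test_that("random links keep their multiplicity but rescue nothing real", {
  expect_identical(nrow(random_link_control(empty_links(), c(chr1 = 100L))), 0L)
  links <- data.frame(from_chrom = "chr1", from_pos = rep(c(10L, 20L), c(3, 1)),
                      to_chrom = "chr1", to_pos = c(100L, 200L, 300L, 400L),
                      strand = "+", proj_ref = "A", proj_alt = "G",
                      reads = 2L, fraction = 1, stringsAsFactors = FALSE)
  g <- rand_genome(100000, 371)
  ctrl <- random_link_control(links, g, seed = 7)
  expect_identical(table(ctrl$from_pos), table(links$from_pos))
  expect_identical(ctrl[, c("from_chrom", "from_pos", "proj_alt")],
                   links[, c("from_chrom", "from_pos", "proj_alt")])
  expect_false(all(ctrl$to_pos == links$to_pos))
  expect_identical(random_link_control(links, g, seed = 7), ctrl)
})

test_that("error rates are zero on clean unique data and recover the error model", {
  g <- rand_genome(20000, 381)
  reads <- sample_reads(g, coverage = 10, seed = 382)
  aln <- align_reads(reads, g, seed = 383)
  clean <- error_rate(aln, g, variant_sites = NULL)
  expect_identical(clean$rate, 0)

  e <- 0.005
  reads_err <- sample_reads(g, coverage = 10, error_rate = e, seed = 384)
  # place reads at their known true origins so the estimator sees every
  # error (an aligner with protected terminal seeds censors terminal errors)
  aln_err <- data.frame(
    qname = reads_err$read_id,
    flag = ifelse(reads_err$strand == "-", 16L, 0L), chrom = reads_err$chrom,
    pos = reads_err$start, mapq = 40L,
    cigar = sprintf("%dM", nchar(reads_err$seq)), strand = reads_err$strand,
    seq = ifelse(reads_err$strand == "-", revcomp(reads_err$seq), reads_err$seq),
    stringsAsFactors = FALSE)
  est <- error_rate(aln_err, g, variant_sites = NULL)
  # binomial sampling noise around the injected rate
  sd3 <- 3 * sqrt(e * (1 - e) / est$total_bases)
  expect_lt(abs(est$rate - e), sd3 + 1e-4)
})
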