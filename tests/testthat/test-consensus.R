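test_that("family grouping keys on probe, tag and strand and rejects tagless reads", {
  reads <- rbind(
    do.call(rbind, lapply(1:5, function(i) tread(paste0("r", i), "ACGT"))),
    tread("r6", "ACGT", strand = "-"),
    tread("r7", "ACGT", tag = "CCCC"),
    tread("r8", "ACGT", tag = ""))
  g <- group_families(reads)
  expect_identical(g$n_families, 3L)           # same key x5, opposite strand, new tag
  expect_identical(nrow(g$rejected), 1L)
  expect_identical(unname(g$family_sizes[paste("mip1", "AAAA", "+", sep = "|")]), 5L)
  # strands are captured separately: never share a family
  expect_identical(length(unique(g$reads$family[g$reads$strand == "+"])), 2L)
  # no reads -> no families
  g0 <- group_families(reads[0, ])
  expect_identical(g0$n_families, 0L)
})

test_that("family consensus is strict majority with N on ties", {
  f3 <- rbind(tread("a", "A"), tread("b", "A"), tread("c", "A"))
  expect_identical(family_consensus(f3)$consensus, "A")
  fm <- rbind(tread("a", "A"), tread("b", "A"), tread("c", "C"))
  expect_identical(family_consensus(fm)$consensus, "A")  # 2/3 > 0.5
  ft <- rbind(tread("a", "A"), tread("b", "C"))
  expect_identical(family_consensus(ft)$consensus, "N")  # tie
  # a higher agreement requirement turns 2/3 into N
  expect_identical(family_consensus(fm, qc_config(family_agreement_min = 0.7))$consensus, "N")
  # raw N calls never vote but the position is still reported
  fn <- rbind(tread("a", "N"), tread("b", "N"))
  expect_identical(family_consensus(fn)$consensus, "N")
  # families below the size floor are dropped
  expect_identical(nrow(family_consensus(f3, qc_config(min_reads_per_family = 4L))), 0L)
})

test_that("pileups count unique molecules, not reads", {
  # 10 families all A: counts{A:10}, depth 10
  reads <- do.call(rbind, lapply(1:10, function(i)
    tread(paste0("r", i), "A", tag = sprintf("T%02d", i))))
  p <- build_pileup(reads)
  expect_identical(p$A, 10L)
  expect_identical(p$depth, 10L)
  # 1000 raw reads from 10 families: depth bounded by the family count
  reads2 <- do.call(rbind, lapply(1:1000, function(i)
    tread(paste0("r", i), "ACG", tag = sprintf("T%02d", i %% 10))))
  p2 <- build_pileup(reads2)
  expect_true(all(p2$depth <= 10L))
  expect_identical(attr(p2, "n_families"), 10L)
  # positions covered by no family are absent
  expect_false(5000L %in% p2$pos)
})

test_that("tied families contribute N, preserving depth conservation", {
  reads <- rbind(tread("a", "A", tag = "T1"), tread("b", "C", tag = "T1"),
                 tread("c", "A", tag = "T2"))
  p <- build_pileup(reads)
  expect_identical(p$A, 1L)
  expect_identical(p$N, 1L)
  expect_identical(p$depth, 1L)       # N excluded from depth
  # counts + n_count = families covering the position
  expect_identical(p$A + p$C + p$G + p$T + p$N, 2L)
})

test_that("pileup construction agrees with per-family consensus aggregation", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  reads <- do.call(rbind, lapply(1:120, function(i)
    tread(sprintf("r%03d", i),
          paste(sample(bases, 6, replace = TRUE), collapse = ""),
          pos_start = sample(100:104, 1),
          tag = sample(c("T1", "T2", "T3", "T4"), 1),
          mip = sample(c("m1", "m2"), 1),
          strand = sample(c("+", "-"), 1))))
  qc <- qc_config()
  p <- build_pileup(reads)
  # independent route: explicit per-family consensus, tallied by hand
  g <- group_families(reads)
  tall <- do.call(rbind, lapply(split(g$reads, g$reads$family), family_consensus, qc = qc))
  for (i in seq_len(nrow(p))) {
    here <- tall[tall$pos == p$pos[i], ]
    for (b in c("A", "C", "G", "T", "N")) {
      expect_identical(p[[b]][i], sum(here$consensus == b))
    }
  }
  # determinism: read order never matters
  perm <- reads[sample(nrow(reads)), ]
  expect_identical(build_pileup(perm), p)
})

test_that("consensus collapsing corrects sequencing errors", {
  # 4000 families x 10 reads, 1% per-read error: consensus base error < 0.01%
  set.seed(51)
  n_fam <- 4000L; n_reads <- 10L; err <- 0.01
  truth <- sample(c("A", "C", "G", "T"), n_fam, replace = TRUE)
  M <- matrix(rep(truth, each = n_reads), nrow = n_reads)
  flip <- which(matrix(runif(n_fam * n_reads) < err, nrow = n_reads))
  M[flip] <- vapply(M[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  reads <- data.frame(read_id = sprintf("r%05d", seq_len(n_fam * n_reads)),
                      mip_id = "m1",
                      tag = sprintf("T%05d", rep(seq_len(n_fam), each = n_reads)),
                      strand = "+", chrom = "chr1",
                      pos_start = rep(seq_len(n_fam), each = n_reads),
                      bases = as.vector(M), quals = "I",
                      stringsAsFactors = FALSE)
  g <- group_families(reads)
  long <- panelmips:::explode_reads(g$reads)
  cons <- panelmips:::consensus_long(long, qc_config()$family_agreement_min)
  called <- cons$consensus[match(paste0("m1|", sprintf("T%05d", seq_len(n_fam)), "|+"),
                                 cons$family)]
  wrong <- called != truth & called != "N"
  expect_lt(mean(wrong), 1e-4)
})

test_that("sample QC flags low tag complexity and read-count outliers", {
  batch <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    read_total = c(5e6, 5e6, 5e6, 1e6, 5e6),
    unique_tags = c(2e6, 2e6, 2e6, 2e6, 599999))
  qc <- sample_qc(batch)
  expect_identical(qc$pass, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_match(qc$reasons[4], "read count")       # 1M < mean - 1 SD
  expect_match(qc$reasons[5], "tag complexity")   # just below 600,000
  # identical read totals: SD = 0 and everyone sits at the mean -> pass
  same <- data.frame(sample_id = c("a", "b", "c"), read_total = 3e6,
                     unique_tags = 1e6)
  expect_true(all(sample_qc(same)$pass))
  # singleton batches cannot support the SD test
  expect_warning(sample_qc(same[1, ]), "skipped")
})

test_that("tagged reads round-trip through the TSV dialect and SAM", {
  reads <- rbind(tread("r1", "ACGTT"), tread("r2", "ACGTT", strand = "-"),
                 tread("r3", "GGTA", pos_start = 200L, tag = "CCGG", mip = "mip2"))
  f <- tempfile(fileext = ".tsv")
  write_tagged_reads(reads, f)
  expect_identical(read_tagged_reads(f), reads)

  skip_if_not_installed("Rsamtools")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:100000",
           sprintf("%s\t%d\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tRX:Z:%s\tXP:Z:%s",
                   reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                   reads$pos_start, nchar(reads$bases), reads$bases,
                   reads$quals, reads$tag, reads$mip_id))
  fs <- tempfile(fileext = ".sam")
  writeLines(sam, fs)
  from_sam <- read_tagged_reads_sam(fs)
  ord <- order(from_sam$read_id)
  expect_identical(from_sam[ord, ]$bases, reads[order(reads$read_id), ]$bases)
  expect_identical(from_sam[ord, ]$tag, reads[order(reads$read_id), ]$tag)
  expect_identical(from_sam[ord, ]$mip_id, reads[order(reads$read_id), ]$mip_id)
  expect_identical(from_sam[ord, ]$strand, reads[order(reads$read_id), ]$strand)
})
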