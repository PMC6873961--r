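somatic_v <- function(id, start, score_items = list(ev_item("E1"), ev_item("E2", level = "B", stars = 3L)),
                      ...) {
  variant_rec(id, chrom = "1", start = start, stop = start, ...,
              evidence = score_items)
}

test_that("eligibility cascade applies rules in order with one primary reason", {
  vars <- list(
    somatic_v("V01", 100L),                                  # eligible, score 55
    somatic_v("V02", 200L, list(ev_item("E", level = "A", stars = 2L))),  # score exactly 20
    somatic_v("V03", 300L, list(ev_item("E", level = "C", stars = 1L))),  # score 1
    variant_rec("V04", chrom = "1", start = 400L, stop = 400L,
                so = list("SO:0001565")),                    # fusion
    variant_rec("V05", chrom = "1", start = 500L, stop = 500L,
                evidence = list(
                  ev_item("Ea", type = "Predisposing", origin = "Germline",
                          significance = "Pathogenic"),
                  ev_item("Eb", type = "Predisposing", origin = "Germline",
                          significance = "Pathogenic", level = "B"))),
    variant_rec("V06", chrom = "1", start = 600L, stop = 600L,
                evidence = list(
                  ev_item("Ec", significance = "Sensitivity/Response"),
                  ev_item("Ed", significance = "Resistance"))),
    variant_rec("V07", with_coords = FALSE))
  out <- filter_eligible(snapshot_from(vars))
  expect_identical(out$eligible, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$reason,
                   c(NA, "evidence score", "evidence score", "not DNA-based",
                     "germline-only", "conflicting evidence", "no coordinates"))
  # score exactly at the threshold is excluded: the gate is strict
  expect_equal(out$evidence_score[out$id == "V02"], 20)

  # germline-only exemption for Predisposing evidence is a flag
  out2 <- filter_eligible(snapshot_from(vars),
                          panel_config(germline_exempt_predisposing = TRUE))
  expect_true(out2$eligible[out2$id == "V05"])

  # conflicting evidence with different drug sets is not "directly" conflicting
  v_drugs <- variant_rec("V08", chrom = "1", start = 700L, stop = 700L,
                         evidence = list(
                           ev_item("Ee", significance = "Sensitivity/Response",
                                   drugs = list("DrugA")),
                           ev_item("Ef", significance = "Resistance",
                                   drugs = list("DrugB"))))
  out3 <- filter_eligible(snapshot_from(list(v_drugs)))
  expect_true(out3$eligible)
})

test_that("a container whose evidence majority cites covered hotspots is redundant", {
  hot1 <- somatic_v("V01", 100L)
  hot2 <- somatic_v("V02", 200L)
  container <- variant_rec("V10", name = "MUTATION", chrom = "1", start = 50L,
                           stop = 1000L, ref = "", alt = "",
                           evidence = list(
                             ev_item("E1", level = "B", stars = 1L,
                                     coords = list("1", 100L, 100L)),
                             ev_item("E2", level = "B", stars = 1L,
                                     coords = list("1", 200L, 200L)),
                             ev_item("E3", level = "B", stars = 1L,
                                     coords = list("1", 100L, 100L)),
                             ev_item("E4", level = "B", stars = 2L)))
  out <- filter_eligible(snapshot_from(list(hot1, hot2, container)))
  # 3 of 4 items (0.75 > 0.5) cite hotspots inside already-selected regions
  expect_identical(out$reason[out$id == "V10"], "redundant container")
  # with a stricter majority requirement the container survives
  out2 <- filter_eligible(snapshot_from(list(hot1, hot2, container)),
                          panel_config(redundancy_majority_fraction = 0.8))
  expect_true(out2$eligible[out2$id == "V10"])
})

test_that("eligibility is monotone in the score threshold", {
  set.seed(21)
  vars <- lapply(1:15, function(i)
    somatic_v(sprintf("V%02d", i), 100L * i,
              list(ev_item("E", level = sample(c("A", "B", "C"), 1),
                           stars = sample(1:5, 1)))))
  snap <- snapshot_from(vars)
  n_at <- vapply(c(0, 5, 10, 20, 40, 60), function(thr)
    sum(filter_eligible(snap, panel_config(min_evidence_score = thr))$eligible),
    numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("strategy assignment splits on length with a strict 250 bp bound", {
  snap <- snapshot_from(list(
    somatic_v("V1", 100L),                                               # length 1
    variant_rec("V2", chrom = "1", start = 1000L, stop = 1002L),          # codon, 3 bp
    variant_rec("V3", chrom = "1", start = 2000L, stop = 2249L, ref = "",
                alt = "", name = "EXON 2"),                               # exactly 250
    variant_rec("V4", chrom = "1", start = 3000L, stop = 3999L, ref = "",
                alt = "", name = "MUTATION")))                            # container
  st <- assign_strategy(snap)
  expect_identical(st, c("hotspot", "hotspot", "sparse_tiling", "full_tiling"))
  # strategy is a partition: every eligible variant gets exactly one
  expect_false(anyNA(st))
  # config-table override
  cfg <- panel_config(tiling_rule = "config_table",
                      config_table = data.frame(id = "V3", strategy = "full_tiling"))
  expect_identical(assign_strategy(snap, cfg)[3], "full_tiling")
})

test_that("region building tiles exons, merges intervals, and honors flanks", {
  gm <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1000, 2000, 3000),
                                                     c(1199, 2199, 3199)),
                               type = "CDS", gene_id = "GENE1", gene_name = "GENE1")
  # two overlapping hotspots coalesce into one region
  snap <- snapshot_from(list(
    variant_rec("V1", gene = "GENE1", chrom = "1", start = 100L, stop = 110L,
                ref = "", alt = "", name = "DEL1"),
    variant_rec("V2", gene = "GENE1", chrom = "1", start = 105L, stop = 120L,
                ref = "", alt = "", name = "DEL2")))
  regions <- build_regions(snap, gm)
  expect_identical(nrow(regions), 1L)
  expect_identical(c(regions$start, regions$stop), c(100L, 120L))
  expect_identical(regions$variant_ids[[1]], c("V1", "V2"))

  # a single hotspot with no flank reproduces the variant interval
  r1 <- build_regions(snap[1, ], gm)
  expect_identical(c(r1$start, r1$stop), c(100L, 110L))
  r1f <- build_regions(snap[1, ], gm, panel_config(hotspot_flank = 25L))
  expect_identical(c(r1f$start, r1f$stop), c(75L, 135L))

  # full tiling of a 3-exon gene: per-base brute force equals total_bp
  cont <- snapshot_from(list(variant_rec("VC", gene = "GENE1", chrom = "1",
                                         start = 900L, stop = 3500L, ref = "",
                                         alt = "", name = "MUTATION")))
  rfull <- build_regions(cont, gm)
  expect_identical(nrow(rfull), 3L)
  ps <- panel_summary(rfull, cont)
  expect_identical(ps$total_bp, 600L)
  expect_identical(ps$total_bp, brute_force_bp(rfull))

  # sparse tiling keeps only exons hit by evidence-cited hotspots
  sparse <- snapshot_from(list(variant_rec(
    "VS", gene = "GENE1", chrom = "1", start = 900L, stop = 3500L, ref = "",
    alt = "", name = "EXONS",
    evidence = list(ev_item("E1", coords = list("1", 2050L, 2050L)),
                    ev_item("E2", level = "B", stars = 3L)))))
  rsp <- build_regions(sparse, gm)
  expect_identical(nrow(rsp), 1L)
  expect_identical(c(rsp$start, rsp$stop), c(2000L, 2199L))

  # a tiled gene missing from the gene models is a hard error naming it
  orphan <- snapshot_from(list(variant_rec("VO", gene = "NOPE", chrom = "1",
                                           start = 1L, stop = 500L, ref = "",
                                           alt = "", name = "MUTATION")))
  expect_error(build_regions(orphan, gm), "NOPE")
})

test_that("merging is idempotent, coalesces bookended intervals, and matches brute force", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    start <- sample(1:300, n, replace = TRUE)
    regions <- data.frame(chrom = sample(c("1", "2"), n, replace = TRUE),
                          start = start, stop = start + sample(0:40, n, replace = TRUE),
                          strategy = "hotspot", stringsAsFactors = FALSE)
    regions$variant_ids <- as.list(sprintf("V%02d", seq_len(n)))
    class(regions) <- c("target_regions", "data.frame")
    m1 <- merge_regions(regions)
    expect_identical(merge_regions(m1), m1)
    # merged regions are sorted, pairwise disjoint per chromosome
    for (ch in unique(m1$chrom)) {
      x <- m1[m1$chrom == ch, ]
      if (nrow(x) > 1) expect_true(all(x$start[-1] > x$stop[-nrow(x)] + 1L))
    }
    expect_identical(sum(m1$stop - m1$start + 1L), brute_force_bp(regions))
  }
  # bookended intervals are contiguous capture targets: they merge
  bk <- data.frame(chrom = "1", start = c(1L, 11L), stop = c(10L, 20L),
                   strategy = "hotspot", stringsAsFactors = FALSE)
  bk$variant_ids <- list("A", "B")
  class(bk) <- c("target_regions", "data.frame")
  mb <- merge_regions(bk)
  expect_identical(nrow(mb), 1L)
  expect_identical(c(mb$start, mb$stop), c(1L, 20L))
})

test_that("evidence percentages reproduce the printed shares from their counts", {
  counts <- c(Predictive = 820, Prognostic = 232, Diagnostic = 52, Predisposing = 64)
  pct <- percent_shares(counts)
  expect_identical(unname(pct), c(70, 20, 4, 6))
  expect_identical(sum(pct), 100)
  expect_equal(unname(percent_shares(counts, "nearest", 1)),
               c(70.2, 19.9, 4.5, 5.5))
})

test_that("BED emission is 0-based half-open and round-trips", {
  regions <- data.frame(chrom = c("7", "2"), start = c(140453136L, 100L),
                        stop = c(140453136L, 250L),
                        strategy = c("hotspot", "full_tiling"),
                        stringsAsFactors = FALSE)
  regions$variant_ids <- list("V600E", c("Va", "Vb"))
  class(regions) <- c("target_regions", "data.frame")
  f <- tempfile(fileext = ".bed")
  write_bed(regions, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#")
  # natural chromosome order puts 2 before 7; closed [s,e] -> (s-1, e]
  expect_identical(lines[2], "2\t99\t250\tfull_tiling:Va,Vb")
  expect_identical(lines[3], "7\t140453135\t140453136\thotspot:V600E")
  back <- read_bed(f)
  expect_identical(back$start, c(100L, 140453136L))
  expect_identical(back$stop, c(250L, 140453136L))
  expect_identical(back$variant_ids[[1]], c("Va", "Vb"))
  # independent coordinate check through rtracklayer's BED importer
  gr <- rtracklayer::import(f, format = "BED")
  expect_identical(GenomicRanges::start(gr), c(100L, 140453136L))
  expect_identical(GenomicRanges::end(gr), c(250L, 140453136L))
  # empty panels still produce a headered file
  write_bed(empty_target_regions(), f)
  expect_match(readLines(f), "^#")
  expect_identical(nrow(read_bed(f)), 0L)
})
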