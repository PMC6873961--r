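test_that("binomial detectability is exact, bounded and monotone", {
  cfg <- rescue_config()  # k = 3, confidence 0.95
  # degenerate inputs: no trials or no per-read probability
  expect_identical(binomial_detectability(0, 0.5), 1)
  expect_identical(binomial_detectability(100, 0), 1)
  expect_identical(binomial_detectability(100, 1), 0)
  # n = 100, p = 0.10, k = 3: adequate coverage
  p100 <- binomial_detectability(100, 0.10)
  expect_equal(p100, 0.0078365, tolerance = 1e-5)
  expect_lt(p100, cfg$confidence)
  # brute-force enumeration of all per-read outcomes, n <= 12
  for (n in c(1, 2, 5, 9, 12)) {
    for (p in c(0.05, 0.3, 0.7)) {
      for (k in c(0, 2, 3)) {
        expect_equal(binomial_detectability(n, p, rescue_config(max_supporting_reads = k)),
                     enum_binom_le_k(n, p, k), tolerance = 1e-12)
      }
    }
  }
  # cross-check against the distribution function at larger n
  expect_equal(binomial_detectability(5000, 0.02), pbinom(3, 5000, 0.02),
               tolerance = 1e-12)
  # monotone non-increasing in n and in p, always in [0, 1]
  ns <- c(0, 1, 5, 20, 100, 500)
  ps <- c(0, 0.01, 0.05, 0.2, 0.6, 1)
  for (p in ps) {
    v <- vapply(ns, binomial_detectability, numeric(1), smmip_vaf = p)
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v >= 0 & v <= 1))
  }
  for (n in ns) {
    v <- vapply(ps, function(p) binomial_detectability(n, p), numeric(1))
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_error(binomial_detectability(10, 1.2), class = "panelmips_input")
})

test_that("germline calls require diploid VAF patterns at adequate normal depth", {
  expect_true(classify_germline(0.52, 100))    # heterozygous
  expect_true(classify_germline(0.95, 100))    # homozygous
  expect_false(classify_germline(0.02, 100))
  expect_false(classify_germline(0.75, 100))   # between the windows
  expect_true(classify_germline(0.40, 100))    # windows are inclusive
  expect_true(classify_germline(0.60, 100))
  expect_identical(classify_germline(NA, 100), NA)   # no matched normal
  expect_identical(classify_germline(0.5, 5), NA)    # depth too low to judge
})

test_that("repeat context detects MN, DN and TR with MN precedence", {
  mk <- function(s) {
    r <- Biostrings::DNAStringSet(s); names(r) <- "x"; r
  }
  pad <- "GGCGTC"  # repeat-free padding
  expect_identical(repeat_context("x", 9, mk("GGCGTCAAAAAAGCTGACGGTCGTACC")), "MN")
  expect_identical(repeat_context("x", 10, mk("GGCGTCATATATATGCTGACGGTCGTA")), "DN")
  expect_identical(repeat_context("x", 9, mk("GGCGTACGACGACGGTTGACGGTCGTA")), "TR")
  # the repeat must touch the variant site: 12 bp away it does not count
  expect_identical(repeat_context("x", 24, mk("AAAAAAGCTGACGGTCGTACCGGCTGACG")), "none")
  # run of 4 is below the homopolymer floor
  expect_identical(repeat_context("x", 8, mk("GGCGTCAAAAGCTGACGGTCGTACCGG")), "none")
  # precedence: a homopolymer embedded in a dinucleotide context reports MN
  expect_identical(repeat_context("x", 10, mk("GGATATAAAAAATATGACGGTCGTACC")), "MN")
  # windows truncate at contig ends rather than erroring
  expect_identical(repeat_context("x", 2, mk("AAAAAAGCTGACGGTCGTACCGGCTGACG")), "MN")
  # independent regex oracle over random windows and planted motifs
  set.seed(71)
  regex_oracle <- function(s, site, w = 10L) {
    lo <- max(1L, site - w); hi <- min(nchar(s), site + w)
    win <- substr(s, lo, hi); center <- site - lo + 1L
    touches <- function(i, len) i <= center + 1L && i + len - 1L >= center - 1L
    # greedy anchored match at every offset covers all repeat phases
    unit_hit <- function(u, min_units) {
      pat <- sprintf("^([ACGT]{%d})\\1{%d,}", u, min_units - 1L)
      for (i in seq_len(nchar(win) - u * min_units + 1L)) {
        m <- regexpr(pat, substring(win, i), perl = TRUE)
        if (m == 1L) {
          len <- attr(m, "match.length")
          unit <- substr(win, i, i + u - 1L)
          if (length(unique(strsplit(unit, "")[[1]])) >= 2 && touches(i, len)) {
            return(TRUE)
          }
        }
      }
      FALSE
    }
    g <- gregexpr("A{5,}|C{5,}|G{5,}|T{5,}", win, perl = TRUE)[[1]]
    len <- attr(g, "match.length")
    if (any(g != -1 & g <= center + 1L & g + len - 1L >= center - 1L)) return("MN")
    if (unit_hit(2L, 3L)) return("DN")
    for (u in 3:6) if (unit_hit(u, 2L)) return("TR")
    "none"
  }
  for (rep in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    site <- sample(5:25, 1)
    expect_identical(repeat_context("x", site, mk(s)),
                     regex_oracle(s, site),
                     info = sprintf("seq %s site %d", s, site))
  }
})

test_that("the rescue cascade assigns exactly one category in fixed order", {
  set.seed(72)
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "GGCGTC", "AAAAAA",
    paste(sample(c("A", "C", "G", "T"), 220, replace = TRUE), collapse = ""))))
  # pick five repeat-free positions for the non-artifact branches
  clean <- Filter(function(p) repeat_context("chr1", p, ref) == "none", 30:220)
  clean <- as.integer(clean[seq(1, length(clean), by = 5)][1:5])
  calls <- data.frame(
    chrom = "chr1",
    pos = c(8L, clean),
    ref = "G", alt = "T", depth = 1000L, alt_count = c(500L, 480L, 100L, 50L, 200L, 300L),
    vaf = c(0.5, 0.48, 0.1, 0.05, 0.2, 0.3), sample_id = "s",
    stringsAsFactors = FALSE)
  class(calls) <- c("variant_calls", "data.frame")
  support <- data.frame(chrom = "chr1", pos = calls$pos, ref = "G", alt = "T",
                        depth = c(100L, 100L, 5L, 6000L, 80L, NA),
                        alt_count = c(0L, 0L, 0L, 0L, 2L, NA),
                        stringsAsFactors = FALSE)
  support <- support[!is.na(support$depth), ]
  normal <- data.frame(chrom = "chr1", pos = calls$pos,
                       A = 0L, C = 0L, G = c(500L, 500L, 1000L, 1000L, 1000L, 1000L),
                       T = c(500L, 500L, 0L, 0L, 0L, 0L), N = 0L,
                       stringsAsFactors = FALSE)
  normal$depth <- normal$G + normal$T
  cl <- classify_rescued(calls, support, normal, ref)
  # pos 8: homopolymer context AND diploid normal VAF -> germline wins (order)
  expect_identical(cl$category, c(
    "germline",                          # normal VAF 0.5, despite MN context
    "germline",                          # plain heterozygous
    "no_support_insufficient_coverage",  # depth 5, P(X<=3) ~ 1
    "no_support_adequate_coverage",      # depth 6000 at VAF 0.05
    "supported_in_original",             # 2 supporting reads
    "unresolvable"))                     # no original depth information
  expect_identical(cl$artifact_subtype[1], "none")  # germline won before repeat test
  # binom_prob present exactly when the no-support branch evaluated it,
  # and only zero-support variants ever reach that branch
  no_support <- cl$category %in% c("no_support_insufficient_coverage",
                                   "no_support_adequate_coverage")
  expect_identical(!is.na(cl$binom_prob), no_support)
  expect_true(all(cl$original_alt_count[no_support] == 0L))
  # artifact context without germline signal
  calls2 <- transform(calls[1, ], pos = 8L)
  class(calls2) <- c("variant_calls", "data.frame")
  normal2 <- transform(normal[1, ], T = 0L, G = 1000L, depth = 1000L)
  cl2 <- classify_rescued(calls2, support, normal2, ref)
  expect_identical(cl2$category, "artifact")
  expect_identical(cl2$artifact_subtype, "MN")
})

test_that("rescue summaries recompute the partition arithmetic", {
  s <- rescue_summary(c(germline = 55, artifact = 36, no_support = 171,
                        supported = 11, no_support_insufficient = 162))
  expect_identical(s$n_classified, 55 + 36 + 171 + 11)
  expect_equal(unname(s$percent),
               c(20.1, 13.2, 62.6, 4.0))
  expect_equal(s$insufficient_pct_of_no_support, 94.7)
  expect_identical(s$clinically_relevant_missed, 171 + 11)
  # empty input: counts zero, percentages undefined
  empty <- classify_rescued(
    structure(data.frame(chrom = character(), pos = integer(), ref = character(),
                         alt = character(), depth = integer(), alt_count = integer(),
                         vaf = numeric(), sample_id = character(),
                         stringsAsFactors = FALSE),
              class = c("variant_calls", "data.frame")),
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), depth = integer(), alt_count = integer()))
  se <- rescue_summary(empty)
  expect_identical(unname(se$counts), c(0L, 0L, 0L, 0L))
  expect_true(all(is.na(se$percent)))
})

test_that("supported-variant VAF concordance matches the covariance oracle", {
  set.seed(81)
  n <- 11
  ovaf <- runif(n, 0.05, 0.5)
  svaf <- ovaf + rnorm(n, 0, 0.03)
  cl <- data.frame(category = "supported_in_original", original_vaf = ovaf,
                   vaf = svaf, stringsAsFactors = FALSE)
  r <- pearson_supported(cl)
  oracle <- mean((ovaf - mean(ovaf)) * (svaf - mean(svaf))) /
    (sqrt(mean((ovaf - mean(ovaf))^2)) * sqrt(mean((svaf - mean(svaf))^2)))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_equal(pearson_supported(data.frame(category = rep("supported_in_original", 2),
                                            original_vaf = c(0.1, 0.4),
                                            vaf = c(0.4, 0.1))), -1)
  expect_error(pearson_supported(cl[1, ]), class = "panelmips_input")
})
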