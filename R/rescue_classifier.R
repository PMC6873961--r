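#' Rescue classification configuration
#'
#' Parameters of the decision cascade applied to variants found only by
#' panel sequencing: germline VAF windows in the matched normal, repeat
#' definitions for the artifact test, and the binomial detectability rule
#' (would at most `max_supporting_reads` variant reads be expected with
#' `confidence` probability, given the original coverage and the observed
#' panel VAF?).
#'
#' @param max_supporting_reads `k` in the binomial test `P(X <= k)`
#'   (default 3).
#' @param confidence classification cutoff: original coverage is
#'   insufficient when `P(X <= k) > confidence` (default 0.95).
#' @param germline_het_window inclusive normal-VAF interval called
#'   heterozygous (default `c(0.40, 0.60)`).
#' @param germline_hom_min normal VAF at or above this is homozygous
#'   (default 0.90).
#' @param homopolymer_min_run minimum single-base run length for a
#'   mononucleotide (MN) repeat context (default 5).
#' @param dinucleotide_min_units minimum consecutive 2-bp units for a
#'   dinucleotide (DN) context (default 3).
#' @param tandem_repeat_min_units minimum consecutive units of length 3-6
#'   for a tandem-repeat (TR) context (default 2).
#' @param repeat_window bp scanned on each side of the variant (default
#'   10).
#' @return an object of class `rescue_config`.
#' @export
rescue_config <- function(max_supporting_reads = 3L,
                          confidence = 0.95,
                          germline_het_window = c(0.40, 0.60),
                          germline_hom_min = 0.90,
                          homopolymer_min_run = 5L,
                          dinucleotide_min_units = 3L,
                          tandem_repeat_min_units = 2L,
                          repeat_window = 10L) {
  stopifnot(max_supporting_reads >= 0, confidence > 0, confidence < 1,
            length(germline_het_window) == 2,
            germline_het_window[1] <= germline_het_window[2])
  structure(list(max_supporting_reads = as.integer(max_supporting_reads),
                 confidence = confidence,
                 germline_het_window = germline_het_window,
                 germline_hom_min = germline_hom_min,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 dinucleotide_min_units = as.integer(dinucleotide_min_units),
                 tandem_repeat_min_units = as.integer(tandem_repeat_min_units),
                 repeat_window = as.integer(repeat_window)),
            class = "rescue_config")
}

#' Binomial detectability of a variant at the original coverage
#'
#' Exact cumulative binomial probability that at most `k` variant-supporting
#' reads occur in `n` original-sequencing reads when each read supports the
#' variant with probability `p` (the observed panel VAF):
#' \deqn{P(X \le k) = \sum_{i=0}^{k} \binom{n}{i} p^i (1-p)^{n-i}.}
#' When this probability exceeds the configured confidence, the original
#' coverage was statistically insufficient to detect the variant. Computed
#' by log-space term summation; degenerate inputs (`n = 0`, `p = 0`) give 1.
#'
#' @param original_depth number of original-sequencing reads `n` at the
#'   site.
#' @param smmip_vaf per-read variant probability `p` in `[0, 1]`.
#' @param cfg a [rescue_config()] supplying `k`.
#' @return `P(X <= k)`, a probability.
#' @examples
#' binomial_detectability(100, 0.10)  # ~0.0078: coverage was adequate
#' @export
binomial_detectability <- function(original_depth, smmip_vaf,
                                   cfg = rescue_config()) {
  n <- original_depth
  p <- smmip_vaf
  k <- cfg$max_supporting_reads
  if (is.na(n) || n < 0) stop_pm("original_depth must be >= 0", "panelmips_input")
  if (is.na(p) || p < 0 || p > 1) stop_pm("smmip_vaf must be in [0, 1]", "panelmips_input")
  n <- as.integer(round(n))
  if (n == 0 || p == 0) return(1)
  if (k >= n) return(1)
  if (p == 1) return(0)
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

#' Germline test on the matched normal
#'
#' A variant is germline when, at adequate normal depth, the normal VAF
#' sits in the heterozygous window (inclusive) or at/above the homozygous
#' threshold; the panel-VAF pattern of germline polymorphisms clusters at
#' 50% and 100%.
#'
#' @param normal_vaf VAF of the variant allele in the matched normal
#'   (`NA` when no normal is available: returns `NA`, test skipped).
#' @param normal_depth consensus depth in the normal at the site.
#' @param cfg a [rescue_config()].
#' @param min_depth minimum normal depth for the test to be informative
#'   (default: the caller's default `min_depth`).
#' @return `TRUE`, `FALSE`, or `NA` (not assessable).
#' @export
classify_germline <- function(normal_vaf, normal_depth, cfg = rescue_config(),
                              min_depth = caller_config()$min_depth) {
  if (is.na(normal_vaf) || is.na(normal_depth)) return(NA)
  if (normal_depth < min_depth) return(NA)
  (normal_vaf >= cfg$germline_het_window[1] & normal_vaf <= cfg$germline_het_window[2]) ||
    normal_vaf >= cfg$germline_hom_min
}

# does a repeat stretch [s, e] (window-local coords) touch the site at
# position `site` (also window-local)? touching = contains or abuts.
touches_site <- function(s, e, site) s <= site + 1L & e >= site - 1L

#' Repeat context around a variant
#'
#' Scans `repeat_window` bp on each side of the site for repeat structure
#' that commonly produces alignment/caller artifacts: mononucleotide runs
#' (MN), dinucleotide repeats (DN), and short tandem repeats with unit
#' length 3-6 (TR). A repeat qualifies when its stretch contains or abuts
#' the variant position. Precedence MN > DN > TR; DN/TR units must contain
#' two distinct bases (otherwise they are mononucleotide runs). Windows are
#' truncated at contig ends.
#'
#' @param chrom,pos variant site (1-based).
#' @param reference `DNAStringSet` or FASTA path.
#' @param cfg a [rescue_config()].
#' @return one of `"MN"`, `"DN"`, `"TR"`, `"none"`.
#' @export
repeat_context <- function(chrom, pos, reference, cfg = rescue_config()) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!chrom %in% names(reference)) {
    stop_pm(sprintf("chromosome '%s' absent from reference", chrom),
            "panelmips_reference")
  }
  len <- length(reference[[chrom]])
  lo <- max(1L, pos - cfg$repeat_window)
  hi <- min(len, pos + cfg$repeat_window)
  s <- as.character(Biostrings::subseq(reference[[chrom]], lo, hi))
  site <- pos - lo + 1L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  # MN: single-base runs
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mn <- r$lengths >= cfg$homopolymer_min_run & touches_site(starts, ends, site)
  if (any(mn)) return("MN")
  # DN then TR: greedy unit scans
  scan_units <- function(u, min_units) {
    nlen <- length(chars)
    i <- 1L
    while (i + u - 1L <= nlen) {
      unit <- chars[i:(i + u - 1L)]
      if (length(unique(unit)) >= 2) {
        reps <- 1L
        while (i + (reps + 1L) * u - 1L <= nlen &&
               all(chars[(i + reps * u):(i + (reps + 1L) * u - 1L)] == unit)) {
          reps <- reps + 1L
        }
        if (reps >= min_units && touches_site(i, i + reps * u - 1L, site)) {
          return(TRUE)
        }
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
    FALSE
  }
  if (scan_units(2L, cfg$dinucleotide_min_units)) return("DN")
  for (u in 3:6) {
    if (scan_units(u, cfg$tandem_repeat_min_units)) return("TR")
  }
  "none"
}

.RESCUE_CATEGORIES <- c("germline", "artifact", "no_support_insufficient_coverage",
                        "no_support_adequate_coverage", "supported_in_original")

#' Classify panel-only variants
#'
#' Applies the fixed decision cascade to variants called from panel
#' sequencing but absent from the original (orthogonal) call set:
#' germline (matched-normal VAF pattern) -> artifact (repeat context) ->
#' no original support (`original_alt_count == 0`; split by the binomial
#' detectability test into insufficient vs. adequate coverage) ->
#' supported in original (`original_alt_count >= 1` but not called). The
#' first matching category wins. Variants with no original-depth
#' information are reported separately as unresolvable.
#'
#' @param calls panel-only `variant_calls`.
#' @param original_support data.frame keyed by site with columns `chrom,
#'   pos, ref, alt, depth, alt_count` from the original sequencing (see
#'   [read_original_support()]).
#' @param normal_pileup optional matched-normal `consensus_pileup`; when
#'   `NULL` the germline test is skipped with a flag.
#' @param reference `DNAStringSet` or FASTA path (repeat context).
#' @param cfg a [rescue_config()].
#' @param caller_cfg a [caller_config()] (normal min depth).
#' @return a `rescue_classifications` data.frame: one row per variant with
#'   `category`, `artifact_subtype` (`MN`/`DN`/`TR`/`none`), `binom_prob`
#'   (present iff `original_alt_count == 0`), `original_depth`,
#'   `original_alt_count`, `original_vaf`, `normal_vaf`, plus the call
#'   columns. Unresolvable variants carry category `"unresolvable"`.
#' @seealso [rescue_summary()], [pearson_supported()]
#' @export
classify_rescued <- function(calls, original_support, normal_pileup = NULL,
                             reference = NULL, cfg = rescue_config(),
                             caller_cfg = caller_config()) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  if (is.character(reference) && !is.null(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  okey <- paste(original_support$chrom, original_support$pos,
                original_support$ref, original_support$alt, sep = ":")
  m <- match(variant_key(calls), okey)
  # positional fallback for records without allele columns
  if (anyNA(m) && !all(c("ref", "alt") %in% names(original_support))) {
    m2 <- match(paste(calls$chrom, calls$pos), paste(original_support$chrom, original_support$pos))
    m[is.na(m)] <- m2[is.na(m)]
  }
  odepth <- original_support$depth[m]
  oalt <- original_support$alt_count[m]
  # normal VAF of the called alt base at each site
  nvaf <- rep(NA_real_, n); ndep <- rep(NA_real_, n)
  if (!is.null(normal_pileup) && nrow(normal_pileup)) {
    nm <- match(paste(calls$chrom, calls$pos),
                paste(normal_pileup$chrom, normal_pileup$pos))
    for (i in seq_len(n)) {
      j <- nm[i]
      if (!is.na(j) && calls$alt[i] %in% c("A", "C", "G", "T")) {
        ndep[i] <- normal_pileup$depth[j]
        nvaf[i] <- if (normal_pileup$depth[j] > 0)
          normal_pileup[[calls$alt[i]]][j] / normal_pileup$depth[j] else NA_real_
      }
    }
  }
  category <- character(n)
  subtype <- rep("none", n)
  binom_prob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(odepth[i])) { category[i] <- "unresolvable"; next }
    g <- classify_germline(nvaf[i], ndep[i], cfg, caller_cfg$min_depth)
    if (isTRUE(g)) { category[i] <- "germline"; next }
    if (!is.null(reference)) {
      rc <- repeat_context(calls$chrom[i], calls$pos[i], reference, cfg)
      if (rc != "none") { category[i] <- "artifact"; subtype[i] <- rc; next }
    }
    if (oalt[i] == 0) {
      binom_prob[i] <- binomial_detectability(odepth[i], calls$vaf[i], cfg)
      category[i] <- if (binom_prob[i] > cfg$confidence)
        "no_support_insufficient_coverage" else "no_support_adequate_coverage"
    } else {
      category[i] <- "supported_in_original"
    }
  }
  out <- cbind(calls, data.frame(
    category = category, artifact_subtype = subtype, binom_prob = binom_prob,
    original_depth = odepth, original_alt_count = oalt,
    original_vaf = ifelse(!is.na(odepth) & odepth > 0, oalt / odepth, NA_real_),
    normal_vaf = nvaf, stringsAsFactors = FALSE))
  class(out) <- c("rescue_classifications", "data.frame")
  out
}

#' Summarize a rescue classification
#'
#' Reduces per-variant classifications to the four top-level category
#' counts (the two no-support subcategories are reported together and also
#' broken out), percentages of the classifiable total at one-decimal
#' rounding, the share of no-support variants attributable to insufficient
#' coverage, and the count of potentially clinically relevant somatic
#' variants missed by the original sequencing (everything that is neither
#' germline nor artifact).
#'
#' Can also be applied directly to a named count vector
#' (`germline`, `artifact`, `no_support`, `supported`, optionally
#' `no_support_insufficient`) to recompute the partition arithmetic of an
#' existing tally.
#'
#' @param x a `rescue_classifications` data.frame or a named count vector.
#' @return a `rescue_summary` list: `counts`, `percent` (1 decimal),
#'   `n_classified`, `n_unresolvable`, `insufficient_pct_of_no_support`,
#'   `clinically_relevant_missed`.
#' @examples
#' rescue_summary(c(germline = 55, artifact = 36, no_support = 171,
#'                  supported = 11, no_support_insufficient = 162))
#' @export
rescue_summary <- function(x) {
  if (is.numeric(x)) {
    counts <- c(germline = unname(x["germline"]), artifact = unname(x["artifact"]),
                no_support = unname(x["no_support"]), supported = unname(x["supported"]))
    n_insuf <- unname(x["no_support_insufficient"])
    n_unres <- 0L
  } else {
    cl <- x$category
    n_unres <- sum(cl == "unresolvable")
    cl <- cl[cl != "unresolvable"]
    counts <- c(
      germline = sum(cl == "germline"),
      artifact = sum(cl == "artifact"),
      no_support = sum(cl %in% c("no_support_insufficient_coverage",
                                 "no_support_adequate_coverage")),
      supported = sum(cl == "supported_in_original"))
    n_insuf <- sum(cl == "no_support_insufficient_coverage")
  }
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 1) else
    stats::setNames(rep(NA_real_, 4), names(counts))
  structure(list(
    counts = counts,
    n_no_support_insufficient = unname(n_insuf),
    percent = pct,
    n_classified = unname(total),
    n_unresolvable = n_unres,
    insufficient_pct_of_no_support = if (!is.na(n_insuf) && counts[["no_support"]] > 0)
      round(100 * n_insuf / counts[["no_support"]], 1) else NA_real_,
    clinically_relevant_missed = unname(counts[["no_support"]] + counts[["supported"]])
  ), class = "rescue_summary")
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat(sprintf("rescued variants: %d classified (%d unresolvable)\n",
              x$n_classified, x$n_unresolvable))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-11s %4d (%s%%)\n", nm, x$counts[[nm]], x$percent[[nm]]))
  }
  if (!is.na(x$insufficient_pct_of_no_support)) {
    cat(sprintf("  no-support with insufficient original coverage: %d (%s%%)\n",
                x$n_no_support_insufficient, x$insufficient_pct_of_no_support))
  }
  cat(sprintf("  clinically relevant missed by original sequencing: %d\n",
              x$clinically_relevant_missed))
  invisible(x)
}

#' VAF concordance for variants supported in the original data
#'
#' Pearson correlation between original-sequencing VAF and panel VAF over
#' variants classified `supported_in_original`.
#'
#' @param classifications a `rescue_classifications` data.frame.
#' @return correlation coefficient; error if fewer than 2 supported
#'   variants.
#' @export
pearson_supported <- function(classifications) {
  sup <- classifications[classifications$category == "supported_in_original", ,
                         drop = FALSE]
  if (nrow(sup) < 2) {
    stop_pm("fewer than 2 supported-in-original variants: correlation undefined",
            "panelmips_input")
  }
  pearson(sup$original_vaf, sup$vaf)
}

#' Read / write an original-sequencing support table
#'
#' TSV with columns `chrom, pos, ref, alt, depth, alt_count`: per-site
#' coverage and variant-supporting read counts from the original
#' (orthogonal) sequencing, as produced by [make_original_calls()] or by
#' tabulating a pileup of the original BAMs.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_original_support <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' @rdname read_original_support
#' @param support the support data.frame.
#' @export
write_original_support <- function(support, path) {
  utils::write.table(support, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
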