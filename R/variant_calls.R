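#' Variant caller configuration
#'
#' Emission thresholds for SNV calls from consensus pileups. These are
#' explicit configuration: consensus (unique-molecule) depth behaves very
#' differently from raw read depth, and appropriate cutoffs depend on
#' family counts and input mass.
#'
#' @param min_depth minimum consensus depth at the site (default 20).
#' @param min_alt_count minimum unique molecules supporting the alternate
#'   base (default 4).
#' @param min_vaf minimum variant allele frequency (default 0.01).
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(min_depth = 20L, min_alt_count = 4L, min_vaf = 0.01) {
  stopifnot(min_depth >= 0, min_alt_count >= 0, min_vaf >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_count = as.integer(min_alt_count),
                 min_vaf = min_vaf), class = "caller_config")
}

#' Call SNVs from a consensus pileup
#'
#' Emits one call per position and non-reference base whose
#' unique-molecule support passes all thresholds. VAF is
#' `alt_count / depth` on consensus (unique-molecule) counts.
#'
#' @param pileup a `consensus_pileup` (already restricted to panel
#'   regions).
#' @param reference `DNAStringSet` or FASTA path covering every pileup
#'   chromosome/position (error otherwise).
#' @param cfg a [caller_config()].
#' @param sample_id sample label carried on each call.
#' @return a `variant_calls` data.frame: `chrom, pos, ref, alt, depth,
#'   alt_count, vaf, sample_id`.
#' @export
call_variants <- function(pileup, reference, cfg = caller_config(),
                          sample_id = "sample") {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(), alt_count = integer(),
                      vaf = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("variant_calls", "data.frame")
  if (!nrow(pileup)) return(empty)
  miss <- setdiff(unique(pileup$chrom), names(reference))
  if (length(miss)) {
    stop_pm(paste0("pileup chromosomes absent from reference: ",
                   paste(miss, collapse = ", ")), "panelmips_reference")
  }
  lens <- Biostrings::width(reference)[match(pileup$chrom, names(reference))]
  if (any(pileup$pos < 1 | pileup$pos > lens)) {
    stop_pm("pileup positions outside the reference sequence", "panelmips_reference")
  }
  ref_base <- vapply(seq_len(nrow(pileup)), function(i)
    as.character(Biostrings::subseq(reference[[pileup$chrom[i]]],
                                    pileup$pos[i], pileup$pos[i])),
    character(1))
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    cnt <- pileup[[b]]
    sel <- b != ref_base & pileup$depth >= cfg$min_depth &
      cnt >= cfg$min_alt_count & cnt / pmax(pileup$depth, 1L) >= cfg$min_vaf
    if (any(sel)) {
      rows[[b]] <- data.frame(
        chrom = pileup$chrom[sel], pos = pileup$pos[sel],
        ref = ref_base[sel], alt = b,
        depth = pileup$depth[sel], alt_count = cnt[sel],
        vaf = cnt[sel] / pileup$depth[sel],
        sample_id = sample_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[chrom_order(out$chrom), , drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Product-moment (Pearson) correlation with explicit degenerate handling
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the correlation coefficient in `[-1, 1]`.
#' @section Errors: a zero-variance input raises a condition of class
#'   `panelmips_zero_variance`, distinct from ordinary input errors.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_pm("x and y must have equal length", "panelmips_input")
  if (length(x) < 2) stop_pm("need at least 2 points", "panelmips_input")
  if (anyNA(x) || anyNA(y)) stop_pm("missing values in input", "panelmips_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_pm("zero variance: correlation undefined", "panelmips_zero_variance")
  }
  stats::cor(x, y, method = "pearson")
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Compare panel calls to an orthogonal truth set
#'
#' Truth variants are first intersected with the panel regions: only
#' overlapping records are eligible (detectable by design). A truth variant
#' counts as detected when a call matches it on all of chromosome,
#' position, reference and alternate allele (alleles normalized on both
#' sides first). Sensitivity is `100 * detected / eligible`; the VAF
#' correlation is computed over detected variants only.
#'
#' @param calls a `variant_calls` data.frame.
#' @param truth data.frame from [read_vcf()] (columns `chrom, pos, ref,
#'   alt, vaf`).
#' @param regions `target_regions` defining the panel footprint.
#' @param reference optional `DNAStringSet` for indel left-alignment.
#' @return a `comparison_result` list: `n_truth_eligible`, `n_detected`,
#'   `sensitivity_pct` (nearest integer), `sensitivity_raw`, `pearson_r`
#'   (`NA` when fewer than 2 detected pairs or degenerate variance), and
#'   `table` (per-truth-variant rows with `truth_vaf`, `smmip_vaf`,
#'   `detected`).
#' @export
compare_to_truth <- function(calls, truth, regions, reference = NULL) {
  truth <- normalize_variants_df(truth, reference)
  calls <- normalize_variants_df(as.data.frame(calls), reference)
  if (nrow(truth)) {
    gr <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$pos, truth$pos + nchar(truth$ref) - 1L))
    truth <- truth[IRanges::overlapsAny(gr, regions_to_granges(regions)), , drop = FALSE]
  }
  n_elig <- nrow(truth)
  m <- match(variant_key(truth), variant_key(calls))
  detected <- !is.na(m)
  tab <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                    alt = truth$alt, truth_vaf = truth$vaf,
                    smmip_vaf = ifelse(detected, calls$vaf[m], NA_real_),
                    detected = detected, stringsAsFactors = FALSE)
  n_det <- sum(detected)
  sens_raw <- if (n_elig > 0) n_det / n_elig else NA_real_
  pr <- NA_real_
  ok <- detected & !is.na(tab$truth_vaf)
  if (sum(ok) >= 2) {
    pr <- tryCatch(pearson(tab$truth_vaf[ok], tab$smmip_vaf[ok]),
                   panelmips_zero_variance = function(e) NA_real_)
  }
  structure(list(
    n_truth_eligible = n_elig, n_detected = n_det,
    sensitivity_pct = if (is.na(sens_raw)) NA_real_ else round(100 * sens_raw),
    sensitivity_raw = sens_raw,
    pearson_r = pr, table = tab
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (is.na(x$sensitivity_raw)) {
    cat("comparison: no eligible truth variants; sensitivity undefined\n")
  } else {
    cat(sprintf("comparison: %d/%d truth variants detected (%d%% sensitivity), VAF r = %s\n",
                x$n_detected, x$n_truth_eligible, x$sensitivity_pct,
                ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  }
  invisible(x)
}
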