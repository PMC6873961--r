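#' Read variant records from a VCF
#'
#' Thin wrapper over `vcfR::read.vcfR()` returning a flat per-allele
#' data.frame. Multiallelic rows are expanded, one row per ALT allele. A
#' VAF per record is recovered from, in order of preference: the `AF` or
#' `VAF` INFO key, or the first sample's `AF` FORMAT value; `NA` when
#' absent.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return data.frame `chrom, pos, ref, alt, vaf`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)) || !nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), stringsAsFactors = FALSE))
  }
  info_af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  if (all(is.na(info_af))) {
    info_af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
  }
  if (all(is.na(info_af)) && ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) >= 2) {
    fmt_af <- tryCatch(
      suppressWarnings(as.numeric(vcfR::extract.gt(v, "AF")[, 1])),
      error = function(e) rep(NA_real_, nrow(fix)))
    info_af <- fmt_af
  }
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  reps <- lengths(alts)
  data.frame(
    chrom = rep(as.character(fix[, "CHROM"]), reps),
    pos = rep(as.integer(fix[, "POS"]), reps),
    ref = rep(toupper(as.character(fix[, "REF"])), reps),
    alt = toupper(unlist(alts)),
    vaf = rep(info_af, reps),
    stringsAsFactors = FALSE
  )
}

#' Write variant calls to a VCF (v4.2)
#'
#' Minimal single-sample VCF with `DP` (consensus depth), `AD`
#' (ref,alt unique-molecule counts) and `AF` FORMAT fields, plus an `AF`
#' INFO mirror so the file round-trips through [read_vcf()].
#'
#' @param calls a `variant_calls` data.frame (see [call_variants()]).
#' @param path output path.
#' @param sample_id sample column name; defaults to the calls' sample id.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, path, sample_id = NULL) {
  sample_id <- sample_id %||% (if (nrow(calls)) calls$sample_id[1] else "SAMPLE")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelmips",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Consensus variant allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Consensus depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Unique-molecule allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Variant allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
          sample_id, sep = "\t"))
  body <- character()
  if (nrow(calls)) {
    calls <- calls[chrom_order(calls$chrom), , drop = FALSE]
    calls <- calls[order(match(calls$chrom, unique(calls$chrom)), calls$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g\tGT:DP:AD:AF\t./.:%d:%d,%d:%.6g",
                    calls$chrom, calls$pos, calls$ref, calls$alt, calls$vaf,
                    calls$depth, calls$depth - calls$alt_count, calls$alt_count,
                    calls$vaf)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Normalize a variant to left-aligned minimal representation
#'
#' Trims shared suffix then prefix bases (keeping at least one base per
#' allele) and, for pure insertions/deletions, shifts the representation
#' left while the flanking reference base matches the trailing base of the
#' longer allele. SNVs are unchanged. Reference sequence is needed only for
#' the left shift; without it only trimming is performed.
#'
#' @param chrom,pos,ref,alt variant; `pos` 1-based.
#' @param reference optional `DNAStringSet`.
#' @return list `chrom, pos, ref, alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is.null(reference)) names(reference) <- sub("\\s.*$", "", names(reference))
  # classical left-align loop: drop matching terminal bases, extending left
  # from the reference whenever an allele would empty out
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr <= 1 && la <= 1) break
    last <- substring(ref, lr)
    if (last != substring(alt, la)) break
    if ((lr == 1 || la == 1) && (is.null(reference) || pos <= 1)) break
    ref <- substring(ref, 1, lr - 1)
    alt <- substring(alt, 1, la - 1)
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      prev <- as.character(Biostrings::subseq(reference[[chrom]], pos - 1L, pos - 1L))
      ref <- paste0(prev, ref); alt <- paste0(prev, alt)
      pos <- pos - 1L
    }
  }
  # shared prefix trim, keeping one anchor base per allele
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, 1, 1) == substring(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

# vectorized normalization over a calls-like data.frame
normalize_variants_df <- function(df, reference = NULL) {
  if (!nrow(df)) return(df)
  for (i in seq_len(nrow(df))) {
    nv <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], reference)
    df$pos[i] <- nv$pos; df$ref[i] <- nv$ref; df$alt[i] <- nv$alt
  }
  df
}
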