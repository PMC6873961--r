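#' Read molecular-tagged reads (TSV dialect)
#'
#' The documented TSV dialect has one aligned read per row with columns
#' `read_id, mip_id, tag, strand, chrom, pos_start, bases, quals`:
#' `pos_start` is the 1-based reference position of the first base,
#' `bases` are the aligned base calls (A/C/G/T/N, no gaps — arms trimmed
#' and indel-free by construction upstream) and `quals` the parallel
#' Phred+33 string. Upstream demultiplexers differ in where they put the
#' molecular tag, so a SAM/BAM reader is also available
#' ([read_tagged_reads_sam()]).
#'
#' @param path TSV path.
#' @return data.frame of tagged reads.
#' @export
read_tagged_reads <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("read_id", "mip_id", "tag",
                                                          "strand", "chrom", "bases",
                                                          "quals")))
  reads <- as.data.frame(dt)
  validate_tagged_reads(reads)
  reads
}

#' @rdname read_tagged_reads
#' @param reads tagged reads data.frame.
#' @export
write_tagged_reads <- function(reads, path) {
  cols <- c("read_id", "mip_id", "tag", "strand", "chrom", "pos_start", "bases", "quals")
  data.table::fwrite(as.data.frame(reads)[, cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read tagged reads from SAM/BAM
#'
#' Extracts the molecular tag and probe identity from SAM auxiliary fields
#' (defaults: `RX` for the raw UMI, `XP` for the probe id, the common
#' conventions). When an aux field is absent the read name is parsed as
#' `name#mip#tag`. Only match-only CIGAR alignments (`<n>M`) are accepted:
#' arm-trimmed smMIP consensus input is expected to be indel-free at the
#' read representation level; other reads are dropped with a warning count.
#' Requires the Rsamtools package.
#'
#' @param path SAM or BAM path (SAM is converted on the fly).
#' @param tag_field,mip_field SAM aux tags for UMI and probe id.
#' @return tagged reads data.frame (TSV dialect columns).
#' @export
read_tagged_reads_sam <- function(path, tag_field = "RX", mip_field = "XP") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_pm("Rsamtools is required for SAM/BAM input", "panelmips_dependency")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c(tag_field, mip_field))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (!n) {
    return(validate_tagged_reads(data.frame(
      read_id = character(), mip_id = character(), tag = character(),
      strand = character(), chrom = character(), pos_start = integer(),
      bases = character(), quals = character(), stringsAsFactors = FALSE)))
  }
  simple <- grepl("^[0-9]+M$", b$cigar)
  if (any(!simple)) {
    warning(sprintf("dropped %d reads with non match-only CIGARs", sum(!simple)),
            call. = FALSE)
  }
  name_bits <- strsplit(b$qname, "#", fixed = TRUE)
  tag <- b$tag[[tag_field]] %||% rep(NA_character_, n)
  mip <- b$tag[[mip_field]] %||% rep(NA_character_, n)
  tag <- ifelse(is.na(tag), vapply(name_bits, function(x) x[3] %||% NA_character_,
                                   character(1)), tag)
  mip <- ifelse(is.na(mip), vapply(name_bits, function(x) x[2] %||% NA_character_,
                                   character(1)), mip)
  out <- data.frame(
    read_id = b$qname,
    mip_id = mip,
    tag = tag,
    strand = ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    chrom = as.character(b$rname),
    pos_start = b$pos,
    bases = as.character(b$seq),
    quals = as.character(b$qual),
    stringsAsFactors = FALSE
  )[simple, , drop = FALSE]
  out$mip_id[is.na(out$mip_id)] <- ""
  out$tag[is.na(out$tag)] <- ""
  rownames(out) <- NULL
  validate_tagged_reads(out)
  out
}
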