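#' Consensus and sequencing-QC configuration
#'
#' @param min_unique_tags minimum library tag complexity: a sample with
#'   fewer distinct captured molecules (probe+tag families) fails QC
#'   (default 600000, strict `<` fails).
#' @param read_count_sd_multiplier a sample fails the read-count test when
#'   its total reads fall below the batch mean minus this many batch
#'   standard deviations (default 1).
#' @param min_reads_per_family families with fewer raw reads are dropped
#'   before consensus (default 1, i.e. keep singletons).
#' @param family_agreement_min fraction of a family's covering reads that
#'   the winning base must strictly exceed to be called as consensus;
#'   default 0.5 is a strict majority, ties yield `N`.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_unique_tags = 600000L,
                      read_count_sd_multiplier = 1,
                      min_reads_per_family = 1L,
                      family_agreement_min = 0.5) {
  stopifnot(min_unique_tags > 0, read_count_sd_multiplier > 0,
            min_reads_per_family >= 1,
            family_agreement_min > 0, family_agreement_min <= 1)
  structure(list(min_unique_tags = as.integer(min_unique_tags),
                 read_count_sd_multiplier = read_count_sd_multiplier,
                 min_reads_per_family = as.integer(min_reads_per_family),
                 family_agreement_min = family_agreement_min),
            class = "qc_config")
}

validate_tagged_reads <- function(reads) {
  need <- c("read_id", "mip_id", "tag", "strand", "chrom", "pos_start", "bases", "quals")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    stop_pm(paste0("tagged reads missing columns: ", paste(miss, collapse = ", ")),
            "panelmips_reads")
  }
  bad <- !reads$strand %in% c("+", "-")
  if (any(bad)) stop_pm("strand must be '+' or '-'", "panelmips_reads")
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    stop_pm("bases and quals must have equal length per read", "panelmips_reads")
  }
  invisible(reads)
}

#' Group tagged reads into single-molecule families
#'
#' Reads sharing a (probe, molecular tag, strand) key derive from the same
#' captured DNA molecule: each strand of a double-tiled probe is a separate
#' family. Reads with a missing or empty tag cannot be assigned and are
#' routed to a reject bucket that the QC report counts.
#'
#' @param reads data.frame of tagged reads (see [read_tagged_reads()] for
#'   the column dialect).
#' @return list with `reads` (accepted reads plus a `family` key column),
#'   `rejected` (tagless reads), `n_families`, and `family_sizes` (named
#'   integer vector of reads per family).
#' @export
group_families <- function(reads) {
  validate_tagged_reads(reads)
  tagless <- is.na(reads$tag) | !nzchar(reads$tag)
  rejected <- reads[tagless, , drop = FALSE]
  acc <- reads[!tagless, , drop = FALSE]
  acc$family <- paste(acc$mip_id, acc$tag, acc$strand, sep = "|")
  sizes <- if (nrow(acc)) table(acc$family) else table(character())
  list(reads = acc, rejected = rejected,
       n_families = length(sizes),
       family_sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

# long per-base representation of reads: family, chrom, pos, base
explode_reads <- function(reads) {
  if (!nrow(reads)) {
    return(data.table::data.table(family = character(), chrom = character(),
                                  pos = integer(), base = character()))
  }
  lens <- nchar(reads$bases)
  dt <- data.table::data.table(
    family = rep(reads$family, lens),
    chrom = rep(reads$chrom, lens),
    pos = unlist(lapply(seq_len(nrow(reads)),
                        function(i) reads$pos_start[i] + seq_len(lens[i]) - 1L)),
    base = unlist(strsplit(reads$bases, "", fixed = TRUE), use.names = FALSE)
  )
  dt
}

# consensus over a long per-base table -> one row per (family, chrom, pos)
consensus_long <- function(long, agreement_min) {
  if (!nrow(long)) {
    return(data.table::data.table(family = character(), chrom = character(),
                                  pos = integer(), consensus = character()))
  }
  counts <- long[base != "N", .(n_base = .N), by = .(family, chrom, pos, base)]
  cover <- long[, .(n_cover = .N), by = .(family, chrom, pos)]
  best <- counts[order(-n_base), .SD[1:min(2, .N)], by = .(family, chrom, pos)]
  top <- best[, .(top = base[1], top_n = n_base[1],
                  tie = .N > 1 && n_base[2] == n_base[1]),
              by = .(family, chrom, pos)]
  res <- merge(cover, top, by = c("family", "chrom", "pos"), all.x = TRUE)
  res[, consensus := data.table::fifelse(
    !is.na(top) & !tie & top_n > agreement_min * n_cover, top, "N")]
  res[is.na(consensus), consensus := "N"]
  res[, .(family, chrom, pos, consensus)]
}

#' Consensus base calls for a single family
#'
#' At every reference position covered by the family, the consensus is the
#' base whose read support strictly exceeds `family_agreement_min` of the
#' reads covering that position; otherwise (ties, split support) the
#' position is called `N`. `N` base calls in the raw reads never vote.
#'
#' @param family data.frame of the family's reads (same dialect as
#'   [read_tagged_reads()]; the `family` column is optional).
#' @param qc a [qc_config()].
#' @return data.frame `chrom`, `pos`, `consensus`, sorted by position;
#'   zero rows if the family is smaller than `min_reads_per_family`.
#' @export
family_consensus <- function(family, qc = qc_config()) {
  if (!nrow(family)) stop_pm("family must be nonempty", "panelmips_input")
  if (is.null(family$family)) family$family <- "f"
  if (nrow(family) < qc$min_reads_per_family) {
    return(data.frame(chrom = character(), pos = integer(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  long <- explode_reads(family)
  res <- consensus_long(long, qc$family_agreement_min)
  out <- as.data.frame(res[order(chrom, pos), .(chrom, pos, consensus)])
  out
}

#' Build consensus pileups from tagged reads
#'
#' Groups reads into (probe, tag, strand) families, calls a per-position
#' strict-majority consensus within each family, and counts each family at
#' most once per position: the result is a unique-molecule pileup. `N`
#' consensus calls are tallied in the `N` column but excluded from `depth`,
#' so `depth = A + C + G + T` never exceeds the number of families covering
#' the position.
#'
#' @param reads tagged reads data.frame, or the list returned by
#'   [group_families()].
#' @param qc a [qc_config()].
#' @param regions optional `target_regions`; positions outside them are
#'   dropped.
#' @return a `consensus_pileup` data.frame: `chrom`, `pos`, `A`, `C`, `G`,
#'   `T`, `N`, `depth`, ordered by chromosome and position. The number of
#'   contributing families is attached as attribute `"n_families"` and the
#'   rejected (tagless) read count as `"n_rejected_reads"`.
#' @export
build_pileup <- function(reads, qc = qc_config(), regions = NULL) {
  fams <- if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads
  } else {
    group_families(reads)
  }
  acc <- fams$reads
  if (nrow(acc) && qc$min_reads_per_family > 1L) {
    keep_fams <- names(fams$family_sizes)[fams$family_sizes >= qc$min_reads_per_family]
    acc <- acc[acc$family %in% keep_fams, , drop = FALSE]
  }
  long <- explode_reads(acc)
  if (!is.null(regions) && nrow(long)) {
    # consensus is per-position, so restricting to the panel footprint first
    # changes nothing but the work done
    gr <- GenomicRanges::GRanges(long$chrom, IRanges::IRanges(long$pos, long$pos))
    long <- long[IRanges::overlapsAny(gr, regions_to_granges(regions))]
  }
  cons <- consensus_long(long, qc$family_agreement_min)
  if (!nrow(cons)) {
    out <- data.frame(chrom = character(), pos = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(), N = integer(),
                      depth = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- data.table::dcast(
      cons[, .(n = .N), by = .(chrom, pos, consensus)],
      chrom + pos ~ factor(consensus, levels = c("A", "C", "G", "T", "N")),
      value.var = "n", fill = 0L, drop = c(TRUE, FALSE))
    out <- as.data.frame(tab)
    for (b in c("A", "C", "G", "T", "N")) {
      if (is.null(out[[b]])) out[[b]] <- 0L
      out[[b]] <- as.integer(out[[b]])
    }
    out$depth <- out$A + out$C + out$G + out$T
    out <- out[order(match(out$chrom, unique(out$chrom[chrom_order(out$chrom)])), out$pos), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_families") <- fams$n_families
  attr(out, "n_rejected_reads") <- nrow(fams$rejected)
  class(out) <- c("consensus_pileup", "data.frame")
  out
}

#' Batch-level sample sequencing QC
#'
#' A sample fails when its tag complexity (distinct captured molecules)
#' falls below `min_unique_tags`, or when its total read count lies more
#' than `read_count_sd_multiplier` standard deviations below the batch
#' mean. The read-count test needs at least two samples; with fewer it is
#' skipped with a warning. The batch is all samples passed in one call.
#'
#' @param samples data.frame with columns `sample_id`, `read_total`,
#'   `unique_tags`.
#' @param qc a [qc_config()].
#' @return data.frame `sample_id`, `pass`, `reasons` (semicolon-joined,
#'   empty when passing).
#' @export
sample_qc <- function(samples, qc = qc_config()) {
  stopifnot(all(c("sample_id", "read_total", "unique_tags") %in% names(samples)))
  reasons <- vector("list", nrow(samples))
  low_tags <- samples$unique_tags < qc$min_unique_tags
  for (i in which(low_tags)) reasons[[i]] <- c(reasons[[i]], "tag complexity")
  if (nrow(samples) >= 2) {
    mu <- mean(samples$read_total)
    s <- stats::sd(samples$read_total)
    low_reads <- samples$read_total < mu - qc$read_count_sd_multiplier * s
    for (i in which(low_reads)) reasons[[i]] <- c(reasons[[i]], "read count")
  } else {
    warning("fewer than 2 samples in batch; read-count SD test skipped",
            call. = FALSE)
  }
  data.frame(sample_id = samples$sample_id,
             pass = lengths(reasons) == 0,
             reasons = vapply(reasons, paste, character(1), collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Write / read a consensus pileup TSV
#'
#' Plain TSV with columns `chrom, pos, A, C, G, T, N, depth`.
#'
#' @param pileup a `consensus_pileup`.
#' @param path file path.
#' @return `path` (writer) or a `consensus_pileup` (reader).
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  class(out) <- c("consensus_pileup", "data.frame")
  out
}
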