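#' Panel design configuration
#'
#' @param min_evidence_score strict lower bound on the variant evidence
#'   score: a variant needs `score > min_evidence_score` (default 20).
#' @param hotspot_max_len variants shorter than this (bp, strict `<`) are
#'   hotspot-targeted; at or above it they are exon-tiled (default 250).
#' @param hotspot_flank padding added to each side of a hotspot target
#'   interval, in bp (default 0).
#' @param exclude_germline_only drop variants whose counted evidence is
#'   exclusively of germline origin (default `TRUE`).
#' @param germline_exempt_predisposing when excluding germline-only
#'   variants, treat Predisposing evidence as clinically retainable so a
#'   variant with only germline Predisposing evidence is kept (default
#'   `FALSE`).
#' @param exclude_conflicting drop variants with directly conflicting
#'   evidence (default `TRUE`); see Details.
#' @param redundancy_majority_fraction a container variant (e.g. a
#'   gene-level "MUTATION" record) is redundant when the fraction of its
#'   counted evidence items citing a hotspot already inside selected
#'   regions strictly exceeds this value (default 0.5, i.e. a majority).
#' @param tiling_rule `"by_name_container"` (default) sends gene-level
#'   container names in `containers_full` to full exon tiling and all other
#'   long variants to sparse tiling; `"config_table"` looks strategies up in
#'   `config_table`.
#' @param containers_full container names assigned full tiling under the
#'   name rule.
#' @param config_table optional data.frame (`id`, `strategy`) consulted when
#'   `tiling_rule = "config_table"`.
#' @param opposition data.frame of opposing clinical-significance label
#'   pairs used by the conflict test; defaults to
#'   [default_opposition_table()].
#'
#' @details "Directly conflicting" is operationalized as two counted,
#' `Supports`-direction evidence items of the same evidence type and same
#' disease (and, for Predictive items, the same drug set) whose
#' clinical-significance labels form an opposing pair.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(min_evidence_score = 20,
                         hotspot_max_len = 250,
                         hotspot_flank = 0,
                         exclude_germline_only = TRUE,
                         germline_exempt_predisposing = FALSE,
                         exclude_conflicting = TRUE,
                         redundancy_majority_fraction = 0.5,
                         tiling_rule = c("by_name_container", "config_table"),
                         containers_full = c("MUTATION", "LOSS", "FRAMESHIFT", "DELETION"),
                         config_table = NULL,
                         opposition = default_opposition_table()) {
  stopifnot(min_evidence_score >= 0, hotspot_max_len > 0, hotspot_flank >= 0,
            redundancy_majority_fraction > 0, redundancy_majority_fraction <= 1)
  structure(list(
    min_evidence_score = min_evidence_score,
    hotspot_max_len = as.integer(hotspot_max_len),
    hotspot_flank = as.integer(hotspot_flank),
    exclude_germline_only = isTRUE(exclude_germline_only),
    germline_exempt_predisposing = isTRUE(germline_exempt_predisposing),
    exclude_conflicting = isTRUE(exclude_conflicting),
    redundancy_majority_fraction = redundancy_majority_fraction,
    tiling_rule = match.arg(tiling_rule),
    containers_full = containers_full,
    config_table = config_table,
    opposition = opposition
  ), class = "panel_config")
}

#' Opposing clinical-significance labels
#'
#' Label pairs considered directly contradictory when asserted by two
#' supporting evidence items about the same clinical context.
#'
#' @return data.frame with columns `a`, `b`.
#' @export
default_opposition_table <- function() {
  data.frame(
    a = c("Sensitivity/Response", "Better Outcome", "Positive",
          "Pathogenic", "Likely Pathogenic"),
    b = c("Resistance", "Poor Outcome", "Negative",
          "Benign", "Likely Benign"),
    stringsAsFactors = FALSE
  )
}

counted_evidence <- function(ev, score_cfg) {
  if (score_cfg$count_only_accepted) ev[ev$status == "accepted", , drop = FALSE] else ev
}

#' @noRd
is_container_variant <- function(name, ref, alt, containers) {
  toupper(name) %in% toupper(containers) | (!nzchar(ref) & !nzchar(alt))
}

# conflict test on one variant's counted evidence
has_conflicting_evidence <- function(ev, opposition) {
  ev <- ev[ev$direction == "Supports", , drop = FALSE]
  if (nrow(ev) < 2) return(FALSE)
  drug_key <- vapply(ev$drugs, function(d) paste(sort(d), collapse = "+"), character(1))
  ctx <- paste(ev$evidence_type, ev$disease,
               ifelse(ev$evidence_type == "Predictive", drug_key, ""), sep = "\r")
  for (g in split(seq_len(nrow(ev)), ctx)) {
    if (length(g) < 2) next
    sig <- ev$clinical_significance[g]
    if (any(opposition$a %in% sig & opposition$b %in% sig)) return(TRUE)
  }
  FALSE
}

#' Filter snapshot variants for panel eligibility
#'
#' Applies the eligibility cascade: a variant is eligible iff it has
#' coordinates, its evidence score strictly exceeds the threshold, it is
#' DNA-based, it is not germline-only, its evidence is not directly
#' conflicting, and (for container variants) it is not redundant with
#' already-selected regions. Every excluded variant carries exactly one
#' primary reason: the first failing test in that order.
#'
#' The redundancy pass visits variants in descending evidence score (ties
#' broken by lexicographic id), accumulating the intervals of variants
#' selected so far; a container is redundant when more than
#' `redundancy_majority_fraction` of its counted evidence items cite a
#' hotspot coordinate already inside the accumulated regions.
#'
#' @param snapshot a `civic_snapshot` from [load_snapshot()].
#' @param cfg a [panel_config()].
#' @param score_cfg a [score_config()]; scores are recomputed if absent.
#' @param so_whitelist DNA-based SO accessions.
#' @return data.frame with columns `id`, `gene`, `name`, `evidence_score`,
#'   `eligible` and `reason` (`NA` for eligible variants), in snapshot
#'   order; the eligible subset of the snapshot is attached as attribute
#'   `"eligible_snapshot"` and also returned by [eligible_variants()].
#' @export
filter_eligible <- function(snapshot, cfg = panel_config(),
                            score_cfg = score_config(),
                            so_whitelist = default_so_whitelist()) {
  n <- nrow(snapshot)
  score <- snapshot$evidence_score %||%
    vapply(snapshot$evidence, evidence_score_items, numeric(1), cfg = score_cfg)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ev <- counted_evidence(snapshot$evidence[[i]], score_cfg)
    if (snapshot$coordinate_free[i]) {
      reason[i] <- "no coordinates"
    } else if (score[i] <= cfg$min_evidence_score) {
      reason[i] <- "evidence score"
    } else if (!suppressWarnings(is_dna_based(snapshot$so_ids[[i]], so_whitelist))) {
      reason[i] <- "not DNA-based"
    } else if (cfg$exclude_germline_only && nrow(ev) > 0) {
      germ <- ev$variant_origin == "Germline"
      if (cfg$germline_exempt_predisposing) {
        germ <- germ & ev$evidence_type != "Predisposing"
        all_germ <- all(ev$variant_origin == "Germline") &&
          !any(ev$evidence_type == "Predisposing")
      } else {
        all_germ <- all(germ)
      }
      if (all_germ) reason[i] <- "germline-only"
    }
    if (is.na(reason[i]) && cfg$exclude_conflicting &&
        has_conflicting_evidence(counted_evidence(snapshot$evidence[[i]], score_cfg),
                                 cfg$opposition)) {
      reason[i] <- "conflicting evidence"
    }
  }
  # redundancy pass over survivors, in selection order
  surv <- which(is.na(reason))
  ord <- surv[order(-score[surv], snapshot$id[surv])]
  sel <- GenomicRanges::GRanges()
  for (i in ord) {
    container <- is_container_variant(snapshot$name[i], snapshot$ref[i],
                                      snapshot$alt[i], cfg$containers_full)
    if (container) {
      ev <- counted_evidence(snapshot$evidence[[i]], score_cfg)
      if (nrow(ev)) {
        cited <- !is.na(ev$hotspot_chrom)
        covered <- logical(nrow(ev))
        if (any(cited) && length(sel)) {
          gr <- GenomicRanges::GRanges(
            ev$hotspot_chrom[cited],
            IRanges::IRanges(ev$hotspot_start[cited], ev$hotspot_stop[cited]))
          covered[cited] <- IRanges::overlapsAny(gr, sel, type = "within")
        }
        if (mean(covered) > cfg$redundancy_majority_fraction) {
          reason[i] <- "redundant container"
          next
        }
      }
    }
    sel <- c(sel, GenomicRanges::GRanges(
      snapshot$chrom[i], IRanges::IRanges(snapshot$start[i], snapshot$stop[i])))
    sel <- GenomicRanges::reduce(sel)
  }
  out <- data.frame(id = snapshot$id, gene = snapshot$gene, name = snapshot$name,
                    evidence_score = score, eligible = is.na(reason),
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "eligible_snapshot") <- snapshot[out$eligible, , drop = FALSE]
  out
}

#' Eligible subset of a snapshot from a [filter_eligible()] result
#' @param filtered return value of [filter_eligible()].
#' @return a `civic_snapshot` restricted to eligible variants.
#' @export
eligible_variants <- function(filtered) attr(filtered, "eligible_snapshot")

#' Assign a capture strategy to each variant
#'
#' Variant length is `stop - start + 1` (closed coordinates). Lengths
#' strictly below `hotspot_max_len` are hotspot-targeted; at or above the
#' bound the variant is exon-tiled, either fully (gene-level container
#' names) or sparsely, per the configured tiling rule.
#'
#' @param v a `civic_snapshot` (or subset); all rows must have coordinates.
#' @param cfg a [panel_config()].
#' @return character vector: `"hotspot"`, `"sparse_tiling"` or
#'   `"full_tiling"`, one per row.
#' @export
assign_strategy <- function(v, cfg = panel_config()) {
  if (any(v$coordinate_free)) {
    stop_pm("assign_strategy requires variants with coordinates", "panelmips_input")
  }
  len <- v$stop - v$start + 1L
  strategy <- ifelse(len < cfg$hotspot_max_len, "hotspot", NA_character_)
  tiled <- which(is.na(strategy))
  if (length(tiled)) {
    if (cfg$tiling_rule == "config_table") {
      if (is.null(cfg$config_table)) {
        stop_pm("tiling_rule 'config_table' needs cfg$config_table", "panelmips_config")
      }
      m <- match(v$id[tiled], cfg$config_table$id)
      strategy[tiled] <- ifelse(is.na(m), "sparse_tiling", cfg$config_table$strategy[m])
    } else {
      full <- is_container_variant(v$name[tiled], v$ref[tiled], v$alt[tiled],
                                   cfg$containers_full) &
        toupper(v$name[tiled]) %in% toupper(cfg$containers_full)
      strategy[tiled] <- ifelse(full, "full_tiling", "sparse_tiling")
    }
  }
  strategy
}

# CDS exon GRanges of one gene from imported gene models
gene_cds <- function(gene_models, gene) {
  md <- S4Vectors::mcols(gene_models)
  nm <- if (!is.null(md$gene_name)) md$gene_name else md$gene_id
  hit <- gene_models[!is.na(md$type) & md$type == "CDS" & !is.na(nm) & nm == gene]
  if (!length(hit)) {
    stop_pm(sprintf("gene '%s' has no CDS features in the gene models", gene),
            "panelmips_gene_models")
  }
  GenomicRanges::reduce(hit)
}

#' Build merged capture target regions
#'
#' Hotspot variants contribute their own interval padded by
#' `hotspot_flank`; fully tiled variants contribute every protein-coding
#' (CDS) exon of their gene; sparsely tiled variants contribute only the
#' CDS exons intersecting at least one evidence-cited hotspot coordinate
#' (falling back to the variant's own interval when no evidence item cites
#' one). All intervals are then merged per chromosome: overlapping or
#' bookended intervals coalesce and their source variant ids are unioned.
#'
#' @param eligible a `civic_snapshot` of eligible variants (see
#'   [eligible_variants()]).
#' @param gene_models a `GRanges` of gene models (e.g.
#'   `rtracklayer::import("genes.gtf")`) or a GTF/GFF3 path; must contain
#'   CDS features for every tiled gene.
#' @param cfg a [panel_config()].
#' @param reference optional `DNAStringSet` (or FASTA path) used to clip
#'   regions to contig ends.
#' @return a `target_regions` data.frame: `chrom`, `start`, `stop`
#'   (1-based, closed), `strategy`, `variant_ids` (list-column), sorted and
#'   pairwise non-overlapping within each chromosome.
#' @export
build_regions <- function(eligible, gene_models, cfg = panel_config(),
                          reference = NULL) {
  if (is.character(gene_models)) gene_models <- rtracklayer::import(gene_models)
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  if (!is.null(reference)) names(reference) <- sub("\\s.*$", "", names(reference))
  strategy <- assign_strategy(eligible, cfg)
  pieces <- list()
  for (i in seq_len(nrow(eligible))) {
    v <- eligible[i, ]
    gr <- switch(strategy[i],
      hotspot = GenomicRanges::GRanges(
        v$chrom,
        IRanges::IRanges(max(1L, v$start - cfg$hotspot_flank),
                         v$stop + cfg$hotspot_flank)),
      full_tiling = gene_cds(gene_models, v$gene),
      sparse_tiling = {
        cds <- gene_cds(gene_models, v$gene)
        ev <- v$evidence[[1]]
        cited <- ev[!is.na(ev$hotspot_chrom), , drop = FALSE]
        anchors <- if (nrow(cited)) {
          GenomicRanges::GRanges(cited$hotspot_chrom,
                                 IRanges::IRanges(cited$hotspot_start, cited$hotspot_stop))
        } else {
          GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$start, v$stop))
        }
        cds[IRanges::overlapsAny(cds, anchors)]
      })
    if (!length(gr)) next
    S4Vectors::mcols(gr)$variant_id <- v$id
    S4Vectors::mcols(gr)$strategy <- strategy[i]
    pieces[[length(pieces) + 1L]] <- gr
  }
  if (!length(pieces)) {
    return(empty_target_regions())
  }
  all_gr <- suppressWarnings(do.call(c, pieces))
  merged <- GenomicRanges::reduce(all_gr, with.revmap = TRUE, min.gapwidth = 1L)
  revmap <- S4Vectors::mcols(merged)$revmap
  ids <- lapply(revmap, function(ix) sort(unique(S4Vectors::mcols(all_gr)$variant_id[ix])))
  strat <- vapply(revmap, function(ix)
    paste(sort(unique(S4Vectors::mcols(all_gr)$strategy[ix])), collapse = "+"),
    character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    stop = GenomicRanges::end(merged),
    strategy = strat, stringsAsFactors = FALSE)
  out$variant_ids <- ids
  if (!is.null(reference)) {
    lens <- Biostrings::width(reference)[match(out$chrom, names(reference))]
    bad <- !is.na(lens) & out$stop > lens
    out$stop[bad] <- lens[bad]
    out <- out[out$start <= out$stop, , drop = FALSE]
  }
  out <- out[chrom_order(out$chrom), , drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_regions", "data.frame")
  out
}

empty_target_regions <- function() {
  out <- data.frame(chrom = character(), start = integer(), stop = integer(),
                    strategy = character(), stringsAsFactors = FALSE)
  out$variant_ids <- list()
  class(out) <- c("target_regions", "data.frame")
  out
}

#' Merge target regions (idempotent)
#'
#' Coalesces overlapping or bookended intervals per chromosome, unioning
#' their variant ids. Already-merged input is returned unchanged.
#'
#' @param regions a `target_regions` data.frame.
#' @return merged `target_regions`.
#' @export
merge_regions <- function(regions) {
  if (!nrow(regions)) return(regions)
  gr <- regions_to_granges(regions)
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 1L)
  revmap <- S4Vectors::mcols(merged)$revmap
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    stop = GenomicRanges::end(merged),
    strategy = vapply(revmap, function(ix)
      paste(sort(unique(unlist(strsplit(regions$strategy[ix], "+", fixed = TRUE)))),
            collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  out$variant_ids <- lapply(revmap, function(ix) sort(unique(unlist(regions$variant_ids[ix]))))
  out <- out[chrom_order(out$chrom), , drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_regions", "data.frame")
  out
}

#' @noRd
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(regions$start, regions$stop))
}

#' Round a count vector to percentages
#'
#' `"largest_remainder"` (default) apportions integer percentages that sum
#' to exactly 100 (floor everything, then hand the leftover points to the
#' largest fractional remainders); `"nearest"` rounds each share
#' independently; `"none"` returns raw shares. `digits` applies to the
#' latter two modes.
#'
#' @param counts non-negative numeric vector (names preserved).
#' @param mode rounding mode.
#' @param digits decimal places for `"nearest"`/`"none"`.
#' @return numeric vector of percentages.
#' @examples
#' percent_shares(c(Predictive = 820, Prognostic = 232,
#'                  Diagnostic = 52, Predisposing = 64))
#' @export
percent_shares <- function(counts, mode = c("largest_remainder", "nearest", "none"),
                           digits = 0) {
  mode <- match.arg(mode)
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  raw <- 100 * counts / tot
  switch(mode,
    none = round(raw, digits = if (digits > 0) digits else 10),
    nearest = round(raw, digits),
    largest_remainder = {
      fl <- floor(raw)
      rem <- raw - fl
      short <- round(100 - sum(fl))
      if (short > 0) {
        give <- order(-rem, -counts)[seq_len(short)]
        fl[give] <- fl[give] + 1
      }
      stats::setNames(fl, names(counts))
    })
}

#' Summarize a designed panel
#'
#' @param regions merged `target_regions`.
#' @param eligible the eligible `civic_snapshot` the panel was built from.
#' @param cfg a [panel_config()] (for strategy assignment).
#' @param score_cfg a [score_config()] (decides which evidence items count).
#' @param percent_mode rounding mode for evidence percentages; see
#'   [percent_shares()].
#' @return a `panel_summary` list: `n_variants`, `n_by_strategy`,
#'   `total_bp` (each base counted once), `evidence_counts` and
#'   `evidence_percent` by evidence type.
#' @export
panel_summary <- function(regions, eligible, cfg = panel_config(),
                          score_cfg = score_config(),
                          percent_mode = "largest_remainder") {
  strategy <- assign_strategy(eligible, cfg)
  n_by <- table(factor(strategy, levels = c("hotspot", "sparse_tiling", "full_tiling")))
  ev_all <- do.call(rbind, lapply(eligible$evidence, counted_evidence, score_cfg = score_cfg))
  counts <- table(factor(ev_all$evidence_type, levels = .EVIDENCE_TYPES))
  structure(list(
    n_variants = nrow(eligible),
    n_by_strategy = stats::setNames(as.integer(n_by), names(n_by)),
    total_bp = if (nrow(regions)) sum(regions$stop - regions$start + 1L) else 0L,
    evidence_counts = stats::setNames(as.integer(counts), names(counts)),
    evidence_percent = percent_shares(
      stats::setNames(as.numeric(counts), names(counts)), mode = percent_mode)
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel: %d variants (%s), %d bp\n", x$n_variants,
              paste(sprintf("%s %d", names(x$n_by_strategy), x$n_by_strategy),
                    collapse = ", "), x$total_bp))
  cat("evidence items:",
      paste(sprintf("%s %d (%s%%)", names(x$evidence_counts), x$evidence_counts,
                    x$evidence_percent), collapse = ", "), "\n")
  invisible(x)
}

#' Write target regions to BED
#'
#' BED is 0-based half-open, so a closed region `[start, stop]` becomes
#' `start-1, stop`. The name column is `strategy:variant_ids` (ids joined
#' with commas). Rows are ordered by natural chromosome order, then start.
#'
#' @param regions a `target_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  lines <- "# panelmips targets (BED: 0-based half-open); name = strategy:variant_ids"
  if (nrow(regions)) {
    regions <- regions[chrom_order(regions$chrom), , drop = FALSE]
    regions <- regions[order(match(regions$chrom, unique(regions$chrom)), regions$start), ,
                       drop = FALSE]
    nm <- paste0(regions$strategy, ":",
                 vapply(regions$variant_ids, paste, character(1), collapse = ","))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", regions$chrom,
                              regions$start - 1L, regions$stop, nm))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a panel BED back into target regions
#'
#' @param path BED path as written by [write_bed()] (plain 3+ column BED is
#'   also accepted; missing names yield empty strategies/ids).
#' @return a `target_regions` data.frame (1-based closed coordinates).
#' @export
read_bed <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) return(empty_target_regions())
  nm <- if (ncol(tab) >= 4) as.character(tab[[4]]) else rep(":", nrow(tab))
  strat <- sub(":.*$", "", nm)
  ids <- strsplit(sub("^[^:]*:", "", nm), ",", fixed = TRUE)
  out <- data.frame(chrom = as.character(tab[[1]]), start = tab[[2]] + 1L,
                    stop = tab[[3]], strategy = strat, stringsAsFactors = FALSE)
  out$variant_ids <- ids
  class(out) <- c("target_regions", "data.frame")
  out
}
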