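#' Match calls to knowledgebase variants by exact coordinates
#'
#' A call annotates a knowledgebase variant only on exact five-key
#' equality: chromosome, start, stop, reference allele, alternate allele
#' (both sides 1-based closed; alleles normalized the same way as in
#' [compare_to_truth()]). No transcript- or protein-level fuzzy matching
#' and no container roll-up is attempted, keeping false annotation risk
#' low. Coordinate-free snapshot records can never match. Duplicate
#' snapshot keys are rejected at [load_snapshot()] time, so a call matches
#' at most one variant.
#'
#' @param calls a `variant_calls` data.frame.
#' @param snapshot a `civic_snapshot`.
#' @param reference optional `DNAStringSet` for indel normalization.
#' @return an `annotation_matches` data.frame: the matching calls with
#'   `civic_variant_id`, `start`, `stop` key columns; zero rows when
#'   nothing matches.
#' @export
match_calls <- function(calls, snapshot, reference = NULL) {
  calls <- normalize_variants_df(as.data.frame(calls), reference)
  snap <- snapshot[!snapshot$coordinate_free, , drop = FALSE]
  call_start <- calls$pos
  call_stop <- calls$pos + nchar(calls$ref) - 1L
  ckey <- paste(calls$chrom, call_start, call_stop,
                toupper(calls$ref), toupper(calls$alt), sep = ":")
  skey <- paste(snap$chrom, snap$start, snap$stop,
                toupper(snap$ref), toupper(snap$alt), sep = ":")
  if (anyDuplicated(skey)) {
    stop_pm("snapshot contains duplicate coordinate keys", "panelmips_duplicate_keys")
  }
  m <- match(ckey, skey)
  hit <- !is.na(m)
  out <- calls[hit, , drop = FALSE]
  out$start <- call_start[hit]
  out$stop <- call_stop[hit]
  out$civic_variant_id <- snap$id[m[hit]]
  rownames(out) <- NULL
  class(out) <- c("annotation_matches", "data.frame")
  out
}

#' Totals and mean matches per sample
#'
#' @param matches an `annotation_matches` data.frame (possibly pooled over
#'   samples).
#' @param n_samples number of samples the matches came from (>= 1).
#' @return list `total_matches`, `mean_per_sample` (1-decimal rounding).
#' @examples
#' # 127 matches over 19 samples -> mean 6.7
#' @export
summarize_matches <- function(matches, n_samples) {
  stopifnot(n_samples >= 1)
  total <- nrow(matches)
  list(total_matches = total, mean_per_sample = round(total / n_samples, 1))
}

evidence_link <- function(id) sprintf("https://civicdb.org/evidence/%s", id)
variant_link <- function(id) sprintf("https://civicdb.org/variants/%s", id)

#' Render a per-sample clinical annotation report
#'
#' Builds the report structure (and its Markdown rendering) for one
#' sample: one block per matched variant, ordered by descending evidence
#' score then genomic position, with the knowledgebase description,
#' assertions, and evidence items grouped by type in the order Predictive,
#' Prognostic, Diagnostic, Predisposing. Hyperlinks are templated from
#' variant and evidence identifiers.
#'
#' @param matches an `annotation_matches` data.frame for the sample.
#' @param snapshot the `civic_snapshot` the matches refer to.
#' @param sample_id sample label.
#' @param out_prefix when non-`NULL`, writes `<out_prefix>.md` and
#'   `<out_prefix>.json`.
#' @return a `clinical_report` list with elements `json` (the report
#'   structure) and `markdown` (character vector of lines).
#' @export
render_report <- function(matches, snapshot, sample_id, out_prefix = NULL) {
  ord <- order(-snapshot$evidence_score[match(matches$civic_variant_id, snapshot$id)],
               match(matches$chrom, unique(matches$chrom[chrom_order(matches$chrom)])),
               matches$pos)
  matches <- matches[ord, , drop = FALSE]
  blocks <- lapply(seq_len(nrow(matches)), function(i) {
    mrow <- matches[i, ]
    v <- snapshot[snapshot$id == mrow$civic_variant_id, ]
    ev <- v$evidence[[1]]
    ev <- ev[order(match(ev$evidence_type, .EVIDENCE_TYPES)), , drop = FALSE]
    list(
      variant_id = v$id, gene = v$gene, name = v$name,
      coordinates = sprintf("%s:%d-%d %s>%s", mrow$chrom, mrow$start, mrow$stop,
                            mrow$ref, mrow$alt),
      vaf = mrow$vaf, depth = mrow$depth,
      evidence_score = v$evidence_score,
      description = v$description,
      assertions = as.list(v$assertions[[1]]),
      link = variant_link(v$id),
      evidence_items = lapply(seq_len(nrow(ev)), function(j) {
        e <- ev[j, ]
        list(id = e$id, evidence_type = e$evidence_type,
             evidence_level = e$evidence_level, trust_rating = e$trust_rating,
             clinical_significance = e$clinical_significance,
             disease = e$disease, drugs = as.list(e$drugs[[1]]),
             citation = e$citation, link = evidence_link(e$id))
      })
    )
  })
  report <- list(sample_id = sample_id, n_matches = nrow(matches),
                 variants = blocks)
  md <- c(sprintf("# Clinical variant report: %s", sample_id), "")
  if (!nrow(matches)) {
    md <- c(md, "No clinically relevant variants matched the knowledgebase.")
  } else {
    for (b in blocks) {
      md <- c(md,
        sprintf("## %s %s (%s)", b$gene, b$name, b$coordinates),
        "",
        sprintf("- VAF %.3f at consensus depth %d; evidence score %.2f ([knowledgebase](%s))",
                b$vaf, b$depth, b$evidence_score, b$link))
      if (nzchar(b$description)) md <- c(md, sprintf("- %s", b$description))
      if (length(b$assertions)) {
        md <- c(md, sprintf("- Assertions: %s", paste(unlist(b$assertions), collapse = "; ")))
      }
      md <- c(md, "", "| Type | Level | Stars | Significance | Disease | Drugs | Citation |",
              "|---|---|---|---|---|---|---|")
      for (e in b$evidence_items) {
        md <- c(md, sprintf("| %s | %s | %d | %s | %s | %s | [%s](%s) |",
                            e$evidence_type, e$evidence_level, e$trust_rating,
                            e$clinical_significance, e$disease,
                            paste(unlist(e$drugs), collapse = ", "),
                            e$citation, e$link))
      }
      md <- c(md, "")
    }
  }
  if (!is.null(out_prefix)) {
    writeLines(md, paste0(out_prefix, ".md"))
    jsonlite::write_json(report, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(json = report, markdown = md), class = "clinical_report")
}

#' Validate a report structure against the shipped schema
#'
#' Structural validation of a report (as produced by [render_report()] or
#' re-read from its JSON file) against the field list shipped in
#' `extdata/report_schema.json`.
#'
#' @param report the report list (`$json` element of a `clinical_report`,
#'   or `jsonlite::read_json()` of a written report).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  need <- c("sample_id", "n_matches", "variants")
  miss <- setdiff(need, names(report))
  if (length(miss)) {
    stop_pm(paste0("report missing fields: ", paste(miss, collapse = ", ")),
            "panelmips_schema")
  }
  if (length(report$variants) != report$n_matches) {
    stop_pm("n_matches does not equal the number of variant blocks", "panelmips_schema")
  }
  vneed <- c("variant_id", "gene", "name", "coordinates", "vaf",
             "evidence_score", "link", "evidence_items")
  for (b in report$variants) {
    miss <- setdiff(vneed, names(b))
    if (length(miss)) {
      stop_pm(paste0("variant block missing fields: ", paste(miss, collapse = ", ")),
              "panelmips_schema")
    }
    eneed <- c("id", "evidence_type", "evidence_level", "trust_rating",
               "clinical_significance", "disease", "citation", "link")
    for (e in b$evidence_items) {
      miss <- setdiff(eneed, names(e))
      if (length(miss)) {
        stop_pm(paste0("evidence item missing fields: ", paste(miss, collapse = ", ")),
                "panelmips_schema")
      }
    }
  }
  invisible(TRUE)
}
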