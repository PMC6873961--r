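#' Evidence-level weighting for the variant evidence score
#'
#' The knowledgebase gates panel inclusion on an aggregate *variant evidence
#' score*: the sum over counted evidence items of an evidence-level weight
#' multiplied by the item's trust rating (0--5 stars). The level weights are
#' configuration, not ground truth; the defaults follow the public
#' knowledgebase convention (validated A = 10 down to preclinical/inferential
#' E = 0.25).
#'
#' @param level_weights named non-negative numeric vector with names
#'   `A,B,C,D,E`.
#' @param count_only_accepted if `TRUE` (default) only evidence items with
#'   `status == "accepted"` contribute to the score; submitted and rejected
#'   items are ignored.
#' @return an object of class `score_config`.
#' @examples
#' score_config()
#' score_config(level_weights = c(A = 8, B = 4, C = 2, D = 1, E = 0.5))
#' @export
score_config <- function(level_weights = c(A = 10, B = 5, C = 1, D = 0.5, E = 0.25),
                         count_only_accepted = TRUE) {
  stopifnot(is.numeric(level_weights), !is.null(names(level_weights)))
  if (!setequal(names(level_weights), c("A", "B", "C", "D", "E"))) {
    stop_pm("level_weights must be named A,B,C,D,E", "panelmips_config")
  }
  if (any(level_weights < 0)) {
    stop_pm("level weights must be non-negative", "panelmips_config")
  }
  structure(
    list(level_weights = level_weights[c("A", "B", "C", "D", "E")],
         count_only_accepted = isTRUE(count_only_accepted)),
    class = "score_config"
  )
}

.EVIDENCE_TYPES  <- c("Predictive", "Prognostic", "Diagnostic", "Predisposing")
.EVIDENCE_LEVELS <- c("A", "B", "C", "D", "E")
.DIRECTIONS      <- c("Supports", "DoesNotSupport")
.ORIGINS         <- c("Somatic", "Germline", "Unknown")
.STATUSES        <- c("accepted", "submitted", "rejected")

# empty evidence table with the canonical columns
empty_evidence <- function() {
  data.frame(
    id = character(), evidence_type = character(), evidence_level = character(),
    trust_rating = integer(), direction = character(),
    clinical_significance = character(), variant_origin = character(),
    disease = character(), drugs = I(list()), status = character(),
    citation = character(), hotspot_chrom = character(),
    hotspot_start = integer(), hotspot_stop = integer(),
    stringsAsFactors = FALSE
  )
}

# validate one raw evidence record (a list from JSON); returns a list with
# either $row (one-row data.frame) or $problems (character vector)
parse_evidence_item <- function(e, variant_id) {
  problems <- character()
  lvl <- as.character(e$evidence_level %||% NA)
  if (is.na(lvl) || !lvl %in% .EVIDENCE_LEVELS) {
    problems <- c(problems, sprintf("unknown evidence_level '%s'", lvl))
  }
  typ <- as.character(e$evidence_type %||% NA)
  if (is.na(typ) || !typ %in% .EVIDENCE_TYPES) {
    problems <- c(problems, sprintf("unknown evidence_type '%s'", typ))
  }
  tr <- suppressWarnings(as.integer(e$trust_rating %||% NA))
  if (is.na(tr) || tr < 0 || tr > 5) {
    problems <- c(problems, sprintf("trust_rating '%s' outside 0..5", e$trust_rating %||% NA))
  }
  dir <- as.character(e$direction %||% "Supports")
  if (!dir %in% .DIRECTIONS) {
    problems <- c(problems, sprintf("unknown direction '%s'", dir))
  }
  org <- as.character(e$variant_origin %||% "Unknown")
  if (!org %in% .ORIGINS) {
    problems <- c(problems, sprintf("unknown variant_origin '%s'", org))
  }
  st <- as.character(e$status %||% "accepted")
  if (!st %in% .STATUSES) {
    problems <- c(problems, sprintf("unknown status '%s'", st))
  }
  if (length(problems)) return(list(problems = problems))
  hc <- e$variant_coordinates %||% list()
  row <- data.frame(
    id = as.character(e$id %||% NA),
    evidence_type = typ, evidence_level = lvl, trust_rating = tr,
    direction = dir,
    clinical_significance = as.character(e$clinical_significance %||% ""),
    variant_origin = org,
    disease = as.character(e$disease %||% ""),
    drugs = I(list(as.character(unlist(e$drugs %||% character())))),
    status = st,
    citation = as.character(e$citation %||% ""),
    hotspot_chrom = as.character(hc$chromosome %||% NA),
    hotspot_start = as.integer(hc$start %||% NA),
    hotspot_stop = as.integer(hc$stop %||% NA),
    stringsAsFactors = FALSE
  )
  list(row = row)
}

parse_variant_record <- function(v) {
  problems <- character()
  id <- as.character(v$id %||% NA)
  if (is.na(id)) problems <- c(problems, "missing variant id")
  co <- v$coordinates %||% list()
  chrom <- as.character(co$chromosome %||% NA)
  start <- suppressWarnings(as.integer(co$start %||% NA))
  stop_ <- suppressWarnings(as.integer(co$stop %||% NA))
  coordinate_free <- is.na(chrom) || is.na(start) || is.na(stop_)
  if (!coordinate_free && start > stop_) {
    problems <- c(problems, sprintf("start (%d) > stop (%d)", start, stop_))
  }
  ev_rows <- list()
  ev <- v$evidence_items %||% list()
  for (i in seq_along(ev)) {
    pe <- parse_evidence_item(ev[[i]], id)
    if (!is.null(pe$problems)) {
      problems <- c(problems, sprintf("evidence item %d: %s", i, pe$problems))
    } else {
      ev_rows[[length(ev_rows) + 1L]] <- pe$row
    }
  }
  if (length(problems)) return(list(problems = problems, id = id))
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_evidence()
  row <- data.frame(
    id = id,
    gene = as.character(v$gene %||% ""),
    name = as.character(v$name %||% ""),
    chrom = chrom, start = start, stop = stop_,
    ref = toupper(as.character(co$reference_bases %||% "")),
    alt = toupper(as.character(co$variant_bases %||% "")),
    build = as.character(co$reference_build %||% "GRCh37"),
    coordinate_free = coordinate_free,
    description = as.character(v$description %||% ""),
    stringsAsFactors = FALSE
  )
  row$so_ids <- I(list(as.character(unlist(v$variant_types %||% character()))))
  row$evidence <- I(list(evidence))
  row$assertions <- I(list(as.character(unlist(v$assertions %||% character()))))
  list(row = row, id = id)
}

#' Load a knowledgebase snapshot
#'
#' Reads a snapshot JSON (top-level `"variants"` array; each record carries
#' `coordinates` \{chromosome, start, stop, reference_bases, variant_bases,
#' reference_build\}, `variant_types` (sequence-ontology accessions) and an
#' `evidence_items` array). Coordinates follow the knowledgebase convention:
#' 1-based, fully closed. Users exporting from a live API should flatten
#' their export to this schema; see the package README.
#'
#' Variants without usable coordinates are loadable but flagged
#' `coordinate_free` (they can never be captured). Records violating the
#' schema (unknown evidence level/type, star rating outside 0--5,
#' start > stop) are rejected: with `strict = TRUE` (default) the load stops
#' with record-level diagnostics, otherwise offending records are dropped
#' with a warning naming each one.
#'
#' @param path path to the snapshot JSON file.
#' @param score_cfg [score_config()] used to compute and cache each
#'   variant's evidence score.
#' @param strict abort on malformed records (default) instead of dropping
#'   them.
#' @return a `civic_snapshot`: a data.frame with one row per variant and
#'   list-columns `so_ids` and `evidence`; column `evidence_score` caches
#'   the computed score.
#' @seealso [variant_evidence_score()], [write_snapshot()]
#' @export
load_snapshot <- function(path, score_cfg = score_config(), strict = TRUE) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$variants)) {
    stop_pm("snapshot JSON lacks a top-level 'variants' array", "panelmips_schema")
  }
  rows <- list(); diags <- character()
  for (v in raw$variants) {
    pv <- parse_variant_record(v)
    if (!is.null(pv$problems)) {
      diags <- c(diags, sprintf("variant '%s': %s", pv$id %||% "?", pv$problems))
    } else {
      rows[[length(rows) + 1L]] <- pv$row
    }
  }
  if (length(diags)) {
    msg <- paste(diags, collapse = "\n  ")
    if (strict) stop_pm(paste0("snapshot validation failed:\n  ", msg), "panelmips_validation")
    warning(paste0("dropped malformed snapshot records:\n  ", msg), call. = FALSE)
  }
  snap <- if (length(rows)) do.call(rbind, rows) else {
    parse_variant_record(list(id = "x"))$row[0, ]
  }
  # duplicate five-key records make exact annotation matching ambiguous
  with_co <- snap[!snap$coordinate_free, , drop = FALSE]
  if (nrow(with_co)) {
    key <- paste(with_co$chrom, with_co$start, with_co$stop, with_co$ref, with_co$alt)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop_pm(paste0("duplicate coordinate keys in snapshot: ",
                     paste(dup, collapse = "; ")), "panelmips_duplicate_keys")
    }
  }
  snap$evidence_score <- vapply(snap$evidence, evidence_score_items,
                                numeric(1), cfg = score_cfg)
  rownames(snap) <- NULL
  class(snap) <- c("civic_snapshot", "data.frame")
  snap
}

#' Serialize a snapshot back to JSON
#'
#' Inverse of [load_snapshot()]: `load_snapshot(write_snapshot(x, f))`
#' reproduces `x` (the cached score is recomputed, not stored).
#'
#' @param snapshot a `civic_snapshot`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  variants <- lapply(seq_len(nrow(snapshot)), function(i) {
    v <- snapshot[i, ]
    ev <- v$evidence[[1]]
    items <- lapply(seq_len(nrow(ev)), function(j) {
      e <- ev[j, ]
      item <- list(
        id = e$id, evidence_type = e$evidence_type,
        evidence_level = e$evidence_level, trust_rating = e$trust_rating,
        direction = e$direction,
        clinical_significance = e$clinical_significance,
        variant_origin = e$variant_origin, disease = e$disease,
        drugs = as.list(e$drugs[[1]]), status = e$status, citation = e$citation
      )
      if (!is.na(e$hotspot_chrom)) {
        item$variant_coordinates <- list(
          chromosome = e$hotspot_chrom, start = e$hotspot_start,
          stop = e$hotspot_stop)
      }
      item
    })
    rec <- list(id = v$id, gene = v$gene, name = v$name,
                variant_types = as.list(v$so_ids[[1]]),
                evidence_items = items)
    if (nzchar(v$description)) rec$description <- v$description
    if (length(v$assertions[[1]])) rec$assertions <- as.list(v$assertions[[1]])
    if (!v$coordinate_free) {
      rec$coordinates <- list(
        chromosome = v$chrom, start = v$start, stop = v$stop,
        reference_bases = v$ref, variant_bases = v$alt,
        reference_build = v$build)
    }
    rec
  })
  jsonlite::write_json(list(variants = variants), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# score an evidence table under a score_config
evidence_score_items <- function(evidence, cfg = score_config()) {
  if (!nrow(evidence)) return(0)
  counted <- if (cfg$count_only_accepted) evidence$status == "accepted" else rep(TRUE, nrow(evidence))
  ev <- evidence[counted, , drop = FALSE]
  if (!nrow(ev)) return(0)
  sum(cfg$level_weights[ev$evidence_level] * ev$trust_rating)
}

#' Variant evidence score
#'
#' Weighted sum, over counted evidence items, of the evidence-level weight
#' times the trust rating. Additive in evidence items and zero for a variant
#' with no counted evidence.
#'
#' @param v one snapshot row (a `civic_snapshot` subset of one variant), a
#'   list with an `evidence` element, or an evidence-item data.frame.
#' @param cfg a [score_config()].
#' @return a non-negative number.
#' @examples
#' ev <- data.frame(evidence_level = c("A", "B"), trust_rating = c(4L, 3L),
#'                  status = "accepted")
#' variant_evidence_score(ev)  # 10*4 + 5*3 = 55
#' @export
variant_evidence_score <- function(v, cfg = score_config()) {
  ev <- if (is.data.frame(v) && "evidence_level" %in% names(v)) {
    v
  } else if (!is.null(v$evidence)) {
    e <- v$evidence
    if (is.list(e) && !is.data.frame(e)) e[[1]] else e
  } else {
    stop_pm("cannot locate evidence items in 'v'", "panelmips_input")
  }
  if (!"status" %in% names(ev)) ev$status <- "accepted"
  evidence_score_items(ev, cfg)
}

#' Default DNA-based sequence-ontology whitelist
#'
#' Sequence-ontology accessions describing alterations detectable from DNA
#' capture sequencing (SNVs, indels, frameshifts, splice-site changes, ...).
#' Transcript-level events (fusions, expression changes) are deliberately
#' absent. Shipped as a plain TSV under `extdata/` and user-overridable in
#' every function that takes a whitelist.
#'
#' @return character vector of SO accessions, named by SO term.
#' @export
default_so_whitelist <- function() {
  path <- system.file("extdata", "so_dna_whitelist.tsv", package = "panelmips",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(tab$so_id, tab$term)
}

#' Is a variant DNA-based?
#'
#' A variant is capturable by DNA probes if any of its sequence-ontology
#' accessions is in the DNA-based whitelist. A variant with no SO accessions
#' is not DNA-based (with a warning), since its eligibility cannot be
#' established.
#'
#' @param v a snapshot row, a list with `so_ids`, or a character vector of
#'   SO accessions.
#' @param whitelist non-empty character vector of allowed SO accessions.
#' @return logical scalar.
#' @export
is_dna_based <- function(v, whitelist = default_so_whitelist()) {
  if (!length(whitelist)) stop_pm("whitelist must be non-empty", "panelmips_input")
  so <- if (is.character(v)) v else {
    s <- v$so_ids
    if (is.list(s) && !is.data.frame(s)) s[[1]] else s
  }
  so <- as.character(unlist(so))
  if (!length(so)) {
    warning("variant carries no sequence-ontology accessions; treating as not DNA-based",
            call. = FALSE)
    return(FALSE)
  }
  any(so %in% whitelist)
}

#' @export
print.civic_snapshot <- function(x, ...) {
  cat(sprintf("civic_snapshot: %d variants (%d coordinate-free), %d evidence items\n",
              nrow(x), sum(x$coordinate_free),
              sum(vapply(x$evidence, nrow, integer(1)))))
  invisible(x)
}
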