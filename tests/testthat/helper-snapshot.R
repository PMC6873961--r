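# builders for tiny in-code knowledgebase fixtures

ev_item <- function(id = "E1", type = "Predictive", level = "A", stars = 4L,
                    direction = "Supports",
                    significance = "Sensitivity/Response", origin = "Somatic",
                    disease = "Melanoma", drugs = list("DrugA"),
                    status = "accepted", coords = NULL) {
  e <- list(id = id, evidence_type = type, evidence_level = level,
            trust_rating = stars, direction = direction,
            clinical_significance = significance, variant_origin = origin,
            disease = disease, drugs = drugs, status = status,
            citation = "PMID:1")
  if (!is.null(coords)) {
    e$variant_coordinates <- list(chromosome = coords[[1]], start = coords[[2]],
                                  stop = coords[[3]])
  }
  e
}

variant_rec <- function(id, gene = "BRAF", name = "V600E", chrom = "7",
                        start = 140453136L, stop = 140453136L, ref = "A",
                        alt = "T", so = list("SO:0001583"),
                        evidence = list(ev_item()), with_coords = TRUE) {
  v <- list(id = id, gene = gene, name = name, variant_types = so,
            evidence_items = evidence)
  if (with_coords) {
    v$coordinates <- list(chromosome = chrom, start = start, stop = stop,
                          reference_bases = ref, variant_bases = alt,
                          reference_build = "GRCh37")
  }
  v
}

write_snapshot_json <- function(variants, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(variants = variants), path, auto_unbox = TRUE,
                       digits = NA)
  path
}

snapshot_from <- function(variants, ...) {
  load_snapshot(write_snapshot_json(variants), ...)
}

# one-probe tagged-read builder: each read one row, bases may span several
# positions starting at pos_start
tread <- function(read_id, bases, pos_start = 100L, mip = "mip1", tag = "AAAA",
                  strand = "+", chrom = "chr1") {
  data.frame(read_id = read_id, mip_id = mip, tag = tag, strand = strand,
             chrom = chrom, pos_start = pos_start, bases = bases,
             quals = strrep("I", nchar(bases)), stringsAsFactors = FALSE)
}
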