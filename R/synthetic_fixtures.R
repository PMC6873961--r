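#' Synthetic validation-cohort configuration
#'
#' Parameters of the seed-deterministic generator that emulates every input
#' of the pipeline: a knowledgebase snapshot spanning all eligibility
#' branches, a reference genome with gene models, molecular-tagged tumor
#' and matched-normal reads with planted variants, an orthogonal truth set,
#' and an "original sequencing" call set with engineered rescue scenarios.
#'
#' Somatic sites are split across original-sequencing regimes:
#' `validated` sites get deep original coverage (present in the original
#' call set), `insufficient` sites get shallow coverage with no supporting
#' reads (the binomial detectability test flags the coverage as
#' insufficient), `adequate` sites get very deep coverage with zero
#' supporting reads (a constructed scenario: statistically the variant
#' should have been seen), and `supported` sites carry 1-3 supporting
#' reads, too few for the original caller. Germline plants appear in tumor
#' and normal at heterozygous/homozygous dosage; artifact plants sit in
#' injected repeat contexts and appear in tumor only.
#'
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param n_genes genes on the simulated contig (4 CDS exons each).
#' @param n_somatic planted somatic SNVs (truth set).
#' @param n_germline,n_artifact planted germline polymorphisms and
#'   repeat-context artifact sites (panel-only by construction).
#' @param n_rescue_insufficient,n_rescue_adequate,n_rescue_supported
#'   somatic sites assigned to the three rescue regimes (the rest are
#'   `validated`).
#' @param fraction_container approximate fraction of snapshot records that
#'   are gene-level container variants; `0` suppresses container archetypes
#'   entirely.
#' @param vaf_range true somatic VAF range (uniform draw); insufficient-
#'   regime sites are constrained to low VAFs so their binomial call is far
#'   from the decision boundary.
#' @param families_per_site unique molecules (probe+tag families) covering
#'   each planted site, split across strands.
#' @param reads_per_family mean reads per family (1 + Poisson(mean-1)).
#' @param per_read_error per-base sequencing error probability.
#' @param read_length bases per read.
#' @param original_depth_mean,original_depth_dispersion negative-binomial
#'   depth model (mean/size) for validated-regime original coverage.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 12L,
                       n_somatic = 30L,
                       n_germline = 6L,
                       n_artifact = 6L,
                       n_rescue_insufficient = 6L,
                       n_rescue_adequate = 2L,
                       n_rescue_supported = 2L,
                       fraction_container = 0.1,
                       vaf_range = c(0.05, 0.6),
                       families_per_site = 500L,
                       reads_per_family = 3,
                       per_read_error = 0.01,
                       read_length = 80L,
                       original_depth_mean = 120,
                       original_depth_dispersion = 10) {
  stopifnot(seed == as.integer(seed),
            per_read_error >= 0, per_read_error <= 1,
            vaf_range[1] >= 0, vaf_range[2] <= 1, vaf_range[1] <= vaf_range[2],
            n_rescue_insufficient + n_rescue_adequate + n_rescue_supported <= n_somatic)
  n_sites <- n_somatic + n_germline + n_artifact
  if (n_sites > n_genes * 4L) {
    stop_pm("not enough exons to place one site per exon; increase n_genes",
            "panelmips_config")
  }
  structure(as.list(environment()), class = "sim_config")
}

.SIM <- list(exon_len = 240L, exons_per_gene = 4L, intron_len = 150L,
             intergenic = 600L, chrom = "sim1")

sim_gene_layout <- function(n_genes) {
  span <- .SIM$exons_per_gene * .SIM$exon_len + (.SIM$exons_per_gene - 1L) * .SIM$intron_len
  gene_start <- .SIM$intergenic + (seq_len(n_genes) - 1L) * (span + .SIM$intergenic)
  exon_start <- outer(gene_start, (seq_len(.SIM$exons_per_gene) - 1L) *
                        (.SIM$exon_len + .SIM$intron_len), `+`)
  list(gene = sprintf("G%02d", seq_len(n_genes)),
       gene_start = gene_start, gene_end = gene_start + span - 1L,
       exon_start = exon_start, exon_end = exon_start + .SIM$exon_len - 1L,
       genome_len = gene_start[n_genes] + span + .SIM$intergenic - 1L)
}

#' Generate the simulated reference genome and gene models
#'
#' One contig of uniform random base composition carrying `n_genes` genes
#' with 4 protein-coding exons each. The windows around planted sites are
#' re-drawn until repeat-free, and repeat motifs (mononucleotide run,
#' dinucleotide repeat, 3-bp tandem repeat, cycled) are injected at
#' artifact sites, so the repeat-context classifier sees exactly the
#' contexts the generator intends.
#'
#' @param cfg a [sim_config()].
#' @return list with `reference` (`DNAStringSet`), `gene_models`
#'   (`GRanges` of CDS features), `layout`, and `sites` (data.frame of
#'   planted sites with true VAFs, normal dosage, type and rescue regime).
#' @export
make_reference <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  lay <- sim_gene_layout(cfg$n_genes)
  chars <- sample(c("A", "C", "G", "T"), lay$genome_len, replace = TRUE)

  # one candidate site per exon, in gene-major order, away from exon edges
  n_sites <- cfg$n_somatic + cfg$n_germline + cfg$n_artifact
  exon_idx <- cbind(gene = rep(seq_len(cfg$n_genes), each = .SIM$exons_per_gene),
                    exon = rep(seq_len(.SIM$exons_per_gene), cfg$n_genes))
  offs <- 60L + sample.int(.SIM$exon_len - 120L, nrow(exon_idx), replace = TRUE)
  site_pos <- vapply(seq_len(nrow(exon_idx)), function(r)
    lay$exon_start[exon_idx[r, "gene"], exon_idx[r, "exon"]] + offs[r] - 1L,
    integer(1))
  site_pos <- site_pos[seq_len(n_sites)]

  type <- c(rep("somatic", cfg$n_somatic),
            rep(c("germline_het", "germline_hom"), length.out = cfg$n_germline),
            rep("artifact", cfg$n_artifact))

  # scrub repeat structure around non-artifact sites
  rcfg <- rescue_config()
  w <- rcfg$repeat_window
  for (i in which(type != "artifact")) {
    lo <- max(1L, site_pos[i] - w); hi <- min(lay$genome_len, site_pos[i] + w)
    repeat {
      ref <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
      names(ref) <- .SIM$chrom
      if (repeat_context(.SIM$chrom, site_pos[i], ref, rcfg) == "none") break
      chars[lo:hi] <- sample(c("A", "C", "G", "T"), hi - lo + 1L, replace = TRUE)
    }
  }
  # inject repeat motifs at artifact sites (cycle MN, DN, TR)
  motifs <- c("AAAAAA", "ATATATAT", "ACGACGACG")
  art <- which(type == "artifact")
  for (j in seq_along(art)) {
    m <- strsplit(motifs[(j - 1L) %% 3L + 1L], "")[[1]]
    s <- site_pos[art[j]] - 2L
    chars[s:(s + length(m) - 1L)] <- m
  }

  reference <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(reference) <- .SIM$chrom

  # rescue regimes over the somatic sites: tail of the somatic block, so
  # the first sites (cited by container archetypes) stay validated
  regime <- rep("validated", n_sites)
  r_start <- cfg$n_somatic - (cfg$n_rescue_insufficient + cfg$n_rescue_adequate +
                                cfg$n_rescue_supported)
  lab <- c(rep("insufficient", cfg$n_rescue_insufficient),
           rep("adequate", cfg$n_rescue_adequate),
           rep("supported", cfg$n_rescue_supported))
  if (length(lab)) regime[r_start + seq_along(lab)] <- lab
  regime[type != "somatic"] <- NA

  vaf <- runif(n_sites, cfg$vaf_range[1], cfg$vaf_range[2])
  # keep insufficient-regime binomial calls far from the decision boundary
  vaf[which(regime == "insufficient")] <-
    runif(sum(regime == "insufficient", na.rm = TRUE), 0.05, 0.12)
  vaf[type == "germline_het"] <- 0.5
  vaf[type == "germline_hom"] <- 1.0
  vaf[type == "artifact"] <- runif(cfg$n_artifact, 0.2, 0.4)
  normal_vaf <- ifelse(type == "germline_het", 0.5,
                       ifelse(type == "germline_hom", 1.0, 0))

  ref_base <- chars[site_pos]
  alt_base <- vapply(ref_base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))

  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    gene = lay$gene[exon_idx[seq_len(n_sites), "gene"]],
    chrom = .SIM$chrom, pos = site_pos, ref = ref_base, alt = alt_base,
    vaf = vaf, normal_vaf = normal_vaf, type = type, regime = regime,
    stringsAsFactors = FALSE)

  gm <- GenomicRanges::GRanges(
    .SIM$chrom,
    IRanges::IRanges(as.vector(t(lay$exon_start)), as.vector(t(lay$exon_end))),
    strand = "+",
    type = "CDS",
    gene_id = rep(lay$gene, each = .SIM$exons_per_gene),
    gene_name = rep(lay$gene, each = .SIM$exons_per_gene))

  list(reference = reference, gene_models = gm, layout = lay, sites = sites)
}

#' Write simulated gene models as GTF
#' @param gene_models `GRanges` with `type`, `gene_id`, `gene_name`.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  md <- S4Vectors::mcols(gene_models)
  lines <- sprintf(
    "%s\tpanelmips_sim\t%s\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; gene_name \"%s\"; transcript_id \"%s.t1\";",
    as.character(GenomicRanges::seqnames(gene_models)), md$type,
    GenomicRanges::start(gene_models), GenomicRanges::end(gene_models),
    as.character(GenomicRanges::strand(gene_models)),
    md$gene_id, md$gene_name, md$gene_id)
  writeLines(lines, path)
  invisible(path)
}

# evidence item builder for the synthetic snapshot
sim_ev <- function(id, type = "Predictive", level = "A", stars = 4L,
                   direction = "Supports", significance = "Sensitivity/Response",
                   origin = "Somatic", disease = "Cancer", drugs = list("DrugA"),
                   status = "accepted", coords = NULL) {
  e <- list(id = id, evidence_type = type, evidence_level = level,
            trust_rating = stars, direction = direction,
            clinical_significance = significance, variant_origin = origin,
            disease = disease, drugs = drugs, status = status,
            citation = paste0("PMID:", abs(sum(utf8ToInt(id)))))
  if (!is.null(coords)) {
    e$variant_coordinates <- list(chromosome = coords[[1]],
                                  start = coords[[2]], stop = coords[[3]])
  }
  e
}

#' Generate a knowledgebase snapshot spanning every eligibility branch
#'
#' Emits one snapshot record per planted site (all eligible hotspot SNVs,
#' with evidence types mixed across Predictive/Prognostic/Diagnostic/
#' Predisposing) plus a fixed set of archetype records exercising each
#' exclusion branch: score at and below the threshold, non-DNA sequence
#' ontology, germline-only evidence, directly conflicting evidence, a
#' redundant container citing already-covered hotspots, an eligible
#' full-tiling container, a sparse-tiling record, a coordinate-free
#' record, and a 250 bp boundary-length record. The accompanying truth
#' table lists the expected eligibility decision, primary exclusion reason
#' and strategy for every record.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [make_reference()] (layout and sites).
#' @param path optional path; when given the snapshot JSON is written
#'   there.
#' @return list with `snapshot` (a `civic_snapshot`), `json` (the raw
#'   list), and `expected` (the eligibility truth table).
#' @export
make_snapshot <- function(cfg = sim_config(), ref = make_reference(cfg),
                          path = NULL) {
  set.seed(cfg$seed + 1L)
  sites <- ref$sites
  lay <- ref$layout
  variants <- list()
  expected <- list()
  ev_types <- rep(c("Predictive", "Predictive", "Predictive", "Prognostic",
                    "Diagnostic", "Predisposing"), length.out = nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    vid <- sprintf("V%03d", i)
    variants[[vid]] <- list(
      id = vid, gene = s$gene, name = sprintf("%s%d%s", s$ref, s$pos, s$alt),
      coordinates = list(chromosome = s$chrom, start = s$pos, stop = s$pos,
                         reference_bases = s$ref, variant_bases = s$alt,
                         reference_build = "GRCh37"),
      variant_types = list("SO:0001583"),
      evidence_items = list(
        sim_ev(paste0("E", vid, "a"), type = ev_types[i], level = "A", stars = 4L),
        sim_ev(paste0("E", vid, "b"), type = ev_types[i], level = "B", stars = 3L)))
    expected[[vid]] <- data.frame(id = vid, expected_eligible = TRUE,
                                  expected_reason = NA_character_,
                                  expected_strategy = "hotspot",
                                  site_id = s$site_id, stringsAsFactors = FALSE)
  }
  arch <- function(id, rec, eligible, reason, strategy) {
    variants[[id]] <<- rec
    expected[[id]] <<- data.frame(id = id, expected_eligible = eligible,
                                  expected_reason = reason,
                                  expected_strategy = strategy,
                                  site_id = NA_character_, stringsAsFactors = FALSE)
  }
  g_last <- cfg$n_genes
  free_pos <- lay$exon_start[g_last, ] + 10L  # spare coordinates, gene n
  # score exactly at the threshold (2-star level A = 20): excluded, strict >
  arch("A01", list(
    id = "A01", gene = lay$gene[g_last], name = "X1Y",
    coordinates = list(chromosome = .SIM$chrom, start = free_pos[1],
                       stop = free_pos[1], reference_bases = "A",
                       variant_bases = "T", reference_build = "GRCh37"),
    variant_types = list("SO:0001583"),
    evidence_items = list(sim_ev("EA01", level = "A", stars = 2L))),
    FALSE, "evidence score", NA)
  # low score
  arch("A02", list(
    id = "A02", gene = lay$gene[g_last], name = "X2Y",
    coordinates = list(chromosome = .SIM$chrom, start = free_pos[2],
                       stop = free_pos[2], reference_bases = "C",
                       variant_bases = "G", reference_build = "GRCh37"),
    variant_types = list("SO:0001583"),
    evidence_items = list(sim_ev("EA02", level = "C", stars = 2L))),
    FALSE, "evidence score", NA)
  # non-DNA sequence ontology (transcript fusion)
  arch("A03", list(
    id = "A03", gene = lay$gene[g_last], name = "FUSION",
    coordinates = list(chromosome = .SIM$chrom, start = free_pos[3],
                       stop = free_pos[3] + 40L, reference_bases = "",
                       variant_bases = "", reference_build = "GRCh37"),
    variant_types = list("SO:0001565"),
    evidence_items = list(sim_ev("EA03", stars = 5L))),
    FALSE, "not DNA-based", NA)
  # germline-only evidence
  arch("A04", list(
    id = "A04", gene = lay$gene[g_last], name = "X3Y",
    coordinates = list(chromosome = .SIM$chrom, start = free_pos[4],
                       stop = free_pos[4], reference_bases = "G",
                       variant_bases = "A", reference_build = "GRCh37"),
    variant_types = list("SO:0001583"),
    evidence_items = list(
      sim_ev("EA04a", type = "Predisposing", origin = "Germline",
             significance = "Pathogenic", stars = 4L, drugs = list()),
      sim_ev("EA04b", type = "Predisposing", origin = "Germline",
             significance = "Likely Pathogenic", stars = 3L, drugs = list()))),
    FALSE, "germline-only", NA)
  # directly conflicting evidence (same type, disease, drug set)
  arch("A05", list(
    id = "A05", gene = lay$gene[g_last], name = "X4Y",
    coordinates = list(chromosome = .SIM$chrom, start = free_pos[1] + 30L,
                       stop = free_pos[1] + 30L, reference_bases = "T",
                       variant_bases = "C", reference_build = "GRCh37"),
    variant_types = list("SO:0001583"),
    evidence_items = list(
      sim_ev("EA05a", significance = "Sensitivity/Response", stars = 4L),
      sim_ev("EA05b", significance = "Resistance", stars = 4L))),
    FALSE, "conflicting evidence", NA)
  # coordinate-free record
  arch("A06", list(
    id = "A06", gene = lay$gene[g_last], name = "EXPRESSION",
    variant_types = list("SO:0001583"),
    evidence_items = list(sim_ev("EA06", stars = 5L))),
    FALSE, "no coordinates", NA)
  # boundary: length exactly 250 goes to the tiling branch (sparse)
  b_start <- lay$exon_start[g_last, 2]
  arch("A07", list(
    id = "A07", gene = lay$gene[g_last], name = "EXON 2 REGION",
    coordinates = list(chromosome = .SIM$chrom, start = b_start,
                       stop = b_start + 249L, reference_bases = "",
                       variant_bases = "", reference_build = "GRCh37"),
    variant_types = list("SO:0001589"),
    evidence_items = list(
      sim_ev("EA07a", stars = 4L,
             coords = list(.SIM$chrom, b_start + 5L, b_start + 5L)),
      sim_ev("EA07b", stars = 3L))),
    TRUE, NA, "sparse_tiling")
  if (cfg$fraction_container > 0) {
    # redundant container on gene 1: 3 of 4 evidence items cite hotspots of
    # already-selected (higher-scored) variants
    g1 <- sites[sites$gene == lay$gene[1], ][1:3, ]
    arch("A08", list(
      id = "A08", gene = lay$gene[1], name = "MUTATION",
      coordinates = list(chromosome = .SIM$chrom, start = lay$gene_start[1],
                         stop = lay$gene_end[1], reference_bases = "",
                         variant_bases = "", reference_build = "GRCh37"),
      variant_types = list("SO:0001583"),
      # score 26: above the gate but below the hotspots it cites, so the
      # selection pass visits it after those hotspots are already covered
      evidence_items = list(
        sim_ev("EA08a", level = "B", stars = 2L,
               coords = list(g1$chrom[1], g1$pos[1], g1$pos[1])),
        sim_ev("EA08b", level = "B", stars = 2L,
               coords = list(g1$chrom[2], g1$pos[2], g1$pos[2])),
        sim_ev("EA08c", level = "C", stars = 3L,
               coords = list(g1$chrom[3], g1$pos[3], g1$pos[3])),
        sim_ev("EA08d", level = "C", stars = 3L))),
      FALSE, "redundant container", NA)
    # eligible full-tiling container on gene 2 (no cited hotspots)
    arch("A09", list(
      id = "A09", gene = lay$gene[2], name = "MUTATION",
      coordinates = list(chromosome = .SIM$chrom, start = lay$gene_start[2],
                         stop = lay$gene_end[2], reference_bases = "",
                         variant_bases = "", reference_build = "GRCh37"),
      variant_types = list("SO:0001583"),
      evidence_items = list(sim_ev("EA09a", stars = 4L), sim_ev("EA09b", stars = 3L))),
      TRUE, NA, "full_tiling")
  }
  json <- list(variants = unname(variants))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(json, tmp, auto_unbox = TRUE, digits = NA)
  snapshot <- load_snapshot(tmp)
  if (!is.null(path)) file.copy(tmp, path, overwrite = TRUE)
  unlink(tmp)
  list(snapshot = snapshot, json = json,
       expected = do.call(rbind, unname(expected)))
}

# simulate reads over planted sites for one sample
simulate_sample_reads <- function(sites, reference, cfg, sample_id, vaf_col,
                                  seed_offset) {
  set.seed(cfg$seed + seed_offset)
  genome_len <- Biostrings::width(reference)[1]
  chrom_chars <- strsplit(as.character(reference[[1]]), "")[[1]]
  half <- cfg$read_length %/% 2L
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    p <- s[[vaf_col]]
    w_start <- max(1L, s$pos - half)
    w_end <- min(genome_len, w_start + cfg$read_length - 1L)
    L <- w_end - w_start + 1L
    site_off <- s$pos - w_start + 1L
    fams <- cfg$families_per_site
    is_alt <- rbinom(fams, 1L, p) == 1L
    n_reads <- 1L + rpois(fams, max(cfg$reads_per_family - 1, 0))
    total <- sum(n_reads)
    M <- matrix(chrom_chars[w_start:w_end], nrow = L, ncol = total)
    fam_of_read <- rep(seq_len(fams), n_reads)
    M[site_off, is_alt[fam_of_read]] <- s$alt
    if (cfg$per_read_error > 0) {
      n_err <- rbinom(1L, L * total, cfg$per_read_error)
      if (n_err > 0) {
        idx <- sample.int(L * total, n_err)
        shift <- sample.int(3L, n_err, replace = TRUE)
        code <- match(M[idx], c("A", "C", "G", "T"))
        M[idx] <- c("A", "C", "G", "T")[(code - 1L + shift) %% 4L + 1L]
      }
    }
    bases <- vapply(seq_len(total), function(j) paste(M[, j], collapse = ""),
                    character(1))
    tags <- vapply(seq_len(fams), function(f)
      paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE), collapse = ""),
      character(1))
    out[[i]] <- data.frame(
      read_id = sprintf("%s_%s_f%04d_r%03d", sample_id, s$site_id,
                        fam_of_read, sequence(n_reads)),
      mip_id = sprintf("mip_%s", s$site_id),
      tag = tags[fam_of_read],
      strand = c("+", "-")[fam_of_read %% 2L + 1L],
      chrom = s$chrom, pos_start = w_start,
      bases = bases, quals = strrep("I", L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate tagged tumor and matched-normal reads with planted variants
#'
#' Every planted site is covered by `families_per_site` unique molecules
#' split across strands; each family is assigned the variant allele with
#' probability equal to the site's VAF (0.5/1.0 for germline dosage in
#' both samples, the somatic/artifact VAF in tumor only), and its reads
#' copy the family haplotype with independent per-base errors.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [make_reference()].
#' @param regions panel `target_regions`; every planted site must fall
#'   inside them (error otherwise).
#' @return list with `tumor`, `normal` (tagged-read data.frames) and
#'   `truth` (somatic truth records: `chrom, pos, ref, alt, vaf`).
#' @export
make_reads <- function(cfg = sim_config(), ref = make_reference(cfg),
                       regions = NULL) {
  sites <- ref$sites
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    if (!all(IRanges::overlapsAny(gr, regions_to_granges(regions)))) {
      stop_pm("planted sites fall outside the panel regions", "panelmips_sim")
    }
  }
  tumor <- simulate_sample_reads(sites, ref$reference, cfg, "tumor1", "vaf", 100L)
  normal <- simulate_sample_reads(sites, ref$reference, cfg, "normal1",
                                  "normal_vaf", 200L)
  truth <- sites[sites$type == "somatic",
                 c("chrom", "pos", "ref", "alt", "vaf", "site_id", "regime")]
  rownames(truth) <- NULL
  list(tumor = tumor, normal = normal, truth = truth)
}

#' Write simple site records as a VCF (v4.2) with an AF INFO field
#' @param sites data.frame `chrom, pos, ref, alt, vaf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_sites <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelmips_sim",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  body <- character()
  if (nrow(sites)) {
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g",
                    sites$chrom, sites$pos, sites$ref, sites$alt, sites$vaf)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate the "original sequencing" call set and support table
#'
#' Draws per-site original coverage from a negative-binomial depth model
#' and variant-supporting reads from a binomial at the true VAF, then
#' applies the rescue regimes: `insufficient` sites get shallow depth
#' (2-8x) and zero support, `adequate` sites deep coverage (3000-6000x)
#' with support forced to zero (constructed scenario), `supported` sites
#' 1-3 supporting reads. A variant enters the original call set only when
#' its supporting reads exceed `max_supporting_reads`. The support table
#' additionally covers germline and artifact plants (germline with dosage
#' support, excluded from the somatic call set as a matched-normal caller
#' would; artifacts with zero support).
#'
#' @param cfg a [sim_config()].
#' @param sites the `sites` data.frame from [make_reference()].
#' @param rescue_cfg a [rescue_config()] (supplies `k`).
#' @return list with `calls` (original somatic call records
#'   `chrom,pos,ref,alt,vaf`), `support` (per-site depth/alt table), and
#'   `expected_categories` (site_id -> expected rescue category for
#'   panel-only sites).
#' @export
make_original_calls <- function(cfg = sim_config(), sites,
                                rescue_cfg = rescue_config()) {
  set.seed(cfg$seed + 300L)
  k <- rescue_cfg$max_supporting_reads
  n <- nrow(sites)
  depth <- rnbinom(n, mu = cfg$original_depth_mean,
                   size = cfg$original_depth_dispersion)
  depth <- pmax(depth, 30L)
  alt <- rbinom(n, depth, ifelse(sites$type == "somatic", sites$vaf,
                                 sites$normal_vaf))
  # validated sites are detected by the original caller by construction:
  # truncated binomial draw with alt > k
  val <- which(!is.na(sites$regime) & sites$regime == "validated")
  if (length(val)) {
    lo <- stats::pbinom(k, depth[val], sites$vaf[val])
    u <- runif(length(val), lo, 1)
    alt[val] <- pmax(stats::qbinom(u, depth[val], sites$vaf[val]), k + 1L)
  }
  ins <- which(!is.na(sites$regime) & sites$regime == "insufficient")
  depth[ins] <- 2L + rpois(length(ins), 3)
  depth[ins] <- pmin(depth[ins], 8L)
  alt[ins] <- 0L
  adq <- which(!is.na(sites$regime) & sites$regime == "adequate")
  depth[adq] <- 3000L + rpois(length(adq), 3000)
  alt[adq] <- 0L
  sup <- which(!is.na(sites$regime) & sites$regime == "supported")
  alt[sup] <- sample(seq_len(k), length(sup), replace = TRUE)
  art <- which(sites$type == "artifact")
  alt[art] <- 0L

  somatic <- sites$type == "somatic"
  called <- somatic & alt > k
  calls <- data.frame(chrom = sites$chrom[called], pos = sites$pos[called],
                      ref = sites$ref[called], alt = sites$alt[called],
                      vaf = alt[called] / depth[called], stringsAsFactors = FALSE)
  support <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                        alt = sites$alt, depth = depth, alt_count = alt,
                        stringsAsFactors = FALSE)
  # expected rescue category for every planted site absent from the calls
  expected <- character(n)
  for (i in seq_len(n)) {
    if (called[i]) { expected[i] <- "detected_in_original"; next }
    expected[i] <- switch(sites$type[i],
      germline_het = , germline_hom = "germline",
      artifact = "artifact",
      somatic = if (alt[i] >= 1) "supported_in_original" else {
        p <- binomial_detectability(depth[i], sites$vaf[i], rescue_cfg)
        if (p > rescue_cfg$confidence) "no_support_insufficient_coverage"
        else "no_support_adequate_coverage"
      })
  }
  list(calls = calls, support = support,
       expected_categories = data.frame(site_id = sites$site_id,
                                        expected_category = expected,
                                        stringsAsFactors = FALSE))
}

#' Build the full synthetic validation cohort
#'
#' Wires the generators together: reference and gene models, snapshot with
#' eligibility truth table, designed panel (filter + merged regions),
#' tagged tumor/normal reads over all planted sites, somatic truth set,
#' and the simulated original sequencing. Everything derives
#' deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, all artifacts are
#'   written there (FASTA, GTF, snapshot JSON, panel BED, read TSVs, truth
#'   and original VCFs, support and expectation tables).
#' @return a `sim_cohort` list: `cfg`, `reference`, `gene_models`,
#'   `sites`, `snapshot`, `expected_eligibility`, `filtered`, `regions`,
#'   `tumor_reads`, `normal_reads`, `truth`, `original` (calls, support,
#'   expected_categories).
#' @export
simulate_validation_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  ref <- make_reference(cfg)
  snap <- make_snapshot(cfg, ref)
  filtered <- filter_eligible(snap$snapshot)
  regions <- build_regions(eligible_variants(filtered), ref$gene_models,
                           reference = ref$reference)
  reads <- make_reads(cfg, ref, regions)
  orig <- make_original_calls(cfg, ref$sites)
  sim <- structure(list(
    cfg = cfg, reference = ref$reference, gene_models = ref$gene_models,
    sites = ref$sites, snapshot = snap$snapshot,
    expected_eligibility = snap$expected, filtered = filtered,
    regions = regions, tumor_reads = reads$tumor, normal_reads = reads$normal,
    truth = reads$truth, original = orig), class = "sim_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$reference, file.path(out_dir, "reference.fa"))
    write_gtf(sim$gene_models, file.path(out_dir, "genes.gtf"))
    write_snapshot(sim$snapshot, file.path(out_dir, "snapshot.json"))
    write_bed(sim$regions, file.path(out_dir, "panel.bed"))
    write_tagged_reads(sim$tumor_reads, file.path(out_dir, "tumor_reads.tsv"))
    write_tagged_reads(sim$normal_reads, file.path(out_dir, "normal_reads.tsv"))
    write_vcf_sites(sim$truth, file.path(out_dir, "truth.vcf"))
    write_vcf_sites(sim$original$calls, file.path(out_dir, "original.vcf"))
    write_original_support(sim$original$support,
                           file.path(out_dir, "original_support.tsv"))
    utils::write.table(sim$expected_eligibility,
                       file.path(out_dir, "expected_eligibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$original$expected_categories,
                       file.path(out_dir, "expected_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim
}

#' Run the analysis pipeline on a simulated cohort
#'
#' Tumor and normal consensus pileups over the panel, SNV calling,
#' sensitivity/VAF comparison against the planted truth, rescue
#' classification of panel-only calls, and knowledgebase annotation.
#'
#' @param sim a `sim_cohort` from [simulate_validation_cohort()].
#' @param caller_cfg a [caller_config()].
#' @param qc a [qc_config()].
#' @param rescue_cfg a [rescue_config()].
#' @return list: `tumor_pileup`, `normal_pileup`, `calls`, `comparison`,
#'   `smmip_only`, `rescue` (classifications), `rescue_summary`,
#'   `matches`, `match_summary`.
#' @export
run_validation_pipeline <- function(sim, caller_cfg = caller_config(),
                                    qc = qc_config(),
                                    rescue_cfg = rescue_config()) {
  tp <- build_pileup(sim$tumor_reads, qc, sim$regions)
  np <- build_pileup(sim$normal_reads, qc, sim$regions)
  calls <- call_variants(tp, sim$reference, caller_cfg, sample_id = "tumor1")
  comparison <- compare_to_truth(calls, sim$truth, sim$regions, sim$reference)
  okey <- variant_key(sim$original$calls)
  smmip_only <- calls[!variant_key(calls) %in% okey, , drop = FALSE]
  rescue <- classify_rescued(smmip_only, sim$original$support, np,
                             sim$reference, rescue_cfg, caller_cfg)
  matches <- match_calls(calls, sim$snapshot, sim$reference)
  list(tumor_pileup = tp, normal_pileup = np, calls = calls,
       comparison = comparison, smmip_only = smmip_only, rescue = rescue,
       rescue_summary = rescue_summary(rescue), matches = matches,
       match_summary = summarize_matches(matches, 1L))
}
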