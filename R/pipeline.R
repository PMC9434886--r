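#' Cohort composition summary
#'
#' Counts and percentages of high-risk disease by ancestry, plus optional
#' per-ancestry positivity rates for a per-sample flag (e.g. fusion
#' positivity). Percentages are reported to one decimal; a zero denominator
#' yields a flagged undefined entry rather than an error.
#'
#' @param metadata Cohort metadata (`sample_id`, `ancestry`, `risk_group`).
#' @param positive_samples Optional character vector of samples positive
#'   for a flag of interest.
#' @param flag_name Label used for the flag rows (default `"flag"`).
#' @return data.frame with `statistic`, `numerator`, `denominator`, `pct`
#'   (one decimal), `undefined`.
#' @export
cohortSummary <- function(metadata, positive_samples = NULL,
                          flag_name = "flag") {
  row <- function(stat, num, den) {
    data.frame(statistic = stat, numerator = num, denominator = den,
               pct = if (den == 0) NA_real_ else round(100 * num / den, 1),
               undefined = den == 0, stringsAsFactors = FALSE)
  }
  hr <- metadata$risk_group == "HRPCa"
  out <- list(row("high_risk_overall", sum(hr), nrow(metadata)))
  for (a in c("African", "European", "Admixed")) {
    sel <- metadata$ancestry == a
    out[[length(out) + 1]] <- row(paste0("high_risk_", a),
                                  sum(hr & sel), sum(sel))
  }
  if (!is.null(positive_samples)) {
    pos <- metadata$sample_id %in% positive_samples
    out[[length(out) + 1]] <- row(paste0(flag_name, "_overall"),
                                  sum(pos), nrow(metadata))
    for (a in c("African", "European", "Admixed")) {
      sel <- metadata$ancestry == a
      out[[length(out) + 1]] <- row(paste0(flag_name, "_", a),
                                    sum(pos & sel), sum(sel))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- read_yaml(config)
  }
  need <- c("vcf_dir_a", "vcf_dir_b", "refflat", "chrom_sizes", "metadata")
  inputs <- config$inputs
  miss <- setdiff(need, names(inputs))
  if (length(miss) > 0) stopf("pipeline config missing input(s): %s",
                              paste(miss, collapse = ", "))
  for (f in names(inputs)) {
    if (!is.null(inputs[[f]]) && !file.exists(inputs[[f]])) {
      stopf("input not found: %s (%s)", inputs[[f]], f)
    }
  }
  config
}

#' Run the full SV landscape pipeline
#'
#' Orchestrates all stages on files written in the package's interchange
#' formats: per-sample VCF import for both callers, cross-caller
#' concordance, SV-type spectra and hyper-SV subtype calling, hotspot
#' detection with gene nomination and ancestry composition, gene-fusion
#' calling (recurrence, ETS-partner tables, mechanism classification and
#' junction mapping for the configured fusion pair), gene CN states,
#' biallelic inactivation over the driver list, burden-mutation association
#' testing, and the cohort summary. All outputs are written as TSV into
#' `outdir`, together with a JSON run manifest recording package version,
#' parameters and input/output checksums; identical inputs and parameters
#' yield identical outputs.
#'
#' @param config A list (or path to a YAML file) with elements `inputs`
#'   (paths: `vcf_dir_a`, `vcf_dir_b`, `refflat`, `chrom_sizes`,
#'   `metadata`, and optionally `cn`, `cn_thresholds`, `allelic`, `snv`,
#'   `driver_genes`), `params` (optional overrides: `tolerance_bp`,
#'   `high_conf_in_at_least`, `min_total`, `dominance`, `width`,
#'   `k_breakpoints`, `k_samples`, `fusion_pair`), and `outdir`.
#' @param quiet Suppress progress messages.
#' @return Invisible list with all stage results.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  config <- readPipelineConfig(config)
  inputs <- config$inputs
  par <- config$params %||% list()
  outdir <- config$outdir %||% "svscape-out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[1/7] importing inputs")
  metadata <- readCohortMetadata(inputs$metadata)
  chrom_sizes <- readChromSizes(inputs$chrom_sizes)
  transcripts <- readRefFlat(inputs$refflat)
  genes <- suppressWarnings(geneUnionIntervals(transcripts))
  importDir <- function(dir, dialect, caller_id) {
    files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
    parts <- lapply(files, function(f) {
      s <- sub("\\.vcf$", "", basename(f))
      svCalls(importSvVcf(f, dialect, s, caller_id))
    })
    SvCallSet(do.call(rbind, parts))
  }
  calls_a <- importDir(inputs$vcf_dir_a, "typed", "callerA")
  calls_b <- importDir(inputs$vcf_dir_b, "bnd-only", "callerB")

  say("[2/7] cross-caller concordance (%d + %d calls)",
      length(calls_a), length(calls_b))
  cpar <- concordanceParams(
    tolerance_bp = par$tolerance_bp %||% 5,
    high_conf_in_at_least = par$high_conf_in_at_least %||% 1
  )
  merged <- mergeCallers(calls_a, calls_b, cpar)
  writeSvTable(merged, file.path(outdir, "merged.tsv"))

  say("[3/7] spectra and hyper-SV subtypes (%d concordant calls)",
      length(merged))
  spectra <- svSpectrum(merged, samples = metadata$sample_id)
  subtypes <- classifyHyperSv(spectra, subtypeParams(
    min_total = par$min_total %||% 100,
    dominance = par$dominance %||% 0.5
  ))
  folds <- ancestryFoldChange(spectra, metadata)

  say("[4/7] hotspots")
  bins <- binBreakpoints(merged, chrom_sizes, width = par$width %||% 1e6)
  hpar <- hotspotParams(k_breakpoints = par$k_breakpoints %||% 3,
                        k_samples = par$k_samples %||% 1.5)
  hot <- callHotspots(bins, hpar)
  hot <- nominateGenes(hot, merged, genes, hpar)
  hot <- ancestryComposition(hot, merged, metadata)

  say("[5/7] gene fusions")
  fus <- orientFusion(callFusions(merged, genes))
  recurrence <- tallyRecurrence(fus, metadata)
  ets <- etsPartnerTable(fus, metadata = metadata)
  pair <- par$fusion_pair %||% c("TMPRSS2", "ERG")
  mech <- NULL; junctions <- NULL
  pair_pos <- fus$gene_5p == pair[1] & fus$gene_3p == pair[2] |
    fus$gene_5p == pair[2] & fus$gene_3p == pair[1]
  for (s in unique(fus$sample_id[pair_pos])) {
    m <- tryCatch(
      classifyFusionMechanism(merged, s, pair[1], pair[2], genes),
      error = function(e) NULL
    )
    if (!is.null(m)) {
      mech <- rbind(mech, data.frame(
        sample_id = s, label = m$label,
        n_supporting_svs = m$n_supporting_svs, stringsAsFactors = FALSE))
    }
    f1 <- fus[pair_pos & fus$sample_id == s, ][1, ]
    j <- mapFusionJunction(
      f1$pos_5p, f1$pos_3p,
      transcripts[transcripts$gene_symbol == pair[1], , drop = FALSE],
      transcripts[transcripts$gene_symbol == pair[2], , drop = FALSE]
    )
    if (nrow(j) > 0) {
      j$sample_id <- s
      junctions <- rbind(junctions, j)
    }
  }

  say("[6/7] gene inactivation and burden association")
  biallelic <- NULL; assoc <- NULL; mm <- NULL
  if (!is.null(inputs$cn) && !is.null(inputs$cn_thresholds)) {
    cn <- read.delim(inputs$cn, stringsAsFactors = FALSE)
    thr <- read.delim(inputs$cn_thresholds, stringsAsFactors = FALSE)
    snv <- if (is.null(inputs$snv)) NULL else
      read.delim(inputs$snv, stringsAsFactors = FALSE)
    allelic <- if (is.null(inputs$allelic)) NULL else
      read.delim(inputs$allelic, stringsAsFactors = FALSE)
    drivers <- if (is.null(inputs$driver_genes)) unique(cn$gene) else
      readLines(inputs$driver_genes)
    cn_calls <- cnGeneCalls(cn, thr)
    mm <- suppressWarnings(buildMutationMatrix(
      snv %||% data.frame(), cn_calls, merged, genes, drivers,
      metadata$sample_id))
    if (!is.null(allelic) && !is.null(snv)) {
      ev <- biallelicEvidence(merged, snv, cn_calls, allelic, transcripts,
                              attr(mm, "genes"), metadata$sample_id)
      biallelic <- classifyBiallelic(ev)
    }
    assoc <- testSvBurdenAssociation(spectra, mutatedMask(mm))
  }

  say("[7/7] cohort summary and manifest")
  pair_samples <- unique(fus$sample_id[pair_pos])
  summary_tab <- cohortSummary(metadata, pair_samples,
                               paste0(pair[1], "-", pair[2]))

  wtsv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(spectra, "spectrum.tsv")
  wtsv(subtypes, "subtypes.tsv")
  wtsv(folds, "ancestry_folds.tsv")
  wtsv(hot, "bins.tsv")
  wtsv(hot[hot$hotspot, , drop = FALSE], "hotspots.tsv")
  wtsv(fus, "fusions.tsv")
  wtsv(recurrence, "fusion_recurrence.tsv")
  wtsv(ets, "ets_partners.tsv")
  wtsv(mech, "fusion_mechanisms.tsv")
  wtsv(junctions, "fusion_junctions.tsv")
  if (!is.null(biallelic)) wtsv(biallelic, "biallelic.tsv")
  if (!is.null(assoc)) wtsv(assoc, "association.tsv")
  wtsv(summary_tab, "summary.tsv")

  input_files <- unlist(lapply(inputs, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  outputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "svscape",
    version = as.character(packageVersion("svscape")),
    params = par,
    inputs = as.list(md5sum(sort(input_files))),
    outputs = as.list(md5sum(sort(outputs)))
  )
  write_json(manifest, file.path(outdir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    merged = merged, spectra = spectra, subtypes = subtypes, folds = folds,
    bins = hot, fusions = fus, recurrence = recurrence, ets = ets,
    mechanisms = mech, junctions = junctions, mutation_matrix = mm,
    biallelic = biallelic, association = assoc, summary = summary_tab,
    manifest = manifest
  ))
}

#' Assemble biallelic-inactivation evidence
#'
#' Builds the per-(sample, gene) evidence frame consumed by
#' [classifyBiallelic()]: the gene CN state, allele-specific copy counts,
#' the number of deletions overlapping an exon, presence of nonsynonymous
#' somatic and germline SNVs, and whether any SV breakend interrupts an
#' exon.
#'
#' @param x [SvCallSet-class] of the cohort.
#' @param small_variants,cn_calls,allelic Evidence tables (see
#'   [buildMutationMatrix()], [cnGeneCalls()]).
#' @param transcripts Transcript table ([readRefFlat()]).
#' @param genes Character vector of genes to assess.
#' @param samples Character vector of samples to assess.
#' @return data.frame ready for [classifyBiallelic()].
#' @export
biallelicEvidence <- function(x, small_variants, cn_calls, allelic,
                              transcripts, genes, samples) {
  df <- svCalls(x)
  ## exon intervals per gene
  tx <- transcripts[transcripts$gene_symbol %in% genes, , drop = FALSE]
  exon_gr <- GRanges(
    rep(tx$chrom, tx$exon_count),
    IRanges(unlist(tx$exon_starts), unlist(tx$exon_ends))
  )
  exon_gr$gene <- rep(tx$gene_symbol, tx$exon_count)

  be <- breakendPositions(x)
  hits_be <- suppressWarnings(
    findOverlaps(GRanges(be$chrom, IRanges(be$pos, be$pos)),
                 exon_gr, ignore.strand = TRUE))
  break_key <- unique(paste(be$sample_id[queryHits(hits_be)],
                            exon_gr$gene[subjectHits(hits_be)]))

  del <- df[df$svtype == "DEL" & !is.na(df$pos2), , drop = FALSE]
  del_key <- character()
  if (nrow(del) > 0) {
    hits_del <- suppressWarnings(
      findOverlaps(GRanges(del$chrom1, IRanges(del$pos1, del$pos2)),
                   exon_gr, ignore.strand = TRUE))
    del_key <- paste(del$sample_id[queryHits(hits_del)],
                     exon_gr$gene[subjectHits(hits_del)])
  }

  ev <- expand.grid(sample_id = samples, gene = genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(ev$sample_id, ev$gene)
  cn_key <- paste(cn_calls$sample_id, cn_calls$gene)
  ev$cn_state <- cn_calls$state[match(key, cn_key)]
  ev$cn_state[is.na(ev$cn_state)] <- 0L
  al_key <- paste(allelic$sample_id, allelic$gene)
  m <- match(key, al_key)
  ev$allele_a <- ifelse(is.na(m), 1L, allelic$allele_a[m])
  ev$allele_b <- ifelse(is.na(m), 1L, allelic$allele_b[m])
  ev$exon_del_count <- as.integer(table(factor(del_key, levels = key))[key])
  nonsyn <- small_variants[small_variants$effect == "nonsynonymous", ,
                           drop = FALSE]
  som_key <- paste(nonsyn$sample_id[nonsyn$origin == "somatic"],
                   nonsyn$gene[nonsyn$origin == "somatic"])
  germ_key <- paste(nonsyn$sample_id[nonsyn$origin == "germline"],
                    nonsyn$gene[nonsyn$origin == "germline"])
  ev$somatic_nonsyn <- key %in% som_key
  ev$germline_nonsyn <- key %in% germ_key
  ev$exon_break <- key %in% break_key
  ev
}
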