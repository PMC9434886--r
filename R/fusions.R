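#' Call gene fusions from SV breakend pairs
#'
#' An SV event is a gene-fusion candidate when its two breakends fall inside
#' the union spans of two different genes (strand-ignored containment).
#' Single-breakend insertions cannot qualify. A breakend lying in several
#' overlapping genes yields one fusion per qualifying gene pair, flagged
#' `ambiguous`.
#'
#' @param x An [SvCallSet-class].
#' @param genes [GenomicRanges::GRanges] from [geneUnionIntervals()]
#'   (metadata columns `gene_symbol`, `gene_strand`).
#' @return data.frame with one row per (event, gene pair): `sample_id`,
#'   `call_idx` (row in `svCalls(x)`), `svtype`, breakend coordinates and
#'   orientations, `gene_a`/`gene_b` (genes hit by breakend 1 and 2),
#'   `strand_gene_a`/`strand_gene_b`, `ambiguous`.
#' @export
callFusions <- function(x, genes) {
  df <- svCalls(x)
  two <- which(!is.na(df$pos2))
  empty <- data.frame(
    sample_id = character(), call_idx = integer(), svtype = character(),
    chrom1 = character(), pos1 = numeric(), strand1 = character(),
    chrom2 = character(), pos2 = numeric(), strand2 = character(),
    gene_a = character(), gene_b = character(),
    strand_gene_a = character(), strand_gene_b = character(),
    ambiguous = logical(), stringsAsFactors = FALSE
  )
  if (length(two) == 0 || length(genes) == 0) return(empty)
  g1 <- GRanges(df$chrom1[two], IRanges(df$pos1[two], df$pos1[two]))
  g2 <- GRanges(df$chrom2[two], IRanges(df$pos2[two], df$pos2[two]))
  h1 <- suppressWarnings(findOverlaps(g1, genes, ignore.strand = TRUE))
  h2 <- suppressWarnings(findOverlaps(g2, genes, ignore.strand = TRUE))
  l1 <- split(subjectHits(h1), queryHits(h1))
  l2 <- split(subjectHits(h2), queryHits(h2))
  common <- intersect(names(l1), names(l2))
  rows <- list()
  for (k in common) {
    i <- two[as.integer(k)]
    combos <- expand.grid(a = l1[[k]], b = l2[[k]], KEEP.OUT.ATTRS = FALSE)
    combos <- combos[genes$gene_symbol[combos$a] != genes$gene_symbol[combos$b], ,
                     drop = FALSE]
    if (nrow(combos) == 0) next
    rows[[k]] <- data.frame(
      sample_id = df$sample_id[i], call_idx = i, svtype = df$svtype[i],
      chrom1 = df$chrom1[i], pos1 = df$pos1[i], strand1 = df$strand1[i],
      chrom2 = df$chrom2[i], pos2 = df$pos2[i], strand2 = df$strand2[i],
      gene_a = genes$gene_symbol[combos$a],
      gene_b = genes$gene_symbol[combos$b],
      strand_gene_a = genes$gene_strand[combos$a],
      strand_gene_b = genes$gene_strand[combos$b],
      ambiguous = nrow(combos) > 1,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Does this breakend retain the transcription start of its gene?
## Orientation "+" retains the segment to the LEFT of the position; a gene's
## TSS sits at the low-coordinate end on "+" strand and at the
## high-coordinate end on "-" strand.
retainsTss <- function(orientation, gene_strand) {
  (gene_strand == "+" & orientation == "+") |
    (gene_strand == "-" & orientation == "-")
}

#' Orient fusion partners
#'
#' Orders the two genes of each fusion into 5' and 3' partners from the
#' breakend orientations and gene strands: the 5' partner is the gene whose
#' retained side contributes its transcription start. When the two ends
#' disagree (both retain or both lose their TSS) or a gene strand is
#' unknown, the pair is ordered alphabetically and flagged `unordered`.
#'
#' @param fusions data.frame from [callFusions()].
#' @return `fusions` with added `gene_5p`, `gene_3p`, `pos_5p`, `pos_3p`,
#'   `unordered`.
#' @export
orientFusion <- function(fusions) {
  n <- nrow(fusions)
  fusions$gene_5p <- NA_character_
  fusions$gene_3p <- NA_character_
  fusions$pos_5p <- NA_real_
  fusions$pos_3p <- NA_real_
  fusions$unordered <- FALSE
  if (n == 0) return(fusions)
  known <- fusions$strand_gene_a %in% c("+", "-") &
    fusions$strand_gene_b %in% c("+", "-")
  a5 <- retainsTss(fusions$strand1, fusions$strand_gene_a)
  b5 <- retainsTss(fusions$strand2, fusions$strand_gene_b)
  ordered <- known & (a5 != b5)
  a_first <- ordered & a5
  b_first <- ordered & b5
  fusions$gene_5p[a_first] <- fusions$gene_a[a_first]
  fusions$gene_3p[a_first] <- fusions$gene_b[a_first]
  fusions$pos_5p[a_first] <- fusions$pos1[a_first]
  fusions$pos_3p[a_first] <- fusions$pos2[a_first]
  fusions$gene_5p[b_first] <- fusions$gene_b[b_first]
  fusions$gene_3p[b_first] <- fusions$gene_a[b_first]
  fusions$pos_5p[b_first] <- fusions$pos2[b_first]
  fusions$pos_3p[b_first] <- fusions$pos1[b_first]
  un <- !ordered
  if (any(un)) {
    first_a <- fusions$gene_a[un] <= fusions$gene_b[un]
    fusions$gene_5p[un] <- ifelse(first_a, fusions$gene_a[un], fusions$gene_b[un])
    fusions$gene_3p[un] <- ifelse(first_a, fusions$gene_b[un], fusions$gene_a[un])
    fusions$pos_5p[un] <- ifelse(first_a, fusions$pos1[un], fusions$pos2[un])
    fusions$pos_3p[un] <- ifelse(first_a, fusions$pos2[un], fusions$pos1[un])
    fusions$unordered[un] <- TRUE
  }
  fusions
}

#' Fusion recurrence table
#'
#' Per unique ordered gene pair, the number of distinct samples carrying the
#' fusion (a sample counts once per pair regardless of supporting SV count)
#' and, when metadata is supplied, the per-ancestry sample breakdown.
#'
#' @param fusions Oriented fusion table from [orientFusion()].
#' @param metadata Optional cohort metadata (`sample_id`, `ancestry`).
#' @return data.frame: `gene_5p`, `gene_3p`, `n_samples`, optional
#'   `n_African`, `n_European`, `n_Admixed`; sorted by decreasing
#'   recurrence.
#' @export
tallyRecurrence <- function(fusions, metadata = NULL) {
  if (nrow(fusions) == 0) {
    out <- data.frame(gene_5p = character(), gene_3p = character(),
                      n_samples = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(fusions$gene_5p, fusions$gene_3p, sep = "\r")
  sp <- split(fusions$sample_id, key)
  out <- data.frame(
    gene_5p = vapply(strsplit(names(sp), "\r"), `[`, character(1), 1),
    gene_3p = vapply(strsplit(names(sp), "\r"), `[`, character(1), 2),
    n_samples = vapply(sp, function(s) length(unique(s)), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    anc <- setNames(metadata$ancestry, metadata$sample_id)
    for (g in c("African", "European", "Admixed")) {
      out[[paste0("n_", g)]] <- vapply(sp, function(s)
        sum(anc[unique(s)] == g, na.rm = TRUE), numeric(1))
    }
  }
  out <- out[order(-out$n_samples, out$gene_5p, out$gene_3p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ETS-family fusion partner summary
#'
#' For each gene in `ets_genes` (by default the prostate-cancer relevant ETS
#' transcription factors and their canonical androgen-responsive partner),
#' tabulates its fusion partners with supporting-SV counts per SV type and,
#' when metadata is supplied, sample counts per ancestry.
#'
#' @param fusions Oriented fusion table from [orientFusion()].
#' @param ets_genes Character vector of genes of interest.
#' @param metadata Optional cohort metadata.
#' @return data.frame: `ets_gene`, `partner`, `n_sv`, `n_samples`,
#'   per-type SV counts, optional per-ancestry sample counts.
#' @export
etsPartnerTable <- function(fusions,
                            ets_genes = c("ERG", "ETV1", "ETV4", "ETV5", "TMPRSS2"),
                            metadata = NULL) {
  cols <- c("ets_gene", "partner", "n_sv", "n_samples",
            paste0("sv_", SV_TYPES))
  empty <- as.data.frame(setNames(
    c(list(character(), character()), replicate(length(cols) - 2, numeric(),
                                                simplify = FALSE)), cols),
    stringsAsFactors = FALSE)
  if (nrow(fusions) == 0) return(empty)
  rows <- list()
  for (g in ets_genes) {
    hit <- fusions$gene_5p == g | fusions$gene_3p == g
    if (!any(hit)) next
    f <- fusions[hit, , drop = FALSE]
    partner <- ifelse(f$gene_5p == g, f$gene_3p, f$gene_5p)
    for (p in sort(unique(partner))) {
      fp <- f[partner == p, , drop = FALSE]
      r <- data.frame(ets_gene = g, partner = p, n_sv = nrow(fp),
                      n_samples = length(unique(fp$sample_id)),
                      stringsAsFactors = FALSE)
      for (t in SV_TYPES) r[[paste0("sv_", t)]] <- sum(fp$svtype == t)
      if (!is.null(metadata)) {
        anc <- setNames(metadata$ancestry, metadata$sample_id)
        for (a in c("African", "European", "Admixed")) {
          r[[paste0("n_", a)]] <- sum(anc[unique(fp$sample_id)] == a, na.rm = TRUE)
        }
      }
      rows[[paste(g, p)]] <- r
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the SV mechanism behind a fusion locus
#'
#' Examines all SVs of one sample with a breakend inside the locus window
#' (the span of the two partner genes plus `flank`) and applies, in order:
#' exactly one deletion linking the two genes and nothing else is a
#' `single-deletion`; one linking deletion plus exactly two translocations
#' whose local ends flank the deleted interval indicates retention of the
#' interstitial segment (`interstitial-retention`); a linking deletion with
#' further overlapping SVs is `deletion-plus-overlapping-SVs`; a sole
#' linking inversion or duplication is `inversion` / `duplication`;
#' anything else is `complex-multi-SV` with the window SV count. A fusion
#' deletion may end up to `downstream_ext` bp downstream (strand-aware) of
#' the 3' gene and still count as linking, flagged `extended`.
#'
#' @param x An [SvCallSet-class].
#' @param sample Sample identifier.
#' @param gene_5p,gene_3p Partner gene symbols.
#' @param genes [GenomicRanges::GRanges] from [geneUnionIntervals()].
#' @param flank Window flank in bp (default 1e5).
#' @param downstream_ext Allowed downstream overshoot of the 3' gene for the
#'   linking deletion (default 1e5).
#' @param flank_window Proximity window in bp used to decide whether two
#'   translocation ends flank the deleted interval (default 1000).
#' @return List of class `fusion_mechanism`: `label`, `n_supporting_svs`,
#'   `extended`, `window_calls` (row indices in `svCalls(x)`).
#' @export
classifyFusionMechanism <- function(x, sample, gene_5p, gene_3p, genes,
                                    flank = 1e5, downstream_ext = 1e5,
                                    flank_window = 1000) {
  df <- sampleCalls(x, sample)
  gi <- function(sym) {
    i <- which(genes$gene_symbol == sym)
    if (length(i) == 0) stopf("gene %s not in annotation", sym)
    i[1]
  }
  i5 <- gi(gene_5p); i3 <- gi(gene_3p)
  chrom <- as.character(GenomicRanges::seqnames(genes))[c(i5, i3)]
  span5 <- c(GenomicRanges::start(genes)[i5], GenomicRanges::end(genes)[i5])
  span3 <- c(GenomicRanges::start(genes)[i3], GenomicRanges::end(genes)[i3])
  if (chrom[1] != chrom[2]) {
    stopf("mechanism classification expects an intra-chromosomal gene pair")
  }
  win <- c(min(span5[1], span3[1]) - flank, max(span5[2], span3[2]) + flank)
  in_win <- function(ch, pos) !is.na(pos) & ch == chrom[1] &
    pos >= win[1] & pos <= win[2]
  w <- which(in_win(df$chrom1, df$pos1) | in_win(df$chrom2, df$pos2))
  if (length(w) == 0) stopf("no SVs at the %s-%s locus in sample %s",
                            gene_5p, gene_3p, sample)
  dfw <- df[w, , drop = FALSE]
  in_span <- function(ch, pos, span) !is.na(pos) & ch == chrom[1] &
    pos >= span[1] & pos <= span[2]
  ## strand-aware downstream extension of the 3' gene for linking deletions
  strand3 <- genes$gene_strand[i3]
  span3_ext <- if (strand3 == "-") c(span3[1] - downstream_ext, span3[2]) else
    c(span3[1], span3[2] + downstream_ext)
  hits5 <- in_span(dfw$chrom1, dfw$pos1, span5) |
    in_span(dfw$chrom2, dfw$pos2, span5)
  hits3 <- in_span(dfw$chrom1, dfw$pos1, span3) |
    in_span(dfw$chrom2, dfw$pos2, span3)
  hits3_ext <- in_span(dfw$chrom1, dfw$pos1, span3_ext) |
    in_span(dfw$chrom2, dfw$pos2, span3_ext)
  linking <- (hits5 & hits3) | (dfw$svtype == "DEL" & hits5 & hits3_ext)
  extended <- any(dfw$svtype == "DEL" & hits5 & !hits3 & hits3_ext & linking)
  if (!any(linking)) {
    stopf("no SV links %s and %s in sample %s (not a fusion locus)",
          gene_5p, gene_3p, sample)
  }
  link_del <- which(linking & dfw$svtype == "DEL")
  others <- which(!linking)
  n_win <- nrow(dfw)
  mech <- function(label, n) {
    structure(list(label = label, n_supporting_svs = n, extended = extended,
                   window_calls = w), class = "fusion_mechanism")
  }
  if (length(link_del) == 1 && n_win == 1) {
    return(mech("single-deletion", 1))
  }
  if (length(link_del) == 1 && length(others) == 2 &&
      all(dfw$svtype[others] == "TRA")) {
    d <- dfw[link_del, ]
    local_end <- vapply(others, function(k) {
      r <- dfw[k, ]
      if (r$chrom1 == chrom[1]) r$pos1 else r$pos2
    }, numeric(1))
    near1 <- abs(local_end - d$pos1) <= flank_window
    near2 <- abs(local_end - d$pos2) <= flank_window
    if ((near1[1] && near2[2]) || (near1[2] && near2[1])) {
      return(mech("interstitial-retention", 3))
    }
  }
  if (length(link_del) >= 1 && length(others) >= 1) {
    return(mech("deletion-plus-overlapping-SVs", n_win))
  }
  if (n_win == 1 && sum(linking) == 1) {
    if (dfw$svtype[linking] == "INV") return(mech("inversion", 1))
    if (dfw$svtype[linking] == "DUP") return(mech("duplication", 1))
  }
  mech("complex-multi-SV", n_win)
}

## exons of one transcript in transcript orientation (exon 1 = 5' most)
exonsInTxOrder <- function(tx) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  if (tx$strand == "-") {
    o <- order(s, decreasing = TRUE)
  } else {
    o <- order(s)
  }
  data.frame(index = seq_along(s), start = s[o], end = e[o])
}

#' Map fusion breakends to retained exons
#'
#' For each combination of one 5'-partner transcript and one 3'-partner
#' transcript, reports the highest-index exon (in transcript orientation)
#' lying wholly upstream of the 5' breakend — the last exon retained in the
#' fusion product — and the lowest-index exon wholly downstream of the 3'
#' breakend — the first retained exon. A breakend falling inside an exon
#' reports that exon with an intra-exonic flag. Transcript combinations
#' whose span does not contain the breakend are skipped and listed in the
#' `skipped` attribute.
#'
#' @param pos_5p,pos_3p Breakend positions in the 5' and 3' partner genes.
#' @param transcripts_5p,transcripts_3p Transcript tables (rows of
#'   [readRefFlat()] output) for the two genes.
#' @return data.frame: `transcript_5p`, `transcript_3p`,
#'   `last_retained_exon_5p`, `intra_exonic_5p`, `first_retained_exon_3p`,
#'   `intra_exonic_3p`; attribute `skipped`.
#' @export
mapFusionJunction <- function(pos_5p, pos_3p, transcripts_5p, transcripts_3p) {
  side5 <- function(tx, pos) {
    ex <- exonsInTxOrder(tx)
    inside <- which(pos >= ex$start & pos <= ex$end)
    if (length(inside) > 0) return(c(exon = inside[1], intra = 1))
    upstream <- if (tx$strand == "-") ex$start > pos else ex$end < pos
    if (!any(upstream)) return(c(exon = NA, intra = 0))
    c(exon = max(which(upstream)), intra = 0)
  }
  side3 <- function(tx, pos) {
    ex <- exonsInTxOrder(tx)
    inside <- which(pos >= ex$start & pos <= ex$end)
    if (length(inside) > 0) return(c(exon = inside[1], intra = 1))
    downstream <- if (tx$strand == "-") ex$end < pos else ex$start > pos
    if (!any(downstream)) return(c(exon = NA, intra = 0))
    c(exon = min(which(downstream)), intra = 0)
  }
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(transcripts_5p))) {
    t5 <- transcripts_5p[i, ]
    if (pos_5p < t5$tx_start || pos_5p > t5$tx_end) {
      skipped <- c(skipped, paste0(t5$transcript_id, " (5')"))
      next
    }
    r5 <- side5(t5, pos_5p)
    for (j in seq_len(nrow(transcripts_3p))) {
      t3 <- transcripts_3p[j, ]
      if (pos_3p < t3$tx_start || pos_3p > t3$tx_end) {
        skipped <- c(skipped, paste0(t3$transcript_id, " (3')"))
        next
      }
      r3 <- side3(t3, pos_3p)
      rows[[paste(i, j)]] <- data.frame(
        transcript_5p = t5$transcript_id, transcript_3p = t3$transcript_id,
        last_retained_exon_5p = unname(r5["exon"]),
        intra_exonic_5p = r5["intra"] == 1,
        first_retained_exon_3p = unname(r3["exon"]),
        intra_exonic_3p = r3["intra"] == 1,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0) data.frame(
    transcript_5p = character(), transcript_3p = character(),
    last_retained_exon_5p = numeric(), intra_exonic_5p = logical(),
    first_retained_exon_3p = numeric(), intra_exonic_3p = logical(),
    stringsAsFactors = FALSE
  ) else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(skipped)
  out
}
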