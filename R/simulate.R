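#' Synthetic cohort configuration
#'
#' Assembles the configuration of the synthetic tumour-cohort generator.
#' The defaults emulate the structure of a 180-tumour prostate-cancer
#' cohort of 115 African, 61 European and 4 admixed patients on a toy
#' three-chromosome genome: per-tumour SV totals with a heavy right tail
#' (gamma-mixed Poisson, cohort mean about 100), per-tumour SV-type
#' mixtures drawn from an ancestry-specific Dirichlet with a planted
#' 2.5-fold African excess of duplication counts (1.6-fold in relative
#' frequency), fifteen planted hyper-SV tumours (five hyper-duplicated,
#' five hyper-deleted, five hyper-translocated), five planted breakpoint
#' hotspot bins, six planted gene-fusion samples covering all fusion
#' mechanisms at an emulated TMPRSS2/ERG-like locus (a 14-exon two-transcript
#' 5' partner and a ten-transcript 3' partner), planted biallelic
#' inactivation evidence, and a planted logistic dependence of one driver
#' gene's mutation probability on duplication burden.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_samples Cohort size.
#' @param ancestry_counts Named counts for African/European/Admixed
#'   (rescaled to `n_samples`).
#' @param chrom_sizes Named chromosome lengths of the toy genome.
#' @param n_genes Number of background genes in the annotation.
#' @param type_means Matrix (rows African/European/Admixed, columns the SV
#'   types) of per-tumour mean event counts.
#' @param dispersion_shape Gamma shape of the per-tumour activity factor
#'   (mean 1); `NULL` disables over-dispersion.
#' @param mixture_concentration Dirichlet concentration of per-tumour type
#'   mixtures; `NULL` uses the fixed ancestry mixture.
#' @param hyper_plants data.frame (`type`, `ancestry`) of hyper-SV plants.
#' @param hotspot_plants list(`n_bins`, `multiplier`) for planted hotspot
#'   bins.
#' @param fusion_plants data.frame (`mechanism`, `ancestry`) of fusion
#'   plants.
#' @param biallelic_plants data.frame (`gene`, `klass`) of biallelic
#'   inactivation plants (assigned to planted hyper samples).
#' @param assoc_plant list(`gene`, `svtype`, `measure`, `beta0`, `beta1`)
#'   for the planted burden-mutation dependence.
#' @param caller list of caller-emulation parameters: `jitter_max_a`,
#'   `jitter_max_b` (per-breakend reporting offsets), `dropout_a`,
#'   `dropout_b`, `false_rate`, `hc_flip`.
#' @param sv_size_meanlog,sv_size_sdlog Log-normal intra-chromosomal event
#'   size (bp).
#' @return List of class `sim_config`.
#' @export
simConfig <- function(seed = 1,
                      n_samples = 180,
                      ancestry_counts = c(African = 115, European = 61, Admixed = 4),
                      chrom_sizes = c(chr1 = 60e6, chr2 = 60e6, chr3 = 60e6),
                      n_genes = 120,
                      type_means = NULL,
                      dispersion_shape = 1.2,
                      mixture_concentration = 4,
                      hyper_plants = NULL,
                      hotspot_plants = list(n_bins = 5, multiplier = 10),
                      fusion_plants = NULL,
                      biallelic_plants = NULL,
                      assoc_plant = list(gene = "SPOP", svtype = "DUP",
                                         measure = "rel_freq",
                                         beta0 = -2.5, beta1 = 8),
                      caller = list(jitter_max_a = 0, jitter_max_b = 3,
                                    dropout_a = 0.05, dropout_b = 0.05,
                                    false_rate = 0.02, hc_flip = 0.02),
                      sv_size_meanlog = log(8e4),
                      sv_size_sdlog = 0.7) {
  if (is.null(type_means)) {
    type_means <- rbind(
      African  = c(DEL = 44, DUP = 24, INS = 0.1, INV = 24, TRA = 24.9),
      European = c(DEL = 33, DUP = 9.6, INS = 0.1, INV = 18, TRA = 14.3)
    )
    type_means <- rbind(type_means,
                        Admixed = colMeans(type_means))
  }
  if (is.null(hyper_plants)) {
    hyper_plants <- data.frame(
      type = rep(c("DUP", "DEL", "TRA"), each = 5),
      ancestry = c(rep("African", 5),
                   c(rep("African", 4), "European"),
                   c(rep("African", 3), rep("European", 2))),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(fusion_plants)) {
    fusion_plants <- data.frame(
      mechanism = c("single-deletion", "interstitial-retention",
                    "deletion-plus-overlapping-SVs", "inversion",
                    "duplication", "complex-multi-SV"),
      ancestry = c("European", "African", "European",
                   "European", "African", "African"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(biallelic_plants)) {
    biallelic_plants <- data.frame(
      gene = c(rep("BRCA2", 4), rep("CDK12", 4)),
      klass = c("Loss/Mutation", "Loss/Loss", "Loss/Break",
                "Mutation/Mutation", rep("Loss/Mutation", 4)),
      host = c(rep("hyper-deleted", 4), rep("hyper-duplicated", 4)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    seed = seed, n_samples = n_samples, ancestry_counts = ancestry_counts,
    chrom_sizes = chrom_sizes, n_genes = n_genes, type_means = type_means,
    dispersion_shape = dispersion_shape,
    mixture_concentration = mixture_concentration,
    hyper_plants = hyper_plants, hotspot_plants = hotspot_plants,
    fusion_plants = fusion_plants, biallelic_plants = biallelic_plants,
    assoc_plant = assoc_plant, caller = caller,
    sv_size_meanlog = sv_size_meanlog, sv_size_sdlog = sv_size_sdlog
  ), class = "sim_config")
}

## region kept free of background breakends so planted fusion mechanisms
## stay identifiable (the emulated TMPRSS2/ERG-like locus on chr3)
FUSION_LOCUS <- list(chrom = "chr3", start = 29.5e6, end = 33.5e6)

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

## ---- annotation -----------------------------------------------------------

## Emulated fusion partner genes: a two-transcript 14-exon 5' partner
## ("TMPRSS2") and a ten-transcript 3' partner ("ERG") sharing their first
## four exon regions, both on the minus strand of chr3.
fusionPartnerTranscripts <- function() {
  rows <- list()
  ## ERG-like: 10 transcripts, 5..14 exons, shared exons 1-4
  shared_erg <- data.frame(
    start = c(30298001, 30294001, 30290001, 30286001),
    end = c(30300000, 30295000, 30291000, 30287000)
  )
  for (t in 1:10) {
    n_extra <- t  # 5..14 exons in total
    extra_start <- 30286001 - 4000 * seq_len(n_extra)
    ex <- rbind(shared_erg,
                data.frame(start = extra_start, end = extra_start + 999))
    ex <- ex[order(ex$start), ]
    rows[[paste0("ERG", t)]] <- data.frame(
      gene_symbol = "ERG", transcript_id = sprintf("ERG.t%02d", t),
      chrom = "chr3", strand = "-",
      tx_start = min(ex$start), tx_end = 30300000,
      exon_count = nrow(ex),
      exon_starts = I(list(ex$start)), exon_ends = I(list(ex$end)),
      stringsAsFactors = FALSE
    )
  }
  ## TMPRSS2-like: 2 transcripts with 14 exons each, shared exons 1-2
  for (t in 1:2) {
    off <- (t - 1) * 200
    e12 <- data.frame(start = c(33058001, 33054001),
                      end = c(33060000, 33055000))
    rest_start <- 33054001 - 3500 * seq_len(12) - off
    ex <- rbind(e12, data.frame(start = rest_start, end = rest_start + 799))
    ex <- ex[order(ex$start), ]
    rows[[paste0("TMPRSS2", t)]] <- data.frame(
      gene_symbol = "TMPRSS2", transcript_id = sprintf("TMPRSS2.t%02d", t),
      chrom = "chr3", strand = "-",
      tx_start = min(ex$start), tx_end = 33060000,
      exon_count = nrow(ex),
      exon_starts = I(list(ex$start)), exon_ends = I(list(ex$end)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

## fixed single-transcript driver genes used by the evidence plants
driverGeneTranscripts <- function() {
  mk <- function(sym, chrom, strand, start, n_exons, exon_len = 300,
                 gap = 5000) {
    s <- start + (seq_len(n_exons) - 1) * (exon_len + gap)
    data.frame(
      gene_symbol = sym, transcript_id = paste0(sym, ".t01"),
      chrom = chrom, strand = strand,
      tx_start = s[1], tx_end = s[n_exons] + exon_len - 1,
      exon_count = n_exons,
      exon_starts = I(list(s)), exon_ends = I(list(s + exon_len - 1)),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    mk("BRCA2", "chr1", "+", 10e6, 10),
    mk("CDK12", "chr1", "+", 20e6, 8),
    mk("SPOP", "chr2", "+", 15e6, 6),
    mk("MYC", "chr2", "+", 40e6, 5)
  )
}

simulateAnnotation <- function(config) {
  fixed <- rbind(fusionPartnerTranscripts(), driverGeneTranscripts())
  n <- config$n_genes
  sizes <- config$chrom_sizes
  rows <- list()
  for (i in seq_len(n)) {
    repeat {
      chrom <- sample(names(sizes), 1, prob = sizes)
      len <- round(rlnorm(1, log(5e4), 0.6))
      start <- floor(runif(1, 1, sizes[[chrom]] - len - 1))
      in_locus <- chrom == FUSION_LOCUS$chrom &&
        start + len >= FUSION_LOCUS$start && start <= FUSION_LOCUS$end
      if (!in_locus) break
    }
    n_ex <- sample(2:12, 1)
    bnd <- sort(c(start, start + len,
                  floor(runif(2 * (n_ex - 1), start + 1, start + len - 1))))
    es <- bnd[seq(1, length(bnd), by = 2)]
    ee <- bnd[seq(2, length(bnd), by = 2)]
    keep <- ee > es
    es <- es[keep]; ee <- ee[keep]
    if (length(es) == 0) { es <- start; ee <- start + len }
    rows[[i]] <- data.frame(
      gene_symbol = sprintf("GENE%03d", i),
      transcript_id = sprintf("GENE%03d.t01", i),
      chrom = chrom, strand = sample(c("+", "-"), 1),
      tx_start = es[1], tx_end = ee[length(ee)],
      exon_count = length(es),
      exon_starts = I(list(es)), exon_ends = I(list(ee)),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(fixed, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

## ---- breakend position sampling -------------------------------------------

## per-1Mb-bin sampling weights with planted hotspot multipliers and the
## fusion locus zeroed out
binWeightTable <- function(chrom_sizes, planted_bins = NULL,
                           multiplier = 1, width = 1e6) {
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- ceiling(chrom_sizes[[ch]] / width)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * width + 1,
               end = pmin(seq_len(n) * width, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bins$weight <- (bins$end - bins$start + 1) / width
  excl <- bins$chrom == FUSION_LOCUS$chrom &
    bins$end >= FUSION_LOCUS$start & bins$start <= FUSION_LOCUS$end
  bins$weight[excl] <- 0
  if (!is.null(planted_bins) && nrow(planted_bins) > 0) {
    key <- paste(bins$chrom, bins$start)
    bins$weight[key %in% paste(planted_bins$chrom, planted_bins$start)] <-
      multiplier
  }
  bins
}

samplePositions <- function(n, wt) {
  if (n == 0) return(data.frame(chrom = character(), pos = numeric()))
  i <- sample.int(nrow(wt), n, replace = TRUE, prob = wt$weight)
  data.frame(chrom = wt$chrom[i],
             pos = floor(runif(n, wt$start[i], wt$end[i] + 1)),
             stringsAsFactors = FALSE)
}

## ---- truth SV generation --------------------------------------------------

simulateTypeCounts <- function(config, ancestry) {
  n <- length(ancestry)
  act <- if (is.null(config$dispersion_shape)) rep(1, n) else
    rgamma(n, shape = config$dispersion_shape,
           rate = config$dispersion_shape)
  means <- config$type_means[ancestry, , drop = FALSE]
  counts <- matrix(0L, n, length(SV_TYPES),
                   dimnames = list(NULL, SV_TYPES))
  for (i in seq_len(n)) {
    m <- means[i, SV_TYPES]
    total <- rpois(1, act[i] * sum(m))
    w <- if (is.null(config$mixture_concentration)) m / sum(m) else
      rdirichlet1(config$mixture_concentration * length(m) * m / sum(m))
    if (total > 0) counts[i, ] <- drop(stats::rmultinom(1, total, w))
  }
  counts
}

## counts for a planted hyper-SV sample: fixed total, dominant fraction
hyperCounts <- function(type, ancestry, config) {
  total <- round(runif(1, 150, 400))
  dom <- round(total * runif(1, 0.55, 0.8))
  rest <- total - dom
  m <- config$type_means[ancestry, SV_TYPES]
  m[type] <- 0
  counts <- setNames(integer(length(SV_TYPES)), SV_TYPES)
  if (rest > 0) counts <- counts + drop(stats::rmultinom(1, rest, m / sum(m)))
  counts[type] <- counts[type] + dom
  counts
}

## realise SV events for one sample given its per-type counts
eventsForCounts <- function(sample_id, counts, wt, config) {
  sizes <- config$chrom_sizes
  rows <- list()
  mkrow <- function(type, c1, p1, s1, c2, p2, s2, ins = NA_real_) {
    data.frame(sample_id = sample_id, caller_id = "truth", svtype = type,
               chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2,
               high_confidence = TRUE, qual = round(runif(1, 100, 999)),
               insert_len = ins, stringsAsFactors = FALSE)
  }
  for (type in c("DEL", "DUP", "INV")) {
    k <- counts[[type]]
    if (k == 0) next
    p <- samplePositions(k, wt)
    size <- pmax(1000, round(rlnorm(k, config$sv_size_meanlog,
                                    config$sv_size_sdlog)))
    pos1 <- p$pos
    lim <- sizes[p$chrom]
    over <- pos1 + size > lim
    pos1[over] <- pmax(1, lim[over] - size[over])
    pos2 <- pos1 + size
    st <- switch(type,
                 DEL = cbind("+", "-"),
                 DUP = cbind("-", "+"),
                 INV = NULL)
    if (type == "INV") {
      ## typed caller INV records carry no side information; keep the
      ## canonical (+,+) junction so both caller views agree with truth
      st <- cbind(rep("+", k), rep("+", k))
    } else {
      st <- st[rep(1, k), , drop = FALSE]
    }
    rows[[type]] <- mkrow(type, p$chrom, pos1, st[, 1],
                          p$chrom, pos2, st[, 2])
  }
  if (counts[["TRA"]] > 0) {
    k <- counts[["TRA"]]
    p1 <- samplePositions(k, wt)
    p2 <- samplePositions(2 * k, wt)  # draw extra to find other-chromosome mates
    rows$TRA <- do.call(rbind, lapply(seq_len(k), function(i) {
      j <- which(p2$chrom != p1$chrom[i])[1]
      if (is.na(j)) {
        other <- setdiff(names(sizes), p1$chrom[i])[1]
        p2j <- data.frame(chrom = other,
                          pos = floor(runif(1, 1, sizes[[other]])))
      } else {
        p2j <- p2[j, ]
        p2 <<- p2[-j, , drop = FALSE]
      }
      mkrow("TRA", p1$chrom[i], p1$pos[i], sample(c("+", "-"), 1),
            p2j$chrom, p2j$pos, sample(c("+", "-"), 1))
    }))
  }
  if (counts[["INS"]] > 0) {
    k <- counts[["INS"]]
    p <- samplePositions(k, wt)
    rows$INS <- mkrow("INS", p$chrom, p$pos, "+",
                      NA_character_, NA_real_, NA_character_,
                      ins = round(runif(k, 50, 500)))
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

## ---- fusion plants --------------------------------------------------------

## genomic interval of intron k (transcript orientation) common to all
## transcripts of a gene
commonIntron <- function(transcripts, k) {
  ivs <- lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- exonsInTxOrder(transcripts[i, ])
    if (k + 1 > nrow(ex)) return(NULL)
    if (transcripts$strand[i] == "-") {
      c(ex$end[k + 1] + 1, ex$start[k] - 1)
    } else {
      c(ex$end[k] + 1, ex$start[k + 1] - 1)
    }
  })
  ivs <- ivs[!vapply(ivs, is.null, logical(1))]
  lo <- max(vapply(ivs, `[`, numeric(1), 1))
  hi <- min(vapply(ivs, `[`, numeric(1), 2))
  if (lo > hi) stopf("no common intron %d", k)
  c(lo, hi)
}

#' Plant a gene fusion with a chosen mechanism
#'
#' Emits the minimal truth SV set realising one of the six fusion
#' mechanisms at the emulated TMPRSS2/ERG-like locus: a single linking
#' deletion; a deletion plus two matching translocations whose ends flank
#' the deleted interval (retention of the interstitial segment); a deletion
#' with additional overlapping SVs; a linking inversion; a linking
#' duplication; or a complex multi-SV constellation (seven SVs). Junction
#' positions are drawn from the configured target introns (defaults: intron
#' 1 or 2 of the 5' partner, intron 2 or 3 of the 3' partner).
#'
#' @param sample_id Sample receiving the fusion.
#' @param mechanism One of the six mechanism labels.
#' @param transcripts Transcript table containing the two partner genes.
#' @param gene_5p,gene_3p Partner gene symbols (defaults TMPRSS2 / ERG).
#' @param intron_5p Target intron of the 5' partner (default drawn from
#'   1:2).
#' @param intron_3p Target intron of the 3' partner (default drawn from
#'   2:3).
#' @param other_chrom Chromosome receiving translocation far ends.
#' @return list(`calls` = truth SV rows, `truth` = one-row data.frame with
#'   the planted mechanism and junction annotation).
#' @export
plantFusion <- function(sample_id, mechanism, transcripts,
                        gene_5p = "TMPRSS2", gene_3p = "ERG",
                        intron_5p = NULL, intron_3p = NULL,
                        other_chrom = "chr1") {
  mechs <- c("single-deletion", "interstitial-retention",
             "deletion-plus-overlapping-SVs", "inversion", "duplication",
             "complex-multi-SV")
  if (!mechanism %in% mechs) stopf("unknown fusion mechanism '%s'", mechanism)
  tx5 <- transcripts[transcripts$gene_symbol == gene_5p, , drop = FALSE]
  tx3 <- transcripts[transcripts$gene_symbol == gene_3p, , drop = FALSE]
  if (is.null(intron_5p)) intron_5p <- sample(1:2, 1)
  if (is.null(intron_3p)) intron_3p <- sample(2:3, 1)
  iv5 <- commonIntron(tx5, intron_5p)
  iv3 <- commonIntron(tx3, intron_3p)
  pos_5p <- floor(mean(iv5))
  pos_3p <- floor(mean(iv3))
  ## on the toy locus the 3' partner sits at lower coordinates
  lo <- min(pos_5p, pos_3p); hi <- max(pos_5p, pos_3p)
  chrom <- tx5$chrom[1]
  mk <- function(type, c1, p1, s1, c2, p2, s2) {
    data.frame(sample_id = sample_id, caller_id = "truth", svtype = type,
               chrom1 = c1, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2,
               high_confidence = TRUE, qual = round(runif(1, 200, 999)),
               insert_len = NA_real_, stringsAsFactors = FALSE)
  }
  del <- mk("DEL", chrom, lo, "+", chrom, hi, "-")
  inter <- c(30400000, 32800000)  # between the two genes, outside both spans
  calls <- switch(
    mechanism,
    "single-deletion" = del,
    "interstitial-retention" = rbind(
      del,
      mk("TRA", chrom, lo + 150, "-", other_chrom,
         floor(runif(1, 1e6, 50e6)), "+"),
      mk("TRA", chrom, hi - 150, "+", other_chrom,
         floor(runif(1, 1e6, 50e6)), "-")
    ),
    "deletion-plus-overlapping-SVs" = rbind(
      del,
      mk("INV", chrom, inter[1], "+", chrom, inter[1] + 3e5, "+"),
      mk("DUP", chrom, inter[2] - 4e5, "-", chrom, inter[2], "+")
    ),
    "inversion" = mk("INV", chrom, lo, "+", chrom, hi, "+"),
    "duplication" = mk("DUP", chrom, lo, "-", chrom, hi, "+"),
    "complex-multi-SV" = rbind(
      mk("INV", chrom, lo, "+", chrom, hi, "+"),
      mk("TRA", chrom, inter[1] + 1e5, "+", other_chrom,
         floor(runif(1, 1e6, 50e6)), "+"),
      mk("TRA", chrom, inter[2] - 1e5, "-", other_chrom,
         floor(runif(1, 1e6, 50e6)), "-"),
      mk("INV", chrom, inter[1] + 2e5, "-", chrom, inter[1] + 5e5, "-"),
      mk("INV", chrom, inter[2] - 6e5, "+", chrom, inter[2] - 2e5, "+"),
      mk("DUP", chrom, inter[1] + 6e5, "-", chrom, inter[1] + 9e5, "+"),
      mk("DEL", chrom, inter[2] - 9e5, "+", chrom, inter[2] - 7e5, "-")
    )
  )
  truth <- data.frame(
    sample_id = sample_id, mechanism = mechanism,
    gene_5p = gene_5p, gene_3p = gene_3p,
    pos_5p = pos_5p, pos_3p = pos_3p,
    intron_5p = intron_5p, intron_3p = intron_3p,
    n_svs = nrow(calls), stringsAsFactors = FALSE
  )
  list(calls = calls, truth = truth)
}

## ---- evidence plants ------------------------------------------------------

## evidence rows realising a planted biallelic class; may add truth SVs
plantBiallelic <- function(sample_id, gene, klass, transcripts) {
  tx <- transcripts[transcripts$gene_symbol == gene, , drop = FALSE][1, ]
  ex1 <- c(tx$exon_starts[[1]][1], tx$exon_ends[[1]][1])
  ex2 <- c(tx$exon_starts[[1]][2], tx$exon_ends[[1]][2])
  chrom <- tx$chrom
  mk <- function(type, p1, s1, c2, p2, s2) {
    data.frame(sample_id = sample_id, caller_id = "truth", svtype = type,
               chrom1 = chrom, pos1 = p1, strand1 = s1,
               chrom2 = c2, pos2 = p2, strand2 = s2,
               high_confidence = TRUE, qual = round(runif(1, 200, 999)),
               insert_len = NA_real_, stringsAsFactors = FALSE)
  }
  snv <- function(origin, effect) {
    data.frame(sample_id = sample_id, gene = gene, origin = origin,
               klass = "SNV", effect = effect, stringsAsFactors = FALSE)
  }
  out <- list(cn_value = 0, allele_a = 1, allele_b = 1,
              svs = NULL, snvs = NULL)
  if (klass == "Loss/Mutation") {
    out$cn_value <- -0.5
    out$allele_a <- 0
    out$snvs <- snv("somatic", "nonsynonymous")
  } else if (klass == "Loss/Loss") {
    out$cn_value <- -1.8
    out$allele_a <- 0; out$allele_b <- 0
    out$svs <- rbind(
      mk("DEL", ex1[1] - 500, "+", chrom, ex1[2] + 500, "-"),
      mk("DEL", ex2[1] - 400, "+", chrom, ex2[2] + 400, "-")
    )
  } else if (klass == "Loss/Break") {
    out$cn_value <- -0.5
    out$allele_a <- 0
    out$svs <- mk("TRA", floor(mean(ex2)), "+", "chr3",
                  floor(runif(1, 40e6, 55e6)), "-")
  } else if (klass == "Mutation/Mutation") {
    out$snvs <- rbind(snv("germline", "nonsynonymous"),
                      snv("somatic", "nonsynonymous"))
  } else {
    stopf("unknown biallelic class '%s'", klass)
  }
  out
}

## ---- caller emulation -----------------------------------------------------

#' Emulate two caller views of a truth SV set
#'
#' Produces two jittered, censored views of a truth call set: caller A
#' (typed dialect) and caller B (breakend-only dialect). Per caller, each
#' truth event is dropped with the configured dropout probability, each
#' breakend position is offset by an integer drawn uniformly from
#' \[-jitter_max, +jitter_max\], the high-confidence flag is flipped off
#' with probability `hc_flip`, and `false_rate` times the truth count of
#' private false calls (uniform positions, random types) are added, flagged
#' by `truth_id = NA`.
#'
#' @param truth [SvCallSet-class] of truth events (any number of samples).
#' @param config [simConfig()] (fields under `caller` are used).
#' @return list(`calls_a`, `calls_b`) of `SvCallSet`s with a `truth_id`
#'   provenance column.
#' @export
emulateCallers <- function(truth, config = simConfig()) {
  df <- svCalls(truth)
  df$truth_id <- seq_len(nrow(df))
  cfg <- config$caller
  view <- function(caller_id, jitter_max, dropout) {
    keep <- runif(nrow(df)) >= dropout
    v <- df[keep, , drop = FALSE]
    if (nrow(v) > 0 && jitter_max > 0) {
      j1 <- sample(-jitter_max:jitter_max, nrow(v), replace = TRUE)
      j2 <- sample(-jitter_max:jitter_max, nrow(v), replace = TRUE)
      v$pos1 <- pmax(1, v$pos1 + j1)
      v$pos2 <- ifelse(is.na(v$pos2), NA, pmax(1, v$pos2 + j2))
      ## keep two-breakend events valid
      bad <- !is.na(v$pos2) & v$chrom1 == v$chrom2 & v$pos1 >= v$pos2
      v$pos2[bad] <- v$pos1[bad] + 1
    }
    if (nrow(v) > 0) {
      flip <- runif(nrow(v)) < cfg$hc_flip
      v$high_confidence <- v$high_confidence & !flip
    }
    n_false <- round(cfg$false_rate * nrow(df))
    if (n_false > 0) {
      wt <- binWeightTable(config$chrom_sizes)
      samples <- sample(unique(df$sample_id), n_false, replace = TRUE)
      fake <- do.call(rbind, lapply(seq_len(n_false), function(i) {
        type <- sample(c("DEL", "DUP", "INV", "TRA"), 1)
        cnt <- setNames(as.integer(SV_TYPES == type), SV_TYPES)
        eventsForCounts(samples[i], as.list(cnt), wt, config)
      }))
      fake$truth_id <- NA_integer_
      v <- rbind(v, fake)
    }
    v$caller_id <- caller_id
    SvCallSet(v)
  }
  list(calls_a = view("callerA", cfg$jitter_max_a, cfg$dropout_a),
       calls_b = view("callerB", cfg$jitter_max_b, cfg$dropout_b))
}

## ---- main generator -------------------------------------------------------

#' Simulate a synthetic tumour cohort
#'
#' Generates a complete truth bundle under a [simConfig()]: cohort
#' metadata, gene annotation, truth SV calls with planted hyper-SV tumours,
#' hotspot bins and fusion loci, two emulated caller views, gene-level
#' copy-number values with per-sample high-level thresholds, small-variant
#' and allele-specific CN evidence realising the planted biallelic
#' inactivation classes, and the truth tables for every stage. The bundle
#' is deterministic given `config$seed`.
#'
#' @param config A [simConfig()].
#' @return List of class `truth_bundle` with elements `config`, `metadata`,
#'   `transcripts`, `genes`, `chrom_sizes`, `truth_svs`, `calls_a`,
#'   `calls_b`, `truth_counts`, `truth_subtypes`, `truth_hotspots`,
#'   `truth_fusions`, `truth_biallelic`, `cn`, `cn_thresholds`, `allelic`,
#'   `small_variants`, `driver_genes`.
#' @export
simulateCohort <- function(config = simConfig()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(config$seed)

  ## metadata -----------------------------------------------------------
  ac <- round(config$ancestry_counts / sum(config$ancestry_counts) *
                config$n_samples)
  ac[1] <- config$n_samples - sum(ac[-1])
  ancestry <- rep(names(ac), ac)
  n <- length(ancestry)
  sample_id <- sprintf("S%04d", seq_len(n))
  hr_prob <- c(African = 81 / 115, European = 53 / 61, Admixed = 1)
  risk <- ifelse(runif(n) < hr_prob[ancestry], "HRPCa",
                 sample(c("IRPCa", "LRPCa"), n, replace = TRUE))
  metadata <- data.frame(sample_id = sample_id, ancestry = ancestry,
                         risk_group = risk, stringsAsFactors = FALSE)

  ## annotation ----------------------------------------------------------
  transcripts <- simulateAnnotation(config)
  genes <- geneUnionIntervals(transcripts)
  driver_genes <- c("BRCA2", "CDK12", "SPOP", "MYC",
                    sprintf("GENE%03d", seq_len(min(26, config$n_genes))))

  ## hotspot plants ------------------------------------------------------
  wt0 <- binWeightTable(config$chrom_sizes)
  eligible <- which(wt0$weight > 0)
  hp <- config$hotspot_plants
  planted_idx <- sort(sample(eligible, hp$n_bins))
  truth_hotspots <- wt0[planted_idx, c("chrom", "start", "end")]
  rownames(truth_hotspots) <- NULL
  wt <- binWeightTable(config$chrom_sizes, truth_hotspots, hp$multiplier)

  ## per-sample SV counts (with hyper plants) ----------------------------
  counts <- simulateTypeCounts(config, ancestry)
  hyper <- config$hyper_plants
  hyper$sample_id <- rep(NA_character_, nrow(hyper))
  used <- character()
  for (i in seq_len(nrow(hyper))) {
    cand <- setdiff(sample_id[ancestry == hyper$ancestry[i]], used)
    hyper$sample_id[i] <- cand[1]
    used <- c(used, cand[1])
    counts[match(cand[1], sample_id), ] <-
      hyperCounts(hyper$type[i], hyper$ancestry[i], config)
  }

  ## truth SV events -----------------------------------------------------
  sv_rows <- lapply(seq_len(n), function(i) {
    eventsForCounts(sample_id[i], as.list(counts[i, ]), wt, config)
  })

  ## fusion plants (samples without a hyper plant) -----------------------
  fp <- config$fusion_plants
  truth_fusions <- NULL
  if (!is.null(fp) && nrow(fp) > 0) {
    fp$sample_id <- NA_character_
    for (i in seq_len(nrow(fp))) {
      cand <- setdiff(sample_id[ancestry == fp$ancestry[i]], used)
      fp$sample_id[i] <- cand[1]
      used <- c(used, cand[1])
      pl <- plantFusion(cand[1], fp$mechanism[i], transcripts)
      sv_rows[[length(sv_rows) + 1]] <- pl$calls
      truth_fusions <- rbind(truth_fusions, pl$truth)
    }
  }

  ## biallelic plants (on planted hyper samples) -------------------------
  bp <- config$biallelic_plants
  cn_over <- list(); snv_rows <- list(); allelic_over <- list()
  truth_biallelic <- NULL
  if (!is.null(bp) && nrow(bp) > 0) {
    for (i in seq_len(nrow(bp))) {
      host_type <- switch(bp$host[i] %||% "hyper-deleted",
                          "hyper-deleted" = "DEL",
                          "hyper-duplicated" = "DUP",
                          "hyper-translocated" = "TRA")
      hosts <- hyper$sample_id[hyper$type == host_type]
      prev <- if (is.null(truth_biallelic)) character() else
        truth_biallelic$sample_id[truth_biallelic$gene == bp$gene[i]]
      s <- setdiff(hosts, prev)[1]
      if (is.na(s)) next
      pl <- plantBiallelic(s, bp$gene[i], bp$klass[i], transcripts)
      if (!is.null(pl$svs)) sv_rows[[length(sv_rows) + 1]] <- pl$svs
      if (!is.null(pl$snvs)) snv_rows[[length(snv_rows) + 1]] <- pl$snvs
      cn_over[[length(cn_over) + 1]] <-
        data.frame(sample_id = s, gene = bp$gene[i], value = pl$cn_value,
                   stringsAsFactors = FALSE)
      allelic_over[[length(allelic_over) + 1]] <-
        data.frame(sample_id = s, gene = bp$gene[i],
                   allele_a = pl$allele_a, allele_b = pl$allele_b,
                   stringsAsFactors = FALSE)
      truth_biallelic <- rbind(truth_biallelic, data.frame(
        sample_id = s, gene = bp$gene[i], klass = bp$klass[i],
        stringsAsFactors = FALSE))
    }
  }

  sv_rows <- sv_rows[!vapply(sv_rows, is.null, logical(1))]
  truth_svs <- SvCallSet(do.call(rbind, sv_rows))

  ## recompute realised per-sample counts (plants added events)
  truth_counts <- svSpectrum(truth_svs, samples = sample_id)
  truth_subtypes <- classifyHyperSv(truth_counts)

  ## caller views --------------------------------------------------------
  views <- emulateCallers(truth_svs, config)

  ## copy-number evidence ------------------------------------------------
  cn_thresholds <- data.frame(
    sample_id = sample_id,
    high_gain = runif(n, 0.9, 1.3),
    high_loss = -runif(n, 0.9, 1.3),
    stringsAsFactors = FALSE
  )
  cn <- expand.grid(sample_id = sample_id, gene = driver_genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cn$value <- rnorm(nrow(cn), 0, 0.03)
  ## MYC gain in four of the hyper-duplicated tumours
  myc_hosts <- utils::head(hyper$sample_id[hyper$type == "DUP"], 4)
  sel <- cn$gene == "MYC" & cn$sample_id %in% myc_hosts
  cn$value[sel] <- cn_thresholds$high_gain[
    match(cn$sample_id[sel], cn_thresholds$sample_id)] + 0.5
  for (ov in cn_over) {
    cn$value[cn$sample_id == ov$sample_id & cn$gene == ov$gene] <- ov$value
  }

  allelic <- expand.grid(sample_id = sample_id, gene = driver_genes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  allelic$allele_a <- 1L; allelic$allele_b <- 1L
  for (ov in allelic_over) {
    i <- allelic$sample_id == ov$sample_id & allelic$gene == ov$gene
    allelic$allele_a[i] <- ov$allele_a
    allelic$allele_b[i] <- ov$allele_b
  }

  ## small variants: background plus the planted burden association ------
  bg <- expand.grid(sample_id = sample_id, gene = driver_genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p_som <- rep(0.03, nrow(bg))
  ap <- config$assoc_plant
  if (!is.null(ap)) {
    xcol <- if (ap$measure == "count") paste0("n_", ap$svtype) else
      paste0("rf_", ap$svtype)
    x <- truth_counts[[xcol]][match(bg$sample_id, truth_counts$sample_id)]
    p_som[bg$gene == ap$gene] <-
      plogis(ap$beta0 + ap$beta1 * x[bg$gene == ap$gene])
  }
  ## planted biallelic cells own their evidence: no background SNVs there
  if (!is.null(truth_biallelic)) {
    planted_cell <- paste(bg$sample_id, bg$gene) %in%
      paste(truth_biallelic$sample_id, truth_biallelic$gene)
    p_som[planted_cell] <- 0
  }
  som <- bg[runif(nrow(bg)) < p_som, , drop = FALSE]
  if (nrow(som) > 0) {
    som$origin <- "somatic"; som$klass <- "SNV"; som$effect <- "nonsynonymous"
  }
  nc <- bg[runif(nrow(bg)) < 0.03, , drop = FALSE]
  if (nrow(nc) > 0) {
    nc$origin <- "somatic"; nc$klass <- "SNV"; nc$effect <- "noncoding"
  }
  small_variants <- rbind(
    if (nrow(som) > 0) som else NULL,
    if (nrow(nc) > 0) nc else NULL,
    if (length(snv_rows) > 0) do.call(rbind, snv_rows) else NULL
  )
  if (is.null(small_variants)) {
    small_variants <- data.frame(sample_id = character(), gene = character(),
                                 origin = character(), klass = character(),
                                 effect = character(), stringsAsFactors = FALSE)
  }
  small_variants <- unique(small_variants)
  rownames(small_variants) <- NULL

  structure(list(
    config = config, metadata = metadata, transcripts = transcripts,
    genes = genes, chrom_sizes = config$chrom_sizes,
    truth_svs = truth_svs, calls_a = views$calls_a, calls_b = views$calls_b,
    truth_counts = truth_counts, truth_subtypes = truth_subtypes,
    truth_hotspots = truth_hotspots, truth_fusions = truth_fusions,
    truth_biallelic = truth_biallelic,
    hyper_plants = hyper,
    cn = cn, cn_thresholds = cn_thresholds, allelic = allelic,
    small_variants = small_variants, driver_genes = driver_genes
  ), class = "truth_bundle")
}

#' Simulate a burden-association cohort
#'
#' Focused generator for power and calibration studies of
#' [testSvBurdenAssociation()]: per-tumour spectra with a duplication
#' relative frequency drawn from a right-skewed Beta(0.8, 2) (emulating the
#' wide duplication spread of real tumour cohorts, including rare
#' duplication-dominated genomes), totals from a heavy-tailed
#' gamma-Poisson, and a mutation indicator for one gene following
#' `P(mutated) = plogis(beta0 + beta1 * x)` where `x` is the chosen burden
#' measure (`NULL` beta coefficients give the null model, mutation
#' probability `null_p` independent of burden).
#'
#' @param n Cohort size.
#' @param beta0,beta1 Logistic coefficients of the planted dependence;
#'   `beta1 = 0` or `NULL` simulates the null.
#' @param gene Gene name for the mutation indicator.
#' @param measure `"rel_freq"` (default) or `"count"`: which duplication
#'   burden drives mutation probability.
#' @param null_p Mutation probability under the null (`beta1 = NULL`).
#' @param total_mean,total_shape Gamma-Poisson total SV count parameters.
#' @return list(`spectra`, `mutated` one-column logical matrix).
#' @export
simulateBurdenCohort <- function(n = 200, beta0 = -2, beta1 = 3,
                                 gene = "G1", measure = "rel_freq",
                                 null_p = 0.2,
                                 total_mean = 100, total_shape = 1.2) {
  act <- rgamma(n, shape = total_shape, rate = total_shape)
  total <- pmax(1, rpois(n, act * total_mean))
  w_dup <- stats::rbeta(n, 0.8, 2)
  base <- c(DEL = 0.45, INS = 0.01, INV = 0.3, TRA = 0.24)
  counts <- t(vapply(seq_len(n), function(i) {
    w <- c(DUP = w_dup[i], base * (1 - w_dup[i]))
    drop(stats::rmultinom(1, total[i], w[SV_TYPES]))
  }, numeric(length(SV_TYPES))))
  colnames(counts) <- SV_TYPES
  spectra <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
  for (t in SV_TYPES) spectra[[paste0("n_", t)]] <- counts[, t]
  spectra$total <- rowSums(counts)
  for (t in SV_TYPES) spectra[[paste0("rf_", t)]] <-
    counts[, t] / spectra$total
  x <- if (measure == "count") spectra$n_DUP else spectra$rf_DUP
  p <- if (is.null(beta1)) rep(null_p, n) else plogis(beta0 + beta1 * x)
  mutated <- matrix(runif(n) < p, ncol = 1,
                    dimnames = list(spectra$sample_id, gene))
  list(spectra = spectra, mutated = mutated)
}

#' Write a truth bundle to disk
#'
#' Materialises a [simulateCohort()] bundle in the file formats the
#' pipeline consumes: per-sample VCFs for the two caller views
#' (`callerA/<sample>.vcf` typed, `callerB/<sample>.vcf` breakend-only),
#' `refflat.txt`, `sizes.tsv`, `cohort.tsv`, `cn.tsv`, `thr.tsv`,
#' `snv.tsv`, `allelic.tsv`, `drivers.txt`, and the truth tables under
#' `truth/`.
#'
#' @param bundle A `truth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTruthBundle <- function(bundle, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "callerA"), showWarnings = FALSE)
  dir.create(file.path(dir, "callerB"), showWarnings = FALSE)
  wtsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(bundle$metadata, "cohort.tsv")
  writeRefFlat(bundle$transcripts, file.path(dir, "refflat.txt"))
  writeLines(paste(names(bundle$chrom_sizes),
                   format(bundle$chrom_sizes, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             file.path(dir, "sizes.tsv"))
  wtsv(bundle$cn, "cn.tsv")
  wtsv(bundle$cn_thresholds, "thr.tsv")
  wtsv(bundle$small_variants, "snv.tsv")
  wtsv(bundle$allelic, "allelic.tsv")
  writeLines(bundle$driver_genes, file.path(dir, "drivers.txt"))
  writeSvTable(bundle$truth_svs, file.path(dir, "truth", "svs.tsv"))
  wtsv(bundle$truth_counts, "truth/spectra.tsv")
  wtsv(bundle$truth_subtypes, "truth/subtypes.tsv")
  wtsv(bundle$truth_hotspots, "truth/hotspots.tsv")
  if (!is.null(bundle$truth_fusions)) wtsv(bundle$truth_fusions, "truth/fusions.tsv")
  if (!is.null(bundle$truth_biallelic)) wtsv(bundle$truth_biallelic, "truth/biallelic.tsv")
  for (s in sampleIds(bundle$calls_a)) {
    writeSvVcf(SvCallSet(sampleCalls(bundle$calls_a, s)),
               file.path(dir, "callerA", paste0(s, ".vcf")), "typed")
  }
  for (s in sampleIds(bundle$calls_b)) {
    writeSvVcf(SvCallSet(sampleCalls(bundle$calls_b, s)),
               file.path(dir, "callerB", paste0(s, ".vcf")), "bnd-only")
  }
  invisible(dir)
}
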