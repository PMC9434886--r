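fusionGenes <- function() suppressWarnings(geneUnionIntervals(fusionTranscripts()))

test_that("fusions require two breakends in two different genes", {
  genes <- fusionGenes()
  ## translocation with ends in the two genes
  tra <- makeCalls("TRA", "chr3", 30292500, "+",
                   chrom2 = "chr4", pos2 = 5e6, strand2 = "-")
  expect_equal(nrow(callFusions(tra, genes)), 0)  # one end intergenic
  del <- makeCalls("DEL", "chr3", 30292500, "+", pos2 = 33056500,
                   strand2 = "-")
  f <- callFusions(del, genes)
  expect_equal(nrow(f), 1)
  expect_setequal(c(f$gene_a, f$gene_b), c("ERG", "TMPRSS2"))
  ## both ends inside one gene: not a fusion
  intra <- makeCalls("DEL", "chr3", 30287500, "+", pos2 = 30292500,
                     strand2 = "-")
  expect_equal(nrow(callFusions(intra, genes)), 0)
  ## single-breakend insertions cannot qualify
  ins <- makeCalls("INS", "chr3", 30292500, "+", insert_len = 100)
  expect_equal(nrow(callFusions(ins, genes)), 0)
})

test_that("a breakend in overlapping genes yields one flagged fusion per pair", {
  tx <- rbind(fusionTranscripts(), data.frame(
    gene_symbol = "OVL", transcript_id = "ovl1", chrom = "chr3",
    strand = "+", tx_start = 30.25e6, tx_end = 30.35e6, exon_count = 1,
    exon_starts = I(list(30.25e6)), exon_ends = I(list(30.35e6)),
    stringsAsFactors = FALSE
  ))
  genes <- suppressWarnings(geneUnionIntervals(tx))
  del <- makeCalls("DEL", "chr3", 30260000, "+", pos2 = 33056500,
                   strand2 = "-")
  f <- callFusions(del, genes)
  expect_equal(nrow(f), 2)  # ERG-TMPRSS2 and OVL-TMPRSS2
  expect_true(all(f$ambiguous))
})

test_that("fusion partners are oriented by retained transcription starts", {
  genes <- fusionGenes()
  ## deletion joining two minus-strand genes: the downstream-coordinate
  ## partner keeps its TSS and becomes the 5' gene
  del <- makeCalls("DEL", "chr3", 30292500, "+", pos2 = 33056500,
                   strand2 = "-")
  f <- orientFusion(callFusions(del, genes))
  expect_equal(f$gene_5p, "TMPRSS2")
  expect_equal(f$gene_3p, "ERG")
  expect_equal(f$pos_5p, 33056500)
  expect_false(f$unordered)
  ## an inversion joins the genes head-to-head: no consistent order
  inv <- makeCalls("INV", "chr3", 30292500, "+", pos2 = 33056500,
                   strand2 = "+")
  fi <- orientFusion(callFusions(inv, genes))
  expect_true(fi$unordered)
  expect_equal(fi$gene_5p, "ERG")  # alphabetical fallback
})

test_that("simulated canonical fusions are always ordered correctly", {
  cfg <- do.call(simConfig, c(list(
    seed = 61, n_samples = 12,
    ancestry_counts = c(African = 6, European = 6, Admixed = 0),
    fusion_plants = data.frame(
      mechanism = rep("single-deletion", 4),
      ancestry = c("African", "African", "European", "European"),
      stringsAsFactors = FALSE),
    caller = cleanCaller()),
    noPlants()[c("hyper_plants", "biallelic_plants", "assoc_plant")]))
  b <- simulateCohort(cfg)
  f <- orientFusion(callFusions(b$truth_svs, b$genes))
  te <- f[f$svtype == "DEL" &
            (f$gene_a %in% c("TMPRSS2", "ERG")) &
            (f$gene_b %in% c("TMPRSS2", "ERG")), ]
  expect_equal(nrow(te), 4)
  expect_true(all(te$gene_5p == "TMPRSS2" & te$gene_3p == "ERG"))
  expect_true(all(!te$unordered))
})

test_that("recurrence counts distinct samples per ordered pair", {
  f <- data.frame(
    gene_5p = c("A", "A", "A", "B"), gene_3p = c("X", "X", "X", "Y"),
    sample_id = c("s1", "s2", "s2", "s3"), stringsAsFactors = FALSE
  )
  r <- tallyRecurrence(f)
  expect_equal(r$n_samples[r$gene_5p == "A"], 2)  # s2 counts once
  expect_equal(r$n_samples[r$gene_5p == "B"], 1)
  expect_equal(nrow(tallyRecurrence(f[0, ])), 0)
  ## tallies match a brute-force group-by on random tables
  set.seed(62)
  rf <- data.frame(
    gene_5p = sample(LETTERS[1:5], 200, replace = TRUE),
    gene_3p = sample(letters[1:5], 200, replace = TRUE),
    sample_id = sample(paste0("s", 1:30), 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  r <- tallyRecurrence(rf)
  for (i in sample(nrow(r), 10)) {
    sel <- rf$gene_5p == r$gene_5p[i] & rf$gene_3p == r$gene_3p[i]
    expect_equal(r$n_samples[i], length(unique(rf$sample_id[sel])))
  }
  ## marginals: total sample-pair observations
  expect_equal(sum(r$n_samples),
               nrow(unique(rf[, c("gene_5p", "gene_3p", "sample_id")])))
})

test_that("ETS partner tables break down partners by SV type and ancestry", {
  f <- data.frame(
    gene_5p = c("TMPRSS2", "TMPRSS2", "ERG"),
    gene_3p = c("G1", "G1", "G2"),
    svtype = c("TRA", "DEL", "INV"),
    sample_id = c("s1", "s2", "s3"),
    stringsAsFactors = FALSE
  )
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   ancestry = c("African", "European", "African"),
                   stringsAsFactors = FALSE)
  tab <- etsPartnerTable(f, metadata = md)
  t_row <- tab[tab$ets_gene == "TMPRSS2" & tab$partner == "G1", ]
  expect_equal(t_row$sv_TRA, 1)
  expect_equal(t_row$sv_DEL, 1)
  expect_equal(t_row$n_African, 1)
  expect_equal(t_row$n_European, 1)
  e_row <- tab[tab$ets_gene == "ERG" & tab$partner == "G2", ]
  expect_equal(e_row$sv_INV, 1)
  ## no ETS-involving fusions: empty summary
  none <- data.frame(gene_5p = "P", gene_3p = "Q", svtype = "DEL",
                     sample_id = "s1", stringsAsFactors = FALSE)
  expect_equal(nrow(etsPartnerTable(none)), 0)
})

test_that("all six planted fusion mechanisms are classified correctly", {
  tx <- fusionTranscripts()
  genes <- fusionGenes()
  mechs <- c("single-deletion", "interstitial-retention",
             "deletion-plus-overlapping-SVs", "inversion", "duplication",
             "complex-multi-SV")
  set.seed(63)
  for (jit in c(0, 3)) {
    for (m in mechs) {
      pl <- plantFusion("sX", m, tx)
      calls <- pl$calls
      if (jit > 0) {
        calls$pos1 <- calls$pos1 + sample(-jit:jit, nrow(calls), TRUE)
        calls$pos2 <- calls$pos2 + sample(-jit:jit, nrow(calls), TRUE)
      }
      got <- classifyFusionMechanism(SvCallSet(calls), "sX",
                                     "TMPRSS2", "ERG", genes)
      expect_equal(got$label, m, label = sprintf("%s at jitter %d", m, jit))
      expect_equal(got$n_supporting_svs, pl$truth$n_svs)
    }
  }
  ## an expected count for the complex class
  pl <- plantFusion("sX", "complex-multi-SV", tx)
  expect_equal(pl$truth$n_svs, 7)
  ## interstitial retention is one deletion plus two translocation pairs
  pl <- plantFusion("sX", "interstitial-retention", tx)
  expect_equal(sort(pl$calls$svtype), c("DEL", "TRA", "TRA"))
  ## a locus without any linking SV is an error
  lone <- makeCalls("DEL", "chr3", 30400000, "+", pos2 = 30500000,
                    strand2 = "-")
  expect_error(classifyFusionMechanism(lone, "s1", "TMPRSS2", "ERG", genes),
               "no SV links")
  expect_error(plantFusion("sX", "chromoplexy", tx), "unknown")
})

## independent oracle: scan the exon list of one transcript directly
junctionOracle <- function(tx, pos, side) {
  s <- tx$exon_starts[[1]]; e <- tx$exon_ends[[1]]
  o <- if (tx$strand == "-") order(s, decreasing = TRUE) else order(s)
  s <- s[o]; e <- e[o]
  inside <- which(pos >= s & pos <= e)
  if (length(inside) > 0) return(inside[1])
  if (side == "5p") {
    up <- if (tx$strand == "-") which(s > pos) else which(e < pos)
    if (length(up) == 0) NA else max(up)
  } else {
    dn <- if (tx$strand == "-") which(e < pos) else which(s > pos)
    if (length(dn) == 0) NA else min(dn)
  }
}

test_that("junction mapping reports retained exons for all transcript pairs", {
  tx <- fusionTranscripts()
  tx5 <- tx[tx$gene_symbol == "TMPRSS2", ]
  tx3 <- tx[tx$gene_symbol == "ERG", ]
  ## breakend in intron 1 of the 5' partner and intron 2 of the 3' partner
  pos5 <- 33056500  # between exon 2 end and exon 1 start (minus strand)
  pos3 <- 30292500  # between exon 3 end and exon 2 start (minus strand)
  j <- mapFusionJunction(pos5, pos3, tx5, tx3)
  expect_equal(nrow(j), 2 * 10)
  expect_true(all(j$last_retained_exon_5p == 1))
  expect_true(all(j$first_retained_exon_3p == 3))
  expect_false(any(j$intra_exonic_5p | j$intra_exonic_3p))
  ## against the independent per-transcript oracle
  for (i in seq_len(nrow(j))) {
    t5 <- tx5[tx5$transcript_id == j$transcript_5p[i], ]
    t3 <- tx3[tx3$transcript_id == j$transcript_3p[i], ]
    expect_equal(j$last_retained_exon_5p[i], junctionOracle(t5, pos5, "5p"))
    expect_equal(j$first_retained_exon_3p[i], junctionOracle(t3, pos3, "3p"))
  }
  ## intron 2 of the 5' partner gives last retained exon 2
  j2 <- mapFusionJunction(33054001 - 1000, pos3, tx5, tx3)
  expect_true(all(j2$last_retained_exon_5p == 2))
  ## a breakend inside exon 4 of the 3' partner reports exon 4, flagged
  j3 <- mapFusionJunction(pos5, 30286500, tx5, tx3)
  expect_true(all(j3$first_retained_exon_3p == 4))
  expect_true(all(j3$intra_exonic_3p))
  ## a breakend outside a transcript span skips that combination
  j4 <- mapFusionJunction(33059500, 30246500, tx5, tx3)
  expect_lt(nrow(j4), 20)
  expect_gt(length(attr(j4, "skipped")), 0)
})

test_that("junction mapping is invariant under coordinate mirroring", {
  tx <- fusionTranscripts()
  t5 <- tx[tx$transcript_id == "TMPRSS2.t01", ]
  pos <- 33056500
  M <- 70e6  # mirror pivot
  mirror <- t5
  mirror$strand <- "+"
  mirror$tx_start <- M - t5$tx_end
  mirror$tx_end <- M - t5$tx_start
  mirror$exon_starts <- I(list(rev(M - t5$exon_ends[[1]])))
  mirror$exon_ends <- I(list(rev(M - t5$exon_starts[[1]])))
  t3 <- tx[tx$transcript_id == "ERG.t05", ]
  j <- mapFusionJunction(pos, 30292500, t5, t3)
  jm <- mapFusionJunction(M - pos, 30292500, mirror, t3)
  expect_equal(jm$last_retained_exon_5p, j$last_retained_exon_5p)
  expect_equal(jm$first_retained_exon_3p, j$first_retained_exon_3p)
})

test_that("fusion breakends always lie inside the named gene spans", {
  cfg <- do.call(simConfig, c(list(
    seed = 64, n_samples = 10,
    ancestry_counts = c(African = 5, European = 5, Admixed = 0),
    caller = cleanCaller()), noPlants()))
  b <- simulateCohort(cfg)
  f <- callFusions(b$truth_svs, b$genes)
  if (nrow(f) > 0) {
    g <- b$genes
    for (i in seq_len(nrow(f))) {
      ga <- g[g$gene_symbol == f$gene_a[i]]
      expect_true(any(
        f$chrom1[i] == as.character(GenomicRanges::seqnames(ga)) &
          f$pos1[i] >= GenomicRanges::start(ga) &
          f$pos1[i] <= GenomicRanges::end(ga)))
    }
  }
  expect_true(TRUE)
})
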