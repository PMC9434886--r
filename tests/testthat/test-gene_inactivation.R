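test_that("CN states follow the two-level threshold step rules", {
  ## worked examples
  expect_equal(geneCnState(0.05, high_gain = 1.2, high_loss = -1.0), 0L)
  expect_equal(geneCnState(1.5, high_gain = 1.2, high_loss = -1.0), 2L)
  expect_equal(geneCnState(-0.5, high_gain = 1.2, high_loss = -1.0), -1L)
  ## grid spanning both threshold pairs, against the stated rules
  hg <- 1.1; hl <- -0.95
  vals <- c(-2, hl - 1e-9, hl, hl + 1e-9, -0.5, -0.1, -0.1 + 1e-9, 0,
            0.1, 0.1 + 1e-9, 0.6, hg, hg + 1e-9, 2)
  got <- geneCnState(vals, hg, hl)
  oracle <- vapply(vals, function(v) {
    if (v > hg) 2L else if (v > 0.1) 1L
    else if (v < hl) -2L else if (v < -0.1) -1L else 0L
  }, integer(1))
  expect_equal(got, oracle)
  ## monotone step function
  expect_true(all(diff(geneCnState(sort(runif(200, -3, 3)), hg, hl)) >= 0))
  ## per-sample thresholds joined by sample
  cn <- data.frame(sample_id = c("s1", "s2"), gene = "G",
                   value = c(1.0, 1.0), stringsAsFactors = FALSE)
  thr <- data.frame(sample_id = c("s1", "s2"),
                    high_gain = c(0.9, 1.2), high_loss = c(-1, -1),
                    stringsAsFactors = FALSE)
  expect_equal(cnGeneCalls(cn, thr)$state, c(2L, 1L))
  expect_error(cnGeneCalls(data.frame(sample_id = "sX", gene = "G",
                                      value = 1), thr), "missing")
})

test_that("the mutation matrix equals brute-force per-cell evaluation", {
  set.seed(71)
  tx <- data.frame(
    gene_symbol = c("G1", "G2", "G3"), transcript_id = c("t1", "t2", "t3"),
    chrom = "chr1", strand = "+",
    tx_start = c(1e6, 3e6, 5e6), tx_end = c(1.5e6, 3.5e6, 5.5e6),
    exon_count = 1,
    exon_starts = I(list(1e6, 3e6, 5e6)),
    exon_ends = I(list(1.5e6, 3.5e6, 5.5e6)), stringsAsFactors = FALSE
  )
  genes <- geneUnionIntervals(tx)
  samples <- paste0("s", 1:8)
  sv <- makeCalls("TRA", "chr1", floor(runif(15, 5e5, 6e6)), "+",
                  chrom2 = "chr2", pos2 = 100, strand2 = "-",
                  sample_id = sample(samples, 15, replace = TRUE))
  snv <- data.frame(
    sample_id = sample(samples, 12, replace = TRUE),
    gene = sample(c("G1", "G2", "G3"), 12, replace = TRUE),
    origin = sample(c("somatic", "germline"), 12, replace = TRUE),
    klass = "SNV",
    effect = sample(c("nonsynonymous", "synonymous", "noncoding"), 12,
                    replace = TRUE), stringsAsFactors = FALSE
  )
  cnc <- data.frame(
    sample_id = rep(samples, 3), gene = rep(c("G1", "G2", "G3"), each = 8),
    state = sample(-2:2, 24, replace = TRUE), stringsAsFactors = FALSE
  )
  mm <- buildMutationMatrix(snv, cnc, sv, genes, c("G1", "G2", "G3"),
                            samples)
  be <- breakendPositions(sv)
  for (s in samples) {
    for (g in c("G1", "G2", "G3")) {
      sel <- snv$sample_id == s & snv$gene == g
      expect_equal(mm$coding_mut[s, g],
                   any(snv$effect[sel] %in% c("nonsynonymous", "synonymous")))
      expect_equal(mm$noncoding_mut[s, g], any(snv$effect[sel] == "noncoding"))
      cs <- cnc$state[cnc$sample_id == s & cnc$gene == g]
      expect_equal(mm$cn_gain[s, g], any(cs == 2))
      expect_equal(mm$cn_loss[s, g], any(cs == -2))
      gr <- genes[genes$gene_symbol == g]
      inb <- be$sample_id == s & be$chrom == "chr1" &
        be$pos >= GenomicRanges::start(gr) & be$pos <= GenomicRanges::end(gr)
      expect_equal(mm$sv_break[s, g], any(inb))
    }
  }
  ## unknown genes are dropped with a warning
  expect_warning(
    mm2 <- buildMutationMatrix(snv, cnc, sv, genes, c("G1", "NOPE"), samples),
    "absent")
  expect_equal(attr(mm2, "genes"), "G1")
})

mkEvidence <- function(cn_state = 0, allele_a = 1, allele_b = 1,
                       exon_del_count = 0, somatic_nonsyn = FALSE,
                       germline_nonsyn = FALSE, exon_break = FALSE) {
  data.frame(sample_id = "s1", gene = "G", cn_state = cn_state,
             allele_a = allele_a, allele_b = allele_b,
             exon_del_count = exon_del_count,
             somatic_nonsyn = somatic_nonsyn,
             germline_nonsyn = germline_nonsyn, exon_break = exon_break,
             stringsAsFactors = FALSE)
}

test_that("biallelic classes follow the four evidence rules", {
  ## (2) two exon-overlapping deletions with zero allele-specific CN
  expect_equal(classifyBiallelic(
    mkEvidence(cn_state = -2, allele_a = 0, allele_b = 0,
               exon_del_count = 2))$klass, "Loss/Loss")
  ## (1) one-allele loss plus somatic nonsynonymous SNV
  expect_equal(classifyBiallelic(
    mkEvidence(cn_state = -1, somatic_nonsyn = TRUE))$klass, "Loss/Mutation")
  expect_equal(classifyBiallelic(
    mkEvidence(allele_a = 0, somatic_nonsyn = TRUE))$klass, "Loss/Mutation")
  ## (3) one-allele loss plus exon-interrupting SV break
  expect_equal(classifyBiallelic(
    mkEvidence(cn_state = -1, exon_break = TRUE))$klass, "Loss/Break")
  ## (4) nonsynonymous germline plus somatic SNV
  expect_equal(classifyBiallelic(
    mkEvidence(somatic_nonsyn = TRUE, germline_nonsyn = TRUE))$klass,
    "Mutation/Mutation")
  ## no qualifying evidence
  expect_equal(classifyBiallelic(mkEvidence())$klass, "none")
  expect_equal(classifyBiallelic(
    mkEvidence(cn_state = -1))$klass, "none")
  ## precedence: complete CN evidence wins, all classes listed
  both <- classifyBiallelic(
    mkEvidence(cn_state = -2, allele_a = 0, allele_b = 0,
               exon_del_count = 2, somatic_nonsyn = TRUE))
  expect_equal(both$klass, "Loss/Loss")
  expect_match(both$all_classes, "Loss/Loss")
  expect_match(both$all_classes, "Loss/Mutation")
})

test_that("BH adjustment matches the hand step-up calculation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.73), 0.73)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, -0.1)), "\\[0, 1\\]")
  set.seed(72)
  for (r in 1:20) {
    p <- runif(sample(1:300, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bhStepUp(p))
    ## monotone in the order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("burden association flags untestable and separated fits", {
  set.seed(73)
  d <- simulateBurdenCohort(n = 150, beta0 = -1.5, beta1 = 0, gene = "G1")
  ## constant predictor
  sp <- d$spectra
  sp$rf_INS <- 0
  sp$n_INS <- 0
  a <- testSvBurdenAssociation(sp, d$mutated, svtypes = "INS")
  expect_true(all(a$untestable))
  expect_true(all(is.na(a$adjusted_p)))
  ## all-mutated outcome
  mut <- d$mutated; mut[] <- TRUE
  a2 <- testSvBurdenAssociation(d$spectra, mut, svtypes = "DUP")
  expect_true(all(a2$untestable))
  ## complete separation falls back to a penalized fit with finite p
  n <- 60
  sp2 <- data.frame(sample_id = paste0("s", 1:n), stringsAsFactors = FALSE)
  for (t in c("DEL", "DUP", "INS", "INV", "TRA")) {
    sp2[[paste0("n_", t)]] <- 0; sp2[[paste0("rf_", t)]] <- 0
  }
  sp2$rf_DUP <- seq(0, 1, length.out = n)
  sp2$n_DUP <- seq_len(n)
  sp2$total <- sp2$n_DUP
  mut2 <- matrix(sp2$rf_DUP > 0.5, ncol = 1,
                 dimnames = list(sp2$sample_id, "G1"))
  a3 <- testSvBurdenAssociation(sp2, mut2, svtypes = "DUP",
                                measures = "rel_freq")
  expect_true(a3$separation)
  expect_false(a3$untestable)
  expect_gt(a3$p_value, 0)
  expect_lt(a3$p_value, 1e-4)  # strong planted effect still detected
})

test_that("the likelihood-ratio test detects a strong planted dependence", {
  set.seed(74)
  d <- simulateBurdenCohort(n = 200, beta0 = -2, beta1 = 3, gene = "G1")
  a <- testSvBurdenAssociation(d$spectra, d$mutated)
  hit <- a[a$svtype == "DUP" & a$measure == "rel_freq", ]
  expect_false(hit$untestable)
  expect_gt(hit$coefficient, 0)
  expect_lt(hit$adjusted_p, 0.05)
  ## BH is applied across all testable combinations of the run
  testable <- !a$untestable
  expect_equal(a$adjusted_p[testable], bhStepUp(a$p_value[testable]))
})

test_that("assembled biallelic evidence recovers planted classes in a cohort", {
  cfg <- do.call(simConfig, c(list(
    seed = 75, n_samples = 24,
    ancestry_counts = c(African = 12, European = 12, Admixed = 0),
    hyper_plants = data.frame(
      type = c("DEL", "DEL", "DEL", "DEL", "DUP"),
      ancestry = c("African", "African", "African", "European", "African"),
      stringsAsFactors = FALSE),
    biallelic_plants = data.frame(
      gene = c("BRCA2", "BRCA2", "BRCA2", "BRCA2", "CDK12"),
      klass = c("Loss/Mutation", "Loss/Loss", "Loss/Break",
                "Mutation/Mutation", "Loss/Mutation"),
      host = c(rep("hyper-deleted", 4), "hyper-duplicated"),
      stringsAsFactors = FALSE),
    caller = cleanCaller(),
    assoc_plant = NULL),
    noPlants()["fusion_plants"]))
  b <- simulateCohort(cfg)
  cn_calls <- cnGeneCalls(b$cn, b$cn_thresholds)
  ev <- biallelicEvidence(b$truth_svs, b$small_variants, cn_calls,
                          b$allelic, b$transcripts,
                          c("BRCA2", "CDK12"), b$metadata$sample_id)
  cls <- classifyBiallelic(ev)
  for (i in seq_len(nrow(b$truth_biallelic))) {
    got <- cls$klass[cls$sample_id == b$truth_biallelic$sample_id[i] &
                       cls$gene == b$truth_biallelic$gene[i]]
    expect_equal(got, b$truth_biallelic$klass[i],
                 label = paste("plant", b$truth_biallelic$klass[i]))
  }
})
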