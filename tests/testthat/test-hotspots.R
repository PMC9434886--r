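toySizes <- c(chr1 = 10e6, chr2 = 8e6)

test_that("binning counts every breakend in its window", {
  cs <- makeCalls("DEL", "chr1", 500000, "+", pos2 = 1500000, strand2 = "-")
  bins <- binBreakpoints(cs, toySizes)
  expect_equal(bins$breakpoint_count[bins$chrom == "chr1" & bins$start == 1], 1)
  expect_equal(bins$breakpoint_count[bins$chrom == "chr1" & bins$start == 1e6 + 1], 1)
  ## two deletions of one sample fully inside one bin: 4 breakpoints, 1 sample
  cs2 <- makeCalls("DEL", "chr1", c(100000, 200000), "+",
                   pos2 = c(150000, 250000), strand2 = "-")
  bins2 <- binBreakpoints(cs2, toySizes)
  b1 <- bins2[bins2$chrom == "chr1" & bins2$start == 1, ]
  expect_equal(b1$breakpoint_count, 4)
  expect_equal(b1$sample_count, 1)
  ## out-of-range breakend is an error naming the record
  bad <- makeCalls("DEL", "chr2", 7.9e6, "+", pos2 = 8.5e6, strand2 = "-")
  expect_error(binBreakpoints(bad, toySizes), "beyond chromosome length")
})

test_that("per-bin totals equal a brute-force scan and conserve breakends", {
  set.seed(51)
  n <- 1000
  types <- sample(c("DEL", "DUP", "INV", "TRA", "INS"), n, replace = TRUE,
                  prob = c(0.4, 0.2, 0.2, 0.15, 0.05))
  chrom1 <- sample(names(toySizes), n, replace = TRUE)
  pos1 <- floor(runif(n, 1, toySizes[chrom1] - 2e5))
  intra <- types %in% c("DEL", "DUP", "INV")
  chrom2 <- ifelse(types == "TRA",
                   ifelse(chrom1 == "chr1", "chr2", "chr1"), chrom1)
  pos2 <- ifelse(intra, pos1 + floor(runif(n, 1e3, 1e5)),
                 ifelse(types == "TRA",
                        floor(runif(n, 1, toySizes[chrom2])), NA))
  cs <- makeCalls(types, chrom1, pos1,
                  ifelse(types == "DEL", "+",
                         ifelse(types == "DUP", "-", "+")),
                  chrom2 = ifelse(types == "INS", NA, chrom2),
                  pos2 = pos2,
                  strand2 = ifelse(types == "INS", NA,
                                   ifelse(types == "DEL", "-", "+")),
                  sample_id = sample(paste0("s", 1:40), n, replace = TRUE))
  bins <- binBreakpoints(cs, toySizes)
  ## brute-force scan over individual breakends
  be <- breakendPositions(cs)
  for (r in sample(nrow(bins), 12)) {
    inb <- be$chrom == bins$chrom[r] &
      be$pos >= bins$start[r] & be$pos <= bins$end[r]
    expect_equal(bins$breakpoint_count[r], sum(inb))
    expect_equal(bins$sample_count[r], length(unique(be$sample_id[inb])))
  }
  expect_equal(sum(bins$breakpoint_count), nrow(be))
})

test_that("the Tukey fence matches a hand-computed quartile interpolation", {
  f <- tukeyFence(c(1, 2, 3, 4, 100), k = 3)
  expect_equal(attr(f, "Q1"), 2)
  expect_equal(attr(f, "Q3"), 4)
  expect_equal(as.numeric(f), 4 + 3 * (4 - 2))
  expect_equal(sum(c(1, 2, 3, 4, 100) > f), 1)  # only the extreme value
  ## random vectors against the independent interpolation oracle
  set.seed(52)
  for (r in 1:20) {
    x <- rpois(sample(5:200, 1), lambda = sample(3:50, 1))
    f <- tukeyFence(x, k = 1.5)
    q1 <- quartileOracle(x, 0.25); q3 <- quartileOracle(x, 0.75)
    expect_equal(attr(f, "Q1"), q1)
    expect_equal(attr(f, "Q3"), q3)
    expect_equal(as.numeric(f), q3 + 1.5 * (q3 - q1))
  }
  ## degenerate and equivariance properties
  expect_equal(as.numeric(tukeyFence(rep(7, 10), k = 3)), 7)
  x <- rgamma(50, 2)
  expect_equal(as.numeric(tukeyFence(3 * x, 1.5)),
               3 * as.numeric(tukeyFence(x, 1.5)))
  expect_error(tukeyFence(numeric(0)), "at least one")
})

test_that("hotspot flags use strict fences and respond to both statistics", {
  bins <- data.frame(chrom = "chr1", start = seq(1, by = 1e6, length.out = 20),
                     end = seq(1e6, by = 1e6, length.out = 20),
                     breakpoint_count = c(rep(10, 18), 200, 10),
                     sample_count = c(rep(5, 18), 40, 5))
  hot <- callHotspots(bins)
  expect_equal(sum(hot$hotspot), 1)
  expect_true(hot$flag_count_outlier[19] && hot$flag_recurrence_outlier[19])
  ## uniform counts: no hotspot (strict inequality at the fence)
  uni <- bins; uni$breakpoint_count <- 10; uni$sample_count <- 5
  expect_equal(sum(callHotspots(uni)$hotspot), 0)
  ## raising k never increases the hotspot count
  set.seed(53)
  bins$breakpoint_count <- rpois(20, 10) + c(rep(0, 15), rep(30, 5))
  bins$sample_count <- pmin(bins$breakpoint_count, rpois(20, 6))
  n_prev <- Inf
  for (k in c(0.5, 1.5, 3, 6)) {
    n <- sum(callHotspots(bins, hotspotParams(k_breakpoints = k,
                                              k_samples = k))$hotspot)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("bin summaries report median and MAD of the populated bins", {
  bins <- data.frame(chrom = "chr1", start = 1, end = 1e6,
                     breakpoint_count = c(0, 5, 10, 15, 20),
                     sample_count = c(0, 2, 6, 6, 10))
  s <- attr(callHotspots(bins), "summary")
  expect_equal(s$n_bins_population, 4)  # zero-breakpoint bin excluded
  expect_equal(s$median_breakpoints, 12.5)
  expect_equal(s$mad_breakpoints, median(abs(c(5, 10, 15, 20) - 12.5)))
  s_all <- attr(callHotspots(bins, hotspotParams(include_empty = TRUE)),
                "summary")
  expect_equal(s_all$n_bins_population, 5)
})

test_that("planted high-rate bins are recovered with few false positives", {
  ## 5 bins at 10x baseline among 300 bins, bin occupancy near the
  ## cohort-scale 10 breakpoints / 6 samples per bin
  tm <- rbind(African = c(DEL = 6.6, DUP = 3.6, INS = 0.1, INV = 3.6, TRA = 3.7),
              European = c(DEL = 5, DUP = 1.4, INS = 0.1, INV = 2.7, TRA = 2.1))
  tm <- rbind(tm, Admixed = colMeans(tm))
  cfg <- do.call(simConfig, c(list(
    seed = 54, n_samples = 100,
    ancestry_counts = c(African = 50, European = 50, Admixed = 0),
    chrom_sizes = c(chr1 = 60e6, chr2 = 60e6, chr3 = 60e6,
                    chr4 = 60e6, chr5 = 60e6),
    type_means = tm,
    hotspot_plants = list(n_bins = 5, multiplier = 10),
    caller = cleanCaller()), noPlants()))
  b <- simulateCohort(cfg)
  bins <- binBreakpoints(b$truth_svs, b$chrom_sizes)
  hot <- callHotspots(bins)
  called <- paste(hot$chrom, hot$start)[hot$hotspot]
  planted <- paste(b$truth_hotspots$chrom, b$truth_hotspots$start)
  expect_equal(sum(planted %in% called), 5)
  expect_lte(sum(!(called %in% planted)), 1)
})

test_that("gene nomination uses breakpoint and sample fractions", {
  tx <- data.frame(gene_symbol = "GENEX", transcript_id = "x1",
                   chrom = "chr1", strand = "+",
                   tx_start = 2.2e6, tx_end = 2.8e6, exon_count = 1,
                   exon_starts = I(list(2.2e6)), exon_ends = I(list(2.8e6)),
                   stringsAsFactors = FALSE)
  genes <- geneUnionIntervals(tx)
  set.seed(56)
  ## 40 samples with one breakend each in the bin, 37 inside the gene,
  ## plus sparse background so the bin stands out as a hotspot
  pos <- c(runif(37, 2.3e6, 2.7e6), runif(3, 2.9e6, 2.95e6))
  bg <- setdiff(seq(5e5, 9.5e6, by = 1e6), 2.5e6)  # keep the target bin clean
  cs <- makeCalls("TRA", c(rep("chr1", 40), rep("chr1", length(bg))),
                  c(sort(pos), bg), "+",
                  chrom2 = "chr2",
                  pos2 = c(rep(5e6, 40), seq(5e5, by = 7e5,
                                             length.out = length(bg))),
                  strand2 = "-",
                  sample_id = c(paste0("s", 1:40), rep("bg", length(bg))))
  bins <- binBreakpoints(cs, toySizes)
  hot <- callHotspots(bins)
  hot <- nominateGenes(hot, cs, genes)
  h <- hot[hot$hotspot & hot$chrom == "chr1" & hot$start == 2e6 + 1, ]
  expect_equal(h$nominated_gene, "GENEX")
  expect_equal(h$gene_breakpoint_fraction, 0.925)
  ## fewer than 5% of breakpoints in any gene: nothing nominated
  pos2 <- c(runif(2, 2.3e6, 2.7e6), runif(58, 2.81e6, 2.99e6))
  cs2 <- makeCalls("TRA", c(rep("chr1", 60), rep("chr1", length(bg))),
                   c(sort(pos2), bg), "+",
                   chrom2 = "chr2",
                   pos2 = c(rep(5e6, 60), seq(5e5, by = 7e5,
                                              length.out = length(bg))),
                   strand2 = "-",
                   sample_id = c(paste0("s", 1:60), rep("bg", length(bg))))
  hot2 <- nominateGenes(callHotspots(binBreakpoints(cs2, toySizes)), cs2, genes)
  h2 <- hot2[hot2$chrom == "chr1" & hot2$start == 2e6 + 1, ]
  expect_true(is.na(h2$nominated_gene))
  ## empty gene annotation: nothing nominated
  hot3 <- nominateGenes(callHotspots(binBreakpoints(cs, toySizes)), cs,
                        GenomicRanges::GRanges())
  expect_true(all(is.na(hot3$nominated_gene)))
})

test_that("hotspot ancestry composition matches a reference chi-squared", {
  md <- data.frame(
    sample_id = c(paste0("a", 1:115), paste0("e", 1:61)),
    ancestry = c(rep("African", 115), rep("European", 61)),
    stringsAsFactors = FALSE
  )
  md <- rbind(md, data.frame(sample_id = "x1", ancestry = "Admixed",
                             stringsAsFactors = FALSE))
  contrib <- c(paste0("a", 1:9), "e1")  # 9 African of 10 contributors
  bg <- seq(5e5, 9.5e6, by = 1e6)
  cs <- makeCalls("TRA", "chr1", c(seq(2.1e6, 2.9e6, length.out = 10), bg),
                  "+", chrom2 = "chr2",
                  pos2 = c(rep(5e6, 10), seq(5e5, by = 7e5,
                                             length.out = length(bg))),
                  strand2 = "-", sample_id = c(contrib, rep("x1", length(bg))))
  hot <- callHotspots(binBreakpoints(cs, toySizes))
  hot <- ancestryComposition(hot, cs, md)
  h <- hot[hot$hotspot, ][1, ]
  expect_equal(h$african_sample_fraction, 0.9)
  expect_equal(h$african_breakpoint_fraction, 0.9)
  tab <- rbind(c(9, 1), c(115 - 9, 61 - 1))
  expect_equal(h$chi2_p, pearsonChi2(tab), tolerance = 1e-10)
  ## contributors drawn proportionally to the cohort: non-significant
  contrib2 <- c(paste0("a", 1:13), paste0("e", 1:7))  # ~115:61 ratio
  cs2 <- makeCalls("TRA", "chr1",
                   c(seq(2.1e6, 2.9e6, length.out = 20), bg), "+",
                   chrom2 = "chr2",
                   pos2 = c(rep(5e6, 20), seq(5e5, by = 7e5,
                                              length.out = length(bg))),
                   strand2 = "-", sample_id = c(contrib2, rep("x1", length(bg))))
  hot2 <- ancestryComposition(callHotspots(binBreakpoints(cs2, toySizes)),
                              cs2, md)
  expect_gt(hot2$chi2_p[hot2$hotspot][1], 0.5)
})

test_that("hotspot calls are invariant to sample order", {
  set.seed(55)
  cs <- makeCalls("TRA", "chr1", floor(runif(60, 1, 9e6)), "+",
                  chrom2 = "chr2", pos2 = floor(runif(60, 1, 7e6)),
                  strand2 = "-", sample_id = sample(paste0("s", 1:10), 60,
                                                    replace = TRUE))
  h1 <- callHotspots(binBreakpoints(cs, toySizes))
  perm <- SvCallSet(svCalls(cs)[sample(60), ])
  h2 <- callHotspots(binBreakpoints(perm, toySizes))
  expect_equal(h1, h2)
})
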