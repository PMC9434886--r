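#' Breakend positions of a call set
#'
#' Expands events into individual breakends: two per two-breakend event, one
#' per single-breakend insertion.
#'
#' @param x An [SvCallSet-class].
#' @return data.frame with `sample_id`, `svtype`, `chrom`, `pos`.
#' @export
breakendPositions <- function(x) {
  df <- svCalls(x)
  one <- data.frame(sample_id = df$sample_id, svtype = df$svtype,
                    chrom = df$chrom1, pos = df$pos1, stringsAsFactors = FALSE)
  two <- !is.na(df$pos2)
  out <- rbind(one, data.frame(sample_id = df$sample_id[two],
                               svtype = df$svtype[two],
                               chrom = df$chrom2[two], pos = df$pos2[two],
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Bin SV breakpoints into fixed genomic windows
#'
#' Tiles each chromosome with non-overlapping windows of `width` bp (the
#' first window starts at position 1) and counts, per window, the total
#' number of SV breakends and the number of distinct samples with at least
#' one breakend. Every breakend of every event contributes one count, so an
#' intra-chromosomal event may contribute two counts to one bin. A breakend
#' beyond the chromosome length (or on a chromosome absent from the sizes
#' table) is an error.
#'
#' @param x An [SvCallSet-class].
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Bin width in bp (default 1e6).
#' @return data.frame with one row per bin: `chrom`, `start`, `end`,
#'   `breakpoint_count`, `sample_count`; attribute `width`.
#' @export
binBreakpoints <- function(x, chrom_sizes, width = 1e6) {
  be <- breakendPositions(x)
  bad <- !(be$chrom %in% names(chrom_sizes))
  if (any(bad)) {
    stopf("breakend chromosome(s) not in the size table: %s",
          paste(unique(be$chrom[bad]), collapse = ", "))
  }
  over <- be$pos > chrom_sizes[be$chrom]
  if (any(over)) {
    stopf("breakend beyond chromosome length: %s:%d (sample %s)",
          be$chrom[which(over)[1]], be$pos[which(over)[1]],
          be$sample_id[which(over)[1]])
  }
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- ceiling(chrom_sizes[[ch]] / width)
    data.frame(chrom = ch,
               start = (seq_len(n) - 1) * width + 1,
               end = pmin(seq_len(n) * width, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  key <- paste(bins$chrom, bins$start)
  bkey <- paste(be$chrom, floor((be$pos - 1) / width) * width + 1)
  idx <- match(bkey, key)
  bins$breakpoint_count <- as.integer(tabulate(idx, nbins = nrow(bins)))
  seen <- !duplicated(paste(idx, be$sample_id))
  bins$sample_count <- as.integer(tabulate(idx[seen], nbins = nrow(bins)))
  rownames(bins) <- NULL
  attr(bins, "width") <- width
  bins
}

#' Tukey-fence outlier threshold
#'
#' Returns `Q3 + k * (Q3 - Q1)`, with quartiles computed by linear
#' interpolation at position `p * (n - 1)` on the sorted values
#' (`stats::quantile` type 7, the default; other interpolation schemes can
#' be selected via `quantile_method`).
#'
#' @param values Numeric vector (at least one value).
#' @param k Fence multiplier (> 0).
#' @param quantile_method Integer quantile type passed to
#'   [stats::quantile()] (default 7).
#' @return The fence threshold; attributes `Q1`, `Q3`, `IQR`.
#' @export
tukeyFence <- function(values, k = 1.5, quantile_method = 7) {
  if (length(values) == 0) stopf("tukeyFence requires at least one value")
  stopifnot(k > 0)
  q <- unname(quantile(values, c(0.25, 0.75), type = quantile_method,
                       names = FALSE))
  fence <- q[2] + k * (q[2] - q[1])
  structure(fence, Q1 = q[1], Q3 = q[2], IQR = q[2] - q[1])
}

#' Hotspot-calling parameters
#'
#' @param k_breakpoints Tukey `k` for the breakpoint-count fence (default 3,
#'   the stringent "far out" fence, since clustered breakpoints can arise in
#'   a single tumour).
#' @param k_samples Tukey `k` for the sample-count fence (default 1.5).
#' @param min_gene_breakpoint_fraction,min_gene_sample_fraction Strict
#'   lower bounds for gene nomination (default 0.5).
#' @param quantile_method Quartile interpolation scheme (default 7).
#' @param include_empty Include zero-breakpoint bins in the fence
#'   population (default `FALSE`: fences are computed over bins with at
#'   least one breakpoint).
#' @param sd_rule Alternative flagging rule: flag bins more than
#'   `sd_multiplier` standard deviations above the mean instead of Tukey
#'   fences (default `FALSE`).
#' @param sd_multiplier Multiplier for the SD rule (default 3).
#' @return List of class `hotspot_params`.
#' @export
hotspotParams <- function(k_breakpoints = 3, k_samples = 1.5,
                          min_gene_breakpoint_fraction = 0.5,
                          min_gene_sample_fraction = 0.5,
                          quantile_method = 7,
                          include_empty = FALSE,
                          sd_rule = FALSE, sd_multiplier = 3) {
  stopifnot(k_breakpoints > 0, k_samples > 0)
  structure(list(
    k_breakpoints = k_breakpoints, k_samples = k_samples,
    min_gene_breakpoint_fraction = min_gene_breakpoint_fraction,
    min_gene_sample_fraction = min_gene_sample_fraction,
    quantile_method = quantile_method, include_empty = include_empty,
    sd_rule = sd_rule, sd_multiplier = sd_multiplier
  ), class = "hotspot_params")
}

#' Call SV breakpoint hotspots
#'
#' Flags bins whose breakpoint count strictly exceeds the Tukey fence with
#' `k_breakpoints` and/or whose sample count strictly exceeds the fence with
#' `k_samples`; a hotspot is a bin with either flag. Fences are computed
#' over bins with at least one breakpoint unless
#' `params$include_empty = TRUE`. The distribution summary (median and MAD
#' of both statistics, quartiles and fences) is attached as the `summary`
#' attribute; MAD is reported both unscaled and with the 1.4826 consistency
#' factor.
#'
#' @param bins data.frame from [binBreakpoints()].
#' @param params [hotspotParams()].
#' @return `bins` with added columns `flag_count_outlier`,
#'   `flag_recurrence_outlier`, `hotspot`; attribute `summary`.
#' @export
callHotspots <- function(bins, params = hotspotParams()) {
  pop <- if (params$include_empty) bins else
    bins[bins$breakpoint_count >= 1, , drop = FALSE]
  if (nrow(pop) == 0) stopf("no bins with breakpoints")
  if (params$sd_rule) {
    fence_bp <- mean(pop$breakpoint_count) +
      params$sd_multiplier * stats::sd(pop$breakpoint_count)
    fence_n <- mean(pop$sample_count) +
      params$sd_multiplier * stats::sd(pop$sample_count)
    summ <- list(rule = "sd", fence_breakpoints = fence_bp,
                 fence_samples = fence_n)
  } else {
    f_bp <- tukeyFence(pop$breakpoint_count, params$k_breakpoints,
                       params$quantile_method)
    f_n <- tukeyFence(pop$sample_count, params$k_samples,
                      params$quantile_method)
    fence_bp <- as.numeric(f_bp); fence_n <- as.numeric(f_n)
    summ <- list(
      rule = "tukey",
      n_bins_population = nrow(pop),
      median_breakpoints = median(pop$breakpoint_count),
      mad_breakpoints = mad(pop$breakpoint_count, constant = 1),
      mad_breakpoints_scaled = mad(pop$breakpoint_count),
      median_samples = median(pop$sample_count),
      mad_samples = mad(pop$sample_count, constant = 1),
      mad_samples_scaled = mad(pop$sample_count),
      Q1_breakpoints = attr(f_bp, "Q1"), Q3_breakpoints = attr(f_bp, "Q3"),
      Q1_samples = attr(f_n, "Q1"), Q3_samples = attr(f_n, "Q3"),
      fence_breakpoints = fence_bp, fence_samples = fence_n
    )
  }
  in_pop <- if (params$include_empty) rep(TRUE, nrow(bins)) else
    bins$breakpoint_count >= 1
  bins$flag_count_outlier <- in_pop & bins$breakpoint_count > fence_bp
  bins$flag_recurrence_outlier <- in_pop & bins$sample_count > fence_n
  bins$hotspot <- bins$flag_count_outlier | bins$flag_recurrence_outlier
  attr(bins, "summary") <- summ
  attr(bins, "params") <- params
  bins
}

#' Nominate candidate driver genes for hotspots
#'
#' For each hotspot bin, computes per overlapping gene the fraction of the
#' bin's breakpoints falling inside the gene union span and the fraction of
#' the bin's contributing samples with at least one breakend in the gene
#' (within the bin; gene overlap is strand-ignored). The gene maximising the
#' breakpoint fraction (ties broken lexicographically) is nominated when
#' either fraction strictly exceeds its threshold.
#'
#' @param bins data.frame from [callHotspots()].
#' @param x The [SvCallSet-class] the bins were computed from.
#' @param genes [GenomicRanges::GRanges] from [geneUnionIntervals()].
#' @param params [hotspotParams()].
#' @return `bins` with added `nominated_gene`, `gene_breakpoint_fraction`,
#'   `gene_sample_fraction`.
#' @export
nominateGenes <- function(bins, x, genes, params = hotspotParams()) {
  be <- breakendPositions(x)
  bins$nominated_gene <- NA_character_
  bins$gene_breakpoint_fraction <- NA_real_
  bins$gene_sample_fraction <- NA_real_
  hs <- which(bins$hotspot)
  if (length(hs) == 0 || length(genes) == 0) return(bins)
  be_gr <- GRanges(be$chrom, IRanges(be$pos, be$pos))
  hits <- suppressWarnings(findOverlaps(be_gr, genes, ignore.strand = TRUE))
  for (h in hs) {
    in_bin <- which(be$chrom == bins$chrom[h] &
                      be$pos >= bins$start[h] & be$pos <= bins$end[h])
    if (length(in_bin) == 0) next
    n_bp <- length(in_bin)
    bin_samples <- unique(be$sample_id[in_bin])
    hh <- hits[queryHits(hits) %in% in_bin]
    if (length(hh) == 0) next
    gene_of <- genes$gene_symbol[subjectHits(hh)]
    q <- queryHits(hh)
    bp_frac <- tapply(rep(1, length(hh)), gene_of, sum) / n_bp
    smp_frac <- vapply(split(q, gene_of), function(ii)
      length(unique(be$sample_id[ii])), numeric(1)) / length(bin_samples)
    gsyms <- sort(names(bp_frac))
    best <- gsyms[which.max(bp_frac[gsyms])]
    if (bp_frac[best] > params$min_gene_breakpoint_fraction ||
        smp_frac[best] > params$min_gene_sample_fraction) {
      bins$nominated_gene[h] <- best
      bins$gene_breakpoint_fraction[h] <- unname(bp_frac[best])
      bins$gene_sample_fraction[h] <- unname(smp_frac[best])
    }
  }
  bins
}

#' Ancestry composition of hotspots
#'
#' For each hotspot bin, the African fraction of its breakpoints and of its
#' contributing samples (admixed samples excluded from both denominators),
#' and the p-value of a 2x2 Pearson chi-squared test without continuity
#' correction (sample contributes to the bin: yes/no, against ancestry
#' African/European). Bins without African/European contributors are
#' flagged undefined.
#'
#' @param bins data.frame from [callHotspots()].
#' @param x The [SvCallSet-class] the bins were computed from.
#' @param metadata Cohort metadata covering all contributing samples.
#' @return `bins` with added `african_breakpoint_fraction`,
#'   `african_sample_fraction`, `chi2_p`, `ancestry_undefined`.
#' @export
ancestryComposition <- function(bins, x, metadata) {
  be <- breakendPositions(x)
  anc <- setNames(metadata$ancestry, metadata$sample_id)
  if (any(!(be$sample_id %in% names(anc)))) {
    stopf("sample(s) missing from metadata: %s",
          paste(setdiff(unique(be$sample_id), names(anc)), collapse = ", "))
  }
  cohort <- metadata$sample_id[metadata$ancestry %in% c("African", "European")]
  bins$african_breakpoint_fraction <- NA_real_
  bins$african_sample_fraction <- NA_real_
  bins$chi2_p <- NA_real_
  bins$ancestry_undefined <- NA
  for (h in which(bins$hotspot)) {
    in_bin <- be$chrom == bins$chrom[h] &
      be$pos >= bins$start[h] & be$pos <= bins$end[h]
    be_anc <- anc[be$sample_id[in_bin]]
    contrib <- unique(be$sample_id[in_bin])
    contrib_ae <- contrib[anc[contrib] %in% c("African", "European")]
    if (length(contrib_ae) == 0) {
      bins$ancestry_undefined[h] <- TRUE
      next
    }
    bins$ancestry_undefined[h] <- FALSE
    keep_bp <- be_anc %in% c("African", "European")
    bins$african_breakpoint_fraction[h] <- mean(be_anc[keep_bp] == "African")
    bins$african_sample_fraction[h] <- mean(anc[contrib_ae] == "African")
    tab <- table(
      factor(cohort %in% contrib_ae, levels = c(TRUE, FALSE)),
      factor(anc[cohort], levels = c("African", "European"))
    )
    if (all(dim(tab) == c(2, 2)) && all(colSums(tab) > 0)) {
      bins$chi2_p[h] <- suppressWarnings(
        chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  bins
}
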