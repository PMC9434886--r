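## Shared fixtures and independent oracles for the test suite.

## quick constructor for canonical call tables
makeCalls <- function(svtype, chrom1, pos1, strand1,
                      chrom2 = chrom1, pos2 = NA, strand2 = NA,
                      sample_id = "s1", caller_id = "test",
                      high_confidence = TRUE, qual = 500, insert_len = NA) {
  SvCallSet(data.frame(
    sample_id = sample_id, caller_id = caller_id, svtype = svtype,
    chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
    chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
    high_confidence = high_confidence, qual = qual, insert_len = insert_len,
    stringsAsFactors = FALSE
  ))
}

## write raw VCF text with the standard header used by the package
writeRawVcf <- function(body_lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate id">',
    '##INFO=<ID=INSLEN,Number=1,Type=Integer,Description="Insert length">',
    '##FILTER=<ID=LowQual,Description="low">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

## independent all-pairs greedy matching oracle for the concordance rule:
## repeated full scans picking the minimum-distance candidate with the
## documented tie-break, never reusing a call.
bruteMatch <- function(a, b, tol = 5, hc_min = 1) {
  da <- svCalls(a); db <- svCalls(b)
  cand <- list()
  for (i in seq_len(nrow(da))) {
    for (j in seq_len(nrow(db))) {
      if (da$svtype[i] != db$svtype[j]) next
      if (da$chrom1[i] != db$chrom1[j]) next
      d1 <- abs(da$pos1[i] - db$pos1[j])
      if (d1 > tol) next
      if (da$svtype[i] == "INS") {
        d <- d1
      } else {
        if (da$chrom2[i] != db$chrom2[j]) next
        d2 <- abs(da$pos2[i] - db$pos2[j])
        if (d2 > tol) next
        d <- d1 + d2
      }
      cand[[length(cand) + 1]] <- c(i = i, j = j, d = d)
    }
  }
  if (length(cand) == 0) return(data.frame(i = integer(), j = integer()))
  cand <- as.data.frame(do.call(rbind, cand))
  keyOf <- function(r) {
    i <- r[["i"]]; j <- r[["j"]]
    c(r[["d"]],
      da$chrom1[i], da$pos1[i],
      ifelse(is.na(da$chrom2[i]), "", da$chrom2[i]),
      ifelse(is.na(da$pos2[i]), -1, da$pos2[i]),
      db$chrom1[j], db$pos1[j],
      ifelse(is.na(db$chrom2[j]), "", db$chrom2[j]),
      ifelse(is.na(db$pos2[j]), -1, db$pos2[j]), i, j)
  }
  lessThan <- function(k1, k2) {
    num <- c(1, 3, 5, 7, 9, 10, 11)  # numeric key positions
    for (p in seq_along(k1)) {
      v1 <- k1[p]; v2 <- k2[p]
      if (p %in% num) { v1 <- as.numeric(v1); v2 <- as.numeric(v2) }
      if (v1 < v2) return(TRUE)
      if (v1 > v2) return(FALSE)
    }
    FALSE
  }
  sel <- list()
  used_a <- rep(FALSE, nrow(da)); used_b <- rep(FALSE, nrow(db))
  repeat {
    avail <- which(!used_a[cand$i] & !used_b[cand$j])
    if (length(avail) == 0) break
    best <- avail[1]
    for (r in avail[-1]) {
      if (lessThan(keyOf(cand[r, ]), keyOf(cand[best, ]))) best <- r
    }
    sel[[length(sel) + 1]] <- cand[best, c("i", "j")]
    used_a[cand$i[best]] <- TRUE
    used_b[cand$j[best]] <- TRUE
  }
  out <- do.call(rbind, sel)
  out <- out[(da$high_confidence[out$i] + db$high_confidence[out$j]) >= hc_min, ,
             drop = FALSE]
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## hand-coded step-up BH oracle
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  ranked <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(1, ranked)
  out
}

## linear interpolation quantile at position p*(n-1), coded independently
quartileOracle <- function(x, p) {
  s <- sort(x)
  h <- p * (length(s) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

## Pearson chi-squared p for a 2x2 table, from the textbook formula
pearsonChi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

## a small deterministic two-gene minus-strand annotation mirroring the
## package's emulated fusion locus
fusionTranscripts <- function() {
  svscape:::fusionPartnerTranscripts()
}

## config helpers -------------------------------------------------------
noPlants <- function() list(
  hyper_plants = data.frame(type = character(), ancestry = character(),
                            stringsAsFactors = FALSE),
  fusion_plants = data.frame(mechanism = character(), ancestry = character(),
                             stringsAsFactors = FALSE),
  biallelic_plants = data.frame(gene = character(), klass = character(),
                                host = character(), stringsAsFactors = FALSE),
  assoc_plant = NULL
)

cleanCaller <- function(jitter_b = 0, dropout_a = 0, dropout_b = 0,
                        false_rate = 0, hc_flip = 0) {
  list(jitter_max_a = 0, jitter_max_b = jitter_b,
       dropout_a = dropout_a, dropout_b = dropout_b,
       false_rate = false_rate, hc_flip = hc_flip)
}
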