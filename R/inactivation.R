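#' Gene-level copy-number state
#'
#' GISTIC-style discretisation of continuous gene copy-number values:
#' values exceeding the per-sample high-level thresholds map to +/-2, values
#' exceeding the fixed low-level thresholds (0.1 and -0.1) but not the
#' high-level thresholds map to +/-1, anything else to 0. The function is a
#' monotone step function of the value.
#'
#' @param value Numeric vector of gene CN values.
#' @param high_gain,high_loss Per-sample high-level thresholds (recycled
#'   against `value`); `high_gain >= low_gain`, `high_loss <= low_loss`.
#' @param low_gain,low_loss Fixed low-level thresholds (defaults 0.1, -0.1).
#' @return Integer vector of states in {-2, -1, 0, 1, 2}.
#' @export
geneCnState <- function(value, high_gain, high_loss,
                        low_gain = 0.1, low_loss = -0.1) {
  stopifnot(all(high_gain >= low_gain), all(high_loss <= low_loss))
  out <- integer(length(value))
  out[value > low_gain] <- 1L
  out[value > high_gain] <- 2L
  out[value < low_loss] <- -1L
  out[value < high_loss] <- -2L
  out
}

#' Apply per-sample thresholds to a gene CN table
#'
#' @param cn data.frame with `sample_id`, `gene`, `value`.
#' @param thresholds data.frame with `sample_id`, `high_gain`, `high_loss`.
#' @param low_gain,low_loss Fixed low-level thresholds.
#' @return `cn` with an added integer `state` column.
#' @export
cnGeneCalls <- function(cn, thresholds, low_gain = 0.1, low_loss = -0.1) {
  m <- match(cn$sample_id, thresholds$sample_id)
  if (any(is.na(m))) {
    stopf("sample(s) missing CN thresholds: %s",
          paste(unique(cn$sample_id[is.na(m)]), collapse = ", "))
  }
  cn$state <- geneCnState(cn$value, thresholds$high_gain[m],
                          thresholds$high_loss[m], low_gain, low_loss)
  cn
}

#' Build the sample-by-gene mutation-evidence matrix
#'
#' Assembles, for every sample and every gene of `gene_list`, the boolean
#' evidence flags used for recurrence displays and association testing:
#' `coding_mut` (SNV/indel in coding region: nonsynonymous or synonymous
#' effect), `noncoding_mut`, `cn_gain` (state +2), `cn_loss` (state -2), and
#' `sv_break` (any SV breakend inside the gene union span). Genes absent
#' from the annotation are dropped with a warning.
#'
#' @param small_variants data.frame with `sample_id`, `gene`, `origin`
#'   (germline/somatic), `klass` (SNV/indel), `effect` (nonsynonymous /
#'   synonymous / noncoding).
#' @param cn_calls data.frame from [cnGeneCalls()] (`sample_id`, `gene`,
#'   `state`).
#' @param x [SvCallSet-class] of the cohort.
#' @param genes [GenomicRanges::GRanges] from [geneUnionIntervals()].
#' @param gene_list Character vector of genes to include (e.g. a driver
#'   list).
#' @param samples Character vector of samples (rows of the matrices).
#' @return Named list of logical samples-by-genes matrices
#'   (`coding_mut`, `noncoding_mut`, `cn_gain`, `cn_loss`, `sv_break`),
#'   class `mutation_matrix`.
#' @export
buildMutationMatrix <- function(small_variants, cn_calls, x, genes,
                                gene_list, samples) {
  known <- gene_list %in% genes$gene_symbol
  if (any(!known)) {
    warnf("gene(s) absent from annotation dropped: %s",
          paste(gene_list[!known], collapse = ", "))
    gene_list <- gene_list[known]
  }
  mk <- function() matrix(FALSE, length(samples), length(gene_list),
                          dimnames = list(samples, gene_list))
  mm <- list(coding_mut = mk(), noncoding_mut = mk(),
             cn_gain = mk(), cn_loss = mk(), sv_break = mk())
  setFlags <- function(mat, s, g) {
    ok <- s %in% samples & g %in% gene_list
    mat[cbind(s[ok], g[ok])] <- TRUE
    mat
  }
  if (nrow(small_variants) > 0) {
    coding <- small_variants$effect %in% c("nonsynonymous", "synonymous")
    mm$coding_mut <- setFlags(mm$coding_mut,
                              small_variants$sample_id[coding],
                              small_variants$gene[coding])
    mm$noncoding_mut <- setFlags(mm$noncoding_mut,
                                 small_variants$sample_id[!coding],
                                 small_variants$gene[!coding])
  }
  if (nrow(cn_calls) > 0) {
    gain <- cn_calls$state == 2
    loss <- cn_calls$state == -2
    mm$cn_gain <- setFlags(mm$cn_gain, cn_calls$sample_id[gain],
                           cn_calls$gene[gain])
    mm$cn_loss <- setFlags(mm$cn_loss, cn_calls$sample_id[loss],
                           cn_calls$gene[loss])
  }
  be <- breakendPositions(x)
  if (nrow(be) > 0) {
    gsub <- genes[genes$gene_symbol %in% gene_list]
    hits <- suppressWarnings(findOverlaps(
      GRanges(be$chrom, IRanges(be$pos, be$pos)), gsub,
      ignore.strand = TRUE))
    mm$sv_break <- setFlags(mm$sv_break,
                            be$sample_id[queryHits(hits)],
                            gsub$gene_symbol[subjectHits(hits)])
  }
  structure(mm, class = "mutation_matrix", samples = samples,
            genes = gene_list)
}

#' Combine evidence flags into a mutated mask
#'
#' @param mm [buildMutationMatrix()] result.
#' @param evidence Which flags count as "mutated" (default: coding
#'   mutations, high-level CN changes and SV breaks).
#' @return Logical samples-by-genes matrix.
#' @export
mutatedMask <- function(mm, evidence = c("coding_mut", "cn_gain",
                                         "cn_loss", "sv_break")) {
  Reduce(`|`, mm[evidence])
}

#' Recurrently mutated genes within hyper-SV groups
#'
#' Returns the genes mutated in at least `min_samples` samples within every
#' hyper-SV subtype group present among the labelled samples.
#'
#' @param mm [buildMutationMatrix()] result.
#' @param subtype_calls data.frame from [classifyHyperSv()].
#' @param min_samples Minimum mutated samples per group (default 3).
#' @param evidence Evidence mask passed to [mutatedMask()].
#' @return Character vector of gene symbols.
#' @export
recurrentGenes <- function(mm, subtype_calls, min_samples = 3,
                           evidence = c("coding_mut", "cn_gain",
                                        "cn_loss", "sv_break")) {
  mask <- mutatedMask(mm, evidence)
  groups <- setdiff(unique(subtype_calls$label), "none")
  if (length(groups) == 0) return(character())
  ok <- rep(TRUE, ncol(mask))
  for (g in groups) {
    s <- intersect(subtype_calls$sample_id[subtype_calls$label == g],
                   rownames(mask))
    ok <- ok & colSums(mask[s, , drop = FALSE]) >= min_samples
  }
  colnames(mask)[ok]
}

#' Classify biallelic gene inactivation
#'
#' Applies the four-class biallelic inactivation scheme to assembled
#' per-(sample, gene) evidence, evaluated from the most to the least direct
#' copy-number evidence: `Loss/Loss` (two exon-overlapping deletions and
#' allele-specific CN of 0 for both alleles), `Loss/Mutation` (loss of one
#' allele plus a nonsynonymous SNV), `Loss/Break` (loss of one allele plus
#' an SV breakpoint interrupting an exon), `Mutation/Mutation` (a
#' nonsynonymous germline and a nonsynonymous somatic SNV of the same
#' gene); `none` otherwise. Allele loss means a negative CN state (-1 or
#' -2) or an allele-specific count of 0 on one allele. All satisfied
#' classes are also listed in `all_classes`.
#'
#' @param evidence data.frame with one row per (sample, gene):
#'   `sample_id`, `gene`, `cn_state`, `allele_a`, `allele_b`
#'   (allele-specific copy counts), `exon_del_count` (deletions overlapping
#'   an exon), `somatic_nonsyn`, `germline_nonsyn`, `exon_break` (SV
#'   breakend inside an exon), all logical except the counts.
#' @return `evidence` with added `klass` and `all_classes` columns.
#' @export
classifyBiallelic <- function(evidence) {
  loss <- evidence$cn_state < 0 |
    (pmin(evidence$allele_a, evidence$allele_b) == 0)
  c_ll <- evidence$allele_a == 0 & evidence$allele_b == 0 &
    evidence$exon_del_count >= 2
  c_lm <- loss & (evidence$somatic_nonsyn | evidence$germline_nonsyn)
  c_lb <- loss & evidence$exon_break
  c_mm <- evidence$somatic_nonsyn & evidence$germline_nonsyn
  klass <- rep("none", nrow(evidence))
  klass[c_mm] <- "Mutation/Mutation"
  klass[c_lb] <- "Loss/Break"
  klass[c_lm] <- "Loss/Mutation"
  klass[c_ll] <- "Loss/Loss"
  evidence$klass <- klass
  evidence$all_classes <- vapply(seq_len(nrow(evidence)), function(i) {
    paste(c("Loss/Loss", "Loss/Mutation", "Loss/Break",
            "Mutation/Mutation")[c(c_ll[i], c_lm[i], c_lb[i], c_mm[i])],
          collapse = ";")
  }, character(1))
  evidence
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Input p-values outside [0, 1] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

## Firth-penalized univariate logistic regression with a penalized
## likelihood-ratio test against the intercept-only model; used as the
## fallback under complete separation, where the unpenalized MLE diverges.
firthLogisticLRT <- function(x, y, maxit = 100, tol = 1e-8) {
  fitOne <- function(X) {
    beta <- rep(0, ncol(X))
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% beta)
      p <- plogis(eta)
      W <- p * (1 - p)
      XtW <- t(X * W)
      Iinf <- XtW %*% X
      Iinv <- solve(Iinf + diag(1e-10, ncol(X)))
      h <- rowSums((X %*% Iinv) * (X * W))
      U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
      step <- drop(Iinv %*% U)
      if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
      beta <- beta + step
      if (max(abs(step)) < tol) break
    }
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    Iinf <- t(X * (p * (1 - p))) %*% X
    list(beta = beta, pll = ll + 0.5 * determinant(Iinf)$modulus)
  }
  n <- length(y)
  full <- fitOne(cbind(1, x))
  null <- fitOne(matrix(1, n, 1))
  stat <- max(0, 2 * (full$pll - null$pll))
  list(coefficient = full$beta[2],
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Test association between SV burden and gene mutation
#'
#' For each (gene, SV type, burden measure) combination, fits a logistic
#' regression of the binary mutation status on the per-tumour burden (total
#' count or relative frequency of the type) and reports the
#' likelihood-ratio p-value of the single-predictor model against the
#' intercept-only model. Combinations with fewer than two samples in either
#' outcome class, or a constant predictor, are flagged untestable. Complete
#' separation is flagged and the p-value is taken from a Firth-penalized
#' fit. Benjamini-Hochberg adjustment is applied across all testable
#' combinations in the run.
#'
#' @param spectra data.frame from [svSpectrum()].
#' @param mutated Logical samples-by-genes matrix from [mutatedMask()] (its
#'   rows must cover the spectra samples).
#' @param genes Genes to test (default all columns of `mutated`).
#' @param svtypes SV types to test (default all five).
#' @param measures `"count"`, `"rel_freq"` or both (default both).
#' @return data.frame with one row per test: `gene`, `svtype`, `measure`,
#'   `n`, `coefficient`, `p_value`, `adjusted_p`, `untestable`,
#'   `separation`, `note`.
#' @export
testSvBurdenAssociation <- function(spectra, mutated,
                                    genes = colnames(mutated),
                                    svtypes = SV_TYPES,
                                    measures = c("count", "rel_freq")) {
  rows <- list()
  for (g in genes) {
    y <- as.integer(mutated[spectra$sample_id, g])
    for (t in svtypes) {
      for (m in measures) {
        xcol <- if (m == "count") paste0("n_", t) else paste0("rf_", t)
        xv <- spectra[[xcol]]
        res <- data.frame(gene = g, svtype = t, measure = m,
                          n = length(y), coefficient = NA_real_,
                          p_value = NA_real_, untestable = FALSE,
                          separation = FALSE, note = "",
                          stringsAsFactors = FALSE)
        if (min(table(factor(y, levels = 0:1))) < 2 || var(xv) == 0) {
          res$untestable <- TRUE
          res$note <- "fewer than 2 samples per class or constant predictor"
        } else {
          w <- withCallingHandlers(
            fit <- glm(y ~ xv, family = binomial()),
            warning = function(cond) invokeRestart("muffleWarning")
          )
          sep <- !fit$converged || any(fit$fitted.values < 1e-8) ||
            any(fit$fitted.values > 1 - 1e-8) || abs(coef(fit)[2]) > 15
          if (sep) {
            fl <- firthLogisticLRT(xv, y)
            res$coefficient <- fl$coefficient
            res$p_value <- fl$p_value
            res$separation <- TRUE
            res$note <- "complete separation; Firth-penalized LRT"
          } else {
            res$coefficient <- unname(coef(fit)[2])
            res$p_value <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                                  lower.tail = FALSE)
          }
        }
        rows[[paste(g, t, m)]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- NA_real_
  testable <- !out$untestable
  if (any(testable)) out$adjusted_p[testable] <- bhAdjust(out$p_value[testable])
  out
}
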