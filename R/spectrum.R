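#' Per-tumour SV-type spectra
#'
#' Tallies, for every sample, the number of events of each SV type (a
#' translocation mate pair counts as one event) and the relative frequency
#' of each type. Samples without calls get zero counts and zero relative
#' frequencies.
#'
#' @param x An [SvCallSet-class].
#' @param samples Optional character vector of samples to report (defaults
#'   to the samples present in `x`); samples without calls are reported with
#'   zeros.
#' @return data.frame with one row per sample: `sample_id`, `n_DEL` ...
#'   `n_TRA`, `total`, `rf_DEL` ... `rf_TRA`.
#' @export
svSpectrum <- function(x, samples = NULL) {
  df <- svCalls(x)
  if (is.null(samples)) samples <- sort(unique(df$sample_id))
  tab <- table(factor(df$sample_id, levels = samples),
               factor(df$svtype, levels = SV_TYPES))
  counts <- as.data.frame.matrix(tab)
  total <- rowSums(counts)
  rf <- counts / ifelse(total == 0, 1, total)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (t in SV_TYPES) out[[paste0("n_", t)]] <- counts[[t]]
  out$total <- as.numeric(total)
  for (t in SV_TYPES) out[[paste0("rf_", t)]] <- rf[[t]]
  rownames(out) <- NULL
  out
}

#' Hyper-SV subtype parameters
#'
#' @param min_total Minimum total SV count for a hyper-SV label (default
#'   100, the cohort-average SV count the definition is anchored to).
#' @param dominance Minimum fraction of the total contributed by a single
#'   SV type (default 0.5). Both thresholds are inclusive.
#' @return List of class `subtype_params`.
#' @export
subtypeParams <- function(min_total = 100, dominance = 0.5) {
  stopifnot(min_total >= 0, dominance > 0, dominance <= 1)
  structure(list(min_total = min_total, dominance = dominance),
            class = "subtype_params")
}

#' Hyper-SV subtype classification
#'
#' A tumour is a hyper-SV subtype when it carries at least `min_total` SVs
#' of which at least a `dominance` fraction belong to a single type; the
#' label is derived from the dominant type (hyper-deleted, hyper-duplicated,
#' hyper-inverted, hyper-translocated, hyper-inserted). The dominant type is
#' the argmax count with ties broken in the fixed order DEL < DUP < INV <
#' TRA < INS; an exact tie at the top is flagged and left unlabelled.
#'
#' @param spectra data.frame from [svSpectrum()].
#' @param params [subtypeParams()].
#' @return data.frame: `sample_id`, `label`, `dominant_type`,
#'   `dominant_fraction`, `total`, `tie`.
#' @export
classifyHyperSv <- function(spectra, params = subtypeParams()) {
  labels <- c(DEL = "hyper-deleted", DUP = "hyper-duplicated",
              INV = "hyper-inverted", TRA = "hyper-translocated",
              INS = "hyper-inserted")
  cn <- paste0("n_", SV_TYPE_TIE_ORDER)
  counts <- as.matrix(spectra[, cn, drop = FALSE])
  top <- apply(counts, 1, max)
  which_top <- apply(counts, 1, which.max)  # first in tie order
  tie <- rowSums(counts == top) > 1 & top > 0
  dominant <- SV_TYPE_TIE_ORDER[which_top]
  dominant[spectra$total == 0] <- NA_character_
  frac <- ifelse(spectra$total == 0, 0, top / spectra$total)
  hyper <- spectra$total >= params$min_total & frac >= params$dominance & !tie
  data.frame(
    sample_id = spectra$sample_id,
    label = ifelse(hyper, unname(labels[dominant]), "none"),
    dominant_type = dominant,
    dominant_fraction = frac,
    total = spectra$total,
    tie = tie,
    stringsAsFactors = FALSE
  )
}

#' Ancestry fold changes of SV burden by type
#'
#' For each SV type, the mean per-tumour count and mean relative frequency
#' within each ancestry group, and the African/European ratio of those means
#' (admixed samples are reported but excluded from the ratio). A zero
#' European mean yields a flagged undefined fold.
#'
#' @param spectra data.frame from [svSpectrum()].
#' @param metadata Cohort metadata with `sample_id` and `ancestry`; every
#'   spectra sample must be present.
#' @return data.frame with one row per SV type: per-ancestry means,
#'   `fold_count`, `fold_rel_freq`, `fold_undefined`.
#' @export
ancestryFoldChange <- function(spectra, metadata) {
  anc <- metadata$ancestry[match(spectra$sample_id, metadata$sample_id)]
  if (any(is.na(anc))) {
    stopf("sample(s) missing from metadata: %s",
          paste(spectra$sample_id[is.na(anc)], collapse = ", "))
  }
  groups <- c("African", "European", "Admixed")
  rows <- lapply(SV_TYPES, function(t) {
    mc <- vapply(groups, function(g)
      mean(spectra[[paste0("n_", t)]][anc == g]), numeric(1))
    mr <- vapply(groups, function(g)
      mean(spectra[[paste0("rf_", t)]][anc == g]), numeric(1))
    undef <- is.na(mc["European"]) || mc["European"] == 0 ||
      is.na(mr["European"]) || mr["European"] == 0
    data.frame(
      svtype = t,
      mean_count_African = mc["African"], mean_count_European = mc["European"],
      mean_count_Admixed = mc["Admixed"],
      mean_rf_African = mr["African"], mean_rf_European = mr["European"],
      mean_rf_Admixed = mr["Admixed"],
      fold_count = if (undef) NA_real_ else mc["African"] / mc["European"],
      fold_rel_freq = if (undef) NA_real_ else mr["African"] / mr["European"],
      fold_undefined = undef,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
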