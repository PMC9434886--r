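#' SvCallSet: a set of somatic SV calls
#'
#' An `SvCallSet` holds somatic structural-variant calls in the canonical
#' internal table: one row per event, each event described by up to two
#' breakends. Coordinates are 1-based. Breakend orientation uses `+` for
#' "retained segment extends to the left of the position" (the break is at
#' the segment's right end) and `-` for the converse, matching VCF breakend
#' bracket semantics. Translocations (`TRA`) are stored once per mate pair
#' with the two ends in canonical order (lexicographic chromosome, then
#' position); insertions may carry a single breakend (`pos2` is `NA`).
#'
#' @slot calls data.frame with columns `sample_id`, `caller_id`, `svtype`
#'   (one of DEL, DUP, INS, INV, TRA), `chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `high_confidence`, `qual`, `insert_len`. Additional
#'   columns (provenance etc.) are preserved.
#'
#' @aliases SvCallSet-class
#' @export
setClass("SvCallSet", representation(calls = "data.frame"))

setValidity("SvCallSet", function(object) {
  df <- object@calls
  miss <- setdiff(SV_TABLE_COLS, names(df))
  if (length(miss) > 0) {
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) return(TRUE)
  msgs <- character()
  if (!all(df$svtype %in% SV_TYPES)) {
    msgs <- c(msgs, paste("svtype must be one of", paste(SV_TYPES, collapse = "/")))
  }
  if (any(is.na(df$pos1)) || any(df$pos1 < 1)) {
    msgs <- c(msgs, "pos1 must be >= 1 and non-missing")
  }
  if (!all(df$strand1 %in% c("+", "-"))) {
    msgs <- c(msgs, "strand1 must be '+' or '-'")
  }
  two <- !is.na(df$pos2)
  if (any(two & !(df$strand2 %in% c("+", "-")))) {
    msgs <- c(msgs, "strand2 must be '+' or '-' for two-breakend events")
  }
  if (any(!two & df$svtype != "INS")) {
    msgs <- c(msgs, "only INS may lack a second breakend")
  }
  tra <- df$svtype == "TRA"
  if (any(tra & (df$chrom1 == df$chrom2))) {
    msgs <- c(msgs, "TRA requires chrom1 != chrom2")
  }
  simple <- df$svtype %in% c("DEL", "DUP", "INV") & two
  if (any(simple & df$chrom1 != df$chrom2)) {
    msgs <- c(msgs, "DEL/DUP/INV require chrom1 == chrom2")
  }
  if (any(simple & df$pos1 >= df$pos2)) {
    msgs <- c(msgs, "DEL/DUP/INV require pos1 < pos2")
  }
  if (!is.logical(df$high_confidence)) {
    msgs <- c(msgs, "high_confidence must be logical")
  }
  if (length(msgs) > 0) return(msgs)
  TRUE
})

#' Construct an SvCallSet
#'
#' Builds an [SvCallSet-class] from a data.frame of calls, filling defaults
#' for optional columns (`high_confidence = TRUE`, `qual = NA`,
#' `insert_len = NA`) and putting translocation mate ends into canonical
#' order (lexicographic chromosome, then position).
#'
#' @param calls data.frame with at least `sample_id`, `caller_id`, `svtype`,
#'   `chrom1`, `pos1`, `strand1` and, for two-breakend events, `chrom2`,
#'   `pos2`, `strand2`.
#' @return An `SvCallSet`.
#' @export
SvCallSet <- function(calls = emptySvTable()) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) > 0) {
    if (is.null(calls$chrom2)) calls$chrom2 <- NA_character_
    if (is.null(calls$pos2)) calls$pos2 <- NA_real_
    if (is.null(calls$strand2)) calls$strand2 <- NA_character_
    if (is.null(calls$high_confidence)) calls$high_confidence <- TRUE
    if (is.null(calls$qual)) calls$qual <- NA_real_
    if (is.null(calls$insert_len)) calls$insert_len <- NA_real_
    calls <- canonicalizeEnds(calls)
  }
  calls <- calls[, c(SV_TABLE_COLS, setdiff(names(calls), SV_TABLE_COLS)), drop = FALSE]
  rownames(calls) <- NULL
  new("SvCallSet", calls = calls)
}

emptySvTable <- function() {
  data.frame(
    sample_id = character(), caller_id = character(), svtype = character(),
    chrom1 = character(), pos1 = numeric(), strand1 = character(),
    chrom2 = character(), pos2 = numeric(), strand2 = character(),
    high_confidence = logical(), qual = numeric(), insert_len = numeric(),
    stringsAsFactors = FALSE
  )
}

## put inter-chromosomal mate ends in canonical order (lexicographic
## chromosome); strands travel with their breakend. Intra-chromosomal
## events must already satisfy pos1 < pos2 (validity enforces it).
canonicalizeEnds <- function(df) {
  two <- !is.na(df$pos2)
  swap <- two & df$chrom1 != df$chrom2 & df$chrom1 > df$chrom2
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <-
      df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  df
}

#' @describeIn SvCallSet Accessor: the calls table (data.frame).
#' @param x,object An `SvCallSet`.
#' @export
svCalls <- function(x) {
  stopifnot(is(x, "SvCallSet"))
  x@calls
}

#' @describeIn SvCallSet Accessor: sorted unique sample identifiers.
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "SvCallSet"))
  sort(unique(x@calls$sample_id))
}

#' @describeIn SvCallSet Number of calls.
#' @export
setMethod("length", "SvCallSet", function(x) nrow(x@calls))

setMethod("show", "SvCallSet", function(object) {
  df <- object@calls
  cat(sprintf(
    "SvCallSet with %d call%s from %d sample%s\n",
    nrow(df), if (nrow(df) == 1) "" else "s",
    length(unique(df$sample_id)),
    if (length(unique(df$sample_id)) == 1) "" else "s"
  ))
  if (nrow(df) > 0) {
    tab <- table(factor(df$svtype, levels = SV_TYPES))
    cat("  types: ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  callers: ", paste(unique(df$caller_id), collapse = ", "), "\n")
  }
  invisible(NULL)
})

## internal: subset an SvCallSet to one sample
sampleCalls <- function(x, sample) {
  df <- svCalls(x)
  df[df$sample_id == sample, , drop = FALSE]
}
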