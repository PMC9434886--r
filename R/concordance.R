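#' Concordance parameters
#'
#' Parameters for the cross-caller concordance merge. Two calls are
#' concordant when they have the same SV type, both breakend positions agree
#' within `tolerance_bp`, and at least `high_conf_in_at_least` of the two
#' calls is high-confidence. With `require_presence_in_both = FALSE`,
#' unmatched high-confidence calls from either caller are additionally kept
#' (the looser single-caller variant).
#'
#' @param tolerance_bp Maximum per-breakend distance in bp (default 5).
#' @param require_presence_in_both Require a match in both call sets
#'   (default `TRUE`).
#' @param high_conf_in_at_least Minimum number of callers (of the two) that
#'   must flag the call high-confidence (default 1).
#' @return List of class `concordance_params`.
#' @export
concordanceParams <- function(tolerance_bp = 5,
                              require_presence_in_both = TRUE,
                              high_conf_in_at_least = 1) {
  stopifnot(tolerance_bp >= 0, high_conf_in_at_least %in% 0:2)
  structure(list(
    tolerance_bp = tolerance_bp,
    require_presence_in_both = require_presence_in_both,
    high_conf_in_at_least = high_conf_in_at_least
  ), class = "concordance_params")
}

#' Filter calls to high-confidence
#'
#' Keeps calls whose `high_confidence` flag is set (derived from
#' `FILTER == "PASS"` at import for both dialects), or applies a custom
#' predicate on the call table — the configurable rule used for breakend-only
#' call sets.
#'
#' @param x An [SvCallSet-class].
#' @param predicate Optional `function(calls_df) -> logical` replacing the
#'   default flag lookup.
#' @return Filtered `SvCallSet`.
#' @export
highConfidenceFilter <- function(x, predicate = NULL) {
  df <- svCalls(x)
  keep <- if (is.null(predicate)) df$high_confidence else predicate(df)
  SvCallSet(df[keep %in% TRUE, , drop = FALSE])
}

#' Classify intra-chromosomal breakend pairs into simple SV types
#'
#' Assigns simple event types from breakend orientations: `(+,-)` is a
#' deletion, `(-,+)` a tandem duplication, `(+,+)` or `(-,-)` an inversion.
#' A pair dominated by inserted sequence (insert length greater than
#' `ins_factor` times the spanned distance) is an insertion; insertions are
#' normalised to a single breakend (`pos2` set to `NA`). Rows that already
#' carry a type (typed records, translocations) pass through unchanged.
#'
#' @param events data.frame of events from [pairBreakends()] (or any frame
#'   with `svtype`, `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`, `insert_len`).
#' @param ins_factor Insert-dominance factor (default 1: insert longer than
#'   the span).
#' @return The events frame with `svtype` filled for every row.
#' @export
classifySimpleType <- function(events, ins_factor = 1) {
  todo <- which(is.na(events$svtype))
  if (length(todo) == 0) return(events)
  e <- events[todo, , drop = FALSE]
  if (any(is.na(e$strand1) | is.na(e$strand2))) {
    stopf("cannot classify breakend pair without orientations")
  }
  if (any(e$chrom1 != e$chrom2)) {
    stopf("classifySimpleType applies to intra-chromosomal pairs only")
  }
  span <- e$pos2 - e$pos1
  is_ins <- !is.na(e$insert_len) & e$insert_len > span * ins_factor
  key <- paste(e$strand1, e$strand2)
  type <- c("+ -" = "DEL", "- +" = "DUP", "+ +" = "INV", "- -" = "INV")[key]
  if (any(is.na(type))) stopf("unexpected orientation pair: %s",
                              paste(unique(key[is.na(type)]), collapse = ", "))
  type[is_ins] <- "INS"
  events$svtype[todo] <- unname(type)
  ## normalise insertions to a single breakend
  ins_rows <- todo[is_ins]
  if (length(ins_rows) > 0) {
    events$chrom2[ins_rows] <- NA_character_
    events$pos2[ins_rows] <- NA_real_
    events$strand2[ins_rows] <- NA_character_
  }
  events
}

## per-candidate breakpoint distance; INS compared on the single position
pairDistance <- function(a, b) {
  d1 <- abs(a$pos1 - b$pos1)
  d2 <- abs(a$pos2 - b$pos2)
  ifelse(a$svtype == "INS", d1, d1 + d2)
}

#' Match two single-sample call sets into concordant SVs
#'
#' Implements the cross-caller concordance rule: candidate pairs must have
#' identical SV type and both breakpoint positions within
#' `params$tolerance_bp` of each other (translocations additionally require
#' both chromosomes to agree after canonical ordering; insertions are
#' compared on their single position). Among candidates a one-to-one greedy
#' matching by ascending total breakpoint distance is applied, ties broken by
#' genomic order, and each input call is used at most once. A matched pair
#' is emitted if it is high-confidence in at least
#' `params$high_conf_in_at_least` of the two callers; merged coordinates are
#' taken from caller A.
#'
#' @param calls_a,calls_b [SvCallSet-class] objects holding calls of the
#'   same single sample from the two callers.
#' @param params [concordanceParams()].
#' @return `SvCallSet` of concordant calls (caller id `"consensus"`), with
#'   provenance columns `idx_a`, `idx_b` (row numbers in the inputs),
#'   `hc_a`, `hc_b`.
#' @export
matchCalls <- function(calls_a, calls_b, params = concordanceParams()) {
  a <- svCalls(calls_a); b <- svCalls(calls_b)
  sa <- unique(a$sample_id); sb <- unique(b$sample_id)
  if (length(sa) > 1 || length(sb) > 1) stopf("matchCalls expects single-sample call sets")
  if (length(sa) == 1 && length(sb) == 1 && sa != sb) {
    stopf("call sets are from different samples: %s vs %s", sa, sb)
  }
  tol <- params$tolerance_bp
  cand <- candidatePairs(a, b, tol)
  sel <- greedySelect(cand, a, b)
  keep <- sel[(a$high_confidence[sel$i] + b$high_confidence[sel$j]) >=
                params$high_conf_in_at_least, , drop = FALSE]
  merged <- a[keep$i, , drop = FALSE]
  merged$caller_id <- rep("consensus", nrow(merged))
  merged$high_confidence <- a$high_confidence[keep$i] | b$high_confidence[keep$j]
  merged$idx_a <- keep$i
  merged$idx_b <- keep$j
  merged$hc_a <- a$high_confidence[keep$i]
  merged$hc_b <- b$high_confidence[keep$j]
  if (!params$require_presence_in_both) {
    ua <- setdiff(which(a$high_confidence), keep$i)
    ub <- setdiff(which(b$high_confidence), keep$j)
    extra <- list()
    if (length(ua) > 0) {
      x <- a[ua, , drop = FALSE]
      x$caller_id <- "consensus"
      x$idx_a <- ua; x$idx_b <- NA_integer_
      x$hc_a <- TRUE; x$hc_b <- NA
      extra$a <- x
    }
    if (length(ub) > 0) {
      x <- b[ub, , drop = FALSE]
      x$caller_id <- "consensus"
      x$idx_a <- NA_integer_; x$idx_b <- ub
      x$hc_a <- NA; x$hc_b <- TRUE
      extra$b <- x
    }
    merged <- do.call(rbind, c(list(merged), extra))
  }
  SvCallSet(merged)
}

## all candidate pairs satisfying type + tolerance constraints
candidatePairs <- function(a, b, tol) {
  out <- list()
  for (t in intersect(unique(a$svtype), unique(b$svtype))) {
    ia <- which(a$svtype == t); ib <- which(b$svtype == t)
    g <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
    ok <- a$chrom1[g$i] == b$chrom1[g$j] &
      abs(a$pos1[g$i] - b$pos1[g$j]) <= tol
    if (t == "INS") {
      ## single-position comparison; insert presence is implied by the type
    } else {
      ok <- ok & a$chrom2[g$i] == b$chrom2[g$j] &
        abs(a$pos2[g$i] - b$pos2[g$j]) <= tol
    }
    ok[is.na(ok)] <- FALSE
    out[[t]] <- g[ok, , drop = FALSE]
  }
  if (length(out) == 0) return(data.frame(i = integer(), j = integer()))
  do.call(rbind, out)
}

## greedy one-to-one selection by ascending total distance with a
## deterministic genomic-order tie-break
greedySelect <- function(cand, a, b) {
  if (nrow(cand) == 0) return(data.frame(i = integer(), j = integer()))
  d <- pairDistance(a[cand$i, , drop = FALSE], b[cand$j, , drop = FALSE])
  fill <- function(v, r) { v[is.na(v)] <- r; v }
  o <- order(d,
             a$chrom1[cand$i], a$pos1[cand$i],
             fill(a$chrom2[cand$i], ""), fill(a$pos2[cand$i], -1),
             b$chrom1[cand$j], b$pos1[cand$j],
             fill(b$chrom2[cand$j], ""), fill(b$pos2[cand$j], -1),
             cand$i, cand$j)
  cand <- cand[o, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      keep[r] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

#' Cohort-level cross-caller merge
#'
#' Applies [matchCalls()] sample by sample over two cohort call sets and
#' binds the per-sample concordant sets.
#'
#' @param calls_a,calls_b [SvCallSet-class] objects from the two callers,
#'   any number of samples.
#' @param params [concordanceParams()].
#' @return `SvCallSet` of concordant calls across the cohort.
#' @export
mergeCallers <- function(calls_a, calls_b, params = concordanceParams()) {
  samples <- union(sampleIds(calls_a), sampleIds(calls_b))
  parts <- lapply(samples, function(s) {
    svCalls(matchCalls(
      SvCallSet(sampleCalls(calls_a, s)),
      SvCallSet(sampleCalls(calls_b, s)),
      params
    ))
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) return(SvCallSet())
  SvCallSet(do.call(rbind, parts))
}
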