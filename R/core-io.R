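## ---- VCF import -----------------------------------------------------------

#' Read a somatic SV VCF
#'
#' Reads an SV VCF in one of two caller dialects and returns the raw records
#' needed downstream (CHROM/POS/ID/REF/ALT/FILTER/QUAL and the INFO fields
#' SVTYPE, END, MATEID, INSLEN). The `typed` dialect emits records typed as
#' DEL/DUP/INS/INV plus BND mate pairs for inter-chromosomal junctions; the
#' `bnd-only` dialect emits every junction as a BND mate pair. Positions stay
#' 1-based. Records with an unknown SVTYPE are skipped with a warning and
#' tallied in the `skip_report` attribute; a malformed breakend ALT string is
#' an error naming the record.
#'
#' @param path Path to a VCF 4.2 file.
#' @param dialect `"typed"` or `"bnd-only"`.
#' @return data.frame of records with attributes `dialect` and `skip_report`.
#' @export
readSvVcf <- function(path, dialect = c("typed", "bnd-only")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- rowRanges(vcf)
  n <- length(rr)
  alt <- VariantAnnotation::alt(vcf)
  if (n > 0 && any(S4Vectors::elementNROWS(alt) != 1)) {
    bad <- names(rr)[S4Vectors::elementNROWS(alt) != 1]
    stopf("multi-allelic SV records are not supported: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(field, default) {
    if (field %in% colnames(info)) {
      v <- info[[field]]
      if (is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x) == 0) default else x[1],
                    default)
      }
      v
    } else {
      rep(default, n)
    }
  }
  rec <- data.frame(
    id = if (is.null(names(rr))) sprintf("rec%06d", seq_len(n)) else names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = if (n == 0) character() else as.character(unlist(alt)),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    filter = VariantAnnotation::filt(vcf),
    svtype = as.character(getInfo("SVTYPE", NA_character_)),
    end = as.numeric(getInfo("END", NA_real_)),
    mateid = as.character(getInfo("MATEID", NA_character_)),
    inslen = as.numeric(getInfo("INSLEN", NA_real_)),
    stringsAsFactors = FALSE
  )
  known <- c("DEL", "DUP", "INS", "INV", "BND")
  bad <- !(rec$svtype %in% known)
  skip_report <- table(rec$svtype[bad])
  if (any(bad)) {
    warnf("skipped %d record(s) with unknown SVTYPE (%s)",
          sum(bad), paste(names(skip_report), collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  attr(rec, "dialect") <- dialect
  attr(rec, "skip_report") <- skip_report
  rec
}

## Decompose a VCF breakend ALT string into local orientation, mate
## coordinates, mate orientation and inserted-sequence length. Encoding:
##   t[p[  -> (+, -)     t]p]  -> (+, +)
##   ]p]t  -> (-, +)     [p[t  -> (-, -)
## where the local orientation "+" means the retained segment extends to the
## left of the local position.
parseBreakendAlt <- function(alt, id = alt) {
  pat_tf <- "^([A-Za-z*]+)\\[([^\\[\\]:]+):([0-9]+)\\[$"
  pat_tb <- "^([A-Za-z*]+)\\]([^\\[\\]:]+):([0-9]+)\\]$"
  pat_bt <- "^\\]([^\\[\\]:]+):([0-9]+)\\]([A-Za-z*]+)$"
  pat_ft <- "^\\[([^\\[\\]:]+):([0-9]+)\\[([A-Za-z*]+)$"
  out <- data.frame(
    orient = NA_character_, mate_chrom = NA_character_,
    mate_pos = NA_real_, mate_orient = NA_character_,
    insert_len = NA_real_, stringsAsFactors = FALSE
  )[rep(1, length(alt)), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(alt)) {
    a <- alt[i]
    if (grepl(pat_tf, a, perl = TRUE)) {
      m <- regmatches(a, regexec(pat_tf, a, perl = TRUE))[[1]]
      out[i, ] <- list("+", m[3], as.numeric(m[4]), "-", nchar(m[2]) - 1)
    } else if (grepl(pat_tb, a, perl = TRUE)) {
      m <- regmatches(a, regexec(pat_tb, a, perl = TRUE))[[1]]
      out[i, ] <- list("+", m[3], as.numeric(m[4]), "+", nchar(m[2]) - 1)
    } else if (grepl(pat_bt, a, perl = TRUE)) {
      m <- regmatches(a, regexec(pat_bt, a, perl = TRUE))[[1]]
      out[i, ] <- list("-", m[2], as.numeric(m[3]), "+", nchar(m[4]) - 1)
    } else if (grepl(pat_ft, a, perl = TRUE)) {
      m <- regmatches(a, regexec(pat_ft, a, perl = TRUE))[[1]]
      out[i, ] <- list("-", m[2], as.numeric(m[3]), "-", nchar(m[4]) - 1)
    } else {
      stopf("malformed breakend ALT '%s' in record %s", a, id[i])
    }
  }
  out
}

#' Pair VCF breakend records into SV events
#'
#' Typed records (DEL/DUP/INS/INV) are mapped directly to two-breakend (or,
#' for INS, single-breakend) events with orientations implied by their type.
#' BND records are paired by mutual `MATEID` reference and emitted once per
#' mate pair; inter-chromosomal pairs are annotated as translocations (TRA),
#' intra-chromosomal pairs are left untyped (`svtype = NA`) for
#' [classifySimpleType()]. BND records whose mate is absent are kept as
#' unpaired entries with `paired = FALSE`, for exclusion downstream. A
#' MATEID reference chain that is not a mutual pair is an error.
#'
#' @param records data.frame from [readSvVcf()].
#' @return data.frame of events, one row per event (columns `svtype`,
#'   `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`, `insert_len`,
#'   `pass`, `qual`, `id1`, `id2`, `paired`), with attribute `n_unpaired`.
#' @export
pairBreakends <- function(records) {
  typed <- records[records$svtype %in% c("DEL", "DUP", "INS", "INV"), , drop = FALSE]
  bnd <- records[records$svtype == "BND", , drop = FALSE]

  rows <- list()
  if (nrow(typed) > 0) {
    s1 <- c(DEL = "+", DUP = "-", INS = "+", INV = "+")[typed$svtype]
    s2 <- c(DEL = "-", DUP = "+", INS = NA, INV = "+")[typed$svtype]
    ins <- typed$svtype == "INS"
    rows$typed <- data.frame(
      svtype = typed$svtype,
      chrom1 = typed$chrom, pos1 = typed$pos, strand1 = unname(s1),
      chrom2 = ifelse(ins, NA_character_, typed$chrom),
      pos2 = ifelse(ins, NA_real_, typed$end),
      strand2 = unname(s2),
      insert_len = typed$inslen,
      pass = typed$filter == "PASS",
      qual = typed$qual,
      id1 = typed$id, id2 = NA_character_,
      paired = TRUE, stringsAsFactors = FALSE
    )
    if (any(!ins & is.na(typed$end))) {
      stopf("typed record(s) missing END: %s",
            paste(typed$id[!ins & is.na(typed$end)], collapse = ", "))
    }
  }

  if (nrow(bnd) > 0) {
    be <- parseBreakendAlt(bnd$alt, bnd$id)
    m <- match(bnd$mateid, bnd$id)
    has_mate <- !is.na(bnd$mateid) & !is.na(m)
    ## mutual-reference check: mate's MATEID must point back
    mutual <- has_mate & bnd$mateid[ifelse(is.na(m), 1L, m)] == bnd$id &
      !is.na(bnd$mateid[ifelse(is.na(m), 1L, m)])
    if (any(has_mate & !mutual)) {
      stopf("MATEID chain is not a mutual mate pair for record(s): %s",
            paste(bnd$id[has_mate & !mutual], collapse = ", "))
    }
    ## emit once per pair: keep the record that sorts first
    first <- mutual & (order(order(bnd$chrom, bnd$pos, bnd$id))
                       < order(order(bnd$chrom, bnd$pos, bnd$id))[ifelse(is.na(m), 1L, m)])
    idx <- which(first)
    if (length(idx) > 0) {
      j <- m[idx]
      rows$bnd <- data.frame(
        svtype = ifelse(bnd$chrom[idx] != bnd$chrom[j], "TRA", NA_character_),
        chrom1 = bnd$chrom[idx], pos1 = bnd$pos[idx], strand1 = be$orient[idx],
        chrom2 = bnd$chrom[j], pos2 = bnd$pos[j], strand2 = be$orient[j],
        insert_len = pmax(be$insert_len[idx], be$insert_len[j], na.rm = TRUE),
        pass = bnd$filter[idx] == "PASS" & bnd$filter[j] == "PASS",
        qual = (bnd$qual[idx] + bnd$qual[j]) / 2,
        id1 = bnd$id[idx], id2 = bnd$id[j],
        paired = TRUE, stringsAsFactors = FALSE
      )
    }
    un <- which(!mutual)
    if (length(un) > 0) {
      rows$unpaired <- data.frame(
        svtype = NA_character_,
        chrom1 = bnd$chrom[un], pos1 = bnd$pos[un], strand1 = be$orient[un],
        chrom2 = be$mate_chrom[un], pos2 = be$mate_pos[un],
        strand2 = be$mate_orient[un],
        insert_len = be$insert_len[un],
        pass = bnd$filter[un] == "PASS",
        qual = bnd$qual[un],
        id1 = bnd$id[un], id2 = NA_character_,
        paired = FALSE, stringsAsFactors = FALSE
      )
    }
  }

  out <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    svtype = character(), chrom1 = character(), pos1 = numeric(),
    strand1 = character(), chrom2 = character(), pos2 = numeric(),
    strand2 = character(), insert_len = numeric(), pass = logical(),
    qual = numeric(), id1 = character(), id2 = character(),
    paired = logical(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  ## same-chromosome pairs: order breakends by position
  intra <- out$paired & !is.na(out$pos2) & out$chrom1 == out$chrom2 &
    out$pos1 > out$pos2
  intra[is.na(intra)] <- FALSE
  if (any(intra)) {
    tmp <- out[intra, c("pos1", "strand1", "id1")]
    out[intra, c("pos1", "strand1", "id1")] <- out[intra, c("pos2", "strand2", "id2")]
    out[intra, c("pos2", "strand2", "id2")] <- tmp
  }
  attr(out, "n_unpaired") <- sum(!out$paired)
  out
}

#' Import an SV VCF into an SvCallSet
#'
#' Convenience chain: [readSvVcf()] then [pairBreakends()] then
#' [classifySimpleType()] for intra-chromosomal breakend pairs, returning an
#' [SvCallSet-class]. Unpaired breakends are excluded (their count is kept in
#' the `n_unpaired` attribute); high confidence is `FILTER == "PASS"`.
#'
#' @inheritParams readSvVcf
#' @param sample_id,caller_id Identifiers attached to every call.
#' @param ins_factor Insert-dominance factor passed to [classifySimpleType()].
#' @return `SvCallSet` with attributes `skip_report` and `n_unpaired`.
#' @export
importSvVcf <- function(path, dialect = c("typed", "bnd-only"),
                        sample_id, caller_id, ins_factor = 1) {
  rec <- readSvVcf(path, dialect)
  ev <- pairBreakends(rec)
  n_unpaired <- attr(ev, "n_unpaired")
  ev <- ev[ev$paired, , drop = FALSE]
  ev <- classifySimpleType(ev, ins_factor = ins_factor)
  cs <- SvCallSet(data.frame(
    sample_id = rep(sample_id, nrow(ev)),
    caller_id = rep(caller_id, nrow(ev)),
    svtype = ev$svtype,
    chrom1 = ev$chrom1, pos1 = ev$pos1, strand1 = ev$strand1,
    chrom2 = ev$chrom2, pos2 = ev$pos2, strand2 = ev$strand2,
    high_confidence = ev$pass, qual = ev$qual, insert_len = ev$insert_len,
    stringsAsFactors = FALSE
  ))
  attr(cs, "skip_report") <- attr(rec, "skip_report")
  attr(cs, "n_unpaired") <- n_unpaired
  cs
}

## ---- gene annotation ------------------------------------------------------

#' Read a refFlat gene-model table
#'
#' Reads the UCSC refFlat format (geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds). UCSC
#' coordinates are 0-based half-open; they are converted to 1-based inclusive
#' on read. A mismatch between `exonCount` and the exon start/end lists is a
#' parse error.
#'
#' @param path Path to a tab-separated refFlat file (no header).
#' @return data.frame with one row per transcript: `gene_symbol`,
#'   `transcript_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `exon_count`,
#'   and list-columns `exon_starts`, `exon_ends` (1-based inclusive, sorted).
#' @export
readRefFlat <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("geneName", "name", "chrom", "strand",
                                 "txStart", "txEnd", "cdsStart", "cdsEnd",
                                 "exonCount", "exonStarts", "exonEnds"))
  parseList <- function(s) {
    lapply(strsplit(as.character(s), ",", fixed = TRUE),
           function(x) as.numeric(x[nzchar(x)]))
  }
  starts <- parseList(df$exonStarts)
  ends <- parseList(df$exonEnds)
  nS <- lengths(starts); nE <- lengths(ends)
  bad <- nS != df$exonCount | nE != df$exonCount
  if (any(bad)) {
    stopf("exonCount does not match exon list length for transcript(s): %s",
          paste(df$name[bad], collapse = ", "))
  }
  ## exons stored sorted by genomic start
  ord <- lapply(starts, order)
  data.frame(
    gene_symbol = df$geneName,
    transcript_id = df$name,
    chrom = df$chrom,
    strand = df$strand,
    tx_start = df$txStart + 1,
    tx_end = df$txEnd,
    exon_count = df$exonCount,
    exon_starts = I(Map(function(x, o) x[o] + 1, starts, ord)),
    exon_ends = I(Map(function(x, o) x[o], ends, ord)),
    stringsAsFactors = FALSE
  )
}

#' Write a transcript table as refFlat
#'
#' Inverse of [readRefFlat()]: 1-based inclusive coordinates are converted
#' back to UCSC 0-based half-open. Used by the synthetic cohort generator.
#'
#' @param transcripts data.frame as returned by [readRefFlat()].
#' @param path Output path.
#' @export
writeRefFlat <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    paste(t$gene_symbol, t$transcript_id, t$chrom, t$strand,
          t$tx_start - 1, t$tx_end, t$tx_start - 1, t$tx_end,
          t$exon_count,
          paste0(paste(t$exon_starts[[1]] - 1, collapse = ","), ","),
          paste0(paste(t$exon_ends[[1]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Per-gene union intervals
#'
#' Collapses transcripts to one interval per (gene, chromosome): the span
#' from the minimum transcript start to the maximum transcript end. A gene
#' symbol appearing on two chromosomes yields two intervals with a warning.
#'
#' @param transcripts data.frame as returned by [readRefFlat()].
#' @return [GenomicRanges::GRanges] with metadata columns `gene_symbol` and
#'   `gene_strand` (`*` if transcripts disagree).
#' @export
geneUnionIntervals <- function(transcripts) {
  key <- paste(transcripts$gene_symbol, transcripts$chrom, sep = "\r")
  sp <- split(seq_len(nrow(transcripts)), key)
  gene <- vapply(sp, function(i) transcripts$gene_symbol[i[1]], character(1))
  chrom <- vapply(sp, function(i) transcripts$chrom[i[1]], character(1))
  start <- vapply(sp, function(i) min(transcripts$tx_start[i]), numeric(1))
  end <- vapply(sp, function(i) max(transcripts$tx_end[i]), numeric(1))
  strand <- vapply(sp, function(i) {
    s <- unique(transcripts$strand[i])
    if (length(s) == 1) s else "*"
  }, character(1))
  dup <- gene[duplicated(gene)]
  if (length(dup) > 0) {
    warnf("gene symbol(s) present on multiple chromosomes: %s",
          paste(unique(dup), collapse = ", "))
  }
  gr <- GRanges(chrom, IRanges(start, end))
  gr$gene_symbol <- unname(gene)
  gr$gene_strand <- unname(strand)
  names(gr) <- NULL
  sort(gr, ignore.strand = TRUE)
}

## ---- tabular inputs -------------------------------------------------------

#' Read the cohort metadata table
#'
#' TSV with header columns `sample_id`, `ancestry` (African/European/Admixed)
#' and `risk_group` (HRPCa/IRPCa/LRPCa; Gleason >= 8 maps to HRPCa). Any
#' additional columns (age, PSA) are preserved. Duplicate sample ids are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
readCohortMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ancestry", "risk_group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- !(df$ancestry %in% c("African", "European", "Admixed"))
  if (any(bad)) stopf("unknown ancestry value(s): %s", paste(unique(df$ancestry[bad]), collapse = ", "))
  df
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read/write the canonical SV table
#'
#' The canonical interchange format is a TSV with columns `sample_id`,
#' `caller_id`, `svtype`, `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#' `strand2`, `high_confidence`, `qual`, `insert_len`. Writing then reading
#' reproduces the call set exactly.
#'
#' @param x An [SvCallSet-class].
#' @param path Path to the TSV file.
#' @return `readSvTable` returns an `SvCallSet`; `writeSvTable` returns
#'   `path` invisibly.
#' @export
writeSvTable <- function(x, path) {
  df <- svCalls(x)[, SV_TABLE_COLS, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSvTable
#' @export
readSvTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(
                     sample_id = "character", caller_id = "character",
                     svtype = "character", chrom1 = "character",
                     pos1 = "numeric", strand1 = "character",
                     chrom2 = "character", pos2 = "numeric",
                     strand2 = "character", high_confidence = "logical",
                     qual = "numeric", insert_len = "numeric"
                   ))
  SvCallSet(df)
}

## ---- VCF writing (synthetic caller views) ---------------------------------

#' Write a single-sample SvCallSet as a VCF
#'
#' Emits either the `typed` dialect (DEL/DUP/INV records with `END`, INS
#' records with `INSLEN`, translocations as BND mate pairs) or the
#' `bnd-only` dialect (every event as a BND mate pair with bracket-notation
#' ALT; insertions become an adjacency over a 1-bp span carrying the inserted
#' sequence). FILTER is `PASS` for high-confidence calls, `LowQual`
#' otherwise.
#'
#' @param x `SvCallSet` containing calls of a single sample.
#' @param path Output path.
#' @param dialect `"typed"` or `"bnd-only"`.
#' @export
writeSvVcf <- function(x, path, dialect = c("typed", "bnd-only")) {
  dialect <- match.arg(dialect)
  df <- svCalls(x)
  if (length(unique(df$sample_id)) > 1) stopf("writeSvVcf expects a single sample")
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="ID of mate breakend">',
    '##INFO=<ID=INSLEN,Number=1,Type=Integer,Description="Length of insertion">',
    '##FILTER=<ID=LowQual,Description="Low confidence call">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t")
  )
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  bndAlt <- function(s1, c2, p2, s2, t) {
    p <- paste0(c2, ":", fmt(p2))
    if (s1 == "+" && s2 == "-") paste0(t, "[", p, "[")
    else if (s1 == "+" && s2 == "+") paste0(t, "]", p, "]")
    else if (s1 == "-" && s2 == "+") paste0("]", p, "]", t)
    else paste0("[", p, "[", t)
  }
  lines <- character()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    flt <- if (isTRUE(r$high_confidence)) "PASS" else "LowQual"
    q <- if (is.na(r$qual)) "." else format(r$qual, trim = TRUE)
    asBndPair <- function(c1, p1, s1, c2, p2, s2, ins_len, tag) {
      ins <- if (!is.na(ins_len) && ins_len > 0) strrep("A", ins_len) else ""
      t1 <- if (s1 == "+") paste0("N", ins) else paste0(ins, "N")
      t2 <- if (s2 == "+") paste0("N", ins) else paste0(ins, "N")
      id1 <- paste0(tag, "_1"); id2 <- paste0(tag, "_2")
      c(paste(c1, fmt(p1), id1, "N", bndAlt(s1, c2, p2, s2, t1), q, flt,
              paste0("SVTYPE=BND;MATEID=", id2), sep = "\t"),
        paste(c2, fmt(p2), id2, "N", bndAlt(s2, c1, p1, s1, t2), q, flt,
              paste0("SVTYPE=BND;MATEID=", id1), sep = "\t"))
    }
    tag <- sprintf("sv%05d", i)
    if (dialect == "typed") {
      if (r$svtype %in% c("DEL", "DUP", "INV")) {
        lines <- c(lines, paste(
          r$chrom1, fmt(r$pos1), tag, "N", paste0("<", r$svtype, ">"), q, flt,
          paste0("SVTYPE=", r$svtype, ";END=", fmt(r$pos2)), sep = "\t"))
      } else if (r$svtype == "INS") {
        lines <- c(lines, paste(
          r$chrom1, fmt(r$pos1), tag, "N", "<INS>", q, flt,
          paste0("SVTYPE=INS;INSLEN=", max(1, r$insert_len, na.rm = TRUE)),
          sep = "\t"))
      } else { # TRA
        lines <- c(lines, asBndPair(r$chrom1, r$pos1, r$strand1,
                                    r$chrom2, r$pos2, r$strand2, NA, tag))
      }
    } else {
      if (r$svtype == "INS") {
        lines <- c(lines, asBndPair(r$chrom1, r$pos1, "+",
                                    r$chrom1, r$pos1 + 1, "-",
                                    max(2, r$insert_len, na.rm = TRUE), tag))
      } else {
        lines <- c(lines, asBndPair(r$chrom1, r$pos1, r$strand1,
                                    r$chrom2, r$pos2, r$strand2,
                                    r$insert_len, tag))
      }
    }
  }
  ## sort body by chromosome then position for a valid VCF
  if (length(lines) > 0) {
    ch <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
    po <- as.numeric(vapply(strsplit(lines, "\t"), `[`, character(1), 2))
    lines <- lines[order(ch, po)]
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
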