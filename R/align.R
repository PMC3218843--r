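# Exhaustive k-mismatch alignment, paired-end resolution, SAM I/O.
#
# An alignment set is a data.table with one row per (read, placement):
#   id, mate         read identity (mate 0 for single-end input)
#   rname, pos0      0-based placement on the reference
#   strand           "+"/"-"
#   nm, mism         Hamming mismatch count and 0-based offsets in
#                    alignment (genome) orientation
#   aseq, aqual      read sequence/quality in alignment orientation
#   unit, placement  read unit (pair or rescued singleton) and placement
#                    index within the unit; UNI/BEST/ALL strategies operate
#                    on placements per unit
#   paired           TRUE when the placement is a valid mate pair

#' Enumerate all k-mismatch alignments of one read
#'
#' Every ungapped placement of the read on either strand of the genome with
#' Hamming distance at most `k`, exhaustively. 'N' counts as a mismatch.
#' Output is deterministic, ordered by sequence, position, strand.
#'
#' @param read Read sequence (character).
#' @param genome A [ref_genome()] or named character vector.
#' @param k Mismatch bound (>= 0).
#' @return A data.table with columns `rname`, `pos0`, `strand`, `nm`,
#'   `mism` (list of 0-based mismatch offsets, alignment orientation).
#' @export
#' @examples
#' g <- ref_genome(c(s = "AAAACGTTTT"))
#' enumerate_alignments("AACG", g, k = 0)
enumerate_alignments <- function(read, genome, k) {
  genome <- as_ref_genome(genome)
  if (!nzchar(read)) stop("empty read")
  if (k < 0) stop("k must be >= 0")
  if (nchar(read) > min(nchar(genome$sequences)))
    stop("read longer than the shortest reference sequence")
  res <- .align_reads_cpp(unname(genome$sequences), toupper(read),
                          as.integer(k))
  dt <- alignment_table(res, genome)
  setorder(dt, rname, pos0, strand)
  dt[]
}

# convert the C++ result to a data.table with a mismatch-offset list column
alignment_table <- function(res, genome) {
  n <- length(res$read)
  mm_start <- c(res$mm_start, length(res$mm_flat))
  mism <- if (n) lapply(seq_len(n), function(i) {
    lo <- mm_start[i] + 1L; hi <- mm_start[i + 1L]
    if (hi >= lo) res$mm_flat[lo:hi] else integer(0)
  }) else list()
  data.table(ridx = res$read,
             rname = names(genome$sequences)[res$seq],
             pos0 = res$pos0,
             strand = ifelse(res$strand > 0, "+", "-"),
             nm = res$nm, mism = mism)
}

#' Align a read set to a genome
#'
#' Enumerates every k-mismatch placement of every read
#' ([enumerate_alignments()] semantics, vectorized), then resolves pairing:
#' paired-end first, single-end rescue for reads whose mates cannot be
#' placed at a valid spacing ([pair_alignments()]).
#'
#' @param reads A `read_set` (see [sample_pe_reads()] / [read_fastq()]).
#' @param genome A [ref_genome()].
#' @param k Mismatch bound.
#' @param insert_range Length-2 vector: valid outer spacing (nt) for mate
#'   pairs.
#' @return An object of class `alignment_set`: list with `alignments`
#'   (data.table described above), `k`, and `genome_names`.
#' @export
align_reads <- function(reads, genome, k = 2L, insert_range = c(150L, 300L)) {
  genome <- as_ref_genome(genome)
  reads <- as.data.table(reads)
  res <- .align_reads_cpp(unname(genome$sequences), reads$seq, as.integer(k))
  dt <- alignment_table(res, genome)
  dt[, id := reads$id[ridx]]
  dt[, mate := reads$mate[ridx]]
  # store read seq/qual in alignment orientation
  fseq <- reads$seq[dt$ridx]; fqual <- reads$qual[dt$ridx]
  neg <- dt$strand == "-"
  dt[, aseq := fseq]
  dt[, aqual := fqual]
  if (any(neg)) {
    dt[neg, aseq := revcomp(aseq)]
    dt[neg, aqual := vapply(aqual, function(x)
      intToUtf8(rev(utf8ToInt(x))), "")]
  }
  dt[, ridx := NULL]
  dt <- pair_alignments(dt, insert_range)
  structure(list(alignments = dt, k = as.integer(k),
                 genome_names = names(genome$sequences)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("<alignment_set> ", nrow(x$alignments), " alignments, k=", x$k,
      ", ", data.table::uniqueN(x$alignments$unit), " read units\n", sep = "")
  invisible(x)
}

#' Resolve paired-end placements
#'
#' Keeps opposite-strand placements of the two mates on the same sequence
#' whose outer span lies within `insert_range`; each surviving combination
#' is one pair placement. Reads whose mate has no co-placement at a valid
#' spacing fall back to their single-end alignments (rescued singletons),
#' mirroring the paired-first / single-end-rescue protocol.
#'
#' @param alns Alignment data.table carrying `id` and `mate` columns (both
#'   mates together), as built by [align_reads()].
#' @param insert_range Length-2 numeric, min <= max.
#' @return The alignment table with `unit`, `placement` and `paired` columns
#'   assigned.
#' @export
pair_alignments <- function(alns, insert_range = c(150L, 300L)) {
  if (insert_range[1] > insert_range[2]) stop("insert_range: min > max")
  alns <- as.data.table(alns)
  if (!nrow(alns)) {
    alns[, `:=`(unit = character(), placement = integer(), paired = logical(),
                mate_pos0 = integer(), mate_strand = character(),
                tlen = integer())]
    return(alns[])
  }
  alns[, rlen := nchar(aseq)]
  alns[, aid := .I]
  a1 <- alns[mate == 1L]; a2 <- alns[mate == 2L]
  pairs <- NULL
  if (nrow(a1) && nrow(a2)) {
    pairs <- merge(
      a1[, .(id, rname, aid1 = aid, pos1 = pos0, strand1 = strand,
             len1 = rlen, nm1 = nm)],
      a2[, .(id, rname, aid2 = aid, pos2 = pos0, strand2 = strand,
             len2 = rlen, nm2 = nm)],
      by = c("id", "rname"), allow.cartesian = TRUE)
    if (nrow(pairs)) {
      pairs[, span := pmax(pos1 + len1, pos2 + len2) - pmin(pos1, pos2)]
      pairs <- pairs[strand1 != strand2 &
                     span >= insert_range[1] & span <= insert_range[2]]
    }
  }
  paired_ids <- if (!is.null(pairs) && nrow(pairs)) unique(pairs$id)
  else character(0)

  out <- list()
  if (length(paired_ids)) {
    setorder(pairs, id, rname, pos1, pos2)
    pairs[, placement := seq_len(.N), by = id]
    p1 <- alns[pairs$aid1]
    p1[, `:=`(unit = pairs$id, placement = pairs$placement, paired = TRUE,
              mate_pos0 = pairs$pos2, mate_strand = pairs$strand2,
              tlen = fifelse(pairs$pos1 <= pairs$pos2, pairs$span,
                             -pairs$span))]
    p2 <- alns[pairs$aid2]
    p2[, `:=`(unit = pairs$id, placement = pairs$placement, paired = TRUE,
              mate_pos0 = pairs$pos1, mate_strand = pairs$strand1,
              tlen = fifelse(pairs$pos2 <= pairs$pos1, pairs$span,
                             -pairs$span))]
    out <- list(p1, p2)
  }
  # single-end rescue: every alignment of a read not in a valid pair
  se <- alns[!(id %in% paired_ids)]
  if (nrow(se)) {
    se[, unit := paste0(id, "/", mate)]
    setorder(se, unit, rname, pos0, strand)
    se[, placement := seq_len(.N), by = unit]
    se[, `:=`(paired = FALSE, mate_pos0 = NA_integer_,
              mate_strand = NA_character_, tlen = NA_integer_)]
    out <- c(out, list(se))
  }
  res <- rbindlist(out, use.names = TRUE)
  res[, c("aid", "rlen") := NULL]
  setorder(res, unit, placement, mate)
  res[]
}

# ---- SAM ----

sam_flag <- function(paired, mate, strand, mate_strand) {
  f <- integer(length(strand))
  f <- f + fifelse(paired, 1L + 2L, 0L)                 # paired + proper
  f <- f + fifelse(strand == "-", 16L, 0L)
  f <- f + fifelse(paired & mate_strand == "-", 32L, 0L)
  f <- f + fifelse(paired & mate == 1L, 64L, 0L)
  f <- f + fifelse(paired & mate == 2L, 128L, 0L)
  f
}

md_tag <- function(aseq, rname, pos0, mism, genome) {
  refseq <- genome$sequences
  vapply(seq_along(aseq), function(i) {
    mm <- mism[[i]]
    if (!length(mm)) return(as.character(nchar(aseq[i])))
    ref <- substring(refseq[[rname[i]]], pos0[i] + 1,
                     pos0[i] + nchar(aseq[i]))
    rb <- strsplit(ref, "")[[1]]
    parts <- character(0); prev <- -1L
    for (m in sort(mm)) {
      parts <- c(parts, as.character(m - prev - 1L), rb[m + 1L])
      prev <- m
    }
    paste0(paste(parts, collapse = ""), nchar(aseq[i]) - prev - 1L)
  }, "")
}

#' Write an alignment set as SAM
#'
#' SAM 1.x with a sequence-dictionary header; FLAG encodes strand and
#' pairing, POS is 1-based, MAPQ 255, CIGAR is all-match (the aligner is
#' ungapped). `NM` carries the mismatch count, `MD` the mismatch layout, and
#' `HI` the placement index within the read unit so multi-placement sets
#' round-trip losslessly through [read_sam()].
#'
#' @param alnset An `alignment_set` (or its alignment data.table).
#' @param genome The [ref_genome()] aligned against.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alnset, genome, path) {
  genome <- as_ref_genome(genome)
  alns <- if (inherits(alnset, "alignment_set") ||
              inherits(alnset, "read_map")) alnset$alignments
  else as.data.table(alnset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
                       nchar(genome$sequences)),
               "@PG\tID:paracall\tPN:paracall"), con)
  if (!nrow(alns)) return(invisible(path))
  flag <- sam_flag(alns$paired, alns$mate, alns$strand, alns$mate_strand)
  md <- md_tag(alns$aseq, alns$rname, alns$pos0, alns$mism, genome)
  # single-end-rescued mates keep their mate index in the QNAME (the
  # usual /1 /2 convention) so the unit structure round-trips
  qname <- fifelse(!alns$paired & !is.na(alns$mate),
                   paste0(alns$id, "/", alns$mate), alns$id)
  lines <- paste(
    qname, flag, alns$rname, alns$pos0 + 1L, 255L,
    paste0(nchar(alns$aseq), "M"),
    fifelse(alns$paired, "=", "*"),
    fifelse(alns$paired, alns$mate_pos0 + 1L, 0L),
    fifelse(alns$paired, alns$tlen, 0L),
    alns$aseq, alns$aqual,
    paste0("NM:i:", alns$nm),
    paste0("MD:Z:", md),
    paste0("HI:i:", alns$placement),
    sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into an alignment set
#'
#' Accepts SAM from [write_sam()] or any external aligner. Records are
#' parsed via Rsamtools (SAM -> BAM -> records); mismatch offsets are
#' recomputed against the reference so external files need no MD tags.
#' Placement indices come from the `HI` tag when present, otherwise are
#' assigned in file order per read.
#'
#' @param path SAM file path.
#' @param genome The [ref_genome()] the file was aligned against.
#' @param k Mismatch bound recorded on the returned set (defaults to the
#'   maximum NM seen).
#' @return An `alignment_set`.
#' @export
read_sam <- function(path, genome, k = NULL) {
  genome <- as_ref_genome(genome)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "seq", "qual", "mpos"),
    tag = c("NM", "HI"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (!n) {
    dt <- data.table(id = character(), mate = integer(), rname = character(),
                     pos0 = integer(), strand = character(), nm = integer(),
                     mism = list(), aseq = character(), aqual = character(),
                     unit = character(), placement = integer(),
                     paired = logical(), mate_pos0 = integer(),
                     mate_strand = character(), tlen = integer())
    return(structure(list(alignments = dt, k = k %||% 0L,
                          genome_names = names(genome$sequences)),
                     class = "alignment_set"))
  }
  flag <- b$flag
  paired <- bitwAnd(flag, 1L) > 0L
  mate <- fifelse(bitwAnd(flag, 128L) > 0L, 2L,
                  fifelse(bitwAnd(flag, 64L) > 0L, 1L, 1L))
  mate[!paired] <- NA_integer_
  strand <- fifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  dt <- data.table(
    id = b$qname, mate = mate,
    rname = as.character(b$rname), pos0 = b$pos - 1L,
    strand = strand,
    aseq = as.character(b$seq), aqual = as.character(b$qual),
    paired = paired,
    mate_pos0 = fifelse(paired, b$mpos - 1L, NA_integer_),
    mate_strand = fifelse(paired,
                          fifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
                          NA_character_),
    hi = if (!is.null(b$tag$HI)) b$tag$HI else NA_integer_)
  seqidx <- match(dt$rname, names(genome$sequences))
  if (anyNA(seqidx)) stop("SAM references sequences absent from the genome")
  dt[, mism := .mismatch_offsets_cpp(unname(genome$sequences), seqidx,
                                     pos0, aseq)]
  dt[, nm := lengths(mism)]
  if (!is.null(b$tag$NM) && !anyNA(b$tag$NM) &&
      any(b$tag$NM != dt$nm))
    stop("NM tags disagree with mismatches recomputed against the reference")
  # unpaired records: recover the mate index from the /1 /2 QNAME
  # convention where present
  suf <- !dt$paired & grepl("/[12]$", dt$id)
  if (any(suf)) {
    dt[suf, mate := as.integer(sub("^.*/", "", id))]
    dt[suf, id := sub("/[12]$", "", id)]
  }
  dt[!paired & is.na(mate), mate := 1L]
  dt[, unit := fifelse(paired, id, paste0(id, "/", mate))]
  if (anyNA(dt$hi)) {
    # without HI tags placements are assigned in coordinate order per mate;
    # for multi-placement pairs the mate matching is then only positional
    setorder(dt, unit, rname, pos0, strand, mate)
    dt[, placement := seq_len(.N), by = .(unit, mate)]
    multi <- dt[paired == TRUE, .N, by = .(unit, mate)]
    if (nrow(multi) && any(multi$N > 1L))
      warning("multi-placement paired SAM without HI tags: mate pairing ",
              "inferred from record order")
  } else dt[, placement := hi]
  dt[, tlen := fifelse(paired,
                       pmax(pos0 + nchar(aseq), mate_pos0 + nchar(aseq)) -
                         pmin(pos0, mate_pos0), NA_integer_)]
  dt[, hi := NULL]
  kk <- if (is.null(k)) max(dt$nm, 0L) else as.integer(k)
  setcolorder(dt, c("rname", "pos0", "strand", "nm", "mism", "id", "mate",
                    "aseq", "aqual", "unit", "placement", "paired",
                    "mate_pos0", "mate_strand", "tlen"))
  setorder(dt, unit, placement, mate)
  structure(list(alignments = dt[], k = kk,
                 genome_names = names(genome$sequences)),
            class = "alignment_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
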