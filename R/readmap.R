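# Read-map strategies, pileups and map statistics.
#
# A read map is the subset of an alignment set retained by one of the four
# classical strategies:
#   UNI     reads (units) with exactly one placement
#   BESTNO  reads whose minimum-mismatch placement is unique (ties dropped)
#   BEST    one minimum-mismatch placement per read, ties broken at random
#           with a recorded seed
#   ALL     every placement of reads with at most d_cap placements; reads
#           exceeding the cap are discarded wholly (max-d, not top-d)

#' Define a read-mapping strategy
#'
#' @param kind One of `"uni"`, `"bestno"`, `"best"`, `"all"`.
#' @param d_cap Maximum placements per read unit (ALL only); `d_cap` is
#'   `d + 1` in the usual notation. Default 200.
#' @param seed Tie-breaking seed (BEST only).
#' @return A `mapping_strategy` object.
#' @export
#' @examples
#' mapping_strategy("all", d_cap = 200)
mapping_strategy <- function(kind = c("uni", "bestno", "best", "all"),
                             d_cap = 200L, seed = 1L) {
  kind <- match.arg(tolower(kind), c("uni", "bestno", "best", "all"))
  if (kind == "all" && d_cap < 1) stop("d_cap must be >= 1")
  structure(list(kind = kind, d_cap = as.integer(d_cap),
                 seed = as.integer(seed)),
            class = "mapping_strategy")
}

#' Apply a mapping strategy to an alignment set
#'
#' Operates per read unit (a mate pair, or a rescued singleton) on its
#' placements; a pair placement's mismatch count is the sum over its two
#' mates. The operation is idempotent and order-independent over reads.
#'
#' @param alnset An `alignment_set` from [align_reads()] / [read_sam()].
#' @param strategy A [mapping_strategy()] or a kind string.
#' @param d_cap,seed Convenience overrides when `strategy` is a string.
#' @return An object of class `read_map`: list with `alignments` (the
#'   retained rows, plus `d1` = placements retained per read, i.e. d+1),
#'   `strategy`, and `k`.
#' @export
apply_strategy <- function(alnset, strategy, d_cap = 200L, seed = 1L) {
  stopifnot(inherits(alnset, "alignment_set"))
  if (is.character(strategy))
    strategy <- mapping_strategy(strategy, d_cap = d_cap, seed = seed)
  alns <- copy(alnset$alignments)
  if (!nrow(alns)) {
    alns[, d1 := integer()]
    return(structure(list(alignments = alns, strategy = strategy,
                          k = alnset$k,
                          genome_names = alnset$genome_names),
                     class = "read_map"))
  }
  pl <- alns[, .(nm_tot = sum(nm)), by = .(unit, placement)]
  np <- pl[, .(n_place = .N), by = unit]
  keep <- switch(strategy$kind,
    uni = {
      merge(pl, np[n_place == 1L], by = "unit")[, .(unit, placement)]
    },
    bestno = {
      best <- pl[, .SD[nm_tot == min(nm_tot)], by = unit]
      uniq <- best[, .N, by = unit][N == 1L, .(unit)]
      merge(best, uniq, by = "unit")[, .(unit, placement)]
    },
    best = {
      best <- pl[, .SD[nm_tot == min(nm_tot)], by = unit]
      with_stream(strategy$seed, "best-ties", {
        setorder(best, unit, placement)
        best[, pick := sample.int(.N, 1L), by = unit]
        best[, .SD[pick[1L]], by = unit][, .(unit, placement)]
      })
    },
    all = {
      merge(pl, np[n_place <= strategy$d_cap], by = "unit")[,
        .(unit, placement)]
    })
  out <- merge(alns, keep, by = c("unit", "placement"))
  out[, d1 := uniqueN(placement), by = unit]
  setorder(out, unit, placement, mate)
  structure(list(alignments = out[], strategy = strategy, k = alnset$k,
                 genome_names = alnset$genome_names),
            class = "read_map")
}

#' @export
print.read_map <- function(x, ...) {
  cat("<read_map> strategy=", x$strategy$kind, ", ",
      nrow(x$alignments), " alignments from ",
      uniqueN(x$alignments$unit), " read units\n", sep = "")
  invisible(x)
}

#' Build per-locus pileups from a read map
#'
#' One column per covered locus. Each pileup entry records the read base,
#' base quality, the placement's mismatch count and whether the focal locus
#' itself is a mismatch against the reference, the read's multiplicity
#' (d+1), and a handle to the alignment so the genotyper can reconstruct
#' the read's other placements (the background terms) and the homologous
#' loci they cover.
#'
#' @param map A `read_map`.
#' @param genome The [ref_genome()].
#' @return An object of class `pileup`: list with `entries` (data.table:
#'   `rname`, `locus`, `aid`, `rid`, `base`, `q`, `offset`, `focal_mm`,
#'   `nm`, `n`, `d1`) and `alignments` (per-alignment table with `aid` and
#'   `rid` keys). `rid` identifies a read (mate); `aid` one placement of it.
#' @export
build_pileups <- function(map, genome) {
  stopifnot(inherits(map, "read_map"))
  genome <- as_ref_genome(genome)
  alns <- copy(map$alignments)
  lens <- nchar(genome$sequences)
  if (nrow(alns)) {
    if (any(alns$pos0 < 0 | alns$pos0 + nchar(alns$aseq) >
            lens[alns$rname]))
      stop("alignment out of genome bounds")
  }
  alns[, aid := .I]
  alns[, rid := paste0(unit, "#", fifelse(is.na(mate), 1L, mate))]
  # multiplicity per read (mate): one alignment per placement of its unit
  alns[, d1 := .N, by = rid]
  n <- nrow(alns)
  if (!n) {
    entries <- data.table(rname = character(), locus = integer(),
                          aid = integer(), rid = character(),
                          base = character(), q = integer(),
                          offset = integer(), focal_mm = logical(),
                          nm = integer(), n = integer(), d1 = integer())
    return(structure(list(entries = entries, alignments = alns,
                          genome_names = names(genome$sequences)),
                     class = "pileup"))
  }
  L <- nchar(alns$aseq)
  reps <- rep(seq_len(n), L)
  off <- sequence(L) - 1L
  entries <- data.table(
    rname = alns$rname[reps],
    locus = alns$pos0[reps] + off,
    aid = reps,
    rid = alns$rid[reps],
    offset = off,
    nm = alns$nm[reps],
    n = L[reps],
    d1 = alns$d1[reps])
  # split seq/qual into per-position vectors
  entries[, base := unlist(strsplit(alns$aseq, ""))]
  entries[, q := unlist(lapply(alns$aqual, function(x) utf8ToInt(x) - 33L))]
  mmkey <- paste0(rep(alns$aid, lengths(alns$mism)),
                  ":", unlist(alns$mism))
  entries[, focal_mm := paste0(aid, ":", offset) %in% mmkey]
  setkey(entries, rname, locus)
  structure(list(entries = entries, alignments = alns,
                 genome_names = names(genome$sequences)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> ", nrow(x$entries), " entries over ",
      nrow(unique(x$entries[, .(rname, locus)])), " loci\n", sep = "")
  invisible(x)
}

#' Extract one pileup column
#'
#' The per-locus view the genotyper consumes: the entries covering the
#' locus, each with the read's other-placement contexts (sequence,
#' homologous locus) attached.
#'
#' @param pileup A `pileup`.
#' @param rname Sequence name.
#' @param locus 0-based position.
#' @return A `pileup_column`: list with `rname`, `locus`, `entries`, and
#'   `others` (data.table of other-placement contexts keyed by `aid`).
#' @export
pileup_column <- function(pileup, rname, locus) {
  want <- data.table(rname = rname, locus = as.integer(locus))
  e <- pileup$entries[want, on = c("rname", "locus"), nomatch = NULL]
  oth <- homolog_contexts(pileup, e)
  structure(list(rname = rname, locus = as.integer(locus),
                 entries = e, others = oth,
                 alignments = pileup$alignments),
            class = "pileup_column")
}

# other-placement contexts for a set of entries: for each entry and each
# other alignment of the same read, the homologous (sequence, locus)
homolog_contexts <- function(pileup, entries) {
  alns <- pileup$alignments
  if (!nrow(entries)) {
    return(data.table(aid = integer(), rid = character(),
                      rname = character(), locus = integer(),
                      other_aid = integer(), other_rname = character(),
                      other_locus = integer()))
  }
  oth <- merge(
    entries[, .(aid, rid, rname, locus, offset,
                strand = alns$strand[aid], n)],
    alns[, .(other_aid = aid, rid, other_rname = rname,
             other_pos0 = pos0, other_strand = strand)],
    by = "rid", allow.cartesian = TRUE)
  oth <- oth[other_aid != aid]
  if (!nrow(oth)) {
    return(data.table(aid = integer(), rid = character(),
                      rname = character(), locus = integer(),
                      other_aid = integer(), other_rname = character(),
                      other_locus = integer()))
  }
  # read-coordinate offset of the focal locus, then back to the other
  # placement's genome coordinates
  oth[, ro := fifelse(strand == "+", offset, n - 1L - offset)]
  oth[, other_locus := other_pos0 +
        fifelse(other_strand == "+", ro, n - 1L - ro)]
  oth[, .(aid, rid, rname, locus, other_aid, other_rname, other_locus)]
}

#' Read-map summary statistics and mismatch-bound selection
#'
#' `map_stats` summarizes a read map: mean read depth over covered loci,
#' mean alignments per retained read, their ratio (the degeneracy ratio),
#' the fraction of genome loci covered, and the fraction of retained reads
#' with more than one placement. `select_k` picks, among read maps built at
#' different mismatch bounds, the `k` that maximizes the degeneracy ratio
#' (mean depth / mean alignments per read); ties go to the smallest `k`.
#'
#' @param map A `read_map`.
#' @param genome The [ref_genome()] (for the covered-loci denominator).
#' @return `map_stats`: a list with `mean_depth`, `mean_alignments`,
#'   `degeneracy_ratio`, `frac_loci_covered`, `frac_reads_nonunique`,
#'   `n_reads`, `n_alignments`.
#' @export
map_stats <- function(map, genome) {
  stopifnot(inherits(map, "read_map"))
  genome <- as_ref_genome(genome)
  alns <- map$alignments
  if (!nrow(alns)) {
    return(structure(list(mean_depth = 0, mean_alignments = 0,
                          degeneracy_ratio = NaN, frac_loci_covered = 0,
                          frac_reads_nonunique = 0, n_reads = 0L,
                          n_alignments = 0L), class = "map_stats"))
  }
  if (is.null(alns$rid)) {
    alns <- copy(alns)
    alns[, rid := paste0(unit, "#", fifelse(is.na(mate), 1L, mate))]
  }
  per_read <- alns[, .(n_aln = .N), by = rid]
  L <- nchar(alns$aseq)
  cov <- data.table(rname = rep(alns$rname, L),
                    locus = rep(alns$pos0, L) + sequence(L) - 1L)
  depth <- cov[, .N, by = .(rname, locus)]
  md <- mean(depth$N)
  ma <- mean(per_read$n_aln)
  structure(list(mean_depth = md, mean_alignments = ma,
                 degeneracy_ratio = md / ma,
                 frac_loci_covered = nrow(depth) / genome$total_length,
                 frac_reads_nonunique = mean(per_read$n_aln > 1L),
                 n_reads = nrow(per_read), n_alignments = nrow(alns)),
            class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  cat(sprintf(paste0("<map_stats> depth=%.2f alignments/read=%.2f ",
                     "ratio=%.2f loci covered=%.1f%% non-unique=%.1f%%\n"),
              x$mean_depth, x$mean_alignments, x$degeneracy_ratio,
              100 * x$frac_loci_covered, 100 * x$frac_reads_nonunique))
  invisible(x)
}

#' @rdname map_stats
#' @param stats_by_k Named list (names = k values) of `map_stats`.
#' @return `select_k`: the chosen integer `k`.
#' @export
#' @examples
#' s <- function(r) structure(list(degeneracy_ratio = r), class = "map_stats")
#' select_k(list(`1` = s(10), `2` = s(12.5), `3` = s(9)))  # 2
select_k <- function(stats_by_k) {
  if (!length(stats_by_k)) stop("no candidate k supplied")
  ks <- as.integer(names(stats_by_k))
  if (anyNA(ks)) stop("stats_by_k must be named by integer k")
  r <- vapply(stats_by_k, function(s) s$degeneracy_ratio, 0)
  ord <- order(ks)
  ks <- ks[ord]; r <- r[ord]
  ks[which.max(r)]
}
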