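# Synthetic templates, diploid sample genomes and error-prone paired-end
# reads. The generator reproduces the study conditions used throughout:
# concatenated-copy templates with controlled inter-copy divergence, 0.0005
# heterozygous + 0.0005 homozygous substitutions per locus, 36-nt paired-end
# reads with Gaussian insert sizes and an empirical per-cycle quality profile.

# Per-cycle mean Phred scores measured from 36-nt paired-end Illumina yeast
# data; the canonical quality profile for simulated reads.
.QMEANS36 <- c(32.8, 32.6, 32.5, 32.5, 31.9, 31.8, 31.7, 31.8, 31.5, 31.3,
               31.2, 31.0, 30.5, 30.4, 29.9, 30.0, 29.3, 29.5, 29.3, 29.2,
               29.1, 29.3, 29.4, 29.6, 29.3, 29.3, 28.6, 28.4, 28.0, 27.7,
               27.2, 26.3, 26.2, 26.0, 24.8, 24.2)

#' Per-cycle base-quality model
#'
#' Phred scores are sampled per sequencing cycle from a Gaussian with a
#' position-specific mean and a common standard deviation, then rounded and
#' clipped to `[floor, ceiling]`. The default means are an empirical 36-cycle
#' Illumina profile (declining from ~33 to ~24 along the read); for other
#' read lengths the profile is linearly interpolated over relative cycle
#' position.
#'
#' @param read_len Read length in nucleotides.
#' @param position_means Per-cycle mean Phred scores; defaults to the
#'   36-cycle empirical profile (interpolated when `read_len != 36`).
#' @param position_sd Gaussian standard deviation in Phred units.
#' @param floor,ceiling Clipping bounds for sampled scores.
#' @return An object of class `quality_model`.
#' @export
#' @examples
#' qm <- quality_model(36)
#' qm$position_means[1:4]
quality_model <- function(read_len = 36L, position_means = NULL,
                          position_sd = 10, floor = 2L, ceiling = 40L) {
  stopifnot(read_len >= 1, floor <= ceiling, position_sd >= 0)
  if (is.null(position_means)) {
    position_means <- if (read_len == length(.QMEANS36)) .QMEANS36
    else stats::approx(x = seq(0, 1, length.out = length(.QMEANS36)),
                       y = .QMEANS36,
                       xout = seq(0, 1, length.out = read_len))$y
  }
  if (length(position_means) != read_len || !all(is.finite(position_means)))
    stop("position_means must be ", read_len, " finite values")
  structure(list(read_len = as.integer(read_len),
                 position_means = position_means,
                 position_sd = position_sd,
                 floor = as.integer(floor), ceiling = as.integer(ceiling)),
            class = "quality_model")
}

sample_qualities <- function(qmodel, n_reads, clip = TRUE) {
  L <- qmodel$read_len
  q <- matrix(rnorm(L * n_reads, mean = qmodel$position_means,
                    sd = qmodel$position_sd), nrow = L)
  q <- round(q)
  if (clip) q <- pmin(pmax(q, qmodel$floor), qmodel$ceiling)
  q
}

#' Build a synthetic repetitive template
#'
#' Constructs a single reference sequence of `unit_length * copies`
#' nucleotides: the first copy is a random GC-weighted sequence and each
#' further copy is the first with every base independently substituted (to a
#' uniformly chosen different base) with probability `inter_copy_divergence`.
#' With `copies = 2` this emulates a genome with two-fold paralogous
#' degeneracy whose paralogs are `100*(1-divergence)` percent identical.
#'
#' @param unit_length Length of one copy, in nucleotides.
#' @param copies Number of concatenated copies (>= 1).
#' @param inter_copy_divergence Per-base substitution proportion between copy
#'   1 and the later copies, in `[0,1]`.
#' @param gc_fraction GC content of the random unit.
#' @param seed Integer seed; drives the `template` RNG stream.
#' @param name Sequence name in the resulting genome.
#' @return A [ref_genome()] with one sequence.
#' @export
#' @examples
#' g <- build_template(1000, copies = 2, inter_copy_divergence = 0.05, seed = 1)
#' g$total_length
build_template <- function(unit_length, copies = 1L,
                           inter_copy_divergence = 0,
                           gc_fraction = 0.4, seed = 1L,
                           name = "template") {
  stopifnot(unit_length >= 1, copies >= 1)
  if (inter_copy_divergence < 0 || inter_copy_divergence > 1)
    stop("inter_copy_divergence must be in [0,1]")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0,1]")
  with_stream(seed, "template", {
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    unit <- sample(.BASES, unit_length, replace = TRUE, prob = probs)
    out <- vector("list", copies)
    out[[1]] <- unit
    if (copies >= 2) for (ci in 2:copies) {
      cp <- unit
      hit <- which(runif(unit_length) < inter_copy_divergence)
      if (length(hit))
        cp[hit] <- vapply(cp[hit], function(b)
          sample(setdiff(.BASES, b), 1L), "")
      out[[ci]] <- cp
    }
    ref_genome(setNames(paste(unlist(out), collapse = ""), name))
  })
}

#' Inject diploid variation into a reference
#'
#' Each locus independently becomes a heterozygous variant with probability
#' `het_rate` (one haplotype substituted) or a homozygous variant with
#' probability `hom_rate` (both haplotypes substituted to the same
#' alternative base). The alternative base is uniform over the three
#' non-reference bases. The defaults are the study conditions: 0.0005 + 0.0005
#' substitutions per locus, i.e. 0.1% total polymorphic divergence.
#'
#' @param ref A [ref_genome()] (or named character vector).
#' @param het_rate,hom_rate Per-locus variant probabilities;
#'   `het_rate + hom_rate <= 1`.
#' @param seed Integer seed; drives the `variants` RNG stream.
#' @return An object of class `sample_genome`: list with `haplotypes` (a list
#'   of two named character vectors, substitutions only so lengths equal the
#'   reference) and `truth`, a data.table with columns `seqname`, `pos0`
#'   (0-based), `ref`, `genotype` (unordered diploid, e.g. "AT"), `zygosity`
#'   ("het"/"hom").
#' @export
#' @examples
#' g <- build_template(500, seed = 1)
#' sg <- inject_variation(g, 0.0005, 0.0005, seed = 2)
#' nrow(sg$truth)
inject_variation <- function(ref, het_rate = 5e-4, hom_rate = 5e-4,
                             seed = 1L) {
  ref <- as_ref_genome(ref)
  if (het_rate < 0 || hom_rate < 0 || het_rate + hom_rate > 1)
    stop("rates must be non-negative and sum to at most 1")
  with_stream(seed, "variants", {
    hap1 <- hap2 <- ref$sequences
    truth <- list()
    for (sn in names(ref$sequences)) {
      s <- ref$sequences[[sn]]
      L <- nchar(s)
      u <- runif(L)
      het <- which(u < het_rate)
      hom <- which(u >= het_rate & u < het_rate + hom_rate)
      if (!length(het) && !length(hom)) next
      bases <- strsplit(s, "")[[1]]
      h1 <- h2 <- bases
      alt_of <- function(b) vapply(b, function(x)
        sample(setdiff(.BASES, x), 1L), "")
      gt <- character(0); pos <- integer(0); rb <- character(0)
      zy <- character(0)
      if (length(het)) {
        alt <- alt_of(bases[het])
        which_hap <- sample(1:2, length(het), replace = TRUE)
        h1[het[which_hap == 1]] <- alt[which_hap == 1]
        h2[het[which_hap == 2]] <- alt[which_hap == 2]
        gt <- c(gt, norm_genotype(paste0(bases[het], alt)))
        pos <- c(pos, het - 1L); rb <- c(rb, bases[het])
        zy <- c(zy, rep("het", length(het)))
      }
      if (length(hom)) {
        alt <- alt_of(bases[hom])
        h1[hom] <- alt; h2[hom] <- alt
        gt <- c(gt, paste0(alt, alt))
        pos <- c(pos, hom - 1L); rb <- c(rb, bases[hom])
        zy <- c(zy, rep("hom", length(hom)))
      }
      hap1[[sn]] <- paste(h1, collapse = "")
      hap2[[sn]] <- paste(h2, collapse = "")
      truth[[sn]] <- data.table(seqname = sn, pos0 = pos, ref = rb,
                                genotype = gt, zygosity = zy)
    }
    truth <- if (length(truth)) setorder(rbindlist(truth), seqname, pos0)
    else data.table(seqname = character(), pos0 = integer(),
                    ref = character(), genotype = character(),
                    zygosity = character())
    structure(list(reference = ref,
                   haplotypes = list(hap1 = hap1, hap2 = hap2),
                   truth = truth),
              class = "sample_genome")
  })
}

#' @export
print.sample_genome <- function(x, ...) {
  cat("<sample_genome> ", length(x$haplotypes$hap1), " sequence(s), ",
      nrow(x$truth), " injected variant(s)\n", sep = "")
  invisible(x)
}

#' Simulate error-prone paired-end reads from a diploid sample
#'
#' The number of pairs is `floor(coverage * |G| / (2 * read_len))` (coverage
#' is therefore a lower bound). Each pair draws a haplotype and a start
#' uniformly; the insert length is Gaussian (`insert_mean`, `insert_sd`),
#' redrawn (up to 100 attempts) when shorter than the read or extending past
#' the sequence end. Mate 1 reads the insert's 5' end forward; mate 2 reads
#' the 3' end reverse-complemented. Sequencing errors flip each base to a
#' uniformly chosen different base with probability `error_rate`; base
#' qualities come from [quality_model()]. The true origin of every read is
#' recorded for evaluation only.
#'
#' @param sample A `sample_genome` from [inject_variation()].
#' @param coverage Expected fold-coverage of the genome.
#' @param read_len Read length (nt).
#' @param insert_mean,insert_sd Gaussian insert-size parameters (nt).
#' @param error_rate Per-base sequencing error probability.
#' @param qmodel A [quality_model()]; defaults to the empirical profile at
#'   `read_len`.
#' @param seed Integer seed; drives the `reads` and `qualities` streams.
#' @return An object of class `read_set`: a data.table with columns
#'   `id`, `mate` (1/2), `seq`, `qual` (Phred+33 string), `origin_seq`,
#'   `origin_pos0`, `origin_strand`, `hap`.
#' @export
#' @examples
#' g <- build_template(2000, seed = 1)
#' sg <- inject_variation(g, 0, 0, seed = 1)
#' rs <- sample_pe_reads(sg, coverage = 2, read_len = 36, seed = 1)
#' nrow(rs)  # 2 * floor(2*2000/72)
sample_pe_reads <- function(sample, coverage, read_len = 36L,
                            insert_mean = 250, insert_sd = 30,
                            error_rate = 0.001, qmodel = NULL,
                            seed = 1L) {
  stopifnot(inherits(sample, "sample_genome"), coverage > 0, read_len >= 1)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0,1)")
  if (is.null(qmodel)) qmodel <- quality_model(read_len)
  if (qmodel$read_len != read_len) stop("quality model length mismatch")
  ref <- sample$reference
  lens <- nchar(ref$sequences)
  npairs <- floor(coverage * ref$total_length / (2 * read_len))
  if (npairs < 1) stop("coverage too low for any read pair")

  reads <- with_stream(seed, "reads", {
    sq <- sample(seq_along(lens), npairs, replace = TRUE,
                 prob = lens / sum(lens))
    hap <- sample(1:2, npairs, replace = TRUE)
    ins <- round(rnorm(npairs, insert_mean, insert_sd))
    bad <- which(ins < read_len | ins > lens[sq])
    attempts <- 0L
    while (length(bad)) {
      attempts <- attempts + 1L
      if (attempts > 100L)
        stop("sequence too short for the requested insert distribution")
      ins[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
      bad <- bad[ins[bad] < read_len | ins[bad] > lens[sq][bad]]
    }
    start <- floor(runif(npairs) * (lens[sq] - ins + 1))  # 0-based
    snames <- names(ref$sequences)[sq]
    # substring extraction vectorized by haplotype/sequence group
    seq1 <- character(npairs); seq2 <- character(npairs)
    start2 <- start + ins - read_len
    for (h in 1:2) for (s in unique(sq[hap == h])) {
      idx <- which(hap == h & sq == s)
      hs <- sample$haplotypes[[h]][[s]]
      seq1[idx] <- substring(hs, start[idx] + 1, start[idx] + read_len)
      seq2[idx] <- substring(hs, start2[idx] + 1, start2[idx] + read_len)
    }
    seq2 <- revcomp(seq2)
    ids <- sprintf("r%07d", seq_len(npairs))
    dt <- data.table(
      id = rep(ids, 2L),
      mate = rep(1:2, each = npairs),
      seq = c(seq1, seq2),
      origin_seq = rep(snames, 2L),
      origin_pos0 = c(start, start2),
      origin_strand = rep(c("+", "-"), each = npairs),
      hap = rep(hap, 2L))
    # sequencing errors: per-read error counts, then positions
    if (error_rate > 0) {
      ne <- rbinom(nrow(dt), read_len, error_rate)
      hit <- which(ne > 0)
      for (i in hit) {
        pos <- sample.int(read_len, ne[i])
        ch <- strsplit(dt$seq[i], "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(.BASES, b), 1L), "")
        data.table::set(dt, i, "seq", paste(ch, collapse = ""))
      }
    }
    dt
  })
  qual <- with_stream(seed, "qualities", {
    qm <- sample_qualities(qmodel, nrow(reads))
    vapply(seq_len(ncol(qm)), function(j) intToUtf8(qm[, j] + 33L), "")
  })
  reads[, qual := qual]
  setorder(reads, id, mate)
  data.table::setattr(reads, "class", c("read_set", class(reads)))
  reads[]
}

#' Write a read set as paired FASTQ files
#'
#' Mates are written to `<prefix>_1.fastq` and `<prefix>_2.fastq`
#' (Phred+33). Single-end read sets (no mate 2) are written to
#' `<prefix>.fastq`.
#'
#' @param reads A `read_set`.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  stopifnot(is.data.frame(reads))
  wr <- function(dt, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(dt$seq, dt$id)),
      Biostrings::PhredQuality(dt$qual))
    Biostrings::writeQualityScaledXStringSet(x, path)
    path
  }
  dt <- as.data.table(reads)
  if (all(dt$mate == 1L, na.rm = TRUE)) {
    paths <- wr(dt, paste0(prefix, ".fastq"))
  } else {
    paths <- c(wr(dt[mate == 1L], paste0(prefix, "_1.fastq")),
               wr(dt[mate == 2L], paste0(prefix, "_2.fastq")))
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read set
#'
#' @param path1 FASTQ for mate 1 (or a single-end FASTQ).
#' @param path2 Optional FASTQ for mate 2.
#' @return A `read_set` data.table (origin columns are `NA`: external reads
#'   carry no truth).
#' @export
read_fastq <- function(path1, path2 = NULL) {
  rd <- function(p, m) {
    # Biostrings warns about dropped metadata columns on plain FASTQ input
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
    data.table(id = sub("\\s.*$", "", names(x)), mate = m,
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               origin_seq = NA_character_, origin_pos0 = NA_integer_,
               origin_strand = NA_character_, hap = NA_integer_)
  }
  dt <- if (is.null(path2)) rd(path1, 1L)
  else rbindlist(list(rd(path1, 1L), rd(path2, 2L)))
  setorder(dt, id, mate)
  data.table::setattr(dt, "class", c("read_set", class(dt)))
  dt[]
}

#' Write and read a truth table of injected variants
#'
#' Tab-delimited with columns `seq`, `pos0` (0-based), `ref`, `genotype`,
#' `zygosity`.
#' @param truth The `truth` data.table of a `sample_genome`.
#' @param path File path.
#' @return `read_truth` returns the data.table; `write_truth` returns `path`
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  dt <- as.data.table(read.table(path, header = TRUE, sep = "\t",
                                 colClasses = c("character", "integer",
                                                "character", "character",
                                                "character")))
  setnames(dt, names(dt)[1], "seqname")
  dt
}
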