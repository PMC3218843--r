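# Internal helpers: seeded RNG streams, sequence utilities, genome container.

# One global integer seed drives named per-purpose streams so that each
# component (template / variants / reads / qualities / tie-breaks) is
# independently reproducible. The derived seed stays below 2^31.
stream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

with_stream <- function(seed, purpose, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(stream_seed(seed, purpose))
  force(code)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

phred_to_char <- function(q) {
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L), "")
}

char_to_phred <- function(s) lapply(s, function(x) utf8ToInt(x) - 33L)

#' Construct a reference genome
#'
#' A reference genome is a named set of nucleotide sequences over A, C, G, T,
#' N. This is the known template against which reads are aligned and
#' genotypes are called.
#'
#' @param sequences Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `ref_genome`: a list with `sequences` (named
#'   character vector) and `total_length`.
#' @export
#' @examples
#' ref_genome(c(chr1 = "ACGTACGT"))
ref_genome <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences))))
    stop("sequences must have unique non-empty names")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  if (any(nchar(sequences) == 0)) stop("sequences must be non-empty")
  structure(list(sequences = sequences,
                 total_length = sum(nchar(sequences))),
            class = "ref_genome")
}

as_ref_genome <- function(x) {
  if (inherits(x, "ref_genome")) x else ref_genome(x)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x$sequences), " sequence(s), ",
      x$total_length, " nt total\n", sep = "")
  invisible(x)
}

#' Read and write reference genomes as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param genome A `ref_genome` (or named character vector) to write.
#' @param path File path.
#' @return `read_fasta` returns a `ref_genome`; `write_fasta` returns `path`
#'   invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_ref_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  ref_genome(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
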