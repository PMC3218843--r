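# Independent brute-force oracle for the multi-locus genotype posterior.
#
# Works entirely at the string level: for every candidate multi-locus
# configuration it builds the two explicit haplotype genome strings,
# re-counts mismatches base by base, and evaluates the full joint of
# prior x read likelihoods, then marginalizes. Shares no code with the
# package's likelihood path beyond elementary arithmetic.

GENO10 <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# prior of one diploid genotype given the reference base
oracle_prior1 <- function(g, ref, theta) {
  al <- strsplit(g, "")[[1]]
  n_alt <- sum(al != ref)
  if (n_alt == 0) 1 - theta - theta^2
  else if (al[1] == al[2]) theta / 6          # homozygous alternative
  else if (n_alt == 1) theta / 6              # het with one alternative
  else theta^2 / 3                            # het with two alternatives
}

# P(read | template string), mixing quality-specific and binomial models
oracle_read_template <- function(seq, qual, tmpl, params) {
  rb <- strsplit(seq, "")[[1]]
  tb <- strsplit(tmpl, "")[[1]]
  p <- 10^(-qual / 10)
  mm <- rb != tb
  pr <- prod(ifelse(mm, p / 3, 1 - p))
  pb <- dbinom(sum(mm), length(rb), params$e)
  if (params$lambda_on_read)
    params$lambda * pr + (1 - params$lambda) * pb
  else (1 - params$lambda) * pr + params$lambda * pb
}

# P(read | diploid genome) = (1/(d+1)) sum over placements of the average
# over the two haplotype templates
oracle_read_lik <- function(read, haps, params) {
  pl <- read$placements
  tot <- 0
  for (i in seq_len(nrow(pl))) {
    L <- nchar(read$seq)
    for (h in 1:2) {
      tmpl <- substring(haps[[h]][[pl$rname[i]]], pl$pos0[i] + 1,
                        pl$pos0[i] + L)
      if (pl$strand[i] == "-") {
        p <- oracle_read_template(oracle_revcomp(read$seq), rev(read$qual),
                                  tmpl, params)
      } else {
        p <- oracle_read_template(read$seq, read$qual, tmpl, params)
      }
      tot <- tot + 0.5 * p
    }
  }
  tot / nrow(pl)
}

substitute_base <- function(seqs, rname, pos0, base) {
  s <- seqs[[rname]]
  substr(s, pos0 + 1, pos0 + 1) <- base
  seqs[[rname]] <- s
  seqs
}

# Exhaustive posterior of the genotype at `focal` (list(rname, locus)).
#
# reads: list of list(seq, qual, placements = data.frame(rname, pos0,
#   strand)); placements are taken as given (they define d+1).
# group: list of loci (list(rname, locus)) that may carry a variant;
#   must include focal. vary = "focal" restricts configurations to those
#   in which only the focal locus deviates from the reference; vary =
#   "group" enumerates every configuration with at most one deviating
#   locus among the group (the restriction implied by one-deviation-per-
#   read when all multireads span the whole group).
oracle_posterior <- function(genome, reads, focal, group = list(focal),
                             params = model_params(), vary = "focal") {
  seqs <- as.list(genome$sequences)
  ref_at <- function(l) substring(seqs[[l$rname]], l$locus + 1, l$locus + 1)
  configs <- list()
  # all-reference configuration
  configs[[1]] <- list(assign = NULL)
  vary_loci <- if (vary == "focal") list(focal) else group
  for (l in vary_loci) {
    rb <- ref_at(l)
    for (g in GENO10) {
      if (g == paste0(rb, rb)) next
      configs[[length(configs) + 1]] <- list(assign = list(locus = l,
                                                           geno = g))
    }
  }
  joint <- numeric(length(configs))
  geno_at_focal <- character(length(configs))
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    hap1 <- seqs; hap2 <- seqs
    prior <- 1
    for (l in group) {
      rb <- ref_at(l)
      g <- paste0(rb, rb)
      if (!is.null(cf$assign) &&
          identical(cf$assign$locus, l)) g <- cf$assign$geno
      prior <- prior * oracle_prior1(g, rb, params$theta)
      al <- strsplit(g, "")[[1]]
      hap1 <- substitute_base(hap1, l$rname, l$locus, al[1])
      hap2 <- substitute_base(hap2, l$rname, l$locus, al[2])
    }
    lik <- 1
    for (rd in reads)
      lik <- lik * oracle_read_lik(rd, list(hap1, hap2), params)
    joint[ci] <- prior * lik
    fg <- paste0(ref_at(focal), ref_at(focal))
    if (!is.null(cf$assign) && identical(cf$assign$locus, focal))
      fg <- cf$assign$geno
    geno_at_focal[ci] <- fg
  }
  post <- vapply(GENO10, function(g)
    sum(joint[geno_at_focal == g]), 0)
  post / sum(post)
}

# Build oracle-format reads from a package pileup: every alignment of each
# read becomes a placement.
oracle_reads_from_pileup <- function(pileup) {
  alns <- pileup$alignments
  out <- list()
  for (r in unique(alns$rid)) {
    a <- alns[alns$rid == r]
    # reconstruct the read-orientation sequence from the first placement
    seq1 <- if (a$strand[1] == "+") a$aseq[1] else oracle_revcomp(a$aseq[1])
    q1 <- utf8ToInt(a$aqual[1]) - 33L
    if (a$strand[1] == "-") q1 <- rev(q1)
    out[[r]] <- list(seq = seq1, qual = q1,
                     placements = data.frame(rname = a$rname,
                                             pos0 = a$pos0,
                                             strand = a$strand))
  }
  out
}
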