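# Shared fixture builders: tiny genomes, hand-made read sets, and small
# end-to-end simulations reused across test files.

# a read_set data.table from explicit sequences/qualities
make_reads <- function(seqs, quals = NULL, ids = NULL, mates = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(L)
    paste(rep("I", L), collapse = ""), "")  # Phred 40
  if (is.null(ids)) ids <- sprintf("t%03d", seq_len(n))
  if (is.null(mates)) mates <- rep(1L, n)
  data.table::data.table(id = ids, mate = mates, seq = seqs, qual = quals,
                         origin_seq = NA_character_,
                         origin_pos0 = NA_integer_,
                         origin_strand = NA_character_, hap = NA_integer_)
}

# deterministic two-copy genome: `unit` duplicated with given edits
# edits: list of list(pos0 = <offset in copy 2>, base = <new base>)
two_copy_genome <- function(unit, edits = list(), name = "tmpl") {
  copy2 <- unit
  for (e in edits) substr(copy2, e$pos0 + 1, e$pos0 + 1) <- e$base
  ref_genome(stats::setNames(paste0(unit, copy2), name))
}

# full small pipeline: returns everything needed by strategy/genotype tests
sim_small <- function(unit_length = 2000, copies = 2, divergence = 0.05,
                      coverage = 20, seed = 1, k = 2, strategy = "all",
                      het_rate = 5e-4, hom_rate = 5e-4,
                      error_rate = 0.001) {
  g <- build_template(unit_length, copies, divergence, seed = seed)
  sg <- inject_variation(g, het_rate, hom_rate, seed = seed + 1)
  rs <- sample_pe_reads(sg, coverage, error_rate = error_rate,
                        seed = seed + 2)
  al <- align_reads(rs, g, k = k)
  mp <- apply_strategy(al, strategy, seed = seed + 3)
  list(genome = g, sample = sg, reads = rs, alnset = al, map = mp)
}

expect_setequal_dt <- function(a, b) {
  testthat::expect_equal(nrow(data.table::fsetdiff(a, b)), 0)
  testthat::expect_equal(nrow(data.table::fsetdiff(b, a)), 0)
}
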