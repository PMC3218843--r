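# strategy fixtures: one read unit with controlled placements built on a
# two-copy template with a single inter-copy edit
strategy_fixture <- function() {
  unit <- "CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTG"
  g <- two_copy_genome(unit, edits = list(list(pos0 = 10, base = "T")))
  # read matching copy 1 exactly, copy 2 with one mismatch (the edit)
  rd <- substring(unit, 6, 25)
  al <- align_reads(make_reads(rd), g, k = 1)
  list(genome = g, alnset = al)
}

test_that("strategies keep the documented placements", {
  fx <- strategy_fixture()
  expect_equal(nrow(fx$alnset$alignments), 2)  # mismatches (0, 1)

  uni <- apply_strategy(fx$alnset, "uni")
  bestno <- apply_strategy(fx$alnset, "bestno")
  best <- apply_strategy(fx$alnset, "best", seed = 3)
  all_ <- apply_strategy(fx$alnset, "all")

  # UNI discards the multiread; BESTNO and BEST keep the 0-mismatch
  # placement; ALL keeps both
  expect_equal(nrow(uni$alignments), 0)
  expect_equal(nrow(bestno$alignments), 1)
  expect_equal(bestno$alignments$nm, 0)
  expect_equal(nrow(best$alignments), 1)
  expect_equal(best$alignments$nm, 0)
  expect_equal(nrow(all_$alignments), 2)
  expect_equal(all_$alignments$d1, c(2L, 2L))
})

test_that("exact ties: BESTNO discards, BEST picks one, ALL keeps all", {
  g <- two_copy_genome("CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTG")
  rd <- substring(g$sequences[[1]], 6, 25)
  al <- align_reads(make_reads(rd), g, k = 1)
  expect_equal(nrow(al$alignments), 2)
  expect_equal(al$alignments$nm, c(0L, 0L))

  expect_equal(nrow(apply_strategy(al, "bestno")$alignments), 0)
  b <- apply_strategy(al, "best", seed = 11)
  expect_equal(nrow(b$alignments), 1)
  # deterministic replay with the same seed
  b2 <- apply_strategy(al, "best", seed = 11)
  expect_identical(b$alignments$pos0, b2$alignments$pos0)
  expect_equal(nrow(apply_strategy(al, "all")$alignments), 2)
})

test_that("a uniquely mapping read is retained identically by all four", {
  g <- build_template(300, seed = 31)
  rd <- substring(g$sequences[[1]], 50, 85)
  al <- align_reads(make_reads(rd), g, k = 0)
  for (st in c("uni", "bestno", "best", "all")) {
    m <- apply_strategy(al, st)
    expect_equal(nrow(m$alignments), 1, info = st)
    expect_equal(m$alignments$pos0, 49, info = st)
    expect_equal(m$alignments$d1, 1L, info = st)
  }
})

test_that("ALL uses max-d semantics: over-cap reads are wholly discarded", {
  unit <- "ATACAGTATTCTGACACCACAGAAC"
  g <- ref_genome(c(s = paste(rep(unit, 3), collapse = "")))
  rd <- substring(unit, 6, 17)
  al <- align_reads(make_reads(rd), g, k = 0)
  expect_equal(nrow(al$alignments), 3)
  expect_equal(nrow(apply_strategy(al, "all", d_cap = 2)$alignments), 0)
  expect_equal(nrow(apply_strategy(al, "all", d_cap = 3)$alignments), 3)
})

test_that("retained-read counts obey the strategy ordering", {
  sim <- sim_small(unit_length = 1200, copies = 2, divergence = 0.02,
                   coverage = 10, seed = 32)
  n_units <- function(m) data.table::uniqueN(m$alignments$unit)
  nu <- n_units(apply_strategy(sim$alnset, "uni"))
  nbn <- n_units(apply_strategy(sim$alnset, "bestno"))
  nb <- n_units(apply_strategy(sim$alnset, "best"))
  na_ <- n_units(apply_strategy(sim$alnset, "all"))
  expect_lte(nu, nbn)
  expect_lte(nbn, nb)
  expect_lte(nu, na_)

  # loci covered by ALL are a superset of loci covered by UNI
  pu_a <- build_pileups(apply_strategy(sim$alnset, "all"), sim$genome)
  pu_u <- build_pileups(apply_strategy(sim$alnset, "uni"), sim$genome)
  la <- unique(pu_a$entries[, .(rname, locus)])
  lu <- unique(pu_u$entries[, .(rname, locus)])
  expect_equal(nrow(data.table::fsetdiff(lu, la)), 0)
})

test_that("strategy application is idempotent and order-independent", {
  sim <- sim_small(unit_length = 800, copies = 2, divergence = 0.02,
                   coverage = 6, seed = 33)
  m1 <- apply_strategy(sim$alnset, "all")
  # feed the retained set back through the same strategy
  again <- structure(list(alignments = m1$alignments, k = sim$alnset$k,
                          genome_names = sim$alnset$genome_names),
                     class = "alignment_set")
  m2 <- apply_strategy(again, "all")
  expect_equal(data.table::setorder(copy(m1$alignments), unit, placement,
                                    mate, rname, pos0)[, .(unit, pos0, nm)],
               data.table::setorder(copy(m2$alignments), unit, placement,
                                    mate, rname, pos0)[, .(unit, pos0, nm)])
  # permuting the input rows changes nothing
  perm <- structure(list(
    alignments = sim$alnset$alignments[sample(.N)],
    k = sim$alnset$k, genome_names = sim$alnset$genome_names),
    class = "alignment_set")
  m3 <- apply_strategy(perm, "uni")
  m4 <- apply_strategy(sim$alnset, "uni")
  expect_setequal_dt(m3$alignments[, .(unit, rname, pos0, strand)],
                     m4$alignments[, .(unit, rname, pos0, strand)])
})

test_that("pileups cover every aligned base exactly once", {
  g <- build_template(400, seed = 34)
  rd <- substring(g$sequences[[1]], 100, 135)
  al <- align_reads(make_reads(rd), g, k = 0)
  pu <- build_pileups(apply_strategy(al, "all"), g)
  # single read of length L: L columns of depth 1
  expect_equal(nrow(pu$entries), 36)
  expect_equal(pu$entries$locus, 99:134)
  expect_true(all(pu$entries$d1 == 1L))

  # depth conservation on a full simulation
  sim <- sim_small(unit_length = 1000, copies = 2, divergence = 0.05,
                   coverage = 8, seed = 35)
  pu2 <- build_pileups(sim$map, sim$genome)
  expect_equal(nrow(pu2$entries), sum(nchar(sim$map$alignments$aseq)))
})

test_that("pileup entries expose their other-placement contexts", {
  g <- two_copy_genome("CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTG")
  rd <- substring(g$sequences[[1]], 6, 25)
  al <- align_reads(make_reads(rd), g, k = 0)
  pu <- build_pileups(apply_strategy(al, "all"), g)
  col <- pileup_column(pu, "tmpl", 10)
  expect_equal(nrow(col$entries), 1)
  # the entry lists exactly one other context, the homologous position
  # in the second copy
  expect_equal(nrow(col$others), 1)
  expect_equal(col$others$other_locus, 10 + 43)
  # and the mirror column points back
  col2 <- pileup_column(pu, "tmpl", 10 + 43)
  expect_equal(col2$others$other_locus, 10)
})

test_that("map statistics and k selection follow their definitions", {
  g <- build_template(300, seed = 36)
  rd1 <- substring(g$sequences[[1]], 21, 56)
  rd2 <- substring(g$sequences[[1]], 41, 76)
  al <- align_reads(make_reads(c(rd1, rd2)), g, k = 0)
  st <- map_stats(apply_strategy(al, "all"), g)
  expect_equal(st$n_reads, 2)
  expect_equal(st$mean_alignments, 1)
  expect_equal(st$frac_loci_covered, 56 / 300)
  # loci 20..55 and 40..75 covered; 40..55 at depth 2
  expect_equal(st$mean_depth, 72 / 56)
  expect_equal(st$degeneracy_ratio, st$mean_depth)
  expect_equal(st$frac_reads_nonunique, 0)

  fake <- function(r) structure(list(degeneracy_ratio = r),
                                class = "map_stats")
  expect_equal(select_k(list(`1` = fake(10), `2` = fake(12.5),
                             `3` = fake(9))), 2L)
  expect_equal(select_k(list(`2` = fake(5))), 2L)
  # ties resolve to the smallest k
  expect_equal(select_k(list(`3` = fake(7), `1` = fake(7))), 1L)
  expect_error(select_k(list()))
})

test_that("alignments per read on a divergent two-copy template track the
           binomial expectation", {
  # a 36-nt window of the second copy differs at Binomial(36, div) sites;
  # a placement on the paralog survives at k = 2 when that count is <= 2,
  # so E[APR] for single-end reads is ~ 1 + P[Binom(36, 0.05) <= 2] and
  # paired units need both windows compatible
  sim <- sim_small(unit_length = 4000, copies = 2, divergence = 0.05,
                   coverage = 15, seed = 37, k = 2)
  st <- map_stats(apply_strategy(sim$alnset, "all"), sim$genome)
  p2 <- pbinom(2, 36, 0.05)
  lo <- 1 + p2^2 - 0.2   # paired-unit bound, generous band
  hi <- 1 + p2 + 0.2     # single-end bound
  expect_gt(st$mean_alignments, lo)
  expect_lt(st$mean_alignments, hi)
})
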