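# helper: a hand-built pileup column with one read over ref "A" carrying
# `base`, plus d identical background placements
manual_column <- function(base = "T", q = 30, d = 0L, n_len = 4L,
                          bg_nm = 1L) {
  aseq <- paste(c(base, rep("A", n_len - 1L)), collapse = "")
  aqual <- paste(rep(intToUtf8(q + 33), n_len), collapse = "")
  nal <- 1L + d
  alns <- data.table::data.table(
    unit = "r1/1", placement = seq_len(nal), mate = 1L,
    rname = "s", pos0 = c(0L, rep(1000L, d)), strand = "+",
    nm = c(1L, rep(bg_nm, d)),
    mism = c(list(0L), rep(list(
      if (bg_nm > 0) seq_len(bg_nm) - 1L else integer(0)), d)),
    aseq = aseq, aqual = aqual, paired = FALSE,
    mate_pos0 = NA_integer_, mate_strand = NA_character_,
    tlen = NA_integer_)
  alns[, aid := .I]
  alns[, rid := "r1/1#1"]
  alns[, d1 := nal]
  entries <- data.table::data.table(
    rname = "s", locus = 0L, aid = 1L, rid = "r1/1#1",
    offset = 0L, nm = 1L, n = n_len, d1 = nal,
    base = base, q = q, focal_mm = TRUE)
  others <- data.table::data.table(
    aid = 1L, rid = "r1/1#1", rname = "s", locus = 0L,
    other_aid = if (d > 0) 2:(d + 1L) else integer(0),
    other_rname = "s",
    other_locus = if (d > 0) rep(1000L, d) else integer(0))
  structure(list(rname = "s", locus = 0L, entries = entries,
                 others = others, alignments = alns),
            class = "pileup_column")
}

test_that("binomial error model evaluates its point mass", {
  expect_equal(p_bin(36, 0, 3e-4), (1 - 3e-4)^36)
  expect_equal(p_bin(36, 0, 3e-4), 0.9892565, tolerance = 1e-6)
  expect_equal(p_bin(2, 1, 0.5), 0.5)
  expect_equal(p_bin(10, 0, 1e-12), 1, tolerance = 1e-9)
  expect_error(p_bin(10, 2, 0))
  expect_error(p_bin(10, 11, 0.1))
})

test_that("read-specific model multiplies per-base terms", {
  expect_equal(p_read(c(30, 30)), 0.999^2)
  expect_equal(p_read(c(30, 30), mismatch_offsets = 1L),
               0.999 * 0.001 / 3)
  expect_equal(p_read(c(1000, 1000)), 1, tolerance = 1e-12)
  expect_error(p_read(c(-5, 30)))
  expect_error(p_read(c(30, 30), mismatch_offsets = 5L))
})

test_that("the mixture interpolates between the two models", {
  p <- model_params(lambda = 1)
  expect_equal(read_template_prob(c(30, 30), integer(0), p), 0.999^2)
  p0 <- model_params(lambda = 0)
  expect_equal(read_template_prob(c(30, 30), integer(0), p0),
               dbinom(0, 2, p0$e))
  # 0.67 * 0.9 + 0.33 * 0.8 = 0.867
  expect_equal(0.67 * 0.9 + (1 - 0.67) * 0.8, 0.867)
  # direction switch swaps the weights
  pa <- model_params(lambda = 0.67, lambda_on_read = TRUE)
  pb <- model_params(lambda = 0.33, lambda_on_read = FALSE)
  expect_equal(read_template_prob(c(20, 25), 0L, pa),
               read_template_prob(c(20, 25), 0L, pb))
})

test_that("genotype prior allocates its class masses and sums to one", {
  pr <- genotype_prior("A", 0.001)
  expect_equal(pr[["AA"]], 0.998999)
  expect_equal(sum(pr), 1)
  expect_equal(sum(pr[c("AC", "AG", "AT")]), 0.001 / 2)
  expect_equal(sum(pr[c("CC", "GG", "TT")]), 0.001 / 2)
  expect_equal(sum(pr[c("CG", "CT", "GT")]), 0.001^2)
  for (th in c(0, 1e-4, 0.01, 0.3))
    expect_equal(sum(genotype_prior("G", th)), 1)
  p0 <- genotype_prior("C", 0)
  expect_equal(unname(p0[genotypes10() == "CC"]), 1)
  expect_error(genotype_prior("A", 0.9))
  expect_error(genotype_prior("Z", 0.001))
})

test_that("stringency transform matches its published anchor points", {
  expect_equal(q_score(1 - 1e-4), 40)
  expect_equal(q_score(1 - 1e-9), 90)
  expect_equal(q_score(0), 0)
  expect_equal(q_score(1), 255)
  expect_equal(q_score(1 - 1e-30, max_q = 100), 100)
  # strictly monotone on [0, 1)
  x <- seq(0, 0.999999, length.out = 200)
  expect_true(all(diff(q_score(x)) > 0))
  expect_error(q_score(-0.1))
})

test_that("read likelihood: allele average, collapse, and washout", {
  params <- model_params()
  col <- manual_column(base = "T", q = 30, d = 0L)
  l_tt <- read_likelihood(col, 1, "TT", params)
  l_aa <- read_likelihood(col, 1, "AA", params)
  l_at <- read_likelihood(col, 1, "AT", params)
  # d = 0: no background, het is the exact average of the homozygotes
  expect_equal(l_at, (l_tt + l_aa) / 2)
  expect_gt(l_tt, l_aa)  # the read carries T

  # explicit check of the hom template collapse against first principles
  p30 <- 10^(-3)
  pr_match <- 0.999^4                    # all four bases match s(T)
  pb_match <- dbinom(0, 4, params$e)
  expect_equal(l_tt, 0.67 * pr_match + 0.33 * pb_match, tolerance = 1e-12)

  # washout: likelihood ratio tends to 1 as d grows (identical reference-
  # matching background placements, so the background term is O(d))
  for (d in c(1e3, 1e6)) {
    cold <- manual_column(base = "T", q = 30, d = as.integer(d),
                          bg_nm = 0L)
    r <- read_likelihood(cold, 1, "TT", params) /
      read_likelihood(cold, 1, "AA", params)
    expect_lt(abs(r - 1), 10 / d)
  }
  # with mismatching background placements the decay is slower but still
  # monotone toward even odds
  r3 <- read_likelihood(manual_column(d = 1000L), 1, "TT", params) /
    read_likelihood(manual_column(d = 1000L), 1, "AA", params)
  r6 <- read_likelihood(manual_column(d = 1000000L), 1, "TT", params) /
    read_likelihood(manual_column(d = 1000000L), 1, "AA", params)
  expect_lt(abs(r6 - 1), abs(r3 - 1) / 100)
  expect_lt(abs(r6 - 1), 0.01)
})

test_that("zero-depth columns return the prior", {
  g <- build_template(100, seed = 41)
  al <- align_reads(make_reads(substring(g$sequences[[1]], 10, 29)), g, 0)
  pu <- build_pileups(apply_strategy(al, "all"), g)
  col <- pileup_column(pu, names(g$sequences), 80)  # uncovered locus
  expect_equal(nrow(col$entries), 0)
  post <- locus_posterior(col, model_params(), ref_base = "C")
  expect_equal(post$posterior, genotype_prior("C", 0.001))
  expect_equal(post$depth, 0)
})

test_that("consistent unique coverage yields a confident variant call", {
  # 50 error-free unique reads all carrying T over reference A
  g <- build_template(400, seed = 42)
  s <- g$sequences[[1]]
  locus <- 199L
  ref <- substring(s, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  reads <- vapply(1:50, function(i) {
    st <- 200 - 36 + ((i * 7) %% 35) + 1
    rd <- substring(s, st, st + 35)
    substr(rd, 200 - st + 1, 200 - st + 1) <- alt
    rd
  }, "")
  al <- align_reads(make_reads(reads), g, k = 1)
  pu <- build_pileups(apply_strategy(al, "all"), g)
  col <- pileup_column(pu, names(g$sequences), locus)
  post <- locus_posterior(col, model_params(), ref_base = ref)
  expect_equal(post$map_genotype, paste0(alt, alt))
  expect_gt(post$Q, 90)
})

test_that("column posterior matches exhaustive template enumeration", {
  # two-copy genome, one inter-copy edit, mixed unique/multi reads
  unit <- "ATACAGTATTCTGACACCACAGAAC"
  g <- two_copy_genome(unit, edits = list(list(pos0 = 12, base = "T")))
  params <- model_params()
  win1 <- substring(g$sequences[[1]], 6, 17)   # copy-1 window
  win2 <- substring(g$sequences[[1]], 31, 42)  # copy-2 window (the edit)
  wvar <- win1
  substr(wvar, 7, 7) <- "A"                    # variant-carrying read
  reads <- make_reads(c(win1, win2, wvar),
                      quals = c("IIIIIIIIIIII", "555555555555",
                                "IIII(IIIIIII"))
  al <- align_reads(reads, g, k = 3)
  pu <- build_pileups(apply_strategy(al, "all"), g)
  orc_reads <- oracle_reads_from_pileup(pu)
  for (locus in c(8L, 12L, 10L)) {
    col <- pileup_column(pu, "tmpl", locus)
    ref <- substring(g$sequences[[1]], locus + 1, locus + 1)
    got <- locus_posterior(col, params, ref_base = ref)$posterior
    covering <- unique(col$entries$rid)
    want <- oracle_posterior(g, orc_reads[covering],
                             focal = list(rname = "tmpl", locus = locus),
                             params = params, vary = "focal")
    expect_equal(unname(got), unname(want), tolerance = 1e-9,
                 info = paste("locus", locus))
  }
})

test_that("multi-locus resolution matches full configuration enumeration", {
  params <- model_params()
  for (copies in 2:3) {
    unit <- "ATACAGTATTCTGACACCACAGAAC"
    seqs <- unit
    if (copies >= 2) seqs <- c(seqs, sub("T", "C", unit))  # edit at char 2
    if (copies >= 3) seqs <- c(seqs, sub("C", "T", unit))  # edit at char 4
    g <- ref_genome(stats::setNames(paste(seqs, collapse = ""), "tmpl"))
    L <- nchar(unit)
    # reads spanning the same window of every copy (the inter-copy edits
    # sit outside the window, so all multireads cover the whole paralog
    # group), plus a variant-carrying read
    win <- substring(unit, 6, 17)
    varread <- win
    substr(varread, 4, 4) <- "G"
    reads <- make_reads(c(win, win, varread),
                        quals = c("IIIIIIIIIIII", "IIIIIIIIIIII",
                                  "IIIIII5IIIII"))
    al <- align_reads(reads, g, k = 2)
    pu <- build_pileups(apply_strategy(al, "all"), g)
    gt <- genotype_pileups(pu, g, params)
    post <- attr(gt, "posterior")
    orc_reads <- oracle_reads_from_pileup(pu)
    focal <- list(rname = "tmpl", locus = 8L)
    group <- lapply(seq_len(copies) - 1L, function(ci)
      list(rname = "tmpl", locus = 8L + ci * L))
    want <- oracle_posterior(g, orc_reads, focal = focal, group = group,
                             params = params, vary = "group")
    row <- which(gt$rname == "tmpl" & gt$pos0 == 8L)
    expect_equal(unname(post[row, ]), unname(want), tolerance = 1e-9,
                 info = paste("copies", copies))
    # and at the second copy of the group
    focal2 <- group[[2]]
    want2 <- oracle_posterior(g, orc_reads, focal = focal2, group = group,
                              params = params, vary = "group")
    row2 <- which(gt$rname == "tmpl" & gt$pos0 == focal2$locus)
    expect_equal(unname(post[row2, ]), unname(want2), tolerance = 1e-9)
  }
})

test_that("posteriors are normalized and degeneracy dilutes confidence", {
  sim <- sim_small(unit_length = 1200, copies = 2, divergence = 0.05,
                   coverage = 15, seed = 43)
  pu <- build_pileups(sim$map, sim$genome)
  gt <- genotype_pileups(pu, sim$genome)
  post <- attr(gt, "posterior")
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_true(all(gt$Q >= 0))
  expect_true(all(gt$map_genotype %in% genotypes10()))
})

test_that("large multiplicity drives the posterior to the prior", {
  params <- model_params()
  col <- manual_column(base = "T", q = 30, d = 1000000L, bg_nm = 0L)
  post <- locus_posterior(col, params, ref_base = "A")$posterior
  prior <- genotype_prior("A", params$theta)
  expect_lt(max(abs(post - prior)), 1e-6)
})

test_that("significance calling honors thresholds and the degeneracy
           correction", {
  mk <- function(map_genotype, Q, m_l, ref = "A") {
    dt <- data.table::data.table(
      rname = "s", pos0 = 1L, ref = ref, map_genotype = map_genotype,
      post_map = 1 - 10^(-Q / 10), Q = Q, depth = 10L,
      multiplicity = 1, degeneracy = 0, m_l = m_l, vaf = 0.5)
    data.table::setattr(dt, "class", c("genotype_table", class(dt)))
    dt
  }
  params <- model_params(q_threshold = 40)
  # MAP = hom-ref is never significant, however confident
  expect_false(call_variants(mk("AA", 200, 1), params)$significant)
  # unique locus: threshold applies unchanged
  expect_true(call_variants(mk("AT", 45, 1), params)$significant)
  # locus linked to 9 others: Q_eff = 40 + 10*log10(10) = 50
  expect_false(call_variants(mk("AT", 45, 10), params)$significant)
  expect_true(call_variants(mk("AT", 51, 10), params)$significant)
  # correction off
  off <- model_params(q_threshold = 40, degeneracy_correction = FALSE)
  expect_true(call_variants(mk("AT", 45, 10), off)$significant)
})

test_that("information diagnostic behaves as the odds analysis predicts", {
  expect_equal(information_diagnostic(10, 5, 0.3, 0.3), 0)
  # increasing in depth at fixed d
  n <- c(1, 5, 10, 50)
  v <- information_diagnostic(n, 2, 0.9, 0.5, c = 0.5)
  expect_true(all(diff(v) > 0))
  # decreasing in multiplicity, tending to zero
  d <- c(0, 1, 10, 100, 1e4)
  w <- information_diagnostic(10, d, 0.9, 0.5, c = 0.5)
  expect_true(all(diff(w) < 0))
  expect_lt(w[length(w)], 1e-3)
  expect_gt(w[1], 1)
  expect_error(information_diagnostic(10, 1, 0, 0.5))
})

test_that("calls export to TSV and VCF and read back consistently", {
  sim <- sim_small(unit_length = 1500, copies = 1, coverage = 20,
                   het_rate = 0.002, hom_rate = 0.002, seed = 44)
  pu <- build_pileups(sim$map, sim$genome)
  calls <- call_variants(genotype_pileups(pu, sim$genome))
  expect_gt(sum(calls$significant), 0)
  tmp <- withr::local_tempdir()
  write_calls_tsv(calls, file.path(tmp, "calls.tsv"))
  back <- read_calls_tsv(file.path(tmp, "calls.tsv"))
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$MAP_genotype, calls$map_genotype)

  write_vcf(calls, sim$genome, file.path(tmp, "calls.vcf"))
  vcf <- VariantAnnotation::readVcf(file.path(tmp, "calls.vcf"))
  sig <- calls[significant == TRUE]
  expect_equal(nrow(vcf), nrow(sig))
  expect_equal(as.integer(SummarizedExperiment::start(
    SummarizedExperiment::rowRanges(vcf))), sig$pos0 + 1L)
  expect_equal(unname(VariantAnnotation::geno(vcf)$DP[, 1]), sig$depth)
})
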