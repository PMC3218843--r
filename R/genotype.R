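# The Bayesian genotyping core.
#
# For a read r covering a focal locus with d other placements, the
# likelihood under diploid genotype xy is
#
#   P(r | G_xy) = (1/(d+1)) * [ 1/2 P(r|s(x)) + 1/2 P(r|s(y)) + sum_j p_bg_j ]
#
# where s(a) is the reference template with allele a substituted at the
# focal position, and each background term p_bg_j evaluates the read
# against its j-th other placement with the reference base there (at most
# one of a read's placements deviates from the reference at the read's
# focal offset). A read-template probability mixes a global binomial error
# model with the read's quality string:
#
#   P(r|s) = lambda * P_read + (1 - lambda) * P_bin(n, k_obs, e)
#
# Per-locus posteriors over the ten diploid genotypes follow by Bayes with
# a heterozygosity-derived prior; an optional multi-locus resolution step
# renormalizes posterior mass across paralogous loci linked by shared
# multi-mapped reads (the configuration space in which at most one linked
# locus carries a variant).

#' Genotyping model parameters
#'
#' @param e Global per-base sequencing error rate for the binomial error
#'   model. Default 0.0003.
#' @param lambda Mixture weight on the read-specific quality model;
#'   `1 - lambda` falls on the global binomial model. Default 0.67. Set
#'   `lambda_on_read = FALSE` to give `lambda` to the binomial model
#'   instead (the mixture direction reversed).
#' @param theta Population heterozygosity prior parameter. Default 0.001.
#' @param q_threshold Minimum stringency Q for a significant SNP call.
#' @param max_q Cap applied to Q scores.
#' @param degeneracy_correction Apply the per-site Bonferroni-style
#'   stringency correction `Q_eff = q_threshold + 10*log10(m_l)`, where
#'   `m_l` counts the focal locus plus the distinct loci linked to it by
#'   shared multi-mapped reads.
#' @param multilocus Resolve posterior mass across linked paralogous loci
#'   (marginalization over single-variant multi-locus configurations)
#'   before calling. When `FALSE` every locus is genotyped from its own
#'   column alone.
#' @param lambda_on_read Mixture direction switch, see `lambda`.
#' @return A `model_params` object.
#' @export
#' @examples
#' model_params()
model_params <- function(e = 3e-4, lambda = 0.67, theta = 0.001,
                         q_threshold = 40, max_q = 255,
                         degeneracy_correction = TRUE,
                         multilocus = TRUE,
                         lambda_on_read = TRUE) {
  if (e <= 0 || e >= 1) stop("e must be in (0,1)")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0,1]")
  if (theta < 0 || theta >= 1 || theta + theta^2 >= 1)
    stop("theta must satisfy 0 <= theta and theta + theta^2 < 1")
  structure(list(e = e, lambda = lambda, theta = theta,
                 q_threshold = q_threshold, max_q = max_q,
                 degeneracy_correction = isTRUE(degeneracy_correction),
                 multilocus = isTRUE(multilocus),
                 lambda_on_read = isTRUE(lambda_on_read)),
            class = "model_params")
}

#' Global binomial error model
#'
#' Point binomial mass `C(n, k) e^k (1-e)^(n-k)`: the probability of
#' observing exactly `kobs` mismatches over a read of length `n` under a
#' uniform per-base error rate `e`.
#'
#' @param n Read length.
#' @param kobs Observed mismatch count, `0 <= kobs <= n`.
#' @param e Per-base error rate in (0,1).
#' @return Probability.
#' @export
#' @examples
#' p_bin(36, 0, 0.0003)  # (1 - 0.0003)^36
p_bin <- function(n, kobs, e) {
  if (any(e <= 0 | e >= 1)) stop("e must be in (0,1)")
  if (any(kobs < 0 | kobs > n)) stop("kobs must be in [0, n]")
  dbinom(kobs, n, e)
}

#' Read-specific quality model
#'
#' `prod over matches (1 - p_i) * prod over mismatches (p_i / 3)` with
#' `p_i = 10^(-q_i/10)`: matching positions contribute their probability of
#' being called correctly, mismatching positions the probability of the one
#' specific erroneous call observed (uniform over the three alternatives).
#'
#' @param qualities Integer Phred scores along the read.
#' @param mismatch_offsets 0-based positions (within the read) that
#'   mismatch the template.
#' @return Probability.
#' @export
#' @examples
#' p_read(c(30, 30), integer(0))  # 0.999^2
#' p_read(c(30, 30), 1L)          # 0.999 * 0.001/3
p_read <- function(qualities, mismatch_offsets = integer(0)) {
  if (any(qualities < 0)) stop("negative qualities")
  if (any(mismatch_offsets < 0 | mismatch_offsets >= length(qualities)))
    stop("mismatch offsets outside the read")
  p <- 10^(-qualities / 10)
  mm <- logical(length(qualities))
  mm[mismatch_offsets + 1L] <- TRUE
  prod(ifelse(mm, p / 3, 1 - p))
}

#' Mixture read-template probability
#'
#' `lambda * P_read + (1 - lambda) * P_bin` (or the reverse direction when
#' `lambda_on_read = FALSE` in the parameters): the probability that the
#' read was sequenced from the given template.
#'
#' @param qualities Integer Phred scores along the read.
#' @param mismatch_offsets 0-based mismatching positions against the
#'   hypothesized template.
#' @param params [model_params()].
#' @return Probability.
#' @export
read_template_prob <- function(qualities, mismatch_offsets, params) {
  pr <- p_read(qualities, mismatch_offsets)
  pb <- p_bin(length(qualities), length(mismatch_offsets), params$e)
  mix_probs(pr, pb, params)
}

mix_probs <- function(pr, pb, params) {
  if (params$lambda_on_read) params$lambda * pr + (1 - params$lambda) * pb
  else (1 - params$lambda) * pr + params$lambda * pb
}

#' Genotype prior from population heterozygosity
#'
#' Pr{homozygous reference} `= 1 - theta - theta^2`; mass `theta/2` split
#' equally over the three single-alternative heterozygotes; `theta/2` over
#' the three homozygous alternatives; `theta^2` over the three
#' double-alternative heterozygotes. Sums to 1 exactly.
#'
#' @param ref_base Reference base, one of A, C, G, T.
#' @param theta Heterozygosity parameter.
#' @return Named numeric vector over [genotypes10()].
#' @export
#' @examples
#' genotype_prior("A", 0.001)[["AA"]]  # 0.998999
genotype_prior <- function(ref_base, theta) {
  ref_base <- toupper(ref_base)
  if (!ref_base %in% .BASES) stop("ref_base must be one of A,C,G,T")
  if (theta < 0 || 1 - theta - theta^2 < 0)
    stop("theta leaves negative homozygous-reference mass")
  alt <- setdiff(.BASES, ref_base)
  pr <- setNames(numeric(10), .G10)
  pr[paste0(ref_base, ref_base)] <- 1 - theta - theta^2
  pr[norm_genotype(paste0(ref_base, alt))] <- theta / 6
  pr[paste0(alt, alt)] <- theta / 6
  dbl <- norm_genotype(c(paste0(alt[1], alt[2]), paste0(alt[1], alt[3]),
                         paste0(alt[2], alt[3])))
  pr[dbl] <- theta^2 / 3
  pr
}

#' Stringency score of a posterior probability
#'
#' `Q = -10 log10(1 - P)`, capped at `max_q`. `Q >= 40` corresponds to a
#' MAP-genotype posterior error below `1e-4`, `Q >= 90` to below `1e-9`,
#' and `Q >= 13` to `P < 0.05`.
#'
#' @param P Posterior probability in `[0, 1]`.
#' @param max_q Cap (returned when `P = 1` or the transform exceeds it).
#' @return Q on the phred-like scale.
#' @export
#' @examples
#' q_score(1 - 1e-4)  # 40
q_score <- function(P, max_q = 255) {
  if (any(P < 0 | P > 1)) stop("P must be in [0,1]")
  q <- ifelse(P >= 1, Inf, -10 * log10(1 - P))
  pmin(pmax(q, 0), max_q)
}

# ---- shared likelihood core ----

# per-alignment quantities: log P_read (all positions, against the
# reference) and the mixture template probability P(r|s_ref)
aln_probs <- function(alns, params) {
  a <- copy(alns)
  n <- nchar(a$aseq)
  # flattened per-base qualities for all alignments at once
  qall <- utf8ToInt(paste(a$aqual, collapse = "")) - 33L
  row <- rep(seq_len(nrow(a)), n)
  p <- 10^(-qall / 10)
  lg <- log1p(-p)
  lp <- as.vector(rowsum(lg, row, reorder = TRUE))
  # replace the match term with the mismatch term at mismatch offsets
  nmm <- lengths(a$mism)
  if (any(nmm > 0)) {
    mmrow <- rep(seq_len(nrow(a)), nmm)
    starts <- cumsum(c(0L, n[-length(n)]))
    flat <- starts[mmrow] + unlist(a$mism) + 1L
    delta <- log(p[flat] / 3) - lg[flat]
    adj <- rowsum(delta, mmrow, reorder = TRUE)
    lp[as.integer(rownames(adj))] <- lp[as.integer(rownames(adj))] + adj[, 1]
  }
  a[, logpread := lp]
  a[, p_all := mix_probs(exp(lp), dbinom(nm, n, params$e), params)]
  a
}

# per-entry likelihood terms: Lm (template allele equals the read base),
# Lmm (any other allele) and the genotype-independent background sum
entry_lik_terms <- function(entries, alns_p, params) {
  e <- copy(entries)
  idx <- match(e$aid, alns_p$aid)
  e[, logpread := alns_p$logpread[idx]]
  e[, p_all := alns_p$p_all[idx]]
  # background: the read's template probability summed over its OTHER
  # placements (all of the read's alignments minus the focal one)
  s <- alns_p[, .(S_read = sum(p_all)), by = rid]
  e[, S_read := s$S_read[match(rid, s$rid)]]
  e[, bg := S_read - p_all]
  p_o <- 10^(-e$q / 10)
  term_focal <- fifelse(e$focal_mm, log(p_o / 3), log1p(-p_o))
  p_rest <- exp(e$logpread - term_focal)
  m0 <- e$nm - e$focal_mm
  pb_m <- dbinom(m0, e$n, params$e)
  pb_mm <- fifelse(m0 + 1L <= e$n, dbinom(pmin(m0 + 1L, e$n), e$n, params$e), 0)
  e[, Lm := mix_probs(p_rest * (1 - p_o), pb_m, params)]
  e[, Lmm := mix_probs(p_rest * (p_o / 3), pb_mm, params)]
  e
}

# per-locus unnormalized log-likelihood matrix (loci x 10 genotypes);
# terms must be sorted by (rname, locus) so gid order equals locus order
loglik_matrix <- function(terms) {
  setorder(terms, rname, locus)
  terms[, gid := .GRP, by = .(rname, locus)]
  M <- matrix(0, nrow(terms), 10L)
  ldiv <- log(terms$d1)
  bidx <- match(terms$base, .BASES)
  for (g in seq_len(10L)) {
    w <- .W10[g, ][bidx]
    w[is.na(w)] <- 0  # 'N' read base supports no allele
    val <- w * terms$Lm + (1 - w) * terms$Lmm + terms$bg
    M[, g] <- log(pmax(val, 1e-300)) - ldiv
  }
  ll <- rowsum(M, terms$gid, reorder = TRUE)
  loci <- unique(terms[, .(gid, rname, locus)])
  setorder(loci, gid)
  list(loci = loci, loglik = ll)
}

#' Per-read likelihood under a diploid genotype
#'
#' `P(r | G_xy) = (1/(d+1)) * [ 1/2 P(r|s(x)) + 1/2 P(r|s(y)) + sum_j
#' p_bg_j ]` for one entry of a pileup column: the allele average over the
#' genotype's two alleles substituted at the focal position, plus the
#' read's background terms against its other placements (reference base
#' there), divided by the number of placements. With `d = 0` this reduces
#' to the allele average alone; for a homozygous genotype the average
#' collapses to a single template; as `d` grows the ratio between any two
#' genotypes' likelihoods tends to 1 (multiread washout).
#'
#' @param column A [pileup_column()].
#' @param i Entry index within the column.
#' @param genotype Unordered diploid genotype, e.g. `"AT"`.
#' @param params [model_params()].
#' @return Likelihood (probability).
#' @export
read_likelihood <- function(column, i, genotype, params = model_params()) {
  stopifnot(inherits(column, "pileup_column"),
            i >= 1, i <= nrow(column$entries))
  genotype <- norm_genotype(genotype)
  if (!genotype %in% .G10) stop("unknown genotype: ", genotype)
  aids <- unique(c(column$entries$aid, column$others$other_aid))
  ap <- aln_probs(column$alignments[aid %in% aids], params)
  terms <- entry_lik_terms(column$entries[i], ap, params)
  if (terms$d1 < 1L) stop("multiplicity must be at least 1")
  w <- if (terms$base %in% .BASES) .W10[genotype, terms$base] else 0
  unname((w * terms$Lm + (1 - w) * terms$Lmm + terms$bg) / terms$d1)
}

#' Posterior genotype distribution at one locus
#'
#' Applies Bayes over the ten diploid genotypes to a single pileup column:
#' `posterior(xy) propto prior(xy) * prod_i P(r_i | G_xy)` with the
#' per-read likelihood described in [read_template_prob()] and the
#' module overview. Computed in log space. A column with no reads returns
#' the prior.
#'
#' @param column A [pileup_column()].
#' @param params [model_params()].
#' @param ref_base Reference base at the locus (taken from the column if
#'   built with a genome).
#' @return A `genotype_posterior`: list with `rname`, `locus`, `ref`,
#'   `posterior` (named 10-vector), `map_genotype`, `P` (MAP posterior),
#'   `Q`, `depth`, `mean_multiplicity`, `degeneracy`.
#' @export
locus_posterior <- function(column, params = model_params(),
                            ref_base = column$ref) {
  stopifnot(inherits(column, "pileup_column"))
  if (is.null(ref_base)) stop("ref_base required")
  prior <- genotype_prior(ref_base, params$theta)
  if (!nrow(column$entries)) {
    post <- prior
  } else {
    ap <- aln_probs(column$alignments[aid %in% unique(
      c(column$entries$aid,
        column$others$other_aid))], params)
    terms <- entry_lik_terms(column$entries, ap, params)
    lm <- loglik_matrix(terms)
    ll <- lm$loglik[1, ] + log(prior)
    if (all(!is.finite(ll))) {
      return(structure(list(rname = column$rname, locus = column$locus,
                            ref = ref_base, posterior = NULL,
                            map_genotype = NA_character_, P = NA_real_,
                            Q = NA_real_, depth = nrow(column$entries),
                            no_call = TRUE), class = "genotype_posterior"))
    }
    post <- exp(ll - logsumexp(ll))
    names(post) <- .G10
  }
  map_i <- map_index(post, paste0(ref_base, ref_base))
  P <- post[[map_i]]
  structure(list(
    rname = column$rname, locus = column$locus, ref = ref_base,
    posterior = post, map_genotype = .G10[map_i], P = P,
    Q = q_score(P, params$max_q),
    depth = nrow(column$entries),
    mean_multiplicity = if (nrow(column$entries))
      mean(column$entries$d1) else NA_real_,
    degeneracy = if (nrow(column$entries))
      sum(column$entries$d1 - 1L) / nrow(column$entries) else NA_real_,
    no_call = FALSE), class = "genotype_posterior")
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat(sprintf("<genotype_posterior> %s:%d ref=%s MAP=%s P=%.6g Q=%.1f\n",
              x$rname, x$locus, x$ref, x$map_genotype, x$P, x$Q))
  invisible(x)
}

# MAP with ties broken toward hom-ref, then lexicographically
map_index <- function(post, ref_geno) {
  ord <- c(match(ref_geno, .G10), setdiff(seq_len(10L), match(ref_geno, .G10)))
  ord[which.max(post[ord])]
}

#' Genotype every covered locus of a pileup
#'
#' Runs the per-locus Bayesian model over all covered loci, then (by
#' default) resolves posterior mass across paralogous loci linked by
#' shared multi-mapped reads: within the restricted configuration space in
#' which at most one linked locus deviates from the reference, the
#' posterior odds of each variant genotype at each locus are renormalized
#' jointly, so evidence that cannot distinguish between paralogs no longer
#' produces confident variant calls at both.
#'
#' @param pileup A [build_pileups()] result.
#' @param genome The [ref_genome()].
#' @param params [model_params()].
#' @param region Optional `list(rname=, start=, end=)` (0-based half-open)
#'   restricting which loci are genotyped (reads overlapping the region
#'   still contribute wherever they align).
#' @return A `genotype_table`: data.table with one row per genotyped locus
#'   (`rname`, `pos0`, `ref`, `map_genotype`, `post_map`, `Q`, `depth`,
#'   `multiplicity`, `degeneracy`, `m_l`, `vaf`) carrying the full
#'   posterior matrix as attribute `"posterior"`.
#' @export
genotype_pileups <- function(pileup, genome, params = model_params(),
                             region = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  genome <- as_ref_genome(genome)
  entries <- pileup$entries
  in_region <- NULL
  if (!is.null(region)) {
    focal <- entries[rname == region$rname & locus >= region$start &
                     locus < region$end]
    # the multi-locus resolution needs the genotype weights of loci linked
    # to the region through shared reads, so extend the working set by one
    # homolog hop; only region loci are reported
    lk <- homolog_links(pileup, focal)
    extra <- unique(lk[, .(rname = other_rname, locus = other_locus)])
    keys <- unique(rbind(focal[, .(rname, locus)], extra))
    entries <- entries[keys, on = c("rname", "locus"), nomatch = NULL]
    in_region <- region
  }
  if (!nrow(entries)) {
    out <- data.table(rname = character(), pos0 = integer(),
                      ref = character(), map_genotype = character(),
                      post_map = numeric(), Q = numeric(),
                      depth = integer(), multiplicity = numeric(),
                      degeneracy = numeric(), m_l = integer(),
                      vaf = numeric())
    data.table::setattr(out, "posterior", matrix(0, 0, 10))
    data.table::setattr(out, "class", c("genotype_table", class(out)))
    return(out[])
  }
  ap <- aln_probs(pileup$alignments, params)
  terms <- entry_lik_terms(entries, ap, params)
  lm <- loglik_matrix(terms)  # also sorts `terms` by (rname, locus)
  loci <- lm$loci
  refb <- substring(genome$sequences[loci$rname],
                    loci$locus + 1L, loci$locus + 1L)
  # prior matrix by reference base
  logprior <- matrix(0, nrow(loci), 10L)
  for (b in .BASES) {
    i <- which(refb == b)
    if (length(i))
      logprior[i, ] <- matrix(log(genotype_prior(b, params$theta)),
                              length(i), 10L, byrow = TRUE)
  }
  logN <- lm$loglik + logprior
  ref_idx <- match(paste0(refb, refb), .G10)
  ref_idx[is.na(ref_idx)] <- 1L  # 'N' reference: fall back, never called

  # homolog links between loci through shared multi-mapped reads
  links <- homolog_links(pileup, entries)
  loci_key <- paste0(loci$rname, ":", loci$locus)
  m_l <- rep(1L, nrow(loci))
  post <- matrix(0, nrow(loci), 10L, dimnames = list(NULL, .G10))

  logW <- logN - logN[cbind(seq_len(nrow(logN)), ref_idx)]
  # per-locus log sum of non-reference relative weights
  V_ne <- vapply(seq_len(nrow(logW)), function(i)
    logsumexp(logW[i, -ref_idx[i]]), 0)

  if (nrow(links)) {
    lk <- unique(links[, .(fkey = paste0(rname, ":", locus),
                           okey = paste0(other_rname, ":", other_locus))])
    cnt <- lk[, .N, by = fkey]
    m_l[match(cnt$fkey, loci_key)] <- 1L + cnt$N
  }
  if (params$multilocus && nrow(links)) {
    lk[, V_other := V_ne[match(okey, loci_key)]]
    # homologs outside the genotyped set carry prior mass only
    pr_only <- log(params$theta + params$theta^2) -
      log(1 - params$theta - params$theta^2)
    lk[is.na(V_other), V_other := pr_only]
    gsum <- lk[, .(V_sum = logsumexp(V_other)), by = fkey]
    V_grp <- rep(-Inf, nrow(loci))
    V_grp[match(gsum$fkey, loci_key)] <- gsum$V_sum
  } else {
    V_grp <- rep(-Inf, nrow(loci))
  }
  logD <- vapply(seq_len(nrow(loci)), function(i)
    logsumexp(c(0, V_ne[i], V_grp[i])), 0)
  for (i in seq_len(nrow(loci))) {
    p <- exp(logW[i, ] - logD[i])
    p[ref_idx[i]] <- exp(logsumexp(c(0, V_grp[i])) - logD[i])
    post[i, ] <- p
  }

  map_i <- vapply(seq_len(nrow(loci)), function(i)
    map_index(post[i, ], .G10[ref_idx[i]]), 0L)
  P <- post[cbind(seq_len(nrow(loci)), map_i)]
  # 1 - P via the complementary mass, stable when P ~ 1
  P_err <- vapply(seq_len(nrow(loci)), function(i)
    sum(post[i, -map_i[i]]), 0)
  Q <- pmin(ifelse(P_err <= 0, Inf, -10 * log10(P_err)), params$max_q)
  Q <- pmax(Q, 0)

  stats <- terms[, .(depth = .N, multiplicity = mean(d1),
                     degeneracy = sum(d1 - 1L) / .N),
                 keyby = .(rname, locus)]
  # terms and loci are both ordered by (rname, locus) via gid
  vaf <- terms[, .(vaf = mean(base != refb[gid[1]])), keyby = gid]$vaf
  out <- data.table(rname = loci$rname, pos0 = loci$locus, ref = refb,
                    map_genotype = .G10[map_i], post_map = P, Q = Q,
                    depth = stats$depth, multiplicity = stats$multiplicity,
                    degeneracy = stats$degeneracy, m_l = m_l, vaf = vaf)
  if (!is.null(in_region)) {
    sel <- out$rname == in_region$rname & out$pos0 >= in_region$start &
      out$pos0 < in_region$end
    out <- out[sel]
    post <- post[sel, , drop = FALSE]
  }
  data.table::setattr(out, "posterior", post)
  data.table::setattr(out, "class", c("genotype_table", class(out)))
  out[]
}

# distinct homolog locus pairs for all entries (focal -> other)
homolog_links <- function(pileup, entries) {
  oth <- homolog_contexts(pileup, entries)
  unique(oth[, .(rname, locus, other_rname, other_locus)])
}

#' Flag significant SNPs
#'
#' A locus is a significant SNP when its MAP genotype differs from
#' homozygous-reference and its stringency Q reaches the effective
#' threshold. With the degeneracy correction on, the threshold is raised
#' Bonferroni-style by `10*log10(m_l)` where `m_l` counts the locus and
#' the distinct loci linked to it through shared multi-mapped reads.
#'
#' @param genotypes A `genotype_table` from [genotype_pileups()].
#' @param params [model_params()] (supplies `q_threshold` and the
#'   correction switch).
#' @return The table with `q_eff` and `significant` columns added.
#' @export
call_variants <- function(genotypes, params = model_params()) {
  gt <- copy(as.data.table(genotypes))
  post <- attr(genotypes, "posterior")
  gt[, q_eff := if (params$degeneracy_correction)
    params$q_threshold + 10 * log10(m_l) else params$q_threshold]
  gt[, significant := map_genotype != paste0(ref, ref) & Q >= q_eff]
  data.table::setattr(gt, "posterior", post)
  if (!inherits(gt, "genotype_table"))
    data.table::setattr(gt, "class", c("genotype_table", class(gt)))
  gt[]
}

#' Information diagnostic: posterior log-odds under homogeneous reads
#'
#' Exact log posterior-odds between two genotypes when every one of `n`
#' reads has the identical likelihood profile (`p_xy` vs `p_xpyp`), each
#' aligning to `d` other loci with a common background term `c` per
#' placement, and the genotype priors are equal:
#' `n * log((p_xy + d*c) / (p_xpyp + d*c))`. Grows linearly in depth `n`
#' and decays toward 0 as the multiplicity `d` grows: multiply mapped
#' reads dilute genotype information.
#'
#' @param n Read depth.
#' @param d Other-placements per read.
#' @param p_xy,p_xpyp Per-read template probabilities under the two
#'   genotypes.
#' @param c Common background template probability per other placement.
#' @return Natural-log odds.
#' @export
#' @examples
#' information_diagnostic(10, 0, 0.9, 0.5)
#' information_diagnostic(10, 1e6, 0.9, 0.5)  # ~ 0
information_diagnostic <- function(n, d, p_xy, p_xpyp, c = 1) {
  if (any(p_xy <= 0 | p_xy > 1 | p_xpyp <= 0 | p_xpyp > 1))
    stop("probabilities must be in (0,1]")
  n * log((p_xy + d * c) / (p_xpyp + d * c))
}

# ---- output ----

#' Write per-locus genotype calls as TSV
#'
#' Columns: `seq`, `pos1` (1-based), `ref`, `MAP_genotype`, `Q`, `depth`,
#' `mean_multiplicity`, `significant`.
#'
#' @param calls A `genotype_table` (after [call_variants()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  dt <- as.data.table(calls)
  out <- dt[, .(seq = rname, pos1 = pos0 + 1L, ref,
                MAP_genotype = map_genotype, Q = round(Q, 2),
                depth, mean_multiplicity = round(multiplicity, 3),
                significant = if ("significant" %in% names(dt))
                  significant else NA)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a calls TSV back into a table
#' @param path Path written by [write_calls_tsv()].
#' @return data.table with 0-based `pos0` restored.
#' @export
read_calls_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character =
                                              c("seq", "ref",
                                                "MAP_genotype")))
  dt[, pos0 := pos1 - 1L]
  dt[]
}

#' Export significant SNPs as VCF 4.2
#'
#' One record per significant call with `GT` (relative to REF/ALT), `GQ`
#' (the stringency Q, capped at 99 per convention is not applied; raw Q)
#' and `DP` fields for a single sample.
#'
#' @param calls A `genotype_table` after [call_variants()].
#' @param genome The [ref_genome()] (for contig headers).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path, sample_name = "sample") {
  genome <- as_ref_genome(genome)
  dt <- as.data.table(calls)
  if (!"significant" %in% names(dt))
    stop("run call_variants() before exporting VCF")
  dt <- dt[significant == TRUE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=paracall",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$sequences),
            nchar(genome$sequences)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)), con)
  if (nrow(dt)) {
    rec <- vapply(seq_len(nrow(dt)), function(i) {
      al <- strsplit(dt$map_genotype[i], "")[[1]]
      alt <- unique(setdiff(al, dt$ref[i]))
      gtidx <- match(al, c(dt$ref[i], alt)) - 1L
      paste(dt$rname[i], dt$pos0[i] + 1L, ".", dt$ref[i],
            paste(alt, collapse = ","), round(dt$Q[i], 1), "PASS",
            paste0("DP=", dt$depth[i]), "GT:GQ:DP",
            paste(paste(sort(gtidx), collapse = "/"),
                  as.integer(round(dt$Q[i])), dt$depth[i], sep = ":"),
            sep = "\t")
    }, "")
    writeLines(rec, con)
  }
  invisible(path)
}
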