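# Truth-based benchmarking: confusion classification with the
# true-position/false-genotype (TPFG) category, rate metrics in both
# published variants, accuracy transforms, call-set concordance, and the
# closed-form binomial read-loss theory.

#' Classify genotype calls against a truth table
#'
#' Partitions loci into TP (significant call at a truth locus with exactly
#' the true diploid genotype), TPFG (significant call at a truth locus with
#' the wrong genotype), FP (significant call elsewhere), FN (truth locus
#' with no significant call — including truth loci the caller never
#' covered), and TN (the remaining assayed loci). The partition identity
#' `TP + TN + FP + FN + TPFG = |assayed ∪ truth|` always holds.
#'
#' @param calls A `genotype_table` after [call_variants()], or any
#'   data.frame with `rname`, `pos0`, `map_genotype`, `significant`.
#' @param truth Truth table (`seqname`, `pos0`, `genotype`), as produced by
#'   [inject_variation()].
#' @param assayed Optional data.table of assayed loci (`rname`, `pos0`);
#'   defaults to the loci present in `calls` (read depth > 0).
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`, `TPFG`,
#'   `n_assayed`.
#' @export
#' @examples
#' # a perfect caller on 100 loci with 5 truth SNPs -> TP=5, TN=95
classify_calls <- function(calls, truth, assayed = NULL) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (!"seqname" %in% names(truth)) setnames(truth, names(truth)[1],
                                             "seqname")
  if (is.null(assayed)) assayed <- calls[, .(rname, pos0)]
  assayed <- unique(as.data.table(assayed)[, .(rname, pos0)])
  tkey <- paste0(truth$seqname, ":", truth$pos0)
  if (anyDuplicated(tkey)) stop("duplicate truth loci")
  akey <- paste0(assayed$rname, ":", assayed$pos0)
  sig <- calls[significant == TRUE]
  skey <- paste0(sig$rname, ":", sig$pos0)
  if (anyDuplicated(skey)) stop("duplicate call loci")
  ti <- match(skey, tkey)
  at_truth <- !is.na(ti)
  tgt <- norm_genotype(truth$genotype)[ti[at_truth]]
  cgt <- norm_genotype(sig$map_genotype[at_truth])
  TP <- sum(tgt == cgt)
  TPFG <- sum(tgt != cgt)
  FP <- sum(!at_truth)
  called_truth <- tkey %in% skey[at_truth]
  FN <- sum(!called_truth)
  universe <- length(union(akey, tkey))
  TN <- universe - TP - TPFG - FP - FN
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, TPFG = TPFG,
                 n_assayed = universe), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d TPFG=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TPFG, x$n_assayed))
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Two published variants of the sensitivity and accuracy formulas exist;
#' both are computed. `methods`: TPR = TP/(TP+FN), accuracy =
#' (TP+TN)/total. `figure`: TPR = (TP+TPFG)/(TP+TPFG+FN), accuracy =
#' (TP+TPFG+TN)/total (the ROC/bar-chart variant, where a right-position/
#' wrong-genotype call still counts as detection). FDR =
#' (FP+TPFG)/(TP+FP+TPFG) and FPR = (FP+TPFG)/(FP+TPFG+TN) are common to
#' both. Undefined (0/0) rates are returned as `NA`.
#'
#' @param counts A `confusion_counts`.
#' @param variant `"methods"` (default) or `"figure"`; selects which TPR /
#'   accuracy fills the headline `TPR`, `FNR`, `accuracy` slots (both are
#'   always present under explicit names).
#' @return A `metrics_report` list.
#' @export
#' @examples
#' m <- metrics(structure(list(TP = 8, TN = 90, FP = 1, FN = 1, TPFG = 1,
#'                             n_assayed = 101), class = "confusion_counts"))
#' m$FDR  # 2/10
metrics <- function(counts, variant = c("methods", "figure")) {
  variant <- match.arg(variant)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    total <- TP + FP + TPFG + TN + FN
    tpr_m <- rate(TP, TP + FN)
    tpr_f <- rate(TP + TPFG, TP + TPFG + FN)
    acc_m <- rate(TP + TN, total)
    acc_f <- rate(TP + TPFG + TN, total)
    fdr <- rate(FP + TPFG, TP + FP + TPFG)
    fpr <- rate(FP + TPFG, FP + TPFG + TN)
    tpr <- if (variant == "methods") tpr_m else tpr_f
    acc <- if (variant == "methods") acc_m else acc_f
    structure(list(TPR = tpr, FNR = if (is.na(tpr)) NA_real_ else 1 - tpr,
                   FPR = fpr, FDR = fdr, accuracy = acc,
                   TPR_methods = tpr_m, TPR_figure = tpr_f,
                   accuracy_methods = acc_m, accuracy_figure = acc_f,
                   variant = variant), class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> [%s] TPR=%.4g FPR=%.4g FDR=%.4g acc=%.6g\n",
              x$variant, x$TPR, x$FPR, x$FDR, x$accuracy))
  invisible(x)
}

#' Log-transformed accuracy
#'
#' `-coefficient * log10(1 - accuracy)`: with coefficient 10 a phred-like
#' scale (0.99999 -> 50.0, a 10-unit step is a ten-fold accuracy gain);
#' with coefficient 1 a plain log scale (0.96 -> 1.4).
#'
#' @param acc Accuracy proportion in `[0, 1]`.
#' @param coefficient 10 (phred-like) or 1 (plain log).
#' @param max_value Cap returned when `acc = 1`.
#' @return Transformed accuracy.
#' @export
#' @examples
#' transform_accuracy(0.99999, 10)  # 50
transform_accuracy <- function(acc, coefficient = 10, max_value = 2550) {
  if (any(acc < 0 | acc > 1)) stop("accuracy must be in [0,1]")
  t <- ifelse(acc >= 1, Inf, -coefficient * log10(1 - acc))
  pmin(t, max_value)
}

#' Concordance between two call sets
#'
#' Loci present in both sets are `matching` when the genotypes agree and
#' `discordant` otherwise; the concordance rate is
#' `matching / (matching + discordant)` (`NA` when no locus is shared).
#' Loci unique to either set are reported as that set's specifics.
#'
#' @param a,b data.frames with `rname`, `pos0`, `genotype` (or
#'   `map_genotype`) columns.
#' @return A `concordance` list: `rate`, `n_matching`, `n_discordant`,
#'   `a_specific`, `b_specific` (data.tables).
#' @export
concordance <- function(a, b) {
  norm <- function(x) {
    x <- as.data.table(x)
    if (!"genotype" %in% names(x) && "map_genotype" %in% names(x))
      setnames(x, "map_genotype", "genotype")
    if (!"rname" %in% names(x) && "seqname" %in% names(x))
      setnames(x, "seqname", "rname")
    x[, .(rname, pos0, genotype = norm_genotype(genotype))]
  }
  a <- norm(a); b <- norm(b)
  m <- merge(a, b, by = c("rname", "pos0"), suffixes = c(".a", ".b"))
  nm <- sum(m$genotype.a == m$genotype.b)
  nd <- nrow(m) - nm
  structure(list(
    rate = if (nrow(m) > 0) nm / nrow(m) else NA_real_,
    n_matching = nm, n_discordant = nd,
    a_specific = a[!b, on = c("rname", "pos0")],
    b_specific = b[!a, on = c("rname", "pos0")]),
    class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(paste0("<concordance> rate=%.4g matching=%d discordant=%d ",
                     "a-only=%d b-only=%d\n"),
              x$rate, x$n_matching, x$n_discordant,
              nrow(x$a_specific), nrow(x$b_specific)))
  invisible(x)
}

#' Expected fraction of reads lost to the mismatch bound
#'
#' The probability that sequencing errors alone push a read past the
#' mismatch bound, `P[Binomial(read_len, per_base_error) > k]` — the
#' closed-form expectation for how many reads a k-bounded aligner discards
#' even with a perfect reference. At a 1% error rate and k = 1 this is
#' ~3.6% of 30-nt reads and ~12.1% of 60-nt reads.
#'
#' @param read_len Read length (nt).
#' @param per_base_error Per-base error probability.
#' @param k Mismatch bound.
#' @return Proportion of reads expected to be discarded.
#' @export
#' @examples
#' expected_discard_fraction(30, 0.01, 1)  # ~0.036
expected_discard_fraction <- function(read_len, per_base_error, k) {
  stopifnot(read_len >= 1, per_base_error >= 0, per_base_error <= 1, k >= 0)
  pbinom(k, read_len, per_base_error, lower.tail = FALSE)
}

#' Recommended mismatch bound
#'
#' `k/|r| ~ 1/|r| + e_max + pi`: one mismatch of slack plus the maximum
#' expected sequencing error rate plus the expected divergence from the
#' reference. The integer bound is the ceiling of the proportion times the
#' read length. A warning is emitted when the proportion exceeds 0.03
#' mismatches per base (beyond which spurious alignment inflates).
#'
#' @param read_len Read length (nt), > 0.
#' @param e_max Maximum expected per-base sequencing error rate.
#' @param divergence Expected sample-to-reference divergence.
#' @return List with `proportion` and integer `k`.
#' @export
#' @examples
#' recommend_k(36, 0.001, 0.001)  # k = 2
recommend_k <- function(read_len, e_max = 0.001, divergence = 0.001) {
  if (read_len <= 0) stop("read_len must be positive")
  stopifnot(e_max >= 0, divergence >= 0)
  prop <- 1 / read_len + e_max + divergence
  if (prop > 0.03)
    warning(sprintf(paste0("recommended mismatch proportion %.4f exceeds ",
                           "0.03 per base; expect spurious alignments"),
                    prop))
  list(proportion = prop, k = as.integer(ceiling(prop * read_len)))
}

#' Per-stringency performance curves
#'
#' Re-thresholds a genotype table over a grid of stringency cutoffs and
#' tabulates confusion counts and metrics at each, the ingredients of
#' ROC-style plots (false positives vs sensitivity).
#'
#' @param genotypes A `genotype_table` from [genotype_pileups()].
#' @param truth Truth table.
#' @param params [model_params()] (degeneracy correction honored).
#' @param q_grid Stringency cutoffs to sweep.
#' @param variant Metric variant, see [metrics()].
#' @return data.table with one row per cutoff: counts and metrics.
#' @export
stringency_curve <- function(genotypes, truth, params = model_params(),
                             q_grid = c(0, 13, 20, 30, 40, 60, 90, 120),
                             variant = "figure") {
  rows <- lapply(q_grid, function(qt) {
    p <- params; p$q_threshold <- qt
    cc <- classify_calls(call_variants(genotypes, p), truth)
    m <- metrics(cc, variant)
    data.table(q = qt, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               TPFG = cc$TPFG, TPR = m$TPR, FPR = m$FPR, FDR = m$FDR,
               accuracy = m$accuracy)
  })
  rbindlist(rows)
}
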