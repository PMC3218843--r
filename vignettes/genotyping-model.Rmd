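---
title: "Multi-locus Bayesian genotyping with multiply mapped reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus Bayesian genotyping with multiply mapped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracall)
```

## The problem

Short-read SNP callers usually keep only reads that map to exactly one
place in the reference. In repetitive or paralogous genomic contexts —
duplicated genes, transposable elements, low-complexity sequence — a large
fraction of reads map to several loci within the mismatch bound *k*, and
discarding them leaves exactly the loci one is trying to genotype with
little or no coverage. Greedier alternatives ("best-guess" mapping) keep
one arbitrary minimum-mismatch placement per read, which recovers coverage
but can pile variant evidence onto the wrong paralog and inflate the false
discovery rate.

`paracall` takes the third route: every placement of every read (up to a
cap) is kept, and a Bayesian model accounts for the ambiguity explicitly.
A multiply mapped read contributes evidence to all of its loci, diluted by
its multiplicity, and posterior mass is resolved across the paralogous loci
that share reads.

## The model

For a locus with reference base $r$ the unknown diploid genotype $g$
ranges over the ten unordered pairs of A, C, G, T. Each read $i$ covering
the locus has $d_i$ additional placements elsewhere in the genome. Its
likelihood under genotype $xy$ is

$$
P(r_i \mid G_{xy}) \;=\; \frac{1}{d_i + 1}\left[
\tfrac12 P(r_i \mid s(x)) + \tfrac12 P(r_i \mid s(y))
\;+\; \sum_{j=1}^{d_i} p^{(j)}_{bg} \right],
$$

where $s(a)$ is the reference template with allele $a$ substituted at the
read's focal offset, and each background term $p^{(j)}_{bg}$ evaluates the
read against its $j$-th other placement with the reference base there. The
restriction behind the background terms is that among the loci a read maps
to, at most one deviates from the reference at the read-homologous
position — identical substitutions arising independently at two paralogs
would require parallel mutation or a variant predating the duplication,
both negligible.

The probability that a read arose from a given template mixes two error
models,

$$
P(r \mid s) \;=\; \lambda \, P_{read} + (1 - \lambda)\, P_{bin},
$$

with $P_{read} = \prod_{\text{match}} (1 - p_i) \prod_{\text{mismatch}}
p_i/3$ built from the per-base qualities ($p_i = 10^{-q_i/10}$), and
$P_{bin}$ the binomial point mass $\binom{n}{k_{obs}} e^{k_{obs}}
(1-e)^{n-k_{obs}}$ at the observed mismatch count under a global per-base
error rate $e$. Assuming reads are independent given the genome, the
per-locus posterior is

$$
P(G_{xy} \mid R) \;\propto\; P(G_{xy}) \prod_i P(r_i \mid G_{xy}),
$$

computed in log space and normalized over the ten genotypes. The prior
comes from the population heterozygosity $\vartheta$: mass
$1-\vartheta-\vartheta^2$ on homozygous-reference, $\vartheta/2$ spread
over the three single-alternative heterozygotes, $\vartheta/2$ over the
three homozygous alternatives, and $\vartheta^2$ over the three
double-alternative heterozygotes. Calls are summarized by the MAP genotype
and the stringency $Q = -10\log_{10}(1 - P_{MAP})$; a significant SNP
requires a non-reference MAP genotype and $Q$ at or above the threshold.

### Resolving paralogs: the multi-locus step

The per-locus formula above conditions the background loci on the
reference. Taken alone it has a blind spot: on a perfectly duplicated
template, reads carrying a variant map to both copies with equal fidelity,
and both copies would be called with high confidence — one of them
falsely. `genotype_pileups()` therefore adds a resolution step that
operates on the restricted configuration space "at most one of the linked
loci carries a variant". Writing $W(l, g)$ for the posterior weight of
genotype $g$ at locus $l$ relative to homozygous-reference (exactly the
per-locus quantity already computed), the posterior of a variant genotype
at $l$ within its group of linked loci $H(l)$ becomes

$$
P(g \,\text{at}\, l) = \frac{W(l,g)}{1 + \sum_{j \in \{l\} \cup H(l)}
\sum_{g' \neq ref} W(j, g')},
$$

and the homozygous-reference mass absorbs the configurations in which the
variant sits at a linked paralog instead. Because each single-variant
configuration's joint likelihood factorizes into the per-locus weights,
this is the exact marginalization over that space — the test suite checks
it to $10^{-9}$ against brute-force enumeration of configurations on small
paralogous instances. On an identical two-copy template the evidence for
an injected variant splits 50/50 between the copies: neither is called (a
false negative, honestly reported) and neither becomes a false positive.
Unique loci are untouched: their group is empty and the formula reduces to
the plain per-locus posterior.

The resolution space deliberately excludes configurations with variants at
two loci that are linked to the focal locus but share no read with each
other; with two-copy templates (the study conditions) such configurations
do not exist, and with higher copy numbers their prior mass is
$O(\vartheta^2)$. The limitation is structural, not numerical.

A second consequence of linked loci is a multiple-testing concern: a
variant tested at $m_l$ homologous positions gets $m_l$ chances to clear
the threshold. With the degeneracy correction enabled (the default), the
threshold is raised Bonferroni-style on the phred scale,
$Q_{eff} = Q_{min} + 10\log_{10} m_l$, with $m_l$ one plus the number of
distinct loci linked to $l$ through shared multi-mapped reads.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `e` | 0.0003 | global per-base error rate of the binomial model |
| `lambda` | 0.67 | weight of the read-specific quality model in the mixture |
| `theta` | 0.001 | expected population heterozygosity (prior) |
| `q_threshold` | 40 | minimum stringency for a significant SNP ($P_{err} < 10^{-4}$) |
| `max_q` | 255 | cap on reported Q |
| `degeneracy_correction` | on | Bonferroni-style threshold correction by $m_l$ |
| `multilocus` | on | paralog resolution step described above |
| `k` (aligner) | 2 | mismatch bound; the rule of thumb is $k/|r| \approx 1/|r| + e_{max} + \pi$, at most 0.03/base |
| `d_cap` | 200 | maximum placements per read for the ALL strategy (max-d, not top-d) |

`lambda` weighs the read-specific term by default; the opposite
orientation of the mixture is available via `lambda_on_read = FALSE`,
since the published description fixes only that the weight tunes between
the two models. Results are insensitive to moderate changes in `lambda`;
both orientations agree exactly at `lambda = 0.5` and swap roles under
`lambda -> 1 - lambda`.

`select_k()` implements the operational rule for choosing the mismatch
bound: build read maps at several `k` and keep the one maximizing the
ratio of mean read depth to mean alignments per read.

## Read-map strategies

`apply_strategy()` reproduces the four classical strategies so they can be
compared on equal footing: **UNI** keeps read units with exactly one
placement; **BESTNO** keeps a unit only when its minimum-mismatch
placement is unique; **BEST** keeps one minimum-mismatch placement,
breaking ties uniformly at random under a recorded seed; **ALL** keeps
every placement of units with at most `d_cap` placements and discards
units above the cap entirely. Mate pairs count as one unit whose
placements are valid pairings (opposite strands, outer span within the
insert window, 150–300 nt by default); mates that cannot be paired are
rescued as single-end units.

## The simulator

The synthetic-data generator reproduces the evaluation protocol the model
was built around: a random GC-weighted template unit concatenated
`copies` times, with each later copy diverged from the first by an
independent per-base substitution probability; diploid samples created by
injecting 0.0005 heterozygous plus 0.0005 homozygous substitutions per
locus (0.1% total polymorphic divergence); paired-end 36-nt reads at a
chosen fold-coverage with Gaussian insert sizes (mean 250, sd 30),
uniform sequencing errors at 0.001 per base, and per-cycle Phred
qualities drawn from a Gaussian (sd 10) around an empirical 36-cycle
Illumina profile declining from ~33 to ~24, rounded and clipped to
[2, 40]. The pair count is `floor(coverage * |G| / (2 * read_len))`, so
the requested coverage is a lower bound. Insert draws shorter than the
read or overrunning the sequence are redrawn (at most 100 attempts);
alternative bases are uniform over the three non-reference bases
(no transition bias); for read lengths other than 36 the quality profile
is interpolated linearly over relative cycle position. A single integer
seed drives separate named streams for template, variants, reads,
qualities and tie-breaks, so each component is independently
reproducible.

What the simulator does *not* emulate: indels and structural variation,
GC-coverage bias and other library-preparation effects, platform-specific
error structure (color space, homopolymer flow), base-quality
miscalibration, and — importantly — the block structure of real paralogs,
whose coding regions can stay identical over hundreds of bases while
flanks diverge. Divergence here is i.i.d. per base, so long identical
inter-copy stretches are exponentially rare. Passing tests on these
templates demonstrate the model's behavior under controlled ambiguity;
they do not certify performance on real repeat families, where mapping
strategies that look adequate here (notably best-guess with paired ends)
can fail badly.

## Numerical choices

Likelihood products are accumulated in log space with a floor of
$10^{-300}$ per factor; posterior normalization uses log-sum-exp. The
stability-critical quantity $1 - P_{MAP}$ is computed as the sum of the
non-MAP posterior masses rather than by subtraction. MAP ties break
toward homozygous-reference, then lexicographically — a tie never becomes
a SNP call. `P_bin` is the binomial point mass at the observed mismatch
count (not a tail), keeping it commensurable with `P_read`, which is also
a point likelihood. Columns with reads suggesting indels are outside the
model and genotyped as substitution columns. Degenerate inputs: a
zero-depth column returns the prior; an all-zero likelihood column is
flagged as a no-call rather than divided by zero.

Coordinates are 0-based half-open internally; 1-based only in the TSV/VCF
exports. The aligner is an exhaustive ungapped Hamming scan (compiled
code) — every placement within the bound on either strand, 'N' counting
as a mismatch, with deterministic output order so downstream tie-breaking
is reproducible.

## Scale of the built-in evaluations

The test suite exercises the full pipeline at desk scale: a 10,000-nt
unit duplicated at 5% divergence (20,000-nt genome), 36-nt paired ends at
50-fold coverage, five replicates, with strategy comparisons at Q ≥ 40;
plus an identical-copies negative control and small enumeration-oracle
instances (two to three paralogous loci, up to six reads) where the exact
posterior can be computed by brute force. These sizes keep a full run in
minutes on one CPU while preserving the regime of interest — mean
alignments per read close to 2, most reads multiply mapped.

## Known limitations

* Substitutions only; indels and CNVs are not modeled, in the genome or
  in the reads.
* The paralog-resolution space is single-variant per linked group (see
  above).
* The degeneracy correction formula is a phred-scale Bonferroni
  ($\alpha/m \Rightarrow +10\log_{10} m$) on the per-site multiplicity;
  it is deliberately conservative, and other corrections (e.g. across
  adjacent covered loci) are not applied.
* Template-location priors are uniform across a read's placements;
  coverage biases from library chemistry would perturb this.
* The exhaustive aligner is built for correctness at desk scale, not for
  whole-genome throughput; any external aligner producing SAM can stand
  in for it (`read_sam()`), with mismatch offsets recomputed against the
  reference.

## A worked run

```{r example, eval = FALSE}
cfg <- default_config(
  template = list(unit_length = 10000, copies = 2,
                  inter_copy_divergence = 0.05),
  reads = list(coverage = 50),
  seed = 1)
res <- run_pipeline(cfg)
res$confusion
res$metrics
```
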