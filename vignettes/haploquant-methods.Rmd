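---
title: "Haplotype and isoform expression from multi-mapping reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype and isoform expression from multi-mapping reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploquant)
library(dplyr)
```

## The problem

RNA-seq reads aligned to a transcriptome rarely identify a single
transcript. Isoforms of one gene share exons, paralogous genes share
homologous stretches, and — when the reference carries both parental
haplotypes of an isoform — a read that does not span a heterozygous site
matches both copies perfectly. Discarding these multi-mapping reads wastes
most of the signal and biases estimates; assigning them heuristically
distorts isoform and allele ratios. haploquant instead models them.

The key data reduction: after filtering, every read maps to a *set* of
reference sequences. Many reads map to the same set, so the sufficient
statistics are one count per unique set — a sparse indicator matrix $M$
with $M_{it} = 1$ when transcript $t$ belongs to set $i$, and counts
$k_i$. The size of $M$ grows with transcriptome complexity, not read
depth, which is what makes the approach scale.

## The Poisson model

With uniform read sampling along a transcript, the number of reads whose
start falls in the region shared by exactly the transcripts of set $i$ is

$$k_i \sim \text{Pois}\Big(b\, s_i \sum_t M_{it}\, \mu_t\Big),$$

where $s_i$ is the effective length of that shared region, $\mu_t$ the
expression of transcript $t$, and $b$ a normalization constant. We set
$b$ to the number of retained reads in millions and measure lengths in
kilobases, so $\mu_t$ is on the RPKM scale. The per-transcript effective
length is the number of possible read start positions,
$l_t = \text{length} - \epsilon + 1$ for read length $\epsilon$, and the
regions of a transcript tile it: $\sum_i s_i M_{it} = l_t$.

A heterozygous site makes this geometry do haplotype work: the
$\epsilon$ start positions covering the site yield reads carrying one
allele only, so each haplotype has an exclusive "shadow" region of length
$\epsilon$ while the rest of the transcript is shared between the two
copies — formally identical to an alternatively spliced exon. The
best-mismatch-stratum filter is what keeps the shadow exclusive: a read
over the site matches its own haplotype with one mismatch fewer than the
alternative, and only minimal-mismatch alignments are retained.

A useful property of both fitting algorithms below is that the $s_i$
cancel: given a set, reads distribute over its member transcripts in
proportion to the $\mu_t$ alone, because the region has the same length
on every member. The package therefore never computes $s_i$ in the
estimation path; `enumerate_region_lengths()` exists purely as a
brute-force oracle for tests, where the tiling identity above is asserted
exactly.

## Estimation

**EM.** Augmenting the data with per-set, per-transcript read counts
$X_{it}$ (with $\sum_t X_{it} = k_i$) gives a standard EM scheme:

- E-step: $E(X_{it}) = k_i\, M_{it}\mu_t / \sum_{t'} M_{it'}\mu_{t'}$,
- M-step: $\mu_t \leftarrow \sum_i E(X_{it}) / (b\, l_t)$,

initialized by splitting each $k_i$ evenly across its set. The
observed-data log-likelihood (up to a constant free of $\mu$) is
$\sum_i k_i \log \sum_t M_{it} \mu_t - b \sum_t l_t \mu_t$ and is
non-decreasing across sweeps — a property the test-suite asserts on
random instances. Convergence is declared when the maximum relative
change of $\mu_t$ over transcripts above $10^{-8}$ drops below $10^{-6}$,
with a 10,000-sweep cap; these values are stringent but cheap at the
problem sizes the package targets.

**Gibbs.** ML estimates at low coverage are frequently exact zeros. For
two equally expressed haplo-isoforms differing at one heterozygote,
sampled uniformly at 0.01 reads per nucleotide with 35 nt reads, the
number of site-covering reads per haplotype is Pois(0.35), so the
probability that one allele is seen and the other is not is
$2(1-e^{-0.35})e^{-0.35} \approx 0.42$ — nearly half the time the ML
estimate of one haplotype is zero and the other inflated
(`allele_dropout_probability()` computes this; the acceptance script
verifies it by Monte Carlo). The package therefore also fits a Bayesian
model with a vague $\text{Gam}(\alpha = 1.2,\ \beta = 0.001)$ prior on
each $\mu_t$, matching the broad, skewed distribution of real expression
values. Conjugacy gives closed-form full conditionals:

$$\{X_{i\cdot}\} \mid \mu, k_i \sim \text{Mult}\big(k_i,\ \propto M_{it}\mu_t\big),
\qquad
\mu_t \mid X \sim \text{Gam}\Big(\alpha + \sum_i X_{it},\ \beta + b\, l_t\Big).$$

The chain starts at the EM solution, runs 1,024 burn-in sweeps and 8,192
kept sweeps thinned by 4 (2,048 retained samples) — enough that the
Monte Carlo standard error diagnostics are meaningful while a fit on a
few hundred transcripts takes well under a second (the sweep loop is
compiled; an R-level reference sweep, `gibbs_sweep()`, is kept for
verification). Posterior means are the headline estimate; medians are
also reported because means of highly skewed posteriors carry a small
upward bias at low expression. MCSEs use the batch-means estimator with
batches of size $\lfloor\sqrt{n}\rfloor$ (an initial-sequence estimator
would also be defensible; batch means was chosen for its simplicity and
the property tests calibrate it on iid and AR(1) chains). Transcripts
with no mapped reads are retained — their posterior is the prior
conditional, never an exact zero. Transcripts shorter than the read
length are excluded up front, with a warning, since $l_t \le 0$ is
undefined.

**Aggregation.** Transcripts with byte-identical sequences are
individually unidentifiable: their chains are strongly anti-correlated
with high variance, but every sweep conserves $\sum_t X_{it} = k_i$, so
their per-sweep sum is precisely estimated. `amalgamate_identical()`
groups by sequence identity (not by shared $M$ columns, which can
coincide by chance at low depth) and summarizes per-sweep sums.
`aggregate_genes()` likewise sums samples per sweep within genes — the
statistically correct aggregation, as opposed to summing posterior
means' MCSEs — and, for genes with heterozygous isoforms, separately
over tag-A and tag-B copies ("haplo-gene" estimates). Homozygous
isoforms of such genes are reported as a distinct `shared` component
rather than folded into either haplotype, since their reads carry no
phase information; users who prefer a different convention can recombine
the components.

## Alignment filtering

Two filters precede set collection. The best-mismatch-stratum filter
keeps, per read (or pair, summing both mates' mismatch counts), only
alignments with the minimal mismatch count; this is what resolves
haplotypes at heterozygous sites. The insert-size filter (paired data
only, applied after the stratum filter) removes alignments farther than
$x$ bp from the expected insert size whenever at least one alignment is
nearer than $x$ bp; $x$ is supplied by the user — one standard deviation
of the insert distribution is a reasonable choice — and the filter can
be disabled entirely, which is advisable when the library's insert
distribution is multi-modal. Insert size is the absolute TLEN-style
outer distance; both filters are idempotent. Mismatch counts come from
the NM tag, and records lacking it are a hard error rather than a silent
guess. Reads aligning to both haplotypes of one transcript and to other
transcripts keep their full set: the model resolves such ties
probabilistically.

## Sequence-bias correction

Read starts are not uniform: the sequence around the start position
modulates the rate. The package fits a Poisson regression of
per-position start counts on one-hot indicators of the bases at offsets
$-20..+20$ around each candidate start (offset 0, the start base itself,
is included; reference-cell coding fixes base A to zero at each offset).
The regression is trained on high-signal transcripts: from the 500
transcripts with the highest per-position coverage, one per gene, so
shared exons are not double-counted. Coverage for this ranking uses
uniquely mapped reads only, and the exposure offset is
$\log(b\,\hat\mu_t)$ with first-pass EM estimates under uniform lengths
— on highly expressed transcripts the plug-in's relative error is small.
Positions whose window overhangs the transcript or contains an N are
dropped from the design.

The fitted preferences define an adjusted effective length
$\tilde l_t = \sum_{p=1}^{l_t} \alpha_{tp}$,
$\alpha_{tp} = \exp(\text{intercept} + \sum_o \text{coef}[o, \text{base}_{p+o}])$.
When computing $\tilde l_t$ (unlike when fitting) overhanging windows are
truncated rather than dropped, so a null model returns $l_t$ exactly.
Because the regression intercept absorbs the absolute start rate — which
belongs to $\mu$, not to a length — the intercept is recentred after
fitting so the mean preference over training positions is 1; adjustments
are then small perturbations around $l_t$ on unbiased data, and a
constant shift of the intercept simply scales all $\tilde l_t$ by a
common factor that the expression estimates absorb inversely. The same
coefficients apply to both haplotypes of a transcript, each evaluated on
its own sequence. Adjusted lengths are stable across lanes and runs, so
`write_adjusted_lengths()` / `read_adjusted_lengths()` let one
computation serve many samples; the reader validates the transcript set
against the reference. Plain maximum likelihood is the default; a small
ridge penalty is available for very small training sets.

## Reference construction

`apply_haplotypes()` edits a base transcriptome to match phased
single-nucleotide calls: transcripts with at least one heterozygote
become an A/B pair differing exactly at the heterozygous positions;
transcripts with only homozygous non-reference calls are edited in
place. Only SNVs are supported — indels change coordinates and are
rejected loudly — and unphased heterozygotes are rejected unless random
phasing is explicitly requested. `lift_variants_to_transcripts()`
bridges genome-coordinate calls (1-based, GFF-style exon intervals) into
transcript coordinates, reverse-complementing alleles on minus-strand
transcripts and flagging (not silently applying) alleles that contradict
the reference base. `build_hybrid_reference()` combines two parental
references into one with two entries per sequence-divergent isoform —
the construction used for F1 hybrids, where every heterozygote in the
hybrid corresponds to a SNP between the parents. Variants on overlapping
transcripts of one gene are applied per transcript independently; if a
caller produced conflicting calls for the same genomic site seen through
different transcripts, both versions survive, and reconciliation is left
to the caller.

## The simulator and its oracles

`simulate_reads()` draws per-transcript read counts
$r_t \sim \text{Pois}(b\,\tilde l_t\,\mu_t / 1000)$, start positions
uniformly (or proportional to a bias model's preferences), and copies
bases from the haplotype-specific sequence with an optional per-base
error rate; paired mode draws insert sizes from a truncated Normal.
Reads are emitted on the sense strand — alignment is to the
transcriptome, so strand is trivial — and qualities are constant.
Identical seeds give byte-identical FASTQ output.

Two oracles make the machinery testable without an external aligner.
`enumerate_region_lengths()` exhaustively assigns every possible
error-free read to its containing set, yielding the $s_i$ and the tiling
identity; it is quadratic and intended for toy references.
`match_reads()` plays the role of an all-best transcriptome aligner: a
k-mer dictionary for the exact (post-filter ideal) regime and a
mismatch-tolerant scan for small cases where the stratum filter needs
non-trivial input. These are testing instruments: real data should be
aligned with a real aligner and fed in as SAM/BAM.

What the simulator does *not* emulate: fragmentation chemistry and
hexamer priming (beyond the generic positional bias model), GC-dependent
amplification, quality-dependent errors, intron-containing genomic
alignment, and incomplete annotation. Passing recovery tests on
simulated data therefore demonstrates the estimator's correctness under
its own model assumptions, not robustness to every artifact of real
libraries.

## Problem sizes and test design

The package's checks run at desk scale, chosen so the full suite
completes in about a minute: EM-vs-numeric-optimizer comparisons on two-
and three-transcript instances; conjugate-posterior comparisons wherever
sets are singletons (there the posterior is exactly
$\text{Gam}(\alpha + k,\ \beta + b l)$); geometry enumeration on
references of up to ~20 short transcripts; recovery on a 100-transcript
reference (30 two-isoform genes with shared exons plus 40 singletons)
with expressed transcripts sequenced at 20+ reads/kb; and haplotype
deconvolution on 30 heterozygote-bearing transcripts with planted
10-fold imbalances in both directions, pooled and re-estimated against
the hybrid reference. Monte Carlo comparisons use 3-4 combined standard
errors as tolerance; chain-dependent checks fix seeds.

## Known limitations

- Within-sample technical (Poisson) variability only: comparing
  biological replicates needs an overdispersed layer (e.g. a negative
  binomial induced by exchangeable Gamma priors) on top of these
  estimates, which is out of scope here, as are differential-expression
  tests.
- Single chain; MCSE is the only convergence diagnostic. The conjugate
  structure makes pathological mixing unlikely at these sizes, but
  multi-chain diagnostics are not provided.
- SNVs only; indels and structural variation require rebuilding the
  reference upstream.
- The bias model is positional-nucleotide only; fragment-GC and
  5'/3'-decay effects are not modeled.
- Estimates are only as complete as the annotation: unannotated
  isoforms must be added to the reference FASTA before alignment.
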