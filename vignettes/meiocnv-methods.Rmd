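---
title: "Models and methods behind meiocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiocnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocnv)
```

meiocnv studies a single question at two levels: when a mouse oocyte
cannot form crossovers, how do its chromosomes partition between the
egg, the polar bodies and the resulting zygote — and can the outcome be
read back from low-coverage single-cell sequencing? The package
therefore contains a generative model of female meiosis and an
analysis pipeline for per-chromosome read counts, connected by a count
simulator, so that every claim the analysis makes can be checked
against a known ground truth.

## The segregation model

Meiosis is simulated per chromosome, at the resolution of individual
chromatids, through three stages.

**Prophase/metaphase I configuration.** Each of the 20 chromosomes of
the oocyte genome (19 autosomes + X; the Y never passes through an
oocyte) independently forms a crossover-linked bivalent with
probability `p_bivalent`. A chromosome that fails to recombine is
present as two unpaired univalents; each univalent independently loses
sister-chromatid cohesion before anaphase I with probability `p_pssc`
(premature sister-chromatid separation, PSSC). `p_bivalent = 1`
describes recombination-proficient control oocytes; `p_bivalent = 0`
describes the recombination-null regime where chiasmata never form.

**Anaphase I** (reductional). A bivalent sends one dyad to the egg and
one to the first polar body, deterministically. An intact univalent is
a single unsplittable unit: it goes whole to the egg or PB1 with
probability 1/2 each. A PSSC univalent contributes two independent
single chromatids, each retained by the egg with probability 1/2.
Whatever the configuration, egg + PB1 hold exactly 4 chromatid copies
of every chromosome — a conservation law the test suite asserts on
every simulated cell.

**Anaphase II and fertilisation** (equational). Each dyad in the egg
normally splits, one chromatid to the zygote and one to the second
polar body; with probability `p_mii_ndj` it nondisjoins and both
chromatids go to one product (either side with probability 1/2). Loose
single chromatids segregate to the zygote with probability 1/2. The
zygote then gains the paternal complement — one chromatid per autosome
plus an X or Y with probability 1/2 each. Maternal chromatids are again
conserved: zygote (maternal) + PB2 = egg, per chromosome.

Assumptions worth making explicit:

* univalents retain sister cohesion unless PSSC fires; this minimal
  model is enough to produce both whole-chromosome errors (intact
  univalent mis-segregation) and loose single chromatids in MII eggs;
* anaphase is always bipolar. Crossover-deficient oocytes frequently
  attempt tripolar anaphases in live imaging, but nothing constrains
  how chromatids would partition among three poles, and the sequenced
  end products (zygote + PB2) are two-product outcomes;
* no chromosome-specific behaviour: all chromosomes share the same
  probabilities, so simulated aneuploidy is exchangeable across
  chromosomes. The cohort summary reports a chi-square-style
  uniformity statistic so users can check this against real data
  rather than assume it;
* PB1 is simulated (it is needed for the conservation laws) but not
  sequenced by default; the polar body matched to each zygote is PB2,
  whose content mirrors the egg's MII partition — this is what makes
  zygote/polar-body reciprocity informative about MII.

All randomness flows through R's session generator; `simulate_cohort()`
takes an explicit seed and records it, and the file pipeline echoes the
seed and a config hash into every output header, so cohorts are
bit-reproducible.

## From karyotypes to read counts

Sequencing measures DNA mass. The expected share of mapped reads for
chromosome $c$ with length $L_c$ and chromatid count $u_c$ is

$$ p_c = \frac{L_c\, u_c}{\sum_k L_k\, u_k}, $$

so a retained extra single chromatid shifts a chromosome's share by
half a copy (copy number 2.5 on the diploid scale) — gains of material
are graded, not binary.

Counts are drawn as Multinomial(depth, $p'$). With overdispersion
`rho > 0`, $p'_c \propto p_c w_c$ where $w_c$ are independent
Gamma(shape $1/\rho$, mean 1) efficiency factors, one per chromosome.
This models per-chromosome amplification efficiency noise, the dominant
artefact of whole-genome-amplified single cells: `rho` is the squared
coefficient of variation of efficiency, so the default `rho = 0.002`
adds ~4.5% relative noise per chromosome on top of the ~1% counting
noise at the default depth of 200,000 mapped reads. Those two defaults
were chosen together: the extra noise is large enough to be plainly
visible in replicate variance (an order of magnitude above multinomial
variance) yet leaves per-chromosome copy-number estimates with a CV
safely below 5%, so a 20% calling threshold sits more than four
standard deviations from a euploid chromosome. What the noise model
does *not* emulate: GC and mappability bias (absorbed in practice by
the empirical reference), read-level artefacts, and any correlation of
amplification noise along the genome. Passing tests therefore show the
procedure is correct under exchangeable per-chromosome noise, not that
real libraries are this well behaved.

## The copy-number procedure

For a test sample, the proportion of reads per chromosome is divided by
the mean proportion in a reference set of karyotypically normal
samples. The resulting ratio $r_c$ is doubled for all autosomes and for
the female X — euploid copy number 2 — while for male samples the X and
Y ratios are used as is, since those chromosomes are single-copy in
euploid male cells:

$$ \mathrm{CN}_c = \begin{cases} 2\, r_c & \text{autosomes; female X} \\
r_c & \text{male X, Y.} \end{cases} $$

Design choices in this stage:

* **Reference mode.** The default reference is sex-matched (separate
  female and male mean-proportion maps; test samples are sexed from
  their Y read share, threshold half the male-reference Y proportion).
  A pooled mixed-sex mode is also provided; it is exactly equivalent on
  autosomes but biases sex chromosomes (a euploid female X reads ~4/3
  against a half-male pool before doubling), so sex_matched is the
  default.
* **Polar bodies need no special handling.** Proportions are
  self-normalising: a haploid PB2 with one chromatid of everything has
  the same read proportions as a diploid cell, so it is analysed
  identically (female pattern, Y absent) and its gains and losses read
  against the same relative baseline.
* **Threshold.** A chromosome is called gained (lost) when
  $\mathrm{CN}_c/b_c - 1 \geq \delta$ (or $\leq -\delta$) against its
  baseline $b_c \in \{2, 1\}$, with $\delta$ = `delta_rel` = 0.2 by
  default. The comparison is inclusive at the boundary. 0.2 is low
  enough to call single-chromatid imbalances (CN 2.5 or 1.5 deviate by
  25%) and high enough that default-noise euploid chromosomes
  essentially never cross it. Copy numbers are reported unrounded;
  nothing downstream depends on integerising them.
* **Complexity.** A sample with 0 aneuploid chromosomes is euploid,
  1–2 simple, and 3 or more complex.

**A known compression limit.** Because proportions must sum to one, a
sample's total DNA mass is unobservable: copy numbers are recovered
only up to a global renormalisation factor (the test suite verifies
the exact closed form, e.g. one extra chromatid on one of 20
equal-length chromosomes yields CN $= 120/41 \approx 2.927$ on that
chromosome and $80/41 \approx 1.951$ elsewhere). When aneuploidies
move a large fraction of total mass — roughly more than
$\delta/(1+\delta)$, e.g. whole-chromosome losses of three large
chromosomes at once — the renormalisation can push truly euploid
chromosomes past the threshold. This is intrinsic to any
read-proportion method, not an implementation artifact; calls on
heavily deranged genomes should be read as relative, which is also why
the matched-pair reciprocity analysis uses call signs rather than
magnitudes.

## Reciprocity analysis

For a matched zygote/PB2 pair (Y excluded — polar bodies carry none),
each chromosome is classified `reciprocal` (opposite-sign calls),
`concordant` (same-sign), `unmatched` (aneuploid in one product only)
or `neutral`. The reciprocity fraction is anchored on the polar body:
among chromosomes aneuploid in the PB, the fraction whose zygote call
has the opposite sign. It is flagged undefined for fully neutral polar
bodies rather than divided by zero, and cohort means are taken over
defined pairs only. Strict sign opposition — not magnitude matching —
defines reciprocity, because magnitudes are half-integer valued and
noisy while signs are stable.

Note what the model predicts here: errors made at anaphase I by intact
univalents are reciprocal between the egg and *PB1*, so they appear
*concordant* between the zygote and PB2 (both inherit the egg's
surplus or deficit); only PSSC chromatids and MII nondisjunction
generate zygote/PB2 reciprocity. The mean reciprocity fraction under
the crossover-null default is verified in the tests against exhaustive
enumeration of the per-chromosome outcome tree (a dynamic program over
the 20-chromosome joint distribution), not against a hand-waved
expectation.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `p_bivalent` | 1 (control) / 0 (crossover-null) | P(chromosome forms a bivalent) |
| `p_pssc` | 0 / 0.5 | P(univalent separates sisters prematurely) |
| `p_mii_ndj` | 0 | P(dyad nondisjoins at anaphase II) |
| `depth` | 200,000 reads | mapped reads per sample |
| `rho` | 0.002 | squared CV of per-chromosome amplification efficiency |
| `delta_rel` | 0.2 | relative copy-number deviation that triggers a call |
| reference | 10 female + 10 male | euploid samples behind the empirical reference |

The crossover-null `p_pssc = 0.5` reflects that metaphase II spreads
of such oocytes show a mixture of whole-chromosome and single-chromatid
errors in comparable numbers; the reference cohort size is an arbitrary
but configurable choice (real reference sets are rarely larger).

## Verification strategy and problem sizes

The test suite leans on three kinds of oracle: exact closed forms on
equal-length genomes (the doubling rule, renormalisation constants),
conservation laws asserted on every simulated cell, and exhaustive
enumeration of the single-chromosome outcome tree compared against
simulated frequencies (20,000 oocytes per parameter set, three
standard errors per outcome category). Cohort-level checks use 1,000
crossover-null eggs (none euploid; the analytic euploid probability is
at most $2^{-20}$ per oocyte), 200 crossover-null zygotes run end to
end through read simulation and calling (essentially all
complex-aneuploid), and a nine-zygote control cohort called 9/9
euploid — sizes chosen so the whole suite completes in about two
minutes on one core while keeping every binomial check comfortably
powered.

## Limitations

* Whole chromosomes only: no segmental CNV, no binned segmentation, no
  GC correction, no mosaicism modelling.
* The simulator's exchangeable-chromosome assumption means it cannot
  emulate chromosome-specific error rates; use the uniformity statistic
  to test that assumption on data rather than assume it.
* Upstream of the count table (basecalling, trimming, alignment,
  filtering) is out of scope; the package consumes idxstats-style
  per-chromosome count files from any aligner toolchain.
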