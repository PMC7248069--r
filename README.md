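# meiocnv

Whole-chromosome aneuploidy analysis for low-coverage single-cell
sequencing of mouse zygotes and polar bodies, plus a chromatid-level
simulator of meiotic chromosome segregation in crossover-deficient
oocytes.

When oocytes cannot form crossovers, every chromosome persists as two
unpaired univalents that mis-segregate at anaphase I — whole, or as
prematurely separated single chromatids — and the errors propagate
through anaphase II into the zygote and its second polar body. At
sequencing depths below 0.01× coverage, the only robust copy-number
signal is each chromosome's share of mapped reads. meiocnv implements
that procedure end to end and pairs it with a generative model so the
whole pipeline can be validated against known truth without any
external data.

## The method

For sample read proportions $p_c$ and mean reference proportions
$\bar{p}_c$ over karyotypically normal samples (sex-matched by
default), the per-chromosome ratio is $r_c = p_c / \bar{p}_c$ and the
predicted copy number is

$$\mathrm{CN}_c = 2 r_c \;\; \text{(autosomes, female X)}, \qquad
  \mathrm{CN}_c = r_c \;\; \text{(male X and Y)},$$

since X and Y are single-copy in euploid male cells. A chromosome is
called gained or lost when $|\mathrm{CN}_c/b_c - 1| \ge \delta$ against
its euploid baseline $b_c$ (default $\delta = 0.2$, which calls
single-chromatid imbalances at CN 2.5/1.5); samples with three or more
aneuploid chromosomes are classified complex. Matched zygote/polar-body
pairs are then compared call-by-call: a chromosome lost by the polar
body and gained by the zygote (or vice versa) is reciprocal, indicating
a mis-partition between the two meiotic products.

The simulator side models prophase bivalent formation (`p_bivalent`),
premature sister-chromatid separation of univalents (`p_pssc`), MII
nondisjunction (`p_mii_ndj`), fertilisation, and overdispersed
multinomial read counts (default 200,000 reads, ~4.5% per-chromosome
amplification noise). See `vignettes/meiocnv-methods.Rmd` for the full
model description.

## Worked example

Simulate ten crossover-null oocytes, sequence the first zygote and its
second polar body in silico, and call both against a simulated euploid
reference:

```r
library(meiocnv)
genome <- mouse_genome()
noise  <- noise_model(depth = 200000, rho = 0.002)

cohort <- simulate_cohort(10, params_crossover_null(), genome, seed = 7)
mii_summary(cohort$oocytes[[1]]$egg)
#> $n_chromosomes
#> [1] 12
#> $n_chromatids
#> [1] 18

ref <- build_reference(simulate_reference_cohort(10, 10, noise, genome,
                                                 seed = 8))
zyg <- simulate_counts(cohort$oocytes[[1]]$zygote, noise, genome)
pb2 <- simulate_counts(cohort$oocytes[[1]]$pb2,  noise, genome)
zyg_calls <- call_aneuploidy(predict_copy_number(zyg, ref))
pb2_calls <- call_aneuploidy(predict_copy_number(pb2, ref))
zyg_calls
#> <aneuploidy_calls> oocyte001_zygote: 10 aneuploid (complex): 1:gain 2:gain
#>   3:loss 4:loss 5:loss 10:gain 11:gain 15:gain 16:loss 19:gain
reciprocity(zyg_calls, pb2_calls, "pair001")
#> <pair_reciprocity> pair001: 2 reciprocal / 4 concordant / 8 unmatched;
#>   fraction=0.200
```

The first egg holds only 12 intact chromosomes plus 18 loose single
chromatids (a euploid egg would have 20 and 0); its zygote is
complex-aneuploid, and 2 of the 10 chromosomes aneuploid in the polar
body show the opposite call in the zygote. Anaphase-I errors made by
intact univalents pass concordantly into both products — only PSSC
chromatids and MII nondisjunction produce zygote/PB2 reciprocity.

The same analysis runs file-based from a shell:

```sh
Rscript inst/cli/meiocnv simulate --out run --n 10 --p-bivalent 0 --seed 7
Rscript inst/cli/meiocnv build-ref --out run
Rscript inst/cli/meiocnv call --out run
Rscript inst/cli/meiocnv pair-report --out run   # pairs.tsv, matrix.tsv, summary.json
```

Inputs need not be simulated: `read_idxstats()` ingests real
`samtools idxstats`-style per-chromosome count tables, and the manifest
format ties samples, sexes, roles and zygote/polar-body pairs together.

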