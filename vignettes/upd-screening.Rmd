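---
title: "Screening variant-call cohorts for uniparental disomy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening variant-call cohorts for uniparental disomy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updscreen)
```

## The problem

Uniparental disomy (UPD) — both homologues of a chromosome inherited from
one parent — escapes standard variant interpretation: the genotypes are
individually unremarkable, and the disease mechanisms (imprinting
disorders, homozygous recessive variants) only emerge at the chromosome
scale. Two complementary signatures make UPD visible in ordinary VCFs:

* **Isodisomy (iUPD)** duplicates a single parental homologue, so the
  whole chromosome (or a segment, for segmental UPD) becomes homozygous —
  visible as runs of homozygosity (ROH) even in a proband-only analysis.
* **Heterodisomy (hUPD)** transmits both homologues of one parent.
  Heterozygosity is preserved, so ROH is silent; what disappears is the
  other parent's exclusive contribution, which only a duo or trio can see.

`updscreen` computes one statistic per signature for every
(sample, autosome) pair, tags them against fixed cutoffs, and emits a
long-format cohort table that can be filtered like any other QC sheet.

## Statistics and model assumptions

### ROH fraction

ROH are called by a rule-based greedy scanner over the position-sorted
variant calls of the proband, not an HMM. The decision the downstream
tagging needs — which of three coarse bands a chromosome falls into — does
not require probabilistic segmentation, and a scanner is deterministic,
parameter-transparent and trivially reproducible across sites and
versions. An HMM backend could be added behind the same
`call_roh_segments()` contract.

A run opens at a homozygous call and extends while

* at most `max_het_interruptions` heterozygous calls interrupt it (the
  next one closes the run at the last supporting homozygous call;
  heterozygous calls seen while no run is open cost nothing), and
* the gap between consecutive informative sites stays ≤ `max_gap`.

Runs with fewer than `min_sites` homozygous calls are discarded; segment
boundaries are the outermost supporting homozygous sites, so a
heterozygous call at a boundary terminates the segment before it. The ROH
fraction divides the merged segment span by the **full chromosome length**
(GRCh37/38 tables ship with the package), matching the "fraction of the
chromosome" definition; exome capture sparsity is absorbed by `max_gap`. A
"span" denominator (first-to-last variant) is available via
`upd_config(roh.denominator = "span")` for targeted panels.

Exome VCFs rarely contain explicit reference calls, so the operative
signal is the absence of heterozygous calls across a stretch of
homozygous-alt sites; `hom_ref` calls count as support when present.

### Inheritance ratio

Each child variant (het or hom-alt, after filters) is assigned an origin
from parental carrier status: a parent *carries* the variant when their
VCF holds a call for the same (chrom, pos, ref, alt) after multi-allelic
decomposition, and *does not carry* it when they were sequenced but have
no such call — exome VCFs emit variant sites only, so absence is read as
non-carriage. Parents are joined **unfiltered**: carrier status asks
whether the caller saw the allele at all, and filtering parents would
convert borderline parental calls into spurious exclusive counts.

With `m` maternal-only and `p` paternal-only counts, the inheritance
ratio is the symmetric pseudocount ratio

$$\mathrm{IR} = \frac{\max(m,p) + c}{\min(m,p) + c}, \qquad c = 1,$$

so UPDs of either parent exceed the cutoff and a zero denominator stays
finite; the direction (maternal/paternal) is carried separately. The
plotting statistic is the relative IR, $m/(m+p)$. The source publication
prints only the cutoffs (duo > 2, trio > 5) and the relative-IR
definition, not the tagging formula; the symmetric form is this package's
choice, consistent with cutoffs sitting just above the biparental value
of ≈ 1, and is recorded in configuration so results are reproducible
either way. Below `min_informative = 10` exclusive sites a chromosome is
*uninformative*, never "low".

In duos the missing parent's attribution pools true transmissions with de
novo variants and artifacts — that noisier denominator is why the duo
cutoff (2) is lower than the trio cutoff (5). Note that with a
common-variant-heavy site panel, "sequenced parent carries" includes many
biparental sites, which biases duo IRs upward; the trio is always the
stronger design.

### Tagging and candidate calls

The tag function is a total step function with **closed** mixed band
[0.2, 0.7] (a fraction of exactly 0.2 or 0.7 is "high mixed", matching
the printed inequalities low < 0.2 / high > 0.7) and **strict** IR
inequalities. Derivation: ROH high → iUPD candidate (regardless of IR);
ROH mixed → segmental-iUPD candidate, or mixed-UPD candidate when IR is
also high (iso- and heterodisomic stretches on one chromosome); ROH low
with IR high → hUPD candidate. Single setups can never produce an
IR-driven call.

### Consanguinity

Parental relatedness produces genome-wide ROH that mimics isodisomy on
several chromosomes and cannot be disambiguated chromosome-by-chromosome.
A sample is flagged when ≥ 3 autosomes are ROH-tagged mixed/high **or**
the genome-wide ROH burden exceeds 5% — computed *excluding the single
largest per-chromosome contributor*. The exclusion matters: a genuine
iUPD of chromosome 1 alone accounts for ~8.6% of the autosomal genome and
would otherwise flag the very sample the screen exists to find, while
consanguinity spreads identity-by-descent over many chromosomes and
clears the criterion comfortably. Flagged samples keep their rows in the
cohort table; ROH-driven calls are downgraded to `none` with note
`consanguinity_suspected`, and IR-driven heterodisomy calls are kept
(genome-wide ROH says nothing about IR). The rule is an explicit
heuristic — the source screen reports only that such samples were
excluded, not its criterion.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `filters.min_depth` | 10 | reads | genotype and allele-fraction calls are unstable below |
| `filters.het_af` | [0.25, 0.75] | fraction | removes the recurrent artifact band at AF ≈ 0.2 (present on every chromosome) and other allele-imbalanced calls |
| `filters.hom_alt_af_min` | 0.85 | fraction | hom-alt calls below are likely miscalls |
| `roh.min_sites` | 25 | hom calls | see run-length analysis below |
| `roh.max_het_interruptions` | 1 | calls | tolerates isolated genotyping errors inside true ROH |
| `roh.max_gap` | 3 | Mb | bridges exome capture deserts without bridging centromeres twice over |
| `roh.terminal_margin` | 2 | Mb | terminal-ROH annotation (terminal ROH deserve scrutiny even in singles) |
| `inheritance.pseudocount` | 1 | count | finite IR at zero denominators |
| `inheritance.min_informative` | 10 | sites | below this an IR is noise |
| `thresholds.*` | 0.2 / 0.7 / 2 / 5 | — | published cutoffs; the single source of truth for tagging *and* plot overlays |
| `consanguinity.*` | 3 chromosomes / 5% | — | heuristic, see above |

**Why `min_sites = 25`.** With the simulator's allele-frequency spectrum
(Beta(0.3, 0.3) truncated to [0.01, 0.99] — U-shaped, common-variant
heavy), roughly half of a proband's emitted calls are homozygous. The
probability that a window starting at a given call runs through ≥ k
homozygous calls with ≤ 1 heterozygous interruption decays like
$p_{\mathrm{hom}}^{k}$; at $p_{\mathrm{hom}} \approx 0.6$ and k = 15 this
is ~10⁻³ per start — hundreds of starts per chromosome yield a few
spurious ~2 Mb runs per chromosome and a genome-wide background of ~4%,
uncomfortably close to both the 5% consanguinity criterion and the
"outbred chromosomes stay < 0.1" expectation. At k = 25 the per-start
probability drops by another ~2.5 orders of magnitude and the observed
background (test suite, 100-trio cohort) is a median of 0 and a maximum
of ~0.05 per chromosome, with every event class still recovered — real
ROH of interest here span hundreds of exome calls.

## The simulator: what it emulates, what it does not

`simulate_cohort()` draws, per family and chromosome, a shared panel of
`sites_per_chromosome` positions (default 1500, exome-order density),
population alternate-allele frequencies from the truncated Beta, parental
haplotypes under Hardy–Weinberg, and transmits **one whole haplotype per
parent per chromosome** (no recombination — sufficient statistical
structure for ROH and IR). Events overwrite transmission on their
interval: iUPD copies one randomly chosen haplotype of the designated
parent twice; hUPD copies the parent's genotype (both haplotypes);
segmental iUPD applies the iUPD mechanism to a terminal interval covering
30–60% of the chromosome (mitotic recombination after trisomic rescue
typically yields terminal segments); consanguinity makes the transmitted
paternal haplotype identical by descent to the transmitted maternal one
over segments totalling 12.5% of the genome (interpreted as the child's
autozygous fraction), each covering 25–60% of its chromosome — by
construction ≥ 3 autosomes land in the mixed ROH band and the flag fires.

Read noise: depth ~ Poisson(60); alt reads ~ Binomial(depth, e) with
e = 0.01 / 0.5 / 0.99 for hom-ref / het / hom-alt; genotype classes are
re-derived from the noisy fraction, and only variant genotypes are
emitted (exome convention). Thirty artifact sites per chromosome and
individual are appended with AF ~ N(0.2, 0.03), recorded heterozygous —
the default filters remove ≥ 90% of them, which is what keeps isodisomy
chromosomes' ROH intact.

Deterministic per-family RNG substreams (derived from the master seed)
make cohorts byte-identical under a fixed seed and independent of cohort
ordering.

**Not emulated:** capture/GC bias, mapping artifacts beyond the AF band,
recombination within chromosomes, de novo variants, mosaicism and
trisomies, and any realistic linkage structure. A green recovery test
therefore establishes that the statistics and cutoffs behave as designed
under idealized exome-like noise — it does not establish clinical
sensitivity on real data, where segmental events shorter than the
simulated 30% minimum, low-level mosaicism, and CNVs (deletions mimic
ROH) all occur.

## Numerical choices and degenerate inputs

* Band edges: ROH 0.2 / 0.7 closed into the mixed band; IR cutoffs
  strict. Verified by a ±10⁻⁹ boundary sweep in the tests.
* Allele fractions of decomposed multi-allelic records keep the
  full-record read total as denominator, so the fractions of one record's
  alleles sum to ≤ 1.
* Chromosomes with no (or < `min_informative`) surviving sites propagate
  `uninformative` tags rather than fabricating "low" calls; depth-0 sites
  carry `NA` fractions and are filtered.
* A child site whose position collides with a parent record under a
  different reference allele is dropped with a warning (likely
  normalization mismatch between callers).
* X and Y are parsed but excluded from the screen: hemizygosity mimics
  ROH and the autosomal cutoffs do not transfer.

## Known limitations

* Duo IRs are biased upward by biparental pooling (see above); duo
  candidates deserve manual review of the allele-fraction plot.
* The consanguinity rule is a heuristic with two fixed constants; highly
  inbred samples can mask a genuine iUPD (the downgraded call is
  retained in the table with its note, so it remains findable).
* The ROH caller reports no statistical confidence, only site counts and
  interruption counts per segment.
* Carrier status treats parental coverage dropouts as non-carriage; the
  child-side depth filter mitigates but cannot eliminate this, and a
  per-site parental-depth check would require parent gVCFs, which the
  tool deliberately does not demand.
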