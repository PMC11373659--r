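---
title: "Pedigree crossover mapping: model, assumptions and design choices"
author: "pedcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree crossover mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcross)
```

## The inference problem

A three-generation pedigree — four grandparents (F0), two parents (F1) and
`n` offspring (F2) — lets every allele an offspring carries be traced, at a
subset of SNPs, to the grandparent it originated from. Crossovers in the
two F1 meioses behind each offspring appear as switches of that
grandparent-of-origin label along the transmitted chromosome. With
whole-genome SNP densities of thousands of markers per Mb, the switch
point is bracketed by two informative markers typically a few hundred
base pairs apart, giving near-base-pair crossover localisation without
sperm typing or large multi-family designs. Each autosomal arm contributes
`2n` observable meioses (`n` paternal, `n` maternal), so with six
offspring the per-arm recombination distance is measured on 12 meioses.

This vignette describes the model and the choices behind each stage; the
README shows the user-facing workflow.

## Phasing by exhaustive trio decomposition

At a biallelic site with dosages (0/1/2), the offspring genotype is
decomposed as `g_off = a_pat + a_mat` where `a_pat` must be an allele the
father can carry and `a_mat` one the mother can carry. Over the 27 dosage
triples this decomposition is unique except when all three individuals are
heterozygous (two decompositions, the site is *ambiguous*) or no
decomposition exists (*Mendelian-inconsistent*, treated as genotyping
error). Ambiguous sites are never guessed: a wrong phase guess would
mimic a double crossover, which is exactly the artifact the downstream
caller must not see.

A resolved parental allele is then assigned to a grandparent when the
parent is heterozygous and its own trio (parent + two grandparents) admits
a unique allele-to-grandparent assignment; if both grandparents could have
contributed either allele the site is uninformative. Both steps are
implemented as exhaustive truth tables over dosage tuples (precomputed
over all 3^5 combinations), so the per-site cost is a single table lookup.

Exclusion classes (missing, ambiguous, uninformative, Mendelian-
inconsistent at either generation) are tallied per offspring and side in
the `exclusions` attribute of the origin series; nothing is dropped
silently.

### Z chromosome

In a ZW system, males (ZZ) recombine along the whole Z while females carry
one Z and one W that pair and recombine only in the pseudoautosomal region
(PAR). Consequently:

* maternal origin series are built only inside the PAR — outside it the
  mother's Z is transmitted clonally and carries no crossover signal;
* paternal series span the whole Z for all offspring. ZW daughters are
  hemizygous outside the PAR; diploid variant callers report them as
  homozygous, so the single non-PAR allele is taken as paternal directly
  (a heterozygous call there is flagged as inconsistent);
* the PAR is treated like an autosome (both parents' meioses count), the
  non-PAR Z counts paternal meioses only.

## Crossover calling with a continuity threshold

For each offspring × side × chromosome series of informative markers, the
cumulative continuity score of a site is the length of the run of
consecutive same-origin markers ending (forward) or starting (backward) at
it. Genuine origin blocks produce long runs; isolated genotyping errors
produce runs of length 1. A crossover is called between every pair of
adjacent maximal same-origin blocks that both contain at least `threshold`
markers (default 50), with interior blocks shorter than the threshold
ignored as noise. Two qualifying blocks of the *same* label separated only
by noise therefore produce no call. The call is reported with the last
marker of the left block and the first of the right block as flanks, their
midpoint as the point estimate, and the interval length as the precision.

Two properties follow by construction and are stated rather than hidden:

* **Detection limit.** A crossover with fewer than `threshold` informative
  markers on one flank — because it lies telomere-ward of the first 50
  markers, or because a second crossover sits closer than the threshold
  span — cannot be called. `co_detectable()` states this predicate
  independently of the caller, and the validation suite measures recovery
  against it. Under telomere-biased placement a small fraction of true
  crossovers is always censored this way, in real data as in simulation;
  raising marker density shrinks but never eliminates the censored zone.
* **Monotonicity.** Raising the threshold can only merge or drop calls,
  never create them.

Both-flank thresholding (rather than one-flank) was chosen because it
makes the noise-suppression rule symmetric and oracle-testable: the caller
is verified against a brute-force run-partition enumeration on thousands
of random series. The threshold counts informative markers, not base
pairs, since the score is defined over scored SNPs.

Identical crossover positions recurring in several offspring that coincide
with scaffold junctions indicate a mis-ordered or mis-oriented scaffold,
not recombination; `flag_scaffold_artifacts()` flags (never deletes) such
groups within a configurable tolerance (default 1 kb), and flagged calls
are excluded from maps by default.

A call whose flanking interval spans the centromere is assigned to the arm
containing its midpoint and flagged `spans_centromere`.

## Recombination maps and centromeres

Arm-level distance is `cM = 100 × COs / meioses` and rate is `cM` divided
by arm length with 1 Mb = 1e6 bp exactly. Arms are labelled `q` (longer)
and `p` (shorter) around the centromere; telocentric chromosomes are a
single `q` arm whose telomeric end is the end away from the centromere.
Telomere distances of calls — physical (bp) and proportional (fraction of
arm length) — are measured from each arm's telomeric end.

`locate_centromere()` approximates centromeres as nucleotide-diversity
deserts: per-site unbiased pairwise diversity `2c(2N−c)/(2N(2N−1))` (with
`c` the alternative-allele count among `2N` genotyped alleles) is summed
in windows (default 500 kb) and divided by window length; the candidate is
the longest run of windows below the 0.1 quantile of that chromosome's
window diversities. Because the 12 pedigree samples give a noisy diversity
estimate, a window-permutation null guards the call: if the observed run
is no longer than the 95th percentile of maximal runs under shuffled
window order, the candidate is flagged low-confidence, and a
constant-diversity chromosome is flagged degenerate. Window size and
quantile are configurable; the defaults are a compromise between
resolution and the SNP counts per window at study-scale densities.

## Statistical tests

* **Paired t-tests** compare paternal vs maternal per-arm cM (and cM/Mb)
  across autosomal arms, two-sided, df = arms − 1. Zero-variance
  differences are reported as degenerate (t = 0, P = 1 when the vectors
  are identical) with a warning rather than an error.
* **Mann–Whitney U** compares paternal vs maternal telomere distances,
  two-sided, U reported for the paternal sample (a fixed convention so
  reported statistics are reproducible); exact null for ≤20 per group
  without ties, otherwise normal approximation with tie and continuity
  correction.
* **Goodness of fit**: observed CO counts per annotation class against
  length-proportional expectations `E_i = N·L_i/ΣL`, Pearson chi-square
  without continuity correction, df = classes − 1 — computed genome-wide
  and inside 6-Mb sub-telomeric windows with class lengths re-measured
  inside the same windows. Crossovers are classified as *points* (the
  midpoint estimate): with mean precisions of a few hundred bp relative to
  multi-kb features, interval-overlap classification would differ only for
  calls straddling a feature boundary, and point semantics keeps every
  call in exactly one class per level (intergenic/genic; exon/intron;
  UTR/CDS, with 5' and 3' UTRs collapsed to one UTR class).
* **Nearest-gene distances** are signed strand-relatively (negative =
  upstream of the nearest gene, 0 = inside).
* **Permutation test of gene proximity**: each intergenic call is
  re-drawn uniformly inside its own containing intergenic interval, the
  median absolute nearest-gene distance recomputed per replicate (1000 by
  default), and the one-sided P is the fraction of replicates with null
  median ≤ observed ("closer than expected"). Constraining draws to each
  call's own interval conditions on the observed interval-size
  distribution, so the test asks only about position *within* intervals.
  For a point inside an intergenic interval the nearest gene is always a
  flanking one, which the implementation exploits; a dual-implementation
  oracle in the test suite verifies the full computation on the same seed
  stream.

## The simulator: what it emulates, and what it does not

`simulate_pedigree()` generates the full study design with known truth:

* **Founders.** Per-site minor-allele fraction uniform on [0.1, 0.5]
  (configurable), alleles drawn independently per haplotype. This
  guarantees a usable informative fraction (~25% of sites per parental
  side) without modelling linkage disequilibrium.
* **Meiosis.** One obligate chiasma per arm (the obligate-chiasma
  hypothesis), each transmitted to the gamete with probability 0.5 — two
  of four chromatids carry each crossover product — so about half of
  segregating arm copies show a crossover. Setting `obligate_co = FALSE`
  switches to Poisson(1) chiasmata per arm with no interference model;
  interference is left off by default because no spacing data are
  available to calibrate it.
* **Placement.** Distance from the telomeric end as a fraction of arm
  length ~ Beta(1, b), a one-parameter monotone telomere bias with mean
  `1/(1+b)` (closed form used by the tests). The sex-specific defaults
  b = 7.11 (paternal) and 4.92 (maternal) are calibrated from the observed
  proportional median positions (9.29% and 13.14%) via the Beta(1, b)
  median `1 − 0.5^(1/b)`, fixed a priori.
* **Z/W.** Females carry one Z and one W; the W is allele-less outside the
  PAR and hemizygous genotypes are coded homozygous, as a diploid caller
  reports them. The PAR sits at the left end of the Z; maternal meioses
  recombine only there (with the chiasma obligate per Z–W pairing), while
  paternal meioses treat the Z as a single arm whose telomeric end is the
  right (non-PAR) end, so paternal crossovers do not pile into the 1.1-Mb
  PAR. Sons receive the maternal Z, the single daughter the W.
* **F0→F1 transmission** passes one founder haplotype per chromosome
  without recombination: grandparental labels are unaffected by
  recombination inside a grandparent's germ line, so this loses no
  generality for detecting F1 crossovers.
* **Noise.** Optional per-genotype error (flip to one of the two other
  dosages) and missingness; both default to 0.
* **Annotation.** Non-overlapping 3–7-exon genes with strand-aware UTRs
  tile ~40% of the sequence (~60% intergenic), so feature tests run at
  realistic class proportions.

The default genome is deliberately small — a 20-Mb two-armed chromosome, a
15-Mb telocentric one and a 10-Mb Z with a 1.1-Mb PAR at 2000 SNPs/Mb —
which keeps a full simulate–phase–call–test cycle around twenty seconds;
validation runs in the test suite use 2–3-Mb single-arm genomes with
50 replicate pedigrees. What the simulator does **not** emulate: linkage
disequilibrium among founder alleles, mutation, gene conversion (short
non-crossover tracts are deliberately out of scope, being
indistinguishable from genotyping error at realistic SNP densities),
crossover interference beyond the obligate chiasma, and W-linked sequence.
Passing tests therefore demonstrate correctness of phasing, calling and
statistics under idealised segregation — they do not certify robustness
to correlated genotyping artifacts (e.g. mis-mapped paralogous regions),
which in real data are handled by the upstream variant filtering and the
scaffold-artifact flag.

## Numerical conventions and degenerate inputs

* Coordinates: VCF/GFF3 1-based inclusive; BED 0-based half-open;
  internal representation 1-based bp. Scaffolds concatenate with zero
  gaps; "−" scaffolds reverse as `new = length − old + 1`.
* A crossover position `x` in the simulator switches haplotypes for sites
  at `pos ≥ x`; recovery checks use the matching half-open convention
  `left < x ≤ right`.
* Equal-length arms: the left arm takes the `q` label (tie-break).
* Midpoints may be half-integers; precision is `right − left` in bp.
* Series shorter than the threshold warn and yield no calls; a sex with
  zero crossovers makes the rank test an error (reported, not silently
  skipped); chromosomes without genes give `NA` nearest-gene distances
  with a warning.
* All simulation, permutation and pipeline stages are seed-deterministic;
  `run_all()` with the same seed and inputs reproduces its output bundle
  bit for bit.

## Known limitations

* Crossovers censored by the detection limit (above) bias per-arm cM
  slightly downward at low marker density; at study-scale densities the
  censored fraction is a few percent concentrated at the extreme arm
  tips.
* The centromere locator recovers only diversity deserts; centromeres
  without a diversity signature in a 12-sample pedigree will be flagged
  low-confidence rather than located.
* The paired arm-level t-test treats arms as independent units; no
  per-offspring random effects are modelled.
* Multi-scaffold chromosomes assume zero-gap concatenation, so absolute
  positions downstream of a gap-containing junction carry the assembly's
  uncertainty.
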