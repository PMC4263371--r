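---
title: "Methods and design notes for the cloneseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the cloneseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneseq)
```

# The problem

Site-directed mutagenesis normally requires picking colonies and Sanger
sequencing each one, which does not scale to the thousands of mutant clones
needed for systematic variant-phenotyping studies. The pooled alternative
implemented here sequences *one colony per mutagenesis attempt per pool* on
a short-read instrument: because every colony in a pool is a clonal plasmid
population and DNA is normalized across colonies before library
preparation, each attempted mutation leaves a predictable allele-fraction
signature at its target site, and the entire insert of every clone is
covered so PCR-introduced secondary mutations can be screened for at the
same time. `cloneseq` implements the computational side of that design end
to end, plus the downstream assays used to phenotype the verified mutants
(GFP stability, yeast two-hybrid disruption, SASA interface classification,
SILAC differential interactomics and cohort statistics).

# The calling model

## The S score

For an attempted mutation with `R_all` reads covering its site and `R_mut`
of them carrying the desired alternative base,

$$ S = k \cdot R_{mut} / R_{all}, $$

where `k` is the number of *distinct mutations attempted on the same gene
in the same pool*. All `k` colonies of one gene contribute equal expected
read share under DNA normalization, so a successful colony sits at allele
fraction `1/k` and scores `S ~ 1` regardless of `k`, while a failed
(pure wild-type) colony scores `S ~ 0`. Conventional diploid variant
callers cannot be used here -- a pool has no ploidy, and `k` differs from
gene to gene.

A colony is called mutation-positive at `S > 0.8`. The published
benchmark of this design found every Sanger-confirmed clone above an
empirical separation bound of `S = 0.44`, with a clear gap between
successes and failures; the stricter 0.8 cutoff is deliberate safety
margin, and the acceptance suite verifies both the gap and the bound on
simulated data.

## Unwanted-mutation screening

Per pool, the sequencing-error background `b` is estimated as the
unweighted mean non-reference allele fraction over all covered non-target
positions. Every non-target site is then tested with an upper-tail
cumulative binomial, `P(X >= nonref | depth, b)`, and flagged below the
deliberately lenient cutoff `alpha = 0.2`: the cost of a false flag is
discarding a redundant colony, while a missed real mutation poisons every
downstream assay of that clone, so type II errors are the ones being
minimized. When the flagged gene has `k > 1` colonies in the pool, 100 nt
reads cannot phase the extra mutation to a colony, and the flag
disqualifies *all* of that gene's colonies in the pool (the "ambiguous"
rule).

One consequence of a calibrated test at `alpha = 0.2` deserves emphasis:
by construction it flags up to ~20% of *null* sites (at 2500x depth and
`b ~ 1e-3` the discrete threshold lands at a ~11% per-site false-positive
rate). That is fine for clone triage but useless for *counting* true PCR
mutation events. `estimate_pcr_error_rate()` therefore adds the pooling
arithmetic the screen itself ignores: a real unwanted mutation lives on a
clone, so its allele fraction must be compatible with at least one whole
colony, i.e. at least `1/(2k)`. With that colony-level condition the
flagged-event count divided by total cloned bases recovers a planted
per-base PCR error rate of 1.3e-4 (0.013%, roughly 4-5 events per
39-colony pool) essentially without bias, which is what the acceptance
target measures. The pure screen remains the default behaviour of
`detect_unwanted()`.

The same reasoning applies to clone resolution on realistic noisy data:
feeding the raw screen's flags to `resolve_clones()` disqualifies
essentially every colony (every gene accumulates some noise flags), so
workflows on simulated or real data at instrument-level noise should pass
`detect_unwanted(..., colony_level = TRUE)` flags, as the README example
does. On clean or low-noise count tables both variants coincide.

`b` is estimated per pool (pools are separate library preparations), in a
single pass; a floor of `1e-6` keeps the binomial tail defined on
noise-free synthetic data.

# The synthetic world

`simulate_pools()` is first-class, tested code, and its defaults *are* the
stated experimental conditions: per-colony mutagenesis success probability
0.80 (0.82 / 0.84 in the two follow-up layouts of `experiment_spec()`),
per-base PCR error 1.3e-4, flat per-base sequencing substitution error
1e-3, 1x100 bp reads, ~2500x target-site coverage. Design choices:

* failed colonies are pure wild type (single-colony picks, no mixtures);
* reads are ungapped uniform substrings -- the analyses are
  substitution-only, so indels, chimeras and quality modelling are out of
  scope; plasmid circularity is ignored (edge coverage loss is irrelevant
  at these depths);
* sequencing errors substitute uniformly among the three non-template
  bases; the error model of the real instrument is not published, so a
  flat rate of 1e-3 is assumed;
* per-colony read counts are Poisson around the DNA-normalized equal
  share; read positions are uniform.

What a green test therefore establishes: the caller's arithmetic,
thresholds, ambiguity logic and rate recovery are correct *under flat
substitution noise with ideal demultiplexing*. It does not establish
robustness to real-instrument artifacts (motif-dependent error, quality
droop, index hopping, mapping bias at repeats), none of which the mapper
or caller attempts to model.

The built-in mapper (`map_and_count()`) exists so the pipeline is
self-contained at desk scale: exact 15-mer seeds every 10 nt, full
Hamming verification, both orientations, discarding reads over 10%
mismatches or with tied best placements. ORF references are short and
non-repetitive, so alignment sensitivity is not the interesting part of
this problem; for real data the `read_mpileup()` entry point consumes
`samtools mpileup` text instead.

# Primer design

Mutagenesis primer pairs follow the QuikChange-style protocol rules:
length 30-50 nt, mutation at the centre or one base off, G/C at both
ends, GC content >= 40%, and

$$ T_m = 81.5 + 0.41(\%GC) - 675/N - \%mismatch \ge 78\,^{\circ}\mathrm{C}, $$

with `%GC` and `%mismatch` rounded half-up to whole numbers first (the
protocol's integer-percent convention) and a single-nucleotide
substitution counting as one mismatched base. When no candidate survives,
the GC bound relaxes to 30% and the output is flagged. Among passing
candidates the ranking is: highest Tm, then shortest primer, then central
mutation placement, then leftmost start -- a deterministic tie-break that
the test suite checks against an independent exhaustive search. The
"centre" of an even-length primer is taken as position `N/2` (1-based).
Reverse primers are exact reverse complements, so they share composition,
length and Tm with the forward primer.

# GFP stability calls

Per plate, `I_background` is the mean of the empty-vector wells and `K`
their range (max - min); each well's normalized intensity is
`I_norm = I - I_background` (a difference, not a ratio -- the only form in
which comparing against `K` is dimensionally coherent), and an allele is
stable when its mean `I_norm` over (by default three) replicates exceeds
`K`. Alleles split across plates are normalized within each plate and
compared against the *largest* involved `K` -- the conservative choice the
protocol leaves open. Calls are invariant to per-plate scaling and
offsets, which the suite tests as properties. A mutant is "diminished"
only relative to a stable wild type; if the wild-type protein itself gives
no signal, the comparison is inconclusive rather than negative.

# Y2H disruption calls

Growth is encoded as integer 2-fold serial-dilution steps (0-4) on the
His3 and Ade2 reporter plates and their cycloheximide controls. A pair is
positive when at least one reporter grows and neither CHX control does
(CHX growth marks spontaneous auto-activators). Because growth steps are
2-fold dilutions, the "50% reduction" disruption criterion is a drop of
at least one step, required on *both* reporters, in the majority of three
replicates. Disruption is undefined when the wild-type interaction is not
detectable (those pairs are excluded, so assay false negatives do not
masquerade as disruptions), and pairs whose wild type activates a single
reporter are flagged incomparable rather than forced through the
two-reporter rule.

# Interface classification

Solvent-accessible surface areas use the Shrake-Rupley quadrature with a
deterministic golden-spiral point set (960 points/atom by default, <1%
quadrature error on the test fixtures), fixed van der Waals radii
(C 1.7, N 1.55, O 1.52, S 1.8, others 1.8 A), hydrogens ignored, and a
probe of radius 1.4 A -- the standard water-probe convention (a "water of
diameter 1.4 A" is read as the universal probe radius; a 0.7 A water
would be physically wrong). A residue is an interface residue when it
buries more than 1 A^2 (strict inequality, absolute area) between its
chain alone and the two-chain complex. A domain pair is an interface
domain pair when a curated domain-domain interaction table names it and
each side holds >= 1 interface residue, or when each side holds >= 5
interface residues on its own. Mutations classify by precedence:
interface residue, then interface domain, then away; residues unresolved
in the structure are "unmapped" and excluded from statistics. Residue
numbering follows the coordinate file's author numbering throughout.

# SILAC scoring

The four-experiment pull-down design (wild-type and mutant bait each
against a GFP control, plus direct wild-type/mutant comparisons in both
label orientations) is summarized per protein by geometric means of
light/heavy peptide ratios, bait-normalized in the two swap experiments so
that global mixing-ratio errors cancel (an invariance the suite tests).
Enrichment over control defines interactors (`WT_p > 2` or `Mut_p > 2`
with >= 5 peptides); loss and gain each require confirmation in *both*
label orientations (`FC < 0.5` or `FC > 2` with >= 5 peptides on each
side); the combined effect size is the read-count-weighted mean of the two
log2 fold changes, which is antisymmetric under label swap -- weakened
interactors get `E < 0`, enhanced ones `E > 0`. P values come from a
two-sided Kolmogorov-Smirnov statistic against the pooled per-peptide log
ratios of unchanged proteins, with a bootstrap null (same-size resamples
of the background; `(1 + b)/(1 + n)` correction so p lies in (0,1]). The
comparison population for the KS background is a documented choice: the
original analysis does not define one, and the printed per-protein E and P
values are not reproducible without the raw peptide tables.

# Cohort statistics

Disruption likelihoods by structural locus are simple fractions with
binomial standard errors. Proportions are compared by two-sided Fisher's
exact tests -- the original analysis never names its test and its printed
P values are not reproduction targets; the implemented test is an
explicit, documented alternative. Same-gene mutation pairs are "same
disease" when their case-folded disease-label sets intersect; profile
concordance is evaluated over the pair's shared tested partners, and pairs
without shared partners are incomparable. Pairs sharing a mutation are
not independent, so these P values are descriptive. The cohort simulator
plants a tunable phenotype-disease fidelity (default 0.9, giving
concordant/discordant same-disease probabilities of 0.82/0.18), which the
estimator recovers within binomial error in the property tests.

# Numerical and scale choices

* The acceptance experiments run at their published colony counts; the
  largest (3528 colonies) runs at 100x rather than >300x coverage to stay
  at desk scale. At 100x the gene carrying 40 co-pooled mutations has
  ~65 reads per colony at a target site, so a true success has a ~5%
  chance per colony of dipping under `S = 0.8`; caller-truth agreement is
  therefore asserted at 99% there and exactly elsewhere.
* The unwanted-mutation rate target averages 50 simulated pools in the
  acceptance script (the stated design) and 15 in the test suite for
  runtime, with the tolerance computed from the realized Poisson scale.
* Read simulation and mapping are compiled (Rcpp) but all randomness goes
  through R's RNG, so a single `set.seed()`/config seed makes FASTQ output
  byte-identical.

# Known limitations

* No indels, anywhere: the mutagenesis design, simulator, mapper and
  caller are substitution-only.
* The mapper is for desk-scale synthetic or plasmid data, not a general
  aligner; no base-quality use, no gapped alignment, no BAM.
* Barcode chemistry and demultiplexing are upstream of this package;
  manifests simply declare pool membership.
* Structure handling reads PDB-format ATOM records only (no mmCIF, no
  assembly generation); interface detection requires a co-crystal or a
  trusted model, and prediction quality is explicitly out of scope.
* SILAC scoring consumes filtered peptide ratio tables; spectral search
  and FDR filtering are upstream.
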