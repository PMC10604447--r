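---
title: "Models and methods behind soilvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soilvirome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilvirome)
```

## The scientific problem

Soil viral communities are thought to be structured as a *seed bank*: a
large reservoir of persistent phages, detectable in metagenomes
year-round but mostly dormant, from which small subsets activate as
conditions change — for example across the snowmelt transition of a
mountainous watershed. Bulk metagenomes alone cannot separate an
integrated or dormant phage from one that is actively replicating.
Paired, strand-specific metatranscriptomes can: transcription of a DNA
phage's genes is direct evidence of activity, and for positive-sense
ssRNA phages the appearance of the *antisense* genome strand marks the
replication intermediate of an ongoing infection.

`soilvirome` implements the downstream-of-assembly analysis chain for
this design: building a non-redundant viral catalog, computing
strand-specific coverage, applying decision rules for activity and
lytic-infection calls, propagating taxonomy and host labels over
reference phylogenies, and testing seasonal community structure and
per-vOTU differential activity. A synthetic community generator with
planted ground truth makes every step testable end-to-end.

## vOTU catalog construction

Viral contigs (with completeness estimates supplied by an external
tool) are first filtered by the standard retention rule: keep a contig
if it is at least 5 kbp long **or** estimated at least 50% complete;
unknown completeness fails the completeness clause. Retained contigs
are clustered into viral operational taxonomic units (vOTUs) at the
species-rank thresholds used across viral metagenomics: 95% average
nucleotide identity (ANI) over 85% aligned fraction (AF), with the
longest member as representative.

The internal aligner finds exact k-mer seeds (k = 11) in both
orientations, chains seeds on a shared diagonal when gaps are at most
100 bp, extends each chained span outward while bases match, and counts
mismatches inside spans against identity. ANI is the
alignment-length-weighted mean identity over fragments; AF is the
merged fragment coverage of each sequence. Records from an external
aligner can be supplied instead — `greedy_cluster()` only consumes the
record table.

Two conventions are deliberate choices where the field's guidelines
leave room:

* the AF clause is applied to the **shorter** sequence of a pair (the
  aniclust convention), so a fragment fully contained in a longer
  genome clusters with it;
* greedy seeding is by decreasing length with lexicographic ids
  breaking ties, which makes the output deterministic and guarantees
  representatives are longest members.

## Strand-specific coverage and RPKM

Coverage is accumulated per position and per strand from read
placements (a BAM reader resolves dUTP-style protocols: with the `rf`
convention, read 1 maps antisense to the transcript and its alignment
strand is flipped to coding-strand sense). Two summaries drive all
decision rules:

* **breadth** — the percent of interval positions covered at a depth
  of at least 1 (strands summed or taken separately);
* **median depth** — the *lower* median over all interval positions.
  The lower median is integer-valued and conservative exactly at the
  50%-breadth boundary: a gene covered on exactly half its positions
  has a lower-median depth of 0 and is *not* called expressed, which
  keeps the two clauses of the expression rule non-redundant.

Abundances are RPKM (reads per kilobase of contig per million library
reads), with a masking rule: a vOTU whose coverage breadth in a library
is below 10% is set to RPKM 0 — sporadic hits to a sliver of a genome
are not treated as presence. The per-million normalizer is the
library's total sequencing depth from the library table, not the
mapped-to-catalog count. The mask uses combined-strand breadth by
default (configurable to coding-strand-only for metatranscriptomes; the
choice is exposed because protocols differ in how much antisense signal
they retain).

## Activity classification

**DNA vOTUs.** A gene is *expressed* in a metatranscriptome when its
coding strand has at least 50% of positions covered and a positive
lower-median depth. A vOTU with at least one expressed gene in a sample
is *active*; if any expressed gene belongs to the lytic category set —
virion structure, encapsidation, or lysis — the vOTU is *active-lytic*
(virion production or host lysis under way). With no expressed gene,
the vOTU is *present-inactive* if its metagenome breadth reaches 10%
(the same threshold as the RPKM mask, so "present" means the same thing
everywhere) and *absent* otherwise. Expression takes precedence over
the presence test: transcription implies presence even when the paired
metagenome misses the genome.

**ssRNA vOTUs.** The genome *is* the transcript, so expression cannot
be scored. Instead: coding-strand breadth at least 50% with positive
lower-median depth makes a vOTU *detected*; antisense breadth of at
least 50% at 1x or more additionally makes it *active* (replicating).
The antisense clause is breadth-only — the median-depth requirement
applies to the coding strand only, exactly as the decision framework is
worded. Replication intermediates are minority species, so demanding
positive antisense median depth would needlessly raise the detection
threshold.

Month-level statuses are the per-sample maximum under the ordering
absent < present-inactive/detected < active < active-lytic: a vOTU is
active in a month when it is active in at least one of that month's
samples. Whether an expressed non-lytic gene in one sample and a lytic
gene in another sample of the same month combine into "active-lytic"
is not specified by the framework; the implementation combines within
the month, which is consistent with the "at least one sample"
aggregation used for activity itself.

## Tree-based annotation propagation and UniFrac

Reference phylogenies (e.g. of the RdRP marker of RNA viruses, rooted
by reverse-transcriptase outgroups) carry annotated reference tips and
unannotated query tips. Branches with support below 50 are collapsed
first — children reattach to the grandparent and the contracted edge's
length is added to theirs, preserving patristic distances (collapsed
trees may therefore carry basal polytomies; they remain rooted objects).

Each query tip then walks its ancestors tip-to-root and stops at the
first clade containing at least one annotated reference. If all
annotated references in that clade agree on the field (taxon or host),
the query inherits the value; otherwise it stays unassigned.
References lacking the queried field are ignored rather than treated
as disagreement, because partial reference metadata is the norm. The
"most recent informative ancestor" semantics is the specific claim —
any deeper unanimous clade necessarily contains the same nearest
references. Assignments propagate verbatim from cluster
representatives to cluster members.

Dataset-to-dataset phylogenetic distance uses the UniFrac family on the
same trees. For branch *i* with length $b_i$ and descendant-proportions
$p_i, q_i$ of the two datasets, the generalized form is

$$d = \frac{\sum_i b_i\,(p_i+q_i)^\alpha\,\frac{|p_i-q_i|}{p_i+q_i}}
           {\sum_i b_i\,(p_i+q_i)^\alpha},$$

with $\alpha = 0.5$ by default (down-weighting abundant lineages
moderately), alongside the classical unweighted form (unique branch
length over spanned branch length). Both modes are exposed because the
phrase "generalized unweighted" is ambiguous in common usage; presence/
absence inputs make the two coincide in spirit, and $\alpha$ is honoured
in generalized mode only.

## Seasonal statistics

* **Occupancy**: a vOTU present (masked RPKM > 0) in at least one
  sample of every season is all-season *core*; present in exactly one
  season, *season-specific*.
* **Community structure**: Bray–Curtis dissimilarities
  ($\sum|x_i-y_i| / \sum(x_i+y_i)$) and a one-factor PERMANOVA with
  freely permuted sample labels,
  $p = (1 + \#[F_{perm} \ge F_{obs}])/(1 + n_{perm})$, 999 permutations
  by default and fully seeded. The implementation follows the
  among/within sum-of-squared-distances partition and is cross-checked
  against `vegan::adonis2` in the test suite.
* **Differential activity**: per-vOTU one-way ANOVA of
  metatranscriptome RPKM across months, with eta-squared
  ($SS_{between}/SS_{total}$) as the effect size, Tukey–Kramer post hoc
  month pairs (via `TukeyHSD`, which applies Kramer's unequal-n
  correction), and Storey q-values across all tested vOTUs. A vOTU is
  *seasonal* when $q \le 0.05$ and $\eta^2 > 0.3$. ANOVA runs on raw
  RPKM by default with a log option, since the effect-size convention
  of profile-analysis tools operates on the supplied profile; eta
  squared is the natural multi-group effect size for that ANOVA.
* **Storey FDR**: $\hat\pi_0 = \#[p > \lambda]/(m(1-\lambda))$ at
  $\lambda = 0.5$ by default (a spline smoother over a
  $\lambda$-grid is optional), clipped to $(0, 1]$ and floored at
  $1/m$; with $\pi_0 = 1$ the q-values equal Benjamini–Hochberg
  adjusted p-values exactly.
* **Profiles**: month-mean RPKM standardized across months (z-scores;
  all zero when the month means are constant), grouped by the host's
  ecological strategy (winter-adapted, snowmelt-specialist,
  spring-adapted) with an explicit "unassigned" panel.

## The synthetic community and what it does (not) show

The generator plants a complete ground truth and emits only files an
analysis would also receive in a real study (FASTA, GFF3, placement and
metadata TSVs, Newick trees). Truth tables are written alongside for
evaluation but are never read by any analysis stage.

Study conditions are fixed at realistic, scaled-down values: four
sampling months (March, May, June, September, mapped to winter,
snowmelt, summer, autumn), three depth increments, two locations, one
replicate — 24 samples with paired metagenome and metatranscriptome
libraries; 150 bp reads clipped at contig ends; negative-binomial
counts with size 5 (Poisson in the limit); 70% of DNA vOTUs active,
5% with a single-month activity peak, and 20% of active vOTUs lytic —
the same order as the fractions reported for snow-dominated soil phage
communities; active ssRNA vOTUs carry 20% of their reads on the minus
strand, replication intermediates being minority species. Expressed
gene sets are drawn once per vOTU and reused in every active month, so
the *schedule*, not expression-set turnover, is the only seasonal
signal. Metagenome viral output is 5% of library depth, and library
totals include simulated unmapped background so that per-million
normalization stays month-stable, as it does in real host-dominated
libraries; an all-viral normalizer would otherwise induce purely
compositional month effects in constitutively active vOTUs.

In noiseless mode, counts are fixed at their means and reads are tiled
end-to-end, which guarantees every scheduled signal reaches 100%
breadth: the classifier chain must then reproduce the planted schedule
for 100% of vOTU-month states, and does. Under negative-binomial noise
with a mean expressed-gene depth of 5x, the balanced accuracy of DNA
active-vs-inactive calls exceeds 0.95 over 200 vOTUs.

What the generator does **not** emulate: sequencing errors and quality
scores, chimeric assembly, multi-mapping between related references,
uneven within-genome coverage biases, provirus boundaries, or real
phylogenetic signal in the genome sequences (trees are simulated
separately with planted clades). Passing tests therefore demonstrate
the correctness of the decision rules and statistics under their own
assumptions, not robustness to assembly or mapping artifacts.

## Numerical and design choices

* Deterministic throughout given a seed; the pipeline derives stage
  seeds from one master seed and records them in provenance JSONs with
  input checksums.
* Lower (not interpolated) medians; ties in clustering broken
  lexicographically; reads clipped, never wrapped, at contig ends.
* Zero-variance vOTUs are excluded from ANOVA and reported; libraries
  with zero total reads yield zero RPKM rather than an error at the
  matrix level (the scalar `rpkm()` treats a zero library total as a
  parameter error).
* Default problem sizes (40 vOTUs in the pipeline demo; 200–400 vOTUs
  in the statistical studies; 500 simulations for the PERMANOVA
  calibration) were chosen so that a complete run is comfortable on a
  single CPU while leaving the statistical checks well-powered.
* Known limitations: the ANI aligner is ungapped (indel-rich pairs
  under-align and may fail AF), the breadth mask choice for
  metatranscriptome RPKM (combined-strand vs coding-strand) is a
  configuration rather than a derived fact, and DNA vOTUs are never
  planted absent from metagenomes — the seed-bank premise — so the
  absent/present-inactive boundary is exercised by construction only
  in degenerate cases.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "virome_out", seed = 1)
run_pipeline(cfg)

## or stage by stage
run_stage("simulate", cfg)
run_stage("cluster", cfg)
```

Every stage reads only files under `out_dir`, writes atomically, and
can be re-run independently; identical config and seed give identical
output checksums.
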