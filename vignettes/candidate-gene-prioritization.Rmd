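---
title: "From RIL phenotypes to ranked candidate genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RIL phenotypes to ranked candidate genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlprior)
```

# Scope

`qtlprior` takes a biparental recombinant-inbred-line (RIL) study — a
genotype matrix, a genetic map, replicated multi-environment phenotypes,
gene models, parental variants, and expression profiles — and produces a
ranked list of candidate genes inside QTL support intervals.  Every stage
is also exercised against a seed-deterministic synthetic-data generator
that plants known QTLs and causal genes, so the whole chain is testable
without any external download.

This vignette is the package's own account of the statistical choices:
what each stage assumes, which tunable parameters matter, what the
generator does and does not emulate, and where the design was genuinely
open.

# The mapping model

## Single-marker scan

The scan statistic at each marker is the RSS-ratio LOD of a
single-predictor least-squares regression of the line-mean phenotype on
marker dosage (0/1/2):

$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}
             = -\frac{n}{2}\log_{10}(1 - r^2).$$

Dosage regression rather than genotype-class ANOVA is appropriate because
RILs are nearly fully homozygous (residual heterozygosity after six
selfing generations is $(1/2)^6 \approx 1.6\%$); the rare heterozygotes
contribute midpoint values.  Missing dosages are handled by exact
pairwise-complete sums per marker — no imputation.  Markers with fewer
than `min_n = 20` informative lines are omitted with a warning;
monomorphic markers are reported with LOD 0 and a flag.  Traits with
multiplicative (log-normal) behaviour, such as ethylene emission, are
scanned after a `log10(x + offset)` transform; the offset is 0 when all
values are positive and otherwise `-min(x) + 1`, a concrete choice for
the "smallest offset making the data positive", which is an open infimum.

The scan phenotype is the arithmetic line mean over replicates within an
environment — a least-squares-mean surrogate.  A full mixed-model (REML)
fit is deliberately out of scope; with the near-balanced designs the
generator produces, the two coincide.

## Genome-wide significance

Thresholds come from 1000 phenotype-label permutations: the genome-wide
maximum LOD is recorded per permutation and the empirical 95th percentile
(type-7 interpolation) is the 5% threshold.  Permutation preserves the
marker-correlation structure of the map, which is what makes the
genome-wide error rate come out right on linked markers.  Both `n_perm`
and `alpha` are configurable; fewer than 100 permutations triggers a
warning because the tail quantile becomes unstable.

## Composite scan

`composite_scan()` conditions each test position on a set of cofactor
markers, excluding any cofactor within `window_cM` (default 10 cM) of the
test position on the same chromosome, and any cofactor column identical
to the test marker.  This is the classical composite-interval-mapping
compromise: background QTLs are absorbed by the cofactors while the local
signal is left intact.  With an empty cofactor set it reduces exactly to
the single-marker scan (a tested identity).

## Support intervals and robust QTLs

LOD-drop support intervals (1.5 for standard, 2.0 for permissive
annotation targets) walk outward from the peak to the first position at
or below `peak − drop`; the reported endpoints extend to the flanking
marker beyond the last position still above the drop line and truncate at
chromosome ends.  Widening the drop can therefore never narrow the
interval (a tested monotonicity property).

A QTL is *robust* when peaks above threshold co-localize (within
`colocalization_cM`, default 10 cM — chosen to match the composite-scan
window scale, as the convention itself leaves this open) in at least two
environments.  The reported peak is the highest-LOD member; peak ties go
to the leftmost position for determinism.  Names are composed as
trait + chromosome number + index along the chromosome (e.g. `EtE3.1`).

## Gene action, epistasis, joint models, heritability

* `gene_action()`: additive component $a = |P_1 - P_2|/2$, dominance
  deviation $d = F_1 - (P_1 + P_2)/2$, and the dominance ratio $d/a$
  (undefined when $a = 0$; reported to one decimal in summary tables).
* `test_epistasis()`: fixed-effects two-way ANOVA on peak-marker
  genotype classes, returning the interaction p-value and the cell-mean
  grid for interaction plots; empty cells are dropped and flagged.
* `fit_qtl_model()`: joint least squares on all robust-QTL peak markers;
  collinear peaks are dropped (later marker loses) and reported.  Effects
  are signed so that a positive value means the dosage-2 (parent-B-type)
  allele raises the trait.
* `estimate_heritability()`: one-way ANOVA over lines,
  $\sigma^2_G = (MS_{line} - MS_{err})/r$ clipped at 0 and
  $h^2 = \sigma^2_G / (\sigma^2_G + MS_{err})$, clipped to $[0,1]$.  This
  is a plot-basis convention (whether line-mean or plot basis is meant is
  ambiguous in common usage; the package declares plot basis and the
  generator calibrates to the same definition, so recovery is testable).
  With unbalanced replication $r$ is replaced by the expected-mean-square
  coefficient $r_0 = (N - \sum_i n_i^2/N)/(k - 1)$.

# Variant consequences

`classify_variants()` assigns exactly one highest-severity consequence
term per (variant, gene) pair, then maps terms to impact tiers through a
fixed table: stop_gained / stop_lost / start_lost / splice_donor /
splice_acceptor / frameshift → HIGH; missense / inframe indels →
MODERATE; synonymous / splice_region → LOW; UTR / intron / upstream /
downstream / intergenic → MODIFIER.  Conventions:

* Codons are reconstructed locally from the reference around the variant;
  minus-strand genes are read on the reverse complement.
* Splice sites follow the usual annotator definition: the first/last two
  intronic bases are donor/acceptor (HIGH); intronic bases 3–8 and the
  three exonic bases flanking a junction are splice_region (LOW).
* Inframe indels are checked for a junction codon that becomes a stop
  (then reported as stop_gained); indels touching the start or stop codon
  are start_lost / stop_lost.
* Variants in models flagged non-translatable get the best-effort term
  `exonic_unclassified` (MODIFIER).
* Multiallelic sites are split upstream (in `read_vcf()`), so
  classification is per alternate allele; a variant overlapping two genes
  yields two annotations.

The test suite holds this classifier to 100% agreement with an
independent oracle that applies the variant to the genomic sequence,
re-extracts and translates the *entire* mutant CDS, and diffs the
proteins.  `filter_to_genic()` implements the genic-space filter: a
variant is kept when inside a gene span or its annotated UTRs, or — for
genes without UTR annotation — within `utr_flank_bp` of the span.  The
default flank of 500 bp is a conservative, configurable stand-in for
unannotated UTR extents.

# Evidence layers and the general score

Five layers are scored per gene inside each 2-LOD interval:

| Layer | Evidence | Weights (defaults) |
|---|---|---|
| proximity | LOD drop at the gene midpoint | `<0.5 → 2`, `0.5–1.0 → 1`, `1.0–1.5 → 0.5`, `>1.5 → 0` |
| polymorphism | max impact among the gene's variants | MODIFIER 0.5, LOW 1.0, MODERATE 1.5, HIGH 2.0 |
| relevance | keyword match in the description | match 1.0; unknown/uncharacterized flagged, scored 0 |
| expression | profile peak in a trait-relevant stage; parental DE | +1 each, capped at 2 |
| association | best validation-panel p-value | `p<1e-4 → 2`, `p<0.01 → 1`, else 0 |

Notes on the open choices:

* The common proximity-tier convention leaves the 1.0–1.5 drop band
  unstated; it scores 0.5 here as the monotone interpolation between the
  neighbouring tiers.
* The polymorphism layer uses the *maximum* impact rather than a sum:
  summing would reward variant-count artifacts of annotation density.
* Expression and association tier weights are declared package
  conventions (these layers have no widely fixed numeric tiers); they
  live in `scoring_weights()` and the YAML config so they can be changed
  without touching code.
* Raw totals are indexed per interval to a 1–10 *general score*:
  `1 + 9(raw − min)/(max − min)`, all genes 5.5 when totals are tied.
  Indexing is interval-relative because candidate comparison happens
  among the genes of one QTL; a global index would let a crowded interval
  crowd out a sparse one.  Ranking by general score always equals ranking
  by raw total (tested property).

Gene midpoints are converted between genetic and physical axes by
piecewise-linear interpolation of the map's bp anchors — the simplest
monotone map consistent with the colinearity the interval logic needs.

Two further evidence operations support candidate follow-up outside the
score card: `expression_trait_correlation()` (Pearson on
`log10(FPKM+1)` vs the possibly log-transformed trait) and
`two_locus_association()` (two-way ANOVA with interaction; joint
R², interaction p, cell-mean grid).  Compact letter displays for
association panels come from an insert-and-absorb algorithm over the
Tukey HSD pairwise p-value matrix at $\alpha = 0.05$ — the grouping is a
pure function of the significance matrix, so input order cannot change
it.  Groups with fewer than two observations are excluded from the
letters.  The heterozygote-additivity flag is set when the het mean lies
strictly between the homozygote means and within the inner half of their
span.

# What the generator emulates — and what it does not

`simulate_ril_population()` descends each line independently from a
uniformly heterozygous F1 by single-seed-descent selfing (default F7, six
rounds), with per-chromosome meiosis as a Poisson crossover process —
the Haldane, no-interference model, so the recombination fraction over
$d$ cM is $r = (1 - e^{-2d/100})/2$ in closed form.  No interference is a
deliberate simplification: it makes every recombination expectation
closed-form testable, at the cost of slightly over-dispersed crossover
counts relative to real meiosis.

`simulate_phenotypes()` builds a line's genetic value as additive +
dominance + pairwise-epistatic QTL terms plus a polygenic normal effect.
QTL `%variance` targets are interpreted as fractions of the *genetic*
variance (the convention used when a QTL is said to explain a share of
genetic variation), with the polygenic term absorbing the remainder; the
residual variance is solved per environment so the realized plot-basis
broad-sense heritability matches the target.  Environment effects are
fixed shifts drawn once; genotype-by-environment interaction is
line-by-environment normal noise (`gxe_sd`, default 0.2 on the unit
genetic-variance scale).  Traits flagged `log_scale` are emitted as
$10^{value}$ so the analysis layer must log-transform, reproducing the
workflow for log-normal traits.

Default study conditions: 164 lines, F7, 12 chromosomes of 120 cM at
2 cM marker spacing, two environments with five replicated plot
observations per line each (five plants per plot is the emulated design),
heritability targets in the 0.3–0.7 band, physical axis 1 cM ≡ 250 kb.

`simulate_annotation_bundle()` tiles two-exon genes (50 bp UTRs, two
300 bp CDS segments, a 200 bp intron) along the physical axis at
`n_genes_per_cM` (default 1/cM — an intentional scale-down from real
genome density, since only the relative evidence of causal vs decoy genes
matters for testing the prioritization logic).  Each planted causal gene
sits exactly at its QTL peak and receives a premature-stop variant, a
4-fold parental differential-expression peak at a trait-relevant stage,
and a relevance keyword in its description; decoys receive random
synonymous/missense/intron/upstream variants, flat profiles, and neutral
or uninformative descriptions.  Reference sequence is materialized only
as per-gene fragments (span ± 1 kb): classification needs coding context
only, and the fragment table keeps the synthetic genome text-sized.

`simulate_diallel_panel()` produces all $n(n-1)/2$ unordered F1s of a
founder set with homozygous founders, so heterozygote expectations are
homozygote midpoints plus any dominance deviation — the validation-panel
geometry for the association layer.

Not emulated (so green tests say nothing about): population structure
and kinship in diverse panels, marker ascertainment bias, genotyping
error beyond uniform missingness, crossover interference, segregation
distortion, structural variation, linkage-map estimation error, and
non-normal residuals.  Passing the planted-truth acceptance checks
demonstrates the machinery is calibrated under the stated generative
model, not that real-data candidate lists would match any particular
published list.

# Numerical and degenerate-input conventions

* $r^2$ is clamped below 1 before the $\log_{10}$ so perfect fits yield a
  large finite LOD instead of infinity.
* Quantile type 7 for permutation thresholds; `alpha = 1` returns the
  minimum permuted maximum (tested boundary).
* Constant phenotypes short-circuit ANOVA helpers to F = 0 / R² = 0
  rather than relying on 0/0 floating-point noise.
* Peak ties: leftmost wins.  Tied raw totals: equal general scores.
* Empty scorecard sets, monomorphic SNPs, zero-length chromosomes,
  missing seeds and jointly impossible `%variance` targets are hard
  errors; pipeline stage failures abort with a stage-named error.
* Seeds are mandatory for every stochastic entry point, and seeded calls
  save/restore the caller's RNG stream.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use these simulation scales:
500 null scans of 150 lines × ~300 markers with 1000-permutation
thresholds for the type-I check; 50 seeds of 200 lines for the planted
two-QTL recovery; 1000 random coding variants against the
translation-diff oracle; 2000 lines for selfing analytics; and 50
end-to-end pipeline runs (200 lines, one 20%-of-genetic-variance QTL,
0.5 genes/cM over two 100 cM chromosomes) for causal-gene top-3
recovery.

# Known limitations

* No hidden-genotype interval mapping between markers (scan resolution is
  the marker grid) and no penalized stepwise multi-QTL search; the joint
  model uses robust peaks only.
* The association layer has no kinship/structure correction; it is a
  one-way ANOVA intended for designed validation panels, not for GWAS in
  structured collections.
* The GFF3 reader assumes one transcript per gene (the first mRNA's
  children define the model).
* Indels spanning exon–intron boundaries are classified per-base by
  severity precedence rather than by transcript re-alignment.
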