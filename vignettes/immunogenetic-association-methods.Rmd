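---
title: "Immunogenetic association analysis with hlakir: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogenetic association analysis with hlakir: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlakir)
library(dplyr)
```

## The problem

Association studies in the MHC usually stop at classical HLA alleles: one
carrier indicator per allele, one regression per indicator. That leaves most
of the biology on the table. Alleles that share a residue in the peptide
binding groove present overlapping peptide repertoires; an individual's two
alleles may be more or less diverged from each other; HLA class I molecules
are also ligands for KIR on NK cells, and it is the *combination* of a KIR
gene and its cognate HLA ligand group that is functional. `hlakir`
transforms diploid HLA calls and KIR gene-content tables into these
biologically meaningful variables and runs a uniform association engine
over all of them.

## Data model

The raw substrate is a *calls table*: one row per individual, an `ID`
column, and two columns per gene (`A_1`, `A_2`, ...) holding allele names in
official nomenclature at 1- to 4-field resolution (e.g. `A*02:01:01:01`).
Fields are 2-3 digits; an optional expression suffix (`N/L/S/C/A/Q`) is
parsed and retained at full resolution but dropped whenever resolution is
reduced. KIR data is a table of `Y`/`1` (presence) vs `N`/`0` (absence) per
KIR gene.

Every transform returns an *experiment*: a tibble of individuals by
variables carrying per-variable metadata (omnibus group, applicable
inheritance models, frequency). Values are copy counts (0/1/2), binary
indicators, or continuous scores:

| experiment | variables | values |
|---|---|---|
| `hla_alleles` | one per allele at the chosen resolution | copies 0/1/2 |
| `hla_supertypes`, `hla_g_groups` | one per dictionary group | copies |
| `hla_aa` | `<GENE>_<pos>_<residue>` | copies |
| `hla_het` | `<GENE>_het` | 0/1 |
| `hla_divergence` | `<GENE>_divergence` | continuous |
| `hla_NK_ligands` | `Bw4`, `Bw6`, `C1`, `C2` (optionally `Bw4_80T/I`) | copies |
| `kir_genes` | one per KIR gene | 0/1 |
| `hla_kir_interactions` | e.g. `KIR2DL1_C2` | 0/1 |

`hla_dataset()` combines experiments with the phenotype table, enforcing
variable-name uniqueness across the whole collection (so any variable can
be substituted into a model formula unambiguously) and inner-joining
individuals by `ID`.

## Dictionaries and alignments

Allele grouping (supertypes, G groups, NK ligands, custom) is driven by
editable two-column TSV dictionaries that declare their field resolution in
a header; a query allele is reduced to that resolution before lookup, and
unmapped alleles simply contribute to no group. An allele may belong to at
most one group per dictionary; violations are load errors. The bundled
tables are small curated subsets of the published groupings intended for
examples and tests -- production analyses should extend them.

Protein alignments use a normalised text layout derived from IPD-IMGT/HLA
alignments: the reference row is explicit, later rows code identity with
the reference as `-`, unknown as `*`, and indels as `.`. Parsing resolves
the identity codes so every cell is explicit. Queries are matched to rows
by 2-field reduction and longest-prefix match, ties broken by file order;
when several 4-field rows share a 2-field prefix but disagree at a
position, the first row in file order wins. Unknown residues are treated as
missing data downstream, never as errors, because real alignments have
incomplete sequences: an individual with an unknown residue is missing for
that position's variables, and unknown positions are excluded from both
the numerator and denominator of divergence.

## The transforms

**Amino-acid expansion.** Only positions that are *variable among the
dataset's observed alleles* (two or more distinct non-unknown residues;
indels count as a residue state) are expanded, one copy-count variable per
residue, grouped per position for the omnibus test. Per individual and
position the counts sum to 2 whenever both calls are present and
sequenced -- the diploid-conservation invariant the tests enforce.

**Grantham divergence.** The divergence of an individual's two alleles at
a gene is the mean Grantham distance between their residues over a region:
the full antigen-recognition domain (mature positions 1-182), or the B or
F peptide-anchor pocket. The 20x20 matrix is computed from Grantham's
formula (composition, polarity, volume; alpha = 1.833, beta = 0.1018,
gamma = 0.000399, scale 50.723, rounded to integers). The formula
reproduces the published integer distances up to the occasional well-known
one-unit rounding difference of the original printed table; the formula is
taken as authoritative. Homozygotes score exactly 0. Individuals with a
missing call are missing, rather than scored against the single known
allele, since a one-allele "divergence" has no interpretation.

**NK ligands and interactions.** Ligand groups are dictionary-first; the
only alignment-derived step is the optional Bw4 split by the position-80
threonine/isoleucine dimorphism, which modulates KIR3DL1 binding.
Interactions are coded as ligand *carrier* status (at least one copy) AND
receptor presence; dose effects can be expressed through custom
dictionaries instead of being defaulted.

## The statistical engine

The model is written once with the literal placeholder `term`, e.g.

```r
hla_model(outcome ~ term + age + term:age, family = "logistic")
```

and the engine substitutes each variable for `term`, fits with
`lm()`/`glm()`/`survival::coxph()` (Efron ties), and extracts the
placeholder coefficient, Wald confidence interval (t-based for linear
models) and p-value. Nominal p-values are corrected across the scanned
variables by `stats::p.adjust` (`BH`, `bonferroni`, `holm`, `BY`, `none`).
Non-converging or aliased fits become flagged missing-statistic rows; the
scan never drops them silently.

**Inheritance encodings** apply to copy-count variables: additive
(identity), dominant (any copy), recessive (two copies), overdominant
(exactly one copy). Binary and continuous variables enter as-is; asking
for an encoding a variable's metadata does not list is an error.

**Frequency filters** operate on allele frequency (copies over 2n) for
copy-count variables and carrier frequency for binary ones -- both are
available for count variables, allele frequency being the default since
it is the scale on which power calculations for count data are usually
done. Continuous variables are exempt.

**Hardy-Weinberg testing** collapses each allele to an allele-vs-rest
biallelic genotype table. The default test is the 1-df chi-square of
observed versus expected counts at the ML allele frequency, without
continuity correction -- calibration at n = 500 is verified by simulation
in the test suite. The exact alternative is the Levene-Haldane conditional
test on the heterozygote count, two-sided by summing all outcomes no more
probable than the observed one. Tables with fewer than two observed
genotype classes are skipped and flagged.

**Omnibus tests.** All residues at a position are tested jointly by a
likelihood-ratio test: full model = covariates + the position's variables
minus a reference level, null model = covariates only, statistic
`2 * (ll_full - ll_null)` on `rank_full - rank_null` degrees of freedom.
The reference level is the most frequent residue, chosen for stable
conditioning. Aliased columns are dropped by the fit and the rank
difference accounts for them. Groups that degenerate to one non-reference
level reduce to the 1-df test and are flagged; groups with no
non-reference level report statistic 0, p = 1. Placeholder-containing
terms of the template are replaced by the group's variables as main
effects; interaction templates are supported in the single-variable scan
only.

**Conditional search** is stepwise forward selection: each round rescans
the experiment with all previously selected variables as covariates and
selects the smallest corrected p-value below the threshold, ties broken by
variable name. Corrected p-values are recomputed within each round
(per-round multiplicity), so a variable's selection criterion is always
"significant among the candidates of this round". The conditioned
variables are placed *before* the placeholder in the design, so a
candidate collinear with an earlier selection is the column the fit
aliases -- it is reported as a flagged row, warned about, and the
next-best candidate considered. Round 1 is by construction identical to
the unconditional scan.

## Synthetic data

The simulation module exists so every claim above is testable offline.
`sim_hla_calls()` draws two alleles per gene independently from the
configured frequency table -- exact Hardy-Weinberg sampling, which gives
the HWE test a true null; an inbreeding parameter adds excess homozygosity
to test power. `sim_phenotype()` builds the linear predictor from planted
effects and draws binary (logistic link), continuous (Gaussian) or
survival (exponential hazard, uniform censoring) outcomes. An LD proxy is
generated by copy-with-flip at the rate matching a target correlation.
Generators are pure functions of their configuration, restore the caller's
RNG state, and emit the exact file dialects the readers parse.

The default frequency tables sketch a small class I + DQB1 panel with a
common-to-rare gradient typical of European cohorts. What the generator
does *not* emulate: linkage disequilibrium between genes (beyond the
explicit proxy), population structure, genotyping error, and realistic
4-field resolution mixtures. Passing tests therefore demonstrate
correctness of the transforms and engine, not robustness to those
real-data complications.

## Numerical and design choices

* Problem sizes in the test suite: oracle equivalence on cohorts of up to
  50 individuals; engine fidelity at n = 200 against independent refits at
  1e-6 relative tolerance; CI coverage of a planted log(2) odds ratio at
  allele frequency 0.2 over 200 cohorts of n = 2000; HWE calibration over
  2000 null cohorts of n = 500; conditional-search recovery over 100
  cohorts of n = 2000.
* The conditional-search simulation plants odds ratios 3.0 and 2.0 on
  common alleles with a 0.95-correlated proxy of the stronger one. These
  sizes were chosen a priori for near-certain marginal power and a
  source-versus-proxy z-separation beyond sampling noise, so that failures
  of the exact-recovery property isolate the selection algorithm itself;
  the residual failure mode is the ~5% per-round false-positive rate that
  the 0.05 selection threshold itself implies. Odds ratios of this size
  are routine in HLA disease association.
* G-group labels (`...G`) are group labels only, never parsed as alleles.
* Expression-suffixed (e.g. null `N`) alleles are retained; whether they
  should contribute to protein-level transforms is a user decision made by
  editing the dictionaries/alignments, not hard-coded.
* p-value formatting in written TSVs is fixed (six decimals, scientific
  below 1e-4) so that reruns are byte-identical.

## Known limitations

KIR copy number and allelic resolution are not modelled -- gene presence
only. Haplotype inference is out of scope. The bundled dictionaries cover
common alleles only. Population reference frequencies are compared against
a user-supplied local table; there is no online retrieval.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 500, effects = c("A*02:01" = log(2)),
                  seed = 7)
calls <- sim_hla_calls(cfg)
alleles <- hla_counts(calls, resolution = 2)
pheno <- sim_phenotype(alleles, cfg)
ds <- hla_dataset(pheno, list(alleles), calls = calls)
run_association(ds, hla_model(outcome ~ term, family = "logistic"),
                "hla_alleles", lower_frequency = 0.02) |>
  tidy() |>
  head()
```
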