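# hlakir

Immunogenetic association analysis for HLA and KIR data, in R.

Association studies in the MHC usually test classical HLA alleles one at a
time. `hlakir` widens that lens: it recodes diploid HLA calls and KIR
gene-content tables into the variables that carry the biology — allele copy
counts at 1- to 4-field resolution, supertype and G-group counts, per-position
amino-acid residue counts from protein alignments, per-gene heterozygosity,
Grantham evolutionary divergence of each individual's allele pair over the
peptide-binding region (or its B/F pockets), Bw4/Bw6/C1/C2 NK-ligand groups,
KIR gene presence, and experimentally validated HLA–KIR interactions — and
runs one consistent statistical engine over all of them.

## The engine in one paragraph

A model is written once with the literal placeholder `term`, e.g.
`outcome ~ term + age` with a logistic, linear or Cox family. The engine
substitutes every variable of an experiment for `term`, fits, and reports the
placeholder's estimate (log-OR &beta;, or log-HR), Wald 95% CI, nominal and
multiplicity-corrected p-values, and variable frequency. On top of the
per-variable scan sit: Hardy–Weinberg tests (1-df &chi;² or Levene–Haldane
exact) with optional filtering, frequency windows, the four genetic
inheritance encodings (additive / dominant / recessive / overdominant), an
omnibus likelihood-ratio test of all residues at an amino-acid position
jointly (statistic 2·(ℓ<sub>full</sub> − ℓ<sub>null</sub>), df = rank
difference), stepwise conditional forward selection of independent signals,
and residue→allele back-mapping. A seeded synthetic-data module generates
genotypes, alignments and phenotypes so everything is testable offline.

## Worked example

Simulate a 500-person cohort with a log(2) odds ratio planted on `A*02:01`,
transform to allele counts, and scan:

```r
library(hlakir)

cfg    <- sim_config(n_individuals = 500, effects = c("A*02:01" = log(2)),
                     seed = 7)
calls  <- sim_hla_calls(cfg)
alleles <- hla_counts(calls, resolution = 2)
pheno  <- sim_phenotype(alleles, cfg)
ds     <- hla_dataset(pheno, list(alleles), calls = calls)

res <- run_association(ds, hla_model(outcome ~ term, family = "logistic"),
                       "hla_alleles", lower_frequency = 0.02)
head(tidy(res)[, c("variable", "estimate", "ci_lo", "ci_hi", "p", "p_adj",
                   "freq")])
#> # A tibble: 6 x 7
#>   variable estimate  ci_lo  ci_hi         p   p_adj  freq
#>   <chr>       <dbl>  <dbl>  <dbl>     <dbl>   <dbl> <dbl>
#> 1 A*02:01     0.588  0.298 0.879  0.0000720 0.00238 0.279
#> 2 B*15:01    -0.390 -0.831 0.0520 0.0838    0.787   0.087
#> 3 A*32:01    -0.520 -1.15  0.110  0.106     0.787   0.043
#> 4 C*07:01    -0.296 -0.657 0.0644 0.107     0.787   0.146
#> 5 B*44:03     0.376 -0.100 0.851  0.122     0.787   0.081
#> 6 A*01:01    -0.233 -0.551 0.0854 0.152     0.787   0.189
```

The planted allele tops the table: estimated log-OR 0.588 (truth
log 2 ≈ 0.693 inside the CI [0.298, 0.879]), Benjamini–Hochberg corrected
p = 0.0024; every other allele is null, and their corrected p-values behave
accordingly.

```r
glance(res)
#> # A tibble: 1 x 4
#>   n_variables n_significant n_failed min_p_adj
#>         <int>         <int>    <int>     <dbl>
#> 1          33             1        0   0.00238
```

Downstream steps compose the same way: `hla_aa_counts()` +
`omnibus_test()` score amino-acid positions, `alleles_for_aa()` maps a
position's residues back to the alleles that carry them,
`conditional_search()` isolates statistically independent signals, and
`autoplot()` draws forest plots of any scan.

## Bundled data

`inst/extdata/` ships small, editable TSV dictionaries (class I supertypes,
G groups, NK-ligand groups), the validated KIR–ligand interaction table,
divergence region presets (ARD, B pocket, F pocket) and a synthetic DQB1
protein-alignment fixture. The dictionaries are curated subsets intended for
examples and tests; extend them for production analyses. See the vignette
(`vignettes/immunogenetic-association-methods.Rmd`) for the methods in full.
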