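# plex8

Rule-based forensic DNA phenotyping: prediction of human **eye color**
(brown / green / blue / not-blue / not-brown) and **skin color**
(light / not-dark / not-light) from genotypes at eight pigmentation SNPs —
rs12913832 (*HERC2*), rs1545397 (*OCA2*), rs16891982 (*SLC45A2*),
rs1426654 (*SLC24A5*), rs885479 (*MC1R*), rs6119471 (*ASIP*),
rs12203592 (*IRF4*) and rs12896399 (*SLC24A4*).

The intended users are forensic and population geneticists who need an
auditable, deterministic genotype-to-phenotype call (e.g. for
unidentified human remains) rather than a probabilistic model.

## The procedure

**Eye color** is a two-step decision tree. Step 1 keys on rs12913832:
A/A or A/G ⇒ *not blue*, G/G ⇒ *not brown*, refined to a positive color
by auxiliary homozygotes —

| rule  | genotype combination |
|-------|----------------------|
| brown | rs12913832 ∈ {A/A, A/G} and (rs6119471 G/G or rs16891982 C/C) |
| green | rs12913832 G/G + rs16891982 C/C, or rs12913832 A/G + rs12203592 T/T |
| blue  | rs12913832 G/G + rs12203592 T/T |

Step 2 upgrades remaining negatives: rs12913832 G/G + rs12896399 T/T ⇒
blue; rs12913832 A/A + rs12896399 G/G ⇒ brown. (`mode = "7plex"` skips
step 2.)

**Skin color** is eliminated from homozygotes only: *light* requires
rs12913832 G/G + rs16891982 G/G + rs1426654 A/A; *not dark* any two of
{rs12913832 G/G, rs16891982 G/G, rs1426654 A/A, rs1545397 T/T,
rs885479 A/A}; *not light* rs6119471 G/G; otherwise *inconclusive*.

The package also ships the published training (n = 803) and test
(n = 212) outcome tables as machine-readable fixtures, the evaluation
semantics (errors, call rates, population-stratified rates), the
contingency-table statistics used for SNP selection (Pearson χ² with
Cramér's V, unweighted Cohen's κ, pooled two-proportion z), and a seeded
Hardy–Weinberg cohort simulator with a controllable
genotype–phenotype discordance rate ε. See
`vignettes/plex8-methods.Rmd` for the model, assumptions and design
decisions.

## Worked example

```r
library(plex8)

g <- empty_genotypes(c("UHR-1", "UHR-2", "UHR-3"))
g$rs12913832 <- c("G/G", "A/G", "A/A")
g$rs16891982 <- c("G/G", "C/G", "C/C")
g$rs1426654  <- c("A/A", "A/G", "A/G")
g$rs12203592 <- c("T/T", "C/T", "C/C")
g$rs12896399 <- c("T/T", "G/T", "G/G")
predict_cohort(g)
#>   sample_id eye_label eye_step eye_rules eye_conflict   skin_label
#> 1     UHR-1      blue        1      blue        FALSE        light
#> 2     UHR-2  not_blue        1                  FALSE inconclusive
#> 3     UHR-3     brown        1     brown        FALSE inconclusive
#>                        skin_rules light_marker_count
#> 1 rs12913832;rs16891982;rs1426654                  3
#> 2                                                  0
#> 3                                                  0
```

UHR-1 carries the blue rule (rs12913832 G/G + rs12203592 T/T) and all
three light-skin markers. UHR-2 is heterozygous at rs12913832, so only
the exclusion call *not blue* is possible, and with no homozygous skin
marker the skin call is inconclusive. UHR-3 matches the brown rule
(rs12913832 A/A + rs16891982 C/C); its rs12896399 G/G is irrelevant
because step 2 never touches step-1 positives.

The packaged outcome tables reproduce the published aggregates — 151
step-1 positive eye descriptions growing to 248 after step 2 in the
training set, with 13 and 12 errors:

```r
s <- summarize_fixture(builtin_fixture("training", "eye"))
c(s$n_positive_step1, s$n_positive_total, s$n_errors_step1, s$n_errors_step2)
#> [1] 151 248  13  12

positive_description_gain(151, 803, 248, 803)$statistic
#> [1] -5.601501
all(verify_tables()$pass)
#> [1] TRUE
```

A command-line front end wraps the same operations
(`inst/scripts/plex8`): `predict`, `evaluate`, `simulate`,
`verify-tables`.

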