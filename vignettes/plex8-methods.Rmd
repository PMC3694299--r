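---
title: "plex8: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plex8: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plex8)
```

## The problem

Forensic DNA phenotyping infers externally visible characteristics from
genotypes when no reference profile exists — typically for unidentified
human remains, where pigmentation cannot be recovered from a skeleton.
`plex8` implements a deterministic, rule-based predictor of eye color
(brown / green / blue, or the exclusion calls *not blue* / *not brown*)
and skin color (*light* / *not dark* / *not light*) from eight
pigmentation SNPs:

```{r}
panel()
```

Unlike likelihood-based systems (IrisPlex-style multinomial regression),
every call here is the result of explicit genotype rules, which makes the
output auditable in a forensic setting. The price is that calls can be
negative ("not blue") or absent (skin prediction uses only homozygous
genotypes, so heterozygous-heavy profiles are *inconclusive*).

## The eye-color procedure

Step 1 keys on rs12913832 (HERC2): A/A or A/G excludes blue
(baseline *not_blue*), G/G excludes brown (*not_brown*); a missing
rs12913832 is a *no_call*. Three auxiliary homozygotes can refine the
baseline to a positive color:

* **brown** — rs12913832 ∈ {A/A, A/G} and (rs6119471 G/G or rs16891982 C/C)
* **green** — rs12913832 G/G and rs16891982 C/C, or rs12913832 A/G and
  rs12203592 T/T
* **blue** — rs12913832 G/G and rs12203592 T/T

Step 2 revisits only samples still holding a negative label:
rs12913832 G/G with rs12896399 T/T becomes **blue**, rs12913832 A/A with
rs12896399 G/G becomes **brown**. Heterozygous rs12913832 samples are
never upgraded. `mode = "7plex"` disables step 2, reproducing the legacy
system's behaviour on the shared SNPs.

Two design points the source procedure leaves open, decided here:

* **Rule conflicts.** The positive rules are not mutually exclusive
  (e.g. rs12913832 G/G + rs16891982 C/C + rs12203592 T/T satisfies both
  green and blue). `predict_eye()` resolves by the fixed precedence
  brown > green > blue — the order in which the rules are stated — sets
  `conflict = TRUE`, and lists every matching rule in `fired_rules`, so
  nothing is silently discarded. Exhaustive enumeration of all
  3^5 = 243 complete genotype vectors shows conflicts are rare corner
  cases, but a forensic tool must still be deterministic on them.
* **Partial data.** A positive rule whose auxiliary SNP is missing simply
  cannot fire; the baseline negative label stands. No imputation is
  attempted.

Enumeration of the 243 complete vectors also establishes the 100% eye
call rate: every vector receives exactly one label and `no_call` occurs
only when rs12913832 itself is missing.

## The skin-color procedure

An elimination process over homozygous genotypes only. Five *light
markers* (rs12913832 G/G, rs16891982 G/G, rs1426654 A/A, rs1545397 T/T,
rs885479 A/A) and one *dark marker* (rs6119471 G/G):

* **light** — rs12913832 G/G and rs16891982 G/G and rs1426654 A/A
* **not_dark** — at least two light markers
* **not_light** — the dark marker, when no lighter rule fired
* **inconclusive** — nothing fired (all-heterozygous profiles)

"Any two" is read as *at least* two: an exactly-two reading would make
the stricter light condition (three named markers) unsatisfiable
nonsense, and the light set is then provably a subset of the not-dark
set over all 3^6 = 729 complete vectors (tested). When a lighter-branch
rule and the dark marker co-fire — an admixture pattern the source rules
never address — the package refuses to choose and returns an explicit
`conflict` label with both signals listed. Surfacing the contradiction
was judged safer than silently preferring either branch; *medium* is
never a positive output.

## Genotype handling

Genotypes are unordered allele pairs (phase is irrelevant to every
rule), canonicalized to sorted strings such as `"A/G"`. Input comes from
a genotype TSV or a VCF (v4.2, `GT` field), with records matched by rsID
and optionally by chromosome/position through a user-supplied lookup
table; `NA`, `.` and `./.` all mean missing. Alleles outside a SNP's
canonical pair are complemented (with a warning) when the SNP is not
strand-ambiguous and the complement fits — a likely opposite-strand
report — but the three complementary-symmetric SNPs (rs16891982 C/G,
rs6119471 C/G, rs1545397 A/T) are never flipped: a strand error there is
undetectable from allele labels, and silent flipping is a classic
phenotyping mistake. Irreconcilable alleles are an error, not a missing
value.

## Evaluation semantics

An *error* is a prediction incompatible with the independently binned
truth (eye: blue/green/brown; skin: light/medium/dark): `not_blue` is
compatible with brown and green, `not_brown` with green and blue,
`not_dark` with light and medium, `not_light` with medium and dark.
Non-calls (`no_call`, `inconclusive`, `conflict`) are excluded from
error denominators; they are an absence of evidence, not a wrong call.

The published error rates use idiosyncratic denominators, reproduced
deliberately and labelled explicitly in `summarize_fixture()` output:
training-set rates divide European errors by all 555 Europeans (the only
population with wide eye-color variation; including others would deflate
the rate without adding information); the test-set step-2 and overall
rates divide by the 110 Europeans *not* positively described in step 1.
Both denominator variants are always computed so the convention is
auditable. One printed figure is internally inconsistent in the source:
5/110 = 4.545% appears as 4.54% (truncated) while 3/110 = 2.727% appears
as 2.73% (rounded); `verify_tables()` therefore allows that single rate
one unit in the last printed digit and checks the underlying counts
exactly.

The training (n = 803) and test (n = 212) outcome tables ship as a
machine-readable fixture (`builtin_fixture()`); `verify_tables()`
recomputes every headline aggregate from it:

```{r}
res <- verify_tables()
all(res$pass)
head(res, 8)
```

## The synthetic cohort generator

No per-sample genotypes were published, so end-to-end testing uses
simulated cohorts with known structure (`cohort_config()`,
`simulate_cohort()`, `generate_cohort()`):

* **Populations** follow the five study codes (AA, SA, EA, E, mix); the
  default mix is the training-set composition (43/27/35/555/143 of 803).
* **Genotypes** are drawn per SNP under Hardy–Weinberg proportions
  (p², 2pq, q²) from per-population frequencies of the trait-associated
  allele. The packaged defaults are plausible magnitudes chosen once for
  realism (e.g. rs12913832 G at 0.75 in Europeans, 0.01–0.07 elsewhere;
  rs6119471 G at 0.85 in African-Americans) and are labelled synthetic —
  they are not estimates from any cohort. SNPs are drawn independently
  (no linkage disequilibrium): the prediction rules treat SNPs
  independently, so LD would not exercise any additional code path.
* **Phenotype truth** is derived from the predictions themselves:
  positive calls fix the bin, negative or inconclusive calls draw
  uniformly from the compatible bins, and with probability ε
  (`discordance`, default 0.02 — the order of the published error rates)
  the bin is replaced by a uniformly drawn *incompatible* bin. This
  truth-from-prediction construction is what makes the expected error
  rate analytically equal to ε, so the evaluation pipeline can be tested
  quantitatively: at n = 5000 the recovered rate lies within three
  binomial standard deviations of ε for ε ∈ {0, 0.02, 0.05, 0.1}.

What a green simulation test does **not** establish: that real cohorts
behave like the generator. Real data have LD (notably in the
HERC2/OCA2 region), population substructure, genotyping dropout that is
not missing-at-random, and genotype–phenotype relationships far messier
than ε-flips. The fixtures of the published tables — not the simulator —
are the package's anchor to real-cohort behaviour.

## Association statistics

`chi_square_independence()` (Pearson χ², Cramér's V, upper-tail P),
`cohens_kappa()` (unweighted; no weighting scheme was named by the
source) and `two_proportion_z()` (pooled variance, two-sided, no
continuity correction — matching the plain web calculators the source
cites) are implemented directly from the formulas and tested against
independent oracles (`stats::chisq.test(correct = FALSE)`,
`prop.test`, and hand-written O/E summations). They are generic
operations: the source's specific values (χ²₄ = 14.09, κ = 0.063,
z = −7.786) depend on unpublished per-sample data — the exact 2×2 input
behind the z-score is not even stated, and 151/803 vs 248/803 gives
z ≈ −5.6 — so they are intentionally not reproduction targets.

## Known limitations

* Exclusion calls dominate: most complete genotypes yield *not_blue* /
  *not_brown* / *not_dark* rather than a positive color.
* The skin predictor cannot call *medium* and is frequently
  inconclusive outside European-like allele-frequency profiles, mirroring
  the published call rates (75% training, 62% test, ~94% for test-set
  Europeans).
* No probabilistic output, no hair color, no liftover between genome
  builds, and no genotype calling from raw assay fluorescence.
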