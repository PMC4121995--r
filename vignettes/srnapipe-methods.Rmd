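---
title: "srnapipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnapipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`srnapipe` analyses a two-library small RNA sequencing experiment —
one control library and one perturbation library, no replicates. This
vignette documents the statistical models, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely
open.

## 1. Cleaning and tag model

Reads are insert + 3' adapter concatenations. The adapter is located
by the first full occurrence, or otherwise by the longest exact
overlap (≥ 6 nt) between the read's 3' end and the adapter's 5' end.
Matching is exact — no mismatch tolerance — which keeps the cleaning
step deterministic and testable; sequencing-error modelling is out of
scope. Reads with mean Phred quality below 20 (configurable;
small-RNA protocols rarely publish their exact cutoff) are discarded
as low-quality, empty inserts are adaptor dimers, and inserts outside
18–30 nt are dropped. The four discard classes partition the input
exactly, an invariant the tests assert on every simulated library.

Cleaned reads collapse into unique **tags** (distinct sequences) with
counts; "unique" statistics count sequences, "total" statistics are
count-weighted. Internally all sequences live in the DNA alphabet
(U→T) so one canonical form is hashed; reports use RNA.

Library overlap percentages need denominators the field never
standardised: here *unique* percentages are relative to the union of
tag sequences and *total* percentages to the grand sum of counts over
both libraries, so common + specific = 100% on each scale.

## 2. Priority-rule annotation

Each tag receives exactly one category by the fixed precedence:
rRNA-class ncRNA (within the block, a GenBank-sourced reference beats
an Rfam one, then rRNA > scRNA > snRNA > snoRNA > tRNA) > known miRNA
> repeat > exon > intron > unannotated. ncRNA and miRNA assignment is
exact substring matching against reference sequences; repeat/exon/
intron assignment overlays genome hits on annotated intervals, with
sense/antisense decided by strand agreement (sense wins if any
same-strand overlap exists). Category resolution is per-tag — one tag,
one category — while the chromosome-distribution report deliberately
counts every hit of a multi-mapped tag; the two summaries therefore
answer different questions and need not add up to each other.

A library passes rRNA QC iff its total-count rRNA fraction is
*strictly* below 0.40.

Known-miRNA quantification: a tag counts toward a mature miRNA when it
equals the mature sequence or lies inside the precursor overlapping
the mature span by ≥ 16 nt (configurable). Tags confined to the loop
or star region count toward the precursor only. This deliberately
ignores isomiR sub-classification.

## 3. Differential expression

Counts are normalised to TPM = count / total clean tags × 10⁶. With
one library per condition no dispersion can be estimated, so the test
is the exact conditional binomial (Audic–Claverie in spirit): given
the combined count `n = x + y`, under the null of equal relative
abundance `y ~ Binomial(n, N₂/(N₁+N₂))`. Two-sidedness uses the
minimum-likelihood rule — sum the probabilities of all outcomes no
more likely than the observed one (with a 1 + 10⁻⁹ relative tolerance
against floating-point ties) — which is well defined for asymmetric
binomials and reproducible. The test is computed on raw counts with
library-size conditioning, not on normalised values; replicate-aware
models are an explicit non-goal.

P-values are Benjamini–Hochberg adjusted. Fold change is
`log₂(TPM₂′/TPM₁′)` with zeros floored at 0.01 TPM first — published
tables print large finite fold changes for miRNAs absent from one
library, which implies some floor; the value is configurable. A miRNA
is *up* iff log₂FC ≥ log₂(min_fold) (boundary inclusive; a printed
log₂FC of exactly 1.00 counts as two-fold) and adjusted P < α.
Defaults: min_fold 2; α = 0.01 for known miRNAs and α = 0.05 for novel
candidates, both exposed because published thresholds differ between
figure captions and text.

## 4. Hairpin folding and novel miRNA calling

The folding engine is a Zuker-style dynamic program over a simplified
nearest-neighbour model: Watson–Crick plus G:U pairs; a 6×6 stacking
table (all entries ≤ 0); linear penalties `hairpin(L) = 3.0 + 0.3L`
(L ≥ 3), `bulge(b) = 3.2 + 0.3b`, `internal(u) = 2.0 + 0.3u`, and
multibranch loops `3.4 + 0.4·branches + 0.3·unpaired` kcal/mol;
interior loops are bounded at 30 unpaired nt. The parameter set ships
as data (`inst/extdata/stack_energies.tsv`, `loop_params.tsv`) so it
can be audited or replaced; its defining property — enforced by test —
is that the DP exactly matches brute-force enumeration of all
structures under the same tables. Energies are handled as integer
tenths of kcal/mol with the pair count packed into the low bits of the
DP key, so (energy, fewest pairs) is minimised exactly and
deterministically on every platform; remaining ties resolve by a fixed
traceback order rather than dot-bracket lexicographic order (a
documented simplification — the oracle pins energy and pair count).

Novel miRNA calling excises ±70 nt windows (a typical hairpin-caller
flank; configurable) around each genome hit of an unannotated tag,
reverse-complementing minus-strand windows, and applies three gates:

* **mfe_pass** — window MFE strictly below −20 kcal/mol;
* **arm_pass** — the "Dicer cleavage site" criterion, operationalised
  (no numeric definition exists in the source literature) as: no tag
  base inside a terminal hairpin loop, partners of the tag's paired
  bases all on one side (one arm), and ≥ 75% of tag bases paired;
* **expression_pass** — tag TPM ≥ 1 in *both* libraries.

Overlapping passing windows on the same chromosome collapse to the
lowest-MFE one regardless of strand, because a hairpin and its reverse
complement describe one physical locus — each planted hairpin is found
both via its mature tag and via the tag's minus-strand match on the
star arm. Candidates are reported both tag-level and locus-collapsed,
since published novel-miRNA tables sometimes list near-identical tags
as distinct entries.

## 5. Targets and enrichment

Target prediction is intermolecular-only duplex hybridisation (no
target secondary structure), sharing the stacking table with the
folding engine: antiparallel pairing, stacks between consecutive
pairs, bulge/interior penalties for gaps bounded at 15 nt per side,
free helix ends, global minimum over all target positions. Scanning is
restricted to supplied 3'UTR sequences by default. Significance uses
an extreme-value form: `s = −E / log₁₀(m·n)`,
`p = 1 − exp(−exp(−(s − 1.9·log₁₀ n)/(0.28·log₁₀ n)))`. The slopes are
the published tool flags; the functional form is this package's
reconstruction, and base-10 logarithms are a deliberate choice — under
natural logarithms those slopes put the EVD location near 10 while no
attainable duplex energy normalises past ~6, leaving nothing
significant. Under log₁₀, perfect complementary sites score
p ≪ 0.05 and random sites hover around 0.05–0.5. The whole p-value
layer can be bypassed with an energy threshold (`max_energy`).

Per gene, each (miRNA, gene) pair counts once; a gene is kept when
strictly more than `min_mirnas` (default 3) up- or down-regulated
miRNAs target it. Enrichment is the upper-tail hypergeometric test
with Bonferroni correction over tested terms; the universe defaults to
all genes in the term map (published analyses rarely state their
universe — this default is documented, not asserted as anyone's
choice). GO-graph propagation and live database retrieval are
non-goals.

## 6. The synthetic world

`sim_config()` fixes the stated world: a 100 kb two-chromosome random
genome (≥ 10× the ~7 kb of planted features); 50 known miRNA hairpins
(mature 21–23 nt, 70% starting with U, perfect-complement star, 10–14
nt loop); 8 GC-biased novel hairpins verified at generation time to
fold below −20 kcal/mol under the package's own model; 10 ncRNAs with
alternating GenBank/Rfam source labels; 14 repeat/exon/intron
intervals; 60 3'UTRs, half carrying planted perfect-complement miRNA
sites; and two libraries of 10⁵ raw reads with 2% adaptor dimers and
2% low-quality reads. Insert lengths follow a discrete 18–30 nt
distribution peaked at 22 nt. Ten miRNAs are planted differentially
expressed at |log₂FC| = 2 with random sign; each DE miRNA is expected
at 100 TPM in its *lower* library with the 4-fold factor applied
upward in the other, so up- and down-regulation are equally
detectable. Non-DE expected proportions are identical across
libraries, and the DE surplus is absorbed by the `random` category so
nulls carry no systematic fold change. Each library draws from its own
RNG stream derived from the master seed; a fixed config is
byte-identical across runs.

The generator emulates the *statistical* structure the analysis
assumes — multinomial category sampling, exact planted fold changes,
adapter/dimer/low-quality contamination, antisense background reads —
and deliberately not sequencing errors, isomiRs, UMIs, paired ends or
real reference databases. A green end-to-end test therefore
establishes that the pipeline recovers planted truth under its own
assumptions, not that it reproduces any published read-level numbers:
the original raw libraries were never deposited, so published tag
totals and per-miRNA fold changes are unreproducible in principle.
What *is* replayed exactly are published DE tables through the
classification rules (26/21 known at α = 0.01, 17/9 beyond four-fold,
8/9 novel at α = 0.05), shipped as plain-text fixtures.

## 7. Numerical choices and degenerate inputs

* Folding: integer decikcal arithmetic — no floating-point
  accumulation; minimum hairpin loop 3; sequences 10–300 nt; all-dot
  structure (MFE 0) when no pair is possible.
* Exact test: errors on `x = y = 0` (untestable); `de_test()` drops
  such rows.
* Fold change: errors when both TPMs are zero.
* Duplex: a scan with no stabilising stack returns a no-hit (energy 0)
  rather than an error; poly-A vs poly-A is the canonical case.
* Enrichment: `k = 0` terms report p = 1; a query gene outside the
  universe is an error naming the offenders.
* Packing: a genome shorter than 10× the planted feature length fails
  explicitly rather than silently truncating.

## 8. Known limitations

Single-library-per-condition testing cannot separate biological from
technical variation; the exact test's p-values are conservative for
overdispersed data. The energy model is a teaching-grade
nearest-neighbour set, adequate for ranking hairpins and duplexes but
not for quantitative thermodynamics (no dangling ends, coaxial
stacking, or sequence-dependent loop terms). The EVD significance
layer is a calibrated reconstruction, not a refit. Genome mapping is
exact-match by default (mismatch budget ≤ 2 available but slow);
SOAP2-style gapped, quality-aware alignment is out of scope.
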