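---
title: "ribostress: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribostress: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostress)
```

This vignette is the package's own account of the statistics it
implements: the models, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely
open.

## The scientific problem

Structural ribosomal protein genes (RPGs) are coordinately down-regulated
in brain tissue under chronic stress (mouse) and in major depressive
disorder (human), while ribosomal protein (RP) pseudogenes — processed
genomic copies with very high sequence identity to their parent mRNAs —
move in the opposite direction. Because a pseudogene transcript can
repress its parent through RNA interference or de-repress it by
sequestering shared miRNAs (the ceRNA route), the anti-correlated pair is
biologically meaningful, and measuring it requires (i) reads attributed
unambiguously to parent vs pseudogene and (ii) a downstream chain of
enrichment and co-expression statistics. `ribostress` implements that
chain at desk scale, with a synthetic-data module that plants every effect
the chain is supposed to detect.

## Read assignment on a composite reference

**Model.** The reference is "composite": genomic-style contigs plus the
spliced parent mRNAs as standalone loci. A read is assigned by *exact
full-length matching* — no mismatches, both strands. The decision rule is
a function of the number of distinct loci containing the read:

| distinct loci | status |
|---|---|
| 1 | `unique`, counted for that locus |
| ≥ 2 | `discarded_multilocus` |
| 0 | `unmapped` |

Multiple occurrences *within* one locus count once: the discard rule is
about loci, not offsets (an open point in the protocol description; we
chose distinct-loci semantics and document it here). A read can therefore
be credited to a pseudogene only if it covers at least one base where the
pseudogene diverges from its parent; in the zero-divergence limit every
parent/pseudogene read is discarded, which the test suite asserts
exactly.

**Assumptions.** Reads are error-free and full-length substrings of some
locus. This is not a simplification of convenience: under a no-mismatch
mapping contract a sequencing error can only move a read from `unique` or
`discarded` to `unmapped`, so error-free simulation keeps the assignment
contract sharp while exercising every decision branch. Gapped alignment,
quality awareness and genome-scale indexing are out of scope — the
matcher is the desk-scale embodiment of the protocol, not an aligner.

**Implementation.** Exact matching uses Biostrings dictionary matching
(`PDict`/`whichPDict`) per locus and strand; the test suite checks it
read-by-read against a naive plain-string scan of every locus on both
strands (10 references × 10,000 reads), a deliberately independent code
path.

## Synthetic data: the stated world

`simulateCounts()` draws gene × sample counts from a negative binomial
with mean

$$\mu_{gs} = \beta_g \cdot \frac{L_s}{10^6} \cdot
  2^{\,\delta_g x_s + \sum_m \lambda_{gm} z_{ms} + \sum_c \gamma_{gc} w_{cs}}$$

and variance $\mu + \phi\mu^2$, where $\beta_g$ is a log-normal base mean
(default meanlog $\log 80$, sdlog 1.1 — a plausible bulk RNA-seq
abundance spread), $L_s$ a log-uniform library size (default 0.5–2
million, so normalisation is genuinely exercised), $\delta_g$ the planted
log2 fold change applied to stress samples ($x_s \in \{0,1\}$),
$z_{ms}$ per-module Gaussian latent factors with loadings
$\lambda_{gm} = \pm 0.8$ on seeds and members, and $w_{cs}$ standard-normal
nuisance covariates with gene-level coefficients
$\gamma_{gc} \sim N(0, \sigma_c)$ (defaults: "age" 0.3, "rin" 0.2 on the
log2 scale). At $\phi = 0$ the generator degenerates to Poisson, which
the tests verify through the variance/mean ratio.

Defaults encode the demonstration world: two species × two sexes × two
groups with 20 samples per (sex, group) cell; 1,200 genes per species
including an 80-member RPG family (48 large-subunit, 32 small-subunit);
15 RPGs planted at log2FC −1 in both species; a 10-gene RP pseudogene
block planted at +1 and loaded at −0.8 on the same latent factor as the
seed RPGs (the anti-correlation mechanism); and a 30-gene synapse block
loaded at +0.8. Dispersion is $\phi = 0.1$, a typical bulk-tissue value.
The planted magnitude of ±1 is a configurable default, not a calibration
to any particular data set — the source studies do not state empirical
RPG effect sizes.

**One deliberate deviation from the simplest latent-factor mechanism:**
each factor is standardised within every (sex, group) cell. An uncentred
factor shared by 15 seed genes carries a finite-sample group-mean
imbalance of sd $0.8\sqrt{2/n}$ that aliases with the planted contrast
and, roughly one run in three, erases the family's BH significance. On
real data this kind of latent variation is precisely what surrogate
variable analysis absorbs; since SVA is intentionally out of scope, the
generator encodes the equivalent assumption — module co-expression is
orthogonal to the group contrast — directly. Within-cell standardisation
leaves within-stratum correlation structure (what the seeded network
measures) untouched.

**What the generator does not emulate:** isoforms, GC and length bias,
sequencing error, batch structure beyond the declared covariates,
single-cell sparsity, and realistic pseudogene counts ("about 2,000" at
genome scale; the toy world plants 10). A green end-to-end test therefore
establishes that the chain detects planted effects of realistic size
under NB noise — not that it would survive every artefact of real tissue
data.

## Differential expression

The DE stage is a documented stand-in for a count-model fit, because the
package's contribution is downstream of DE and every stage reads plain
TSV — externally computed tables (e.g. DESeq2 on real data) can be
dropped in via `readDETable()`. The internal chain is:

1. **Low-count filter** (`filterLowCounts`): genes with mean count ≤ 5
   across all samples are removed. The source protocol's phrase "mean row
   sum ≤ 5" is self-contradictory (a mean and a row sum differ by a
   factor of the sample count); both readings are implemented behind
   `stat = c("mean", "sum")` with *mean* as the default, the reading
   under which the stated threshold is scale-free in the number of
   samples.
2. **log2-CPM** (`normalizeLogCPM`): $\log_2(10^6 c/L + 1)$, library
   sizes computed after filtering; the pseudocount of 1 maps zero counts
   to zero.
3. **Covariate residualisation** (`covariateAdjust`): OLS residuals on
   an intercept plus the declared covariates (never the group label).
   This replaces surrogate-variable estimation with user-supplied
   covariates; rank-deficient designs fail loudly with the collinear
   columns named.
4. **Welch t per gene** (`deTest`), log2FC = case mean − control mean,
   two-sided p. Zero-variance degenerate genes get the smallest
   representable double (difference present) or 1 (no difference), with a
   warning — a NaN would silently poison BH.
5. **BH correction** (`bhAdjust`, wrapping `stats::p.adjust`) and
   **threshold selection** (`selectSignificant`): raw *P* < 0.05 for
   MDD-style contrasts, BH *q* < 0.05 for chronic-stress contrasts —
   the two rules the source analyses used, both exposed as modes.

The demo pools sexes within a species for the DE contrast (with sex as a
covariate) and keeps the fully factorial split for the network stage,
where sex-specific coordination is the question of interest; whether the
original figure columns pooled sexes is not stated, so strata are fully
factorial by default.

## Family and GO enrichment

Over-representation is the hypergeometric upper tail
$p = P[X \ge k]$, $X \sim \mathrm{Hypergeometric}(N, K, n)$, identical to
one-sided Fisher's exact test; the suite verifies both identities (exact
enumeration for all $N \le 12$, and `fisher.test` agreement). Only
over-representation is computed, matching the enrichment tool the
analysis mirrors. The default universe is 21,196 genes (that tool's
genomic background); synthetic runs override it with the simulated
universe size, and the GO universe defaults to the annotated genes of the
fixture. BH is applied across the families (or terms) tested in one
call. Scores are reported as $-\log_{10} q$, capped (default 10) for
display.

Cross-species harmonisation applies an explicit 1:1 ortholog map first
(many-to-many rows are rejected), then the mouse-title-case ↔
human-upper-case convention; the original harmonisation rule is not
described, so the case convention is this package's choice, with the map
as the escape hatch. Pseudogene suffixes (`-ps\d*` mouse, `AS\d*` human)
strip to the parent symbol; because genuine human symbols can end in
"AS", stripping can be gated on an explicit pseudogene list when one is
available, falling back to pattern-only mode otherwise.

## Seeded co-expression networks

Each seed RPG is correlated (tie-corrected Spearman) against every other
gene within a (species × sex × group) stratum; genes with raw
*P* < 0.05 are split by sign. No multiple-testing correction is applied
at this stage — the thresholded lists feed FDR-corrected enrichment, so
correcting twice would be conservative and unfaithful to the original
rule. Strata with fewer than 4 samples are skipped with a message.

Two p-value routes exist deliberately. The pairwise operation
`spearmanTest()` delegates to `stats::cor.test()`, which uses the exact
null distribution for small tie-free samples — the acceptance suite shows
it matches a full-permutation enumeration to machine precision for
n ≤ 8. The vectorised network stage uses the asymptotic
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation for speed; at the default
stratum size (n = 20) the approximation's error is far below the 0.05
decision threshold's granularity, and the null false-positive rate per
seed is verified to sit at 0.05 ± 0.02. A t-approximation *everywhere*
would be simpler but demonstrably cannot reproduce exact small-n
p-values (error up to 0.15 at n = 4), which is why the exact route is
kept for the pairwise operation.

## Themes and the signed matrix

GO annotations propagate upward (a gene annotated to a term is annotated
to all `is_a` ancestors; construction rejects cyclic edge sets via
topological sort). A theme matches a term through either route: a
case-insensitive keyword substring of the term name (tokenising would be
stricter than a plain "text query", so substring it is), or descent from
an anchor term — the anchor itself included, since a theme should label
its own anchor. All matching themes are recorded; when the two routes
disagree there is no documented priority, so no priority is invented. A
term matching nothing is labelled `unclassified`, keeping assignment
total.

For each (stratum, sign) the per-seed correlate lists are pooled for the
stratum-level enrichment, while each seed's own list is tested separately
to produce `contributing_seeds` — the number of seeds whose list yields
*q* < 0.05 for the term. Terms significant in the pooled list but
supported by zero individual seeds are dropped: the displayed
matrices attach a per-seed count to every pathway, and a row with count 0
would be unreportable. The signed matrix encodes negative-list
enrichments as negative $-\log_{10} q$ entries, mirroring the
two-colour condition × pathway figures; `pathwayOverlap()` then
intersects the q-filtered term sets of, e.g., down-regulated RPGs and
suffix-stripped up-regulated pseudogenes, preserving each side's
enrichment strength.

## Numerical and degenerate-input policy

* Hypergeometric p via `phyper(k-1, K, N-K, n, lower.tail = FALSE)`;
  exact for all relevant sizes.
* BH via `stats::p.adjust`; inputs outside [0, 1] or NA are errors, not
  silently dropped.
* q = 0 is capped at the display cap with a warning rather than mapped to
  infinity.
* Constant expression vectors make a correlation undefined: the pairwise
  test errors, and the network stage drops constant genes (reporting
  dropped seeds) rather than emitting NaNs.
* All generators take an explicit seed and restore the caller's RNG
  state, so every output is a pure function of (parameters, seed);
  repeated pipeline runs with one seed are byte-identical, which the
  acceptance suite checks with file checksums.

## Known limitations

* The Welch stand-in has less power than a shrinkage-based count model at
  small n and makes a normality-after-log approximation; for real data,
  import DESeq2 tables.
* Exact full-length matching is O(reads × loci) and intended for
  references up to tens of kilobases — it is a contract-faithful model of
  the alignment protocol, not a production aligner.
* The OBO reader parses only `id`, `name`, `namespace` and `is_a`;
  relationship types, obsolescence and cross-references are ignored.
* Pattern-only suffix stripping can collide with genuine symbols (e.g.
  "GAS5"); supply a pseudogene list where one exists.
* The toy GO fixture has 13 terms; theme clustering behaviour on a full
  ontology (thousands of terms, deep diamonds) is exercised only in
  shape, not in scale.
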