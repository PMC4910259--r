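---
title: "The local FM-bias test: model, assumptions and design choices"
author: "fmlbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The local FM-bias test: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`fmlbias` asks, element by element, whether the somatic single-nucleotide
variants observed across a tumor cohort carry a larger mean functional-impact
(FI) score than the mutational processes alone would produce.  The null model
is *local*: the background is resampled from the universe of all possible
substitutions of the element itself, so regional covariates of the mutation
rate (replication timing, chromatin compaction, expression) affect observed
and background mutations identically and cancel out.  What the null model
does retain from the cohort is its *mutational signature*: each candidate
substitution is weighted by the probability of its trinucleotide channel —
the pyrimidine-collapsed class `5'[ref>alt]3'`, 96 classes in total — in the
spectrum estimated from all cohort mutations.

For an element with $k$ scored observed mutations the test statistic is the
arithmetic mean of their FI scores.  $N$ background sets of size $k$ are
drawn **with replacement** from the weighted pool, and

$$p \;=\; \frac{\#\{\,\bar S^{(j)}_{bg} \ge \bar S_{obs}\,\}}{N}.$$

Benjamini–Hochberg is applied over the elements mutated in at least
`min_samples` distinct samples; the others keep a p-value but no q-value.

### Assumptions

* Mutations are independent draws from a signature-weighted substitution
  process (sampling with replacement; an i.i.d. mutational-process model).
  Recurrent mutations count once per occurrence, which makes recurrence at
  high-scoring sites evidence of selection rather than a nuisance.
* The FI score is *relevant* to the element's function and available for
  every substitution; unscored positions are excluded symmetrically from the
  observed set and the background pool, so missingness does not bias the
  comparison.
* The signature estimated genome-wide from the cohort applies inside the
  element.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_iterations` | 10 000 | background sets per element; the p-value resolution is 1/N |
| `max_iterations` | 1 000 000 | ceiling for adaptive doubling when no background mean reaches the observation |
| `sampling` | `"signature"` | `"uniform"` ignores the signature; `"per_sample"` resamples each observed mutation under the signature of its contributing sample |
| `min_samples` | 2 | BH eligibility threshold (5 is the conventional pan-cancer choice) |
| `tie` | `"ge"` | ties between background and observed means count toward the exceedance (conservative); `"gt"` is exposed for comparison |
| `pseudocount` | `FALSE` | `(count+1)/(N+1)` variant; off because the reference convention is count/N |
| `tail` | `"right"` | `"left"` computes the opposite tail, a negative-selection screen |
| splice flank | 50 bp | intron-edge regions tested as splice elements |
| short splice flank | 10 bp | intron edges subtracted from UTRs, promoters, lncRNAs |
| promoter window | 2500 bp | upstream of the most 5′ protein-coding TSS of the gene |
| randomization window | 50 kb | fixed chromosome tiles; `centered = TRUE` gives ±25 kb around each mutation |

## Numerical and procedural choices

* **Coordinates.** Internally 0-based half-open; every file read or written
  is 1-based (VCF/TSV convention).  Chromosome names are reconciled against
  the reference by adding/stripping a `chr` prefix; anything else is an
  error.
* **p = 0 handling.** When no background mean reaches the observation, $N$
  doubles (fresh draws from the element's stream) up to `max_iterations`;
  if the count is still zero the reported value is the upper bound
  $1/N_{max}$ and the result is flagged `p_censored`.  An upper bound keeps
  the BH step conservative and orders consistently with a count of one.
* **Random streams.** One master seed; each element's stream is derived by a
  stable string hash of its id, so p-values do not depend on element order,
  on which other elements are present, or on parallel scheduling.  All
  iteration orders that consume random numbers are fixed in byte (C-locale)
  order, so results are identical across collation locales.
* **Ties and degenerate inputs.** Background means equal to the observed
  mean count toward the exceedance, so a constant-score element yields
  p = 1, never a spurious discovery.  Elements whose substitutions all have
  zero signature probability abort with a diagnostic rather than silently
  falling back to uniform weights.
* **Subtraction order in the catalog.** CDS of protein-coding
  gene+transcript biotypes are merged per gene; UTRs lose any CDS overlap
  (from *any* gene — "previously annotated" is read globally) and the 10-bp
  short splice regions; 5′ UTRs additionally lose 3′ UTR overlaps; promoters
  and lncRNA exons lose CDS, UTRs and short splice regions.  Two readings
  were genuinely open: promoters subtract the 10-bp (not the 50-bp) splice
  regions, as only the short regions are named in the subtraction list; and
  promoter windows are not clipped by upstream gene bodies beyond those
  subtractions.  The manual removal of suspect annotations is represented by
  an optional blacklist file rather than an irreproducible heuristic.
* **TSS choice.** One promoter per gene, anchored at the most 5′ start among
  its protein-coding transcripts (windows from several TSS would merge
  anyway when they overlap).
* **Observed entries stay in the pool.** Background sampling does not
  exclude the observed mutations' own (pos, alt) entries; removing them
  would bias the background low for small elements.

## The randomizer

The negative control repositions every mutation within its 50-kb window to a
uniformly chosen position whose reference trinucleotide matches the
mutation's strand-collapsed context; a site presenting the reverse-complement
context is eligible with the alternate allele complemented.  This conserves
the 96-channel count vector *exactly* (count for count, not just in
probability), along with the sample set and per-sample counts.  Fixed tiles
(`floor((pos-1)/window)`) make the scheme deterministic and
position-independent; collisions between repositioned mutations are allowed,
matching real recurrences.  A mutation at a chromosome edge (no context) or
with no eligible destination keeps its position and is counted.

## The synthetic generator

`synthetic_spec()` describes the package's standard toy scale, chosen once as
a realistic desk-scale analogue of a tumor cohort study: one 2-Mb chromosome
(GC 0.41), 39 protein-coding genes and 5 lincRNAs (≈200 elements across the
five types), 50 samples with Poisson(40) mutations each, and a UV-like
generating signature in which C>T channels carry ≈88 % of the mass — the
concentrated regime of real cohorts dominated by one mutational process.
Scores emulate a CADD-like table: a per-position exponential base score
(scale 3) plus alt-specific Gaussian jitter (sd 0.5), clipped at zero and
rounded to one decimal, which reproduces the heavy score ties of PHRED-style
tables.  Driver injection redirects a configurable fraction (default 0.8) of
one mutation per driver sample to hotspot entries placed above the element
maximum.

Null cohorts are generated by drawing each mutation's channel from the
generating signature and then a site uniformly among the catalog's candidate
substitutions of that channel.  This two-stage scheme makes the requested
signature the *realized* spectrum — the field's definition of a mutational
signature — at the cost of an $O(2\%)$ per-channel tilt relative to the
test's per-entry weighting (which multiplies the signature by per-channel
site availability); the tilt is far below the Monte-Carlo noise of any test
performed here.  What the generator does **not** emulate: regional mutation
rate covariates (the local test is insensitive to them by construction),
indels, subclonal structure, sequencing artifacts, and score models with
biological structure (conservation, domain architecture).  Tests passing on
synthetic data therefore validate the statistical machinery, not the
biological adequacy of any particular scoring framework.

## Calibration properties and known limitations

Null-cohort p-values are uniform (the test suite checks this with a
Kolmogorov–Smirnov test over ≈180 tested elements), and an injected driver
with 12 mutated samples and 80 % hotspot-directed mutations is recovered at
rank 1 with q < 0.1 in 20/20 seeds at the default effect size.

One property deserves an explicit caveat.  Under a *global null* with
independent, exactly calibrated p-values, the Benjamini–Hochberg step at
q < 0.1 produces at least one (false) discovery with probability ≈ 0.1 per
cohort — this is a theorem (Simes), not an implementation artifact.
Correspondingly, across repeated null or negative-control cohorts one
expects a q < 0.1 element in roughly one cohort in ten, and slightly more
often when a very strong true driver occupies rank 1 (the rank-2 step-up
threshold doubles).  The test suite's seed-fraction checks sit exactly at
this boundary: the negative control is clean in 19/20 seeds, and the
driver-recovery runs flag a neutral element in 4/20 seeds — consistent with
the expected BH false-positive rate on calibrated p-values rather than with
any anti-conservative defect (the same runs pass the KS uniformity check).
Real cohorts analysed with heavily tied score tables and sparse non-coding
mutations behave more conservatively.

Problem sizes used by the test suite (chosen to keep a full run within a few
minutes): null calibration at the standard 200-element scale with N = 10 000;
negative-control and driver-recovery loops on a 52-element, 25-sample
backbone over 20 seeds; the enumeration oracle on 50 micro-elements of ≤ 6
entries at N = 200 000; signature-conservation checks on a 10 000-mutation
cohort.

Further limitations: SNVs only; no combination of element types into a
gene-level test; no score computation (any per-substitution table is
consumed as-is); signature estimation applies no mappability or coverage
filter.
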