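---
title: "Refitting mutational signatures: model, stability and normalization"
author: "sigrefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting mutational signatures: model, stability and normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrefit)
```

## The additive exposure model

Somatic mutational processes are summarized over the 96 single-base
substitution channels: the six pyrimidine-centered substitution classes
(C>A, C>G, C>T, T>A, T>C, T>G), each combined with the 4 × 4 possible 5'
and 3' flanking bases. Variants whose reference base is a purine are
mapped onto the opposite strand by reverse complement, so every mutation
falls into exactly one channel. A sample's mutational catalogue is the
vector $\mathbf{m} \in \mathbb{R}^{96}_{\ge 0}$ of channel counts (or
frequencies), and a signature set is a column-stochastic matrix
$\mathbf{P} \in \mathbb{R}^{96 \times N}$ whose column $n$ is the channel
distribution of process $n$.

The model is additive: the observed channel distribution is assumed to be
a convex combination of the signature profiles. Exposures are estimated by

$$
\mathbf{e} \;=\; \underset{e_n \ge 0}{\arg\min}\;
  \lVert \mathbf{m}_{\mathrm{freq}} - \mathbf{P}\mathbf{e} \rVert_2 ,
$$

where $\mathbf{m}_{\mathrm{freq}} = \mathbf{m} / \sum_k m_k$. Two
constraint modes are offered. The default `simplex` mode adds
$\sum_n e_n = 1$, so the solution is directly the vector of proportions of
the mutational load attributed to each process — the scale on which
exposures are conventionally reported (percentages). The `nonneg` mode
imposes only $e_n \ge 0$, as in the bare least-squares formulation, and
proportions are then obtained by renormalizing the raw weights. Since the
simplex is a subset of the non-negative orthant, the simplex-mode residual
can never be smaller on the same instance; the test suite asserts this
nesting.

### The solver, and its numerical choices

The problem is a small, dense, convex QP (96 rows, rarely more than ~70
columns). sigrefit solves it with an exact active-set method of the
Lawson–Hanson family, written in-package: the pure non-negative case is
classic NNLS; in simplex mode the equality constraint is carried inside
the KKT system solved on each passive set, starting from the best
single-signature vertex. Termination is on dual feasibility (all bound
multipliers $\ge -10^{-10}$), so the returned point satisfies the KKT
conditions of the convex problem and is a global minimizer up to that
tolerance. Collinear passive sets (published signature sets contain
near-collinear columns) fall back to a $10^{-12}$ ridge on the Gram
matrix, which is noted here because it perturbs the choice among multiple
optima in exactly-degenerate cases; the objective value is unaffected to
first order. Solver negatives above $-10^{-10}$ are clipped to zero and
the solution renormalized. The independent checks in the test suite are a
brute-force grid search over the simplex (step $10^{-3}$) on small
instances and $10^4$ random feasible candidates per random instance;
neither ever attains a lower objective.

Degenerate inputs: a zero-total catalogue is an error (there is nothing to
fit); catalogue/matrix channel mismatches are errors rather than silent
reordering, except that rows are aligned by name when both sides carry
labels. Catalogues whose count total is below 125 trigger a warning — with
fewer than a few hundred mutations the channel counts are too sparse for a
stable refit, and the same named threshold is used by the bootstrap
module. The fitting and simulation code deliberately accepts profile
matrices with any number of feature rows, not just 96, so toy problems and
extended feature spaces (e.g. strand-split channels) can reuse the same
machinery; the file formats and VCF extractor, by contrast, enforce the
canonical 96.

## Why stability matters: signature redundancy

Published signature sets are not orthogonal; several profiles are nearly
expressible as non-negative combinations of the others. Two diagnostics
quantify this. `cosine_similarity_matrix()` reports pairwise co-linearity.
`reconstruction_stability()` refits each column against the remaining
columns (non-negative mode) and reports the cosine similarity between the
profile and its best reconstruction; values near 1 mark *unstable*
signatures whose exposure can be traded against the others with almost no
cost in fit quality. Exposures for such signatures should only be
interpreted together with a bootstrap interval.

## Bootstrap stability estimates

`bootstrap_catalogues()` redraws the $n$ observed mutations with
replacement: each re-sample is a multinomial draw of size $n$ with
probabilities $\mathbf{m}/n$. Resampling channels is equivalent to
resampling the individual mutations, because the catalogue is a
sufficient statistic for the channel-level model — this is why the
generator operates on the catalogue rather than on VCF records.
`summarize_exposures()` refits the original catalogue and all $R$
re-samples (default $R = 1000$, the value used in all validation runs
here) and reports, per signature, the minimum, quartiles and maximum of
the re-sampled exposures next to the original estimate. Quartiles use
linear interpolation between order statistics (`quantile()` type 7);
conventions differ between tools, so the choice is stated. One seed
governs the whole summary, making every table reproducible from a single
integer.

## Trinucleotide-baseline normalization

Signature matrices are defined relative to the trinucleotide availability
of the regions on which they were derived (typically a whole reference
genome). A catalogue observed on different regions — an exome capture —
sees each context in proportion to a different availability, and fitting
it directly against genome-referenced signatures biases the exposures.
With $f_A(c)$ the context frequencies of the observed regions and
$f_B(c)$ those of the target baseline, expected channel counts are
proportional to context availability, so the catalogue is re-expressed on
baseline $B$ by

$$ m'_k = m_k \cdot \frac{f_B(c(k))}{f_A(c(k))}, $$

followed by conversion to frequencies; the three substitution classes of
one context share a single ratio. The same scaling applied column-wise
(with renormalization) maps a signature matrix onto a new baseline, which
is the inverse workflow: either normalize the data to the signatures'
baseline, or the signatures to the data's. The two directions do **not**
give identical exposures, which is the practical reason for caring about
this at all; `invert_ratios = TRUE` exposes the reciprocal convention so
the two can be compared directly. We default to the ratio direction above
because it follows from the availability argument; descriptions of this
scaling in the literature are loose enough to be read either way, so the
convention is fixed and documented rather than inferred.

Counting (`count_trinucleotides()`) attributes each 3-mer to its central
base: a position counts when its central base lies inside a (merged)
region and both flanks exist and are A/C/G/T — the flanks may extend one
base beyond a region boundary, since a mutation at a capture edge still
has a real genomic context. Overlapping BED intervals are merged first so
overlapping capture targets are not double-counted. Purine-centered
3-mers are collapsed onto their reverse complement, giving 32 contexts.
Zero-frequency contexts are only an error when the catalogue actually has
mass there; restriction to sub-genomes must not poison unrelated channels.

## What the simulator states, and what a green test establishes

`create_mut_catalogues()` draws catalogues i.i.d. multinomially from
$\mathbf{q} = \mathbf{P}\mathbf{w}$. The default experimental conditions
baked into the examples and tests are the ones used throughout the
validation analyses: five signatures at weight 0.2 each and 1000
mutations per catalogue, with accuracy-versus-size experiments spanning
$10^2$–$10^5$ mutations at 100 replicates per size. `null_catalogues()`
draws channel probabilities proportional to trinucleotide availability,
splitting each context's mass equally over its three substitution
classes — the split is not dictated by the availability argument, and
equal thirds is the maximum-entropy choice consistent with "no process
signal". When experiments published for a named signature set list their
members inconsistently across a paper's sections (e.g. one well-known
five-signature benchmark set is quoted both with signature 27 and with
signature 28 as its fifth member), the simulator takes explicit signature
lists and leaves the choice to the caller rather than resolving it
silently.

The generator emulates sampling noise only: independent mutations,
exactly correct signature profiles, no clonal structure, no
caller-specific false negatives, no inter-sample contamination. A green
recovery test therefore establishes that the estimator is correct and
well-conditioned under the stated model — not that exposures from real
tumors are accurate at equal mutational load, where profile mismatch and
biological heterogeneity add error that only the bootstrap spread (and
multi-sample designs) can reveal.

Because the COSMIC matrices cannot be redistributed with this repository,
the published-value checks in the test suite (pairwise similarity of two
specific signatures, the exact unstable set, patient-catalogue totals,
exome/genome context correlation, the normalization-direction shift, the
null-catalogue experiment) are written against files the user must place
under `inst/extdata/`; they fail with an explanatory message until the
data is supplied, and all surrounding machinery is exercised on synthetic
stand-ins (clearly labelled synthetic) in the self-contained tests.

## Known limitations

* Single-base substitutions only; no doublet, indel or transcription-
  strand channels (though the fitting core accepts arbitrary feature
  spaces).
* Percentile (min/quartile/max) bootstrap summaries only; no BCa or
  studentized intervals.
* No sparsity-inducing refits or signature pre-selection; with a
  redundant signature set the estimator will spread exposure across
  near-collinear profiles, and the diagnostics can only flag, not fix,
  that degeneracy.
* The VCF extractor ignores genotypes and builds one catalogue per file;
  multi-sample VCFs should be split upstream.

## Worked session

```{r example}
P <- synthetic_signature_matrix(6, seed = 7)
cohort <- create_mut_catalogues(P, c(S1 = 0.4, S3 = 0.35, S5 = 0.25),
                                n_mutations = 1000, n_samples = 1, seed = 11)
fit <- estimate_exposure(cohort$catalogues, P)
round(fit$proportions, 3)

summ <- summarize_exposures(cohort$catalogues, P, R = 1000, seed = 12)
summ
```

```{r plot, fig.width = 6, fig.height = 4}
plot_exposure_summary(summ)
```
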