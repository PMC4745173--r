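---
title: "Methods: translation-invariant wavelet spectral slopes for DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translation-invariant wavelet spectral slopes for DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveslope)
```

## The problem

Coding (exonic) and noncoding (intronic) stretches of eukaryotic DNA differ
in their statistical texture: introns tend to show stronger long-range
correlation — *regularity* — than exons. Classical ways of quantifying this
(DNA walks, binary indicator spectra) first map the four letters A, C, G, T
to numbers, and the resulting spectral measure depends on which mapping was
chosen: a purine/pyrimidine walk and a weak/strong-hydrogen-bond walk give
different slopes for the same sequence. `waveslope` implements a regularity
measure that removes this ambiguity.

## The model

### Encoding

A sequence of length $N$ becomes a $4 \times N$ binary matrix $Y$: under an
assignment order such as `ACGT`, the letter at position $i$ of the order is
coded as the unit vector $e_i$, and column $j$ of $Y$ is the unit vector of
residue $j$. Accumulating each row left to right gives $Y^*$, whose rows are
the running counts of the four letters — four monotone step functions whose
joint roughness carries the sequence's correlation structure.

### Transform and slope

$Y^*$ is transformed by the 2-D *scale-mixing* Haar transform

$$Z = W_r \, Y^* \, W_N',$$

where $W_r$ is the depth-2 Haar matrix on the 4 (or 16) rows and $W_N$ a
depth-2 Haar matrix on the columns. Rows of every wavelet matrix are ordered
coarsest-first (scaling rows, then detail levels down to the finest); this
ordering is load-bearing because the slope is defined on fixed submatrices of
$Z$. Two detail blocks form the spectral hierarchy: for the 4-row transform
$Z_1 = Z(2,\, N/4{+}1{:}N/2)$ and $Z_2 = Z(3{:}4,\, N/2{+}1{:}N)$. The
log-spectral slope is

$$s = \log \overline{Z_2^{\circ 2}} - \log \overline{Z_1^{\circ 2}},$$

the difference of log mean squared entries of the finest and next-coarser
detail blocks. $s < 0$ means energy decays toward fine scales (persistence,
regularity); $s \approx 0$ is what independent random letters produce;
$s > 0$ indicates anti-persistent zig-zagging. For a monofractal of Hurst
exponent $H$ and dimension $d$ the dyadic calibration is $s = -(2H + d)$ in
base-2 logs; the extreme case is a homopolymer window, whose cumulative row
is a perfect linear ramp ($H = 1$, $d = 1$) and whose slope is exactly
$-\log 8$ ($-3$ in base 2) — the most negative value a single-composition
window can attain, and a useful analytic anchor for tests.

### Equivalence classes and the invariant encoding

Permuting letters within the two pairs of an assignment order, or swapping
the pairs, leaves every slope unchanged, so the 24 orders collapse into
$4!/(2!\,2!\,2!) = 3$ classes, one per chemical pairing: amino/keto (AC|GT),
purine/pyrimidine (AG|CT), weak/strong hydrogen bonds (AT|CG). Stacking one
single-code encoding from each class yields a 12-row matrix, zero-padded to
16 rows for the dyadic machinery. The detail blocks of the 16-row transform
are $Z_1 = Z(5{:}7,\,N/4{+}1{:}N/2)$ and $Z_2 = Z(9{:}14,\,N/2{+}1{:}N)$;
rows 8, 15 and 16 touch only the padding rows and are excluded. Because each
class contributes symmetrically to these blocks, the resulting slope is
*identical* — not merely close — for every one of the $8^3$ representative
triples and every block order, which the test suite verifies exhaustively.
The zero value of the padding is fixed (not configurable): for the Haar
basis, constant rows are annihilated by every detail filter, so the padding
provably never leaks into the blocks that are read; this is asserted for
Haar only and is one reason no other wavelet family is offered.

### Windowed ("cumulative evolutionary") slopes

A window of $k$ nucleotides slides along the sequence in steps divisible
by 4, and each window's slope is computed with the accumulation restarted at
the window start. Restarting versus slicing the whole-sequence $Y^*$ is
provably immaterial: the two differ by per-row constants, which Haar detail
blocks annihilate, so either convention gives the same series (the suite
checks this to $10^{-8}$). The defaults, window $2^5 = 32$ and step
$2^3 = 8$, are chosen so that coding stretches as short as ~50 nt still
cover whole windows; smaller windows get noisy, larger ones lose locality.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window`, `step` | 32, 8 nt | locality/noise trade-off of the slope series; both divisible by 4 |
| `log_base` | `"e"` | scale of reported slopes; base 2 makes the $-(2H+d)$ calibration literal |
| `reps` | `ACGT, AGCT, ATCG` | representative triple; any choice gives the same slope (verified) |
| `mallat_threshold` | $2^{11}$ | above this width the column transform switches from the explicit matrix product to pyramidal filtering; the two paths agree to $10^{-8}$ relative and the switch only affects speed |
| `strict` | `FALSE` | non-ACGT residues make the window/sequence slope missing rather than raising |

Natural log is the default because the defining formula is stated with an
unqualified log and it keeps slope magnitudes on a convenient scale
(around $-1.7$ to $-1.8$ for insect-like gene composition); base 2 is available and
every output records its base. Global slopes truncate the sequence to its
leading $2^{\lfloor \log_2 N\rfloor}$ residues (the prefix, dropping the
tail), since the transform needs a power-of-2 width.

## Region scoring

Gene annotations (BED6 exon lines or GFF3 CDS features) define exons; the
within-gene complement defines introns. Minus-strand genes are reverse
complemented and their intervals remapped, so analysis always reads 5' to
3'. Every window is labeled `exon` (fully exonic), `intron` (fully
intronic), or `combination` (straddling a boundary) — the combination label
exists so boundary windows never contaminate either sample. Maximal runs of
one label form sections; a section's observation is the mean of its finite
window slopes, and a section containing an infinite slope (a zero-energy
finest block, e.g. from locally periodic sequence) is excluded from pooling
but counted, per gene, in two diagnostics: genes with any infinite-slope
section and genes whose infinite slopes are intron-only. Exclusion operates
on whole sections rather than single windows because a section is the unit
of observation; window-level retention would bias section means computed
from the surviving windows. Pooled exon and intron section means are then
compared with a pooled-variance two-sample t-test, and their separation is
summarized by the Youden-maximizing threshold $s^*$ with sensitivity,
specificity, accuracy and Matthews correlation.

Statistical observations are *section means*, not raw windows. Combination
sections are reported but never folded into the exon or intron samples.

## Resampling significance

Two nulls are provided for a single sequence's global slope. The
*multinomial bootstrap* draws iid sequences with the observed base
proportions (composition matched in expectation); the *permutation test*
shuffles the observed residues (composition matched exactly). Both report
the left-tail-inclusive fraction of null slopes at or below the observed
slope — inclusive tie handling is the conservative choice, and non-finite
null slopes stay in the denominator with a count reported. The observed
slope is computed through the identical code path as the replicates so that
ties are exact, not floating-point accidents. Given a seed, both procedures
are fully reproducible.

## Numerical choices

- $\sqrt{2}/2$ is computed, never a hard-coded decimal; orthogonality of
  every built wavelet matrix is tested to $10^{-10}$ and the transform
  conserves Frobenius energy to the same tolerance.
- Degenerate energies never raise: $Z_2$-energy zero gives $-\infty$,
  $Z_1$-energy zero gives $+\infty$, both zero gives a missing slope.
  Infinite slopes are retained in series (flagged), so downstream exclusion
  is explicit and countable.
- The Youden scan uses midpoints between consecutive distinct pooled values
  plus outer sentinels; ties break toward the smallest threshold. A
  brute-force scan over all data-driven thresholds guards this in tests.
- Kernel density summaries use a Gaussian kernel with Silverman's
  rule-of-thumb bandwidth on a 100-point grid covering exactly the data
  range; the kernel and bandwidth are free choices here, and both are
  recorded in the output.
- The pooled-variance Student t is the default two-sample test; Welch is
  available behind `var_equal = FALSE`.

## The synthetic generator

`synthetic_gene_set()` emulates a GC-poor insect-like gene set: 20 genes of
3–6 exons, exon lengths 50–400 nt (insect exons average roughly 240 nt), intron
lengths 500–3000 nt (insect introns run to kilobase scale), exon GC near 32 %
and intron GC near 25 % via the stationary probabilities. Introns are
persistent first-order Markov chains (transition $\rho I + (1-\rho)1p'$,
default $\rho = 0.9$) — the simplest mechanism that yields more negative
slopes than matched-composition iid exons. This is a modeling convenience:
real intron regularity has an unknown mechanism, and no claim is made that
introns are Markovian. Consequently, passing tests on these fixtures shows
that the pipeline *recovers a known regularity contrast end to end*; it does
not validate the biological magnitude of the exon/intron difference, splice
site motifs, codon structure, isoform complexity, or assembly artifacts of
real genomes, none of which the generator emulates.

Problem sizes used by the test suite — sequences of a few hundred to a few
thousand nucleotides, 20-gene fixtures, a few hundred resampling replicates
— are deliberately compact desk-scale choices; all statistics scale to
chromosome-size inputs through the same interfaces, with the Mallat path
taking over the column transform for long windows.

## Known limitations

- Only the Haar family is implemented; it is the natural basis for
  piecewise-constant cumulative rows and the only one for which the
  zero-padding guarantee holds.
- The slope uses exactly two spectral points, so no multi-level regression
  or confidence interval for a Hurst exponent is offered.
- CDS intervals are taken as the definition of exons; UTRs and alternative
  isoforms are not modeled.
- Windows extending past the last full position are discarded rather than
  shortened, so up to `window - 1` trailing nucleotides go unscored.
- Sequences shorter than 8 nt (global) or one window (series) are rejected.
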