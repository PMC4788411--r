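---
title: "Methods: codon-usage diagnostics, recoding, and reporter quantification"
author: "plastidReporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage diagnostics, recoding, and reporter quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidReporter)
```

This vignette is the package's own account of the statistics and
procedures it implements: the definitions, the assumptions behind them,
the parameters that matter, and the design decisions taken where more
than one reasonable convention exists. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# Codon-usage model

## The reference table

A `CodonUsageTable` holds, for a chosen genetic code (default NCBI
translation table 11, the plastid/bacterial code), the observation count
of each of the 64 triplets over a set of coding sequences, and the
*synonymous-relative frequency* of each triplet:

$$ f(c) = \frac{n(c)}{\sum_{c' \in \mathrm{fam}(c)} n(c')} $$

where `fam(c)` is the set of synonyms encoding the same amino acid
(Met and Trp are single-member families; the three stop triplets form
the stop family when `includeStops = TRUE`). Frequencies of an observed
family sum to exactly 1; families never observed are flagged and carry
frequency 0 for all members.

Assumptions: sequences are strictly in-frame multiples of 3 over
A/C/G/T. Input is upper-cased, but any other symbol (including IUPAC
ambiguity codes) is a hard error rather than being skipped — the
downstream statistics are count-exact, and silently dropping codons
would bias them.

## Diagnostics

* **GC3** — fraction of codons whose third base is G or C. The stop
  codon, when present, is one of the codons: per-gene arithmetic in the
  field is typically quoted over the full CDS length including the
  terminator, and counting it keeps the codon total of a CDS equal to
  length/3. `gc3()` also accepts a usage table, where it returns the
  count-weighted GC3 of the source CDS set — the natural "CDS-wide"
  genome value.
* **Optimal codon** — the most frequent triplet within its family.
  Ties at the family maximum are broken by lexicographic triplet order,
  deterministically, and the family is flagged in `tieFamilies` so the
  tie never passes silently. Consequently every observed family has
  exactly one optimal codon.
* **Rare codon** — synonymous-relative frequency ≤ 0.10, *inclusive*;
  a codon sitting exactly on the boundary is rare. Members of
  unobserved families are rare (frequency 0 — never seen in the
  reference is the strongest form of rarity). In the degenerate case of
  a family maximum at or below 0.10, optimal takes precedence and a
  warning flags the precedence decision.
* **Mean codon frequency difference** — a scalar distance between a
  gene's own synonymous-relative frequency profile
  $f_\mathrm{gene}$ and the reference profile $f_\mathrm{ref}$,
  reported in percent. Three variants are implemented:
  * `global` (default): unweighted mean of
    $|f_\mathrm{gene}(c) - f_\mathrm{ref}(c)|$ over all 64 triplets;
    triplets of families absent from the gene contribute their
    reference frequency.
  * `position`: the mean over codon *positions* of the difference at
    the triplet occupying each position (occurrence-weighted).
  * `present`: unweighted mean over the distinct triplets present in
    the gene.

  The literature quoting this statistic rarely states its formula, so
  the choice of default is a genuine design decision. We default to
  `global` on the following reasoning: for a fully GC-optimized gene
  scored against a strongly AT-biased table, the `position` variant is
  dominated by rare-codon positions where
  $f_\mathrm{gene} \approx 1$ and $f_\mathrm{ref} \le 0.1$, so it
  saturates toward 90–100 %; the 64-triplet mean also credits the
  AT-ending codons the gene fails to use and lands in the more moderate
  range such comparisons typically report. All three variants are one
  keyword away (`variant=`), and every variant is zero for a gene whose
  usage matches the table exactly.
* **Synonymous-change accounting** (`compareSynonymous`) — for two
  equal-length sequences with identical translations, the number of
  codon positions whose triplets differ, in total and per consecutive
  window of `segmentSize` codons (default 80; windows are 1-based codon
  indices, the last window may be short). A non-synonymous difference is
  an error that reports the offending positions: the statistic is only
  defined for synonymous recodings, and silently tolerating an amino
  acid change would make "n changed" meaningless.

## Recoding strategies

`optimizeCds` produces a synonymous recoding under three strategies:
`max` (every codon becomes its family optimum — including the stop,
recoded to the optimal stop), `match` (each position sampled from the
family's reference frequencies; requires an explicit seed), and
`threshold` (only codons at or below `rareCeiling` are promoted to the
family optimum; a non-rare stop is kept). Translation identity is
asserted after recoding, an internal stop in the input is rejected, and
single-member families can never change. Forbidden motifs are removed
greedily by switching overlapping codons to their next-most-frequent
synonyms; an unavoidable motif (e.g. spanning single-member families) is
reported, never silently dropped.

Note a deliberate non-goal: the package does not try to reproduce any
particular published optimized gene base-for-base. Commercial design
algorithms optimize opaque multi-term objectives (real optimized genes
are typically ~70 % optimal, not 100 %), so the deposited artifact of
such a design is a diagnostics *input*, not a target the `max` strategy
should hit.

A caution on monotonicity: recoding with `max` lowers the mean codon
frequency difference for genes that are *far* from the table (the
realistic use case — a GC-rich gene against an AT-rich table), and the
test suite asserts exactly that. It is not a theorem for arbitrary
inputs: a gene already matching the table has distance near 0, while a
fully `max`-recoded gene has distance bounded away from 0 whenever
family maxima are below 1.

## GenBank extraction

`extractCds` parses single-record GenBank flat files (the location
grammar `join()`, `order()`, `complement()`, nested combinations, and
partial-end markers) and applies an explicit policy: frame check
(`requireMod3`), internal-stop check, minimum length (in codons),
`/pseudo` exclusion, and inverted-repeat deduplication (same gene name
*and* identical sequence counted once, so duplicated IR genes do not
double-weight the usage table; the toggle is exposed because published
CDS censuses are often silent on this point). Rejections are logged with
reasons in an extraction report, never fatal. Coordinates are parsed
1-based inclusive (the GenBank convention) and converted internally to
0-based half-open; the conversion round-trips exactly.

# Image quantification model

The fluorescence procedure quantifies reporter expression per plastid
while correcting for tissue depth: plastids deeper in the thallus yield
less light in *both* the reporter channel (CFP emission window) and the
chlorophyll autofluorescence channel, so the per-particle ratio
mean(CFP)/mean(auto) cancels depth to first order. The pipeline is:

1. **Rolling-ball background subtraction** (`rollingBallSubtract`,
   default radius 5 px). Background is defined as the grayscale
   *opening* of the image by a non-flat ball structuring element of
   radius r — the surface traced by a ball rolling under the intensity
   landscape — and the result is image − background clipped at 0. This
   is the mathematically crisp form of the classical rolling-ball
   operation; the historical implementation in common image software
   approximates it with a sliding paraboloid and radius-dependent
   shrinking, so small numeric divergence from that tool is expected.
   Two consequences worth knowing: a constant image returns exactly
   zero, and a feature survives subtraction only if it is *narrower*
   than the ball — which is why the synthetic scene generator defaults
   to particle radii below 5 px.
2. **Binary mask** (`makeMask`) of the background-subtracted
   autofluorescence channel. The threshold method is a declared
   default, not an inference: IsoData-style iterative intermeans
   (historically the default "binary transformation" of the cited image
   software), with Otsu between-class-variance maximization as the
   alternative. A constant image yields an empty mask with a warning —
   an imaging failure should not crash a batch run.
3. **Watershed splitting** (`watershedSplit`) of touching particles
   along ridges of the Euclidean distance transform (EBImage's
   watershed on the distance map; `ext = 1` gives a minimum seed
   separation of about 2 px, `tolerance = 1` the minimum depth
   separating two seeds). Labels are consecutive from 1; an empty mask
   has zero labels.
4. **Per-particle ratios** (`particleTable`): area, mean intensity per
   channel, and ratio = mean_cfp/mean_auto. Particles with zero mean
   autofluorescence are excluded and counted (their ratio is
   undefined). Measurement happens on the raw channels by default —
   intensities are assumed linear (no gamma correction) and offset-free;
   `measure = "subtracted"` is available when both channels carry a
   constant offset.
5. **Aggregation**: per-section mean of particle ratios, then mean ±
   SD *across sections* (error bars between thallus sections, the
   replication unit of the experimental design; per-particle SD within
   a section is reported separately). With a single section the
   cross-section SD is reported as `NA`, not 0. `foldChange` divides
   two section-level means, e.g. transformant over wild type.

The ratio is invariant under scaling both channels by a common positive
factor and linear in a scaling of the reporter channel alone — both
asserted in the suite.

# Gel densitometry model

Band densities are taken as measured inputs (mean gray value over a
fixed band region; band detection on gel images is out of scope). The
standard curve is unweighted OLS of mean replicate density on loaded
amount — unweighted because dilution series rarely come with reliable
per-point variance estimates; inverse-variance weighting and a
through-origin fit are exposed as options, with the free intercept as
default since blank signal on a gel is common. Inverse prediction is

$$ \hat{x} = (d - \hat\beta_0)/\hat\beta_1 $$

with a delta-method standard error combining the fit's
intercept/slope covariance with the unknown band's own replicate
variance, and a t-interval on the fit's residual degrees of freedom
(slightly conservative in simulation, by design — the band SD enters as
known). A negative estimate is reported as below detection with the raw
value retained. Conversion to tissue concentration makes every
extraction factor explicit:
`ng/mg = ng · (V_buffer / V_loaded) · dilution / m_fresh`,
rather than hard-coding any particular experiment's constants.

# Synthetic data: what it emulates, and what it does not

All generators are seeded (Mersenne-Twister, rejection sampling) and
bit-reproducible.

* `chloroplastStyleProfile()` is a fixed synthetic synonymous-frequency
  profile with the statistical character of an AT-rich plastome — in
  nearly every family an A/T-ending codon dominates and G/C-ending
  codons are rare or intermediate (Cys is deliberately C-optimal so
  GC-ending optimal codons exist). It is a stand-in, not counts from a
  sequenced genome.
* `syntheticReporterPair()` constructs, deterministically, a 240-codon
  native/recoded gene pair whose headline diagnostics are known *by
  construction* against that profile: native GC3 231/240 = 96.25 %,
  recoded GC3 30/240 = 12.50 %, 212 codons changed distributed
  72/71/69 over the three 80-codon segments, native composition
  16 optimal/160 rare, recoded 174 optimal/15 rare. This reproduces
  the arithmetic of a published chloroplast reporter optimization at
  exactly the printed values, which is what makes it a sharp
  end-to-end oracle; it does not reproduce any deposited nucleotide
  sequence, and emergent quantities not designed in (the mean codon
  frequency differences) are asserted only qualitatively.
* `syntheticPlastome()` draws a CDS census (default 94 genes, mean 230
  codons) from the profile, adjusts third bases by deterministic
  synonymous swaps until the set-wide GC3 hits the target (default
  0.1210) to within one codon, and assembles a GenBank record with
  both strands, split (`join`) genes, verbatim inverted-repeat
  duplicates, a `/pseudo` gene and a frame-violating feature — so the
  extraction policy has real work to do.
* `genPlastidScene()` renders soft-edged discs whose reporter-channel
  signal is exactly ratio × autofluorescence before noise, plus
  per-channel offsets and Gaussian read noise (scene SNR =
  amplitude/noiseSd). Truth labels are each particle's half-maximum
  footprint. It does *not* model a point-spread function, chlorophyll
  texture within plastids, depth-dependent attenuation (the very thing
  the ratio corrects for), or 3-D structure — so pipeline-recovery
  tests demonstrate correctness of the computation, not robustness to
  real optics.
* `genGelSeries()` produces densities slope·ng + intercept + Gaussian
  noise over a 10-point 2-fold dilution series from 1000 ng — the
  standard design of an in-gel fluorescence quantification — with
  replicates.

Problem sizes in the suite were chosen to make sampling error small
relative to the asserted tolerances while keeping the default test run
fast: 1000-case loops for the scalar codon properties, 20 seeds × 6
scenes of 160² px at SNR 10 for the fold-change recovery (asserted
within 5 %), 100 seeds for gel slope recovery at 2 % noise (within
5 %), and 1000 simulated fits for interval coverage (asserted ≥ 93 %
at the 95 % level, the excess being the documented conservatism).

# Numerical conventions and degenerate inputs

* Family frequency normalization is exact to 1e-12 and validated on
  every object construction.
* Optimal-codon ties: lexicographic, flagged; rare threshold boundary:
  inclusive.
* The usage-table TSV serializes frequencies at 4 decimals but
  round-trips losslessly because counts are integers and frequencies
  are recomputed from them on read; frequency-only tables are
  materialized as pseudo-counts at the stated precision.
* A flat standard curve (slope indistinguishable from zero at the data
  scale) is rejected at inverse prediction rather than returning a
  numerically explosive estimate.
* Empty masks, single sections, unobserved codon families, and
  below-detection bands all return flagged, well-typed results rather
  than errors; malformed sequences (frame, alphabet, internal stops,
  duplicate FASTA ids) and impossible geometries (ball radius beyond
  half the image) are errors.

# Known limitations

* No codon adaptation index, tRNA-adaptation or RNA-structure scoring;
  the diagnostics are frequency-based only.
* The GenBank reader handles single-record flat files with the location
  forms above; multi-record files and remote fetches are out of scope.
* The watershed operates in 2-D on the distance transform; heavily
  overlapping or concave particles can merge or oversplit, and 3-D
  stacks are not supported.
* Inverse prediction uses the delta method, not Fieller's theorem, so
  intervals are approximate for low-information fits.
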