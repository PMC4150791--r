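---
title: "Models and conventions behind satselseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind satselseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satselseq)
```

This vignette is the package's own account of what it computes: the
models, the conventions adopted where the experimental design leaves a
choice open, and the limits of what the simulation-based tests
demonstrate.

## The experimental design being modeled

A Sat-Sel-Seq experiment diversifies one codon of a target protein at a
time with a degenerate NNS codon (N = A/C/G/T at positions 1–2, S = C/G
at position 3). The 32-codon NNS set encodes all 20 amino acids and a
single stop codon, TAG; codon multiplicity is uneven (Arg and Leu have
three NNS codons each, many residues have one). A *silent* synonymous
substitution at the codon immediately 3′ of the randomized one — the
positional barcode — marks the library identity inside the amplicon
itself. Each round of activity-based selection is amplified with primers
carrying an 8-bp generational barcode, so a single pooled sequencing run
contains every (position × generation) sample.

The package works against a deterministic synthetic reference,
`aid_loop_amplicon()`: a 297-nt coding window covering residues 71–169,
with the hotspot-recognition loop `LYFCEDRKAEP` at residues 113–123 and a
fixed filler peptide elsewhere (the codon-optimized gene sequence outside
the loop is not part of the method, and no such sequence is published, so
the flanks are openly synthetic). One preferred *E. coli* codon is used
per residue.

### Barcode conventions

Two conventions are ours, chosen once and kept:

* **Barcode codons are non-NNS codons wherever possible.** At two-codon
  amino acids the reference's third-base orientation is chosen so the
  synonymous partner ends in A/T. A codon drawn at a randomized NNS site
  then never coincides with a barcode, which makes noise-free decoding
  exact. The remaining ambiguity class — an error-derived non-NNS codon
  at a variable position that equals the 5′ neighbor library's barcode —
  is resolved structurally during demultiplexing (below).
* **Default barcode selection** prefers non-NNS synonyms, then maximal
  Hamming distance from the wild-type codon, then alphabetical order.
  The experiment only requires *a* silent mutation; this rule makes the
  choice reproducible. The duplicate library at Phe115 (id `115b`)
  cannot reuse slot 116 (Cys has a single synonym, taken by `115a`), so
  the builder scans further 3′ slots for the nearest one with an unused
  synonym, landing on CGA at residue 119 — distinct from every other
  library signature.

Generational barcodes default to four 8-mers at pairwise Hamming
distance 8 behind a fixed 10-nt leader; sets closer than distance 2 warn
at construction.

## Selection simulator

Selection is modeled as a single multinomial bottleneck per cycle:
survivors are drawn with probability proportional to
`count(v) · w(v)`, where `w` is a relative fitness defined at the
amino-acid level (synonymous codons share `w`; codon-level overrides are
available). This collapses plating survival and regrowth into one
relative fitness — appropriate because each experimental cycle is a
plate bottleneck followed by regrowth, and only relative representation
is observed. Stop codons default to `w = 0` (the expression cassette
carries a stop for negative selection). The deterministic expectation
`p′ = p·w / Σ p·w` (`expected_frequencies()`) serves as the analytic
oracle for the stochastic engine in the tests.

The sequencing error model is substitution-only and uniform, i.i.d. per
base at rate ε (default 7×10⁻⁴ per base, matching the low off-target
substitution rate observed in this kind of amplicon data). Indels and
homopolymer artifacts are deliberately out of the noise model, which is
what licenses anchored (alignment-free) decoding.

Default campaign sizes — starting depth 10⁴, bottleneck 10⁴ (kept ≥10×
the number of distinct variants, warning otherwise), 3 selection rounds,
5000 reads per (library, generation) — are the scale at which one
position's selection is well determined while a full-panel simulation
stays interactive. The demonstration fitness map
(`demo_fitness_map()`) is a fixed geometric ladder from 0.25 to 2.5
across the 20 amino acids (stop 0): fully ranked so that rank-recovery
has an unambiguous target, with a ten-fold dynamic range comparable to
the activity spread loop mutations produce.

All randomness flows from one master seed; `run_campaign()` derives one
sub-seed per stage, so any stage can be reproduced in isolation.

## Demultiplexing

Reads are **anchored, not aligned**: a read is oriented by exact match of
the constant 12-bp flank (the first 12 nt of the amplicon) immediately
after the generational barcode, trying forward then reverse-complement
orientation. The original analysis aligned reads before filtering, but no
aligner or parameters are recoverable; with a substitution-only error
model, anchored decoding is deterministic, testable, and loses only the
~`12ε` of reads with an error inside the anchor.

Decoding then applies, in order: generational barcode (exact match by
default; tolerance 1 uses nearest-unique semantics, ambiguous → reject),
positional barcode (the codon at each library's barcode slot is compared
with that library's barcode codon), and codon observation at the assigned
library's NNS slot. Zero barcode hits or an unexplained multiple hit
reject the read, mirroring the experiment's filter "lacking either the
generational barcode or a single positional barcode". One multiple-hit
class is resolved rather than rejected: a hit that falls *inside a
candidate library's own randomized codon* is no evidence of a chimera —
the variable codon may legitimately read as the 5′ neighbor's barcode —
so if exactly one candidate explains all other hits this way, the read is
assigned to it. Codons observed at the variable position are tabulated
even when they are not legal NNS codons (they arise by sequencing error);
a QC flag marks them.

The off-target rate estimator divides mismatches by comparable bases,
where comparable bases exclude the anchor, every NNS-capable codon of the
panel and every barcode slot — positions that are either conditioned on
by the filters or legitimately variable. This keeps the estimator
unbiased, which the tests check against the configured ε.

## Enrichment and the G0 correction

Frequencies are plain count ratios per (library, generation), at codon
level and aggregated to 21 amino-acid-or-stop symbols. The stop symbol is
retained as a 21st category throughout: its trajectory (rapid extinction
under selection) is a built-in negative control.

Because NNS codon multiplicity is uneven, raw final-generation
frequencies overstate multi-codon residues (Arg starts near 3/32, most
residues near 1/32). The corrected logo mode scales final counts by
starting counts per symbol:

```
e(aa) = (c_G3(aa) + a) / (c_G0(aa) + a),   a = 0.5,
```

renormalized to heights summing to 1 per position. The pseudocount keeps
ratios finite for symbols driven extinct by G3 (common under strong
selection) and is half a count — small against typical per-symbol depths
of hundreds. Logo heights are frequencies (or normalized enrichments),
not information bits, matching how these selections are summarized.
Each position is normalized independently; read depth differences between
positions do not weight the logo.

Replicate concordance uses the Euclidean distance and cosine similarity
of amino-acid frequency vectors, the two multivariate agreement metrics
used for duplicate libraries selected independently.

## Assays

* **XXC preference profiles.** Sixteen substrates place the target
  cytosine in every `x2 x1 C` context with x ∈ {A, mC, G, T}
  (5-methylcytosine stands in for cytosine as a less reactive neighbor).
  Product formation is averaged, unweighted, over the four substrates
  sharing a symbol at the −1 (or −2) position and normalized to relative
  reactivities summing to 1. Unweighted averaging is a documented
  convention; the alternative (weighting by reaction extent) is not what
  "averaged across substrates" describes.
* **Fluctuation frequencies** are resistant/viable ratios per culture
  with mean ± SD. Group comparison reports the fold change of means and
  a two-sided Welch t-test on log₁₀(frequency + 10⁻⁹) — frequencies are
  approximately log-normal across cultures, and the published analyses
  state only a significance threshold, not a test, so the test choice is
  ours and is recorded here. All-zero groups fall back to a rank test; a
  zero-variance pair degenerates to an equality check. Mutation *rate*
  estimators (Luria–Delbrück / MSS) are out of scope: the quantity
  tracked is a frequency.
* **Michaelis–Menten fits** minimize Σ(vᵢ − Vmax·Sᵢ/(Km + Sᵢ))² by
  Levenberg–Marquardt with Vmax₀ = max rate and Km₀ = the concentration
  nearest half-max, bounded below at 0; standard errors come from the
  Jacobian at the optimum.

## Trajectory geometry

Multi-model PDB files are read frame by frame; atoms are classified DNA
by the residue-name whitelist DA/DC/DG/DT, protein otherwise.

* **Contacts**: per frame, the minimum over all (residue atom, DNA atom)
  Euclidean distances; time averages are arithmetic means over the
  analyzed frame range (restrictable, e.g. to the equilibrated tail of a
  simulation).
* **H-bond occupancy**: fraction of frames where ≥1 donor–acceptor pair
  satisfies distance ≤ 3.5 Å (closed interval) and, when hydrogens are
  given, a D–H…A angle ≥ 140°. These geometric criteria are stated
  conventions — the reference analyses defer their criteria to
  supplementary material — and both thresholds are configurable. Without
  hydrogens a distance-only criterion applies, with a warning.
* **SASA**: Shrake–Rupley quadrature with a deterministic golden-spiral
  point set (default 960 points/atom), Bondi radii, probe 1.4 Å. At 960
  points an isolated sphere is exact to machine precision and rigid-body
  rotations move per-residue values by well under 1%; raise `n_points`
  where tighter invariance matters.
* **Burial fractions**: 1 − mean(SASA)/reference, clamped to [0, 1].
  The default reference is the theoretical maximum per-residue exposure
  of an extended Gly-X-Gly tripeptide (Tien et al. 2013); any reference
  state can be substituted. Published per-residue burial values for this
  system derive from the original long MD trajectories, which are not
  distributable; they motivate the functionality but are not
  reproduction targets.

## What the tests do and do not show

The test suite validates every operation against independent oracles:
closed-form expectations for selection dynamics, binomial statistics for
the noise model, brute-force scans for geometry, and exact inversion of
the noise-free simulator by the decoder. End-to-end, a simulated campaign
at default sizes recovers the generating amino-acid fitness ranking with
Spearman ρ ≈ 0.98 via corrected G3 enrichment, and independently selected
duplicate libraries are concordant (cosine > 0.95).

The simulator emulates multinomial sampling, bottleneck selection and
uniform substitution noise. It does **not** emulate 454 homopolymer
indels, PCR amplification bias or chimera formation, plasmid copy-number
effects, within-culture growth dynamics, or epistasis (fitness is
per-symbol at one position). Passing tests therefore demonstrate that the
decoding and enrichment machinery is correct and well calibrated under
the stated error model — not that real sequencing data are free of the
artifacts the model excludes. Problem sizes in the tests (campaigns of
10⁴–2×10⁴ reads, trajectories of 10 frames × ≤60 atoms, 200-replicate
noise studies) were chosen as the smallest at which the statistical
assertions have comfortable power.
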