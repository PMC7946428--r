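---
title: "Two-guide non-coding knock-in: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-guide non-coding knock-in: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkitdesign)
```

This vignette records the scientific model behind each module, the
conventions the implementation commits to, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The editing model

The strategy tags a protein by excising the genomic span around the coding
stretch of interest with **two SpCas9 cuts in non-coding DNA** and
replacing it, via NHEJ, with a donor fragment carrying the same span plus
an in-frame tag cassette. The package models four allele fates
deterministically — `unedited`, `forward` insertion, `reverse` insertion
and donor-less `none_ko` religation — rather than simulating repair
kinetics: cut/insertion rates in cells are unknown, and the method's
correctness argument is structural, not kinetic. The re-cut ratchet is
captured by a flag: an allele containing both original 23-nt
protospacer+PAM footprints is *re-cuttable* and therefore not a terminal
state.

**Cut geometry.** The SpCas9 blunt cut is fixed 3 bp 5' of the PAM,
between protospacer positions 17|18. Internally every cut is encoded as
"index of the last base kept on the left", in 1-based closed coordinates.
We deliberately use 1-based closed intervals throughout (the
IRanges/Biostrings convention) instead of 0-based half-open ones: the
package is built on those containers, and mixing conventions inside R is
the classic source of off-by-one errors. GFF3 input is already 1-based.

**Switch-and-flip donor.** The donor is
`rc(site2) | arm1 | linker5+tag+linker3 | arm2 | rc(site1)`, where each
`site` is the full 23-nt protospacer+PAM footprint *as read on the locus
sense strand* and `rc` is reverse complement; guide 2's flipped site sits
at the donor 5' end and guide 1's at the 3' end. This orientation
convention is forced by the re-cut requirement, which the simulator
enforces as an invariant: when Cas9 releases the donor (cutting −3 within
each flipped end site) and the fragment ligates in *reverse*, the stub
arithmetic regenerates both original footprints exactly at the two
junctions; a *forward* ligation leaves only partial stubs and destroys both
sites. A plus-strand guide leaves a 17-nt stub on the fragment and 6 nt on
the genomic side; a minus-strand guide the mirror image. Junction
seamlessness is deliberately **not** required — the stubs land in
non-coding DNA, and correctness is defined at the transcript/protein
level.

**Junction self-reconstitution screen.** A subtlety not visible in the
qualitative description: if the two protospacers share their 3-nt
PAM-proximal tail (and the PAM N matches), a *clean forward* junction can
itself reconstitute one of the target sites, making the knock-in allele
re-cuttable. The probability is about 4⁻⁴ per pair, but over many candidate
pairs it is a real hazard, so `pickGuidePairs(..., locus =)` constructs
both forward-junction neighbourhoods in silico and discards offending
pairs, and the synthetic-locus generator rerolls such plantings.

## Guide selection

- **Non-coding regions only**: cuts must fall in the 5'UTR or an intron
  (intergenic optionally), at least `minSpliceDist = 100` bp from every
  interior splice junction. The 100 bp default reflects the usual "~100 bp
  from splice junctions" design rule for leaving mRNA processing intact; it
  is configurable because the rule is approximate.
- **Start-codon clearance**: when the start codon lies in the target exon,
  the upstream cut must additionally sit at least 25 bp 5' of the CDS
  start. Rationale: junction INDELs (modelled up to 10 bp) must not be able
  to reach the Kozak context, and splice-aware ORF calling anchors on the
  20 bp upstream of the ATG.
- **Scoring** is a deliberately transparent heuristic, not a trained
  efficiency predictor: start at 1.0, −0.3 for GC outside [0.4, 0.7], −0.3
  for any homopolymer run ≥ 5, −0.2·min(1, extra off-target hits at ≤ 3
  mismatches), clamped to [0, 1]. It exists to make ranking deterministic
  and auditable; a laboratory can substitute any scorer that fills the
  `onScore` column.
- **Off-target search** is an exhaustive Hamming scan (both strands, exact
  NGG, mismatches counted over the 20-mer) — conservative and adequate at
  single-locus scale; it makes no seed-region distinction.
- **Pairing** ranks by min(guide scores), then smaller excision, then
  leftmost upstream cut, and requires the excised span to contain the
  target exon's coding stretch and the insertion point.

## Transcript and protein prediction

Edited alleles are interpreted by **unique anchor matching**: 30-bp
wild-type sequences flanking each exon boundary are located in the allele
(exact, unique matches), introns whose both anchors map are spliced out,
and an intron with a destroyed splice site is retained. The CDS start is
found via the 20 bp immediately upstream of the annotated ATG; if that
context is absent (e.g. the start codon was excised) no ORF is called.
Translation runs to the first stop. This mirrors the wet-lab verification
(RT-PCR plus cDNA sequencing across the splice junctions) and is fully
deterministic. The anchors impose mild geometric preconditions — insertion
points ≥ 30 bp from exon ends, cuts ≥ 25 bp from the ATG — which the
pair-picker and the synthetic-locus generator respect.

NHEJ is modelled as blunt ligation with optional seeded junction INDELs
(insertion of random bases or deletion left of the junction, ≤ `maxIndel`
bp, reproducible under a seed). No resection or microhomology modelling is
attempted.

## Cloning primers

The four-fragment guide-vector assembly uses the published fixed template
primers verbatim (lower case marks vector-side fixed flanks, upper case the
guide-dependent region; comparisons are case-insensitive). The 19/20-N rule
is interpreted as: the template's fixed flanking base supplies the
U6-required leading G (or its complement), so a G-start guide contributes
19 filled bases and any other guide 20 — every expressed guide begins with
G either way. The in-silico assembly check builds synthetic amplicons
(primer + random interior + reverse-complemented reverse primer) and merges
them by their terminal overlaps into one circular sequence containing both
guide cassettes in tandem.

Donor-assembly primers place an `overlap`-bp (default 25) homology tail on
each fragment's forward primer, copied from the end of the preceding
fragment, so adjacent amplicons share exactly that many bases and overlap
merging reconstructs the donor string exactly. Annealing regions grow from
18 nt until the Wallace-rule estimate (2·AT + 4·GC) reaches 60 °C, capped
at 35 nt — a deterministic stand-in for per-construct primer optimisation.
Vector-junction tails default to empty strings and should be set to the
linearised backbone ends for real cloning.

## Quantification conventions

- **Efficiency** is `100 × GFP⁺ / denominator⁺`; the denominator is the
  transfection marker (mCherry) in culture or the Cas9 stain in dual-virus
  experiments. With several coverslips the package averages per-coverslip
  percentages and reports their SEM — the plausible reading of per-group
  error bars; the per-cell alternative is a one-liner on the same counts.
- **KI/WT/KO**: GFP⁺ cells are KI; remaining marker-stained cells split at
  the whole-image ("maxiROI") mean intensity, above → WT, at or below →
  KO. Fractions are over all transfected cells, so the three classes
  partition 100%.
- **Colocalization** is the OLS slope of signal B on signal A over
  background-subtracted ROI pairs; R² is computed from residual and total
  sums of squares directly.
- **FRAP**: traces are background-subtracted (mean of two background ROIs)
  and normalized so the pre-bleach mean is 1 and the first post-bleach
  value is 0 — this pins the one-phase-decay intercept at 0, making the
  published Prism convention `Y = (Y0 − Plateau)e^(−Kx) + Plateau` reduce
  to `f(t') = plateau(1 − e^(−t'/τ))` with τ = 1/K in minutes. The
  immobile fraction is `1 − plateau`. Fitting is Levenberg–Marquardt
  (`minpack.lm::nlsLM`, which tolerates the zero-residual noiseless case)
  with deterministic initialisation: plateau₀ = mean of the last two
  points, τ₀ = linearly interpolated time to half plateau divided by ln 2;
  bounds τ > 0, plateau ∈ [0, 1.5], plateaus above 1 flagged. Pooling
  averages traces pointwise on a common grid and fits the mean trace, the
  convention used for pooled-spine analyses.

## What the synthetic data emulate — and what they do not

`makeToyLocus` builds a compact locus with the shape that matters for the
method: flank | exon 1 (5'UTR + signal-peptide-bearing CDS) | intron |
exon 2 (CDS end + 3'UTR) | flank, with 23-nt target sites planted at
chosen cut positions (default: one in the 5'UTR, one in intron 1, both
≥ 100 bp from the splice junctions), each verified unique genome-wide at 0
mismatches. Defaults (220 bp 5'UTR, 90+120 bp CDS, 400 bp intron, 150 bp
flanks, 4-codon signal peptide) keep property sweeps fast while leaving
room for every geometric constraint to bind. `makeFrapTrace` samples the
one-phase-decay model on a 1-minute grid (two pre-bleach points, ten
post-bleach points by default) matching 60-second z-stack acquisition;
`makeCellTable` draws multinomial KI/KO/WT classes with class-specific
Gaussian marker intensities. All generators consume a single integer seed
through a private RNG stream.

What passing tests therefore show: the design arithmetic, the
switch-and-flip orientation logic, the splice-aware interpretation and the
quantification formulas are correct on sequences whose annotation is exact
and whose sites are unique. What they do not show: performance on
repetitive genomes with ambiguous anchors, multi-isoform loci (one
transcript — the longest CDS — is used per gene), chromatin or delivery
effects on cutting, or real INDEL spectra.

## Numerical and testing choices

- Problem sizes: property sweeps run 200 synthetic loci (~1.2–1.6 kb each)
  with varied UTR/intron lengths, guide strands and signal-peptide lengths;
  off-target oracle comparisons use random genomes up to 10 kb at ≤ 3
  mismatches. These sizes exercise every geometric branch while keeping a
  full run to a few minutes.
- τ from a single short noisy trace is weakly identified: at σ = 0.05 with
  ten 1-minute post-bleach points, single-trace τ errors exceed 10%. The
  parameter-recovery test therefore uses 20 post-bleach points at σ = 0.02
  (within the ≤ 0.05 noise regime the recovery property targets), and the
  pooled-fit test shows how averaging 46 spine traces restores precision —
  which is exactly why pooling is the analysis convention.
- Ties in pair ranking break by excision length then leftmost cut, making
  reports byte-reproducible. The CLI re-derives a design bundle from its
  JSON summary by exact footprint position+strand match and refuses
  ambiguous bundles.
- Degenerate inputs fail loudly with named errors ("gene not found",
  "window error", "no pair", "frame error", "donor sites ambiguous",
  "splice mapping ambiguous", "trace unusable", "grid mismatch").

## Known limitations

- No modelling of concatemeric or partial-vector integrations at the cut
  sites, and no quantitative prediction of in-cell knock-in efficiency.
- The GenBank writer emits a minimal single-record dialect (LOCUS,
  misc_features with labels, ORIGIN) sufficient for viewer import and
  round-tripping, not the full feature-key vocabulary.
- The off-target scan is bounded by the supplied FASTA; it is not a
  genome-wide aggregation service.
- Guide scoring is intentionally naive; treat it as a deterministic ranking
  device, not biology.
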