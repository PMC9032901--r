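---
title: "Chemotaxonomic fingerprint networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemotaxonomic fingerprint networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingernet)
```

## The problem and the model

Whole-cell MALDI-ToF spectra of microbial isolates are reproducible
enough that two deposits of the same strain produce near-identical peak
patterns, and different strains of one taxonomic order still share a
recognisable subset of peaks (conserved ribosomal and membrane
components). `fingernet` exploits this: it reduces each acquisition
replicate to a normalised peak list (a discrete intensity distribution
over *m/z*), scores all pairs by greedy-matched cosine similarity,
builds a thresholded mutual top-*k* network, and reads classification
off the network's connected components annotated with known taxonomy.
The unit of analysis is the *replicate*: replicates are never averaged,
each is a node, and the first sanity check of any panel is that
replicate pairs are mutual nearest neighbours.

The approach supports *dereplication* — grouping isolates so redundant
ones are not re-studied — and order/genus-level classification. It does
not identify species, and the package deliberately exposes no species
level call.

## The preprocessing chain

`preprocess_pipeline()` applies, in order: mass-window trim, square-root
transform, Savitzky–Golay smoothing, SNIP baseline subtraction, robust
noise estimation with S/N peak picking, close-peak merging, and total
ion current normalisation.

| parameter | default | units | why |
|---|---|---|---|
| trim window (protein) | 3500–20000 | Da | removes the matrix-dominated low-mass region |
| trim window (lipid) | 400–2000 | Da | full reflectron acquisition range |
| `sg_half_window` | 15 | points | standard biotyping smoothing width; cubic fit |
| `snip_iterations` | 30 | points (max clip half-window) | baseline varies slowly relative to peak width |
| `snr_threshold` | 6 | ratio | conventional retention cutoff for fingerprints |
| `peak_half_window` | 20 | points | local-maximum window; ties go to the lower index |
| merge tolerance | 2.0 / 0.5 | Da (protein/lipid) | centroid scatter of linear vs reflectron mode |

Numerical choices worth stating explicitly:

* **Savitzky–Golay edges.** Interior points use the closed-form
  convolution weights; the first and last `half_window` points are fitted
  with the truncated window actually available. A constant or cubic
  signal is reproduced exactly (to 1e-8 relative), which the tests assert.
* **SNIP schedule.** The clipping window *decreases* from 30 to 1. No
  log-log-sqrt pre-compression is applied because the chain already
  square-root transforms intensities upstream; an `increasing` schedule
  is available for comparison. The estimate never exceeds the signal
  pointwise, so baseline-subtracted intensities are never negative.
* **Noise.** 1.4826 × MAD of the whole baseline-corrected spectrum — a
  robust, parameter-free estimator. Its whole-spectrum nature is also its
  main limitation: if the noise level varies strongly across the mass
  axis, the single estimate is unrepresentative of the noisiest region,
  and points there can exceed 6 × noise by chance. On long (≈18k-point)
  acquisitions a *blank* spectrum therefore occasionally yields one to
  three marginal (S/N barely 6) junk peaks rather than coming out empty;
  real fingerprints sit at S/N 30+ and are unaffected. A blank with no
  point at S/N ≥ 6 is reported as unusable rather than emitted as an
  empty fingerprint.
* **Stage order.** The canonical order estimates noise on the smoothed,
  baseline-corrected signal, which is the only order in which an S/N
  cutoff is meaningful. `step_order` permits non-canonical orders
  (including peak picking first) for method comparison; after
  centroiding, remaining profile stages degrade to no-ops or elementwise
  transforms and are intended for comparison runs only.

## Similarity and the match tolerance

Peaks are paired greedily one-to-one within an *m/z* tolerance, strongest
intensity products first, ties broken by smaller Δm/z and then index —
the molecular-networking convention. The greedy score never exceeds the
optimal-assignment score (tests enumerate the optimum exhaustively on
small lists) and attains it when no peak has two candidates.

The default tolerances are 6.0 Da (protein, linear mode) and 0.2 Da
(lipid, reflectron mode). The rationale is that a matching tolerance
must cover the replicate-to-replicate scatter of a peak's measured
position: if single-replicate jitter has standard deviation σ, the
position difference between two replicates has standard deviation σ√2,
and the tolerance should be ≈ 2.8 of those. For reflectron-mode lipid
spectra σ ≈ 0.05 Da gives 0.2 Da; for linear-mode protein spectra
σ ≈ 1.5 Da gives 6.0 Da. A 2 Da protein tolerance — 200 ppm at 10 kDa —
is far below what linear-mode biotyping can hold (common practice bins
at 0.002 × *m/z*, i.e. 7–40 Da over 3.5–20 kDa) and, with realistic
jitter, caps the replicate self-similarity near 0.65, destroying the
replicate-nearest-neighbour property. Both tolerances are configuration,
not constants, and are echoed into every output header.

## Network, clusters, and the embedding

Candidate edges need cosine ≥ threshold (default 0.7); an edge survives
only if each endpoint ranks the other within its top-*k* (default 10)
candidates. Mutual top-*k* prevents a promiscuous fingerprint from
absorbing everything into one component. Clusters are defined as the
connected components of this graph — a reproducible surrogate for
cluster boundaries drawn by eye on a map — and every report header
states this definition.

The 2-D map is t-SNE on *d* = 1 − cosine with perplexity 15 (clipped to
(n−1)/3), 1000 iterations, early exaggeration 12 for the first quarter,
and a deterministic initialisation from the top two principal axes of
the double-centred similarity matrix, so identical inputs give identical
coordinates and the recorded seed is provenance, not an input. The
learning rate defaults to `max(n / early_exaggeration, 10)`: fixed large
rates tuned for datasets of hundreds of points oscillate on the tens-of-
points panels typical here, separating even duplicate fingerprints.
Sub-threshold pairs are *not* pruned for the embedding — thresholding
applies to the network only — so the map sees the complete dissimilarity
structure. Embedding quality is measured by trustworthiness at k = 5,
which penalises embedded neighbours that are not neighbours in *d*.

## Reporting conventions

Percentages are rounded to one decimal, halves away from zero, matching
the reporting style of biotyping studies. A query fingerprint is
*matched* when the plurality order among its cluster mates equals its
own order; plurality ties count in the query's favour, so a new cluster
formed entirely by same-order queries is a success (this mirrors how
such studies count new clusters, and inflates "matched" when queries
dominate a cluster — a property users should know). `merge_manifests()`
resolves id collisions across panels by source-prefixing and refuses
conflicting taxonomy. The PEG flagger scans for the longest arithmetic
ladder at 44.026 Da spacing (tolerance 0.05 Da, minimum run 5): on
random 20-peak lipid lists the false-positive rate is below 1%, and
removing flagged fingerprints can only reduce cross-order edges.

## What the simulator emulates — and what it does not

`simulate_panel()` draws a three-level peak hierarchy: 30 order-shared,
10 genus-shared and 10 strain-specific peaks per strain, uniform over
the trimmed mass range with minimum spacing twice the merge tolerance,
with lognormal base intensities (sdlog 0.5 — the square-root-compressed
image of raw lognormal(0,1) peak heights, since simulated peak lists
stand for post-transform fingerprints) normalised per template. A
replicate keeps each peak with probability 0.9, jitters positions
(σ = 1.5 Da protein / 0.05 Da lipid), multiplies intensities by
lognormal noise (sdlog 0.3), adds Poisson(5) uniform noise peaks, and
optionally appends a PEG ladder. Raw profiles add Gaussian peaks
(σ = 3 Da on a 1 Da grid for protein — FWHM ≈ 7 Da, the resolution of
linear-mode ToF at these masses), a slowly decaying exponential baseline
(amplitude 100, decay 20000 Da, so the post-√ noise floor is roughly
uniform where the MAD estimator assumes it is), and half-normal shot
noise scaled with the local ion flux. An adversarial setting (jitter
4 Da, dropout 0.3) exercises the isolated/misassigned reporting paths.
All randomness flows from one root seed through per-object derived
seeds.

Deliberately absent: physically realistic ToF peak shapes and detector
saturation, isotopic structure, *m/z*-dependent resolution, correlated
chemical noise, and any genus/species-level intensity signature beyond
shared peak sets. Passing tests on simulated panels therefore
demonstrate that the pipeline recovers the similarity structure the
generator encodes — hierarchical shared peaks under replicate noise —
not that real spectra of any particular taxon will separate equally
well.

## Problem sizes and determinism

The test suite and the acceptance script run on a 48-fingerprint default
panel (4 orders × 3 genera × 2 strains × 2 replicates), 20 raw spectra
of ~18k points for the preprocessing round trip, 1000 random pairs for
the greedy-vs-optimal comparison, and 1000 random lipid lists for the
polymer false-positive rate — sizes chosen so the whole suite completes
in well under a minute per file while keeping every Monte-Carlo estimate
stable to the asserted tolerance. The full pipeline is deterministic
given seeds; rerunning with the same inputs reproduces every output file
byte-for-byte (the run manifest, which carries a timestamp, excepted).

## Known limitations

* Blank (peak-free) long acquisitions can emit a few marginal peaks, as
  discussed above; filter on peak count or S/N margin when screening
  extraction controls.
* The whole-spectrum MAD noise model assumes a roughly uniform noise
  floor after the square-root transform.
* Cluster purity at the *order* level says nothing about genus or
  species resolution; with few replicates per strain, mutual top-*k*
  with small *k* can split a true cluster.
* t-SNE preserves neighbourhoods, not global geometry; distances between
  well-separated clusters on the map carry no meaning, which is why all
  quantitative reporting is network-based.
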