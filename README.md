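# fingernet

Chemotaxonomic dereplication of microbial isolates from MALDI-ToF MS¹
fingerprints.

Environmental microbiology labs accumulate isolates far faster than they
can be identified, and most are re-isolations of strains already studied.
Whole-cell MALDI-ToF mass spectrometry produces a protein fingerprint
(linear mode, *m/z* 2,000–20,000) or a lipid fingerprint (reflectron mode,
*m/z* 400–2,000) per deposit in minutes, and isolates whose fingerprints
agree can be grouped — *dereplicated* — without sequencing every one.
`fingernet` implements the computational half of that workflow for people
who have spectra and a partial set of trusted taxonomic labels: it turns
raw profile spectra into peak lists, compares them all-against-all, lays
the resulting similarity structure out as a network and a 2-D map, and
reports how well the data-driven clusters agree with taxonomy at the
order level.

## The method

**Preprocessing.** Each profile spectrum is trimmed to the informative
mass window (3.5–20 kDa for protein spectra), intensity-stabilised with a
square root, smoothed by a Savitzky–Golay filter (half-window 15 points,
cubic), baseline-corrected with the SNIP iterative clipping estimator
(30 iterations, decreasing window schedule), and reduced to the peaks
with signal-to-noise ≥ 6, where noise is 1.4826 × the median absolute
deviation of the corrected spectrum. Peak intensities are normalised to
unit total ion current, so every fingerprint is a discrete probability
vector over its peak positions.

**Comparison.** Two fingerprints *a*, *b* are compared by the cosine
score

> S(a,b) = Σ₍matched pairs₎ Iₐᵢ·I_bⱼ / (‖Iₐ‖₂ ‖I_b‖₂)

with peaks paired greedily, one-to-one, within an *m/z* tolerance
(6.0 Da protein / 0.2 Da lipid by default), strongest intensity products
first. The score is symmetric, bounded in [0, 1] and invariant to
intensity scaling. Protein and lipid fingerprints are never mixed.

**Network and map.** Pairs scoring at or above a cosine threshold
(default 0.7) become candidate edges; an edge is kept only if each
endpoint ranks the other in its top-*k* candidates (mutual top-*k*,
default 10), the standard molecular-networking rule that prevents hub
nodes. Clusters are the connected components of this network. For visual
inspection, the full dissimilarity structure *d* = 1 − cosine is embedded
in 2-D by a deterministic t-SNE (PCA initialisation, no random restarts).

**Reporting.** Against a taxonomy manifest (TSV of per-fingerprint order,
genus, species, reference/query status), the package reports per-cluster
order composition (counts and percentages of each order and cluster) and,
for query fingerprints, a concordance summary: *matched* (clustered with
a plurality of its own order), *isolated* (singleton), or *misassigned*.
A polymer flagger detects polyethylene-glycol contamination — ladders of
peaks spaced by the 44.026 Da ethylene-oxide repeat — which otherwise
creates artifactual lipid clusters.

**Simulator.** A hierarchical generator produces taxon-structured
synthetic panels (order-, genus- and strain-level peak sets plus
replicate noise, optional PEG spikes, and raw profile spectra with
baseline and shot noise), so the whole pipeline is testable with no
external data.

## Worked example

```r
library(fingernet)

cfg   <- sim_config(seed = 42L)            # 4 orders x 3 genera x 2 strains x 2 reps
panel <- simulate_panel(cfg)
run   <- run_pipeline(panel$peaklists, panel$manifest, seed = 42L)
run
#> <fingernet_run> 48 fingerprints, 36 edges, 20 clusters
#> queries: 48 | matched 100.0% | isolated 0.0% | misassigned 0.0%

head(run$composition, 3)
#> # A tibble: 3 x 5
#>   cluster_id  order   count pct_of_order pct_of_cluster
#>   <chr>       <chr>   <int>        <dbl>          <dbl>
#> 1 o01g01s01.1 order01     2         16.7            100
#> 2 o01g01s02.1 order01     2         16.7            100
#> 3 o01g02s01.1 order01     4         33.3            100
```

All 48 fingerprints land in clusters whose plurality order equals their
own (`matched 100.0%`), every cluster is single-order
(`pct_of_cluster = 100`), and e.g. the 4-member cluster `o01g02s01.1`
holds both replicates of the two strains of one genus — replicates
cluster with their strain, strains with their genus, genera with their
order. `autoplot(run$embedding, manifest = panel$manifest)` draws the
t-SNE map coloured by order; `tidy(run)` returns coordinates and cluster
labels as a tibble.

A command-line wrapper with `simulate`, `preprocess`, `similarity`,
`embed`, `report`, `flag-polymers` and `run` subcommands is installed at
`inst/cli/fingernet.R`:

```sh
Rscript inst/cli/fingernet.R run --taxonomy panel.tsv --seed 42 \
    --outdir results/ panel.mgf
```

## Scope

Cluster/taxonomy concordance is classification support for
dereplication, not species identification. Bruker raw directories and
mzML are out of scope (convert to mzXML); *m/z* recalibration across
spectra, isotope deconvolution and MS² scoring are not performed.
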