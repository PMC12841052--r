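---
title: "Virtual DEL design from a compact diazide scaffold: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual DEL design from a compact diazide scaffold: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

DNA-encoded libraries (DELs) couple each small molecule ("warhead") to a DNA
barcode so that pooled collections of 10^4--10^8 compounds can be synthesised
and screened together. The chemistry available on-DNA is limited, so *platform
molecules* — scaffolds carrying several orthogonal reactive handles — decide
which regions of chemical space a DEL can reach.

`cddap` models a compact diazide platform: 3-azido-5-(azidomethyl)benzoic
acid, carrying one **aromatic azide** and one **benzylic azide** of different
reactivity on a single benzoic-acid core. The aromatic azide reacts first
(organocatalytic enolate [3+2] cycloaddition, or selective reduction by mild
thiol/phosphine reagents); the benzylic azide is elaborated second (CuAAC or
reduction + amidation). Crossing the two step choices gives four library
architectures:

| scheme | step 1 (aromatic azide) | step 2 (benzylic azide) | BB1 | BB2 |
|---|---|---|---|---|
| A | enolate [3+2] cycloaddition | CuAAC | active methylene | terminal alkyne |
| B | enolate [3+2] cycloaddition | reduction + amidation | active methylene | carboxylic acid |
| C | reduction + amidation | CuAAC | carboxylic acid | terminal alkyne |
| D | reduction + amidation | reduction + amidation | carboxylic acid | carboxylic acid |

The package reproduces, as tested reusable code, the *in-silico*
characterisation of these libraries: building-block (BB) curation, product
enumeration, drug-likeness profiling, and chemical-space occupancy analysis
against a reference compound population.

## Architecture: R logic, RDKit mechanics

All of the analysis logic — thresholds, desirability functions, clustering,
density estimation, occupancy, correlations, the pipeline — is R (plus one
Rcpp kernel for the KDE grid). Molecular mechanics (SMILES sanitisation,
descriptors, fingerprints, reaction application, UMAP) are delegated to a
batch-mode Python worker (`inst/python/worker.py`) backed by RDKit and
umap-learn, invoked per *batch*, never per molecule. The worker is a plain
subprocess with JSON/CSV exchange; set `options(cddap.python = ...)` if the
interpreter is not simply `python` on the `PATH`.

## Building-block curation

Raw candidate lists (`.smi` or CSV) pass through:

1. **Desalting** — keep the largest covalent fragment by heavy-atom count,
   ties broken by canonical-SMILES sort order (so the result cannot depend on
   fragment order); neutralise simple protonation states only. No tautomer
   canonicalisation: it is not needed for the downstream descriptors and
   would make curation depend on a tautomer model.
2. **Class filter** — SMARTS per class, with cross-reactivity guards:
   * *active methylene*: CH2 flanked by a **ketone** carbonyl on one side and
     a second activating group (carbonyl, sulfonyl, nitrile, or aryl) on the
     other. The ketone requirement is deliberate: the enolate [3+2]
     cycloaddition consumes a carbon-flanked carbonyl (its oxygen leaves as
     water), so a methylene activated only by ester/amide/nitrile groups has
     no well-defined product under this chemistry. The pattern admits benzyl
     phenyl ketone, β-ketoesters, β-ketoamides, β-ketosulfones and
     1,3-diketones.
   * *terminal alkyne*: exactly one C≡C–H; no azide, no carboxylic acid.
   * *carboxylic acid*: exactly one COOH; no azide, terminal alkyne, or free
     primary amine (all would cross-react during enumeration).
3. **Rule-of-2 filter** — MW < 200 g/mol, clogP < 2, HBD ≤ 2, HBA ≤ 4.
   clogP is the Crippen atomic-contribution estimate; HBD/HBA are Lipinski
   counts (N–H plus O–H hydrogens; N plus O atoms), shared with the
   rule-of-5 profile so one descriptor set serves both filters. Because
   descriptor engines differ, absolute pass counts on a real catalogue will
   not match numbers produced with other clogP/HB definitions — the
   *boundary*, not the engine, is the contract.
4. **Diversity selection** — Morgan fingerprints (1024 bits, radius 2),
   k-means on the 0/1 coordinates under Euclidean distance, k = 200.
   Implementation details that matter for reproducibility:
   * k-means++ seeding, Lloyd iterations (max 300), relative centroid-shift
     tolerance 1e-4, all under one integer seed;
   * inputs are sorted by canonical SMILES before clustering, so a fixed
     seed gives the same representatives regardless of input order;
   * clustering operates on *unique* fingerprint vectors carrying
     multiplicity weights — mathematically identical to clustering the raw
     rows, and exactly invariant under duplicated candidates;
   * each cluster is represented by the member nearest its centroid
     (fingerprints have no meaningful "synthetic centroid structure"), ties
     broken by canonical-SMILES order.

## Scheme enumeration

Each transform is a reaction SMARTS applied by the worker, with site
targeting that encodes the scaffold's reactivity hierarchy:

* the enolate cycloaddition and the "aromatic" reduction only match
  aryl-bound azides;
* CuAAC and the "aliphatic" reduction *refuse* any structure whose aromatic
  azide is still intact — applying step 2 first is a contract violation, not
  a silent reordering.

Product identity is deterministic: all sanitizable products of a reaction
application are canonicalised and the lexicographically smallest SMILES is
kept. For unsymmetrical 1,3-diketones (two competing ketone sites) this picks
one product reproducibly and flags the record (`ambiguous_site`). Mass
bookkeeping is exact: scheme deltas relative to scaffold + BB1 + BB2 are
−18.0106 (A), −62.0116 (B), −44.0011 (C) and −88.0021 (D) Da monoisotopic,
from water loss (−18.0106) per condensation and −25.9905 (lose N2, gain H2)
per azide reduction; the test suite enforces them to 1e-3 on random pairs.

The DNA headpiece is represented by an N-methyl amide cap on the scaffold
acid. The cap matters for properties: the amide linkage contributes one
acceptor to every warhead (part of why scheme A warheads start at HBA 5),
and the choice of cap shifts MW by ~15–30 g/mol. N-methyl, rather than a
primary amide, avoids adding a donor pair that the DNA linkage does not have.
Enumeration is BB1-major, keeps failed pairs with their provenance, and
retains duplicate products (DEL counting is per combination).

## Drug-likeness

`ro5vc` counts strict violations of MW > 500, clogP > 5, HBD > 5, HBA > 10.
QED is computed in R as the weighted geometric mean of eight asymmetric
double-sigmoid desirability functions (MW, ALOGP, HBA, HBD, PSA, rotatable
bonds, aromatic rings, structural alerts) with the published mean weights;
the raw descriptors come from the worker, and the test suite pins the R
implementation against RDKit's reference QED to 1e-6. Molecular weight is
the average (not monoisotopic) weight throughout the profiling module.
Medians use the midpoint convention for even n.

## Chemical space

Embedding follows the fit-on-reference / transform-queries discipline:
functional-class (FCFP-style) circular fingerprints, radius 2, 1024 bits;
UMAP with `n_neighbors = 50`, Jaccard metric, two components, fixed seed
(default 42). Two numerical choices worth knowing:

* **Initialisation is seeded-random, not spectral.** Jaccard neighbour
  graphs over chemically diverse sets are frequently disconnected;
  umap-learn's spectral initialisation then falls through to an ARPACK
  eigensolve whose starting vector ignores the seed, and refits stop being
  reproducible across processes. With seeded random initialisation, the
  same seed and input give bit-identical coordinates — which the package
  promises. Coordinate *values* therefore differ from a spectral-init run;
  all downstream statistics are region-level and unaffected in kind.
* **Transforming the training set** lands near, not exactly on, the fitted
  coordinates (solver tolerance); tests assert closeness relative to the
  embedding span, not equality.

Density maps use a Gaussian KDE with full data covariance and Scott's-rule
bandwidth (factor n^(-1/6) in 2-D), matching `scipy.stats.gaussian_kde`,
evaluated by compiled code on a shared lattice: one grid spanning the union
bounding box of all embedded sets, padded 5% per side, default 512 × 512
(tests use coarser grids purely for runtime). Kernels are truncated at 8σ
(mass loss < 1e-14). The occupied region is `density > 0.01` on the *raw*
normalised density (integrates to 1); heat-map normalisation is display-only.
`occupancy(library, reference)` is the fraction of reference-occupied cells
also occupied by the library.

Two subtleties of normalised KDE that the API surfaces honestly: under
Scott's rule both the factor and the (unbiased) covariance depend on n, so
duplicating every point changes the map slightly, and adding points to a set
can *shrink* its superlevel area (each kernel carries mass 1/n). Passing an
explicit `bw_factor` switches to the population covariance with a fixed
factor, under which duplication invariance is exact and far-cluster
additions grow the area monotonically; the default remains scipy-compatible.

## Synthetic data: what the stated world is

The generators make the pipeline testable without catalogue downloads.

* `gen_bbs()` builds class-valid candidates from fixed combinatorial
  template grids (class head + decoration fragments). The grid is classified
  once with the package's own rule-of-2 filter; candidates are then drawn
  from the pass and fail arms so the realised fail fraction is binomial
  around the target (default 0.3 — a realistic catalogue attrition rate at
  this stage; there is no published value to copy). Class patterns hold by
  construction; uniqueness is canonical-SMILES-exact; capacity limits are
  reported as errors (223 / 282 / 1150 Ro2-passing uniques for alkynes /
  acids / active methylenes).
* `gen_reference()` emulates an approved-drug population as a mixture:
  drug-like small molecules (aryl head + polar linker + ring/chain tail,
  MW ≈ 230–420, QED ≥ 0.65 across the grid) plus a heavy tail (default
  15.2%) of linear oligo-amide chains. Chains sample 25–60 glycine/alanine/
  serine/valine/phenylalanine-like residues and are extended until
  MW > 1500, so every heavy member's QED falls below 0.2 — reproducing the
  *shape* of a real approved-drug set (a peptide-therapeutic tail dragging
  mean QED down) without any external structures. The stated residue range
  in the design brief (10–60) is narrowed at the low end because a
  10-residue glycine chain (≈ 588 Da) cannot satisfy the simultaneous
  MW > 1500 requirement.

What a green test does **not** establish: the generators do not mimic any
vendor catalogue's structural distribution or a real database's scaffold
diversity, so library-level percentages (Ro5VC fractions, mean MW/QED,
occupancy rates) computed on synthetic inputs are *internally* consistent
quantities, not predictions of the published values — those depend on
undeposited BB selections and an unstated clustering seed. The acceptance
suite therefore checks exact combinatorial facts (cardinality, mass ledger,
regiochemistry), estimator correctness against analytic/fine-grid oracles,
and order/shape recovery (occupancy ranking, planted occupancy–QED
correlation, the 15.2% low-QED tail) rather than those percentages.

## Degenerate inputs and tie-breaks (summary)

* unparsable SMILES: rejected per record with a reason, never fatal in batch
  paths; strict single-molecule transforms raise errors.
* fewer candidates than k: every survivor becomes its own representative,
  with a warning.
* fewer than 3 or collinear points: `kde_map()` refuses (singular
  covariance) and suggests jitter.
* mismatched lattices: `occupancy()` refuses; build both maps from one
  `build_grid()`.
* all ties (fragment choice, cluster representative, multi-site reactions)
  resolve by canonical-SMILES sort order.

## Known limitations

* Yields, kinetics and side reactions (e.g. diazo transfer competing with
  the cycloaddition for bulky substrates) are out of scope; enumeration
  assumes the selectivity the platform is designed to provide.
* The Python worker costs ~1 s per batch call (interpreter start-up) and
  ~25 s for the first UMAP call (JIT); use `embed_sets()` to fit and
  project several sets in one process.
* Descriptor-engine differences (clogP, HB definitions) shift absolute
  filter counts relative to other toolkits; thresholds, not engines, are
  the specification.
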