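# adswap — detection and alignment of 3D domain-swapping proteins

Three-dimensional domain swapping (DS) is an oligomerization mechanism in
which identical protein chains exchange equivalent structural regions
("swapped domains") through a flexible hinge loop, so that the monomeric
*closed* form and the oligomeric *open* form of the same protein differ by
a large rigid motion of one domain. Conventional rigid-body structure
comparison superposes only one domain of such a closed/open pair at a time
and misses the global relationship. `adswap` is for structural
bioinformaticians who need to decide, for a *pair* of chains, whether they
are DS-related, of which type (N-terminal, C-terminal, middle), where the
hinge loops lie, and how similar the structures really are when each
domain gets its own superposition.

## Method at a glance

* Secondary structure elements (SSEs) are vectorized and every SSE pair of
  a chain becomes a point in its **angle-distance (A-D) image** — the
  inter-vector angle vs. the inter-centroid distance, both normalized.
  The image is a rigid-motion invariant of the chain.
* A **pair graph** scores pairings of A-D points across the two images
  (vertices) and their geometric compatibility (edges); vertex weights
  W_ij are voted onto SSE pairs, whose weighted matching scores
  M̃(a, a′) feed a greedy one-to-one, order-preserving **SSE matching**.
  Matching needs no superposition, so both domains of a DS pair are
  matched at once.
* Matched SSEs anchor a superposition-dependent residue alignment
  (dynamic programming + iterative Kabsch), which converges onto the main
  domain. Per matched SSE pair, the post-superposition angle and distance
  give the **A·D product** P_ad = (θ/180°)(d/25 Å); its profile is
  morphologically smoothed, and a Student-t test (80 % confidence) on the
  adjacent differences localizes the hinge. Opening points are refined
  against the alignment mask, candidate swapped fragments validated by
  their own rigid alignment, and hinge ranges determined from backbone
  torsion differences with cutoff θ₀ = 25°·n_hl.
* With both domains independently superposed, the package reports
  **virtual measures** (virtual alignment size/ratio, vRMSD, vQ-score,
  vS-div) and the **DS score**

  DS = η · S₀ · exp(−[m₀(1−γ_θ) + m₁(1−γ_d) + m₂·μ_sd]) ∈ [0, 1]

  where η gates on a validated hinge, S₀ is the vQ-score, γ_θ and γ_d are
  the normalized angular difference and displacement of the swapped
  domains, and μ_sd their minimal structural diversity. m₀–m₂ and the
  decision cutoff are trained by MCC grid search on labeled pairs.

A seeded generator of synthetic closed/open two-domain chains
(`fixtureSpec()`, `makeFixturePair()`) makes the whole pipeline testable
without any structure download.

## Worked example

```r
library(adswap)

fx  <- makeFixturePair(fixtureSpec(swap_side = "C", rotation = 120, seed = 1))
rep <- compareChains(fx$closed, fx$open)
rep
#> DSReport
#>   DS score : 0.1963 (not DS)
#>   type     : C  eta: 1
#>   factors  : gamma_theta=0.667 gamma_d=0.567 mu_sd=0.798 s0=0.938
#>   virtual  : size=90 ratio=100.0% vRMSD=0.770 vQ=0.938
rep@hinges$Q[[1]]$range
#> [1] 55 62
```

Reading the output: the fixture plants a C-terminal swap by rotating the
second domain 120° about the hinge at residue 58. The detector classifies
the pair as a C-terminal swap with a validated hinge (η = 1) spanning
residues 55–62; γ_θ = 0.667 recovers the planted 120°/180°; the virtual
superposition aligns all 90 residues at 0.77 Å although no single rigid
superposition can. The DS score here uses the untrained default model
(m₀ = m₁ = m₂ = 1, cutoff 0.5) — train on labeled pairs for a calibrated
decision:

```r
tr <- trainFromManifest("pairs.tsv")   # pathQ chainQ pathS chainS label
writeDSModel(tr$model, "model.json")
```

A thin command-line interface ships in `inst/exec/adswap`
(`adswap compare Q.pdb:A S.pdb:A -o out/`, `adswap train manifest.tsv`,
`adswap eval manifest.tsv`).

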