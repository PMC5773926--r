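---
title: "Structural fragment queries by triangle-inequality pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural fragment queries by triangle-inequality pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragpick)
```

## The problem and the model

A *fragment* here is a window of L consecutive, peptide-bonded residues from
one protein chain, represented by the four backbone atoms N, Cα, C, O of
each residue (4L atoms, Ångström coordinates). The distance between two
fragments of equal length is the superposition RMSD: the root-mean-square
deviation of corresponding atoms minimized over all proper rigid-body
motions (rotation + translation; reflections are excluded, so mirror-image
backbones are *not* at distance zero). Correspondence is positional —
residue i of one fragment pairs with residue i of the other — which is what
makes the distance sequence-independent and fast.

Superposition RMSD is a metric. The load-bearing consequence is the
triangle inequality: for a query `q` with threshold `d_q` and any fixed
*reference fragment* `r`,

$$ \mathrm{rmsd}(q,f) \le d_q \;\Rightarrow\;
   \mathrm{rmsd}(f,r) \in [\,\mathrm{rmsd}(q,r)-d_q,\; \mathrm{rmsd}(q,r)+d_q\,]. $$

If the distances of all database fragments to a few references are
precomputed and kept sorted, a query touches each reference once, performs a
binary-search range query per reference, intersects the candidate sets, and
computes exact RMSDs only on the survivors. The result — this is asserted
against a brute-force linear scan throughout the test suite — is *exactly*
the set a full scan would return, in the same order. Pruning buys speed,
never correctness.

## The RMSD kernel

The production kernel is the QCP (quaternion characteristic polynomial)
method: after centering, the optimal-superposition RMSD satisfies
`rmsd² = (G_a + G_b − 2λ_max)/N`, where `G` are the squared norms of the
centered sets and `λ_max` is the largest eigenvalue of the 4×4 quaternion
key matrix built from the 3×3 correlation matrix. The characteristic
polynomial coefficients are derived from traces of the key matrix
(Faddeev–LeVerrier; the matrix is traceless so the cubic term vanishes),
and `λ_max` is found by Newton iteration started at its upper bound
`(G_a+G_b)/2`, which converges monotonically from above. The implementation
falls back to a self-contained Jacobi eigensolver if Newton fails to
converge in 50 iterations.

An independent Kabsch implementation (SVD of the covariance matrix,
determinant-sign reflection correction, explicit rotation, direct deviation
measurement) exists solely as a cross-check; the two agree within 1e-6 Å
over tens of thousands of randomized pairs in the acceptance suite. Atoms
are unweighted.

Numerical choices worth knowing:

* `(G_a+G_b)` and `2λ_max` cancel catastrophically for (near-)identical
  inputs. Squared-RMSD residuals below `1e-11·(G_a+G_b)/N` — the eigenvalue
  noise floor — are clamped to exactly 0. This is what makes "query the
  database with one of its own fragments at threshold 0" return that
  fragment at RMSD exactly 0, and it zeroes only distances of order
  1e-5 Å and below, far under any meaningful structural signal (and under
  the float32 storage resolution of the index).
* Index tables store distances as float32. At query time the pruning
  interval is widened outward by ε = 1e-4 Å so storage rounding can never
  exclude a true match; the exact refinement pass removes any false
  positives this admits, so ε affects only work done, not results.

## Database construction

`extract_fragments()` slides a window of L residues over every
*geometric-continuity run* of every chain: residues i and i+1 belong to the
same run iff the C(i)–N(i+1) distance is ≤ 2.0 Å (the peptide bond is
~1.33 Å; 2.0 tolerates poor geometry while catching real gaps). Author
numbering is never trusted — insertion codes and renumbered files make
numbering arithmetic unsafe, so windows are defined over the chain's
resolved order and a numbering gap with intact geometry does *not* split a
run. Residues missing any of the four backbone atoms are skipped (splitting
runs), as are non-standard residues other than MSE (→ M) and UNK (→ X);
alternate locations keep `' '`/`'A'`; only the first model of multi-model
files is read. A run of m residues contributes max(0, m − L + 1) windows,
the closed form the extraction tests assert.

The binary format ("FRGR") is little-endian with a fixed per-fragment
record: 4-byte PDB code, chain byte, per-residue residue numbers (i32) and
insertion codes, sequence bytes, then 4·L·3 float32 coordinates — float32
preserves PDB's 3-decimal precision for |coordinate| < 10⁴ Å. Residue ids
are stored per residue rather than as a single window start: fragments with
insertion codes or numbering gaps could not otherwise survive a round trip
losslessly, and lossless field-level round-tripping is an acceptance
criterion. The format is this package's own; no compatibility with any
other tool's databases is claimed. A database is bound to its index by an
md5 content hash computed over float32-quantized coordinates (idempotent
under the binary round trip); querying with a foreign index is rejected.

## Reference selection and the index

Pruning works best with ≥ 3 references far from each other. The implemented
heuristic: pick `f_i` uniformly at random (seeded), compute its distance to
every fragment, take the furthest fragment as `f_j` and the fragment at the
median of the distance list as `f_k`. With even counts the *lower* median
(0-based index ⌊(n−1)/2⌋ of the sorted list) is used — deterministic, no
interpolation between fragments — and all ties break to the lowest fragment
id. Any user-supplied reference list (n ≥ 1) is also accepted; greedy pivot
selection schemes from the metric-indexing literature are deliberately not
implemented. Indices persist to a separate "FRGX" file and are regenerable
at will; for one-off tasks the ranker below avoids indexing entirely.

## Query semantics

The pipeline order is: pruning → PDB-code exclusion → sequence regex →
exact refinement → sort (ascending RMSD, ties by fragment id) → limit.
Design choices that were genuinely open:

* **Regex anchoring.** A sequence constraint must describe the *entire*
  L-letter sequence (`A.{11}G` for "13-mer starting Ala, ending Gly");
  unanchored substring matching silently surprises. The regex runs after
  pruning and before refinement, so sequence-rejected candidates never cost
  an RMSD.
* **"N first" determinism.** "First found" is pinned to fragment-id scan
  order, making the result machine- and parallelism-independent; the output
  is then re-sorted by RMSD. "N best" truncates the fully ranked list.
* **Auto-widening** re-queries at d_q, d_q+step, … (defaults: step 0.25 Å,
  ceiling 10 Å) until a target match count is reached; additive steps keep
  successive result sets nested, and the final list provably equals a fresh
  query at the final threshold. Stopping at the ceiling short of the target
  sets a flag rather than erroring.
* **Masked (gapped) queries bypass the index.** The index bounds are valid
  for the metric the index was built on — full-length RMSD. Masked RMSD
  (restricted to ≥ 3 selected residue positions, e.g. three anchor residues
  on each side of a loop gap) is a *different* metric, so masked queries
  run as a linear scan, which is exactly as accurate and entirely adequate
  for one-off loop-closure tasks. Masks are 1-based residue positions in
  the R API and 1-based ranges (`--mask 1-3,11-13`) on the command line.
* **Parallelism is a contract, not a primitive.** `--threads` is accepted
  and validated; the implementation is sequential because the compiled
  one-vs-many kernel already clears every budgeted workload, and results
  are thereby trivially invariant to the thread count — the property the
  determinism criterion actually tests.

## The ranker

`rank_one_vs_many()` / `fragpick rank` compute the (optionally masked)
backbone RMSD of one fragment against an arbitrary pool — PDB files or a
binary database — with no index, sorted ascending, ties by pool ordinal.
Both input routes share the extraction and kernel code, so they rank
identical content identically; the binary route skips text parsing, which
is the entire reason the format exists, and the suite asserts (as a
non-binding smoke check) that it is the faster path on a 10,000-fragment
pool.

## What the synthetic generators emulate — and what they do not

All tests run on generated structures: `make_helix_chain()` builds ideal
α-helical backbones by internal-coordinate placement (φ = −57°, ψ = −47°,
ω = 180°; bonds N–Cα 1.458, Cα–C 1.525, C–N 1.329, C=O 1.231 Å), optionally
with seeded Gaussian jitter; `make_break_chain()` plants C–N gaps of exact
size to exercise continuity logic; `make_decoy_pool()` produces copies of a
base fragment under i.i.d. coordinate noise plus a random rigid motion, so
the expected distance to the base scales with σ while poses are scrambled.
Everything is deterministic under (parameters, seed).

These fixtures cover the *metric* and *bookkeeping* behavior of the tool
completely — distances, pruning bounds, filters, persistence, extraction
edge cases. They do not emulate real conformational diversity, sidechains,
crystallographic disorder beyond missing atoms/altlocs, or the distance
distribution of a real structure collection at 30% sequence identity. A
green suite therefore establishes that queries are exact and deterministic
on any input, not that any particular pruning ratio will be achieved on a
real fragment set — pruning effectiveness is data-dependent by nature.

## Known limitations

* PDB input only (fixed-column v3.3); no mmCIF, no sidechains, no models
  beyond the first, no automatic structure download, no sequence-identity
  filtering of the input set (curate the file list upstream).
* One database per fragment length; multi-length collections are multiple
  databases.
* Alternative similarity scores and flexible or sequence-dependent
  alignment are out of scope; the distance is backbone superposition RMSD,
  full stop.
* The binary format targets |coordinates| < 10⁴ Å (float32 at 3 decimals),
  which every real structure satisfies.
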