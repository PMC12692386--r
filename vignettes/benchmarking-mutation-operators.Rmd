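---
title: "Benchmarking molecular mutation operators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking molecular mutation operators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molmutbench)
```

## The problem

Mutation operators are the workhorses of evolutionary molecular design:
given a parent molecule, they propose a structurally perturbed offspring.
Different representations give rise to very different operators - direct
graph edits, corpus-trained graph growth, reaction-template application,
and token edits on SMILES or SELFIES strings - and they trade off
chemical validity, computational cost, and how far and in what direction
they move a molecule's properties. `molmutbench` implements five such
operators behind one protocol so those trade-offs can be measured on a
common population:

* **GB-GA** - primitive graph edits (add/remove atom or bond, change
  element or bond order, form/cleave a ring), each candidate checked by
  sanitization, invalid candidates rejected and resampled.
* **GB-GM** - attachment events sampled from probabilities estimated on a
  reference corpus (which element, which bond order, conditioned on the
  attachment atom's element), plus corpus-frequency ring formation;
  sanitization-checked with resampling like GB-GA.
* **SCC** - reaction-SMARTS templates ("click-like" transforms) applied
  to the parent with reagents drawn from a building-block library.
* **SF-T** - insert/replace/delete edits on SELFIES tokens; the SELFIES
  grammar encodes valence constraints, so every non-empty decode is valid
  by construction.
* **SM-T** - the same edits on SMILES tokens, which carry no such
  guarantee; its raw validity is the phenomenon being measured, so it
  never resamples.

Validity is decided by one uniform external check for all operators:
parsing plus full sanitization (syntax, ring-closure bookkeeping,
kekulization, valence against the standard valence table, aromaticity
perception). No operator's internal validity shortcut is trusted, and the
`valid` flag of every mutation record equals an independent
re-sanitization of its SMILES.

## The protocol

Each operator is asked for *k* independent mutants per seed molecule at
budgets k = 1, 3, 5, over a common seed population (500 molecules by
default). Per (operator, budget) population the report records:

* validity: `100 * valid / requested` - the denominator is always
  `seeds * k`, so operator skips and failures count against validity;
* wall-clock time summed over operator calls only (metric computation and
  I/O excluded), and throughput in molecules per second;
* conservation: mean absolute parent-to-mutant shift of predicted pIC50
  under fingerprint random-forest QSAR models (direction discarded);
* complexity: mean absolute parent-mutant differences of ten quantities -
  molecular weight, ring count, heteroatom count, chiral-carbon fraction,
  sp3-carbon fraction, the degree-factorial Bertz index
  `BI = sum_i ln(deg(i)!)`, a Hann-style feature-density proxy, the
  Wiener index `WI = (1/2) sum_ij d_ij` over shortest paths, QED and a
  physicochemical complexity index `PCI = logP + (HBA - HBD)`;
* diversity: parent-mutant Tanimoto similarity on radius-2/2048-bit
  circular fingerprints, population similarity CDFs, a standardized
  two-component PCA of nine descriptors, and histogram Kullback-Leibler
  divergences `D(original || mutated)` per descriptor.

```{r protocol, eval = FALSE}
seeds <- generate_seed_set(500, rng_seed = 1)
protocol <- benchmark_protocol(seeds, budgets = c(1, 3, 5), rng_seed = 1)
report <- run_benchmark(protocol)
report
write_report(report, "benchmark_out")
```

## Tunable parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `edits_per_mutant` | 1 | token/graph edits per requested mutant |
| `resample_cap` | 20 (50 in stress tests) | rejection-sampling retries for GB-GA/GB-GM; 0 disables |
| `max_heavy_atoms` | 120 | growth guard; larger mutants are invalid (`size-guard`) |
| `element_palette` | C, N, O, F | elements available to graph edits, matching the mutation alphabets |
| `ring_sizes` | 3-7 | ring sizes GB-GA may form |
| `remove_policy` | largest-fragment | keep the biggest piece when a removal disconnects the molecule (alternative: reject the edit) |
| KL `n_bins`, `epsilon` | 50, 1e-10 | shared-range histogram bins and smoothing |
| fingerprint | radius 2, 2048 bits | circular substructure hashing |

The SMILES mutation alphabet is exactly the 13 characters
`F O N C ( ) = # 1 2 3 4 5`; the SELFIES alphabet is the 15 tokens
`[epsilon] [Ring1] [Ring2] [Branch1_1] [Branch1_2] [Branch1_3] [F] [O]
[=O] [N] [=N] [#N] [C] [=C] [#C]`. Seed molecules may contain symbols
outside these alphabets (the tokenizer handles the full SMILES language,
including `Cl`/`Br`, bracket atoms and stereo marks); mutation only ever
*inserts or substitutes* symbols from the alphabet. Stereo descriptors
are tokenized as ordinary tokens, never inserted, and dropped at
canonicalization - stereochemistry is outside the scope of the benchmark.

## The synthetic seed population

The packaged seed generator draws uniform-random SELFIES token sequences
(5-25 tokens by default) and decodes them, which guarantees validity and
restricts chemistry to neutral C/N/O/F molecules. Two properties of this
construction matter for interpretation:

* **Molecules are small.** Uniform sequences truncate at the terminator
  token, so decoded molecules have a median of about 5 heavy atoms
  whatever the token range. A drug-like seed set (the natural reference
  population for this kind of benchmark) has 20-30 heavy atoms; absolute
  magnitudes measured here - similarity means, delta scales, validity of
  SM-T (token edits are more often fatal on short strings) - are
  compressed or amplified accordingly. The benchmark's conclusions are
  therefore read *directionally* (which operator is most/least valid,
  which grows molecules), not as portable magnitudes.
* **Chemistry is exotic.** Random derivations produce motifs (N-N and
  O-O chains, cumulated dienes, strained rings) that are rare in curated
  libraries. A small fraction (~7%) of seeds are fully saturated
  (e.g. O=C=O-like micro-molecules) and cannot be grown by GB-GM at all;
  these surface as `operator-skip` records and count against validity.

Real seed sets in `.smi` format drop into the same readers and protocol.

## The synthetic structure-activity oracle

QSAR conservation scoring needs labeled training data. In place of
assay-derived tables, the packaged oracle labels molecules with
`pIC50 = clip(intercept + w . z(descriptors) + N(0, sigma), 2, 12)`,
where `z` standardizes the nine-descriptor vector over the generated set.
The default weight vector emphasizes lipophilicity (logP 1.0), size
(MW 0.8) and hydrogen-bonding/polarity (TPSA 0.6, HBA +0.4, HBD -0.4,
rotatable bonds -0.3, sp3 fraction +0.3) - the property axes that
fingerprint QSAR models typically latch onto in real assay data - with
intercept 6 and assay noise sigma = 0.3 pIC50 units.

A caveat the package measures rather than hides: on the small synthetic
molecules above, a descriptor-linear signal is only partially expressible
from *binary* fingerprints, because presence/absence bits lose atom
multiplicities and near-homologous molecules alias. The random forest
(500 trees, fixed seed; `ranger` backend) reaches a held-out R-squared of
about 0.65 on the n = 2000 recovery experiment, and sparse linear probes
on the same bits plateau near 0.76, so this is a representation ceiling,
not an underfit ensemble. On drug-sized, chemically diverse training
data the same pipeline behaves like a standard fingerprint RF QSAR.

## Numerical choices and degenerate inputs

* Validity error categories: `syntax`, `unclosed-ring`, `valence`,
  `kekulize`, `empty-input`, plus operator-level `size-guard`,
  `resample-exhausted`, `no-template-match` and `operator-skip`. The
  empty string after an edit is invalid (`empty-input`) and stays in the
  validity denominator.
* Canonicalization uses iterative Morgan-style refinement of local atom
  invariants with deterministic tie-breaking; remaining ties after
  refinement are (near-)automorphic atoms, so the output is invariant to
  the input's atom ordering. Aromaticity is re-perceived on the
  kekulized graph (Hueckel 4n+2 over rings of size 5-7, with a fused-ring
  allowance), so aromatic and Kekule writings normalize identically.
* The SELFIES decoder tracks remaining bonding capacity per atom and
  clamps every requested bond order, which is what makes any token
  sequence decode to a sanitizable molecule; branch lengths and ring
  reaches are read through single-token indices and clamped to what
  exists. The encoder retries its derivation from every atom as root
  before declaring a molecule unencodable (needed when a fixed
  double-bond ring closure depends on where the spanning tree is rooted).
* KL divergence is estimated from shared-range histograms (50 bins,
  epsilon = 1e-10 added to every bin, natural log), direction
  `D(original || mutated)`. The estimator is exactly zero for identical
  samples and converges to the closed-form value for known Gaussians
  within a few percent at n = 1e5. Degenerate all-identical samples are
  treated as a single effective bin (divergence 0 against themselves).
* PCA standardizes columns first (the nine descriptors are on
  incommensurate scales), drops zero-variance columns with a warning, and
  fixes signs so each component's largest-magnitude loading is positive.
* Tanimoto over two empty fingerprints is defined as 1.0 with a warning.
* Timing is wall-clock around the operator call only, summed per
  population; throughput numbers are hardware-dependent and never
  asserted against.

## Design choices where the design was open

* **Bertz index**: the degree-factorial form `sum ln(deg!)` is used
  because that is the quantity the benchmark tracks; it is *not* the
  classical Bertz CT, and the two are not interchangeable.
* **Hann index**: implemented as a feature-density proxy,
  `(rings + heteroatoms + chiral centers) / heavy atoms`; the exact
  literature formula this stands in for is ambiguous, so the function is
  deliberately small and swappable.
* **PCI** weights default to (1, 1); both are configurable.
* **Chirality**: potential stereocenters (assigned or unassigned) count
  as chiral carbons, judged by pairwise-distinct substituent environments
  under symmetry-respecting Morgan ranks.
* **GB-GM context granularity** is the single attachment atom's element -
  the smallest model consistent with sampling "which atom/bond to add
  next given the current context"; its training corpus defaults to the
  protocol's own seed set.
* **SM-T never resamples** (its raw validity is the measurand); GB-GA and
  GB-GM resample; SF-T needs no resampling; SCC retries across templates
  only.
* **Duplicates among the k mutants are kept** - the budget protocol asks
  for k independent draws, and deduplication is a reporting option.
* **logP and TPSA** come from OpenBabel (batched through the `obabel`
  binary, with the ChemmineOB in-process binding as fallback); all other
  descriptors are computed on the package's own molecular graph. QED uses
  the published desirability parameterization with the structural-alert
  count fixed at zero (no alert library is bundled), which shifts QED by
  a molecule-independent factor and leaves it strictly inside (0, 1).

## Problem sizes

The packaged experiments use a 500-seed population at budgets 1/3/5 for
the headline run, 10,000 samples for the SELFIES validity stress test,
n = 2000 molecules for the QSAR recovery experiment, and a 60-seed,
two-budget protocol for the bit-for-bit determinism check; unit tests
work on 100-120 molecule fixtures. These sizes give stable population
statistics for a benchmark whose molecules are a few atoms in size while
keeping a full run in the minutes range on one core.

## Known limitations

* No stereochemistry, isotopes, or radical species; charges are limited
  to common drug-like states. `NRE` is identically zero.
* Aromaticity perception covers simple and ortho-fused 5-7 rings;
  exotic polycyclics may stay in Kekule form (consistently so, which is
  what canonicalization requires).
* The reaction-SMARTS engine implements the subset of the language the
  packaged templates need (element/aromaticity, exact H counts, `!H0`,
  charge, ring membership, `*`, maps); it is not a general SMARTS
  matcher, though user template files in the same subset load fine.
* The SELFIES codec covers the benchmark's 15-token alphabet (neutral
  C/N/O/F, single fragment, `Branch1`/`Ring1`/`Ring2` reach); molecules
  outside it are reported as operator skips rather than silently
  re-encoded.
* Passing tests on the synthetic population demonstrate the machinery
  and the qualitative operator ordering, not quantitative transfer to
  drug-sized chemistry.
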