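---
title: "Minimizer-based taxonomic classification with a compact hash table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-based taxonomic classification with a compact hash table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerlca)
```

## The problem and the model

Taxonomic classification of shotgun metagenomic reads asks, for each
sequenced fragment, which taxon it most plausibly came from.  The k-mer/LCA
approach answers this without alignment: every k-mer of a reference library
is associated with the lowest common ancestor (LCA) of all genomes that
contain it, and a read is classified by accumulating the LCA labels of its
own k-mers.  `kmerlca` implements the memory-efficient variant of this idea
in which only each k-mer's *minimizer* — its smallest ℓ-mer under a chosen
ordering (ℓ ≤ k) — is stored and queried, and where the store is a
probabilistic *compact hash table* (CHT) holding a truncated hash code
instead of the full key.

The pipeline for one ℓ-mer is fixed: extract → canonicalize (the smaller of
the ℓ-mer and its reverse complement, so strand does not matter) → apply the
spaced-seed mask → XOR with a toggle constant.  The resulting 64-bit word is
the candidate value; the minimum candidate over the k-mer's window is the
k-mer's minimizer, and that exact word is what the table stores and is
queried with, so "distinct minimizer" means the same thing at build time and
at classification time.  The minimizer is often described informally as the
lexicographically smallest canonical ℓ-mer; because the XOR shuffle permutes
the ordering, the implemented ordering is the shuffled one, which is what
actually governs the statistic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 35 (nt), 15 (protein) | window length whose minimizer is looked up |
| `l` | 31 (nt), 12 (protein) | minimizer length; 2 bits/base (nt) or 4 bits/symbol (protein), so ℓ ≤ 31 or ℓ ≤ 15 |
| `spaces` (s) | 7 (nt), 0 (protein) | spaced-seed masked positions: starting at the next-to-rightmost position, every other position until s are masked (ℓ = 12, s = 3 gives the pattern 1111 1101 0101) |
| `toggle` | `9e3779b97f4a7c15` | odd 64-bit XOR constant permuting the candidate ordering (avoids low-complexity bias); recorded in the manifest |
| load factor | 0.7 | table cells are sized as ⌈D/0.7⌉ from the capacity estimate D |
| `key_bits` | table-derived | compact code width is 32 − value bits; value bits are the minimum that fit the renumbered taxonomy (no 17-bit floor is imposed — 17 bits is what a real full-scale database happens to need, and small databases benefit from wider codes) |
| subsample `f` | 1 | hash-based subsampling keeps minimizers with `fmix64(m) ≥ v = (1−f)·(2^64−1)`, at build and classify time alike |

Sensitivity is governed mainly by ℓ − s (the number of compared bases);
increasing s trades precision for sensitivity, and growing k − ℓ shrinks the
table at some cost in specificity.

## Numerical and design choices

* **BFS renumbering.**  The taxonomy is pruned to the nodes carrying
  reference sequences plus their ancestors and renumbered breadth-first from
  the root (internal ID 1), so every ancestor has a smaller ID than its
  descendants and `lca(a, b)` is just "replace the larger with its parent
  until equal".  Sibling order within a BFS level is ascending external ID —
  the tie-break is not specified by the method's description, and this
  choice makes numbering reproducible.  Internal ID 0 is reserved for
  "no taxon", matching the table's use of 0 for empty cells.
* **Empty versus zero code.**  A populated cell is `(code << value_bits) |
  value` with value ≥ 1; a compact code of 0 is remapped to 1 so that the
  all-zero word is unambiguously "empty".  The bias is negligible
  (2^−key_bits of keys share code 1 instead of having their own).
* **Probing.**  Linear probing wraps circularly; a full table is a hard
  error rather than a silent drop, because the builder sizes to a 0.7 load
  and running out of room means the capacity estimate was bypassed.
* **Capacity estimation.**  Distinct minimizers are estimated by the mod-F
  sketch (keep distinct m with `fmix64(m) mod 1024 < 4`; estimate |Q|·256).
  For libraries so small that |Q| < 100 the variance would dominate, so the
  builder counts exactly instead; the sketch's unbiasedness is tested at
  |Q| ≳ 500.
* **Ties and ambiguity.**  Window minima keep the leftmost occurrence on
  equal values (the deque pops only strictly larger candidates), so results
  are deterministic.  A k-mer overlapping any non-ACGT character emits
  nothing but still counts toward fragment length; at classification time
  such k-mers are reported as an ambiguous run.
* **Classification.**  Consecutive k-mers sharing a minimizer reuse the
  previous lookup through a depth-1 cache (the method's description implies
  exactly one remembered minimizer).  Sub-threshold minimizers count as
  no-hit k-mers so the run-length output remains a lossless encoding.
  Resolution scores each leaf of the pruned hit tree by the sum of counts on
  its root-to-leaf path; ties resolve to the LCA of the tied leaves, our
  reading of the predecessor tool's behavior.  Fragments shorter than k have
  zero k-mers and are unclassified.  A confidence-threshold reclassification
  stage present in later released versions of the reference tool is out of
  scope here.
* **Translated search.**  DNA queries are translated in all six frames with
  the standard genetic code into a 16-symbol reduced amino-acid alphabet (15
  groups over the 20 standard residues — ours merges D/E, I/V, K/R, L/M,
  S/T — plus one symbol shared by selenocysteine, pyrrolysine and stop).
  The exact 15-group partition of the original reduced alphabet is not fixed by the method's
  description, so the alphabet ships as a documented configuration default,
  recorded in the database manifest; any 15-group partition yields a working
  system.  Stop symbols are storable characters, not breakers; X and unknown
  letters break k-mers.  Protein minimizers skip canonicalization.
* **Hash subsampling and the capacity sketch.**  The capacity estimate D is
  computed before subsampling and f applied afterwards, matching the
  narrative in which the estimate is S′ and the user's budget S determines
  f = S/S′.

## The synthetic world

The generator emulates the strain-exclusion benchmark without downloads: a
domain → genus → species → strain taxonomy; a uniform-random root genome;
children diverged from their parents by independent per-base substitution
(defaults 10% genus, 2% species, 0.5% strain — chosen once so that sister
strains are close enough for genus- and species-level matching to be
learnable from 100 bp reads while strain identity stays ambiguous); and
100 bp paired-end reads with per-base errors at 0.4% mismatch, 0.005%
insertion, 0.005% deletion, fragment lengths normal with mean 300 and sd 25
(the benchmark's fragment-length distribution is not stated; these are
conventional Illumina-like values, exposed as arguments).

Deliberate simplifications: genome evolution is substitution-only (no
structural change, so truth coordinates stay trivial — read-level indels are
still exercised by the simulator); qualities are constant placeholders (the
classifier ignores them); there is no coverage or GC bias.  Passing tests
therefore demonstrate the machinery's correctness and its behavior under
point divergence and sequencing error, not performance on real genomes with
repeats, low-complexity tracts (masking is honored on input rather than
performed), horizontal transfer, or contamination.

Error-rate calibration compares read bases positionally with the recorded
origin; mates whose error record contains an indel are excluded from that
comparison (a shifted tail would be misattributed as mismatches), which
discards about 1% of mates at default rates.

## Problem sizes used by the checks

The collision experiments use uniformly random
synthetic genomes, which the original evaluation itself used for exactly
this purpose — with a ~5 Mbp reference and a 4 Mbp query in
`scripts/acceptance.R`, and a 1.25 Mbp / 1 Mbp pair in the test suite: the
absent-key error rate of a CHT depends on load factor and code width, not on
genome size, and the collision bounds only tighten at smaller scale.  At
load 0.70 with 15-bit codes the measured absent-key error is ≈ 0.015–0.016%
(a miss scans ≈ 6 occupied cells, each matching a random 15-bit code with
probability 2^−15).  Strain-exclusion runs in the tests use 18 genomes of
20–25 kb and 100–150 fragments per held-out strain; the calibration run uses
1,000 fragments (the benchmark's full per-strain depth of 500,000 is a
scale choice, not a different procedure).

## Known limitations

* Single-threaded by contract; the LCA merge is commutative and
  associative, so a sharded builder is possible but not provided.
* No resizing of a populated table (the full hash code is not recoverable
  from a cell), no deletion, no quotient-filter variant.
* No low-complexity masking (masked input is honored), no handling of
  merged/deleted taxonomy IDs, no quality-aware simulation.
* The value returned for a key indistinguishable from other inserted keys
  is an ancestor of the true LCA — never a disjoint taxon for an inserted
  key — but absent keys can draw false LCAs at the documented sub-percent
  rate.
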