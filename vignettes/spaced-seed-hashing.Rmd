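---
title: "Incremental spaced-seed hashing: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental spaced-seed hashing: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fshash)
```

## The problem

Spaced seeds — binary patterns such as `10111011`, where `1` marks a match
position and `0` a don't-care — are used in place of contiguous k-mers in
read classification, alignment-free comparison and homology search, because
tolerating mismatches at fixed positions improves sensitivity. The price is
computational: a contiguous k-mer hash can be rolled from one position to
the next (consecutive k-mers share k-1 symbols), while the Q-gram a spaced
seed extracts at position i+1 shares few symbols with the one at position i
in their respective hash layouts, so spaced-seed hashes are traditionally
recomputed from scratch at every position. `fshash` removes most of that
recomputation.

## The hash

A seed is described by its shape `Q` (the set of 0-based offsets of its
`1`s), weight `W = |Q|`, and span `s(Q) = max(Q) + 1`. With the 2-bit
nucleotide code `A=00, C=01, G=10, T=11`, the Rabin-Karp hash of the Q-gram
at position `i` of a sequence `x` is

    h(x[i+Q]) = OR over k in Q of ( encode(x[i+k]) << 2*m(k) )

where `m(k)` counts the match positions strictly left of `k`. The r-th
matched symbol therefore occupies bit offsets `2r, 2r+1`, first matched
symbol in the least-significant bits. No modular reduction is applied: the
hash is the exact `2W`-bit word, which is why weights are capped at 32 (one
64-bit word). Because R doubles are exact only to 2^53, hash values cross
into R as decimal strings; `hash_bits()` renders them MSB-first the way the
worked examples below print them.

```{r worked}
hash_sequence("ACTGACTGGA", "10111011", bits = TRUE)
```

## Incremental reuse

The engine computes all hashes in order and, at position `i`, reuses the
hash computed at position `i - j`. The positions of the seed whose encoded
symbols survive that reuse are

    C_j = { k-j in Q : k in Q and m(k-j) = m(k) - m(j) }

after a single uniform right shift of the old word by `2*m(j)` bits; the
`W - |C_j|` missing symbols are read from the sequence and OR-ed in. The
membership condition is rank alignment, not mere overlap: `|C_j|` can be
strictly smaller than `|Q ∩ (Q - j)|` (for `10111011` at `j = 2` the
overlap is 3 but only positions `{0, 4}` keep their ranks).

Per position the engine picks the `j` in the available window maximizing
`|C_j|`. Over a window of size `s`, `best_previous()` implements
`ArgBH(s) = argmax_{j in 1..s} |C_j|`. All of this combinatorial structure
is precomputed once per seed (`compatibility()`, `O(span^2 * weight)`) and
never touched per position; hashing keeps only a ring buffer of the last
`span - 1` hash words, so memory is independent of read length.

```{r compat}
tidy(compatibility("10111011"))
```

### Multiple seeds

When a set of seeds of one common span `L` is hashed simultaneously, seed
`y` at position `i` may reuse the hash of *any* seed `z` at `i - j`, with
the cross-compatibility sets
`C^yz_j = { k-j in Q_y : k in Q_z and m_y(k-j) = m_z(k) - m_z(j) }` and the
selector `ArgBSH(y, s) = argmax_{z, j<=s} |C^yz_j|`. The membership
predicate guarantees that a uniform right shift by `2*m_z(j)` lands every
kept field at its target offset `2*m_y(k-j)`, so no per-field remapping is
needed; the oracle-equivalence property tests guard this invariant
directly. Reuse is restricted to strictly earlier positions (`j >= 1`):
same-position cross-seed reuse would fall outside the selector's stated
index range, so it is deliberately not attempted.

## Design choices

* **Tie-breaking.** The argmax over `j` is not unique in general. Ties go
  to the smallest `j` (and for seed sets, then to the smallest source seed
  index): a shorter lookback keeps the dependency chain short and is
  cache-friendlier, and determinism makes plans reproducible byte for byte.
* **Ambiguous bases.** Sequences are split into maximal `A/C/G/T` runs
  (case-folded); each run is hashed independently with a fresh ring buffer.
  Windows overlapping an `N` are simply not emitted — every emitted hash is
  valid by construction, with no per-bit validity bookkeeping. The
  alternative (emitting flagged hashes over ambiguous windows) would
  complicate every consumer for no benefit to the use cases served here.
* **Transient.** Position 0 of each run is hashed naively; position
  `i < span - 1` restricts the argmax to the window that actually exists.
  Steady-state accounting (`count_encodings()`) discards the first
  `span - 1` positions of each run.
* **Pattern validation.** Seeds must begin and end with `1`; otherwise
  `span = max(Q) + 1` would silently disagree with the pattern length. All
  published seeds satisfy this. Violations are errors, never silent
  normalization, as is a weight above 32.
* **Strings for hash values.** A 64-bit hash does not fit an R integer or
  (exactly) a double above 2^53. Decimal strings are exact for every
  permitted weight, group and join cleanly, and serialize to TSV unchanged.

## Cost model and predicted speedup

The portable cost proxy is the number of symbols read and encoded: naive
hashing encodes `W` symbols per position; the incremental engine encodes
`W - |C_ArgBH(span-1)|` per steady-state position. Under the simplifying
assumption that a shift and an insertion cost the same, the predicted
steady-state speedup implemented by `predicted_speedup()` is the ratio

    W / (W - |C_ArgBH(span-1)|)

and, for simultaneous seed sets, the aggregate
`sum(W_y) / sum(W_y - kept_y)` with `kept_y` from `ArgBSH`. This formula is
this package's own reconstruction of that cost model; wall-clock speedups
additionally reflect memory effects and the true relative cost of shifts
versus insertions, so `fsh_benchmark()` reports wall-clock times as
informational only and never asserts on them.

```{r speedup}
predicted_speedup(list("10111011", "10101010101", strrep("1", 22)))
```

A seed's structure decides its savings: the alternating seed
`10101010101` keeps 5 of its 6 symbols (one insertion per position, like a
contiguous k-mer), while `10111011` keeps 3 of 6.

## The synthetic read generator

`simulate_reads()` emulates the *shape* of shotgun metagenomic read sets —
a random uniform genome, reads drawn uniformly from its positions, and
independent uniform substitutions at a per-base rate of 1% by default, the
typical short-read error level; read lengths default to the 80–700 bp range
of short-read and long-read sets when the caller picks them. It does not
model indels, position-dependent (Illumina-profile) error rates,
homopolymer artifacts, coverage bias, or real genome composition. That is
deliberate: the hashing engine is insensitive to *where* errors fall — only
read length and the presence of ambiguous symbols change its behavior — so
passing tests on these reads demonstrate correctness and cost accounting,
not robustness to sequencer-specific artifacts. The generator is
deterministic given its `rng_seed` and leaves the global RNG stream
untouched.

## Problem sizes used by the tests

The test suite exercises: the worked 10 bp example; ~1,000 random
(sequence, seed) pairs up to 500 bp with seeds up to span 16, plus ~100
random equal-span seed sets, all checked bit-for-bit against the naive
reference (which is itself checked against an independent plain-arithmetic
oracle); steady-state encoding counts on a 10^5 bp random string; and
simulated read sets of 80 bp and 700 bp reads for the transient-dilution
check. These sizes keep the full suite under a minute while covering every
code path; the engine itself streams arbitrarily long inputs.

## Known limitations

* Only the Rabin-Karp OR/shift hash is implemented. A cyclic-polynomial
  variant (rotations and XOR) would need a well-defined way to retire stale
  terms under XOR and is out of scope.
* Canonical (strand-symmetric) hashing and reverse complements are not
  provided; callers wanting them hash both strands.
* Seed *design* (sensitivity optimization, overlap-complexity minimization)
  is out of scope — seeds are inputs. `seed_overlap()` is exposed alongside
  `|C_j|` for exploration, but when the two differ is documented only by
  example, not characterized.
* Heterogeneous-span seed sets cannot be hashed simultaneously; hash them
  independently instead.
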