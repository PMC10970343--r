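---
title: "CAT trilateration profiles: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAT trilateration profiles: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catseq)
```

## The model

`catseq` locates every DNA sequence relative to three fixed reference
points — the C-, A- and T-benchmarks, infinite periodic repeats with periods
`AGTC`, `ACGT` and `GTAC` — and compares sequences through those locations
only. The design constraint on the trio is structural: the A- and
T-benchmarks agree at no position, so a base can match at most one of them
positionally, while the C-benchmark agrees with each at exactly 25% of
positions and acts as the third reference that makes trilateration
well-posed.

### Stage one: profile accumulation

Scoring a sequence against one benchmark is a single left-to-right pass.
At zero-based position $i$ with observed base $b$:

* exact match ($b$ equals the benchmark base, i.e. circular distance 0
  within the 4-periodic benchmark): exact score $em = 1$, near score 0;
* otherwise the near score is `baseDistance[d]` where $d$ is the circular
  distance between $b$'s canonical slot in the period and $i \bmod 4$:
  adjacent neighbor ($d \in \{1,3\}$) 0.6, far neighbor ($d = 2$) 0.4.

The accumulation couples each position to its history:

```
nearMatches        += nm + prevMatches * nm
exactMatches       += em + prevMatches * em
prevMatches         = sequencePrevLength / (i + 1) + em + nm - minPoint
bonusTotal         += (i == n - 1 ? 0 : prevMatches)
sequencePrevLength += prevMatches
```

`prevMatches` plays the role a positional weight plays in a numeral system:
a run of matches raises the value of later matches, so profiles separate
sequences that share base composition but differ in order. The normalized
result `dnaDistance = (nearMatches + exactMatches) / (bonusTotal + n)` is
the sequence's "distance" to that benchmark.

### Stage two: trilateration and comparison

With the benchmark-to-benchmark separation fixed at 1, each cyclically
consecutive benchmark pair (C→A, A→T, T→C) forms a triangle with the two
distances; the cosine theorem gives $\cos\alpha = (d_1^2 + 1 - d_2^2) /
(2 d_1)$, the foot of the altitude $D = d_1 \cos\alpha$ and the altitude
$H = \sqrt{d_1^2 - D^2}$. The six numbers are the profile. Comparison is
then per-benchmark Euclidean distance between the $(D, H)$ pairs and
$\text{similarity} = 1 - (r_C + r_A + r_T)/3$, reported in percent. The
comparison reads nothing but the twelve stored numbers, which is the
method's point: cost independent of sequence length.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `baseDistance` | `c(0, 0.6, 0.4, 0.6)` | near-match weight by circular distance (unitless score per position) |
| `minPoint` | `0.4` | floor subtracted in the `prevMatches` recurrence |
| match/mismatch/gap | `1 / -1 / -1` | Needleman–Wunsch scoring (linear gaps) |
| equality tolerance | `1e-12` | per-benchmark profile distance below which two profiles count as a 100% match |

`minPoint` is not pinned down by the method's published description; we set
it to the smallest nonzero match score, so a bare near-far match (0.4)
exactly cancels the floor. It is configurable through `cat_constants()` and
recorded in every profile's provenance, and profiles produced under
different constants refuse to compare — the geometry is only meaningful
within one provenance. The alignment scoring scheme is likewise a
convention, not part of the profile method; the defaults are the simplest
symmetric scheme.

## Numerical choices

* **Initialization.** All accumulators start at 0. The recurrence is applied
  literally, including the exclusion of the last position's `prevMatches`
  from `bonusTotal`; `prevMatches` may go negative early in poorly matching
  sequences, which is tolerated (the accumulator result carries a `flagged`
  field if a summed total ends negative — not observed for any sequence in
  the exhaustive spaces we enumerate).
* **Triangle repair.** Two normalized match ratios and a unit base need not
  satisfy the triangle inequality. `cos α` is clamped to $[-1, 1]$ and the
  altitude radicand floored at 0; `triangle_legs()` records when either
  correction fired. Inside the clamp-free region $D^2 + H^2 = d_1^2$ holds
  to 1e-9 and is asserted as a test invariant. A degenerate $d_1 = 0$ leg
  yields $(D, H) = (0, 0)$ with a flag.
* **Pairing convention.** The method computes a $(D, H)$ pair per benchmark
  but leaves open which two distances form each triangle. We fix the cyclic
  convention: leg $X$ uses (distance to $X$, distance to successor of $X$)
  with successor order C→A→T→C. The choice is arbitrary but must be uniform,
  so it is stamped into provenance (`"pairing": "cyclic-CAT"`) and guarded
  at comparison time.
* **Clamped similarity.** The raw similarity $1 - (r_C + r_A + r_T)/3$ can
  go negative for very distant profiles; the percentage clamps to
  $[0, 100]$ and the raw value stays available for diagnostics.
* **Equality tolerance.** "100% match" in collision counting and
  `full_match` means every per-benchmark distance below `1e-12` — numerical
  equality of doubles, far below any score granularity.
* **Serialization.** Sidecar JSON numbers are written with 17 significant
  digits, so `read_profiles(write_profiles(p))` is bit-identical and
  reloaded profiles compare exactly like in-memory ones.
* **Determinism.** Profiles are pure functions of (sequence, provenance);
  Needleman–Wunsch traceback breaks ties deterministically (diagonal, then
  gap in the second sequence, then gap in the first); every sampling
  operation takes an explicit seed.

## What the synthetic data does and does not show

`generate_fixtures()` draws i.i.d. uniform bases, which is exactly the
population over which the collision and self-similarity claims are stated,
and exhaustive enumeration (`enumerate_space()`, `collision_experiment()`)
covers complete $4^n$ spaces, which is stronger than any sampling for the
lengths it reaches. Neither emulates real genomes: no GC bias, repeats,
homopolymer runs, or homology structure. Passing tests therefore establish
the method's internal claims — exact self-similarity, profile uniqueness at
the examined lengths, constant-time comparison — not that the percent
similarity tracks alignment identity on biological data; the method is a
pre-filter whose candidates should be confirmed by alignment, and the
package ships Needleman–Wunsch for exactly that.

Problem sizes used by the test suite: exhaustive collision runs at lengths
8 and 10 (65,536 and 1,048,576 sequences, 1,000 queries each), an
exhaustive length-5 store for search, alignment oracle checks on all pairs
up to length 2 plus seeded pairs up to length 5, and timing probes at
sequence lengths 100–50,000 for the constant-time trend. Timings are
asserted only as qualitative trends (profile comparison flat in length,
alignment growing), never as wall-clock values, which are hardware-bound.

## Known limitations

* Collision-freeness is verified exhaustively only at the enumerated
  lengths; nothing is proved for longer sequences, and profiles of
  sequences of *different* lengths can in principle coincide.
* The similarity percentage is a heuristic score, not a metric with an
  alignment interpretation; negative raw values are clamped.
* Only the `{A,C,G,T}` alphabet is scored. `N`/IUPAC codes are rejected by
  default; the opt-in `ambiguous = "zero"` mode scores them as silent
  positions, which biases distances low for N-rich sequences.
* The literal recurrence ties `bonusTotal` to sequence length, so profiles
  are comparable across lengths arithmetically but the collision guarantees
  are stated within one length.
* An area-overlap refinement of stage two (comparing the triangles as
  polygons rather than by vertex distance) exists as an idea in the
  literature; it is out of scope here.
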