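---
title: "CGR indexes for DNA string matching: model, guarantees, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CGR indexes for DNA string matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrmatch)
```

## The map and why its geometry carries string structure

Chaos Game Representation drives an iterated function system over the
unit square: starting from `x0`, each base moves the current point a
fraction `r` of the way toward that base's corner (A, C, G, T at the
four corners).  After encoding a prefix `S[..i]`, the point's position
is dominated by the most recent symbols — the last base decides the
quadrant, the one before it the sub-quadrant, and so on.  Two prefixes
ending in the same `L` bases therefore lie within `(1-r)^L` of each
other, which for the classical `r = 1/2` gives the familiar `2^-L`
bound.

That bound is only necessary.  In base 2 a subtraction can carry
*through* the digit where two strings first disagree: `AT` maps to
(0.625, 0.625) and `TA` to (0.375, 0.375), a distance of 0.25,
although the strings share no suffix at all.  Padding the pair to
`A...AT` / `T...TA` drives the distance toward zero while the true
common suffix stays 0, so no threshold rescues the estimate.

The fix is arithmetic, not geometric: with `r = 2/3` and
`x0 = (2/3, 2/3)` every coordinate has a base-3 expansion that uses
only the digits 0 and 2 (the Cantor set).  With the digit 1 never
present, a carry cannot mask the first disagreeing digit, and

`|x_i - x_j|_inf < 3^-L`  ⇔  the two prefixes share an `L`-long suffix.

The digit expansion is explicit: digit `m` (most significant first) of
the prefix-`i` coordinate is twice the axis bit of `S[i - m + 1]`,
followed by a terminator digit 2 and zeros contributed by `x0`.  The
encoding is lossless — `decodeSequence()` inverts it — and the
equivalence turns one subtraction plus one base-3 logarithm into a
longest-common-suffix oracle.  Longest common *extension* (LCE)
queries, the primitive behind all algorithms here, are the same query
on the reversed strings, so each bundle (`cgrBundle`) keeps indexes of
the transforms an algorithm needs: reverse for LCE, reverse complement
for palindrome arms.

## Backends and numerical choices

Two index backends share one query interface:

* **float** — an `(N+1) × 2` double matrix filled by the recurrence
  (a linear recursive filter, O(N)).  A query computes
  `floor(-log3 d)` and then verifies the result against the adjacent
  powers of 3, because the logarithm itself can land on the wrong side
  of a boundary by rounding.  Base-3 digits beyond position ~32 sink
  below double resolution, so queries whose answer would reach 30
  shared bases (`.LMAX = 30`) are re-answered by exact digit
  comparison.  The fallback makes float results exact at every length
  while keeping the common case a constant-time arithmetic step.
* **exact** — the per-symbol vertex bits, from which any prefix's
  digit string is read off without rounding.  A query counts common
  leading digits on both axes at once; on w-bit words this is the
  classic word-packed comparison, and in R it is one vectorized
  equality scan.

Two conventions guard the theorem's edge cases.  The equivalence is
proven for equal prefix lengths; for unequal `(i, j)` the `x0`
terminator digit of the shorter coordinate can collide with a content
digit of the longer one (query `G` vs `GG`: the digit strings share
two leading digits on one axis although only one symbol matches), so
all results are clamped to `min(i, j)`.  Coincident coordinates (a
zero distance, where the logarithm is undefined) return that clamped
maximum.  A nonzero distance is never an exact power of 3 — the
difference of two digit-{0,2} expansions with terminators has its
first nonzero digit strictly between consecutive powers — so the
floor-based rule needs no tie-break.

The `leftInsert` operation uses the update
`x + r (1-r)^N (y - x0)` for a string of length `N` before the edit.
This exponent is forced by the closed form
`x_i = (1-r)^i x0 + r Σ (1-r)^{i-k} y_k`: the prepended symbol becomes
the `k = 1` term with weight `r (1-r)^N`, and only this choice makes
`leftDelete` (which removes a weight-`r (1-r)^{N-1}` term) its exact
inverse, as the round-trip tests verify bit-exactly on the digit
backend.

The naive base-2 estimate is deliberately retained
(`naiveBase2Estimate`) as the demonstration of the carry artifact.  It
is implemented as the leading-zero count `max{l : d < 2^-l}`, the
form that is a true upper bound on the common-suffix length; on the
textbook examples (distances that are exact powers of two) it equals
the printed `floor(-log2 d) - 1` values.

## The algorithms on top of LCE

**Matching.**  `matchesScan` asks one LCE per window start; a window
is an occurrence iff the extension reaches the pattern's end.
`kMismatchMatches` intercalates extensions with jumps over single
mismatches, at most `k + 1` extensions per window (asserted by
instrumentation in the tests), reporting each hit's exact Hamming
distance.

**Quadtree.**  `qtBuild` inserts reversed prefixes into a four-way
digital search tree, first-empty-slot, children in fixed A, C, G, T
order — deliberately the naive quadratic-worst-case construction,
because it reproduces the tree shape of the worked `GACGA` example
node for node; a linear suffix-tree-style construction would not.
Search descends along the reversed pattern: path nodes are certified
as occurrences with one LCE each (their stored position may be a full
match even though the node sits above depth `L`), and on reaching
depth `L` the whole subtree is reported, giving O(L + occ).

**Palindromes.**  A complemented palindrome's left arm equals the
reverse complement of its right arm, so the backward extension from a
center is a forward extension over the reverse complement of S:
radius = one longest-common-suffix query between the direct index at
`i` and the reverse-complement index at `N - i - g`.  Fixed gaps shift
the right-arm anchor; mismatch budgets reuse the kangaroo walk.  Only
even-total-length (complemented) palindromes are in scope; mirror
repeats are not.

**Tandem repeats.**  The divide-and-conquer recursion tests, at each
block midpoint `m` and radius `rho`, the anchors `m` and `m - rho`:
one backward and one forward extension bound the run of period-`rho`
agreement around the anchor, and every window of `rho` consecutive
agreeing positions inside the run is a tandem start.  The two anchors
cover the two ways a tandem can cross the midpoint (first copy
containing `m`, or second copy crossing the boundary), every repeat is
found at exactly the recursion node whose midpoint it crosses, and
duplicates discovered at several anchors are removed by
`(start, radius)` key.  Both primitive and non-primitive repeats are
reported (the `TTATTA` example wants the nested radius-1 and radius-3
hits).  With mismatch budgets the walks collect up to `k + 1` mismatch
positions per side and each candidate window is filtered by its exact
in-window count.  Correctness is anchored to an O(N³) brute-force
oracle in the tests; the query count is checked to grow as
O(N log N).

**Longest common substring.**  All prefix coordinates of both strings
are sorted in quadrant order — sub-squares (0,0), (0,1), (1,1), (1,0),
i.e. reversed prefixes compared lexicographically under A < C < T < G —
using a comparator that skips shared quadrants with one LCE.  The
maximal cross-string common suffix is attained at an adjacent pair of
the sorted order (the suffix-array adjacency argument), so one linear
scan finds it.  Ties between identical reversed prefixes are refined
by (length, origin, position); any total refinement preserves the
adjacency property.  A comparison-based merge sort is used because the
order is defined by the comparator, not by a materializable key.

**Rolling hash.**  The CGR recurrence is itself a rolling hash: a
window slides by one left deletion plus one iteration,
`h' = (1-r) h - r (1-r)^L (y_out - x0) + r y_in`.  The float mode is
faithful to that update but drifts at the
10^-15-per-roll level (bounded to < 10^-9 over a 10^4-base pass in the
tests), and long windows push `(1-r)^L` below double resolution.  The
default modular mode therefore carries the window's scaled digit
polynomial `Σ d_t 3^{t-1}` per axis modulo the Mersenne prime
`2^61 - 1` — exact for any window length, rolled with one modular
multiply-add (implemented in C++, since 61-bit modular products need
128-bit intermediates).  A hash hit requires both axes to match and is
always verified with one LCE before being reported, so Rabin–Karp
output equals the scan's deterministically.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `variant` | `"cantor"` | `r = 2/3`, `x0 = (2/3, 2/3)`; required by every matching algorithm.  `"standard"` (`r = 1/2`) supports coordinate dumps, the k-mer grid and the naive estimate. |
| `backend` | `"float"` | per-query O(1) arithmetic with exact fallback; `"exact"` digit comparison, exact at any length. |
| `gap` | 0 | spacer between palindrome arms (fixed-gap variant); unbounded-gap inverted repeats are out of scope. |
| `k` | 0 | mismatch budget (Hamming); `k >= |P|` makes every window a hit. |
| `minRadius` | 1 | smallest palindrome/tandem radius reported. |

Custom `r`/`x0` values (random start, circular seeding) are accepted
for coordinate dumps only: the suffix equivalence is proven for the
Cantor preset, and the matching algorithms pin it.

Positions are 1-based inclusive everywhere in the API, with
`toBed()`/`fromBed()` converting to 0-based half-open at the I/O
boundary.  Non-ACGT input is rejected naming the offending position
(CGR is undefined off the alphabet); `readFasta(policy = "split")`
optionally treats each maximal ACGT run as its own record with the
original interval recorded in the id.  Lowercase is folded to upper.

## What the synthetic generator does and does not emulate

`randomDna` draws i.i.d. uniform bases; `makeFixture` overwrites a
seeded background with planted matches, tandems or palindromes and
returns machine-readable truth.  This emulates the uniform random
sequences used for the package's property tests and matches the
worked examples' scale; it does not emulate the composition bias,
long-range correlation or repeat families of real genomes.  Passing
tests therefore certify algorithmic correctness (agreement with
brute-force oracles on every tested instance, planted features
recovered exactly), not biological discovery performance; on real
sequences the algorithms remain exact but output sizes (`occ`, `z`)
and hence running times will differ from the uniform-background
expectations.

Test problem sizes were chosen so the whole suite runs in minutes on
one core while still exercising every boundary: exhaustive
position-pair grids up to length 128 (float) and 512 (exact,
sampled), 200 random text/pattern pairs per engine, repeat oracles up
to length 200, and a 10^4-base rolling-hash pass.

## Known limitations

* Quadtree construction is worst-case quadratic (degenerate texts);
  the linear-time alternative is deliberately not implemented.
* The float backend's constant-time claim holds per query in the
  word-RAM sense; in R the constant is an interpreted-function call.
* Only substitutions are modelled (`k`-mismatch); edit-distance
  (indel) matching is out of scope, as are non-DNA alphabets.
* `longestCommonSubstring` reports one witness pair, not all of them.
* Unbounded-gap separated palindromes (general inverted repeats) are
  not offered; the gap must be fixed per call.
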