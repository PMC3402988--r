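# cgrmatch

String matching for DNA through Chaos Game Representation (CGR).

## The problem and the idea

CGR maps every prefix `S[..i]` of a DNA string onto a point of the unit
square by iterating

    x_0 = (1/2, 1/2)
    x_i = x_{i-1} + r (y_i - x_{i-1}),    r = 1/2

where `y_i` is the corner assigned to the i-th base (A = (0,0),
C = (0,1), G = (1,0), T = (1,1)).  Prefixes that end in the same
`L`-long suffix land within `2^-L` of each other — but the converse
fails: a binary carry can make unrelated prefixes look close (`AT` and
`TA` sit 0.25 apart, mimicking a shared suffix of length 1 that does
not exist).

Re-embedding the map in the **Cantor set** — contraction ratio
`r = 2/3`, start point `(2/3, 2/3)`, so every coordinate has a base-3
expansion using only the digits 0 and 2 — removes the carry artifact.
Under that embedding,

    |x_i^{S1} - x_j^{S2}|_inf < 3^-L   <=>   the prefixes share an L-long suffix,

an equivalence, not just a necessary condition.  A coordinate table
therefore answers **longest common extension (LCE) queries in constant
time** (one logarithm, or a digit comparison on the exact backend), and
classical string algorithms that are built from LCE queries can run on
the coordinates directly:

* exact pattern matching and counting (`matchesScan`, `countScan`) —
  one LCE per window, O(N);
* k-mismatch matching (`kMismatchMatches`) — at most k+1 LCE
  "kangaroo" extensions per window, O(kN);
* maximal complemented palindromes, exact / fixed-gap / k-mismatch
  (`palindromeRadius`, `allMaximalPalindromes`) — O(N) to O(kN);
* all tandem repeats, exact and k-mismatch (`allTandemRepeats`,
  `kMismatchTandemRepeats`) — divide and conquer with two LCEs per
  midpoint/radius, O(N log N + z);
* longest common substring (`longestCommonSubstring`) — quadrant-order
  sorting of the merged coordinates, O((N+M) log (N+M));
* a quadtree / CGR-tree index (`qtBuild`, `qtMatches`) with
  O(L + occ) search;
* a rolling hash for Rabin–Karp search (`rkHashInit`, `rkRoll`,
  `rabinKarpSearch`, `rkIndex`) — the CGR recurrence itself rolls in
  O(1); the default modular mode reduces the base-3 digit polynomial
  modulo the Mersenne prime 2^61 − 1 and is exact for any window
  length.

Indexes come in two backends: `float` (an N×2 coordinate matrix) and
`exact` (the base-3 digit representation, lossless at any length);
float queries that would exceed double precision fall back to exact
digit comparison transparently, so results are always exact.

## A worked example

```r
library(cgrmatch)

# the carry artifact, and its Cantor fix
std <- function(s) cgrIndex(s, variant = "standard")
cgrCoord(std("AT"), 2)                                   # 0.625 0.625
cgrCoord(std("TA"), 2)                                   # 0.375 0.375
naiveBase2Estimate(std("AT"), 2, std("TA"), 2)           # 1  (wrong)
longestCommonSuffix(cgrIndex("AT"), 2, cgrIndex("TA"), 2) # 0 (right)

# repeats
allMaximalPalindromes("TTATAA")
#>   center gap radius mismatches start end
#> 1      2   0      1          0     2   3
#> 2      3   0      3          0     1   6
#> 3      4   0      1          0     4   5
allTandemRepeats("TTATTA")[, c("start", "radius")]
#>   start radius
#> 1     1      1
#> 2     1      3
#> 3     4      1

# search
matchesScan("GACGA", "GA")$start      # 1 4
qtSerialize(qtBuild("GACGA"))
#> [2: [,, 5: [,,,],], 3: [,,,], 1: [, 4: [,,,],,],]
longestCommonSubstring("GATTACA", "TTACCC")$substring   # "TTAC"
```

`TTATAA` carries complemented palindromes of radius 1 (`AT`), 2
(`TATA`) and 3 (the full string); only the radius-3 one is maximal at
its center.  `TTATTA` contains the tandem repeat `TT` at positions 1
and 4 and the full-string tandem `TTATTA` of radius 3.

## Command line

A thin `cgrmatch` script (installed under `exec/`) exposes the same
operations: `coords`, `lce`, `match`, `count`, `palindromes`,
`tandems`, `lcs`, `kmers`, `random`.  Output is TSV with 1-based
inclusive coordinates, or BED (0-based half-open) with `--bed`.

```sh
cgrmatch tandems genome.fa --min-radius 2
cgrmatch match genome.fa --pattern GATTACA --engine quadtree
cgrmatch coords seq.fa --variant cantor --backend exact --out coords.tsv
```

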