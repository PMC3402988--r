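# Longest common suffix / extension queries, the flawed base-2 estimate,
# suffix/prefix predicates.

test_that("cantor longest common suffix matches hand-checked cases", {
  expect_identical(longestCommonSuffix(cgrIndex("AT"), 2, cgrIndex("TA"), 2),
                   0L)
  idx <- cgrIndex("GATTACA")
  expect_identical(longestCommonSuffix(idx, 5, idx, 5), 5L)
  expect_identical(longestCommonSuffix(cgrIndex("GAT"), 3,
                                       cgrIndex("CAT"), 3), 2L)
  # the min(i, j) clamp against the x0-tail collision
  expect_identical(longestCommonSuffix(cgrIndex("G"), 1,
                                       cgrIndex("GG"), 2), 1L)
  expect_error(longestCommonSuffix(cgrIndex("ACGT", variant = "standard"), 2,
                                   cgrIndex("ACGT"), 2), "cantor")
  expect_error(longestCommonSuffix(idx, 0, idx, 3), "out of range")
})

test_that("longest common suffix equals the brute-force oracle on all pairs", {
  set.seed(201)
  # float backend, exhaustive grids
  for (rep in 1:3) {
    n1 <- sample(30:64, 1); n2 <- sample(30:64, 1)
    s1 <- rndDna(n1); s2 <- rndDna(n2)
    i1 <- cgrIndex(s1); i2 <- cgrIndex(s2)
    for (i in seq_len(n1)) for (j in seq_len(n2))
      expect_identical(longestCommonSuffix(i1, i, i2, j),
                       oracleLcs(s1, i, s2, j))
  }
  # exact backend, longer sequences, exhaustive grid
  s1 <- rndDna(128); s2 <- rndDna(128)
  e1 <- cgrIndex(s1, backend = "exact"); e2 <- cgrIndex(s2, backend = "exact")
  for (i in seq_len(128)) for (j in seq_len(128))
    expect_identical(longestCommonSuffix(e1, i, e2, j),
                     oracleLcs(s1, i, s2, j))
  # long shared suffixes cross the float precision cap transparently
  core <- rndDna(120)
  s1 <- paste0("A", core); s2 <- paste0("C", core)
  f1 <- cgrIndex(s1); f2 <- cgrIndex(s2)
  expect_identical(longestCommonSuffix(f1, 121, f2, 121), 120L)
  expect_identical(longestCommonSuffix(f1, 121, f1, 121), 121L)
})

test_that("base-2 estimate over-reports on the AT/TA family but bounds truth", {
  std <- function(s) cgrIndex(s, variant = "standard")
  expect_identical(naiveBase2Estimate(std("AT"), 2, std("TA"), 2), 1L)
  s1 <- paste0(strrep("A", 19), "T")
  s2 <- paste0(strrep("T", 19), "A")
  expect_identical(naiveBase2Estimate(std(s1), 20, std(s2), 20), 19L)
  expect_identical(longestCommonSuffix(cgrIndex(s1, backend = "exact"), 20,
                                       cgrIndex(s2, backend = "exact"), 20),
                   0L)
  idx <- std("GATTACA")
  expect_identical(naiveBase2Estimate(idx, 4, idx, 4), 4L)
  expect_error(naiveBase2Estimate(cgrIndex("AT"), 2, cgrIndex("TA"), 2),
               "standard")
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    s1 <- rndDna(n); s2 <- rndDna(n)
    i <- sample(n, 1); j <- sample(n, 1)
    est <- naiveBase2Estimate(std(s1), i, std(s2), j)
    expect_gte(est, oracleLcs(s1, i, s2, j))
  }
})

test_that("shared suffixes put standard coordinates within 2^-L (necessary only)", {
  set.seed(203)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    s1 <- rndDna(n)
    # keep L within float resolution: near L ~ 50 the true distance
    # falls below the ulp of the coordinates and quantizes to 2^-L
    L <- sample(min(n - 1, 40), 1)
    s2 <- paste0(rndDna(n - L), substr(s1, n - L + 1, n))
    x1 <- cgrCoord(cgrIndex(s1, variant = "standard"), n)
    x2 <- cgrCoord(cgrIndex(s2, variant = "standard"), n)
    expect_lt(max(abs(x1 - x2)), 2^-L)
  }
  # the converse fails: AT and TA are within 2^-1 with no common suffix
  d <- max(abs(cgrCoord(cgrIndex("AT", variant = "standard"), 2) -
               cgrCoord(cgrIndex("TA", variant = "standard"), 2)))
  expect_lt(d, 2^-1)
})

test_that("LCE equals the brute-force prefix-extension oracle", {
  expect_identical(lce("ACGT", 2, "TCGT", 2), 3L)
  expect_identical(lce("AT", 1, "TA", 1), 0L)
  s <- "GATTACA"
  b <- cgrBundle(s, which = "reverse")
  for (i in 1:7) expect_identical(lce(b, i, b, i), 7L - i + 1L)
  expect_error(lce(cgrBundle(s, which = "direct"), 1, s, 1), "reverse")
  set.seed(204)
  for (rep in 1:40) {
    n <- sample(2:80, 1); m <- sample(2:80, 1)
    s1 <- rndDna(n); s2 <- rndDna(m)
    b1 <- cgrBundle(s1, which = "reverse")
    b2 <- cgrBundle(s2, which = "reverse")
    for (t in 1:10) {
      i <- sample(n, 1); j <- sample(m, 1)
      expect_identical(lce(b1, i, b2, j), oracleLce(s1, i, s2, j))
    }
  }
})

test_that("isSuffix / isPrefix answer through a single LCE query", {
  expect_true(isSuffix("GA", "GACGA"))
  expect_true(isPrefix("GA", "GACGA"))
  expect_false(isSuffix("AT", "TA"))
  expect_false(isPrefix("AT", "TA"))
  expect_false(isSuffix("GACGAT", "GACGA"))   # longer than text, not an error
  set.seed(205)
  for (rep in 1:50) {
    s <- rndDna(sample(5:60, 1))
    n <- nchar(s)
    l <- sample(n, 1)
    expect_true(isSuffix(substr(s, n - l + 1, n), s))
    expect_true(isPrefix(substr(s, 1, l), s))
    p <- rndDna(l)
    expect_identical(isSuffix(p, s), substr(s, n - l + 1, n) == p)
    expect_identical(isPrefix(p, s), substr(s, 1, l) == p)
  }
})

test_that("query time is flat in text length (loose O(1) check)", {
  set.seed(206)
  mk <- function(n) cgrIndex(rndDna(n))
  small <- mk(100); big <- mk(8000)
  tSmall <- system.time(for (r in 1:4000)
    longestCommonSuffix(small, 50L, small, 60L))["elapsed"]
  tBig <- system.time(for (r in 1:4000)
    longestCommonSuffix(big, 4000L, big, 6000L))["elapsed"]
  expect_lt(tBig, tSmall * 25 + 0.5)
})
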