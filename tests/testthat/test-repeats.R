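# Complemented palindromes and tandem repeats.

test_that("palindrome radii match the worked examples", {
  expect_identical(palindromeRadius("TTATAA", 3)$radius, 3L)
  expect_identical(palindromeRadius("TATA", 2)$radius, 2L)
  expect_identical(palindromeRadius("AT", 1)$radius, 1L)
  expect_identical(palindromeRadius("TTATAA", 5)$radius, 0L)
  expect_error(palindromeRadius("TTATAA", 6), "out of range")
  expect_error(palindromeRadius("TTATAA", 3, gap = 5), "right arm")
})

test_that("gapped and k-mismatch radii agree with a brute-force check", {
  bruteRadius <- function(s, i, g, k) {
    cs <- chars(s); n <- length(cs)
    maxRho <- min(i, n - i - g)
    if (maxRho < 1L) return(list(radius = 0L, mismatches = 0L))
    t <- seq_len(maxRho)
    cm <- cumsum(cs[i - t + 1L] != compChars(cs[i + g + t]))
    ok <- which(cm <= k)
    if (!length(ok)) return(list(radius = 0L, mismatches = 0L))
    list(radius = max(ok), mismatches = as.integer(cm[max(ok)]))
  }
  got <- palindromeRadius("AAGTAA", 2, gap = 2)
  expect_identical(got, bruteRadius("AAGTAA", 2, 2, 0))
  set.seed(501)
  for (rep in 1:60) {
    s <- rndDna(sample(4:120, 1))
    n <- nchar(s)
    g <- sample(0:min(3, n - 2), 1)
    i <- sample(n - g - 1, 1)
    k <- sample(0:2, 1)
    expect_identical(palindromeRadius(s, i, gap = g, k = k),
                     bruteRadius(s, i, g, k))
  }
})

test_that("all maximal palindromes equal the all-centers oracle", {
  got <- allMaximalPalindromes("TTATAA")
  expect_identical(got$center, c(2L, 3L, 4L))
  expect_identical(got$radius, c(1L, 3L, 1L))
  expect_identical(got$start[got$center == 3L], 1L)
  expect_identical(got$end[got$center == 3L], 6L)
  tata <- allMaximalPalindromes("TATA")
  expect_identical(tata$radius[tata$center == 2L], 2L)
  expect_identical(nrow(allMaximalPalindromes("AAAA")), 0L)
  set.seed(502)
  for (rep in 1:40) {
    s <- rndDna(sample(4:150, 1))
    for (k in 0:2) {
      got <- allMaximalPalindromes(s, k = k)
      ref <- oraclePalindromes(s, k = k)
      expect_identical(got$center, ref$center)
      expect_identical(got$radius, ref$radius)
      expect_identical(got$mismatches, ref$mismatches)
    }
  }
})

test_that("reported palindrome radii are maximal under the budget", {
  set.seed(503)
  for (rep in 1:25) {
    s <- rndDna(sample(10:100, 1))
    cs <- chars(s); n <- length(cs)
    k <- sample(0:2, 1)
    got <- allMaximalPalindromes(s, k = k)
    for (r in seq_len(nrow(got))) {
      i <- got$center[r]; rho <- got$radius[r]
      if (rho + 1L > min(i, n - i)) next  # no room to extend
      t <- seq_len(rho + 1L)
      expect_gt(sum(cs[i - t + 1L] != compChars(cs[i + t])), k)
    }
  }
})

test_that("tandem repeats match the printed examples and the O(N^3) oracle", {
  got <- allTandemRepeats("TTATTA")
  expect_identical(got[c("start", "radius")],
                   data.frame(start = c(1L, 1L, 4L), radius = c(1L, 3L, 1L)))
  got <- allTandemRepeats("AAAA")
  expect_identical(got[c("start", "radius")],
                   data.frame(start = c(1L, 1L, 2L, 3L),
                              radius = c(1L, 2L, 1L, 1L)))
  expect_identical(nrow(allTandemRepeats("ACGT")), 0L)
  set.seed(504)
  for (rep in 1:40) {
    s <- rndDna(sample(2:100, 1))
    got <- allTandemRepeats(s)
    ref <- oracleTandems(s)
    expect_identical(got[c("start", "radius", "mismatches")], ref)
  }
})

test_that("planted tandem repeats of period 2-6 are all recovered", {
  set.seed(505)
  for (rep in 1:10) {
    period <- sample(2:6, 1)
    unit <- rndDna(period)
    at <- sample(1:80, 1)
    fx <- makeFixture(100, seed = 500 + rep,
                      plants = list(list(kind = "tandem",
                                         payload = strrep(unit, 2),
                                         at = at)))
    expect_identical(fx$truth$radius, period)
    got <- allTandemRepeats(fx$sequence)
    expect_true(any(got$start == at & got$radius == period))
  }
})

test_that("k-mismatch tandem repeats equal the Hamming oracle", {
  got <- kMismatchTandemRepeats("TTCTTA", 1)
  expect_true(any(got$start == 1L & got$radius == 3L & got$mismatches == 1L))
  set.seed(506)
  for (rep in 1:25) {
    s <- rndDna(sample(2:80, 1))
    for (k in 1:2) {
      got <- kMismatchTandemRepeats(s, k)
      ref <- oracleTandems(s, k = k)
      expect_identical(got[c("start", "radius", "mismatches")], ref)
      exact <- allTandemRepeats(s)
      # exact hits are a subset of any k-mismatch result
      expect_true(all(paste(exact$start, exact$radius) %in%
                      paste(got$start, got$radius)))
    }
  }
  # saturated budget: every window is a hit
  s <- "ACGTAC"
  got <- kMismatchTandemRepeats(s, 6)
  ref <- oracleTandems(s, k = 6)
  expect_identical(got[c("start", "radius", "mismatches")], ref)
  expect_identical(nrow(got), 9L)   # all (start, radius) windows of N = 6
})

test_that("exact tandem detection issues O(N log N) LCE queries", {
  set.seed(507)
  for (n in c(200L, 800L)) {
    s <- rndDna(n)
    got <- allTandemRepeats(s, instrument = TRUE)
    expect_lt(attr(got, "lceQueries"), 10 * n * log2(n))
  }
})
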