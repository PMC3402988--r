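# Core encoding: coordinate construction, closed form, bundles, edits,
# exact digits, decoding, sub-square k-mer counts.

test_that("standard and cantor encodings reproduce hand-computed coordinates", {
  expect_equal(cgrCoord(cgrIndex("AT", variant = "standard"), 2),
               c(0.625, 0.625))
  expect_equal(cgrCoord(cgrIndex("TA", variant = "standard"), 2),
               c(0.375, 0.375))
  expect_equal(cgrCoord(cgrIndex("GA", variant = "standard"), 2),
               c(0.375, 0.125))
  # cantor: "AT" has per-axis base-3 digits 0.202..., value 20/27
  expect_equal(cgrCoord(cgrIndex("AT", backend = "exact"), 2),
               c(20 / 27, 20 / 27))
  d <- cgrDigits(cgrIndex("AT", backend = "exact"), 2)
  expect_identical(d@x1, c(2L, 0L))
  expect_identical(d@x2, c(2L, 0L))
  expect_equal(cgrClosedForm("A", 1, variant = "cantor"), c(2 / 9, 2 / 9))
  expect_equal(cgrClosedForm("AT", 2, variant = "standard"), c(0.625, 0.625))
  expect_equal(cgrClosedForm("ACGT", 0, variant = "standard"), c(0.5, 0.5))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(cgrIndex(""), "non-empty")
  expect_error(cgrIndex("ACNGT"), "position 3")
  expect_error(cgrIndex("ACGT", variant = "standard", backend = "exact"),
               "unsupported configuration")
  expect_error(cgrCoord(cgrIndex("ACGT"), 5), "out of range")
  expect_error(cgrClosedForm("ACGT", -1), "out of range")
  # lowercase is accepted and uppercased
  expect_identical(cgrSequence(cgrIndex("acgt")), "ACGT")
})

test_that("iterative and closed-form coordinates agree on random sequences", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(1:200, 1)
    s <- rndDna(n)
    i <- sample(n, 1)
    for (v in c("standard", "cantor")) {
      idx <- cgrIndex(s, variant = v)
      expect_lt(max(abs(cgrCoord(idx, i) - cgrClosedForm(s, i, variant = v))),
                1e-12)
    }
  }
})

test_that("exact digit strings evaluate to the closed-form sum as rationals", {
  set.seed(102)
  for (rep in 1:20) {
    n <- sample(1:30, 1)   # 3^(n+1) stays exactly representable
    s <- rndDna(n)
    idx <- cgrIndex(s, backend = "exact")
    for (i in seq_len(n)) {
      d <- cgrDigits(idx, i)
      # integer numerator over 3^(i+1), from the digit string...
      numDigits <- sum(d@x1 * 3^(i + 1 - seq_len(i))) + 2
      # ...and from the closed-form sum 2*3^-i/3 + sum 2*3^(k-i-1)*y_k
      bits <- as.integer(chars(substr(s, 1, i)) %in% c("G", "T"))
      numSum <- 2 + sum(2 * bits * 3^(seq_len(i)))
      expect_identical(numDigits, numSum)
      expect_equal(numDigits / 3^(i + 1), cgrCoord(idx, i)[1])
    }
  }
})

test_that("bundles encode the declared sequence transforms", {
  b <- cgrBundle("GACGA")
  expect_identical(cgrSequence(b@reverse), "AGCAG")
  expect_identical(cgrSequence(b@complement), "CTGCT")
  expect_identical(cgrSequence(b@revcomp), "TCGTC")
  expect_identical(cgrSequence(cgrBundle("AT", which = "revcomp")@revcomp),
                   "AT")
  expect_identical(cgrSequence(cgrBundle("ACG", which = "complement")@complement),
                   "TGC")
  expect_null(cgrBundle("ACGT", which = "direct")@reverse)
})

test_that("left/right insertions and deletions are exact mutual inverses", {
  p <- cgrParams("standard")
  xA <- cgrCoord(cgrIndex("A", variant = "standard"), 1)
  xGA <- cgrCoord(cgrIndex("GA", variant = "standard"), 2)
  expect_equal(leftInsert(xA, "G", 1, p), xGA)
  expect_equal(leftDelete(xGA, "G", 2, p), xA)
  expect_equal(leftInsert(c(0.5, 0.5), "A", 0, p), c(0.25, 0.25))
  expect_equal(leftDelete(xA, "A", 1, p), c(0.5, 0.5))
  expect_equal(rightInsert(cgrCoord(cgrIndex("G", variant = "standard"), 1),
                           "A", p), xGA)
  expect_equal(rightDelete(xGA, "A", p), c(0.75, 0.25))
  expect_error(rightDelete(c(0.5, 0.5), "A", p), "empty")

  set.seed(103)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    s <- rndDna(n)
    a <- sample(c("A", "C", "G", "T"), 1)
    for (v in c("standard", "cantor")) {
      pp <- cgrParams(v)
      x <- cgrCoord(cgrIndex(s, variant = v), n)
      expect_lt(max(abs(leftDelete(leftInsert(x, a, n, pp), a, n + 1, pp) - x)),
                1e-12)
      expect_lt(max(abs(rightDelete(rightInsert(x, a, pp), a, pp) - x)),
                1e-12)
    }
  }
})

test_that("digit-space edits mirror string edits bit-exactly", {
  idxAT <- cgrIndex("AT", backend = "exact")
  dT <- leftDelete(cgrDigits(idxAT, 2), "A", 2)
  expect_identical(dT@x1, 2L)   # "T" alone: digit string "2" + tail
  expect_identical(decodeSequence(dT), "T")
  set.seed(104)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    s <- rndDna(n)
    a <- sample(c("A", "C", "G", "T"), 1)
    d <- cgrDigits(cgrIndex(s, backend = "exact"), n)
    expect_identical(decodeSequence(leftInsert(d, a)), paste0(a, s))
    expect_identical(decodeSequence(rightInsert(d, a)), paste0(s, a))
    expect_identical(decodeSequence(leftDelete(d, substr(s, 1, 1))),
                     substr(s, 2, n))
  }
})

test_that("decode inverts encode on random sequences", {
  expect_identical(decodeSequence(list(x1 = c(2L, 0L), x2 = c(2L, 0L))), "AT")
  expect_identical(decodeSequence(list(x1 = integer(0), x2 = integer(0))), "")
  expect_error(decodeSequence(list(x1 = 1L, x2 = 0L)), "0 or 2")
  set.seed(105)
  for (rep in 1:100) {
    n <- sample(1:200, 1)
    s <- rndDna(n)
    idx <- cgrIndex(s, backend = "exact")
    expect_identical(decodeSequence(cgrDigits(idx, n)), s)
  }
})

test_that("sub-square counts equal sliding-window k-mer counts", {
  cnt <- kmerCounts(cgrIndex("GACGA", variant = "standard"), 2)
  expect_identical(cnt, c(AC = 1L, CG = 1L, GA = 2L))
  expect_identical(kmerCounts(cgrIndex("AAAA", variant = "standard"), 1),
                   c(A = 4L))
  expect_error(kmerCounts(cgrIndex("ACGT"), 2), "standard-variant")
  set.seed(106)
  for (rep in 1:25) {
    n <- sample(10:300, 1)
    s <- rndDna(n)
    idx <- cgrIndex(s, variant = "standard")
    expect_identical(sum(kmerCounts(idx, 1)), n)
    for (m in 1:4) {
      ref <- table(substring(s, seq_len(n - m + 1), m:n))
      got <- kmerCounts(idx, m)
      expect_setequal(names(got), names(ref))
      expect_identical(unname(got[names(ref)]), as.integer(ref))
    }
  }
})
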