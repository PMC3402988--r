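# Independent brute-force oracles used to anchor the CGR algorithms.
# All work directly on character vectors and never touch the package's
# coordinate machinery.

rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

compChars <- function(ch) c(A = "T", C = "G", G = "C", T = "A")[ch]

# longest common suffix of s1[..i] and s2[..j], character by character
oracleLcs <- function(s1, i, s2, j) {
  l <- 0L
  while (l < min(i, j) &&
         substr(s1, i - l, i - l) == substr(s2, j - l, j - l))
    l <- l + 1L
  l
}

# longest common prefix of s1[i..] and s2[j..]
oracleLce <- function(s1, i, s2, j) {
  n <- nchar(s1); m <- nchar(s2)
  l <- 0L
  while (i + l <= n && j + l <= m &&
         substr(s1, i + l, i + l) == substr(s2, j + l, j + l))
    l <- l + 1L
  l
}

# exact occurrences via Biostrings (independent of any CGR code path)
oracleSearch <- function(S, P) {
  hits <- Biostrings::matchPattern(P, Biostrings::DNAString(S))
  sort(BiocGenerics::start(hits))
}

# k-mismatch windows with exact Hamming distances
oracleHamming <- function(S, P, k) {
  cs <- chars(S); cp <- chars(P)
  L <- length(cp); n <- length(cs)
  if (L > n) return(data.frame(start = integer(0), mismatches = integer(0)))
  starts <- seq_len(n - L + 1L)
  mism <- vapply(starts, function(i)
    sum(cs[i:(i + L - 1L)] != cp), integer(1))
  data.frame(start = starts[mism <= k], mismatches = mism[mism <= k])
}

# maximal complemented-palindrome radius per center under budget k
oraclePalindromes <- function(S, gap = 0L, k = 0L, minRadius = 1L) {
  cs <- chars(S); n <- length(cs)
  out <- data.frame(center = integer(0), radius = integer(0),
                    mismatches = integer(0))
  top <- n - gap - 1L
  if (top < 1L) return(out)
  for (i in seq_len(top)) {
    maxRho <- min(i, n - i - gap)
    if (maxRho < 1L) next
    t <- seq_len(maxRho)
    neq <- cs[i - t + 1L] != compChars(cs[i + gap + t])
    cm <- cumsum(neq)
    ok <- which(cm <= k)
    if (!length(ok)) next
    rho <- max(ok)
    if (rho >= minRadius)
      out <- rbind(out, data.frame(center = i, radius = rho,
                                   mismatches = cm[rho]))
  }
  out
}

# every (start, radius) tandem window with Hamming distance <= k
oracleTandems <- function(S, k = 0L, minRadius = 1L) {
  cs <- chars(S); n <- length(cs)
  res <- list()
  for (rho in seq_len(n %/% 2L)) {
    if (rho < minRadius) next
    neq <- as.integer(cs[seq_len(n - rho)] != cs[seq_len(n - rho) + rho])
    cm <- c(0L, cumsum(neq))
    starts <- seq_len(n - 2L * rho + 1L)
    mism <- cm[starts + rho] - cm[starts]
    keep <- mism <= k
    if (any(keep))
      res[[length(res) + 1L]] <- data.frame(start = starts[keep],
                                            radius = rho,
                                            mismatches = mism[keep])
  }
  if (!length(res))
    return(data.frame(start = integer(0), radius = integer(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$radius), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# longest common substring length by row-wise dynamic programming
oracleLcsDp <- function(S1, S2) {
  c1 <- chars(S1); c2 <- chars(S2)
  m <- length(c2)
  prev <- integer(m)
  best <- 0L
  for (i in seq_along(c1)) {
    curr <- as.integer(c1[i] == c2) * (c(0L, prev[-m]) + 1L)
    best <- max(best, curr)
    prev <- curr
  }
  best
}

# --- independent base-3 digit arithmetic for the Cantor theorem ------------

# base-3 digit expansion (most significant first, incl. the terminator 2)
# of the Cantor coordinate of s[..i] on one axis
cantorAxisDigits <- function(s, i, axis) {
  ch <- chars(substr(s, 1, i))
  bit <- if (axis == 1) ch %in% c("G", "T") else ch %in% c("C", "T")
  c(2L * as.integer(rev(bit)), 2L)
}

# schoolbook base-3 subtraction |a - b| of equal-length digit vectors;
# returns the digit vector of the absolute difference
sub3 <- function(a, b) {
  cmp <- which(a != b)
  if (!length(cmp)) return(integer(length(a)))
  if (a[cmp[1]] < b[cmp[1]]) { t <- a; a <- b; b <- t }
  d <- integer(length(a))
  borrow <- 0L
  for (m in rev(seq_along(a))) {
    v <- a[m] - b[m] - borrow
    borrow <- if (v < 0L) { v <- v + 3L; 1L } else 0L
    d[m] <- v
  }
  d
}

# min over the two axes of the leading-zero count of the exact base-3
# coordinate difference (Inf when the prefixes are identical)
cantorDiffLeadingZeros <- function(s1, s2, i) {
  lz <- function(axis) {
    d <- sub3(cantorAxisDigits(s1, i, axis), cantorAxisDigits(s2, i, axis))
    nz <- which(d != 0L)
    if (!length(nz)) Inf else nz[1] - 1L
  }
  min(lz(1), lz(2))
}
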