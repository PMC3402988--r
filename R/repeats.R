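# Maximal complemented palindromes (exact, fixed-gap, k-mismatch) and
# tandem repeats (exact and k-mismatch) via LCE queries.

#' Complemented-palindrome radius at a center
#'
#' A complemented palindrome of radius \eqn{\rho} and gap \eqn{g} at
#' center \eqn{i} satisfies: the left arm \code{S[i-rho+1..i]} equals the
#' reverse complement of the right arm \code{S[i+g+1..i+g+rho]}.  The
#' radius is found by one longest-common-suffix query between the direct
#' index at \code{i} and the reverse-complement index at
#' \code{N - i - g} (the backward extension is a forward extension over
#' the reverse complement of S); with a mismatch budget \code{k > 0} the
#' query is repeated after jumping each mismatch, at most \code{k + 1}
#' extensions.
#'
#' @param S text: a string or a \linkS4class{CgrBundle} holding direct
#'   and revcomp cantor indexes.
#' @param center 1-based position of the last symbol of the left arm,
#'   \code{1 <= center < N}.
#' @param gap spacer between the arms, \code{>= 0} (0 = adjacent).
#' @param k mismatch budget, \code{>= 0}.
#' @return list with \code{radius} (maximal under the budget, possibly
#'   0) and \code{mismatches} (exact count within the radius).
#' @examples
#' palindromeRadius("TTATAA", 3)$radius  # 3
#' palindromeRadius("TATA", 2)$radius    # 2
#' @export
palindromeRadius <- function(S, center, gap = 0L, k = 0L) {
  b <- .asBundle(S, c("direct", "revcomp"), "text")
  n <- length(b)
  center <- .checkPos(center, n - 1L, "center")
  stopifnot(gap >= 0L, k >= 0L)
  gap <- as.integer(gap)
  k <- as.integer(k)
  if (center + gap + 1L > n)
    stop("gap ", gap, " leaves no right arm at center ", center)
  .palRadius(b@direct, b@revcomp, n, center, gap, k)
}

.palRadius <- function(direct, revcomp, n, i, g, k) {
  maxRho <- min(i, n - i - g)
  rho <- 0L
  m <- 0L
  repeat {
    e <- .lcsIdx(direct, i - rho, revcomp, n - i - g - rho)
    rho <- rho + min(e, maxRho - rho)
    if (rho >= maxRho || m == k) break
    m <- m + 1L               # jump over the mismatching pair
    rho <- rho + 1L
    if (rho >= maxRho) break
  }
  list(radius = rho, mismatches = m)
}

#' All maximal complemented palindromes
#'
#' Reports, for every center with radius at least \code{minRadius}, the
#' maximal radius under the mismatch budget (only the biggest palindrome
#' per center is extracted).  One LCE walk per center: \eqn{O(N)} for
#' \code{k = 0}, \eqn{O(kN)} otherwise.
#'
#' @param S text string (or bundle as in
#'   \code{\link{palindromeRadius}}).
#' @param gap fixed spacer between arms (0 = adjacent halves).
#' @param k mismatch budget.
#' @param minRadius smallest radius to report.
#' @return data.frame with columns \code{center}, \code{gap},
#'   \code{radius}, \code{mismatches}, \code{start}, \code{end}
#'   (the palindrome spans \code{S[start..end]}), centers ascending.
#' @examples
#' allMaximalPalindromes("TTATAA")
#' @export
allMaximalPalindromes <- function(S, gap = 0L, k = 0L, minRadius = 1L) {
  b <- .asBundle(S, c("direct", "revcomp"), "text")
  n <- length(b)
  stopifnot(gap >= 0L, k >= 0L, minRadius >= 1L)
  gap <- as.integer(gap)
  k <- as.integer(k)
  centers <- radii <- mism <- integer(0)
  top <- n - gap - 1L
  if (top >= 1L) for (i in seq_len(top)) {
    res <- .palRadius(b@direct, b@revcomp, n, i, gap, k)
    if (res$radius >= minRadius) {
      centers <- c(centers, i)
      radii <- c(radii, res$radius)
      mism <- c(mism, res$mismatches)
    }
  }
  data.frame(center = centers, gap = rep(gap, length(centers)),
             radius = radii, mismatches = mism,
             start = centers - radii + 1L,
             end = centers + gap + radii)
}

## ---- tandem repeats -------------------------------------------------------

# Divide-and-conquer (Landau-Schmidt style): at each recursion block
# [lo, hi] with midpoint m, a tandem of radius rho crossing the midpoint
# has its first copy containing anchor m (second copy starts after m) or
# anchor m - rho (second copy crosses the boundary).  For each anchor h
# and radius rho, one backward extension (common suffix of the prefixes
# ending at h and h + rho) and one forward extension (LCE of the
# suffixes at h + 1 and h + rho + 1) bound the run of period-rho
# agreement around h; every window [p, p + rho - 1] inside it yields a
# tandem start.  With a mismatch budget the walks jump over up to k + 1
# mismatching positions per side and hits are filtered by their exact
# in-window mismatch count.
.tandemFind <- function(S, k = 0L, minRadius = 1L, instrument = FALSE) {
  S <- .checkSeq(S, "text")
  n <- nchar(S)
  b <- cgrBundle(S, which = c("direct", "reverse"), variant = "cantor")
  direct <- b@direct
  reverse <- b@reverse
  acc <- new.env(parent = emptyenv())
  acc$start <- acc$radius <- acc$mism <- integer(0)
  acc$queries <- 0L

  lcsq <- function(i, j) {          # backward: common suffix of prefixes
    acc$queries <- acc$queries + 1L
    .lcsIdx(direct, i, direct, j)
  }
  lceq <- function(i, j) {          # forward: LCE of suffixes
    acc$queries <- acc$queries + 1L
    .lcsIdx(reverse, n - i + 1L, reverse, n - j + 1L)
  }

  # scan period-rho agreement left from h (inclusive): return the lowest
  # fully scanned position and up to k+1 mismatch positions found
  bwalk <- function(h, rho, lo) {
    miss <- integer(0)
    t <- h
    while (t >= lo) {
      e <- min(lcsq(t, t + rho), t - lo + 1L)
      t <- t - e
      if (t < lo) break
      miss <- c(miss, t)            # S[t] != S[t + rho]
      if (length(miss) > k) break
      t <- t - 1L
    }
    list(floor = max(t + 1L, lo), miss = miss)
  }
  # scan right from h + 1; agreement position t means S[t] == S[t + rho],
  # only meaningful while t + rho <= hi
  fwalk <- function(h, rho, hi) {
    miss <- integer(0)
    t <- h
    top <- hi - rho
    while (t < top) {
      e <- min(lceq(t + 1L, t + rho + 1L), top - t)
      t <- t + e
      if (t >= top) break
      miss <- c(miss, t + 1L)
      if (length(miss) > k) break
      t <- t + 1L
    }
    list(ceil = min(t, top), miss = miss)
  }

  crossing <- function(h, rho, lo, hi) {
    bw <- bwalk(h, rho, lo)
    fw <- fwalk(h, rho, hi)
    pmin_ <- max(lo, bw$floor, h - rho + 1L)
    pmax_ <- min(h, fw$ceil - rho + 1L, hi - 2L * rho + 1L)
    if (pmax_ < pmin_) return()
    miss <- sort(c(bw$miss, fw$miss))
    p <- pmin_:pmax_
    cnt <- findInterval(p + rho - 1L, miss) - findInterval(p - 1L, miss)
    ok <- cnt <= k
    if (!any(ok)) return()
    acc$start <- c(acc$start, p[ok])
    acc$radius <- c(acc$radius, rep(rho, sum(ok)))
    acc$mism <- c(acc$mism, cnt[ok])
  }

  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L) return()
    m <- (lo + hi) %/% 2L
    for (rho in seq_len(len %/% 2L)) {
      if (m + rho <= hi) crossing(m, rho, lo, hi)
      if (m - rho >= lo) crossing(m - rho, rho, lo, hi)
    }
    recurse(lo, m)
    recurse(m + 1L, hi)
  }
  recurse(1L, n)

  out <- data.frame(start = acc$start, radius = acc$radius,
                    mismatches = acc$mism)
  out <- out[!duplicated(out[c("start", "radius")]), , drop = FALSE]
  out <- out[out$radius >= minRadius, , drop = FALSE]
  out <- out[order(out$start, out$radius), , drop = FALSE]
  rownames(out) <- NULL
  out$end <- out$start + 2L * out$radius - 1L
  if (instrument) attr(out, "lceQueries") <- acc$queries
  out
}

#' All tandem repeats
#'
#' A tandem repeat of radius \eqn{\rho} at start \eqn{p} consists of two
#' adjacent identical copies: \code{S[p..p+rho-1] == S[p+rho..p+2rho-1]}.
#' All of them (primitive and non-primitive) are located by recursive
#' halving with two LCE queries per midpoint/radius pair — a crossing
#' tandem exists iff the backward and forward extensions around the
#' midpoint cover a full period — in \eqn{O(N \log N + z)} time for
#' \eqn{z} reported repeats.
#'
#' @param S text string.
#' @param minRadius smallest radius to report.
#' @param instrument if TRUE, attach attribute \code{"lceQueries"} (the
#'   total number of LCE queries issued).
#' @return data.frame with columns \code{start}, \code{radius},
#'   \code{mismatches} (all 0 here), \code{end}, sorted by
#'   (start, radius).
#' @examples
#' allTandemRepeats("TTATTA")[, c("start", "radius")]
#' @export
allTandemRepeats <- function(S, minRadius = 1L, instrument = FALSE) {
  stopifnot(minRadius >= 1L)
  .tandemFind(S, k = 0L, minRadius = as.integer(minRadius),
              instrument = instrument)
}

#' All k-mismatch tandem repeats
#'
#' Same recursion as \code{\link{allTandemRepeats}} with every LCE
#' replaced by a mismatch-jumping walk of at most \code{k + 1}
#' extensions; hits report the exact Hamming distance between the two
#' copies (\eqn{O(kN \log N + z)}).
#'
#' @param S text string.
#' @param k mismatch budget, \code{>= 1}.
#' @param minRadius smallest radius to report.
#' @return data.frame as in \code{\link{allTandemRepeats}} with exact
#'   \code{mismatches} counts \code{<= k}.
#' @examples
#' kMismatchTandemRepeats("TTCTTA", 1)
#' @export
kMismatchTandemRepeats <- function(S, k, minRadius = 1L) {
  stopifnot(length(k) == 1L, !is.na(k), k >= 1L, minRadius >= 1L)
  .tandemFind(S, k = as.integer(k), minRadius = as.integer(minRadius))
}
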