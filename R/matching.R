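# Standard-index exact matching/counting and k-mismatch approximate
# matching (kangaroo jumps over mismatches, at most k+1 LCE extensions
# per window).

#' Exact pattern matching by LCE scan
#'
#' Slides the pattern over every window start \code{i} and reports an
#' occurrence iff the longest common extension of \code{S[i..]} and
#' \code{P[1..]} equals \code{|P|} — one constant-time query on the
#' reverse cantor indexes per window, \eqn{O(N)} total.
#'
#' @param S text: a string or a \linkS4class{CgrBundle} with a reverse
#'   cantor index.
#' @param P pattern string.
#' @return \code{matchesScan}: data.frame with columns \code{start}
#'   (1-based, ascending) and \code{mismatches} (all 0);
#'   \code{countScan}: integer occurrence count.
#' @examples
#' matchesScan("GACGA", "GA")$start  # 1 4
#' @export
matchesScan <- function(S, P) {
  bS <- .asBundle(S, "reverse", "text")
  P <- .checkSeq(P, "pattern")
  n <- length(bS)
  L <- nchar(P)
  if (L > n)
    return(data.frame(start = integer(0), mismatches = integer(0)))
  revS <- bS@reverse
  revP <- cgrIndex(.revSeq(P),
                   backend = if (revS@backend == "exact") "exact" else "float")
  starts <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    if (.lcsIdx(revS, n - i + 1L, revP, L) == L)
      starts <- c(starts, i)
  }
  data.frame(start = starts, mismatches = integer(length(starts)))
}

#' @rdname matchesScan
#' @export
countScan <- function(S, P) nrow(matchesScan(S, P))

#' Approximate matching with up to k mismatches
#'
#' For each window start the pattern is matched by at most \code{k + 1}
#' LCE extensions: extend, jump over the mismatching position, extend
#' again, until either the end of the pattern is reached (a hit, with
#' its exact Hamming distance) or the budget is exhausted.  Total cost
#' \eqn{O(kN)}.
#'
#' @param S text: a string or a \linkS4class{CgrBundle} with a reverse
#'   cantor index.
#' @param P pattern string.
#' @param k mismatch budget, \code{k >= 0} (\code{k = 0} reduces to
#'   \code{\link{matchesScan}}; \code{k >= |P|} makes every window a
#'   hit).
#' @param instrument if TRUE, attach attribute \code{"extensions"} (the
#'   per-window LCE extension counts) to the result.
#' @return data.frame with columns \code{start} and \code{mismatches}
#'   (exact Hamming distance of the reported window), starts ascending.
#' @examples
#' kMismatchMatches("ACGTACGT", "ACCT", 1)
#' @export
kMismatchMatches <- function(S, P, k, instrument = FALSE) {
  bS <- .asBundle(S, "reverse", "text")
  P <- .checkSeq(P, "pattern")
  stopifnot(length(k) == 1L, !is.na(k), k >= 0L)
  k <- as.integer(k)
  n <- length(bS)
  L <- nchar(P)
  if (L > n) {
    out <- data.frame(start = integer(0), mismatches = integer(0))
    if (instrument) attr(out, "extensions") <- integer(0)
    return(out)
  }
  revS <- bS@reverse
  revP <- cgrIndex(.revSeq(P),
                   backend = if (revS@backend == "exact") "exact" else "float")
  starts <- integer(0)
  mism <- integer(0)
  exts <- integer(n - L + 1L)
  for (i in seq_len(n - L + 1L)) {
    p <- 1L     # next pattern position to match
    m <- 0L
    nx <- 0L
    repeat {
      # LCE of S[i + p - 1 ..] and P[p ..], clamped to the window
      e <- .lcsIdx(revS, n - (i + p - 1L) + 1L, revP, L - p + 1L)
      nx <- nx + 1L
      p <- p + e
      if (p > L) break
      if (m == k) { p <- -1L; break }   # budget exhausted at a mismatch
      m <- m + 1L
      p <- p + 1L                       # jump over the mismatch
      if (p > L) break
    }
    exts[i] <- nx
    if (p > 0L) {
      starts <- c(starts, i)
      mism <- c(mism, m)
    }
  }
  out <- data.frame(start = starts, mismatches = mism)
  if (instrument) attr(out, "extensions") <- exts
  out
}
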