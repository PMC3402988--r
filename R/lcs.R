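# Longest common substring via quadrant-order sorting of the merged CGR
# coordinates and adjacent-pair LCE scanning.

# comparator on (index, position) pairs: lexicographic order of reversed
# prefixes under the quadrant symbol order A < C < T < G, realized as one
# longest-common-suffix query plus one symbol comparison at the first
# divergence; equal full prefixes tie-break by (length, origin, position)
.QRANK <- c(A = 1L, C = 2L, T = 3L, G = 4L)

.coordCmp <- function(idxA, iA, idxB, iB, originA, originB) {
  ell <- .lcsIdx(idxA, iA, idxB, iB)
  if (ell == min(iA, iB)) {
    if (iA != iB) return(if (iA < iB) -1L else 1L)
    if (originA != originB) return(if (originA < originB) -1L else 1L)
    if (iA == iB && originA == originB) return(0L)
  }
  a <- .QRANK[[substr(idxA@seq, iA - ell, iA - ell)]]
  b <- .QRANK[[substr(idxB@seq, iB - ell, iB - ell)]]
  if (a < b) -1L else 1L
}

#' Quadrant order on CGR coordinates
#'
#' Total preorder used to sort merged CGR coordinates for the longest
#' common substring: sub-squares are visited in the order (0,0), (0,1),
#' (1,1), (1,0) — equivalently, reversed prefixes compare
#' lexicographically under the symbol order A < C < T < G.  The
#' comparison skips the shared quadrants with one longest-common-suffix
#' query and then orders by the first divergent symbol.
#'
#' @param index1,index2 cantor \linkS4class{CgrIndex} objects.
#' @param i,j prefix lengths being compared.
#' @param origin1,origin2 stability tie-breaks for equal full prefixes.
#' @return -1, 0 or +1.
#' @examples
#' a <- cgrIndex("TA"); b <- cgrIndex("GA")
#' coordinateOrder(a, 2, b, 2)   # -1: "...TA" sorts before "...GA"
#' @export
coordinateOrder <- function(index1, i, index2, j,
                            origin1 = 1L, origin2 = 2L) {
  stopifnot(is(index1, "CgrIndex"), is(index2, "CgrIndex"))
  .checkCantor(index1); .checkCantor(index2)
  i <- .checkPos(i, length(index1), "i")
  j <- .checkPos(j, length(index2), "j")
  .coordCmp(index1, i, index2, j, origin1, origin2)
}

# stable bottom-up merge sort with a 3-way comparator on element ids
.mergeSortBy <- function(n, cmp) {
  ord <- seq_len(n)
  width <- 1L
  while (width < n) {
    lo <- 1L
    while (lo + width <= n) {
      mid <- lo + width - 1L
      hi <- min(lo + 2L * width - 1L, n)
      left <- ord[lo:mid]
      right <- ord[(mid + 1L):hi]
      merged <- integer(hi - lo + 1L)
      a <- 1L; b <- 1L; t <- 1L
      while (a <= length(left) && b <= length(right)) {
        if (cmp(left[a], right[b]) <= 0L) {
          merged[t] <- left[a]; a <- a + 1L
        } else {
          merged[t] <- right[b]; b <- b + 1L
        }
        t <- t + 1L
      }
      if (a <= length(left)) merged[t:length(merged)] <- left[a:length(left)]
      if (b <= length(right)) merged[t:length(merged)] <- right[b:length(right)]
      ord[lo:hi] <- merged
      lo <- hi + 1L
    }
    width <- 2L * width
  }
  ord
}

#' Longest common substring of two sequences
#'
#' Joins the CGR coordinates of all prefixes of both strings, sorts them
#' in quadrant order (\eqn{O((N+M)\log(N+M))} comparisons, each a
#' constant-time LCE plus one symbol look), then scans consecutive
#' cross-origin pairs: the maximal common suffix over all cross pairs is
#' attained at an adjacent pair in sorted order, and equals the longest
#' common substring.
#'
#' @param S1,S2 non-empty DNA strings.
#' @return list with \code{length}, \code{end1}, \code{end2} (1-based
#'   end positions of one occurrence in each string; NA when the length
#'   is 0) and \code{substring}.
#' @examples
#' longestCommonSubstring("GATTACA", "TTACCC")$substring  # "TTAC"
#' @export
longestCommonSubstring <- function(S1, S2) {
  S1 <- .checkSeq(S1, "S1")
  S2 <- .checkSeq(S2, "S2")
  idx1 <- cgrIndex(S1)
  idx2 <- cgrIndex(S2)
  n <- nchar(S1)
  m <- nchar(S2)
  origin <- c(rep(1L, n), rep(2L, m))
  pos <- c(seq_len(n), seq_len(m))
  idxOf <- function(e) if (origin[e] == 1L) idx1 else idx2
  cmp <- function(a, b)
    .coordCmp(idxOf(a), pos[a], idxOf(b), pos[b], origin[a], origin[b])
  ord <- .mergeSortBy(n + m, cmp)
  best <- 0L
  e1 <- e2 <- NA_integer_
  for (t in seq_len(n + m - 1L)) {
    a <- ord[t]
    b <- ord[t + 1L]
    if (origin[a] == origin[b]) next
    ell <- .lcsIdx(idxOf(a), pos[a], idxOf(b), pos[b])
    if (ell > best) {
      best <- ell
      e1 <- if (origin[a] == 1L) pos[a] else pos[b]
      e2 <- if (origin[a] == 1L) pos[b] else pos[a]
    }
  }
  list(length = best, end1 = e1, end2 = e2,
       substring = if (best > 0L) substr(S1, e1 - best + 1L, e1) else "")
}
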