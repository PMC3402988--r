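# Longest common suffix / longest common extension queries on
# Cantor-embedded indexes, the flawed base-2 estimate, and the derived
# IS PREFIX / IS SUFFIX predicates.

# float suffix comparisons beyond this length fall below double-precision
# resolution of the base-3 digits and are answered by exact digit
# comparison instead
.LMAX <- 30L

# exact common-leading-digit count between prefix coordinates: compare
# the trailing m symbol-bit pairs (both axes at once); m = min(i, j)
# clamps out any x0-terminator collision
.lcsBits <- function(b1, i, b2, j, m) {
  ii <- i - 0:(m - 1L)
  jj <- j - 0:(m - 1L)
  neq <- (b1[ii, 1L] != b2[jj, 1L]) | (b1[ii, 2L] != b2[jj, 2L])
  w <- which(neq)
  if (length(w)) w[1L] - 1L else m
}

# core longest-common-suffix query on cantor indexes; no validation
.lcsIdx <- function(idx1, i, idx2, j) {
  m <- min(i, j)
  if (m <= 0L) return(0L)
  if (idx1@backend == "exact" || idx2@backend == "exact")
    return(.lcsBits(idx1@bits, i, idx2@bits, j, m))
  d <- max(abs(idx1@coords[i + 1L, ] - idx2@coords[j + 1L, ]))
  if (d == 0)                    # truly coincident prefixes agree on all
    return(.lcsBits(idx1@bits, i, idx2@bits, j, m))   # of min(i, j)
  ell <- floor(-log(d) / log(3))
  # boundary verification against powers of 3 (guards float rounding of
  # the logarithm; a nonzero distance is never an exact power of 3)
  while (ell < m && d < 3^-(ell + 1)) ell <- ell + 1
  while (ell > 0 && d >= 3^-ell) ell <- ell - 1
  if (ell < 0) ell <- 0
  if (ell >= .LMAX)              # precision cap: answer exactly instead
    return(.lcsBits(idx1@bits, i, idx2@bits, j, m))
  as.integer(min(ell, m))
}

.checkPos <- function(i, n, what = "i") {
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop("position ", what, " out of range [1, ", n, "]")
  as.integer(i)
}

.checkCantor <- function(idx) {
  if (idx@params@variant != "cantor")
    stop("longest-common-suffix queries require cantor-variant indexes ",
         "(got '", idx@params@variant, "')")
}

#' Longest common suffix of two prefixes, in constant time
#'
#' Returns \eqn{\max\{L \ge 0 : S_1[i-L+1..i] = S_2[j-L+1..j]\}} from the
#' Cantor-embedded coordinates alone: under the cantor preset,
#' \eqn{|x_i - x_j|_\infty < 3^{-L}} holds \emph{if and only if} the two
#' prefixes share an \eqn{L}-long suffix, so the answer is the largest
#' \eqn{L} with the coordinate distance below \eqn{3^{-L}} — one
#' logarithm on the float backend, a common-leading-digit count on the
#' exact backend.  Results are clamped to \code{min(i, j)} (for unequal
#' prefix lengths the x0 terminator digit could otherwise collide with a
#' content digit); coincident coordinates return the clamped maximum.
#'
#' @param index1,index2 cantor-variant \linkS4class{CgrIndex} objects
#'   (any mix of backends; float queries beyond 30 shared bases fall back
#'   to exact digit comparison).
#' @param i,j query positions (prefix lengths), 1-based.
#' @return Integer length of the longest common suffix.
#' @examples
#' longestCommonSuffix(cgrIndex("AT"), 2, cgrIndex("TA"), 2)   # 0
#' longestCommonSuffix(cgrIndex("GAT"), 3, cgrIndex("CAT"), 3) # 2
#' @export
longestCommonSuffix <- function(index1, i, index2, j) {
  stopifnot(is(index1, "CgrIndex"), is(index2, "CgrIndex"))
  .checkCantor(index1); .checkCantor(index2)
  i <- .checkPos(i, length(index1), "i")
  j <- .checkPos(j, length(index2), "j")
  .lcsIdx(index1, i, index2, j)
}

#' The naive base-2 common-suffix estimate (demonstrably unreliable)
#'
#' On standard-variant indexes (\code{r = 1/2}) the coordinate distance
#' below \eqn{2^{-L}} is only a \emph{necessary} condition for an
#' \eqn{L}-long common suffix, so the leading-zero count of the distance,
#' \eqn{\max\{\ell : |x_i - x_j|_\infty < 2^{-\ell}\}}, over-reports
#' whenever a binary carry masks a mismatch: for AT versus TA it returns
#' 1 while the true common suffix is 0, and extending the pair to
#' \eqn{A\cdots AT} / \eqn{T\cdots TA} drives the estimate to
#' \eqn{N - 1}.  Retained to demonstrate the artifact the Cantor
#' embedding removes.
#'
#' @param index1,index2 standard-variant \linkS4class{CgrIndex} objects.
#' @param i,j query positions.
#' @return Integer estimate (an upper bound on the true common-suffix
#'   length); coincident coordinates return \code{min(i, j)}.
#' @examples
#' naiveBase2Estimate(cgrIndex("AT", variant = "standard"), 2,
#'                    cgrIndex("TA", variant = "standard"), 2)  # 1, not 0
#' @export
naiveBase2Estimate <- function(index1, i, index2, j) {
  stopifnot(is(index1, "CgrIndex"), is(index2, "CgrIndex"))
  if (index1@params@variant != "standard" ||
      index2@params@variant != "standard")
    stop("the base-2 estimate is defined for standard-variant indexes")
  i <- .checkPos(i, length(index1), "i")
  j <- .checkPos(j, length(index2), "j")
  m <- min(i, j)
  d <- max(abs(index1@coords[i + 1L, ] - index2@coords[j + 1L, ]))
  if (d == 0) return(as.integer(m))
  ell <- floor(-log2(d))
  while (ell < m && d < 2^-(ell + 1)) ell <- ell + 1
  while (ell > 0 && d >= 2^-ell) ell <- ell - 1
  as.integer(max(0, min(ell, m)))
}

#' Longest common extension (LCE) query
#'
#' Length of the longest common prefix of the suffixes \code{S1[i..]} and
#' \code{S2[j..]}.  By suffix/prefix duality this is the longest common
#' suffix of the corresponding \emph{reversed} prefixes, so the query is
#' answered in constant time on the reverse cantor indexes at positions
#' \code{(N - i + 1, M - j + 1)}, clamped to the remaining lengths.
#'
#' @param bundle1,bundle2 \linkS4class{CgrBundle} objects holding reverse
#'   cantor indexes (plain character sequences are also accepted and
#'   encoded on the fly).
#' @param i,j 1-based suffix start positions.
#' @return Integer extension length.
#' @examples
#' lce("ACGT", 2, "TCGT", 2)  # 3
#' @export
lce <- function(bundle1, i, bundle2, j) {
  bundle1 <- .asBundle(bundle1, "reverse", "S1")
  bundle2 <- .asBundle(bundle2, "reverse", "S2")
  n <- length(bundle1)
  m <- length(bundle2)
  i <- .checkPos(i, n, "i")
  j <- .checkPos(j, m, "j")
  .lcsIdx(bundle1@reverse, n - i + 1L, bundle2@reverse, m - j + 1L)
}

#' Suffix and prefix predicates through LCE
#'
#' \code{isSuffix(P, S)} is true iff the longest common suffix of the full
#' strings (query at positions \code{(|P|, |S|)}) equals \code{|P|};
#' \code{isPrefix} applies the same test to the reversed strings.
#' Patterns longer than the text return \code{FALSE}.
#'
#' @param P pattern string.
#' @param S subject string.
#' @return Logical scalar.
#' @examples
#' isSuffix("GA", "GACGA")  # TRUE
#' isPrefix("GA", "GACGA")  # TRUE
#' @export
isSuffix <- function(P, S) {
  P <- .checkSeq(P, "pattern")
  S <- .checkSeq(S, "subject")
  L <- nchar(P)
  n <- nchar(S)
  if (L > n) return(FALSE)
  .lcsIdx(cgrIndex(P), L, cgrIndex(S), n) == L
}

#' @rdname isSuffix
#' @export
isPrefix <- function(P, S) {
  P <- .checkSeq(P, "pattern")
  S <- .checkSeq(S, "subject")
  if (nchar(P) > nchar(S)) return(FALSE)
  isSuffix(.revSeq(P), .revSeq(S))
}
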