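# CGR rolling hash and Rabin-Karp search.  The CGR recurrence itself is
# a rolling hash: the coordinate of a window updates in constant time
# under a left deletion plus one CGR step.  The float mode uses the
# coordinates directly (faithful to the recurrence, subject to drift);
# the default modular mode carries the window's scaled base-3 digit
# polynomial modulo the Mersenne prime 2^61 - 1, which rolls exactly for
# any window length.

.splitToChar <- function(hl) sprintf("%.0f*2^31+%.0f", hl[1], hl[2])

.rkWindowDigits <- function(bits, i, L) {
  # digit of window position t (t = 1 first symbol), per axis
  idx <- i:(i + L - 1L)
  list(d1 = 2L * bits[idx, 1L], d2 = 2L * bits[idx, 2L])
}

#' Initialize a CGR rolling hash
#'
#' Float mode: the hash of \code{S[i..i+L-1]} is its fresh CGR
#' coordinate.  Modular mode: per axis, the window's scaled base-3 digit
#' polynomial \eqn{\sum_t d_t 3^{t-1}} reduced modulo \eqn{2^{61}-1}
#' (exact for any \code{L}).
#'
#' @param S text string.
#' @param i window start (1-based).
#' @param L window length, \code{L >= 1}.
#' @param params a \linkS4class{CgrParams} (float mode; default
#'   standard preset).
#' @param mode \code{"modular"} (default, exact) or \code{"float"}.
#' @return A \linkS4class{RollingHash}.
#' @examples
#' h <- rkHashInit("GACGA", 1, 2, mode = "float")
#' h@value   # (0.375, 0.125), the coordinate of "GA"
#' @export
rkHashInit <- function(S, i, L, params = cgrParams("standard"),
                       mode = c("modular", "float")) {
  mode <- match.arg(mode)
  S <- .checkSeq(S, "text")
  n <- nchar(S)
  if (length(L) != 1L || is.na(L) || L < 1L)
    stop("window length L must be at least 1")
  L <- as.integer(L)
  i <- .checkPos(i, n, "i")
  if (i + L - 1L > n) stop("window [", i, ", ", i + L - 1L,
                           "] runs past the text end (N = ", n, ")")
  if (mode == "float") {
    value <- cgrClosedForm(substr(S, i, i + L - 1L), L, params = params)
  } else {
    d <- .rkWindowDigits(.seqBits(S), i, L)
    value <- .rk_mod_init(d$d1, d$d2)
  }
  new("RollingHash", mode = mode, value = value, L = L,
      start = i, params = params)
}

#' Roll a CGR hash one symbol forward
#'
#' Slides the window by one: float mode applies
#' \eqn{h' = (1-r) h - r (1-r)^L (y_{out} - x_0) + r\, y_{in}} (a left
#' deletion followed by one CGR step); modular mode removes the lowest
#' digit and appends the new one, exactly.  \eqn{O(1)} per roll.
#'
#' @param h a \linkS4class{RollingHash}.
#' @param outSymbol the current window's first symbol.
#' @param inSymbol the symbol entering at the right.
#' @return The updated \linkS4class{RollingHash}.
#' @examples
#' h <- rkHashInit("GACGA", 1, 2, mode = "float")
#' rkRoll(h, "G", "C")@value   # coordinate of "AC": (0.125, 0.625)
#' @export
rkRoll <- function(h, outSymbol, inSymbol) {
  stopifnot(is(h, "RollingHash"))
  if (h@mode == "float") {
    r <- h@params@r
    value <- (1 - r) * h@value -
      r * (1 - r)^h@L * (.vertex(toupper(outSymbol)) - h@params@x0) +
      r * .vertex(toupper(inSymbol))
  } else {
    value <- .rk_mod_roll(h@value, h@L,
                          .symDigits(outSymbol), .symDigits(inSymbol))
  }
  initialize(h, value = value, start = h@start + 1L)
}

.rkEqual <- function(a, b, mode) {
  if (mode == "modular") all(a == b) else all(abs(a - b) < 1e-9)
}

.rkKey <- function(value, mode) {
  if (mode == "modular") paste(value, collapse = "_") else
    paste(signif(value, 12), collapse = "_")
}

#' Rabin-Karp search with the CGR rolling hash
#'
#' Scans all windows of \code{|P|} bases with \code{\link{rkRoll}},
#' compares against the pattern hash, and verifies every hash hit with a
#' constant-time longest-common-suffix query (hash equality alone is
#' randomized); only verified occurrences are reported, so the output
#' always equals \code{\link{matchesScan}}.
#'
#' @param S text string.
#' @param P pattern string.
#' @param mode \code{"modular"} (default) or \code{"float"}.
#' @return data.frame with columns \code{start}, \code{mismatches}
#'   (all 0).
#' @examples
#' rabinKarpSearch("GACGA", "GA")$start  # 1 4
#' @export
rabinKarpSearch <- function(S, P, mode = c("modular", "float")) {
  mode <- match.arg(mode)
  S <- .checkSeq(S, "text")
  P <- .checkSeq(P, "pattern")
  n <- nchar(S)
  L <- nchar(P)
  if (L > n)
    return(data.frame(start = integer(0), mismatches = integer(0)))
  hP <- rkHashInit(P, 1L, L, mode = mode)
  idxS <- cgrIndex(S)
  idxP <- cgrIndex(P)
  chS <- .seqChars(S)
  h <- rkHashInit(S, 1L, L, mode = mode)
  starts <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    if (.rkEqual(h@value, hP@value, mode) &&
        .lcsIdx(idxS, i + L - 1L, idxP, L) == L)
      starts <- c(starts, i)
    if (i + L <= n) h <- rkRoll(h, chS[i], chS[i + L])
  }
  data.frame(start = starts, mismatches = integer(length(starts)))
}

#' Hash index of all L-windows of a text
#'
#' Builds, in one rolling pass (\eqn{O(N)}), a hash table mapping each
#' window hash value to the list of its start positions.
#' \code{rkQuery} looks up the pattern's hash and verifies each bucket
#' entry with a longest-common-suffix query, for an expected
#' \eqn{O(L + occ)} search.
#'
#' @param S text string.
#' @param L window length.
#' @param mode \code{"modular"} (default) or \code{"float"}.
#' @return \code{rkIndex}: a list with elements \code{map} (named list,
#'   hash key to integer starts), \code{S}, \code{L}, \code{mode};
#'   \code{rkQuery}: sorted integer vector of verified start positions.
#' @examples
#' idx <- rkIndex("GACGA", 2)
#' rkQuery(idx, "GA")  # 1 4
#' @export
rkIndex <- function(S, L, mode = c("modular", "float")) {
  mode <- match.arg(mode)
  S <- .checkSeq(S, "text")
  n <- nchar(S)
  if (length(L) != 1L || is.na(L) || L < 1L || L > n)
    stop("window length L out of range [1, ", n, "]")
  L <- as.integer(L)
  chS <- .seqChars(S)
  map <- new.env(parent = emptyenv())
  h <- rkHashInit(S, 1L, L, mode = mode)
  for (i in seq_len(n - L + 1L)) {
    key <- .rkKey(h@value, mode)
    map[[key]] <- c(map[[key]], i)
    if (i + L <= n) h <- rkRoll(h, chS[i], chS[i + L])
  }
  list(map = as.list(map), S = S, L = L, mode = mode)
}

#' @rdname rkIndex
#' @param index an index built by \code{rkIndex}.
#' @param P pattern of length \code{index$L}.
#' @export
rkQuery <- function(index, P) {
  P <- .checkSeq(P, "pattern")
  if (nchar(P) != index$L)
    stop("pattern length must equal the indexed window length ", index$L)
  hP <- rkHashInit(P, 1L, index$L, mode = index$mode)
  cand <- index$map[[.rkKey(hP@value, index$mode)]]
  if (is.null(cand)) return(integer(0))
  idxS <- cgrIndex(index$S)
  idxP <- cgrIndex(P)
  L <- index$L
  sort(cand[vapply(cand, function(i)
    .lcsIdx(idxS, i + L - 1L, idxP, L) == L, logical(1))])
}
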