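# Core encoding: CGR coordinate construction (iterative and closed form),
# index bundles over sequence transforms, incremental edit operations,
# exact digit representation and decoding, sub-square k-mer counting.

.BASES <- c("A", "C", "G", "T")

# vertex map: A=(0,0), C=(0,1), G=(1,0), T=(1,1)
.VERTX <- c(A = 0, C = 0, G = 1, T = 1)
.VERTY <- c(A = 0, C = 1, G = 0, T = 1)

.vertex <- function(symbol) {
  if (!symbol %in% .BASES) stop("invalid symbol '", symbol, "'")
  c(.VERTX[[symbol]], .VERTY[[symbol]])
}

# Validate/normalise a sequence: uppercase, reject non-ACGT naming the
# first offending position.  CGR is undefined off {A,C,G,T}.
.checkSeq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq)) stop(what, " must be a single string")
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop(what, " must be non-empty")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop(what, " contains non-ACGT symbol '",
         substr(seq, bad, bad), "' at position ", bad)
  seq
}

.seqChars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# N x 2 matrix of vertex bits per symbol
.seqBits <- function(seq) {
  ch <- .seqChars(seq)
  cbind(as.integer(ch %in% c("G", "T")), as.integer(ch %in% c("C", "T")))
}

# numeric value of an exact Cantor coordinate (prefix length i) incl. tail
.exactValue <- function(bits, i) {
  if (i == 0L) return(c(2 / 3, 2 / 3))
  p <- 3^-(seq_len(i))
  tail3 <- 2 / 3 * 3^-i
  c(sum(2 * bits[i:1L, 1L] * p) + tail3,
    sum(2 * bits[i:1L, 2L] * p) + tail3)
}

.revSeq <- function(seq) intToUtf8(rev(utf8ToInt(seq)))
.compSeq <- function(seq) chartr("ACGT", "TGCA", seq)
.revcompSeq <- function(seq) .revSeq(.compSeq(seq))

#' Build a CGR coordinate index
#'
#' Encodes a DNA sequence as the array of CGR coordinates of all its
#' prefixes, iterating \code{x_i = x_{i-1} + r (y_i - x_{i-1})} from
#' \code{x0}, where \code{y_i} is the vertex of symbol \code{i} (A, C, G,
#' T at (0,0), (0,1), (1,0), (1,1)).  The \code{"cantor"} variant
#' (\code{r = 2/3}, \code{x0 = (2/3, 2/3)}) embeds the coordinates in the
#' Cantor set; only it supports the exact digit backend and
#' longest-common-suffix queries.
#'
#' @param seq DNA string over ACGT (lowercase accepted).
#' @param variant \code{"cantor"} (default) or \code{"standard"}; ignored
#'   when \code{params} is supplied.
#' @param backend \code{"float"} (coordinate matrix) or \code{"exact"}
#'   (digit representation; cantor preset only).
#' @param params optional \linkS4class{CgrParams} overriding
#'   \code{variant} (custom \code{r}/\code{x0} allowed for coordinate
#'   dumps).
#' @return A \linkS4class{CgrIndex}.
#' @examples
#' idx <- cgrIndex("AT", variant = "standard")
#' cgrCoord(idx, 2)   # (0.625, 0.625)
#' @export
cgrIndex <- function(seq, variant = c("cantor", "standard"),
                     backend = c("float", "exact"), params = NULL) {
  backend <- match.arg(backend)
  if (is.null(params)) params <- cgrParams(match.arg(variant))
  stopifnot(is(params, "CgrParams"))
  seq <- .checkSeq(seq)
  bits <- .seqBits(seq)
  if (backend == "exact") {
    if (params@variant != "cantor")
      stop("unsupported configuration: the exact backend requires the ",
           "cantor preset (r = 2/3, x0 = (2/3, 2/3))")
    coords <- matrix(numeric(0), nrow = 0L, ncol = 2L)
  } else {
    r <- params@r
    # x_i = (1 - r) x_{i-1} + r y_i: a linear recursive filter per axis
    coords <- rbind(
      params@x0,
      cbind(
        as.numeric(stats::filter(r * bits[, 1L], 1 - r,
                                 method = "recursive", init = params@x0[1L])),
        as.numeric(stats::filter(r * bits[, 2L], 1 - r,
                                 method = "recursive", init = params@x0[2L]))))
    dimnames(coords) <- NULL
  }
  new("CgrIndex", seq = seq, params = params, backend = backend,
      coords = coords, bits = bits)
}

#' Closed-form CGR coordinate
#'
#' Evaluates the coordinate of the prefix of length \code{i} by direct
#' summation, \eqn{x_i = (1-r)^i x_0 + r \sum_{k=1}^{i} (1-r)^{i-k} y_k},
#' independently of the iterative path.
#'
#' @param seq DNA string.
#' @param i prefix length, \code{0 <= i <= nchar(seq)} (\code{i = 0}
#'   returns \code{x0}).
#' @param variant,params as in \code{\link{cgrIndex}}.
#' @return numeric(2) coordinate.
#' @examples
#' cgrClosedForm("AT", 2, variant = "standard")  # (0.625, 0.625)
#' @export
cgrClosedForm <- function(seq, i, variant = c("cantor", "standard"),
                          params = NULL) {
  if (is.null(params)) params <- cgrParams(match.arg(variant))
  seq <- .checkSeq(seq)
  n <- nchar(seq)
  if (length(i) != 1L || is.na(i) || i < 0L || i > n)
    stop("position i out of range [0, ", n, "]")
  i <- as.integer(i)
  if (i == 0L) return(params@x0)
  r <- params@r
  bits <- .seqBits(seq)
  w <- r * (1 - r)^(i - seq_len(i))           # weight of y_k, k = 1..i
  (1 - r)^i * params@x0 +
    c(sum(w * bits[seq_len(i), 1L]), sum(w * bits[seq_len(i), 2L]))
}

#' Build a bundle of CGR indexes
#'
#' Builds the CGR indexes of the requested deterministic transforms of
#' one source sequence: \code{"direct"}, \code{"reverse"},
#' \code{"complement"} (A-T, C-G base pairing) and \code{"revcomp"}.
#'
#' @param seq DNA string.
#' @param which character subset of
#'   \code{c("direct", "reverse", "complement", "revcomp")}.
#' @param variant,backend,params as in \code{\link{cgrIndex}}.
#' @return A \linkS4class{CgrBundle}.
#' @examples
#' b <- cgrBundle("GACGA", which = c("direct", "reverse"))
#' cgrSequence(b@reverse)  # "AGCAG"
#' @export
cgrBundle <- function(seq,
                      which = c("direct", "reverse", "complement", "revcomp"),
                      variant = c("cantor", "standard"),
                      backend = c("float", "exact"), params = NULL) {
  which <- match.arg(which, several.ok = TRUE)
  backend <- match.arg(backend)
  if (is.null(params)) params <- cgrParams(match.arg(variant))
  seq <- .checkSeq(seq)
  mk <- function(s) cgrIndex(s, backend = backend, params = params)
  new("CgrBundle", seq = seq,
      direct = if ("direct" %in% which) mk(seq) else NULL,
      reverse = if ("reverse" %in% which) mk(.revSeq(seq)) else NULL,
      complement = if ("complement" %in% which) mk(.compSeq(seq)) else NULL,
      revcomp = if ("revcomp" %in% which) mk(.revcompSeq(seq)) else NULL)
}

# coerce seq/bundle to a bundle holding the needed members (cantor/float)
.asBundle <- function(x, need, what = "sequence") {
  if (is(x, "CgrBundle")) {
    for (s in need) {
      idx <- slot(x, s)
      if (is.null(idx))
        stop("bundle lacks the required '", s, "' index")
      if (idx@params@variant != "cantor")
        stop("matching algorithms require cantor-variant indexes")
    }
    return(x)
  }
  cgrBundle(.checkSeq(x, what), which = need, variant = "cantor")
}

## ---- incremental edit operations -----------------------------------------

#' Incremental CGR edit operations
#'
#' Update a CGR coordinate in constant time when the encoded string is
#' edited at either end.  With \eqn{y} the vertex of the edited symbol
#' and \eqn{n} the length of the string \emph{before} the edit:
#' \describe{
#'   \item{\code{leftInsert}}{prepend a symbol:
#'     \eqn{x + r (1-r)^{n} (y - x_0)}.}
#'   \item{\code{leftDelete}}{remove the first symbol:
#'     \eqn{x - r (1-r)^{n-1} (y - x_0)}; exact inverse of
#'     \code{leftInsert}.}
#'   \item{\code{rightInsert}}{append a symbol: one CGR step
#'     \eqn{(1-r) x + r y}.}
#'   \item{\code{rightDelete}}{remove the last symbol:
#'     \eqn{(x - r y) / (1-r)}.}
#' }
#' Methods on \linkS4class{CgrDigits} perform the same edits on the exact
#' base-3 digit representation (drop/append digits), bit-exactly.
#'
#' @param x numeric(2) coordinate, or a \linkS4class{CgrDigits}.
#' @param symbol the edited symbol (for deletions it must equal the
#'   symbol actually removed).
#' @param n length of the encoded string before the edit (numeric
#'   methods of the left operations only).
#' @param params a \linkS4class{CgrParams}; default standard preset.
#' @return Same representation as \code{x}, for the edited string.
#' @examples
#' p <- cgrParams("standard")
#' xGA <- cgrCoord(cgrIndex("GA", variant = "standard"), 2)
#' leftDelete(xGA, "G", 2, p)           # coordinate of "A"
#' rightInsert(cgrCoord(cgrIndex("G", variant = "standard"), 1), "A", p)
#' @name cgr-edits
NULL

#' @rdname cgr-edits
#' @export
setGeneric("leftInsert", function(x, symbol, n, params, ...)
  standardGeneric("leftInsert"))

#' @rdname cgr-edits
#' @export
setGeneric("leftDelete", function(x, symbol, n, params, ...)
  standardGeneric("leftDelete"))

#' @rdname cgr-edits
#' @export
setGeneric("rightInsert", function(x, symbol, params, ...)
  standardGeneric("rightInsert"))

#' @rdname cgr-edits
#' @export
setGeneric("rightDelete", function(x, symbol, params, ...)
  standardGeneric("rightDelete"))

#' @rdname cgr-edits
setMethod("leftInsert", "numeric",
          function(x, symbol, n, params = cgrParams("standard")) {
  stopifnot(length(x) == 2L, n >= 0L)
  r <- params@r
  x + r * (1 - r)^n * (.vertex(toupper(symbol)) - params@x0)
})

#' @rdname cgr-edits
setMethod("leftDelete", "numeric",
          function(x, symbol, n, params = cgrParams("standard")) {
  stopifnot(length(x) == 2L)
  if (n < 1L) stop("cannot left-delete from an empty string")
  r <- params@r
  x - r * (1 - r)^(n - 1) * (.vertex(toupper(symbol)) - params@x0)
})

#' @rdname cgr-edits
setMethod("rightInsert", "numeric",
          function(x, symbol, params = cgrParams("standard")) {
  stopifnot(length(x) == 2L)
  r <- params@r
  (1 - r) * x + r * .vertex(toupper(symbol))
})

#' @rdname cgr-edits
setMethod("rightDelete", "numeric",
          function(x, symbol, params = cgrParams("standard")) {
  stopifnot(length(x) == 2L)
  if (all(x == params@x0))
    stop("cannot right-delete at x0 (empty string)")
  r <- params@r
  (x - r * .vertex(toupper(symbol))) / (1 - r)
})

.symDigits <- function(symbol) {
  v <- .vertex(toupper(symbol))
  as.integer(2 * v)
}

# digit-space edits: digit m corresponds to symbol S[i - m + 1], so the
# first symbol is the least significant content digit (last element)
#' @rdname cgr-edits
setMethod("leftInsert", "CgrDigits", function(x, symbol, n, params) {
  d <- .symDigits(symbol)
  new("CgrDigits", x1 = c(x@x1, d[1L]), x2 = c(x@x2, d[2L]))
})

#' @rdname cgr-edits
setMethod("leftDelete", "CgrDigits", function(x, symbol, n, params) {
  i <- length(x@x1)
  if (i < 1L) stop("cannot left-delete from an empty string")
  d <- .symDigits(symbol)
  if (x@x1[i] != d[1L] || x@x2[i] != d[2L])
    stop("first symbol of the encoded string is not '", symbol, "'")
  new("CgrDigits", x1 = x@x1[-i], x2 = x@x2[-i])
})

#' @rdname cgr-edits
setMethod("rightInsert", "CgrDigits", function(x, symbol, params) {
  d <- .symDigits(symbol)
  new("CgrDigits", x1 = c(d[1L], x@x1), x2 = c(d[2L], x@x2))
})

#' @rdname cgr-edits
setMethod("rightDelete", "CgrDigits", function(x, symbol, params) {
  if (length(x@x1) < 1L) stop("cannot right-delete an empty string")
  d <- .symDigits(symbol)
  if (x@x1[1L] != d[1L] || x@x2[1L] != d[2L])
    stop("last symbol of the encoded string is not '", symbol, "'")
  new("CgrDigits", x1 = x@x1[-1L], x2 = x@x2[-1L])
})

## ---- exact digits and decoding -------------------------------------------

#' Exact base-3 digits of a Cantor-embedded prefix coordinate
#'
#' Returns the per-axis digit sequences (over \{0, 2\}, most significant
#' first) of the coordinate of the prefix of length \code{i} of an
#' exact-backend index.  Digit \eqn{m} is twice the axis bit of symbol
#' \eqn{S[i-m+1]}; the x0 tail (digit 2 then zeros) is implicit.
#'
#' @param index a cantor \linkS4class{CgrIndex}.
#' @param i prefix length, \code{1 <= i <= length(index)}.
#' @return A \linkS4class{CgrDigits}.
#' @examples
#' d <- cgrDigits(cgrIndex("AT", backend = "exact"), 2)
#' d@x1  # 2 0  (base-3 0.202 with the implicit tail)
#' @export
cgrDigits <- function(index, i) {
  stopifnot(is(index, "CgrIndex"))
  if (index@params@variant != "cantor")
    stop("exact digits are defined for the cantor preset only")
  n <- length(index)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop("position i out of range [1, ", n, "]")
  i <- as.integer(i)
  new("CgrDigits",
      x1 = 2L * index@bits[i:1L, 1L],
      x2 = 2L * index@bits[i:1L, 2L])
}

#' Decode a sequence from its exact Cantor digits
#'
#' Inverts the Cantor-embedded encoding: digit \eqn{m} of axis \eqn{b}
#' carries the axis-\eqn{b} vertex bit of symbol \eqn{S[i-m+1]}, so the
#' two digit sequences determine the string uniquely
#' (\code{decodeSequence(cgrDigits(idx, i))} recovers the length-i
#' prefix).
#'
#' @param digits a \linkS4class{CgrDigits} (or a list with integer
#'   components \code{x1}, \code{x2} of digits over \{0, 2\}).
#' @return The decoded DNA string ("" for empty digit sequences).
#' @examples
#' decodeSequence(cgrDigits(cgrIndex("GACGA", backend = "exact"), 5))
#' @export
decodeSequence <- function(digits) {
  if (!is(digits, "CgrDigits")) {
    if (!is.list(digits) || is.null(digits$x1) || is.null(digits$x2))
      stop("digits must be a CgrDigits object or a list with x1 and x2")
    digits <- new("CgrDigits", x1 = as.integer(digits$x1),
                  x2 = as.integer(digits$x2))
  }
  i <- length(digits@x1)
  if (i == 0L) return("")
  b1 <- rev(digits@x1) / 2L   # bits of S[1..i]
  b2 <- rev(digits@x2) / 2L
  paste(.BASES[1L + 2L * b1 + b2], collapse = "")
}

## ---- sub-square k-mer counting -------------------------------------------

#' Count k-mers through CGR sub-squares
#'
#' Partitions the unit square into a \eqn{2^m \times 2^m} grid, assigns
#' the coordinate of every prefix of length at least \code{m} to its
#' cell, and labels each cell by the \code{m}-long suffix it encodes.
#' For the standard variant the resulting counts equal sliding-window
#' m-mer counts of the sequence (prefixes shorter than \code{m} are
#' skipped: their cell is contaminated by the initial point).
#'
#' @param index a standard-variant float \linkS4class{CgrIndex}.
#' @param m word length, \code{1 <= m <= length(index)}.
#' @return Named integer vector of m-mer counts (m-mers absent from the
#'   sequence are absent from the vector), names sorted.
#' @examples
#' kmerCounts(cgrIndex("GACGA", variant = "standard"), 2)
#' @export
kmerCounts <- function(index, m) {
  stopifnot(is(index, "CgrIndex"))
  if (index@params@variant != "standard" || index@backend != "float")
    stop("sub-square counting requires a standard-variant float index")
  n <- length(index)
  if (length(m) != 1L || is.na(m) || m < 1L || m > n)
    stop("word length m out of range [1, ", n, "]")
  m <- as.integer(m)
  g <- 2^m
  xy <- index@coords[(m:n) + 1L, , drop = FALSE]
  ix <- pmin(floor(xy[, 1L] * g), g - 1)   # clamp the x -> 1 rounding edge
  iy <- pmin(floor(xy[, 2L] * g), g - 1)
  tab <- table(ix * g + iy)
  cells <- as.numeric(names(tab))
  cix <- cells %/% g
  ciy <- cells %% g
  # bit at significance 2^(j-1) of the cell index is the vertex bit of
  # the j'th character of the m-mer (msb encodes the most recent symbol)
  lab <- vapply(seq_along(cells), function(t) {
    j <- seq_len(m)
    b1 <- (cix[t] %/% 2^(j - 1)) %% 2
    b2 <- (ciy[t] %/% 2^(j - 1)) %% 2
    paste(.BASES[1 + 2 * b1 + b2], collapse = "")
  }, character(1))
  out <- as.integer(tab)
  names(out) <- lab
  out[order(names(out))]
}
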