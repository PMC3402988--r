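# Central S4 classes: parameter set, coordinate index, index bundle,
# quadtree index, rolling hash state, exact digit representation.

#' CGR iteration parameters
#'
#' Holds the contraction ratio \code{r} and initial point \code{x0} of the
#' CGR iterated function system.  Two presets matter: \code{"standard"}
#' (\code{r = 1/2}, \code{x0 = (1/2, 1/2)}), the original formulation, and
#' \code{"cantor"} (\code{r = 2/3}, \code{x0 = (2/3, 2/3)}), the Cantor-set
#' embedding under which coordinate proximity is equivalent to suffix
#' sharing.  Other values are accepted (variant \code{"custom"}) for
#' coordinate dumps only; all matching algorithms pin the cantor preset.
#'
#' @slot r numeric contraction ratio, \code{1/2 <= r < 1}.
#' @slot x0 numeric(2) initial point in the unit square.
#' @slot variant one of \code{"standard"}, \code{"cantor"}, \code{"custom"}.
#' @exportClass CgrParams
setClass("CgrParams",
         slots = c(r = "numeric", x0 = "numeric", variant = "character"))

setValidity("CgrParams", function(object) {
  if (length(object@r) != 1L || is.na(object@r) ||
      object@r < 0.5 || object@r >= 1)
    return("contraction ratio r must satisfy 1/2 <= r < 1")
  if (length(object@x0) != 2L || anyNA(object@x0) ||
      any(object@x0 < 0) || any(object@x0 > 1))
    return("x0 must be a point in [0,1]^2")
  if (!object@variant %in% c("standard", "cantor", "custom"))
    return("variant must be 'standard', 'cantor' or 'custom'")
  TRUE
})

#' Construct CGR parameters
#'
#' @param variant \code{"cantor"} (default) or \code{"standard"} preset.
#' @param r,x0 optional overrides; supplying either yields a
#'   \code{"custom"} variant unless the values coincide with a preset.
#' @return A \linkS4class{CgrParams} object.
#' @examples
#' cgrParams("standard")
#' cgrParams("cantor")
#' @export
cgrParams <- function(variant = c("cantor", "standard"), r = NULL, x0 = NULL) {
  variant <- match.arg(variant)
  rr <- if (variant == "cantor") 2 / 3 else 1 / 2
  xx <- if (variant == "cantor") c(2 / 3, 2 / 3) else c(1 / 2, 1 / 2)
  if (!is.null(r)) rr <- as.numeric(r)
  if (!is.null(x0)) xx <- as.numeric(x0)
  variant <- if (identical(rr, 2 / 3) && identical(xx, c(2 / 3, 2 / 3))) {
    "cantor"
  } else if (identical(rr, 1 / 2) && identical(xx, c(1 / 2, 1 / 2))) {
    "standard"
  } else "custom"
  new("CgrParams", r = rr, x0 = xx, variant = variant)
}

#' CGR coordinate index of a DNA sequence
#'
#' Stores, for a sequence of length \eqn{N}, the CGR coordinate of every
#' prefix.  The float backend keeps an \eqn{(N+1) \times 2} matrix of
#' doubles (row 1 is \code{x0}); the exact backend represents each
#' coordinate implicitly through the per-symbol axis bits, from which the
#' base-3 digit expansion of any prefix coordinate can be read off
#' without rounding.  The axis bit matrix is kept for both backends: the
#' float LCE path falls back to exact digit comparison once a query
#' exceeds double-precision resolution.
#'
#' @slot seq the encoded sequence (uppercase ACGT character scalar).
#' @slot params a \linkS4class{CgrParams}.
#' @slot backend \code{"float"} or \code{"exact"}.
#' @slot coords numeric matrix of prefix coordinates (float backend);
#'   0-row matrix for the exact backend.
#' @slot bits integer matrix (N x 2) of per-symbol vertex bits.
#' @exportClass CgrIndex
setClass("CgrIndex",
         slots = c(seq = "character", params = "CgrParams",
                   backend = "character", coords = "matrix",
                   bits = "matrix"))

setValidity("CgrIndex", function(object) {
  n <- nchar(object@seq)
  if (length(object@seq) != 1L || n < 1L)
    return("seq must be a single non-empty sequence")
  if (!object@backend %in% c("float", "exact"))
    return("backend must be 'float' or 'exact'")
  if (object@backend == "exact" && object@params@variant != "cantor")
    return("exact backend requires the cantor preset")
  if (nrow(object@bits) != n || ncol(object@bits) != 2L)
    return("bits must be an N x 2 matrix")
  if (object@backend == "float" &&
      (nrow(object@coords) != n + 1L || ncol(object@coords) != 2L))
    return("coords must be an (N+1) x 2 matrix for the float backend")
  TRUE
})

setMethod("show", "CgrIndex", function(object) {
  cat(sprintf("CgrIndex of %d bases (%s variant, %s backend)\n",
              nchar(object@seq), object@params@variant, object@backend))
  s <- object@seq
  if (nchar(s) > 40) s <- paste0(substr(s, 1, 37), "...")
  cat("  sequence: ", s, "\n", sep = "")
  cat(sprintf("  r = %.6g, x0 = (%.6g, %.6g)\n",
              object@params@r, object@params@x0[1], object@params@x0[2]))
})

#' @describeIn CgrIndex-class number of encoded bases.
#' @param x a \code{CgrIndex}.
#' @export
setMethod("length", "CgrIndex", function(x) nchar(x@seq))

#' Accessors for CgrIndex
#'
#' \code{cgrSequence} returns the encoded sequence, \code{cgrCoords} the
#' full N x 2 coordinate matrix (rows are prefix lengths 1..N),
#' \code{cgrCoord} the coordinate of the prefix of length \code{i}
#' (\code{i = 0} gives \code{x0}), \code{cgrVariant}/\code{cgrBackend}
#' the respective labels.  For the exact backend coordinates are
#' evaluated from the digit expansion on demand (as doubles, for
#' display; the digit representation itself is available through
#' \code{\link{cgrDigits}}).
#'
#' @param x a \linkS4class{CgrIndex}.
#' @param i prefix length, \code{0 <= i <= length(x)}.
#' @return \code{cgrCoord}: numeric(2); \code{cgrCoords}: numeric matrix.
#' @name cgr-accessors
NULL

#' @rdname cgr-accessors
#' @export
cgrSequence <- function(x) x@seq

#' @rdname cgr-accessors
#' @export
cgrVariant <- function(x) x@params@variant

#' @rdname cgr-accessors
#' @export
cgrBackend <- function(x) x@backend

#' @rdname cgr-accessors
#' @export
cgrCoord <- function(x, i) {
  n <- length(x)
  if (length(i) != 1L || is.na(i) || i < 0L || i > n)
    stop("position i out of range [0, ", n, "]")
  i <- as.integer(i)
  if (x@backend == "float") return(unname(x@coords[i + 1L, ]))
  .exactValue(x@bits, i)
}

#' @rdname cgr-accessors
#' @export
cgrCoords <- function(x) {
  if (x@backend == "float") {
    m <- x@coords[-1L, , drop = FALSE]
    dimnames(m) <- list(NULL, c("x1", "x2"))
    return(m)
  }
  t(vapply(seq_len(length(x)), function(i) .exactValue(x@bits, i),
           numeric(2)))
}

setClassUnion("CgrIndexOrNULL", c("CgrIndex", "NULL"))

#' Bundle of CGR indexes over one source sequence
#'
#' Different algorithms need the CGR index of deterministic transforms of
#' the same sequence: the direct string, its reverse (for LCE via
#' suffix/prefix duality), its complement, and its reverse complement
#' (for complemented-palindrome arms).  A \code{CgrBundle} carries any
#' subset of the four, all built with the same variant and backend.
#'
#' @slot seq the source sequence.
#' @slot direct,reverse,complement,revcomp \linkS4class{CgrIndex} or NULL.
#' @exportClass CgrBundle
setClass("CgrBundle",
         slots = c(seq = "character",
                   direct = "CgrIndexOrNULL", reverse = "CgrIndexOrNULL",
                   complement = "CgrIndexOrNULL", revcomp = "CgrIndexOrNULL"))

setMethod("show", "CgrBundle", function(object) {
  have <- c("direct", "reverse", "complement", "revcomp")
  have <- have[!vapply(have, function(s) is.null(slot(object, s)), logical(1))]
  cat(sprintf("CgrBundle of %d bases: %s\n",
              nchar(object@seq), paste(have, collapse = ", ")))
})

#' @describeIn CgrBundle-class number of bases in the source sequence.
#' @param x a \code{CgrBundle}.
#' @export
setMethod("length", "CgrBundle", function(x) nchar(x@seq))

#' Quadtree (CGR-tree) index
#'
#' A four-way digital search tree over the reversed prefixes of a text.
#' Node slots follow the fixed child order A, C, G, T.  Each node stores
#' one text position (the prefix length whose reversed prefix was
#' inserted); insertion descends along the reversed prefix and places the
#' new node in the first empty slot.  Row 1 is the (position-less) root.
#'
#' @slot seq the indexed text.
#' @slot pos integer vector of stored positions (NA for the root).
#' @slot children integer matrix (nodes x 4); 0 marks an empty slot.
#' @exportClass QuadtreeIndex
setClass("QuadtreeIndex",
         slots = c(seq = "character", pos = "integer", children = "matrix"))

setValidity("QuadtreeIndex", function(object) {
  if (nrow(object@children) != length(object@pos))
    return("children must have one row per node")
  if (ncol(object@children) != 4L)
    return("children must have 4 slots per node (A, C, G, T)")
  p <- object@pos[-1L]
  if (length(p) && !setequal(p, seq_along(p)))
    return("stored positions must be a permutation of 1..N")
  TRUE
})

setMethod("show", "QuadtreeIndex", function(object) {
  cat(sprintf("QuadtreeIndex of \"%s\" (%d nodes)\n",
              if (nchar(object@seq) > 30)
                paste0(substr(object@seq, 1, 27), "...") else object@seq,
              length(object@pos) - 1L))
  cat(" ", qtSerialize(object), "\n")
})

#' Rolling hash state for CGR-based Rabin-Karp search
#'
#' In float mode the hash of a window is its fresh CGR coordinate, rolled
#' by one left deletion plus one CGR step.  In modular mode each axis
#' carries the window's scaled base-3 digit polynomial reduced modulo the
#' Mersenne prime 2^61 - 1, which rolls exactly for any window length.
#' Residues exceed the exact integer range of a double and are therefore
#' stored as (hi, lo) 31/30-bit splits, two per axis.
#'
#' @slot mode \code{"modular"} or \code{"float"}.
#' @slot value numeric(2) coordinate (float) or numeric(4) residue splits.
#' @slot L window length in bases.
#' @slot start current window start (1-based).
#' @slot params a \linkS4class{CgrParams} (float mode).
#' @exportClass RollingHash
setClass("RollingHash",
         slots = c(mode = "character", value = "numeric", L = "integer",
                   start = "integer", params = "CgrParams"))

setMethod("show", "RollingHash", function(object) {
  cat(sprintf("RollingHash (%s mode), window L = %d starting at %d\n",
              object@mode, object@L, object@start))
  if (object@mode == "float")
    cat(sprintf("  value = (%.10g, %.10g)\n",
                object@value[1], object@value[2]))
  else
    cat(sprintf("  residues = (%s, %s) mod 2^61-1\n",
                .splitToChar(object@value[1:2]),
                .splitToChar(object@value[3:4])))
})

#' Exact Cantor-embedded coordinate as base-3 digits
#'
#' Per-axis digit sequences over \{0, 2\} (most significant first) of the
#' Cantor-embedded CGR coordinate of a prefix of length \eqn{i}; digit
#' \eqn{m} equals twice the axis bit of symbol \eqn{S[i - m + 1]}.  The
#' terminator digit 2 followed by zeros (the \code{x0 = 2/3} tail) is
#' implicit.  This representation is lossless: \code{\link{decodeSequence}}
#' recovers the encoded string.
#'
#' @slot x1,x2 integer digit vectors over \{0, 2\}.
#' @exportClass CgrDigits
setClass("CgrDigits", slots = c(x1 = "integer", x2 = "integer"))

setValidity("CgrDigits", function(object) {
  if (length(object@x1) != length(object@x2))
    return("axis digit sequences must have equal length")
  if (!all(object@x1 %in% c(0L, 2L)) || !all(object@x2 %in% c(0L, 2L)))
    return("digits must be 0 or 2")
  TRUE
})

setMethod("show", "CgrDigits", function(object) {
  cat(sprintf("CgrDigits (%d symbols)\n", length(object@x1)))
  cat("  x1: 0.", paste(object@x1, collapse = ""), "(2)\n", sep = "")
  cat("  x2: 0.", paste(object@x2, collapse = ""), "(2)\n", sep = "")
})

#' @describeIn CgrDigits-class number of encoded symbols.
#' @param x a \code{CgrDigits}.
#' @export
setMethod("length", "CgrDigits", function(x) length(x@x1))
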