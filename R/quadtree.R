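# Quadtree (CGR-tree) index: a four-way digital search tree over the
# reversed prefixes of a text, supporting O(L + occ) pattern search.

.slotOf <- function(ch) match(ch, .BASES)

#' Build a quadtree index
#'
#' Inserts the reversed prefix \code{reverse(S[..p])} for
#' \code{p = 1..N}, in order, into a four-way digital search tree: the
#' descent follows the reversed prefix symbol by symbol (child slots in
#' fixed A, C, G, T order) and the new node, storing position \code{p},
#' is placed in the first empty slot.  At most one node per text
#' position is created; the path to the node storing \code{p} spells a
#' prefix of \code{reverse(S[..p])}.
#'
#' @param S text string over ACGT.
#' @return A \linkS4class{QuadtreeIndex}.
#' @examples
#' qtSerialize(qtBuild("GACGA"))
#' @export
qtBuild <- function(S) {
  S <- .checkSeq(S, "text")
  n <- nchar(S)
  ch <- .seqChars(S)
  pos <- rep(NA_integer_, n + 1L)
  children <- matrix(0L, nrow = n + 1L, ncol = 4L)
  nnode <- 1L                       # row 1 is the root
  for (p in seq_len(n)) {
    cur <- 1L
    for (d in seq_len(p)) {         # reverse(S[..p])[d] = S[p - d + 1]
      s <- .slotOf(ch[p - d + 1L])
      nxt <- children[cur, s]
      if (nxt == 0L) {
        nnode <- nnode + 1L
        pos[nnode] <- p
        children[cur, s] <- nnode
        break
      }
      cur <- nxt
    }
  }
  new("QuadtreeIndex", seq = S, pos = pos[seq_len(nnode)],
      children = children[seq_len(nnode), , drop = FALSE])
}

.qtSerializeNode <- function(qt, node) {
  parts <- vapply(1:4, function(s) {
    child <- qt@children[node, s]
    if (child == 0L) return("")
    paste0(if (s > 1L) " " else "", qt@pos[child], ": ",
           .qtSerializeNode(qt, child))
  }, character(1))
  paste0("[", paste(parts, collapse = ","), "]")
}

#' Serialize / parse a quadtree in bracket notation
#'
#' \code{qtSerialize} renders the tree with children in A, C, G, T
#' order, occupied slots as \code{p: [...]} and empty slots as empty
#' strings, comma-separated; the empty tree is \code{"[,,,]"}.
#' \code{qtParse} inverts the rendering (the text is not recoverable
#' from the bracket form, so the parsed tree has an empty \code{seq}).
#'
#' @param qt a \linkS4class{QuadtreeIndex}.
#' @param s a serialized tree string.
#' @return \code{qtSerialize}: character scalar; \code{qtParse}: a
#'   \linkS4class{QuadtreeIndex}.
#' @examples
#' qtSerialize(qtBuild("G"))  # "[,, 1: [,,,],]"
#' @export
qtSerialize <- function(qt) {
  stopifnot(is(qt, "QuadtreeIndex"))
  .qtSerializeNode(qt, 1L)
}

#' @rdname qtSerialize
#' @export
qtParse <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  env <- new.env(parent = emptyenv())
  env$pos <- NA_integer_
  env$children <- matrix(0L, nrow = 1L, ncol = 4L)
  env$i <- 1L
  peek <- function() substr(s, env$i, env$i)
  eat <- function(chr) {
    if (peek() != chr)
      stop("malformed quadtree string at character ", env$i,
           ": expected '", chr, "'")
    env$i <- env$i + 1L
  }
  parseNode <- function(node) {
    eat("[")
    for (slot in 1:4) {
      while (peek() == " ") env$i <- env$i + 1L
      if (!peek() %in% c(",", "]")) {       # occupied: "p: [...]"
        j <- env$i
        while (substr(s, j, j) %in% as.character(0:9)) j <- j + 1L
        p <- as.integer(substr(s, env$i, j - 1L))
        if (is.na(p)) stop("malformed position at character ", env$i)
        env$i <- j
        eat(":"); eat(" ")
        env$pos <- c(env$pos, p)
        env$children <- rbind(env$children, rep(0L, 4L))
        child <- length(env$pos)
        env$children[node, slot] <- child
        parseNode(child)
      }
      if (slot < 4L) eat(",")
    }
    eat("]")
  }
  parseNode(1L)
  if (env$i != nchar(s) + 1L)
    stop("trailing characters after quadtree string")
  new("QuadtreeIndex", seq = "", pos = env$pos, children = env$children)
}

# all stored positions in the subtree rooted at node (inclusive)
.qtSubtreePositions <- function(qt, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, qt@pos[cur])
    kids <- qt@children[cur, ]
    stack <- c(stack, kids[kids != 0L])
  }
  out
}

#' Pattern search on a quadtree index
#'
#' Descends along the reversed pattern.  Every node met before depth
#' \code{L} stores a position whose reversed prefix diverges from the
#' search path early, so a constant-time coordinate check (a
#' longest-common-suffix query between the prefix of S ending at the
#' stored position and the full pattern, on cantor indexes) decides
#' whether it is a genuine occurrence.  On reaching depth \code{L},
#' every node of the subtree is an occurrence.  Total cost is
#' \eqn{O(L + occ)}.
#'
#' @param qt a \linkS4class{QuadtreeIndex} built from the text.
#' @param P pattern string.
#' @param bundle optional \linkS4class{CgrBundle} of the text holding a
#'   direct cantor index (built on the fly if missing).
#' @return \code{qtMatches}: sorted integer vector of 1-based start
#'   positions; \code{qtCount}: their number.
#' @examples
#' qtMatches(qtBuild("GACGA"), "GA")  # 1 4
#' @export
qtMatches <- function(qt, P, bundle = NULL) {
  stopifnot(is(qt, "QuadtreeIndex"))
  if (nchar(qt@seq) == 0L) stop("quadtree lacks its text (parsed tree?)")
  P <- .checkSeq(P, "pattern")
  L <- nchar(P)
  n <- nchar(qt@seq)
  if (L > n) return(integer(0))
  bundle <- if (is.null(bundle)) .asBundle(qt@seq, "direct") else
    .asBundle(bundle, "direct")
  idxS <- bundle@direct
  idxP <- cgrIndex(P, backend = if (idxS@backend == "exact")
    "exact" else "float")
  pr <- rev(.seqChars(P))
  hits <- integer(0)
  cur <- 1L
  for (d in seq_len(L)) {
    child <- qt@children[cur, .slotOf(pr[d])]
    if (child == 0L) break
    if (d == L) {
      hits <- c(hits, .qtSubtreePositions(qt, child))
    } else {
      p <- qt@pos[child]
      if (p >= L && .lcsIdx(idxS, p, idxP, L) == L)
        hits <- c(hits, p)
    }
    cur <- child
  }
  sort(hits - L + 1L)
}

#' @rdname qtMatches
#' @export
qtCount <- function(qt, P, bundle = NULL) length(qtMatches(qt, P, bundle))
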