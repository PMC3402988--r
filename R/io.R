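# FASTA I/O (through Biostrings), seeded synthetic DNA and planted
# fixtures, TSV/BED writers.

#' Read and write FASTA
#'
#' \code{readFasta} parses a (possibly multi-record, line-wrapped,
#' CRLF-tolerant) FASTA file into a named character vector of uppercase
#' sequences; record ids are the first whitespace-delimited token of each
#' header and must be unique.  Non-ACGT symbols are rejected with the
#' record and position named (\code{policy = "error"}, the default), or
#' each maximal ACGT run becomes its own record with the original
#' interval appended to the id (\code{policy = "split"}).
#'
#' @param path file path.
#' @param policy \code{"error"} or \code{"split"} for non-ACGT symbols.
#' @return Named character vector of sequences.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeFasta(c(s1 = "GACGA"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, policy = c("error", "split")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA header: empty record id")
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  out <- character(0)
  for (id in ids) {
    s <- seqs[[id]]
    bad <- regexpr("[^ACGT]", s)
    if (bad < 0L) {
      out[[id]] <- s
    } else if (policy == "error") {
      stop("record '", id, "' contains non-ACGT symbol '",
           substr(s, bad, bad), "' at position ", bad)
    } else {
      runs <- gregexpr("[ACGT]+", s)[[1L]]
      if (runs[1L] == -1L) next
      for (t in seq_along(runs)) {
        from <- runs[t]
        to <- from + attr(runs, "match.length")[t] - 1L
        out[[sprintf("%s:%d-%d", id, from, to)]] <- substr(s, from, to)
      }
    }
  }
  out
}

#' @rdname readFasta
#' @param records named character vector of sequences.
#' @export
writeFasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  set <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# run expr with a locally seeded RNG, leaving the global stream untouched
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded random DNA
#'
#' I.i.d. uniform ACGT symbols from a locally seeded generator (the
#' global RNG stream is left untouched when \code{seed} is given).
#'
#' @param length number of bases, \code{>= 1}.
#' @param seed optional integer seed; identical seeds give identical
#'   sequences.
#' @return DNA string.
#' @examples
#' randomDna(10, seed = 1)
#' @export
randomDna <- function(length, seed = NULL) {
  stopifnot(length >= 1L)
  .withSeed(seed,
            paste(sample(.BASES, length, replace = TRUE), collapse = ""))
}

#' Random sequence with planted features
#'
#' Generates a seeded random background and overwrites it with the
#' requested payloads, returning machine-readable ground truth for
#' oracle tests.  Plant kinds: \code{"match"} (payload = the pattern),
#' \code{"tandem"} (payload = both copies, even length; truth radius is
#' half the payload), \code{"palindrome"} (payload must equal its own
#' reverse complement; truth center/radius refer to the adjacent-arm
#' form).  Plants are applied in order; overlapping plants overwrite
#' earlier ones (their truth rows then no longer hold).
#'
#' @param length background length.
#' @param seed optional integer seed.
#' @param plants list of \code{list(kind =, payload =, at =)} entries.
#' @return list with \code{sequence} and \code{truth} (data.frame with
#'   columns kind, payload, start, end, center, radius).
#' @examples
#' fx <- makeFixture(20, seed = 1,
#'                   plants = list(list(kind = "tandem",
#'                                      payload = "ACGACG", at = 5)))
#' fx$truth
#' @export
makeFixture <- function(length, seed = NULL, plants = list()) {
  s <- randomDna(length, seed)
  truth <- data.frame(kind = character(0), payload = character(0),
                      start = integer(0), end = integer(0),
                      center = integer(0), radius = integer(0))
  for (pl in plants) {
    stopifnot(is.list(pl), !is.null(pl$kind), !is.null(pl$payload),
              !is.null(pl$at))
    kind <- match.arg(pl$kind, c("match", "tandem", "palindrome"))
    payload <- .checkSeq(pl$payload, "plant payload")
    at <- as.integer(pl$at)
    w <- nchar(payload)
    if (at < 1L || at + w - 1L > length)
      stop("plant at position ", at, " overlaps the sequence end")
    center <- radius <- NA_integer_
    if (kind == "tandem") {
      if (w %% 2L != 0L ||
          substr(payload, 1L, w / 2L) != substr(payload, w / 2L + 1L, w))
        stop("tandem payload must be two identical adjacent copies")
      radius <- w %/% 2L
    }
    if (kind == "palindrome") {
      if (payload != .revcompSeq(payload))
        stop("palindrome payload must equal its own reverse complement")
      radius <- w %/% 2L
      center <- at + radius - 1L
    }
    substr(s, at, at + w - 1L) <- payload
    truth <- rbind(truth, data.frame(kind = kind, payload = payload,
                                     start = at, end = at + w - 1L,
                                     center = center, radius = radius))
  }
  list(sequence = s, truth = truth)
}

#' Interval coordinate conversion
#'
#' Hit tables carry 1-based inclusive coordinates throughout the API;
#' these helpers convert to and from 0-based half-open (BED) intervals:
#' \code{start_bed = start - 1}, \code{end_bed = end}.
#'
#' @param df data.frame with columns \code{start}, \code{end}.
#' @return The converted data.frame.
#' @examples
#' toBed(data.frame(start = 1L, end = 5L))
#' @export
toBed <- function(df) {
  stopifnot(all(c("start", "end") %in% names(df)))
  df$start <- df$start - 1L
  df
}

#' @rdname toBed
#' @export
fromBed <- function(df) {
  stopifnot(all(c("start", "end") %in% names(df)))
  df$start <- df$start + 1L
  df
}

# TSV writer with a commented header line
.writeTsv <- function(df, con) {
  lines <- c(paste0("#", paste(names(df), collapse = "\t")),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)),
                                            list(sep = "\t"))))
  writeLines(lines, con)
}
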