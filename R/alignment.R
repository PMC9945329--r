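#' Pairwise position alignment between two proteins
#'
#' An injective mapping between residue positions of two proteins (0-based),
#' as produced by a sequence-based structure alignment. Used to translate
#' contact pairs of one protein onto the other for difference maps and
#' core-swap accounting.
#'
#' @param pos_a,pos_b Integer vectors of equal length: equivalent 0-based
#'   residue positions in protein a and protein b.
#' @return A `position_alignment` (data.frame with columns `pos_a`, `pos_b`).
#' @export
position_alignment <- function(pos_a, pos_b) {
  pos_a <- as.integer(pos_a)
  pos_b <- as.integer(pos_b)
  stopifnot(length(pos_a) == length(pos_b))
  if (anyDuplicated(pos_a) || anyDuplicated(pos_b)) {
    stop("alignment must be injective in both directions")
  }
  if (any(pos_a < 0L) || any(pos_b < 0L)) {
    stop("alignment positions must be non-negative")
  }
  out <- data.frame(pos_a = pos_a, pos_b = pos_b)
  class(out) <- c("position_alignment", "data.frame")
  out
}

#' Identity alignment of length n
#' @param n Number of positions.
#' @return A `position_alignment` mapping i -> i for i in 0..n-1.
#' @export
identity_alignment <- function(n) {
  position_alignment(seq_len(n) - 1L, seq_len(n) - 1L)
}

#' Read an alignment from a two-column TSV or an aligned FASTA pair
#'
#' TSV input: two columns of equivalent positions, 1-based in the file
#' (converted to 0-based internally), `#` comments allowed. FASTA input: a
#' file with exactly two aligned sequences of equal length; columns where
#' both sequences have a residue (not `-`) become aligned position pairs.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"fasta"`; default guessed from the first byte.
#' @return A `position_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, header = FALSE, comment.char = "#")
    if (ncol(tab) < 2L) stop("alignment TSV needs two columns")
    return(position_alignment(tab[[1]] - 1L, tab[[2]] - 1L))
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2L) stop("aligned FASTA must contain exactly two records")
  seq_of <- function(from, to) {
    paste(gsub("\\s", "", lines[from:to]), collapse = "")
  }
  ends <- c(hdr[2] - 1L, length(lines))
  s1 <- seq_of(hdr[1] + 1L, ends[1])
  s2 <- seq_of(hdr[2] + 1L, ends[2])
  if (nchar(s1) != nchar(s2)) stop("aligned sequences differ in length")
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  ia <- cumsum(c1 != "-") - 1L
  ib <- cumsum(c2 != "-") - 1L
  both <- c1 != "-" & c2 != "-"
  position_alignment(ia[both], ib[both])
}

# forward lookup pos_a -> pos_b; NA where unaligned
aln_forward <- function(aln, pos, reverse = FALSE) {
  from <- if (reverse) aln$pos_b else aln$pos_a
  to <- if (reverse) aln$pos_a else aln$pos_b
  to[match(pos, from)]
}
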