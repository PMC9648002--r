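#' Construct a ScaffoldSet
#'
#' A ScaffoldSet is the shared container for any assembly handled by the
#' package: an ordered, uniquely named set of linear nucleotide sequences
#' plus a per-scaffold circularity flag (the mitochondrial scaffold is the
#' only circular one in practice). Sequences are normalized to uppercase
#' and restricted to the alphabet A/C/G/T/N.
#'
#' @param sequences A named character vector or
#'   [Biostrings::DNAStringSet] of scaffold sequences. Names must be
#'   unique and sequences non-empty.
#' @param circular Logical vector (recycled or named) flagging circular
#'   scaffolds; defaults to all-linear.
#' @return An object of class `ScaffoldSet`: a list with elements `seq`
#'   (a `DNAStringSet`) and `circular` (named logical).
#' @examples
#' ss <- ScaffoldSet(c(chr1 = "ACGTACGT", chrM = "ACGT"),
#'                   circular = c(chr1 = FALSE, chrM = TRUE))
#' scaffold_lengths(ss)
#' @export
ScaffoldSet <- function(sequences, circular = NULL) {
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || any(names(sequences) == ""))
      stop("all scaffolds must be named")
    sequences <- toupper(sequences)
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad))
      stop("sequences restricted to A/C/G/T/N; offending scaffold(s): ",
           paste(names(sequences)[bad], collapse = ", "))
    if (any(nchar(sequences) == 0))
      stop("scaffold sequences must be non-empty: ",
           paste(names(sequences)[nchar(sequences) == 0],
                 collapse = ", "))
    sequences <- Biostrings::DNAStringSet(sequences)
  } else if (!methods::is(sequences, "DNAStringSet")) {
    stop("`sequences` must be a named character vector or DNAStringSet")
  }
  nm <- names(sequences)
  if (is.null(nm) || anyDuplicated(nm))
    stop("scaffold names must be present and unique")
  if (any(Biostrings::width(sequences) == 0))
    stop("scaffold sequences must be non-empty: ",
         paste(nm[Biostrings::width(sequences) == 0], collapse = ", "))
  freq <- Biostrings::alphabetFrequency(sequences)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, !(colnames(freq) %in% allowed), drop = FALSE])
  if (any(other > 0))
    stop("sequences restricted to A/C/G/T/N; offending scaffold(s): ",
         paste(nm[other > 0], collapse = ", "))
  if (is.null(circular)) {
    circular <- setNames(rep(FALSE, length(nm)), nm)
  } else if (!is.null(names(circular))) {
    circ <- setNames(rep(FALSE, length(nm)), nm)
    circ[intersect(names(circular), nm)] <-
      circular[intersect(names(circular), nm)]
    circular <- circ
  } else {
    circular <- setNames(rep_len(as.logical(circular), length(nm)), nm)
  }
  structure(list(seq = sequences, circular = circular),
            class = "ScaffoldSet")
}

#' @export
print.ScaffoldSet <- function(x, ...) {
  cat("ScaffoldSet with", length(x$seq), "scaffold(s),",
      format(sum(Biostrings::width(x$seq)), big.mark = ","), "bp total\n")
  n <- min(6L, length(x$seq))
  for (i in seq_len(n))
    cat(sprintf("  %s  %s bp%s\n", names(x$seq)[i],
                format(Biostrings::width(x$seq)[i], big.mark = ","),
                if (x$circular[i]) "  (circular)" else ""))
  if (length(x$seq) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.ScaffoldSet <- function(x) length(x$seq)

#' Scaffold names and lengths
#' @param x A [ScaffoldSet].
#' @return `scaffold_names()` a character vector; `scaffold_lengths()` a
#'   named integer vector of sequence lengths in bp.
#' @export
scaffold_names <- function(x) names(x$seq)

#' @rdname scaffold_names
#' @export
scaffold_lengths <- function(x)
  setNames(Biostrings::width(x$seq), names(x$seq))

#' Extract one scaffold sequence as a character string
#' @param x A [ScaffoldSet].
#' @param name Scaffold name.
#' @param start,end Optional 1-based inclusive sub-range.
#' @export
scaffold_seq <- function(x, name, start = NULL, end = NULL) {
  if (!name %in% names(x$seq)) stop("unknown scaffold: ", name)
  s <- x$seq[[name]]
  if (is.null(start)) start <- 1L
  if (is.null(end)) end <- length(s)
  if (start < 1 || end > length(s) || end < start)
    stop("sub-range [", start, ", ", end, "] outside scaffold ", name)
  as.character(Biostrings::subseq(s, start, end))
}

#' Read and write multi-record FASTA
#'
#' Thin wrappers around Biostrings I/O that apply the ScaffoldSet
#' invariants: names are the first whitespace-delimited token of each
#' header, sequences are uppercased, and an empty record is an error.
#' A write/read round trip preserves names, order and sequence content.
#'
#' @param path File path.
#' @param circular Passed to [ScaffoldSet()].
#' @return `read_fasta()` a [ScaffoldSet].
#' @export
read_fasta <- function(path, circular = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ScaffoldSet(setNames(toupper(as.character(seqs)), names(seqs)),
              circular = circular)
}

#' @rdname read_fasta
#' @param x A [ScaffoldSet].
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "ScaffoldSet"))
  Biostrings::writeXStringSet(x$seq, filepath = path, width = width)
  invisible(path)
}
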