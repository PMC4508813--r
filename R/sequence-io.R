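# Genome sequence I/O and low-level sequence utilities.
#
# Genomes are represented as named character vectors of uppercase DNA over
# {A,C,G,T,N}. All coordinates in the package are 1-based inclusive, the
# native convention of R, IRanges and GFF3.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Split a DNA string into a character vector of single bases
#' @noRd
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Count mismatches between two equal-length base vectors.
#' N never matches anything, including another N.
#' @noRd
.mm_count <- function(a, b) sum(a != b | a == "N" | b == "N")

#' Reverse complement
#'
#' Reverse-complements DNA strings over the alphabet A, C, G, T, N.
#' N maps to N. Vectorized over its input.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    if (grepl("[^ACGTN]", s)) stop("revcomp: alphabet must be A/C/G/T/N")
    paste(rev(.COMP[.chars(s)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a genome from a FASTA file
#'
#' Reads one or more sequences, uppercases them and converts characters
#' outside A/C/G/T/N to N (the number converted is reported via
#' `message()`). Sequence ids are the first whitespace-delimited token of
#' each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  n_bad <- sum(nchar(seqs) - nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    message("read_genome: converted ", n_bad, " non-ACGTN character(s) to N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in FASTA: ", path)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of DNA sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("write_fasta: sequences must be named")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
  invisible(path)
}

#' Shannon entropy (bits) of overlapping dinucleotides
#'
#' Used to flag low-complexity hairpin stems: mono- and di-nucleotide
#' repeats have dinucleotide entropy of at most 1 bit.
#'
#' @param s a DNA string (length >= 2).
#' @return entropy in bits.
#' @export
dinucleotide_entropy <- function(s) {
  ch <- .chars(s)
  n <- length(ch)
  if (n < 2L) return(0)
  di <- paste0(ch[-n], ch[-1L])
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

#' Run with a temporary RNG seed, restoring global RNG state
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Greedy selection of mutually non-overlapping intervals
#'
#' @param df data frame with `start` and `end` columns (and optionally
#'   `seqid`), already ordered by decreasing priority.
#' @return logical vector: keep this row?
#' @noRd
.greedy_nonoverlap <- function(df) {
  n <- nrow(df)
  keep <- logical(n)
  if (n == 0L) return(keep)
  sid <- if ("seqid" %in% names(df)) as.character(df$seqid) else rep("", n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in kept_idx) {
      if (sid[i] == sid[j] &&
          df$start[i] <= df$end[j] && df$end[i] >= df$start[j]) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  keep
}
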