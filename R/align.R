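# Alignment helpers shared by the detectors and the curation operations:
# global/local pairwise identity, consensus building against a centroid,
# and the substitution-only consensus-to-genome matcher that stands in for
# an external masker/mapper.

.sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Global pairwise identity of two DNA strings
#'
#' Identity is matches / alignment length of a Needleman-Wunsch global
#' alignment, counting every alignment column including terminal gaps.
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
global_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .sub_matrix(), gapOpening = 4, gapExtension = 1)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- .chars(as.character(Biostrings::alignedSubject(aln)))
  sum(pa == sa & pa != "-" & pa != "N") / length(pa)
}

#' Does a sequence pair satisfy an identity/coverage/length family rule?
#'
#' The 80-80-80 style criterion: a local alignment of at least `min_len`
#' columns, covering at least `min_cov` of the shorter sequence, at
#' identity at least `min_id`.
#'
#' @param a,b DNA strings.
#' @param min_id minimum identity over the aligned region.
#' @param min_cov minimum fraction of the shorter sequence aligned.
#' @param min_len minimum alignment length in bp.
#' @return logical.
#' @export
pair_in_family <- function(a, b, min_id = 0.80, min_cov = 0.80,
                           min_len = 80L) {
  short <- min(nchar(a), nchar(b))
  if (short == 0L) return(FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- .chars(as.character(Biostrings::alignedSubject(aln)))
  ncols <- length(pa)
  if (ncols == 0L) return(FALSE)
  ident <- sum(pa == sa & pa != "-" & pa != "N") / ncols
  ncols >= max(min_len, ceiling(min_cov * short)) && ident >= min_id
}

#' Majority-rule consensus of sequences against a centroid
#'
#' Each member is globally aligned to the centroid; bases are collected per
#' centroid column (insertions relative to the centroid are ignored,
#' deletions count as gaps). The consensus takes the per-column majority
#' character, drops majority-gap columns, and breaks ties in the fixed base
#' order A < C < G < T (a base always beats a gap in a tie).
#'
#' @param members character vector of member sequences (oriented).
#' @param centroid the centroid sequence the columns refer to.
#' @return consensus DNA string.
#' @export
consensus_against_centroid <- function(members, centroid) {
  stopifnot(length(members) >= 1L, nchar(centroid) >= 1L)
  nc <- nchar(centroid)
  mat <- matrix("-", nrow = length(members), ncol = nc)
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (m == centroid) {
      mat[i, ] <- .chars(m)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(m), Biostrings::DNAString(centroid),
      type = "global", substitutionMatrix = .sub_matrix(),
      gapOpening = 4, gapExtension = 1)
    pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
    sa <- .chars(as.character(Biostrings::alignedSubject(aln)))
    cpos <- cumsum(sa != "-")
    keep <- sa != "-"
    mat[i, cpos[keep]] <- pa[keep]
  }
  base_order <- c("A", "C", "G", "T", "N", "-")
  cons <- vapply(seq_len(nc), function(j) {
    col <- mat[, j]
    tab <- table(factor(col, levels = base_order))
    best <- names(tab)[which.max(tab)]  # which.max takes first max: A<C<G<T, gap last
    best
  }, character(1))
  paste(cons[cons != "-"], collapse = "")
}

#' Find genome copies of a consensus by substitution-only scanning
#'
#' Slides the consensus (and its reverse complement) along the sequence and
#' reports every full-length placement whose Hamming identity is at least
#' `min_identity`. N never matches. Used as the internal stand-in for an
#' external masking/mapping tool; it does not recover indel-diverged or
#' truncated copies.
#'
#' @param seq a DNA string.
#' @param consensus the query sequence.
#' @param min_identity minimum identity fraction.
#' @param strands strands to scan (`"+"`, `"-"` or both).
#' @return data frame with columns start, end, strand, mm, identity.
#' @export
match_consensus <- function(seq, consensus, min_identity = 0.80,
                            strands = c("+", "-")) {
  len <- nchar(consensus)
  stopifnot(len >= 1L)
  max_mm <- floor((1 - min_identity) * len)
  subj <- Biostrings::DNAString(seq)
  chv <- .chars(seq)
  out <- list()
  for (st in strands) {
    pat <- if (st == "+") consensus else revcomp(consensus)
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0L) next
    starts <- BiocGenerics::start(hits)
    ends <- BiocGenerics::end(hits)
    pchv <- .chars(pat)
    mm <- vapply(seq_along(starts), function(i) {
      .mm_count(chv[starts[i]:ends[i]], pchv)
    }, integer(1))
    keep <- mm <= max_mm
    if (!any(keep)) next
    out[[st]] <- data.frame(start = starts[keep], end = ends[keep],
                            strand = st, mm = mm[keep],
                            identity = 1 - mm[keep] / len,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mm = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}
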