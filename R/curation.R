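# Repeat-library post-processing shared across datasets: composition
# filtering, redundancy clustering at 90 % identity, family definition
# (the 80-80-80 convention), within-family centroid selection (d = 0.80),
# the small-family filter for LTR retrotransposon libraries, and the TRIM
# length/reverse-transcriptase filter.

#' Base-composition filter
#'
#' Removes sequences whose AT or GC content falls below `min_frac`
#' ("less than 5 % AT or GC content"). N bases are excluded from both the
#' numerator and the denominator; all-N sequences are removed.
#'
#' @param seqs named character vector of sequences.
#' @param min_frac removal threshold (default 0.05; a sequence at exactly
#'   5 % is kept).
#' @return list with `kept` and `removed` (both named character vectors).
#' @export
composition_filter <- function(seqs, min_frac = 0.05) {
  stopifnot(all(nchar(seqs) > 0L))
  frac <- vapply(seqs, function(s) {
    ch <- .chars(s)
    ch <- ch[ch != "N"]
    if (length(ch) == 0L) return(c(at = -1, gc = -1))  # all-N: removed
    c(at = mean(ch %in% c("A", "T")), gc = mean(ch %in% c("G", "C")))
  }, numeric(2))
  remove <- frac["at", ] < min_frac | frac["gc", ] < min_frac
  if (any(frac["at", ] < 0))
    message("composition_filter: removed ", sum(frac["at", ] < 0),
            " all-N sequence(s)")
  list(kept = seqs[!remove], removed = seqs[remove])
}

#' Greedy redundancy clustering of a repeat library
#'
#' Greedy incremental clustering, longest sequence first (lexicographic
#' tie-break): a sequence joins the first centroid to which its global
#' identity reaches `threshold`, otherwise founds a new cluster. Cluster
#' centroids are the non-redundant library representatives.
#'
#' @param seqs named character vector of sequences.
#' @param threshold identity threshold (default 0.90).
#' @return data frame with columns id, cluster, centroid_id, identity (to
#'   the centroid; 1 for centroids themselves).
#' @export
cluster_redundancy <- function(seqs, threshold = 0.90) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  cent_idx <- integer(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(cent_idx)) {
      ident <- global_identity(seqs[[i]], seqs[[cent_idx[k]]])
      if (ident >= threshold) {
        rows[[i]] <- data.frame(id = names(seqs)[i], cluster = k,
                                centroid_id = names(seqs)[cent_idx[k]],
                                identity = ident, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      k <- length(cent_idx)
      rows[[i]] <- data.frame(id = names(seqs)[i], cluster = k,
                              centroid_id = names(seqs)[i], identity = 1,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Define families by single-linkage under an identity/coverage rule
#'
#' Two sequences are linked when they share at least `min_id` identity
#' over at least `min_cov` of the shorter sequence with an aligned region
#' of at least `min_len` bp (the 80-80-80 convention); families are the
#' connected components. Family ids are assigned by decreasing family
#' size.
#'
#' @param seqs named character vector.
#' @param min_id,min_cov,min_len family-definition parameters.
#' @return data frame with columns id, family_id.
#' @export
define_families <- function(seqs, min_id = 0.80, min_cov = 0.80,
                            min_len = 80L) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(i + 1L, n)) {
      if (find(i) == find(j)) next
      if (pair_in_family(seqs[[i]], seqs[[j]], min_id, min_cov, min_len))
        parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), names(sizes))
  fam_of <- stats::setNames(seq_along(ord), names(sizes)[ord])
  data.frame(id = names(seqs),
             family_id = as.integer(fam_of[as.character(comp)]),
             stringsAsFactors = FALSE)
}

#' Select within-family centroid representatives
#'
#' Greedy clustering of one family's members at identity `d`
#' (longest-first); the centroids are returned as the family's
#' non-redundant representatives.
#'
#' @param seqs named character vector of one family's members.
#' @param d identity threshold (default 0.80).
#' @return character vector of representative ids.
#' @export
select_centroids <- function(seqs, d = 0.80) {
  stopifnot(length(seqs) >= 1L)
  cl <- cluster_redundancy(seqs, threshold = d)
  unique(cl$centroid_id)
}

#' Remove small families without retroelement protein domains
#'
#' A family is kept when it has at least `min_copies` members or any
#' member carries a Copia or Gypsy domain annotation. Annotations are
#' supplied externally; missing ids are treated as domain-free.
#'
#' @param families data frame with columns id, family_id.
#' @param domains optional data frame with columns id and domain (values
#'   `"copia"`, `"gypsy"`, `"none"`).
#' @param min_copies minimum family size (default 3, inclusive).
#' @return filtered `families`.
#' @export
filter_small_families <- function(families, domains = NULL,
                                  min_copies = 3L) {
  dom <- rep("none", nrow(families))
  if (!is.null(domains) && nrow(domains) > 0L) {
    m <- match(families$id, domains$id)
    dom[!is.na(m)] <- domains$domain[m[!is.na(m)]]
  }
  keep_fams <- vapply(split(seq_len(nrow(families)), families$family_id),
                      function(idx) {
                        length(idx) >= min_copies ||
                          any(dom[idx] %in% c("copia", "gypsy"))
                      }, logical(1))
  fams_ok <- names(keep_fams)[keep_fams]
  families[as.character(families$family_id) %in% fams_ok, , drop = FALSE]
}

#' TRIM length / reverse-transcriptase filter
#'
#' Keeps elements shorter than `max_len` (exclusive) without reverse
#' transcriptase homology; terminal-repeat retrotransposons in miniature
#' are by definition short and non-autonomous.
#'
#' @param seqs named character vector of elements.
#' @param rt_homology named logical vector (or NULL for all-FALSE).
#' @param max_len maximum length in bp (default 1600, exclusive).
#' @return named character vector of retained elements.
#' @export
trim_filter <- function(seqs, rt_homology = NULL, max_len = 1600L) {
  if (is.null(rt_homology)) rt_homology <- stats::setNames(
    rep(FALSE, length(seqs)), names(seqs))
  rt <- rt_homology[names(seqs)]
  rt[is.na(rt)] <- FALSE
  seqs[nchar(seqs) < max_len & !rt]
}
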