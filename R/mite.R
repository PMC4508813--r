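# Non-autonomous DNA transposon (MITE) discovery.
#
# The genome is scanned in 1000 bp windows (200 bp overlap) for inverted
# repeats flanked by a target-site duplication:
#   * Stowaway: TA dinucleotide TSD immediately flanking the element, and
#     the canonical CTCCTCCC motif within the terminal inverted repeat;
#   * Tourist: identical 3 bp flanks, TIR beginning with G or C and at
#     least 8 bp long.
# Candidates are clustered into multi-copy groups (reverse-complement
# redundancy folded), a consensus is derived per group, refined from 30-40
# genomic copies, and final consensuses are mapped back to the genome with
# longest-hit priority at shared loci.

#' Superfamily structural rule for the inverted-repeat scan
#'
#' @param name `"stowaway"` or `"tourist"`.
#' @return an object of class `mite_rule` with fields name, tsd_len,
#'   tsd_literal, tir_motif, min_tir, first_base.
#' @export
mite_rule <- function(name = c("stowaway", "tourist")) {
  name <- match.arg(name)
  if (name == "stowaway") {
    structure(list(name = "stowaway", tsd_len = 2L, tsd_literal = "TA",
                   tir_motif = "CTCCTCCC", min_tir = 10L,
                   first_base = NULL), class = "mite_rule")
  } else {
    structure(list(name = "tourist", tsd_len = 3L, tsd_literal = NULL,
                   tir_motif = NULL, min_tir = 8L,
                   first_base = c("G", "C")), class = "mite_rule")
  }
}

#' Tile a sequence into overlapping scan windows
#'
#' Windows start at multiples of `size - overlap`; the last window is
#' clamped to the sequence end. Their union covers every base.
#'
#' @param len sequence length.
#' @param size window size (default 1000).
#' @param overlap window overlap (default 200); must be below `size`.
#' @return data frame with columns start, end (1-based inclusive).
#' @export
iter_windows <- function(len, size = 1000L, overlap = 200L) {
  if (size <= overlap) stop("window size must exceed overlap")
  starts <- seq.int(1L, max(1L, len - overlap), by = size - overlap)
  data.frame(start = starts, end = pmin(starts + size - 1L, len))
}

.empty_mite_cands <- function() {
  data.frame(start = integer(), end = integer(), tir_len = integer(),
             kind = character(), tsd = character(), seq = character(),
             stringsAsFactors = FALSE)
}

# Precomputed whole-sequence flank index, shared across windows:
# stowaway: positions of TA dinucleotides; tourist: 3-mer codes and the
# (sorted) positions of each 3-mer.
.mite_scan_index <- function(chv, rule) {
  n <- length(chv)
  if (rule$name == "stowaway") {
    list(ta_at = which(chv[-n] == "T" & chv[-1L] == "A"))
  } else {
    code <- c(A = 0L, C = 1L, G = 2L, T = 3L)[chv]
    c3 <- code[seq_len(n - 2L)] * 16L +
      code[seq_len(n - 2L) + 1L] * 4L + code[seq_len(n - 2L) + 2L]
    valid3 <- which(!is.na(c3))
    list(c3 = c3, pos_by_code = split(valid3, c3[valid3]))
  }
}

# Sorted-vector range extraction: values of v in [lo, hi].
.in_range <- function(v, lo, hi) {
  i <- findInterval(lo - 0.5, v) + 1L
  j <- findInterval(hi + 0.5, v)
  if (i > j) integer(0) else v[i:j]
}

# Maximal TIR length per (s, e) pair: the largest t <= floor(len/2) whose
# cumulative arm substitution count stays within max_mm (N never matches).
# Vectorized over e for a fixed s.
.tir_lengths <- function(chv, s, es, max_mm) {
  tcap <- pmax(0L, (es - s + 1L) %/% 2L)
  tl <- integer(length(es))
  mm <- integer(length(es))
  active <- which(tcap >= 1L)
  t <- 1L
  while (length(active) > 0L) {
    a <- chv[s + t - 1L]
    b <- chv[es[active] - t + 1L]
    ok <- a != "N" & b != "N" & a == .COMP[b]
    mm[active] <- mm[active] + !ok
    surv <- mm[active] <= max_mm
    tl[active[surv]] <- t
    active <- active[surv & t + 1L <= tcap[active]]
    t <- t + 1L
  }
  tl
}

#' Detect MITE candidates on a sequence region
#'
#' Enumerates all (start, end) pairs with element length in
#' `[min_len, max_len]`, terminal inverted complementarity with at most
#' `max_tir_mm` substitutions, the rule's TIR constraints, and the flanking
#' TSD (literal TA for Stowaway; identical 3-mers for Tourist). The
#' reported `tir_len` is the maximal complementary length. Both element
#' orientations are accepted (the structure is reverse-complement
#' symmetric; orientation-specific constraints are checked on both
#' readings). `from`/`to` bound the element start position; the element
#' body and flanks are read from the full sequence.
#'
#' @param seq a DNA string (or its character vector).
#' @param rule a [mite_rule()].
#' @param from,to bounds for the element start (default whole sequence).
#' @param min_len,max_len element length bounds (bp).
#' @param max_tir_mm maximum TIR substitutions (default 1).
#' @param .index precomputed [.mite_scan_index] (internal; built when NULL).
#' @return data frame with columns start, end, tir_len, kind, tsd, seq.
#' @export
detect_mite_candidates <- function(seq, rule, from = 1L, to = NULL,
                                   min_len = 50L, max_len = 800L,
                                   max_tir_mm = 1L, .index = NULL) {
  chv <- if (is.character(seq) && length(seq) == 1L) .chars(seq) else seq
  n <- length(chv)
  if (is.null(to)) to <- n
  k <- rule$tsd_len
  from <- max(from, k + 1L)
  to <- min(to, n - min_len + 1L - k)
  if (from > to) return(.empty_mite_cands())

  if (is.null(.index)) .index <- .mite_scan_index(chv, rule)

  rows <- list()
  for (s in from:to) {
    # Left TSD constraint.
    if (rule$name == "stowaway") {
      if (!(chv[s - 2L] == "T" && chv[s - 1L] == "A")) next
      e_lo <- s + min_len - 1L
      e_hi <- min(s + max_len - 1L, n - 2L)
      if (e_lo > e_hi) next
      es <- .in_range(.index$ta_at, e_lo + 1L, e_hi + 1L) - 1L
    } else {
      left3 <- .index$c3[s - 3L]
      if (is.na(left3)) next
      e_lo <- s + min_len - 1L
      e_hi <- min(s + max_len - 1L, n - 3L)
      if (e_lo > e_hi) next
      cand <- .index$pos_by_code[[as.character(left3)]]
      if (is.null(cand)) next
      es <- .in_range(cand, e_lo + 1L, e_hi + 1L) - 1L
      if (length(es) > 0L) {
        # First-base rule on either element reading: the 5' TIR begins
        # with G/C on the plus reading (base at s) or on the reverse
        # complement reading (complement of base at e, i.e. chv[e] G/C).
        es <- es[chv[s] %in% rule$first_base | chv[es] %in% rule$first_base]
      }
    }
    if (length(es) == 0L) next
    tl <- .tir_lengths(chv, s, es, max_tir_mm)
    ok <- tl >= rule$min_tir
    es <- es[ok]; tl <- tl[ok]
    if (length(es) == 0L) next
    if (!is.null(rule$tir_motif)) {
      rc_motif <- revcomp(rule$tir_motif)
      keep <- vapply(seq_along(es), function(ii) {
        t <- tl[ii]
        tir5 <- paste(chv[s:(s + t - 1L)], collapse = "")
        tir3 <- paste(chv[(es[ii] - t + 1L):es[ii]], collapse = "")
        grepl(rule$tir_motif, tir5, fixed = TRUE) ||
          grepl(rc_motif, tir5, fixed = TRUE) ||
          grepl(rule$tir_motif, tir3, fixed = TRUE) ||
          grepl(rc_motif, tir3, fixed = TRUE)
      }, logical(1))
      es <- es[keep]; tl <- tl[keep]
      if (length(es) == 0L) next
    }
    tsd <- if (rule$name == "stowaway") rep("TA", length(es)) else
      paste(chv[s - 3L], chv[s - 2L], chv[s - 1L], sep = "")
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = es, tir_len = tl, kind = rule$name, tsd = tsd,
      seq = vapply(es, function(e) paste(chv[s:e], collapse = ""),
                   character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.empty_mite_cands())
  res <- do.call(rbind, rows)
  res <- unique(res)
  rownames(res) <- NULL
  res[order(res$start, res$end), , drop = FALSE]
}

#' Windowed MITE candidate scan over a whole sequence
#'
#' Applies [detect_mite_candidates()] to each [iter_windows()] window
#' (window bounds constrain the element start; flanks and body are read
#' from the full sequence) and deduplicates candidates found in
#' overlapping windows. Candidates overlapping `exclude` intervals — e.g.
#' previously annotated large elements, whose internal repeats would
#' otherwise satisfy the loose inverted-repeat rules — are dropped.
#'
#' @param seq a DNA string.
#' @param rule a [mite_rule()].
#' @param window_size,window_overlap window tiling parameters.
#' @param exclude optional data frame with start/end columns of intervals
#'   to exclude.
#' @param ... passed to [detect_mite_candidates()].
#' @return candidate data frame.
#' @export
scan_mite_candidates <- function(seq, rule, window_size = 1000L,
                                 window_overlap = 200L, exclude = NULL,
                                 ...) {
  chv <- .chars(seq)
  idx <- .mite_scan_index(chv, rule)
  wins <- iter_windows(length(chv), window_size, window_overlap)
  parts <- lapply(seq_len(nrow(wins)), function(i) {
    detect_mite_candidates(chv, rule, from = wins$start[i], to = wins$end[i],
                           .index = idx, ...)
  })
  res <- do.call(rbind, parts)
  if (is.null(res) || nrow(res) == 0L) return(.empty_mite_cands())
  res <- unique(res)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    bad <- vapply(seq_len(nrow(res)), function(i) {
      any(res$start[i] <= exclude$end & res$end[i] >= exclude$start)
    }, logical(1))
    res <- res[!bad, , drop = FALSE]
  }
  rownames(res) <- NULL
  res[order(res$start, res$end), , drop = FALSE]
}

# 8-mer integer fingerprint of a sequence, for cheap cluster prescreens.
.kmer_fingerprint <- function(s, k = 8L) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)[.chars(s)]
  n <- length(code)
  if (n < k) return(integer(0))
  v <- integer(n - k + 1L)
  for (j in seq_len(k)) {
    v <- v * 4L + code[j:(n - k + j)]
  }
  unique(v[!is.na(v)])
}

#' Cluster MITE candidates into multi-copy groups
#'
#' Greedy centroid clustering, longest candidate first: each candidate
#' joins the first existing centroid to which its global identity (either
#' orientation) reaches `identity_threshold`, otherwise founds a new
#' centroid. Reverse-complement redundancy is thereby folded. Singleton
#' groups (single-copy sequences) are discarded. A shared-8-mer prescreen
#' avoids aligning unrelated pairs.
#'
#' @param cands candidate data frame (needs a `seq` column).
#' @param identity_threshold minimum identity to a centroid (default 0.80).
#' @return list of groups; each group is a list with `centroid` (sequence),
#'   `members` (candidate rows) and `oriented` (member sequences in
#'   centroid orientation).
#' @export
cluster_mite_candidates <- function(cands, identity_threshold = 0.80) {
  if (nrow(cands) == 0L) return(list())
  ord <- order(-nchar(cands$seq), cands$seq)
  cands <- cands[ord, , drop = FALSE]
  centroids <- character(0)
  fps <- list()
  assign_to <- integer(nrow(cands))
  orient <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    s <- cands$seq[i]
    rc <- revcomp(s)
    fp <- .kmer_fingerprint(s)
    fp_rc <- .kmer_fingerprint(rc)
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      shared_f <- mean(fp %in% fps[[ci]])
      shared_r <- mean(fp_rc %in% fps[[ci]])
      if (max(shared_f, shared_r, na.rm = TRUE) < 0.3) next
      if (shared_f >= shared_r) {
        if (global_identity(s, centroids[ci]) >= identity_threshold) {
          assign_to[i] <- ci; orient[i] <- "+"; placed <- TRUE; break
        }
      }
      if (!placed && global_identity(rc, centroids[ci]) >= identity_threshold) {
        assign_to[i] <- ci; orient[i] <- "-"; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, s)
      fps[[length(centroids)]] <- fp
      assign_to[i] <- length(centroids)
      orient[i] <- "+"
    }
  }
  groups <- list()
  for (ci in seq_along(centroids)) {
    idx <- which(assign_to == ci)
    if (length(idx) < 2L) next  # singleton: not a multi-copy family
    memb <- cands[idx, , drop = FALSE]
    # "Multiple copies" means distinct loci: overlapping member intervals
    # (nested candidate calls at one site) count as one copy.
    sid <- if ("seqid" %in% names(memb)) memb$seqid else rep("", nrow(memb))
    o <- order(sid, memb$start, memb$end)
    n_loci <- 1L
    hi <- memb$end[o[1]]; cur_sid <- sid[o[1]]
    for (r in o[-1]) {
      if (sid[r] != cur_sid || memb$start[r] > hi) {
        n_loci <- n_loci + 1L
        cur_sid <- sid[r]; hi <- memb$end[r]
      } else hi <- max(hi, memb$end[r])
    }
    if (n_loci < 2L) next
    oriented <- ifelse(orient[idx] == "+", memb$seq, revcomp(memb$seq))
    groups[[length(groups) + 1L]] <- list(centroid = centroids[ci],
                                          members = memb,
                                          oriented = oriented)
  }
  # Largest family first; ties by centroid string for determinism.
  sizes <- vapply(groups, function(g) nrow(g$members), integer(1))
  cents <- vapply(groups, function(g) g$centroid, character(1))
  groups[order(-sizes, cents)]
}

#' First-round consensus of a candidate group
#'
#' Majority-rule consensus of the group members
#' (see [consensus_against_centroid()]). The reference is a member of the
#' group's modal length rather than the clustering centroid: the centroid
#' is the longest member by construction, and a chance boundary-extended
#' variant in that position would otherwise skew the consensus ends, while
#' true TSD-anchored candidates share the exact element length and
#' dominate the length distribution.
#'
#' @param group one group from [cluster_mite_candidates()].
#' @return consensus DNA string.
#' @export
build_mite_consensus <- function(group) {
  stopifnot(length(group$oriented) >= 2L)
  lens <- nchar(group$oriented)
  tab <- table(lens)
  modal <- as.integer(names(tab)[order(-as.integer(tab),
                                       as.integer(names(tab)))][1])
  ref <- group$oriented[which(lens == modal)[1]]
  consensus_against_centroid(group$oriented, ref)
}

#' Second-round consensus from genomic copies
#'
#' Re-collects up to `n_copies` best-identity genomic copies of the
#' consensus and rebuilds the consensus from them; fewer than `min_copies`
#' available copies are all used (reported via `message()`). A consensus
#' that maps nowhere is returned unchanged.
#'
#' @param consensus first-round consensus.
#' @param seq genome sequence.
#' @param n_copies maximum copies used (default 40).
#' @param min_copies intended minimum (default 30).
#' @param min_identity minimum copy identity.
#' @return refined consensus string.
#' @export
refine_mite_consensus <- function(consensus, seq, n_copies = 40L,
                                  min_copies = 30L, min_identity = 0.80) {
  hits <- match_consensus(seq, consensus, min_identity = min_identity)
  if (nrow(hits) == 0L) {
    message("refine_mite_consensus: consensus maps nowhere; kept unchanged")
    return(consensus)
  }
  hits <- hits[order(-hits$identity, hits$start), , drop = FALSE]
  hits <- utils::head(hits, n_copies)
  if (nrow(hits) < min_copies) {
    message("refine_mite_consensus: only ", nrow(hits),
            " copies available (intended ", min_copies, "-", n_copies, ")")
  }
  copies <- vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(seq, hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }, character(1))
  consensus_against_centroid(copies, consensus)
}

#' Map family consensuses to the genome with longest-hit priority
#'
#' Collects hits of all family consensuses on both strands and resolves
#' overlapping hits greedily by decreasing hit length, then higher
#' identity, then lower family id; surviving placements are pairwise
#' non-overlapping.
#'
#' @param seq genome sequence.
#' @param families data frame with columns family_id, consensus, kind.
#' @param min_identity minimum placement identity.
#' @return data frame with columns family_id, kind, start, end, strand,
#'   identity.
#' @export
map_mite_families <- function(seq, families, min_identity = 0.80) {
  empty <- data.frame(family_id = integer(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(families) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(families))) {
    h <- match_consensus(seq, families$consensus[i],
                         min_identity = min_identity)
    if (nrow(h) == 0L) next
    h$family_id <- families$family_id[i]
    h$kind <- families$kind[i]
    out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-(res$end - res$start), -res$identity, res$family_id,
                   res$start), , drop = FALSE]
  res <- res[.greedy_nonoverlap(res), , drop = FALSE]
  res <- res[order(res$start),
             c("family_id", "kind", "start", "end", "strand", "identity")]
  rownames(res) <- NULL
  res
}

#' MITE discovery pipeline on a genome
#'
#' Windowed candidate scan under the requested rules, clustering into
#' multi-copy groups, two-round consensus building, and genome-wide
#' placement with longest-hit priority.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param rules character vector among `"stowaway"`, `"tourist"`.
#' @param exclude optional data frame of intervals (seqid, start, end) to
#'   exclude from the candidate scan (e.g. previously annotated elements).
#' @param min_len,max_len,max_tir_mm candidate-scan parameters.
#' @param window_size,window_overlap window tiling parameters.
#' @param identity_threshold clustering identity threshold.
#' @param min_identity_map placement identity threshold.
#' @param refine second-round consensus refinement (default TRUE).
#' @return list with `calls` (placements, with seqid and kind columns),
#'   `families` (consensus table) and `candidates`.
#' @export
find_mites <- function(genome, rules = c("stowaway", "tourist"),
                       exclude = NULL, min_len = 50L, max_len = 800L,
                       max_tir_mm = 1L, window_size = 1000L,
                       window_overlap = 200L, identity_threshold = 0.80,
                       min_identity_map = 0.80, refine = TRUE) {
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  all_cands <- list()
  for (sid in names(genome)) {
    excl <- if (!is.null(exclude)) {
      if ("seqid" %in% names(exclude))
        exclude[exclude$seqid == sid, , drop = FALSE]
      else exclude
    }
    for (rn in rules) {
      cc <- scan_mite_candidates(genome[[sid]], mite_rule(rn),
                                 window_size, window_overlap, exclude = excl,
                                 min_len = min_len, max_len = max_len,
                                 max_tir_mm = max_tir_mm)
      if (nrow(cc) > 0L) {
        cc$seqid <- sid
        all_cands[[paste(sid, rn)]] <- cc
      }
    }
  }
  cands <- if (length(all_cands)) do.call(rbind, all_cands) else {
    e <- .empty_mite_cands(); e$seqid <- character(0); e
  }
  groups <- list()
  for (rn in rules) {
    sub <- cands[cands$kind == rn, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gg <- cluster_mite_candidates(sub, identity_threshold)
    for (g in gg) { g$kind <- rn; groups[[length(groups) + 1L]] <- g }
  }
  # Family-level redundancy removal: shifted variant candidates of one
  # element family can cluster into their own smaller group; a group
  # whose member loci mostly overlap a larger retained family is
  # redundant with it and dropped.
  sizes <- vapply(groups, function(g) nrow(g$members), integer(1))
  cents <- vapply(groups, function(g) g$centroid, character(1))
  groups <- groups[order(-sizes, cents)]
  retained <- list()
  taken <- data.frame(seqid = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  for (g in groups) {
    m <- g$members
    sid <- if ("seqid" %in% names(m)) as.character(m$seqid) else
      rep("", nrow(m))
    ovl <- vapply(seq_len(nrow(m)), function(i) {
      any(taken$seqid == sid[i] & m$start[i] <= taken$end &
            m$end[i] >= taken$start)
    }, logical(1))
    if (mean(ovl) > 0.5) next
    retained[[length(retained) + 1L]] <- g
    taken <- rbind(taken, data.frame(seqid = sid, start = m$start,
                                     end = m$end, stringsAsFactors = FALSE))
  }
  fam_rows <- list()
  fid <- 0L
  for (g in retained) {
    cons <- build_mite_consensus(g)
    if (refine) {
      for (sid in names(genome)) {
        cons <- suppressMessages(
          refine_mite_consensus(cons, genome[[sid]],
                                min_identity = min_identity_map))
      }
    }
    fid <- fid + 1L
    fam_rows[[fid]] <- data.frame(family_id = fid, kind = g$kind,
                                  consensus = cons,
                                  n_members = nrow(g$members),
                                  stringsAsFactors = FALSE)
  }
  families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family_id = integer(), kind = character(),
               consensus = character(), n_members = integer(),
               stringsAsFactors = FALSE)
  calls <- list()
  for (sid in names(genome)) {
    pl <- map_mite_families(genome[[sid]], families,
                            min_identity = min_identity_map)
    if (nrow(pl) > 0L) {
      pl$seqid <- sid
      calls[[sid]] <- pl
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(family_id = integer(), kind = character(), start = integer(),
               end = integer(), strand = character(), identity = numeric(),
               seqid = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, families = families, candidates = cands)
}
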