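# MULE (Mutator-like element) detection from a TIR-family library.
#
# A complete MULE is called when: 1) two hits of the same TIR family are
# found, 2) in opposite orientation, 3) with an inner distance below 20 kb,
# and 4) a 7-11 bp target-site duplication (TSD) flanks both repeats, with
# at most 2 mismatches/indels for 9-11 bp TSDs, 1 for 8 bp, and a perfect
# match for 7 bp, allowing a 10 bp swing of each TSD from the putative
# element ends. De novo TIR families additionally require at least five
# validated elements genome-wide. Calls are classified as autonomous
# (transposase homology and length > 3 kb), Pack-MULE (non-transposase
# protein homology) or non-autonomous; protein homology and masking
# fractions are supplied as input tables.

#' TSD validation rules
#'
#' @param lengths TSD lengths to try (decreasingly diagnostic; default
#'   7-11 bp).
#' @param tolerance named vector of maximum edit distances per length.
#' @param swing maximum offset of each TSD from the putative element end.
#' @return an object of class `tsd_rules`.
#' @export
tsd_rules <- function(lengths = 7:11,
                      tolerance = c("7" = 0L, "8" = 1L, "9" = 2L,
                                    "10" = 2L, "11" = 2L),
                      swing = 10L) {
  stopifnot(all(as.character(lengths) %in% names(tolerance)))
  structure(list(lengths = as.integer(lengths),
                 tolerance = tolerance, swing = as.integer(swing)),
            class = "tsd_rules")
}

#' Build a TIR-family library
#'
#' @param consensus character vector of TIR consensus sequences.
#' @param family_id optional ids (default sequence along input).
#' @param source `"known"` or `"de_novo"` per family; de novo families are
#'   subject to the minimum-support rule in [call_mules()].
#' @return data frame with columns family_id, consensus, source.
#' @export
tir_library <- function(consensus, family_id = seq_along(consensus),
                        source = "de_novo") {
  stopifnot(length(consensus) >= 1L, all(nchar(consensus) > 0L))
  data.frame(family_id = family_id, consensus = toupper(consensus),
             source = rep_len(source, length(consensus)),
             stringsAsFactors = FALSE)
}

#' Remove TIR families heavily masked by known non-MULE repeats
#'
#' Families with at least `max_masked` of their length masked are removed;
#' families absent from the table are treated as unmasked (and reported).
#'
#' @param lib TIR library data frame.
#' @param masks data frame with columns family_id and masked_frac, or NULL.
#' @param max_masked removal threshold (default 0.30: a family at exactly
#'   30 percent is removed).
#' @return filtered library.
#' @export
filter_tir_library <- function(lib, masks = NULL, max_masked = 0.30) {
  if (is.null(masks) || nrow(masks) == 0L) return(lib)
  frac <- masks$masked_frac[match(lib$family_id, masks$family_id)]
  if (anyNA(frac)) {
    message("filter_tir_library: ", sum(is.na(frac)),
            " family(ies) missing from mask table; treated as unmasked")
    frac[is.na(frac)] <- 0
  }
  lib[frac < max_masked, , drop = FALSE]
}

#' Locate TIR-library hits on a sequence
#'
#' Substitution-only sliding scan of each family consensus on both strands
#' at identity at least `min_identity` (full consensus length; the
#' internal stand-in for an external masking run). Overlapping hits are
#' resolved to the best per locus (highest identity, then longest).
#'
#' @param seq a DNA string.
#' @param lib TIR library data frame.
#' @param min_identity minimum hit identity (default 0.80).
#' @return data frame with columns family_id, start, end, strand, identity.
#' @export
locate_tir_hits <- function(seq, lib, min_identity = 0.80) {
  out <- list()
  for (i in seq_len(nrow(lib))) {
    if (nchar(lib$consensus[i]) < 10L)
      stop("TIR consensus shorter than 10 bp (family ",
           lib$family_id[i], ")")
    h <- match_consensus(seq, lib$consensus[i], min_identity = min_identity)
    if (nrow(h) == 0L) next
    h$family_id <- lib$family_id[i]
    out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0L) {
    return(data.frame(family_id = integer(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$identity, -(res$end - res$start)), , drop = FALSE]
  res <- res[.greedy_nonoverlap(res), , drop = FALSE]
  res <- res[order(res$start), c("family_id", "start", "end", "strand",
                                 "identity")]
  rownames(res) <- NULL
  res
}

#' Pair TIR hits into candidate elements
#'
#' Candidates are (plus-strand hit, downstream minus-strand hit) pairs of
#' the same family with inner distance (between TIR inner edges) below
#' `max_span`. Nested/overlapping pairs all become candidates; they are
#' disambiguated after TSD validation.
#'
#' @param hits data frame from [locate_tir_hits()].
#' @param max_span maximum inner distance in bp (exclusive; default 20000).
#' @return data frame with columns family_id, start, end, tir1_start,
#'   tir1_end, tir2_start, tir2_end, inner_dist.
#' @export
pair_tirs <- function(hits, max_span = 20000L) {
  empty <- data.frame(family_id = integer(), start = integer(),
                      end = integer(), tir1_start = integer(),
                      tir1_end = integer(), tir2_start = integer(),
                      tir2_end = integer(), inner_dist = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  out <- list()
  for (fid in unique(hits$family_id)) {
    plus <- hits[hits$family_id == fid & hits$strand == "+", , drop = FALSE]
    minus <- hits[hits$family_id == fid & hits$strand == "-", , drop = FALSE]
    if (nrow(plus) == 0L || nrow(minus) == 0L) next
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        if (minus$start[j] <= plus$end[i]) next
        inner <- minus$start[j] - plus$end[i] - 1L
        if (inner >= max_span) next
        out[[length(out) + 1L]] <- data.frame(
          family_id = fid, start = plus$start[i], end = minus$end[j],
          tir1_start = plus$start[i], tir1_end = plus$end[i],
          tir2_start = minus$start[j], tir2_end = minus$end[j],
          inner_dist = inner, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end), , drop = FALSE]
}

# Levenshtein distance between two flank k-mers; Inf when a k-mer contains
# N or runs off the sequence.
.flank_kmers <- function(chv, from, len) {
  n <- length(chv)
  if (from < 1L || from + len - 1L > n) return(NA_character_)
  s <- chv[from:(from + len - 1L)]
  if (any(s == "N")) return(NA_character_)
  paste(s, collapse = "")
}

#' Validate the target-site duplication of a candidate element
#'
#' Searches all TSD lengths and all left/right offsets within the swing;
#' the flank k-mers are compared by unit-cost Levenshtein edit distance. A
#' combination passes when the distance is at most the length's tolerance.
#' The best match is chosen by lowest distance, then smallest total
#' absolute offset, then longest length, then leftmost offsets.
#'
#' @param seq a DNA string (or its character vector).
#' @param start,end candidate element interval (1-based inclusive).
#' @param rules a [tsd_rules()] object.
#' @return list with length, dist, off_left, off_right, left_start,
#'   right_start, left_seq, right_seq — or NULL when no combination passes.
#' @export
validate_tsd <- function(seq, start, end, rules = tsd_rules()) {
  chv <- if (is.character(seq) && length(seq) == 1L) .chars(seq) else seq
  sw <- rules$swing
  offs <- seq(-sw, sw)
  best <- NULL
  for (L in rules$lengths) {
    tol <- rules$tolerance[[as.character(L)]]
    left <- vapply(offs, function(o) .flank_kmers(chv, start - L + o, L),
                   character(1))
    right <- vapply(offs, function(o) .flank_kmers(chv, end + 1L + o, L),
                    character(1))
    ok_l <- which(!is.na(left)); ok_r <- which(!is.na(right))
    if (length(ok_l) == 0L || length(ok_r) == 0L) next
    d <- utils::adist(left[ok_l], right[ok_r])
    pass <- which(d <= tol, arr.ind = TRUE)
    if (nrow(pass) == 0L) next
    for (r in seq_len(nrow(pass))) {
      il <- ok_l[pass[r, 1]]; ir <- ok_r[pass[r, 2]]
      cand <- list(length = L, dist = as.integer(d[pass[r, 1], pass[r, 2]]),
                   off_left = offs[il], off_right = offs[ir],
                   left_start = start - L + offs[il],
                   right_start = end + 1L + offs[ir],
                   left_seq = left[il], right_seq = right[ir])
      if (is.null(best)) { best <- cand; next }
      b_key <- c(best$dist, abs(best$off_left) + abs(best$off_right),
                 -best$length, best$off_left, best$off_right)
      c_key <- c(cand$dist, abs(cand$off_left) + abs(cand$off_right),
                 -cand$length, cand$off_left, cand$off_right)
      cmp <- sign(c_key - b_key)
      first <- cmp[cmp != 0][1]
      if (!is.na(first) && first < 0) best <- cand
    }
  }
  best
}

#' Call MULEs from TSD-validated candidates
#'
#' Applies the de novo family-support rule (a de novo TIR consensus needs
#' at least `min_family_support` validated elements genome-wide; known
#' families are exempt), then resolves overlapping candidates to the best
#' TSD (same ordering as [validate_tsd()]).
#'
#' @param cands candidate data frame ([pair_tirs()] output) augmented with
#'   TSD columns `tsd_len`, `tsd_dist`, `tsd_off_left`, `tsd_off_right`
#'   (only TSD-validated rows).
#' @param lib TIR library (for the known/de novo source).
#' @param min_family_support minimum validated elements per de novo family.
#' @return data frame of MULE calls (kind `"mule"`).
#' @export
call_mules <- function(cands, lib, min_family_support = 5L) {
  empty <- data.frame(family_id = integer(), start = integer(),
                      end = integer(), tsd_len = integer(),
                      tsd_dist = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cands) == 0L) return(empty)
  src <- lib$source[match(cands$family_id, lib$family_id)]
  counts <- table(cands$family_id)
  supported <- cands$family_id %in%
    names(counts)[counts >= min_family_support] | src == "known"
  cands <- cands[supported, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty)
  ord <- order(cands$tsd_dist,
               abs(cands$tsd_off_left) + abs(cands$tsd_off_right),
               -cands$tsd_len, cands$start)
  cands <- cands[ord, , drop = FALSE]
  cands <- cands[.greedy_nonoverlap(cands), , drop = FALSE]
  cands <- cands[order(cands$start), , drop = FALSE]
  cands$kind <- "mule"
  cands$strand <- "+"
  rownames(cands) <- NULL
  cands
}

#' Classify MULE calls from protein-homology evidence
#'
#' Calls containing a known non-MULE transposon hit are removed. Remaining
#' calls with transposase homology and length above `min_len_auto` are
#' autonomous; calls with non-transposase protein homology are Pack-MULEs;
#' everything else is non-autonomous. Homology evidence is an input table
#' (e-values above `evalue_max` are ignored).
#'
#' @param calls data frame from [call_mules()] (row order gives call ids).
#' @param protein_hits data frame with columns call_id, subject_class
#'   (`"transposase"`, `"other"`, `"non_mule_te"`) and evalue, or NULL.
#' @param evalue_max e-value threshold (default 1e-9).
#' @param min_len_auto minimum autonomous length in bp (default 3000,
#'   exclusive).
#' @return `calls` with a `klass` column, minus removed calls.
#' @export
classify_mules <- function(calls, protein_hits = NULL, evalue_max = 1e-9,
                           min_len_auto = 3000L) {
  if (nrow(calls) == 0L) {
    calls$klass <- character(0)
    return(calls)
  }
  calls$klass <- "nonautonomous"
  if (is.null(protein_hits) || nrow(protein_hits) == 0L) return(calls)
  ph <- protein_hits[protein_hits$evalue < evalue_max, , drop = FALSE]
  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    h <- ph[ph$call_id == i, , drop = FALSE]
    if (nrow(h) == 0L) next
    if (any(h$subject_class == "non_mule_te")) { drop[i] <- TRUE; next }
    len <- calls$end[i] - calls$start[i] + 1L
    if (any(h$subject_class == "transposase") && len > min_len_auto) {
      calls$klass[i] <- "autonomous"
    } else if (any(h$subject_class == "other")) {
      calls$klass[i] <- "pack_mule"
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Independently re-validate a MULE call
#'
#' Rechecks the four criteria against the raw sequence: two TIR tracts of
#' the call's family at the element ends at the required identity, in
#' opposite orientation, inner distance below `max_span`, and a TSD
#' satisfying the rules (rechecked with a direct edit-distance
#' computation).
#'
#' @param call one-row data frame of a MULE call.
#' @param seq the DNA string.
#' @param lib TIR library.
#' @param rules a [tsd_rules()] object.
#' @param min_identity minimum TIR identity.
#' @param max_span maximum inner distance.
#' @return TRUE, or FALSE with a `reasons` attribute.
#' @export
validate_mule_call <- function(call, seq, lib, rules = tsd_rules(),
                               min_identity = 0.80, max_span = 20000L) {
  chv <- .chars(seq)
  reasons <- character(0)
  cons <- lib$consensus[match(call$family_id, lib$family_id)]
  if (is.na(cons)) {
    reasons <- c(reasons, "unknown family")
  } else {
    tl <- nchar(cons)
    cch <- .chars(cons)
    left <- chv[call$tir1_start:call$tir1_end]
    right <- chv[call$tir2_start:call$tir2_end]
    if (length(left) != tl ||
        .mm_count(left, cch) / tl > 1 - min_identity + 1e-9)
      reasons <- c(reasons, "left TIR does not match family consensus")
    rc <- rev(.COMP[cch])
    if (length(right) != tl ||
        .mm_count(right, rc) / tl > 1 - min_identity + 1e-9)
      reasons <- c(reasons,
                   "right TIR is not the reverse complement orientation")
    inner <- call$tir2_start - call$tir1_end - 1L
    if (inner < 0L || inner >= max_span)
      reasons <- c(reasons, "inner distance outside (0, 20 kb)")
  }
  tsd <- validate_tsd(chv, call$start, call$end, rules)
  if (is.null(tsd)) {
    reasons <- c(reasons, "no valid TSD")
  } else {
    tol <- rules$tolerance[[as.character(tsd$length)]]
    if (tsd$dist > tol) reasons <- c(reasons, "TSD beyond tolerance")
  }
  if (length(reasons) == 0L) return(TRUE)
  structure(FALSE, reasons = reasons)
}

#' Detect MULEs on a genome from a TIR-family library
#'
#' Full pipeline: mask filtering of the library, TIR-hit location, TIR
#' pairing, TSD validation, family-support filtering, overlap resolution
#' and classification. Every call is re-validated with
#' [validate_mule_call()] before being returned.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param lib TIR library ([tir_library()]).
#' @param masks optional per-family masked-fraction table
#'   (see [filter_tir_library()]).
#' @param protein_hits optional protein-homology table
#'   (see [classify_mules()]).
#' @param min_identity minimum TIR-hit identity.
#' @param max_span maximum inner distance between TIRs (bp).
#' @param rules a [tsd_rules()] object.
#' @param min_family_support minimum validated elements per de novo family.
#' @return list with `calls` (data frame with seqid column) and `tir_hits`.
#' @export
find_mules <- function(genome, lib, masks = NULL, protein_hits = NULL,
                       min_identity = 0.80, max_span = 20000L,
                       rules = tsd_rules(), min_family_support = 5L) {
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  lib <- filter_tir_library(lib, masks)
  all_cands <- list()
  all_hits <- list()
  for (sid in names(genome)) {
    if (nrow(lib) == 0L) break
    hits <- locate_tir_hits(genome[[sid]], lib, min_identity = min_identity)
    if (nrow(hits) > 0L) {
      h <- hits; h$seqid <- sid
      all_hits[[sid]] <- h
    }
    cands <- pair_tirs(hits, max_span = max_span)
    if (nrow(cands) == 0L) next
    chv <- .chars(genome[[sid]])
    keep <- logical(nrow(cands))
    tsd_cols <- matrix(NA_integer_, nrow(cands), 4L)
    for (i in seq_len(nrow(cands))) {
      tsd <- validate_tsd(chv, cands$start[i], cands$end[i], rules)
      if (!is.null(tsd)) {
        keep[i] <- TRUE
        tsd_cols[i, ] <- c(tsd$length, tsd$dist, tsd$off_left, tsd$off_right)
      }
    }
    cands <- cands[keep, , drop = FALSE]
    if (nrow(cands) == 0L) next
    cands$tsd_len <- tsd_cols[keep, 1]
    cands$tsd_dist <- tsd_cols[keep, 2]
    cands$tsd_off_left <- tsd_cols[keep, 3]
    cands$tsd_off_right <- tsd_cols[keep, 4]
    cands$seqid <- sid
    all_cands[[sid]] <- cands
  }
  cands <- if (length(all_cands)) do.call(rbind, all_cands) else
    data.frame(family_id = integer(), start = integer(), end = integer(),
               tir1_start = integer(), tir1_end = integer(),
               tir2_start = integer(), tir2_end = integer(),
               inner_dist = integer(), tsd_len = integer(),
               tsd_dist = integer(), tsd_off_left = integer(),
               tsd_off_right = integer(), seqid = character(),
               stringsAsFactors = FALSE)
  calls <- call_mules(cands, lib, min_family_support = min_family_support)
  calls <- classify_mules(calls, protein_hits)
  if (nrow(calls) > 0L) {
    ok <- vapply(seq_len(nrow(calls)), function(i) {
      isTRUE(validate_mule_call(calls[i, ], genome[[calls$seqid[i]]], lib,
                                rules, min_identity, max_span))
    }, logical(1))
    calls <- calls[ok, , drop = FALSE]
  }
  rownames(calls) <- NULL
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  list(calls = calls, tir_hits = hits)
}
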