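# Two-step Helitron detection.
#
# Helitrons are rolling-circle transposons without TIRs or TSDs. Their
# diagnostic structure is at the 3' end: a short palindromic hairpin
# (stem 7-10 nt with at most one arm mismatch, loop 2-4 nt), a 6-10 nt
# spacer, and a CTRR terminus followed by the host T of the A|element|T
# insertion context.
#
# Step 1 (stringent): scan the genome for hairpin + CTRRT termini, drop
# low-complexity stems, group termini into families of identical stems
# (families with fewer than 5 members are not considered), recover each
# family's element boundaries from pairwise comparison of 15 kb-upstream /
# 200 bp-downstream context tracts, and extract 40 bp end tracts into an
# end library.
#
# Step 2 (relaxed): rescan the genome with the end library, allowing up to
# 4 mismatches per 40 bp end, and pair 5'/3' end hits into complete-element
# calls under the criteria: (a) expected end orientation, (b) span longer
# than 200 bp and shorter than 15 kb, (c) at most 4 mismatches per end,
# (d) at most 1 mismatch in the 3' CTRR terminus, (e) the Helitron AT
# insertion rule (host A immediately 5', host T immediately 3').

#' Hairpin / terminus pattern parameters
#'
#' Defaults encode the stem 7-10 / loop 2-4 / one stem mismatch (no indels)
#' / spacer 6-10 / CTRRT pattern (R = A or G).
#'
#' @param stem_min,stem_max stem arm length bounds (nt).
#' @param loop_min,loop_max loop length bounds (nt).
#' @param stem_mismatches maximum substitutions between the second arm and
#'   the reverse complement of the first.
#' @param spacer_min,spacer_max spacer length bounds between hairpin and
#'   terminus motif.
#' @param min_stem_entropy stems with dinucleotide entropy at or below this
#'   many bits (mono- and di-nucleotide repeats) are treated as low
#'   complexity.
#' @return an object of class `hairpin_params`.
#' @export
hairpin_params <- function(stem_min = 7L, stem_max = 10L,
                           loop_min = 2L, loop_max = 4L,
                           stem_mismatches = 1L,
                           spacer_min = 6L, spacer_max = 10L,
                           min_stem_entropy = 1.0) {
  stopifnot(stem_min >= 1L, stem_max >= stem_min,
            loop_min >= 0L, loop_max >= loop_min,
            spacer_min >= 0L, spacer_max >= spacer_min,
            stem_mismatches >= 0L)
  structure(list(stem_min = as.integer(stem_min),
                 stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 stem_mismatches = as.integer(stem_mismatches),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 min_stem_entropy = min_stem_entropy),
            class = "hairpin_params")
}

.empty_termini <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             stem = character(), stem_len = integer(), loop_len = integer(),
             spacer_len = integer(), term_pos = integer(),
             stringsAsFactors = FALSE)
}

# Scan one strand (given as a character vector); coordinates local to chv.
.scan_termini_strand <- function(chv, p) {
  s <- paste(chv, collapse = "")
  hits <- gregexpr("CT[AG][AG]T", s)[[1]]
  if (hits[1] == -1L) return(.empty_termini())
  comp <- .COMP
  rows <- vector("list", length(hits))
  for (hi in seq_along(hits)) {
    q <- hits[hi]  # CTRR at q..q+3, host T at q+4
    best <- NULL
    for (stem in seq(p$stem_max, p$stem_min)) {
      for (loop in seq(p$loop_min, p$loop_max)) {
        for (sp in seq(p$spacer_min, p$spacer_max)) {
          a2_end <- q - sp - 1L
          a2_start <- a2_end - stem + 1L
          a1_end <- a2_start - loop - 1L
          a1_start <- a1_end - stem + 1L
          if (a1_start < 1L) next
          arm1 <- chv[a1_start:a1_end]
          arm2 <- chv[a2_start:a2_end]
          rc1 <- rev(comp[arm1])
          mm <- sum(rc1 != arm2 | arm1[stem:1L] == "N" | arm2 == "N")
          if (mm <= p$stem_mismatches) {
            cand <- list(start = a1_start, stem = stem, loop = loop,
                         spacer = sp)
            if (is.null(best) ||
                cand$stem > best$stem ||
                (cand$stem == best$stem && cand$loop < best$loop) ||
                (cand$stem == best$stem && cand$loop == best$loop &&
                 cand$spacer < best$spacer)) {
              best <- cand
            }
          }
        }
      }
    }
    if (!is.null(best)) {
      rows[[hi]] <- data.frame(
        start = best$start, end = q + 4L, strand = "+",
        stem = paste(chv[best$start:(best$start + best$stem - 1L)],
                     collapse = ""),
        stem_len = best$stem, loop_len = best$loop, spacer_len = best$spacer,
        term_pos = q + 3L, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_termini())
  do.call(rbind, rows)
}

#' Scan a sequence for hairpin / CTRRT Helitron termini
#'
#' Reports, for each CTRRT motif occurrence on either strand, the best
#' upstream hairpin placement (longest stem, then smallest loop, then
#' smallest spacer) satisfying the pattern. `term_pos` is the genomic
#' (plus-strand) coordinate of the 3'-terminal CTRR base; the candidate
#' interval spans the hairpin through the motif's host T.
#'
#' @param seq a DNA string.
#' @param params a [hairpin_params()] object.
#' @param strands strands to scan.
#' @return data frame of terminus candidates, ordered by start.
#' @export
scan_hairpin_termini <- function(seq, params = hairpin_params(),
                                 strands = c("+", "-")) {
  n <- nchar(seq)
  min_span <- 2L * params$stem_min + params$loop_min + params$spacer_min + 5L
  if (n < min_span) return(.empty_termini())
  chv <- .chars(seq)
  out <- list()
  if ("+" %in% strands) out$plus <- .scan_termini_strand(chv, params)
  if ("-" %in% strands) {
    res <- .scan_termini_strand(rev(.COMP[chv]), params)
    if (nrow(res) > 0L) {
      new_start <- n - res$end + 1L
      new_end <- n - res$start + 1L
      res$term_pos <- n - res$term_pos + 1L
      res$start <- new_start
      res$end <- new_end
      res$strand <- "-"
    }
    out$minus <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(.empty_termini())
  rownames(res) <- NULL
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

#' Drop low-complexity terminus candidates
#'
#' Removes candidates whose stem is a mono- or di-nucleotide repeat,
#' operationalized as dinucleotide entropy at or below
#' `params$min_stem_entropy` bits.
#'
#' @param termini data frame from [scan_hairpin_termini()].
#' @param params a [hairpin_params()] object.
#' @return filtered data frame.
#' @export
filter_low_complexity <- function(termini, params = hairpin_params()) {
  if (nrow(termini) == 0L) return(termini)
  ent <- vapply(termini$stem, dinucleotide_entropy, numeric(1))
  termini[ent > params$min_stem_entropy, , drop = FALSE]
}

#' Group terminus candidates into families of identical stems
#'
#' Families are exact-string partitions by stem sequence; families with
#' fewer than `min_members` members are not considered. Family ids are
#' assigned in order of decreasing size, ties broken by lexicographic stem.
#'
#' @param termini data frame of terminus candidates (may span several
#'   sequences; include a `seqid` column in that case).
#' @param min_members minimum family size (default 5; a family of exactly
#'   5 is kept).
#' @return the input rows of retained families with a `family_id` column.
#' @export
group_terminus_families <- function(termini, min_members = 5L) {
  if (nrow(termini) == 0L) return(termini[0, , drop = FALSE])
  tab <- table(termini$stem)
  keep_stems <- names(tab)[tab >= min_members]
  if (length(keep_stems) == 0L) {
    res <- termini[0, , drop = FALSE]
    res$family_id <- integer(0)
    return(res)
  }
  ord <- order(-as.integer(tab[keep_stems]), keep_stems)
  keep_stems <- keep_stems[ord]
  fam_id <- stats::setNames(seq_along(keep_stems), keep_stems)
  res <- termini[termini$stem %in% keep_stems, , drop = FALSE]
  res$family_id <- as.integer(fam_id[res$stem])
  res <- res[order(res$family_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract strand-normalized context tracts around family termini
#'
#' For each member, extracts the tract spanning `upstream` bases through
#' the 3'-terminal CTRR base plus `downstream` bases beyond it (clamped at
#' the sequence boundaries), reverse-complemented for minus-strand members
#' so that the terminus always lies `downstream` bases from the tract end.
#'
#' @param members data frame with `term_pos` and `strand` columns.
#' @param seq the DNA string the members lie on.
#' @param upstream,downstream context sizes in bp (defaults 15000 and 200).
#' @return list with `tracts` (character vector) and `term_offset`
#'   (position of the terminal CTRR base within each tract).
#' @export
extract_context_tracts <- function(members, seq, upstream = 15000L,
                                   downstream = 200L) {
  n <- nchar(seq)
  if (any(members$term_pos < 1L | members$term_pos > n))
    stop("extract_context_tracts: member terminus outside sequence")
  tracts <- character(nrow(members))
  offs <- integer(nrow(members))
  for (i in seq_len(nrow(members))) {
    t <- members$term_pos[i]
    if (members$strand[i] == "+") {
      a <- max(1L, t - upstream + 1L)
      b <- min(n, t + downstream)
      tracts[i] <- substr(seq, a, b)
      offs[i] <- t - a + 1L
    } else {
      a <- max(1L, t - downstream)
      b <- min(n, t + upstream - 1L)
      tracts[i] <- revcomp(substr(seq, a, b))
      offs[i] <- b - t + 1L
    }
  }
  list(tracts = tracts, term_offset = offs)
}

# Ungapped upstream extension of the shared segment between two tracts,
# anchored at their termini. Returns the extension length (in bases,
# counting the terminus base as 1) at the score maximum.
.pair_extension <- function(ci, cj, ti, tj, match = 1L, mismatch = -3L,
                            xdrop = 12L) {
  score <- 0L; best <- 0L; best_x <- 0L
  x <- 0L
  repeat {
    pi <- ti - x; pj <- tj - x
    if (pi < 1L || pj < 1L) break
    a <- ci[pi]; b <- cj[pj]
    if (a != "N" && b != "N" && a == b) score <- score + match
    else score <- score + mismatch
    if (score > best) { best <- score; best_x <- x }
    if (score <= best - xdrop) break
    x <- x + 1L
  }
  best_x + 1L
}

#' Infer a terminus family's element ends from its context tracts
#'
#' Automated surrogate for manual dot-plot curation: for every tract pair,
#' the segment shared by the two copies is recovered by ungapped extension
#' upstream from the anchored terminus (+1 match / -3 mismatch, X-drop 12);
#' the pair's 5' boundary is the score maximum. The family boundary is the
#' least-extended (most downstream) boundary supported by at least
#' `min_pair_support` pairs within `boundary_tol` bp, which resists chance
#' flank matches. If the boundary base is a near-unanimous A across
#' members, that A is attributed to the host insertion context and the
#' boundary shifted inside by one. Families are then required to satisfy a
#' family-level AT-context vote: at least `at_vote` of members must show a
#' host A immediately 5' of the inferred start (the host T 3' of the CTRR
#' terminus is guaranteed by the scan pattern itself).
#'
#' @param tracts character vector of strand-normalized context tracts.
#' @param term_offset terminus position within each tract
#'   (see [extract_context_tracts()]).
#' @param boundary_tol agreement tolerance between pair boundaries (bp).
#' @param min_pair_support minimum number of agreeing pairs.
#' @param at_vote minimum fraction of members supporting the A context.
#' @param min_span minimum element span (terminus to 5' start) in bp.
#' @return list with 40 bp `five_tract` and `three_tract`, `span`,
#'   `n_support`, `at_ok`, and `ok` (FALSE with a `reason` when the family
#'   is rejected).
#' @export
infer_family_ends <- function(tracts, term_offset, boundary_tol = 10L,
                              min_pair_support = 2L, at_vote = 0.8,
                              min_span = 100L) {
  stopifnot(length(tracts) == length(term_offset))
  nmem <- length(tracts)
  if (nmem < 2L) return(list(ok = FALSE, reason = "fewer than 2 tracts"))
  chl <- lapply(tracts, .chars)
  exts <- c()
  for (i in seq_len(nmem - 1L)) {
    for (j in seq(i + 1L, nmem)) {
      exts <- c(exts, .pair_extension(chl[[i]], chl[[j]],
                                      term_offset[i], term_offset[j]))
    }
  }
  # Supported boundaries: extension values other pairs agree with.
  support <- vapply(exts, function(e) sum(abs(exts - e) <= boundary_tol),
                    integer(1))
  good <- exts[support >= min_pair_support]
  if (length(good) == 0L)
    return(list(ok = FALSE, reason = "no consistent boundary"))
  # Modal supported extension: chance flank matches push individual pair
  # extensions a few bases past the host A, but most pairs stop exactly
  # at it, so the most frequent supported value marks the boundary.
  tab <- table(good)
  ext0 <- as.integer(names(tab)[order(-as.integer(tab),
                                      as.integer(names(tab)))][1])
  n_support <- sum(abs(exts - ext0) <= boundary_tol)

  # Locate the host insertion A by a near-unanimous vote across members
  # in a window around the boundary; the element starts right after it.
  dd <- seq(-boundary_tol, boundary_tol)
  frac_A <- vapply(dd, function(d) {
    b <- vapply(seq_len(nmem), function(i) {
      p <- term_offset[i] - ext0 + d
      if (p >= 1L && p <= length(chl[[i]])) chl[[i]][p] else NA_character_
    }, character(1))
    if (all(is.na(b))) NA_real_ else mean(b == "A", na.rm = TRUE)
  }, numeric(1))
  hit <- which(!is.na(frac_A) & frac_A >= at_vote)
  if (length(hit) == 0L)
    return(list(ok = FALSE, reason = "AT insertion context not supported",
                at_ok = FALSE))
  # strongest A support first (the true host A is near-unanimous), then
  # proximity to the extension boundary
  d_a <- dd[hit[order(-frac_A[hit], abs(dd[hit]), dd[hit])][1]]
  starts <- term_offset - ext0 + d_a + 1L
  in_b <- starts >= 1L
  if (!any(in_b)) return(list(ok = FALSE, reason = "boundary out of tract"))

  span <- term_offset[which(in_b)[1]] - starts[which(in_b)[1]] + 1L
  if (span < max(min_span, 40L))
    return(list(ok = FALSE, reason = "inferred element too short"))

  # Majority-rule 40 bp end tracts across members (columns are anchored).
  five_mat <- vapply(seq_len(nmem), function(i) {
    s <- starts[i]
    if (s >= 1L && s + 39L <= length(chl[[i]])) chl[[i]][s:(s + 39L)]
    else rep(NA_character_, 40L)
  }, character(40))
  three_mat <- vapply(seq_len(nmem), function(i) {
    e <- term_offset[i]
    if (e - 39L >= 1L) chl[[i]][(e - 39L):e] else rep(NA_character_, 40L)
  }, character(40))
  maj <- function(mat) {
    paste(apply(mat, 1L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) return("N")
      tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
      names(tab)[which.max(tab)]
    }), collapse = "")
  }
  list(ok = TRUE, five_tract = maj(five_mat), three_tract = maj(three_mat),
       span = span, n_support = n_support, at_ok = TRUE)
}

#' Build a Helitron end library from step-1 families
#'
#' Runs [extract_context_tracts()] and [infer_family_ends()] per family and
#' collects the accepted families' 40 bp end tracts.
#'
#' @param families data frame from [group_terminus_families()] (with a
#'   `seqid` column when the genome has several sequences).
#' @param genome named character vector of sequences.
#' @param upstream,downstream context-tract sizes (bp).
#' @param ... passed to [infer_family_ends()].
#' @return data frame with columns family_id, end (`"five"`/`"three"`),
#'   tract, span; rejected families are reported via `message()`.
#' @export
build_end_library <- function(families, genome, upstream = 15000L,
                              downstream = 200L, ...) {
  out <- list()
  if (nrow(families) > 0L && is.null(families$seqid)) {
    if (length(genome) != 1L)
      stop("families lack a seqid column but genome has several sequences")
    families$seqid <- names(genome)[1]
  }
  for (fid in unique(families$family_id)) {
    mem <- families[families$family_id == fid, , drop = FALSE]
    tr <- list(tracts = character(0), term_offset = integer(0))
    for (sid in unique(mem$seqid)) {
      part <- extract_context_tracts(mem[mem$seqid == sid, , drop = FALSE],
                                     genome[[sid]], upstream, downstream)
      tr$tracts <- c(tr$tracts, part$tracts)
      tr$term_offset <- c(tr$term_offset, part$term_offset)
    }
    ends <- infer_family_ends(tr$tracts, tr$term_offset, ...)
    if (!isTRUE(ends$ok)) {
      message("helitron family ", fid, " rejected: ", ends$reason)
      next
    }
    out[[as.character(fid)]] <- data.frame(
      family_id = fid, end = c("five", "three"),
      tract = c(ends$five_tract, ends$three_tract),
      span = ends$span, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(family_id = integer(), end = character(),
                      tract = character(), span = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan a sequence with a Helitron end library
#'
#' Substitution-only (Hamming) sliding scan of every 40 bp end tract on
#' both strands; every placement with at most `max_mm` mismatches is
#' reported. N never matches.
#'
#' @param seq a DNA string.
#' @param lib end library from [build_end_library()].
#' @param max_mm maximum mismatches per 40 bp end (default 4).
#' @return data frame with columns family_id, end, strand, start, end_pos,
#'   mm.
#' @export
scan_end_library <- function(seq, lib, max_mm = 4L) {
  stopifnot(all(nchar(lib$tract) == 40L))
  subj <- Biostrings::DNAString(seq)
  chv <- .chars(seq)
  out <- list()
  for (i in seq_len(nrow(lib))) {
    for (st in c("+", "-")) {
      pat <- if (st == "+") lib$tract[i] else revcomp(lib$tract[i])
      hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                       with.indels = FALSE, fixed = TRUE)
      if (length(hits) == 0L) next
      starts <- BiocGenerics::start(hits)
      pchv <- .chars(pat)
      mm <- vapply(starts, function(s) .mm_count(chv[s:(s + 39L)], pchv),
                   integer(1))
      keep <- mm <= max_mm
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        family_id = lib$family_id[i], end = lib$end[i], strand = st,
        start = starts[keep], end_pos = starts[keep] + 39L, mm = mm[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(family_id = integer(), end = character(),
                      strand = character(), start = integer(),
                      end_pos = integer(), mm = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$end_pos), , drop = FALSE]
}

# Count mismatches of the terminal 4 bases of a call against the CTRR
# motif (R = A or G; pyrimidines and N count as mismatches).
.ctrr_mismatches <- function(bases4) {
  mm <- 0L
  if (bases4[1] != "C") mm <- mm + 1L
  if (bases4[2] != "T") mm <- mm + 1L
  if (!bases4[3] %in% c("A", "G")) mm <- mm + 1L
  if (!bases4[4] %in% c("A", "G")) mm <- mm + 1L
  mm
}

#' Pair end-library hits into complete Helitron calls
#'
#' Pairs same-family, same-strand 5' and 3' end hits with the 5' end
#' upstream in element orientation, span strictly between `min_span` and
#' `max_span`, per-end mismatches at most `max_mm`, at most `ctrr_max_mm`
#' mismatches in the 3'-terminal CTRR, and (by default) the AT insertion
#' context. Each 3' hit pairs with its nearest eligible 5' hit; remaining
#' hits may seed other calls; overlapping calls of the same family are
#' merged to the longest.
#'
#' @param hits data frame from [scan_end_library()].
#' @param seq the DNA string the hits lie on.
#' @param max_mm maximum mismatches per end.
#' @param ctrr_max_mm maximum mismatches within the terminal CTRR.
#' @param min_span,max_span exclusive span bounds (bp): the element length
#'   must satisfy `span > min_span` and `span < max_span`.
#' @param at_rule require host A immediately 5' and host T immediately 3'
#'   of the element.
#' @return data frame of Helitron calls with evidence columns.
#' @export
pair_helitron_ends <- function(hits, seq, max_mm = 4L, ctrr_max_mm = 1L,
                               min_span = 200L, max_span = 15000L,
                               at_rule = TRUE) {
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), family_id = integer(),
                      five_mm = integer(), three_mm = integer(),
                      ctrr_mm = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  chv <- .chars(seq)
  n <- length(chv)
  hits <- hits[hits$mm <= max_mm, , drop = FALSE]
  calls <- list()
  for (fid in unique(hits$family_id)) {
    for (st in c("+", "-")) {
      f5 <- hits[hits$family_id == fid & hits$strand == st &
                 hits$end == "five", , drop = FALSE]
      f3 <- hits[hits$family_id == fid & hits$strand == st &
                 hits$end == "three", , drop = FALSE]
      if (nrow(f5) == 0L || nrow(f3) == 0L) next
      for (k in seq_len(nrow(f3))) {
        if (st == "+") {
          el_end <- f3$end_pos[k]
          spans <- el_end - f5$start + 1L
          elig <- which(spans > min_span & spans < max_span)
          if (length(elig) == 0L) next
          pick <- elig[which.max(f5$start[elig])]  # nearest upstream 5'
          el_start <- f5$start[pick]
          term4 <- chv[(el_end - 3L):el_end]
        } else {
          el_start <- f3$start[k]
          spans <- f5$end_pos - el_start + 1L
          elig <- which(spans > min_span & spans < max_span)
          if (length(elig) == 0L) next
          pick <- elig[which.min(f5$end_pos[elig])]
          el_end <- f5$end_pos[pick]
          term4 <- rev(.COMP[chv[el_start:(el_start + 3L)]])
        }
        cmm <- .ctrr_mismatches(term4)
        if (cmm > ctrr_max_mm) next
        if (at_rule) {
          if (el_start - 1L < 1L || el_end + 1L > n) next
          if (chv[el_start - 1L] != "A" || chv[el_end + 1L] != "T") next
        }
        calls[[length(calls) + 1L]] <- data.frame(
          start = el_start, end = el_end, strand = st, family_id = fid,
          five_mm = f5$mm[pick], three_mm = f3$mm[k], ctrr_mm = cmm,
          kind = "helitron", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  res <- do.call(rbind, calls)
  res <- unique(res)
  # Merge overlapping same-family calls to the longest.
  res <- res[order(-(res$end - res$start)), , drop = FALSE]
  keep <- logical(nrow(res))
  for (fid in unique(res$family_id)) {
    idx <- which(res$family_id == fid)
    sub <- res[idx, , drop = FALSE]
    keep[idx] <- .greedy_nonoverlap(sub)
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Independently re-validate a Helitron call
#'
#' Checks the call against the raw sequence and the end library: end
#' orientation, span bounds, per-end mismatch counts, the CTRR terminus,
#' and the AT insertion context.
#'
#' @param call one-row data frame (a row of [pair_helitron_ends()] output).
#' @param seq the DNA string.
#' @param lib the end library.
#' @param max_mm,ctrr_max_mm,min_span,max_span,at_rule as in
#'   [pair_helitron_ends()].
#' @return TRUE, or FALSE with a `reasons` attribute.
#' @export
validate_helitron_call <- function(call, seq, lib, max_mm = 4L,
                                   ctrr_max_mm = 1L, min_span = 200L,
                                   max_span = 15000L, at_rule = TRUE) {
  chv <- .chars(seq)
  n <- length(chv)
  reasons <- character(0)
  span <- call$end - call$start + 1L
  if (!(span > min_span && span < max_span))
    reasons <- c(reasons, "span outside (200, 15000)")
  ltr <- lib[lib$family_id == call$family_id, , drop = FALSE]
  t5 <- ltr$tract[ltr$end == "five"]
  t3 <- ltr$tract[ltr$end == "three"]
  if (length(t5) != 1L || length(t3) != 1L) {
    reasons <- c(reasons, "family missing from end library")
  } else if (call$end - call$start + 1L >= 80L) {
    if (call$strand == "+") {
      m5 <- .mm_count(chv[call$start:(call$start + 39L)], .chars(t5))
      m3 <- .mm_count(chv[(call$end - 39L):call$end], .chars(t3))
    } else {
      m5 <- .mm_count(rev(.COMP[chv[(call$end - 39L):call$end]]), .chars(t5))
      m3 <- .mm_count(rev(.COMP[chv[call$start:(call$start + 39L)]]),
                      .chars(t3))
    }
    if (m5 > max_mm) reasons <- c(reasons, "5' end exceeds mismatch limit")
    if (m3 > max_mm) reasons <- c(reasons, "3' end exceeds mismatch limit")
  } else {
    reasons <- c(reasons, "element shorter than two end tracts")
  }
  term4 <- if (call$strand == "+") chv[(call$end - 3L):call$end]
           else rev(.COMP[chv[call$start:(call$start + 3L)]])
  if (.ctrr_mismatches(term4) > ctrr_max_mm)
    reasons <- c(reasons, "CTRR terminus exceeds mismatch limit")
  if (at_rule) {
    ok_at <- call$start - 1L >= 1L && call$end + 1L <= n &&
      chv[call$start - 1L] == "A" && chv[call$end + 1L] == "T"
    if (!ok_at) reasons <- c(reasons, "AT insertion context violated")
  }
  if (length(reasons) == 0L) return(TRUE)
  structure(FALSE, reasons = reasons)
}

#' Two-step Helitron detection on a genome
#'
#' Runs the stringent terminus scan, family grouping and end-library
#' construction (step 1), then the relaxed end-library scan and end
#' pairing (step 2). An existing end library can be supplied to skip
#' step 1. Every call is re-validated with [validate_helitron_call()]
#' before being returned.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param params a [hairpin_params()] object.
#' @param end_lib optional precomputed end library.
#' @param min_members minimum terminus-family size.
#' @param max_mm,ctrr_max_mm,min_span,max_span,at_rule step-2 criteria.
#' @param upstream,downstream context-tract sizes for step 1.
#' @return list with `calls` (data frame with seqid column), `end_library`
#'   and `termini`.
#' @export
find_helitrons <- function(genome, params = hairpin_params(),
                           end_lib = NULL, min_members = 5L,
                           max_mm = 4L, ctrr_max_mm = 1L,
                           min_span = 200L, max_span = 15000L,
                           at_rule = TRUE,
                           upstream = 15000L, downstream = 200L) {
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  termini <- NULL
  if (is.null(end_lib)) {
    tl <- lapply(names(genome), function(sid) {
      t <- scan_hairpin_termini(genome[[sid]], params)
      t <- filter_low_complexity(t, params)
      if (nrow(t) > 0L) t$seqid <- sid
      t
    })
    termini <- do.call(rbind, tl[vapply(tl, nrow, integer(1)) > 0L])
    if (is.null(termini)) termini <- .empty_termini()
    fams <- group_terminus_families(termini, min_members = min_members)
    end_lib <- build_end_library(fams, genome, upstream, downstream)
  }
  calls <- list()
  for (sid in names(genome)) {
    if (nrow(end_lib) == 0L) break
    hits <- scan_end_library(genome[[sid]], end_lib, max_mm = max_mm)
    cl <- pair_helitron_ends(hits, genome[[sid]], max_mm = max_mm,
                             ctrr_max_mm = ctrr_max_mm, min_span = min_span,
                             max_span = max_span, at_rule = at_rule)
    if (nrow(cl) == 0L) next
    ok <- vapply(seq_len(nrow(cl)), function(i) {
      isTRUE(validate_helitron_call(cl[i, ], genome[[sid]], end_lib,
                                    max_mm, ctrr_max_mm, min_span, max_span,
                                    at_rule))
    }, logical(1))
    cl <- cl[ok, , drop = FALSE]
    if (nrow(cl) > 0L) {
      cl$seqid <- sid
      calls[[sid]] <- cl
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(start = integer(), end = integer(), strand = character(),
               family_id = integer(), five_mm = integer(),
               three_mm = integer(), ctrr_mm = integer(), kind = character(),
               seqid = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, end_library = end_lib, termini = termini)
}
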