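# Synthetic-genome generator: i.i.d. background plus planted, structurally
# correct elements with ground-truth annotations.
#
# Planted elements satisfy their detector's structural criteria exactly at
# divergence 0: Helitrons end in a hairpin + spacer + CTRR terminus and
# are inserted between a host A and T; MULEs are TIR + body + revcomp(TIR)
# flanked by a duplicated host k-mer TSD; Stowaway MITEs carry the
# CTCCTCCC motif at the 5' TIR start and a TA TSD; Tourist MITEs begin
# with G/C, have TIRs of at least 8 bp and a duplicated host 3-mer TSD.
# Divergence is applied per copy as independent substitutions (no indels),
# so planted boundaries stay exact. Element bodies are rejection-sampled
# so that no element contains a chance hairpin+CTRRT terminus other than a
# Helitron's own designed one, keeping the planted-genome truth
# unambiguous for the terminus-anchored detector.

#' Simulate an i.i.d. background sequence
#'
#' @param length sequence length (at least 1000).
#' @param seed optional RNG seed (global RNG state is restored).
#' @param gc GC fraction (default 0.44).
#' @return a DNA string.
#' @export
simulate_background <- function(length, seed = NULL, gc = 0.44) {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

.rand_seq <- function(n, gc = 0.44) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# draw one value from a vector, safe for length-1 vectors
.sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# TRUE when the sequence contains no hairpin+CTRRT terminus on either
# strand (a trailing T is appended so that a terminal CTRR + host T also
# counts).
.terminus_free <- function(s, params = hairpin_params()) {
  nrow(scan_hairpin_termini(paste0(s, "T"), params, strands = "+")) == 0L &&
    nrow(scan_hairpin_termini(paste0(revcomp(s), "T"), params,
                              strands = "+")) == 0L
}

#' Specification of a planted element family set
#'
#' @param kind `"helitron"`, `"mule"`, `"stowaway"`, `"tourist"` or
#'   `"generic_repeat"`.
#' @param n_families number of families.
#' @param copies_per_family copies planted per family.
#' @param length_range element length range (bp).
#' @param divergence per-copy per-base substitution rate.
#' @param tir_range MULE TIR length range (bp).
#' @param tsd_len MULE TSD length: one value, or a range sampled per copy
#'   (default 7-11).
#' @param mite_tir_range MITE TIR length range (bp).
#' @return an object of class `element_spec`.
#' @export
element_spec <- function(kind = c("helitron", "mule", "stowaway", "tourist",
                                  "generic_repeat"),
                         n_families = 4L, copies_per_family = 5L,
                         length_range = NULL, divergence = 0,
                         tir_range = c(100L, 180L), tsd_len = 7:11,
                         mite_tir_range = c(10L, 14L)) {
  kind <- match.arg(kind)
  if (is.null(length_range)) {
    length_range <- switch(kind,
      helitron = c(600L, 1500L), mule = c(2200L, 3800L),
      stowaway = c(130L, 450L), tourist = c(130L, 450L),
      generic_repeat = c(300L, 800L))
  }
  if (kind == "stowaway" && mite_tir_range[1] < 10L)
    stop("stowaway TIRs must be at least 10 bp (8 bp motif + TSD adjacency)")
  if (kind == "tourist" && mite_tir_range[1] < 8L)
    stop("tourist TIRs must be at least 8 bp")
  structure(list(kind = kind, n_families = as.integer(n_families),
                 copies_per_family = as.integer(copies_per_family),
                 length_range = as.integer(length_range),
                 divergence = divergence,
                 tir_range = as.integer(tir_range),
                 tsd_len = as.integer(tsd_len),
                 mite_tir_range = as.integer(mite_tir_range)),
            class = "element_spec")
}

#' Generate one ancestral element for a family
#'
#' Returns the element sequence plus the structural metadata the truth set
#' records. Uses the current RNG state; see [simulate_te_genome()] for the
#' seeded entry point.
#'
#' @param spec an [element_spec()].
#' @param gc background GC content used for random parts.
#' @param max_tries rejection-sampling budget for the terminus screen.
#' @return list with `seq` and `meta` (structural coordinates).
#' @export
make_element <- function(spec, gc = 0.44, max_tries = 200L) {
  L <- .sample1(spec$length_range[1]:spec$length_range[2])
  for (try in seq_len(max_tries)) {
    if (spec$kind == "helitron") {
      stem <- .sample1(7:10); loop <- .sample1(2:4)
      spacer <- .sample1(6:10)
      tail_len <- 2L * stem + loop + spacer + 4L
      body_len <- L - tail_len - 2L
      if (body_len < 40L) stop("helitron length_range too short")
      arm1 <- .rand_seq(stem, gc)
      el <- paste0("TC", .rand_seq(body_len, gc), arm1, .rand_seq(loop, gc),
                   revcomp(arm1), .rand_seq(spacer, gc),
                   "CT", paste(sample(c("A", "G"), 2L, replace = TRUE),
                               collapse = ""))
      # The designed terminus must be the only one (on either strand).
      des <- scan_hairpin_termini(paste0(el, "T"), strands = "+")
      ok <- nrow(des) == 1L && des$term_pos == L &&
        des$stem == arm1 &&
        nrow(scan_hairpin_termini(paste0(revcomp(el), "T"),
                                  strands = "+")) == 0L &&
        dinucleotide_entropy(arm1) > 1.0
      if (ok) {
        return(list(seq = el,
                    meta = list(stem = arm1, stem_len = stem, loop = loop,
                                spacer = spacer)))
      }
    } else if (spec$kind == "mule") {
      tir_len <- .sample1(spec$tir_range[1]:spec$tir_range[2])
      body_len <- L - 2L * tir_len
      if (body_len < 50L) stop("mule length_range too short for TIRs")
      tir <- .rand_seq(tir_len, gc)
      el <- paste0(tir, .rand_seq(body_len, gc), revcomp(tir))
      if (.terminus_free(el)) {
        return(list(seq = el, meta = list(tir = tir, tir_len = tir_len)))
      }
    } else if (spec$kind %in% c("stowaway", "tourist")) {
      tir_len <- .sample1(spec$mite_tir_range[1]:spec$mite_tir_range[2])
      body_len <- L - 2L * tir_len
      if (body_len < 20L) stop("MITE length_range too short for TIRs")
      tir <- if (spec$kind == "stowaway") {
        paste0("CTCCTCCC", .rand_seq(tir_len - 8L, gc))
      } else {
        paste0(sample(c("G", "C"), 1L), .rand_seq(tir_len - 1L, gc))
      }
      el <- paste0(tir, .rand_seq(body_len, gc), revcomp(tir))
      if (.terminus_free(el)) {
        return(list(seq = el, meta = list(tir = tir, tir_len = tir_len)))
      }
    } else {  # generic_repeat
      el <- .rand_seq(L, gc)
      if (.terminus_free(el)) return(list(seq = el, meta = list()))
    }
  }
  stop("make_element: could not generate a terminus-clean ", spec$kind,
       " in ", max_tries, " tries")
}

# Apply per-base substitutions (never to the same base) at rate `rate`.
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- .chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Plant element copies into a background genome
#'
#' Insertion sites are uniform and non-overlapping (minimum 100 bp between
#' sites). MULE and MITE insertions duplicate the host k-mer at the site
#' into a TSD (the Stowaway site is set to TA first); Helitron insertions
#' set the host context to A | element | T. Each copy is optionally
#' reverse-complement inserted and then diverged by per-copy
#' substitutions, so TSD/TIR degradation is realistic. Truth intervals are
#' the element spans excluding TSDs.
#'
#' @param background a DNA string.
#' @param specs list of [element_spec()] objects.
#' @param seed optional RNG seed.
#' @param seqid sequence name used in the truth set.
#' @param min_gap minimum distance between planted sites (bp).
#' @param max_attempts site-sampling budget.
#' @return list with `seq` (genome string), `truth` (data frame),
#'   `families` (per-family ancestral sequences and metadata).
#' @export
implant_elements <- function(background, specs, seed = NULL,
                             seqid = "chr1", min_gap = 100L,
                             max_attempts = 1000L) {
  .with_seed(seed, {
    n <- nchar(background)
    plan <- list()
    families <- list()
    fam_counter <- 0L
    for (spec in specs) {
      for (f in seq_len(spec$n_families)) {
        fam_counter <- fam_counter + 1L
        anc <- make_element(spec)
        families[[fam_counter]] <- list(family_id = fam_counter,
                                        kind = spec$kind, seq = anc$seq,
                                        meta = anc$meta, spec = spec)
        for (cp in seq_len(spec$copies_per_family)) {
          plan[[length(plan) + 1L]] <- list(
            family_id = fam_counter, kind = spec$kind, copy = cp,
            seq = anc$seq, divergence = spec$divergence,
            tsd_len = switch(spec$kind,
              mule = if (length(spec$tsd_len) > 1L)
                sample(spec$tsd_len, 1L) else spec$tsd_len,
              stowaway = 2L, tourist = 3L, 0L),
            strand = sample(c("+", "-"), 1L))
        }
      }
    }
    total_len <- sum(vapply(plan, function(p) nchar(p$seq), numeric(1)))
    if (total_len >= 0.5 * n)
      stop("implant_elements: planted length exceeds half the background")

    # Non-overlapping insertion points in background coordinates.
    k <- length(plan)
    margin <- 2000L
    sites <- integer(0)
    for (a in seq_len(max_attempts)) {
      cand <- sort(sample(seq(margin, n - margin), k))
      if (k == 1L || all(diff(cand) >= min_gap)) { sites <- cand; break }
    }
    if (length(sites) == 0L)
      stop("implant_elements: could not place ", k,
           " non-overlapping sites in ", max_attempts, " attempts")
    ord <- sample.int(k)  # which plan entry goes to which site

    bg <- .chars(background)
    pieces <- character(0)
    truth <- vector("list", k)
    prev <- 0L   # last background position consumed
    offset <- 0L # cumulative inserted length so far
    for (si in seq_len(k)) {
      p <- plan[[ord[si]]]
      site <- sites[si]
      el <- if (p$strand == "-") revcomp(p$seq) else p$seq
      if (p$kind == "helitron") {
        bg[site] <- "A"; bg[site + 1L] <- "T"
        host_left <- paste(bg[(prev + 1L):site], collapse = "")
        el_m <- .mutate_seq(el, p$divergence)
        pieces <- c(pieces, host_left, el_m)
        start <- site + offset + 1L
        end <- start + nchar(el_m) - 1L
        offset <- offset + nchar(el_m)
        prev <- site
        tsd <- ""
      } else if (p$kind %in% c("mule", "stowaway", "tourist")) {
        kk <- p$tsd_len
        if (p$kind == "stowaway") { bg[site + 1L] <- "T"; bg[site + 2L] <- "A" }
        tsd <- paste(bg[(site + 1L):(site + kk)], collapse = "")
        host_left <- paste(bg[(prev + 1L):(site + kk)], collapse = "")
        el_m <- .mutate_seq(el, p$divergence)
        tsd_m <- .mutate_seq(tsd, p$divergence)
        pieces <- c(pieces, host_left, el_m, tsd_m)
        start <- site + kk + offset + 1L
        end <- start + nchar(el_m) - 1L
        offset <- offset + nchar(el_m) + kk
        prev <- site + kk
      } else {  # generic_repeat: plain insertion
        host_left <- paste(bg[(prev + 1L):site], collapse = "")
        el_m <- .mutate_seq(el, p$divergence)
        pieces <- c(pieces, host_left, el_m)
        start <- site + offset + 1L
        end <- start + nchar(el_m) - 1L
        offset <- offset + nchar(el_m)
        prev <- site
        tsd <- ""
      }
      truth[[si]] <- data.frame(
        seqid = seqid, start = start, end = end, kind = p$kind,
        family_id = p$family_id, copy = p$copy, strand = p$strand,
        tsd = tsd, tsd_len = p$tsd_len, stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, paste(bg[(prev + 1L):n], collapse = ""))
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(seq = paste(pieces, collapse = ""), truth = truth,
         families = families)
  })
}

#' Default study-condition simulation configuration
#'
#' 500 kb background at GC 0.44 with 4 Helitron families of 5 copies,
#' 4 MULE families of 5 copies, 3 Stowaway families of 5 copies and
#' 3 Tourist families of 5 copies, at the given divergence.
#'
#' @param length background length.
#' @param gc background GC fraction.
#' @param divergence per-copy substitution rate applied to every kind.
#' @return list with `length`, `gc` and `specs`.
#' @export
sim_config <- function(length = 500000L, gc = 0.44, divergence = 0) {
  list(length = length, gc = gc, specs = list(
    element_spec("helitron", n_families = 4L, copies_per_family = 5L,
                 divergence = divergence),
    element_spec("mule", n_families = 4L, copies_per_family = 5L,
                 divergence = divergence),
    element_spec("stowaway", n_families = 3L, copies_per_family = 5L,
                 divergence = divergence),
    element_spec("tourist", n_families = 3L, copies_per_family = 5L,
                 divergence = divergence)))
}

#' Simulate a genome with planted elements and ground truth
#'
#' Generates the background, plants every element of the configuration and
#' returns the genome, the truth set, the per-family ancestral sequences
#' and the MULE TIR library the planted families imply. With `out_prefix`,
#' writes `<prefix>.fa`, `<prefix>.truth.gff3` and `<prefix>.truth.tsv`.
#'
#' @param config a [sim_config()] list.
#' @param seed RNG seed (same seed, byte-identical output).
#' @param seqid sequence name.
#' @param out_prefix optional output path prefix.
#' @return list with `genome` (named character vector), `truth`,
#'   `families`, `tir_library`.
#' @export
simulate_te_genome <- function(config = sim_config(), seed = 1L,
                               seqid = "chr1", out_prefix = NULL) {
  bg <- simulate_background(config$length, seed = seed, gc = config$gc)
  res <- implant_elements(bg, config$specs, seed = seed + 1L, seqid = seqid)
  genome <- stats::setNames(res$seq, seqid)
  mule_fams <- Filter(function(f) f$kind == "mule", res$families)
  tir_lib <- if (length(mule_fams)) {
    tir_library(
      consensus = vapply(mule_fams, function(f) f$meta$tir, character(1)),
      family_id = vapply(mule_fams, function(f) f$family_id, integer(1)),
      source = "de_novo")
  } else NULL
  out <- list(genome = genome, truth = res$truth, families = res$families,
              tir_library = tir_lib)
  if (!is.null(out_prefix)) {
    write_fasta(genome, paste0(out_prefix, ".fa"))
    write_gff3(res$truth, paste0(out_prefix, ".truth.gff3"),
               seqlens = stats::setNames(nchar(genome), names(genome)))
    utils::write.table(res$truth, paste0(out_prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
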