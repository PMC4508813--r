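# Independent brute-force oracles used to cross-check the scanners.
# These enumerate every placement explicitly and share no code with the
# package's anchored/indexed implementations.

BASES <- c("A", "C", "G", "T")
CMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# --- hairpin/terminus oracle -------------------------------------------

# Enumerates every (start, stem, loop, spacer) placement on one strand and
# applies the same per-terminus canonicalization the scanner documents
# (longest stem, then smallest loop, then smallest spacer).
oracle_hairpin_strand <- function(chv, p) {
  n <- length(chv)
  plac <- list()
  for (stem in p$stem_min:p$stem_max) {
    for (loop in p$loop_min:p$loop_max) {
      for (sp in p$spacer_min:p$spacer_max) {
        span <- 2L * stem + loop + sp + 5L
        if (n < span) next
        starts <- seq_len(n - span + 1L)
        mm <- integer(length(starts))
        for (k in seq_len(stem)) {
          a <- chv[starts + k - 1L]
          b <- chv[starts + 2L * stem + loop - k]
          mm <- mm + (CMP[a] != b | a == "N" | b == "N")
        }
        m <- starts + 2L * stem + loop + sp
        ok <- mm <= p$stem_mismatches &
          chv[m] == "C" & chv[m + 1L] == "T" &
          chv[m + 2L] %in% c("A", "G") & chv[m + 3L] %in% c("A", "G") &
          chv[m + 4L] == "T"
        if (any(ok)) {
          plac[[length(plac) + 1L]] <- data.frame(
            start = starts[ok], stem_len = stem, loop_len = loop,
            spacer_len = sp, term_pos = m[ok] + 3L)
        }
      }
    }
  }
  if (length(plac) == 0L) return(NULL)
  d <- do.call(rbind, plac)
  # canonical placement per terminus
  out <- lapply(split(d, d$term_pos), function(g) {
    g <- g[order(-g$stem_len, g$loop_len, g$spacer_len), ]
    g[1, ]
  })
  d <- do.call(rbind, out)
  d$end <- d$term_pos + 1L
  d$stem <- vapply(seq_len(nrow(d)), function(i) {
    paste(chv[d$start[i]:(d$start[i] + d$stem_len[i] - 1L)], collapse = "")
  }, character(1))
  d
}

oracle_hairpin <- function(seq, p = hairpin_params()) {
  chv <- str_chars(seq)
  n <- length(chv)
  plus <- oracle_hairpin_strand(chv, p)
  if (!is.null(plus)) plus$strand <- "+"
  minus <- oracle_hairpin_strand(rev(CMP[chv]), p)
  if (!is.null(minus)) {
    tmp_start <- n - minus$end + 1L
    minus$end <- n - minus$start + 1L
    minus$start <- tmp_start
    minus$term_pos <- n - minus$term_pos + 1L
    minus$strand <- "-"
  }
  d <- rbind(plus, minus)
  if (is.null(d)) return(NULL)
  d <- d[order(d$start, d$end, d$strand),
         c("start", "end", "strand", "stem", "stem_len", "loop_len",
           "spacer_len", "term_pos")]
  rownames(d) <- NULL
  d
}

# --- 40 bp end-scan oracle ---------------------------------------------

oracle_end_scan <- function(seq, lib, max_mm = 4L) {
  chv <- str_chars(seq)
  n <- length(chv)
  rows <- list()
  for (i in seq_len(nrow(lib))) {
    for (st in c("+", "-")) {
      tr <- lib$tract[i]
      tch <- str_chars(tr)
      if (st == "-") tch <- rev(CMP[tch])
      L <- length(tch)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      mm <- integer(length(starts))
      for (k in seq_len(L)) {
        a <- chv[starts + k - 1L]
        mm <- mm + (a != tch[k] | a == "N" | tch[k] == "N")
      }
      ok <- mm <= max_mm
      if (any(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = lib$family_id[i], end = lib$end[i], strand = st,
          start = starts[ok], end_pos = starts[ok] + L - 1L, mm = mm[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(family_id = integer(), end = character(),
                      strand = character(), start = integer(),
                      end_pos = integer(), mm = integer()))
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$end_pos), ]
  rownames(d) <- NULL
  d
}

# --- textbook Levenshtein DP (row-vectorized) --------------------------

oracle_levenshtein <- function(a, b) {
  av <- str_chars(a); bv <- str_chars(b)
  na <- length(av); nb <- length(bv)
  prev <- 0:nb
  for (i in seq_len(na)) {
    sub_cost <- prev[1:nb] + (av[i] != bv)
    del_cost <- prev[2:(nb + 1)] + 1L
    cur0 <- pmin(sub_cost, del_cost)
    cur0 <- c(i, cur0)
    # propagate insertions left-to-right: cur[j] = min over i<=j of
    # cur0[i] + (j - i)
    idx <- seq_len(nb + 1L)
    cm <- cummin(cur0 - idx)
    cur <- pmin(cur0, cm + idx)
    prev <- cur
  }
  prev[nb + 1L]
}

# Exhaustive TSD decision over all (length, left offset, right offset)
# combinations, using the same documented preference order.
oracle_tsd_decision <- function(seq, start, end, rules = tsd_rules()) {
  chv <- str_chars(seq)
  n <- length(chv)
  rows <- list()
  for (L in rules$lengths) {
    tol <- rules$tolerance[[as.character(L)]]
    for (ol in -rules$swing:rules$swing) {
      lfrom <- start - L + ol
      if (lfrom < 1L || lfrom + L - 1L > n) next
      left <- chv[lfrom:(lfrom + L - 1L)]
      if (any(left == "N")) next
      for (or in -rules$swing:rules$swing) {
        rfrom <- end + 1L + or
        if (rfrom < 1L || rfrom + L - 1L > n) next
        right <- chv[rfrom:(rfrom + L - 1L)]
        if (any(right == "N")) next
        d <- oracle_levenshtein(paste(left, collapse = ""),
                                paste(right, collapse = ""))
        if (d <= tol) {
          rows[[length(rows) + 1L]] <- data.frame(
            length = L, dist = d, off_left = ol, off_right = or)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  d <- do.call(rbind, rows)
  d <- d[order(d$dist, abs(d$off_left) + abs(d$off_right), -d$length,
               d$off_left, d$off_right), ]
  as.list(d[1, ])
}

# --- exhaustive MITE candidate oracle ----------------------------------

oracle_mite <- function(seq, rule, min_len = 50L, max_len = 800L,
                        max_tir_mm = 1L) {
  chv <- str_chars(seq)
  n <- length(chv)
  k <- rule$tsd_len
  rows <- list()
  for (s in (k + 1L):(n - min_len + 1L - k)) {
    if (rule$name == "stowaway" &&
        !(chv[s - 2L] == "T" && chv[s - 1L] == "A")) next
    for (e in (s + min_len - 1L):min(s + max_len - 1L, n - k)) {
      if (rule$name == "stowaway") {
        if (!(chv[e + 1L] == "T" && chv[e + 2L] == "A")) next
      } else {
        l3 <- chv[(s - 3L):(s - 1L)]
        r3 <- chv[(e + 1L):(e + 3L)]
        if (any(l3 == "N") || any(r3 == "N") || !all(l3 == r3)) next
        if (!(chv[s] %in% c("G", "C") || chv[e] %in% c("G", "C"))) next
      }
      # maximal cumulative-mismatch TIR length
      tcap <- (e - s + 1L) %/% 2L
      mm <- 0L; tl <- 0L
      for (t in seq_len(tcap)) {
        a <- chv[s + t - 1L]; b <- chv[e - t + 1L]
        if (!(a != "N" && b != "N" && CMP[b] == a)) mm <- mm + 1L
        if (mm > max_tir_mm) break
        tl <- t
      }
      if (tl < rule$min_tir) next
      if (rule$name == "stowaway") {
        tir5 <- paste(chv[s:(s + tl - 1L)], collapse = "")
        tir3 <- paste(chv[(e - tl + 1L):e], collapse = "")
        has <- grepl("CTCCTCCC", tir5, fixed = TRUE) ||
          grepl("GGGAGGAG", tir5, fixed = TRUE) ||
          grepl("CTCCTCCC", tir3, fixed = TRUE) ||
          grepl("GGGAGGAG", tir3, fixed = TRUE)
        if (!has) next
      }
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e,
                                              tir_len = tl)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      tir_len = integer()))
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$end), ]
  rownames(d) <- NULL
  d
}
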