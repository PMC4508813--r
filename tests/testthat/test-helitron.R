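# Helitron detection: terminus scan, family grouping, context tracts,
# end inference, end-library scan, pairing criteria and soundness.

make_terminus_construct <- function(motif = "CTGAT") {
  # perfect stem 8, loop 3, spacer 7, then the terminus motif
  paste0("GGGTTTAAC", "GCATTCGA", "TAC", "TCGAATGC", "AACCTTG", motif,
         "CCCAAG")
}

test_that("terminus scan accepts the constructed pattern and rejects a bad R", {
  t <- scan_hairpin_termini(make_terminus_construct("CTGAT"), strands = "+")
  expect_gte(nrow(t), 1L)
  expect_identical(t$term_pos[1], as.integer(regexpr("CTGAT",
    make_terminus_construct("CTGAT"))) + 3L)
  # second R position is a pyrimidine -> motif violated
  expect_identical(
    nrow(scan_hairpin_termini(make_terminus_construct("CTGCT"),
                              strands = "+")), 0L)
})

test_that("terminus scan equals the brute-force placement oracle", {
  set.seed(0)
  n_with_hits <- 0L
  for (i in 1:60) {
    s <- random_seq(2000)
    if (i %% 10 == 0) {  # plant a designed terminus to enrich positives
      el <- make_element(element_spec("helitron", length_range = c(300, 400)))
      pos <- sample(500:1200, 1)
      s <- paste0(substr(s, 1, pos), "A", el$seq, "T",
                  substr(s, pos + 1, 2000))
    }
    got <- scan_hairpin_termini(s)
    want <- oracle_hairpin(s)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      n_with_hits <- n_with_hits + 1L
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
  expect_gte(n_with_hits, 5L)
})

test_that("terminus scan is strand symmetric", {
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(1500)
    n <- nchar(s)
    a <- scan_hairpin_termini(s)
    b <- scan_hairpin_termini(revcomp(s))
    if (nrow(a) == 0L) { expect_identical(nrow(b), 0L); next }
    # mirror b back into a's coordinates
    b2 <- b
    b2$term_pos <- n - b$term_pos + 1L
    b2$start <- n - b$end + 1L
    b2$end <- n - b$start + 1L
    b2$strand <- ifelse(b$strand == "+", "-", "+")
    b2 <- b2[order(b2$start, b2$end, b2$strand), names(a)]
    expect_equal(a, b2, ignore_attr = TRUE)
  }
})

test_that("low-complexity stems are dropped", {
  t <- data.frame(start = 1:3, end = 31:33, strand = "+",
                  stem = c("AAAAAAAA", "ATATATAT", "GCATTCGA"),
                  stem_len = 8L, loop_len = 3L, spacer_len = 7L,
                  term_pos = 27:29, stringsAsFactors = FALSE)
  kept <- filter_low_complexity(t)
  expect_identical(kept$stem, "GCATTCGA")
})

test_that("family grouping partitions by stem with the 5-member floor", {
  t <- data.frame(start = 1:9, end = 31:39, strand = "+",
                  stem = c(rep("ACGTACG", 6), rep("TTTCCCA", 3)),
                  stem_len = 7L, loop_len = 2L, spacer_len = 6L,
                  term_pos = 27:35, stringsAsFactors = FALSE)
  fams <- group_terminus_families(t)
  expect_identical(unique(fams$stem), "ACGTACG")
  expect_identical(nrow(fams), 6L)

  # boundary: exactly 5 members is kept
  fams5 <- group_terminus_families(t[1:5, ])
  expect_identical(nrow(fams5), 5L)
  expect_identical(unique(fams5$family_id), 1L)

  expect_identical(nrow(group_terminus_families(t[0, ])), 0L)
})

test_that("context tracts span 15 kb up / 200 bp down with edge clamping", {
  set.seed(4)
  g <- random_seq(20000)
  mem <- data.frame(term_pos = 16000L, strand = "+")
  tr <- extract_context_tracts(mem, g)
  expect_identical(nchar(tr$tracts), 15200L)
  expect_identical(tr$term_offset, 15000L)

  mem2 <- data.frame(term_pos = 1000L, strand = "+")
  tr2 <- extract_context_tracts(mem2, g)
  expect_identical(nchar(tr2$tracts), 1200L)
  expect_identical(tr2$term_offset, 1000L)

  mem3 <- data.frame(term_pos = 16000L, strand = "-")
  tr3 <- extract_context_tracts(mem3, g)
  expect_identical(
    tr3$tracts, revcomp(substr(g, 16000 - 200, 16000 + 15000 - 1)))

  expect_error(extract_context_tracts(
    data.frame(term_pos = 30000L, strand = "+"), g), "outside")
})

test_that("family end inference recovers exact ends from exact copies", {
  set.seed(9)
  el <- make_element(element_spec("helitron", length_range = c(900, 1100)))$seq
  L <- nchar(el)
  tracts <- character(3); offs <- integer(3)
  for (i in 1:3) {
    up <- random_seq(2500); down <- random_seq(200)
    tracts[i] <- paste0(up, "A", el, "T", substr(down, 2, 200))
    offs[i] <- nchar(up) + 1L + L
  }
  ends <- infer_family_ends(tracts, offs)
  expect_true(ends$ok)
  expect_identical(ends$five_tract, substr(el, 1, 40))
  expect_identical(ends$three_tract, substr(el, L - 39, L))
  expect_identical(ends$span, L)
})

test_that("end inference rejects tract sets without shared segments", {
  set.seed(10)
  tracts <- c(random_seq(800), random_seq(800))
  ends <- infer_family_ends(tracts, c(780L, 780L))
  expect_false(isTRUE(ends$ok))
})

test_that("end inference rejects families violating the AT context vote", {
  set.seed(11)
  el <- make_element(element_spec("helitron", length_range = c(500, 700)))$seq
  L <- nchar(el)
  # keep the element's first bases A-free so the boundary A vote has no
  # spurious in-element support
  el <- paste0("TCGTCGTCGTCG", substr(el, 13, L))
  tracts <- character(4); offs <- integer(4)
  for (i in 1:4) {
    up <- gsub("A", "C", random_seq(1200))
    # insert WITHOUT the host A context
    tracts[i] <- paste0(up, "C", el, "T", random_seq(199))
    offs[i] <- nchar(up) + 1L + L
  }
  ends <- infer_family_ends(tracts, offs)
  expect_false(isTRUE(ends$ok))
})

test_that("end inference stays within 10 bp of truth at 2 % divergence", {
  set.seed(12)
  spec <- element_spec("helitron", length_range = c(900, 1100),
                       divergence = 0.02)
  el <- make_element(spec)$seq
  L <- nchar(el)
  tracts <- character(5); offs <- integer(5)
  for (i in 1:5) {
    up <- random_seq(2000)
    copy <- strucTE:::.mutate_seq(el, 0.02)
    tracts[i] <- paste0(up, "A", copy, "T", random_seq(199))
    offs[i] <- nchar(up) + 1L + L
  }
  ends <- infer_family_ends(tracts, offs)
  expect_true(ends$ok)
  expect_lte(abs(ends$span - L), 10L)
})

test_that("end-library scan equals the naive all-positions oracle", {
  set.seed(7)
  lib <- data.frame(family_id = c(1L, 1L), end = c("five", "three"),
                    tract = c(random_seq(40), random_seq(40)),
                    stringsAsFactors = FALSE)
  for (i in 1:50) {
    s <- random_seq(2000)
    # plant a degraded copy of a tract sometimes
    if (i %% 3 == 0) {
      t <- str_chars(lib$tract[1])
      nmut <- sample(0:5, 1)
      pos <- sample(40, nmut)
      for (p in pos) t[p] <- sample(setdiff(BASES, t[p]), 1)
      at <- sample(1:(2000 - 40), 1)
      s <- paste0(substr(s, 1, at - 1), paste(t, collapse = ""),
                  substr(s, at + 40, 2000))
    }
    got <- scan_end_library(s, lib)
    want <- oracle_end_scan(s, lib)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("planted tracts hit at 0 mismatches; 5 substitutions do not hit", {
  set.seed(8)
  tract <- random_seq(40)
  lib <- data.frame(family_id = 1L, end = "five", tract = tract,
                    stringsAsFactors = FALSE)
  bg <- random_seq(3000)
  s <- paste0(substr(bg, 1, 999), tract, substr(bg, 1040, 3000))
  hits <- scan_end_library(s, lib)
  expect_true(any(hits$start == 1000 & hits$mm == 0))

  t5 <- str_chars(tract)
  for (p in sample(40, 5)) t5[p] <- sample(setdiff(BASES, t5[p]), 1)
  s5 <- paste0(substr(bg, 1, 999), paste(t5, collapse = ""),
               substr(bg, 1040, 3000))
  hits5 <- scan_end_library(s5, lib)
  expect_false(any(hits5$start == 1000))
})

test_that("end pairing enforces criteria a-e on constructed cases", {
  set.seed(21)
  el <- make_element(element_spec("helitron", length_range = c(800, 900)))$seq
  L <- nchar(el)
  lib <- data.frame(family_id = 1L, end = c("five", "three"),
                    tract = c(substr(el, 1, 40), substr(el, L - 39, L)),
                    span = L, stringsAsFactors = FALSE)
  flank <- random_seq(4000)
  good <- paste0(substr(flank, 1, 1999), "A", el, "T",
                 substr(flank, 2002 + L, 4000))
  calls <- pair_helitron_ends(scan_end_library(good, lib), good)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, 2001L)
  expect_identical(calls$end, 2000L + L)
  expect_true(isTRUE(validate_helitron_call(calls[1, ], good, lib)))

  # preceding base G violates the AT rule
  bad <- paste0(substr(flank, 1, 1999), "G", el, "T",
                substr(flank, 2002 + L, 4000))
  expect_identical(nrow(pair_helitron_ends(scan_end_library(bad, lib), bad)),
                   0L)

  # ends 150 bp apart: span no longer than 200
  short <- paste0(substr(flank, 1, 1999), "A", substr(el, 1, 40),
                  random_seq(70), substr(el, L - 39, L), "T",
                  substr(flank, 2000, 3000))
  expect_identical(
    nrow(pair_helitron_ends(scan_end_library(short, lib), short)), 0L)
})

test_that("overlapping same-family calls merge to the longest", {
  hits <- data.frame(
    family_id = 1L,
    end = c("five", "five", "three"),
    strand = "+",
    start = c(1000L, 1500L, 2461L),
    end_pos = c(1039L, 1539L, 2500L),
    mm = 0L, stringsAsFactors = FALSE)
  # fabricate a sequence satisfying terminus + AT at both candidate spans
  set.seed(30)
  chv <- str_chars(random_seq(3000))
  chv[999] <- "A"; chv[1499] <- "A"  # both 5' candidates A-preceded
  chv[2497:2500] <- c("C", "T", "G", "A"); chv[2501] <- "T"
  s <- paste(chv, collapse = "")
  calls <- pair_helitron_ends(hits, s)
  # nearest pairing picks the 1500 5' end; no overlapping longer call kept
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, 1500L)
})

test_that("helitron recovery on a small planted genome is exact", {
  cfg <- sim_config(length = 100000, divergence = 0)
  cfg$specs <- cfg$specs[1]
  sim <- simulate_te_genome(cfg, seed = 13)
  res <- find_helitrons(sim$genome)
  sc <- score_calls(res$calls, sim$truth)
  expect_identical(sc$recall[1], 1)
  expect_identical(sc$precision[1], 1)
  expect_identical(sc$boundary_error[1], 0)
  # soundness: every call revalidates
  for (i in seq_len(nrow(res$calls))) {
    expect_true(isTRUE(validate_helitron_call(
      res$calls[i, ], sim$genome[[res$calls$seqid[i]]], res$end_library)))
  }
})
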