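# MULE detection: library filtering, TIR hits, pairing criteria, TSD
# validation against an exhaustive oracle, family support, classification
# and call soundness.

test_that("mask filtering removes families at or above 30 percent", {
  lib <- tir_library(c(a = random_seq(60), b = random_seq(60),
                       c = random_seq(60)), family_id = 1:3)
  masks <- data.frame(family_id = 1:3, masked_frac = c(0.29, 0.30, 0.95))
  kept <- filter_tir_library(lib, masks)
  expect_identical(kept$family_id, 1L)
  # family missing from the table is treated as unmasked
  expect_message(
    kept2 <- filter_tir_library(lib, masks[2:3, ]), "missing")
  expect_identical(kept2$family_id, 1L)
  # empty table keeps everything
  expect_identical(nrow(filter_tir_library(lib, NULL)), 3L)
})

test_that("TIR hits are found verbatim and absent when not present", {
  set.seed(31)
  tir <- random_seq(120)
  lib <- tir_library(tir)
  bg <- random_seq(5000)
  g <- paste0(substr(bg, 1, 999), tir, substr(bg, 1120, 5000))
  hits <- locate_tir_hits(g, lib)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 1000L)
  expect_identical(hits$identity, 1)
  expect_identical(hits$strand, "+")

  expect_identical(nrow(locate_tir_hits(random_seq(5000), lib)), 0L)
})

test_that("TIR hits recover planted 10 percent-diverged copies at 0.80", {
  set.seed(32)
  tir <- random_seq(150)
  lib <- tir_library(tir)
  g <- random_seq(20000)
  where <- c(2000, 8000, 14000)
  for (p in where) {
    copy <- strucTE:::.mutate_seq(tir, 0.10)
    g <- paste0(substr(g, 1, p - 1), copy, substr(g, p + 150, nchar(g)))
  }
  hits <- locate_tir_hits(g, lib)
  expect_true(all(where %in% hits$start))
  expect_true(all(hits$identity >= 0.80))
})

test_that("TIR pairing enforces family, orientation and distance criteria", {
  hits <- data.frame(
    family_id = c(1L, 1L, 1L, 2L, 1L),
    start = c(1000L, 6000L, 9000L, 12000L, 40000L),
    end = c(1100L, 6100L, 9100L, 12100L, 40100L),
    strand = c("+", "-", "+", "-", "-"),
    identity = 1)
  cands <- pair_tirs(hits)
  # (1+,2-) and (3+,5-)? 3->5 inner distance is 30899 >= 20000: rejected;
  # (1+,5-) likewise; (3+,4-) is family-mismatched
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$start, 1000L)
  expect_identical(cands$end, 6100L)
  expect_identical(cands$inner_dist, 4899L)

  # same-strand pair: no candidate
  same <- hits[c(1, 3), ]
  expect_identical(nrow(pair_tirs(same)), 0L)
})

test_that("TSD validation accepts identical 9-mers and rejects 7-mers with a mismatch", {
  set.seed(33)
  tsd <- random_seq(9)
  g <- paste0(random_seq(200), tsd, random_seq(500), tsd, random_seq(200))
  start <- 200 + 9 + 1
  end <- 200 + 9 + 500
  m <- validate_tsd(g, start, end)
  expect_identical(m$length, 9L)
  expect_identical(m$dist, 0L)
  expect_identical(m$off_left, 0L)
  expect_identical(m$off_right, 0L)

  # 7 bp TSD with one substitution: perfect match required at 7 bp
  only7 <- tsd_rules(lengths = 7L, tolerance = c("7" = 0L), swing = 0L)
  tsd7 <- "ACGTCCA"; tsd7mm <- "ACGGCCA"
  g2 <- paste0(random_seq(60), tsd7, random_seq(100), tsd7mm, random_seq(60))
  s2 <- 60 + 7 + 1; e2 <- 60 + 7 + 100
  expect_null(validate_tsd(g2, s2, e2, only7))
  # ...and the same flanks with identical 7-mers pass
  g3 <- paste0(substr(g2, 1, 60), tsd7, substr(g2, 68, 167), tsd7,
               substr(g2, 175, nchar(g2)))
  m3 <- validate_tsd(g3, s2, e2, only7)
  expect_identical(m3$length, 7L)
  expect_identical(m3$dist, 0L)
})

test_that("TSD decisions match the exhaustive edit-distance oracle", {
  set.seed(34)
  n_nontrivial <- 0L
  for (trial in 1:60) {
    g <- random_seq(120)
    if (trial %% 3 == 0) {  # plant a real TSD at a random offset
      L <- sample(7:11, 1)
      tsd <- random_seq(L)
      off <- sample(-3:3, 1)
      g <- paste0(substr(g, 1, 40 - L + off), tsd,
                  substr(g, 41 + off, 80), tsd, substr(g, 81 + L, 120))
    }
    start <- 41L; end <- min(nchar(g) - 30L, 90L)
    got <- validate_tsd(g, start, end)
    want <- oracle_tsd_decision(g, start, end)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_nontrivial <- n_nontrivial + 1L
      expect_identical(got$length, as.integer(want$length))
      expect_identical(got$dist, as.integer(want$dist))
      expect_identical(got$off_left, as.integer(want$off_left))
      expect_identical(got$off_right, as.integer(want$off_right))
    }
  }
  expect_gte(n_nontrivial, 15L)
})

test_that("loosening the tolerance map never loses validated candidates", {
  set.seed(35)
  loose <- tsd_rules(tolerance = c("7" = 1L, "8" = 2L, "9" = 3L,
                                   "10" = 3L, "11" = 3L))
  n_def <- 0L; n_loose <- 0L
  for (trial in 1:120) {
    g <- random_seq(100)
    ok_def <- !is.null(validate_tsd(g, 41L, 60L))
    ok_loose <- !is.null(validate_tsd(g, 41L, 60L, loose))
    n_def <- n_def + ok_def
    n_loose <- n_loose + ok_loose
    if (ok_def) expect_true(ok_loose)
  }
  expect_gte(n_loose, n_def)
})

test_that("de novo family support threshold is enforced; known families exempt", {
  base <- data.frame(
    tir1_start = 1L, tir1_end = 100L, tir2_start = 901L, tir2_end = 1000L,
    inner_dist = 800L, tsd_len = 9L, tsd_dist = 0L,
    tsd_off_left = 0L, tsd_off_right = 0L)
  mk <- function(fid, n, offset = 0L) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      r <- base
      r$family_id <- fid
      r$start <- offset + i * 2000L
      r$end <- r$start + 999L
      r
    }))
  }
  lib <- tir_library(c(random_seq(100), random_seq(100), random_seq(100)),
                     family_id = 1:3,
                     source = c("de_novo", "de_novo", "known"))
  cands4 <- mk(1L, 4L)
  expect_identical(nrow(call_mules(cands4, lib)), 0L)
  cands5 <- mk(1L, 5L)
  expect_identical(nrow(call_mules(cands5, lib)), 5L)
  known1 <- mk(3L, 1L, offset = 100000L)
  expect_identical(nrow(call_mules(known1, lib)), 1L)
})

test_that("classification follows the protein-evidence rules", {
  calls <- data.frame(
    family_id = 1L, start = c(1L, 5001L, 9001L, 13001L),
    end = c(4000L, 7000L, 12800L, 14800L), tsd_len = 9L, tsd_dist = 0L,
    kind = "mule")
  hits <- data.frame(
    call_id = c(1L, 2L, 3L, 4L, 4L),
    subject_class = c("transposase", "other", "transposase", "other",
                      "non_mule_te"),
    evalue = c(1e-20, 1e-12, 1e-30, 1e-15, 1e-40))
  out <- classify_mules(calls, hits)
  # call 1: 4 kb + transposase -> autonomous
  expect_identical(out$klass[out$start == 1L], "autonomous")
  # call 2: 2 kb + non-transposase protein -> pack_mule
  expect_identical(out$klass[out$start == 5001L], "pack_mule")
  # call 3: transposase but only 3.8 kb -> autonomous (length > 3 kb)
  expect_identical(out$klass[out$start == 9001L], "autonomous")
  # call 4 overlaps a known non-MULE transposon -> dropped
  expect_false(13001L %in% out$start)
  # high e-values are ignored entirely
  weak <- transform(hits, evalue = 1)
  out2 <- classify_mules(calls, weak)
  expect_identical(unique(out2$klass), "nonautonomous")
})

test_that("planted MULEs are recovered exactly with exact TSD lengths", {
  cfg <- sim_config(length = 130000, divergence = 0)
  cfg$specs <- cfg$specs[2]
  sim <- simulate_te_genome(cfg, seed = 21)
  res <- find_mules(sim$genome, sim$tir_library)
  sc <- score_calls(res$calls, sim$truth)
  expect_identical(sc$recall[1], 1)
  expect_identical(sc$precision[1], 1)
  expect_identical(sc$boundary_error[1], 0)
  m <- merge(sim$truth, res$calls, by = c("start", "end"))
  expect_identical(nrow(m), nrow(sim$truth))
  expect_identical(m$tsd_len.x, m$tsd_len.y)
  # soundness: every call revalidates criteria 1-4
  for (i in seq_len(nrow(res$calls))) {
    expect_true(isTRUE(validate_mule_call(
      res$calls[i, ], sim$genome[[res$calls$seqid[i]]], sim$tir_library)))
  }
})

test_that("recall degrades monotonically with divergence", {
  rec <- vapply(c(0.02, 0.30), function(dv) {
    cfg <- sim_config(length = 80000, divergence = dv)
    cfg$specs <- cfg$specs[2]
    cfg$specs[[1]]$n_families <- 2L
    sim <- simulate_te_genome(cfg, seed = 40)
    res <- find_mules(sim$genome, sim$tir_library)
    suppressWarnings(score_calls(res$calls, sim$truth)$recall[1])
  }, numeric(1))
  expect_gte(rec[1], rec[2])
  expect_gt(rec[1], 0.8)   # 2 % divergence: TIRs still above 0.80 identity
  expect_lt(rec[2], 0.5)   # 30 % divergence: far below the threshold
})
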