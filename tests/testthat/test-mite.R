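# MITE discovery: window arithmetic, rule constraints, oracle
# equivalence, window-overlap invariance, clustering, consensus building
# and longest-hit mapping.

test_that("window tiling matches the documented arithmetic", {
  w <- iter_windows(2000L)
  expect_identical(w$start, c(1L, 801L, 1601L))
  expect_identical(w$end, c(1000L, 1800L, 2000L))

  w500 <- iter_windows(500L)
  expect_identical(nrow(w500), 1L)
  expect_identical(w500$end, 500L)

  expect_error(iter_windows(1000L, size = 200L, overlap = 200L), "exceed")

  # coverage: every base in at least one window
  for (len in c(999L, 1000L, 1001L, 2741L)) {
    w <- iter_windows(len)
    covered <- rep(FALSE, len)
    for (i in seq_len(nrow(w))) covered[w$start[i]:w$end[i]] <- TRUE
    expect_true(all(covered))
  }
})

make_stowaway <- function(body_len = 150) {
  tir <- paste0("CTCCTCCC", "GTTGC")
  el <- paste0(tir, random_seq(body_len), revcomp(tir))
  list(el = el, with_tsd = paste0("TA", el, "TA"))
}

test_that("constructed Stowaway and Tourist candidates are detected", {
  set.seed(50)
  st <- make_stowaway()
  g <- paste0(random_seq(300), st$with_tsd, random_seq(300))
  cands <- detect_mite_candidates(g, mite_rule("stowaway"))
  expect_true(any(cands$start == 303 & cands$end == 302 + nchar(st$el)))
  expect_true(all(cands$tsd == "TA"))

  # tourist: duplicated host 3-mer, TIR starting with G
  tir <- paste0("G", random_seq(9))
  el <- paste0(tir, random_seq(140), revcomp(tir))
  tsd <- random_seq(3)
  g2 <- paste0(random_seq(250), tsd, el, tsd, random_seq(250))
  cands2 <- detect_mite_candidates(g2, mite_rule("tourist"))
  expect_true(any(cands2$start == 254 & cands2$end == 253 + nchar(el)))

  # tourist TIR beginning with A or T (on both readings) is rejected
  tirA <- paste0("A", random_seq(9))
  elA <- paste0(tirA, random_seq(140), revcomp(tirA))
  g3 <- paste0(random_seq(250), tsd, elA, tsd, random_seq(250))
  cands3 <- detect_mite_candidates(g3, mite_rule("tourist"))
  expect_false(any(cands3$start == 254 & cands3$end == 253 + nchar(elA)))
})

test_that("candidate scan equals the exhaustive triple-loop oracle", {
  set.seed(51)
  for (rule_name in c("stowaway", "tourist")) {
    rule <- mite_rule(rule_name)
    n_nonempty <- 0L
    for (i in 1:30) {
      g <- random_seq(700)
      if (i %% 4 == 0) {  # plant an element to enrich positives
        spec <- element_spec(rule_name, length_range = c(120, 250))
        el <- make_element(spec)$seq
        tsd <- if (rule_name == "stowaway") "TA" else random_seq(3)
        at <- sample(200:350, 1)
        g <- paste0(substr(g, 1, at), tsd, el, tsd,
                    substr(g, at + 1, 700))
      }
      got <- detect_mite_candidates(g, rule)
      want <- oracle_mite(g, rule)
      expect_identical(got[, c("start", "end", "tir_len")], want)
      if (nrow(want) > 0L) n_nonempty <- n_nonempty + 1L
    }
    expect_gte(n_nonempty, 7L)
  }
})

test_that("windowed scan is invariant to the window tiling", {
  set.seed(52)
  for (i in 1:5) {
    g <- random_seq(5000)
    for (j in 1:3) {  # plant tourists across future window boundaries
      el <- make_element(element_spec("tourist",
                                      length_range = c(150, 400)))$seq
      tsd <- random_seq(3)
      at <- c(700, 1550, 3100)[j]
      g <- paste0(substr(g, 1, at), tsd, el, tsd, substr(g, at + 1, nchar(g)))
    }
    a <- scan_mite_candidates(g, mite_rule("tourist"),
                              window_size = 1000L, window_overlap = 200L)
    b <- scan_mite_candidates(g, mite_rule("tourist"),
                              window_size = nchar(g), window_overlap = 200L)
    expect_identical(a, b)
  }
})

test_that("clustering groups copies, folds reverse complements, drops singletons", {
  set.seed(53)
  el <- make_element(element_spec("stowaway", length_range = c(150, 200)))$seq
  other <- random_seq(170)
  cands <- data.frame(
    start = seq(1, by = 1000, length.out = 6),
    end = seq(1, by = 1000, length.out = 6) + nchar(c(rep(el, 5), other)) - 1,
    tir_len = 10L, kind = "stowaway", tsd = "TA",
    seq = c(el, el, revcomp(el), el, el, other),
    stringsAsFactors = FALSE)
  groups <- cluster_mite_candidates(cands)
  expect_identical(length(groups), 1L)
  expect_identical(nrow(groups[[1]]$members), 5L)
  # reverse-complemented member is re-oriented
  expect_identical(unique(groups[[1]]$oriented), el)

  expect_identical(length(cluster_mite_candidates(cands[0, ])), 0L)
})

test_that("same-locus nested candidates do not count as multiple copies", {
  set.seed(54)
  el <- random_seq(200)
  cands <- data.frame(
    start = c(1000L, 1002L), end = c(1199L, 1197L),
    tir_len = 10L, kind = "tourist", tsd = "CAT",
    seq = c(el, substr(el, 3, 198)), stringsAsFactors = FALSE)
  expect_identical(length(cluster_mite_candidates(cands)), 0L)
})

test_that("consensus is the member sequence for identical members and majority otherwise", {
  s <- "ACGTACGTACGTACGTACGT"
  g <- list(centroid = s, members = data.frame(seq = rep(s, 3)),
            oriented = rep(s, 3))
  expect_identical(build_mite_consensus(g), s)

  v1 <- s
  v2 <- sub("^ACGT", "CCGT", s)  # column 1: 2xA, 1xC -> A
  g2 <- list(centroid = s, members = data.frame(seq = c(v1, v1, v2)),
             oriented = c(v1, v1, v2))
  expect_identical(build_mite_consensus(g2), s)
})

test_that("second-round consensus is a fixed point on exact copies and improves on diverged ones", {
  set.seed(55)
  anc <- make_element(element_spec("tourist", length_range = c(180, 220)))$seq
  g <- random_seq(30000)
  for (p in seq(2000, 26000, by = 700)) {  # 35 exact copies
    g <- paste0(substr(g, 1, p - 1), anc, substr(g, p + nchar(anc), nchar(g)))
  }
  expect_identical(refine_mite_consensus(anc, g), anc)

  # diverged copies: the refined consensus moves toward the ancestor
  g2 <- random_seq(30000)
  for (p in seq(2000, 23000, by = 700)) {
    copy <- strucTE:::.mutate_seq(anc, 0.05)
    g2 <- paste0(substr(g2, 1, p - 1), copy,
                 substr(g2, p + nchar(anc), nchar(g2)))
  }
  round1 <- strucTE:::.mutate_seq(anc, 0.05)  # a noisy first-round consensus
  round2 <- refine_mite_consensus(round1, g2)
  d1 <- utils::adist(round1, anc)[1, 1]
  d2 <- utils::adist(round2, anc)[1, 1]
  expect_lte(d2, d1)
  expect_lt(d2, 3)

  # two copies only: used with a message
  g3 <- paste0(random_seq(1000), anc, random_seq(1000), anc, random_seq(1000))
  expect_message(refine_mite_consensus(anc, g3), "only 2 copies")
})

test_that("mapping resolves shared loci by longest hit with documented tie-breaks", {
  set.seed(56)
  shared <- random_seq(250)
  fams <- data.frame(family_id = c(1L, 2L),
                     kind = "tourist",
                     consensus = c(paste0(shared, random_seq(50)), shared),
                     stringsAsFactors = FALSE)
  g <- paste0(random_seq(500), fams$consensus[1], random_seq(500))
  pl <- map_mite_families(g, fams)
  expect_identical(nrow(pl), 1L)
  expect_identical(pl$family_id, 1L)  # 300 bp hit beats the 250 bp hit

  # non-overlapping placements are all kept
  g2 <- paste0(random_seq(300), fams$consensus[1], random_seq(300),
               fams$consensus[2], random_seq(300))
  pl2 <- map_mite_families(g2, fams)
  expect_identical(nrow(pl2), 2L)

  # equal length, equal identity: lower family id wins
  fams3 <- data.frame(family_id = c(2L, 1L), kind = "tourist",
                      consensus = shared, stringsAsFactors = FALSE)
  g3 <- paste0(random_seq(400), shared, random_seq(400))
  pl3 <- map_mite_families(g3, fams3)
  expect_identical(nrow(pl3), 1L)
  expect_identical(pl3$family_id, 1L)
})

test_that("placements are pairwise non-overlapping", {
  set.seed(57)
  cfg <- sim_config(length = 60000, divergence = 0)
  cfg$specs <- cfg$specs[3:4]
  cfg$specs[[1]]$n_families <- 2L
  cfg$specs[[2]]$n_families <- 2L
  sim <- simulate_te_genome(cfg, seed = 58)
  res <- find_mites(sim$genome)
  pl <- res$calls
  if (nrow(pl) > 1L) {
    pl <- pl[order(pl$start), ]
    expect_true(all(pl$start[-1] > pl$end[-nrow(pl)]))
  }
  sc <- score_calls(res$calls, sim$truth)
  expect_identical(sc$recall[1], 1)
  expect_identical(sc$precision[1], 1)
  expect_identical(sc$boundary_error[1], 0)
})

test_that("excluded intervals are not scanned for candidates", {
  set.seed(59)
  st <- make_stowaway()
  g <- paste0(random_seq(300), st$with_tsd, random_seq(300))
  excl <- data.frame(start = 250L, end = 400L)
  cands <- scan_mite_candidates(g, mite_rule("stowaway"), exclude = excl)
  expect_false(any(cands$start == 303))
})
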