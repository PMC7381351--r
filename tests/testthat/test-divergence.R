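# NG86 divergence against the brute-force oracle, window construction,
# and the distribution/rate tests.

test_that("identical sequences have zero divergence", {
  set.seed(3)
  s <- random_cds(30)
  d <- ng86(s, s)
  expect_equal(d$Ks, 0)
  expect_equal(d$Ka, 0)
  expect_equal(d$Sd, 0)
  expect_equal(d$Nd, 0)
})

test_that("hand-counted single-synonymous-difference case is exact", {
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  d <- ng86(a, b)
  expect_equal(d$S, 10 / 3, tolerance = 1e-12)
  expect_equal(d$Sd, 1)
  expect_equal(d$p_s, 0.3, tolerance = 1e-12)
  expect_equal(d$Ks, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(d$Nd, 0)
  expect_equal(d$Ka, 0)
})

test_that("NG86 matches the pathway-enumeration oracle on random pairs", {
  set.seed(101)
  n_pairs <- 200
  worst <- 0
  for (i in seq_len(n_pairs)) {
    a <- random_cds(50)
    b <- mutate_seq(a, sample(5:40, 1))
    d <- ng86(a, b)
    o <- oracle_ng86(a, b)
    worst <- max(worst, abs(d$S - o$S), abs(d$N - o$N),
                 abs(d$Sd - o$Sd), abs(d$Nd - o$Nd))
    if (!is.na(o$Ks)) worst <- max(worst, abs(d$Ks - o$Ks))
    if (!is.na(o$Ka)) worst <- max(worst, abs(d$Ka - o$Ka))
    # site conservation, exact
    expect_equal(d$S + d$N, 3 * d$codons_compared, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-9)
})

test_that("gapped and ambiguous codons are excluded from comparison", {
  a <- "TTTAAAGGG"
  b <- "TTT---GGN"
  d <- ng86(a, b)
  expect_equal(d$codons_compared, 1L)
})

test_that("concatenation preserves length, taxa, and site counts", {
  set.seed(5)
  mk <- function(n) {
    codon_alignment(c(A = random_cds(n), B = random_cds(n)))
  }
  a1 <- mk(10); a2 <- mk(20)
  cc <- concatenate_alignments(list(x = a1, y = a2))
  expect_equal(cc$length, 90)
  expect_error(concatenate_alignments(list()), "no alignments")
  expect_error(concatenate_alignments(list(
    a1, codon_alignment(c(A = random_cds(5), C = random_cds(5))))),
    "taxa")
  # per-gene S adds up to the concatenated S
  s1 <- ng86(a1$seqs[["A"]], a1$seqs[["B"]])$S
  s2 <- ng86(a2$seqs[["A"]], a2$seqs[["B"]])$S
  sc <- ng86(cc$seqs[["A"]], cc$seqs[["B"]])$S
  expect_equal(s1 + s2, sc, tolerance = 1e-9)
})

test_that("ragged alignments are rejected", {
  expect_error(codon_alignment(c(A = "TTTAAA", B = "TTTA")), "ragged")
})

test_that("window closing rule yields the forced window counts", {
  # identical sequences of phenylalanine codons: S = 1/3 per codon, no
  # differences; 4500 codons give S = 1500 -> exactly 3 windows, Ks 0
  aln <- codon_alignment(c(A = strrep("TTT", 4500), B = strrep("TTT", 4500)))
  w <- windowed_ks(aln, "A", "B", window_syn_sites = 500)
  expect_equal(nrow(w), 3L)
  expect_true(all(w$Ks == 0))
  expect_true(all(w$syn_sites >= 500 - 1e-6))

  # short alignment: warning and empty series
  short <- codon_alignment(c(A = strrep("TTT", 30), B = strrep("TTT", 30)))
  expect_warning(w0 <- windowed_ks(short, "A", "B"), "below one window")
  expect_equal(nrow(w0), 0L)
})

test_that("window accounting never exceeds the full-alignment differences", {
  set.seed(8)
  for (rep in 1:5) {
    a <- random_cds(1200)
    b <- mutate_seq(a, 400)
    aln <- codon_alignment(c(A = a, B = b))
    w <- windowed_ks(aln, "A", "B", window_syn_sites = 100)
    full <- ng86(a, b)
    expect_true(nrow(w) >= 1)
    expect_lte(sum(w$Sd), full$Sd + 1e-9)
    expect_equal(sum(w$syn_sites) <= full$S + 1e-9, TRUE)
  }
})

test_that("Mann-Whitney exact and approximate branches behave correctly", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # identical samples: p = 1 under the tie-corrected approximation
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "empty")

  # exact p agrees with full enumeration on random no-tie samples
  set.seed(12)
  for (rep in 1:10) {
    x <- round(stats::runif(sample(3:6, 1)), 6)
    y <- round(stats::runif(sample(3:6, 1)), 6)
    r3 <- mann_whitney(x, y)
    expect_equal(r3$p_value, oracle_mw_p(x, y), tolerance = 1e-9)
  }
})

test_that("windowed pair-vs-all comparison detects reduced HGT divergence", {
  detect <- vapply(1:40, function(sd) {
    ss <- simulate_strain_set(hgt_scenario_config(seed = sd))
    alns <- align_families(ss$genes)
    hgt_fams <- sprintf("FAM%03d", unique(ss$genes$family[ss$genes$hgt_flag]))
    all_fams <- setdiff(names(alns), hgt_fams)
    conc_all <- concatenate_alignments(alns[all_fams])
    conc_pair <- concatenate_alignments(alns[hgt_fams])
    w_all <- windowed_ks(conc_all, "A", "B", window_syn_sites = 100)
    w_pair <- windowed_ks(conc_pair, "A", "B", window_syn_sites = 100)
    if (nrow(w_all) < 10 || nrow(w_pair) < 10) return(NA)
    mann_whitney(w_pair$Ks, w_all$Ks, alternative = "less")$p_value < 0.05
  }, logical(1))
  expect_true(all(!is.na(detect)))
  expect_gte(mean(detect), 0.80)
})

test_that("Tajima relative rate test reproduces closed-form cases", {
  # symmetric counts: chi-square 0, p 1, built from explicit sequences
  a <- paste0(strrep("TTT", 4), strrep("AAA", 4), strrep("GGG", 10))
  b <- paste0(strrep("TTC", 4), strrep("AAG", 4), strrep("GGG", 10))
  # outgroup agrees with b at a's unique sites and with a at b's
  o <- paste0(strrep("TTC", 4), strrep("AAA", 4), strrep("GGG", 10))
  r <- tajima_rrt(a, b, o, mode = "third_codon")
  expect_equal(r$m1, 4)  # a unique where b == outgroup
  expect_equal(r$m2, 4)
  expect_equal(r$chi_square, 0)
  expect_equal(r$p_value, 1)

  # (m1, m2) = (5, 0): chi-square 5, p = 0.02535
  a2 <- paste0(strrep("TTT", 5), strrep("GGG", 10))
  b2 <- paste0(strrep("TTC", 5), strrep("GGG", 10))
  o2 <- b2
  r2 <- tajima_rrt(a2, b2, o2, mode = "third_codon")
  expect_equal(r2$m1, 5)
  expect_equal(r2$m2, 0)
  expect_equal(r2$chi_square, 5)
  expect_equal(r2$p_value, 0.02535, tolerance = 1e-3)
  expect_equal(r2$p_value, stats::pchisq(5, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(tajima_rrt("TTT", "TTTAAA", "TTT"), "equal")
})

test_that("amino-acid mode ignores synonymous third-position changes", {
  a <- strrep("TTT", 10)
  b <- strrep("TTC", 10)  # all synonymous differences
  o <- b
  r_nt <- tajima_rrt(a, b, o, mode = "third_codon")
  r_aa <- tajima_rrt(a, b, o, mode = "amino_acid")
  expect_equal(r_nt$m1, 10)
  expect_equal(r_aa$m1 + r_aa$m2, 0)
  expect_equal(r_aa$p_value, 1)
})

test_that("selection strength controls the Ka/Ks ratio", {
  # near-neutral evolution: Ka/Ks close to 1
  cfg1 <- two_strain_config(total_branch = 0.4, n_families = 10,
                            codon_length = 500, omega = 1, seed = 3)
  ss1 <- simulate_strain_set(cfg1)
  a <- paste(ss1$genes$sequence[ss1$genes$strain_id == "A"], collapse = "")
  b <- paste(ss1$genes$sequence[ss1$genes$strain_id == "B"], collapse = "")
  d1 <- ng86(a, b)
  expect_gt(d1$Ka / d1$Ks, 0.8)
  expect_lt(d1$Ka / d1$Ks, 1.2)

  # strong purifying selection: ratio collapses toward zero
  cfg2 <- two_strain_config(total_branch = 0.4, n_families = 10,
                            codon_length = 500, omega = 0.02, seed = 3)
  ss2 <- simulate_strain_set(cfg2)
  a2 <- paste(ss2$genes$sequence[ss2$genes$strain_id == "A"], collapse = "")
  b2 <- paste(ss2$genes$sequence[ss2$genes$strain_id == "B"], collapse = "")
  d2 <- ng86(a2, b2)
  expect_lt(d2$Ka / d2$Ks, 0.1)
})

test_that("simulator-target Ks is recovered with small relative bias", {
  ks <- vapply(1:3, function(sd) {
    cfg <- two_strain_config(total_branch = 0.3, n_families = 1,
                             codon_length = 10000, seed = sd)
    ss <- simulate_strain_set(cfg)
    ng86(ss$genes$sequence[1], ss$genes$sequence[2])$Ks
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.3) / 0.3, 0.10)
})
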