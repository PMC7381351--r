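# Reciprocal-best-hit classification: scorer behaviour against a
# brute-force frame-enumeration oracle, the labeling rules, and
# recovery of simulated truth.

gene_df <- function(ids, seqs, strain) {
  data.frame(gene_id = ids, strain_id = strain, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("a gene finds its identical copy among random subjects", {
  set.seed(1)
  q <- random_cds(40)
  subs <- gene_df(c("B1", "B2", "B3"),
                  c(q, random_cds(40), random_cds(40)), "B")
  hit <- best_hit(gene_df("A1", q, "A"), subs)
  expect_equal(hit$gene_id, "B1")
})

test_that("hits below the score threshold are reported as none", {
  set.seed(2)
  q <- gene_df("A1", random_cds(30), "A")
  subs <- gene_df("B1", random_cds(30), "B")
  hit <- best_hit(q, subs, score_threshold = 1e6)
  expect_true(is.na(hit$gene_id))
})

test_that("best hit equals the argmax of an exhaustive frame-pair oracle", {
  mat <- baeocomp:::.aa_matrix()
  set.seed(7)
  for (rep in 1:5) {
    q <- random_cds(50)
    base <- random_cds(50)
    subs <- gene_df(c("B1", "B2", "B3"),
                    c(mutate_seq(base, 20), mutate_seq(q, 12),
                      random_cds(50)), "B")
    hit <- best_hit(gene_df("A1", q, "A"), subs, score_threshold = 0)
    oracle_scores <- vapply(subs$sequence, function(sseq) {
      best <- -Inf
      for (fq in 1:3) {
        for (fs in 1:3) {
          best <- max(best, oracle_sw(oracle_translate(q, fq),
                                      oracle_translate(sseq, fs), mat))
        }
      }
      best
    }, numeric(1))
    expect_equal(hit$gene_id, subs$gene_id[which.max(oracle_scores)])
    expect_equal(hit$score, max(oracle_scores))
  }
})

test_that("RBH labeling follows the forward/reverse rules", {
  set.seed(11)
  a1 <- random_cds(60)
  b1 <- mutate_seq(a1, 15)
  a2 <- random_cds(60)
  b2 <- mutate_seq(a2, 15)
  qs <- gene_df(c("A1", "A2"), c(a1, a2), "A")
  ss <- gene_df(c("B1", "B2"), c(b1, b2), "B")

  call <- classify_rbh(qs[1, ], qs, ss)
  expect_equal(call$label, "ortholog")
  expect_equal(call$forward_best, "B1")
  expect_equal(call$reverse_best, "A1")

  # forward hit exists but the subject's best reverse hit is a closer
  # duplicate of the query -> paralog
  a1_dup <- mutate_seq(b1, 2)   # nearly identical to B1
  qs2 <- gene_df(c("A1", "A9"), c(a1, a1_dup), "A")
  call2 <- classify_rbh(qs2[1, ], qs2, ss)
  expect_equal(call2$label, "paralog")
  expect_equal(call2$reverse_best, "A9")

  # no forward hit above threshold -> no similarity
  call3 <- classify_rbh(qs[1, ], qs, ss, score_threshold = 1e6)
  expect_equal(call3$label, "no_similarity")
  expect_true(is.na(call3$forward_best))
})

test_that("batch calls agree with single-gene classification", {
  set.seed(13)
  qs <- gene_df(paste0("A", 1:4),
                vapply(1:4, function(i) random_cds(40), ""), "A")
  ss <- gene_df(paste0("B", 1:3),
                c(mutate_seq(qs$sequence[1], 10),
                  mutate_seq(qs$sequence[2], 10), random_cds(40)), "B")
  batch <- rbh_strain(qs, ss, score_threshold = 40)
  for (i in 1:4) {
    single <- classify_rbh(qs[i, ], qs, ss, score_threshold = 40)
    expect_equal(batch$label[i], single$label)
    expect_equal(batch$forward_best[i], single$forward_best)
  }
})

test_that("precomputed hit tables give the same labels as the rules imply", {
  fw <- data.frame(query = c("A1", "A1", "A2"),
                   subject = c("B1", "B2", "B1"),
                   score = c(100, 80, 90))
  rv <- data.frame(query = c("B1", "B1"), subject = c("A1", "A2"),
                   score = c(95, 60))
  calls <- rbh_from_hits(fw, rv, c("A1", "A2", "A3"), "B")
  expect_equal(calls$label, c("ortholog", "paralog", "no_similarity"))
  expect_equal(calls$forward_best, c("B1", "B1", NA))
})

test_that("homology summary partitions and formats percentages", {
  # Pleurocapsa-style row: 3880 orthologs of 8104 genes is 47.9%
  mk_calls <- function(n_o, n_p, n_n, strain) {
    n <- n_o + n_p + n_n
    data.frame(query_gene = sprintf("g%05d", seq_len(n)),
               subject_strain = strain,
               label = rep(c("ortholog", "paralog", "no_similarity"),
                           c(n_o, n_p, n_n)))
  }
  s <- summarize_homology(mk_calls(3880, 2118, 2106, "S1"), 8104)
  expect_equal(s$pct_orthologs, 47.9)
  expect_equal(s$orthologs + s$paralogs + s$no_similarity, 8104)

  s2 <- summarize_homology(mk_calls(4, 3, 3, "S1"), 10)
  expect_equal(unlist(s2[, c("pct_orthologs", "pct_paralogs",
                             "pct_no_similarity")], use.names = FALSE),
               c(40.0, 30.0, 30.0))

  # a strain with missing calls is an error
  expect_error(summarize_homology(mk_calls(4, 3, 2, "S1"), 10), "calls")
})

test_that("union of no-similarity labels requires absence everywhere", {
  genes <- sprintf("g%02d", 1:4)
  strains <- paste0("S", 1:6)
  calls <- expand.grid(query_gene = genes, subject_strain = strains,
                       stringsAsFactors = FALSE)
  calls$label <- "ortholog"
  # g01: no similarity in 5 of 6 strains; g02: in all 6
  calls$label[calls$query_gene == "g01" & calls$subject_strain != "S6"] <-
    "no_similarity"
  calls$label[calls$query_gene == "g02"] <- "no_similarity"
  expect_equal(union_no_similarity(calls), "g02")
  # all-ortholog calls: empty set
  calls$label <- "ortholog"
  expect_length(union_no_similarity(calls), 0)
  # incomplete coverage errors
  expect_error(union_no_similarity(calls[-1, ]), "cover")
})

test_that("strain-specific simulated genes are exactly the union set", {
  cfg <- sim_config(n_strains = 2, tree = "(A:0.2,B:0.2);",
                    n_families = 100, codon_length = 60,
                    dup_fraction = 0, loss_fraction = 0.2,
                    hgt_fraction = 0, frameshift_fraction = 0,
                    focal_strain = "A", seed = 31)
  ss <- simulate_strain_set(cfg)
  calls <- rbh_all(ss$genes, "A", score_threshold = 50)
  lost <- ss$relations$gene_id[ss$relations$relation == "absent"]
  expect_length(lost, 20)  # 0.2 x 100 families lost in B
  expect_setequal(union_no_similarity(calls), lost)
})

test_that("simulated orthologs and duplicate-confounded genes are recovered", {
  cfg <- sim_config(n_strains = 3, tree = "((A:0.15,B:0.15):0.1,C:0.3);",
                    n_families = 30, codon_length = 80,
                    dup_fraction = 0.3, loss_fraction = 0,
                    hgt_fraction = 0, frameshift_fraction = 0,
                    focal_strain = "A", seed = 17)
  ss <- simulate_strain_set(cfg)
  calls <- rbh_all(ss$genes, "A", score_threshold = 50)
  truth <- calls_from_truth(ss)
  m <- merge(calls, truth, by = c("query_gene", "subject_strain"),
             suffixes = c("", "_truth"))
  ort <- m[m$label_truth == "ortholog", ]
  par <- m[m$label_truth == "paralog", ]
  expect_gte(mean(ort$label == "ortholog"), 0.95)
  expect_gte(mean(par$label == "paralog"), 0.90)

  # ortholog symmetry: calls from B back to strain A agree
  calls_b <- rbh_all(ss$genes, "B", score_threshold = 50)
  ab <- calls[calls$subject_strain == "B" & calls$label == "ortholog", ]
  back <- calls_b[match(ab$forward_best, calls_b$query_gene), ]
  back <- back[back$subject_strain == "A", ]
  ba <- calls_b[calls_b$query_gene %in% ab$forward_best &
                  calls_b$subject_strain == "A", ]
  sym <- merge(ab, ba, by.x = "forward_best", by.y = "query_gene")
  expect_gte(mean(sym$label.y == "ortholog" &
                    sym$forward_best.y == sym$query_gene), 0.99)
})
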