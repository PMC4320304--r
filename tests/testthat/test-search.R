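test_that("local alignment matches the full-DP Smith-Waterman oracle", {
  S <- blosum62()
  # classic textbook pair, frozen against the oracle
  expect_equal(align_local("HEAGAWGHEE", "PAWHEAE")$score,
               sw_oracle("HEAGAWGHEE", "PAWHEAE", S))
  set.seed(11)
  for (k in 1:25) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    expect_equal(align_local(a, b)$score, sw_oracle(a, b, S))
    # score symmetry for a symmetric matrix
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
})

test_that("self-alignment scores the diagonal sum and spans the sequence", {
  S <- blosum62()
  s <- "MKWVTFISLLFLFSSAYS"
  al <- align_local(s, s)
  expect_equal(al$score, sum(S[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])]))
  expect_equal(al$a_span, c(1, nchar(s)))
  expect_equal(al$b_span, c(1, nchar(s)))
})

test_that("alignments with no positive-scoring cell return score 0, empty spans", {
  mat <- matrix(c(1, -4, -4, 1), 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
  sc <- scoring_params(matrix = mat, gap_open = 100, gap_ext = 100)
  al <- align_local("AAAA", "CCCC", sc)
  expect_equal(al$score, 0)
  expect_length(al$a_span, 0)
  expect_length(al$b_span, 0)
})

test_that("alphabet mismatches are rejected", {
  mat <- matrix(1, 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(align_local("AG", "AC", scoring_params(matrix = mat)),
               "alphabet mismatch")
})

test_that("E-values follow the Karlin-Altschul form", {
  sc <- scoring_params()
  # S = 0: exponent vanishes
  expect_equal(evalue_of(0, 100, 1000, sc), sc$K * 100 * 1000)
  # linear in database size
  expect_equal(evalue_of(50, 100, 2000, sc), 2 * evalue_of(50, 100, 1000, sc))
  # direct one-line formula evaluation
  expect_equal(evalue_of(100, 250, 250, sc),
               0.134 * 250 * 250 * exp(-0.3176 * 100))
  # monotone decreasing in score
  ev <- evalue_of(seq(0, 200, 10), 100, 1000, sc)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue_of(10, 0, 100, sc), "positive")
})

test_that("database search ranks an exact copy first and respects divergence", {
  set.seed(21)
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 31)
  anchor <- fam$genes[["arabidopsis_g1"]]
  # db: exact copy of the query + unrelated sequences
  unrelated <- replicate(3, {
    f <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = sample.int(1000, 1))
    f$genes[["barley_g1"]]$cds$residues
  })
  db <- species_db("barley", c(
    list(seq_record("copy", "barley", "cds", anchor$cds$residues)),
    lapply(seq_along(unrelated), function(i)
      seq_record(paste0("u", i), "barley", "cds", unrelated[[i]]))))
  hl <- search(anchor$cds, db)
  expect_identical(top_hit(hl)$subject_id, "copy")

  # closer homologue outranks a distant one
  near <- orthoclock:::evolve_seq(anchor$cds$residues, 0.05,
                                  orthoclock:::tn93_Q(), preserve_orf = TRUE)
  far <- orthoclock:::evolve_seq(anchor$cds$residues, 0.40,
                                 orthoclock:::tn93_Q(), preserve_orf = TRUE)
  db2 <- species_db("rice", list(seq_record("near", "rice", "cds", near),
                                 seq_record("far", "rice", "cds", far)))
  hl2 <- search(anchor$cds, db2)
  expect_identical(hl2$subject_id, c("near", "far"))
})

test_that("searching an empty database returns an empty hit list", {
  q <- seq_record("q", "arabidopsis", "cds", "ATGGCTGCTTGCTAA")
  hl <- search(q, species_db("rice"))
  expect_s3_class(hl, "hit_list")
  expect_equal(nrow(hl), 0)
  expect_null(top_hit(hl))
})

test_that("the query is excluded from its home database and order is canonical", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 41)
  g <- fam$genes[["barley_g1"]]
  home <- species_db("barley", list(
    g$cds, seq_record("barley_g2", "barley", "cds",
                      orthoclock:::evolve_seq(g$cds$residues, 0.05,
                                              orthoclock:::tn93_Q(),
                                              preserve_orf = TRUE))))
  hl <- search(g$cds, home)
  expect_false("barley_g1" %in% hl$subject_id)
})

test_that("hit lists are invariant to database record order", {
  fam <- simulate_family(default_species_tree(), seed = 51)
  dbs <- databases_from_family(fam)
  q <- fam$genes[[1]]$cds
  db <- dbs[["barley"]]
  hl1 <- search(q, db)
  perm <- species_db("barley", rev(db$records))
  hl2 <- search(q, perm)
  expect_equal(as.data.frame(hl1), as.data.frame(hl2))
})

test_that("top-hit tie-breaks fall back to the lexicographically smaller id", {
  # two identical subjects force exactly equal scores
  q <- seq_record("q", "a", "cds", "ATGGCTTGCAAGGAGTGGTGA")
  db <- species_db("b", list(
    seq_record("zz", "b", "cds", "ATGGCTTGCAAGGAGTGGTGA"),
    seq_record("aa", "b", "cds", "ATGGCTTGCAAGGAGTGGTGA")))
  hl <- search(q, db, report_threshold = 10)
  expect_identical(top_hit(hl)$subject_id, "aa")
})

test_that("hit tables serialize as 12-column tabular output", {
  fam <- simulate_family(default_species_tree(), seed = 61)
  dbs <- databases_from_family(fam)
  hl <- search(fam$genes[[1]]$cds, dbs[["rice"]])
  path <- tempfile(fileext = ".tsv")
  write_hit_table(hl, path)
  tab <- utils::read.delim(path, header = FALSE)
  expect_equal(ncol(tab), 12)
  expect_equal(nrow(tab), nrow(hl))
})
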