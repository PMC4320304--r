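pipeline_seeds_for_test <- function(fam) {
  sps <- sort(unique(vapply(fam$genes, `[[`, character(1), "species")))
  sp <- if ("arabidopsis" %in% sps) "arabidopsis" else sps[1]
  sort(vapply(Filter(function(g) g$species == sp, fam$genes),
              `[[`, character(1), "id"))
}

# small hand-made hit lists for the tie rule
mk_hl <- function(evalues, bitscores = NULL, ids = NULL) {
  n <- length(evalues)
  ids <- ids %||% sprintf("h%d", seq_len(n))
  bitscores <- bitscores %||% rev(seq_len(n))
  hl <- data.frame(query_id = "q", subject_id = ids, subject_species = "sp",
                   raw_score = rev(seq_len(n)), bitscore = bitscores,
                   evalue = evalues, pident = 90, length = 100, mismatch = 1,
                   gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100)
  structure(hl[order(hl$evalue, -hl$bitscore, hl$subject_id), ],
            class = c("hit_list", "data.frame"), query_id = "q",
            target_species = "sp")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("similar-E-value selection keeps hits within the ratio of the top", {
  expect_equal(similar_evalue_hits(mk_hl(c(1e-50, 1e-49)), 10)$subject_id,
               c("h1", "h2"))
  expect_equal(similar_evalue_hits(mk_hl(c(1e-50, 1e-20)), 10)$subject_id,
               "h1")
  # zero top E-value falls back to a bit-score window
  hl0 <- mk_hl(c(0, 0, 1e-100), bitscores = c(500, 499.5, 300))
  expect_equal(similar_evalue_hits(hl0, 10, bit_delta = 2)$subject_id,
               c("h1", "h2"))
  expect_equal(nrow(similar_evalue_hits(orthoclock:::empty_hit_list("q", "sp"),
                                        10)), 0)
  expect_error(similar_evalue_hits(mk_hl(1e-5), ratio = 0.5), "ratio")
})

test_that("recent duplicates are both returned as E-value ties", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 71)
  base <- fam$genes[["barley_g1"]]$cds$residues
  Q <- orthoclock:::tn93_Q()
  # two subject copies ~2% diverged from each other
  c1 <- orthoclock:::evolve_seq(base, 0.01, Q, preserve_orf = TRUE)
  c2 <- orthoclock:::evolve_seq(base, 0.01, Q, preserve_orf = TRUE)
  db <- species_db("rice", list(seq_record("r1", "rice", "cds", c1),
                                seq_record("r2", "rice", "cds", c2)))
  hl <- search(fam$genes[["arabidopsis_g1"]]$cds, db)
  expect_setequal(similar_evalue_hits(hl, 10)$subject_id, c("r1", "r2"))
})

test_that("reciprocal checks hold for mutually nearest genes and report the partner otherwise", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 81)
  dbs <- databases_from_family(fam)
  rc <- reciprocal_check("arabidopsis_g1", "barley", dbs)
  expect_true(rc$holds)
  expect_identical(rc$via, "barley_g1")

  # duplication in the query species: exactly one copy passes, the other is
  # pointed at the passing partner (the LHY/CCA1 reciprocity pattern)
  Q <- orthoclock:::tn93_Q()
  a1 <- fam$genes[["arabidopsis_g1"]]$cds$residues
  a2 <- orthoclock:::evolve_seq(a1, 0.15, Q, preserve_orf = TRUE)
  dbs2 <- dbs
  dbs2[["arabidopsis"]] <- species_db("arabidopsis", list(
    seq_record("arabidopsis_g1", "arabidopsis", "cds", a1),
    seq_record("arabidopsis_g2", "arabidopsis", "cds", a2)))
  r1 <- reciprocal_check("arabidopsis_g1", "barley", dbs2)
  r2 <- reciprocal_check("arabidopsis_g2", "barley", dbs2)
  expect_true(xor(r1$holds, r2$holds))
  failed <- if (r1$holds) r2 else r1
  expect_identical(failed$partner,
                   if (r1$holds) "arabidopsis_g1" else "arabidopsis_g2")
})

test_that("family expansion is idempotent and only grows the frontier", {
  st <- family_state(c("b", "a"))
  expect_identical(st$frontier, c("a", "b"))
  st$tested_genes <- c("a", "b")
  st$frontier <- character(0)
  st2 <- expand_family(st, "c", c("d", "a"))
  expect_setequal(st2$frontier, c("c", "d"))
  st3 <- expand_family(st2, "c", "d")   # already queued: no-op + counter
  expect_identical(st3$frontier, st2$frontier)
  expect_equal(st3$iteration_count, st2$iteration_count + 1)
})

test_that("single-copy families classify as all-orthologue cliques", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 91)
  res <- classify_orthologues(databases_from_family(fam), "arabidopsis_g1")
  expect_equal(sum(res$calls$relation == "paralogue"), 0)
  o <- res$calls[res$calls$relation == "orthologue", ]
  expect_equal(nrow(o), choose(6, 2))
  expect_false(any(o$ambiguity))
  # symmetry via canonical pair storage
  expect_identical(call_between(res, "barley_g1", "rice_g1"),
                   call_between(res, "rice_g1", "barley_g1"))
})

test_that("a post-speciation duplication yields paralogues plus flagged co-orthologues", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 101)
  Q <- orthoclock:::tn93_Q()
  a1 <- fam$genes[["arabidopsis_g1"]]$cds$residues
  a2 <- orthoclock:::evolve_seq(a1, 0.04, Q, preserve_orf = TRUE)
  dbs <- databases_from_family(fam)
  dbs[["arabidopsis"]] <- species_db("arabidopsis", list(
    seq_record("arabidopsis_g1", "arabidopsis", "cds", a1),
    seq_record("arabidopsis_g2", "arabidopsis", "cds", a2)))
  res <- classify_orthologues(dbs, c("arabidopsis_g1", "arabidopsis_g2"))
  par <- call_between(res, "arabidopsis_g1", "arabidopsis_g2")
  expect_identical(par$relation, "paralogue")
  cb1 <- call_between(res, "arabidopsis_g1", "barley_g1")
  cb2 <- call_between(res, "arabidopsis_g2", "barley_g1")
  expect_identical(cb1$relation, "orthologue")
  expect_identical(cb2$relation, "orthologue")
  expect_true(cb1$ambiguity || cb2$ambiguity)   # one-to-many flagged, never silent
})

test_that("species with empty databases are recorded as absences", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 111, drop_species = "moss")
  res <- classify_orthologues(databases_from_family(fam), "arabidopsis_g1")
  expect_true("moss" %in% res$absences$species)
  o <- res$calls[res$calls$relation == "orthologue", ]
  expect_equal(nrow(o), choose(5, 2))
})

test_that("classification is invariant to seed order", {
  fam <- simulate_family(default_species_tree(), seed = 121)
  dbs <- databases_from_family(fam)
  seeds <- sort(vapply(Filter(function(g) g$species == "arabidopsis",
                              fam$genes), `[[`, character(1), "id"))
  if (length(seeds) >= 1) {
    r1 <- classify_orthologues(dbs, seeds)
    r2 <- classify_orthologues(dbs, rev(seeds))
    expect_equal(r1$calls, r2$calls)
    expect_equal(r1$graph, r2$graph)
  }
})

test_that("termination stays within the gene x species bound", {
  fam <- simulate_family(default_species_tree(), seed = 131)
  dbs <- databases_from_family(fam)
  res <- classify_orthologues(dbs, pipeline_seeds_for_test(fam))
  bound <- length(res$state$tested_genes) * (length(dbs) + 1)
  expect_lte(res$state$iteration_count, bound * 2)
  expect_length(res$state$frontier, 0)
})

test_that("orthology calls and the reciprocity graph export as TSV", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 141)
  res <- classify_orthologues(databases_from_family(fam), "arabidopsis_g1")
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_orthology_calls(res, p1)
  write_reciprocity_graph(res, p2)
  expect_equal(nrow(utils::read.delim(p1)), nrow(res$calls))
  expect_equal(nrow(utils::read.delim(p2)), nrow(res$graph))
})
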