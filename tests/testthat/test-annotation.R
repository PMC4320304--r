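mk_gene <- function(seed = 1, n_introns = 2) {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         n_introns = n_introns, seed = seed)
  fam$genes[["barley_g1"]]
}

test_that("gene models enforce sorted exons, minimum introns and CDS containment", {
  expect_error(gene_model("g", "gen", "+",
                          data.frame(start = c(1, 5), end = c(10, 20))),
               "overlap")
  expect_error(gene_model("g", "gen", "+",
                          data.frame(start = c(1, 13), end = c(10, 20))),
               "intron shorter")
  expect_error(gene_model("g", "gen", "+",
                          data.frame(start = 10, end = 20),
                          cds = data.frame(start = 5, end = 15)),
               "outside exons")
})

test_that("simulator-built models pass validation; engineered defects are localized", {
  g <- mk_gene(seed = 201)
  expect_true(validate_model(g$model, g$genomic)$passed)

  # GT -> GC at the first intron donor
  res <- g$genomic$residues
  d <- g$model$exons$end[1] + 1L
  broken <- paste0(substr(res, 1, d), "C", substr(res, d + 2, nchar(res)))
  v <- validate_model(g$model, seq_record(g$id, g$species, "genomic", broken))
  expect_false(v$passed)
  expect_true(any(v$violations$rule == 2 & v$violations$location == "intron 1"))

  # exon boundary shifted +1: frameshift, verified independently by translation
  ex <- g$model$exons
  ex$start[2] <- ex$start[2] + 1L
  shifted <- gene_model(g$id, g$id, "+", ex)
  spliced <- spliced_cds(shifted, g$genomic)
  aa <- suppressWarnings(translate_cds(substr(spliced, 1,
                                              (nchar(spliced) %/% 3) * 3)))
  v2 <- validate_model(shifted, g$genomic)
  expect_false(v2$passed)
  if (grepl("\\*", aa)) expect_true(any(v2$violations$rule == 3))

  expect_error(
    validate_model(gene_model("g", "gen", "+",
                              data.frame(start = 1, end = 10^6)), g$genomic),
    "outside the genomic")
})

test_that("re-annotation against the true CDS recovers the generator's structure", {
  for (s in c(211, 212, 213, 214, 215)) {
    fam <- simulate_family(default_species_tree(), seed = s)
    for (g in fam$genes[seq_len(min(3, length(fam$genes)))]) {
      m <- reannotate(g$genomic, list(g$cds))
      expect_identical(spliced_cds(m, g$genomic), g$cds$residues)
      expect_equal(m$exons, g$model$exons)
      expect_true(validate_model(m, g$genomic)$passed)
      expect_false(m$partial)
    }
  }
})

test_that("an intronless gene with exact CDS evidence yields a single-exon model", {
  cds <- "ATGGCTTGCAAGGAGTGGTCTTTCGGTAGCTAA"
  m <- reannotate(seq_record("g", "sp", "genomic", cds),
                  list(seq_record("c", "sp", "cds", cds, complete = TRUE)))
  expect_equal(nrow(m$exons), 1)
  expect_equal(m$exons$end, nchar(cds))
  expect_false(m$partial)
})

test_that("re-annotation works on the reverse strand", {
  g <- mk_gene(seed = 221)
  rc <- seq_record(g$id, g$species, "genomic", revcomp(g$genomic$residues))
  m <- reannotate(rc, list(g$cds))
  expect_identical(m$strand, "-")
  expect_identical(spliced_cds(m, rc), g$cds$residues)
})

test_that("evidence missing an exon gives a partial-flagged model with correct remaining exons", {
  g <- mk_gene(seed = 231, n_introns = 2)
  ex <- g$model$exons
  lens <- ex$end - ex$start + 1
  # homologue evidence lacking the middle exon
  cds <- g$cds$residues
  partial_ev <- paste0(substr(cds, 1, lens[1]),
                       substr(cds, lens[1] + lens[2] + 1, nchar(cds)))
  m <- reannotate(g$genomic, list(seq_record("ev", "sp", "cds", partial_ev,
                                             complete = FALSE)))
  expect_true(m$partial)
  expect_identical(spliced_cds(m, g$genomic), partial_ev)
  expect_true(all(c(ex$start[1], ex$end[3]) %in% c(m$exons$start, m$exons$end)))
})

test_that("re-annotation failure is explicit when no model can satisfy constraints", {
  expect_warning(
    m <- reannotate(seq_record("g", "sp", "genomic", "CCCCCCCCCCCC"),
                    list(seq_record("c", "sp", "cds", "AAAGGGTTTAAA"))),
    "no constraint-satisfying")
  expect_null(m)
})

test_that("structure comparison: identity, lineage-specific gain, length ratios", {
  g <- mk_gene(seed = 241)
  # a model against itself: no differences
  d0 <- compare_structures(g$model, g$model, g$genomic, g$genomic)
  expect_equal(sum(d0$type != "intron_conserved"), 0)

  # same CDS, one additional intron in lineage b
  cds <- g$cds$residues
  ia <- insert_introns(cds, 1, positions = 100L, seed = 7, gene_id = "a")
  ib <- insert_introns(cds, 2, positions = c(100L, 130L), seed = 8,
                       gene_id = "b")
  diff <- compare_structures(
    ia$model, ib$model,
    seq_record("a", "sp", "genomic", ia$genomic),
    seq_record("b", "sp", "genomic", ib$genomic))
  expect_equal(sum(diff$type == "intron_gain_b"), 1)
  expect_equal(sum(diff$type == "intron_gain_a"), 0)
  expect_equal(sum(diff$type == "intron_conserved"), 1)

  # equal structure, 5x intron length: ratio records only
  i1 <- insert_introns(cds, 1, length_range = c(60, 60), positions = 150L,
                       seed = 9, gene_id = "s")
  i2 <- insert_introns(cds, 1, length_range = c(300, 300), positions = 150L,
                       seed = 10, gene_id = "l")
  d2 <- compare_structures(
    i1$model, i2$model,
    seq_record("s", "sp", "genomic", i1$genomic),
    seq_record("l", "sp", "genomic", i2$genomic))
  expect_equal(sum(grepl("gain", d2$type)), 0)
  expect_equal(d2$ratio[d2$type == "intron_conserved"], 5)
})

test_that("gene models round-trip through GFF3", {
  g <- mk_gene(seed = 251)
  path <- tempfile(fileext = ".gff3")
  write_gene_models(list(g$model), path)
  back <- read_gene_models(path)
  expect_equal(back[[g$model$gene_id]]$exons, g$model$exons)
  expect_identical(back[[g$model$gene_id]]$strand, g$model$strand)
})
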