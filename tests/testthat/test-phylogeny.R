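jc_pair <- function(t, L = 6000, seed = 5) {
  restore <- orthoclock:::push_seed(seed)
  on.exit(restore())
  root <- random_dna(L)
  child <- orthoclock:::evolve_seq(root, t, orthoclock:::tn93_Q())
  structure(c(a = root, b = child), class = "codon_alignment")
}

test_that("identical rows give zero distances", {
  ca <- structure(c(a = "ATGGCTTGC", b = "ATGGCTTGC", c = "ATGGCTTGC"),
                  class = "codon_alignment")
  dm <- mcl_distances(ca)
  expect_true(all(dm == 0))
  expect_false(any(attr(dm, "saturated")))
})

test_that("distances match the Jukes-Cantor closed form on JC data", {
  ca <- jc_pair(0.15)
  p <- mean(strsplit(ca[[1]], "")[[1]] != strsplit(ca[[2]], "")[[1]])
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  dm <- mcl_distances(ca)
  expect_lt(abs(dm[1, 2] - jc) / jc, 0.02)
})

test_that("the two-row case equals an independent TN93 estimate", {
  restore <- orthoclock:::push_seed(9)
  on.exit(restore())
  root <- random_dna(3000)
  child <- orthoclock:::evolve_seq(root, 0.2,
                                   orthoclock:::tn93_Q(kappa1 = 3, kappa2 = 2))
  ca <- structure(c(a = root, b = child), class = "codon_alignment")
  dm <- mcl_distances(ca)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(c(root, child), "")))
  ref <- as.numeric(ape::dist.dna(bin, model = "TN93"))
  expect_lt(abs(dm[1, 2] - ref) / ref, 1e-3)
})

test_that("gapped input is refused before distance estimation", {
  ca <- structure(c(a = "ATG---", b = "ATGGCT"), class = "codon_alignment")
  expect_error(mcl_distances(ca), "mask_incomplete_columns")
})

test_that("distances increase monotonically with simulated divergence", {
  ds <- vapply(seq(0.05, 0.5, by = 0.05), function(t)
    mcl_distances(jc_pair(t, L = 3000, seed = 13))[1, 2], numeric(1))
  expect_identical(order(ds), seq_along(ds))   # rank correlation 1
})

test_that("saturated pairs are flagged and refused by tree building", {
  ca <- structure(c(a = strrep("AC", 30), b = strrep("CA", 30),
                    c = strrep("AC", 30)), class = "codon_alignment")
  dm <- mcl_distances(ca)
  expect_true(any(attr(dm, "saturated")))
  expect_error(nj_tree(dm), "saturated")
})

test_that("NJ recovers the additive four-taxon tree exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(ape::dist.topo(tr, ref), 0, ignore_attr = TRUE)
  # branch lengths recovered from the additive metric
  m <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(m, d, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 0)   # (dAB + dAC - dBC)/2
  expect_equal(unname(bl["B"]), 2)
  expect_equal(unname(bl["C"]), 3)
})

test_that("NJ agrees with an independent implementation on random near-additive matrices", {
  set.seed(17)
  for (k in 1:15) {
    n <- sample(4:8, 1)
    rt <- ape::rtree(n)
    rt$edge.length <- stats::runif(nrow(rt$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(rt)
    ord <- sort(rownames(dm))
    dm <- dm[ord, ord]
    noise <- matrix(stats::runif(n * n, 0, 0.02), n, n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dmn <- dm + noise
    t1 <- nj_tree(dmn)
    t2 <- ape::nj(stats::as.dist(dmn))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative branch estimates are clamped with a warning", {
  # three-point formulas give lB = (2 + 3 - 10)/2 < 0
  d <- matrix(c(0, 2, 10, 2, 0, 3, 10, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_warning(tr <- nj_tree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("a single bootstrap replicate yields all-or-nothing supports", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 401)
  pa <- align_proteins(lapply(fam$genes, `[[`, "protein"))
  ca <- mask_incomplete_columns(backtranslate(pa, lapply(fam$genes, `[[`, "cds")))
  bt <- bootstrap_tree(ca, replicates = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("an unambiguous split receives 100% support", {
  # two divergent clades, zero within-clade variation
  a <- strrep("ATGGCTTGCAAG", 30)
  b <- strrep("CTGGCTTGCTAG", 30)   # two fixed differences per repeat
  ca <- structure(c(x1 = a, x2 = a, y1 = b, y2 = b),
                  class = "codon_alignment")
  bt <- bootstrap_tree(ca, replicates = 50, seed = 5)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("bootstrap supports are equivariant under leaf relabelling", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 411)
  pa <- align_proteins(lapply(fam$genes, `[[`, "protein"))
  ca <- mask_incomplete_columns(backtranslate(pa, lapply(fam$genes, `[[`, "cds")))
  bt1 <- bootstrap_tree(ca, replicates = 60, seed = 11)
  swap <- function(x) chartr("1", "9", x)   # relabel *_g1 -> *_g9
  ca2 <- structure(setNames(unname(ca), swap(names(ca))),
                   class = "codon_alignment")
  bt2 <- bootstrap_tree(ca2, replicates = 60, seed = 11)
  key <- function(tr) sort(tr$node.label[tr$node.label != ""])
  expect_identical(key(bt1), key(bt2))
})

test_that("rooting places the outgroup correctly and preserves supports", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)80:1);")
  r1 <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(r1))
  expect_true("A" %in% r1$tip.label)
  r2 <- root_with_outgroup(tr, c("C", "D"))
  expect_true(ape::is.monophyletic(r2, c("C", "D")))
  # the single AB|CD split keeps its support label through rerooting
  expect_true(any(c("80", "90") %in% r2$node.label))
  # non-monophyletic outgroup: error unless the manual override is set
  expect_error(root_with_outgroup(tr, c("A", "C")), "not monophyletic")
  r3 <- root_with_outgroup(tr, c("A", "C"), root_edge_override = TRUE)
  expect_true(ape::is.rooted(r3))
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")
})

test_that("pseudogene filtering drops flagged records and reports counts", {
  fam <- simulate_family(default_species_tree(), dup_rate = 0, loss_rate = 0,
                         seed = 421)
  genes <- fam$genes
  expect_identical(exclude_pseudogenes(lapply(genes, `[[`, "cds")),
                   lapply(genes, `[[`, "cds"))
  ps <- make_pseudogene(genes[[1]])
  recs <- c(list(ps$cds), lapply(genes[-1], `[[`, "cds"))
  expect_message(kept <- exclude_pseudogenes(recs), "excluding 1")
  expect_length(kept, length(recs) - 1)
  expect_false(ps$id %in% vapply(kept, `[[`, character(1), "id"))
  all_flagged <- lapply(recs, function(r) { r$pseudogene <- TRUE; r })
  expect_warning(expect_message(out <- exclude_pseudogenes(all_flagged)),
                 "nothing left")
  expect_length(out, 0)
})

test_that("distance matrices serialize in square PHYLIP format", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- tempfile(fileext = ".dist")
  write_phylip_dist(d, p)
  lines <- readLines(p)
  expect_identical(lines[1], " 3")
  expect_match(lines[2], "^A +0.000000 2.000000 3.000000$")
})

test_that("thresholded Newick rendering blanks weak supports but keeps them in the object", {
  tr <- ape::read.tree(text = "((A:1,B:1)42:1,(C:1,D:1)88:1);")
  attr(tr, "support_threshold") <- 50
  path <- tempfile(fileext = ".nwk")
  write_support_newick(tr, path)
  txt <- readLines(path)
  expect_false(grepl("42", txt))
  expect_true(grepl("88", txt))
  expect_true("42" %in% tr$node.label)
})
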