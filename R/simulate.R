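#' Species tree specification for family simulation
#'
#' @param newick Rooted Newick string with branch lengths in substitutions
#'   per site and unique species names.
#' @return A `species_tree_spec` (list with `tree` (phylo) and `newick`).
#' @export
species_tree_spec <- function(newick) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse species tree Newick")
  if (anyDuplicated(tree$tip.label)) stop("species names must be unique")
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  structure(list(tree = tree, newick = newick), class = "species_tree_spec")
}

#' Default six-species plant tree
#'
#' Three monocots (barley, wheat, rice), two dicots (arabidopsis, tomato) and
#' moss as the basal outgroup. Branch lengths are in substitutions per site
#' and keep every pairwise path at or below ~0.5 subst/site, the regime in
#' which protein-space reciprocal-best-hit classification is reliable.
#'
#' @return A [species_tree_spec()].
#' @export
default_species_tree <- function() {
  species_tree_spec(paste0(
    "(((arabidopsis:0.10,tomato:0.10):0.08,",
    "((barley:0.06,wheat:0.06):0.04,rice:0.10):0.08):0.08,moss:0.22);"))
}

# ---- TN93 substitution machinery ------------------------------------------

NT <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

tn93_Q <- function(kappa1 = 1, kappa2 = 1, base_freq = rep(0.25, 4)) {
  stopifnot(length(base_freq) == 4, abs(sum(base_freq) - 1) < 1e-8,
            kappa1 > 0, kappa2 > 0)
  pi <- stats::setNames(base_freq, NT)
  Q <- matrix(0, 4, 4, dimnames = list(NT, NT))
  for (i in NT) for (j in NT) {
    if (i == j) next
    rate <- pi[j]
    if ((i == "A" && j == "G") || (i == "G" && j == "A")) rate <- rate * kappa1
    if ((i == "C" && j == "T") || (i == "T" && j == "C")) rate <- rate * kappa2
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))   # scale: 1 expected substitution per unit time
  Q / mu
}

tn93_P <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Evolve a nucleotide string for time t (subst/site) under TN93. With
# preserve_orf, the start codon is pinned to ATG, the terminal stop codon is
# retained, and internal codons that mutate into stops are redrawn from the
# parent codon (rejection sampling), so every simulated CDS stays a clean ORF.
evolve_seq <- function(seq, t, Q, preserve_orf = FALSE) {
  if (t <= 0) return(seq)
  P <- tn93_P(Q, t)
  x <- strsplit(seq, "")[[1L]]
  draw <- function(parent_chars) {
    probs <- P[parent_chars, , drop = FALSE]
    cp <- t(apply(probs, 1L, cumsum))
    u <- stats::runif(length(parent_chars))
    NT[max.col(cp >= u, ties.method = "first")]
  }
  y <- draw(x)
  if (preserve_orf) {
    L <- length(x)
    stopifnot(L %% 3L == 0L)
    y[1:3] <- c("A", "T", "G")
    ncod <- L %/% 3L
    codon_str <- function(v, k) paste(v[(3 * k - 2):(3 * k)], collapse = "")
    for (k in 2:(ncod - 1L)) {
      tries <- 0L
      while (codon_str(y, k) %in% STOPS && tries < 50L) {
        y[(3 * k - 2):(3 * k)] <- draw(x[(3 * k - 2):(3 * k)])
        tries <- tries + 1L
      }
      if (codon_str(y, k) %in% STOPS)
        y[(3 * k - 2):(3 * k)] <- x[(3 * k - 2):(3 * k)]
    }
    if (!codon_str(y, ncod) %in% STOPS)
      y[(3 * ncod - 2):(3 * ncod)] <- x[(3 * ncod - 2):(3 * ncod)]
  }
  paste(y, collapse = "")
}

random_cds <- function(n_codons, base_freq = rep(0.25, 4)) {
  stopifnot(n_codons >= 3)
  cod <- character(n_codons)
  cod[1L] <- "ATG"
  for (k in 2:(n_codons - 1L)) {
    repeat {
      c3 <- paste(sample(NT, 3L, replace = TRUE, prob = base_freq),
                  collapse = "")
      if (!c3 %in% STOPS) break
    }
    cod[k] <- c3
  }
  cod[n_codons] <- sample(STOPS, 1L)
  paste(cod, collapse = "")
}

# ---- gene-family birth-death simulation -----------------------------------

#' Simulate a gene family with known history over a species tree
#'
#' Duplication and loss events are drawn as Poisson processes along the
#' species-tree branches (rates per unit branch length); sequences evolve
#' along the resulting gene tree under TN93 (Jukes--Cantor by default) with
#' ORF-preserving rejection of stop codons; genomic sequences carry GT..AG
#' introns at family-wide conserved positions (per-gene intron lengths and
#' interiors differ). The returned object carries the full ground truth:
#' gene tree with speciation/duplication node labels, event list, per-pair
#' orthology relation (orthologue iff the pair's last common event is a
#' speciation) and true gene models.
#'
#' @param st A [species_tree_spec()].
#' @param dup_rate,loss_rate Event rates per unit branch length (>= 0).
#' @param root_cds_length Ancestral CDS length in nt (divisible by 3;
#'   includes the ATG and terminal stop).
#' @param seed RNG seed; identical inputs and seed give byte-identical
#'   output.
#' @param kappa1,kappa2,base_freq TN93 parameters (defaults give JC).
#' @param n_introns Introns inserted into every gene's genomic sequence.
#' @param intron_length_range Intron length range (nt, uniform).
#' @param drop_species Species whose family members are removed after
#'   simulation (constructed lineage-specific loss).
#' @return A `family_sim`: list with `genes` (each gene a list of id,
#'   species, cds/protein/genomic [seq_record()]s, `model` truth and
#'   `pseudogene` flag), `gene_tree` (phylo, node labels S/D), `events`,
#'   `truth` (pairwise relation table), `species` and `params`. A family
#'   extinct everywhere yields `genes = list()` and `extinct = TRUE`.
#' @export
simulate_family <- function(st, dup_rate = 0.3, loss_rate = 0.1,
                            root_cds_length = 300, seed = 1,
                            kappa1 = 1, kappa2 = 1,
                            base_freq = rep(0.25, 4),
                            n_introns = 2, intron_length_range = c(60, 200),
                            drop_species = character(0)) {
  stopifnot(inherits(st, "species_tree_spec"), dup_rate >= 0, loss_rate >= 0,
            root_cds_length %% 3L == 0L, root_cds_length >= 30L)
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  Q <- tn93_Q(kappa1, kappa2, base_freq)
  tree <- st$tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids_of <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
  elen <- function(node) tree$edge.length[tree$edge[, 2L] == node]

  events <- list()
  note_event <- function(type, species_branch, time)
    events[[length(events) + 1L]] <<- data.frame(
      type = type, branch = species_branch, time = time)

  rexp_or_inf <- function(rate) if (rate > 0) stats::rexp(1L, rate) else Inf

  # lineage arriving at `node` (a speciation point or tip)
  sim_node <- function(node) {
    if (node <= ntip) {
      return(list(type = "tip", species = tree$tip.label[node],
                  blen = 0, children = NULL))
    }
    ch <- lapply(kids_of(node), function(k) sim_branch(k, elen(k), 0))
    ch <- ch[!vapply(ch, is.null, logical(1))]
    if (!length(ch)) return(NULL)
    if (length(ch) == 1L) {
      # pass-through: absorb this node, keep accumulated branch below
      return(ch[[1L]])
    }
    list(type = "spec", species = NA_character_, blen = 0, children = ch)
  }

  # lineage travelling towards species-tree node `to`, `remaining` length
  # left on the branch; `consumed` accumulates into the gene-tree edge
  sim_branch <- function(to, remaining, consumed) {
    branch_name <- if (to <= ntip) tree$tip.label[to] else paste0("node", to)
    t_dup <- rexp_or_inf(dup_rate)
    t_loss <- rexp_or_inf(loss_rate)
    t_next <- min(t_dup, t_loss)
    if (t_next >= remaining) {
      res <- sim_node(to)
      if (is.null(res)) return(NULL)
      res$blen <- res$blen + remaining + consumed
      return(res)
    }
    if (t_loss <= t_dup) {
      note_event("loss", branch_name, t_loss)
      return(NULL)
    }
    note_event("duplication", branch_name, t_dup)
    left <- sim_branch(to, remaining - t_dup, 0)
    right <- sim_branch(to, remaining - t_dup, 0)
    ok <- !c(is.null(left), is.null(right))
    if (!any(ok)) return(NULL)
    if (sum(ok) == 1L) {
      res <- if (ok[1L]) left else right
      res$blen <- res$blen + t_dup + consumed
      return(res)
    }
    list(type = "dup", species = NA_character_, blen = consumed + t_dup,
         children = list(left, right))
  }

  gt <- sim_node(root)

  if (is.null(gt)) {
    return(structure(list(genes = list(), gene_tree = NULL,
                          events = bind_events(events), truth = empty_truth(),
                          species = tree$tip.label, extinct = TRUE,
                          params = list(dup_rate = dup_rate,
                                        loss_rate = loss_rate, seed = seed)),
                     class = "family_sim"))
  }

  # assign ids (per-species counters, traversal order) and evolve sequences
  counters <- stats::setNames(integer(length(tree$tip.label)), tree$tip.label)
  root_cds <- random_cds(root_cds_length %/% 3L, base_freq)
  genes <- list()
  decorate <- function(node, parent_cds) {
    cds <- evolve_seq(parent_cds, node$blen, Q, preserve_orf = TRUE)
    if (node$type == "tip") {
      counters[node$species] <<- counters[node$species] + 1L
      id <- sprintf("%s_g%d", node$species, counters[node$species])
      genes[[id]] <<- list(id = id, species = node$species, cds = cds)
      node$gene_id <- id
    } else {
      node$children <- lapply(node$children, decorate, parent_cds = cds)
    }
    node
  }
  gt <- decorate(gt, root_cds)

  # conserved intron positions, drawn once from the ancestral CDS
  L <- root_cds_length
  intron_after <- if (n_introns > 0)
    sort(sample.int(L - 1L, n_introns)) else integer(0)

  genes <- lapply(genes, function(g) {
    ii <- insert_introns(g$cds, n_introns, intron_length_range, seed = NULL,
                         positions = intron_after, gene_id = g$id,
                         genomic_id = g$id)
    list(id = g$id, species = g$species,
         cds = seq_record(g$id, g$species, "cds", g$cds, complete = TRUE),
         protein = seq_record(g$id, g$species, "protein",
                              translate_cds(g$cds)),
         genomic = seq_record(g$id, g$species, "genomic", ii$genomic),
         model = ii$model, pseudogene = FALSE)
  })

  if (length(drop_species)) {
    keep <- vapply(genes, function(g) !g$species %in% drop_species, logical(1))
    genes <- genes[keep]
    note_event("constructed_loss", paste(drop_species, collapse = ","), NA)
  }

  truth <- truth_from_gene_tree(gt, names(genes))
  phylo_gt <- gene_tree_phylo(gt)

  structure(list(genes = genes, gene_tree = phylo_gt,
                 events = bind_events(events), truth = truth,
                 species = tree$tip.label, extinct = length(genes) == 0L,
                 params = list(dup_rate = dup_rate, loss_rate = loss_rate,
                               root_cds_length = root_cds_length, seed = seed,
                               kappa1 = kappa1, kappa2 = kappa2,
                               base_freq = base_freq,
                               n_introns = n_introns)),
            class = "family_sim")
}

bind_events <- function(events) {
  if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), branch = character(0), time = numeric(0))
}

empty_truth <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             species_a = character(0), species_b = character(0),
             relation = character(0), stringsAsFactors = FALSE)
}

# all surviving-tip pairs labelled by the event at their last common node
truth_from_gene_tree <- function(gt, surviving) {
  rows <- list()
  tips_below <- function(node) {
    if (node$type == "tip") {
      return(data.frame(gene = node$gene_id, species = node$species,
                        stringsAsFactors = FALSE))
    }
    sets <- lapply(node$children, tips_below)
    rel <- if (node$type == "spec") "orthologue" else "paralogue"
    for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
      for (a in seq_len(nrow(sets[[j]]))) for (b in seq_len(nrow(sets[[i]]))) {
        ga <- sets[[j]][a, ]; gb <- sets[[i]][b, ]
        k <- order(c(ga$gene, gb$gene))
        two <- rbind(ga, gb)[k, ]
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_a = two$gene[1L], gene_b = two$gene[2L],
          species_a = two$species[1L], species_b = two$species[2L],
          relation = rel, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, sets)
  }
  tips_below(gt)
  out <- if (length(rows)) do.call(rbind, rows) else empty_truth()
  out <- out[out$gene_a %in% surviving & out$gene_b %in% surviving, ,
             drop = FALSE]
  out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
}

gene_tree_phylo <- function(gt) {
  nwk <- function(node) {
    if (node$type == "tip")
      return(sprintf("%s:%.8f", node$gene_id, node$blen))
    lab <- if (node$type == "spec") "S" else "D"
    sprintf("(%s)%s:%.8f",
            paste(vapply(node$children, nwk, character(1)), collapse = ","),
            lab, node$blen)
  }
  if (gt$type == "tip")
    return(NULL)  # single surviving gene: no tree
  ape::read.tree(text = paste0(nwk(gt), ";"))
}

#' Insert GT..AG introns into a coding sequence
#'
#' Introns (beginning GT, ending AG, interiors random) are inserted after the
#' given CDS positions (uniformly drawn when not supplied; any phase 0/1/2).
#' Splicing the genomic sequence by the returned model reproduces the CDS
#' exactly.
#'
#' @param cds CDS string.
#' @param n_introns Number of introns (>= 0).
#' @param length_range Intron length range (min >= 6 nt).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param positions Optional CDS positions after which introns fall
#'   (1 .. nchar(cds)-1, distinct, sorted).
#' @param gene_id,genomic_id Identifiers for the truth [gene_model()].
#' @return List with `genomic` (string), `model` ([gene_model()]) and
#'   `positions`.
#' @export
insert_introns <- function(cds, n_introns, length_range = c(60, 200),
                           seed = NULL, positions = NULL,
                           gene_id = "gene", genomic_id = "genomic") {
  stopifnot(n_introns >= 0, length_range[1L] >= 6)
  if (!is.null(seed)) {
    restore <- push_seed(seed)
    on.exit(restore(), add = TRUE)
  }
  L <- nchar(cds)
  if (is.null(positions)) {
    positions <- if (n_introns > 0) sort(sample.int(L - 1L, n_introns))
                 else integer(0)
  }
  stopifnot(length(positions) == n_introns, !is.unsorted(positions),
            !anyDuplicated(positions))
  if (n_introns == 0L) {
    return(list(genomic = cds,
                model = gene_model(gene_id, genomic_id, "+",
                                   data.frame(start = 1L, end = L)),
                positions = integer(0)))
  }
  ilens <- length_range[1L] - 1L +
    sample.int(length_range[2L] - length_range[1L] + 1L, n_introns,
               replace = TRUE)
  introns <- vapply(ilens, function(l)
    paste0("GT", paste(sample(NT, l - 4L, replace = TRUE), collapse = ""), "AG"),
    character(1))
  bounds <- c(0L, positions, L)
  pieces <- substring(cds, utils::head(bounds, -1L) + 1L, bounds[-1L])
  genomic <- pieces[1L]
  exon_start <- 1L
  exons <- data.frame(start = 1L, end = nchar(pieces[1L]))
  for (k in seq_len(n_introns)) {
    genomic <- paste0(genomic, introns[k], pieces[k + 1L])
    s <- nchar(genomic) - nchar(pieces[k + 1L]) + 1L
    exons <- rbind(exons, data.frame(start = s, end = nchar(genomic)))
  }
  list(genomic = genomic,
       model = gene_model(gene_id, genomic_id, "+", exons),
       positions = positions)
}

#' Truncate a simulated gene into a pseudogene
#'
#' Halves the CDS (codon-aligned) and sets the pseudogene flag -- the pattern
#' of a half-length predicted protein that is excluded from tree estimation.
#'
#' @param g A gene entry from [simulate_family()]`$genes`.
#' @param seed Unused placeholder for interface symmetry (truncation is
#'   deterministic).
#' @return The modified gene entry (`pseudogene = TRUE`).
#' @export
make_pseudogene <- function(g, seed = NULL) {
  ncod <- nchar(g$cds$residues) %/% 3L
  keep <- (ncod %/% 2L) * 3L
  cds <- substr(g$cds$residues, 1L, keep)
  g$cds <- seq_record(g$id, g$species, "cds", cds, complete = NA,
                      pseudogene = TRUE)
  g$protein <- seq_record(g$id, g$species, "protein",
                          suppressWarnings(translate_cds(cds)),
                          pseudogene = TRUE)
  g$genomic <- seq_record(g$id, g$species, "genomic", cds, pseudogene = TRUE)
  g$model <- gene_model(g$id, g$id, "+", data.frame(start = 1L, end = keep),
                        complete = FALSE)
  g$pseudogene <- TRUE
  g
}

#' Build per-species databases from a simulated family
#'
#' Every species of the species tree gets a database (possibly empty, which
#' downstream classification records as "no family member detected").
#'
#' @param fam A `family_sim`.
#' @param moltype Which sequence to load (`"cds"` or `"protein"`).
#' @return Named list of [species_db()] objects.
#' @export
databases_from_family <- function(fam, moltype = c("cds", "protein")) {
  moltype <- match.arg(moltype)
  out <- lapply(fam$species, function(sp) {
    recs <- lapply(Filter(function(g) g$species == sp, fam$genes),
                   `[[`, moltype)
    species_db(sp, unname(recs))
  })
  stats::setNames(out, fam$species)
}

#' Write a simulated family to disk
#'
#' FASTA (CDS, protein, genomic), GFF3 truth models, TSV truth/event tables,
#' Newick trees and a JSON manifest with file checksums, all under one
#' directory.
#'
#' @param fam A `family_sim`.
#' @param dir Output directory (created).
#' @return The manifest as a list, invisibly.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  if (length(fam$genes)) {
    for (mt in c("cds", "protein", "genomic"))
      write_fasta(lapply(fam$genes, `[[`, mt),
                  put(file.path(dir, paste0("family_", mt, ".fasta"))))
    write_gene_models(lapply(fam$genes, `[[`, "model"),
                      put(file.path(dir, "truth_models.gff3")))
  }
  utils::write.table(fam$truth, put(file.path(dir, "truth_orthology.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fam$events, put(file.path(dir, "events.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fam$gene_tree))
    ape::write.tree(fam$gene_tree, put(file.path(dir, "gene_tree.nwk")))
  manifest <- list(
    n_genes = length(fam$genes),
    species = fam$species,
    extinct = isTRUE(fam$extinct),
    params = fam$params,
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("<family_sim> %d genes in %d/%d species; %d event(s)%s\n",
              length(x$genes),
              length(unique(vapply(x$genes, `[[`, character(1), "species"))),
              length(x$species), nrow(x$events),
              if (isTRUE(x$extinct)) " [extinct]" else ""))
  invisible(x)
}
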