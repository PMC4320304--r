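#' Hits with an E-value similar to the top hit
#'
#' Candidate paralogues are hits whose E-value is within `ratio` (default one
#' order of magnitude) of the best hit. When the top E-value underflows to
#' zero the criterion falls back to bit scores within `bit_delta` bits of the
#' top. The top hit itself is always included.
#'
#' @param hl A `hit_list` from [search()].
#' @param ratio E-value ratio defining "similar" (>= 1).
#' @param bit_delta Bit-score window used when the top E-value is 0.
#' @return The qualifying rows of `hl` (possibly zero rows).
#' @export
similar_evalue_hits <- function(hl, ratio = 10, bit_delta = 2) {
  stopifnot(ratio >= 1)
  if (!nrow(hl)) return(hl)
  top <- hl[1L, ]
  keep <- if (top$evalue == 0) hl$bitscore >= top$bitscore - bit_delta
          else hl$evalue <= ratio * top$evalue
  keep[1L] <- TRUE
  hl[keep, , drop = FALSE]
}

#' Reciprocal-best-hit check between a gene and a target species
#'
#' The check holds when the top hit of `gene_id` in `species_b` itself has
#' `gene_id` as its top hit back in the gene's home species. When the
#' reciprocal search lands on a different home-species gene, that gene is
#' returned as `partner` so the family expansion can pick it up.
#'
#' @param gene_id Query gene id.
#' @param species_b Target species name.
#' @param databases Named list of [species_db()] (names are species).
#' @param scoring,report_threshold Passed to [search()].
#' @return List with `holds` (logical), `via` (top hit in `species_b`, or NA)
#'   and `partner` (the home-species gene the reciprocal search identified,
#'   NA when there was no hit).
#' @export
reciprocal_check <- function(gene_id, species_b, databases,
                             scoring = scoring_params(),
                             report_threshold = 1e-5) {
  home <- find_species(gene_id, databases)
  q <- db_get(databases[[home]], gene_id)
  fwd <- top_hit(search(q, databases[[species_b]], scoring, report_threshold))
  if (is.null(fwd))
    return(list(holds = FALSE, via = NA_character_, partner = NA_character_))
  back <- top_hit(search(db_get(databases[[species_b]], fwd$subject_id),
                         databases[[home]], scoring, report_threshold))
  if (is.null(back))
    return(list(holds = FALSE, via = fwd$subject_id, partner = NA_character_))
  list(holds = identical(back$subject_id, gene_id), via = fwd$subject_id,
       partner = back$subject_id)
}

find_species <- function(gene_id, databases) {
  for (sp in names(databases))
    if (gene_id %in% names(databases[[sp]]$records)) return(sp)
  stop("gene '", gene_id, "' not found in any database")
}

#' Create a fresh family-expansion state
#'
#' @param seed_genes Character vector of seed gene ids.
#' @return A `family_state` list with `frontier`, `tested` (query/species
#'   pairs already searched) and `iteration_count`.
#' @export
family_state <- function(seed_genes) {
  structure(list(seed_genes = sort(unique(seed_genes)),
                 frontier = sort(unique(seed_genes)),
                 tested = character(0), tested_genes = character(0),
                 iteration_count = 0L),
            class = "family_state")
}

#' Add a gene and its family members to the expansion frontier
#'
#' Fired when a reciprocal check lands on a different gene than the query: the
#' newly identified gene and all its family members (by default, its
#' similar-E-value clique in the home species) enter the frontier unless
#' already tested. Re-adding tested genes is a no-op apart from the iteration
#' counter, so expansion terminates.
#'
#' @param state A [family_state()].
#' @param trigger_gene Gene id returned by a failed reciprocal check.
#' @param members Family members of `trigger_gene` (gene ids).
#' @return The updated `family_state`.
#' @export
expand_family <- function(state, trigger_gene, members = character(0)) {
  stopifnot(inherits(state, "family_state"))
  cand <- setdiff(unique(c(trigger_gene, members)),
                  c(state$tested_genes, state$frontier))
  state$frontier <- sort(c(state$frontier, cand))
  state$iteration_count <- state$iteration_count + 1L
  state
}

#' Iterative cross-species reciprocal-hit orthology classification
#'
#' Implements the full inference chain: seed genes are searched against every
#' other species' database; top hits and similar-E-value hits join the search
#' frontier (so each discovered candidate is itself subjected to cross-species
#' reciprocal searches, and gene families expand when a reciprocal search
#' lands on a new family member); at the fixed point every pair of genes in
#' the reciprocity graph receives exactly one call:
#'
#' * `orthologue` -- mutual top hits across species (one-to-many situations
#'   are still emitted as orthologue but carry `ambiguity = TRUE`, including
#'   co-orthologues recovered through a home-species paralogue of the mutual
#'   partner);
#' * `paralogue` -- same-species genes that are similar-E-value co-members
#'   and/or reciprocate to the same partner set in other species;
#' * `unresolved` -- everything else.
#'
#' Mutual-top-hit components are additionally checked for full cross-species
#' clique consistency (each member the top hit of every other member in its
#' species); calls in components failing the check keep their per-pair calls
#' but carry a `partial_clique` warning in the evidence trail.
#'
#' @param databases Named list of [species_db()] objects (>= 2 species).
#' @param seeds Seed gene ids (must exist in some database).
#' @param scoring A [scoring_params()].
#' @param ratio,bit_delta "Similar E-value" definition, see
#'   [similar_evalue_hits()].
#' @param report_threshold Search reporting threshold.
#' @return An `orthology_result`: list with `calls` (data frame: gene_a,
#'   species_a, gene_b, species_b, relation, ambiguity, evidence), `graph`
#'   (top-hit/tie edge list), `absences` (gene x species with no detectable
#'   family member), `state` (final [family_state()]) and `hits` (memoized
#'   hit lists).
#' @export
classify_orthologues <- function(databases, seeds, scoring = scoring_params(),
                                 ratio = 10, bit_delta = 2,
                                 report_threshold = 1e-5) {
  stopifnot(length(databases) >= 2, !is.null(names(databases)))
  species <- names(databases)
  state <- family_state(seeds)
  for (s in seeds) find_species(s, databases)  # existence check

  edges <- list()
  hits <- list()
  absences <- list()
  gene_species <- character(0)

  while (length(state$frontier)) {
    g <- state$frontier[1L]
    state$frontier <- state$frontier[-1L]
    state$tested_genes <- union(state$tested_genes, g)
    state$iteration_count <- state$iteration_count + 1L
    home <- find_species(g, databases)
    gene_species[g] <- home
    discovered <- character(0)
    for (tsp in species) {
      key <- paste(g, tsp, sep = "\r")
      if (key %in% state$tested) next
      state$tested <- c(state$tested, key)
      hl <- search(db_get(databases[[home]], g), databases[[tsp]],
                   scoring, report_threshold)
      hits[[paste(g, tsp, sep = "|")]] <- hl
      if (!nrow(hl)) {
        if (tsp != home)
          absences[[length(absences) + 1L]] <-
            data.frame(gene = g, species = tsp, stringsAsFactors = FALSE)
        next
      }
      ties <- similar_evalue_hits(hl, ratio, bit_delta)
      edges[[length(edges) + 1L]] <- data.frame(
        from_gene = g, from_species = home, to_gene = ties$subject_id,
        to_species = tsp, evalue = ties$evalue, bitscore = ties$bitscore,
        rank = seq_len(nrow(ties)),
        top = seq_len(nrow(ties)) == 1L, stringsAsFactors = FALSE)
      discovered <- c(discovered, ties$subject_id)
    }
    state <- expand_family(state, character(0), discovered)
  }

  graph <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from_gene = character(0), from_species = character(0),
               to_gene = character(0), to_species = character(0),
               evalue = numeric(0), bitscore = numeric(0),
               rank = integer(0), top = logical(0))
  absences <- if (length(absences)) do.call(rbind, absences) else
    data.frame(gene = character(0), species = character(0))

  calls <- build_calls(graph, gene_species, ratio)
  structure(list(calls = calls, graph = graph, absences = absences,
                 state = state, hits = hits, species = species),
            class = "orthology_result")
}

# classify every unordered pair of tested genes from the reciprocity graph
build_calls <- function(graph, gene_species, ratio) {
  genes <- sort(names(gene_species))
  empty <- data.frame(gene_a = character(0), species_a = character(0),
                      gene_b = character(0), species_b = character(0),
                      relation = character(0), ambiguity = logical(0),
                      evidence = character(0), stringsAsFactors = FALSE)
  if (length(genes) < 2) return(empty)

  tops <- graph[graph$top, , drop = FALSE]
  top_of <- function(g, sp) {
    v <- tops$to_gene[tops$from_gene == g & tops$to_species == sp]
    if (length(v)) v[1L] else NA_character_
  }
  ties_of <- function(g, sp) graph$to_gene[graph$from_gene == g &
                                           graph$to_species == sp]
  home_ties <- function(g) setdiff(ties_of(g, gene_species[g]), g)
  partners <- function(g) {
    sp <- gene_species[g]
    unique(tops$to_gene[tops$from_gene == g & tops$to_species != sp])
  }
  mutual <- function(a, b) {
    identical(top_of(a, gene_species[b]), b) &&
      identical(top_of(b, gene_species[a]), a)
  }

  # mutual-top-hit components for the clique-consistency warning
  mut_pairs <- list()
  for (i in seq_along(genes)) for (j in seq_len(i - 1L)) {
    a <- genes[j]; b <- genes[i]
    if (gene_species[a] != gene_species[b] && mutual(a, b))
      mut_pairs[[length(mut_pairs) + 1L]] <- c(a, b)
  }
  comp <- stats::setNames(seq_along(genes), genes)
  for (p in mut_pairs) {
    ca <- comp[p[1L]]; cb <- comp[p[2L]]
    comp[comp == cb] <- ca
  }
  clique_ok <- vapply(unique(comp), function(cc) {
    mem <- names(comp)[comp == cc]
    if (length(mem) < 3) return(TRUE)
    for (i in seq_along(mem)) for (j in seq_len(i - 1L)) {
      a <- mem[j]; b <- mem[i]
      if (gene_species[a] != gene_species[b] && !mutual(a, b)) return(FALSE)
    }
    TRUE
  }, logical(1))
  names(clique_ok) <- as.character(unique(comp))

  rows <- list()
  for (i in seq_along(genes)) for (j in seq_len(i - 1L)) {
    a <- genes[j]; b <- genes[i]
    sa <- gene_species[a]; sb <- gene_species[b]
    relation <- "unresolved"; amb <- FALSE; ev <- character(0)
    if (sa != sb) {
      if (mutual(a, b)) {
        relation <- "orthologue"
        ev <- "mutual_top_hit"
        # one-to-many: another gene of a's species also resolves to b (or v.v.)
        co_a <- any(vapply(home_ties(a), function(x)
          identical(top_of(x, sb), b), logical(1)))
        co_b <- any(vapply(home_ties(b), function(x)
          identical(top_of(x, sa), a), logical(1)))
        if (co_a || co_b) { amb <- TRUE; ev <- c(ev, "one_to_many") }
        if (!clique_ok[as.character(comp[a])])
          ev <- c(ev, "partial_clique")
      } else {
        # co-orthologue: a's top in sb is b, but b reciprocates to a home
        # paralogue of a (or the symmetric situation)
        co1 <- identical(top_of(a, sb), b) && !is.na(top_of(b, sa)) &&
          (top_of(b, sa) %in% home_ties(a) || a %in% home_ties(top_of(b, sa)))
        co2 <- identical(top_of(b, sa), a) && !is.na(top_of(a, sb)) &&
          (top_of(a, sb) %in% home_ties(b) || b %in% home_ties(top_of(a, sb)))
        if (co1 || co2) {
          relation <- "orthologue"; amb <- TRUE
          ev <- c("shared_partner_coorthologue", "one_to_many")
        }
      }
    } else {
      tie <- b %in% home_ties(a) || a %in% home_ties(b)
      shared <- length(intersect(partners(a), partners(b))) > 0
      if (tie || shared) {
        relation <- "paralogue"
        ev <- c(if (tie) "home_evalue_tie", if (shared) "shared_partner_set")
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, species_a = sa, gene_b = b, species_b = sb,
      relation = relation, ambiguity = amb,
      evidence = paste(ev, collapse = ";"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
}

#' @export
print.orthology_result <- function(x, ...) {
  tab <- table(x$calls$relation)
  cat("<orthology_result>", length(x$state$tested_genes), "genes across",
      length(x$species), "species;",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Retrieve the relation called for a pair of genes
#' @param result An `orthology_result`.
#' @param gene_a,gene_b Gene ids.
#' @return One-row data frame (the call), or `NULL` if the pair never
#'   co-occurred in the graph.
#' @export
call_between <- function(result, gene_a, gene_b) {
  k <- sort(c(gene_a, gene_b))
  row <- result$calls[result$calls$gene_a == k[1L] &
                      result$calls$gene_b == k[2L], , drop = FALSE]
  if (nrow(row)) row else NULL
}

#' Write orthology calls as TSV
#' @param result An `orthology_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthology_calls <- function(result, path) {
  utils::write.table(result$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the reciprocity graph edge list as TSV
#' @param result An `orthology_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reciprocity_graph <- function(result, path) {
  utils::write.table(result$graph, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
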