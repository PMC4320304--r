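#' The ten ancestral core clock components
#'
#' Family labels for the core clock components inferred to have been present
#' in the common ancestor of monocots and dicots: LHY, TOC1, the two ancestral
#' PRR genes (PRR3/7 and PRR9/5), GI, LUX, ELF3, FKF1, ZTL and ELF4-like3.
#'
#' @return Character vector of family labels.
#' @export
core_clock_components <- function() {
  c("LHY", "TOC1", "PRR37", "PRR95", "GI", "LUX", "ELF3", "FKF1", "ZTL",
    "ELF4L3")
}

#' Load the clock-gene catalogue
#'
#' Reads the packaged catalogue of Arabidopsis clock genes and their barley
#' homologues (curated from the published literature; the `source` column
#' records whether an entry comes from the tabulated catalogue or from
#' text-only mentions) or a user-supplied table in the same TSV schema:
#' family, species, gene_name, identifier, relation_to_arabidopsis
#' (reference / one_to_one_orthologue / orthologue_ambiguous / paralogue /
#' absent), partial, core_clock, source. Validation errors name the offending
#' row: identifiers must be unique within a species and absent entries carry
#' no identifier.
#'
#' @param path TSV file (defaults to the packaged fixture).
#' @return A `catalogue` data frame.
#' @export
load_catalogue <- function(path = system.file("extdata", "clock_catalogue.tsv",
                                              package = "orthoclock")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("family", "species", "gene_name", "identifier",
            "relation_to_arabidopsis", "partial", "core_clock", "source")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("catalogue is missing column(s): ", paste(missing, collapse = ","))
  tab$partial <- toupper(tab$partial) == "TRUE"
  tab$core_clock <- toupper(tab$core_clock) == "TRUE"
  tab$identifier[is.na(tab$identifier)] <- ""
  tab$gene_name[is.na(tab$gene_name)] <- ""
  rels <- c("reference", "one_to_one_orthologue", "orthologue_ambiguous",
            "paralogue", "absent")
  bad <- which(!tab$relation_to_arabidopsis %in% rels)
  if (length(bad))
    stop("row ", bad[1L], ": unknown relation '",
         tab$relation_to_arabidopsis[bad[1L]], "'")
  ab <- which(tab$relation_to_arabidopsis == "absent" & nzchar(tab$identifier))
  if (length(ab))
    stop("row ", ab[1L], ": absent entry carries identifier '",
         tab$identifier[ab[1L]], "'")
  for (sp in unique(tab$species)) {
    ids <- tab$identifier[tab$species == sp & nzchar(tab$identifier)]
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1L]
      stop("duplicate identifier '", dup, "' for species ", sp, " (row ",
           which(tab$identifier == dup)[2L], ")")
    }
  }
  structure(tab, class = c("catalogue", "data.frame"))
}

#' Summarise the catalogue
#'
#' Recomputes the headline tallies from the entries (never stored): the
#' number of distinct barley homologues, the count and percentage of
#' ancestral core components with a one-to-one barley orthologue (numerator,
#' denominator and component list are all reported alongside the percentage),
#' and per-species, per-family copy counts.
#'
#' @param entries A `catalogue` from [load_catalogue()].
#' @param scope Optional character vector of family labels to restrict to.
#' @return A `summary_report` list.
#' @export
summarize_catalogue <- function(entries, scope = NULL) {
  tab <- as.data.frame(entries)
  if (!is.null(scope)) tab <- tab[tab$family %in% scope, , drop = FALSE]
  present <- tab[tab$relation_to_arabidopsis != "absent", , drop = FALSE]
  barley <- present[present$species == "barley", , drop = FALSE]
  core <- intersect(core_clock_components(), unique(entries$family))
  core <- core[if (is.null(scope)) TRUE else core %in% scope]
  one2one <- barley[barley$relation_to_arabidopsis == "one_to_one_orthologue" &
                    barley$family %in% core, , drop = FALSE]
  fam_counts <- if (nrow(present))
    as.data.frame(table(species = present$species, family = present$family),
                  stringsAsFactors = FALSE) else
    data.frame(species = character(0), family = character(0), Freq = integer(0))
  fam_counts <- fam_counts[fam_counts$Freq > 0, , drop = FALSE]
  structure(list(
    barley_gene_count = nrow(barley),
    barley_identifier_count = sum(nzchar(barley$identifier)),
    core_components = core,
    core_one_to_one_genes = one2one$gene_name,
    core_one_to_one_families = unique(one2one$family),
    core_one_to_one_count = length(unique(one2one$family)),
    core_one_to_one_pct = if (length(core))
      100 * length(unique(one2one$family)) / length(core) else NA_real_,
    family_copy_counts = fam_counts,
    absent_in_barley = tab$family[tab$species == "barley" &
                                  tab$relation_to_arabidopsis == "absent"],
    partial_barley_genes = barley$gene_name[barley$partial]),
    class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  cat(sprintf("  barley homologues: %d (%d with identifiers)\n",
              x$barley_gene_count, x$barley_identifier_count))
  cat(sprintf("  core one-to-one orthologues: %d / %d components (%.0f%%)\n",
              x$core_one_to_one_count, length(x$core_components),
              x$core_one_to_one_pct))
  cat("    components:", paste(x$core_components, collapse = ", "), "\n")
  cat("    one-to-one:", paste(x$core_one_to_one_families, collapse = ", "),
      "\n")
  if (length(x$absent_in_barley))
    cat("  absent in barley:", paste(x$absent_in_barley, collapse = ", "),
        "\n")
  invisible(x)
}
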