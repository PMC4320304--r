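#' Pipeline configuration
#'
#' Flat key--value configuration for [run_pipeline()]; any subset may also be
#' supplied as a YAML file via `config_file`. Defaults reflect the study
#' conditions the pipeline emulates (2000 bootstrap replicates with a 50\%
#' display threshold, E-value similarity ratio 10, reporting threshold
#' 1e-5, GT..AG-only splice sites).
#'
#' @param seed Master RNG seed; per-family seeds are derived from it.
#' @param n_families Number of synthetic families simulated.
#' @param species_tree Newick species tree (defaults to
#'   [default_species_tree()]).
#' @param dup_rate,loss_rate Birth--death rates per unit branch length.
#' @param root_cds_length Ancestral CDS length (nt).
#' @param n_introns Introns per simulated gene.
#' @param evalue_ratio "Similar E-value" ratio for paralogue ties.
#' @param report_threshold Search E-value reporting threshold.
#' @param bootstrap_replicates,support_threshold Bootstrap settings.
#' @param resample Bootstrap resampling unit (`"codon"` or `"nucleotide"`).
#' @param config_file Optional YAML file whose entries override the above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_families = 20,
                            species_tree = default_species_tree()$newick,
                            dup_rate = 0.3, loss_rate = 0.1,
                            root_cds_length = 300, n_introns = 2,
                            evalue_ratio = 10, report_threshold = 1e-5,
                            bootstrap_replicates = 2000,
                            support_threshold = 50,
                            resample = "codon",
                            config_file = NULL) {
  cfg <- list(seed = seed, n_families = n_families,
              species_tree = species_tree, dup_rate = dup_rate,
              loss_rate = loss_rate, root_cds_length = root_cds_length,
              n_introns = n_introns, evalue_ratio = evalue_ratio,
              report_threshold = report_threshold,
              bootstrap_replicates = bootstrap_replicates,
              support_threshold = support_threshold, resample = resample)
  if (!is.null(config_file)) {
    over <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ","))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full inference chain on synthetic families
#'
#' Simulate -> search/classify -> re-annotate -> align -> tree -> report, with
#' every stage's outputs written under `outdir` and summarised in a JSON
#' manifest with file checksums; a fixed seed gives a byte-identical
#' manifest. Classification, re-annotation and tree estimation are scored
#' against the simulator's ground truth.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Subset of stages to run (later stages need earlier ones
#'   within the same call).
#' @return The report list, invisibly; on-disk outputs include
#'   `orthology_calls.tsv`, `reciprocity_graph.tsv`, truth tables, trees and
#'   `report.json` / `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = c("simulate", "classify", "annotate",
                                    "align", "tree", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- species_tree_spec(config$species_tree)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  report <- list(seed = config$seed, n_families = config$n_families)

  run_stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fams <- NULL
  if ("simulate" %in% stages) {
    fams <- run_stage("simulate", {
      lapply(seq_len(config$n_families), function(i)
        simulate_family(st, dup_rate = config$dup_rate,
                        loss_rate = config$loss_rate,
                        root_cds_length = config$root_cds_length,
                        n_introns = config$n_introns,
                        seed = config$seed * 1000L + i))
    })
    write_family(fams[[1L]], file.path(outdir, "family_01"))
    put(file.path(outdir, "family_01", "manifest.json"))
    truth_all <- do.call(rbind, lapply(seq_along(fams), function(i)
      cbind(family = sprintf("fam%02d", i), fams[[i]]$truth)))
    utils::write.table(truth_all, put(file.path(outdir, "truth_orthology.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$n_genes <- sum(vapply(fams, function(f) length(f$genes), integer(1)))
    report$n_extinct <- sum(vapply(fams, function(f) isTRUE(f$extinct),
                                   logical(1)))
  }

  if ("classify" %in% stages && !is.null(fams)) {
    res <- run_stage("classify", {
      lapply(fams, function(fam) {
        if (length(fam$genes) < 2) return(NULL)
        dbs <- databases_from_family(fam)
        seeds <- pipeline_seeds(fam)
        classify_orthologues(dbs, seeds, ratio = config$evalue_ratio,
                             report_threshold = config$report_threshold)
      })
    })
    calls_all <- do.call(rbind, lapply(seq_along(res), function(i)
      if (is.null(res[[i]])) NULL else
        cbind(family = sprintf("fam%02d", i), res[[i]]$calls)))
    utils::write.table(calls_all, put(file.path(outdir, "orthology_calls.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    graph_all <- do.call(rbind, lapply(seq_along(res), function(i)
      if (is.null(res[[i]])) NULL else
        cbind(family = sprintf("fam%02d", i), res[[i]]$graph)))
    utils::write.table(graph_all,
                       put(file.path(outdir, "reciprocity_graph.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pr <- orthology_scores(fams, res)
    report$orthologue_precision <- pr$precision
    report$orthologue_recall <- pr$recall
    report$n_orthologue_pairs_true <- pr$n_true
    report$n_orthologue_pairs_called <- pr$n_called
  }

  if ("annotate" %in% stages && !is.null(fams)) {
    rec <- run_stage("annotate", {
      hits <- 0L; total <- 0L
      for (fam in fams) {
        for (g in fam$genes[seq_len(min(2L, length(fam$genes)))]) {
          total <- total + 1L
          m <- reannotate(g$genomic, list(g$cds))
          ok <- !is.null(m) &&
            identical(spliced_cds(m, g$genomic), g$cds$residues) &&
            nrow(m$exons) == nrow(g$model$exons) &&
            validate_model(m, g$genomic)$passed
          if (ok) hits <- hits + 1L
        }
      }
      list(rate = if (total) hits / total else NA_real_, n = total)
    })
    report$reannotation_recovery_rate <- rec$rate
    report$reannotation_cases <- rec$n
  }

  aln <- NULL
  if ("align" %in% stages && !is.null(fams)) {
    aln <- run_stage("align", {
      fam <- fams[[1L]]
      genes <- exclude_pseudogenes(fam$genes)
      if (length(genes) < 3) NULL else {
        pa <- align_proteins(lapply(genes, `[[`, "protein"))
        ca <- backtranslate(pa, lapply(genes, `[[`, "cds"))
        ca <- mask_incomplete_columns(ca)
        write_alignment_fasta(ca, put(file.path(outdir, "family_01_codon.fasta")))
        ca
      }
    })
  }

  if ("tree" %in% stages && !is.null(aln)) {
    run_stage("tree", {
      tr <- bootstrap_tree(aln, replicates = config$bootstrap_replicates,
                           threshold = config$support_threshold,
                           seed = config$seed,
                           resample = config$resample)
      moss <- grep("^moss_", tr$tip.label, value = TRUE)
      if (length(moss) && length(moss) < ape::Ntip(tr) - 1L) {
        tr <- tryCatch(root_with_outgroup(tr, moss), error = function(e) tr)
      }
      write_support_newick(tr, put(file.path(outdir, "family_01_tree.nwk")))
      report$family1_mean_support <- mean(suppressWarnings(
        as.numeric(tr$node.label)), na.rm = TRUE)
    })
  }

  if ("report" %in% stages) {
    run_stage("report", {
      cat_sum <- summarize_catalogue(load_catalogue())
      report$catalogue_barley_genes <- cat_sum$barley_gene_count
      report$catalogue_core_one_to_one <- cat_sum$core_one_to_one_count
      report$catalogue_core_pct <- cat_sum$core_one_to_one_pct
      jsonlite::write_json(report, put(file.path(outdir, "report.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }

  manifest <- list(config = unclass(config), stages = stages,
                   files = lapply(stats::setNames(paths, basename(paths)),
                                  function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# seeds for classification: all genes of the first species (lexicographic
# among species that have genes) -- the "Arabidopsis role"
pipeline_seeds <- function(fam) {
  sps <- sort(unique(vapply(fam$genes, `[[`, character(1), "species")))
  sp <- if ("arabidopsis" %in% sps) "arabidopsis" else sps[1L]
  sort(vapply(Filter(function(g) g$species == sp, fam$genes),
              `[[`, character(1), "id"))
}

# micro-averaged precision/recall of orthologue calls against simulator truth
orthology_scores <- function(fams, results) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(fams)) {
    fam <- fams[[i]]; res <- results[[i]]
    if (is.null(res)) next
    truth <- fam$truth
    true_o <- paste(truth$gene_a, truth$gene_b)[truth$relation == "orthologue"]
    calls <- res$calls
    called_o <- paste(calls$gene_a, calls$gene_b)[calls$relation == "orthologue"]
    tp <- tp + length(intersect(called_o, true_o))
    fp <- fp + length(setdiff(called_o, true_o))
    fn <- fn + length(setdiff(true_o, called_o))
  }
  list(precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       n_true = tp + fn, n_called = tp + fp)
}
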