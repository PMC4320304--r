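#' Progressive protein multiple alignment
#'
#' Standard progressive alignment in the ClustalW mould: pairwise shared
#' k-mer (k = 3) distances, a neighbour-joining guide tree, and
#' profile--profile alignment (BLOSUM62, affine gaps) at each merge. The
#' procedure is fully deterministic; CDS records are translated first and a
#' trailing stop codon is trimmed and never aligned.
#'
#' @param records List of protein or CDS [seq_record()] objects (>= 2), or a
#'   named character vector of protein sequences.
#' @param scoring A [scoring_params()] used for the profile alignment.
#' @return A `protein_alignment`: named character vector of equal-length
#'   gapped rows; removing gaps from any row reproduces its input protein.
#' @export
align_proteins <- function(records, scoring = scoring_params()) {
  prots <- proteins_of(records)
  n <- length(prots)
  stopifnot(n >= 2)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZ]", prots)
  if (any(bad))
    stop("non-amino-acid symbols in sequence(s): ",
         paste(names(prots)[bad], collapse = ","))
  ids <- names(prots)
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  chars <- lapply(prots, function(p) strsplit(p, "")[[1L]])

  merge_order <- if (n == 2) list(c(1L, 2L)) else guide_merges(prots)
  # clusters: list of character matrices (rows = sequences)
  clusters <- lapply(seq_len(n), function(i)
    matrix(chars[[i]], nrow = 1L, dimnames = list(ids[i], NULL)))
  for (mo in merge_order) {
    a <- clusters[[mo[1L]]]; b <- clusters[[mo[2L]]]
    clusters[[mo[1L]]] <- merge_profiles(a, b, scoring)
    clusters[mo[2L]] <- list(NULL)
  }
  final <- clusters[[which(!vapply(clusters, is.null, logical(1)))[1L]]]
  rows <- apply(final, 1L, paste, collapse = "")
  structure(rows[ids], class = "protein_alignment")
}

proteins_of <- function(records) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    return(toupper(records))
  }
  if (inherits(records, "species_db")) records <- records$records
  stopifnot(all(vapply(records, inherits, logical(1), "seq_record")))
  prots <- vapply(records, function(r) {
    p <- if (r$moltype == "cds") translate_cds(r$residues) else r$residues
    if (grepl("\\*", sub("\\*$", "", p)))
      stop("internal stop codon in '", r$id, "'")
    sub("\\*$", "", p)
  }, character(1))
  names(prots) <- vapply(records, `[[`, character(1), "id")
  prots
}

# shared 3-mer distance + NJ guide tree -> ordered list of cluster merges
guide_merges <- function(prots) {
  n <- length(prots)
  k <- 3L
  kmers <- lapply(prots, function(p) {
    L <- nchar(p)
    if (L < k) return(character(0))
    unique(substring(p, 1:(L - k + 1L), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(names(prots), names(prots)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  tr <- nj_tree(d)
  tr <- ape::root(tr, outgroup = sort(names(prots))[1L], resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "postorder")
  # walk edges in postorder: each internal node merges the clusters of its
  # children; repr[] tracks which cluster index holds each node's alignment
  idx <- stats::setNames(seq_len(n), names(prots))
  repr <- integer(ape::Ntip(tr) + ape::Nnode(tr))
  repr[seq_len(ape::Ntip(tr))] <- idx[tr$tip.label]
  merges <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    if (repr[p] == 0L) repr[p] <- repr[ch]
    else merges[[length(merges) + 1L]] <- c(repr[p], repr[ch])
  }
  merges
}

# profile-profile alignment of two cluster matrices
merge_profiles <- function(a, b, scoring) {
  S <- scoring$matrix
  states <- rownames(S)
  pa <- profile_freq(a, states)
  pb <- profile_freq(b, states)
  colscore <- crossprod(pa, S %*% pb)
  path <- .nw_profile_path(colscore, scoring$gap_open, scoring$gap_ext)
  L <- length(path$a)
  out <- matrix("-", nrow = nrow(a) + nrow(b), ncol = L,
                dimnames = list(c(rownames(a), rownames(b)), NULL))
  ai <- path$a; bj <- path$b
  out[seq_len(nrow(a)), ai > 0] <- a[, ai[ai > 0], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), bj > 0] <- b[, bj[bj > 0], drop = FALSE]
  out
}

profile_freq <- function(m, states) {
  f <- matrix(0, nrow = length(states), ncol = ncol(m),
              dimnames = list(states, NULL))
  for (s in setdiff(unique(as.vector(m)), "-"))
    f[s, ] <- colMeans(m == s)
  f
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d sequences x %d columns\n",
              length(x), nchar(x[1L])))
  invisible(x)
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Projects each aligned amino acid back to its source codon and each gap to
#' `---`, so the nucleotide alignment preserves codon structure exactly. Every
#' CDS must translate to its ungapped protein row (a trailing stop codon is
#' tolerated and trimmed); a mismatch is a hard error naming the gene and the
#' first offending position.
#'
#' @param pa A `protein_alignment`.
#' @param cds_map Named character vector or list of CDS strings /
#'   [seq_record()]s covering every row of `pa`.
#' @return A `codon_alignment`: named character vector of gapped CDS rows,
#'   with 3x the protein column count.
#' @export
backtranslate <- function(pa, cds_map) {
  if (is.list(cds_map))
    cds_map <- vapply(cds_map, function(x)
      if (inherits(x, "seq_record")) x$residues else x, character(1))
  rows <- character(length(pa))
  names(rows) <- names(pa)
  for (id in names(pa)) {
    cds <- cds_map[[id]]
    if (is.null(cds) || is.na(cds)) stop("no CDS supplied for '", id, "'")
    cds <- toupper(cds)
    ungapped <- gsub("-", "", pa[[id]])
    aa <- suppressWarnings(translate_cds(cds))
    if (aa != ungapped) {
      diffat <- which(strsplit(aa, "")[[1L]][seq_len(min(nchar(aa), nchar(ungapped)))] !=
                      strsplit(ungapped, "")[[1L]][seq_len(min(nchar(aa), nchar(ungapped)))])
      stop("CDS of '", id, "' does not translate to its aligned protein ",
           "(first mismatch at residue ",
           if (length(diffat)) diffat[1L] else min(nchar(aa), nchar(ungapped)) + 1L,
           ")")
    }
    if (nchar(cds) %% 3L == 0L &&
        substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA") &&
        nchar(aa) * 3L == nchar(cds) - 3L)
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    gapped <- strsplit(pa[[id]], "")[[1L]]
    out <- character(length(gapped))
    out[gapped == "-"] <- "---"
    out[gapped != "-"] <- codons
    rows[[id]] <- paste(out, collapse = "")
  }
  structure(rows, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d sequences x %d nt columns (%d codons)\n",
              length(x), nchar(x[1L]), nchar(x[1L]) %/% 3L))
  invisible(x)
}

#' Remove codon columns containing gaps or ambiguity symbols
#'
#' Complete-deletion: any codon column with a gap, `N` or ambiguity symbol in
#' any row is dropped, as done before distance estimation so that every
#' retained column is observed in all sequences. The result keeps codon
#' structure (column count divisible by 3).
#'
#' @param ca A `codon_alignment`.
#' @return The masked `codon_alignment`; a zero-column result (e.g. one row
#'   entirely gapped) is returned with a warning.
#' @export
mask_incomplete_columns <- function(ca) {
  mat <- codon_matrix(ca)
  ok <- apply(mat, 2L, function(col) all(!grepl("[^ACGT]", col)))
  kept <- mat[, ok, drop = FALSE]
  if (!ncol(kept)) warning("complete-deletion removed every codon column")
  out <- apply(kept, 1L, paste, collapse = "")
  if (!ncol(kept)) out <- stats::setNames(character(length(ca)), names(ca))
  structure(out, class = "codon_alignment")
}

codon_matrix <- function(ca) {
  L <- nchar(ca[[1L]])
  stopifnot(L %% 3L == 0L, all(nchar(ca) == L))
  ncod <- L %/% 3L
  mat <- vapply(ca, function(row)
    substring(row, seq(1L, L, 3L), seq(3L, L, 3L)), character(ncod))
  if (ncod == 1L) mat <- matrix(mat, nrow = 1L)
  t(mat)  # rows = sequences, cols = codons
}

#' Write an alignment to aligned FASTA
#' @param aln A `protein_alignment` or `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(aln)) {
    writeLines(paste0(">", id), con)
    writeLines(gsub("(.{60})", "\\1\n", aln[[id]], perl = TRUE), con)
  }
  invisible(path)
}

#' Write an alignment in sequential PHYLIP format
#' @param aln A `protein_alignment` or `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(aln), nchar(aln[[1L]])), con)
  for (id in names(aln))
    writeLines(sprintf("%-10s%s", substr(id, 1L, 10L), aln[[id]]), con)
  invisible(path)
}
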