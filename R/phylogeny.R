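#' Composite-likelihood (pooled TN93) evolutionary distances
#'
#' Distances in substitutions per site under the Tamura--Nei (TN93) model with
#' substitution parameters shared across all pairs: base frequencies are
#' estimated once from the pooled alignment, and each pairwise distance is
#' computed from that pair's transition/transversion proportions under the
#' shared frequencies. This is the documented core of "composite likelihood"
#' distance estimation; exact numeric equality with any particular GUI
#' implementation is not a contract (closed-form limits and simulation
#' recovery are, see the package tests).
#'
#' Apply [mask_incomplete_columns()] first: rows must be equal length and free
#' of gaps/ambiguities. A pair whose corrected distance diverges (logarithm of
#' a non-positive argument) is flagged saturated and set `NA`; [nj_tree()]
#' refuses such matrices.
#'
#' @param ca A `codon_alignment` (or any named character vector of equal
#'   length nucleotide strings).
#' @return A `dist_matrix`: symmetric numeric matrix (zero diagonal) with a
#'   logical `saturated` attribute matrix.
#' @export
mcl_distances <- function(ca) {
  stopifnot(length(ca) >= 2)
  labels <- names(ca)
  mat <- do.call(rbind, strsplit(unname(as.character(ca)), ""))
  rownames(mat) <- labels
  if (any(!mat %in% c("A", "C", "G", "T")))
    stop("alignment contains gaps or ambiguity symbols; ",
         "apply mask_incomplete_columns() first")
  n <- length(labels)
  L <- ncol(mat)
  # pooled (shared) base frequencies
  pi <- table(factor(mat, levels = c("A", "C", "G", "T"))) / length(mat)
  pi <- as.numeric(pi); names(pi) <- c("A", "C", "G", "T")
  gR <- pi["A"] + pi["G"]; gY <- pi["C"] + pi["T"]
  k1 <- 2 * pi["A"] * pi["G"] / gR
  k2 <- 2 * pi["C"] * pi["T"] / gY
  k3 <- 2 * (gR * gY - pi["A"] * pi["G"] * gY / gR - pi["C"] * pi["T"] * gR / gY)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    a <- mat[i, ]; b <- mat[j, ]
    diff <- a != b
    P1 <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A"))) / L
    P2 <- sum(diff & ((a == "C" & b == "T") | (a == "T" & b == "C"))) / L
    Q <- sum(diff) / L - P1 - P2
    # degenerate pooled frequencies (an entirely missing base class) zero a
    # denominator; the corresponding term is 0 when its numerator is too,
    # otherwise the pair is unrecoverable under the model
    safe <- function(num, den) if (den > 0) num / den else if (num > 0) Inf else 0
    w1 <- 1 - safe(P1, k1) - safe(Q, 2 * gR)
    w2 <- 1 - safe(P2, k2) - safe(Q, 2 * gY)
    w3 <- 1 - safe(Q, 2 * gR * gY)
    if (!all(is.finite(c(w1, w2, w3))) || w1 <= 0 || w2 <= 0 || w3 <= 0) {
      d[i, j] <- d[j, i] <- NA_real_
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      dij <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
      d[i, j] <- d[j, i] <- unname(dij)
    }
  }
  structure(d, class = c("dist_matrix", "matrix"), saturated = sat)
}

#' Neighbour-joining tree from a distance matrix
#'
#' The classic Saitou--Nei agglomeration with the Studier--Keppler Q
#' criterion. Ties in Q are broken lexicographically on the (sorted) label
#' pair so the result is bit-reproducible; negative branch length estimates
#' are clamped to zero with a warning. Saturated (NA) entries are refused.
#'
#' @param dm A `dist_matrix` from [mcl_distances()], or any symmetric labelled
#'   numeric matrix (>= 3 labels).
#' @return An unrooted `phylo` tree (no support values).
#' @export
nj_tree <- function(dm) {
  d <- unclass(dm)
  sat <- attr(dm, "saturated")
  if (!is.null(sat) && any(sat))
    stop("distance matrix has saturated entries (",
         sum(sat) / 2, " pair(s)); resolve before tree building")
  if (any(!is.finite(d[upper.tri(d)])))
    stop("distance matrix has non-finite entries")
  labels <- rownames(d)
  stopifnot(!is.null(labels), length(labels) >= 3)
  sub <- stats::setNames(labels, labels)   # newick fragment per active node
  act <- labels
  clamped <- FALSE
  fmt <- function(x) sprintf("%.10g", x)
  while (length(act) > 3L) {
    r <- length(act)
    dd <- d[act, act]
    R <- rowSums(dd)
    # Q criterion; pick the minimal pair, ties -> lexicographic on labels
    best <- NULL
    for (i in seq_len(r)) for (j in seq_len(i - 1L)) {
      q <- (r - 2) * dd[i, j] - R[i] - R[j]
      pair <- sort(c(act[i], act[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (pair[1L] < best$pair[1L] ||
            (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
        best <- list(q = q, i = act[i], j = act[j], pair = pair)
      }
    }
    i <- best$i; j <- best$j
    li <- dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dd[i, j] - li
    if (li < 0 || lj < 0) { clamped <- TRUE; li <- max(li, 0); lj <- max(lj, 0) }
    new <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    others <- setdiff(act, c(i, j))
    dnew <- (d[i, others] + d[j, others] - d[i, j]) / 2
    lab <- paste0("__n", length(sub) + 1L)
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- lab
    d[lab, others] <- d[others, lab] <- dnew
    sub[lab] <- new
    act <- c(others, lab)
  }
  # terminal trifurcation
  a <- act[1L]; b <- act[2L]; c3 <- act[3L]
  la <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  lb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  lc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  if (any(c(la, lb, lc) < 0)) clamped <- TRUE
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  if (clamped) warning("negative branch length estimate(s) clamped to 0")
  nwk <- paste0("(", sub[a], ":", fmt(la), ",", sub[b], ":", fmt(lb), ",",
                sub[c3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the full-data tree ([mcl_distances()] + [nj_tree()]), then resamples
#' alignment columns with replacement -- codon triplets by default, to respect
#' codon structure -- rebuilds the tree for each replicate, and maps internal
#' edge bipartition frequencies onto the full-data tree as percentage node
#' labels. Replicates whose resampled distances saturate are counted as
#' non-supporting and tallied in the `failed_replicates` attribute. Supports
#' below `threshold` are retained in the object but suppressed by the default
#' renderer ([write_support_newick()]).
#'
#' @param ca A `codon_alignment` (complete-deletion applied).
#' @param replicates Bootstrap replicates (conventional published choice
#'   2000; tests use 100--200).
#' @param threshold Display threshold percentage (default 50).
#' @param seed RNG seed for resampling.
#' @param resample `"codon"` (default) or `"nucleotide"` columns.
#' @return A `phylo` tree with `node.label` percentages and attributes
#'   `support_threshold`, `replicates`, `failed_replicates`.
#' @export
bootstrap_tree <- function(ca, replicates = 2000, threshold = 50, seed = 1,
                           resample = c("codon", "nucleotide")) {
  resample <- match.arg(resample)
  stopifnot(replicates >= 1, threshold >= 0, threshold <= 100)
  full <- nj_tree(mcl_distances(ca))
  mat <- codon_matrix(ca)
  if (resample == "nucleotide")
    mat <- do.call(rbind, strsplit(unname(as.character(ca)), ""))
  rownames(mat) <- names(ca)
  ncol_units <- ncol(mat)
  stopifnot(ncol_units >= 1)
  restore <- push_seed(seed)
  on.exit(restore(), add = TRUE)
  trees <- list()
  failed <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol_units, ncol_units, replace = TRUE)
    rep_ca <- apply(mat[, idx, drop = FALSE], 1L, paste, collapse = "")
    tr <- tryCatch(nj_tree(mcl_distances(rep_ca)), error = function(e) NULL)
    if (is.null(tr)) failed <- failed + 1L else trees[[length(trees) + 1L]] <- tr
  }
  counts <- if (length(trees))
    ape::prop.clades(full, trees, rooted = FALSE) else
    rep(0L, ape::Nnode(full))
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1)
  full$node.label <- as.character(support)
  # the basal (display root) node of an unrooted tree carries no support
  full$node.label[1L] <- ""
  attr(full, "support_threshold") <- threshold
  attr(full, "replicates") <- replicates
  attr(full, "failed_replicates") <- failed
  full
}

#' Root a tree on the edge separating an outgroup
#'
#' The outgroup must be present and monophyletic in the unrooted tree; the
#' root is placed on the edge separating it from the ingroup and support
#' labels are preserved (treated as edge labels while rerooting). When no
#' true outgroup exists and a root must be forced onto a named family branch,
#' set `root_edge_override = TRUE` to root on the branch of the first
#' outgroup label's family despite non-monophyly.
#'
#' @param tree A `phylo` (e.g. from [bootstrap_tree()]).
#' @param outgroup_labels Tip labels of the outgroup.
#' @param root_edge_override Force rooting when the outgroup is not
#'   monophyletic (manual root-edge placement).
#' @return A rooted `phylo` with supports preserved.
#' @export
root_with_outgroup <- function(tree, outgroup_labels,
                               root_edge_override = FALSE) {
  missing <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing))
    stop("outgroup label(s) not in tree: ", paste(missing, collapse = ","))
  mono <- length(outgroup_labels) == 1L ||
    ape::is.monophyletic(tree, outgroup_labels)
  if (!mono && !root_edge_override)
    stop("outgroup {", paste(outgroup_labels, collapse = ","),
         "} is not monophyletic; tree left unrooted ",
         "(set root_edge_override = TRUE to force a root edge)")
  og <- if (mono) outgroup_labels else outgroup_labels[1L]
  out <- ape::root(tree, outgroup = og, resolve.root = TRUE,
                   edgelabel = TRUE)
  for (a in c("support_threshold", "replicates", "failed_replicates"))
    attr(out, a) <- attr(tree, a)
  out
}

#' Bootstrap support of the split separating a set of tips
#'
#' Looks up the support attached to the internal edge that separates `tips`
#' from the remaining leaves. On an unrooted tree the split may be stored on
#' either side of the edge: when the tips' MRCA is the basal trifurcation the
#' complementary clade carries the label.
#'
#' @param tree A `phylo` with numeric support node labels (e.g. from
#'   [bootstrap_tree()]).
#' @param tips Tip labels on one side of the split.
#' @return The support value, or `NA` when the split is absent from the tree.
#' @export
edge_support <- function(tree, tips) {
  if (!ape::is.monophyletic(tree, tips)) {
    comp <- setdiff(tree$tip.label, tips)
    if (!ape::is.monophyletic(tree, comp)) return(NA_real_)
    tips <- comp
  }
  node <- if (length(tips) == 1L) return(NA_real_) else
    ape::getMRCA(tree, tips)
  root <- ape::Ntip(tree) + 1L
  if (node == root) {
    comp <- setdiff(tree$tip.label, tips)
    if (length(comp) < 2L || !ape::is.monophyletic(tree, comp))
      return(NA_real_)
    node <- ape::getMRCA(tree, comp)
    if (node == root) return(NA_real_)
  }
  suppressWarnings(as.numeric(tree$node.label[node - ape::Ntip(tree)]))
}

#' Drop pseudogene-flagged records before phylogenetic analysis
#'
#' Pseudogenes are excluded from tree estimation to avoid poorly supported
#' topologies; the number removed is reported via a message.
#'
#' @param records List of [seq_record()] objects.
#' @param flags Optional logical vector or character vector of ids overriding
#'   the records' own `pseudogene` flags.
#' @return The filtered record list.
#' @export
exclude_pseudogenes <- function(records, flags = NULL) {
  if (is.null(flags)) {
    drop <- vapply(records, function(r) isTRUE(r$pseudogene), logical(1))
  } else if (is.character(flags)) {
    drop <- vapply(records, function(r) r$id %in% flags, logical(1))
  } else {
    stopifnot(length(flags) == length(records))
    drop <- as.logical(flags)
  }
  if (any(drop))
    message("excluding ", sum(drop), " pseudogene(s): ",
            paste(vapply(records[drop], `[[`, character(1), "id"),
                  collapse = ","))
  if (all(drop)) warning("all records flagged pseudogene; nothing left")
  records[!drop]
}

#' Write a tree as Newick with thresholded support labels
#'
#' Internal-node support values below the display threshold are blanked, the
#' conventional ">50\%" rendering of bootstrap figures.
#'
#' @param tree A `phylo` with support node labels.
#' @param path Output path.
#' @param threshold Display threshold; defaults to the tree's
#'   `support_threshold` attribute (else 50).
#' @return `path`, invisibly.
#' @export
write_support_newick <- function(tree, path,
                                 threshold = attr(tree, "support_threshold") %||% 50) {
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(v) & v <= threshold] <- ""
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param dm A `dist_matrix` (or labelled symmetric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  d <- unclass(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste0(sprintf("%-10s", substr(rownames(d)[i], 1L, 10L)),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

# set the RNG deterministically and return a restorer for the previous state
push_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
    invisible()
  }
}
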