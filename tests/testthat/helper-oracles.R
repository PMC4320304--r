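# Independent reference implementations used only to check the package's
# fast paths. They are deliberately naive (full matrices, explicit loops).

# Full-matrix Smith-Waterman with affine gaps; returns the optimal score.
# Gap of length L costs open + L * ext (opening charged with the first
# extension), matching the package's convention.
sw_oracle <- function(a, b, S, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      S[A[i - 1], B[j - 1]]
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    best <- max(best, M[i, j])
  }
  best
}

# Full-matrix global Needleman-Wunsch score with affine gaps.
nw_oracle <- function(a, b, S, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      S[A[i - 1], B[j - 1]]
    X[i, j] <- max(M[i - 1, j], Y[i - 1, j]) - open - ext
    X[i, j] <- max(X[i, j], X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1], X[i, j - 1]) - open - ext
    Y[i, j] <- max(Y[i, j], Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force last-common-event oracle: recompute every pairwise orthology
# label from the simulated gene tree (node labels S = speciation,
# D = duplication) via the MRCA, independent of the simulator's own
# truth-table construction.
lca_truth_oracle <- function(gene_tree) {
  tips <- gene_tree$tip.label
  out <- list()
  for (i in seq_along(tips)) for (j in seq_len(i - 1)) {
    mrca <- ape::getMRCA(gene_tree, c(tips[i], tips[j]))
    lab <- gene_tree$node.label[mrca - ape::Ntip(gene_tree)]
    k <- sort(c(tips[i], tips[j]))
    out[[length(out) + 1]] <- data.frame(
      gene_a = k[1], gene_b = k[2],
      relation = if (lab == "S") "orthologue" else "paralogue",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
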