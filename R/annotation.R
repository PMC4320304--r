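#' Construct an exon--intron gene model
#'
#' Coordinates are 1-based closed intervals on the forward genomic strand
#' (GFF3 convention) with a strand flag; internal logic works in transcript
#' orientation after strand normalisation. Exons must be sorted, non
#' overlapping, and separated by introns of at least 4 nt; the CDS intervals
#' must lie within the exon union.
#'
#' @param gene_id Gene identifier.
#' @param genomic_id Id of the genomic [seq_record()] the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data frame of exon `start`, `end`.
#' @param cds Two-column matrix/data frame of coding intervals (defaults to
#'   `exons`, i.e. no UTRs).
#' @param complete Whether the model is a full-length ORF (spliced CDS then
#'   must be divisible by 3, begin ATG and end with a stop).
#' @param partial Flag for models reconstructed from incomplete evidence.
#' @return A `gene_model` object. UTR intervals are derived, never stored.
#' @export
gene_model <- function(gene_id, genomic_id, strand = c("+", "-"), exons,
                       cds = NULL, complete = TRUE, partial = FALSE) {
  strand <- match.arg(strand)
  exons <- as_intervals(exons)
  cds <- if (is.null(cds)) exons else as_intervals(cds)
  if (nrow(exons) > 1L) {
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      stop("exons overlap or are unsorted in model '", gene_id, "'")
    gaps <- exons$start[-1L] - exons$end[-nrow(exons)] - 1L
    if (any(gaps < 4L))
      stop("intron shorter than 4 nt in model '", gene_id, "'")
  }
  for (k in seq_len(nrow(cds))) {
    inside <- any(cds$start[k] >= exons$start & cds$end[k] <= exons$end)
    if (!inside) stop("CDS interval outside exons in model '", gene_id, "'")
  }
  structure(list(gene_id = gene_id, genomic_id = genomic_id, strand = strand,
                 exons = exons, cds = cds, complete = complete,
                 partial = partial),
            class = "gene_model")
}

as_intervals <- function(x) {
  x <- as.data.frame(x)
  colnames(x)[1:2] <- c("start", "end")
  x <- x[order(x$start), 1:2, drop = FALSE]
  stopifnot(all(x$end >= x$start))
  rownames(x) <- NULL
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand): %d exon(s), CDS %d nt%s%s\n",
              x$gene_id, x$strand, nrow(x$exons),
              sum(x$cds$end - x$cds$start + 1L),
              if (x$partial) " [partial]" else "",
              if (!x$complete) " [incomplete ORF]" else ""))
  invisible(x)
}

extract_intervals <- function(residues, iv) {
  paste(substring(residues, iv$start, iv$end), collapse = "")
}

#' Spliced CDS of a gene model
#'
#' Concatenates the coding intervals and reverse-complements on the minus
#' strand, yielding the CDS in transcript orientation.
#'
#' @param model A [gene_model()].
#' @param genomic The genomic [seq_record()] it refers to.
#' @return Nucleotide string.
#' @export
spliced_cds <- function(model, genomic) {
  s <- extract_intervals(genomic$residues, model$cds)
  if (model$strand == "-") revcomp(s) else s
}

#' Derived UTR intervals of a gene model
#' @param model A [gene_model()].
#' @return List with `utr5` and `utr3` interval data frames (forward-strand
#'   coordinates; which end is 5' depends on the strand).
#' @export
utr_intervals <- function(model) {
  cs <- min(model$cds$start); ce <- max(model$cds$end)
  left <- right <- list()
  for (k in seq_len(nrow(model$exons))) {
    e <- model$exons[k, ]
    if (e$start < cs) left[[length(left) + 1L]] <-
      data.frame(start = e$start, end = min(e$end, cs - 1L))
    if (e$end > ce) right[[length(right) + 1L]] <-
      data.frame(start = max(e$start, ce + 1L), end = e$end)
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(start = integer(0), end = integer(0))
  if (model$strand == "+") list(utr5 = bind(left), utr3 = bind(right))
  else list(utr5 = bind(right), utr3 = bind(left))
}

#' Validate a gene model against the re-annotation criteria
#'
#' Checks the two sequence-intrinsic criteria used when curating gene models:
#' every intron must begin with GT and end with AG (5' and 3' splice sites,
#' strand-aware), and the spliced CDS must maintain an open reading frame
#' (no internal stop codons; for a model flagged complete it must also begin
#' with ATG, end with a stop codon and have length divisible by 3).
#'
#' @param model A [gene_model()].
#' @param genomic The genomic [seq_record()].
#' @return An `annotation_verdict`: list with `passed` and a `violations`
#'   data frame (columns rule, location, detail).
#' @export
validate_model <- function(model, genomic) {
  if (max(model$exons$end) > nchar(genomic$residues) || min(model$exons$start) < 1L)
    stop("model '", model$gene_id, "' has coordinates outside the genomic sequence")
  v <- list()
  ex <- model$exons
  n_introns <- nrow(ex) - 1L
  if (n_introns > 0L) {
    # introns in transcript order
    ord <- if (model$strand == "+") seq_len(n_introns) else rev(seq_len(n_introns))
    for (t in seq_len(n_introns)) {
      k <- ord[t]
      iseq <- substring(genomic$residues, ex$end[k] + 1L, ex$start[k + 1L] - 1L)
      if (model$strand == "-") iseq <- revcomp(iseq)
      if (substr(iseq, 1L, 2L) != "GT" ||
          substr(iseq, nchar(iseq) - 1L, nchar(iseq)) != "AG")
        v[[length(v) + 1L]] <- data.frame(
          rule = 2L, location = sprintf("intron %d", t),
          detail = sprintf("boundaries %s..%s (expected GT..AG)",
                           substr(iseq, 1, 2),
                           substr(iseq, nchar(iseq) - 1L, nchar(iseq))))
    }
  }
  cds <- spliced_cds(model, genomic)
  aa <- suppressWarnings(translate_cds(substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)))
  internal <- grepl("\\*", aa)
  if (internal)
    v[[length(v) + 1L]] <- data.frame(
      rule = 3L, location = sprintf("codon %d", regexpr("\\*", aa)),
      detail = "internal stop codon in spliced CDS")
  if (isTRUE(model$complete)) {
    if (nchar(cds) %% 3L != 0L)
      v[[length(v) + 1L]] <- data.frame(rule = 3L, location = "CDS",
        detail = "spliced CDS length not divisible by 3")
    if (substr(cds, 1L, 3L) != "ATG")
      v[[length(v) + 1L]] <- data.frame(rule = 3L, location = "codon 1",
        detail = "complete model does not begin with ATG")
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA"))
      v[[length(v) + 1L]] <- data.frame(rule = 3L, location = "last codon",
        detail = "complete model does not end with a stop codon")
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = integer(0), location = character(0),
               detail = character(0))
  structure(list(model = model, passed = nrow(violations) == 0L,
                 violations = violations),
            class = "annotation_verdict")
}

#' @export
print.annotation_verdict <- function(x, ...) {
  cat(sprintf("<annotation_verdict> %s: %s\n", x$model$gene_id,
              if (x$passed) "PASS" else
                paste0("FAIL (", nrow(x$violations), " violation(s))")))
  if (!x$passed) print(x$violations)
  invisible(x)
}

#' Re-annotate a genomic sequence against CDS evidence
#'
#' Finds the exon--intron model that maximises the spliced-CDS alignment score
#' to the best-scoring evidence sequence, subject to the hard constraints that
#' every intron begins GT and ends AG and that the spliced CDS maintains an
#' ORF. The search is an exact spliced-alignment dynamic programme; both
#' strands are tried and all evidence sequences are ranked by alignment score
#' (runner-up scores are reported in the result attributes). Models whose
#' evidence covers only part of the CDS, or whose spliced sequence fails ORF
#' checks, are flagged partial rather than silently returned as valid.
#'
#' @param genomic A genomic [seq_record()].
#' @param evidence_cds List of CDS/transcript [seq_record()] evidence
#'   (homologues or transcripts); at least one required.
#' @param search_window Genomic window (nt) retained around the best exact
#'   18-mer evidence anchor when the genomic sequence is large (default 5000).
#' @param match,mismatch,gap_open,gap_ext,intron_penalty,min_intron Spliced
#'   alignment scoring.
#' @return A [gene_model()] (attributes: `score`, `evidence_id`,
#'   `evidence_scores`), or `NULL` with a warning when no positive-scoring
#'   constraint-satisfying model exists.
#' @export
reannotate <- function(genomic, evidence_cds, search_window = 5000,
                       match = 2, mismatch = -3, gap_open = 5, gap_ext = 2,
                       intron_penalty = 4, min_intron = 4) {
  stopifnot(inherits(genomic, "seq_record"), length(evidence_cds) >= 1)
  if (inherits(evidence_cds, "seq_record")) evidence_cds <- list(evidence_cds)
  gseq <- genomic$residues
  offset <- 0L
  best <- NULL
  scores <- stats::setNames(numeric(length(evidence_cds)),
                            vapply(evidence_cds, `[[`, character(1), "id"))
  for (e in seq_along(evidence_cds)) {
    ev <- evidence_cds[[e]]
    region <- anchor_region(gseq, ev$residues, search_window)
    for (strand in c("+", "-")) {
      g <- if (strand == "+") substring(gseq, region[1L], region[2L])
           else revcomp(substring(gseq, region[1L], region[2L]))
      al <- .spliced_align(ev$residues, g, match, mismatch, gap_open, gap_ext,
                           intron_penalty, min_intron)
      if (al$score > scores[e]) scores[e] <- al$score
      if (al$score > 0 && nrow(al$exons) > 0 &&
          (is.null(best) || al$score > best$score)) {
        best <- al; best$strand <- strand; best$evidence <- ev
        best$region <- region
      }
    }
  }
  if (is.null(best)) {
    warning("no constraint-satisfying gene model found for '",
            genomic$id, "'")
    return(NULL)
  }
  ex <- best$exons
  rlen <- best$region[2L] - best$region[1L] + 1L
  if (best$strand == "-") {
    ex <- cbind(rlen - ex[, 2L] + 1L, rlen - ex[, 1L] + 1L)
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  ex <- ex + best$region[1L] - 1L
  ev <- best$evidence
  partial <- best$n_cds_deleted > 0 || identical(ev$complete, FALSE)
  model <- gene_model(paste0(genomic$id, ".m1"), genomic$id, best$strand,
                      data.frame(start = ex[, 1L], end = ex[, 2L]),
                      complete = !partial, partial = partial)
  cds <- spliced_cds(model, genomic)
  aa <- suppressWarnings(translate_cds(substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)))
  if (grepl("\\*", aa) || nchar(cds) %% 3L != 0L) {
    model$complete <- FALSE
    model$partial <- TRUE
  }
  attr(model, "score") <- best$score
  attr(model, "evidence_id") <- ev$id
  attr(model, "evidence_scores") <- sort(scores, decreasing = TRUE)
  model
}

# restrict the DP to a window around the best exact 18-mer anchor when the
# genomic sequence is much larger than the window
anchor_region <- function(gseq, cds, window) {
  n <- nchar(gseq)
  if (n <= 2L * window) return(c(1L, n))
  k <- 18L
  probes <- unique(pmax(1L, round(seq(1L, nchar(cds) - k, length.out = 8L))))
  for (p in probes) {
    hit <- regexpr(substr(cds, p, p + k - 1L), gseq, fixed = TRUE)
    if (hit > 0L)
      return(c(max(1L, hit - window), min(n, hit + window)))
  }
  c(1L, n)
}

#' Compare the exon--intron structure of two gene models
#'
#' Maps the intron positions of both models into shared protein-alignment
#' coordinates and reports, per aligned position, whether an intron is
#' conserved (with its length ratio) or present in only one model
#' ("additional intron"), plus UTR length differences. The comparison is
#' symmetric up to swapping the a/b labels.
#'
#' @param a,b [gene_model()] objects.
#' @param genomic_a,genomic_b Their genomic [seq_record()]s.
#' @param pairing Optional codon coordinate map, a data frame with columns
#'   `codon_a`, `codon_b` (NA for unaligned codons). Computed from a pairwise
#'   protein alignment of the two spliced CDS when omitted.
#' @return A `structure_diff` data frame: columns `type`
#'   (`intron_conserved`, `intron_gain_a`, `intron_gain_b`, `utr_diff`),
#'   `codon_a`, `codon_b`, `phase`, `len_a`, `len_b`, `ratio`.
#' @export
compare_structures <- function(a, b, genomic_a, genomic_b, pairing = NULL) {
  cds_a <- spliced_cds(a, genomic_a)
  cds_b <- spliced_cds(b, genomic_b)
  if (is.null(pairing)) {
    pa <- align_proteins(list(
      seq_record("..a", "a", "cds", cds_a, complete = a$complete),
      seq_record("..b", "b", "cds", cds_b, complete = b$complete)))
    pairing <- pairing_from_alignment(pa, "..a", "..b")
  }
  ia <- cds_introns(a)
  ib <- cds_introns(b)
  map_ab <- stats::setNames(pairing$codon_b, pairing$codon_a)
  rows <- list()
  used_b <- logical(nrow(ib))
  for (k in seq_len(nrow(ia))) {
    cb <- unname(map_ab[as.character(ia$codon[k])])
    j <- if (!is.na(cb))
      which(ib$codon == cb & ib$phase == ia$phase[k]) else integer(0)
    if (length(j)) {
      used_b[j[1L]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        type = "intron_conserved", codon_a = ia$codon[k], codon_b = cb,
        phase = ia$phase[k], len_a = ia$len[k], len_b = ib$len[j[1L]],
        ratio = ib$len[j[1L]] / ia$len[k])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "intron_gain_a", codon_a = ia$codon[k], codon_b = cb,
        phase = ia$phase[k], len_a = ia$len[k], len_b = NA_real_,
        ratio = NA_real_)
    }
  }
  for (j in which(!used_b))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "intron_gain_b", codon_a = NA_real_, codon_b = ib$codon[j],
      phase = ib$phase[j], len_a = NA_real_, len_b = ib$len[j],
      ratio = NA_real_)
  ua <- utr_intervals(a); ub <- utr_intervals(b)
  for (u in c("utr5", "utr3")) {
    la <- sum(ua[[u]]$end - ua[[u]]$start + 1L)
    lb <- sum(ub[[u]]$end - ub[[u]]$start + 1L)
    if (la != lb)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "utr_diff", codon_a = NA_real_, codon_b = NA_real_,
        phase = NA_real_, len_a = la, len_b = lb,
        ratio = if (la > 0) lb / la else NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), codon_a = numeric(0),
               codon_b = numeric(0), phase = numeric(0), len_a = numeric(0),
               len_b = numeric(0), ratio = numeric(0))
  class(out) <- c("structure_diff", "data.frame")
  out
}

# intron positions of a model in CDS coordinates: nt offset of the preceding
# exonic base (transcript orientation), expressed as codon index + phase
cds_introns <- function(m) {
  cds <- m$cds
  lens <- cds$end - cds$start + 1L
  if (m$strand == "-") lens <- rev(lens)
  n <- length(lens) - 1L
  if (n < 1L)
    return(data.frame(codon = integer(0), phase = integer(0), len = numeric(0)))
  pos <- cumsum(lens)[seq_len(n)]
  ord <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
  ilen <- (cds$start[-1L] - cds$end[-nrow(cds)] - 1L)[ord]
  data.frame(codon = (pos + 2L) %/% 3L, phase = pos %% 3L, len = ilen)
}

pairing_from_alignment <- function(pa, id_a, id_b) {
  ra <- strsplit(pa[[id_a]], "")[[1L]]
  rb <- strsplit(pa[[id_b]], "")[[1L]]
  ca <- cumsum(ra != "-"); ca[ra == "-"] <- NA
  cb <- cumsum(rb != "-"); cb[rb == "-"] <- NA
  data.frame(codon_a = ca, codon_b = cb)[!is.na(ca), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS and derived five_prime_UTR/three_prime_UTR
#' features per model (via rtracklayer).
#'
#' @param models List of [gene_model()] objects.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  feats <- list()
  add <- function(seqid, type, iv, strand, id = NULL, parent = NULL,
                  phase = NA_integer_) {
    if (!nrow(iv)) return()
    feats[[length(feats) + 1L]] <<- data.frame(
      seqid = seqid, start = iv$start, end = iv$end, strand = strand,
      type = type, ID = id %||% NA_character_,
      Parent = parent %||% NA_character_, phase = phase)
  }
  for (m in models) {
    span <- data.frame(start = min(m$exons$start), end = max(m$exons$end))
    add(m$genomic_id, "gene", span, m$strand, m$gene_id)
    mrna <- paste0(m$gene_id, ".t1")
    add(m$genomic_id, "mRNA", span, m$strand, mrna, m$gene_id)
    add(m$genomic_id, "exon", m$exons, m$strand, NULL, mrna)
    lens <- m$cds$end - m$cds$start + 1L
    if (m$strand == "-") lens <- rev(lens)
    before <- c(0L, cumsum(lens)[-length(lens)])
    ph <- (3L - before %% 3L) %% 3L
    if (m$strand == "-") ph <- rev(ph)
    add(m$genomic_id, "CDS", m$cds, m$strand, NULL, mrna, phase = ph)
    u <- utr_intervals(m)
    add(m$genomic_id, "five_prime_UTR", u$utr5, m$strand, NULL, mrna)
    add(m$genomic_id, "three_prime_UTR", u$utr3, m$strand, NULL, mrna)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type)
  gr$ID <- df$ID
  gr$Parent <- df$Parent
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reconstructs one [gene_model()] per gene feature from its exon and CDS
#' children (via rtracklayer).
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  out <- list()
  for (k in seq_along(genes)) {
    gid <- genes$ID[k]
    mrna <- gr[gr$type == "mRNA" & vapply(gr$Parent, function(p)
      gid %in% p, logical(1))]
    mid <- mrna$ID[1L]
    kids <- gr[vapply(gr$Parent, function(p) mid %in% p, logical(1))]
    ex <- kids[kids$type == "exon"]
    cds <- kids[kids$type == "CDS"]
    out[[gid]] <- gene_model(
      gid, as.character(GenomicRanges::seqnames(genes))[k],
      as.character(GenomicRanges::strand(genes))[k],
      data.frame(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)),
      if (length(cds)) data.frame(start = GenomicRanges::start(cds),
                                  end = GenomicRanges::end(cds)) else NULL)
  }
  out
}
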