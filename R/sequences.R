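#' @useDynLib orthoclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

MOLTYPES <- c("protein", "cds", "genomic")

#' Create a species-tagged sequence record
#'
#' The atom of every search and simulation: a single protein, CDS or genomic
#' sequence carrying its species of origin.
#'
#' @param id Unique identifier (unique within a [species_db()]).
#' @param species Species tag, e.g. `"barley"`.
#' @param moltype One of `"protein"`, `"cds"`, `"genomic"`.
#' @param residues Sequence string (amino acids or nucleotides, upper case).
#' @param complete For CDS records, whether the sequence is a full-length ORF;
#'   complete CDS must have length divisible by 3.
#' @param pseudogene Logical pseudogene flag (see [exclude_pseudogenes()]).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, species, moltype = c("protein", "cds", "genomic"),
                       residues, complete = NA, pseudogene = FALSE) {
  moltype <- match.arg(moltype)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("residues must be non-empty for record '", id, "'")
  if (moltype == "protein") {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", residues))
      stop("record '", id, "': non-amino-acid symbols in protein residues")
  } else {
    if (grepl("[^ACGTN]", residues))
      stop("record '", id, "': non-nucleotide symbols in ", moltype, " residues")
  }
  if (moltype == "cds" && isTRUE(complete) && nchar(residues) %% 3L != 0L)
    stop("record '", id, "': complete CDS length not divisible by 3")
  structure(list(id = id, species = species, moltype = moltype,
                 residues = residues, complete = complete,
                 pseudogene = isTRUE(pseudogene)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %s] %d residues%s\n", x$id, x$species,
              x$moltype, nchar(x$residues),
              if (x$pseudogene) " (pseudogene)" else ""))
  invisible(x)
}

#' Bundle records of one species into a searchable database
#'
#' All records must share the species tag and moltype; ids must be unique.
#'
#' @param species Species tag.
#' @param records List of [seq_record()] objects.
#' @return An object of class `species_db`.
#' @export
species_db <- function(species, records = list()) {
  if (length(records)) {
    stopifnot(all(vapply(records, inherits, logical(1), "seq_record")))
    sp <- vapply(records, `[[`, character(1), "species")
    mt <- vapply(records, `[[`, character(1), "moltype")
    ids <- vapply(records, `[[`, character(1), "id")
    if (!all(sp == species)) stop("records from species ", paste(unique(sp[sp != species]), collapse = ","),
                                  " in database for ", species)
    if (length(unique(mt)) > 1L) stop("mixed moltypes in database for ", species)
    if (anyDuplicated(ids)) stop("duplicate ids in database for ", species, ": ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ","))
    names(records) <- ids
  }
  structure(list(species = species, records = records,
                 moltype = if (length(records)) records[[1L]]$moltype else NA_character_),
            class = "species_db")
}

#' @export
print.species_db <- function(x, ...) {
  cat(sprintf("<species_db> %s: %d %s records\n", x$species,
              length(x$records), x$moltype))
  invisible(x)
}

#' Look up a record by id
#' @param db A [species_db()].
#' @param id Record identifier.
#' @return The matching `seq_record`; error if absent.
#' @export
db_get <- function(db, id) {
  rec <- db$records[[id]]
  if (is.null(rec)) stop("no record '", id, "' in database for ", db$species)
  rec
}

#' Translate a CDS to protein
#'
#' Standard-code translation; a trailing stop codon is trimmed.
#'
#' @param residues Nucleotide string, length divisible by 3 for full codons
#'   (trailing partial codon is dropped with a warning).
#' @return Amino-acid string (internal stops appear as `*`).
#' @export
translate_cds <- function(residues) {
  residues <- toupper(residues)
  extra <- nchar(residues) %% 3L
  if (extra != 0L) {
    warning("CDS length not divisible by 3; dropping ", extra, " trailing nt")
    residues <- substr(residues, 1L, nchar(residues) - extra)
  }
  L <- nchar(residues)
  if (!L) return("")
  codons <- substring(residues, seq(1L, L, 3L), seq(3L, L, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # any codon with N/ambiguity
  sub("\\*$", "", paste(aa, collapse = ""))
}

#' Reverse-complement a nucleotide string
#' @param x Nucleotide string.
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a FASTA file into a species database
#'
#' The species is taken from a `[species=...]` tag in the header if present,
#' else from `species`, else from the file name (basename without extension).
#'
#' @param path FASTA file.
#' @param moltype Moltype of all records in the file.
#' @param species Fallback species tag.
#' @return A [species_db()].
#' @export
read_fasta_db <- function(path, moltype = c("protein", "cds", "genomic"),
                          species = NULL) {
  moltype <- match.arg(moltype)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fallback <- species %||% sub("\\.[^.]*$", "", basename(path))
  sp_of <- vapply(headers, function(h) {
    tag <- regmatches(h, regexpr("\\[species=[^]]+\\]", h))
    if (length(tag)) sub("\\[species=([^]]+)\\]", "\\1", tag) else fallback
  }, character(1), USE.NAMES = FALSE)
  if (length(unique(sp_of)) > 1L)
    stop("FASTA mixes species (", paste(unique(sp_of), collapse = ","),
         "); a species database holds one species")
  ids <- sub("\\s.*$", "", headers)
  pseudo <- grepl("\\[pseudogene\\]", headers)
  recs <- lapply(seq_along(set), function(i)
    seq_record(ids[i], sp_of[i], moltype, as.character(set[[i]]),
               pseudogene = pseudo[i]))
  species_db(sp_of[1L], recs)
}

#' Write sequence records to FASTA
#'
#' Headers carry the `[species=...]` tag so [read_fasta_db()] round-trips.
#'
#' @param records List of [seq_record()] objects (or a `species_db`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "species_db")) records <- records$records
  lines <- unlist(lapply(records, function(r) {
    hdr <- sprintf(">%s [species=%s]%s", r$id, r$species,
                   if (r$pseudogene) " [pseudogene]" else "")
    c(hdr, gsub("(.{60})", "\\1\n", r$residues, perl = TRUE))
  }), use.names = FALSE)
  writeLines(sub("\n$", "", lines), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
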