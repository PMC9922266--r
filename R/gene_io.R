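#' Construct a validated gene set
#'
#' A gene set is a plain `data.frame` with one row per gene and the columns
#' `gene_id` (unique, non-empty class label), `description` (free text,
#' typically the full FASTA header), `sequence` (upper-case DNA over
#' A/C/G/T/N) and `length` (nucleotide count). All package operations that
#' take "genes" accept this container.
#'
#' @param gene_id character vector of unique, non-empty identifiers.
#' @param sequence character vector of DNA sequences; folded to upper case.
#'   Characters outside A/C/G/T/N are rejected with an error naming the
#'   offending gene.
#' @param description optional character vector of free-text descriptions;
#'   defaults to `gene_id`.
#' @return A `data.frame` with columns `gene_id`, `description`, `sequence`,
#'   `length`.
#' @examples
#' gene_set(c("g1", "g2"), c("CATCATCATCAT", "ACGTACGT"))
#' @export
gene_set <- function(gene_id, sequence, description = gene_id) {
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  description <- as.character(description)
  if (length(gene_id) != length(sequence))
    stop("gene_id and sequence must have the same length")
  if (any(!nzchar(gene_id)))
    stop("empty gene_id at position ", which(!nzchar(gene_id))[1])
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", dup[1])
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence of gene '", gene_id[bad][1],
         "' contains characters outside A/C/G/T/N")
  data.frame(gene_id = gene_id,
             description = rep_len(description, length(gene_id)),
             sequence = sequence,
             length = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Read a gene set from a FASTA file
#'
#' Each record becomes one gene; `gene_id` is the first whitespace-delimited
#' token of the header and the full header is kept as `description`.
#' Sequences are folded to upper case; characters outside A/C/G/T/N, empty
#' sequences and duplicate identifiers are rejected with an error naming the
#' offending record. Record order is preserved.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return A gene set `data.frame` (see [gene_set()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(recs) == 0)
    stop("no records in FASTA file: ", path)
  headers <- names(recs)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    stop("malformed FASTA '", path, "': record with empty header")
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[`, character(1), 1L)
  seqs <- as.character(recs)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[empty][1], "' in ", path)
  gene_set(ids, seqs, description = trimws(headers))
}

#' Write a gene set to a FASTA file
#'
#' Records are emitted unwrapped (one sequence line per gene), headed by the
#' stored description. `read_fasta(write_fasta(g, path))` reproduces the
#' identifiers and sequences of `g`.
#'
#' @param genes a non-empty gene set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path) {
  check_gene_set(genes)
  if (nrow(genes) == 0)
    stop("refusing to write an empty gene set")
  x <- Biostrings::BStringSet(genes$sequence)
  names(x) <- genes$description
  Biostrings::writeXStringSet(x, path, width = max(genes$length, 1L))
  invisible(path)
}

#' Dataset-inclusion filter on tandem-repeat content
#'
#' Retains exactly the genes whose tandem-repeat scan yields at least one
#' tract with a repeat unit in `ru_subset` (or any unit when `"any"`) and a
#' repeat count of at least `min_rc`. With the defaults this is the standard
#' inclusion rule: keep genes carrying at least one trinucleotide repeat unit
#' repeated more than three times. The filter is idempotent and may return an
#' empty set.
#'
#' @param genes a gene set.
#' @param ru_subset character vector of repeat units, or `"any"`.
#' @param min_rc minimum repeat count a qualifying tract must reach.
#' @param motif_len repeat-unit length in nucleotides (default 3).
#' @return The filtered gene set, rows in their original order.
#' @export
filter_gene_set <- function(genes, ru_subset = "any", min_rc = 4L,
                            motif_len = 3L) {
  check_gene_set(genes)
  min_rc <- as.integer(min_rc)
  if (min_rc < 1L) stop("min_rc must be >= 1")
  keep <- vapply(genes$sequence, function(s) {
    tr <- scan_tandem_repeats(s, motif_len = motif_len, min_rc = min_rc)
    if (nrow(tr) == 0) return(FALSE)
    if (identical(ru_subset, "any")) TRUE else any(tr$ru %in% ru_subset)
  }, logical(1), USE.NAMES = FALSE)
  genes[keep, , drop = FALSE]
}

check_gene_set <- function(genes) {
  if (!is.data.frame(genes) ||
      !all(c("gene_id", "sequence", "length") %in% names(genes)))
    stop("expected a gene set data.frame with gene_id/sequence/length columns")
  invisible(genes)
}
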