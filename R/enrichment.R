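#' The repeat-unit universe
#'
#' All `4^motif_len` motifs over A/C/G/T in alphabetical order; 64
#' trinucleotides with the default.
#'
#' @param motif_len motif length in nucleotides.
#' @return Character vector of motifs.
#' @export
ru_universe <- function(motif_len = 3L) {
  bases <- c("A", "C", "G", "T")
  out <- ""
  for (i in seq_len(motif_len))
    out <- as.vector(t(outer(out, bases, paste0)))
  sort(out)
}

#' Normalize a repeat profile
#'
#' Turns the per-unit repeat sums (RS) of one gene into an enrichment value
#' under one of four schemes:
#' \describe{
#'   \item{raw}{the repeat sum unchanged.}
#'   \item{len}{RS divided by the gene length (between-gene factor: longer
#'     genes carry more repeats).}
#'   \item{cnt}{RS divided by the summed RS over the gene's present units
#'     (within-gene composition; rows sum to 1).}
#'   \item{mm}{min-max: `(RS - min RS) / (max RS - min RS)` over the gene's
#'     present units, defined as 0 when the range is 0 (single unit or all
#'     units tied).}
#' }
#'
#' @param profile a [build_profile()] result.
#' @param scheme one of `"raw"`, `"len"`, `"cnt"`, `"mm"`.
#' @return Named numeric vector over the units present in the profile;
#'   empty profile gives an empty vector.
#' @export
normalize_profile <- function(profile,
                              scheme = c("raw", "len", "cnt", "mm")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(profile, "repeat_profile"))
  if (scheme == "len" && profile$length == 0)
    stop("zero-length gene: ", profile$gene_id)
  rs <- profile$rs
  if (length(rs) == 0) return(stats::setNames(numeric(0), character(0)))
  switch(scheme,
    raw = rs,
    len = rs / profile$length,
    cnt = rs / sum(rs),
    mm = {
      rng <- max(rs) - min(rs)
      if (rng == 0) stats::setNames(rep(0, length(rs)), names(rs))
      else (rs - min(rs)) / rng
    })
}

#' Build a cohort enrichment table
#'
#' One row per gene, one column per repeat unit of the universe. Units
#' absent from a gene (no tract with `rc >= min_rc`) carry `NA`, which is
#' distinct from an explicit zero; downstream tests decide how to treat
#' absence via their `zero_fill` flag.
#'
#' @param genes a non-empty gene set.
#' @param scheme normalization scheme, see [normalize_profile()].
#' @param motif_len,min_rc scanner parameters.
#' @return A `data.frame` with `rownames` = gene ids and the scheme,
#'   `motif_len` and `min_rc` recorded as attributes (class
#'   `enrichment_table`).
#' @export
build_table <- function(genes, scheme = c("raw", "len", "cnt", "mm"),
                        motif_len = 3L, min_rc = 4L) {
  scheme <- match.arg(scheme)
  check_gene_set(genes)
  if (nrow(genes) == 0) stop("empty gene set")
  universe <- ru_universe(motif_len)
  vals <- matrix(NA_real_, nrow = nrow(genes), ncol = length(universe),
                 dimnames = list(genes$gene_id, universe))
  for (i in seq_len(nrow(genes))) {
    p <- build_profile(genes[i, , drop = FALSE], motif_len = motif_len,
                       min_rc = min_rc)
    v <- normalize_profile(p, scheme)
    vals[i, names(v)] <- v
  }
  out <- as.data.frame(vals)
  attr(out, "scheme") <- scheme
  attr(out, "motif_len") <- as.integer(motif_len)
  attr(out, "min_rc") <- as.integer(min_rc)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Per-unit descriptive statistics of an enrichment table
#'
#' Mean, maximum, minimum and sample standard deviation of the (normalized)
#' repeat sums for each unit of the universe. With
#' `include_absent_as_zero = FALSE` the statistics run over the genes
#' carrying the unit; with `TRUE` absent genes enter as zeros so the
#' statistics run over the whole cohort. Units carried by a single gene get
#' `sd = 0`; units absent from every gene get `NA` moments.
#'
#' @param table an [build_table()] result.
#' @param include_absent_as_zero treat absent units as zero enrichment.
#' @return A `data.frame` with columns `ru`, `n_genes` (carriers), `mean`,
#'   `max`, `min`, `sd`.
#' @export
summarize_rus <- function(table, include_absent_as_zero = FALSE) {
  stopifnot(inherits(table, "enrichment_table"), nrow(table) > 0)
  stats_one <- function(u) {
    x <- table[[u]]
    n_car <- sum(!is.na(x))
    if (n_car == 0)
      return(c(0, NA_real_, NA_real_, NA_real_, NA_real_))
    if (include_absent_as_zero) x[is.na(x)] <- 0 else x <- x[!is.na(x)]
    s <- if (length(x) > 1) stats::sd(x) else 0
    c(n_car, mean(x), max(x), min(x), s)
  }
  m <- t(vapply(names(table), stats_one, numeric(5)))
  data.frame(ru = names(table), n_genes = as.integer(m[, 1]),
             mean = m[, 2], max = m[, 3], min = m[, 4], sd = m[, 5],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#'
#' Rows are genes, columns the repeat-unit universe; absent units are empty
#' cells.
#'
#' @param table an enrichment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  out <- cbind(gene_id = rownames(table), as.data.frame(table))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
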