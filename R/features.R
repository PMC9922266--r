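#' First-encountered mode of a repeat-count collection
#'
#' The most frequent value; among equally frequent values the one whose
#' first occurrence comes earliest in scan order. This is the
#' "most common repeat count" feature.
#'
#' @param rcs non-empty integer vector in scan order.
#' @return A single value from `rcs`.
#' @examples
#' first_mode(c(6, 4, 4))  # 4
#' first_mode(c(5, 5, 4, 4))  # 5
#' @export
first_mode <- function(rcs) {
  if (length(rcs) == 0) stop("first_mode of an empty collection")
  ux <- unique(rcs)
  ux[which.max(tabulate(match(rcs, ux)))]
}

#' Build the repeat-count feature matrix
#'
#' Every gene contributes exactly three rows: the maximum, minimum and
#' most-common (first-encountered mode) repeat count per selected repeat
#' unit, from the gene's tract scan at `min_rc`. Units absent from a gene
#' are encoded as 0 in all three rows. The raw rows are then normalized:
#' \describe{
#'   \item{raw}{repeat counts unchanged.}
#'   \item{len}{divided by the gene length.}
#'   \item{cnt}{divided by the summed repeat sums of the gene's full
#'     profile (all units at `min_rc`, not just the selected ones).}
#'   \item{mm}{min-max over the gene's full repeat-sum profile,
#'     `(x - min RS) / (max RS - min RS)`, 0 when the range is 0. Values
#'     may fall outside `[0, 1]` because a repeat count can lie outside the
#'     gene's repeat-sum range.}
#'   \item{zsc}{per-column z-score `(x - mean) / sd` with the sample
#'     (`n - 1`) standard deviation, fitted over this matrix, or taken from
#'     `fit_stats` to transform held-out data without leakage;
#'     zero-variance columns map to 0.}
#' }
#'
#' @param genes a gene set; every gene must carry at least one selected
#'   unit at `min_rc` (pre-filter with [filter_gene_set()]).
#' @param selected ordered character vector of selected repeat units
#'   (the feature columns).
#' @param min_rc,motif_len scanner parameters.
#' @param norm_scheme one of `"raw"`, `"len"`, `"cnt"`, `"mm"`, `"zsc"`.
#' @param fit_stats optional `fit_stats` component of a previously built
#'   z-scored matrix, reused to transform new data.
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix, `3 * n_genes` rows), `raw` (pre-normalization
#'   matrix), `gene_id`, `variant` (`"max"`, `"min"`, `"most"` per row),
#'   `selected`, `norm_scheme` and `fit_stats` (per-column mean/sd for
#'   `zsc`, otherwise `NULL`).
#' @export
build_features <- function(genes, selected, min_rc = 4L,
                           norm_scheme = c("raw", "len", "cnt", "mm", "zsc"),
                           fit_stats = NULL, motif_len = 3L) {
  norm_scheme <- match.arg(norm_scheme)
  check_gene_set(genes)
  stopifnot(length(selected) > 0)
  n <- nrow(genes)
  variants <- c("max", "min", "most")
  raw <- matrix(0, nrow = 3 * n, ncol = length(selected),
                dimnames = list(NULL, selected))
  vals <- raw
  gene_id <- rep(genes$gene_id, each = 3)
  variant <- rep(variants, times = n)
  rownames(raw) <- rownames(vals) <- paste(gene_id, variant, sep = "|")
  for (i in seq_len(n)) {
    p <- build_profile(genes[i, , drop = FALSE], motif_len = motif_len,
                       min_rc = min_rc)
    if (!any(selected %in% names(p$rs)))
      stop("gene '", genes$gene_id[i],
           "' carries none of the selected repeat units at min_rc = ",
           min_rc)
    rows <- (i - 1) * 3 + 1:3
    for (u in intersect(selected, names(p$rs))) {
      rc <- p$rc_lists[[u]]
      raw[rows, u] <- c(max(rc), min(rc), first_mode(rc))
    }
    vals[rows, ] <- switch(norm_scheme,
      raw = raw[rows, , drop = FALSE],
      len = raw[rows, , drop = FALSE] / p$length,
      cnt = raw[rows, , drop = FALSE] / sum(p$rs),
      mm = {
        rng <- max(p$rs) - min(p$rs)
        if (rng == 0) matrix(0, 3, length(selected))
        else (raw[rows, , drop = FALSE] - min(p$rs)) / rng
      },
      zsc = raw[rows, , drop = FALSE])
  }
  out_stats <- NULL
  if (norm_scheme == "zsc") {
    if (is.null(fit_stats)) {
      mu <- colMeans(vals)
      sd_ <- apply(vals, 2, stats::sd)
      fit_stats <- list(mean = mu, sd = sd_)
    }
    vals <- zscore_apply(vals, fit_stats)
    out_stats <- fit_stats
  }
  structure(list(values = vals, raw = raw, gene_id = gene_id,
                 variant = variant, selected = selected,
                 norm_scheme = norm_scheme, fit_stats = out_stats,
                 min_rc = as.integer(min_rc),
                 motif_len = as.integer(motif_len)),
            class = "feature_matrix")
}

# Apply stored column statistics; sd of 0 (or NA) maps the column to 0.
zscore_apply <- function(x, fit_stats) {
  mu <- fit_stats$mean[colnames(x)]
  sd_ <- fit_stats$sd[colnames(x)]
  out <- sweep(x, 2, mu, `-`)
  ok <- !is.na(sd_) & sd_ > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, sd_[ok], `/`)
  out[, !ok] <- 0
  out
}

#' Write a feature matrix as TSV
#'
#' Row labels are `gene_id|variant`; the normalization scheme is recorded
#' in a header comment line.
#'
#' @param features a [build_features()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# norm_scheme=", features$norm_scheme), con)
  out <- data.frame(row = rownames(features$values),
                    features$values, check.names = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix:", nrow(x$values), "rows (",
      length(unique(x$gene_id)), "genes x 3 variants ),",
      ncol(x$values), "repeat units,", x$norm_scheme, "normalization\n")
  invisible(x)
}
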