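#' Greedy scan for maximal tandem repeat tracts
#'
#' Makes a single left-to-right pass over the sequence. At cursor position
#' `i` (0-based) the scanner counts the maximal number `k` of adjacent copies
#' of the `motif_len`-mer starting at `i`. If `k >= min_rc` a tract is
#' emitted and the cursor jumps past it (`i + motif_len * k`); otherwise the
#' cursor advances by one nucleotide. The jump-on-emit rule means cyclic
#' rotations inside an emitted tract are never re-reported, while
#' sub-threshold runs never hide a qualifying run in a shifted frame.
#' A motif containing `N` never starts a tract.
#'
#' @param sequence a single DNA string over A/C/G/T/N (lower case folded).
#' @param motif_len motif length in nucleotides; the trinucleotide default
#'   gives the 64-unit repeat alphabet used throughout the package.
#' @param min_rc minimum repeat count for a tract to be reported. The
#'   default of 4 is the usual human cut-off (repeat unit present more than
#'   three times); it is a tunable parameter.
#' @return A `data.frame` with columns `ru` (motif), `start` (0-based
#'   offset), `rc` (repeat count) and `span` (`motif_len * rc` nucleotides),
#'   tracts non-overlapping and in ascending `start` order.
#' @examples
#' scan_tandem_repeats("CATCATCATCATG")
#' @export
scan_tandem_repeats <- function(sequence, motif_len = 3L, min_rc = 4L) {
  stopifnot(length(sequence) == 1L, !is.na(sequence))
  motif_len <- as.integer(motif_len)
  min_rc <- as.integer(min_rc)
  if (motif_len < 1L) stop("motif_len must be >= 1")
  if (min_rc < 1L) stop("min_rc must be >= 1")
  s <- toupper(sequence)
  L <- nchar(s)
  empty <- data.frame(ru = character(0), start = integer(0),
                      rc = integer(0), span = integer(0),
                      stringsAsFactors = FALSE)
  if (L < motif_len * min_rc) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A/C/G/T/N")
  w <- motif_len
  # ext[i] = length of the run of positions j >= i with ch[j] == ch[j + w]
  # (N never matches); adjacent copies of the motif at i are 1 + ext[i] %/% w
  ext <- integer(L)
  if (L > w) {
    idx <- seq_len(L - w)
    m <- ch[idx] == ch[idx + w] & ch[idx] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths))
      if (r$values[j]) ext[starts[j]:ends[j]] <- rev(seq_len(r$lengths[j]))
  }
  ru <- character(0); start <- integer(0); rc <- integer(0)
  i <- 1L
  last <- L - w + 1L
  while (i <= last) {
    k <- 1L + ext[i] %/% w
    if (k >= min_rc && !anyNA(match(ch[i:(i + w - 1L)],
                                    c("A", "C", "G", "T")))) {
      ru <- c(ru, substr(s, i, i + w - 1L))
      start <- c(start, i - 1L)
      rc <- c(rc, k)
      i <- i + w * k
    } else {
      i <- i + 1L
    }
  }
  data.frame(ru = ru, start = start, rc = rc, span = w * rc,
             stringsAsFactors = FALSE)
}

#' Build a per-gene repeat profile
#'
#' Aggregates the tracts of one gene into the per-repeat-unit structures
#' used downstream: `rc_lists` maps each repeat unit to its ordered
#' repeat-count collection (scan order) and `rs` maps it to the repeat sum,
#' the sum of those counts. The repeat sum is the package's enrichment
#' metric: it accumulates every tract of a unit across the whole gene rather
#' than only the longest one.
#'
#' @param gene a one-row gene set, or a single DNA string.
#' @param gene_id identifier used when `gene` is a bare string.
#' @param motif_len,min_rc scanner parameters, see [scan_tandem_repeats()].
#' @return An object of class `repeat_profile`: a list with elements
#'   `gene_id`, `length`, `tracts` (tract table), `rc_lists` (named list of
#'   integer vectors) and `rs` (named numeric vector).
#' @examples
#' p <- build_profile(demo_gene())
#' p$rs
#' @export
build_profile <- function(gene, gene_id = "gene", motif_len = 3L,
                          min_rc = 4L) {
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    sequence <- gene$sequence
    gene_id <- gene$gene_id
  } else {
    sequence <- as.character(gene)
  }
  tracts <- scan_tandem_repeats(sequence, motif_len = motif_len,
                                min_rc = min_rc)
  rc_lists <- split(tracts$rc, factor(tracts$ru, levels = unique(tracts$ru)))
  rs <- vapply(rc_lists, sum, numeric(1))
  structure(list(gene_id = gene_id,
                 length = nchar(sequence),
                 tracts = tracts,
                 rc_lists = rc_lists,
                 rs = rs,
                 motif_len = as.integer(motif_len),
                 min_rc = as.integer(min_rc)),
            class = "repeat_profile")
}

#' Scan every gene of a set
#'
#' @param genes a gene set.
#' @param motif_len,min_rc scanner parameters, see [scan_tandem_repeats()].
#' @return One tract table with a leading `gene_id` column.
#' @export
scan_gene_set <- function(genes, motif_len = 3L, min_rc = 4L) {
  check_gene_set(genes)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    tr <- scan_tandem_repeats(genes$sequence[i], motif_len, min_rc)
    if (nrow(tr)) cbind(gene_id = genes$gene_id[i], tr,
                        stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), ru = character(0),
                      start = integer(0), rc = integer(0), span = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("repeat profile for", x$gene_id, "(", x$length, "nt )\n")
  if (length(x$rs) == 0) {
    cat("  no tracts with rc >=", x$min_rc, "\n")
  } else {
    for (u in names(x$rs))
      cat(sprintf("  %s: rs = %g, rc = [%s]\n", u, x$rs[[u]],
                  paste(x$rc_lists[[u]], collapse = ", ")))
  }
  invisible(x)
}
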