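#' Per-repeat-unit Mann-Whitney U tests between two cohorts
#'
#' For each repeat unit of the universe the two samples are the per-gene
#' normalized repeat sums of the two cohorts. Genes lacking the unit are
#' excluded when `zero_fill` is off (the default) and included as zeros when
#' it is on. The test is two-sided. When both samples have at most eight
#' observations the p-value comes from exhaustive enumeration of the
#' rank-label permutations (ties handled through midranks); for larger
#' samples the normal approximation with tie and continuity correction is
#' used. Units with an empty sample in either cohort are skipped with a
#' recorded reason.
#'
#' @param tableA,tableB enrichment tables built with the same scheme.
#' @param zero_fill include genes lacking the unit as zero enrichment.
#' @return A `data.frame` of class `ru_test` with columns `ru`, `n_a`,
#'   `n_b`, `u_stat` (U of cohort A), `p_raw` and `note` (skip reason or
#'   `""`).
#' @export
mwu_per_ru <- function(tableA, tableB, zero_fill = FALSE) {
  stopifnot(inherits(tableA, "enrichment_table"),
            inherits(tableB, "enrichment_table"))
  if (!identical(attr(tableA, "scheme"), attr(tableB, "scheme")))
    stop("cohort tables use different normalization schemes: ",
         attr(tableA, "scheme"), " vs ", attr(tableB, "scheme"))
  universe <- names(tableA)
  res <- lapply(universe, function(u) {
    xa <- tableA[[u]]; xb <- tableB[[u]]
    if (zero_fill) {
      xa[is.na(xa)] <- 0; xb[is.na(xb)] <- 0
    } else {
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    }
    if (length(xa) == 0 || length(xb) == 0) {
      side <- if (length(xa) == 0) "A" else "B"
      return(data.frame(ru = u, n_a = length(xa), n_b = length(xb),
                        u_stat = NA_real_, p_raw = NA_real_,
                        note = paste0("skipped: no observations in cohort ",
                                      side),
                        stringsAsFactors = FALSE))
    }
    t <- mwu_test(xa, xb)
    data.frame(ru = u, n_a = length(xa), n_b = length(xb),
               u_stat = t$u, p_raw = t$p, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "scheme") <- attr(tableA, "scheme")
  class(out) <- c("ru_test", "data.frame")
  out
}

# Two-sided Mann-Whitney U. U is the number of (a, b) pairs with a > b,
# ties counted 1/2 (equivalently the rank-sum form). Exact permutation
# enumeration for small samples, otherwise the tie- and continuity-corrected
# normal approximation of stats::wilcox.test.
mwu_test <- function(x, y, exact_max_n = 8L) {
  n_a <- length(x); n_b <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a <= exact_max_n && n_b <= exact_max_n) {
    combs <- utils::combn(n_a + n_b, n_a)
    offset <- n_a * (n_a + 1) / 2
    u_perm <- colSums(matrix(r[combs], nrow = n_a)) - offset
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_perm <= u + eps), mean(u_perm >= u - eps)))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
  }
  list(u = u, p = p)
}

#' Two-stage step-up false discovery rate adjustment
#'
#' The adaptive two-stage linear step-up procedure: stage one runs the
#' linear step-up test at level `q' = q / (1 + q)` and counts `r1`
#' rejections, giving the null-proportion estimate `m0 = m - r1`; unless
#' `r1` is 0 or `m`, stage two re-runs the step-up test at level
#' `q' * m / m0`. Adjusted p-values are the monotone step-up values scaled
#' by `(m0 / m) * (1 + q)` and clipped to `[0, 1]`, so that
#' `p_adj <= q` reproduces the stage-two rejection decision (they are
#' specific to the chosen `q` and may fall below the raw p). A significance
#' tier is attached from the adjusted p-value.
#'
#' @param results a [mwu_per_ru()] result (rows with `NA` `p_raw` pass
#'   through unadjusted).
#' @param q target false discovery rate, default 0.1.
#' @return `results` with added columns `p_adj`, `significant` and `tier`
#'   (`"p<0.001"`, `"p<0.01"`, `"p<0.05"` or `"ns"`).
#' @export
adjust_two_stage <- function(results, q = 0.1) {
  stopifnot(is.data.frame(results), "p_raw" %in% names(results),
            q > 0, q < 1)
  out <- results
  out$p_adj <- NA_real_
  out$significant <- NA
  tested <- which(!is.na(out$p_raw))
  if (length(tested)) {
    p <- out$p_raw[tested]
    m <- length(p)
    qp <- q / (1 + q)
    bh <- stats::p.adjust(p, method = "BH")
    r1 <- sum(bh <= qp)
    if (r1 == 0 || r1 == m) {
      p_adj <- pmin(1, bh * (1 + q))
      sig <- bh <= qp
    } else {
      m0 <- m - r1
      sig <- bh <= qp * m / m0
      p_adj <- pmin(1, bh * (m0 / m) * (1 + q))
    }
    out$p_adj[tested] <- p_adj
    out$significant[tested] <- sig
  }
  out$tier <- ifelse(is.na(out$p_adj), NA_character_,
              ifelse(out$p_adj < 0.001, "p<0.001",
              ifelse(out$p_adj < 0.01, "p<0.01",
              ifelse(out$p_adj < 0.05, "p<0.05", "ns"))))
  attr(out, "q") <- q
  class(out) <- c("ru_test", "data.frame")
  out
}

#' Rank repeat units into most- and least-significant sets
#'
#' The most significant repeat units (MSRU) are the first `k_msru` by
#' ascending adjusted p-value; the least significant (LSRU) the first
#' `k_lsru` by descending adjusted p-value after removing any unit already
#' ranked most-significant, so the two sets never overlap. Ties are broken
#' by ascending raw p, then alphabetically, making the ranking
#' deterministic.
#'
#' @param results an adjusted [mwu_per_ru()] result (see
#'   [adjust_two_stage()]).
#' @param k_msru,k_lsru prefix sizes; their sum must not exceed the number
#'   of tested units.
#' @return An object of class `ranked_rus`: `list(msru = ..., lsru = ...)`.
#' @export
rank_rus <- function(results, k_msru, k_lsru) {
  stopifnot(is.data.frame(results), "p_adj" %in% names(results))
  tested <- results[!is.na(results$p_adj), , drop = FALSE]
  n <- nrow(tested)
  if (k_msru + k_lsru > n)
    stop("k_msru + k_lsru (", k_msru + k_lsru,
         ") exceeds the ", n, " tested repeat units; sets would overlap")
  asc <- tested[order(tested$p_adj, tested$p_raw, tested$ru), ]
  msru <- utils::head(asc$ru, k_msru)
  desc <- tested[order(-tested$p_adj, tested$p_raw, tested$ru), ]
  lsru <- utils::head(setdiff(desc$ru, msru), k_lsru)
  structure(list(msru = msru, lsru = lsru), class = "ranked_rus")
}

#' Write a significance table as TSV
#'
#' @param results an adjusted and optionally ranked test result.
#' @param path output path.
#' @param ranked optional [rank_rus()] result; adds `msru_rank` and
#'   `lsru_rank` columns.
#' @return `path`, invisibly.
#' @export
write_significance_tsv <- function(results, path, ranked = NULL) {
  out <- as.data.frame(results)
  if (!is.null(ranked)) {
    out$msru_rank <- match(out$ru, ranked$msru)
    out$lsru_rank <- match(out$ru, ranked$lsru)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
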