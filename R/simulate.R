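#' The 64-nt worked-example gene
#'
#' A canonical demonstration sequence carrying three CAT tracts (6, 4 and 4
#' copies at offsets 0, 21 and 34) and one AAG tract (4 copies at offset
#' 46), separated by spacers verified free of any other trinucleotide
#' tandem with four or more copies. Its repeat profile has
#' `rs = c(CAT = 14, AAG = 4)`, max/min/most-common CAT repeat counts of
#' 6/4/4 and a longest tract of 18 nt.
#'
#' @return A one-row gene set.
#' @examples
#' build_profile(demo_gene())$rs
#' @export
demo_gene <- function() {
  gene_set("demo_gene",
           paste0("CATCATCATCATCATCAT", "GCG", "CATCATCATCAT", "G",
                  "CATCATCATCAT", "AAGAAGAAGAAG", "CTGGTC"),
           description = paste("demo_gene 64-nt worked example with three",
                               "CAT tracts and one AAG tract"))
}

#' Generate a spacer that plants no unintended repeats
#'
#' Draws random A/C/G/T bases and verifies by brute-force scan that the
#' concatenation `left + spacer + right` contains exactly the tandem tracts
#' of `left` and `right` alone: the spacer neither introduces a new tract
#' of any repeat unit nor extends an adjacent tract. Draws are retried up
#' to `max_tries` times; an impossible construction (e.g. a zero-length
#' spacer between two tracts of the same unit) fails with an error.
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param length spacer length in nucleotides (>= 0).
#' @param left,right flanking context sequences (may be `""`).
#' @param motif_len,min_rc scanner parameters defining "unintended tract".
#' @param max_tries bounded number of redraws.
#' @return The spacer string.
#' @export
neutral_spacer <- function(length, left = "", right = "", motif_len = 3L,
                           min_rc = 4L, max_tries = 100L) {
  stopifnot(length >= 0)
  expected <- rbind(
    scan_tandem_repeats(left, motif_len, min_rc),
    within(scan_tandem_repeats(right, motif_len, min_rc),
           start <- start + nchar(left) + as.integer(length)))
  for (i in seq_len(max_tries)) {
    sp <- if (length == 0) "" else
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    got <- scan_tandem_repeats(paste0(left, sp, right), motif_len, min_rc)
    if (nrow(got) == nrow(expected) &&
        all(got$ru == expected$ru) && all(got$start == expected$start) &&
        all(got$rc == expected$rc))
      return(sp)
    if (length == 0) break
  }
  stop("could not build a neutral spacer of length ", length,
       " between the given contexts after ", max_tries, " tries")
}

#' Specify a two-cohort simulation with planted repeat tracts
#'
#' Defines the study conditions for the synthetic-cohort generator: each
#' gene of both cohorts carries one tract (per `tracts_per_gene`) of every
#' planted repeat unit, with repeat counts drawn as
#' `min_rc + Poisson(rc_base_mean)`; the shifted units get `rc_shift`
#' extra copies in cohort A only, all other units staying exchangeable
#' between cohorts. The defaults describe a moderate two-cohort design: 60
#' genes per cohort, 600-nt genes, ten planted units of which five are
#' shifted by four extra copies.
#'
#' @param n_genes genes per cohort.
#' @param gene_length gene length in nucleotides (single value).
#' @param planted_rus distinct trinucleotide units planted in every gene.
#' @param shifted_rus subset of `planted_rus` whose repeat-count
#'   distribution is shifted in cohort A.
#' @param rc_base_mean Poisson mean of the repeat-count excess over
#'   `min_rc`.
#' @param rc_shift between-cohort shift in repeat copies.
#' @param tracts_per_gene tracts planted per unit per gene.
#' @param min_rc,motif_len scanner parameters.
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 60L, gene_length = 600L,
                     planted_rus = c("CAT", "AAG", "ATC", "GTC", "TTA",
                                     "CCG", "ACA", "GGA", "TGA", "CTT"),
                     shifted_rus = c("CAT", "AAG", "ATC", "GTC", "TTA"),
                     rc_base_mean = 2, rc_shift = 4L, tracts_per_gene = 1L,
                     min_rc = 4L, motif_len = 3L, seed = 1L) {
  stopifnot(n_genes >= 1, gene_length >= 1, tracts_per_gene >= 1,
            rc_base_mean >= 0, rc_shift >= 0, min_rc >= 2)
  if (any(nchar(planted_rus) != motif_len) ||
      any(grepl("[^ACGT]", planted_rus)))
    stop("planted_rus must be motifs of length ", motif_len, " over ACGT")
  if (anyDuplicated(planted_rus)) stop("planted_rus must be distinct")
  if (!all(shifted_rus %in% planted_rus))
    stop("shifted_rus must be a subset of planted_rus")
  n_tracts <- length(planted_rus) * tracts_per_gene
  min_span <- n_tracts * motif_len * min_rc + 2 * (n_tracts + 1)
  if (gene_length < min_span)
    stop("infeasible spec: gene_length ", gene_length, " cannot hold ",
         n_tracts, " tracts plus spacers (needs >= ", min_span, ")")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 planted_rus = planted_rus, shifted_rus = shifted_rus,
                 rc_base_mean = rc_base_mean,
                 rc_shift = as.integer(rc_shift),
                 tracts_per_gene = as.integer(tracts_per_gene),
                 min_rc = as.integer(min_rc),
                 motif_len = as.integer(motif_len),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate two synthetic cohorts with a known truth table
#'
#' Builds seeded, reproducible gene sets for cohorts A and B according to a
#' [sim_spec()]. Tracts are placed in random order with neutral spacers
#' between them, and every finished gene is re-scanned to confirm that the
#' greedy scanner recovers exactly the planted tracts, so the truth table
#' is unambiguous.
#'
#' @param spec a [sim_spec()].
#' @return `list(cohort_a, cohort_b, truth)` where `truth` is a
#'   `data.frame` with columns `cohort`, `gene_id`, `ru`, `start`, `rc`.
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    truth <- list()
    sets <- list()
    for (cohort in c("A", "B")) {
      ids <- sprintf("%s_g%03d", cohort, seq_len(spec$n_genes))
      seqs <- character(spec$n_genes)
      for (g in seq_len(spec$n_genes)) {
        built <- build_planted_gene(spec, cohort)
        seqs[g] <- built$sequence
        truth[[length(truth) + 1]] <-
          cbind(cohort = cohort, gene_id = ids[g], built$tracts,
                stringsAsFactors = FALSE)
      }
      sets[[cohort]] <- gene_set(ids, seqs)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(cohort_a = sets$A, cohort_b = sets$B,
         truth = truth[, c("cohort", "gene_id", "ru", "start", "rc")])
  })
}

# Assemble one gene: draw repeat counts, lay tracts in random order with
# neutral spacers, and verify the scan recovers exactly the planted truth.
build_planted_gene <- function(spec, cohort, max_tries = 20L) {
  w <- spec$motif_len
  rus <- rep(spec$planted_rus, each = spec$tracts_per_gene)
  for (attempt in seq_len(max_tries)) {
    rc <- spec$min_rc + stats::rpois(length(rus), spec$rc_base_mean)
    if (cohort == "A")
      rc <- rc + ifelse(rus %in% spec$shifted_rus, spec$rc_shift, 0L)
    ord <- sample(length(rus))
    ru_o <- rus[ord]; rc_o <- rc[ord]
    span <- sum(w * rc_o)
    n_sp <- length(rus) + 1L
    remaining <- spec$gene_length - span
    if (remaining < 2L * n_sp) next  # unlucky Poisson tail; redraw
    sp_len <- rep(remaining %/% n_sp, n_sp)
    extra <- remaining - sum(sp_len)
    if (extra > 0) sp_len[seq_len(extra)] <- sp_len[seq_len(extra)] + 1L
    cur <- ""
    start <- integer(length(rus))
    ok <- TRUE
    for (j in seq_along(ru_o)) {
      tract <- strrep(ru_o[j], rc_o[j])
      sp <- tryCatch(
        neutral_spacer(sp_len[j], left = tail_chars(cur, 30L),
                       right = tract, motif_len = w,
                       min_rc = spec$min_rc),
        error = function(e) NULL)
      if (is.null(sp)) { ok <- FALSE; break }
      cur <- paste0(cur, sp)
      start[j] <- nchar(cur)
      cur <- paste0(cur, tract)
    }
    if (!ok) next
    sp <- tryCatch(
      neutral_spacer(sp_len[n_sp], left = tail_chars(cur, 30L), right = "",
                     motif_len = w, min_rc = spec$min_rc),
      error = function(e) NULL)
    if (is.null(sp)) next
    cur <- paste0(cur, sp)
    planted <- data.frame(ru = ru_o, start = start, rc = rc_o,
                          stringsAsFactors = FALSE)
    planted <- planted[order(planted$start), ]
    got <- scan_tandem_repeats(cur, w, spec$min_rc)
    if (nrow(got) == nrow(planted) && all(got$ru == planted$ru) &&
        all(got$start == planted$start) && all(got$rc == planted$rc))
      return(list(sequence = cur, tracts = planted))
  }
  stop("failed to assemble a planted gene after ", max_tries, " attempts;",
       " the spec leaves too little spacer room")
}

tail_chars <- function(s, n) {
  L <- nchar(s)
  if (L <= n) s else substr(s, L - n + 1L, L)
}
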