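# Independent oracles used across the suite. Each is a deliberately plain
# implementation (nested loops, explicit pairwise counting, sorted-vector
# arithmetic) kept separate from the package's code paths.

# Nested-loop greedy tandem scanner: motif at the cursor, count adjacent
# copies by substring comparison, emit-and-jump or advance by one.
oracle_scan <- function(s, motif_len = 3, min_rc = 4) {
  s <- toupper(s)
  L <- nchar(s)
  w <- motif_len
  res <- list()
  i <- 1
  while (i + w - 1 <= L) {
    motif <- substr(s, i, i + w - 1)
    if (!grepl("N", motif, fixed = TRUE)) {
      k <- 1
      while (i + (k + 1) * w - 1 <= L &&
             substr(s, i + k * w, i + (k + 1) * w - 1) == motif)
        k <- k + 1
      if (k >= min_rc) {
        res[[length(res) + 1]] <- data.frame(
          ru = motif, start = as.integer(i - 1), rc = as.integer(k),
          span = as.integer(w * k), stringsAsFactors = FALSE)
        i <- i + k * w
        next
      }
    }
    i <- i + 1
  }
  if (length(res)) {
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  } else {
    data.frame(ru = character(0), start = integer(0), rc = integer(0),
               span = integer(0), stringsAsFactors = FALSE)
  }
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive two-sided Mann-Whitney oracle: U by explicit pairwise
# comparison, p by enumerating every assignment of group labels.
oracle_mwu <- function(x, y) {
  na <- length(x)
  nb <- length(y)
  pool <- c(x, y)
  u_of <- function(a_idx) {
    a <- pool[a_idx]
    b <- pool[-a_idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(na + nb, na), 2, u_of)
  eps <- 1e-9
  list(u = u_obs,
       p = min(1, 2 * min(mean(us <= u_obs + eps),
                          mean(us >= u_obs - eps))))
}

# Literal transcription of the two-stage step-up procedure working on the
# sorted p-vector (no call to stats::p.adjust).
oracle_two_stage <- function(p, q = 0.1) {
  m <- length(p)
  qp <- q / (1 + q)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  r1 <- sum(adj <= qp)
  if (r1 == 0 || r1 == m) {
    padj_s <- pmin(1, adj * (1 + q))
    sig_s <- adj <= qp
  } else {
    m0 <- m - r1
    sig_s <- adj <= qp * m / m0
    padj_s <- pmin(1, adj * (m0 / m) * (1 + q))
  }
  padj <- numeric(m)
  sig <- logical(m)
  padj[ord] <- padj_s
  sig[ord] <- sig_s
  list(p_adj = padj, significant = sig)
}

# Assemble a gene with the given tracts in order, separated by verified
# neutral spacers, and confirm the scan recovers exactly the plant.
assemble_gene <- function(rus, rcs, spacer_len = 4, min_rc = 4,
                          max_tries = 20) {
  for (try in seq_len(max_tries)) {
    cur <- ""
    ok <- TRUE
    for (j in seq_along(rus)) {
      tract <- strrep(rus[j], rcs[j])
      sp <- tryCatch(
        neutral_spacer(spacer_len, left = cur, right = tract,
                       min_rc = min_rc),
        error = function(e) NULL)
      if (is.null(sp)) {
        ok <- FALSE
        break
      }
      cur <- paste0(cur, sp, tract)
    }
    if (!ok) next
    got <- scan_tandem_repeats(cur, 3, min_rc)
    if (nrow(got) == length(rus) && all(got$ru == rus) &&
        all(got$rc == rcs))
      return(cur)
  }
  stop("assemble_gene: could not realise the requested tract layout")
}

# Gene set whose `info` units carry gene-specific repeat counts while the
# `const` units sit at a fixed count in every gene; patterns are distinct
# across genes (counts 4 + (g * j) mod 11 with gene index g <= 10).
make_fingerprint_genes <- function(n_genes, info, const, seed = 1) {
  stopifnot(n_genes <= 10)
  withr::with_seed(seed, {
    ids <- sprintf("g%02d", seq_len(n_genes))
    seqs <- vapply(seq_len(n_genes), function(g) {
      rus <- c(info, const)
      rcs <- c(4 + (g * seq_along(info)) %% 11, rep(4, length(const)))
      assemble_gene(rus, rcs)
    }, character(1))
    gene_set(ids, seqs)
  })
}

# 46 pairwise-distinct repeat units for fingerprinting fixtures.
fingerprint_rus <- function() {
  u <- ru_universe()
  u <- u[!u %in% c("AAA", "CCC", "GGG", "TTT")]
  u[seq_len(46)]
}
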