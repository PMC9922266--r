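make_raw_table <- function(values) {
  # values: named list ru -> numeric vector (one value per gene, NA absent)
  n <- length(values[[1]])
  m <- matrix(NA_real_, nrow = n, ncol = 64,
              dimnames = list(sprintf("g%03d", seq_len(n)), ru_universe()))
  for (u in names(values)) m[, u] <- values[[u]]
  out <- as.data.frame(m)
  attr(out, "scheme") <- "raw"
  attr(out, "motif_len") <- 3L
  attr(out, "min_rc") <- 4L
  class(out) <- c("enrichment_table", "data.frame")
  out
}

test_that("identical cohorts give central U statistics and null p-values", {
  withr::with_seed(2, {
    tab <- make_raw_table(list(CAT = runif(9, 4, 30), AAG = runif(9, 4, 30)))
  })
  res <- mwu_per_ru(tab, tab)
  tested <- res[!is.na(res$p_raw), ]
  expect_equal(nrow(tested), 2)
  expect_equal(tested$u_stat, rep(9 * 9 / 2, 2))
  expect_true(all(tested$p_raw > 0.9))
})

test_that("complete separation reaches the exact enumeration p-value", {
  a <- make_raw_table(list(CAT = rep(10, 5)))
  b <- make_raw_table(list(CAT = rep(20, 5)))
  res <- mwu_per_ru(a, b)
  row <- res[res$ru == "CAT", ]
  expect_equal(row$u_stat, 0)
  expect_equal(row$p_raw, 2 / choose(10, 5))
  # orientation: swapping cohorts mirrors U
  rev <- mwu_per_ru(b, a)
  expect_equal(rev[rev$ru == "CAT", "u_stat"], 25)
  expect_equal(rev[rev$ru == "CAT", "p_raw"], row$p_raw)
})

test_that("small-sample tests match the exhaustive permutation oracle", {
  withr::with_seed(31, {
    for (i in 1:40) {
      n_a <- sample(2:7, 1)
      n_b <- sample(2:7, 1)
      # mix continuous draws and tie-rich integer draws
      if (i %% 2) {
        x <- round(runif(n_a, 0, 40), 3)
        y <- round(runif(n_b, 0, 40), 3)
      } else {
        x <- sample(4:8, n_a, replace = TRUE)
        y <- sample(4:9, n_b, replace = TRUE)
      }
      a <- make_raw_table(list(CAT = c(x, rep(NA, 8 - n_a))))
      b <- make_raw_table(list(CAT = c(y, rep(NA, 8 - n_b))))
      got <- mwu_per_ru(a, b)
      got <- got[got$ru == "CAT", ]
      exp <- oracle_mwu(x, y)
      expect_equal(got$u_stat, exp$u)
      expect_equal(got$p_raw, exp$p)
      expect_equal(got$n_a, n_a)
      expect_equal(got$n_b, n_b)
    }
  })
})

test_that("U symmetry and bounds hold on random inputs", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n_a <- sample(3:30, 1)
      n_b <- sample(3:30, 1)
      x <- sample(4:12, n_a, replace = TRUE)
      y <- sample(4:12, n_b, replace = TRUE)
      a <- make_raw_table(list(CAT = c(x, rep(NA, 30 - n_a))))
      b <- make_raw_table(list(CAT = c(y, rep(NA, 30 - n_b))))
      u_ab <- mwu_per_ru(a, b)
      u_ab <- u_ab[u_ab$ru == "CAT", "u_stat"]
      u_ba <- mwu_per_ru(b, a)
      u_ba <- u_ba[u_ba$ru == "CAT", "u_stat"]
      expect_equal(u_ab + u_ba, n_a * n_b)
      expect_gte(u_ab, 0)
      expect_lte(u_ab, n_a * n_b)
    }
  })
})

test_that("zero_fill includes non-carriers and empty cohorts are skipped", {
  a <- make_raw_table(list(CAT = c(10, 12, NA, NA, NA)))
  b <- make_raw_table(list(AAG = c(4, 5, 6, NA, NA)))
  res <- mwu_per_ru(a, b)
  expect_true(all(is.na(res$p_raw)))
  expect_match(res[res$ru == "CAT", "note"], "cohort B")
  expect_match(res[res$ru == "AAG", "note"], "cohort A")
  filled <- mwu_per_ru(a, b, zero_fill = TRUE)
  cat_row <- filled[filled$ru == "CAT", ]
  expect_equal(cat_row$n_a, 5)
  expect_equal(cat_row$n_b, 5)
  expect_false(is.na(cat_row$p_raw))
  # scheme guard
  b2 <- b
  attr(b2, "scheme") <- "len"
  expect_error(mwu_per_ru(a, b2), "schemes")
})

test_that("two-stage adjustment matches the reference implementation", {
  # values frozen from an independent reference implementation of the
  # two-stage step-up procedure at q = 0.1
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.36)
  res <- adjust_two_stage(
    data.frame(ru = letters[1:10], p_raw = p, stringsAsFactors = FALSE),
    q = 0.1)
  expect_equal(res$p_adj,
               c(0.0055, 0.022, 0.0462, 0.0462, 0.0462, 0.055,
                 0.0581428571429, 0.129555555556, 0.129555555556, 0.198),
               tolerance = 1e-9)
  expect_equal(res$significant,
               c(rep(TRUE, 7), rep(FALSE, 3)))
  # no-rejection vector: all adjusted p saturate at 1
  res2 <- adjust_two_stage(
    data.frame(ru = letters[1:5], p_raw = c(0.9, 0.5, 0.7, 0.85, 0.99)),
    q = 0.1)
  expect_equal(res2$p_adj, rep(1, 5))
  expect_false(any(res2$significant))
  # single test reduces to comparison with q / (1 + q)
  res3 <- adjust_two_stage(data.frame(ru = "a", p_raw = 0.001), q = 0.1)
  expect_true(res3$significant)
  expect_equal(res3$tier, "p<0.01")
})

test_that("two-stage agrees with an independent transcription on random vectors", {
  withr::with_seed(55, {
    for (i in 1:100) {
      m <- sample(3:64, 1)
      p <- runif(m)^sample(1:3, 1)
      res <- adjust_two_stage(
        data.frame(ru = as.character(seq_len(m)), p_raw = p), q = 0.1)
      ref <- oracle_two_stage(p, q = 0.1)
      expect_equal(res$p_adj, ref$p_adj)
      expect_equal(res$significant, ref$significant)
      expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
    }
  })
})

test_that("two-stage rejections contain the stage-one step-up rejections", {
  # the adaptive second stage re-tests at a level at least as large as the
  # first stage's q / (1 + q), so its rejections contain the stage-one set
  withr::with_seed(91, {
    for (i in 1:50) {
      m <- sample(5:64, 1)
      p <- runif(m)^sample(1:4, 1)
      q <- 0.1
      res <- adjust_two_stage(
        data.frame(ru = as.character(seq_len(m)), p_raw = p), q = q)
      stage1 <- stats::p.adjust(p, "BH") <= q / (1 + q)
      expect_true(all(res$significant[stage1]))
      expect_gte(sum(res$significant), sum(stage1))
    }
  })
})

test_that("tiers follow the adjusted p thresholds", {
  res <- adjust_two_stage(
    data.frame(ru = letters[1:4],
               p_raw = c(1e-6, 0.002, 0.02, 0.9)), q = 0.1)
  expect_equal(res$tier[res$p_adj < 0.001][1], "p<0.001")
  expect_equal(res$tier[res$p_adj >= 0.05], "ns")
  expect_true(all(res$tier %in% c("p<0.001", "p<0.01", "p<0.05", "ns")))
})

test_that("ranking orders by adjusted p with deterministic tie-breaks", {
  res <- data.frame(ru = c("AAA", "CCC", "GGG"),
                    p_raw = c(0.001, 0.9, 0.5),
                    p_adj = c(0.001, 0.9, 0.5),
                    stringsAsFactors = FALSE)
  rk <- rank_rus(res, 1, 1)
  expect_equal(rk$msru, "AAA")
  expect_equal(rk$lsru, "CCC")
  # all adjusted p tied: fall back to raw p, then alphabetical
  tied <- data.frame(ru = c("TTT", "AAA", "GGG", "CCC"),
                     p_raw = c(0.5, 0.5, 0.2, 0.5),
                     p_adj = rep(0.6, 4), stringsAsFactors = FALSE)
  rk2 <- rank_rus(tied, 2, 2)
  expect_equal(rk2$msru, c("GGG", "AAA"))
  expect_equal(rk2$lsru, c("CCC", "TTT"))
  expect_length(intersect(rk2$msru, rk2$lsru), 0)
  # repeated calls are identical
  expect_identical(rank_rus(tied, 2, 2), rk2)
  # overlap guard
  expect_error(rank_rus(tied, 3, 2), "exceed")
})

test_that("planted shifted units are recovered at the top of the ranking", {
  hits <- vapply(1:12, function(rep) {
    sim <- generate_cohorts(sim_spec(seed = 1000 + rep))
    ta <- build_table(sim$cohort_a, "len")
    tb <- build_table(sim$cohort_b, "len")
    res <- adjust_two_stage(mwu_per_ru(ta, tb))
    rk <- rank_rus(res, 5, 5)
    setequal(rk$msru, c("CAT", "AAG", "ATC", "GTC", "TTA"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("type-I error stays controlled on null cohorts", {
  # both cohorts from the same generator: count replicates with any
  # spuriously strong unit at the p<0.01 tier
  false_hits <- vapply(1:10, function(rep) {
    spec <- sim_spec(n_genes = 30, shifted_rus = character(0),
                     seed = 2000 + rep)
    sim <- generate_cohorts(spec)
    res <- adjust_two_stage(mwu_per_ru(build_table(sim$cohort_a, "len"),
                                       build_table(sim$cohort_b, "len")))
    any(res$tier %in% c("p<0.001", "p<0.01"), na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(false_hits), 0.3)
})
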