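#' Seeded holdout split of a gene set
#'
#' Uniformly samples whole genes (a gene's three feature rows are never
#' separated) into a tuning set of `floor(fraction * n)` genes and an
#' evaluation set holding the rest. The floor rule means e.g. 3 genes at
#' fraction 0.5 split 1 + 2.
#'
#' @param genes a gene set.
#' @param fraction tuning fraction in (0, 1); default 0.15.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return `list(tuning = ..., evaluation = ...)` of gene sets.
#' @export
holdout_split <- function(genes, fraction = 0.15, seed = 1L) {
  check_gene_set(genes)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(genes)
  k <- floor(fraction * n)
  if (k < 1 || k >= n)
    stop("gene set of size ", n, " too small for a non-empty split at ",
         "fraction ", fraction)
  idx <- withr::with_seed(seed, sample.int(n, k))
  list(tuning = genes[sort(idx), , drop = FALSE],
       evaluation = genes[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Build the nested evaluation test sets
#'
#' For each prefix size `k`, the test set holds the genes carrying at least
#' one unit from the top-`k` most-significant prefix *and* at least one from
#' the top-`k` least-significant prefix (each with repeat count `>= min_rc`).
#' The final set (`Test-6` with the default `ks`) holds every gene carrying
#' any repeat unit at all. Nested ranking prefixes give nested test sets.
#'
#' @param genes the evaluation gene set.
#' @param ranked a [rank_rus()] result with prefixes of every `k`.
#' @param ks prefix sizes, default `c(5, 10, 15, 20, 23)`.
#' @param min_rc,motif_len scanner parameters.
#' @return Named list (`Test-1` ... `Test-<n+1>`) of gene-id vectors.
#' @export
make_test_sets <- function(genes, ranked, ks = c(5L, 10L, 15L, 20L, 23L),
                           min_rc = 4L, motif_len = 3L) {
  check_gene_set(genes)
  stopifnot(inherits(ranked, "ranked_rus"),
            max(ks) <= length(ranked$msru), max(ks) <= length(ranked$lsru))
  present <- lapply(genes$sequence, function(s)
    unique(scan_tandem_repeats(s, motif_len, min_rc)$ru))
  plan <- list()
  for (i in seq_along(ks)) {
    k <- ks[i]
    keep <- vapply(present, function(p)
      any(ranked$msru[seq_len(k)] %in% p) &&
      any(ranked$lsru[seq_len(k)] %in% p), logical(1))
    plan[[paste0("Test-", i)]] <- genes$gene_id[keep]
  }
  plan[[paste0("Test-", length(ks) + 1)]] <-
    genes$gene_id[lengths(present) > 0]
  plan
}

#' The default SVM hyperparameter grid
#'
#' Cost `C` in \{0.1, 0.5, 1, 10\}, `gamma` in \{0.1, 0.5, 1, 10\} and
#' kernel in \{linear, rbf\}, enumerated in declaration order (the
#' tie-break order of [grid_search_svm()]).
#'
#' @return A `data.frame` with columns `C`, `gamma`, `kernel`.
#' @export
default_svm_grid <- function() {
  expand.grid(C = c(0.1, 0.5, 1, 10), gamma = c(0.1, 0.5, 1, 10),
              kernel = c("linear", "rbf"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Stratified fold assignment: each gene's three variant rows are spread
# over the folds, the variant-to-fold mapping randomized per gene.
make_folds <- function(features, folds, seed) {
  genes <- unique(features$gene_id)
  withr::with_seed(seed, {
    fold <- integer(length(features$gene_id))
    for (g in genes) {
      rows <- which(features$gene_id == g)
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    fold
  })
}

# Train an SVM on the training rows and predict the test rows.
svm_fold <- function(train_x, train_y, test_x, params) {
  kern <- if (identical(params$kernel, "rbf")) "radial" else params$kernel
  fit <- e1071::svm(x = train_x, y = train_y, kernel = kern,
                    cost = params$C, gamma = params$gamma, scale = FALSE)
  as.character(stats::predict(fit, test_x))
}

#' Exhaustive SVM grid search by stratified cross-validation
#'
#' Every grid cell is scored by mean fold accuracy under the same seeded
#' stratified folds; ties are broken by grid declaration order, so the
#' selection is deterministic given the seed.
#'
#' @param features a [build_features()] result.
#' @param grid hyperparameter grid, default [default_svm_grid()].
#' @param folds number of folds, default 3.
#' @param seed integer seed for the fold assignment.
#' @return List with the winning `C`, `gamma`, `kernel`, its `accuracy`,
#'   and the full `grid_results` table.
#' @export
grid_search_svm <- function(features, grid = default_svm_grid(),
                            folds = 3L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"), nrow(grid) >= 1)
  labels <- features$gene_id
  if (length(unique(labels)) < 2)
    stop("grid search needs at least two classes")
  fold <- make_folds(features, folds, seed)
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, ])
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- fold == f
      pred <- svm_fold(features$values[tr, , drop = FALSE],
                       factor(labels[tr]),
                       features$values[te, , drop = FALSE], params)
      mean(pred == labels[te])
    }, numeric(1))
    acc[i] <- mean(fold_acc)
  }
  best <- which.max(acc)
  list(C = grid$C[best], gamma = grid$gamma[best],
       kernel = grid$kernel[best], accuracy = acc[best],
       grid_results = cbind(grid, accuracy = acc))
}

#' Stratified cross-validated SVM evaluation
#'
#' Splits each gene's three variant rows over the folds (one per fold with
#' the default 3), trains on the remaining folds and predicts the held-out
#' fold, reporting accuracy, macro precision/recall/F1 and the multiclass
#' Matthews correlation coefficient per fold and as fold means. With a
#' z-scored matrix and `leakage_safe = TRUE` the column statistics are
#' re-fitted on the training folds only.
#'
#' @param features a [build_features()] result.
#' @param params list with `C`, `gamma`, `kernel`
#'   (default `C = 0.1`, `gamma = 0.1`, linear).
#' @param folds number of folds, default 3.
#' @param seed integer seed for the fold assignment.
#' @param leakage_safe refit z-score statistics within training folds.
#' @param labels optional row labels overriding the gene ids (the fold
#'   structure still groups rows by gene).
#' @return An object of class `cv_report`.
#' @export
evaluate_cv <- function(features,
                        params = list(C = 0.1, gamma = 0.1,
                                      kernel = "linear"),
                        folds = 3L, seed = 1L, leakage_safe = FALSE,
                        labels = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(labels)) labels <- features$gene_id
  stopifnot(length(labels) == nrow(features$values))
  if (length(unique(labels)) < 2)
    stop("evaluation needs at least two classes")
  counts <- table(features$gene_id)
  if (any(counts < folds))
    stop("gene '", names(counts)[counts < folds][1],
         "' has fewer rows than folds")
  fold <- make_folds(features, folds, seed)
  refit <- leakage_safe && identical(features$norm_scheme, "zsc")
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    if (refit) {
      raw_tr <- features$raw[tr, , drop = FALSE]
      fs <- list(mean = colMeans(raw_tr),
                 sd = apply(raw_tr, 2, stats::sd))
      train_x <- zscore_apply(raw_tr, fs)
      test_x <- zscore_apply(features$raw[te, , drop = FALSE], fs)
    } else {
      train_x <- features$values[tr, , drop = FALSE]
      test_x <- features$values[te, , drop = FALSE]
    }
    pred <- svm_fold(train_x, factor(labels[tr]), test_x, params)
    truth <- as.character(labels[te])
    c(accuracy = mean(pred == truth), macro_metrics(truth, pred),
      mcc = multiclass_mcc(truth, pred))
  })
  per_fold <- do.call(rbind, per_fold)
  agg <- colMeans(per_fold)
  structure(list(accuracy = agg[["accuracy"]],
                 macro_f1 = agg[["macro_f1"]],
                 macro_precision = agg[["macro_precision"]],
                 macro_recall = agg[["macro_recall"]],
                 mcc = agg[["mcc"]],
                 per_fold = as.data.frame(per_fold),
                 n_classes = length(unique(labels)),
                 n_samples = nrow(features$values),
                 hyperparams = params,
                 folds = folds, seed = seed),
            class = "cv_report")
}

# Macro-averaged precision, recall and F1 over the union of observed
# classes; empty denominators contribute 0 (the usual zero-division rule).
macro_metrics <- function(truth, pred) {
  levels <- union(truth, pred)
  tt <- factor(truth, levels = levels)
  pp <- factor(pred, levels = levels)
  cm <- table(tt, pp)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  c(macro_f1 = mean(f1), macro_precision = mean(prec),
    macro_recall = mean(rec))
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance form over the full K-class confusion matrix:
#' `(s * c - sum(t_k p_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the correctly predicted count, `s` the total, and `t_k`, `p_k`
#' the true and predicted counts of class `k`. Reduces to the classical
#' binary MCC for two classes. Degenerate inputs (a single observed class
#' on either side) give 0 with a warning.
#'
#' @param truth,pred equal-length label vectors.
#' @return A number in `[-1, 1]`.
#' @export
multiclass_mcc <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred differ in length")
  if (length(truth) == 0) stop("empty label collections")
  levels <- union(truth, pred)
  cm <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (denom == 0) {
    warning("degenerate confusion matrix; MCC undefined, returning 0")
    return(0)
  }
  (s * c_ - sum(t_k * p_k)) / denom
}

#' Seeded random-run subsample of a gene set
#'
#' One independent uniform draw on `[0, 1)` per gene; a gene is kept when
#' its draw falls below `threshold`. Intended to be repeated with distinct
#' seeds to build several random runs of a large cohort, each followed by
#' re-running the significance stage.
#'
#' @param genes a gene set.
#' @param threshold keep probability in (0, 1]; default 1/6.
#' @param seed integer seed.
#' @return The sampled gene set.
#' @export
random_run_sample <- function(genes, threshold = 1 / 6, seed = 1L) {
  check_gene_set(genes)
  stopifnot(threshold > 0, threshold <= 1)
  draws <- withr::with_seed(seed, stats::runif(nrow(genes)))
  genes[draws < threshold, , drop = FALSE]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("cross-validated SVM (%d classes, %d rows, %d folds,",
                     " C=%g gamma=%g kernel=%s)\n"),
              x$n_classes, x$n_samples, x$folds, x$hyperparams$C,
              x$hyperparams$gamma, x$hyperparams$kernel))
  cat(sprintf(
    "  accuracy %.3f | macro F1 %.3f | precision %.3f | recall %.3f | MCC %.3f\n",
    x$accuracy, x$macro_f1, x$macro_precision, x$macro_recall, x$mcc))
  invisible(x)
}
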