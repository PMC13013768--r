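# Split construction, split-balance chi-square testing, classification
# metrics, DeLong AUC comparison, stress-test subsampling and frame-level
# soft voting. The chi-square and DeLong machinery delegates to stats::
# chisq.test and pROC, the standard implementations.

#' Stratified holdout split
#'
#' Marks exactly `n_per_class` uniformly sampled images per class as the
#' hold-out test set; everything else forms the training pool.
#'
#' @param m A manifest.
#' @param n_per_class Hold-out size per class.
#' @param rng A [seeded_rng()] stream.
#' @return A data frame `(image_path, label, assignment)` with assignment
#'   `"holdout"` or `"pool"`.
#' @export
stratified_holdout <- function(m, n_per_class, rng = seeded_rng(0)) {
  validate_manifest(m)
  if (n_per_class < 0L) stop("n_per_class must be >= 0")
  assignment <- rep("pool", nrow(m))
  for (lab in CLASS_LABELS) {
    idx <- which(m$label == lab)
    if (length(idx) < n_per_class)
      stop("class ", lab, " has ", length(idx), " samples; cannot hold out ", n_per_class)
    if (n_per_class > 0L) assignment[rng_pick(rng, idx, n_per_class)] <- "holdout"
  }
  data.frame(image_path = m$image_path, label = m$label,
             assignment = assignment, stringsAsFactors = FALSE)
}

#' Stratified k-fold split
#'
#' Partitions the pool into `k` folds so that per-class fold sizes differ by
#' at most one, preserving the class proportions of the pool in every fold.
#'
#' @param pool A manifest (e.g. the pool rows of a holdout plan).
#' @param k Number of folds (>= 2).
#' @param rng A [seeded_rng()] stream.
#' @return A data frame `(image_path, label, fold)` with folds `1..k`.
#' @export
stratified_kfold <- function(pool, k, rng = seeded_rng(0)) {
  validate_manifest(pool)
  if (k < 2L) stop("k must be >= 2")
  fold <- integer(nrow(pool))
  for (lab in CLASS_LABELS) {
    idx <- which(pool$label == lab)
    n <- length(idx)
    if (n > 0L && n < k) stop("class ", lab, " has fewer samples than folds")
    if (n == 0L) next
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    perm <- rng_pick(rng, idx, n)
    fold[perm] <- rep(seq_len(k), times = sizes)
  }
  data.frame(image_path = pool$image_path, label = pool$label,
             fold = fold, stringsAsFactors = FALSE)
}

#' Pearson chi-square test of independence
#'
#' Pearson's X^2 = sum (O - E)^2 / E with expected counts from the row and
#' column margins, df = (r-1)(c-1), and an upper-tail chi-square p-value.
#' No continuity correction is applied (the convention under which the
#' split-balance p-values of stratified endoscopy datasets are normally
#' reported).
#'
#' @param counts An r x c matrix of non-negative integer counts (r, c >= 2).
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("contingency table is empty")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Split-balance report
#'
#' For each categorical covariate, cross-tabulates training vs test
#' membership and runs the Pearson chi-square test of independence,
#' reporting cell percentages per column (cell / column total x 100,
#' rounded to one decimal) alongside the counts.
#'
#' @param train,test Manifests (or data frames) carrying the covariate
#'   columns.
#' @param covariates Character vector of column names to compare.
#' @return A list: `tests` — data frame `(covariate, statistic, df,
#'   p_value)`; `tables` — per covariate, a list with `counts` and
#'   `percent` matrices (levels x \{train, test\}).
#' @export
balance_report <- function(train, test, covariates = "label") {
  miss <- setdiff(covariates, intersect(names(train), names(test)))
  if (length(miss)) stop("covariate(s) absent from manifests: ", paste(miss, collapse = ", "))
  tests <- list(); tables <- list()
  for (cov in covariates) {
    lev <- unique(c(train[[cov]], test[[cov]]))
    counts <- cbind(train = as.integer(table(factor(train[[cov]], levels = lev))),
                    test = as.integer(table(factor(test[[cov]], levels = lev))))
    rownames(counts) <- lev
    res <- chi_square_independence(counts)
    percent <- round(sweep(counts, 2, colSums(counts), "/") * 100, 1)
    tests[[cov]] <- data.frame(covariate = cov, statistic = res$statistic,
                               df = res$df, p_value = res$p_value,
                               stringsAsFactors = FALSE)
    tables[[cov]] <- list(counts = counts, percent = percent)
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       tables = tables)
}

validate_predictions <- function(preds) {
  need <- c("sample_id", "true_label", "score")
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("prediction records missing columns: ", paste(miss, collapse = ", "))
  if (any(!preds$true_label %in% CLASS_LABELS)) stop("unknown true_label in predictions")
  if (any(preds$score < 0 | preds$score > 1)) stop("scores must lie in [0, 1]")
  invisible(preds)
}

#' Read / write prediction record CSVs
#'
#' Columns: `sample_id, group_id, true_label, score` where `score` is the
#' predicted probability of class AD.
#'
#' @param path CSV path.
#' @param preds Prediction data frame.
#' @return `read_predictions` returns the validated data frame.
#' @export
read_predictions <- function(path) {
  validate_predictions(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_predictions
#' @export
write_predictions <- function(preds, path) {
  validate_predictions(preds)
  utils::write.csv(preds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Mann-Whitney AUC with ties counted 1/2 (midranks); AD is positive.
auc_mann_whitney <- function(labels, scores) {
  pos <- labels == "AD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' AUC by the Mann-Whitney formulation (tied scores count one half), plus
#' confusion-matrix metrics at the given score threshold. AD is the
#' positive class; a sample is called AD when `score >= threshold`.
#'
#' @param preds Prediction records (see [read_predictions()]).
#' @param threshold Operating point on the score.
#' @return Named list: `AUC`, `ACC`, `SEN`, `SPE`, `PPV`, `NPV`.
#' @export
classification_metrics <- function(preds, threshold = 0.5) {
  validate_predictions(preds)
  truth_pos <- preds$true_label == "AD"
  if (!any(truth_pos) || all(truth_pos))
    stop("both classes must be present in the prediction records")
  pred_pos <- preds$score >= threshold
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos); tn <- sum(!pred_pos & !truth_pos)
  list(AUC = auc_mann_whitney(preds$true_label, preds$score),
       ACC = (tp + tn) / length(truth_pos),
       SEN = tp / (tp + fn), SPE = tn / (tn + fp),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two classifiers scored on the same samples using
#' DeLong's placement-value covariance estimator (two-sided normal
#' reference), as implemented in pROC.
#'
#' @param preds_a,preds_b Prediction records over identical samples
#'   (matched by `sample_id`).
#' @return A list: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(preds_a, preds_b) {
  validate_predictions(preds_a); validate_predictions(preds_b)
  if (nrow(preds_a) != nrow(preds_b) ||
      !setequal(preds_a$sample_id, preds_b$sample_id))
    stop("predictions are not paired: sample ids differ")
  b <- preds_b[match(preds_a$sample_id, preds_b$sample_id), ]
  if (!identical(preds_a$true_label, b$true_label))
    stop("paired predictions disagree on true labels")
  roc_a <- pROC::roc(preds_a$true_label, preds_a$score, levels = c("HP", "AD"),
                     direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(b$true_label, b$score, levels = c("HP", "AD"),
                     direction = "<", quiet = TRUE)
  res <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  list(auc_a = as.numeric(pROC::auc(roc_a)), auc_b = as.numeric(pROC::auc(roc_b)),
       z = unname(res$statistic), p_value = res$p.value)
}

#' Nested stress-test subsampling schedule
#'
#' Builds one training subset per fraction, stratified by class with sizes
#' `round(fraction * n_class)`, and nested across fractions (the 10% subset
#' is contained in the 20% subset, and so on) so that performance curves
#' vary smoothly with the data budget.
#'
#' @param pool A manifest.
#' @param fractions Increasing fractions in (0, 1].
#' @param rng A [seeded_rng()] stream.
#' @return A named list (one element per fraction) of data frames
#'   `(image_path, label, assignment)` with assignment `"train"` or
#'   `"unused"`.
#' @export
stress_schedule <- function(pool, fractions = seq(0.1, 1, by = 0.1),
                            rng = seeded_rng(0)) {
  validate_manifest(pool)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  perms <- lapply(CLASS_LABELS, function(lab) {
    idx <- which(pool$label == lab)
    if (length(idx)) rng_pick(rng, idx, length(idx)) else integer(0)
  })
  names(perms) <- CLASS_LABELS
  plans <- lapply(fractions, function(f) {
    assignment <- rep("unused", nrow(pool))
    for (lab in CLASS_LABELS) {
      take <- round(f * length(perms[[lab]]))
      if (take > 0L) assignment[perms[[lab]][seq_len(take)]] <- "train"
    }
    data.frame(image_path = pool$image_path, label = pool$label,
               assignment = assignment, stringsAsFactors = FALSE)
  })
  names(plans) <- sprintf("%g", fractions)
  plans
}

#' Frame-level soft voting
#'
#' Aggregates frame predictions into one record per group (video clip /
#' patient) by averaging the scores; the group label must be consistent
#' across its members.
#'
#' @param preds Prediction records carrying a `group_id` column.
#' @return One prediction record per group, scores averaged.
#' @export
soft_vote <- function(preds) {
  validate_predictions(preds)
  if (!"group_id" %in% names(preds) || anyNA(preds$group_id))
    stop("soft voting requires a complete group_id column")
  groups <- split(preds, preds$group_id)
  rows <- lapply(groups, function(g) {
    if (length(unique(g$true_label)) != 1L)
      stop("inconsistent true labels within group ", g$group_id[1])
    data.frame(sample_id = g$group_id[1], group_id = g$group_id[1],
               true_label = g$true_label[1], score = mean(g$score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
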