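# Dummy manifest with fake paths (split logic never opens images).
dummy_manifest <- function(n_ad, n_hp) {
  n <- n_ad + n_hp
  manifest(image_path = sprintf("img_%05d.png", seq_len(n)),
           label = c(rep("AD", n_ad), rep("HP", n_hp)),
           x_min = 0L, y_min = 0L, width = 10L, height = 10L)
}

test_that("Pearson chi-square matches the textbook formula on a margin sweep", {
  rng <- seeded_rng(71)
  for (i in 1:40) {
    r <- rng_pick(rng, 2:3); cc <- rng_pick(rng, 2:3)
    counts <- matrix(rng_int(rng, r * cc, 1, 50), r, cc)
    res <- chi_square_independence(counts)
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    x2 <- sum((counts - expected)^2 / expected)
    expect_equal(res$statistic, x2, tolerance = 1e-12)
    expect_equal(res$df, (r - 1) * (cc - 1))
    expect_equal(res$p_value, stats::pchisq(x2, (r - 1) * (cc - 1), lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("chi-square degenerate and invalid tables behave as specified", {
  prop <- matrix(c(10, 20, 10, 20), 2, 2)   # identical row proportions
  res <- chi_square_independence(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  even <- matrix(10, 2, 2)                  # hand-computed E = 10 everywhere
  expect_equal(chi_square_independence(even)$statistic, 0)

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
  expect_error(chi_square_independence(matrix(1:3, 1, 3)), "2 x 2")
})

test_that("balance_report computes per-covariate tests and column percentages", {
  train <- data.frame(label = c(rep("AD", 60), rep("HP", 40)),
                      location = rep(c("left", "right"), 50))
  test <- data.frame(label = c(rep("AD", 30), rep("HP", 20)),
                     location = rep(c("left", "right"), 25))
  rep <- balance_report(train, test, c("label", "location"))
  expect_equal(nrow(rep$tests), 2)
  expect_true(all(rep$tests$p_value == 1))  # identical proportions
  expect_equal(rep$tables$label$percent["AD", "train"], 60.0)
  expect_equal(rep$tables$label$percent["AD", "test"], 60.0)
  expect_error(balance_report(train, test, "size"), "absent")
})

test_that("stratified holdout draws exact per-class counts, deterministically", {
  m <- dummy_manifest(30, 20)
  plan <- stratified_holdout(m, 5, seeded_rng(3))
  held <- plan[plan$assignment == "holdout", ]
  expect_equal(as.vector(table(held$label)[c("AD", "HP")]), c(5L, 5L))
  pool <- plan[plan$assignment == "pool", ]
  expect_equal(sum(pool$label == "AD"), 25)

  expect_identical(stratified_holdout(m, 5, seeded_rng(3)), plan)
  expect_true(all(stratified_holdout(m, 0, seeded_rng(1))$assignment == "pool"))
  expect_error(stratified_holdout(dummy_manifest(3, 3), 5), "cannot hold out")
})

test_that("stratified k-fold partitions each class to within one sample", {
  m <- dummy_manifest(10, 10)
  folds <- stratified_kfold(m, 5, seeded_rng(4))
  tab <- table(folds$label, folds$fold)
  expect_true(all(tab == 2))

  m2 <- dummy_manifest(11, 10)
  folds2 <- stratified_kfold(m2, 5, seeded_rng(5))
  sizes <- as.vector(table(folds2$fold[folds2$label == "AD"]))
  expect_equal(sort(sizes), c(2, 2, 2, 2, 3))

  # partition: every sample in exactly one fold
  expect_equal(sort(unique(folds$fold)), 1:5)
  expect_equal(length(folds$fold), nrow(m))
})

test_that("Mann-Whitney AUC equals exhaustive pair counting and trapezoidal ROC", {
  perfect <- data.frame(sample_id = as.character(1:6),
                        true_label = c("AD", "AD", "AD", "HP", "HP", "HP"),
                        score = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  met <- classification_metrics(perfect)
  expect_equal(met$AUC, 1)
  expect_equal(met$ACC, 1)

  ties <- perfect; ties$score <- 0.5
  expect_equal(classification_metrics(ties)$AUC, 0.5)

  rng <- seeded_rng(72)
  for (i in 1:10) {
    n <- 14
    preds <- data.frame(sample_id = as.character(1:n),
                        true_label = rng_pick(rng, rep(c("AD", "HP"), 7), n),
                        score = round(rng_unif(rng, n), 2))  # rounded: forces ties
    if (length(unique(preds$true_label)) < 2) next
    auc <- classification_metrics(preds)$AUC
    expect_equal(auc, brute_auc(preds$true_label, preds$score), tolerance = 1e-12)
    roc <- pROC::roc(preds$true_label, preds$score, levels = c("HP", "AD"),
                     direction = "<", quiet = TRUE)
    expect_equal(auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  }

  single <- perfect; single$true_label <- "AD"
  expect_error(classification_metrics(single), "both classes")
})

test_that("confusion-matrix metrics match hand counts at the 0.5 threshold", {
  preds <- data.frame(sample_id = as.character(1:8),
                      true_label = c("AD", "AD", "AD", "AD", "HP", "HP", "HP", "HP"),
                      score = c(0.9, 0.6, 0.4, 0.5, 0.1, 0.55, 0.2, 0.3))
  met <- classification_metrics(preds)
  # predicted AD: scores >= 0.5 -> TP = 3, FN = 1, FP = 1, TN = 3
  expect_equal(met$SEN, 3 / 4)
  expect_equal(met$SPE, 3 / 4)
  expect_equal(met$PPV, 3 / 4)
  expect_equal(met$NPV, 3 / 4)
  expect_equal(met$ACC, 6 / 8)
})

test_that("DeLong comparison is null for identical classifiers and antisymmetric", {
  rng <- seeded_rng(73)
  n <- 40
  labels <- rep(c("AD", "HP"), each = n / 2)
  base <- ifelse(labels == "AD", 0.62, 0.42)
  a <- data.frame(sample_id = as.character(1:n), true_label = labels,
                  score = pmin(pmax(base + rng_norm(rng, n, 0.15), 0), 1))
  b <- data.frame(sample_id = as.character(1:n), true_label = labels,
                  score = pmin(pmax(base + rng_norm(rng, n, 0.25), 0), 1))

  same <- delong_test(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  ab <- delong_test(a, b); ba <- delong_test(b, a)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  mismatched <- b; mismatched$sample_id <- as.character(101:140)
  expect_error(delong_test(a, mismatched), "not paired")
})

test_that("the DeLong variance agrees with a bootstrap of the AUC difference", {
  rng <- seeded_rng(74)
  n <- 40
  labels <- rep(c("AD", "HP"), each = n / 2)
  base <- ifelse(labels == "AD", 0.65, 0.40)
  a <- data.frame(sample_id = as.character(1:n), true_label = labels,
                  score = pmin(pmax(base + rng_norm(rng, n, 0.18), 0), 1))
  b <- data.frame(sample_id = as.character(1:n), true_label = labels,
                  score = pmin(pmax(0.5 + rng_norm(rng, n, 0.25), 0), 1))
  res <- delong_test(a, b)
  sd_delong <- abs((res$auc_a - res$auc_b) / res$z)

  ad_idx <- which(labels == "AD"); hp_idx <- which(labels == "HP")
  boots <- vapply(1:10000, function(i) {
    idx <- c(rng_pick(rng, ad_idx, n / 2, replace = TRUE),
             rng_pick(rng, hp_idx, n / 2, replace = TRUE))
    pos <- labels[idx] == "AD"; n1 <- sum(pos); n0 <- sum(!pos)
    r1 <- rank(a$score[idx]); r2 <- rank(b$score[idx])
    (sum(r1[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0) -
      (sum(r2[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  expect_lt(abs(sd_delong - stats::sd(boots)) / stats::sd(boots), 0.15)
})

test_that("stress schedules are stratified, sized by rounding, and nested", {
  m <- dummy_manifest(100, 100)
  plans <- stress_schedule(m, seq(0.1, 1, 0.1), seeded_rng(6))
  sizes <- vapply(plans, function(p) sum(p$assignment == "train" & p$label == "AD"),
                  numeric(1))
  expect_equal(unname(sizes), seq(10, 100, 10))
  expect_true(all(plans[["1"]]$assignment == "train"))
  for (i in 1:9) {
    cur <- plans[[i]]$assignment == "train"
    nxt <- plans[[i + 1]]$assignment == "train"
    expect_true(all(nxt[cur]))              # nesting
  }
  expect_error(stress_schedule(m, c(0, 0.5)), "fractions")
})

test_that("soft voting averages scores per group and validates labels", {
  p <- data.frame(sample_id = as.character(1:5),
                  group_id = c("g1", "g1", "g1", "g2", "g3"),
                  true_label = c("AD", "AD", "AD", "HP", "AD"),
                  score = c(0.2, 0.4, 0.9, 0.3, 0.8))
  v <- soft_vote(p)
  v <- v[order(v$group_id), ]
  expect_equal(v$score, c(0.5, 0.3, 0.8))
  expect_equal(nrow(v), 3)

  bad <- p; bad$true_label[2] <- "HP"
  expect_error(soft_vote(bad), "inconsistent")
  expect_error(soft_vote(p[, -2]), "group_id")
})

test_that("soft voting improves AUC on noisy frames in expectation", {
  rng <- seeded_rng(75)
  gains <- vapply(1:100, function(sim) {
    n_groups <- 20; frames <- 5
    glab <- rep(c("AD", "HP"), each = n_groups / 2)
    signal <- ifelse(glab == "AD", 0.6, 0.4)
    p <- data.frame(
      sample_id = as.character(seq_len(n_groups * frames)),
      group_id = rep(sprintf("g%02d", seq_len(n_groups)), each = frames),
      true_label = rep(glab, each = frames),
      score = pmin(pmax(rep(signal, each = frames) +
                          rng_norm(rng, n_groups * frames, 0.2), 0), 1))
    grouped <- soft_vote(p)
    classification_metrics(grouped)$AUC - classification_metrics(p)$AUC
  }, numeric(1))
  expect_gt(mean(gains), 0)
})
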