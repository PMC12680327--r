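test_that("score reproduces hand-pooled positive-class micro P/R/F1", {
  gold <- c("effect", "effect", "effect", "false", "false")
  pred <- c("effect", "effect", "false", "false", "effect")
  r <- score(gold, pred)
  # hand pooling over positive classes: TP=2, FP=1, FN=1
  expect_equal(unname(r$micro_positive), c(2 / 3, 2 / 3, 2 / 3))
  expect_equal(sum(r$confusion), 5)
  expect_equal(r$confusion["effect", "effect"], 2, ignore_attr = TRUE)
  expect_equal(r$confusion["false", "effect"], 1, ignore_attr = TRUE)
})

test_that("perfect predictions give F1 = 1 and a diagonal confusion matrix", {
  gold <- sample(ddi_labels(), 30, replace = TRUE)
  r <- score(gold, gold)
  expect_equal(unname(r$micro_positive["f1"]), 1)
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)
})

test_that("predicting everything false zeroes the positive micro scores", {
  gold <- c("effect", "mechanism", "false", "false")
  pred <- rep("false", 4)
  r <- score(gold, pred)
  expect_equal(unname(r$micro_positive), c(0, 0, 0))
})

test_that("positive micro-F1 ignores the volume of correct false predictions", {
  gold <- c("effect", "mechanism", "advise", "false")
  pred <- c("effect", "advise", "advise", "false")
  base <- score(gold, pred)$micro_positive
  inflated <- score(c(gold, rep("false", 200)),
                    c(pred, rep("false", 200)))$micro_positive
  expect_equal(inflated, base)
})

test_that("confusion marginals reconcile with the per-class counts", {
  set.seed(5)
  gold <- sample(ddi_labels(), 100, replace = TRUE)
  pred <- sample(ddi_labels(), 100, replace = TRUE)
  r <- score(gold, pred)
  tp <- diag(r$confusion)
  fp <- colSums(r$confusion) - tp
  fn <- rowSums(r$confusion) - tp
  for (i in seq_along(ddi_labels())) {
    p <- if (tp[i] + fp[i] > 0) tp[i] / (tp[i] + fp[i]) else 0
    expect_equal(unname(r$per_class$precision[i]), unname(p))
    rr <- if (tp[i] + fn[i] > 0) tp[i] / (tp[i] + fn[i]) else 0
    expect_equal(unname(r$per_class$recall[i]), unname(rr))
  }
  expect_error(score(gold, pred[-1]), "lengths differ")
})

test_that("rank AUC: perfect ranker 1, random scorer near 0.5, pROC agreement", {
  set.seed(8)
  gold <- c(rep("effect", 50), rep("false", 50))
  scores <- cbind(effect = c(runif(50, 0.6, 1), runif(50, 0, 0.4)))
  scores <- cbind(scores, false = 1 - scores[, "effect"])
  r <- score(gold, gold, scores)
  expect_equal(unname(r$auc["effect"]), 1)
  null_scores <- matrix(runif(1000), 500, 2,
                        dimnames = list(NULL, c("effect", "false")))
  gold2 <- sample(c("effect", "false"), 500, replace = TRUE)
  r2 <- score(gold2, gold2, null_scores)
  expect_lt(abs(r2$auc["effect"] - 0.5), 0.05)
  # independent cross-check against pROC on a small tied-score case
  skip_if_not_installed("pROC")
  s <- c(0.9, 0.8, 0.8, 0.4, 0.35, 0.2)
  is_pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  ours <- protoddi:::rank_auc(s, is_pos)
  ref <- as.numeric(pROC::auc(pROC::roc(response = is_pos, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("separability distinguishes separated from null labelings", {
  set.seed(31)
  x <- rbind(matrix(rnorm(100 * 2), 100),
             matrix(rnorm(100 * 2, mean = 1000), 100))
  labs <- rep(c("a", "b"), each = 100)
  sep <- separability(x, labs)
  expect_gt(sep["silhouette"], 0.9)
  expect_gt(sep["between"], sep["within"])
  # one blob with shuffled labels: silhouette near zero
  y <- matrix(rnorm(200 * 2), 200)
  null_labs <- sample(rep(c("a", "b"), each = 100))
  expect_lt(abs(separability(y, null_labs)["silhouette"]), 0.1)
  # permutation invariance
  perm <- sample(200)
  expect_equal(separability(x[perm, ], labs[perm]), sep, tolerance = 1e-12)
  # singleton classes are excluded with a warning
  expect_warning(s2 <- separability(rbind(x, c(0, 0)), c(labs, "solo")),
                 "solo")
  expect_equal(s2["silhouette"], sep["silhouette"], tolerance = 1e-12)
  expect_error(suppressWarnings(separability(y[1:3, ], c("a", "a", "b"))),
               "2 classes")
})

test_that("paired t matches the closed-form formula and guards degeneracy", {
  a <- c(0.84, 0.86, 0.83, 0.88, 0.85)
  b <- c(0.80, 0.83, 0.82, 0.84, 0.81)
  out <- paired_t(a, b)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_closed, tolerance = 1e-12)
  expect_equal(out$p_value,
               2 * pt(abs(t_closed), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # constant nonzero difference: zero variance is guarded, not an error
  const <- paired_t(a, a - 0.02)
  expect_equal(const$t, Inf)
  expect_equal(const$p_value, 0)
  expect_error(paired_t(a, b[-1]), "equal run counts")
})

test_that("stability on identical configurations is an exact null", {
  corpus <- easy_corpus(5)
  cfg <- quick_config(epochs = 3)
  rep <- suppressWarnings(stability(corpus, n_runs = 2, cfg, cfg))
  expect_equal(rep$t, 0)
  expect_equal(rep$p_value, 1)
  expect_identical(rep$runs_a, rep$runs_b)
})

test_that("few-shot curve rows are deterministic per (k, seed)", {
  corpus <- easy_corpus(8)
  cfg <- quick_config(epochs = 4)
  curve <- suppressWarnings(fewshot_curve(corpus, k_values = 1,
                                          seeds = c(2, 2), config = cfg))
  expect_equal(nrow(curve), 2L)
  expect_equal(curve$micro_f1[1], curve$micro_f1[2])
  expect_true(all(is.finite(curve$micro_f1)))
})

test_that("the ablation table always has its four variants", {
  corpus <- easy_corpus(6)
  tab <- suppressWarnings(run_ablation(corpus, quick_config(epochs = 3)))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$variant, c("full", "no_proto", "no_contrast",
                                 "neither"))
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
})

test_that("the weight sweep covers its grid and matches the CE-only ablation", {
  corpus <- easy_corpus(6)
  cfg <- quick_config(epochs = 3)
  grid <- suppressWarnings(lambda_sweep(corpus, lambda1 = c(0, 0.5),
                                        lambda2 = 0, config = cfg))
  expect_equal(nrow(grid), 2L)
  expect_true(all(is.finite(grid$micro_f1)))
  tab <- suppressWarnings(run_ablation(corpus, cfg))
  expect_equal(grid$micro_f1[grid$lambda1 == 0 & grid$lambda2 == 0],
               tab$f1[tab$variant == "neither"], tolerance = 1e-12)
})
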