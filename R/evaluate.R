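#' Score predictions against gold labels
#'
#' Produces a confusion matrix, per-class precision/recall/F1, and the
#' DDI-2013 headline metric: micro-averaged P/R/F1 with true/false
#' positives/negatives pooled over the four positive (non-`false`) classes
#' only — correctly predicted `false` instances never enter the pooled
#' counts. Macro-averaged and all-class micro scores are also reported. When
#' per-class scores are supplied, one-vs-rest AUCs are computed by the rank
#' (Mann-Whitney) statistic.
#'
#' @param gold Character vector of gold labels.
#' @param pred Character vector of predicted labels (same length).
#' @param scores Optional n x k probability matrix with class-named columns.
#' @return An `eval_report`: `confusion`, `per_class` (data frame),
#'   `micro_positive`, `macro`, `micro_all` (named P/R/F1 vectors), `auc`
#'   (named vector or NULL), `n_instances`.
#' @export
score <- function(gold, pred, scores = NULL) {
  if (length(gold) != length(pred)) {
    stop("gold and pred lengths differ (", length(gold), " vs ",
         length(pred), ")")
  }
  classes <- order_classes(c(gold, pred))
  if (all(classes %in% ddi_labels())) classes <- ddi_labels()
  gf <- factor(gold, levels = classes)
  pf <- factor(pred, levels = classes)
  confusion <- table(gold = gf, predicted = pf)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f1)
  }
  per_class <- t(mapply(prf, tp, fp, fn))
  per_class <- data.frame(label = classes, per_class, row.names = NULL)
  positive <- setdiff(classes, "false")
  pos <- match(positive, classes)
  micro_positive <- prf(sum(tp[pos]), sum(fp[pos]), sum(fn[pos]))
  macro <- c(precision = mean(per_class$precision[pos]),
             recall = mean(per_class$recall[pos]),
             f1 = mean(per_class$f1[pos]))
  micro_all <- prf(sum(tp), sum(fp), sum(fn))
  auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(nrow(scores) == length(gold))
    auc <- vapply(classes, function(cl) {
      if (!cl %in% colnames(scores)) return(NA_real_)
      rank_auc(scores[, cl], gold == cl)
    }, numeric(1))
  }
  structure(list(confusion = confusion, per_class = per_class,
                 micro_positive = micro_positive, macro = macro,
                 micro_all = micro_all, auc = auc,
                 n_instances = length(gold)),
            class = "eval_report")
}

# One-vs-rest AUC by the rank statistic (midranks handle score ties).
rank_auc <- function(s, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d\n", x$n_instances))
  cat(sprintf("  micro (positive classes): P=%.3f R=%.3f F1=%.3f\n",
              x$micro_positive["precision"], x$micro_positive["recall"],
              x$micro_positive["f1"]))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    n_instances = report$n_instances,
    confusion = as.data.frame.matrix(unclass(report$confusion)),
    per_class = report$per_class,
    micro_positive = as.list(report$micro_positive),
    macro = as.list(report$macro),
    micro_all = as.list(report$micro_all),
    auc = if (is.null(report$auc)) NULL else as.list(report$auc)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Stratified train/eval split; every class with >= 2 instances lands in both
# parts.
split_instances <- function(instances, eval_fraction = 0.4, seed = 1L) {
  labs <- vapply(instances, function(x) x$label, character(1))
  with_seed(seed, {
    eval_idx <- unlist(lapply(order_classes(labs), function(cl) {
      pool <- which(labs == cl)
      pool <- pool[sample.int(length(pool))]
      n_ev <- min(max(1L, round(eval_fraction * length(pool))),
                  max(length(pool) - 1L, 0L))
      pool[seq_len(n_ev)]
    }))
    train_idx <- setdiff(seq_along(instances), eval_idx)
    list(train = instances[train_idx], eval = instances[sort(eval_idx)])
  })
}

#' Few-shot support-size curve
#'
#' For each support size k and each seed: draws a k-shot support set from the
#' training part of a stratified split, trains the full model on that support
#' set only, and scores micro-positive F1 on the held-out part (which never
#' enters prototypes).
#'
#' @param corpus A [ddi_corpus()] or instance list.
#' @param k_values Integer vector of support sizes.
#' @param seeds Integer vector of run seeds (duplicates give duplicate rows).
#' @param config Base [train_config()]; the run seed overrides `config$seed`.
#' @param eval_fraction Held-out fraction of the stratified split.
#' @param with_replacement Passed to [sample_support()]; needed when a class
#'   has fewer than k instances.
#' @return Data frame with columns `k_shot`, `seed`, `micro_f1`.
#' @export
fewshot_curve <- function(corpus, k_values, seeds, config = train_config(),
                          eval_fraction = 0.4, with_replacement = FALSE) {
  insts <- as_instances(corpus, config$marker_scheme)
  parts <- split_instances(insts, eval_fraction, config$seed)
  gold <- vapply(parts$eval, function(x) x$label, character(1))
  rows <- list()
  for (s in seeds) {
    for (k in k_values) {
      supp <- sample_support(parts$train,
                             few_shot_spec(k, seed = s,
                                           with_replacement = with_replacement))
      cfg <- config
      cfg$seed <- as.integer(s)
      model <- suppressWarnings(train(supp, config = cfg))
      pred <- predict(model, parts$eval)$labels
      rows[[length(rows) + 1L]] <- data.frame(
        k_shot = k, seed = s,
        micro_f1 = unname(score(gold, pred)$micro_positive["f1"]))
    }
  }
  do.call(rbind, rows)
}

#' Loss-component ablation table
#'
#' Trains four variants under identical seed/config except for the loss
#' switches — full objective, without the prototypical loss, without the
#' contrastive loss, and cross-entropy only — and scores each on the held-out
#' part of a stratified split.
#'
#' @param corpus A [ddi_corpus()] or instance list.
#' @param config Base [train_config()].
#' @param eval_fraction Held-out fraction.
#' @return Data frame `(variant, precision, recall, f1)` with 4 rows.
#' @export
run_ablation <- function(corpus, config = train_config(),
                         eval_fraction = 0.4) {
  insts <- as_instances(corpus, config$marker_scheme)
  parts <- split_instances(insts, eval_fraction, config$seed)
  gold <- vapply(parts$eval, function(x) x$label, character(1))
  variants <- list(full = character(),
                   no_proto = "no_proto",
                   no_contrast = "no_contrast",
                   neither = c("no_proto", "no_contrast"))
  rows <- lapply(names(variants), function(v) {
    cfg <- config
    cfg$ablation <- variants[[v]]
    model <- suppressWarnings(train(parts$train, config = cfg))
    m <- score(gold, predict(model, parts$eval)$labels)$micro_positive
    data.frame(variant = v, precision = unname(m["precision"]),
               recall = unname(m["recall"]), f1 = unname(m["f1"]))
  })
  do.call(rbind, rows)
}

#' Loss-weight sweep
#'
#' Trains one model per grid point of the auxiliary loss weights and reports
#' held-out micro-positive F1. The default grid includes the operating point
#' (0.5, 0.1).
#'
#' @param corpus A [ddi_corpus()] or instance list.
#' @param lambda1,lambda2 Numeric grids; the sweep runs their cross product.
#' @param config Base [train_config()].
#' @param eval_fraction Held-out fraction.
#' @return Data frame `(lambda1, lambda2, micro_f1)`.
#' @export
lambda_sweep <- function(corpus, lambda1 = c(0, 0.5, 1),
                         lambda2 = c(0, 0.1, 0.3),
                         config = train_config(), eval_fraction = 0.4) {
  grid <- expand.grid(lambda1 = lambda1, lambda2 = lambda2,
                      KEEP.OUT.ATTRS = FALSE)
  insts <- as_instances(corpus, config$marker_scheme)
  parts <- split_instances(insts, eval_fraction, config$seed)
  gold <- vapply(parts$eval, function(x) x$label, character(1))
  grid$micro_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$weights <- loss_weights(grid$lambda1[i], grid$lambda2[i],
                                config$weights$tau)
    model <- suppressWarnings(train(parts$train, config = cfg))
    unname(score(gold, predict(model, parts$eval)$labels)$micro_positive["f1"])
  }, numeric(1))
  grid
}

#' Embedding cohesion and separation summary
#'
#' Mean silhouette width (Euclidean distances), mean within-class pairwise
#' distance, and mean between-class pairwise distance of a labeled embedding
#' set. Singleton classes are excluded with a warning.
#'
#' @param emb A `labeled_embeddings` object, or a matrix with `labels`.
#' @param labels Labels when `emb` is a matrix.
#' @return Named numeric vector `(silhouette, within, between)`.
#' @export
separability <- function(emb, labels = NULL) {
  if (inherits(emb, "labeled_embeddings")) {
    x <- emb$vectors; labels <- emb$labels
  } else {
    x <- as.matrix(emb)
  }
  stopifnot(length(labels) == nrow(x))
  counts <- table(labels)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons) > 0L) {
    warning("excluding singleton class(es): ",
            paste(singletons, collapse = ", "), call. = FALSE)
    keep <- !(labels %in% singletons)
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) {
    stop("separability needs at least 2 classes with >= 2 points each")
  }
  d <- stats::dist(x)
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  dm <- as.matrix(d)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  c(silhouette = mean(sil[, "sil_width"]),
    within = mean(dm[same & !is.na(same)]),
    between = mean(dm[!same & !is.na(same)]))
}

#' Multi-seed stability comparison of two configurations
#'
#' Trains both configurations on the same stratified split for each of
#' `n_runs` seeds and compares per-run held-out metrics with a paired t-test
#' (two-sided). With a degenerate (zero-variance) difference the statistic is
#' reported as 0 with p = 1 when all differences are zero, and as signed
#' infinity with p = 0 otherwise.
#'
#' @param corpus A [ddi_corpus()] or instance list.
#' @param n_runs Number of paired runs (>= 2).
#' @param configA,configB The two [train_config()]s (run seed overrides
#'   their `seed`).
#' @param eval_fraction Held-out fraction.
#' @param metric `"accuracy"` (default) or `"micro_f1"`.
#' @param base_seed First run seed; runs use `base_seed + 0:(n_runs-1)`.
#' @return A `stability_report`: per-run metrics, means, SDs, paired t
#'   statistic and p-value.
#' @export
stability <- function(corpus, n_runs, configA, configB = configA,
                      eval_fraction = 0.4,
                      metric = c("accuracy", "micro_f1"), base_seed = 100L) {
  stopifnot(n_runs >= 2)
  metric <- match.arg(metric)
  insts <- as_instances(corpus, configA$marker_scheme)
  parts <- split_instances(insts, eval_fraction, configA$seed)
  gold <- vapply(parts$eval, function(x) x$label, character(1))
  one_run <- function(cfg, s) {
    cfg$seed <- as.integer(s)
    model <- suppressWarnings(train(parts$train, config = cfg))
    pred <- predict(model, parts$eval)$labels
    if (metric == "accuracy") mean(pred == gold)
    else unname(score(gold, pred)$micro_positive["f1"])
  }
  seeds <- base_seed + seq_len(n_runs) - 1L
  a <- vapply(seeds, function(s) one_run(configA, s), numeric(1))
  b <- vapply(seeds, function(s) one_run(configB, s), numeric(1))
  structure(c(paired_t(a, b),
              list(runs_a = a, runs_b = b, metric = metric, seeds = seeds)),
            class = "stability_report")
}

#' Paired t-test with degenerate-variance guard
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return List with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `p_value`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired comparison needs equal run counts (", length(a), " vs ",
         length(b), ")")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    t <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
       sd_b = stats::sd(b), t = t, p_value = p)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> %d paired runs (%s)\n",
                     "  A: %.4f (sd %.4f)   B: %.4f (sd %.4f)\n",
                     "  paired t = %.3f, p = %.4g\n"),
              length(x$runs_a), x$metric, x$mean_a, x$sd_a, x$mean_b,
              x$sd_b, x$t, x$p_value))
  invisible(x)
}
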