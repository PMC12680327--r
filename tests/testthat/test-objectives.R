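test_that("prototypes are per-class support means", {
  # mean of one: centroid equals the instance embedding
  b <- embedding_batch(z = rbind(c(1, 2), c(3, 4)),
                       labels = c("effect", "false"),
                       role = c("support", "support"))
  p <- compute_prototypes(b)
  expect_equal(p$centroids["effect", ], c(1, 2), ignore_attr = TRUE)
  # midpoint
  b2 <- embedding_batch(z = rbind(c(0, 0), c(2, 2)),
                        labels = c("int", "int"),
                        role = c("support", "support"))
  expect_equal(compute_prototypes(b2)$centroids["int", ], c(1, 1),
               ignore_attr = TRUE)
  expect_error(compute_prototypes(
    embedding_batch(z = rbind(c(1, 1)), labels = "int", role = "query")),
    "no support")
})

test_that("prototypes match a groupby-mean oracle and report omitted classes", {
  set.seed(101)
  z <- matrix(rnorm(40 * 5), 40)
  labels <- sample(ddi_labels(), 40, replace = TRUE)
  role <- rep("support", 40)
  role[labels == "int"] <- "query"  # int gets no support
  b <- embedding_batch(z = z, labels = labels, role = role)
  p <- compute_prototypes(b)
  oracle <- groupby_mean(z[role == "support", ], labels[role == "support"])
  for (cl in p$classes) {
    expect_equal(p$centroids[cl, ], oracle[cl, ], tolerance = 1e-12)
  }
  expect_false("int" %in% p$classes)
  expect_true("int" %in% attr(p, "omitted"))
  expect_equal(p$support_counts[p$classes],
               table(labels[role == "support"])[p$classes],
               ignore_attr = TRUE)
})

test_that("distance softmax has the stated closed forms", {
  protos <- prototype_set(c("false", "effect"), rbind(c(-1, 0), c(1, 0)),
                          c(1, 1))
  # equidistant query -> (0.5, 0.5); single class -> 1
  expect_equal(unname(proto_probabilities(c(0, 5), protos)), c(0.5, 0.5))
  one <- prototype_set("advise", rbind(c(3, 3)), 1)
  expect_equal(unname(proto_probabilities(c(9, 9), one)), 1)
  # d^2 = 0 vs 1 -> P = 1/(1 + e^-1)
  p2 <- prototype_set(c("a", "b"), rbind(c(0, 0), c(1, 0)), c(1, 1))
  expect_equal(unname(proto_probabilities(c(0, 0), p2)["a"]),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_error(proto_probabilities(c(1, 2, 3), protos), "dimension mismatch")
})

test_that("distance softmax properties: normalization, argmax, monotonicity", {
  set.seed(77)
  protos <- prototype_set(paste0("c", 1:4), matrix(rnorm(4 * 6), 4), rep(2, 4))
  for (i in 1:25) {
    zq <- rnorm(6, sd = 2)
    p <- proto_probabilities(zq, protos)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    d2 <- rowSums((protos$centroids - matrix(zq, 4, 6, byrow = TRUE))^2)
    expect_equal(which.max(p), which.min(d2), ignore_attr = TRUE)
  }
  # decreasing one distance strictly increases that class's probability
  grid <- seq(3, 0, by = -0.25)
  probs <- vapply(grid, function(d) {
    logits <- matrix(c(-d^2, -1, -2), 1)
    colnames(logits) <- c("a", "b", "c")
    protoddi:::softmax_rows(logits)[1, "a"]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("prototypical loss closed forms and positivity", {
  # queries on their own prototypes, others 1e6 away -> loss ~ 0
  protos <- prototype_set(c("a", "b"), rbind(c(0, 0), c(1e3, 0)), c(1, 1))
  b <- embedding_batch(z = rbind(c(0, 0), c(1e3, 0)), labels = c("a", "b"),
                       role = c("query", "query"))
  expect_lt(proto_loss(b, protos), 1e-6)
  # single listed class -> exactly 0
  one <- prototype_set("a", rbind(c(5, 5)), 1)
  b1 <- embedding_batch(z = rbind(c(0, 0)), labels = "a", role = "query")
  expect_identical(proto_loss(b1, one), 0)
  # two-class d^2 = 0 vs 1 -> -log(1/(1+e^-1))
  p2 <- prototype_set(c("a", "b"), rbind(c(0, 0), c(1, 0)), c(1, 1))
  bq <- embedding_batch(z = rbind(c(0, 0)), labels = "a", role = "query")
  expect_equal(proto_loss(bq, p2), -log(1 / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_gte(proto_loss(bq, p2), 0)
  # unknown query label names the label
  bad <- embedding_batch(z = rbind(c(0, 0)), labels = "zzz", role = "query")
  expect_error(proto_loss(bad, p2), "zzz")
})

test_that("cosine similarity endpoints", {
  a <- c(1, 2, 3)
  expect_equal(cosine_sim(a, a), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(a, -a), -1)
  expect_error(cosine_sim(c(0, 0), a), "zero-norm")
})

test_that("contrastive loss matches closed forms", {
  w <- loss_weights(tau = 1)
  # identical embeddings: uniform softmax over n-1 non-anchors
  for (n in c(4, 6)) {
    b <- embedding_batch(z = matrix(1, n, 3),
                         labels = rep(c("a", "b"), length.out = n))
    expect_equal(supcon_loss(b, w), log(n - 1), tolerance = 1e-9)
  }
  # the four-point two-class configuration: log(1 + 2/e) per anchor
  b4 <- embedding_batch(z = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
                        labels = c("a", "a", "b", "b"))
  expect_equal(supcon_loss(b4, w), log(1 + 2 * exp(-1)), tolerance = 1e-9)
  # degenerate batch: all anchors singleton labels
  deg <- embedding_batch(z = matrix(rnorm(6), 2), labels = c("a", "b"))
  expect_error(supcon_loss(deg, w), "degenerate")
})

test_that("contrastive loss equals the brute-force double loop", {
  set.seed(303)
  for (rep in 1:50) {
    n <- sample(4:16, 1)
    dim <- sample(2:8, 1)
    b <- random_batch(n, dim)
    tau <- sample(c(0.07, 0.5, 1), 1)
    w <- loss_weights(tau = tau)
    expect_equal(supcon_loss(b, w),
                 brute_supcon(b$v, b$labels, tau), tolerance = 1e-6)
    expect_equal(supcon_loss(b, w, average = FALSE),
                 brute_supcon(b$v, b$labels, tau, average = FALSE),
                 tolerance = 1e-6)
    expect_equal(supcon_loss(b, w, use_head = FALSE),
                 brute_supcon(b$z, b$labels, tau), tolerance = 1e-6)
  }
})

test_that("contrastive loss is invariant to reordering and global rescaling", {
  set.seed(9)
  b <- random_batch(12, 5)
  w <- loss_weights(tau = 0.2)
  base <- supcon_loss(b, w)
  perm <- sample(12)
  bp <- embedding_batch(z = b$z[perm, ], v = b$v[perm, ],
                        labels = b$labels[perm], role = b$role[perm])
  expect_equal(supcon_loss(bp, w), base, tolerance = 1e-9)
  for (c_scale in c(0.01, 7)) {
    bs <- embedding_batch(z = b$z, v = b$v * c_scale, labels = b$labels,
                          role = b$role)
    expect_equal(supcon_loss(bs, w), base, tolerance = 1e-7)
  }
})

test_that("high-temperature limit flattens the contrastive softmax", {
  set.seed(21)
  for (n in c(4, 8, 16)) {
    b <- random_batch(n, 6)
    expect_equal(supcon_loss(b, loss_weights(tau = 1e6)), log(n - 1),
                 tolerance = 1e-4)
  }
})

test_that("cross-entropy closed forms", {
  # dominant true logit -> ~0
  big <- rbind(c(1e3, 0, 0), c(0, 1e3, 0))
  expect_lt(ce_loss(big, c(1, 2)), 1e-6)
  # uniform logits -> log k
  for (k in c(2, 5, 9)) {
    expect_equal(ce_loss(matrix(0, 3, k), rep(1, 3)), log(k),
                 tolerance = 1e-12)
  }
  # 2x2 example
  expect_equal(ce_loss(rbind(c(1, 0), c(0, 1)), c(1, 2)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  named <- matrix(c(2, 0, 0, 2), 2, dimnames = list(NULL, c("false", "int")))
  expect_equal(ce_loss(named, c("false", "int")),
               ce_loss(named, c(1, 2)))
  expect_error(ce_loss(named, c("false", "zzz")), "zzz")
})

test_that("the joint objective is affine in its components", {
  w <- loss_weights(lambda1 = 0.5, lambda2 = 0.1)
  expect_equal(total_loss(1.0, 0.4, 0.6, w), 1.26)
  expect_equal(total_loss(2, 5, 7, loss_weights(0, 0)), 2)
  w2 <- loss_weights(lambda1 = 1.0, lambda2 = 0.1)
  expect_equal(total_loss(1.0, 0.4, 0.6, w2) - total_loss(1.0, 0.4, 0.6, w),
               0.5 * 0.4)
  set.seed(1)
  comps <- runif(3)
  for (l1 in c(0, 0.3)) for (l2 in c(0, 0.9)) {
    expect_equal(total_loss(comps[1], comps[2], comps[3],
                            loss_weights(l1, l2)),
                 comps[1] + l1 * comps[2] + l2 * comps[3])
  }
})

test_that("zero-norm contrastive vectors are an error, not a silent epsilon", {
  b <- embedding_batch(z = rbind(c(1, 1), c(0, 0), c(1, 0)),
                       labels = c("a", "a", "b"))
  expect_error(supcon_loss(b, loss_weights()), "zero-norm")
})
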