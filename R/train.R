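#' Training configuration
#'
#' Defaults are the desk-scale profile for the built-in toy encoder (Adam,
#' learning rate 1e-3, 30 epochs, batch 16, support fraction 0.5). For an
#' external pretrained-transformer backbone the customary profile is learning
#' rate 5e-5 with the same batch size and epoch count.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size (>= 2); a warning is emitted when it is
#'   below twice the number of classes present.
#' @param support_fraction Fraction of each class assigned the support role
#'   within batches, in (0, 1).
#' @param learning_rate Adam step size.
#' @param weights A [loss_weights()].
#' @param ablation Character subset of `c("no_proto", "no_contrast")`; an
#'   ablated component is skipped (recorded as 0 in the history).
#' @param seed Integer seed driving initialization and shuffling.
#' @param ce_source `"head"` (linear classifier on z, default) or
#'   `"prototypes"` (cross-entropy on the distance-softmax probabilities).
#' @param contrast_on `"head"` (projection-head output v, default) or `"z"`.
#' @param supcon_average Average the contrastive loss over contributing
#'   anchors (default `TRUE`).
#' @param marker_scheme Entity-marker scheme for [build_instances()].
#' @param dim_embed,dim_hidden,dim_z,dim_v,buckets Toy-encoder and projection
#'   dimensions.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L,
                         support_fraction = 0.5, learning_rate = 1e-3,
                         weights = loss_weights(), ablation = character(),
                         seed = 1L, ce_source = c("head", "prototypes"),
                         contrast_on = c("head", "z"),
                         supcon_average = TRUE,
                         marker_scheme = "markers",
                         dim_embed = 32L, dim_hidden = 64L, dim_z = 32L,
                         dim_v = 32L, buckets = 4096L) {
  stopifnot(epochs >= 1, batch_size >= 2, support_fraction > 0,
            support_fraction < 1, learning_rate > 0,
            all(ablation %in% c("no_proto", "no_contrast")))
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    support_fraction = support_fraction, learning_rate = learning_rate,
    weights = weights, ablation = ablation, seed = as.integer(seed),
    ce_source = match.arg(ce_source), contrast_on = match.arg(contrast_on),
    supcon_average = isTRUE(supcon_average), marker_scheme = marker_scheme,
    dim_embed = as.integer(dim_embed), dim_hidden = as.integer(dim_hidden),
    dim_z = as.integer(dim_z), dim_v = as.integer(dim_v),
    buckets = as.integer(buckets)
  ), class = "train_config")
}

#' Few-shot support specification
#'
#' @param k_per_class Support instances per class (>= 1).
#' @param classes Optional label subset (default: all labels present).
#' @param seed Sampling seed.
#' @param with_replacement Sample with replacement (required when a class has
#'   fewer than `k_per_class` instances).
#' @return A `few_shot_spec` list.
#' @export
few_shot_spec <- function(k_per_class, classes = NULL, seed = 1L,
                          with_replacement = FALSE) {
  stopifnot(k_per_class >= 1)
  structure(list(k_per_class = as.integer(k_per_class), classes = classes,
                 seed = as.integer(seed),
                 with_replacement = isTRUE(with_replacement)),
            class = "few_shot_spec")
}

#' Sample a k-shot support subset
#'
#' Draws exactly `k_per_class` instances per class, deterministically given
#' the spec seed.
#'
#' @param instances List of `pair_instance` objects.
#' @param spec A [few_shot_spec()].
#' @return Sublist of `instances`; selected indices in attribute `"indices"`.
#' @export
sample_support <- function(instances, spec) {
  labs <- vapply(instances, function(x) x$label, character(1))
  classes <- if (is.null(spec$classes)) order_classes(labs) else spec$classes
  with_seed(spec$seed, {
    idx <- unlist(lapply(classes, function(cl) {
      pool <- which(labs == cl)
      if (length(pool) < spec$k_per_class && !spec$with_replacement) {
        stop("class '", cl, "' has only ", length(pool),
             " instance(s); cannot draw ", spec$k_per_class,
             " without replacement")
      }
      pool[sample.int(length(pool), spec$k_per_class,
                      replace = spec$with_replacement)]
    }))
    out <- instances[idx]
    attr(out, "indices") <- idx
    out
  })
}

#' Stratified support/query mini-batches
#'
#' Assigns support/query roles per class by `support_fraction` (every class
#' keeps at least one support instance; a singleton class is support-only,
#' with a warning) and distributes instances over batches so that each batch
#' holds at least one support instance of every class it includes. Shuffling
#' is driven only by `seed`.
#'
#' @param instances List of `pair_instance` objects, or a label vector.
#' @param config A [train_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @param warn Emit composition warnings (silenced on repeat epochs).
#' @return List of batches, each `list(support = indices, query = indices)`.
#' @export
make_batches <- function(instances, config, seed = config$seed, warn = TRUE) {
  labs <- if (is.character(instances)) instances else
    vapply(instances, function(x) x$label, character(1))
  classes <- order_classes(labs)
  if (config$batch_size < 2L) stop("batch_size must be >= 2")
  if (warn && config$batch_size < 2L * length(classes)) {
    warning("batch_size ", config$batch_size, " is below twice the number ",
            "of classes (", length(classes), "); some batches will miss ",
            "classes", call. = FALSE)
  }
  n <- length(labs)
  n_batches <- max(1L, ceiling(n / config$batch_size))
  with_seed(seed, {
    support <- vector("list", n_batches)
    query <- vector("list", n_batches)
    for (cl in classes) {
      pool <- which(labs == cl)
      pool <- pool[sample.int(length(pool))]
      n_c <- length(pool)
      if (n_c == 1L) {
        if (warn) {
          warning("class '", cl, "' has a single instance; assigned the ",
                  "support role only", call. = FALSE)
        }
        n_sup <- 1L
      } else {
        n_sup <- min(max(1L, round(config$support_fraction * n_c)), n_c - 1L)
      }
      sup <- pool[seq_len(n_sup)]
      qry <- pool[setdiff(seq_len(n_c), seq_len(n_sup))]
      off <- sample.int(n_batches, 1L) - 1L
      sup_b <- (off + seq_along(sup) - 1L) %% n_batches + 1L
      for (i in seq_along(sup)) {
        support[[sup_b[i]]] <- c(support[[sup_b[i]]], sup[i])
      }
      eligible <- sort(unique(sup_b))
      off_q <- sample.int(length(eligible), 1L) - 1L
      qry_b <- eligible[(off_q + seq_along(qry) - 1L) %% length(eligible) + 1L]
      for (i in seq_along(qry)) {
        query[[qry_b[i]]] <- c(query[[qry_b[i]]], qry[i])
      }
    }
    batches <- lapply(seq_len(n_batches), function(b) {
      list(support = sort(support[[b]]), query = sort(query[[b]]))
    })
    sizes <- vapply(batches, function(b) length(b$support) + length(b$query),
                    integer(1))
    batches <- batches[sizes > 0L]
    sizes <- sizes[sizes > 0L]
    # merge undersized batches so every batch supports a contrastive term
    while (length(batches) > 1L && any(sizes < 2L)) {
      i <- which(sizes < 2L)[1]
      j <- if (i == 1L) 2L else i - 1L
      batches[[j]] <- list(
        support = sort(c(batches[[j]]$support, batches[[i]]$support)),
        query = sort(c(batches[[j]]$query, batches[[i]]$query)))
      batches[[i]] <- NULL
      sizes <- vapply(batches, function(b) length(b$support) +
                        length(b$query), integer(1))
    }
    batches
  })
}

# --- internal forward/backward ---------------------------------------------

# Prototypical term: loss and gradient w.r.t. the full batch Z.
# eval_idx are the rows scored against prototypes built from sup_idx rows.
# Eval rows with labels absent from the support classes are skipped.
proto_grad <- function(Z, labs, sup_idx, eval_idx) {
  sup_labs <- labs[sup_idx]
  classes <- order_classes(sup_labs)
  counts <- vapply(classes, function(cl) sum(sup_labs == cl), numeric(1))
  mu <- t(vapply(classes, function(cl) {
    colMeans(Z[sup_idx[sup_labs == cl], , drop = FALSE])
  }, numeric(ncol(Z))))
  eval_idx <- eval_idx[labs[eval_idx] %in% classes]
  if (length(eval_idx) == 0L) return(NULL)
  Q <- Z[eval_idx, , drop = FALSE]
  protos <- prototype_set(classes, mu, counts)
  logits <- proto_logits(Q, protos, squared = TRUE)
  true_col <- match(labs[eval_idx], classes)
  P <- softmax_rows(logits)
  m <- length(eval_idx)
  loss <- nll_from_logits(logits, true_col)
  G <- P
  G[cbind(seq_len(m), true_col)] <- G[cbind(seq_len(m), true_col)] - 1
  G <- G / m
  dZ <- matrix(0, nrow(Z), ncol(Z))
  # d/dz_q: rows of G sum to 0, so only the prototype-weighted term survives
  dZ[eval_idx, ] <- dZ[eval_idx, ] + 2 * (G %*% mu)
  dMu <- 2 * (t(G) %*% Q - colSums(G) * mu)
  for (ci in seq_along(classes)) {
    rows <- sup_idx[sup_labs == classes[ci]]
    dZ[rows, ] <- dZ[rows, ] +
      matrix(dMu[ci, ] / counts[ci], length(rows), ncol(Z), byrow = TRUE)
  }
  list(loss = loss, dZ = dZ)
}

# Supervised contrastive term: loss and gradient w.r.t. V.
# Returns NULL when no anchor has a positive (degenerate batch).
supcon_grad <- function(V, labs, tau, average = TRUE) {
  n <- nrow(V)
  if (n < 2L) return(NULL)
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) {
    stop("zero-norm contrastive embedding (dead projection head)")
  }
  U <- V / norms
  S0 <- U %*% t(U)
  S0[S0 > 1] <- 1; S0[S0 < -1] <- -1
  same <- outer(labs, labs, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  anchors <- which(n_pos > 0L)
  if (length(anchors) == 0L) return(NULL)
  S <- S0 / tau
  diag(S) <- -Inf
  mx <- apply(S, 1L, max)
  W <- exp(S - mx)          # softmax numerators, anchor column zero
  sm <- W / rowSums(W)
  lse <- mx + log(rowSums(W))
  per_anchor <- vapply(anchors, function(i) mean(lse[i] - S[i, same[i, ]]),
                       numeric(1))
  loss <- if (average) mean(per_anchor) else sum(per_anchor)
  scale <- if (average) 1 / length(anchors) else 1
  Gs <- matrix(0, n, n)
  Gs[anchors, ] <- (sm[anchors, , drop = FALSE] -
                      same[anchors, , drop = FALSE] /
                        n_pos[anchors]) * (scale / tau)
  diag(Gs) <- 0
  B <- Gs + t(Gs)
  dV <- (B %*% U - rowSums(B * S0) * U) / norms
  list(loss = loss, dV = dV)
}

# One Adam update; state is a list of (m, v) per parameter name.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Loss components and parameter gradients for one mini-batch of the toy
# pipeline. Z/H/M follow the forward pass; `fixed_z = TRUE` (encoder bypass)
# treats Z as the input and only trains head + classifier.
batch_step <- function(params, A_b, Z_fixed, labs, sup, qry, config,
                       classes) {
  w <- config$weights
  use_proto <- !("no_proto" %in% config$ablation) && w$lambda1 > 0
  use_contrast <- !("no_contrast" %in% config$ablation) && w$lambda2 > 0
  fixed_z <- is.null(A_b)

  if (fixed_z) {
    Z <- Z_fixed
  } else {
    M <- as.matrix(A_b %*% params$E)
    H <- tanh(sweep(M %*% params$W1, 2L, params$b1, "+"))
    Z <- sweep(H %*% params$Wp, 2L, params$bp, "+")
  }
  n_b <- nrow(Z)
  V <- sweep(Z %*% params$Wq, 2L, params$bq, "+")

  dZ <- matrix(0, n_b, ncol(Z))
  grads <- list()

  # cross-entropy
  if (config$ce_source == "head") {
    logits <- sweep(Z %*% params$Wc, 2L, params$bc, "+")
    true_col <- match(labs, classes)
    l_ce <- nll_from_logits(logits, true_col)
    P <- softmax_rows(logits)
    dL <- P
    dL[cbind(seq_len(n_b), true_col)] <- dL[cbind(seq_len(n_b), true_col)] - 1
    dL <- dL / n_b
    grads$Wc <- t(Z) %*% dL
    grads$bc <- colSums(dL)
    dZ <- dZ + dL %*% t(params$Wc)
  } else {
    pg <- proto_grad(Z, labs, sup_idx = seq_len(n_b)[sup], eval_idx = seq_len(n_b))
    l_ce <- if (is.null(pg)) 0 else pg$loss
    if (!is.null(pg)) dZ <- dZ + pg$dZ
  }

  # prototypical loss on queries vs batch-support prototypes
  l_proto <- 0
  if (use_proto && any(sup) && any(qry)) {
    pg <- proto_grad(Z, labs, sup_idx = which(sup), eval_idx = which(qry))
    if (!is.null(pg)) {
      l_proto <- pg$loss
      dZ <- dZ + w$lambda1 * pg$dZ
    }
  }

  # supervised contrastive loss across the whole batch
  l_contrast <- 0
  if (use_contrast) {
    target <- if (config$contrast_on == "head") V else Z
    sg <- supcon_grad(target, labs, w$tau, config$supcon_average)
    if (!is.null(sg)) {
      l_contrast <- sg$loss
      if (config$contrast_on == "head") {
        grads$Wq <- w$lambda2 * (t(Z) %*% sg$dV)
        grads$bq <- w$lambda2 * colSums(sg$dV)
        dZ <- dZ + w$lambda2 * (sg$dV %*% t(params$Wq))
      } else {
        dZ <- dZ + w$lambda2 * sg$dV
      }
    }
  }
  if (config$contrast_on == "head" && is.null(grads$Wq)) {
    grads$Wq <- params$Wq * 0
    grads$bq <- params$bq * 0
  }

  if (!fixed_z) {
    grads$Wp <- t(H) %*% dZ
    grads$bp <- colSums(dZ)
    dH <- dZ %*% t(params$Wp)
    dPre <- dH * (1 - H^2)
    grads$W1 <- t(M) %*% dPre
    grads$b1 <- colSums(dPre)
    dM <- dPre %*% t(params$W1)
    grads$E <- as.matrix(Matrix::crossprod(A_b, dM))
  }

  l_total <- l_ce + w$lambda1 * l_proto + w$lambda2 * l_contrast
  list(l_ce = l_ce, l_proto = l_proto, l_contrast = l_contrast,
       l_total = l_total, grads = grads)
}

# Prototypes of the full pool (every instance acts as support).
pool_prototypes <- function(Z, labs) {
  compute_prototypes(embedding_batch(z = Z, labels = labs,
                                     role = rep("support", nrow(Z))))
}

#' Train the joint prototype + contrastive classifier
#'
#' Non-episodic optimization: each epoch partitions the training instances
#' into stratified mini-batches with support/query roles
#' ([make_batches()]); per batch, class prototypes are computed from the
#' support instances, the prototypical loss is taken over the queries, the
#' supervised contrastive loss over the entire batch, cross-entropy per
#' `ce_source`, and one Adam step is applied to the joint objective. After
#' the final epoch, inference prototypes are recomputed from the full
#' training pool. Fully reproducible given `config$seed`.
#'
#' @param corpus_train A [ddi_corpus()] or list of `pair_instance`s.
#' @param corpus_dev Optional dev corpus/instances (adds per-epoch dev
#'   micro-F1 to the history).
#' @param config A [train_config()].
#' @return A `ddi_model`: encoder/projection/head/classifier parameters,
#'   `inference_prototypes`, `classes`, and a per-epoch `history` data frame
#'   (`l_ce`, `l_proto`, `l_contrast`, `l_total`, `train_acc`,
#'   `dev_micro_f1`).
#' @export
train <- function(corpus_train, corpus_dev = NULL, config = train_config()) {
  insts <- as_instances(corpus_train, config$marker_scheme)
  if (length(insts) == 0L) stop("training corpus yields no instances")
  dev <- if (!is.null(corpus_dev)) as_instances(corpus_dev,
                                                config$marker_scheme)
  labs <- vapply(insts, function(x) x$label, character(1))
  classes <- order_classes(labs)

  enc <- toy_encoder(dim_embed = config$dim_embed,
                     dim_out = config$dim_hidden,
                     buckets = config$buckets, seed = config$seed)
  params <- with_seed(config$seed + 1L, list(
    E = enc$E, W1 = enc$W1, b1 = enc$b1,
    Wp = init_matrix(config$dim_hidden, config$dim_z),
    bp = numeric(config$dim_z),
    Wq = init_matrix(config$dim_z, config$dim_v),
    bq = numeric(config$dim_v),
    Wc = init_matrix(config$dim_z, length(classes)),
    bc = numeric(length(classes))
  ))

  texts <- vapply(insts, function(x) x$marked_text, character(1))
  A <- feature_matrix(texts, enc$buckets, enc$max_tokens)
  A_dev <- if (!is.null(dev) && length(dev) > 0L) {
    feature_matrix(vapply(dev, function(x) x$marked_text, character(1)),
                   enc$buckets, enc$max_tokens)
  }

  state <- list(t = 0L, m = list(), v = list())
  history <- vector("list", config$epochs)
  encode_pool <- function(Ax) {
    Mx <- as.matrix(Ax %*% params$E)
    Hx <- tanh(sweep(Mx %*% params$W1, 2L, params$b1, "+"))
    sweep(Hx %*% params$Wp, 2L, params$bp, "+")
  }

  for (epoch in seq_len(config$epochs)) {
    batches <- make_batches(labs, config,
                            seed = (config$seed + epoch * 1009L) %% .Machine$integer.max,
                            warn = epoch == 1L)
    comps <- matrix(0, length(batches), 4L)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      idx <- c(b$support, b$query)
      sup <- c(rep(TRUE, length(b$support)), rep(FALSE, length(b$query)))
      step <- batch_step(params, A[idx, , drop = FALSE], NULL, labs[idx],
                         sup, !sup, config, classes)
      if (!is.finite(step$l_total)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi)
      }
      upd <- adam_step(params, step$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      comps[bi, ] <- c(step$l_ce, step$l_proto, step$l_contrast,
                       step$l_total)
    }
    Zp <- encode_pool(A)
    protos <- pool_prototypes(Zp, labs)
    pred <- protos$classes[max.col(proto_logits(Zp, protos),
                                   ties.method = "first")]
    dev_f1 <- NA_real_
    if (!is.null(A_dev)) {
      Zd <- encode_pool(A_dev)
      pd <- protos$classes[max.col(proto_logits(Zd, protos),
                                   ties.method = "first")]
      gd <- vapply(dev, function(x) x$label, character(1))
      dev_f1 <- score(gd, pd)$micro_positive["f1"]
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, l_ce = mean(comps[, 1]), l_proto = mean(comps[, 2]),
      l_contrast = mean(comps[, 3]), l_total = mean(comps[, 4]),
      train_acc = mean(pred == labs), dev_micro_f1 = unname(dev_f1))
  }

  Zp <- encode_pool(A)
  structure(list(
    params = params,
    encoder_meta = list(buckets = enc$buckets, max_tokens = enc$max_tokens),
    classes = classes,
    inference_prototypes = pool_prototypes(Zp, labs),
    config = config,
    history = do.call(rbind, history)
  ), class = "ddi_model")
}

as_instances <- function(x, scheme = "markers") {
  if (inherits(x, "ddi_corpus")) build_instances(x, scheme = scheme) else x
}

#' Train directly on labeled embeddings (encoder bypass)
#'
#' Treats the supplied vectors as the shared embeddings `z` (no encoder, no
#' task projection); only the contrastive head and the linear classifier are
#' trainable. Useful for objective-level checks on controlled geometry, e.g.
#' Gaussian blobs with known centers.
#'
#' @param emb A `labeled_embeddings` object (see [generate_blobs()]).
#' @param config A [train_config()].
#' @return A `ddi_model` whose `inference_prototypes` are the per-class means
#'   of the full pool; [predict()] on such a model takes an embedding matrix.
#' @export
train_embeddings <- function(emb, config = train_config()) {
  Z_all <- as.matrix(emb$vectors)
  labs <- as.character(emb$labels)
  classes <- order_classes(labs)
  d <- ncol(Z_all)
  params <- with_seed(config$seed + 1L, list(
    Wq = init_matrix(d, config$dim_v), bq = numeric(config$dim_v),
    Wc = init_matrix(d, length(classes)), bc = numeric(length(classes))
  ))
  state <- list(t = 0L, m = list(), v = list())
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    batches <- make_batches(labs, config,
                            seed = (config$seed + epoch * 1009L) %% .Machine$integer.max,
                            warn = epoch == 1L)
    comps <- matrix(0, length(batches), 4L)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      idx <- c(b$support, b$query)
      sup <- c(rep(TRUE, length(b$support)), rep(FALSE, length(b$query)))
      step <- batch_step(params, NULL, Z_all[idx, , drop = FALSE], labs[idx],
                         sup, !sup, config, classes)
      if (!is.finite(step$l_total)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi)
      }
      upd <- adam_step(params, step$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      comps[bi, ] <- c(step$l_ce, step$l_proto, step$l_contrast,
                       step$l_total)
    }
    protos <- pool_prototypes(Z_all, labs)
    pred <- protos$classes[max.col(proto_logits(Z_all, protos),
                                   ties.method = "first")]
    history[[epoch]] <- data.frame(
      epoch = epoch, l_ce = mean(comps[, 1]), l_proto = mean(comps[, 2]),
      l_contrast = mean(comps[, 3]), l_total = mean(comps[, 4]),
      train_acc = mean(pred == labs), dev_micro_f1 = NA_real_)
  }
  structure(list(
    params = params, encoder_meta = NULL, classes = classes,
    inference_prototypes = pool_prototypes(Z_all, labs),
    config = config, history = do.call(rbind, history)
  ), class = "ddi_model")
}

# Shared-embedding matrix for instances (or an embedding matrix passthrough).
model_embed <- function(model, x) {
  if (is.null(model$encoder_meta)) {
    if (!is.matrix(x)) stop("this model was trained on embeddings; ",
                            "supply an n x d matrix")
    return(x)
  }
  insts <- as_instances(x, model$config$marker_scheme)
  texts <- vapply(insts, function(i) i$marked_text, character(1))
  A <- feature_matrix(texts, model$encoder_meta$buckets,
                      model$encoder_meta$max_tokens)
  M <- as.matrix(A %*% model$params$E)
  H <- tanh(sweep(M %*% model$params$W1, 2L, model$params$b1, "+"))
  sweep(H %*% model$params$Wp, 2L, model$params$bp, "+")
}

#' Shared embeddings of instances under a trained model
#'
#' @param model A `ddi_model`.
#' @param x Instances (or corpus), or an embedding matrix for
#'   encoder-bypass models.
#' @return n x dim_z matrix.
#' @export
embed_instances <- function(model, x) model_embed(model, x)

#' Predict DDI labels with a trained model
#'
#' Labels are assigned by the softmax over negative squared distances to the
#' precomputed inference prototypes; exact distance ties resolve to the
#' earlier class in canonical order. Deterministic and invariant to instance
#' ordering.
#'
#' @param object A `ddi_model`.
#' @param newdata Instances, a corpus, or (for encoder-bypass models) an
#'   embedding matrix.
#' @param ... Unused.
#' @return List with `labels` (character) and `probs` (n x k matrix, columns
#'   named by class).
#' @export
predict.ddi_model <- function(object, newdata, ...) {
  Z <- model_embed(object, newdata)
  protos <- object$inference_prototypes
  probs <- softmax_rows(proto_logits(Z, protos))
  list(labels = protos$classes[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' @export
print.ddi_model <- function(x, ...) {
  h <- utils::tail(x$history, 1L)
  cat(sprintf(paste0("<ddi_model> %d classes (%s)\n",
                     "  epochs=%d  final L_total=%.4f  train_acc=%.3f\n"),
              length(x$classes), paste(x$classes, collapse = ", "),
              nrow(x$history), h$l_total, h$train_acc))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file serialization of all parameter groups, prototypes, config and
#' history.
#'
#' @param model A `ddi_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ddi_model")) stop("'", path, "' is not a model checkpoint")
  m
}
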