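#' Loss weights for the joint objective
#'
#' The joint training objective is
#' `L_total = L_CE + lambda1 * L_proto + lambda2 * L_contrast`.
#' Defaults `lambda1 = 0.5`, `lambda2 = 0.1` are the operating point used
#' throughout; `tau` is the temperature dividing cosine similarities in the
#' supervised contrastive loss (default 0.07, the established supervised
#' contrastive choice).
#'
#' @param lambda1 Weight of the prototypical loss (>= 0).
#' @param lambda2 Weight of the contrastive loss (>= 0).
#' @param tau Contrastive temperature (> 0).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 0.5, lambda2 = 0.1, tau = 0.07) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, tau > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, tau = tau),
            class = "loss_weights")
}

# Canonical-first ordering for arbitrary label sets.
order_classes <- function(labels) {
  u <- unique(labels)
  c(intersect(ddi_labels(), u), sort(setdiff(u, ddi_labels())))
}

#' Construct a prototype set
#'
#' @param classes Ordered label vector (one per centroid row).
#' @param centroids k x dim_z matrix of class centroids.
#' @param support_counts Per-class support sizes (>= 1).
#' @return A `prototype_set`.
#' @export
prototype_set <- function(classes, centroids, support_counts) {
  centroids <- as.matrix(centroids)
  stopifnot(length(classes) == nrow(centroids),
            length(support_counts) == length(classes),
            all(support_counts >= 1), all(is.finite(centroids)))
  rownames(centroids) <- classes
  structure(list(classes = as.character(classes), centroids = centroids,
                 support_counts = stats::setNames(as.integer(support_counts),
                                                  classes)),
            class = "prototype_set")
}

#' Compute class prototypes from a batch's support instances
#'
#' Each prototype is the arithmetic mean of the shared embeddings `z` of the
#' support instances of its class. Classes with no support instance in the
#' batch are omitted and reported in the `"omitted"` attribute.
#'
#' @param batch An [embedding_batch()].
#' @return A [prototype_set()].
#' @export
compute_prototypes <- function(batch) {
  sup <- batch$role == "support"
  if (!any(sup)) stop("batch contains no support instances")
  z <- batch$z[sup, , drop = FALSE]
  labs <- batch$labels[sup]
  classes <- order_classes(labs)
  centroids <- t(vapply(classes, function(cl) {
    colMeans(z[labs == cl, , drop = FALSE])
  }, numeric(ncol(z))))
  out <- prototype_set(classes, centroids,
                       vapply(classes, function(cl) sum(labs == cl),
                              integer(1)))
  present <- unique(batch$labels)
  attr(out, "omitted") <- setdiff(order_classes(present), classes)
  out
}

# Negative (squared) Euclidean distance logits, one row per query.
proto_logits <- function(Z, protos, squared = TRUE) {
  Z <- if (is.null(dim(Z))) matrix(Z, nrow = 1L) else as.matrix(Z)
  if (ncol(Z) != ncol(protos$centroids)) {
    stop("dimension mismatch: query dim ", ncol(Z), " vs prototype dim ",
         ncol(protos$centroids))
  }
  # ||z - mu||^2 = ||z||^2 - 2 z.mu + ||mu||^2
  d2 <- outer(rowSums(Z^2), rep(1, nrow(protos$centroids))) -
    2 * Z %*% t(protos$centroids) +
    outer(rep(1, nrow(Z)), rowSums(protos$centroids^2))
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  logits <- if (squared) -d2 else -sqrt(d2)
  colnames(logits) <- protos$classes
  logits
}

# Numerically stable row-wise softmax.
softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Class probabilities of a query under a prototype set
#'
#' Softmax over negative squared Euclidean distances to the class centroids
#' (computed with max-subtraction for stability). Set `squared = FALSE` for
#' plain Euclidean distances.
#'
#' @param z_q Query embedding (vector) or n x dim_z matrix of queries.
#' @param protos A [prototype_set()].
#' @param squared Use squared distances (default `TRUE`).
#' @return Named probability vector (single query) or row-wise probability
#'   matrix.
#' @export
proto_probabilities <- function(z_q, protos, squared = TRUE) {
  p <- softmax_rows(proto_logits(z_q, protos, squared))
  if (is.null(dim(z_q))) drop(p) else p
}

#' Prototypical loss over query instances
#'
#' Mean over query-role instances of the negative log-probability of the true
#' class under [proto_probabilities()].
#'
#' @param batch An [embedding_batch()]; only `role == "query"` rows enter.
#' @param protos A [prototype_set()].
#' @param squared Use squared distances (default `TRUE`).
#' @return Nonnegative scalar.
#' @export
proto_loss <- function(batch, protos, squared = TRUE) {
  q <- batch$role == "query"
  if (!any(q)) stop("batch contains no query instances")
  labs <- batch$labels[q]
  missing <- setdiff(unique(labs), protos$classes)
  if (length(missing) > 0L) {
    stop("query label(s) absent from prototype set: ",
         paste(missing, collapse = ", "))
  }
  logits <- proto_logits(batch$z[q, , drop = FALSE], protos, squared)
  nll_from_logits(logits, match(labs, protos$classes))
}

# Mean negative log softmax-probability of the true column, stably.
nll_from_logits <- function(logits, true_col) {
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), true_col)])
}

#' Cosine similarity
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for zero-norm vectors")
  }
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# Pairwise cosine-similarity matrix of the rows of V; errors on zero rows
# (a zero contrastive vector indicates a dead projection head).
cosine_matrix <- function(V) {
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) {
    stop("zero-norm embedding row(s): ", paste(which(norms == 0),
                                               collapse = ", "))
  }
  U <- V / norms
  S <- U %*% t(U)
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' Supervised contrastive loss over a batch
#'
#' For each anchor i with a non-empty positive set P(i) (same-label,
#' non-anchor instances), the loss is the mean over j in P(i) of the negative
#' log of a temperature-scaled softmax of cosine similarities over all
#' non-anchor instances. Anchors with empty P(i) contribute nothing; by
#' default the sum is divided by the number of contributing anchors so the
#' magnitude is batch-size independent (`average = FALSE` gives the pure
#' sum). Computed on the projection-head output `v` by default
#' (`use_head = FALSE` uses the shared embedding `z`).
#'
#' @param batch An [embedding_batch()] with >= 2 rows; support/query roles
#'   are ignored (the loss spans the whole batch).
#' @param weights A [loss_weights()]; only `tau` is used.
#' @param use_head Contrast head outputs `v` (default) or shared `z`.
#' @param average Divide by the number of contributing anchors (default).
#' @return Nonnegative scalar.
#' @export
supcon_loss <- function(batch, weights = loss_weights(), use_head = TRUE,
                        average = TRUE) {
  V <- if (use_head) batch$v else batch$z
  n <- nrow(V)
  if (n < 2L) stop("contrastive loss needs a batch of at least 2 instances")
  S <- cosine_matrix(V) / weights$tau
  labs <- batch$labels
  same <- outer(labs, labs, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  anchors <- which(n_pos > 0L)
  if (length(anchors) == 0L) {
    stop("degenerate batch: no anchor has a same-label positive")
  }
  diag(S) <- -Inf  # excludes the anchor from its own softmax
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  per_anchor <- vapply(anchors, function(i) {
    mean(lse[i] - S[i, same[i, ]])
  }, numeric(1))
  if (average) mean(per_anchor) else sum(per_anchor)
}

#' Cross-entropy loss from logits
#'
#' @param logits n x k matrix (columns named with class labels, or unnamed
#'   with integer `labels`).
#' @param labels Length-n true labels: integers (column indices) or
#'   characters matched against `colnames(logits)`.
#' @return Mean negative log softmax-probability of the true class.
#' @export
ce_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  if (is.character(labels) || is.factor(labels)) {
    idx <- match(as.character(labels), colnames(logits))
    if (anyNA(idx)) {
      stop("label(s) outside the logit vocabulary: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
    }
  } else {
    idx <- as.integer(labels)
    if (any(idx < 1L | idx > ncol(logits))) {
      stop("label index outside 1..", ncol(logits))
    }
  }
  stopifnot(length(idx) == nrow(logits))
  nll_from_logits(logits, idx)
}

#' Joint objective
#'
#' `L_total = L_CE + lambda1 * L_proto + lambda2 * L_contrast`.
#'
#' @param l_ce,l_proto,l_contrast Component losses (finite).
#' @param weights A [loss_weights()].
#' @return Scalar.
#' @export
total_loss <- function(l_ce, l_proto, l_contrast,
                       weights = loss_weights()) {
  stopifnot(is.finite(l_ce), is.finite(l_proto), is.finite(l_contrast))
  l_ce + weights$lambda1 * l_proto + weights$lambda2 * l_contrast
}
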