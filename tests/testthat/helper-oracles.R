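# Independent brute-force reference for the supervised contrastive loss:
# literal double loop over anchors and positives, no shared code with the
# package implementation.
brute_supcon <- function(V, labels, tau, average = TRUE) {
  n <- nrow(V)
  cs <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  total <- 0
  contributing <- 0
  for (i in seq_len(n)) {
    pos <- setdiff(which(labels == labels[i]), i)
    if (length(pos) == 0) next
    contributing <- contributing + 1
    denom <- 0
    for (k in setdiff(seq_len(n), i)) {
      denom <- denom + exp(cs(V[i, ], V[k, ]) / tau)
    }
    s <- 0
    for (j in pos) {
      s <- s + log(exp(cs(V[i, ], V[j, ]) / tau) / denom)
    }
    total <- total - s / length(pos)
  }
  if (contributing == 0) stop("degenerate batch")
  if (average) total / contributing else total
}

# Independent per-class mean oracle.
groupby_mean <- function(z, labels) {
  cls <- sort(unique(labels))
  out <- t(sapply(cls, function(cl) colMeans(z[labels == cl, , drop = FALSE])))
  rownames(out) <- cls
  out
}

# Random embedding batch with guaranteed contrastive structure (at least one
# repeated label).
random_batch <- function(n, dim, n_classes = 5) {
  repeat {
    labels <- sample(ddi_labels()[seq_len(n_classes)], n, replace = TRUE)
    if (max(table(labels)) >= 2) break
  }
  roles <- rep(c("support", "query"), length.out = n)
  embedding_batch(z = matrix(rnorm(n * dim), n),
                  v = matrix(rnorm(n * dim), n),
                  labels = labels, role = sample(roles))
}

# The worked aspirin/warfarin example sentence as a one-sentence corpus file.
aspirin_fixture <- function(path = tempfile(fileext = ".xml")) {
  text <- "The coadministration of aspirin and warfarin may increase the risk of bleeding."
  span <- function(word) {
    a <- as.integer(regexpr(word, text, fixed = TRUE)) - 1L
    matrix(c(a, a + nchar(word)), ncol = 2,
           dimnames = list(NULL, c("start", "end")))
  }
  s <- sentence_record(
    "d1.s1", text,
    entities = list(entity_mention("d1.s1.e0", "aspirin", span("aspirin")),
                    entity_mention("d1.s1.e1", "warfarin", span("warfarin"))),
    pairs = data.frame(id = "d1.s1.p0", e1 = "d1.s1.e0", e2 = "d1.s1.e1",
                       label = "effect", stringsAsFactors = FALSE))
  write_corpus(ddi_corpus(list(d1 = list(s))), path)
  path
}

# Tiny easy corpus shared by smoke tests.
easy_corpus <- function(n_per_class = 8, seed = 11) {
  generate_corpus(synthetic_corpus_config(
    stats::setNames(rep(n_per_class, 5), ddi_labels()), seed = seed))
}

quick_config <- function(epochs = 5L, seed = 7L, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}
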