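# --- tokenization and hashed features -------------------------------------

# Whitespace/punctuation tokenization; entity-marker tokens like "[E1]" are
# ordinary tokens. Input longer than `max_tokens` is truncated.
tokenize <- function(text, max_tokens = 300L) {
  text <- gsub("([.,;:!?()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  toks
}

# Deterministic 31-ary polynomial rolling hash (platform independent).
hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

# Unigram + adjacent-bigram feature buckets (1-based), truncation applied.
hashed_features <- function(text, buckets, max_tokens = 300L) {
  toks <- tokenize(text, max_tokens)
  if (length(toks) == 0L) {
    stop("text yields no tokens after tokenization: ", sQuote(text))
  }
  feats <- toks
  if (length(toks) > 1L) {
    feats <- c(feats, paste(toks[-length(toks)], toks[-1L], sep = "_"))
  }
  vapply(feats, hash_string, numeric(1), USE.NAMES = FALSE) %% buckets + 1L
}

# Row-normalized sparse incidence matrix (n x buckets): row i holds the
# relative frequency of each feature bucket of text i, so A %*% E is a mean
# pooled embedding lookup.
feature_matrix <- function(texts, buckets, max_tokens = 300L) {
  idx <- lapply(texts, hashed_features, buckets = buckets,
                max_tokens = max_tokens)
  lens <- lengths(idx)
  Matrix::sparseMatrix(
    i = rep(seq_along(texts), lens),
    j = unlist(idx),
    x = 1 / rep(lens, lens),
    dims = c(length(texts), buckets)
  )
}

# --- parameter constructors ------------------------------------------------

init_matrix <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)), n_in, n_out)
}

#' Construct a toy sentence encoder
#'
#' A deterministic, trainable stand-in for a pretrained transformer backbone:
#' tokens and adjacent token bigrams are hashed into a fixed number of
#' buckets, looked up in a trainable embedding table, mean-pooled, and passed
#' through one tanh hidden layer. The pooled read-out plays the role of the
#' backbone's sentence-level summary vector. Inputs are truncated at
#' `max_tokens` tokens.
#'
#' @param dim_embed Embedding-table dimension.
#' @param dim_out Hidden (output) dimension of the encoder.
#' @param buckets Number of hash buckets.
#' @param max_tokens Truncation length (default 300 tokens).
#' @param seed Seed for parameter initialization.
#' @return An encoder object (class `toy_encoder`) with fields `name`,
#'   `dim_out`, and trainable parameters `E`, `W1`, `b1`.
#' @export
toy_encoder <- function(dim_embed = 32L, dim_out = 64L, buckets = 4096L,
                        max_tokens = 300L, seed = 1L) {
  with_seed(seed, {
    structure(list(
      name = "toy", dim_out = as.integer(dim_out),
      buckets = as.integer(buckets), max_tokens = as.integer(max_tokens),
      E = init_matrix(buckets, dim_embed),
      W1 = init_matrix(dim_embed, dim_out),
      b1 = numeric(dim_out)
    ), class = c("toy_encoder", "ddi_encoder"))
  })
}

#' Wrap an external sentence encoder
#'
#' Adapter for a user-supplied backbone (e.g. a pretrained transformer served
#' out of process): `encode_fun` takes a character vector of marked sentences
#' and returns an n x `dim_out` matrix of sentence vectors (for a
#' transformer, the summary-token hidden state). The adapter is frozen: it
#' exposes no trainable parameters to the package optimizer.
#'
#' @param encode_fun Function: character vector -> n x dim_out matrix.
#' @param dim_out Output dimension.
#' @param name Registry name.
#' @return An encoder object (class `external_encoder`).
#' @export
external_encoder <- function(encode_fun, dim_out,
                             name = "external-transformer") {
  stopifnot(is.function(encode_fun), dim_out >= 1)
  structure(list(name = name, dim_out = as.integer(dim_out),
                 encode_fun = encode_fun),
            class = c("external_encoder", "ddi_encoder"))
}

#' Create an encoder by registry name
#'
#' @param name `"toy"` (the built-in hashed-feature encoder) or
#'   `"external-transformer"` (requires `encode_fun` and `dim_out`).
#' @param ... Passed to the encoder constructor.
#' @return A `ddi_encoder` object.
#' @export
make_encoder <- function(name = c("toy", "external-transformer"), ...) {
  name <- match.arg(name)
  switch(name, toy = toy_encoder(...), `external-transformer` = {
    external_encoder(...)
  })
}

#' Pooled sentence vectors from an encoder
#'
#' @param encoder A `ddi_encoder`.
#' @param texts Character vector of marked sentences.
#' @return n x dim_out numeric matrix.
#' @export
encode_texts <- function(encoder, texts) UseMethod("encode_texts", encoder)

#' @export
encode_texts.toy_encoder <- function(encoder, texts) {
  A <- feature_matrix(texts, encoder$buckets, encoder$max_tokens)
  toy_forward(encoder, A)$H
}

#' @export
encode_texts.external_encoder <- function(encoder, texts) {
  H <- encoder$encode_fun(texts)
  if (!is.matrix(H) || ncol(H) != encoder$dim_out) {
    stop("external encoder returned dimension ", ncol(H),
         " but declared dim_out ", encoder$dim_out)
  }
  H
}

# Forward pass through the toy encoder given a precomputed feature matrix.
toy_forward <- function(encoder, A) {
  M <- as.matrix(A %*% encoder$E)
  pre <- sweep(M %*% encoder$W1, 2L, encoder$b1, "+")
  list(M = M, H = tanh(pre))
}

#' Encode a single marked sentence with the toy encoder
#'
#' @param marked_text One sentence (with or without entity markers).
#' @param encoder A [toy_encoder()].
#' @return Numeric vector of length `encoder$dim_out`.
#' @export
toy_encode <- function(marked_text, encoder) {
  stopifnot(length(marked_text) == 1L)
  drop(encode_texts(encoder, marked_text))
}

# --- linear projections ----------------------------------------------------

#' Construct linear projection parameters
#'
#' Weights are stored input x output, so a batch projects as
#' `H %*% W + b` (row per instance). Used both for the task projection
#' (encoder output -> shared embedding z) and the contrastive projection head
#' (z -> v).
#'
#' @param dim_in,dim_out Input/output dimensions.
#' @param seed Seed for initialization; `identity = TRUE` instead initializes
#'   `W` to the identity (requires `dim_in == dim_out`) and `b` to zero.
#' @param identity Initialize as the identity map?
#' @return A `linear_projection` list with `W` (dim_in x dim_out) and `b`.
#' @export
linear_projection <- function(dim_in, dim_out, seed = 1L, identity = FALSE) {
  if (identity) {
    stopifnot(dim_in == dim_out)
    W <- diag(dim_in)
  } else {
    W <- with_seed(seed, init_matrix(dim_in, dim_out))
  }
  structure(list(W = W, b = numeric(dim_out)), class = "linear_projection")
}

#' Apply a linear projection
#'
#' @param x Numeric vector (length dim_in) or n x dim_in matrix.
#' @param proj A [linear_projection()].
#' @return Projected vector or matrix.
#' @export
project <- function(x, proj) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(proj$W)) {
    stop("dimension mismatch: input has ", ncol(x), " columns but projection",
         " expects ", nrow(proj$W))
  }
  out <- sweep(x %*% proj$W, 2L, proj$b, "+")
  if (nrow(out) == 1L) drop(out) else out
}

# --- batch encoding --------------------------------------------------------

#' Encode instances into a labeled embedding batch
#'
#' Runs the encoder over the instances' marked sentences, applies the task
#' projection (`z = W_p h + b_p`) and the contrastive projection head
#' (`v = W_q z + b_q`), preserving instance order.
#'
#' @param instances List of `pair_instance` objects (see
#'   [build_instances()]).
#' @param encoder A `ddi_encoder`.
#' @param proj Task projection ([linear_projection()], dim_out x dim_z).
#' @param head Contrastive head ([linear_projection()], dim_z x dim_v).
#' @param role Optional per-instance role vector over `support` / `query`
#'   (default all `query`).
#' @return An `embedding_batch` list: `z`, `v` (matrices), `labels`, `role`,
#'   `instance_ids`.
#' @export
encode_batch <- function(instances, encoder, proj, head, role = NULL) {
  stopifnot(length(instances) > 0L)
  texts <- vapply(instances, function(x) x$marked_text, character(1))
  H <- encode_texts(encoder, texts)
  Z <- project(H, proj)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  V <- project(Z, head)
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  if (is.null(role)) role <- rep("query", length(instances))
  embedding_batch(
    z = Z, v = V,
    labels = vapply(instances, function(x) x$label, character(1)),
    role = role,
    instance_ids = vapply(instances, function(x) x$instance_id, character(1))
  )
}

#' Construct an embedding batch
#'
#' @param z n x dim_z matrix of shared embeddings.
#' @param v n x dim_v matrix of contrastive-head outputs (defaults to `z`).
#' @param labels Length-n label vector.
#' @param role Length-n vector over `support` / `query`.
#' @param instance_ids Length-n ids.
#' @return An `embedding_batch` list.
#' @export
embedding_batch <- function(z, v = z, labels,
                            role = rep("query", nrow(z)),
                            instance_ids = as.character(seq_len(nrow(z)))) {
  z <- as.matrix(z); v <- as.matrix(v)
  n <- nrow(z)
  stopifnot(nrow(v) == n, length(labels) == n, length(role) == n,
            length(instance_ids) == n, all(role %in% c("support", "query")))
  structure(list(z = z, v = v, labels = as.character(labels),
                 role = as.character(role),
                 instance_ids = as.character(instance_ids)),
            class = "embedding_batch")
}
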