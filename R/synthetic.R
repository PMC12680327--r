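# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' DDI-2013 training-set class frequencies
#'
#' Published class counts of the DDI Extraction 2013 training split, used as
#' the reference imbalance profile for synthetic corpora (the `false` class
#' dominates with 23772 of 27792 instances).
#'
#' @return Named integer vector in canonical label order.
#' @export
ddi2013_train_counts <- function() {
  c(false = 23772L, effect = 1687L, mechanism = 1319L, advise = 826L,
    int = 188L)
}

#' Scale reference class counts to a total (largest-remainder apportionment)
#'
#' @param counts Named nonnegative counts (the reference profile).
#' @param total Target total.
#' @return Named integer counts summing exactly to `total`.
#' @export
#' @examples
#' scale_counts(ddi2013_train_counts(), 300)
scale_counts <- function(counts, total) {
  stopifnot(total >= 0, all(counts >= 0), sum(counts) > 0)
  quota <- counts / sum(counts) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    # ties on fractional parts broken by canonical (input) order
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Class proportions of a count vector
#'
#' @param counts Named nonnegative counts, sum > 0.
#' @return Named proportions summing to 1.
#' @export
imbalance_profile <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) <= 0) stop("all counts are zero")
  counts / sum(counts)
}

#' Configuration for the template-based synthetic corpus generator
#'
#' @param per_class_counts Named counts over [ddi_labels()] (missing labels
#'   count 0).
#' @param cue_strength Fraction in `[0,1]` of instances whose sentence
#'   contains an unambiguous class-cue phrase; the remainder use generic
#'   co-mention templates (label kept).
#' @param vocab_noise Per-instance probability of inserting 1-3 distractor
#'   tokens at random positions.
#' @param overlap_classes Optional list of 2-element label vectors; classes in
#'   a pair draw half of their cue sentences from a shared ambiguous cue bank
#'   ("hard mode", emulating effect/mechanism confusions).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_corpus_config` list.
#' @export
synthetic_corpus_config <- function(per_class_counts, cue_strength = 1,
                                    vocab_noise = 0, overlap_classes = NULL,
                                    seed = 1L) {
  counts <- stats::setNames(integer(5), ddi_labels())
  bad <- setdiff(names(per_class_counts), ddi_labels())
  if (length(bad) > 0L) {
    stop("per_class_counts names not in the template bank: ",
         paste(bad, collapse = ", "))
  }
  counts[names(per_class_counts)] <- as.integer(per_class_counts)
  stopifnot(all(counts >= 0), cue_strength >= 0, cue_strength <= 1,
            vocab_noise >= 0, vocab_noise <= 1)
  if (!is.null(overlap_classes)) {
    for (p in overlap_classes) {
      stopifnot(length(p) == 2L, all(p %in% ddi_labels()))
    }
  }
  structure(list(per_class_counts = counts, cue_strength = cue_strength,
                 vocab_noise = vocab_noise,
                 overlap_classes = overlap_classes, seed = as.integer(seed)),
            class = "synthetic_corpus_config")
}

# ~50 invented drug-like names; single tokens so character offsets stay simple.
synthetic_drug_names <- function() {
  c("abexanib", "bortelin", "cadrivir", "dexolumab", "eprazinol",
    "fentramab", "gliposide", "hepradine", "ibextran", "jocavir",
    "kentrazole", "lomiprene", "mabretix", "nortevan", "oxaplidin",
    "pentrafil", "quibradine", "rostevamab", "sertaplon", "tabrexine",
    "ulodipine", "vebractam", "wortenib", "xafridone", "yomitrex",
    "zelparin", "amcovir", "beprazide", "cortemab", "delfexine",
    "enzoplat", "fabrodil", "gantrevir", "hylodipra", "imbextan",
    "jentrazol", "kolvamide", "lurbexin", "mativast", "nubraphen",
    "ocrebine", "pylvatinib", "quolazine", "rembactam", "sovradone",
    "trexovan", "uvemicin", "vantreol", "xylodart", "zubrafine")
}

cue_template_bank <- function() {
  list(
    mechanism = c(
      "{D1} inhibits CYP3A4 metabolism of {D2} .",
      "{D1} decreases the plasma clearance of {D2} .",
      "absorption of {D2} is markedly reduced by {D1} .",
      "{D1} induces hepatic enzymes that accelerate elimination of {D2} .",
      "{D1} raises serum concentrations of {D2} through CYP2D6 inhibition ."),
    effect = c(
      "{D1} increases the risk of bleeding when given with {D2} .",
      "coadministration of {D1} and {D2} may potentiate sedation .",
      "{D1} enhances the hypotensive effect of {D2} .",
      "concurrent {D1} and {D2} can cause additive QT prolongation .",
      "{D1} increases the risk of seizures if combined with {D2} ."),
    advise = c(
      "{D1} should not be coadministered with {D2} .",
      "avoid combining {D1} with {D2} during therapy .",
      "caution is advised when {D1} is prescribed together with {D2} .",
      "patients receiving {D2} should discontinue {D1} first ."),
    int = c(
      "{D1} interacts with {D2} .",
      "an interaction between {D1} and {D2} has been reported .",
      "{D1} may interact with {D2} .",
      "a possible interaction of {D1} with {D2} was observed ."),
    false = c(
      "{D1} and {D2} were both included in the formulary list .",
      "patients received {D1} , {D2} , or placebo in the trial .",
      "the study measured levels of {D1} and of {D2} separately .",
      "{D1} was administered in arm one and {D2} in arm two .",
      "no baseline data on {D1} or {D2} were collected .")
  )
}

# Cues plausible under either class of an overlap pair.
overlap_template_bank <- function() {
  c("{D1} alters the action of {D2} .",
    "{D1} modifies the response to {D2} .",
    "{D1} changes overall exposure to {D2} .",
    "{D1} affects the activity of {D2} .")
}

# Generic co-mentions carrying no class cue.
generic_template_bank <- function() {
  c("{D1} and {D2} were given to the patient .",
    "the discharge report mentions {D1} together with {D2} .",
    "{D1} was noted in the chart along with {D2} .",
    "hospital records list {D1} and {D2} .")
}

distractor_tokens <- function() {
  c("notably", "reportedly", "previously", "clinically", "however",
    "furthermore", "occasionally", "apparently", "in", "adults",
    "during", "follow-up", "per", "protocol", "at", "baseline")
}

#' Generate a labeled synthetic DDI corpus
#'
#' Builds sentences from a fixed per-class template bank with invented drug
#' names, yielding exactly the requested per-class instance counts (one
#' annotated pair per sentence, two drug entities with consistent character
#' offsets). Deterministic given the config seed.
#'
#' @param config A [synthetic_corpus_config()].
#' @return A [ddi_corpus()].
#' @export
#' @examples
#' cfg <- synthetic_corpus_config(c(effect = 3, false = 5), seed = 7)
#' label_counts(build_instances(generate_corpus(cfg)))
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_corpus_config"))
  with_seed(config$seed, {
    labels <- rep(names(config$per_class_counts), config$per_class_counts)
    labels <- sample(labels)
    drugs <- synthetic_drug_names()
    cues <- cue_template_bank()
    overlap_members <- unique(unlist(config$overlap_classes))
    sentences <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      lab <- labels[i]
      tmpl <- if (stats::runif(1) < config$cue_strength) {
        if (lab %in% overlap_members && stats::runif(1) < 0.5) {
          sample(overlap_template_bank(), 1L)
        } else sample(cues[[lab]], 1L)
      } else sample(generic_template_bank(), 1L)
      dd <- sample(drugs, 2L)
      tokens <- strsplit(tmpl, " ", fixed = TRUE)[[1]]
      if (stats::runif(1) < config$vocab_noise) {
        for (tok in sample(distractor_tokens(), sample(1:3, 1L))) {
          at <- sample(seq_len(length(tokens) + 1L), 1L)
          tokens <- append(tokens, tok, after = at - 1L)
        }
      }
      sentences[[i]] <- make_template_sentence(
        sid = paste0("s", i), tokens = tokens, d1 = dd[1], d2 = dd[2],
        label = lab)
    }
    docs <- split(sentences, ceiling(seq_along(sentences) / 25))
    names(docs) <- paste0("d", seq_along(docs))
    ddi_corpus(docs, provenance = sprintf("synthetic(seed=%d)", config$seed))
  })
}

# Substitute drug names into a token template and record their offsets.
make_template_sentence <- function(sid, tokens, d1, d2, label) {
  tokens[tokens == "{D1}"] <- d1
  tokens[tokens == "{D2}"] <- d2
  text <- paste(tokens, collapse = " ")
  starts <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  span_of <- function(name) {
    k <- which(tokens == name)[1]
    matrix(c(starts[k], starts[k] + nchar(name)), ncol = 2L,
           dimnames = list(NULL, c("start", "end")))
  }
  e1 <- entity_mention(paste0(sid, ".e0"), d1, span_of(d1))
  e2 <- entity_mention(paste0(sid, ".e1"), d2, span_of(d2))
  sentence_record(sid, text, list(e1, e2), data.frame(
    id = paste0(sid, ".p0"), e1 = e1$id, e2 = e2$id, label = label,
    stringsAsFactors = FALSE))
}

#' Configuration for Gaussian-blob embedding sets
#'
#' @param n_classes Number of classes (>= 1).
#' @param dim Embedding dimension (>= 1).
#' @param center_separation Minimum pairwise center distance, in units of
#'   `sigma`.
#' @param sigma Isotropic standard deviation of each class blob.
#' @param per_class_counts Named or unnamed vector of per-class sample counts
#'   (recycled to `n_classes`).
#' @param seed Integer seed.
#' @return A `blob_config` list.
#' @export
blob_config <- function(n_classes, dim, center_separation = 6, sigma = 1,
                        per_class_counts = 50, seed = 1L) {
  stopifnot(n_classes >= 1, dim >= 1, sigma > 0, center_separation >= 0)
  counts <- rep_len(as.integer(per_class_counts), n_classes)
  structure(list(n_classes = as.integer(n_classes), dim = as.integer(dim),
                 center_separation = center_separation, sigma = sigma,
                 per_class_counts = counts, seed = as.integer(seed)),
            class = "blob_config")
}

#' Sample labeled Gaussian-blob embeddings
#'
#' Class centers are drawn at random directions and rescaled so the minimum
#' pairwise center distance equals `center_separation * sigma`; each class
#' then samples from an isotropic Gaussian at its center. Deterministic given
#' the seed.
#'
#' @param config A [blob_config()].
#' @return A `labeled_embeddings` list with `vectors` (n x d matrix),
#'   `labels` (character, `"c1"`..`"ck"`), and `true_centers` (k x d matrix).
#' @export
generate_blobs <- function(config) {
  stopifnot(inherits(config, "blob_config"))
  k <- config$n_classes; d <- config$dim
  with_seed(config$seed, {
    centers <- matrix(stats::rnorm(k * d), nrow = k)
    if (k > 1L) {
      dmin <- min(stats::dist(centers))
      if (!is.finite(dmin) || dmin <= 0) {
        stop("cannot place ", k, " separated centers in dimension ", d)
      }
      centers <- centers * (config$center_separation * config$sigma / dmin)
    }
    rownames(centers) <- paste0("c", seq_len(k))
    n <- sum(config$per_class_counts)
    labels <- rep(rownames(centers), config$per_class_counts)
    vectors <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = config$sigma), nrow = n)
    dimnames(vectors) <- NULL
    structure(list(vectors = vectors, labels = labels,
                   true_centers = centers),
              class = "labeled_embeddings")
  })
}

#' Write / read a blob embedding set as a TSV pair
#'
#' `<prefix>.vectors.tsv` holds the n x d matrix, `<prefix>.labels.tsv` one
#' label per line.
#'
#' @param emb A `labeled_embeddings` object.
#' @param prefix Path prefix for the two files.
#' @return `prefix` invisibly (write) / a `labeled_embeddings` without
#'   `true_centers` (read).
#' @export
write_blobs <- function(emb, prefix) {
  utils::write.table(emb$vectors, paste0(prefix, ".vectors.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(emb$labels, paste0(prefix, ".labels.tsv"))
  invisible(prefix)
}

#' @rdname write_blobs
#' @export
read_blobs <- function(prefix) {
  vectors <- as.matrix(utils::read.table(paste0(prefix, ".vectors.tsv"),
                                         sep = "\t"))
  dimnames(vectors) <- NULL
  structure(list(vectors = vectors,
                 labels = readLines(paste0(prefix, ".labels.tsv")),
                 true_centers = NULL),
            class = "labeled_embeddings")
}
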