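#' Construct an entity mention
#'
#' A drug mention inside a sentence. `spans` uses the package-internal
#' 0-based half-open convention `[start, end)`; discontinuous mentions carry
#' several spans. Conversion from the corpus file's 0-based *inclusive*
#' offsets happens only at the I/O boundary ([read_corpus()] /
#' [write_corpus()]).
#'
#' @param id Entity id, unique within its sentence.
#' @param text Surface string of the mention (discontinuous parts joined by a
#'   single space).
#' @param spans Integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per contiguous span, sorted and non-overlapping.
#' @param etype Entity type string, usually `"drug"`.
#' @return An object of class `entity_mention`.
#' @export
entity_mention <- function(id, text, spans, etype = "drug") {
  spans <- matrix(as.integer(spans), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) == 0L) stop("entity '", id, "': spans must be non-empty")
  if (any(spans[, "start"] > spans[, "end"])) {
    stop("entity '", id, "': span start exceeds end")
  }
  if (is.unsorted(spans[, "start"], strictly = TRUE) && nrow(spans) > 1L) {
    stop("entity '", id, "': spans must be sorted")
  }
  if (nrow(spans) > 1L &&
      any(spans[-nrow(spans), "end"] > spans[-1L, "start"])) {
    stop("entity '", id, "': spans overlap")
  }
  structure(list(id = as.character(id), text = as.character(text),
                 spans = spans, etype = as.character(etype)),
            class = "entity_mention")
}

#' Construct a sentence record
#'
#' @param id Sentence id (unique corpus-wide).
#' @param text Sentence text.
#' @param entities List of [entity_mention()] objects.
#' @param pairs Data frame with columns `id`, `e1`, `e2`, `label`; one row
#'   per annotated candidate pair. `label` must be one of [ddi_labels()].
#' @return An object of class `sentence_record`.
#' @export
sentence_record <- function(id, text, entities = list(), pairs = empty_pairs()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  eids <- vapply(entities, function(e) e$id, character(1))
  if (anyDuplicated(eids)) {
    stop("sentence '", id, "': duplicated entity ids")
  }
  if (nrow(pairs) > 0L) {
    missing <- setdiff(unique(c(pairs$e1, pairs$e2)), eids)
    if (length(missing) > 0L) {
      stop("sentence '", id, "': pair references unknown entity id(s): ",
           paste(missing, collapse = ", "))
    }
    as_ddi_factor(pairs$label)  # validates the vocabulary
  }
  structure(list(id = as.character(id), text = as.character(text),
                 entities = entities, pairs = pairs),
            class = "sentence_record")
}

empty_pairs <- function() {
  data.frame(id = character(), e1 = character(), e2 = character(),
             label = character(), stringsAsFactors = FALSE)
}

#' Construct a corpus
#'
#' @param documents Named list: document id -> list of [sentence_record()]s.
#' @param provenance Free-text provenance string.
#' @return An object of class `ddi_corpus`.
#' @export
ddi_corpus <- function(documents = list(), provenance = "") {
  sids <- unlist(lapply(documents, function(d) {
    vapply(d, function(s) s$id, character(1))
  }), use.names = FALSE)
  if (anyDuplicated(sids)) {
    stop("sentence ids must be unique corpus-wide")
  }
  structure(list(documents = documents, provenance = as.character(provenance)),
            class = "ddi_corpus")
}

#' @export
print.ddi_corpus <- function(x, ...) {
  sents <- corpus_sentences(x)
  np <- sum(vapply(sents, function(s) nrow(s$pairs), integer(1)))
  cat(sprintf("<ddi_corpus> %d document(s), %d sentence(s), %d annotated pair(s)\n",
              length(x$documents), length(sents), np))
  invisible(x)
}

# Flat list of all sentence records.
corpus_sentences <- function(corpus) {
  unlist(corpus$documents, recursive = FALSE, use.names = FALSE)
}

#' Read a DDI-2013-dialect XML corpus
#'
#' Parses the XML dialect `<document>` / `<sentence>` / `<entity>` / `<pair>`.
#' Entity `charOffset` attributes are 0-based inclusive ranges (`"21-27"`),
#' possibly semicolon-separated for discontinuous mentions; they are converted
#' to the internal 0-based half-open convention. Pair elements carry
#' `ddi="false"` or `ddi="true"` with a `type` in effect / mechanism / advise
#' / int.
#'
#' @param path Path to the XML file.
#' @return A [ddi_corpus()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".xml")
#' write_corpus(generate_corpus(synthetic_corpus_config(
#'   per_class_counts = c(false = 2, effect = 1, mechanism = 0, advise = 0,
#'                        int = 0), seed = 1)), f)
#' read_corpus(f)
read_corpus <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("malformed XML in '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  docs <- xml2::xml_find_all(doc, ".//document")
  documents <- list()
  for (d in docs) {
    did <- xml2::xml_attr(d, "id")
    sents <- lapply(xml2::xml_find_all(d, "./sentence"), parse_sentence)
    documents[[did]] <- sents
  }
  ddi_corpus(documents, provenance = path)
}

parse_sentence <- function(node) {
  sid <- xml2::xml_attr(node, "id")
  text <- xml2::xml_attr(node, "text")
  entities <- lapply(xml2::xml_find_all(node, "./entity"), function(e) {
    entity_mention(
      id = xml2::xml_attr(e, "id"),
      text = xml2::xml_attr(e, "text"),
      spans = parse_char_offset(xml2::xml_attr(e, "charOffset")),
      etype = xml2::xml_attr(e, "type")
    )
  })
  pnodes <- xml2::xml_find_all(node, "./pair")
  pairs <- if (length(pnodes) == 0L) empty_pairs() else data.frame(
    id = xml2::xml_attr(pnodes, "id"),
    e1 = xml2::xml_attr(pnodes, "e1"),
    e2 = xml2::xml_attr(pnodes, "e2"),
    label = mapply(function(ddi, type) {
      if (identical(ddi, "false")) "false"
      else if (identical(ddi, "true")) {
        if (is.na(type) || !type %in% ddi_positive_labels()) {
          stop("sentence '", sid, "': unknown pair type '", type, "'",
               call. = FALSE)
        }
        type
      } else stop("sentence '", sid, "': ddi attribute must be true/false",
                  call. = FALSE)
    }, xml2::xml_attr(pnodes, "ddi"), xml2::xml_attr(pnodes, "type"),
    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  sentence_record(sid, text, entities, pairs)
}

# "21-26;55-60" (0-based inclusive) -> half-open span matrix.
parse_char_offset <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- t(vapply(parts, function(p) {
    se <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(se) != 2L || anyNA(se)) stop("bad charOffset '", s, "'")
    c(se[1], se[2] + 1L)  # inclusive end -> half-open
  }, integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

format_char_offset <- function(spans) {
  paste(sprintf("%d-%d", spans[, "start"], spans[, "end"] - 1L),
        collapse = ";")
}

#' Write a corpus in the DDI-2013 XML dialect
#'
#' The emitted file re-reads ([read_corpus()]) to a structurally equal corpus;
#' internal half-open offsets are converted back to the file's 0-based
#' inclusive convention.
#'
#' @param corpus A [ddi_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ddi_corpus"))
  root <- xml2::xml_new_root("corpus")
  for (did in names(corpus$documents)) {
    dnode <- xml2::xml_add_child(root, "document", id = did)
    for (s in corpus$documents[[did]]) {
      snode <- xml2::xml_add_child(dnode, "sentence", id = s$id, text = s$text)
      for (e in s$entities) {
        xml2::xml_add_child(snode, "entity", id = e$id,
                            charOffset = format_char_offset(e$spans),
                            type = e$etype, text = e$text)
      }
      if (nrow(s$pairs) > 0L) {
        for (i in seq_len(nrow(s$pairs))) {
          lab <- s$pairs$label[i]
          attrs <- list(id = s$pairs$id[i], e1 = s$pairs$e1[i],
                        e2 = s$pairs$e2[i],
                        ddi = if (lab == "false") "false" else "true")
          node <- do.call(xml2::xml_add_child, c(list(snode, "pair"), attrs))
          if (lab != "false") xml2::xml_set_attr(node, "type", lab)
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

marker_tokens <- function() c("[E1] ", " [/E1]", "[E2] ", " [/E2]")

#' Build classification instances from annotated pairs
#'
#' Emits exactly one instance per annotated `<pair>` element (no exhaustive
#' pair enumeration). `marked_text` carries the sentence with boundary tokens
#' around the two target mentions: scheme `"markers"` (default) inserts
#' literal `[E1] ... [/E1]` / `[E2] ... [/E2]` around the mentions, scheme
#' `"mask"` replaces the two target mentions with `DRUG1` / `DRUG2`.
#' Discontinuous mentions are marked on their first contiguous span only; all
#' spans are retained on the mention records. Non-target drug mentions are
#' left untouched unless `mask_other = TRUE` replaces them with `DRUG0`.
#'
#' @param corpus A [ddi_corpus()].
#' @param scheme `"markers"` or `"mask"`.
#' @param mask_other Also mask non-target drug mentions? Default `FALSE`.
#' @return List of `pair_instance` objects with fields `instance_id`,
#'   `sentence_id`, `raw_text`, `e1`, `e2`, `label`, `marked_text`.
#' @export
build_instances <- function(corpus, scheme = c("markers", "mask"),
                            mask_other = FALSE) {
  scheme <- match.arg(scheme)
  out <- list()
  for (s in corpus_sentences(corpus)) {
    if (nrow(s$pairs) == 0L) next
    ents <- stats::setNames(s$entities,
                            vapply(s$entities, function(e) e$id, character(1)))
    for (i in seq_len(nrow(s$pairs))) {
      e1 <- ents[[s$pairs$e1[i]]]
      e2 <- ents[[s$pairs$e2[i]]]
      out[[length(out) + 1L]] <- structure(list(
        instance_id = s$pairs$id[i],
        sentence_id = s$id,
        raw_text = s$text,
        e1 = e1, e2 = e2,
        label = s$pairs$label[i],
        marked_text = mark_sentence(s, e1, e2, scheme, mask_other)
      ), class = "pair_instance")
    }
  }
  out
}

# Insert markers (or masks) around the first span of each target mention.
mark_sentence <- function(sent, e1, e2, scheme, mask_other) {
  text <- sent$text
  if (scheme == "markers" && grepl("\\[/?E[12]\\]", text)) {
    stop("sentence '", sent$id,
         "': text already contains entity-marker tokens")
  }
  sp1 <- e1$spans[1L, , drop = TRUE]
  sp2 <- e2$spans[1L, , drop = TRUE]
  if (max(sp1["start"], sp2["start"]) < min(sp1["end"], sp2["end"])) {
    stop("sentence '", sent$id,
         "': target entity spans overlap; marker insertion is ambiguous")
  }
  edits <- list(
    list(span = sp1, open = "[E1] ", close = " [/E1]", mask = "DRUG1"),
    list(span = sp2, open = "[E2] ", close = " [/E2]", mask = "DRUG2")
  )
  if (mask_other) {
    targets <- c(e1$id, e2$id)
    for (e in sent$entities) {
      if (e$id %in% targets || e$etype != "drug") next
      edits[[length(edits) + 1L]] <-
        list(span = e$spans[1L, , drop = TRUE], open = "", close = "",
             mask = "DRUG0")
    }
  }
  # apply right-to-left so earlier offsets stay valid
  ord <- order(vapply(edits, function(ed) ed$span["start"], integer(1)),
               decreasing = TRUE)
  for (ed in edits[ord]) {
    a <- ed$span["start"]; b <- ed$span["end"]  # 0-based half-open
    before <- substr(text, 1L, a)
    inside <- substr(text, a + 1L, b)
    after <- substr(text, b + 1L, nchar(text))
    text <- if (scheme == "mask" || identical(ed$mask, "DRUG0")) {
      paste0(before, ed$mask, after)
    } else {
      paste0(before, ed$open, inside, ed$close, after)
    }
  }
  text
}

#' Remove entity-marker tokens from marked text
#'
#' Inverse of the `"markers"` scheme of [build_instances()]: stripping the
#' `[E1] `/` [/E1]`/`[E2] `/` [/E2]` tokens recovers the raw sentence.
#'
#' @param marked_text Character vector.
#' @return Character vector with marker tokens removed.
#' @export
strip_markers <- function(marked_text) {
  gsub("\\[E([12])\\] (.*?) \\[/E\\1\\]", "\\2", marked_text)
}

#' Count instances per DDI label
#'
#' @param instances List of instances from [build_instances()].
#' @return Named integer vector over the full vocabulary, canonical order;
#'   labels absent from `instances` get 0.
#' @export
label_counts <- function(instances) {
  labs <- vapply(instances, function(x) x$label, character(1))
  tab <- table(as_ddi_factor(if (length(labs)) labs else character()))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.pair_instance <- function(x, ...) {
  cat(sprintf("<pair_instance %s> label=%s\n  %s\n",
              x$instance_id, x$label, x$marked_text))
  invisible(x)
}
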