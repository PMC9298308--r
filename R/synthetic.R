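# Synthetic-corpus generator: documents with the statistical structure of
# annotated preclinical full texts (length distribution, per-item reporting
# prevalence) and planted evidence sentences, so that every other module is
# testable fully offline. The text is template noise, not natural language:
# it emulates document length, reporting prevalence and cue-phrase
# placement, nothing else.

synth_phrase_banks <- function() {
  list(
    random_allocation = list(
      canonical = c(
        "a randomisation code was used to allocate animals to treatment group",
        "animals were randomly allocated to treatment or control groups",
        "rats were randomly assigned to the experimental groups"
      ),
      paraphrase = c(
        "allocation to experimental group was performed at random using a computer generated sequence",
        "group assignment was determined by random allocation"
      )
    ),
    blinding = list(
      canonical = c(
        "sections were screened by a person unaware of the treatment condition of the animals",
        "outcomes were measured by an observer blind to the experimental conditions",
        "assessment of outcome was performed blinded to group identity"
      ),
      paraphrase = c(
        "the investigator scoring behaviour was unaware of the treatment received",
        "scoring was carried out by raters masked to group allocation"
      )
    ),
    conflict_of_interest = list(
      canonical = c(
        "the authors declare that they have no competing interests",
        "the authors report no conflict of interests",
        "no potential conflict of interests was reported by the authors"
      ),
      paraphrase = c(
        "all authors state the absence of any financial relationship that could be construed as a potential conflict of interests"
      )
    ),
    welfare_compliance = list(
      canonical = c(
        "experiments were performed in accordance with protocols approved by the institutional animal care and use committee",
        "all procedures complied with national guidelines for the care and use of laboratory animals",
        "animal experiments were approved by the local ethics committee and complied with welfare regulations"
      ),
      paraphrase = c(
        "husbandry and procedures followed institutional animal welfare regulations"
      )
    ),
    animal_exclusion = list(
      canonical = c(
        "animals in which the lesion was incomplete were excluded from the data analyses",
        "two animals were excluded from the final analysis because of surgical complications",
        "all animals and all measured outcomes are accounted for in the final analysis"
      ),
      paraphrase = c(
        "data from mice that failed the inclusion criteria were omitted from analysis"
      )
    )
  )
}

synth_distractors <- function() {
  c("animals were randomly selected for testing",
    "samples were selected at random for imaging",
    "the observer noted the group identity on the score sheet",
    "interests in the outcome were discussed by the committee",
    "no animals were available for the additional cohort")
}

synth_filler_vocab <- function() {
  c("the", "a", "of", "and", "in", "to", "was", "were", "with", "for",
    "mice", "rats", "animals", "group", "groups", "treatment", "control",
    "vehicle", "drug", "dose", "saline", "injection", "daily", "weekly",
    "brain", "tissue", "cells", "neurons", "cortex", "hippocampus",
    "behaviour", "test", "task", "maze", "latency", "distance", "score",
    "protein", "expression", "levels", "analysis", "data", "results",
    "significant", "increase", "decrease", "compared", "baseline",
    "measured", "observed", "performed", "obtained", "collected",
    "after", "before", "during", "between", "within", "following",
    "days", "weeks", "hours", "minutes", "mean", "standard", "error",
    "figure", "table", "shown", "values", "female", "male", "weight",
    "body", "water", "food", "housed", "cage", "light", "cycle",
    "surgery", "anaesthesia", "model", "lesion", "stroke", "infarct",
    "volume", "outcome", "primary", "secondary", "study", "experiment",
    "procedure", "method", "section", "staining", "antibody", "buffer",
    "solution", "concentration", "temperature", "room", "laboratory")
}

#' Specification of a synthetic corpus
#'
#' Defaults mirror the reporting prevalences observed in large annotated
#' preclinical corpora (27.5% random allocation, 30.6% blinding, 78.0%
#' conflict of interests, 31.5% welfare compliance, 12.2% animal
#' exclusions) and their document statistics (about 180 sentences and 28
#' tokens per sentence, i.e. roughly 5000 tokens per document).
#'
#' @param n_docs Number of documents.
#' @param prevalence Named per-item positive rates.
#' @param mean_sentences Mean sentences per document (default 180).
#' @param mean_tokens Mean tokens per sentence, including the sentence
#'   terminator (default 28).
#' @param distractor_rate Probability that an item-negative document
#'   contains a near-miss distractor sentence (default 0.3).
#' @param paraphrase_rate Probability that a planted evidence sentence is
#'   drawn from the paraphrase bank instead of the canonical bank
#'   (default 0.2).
#' @param junk_rate Per-sentence probability of an injected junk token,
#'   emulating residual conversion noise (default 0).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_docs,
                       prevalence = c(random_allocation = 0.275,
                                      blinding = 0.306,
                                      conflict_of_interest = 0.780,
                                      welfare_compliance = 0.315,
                                      animal_exclusion = 0.122),
                       mean_sentences = 180, mean_tokens = 28,
                       distractor_rate = 0.3, paraphrase_rate = 0.2,
                       junk_rate = 0, seed = 1L) {
  stopifnot(n_docs >= 1, all(prevalence >= 0), all(prevalence <= 1))
  banks <- synth_phrase_banks()
  for (item in names(prevalence)) {
    if (prevalence[[item]] > 0 &&
        length(banks[[item]]$canonical) == 0) {
      stop("positive prevalence for item without phrases: ", item)
    }
  }
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 mean_sentences = mean_sentences, mean_tokens = mean_tokens,
                 distractor_rate = distractor_rate,
                 paraphrase_rate = paraphrase_rate, junk_rate = junk_rate,
                 seed = as.integer(seed), banks = banks,
                 distractors = synth_distractors()),
            class = "synth_spec")
}

synth_sentence <- function(vocab, mean_tokens) {
  len <- max(3L, rpois(1, mean_tokens - 1))
  c(sample(vocab, len, replace = TRUE), ".")
}

phrase_to_sentence <- function(phrase) {
  c(strsplit(phrase, "\\s+")[[1]], ".")
}

#' Generate a synthetic corpus with planted evidence sentences
#'
#' Exactly `round(n_docs * prevalence[item])` documents are positive for
#' each item; every positive contains at least one evidence sentence from
#' that item's phrase bank at a random position, negatives contain none
#' (but may contain near-miss distractor sentences at
#' `distractor_rate`).
#'
#' @param spec A [synth_spec()].
#' @return List of `clean_document`s with per-item 0/1 labels; attribute
#'   `planted` holds, per document, the item -> sentence-index map of the
#'   planted evidence.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  # scrambled stream so that reusing one seed for generation and for
  # split_corpus() does not correlate the label draw with the split draw
  set.seed(bitwXor(spec$seed, 1301081L))
  n <- spec$n_docs
  items <- names(spec$prevalence)
  vocab <- synth_filler_vocab()

  pos <- lapply(items, function(item) {
    n_pos <- round(n * spec$prevalence[[item]])
    sample.int(n, n_pos)
  })
  names(pos) <- items

  docs <- vector("list", n)
  planted_all <- vector("list", n)
  for (i in seq_len(n)) {
    n_sent <- max(8L, rpois(1, spec$mean_sentences))
    sents <- lapply(seq_len(n_sent), function(j) {
      s <- synth_sentence(vocab, spec$mean_tokens)
      if (spec$junk_rate > 0 && runif(1) < spec$junk_rate) {
        junk <- paste(sample(letters, 8, replace = TRUE), collapse = "")
        s <- append(s, junk, after = sample(length(s) - 1, 1))
      }
      s
    })
    labels <- setNames(integer(length(items)), items)
    planted <- list()
    for (item in items) {
      if (i %in% pos[[item]]) {
        labels[[item]] <- 1L
        bank <- spec$banks[[item]]
        use_para <- length(bank$paraphrase) > 0 &&
          runif(1) < spec$paraphrase_rate
        phrase <- sample(if (use_para) bank$paraphrase else bank$canonical, 1)
        free <- setdiff(seq_along(sents), unlist(planted))
        at <- if (length(free) == 1) free else sample(free, 1)
        sents[[at]] <- phrase_to_sentence(phrase)
        planted[[item]] <- at
      } else if (runif(1) < spec$distractor_rate) {
        at <- sample.int(length(sents), 1)
        # distractors never overwrite planted evidence
        if (!(at %in% unlist(planted))) {
          sents[[at]] <- phrase_to_sentence(sample(spec$distractors, 1))
        }
      }
    }
    docs[[i]] <- clean_document(sprintf("synth-%04d", i), sents, labels)
    planted_all[[i]] <- planted
  }
  names(planted_all) <- vapply(docs, function(d) d$doc_id, "")
  attr(docs, "planted") <- planted_all
  docs
}

#' Generate labels and error-corrupted predictions
#'
#' For testing evaluation code: labels have exactly
#' `round(n_docs * prevalence)` positives; predictions independently flip
#' positives to 0 with probability `fn_rate` and negatives to 1 with
#' probability `fp_rate`.
#'
#' @param n_docs Number of records.
#' @param prevalence Positive label rate (default 0.275).
#' @param fn_rate,fp_rate Flip probabilities (defaults 0).
#' @param seed Integer seed.
#' @return List with `labels` and `preds` (0/1 integer vectors).
#' @export
generate_labelled_predictions <- function(n_docs, prevalence = 0.275,
                                          fn_rate = 0, fp_rate = 0,
                                          seed = 1L) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1)
  set.seed(as.integer(seed))
  n_pos <- round(n_docs * prevalence)
  labels <- integer(n_docs)
  labels[sample.int(n_docs, n_pos)] <- 1L
  preds <- labels
  flip_fn <- labels == 1L & runif(n_docs) < fn_rate
  flip_fp <- labels == 0L & runif(n_docs) < fp_rate
  preds[flip_fn] <- 0L
  preds[flip_fp] <- 1L
  list(labels = labels, preds = preds)
}
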