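# Seeded generator of DDI-style annotated corpora, drug dictionaries and
# word-embedding tables. Entity names are built from morpheme inventories
# with type-characteristic suffixes, so surface morphology, dictionary
# membership and embedding clusters all carry learnable signal; a
# configurable share of drug names also occurs unannotated in non-mention
# contexts, making context (conjunction) features informative.

# fixed derivation fanning one global seed out into independent streams
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Configuration of the synthetic corpus generator
#'
#' @param seed global integer seed; all streams (corpus, dictionaries,
#'   embeddings) are derived from it deterministically.
#' @param n_sentences number of sentences to generate.
#' @param mixture named probabilities over the four entity types. The
#'   default is skewed like real DDI-style corpora: drugs dominate and
#'   `no-human` is rare (64/23/9/4%).
#' @param dict_coverage fraction of the distinct entity-name vocabulary
#'   each generated dictionary contains.
#' @param embed_dim dimension of generated word embeddings.
#' @param noise_rate probability of inserting an uninformative noise token
#'   at each sentence position.
#' @param ambiguous_rate probability that a sentence uses an ambiguous
#'   frame, in which a drug name occurs unannotated (e.g. an endogenous
#'   substance reading).
#' @return Object of class `dnr_sim_config`.
#' @export
simulate_config <- function(seed = 1L, n_sentences = 100L,
                            mixture = c(drug = 0.64, brand = 0.09,
                                        group = 0.23, `no-human` = 0.04),
                            dict_coverage = 0.8, embed_dim = 50L,
                            noise_rate = 0.05, ambiguous_rate = 0.1) {
  full <- setNames(numeric(4), dnr_entity_types())
  if (is.null(names(mixture)) ||
      length(setdiff(names(mixture), dnr_entity_types()))) {
    stop("mixture must be named over ", paste(dnr_entity_types(),
                                              collapse = ", "))
  }
  full[names(mixture)] <- mixture
  if (abs(sum(full) - 1) > 1e-8 || any(full < 0)) {
    stop("mixture probabilities must be non-negative and sum to 1")
  }
  if (dict_coverage < 0 || dict_coverage > 1) {
    stop("dict_coverage must lie in [0, 1]")
  }
  if (embed_dim < 2L) stop("embed_dim must be >= 2")
  structure(list(seed = as.integer(seed),
                 n_sentences = as.integer(n_sentences),
                 mixture = full, dict_coverage = dict_coverage,
                 embed_dim = as.integer(embed_dim),
                 noise_rate = noise_rate, ambiguous_rate = ambiguous_rate),
            class = "dnr_sim_config")
}

SALT_WORDS <- c("hydrochloride", "sodium", "sulfate", "acetate")
GROUP_MODIFIERS <- c("beta", "calcium", "channel", "proton", "pump",
                     "monoamine", "oxidase")
FILLER_WORDS <- c("the", "of", "and", "with", "in", "patients", "treated",
                  "may", "reduce", "increase", "plasma", "levels", "effect",
                  "dose", "during", "therapy", "observed", "clinical",
                  "studies", "was", "not", "recommended", "should", "be",
                  "adjusted", "risk", "use", "is", "a", "healthy",
                  "subjects", "exposure", "concomitant", "administration",
                  "showed", "elevated", "liver", "enzymes", "vary",
                  "widely", "endogenous", "secretion", "received",
                  "coadministration", "interaction", "no", "significant")

make_name_inventory <- function() {
  syll1 <- c("lo", "fe", "ta", "oxi", "ce", "vela", "mi", "do", "ra", "ni",
             "pra", "zu", "ke", "bu", "sa", "tri")
  syll2 <- c("ri", "na", "to", "ve", "li", "pa", "mo", "du", "ga", "si")
  drug_suffix <- c("mab", "vir", "cillin", "azole", "pril", "olol",
                   "statin", "mycin", "afil", "parin")
  nohuman_suffix <- c("thion", "fos", "carb", "trin", "quat")
  brand_suffix <- c("ex", "or", "ra", "in", "za", "vo")
  coin <- function(k, suffixes) {
    out <- character(0)
    while (length(out) < k) {
      out <- unique(c(out, paste0(sample(syll1, 1), sample(syll2, 1),
                                  sample(suffixes, 1))))
    }
    out
  }
  drugs <- coin(60, drug_suffix)
  nohuman <- coin(25, nohuman_suffix)
  brands0 <- coin(30, brand_suffix)
  brands <- paste0(toupper(substr(brands0, 1, 1)),
                   substr(brands0, 2, nchar(brands0)))
  heads <- c("inhibitors", "blockers", "agonists", "antagonists",
             "antibiotics", "diuretics", "anticoagulants",
             "corticosteroids", "antidepressants", "barbiturates")
  groups <- c(heads,
              paste("beta", sample(heads, 4)),
              paste("calcium channel", sample(heads, 3)),
              paste("proton pump", sample(heads, 3)),
              paste("monoamine oxidase", sample(heads, 3)))
  list(drug = drugs, brand = brands, group = unique(groups),
      `no-human` = nohuman,
       ambiguous = sample(drugs, 3))
}

sample_mention_tokens <- function(type, inv) {
  if (type == "drug") {
    name <- sample(inv$drug, 1)
    u <- runif(1)
    if (u < 0.70) name
    else if (u < 0.92) c(name, sample(SALT_WORDS, 1))
    else c(name, sample(SALT_WORDS, 2))
  } else if (type == "brand") {
    sample(inv$brand, 1)
  } else if (type == "group") {
    strsplit(sample(inv$group, 1), " ", fixed = TRUE)[[1]]
  } else {
    sample(inv$`no-human`, 1)
  }
}

SENTENCE_FRAMES <- list(
  c("coadministration", "of", "{M}", "and", "{M}", "increased", "plasma",
    "exposure", "."),
  c("{M}", "may", "reduce", "the", "effect", "of", "{M}", "in", "patients",
    "."),
  c("patients", "treated", "with", "{M}", "showed", "elevated", "liver",
    "enzymes", "."),
  c("the", "dose", "of", "{M}", "should", "be", "adjusted", "during",
    "therapy", "with", "{M}", "."),
  c("use", "of", "{M}", "with", "{M}", "is", "not", "recommended", "."),
  c("{M}", "increased", "the", "risk", "of", "bleeding", "with", "{M}",
    "."),
  c("no", "significant", "interaction", "was", "observed", "in", "clinical",
    "studies", "."),
  c("concomitant", "administration", "of", "{M}", "requires", "monitoring",
    ".")
)
AMBIGUOUS_FRAME <- c("endogenous", "{A}", "levels", "vary", "widely", "in",
                     "healthy", "subjects", ".")

random_noise_token <- function() {
  u <- runif(1)
  if (u < 0.4) as.character(sample.int(500, 1))
  else if (u < 0.7) paste0(sample.int(40, 1) * 5, "mg")
  else sample(c("(", ")", "%", "q8h", "b.i.d"), 1)
}

#' Generate a synthetic annotated corpus
#'
#' Produces sentences whose entity mentions (1--3 tokens) are always
#' token-aligned by construction, typed by the configured mixture and
#' built from type-characteristic morphology. Deterministic under the
#' config seed.
#'
#' @param config a [simulate_config()].
#' @return List of [dnr_sentence()] with doc ids `s1..sN`; the name
#'   inventory used is attached as attribute `"inventory"`.
#' @export
generate_corpus <- function(config = simulate_config()) {
  stopifnot(inherits(config, "dnr_sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    inv <- make_name_inventory()
    types <- dnr_entity_types()
    sentences <- vector("list", config$n_sentences)
    for (si in seq_len(config$n_sentences)) {
      use_amb <- runif(1) < config$ambiguous_rate
      frame <- if (use_amb) AMBIGUOUS_FRAME
               else SENTENCE_FRAMES[[sample.int(length(SENTENCE_FRAMES), 1)]]
      toks <- character(0)
      mention_rows <- list()
      for (w in frame) {
        if (w == "{M}") {
          tp <- sample(types, 1, prob = config$mixture)
          mt <- sample_mention_tokens(tp, inv)
          first <- length(toks) + 1L
          toks <- c(toks, mt)
          mention_rows[[length(mention_rows) + 1L]] <-
            list(first = first, last = length(toks), type = tp)
        } else if (w == "{A}") {
          toks <- c(toks, sample(inv$ambiguous, 1))
        } else {
          toks <- c(toks, w)
        }
        if (runif(1) < config$noise_rate) toks <- c(toks, random_noise_token())
      }
      starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)]
      tok_df <- data.frame(text = toks, start = starts,
                           end = starts + nchar(toks),
                           index = seq_along(toks) - 1L,
                           stringsAsFactors = FALSE)
      men <- if (length(mention_rows)) {
        data.frame(
          start = vapply(mention_rows, function(m) starts[m$first],
                         integer(1)),
          end = vapply(mention_rows, function(m)
            starts[m$last] + nchar(toks[m$last]), integer(1)),
          type = vapply(mention_rows, `[[`, character(1), "type"),
          stringsAsFactors = FALSE)
      } else NULL
      sentences[[si]] <- dnr_sentence(paste(toks, collapse = " "),
                                      mentions = men, tokens = tok_df,
                                      doc_id = paste0("s", si))
    }
    attr(sentences, "inventory") <- inv
    sentences
  })
}

corpus_inventory <- function(corpus) {
  inv <- attr(corpus, "inventory")
  if (is.null(inv)) {
    # reconstruct name vocabulary from the annotated mentions
    men <- do.call(rbind, lapply(corpus, `[[`, "mentions"))
    words <- function(tp) {
      w <- unlist(strsplit(men$text[men$type == tp], " ", fixed = TRUE))
      setdiff(unique(w), SALT_WORDS)
    }
    inv <- list(drug = words("drug"), brand = words("brand"),
                group = unique(men$text[men$type == "group"]),
                `no-human` = words("no-human"), ambiguous = character(0))
  }
  inv
}

exact_fraction <- function(x, coverage) {
  k <- round_half_away(coverage * length(x))
  if (k <= 0L) character(0) else sample(x)[seq_len(k)]
}

#' Generate three drug-dictionary fixtures from a corpus
#'
#' Each dictionary contains an (exact) `coverage` fraction of the distinct
#' entity-name vocabulary plus common-word distractors; the three draws are
#' independent, so the dictionaries overlap but differ. The first two
#' emulate curated drug/brand lists; the third is broader and also samples
#' non-human substance names.
#'
#' @param corpus from [generate_corpus()].
#' @param coverage fraction in `[0, 1]` of distinct name words included.
#' @param seed integer seed.
#' @return List of three [dnr_dictionary()] objects.
#' @export
generate_dictionaries <- function(corpus, coverage = 0.8, seed = 1L) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  inv <- corpus_inventory(corpus)
  with_seed(derive_seed(seed, 2L), {
    # each word stratum is sampled at the exact coverage fraction, so the
    # realized token-level hit rate concentrates tightly around `coverage`
    mk <- function(name, strata) {
      terms <- unlist(lapply(strata, exact_fraction, coverage = coverage))
      distract <- sample(FILLER_WORDS, 12)
      dnr_dictionary(c(terms, distract), name = name)
    }
    list(mk("DrugBank", list(inv$drug, SALT_WORDS, tolower(inv$brand))),
         mk("FDA", list(inv$drug, SALT_WORDS, tolower(inv$brand))),
         mk("Jochem", list(inv$drug, SALT_WORDS, inv$`no-human`)))
  })
}

#' Generate a word-embedding table from a corpus
#'
#' Every corpus word gets a vector sampled around a Gaussian center shared
#' by its category (one center per entity type plus one for common words),
#' so k-means clustering of the table recovers the type structure. A small
#' fraction of the vocabulary is left out of the table to exercise the
#' out-of-vocabulary path.
#'
#' @param corpus from [generate_corpus()].
#' @param dimension embedding dimension (>= 2).
#' @param seed integer seed.
#' @param oov_rate fraction of vocabulary excluded from the table.
#' @return Numeric matrix with words as rownames; the category of each
#'   word is attached as attribute `"category"`.
#' @export
generate_embeddings <- function(corpus, dimension = 50L, seed = 1L,
                                oov_rate = 0.05) {
  if (dimension < 2L) stop("dimension must be >= 2")
  inv <- corpus_inventory(corpus)
  vocab <- unique(tolower(unlist(lapply(corpus, function(s) s$tokens$text))))
  group_words <- setdiff(unique(unlist(strsplit(inv$group, " ", fixed = TRUE))),
                         GROUP_MODIFIERS)
  category <- rep("common", length(vocab))
  names(category) <- vocab
  category[vocab %in% inv$drug] <- "drug"
  category[vocab %in% tolower(inv$brand)] <- "brand"
  category[vocab %in% group_words] <- "group"
  category[vocab %in% inv$`no-human`] <- "no-human"
  with_seed(derive_seed(seed, 3L), {
    cats <- unique(category)
    centers <- matrix(stats::rnorm(length(cats) * dimension, sd = 6),
                      nrow = length(cats),
                      dimnames = list(cats, NULL))
    emb <- centers[category, , drop = FALSE] +
      matrix(stats::rnorm(length(vocab) * dimension), nrow = length(vocab))
    rownames(emb) <- vocab
    keep <- sort(sample(seq_along(vocab),
                        length(vocab) - floor(oov_rate * length(vocab))))
    emb <- emb[keep, , drop = FALSE]
    attr(emb, "category") <- category[keep]
    emb
  })
}

#' Generate the full resource bundle for a pipeline run
#'
#' Corpus, three dictionaries, embedding table and a fitted embedding
#' cluster model, all derived from one config.
#'
#' @param config a [simulate_config()].
#' @param k number of embedding clusters; default one per entity category.
#' @return List with `corpus`, `dictionaries`, `embeddings`, `clusters`.
#' @export
generate_resources <- function(config = simulate_config(), k = 5L) {
  corpus <- generate_corpus(config)
  dicts <- generate_dictionaries(corpus, config$dict_coverage, config$seed)
  emb <- generate_embeddings(corpus, config$embed_dim, config$seed)
  clusters <- fit_embedding_clusters(emb, k = k,
                                     seed = derive_seed(config$seed, 4L))
  list(corpus = corpus, dictionaries = dicts, embeddings = emb,
       clusters = clusters)
}
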