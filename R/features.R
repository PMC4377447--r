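#' Singleton feature template registry
#'
#' The sixteen default templates: `f1` word, `f2` POS, `f3` chunk, `f4`
#' orthography, `f5`--`f7` dictionary membership, `f8` embedding cluster,
#' `f9`--`f11` prefixes of length 3/4/5, `f12`--`f14` suffixes of length
#' 3/4/5, `f15` generalized word shape, `f16` brief word shape.
#'
#' @return data.frame with columns `id` (1..16), `tid` (`"f1"`..`"f16"`)
#'   and `name`.
#' @export
singleton_templates <- function() {
  data.frame(
    id = 1:16,
    tid = paste0("f", 1:16),
    name = c("word", "pos", "chunk", "orthographic",
             "dict-DrugBank", "dict-FDA", "dict-Jochem",
             "embedding-cluster",
             "prefix3", "prefix4", "prefix5",
             "suffix3", "suffix4", "suffix5",
             "shape-generalized", "shape-brief"),
    stringsAsFactors = FALSE)
}

BOS_VALUE <- "__BOS__"
EOS_VALUE <- "__EOS__"

#' Word feature: the surface form itself
#' @param token a non-empty token string.
#' @return The feature value (the token).
#' @export
extract_word <- function(token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(token)) {
    stop("empty token")
  }
  token
}

#' Orthographic feature
#'
#' Classifies a token into one of `All-capitalized`, `Is-capitalized`,
#' `All-digits`, `Alphanumeric` (first matching class in that precedence
#' order; `Other` when none applies) and flags whether it contains a
#' hyphen. `Alphanumeric` means the token contains at least one letter and
#' one digit, internal symbols allowed.
#'
#' @param token non-empty token string.
#' @return Named character vector `c(class = ..., hyphen = "Y"/"N")`.
#' @export
extract_orthographic <- function(token) {
  stopifnot(nzchar(token))
  cls <-
    if (grepl("^[[:upper:]]+$", token)) "All-capitalized"
    else if (grepl("^[[:upper:]]", token)) "Is-capitalized"
    else if (grepl("^[[:digit:]]+$", token)) "All-digits"
    else if (grepl("[[:alpha:]]", token) && grepl("[[:digit:]]", token))
      "Alphanumeric"
    else "Other"
  c(class = cls, hyphen = if (grepl("-", token, fixed = TRUE)) "Y" else "N")
}

#' Affix features: prefixes and suffixes of length 3, 4 and 5
#'
#' Affixes longer than the token are omitted (not padded), so a token of
#' `nchar` 4 yields only the length-3 and length-4 affixes.
#'
#' @param token non-empty token string.
#' @return Named character vector with elements among `prefix3..prefix5`,
#'   `suffix3..suffix5`.
#' @export
extract_affixes <- function(token) {
  stopifnot(nzchar(token))
  n <- nchar(token)
  out <- character(0)
  for (len in 3:5) {
    if (n >= len) {
      out[paste0("prefix", len)] <- substr(token, 1L, len)
      out[paste0("suffix", len)] <- substr(token, n - len + 1L, n)
    }
  }
  out
}

#' Word shape feature
#'
#' The generalized word class maps every uppercase letter, lowercase
#' letter, digit and other character to `X`, `x`, `0` and `O`; the brief
#' word class additionally collapses consecutive identical symbols. E.g.
#' `"Aspirin1+"` has shapes `"Xxxxxxx0O"` and `"Xx0O"`.
#'
#' @param token non-empty token string.
#' @param mode `"generalized"` or `"brief"`.
#' @return The shape string.
#' @export
word_shape <- function(token, mode = c("generalized", "brief")) {
  stopifnot(nzchar(token))
  mode <- match.arg(mode)
  shape <- gsub("[[:upper:]]", "X", token)
  shape <- gsub("[[:lower:]]", "x", shape)
  shape <- gsub("[[:digit:]]", "0", shape)
  shape <- gsub("[^Xx0]", "O", shape)
  if (mode == "brief") shape <- gsub("(.)\\1+", "\\1", shape)
  shape
}

#' Dictionary membership feature
#'
#' `"Y"` iff the lower-cased token appears in the dictionary's word set
#' (single-word terms or any word of a multiword term), else `"N"`.
#'
#' @param token token string.
#' @param dictionary a [dnr_dictionary()].
#' @return `"Y"` or `"N"`.
#' @export
extract_dictionary <- function(token, dictionary) {
  stopifnot(inherits(dictionary, "dnr_dictionary"))
  if (dict_contains(dictionary, token)) "Y" else "N"
}

#' Embedding-cluster feature
#'
#' The semantic class (k-means cluster id) a word belongs to; the dedicated
#' id `"OOV"` for out-of-vocabulary words.
#'
#' @param token token string.
#' @param model a [fit_embedding_clusters()] model.
#' @return Cluster id as a character scalar.
#' @export
extract_embedding_cluster <- function(token, model) {
  stopifnot(inherits(model, "dnr_cluster_model"))
  unname(cluster_id(model, token))
}

#' Feature-extraction configuration
#'
#' Bundles the resources and the set of enabled singleton templates used by
#' [extract_sentence_features()] and [extract_features()].
#'
#' @param templates integer vector of enabled template ids (subset of
#'   1..16). Templates 5--7 require `dictionaries`; template 8 requires
#'   `clusters`; 2--3 require a tagger.
#' @param tagger a function `tokens -> list(pos, chunk)`; see
#'   [simple_tagger()].
#' @param dictionaries list of up to three [dnr_dictionary()] objects (in
#'   template order f5, f6, f7).
#' @param clusters a [fit_embedding_clusters()] model or `NULL`.
#' @param conjunctions a [conjunction_set()] (e.g. `rbind(build_S1(),
#'   build_S2())`) or `NULL` for singleton features only.
#' @param window half-width of the context window (2 gives the 5-token
#'   window).
#' @return Object of class `dnr_feature_config`.
#' @export
feature_config <- function(templates = 1:16, tagger = simple_tagger,
                           dictionaries = list(), clusters = NULL,
                           conjunctions = NULL, window = 2L) {
  templates <- sort(unique(as.integer(templates)))
  if (length(templates) == 0L || any(templates < 1L | templates > 16L)) {
    stop("'templates' must be a non-empty subset of 1..16")
  }
  ndict <- length(dictionaries)
  need_dict <- intersect(templates, 5:7)
  if (length(need_dict) && ndict < max(need_dict) - 4L) {
    stop("templates f5-f7 enabled but only ", ndict, " dictionaries supplied")
  }
  if (8L %in% templates && is.null(clusters)) {
    stop("template f8 enabled but no cluster model supplied")
  }
  structure(list(templates = templates, tagger = tagger,
                 dictionaries = dictionaries, clusters = clusters,
                 conjunctions = conjunctions, window = as.integer(window)),
            class = "dnr_feature_config")
}

# Per-token singleton values for one sentence: a list keyed by template id
# ("f1".."f16") of character vectors (NA where an affix is omitted), plus
# the auxiliary hyphen flag vector used for the extra f4 feature.
singleton_values <- function(sentence, config) {
  words <- sentence$tokens$text
  n <- length(words)
  if (n == 0L) return(list(values = list(), hyphen = NULL, n = 0L))
  vals <- list()
  tpl <- config$templates
  if (any(c(2L, 3L) %in% tpl)) {
    tagging <- check_tagger_output(config$tagger(words), n)
    if (2L %in% tpl) vals$f2 <- tagging$pos
    if (3L %in% tpl) vals$f3 <- tagging$chunk
  }
  if (1L %in% tpl) vals$f1 <- words
  hyph <- NULL
  if (4L %in% tpl) {
    orth <- vapply(words, extract_orthographic, character(2))
    vals$f4 <- unname(orth["class", ])
    hyph <- unname(orth["hyphen", ])
  }
  for (d in seq_len(3L)) {
    id <- 4L + d
    if (id %in% tpl) {
      dict <- config$dictionaries[[d]]
      vals[[paste0("f", id)]] <-
        ifelse(tolower(words) %in% dict$words, "Y", "N")
    }
  }
  if (8L %in% tpl) vals$f8 <- unname(cluster_id(config$clusters, words))
  if (any(9:14 %in% tpl)) {
    nc <- nchar(words)
    for (len in 3:5) {
      pid <- paste0("f", 6L + len)   # f9..f11
      sid <- paste0("f", 9L + len)   # f12..f14
      pre <- ifelse(nc >= len, substr(words, 1L, len), NA_character_)
      suf <- ifelse(nc >= len, substr(words, nc - len + 1L, nc),
                    NA_character_)
      if ((6L + len) %in% tpl) vals[[pid]] <- pre
      if ((9L + len) %in% tpl) vals[[sid]] <- suf
    }
  }
  if (15L %in% tpl) {
    vals$f15 <- vapply(words, word_shape, character(1), mode = "generalized")
  }
  if (16L %in% tpl) {
    vals$f16 <- vapply(words, word_shape, character(1), mode = "brief")
  }
  list(values = vals, hyphen = hyph, n = n)
}

# Value of template `tid` at absolute position p for a sentence of n tokens;
# sentinel beyond the edges, NA when omitted (short-word affix).
value_at <- function(vals, tid, p, n) {
  if (p < 1L) return(BOS_VALUE)
  if (p > n) return(EOS_VALUE)
  vals[[tid]][p]
}

#' Extract window-expanded singleton features for every token
#'
#' Every enabled template is instantiated at each window offset `j` in
#' `-window..window` relative to the target token; positions beyond the
#' sentence edges carry BOS/EOS sentinel values. Feature strings are
#' serialized as `f<i>[<j>]=<value>`; the orthographic template
#' additionally emits a `f4[<j>]=HYPHEN-Y/N` flag. Short-word affixes are
#' omitted rather than padded.
#'
#' @param sentence a [dnr_sentence()].
#' @param config a [feature_config()].
#' @return List (one element per token) of character vectors of serialized
#'   feature strings.
#' @export
extract_sentence_features <- function(sentence, config = feature_config()) {
  sv <- singleton_values(sentence, config)
  n <- sv$n
  offs <- seq.int(-config$window, config$window)
  tids <- paste0("f", config$templates)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    feats <- character(0)
    for (tid in tids) {
      for (j in offs) {
        v <- value_at(sv$values, tid, t + j, n)
        if (!is.na(v)) {
          feats <- c(feats, paste0(tid, "[", j, "]=", v))
        }
        if (tid == "f4" && !is.null(sv$hyphen) &&
            t + j >= 1L && t + j <= n) {
          feats <- c(feats, paste0("f4[", j, "]=HYPHEN-", sv$hyphen[t + j]))
        }
      }
    }
    out[[t]] <- feats
  }
  out
}

#' Extract the full feature representation of a sentence
#'
#' Window-expanded singleton features plus, when the configuration carries
#' a conjunction template set, the conjunction features.
#'
#' @param sentence a [dnr_sentence()].
#' @param config a [feature_config()].
#' @return List (one element per token) of character vectors.
#' @export
extract_features <- function(sentence, config = feature_config()) {
  singles <- extract_sentence_features(sentence, config)
  if (is.null(config$conjunctions)) return(singles)
  conj <- apply_conjunctions(sentence, config$conjunctions, config)
  Map(c, singles, conj)
}
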