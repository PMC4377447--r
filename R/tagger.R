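#' Deterministic rule-based POS/chunk tagger
#'
#' A bundled stand-in for an external biomedical tagger, satisfying the
#' tagger contract used by [extract_sentence_features()]: given the token
#' surface forms of one sentence it returns one POS label and one chunk
#' label per token, deterministically. POS labels come from a small
#' Penn-style set assigned by closed-class lists and suffix rules; chunks
#' are BIO noun-phrase/verb-phrase labels from a simple grammar
#' (determiner/adjective/noun runs form NPs).
#'
#' @param tokens character vector of token surface forms.
#' @return list with components `pos` and `chunk`, character vectors of the
#'   same length as `tokens`.
#' @export
simple_tagger <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(list(pos = character(0), chunk = character(0)))
  dets <- c("the", "a", "an", "this", "that", "these", "those", "each",
            "any", "no", "its")
  conj <- c("and", "or", "but", "nor")
  prep <- c("of", "in", "with", "to", "for", "on", "by", "after", "before",
            "during", "at", "from", "into", "between", "as", "than")
  verbs <- c("is", "are", "was", "were", "be", "been", "has", "have", "had",
             "may", "can", "should", "must", "do", "does", "did", "will")
  prons <- c("it", "they", "we", "patients")
  lw <- tolower(tokens)
  pos <- character(n)
  for (i in seq_len(n)) {
    w <- tokens[i]; l <- lw[i]
    pos[i] <-
      if (grepl("^[0-9][0-9.,%/-]*$", w)) "CD"
      else if (!grepl("[[:alnum:]]", w)) "PUNCT"
      else if (l %in% dets) "DT"
      else if (l %in% conj) "CC"
      else if (l %in% prep) "IN"
      else if (l %in% verbs) "VB"
      else if (l %in% prons) "PRP"
      else if (grepl("ly$", l)) "RB"
      else if (grepl("(ed|en)$", l) && nchar(l) > 3L) "VBN"
      else if (grepl("ing$", l) && nchar(l) > 4L) "VBG"
      else if (grepl("(ive|al|ous|ic|ant|ent|able)$", l) && nchar(l) > 4L) "JJ"
      else if (grepl("s$", l) && !grepl("(ss|us|is)$", l) && nchar(l) > 3L)
        "NNS"
      else if (grepl("^[A-Z]", w)) "NNP"
      else "NN"
  }
  nounish <- pos %in% c("DT", "JJ", "NN", "NNS", "NNP", "CD")
  chunk <- character(n)
  for (i in seq_len(n)) {
    chunk[i] <-
      if (nounish[i]) {
        if (i > 1L && nounish[i - 1L]) "I-NP" else "B-NP"
      } else if (pos[i] %in% c("VB", "VBN", "VBG")) "B-VP"
      else "O"
  }
  list(pos = pos, chunk = chunk)
}

check_tagger_output <- function(tagging, n) {
  if (!is.list(tagging) || is.null(tagging$pos) || is.null(tagging$chunk) ||
      length(tagging$pos) != n || length(tagging$chunk) != n) {
    stop("tagger contract violated: need pos and chunk vectors of length ", n)
  }
  invisible(tagging)
}
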