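# Conjunction features: 2-tuple combinations of singleton features, denoted
# f_{i1}[j1]_f_{i2}[j2]. Member values are escaped before joining so the
# serialized form parses unambiguously even when a value contains "_".

escape_value <- function(v) gsub("_", "%5F", gsub("%", "%25", v, fixed = TRUE),
                                 fixed = TRUE)

#' Build a conjunction template set
#'
#' A conjunction template pairs two singleton features, each identified by
#' a template id and a window offset; the instantiated feature's value is
#' the `"_"`-joined pair of member values.
#'
#' @param i1,j1,i2,j2 equal-length integer vectors: template ids (1..16)
#'   and window offsets (within `-2..2`) of the two members.
#' @param name set name (e.g. `"S1"`, `"S2"`, `"custom"`).
#' @return data.frame of class `dnr_conjunction_set` with columns
#'   `i1,j1,i2,j2`.
#' @export
conjunction_set <- function(i1, j1, i2, j2, name = "custom") {
  stopifnot(length(i1) == length(j1), length(i1) == length(i2),
            length(i1) == length(j2))
  if (any(c(j1, j2) < -2L | c(j1, j2) > 2L)) {
    stop("conjunction member offsets must lie within [-2, 2]")
  }
  if (any(c(i1, i2) < 1L | c(i1, i2) > 16L)) {
    stop("conjunction member template ids must lie within 1..16")
  }
  out <- data.frame(i1 = as.integer(i1), j1 = as.integer(j1),
                    i2 = as.integer(i2), j2 = as.integer(j2))
  attr(out, "name") <- name
  class(out) <- c("dnr_conjunction_set", "data.frame")
  out
}

#' The S1 conjunction template set: same-type bigrams in the window
#'
#' For each of the word, POS and chunk templates (`f1`--`f3`) and each
#' offset `m` in `-2..1`, the bigram `f_i[m]_f_i[m+1]` of two adjacent
#' window positions: 12 templates in total.
#'
#' @return A [conjunction_set()] of 12 templates named `"S1"`.
#' @export
build_S1 <- function() {
  grid <- expand.grid(m = -2:1, i = 1:3)
  conjunction_set(grid$i, grid$m, grid$i, grid$m + 1L, name = "S1")
}

#' The S2 conjunction template set: cross-type pairs at the target word
#'
#' All unordered pairs of different templates among `f2`--`f8` at offset 0
#' (21 pairs), plus the two word pairs `f1[0]_f2[0]` and `f1[0]_f3[0]`
#' (the word feature combines only with POS and chunk): 23 templates.
#'
#' @return A [conjunction_set()] of 23 templates named `"S2"`.
#' @export
build_S2 <- function() {
  pairs <- t(combn(2:8, 2L))
  conjunction_set(c(1L, 1L, pairs[, 1L]), rep(0L, 2L + nrow(pairs)),
                  c(2L, 3L, pairs[, 2L]), rep(0L, 2L + nrow(pairs)),
                  name = "S2")
}

#' Read a conjunction template set from a text spec
#'
#' One template per line in the form `f1[-2]_f1[-1]`; blank lines and lines
#' starting with `#` are ignored. Lets custom sets beyond S1/S2 be declared
#' without code changes.
#'
#' @param path file path.
#' @param name set name.
#' @return A [conjunction_set()].
#' @export
read_conjunction_set <- function(path, name = "custom") {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pat <- "^f([0-9]+)\\[(-?[0-9]+)\\]_f([0-9]+)\\[(-?[0-9]+)\\]$"
  ok <- grepl(pat, lines)
  if (any(!ok)) stop("malformed conjunction template: ", lines[!ok][1L])
  conjunction_set(as.integer(sub(pat, "\\1", lines)),
                  as.integer(sub(pat, "\\2", lines)),
                  as.integer(sub(pat, "\\3", lines)),
                  as.integer(sub(pat, "\\4", lines)),
                  name = name)
}

#' Instantiate conjunction features over a sentence
#'
#' For every token and every template in the set, joins the two member
#' singleton values (with BOS/EOS sentinels beyond sentence edges) into
#' one feature string `f<i1>[<j1>]_f<i2>[<j2>]=<v1>_<v2>`. A conjunction
#' whose member is omitted (a short-word affix) is itself omitted.
#'
#' @param sentence a [dnr_sentence()].
#' @param set a [conjunction_set()].
#' @param config a [feature_config()]; its enabled templates must cover the
#'   member templates of `set`.
#' @return List (one element per token) of character vectors.
#' @export
apply_conjunctions <- function(sentence, set, config = feature_config()) {
  stopifnot(inherits(set, "dnr_conjunction_set"))
  need <- sort(unique(c(set$i1, set$i2)))
  missing_tpl <- setdiff(need, config$templates)
  if (length(missing_tpl)) {
    stop("conjunction set references disabled template(s): f",
         paste(missing_tpl, collapse = ", f"))
  }
  sv <- singleton_values(sentence, config)
  n <- sv$n
  heads <- paste0("f", set$i1, "[", set$j1, "]_f", set$i2, "[", set$j2, "]=")
  t1 <- paste0("f", set$i1); t2 <- paste0("f", set$i2)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    feats <- character(0)
    for (r in seq_len(nrow(set))) {
      v1 <- value_at(sv$values, t1[r], t + set$j1[r], n)
      v2 <- value_at(sv$values, t2[r], t + set$j2[r], n)
      if (is.na(v1) || is.na(v2)) next  # omitted member suppresses the pair
      feats <- c(feats, paste0(heads[r], escape_value(v1), "_",
                               escape_value(v2)))
    }
    out[[t]] <- feats
  }
  out
}
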