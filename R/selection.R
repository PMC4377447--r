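# Feature selection against coarse BILOU tags: Chi-square, mutual
# information and information gain over (feature present/absent) x (tag)
# token events, with max-over-tags aggregation into an importance score
# and top-fraction retention.

#' Collapse a typed BILOU tag to its coarse positional letter
#'
#' @param tag character vector of typed tags (e.g. `"B-drug"`, `"O"`).
#' @return Character vector of letters in `{B, I, L, O, U}`.
#' @export
collapse_tag <- function(tag) {
  letters5 <- substr(tag, 1L, 1L)
  bad <- !(letters5 %in% c("B", "I", "L", "O", "U"))
  if (any(bad)) stop("invalid tag: ", tag[bad][1L])
  letters5
}

#' Contingency table of one feature against one tag
#'
#' Counts token events in the training data: `N11` tokens carrying feature
#' `f` with tag `t`, `N10` carrying `f` with another tag, `N01` lacking
#' `f` with tag `t`, `N00` neither.
#'
#' @param feature_lists list over tokens of character vectors (each token's
#'   feature set), concatenated over the corpus.
#' @param tags character vector of coarse tags, one per token.
#' @param feature the feature string `f`.
#' @param tag the tag `t`.
#' @return Named integer vector `c(n11, n10, n01, n00)`.
#' @export
count_contingency <- function(feature_lists, tags, feature, tag) {
  stopifnot(length(feature_lists) == length(tags), length(tags) > 0L)
  has_f <- vapply(feature_lists, function(fs) feature %in% fs, logical(1))
  is_t <- tags == tag
  c(n11 = sum(has_f & is_t), n10 = sum(has_f & !is_t),
    n01 = sum(!has_f & is_t), n00 = sum(!has_f & !is_t))
}

#' Chi-square score of a 2x2 contingency table
#'
#' The four-cell sum of `(N - E)^2 / E` where the expected counts `E` come
#' from the row and column marginals under independence. Degenerate tables
#' (a zero marginal) score 0 by convention.
#'
#' @param table numeric vector `c(n11, n10, n01, n00)` or a matrix/table
#'   with those four cells.
#' @return Non-negative chi-square statistic (no continuity correction).
#' @export
chi_square <- function(table) {
  n <- as.numeric(table)
  stopifnot(length(n) == 4L)
  n11 <- n[1]; n10 <- n[2]; n01 <- n[3]; n00 <- n[4]
  N <- sum(n)
  if (N <= 0) stop("empty contingency table")
  rf <- n11 + n10; rn <- n01 + n00; ct <- n11 + n01; cn <- n10 + n00
  if (rf == 0 || rn == 0 || ct == 0 || cn == 0) return(0)
  e <- c(rf * ct, rf * cn, rn * ct, rn * cn) / N
  sum((n - e)^2 / e)
}

#' Mutual information of a 2x2 contingency table, in bits
#'
#' Plug-in estimate `sum P(F,C) log2 P(F,C)/(P(F)P(C))` with probabilities
#' taken as relative counts; `0 * log(0)` terms contribute 0.
#'
#' @inheritParams chi_square
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(table) {
  n <- as.numeric(table)
  stopifnot(length(n) == 4L)
  N <- sum(n)
  if (N <= 0) stop("empty contingency table")
  p <- n / N
  pf <- c(p[1] + p[2], p[1] + p[2], p[3] + p[4], p[3] + p[4])
  pc <- c(p[1] + p[3], p[2] + p[4], p[1] + p[3], p[2] + p[4])
  terms <- ifelse(p > 0, p * log2(p / (pf * pc)), 0)
  sum(terms)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a feature over the coarse tag distribution, in bits
#'
#' `H(T) - H(T | e_f)` where `T` is the 5-valued coarse-tag variable and
#' `e_f` indicates presence of the feature at the current word.
#'
#' @param feature_lists,tags as in [count_contingency()].
#' @param feature the feature string.
#' @return Information gain in `[0, H(T)]` (up to floating tolerance).
#' @export
information_gain <- function(feature_lists, tags, feature) {
  stopifnot(length(feature_lists) == length(tags), length(tags) > 0L)
  has_f <- vapply(feature_lists, function(fs) feature %in% fs, logical(1))
  ig_from_counts(table(factor(tags)[has_f]), table(factor(tags)[!has_f]))
}

ig_from_counts <- function(counts_present, counts_absent) {
  n1 <- sum(counts_present); n0 <- sum(counts_absent); N <- n1 + n0
  h <- entropy_bits(as.numeric(counts_present) + as.numeric(counts_absent))
  h1 <- if (n1 > 0) entropy_bits(as.numeric(counts_present)) else 0
  h0 <- if (n0 > 0) entropy_bits(as.numeric(counts_absent)) else 0
  h - (n1 / N) * h1 - (n0 / N) * h0
}

#' Score every feature by an association statistic with the tag variable
#'
#' Builds, for every distinct feature string in the corpus, the per-tag
#' contingency counts against the coarse tags `{B, I, L, O, U}` (or the
#' full typed tags when `typed = TRUE`) and computes the importance score
#' `I(f)`: the maximum over tags of the per-tag Chi-square or mutual
#' information, or the information gain directly.
#'
#' @param feature_lists list over tokens of character vectors of features;
#'   pass the concatenation over all training sentences (see
#'   [corpus_features()]).
#' @param tags character vector of typed tags, one per token.
#' @param statistic `"chi2"`, `"mi"` or `"ig"`.
#' @param typed score against the typed tags instead of collapsing to the
#'   coarse letters (default `FALSE`, the standard protocol).
#' @return data.frame of class `dnr_importance` with columns `feature`,
#'   `score`, sorted by score descending then feature ascending (the fixed
#'   tie order used by [select_top_fraction()]).
#' @export
feature_importance <- function(feature_lists, tags,
                               statistic = c("chi2", "mi", "ig"),
                               typed = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(length(feature_lists) == length(tags))
  if (length(tags) == 0L) stop("empty training data")
  cls <- if (typed) tags else collapse_tag(tags)
  nf <- lengths(feature_lists)
  dt <- data.table(
    feature = unlist(feature_lists, use.names = FALSE),
    tag = rep(cls, nf))
  N <- length(cls)
  n_t <- table(cls)
  # joint counts: tokens carrying f with tag t (a token's feature set is a
  # set, so duplicates within a token are collapsed)
  dt <- unique(dt[, tok := rep(seq_len(N), nf)],
               by = c("feature", "tok"))
  joint <- dt[, .(n11 = .N), by = .(feature, tag)]
  df <- joint[, .(df = sum(n11)), by = feature]
  if (statistic == "ig") {
    h_total <- entropy_bits(as.numeric(n_t))
    wide <- data.table::dcast(joint, feature ~ tag, value.var = "n11",
                              fill = 0L)
    for (tn in setdiff(names(n_t), names(wide))) wide[[tn]] <- 0L
    tag_names <- names(n_t)
    present <- as.matrix(wide[, tag_names, with = FALSE])
    absent <- matrix(rep(as.numeric(n_t[tag_names]), each = nrow(present)),
                     nrow = nrow(present)) - present
    score <- vapply(seq_len(nrow(present)), function(i) {
      ig_from_counts(present[i, ], absent[i, ])
    }, numeric(1))
    out <- data.table(feature = wide$feature, score = score)
  } else {
    # full cross of features x tags: a tag never co-occurring with f can
    # still dominate the max (negative association)
    full <- data.table::CJ(feature = df$feature, tag = names(n_t))
    full <- joint[full, on = c("feature", "tag")]
    full[is.na(n11), n11 := 0L]
    full <- df[full, on = "feature"]
    full[, nt := as.numeric(n_t[tag])]
    full[, `:=`(n10 = df - n11, n01 = nt - n11, n00 = N - df - nt + n11)]
    if (statistic == "chi2") {
      full[, s := {
        e11 <- df * nt / N; e10 <- df * (N - nt) / N
        e01 <- (N - df) * nt / N; e00 <- (N - df) * (N - nt) / N
        val <- (n11 - e11)^2 / e11 + (n10 - e10)^2 / e10 +
          (n01 - e01)^2 / e01 + (n00 - e00)^2 / e00
        ifelse(df == 0 | df == N | nt == 0 | nt == N, 0, val)
      }]
    } else {
      full[, s := {
        pf <- df / N; pt <- nt / N
        term <- function(nn, pa, pb) {
          p <- nn / N
          ifelse(p > 0, p * log2(p / (pa * pb)), 0)
        }
        term(n11, pf, pt) + term(n10, pf, 1 - pt) +
          term(n01, 1 - pf, pt) + term(n00, 1 - pf, 1 - pt)
      }]
    }
    out <- full[, .(score = max(s)), by = feature]
  }
  out <- out[order(-score, feature)]
  res <- as.data.frame(out)
  attr(res, "statistic") <- statistic
  attr(res, "tags") <- if (typed) "typed" else "coarse"
  class(res) <- c("dnr_importance", "data.frame")
  res
}

#' Flatten a corpus into per-token feature sets and tags
#'
#' Convenience wrapper running [extract_features()] and [encode_bilou()]
#' over a list of sentences and concatenating the per-token results.
#'
#' @param sentences list of [dnr_sentence()].
#' @param config a [feature_config()].
#' @return list with `features` (list over all tokens) and `tags`
#'   (character vector of typed tags).
#' @export
corpus_features <- function(sentences, config = feature_config()) {
  feats <- lapply(sentences, extract_features, config = config)
  tags <- lapply(sentences, encode_bilou)
  list(features = do.call(c, feats), tags = unlist(tags))
}

round_half_away <- function(x) floor(x + 0.5)

#' Retain the top fraction of features by importance
#'
#' Keeps the `round(p * n)` highest-scoring features (rounding half away
#' from zero), with the deterministic tie order of [feature_importance()]
#' (score descending, feature string ascending); the retained subset is
#' therefore monotone in `p`.
#'
#' @param importance a `dnr_importance` table (or any data.frame with
#'   `feature` and `score`, which will be ordered the same way).
#' @param p fraction in `(0, 1]`.
#' @return Character vector of retained feature strings.
#' @export
select_top_fraction <- function(importance, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("'p' must lie in (0, 1]")
  }
  imp <- as.data.frame(importance)
  imp <- imp[order(-imp$score, imp$feature), , drop = FALSE]
  k <- round_half_away(p * nrow(imp))
  head(imp$feature, k)
}

#' Write / read an importance table as TSV
#'
#' Columns `feature<TAB>statistic<TAB>score`.
#' @param importance a `dnr_importance` table.
#' @param path file path.
#' @export
write_importance <- function(importance, path) {
  stat <- attr(importance, "statistic")
  if (is.null(stat)) stat <- "score"
  write.table(data.frame(feature = importance$feature, statistic = stat,
                         score = importance$score),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_importance
#' @export
read_importance <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   quote = "", fileEncoding = "UTF-8",
                   col.names = c("feature", "statistic", "score"))
  res <- data.frame(feature = df$feature, score = df$score,
                    stringsAsFactors = FALSE)
  attr(res, "statistic") <- df$statistic[1L]
  class(res) <- c("dnr_importance", "data.frame")
  res
}

#' Write a retained-feature list (one feature per line)
#' @param features character vector of retained feature strings.
#' @param path file path.
#' @export
write_feature_list <- function(features, path) {
  writeLines(features, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_feature_list
#' @export
read_feature_list <- function(path) readLines(path, encoding = "UTF-8")
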