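# Entity-level evaluation under the four DDI-style criteria:
#   strict  - boundary and type both exactly match a gold mention
#   exact   - boundary exactly matches, type ignored
#   type    - character overlap >= 1 with a gold mention of the same type
#   partial - character overlap >= 1, type ignored
# Matching is one-to-one: each gold and each predicted mention takes part
# in at most one match.

MATCH_CRITERIA <- c("strict", "exact", "type", "partial")

pair_qualifies <- function(g, p, criterion) {
  switch(criterion,
         strict = g$start == p$start && g$end == p$end && g$type == p$type,
         exact = g$start == p$start && g$end == p$end,
         type = g$type == p$type &&
           min(g$end, p$end) - max(g$start, p$start) >= 1L,
         partial = min(g$end, p$end) - max(g$start, p$start) >= 1L,
         stop("unknown criterion: ", criterion))
}

sort_mentions <- function(m) {
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  if (nrow(m)) m <- m[order(m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Match predicted mentions against gold under one criterion
#'
#' Computes an explicit one-to-one match assignment and the resulting
#' (TP, FP, FN) counts. The default assignment is greedy: gold mentions in
#' document order, each matched to the first unconsumed qualifying
#' prediction in document order. `method = "optimal"` computes the
#' maximum one-to-one matching by exhaustive search (intended for small
#' inputs, as an oracle for the greedy rule).
#'
#' @param gold,pred mention data.frames with columns `start`, `end`,
#'   `type`.
#' @param criterion one of `"strict"`, `"exact"`, `"type"`, `"partial"`.
#' @param method `"greedy"` or `"optimal"`.
#' @return List with `tp`, `fp`, `fn` and `pairs` (a 2-column matrix of
#'   matched gold/pred row indices after sorting by document order).
#' @export
match_mentions <- function(gold, pred,
                           criterion = c("strict", "exact", "type",
                                         "partial"),
                           method = c("greedy", "optimal")) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  gold <- sort_mentions(gold)
  pred <- sort_mentions(pred)
  ng <- nrow(gold); np <- nrow(pred)
  qual <- matrix(FALSE, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      qual[i, j] <- pair_qualifies(gold[i, ], pred[j, ], criterion)
    }
  }
  pairs <- matrix(integer(0), ncol = 2L)
  if (method == "greedy") {
    used <- logical(np)
    for (i in seq_len(ng)) {
      j <- which(qual[i, ] & !used)
      if (length(j)) {
        used[j[1L]] <- TRUE
        pairs <- rbind(pairs, c(i, j[1L]))
      }
    }
  } else {
    best <- recursive_match(qual, 1L, logical(np))
    if (length(best)) {
      pairs <- do.call(rbind, best)
    }
  }
  tp <- nrow(pairs)
  list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs)
}

# exhaustive maximum bipartite matching over the qualification matrix
recursive_match <- function(qual, i, used) {
  if (i > nrow(qual)) return(list())
  best <- recursive_match(qual, i + 1L, used)  # leave gold i unmatched
  for (j in which(qual[i, ] & !used)) {
    u <- used; u[j] <- TRUE
    cand <- c(list(c(i, j)), recursive_match(qual, i + 1L, u))
    if (length(cand) > length(best)) best <- cand
  }
  best
}

#' Precision, recall and F1 from match counts
#'
#' Percentages; zero denominators score 0 by convention.
#'
#' @param tp,fp,fn counts.
#' @return Named numeric vector `c(TP, FP, FN, P, R, F1)` with P/R/F1 as
#'   percentages.
#' @export
eval_scores <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(TP = tp, FP = fp, FN = fn, P = p, R = r, F1 = f1)
}

as_doc_list <- function(x) {
  if (is.data.frame(x)) list(x) else x
}

#' Score predictions against gold under one criterion
#'
#' Micro-averages the one-to-one match counts over documents.
#'
#' @param gold,pred a mention data.frame (single document) or a list of
#'   them (one per document, aligned).
#' @param criterion one of `"strict"`, `"exact"`, `"type"`, `"partial"`.
#' @return Named numeric vector as in [eval_scores()].
#' @export
score_mentions <- function(gold, pred, criterion = "strict") {
  gold <- as_doc_list(gold); pred <- as_doc_list(pred)
  stopifnot(length(gold) == length(pred))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (d in seq_along(gold)) {
    m <- match_mentions(gold[[d]], pred[[d]], criterion)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  eval_scores(tp, fp, fn)
}

#' Score under all four criteria
#'
#' @inheritParams score_mentions
#' @return data.frame with one row per criterion and columns
#'   `TP, FP, FN, P, R, F1`.
#' @export
score_all_criteria <- function(gold, pred) {
  out <- t(vapply(MATCH_CRITERIA, function(cr) score_mentions(gold, pred, cr),
                  numeric(6)))
  data.frame(criterion = MATCH_CRITERIA, as.data.frame(out),
             row.names = NULL)
}

#' Per-type strict scores
#'
#' Restricts gold and predictions to each entity type in turn and scores
#' under strict matching.
#'
#' @inheritParams score_mentions
#' @param entity_types types to report.
#' @return data.frame with one row per type.
#' @export
score_per_type <- function(gold, pred, entity_types = dnr_entity_types()) {
  gold <- as_doc_list(gold); pred <- as_doc_list(pred)
  out <- t(vapply(entity_types, function(tp) {
    g <- lapply(gold, function(m) m[m$type == tp, , drop = FALSE])
    p <- lapply(pred, function(m) m[m$type == tp, , drop = FALSE])
    score_mentions(g, p, "strict")
  }, numeric(6)))
  data.frame(type = entity_types, as.data.frame(out), row.names = NULL)
}

#' Write an evaluation report as TSV
#'
#' Emits the four overall criterion rows followed by per-type strict rows,
#' with P/R/F1 as percentages rounded to two decimals.
#'
#' @inheritParams score_mentions
#' @param path output file path.
#' @return The report data.frame, invisibly.
#' @export
write_eval_report <- function(gold, pred, path) {
  all <- score_all_criteria(gold, pred)
  per <- score_per_type(gold, pred)
  rep1 <- data.frame(row = all$criterion, all[, -1])
  rep2 <- data.frame(row = paste0(per$type, " (strict)"), per[, -1])
  rep <- rbind(rep1, rep2)
  rep$P <- round(rep$P, 2); rep$R <- round(rep$R, 2)
  rep$F1 <- round(rep$F1, 2)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(rep)
}
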