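# Linear-chain CRF tagger over the selected feature set. Parameters are
# estimated by L2-penalized maximum likelihood (forward-backward gradients
# from the compiled core, L-BFGS-B through stats::optim); decoding is
# Viterbi. The regularization coefficient is the single exposed knob, with
# the grid {0.5, 0.6, ..., 1.5} and 10-fold cross-validation as defaults
# for tuning.

#' Assemble training/prediction instances from annotated sentences
#'
#' Extracts features and BILOU labels for every sentence and, when a
#' retained-feature set is given, drops all features outside it (the
#' dropped count is reported via `message()`).
#'
#' @param sentences non-empty list of [dnr_sentence()].
#' @param config a [feature_config()].
#' @param retained character vector of retained feature strings from
#'   [select_top_fraction()], or `NULL` to keep all features.
#' @return List of instances (class `dnr_instances`), each a list with
#'   `features` (per-token list of character vectors) and `labels`.
#' @export
assemble_instances <- function(sentences, config = feature_config(),
                               retained = NULL) {
  if (length(sentences) == 0L) stop("empty corpus")
  inst <- lapply(sentences, function(s) {
    list(features = extract_features(s, config), labels = encode_bilou(s))
  })
  if (!is.null(retained)) {
    if (length(retained) == 0L) {
      warning("empty retained-feature set: instances will carry no features")
    }
    total <- 0L; kept <- 0L
    inst <- lapply(inst, function(x) {
      x$features <- lapply(x$features, function(fs) {
        total <<- total + length(fs)
        out <- fs[fs %in% retained]
        kept <<- kept + length(out)
        out
      })
      x
    })
    message(sprintf("feature filtering kept %d of %d feature occurrences",
                    kept, total))
  }
  structure(inst, class = "dnr_instances")
}

#' Train a linear-chain CRF tagger
#'
#' Maximizes the conditional log-likelihood of the label sequences with an
#' L2 penalty `0.5 * c2 * ||w||^2`, via L-BFGS-B on analytic gradients.
#' Training is deterministic for a fixed instance set and configuration
#' (weights start at zero; the objective is convex).
#'
#' @param instances from [assemble_instances()].
#' @param labels the label alphabet; defaults to [tag_inventory()].
#' @param c2 regularization coefficient (a value from the default tuning
#'   grid `seq(0.5, 1.5, by = 0.1)`; see [tune_regularization()]).
#' @param max_iter maximum L-BFGS iterations.
#' @return Model of class `dnr_crf`: feature alphabet, label alphabet,
#'   packed weight vector and optimizer diagnostics.
#' @export
crf_train <- function(instances, labels = tag_inventory(), c2 = 1.0,
                      max_iter = 200L) {
  if (length(instances) == 0L) stop("no training instances")
  if (c2 < 0) stop("c2 must be non-negative")
  obs <- unique(unlist(lapply(instances, `[[`, "labels")))
  bad <- setdiff(obs, labels)
  if (length(bad)) stop("label(s) outside the inventory: ",
                        paste(bad, collapse = ", "))
  feat_alpha <- sort(unique(unlist(lapply(instances, function(x)
    unlist(x$features, use.names = FALSE)))))
  Fn <- length(feat_alpha)
  L <- length(labels)
  feats <- lapply(instances, function(x) {
    lapply(x$features, function(fs) {
      match(fs, feat_alpha) - 1L
    })
  })
  labs <- lapply(instances, function(x) match(x$labels, labels) - 1L)
  npar <- Fn * L + L * L + 2L * L
  env <- new.env()
  env$last_w <- NULL; env$last <- NULL
  objective <- function(w) {
    env$last <- .crf_nll_grad(w, feats, labs, L, Fn, c2)
    env$last_w <- w
    env$last$nll
  }
  gradient <- function(w) {
    if (is.null(env$last_w) || !identical(w, env$last_w)) {
      env$last <- .crf_nll_grad(w, feats, labs, L, Fn, c2)
      env$last_w <- w
    }
    env$last$grad
  }
  fit <- optim(numeric(npar), fn = objective, gr = gradient,
               method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter), factr = 1e8))
  structure(list(features = feat_alpha, labels = labels, w = fit$par,
                 c2 = c2, value = fit$value,
                 convergence = fit$convergence, counts = fit$counts),
            class = "dnr_crf")
}

#' @export
print.dnr_crf <- function(x, ...) {
  cat("<dnr_crf: ", length(x$features), " features, ",
      length(x$labels), " labels, c2 = ", x$c2, ">\n", sep = "")
  invisible(x)
}

#' Persist / restore a trained CRF model
#'
#' The model is written as a plain-text file: a header with the label
#' alphabet and `c2`, the feature alphabet, and the packed weight vector.
#'
#' @param model a `dnr_crf` model.
#' @param path file path.
#' @export
write_crf <- function(model, path) {
  stopifnot(inherits(model, "dnr_crf"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("dnr_crf\t1",
               paste(model$labels, collapse = "\t"),
               as.character(model$c2),
               as.character(length(model$features))), con)
  writeLines(model$features, con)
  writeLines(sprintf("%.17g", model$w), con)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1L], "dnr_crf")) stop("not a dnr_crf model file")
  labels <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]]
  c2 <- as.numeric(lines[3L])
  Fn <- as.integer(lines[4L])
  features <- lines[4L + seq_len(Fn)]
  w <- as.numeric(lines[(4L + Fn + 1L):length(lines)])
  structure(list(features = features, labels = labels, w = w, c2 = c2,
                 value = NA_real_, convergence = NA_integer_, counts = NULL),
            class = "dnr_crf")
}

#' Predict BILOU tags for sentences
#'
#' Features unknown to the model are ignored; every emitted tag belongs to
#' the model's label alphabet.
#'
#' @param model a `dnr_crf` model.
#' @param sentences list of [dnr_sentence()] (featurized with `config`), or
#'   a pre-assembled `dnr_instances` object.
#' @param config a [feature_config()]; must match the one used to build
#'   the training features.
#' @return List of character vectors of predicted tags, one per sentence.
#' @export
crf_predict <- function(model, sentences, config = feature_config()) {
  stopifnot(inherits(model, "dnr_crf"))
  feats <- if (inherits(sentences, "dnr_instances")) {
    lapply(sentences, `[[`, "features")
  } else {
    lapply(sentences, extract_features, config = config)
  }
  L <- length(model$labels)
  Fn <- length(model$features)
  lapply(feats, function(sf) {
    idx <- lapply(sf, function(fs) {
      m <- match(fs, model$features)
      as.integer(m[!is.na(m)] - 1L)
    })
    if (length(idx) == 0L) return(character(0))
    path <- .crf_viterbi(model$w, idx, L, Fn)
    model$labels[path + 1L]
  })
}

#' Predict entity mentions for sentences
#'
#' Runs [crf_predict()] and decodes the tag sequences into mentions with
#' the lenient BILOU repair (a tagger may emit invalid transitions).
#'
#' @inheritParams crf_predict
#' @return List of mention data.frames, one per sentence.
#' @export
crf_predict_mentions <- function(model, sentences,
                                 config = feature_config()) {
  tags <- crf_predict(model, sentences, config)
  Map(function(tg, s) {
    suppressMessages(decode_bilou(tg, s$tokens, strict = FALSE))
  }, tags, sentences)
}

#' Tune the regularization coefficient by cross-validated strict F1
#'
#' Evaluates every grid value by K-fold cross-validation at the sentence
#' level: folds partition the sentences (seeded, so the assignment is
#' reproducible), each fold is tagged by a model trained on the others,
#' and predicted mentions are scored against gold under the strict
#' criterion, micro-averaged over the held-out sentences.
#'
#' @param sentences list of [dnr_sentence()]; at least `folds` of them.
#' @param config a [feature_config()].
#' @param grid candidate coefficients; default `seq(0.5, 1.5, by = 0.1)`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param retained optional retained-feature set.
#' @param labels label alphabet.
#' @param max_iter L-BFGS iteration cap per fit.
#' @return List with `best_c2`, `scores` (data.frame `c2`, `f1`) and
#'   `fold` (the fold id of every sentence).
#' @export
tune_regularization <- function(sentences, config = feature_config(),
                                grid = seq(0.5, 1.5, by = 0.1),
                                folds = 10L, seed = 1L, retained = NULL,
                                labels = tag_inventory(), max_iter = 100L) {
  n <- length(sentences)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many sentences as folds")
  if (any(grid <= 0)) stop("grid values must be positive")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  inst <- suppressMessages(assemble_instances(sentences, config, retained))
  scores <- vapply(grid, function(c2) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (k in seq_len(folds)) {
      tr <- inst[fold_id != k]
      class(tr) <- "dnr_instances"
      model <- crf_train(tr, labels = labels, c2 = c2,
                         max_iter = max_iter)
      held <- which(fold_id == k)
      # instances carry no tokens; decode tags against the sentences
      tags <- crf_predict(model, structure(inst[held],
                                           class = "dnr_instances"))
      for (ii in seq_along(held)) {
        s <- sentences[[held[ii]]]
        pm <- suppressMessages(decode_bilou(tags[[ii]], s$tokens,
                                            strict = FALSE))
        m <- match_mentions(s$mentions, pm, criterion = "strict")
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      }
    }
    unname(eval_scores(tp, fp, fn)["F1"])
  }, numeric(1))
  best <- grid[which.max(scores)]
  list(best_c2 = best,
       scores = data.frame(c2 = grid, f1 = scores),
       fold = fold_id)
}
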