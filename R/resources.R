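#' Construct a drug dictionary
#'
#' A dictionary is a named, case-insensitive membership set. A token is a
#' member if it equals a single-word term or any whitespace-delimited token
#' of a multiword term (membership is scored per word).
#'
#' @param terms character vector of dictionary terms (possibly multiword).
#' @param name dictionary name (e.g. `"DrugBank"`, `"FDA"`, `"Jochem"`).
#' @return Object of class `dnr_dictionary`.
#' @export
dnr_dictionary <- function(terms, name = "dictionary") {
  if (length(terms) == 0L) stop("dictionary must be non-empty")
  words <- unique(tolower(unlist(strsplit(terms, "[[:space:]]+"))))
  words <- words[nzchar(words)]
  structure(list(name = name, words = words), class = "dnr_dictionary")
}

#' Read a dictionary file (one term per line, UTF-8)
#'
#' @param path file path.
#' @param name dictionary name; defaults to the file's base name.
#' @return Object of class `dnr_dictionary`.
#' @export
read_dictionary <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  terms <- readLines(path, encoding = "UTF-8")
  terms <- terms[nzchar(trimws(terms))]
  dnr_dictionary(terms, name = name)
}

#' Write a dictionary file (one term per line)
#' @param dict a `dnr_dictionary` or character vector of terms.
#' @param path output path.
#' @export
write_dictionary <- function(dict, path) {
  terms <- if (inherits(dict, "dnr_dictionary")) dict$words else dict
  writeLines(terms, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.dnr_dictionary <- function(x, ...) {
  cat("<dnr_dictionary '", x$name, "': ", length(x$words), " words>\n",
      sep = "")
  invisible(x)
}

dict_contains <- function(dict, token) tolower(token) %in% dict$words

#' Read a word-embedding table (word2vec text format)
#'
#' Each line holds a word followed by `D` whitespace-separated reals. An
#' optional first header line `V D` (two integers) is recognized and
#' skipped; otherwise the dimension is inferred from the first line.
#'
#' @param path file path.
#' @return Numeric matrix with one row per word, words as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file")
  first <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))) &&
      all(as.numeric(first) == round(as.numeric(first)))) {
    lines <- lines[-1L]  # word2vec header "V D"
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  d <- length(parts[[1L]]) - 1L
  if (d < 1L) stop("embedding file has no vector components")
  mat <- t(vapply(parts, function(p) {
    if (length(p) != d + 1L) stop("inconsistent embedding dimension")
    as.numeric(p[-1L])
  }, numeric(d)))
  rownames(mat) <- words
  mat
}

#' Write an embedding table in word2vec text format (with header line)
#' @param emb numeric matrix with words as rownames.
#' @param path output path.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1L, function(v)
                     paste(formatC(v, format = "g", digits = 8),
                           collapse = " "))), con)
  invisible(path)
}

kmeanspp_centers <- function(x, k) {
  # k-means++ seeding: first center uniform, then proportional to squared
  # distance to the nearest chosen center
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster word embeddings into semantic classes
#'
#' Runs k-means over the embedding vectors; the cluster id a word falls in
#' is used as a discrete semantic-class feature by
#' [extract_embedding_cluster()]. Seeding is k-means++-style under the
#' supplied random seed; Lloyd iterations are delegated to
#' [stats::kmeans()] (at most 300). Out-of-vocabulary words map to the
#' dedicated id `"OOV"`.
#'
#' @param embeddings numeric matrix with words as rownames (see
#'   [read_embeddings()]).
#' @param k number of clusters, `2 <= k <= nrow(embeddings)`. The default
#'   400 reflects a grid search over `{100, 200, ..., 1000}` semantic
#'   classes on full-scale corpora; small corpora need a smaller `k`.
#' @param seed integer random seed (clustering is deterministic given it).
#' @return Object of class `dnr_cluster_model` with fields `assignment`
#'   (named integer vector of cluster ids in `1..k`), `k`, `dim` and
#'   `oov_id`.
#' @export
fit_embedding_clusters <- function(embeddings, k = 400L, seed = 1L) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  n <- nrow(embeddings)
  if (k < 2L || k > n) {
    stop("k must satisfy 2 <= k <= vocabulary size (", n, ")")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  init <- kmeanspp_centers(embeddings, k)
  fit <- suppressWarnings(
    kmeans(embeddings, centers = init, iter.max = 300L, algorithm = "Lloyd"))
  structure(list(assignment = setNames(fit$cluster,
                                       tolower(rownames(embeddings))),
                 k = k, dim = ncol(embeddings), oov_id = "OOV"),
            class = "dnr_cluster_model")
}

#' @export
print.dnr_cluster_model <- function(x, ...) {
  cat("<dnr_cluster_model: ", length(x$assignment), " words, k = ", x$k,
      ", dim = ", x$dim, ">\n", sep = "")
  invisible(x)
}

cluster_id <- function(model, token) {
  id <- model$assignment[tolower(token)]
  ifelse(is.na(id), model$oov_id, as.character(id))
}
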