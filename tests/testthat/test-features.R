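test_that("template registry holds the sixteen default templates", {
  reg <- singleton_templates()
  expect_equal(nrow(reg), 16L)
  expect_equal(reg$tid, paste0("f", 1:16))
  expect_false(anyDuplicated(reg$tid) > 0)
})

test_that("word, orthographic and affix extractors match hand-derived values", {
  expect_equal(extract_word("apigenin"), "apigenin")
  expect_equal(extract_word("Aspirin1+"), "Aspirin1+")
  expect_error(extract_word(""), "empty")

  expect_equal(extract_orthographic("ABC"),
               c(class = "All-capitalized", hyphen = "N"))
  expect_equal(extract_orthographic("interleukin-2"),
               c(class = "Alphanumeric", hyphen = "Y"))
  expect_equal(extract_orthographic("Bextra"),
               c(class = "Is-capitalized", hyphen = "N"))
  expect_equal(extract_orthographic("2013")[["class"]], "All-digits")
  expect_equal(extract_orthographic("...")[["class"]], "Other")

  expect_equal(unname(extract_affixes("interleukin-2")),
               c("int", "n-2", "inte", "in-2", "inter", "kin-2"))
  expect_equal(extract_affixes("aspirin")[["prefix3"]], "asp")
  expect_equal(extract_affixes("aspirin")[["suffix5"]], "pirin")
  expect_length(extract_affixes("ab"), 0L)
  expect_length(extract_affixes("abcd"), 4L)  # lengths 3 and 4 only
})

test_that("word shapes map character classes and collapse runs", {
  expect_equal(word_shape("Aspirin1+", "generalized"), "Xxxxxxx0O")
  expect_equal(word_shape("Aspirin1+", "brief"), "Xx0O")
  expect_equal(word_shape("ABC", "generalized"), "XXX")
  expect_equal(word_shape("ABC", "brief"), "X")
})

test_that("shape invariants hold over random tokens", {
  set.seed(31)
  alphabet <- c(LETTERS, letters, 0:9, "-", "+", "(", ")")
  for (i in 1:200) {
    tok <- paste(sample(alphabet, sample.int(12, 1), replace = TRUE),
                 collapse = "")
    g <- word_shape(tok, "generalized")
    b <- word_shape(tok, "brief")
    expect_equal(nchar(g), nchar(tok))
    expect_lte(nchar(b), nchar(g))
    expect_false(grepl("(.)\\1", b))
  }
})

test_that("dictionary membership is case-insensitive and per word", {
  d <- dnr_dictionary(c("aspirin", "calcium channel blockers"), "fixture")
  expect_equal(extract_dictionary("aspirin", d), "Y")
  expect_equal(extract_dictionary("ASPIRIN", d), "Y")
  expect_equal(extract_dictionary("channel", d), "Y")  # word of multiword term
  expect_equal(extract_dictionary("the", d), "N")
  expect_error(dnr_dictionary(character(0)), "non-empty")
})

test_that("dictionary files round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Aspirin", "beta blockers", ""), path)
  d <- read_dictionary(path, "fx")
  expect_setequal(d$words, c("aspirin", "beta", "blockers"))
})

test_that("embedding clustering separates planted groups and is seeded", {
  set.seed(77)
  a <- matrix(rnorm(40 * 10, mean = 0), 40, 10)
  b <- matrix(rnorm(40 * 10, mean = 8), 40, 10)
  emb <- rbind(a, b)
  rownames(emb) <- paste0("w", 1:80)
  m1 <- fit_embedding_clusters(emb, k = 2L, seed = 3L)
  m2 <- fit_embedding_clusters(emb, k = 2L, seed = 3L)
  expect_identical(m1$assignment, m2$assignment)
  # distance oracle: the two planted groups land in distinct clusters
  ca <- unique(m1$assignment[1:40])
  cb <- unique(m1$assignment[41:80])
  expect_length(ca, 1L)
  expect_length(cb, 1L)
  expect_false(ca == cb)

  expect_equal(extract_embedding_cluster("w1", m1),
               as.character(m1$assignment[["w1"]]))
  expect_equal(extract_embedding_cluster("unseen-word", m1), "OOV")

  mall <- fit_embedding_clusters(emb, k = 80L, seed = 1L)
  expect_length(unique(mall$assignment), 80L)
  expect_error(fit_embedding_clusters(emb, k = 1L), "k must")
  expect_error(fit_embedding_clusters(emb, k = 81L), "k must")
  expect_equal(formals(fit_embedding_clusters)$k, 400L)
})

test_that("embedding files round-trip through the word2vec text format", {
  emb <- matrix(round(rnorm(12), 4), 4, 3,
                dimnames = list(c("alpha", "beta", "gamma", "delta"), NULL))
  path <- withr::local_tempfile(fileext = ".vec")
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_equal(back, emb, tolerance = 1e-6)
  # also readable without the header line
  writeLines(paste("solo", "0.5", "-1.25"), path)
  expect_equal(unname(read_embeddings(path)["solo", ]), c(0.5, -1.25))
})

test_that("window expansion instantiates every template at every offset", {
  s <- fig1_sentence()
  cfg <- feature_config(templates = 1L)
  feats <- extract_sentence_features(s, cfg)
  expect_equal(feats[[3L]],
               c("f1[-2]=luteolin", "f1[-1]=and", "f1[0]=apigenin",
                 "f1[1]=experienced", "f1[2]=extensive"))
  # edge positions carry sentinels
  expect_true("f1[-2]=__BOS__" %in% feats[[1L]])
  expect_true("f1[2]=__EOS__" %in% feats[[4L]])

  one <- dnr_sentence("apigenin")
  f1 <- extract_sentence_features(one, cfg)[[1L]]
  expect_setequal(f1, c("f1[-2]=__BOS__", "f1[-1]=__BOS__",
                        "f1[0]=apigenin", "f1[1]=__EOS__", "f1[2]=__EOS__"))
})

test_that("per-token singleton counts equal templates x window minus omissions", {
  res <- shared_resources()
  s <- res$res$corpus[[2L]]
  cfg <- feature_config(dictionaries = res$res$dictionaries,
                        clusters = res$res$clusters)
  feats <- extract_sentence_features(s, cfg)
  n <- nrow(s$tokens)
  for (t in seq_len(n)) {
    fs <- feats[[t]]
    # direct enumeration: affix templates at in-range positions with short
    # tokens are the only omissions; the hyphen flag is a separate extra
    omitted <- 0L
    for (j in -2:2) {
      p <- t + j
      if (p >= 1L && p <= n) {
        nc <- nchar(s$tokens$text[p])
        omitted <- omitted + sum(nc < 3:5) * 2L
      }
    }
    hyphen <- sum(grepl("=HYPHEN-", fs, fixed = FALSE))
    expect_equal(length(fs) - hyphen, 16L * 5L - omitted)
    expect_false(anyDuplicated(fs) > 0)
  }
})

test_that("feature extraction is pure and additive in templates", {
  res <- shared_resources()
  s <- res$res$corpus[[3L]]
  cfg <- res$config
  expect_identical(extract_sentence_features(s, cfg),
                   extract_sentence_features(s, cfg))
  cfg_no15 <- feature_config(templates = setdiff(1:16, 15L),
                             dictionaries = res$res$dictionaries,
                             clusters = res$res$clusters)
  full <- extract_sentence_features(s, cfg)
  drop <- extract_sentence_features(s, cfg_no15)
  for (t in seq_along(full)) {
    expect_setequal(setdiff(full[[t]], drop[[t]]),
                    full[[t]][startsWith(full[[t]], "f15[")])
  }
})

test_that("a broken tagger contract is detected", {
  bad_tagger <- function(tokens) list(pos = "NN", chunk = "O")
  cfg <- feature_config(templates = 1:2, tagger = bad_tagger)
  expect_error(extract_sentence_features(fig1_sentence(), cfg),
               "tagger contract")
})
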