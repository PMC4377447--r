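test_that("tag inventory has 4T+1 tags in a deterministic order", {
  inv <- tag_inventory()
  expect_length(inv, 17L)
  expect_equal(inv[1:4], c("B-drug", "I-drug", "L-drug", "U-drug"))
  expect_equal(inv[17L], "O")
  expect_false(anyDuplicated(inv) > 0)

  expect_equal(tag_inventory("drug"),
               c("B-drug", "I-drug", "L-drug", "U-drug", "O"))
  expect_error(tag_inventory(character(0)), "non-empty")
  expect_error(tag_inventory(c("drug", "drug")), "duplicated")
})

test_that("BILOU encoding follows the scheme definition", {
  expect_equal(encode_bilou(fig1_sentence()),
               c("U-drug", "O", "U-drug", "O", "O"))
  expect_equal(encode_bilou(group_sentence()),
               c("B-group", "I-group", "L-group"))
  s <- dnr_sentence("no mentions here")
  expect_equal(encode_bilou(s), rep("O", 3L))
})

test_that("mentions crossing token boundaries error unless snapped", {
  s <- dnr_sentence("luteolin and apigenin",
                    mentions = data.frame(start = 0L, end = 4L,
                                          type = "drug"))
  expect_error(encode_bilou(s), "align")
  expect_message(tags <- encode_bilou(s, snap = TRUE), "snapped")
  expect_equal(tags, c("U-drug", "O", "O"))
})

test_that("decoding inverts encoding and validates transitions", {
  f1 <- fig1_sentence()
  men <- decode_bilou(encode_bilou(f1), f1$tokens)
  expect_equal(men$start, f1$mentions$start)
  expect_equal(men$end, f1$mentions$end)
  expect_equal(men$type, f1$mentions$type)

  g <- group_sentence()
  men <- decode_bilou(c("B-group", "I-group", "L-group"), g$tokens)
  expect_equal(nrow(men), 1L)
  expect_equal(men$text, "iodinated contrast media")

  two <- dnr_sentence("alpha beta")
  expect_error(decode_bilou(c("I-drug", "O"), two$tokens), "invalid BILOU")
  expect_error(decode_bilou(c("B-drug", "O"), two$tokens), "invalid BILOU")
  expect_error(decode_bilou(c("B-drug", "L-group"), two$tokens),
               "invalid BILOU")
})

test_that("lenient decoding repairs stray tags and reports repairs", {
  two <- dnr_sentence("alpha beta")
  men <- suppressMessages(decode_bilou(c("I-drug", "O"), two$tokens,
                                       strict = FALSE))
  expect_equal(nrow(men), 1L)
  expect_equal(men$type, "drug")
  expect_equal(attr(men, "repairs"), 2L)  # stray I, then left open at O

  men <- suppressMessages(decode_bilou(c("B-drug", "L-group"), two$tokens,
                                       strict = FALSE))
  expect_equal(men$type, c("drug", "group"))
})

test_that("encode/decode round-trips mention sets on generated corpora", {
  corpus <- generate_corpus(simulate_config(seed = 5L, n_sentences = 40L))
  inv <- tag_inventory()
  for (s in corpus) {
    tags <- encode_bilou(s)
    expect_true(all(tags %in% inv))
    men <- decode_bilou(tags, s$tokens)
    expect_equal(men$start, s$mentions$start)
    expect_equal(men$end, s$mentions$end)
    expect_equal(men$type, s$mentions$type)
  }
})

test_that("overlapping mentions are rejected", {
  expect_error(
    dnr_sentence("abc def ghi",
                 mentions = data.frame(start = c(0L, 4L), end = c(7L, 11L),
                                       type = c("drug", "drug"))),
    "overlapping")
  expect_error(
    dnr_sentence("abc", mentions = data.frame(start = 2L, end = 2L,
                                              type = "drug")),
    "start >= end")
  expect_error(
    dnr_sentence("abc", mentions = data.frame(start = 0L, end = 3L,
                                              type = "protein")),
    "unknown entity type")
})

test_that("tokenizer keeps internal symbols and peels edge punctuation", {
  tok <- tokenize_text("interleukin-2, and (aspirin).")
  expect_equal(tok$text,
               c("interleukin-2", ",", "and", "(", "aspirin", ")."))
  expect_equal(tok$start[1L], 0L)
  expect_equal(tok$end[1L], 13L)
  # offsets slice the original text
  txt <- "interleukin-2, and (aspirin)."
  expect_equal(substring(txt, tok$start + 1L, tok$end), tok$text)
})

test_that("CoNLL write then read is the identity on tokens and tags", {
  corpus <- generate_corpus(simulate_config(seed = 6L, n_sentences = 12L))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(corpus, path)
  back <- read_conll(path)
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$tokens$text, corpus[[i]]$tokens$text)
    expect_equal(encode_bilou(back[[i]]), encode_bilou(corpus[[i]]))
  }
})

test_that("CoNLL reader validates structure and tags", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(character(0), path)
  expect_length(read_conll(path), 0L)

  writeLines(c("aspirin\t0\t7\tU-chemical"), path)
  expect_error(read_conll(path), "U-chemical")
  writeLines(c("aspirin\t0\t7"), path)
  expect_error(read_conll(path), "line 1")
  writeLines(c("aspirin\tx\t7\tO"), path)
  expect_error(read_conll(path), "offsets")
})

test_that("standoff read pairs sentences with their typed mentions", {
  tpath <- withr::local_tempfile(fileext = ".txt")
  apath <- withr::local_tempfile(fileext = ".ann")
  corpus <- generate_corpus(simulate_config(seed = 9L, n_sentences = 8L))
  write_standoff(corpus, tpath, apath)
  back <- read_standoff(tpath, apath)
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$mentions$start, corpus[[i]]$mentions$start)
    expect_equal(back[[i]]$mentions$type, corpus[[i]]$mentions$type)
  }
  writeLines("s99\t0\t3\tdrug\tfoo", apath)
  expect_error(read_standoff(tpath, apath), "unknown document")
})
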