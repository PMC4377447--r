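test_that("typed tags collapse to coarse letters", {
  expect_equal(collapse_tag(c("B-drug", "O", "U-no-human", "L-group")),
               c("B", "O", "U", "L"))
  expect_error(collapse_tag("X-drug"), "invalid tag")
})

test_that("contingency counts come out as hand counts on fixtures", {
  fl <- list(c("f"), c("f"), c("f"), c("g"))
  tg <- c("U", "U", "O", "U")
  expect_equal(count_contingency(fl, tg, "f", "U"),
               c(n11 = 2L, n10 = 1L, n01 = 1L, n00 = 0L))
  expect_equal(unname(count_contingency(fl, tg, "absent", "U")[1:2]),
               c(0L, 0L))
  expect_equal(count_contingency(list("f"), "U", "f", "U"),
               c(n11 = 1L, n10 = 0L, n01 = 0L, n00 = 0L))
})

test_that("chi-square matches hand computation and conventions", {
  expect_equal(chi_square(c(5, 5, 5, 5)), 0)
  expect_equal(chi_square(c(49, 1, 1, 49)), 92.16)
  expect_equal(chi_square(c(0, 0, 10, 90)), 0)  # degenerate marginal
  expect_error(chi_square(c(0, 0, 0, 0)), "empty")
})

test_that("chi-square agrees with a brute-force four-cell oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample.int(50, 4L, replace = TRUE) - 1L
    if (sum(n) == 0L) n[1] <- 1L
    obs <- matrix(n, 2L, byrow = TRUE)
    rs <- rowSums(obs); cs <- colSums(obs)
    expected <- if (any(rs == 0) || any(cs == 0)) 0 else {
      E <- outer(rs, cs) / sum(n)
      sum((obs - E)^2 / E)
    }
    expect_lt(abs(chi_square(n) - expected), 1e-9)
  }
})

test_that("mutual information matches the plug-in estimate in bits", {
  expect_equal(mutual_information(c(5, 5, 5, 5)), 0)
  expect_equal(mutual_information(c(50, 0, 0, 50)), 1)
  expect_equal(mutual_information(c(49, 1, 1, 49)), 0.858559457458,
               tolerance = 1e-10)
  # plug-in oracle on random tables
  set.seed(55)
  for (i in 1:200) {
    n <- sample.int(30, 4L, replace = TRUE)
    p <- n / sum(n)
    pf <- p[1] + p[2]; pc <- p[1] + p[3]
    oracle <- sum(ifelse(p > 0, p * log2(p / (c(pf * pc, pf * (1 - pc),
                                                (1 - pf) * pc,
                                                (1 - pf) * (1 - pc)))), 0))
    expect_lt(abs(mutual_information(n) - oracle), 1e-12)
    expect_gte(mutual_information(n), -1e-12)
  }
})

test_that("information gain equals the entropy-difference oracle", {
  # feature leaves the tag distribution unchanged -> IG = 0
  fl <- c(rep(list("f"), 4L), rep(list(character(0)), 4L))
  tg <- c("O", "U", "O", "U", "O", "U", "O", "U")
  expect_equal(information_gain(fl, tg, "f"), 0)
  # feature perfectly predicts a balanced binary tag -> 1 bit
  tg2 <- c(rep("U", 4L), rep("O", 4L))
  expect_equal(information_gain(fl, tg2, "f"), 1)
  # 10-token fixture against an independent plug-in entropy computation
  fl3 <- c(rep(list("f"), 6L), rep(list(character(0)), 4L))
  tg3 <- c("B", "I", "L", "O", "O", "U", "O", "O", "O", "U")
  H <- function(cnt) { p <- cnt[cnt > 0] / sum(cnt); -sum(p * log2(p)) }
  oracle <- H(table(tg3)) -
    0.6 * H(table(tg3[1:6])) - 0.4 * H(table(tg3[7:10]))
  expect_equal(information_gain(fl3, tg3, "f"), oracle, tolerance = 1e-12)
  expect_gte(oracle, 0)
  expect_lte(oracle, H(table(tg3)))
})

test_that("importance is the max over coarse tags and IG directly", {
  # one feature occurring only with U among a sea of O tokens
  fl <- c(rep(list("f"), 3L), rep(list(character(0)), 7L))
  tg <- c("U-drug", "U-drug", "U-drug", rep("O", 7L))
  for (st in c("chi2", "mi")) {
    imp <- feature_importance(fl, tg, st)
    per_tag <- vapply(c("B", "I", "L", "O", "U"), function(t) {
      tab <- count_contingency(fl, collapse_tag(tg), "f", t)
      if (st == "chi2") chi_square(tab) else mutual_information(tab)
    }, numeric(1))
    expect_equal(imp$score[imp$feature == "f"], max(per_tag))
    # with only two observed tags, U and its complement O score equally
    expect_equal(per_tag[["U"]], max(per_tag))
  }
  imp_ig <- feature_importance(fl, tg, "ig")
  expect_equal(imp_ig$score[imp_ig$feature == "f"],
               information_gain(fl, collapse_tag(tg), "f"),
               tolerance = 1e-12)
})

test_that("importance scores are finite, complete and tie-ordered", {
  res <- shared_resources()
  cf <- corpus_features(res$res$corpus[1:30], res$config)
  for (st in c("chi2", "mi", "ig")) {
    imp <- feature_importance(cf$features, cf$tags, st)
    expect_equal(sort(imp$feature),
                 sort(unique(unlist(cf$features))))
    expect_true(all(is.finite(imp$score)))
    expect_true(all(imp$score >= -1e-9))
    expect_true(all(diff(imp$score) <= 1e-12))
  }
})

test_that("top-fraction selection rounds half away from zero and nests", {
  imp <- data.frame(feature = c("a", "b", "c", "d", "e"),
                    score = c(3, 2, 1, 0.5, 0.1))
  expect_equal(select_top_fraction(imp, 0.4), c("a", "b"))
  expect_equal(select_top_fraction(imp, 1), imp$feature)
  expect_error(select_top_fraction(imp, 0), "p")
  expect_error(select_top_fraction(imp, 1.2), "p")
  # the count the full-scale protocol reports: 40% of 294782 features
  fake <- data.frame(feature = sprintf("f%06d", 1:294782),
                     score = rep(1, 294782))
  expect_length(select_top_fraction(fake, 0.4), 117913L)
  # monotone nesting under the fixed tie order
  set.seed(12)
  imp2 <- data.frame(feature = sprintf("x%03d", 1:50),
                     score = sample(rep(c(2, 1, 0.5), length.out = 50)))
  prev <- character(0)
  for (p in seq(0.1, 1, by = 0.1)) {
    cur <- select_top_fraction(imp2, p)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a planted predictive feature outranks noise for all statistics", {
  set.seed(2024)
  n <- 600L
  tags <- sample(c("U-drug", "O"), n, replace = TRUE, prob = c(0.3, 0.7))
  fl <- lapply(seq_len(n), function(i) {
    out <- character(0)
    # dictionary-like feature: fires on 90% of drug tokens, 5% of others
    if ((tags[i] != "O" && runif(1) < 0.9) ||
        (tags[i] == "O" && runif(1) < 0.05)) out <- c(out, "f5[0]=Y")
    if (runif(1) < 0.5) out <- c(out, "noise[0]=Z")
    out
  })
  for (st in c("chi2", "mi", "ig")) {
    imp <- feature_importance(fl, tags, st)
    sc <- setNames(imp$score, imp$feature)
    expect_gt(sc[["f5[0]=Y"]], sc[["noise[0]=Z"]])
  }
})

test_that("importance tables and feature lists round-trip as TSV", {
  res <- shared_resources()
  cf <- corpus_features(res$res$corpus[1:5], res$config)
  imp <- feature_importance(cf$features, cf$tags, "chi2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_importance(imp, path)
  back <- read_importance(path)
  expect_equal(back$feature, imp$feature)
  expect_equal(back$score, imp$score, tolerance = 1e-6)
  expect_equal(attr(back, "statistic"), "chi2")
  lpath <- withr::local_tempfile(fileext = ".txt")
  keep <- select_top_fraction(imp, 0.25)
  write_feature_list(keep, lpath)
  expect_equal(read_feature_list(lpath), keep)
})
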