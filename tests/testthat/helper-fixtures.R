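# Shared fixtures, built in code at test time.

# The worked-example sentence: two single-token drug mentions.
fig1_sentence <- function() {
  text <- "luteolin and apigenin experienced extensive"
  dnr_sentence(text, mentions = data.frame(
    start = c(0L, 13L), end = c(8L, 21L),
    type = c("drug", "drug"), stringsAsFactors = FALSE))
}

# A sentence whose only mention spans three tokens.
group_sentence <- function() {
  dnr_sentence("iodinated contrast media",
               mentions = data.frame(start = 0L, end = 24L, type = "group"))
}

# Memoized mid-sized resource bundle so CRF tests share one generation run.
shared_env <- new.env()
shared_resources <- function() {
  if (is.null(shared_env$res)) {
    cfg <- simulate_config(seed = 42L, n_sentences = 120L)
    shared_env$res <- generate_resources(cfg)
    shared_env$config <- feature_config(
      dictionaries = shared_env$res$dictionaries,
      clusters = shared_env$res$clusters)
  }
  list(res = shared_env$res, config = shared_env$config)
}

random_mentions <- function(n, max_pos = 60L, types = dnr_entity_types()) {
  # non-overlapping typed spans in one coordinate system
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0)))
  }
  bounds <- sort(sample.int(max_pos, 2L * n))
  starts <- bounds[seq(1L, 2L * n, by = 2L)]
  ends <- bounds[seq(2L, 2L * n, by = 2L)]
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep],
             type = sample(types, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}
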