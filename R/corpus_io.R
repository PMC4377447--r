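#' @useDynLib dnr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats kmeans optim runif setNames
#' @importFrom utils head read.delim write.table combn
NULL

#' Entity types of the drug-name recognition task
#'
#' The four mention types annotated in DDI-style corpora: substances for
#' human use described by their generic name (`drug`), branded/trade names
#' (`brand`), drug classes (`group`) and active substances not approved for
#' human use (`no-human`).
#'
#' @return Character vector of the four canonical entity types.
#' @export
dnr_entity_types <- function() c("drug", "brand", "group", "no-human")

#' BILOU tag inventory for a set of entity types
#'
#' Builds the label alphabet of the sequence-labeling formulation: for every
#' entity type the four positional tags `B-` (beginning), `I-` (inside),
#' `L-` (last) and `U-` (unit length), plus the single outside tag `O`.
#' For the four standard types this yields the 17-tag inventory.
#'
#' @param entity_types character vector of entity type names (non-empty,
#'   no duplicates). Defaults to [dnr_entity_types()].
#' @return Character vector of `4 * length(entity_types) + 1` tags, ordered
#'   B/I/L/U per type in the given type order, with `"O"` last.
#' @examples
#' length(tag_inventory())  # 17
#' tag_inventory("drug")
#' @export
tag_inventory <- function(entity_types = dnr_entity_types()) {
  if (length(entity_types) == 0L) {
    stop("'entity_types' must be a non-empty set of type names")
  }
  if (anyDuplicated(entity_types)) {
    stop("'entity_types' contains duplicated type names")
  }
  c(as.vector(vapply(entity_types,
                     function(tp) paste0(c("B-", "I-", "L-", "U-"), tp),
                     character(4L))),
    "O")
}

#' Tokenize sentence text
#'
#' Splits on whitespace, then peels leading and trailing punctuation runs
#' off each chunk as separate tokens. Hyphens, brackets and other symbols
#' *inside* a chunk are kept, so names such as `interleukin-2` or bracketed
#' IUPAC fragments remain single tokens.
#'
#' @param text a single character string.
#' @return data.frame with columns `text`, `start`, `end` (0-based,
#'   half-open character offsets) and `index` (0-based token position).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- character(0); starts <- integer(0)
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] != -1L) {
    for (ci in seq_along(m)) {
      chunk <- substr(text, m[ci], m[ci] + attr(m, "match.length")[ci] - 1L)
      off <- m[ci] - 1L  # 0-based
      # leading punctuation run
      lead <- regmatches(chunk, regexpr("^[^[:alnum:]]+", chunk))
      core <- chunk
      if (length(lead) == 1L && nchar(lead) < nchar(chunk)) {
        toks <- c(toks, lead); starts <- c(starts, off)
        core <- substr(chunk, nchar(lead) + 1L, nchar(chunk))
        off <- off + nchar(lead)
      }
      trail <- regmatches(core, regexpr("[^[:alnum:]]+$", core))
      if (length(trail) == 1L && nchar(trail) < nchar(core)) {
        body <- substr(core, 1L, nchar(core) - nchar(trail))
        toks <- c(toks, body); starts <- c(starts, off)
        toks <- c(toks, trail); starts <- c(starts, off + nchar(body))
      } else {
        toks <- c(toks, core); starts <- c(starts, off)
      }
    }
  }
  data.frame(text = toks, start = starts, end = starts + nchar(toks),
             index = seq_along(toks) - 1L, stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0),
             type = character(0), text = character(0),
             stringsAsFactors = FALSE)
}

#' Construct an annotated sentence
#'
#' The unit of labeling: sentence text, its tokens with character offsets,
#' and zero or more typed entity mentions. Mentions must be non-overlapping;
#' alignment with token boundaries is checked by [encode_bilou()].
#'
#' @param text sentence string.
#' @param mentions data.frame with columns `start`, `end` (0-based,
#'   half-open), `type`; a `text` column is filled in if absent.
#' @param tokens optional pre-tokenized data.frame as returned by
#'   [tokenize_text()]; tokenized from `text` when `NULL`.
#' @param doc_id optional document/sentence identifier.
#' @param entity_types allowed mention types.
#' @return An object of class `dnr_sentence`.
#' @export
dnr_sentence <- function(text, mentions = NULL, tokens = NULL,
                         doc_id = NA_character_,
                         entity_types = dnr_entity_types()) {
  if (is.null(tokens)) tokens <- tokenize_text(text)
  if (is.null(mentions) || nrow(mentions) == 0L) {
    mentions <- empty_mentions()
  } else {
    mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
    if (!all(c("start", "end", "type") %in% names(mentions))) {
      stop("mentions need columns start, end, type")
    }
    bad <- setdiff(unique(mentions$type), entity_types)
    if (length(bad)) {
      stop("unknown entity type(s): ", paste(bad, collapse = ", "))
    }
    if (any(mentions$start >= mentions$end)) {
      stop("mention with start >= end")
    }
    mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
    if (nrow(mentions) > 1L &&
        any(mentions$start[-1L] < mentions$end[-nrow(mentions)])) {
      stop("overlapping mentions cannot be represented by one tag per token")
    }
    if (is.null(mentions$text)) {
      mentions$text <- substring(text, mentions$start + 1L, mentions$end)
    }
    rownames(mentions) <- NULL
  }
  structure(list(text = text, tokens = tokens, mentions = mentions,
                 doc_id = doc_id),
            class = "dnr_sentence")
}

#' @export
print.dnr_sentence <- function(x, ...) {
  cat("<dnr_sentence", if (!is.na(x$doc_id)) paste0("[", x$doc_id, "]"), ">\n")
  cat("  ", x$text, "\n", sep = "")
  cat("  tokens: ", nrow(x$tokens), ", mentions: ", nrow(x$mentions), "\n",
      sep = "")
  if (nrow(x$mentions)) {
    for (i in seq_len(nrow(x$mentions))) {
      cat(sprintf("    [%d,%d) %s: %s\n", x$mentions$start[i],
                  x$mentions$end[i], x$mentions$type[i], x$mentions$text[i]))
    }
  }
  invisible(x)
}

#' Encode mentions as a BILOU tag sequence
#'
#' Single-token mentions become `U-<type>`; multi-token mentions become
#' `B-<type>`, zero or more `I-<type>` and a final `L-<type>`; all other
#' tokens are `O`.
#'
#' @param sentence a [dnr_sentence()].
#' @param snap if `TRUE`, mention boundaries that fall strictly inside a
#'   token are snapped outward to the enclosing token boundaries (with a
#'   message); the default is to raise an error.
#' @return Character vector of tags, one per token.
#' @export
encode_bilou <- function(sentence, snap = FALSE) {
  stopifnot(inherits(sentence, "dnr_sentence"))
  tok <- sentence$tokens
  tags <- rep("O", nrow(tok))
  men <- sentence$mentions
  for (i in seq_len(nrow(men))) {
    s <- men$start[i]; e <- men$end[i]
    first <- which(tok$start <= s & tok$end > s)
    last <- which(tok$start < e & tok$end >= e)
    if (length(first) != 1L || length(last) != 1L ||
        !(s %in% tok$start) || !(e %in% tok$end)) {
      if (snap && length(first) == 1L && length(last) == 1L) {
        message(sprintf("snapped mention [%d,%d) to token boundaries [%d,%d)",
                        s, e, tok$start[first], tok$end[last]))
      } else {
        stop(sprintf(
          "mention [%d,%d) '%s' does not align with token boundaries",
          s, e, men$text[i]))
      }
    }
    if (first == last) {
      tags[first] <- paste0("U-", men$type[i])
    } else {
      tags[first] <- paste0("B-", men$type[i])
      if (last > first + 1L) {
        tags[(first + 1L):(last - 1L)] <- paste0("I-", men$type[i])
      }
      tags[last] <- paste0("L-", men$type[i])
    }
  }
  tags
}

tag_letter <- function(tags) substr(tags, 1L, 1L)
tag_type <- function(tags) ifelse(tags == "O", NA_character_,
                                  substring(tags, 3L))

#' Decode a BILOU tag sequence into entity mentions
#'
#' Inverse of [encode_bilou()] on valid sequences. In strict mode (default)
#' invalid transitions -- an `I`/`L` with no open entity, a type change mid
#' entity, or an entity left open -- raise an error. In lenient mode a
#' standard repair is applied: a stray `I`/`L` starts (or closes) a new
#' entity and an interrupted entity is closed at the last consistent token;
#' repairs are reported via `message()` and counted in the `"repairs"`
#' attribute.
#'
#' @param tags character vector of BILOU tags.
#' @param tokens token data.frame (as in [dnr_sentence()]), same length.
#' @param strict logical; see above.
#' @return Mention data.frame (`start`, `end`, `type`, `text`).
#' @export
decode_bilou <- function(tags, tokens, strict = TRUE) {
  if (length(tags) != nrow(tokens)) {
    stop("tags and tokens must have equal length")
  }
  out <- list(); repairs <- 0L
  open_type <- NULL; open_start <- NA_integer_; open_first <- NA_integer_
  bad <- function(msg, i) {
    if (strict) stop(sprintf("invalid BILOU sequence at token %d: %s", i, msg))
    message(sprintf("BILOU repair at token %d: %s", i, msg))
    repairs <<- repairs + 1L
  }
  close_open <- function(last_idx) {
    out[[length(out) + 1L]] <<- list(start = open_start,
                                     end = tokens$end[last_idx],
                                     type = open_type)
    open_type <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]; lt <- tag_letter(tg); tp <- tag_type(tg)
    if (lt == "O") {
      if (!is.null(open_type)) { bad("entity interrupted by O", i)
        close_open(i - 1L) }
    } else if (lt == "U") {
      if (!is.null(open_type)) { bad("entity interrupted by U", i)
        close_open(i - 1L) }
      open_type <- tp; open_start <- tokens$start[i]
      close_open(i)
    } else if (lt == "B") {
      if (!is.null(open_type)) { bad("entity interrupted by B", i)
        close_open(i - 1L) }
      open_type <- tp; open_start <- tokens$start[i]; open_first <- i
    } else if (lt %in% c("I", "L")) {
      if (is.null(open_type)) {
        bad(sprintf("%s with no open entity", lt), i)
        open_type <- tp; open_start <- tokens$start[i]; open_first <- i
      } else if (!identical(open_type, tp)) {
        bad("entity type change mid-entity", i)
        close_open(i - 1L)
        open_type <- tp; open_start <- tokens$start[i]; open_first <- i
      }
      if (lt == "L" && !is.null(open_type)) close_open(i)
    } else {
      stop("unknown tag letter in '", tg, "'")
    }
  }
  if (!is.null(open_type)) {
    bad("entity left open at sentence end", length(tags))
    close_open(length(tags))
  }
  if (length(out) == 0L) return(structure(empty_mentions(), repairs = repairs))
  men <- data.frame(start = vapply(out, `[[`, integer(1), "start"),
                    end = vapply(out, `[[`, integer(1), "end"),
                    type = vapply(out, `[[`, character(1), "type"),
                    stringsAsFactors = FALSE)
  men$text <- vapply(seq_len(nrow(men)), function(i) {
    idx <- tokens$start >= men$start[i] & tokens$end <= men$end[i]
    paste(tokens$text[idx], collapse = " ")
  }, character(1))
  structure(men, repairs = repairs)
}

parse_tag <- function(tag, entity_types) {
  if (tag == "O") return(TRUE)
  ok <- grepl("^[BILU]-", tag) && substring(tag, 3L) %in% entity_types
  ok
}

#' Read a CoNLL-style annotated corpus
#'
#' Format: one token per line with tab-separated columns
#' `token<TAB>start<TAB>end<TAB>tag`, a blank line between sentences, UTF-8.
#'
#' @param path file path.
#' @param entity_types allowed entity types for tag validation.
#' @return List of [dnr_sentence()] objects.
#' @export
read_conll <- function(path, entity_types = dnr_entity_types()) {
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list(); cur <- list()
  flush <- function(cur) {
    if (length(cur) == 0L) return(NULL)
    tok <- data.frame(
      text = vapply(cur, `[[`, character(1), 1L),
      start = as.integer(vapply(cur, `[[`, character(1), 2L)),
      end = as.integer(vapply(cur, `[[`, character(1), 3L)),
      stringsAsFactors = FALSE)
    tok$index <- seq_len(nrow(tok)) - 1L
    tags <- vapply(cur, `[[`, character(1), 4L)
    # reconstruct text from offsets
    txt <- character(max(tok$end))
    txt[] <- " "
    for (i in seq_len(nrow(tok))) {
      substr_chars <- strsplit(tok$text[i], "")[[1]]
      txt[(tok$start[i] + 1L):tok$end[i]] <- substr_chars
    }
    text <- paste(txt, collapse = "")
    men <- decode_bilou(tags, tok, strict = TRUE)
    dnr_sentence(text, mentions = men, tokens = tok,
                 entity_types = entity_types)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) {
      s <- flush(cur); if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      cur <- list(); next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4L) {
      stop(sprintf("malformed CoNLL line %d: expected 4 tab-separated fields",
                   ln))
    }
    if (is.na(suppressWarnings(as.integer(parts[2]))) ||
        is.na(suppressWarnings(as.integer(parts[3])))) {
      stop(sprintf("malformed offsets on line %d", ln))
    }
    if (!parse_tag(parts[4], entity_types)) {
      stop(sprintf("unknown tag '%s' on line %d", parts[4], ln))
    }
    cur[[length(cur) + 1L]] <- parts
  }
  s <- flush(cur); if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
  sentences
}

#' Write sentences in CoNLL format
#'
#' @param sentences list of [dnr_sentence()].
#' @param path output file path.
#' @export
write_conll <- function(sentences, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    tags <- encode_bilou(s)
    writeLines(paste(s$tokens$text, s$tokens$start, s$tokens$end, tags,
                     sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read plain text plus standoff annotations
#'
#' The text file holds one sentence per line (implicit ids `s1`, `s2`, ...).
#' The annotation file holds one mention per line:
#' `document-id<TAB>start<TAB>end<TAB>type<TAB>text`, offsets into the
#' sentence line.
#'
#' @param text_path path to the sentence file.
#' @param ann_path path to the standoff annotation file.
#' @param entity_types allowed entity types.
#' @return List of [dnr_sentence()] objects with `doc_id` set.
#' @export
read_standoff <- function(text_path, ann_path,
                          entity_types = dnr_entity_types()) {
  texts <- readLines(text_path, encoding = "UTF-8")
  ids <- paste0("s", seq_along(texts))
  anns <- if (file.exists(ann_path) && file.size(ann_path) > 0) {
    read.delim(ann_path, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("doc", "start", "end", "type", "text"),
               quote = "", fileEncoding = "UTF-8")
  } else {
    data.frame(doc = character(0), start = integer(0), end = integer(0),
               type = character(0), text = character(0))
  }
  bad <- setdiff(unique(anns$doc), ids)
  if (length(bad)) stop("annotation for unknown document id: ",
                        paste(bad, collapse = ", "))
  lapply(seq_along(texts), function(i) {
    mi <- anns[anns$doc == ids[i], c("start", "end", "type", "text")]
    dnr_sentence(texts[i], mentions = mi, doc_id = ids[i],
                 entity_types = entity_types)
  })
}

#' Write sentences as text plus standoff annotations
#'
#' @param sentences list of [dnr_sentence()].
#' @param text_path,ann_path output paths (see [read_standoff()]).
#' @export
write_standoff <- function(sentences, text_path, ann_path) {
  ids <- vapply(seq_along(sentences), function(i) {
    id <- sentences[[i]]$doc_id
    if (is.na(id)) paste0("s", i) else id
  }, character(1))
  writeLines(vapply(sentences, `[[`, character(1), "text"), text_path,
             useBytes = TRUE)
  con <- file(ann_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(sentences)) {
    m <- sentences[[i]]$mentions
    if (nrow(m)) {
      writeLines(paste(ids[i], m$start, m$end, m$type, m$text, sep = "\t"),
                 con)
    }
  }
  invisible(ann_path)
}
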