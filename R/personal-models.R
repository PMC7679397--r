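#' Default function-word stoplist
#'
#' A fixed list of English function words (articles, pronouns, prepositions,
#' conjunctions, auxiliaries and other closed-class items) removed when
#' extracting content words from scenario descriptions.  Users replicating
#' the analysis on real descriptions can substitute their own list to match
#' their tagging scheme.
#'
#' @return character vector of lowercase stopwords.
#' @export
default_stoplist <- function() {
  c("a", "an", "the", "and", "or", "but", "nor", "so", "yet", "if", "then",
    "than", "that", "this", "these", "those", "there", "here",
    "i", "me", "my", "mine", "myself", "we", "us", "our", "ours", "ourselves",
    "you", "your", "yours", "yourself", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves",
    "who", "whom", "whose", "which", "what", "when", "where", "why", "how",
    "am", "is", "are", "was", "were", "be", "been", "being",
    "have", "has", "had", "having", "do", "does", "did", "doing",
    "will", "would", "shall", "should", "can", "could", "may", "might",
    "must", "ought",
    "in", "on", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below",
    "to", "from", "up", "down", "out", "off", "over", "under", "of",
    "as", "not", "no", "only", "own", "same", "such", "too", "very",
    "just", "also", "while", "because", "until", "although", "though",
    "each", "few", "more", "most", "other", "some", "any", "all", "both",
    "s", "t", "d", "ll", "m", "re", "ve", "im", "dont", "didnt", "wasnt")
}

#' Extract content words from a scenario description
#'
#' Lowercases the description, strips punctuation, splits on whitespace,
#' drops stoplist words and any token absent from the lexicon.  Original
#' token order is preserved and duplicates are kept (each occurrence
#' contributes to the additive composition).
#'
#' @param description a single non-empty character string.
#' @param lexicon a word-embedding matrix with words as rownames, or a
#'   character vector of known words.
#' @param stoplist character vector of words to drop
#'   (default [default_stoplist()]).
#' @return character vector of retained content words, in order.
#' @export
extract_content_words <- function(description, lexicon,
                                  stoplist = default_stoplist()) {
  if (!is.character(description) || length(description) != 1L ||
      !nzchar(trimws(description))) {
    stop("description must be a single non-empty string")
  }
  known <- if (is.matrix(lexicon)) rownames(lexicon) else as.character(lexicon)
  txt <- tolower(description)
  txt <- gsub("[^[:alnum:][:space:]]", " ", txt)
  tokens <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  kept <- tokens[!(tokens %in% stoplist) & tokens %in% known]
  if (length(kept) == 0L) {
    stop("no modelable content words remain after filtering: \"",
         description, "\"")
  }
  kept
}

#' Compose a verbal vector by pointwise addition of word embeddings
#'
#' Maps each content word to its embedding vector and sums the vectors
#' pointwise.  Composition is deliberately naive -- word order and syntax
#' are ignored -- and linear: composing a concatenation of two word lists
#' equals the sum of their compositions.
#'
#' @param words non-empty character vector of words, all present in the
#'   lexicon; duplicates contribute once per occurrence.
#' @param lexicon word-embedding matrix with words as rownames.
#' @return numeric embedding-dimension vector.
#' @export
compose_verbal_vector <- function(words, lexicon) {
  if (length(words) == 0L) stop("empty word list")
  missing <- setdiff(words, rownames(lexicon))
  if (length(missing) > 0L) {
    stop("words absent from lexicon: ", paste(missing, collapse = ", "))
  }
  colSums(lexicon[words, , drop = FALSE])
}

#' Build the verbal model matrix for one participant
#'
#' One composed vector per scenario description: content words are extracted
#' and their embeddings summed.
#'
#' @param descriptions character vector, one description per scenario.
#' @param lexicon word-embedding matrix with words as rownames.
#' @param stoplist stopword vector passed to [extract_content_words()].
#' @return list with `values` (S x D matrix) and `word_lists` (retained
#'   content words per scenario).
#' @export
verbal_matrix <- function(descriptions, lexicon,
                          stoplist = default_stoplist()) {
  word_lists <- lapply(descriptions, extract_content_words,
                       lexicon = lexicon, stoplist = stoplist)
  values <- t(vapply(word_lists, compose_verbal_vector,
                     numeric(ncol(lexicon)), lexicon = lexicon))
  rownames(values) <- names(descriptions)
  list(values = values, word_lists = word_lists)
}

#' Normalize attribute ratings within participant
#'
#' Standardizes each attribute column of a scenario x attribute rating
#' matrix: the mean rating of the attribute across scenarios is subtracted
#' and the result divided by the standard deviation.  The default follows
#' the population-SD (divide by N) z-score convention; `sd_type = "sample"`
#' switches to N-1.  A constant column has no within-participant variance to
#' standardize, so it is set to zeros with a warning rather than producing
#' NaN -- this keeps the matrix shape intact for similarity computation.
#'
#' @param raw numeric S x A matrix of raw Likert ratings.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return the standardized matrix (same dimnames).
#' @export
normalize_attribute_ratings <- function(raw,
                                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 scenarios to normalize")
  out <- .zscore_cols(raw, sd_type = sd_type)
  col_var <- apply(raw, 2L, stats::var)
  if (any(col_var == 0)) {
    warning("constant attribute column(s) set to zero: ",
            paste(which(col_var == 0), collapse = ", "))
  }
  dimnames(out) <- dimnames(raw)
  out
}

#' Read a word-embedding table in plain-text dialect
#'
#' Reads the standard one-line-per-word format `word v1 v2 ... vd`
#' (space-separated, no header) used by distributional semantic models such
#' as GloVe.  Lookups elsewhere in the package are on the lowercase-folded
#' form, so words are stored as read.
#'
#' @param path file path.
#' @return numeric matrix with words as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    stop("inconsistent embedding dimensionality in ", path)
  }
  words <- vapply(parts, `[`, character(1), 1L)
  values <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dims[1L])))
  if (anyNA(values)) stop("non-numeric embedding values in ", path)
  rownames(values) <- words
  values
}

#' Write a word-embedding table in plain-text dialect
#'
#' @param embeddings numeric matrix with words as rownames.
#' @param path output file path.
#' @export
write_embeddings <- function(embeddings, path) {
  lines <- vapply(seq_len(nrow(embeddings)), function(i) {
    paste(c(rownames(embeddings)[i],
            format(embeddings[i, ], scientific = FALSE, trim = TRUE,
                   digits = 9)), collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a scenario x attribute ratings table (TSV)
#'
#' Expects a header row of attribute names and a first column of scenario
#' names.
#'
#' @param path file path.
#' @return numeric matrix, scenarios in rows.
#' @export
read_ratings_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Write a scenario x attribute ratings table (TSV)
#'
#' @param ratings numeric matrix, scenarios in rows.
#' @param path output file path.
#' @export
write_ratings_tsv <- function(ratings, path) {
  df <- data.frame(scenario = rownames(ratings), ratings,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
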