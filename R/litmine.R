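#' Filter compounds by reported mean lifespan extension
#'
#' Keeps records whose best reported mean lifespan change is strictly above
#' the threshold ("above 5%" is read as a strict inequality, so a record at
#' exactly the threshold is dropped). Idempotent and monotone in the
#' threshold.
#'
#' @param records data.frame with a `mean_lifespan_change_pct` column.
#' @param min_extension_pct threshold in percent (default 5).
#' @return The qualifying rows.
#' @export
filter_lifespan <- function(records, min_extension_pct = 5.0) {
  stopifnot("mean_lifespan_change_pct" %in% names(records))
  records[records$mean_lifespan_change_pct > min_extension_pct, ,
          drop = FALSE]
}

#' Count distinct ECM keywords in a text
#'
#' Case-insensitive token-prefix matching: the text is split into word
#' tokens (runs of letters, digits and hyphens) and a keyword matches any
#' token that begins with it. Prefix matching lets "TGF" hit "TGFbeta"
#' while "matrix" does not hit hypothetical tokens merely containing it.
#' Each keyword counts at most once (distinct counting); per-keyword token
#' occurrence totals are also returned for the occurrence-counting mode.
#'
#' @param text character scalar.
#' @param keywords non-empty character vector; defaults to [ecm_keywords()].
#' @return List with `count` (distinct keywords matched), `matched`
#'   (the keywords) and `occurrences` (named integer vector of token hits
#'   per keyword).
#' @export
keyword_hits <- function(text, keywords = ecm_keywords()) {
  if (!length(keywords)) stop("keywords must be non-empty")
  tokens <- regmatches(text, gregexpr("[[:alnum:]-]+", text))[[1]]
  lower_tokens <- tolower(tokens)
  occ <- vapply(keywords, function(kw) {
    sum(startsWith(lower_tokens, tolower(kw)))
  }, integer(1))
  matched <- keywords[occ > 0]
  list(count = length(matched), matched = matched, occurrences = occ)
}

#' Flag compound records as ECM-linked
#'
#' Fills `keyword_hits` (distinct-keyword count over `abstract_text`, or
#' total occurrences when `distinct = FALSE`) and sets
#' `ecm_linked = keyword_hits >= 1`.
#'
#' @param records data.frame with an `abstract_text` column.
#' @param keywords keyword list; defaults to [ecm_keywords()].
#' @param distinct count distinct keywords (default) or total occurrences.
#' @return `records` with `keyword_hits` and `ecm_linked` columns added.
#' @export
flag_ecm <- function(records, keywords = ecm_keywords(), distinct = TRUE) {
  stopifnot("abstract_text" %in% names(records))
  hits <- vapply(records$abstract_text, function(txt) {
    h <- keyword_hits(txt, keywords)
    if (distinct) h$count else sum(h$occurrences)
  }, integer(1), USE.NAMES = FALSE)
  records$keyword_hits <- hits
  records$ecm_linked <- hits >= 1L
  records
}
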