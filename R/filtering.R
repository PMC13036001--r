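#' Construct a filter plugin
#'
#' Plugins wrap external sequence classifiers (numbering tools, humanness
#' models, confidence scorers) behind a uniform contract: a deterministic
#' callable taking the light sequence (and optionally its heavy context)
#' and returning a pass/fail verdict with a scalar score.  A plugin that
#' throws marks the sequence as failing that plugin; the stack continues.
#'
#' @param name plugin name (used in outcome reports)
#' @param fn `function(light, heavy = NULL)` returning
#'   `list(pass = logical, score = numeric)`
#' @return an object of class `filter_plugin`
#' @export
filter_plugin <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  structure(list(name = name, fn = fn), class = "filter_plugin")
}

#' Apply the post-generation filter stack
#'
#' The built-in validity filter (the sequence must be annotatable by
#' [annotate_regions()]) is always applied first and is non-optional;
#' plugins are applied in order; duplicate light sequences (exact string
#' equality, earliest occurrence kept) are removed when requested.  An
#' outcome row is recorded for every input, including removed ones.
#'
#' @param results a list of `generation_result` objects or a character
#'   vector of light sequences
#' @param plugins list of [filter_plugin()] objects
#' @param drop_duplicates remove exact duplicate light sequences
#' @param heavy optional heavy-chain context passed to plugins
#' @param scheme annotation scheme for the validity filter
#' @return list with `kept` (character vector of surviving sequences) and
#'   `outcomes` (data.frame: `id`, `light`, one verdict column per filter,
#'   `duplicate`, `final`)
#' @export
apply_filter_stack <- function(results, plugins = list(),
                               drop_duplicates = TRUE, heavy = NULL,
                               scheme = "imgt") {
  seqs <- if (is.character(results)) results
  else vapply(results, function(r) r$light, "")
  gen_failed <- if (is.character(results)) rep(FALSE, length(results))
  else vapply(results, function(r) isTRUE(r$failed), logical(1))
  n <- length(seqs)
  out <- data.frame(id = sprintf("seq%04d", seq_len(n)), light = seqs,
                    stringsAsFactors = FALSE)
  out$validity <- !gen_failed & vapply(seqs, function(s)
    nzchar(s) && !is.null(annotate_regions(s, scheme)), logical(1))
  alive <- out$validity
  for (pl in plugins) {
    stopifnot(inherits(pl, "filter_plugin"))
    verdict <- rep(NA, n)  # NA = skipped (already removed upstream)
    for (i in which(alive)) {
      verdict[i] <- tryCatch(isTRUE(pl$fn(seqs[i], heavy)$pass),
                             error = function(e) FALSE)
    }
    out[[pl$name]] <- verdict
    alive <- alive & !is.na(verdict) & verdict
  }
  if (drop_duplicates) {
    key <- ifelse(alive, seqs, paste0("removed", seq_len(n)))
    out$duplicate <- alive & duplicated(key)
    alive <- alive & !out$duplicate
  } else {
    out$duplicate <- FALSE
  }
  out$final <- alive
  list(kept = seqs[alive], outcomes = out)
}

#' Evenly spaced diversity selection over ordered confidence scores
#'
#' Sorts the sequences ascending by score (ties keep input order) and takes
#' the evenly spaced ranks `round(i * (n - 1) / (k - 1)) + 1` for
#' `i = 0, ..., k - 1` (the lowest-scoring sequence for `k = 1`); for
#' `k >= 2` the minimum- and maximum-score sequences are always included.
#' The generator's per-sequence mean log-probability is the conventional
#' score when no external confidence plugin is configured.
#'
#' @param sequences character vector
#' @param confidence_scores numeric vector aligned with `sequences`
#' @param k number of sequences to select (`1 <= k <= length(sequences)`)
#' @return the selected sequences, in ascending score order
#' @export
select_diverse <- function(sequences, confidence_scores, k) {
  n <- length(sequences)
  stopifnot(length(confidence_scores) == n)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= number of sequences")
  ord <- order(confidence_scores)
  idx <- if (k == 1) 1L else round((seq_len(k) - 1) * (n - 1) / (k - 1)) + 1L
  sequences[ord[idx]]
}

#' Mean per-token log-probability of generation results
#'
#' The default confidence score for [select_diverse()].
#'
#' @param results list of `generation_result`
#' @return numeric vector
#' @export
generation_confidence <- function(results) {
  vapply(results, function(r) mean(r$per_token_logprob), 0)
}
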