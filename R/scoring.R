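#' Teacher-forced log-likelihood of a light chain given a heavy chain
#'
#' The sum over light-chain tokens (residues plus the stop token) of the
#' log-softmax probability assigned by the model given the heavy chain and
#' the preceding light-chain tokens.
#'
#' @param model a model object (anything with a [model_logits()] method)
#' @param heavy heavy-chain sequence (`""` for unconditional scoring)
#' @param light light-chain sequence
#' @param vocab token vocabulary
#' @return list with `total` (nats), `per_token` (length `nchar(light) + 1`)
#'   and `n_tokens`
#' @export
sequence_loglik <- function(model, heavy, light, vocab = default_vocab()) {
  src <- tokenize(heavy, vocab)
  tgt <- tokenize(light, vocab)
  tin <- tgt[-length(tgt)]
  tout <- tgt[-1]
  lg <- model_logits(model, src, tin)
  per <- vapply(seq_along(tout), function(t) log_softmax(lg[t, ])[tout[t]], 0)
  list(total = sum(per), per_token = per, n_tokens = length(per))
}

#' Perplexity of a light chain given a heavy chain
#'
#' `exp(-mean per-token log-likelihood)`; lower is more confident.
#'
#' @inheritParams sequence_loglik
#' @return scalar perplexity
#' @export
perplexity <- function(model, heavy, light, vocab = default_vocab()) {
  ll <- sequence_loglik(model, heavy, light, vocab)
  exp(-ll$total / ll$n_tokens)
}

#' Unconditional log-likelihood of a light chain
#'
#' The same teacher-forced score with an empty heavy chain (the encoder sees
#' only the start and stop tokens); the operationalisation of the
#' "unconditional probability" used by [pairing_preference()].
#'
#' @inheritParams sequence_loglik
#' @return total log-likelihood (nats)
#' @export
unconditional_loglik <- function(model, light, vocab = default_vocab()) {
  sequence_loglik(model, "", light, vocab)$total
}

#' Pairing-preference statistic between two candidate light chains
#'
#' With `a = P(native | heavy) / P(native)` and
#' `b = P(alternative | heavy) / P(alternative)` (conditional sequence
#' probabilities normalised by the unconditional ones), the statistic is
#' `(a - b) / (a + b)`, computed in log space as
#' `tanh((log a - log b) / 2)` so that products of ~110 token probabilities
#' cannot underflow.  Bounded in `[-1, 1]`; zero for identical candidates;
#' antisymmetric under swapping them; positive when the native pairing is
#' preferred after unconditional normalisation.
#'
#' @param model a model object
#' @param heavy heavy-chain sequence
#' @param light_native,light_alternative the two candidate light chains
#' @param vocab token vocabulary
#' @return an object of class `preference_statistic`: `value` plus the two
#'   normalised log-ratio components `log_a`, `log_b`
#' @export
pairing_preference <- function(model, heavy, light_native, light_alternative,
                               vocab = default_vocab()) {
  la <- sequence_loglik(model, heavy, light_native, vocab)$total -
    unconditional_loglik(model, light_native, vocab)
  lb <- sequence_loglik(model, heavy, light_alternative, vocab)$total -
    unconditional_loglik(model, light_alternative, vocab)
  structure(list(value = tanh((la - lb) / 2), log_a = la, log_b = lb),
            class = "preference_statistic")
}

#' @export
print.preference_statistic <- function(x, ...) {
  cat(sprintf("pairing preference: %.4f (log a = %.2f, log b = %.2f)\n",
              x$value, x$log_a, x$log_b))
  invisible(x)
}

#' Revert a light chain to its nearest germline
#'
#' Chooses the nearest V germline by ungapped identity over the V-encoded
#' span (FR1 through the second conserved cysteine) and the nearest J
#' germline over the J-encoded span (the trailing `j_cdr3 + fr4_len`
#' residues), then replaces every mismatching position in those spans with
#' the germline residue.  CDR3 junction residues covered by neither span are
#' left untouched; length is preserved (no indel handling).
#'
#' @param light light-chain sequence
#' @param germline_set a [light_germline_set()]
#' @param annotation optional precomputed [annotate_regions()] result
#' @return the reverted sequence with attributes `v_id`, `j_id` and
#'   `n_reverted`, or `NA` (with attribute `reason`) if no germline reaches
#'   50% identity or the chain cannot be annotated
#' @export
germline_revert <- function(light, germline_set, annotation = NULL) {
  if (is.null(annotation)) annotation <- annotate_regions(light)
  if (is.null(annotation))
    return(structure(NA_character_, reason = "unannotatable"))
  asg <- nearest_germline(light, germline_set, annotation)
  if (is.null(asg))
    return(structure(NA_character_, reason = "unannotatable"))
  if (asg$v_identity < 0.5)
    return(structure(NA_character_, reason = "no germline above 50% identity"))
  chars <- strsplit(light, "", fixed = TRUE)[[1]]
  vrec <- Find(function(r) r$id == asg$best_v_id, germline_set$v)
  jrec <- Find(function(r) r$id == asg$best_j_id, germline_set$j)
  vch <- strsplit(vrec$seq, "", fixed = TRUE)[[1]]
  jch <- strsplit(jrec$seq, "", fixed = TRUE)[[1]]
  v_span <- min(annotation$boundaries["FR3", "end"], length(vch))
  n_rev <- 0L
  for (p in seq_len(v_span)) {
    if (chars[p] != vch[p]) { chars[p] <- vch[p]; n_rev <- n_rev + 1L }
  }
  j_len <- min(length(jch), length(chars))
  off <- length(chars) - j_len
  for (k in seq_len(j_len)) {
    if (chars[off + k] != jch[length(jch) - j_len + k]) {
      chars[off + k] <- jch[length(jch) - j_len + k]
      n_rev <- n_rev + 1L
    }
  }
  structure(paste(chars, collapse = ""),
            v_id = asg$best_v_id, j_id = asg$best_j_id, n_reverted = n_rev)
}

#' Analytic stub model with uniform next-token logits
#'
#' A model-like object whose [model_logits()] method returns zero logits on
#' a fixed support (residues plus the stop token by default) and `-Inf`
#' elsewhere, regardless of the inputs.  The softmax is then exactly uniform
#' over the support, so `perplexity == effective vocabulary size` by
#' construction; used as an analytic oracle in tests and examples.
#'
#' @param vocab token vocabulary
#' @param support_ids token ids carrying probability mass
#' @return an object of class `lcgen_uniform_stub`
#' @export
uniform_stub_model <- function(vocab = default_vocab(),
                               support_ids = vocab$sample_ids) {
  structure(list(vocab = vocab, support_ids = as.integer(support_ids)),
            class = "lcgen_uniform_stub")
}

#' @export
model_logits.lcgen_uniform_stub <- function(model, src_ids, tgt_in_ids) {
  lg <- matrix(-Inf, nrow = length(tgt_in_ids), ncol = model$vocab$size)
  lg[, model$support_ids] <- 0
  lg
}
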