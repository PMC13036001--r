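#' Curate paired sequences
#'
#' Applies the dataset-cleaning rules in order: (1) remove pairs where either
#' chain is missing the conserved cysteine anchors (i.e. cannot be annotated
#' by [annotate_regions()]); (2) remove pairs with characters outside the
#' 20-letter amino-acid alphabet; (3) remove exact duplicate
#' `(heavy, light)` tuples (first occurrence kept).  Each pair is counted
#' once, under its first failing rule.  Curation never fails; it filters.
#'
#' @param pairs data.frame with columns `heavy` and `light` (other columns
#'   carried through)
#' @param scheme numbering scheme for the anchor check
#' @return list with `pairs` (the kept rows) and `report`, a curation report
#'   with counts `n_input`, `n_missing_cysteine`, `n_unknown_residue`,
#'   `n_duplicate_pair`, `n_kept`
#' @export
curate_pairs <- function(pairs, scheme = "imgt") {
  stopifnot(is.data.frame(pairs))
  if (!nrow(pairs)) {
    report <- list(n_input = 0L, n_missing_cysteine = 0L,
                   n_unknown_residue = 0L, n_duplicate_pair = 0L, n_kept = 0L)
    class(report) <- "curation_report"
    return(list(pairs = pairs, report = report))
  }
  stopifnot(all(c("heavy", "light") %in% names(pairs)))
  n <- nrow(pairs)
  ok_alpha <- is_valid_aa(pairs$heavy) & is_valid_aa(pairs$light)
  ok_anchor <- vapply(seq_len(n), function(i) {
    !is.null(annotate_regions(pairs$heavy[i], scheme)) &&
      !is.null(annotate_regions(pairs$light[i], scheme))
  }, logical(1))
  fail_anchor <- !ok_anchor
  fail_alpha <- ok_anchor & !ok_alpha
  key <- paste(pairs$heavy, pairs$light, sep = "|")
  survivors <- ok_anchor & ok_alpha
  dup <- survivors & duplicated(ifelse(survivors, key, paste0("uniq", seq_len(n))))
  kept <- survivors & !dup
  report <- list(
    n_input = n,
    n_missing_cysteine = sum(fail_anchor),
    n_unknown_residue = sum(fail_alpha),
    n_duplicate_pair = sum(dup),
    n_kept = sum(kept))
  class(report) <- "curation_report"
  stopifnot(report$n_kept == report$n_input - report$n_missing_cysteine -
              report$n_unknown_residue - report$n_duplicate_pair)
  list(pairs = pairs[kept, , drop = FALSE], report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(paste0("curation: %d in, %d removed (missing cysteine %d, ",
                     "unknown residue %d, duplicate pair %d), %d kept\n"),
              x$n_input, x$n_input - x$n_kept, x$n_missing_cysteine,
              x$n_unknown_residue, x$n_duplicate_pair, x$n_kept))
  invisible(x)
}

#' Random train / validation / test split with duplicate-heavy exclusion
#'
#' Partitions the pairs at the requested fractions (within one pair of exact
#' proportions), then drops from the test set any pair whose heavy sequence
#' occurs verbatim in train or validation.  Reproducible per seed.
#'
#' @param pairs data.frame of curated pairs
#' @param fractions length-3 vector summing to 1
#' @param seed integer seed
#' @return list with data.frames `train`, `validation`, `test`
#' @export
split_dataset <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(pairs), length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(pairs)
  if (n < 10) stop("need at least 10 pairs to split")
  idx <- with_preserved_rng(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  train <- pairs[idx[seq_len(n_train)], , drop = FALSE]
  validation <- pairs[idx[n_train + seq_len(n_val)], , drop = FALSE]
  test <- pairs[idx[-seq_len(n_train + n_val)], , drop = FALSE]
  seen <- unique(c(train$heavy, validation$heavy))
  test <- test[!(test$heavy %in% seen), , drop = FALSE]
  list(train = train, validation = validation, test = test)
}

#' Training configuration
#'
#' Defaults follow the published protocol: 4 epochs, batch size 64, Adam
#' with default moments, cosine-scheduled learning rate with 5% linear
#' warm-up to a maximum of 1e-4, teacher-forced cross-entropy averaged over
#' non-padding target tokens.
#'
#' @param epochs,batch_size,max_lr,warmup_fraction,seed as described
#' @return an object of class `train_config`
#' @export
train_config <- function(epochs = 4L, batch_size = 64L, max_lr = 1e-4,
                         warmup_fraction = 0.05, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, max_lr > 0,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 max_lr = max_lr, warmup_fraction = warmup_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given optimiser step
#'
#' Linear ramp from 0 to `max_lr` over the first
#' `ceiling(warmup_fraction * total_steps)` steps, then cosine decay from
#' `max_lr` to 0 at `total_steps`; continuous at the junction.
#'
#' @param step step index in `[0, total_steps]`
#' @param total_steps total optimiser steps of the run
#' @param config a [train_config()]
#' @return the learning rate (scalar)
#' @export
lr_at_step <- function(step, total_steps, config = train_config()) {
  if (step < 0 || step > total_steps) stop("step out of [0, total_steps]")
  warmup <- ceiling(config$warmup_fraction * total_steps)
  if (step <= warmup) return(config$max_lr * step / warmup)
  config$max_lr * 0.5 * (1 + cos(pi * (step - warmup) / (total_steps - warmup)))
}

# tokenize a column of sequences once, as a list of id vectors
tokenize_column <- function(seqs, vocab) {
  lapply(seqs, tokenize, vocab = vocab)
}

# pad a list of token vectors into a (B x Lmax) id matrix + length vector
pad_batch <- function(tok_list, pad_id) {
  lens <- lengths(tok_list)
  L <- max(lens)
  m <- matrix(pad_id, nrow = length(tok_list), ncol = L)
  for (i in seq_along(tok_list)) m[i, seq_len(lens[i])] <- tok_list[[i]]
  list(ids = m, lens = as.integer(lens))
}

# one teacher-forced pass over a pair batch; returns the cpp_batch result
batch_pass <- function(model, src_tok, tgt_tok, dropout, seed, want_grads) {
  vocabpad <- 1L
  s <- pad_batch(src_tok, vocabpad)
  tfull <- pad_batch(tgt_tok, vocabpad)
  Lt <- ncol(tfull$ids)
  tin <- tfull$ids[, -Lt, drop = FALSE]
  tout <- tfull$ids[, -1L, drop = FALSE]
  cpp_batch(model$params, unclass(model$config),
            s$ids, s$lens, tin, tout, tfull$lens - 1L,
            dropout, as.integer(seed), want_grads, FALSE)
}

#' Train the model
#'
#' Teacher-forced cross-entropy on light-chain tokens conditioned on the
#' heavy chain, optimised with Adam under the warm-up/cosine schedule.
#' Epoch-level shuffling uses the run seed; the per-epoch train loss is the
#' token-weighted mean over batches, and validation loss is computed with
#' dropout disabled.  A non-finite loss aborts with the offending batch
#' index.  The returned model is the final-epoch model.
#'
#' @param model an `lcgen_model` (its `config$dropout` is used for training)
#' @param train_pairs,val_pairs data.frames with `heavy` and `light` columns
#' @param config a [train_config()]
#' @param checkpoint_dir optional directory; a checkpoint is saved after
#'   every epoch
#' @param vocab token vocabulary
#' @param quiet suppress per-epoch messages
#' @return list with `model` (trained) and `log` (data.frame epoch, split,
#'   loss)
#' @export
train_model <- function(model, train_pairs, val_pairs = NULL,
                        config = train_config(), checkpoint_dir = NULL,
                        vocab = default_vocab(), quiet = FALSE) {
  stopifnot(inherits(model, "lcgen_model"), inherits(config, "train_config"))
  n <- nrow(train_pairs)
  stopifnot(n >= 1)
  src_tok <- tokenize_column(train_pairs$heavy, vocab)
  tgt_tok <- tokenize_column(train_pairs$light, vocab)
  vsrc <- if (!is.null(val_pairs) && nrow(val_pairs))
    tokenize_column(val_pairs$heavy, vocab)
  vtgt <- if (!is.null(val_pairs) && nrow(val_pairs))
    tokenize_column(val_pairs$light, vocab)

  bs <- config$batch_size
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- config$epochs * steps_per_epoch
  params <- model$params
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  log <- list()
  step <- 0L

  with_preserved_rng(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0; tr_tok <- 0
      for (bi in seq_len(steps_per_epoch)) {
        rows <- ord[((bi - 1) * bs + 1):min(bi * bs, n)]
        drop_seed <- sample.int(.Machine$integer.max, 1)
        res <- batch_pass(model, src_tok[rows], tgt_tok[rows],
                          model$config$dropout, drop_seed, TRUE)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
        step <- step + 1L
        lr <- lr_at_step(step, total_steps, config)
        g <- res$grads
        for (nm in names(params)) {
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g[[nm]]
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- m1[[nm]] / (1 - b1^step)
          vhat <- m2[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        model$params <- params
        tr_loss <- tr_loss + res$loss * res$n_tokens
        tr_tok <- tr_tok + res$n_tokens
      }
      log[[length(log) + 1]] <- data.frame(epoch = epoch, split = "train",
                                           loss = tr_loss / tr_tok)
      if (!is.null(vsrc)) {
        vl <- evaluate_loss(model, vsrc, vtgt, bs)
        log[[length(log) + 1]] <- data.frame(epoch = epoch, split = "validation",
                                             loss = vl)
      }
      if (!quiet)
        message(sprintf("epoch %d: train loss %.4f%s", epoch, tr_loss / tr_tok,
                        if (!is.null(vsrc))
                          sprintf(", validation loss %.4f", vl) else ""))
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_checkpoint(model, file.path(checkpoint_dir,
                                         sprintf("epoch%02d.rds", epoch)))
      }
    }
  })
  list(model = model, log = do.call(rbind, log))
}

# token-weighted mean cross-entropy with dropout disabled
evaluate_loss <- function(model, src_tok, tgt_tok, batch_size = 64L) {
  n <- length(src_tok)
  loss <- 0; tok <- 0
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1, n)
    res <- batch_pass(model, src_tok[rows], tgt_tok[rows], 0, 0L, FALSE)
    loss <- loss + res$loss * res$n_tokens
    tok <- tok + res$n_tokens
  }
  loss / tok
}

#' Mean held-out cross-entropy of a model on paired data
#'
#' @param model an `lcgen_model`
#' @param pairs data.frame with `heavy`, `light`
#' @param vocab token vocabulary
#' @return mean per-token negative log-likelihood (nats)
#' @export
dataset_loss <- function(model, pairs, vocab = default_vocab()) {
  evaluate_loss(model, tokenize_column(pairs$heavy, vocab),
                tokenize_column(pairs$light, vocab))
}
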