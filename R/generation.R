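#' Sampling configuration
#'
#' Defaults follow the published inference settings: nucleus (top-p)
#' sampling with `p = 0.9` at temperature 1.0.
#'
#' @param top_p nucleus mass in `(0, 1]`
#' @param temperature softmax temperature (> 0)
#' @param rng_seed integer seed for the draw
#' @param max_len maximum number of generated residues
#' @return an object of class `sampling_config`
#' @export
sampling_config <- function(top_p = 0.9, temperature = 1.0, rng_seed = 1L,
                            max_len = 160L) {
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(top_p = top_p, temperature = temperature,
                 rng_seed = as.integer(rng_seed), max_len = as.integer(max_len)),
            class = "sampling_config")
}

#' Decoding constraints
#'
#' Bundles the optional germline seed and grafted CDRs for constrained
#' decoding.  At most one germline restriction may be given.  When CDR1 and
#' CDR2 are provided without a restriction or explicit seed (and a CDR
#' reference is available), the light-chain type is inferred by BLOSUM62
#' alignment against germline CDRs and used as a type-level seed.
#'
#' @param seed_prefix explicit seed residues (any length; `""` for none)
#' @param restriction `NULL` or `list(level, value)` with level one of
#'   `"type"` (`value` "kappa"/"lambda"), `"v_family"`, `"v_gene"`
#' @param cdr1,cdr2,cdr3 optional CDR sequences to graft
#' @param scheme numbering scheme governing CDR placement ("imgt"/"kabat")
#' @param germline_table a [germline_frequency_table()] (needed for
#'   restriction seeding)
#' @param cdr_reference a [germline_cdr_reference()] (needed for automatic
#'   type inference)
#' @return an object of class `generation_constraints`
#' @export
generation_constraints <- function(seed_prefix = "", restriction = NULL,
                                   cdr1 = NULL, cdr2 = NULL, cdr3 = NULL,
                                   scheme = "imgt", germline_table = NULL,
                                   cdr_reference = NULL) {
  if (nzchar(seed_prefix)) seed_prefix <- validate_aa(seed_prefix, "seed_prefix")
  if (!is.null(restriction)) {
    stopifnot(is.list(restriction), all(c("level", "value") %in% names(restriction)))
    restriction$level <- match.arg(restriction$level,
                                   c("type", "v_family", "v_gene"))
  }
  for (nm in c("cdr1", "cdr2", "cdr3")) {
    v <- get(nm)
    if (!is.null(v)) assign(nm, validate_aa(v, nm))
  }
  structure(list(seed_prefix = seed_prefix, restriction = restriction,
                 cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
                 scheme = tolower(scheme), germline_table = germline_table,
                 cdr_reference = cdr_reference),
            class = "generation_constraints")
}

#' Nucleus (top-p) support of a probability distribution
#'
#' The smallest set of tokens, taken in descending-probability order (ties
#' broken by token id), whose cumulative probability reaches `top_p`; the
#' boundary-crossing token is included.
#'
#' @param probabilities nonnegative vector summing to 1 (within 1e-6)
#' @param top_p nucleus mass in `(0, 1]`
#' @return sorted integer ids of the kept tokens
#' @export
nucleus_support <- function(probabilities, top_p) {
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-6)
    stop("probabilities must be nonnegative and sum to 1")
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]")
  ord <- order(probabilities, decreasing = TRUE)
  cums <- cumsum(probabilities[ord])
  k <- which(cums >= top_p - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  keep <- ord[seq_len(k)]
  if (top_p == 1) keep <- keep[probabilities[keep] > 0]
  sort(keep)
}

#' Scale logits by a sampling temperature
#'
#' Elementwise division; temperature 1 is the identity, and the limit
#' `T -> 0` concentrates all probability on the argmax.
#'
#' @param logits numeric vector
#' @param temperature positive scalar
#' @return scaled logits
#' @export
apply_temperature <- function(logits, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a positive scalar")
  logits / temperature
}

# numerically safe log-softmax / softmax (tolerates -Inf entries)
log_softmax <- function(x) {
  m <- max(x[is.finite(x)])
  x - (m + log(sum(exp(x - m))))
}
softmax <- function(x) {
  m <- max(x[is.finite(x)])
  e <- exp(x - m)
  e / sum(e)
}

#' Draw a germline-frequency-weighted seed prefix
#'
#' Type restrictions seed with the first two residues; V-family and V-gene
#' restrictions with the first ten.  The row is drawn with probability
#' proportional to its frequency weight among the matching rows; uses R's
#' current RNG stream.
#'
#' @param restriction `list(level, value)` as in [generation_constraints()]
#' @param table a [germline_frequency_table()]
#' @return the seed string, with the chosen germline id in attribute
#'   `"source_id"`
#' @export
make_germline_seed <- function(restriction, table) {
  stopifnot(is.list(restriction), is.data.frame(table))
  rows <- switch(restriction$level,
                 type = table[table$type == restriction$value, ],
                 v_family = table[table$family == restriction$value, ],
                 v_gene = table[table$id == restriction$value, ])
  if (!nrow(rows))
    stop("unknown germline restriction: ", restriction$value)
  i <- if (nrow(rows) == 1) 1L else
    sample.int(nrow(rows), 1, prob = rows$weight)
  seed <- if (restriction$level == "type") rows$leading2[i] else rows$leading10[i]
  structure(seed, source_id = rows$id[i])
}

# cached BLOSUM62 matrix from Biostrings
blosum62 <- function() {
  if (is.null(.lcgen_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .lcgen_env$blosum62 <- e$BLOSUM62
  }
  .lcgen_env$blosum62
}

#' Ungapped BLOSUM62 alignment score of two sequences
#'
#' The maximum, over all equal-length sliding windows of the shorter
#' sequence against the longer, of the summed BLOSUM62 substitution scores.
#'
#' @param a,b amino-acid strings
#' @return the best window score (scalar)
#' @export
blosum_align_score <- function(a, b) {
  B <- blosum62()
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  n <- length(ca); m <- length(cb)
  if (n == 0) return(0)
  best <- -Inf
  for (off in 0:(m - n)) {
    s <- sum(B[cbind(ca, cb[(off + 1):(off + n)])])
    if (s > best) best <- s
  }
  best
}

#' Infer kappa vs lambda from CDR sequences
#'
#' Scores each provided CDR against the corresponding germline CDR set of
#' each type with [blosum_align_score()] and returns the type with the
#' higher total best-match score; ties resolve to kappa (the majority
#' class).
#'
#' @param cdr1,cdr2 CDR sequences (at least one non-`NULL`)
#' @param reference a [germline_cdr_reference()]
#' @return `"kappa"` or `"lambda"`
#' @export
infer_chain_type <- function(cdr1 = NULL, cdr2 = NULL, reference) {
  if (is.null(cdr1) && is.null(cdr2))
    stop("at least one of cdr1/cdr2 must be provided")
  if (!all(c("kappa", "lambda") %in% names(reference)))
    stop("reference must contain kappa and lambda germline CDR sets")
  score_type <- function(tp) {
    tot <- 0
    for (slot in c("cdr1", "cdr2")) {
      q <- get(slot)
      refs <- reference[[tp]][[slot]]
      if (!is.null(q) && length(refs))
        tot <- tot + max(vapply(refs, blosum_align_score, 0, a = q))
    }
    tot
  }
  sk <- score_type("kappa"); sl <- score_type("lambda")
  if (sl > sk) "lambda" else "kappa"
}

# ------------------------------------------------------------------
# constrained-decoding state machine
#
# Phases: seed residues are forced first; with CDR1 given, the first
# cysteine emitted in the scheme's window triggers grafting of CDR1 followed
# by the forced tryptophan and the fixed-length FR2; with only CDR2 given,
# FR2 keys off the first tryptophan emitted past the cysteine window; CDR2
# is grafted directly after FR2; with CDR3 given, the first cysteine at a
# structurally plausible FR3-end position triggers grafting of CDR3
# followed by the forced phenylalanine.  The stop token is never forced.
make_constraint_stepper <- function(constraints, tab) {
  queue <- strsplit(constraints$seed_prefix, "", fixed = TRUE)[[1]]
  has1 <- !is.null(constraints$cdr1)
  has2 <- !is.null(constraints$cdr2)
  has3 <- !is.null(constraints$cdr3)
  after_fr2 <- if (has3) "watch_c2" else "free"
  phase <- if (has1) "watch_c1" else if (has2) "watch_w" else
    if (has3) "watch_c2" else "free"
  fr2_left <- 0L
  c2_min <- NA_integer_
  failed <- FALSE
  global_c2_min <- tab$c1_window[1] + tab$cdr1_range[1] + tab$fr2_len +
    tab$cdr2_range[1] + tab$fr3_len

  enter_fr2 <- function() {
    fr2_left <<- tab$fr2_len - 1L
    phase <<- "fr2"
  }
  # grafting foreign CDRs of a different length shifts the model's learned
  # absolute positions, so its FR3-end cysteine may come a residue or two
  # before the nominal fixed-length offset; the trigger uses a minimum
  # distance (as the annotation heuristic does), not an exact one
  fr3_slack <- 2L
  enter_watch_c2 <- function(base_pos) {
    if (has3) {
      c2_min <<- as.integer(base_pos + tab$fr3_len - fr3_slack)
      phase <<- "watch_c2"
    } else phase <<- "free"
  }

  list(
    decide = function(next_pos) {
      if (length(queue)) list(type = "forced", residue = queue[1])
      else list(type = "free")
    },
    observe = function(pos, residue) {
      if (length(queue)) {
        queue <<- queue[-1]
        if (!length(queue)) {
          # a forced block just completed
          if (phase == "watch_c1" || phase == "queue_cdr1") {
            # seed block done, nothing structural
          }
          if (phase == "queue_cdr1") enter_fr2()
          else if (phase == "queue_cdr2") enter_watch_c2(pos)
          else if (phase == "queue_cdr3") phase <<- "free"
        }
        return(invisible(NULL))
      }
      if (phase == "watch_c1") {
        if (residue == "C" && pos >= tab$c1_window[1] && pos <= tab$c1_window[2]) {
          queue <<- c(strsplit(constraints$cdr1, "", fixed = TRUE)[[1]], "W")
          phase <<- "queue_cdr1"
        } else if (pos >= tab$c1_window[2]) {
          failed <<- TRUE
        }
      } else if (phase == "watch_w") {
        if (residue == "W" && pos > tab$c1_window[2]) enter_fr2()
      } else if (phase == "fr2") {
        fr2_left <<- fr2_left - 1L
        if (fr2_left <= 0L) {
          if (has2) {
            queue <<- strsplit(constraints$cdr2, "", fixed = TRUE)[[1]]
            phase <<- "queue_cdr2"
          } else enter_watch_c2(pos + tab$cdr2_range[1])
        }
      } else if (phase == "watch_c2") {
        if (is.na(c2_min)) c2_min <<- as.integer(global_c2_min)
        if (residue == "C" && pos >= c2_min) {
          queue <<- c(strsplit(constraints$cdr3, "", fixed = TRUE)[[1]], "F")
          phase <<- "queue_cdr3"
        }
      }
      invisible(NULL)
    },
    finished = function() !length(queue) && phase %in% c("free"),
    failed = function() failed
  )
}

#' Generate one light chain for a heavy chain
#'
#' Autoregressive decoding: at each step the constraint engine either forces
#' the next residue (seed prefix, grafted CDRs, the conserved tryptophan
#' after CDR1, the phenylalanine after CDR3) or frees the step for
#' temperature-scaled nucleus sampling.  Forced tokens bypass temperature
#' and the nucleus filter, but their model log-probabilities (raw,
#' temperature-1 log-softmax, like all recorded log-probabilities) are kept
#' for scoring.  Decoding ends at the stop token or at the length cap, and
#' every output is validated with [annotate_regions()].
#'
#' @param model a trained `lcgen_model`
#' @param heavy heavy-chain amino-acid sequence
#' @param constraints a [generation_constraints()]
#' @param sampling a [sampling_config()]
#' @param vocab token vocabulary
#' @return an object of class `generation_result`: `light`,
#'   `per_token_logprob` (one entry per residue plus the stop token),
#'   `constrained_mask`, `seed_used`, and flags `failed` (a required anchor
#'   never appeared, or decoding ended with constraints pending),
#'   `truncated` (no stop before the cap) and `valid` (annotatable output)
#' @export
generate_light <- function(model, heavy, constraints = generation_constraints(),
                           sampling = sampling_config(),
                           vocab = default_vocab()) {
  tab <- scheme_table(constraints$scheme)
  src <- tokenize(heavy, vocab)
  max_res <- min(sampling$max_len, model$config$max_len - 2L)

  with_preserved_rng(sampling$rng_seed, {
    seed_prefix <- constraints$seed_prefix
    if (!nzchar(seed_prefix) && !is.null(constraints$restriction)) {
      if (is.null(constraints$germline_table))
        stop("a germline_table is required for restriction seeding")
      seed_prefix <- make_germline_seed(constraints$restriction,
                                        constraints$germline_table)
    } else if (!nzchar(seed_prefix) && is.null(constraints$restriction) &&
               !is.null(constraints$cdr1) && !is.null(constraints$cdr2) &&
               !is.null(constraints$cdr_reference) &&
               !is.null(constraints$germline_table)) {
      tp <- infer_chain_type(constraints$cdr1, constraints$cdr2,
                             constraints$cdr_reference)
      seed_prefix <- make_germline_seed(list(level = "type", value = tp),
                                        constraints$germline_table)
    }
    local_constraints <- constraints
    local_constraints$seed_prefix <- as.character(seed_prefix)
    stepper <- make_constraint_stepper(local_constraints, tab)

    ptr <- cpp_decoder_init(model$params, unclass(model$config), src)
    logits <- cpp_decoder_step(ptr, vocab$start_id)
    emitted <- character(0)
    lps <- numeric(0)
    mask <- logical(0)
    failed <- FALSE
    truncated <- FALSE
    repeat {
      pos <- length(emitted) + 1L
      act <- stepper$decide(pos)
      ll <- log_softmax(logits)
      if (act$type == "forced") {
        tok <- unname(vocab$index[act$residue])
        forced <- TRUE
      } else {
        tok <- sample_next_token(logits, vocab, sampling)
        forced <- FALSE
      }
      lps <- c(lps, ll[tok])
      if (tok == vocab$stop_id) {
        if (!stepper$finished()) failed <- TRUE
        break
      }
      emitted <- c(emitted, vocab$tokens[tok])
      mask <- c(mask, forced)
      stepper$observe(pos, vocab$tokens[tok])
      if (stepper$failed()) {
        failed <- TRUE
        break
      }
      if (length(emitted) >= max_res) {
        truncated <- TRUE
        if (!stepper$finished()) failed <- TRUE
        break
      }
      logits <- cpp_decoder_step(ptr, tok)
    }
    light <- paste(emitted, collapse = "")
    ann <- if (!failed && nzchar(light))
      annotate_regions(light, constraints$scheme)
    structure(list(
      light = light,
      per_token_logprob = lps,
      constrained_mask = mask,
      seed_used = as.character(seed_prefix),
      failed = failed,
      truncated = truncated,
      valid = !failed && !is.null(ann),
      annotation = ann
    ), class = "generation_result")
  })
}

# one free sampling step: restrict support to residues + stop, apply
# temperature, nucleus-filter, renormalise, draw
sample_next_token <- function(logits, vocab, sampling) {
  lg <- logits
  lg[setdiff(seq_len(vocab$size), vocab$sample_ids)] <- -Inf
  p <- softmax(apply_temperature(lg, sampling$temperature))
  keep <- nucleus_support(p, sampling$top_p)
  pk <- p[keep] / sum(p[keep])
  keep[sample.int(length(keep), 1, prob = pk)]
}

#' @export
print.generation_result <- function(x, ...) {
  cat(sprintf("generation_result: %s%s\n  %s\n",
              if (x$failed) "FAILED" else if (x$valid) "valid" else "invalid",
              if (x$truncated) " (truncated)" else "",
              x$light))
  invisible(x)
}

#' Generate a batch of light chains
#'
#' `n` independent draws with per-draw seeds derived deterministically from
#' the master seed in `sampling$rng_seed`; order-stable.
#'
#' @inheritParams generate_light
#' @param n number of sequences (>= 1)
#' @return list of `generation_result`
#' @export
generate_batch <- function(model, heavy, n = 20L,
                           constraints = generation_constraints(),
                           sampling = sampling_config(),
                           vocab = default_vocab()) {
  stopifnot(n >= 1)
  seeds <- with_preserved_rng(sampling$rng_seed,
                              sample.int(.Machine$integer.max, n))
  lapply(seq_len(n), function(i) {
    s <- sampling
    s$rng_seed <- seeds[i]
    generate_light(model, heavy, constraints, s, vocab)
  })
}
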