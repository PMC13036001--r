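#' Model configuration
#'
#' Hyperparameters of the encoder-decoder next-token model.  The defaults are
#' the published full-scale configuration: 6 encoder and 6 decoder layers,
#' 8 attention heads, embedding and feed-forward width 512, dropout 0.1,
#' fixed sinusoidal positional encoding, and a 24-token vocabulary (padding,
#' start, stop, 20 amino acids, one reserved token) -- the unique vocabulary
#' size for which the architecture's trainable parameter count equals
#' 25,284,632 (see [resolve_vocab_layout()]).
#'
#' @param n_encoder_layers,n_decoder_layers number of layers per stack
#' @param n_heads attention heads; must divide `d_model`
#' @param d_model embedding / hidden width
#' @param d_feedforward feed-forward inner width
#' @param dropout dropout fraction in `[0, 1)`
#' @param vocab_size token vocabulary size (>= 22)
#' @param max_len maximum tokenized sequence length
#' @return an object of class `model_config`
#' @export
model_config <- function(n_encoder_layers = 6L, n_decoder_layers = 6L,
                         n_heads = 8L, d_model = 512L, d_feedforward = 512L,
                         dropout = 0.1, vocab_size = 24L, max_len = 200L) {
  cfg <- list(
    n_encoder_layers = as.integer(n_encoder_layers),
    n_decoder_layers = as.integer(n_decoder_layers),
    n_heads = as.integer(n_heads),
    d_model = as.integer(d_model),
    d_feedforward = as.integer(d_feedforward),
    dropout = dropout,
    vocab_size = as.integer(vocab_size),
    max_len = as.integer(max_len)
  )
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$vocab_size < 22L) stop("vocab_size must be at least 22")
  if (any(unlist(cfg[c(1, 2, 3, 4, 5, 8)]) < 1L)) stop("invalid config value")
  class(cfg) <- "model_config"
  cfg
}

# named list of tensor dimensions; the single source of truth for the
# parameter layout (used by initialisation, counting, and the C++ core,
# whose parse_params expects exactly these names)
param_shapes <- function(config) {
  d <- config$d_model; ff <- config$d_feedforward; V <- config$vocab_size
  shp <- list(src_emb = c(V, d), tgt_emb = c(V, d))
  attn <- function(pre) {
    s <- list(c(d, d), d, c(d, d), d, c(d, d), d, c(d, d), d)
    names(s) <- paste0(pre, c("wq", "bq", "wk", "bk", "wv", "bv", "wo", "bo"))
    s
  }
  block <- function(pre) {
    s <- list(c(ff, d), ff, c(d, ff), d)
    names(s) <- paste0(pre, c("ff_w1", "ff_b1", "ff_w2", "ff_b2"))
    s
  }
  lns <- function(pre, k) {
    s <- rep(list(d), 2 * k)
    names(s) <- paste0(pre, "ln", rep(seq_len(k), each = 2), "_", c("g", "b"))
    s
  }
  for (i in seq_len(config$n_encoder_layers)) {
    pre <- sprintf("enc%d_", i)
    shp <- c(shp, attn(pre), block(pre), lns(pre, 2L))
  }
  for (i in seq_len(config$n_decoder_layers)) {
    pre <- sprintf("dec%d_", i)
    shp <- c(shp, attn(paste0(pre, "self_")), attn(paste0(pre, "cross_")),
             block(pre), lns(pre, 3L))
  }
  shp <- c(shp,
           list(enc_norm_g = d, enc_norm_b = d, dec_norm_g = d, dec_norm_b = d,
                out_w = c(V, d), out_b = V))
  shp
}

#' Build a model with Xavier-normal initial weights
#'
#' All weight matrices (including the embeddings and the output projection)
#' are drawn from a zero-mean normal with variance `2 / (fan_in + fan_out)`
#' (Glorot initialisation); biases start at zero and layer-norm gains at one.
#' Reproducible for a fixed seed, without disturbing the caller's RNG state.
#'
#' @param config a [model_config()]
#' @param rng_seed integer seed
#' @return an object of class `lcgen_model` with elements `config` and
#'   `params` (named list of matrices/vectors)
#' @export
build_model <- function(config = model_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  shapes <- param_shapes(config)
  params <- with_preserved_rng(rng_seed, {
    lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (length(dm) == 2L) {
        sd <- sqrt(2 / (dm[1] + dm[2]))
        matrix(rnorm(prod(dm), 0, sd), nrow = dm[1], ncol = dm[2])
      } else if (grepl("(ln[0-9]+_g|norm_g)$", nm)) {
        rep(1, dm)
      } else {
        rep(0, dm)
      }
    })
  })
  names(params) <- names(shapes)
  structure(list(config = config, params = params), class = "lcgen_model")
}

# run expr with a locally seeded RNG, restoring the caller's stream after
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.lcgen_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "lcgen_model: %d+%d layers, %d heads, d_model %d, d_ff %d, vocab %d (%s trainable parameters)\n",
    cfg$n_encoder_layers, cfg$n_decoder_layers, cfg$n_heads, cfg$d_model,
    cfg$d_feedforward, cfg$vocab_size,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Brute-force enumeration: the sum of the sizes of every parameter tensor.
#' [param_count_formula()] gives the equivalent closed form.
#'
#' @param model an `lcgen_model`
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "lcgen_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Closed-form trainable parameter count
#'
#' For width `d`, feed-forward width `f`, vocabulary `V`, `E` encoder and
#' `D` decoder layers:
#' \deqn{2 V d + E (4d^2 + 4d + 2df + f + d + 4d) +
#'       D (8d^2 + 8d + 2df + f + d + 6d) + 2 \cdot 2d + V d + V}
#' i.e. separate source/target embeddings; per layer one (encoder) or two
#' (decoder) attention blocks of `4(d^2 + d)`, a feed-forward pair
#' `df + f + fd + d`, and `2d` per layer norm (two in encoder layers, three
#' in decoder layers); a final layer norm per stack; and an untied output
#' projection with bias.
#'
#' @param config a [model_config()]
#' @return the parameter count implied by the architecture
#' @export
param_count_formula <- function(config) {
  d <- config$d_model; f <- config$d_feedforward; V <- config$vocab_size
  E <- config$n_encoder_layers; D <- config$n_decoder_layers
  attn <- 4 * d^2 + 4 * d
  ffwd <- d * f + f + f * d + d
  enc_layer <- attn + ffwd + 2 * (2 * d)
  dec_layer <- 2 * attn + ffwd + 3 * (2 * d)
  2 * V * d + E * enc_layer + D * dec_layer + 2 * (2 * d) + V * d + V
}

#' Resolve the vocabulary / projection layout from the published total
#'
#' The published architecture states the layer counts, width, and the total
#' of 25,284,632 trainable parameters, but not the vocabulary size or
#' whether embeddings/projection are tied.  This exhaustive search over
#' vocabulary sizes 21-32 x {tied, separate} source/target embeddings x
#' {tied, untied} output projection x {with, without} projection bias x
#' {with, without} final per-stack layer norms finds all combinations whose
#' count matches a target total for the 6+6-layer, d = 512 configuration.
#'
#' @param target total parameter count to match
#' @param d,f,E,D architecture dimensions searched under
#' @return data.frame of matching layouts (one row expected:
#'   vocab 24, separate embeddings, untied projection with bias, final norms)
#' @export
resolve_vocab_layout <- function(target = 25284632, d = 512, f = 512, E = 6, D = 6) {
  attn <- 4 * d^2 + 4 * d
  ffwd <- d * f + f + f * d + d
  grid <- expand.grid(vocab = 21:32, tied_emb = c(TRUE, FALSE),
                      tied_proj = c(TRUE, FALSE), proj_bias = c(TRUE, FALSE),
                      final_norms = c(TRUE, FALSE))
  grid$count <- with(grid, {
    stack <- E * (attn + ffwd + 4 * d) + D * (2 * attn + ffwd + 6 * d) +
      ifelse(final_norms, 2 * (2 * d), 0)
    emb <- ifelse(tied_emb, vocab * d, 2 * vocab * d)
    proj <- ifelse(tied_proj, 0, vocab * d) + ifelse(proj_bias, vocab, 0)
    stack + emb + proj
  })
  grid[grid$count == target, , drop = FALSE]
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d))` and entry `(pos, 2i + 1)`
#' is `cos(pos / 10000^(2i/d))`, with `pos` and `i` counted from zero.
#'
#' @param length number of positions (>= 1)
#' @param d_model encoding width
#' @return a `length` x `d_model` matrix
#' @export
positional_encoding <- function(length, d_model) {
  if (length < 1) stop("length must be >= 1")
  cpp_positional_encoding(as.integer(length), as.integer(d_model))
}

#' Teacher-forced logits for every decoder position
#'
#' Generic over model-like objects so that analytic stub models can stand in
#' for the network in tests and documentation.  Dropout is disabled:
#' inference is deterministic.
#'
#' @param model a model object
#' @param src_ids tokenized source (heavy) sequence, `[start, ..., stop]`
#' @param tgt_in_ids decoder input ids, beginning with the start token
#' @return a `length(tgt_in_ids)` x `vocab_size` matrix; row `t` holds the
#'   logits for the token following `tgt_in_ids[1:t]`
#' @export
model_logits <- function(model, src_ids, tgt_in_ids) UseMethod("model_logits")

#' @export
model_logits.lcgen_model <- function(model, src_ids, tgt_in_ids) {
  stopifnot(length(src_ids) >= 2L, length(tgt_in_ids) >= 1L)
  res <- cpp_batch(model$params, unclass(model$config),
                   matrix(as.integer(src_ids), nrow = 1),
                   length(src_ids),
                   matrix(as.integer(tgt_in_ids), nrow = 1),
                   matrix(as.integer(tgt_in_ids), nrow = 1),
                   length(tgt_in_ids),
                   0, 0L, FALSE, TRUE)
  res$logits
}

#' Next-token logits given a heavy chain and a light-chain prefix
#'
#' @param model a model object
#' @param heavy_tokens tokenized heavy sequence (`[start, ..., stop]`)
#' @param light_prefix_tokens decoder prefix, beginning with the start token
#' @return numeric vector of `vocab_size` logits for the next token
#' @export
next_token_logits <- function(model, heavy_tokens, light_prefix_tokens) {
  if (length(light_prefix_tokens) < 1L)
    stop("the prefix must contain at least the start token")
  lg <- model_logits(model, heavy_tokens, light_prefix_tokens)
  lg[nrow(lg), ]
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration and the named
#' parameter tensors.  The loader validates every tensor shape against the
#' configuration and rejects mismatches.
#'
#' @param model an `lcgen_model`
#' @param path file path
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "lcgen_model"))
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `lcgen_model`
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !all(c("config", "params") %in% names(obj)))
    stop("not a model checkpoint: ", path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  shapes <- param_shapes(cfg)
  if (!identical(sort(names(obj$params)), sort(names(shapes))))
    stop("checkpoint parameter names do not match the configuration")
  for (nm in names(shapes)) {
    want <- shapes[[nm]]
    got <- obj$params[[nm]]
    ok <- if (length(want) == 2L) {
      is.matrix(got) && all(dim(got) == want)
    } else {
      is.numeric(got) && !is.matrix(got) && length(got) == want
    }
    if (!ok) stop("checkpoint tensor shape mismatch for ", nm)
  }
  structure(list(config = cfg, params = obj$params[names(shapes)]),
            class = "lcgen_model")
}
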