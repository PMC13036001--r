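test_that("Xavier-normal initialisation has the Glorot variance", {
  m <- build_model(model_config(), 1)
  w <- m$params$enc1_wq  # 512 x 512
  expect_lt(abs(var(as.vector(w)) - 2 / 1024) / (2 / 1024), 0.10)
  expect_equal(mean(as.vector(w)), 0, tolerance = 5e-4)
  # biases zero, layer-norm gains one
  expect_true(all(m$params$enc1_bq == 0))
  expect_true(all(m$params$enc1_ln1_g == 1))
})

test_that("initialisation is reproducible per seed and varies across seeds", {
  cfg <- model_config(n_encoder_layers = 1, n_decoder_layers = 1, n_heads = 2,
                      d_model = 16, d_feedforward = 16)
  expect_identical(build_model(cfg, 5)$params, build_model(cfg, 5)$params)
  a <- build_model(cfg, 1)$params
  b <- build_model(cfg, 2)$params
  expect_true(any(mapply(function(x, y) any(x != y), a, b)))
})

test_that("closed-form parameter count equals brute-force enumeration", {
  set.seed(10)
  for (i in 1:20) {
    h <- sample(c(1, 2, 4), 1)
    cfg <- model_config(n_encoder_layers = sample(1:3, 1),
                        n_decoder_layers = sample(1:3, 1),
                        n_heads = h, d_model = h * sample(2:6, 1),
                        d_feedforward = sample(2:12, 1),
                        vocab_size = sample(22:32, 1))
    m <- build_model(cfg, i)
    expect_identical(count_parameters(m), param_count_formula(cfg))
  }
})

test_that("doubling the vocabulary changes the count by the embedding+projection delta", {
  cfg1 <- model_config(n_encoder_layers = 1, n_decoder_layers = 1, n_heads = 2,
                       d_model = 8, d_feedforward = 8, vocab_size = 24L)
  cfg2 <- model_config(n_encoder_layers = 1, n_decoder_layers = 1, n_heads = 2,
                       d_model = 8, d_feedforward = 8, vocab_size = 48L)
  delta <- count_parameters(build_model(cfg2, 1)) -
    count_parameters(build_model(cfg1, 1))
  # two embeddings + projection weight: 3 * d per vocab entry, + 1 bias each
  expect_identical(delta, 24 * (3 * 8 + 1))
})

test_that("the published-total layout search has a unique solution", {
  hit <- resolve_vocab_layout()
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$vocab, 24L)
  expect_false(hit$tied_emb)
  expect_false(hit$tied_proj)
  expect_true(hit$proj_bias)
  expect_true(hit$final_norms)
})

test_that("positional encoding matches the sinusoidal formula", {
  pe <- positional_encoding(20, 16)
  expect_equal(pe[1, ], rep(c(0, 1), 8))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  # full formula, recomputed independently in R
  ref <- outer(0:19, 0:15, function(pos, i) {
    ang <- pos / 10000^((i - i %% 2) / 16)
    ifelse(i %% 2 == 0, sin(ang), cos(ang))
  })
  expect_equal(pe, ref, tolerance = 1e-12)
})

test_that("next-token distributions normalise and depend on the heavy chain", {
  m <- micro_model()
  v <- default_vocab()
  set.seed(2)
  for (i in 1:20) {
    heavy <- random_aa(1, sample(50:80, 1))
    prefix <- tokenize(random_aa(1, sample(5:40, 1)), v)
    prefix <- prefix[-length(prefix)]
    lg <- next_token_logits(m, tokenize(heavy, v), prefix)
    expect_true(all(is.finite(lg)))
    p <- exp(lg - max(lg)); p <- p / sum(p)
    expect_lt(abs(sum(p) - 1), 1e-6)
  }
  h1 <- random_aa(1, 60)
  h2 <- paste(rev(strsplit(h1, "")[[1]]), collapse = "")
  p <- tokenize("ACDEF", v)[1:5]
  expect_gt(max(abs(next_token_logits(m, tokenize(h1, v), p) -
                    next_token_logits(m, tokenize(h2, v), p))), 1e-6)
})

test_that("stepwise decoding reproduces teacher-forced logits", {
  m <- micro_model()
  v <- default_vocab()
  heavy <- tokenize(random_aa(1, 40), v)
  tgt_in <- tokenize(random_aa(1, 25), v)
  tgt_in <- tgt_in[-length(tgt_in)]
  tf <- model_logits(m, heavy, tgt_in)
  ptr <- lcgen:::cpp_decoder_init(m$params, unclass(m$config), heavy)
  stepwise <- t(vapply(tgt_in, function(tok)
    lcgen:::cpp_decoder_step(ptr, tok), numeric(v$size)))
  expect_lt(max(abs(tf - stepwise)), 1e-4)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(n_encoder_layers = 1, n_decoder_layers = 1, n_heads = 2,
                      d_model = 8, d_feedforward = 8, dropout = 0, max_len = 30)
  m <- build_model(cfg, 7)
  src <- rbind(c(2, 5, 6, 7, 3, 1), c(2, 8, 9, 3, 1, 1))
  slen <- c(5L, 4L)
  tfull <- rbind(c(2, 6, 7, 8, 3), c(2, 9, 10, 3, 1))
  tin <- tfull[, 1:4]; tout <- tfull[, 2:5]; tlen <- c(4L, 3L)
  loss_at <- function(params)
    lcgen:::cpp_batch_dbl(params, unclass(cfg), src, slen, tin, tout, tlen,
                          0, 1L, FALSE, FALSE)$loss
  res <- lcgen:::cpp_batch_dbl(m$params, unclass(cfg), src, slen, tin, tout,
                               tlen, 0, 1L, TRUE, FALSE)
  g <- res$grads
  eps <- 1e-6
  set.seed(4)
  for (nm in names(m$params)) {
    i <- sample(length(m$params[[nm]]), 1)
    up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})

test_that("gradient reaches every parameter tensor", {
  cfg <- model_config(n_encoder_layers = 2, n_decoder_layers = 2, n_heads = 2,
                      d_model = 8, d_feedforward = 8, dropout = 0, max_len = 30)
  m <- build_model(cfg, 9)
  src <- matrix(c(2, 5, 6, 7, 3), nrow = 1)
  tfull <- matrix(c(2, 6, 7, 8, 3), nrow = 1)
  res <- lcgen:::cpp_batch(m$params, unclass(cfg), src, 5L,
                           tfull[, 1:4, drop = FALSE],
                           tfull[, 2:5, drop = FALSE], 4L, 0, 1L, TRUE, FALSE)
  for (nm in names(res$grads)) {
    # key biases receive exactly zero gradient by softmax shift invariance
    if (grepl("_bk$", nm)) next
    expect_gt(max(abs(res$grads[[nm]])), 0, label = sprintf("grad of %s", nm))
  }
})

test_that("checkpoints round-trip and reject shape mismatches", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  m <- micro_model()
  save_checkpoint(m, tmp)
  back <- load_checkpoint(tmp)
  expect_equal(back$params, m$params)
  expect_identical(unclass(back$config), unclass(m$config))
  bad <- list(config = unclass(m$config), params = m$params)
  bad$params$out_w <- bad$params$out_w[, -1]
  saveRDS(bad, tmp)
  expect_error(load_checkpoint(tmp), "shape mismatch")
})
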