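test_that("uniform stub gives the closed-form likelihood and perplexity", {
  stub <- uniform_stub_model()  # 21 effective tokens: 20 residues + stop
  light <- random_aa(1, 50)
  ll <- sequence_loglik(stub, random_aa(1, 60), light)
  expect_equal(ll$total, -(50 + 1) * log(21))
  expect_equal(ll$total, sum(ll$per_token), tolerance = 1e-6)
  expect_equal(perplexity(stub, random_aa(1, 60), light), 21)
  # encoder-blind: identical for any heavy input
  expect_identical(perplexity(stub, "", light),
                   perplexity(stub, random_aa(1, 80), light))
  smaller <- uniform_stub_model(support_ids = c(3L, 4:8))  # stop + 5 residues
  expect_equal(perplexity(smaller, "", "ACDEF"), 6)
})

test_that("perplexity and log-likelihood are mutually consistent", {
  m <- micro_model()
  set.seed(3)
  for (i in 1:5) {
    heavy <- random_aa(1, sample(40:70, 1))
    light <- random_aa(1, sample(30:60, 1))
    ll <- sequence_loglik(m, heavy, light)
    expect_equal(ll$total, sum(ll$per_token), tolerance = 1e-9)
    expect_identical(ll$n_tokens, nchar(light) + 1L)
    expect_equal(perplexity(m, heavy, light),
                 exp(-ll$total / ll$n_tokens), tolerance = 1e-12)
    expect_gt(perplexity(m, heavy, light), 0)
  }
})

test_that("unconditional scoring is empty-heavy scoring by construction", {
  m <- micro_model()
  light <- random_aa(1, 40)
  expect_identical(unconditional_loglik(m, light),
                   sequence_loglik(m, "", light)$total)
  expect_true(is.finite(unconditional_loglik(m, light)))
})

test_that("pairing preference is zero at identity, antisymmetric, bounded", {
  m <- micro_model()
  h <- random_aa(1, 60)
  l1 <- random_aa(1, 45)
  l2 <- random_aa(1, 52)
  expect_identical(pairing_preference(m, h, l1, l1)$value, 0)
  ab <- pairing_preference(m, h, l1, l2)
  ba <- pairing_preference(m, h, l2, l1)
  expect_equal(ab$value, -ba$value, tolerance = 1e-12)
  # bounded even for extreme length mismatch (log-space implementation)
  long <- random_aa(1, 150)
  short <- random_aa(1, 5)
  v <- pairing_preference(m, h, long, short)$value
  expect_gte(v, -1); expect_lte(v, 1)
})

test_that("pairing preference matches hand arithmetic on model probabilities", {
  m <- micro_model()
  h <- random_aa(1, 50)
  l1 <- random_aa(1, 30)
  l2 <- random_aa(1, 33)
  la <- sequence_loglik(m, h, l1)$total - unconditional_loglik(m, l1)
  lb <- sequence_loglik(m, h, l2)$total - unconditional_loglik(m, l2)
  got <- pairing_preference(m, h, l1, l2)
  expect_equal(got$value, tanh((la - lb) / 2), tolerance = 1e-12)
  # (a - b) / (a + b) form agrees where exponentials are representable
  a <- exp(la); b <- exp(lb)
  expect_equal(got$value, (a - b) / (a + b), tolerance = 1e-9)
})

test_that("greedy decoding maximises every stepwise choice", {
  fx <- reference_fixture()
  heavy <- fx$splits$test$heavy[6]
  v <- default_vocab()
  greedy <- generate_light(fx$model, heavy,
                           sampling = sampling_config(top_p = 1,
                                                      temperature = 1e-9,
                                                      rng_seed = 1))
  # every emitted token is the argmax of the model's distribution over the
  # sampleable support at its step (the defining property of the T -> 0,
  # top-p = 1 limit; greedy is stepwise-optimal, not sequence-level MAP)
  tgt <- tokenize(greedy$light, v)
  lg <- model_logits(fx$model, tokenize(heavy, v), tgt[-length(tgt)])
  tout <- tgt[-1]
  for (t in seq_along(tout)) {
    z <- lg[t, ]
    z[setdiff(seq_len(v$size), v$sample_ids)] <- -Inf
    expect_identical(which.max(z), tout[t])
  }
  # stepwise optimality makes greedy beat typical samples in aggregate
  alts <- generate_batch(fx$model, heavy, n = 50,
                         sampling = sampling_config(rng_seed = 55))
  score <- function(l) sequence_loglik(fx$model, heavy, l)$total
  expect_gt(score(greedy$light),
            mean(vapply(alts, function(g) score(g$light), 0)))
})

test_that("germline reversion restores exactly the planted V/J mutations", {
  ds <- stats_dataset()
  lset <- light_germline_set(ds$repertoire)
  n_checked <- 0
  for (i in seq_len(nrow(ds$pairs))) {
    if (n_checked >= 10) break
    tr <- ds$truth[i, ]
    if (tr$n_mut_light < 3 || tr$n_mut_light > 15) next
    ann <- truth_annotation(ds$pairs$light[i], tr$light_germ)
    rv <- germline_revert(ds$pairs$light[i], lset, ann)
    expect_false(is.na(rv))
    expect_identical(attr(rv, "v_id"), tr$light_v)
    expect_identical(attr(rv, "j_id"), tr$light_j)
    # every germline-encoded position restored; junction left untouched
    v_end <- ann$boundaries["FR3", "end"]
    jlen <- nchar(Find(function(r) r$id == tr$light_j, lset$j)$seq)
    L <- nchar(ds$pairs$light[i])
    germ_cov <- c(seq_len(v_end), (L - jlen + 1):L)
    pos <- as.integer(strsplit(tr$light_mut_pos, ",")[[1]])
    expected <- strsplit(ds$pairs$light[i], "")[[1]]
    gch <- strsplit(tr$light_germ, "")[[1]]
    expected[intersect(pos, germ_cov)] <- gch[intersect(pos, germ_cov)]
    expect_identical(as.character(rv), paste(expected, collapse = ""))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("germline reversion is an idempotent fixed point on germlines", {
  ds <- stats_dataset()
  lset <- light_germline_set(ds$repertoire)
  germ <- lset$v[[1]]$exemplar
  rv <- germline_revert(germ, lset)
  expect_identical(as.character(rv), germ)
  mut <- ds$pairs$light[which(ds$truth$n_mut_light %in% 3:12)[1]]
  once <- germline_revert(mut, lset)
  twice <- germline_revert(as.character(once), lset)
  expect_identical(as.character(twice), as.character(once))
})

test_that("reversion flags chains without a close germline", {
  ds <- stats_dataset()
  lset <- light_germline_set(ds$repertoire)
  germ <- lset$v[[1]]$exemplar
  ann <- annotate_regions(germ)
  # mutate well past 50% of the V span, avoiding the anchor residues
  chars <- strsplit(germ, "")[[1]]
  v_end <- ann$boundaries["FR3", "end"]
  anchors <- c(ann$boundaries["FR1", "end"], ann$boundaries["FR2", "start"],
               v_end, ann$boundaries["FR4", "start"])
  set.seed(8)
  idx <- setdiff(seq_len(v_end), anchors)
  for (p in idx[seq_len(floor(0.7 * length(idx)))])
    chars[p] <- sample(setdiff(AA_ALPHABET, c(chars[p], "C", "W")), 1)
  far <- paste(chars, collapse = "")
  rv <- germline_revert(far, lset, annotate_regions(far, germline_hint = ann))
  expect_true(is.na(rv))
  expect_match(attr(rv, "reason"), "50%")
})
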