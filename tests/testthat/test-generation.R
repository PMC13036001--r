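# independent brute-force oracle: smallest prefix of the descending-order
# distribution whose cumulative mass reaches p
nucleus_oracle <- function(p, top_p) {
  ord <- order(p, decreasing = TRUE)
  for (k in seq_along(ord)) {
    if (sum(p[ord[seq_len(k)]]) >= top_p - 1e-12) return(sort(ord[seq_len(k)]))
  }
  sort(ord)
}

test_that("nucleus support equals the brute-force definition", {
  expect_identical(nucleus_support(c(0.5, 0.3, 0.15, 0.05), 0.9), c(1L, 2L, 3L))
  expect_identical(nucleus_support(c(0, 1, 0), 0.5), 2L)
  expect_identical(nucleus_support(c(0.2, 0, 0.8), 1.0), c(1L, 3L))
  set.seed(6)
  for (i in 1:200) {
    p <- rexp(24); p <- p / sum(p)
    tp <- runif(1, 0.05, 1)
    expect_identical(nucleus_support(p, tp), nucleus_oracle(p, tp))
  }
  expect_error(nucleus_support(c(0.5, 0.6), 0.9), "sum to 1")
})

test_that("temperature scaling behaves at 1, at 2, and in the greedy limit", {
  lg <- c(2, 0)
  expect_identical(apply_temperature(lg, 1), lg)
  p2 <- exp(apply_temperature(lg, 2)); p2 <- p2 / sum(p2)
  expect_equal(p2[1] / p2[2], exp(1))
  tiny <- exp((apply_temperature(lg, 1e-9) - max(apply_temperature(lg, 1e-9))))
  expect_equal(tiny / sum(tiny), c(1, 0))
  expect_error(apply_temperature(lg, 0), "positive")
})

test_that("germline seeds have the right length and frequency weighting", {
  rep <- build_default_repertoire()
  tab <- germline_frequency_table(rep)
  one <- tab[tab$id == tab$id[1], ]
  set.seed(1)
  s <- make_germline_seed(list(level = "v_gene", value = one$id[1]), tab)
  expect_identical(as.character(s), one$leading10[1])
  expect_identical(attr(s, "source_id"), one$id[1])
  s2 <- make_germline_seed(list(level = "v_family", value = tab$family[1]), tab)
  expect_identical(nchar(as.character(s2)), 10L)
  s3 <- make_germline_seed(list(level = "type", value = "lambda"), tab)
  expect_identical(nchar(as.character(s3)), 2L)
  expect_identical(substr(as.character(s3), 1, 2), "QS")
  expect_error(make_germline_seed(list(level = "v_gene", value = "nope"), tab),
               "unknown germline")

  # 3:1 weights respected within 5 percentage points over 10,000 draws
  toy <- data.frame(id = c("g1", "g2"), type = "kappa", family = c("f1", "f2"),
                    leading2 = "DI", leading10 = c("AAAAAAAAAA", "GGGGGGGGGG"),
                    weight = c(3, 1))
  set.seed(2)
  draws <- replicate(10000, attr(make_germline_seed(
    list(level = "type", value = "kappa"), toy), "source_id"))
  expect_lt(abs(mean(draws == "g1") - 0.75), 0.05)
})

test_that("chain-type inference uses BLOSUM62 best-window scores", {
  B <- lcgen:::blosum62()
  expect_identical(unname(B["Q", "Q"] + B["S", "S"] + B["W", "W"]), 20L)
  expect_equal(blosum_align_score("QSW", "QSW"), 20)
  ref <- list(kappa = list(cdr1 = c("QSISSY", "RASQGI"), cdr2 = c("AAS")),
              lambda = list(cdr1 = c("GGNNIG"), cdr2 = c("DDS")))
  expect_identical(infer_chain_type("QSISSY", NULL, ref), "kappa")
  expect_identical(infer_chain_type(NULL, "DDS", ref), "lambda")
  sym <- list(kappa = ref$kappa, lambda = ref$kappa)
  expect_identical(infer_chain_type("QSISSY", "AAS", sym), "kappa")
  expect_error(infer_chain_type(NULL, NULL, ref), "at least one")
})

test_that("constrained decoding grafts CDRs on the conserved anchors", {
  fx <- reference_fixture()
  sp <- fx$splits
  j <- 1
  ann <- truth_annotation(sp$test$light[j], fx$test_truth$light_germ[j])
  regs <- region_sequences(sp$test$light[j], ann)
  con <- generation_constraints(cdr1 = regs[["CDR1"]], cdr2 = regs[["CDR2"]],
                                cdr3 = regs[["CDR3"]])
  fr2 <- scheme_table("imgt")$fr2_len
  nfail <- 0
  for (i in 1:10) {
    g <- generate_light(fx$model, sp$test$heavy[j], con,
                        sampling_config(rng_seed = 100 + i))
    if (g$failed) { nfail <- nfail + 1; next }
    expect_true(grepl(paste0(regs[["CDR1"]], "W"), g$light, fixed = TRUE))
    expect_true(grepl(paste0("C", regs[["CDR3"]], "F"), g$light, fixed = TRUE))
    # FR2 distance contract: CDR2 starts exactly fr2_len after CDR1's end
    p1 <- regexpr(paste0(regs[["CDR1"]], "W"), g$light, fixed = TRUE)
    w_pos <- as.integer(p1) + nchar(regs[["CDR1"]])
    p2 <- regexpr(regs[["CDR2"]], g$light, fixed = TRUE)
    expect_identical(as.integer(p2) - w_pos, fr2)
    # grafted residues and the forced tryptophan are flagged in the mask
    expect_identical(length(g$constrained_mask), nchar(g$light))
    expect_true(all(g$constrained_mask[seq.int(p1, w_pos)]))
    expect_true(all(g$constrained_mask[seq.int(p2, p2 + nchar(regs[["CDR2"]]) - 1L)]))
  }
  expect_lte(nfail, 2)
})

test_that("no-constraint generation leaves every step free", {
  fx <- reference_fixture()
  g <- generate_light(fx$model, fx$splits$test$heavy[2],
                      sampling = sampling_config(rng_seed = 3))
  expect_false(any(g$constrained_mask))
  expect_identical(length(g$per_token_logprob),
                   nchar(g$light) + as.integer(!g$truncated))
})

test_that("generation is deterministic per seed and greedy at T -> 0", {
  fx <- reference_fixture()
  heavy <- fx$splits$test$heavy[3]
  a <- generate_light(fx$model, heavy, sampling = sampling_config(rng_seed = 11))
  b <- generate_light(fx$model, heavy, sampling = sampling_config(rng_seed = 11))
  expect_identical(a$light, b$light)
  expect_identical(a$per_token_logprob, b$per_token_logprob)
  g1 <- generate_light(fx$model, heavy,
                       sampling = sampling_config(top_p = 1, temperature = 1e-9,
                                                  rng_seed = 1))
  g2 <- generate_light(fx$model, heavy,
                       sampling = sampling_config(top_p = 1, temperature = 1e-9,
                                                  rng_seed = 999))
  expect_identical(g1$light, g2$light)
})

test_that("batch generation is order-stable, reproducible, seed-sensitive", {
  fx <- reference_fixture()
  heavy <- fx$splits$test$heavy[4]
  b1 <- generate_batch(fx$model, heavy, n = 20,
                       sampling = sampling_config(rng_seed = 7))
  expect_length(b1, 20)
  b2 <- generate_batch(fx$model, heavy, n = 20,
                       sampling = sampling_config(rng_seed = 7))
  expect_identical(vapply(b1, `[[`, "", "light"), vapply(b2, `[[`, "", "light"))
  b3 <- generate_batch(fx$model, heavy, n = 20,
                       sampling = sampling_config(rng_seed = 8))
  expect_true(any(vapply(b1, `[[`, "", "light") !=
                    vapply(b3, `[[`, "", "light")))
})

test_that("germline-restricted generation always starts with the seed", {
  fx <- reference_fixture()
  tab <- germline_frequency_table(fx$repertoire)
  for (restr in list(list(level = "type", value = "kappa"),
                     list(level = "v_family", value = tab$family[1]),
                     list(level = "v_gene", value = tab$id[5]))) {
    con <- generation_constraints(restriction = restr, germline_table = tab)
    for (i in 1:5) {
      g <- generate_light(fx$model, fx$splits$test$heavy[5], con,
                          sampling_config(rng_seed = 400 + i))
      expect_identical(nchar(g$seed_used),
                       if (restr$level == "type") 2L else 10L)
      expect_true(startsWith(g$light, g$seed_used))
      expect_true(all(g$constrained_mask[seq_len(nchar(g$seed_used))]))
    }
  }
})
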