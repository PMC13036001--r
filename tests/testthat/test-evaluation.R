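test_that("germline self-assignment has identity one; mutations only lower it", {
  ds <- stats_dataset()
  lset <- light_germline_set(ds$repertoire)
  germ <- lset$v[[3]]$exemplar
  asg <- nearest_germline(germ, lset)
  expect_identical(asg$best_v_id, lset$v[[3]]$id)
  expect_identical(asg$v_identity, 1)
  expect_identical(asg$j_identity, 1)
  expect_identical(asg$mean_identity, 1)

  # monotone decrease against the true germline as mutations accumulate
  ann <- annotate_regions(germ)
  v_end <- ann$boundaries["FR3", "end"]
  anchors <- c(ann$boundaries["FR1", "end"], ann$boundaries["FR2", "start"],
               v_end, ann$boundaries["FR4", "start"])
  chars <- strsplit(germ, "")[[1]]
  set.seed(11)
  prev <- 1
  for (p in sample(setdiff(seq_len(v_end), anchors), 12)) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    seq <- paste(chars, collapse = "")
    id <- sum(strsplit(seq, "")[[1]][seq_len(v_end)] ==
                strsplit(germ, "")[[1]][seq_len(v_end)]) / v_end
    expect_lte(id, prev)
    prev <- id
  }
})

test_that("planted mutation arithmetic matches the reported V identity", {
  ds <- stats_dataset()
  lset <- light_germline_set(ds$repertoire)
  i <- which(ds$truth$n_mut_light %in% 5:8)[1]
  tr <- ds$truth[i, ]
  ann <- truth_annotation(ds$pairs$light[i], tr$light_germ)
  v_end <- ann$boundaries["FR3", "end"]
  pos <- as.integer(strsplit(tr$light_mut_pos, ",")[[1]])
  k <- sum(pos <= v_end)
  asg <- nearest_germline(ds$pairs$light[i], lset, ann)
  expect_identical(asg$best_v_id, tr$light_v)
  expect_equal(asg$v_identity, (v_end - k) / v_end, tolerance = 1e-12)
})

test_that("per-region counts match planted tallies and partition the Hamming distance", {
  ds <- stats_dataset()
  checked <- 0
  for (i in seq_len(nrow(ds$pairs))) {
    if (checked >= 8) break
    tr <- ds$truth[i, ]
    if (tr$n_mut_light < 2) next
    ann <- truth_annotation(ds$pairs$light[i], tr$light_germ)
    cm <- count_region_mutations(ds$pairs$light[i], tr$light_germ, ann)
    pos <- as.integer(strsplit(tr$light_mut_pos, ",")[[1]])
    b <- ann$boundaries
    planted <- vapply(rownames(b), function(rg)
      sum(pos >= b[rg, "start"] & pos <= b[rg, "end"]), 0L)
    expect_identical(cm$counts, planted)
    expect_identical(sum(cm$counts), tr$n_mut_light)
    expect_identical(cm$v_total + cm$junction_total, sum(cm$counts))
    checked <- checked + 1
  }
  expect_gte(checked, 5)
  # identical sequences give all-zero counts
  germ <- ds$truth$light_germ[1]
  zero <- count_region_mutations(germ, germ, annotate_regions(germ))
  expect_true(all(zero$counts == 0))
  expect_error(count_region_mutations("ACD", germ, annotate_regions(germ)),
               "length")
})

test_that("Pearson machinery matches a two-pass textbook implementation", {
  set.seed(21)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  pairs <- NULL  # direct access to the statistic via a synthetic wrapper
  r2p <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    r <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
  }
  ct <- stats::cor.test(x, y)
  oracle <- r2p(x, y)
  expect_equal(unname(ct$estimate), oracle$r, tolerance = 1e-12)
  expect_equal(ct$p.value, oracle$p, tolerance = 1e-12)
  # and the package's correlation agrees with both on real assignments
  ds <- stats_dataset()
  cc <- coevolution_correlation(ds$pairs[1:120, ],
                                heavy_germline_set(ds$repertoire),
                                light_germline_set(ds$repertoire))
  oc <- r2p(cc$heavy_identity, cc$light_identity)
  expect_equal(cc$r, oc$r, tolerance = 1e-12)
  expect_equal(cc$p_value, oc$p, tolerance = 1e-12)
})

test_that("native pairs correlate and shuffled pairs do not", {
  ds <- stats_dataset()
  hset <- heavy_germline_set(ds$repertoire)
  lset <- light_germline_set(ds$repertoire)
  sub <- ds$pairs[1:800, ]
  native <- coevolution_correlation(sub, hset, lset)
  expect_gt(native$r, 0.3)
  expect_lt(native$p_value, 1e-6)
  shuf <- sub
  set.seed(2)
  shuf$light <- sample(shuf$light)
  expect_lt(abs(coevolution_correlation(shuf, hset, lset)$r), 0.1)
})

test_that("novelty scan flags copies and stays low under the random null", {
  ds <- stats_dataset()
  ref <- ds$pairs$light[1:100]
  hit <- novelty_scan(ref[3], ref)
  expect_identical(hit$max_identity, 1)
  expect_true(hit$exact_match)
  # symmetry of the pairwise identity
  a <- random_aa(1, 110); b <- random_aa(1, 110)
  expect_identical(novelty_scan(a, b)$max_identity,
                   novelty_scan(b, a)$max_identity)
  set.seed(31)
  nov <- novelty_scan(random_aa(20, 110), random_aa(100, 110))
  expect_true(all(nov$max_identity < 0.6))
  expect_false(any(nov$exact_match))
})
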