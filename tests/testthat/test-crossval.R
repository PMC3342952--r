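test_that("partitions are balanced, disjoint and exhaustive", {
  ids <- sprintf("L%03d", 1:157)
  g <- make_partition(ids, 5, seed = 90)
  expect_equal(sort(table(lengths(g))), sort(table(c(32, 32, 31, 31, 31))))
  expect_setequal(unlist(g), ids)
  expect_equal(sum(lengths(g)), 157)
  g2 <- make_partition(sprintf("x%d", 1:10), 5, seed = 91)
  expect_true(all(lengths(g2) == 2))
  expect_error(make_partition(ids, 1), "n_groups")
})

test_that("fold enumeration covers all C(n_groups, q) splits", {
  ids <- sprintf("L%02d", 1:20)
  g <- make_partition(ids, 5, seed = 92)
  expect_length(enumerate_folds(g, 4), 5)
  expect_length(enumerate_folds(g, 3), 10)
  folds <- enumerate_folds(g, 4)
  # with q = n_groups - 1 every line is validated exactly once
  valid_all <- unlist(lapply(folds, `[[`, "valid"))
  expect_setequal(valid_all, ids)
  expect_equal(anyDuplicated(valid_all), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$valid), 0)
    expect_setequal(c(f$train, f$valid), ids)
  }
  # q = 3: every line validated in choose(4, 1...)=... combinatorial count
  folds3 <- enumerate_folds(g, 3)
  cnt <- table(unlist(lapply(folds3, `[[`, "valid")))
  expect_true(all(cnt == choose(4, 3) ))  # appears in C(n-1, q) validation sets
})

test_that("SNP selection strategies follow their stated conventions", {
  gm <- make_iid_gm(n = 40, m = 12, seed = 93)
  expect_identical(select_snps("all", gm_train = gm), 1:12)
  expect_identical(select_snps("thin_every_k", list(k = 1), gm), 1:12)
  expect_identical(select_snps("thin_every_k", list(k = 4), gm),
                   c(1L, 5L, 9L))  # anchored at the first SNP
  set.seed(94)
  r <- select_snps("random_m", list(m = 5), gm)
  expect_length(r, 5)
  expect_true(!is.unsorted(r))
  b <- select_snps("random_blocks", list(n_blocks = 2, block_size = 3), gm)
  expect_lte(length(b), 6)
  expect_error(select_snps("random_m", list(m = 99), gm), "more SNPs")

  # maf bins partition the SNPs by minor allele frequency
  bins <- lapply(1:3, function(b) {
    select_snps("maf_bin", list(n_bins = 3, bin = b), gm)
  })
  expect_setequal(unlist(bins), 1:12)
  maf <- pmin(allele_freq(gm), 1 - allele_freq(gm))
  expect_lte(max(maf[bins[[1]]]), min(maf[bins[[3]]]))
})

test_that("effect-based selection ranks by training-fold GBLUP effects", {
  gm <- make_iid_gm(n = 60, m = 400, seed = 95)
  set.seed(96)
  y <- as.numeric(gm$codes[, 7] * 2) + rnorm(60, 0, 0.5)
  top <- select_snps("top_abs_effect", list(n_top = 20), gm, y_train = y)
  expect_length(top, 20)
  expect_true(7 %in% top)
  frac <- select_snps("top_variance", list(fraction = 0.05), gm, y_train = y)
  expect_length(frac, 20)
  expect_error(select_snps("top_abs_effect", list(n_top = 20), gm),
               "training phenotypes")
})

test_that("predictive ability and accuracy follow their definitions", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(x, -x), -1)
  # constructed orthogonal pair
  a <- c(1, -1, 1, -1)
  b <- c(1, 1, -1, -1)
  expect_lt(abs(predictive_ability(a, b)), 1e-12)
  expect_error(predictive_ability(rep(1, 5), x), "constant")
  expect_error(predictive_ability(x[1:2], x[1:2]), "at least 3")

  expect_equal(accuracy(0.2, 1.0), 0.2)
  expect_equal(accuracy(0.2, 0.25), 0.4)
  expect_error(accuracy(0.2, 0), "h2")
  expect_warning(acc <- accuracy(0.9, 0.5), "clipped")
  expect_equal(acc, 1)
})

test_that("cross-validation is reproducible and bookkeeping is consistent", {
  fx <- sim_panel_fixture()
  gm <- fx$gm
  tm <- random_trait_model(gm, 150, target_h2 = 0.9, seed = 100)
  rec <- simulate_phenotypes(gm, tm, 1, 20, seed = 101)
  ph <- summarize_line_phenotypes(rec)
  sch <- cv_scheme(q = 4, replicates = 3, seed = 102)
  a <- run_cv(gm, ph, sch)
  b <- run_cv(gm, ph, sch)
  expect_identical(a$folds, b$folds)
  expect_equal(a$mean, mean(a$replicate_means))
  expect_equal(a$se, sd(a$replicate_means) / sqrt(3))
  expect_equal(nrow(a$folds), 3 * choose(5, 4))
  expect_equal(unname(tapply(a$folds$fold, a$folds$replicate, length)),
               rep(5, 3), ignore_attr = TRUE)
})

test_that("training uses only training-fold information", {
  fx <- sim_panel_fixture()
  gm <- fx$gm
  tm <- random_trait_model(gm, 150, target_h2 = 0.9, seed = 103)
  rec <- simulate_phenotypes(gm, tm, 1, 20, seed = 104)
  ph <- summarize_line_phenotypes(rec)
  sch <- cv_scheme(q = 4, replicates = 2, train_sex = "M", valid_sex = "F",
                   snp_strategy = "top_abs_effect",
                   strategy_params = list(n_top = 100), seed = 105)
  clean <- run_cv(gm, ph, sch)
  corrupted <- ph
  set.seed(106)
  corrupted$median_F <- sample(corrupted$median_F)  # validation phenotype only
  dirty <- run_cv(gm, corrupted, sch)
  # everything upstream of the final correlation is untouched
  expect_identical(clean$folds$h2_train, dirty$folds$h2_train)
  expect_identical(clean$folds$train_size, dirty$folds$train_size)
  expect_false(isTRUE(all.equal(clean$folds$correlation,
                                dirty$folds$correlation)))
})

test_that("cross-sex constellations and line exclusion are honored", {
  fx <- sim_panel_fixture()
  gm <- fx$gm
  tm <- random_trait_model(gm, 150, target_h2 = 0.9, sex_interaction_sd = 0.3,
                           seed = 107)
  rec <- simulate_phenotypes(gm, tm, 1, 20, seed = 108)
  ph <- summarize_line_phenotypes(rec)
  drop_ids <- gm$line_ids[1:10]
  sch <- cv_scheme(q = 4, replicates = 2, exclude_line_ids = drop_ids,
                   seed = 109)
  res <- run_cv(gm, ph, sch)
  expect_equal(res$folds$train_size + 10, rep(50, nrow(res$folds)))
})
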