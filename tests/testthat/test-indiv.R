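test_that("REML on a balanced one-way layout equals the ANOVA closed form", {
  set.seed(170)
  a <- 12; r <- 8
  lines <- sprintf("L%02d", 1:a)
  rec <- make_records(lines, n_per_cell = r, n_reps = 1, sigma_line = 1.3,
                      sigma_e = 0.9, sexes = "F")
  fit <- fit_indiv_model(rec, 1, sex_mode = "F", include_replicate = FALSE)
  # textbook one-way ANOVA REML oracle
  ybar_i <- tapply(rec$value, rec$line, mean)
  ybar <- mean(rec$value)
  ssb <- r * sum((ybar_i - ybar)^2)
  sse <- sum((rec$value - ybar_i[rec$line])^2)
  msb <- ssb / (a - 1); mse <- sse / (a * (r - 1))
  expect_equal(fit$estimates[["sigma_e2"]], mse, tolerance = 1e-6)
  expect_equal(fit$estimates[["sigma_line2"]], max(0, (msb - mse) / r),
               tolerance = 1e-6)
})

test_that("pooled model 1 agrees with an lme4 REML fit", {
  skip_if_not_installed("lme4")
  set.seed(171)
  lines <- sprintf("L%02d", 1:15)
  rec <- make_records(lines, n_per_cell = 6, n_reps = 2, sigma_line = 1,
                      sigma_sexline = 0.5, sigma_rep = 0.3, sigma_e = 1)
  fit <- fit_indiv_model(rec, 1)
  rec$sl <- interaction(rec$sex, rec$line)
  rec$rp <- interaction(rec$sex, rec$line, rec$replicate)
  lf <- lme4::lmer(value ~ sex + (1 | line) + (1 | sl) + (1 | rp), data = rec,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  get <- function(g) vc$vcov[vc$grp == g]
  expect_equal(fit$estimates[["sigma_line2"]], get("line"), tolerance = 1e-3)
  expect_equal(fit$estimates[["sigma_sexline2"]], get("sl"), tolerance = 1e-3)
  expect_equal(fit$estimates[["sigma_rep2"]], get("rp"), tolerance = 1e-3)
  expect_equal(fit$estimates[["sigma_e2"]], get("Residual"), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-4)
})

test_that("model likelihoods are nested and the G effect is detected", {
  fx <- sim_panel_fixture()
  gm <- drop_monomorphic(subset_geno(fx$gm, lines = 1:40))
  G <- compute_grm(gm)$G
  set.seed(172)
  g <- draw_gblup_y(G, 0.6, 0, mu = 0)  # pure genomic line values
  rec <- make_records(gm$line_ids, n_per_cell = 6, n_reps = 2,
                      line_vals = g, sigma_rep = 0.2, sigma_e = 1)
  f1 <- fit_indiv_model(rec, 1, G = G)
  f2 <- fit_indiv_model(rec, 2, G = G)
  f3 <- fit_indiv_model(rec, 3, G = G)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_gte(f3$loglik, f2$loglik - 1e-6)
  out <- lrt(f1, f2)
  expect_lt(out$p_value, 0.05)
  expect_gte(out$statistic, 0)
})

test_that("LRT arithmetic: point mass at zero and the 0.05 quantile", {
  f <- structure(list(loglik = -10, criterion = "REML", n_records = 100),
                 class = "indiv_fit")
  same <- lrt(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  f2 <- structure(list(loglik = -10 + 2.706 / 2, criterion = "REML",
                       n_records = 100), class = "indiv_fit")
  out <- lrt(f, f2)
  expect_equal(out$statistic, 2.706)
  expect_equal(out$p_value, 0.05, tolerance = 1e-3)
  expect_error(lrt(f2, f), "negative")
})

test_that("heritability ratios follow the stated compositions", {
  m1 <- structure(list(estimates = c(sigma_line2 = 1, sigma_sexline2 = 1,
                                     sigma_rep2 = 0, sigma_e2 = 2)),
                  class = "indiv_fit")
  expect_equal(broad_sense_h2(m1), 0.25)
  m1b <- structure(list(estimates = c(sigma_line2 = 1, sigma_sexline2 = 0,
                                      sigma_rep2 = 0, sigma_e2 = 0)),
                   class = "indiv_fit")
  expect_equal(broad_sense_h2(m1b), 1)
  m1c <- structure(list(estimates = c(sigma_line2 = 0, sigma_sexline2 = 1,
                                      sigma_rep2 = 0, sigma_e2 = 1)),
                   class = "indiv_fit")
  expect_equal(broad_sense_h2(m1c), 0)

  m2 <- structure(list(estimates = c(sigma_line2 = 0, sigma_a2 = 1,
                                     sigma_e2 = 1)), class = "indiv_fit")
  expect_equal(narrow_sense_h2_indiv(m2), 0.5)
  m3 <- structure(list(estimates = c(sigma_line2 = 0, sigma_a2 = 1,
                                     sigma_aa2 = 0.5, sigma_e2 = 1)),
                  class = "indiv_fit")
  expect_lt(narrow_sense_h2_indiv(m3), narrow_sense_h2_indiv(m2))
  m2all <- structure(list(estimates = c(sigma_a2 = 1, sigma_e2 = 0)),
                     class = "indiv_fit")
  expect_equal(narrow_sense_h2_indiv(m2all), 1)
})

test_that("sigma_a2 sits at the zero boundary when no genomic signal exists", {
  fx <- sim_panel_fixture()
  gm <- drop_monomorphic(subset_geno(fx$gm, lines = 1:30))
  G <- compute_grm(gm)$G
  set.seed(173)
  at_zero <- replicate(10, {
    rec <- make_records(gm$line_ids, n_per_cell = 4, n_reps = 1,
                        sigma_line = 1, sigma_e = 1, sexes = "F")
    f2 <- fit_indiv_model(rec, 2, G = G, sex_mode = "F",
                          include_replicate = FALSE)
    f2$estimates[["sigma_a2"]] < 0.05
  })
  expect_gte(sum(at_zero), 6)
})

test_that("variance components are recovered within tolerance", {
  set.seed(174)
  truth <- c(line = 1.5, sexline = 0.6, rep = 0.3, e = 1)
  est <- replicate(8, {
    lines <- sprintf("L%02d", 1:40)
    rec <- make_records(lines, n_per_cell = 10, n_reps = 2,
                        sigma_line = sqrt(truth["line"]),
                        sigma_sexline = sqrt(truth["sexline"]),
                        sigma_rep = sqrt(truth["rep"]),
                        sigma_e = sqrt(truth["e"]))
    fit_indiv_model(rec, 1)$estimates
  })
  got <- rowMeans(est)
  expect_lt(abs(got[["sigma_line2"]] - truth["line"]) / truth["line"], 0.25)
  expect_lt(abs(got[["sigma_sexline2"]] - truth["sexline"]) / truth["sexline"],
            0.25)
  expect_lt(abs(got[["sigma_e2"]] - truth["e"]) / truth["e"], 0.1)
})
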