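test_that("GRM matches the hand-computed VanRaden example", {
  meta <- data.frame(chrom_arm = "2L", pos_bp = 1L, pos_morgan = 0)
  gm <- geno_matrix(matrix(c(0L, 2L), 2, 1), c("a", "b"), meta)
  g <- compute_grm(gm)
  expect_equal(g$G, matrix(c(2, -2, -2, 2), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(g$denominator, 0.5)
  expect_error(compute_grm(geno_matrix(matrix(c(2L, 2L), 2, 1), c("a", "b"),
                                       meta)),
               "monomorphic")
})

test_that("GRM structural invariances: duplicates, permutation, symmetry", {
  gm <- make_iid_gm(n = 20, m = 120, seed = 60)
  gm$codes[20, ] <- gm$codes[1, ]  # duplicate line
  g <- compute_grm(gm)$G
  expect_equal(g[1, 20], g[1, 1])
  expect_equal(g[20, 20], g[1, 1])
  expect_equal(g, t(g))
  set.seed(66)
  perm <- sample(ncol(gm$codes))
  gm_perm <- geno_matrix(gm$codes[, perm],
                         gm$line_ids,
                         data.frame(chrom_arm = "2L",
                                    pos_bp = seq_len(ncol(gm$codes)),
                                    pos_morgan = 0))
  gp <- compute_grm(gm_perm)$G
  expect_equal(gp, g, ignore_attr = TRUE)
})

test_that("GRM is PSD and its expectation matches pedigree relationships", {
  gm <- make_iid_gm(n = 30, m = 400, seed = 61)
  g <- compute_grm(gm, check_psd = TRUE)  # PSD guard passes
  ev <- eigen(g$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(g$G)))

  # E[G] for full sibs ~ 0.5: simulate unlinked gametogenesis of one family
  # many times; allele frequencies fixed in the (large) base population
  set.seed(62)
  m <- 400
  p <- runif(m, 0.2, 0.8)
  denom <- 2 * sum(p * (1 - p))
  reps <- 200
  gsib <- replicate(reps, {
    mom <- matrix(rbinom(2 * m, 1, rep(p, each = 2)), 2, m)
    dad <- matrix(rbinom(2 * m, 1, rep(p, each = 2)), 2, m)
    kid <- function() {
      mom[cbind(sample(1:2, m, TRUE), 1:m)] +
        dad[cbind(sample(1:2, m, TRUE), 1:m)]
    }
    z1 <- kid() - 2 * p
    z2 <- kid() - 2 * p
    sum(z1 * z2) / denom
  })
  mc_se <- sd(gsib) / sqrt(reps)
  expect_lt(abs(mean(gsib) - 0.5), 3 * mc_se)
})

test_that("mean off-diagonal relationship of an unstructured panel is near zero", {
  gm <- make_iid_gm(n = 150, m = 300, seed = 63)
  g <- compute_grm(gm)$G
  off <- g[upper.tri(g)]
  # in-sample centering makes the exact mean -mean(diag)/(n-1); near zero at
  # panel sizes, and the grand sum of G vanishes identically
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(abs(sum(g)), 1e-8 * sum(diag(g)))
})

test_that("GRM from growing SNP subsets converges to the full-SNP GRM", {
  fx <- sim_panel_fixture()
  gm <- fx$gm
  gfull <- compute_grm(gm)$G
  v <- function(M) M[upper.tri(M, diag = TRUE)]
  cors <- sapply(c(8, 4, 2), function(k) {
    idx <- seq(1, ncol(gm$codes), by = k)
    sub <- subset_geno(gm, snps = idx)
    p <- allele_freq(sub)
    sub <- subset_geno(sub, snps = which(p > 0 & p < 1))
    cor(v(compute_grm(sub)$G), v(gfull))
  })
  expect_true(all(diff(cors) > 0) || cors[3] > 0.98)
  expect_gt(cors[3], 0.9)
})

test_that("SNP filters apply the stated thresholds on a hand-checked fixture", {
  set.seed(64)
  n <- 70
  codes <- 2L * matrix(rbinom(n * 10, 1, 0.5), n, 10)
  # SNP 1: minor allele in 3 lines only -> removed (threshold is >= 4)
  codes[, 1] <- 0L; codes[1:3, 1] <- 2L
  # SNP 2: minor allele in exactly 4 lines -> kept
  codes[, 2] <- 0L; codes[1:4, 2] <- 2L
  # SNP 5: called in 59 lines only -> removed (threshold >= 60)
  codes[1:11, 5] <- NA_integer_
  meta <- data.frame(chrom_arm = "2L", pos_bp = seq_len(10) * 100L,
                     pos_morgan = 0,
                     coverage = c(10, 10, 30, 2, 10, 10, 2.01, 29.99, 10, 10),
                     n_called = as.integer(colSums(!is.na(codes))))
  gm <- geno_matrix(codes, sprintf("L%02d", 1:n), meta)
  out <- apply_snp_filters(gm, cov_min = 2, cov_max = 30,
                           min_minor_lines = 4, min_called = 60)
  # hand count: drop SNP1 (minor in 3), SNP3 (cov 30, strict), SNP4 (cov 2,
  # strict), SNP5 (called in 59); SNP7 (2.01) and SNP8 (29.99) survive coverage
  kept <- out$snp_meta$pos_bp / 100
  expect_setequal(kept, c(2, 6, 7, 8, 9, 10))
  expect_error(apply_snp_filters(gm, cov_min = 100), "all SNPs removed")
})

test_that("naive imputation uses the per-SNP mode with ties to the lower code", {
  meta <- data.frame(chrom_arm = "2L", pos_bp = c(1L, 2L, 3L), pos_morgan = 0)
  codes <- matrix(c(0L, 0L, NA, 2L,
                    0L, 2L, NA, NA,
                    2L, 2L, 2L, 0L), 4, 3)
  gm <- geno_matrix(codes, c("a", "b", "c", "d"), meta)
  imp <- impute_missing_naive(gm)
  expect_identical(imp$codes[3, 1], 0L)          # mode of {0,0,2}
  expect_identical(as.integer(imp$codes[3:4, 2]), c(0L, 0L))  # tie 0 vs 2 -> 0
  expect_identical(imp$codes[, 3], gm$codes[, 3])  # untouched column
  expect_false(anyNA(imp$codes))
  expect_identical(impute_missing_naive(imp)$codes, imp$codes)  # identity
})

test_that("Hadamard square matches hand arithmetic and stays PSD", {
  meta <- data.frame(chrom_arm = "2L", pos_bp = 1L, pos_morgan = 0)
  gm <- geno_matrix(matrix(c(0L, 2L), 2, 1), c("a", "b"), meta)
  g <- compute_grm(gm)
  h <- hadamard_square(g)
  expect_equal(unname(h$G), matrix(4, 2, 2))
  expect_identical(h$kind, "hadamard_epistatic")
  expect_error(hadamard_square(h), "additive")

  gm2 <- make_iid_gm(n = 25, m = 200, seed = 65)
  g2 <- compute_grm(gm2)
  h2 <- hadamard_square(g2)
  expect_equal(diag(h2$G), diag(g2$G)^2)
  ev <- eigen(h2$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(h2$G)))
})
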