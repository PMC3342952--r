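# Shared fixtures, built in code. Heavy objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small unstructured inbred panel: independent {0,2} columns on two arms.
make_iid_gm <- function(n = 50, m = 200, seed = 1, arms = c("2L", "3R")) {
  set.seed(seed)
  p <- runif(m, 0.15, 0.85)
  codes <- 2L * matrix(rbinom(n * m, 1, rep(p, each = n)), n, m)
  half <- ceiling(m / 2)
  meta <- data.frame(
    chrom_arm = rep(arms, times = c(half, m - half)),
    pos_bp = c(sort(sample.int(5e6, half)), sort(sample.int(5e6, m - half))),
    pos_morgan = NA_real_)
  meta$pos_morgan <- ifelse(meta$chrom_arm == arms[1],
                            meta$pos_bp / 5e6 * 0.5, meta$pos_bp / 5e6 * 0.5)
  geno_matrix(codes, sprintf("L%03d", seq_len(n)), meta)
}

# One simulated panel reused across tests: Wright-Fisher base population,
# full-sib inbred lines, polymorphic SNPs only.
sim_panel_fixture <- function() {
  cache_fixture("sim_panel", function() {
    spec <- population_spec(Ne_sim = 40, n_snps = 1200, n_generations_base = 60)
    panel <- simulate_base_population(spec, seed = 42)
    gm <- derive_inbred_lines(panel, n_lines = 60, n_gen_fullsib = 20, seed = 43)
    p <- allele_freq(gm)
    list(panel = panel, gm = subset_geno(gm, snps = which(p > 0 & p < 1)))
  })
}

# Independent dense-likelihood oracle for the line-mean model: evaluates the
# exact Gaussian log-likelihood at a given h2 without the eigendecomposition
# shortcut used by the fitter.
dense_profile_ll <- function(h2, y, G) {
  n <- length(y)
  V0 <- h2 * G + (1 - h2) * diag(n)
  Vi <- tryCatch(solve(V0), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  one <- rep(1, n)
  mu <- sum(Vi %*% y * one) / sum(Vi %*% one * one)
  r <- y - mu
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  ld <- determinant(V0, logarithm = TRUE)$modulus
  -0.5 * (n * log(2 * pi * s2) + as.numeric(ld) + n)
}

# Draw y from the GBLUP model itself: y = mu + g + e, g ~ N(0, sg2 * G).
draw_gblup_y <- function(G, sg2, se2, mu = 0) {
  eg <- eigen(G, symmetric = TRUE)
  n <- nrow(G)
  g <- as.numeric(eg$vectors %*% (sqrt(pmax(eg$values, 0) * sg2) * rnorm(n)))
  mu + g + rnorm(n, 0, sqrt(se2))
}

# Balanced records for the variance-component models.
make_records <- function(lines, n_per_cell = 5, n_reps = 2,
                         sigma_line = 1, sigma_sexline = 0, sigma_rep = 0,
                         sigma_e = 1, line_vals = NULL, sexes = c("F", "M")) {
  nl <- length(lines)
  if (is.null(line_vals)) line_vals <- rnorm(nl, 0, sigma_line)
  out <- list()
  for (s in sexes) {
    sl <- rnorm(nl, 0, sigma_sexline)
    for (r in seq_len(n_reps)) {
      rd <- rnorm(nl, 0, sigma_rep)
      base <- line_vals + sl + rd
      out[[length(out) + 1L]] <- data.frame(
        line = rep(lines, each = n_per_cell), sex = s, replicate = paste0(s, r),
        value = rep(base, each = n_per_cell) +
          rnorm(nl * n_per_cell, 0, sigma_e))
    }
  }
  do.call(rbind, out)
}
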