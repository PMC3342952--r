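#' Fit the line-mean GBLUP model by maximum likelihood
#'
#' Model: `y = mu 1 + g + e` with `g ~ N(0, G sigma_g2)` and
#' `e ~ N(0, I sigma_e2)`, where y are per-line phenotypic values (averages of
#' sex medians) and G the genomic relationship matrix of the same lines.
#' The likelihood is profiled over `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`:
#' one eigendecomposition of G makes every evaluation O(n), and the 1-D profile
#' is maximized by a 101-point grid followed by golden-section refinement
#' (tolerance 1e-8 in h2); boundary optima at 0 or 1 are allowed.
#'
#' A GRM built with in-sample allele frequencies is singular: column centering
#' puts the vector of ones in its null space, and along that direction (which
#' the mean absorbs exactly) the Gaussian ML likelihood is unbounded as
#' `h2 -> 1`. When G has null eigenvalues, the likelihood is therefore
#' evaluated on the contrasts orthogonal to the null space (where h2 is
#' identifiable) and `mu` is estimated from the excluded directions; for a
#' nonsingular training submatrix this is the plain full ML fit.
#'
#' @param y_train numeric vector of line phenotypes (length >= 3).
#' @param G_train GRM submatrix of the same lines (matrix or `"grm"`).
#' @return an object of class `"varcomp"`: list with `mu`, `sigma_g2`,
#'   `sigma_e2`, `h2`, `loglik`, `n_used` (contrast dimension).
#' @export
fit_gblup_ml <- function(y_train, G_train) {
  if (inherits(G_train, "grm")) G_train <- G_train$G
  n <- length(y_train)
  if (n < 3) stop("need at least 3 training lines")
  if (any(!is.finite(y_train))) stop("non-finite phenotypes")
  if (var(y_train) == 0) stop("zero phenotypic variance")
  if (!all(dim(G_train) == n)) stop("G_train dimensions do not match y_train")
  eg <- eigen(G_train, symmetric = TRUE)
  ty <- as.numeric(crossprod(eg$vectors, y_train))
  t1 <- as.numeric(crossprod(eg$vectors, rep(1, n)))
  lam <- eg$values
  keep <- lam > 1e-8 * max(lam)
  lam <- pmax(lam, 0)
  n_eff <- sum(keep)
  drop_mass <- sum(t1[!keep]^2)
  mu_from_dropped <- drop_mass > n / 2

  prof <- function(h2) {
    v <- h2 * lam + (1 - h2)
    vk <- v[keep]
    if (any(vk <= 0)) return(list(ll = -Inf))
    if (mu_from_dropped) {
      # the ones-vector lies in null(G): mu comes from the excluded direction
      mu <- sum(t1[!keep] * ty[!keep]) / drop_mass
    } else {
      mu <- sum((t1 * ty / v)[keep]) / sum((t1^2 / v)[keep])
    }
    r <- (ty - mu * t1)[keep]
    s2 <- sum(r^2 / vk) / n_eff       # ML estimate of total variance
    ll <- -0.5 * (n_eff * log(2 * pi * s2) + sum(log(vk)) + n_eff)
    list(ll = ll, mu = mu, s2 = s2)
  }
  grid <- seq(0, 1, length.out = 101)
  lls <- vapply(grid, function(h) prof(h)$ll, 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(101, i + 1)]
  opt <- optimize(function(h) prof(h)$ll, c(lo, hi), maximum = TRUE,
                  tol = 1e-8)
  h2 <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  fit <- prof(h2)
  structure(list(mu = fit$mu, sigma_g2 = h2 * fit$s2,
                 sigma_e2 = (1 - h2) * fit$s2, h2 = h2, loglik = fit$ll,
                 n_used = n_eff),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("GBLUP ML fit: mu=%.4g sigma_g2=%.4g sigma_e2=%.4g h2=%.4f loglik=%.4f\n",
              x$mu, x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

#' GBLUP narrow-sense heritability
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` from the line-mean model fit.
#'
#' @param varcomp a `"varcomp"` or list with `sigma_g2`, `sigma_e2`.
#' @return numeric in \[0, 1\].
#' @export
gblup_h2 <- function(varcomp) {
  tot <- varcomp$sigma_g2 + varcomp$sigma_e2
  if (tot == 0) stop("sigma_g2 + sigma_e2 is zero; heritability undefined")
  varcomp$sigma_g2 / tot
}

#' BLUP genetic values for all lines from a training subset
#'
#' Computes `g_hat` for every line (phenotyped or not) given variance
#' components. The default route is the covariance projection
#' `g_hat = sigma_g2 * G[, t] V_t^{-1} (y_train - mu)` with
#' `V_t = G[t, t] sigma_g2 + I sigma_e2`; `method = "mme"` solves the full
#' mixed-model equations with an incidence matrix selecting the training lines
#' (the two routes are algebraically identical and asserted against each other
#' in the tests). Predicted phenotype of a validation line is `mu + g_hat`.
#'
#' @param y_train phenotypes of the training lines.
#' @param G_all GRM of all lines (matrix or `"grm"`).
#' @param train_idx integer indices of the training lines in `G_all`.
#' @param varcomp a `"varcomp"` fitted on the training lines.
#' @param method `"projection"` (default) or `"mme"`.
#' @return list with `g_hat` (all lines), `pred` (`mu + g_hat`), `mu`.
#' @export
solve_mme <- function(y_train, G_all, train_idx, varcomp,
                      method = c("projection", "mme")) {
  method <- match.arg(method)
  if (inherits(G_all, "grm")) G_all <- G_all$G
  n <- nrow(G_all)
  t_idx <- as.integer(train_idx)
  if (length(y_train) != length(t_idx)) stop("y_train and train_idx lengths differ")
  sg <- varcomp$sigma_g2; se <- varcomp$sigma_e2; mu <- varcomp$mu
  if (sg == 0) {
    g <- rep(0, n)
    mu <- mean(y_train)  # GLS mean when V is proportional to I
    return(list(g_hat = g, pred = mu + g, mu = mu))
  }
  if (method == "projection") {
    Vt <- sg * G_all[t_idx, t_idx, drop = FALSE] + diag(se, length(t_idx))
    Vi1 <- tryCatch(solve(Vt, rep(1, length(t_idx))),
                    error = function(e) stop("V_t is singular: ",
                                             conditionMessage(e)))
    # GLS mean given the variance components (equals the ML mu when varcomp
    # was fitted on this training set; identical to the MME solution)
    mu <- sum(Vi1 * y_train) / sum(Vi1)
    sol <- solve(Vt, y_train - mu)
    g <- as.numeric(sg * G_all[, t_idx, drop = FALSE] %*% sol)
  } else {
    if (se <= 0) stop("MME route requires sigma_e2 > 0")
    nt <- length(t_idx)
    Z <- matrix(0, nt, n)
    Z[cbind(seq_len(nt), t_idx)] <- 1
    Ginv <- tryCatch(solve(G_all), error = function(e) {
      warning("G is singular; adding ridge 1e-8 * mean(diag) to its diagonal")
      solve(G_all + diag(1e-8 * mean(diag(G_all)), n))
    })
    # coefficient matrix for (mu, g); X = 1_nt
    C <- rbind(
      cbind(nt / se, t(colSums(Z)) / se),
      cbind(colSums(Z) / se, crossprod(Z) / se + Ginv / sg)
    )
    rhs <- c(sum(y_train) / se, as.numeric(crossprod(Z, y_train)) / se)
    sol <- solve(C, rhs)
    mu <- sol[1]
    g <- sol[-1]
  }
  list(g_hat = g, pred = mu + g, mu = mu)
}

#' Back-solve SNP effects from the GBLUP fit (RRBLUP equivalence)
#'
#' The line-mean GBLUP model is equivalent to a random-regression model in
#' which every SNP effect is drawn from one normal distribution with variance
#' `sigma_g2 / d` (d = the GRM denominator). The BLUP of the effect vector is
#' `a_hat = (sigma_g2 / d) Z' V^{-1} (y - mu)` with `Z = W - 2P`; it satisfies
#' `Z a_hat = g_hat` exactly, and only an n x n inversion is needed. Effects
#' are estimated from all phenotyped lines. The per-SNP marked additive
#' variance is `v_j = 2 p_j (1 - p_j) a_j^2`.
#'
#' @param y_all phenotypes of all lines in `gm` (same order).
#' @param gm the [geno_matrix()] the GRM was built from.
#' @param varcomp a `"varcomp"` fitted on `y_all`.
#' @param grm optional precomputed `"grm"` of `gm` (recomputed otherwise).
#' @return object of class `"snp_effects"`: data.frame with `chrom_arm`,
#'   `pos_bp`, `effect`, `v_j`, plus attributes `mu`, `p`, `g_hat`.
#' @export
backsolve_snp_effects <- function(y_all, gm, varcomp, grm = NULL) {
  if (is.null(grm)) grm <- compute_grm(gm)
  G <- grm$G
  n <- nrow(G)
  if (length(y_all) != n) stop("y_all length does not match gm")
  sg <- varcomp$sigma_g2; se <- varcomp$sigma_e2; mu <- varcomp$mu
  p <- grm$p
  Z <- sweep(gm$codes, 2, 2 * p)
  if (sg == 0) {
    a <- rep(0, ncol(Z))
    g <- rep(0, n)
  } else {
    V <- sg * G + diag(se, n)
    sol <- tryCatch(solve(V, y_all - mu), error = function(e) {
      warning("V is singular; adding ridge 1e-8 * mean(diag) before solving")
      solve(V + diag(1e-8 * mean(diag(V)), n), y_all - mu)
    })
    a <- as.numeric((sg / grm$denominator) * crossprod(Z, sol))
    g <- as.numeric(sg * G %*% sol)
  }
  out <- data.frame(chrom_arm = gm$snp_meta$chrom_arm,
                    pos_bp = gm$snp_meta$pos_bp,
                    effect = a, v_j = 2 * p * (1 - p) * a^2,
                    row.names = NULL)
  attr(out, "mu") <- mu
  attr(out, "p") <- p
  attr(out, "g_hat") <- g
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Predict phenotypes from SNP effects
#'
#' `mu + Z a_hat` with `Z = W - 2P` using the allele frequencies stored with
#' the effects (the RRBLUP side of the GBLUP/RRBLUP identity).
#'
#' @param effects a `"snp_effects"` object.
#' @param gm genotype matrix of the lines to predict (same SNP set).
#' @return numeric vector of predicted phenotypes.
#' @export
predict_snp_effects <- function(effects, gm) {
  if (nrow(effects) != ncol(gm$codes)) {
    stop("SNP count mismatch between effects and genotypes")
  }
  Z <- sweep(gm$codes, 2, 2 * attr(effects, "p"))
  as.numeric(attr(effects, "mu") + Z %*% effects$effect)
}
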