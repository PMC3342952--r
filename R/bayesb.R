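#' BayesB sampler configuration
#'
#' Priors: each marker variance is zero with probability `pi` and otherwise a
#' scaled inverse-chi-square draw with `nu` degrees of freedom and scale `S`,
#' so each marker effect is marginally a point mass at zero mixed with a
#' t-distribution. The residual variance has a scaled inverse-chi-square prior
#' `(nu_e, S_e)`. Scales are calibrated from the GBLUP variance components via
#' [calibrate_scale()] / [calibrate_residual_scale()] so the prior matches
#' their order of magnitude. Chain defaults are desk-scaled.
#'
#' @param pi prior fraction of zero-effect SNPs, in \[0, 1).
#' @param nu prior degrees of freedom for marker variances (> 2).
#' @param scale marker-variance scale S (see [calibrate_scale()]).
#' @param nu_e,scale_e residual-variance prior.
#' @param chain_length,burn_in,thinning MCMC schedule
#'   (`chain_length > burn_in >= 0`).
#' @param mh_iters Metropolis-Hastings cycles per locus update (>= 1).
#' @param seed integer seed; identical seeds give identical chains.
#' @return an object of class `"bayesb_config"`.
#' @export
bayesb_config <- function(pi = 0.95, nu = 4.2, scale, nu_e = 4.2, scale_e,
                          chain_length = 10000, burn_in = 2000, thinning = 10,
                          mh_iters = 100, seed = NULL) {
  if (pi < 0 || pi >= 1) stop("pi must be in [0, 1)")
  if (chain_length <= burn_in || burn_in < 0) {
    stop("need chain_length > burn_in >= 0")
  }
  if (mh_iters < 1) stop("mh_iters must be >= 1")
  if (nu <= 2) stop("nu must exceed 2 for the prior mean to exist")
  structure(list(pi = pi, nu = nu, scale = scale, nu_e = nu_e,
                 scale_e = scale_e, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning),
                 mh_iters = as.integer(mh_iters), seed = seed),
            class = "bayesb_config")
}

#' Calibrate the BayesB marker-variance scale
#'
#' Chooses S so the prior-expected total marked variance
#' `(1 - pi) * sum_j 2 p_j (1 - p_j) * E[sigma_gj^2]` equals a target additive
#' variance (typically the GBLUP `sigma_g2`), with
#' `E[sigma_gj^2] = S * nu / (nu - 2)`.
#'
#' @param target_sigma_g2 target additive genetic variance (> 0).
#' @param gm the [geno_matrix()] supplying allele frequencies.
#' @param pi prior fraction of zero-effect SNPs (< 1).
#' @param nu prior degrees of freedom (> 2).
#' @return the scale S.
#' @export
calibrate_scale <- function(target_sigma_g2, gm, pi = 0.95, nu = 4.2) {
  if (nu <= 2) stop("prior mean undefined for nu <= 2")
  if (pi >= 1) stop("pi = 1 leaves no marker to carry variance")
  if (target_sigma_g2 <= 0) stop("target_sigma_g2 must be positive")
  p <- allele_freq(gm)
  target_sigma_g2 / ((1 - pi) * sum(2 * p * (1 - p)) * nu / (nu - 2))
}

#' Calibrate the BayesB residual-variance scale
#'
#' S_e such that the prior mean `S_e * nu_e / (nu_e - 2)` equals a target
#' residual variance (typically the GBLUP `sigma_e2`).
#'
#' @param target_sigma_e2 target residual variance (> 0).
#' @param nu_e prior degrees of freedom (> 2).
#' @return the scale S_e.
#' @export
calibrate_residual_scale <- function(target_sigma_e2, nu_e = 4.2) {
  if (nu_e <= 2) stop("prior mean undefined for nu_e <= 2")
  if (target_sigma_e2 <= 0) stop("target_sigma_e2 must be positive")
  target_sigma_e2 * (nu_e - 2) / nu_e
}

#' Run the BayesB marker-effect MCMC
#'
#' Gibbs sampling over the mean, the residual variance and, per locus, the
#' marker variance (Metropolis-Hastings with the mixture prior as proposal,
#' `mh_iters` cycles against the marginal likelihood of the locus-corrected
#' data) and the marker effect (Gibbs, given a nonzero variance). Genotype
#' columns are centered internally; posterior summaries are over retained
#' samples.
#'
#' @param y line phenotypes (one per line of `gm`).
#' @param gm a [geno_matrix()] with no missing cells.
#' @param config a [bayesb_config()].
#' @return object of class `"bayesb_result"`: list with `effects`
#'   (posterior-mean effect per SNP), `inclusion` (posterior inclusion
#'   frequency), `mu`, `sigma_e2`, `n_retained`, `fitted_count` (per-iteration
#'   fitted-SNP count), `sigma_e2_trace`, `snp_id`, `col_center`.
#' @export
run_bayesb <- function(y, gm, config) {
  if (anyNA(gm$codes)) stop("missing genotypes present; impute first")
  if (length(y) != nrow(gm$codes)) stop("y length does not match gm")
  W <- gm$codes
  ctr <- colMeans(W)
  Wc <- sweep(W, 2, ctr)
  res <- with_seed(config$seed, {
    bayesb_mcmc(as.numeric(y), Wc, config$pi, config$nu, config$scale,
                config$nu_e, config$scale_e, config$chain_length,
                config$burn_in, config$mh_iters, config$thinning)
  })
  structure(c(res, list(snp_id = colnames(W), col_center = ctr,
                        config = config)),
            class = "bayesb_result")
}

#' @export
print.bayesb_result <- function(x, ...) {
  cat(sprintf(
    "bayesb_result: %d SNPs, %d retained samples, mean fitted/iter %.1f, sigma_e2 %.4g\n",
    length(x$effects), x$n_retained, mean(x$fitted_count), x$sigma_e2))
  invisible(x)
}

#' Predict phenotypes from a BayesB fit
#'
#' `mu + W_validation a_hat` with the training-column centering applied, where
#' `a_hat` are posterior-mean effects.
#'
#' @param result a `"bayesb_result"`.
#' @param gm_validation genotypes of lines to predict; SNP set must match the
#'   training set.
#' @return numeric vector of predicted phenotypes.
#' @export
predict_bayesb <- function(result, gm_validation) {
  ids <- colnames(gm_validation$codes)
  if (!identical(ids, result$snp_id)) {
    off <- union(setdiff(ids, result$snp_id), setdiff(result$snp_id, ids))
    if (length(off) == 0) off <- "(same set, different order)"
    stop("SNP mismatch between fit and validation genotypes: ",
         paste(head(off, 5), collapse = ", "))
  }
  Wc <- sweep(gm_validation$codes, 2, result$col_center)
  as.numeric(result$mu + Wc %*% result$effects)
}
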