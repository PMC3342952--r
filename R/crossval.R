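#' Pearson predictive ability
#'
#' Correlation between predicted genetic values and observed phenotypes of a
#' validation set.
#'
#' @param pred,obs numeric vectors (>= 3 pairs, both with nonzero variance).
#' @return correlation in \[-1, 1\].
#' @export
predictive_ability <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) < 3) stop("need at least 3 prediction/observation pairs")
  if (sd(pred) == 0 || sd(obs) == 0) {
    stop("predictive ability undefined: constant predictions or observations")
  }
  cor(pred, obs)
}

#' Prediction accuracy from predictive ability
#'
#' Observed predictive ability divided by the square root of the observed
#' heritability (correlation between true and predicted genetic values).
#'
#' @param pred_ability predictive ability.
#' @param h2 heritability in (0, 1].
#' @return accuracy, clipped to \[-1, 1\] with a warning if outside.
#' @export
accuracy <- function(pred_ability, h2) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  r <- pred_ability / sqrt(h2)
  if (abs(r) > 1) {
    warning("accuracy ", signif(r, 4), " outside [-1, 1]; clipped")
    r <- max(-1, min(1, r))
  }
  r
}

#' Random partition of lines into groups of near-equal size
#'
#' @param line_ids character vector of line ids.
#' @param n_groups number of groups (>= 2); sizes differ by at most 1.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list of character vectors, one per group.
#' @export
make_partition <- function(line_ids, n_groups, seed = NULL) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (n_groups > length(line_ids)) stop("more groups than lines")
  with_seed(seed, {
    shuffled <- sample(line_ids)
    unname(split(shuffled, rep(seq_len(n_groups), length.out = length(shuffled))))
  })
}

#' Enumerate all train/validation folds of a (q : p) scheme
#'
#' Every choice of `q` training groups out of the partition is one fold, giving
#' `choose(n_groups, q)` folds in canonical (combn) order.
#'
#' @param groups list of line-id vectors from [make_partition()].
#' @param q number of training groups, `1 <= q < length(groups)`.
#' @return list of folds, each `list(train, valid)` of line ids.
#' @export
enumerate_folds <- function(groups, q) {
  g <- length(groups)
  if (q < 1 || q >= g) stop("need 1 <= q < n_groups")
  combs <- combn(g, q)
  lapply(seq_len(ncol(combs)), function(k) {
    tr <- combs[, k]
    list(train = unlist(groups[tr], use.names = FALSE),
         valid = unlist(groups[-tr], use.names = FALSE))
  })
}

#' Select a SNP subset for relationship-matrix construction
#'
#' Strategies mirror the marker-density and SNP-selection series: `all`;
#' `thin_every_k` (every k-th SNP of the genome-wide ordered list, anchored at
#' the first SNP); `random_m` (`params$m` SNPs at random); `random_blocks`
#' (`params$n_blocks` random blocks of `params$block_size` adjacent SNPs);
#' `maf_bin` (sort by minor allele frequency, cut into `params$n_bins` equal
#' blocks, take block `params$bin`); `top_abs_effect` / `top_variance` (rank by
#' |effect| or by marked variance from a GBLUP back-solve fitted on the
#' training fold only). Effect-based strategies must receive training data
#' only.
#'
#' @param strategy one of `"all"`, `"thin_every_k"`, `"random_m"`,
#'   `"random_blocks"`, `"maf_bin"`, `"top_abs_effect"`, `"top_variance"`.
#' @param params list of strategy parameters (`k`, `m`, `n_blocks`,
#'   `block_size`, `n_bins`, `bin`, `fraction` or `n_top`).
#' @param gm_train genotypes of the training lines.
#' @param y_train training phenotypes (effect-based strategies only).
#' @return sorted integer vector of SNP column indices.
#' @export
select_snps <- function(strategy, params = list(), gm_train, y_train = NULL) {
  m <- ncol(gm_train$codes)
  idx <- switch(strategy,
    all = seq_len(m),
    thin_every_k = {
      k <- params$k %||% 1
      if (k < 1) stop("k must be >= 1")
      seq(1, m, by = k)
    },
    random_m = {
      nm <- params$m
      if (nm > m) stop("requested more SNPs than exist")
      sort(sample.int(m, nm))
    },
    random_blocks = {
      nb <- params$n_blocks; bs <- params$block_size
      if (nb * bs > m) stop("requested more SNPs than exist")
      starts <- sample.int(m - bs + 1, nb)
      sort(unique(unlist(lapply(starts, function(s) s:(s + bs - 1)))))
    },
    maf_bin = {
      nb <- params$n_bins; b <- params$bin
      if (is.null(nb) || is.null(b) || b < 1 || b > nb) {
        stop("maf_bin needs n_bins and a valid bin index")
      }
      maf <- pmin(allele_freq(gm_train), 1 - allele_freq(gm_train))
      o <- order(maf)
      sizes <- rep(floor(m / nb), nb)
      sizes[seq_len(m - sum(sizes))] <- sizes[seq_len(m - sum(sizes))] + 1
      grp <- rep(seq_len(nb), times = sizes)
      sort(o[grp == b])
    },
    top_abs_effect = ,
    top_variance = {
      if (is.null(y_train)) stop("effect-based selection needs training phenotypes")
      n_top <- params$n_top %||% max(1, round((params$fraction %||% 0.05) * m))
      if (n_top > m) stop("requested more SNPs than exist")
      poly <- which(apply(gm_train$codes, 2, function(x) length(unique(x))) > 1)
      gmp <- subset_geno(gm_train, snps = poly)
      grm <- compute_grm(gmp)
      vc <- fit_gblup_ml(y_train, grm)
      eff <- backsolve_snp_effects(y_train, gmp, vc, grm = grm)
      score <- numeric(m)  # monomorphic SNPs keep score 0, never selected first
      score[poly] <- if (strategy == "top_abs_effect") abs(eff$effect) else eff$v_j
      sort(order(score, decreasing = TRUE)[seq_len(n_top)])
    },
    stop("unknown snp strategy: ", strategy)
  )
  as.integer(idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a cross-validation scheme
#'
#' @param n_groups groups the lines are divided into (default 5).
#' @param q training groups per fold (`(q : n_groups - q)`-CV).
#' @param replicates independent random partitions (default 20).
#' @param train_sex,valid_sex phenotype used in training / validation:
#'   `"avg"` (average of sex medians), `"M"` or `"F"` (single-sex medians).
#' @param snp_strategy,strategy_params SNP subset used to build the GRM, see
#'   [select_snps()].
#' @param exclude_line_ids lines dropped before partitioning.
#' @param predictor `"gblup"` or `"bayesb"`.
#' @param bayesb list of [bayesb_config()] overrides (`pi`, `chain_length`,
#'   ...); scales are calibrated per training fold from the GBLUP fit.
#' @param seed integer seed; identical scheme + seed gives identical results.
#' @return an object of class `"cv_scheme"`.
#' @export
cv_scheme <- function(n_groups = 5, q = 4, replicates = 20,
                      train_sex = c("avg", "M", "F"),
                      valid_sex = c("avg", "M", "F"),
                      snp_strategy = "all", strategy_params = list(),
                      exclude_line_ids = NULL,
                      predictor = c("gblup", "bayesb"), bayesb = list(),
                      seed = NULL) {
  if (q < 1 || q >= n_groups) stop("need 1 <= q < n_groups")
  structure(list(n_groups = n_groups, q = q, replicates = replicates,
                 train_sex = match.arg(train_sex),
                 valid_sex = match.arg(valid_sex),
                 snp_strategy = snp_strategy,
                 strategy_params = strategy_params,
                 exclude_line_ids = exclude_line_ids,
                 predictor = match.arg(predictor), bayesb = bayesb,
                 seed = seed),
            class = "cv_scheme")
}

pheno_column <- function(pheno, which) {
  switch(which, avg = pheno$y, M = pheno$median_M, F = pheno$median_F)
}

#' Run a replicated grouped cross-validation
#'
#' Per replicate: a fresh random partition; per fold: SNP selection and
#' variance-component estimation on the training fold only, BLUP (or BayesB)
#' prediction of the validation lines, and the Pearson correlation with the
#' validation phenotype. Fold correlations are averaged per replicate; the
#' overall mean is the mean of replicate means and its standard error is
#' `sd(replicate means)/sqrt(replicates)`.
#'
#' @param gm a [geno_matrix()] (no missing cells).
#' @param pheno line phenotype table from [summarize_line_phenotypes()] (or
#'   individual records, summarized internally).
#' @param scheme a [cv_scheme()].
#' @return object of class `"cv_result"`: list with `folds` (data.frame:
#'   replicate, fold, train_size, correlation, h2_train), `replicate_means`,
#'   `mean`, `se`, `n_undefined` (correlations recorded as 0), `scheme`.
#' @export
run_cv <- function(gm, pheno, scheme) {
  if (!is.null(pheno$value)) pheno <- summarize_line_phenotypes(pheno)
  if (!is.null(scheme$exclude_line_ids)) {
    pheno <- pheno[!pheno$line %in% scheme$exclude_line_ids, , drop = FALSE]
  }
  keep <- intersect(gm$line_ids, pheno$line)
  gm <- subset_geno(gm, lines = keep)
  pheno <- pheno[match(keep, pheno$line), , drop = FALSE]
  y_tr_all <- pheno_column(pheno, scheme$train_sex)
  y_va_all <- pheno_column(pheno, scheme$valid_sex)
  n <- length(keep)
  n_undef <- 0L
  rows <- list()

  with_seed(scheme$seed, {
    for (rep_i in seq_len(scheme$replicates)) {
      groups <- make_partition(gm$line_ids, scheme$n_groups)
      folds <- enumerate_folds(groups, scheme$q)
      for (f in seq_along(folds)) {
        tr <- match(folds[[f]]$train, gm$line_ids)
        va <- match(folds[[f]]$valid, gm$line_ids)
        if (length(va) < 3) stop("validation fold with fewer than 3 lines")
        gm_tr <- subset_geno(gm, lines = tr)
        snp_idx <- select_snps(scheme$snp_strategy, scheme$strategy_params,
                               gm_tr, y_train = y_tr_all[tr])
        gm_sub <- subset_geno(gm, snps = snp_idx)
        poly <- which(apply(gm_sub$codes, 2, function(x) length(unique(x))) > 1)
        if (!length(poly)) stop("no polymorphic SNPs left after selection")
        gm_sub <- subset_geno(gm_sub, snps = poly)
        grm <- compute_grm(gm_sub)
        vc <- fit_gblup_ml(y_tr_all[tr], grm$G[tr, tr])
        if (scheme$predictor == "gblup") {
          # boundary fits (sigma_e2 = 0) with duplicated genotype rows make
          # V_t exactly singular; a vanishing nugget keeps prediction defined
          vc_pred <- vc
          vc_pred$sigma_e2 <- max(vc$sigma_e2, 1e-8 * var(y_tr_all[tr]))
          blup <- solve_mme(y_tr_all[tr], grm, tr, vc_pred)
          pred <- blup$pred[va]
        } else {
          ov <- scheme$bayesb
          cfg <- bayesb_config(
            pi = ov$pi %||% 0.95, nu = ov$nu %||% 4.2,
            scale = ov$scale %||% calibrate_scale(
              max(vc$sigma_g2, 1e-8 * var(y_tr_all[tr])),
              gm_sub, pi = ov$pi %||% 0.95, nu = ov$nu %||% 4.2),
            nu_e = ov$nu_e %||% 4.2,
            scale_e = ov$scale_e %||% calibrate_residual_scale(
              max(vc$sigma_e2, 1e-8 * var(y_tr_all[tr])), ov$nu_e %||% 4.2),
            chain_length = ov$chain_length %||% 10000,
            burn_in = ov$burn_in %||% 2000,
            thinning = ov$thinning %||% 10,
            mh_iters = ov$mh_iters %||% 100)
          fit <- run_bayesb(y_tr_all[tr], subset_geno(gm_sub, lines = tr), cfg)
          pred <- predict_bayesb(fit, subset_geno(gm_sub, lines = va))
        }
        r <- tryCatch(predictive_ability(pred, y_va_all[va]),
                      error = function(e) {
                        warning("undefined correlation recorded as 0: ",
                                conditionMessage(e))
                        n_undef <<- n_undef + 1L
                        0
                      })
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, fold = f, train_size = length(tr),
          correlation = r, h2_train = vc$h2)
      }
    }
  })
  folds_df <- do.call(rbind, rows)
  rep_means <- tapply(folds_df$correlation, folds_df$replicate, mean)
  structure(list(folds = folds_df,
                 replicate_means = as.numeric(rep_means),
                 mean = mean(rep_means),
                 se = sd(rep_means) / sqrt(scheme$replicates),
                 n_undefined = n_undef, scheme = scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%d:%d, %s): mean predictive ability %.4f (SE %.4f), %d replicates\n",
              x$scheme$q, x$scheme$n_groups - x$scheme$q, x$scheme$predictor,
              x$mean, x$se, x$scheme$replicates))
  invisible(x)
}
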