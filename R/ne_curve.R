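#' Effective number of independently segregating genome segments
#'
#' `Me = 2 Ne L* / ln(4 Ne L*)`. The `"drosophila"` variant uses the
#' sex-averaged map length `L* = L_female / 2` because males do not recombine;
#' the `"mammal"` variant uses `L* = L_female` (recombination in both sexes),
#' so `drosophila(Ne, L) = mammal(Ne, L/2)` by construction.
#'
#' @param Ne effective population size (>= 2).
#' @param L_female female genome length, Morgan (> 0).
#' @param variant `"drosophila"` (default) or `"mammal"`.
#' @param ln_const the constant inside the logarithm (default 4).
#' @return Me, the number of independent segments.
#' @export
effective_segments <- function(Ne, L_female, variant = c("drosophila", "mammal"),
                               ln_const = 4) {
  variant <- match.arg(variant)
  if (any(Ne < 2)) stop("Ne must be >= 2")
  if (L_female <= 0) stop("L_female must be positive")
  Ls <- if (variant == "drosophila") L_female / 2 else L_female
  arg <- ln_const * Ne * Ls
  if (any(arg <= 1)) stop("argument of ln is <= 1; Me undefined at this Ne*L")
  2 * Ne * Ls / log(arg)
}

#' Expected accuracy of genomic prediction (modified Daetwyler formula)
#'
#' The expected accuracy is `sqrt(T h2 / (T h2 + Me))`, with `T` the training-set size, `h2` the
#' narrow-sense heritability from the line-mean GBLUP model and `Me` the number
#' of independently segregating genome segments from [effective_segments()].
#'
#' @param T_train training-set size (> 0; may be a non-integer average).
#' @param h2 heritability in \[0, 1\].
#' @param Ne effective population size.
#' @param L_female female genome length, Morgan.
#' @param variant,ln_const passed to [effective_segments()].
#' @return expected accuracy in \[0, 1).
#' @export
expected_accuracy <- function(T_train, h2, Ne, L_female,
                              variant = "drosophila", ln_const = 4) {
  if (any(T_train <= 0)) stop("training-set size must be positive")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  Me <- effective_segments(Ne, L_female, variant, ln_const)
  sqrt(T_train * h2 / (T_train * h2 + Me))
}

ne_sse <- function(Ne, points, h2, L_female, variant, ln_const) {
  r <- expected_accuracy(points$T, h2, Ne, L_female, variant, ln_const)
  sum((points$r_bar - r)^2)
}

#' Least-squares fit of Ne to empirical accuracy points
#'
#' Finds Ne minimizing the sum of squared differences between observed mean
#' accuracies and the expected-accuracy curve at the observed training sizes,
#' by a log-scale grid search refined with [optimize()]. Accuracies are CV
#' predictive abilities divided by `sqrt(h2)`.
#'
#' @param points data.frame with columns `T` (training size) and `r_bar`
#'   (mean accuracy), >= 2 distinct T.
#' @param h2 GBLUP heritability used to convert predictive ability to accuracy
#'   and entering the curve.
#' @param L_female female genome length, Morgan.
#' @param ne_range search range for Ne.
#' @param variant,ln_const passed to [effective_segments()].
#' @return object of class `"ne_fit"`: list with `Ne_hat`, `Me`, `R2`, `sse`,
#'   `points`, `h2`, `L_female`, `variant`, `ln_const`.
#' @export
fit_ne <- function(points, h2, L_female, ne_range = c(2, 1e7),
                   variant = "drosophila", ln_const = 4) {
  points <- as.data.frame(points)
  if (length(unique(points$T)) < 2) {
    stop("need at least 2 points with distinct training sizes")
  }
  if (all(points$r_bar == 0)) stop("degenerate points: all accuracies are zero")
  lo <- max(ne_range[1], 1.01 / (ln_const * ifelse(variant == "drosophila",
                                                   L_female / 2, L_female)))
  grid <- exp(seq(log(max(lo, 2)), log(ne_range[2]), length.out = 200))
  sse <- vapply(grid, ne_sse, 0, points = points, h2 = h2,
                L_female = L_female, variant = variant, ln_const = ln_const)
  i <- which.min(sse)
  bl <- grid[max(1, i - 1)]; bu <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(ne) ne_sse(ne, points, h2, L_female, variant,
                                      ln_const),
                  c(bl, bu), tol = 1e-6)
  ne_hat <- if (opt$objective <= sse[i]) opt$minimum else grid[i]
  best <- ne_sse(ne_hat, points, h2, L_female, variant, ln_const)
  sst <- sum((points$r_bar - mean(points$r_bar))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best / sst)) else NA_real_
  structure(list(Ne_hat = ne_hat,
                 Me = effective_segments(ne_hat, L_female, variant, ln_const),
                 R2 = r2, sse = best, points = points, h2 = h2,
                 L_female = L_female, variant = variant, ln_const = ln_const),
            class = "ne_fit")
}

#' @export
print.ne_fit <- function(x, ...) {
  cat(sprintf("ne_fit: Ne_hat = %.1f (Me = %.1f, R2 = %.3f) from %d accuracy points\n",
              x$Ne_hat, x$Me, x$R2, nrow(x$points)))
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% BC bootstrap CI: [%.1f, %.1f] (B = %d)\n",
                round(100 * (1 - x$alpha)), x$ci[1], x$ci[2], x$B))
  }
  invisible(x)
}

#' Bias-corrected bootstrap confidence interval for the Ne fit
#'
#' Resamples the accuracy points with replacement, refits Ne per resample, and
#' forms the bias-corrected percentile interval: with
#' `z0 = qnorm(F_boot(Ne_hat))` (the normal quantile of the bootstrap CDF at
#' the point estimate), the bounds are the bootstrap quantiles at
#' `pnorm(2 z0 -/+ z_(1 - alpha/2))`. When exactly half the bootstrap
#' estimates fall below `Ne_hat`, `z0 = 0` and the interval reduces to the
#' plain percentile interval.
#'
#' @param fit an `"ne_fit"` from [fit_ne()].
#' @param B bootstrap replicates (>= 200).
#' @param alpha total error (two tails); default 0.10 for a 90% interval.
#' @param seed integer seed.
#' @return the `"ne_fit"` with elements `ci` (lo, hi), `z0`, `boot`
#'   (bootstrap estimates), `B`, `alpha` added; a degenerate bootstrap
#'   distribution is flagged with a warning.
#' @export
bootstrap_bc_ci <- function(fit, B = 1000, alpha = 0.10, seed = NULL) {
  if (B < 200) stop("B must be >= 200")
  pts <- fit$points
  n <- nrow(pts)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        take <- sample.int(n, n, replace = TRUE)
        ps <- pts[take, , drop = FALSE]
        if (length(unique(ps$T)) >= 2 && any(ps$r_bar != 0)) break
      }
      fit_ne(ps, fit$h2, fit$L_female, variant = fit$variant,
             ln_const = fit$ln_const)$Ne_hat
    }, 0)
  })
  if (length(unique(boot)) == 1) {
    warning("all bootstrap fits identical; interval is degenerate")
  }
  frac <- mean(boot < fit$Ne_hat)
  z0 <- qnorm(min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B)))
  if (alpha >= 1) {
    lohi <- rep(quantile(boot, pnorm(2 * z0), type = 7, names = FALSE), 2)
  } else {
    zq <- qnorm(1 - alpha / 2)
    probs <- pnorm(c(2 * z0 - zq, 2 * z0 + zq))
    lohi <- quantile(boot, probs, type = 7, names = FALSE)
  }
  fit$ci <- lohi
  fit$z0 <- z0
  fit$boot <- boot
  fit$B <- B
  fit$alpha <- alpha
  fit
}

#' Expected-accuracy curve over a training-size grid
#'
#' Table form of the fitted curve for plotting against empirical points.
#'
#' @param fit an `"ne_fit"`.
#' @param T_grid training sizes to evaluate (default: 50 points spanning the
#'   observed range).
#' @return data.frame with columns `T` and `r`.
#' @export
ne_curve_table <- function(fit, T_grid = NULL) {
  if (is.null(T_grid)) {
    T_grid <- seq(min(fit$points$T), max(fit$points$T), length.out = 50)
  }
  data.frame(T = T_grid,
             r = expected_accuracy(T_grid, fit$h2, fit$Ne_hat, fit$L_female,
                                   fit$variant, fit$ln_const))
}
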