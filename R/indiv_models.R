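#' @importFrom Matrix sparseMatrix crossprod t Diagonal
NULL

# Sparse incidence matrix mapping records to factor levels.
incidence <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# log-determinant and inverse of a covariance kernel, with a loud ridge if
# numerically singular.
kernel_inverse <- function(K, label) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    warning(label, " covariance is numerically singular; adding ridge ",
            "1e-8 * mean(diag)")
    ch <- chol(K + diag(1e-8 * mean(diag(K)), nrow(K)))
  }
  list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

# Likelihood machinery: V = sigma_e2 * (I + sum_k gamma_k Z_k K_k Z_k').
# Blocks with gamma = 0 are dropped from the Woodbury system.
# Sufficient statistics are precomputed once; each evaluation costs one
# Cholesky of a q x q matrix (q = total active random levels).
make_vc_loglik <- function(y, X, blocks, criterion) {
  N <- length(y)
  p <- ncol(X)
  Zall <- do.call(cbind, lapply(blocks, `[[`, "Z"))
  qk <- vapply(blocks, function(b) ncol(b$Z), 0L)
  offs <- cumsum(c(0L, qk))
  ZtZ <- as.matrix(Matrix::crossprod(Zall))
  ZtX <- as.matrix(Matrix::crossprod(Zall, X))
  Zty <- as.numeric(Matrix::crossprod(Zall, y))
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  yty <- sum(y^2)

  function(gamma) {
    active <- which(gamma > 0)
    if (length(active)) {
      cols <- unlist(lapply(active, function(k) (offs[k] + 1L):offs[k + 1L]))
      M <- ZtZ[cols, cols, drop = FALSE]
      logdetD <- 0
      at <- 0L
      for (k in active) {
        rng <- (at + 1L):(at + qk[k])
        if (is.null(blocks[[k]]$Kinv)) {
          diag(M)[rng] <- diag(M)[rng] + 1 / gamma[k]
          logdetD <- logdetD + qk[k] * log(gamma[k])
        } else {
          M[rng, rng] <- M[rng, rng] + blocks[[k]]$Kinv / gamma[k]
          logdetD <- logdetD + qk[k] * log(gamma[k]) + blocks[[k]]$logdetK
        }
        at <- at + qk[k]
      }
      R <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(R)) return(list(m2ll = Inf))
      logdetH <- 2 * sum(log(diag(R))) + logdetD
      u_y <- backsolve(R, Zty[cols], transpose = TRUE)
      u_X <- backsolve(R, ZtX[cols, , drop = FALSE], transpose = TRUE)
      yHy <- yty - sum(u_y^2)
      XHX <- XtX - crossprod(u_X)
      XHy <- Xty - as.numeric(crossprod(u_X, u_y))
    } else {
      logdetH <- 0
      yHy <- yty
      XHX <- XtX
      XHy <- Xty
    }
    chX <- tryCatch(chol(XHX), error = function(e) NULL)
    if (is.null(chX)) return(list(m2ll = Inf))
    beta <- backsolve(chX, backsolve(chX, XHy, transpose = TRUE))
    yPy <- yHy - sum(XHy * beta)
    if (yPy <= 0) return(list(m2ll = Inf))
    if (criterion == "REML") {
      df <- N - p
      s2 <- yPy / df
      m2ll <- df * (log(2 * pi) + 1) + df * log(s2) + logdetH +
        2 * sum(log(diag(chX)))
    } else {
      s2 <- yPy / N
      m2ll <- N * (log(2 * pi) + 1) + N * log(s2) + logdetH
    }
    list(m2ll = m2ll, sigma_e2 = s2, beta = beta)
  }
}

optimize_vc <- function(loglik_fn, n_terms, max_iter = 2000) {
  if (n_terms == 0) {
    ev <- loglik_fn(numeric(0))
    return(list(gamma = numeric(0), eval = ev, convergence = 0))
  }
  obj <- function(theta) loglik_fn(pmin(exp(theta), 1e8))$m2ll
  starts <- list(rep(log(0.5), n_terms), rep(log(0.05), n_terms))
  if (n_terms > 1) {
    # warm start at the optimum of the model without its last term, so the
    # fuller model never scores below its nested reduction
    sub <- optimize_vc(function(g) loglik_fn(c(g, 0)), n_terms - 1, max_iter)
    starts <- c(starts,
                list(c(log(pmax(sub$gamma, 1e-8)), log(1e-8))))
  }
  best <- NULL
  for (st in starts) {
    fit <- if (n_terms == 1) {
      optim(st, obj, method = "Brent", lower = -30, upper = 20,
            control = list(maxit = max_iter))
    } else {
      fit1 <- optim(st, obj, method = "Nelder-Mead",
                    control = list(maxit = max_iter, reltol = 1e-12))
      # one restart from the found optimum guards against premature collapse
      optim(fit1$par, obj, method = "Nelder-Mead",
            control = list(maxit = max_iter, reltol = 1e-12))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  gamma <- exp(best$par)
  # boundary projection: zero out vanishing components if that does not hurt
  for (k in order(gamma)) {
    if (gamma[k] < 1e-6) {
      g0 <- gamma
      g0[k] <- 0
      if (loglik_fn(g0)$m2ll <= loglik_fn(gamma)$m2ll + 1e-8) gamma <- g0
    }
  }
  if (best$convergence != 0 && best$value < Inf) {
    warning("variance-component optimizer reported convergence code ",
            best$convergence)
  }
  list(gamma = gamma, eval = loglik_fn(gamma), convergence = best$convergence)
}

#' Fit variance-component models to individual trait records
#'
#' Model 1: fixed sex effect, random line effect (identity covariance), random
#' line-by-sex interaction and a replicate term nested in (sex x line). Model 2
#' adds a genomic line effect with covariance `G sigma_a2`. Model 3 further
#' adds an additive-by-additive epistatic line effect with covariance
#' `(G o G) sigma_aa2` (Hadamard square). Per-sex fits drop the sex and
#' line-by-sex terms and reduce the replicate term to replicate(line).
#' Estimation is REML by default (ML optional); the likelihood is profiled
#' over the residual variance and maximized over variance ratios with
#' non-negativity enforced by boundary projection.
#'
#' @param records data.frame (`line`, `sex`, `replicate`, `value`).
#' @param model_id 1, 2 or 3.
#' @param G additive GRM (`"grm"` or matrix with line-id dimnames); required
#'   for models 2-3.
#' @param sex_mode `"pooled"` (default), `"F"` or `"M"`.
#' @param criterion `"REML"` (default) or `"ML"`.
#' @param include_replicate include the replicate term (set `FALSE` for data
#'   without replicate structure).
#' @param max_iter optimizer iteration cap.
#' @return object of class `"indiv_fit"`: list with `model`, `criterion`,
#'   `estimates` (named variance components incl. `sigma_e2`), `fixed`
#'   (effects), `loglik`, `convergence`, `n_records`, `sex_mode`, `terms`.
#' @export
fit_indiv_model <- function(records, model_id, G = NULL,
                            sex_mode = c("pooled", "F", "M"),
                            criterion = c("REML", "ML"),
                            include_replicate = TRUE, max_iter = 2000) {
  sex_mode <- match.arg(sex_mode)
  criterion <- match.arg(criterion)
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3")
  if (model_id >= 2 && is.null(G)) stop("models 2-3 require G")
  if (inherits(G, "grm")) G <- G$G
  if (sex_mode != "pooled") records <- records[records$sex == sex_mode, ]
  if (!nrow(records)) stop("no records for sex_mode ", sex_mode)
  lines <- sort(unique(records$line))
  if (!is.null(G)) {
    missing_lines <- setdiff(lines, rownames(G))
    if (length(missing_lines)) {
      stop("lines absent from G: ", paste(head(missing_lines, 5), collapse = ", "))
    }
    G <- G[lines, lines]
  }
  y <- records$value
  line_f <- factor(records$line, levels = lines)

  pooled <- sex_mode == "pooled"
  X <- if (pooled) {
    cbind(intercept = rep(1, length(y)), sexM = as.numeric(records$sex == "M"))
  } else {
    matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  }

  blocks <- list()
  blocks$line <- list(Z = incidence(line_f), Kinv = NULL, logdetK = 0)
  if (pooled) {
    blocks$sex_line <- list(Z = incidence(interaction(records$sex, line_f,
                                                      drop = TRUE)),
                            Kinv = NULL, logdetK = 0)
  }
  if (include_replicate) {
    repf <- if (pooled) {
      interaction(records$sex, line_f, records$replicate, drop = TRUE)
    } else {
      interaction(line_f, records$replicate, drop = TRUE)
    }
    if (nlevels(repf) < length(y)) {
      blocks$replicate <- list(Z = incidence(repf), Kinv = NULL, logdetK = 0)
    }
  }
  if (model_id >= 2) {
    ki <- kernel_inverse(G, "G")
    blocks$additive <- list(Z = incidence(line_f), Kinv = ki$inv,
                            logdetK = ki$logdet)
  }
  if (model_id == 3) {
    ki2 <- kernel_inverse(G * G, "G o G")
    blocks$epistatic <- list(Z = incidence(line_f), Kinv = ki2$inv,
                             logdetK = ki2$logdet)
  }

  llf <- make_vc_loglik(y, X, blocks, criterion)
  opt <- optimize_vc(llf, length(blocks), max_iter)
  if (!is.finite(opt$eval$m2ll)) {
    stop("variance-component fit did not converge; last gamma = ",
         paste(signif(opt$gamma, 4), collapse = ", "))
  }
  s2e <- opt$eval$sigma_e2
  comp <- opt$gamma * s2e
  names(comp) <- paste0("sigma_", c(line = "line2", sex_line = "sexline2",
                                    replicate = "rep2", additive = "a2",
                                    epistatic = "aa2")[names(blocks)])
  fixed <- as.numeric(opt$eval$beta)
  names(fixed) <- colnames(X)
  structure(list(model = model_id, criterion = criterion,
                 estimates = c(comp, sigma_e2 = unname(s2e)), fixed = fixed,
                 loglik = unname(-0.5 * opt$eval$m2ll),
                 convergence = opt$convergence,
                 n_records = length(y), sex_mode = sex_mode,
                 terms = names(blocks)),
            class = "indiv_fit")
}

#' @export
print.indiv_fit <- function(x, ...) {
  cat(sprintf("indiv_fit model %d (%s, %s): loglik %.4f\n", x$model,
              x$criterion, x$sex_mode, x$loglik))
  print(signif(x$estimates, 5))
  invisible(x)
}

#' Likelihood-ratio test for one boundary variance component
#'
#' `statistic = 2 * (loglik_full - loglik_reduced)`; because the tested
#' variance lies on the boundary of the parameter space, the null distribution
#' is the mixture `0.5 chi2_0 + 0.5 chi2_1` (a plain chi2_1 is available as a
#' conservative option).
#'
#' @param fit_reduced,fit_full nested `"indiv_fit"` objects on the same data
#'   and criterion.
#' @param mixture use the boundary mixture (default) or plain chi2_1.
#' @return list with `statistic`, `p_value`, `df = 1`.
#' @export
lrt <- function(fit_reduced, fit_full, mixture = TRUE) {
  if (fit_reduced$criterion != fit_full$criterion) {
    stop("fits use different criteria")
  }
  if (fit_reduced$n_records != fit_full$n_records) {
    stop("fits appear to use different data")
  }
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-4) {
    stop("negative LRT statistic (", signif(stat, 4),
         "): the full model fit failed to dominate the reduced fit")
  }
  stat <- max(0, stat)
  p <- if (mixture) {
    0.5 * (stat <= 0) + 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, df = 1)
}

#' Broad-sense heritability from a Model-1 fit
#'
#' `H2 = sigma_line2 / (sigma_line2 + sigma_sexline2 + sigma_rep2 + sigma_e2)`
#' by default; the non-residual denominator terms can be toggled.
#'
#' @param fit a model-1 `"indiv_fit"`.
#' @param include_sexline,include_rep include the respective terms in the
#'   denominator when present.
#' @return H2 in \[0, 1\].
#' @export
broad_sense_h2 <- function(fit, include_sexline = TRUE, include_rep = TRUE) {
  est <- fit$estimates
  num <- est[["sigma_line2"]]
  den <- num + est[["sigma_e2"]]
  if (include_sexline && "sigma_sexline2" %in% names(est)) {
    den <- den + est[["sigma_sexline2"]]
  }
  if (include_rep && "sigma_rep2" %in% names(est)) {
    den <- den + est[["sigma_rep2"]]
  }
  if (den == 0) stop("total variance is zero; H2 undefined")
  num / den
}

#' Narrow-sense heritability from a Model-2 or Model-3 fit
#'
#' `h2 = sigma_a2 / (sum of all estimated variance components)`; in Model 3
#' the epistatic variance enters the denominator but not the numerator.
#'
#' @param fit a model-2 or model-3 `"indiv_fit"`.
#' @return h2 in \[0, 1\].
#' @export
narrow_sense_h2_indiv <- function(fit) {
  est <- fit$estimates
  if (!"sigma_a2" %in% names(est)) {
    stop("fit has no additive genomic component (model 2 or 3 required)")
  }
  den <- sum(est)
  if (den == 0) stop("total variance is zero; h2 undefined")
  est[["sigma_a2"]] / den
}
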