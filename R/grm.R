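#' Apply sequence-data SNP filters
#'
#' Retains SNPs with coverage strictly greater than `cov_min` and strictly less
#' than `cov_max`, whose minor allele is present in at least `min_minor_lines`
#' lines, and which are called in at least `min_called` lines. A filter is
#' skipped (with a message) when its annotation is absent and it was not
#' explicitly requested; passing `NULL` disables a filter.
#'
#' @param gm a [geno_matrix()].
#' @param cov_min,cov_max coverage window (exclusive on both sides).
#' @param min_minor_lines minimum number of lines carrying the minor allele.
#' @param min_called minimum number of lines with a called genotype.
#' @param verbose log per-filter removal counts.
#' @return filtered [geno_matrix()], SNP order preserved; attribute
#'   `"filter_report"` holds the per-filter removal counts.
#' @export
apply_snp_filters <- function(gm, cov_min = 2, cov_max = 30,
                              min_minor_lines = 4, min_called = 60,
                              verbose = FALSE) {
  m <- ncol(gm$codes)
  keep <- rep(TRUE, m)
  report <- c()
  if (!is.null(cov_min) || !is.null(cov_max)) {
    if (is.null(gm$snp_meta$coverage)) {
      stop("coverage filter requested but snp_meta has no coverage column")
    }
    cv <- gm$snp_meta$coverage
    ok <- (is.null(cov_min) | cv > cov_min) & (is.null(cov_max) | cv < cov_max)
    report["coverage"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(min_called)) {
    nc <- gm$snp_meta$n_called
    if (is.null(nc)) nc <- colSums(!is.na(gm$codes))
    ok <- nc >= min_called
    report["n_called"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(min_minor_lines)) {
    # number of lines carrying >=1 copy of the rarer allele
    carrier <- apply(gm$codes, 2, function(x) {
      x <- x[!is.na(x)]
      min(sum(x > 0), sum(x < 2))
    })
    ok <- carrier >= min_minor_lines
    report["minor_lines"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!any(keep)) stop("all SNPs removed by filters")
  if (verbose) {
    message("SNP filters removed: ",
            paste(names(report), report, sep = "=", collapse = ", "),
            "; retained ", sum(keep), "/", m)
  }
  out <- subset_geno(gm, snps = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Naive per-SNP mode imputation of missing genotypes
#'
#' Sets each missing cell to the most frequent code of its SNP among called
#' lines; ties resolve to the lower code. A simple stand-in for
#' haplotype-model imputation.
#'
#' @param gm a [geno_matrix()].
#' @return a [geno_matrix()] without missing cells.
#' @export
impute_missing_naive <- function(gm) {
  codes <- gm$codes
  nmiss <- colSums(is.na(codes))
  for (j in which(nmiss > 0)) {
    x <- codes[, j]
    called <- x[!is.na(x)]
    if (!length(called)) stop("SNP ", colnames(codes)[j], " has zero called lines")
    tab <- tabulate(called + 1L, nbins = 3L)  # counts of codes 0,1,2
    mode <- which(tab == max(tab))[1] - 1L    # tie -> lower code
    x[is.na(x)] <- mode
    codes[, j] <- x
  }
  geno_matrix(codes, gm$line_ids, gm$snp_meta)
}

#' Compute the genomic relationship matrix
#'
#' VanRaden's method 1: `G = ZZ' / (2 * sum(p_j (1 - p_j)))` with
#' `Z = W - 2P`, where column j of `2P` is `2 p_j` and `p_j` is the frequency
#' of the second allele computed from the analyzed lines themselves. The
#' alternative `scaling = "per_snp"` standardizes each column by
#' `sqrt(2 p_j (1 - p_j))` and divides by the SNP count.
#'
#' @param gm a [geno_matrix()] with no missing cells and no monomorphic SNP.
#' @param scaling `"vanraden1"` (default) or `"per_snp"`.
#' @param psd_tol PSD guard: an eigenvalue below `-psd_tol * trace(G)` is an
#'   error rather than silently bent.
#' @param check_psd verify positive semi-definiteness (costs one
#'   eigendecomposition).
#' @return an object of class `"grm"`: list with `G` (n x n, dimnames =
#'   line ids), `kind = "additive"`, `n_snps_used`, `denominator`, `p` (allele
#'   frequencies used).
#' @export
compute_grm <- function(gm, scaling = c("vanraden1", "per_snp"),
                        psd_tol = 1e-8, check_psd = FALSE) {
  scaling <- match.arg(scaling)
  W <- gm$codes
  if (anyNA(W)) stop("missing genotypes present; impute first")
  p <- colMeans(W) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop(sum(mono), " monomorphic SNP(s) present (e.g. ",
         colnames(W)[which(mono)[1]], "); apply filters first")
  }
  Z <- sweep(W, 2, 2 * p)
  if (scaling == "vanraden1") {
    denom <- 2 * sum(p * (1 - p))
    G <- tcrossprod(Z) / denom
  } else {
    Zs <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    denom <- ncol(W)
    G <- tcrossprod(Zs) / denom
  }
  dimnames(G) <- list(gm$line_ids, gm$line_ids)
  res <- structure(list(G = G, kind = "additive", n_snps_used = ncol(W),
                        denominator = denom, p = p, scaling = scaling),
                   class = "grm")
  if (check_psd) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -psd_tol * sum(diag(G))) {
      stop("G fails the PSD guard: min eigenvalue ", min(ev))
    }
  }
  res
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d x %d from %d SNPs, denominator %.4g\n",
              x$kind, nrow(x$G), ncol(x$G), x$n_snps_used, x$denominator))
  invisible(x)
}

#' Hadamard square of an additive GRM
#'
#' Elementwise square `G * G`, the covariance structure of additive-by-additive
#' epistatic line effects. PSD is inherited from G (Schur product theorem).
#'
#' @param grm an additive `"grm"`.
#' @return a `"grm"` with `kind = "hadamard_epistatic"`.
#' @export
hadamard_square <- function(grm) {
  if (!inherits(grm, "grm") || grm$kind != "additive") {
    stop("hadamard_square expects an additive grm")
  }
  out <- grm
  out$G <- grm$G * grm$G
  out$kind <- "hadamard_epistatic"
  out
}

#' Write / read a GRM as a symmetric text matrix with line-id header
#'
#' @param grm a `"grm"`.
#' @param path output path.
#' @return `path` invisibly (write); a numeric matrix with dimnames (read).
#' @export
write_grm <- function(grm, path) {
  write.table(grm$G, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm_matrix <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                       check.names = FALSE))
}
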