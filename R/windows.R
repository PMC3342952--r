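#' Single-marker regression GWAS on line phenotypes
#'
#' Simple regression of the line phenotype on the allele-count code of each
#' SNP with two-sided p-values; a stand-in generator of association anchors
#' for the window comparison. Monomorphic SNPs get p = 1 and a flag.
#'
#' @param pheno line phenotype table (or individual records, summarized first)
#'   matching the lines of `gm`.
#' @param gm a [geno_matrix()].
#' @param trait which phenotype column: `"avg"`, `"M"` or `"F"`.
#' @return data.frame per SNP: `chrom_arm`, `pos_bp`, `beta`, `p_value`,
#'   `monomorphic`.
#' @export
single_marker_gwas <- function(pheno, gm, trait = "avg") {
  if (!is.null(pheno$value)) pheno <- summarize_line_phenotypes(pheno)
  keep <- intersect(gm$line_ids, pheno$line)
  if (length(keep) < 3) stop("need >= 3 lines with phenotype and genotype")
  gm <- subset_geno(gm, lines = keep)
  y <- pheno_column(pheno[match(keep, pheno$line), ], trait)
  W <- gm$codes
  n <- length(y)
  sw <- apply(W, 2, sd)
  mono <- sw == 0
  r <- rep(0, ncol(W))
  if (sd(y) > 0) {
    r[!mono] <- suppressWarnings(as.numeric(cor(y, W[, !mono, drop = FALSE])))
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[mono] <- 1
  beta <- r * sd(y) / ifelse(mono, NA, sw)
  data.frame(chrom_arm = gm$snp_meta$chrom_arm, pos_bp = gm$snp_meta$pos_bp,
             beta = beta, p_value = p, monomorphic = mono, row.names = NULL)
}

split_by_arm <- function(effects) {
  arms <- unique(effects$chrom_arm)
  lapply(arms, function(a) which(effects$chrom_arm == a))
}

as_effects_df <- function(effects) {
  if (is.numeric(effects)) {
    effects <- data.frame(chrom_arm = "1", pos_bp = seq_along(effects),
                          effect = effects)
  }
  if (!all(c("chrom_arm", "pos_bp", "effect") %in% names(effects))) {
    stop("effects need columns chrom_arm, pos_bp, effect")
  }
  effects
}

#' Sliding-window sums of absolute SNP effects
#'
#' Background distribution: per chromosome arm, overlapping windows of `w`
#' adjacent SNPs displaced by `step` SNPs; each window's statistic is the sum
#' of |effect|. Windows never span arm boundaries. On a single arm the window
#' count is `floor((m - w) / step) + 1`.
#'
#' @param effects a `"snp_effects"` data.frame (or plain numeric vector,
#'   treated as one arm).
#' @param w window size in SNPs (default 100).
#' @param step displacement in SNPs (default 10).
#' @return data.frame per window: `chrom_arm`, `start_bp`, `end_bp`, `sum_abs`.
#' @export
sliding_window_sums <- function(effects, w = 100, step = 10) {
  effects <- as_effects_df(effects)
  out <- list()
  for (idx in split_by_arm(effects)) {
    m <- length(idx)
    if (w > m) next
    starts <- seq(1, m - w + 1, by = step)
    ae <- abs(effects$effect[idx])
    cs <- c(0, cumsum(ae))
    out[[length(out) + 1L]] <- data.frame(
      chrom_arm = effects$chrom_arm[idx[1]],
      start_bp = effects$pos_bp[idx[starts]],
      end_bp = effects$pos_bp[idx[starts + w - 1]],
      sum_abs = cs[starts + w] - cs[starts])
  }
  if (!length(out)) stop("window size w exceeds the SNP count on every arm")
  do.call(rbind, out)
}

#' Anchored window sums around top association positions
#'
#' Takes the `k` most significant anchors, maps each to the SNP list, and sums
#' |effect| over the anchor SNP plus its `per_side` nearest neighbors on each
#' side within the arm (window truncated at arm ends, truncation recorded).
#'
#' @param effects a `"snp_effects"` data.frame.
#' @param anchors data.frame with `chrom_arm`, `pos_bp` and `p_value`.
#' @param k number of top anchors by significance (default 75).
#' @param per_side neighbors on each side (default 50, i.e. 101-SNP windows
#'   including the anchor).
#' @return data.frame per anchor: `chrom_arm`, `pos_bp`, `p_value`, `sum_abs`,
#'   `n_snps`, `truncated`.
#' @export
anchored_window_sums <- function(effects, anchors, k = 75, per_side = 50) {
  effects <- as_effects_df(effects)
  if (k > nrow(anchors)) stop("k exceeds the number of anchors")
  anchors <- anchors[order(anchors$p_value), ][seq_len(k), ]
  arm_idx <- split_by_arm(effects)
  names(arm_idx) <- vapply(arm_idx, function(i) effects$chrom_arm[i[1]], "")
  res <- lapply(seq_len(k), function(i) {
    a <- anchors[i, ]
    idx <- arm_idx[[as.character(a$chrom_arm)]]
    if (is.null(idx)) stop("anchor arm not in SNP map: ", a$chrom_arm)
    j <- match(a$pos_bp, effects$pos_bp[idx])
    if (is.na(j)) {
      stop("anchor not mappable to the SNP list: ", a$chrom_arm, ":", a$pos_bp)
    }
    lo <- max(1, j - per_side)
    hi <- min(length(idx), j + per_side)
    data.frame(chrom_arm = a$chrom_arm, pos_bp = a$pos_bp,
               p_value = a$p_value,
               sum_abs = sum(abs(effects$effect[idx[lo:hi]])),
               n_snps = hi - lo + 1,
               truncated = (hi - lo + 1) < (2 * per_side + 1))
  })
  do.call(rbind, res)
}

#' Exceedance of anchored window sums over a background quantile
#'
#' `threshold` is the empirical `q`-quantile (type-7 interpolation) of the
#' background sliding-window sums; the reported fraction is the share of
#' anchored sums strictly above it. If GWAS signals coincide with regions of
#' large SNP effects, the fraction exceeds `1 - q`.
#'
#' @param background numeric window sums (or the data.frame from
#'   [sliding_window_sums()]).
#' @param anchored numeric anchored sums (or the data.frame from
#'   [anchored_window_sums()]).
#' @param q background quantile in (0, 1), default 0.90.
#' @return list with `threshold` and `fraction`.
#' @export
exceedance <- function(background, anchored, q = 0.90) {
  if (is.data.frame(background)) background <- background$sum_abs
  if (is.data.frame(anchored)) anchored <- anchored$sum_abs
  if (!length(background) || !length(anchored)) stop("empty input sample")
  if (q <= 0 || q >= 1) stop("q must be inside (0, 1)")
  thr <- quantile(background, q, type = 7, names = FALSE)
  list(threshold = thr, fraction = mean(anchored > thr))
}
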