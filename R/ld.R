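#' Squared correlation of allele frequencies between two loci
#'
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))` with `D = p_AB - p_A p_B`.
#' Fully inbred lines are haplotypes, so haplotype frequencies are counted
#' directly from the \{0, 2\} genotype columns; heterozygous inputs are
#' rejected rather than phased.
#'
#' @param col_a,col_b genotype code columns in \{0, 2\}, both polymorphic.
#' @return r-squared in \[0, 1\].
#' @export
r_squared <- function(col_a, col_b) {
  if (any(col_a == 1L, na.rm = TRUE) || any(col_b == 1L, na.rm = TRUE)) {
    stop("heterozygous codes present; r_squared expects inbred {0,2} columns")
  }
  ok <- !is.na(col_a) & !is.na(col_b)
  xa <- col_a[ok] / 2
  xb <- col_b[ok] / 2
  pa <- mean(xa); pb <- mean(xb)
  if (pa <= 0 || pa >= 1) stop("col_a is monomorphic")
  if (pb <= 0 || pb >= 1) stop("col_b is monomorphic")
  D <- mean(xa * xb) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

ld_pair_table <- function(gm, ia, ib, category) {
  meta <- gm$snp_meta
  r2 <- vapply(seq_along(ia), function(k) {
    r_squared(gm$codes[, ia[k]], gm$codes[, ib[k]])
  }, 0)
  same_arm <- meta$chrom_arm[ia] == meta$chrom_arm[ib]
  data.frame(
    snp_a = colnames(gm$codes)[ia], snp_b = colnames(gm$codes)[ib],
    r2 = r2,
    distance_bp = ifelse(same_arm, abs(meta$pos_bp[ib] - meta$pos_bp[ia]), NA),
    distance_morgan = ifelse(same_arm,
                             abs(meta$pos_morgan[ib] - meta$pos_morgan[ia]), NA),
    category = category, row.names = NULL)
}

#' Drop monomorphic SNP columns
#'
#' Keeps SNPs with allele frequency strictly between 0 and 1 among the current
#' lines; needed after subsetting lines and before GRM or LD computations.
#'
#' @param gm a [geno_matrix()].
#' @return a [geno_matrix()] with only polymorphic SNPs.
#' @export
drop_monomorphic <- function(gm) {
  p <- allele_freq(gm)
  subset_geno(gm, snps = which(p > 0 & p < 1))
}

#' Distribution of LD between neighboring SNPs under thinning
#'
#' Keeps every `thin_k`-th SNP of the genome-wide ordered list and computes r2
#' for all pairs of retained SNPs that are adjacent within a chromosome arm
#' (the marker-density series of neighbor LD).
#'
#' @param gm a [geno_matrix()] of inbred lines, ordered by (arm, pos).
#' @param thin_k thinning factor (1 = all SNPs).
#' @param breaks r2 bin edges for the binned summary.
#' @return object of class `"ld_dist"`: list with `pairs` (data.frame),
#'   `mean_r2`, `bin_counts`, `thin_k`.
#' @export
neighbor_ld_distribution <- function(gm, thin_k = 1,
                                     breaks = seq(0, 1, by = 0.1)) {
  gm <- drop_monomorphic(gm)
  m <- ncol(gm$codes)
  keep <- seq(1, m, by = thin_k)
  ia <- keep[-length(keep)]
  ib <- keep[-1]
  same <- gm$snp_meta$chrom_arm[ia] == gm$snp_meta$chrom_arm[ib]
  ia <- ia[same]; ib <- ib[same]
  if (!length(ia)) stop("fewer than 2 retained SNPs on every arm after thinning")
  pairs <- ld_pair_table(gm, ia, ib, paste0("neighbor@k=", thin_k))
  bins <- table(cut(pairs$r2, breaks = breaks, include.lowest = TRUE))
  structure(list(pairs = pairs, mean_r2 = mean(pairs$r2),
                 bin_counts = bins, thin_k = thin_k),
            class = "ld_dist")
}

#' Long-range LD between arm ends or across arms
#'
#' `mode = "ends_of_arm"` samples pairs with one SNP in the first and one in
#' the last `end_window` SNPs of the same arm; `mode = "across_arms"` samples
#' pairs from different chromosome arms (no distance defined). With
#' independent loci the expected r2 is about `1/n` (sampling noise floor).
#'
#' @param gm a [geno_matrix()] of inbred lines.
#' @param n_pairs pairs to sample per mode (capped at the number available,
#'   sampling without replacement).
#' @param mode `"ends_of_arm"` or `"across_arms"`.
#' @param end_window SNPs counted as an arm end.
#' @param seed integer seed.
#' @return an `"ld_dist"` object.
#' @export
long_range_ld <- function(gm, n_pairs = 1000,
                          mode = c("ends_of_arm", "across_arms"),
                          end_window = 5000, seed = NULL) {
  mode <- match.arg(mode)
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  gm <- drop_monomorphic(gm)
  meta <- gm$snp_meta
  arms <- unique(meta$chrom_arm)
  with_seed(seed, {
    if (mode == "ends_of_arm") {
      cand <- list()
      for (a in arms) {
        idx <- which(meta$chrom_arm == a)
        if (length(idx) < 2 * end_window) {
          stop("arm ", a, " too short for end windows of ", end_window, " SNPs")
        }
        first <- idx[seq_len(end_window)]
        last <- idx[seq(length(idx) - end_window + 1, length(idx))]
        cand[[a]] <- expand.grid(a = first, b = last)
      }
      cand <- do.call(rbind, cand)
    } else {
      if (length(arms) < 2) stop("across_arms mode needs >= 2 arms")
      m <- nrow(meta)
      arm_of <- meta$chrom_arm
      if (m <= 1500) {
        cand <- expand.grid(a = seq_len(m), b = seq_len(m))
        cand <- cand[arm_of[cand$a] < arm_of[cand$b], ]
      } else {
        # large panels: rejection-sample unique cross-arm pairs
        draw <- function(k) {
          a <- sample.int(m, k, replace = TRUE)
          b <- sample.int(m, k, replace = TRUE)
          ok <- arm_of[a] != arm_of[b]
          unique(data.frame(a = pmin(a, b)[ok], b = pmax(a, b)[ok]))
        }
        cand <- draw(4L * n_pairs)
        while (nrow(cand) < n_pairs) cand <- unique(rbind(cand, draw(2L * n_pairs)))
      }
    }
    take <- sample.int(nrow(cand), min(n_pairs, nrow(cand)))
    pairs <- ld_pair_table(gm, cand$a[take], cand$b[take], mode)
    structure(list(pairs = pairs, mean_r2 = mean(pairs$r2),
                   bin_counts = table(cut(pairs$r2, seq(0, 1, 0.1),
                                          include.lowest = TRUE)),
                   mode = mode),
              class = "ld_dist")
  })
}

#' @export
print.ld_dist <- function(x, ...) {
  cat(sprintf("ld_dist: %d pairs, mean r2 = %.4f\n", nrow(x$pairs), x$mean_r2))
  invisible(x)
}

#' Sample within-arm SNP pairs in a Morgan-distance window
#'
#' Utility for distance-binned LD summaries (the input to [sved_ne()]): draws
#' up to `max_pairs` SNP pairs on the same arm whose female-map distance falls
#' in `[min_morgan, max_morgan]`.
#'
#' @param gm a [geno_matrix()] of inbred lines.
#' @param min_morgan,max_morgan distance window (female Morgan).
#' @param max_pairs cap on sampled pairs.
#' @param seed integer seed.
#' @return data.frame of pairs with `r2`, `distance_bp`, `distance_morgan`.
#' @export
sample_ld_pairs <- function(gm, min_morgan, max_morgan, max_pairs = 2000,
                            seed = NULL) {
  gm <- drop_monomorphic(gm)
  meta <- gm$snp_meta
  with_seed(seed, {
    cand_a <- integer(0); cand_b <- integer(0)
    for (a in unique(meta$chrom_arm)) {
      idx <- which(meta$chrom_arm == a)
      pos <- meta$pos_morgan[idx]
      lo <- findInterval(pos + min_morgan, pos) + 1L
      hi <- findInterval(pos + max_morgan, pos)
      ok <- which(lo <= hi)
      for (i in ok) {
        cand_a <- c(cand_a, rep(idx[i], hi[i] - lo[i] + 1L))
        cand_b <- c(cand_b, idx[lo[i]:hi[i]])
      }
    }
    if (!length(cand_a)) stop("no SNP pairs in the requested distance window")
    take <- sample.int(length(cand_a), min(max_pairs, length(cand_a)))
    ld_pair_table(gm, cand_a[take], cand_b[take],
                  sprintf("dist[%g,%g]M", min_morgan, max_morgan))
  })
}

#' LD-based effective population size (Sved's formula)
#'
#' Inverts `E[r2] = 1 / (1 + 4 Ne c_eff) + 1/n` for Ne, where `1/n` is the
#' finite-sample baseline, `c_eff = sex_averaging_factor * c_female` is the
#' sex-averaged recombination rate (no recombination in male Drosophila), and
#' the estimate refers to roughly `1 / (2 c_eff)` generations ago.
#'
#' @param mean_r2 mean r2 in a distance bin (> 1/n_lines).
#' @param c_female female recombination distance of the bin, Morgan.
#' @param n_lines number of lines the r2 values were computed from.
#' @param sex_averaging_factor multiplier turning the female rate into the
#'   sex-averaged rate; default 0.5.
#' @return object of class `"ne_ld"`: list with `Ne_hat`, `c_eff`, `c_female`,
#'   `n_lines`, `generations_ago`, `mean_r2`.
#' @export
sved_ne <- function(mean_r2, c_female, n_lines, sex_averaging_factor = 0.5) {
  if (c_female <= 0) stop("c_female must be positive")
  adj <- mean_r2 - 1 / n_lines
  if (adj <= 0) {
    stop("mean_r2 <= 1/n: LD is at the sampling noise floor, Ne unbounded")
  }
  c_eff <- sex_averaging_factor * c_female
  ne <- (1 / adj - 1) / (4 * c_eff)
  structure(list(Ne_hat = ne, c_eff = c_eff, c_female = c_female,
                 n_lines = n_lines, generations_ago = 1 / (2 * c_eff),
                 mean_r2 = mean_r2),
            class = "ne_ld")
}

#' @export
print.ne_ld <- function(x, ...) {
  cat(sprintf("Sved Ne estimate: %.1f (mean r2 %.4f at c_eff %.4g, ~%.0f generations ago)\n",
              x$Ne_hat, x$mean_r2, x$c_eff, x$generations_ago))
  invisible(x)
}
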