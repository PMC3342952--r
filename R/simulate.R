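#' Default Drosophila-like genetic map
#'
#' Five major chromosome arms with physical lengths close to the euchromatic
#' arm sizes of the D. melanogaster reference and female map lengths summing to
#' about 2.9 Morgan. Males do not recombine; all Morgan lengths are female map
#' lengths.
#'
#' @return data.frame with columns `chrom_arm`, `length_bp`,
#'   `length_morgan_female`.
#' @export
dgrp_map <- function() {
  data.frame(
    chrom_arm = c("2L", "2R", "3L", "3R", "X"),
    length_bp = c(23.0e6, 21.1e6, 24.5e6, 27.9e6, 22.4e6),
    length_morgan_female = c(0.55, 0.53, 0.55, 0.55, 0.70)
  )
}

#' Specify a base population for forward simulation
#'
#' @param Ne_sim number of diploid individuals per generation (>= 2).
#' @param n_snps number of sites seeded at generation 0; only sites still
#'   segregating at the end are retained.
#' @param n_generations_base generations of random mating simulated forward.
#' @param map data.frame of arms as in [dgrp_map()]; arms assort independently
#'   and recombine only in females (Haldane model, no interference).
#' @param mutation_rate per-site, per-gamete allele-flip probability.
#' @param init_freq_range range of the uniform distribution founder allele
#'   frequencies are drawn from.
#' @return an object of class `"pop_spec"`.
#' @export
population_spec <- function(Ne_sim = 100, n_snps = 5000,
                            n_generations_base = 200, map = dgrp_map(),
                            mutation_rate = 0, init_freq_range = c(0.05, 0.95)) {
  if (Ne_sim < 2) stop("Ne_sim must be >= 2")
  if (any(map$length_morgan_female < 0)) stop("female map lengths must be >= 0")
  if (any(map$length_bp <= 0)) stop("length_bp must be positive")
  structure(list(Ne_sim = as.integer(Ne_sim), n_snps = as.integer(n_snps),
                 n_generations_base = as.integer(n_generations_base),
                 map = map, mutation_rate = mutation_rate,
                 init_freq_range = init_freq_range),
            class = "pop_spec")
}

# Column indices and female Morgan positions per arm, for fast gamete assembly.
arm_layout <- function(snp_meta, map) {
  arms <- map$chrom_arm
  list(idx = lapply(arms, function(a) which(snp_meta$chrom_arm == a)),
       len = map$length_morgan_female,
       pos = lapply(arms, function(a) snp_meta$pos_morgan[snp_meta$chrom_arm == a]))
}

# One female (recombinant) gamete. h1/h2: parental haplotypes (0/1 vectors).
female_gamete <- function(h1, h2, lay) {
  out <- h1
  for (a in seq_along(lay$idx)) {
    idx <- lay$idx[[a]]
    if (!length(idx)) next
    nx <- rpois(1L, lay$len[a])
    if (nx == 0L) {
      if (runif(1) < 0.5) out[idx] <- h2[idx]
    } else {
      x <- sort(runif(nx, 0, lay$len[a]))
      take2 <- (findInterval(lay$pos[[a]], x) + (runif(1) < 0.5)) %% 2L == 1L
      seg <- idx[take2]
      out[seg] <- h2[seg]
    }
  }
  out
}

# One male gamete: no recombination, one intact homolog per arm.
male_gamete <- function(h1, h2, lay) {
  out <- h1
  for (a in seq_along(lay$idx)) {
    idx <- lay$idx[[a]]
    if (length(idx) && runif(1) < 0.5) out[idx] <- h2[idx]
  }
  out
}

#' Simulate a base population by forward Wright-Fisher mating
#'
#' Discrete generations, random union of gametes: every offspring receives one
#' recombinant maternal gamete (crossovers Poisson on the female Morgan map,
#' Haldane, no interference) and one intact paternal gamete per arm (no male
#' recombination). Diversity enters as standing variation at generation 0, with
#' per-site founder frequencies drawn uniformly from `init_freq_range`;
#' `mutation_rate` optionally flips alleles in gametes. Sites fixed by drift
#' are dropped from the returned panel.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; identical seeds give identical panels.
#' @return an object of class `"hap_panel"`: list with `haps`
#'   (2*Ne_sim x n_segregating 0/1 matrix; rows 2i-1, 2i are individual i),
#'   `snp_meta`, and `spec`.
#' @export
simulate_base_population <- function(spec, seed = NULL) with_seed(seed, {
  map <- spec$map
  frac <- map$length_bp / sum(map$length_bp)
  m_arm <- pmax(2L, round(spec$n_snps * frac))
  meta <- do.call(rbind, lapply(seq_len(nrow(map)), function(a) {
    pos <- sort(sample.int(map$length_bp[a], m_arm[a]))
    data.frame(chrom_arm = map$chrom_arm[a], pos_bp = pos,
               pos_morgan = pos / map$length_bp[a] * map$length_morgan_female[a])
  }))
  m <- nrow(meta)
  nh <- 2L * spec$Ne_sim
  p0 <- runif(m, spec$init_freq_range[1], spec$init_freq_range[2])
  haps <- matrix(rbinom(nh * m, 1L, rep(p0, each = nh)), nrow = nh)
  lay <- arm_layout(meta, map)
  Ne <- spec$Ne_sim
  for (gen in seq_len(spec$n_generations_base)) {
    nxt <- matrix(0L, nh, m)
    mothers <- sample.int(Ne, Ne, replace = TRUE)
    fathers <- sample.int(Ne, Ne, replace = TRUE)
    for (i in seq_len(Ne)) {
      mg <- female_gamete(haps[2L * mothers[i] - 1L, ], haps[2L * mothers[i], ], lay)
      pg <- male_gamete(haps[2L * fathers[i] - 1L, ], haps[2L * fathers[i], ], lay)
      if (spec$mutation_rate > 0) {
        flip <- runif(m) < spec$mutation_rate
        mg[flip] <- 1L - mg[flip]
        flip <- runif(m) < spec$mutation_rate
        pg[flip] <- 1L - pg[flip]
      }
      nxt[2L * i - 1L, ] <- mg
      nxt[2L * i, ] <- pg
    }
    haps <- nxt
  }
  f <- colMeans(haps)
  keep <- f > 0 & f < 1
  if (!any(keep)) {
    stop("all sites fixed by drift; increase n_snps, reduce generations, ",
         "or add mutation")
  }
  structure(list(haps = haps[, keep, drop = FALSE],
                 snp_meta = meta[keep, , drop = FALSE], spec = spec),
            class = "hap_panel")
})

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes x %d segregating sites\n",
              nrow(x$haps), ncol(x$haps)))
  invisible(x)
}

#' Derive fully inbred lines by repeated full-sib mating
#'
#' Each line starts from a random pair of distinct base-population individuals
#' and is propagated by brother-sister mating for `n_gen_fullsib` generations
#' (one brother and one sister kept per generation; female meiosis recombines,
#' male meiosis does not). One individual of the final generation is genotyped.
#' With `force_homozygous = TRUE` (the default, matching the \{0,2\} analysis
#' assumption) residual heterozygous calls are set to the major allele among
#' the final sib pair's four haplotypes, ties to the lower code; with `FALSE`
#' the raw genotype (codes 0/1/2) is returned.
#'
#' @param panel a `"hap_panel"` from [simulate_base_population()].
#' @param n_lines number of lines (independent lineages).
#' @param n_gen_fullsib generations of full-sib mating; 0 genotypes a base
#'   founder directly (outbred).
#' @param seed integer seed.
#' @param force_homozygous force residual heterozygotes to homozygous codes.
#' @return a [geno_matrix()] with `n_lines` rows.
#' @export
derive_inbred_lines <- function(panel, n_lines, n_gen_fullsib = 20,
                                seed = NULL, force_homozygous = TRUE) {
  with_seed(seed, {
    Ne <- nrow(panel$haps) / 2L
    npairs <- choose(Ne, 2)
    if (n_lines > npairs) {
      stop("n_lines (", n_lines, ") exceeds distinct founder pairs available (",
           npairs, ")")
    }
    lay <- arm_layout(panel$snp_meta, panel$spec$map)
    m <- ncol(panel$haps)
    codes <- matrix(0L, n_lines, m)
    used <- character(0)
    for (l in seq_len(n_lines)) {
      repeat {
        pr <- sort(sample.int(Ne, 2L))
        key <- paste(pr, collapse = "-")
        if (!key %in% used) { used <- c(used, key); break }
      }
      fh <- list(panel$haps[2L * pr[1] - 1L, ], panel$haps[2L * pr[1], ])
      mh <- list(panel$haps[2L * pr[2] - 1L, ], panel$haps[2L * pr[2], ])
      if (n_gen_fullsib == 0) {
        codes[l, ] <- fh[[1]] + fh[[2]]
        next
      }
      for (g in seq_len(n_gen_fullsib)) {
        s1 <- list(female_gamete(fh[[1]], fh[[2]], lay),
                   male_gamete(mh[[1]], mh[[2]], lay))
        s2 <- list(female_gamete(fh[[1]], fh[[2]], lay),
                   male_gamete(mh[[1]], mh[[2]], lay))
        fh <- s1
        mh <- s2
      }
      gt <- fh[[1]] + fh[[2]]
      if (force_homozygous) {
        het <- gt == 1L
        if (any(het)) {
          cnt <- fh[[1]] + fh[[2]] + mh[[1]] + mh[[2]]  # copies of allele 1 in 4 haps
          gt[het] <- ifelse(cnt[het] > 2L, 2L, 0L)      # tie (2 of 4) -> lower code
        }
      }
      codes[l, ] <- gt
    }
    gm <- geno_matrix(codes, sprintf("line_%03d", seq_len(n_lines)),
                      panel$snp_meta)
    order_geno(gm)
  })
}

#' Overlay sequencing-artifact annotations on a genotype panel
#'
#' Draws a per-SNP coverage from a uniform distribution over `coverage_range`
#' and masks each genotype cell as missing independently with probability
#' `missing_rate`; `n_called` records the remaining calls per SNP. These are
#' the fields the preprocessing filters act on.
#'
#' @param gm a [geno_matrix()].
#' @param coverage_range numeric length-2; default spans the filter window so
#'   that some SNPs fail the coverage rule.
#' @param missing_rate per-cell missingness probability in \[0, 1\].
#' @param seed integer seed.
#' @return `gm` with `coverage` and `n_called` columns in `snp_meta` and
#'   missing cells in `codes`.
#' @export
annotate_sequencing_artifacts <- function(gm, coverage_range = c(1, 35),
                                          missing_rate = 0.01, seed = NULL) {
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  with_seed(seed, {
    n <- nrow(gm$codes); m <- ncol(gm$codes)
    codes <- gm$codes
    if (missing_rate > 0) {
      codes[runif(n * m) < missing_rate] <- NA_integer_
    }
    meta <- gm$snp_meta
    meta$coverage <- runif(m, coverage_range[1], coverage_range[2])
    meta$n_called <- as.integer(colSums(!is.na(codes)))
    geno_matrix(codes, gm$line_ids, meta)
  })
}

#' Define a generating trait model
#'
#' The trait is polygenic additive on allele-count codes, with optional fixed
#' sex difference, line-by-sex interaction, additive-by-additive epistatic
#' pairs (effects on centered code products), a line-level environmental
#' deviation, replicate deviations, and individual residuals. When `target_h2`
#' is given, `line_env_sd` is calibrated at simulation time so the sex-averaged
#' line means have that heritability (genetic variance taken from the realized
#' panel; replicate and residual noise average out over many records).
#'
#' @param causal_idx SNP column indices carrying additive effects.
#' @param add_eff additive effect per causal SNP (trait units per allele copy).
#' @param mu overall mean.
#' @param sex_effect fixed male minus female difference.
#' @param sex_interaction_sd sd of line-by-sex genetic deviations.
#' @param epistatic_pairs integer matrix (k x 2) of interacting SNP columns,
#'   or `NULL`.
#' @param epi_eff effect per epistatic pair.
#' @param line_env_sd sd of the line-level environmental deviation.
#' @param replicate_sd sd of replicate deviations (nested in line-by-sex).
#' @param residual_sd sd of individual residuals.
#' @param target_h2 optional line-mean heritability target overriding
#'   `line_env_sd`.
#' @param skewed if `TRUE`, residuals are mean-centered log-normal (the skew
#'   that motivates analyzing medians); default normal.
#' @return an object of class `"trait_model"`.
#' @export
trait_model <- function(causal_idx, add_eff, mu = 0, sex_effect = 0,
                        sex_interaction_sd = 0, epistatic_pairs = NULL,
                        epi_eff = numeric(0), line_env_sd = 0,
                        replicate_sd = 0, residual_sd = 1, target_h2 = NULL,
                        skewed = FALSE) {
  if (length(causal_idx) != length(add_eff)) {
    stop("causal_idx and add_eff lengths differ")
  }
  sds <- c(sex_interaction_sd, line_env_sd, replicate_sd, residual_sd)
  if (any(sds < 0)) stop("all sds must be >= 0")
  if (!is.null(epistatic_pairs)) {
    epistatic_pairs <- matrix(as.integer(epistatic_pairs), ncol = 2)
    if (nrow(epistatic_pairs) != length(epi_eff)) {
      stop("epistatic_pairs rows != length(epi_eff)")
    }
  }
  structure(list(causal_idx = as.integer(causal_idx), add_eff = add_eff,
                 mu = mu, sex_effect = sex_effect,
                 sex_interaction_sd = sex_interaction_sd,
                 epistatic_pairs = epistatic_pairs, epi_eff = epi_eff,
                 line_env_sd = line_env_sd, replicate_sd = replicate_sd,
                 residual_sd = residual_sd, target_h2 = target_h2,
                 skewed = skewed),
            class = "trait_model")
}

#' Draw a polygenic additive trait model for a panel
#'
#' Convenience constructor: picks `n_causal` SNP columns at random, draws their
#' effects from N(0, 1) scaled so the base-population additive variance
#' 2*sum(p(1-p)a^2) equals `sigma_a2`, and forwards the remaining arguments to
#' [trait_model()].
#'
#' @param gm a [geno_matrix()].
#' @param n_causal number of causal SNPs.
#' @param sigma_a2 base-population additive genetic variance to target.
#' @param seed integer seed.
#' @param ... passed to [trait_model()].
#' @return a `"trait_model"`.
#' @export
random_trait_model <- function(gm, n_causal, sigma_a2 = 1, seed = NULL, ...) {
  with_seed(seed, {
    m <- ncol(gm$codes)
    if (n_causal > m) stop("n_causal exceeds number of SNPs")
    idx <- sort(sample.int(m, n_causal))
    a <- rnorm(n_causal)
    p <- allele_freq(gm)[idx]
    raw <- 2 * sum(p * (1 - p) * a^2)
    if (raw <= 0) stop("causal SNPs are monomorphic; cannot scale effects")
    a <- a * sqrt(sigma_a2 / raw)
    trait_model(causal_idx = idx, add_eff = a, ...)
  })
}

# Line-level genetic value: additive part plus epistatic pair products
# (products of codes centered at 2p).
line_genetic_values <- function(gm, tm) {
  W <- gm$codes
  if (length(tm$causal_idx) &&
      (max(tm$causal_idx) > ncol(W) || min(tm$causal_idx) < 1)) {
    stop("causal index out of range")
  }
  gv <- if (length(tm$causal_idx)) {
    as.numeric(W[, tm$causal_idx, drop = FALSE] %*% tm$add_eff)
  } else rep(0, nrow(W))
  if (!is.null(tm$epistatic_pairs) && nrow(tm$epistatic_pairs)) {
    p <- allele_freq(gm)
    for (k in seq_len(nrow(tm$epistatic_pairs))) {
      q <- tm$epistatic_pairs[k, 1]; r <- tm$epistatic_pairs[k, 2]
      gv <- gv + tm$epi_eff[k] * (W[, q] - 2 * p[q]) * (W[, r] - 2 * p[r])
    }
  }
  gv
}

#' Simulate replicated individual phenotype records
#'
#' Each individual value is mu + additive genetic value + fixed sex effect +
#' line-by-sex deviation + epistatic term + line environmental deviation +
#' replicate deviation + residual. Per (line, sex) there are
#' `n_reps_per_sex * n_ind_per_rep` records.
#'
#' @param gm a [geno_matrix()].
#' @param tm a [trait_model()].
#' @param n_reps_per_sex replicates per sex (default 2).
#' @param n_ind_per_rep individuals measured per replicate (default 50, i.e.
#'   ~100 records per sex per line).
#' @param seed integer seed.
#' @return data.frame of records (`line`, `sex`, `replicate`, `value`).
#' @export
simulate_phenotypes <- function(gm, tm, n_reps_per_sex = 2, n_ind_per_rep = 50,
                                seed = NULL) with_seed(seed, {
  n <- nrow(gm$codes)
  gv <- line_genetic_values(gm, tm)
  line_env_sd <- tm$line_env_sd
  if (!is.null(tm$target_h2)) {
    h2 <- tm$target_h2
    if (h2 <= 0 || h2 > 1) stop("target_h2 must be in (0, 1]")
    vg <- var(gv)
    line_env_sd <- if (h2 == 1) 0 else sqrt(vg * (1 - h2) / h2)
  }
  line_env <- rnorm(n, 0, line_env_sd)
  sexes <- c("F", "M")
  sex_fix <- c(F = -tm$sex_effect / 2, M = tm$sex_effect / 2)
  out <- vector("list", 2L * n_reps_per_sex)
  k <- 0L
  sexline <- matrix(rnorm(2 * n, 0, tm$sex_interaction_sd), n, 2,
                    dimnames = list(NULL, sexes))
  for (s in sexes) {
    for (r in seq_len(n_reps_per_sex)) {
      rep_dev <- rnorm(n, 0, tm$replicate_sd)
      base <- tm$mu + gv + sex_fix[[s]] + sexline[, s] + line_env + rep_dev
      vals <- rep(base, each = n_ind_per_rep)
      nn <- n * n_ind_per_rep
      res <- if (tm$skewed) {
        sdl <- sqrt(log(1 + 1))  # log-normal with cv 1, scaled to residual_sd
        raw <- rlnorm(nn, -sdl^2 / 2, sdl)
        tm$residual_sd * (raw - 1) / sqrt(exp(sdl^2) - 1)
      } else rnorm(nn, 0, tm$residual_sd)
      k <- k + 1L
      out[[k]] <- data.frame(
        line = rep(gm$line_ids, each = n_ind_per_rep),
        sex = s, replicate = paste0(s, r), value = vals + res,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
})

#' Summarize records into per-line phenotypic values
#'
#' The analyzed line value is the average of the per-sex medians,
#' y = (median_F + median_M) / 2. Medians of even-length samples use the
#' midpoint of the two central order statistics. Medians are used because
#' individual trait distributions are skewed.
#'
#' @param records data.frame of individual records
#'   (`line`, `sex`, `replicate`, `value`).
#' @return data.frame with one row per line: `line`, `median_F`, `median_M`,
#'   `y`, `n_records_F`, `n_records_M`.
#' @export
summarize_line_phenotypes <- function(records) {
  lines <- unique(records$line)
  med <- function(l, s) {
    v <- records$value[records$line == l & records$sex == s]
    if (!length(v)) stop("line ", l, " has no records for sex ", s)
    median(v)
  }
  cnt <- function(l, s) sum(records$line == l & records$sex == s)
  mf <- vapply(lines, med, 0, s = "F")
  mm <- vapply(lines, med, 0, s = "M")
  data.frame(line = lines, median_F = mf, median_M = mm, y = (mf + mm) / 2,
             n_records_F = vapply(lines, cnt, 0L, s = "F"),
             n_records_M = vapply(lines, cnt, 0L, s = "M"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete inbred-line panel with phenotypes
#'
#' One-call wrapper over [simulate_base_population()], [derive_inbred_lines()],
#' [random_trait_model()], [simulate_phenotypes()] and
#' [summarize_line_phenotypes()], emulating a DGRP-like study: a panel of fully
#' homozygous lines from 20 generations of full-sib mating, a polygenic
#' additive trait, and ~100 replicated measurements per sex per line.
#'
#' @param n_lines number of inbred lines.
#' @param n_causal causal SNPs for the trait.
#' @param h2 line-mean heritability target.
#' @param spec a [population_spec()].
#' @param n_gen_fullsib full-sib generations.
#' @param n_reps_per_sex,n_ind_per_rep record structure per (line, sex).
#' @param seed integer seed driving all stages.
#' @param ... further arguments to [trait_model()] via [random_trait_model()].
#' @return list with `gm` (genotypes), `tm` (trait model), `records`,
#'   `pheno` (line summary), and `panel` (base haplotypes).
#' @export
simulate_panel <- function(n_lines = 157, n_causal = 500, h2 = 0.9,
                           spec = population_spec(), n_gen_fullsib = 20,
                           n_reps_per_sex = 2, n_ind_per_rep = 50,
                           seed = NULL, ...) with_seed(seed, {
  panel <- simulate_base_population(spec)
  gm <- derive_inbred_lines(panel, n_lines, n_gen_fullsib)
  poly <- which(apply(gm$codes, 2, function(x) length(unique(x))) > 1)
  gm <- subset_geno(gm, snps = poly)
  tm <- random_trait_model(gm, n_causal = min(n_causal, ncol(gm$codes)),
                           target_h2 = h2, ...)
  records <- simulate_phenotypes(gm, tm, n_reps_per_sex, n_ind_per_rep)
  list(gm = gm, tm = tm, records = records,
       pheno = summarize_line_phenotypes(records), panel = panel)
})
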