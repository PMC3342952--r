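#' @useDynLib inbredgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median optimize pchisq pnorm pt qnorm quantile rbinom
#'   rnorm rpois runif sd var rlnorm optim ks.test binom.test
#' @importFrom utils combn read.table write.table head
NULL

#' Construct a genotype matrix for a panel of lines
#'
#' The central container of the package: an `n_lines x n_snps` integer matrix of
#' allele-count codes (0/1/2 copies of the second allele, `NA` = missing call)
#' together with a per-SNP map. Fully inbred lines carry only codes 0 and 2, so
#' each line is effectively a haplotype.
#'
#' @param codes integer matrix, lines in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param line_ids character vector of unique line identifiers, one per row.
#' @param snp_meta data.frame with one row per SNP and columns `chrom_arm`
#'   (character), `pos_bp` (positive integer, strictly increasing within arm),
#'   `pos_morgan` (non-negative numeric, may be `NA`), and optionally
#'   `coverage` and `n_called`.
#' @return An object of class `"geno_matrix"`: a list with elements `codes`,
#'   `line_ids`, `snp_meta`.
#' @export
geno_matrix <- function(codes, line_ids, snp_meta) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (anyDuplicated(line_ids)) stop("line_ids must be unique")
  if (length(line_ids) != nrow(codes)) stop("line_ids length != nrow(codes)")
  if (nrow(snp_meta) != ncol(codes)) stop("snp_meta rows != ncol(codes)")
  need <- c("chrom_arm", "pos_bp")
  if (!all(need %in% names(snp_meta))) {
    stop("snp_meta must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.null(snp_meta$pos_morgan)) snp_meta$pos_morgan <- NA_real_
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(snp_meta$pos_bp <= 0)) stop("pos_bp must be positive")
  for (arm in unique(snp_meta$chrom_arm)) {
    p <- snp_meta$pos_bp[snp_meta$chrom_arm == arm]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("pos_bp must be strictly increasing within chrom_arm ", arm)
    }
  }
  rownames(codes) <- line_ids
  snp_id <- paste0(snp_meta$chrom_arm, ":", snp_meta$pos_bp)
  colnames(codes) <- snp_id
  rownames(snp_meta) <- NULL
  structure(
    list(codes = codes, line_ids = as.character(line_ids),
         snp_meta = as.data.frame(snp_meta)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d SNPs on %d arm(s); %d missing cells\n",
              nrow(x$codes), ncol(x$codes),
              length(unique(x$snp_meta$chrom_arm)), sum(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Allele frequencies of the second allele
#'
#' @param gm a [geno_matrix()].
#' @return numeric vector `p_j` = (mean code)/2 per SNP, missing cells excluded.
#' @export
allele_freq <- function(gm) {
  colMeans(gm$codes, na.rm = TRUE) / 2
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param lines row index (ids, logical or integer); `NULL` keeps all.
#' @param snps column index; `NULL` keeps all.
#' @return a [geno_matrix()].
#' @export
subset_geno <- function(gm, lines = NULL, snps = NULL) {
  if (is.null(lines)) lines <- seq_along(gm$line_ids)
  if (is.character(lines)) lines <- match(lines, gm$line_ids)
  if (is.null(snps)) snps <- seq_len(ncol(gm$codes))
  geno_matrix(gm$codes[lines, snps, drop = FALSE],
              gm$line_ids[lines],
              gm$snp_meta[snps, , drop = FALSE])
}

# Order SNP columns by (chrom_arm, pos_bp); stable arm order = first appearance.
order_geno <- function(gm) {
  arms <- unique(gm$snp_meta$chrom_arm)
  o <- order(match(gm$snp_meta$chrom_arm, arms), gm$snp_meta$pos_bp)
  subset_geno(gm, snps = o)
}

#' Read genotypes from disk
#'
#' Two formats are supported. `"matrix"` is the package's tab-separated text
#' format: a header row of SNP ids (`arm:pos`), one row per line with the line
#' id in the first column and codes 0/1/2/NA after it; an optional `<path>.map`
#' sidecar (TSV: snp_id, chrom_arm, pos_bp, pos_morgan, coverage, n_called)
#' restores the full SNP map. `"vcf"` is a minimal read-only VCF dialect:
#' biallelic SNP records with a GT field and diploid genotypes, parsed with
#' vcfR; `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`.
#'
#' @param path file path.
#' @param format `"matrix"` or `"vcf"`.
#' @return a [geno_matrix()] with SNPs ordered by (chrom_arm, pos_bp).
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  gm <- switch(format,
               matrix = read_geno_matrix_format(path),
               vcf = read_geno_vcf(path))
  order_geno(gm)
}

read_geno_matrix_format <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("matrix format needs a line_id column and >=1 SNP")
  line_ids <- tab[[1]]
  codes <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(codes) <- "integer")
  snp_id <- colnames(tab)[-1]
  mp <- paste0(path, ".map")
  if (file.exists(mp)) {
    meta <- read.table(mp, header = TRUE, sep = "\t", check.names = FALSE)
    if (!identical(as.character(meta$snp_id), snp_id)) {
      stop("sidecar map does not match matrix columns: ", mp)
    }
    meta$snp_id <- NULL
  } else {
    parts <- strsplit(snp_id, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) stop("malformed SNP id in header column ", bad[1] + 1L)
    meta <- data.frame(chrom_arm = vapply(parts, `[`, "", 1),
                       pos_bp = as.integer(vapply(parts, `[`, "", 2)),
                       pos_morgan = NA_real_)
  }
  geno_matrix(codes, line_ids, meta)
}

read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic site(s) rejected: ",
         paste(fix[multi, "CHROM"], fix[multi, "POS"], sep = ":", collapse = ", "))
  }
  notsnp <- nchar(ref) != 1 | nchar(alt) != 1
  if (any(notsnp)) {
    stop("non-SNP record(s) rejected: ",
         paste(fix[notsnp, "CHROM"], fix[notsnp, "POS"], sep = ":", collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  code1 <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || !all(al %in% c("0", "1"))) {
      stop("malformed diploid GT value: '", g, "'")
    }
    sum(al == "1")
  }
  codes <- t(apply(gt, c(1, 2), code1))  # samples x snps
  meta <- data.frame(chrom_arm = fix[, "CHROM"],
                     pos_bp = as.integer(fix[, "POS"]),
                     pos_morgan = NA_real_)
  geno_matrix(codes, colnames(v@gt)[-1], meta)
}

#' Write genotypes to the tab-separated matrix format
#'
#' Writes the code matrix (missing as `NA`) plus a `<path>.map` sidecar holding
#' the full SNP map, so that [read_genotypes()] inverts the write bit-exactly.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  if (ncol(gm$codes) == 0) stop("refusing to write a genotype matrix with no SNPs")
  tab <- data.frame(line_id = gm$line_ids, gm$codes, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- gm$snp_meta
  meta <- cbind(snp_id = colnames(gm$codes), meta)
  write.table(meta, paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read individual phenotype records
#'
#' @param path CSV with header columns `line`, `sex`, `replicate`, `value`.
#' @return data.frame with columns `line` (character), `sex` (`"F"`/`"M"`),
#'   `replicate` (character), `value` (numeric).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- read.table(path, header = TRUE, sep = ",", colClasses = "character")
  need <- c("line", "sex", "replicate", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_sex <- which(!tab$sex %in% c("F", "M"))
  if (length(bad_sex)) {
    stop("unknown sex token '", tab$sex[bad_sex[1]], "' in row ", bad_sex[1])
  }
  val <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(val))
  if (length(bad)) {
    stop("non-numeric value '", tab$value[bad[1]], "' in row ", bad[1])
  }
  data.frame(line = tab$line, sex = tab$sex, replicate = tab$replicate,
             value = val, stringsAsFactors = FALSE)
}

#' Write individual phenotype records
#'
#' @param records data.frame as returned by [read_phenotypes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  write.table(records[, c("line", "sex", "replicate", "value")], path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
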