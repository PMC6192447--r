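#' Simulate SNP genotypes on a pedigree by gene dropping
#'
#' Founders are drawn in Hardy-Weinberg equilibrium at per-SNP minor allele
#' frequencies sampled uniformly from `[maf_low, maf_high]`; each non-founder
#' receives one allele from each parent by Mendelian transmission. Dosages
#' count copies of allele A1. Missingness is applied uniformly at random
#' afterwards.
#'
#' @param ped A `pedigree`.
#' @param n_snps Number of autosomal SNPs.
#' @param maf_low,maf_high Bounds of the founder minor-allele-frequency range,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param missing_rate Probability that any genotype call is set missing.
#' @param seed Integer seed.
#' @return An object of class `"genotype_matrix"`: an integer matrix
#'   (individuals x SNPs, values 0/1/2 or `NA`) with individual ids as
#'   rownames, SNP ids as colnames, and attributes `chrom`, `pos`, `a1`,
#'   `a2`, `maf` (the generating frequencies).
#' @export
simulate_genotypes <- function(ped, n_snps, maf_low = 0.05, maf_high = 0.5,
                               missing_rate = 0, seed = 1L) {
  validate_pedigree(ped)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  n <- nrow(ped)
  m <- as.integer(n_snps)
  p <- stats::runif(m, maf_low, maf_high)
  # allele matrices: one chromosome copy each, 0/1 per individual x SNP
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  gen <- if (is.null(ped$generation)) rep(0L, n) else ped$generation
  ord <- order(gen, ped$id)
  pos_of <- function(ids) match(ids, ped$id)
  for (i in ord) {
    if (is.na(ped$father[i])) {
      H1[i, ] <- stats::rbinom(m, 1L, p)
      H2[i, ] <- stats::rbinom(m, 1L, p)
    } else {
      fi <- pos_of(ped$father[i]); mi <- pos_of(ped$mother[i])
      pick1 <- stats::runif(m) < 0.5
      pick2 <- stats::runif(m) < 0.5
      H1[i, ] <- ifelse(pick1, H1[fi, ], H2[fi, ])
      H2[i, ] <- ifelse(pick2, H1[mi, ], H2[mi, ])
    }
  }
  X <- H1 + H2
  if (missing_rate > 0)
    X[stats::runif(length(X)) < missing_rate] <- NA_integer_
  dimnames(X) <- list(ped$id, sprintf("snp%06d", seq_len(m)))
  structure(X, class = c("genotype_matrix", class(X)),
            chrom = rep(1L, m), pos = seq_len(m) * 1000L,
            a1 = rep("A", m), a2 = rep("G", m), maf = p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %.3f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

geno_attrs <- function(geno) {
  m <- ncol(geno)
  list(chrom = attr(geno, "chrom") %||% rep(1L, m),
       pos   = attr(geno, "pos")   %||% seq_len(m),
       a1    = attr(geno, "a1")    %||% rep("A", m),
       a2    = attr(geno, "a2")    %||% rep("G", m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' Writes the SNP-major binary `.bed` (magic bytes `0x6C 0x1B 0x01`), the
#' `.bim` SNP table and the `.fam` individual table. Dosage is the A1-allele
#' count, mapped to the standard 2-bit codes (00 = hom A1, 10 = het,
#' 11 = hom A2, 01 = missing).
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @param ped Optional `pedigree` supplying parent/sex columns for the
#'   `.fam`; zeroes are written otherwise.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, ped = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  at <- geno_attrs(geno)
  ids <- rownames(geno)
  # .bed, SNP-major: each SNP packed into ceiling(n/4) bytes, LSB-first
  codes <- matrix(3L, nrow = n, ncol = m)        # 11 = hom A2 (dosage 0)
  codes[!is.na(geno) & geno == 2L] <- 0L         # 00 = hom A1
  codes[!is.na(geno) & geno == 1L] <- 2L         # 10 = het
  codes[is.na(geno)] <- 1L                       # 01 = missing
  nb <- ceiling(n / 4)
  pad <- nb * 4L - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  i4 <- seq(1L, nb * 4L, by = 4L)
  bytes <- codes[i4, , drop = FALSE] +
    codes[i4 + 1L, , drop = FALSE] * 4L +
    codes[i4 + 2L, , drop = FALSE] * 16L +
    codes[i4 + 3L, , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(
    data.frame(at$chrom, colnames(geno), 0, at$pos, at$a1, at$a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  if (!is.null(ped)) {
    ix <- match(ids, as.character(ped$id))
    fam <- data.frame(1, ids,
                      ifelse(is.na(ped$father[ix]), 0L, ped$father[ix]),
                      ifelse(is.na(ped$mother[ix]), 0L, ped$mother[ix]),
                      ped$sex[ix] + 1L, -9)
  } else {
    fam <- data.frame(1, ids, 0L, 0L, 0L, -9)
  }
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix Path prefix of the fileset.
#' @return A `genotype_matrix` (dosage of allele A1).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim); nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6CL, 0x1BL, 0x01L)))
    stop("not a SNP-major PLINK .bed file (bad magic bytes)")
  raw <- readBin(con, "raw", nb * m)
  if (length(raw) != nb * m) stop("bed size mismatch with bim/fam dimensions")
  b <- as.integer(raw)
  two_bits <- cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  codes <- matrix(t(two_bits), nrow = nb * 4L)   # (4*nb) x m, LSB-first order
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(NA_integer_, n, m)
  X[codes == 0L] <- 2L
  X[codes == 2L] <- 1L
  X[codes == 3L] <- 0L
  dimnames(X) <- list(fam[[2]], bim$id)
  structure(X, class = c("genotype_matrix", class(X)),
            chrom = bim$chrom, pos = bim$pos, a1 = bim$a1, a2 = bim$a2)
}
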