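#' @title Relationship matrices for variance-component models
#' @description Constructors and I/O for the five variance-structure
#'   matrices: G (genomic relationship), K (relatedness-thresholded kinship),
#'   and the binary shared-environment matrices F (nuclear family), S (full
#'   sibling) and C (couple).
#' @name relationship-matrices
NULL

new_relmat <- function(values, kind, n_snps_used = NA_integer_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("relationship matrix needs individual ids as dimnames")
  structure(list(values = values, ids = rownames(values), kind = kind,
                 n_snps_used = n_snps_used), class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("relmat[%s]: %d x %d%s\n", x$kind, length(x$ids), length(x$ids),
              if (is.na(x$n_snps_used)) "" else sprintf(", %d SNPs", x$n_snps_used)))
  invisible(x)
}

#' Compute the genomic relationship matrix (G)
#'
#' GCTA-style estimator on standardized dosages with in-sample allele
#' frequencies: `G_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))`. Missing genotypes are mean-imputed per SNP before
#' standardization, so they contribute zero to the sum.
#'
#' @param geno A QC'd `genotype_matrix` with no monomorphic SNPs.
#' @return A `relmat` of kind `"G"`.
#' @export
compute_grm <- function(geno) {
  X <- unclass(geno)
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNPs present; run apply_qc() first")
  m <- ncol(X)
  Z <- sweep(X, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0                       # mean imputation
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(Z) / m
  dimnames(G) <- list(rownames(geno), rownames(geno))
  new_relmat(G, "G", n_snps_used = m)
}

#' Threshold a GRM into a pedigree-associated kinship matrix (K)
#'
#' Off-diagonal entries below the relatedness threshold are set to zero;
#' entries at or above it, and the diagonal, are kept unchanged. Fitted
#' jointly with G, K tags additive genetic variance associated with close
#' relatives beyond what common SNPs capture.
#'
#' @param G A `relmat` of kind `"G"`.
#' @param t Relatedness threshold (default 0.05).
#' @return A `relmat` of kind `"K"`.
#' @export
threshold_grm <- function(G, t = 0.05) {
  stopifnot(inherits(G, "relmat"))
  K <- G$values
  off <- K < t
  diag(off) <- FALSE
  K[off] <- 0
  new_relmat(K, "K", n_snps_used = G$n_snps_used)
}

#' Build a binary shared-environment matrix (F, S or C)
#'
#' Indicator matrices over pedigree relationships with unit diagonal:
#' `family` links all members of a nuclear-family unit (a couple plus their
#' common offspring; individuals belonging to several units are linked to
#' the members of each); `sibling` links pairs sharing both parents;
#' `couple` links mutual spouses.
#'
#' @param ped A `pedigree`.
#' @param kind One of `"family"`, `"sibling"`, `"couple"`.
#' @return A `relmat` of kind `"F"`, `"S"` or `"C"`.
#' @export
build_environment_matrix <- function(ped, kind = c("family", "sibling", "couple")) {
  kind <- match.arg(kind)
  cs <- pedigree_counts(ped)
  n <- nrow(ped)
  M <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  link <- function(ids) {
    ix <- match(ids, ped$id)
    M[ix, ix] <<- 1
  }
  if (kind == "family") {
    lapply(cs$families, link)
  } else if (kind == "sibling") {
    prs <- cs$sib_pairs
    if (nrow(prs)) apply(prs, 1L, function(p) link(p))
  } else {
    prs <- cs$couple_pairs
    if (nrow(prs)) apply(prs, 1L, function(p) link(p))
  }
  diag(M) <- 1
  new_relmat(M, c(family = "F", sibling = "S", couple = "C")[[kind]])
}

#' Write a relationship matrix in GCTA binary GRM format
#'
#' Writes `prefix.grm.bin` (lower triangle including diagonal, row-wise,
#' 4-byte little-endian floats), `prefix.grm.N.bin` (per-pair SNP counts as
#' floats) and `prefix.grm.id` (family and individual id columns).
#'
#' @param M A `relmat`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(M, prefix) {
  stopifnot(inherits(M, "relmat"))
  V <- M$values
  n <- nrow(V)
  lower <- V[upper.tri(V, diag = TRUE)]  # upper tri in column order == lower tri row-wise
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  nsnp <- if (is.na(M$n_snps_used)) 0 else M$n_snps_used
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(nsnp), length(lower)), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(data.frame(1, M$ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM fileset
#'
#' @param prefix Path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triplet.
#' @param kind Kind tag to attach (default `"G"`).
#' @return A `relmat`.
#' @export
read_grm <- function(prefix, kind = "G") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  nel <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", n = nel + 1L, size = 4L, endian = "little")
  close(con)
  if (length(vals) != nel)
    stop(sprintf("GRM size mismatch: %d entries read, %d expected from id file", length(vals), nel))
  V <- matrix(0, n, n, dimnames = list(ids, ids))
  V[upper.tri(V, diag = TRUE)] <- vals
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  nfile <- paste0(prefix, ".grm.N.bin")
  nsnp <- NA_integer_
  if (file.exists(nfile)) {
    con <- file(nfile, "rb")
    nv <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
    close(con)
    if (length(nv)) nsnp <- as.integer(nv)
  }
  new_relmat(V, kind, n_snps_used = nsnp)
}
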