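#' Quality-control thresholds for SNP and individual filtering
#'
#' Defaults follow standard array-genotyping practice: SNP call rate >= 98%,
#' per-individual missingness <= 2%, Hardy-Weinberg exact p > 1e-6, minor
#' allele frequency > 1%.
#'
#' @param snp_call_rate_min Minimum per-SNP call rate (fraction).
#' @param indiv_missing_max Maximum per-individual missing fraction.
#' @param hwe_p_min SNPs with exact HWE p <= this value are dropped.
#' @param maf_min SNPs with minor allele frequency <= this value are dropped.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.98, indiv_missing_max = 0.02,
                          hwe_p_min = 1e-6, maf_min = 0.01) {
  v <- c(snp_call_rate_min = snp_call_rate_min, indiv_missing_max = indiv_missing_max,
         hwe_p_min = hwe_p_min, maf_min = maf_min)
  if (any(v <= 0) || any(v >= 1)) stop("all QC thresholds must lie in (0, 1)")
  structure(as.list(v), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the two-sided
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (probability-mass inclusion).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(25, 50, 25)  # 1: heterozygotes at the conditional mode
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)  # feasible heterozygote counts
  # log P(n_Aa = h | n, nA) up to a common constant
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

per_snp_stats <- function(geno) {
  n <- nrow(geno)
  miss <- colSums(is.na(geno))
  called <- n - miss
  n_a1hom <- colSums(geno == 2L, na.rm = TRUE)
  n_het <- colSums(geno == 1L, na.rm = TRUE)
  n_a2hom <- called - n_a1hom - n_het
  p <- ifelse(called > 0, (2 * n_a1hom + n_het) / (2 * called), NA_real_)
  list(call_rate = called / n, n_a1hom = n_a1hom, n_het = n_het,
       n_a2hom = n_a2hom, maf = pmin(p, 1 - p))
}

#' Apply genotype quality control
#'
#' Filters in a fixed order: (1) SNP call rate, (2) individual missingness,
#' (3) per-SNP statistics recomputed on retained individuals, (4) exact HWE,
#' (5) MAF. The operation is idempotent.
#'
#' @param geno A `genotype_matrix`.
#' @param thr A [qc_thresholds()].
#' @return A list with `geno` (the filtered `genotype_matrix`) and `report`
#'   (class `"qc_report"`: per-rule SNP drop counts, individuals dropped,
#'   retained totals).
#' @export
apply_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  n0 <- nrow(geno); m0 <- ncol(geno)
  at <- geno_attrs(geno)
  st <- per_snp_stats(geno)
  keep_cr <- st$call_rate >= thr$snp_call_rate_min
  g1 <- geno[, keep_cr, drop = FALSE]
  ind_miss <- rowMeans(is.na(g1))
  keep_ind <- ind_miss <= thr$indiv_missing_max
  g2 <- g1[keep_ind, , drop = FALSE]
  st2 <- per_snp_stats(g2)
  hwe_p <- mapply(function(a, h, b) if (a + h + b == 0) 0 else hwe_exact_test(a, h, b),
                  st2$n_a1hom, st2$n_het, st2$n_a2hom)
  keep_hwe <- hwe_p > thr$hwe_p_min
  keep_maf <- !is.na(st2$maf) & st2$maf > thr$maf_min
  keep_snp <- keep_hwe & keep_maf
  g3 <- g2[, keep_snp, drop = FALSE]
  if (nrow(g3) == 0L || ncol(g3) == 0L)
    stop("QC removed all individuals or all SNPs; relax thresholds or check input")
  sel <- which(keep_cr)[keep_snp]
  out <- structure(g3, class = c("genotype_matrix", "matrix", "array"),
                   chrom = at$chrom[sel], pos = at$pos[sel],
                   a1 = at$a1[sel], a2 = at$a2[sel])
  report <- structure(list(
    snps_dropped_by_rule = c(call_rate = sum(!keep_cr),
                             hwe = sum(!keep_hwe & keep_maf),
                             maf = sum(!keep_maf)),
    individuals_dropped = sum(!keep_ind),
    snps_retained = ncol(g3), individuals_retained = nrow(g3),
    snps_input = m0, individuals_input = n0), class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d SNPs and %d/%d individuals retained\n",
              x$snps_retained, x$snps_input, x$individuals_retained, x$individuals_input))
  cat(sprintf("  dropped SNPs by rule: call rate %d, HWE %d, MAF %d; individuals dropped: %d\n",
              x$snps_dropped_by_rule[["call_rate"]], x$snps_dropped_by_rule[["hwe"]],
              x$snps_dropped_by_rule[["maf"]], x$individuals_dropped))
  invisible(x)
}

#' Identity-by-state similarity matrix
#'
#' Mean proportion of alleles shared identical-by-state over SNPs non-missing
#' in both members of each pair: `1 - |x_i - x_j| / 2` averaged over SNPs.
#'
#' @param geno A `genotype_matrix`.
#' @return A symmetric N x N matrix with entries in `[0, 1]`.
#' @export
ibs_matrix <- function(geno) {
  X <- unclass(geno)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  storage.mode(X0) <- "double"; storage.mode(obs) <- "double"
  # sum |xi - xj| = sum (xi - xj)^2 - 2 * #{(0,2) pairs}; restrict to co-called SNPs
  XX <- tcrossprod(X0)                 # sum xi xj
  X2 <- tcrossprod(X0^2, obs)          # sum xi^2 over co-called
  sqdiff <- X2 + t(X2) - 2 * XX
  hom0 <- (X0 == 0) * obs; hom2 <- (X0 == 2) * obs
  n02 <- tcrossprod(hom0, hom2); n02 <- n02 + t(n02)
  pairs_called <- tcrossprod(obs)
  absdiff <- sqdiff - 2 * n02
  ibs <- 1 - absdiff / (2 * pmax(pairs_called, 1))
  dimnames(ibs) <- list(rownames(geno), rownames(geno))
  ibs
}

#' Multidimensional-scaling ancestry components
#'
#' Classical MDS (principal coordinates) of the identity-by-state distance
#' `1 - IBS` within the cohort, for use as ancestry covariates. Axes are
#' ordered by eigenvalue and zero-centered.
#'
#' @param geno A QC'd `genotype_matrix`.
#' @param n_components Number of axes to return (default 4).
#' @param founders_only Optional vector of individual ids on which to compute
#'   the axes (e.g. founders only, to avoid family-driven components).
#'   Excluded individuals are not projected; their components are set to 0.
#' @return A data frame `id`, `MDS1..MDSk`.
#' @export
compute_mds <- function(geno, n_components = 4L, founders_only = NULL) {
  n <- nrow(geno)
  if (n_components > n - 1L) stop("n_components must be <= N - 1")
  sub <- if (is.null(founders_only)) rownames(geno) else as.character(founders_only)
  ibs <- ibs_matrix(geno[sub, , drop = FALSE])
  d <- stats::as.dist(1 - ibs)
  mds <- stats::cmdscale(d, k = n_components)
  out <- matrix(0, n, n_components, dimnames = list(rownames(geno), NULL))
  out[sub, ] <- mds
  res <- data.frame(id = rownames(geno), out, row.names = NULL)
  names(res)[-1] <- paste0("MDS", seq_len(n_components))
  res
}
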