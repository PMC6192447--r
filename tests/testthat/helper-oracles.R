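# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths.

# Profiled restricted likelihood evaluated on a dense grid of variance
# fractions (residual fraction = 1 - sum; total variance profiled out).
grid_reml_oracle <- function(y, X, Ms, step = 0.01) {
  n <- length(y)
  X <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
  p <- ncol(X)
  k <- length(Ms)
  fr <- seq(0, 0.99, by = step)
  grid <- if (k == 1) matrix(fr, ncol = 1) else as.matrix(expand.grid(fr, fr))
  grid <- grid[rowSums(grid) <= 0.99 + 1e-9, , drop = FALSE]
  best <- -Inf; bestf <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- grid[i, ]
    W <- diag(1 - sum(f), n)
    for (j in seq_len(k)) W <- W + f[j] * Ms[[j]]
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) next
    Wi <- chol2inv(ch)
    WiX <- Wi %*% X
    cX <- chol(crossprod(X, WiX))
    P <- Wi - WiX %*% chol2inv(cX) %*% t(WiX)
    s <- sum(y * (P %*% y)) / (n - p)
    ll <- -0.5 * ((n - p) * log(s) + 2 * sum(log(diag(ch))) +
                    2 * sum(log(diag(cX))) + (n - p))
    if (ll > best) { best <- ll; bestf <- f }
  }
  list(logL = best, fractions = bestf)
}

# Exact expected additive relationship by exhaustive enumeration of all
# founder-allele transmission patterns (2 meioses per non-founder). Only
# feasible for tiny pedigrees; independent of the recursive tabular method.
additive_matrix_enumeration <- function(ped) {
  n <- nrow(ped)
  nonf <- which(!is.na(ped$father))
  nmei <- 2L * length(nonf)
  stopifnot(nmei <= 16L)
  founders <- which(is.na(ped$father))
  # founder allele labels: two unique alleles each
  allele1 <- allele2 <- integer(n)
  allele1[founders] <- seq(1, 2 * length(founders), by = 2)
  allele2[founders] <- seq(2, 2 * length(founders), by = 2)
  acc <- matrix(0, n, n)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  # process non-founders in generation order
  ord <- nonf[order(ped$generation[nonf])]
  for (pattern in 0:(2^nmei - 1)) {
    bits <- as.integer(intToBits(pattern))[seq_len(nmei)]
    a1 <- allele1; a2 <- allele2
    for (j in seq_along(ord)) {
      i <- ord[j]
      b1 <- bits[2L * j - 1L]; b2 <- bits[2L * j]
      a1[i] <- if (b1 == 0L) a1[fa[i]] else a2[fa[i]]
      a2[i] <- if (b2 == 0L) a1[mo[i]] else a2[mo[i]]
    }
    # IBD sharing: A_ij = E[(share of alleles ibd)]; kinship phi_ij =
    # P(random allele of i == random allele of j); A = 2 phi
    for (i in seq_len(n)) for (j in i:n) {
      phi <- ((a1[i] == a1[j]) + (a1[i] == a2[j]) +
                (a2[i] == a1[j]) + (a2[i] == a2[j])) / 4
      acc[i, j] <- acc[i, j] + phi
    }
  }
  A <- 2 * (acc + t(acc) - diag(diag(acc))) / 2^nmei
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Exact HWE p by direct enumeration over all genotype configurations with
# the observed allele counts, computed from multinomial coefficients.
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) + h * log(2))
  }, 0)
  pr <- w / sum(w)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Minimal independent GCTA GRM parser written directly from the format
# description (float32 lower triangle incl. diagonal, row-wise).
read_grm_independent <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"))[[2]]
  n <- length(ids)
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  v <- readBin(con, "numeric", n * (n + 1) / 2, size = 4, endian = "little")
  close(con)
  M <- matrix(NA_real_, n, n)
  idx <- 1
  for (i in 1:n) for (j in 1:i) {
    M[i, j] <- M[j, i] <- v[idx]; idx <- idx + 1
  }
  dimnames(M) <- list(ids, ids)
  M
}

# Minimal independent PLINK .bed parser (SNP-major), from the format spec.
read_bed_independent <- function(prefix, n, m) {
  con <- file(paste0(prefix, ".bed"), "rb")
  raw <- readBin(con, "raw", 3 + ceiling(n / 4) * m)
  close(con)
  stopifnot(identical(as.integer(raw[1:3]), c(108L, 27L, 1L)))
  body <- as.integer(raw[-(1:3)])
  nb <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  for (s in 1:m) {
    bytes <- body[((s - 1) * nb + 1):(s * nb)]
    g <- integer(0)
    for (b in bytes) {
      for (sh in c(1, 4, 16, 64)) {
        code <- (b %/% sh) %% 4
        g <- c(g, switch(code + 1, 2L, NA_integer_, 1L, 0L))
      }
    }
    out[, s] <- g[1:n]
  }
  out
}
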