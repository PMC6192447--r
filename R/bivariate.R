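## Bivariate GREML: the two trait vectors are stacked into one system
## y* = (y1', y2')' with block covariance
##   V = sum_c [ v_c1 M_11   c_c M_12 ;  c_c M_21   v_c2 M_22 ] + residual,
## where M is a relationship matrix over the union of individuals and the
## residual uses the identity (cross-block: same-individual pairs only).
## Individuals missing one trait are retained for the other.

bivar_dmat <- function(Msub, n1, n2, which) {
  n <- n1 + n2
  D <- matrix(0, n, n)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  if (which == "v1") D[i1, i1] <- Msub$M11
  else if (which == "v2") D[i2, i2] <- Msub$M22
  else { D[i1, i2] <- Msub$M12; D[i2, i1] <- t(Msub$M12) }
  D
}

#' Bivariate REML fit of genetic correlations
#'
#' Estimates, for two traits measured on (partially) overlapping
#' individuals, the per-trait variance components and cross-trait
#' covariances of the common-variant genetic component (G), the
#' pedigree-associated genetic component (K) and the residual, by AI-REML on
#' the stacked two-trait system. Genetic correlations are
#' `r = cov / sqrt(var1 * var2)` with delta-method standard errors, clamped
#' to `[-1, 1]` with a warning when the unconstrained optimum lies outside.
#'
#' @param y1,y2 Trait vectors over the same individual index (NAs allowed;
#'   an individual missing one trait is kept for the other).
#' @param X Covariate matrix/data frame over the same index (intercept
#'   added; fixed effects are estimated separately per trait).
#' @param G,K Relationship matrices (`relmat` or plain); `K = NULL` drops
#'   the pedigree component.
#' @param ids Individual ids aligning the vectors with the matrices
#'   (defaults to `names(y1)`).
#' @param tol,max_iter As in [reml_fit()].
#' @return An object of class `"bivariate_fit"` with `r_G`, `r_G_se`,
#'   `r_K`, `r_K_se`, per-trait component fractions, `logL`, `n1`, `n2`,
#'   `converged`, and the internal state needed by [lrt_correlation()].
#' @export
bivariate_fit <- function(y1, y2, X = NULL, G, K = NULL, ids = NULL,
                          tol = 1e-4, max_iter = 100L) {
  if (length(y1) != length(y2)) stop("y1 and y2 must be over the same individual index")
  if (is.null(ids)) ids <- names(y1)
  if (is.null(ids)) ids <- as.character(seq_along(y1))
  if (is.null(X)) X <- matrix(1, length(y1), 1L)
  X <- as.matrix(X)
  if (!any(apply(X, 2L, function(col) all(col == col[1L] & col[1L] != 0))))
    X <- cbind(1, X)
  ok1 <- stats::complete.cases(y1, X)
  ok2 <- stats::complete.cases(y2, X)
  if (!any(ok1) || !any(ok2)) stop("no complete cases for one of the traits")
  ids1 <- ids[ok1]; ids2 <- ids[ok2]
  n1 <- length(ids1); n2 <- length(ids2)
  mats <- list(G = G)
  if (!is.null(K)) mats$K <- K
  subm <- lapply(names(mats), function(nm) {
    Mfull <- align_matrix(mats[[nm]], union(ids1, ids2), nm)
    list(M11 = Mfull[ids1, ids1, drop = FALSE],
         M22 = Mfull[ids2, ids2, drop = FALSE],
         M12 = Mfull[ids1, ids2, drop = FALSE])
  })
  names(subm) <- names(mats)
  Ident <- list(M11 = diag(n1), M22 = diag(n2),
                M12 = outer(ids1, ids2, `==`) * 1)
  subm$E <- Ident
  ystar <- c(y1[ok1], y2[ok2])
  Xstar <- rbind(cbind(X[ok1, , drop = FALSE], matrix(0, n1, ncol(X))),
                 cbind(matrix(0, n2, ncol(X)), X[ok2, , drop = FALSE]))
  keep <- qr(Xstar)$pivot[seq_len(qr(Xstar)$rank)]
  Xstar <- Xstar[, sort(keep), drop = FALSE]
  # parameter layout: for each component (G[,K],E): v1, v2, c
  Dlist <- list(); var_idx <- integer(0); cov_bounds <- list(); pmap <- list()
  for (nm in names(subm)) {
    j0 <- length(Dlist)
    Dlist[[j0 + 1L]] <- bivar_dmat(subm[[nm]], n1, n2, "v1")
    Dlist[[j0 + 2L]] <- bivar_dmat(subm[[nm]], n1, n2, "v2")
    Dlist[[j0 + 3L]] <- bivar_dmat(subm[[nm]], n1, n2, "c")
    var_idx <- c(var_idx, j0 + 1L, j0 + 2L)
    cov_bounds[[length(cov_bounds) + 1L]] <- c(j0 + 3L, j0 + 1L, j0 + 2L)
    pmap[[nm]] <- c(v1 = j0 + 1L, v2 = j0 + 2L, c = j0 + 3L)
  }
  nc <- length(subm)
  vp1 <- stats::var(stats::lm.fit(cbind(1, X[ok1, , drop = FALSE]), y1[ok1])$residuals)
  vp2 <- stats::var(stats::lm.fit(cbind(1, X[ok2, , drop = FALSE]), y2[ok2])$residuals)
  both <- intersect(ids1, ids2)
  r0 <- if (length(both) > 10)
    stats::cor(y1[ok1][match(both, ids1)], y2[ok2][match(both, ids2)]) else 0
  init <- numeric(3L * nc)
  for (nm in names(subm)) {
    init[pmap[[nm]][["v1"]]] <- vp1 / nc
    init[pmap[[nm]][["v2"]]] <- vp2 / nc
    init[pmap[[nm]][["c"]]] <- 0.5 * r0 * sqrt(vp1 * vp2) / nc
  }
  floor_val <- 1e-6 * max(vp1, vp2)
  res <- reml_core(ystar, Xstar, Dlist, init, var_idx = var_idx,
                   cov_bounds = cov_bounds, tol = tol, max_iter = max_iter,
                   floor_val = floor_val)
  theta <- res$theta
  AIinv <- tryCatch(solve(res$AI), error = function(e)
    solve(res$AI + diag(1e-8 * max(diag(res$AI)), length(theta))))
  corr_of <- function(nm) {
    ix <- pmap[[nm]]
    v1 <- theta[ix[["v1"]]]; v2 <- theta[ix[["v2"]]]; cc <- theta[ix[["c"]]]
    if (v1 <= floor_val * (1 + 1e-8) || v2 <= floor_val * (1 + 1e-8))
      return(list(r = NA_real_, se = NA_real_, defined = FALSE))
    s <- sqrt(v1 * v2)
    r <- cc / s
    grad <- numeric(length(theta))
    grad[ix[["c"]]] <- 1 / s
    grad[ix[["v1"]]] <- -cc / (2 * v1 * s)
    grad[ix[["v2"]]] <- -cc / (2 * v2 * s)
    se <- sqrt(max(drop(t(grad) %*% AIinv %*% grad), 0))
    if (abs(r) > 1) {
      warning(sprintf("unconstrained %s correlation %.3f outside [-1, 1]; clamped", nm, r))
      r <- sign(r)
    }
    list(r = r, se = se, defined = TRUE)
  }
  rg <- corr_of("G")
  rk <- if ("K" %in% names(pmap)) corr_of("K") else list(r = NULL, se = NULL, defined = FALSE)
  tot1 <- sum(theta[vapply(pmap, `[[`, 0L, "v1")])
  tot2 <- sum(theta[vapply(pmap, `[[`, 0L, "v2")])
  fr1 <- vapply(pmap, function(ix) theta[ix[["v1"]]] / tot1, 0)
  fr2 <- vapply(pmap, function(ix) theta[ix[["v2"]]] / tot2, 0)
  structure(list(r_G = rg$r, r_G_se = rg$se, r_G_defined = rg$defined,
                 r_K = rk$r, r_K_se = rk$se, r_K_defined = rk$defined,
                 fractions1 = fr1, fractions2 = fr2,
                 vcs = theta, pmap = pmap, logL = res$logL,
                 n1 = n1, n2 = n2, converged = res$converged,
                 iterations = res$iterations,
                 internal = list(ystar = ystar, Xstar = Xstar, Dlist = Dlist,
                                 var_idx = var_idx, cov_bounds = cov_bounds,
                                 floor_val = floor_val, tol = tol,
                                 max_iter = max_iter)),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate REML: n1 = %d, n2 = %d, logL = %.4f%s\n",
              x$n1, x$n2, x$logL, if (x$converged) "" else " (NOT converged)"))
  if (x$r_G_defined) cat(sprintf("  r_G = %.3f (SE %.3f)\n", x$r_G, x$r_G_se))
  if (isTRUE(x$r_K_defined)) cat(sprintf("  r_K = %.3f (SE %.3f)\n", x$r_K, x$r_K_se))
  invisible(x)
}

#' Likelihood-ratio test of a genetic correlation
#'
#' Refits the bivariate model with the named component's cross-trait
#' covariance fixed at zero and compares restricted log-likelihoods:
#' `statistic = max(0, 2 (logL - logL_constrained))`, with the one-tailed
#' `p = 0.5 P(chisq_1 > statistic)`.
#'
#' @param fit A [bivariate_fit()] result.
#' @param component `"G"` or `"K"`.
#' @return An `"lrt_result"` list (`statistic`, `p`, `component`), with
#'   `constrained_converged` flagging the constrained refit.
#' @export
lrt_correlation <- function(fit, component = c("G", "K")) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "bivariate_fit"))
  if (!component %in% names(fit$pmap)) stop("component not in the fitted model")
  cix <- fit$pmap[[component]][["c"]]
  it <- fit$internal
  keep <- setdiff(seq_along(it$Dlist), cix)
  Dlist0 <- it$Dlist[keep]
  var_idx0 <- match(intersect(it$var_idx, keep), keep)
  cb0 <- list()
  for (b in it$cov_bounds) {
    if (b[1L] == cix) next
    cb0[[length(cb0) + 1L]] <- match(b, keep)
  }
  init0 <- fit$vcs[keep]
  res0 <- reml_core(it$ystar, it$Xstar, Dlist0, init0, var_idx = var_idx0,
                    cov_bounds = cb0, tol = it$tol, max_iter = it$max_iter,
                    floor_val = it$floor_val)
  stat <- max(0, 2 * (fit$logL - res0$logL))
  structure(list(statistic = stat,
                 p = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df_boundary = TRUE, component = component,
                 constrained_converged = res0$converged), class = "lrt_result")
}
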