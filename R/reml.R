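## Restricted maximum likelihood for variance-component models
##
## The model is y ~ N(X beta, V),  V = sum_j theta_j D_j, where the D_j are
## relationship matrices plus the residual identity (univariate), or the
## block derivative matrices of a stacked two-trait system (bivariate).
## Estimation is by the average-information algorithm with an EM first step
## and EM/step-halving fallbacks; variances are floored at a small positive
## value, which corresponds to the boundary estimate reported as 0.00.

# One evaluation of the restricted log-likelihood and its workspace.
# Returns NULL if V is not positive definite.
reml_eval <- function(theta, Dlist, y, X) {
  V <- Dlist[[1L]] * theta[1L]
  for (j in seq_along(Dlist)[-1L]) V <- V + Dlist[[j]] * theta[j]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  P <- Vi - ViX %*% chol2inv(cX) %*% t(ViX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cX))) + yPy)
  list(logL = logL, P = P, Py = Py)
}

# Average-information REML over an arbitrary list of derivative matrices.
# var_idx: indices of theta constrained to [floor, Inf); cov_bounds: list of
# c(cov, v1, v2) index triples for covariance parameters clamped inside the
# PSD box |c| <= 0.99 sqrt(v1 v2).
reml_core <- function(y, X, Dlist, init, var_idx, cov_bounds = list(),
                      tol = 1e-4, max_iter = 100L, floor_val = NULL,
                      verbose = FALSE) {
  n <- length(y)
  k <- length(Dlist)
  theta <- init
  if (is.null(floor_val)) floor_val <- 1e-6 * stats::var(y)
  clamp <- function(th) {
    th[var_idx] <- pmax(th[var_idx], floor_val)
    for (b in cov_bounds) {
      lim <- 0.99 * sqrt(th[b[2L]] * th[b[3L]])
      th[b[1L]] <- max(-lim, min(lim, th[b[1L]]))
    }
    th
  }
  theta <- clamp(theta)
  ev <- reml_eval(theta, Dlist, y, X)
  if (is.null(ev)) stop("initial variance parameters give a singular covariance matrix")
  logL_hist <- ev$logL
  converged <- FALSE
  AI <- NULL
  lambda <- 0   # LM damping, annealed across iterations
  for (iter in seq_len(max_iter)) {
    P <- ev$P; Py <- ev$Py
    Q <- matrix(0, n, k)
    trPD <- numeric(k)
    for (j in seq_len(k)) {
      Q[, j] <- Dlist[[j]] %*% Py
      trPD[j] <- sum(P * Dlist[[j]])
    }
    yPDPy <- drop(crossprod(Py, Q))
    score <- -0.5 * (trPD - yPDPy)
    PQ <- P %*% Q
    AI <- 0.5 * crossprod(Q, PQ)
    em_prop <- function() {
      prop <- theta
      prop[var_idx] <- theta[var_idx] +
        theta[var_idx]^2 * (yPDPy[var_idx] - trPD[var_idx]) / n
      clamp(prop)
    }
    if (iter == 1L && length(cov_bounds) == 0L) {
      # EM first step: monotone and safely inside the parameter space
      prop <- em_prop()
      ev_new <- reml_eval(prop, Dlist, y, X)
      if (!is.null(ev_new)) { theta <- prop; ev <- ev_new }
      logL_hist <- c(logL_hist, ev$logL)
      next
    }
    # active set: variances pinned at the floor with a negative gradient are
    # held fixed, so the update cannot thrash against the boundary
    pinned <- seq_len(k) %in% var_idx & theta <= floor_val * (1 + 1e-8) & score < 0
    free <- which(!pinned)
    if (length(free) == 0L) {
      logL_hist <- c(logL_hist, ev$logL)
      converged <- TRUE
      break
    }
    # Levenberg-Marquardt damped AI step: an ill-conditioned AI matrix (e.g.
    # nearly collinear components) bends the step toward the scaled gradient
    AIf <- AI[free, free, drop = FALSE]
    dscale <- pmax(diag(AIf), 1e-12 * max(diag(AIf)))
    accepted <- FALSE
    pred_inc <- Inf
    for (h in seq_len(12L)) {
      dfree <- tryCatch(solve(AIf + diag(lambda * dscale, length(free)), score[free]),
                        error = function(e) NULL)
      if (!is.null(dfree) && all(is.finite(dfree))) {
        delta <- rep(0, k)
        delta[free] <- dfree
        prop <- clamp(theta + delta)
        ev_new <- reml_eval(prop, Dlist, y, X)
        if (!is.null(ev_new) && ev_new$logL >= ev$logL - 1e-8) {
          pred_inc <- sum(score[free] * dfree) / 2
          theta <- prop; ev <- ev_new; accepted <- TRUE
          lambda <- if (lambda < 1e-3) 0 else lambda / 10
          break
        }
      }
      lambda <- if (lambda == 0) 0.01 else lambda * 10
    }
    if (!accepted) {
      # EM fallback on the variance parameters (guaranteed uphill)
      prop <- em_prop()
      ev_new <- reml_eval(prop, Dlist, y, X)
      if (!is.null(ev_new) && ev_new$logL >= ev$logL - 1e-8) {
        theta <- prop; ev <- ev_new; accepted <- TRUE
      }
    }
    logL_hist <- c(logL_hist, ev$logL)
    if (verbose)
      message(sprintf("iter %d: logL = %.6f (lambda %.2g)", iter, ev$logL, lambda))
    if (!accepted) {  # no ascent direction found: stationary point
      converged <- TRUE
      break
    }
    nh <- length(logL_hist)
    dlogL <- abs(logL_hist[nh] - logL_hist[nh - 1L])
    # converged only when both the achieved and the predicted quadratic-model
    # improvement are below tolerance (guards against damped-step stalls)
    if (iter >= 2L && dlogL < tol && pred_inc < 100 * tol) {
      converged <- TRUE
      break
    }
  }
  at_floor <- theta[var_idx] <= floor_val * (1 + 1e-8)
  list(theta = theta, logL = ev$logL, AI = AI, converged = converged,
       iterations = length(logL_hist) - 1L, at_floor = at_floor,
       floor_val = floor_val, logL_hist = logL_hist)
}

align_matrix <- function(M, ids, label) {
  if (inherits(M, "relmat")) {
    if (!all(ids %in% M$ids))
      stop(sprintf("matrix '%s' is missing individuals present in y", label))
    M$values[ids, ids, drop = FALSE]
  } else {
    M <- as.matrix(M)
    if (!is.null(rownames(M))) {
      if (!all(ids %in% rownames(M)))
        stop(sprintf("matrix '%s' is missing individuals present in y", label))
      M[ids, ids, drop = FALSE]
    } else {
      if (nrow(M) != length(ids))
        stop(sprintf("matrix '%s' has no ids and does not match y's length", label))
      M
    }
  }
}

#' Fit a multi-component variance decomposition by AI-REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X beta, sum_c sigma2_c M_c + sigma2_e I)` by average-information
#' REML (EM first step, EM/step-halving fallback when an AI step leaves the
#' parameter space, variances floored at `1e-6` of the phenotypic variance).
#' Standard errors come from the inverse average-information matrix; variance
#' fractions and their SEs by the delta method.
#'
#' @param y Trait vector (names, if present, are individual ids).
#' @param X Fixed-effect design matrix (an intercept column is prepended if
#'   absent); `NULL` for intercept only.
#' @param matrices Named list of relationship matrices (`relmat` objects or
#'   plain matrices). Names such as `"G"`, `"K"`, `"F"`, `"S"`, `"C"` label
#'   the components. May be empty, in which case the residual variance is
#'   the OLS estimate with the `N - p` denominator.
#' @param ids Individual ids aligning `y` with the matrices (defaults to
#'   `names(y)`; plain unnamed matrices are taken as already aligned).
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-4`).
#' @param max_iter Maximum number of iterations (default 100).
#' @param start Optional starting variances (one per component plus
#'   residual).
#' @param verbose Print per-iteration log-likelihoods.
#' @return An object of class `"reml_fit"`: `fractions` (per component and
#'   residual), `se`, `vcs` (variance estimates), `logL`, `n_used`,
#'   `converged`, `h2n` (sum of G and K fractions when both present),
#'   `components`, `at_floor`.
#' @export
reml_fit <- function(y, X = NULL, matrices = list(), ids = NULL,
                     tol = 1e-4, max_iter = 100L, start = NULL,
                     verbose = FALSE) {
  if (is.null(ids)) ids <- names(y)
  if (is.null(X)) X <- matrix(1, length(y), 1L, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2L, function(col) all(col == col[1L] & col[1L] != 0))))
    X <- cbind(intercept = 1, X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  if (!is.null(ids)) ids <- ids[cc]
  n <- length(y)
  k <- length(matrices)
  if (n <= ncol(X) + k) stop("too few complete cases for the requested model")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design matrix")
  comp_names <- names(matrices)
  if (k > 0L && (is.null(comp_names) || any(comp_names == "")))
    stop("'matrices' must be a named list")
  if (k == 0L) {
    fit0 <- stats::lm.fit(X, y)
    p <- ncol(X)
    s2 <- sum(fit0$residuals^2) / (n - p)
    logL <- -0.5 * ((n - p) * log(s2) + determinant(crossprod(X))$modulus[1L] + (n - p))
    return(structure(list(
      fractions = c(residual = 1), se = c(residual = NA_real_),
      vcs = c(residual = s2), vcs_se = c(residual = sqrt(2 * s2^2 / (n - p))),
      logL = logL, n_used = n, converged = TRUE, iterations = 0L,
      h2n = NULL, h2n_se = NULL, components = character(0),
      at_floor = logical(0), fixef = fit0$coefficients), class = "reml_fit"))
  }
  Dlist <- c(lapply(seq_len(k), function(j)
    align_matrix(matrices[[j]], if (is.null(ids)) as.character(seq_len(n)) else ids,
                 comp_names[j])), list(diag(n)))
  vp <- stats::var(stats::lm.fit(X, y)$residuals) * (n - 1) / (n - ncol(X))
  init <- if (is.null(start)) rep(vp / (k + 1), k + 1L) else start
  res <- reml_core(y, X, Dlist, init, var_idx = seq_len(k + 1L),
                   tol = tol, max_iter = max_iter,
                   floor_val = 1e-6 * vp, verbose = verbose)
  theta <- res$theta
  total <- sum(theta)
  frac <- theta / total
  names(frac) <- c(comp_names, "residual")
  # delta-method SEs of fractions from the AI covariance of the variances
  AIinv <- tryCatch(solve(res$AI), error = function(e)
    solve(res$AI + diag(1e-8 * max(diag(res$AI)), k + 1L)))
  J <- (diag(k + 1L) * total - matrix(theta, k + 1L, k + 1L)) / total^2
  se <- sqrt(pmax(diag(J %*% AIinv %*% t(J)), 0))
  names(se) <- names(frac)
  h2n <- h2n_se <- NULL
  if (all(c("G", "K") %in% comp_names)) {
    gk <- match(c("G", "K"), names(frac))
    h2n <- sum(frac[gk])
    w <- rep(0, k + 1L); w[gk] <- 1
    h2n_se <- sqrt(max(drop(t(w) %*% J %*% AIinv %*% t(J) %*% w), 0))
  }
  low_id <- min(eigen(res$AI, symmetric = TRUE, only.values = TRUE)$values)
  if (low_id < 1e-10 * max(diag(res$AI)))
    warning("average-information matrix is near-singular: some variance components are not separately identifiable")
  structure(list(fractions = frac, se = se, vcs = stats::setNames(theta, names(frac)),
                 vcs_se = stats::setNames(sqrt(pmax(diag(AIinv), 0)), names(frac)),
                 logL = res$logL, n_used = n, converged = res$converged,
                 iterations = res$iterations, h2n = h2n, h2n_se = h2n_se,
                 components = comp_names, at_floor = res$at_floor[seq_len(k)],
                 total_var = total), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  code <- paste(x$components, collapse = "")
  cat(sprintf("REML fit [%s]: n = %d, logL = %.4f%s\n",
              if (nzchar(code)) code else "residual only", x$n_used, x$logL,
              if (x$converged) "" else " (NOT converged)"))
  tab <- data.frame(fraction = sprintf("%.4f", x$fractions),
                    se = sprintf("%.4f", x$se), row.names = names(x$fractions))
  print(tab)
  if (!is.null(x$h2n)) cat(sprintf("h2n (G + K) = %.4f (%.4f)\n", x$h2n, x$h2n_se))
  invisible(x)
}

#' Boundary likelihood-ratio test for a single variance component
#'
#' The null value of a variance component lies on the boundary of the
#' parameter space, so the LRT statistic `max(0, 2 (logL_full -
#' logL_reduced))` is referred to the 50:50 mixture of a point mass at zero
#' and a chi-square with 1 df: `p = 0.5 P(chisq_1 > statistic)` (one-tailed).
#'
#' @param full,reduced `reml_fit` objects whose component sets differ by
#'   exactly one component (reduced nested in full).
#' @return A list of class `"lrt_result"`: `statistic`, `p`, `df_boundary`,
#'   `component` (the tested component).
#' @export
lrt_component <- function(full, reduced) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  extra <- setdiff(full$components, reduced$components)
  if (length(extra) != 1L || !all(reduced$components %in% full$components))
    stop("reduced model must be nested in the full model and differ by exactly one component")
  stat <- max(0, 2 * (full$logL - reduced$logL))
  structure(list(statistic = stat,
                 p = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df_boundary = TRUE, component = extra), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("boundary LRT [%s]: statistic = %.4f, one-tailed p = %.4g\n",
              x$component, x$statistic, x$p))
  invisible(x)
}

#' Backward stepwise selection over variance components
#'
#' Starting from the model with all supplied components, each current
#' component is tested with a boundary LRT against the model dropping it
#' alone; if any p-value is at or above `alpha`, the single component with
#' the largest p (ties broken by the smaller estimated fraction) is removed
#' and the procedure repeats, until every remaining component is
#' significant. All fits are cached and reused across rounds.
#'
#' @param y,X,ids,tol,max_iter As in [reml_fit()].
#' @param matrices Named list of candidate component matrices (e.g. G, K, F,
#'   S, C).
#' @param alpha Retention threshold on the one-tailed LRT p (default 0.05).
#' @return A list of class `"backward_selection"`: `components` (retained),
#'   `fit` (final `reml_fit`), `trace` (per-round tested p-values and the
#'   component dropped), `fits` (cache of all models fitted, keyed by model
#'   code).
#' @export
backward_select <- function(y, X = NULL, matrices, ids = NULL, alpha = 0.05,
                            tol = 1e-4, max_iter = 100L) {
  stopifnot(length(matrices) >= 1L)
  cache <- new.env(parent = emptyenv())
  code_of <- function(comps) if (length(comps)) paste(comps, collapse = "") else "(none)"
  get_fit <- function(comps, start = NULL) {
    key <- code_of(comps)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- reml_fit(y, X, matrices[comps], ids = ids, tol = tol,
                  max_iter = max_iter, start = start)
    cache[[key]] <- f
    f
  }
  current <- names(matrices)
  trace <- list()
  repeat {
    full <- get_fit(current)
    ps <- vapply(current, function(comp) {
      red_comps <- setdiff(current, comp)
      st <- full$vcs[c(red_comps, "residual")]
      red <- get_fit(red_comps, start = unname(st))
      lrt_component(full, red)$p
    }, 0)
    round_rec <- list(components = current, p = ps, dropped = NA_character_)
    if (all(ps < alpha) || length(current) == 0L) {
      trace[[length(trace) + 1L]] <- round_rec
      break
    }
    worst <- which(ps == max(ps))
    if (length(worst) > 1L) {  # tie: drop the component with the smaller fraction
      fr <- full$fractions[current[worst]]
      worst <- worst[which.min(fr)]
    }
    round_rec$dropped <- current[worst]
    trace[[length(trace) + 1L]] <- round_rec
    current <- setdiff(current, current[worst])
    if (length(current) == 0L) break
  }
  final <- get_fit(current)
  structure(list(components = current, fit = final, trace = trace,
                 fits = as.list(cache), alpha = alpha,
                 empty = length(current) == 0L), class = "backward_selection")
}

#' @export
print.backward_selection <- function(x, ...) {
  cat(sprintf("backward selection: %d round(s), final model [%s]\n",
              length(x$trace),
              if (length(x$components)) paste(x$components, collapse = "") else "fixed effects only"))
  for (i in seq_along(x$trace)) {
    r <- x$trace[[i]]
    cat(sprintf("  round %d: %s%s\n", i,
                paste(sprintf("%s=%.3g", r$components, r$p), collapse = " "),
                if (is.na(r$dropped)) " -> stop" else paste0(" -> drop ", r$dropped)))
  }
  invisible(x)
}

#' Format a set of model fits as a report table
#'
#' Renders, per trait, one row per model (e.g. the genetics-only GK model,
#' the full GKFSC model and the backward-selected model) with each variance
#' fraction shown as `"est (se)"`, starred when its one-tailed LRT p-value
#' (if supplied) is below `alpha`.
#'
#' @param fits Named list (model label -> `reml_fit`), or a named list of
#'   such lists (trait -> models).
#' @param p_values Optional parallel structure of named numeric vectors of
#'   per-component LRT p-values.
#' @param alpha Significance threshold for starring (default 0.05).
#' @return A data frame with columns `trait`, `model`, `code`, `n`, and one
#'   column per component (G, K, F, S, C) plus `residual`.
#' @export
report_table <- function(fits, p_values = NULL, alpha = 0.05) {
  comps <- c("G", "K", "F", "S", "C", "residual")
  empty <- stats::setNames(as.list(rep(NA_character_, length(comps))), comps)
  if (length(fits) == 0L)
    return(cbind(data.frame(trait = character(0), model = character(0),
                            code = character(0), n = integer(0)),
                 as.data.frame(lapply(empty, function(x) character(0)))))
  nested <- all(vapply(fits, function(f) is.list(f) && !inherits(f, "reml_fit"), TRUE))
  if (!nested) { fits <- list(trait = fits); p_values <- if (!is.null(p_values)) list(trait = p_values) }
  rows <- list()
  for (tr in names(fits)) {
    for (md in names(fits[[tr]])) {
      f <- fits[[tr]][[md]]
      stopifnot(inherits(f, "reml_fit"))
      cells <- empty
      for (cn in names(f$fractions)) {
        star <- ""
        pv <- p_values[[tr]][[md]]
        if (!is.null(pv) && cn %in% names(pv) && is.finite(pv[[cn]]) && pv[[cn]] < alpha)
          star <- "*"
        cells[[cn]] <- sprintf("%.2f (%.2f)%s", f$fractions[[cn]], f$se[[cn]], star)
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(trait = tr, model = md,
                   code = paste(f$components, collapse = ""), n = f$n_used),
        as.data.frame(cells, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
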