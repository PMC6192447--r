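#' Score the Brief Resilience Scale
#'
#' Six 1-5 Likert items; even-numbered items are reverse-coded
#' (`x -> 6 - x`) and the score is the mean of the six recoded items.
#' Incomplete responses are prorated (mean of available items) when at least
#' half the items are present, otherwise the score is `NA`.
#'
#' @param items A numeric vector of 6 item responses, or a matrix/data frame
#'   with 6 item columns (one row per respondent).
#' @return Resilience score(s) in `[1, 5]`.
#' @examples
#' score_brs(c(5, 1, 5, 1, 5, 1))  # 5: even items reverse to 5
#' @export
score_brs <- function(items) {
  X <- as.matrix(items)
  if (is.vector(items) && is.null(dim(items))) X <- matrix(items, nrow = 1L)
  if (ncol(X) != 6L) stop("BRS requires exactly 6 items")
  check_likert(X)
  X[, c(2L, 4L, 6L)] <- 6 - X[, c(2L, 4L, 6L)]
  n_ok <- rowSums(!is.na(X))
  out <- ifelse(n_ok >= 3L, rowMeans(X, na.rm = TRUE), NA_real_)
  if (is.vector(items) && is.null(dim(items))) out[[1L]] else unname(out)
}

check_likert <- function(X) {
  v <- X[!is.na(X)]
  if (length(v) && (any(v < 1) || any(v > 5)))
    stop("item responses must lie in 1..5 (or be missing)")
  invisible(TRUE)
}

#' Default CISS item-to-subscale map
#'
#' The published assignment is proprietary to the instrument; the shipped
#' placeholder maps items 1-16 to task-, 17-32 to emotion- and 33-48 to
#' avoidance-oriented coping. Supply your own map to [score_ciss()] to use a
#' licensed layout.
#'
#' @return A named integer vector of length 48 with values in `ToC`, `EoC`,
#'   `AoC` order encoded as subscale labels.
#' @export
ciss_default_map <- function() {
  stats::setNames(rep(c("ToC", "EoC", "AoC"), each = 16L),
                  sprintf("item%02d", 1:48))
}

#' Score the Coping Inventory for Stressful Situations
#'
#' 48 1-5 Likert items summed over three 16-item subscales: task-oriented
#' (ToC), emotion-oriented (EoC) and avoidance-oriented (AoC) coping.
#' Subscales with at least half their items present are prorated to the full
#' 16-item sum; otherwise `NA`.
#'
#' @param items A length-48 vector or a 48-column matrix/data frame.
#' @param map Item-to-subscale assignment; see [ciss_default_map()].
#' @return A data frame (or named vector for a single response) with columns
#'   `ToC`, `EoC`, `AoC`, each in `[16, 80]` for complete responses.
#' @examples
#' score_ciss(rep(1, 48))  # c(ToC = 16, EoC = 16, AoC = 16)
#' @export
score_ciss <- function(items, map = ciss_default_map()) {
  single <- is.vector(items) && is.null(dim(items))
  X <- if (single) matrix(items, nrow = 1L) else as.matrix(items)
  if (ncol(X) != 48L) stop("CISS requires exactly 48 items")
  if (length(map) != 48L || !all(map %in% c("ToC", "EoC", "AoC")))
    stop("subscale map must assign each of 48 items to ToC, EoC or AoC")
  if (any(table(map) != 16L)) stop("each CISS subscale must contain 16 items")
  check_likert(X)
  sums <- matrix(NA_real_, nrow(X), 3L, dimnames = list(NULL, c("ToC", "EoC", "AoC")))
  for (s in colnames(sums)) {
    cols <- which(map == s)
    n_ok <- rowSums(!is.na(X[, cols, drop = FALSE]))
    sums[, s] <- ifelse(n_ok >= 8L, rowMeans(X[, cols, drop = FALSE], na.rm = TRUE) * 16, NA_real_)
  }
  if (single) sums[1L, ] else as.data.frame(sums)
}

#' Covariate-adjusted Pearson correlation
#'
#' Residualizes both trait vectors on the covariates (plus an intercept) by
#' ordinary least squares and returns the Pearson correlation of the
#' residuals with its large-sample standard error
#' `sqrt((1 - r^2) / (n - 2 - q))`, `q` the number of covariates. With no
#' covariates this is the plain Pearson correlation. Rows with any missing
#' value are dropped.
#'
#' @param x,y Trait vectors.
#' @param covars Optional data frame / matrix of covariates (e.g. age and a
#'   0/1 sex indicator).
#' @return A list with `r`, `se` and `n`.
#' @export
adjusted_pearson <- function(x, y, covars = NULL) {
  q <- if (is.null(covars)) 0L else ncol(as.matrix(covars))
  cc <- stats::complete.cases(x, y, if (is.null(covars)) rep(TRUE, length(x)) else covars)
  if (sum(cc) < 4L + q) stop("too few complete cases for adjusted correlation")
  x <- x[cc]; y <- y[cc]
  if (q > 0L) {
    Z <- as.matrix(covars)[cc, , drop = FALSE]
    x <- stats::lm.fit(cbind(1, Z), x)$residuals
    y <- stats::lm.fit(cbind(1, Z), y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero residual variance; adjusted correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  list(r = r, se = sqrt((1 - r^2) / (n - 2L - q)), n = n)
}

#' Simulate Likert questionnaire responses from latent trait scores
#'
#' Generates item responses consistent with a latent trait: each item's
#' propensity is the standardized latent score plus independent normal item
#' noise, discretized into five ordered categories at fixed thresholds.
#' For the BRS, even-numbered items are stored reverse-keyed (so scoring
#' reverses them back); CISS items are emitted in three 16-item blocks
#' driven by the ToC, EoC and AoC latent scores.
#'
#' @param latent A data frame with an `id` column and the latent trait
#'   column(s): `resilience` for BRS; `ToC`, `EoC`, `AoC` for CISS.
#' @param instrument `"BRS"` or `"CISS"`.
#' @param item_noise Standard deviation of the item-level noise on the
#'   standardized latent scale. The default 0.9 is calibrated so that BRS
#'   internal consistency (Cronbach's alpha) falls in the 0.80-0.91 band
#'   reported for the instrument.
#' @param missing_rate Probability an item response is missing.
#' @param seed Integer seed.
#' @return A data frame `id`, `item01..itemNN`.
#' @export
simulate_items <- function(latent, instrument = c("BRS", "CISS"),
                           item_noise = 0.9, missing_rate = 0, seed = 1L) {
  instrument <- match.arg(instrument)
  set.seed(seed)
  n <- nrow(latent)
  gen_block <- function(z, k, reverse_even = FALSE) {
    zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    cuts <- c(-1.5, -0.5, 0.5, 1.5) * sqrt(1 + item_noise^2)
    items <- sapply(seq_len(k), function(j) {
      prop <- zs + stats::rnorm(n, 0, item_noise)
      resp <- findInterval(prop, cuts) + 1L
      if (reverse_even && j %% 2L == 0L) resp <- 6L - resp
      resp
    })
    items
  }
  if (instrument == "BRS") {
    if (!"resilience" %in% names(latent)) stop("latent table needs a 'resilience' column")
    X <- gen_block(latent$resilience, 6L, reverse_even = TRUE)
  } else {
    need <- c("ToC", "EoC", "AoC")
    if (!all(need %in% names(latent)))
      stop("latent table needs 'ToC', 'EoC' and 'AoC' columns")
    X <- do.call(cbind, lapply(need, function(tr) gen_block(latent[[tr]], 16L)))
  }
  if (missing_rate > 0) X[stats::runif(length(X)) < missing_rate] <- NA_integer_
  out <- data.frame(id = latent$id, X)
  names(out)[-1L] <- sprintf("item%02d", seq_len(ncol(X)))
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total score))`,
#' computed on complete responses. Reverse-keyed items should be recoded
#' first (as [score_brs()] does internally).
#'
#' @param X Matrix or data frame of item responses (rows = respondents).
#' @return Cronbach's alpha.
#' @export
cronbach_alpha <- function(X) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  k / (k - 1) * (1 - sum(apply(X, 2L, stats::var)) / stats::var(rowSums(X)))
}
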