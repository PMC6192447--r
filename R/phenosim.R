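#' Specify the generative variance structure of a simulated trait
#'
#' Fractions of total phenotypic variance assigned to the common-variant
#' genetic component (tagged by G), the additional pedigree-associated
#' genetic component (tagged by K), and the nuclear-family, full-sibling and
#' couple shared-environment components (F, S, C). The residual fraction is
#' `1 - sum(fractions)`.
#'
#' @param h2_g,h2_p,e2_f,e2_s,e2_c Variance fractions in `[0, 1]` summing to
#'   at most 1.
#' @param beta_age,beta_sex Fixed-effect sizes for age (per year) and sex
#'   (0/1 indicator).
#' @param total_var Total phenotypic variance after fixed effects.
#' @return An object of class `"variance_spec"`.
#' @export
variance_spec <- function(h2_g = 0, h2_p = 0, e2_f = 0, e2_s = 0, e2_c = 0,
                          beta_age = 0, beta_sex = 0, total_var = 1) {
  fr <- c(h2_g = h2_g, h2_p = h2_p, e2_f = e2_f, e2_s = e2_s, e2_c = e2_c)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) stop("variance fractions must lie in [0, 1]: ", paste(bad, collapse = ", "))
  if (sum(fr) > 1 + 1e-12) stop("variance fractions sum to more than 1")
  if (total_var <= 0) stop("total_var must be positive")
  structure(list(fractions = fr, beta_age = beta_age, beta_sex = beta_sex,
                 total_var = total_var), class = "variance_spec")
}

#' Specify a bivariate generative model
#'
#' Two [variance_spec()]s plus the cross-trait correlations of the
#' common-variant genetic effects (`r_G`), the pedigree-associated genetic
#' effects (`r_K`) and the residuals (`r_E`). Shared-environment effects are
#' drawn independently per trait.
#'
#' @param trait1,trait2 [variance_spec()] objects.
#' @param r_G,r_K,r_E Correlations in `[-1, 1]`.
#' @return An object of class `"bivariate_spec"`.
#' @export
bivariate_spec <- function(trait1, trait2, r_G = 0, r_K = 0, r_E = 0) {
  stopifnot(inherits(trait1, "variance_spec"), inherits(trait2, "variance_spec"))
  for (r in c(G = r_G, K = r_K, E = r_E))
    if (abs(r) > 1) stop("correlations must lie in [-1, 1] (implied covariance not PSD)")
  structure(list(trait1 = trait1, trait2 = trait2, r_G = r_G, r_K = r_K, r_E = r_E),
            class = "bivariate_spec")
}

scale_to_var <- function(v, target_var) {
  v <- v - mean(v)
  s <- stats::sd(v)
  if (target_var <= 0 || s == 0) return(v * 0)
  v / s * sqrt(target_var)
}

standardized_dosages <- function(geno, cols = NULL) {
  X <- unclass(geno)
  storage.mode(X) <- "double"
  if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  Z <- sweep(X, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0
  sweep(Z, 2L, sqrt(pmax(2 * p * (1 - p), 1e-12)), `/`)
}

# one shared draw per group; singletons get independent draws
group_effect <- function(groups_list, ids) {
  eff <- stats::rnorm(length(ids))               # independent baseline draw
  names(eff) <- ids
  for (g in groups_list) {
    val <- stats::rnorm(1L)
    eff[as.character(g)] <- val
  }
  unname(eff)
}

sim_components <- function(ped, geno, spec, n_causal, A_chol, causal_cols,
                           effects = NULL) {
  n <- nrow(ped)
  fr <- spec$fractions
  tv <- spec$total_var
  cs <- pedigree_counts(ped)
  out <- list()
  # common-variant genetic: standardized causal dosages x normal effects
  if (fr[["h2_g"]] > 0) {
    Z <- standardized_dosages(geno, causal_cols)
    a <- if (is.null(effects)) stats::rnorm(length(causal_cols)) else effects
    out$g <- scale_to_var(unname(drop(Z %*% a)), fr[["h2_g"]] * tv)
  } else out$g <- numeric(n)
  # pedigree-associated genetic: MVN with expected-relationship covariance
  if (fr[["h2_p"]] > 0) {
    out$k <- scale_to_var(drop(crossprod(A_chol, stats::rnorm(n))), fr[["h2_p"]] * tv)
  } else out$k <- numeric(n)
  out$f <- if (fr[["e2_f"]] > 0)
    scale_to_var(group_effect(cs$families, ped$id), fr[["e2_f"]] * tv) else numeric(n)
  sibships <- Filter(function(s) length(s) >= 2L,
                     split(ped$id[!is.na(ped$father)],
                           paste(ped$father[!is.na(ped$father)],
                                 ped$mother[!is.na(ped$father)])))
  out$s <- if (fr[["e2_s"]] > 0)
    scale_to_var(group_effect(sibships, ped$id), fr[["e2_s"]] * tv) else numeric(n)
  couples <- if (nrow(cs$couple_pairs)) asplit(cs$couple_pairs, 1L) else list()
  out$c <- if (fr[["e2_c"]] > 0)
    scale_to_var(group_effect(couples, ped$id), fr[["e2_c"]] * tv) else numeric(n)
  res_fr <- 1 - sum(fr)
  out$e <- if (res_fr > 1e-12)
    scale_to_var(stats::rnorm(n), res_fr * tv) else numeric(n)
  out
}

#' Simulate phenotypes with known variance structure
#'
#' Generates `y = beta_age * age + beta_sex * sex + g + k + f + s + c + e`:
#' `g` is a weighted sum of standardized causal-SNP dosages with standard
#' normal effect sizes; `k` is multivariate normal with covariance
#' proportional to the expected pedigree relationship matrix; `f`, `s`, `c`
#' are one shared draw per nuclear-family unit / sibship / couple
#' (individuals outside any such group receive independent draws); `e` is
#' independent noise. Each component is rescaled so its realized sample
#' variance matches its specified fraction of `total_var` exactly.
#'
#' @param ped A `pedigree`.
#' @param geno A `genotype_matrix` aligned to `ped`.
#' @param spec A [variance_spec()].
#' @param n_causal Number of causal SNPs (sampled without replacement).
#' @param seed Integer seed.
#' @param trait_name Column name for the simulated trait.
#' @return A data frame (`id`, `age`, `sex`, trait) with attribute
#'   `"truth"`: the realized variance fractions and the component vectors.
#' @export
simulate_phenotypes <- function(ped, geno, spec, n_causal = 500L, seed = 1L,
                                trait_name = "trait") {
  stopifnot(inherits(spec, "variance_spec"))
  if (n_causal > ncol(geno)) stop("n_causal exceeds the number of SNPs")
  set.seed(seed)
  n <- nrow(ped)
  age <- stats::runif(n, 18, 90)
  sex <- ped$sex
  A_chol <- if (spec$fractions[["h2_p"]] > 0)
    chol(pedigree_additive_matrix(ped) + diag(1e-8, n)) else NULL
  causal_cols <- sort(sample.int(ncol(geno), n_causal))
  comp <- sim_components(ped, geno, spec, n_causal, A_chol, causal_cols)
  y <- spec$beta_age * age + spec$beta_sex * sex +
    comp$g + comp$k + comp$f + comp$s + comp$c + comp$e
  out <- data.frame(id = ped$id, age = age, sex = sex, y)
  names(out)[4L] <- trait_name
  tot <- comp$g + comp$k + comp$f + comp$s + comp$c + comp$e
  attr(out, "truth") <- list(
    spec = spec,
    realized = c(vapply(comp[c("g", "k", "f", "s", "c")], stats::var, 0),
                 e = stats::var(comp$e)) / stats::var(tot),
    components = comp, causal = causal_cols)
  out
}

#' Simulate a correlated pair of traits
#'
#' As [simulate_phenotypes()], with the common-variant genetic effects of
#' the two traits drawn at the same causal SNPs from a bivariate normal with
#' correlation `r_G`, the pedigree-associated effects correlated at `r_K`,
#' and residuals correlated at `r_E`. Shared-environment draws are
#' independent between traits.
#'
#' @param ped,geno,n_causal,seed As in [simulate_phenotypes()].
#' @param spec A [bivariate_spec()].
#' @param trait_names Column names of the two traits.
#' @return A data frame (`id`, `age`, `sex`, two traits) with a `"truth"`
#'   attribute holding per-trait components.
#' @export
simulate_bivariate_phenotypes <- function(ped, geno, spec, n_causal = 500L,
                                          seed = 1L,
                                          trait_names = c("trait1", "trait2")) {
  stopifnot(inherits(spec, "bivariate_spec"))
  set.seed(seed)
  n <- nrow(ped)
  age <- stats::runif(n, 18, 90)
  sex <- ped$sex
  need_k <- spec$trait1$fractions[["h2_p"]] > 0 || spec$trait2$fractions[["h2_p"]] > 0
  A_chol <- if (need_k) chol(pedigree_additive_matrix(ped) + diag(1e-8, n)) else NULL
  causal_cols <- sort(sample.int(ncol(geno), n_causal))
  # correlated effect-size pairs
  z1 <- stats::rnorm(n_causal); z2 <- stats::rnorm(n_causal)
  a1 <- z1
  a2 <- spec$r_G * z1 + sqrt(max(0, 1 - spec$r_G^2)) * z2
  comp1 <- sim_components(ped, geno, spec$trait1, n_causal, A_chol, causal_cols,
                          effects = a1)
  # correlated pedigree and residual draws, independent F/S/C draws
  set.seed(seed + 1L)
  comp2 <- sim_components(ped, geno, spec$trait2, n_causal, A_chol, causal_cols,
                          effects = a2)
  if (need_k && spec$trait2$fractions[["h2_p"]] > 0) {
    u1 <- if (spec$trait1$fractions[["h2_p"]] > 0 && stats::sd(comp1$k) > 0)
      comp1$k / stats::sd(comp1$k) else drop(crossprod(A_chol, stats::rnorm(n)))
    u2 <- drop(crossprod(A_chol, stats::rnorm(n)))
    comp2$k <- scale_to_var(spec$r_K * u1 + sqrt(max(0, 1 - spec$r_K^2)) * u2,
                            spec$trait2$fractions[["h2_p"]] * spec$trait2$total_var)
  }
  r1 <- 1 - sum(spec$trait1$fractions); r2 <- 1 - sum(spec$trait2$fractions)
  if (r1 > 1e-12 && r2 > 1e-12 && spec$r_E != 0) {
    v1 <- if (stats::sd(comp1$e) > 0) comp1$e / stats::sd(comp1$e) else stats::rnorm(n)
    comp2$e <- scale_to_var(spec$r_E * v1 + sqrt(max(0, 1 - spec$r_E^2)) * stats::rnorm(n),
                            r2 * spec$trait2$total_var)
  }
  mk_y <- function(sp, comp) sp$beta_age * age + sp$beta_sex * sex +
    comp$g + comp$k + comp$f + comp$s + comp$c + comp$e
  out <- data.frame(id = ped$id, age = age, sex = sex,
                    y1 = mk_y(spec$trait1, comp1), y2 = mk_y(spec$trait2, comp2))
  names(out)[4:5] <- trait_names
  attr(out, "truth") <- list(spec = spec, comp1 = comp1, comp2 = comp2,
                             causal = causal_cols)
  out
}
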