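#' Specify a simulated multi-generation family cohort
#'
#' Captures the structural parameters of a simulated pedigree: number of
#' founder families, the distribution of offspring per couple, the number of
#' couple generations, and the fraction of offspring who later form couples
#' of their own (marrying a spouse drawn from outside the pedigree, so no
#' inbreeding loops arise).
#'
#' @param n_families Number of founder couples (>= 1).
#' @param offspring Offspring-per-couple rule: a single non-negative integer
#'   (every couple has exactly that many children), or a function
#'   `function(n)` returning `n` non-negative integer counts. The default,
#'   `1 + Poisson(1.5)`, reproduces at desk scale the ratio of full-sib
#'   pairs to couple pairs (about 3:1) seen in large family cohorts.
#' @param n_generations Number of reproducing generations; `1` means founder
#'   couples plus their offspring only.
#' @param couple_fraction Fraction in `[0, 1]` of each offspring generation
#'   that is paired with a new marrying-in spouse (only relevant when
#'   `n_generations > 1`, where such couples have children of their own).
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return An object of class `"pedigree_spec"`.
#' @seealso [simulate_pedigree()]
#' @export
pedigree_spec <- function(n_families = 450L,
                          offspring = function(n) 1L + stats::rpois(n, 1.5),
                          n_generations = 1L,
                          couple_fraction = 0.3,
                          seed = 1L) {
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1)
    stop("invalid 'n_families': must be a single count >= 1")
  if (is.numeric(offspring)) {
    k <- as.integer(offspring)
    if (length(k) != 1L || k < 0) stop("invalid 'offspring': count must be >= 0")
    offspring <- local({kk <- k; function(n) rep.int(kk, n)})
  }
  if (!is.function(offspring)) stop("invalid 'offspring': number or function required")
  if (!is.numeric(n_generations) || n_generations < 1)
    stop("invalid 'n_generations': must be >= 1")
  if (!is.numeric(couple_fraction) || couple_fraction < 0 || couple_fraction > 1)
    stop("invalid 'couple_fraction': must be in [0, 1]")
  structure(list(n_families = as.integer(n_families), offspring = offspring,
                 n_generations = as.integer(n_generations),
                 couple_fraction = couple_fraction, seed = as.integer(seed)),
            class = "pedigree_spec")
}

#' Simulate a multi-generation pedigree
#'
#' Generates founder couples, their offspring, and (for multi-generation
#' specs) new couples formed by pairing a fraction of each offspring
#' generation with marrying-in founder spouses. Every non-founder has both
#' parents in the pedigree and spouse links are mutual.
#'
#' @param spec A [pedigree_spec()].
#' @return A data frame of class `"pedigree"` with columns `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (0 = female, 1 = male), `spouse`
#'   (`NA` if unpaired) and `generation`.
#' @examples
#' ped <- simulate_pedigree(pedigree_spec(n_families = 5, offspring = 2, seed = 7))
#' nrow(ped)  # 5 couples + 10 offspring = 20
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "pedigree_spec"))
  set.seed(spec$seed)
  id <- integer(0); father <- integer(0); mother <- integer(0)
  sex <- integer(0); spouse <- integer(0); generation <- integer(0)
  nxt <- 1L
  new_indiv <- function(n, sx, fa, mo, gen) {
    ids <- seq.int(nxt, length.out = n)
    id <<- c(id, ids); sex <<- c(sex, sx); father <<- c(father, fa)
    mother <<- c(mother, mo); spouse <<- c(spouse, rep(NA_integer_, n))
    generation <<- c(generation, rep.int(gen, n))
    nxt <<- nxt + n
    ids
  }
  # founder couples
  fathers <- new_indiv(spec$n_families, rep.int(1L, spec$n_families),
                       rep(NA_integer_, spec$n_families), rep(NA_integer_, spec$n_families), 0L)
  mothers <- new_indiv(spec$n_families, rep.int(0L, spec$n_families),
                       rep(NA_integer_, spec$n_families), rep(NA_integer_, spec$n_families), 0L)
  spouse[fathers] <- mothers; spouse[mothers] <- fathers
  couples_f <- fathers; couples_m <- mothers
  for (gen in seq_len(spec$n_generations)) {
    nk <- as.integer(spec$offspring(length(couples_f)))
    if (any(is.na(nk)) || any(nk < 0)) stop("invalid 'offspring': counts must be >= 0")
    fa <- rep.int(couples_f, nk); mo <- rep.int(couples_m, nk)
    n_off <- length(fa)
    if (n_off == 0L) break
    kids <- new_indiv(n_off, stats::rbinom(n_off, 1L, 0.5), fa, mo, gen)
    if (gen == spec$n_generations) break
    # a fraction of this generation marries in a new spouse and reproduces
    n_pair <- round(spec$couple_fraction * n_off)
    if (n_pair == 0L) break
    paired <- sort(sample(kids, n_pair))
    inlaws <- new_indiv(n_pair, 1L - sex[paired],
                        rep(NA_integer_, n_pair), rep(NA_integer_, n_pair), gen)
    spouse[paired] <- inlaws; spouse[inlaws] <- paired
    couples_f <- ifelse(sex[paired] == 1L, paired, inlaws)
    couples_m <- ifelse(sex[paired] == 1L, inlaws, paired)
  }
  ped <- data.frame(id = id, father = father, mother = mother, sex = sex,
                    spouse = spouse, generation = generation)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cs <- pedigree_counts(x)
  cat(sprintf("pedigree: %d individuals (%d founders), %d couple pairs, %d full-sib pairs, %d nuclear families\n",
              nrow(x), sum(is.na(x$father)), cs$n_couples, cs$n_sib_pairs, cs$n_families))
  invisible(x)
}

as_pedigree <- function(df) {
  need <- c("id", "father", "mother", "sex", "spouse")
  if (!all(need %in% names(df)))
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  df$id <- as.integer(df$id)
  validate_pedigree(df)
  class(df) <- unique(c("pedigree", class(df)))
  df
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
  nonf <- !is.na(ped$father) | !is.na(ped$mother)
  if (any(nonf & (is.na(ped$father) | is.na(ped$mother))))
    stop("every non-founder must have both parents present")
  if (!all(stats::na.omit(c(ped$father, ped$mother)) %in% ped$id))
    stop("parent ids missing from pedigree")
  sp <- ped$spouse
  has <- !is.na(sp)
  if (any(has)) {
    idx <- match(sp[has], ped$id)
    if (any(is.na(idx)) || !all(ped$spouse[idx] == ped$id[has]))
      stop("spouse links must be mutual")
  }
  invisible(TRUE)
}

#' Enumerate nuclear-family units, sib pairs and couples of a pedigree
#'
#' A nuclear-family unit is a couple plus their common offspring; full
#' siblings share both parents; couples are the mutual spouse links. An
#' individual can belong to several units (offspring in one, parent in
#' another).
#'
#' @param ped A `pedigree`.
#' @return A list with `families` (list of member-id vectors, units with >= 2
#'   members), `sib_pairs` and `couple_pairs` (two-column id matrices), and
#'   the counts `n_families`, `n_sib_pairs`, `n_couples`.
#' @export
pedigree_counts <- function(ped) {
  validate_pedigree(ped)
  nonf <- !is.na(ped$father)
  key <- paste(ped$father[nonf], ped$mother[nonf])
  kids_by_unit <- split(ped$id[nonf], key)
  fams <- lapply(names(kids_by_unit), function(k) {
    par <- as.integer(strsplit(k, " ", fixed = TRUE)[[1L]])
    c(par, kids_by_unit[[k]])
  })
  # couples without children still form a (2-member) unit
  sp_ok <- !is.na(ped$spouse) & ped$id < ped$spouse
  cpl <- cbind(ped$id[sp_ok], ped$spouse[sp_ok])
  if (nrow(cpl)) {
    keyset <- names(kids_by_unit)  # keys are "father mother"
    have_kids <- paste(cpl[, 1], cpl[, 2]) %in% keyset |
                 paste(cpl[, 2], cpl[, 1]) %in% keyset
    fams <- c(fams, lapply(which(!have_kids), function(i) cpl[i, ]))
  }
  sibs <- do.call(rbind, lapply(kids_by_unit, function(k) {
    if (length(k) < 2L) return(NULL)
    t(utils::combn(sort(k), 2L))
  }))
  if (is.null(sibs)) sibs <- matrix(integer(0), 0, 2)
  list(families = fams, sib_pairs = sibs, couple_pairs = cpl,
       n_families = length(fams), n_sib_pairs = nrow(sibs), n_couples = nrow(cpl))
}

#' Expected additive relationship matrix from a pedigree
#'
#' Computes the numerator relationship matrix A = 2 * kinship by the standard
#' recursive (tabular) method: individuals are processed parents-first;
#' A(i,j) = (A(father_i, j) + A(mother_i, j)) / 2 for j processed before i,
#' and A(i,i) = 1 + A(father_i, mother_i) / 2.
#'
#' @param ped A `pedigree`.
#' @return A symmetric matrix with `ped$id` as dimnames.
#' @export
pedigree_additive_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  if (is.null(ped$generation)) {
    gen <- rep(0L, n)  # derive a parents-first depth when not supplied
    repeat {
      g2 <- ifelse(is.na(ped$father), 0L,
                   pmax(gen[match(ped$father, ped$id)], gen[match(ped$mother, ped$id)]) + 1L)
      g2[is.na(g2)] <- 0L
      if (identical(g2, gen)) break
      gen <- g2
    }
  } else gen <- ped$generation
  ord <- order(gen, ped$id)
  ids_o <- ped$id[ord]
  idx <- match(ped$id, ids_o)             # position of each id in processing order
  fa <- match(ped$father[ord], ids_o)
  mo <- match(ped$mother[ord], ids_o)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      A[i, i] <- 1
    } else {
      if (fa[i] >= i || mo[i] >= i) stop("pedigree ordering failure: parent after child")
      j <- seq_len(i - 1L)
      A[i, j] <- A[j, i] <- (A[fa[i], j] + A[mo[i], j]) / 2
      A[i, i] <- 1 + A[fa[i], mo[i]] / 2
    }
  }
  A <- A[idx, idx, drop = FALSE]
  dimnames(A) <- list(ped$id, ped$id)
  A
}
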