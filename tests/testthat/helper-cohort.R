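# A mid-size cohort shared across test files, built once per session.
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (!is.null(.cohort_cache$c1)) return(.cohort_cache$c1)
  ped <- simulate_pedigree(pedigree_spec(n_families = 120L, seed = 101L))
  geno <- simulate_genotypes(ped, 2000L, maf_low = 0.05, maf_high = 0.5,
                             missing_rate = 0.002, seed = 102L)
  gq <- apply_qc(geno)$geno
  cohort <- list(
    ped = ped, geno = gq,
    G = compute_grm(gq),
    Fm = build_environment_matrix(ped, "family"),
    Sm = build_environment_matrix(ped, "sibling"),
    Cm = build_environment_matrix(ped, "couple"))
  cohort$K <- threshold_grm(cohort$G)
  .cohort_cache$c1 <- cohort
  cohort
}
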