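#' Default configuration for a synthetic study run
#'
#' Returns the configuration list [run_study()] expects, populated with a
#' desk-scale demonstration cohort: ~1,000 individuals in complete nuclear
#' families, 5,000 common SNPs, and four latent traits whose generative
#' variance fractions follow the regimes used throughout the package's
#' validation experiments (resilience G/F = 0.06/0.05; task-oriented coping
#' G/S/C = 0.14/0.10/0.18; emotion-oriented G/F/C = 0.15/0.05/0.14;
#' avoidance-oriented G/S/C = 0.15/0.07/0.18).
#'
#' @param seed Integer seed for every stage.
#' @param out_dir Output directory.
#' @return A named list; edit fields as needed before passing to
#'   [run_study()].
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("famvar_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    pedigree = list(n_families = 220L, offspring_lambda = 1.5, n_generations = 1L,
                    couple_fraction = 0),
    genotypes = list(n_snps = 5000L, maf_low = 0.05, maf_high = 0.5,
                     missing_rate = 0.005),
    qc = list(snp_call_rate_min = 0.98, indiv_missing_max = 0.02,
              hwe_p_min = 1e-6, maf_min = 0.01),
    n_causal = 500L,
    item_noise = 0.9,
    item_missing = 0,
    traits = list(
      resilience = list(h2_g = 0.06, e2_f = 0.05, beta_age = -0.005, beta_sex = 0.1),
      ToC = list(h2_g = 0.14, e2_s = 0.10, e2_c = 0.18, beta_age = 0.01, beta_sex = -0.5),
      EoC = list(h2_g = 0.15, e2_f = 0.05, e2_c = 0.14, beta_age = -0.01, beta_sex = 0.5),
      AoC = list(h2_g = 0.15, e2_s = 0.07, e2_c = 0.18, beta_age = 0.005, beta_sex = 0.3)),
    bivariate_pairs = list(c("resilience", "EoC")),
    fit_scored = TRUE)
}

trait_spec <- function(tr) {
  known <- c("h2_g", "h2_p", "e2_f", "e2_s", "e2_c", "beta_age", "beta_sex", "total_var")
  bad <- setdiff(names(tr), known)
  if (length(bad)) stop("unknown trait spec fields: ", paste(bad, collapse = ", "))
  do.call(variance_spec, tr)
}

#' Run the full synthetic study replica
#'
#' Orchestrates simulate -> QC -> relationship matrices -> questionnaire
#' scoring -> univariate models (GK, full GKFSC, backward selection) ->
#' bivariate genetic correlations -> report. All stage outputs are persisted
#' in standard formats (PLINK bed/bim/fam, GCTA GRM triplets, TSV tables,
#' JSON reports) so each stage can be cross-validated externally, and the
#' run is deterministic given the seed.
#'
#' @param config A configuration list (see [default_config()]), or the path
#'   of a YAML or JSON file holding one.
#' @return Invisibly, a list with the fitted models, report tables and file
#'   paths (`table1`, `table2`, `table3`, `qc_report`, `manifest`).
#' @export
run_study <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading a YAML config requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stage <- "simulate"
  result <- tryCatch({
    ## --- simulation -------------------------------------------------------
    pd <- config$pedigree
    spec <- pedigree_spec(
      n_families = pd$n_families,
      offspring = if (!is.null(pd$offspring_exact)) pd$offspring_exact
                  else local({lam <- pd$offspring_lambda %||% 1.5
                              function(n) 1L + stats::rpois(n, lam)}),
      n_generations = pd$n_generations %||% 1L,
      couple_fraction = pd$couple_fraction %||% 0,
      seed = seed)
    ped <- simulate_pedigree(spec)
    gn <- config$genotypes
    geno <- simulate_genotypes(ped, n_snps = gn$n_snps,
                               maf_low = gn$maf_low %||% 0.05,
                               maf_high = gn$maf_high %||% 0.5,
                               missing_rate = gn$missing_rate %||% 0,
                               seed = seed + 1L)
    write_plink(geno, file.path(out, "cohort"), ped = ped)
    utils::write.table(ped, file.path(out, "pedigree.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## --- QC ---------------------------------------------------------------
    stage <- "genotype_qc"
    thr <- do.call(qc_thresholds, config$qc %||% list())
    qc <- apply_qc(geno, thr)
    jsonlite::write_json(unclass(qc$report), file.path(out, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    gq <- qc$geno
    kept_ids <- rownames(gq)
    pedk <- ped[match(kept_ids, as.character(ped$id)), ]
    ## --- relationship matrices -------------------------------------------
    stage <- "relationship_matrices"
    G <- compute_grm(gq)
    K <- threshold_grm(G, t = 0.05)
    Fm <- build_environment_matrix(pedk, "family")
    Sm <- build_environment_matrix(pedk, "sibling")
    Cm <- build_environment_matrix(pedk, "couple")
    write_grm(G, file.path(out, "grm_G"))
    write_grm(K, file.path(out, "grm_K"))
    mats <- list(G = G, K = K, F = Fm, S = Sm, C = Cm)
    ## --- MDS covariates ---------------------------------------------------
    stage <- "mds"
    mds <- compute_mds(gq, n_components = 4L)
    utils::write.table(mds, file.path(out, "mds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## --- phenotypes and questionnaire scoring -----------------------------
    stage <- "phenotypes"
    latent <- NULL
    truths <- list()
    for (i in seq_along(config$traits)) {
      tn <- names(config$traits)[i]
      ph <- simulate_phenotypes(pedk, gq, trait_spec(config$traits[[i]]),
                                n_causal = config$n_causal %||% 500L,
                                seed = seed + 10L + i, trait_name = tn)
      truths[[tn]] <- attr(ph, "truth")$realized
      latent <- if (is.null(latent)) ph else cbind(latent, ph[tn])
    }
    brs_items <- simulate_items(latent, "BRS", item_noise = config$item_noise %||% 0.9,
                                missing_rate = config$item_missing %||% 0,
                                seed = seed + 20L)
    ciss_items <- simulate_items(latent, "CISS", item_noise = config$item_noise %||% 0.9,
                                 missing_rate = config$item_missing %||% 0,
                                 seed = seed + 21L)
    scored <- data.frame(id = latent$id, age = latent$age, sex = latent$sex,
                         resilience = score_brs(brs_items[, -1L]),
                         score_ciss(ciss_items[, -1L]))
    # fit either the questionnaire-scored traits or the latent traits
    traits_tab <- if (isTRUE(config$fit_scored)) {
      stopifnot(identical(sort(names(config$traits)),
                          sort(c("resilience", "ToC", "EoC", "AoC"))))
      scored
    } else latent
    utils::write.table(latent, file.path(out, "phenotypes_latent.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scored, file.path(out, "phenotypes_scored.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truths, file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ## --- table 1: adjusted phenotypic correlations ------------------------
    stage <- "table1"
    tnames <- setdiff(names(traits_tab), c("id", "age", "sex"))
    t1 <- do.call(rbind, lapply(utils::combn(tnames, 2L, simplify = FALSE), function(pr) {
      ap <- adjusted_pearson(traits_tab[[pr[1L]]], traits_tab[[pr[2L]]],
                             traits_tab[, c("age", "sex")])
      data.frame(trait1 = pr[1L], trait2 = pr[2L], r = ap$r, se = ap$se, n = ap$n)
    }))
    utils::write.table(format(t1, digits = 4), file.path(out, "table1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ## --- univariate models -------------------------------------------------
    stage <- "variance_components"
    covars <- cbind(age = traits_tab$age, sex = traits_tab$sex,
                    as.matrix(mds[match(traits_tab$id, mds$id), -1L]))
    fits <- list(); pvals <- list(); selections <- list()
    for (tn in tnames) {
      yv <- stats::setNames(traits_tab[[tn]], traits_tab$id)
      sel <- backward_select(yv, covars, mats)
      gk <- sel$fits[["GK"]] %||% reml_fit(yv, covars, mats[c("G", "K")])
      full <- sel$fits[["GKFSC"]]
      fits[[tn]] <- list(`Genetics only` = gk, Full = full,
                         `Backward selection` = sel$fit)
      # per-component one-tailed LRT p in each reported model
      pv_of <- function(fit) {
        vapply(fit$components, function(cp) {
          red <- reml_fit(yv, covars, mats[setdiff(fit$components, cp)])
          lrt_component(fit, red)$p
        }, 0)
      }
      pvals[[tn]] <- list(`Genetics only` = pv_of(gk), Full = pv_of(full),
                          `Backward selection` = pv_of(sel$fit))
      selections[[tn]] <- sel
    }
    t2 <- report_table(fits, pvals)
    utils::write.table(t2, file.path(out, "table2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(fits, function(fl) lapply(fl, function(f)
        list(code = paste(f$components, collapse = ""),
             fractions = as.list(f$fractions), se = as.list(f$se),
             logL = f$logL, n = f$n_used, converged = f$converged))),
      file.path(out, "table2.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ## --- bivariate genetic correlations ------------------------------------
    stage <- "bivariate"
    t3rows <- list()
    for (pr in config$bivariate_pairs %||% list()) {
      y1 <- stats::setNames(traits_tab[[pr[1L]]], traits_tab$id)
      y2 <- stats::setNames(traits_tab[[pr[2L]]], traits_tab$id)
      bf <- bivariate_fit(y1, y2, covars, G = G, K = K)
      pG <- lrt_correlation(bf, "G")
      pK <- lrt_correlation(bf, "K")
      t3rows[[length(t3rows) + 1L]] <- data.frame(
        trait1 = pr[1L], trait2 = pr[2L],
        r_G = bf$r_G, r_G_se = bf$r_G_se, p_rG = pG$p,
        r_K = bf$r_K %||% NA_real_, r_K_se = bf$r_K_se %||% NA_real_, p_rK = pK$p,
        converged = bf$converged)
    }
    t3 <- if (length(t3rows)) do.call(rbind, t3rows) else
      data.frame(trait1 = character(0), trait2 = character(0))
    utils::write.table(format(t3, digits = 4), file.path(out, "table3.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ## --- manifest ----------------------------------------------------------
    stage <- "manifest"
    cfg_echo <- config
    cfg_echo$pedigree$offspring_exact <- NULL  # functions do not serialize
    cfg_echo$out_dir <- NULL                   # location must not affect the hash
    manifest <- list(
      package = "famvar",
      version = as.character(utils::packageVersion("famvar")),
      seed = seed,
      n_individuals = nrow(pedk), n_snps_postqc = ncol(gq),
      counts = pedigree_counts(pedk)[c("n_families", "n_sib_pairs", "n_couples")],
      config_hash = sum(utf8ToInt(paste(utils::capture.output(utils::str(cfg_echo)), collapse = ""))),
      traits = tnames)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(pedigree = pedk, genotypes = gq, matrices = mats, mds = mds,
         latent = latent, scored = scored, truths = truths,
         table1 = t1, fits = fits, p_values = pvals, selections = selections,
         table2 = t2, table3 = t3, manifest = manifest, out_dir = out)
  }, error = function(e) {
    stop(sprintf("study pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Stacked-bar plot of variance fractions
#'
#' Draws, per trait, the backward-selected model's variance fractions as a
#' stacked bar (residual omitted).
#'
#' @param fits Named list (trait -> `reml_fit`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_variance_fractions <- function(fits, ...) {
  comps <- c("G", "K", "F", "S", "C")
  mat <- sapply(fits, function(f) {
    v <- stats::setNames(rep(0, length(comps)), comps)
    keep <- intersect(names(f$fractions), comps)
    v[keep] <- f$fractions[keep]
    v
  })
  graphics::barplot(mat, legend.text = comps, ylab = "variance fraction",
                    ylim = c(0, min(1, max(colSums(mat)) * 1.4)), ...)
  invisible(mat)
}
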