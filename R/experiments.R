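#' Simulation scenario configuration
#'
#' Describes one cell of the design-by-kinship-measure simulation grid: the
#' pedigree design, the true and fitted kinship kinds, the true parameters,
#' and the replication. Defaults follow the main study conditions: 100
#' sibships of 14 (total sample size 1400), sigma2 = 1, 500 replicates.
#'
#' Kinship kinds for `gt`/`gf`: `"pedigree_2psi"`, `"realized_2phi"`,
#' `"realized_2phi_chr"` (uses `star_chromosomes`), `"grm_classic"`, or a
#' plugin function `function(geno, freqs, constrain_diagonal)`.
#'
#' @param design structure label for [build_pedigree()].
#' @param size,degree structure parameters.
#' @param n_blocks number of independent pedigrees m.
#' @param h2,sigma2 true parameter values.
#' @param gt,gf true and fitted kinship kinds.
#' @param reps number of simulation replicates.
#' @param map genetic map.
#' @param star_chromosomes chromosome subset for `"realized_2phi_chr"`.
#' @param markers marker-panel parameters for GRM kinds: a list with `M`,
#'   `n_pool` (pool haplotype count; defaults to the founder haplotype count),
#'   `maf_min`, `ld`.
#' @param constrain_diagonal constrain GRM diagonals to 1.
#' @param seed master seed; every source of randomness in the scenario is
#'   derived from it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(design = "sibship", size = 14, degree = NULL,
                            n_blocks = 100, h2 = 0.5, sigma2 = 1,
                            gt = "realized_2phi", gf = "realized_2phi",
                            reps = 500, map = default_genetic_map(),
                            star_chromosomes = "22", markers = NULL,
                            constrain_diagonal = FALSE, seed = 1) {
  stopifnot(reps >= 1, n_blocks >= 1)
  cfg <- list(design = design, size = size, degree = degree,
              n_blocks = as.integer(n_blocks), h2 = h2, sigma2 = sigma2,
              gt = gt, gf = gf, reps = as.integer(reps), map = map,
              star_chromosomes = star_chromosomes, markers = markers,
              constrain_diagonal = constrain_diagonal,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

needs_descent <- function(kind) {
  is.function(kind) || kind %in% c("realized_2phi", "realized_2phi_chr",
                                   "grm_classic")
}

needs_markers <- function(kind) is.function(kind) || kind == "grm_classic"

kinship_from_kind <- function(kind, cfg, psi2_rep, dr, geno) {
  if (is.function(kind)) {
    if (is.null(geno)) stop("plugin Gf requested but no marker configuration")
    return(grm_plugin(geno, kind,
                      constrain_diagonal = isTRUE(cfg$constrain_diagonal)))
  }
  switch(kind,
    pedigree_2psi = psi2_rep,
    realized_2phi = realized_kinship(dr),
    realized_2phi_chr = realized_kinship(dr, cfg$star_chromosomes),
    grm_classic = {
      if (is.null(geno)) stop("GRM requested but no marker configuration")
      classic_grm(geno,
                  constrain_diagonal = isTRUE(cfg$constrain_diagonal))
    },
    stop("unknown kinship kind: ", kind))
}

scenario_pool <- function(cfg, ped) {
  if (!needs_markers(cfg$gt) && !needs_markers(cfg$gf)) return(NULL)
  mk <- cfg$markers
  if (is.null(mk)) stop("scenario requires markers but no marker config")
  n_found <- 2L * sum(ped$father == 0L) * cfg$n_blocks
  simulate_founder_haplotypes(cfg$map, M = mk$M,
                              n_haplotypes = mk$n_pool %||% n_found,
                              seed = derive_seed(cfg$seed, 3L),
                              maf_min = mk$maf_min %||% 0.05,
                              ld = mk$ld %||% 0.5)
}

#' Run one simulation scenario
#'
#' Executes the per-replicate loop: simulate genome-wide descent in the
#' pedigrees, build the true (Gt) and fitted (Gf) correlation matrices,
#' simulate a trait under Gt, fit the two-component model with Gf, and (when
#' both matrices are available) solve for the pseudo-true parameters and the
#' sandwich asymptotic standard error given that replicate's (Gt, Gf).
#' Aggregates empirical and analytical summaries across replicates.
#'
#' @param cfg a [scenario_config()].
#' @param progress print a progress message every `progress` replicates
#'   (0 = silent).
#' @return an object of class `scenario_result`: `summary` (one-row data
#'   frame) and `replicates` (per-replicate records).
#' @export
run_scenario <- function(cfg, progress = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  ped <- build_pedigree(cfg$design, size = cfg$size, degree = cfg$degree)
  psi2_rep <- rep_kinship(pedigree_kinship(ped), cfg$n_blocks)
  pool <- scenario_pool(cfg, ped)
  recs <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    dr <- NULL; geno <- NULL
    if (needs_descent(cfg$gt) || needs_descent(cfg$gf)) {
      dr <- simulate_descent(ped, cfg$map, m = cfg$n_blocks,
                             seed = derive_seed(cfg$seed, 10L, r))
    }
    if (needs_markers(cfg$gt) || needs_markers(cfg$gf)) {
      geno <- drop_genotypes(dr, pool)
    }
    Gt <- kinship_from_kind(cfg$gt, cfg, psi2_rep, dr, geno)
    Gf <- if (identical(cfg$gt, cfg$gf)) Gt
          else kinship_from_kind(cfg$gf, cfg, psi2_rep, dr, geno)
    y <- simulate_trait(Gt, trait_model(cfg$h2, cfg$sigma2),
                        seed = derive_seed(cfg$seed, 20L, r))
    fit <- fit_mle(y, Gf)
    prob <- misspec_problem(Gt, Gf, cfg$h2, cfg$sigma2)
    pt <- pseudo_true(prob)
    sw <- sandwich_acov(prob, pt)
    recs[[r]] <- data.frame(rep = r, h2_hat = fit$h2,
                            sigma2_hat = fit$sigma2,
                            boundary = fit$boundary,
                            h2_pseudo_true = pt$h2, ase_h2 = sw$ase_h2)
    if (progress > 0 && r %% progress == 0)
      message("replicate ", r, "/", cfg$reps)
  }
  reps <- do.call(rbind, recs)
  summary <- data.frame(design = cfg$design,
                        gt = kind_label(cfg$gt), gf = kind_label(cfg$gf),
                        h2_0 = cfg$h2, reps = cfg$reps,
                        N = nrow(psi2_rep$matrix),
                        h2_emp_mean = mean(reps$h2_hat),
                        h2_emp_sd = sd(reps$h2_hat),
                        h2_analytical = mean(reps$h2_pseudo_true),
                        se_analytical = mean(reps$ase_h2))
  structure(list(config = cfg, summary = summary, replicates = reps),
            class = "scenario_result")
}

kind_label <- function(kind) if (is.function(kind)) "grm_plugin" else kind

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Main-study scenario table
#'
#' Runs the grid of (Gt, Gf) combinations over the pedigree-based kinship
#' measures (2 Psi, 2 Phi, 2 Phi*) for one design and heritability value, in
#' the layout of the paper-style empirical/analytical comparison table.
#'
#' @param design,size,n_blocks,h2,reps,map,star_chromosomes,seed
#'   see [scenario_config()].
#' @param kinds kinship kinds to cross for Gt and Gf (Gt = `"pedigree_2psi"`
#'   cells are included for completeness).
#' @return a data frame, one row per (Gt, Gf) cell.
#' @export
run_design_table <- function(design = "sibship", size = 14, n_blocks = 100,
                             h2 = 0.5, reps = 500,
                             map = default_genetic_map(),
                             star_chromosomes = "22", seed = 1,
                             kinds = c("pedigree_2psi", "realized_2phi",
                                       "realized_2phi_chr")) {
  grid <- expand.grid(gt = kinds, gf = kinds, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- scenario_config(design = design, size = size,
                           n_blocks = n_blocks, h2 = h2,
                           gt = grid$gt[g], gf = grid$gf[g], reps = reps,
                           map = map, star_chromosomes = star_chromosomes,
                           seed = derive_seed(seed, 30L, g))
    run_scenario(cfg)$summary
  })
  do.call(rbind, out)
}

#' Cousinship (population-design) bias study
#'
#' For grids of cousinship degree and size, computes the pseudo-true
#' heritability limit when the fitted matrix differs from the truth among
#' realized kinship and marker-based GRM measures, averaged over descent and
#' marker replicates. The total analyzed sample size is held fixed, so the
#' number of independent cousinships is `round(total_n / size)`.
#'
#' @param degrees cousinship degrees (2 = second cousins, 3 = third cousins).
#' @param sizes analyzed individuals per cousinship.
#' @param gt,gf kinship kinds (or plugin function for `gf`).
#' @param constrain_diagonal logical vector of diagonal constraints to cross.
#' @param total_n total analyzed sample size held fixed across cells.
#' @param reps descent/marker replicates averaged per cell.
#' @param h2,sigma2 true parameters.
#' @param markers marker-panel parameters (see [scenario_config()]).
#' @param map genetic map.
#' @param seed master seed.
#' @return a data frame with one row per grid cell and the averaged
#'   pseudo-true `h2_limit`.
#' @export
run_cousinship_study <- function(degrees = c(2, 3), sizes = c(4, 10),
                                 gt = "realized_2phi", gf = "grm_classic",
                                 constrain_diagonal = c(TRUE, FALSE),
                                 total_n = 2000, reps = 5, h2 = 0.5,
                                 sigma2 = 1,
                                 markers = list(M = 2000, ld = 0.5),
                                 map = default_genetic_map(), seed = 1) {
  grid <- expand.grid(degree = degrees, size = sizes,
                      constrain_diagonal = constrain_diagonal)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    m <- as.integer(round(total_n / grid$size[g]))
    cfg <- scenario_config(design = "cousinship", size = grid$size[g],
                           degree = grid$degree[g], n_blocks = m, h2 = h2,
                           sigma2 = sigma2, gt = gt, gf = gf, reps = reps,
                           map = map, markers = markers,
                           constrain_diagonal = grid$constrain_diagonal[g],
                           seed = derive_seed(seed, 40L, g))
    ped <- build_pedigree("cousinship", size = cfg$size, degree = cfg$degree)
    psi2_rep <- rep_kinship(pedigree_kinship(ped), m)
    pool <- scenario_pool(cfg, ped)
    h1 <- vapply(seq_len(reps), function(r) {
      dr <- simulate_descent(ped, map, m = m,
                             seed = derive_seed(cfg$seed, 10L, r))
      geno <- if (needs_markers(gt) || needs_markers(gf))
        drop_genotypes(dr, pool) else NULL
      Gt <- kinship_from_kind(gt, cfg, psi2_rep, dr, geno)
      Gf <- kinship_from_kind(gf, cfg, psi2_rep, dr, geno)
      pseudo_true(misspec_problem(Gt, Gf, h2, sigma2))$h2
    }, numeric(1))
    data.frame(degree = grid$degree[g], size = grid$size[g], n_blocks = m,
               constrain_diagonal = grid$constrain_diagonal[g],
               gt = kind_label(gt), gf = kind_label(gf),
               h2_0 = h2, h2_limit = mean(h1), h2_limit_sd = sd(h1),
               reps = reps)
  })
  do.call(rbind, out)
}

#' Eigenvalue summary of a kinship measure for a design
#'
#' Pools the eigenvalues of the per-pedigree kinship blocks across simulation
#' replicates and returns their empirical cumulative distribution, together
#' with the distinct eigenvalues of the pedigree expectation 2 Psi as
#' reference lines. Useful to see how much more spread realized kinship on a
#' short genome segment has than genome-wide realized kinship.
#'
#' @param design,size,degree structure, see [build_pedigree()].
#' @param kind kinship kind to summarize.
#' @param n_blocks independent pedigrees per replicate.
#' @param reps descent replicates pooled.
#' @param map genetic map.
#' @param chromosomes subset for `"realized_2phi_chr"`.
#' @param seed master seed.
#' @return a list with `values` (sorted pooled eigenvalues), `cdf` (data
#'   frame `value`, `cdf`) and `reference` (distinct 2 Psi eigenvalues).
#' @export
eigen_summary <- function(design = "sibship", size = 14, degree = NULL,
                          kind = "realized_2phi", n_blocks = 100, reps = 1,
                          map = default_genetic_map(), chromosomes = "22",
                          seed = 1) {
  ped <- build_pedigree(design, size = size, degree = degree)
  psi2 <- pedigree_kinship(ped)
  ref <- sort(unique(round(eigen(psi2$matrix, symmetric = TRUE,
                                 only.values = TRUE)$values, 9)))
  vals <- unlist(lapply(seq_len(reps), function(r) {
    km <- if (kind == "pedigree_2psi") rep_kinship(psi2, n_blocks)
    else {
      dr <- simulate_descent(ped, map, m = n_blocks,
                             seed = derive_seed(seed, 10L, r))
      switch(kind,
             realized_2phi = realized_kinship(dr),
             realized_2phi_chr = realized_kinship(dr, chromosomes),
             stop("unsupported kind for eigen_summary: ", kind))
    }
    eigen_transform(km)$lambda
  }), use.names = FALSE)
  vals <- sort(vals)
  list(values = vals,
       cdf = data.frame(value = vals,
                        cdf = seq_along(vals) / length(vals)),
       reference = ref)
}
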