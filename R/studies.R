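#' Replicate study: effect of modeling the hierarchy on coefficient RMSE
#'
#' For each replicate: simulate a multilevel study, fit the hierarchical and
#' the flat model, and evaluate coefficient RMSE against the realized truth,
#' in aggregate and by spatial scale. Replicate `r` uses seed
#' `base_seed + r`, so replicate sets are extensible without reshuffling.
#'
#' @param config A [sim_config()] (per-replicate seed is overridden).
#' @param n_replicates Number of replicates.
#' @param sampler A [sampler_control()] used for both models.
#' @param priors A [shade_priors()].
#' @param seed Base seed.
#' @return List with `replicates` (long data frame: replicate, hierarchical,
#'   scale, rmse) and `table` (mean and 2.5/97.5% quantiles over replicates
#'   per model x scale); failed replicates are excluded and counted in
#'   `$n_failed`.
#' @export
run_pooling_study <- function(config = sim_config(), n_replicates = 100,
                              sampler = sampler_control(),
                              priors = shade_priors(), seed = 1) {
  stopifnot(n_replicates >= 1)
  rows <- list()
  n_failed <- 0
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- seed + r
      study <- simulate_study(cfg)
      designs <- study_designs(study)
      fh <- fit_shade(designs, study$meta, priors, sampler, seed = seed + r)
      ff <- fit_flat(designs, priors, sampler, seed = seed + r)
      eh <- rmse_eval(fh, study$truth)
      ef <- rmse_eval(ff, study$truth)
      rbind(
        data.frame(replicate = r, hierarchical = TRUE,
                   scale = c("all", names(eh$by_scale)),
                   rmse = c(eh$aggregate, unname(eh$by_scale))),
        data.frame(replicate = r, hierarchical = FALSE,
                   scale = c("all", names(ef$by_scale)),
                   rmse = c(ef$aggregate, unname(ef$by_scale))))
    }, error = function(e) {
      warnf("replicate %d failed: %s", r, conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1 else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) stopf("all replicates failed")
  reps <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(
    split(reps, list(reps$hierarchical, reps$scale)), function(d) {
      data.frame(hierarchical = d$hierarchical[1], scale = d$scale[1],
                 rmse = mean(d$rmse),
                 lo = unname(quantile(d$rmse, 0.025)),
                 hi = unname(quantile(d$rmse, 0.975)))
    }))
  rownames(tab) <- NULL
  list(replicates = reps, table = tab, n_failed = n_failed)
}

#' Replicate study: sign-detection accuracy of three methods
#'
#' For each condition (target density x images per patient) and replicate:
#' simulate, then label the interaction sign at the test distances per image
#' with (i) the hierarchical model's image-level credible intervals, (ii)
#' the flat model's, and (iii) the G-cross CSR envelope test. A label is
#' correct when it equals the sign of the realized image-level true curve at
#' that distance.
#'
#' @param target_densities Target-type point counts per image to sweep (the
#'   sparse-target condition is the hard one for unpooled methods).
#' @param source_densities Source-type point counts per image to sweep;
#'   crossed with `target_densities`.
#' @param images_per_patient Values to sweep.
#' @param n_replicates Replicates per condition.
#' @param patients_per_cohort Patients per cohort in each simulated study.
#' @param config Base [sim_config()] supplying everything not swept.
#' @param sampler A [sampler_control()].
#' @param test_distances Distances at which signs are scored (microns).
#' @param n_sim_envelope CSR simulations for the envelope test.
#' @param seed Base seed.
#' @return Data frame: target_density, source_density, images_per_patient,
#'   distance, method, proportion_correct (plus n_images scored).
#' @export
run_detection_study <- function(target_densities = c(15, 150),
                                source_densities = c(15, 150),
                                images_per_patient = 1:3,
                                n_replicates = 30, patients_per_cohort = 3,
                                config = sim_config(),
                                sampler = sampler_control(),
                                test_distances = c(20, 40, 60),
                                n_sim_envelope = 39, seed = 1) {
  results <- list()
  cond_id <- 0
  conds <- expand.grid(target = target_densities, source = source_densities,
                       ipp = images_per_patient)
  for (ci in seq_len(nrow(conds))) {
    {
      dens <- conds$target[ci]
      ipp <- conds$ipp[ci]
      cond_id <- cond_id + 1
      nd <- length(test_distances)
      correct <- list(shade = numeric(nd), flat = numeric(nd),
                      gcross = numeric(nd))
      total <- 0
      for (r in seq_len(n_replicates)) {
        rep_seed <- seed + 1000 * cond_id + r
        cfg <- config
        cfg$patients_per_cohort <- patients_per_cohort
        cfg$images_per_patient <- ipp
        cfg$n_source <- conds$source[ci]
        cfg$n_target <- dens
        cfg$seed <- rep_seed
        study <- simulate_study(cfg)
        designs <- study_designs(study)
        fh <- fit_shade(designs, study$meta, sampler = sampler,
                        seed = rep_seed)
        ff <- fit_flat(designs, sampler = sampler, seed = rep_seed)
        B <- eval_basis(cfg$basis, test_distances)
        for (m in seq_along(designs)) {
          true_sic <- drop(B %*% as.vector(study$truth$delta[m, 1, ]))
          truth_lab <- ifelse(true_sic > 0, "positive", "negative")
          lab_h <- sign_detection(
            sic_curve(fh, "image", study$meta$image_id[m],
                      distances = test_distances), test_distances)
          lab_f <- sign_detection(
            sic_curve(ff, "image", study$meta$image_id[m],
                      distances = test_distances), test_distances)
          im <- study$images[[m]]
          both <- point_pattern(
            c(im$sources[[1]]$x, im$targets$x),
            c(im$sources[[1]]$y, im$targets$y),
            c(rep("source", length(im$sources[[1]]$x)),
              rep("target", length(im$targets$x))),
            im$targets$window)
          lab_g <- csr_envelope(both, "source", "target",
                                r_grid = seq(0, max(test_distances), by = 2),
                                n_sim = n_sim_envelope,
                                seed = rep_seed + 31 * m,
                                test_distances = test_distances)$detection
          correct$shade <- correct$shade + (lab_h == truth_lab)
          correct$flat <- correct$flat + (lab_f == truth_lab)
          correct$gcross <- correct$gcross + (lab_g == truth_lab)
          total <- total + 1
        }
      }
      for (method in names(correct)) {
        results[[length(results) + 1]] <- data.frame(
          target_density = dens, source_density = conds$source[ci],
          images_per_patient = ipp,
          distance = test_distances, method = method,
          proportion_correct = correct[[method]] / total,
          n_scored = total)
      }
    }
  }
  do.call(rbind, results)
}
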