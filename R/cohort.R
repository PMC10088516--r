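#' Simulate a chunk-level longitudinal cohort
#'
#' Generates per-subject, per-chunk feature summaries at two timepoints for
#' statistical validation. Each subject draws a multiplicative scale per
#' chunk (between-subject caliber variation) around population feature means
#' matching a typical non-symptomatic intracranial profile (area 5.76 mm^2,
#' misr 1.00 mm, min/max diameter 2.06/2.91 mm, ratio 0.78, curvature
#' 0.12/mm, torsion 0.05/mm, perimeter 8.45 mm, circularity 0.95); follow-up
#' values apply the injected percent increase plus measurement noise.
#' Defaults mirror the validation conditions: 30 subjects, 20%
#' between-subject SD, 2% measurement noise.
#'
#' @param n_subjects number of subjects (default 30).
#' @param n_chunks number of chunks (default 19).
#' @param effect_pct injected percent increase at follow-up: scalar applied
#'   to all features, or named vector per feature (unnamed features get 0).
#' @param between_sd_frac between-subject SD as a fraction of the mean.
#' @param noise_sd_frac measurement noise SD as a fraction of the mean.
#' @param seed RNG seed.
#' @return list with `cohort` (long data.frame: `subject_id`, `timepoint`,
#'   `chunk_id`, nine feature columns) and `covariates` (data.frame:
#'   `subject_id`, `age`, `sex`, `sbp`, `ldl_change_pct`,
#'   `therapy_days`).
#' @export
simulate_chunk_cohort <- function(n_subjects = 30, n_chunks = 19,
                                  effect_pct = 0,
                                  between_sd_frac = 0.2,
                                  noise_sd_frac = 0.02,
                                  seed = NULL) {
  base_means <- c(area_mm2 = 5.76, misr_mm = 1.00, min_diameter_mm = 2.06,
                  max_diameter_mm = 2.91, min_max_ratio = 0.78,
                  curvature_per_mm = 0.12, torsion_per_mm = 0.05,
                  perimeter_mm = 8.45, circularity = 0.95)
  feats <- names(base_means)
  eff <- setNames(rep(0, length(feats)), feats)
  if (is.null(names(effect_pct))) eff[] <- effect_pct
  else eff[names(effect_pct)] <- effect_pct
  with_seed(seed, {
    # deterministic chunk-to-chunk caliber spread
    chunk_scale <- seq(0.7, 1.5, length.out = n_chunks)
    rows <- vector("list", n_subjects * n_chunks * 2)
    r <- 0L
    for (s in seq_len(n_subjects)) {
      subj_scale <- pmax(0.2, 1 + rnorm(n_chunks, 0, between_sd_frac))
      for (ck in seq_len(n_chunks)) {
        truth <- base_means * chunk_scale[ck] * subj_scale[ck]
        # dimensionless shape features do not scale with caliber
        truth[c("min_max_ratio", "circularity")] <-
          base_means[c("min_max_ratio", "circularity")]
        for (tp in c("baseline", "followup")) {
          v <- truth
          if (tp == "followup") v <- v * (1 + eff / 100)
          v <- v + rnorm(length(v), 0, noise_sd_frac * abs(base_means))
          r <- r + 1L
          rows[[r]] <- data.frame(subject_id = paste0("S", s),
                                  timepoint = tp, chunk_id = ck,
                                  as.list(v))
        }
      }
    }
    cohort <- do.call(rbind, rows)
    covariates <- data.frame(
      subject_id = paste0("S", seq_len(n_subjects)),
      age = round(rnorm(n_subjects, 62.9, 14.4)),
      sex = stats::rbinom(n_subjects, 1, 0.593),
      sbp = round(rnorm(n_subjects, 132, 16)),
      ldl_change_pct = rnorm(n_subjects, -50.8, 15),
      therapy_days = round(rnorm(n_subjects, 179.4, 19.4)))
    list(cohort = cohort, covariates = covariates)
  })
}

#' Simulate a two-timepoint phantom cohort through the full image pipeline
#'
#' End-to-end parameter-recovery harness: every subject is a straight
#' cylinder phantom whose radius is drawn around `radius_mm`; the follow-up
#' phantom inflates the radius by `inflation_pct` percent (so diameter-type
#' features increase by the same percentage). Both volumes are pushed
#' through segmentation, surface extraction, centerline computation,
#' resampling and feature extraction, and summarised with a single-chunk
#' atlas — exactly the clinical processing chain.
#'
#' @param n_subjects number of subjects.
#' @param inflation_pct percent radius (= diameter) increase at follow-up.
#' @param radius_mm mean baseline lumen radius (mm).
#' @param radius_sd_mm between-subject SD of the baseline radius.
#' @param length_mm tube length (mm).
#' @param spacing_mm voxel size (mm).
#' @param noise_sigma Rician noise scale (intensity units; foreground is 100).
#' @param seed RNG seed.
#' @return long cohort data.frame as in [simulate_chunk_cohort()], with
#'   `chunk_id = 1`.
#' @export
simulate_phantom_cohort <- function(n_subjects = 30, inflation_pct = 6,
                                    radius_mm = 1.6, radius_sd_mm = 0.15,
                                    length_mm = 12, spacing_mm = 0.284,
                                    noise_sigma = 2, seed = 1) {
  radii <- with_seed(seed, pmax(1.1, rnorm(n_subjects, radius_mm, radius_sd_mm)))
  atlas <- mini_atlas(1)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (tp in c("baseline", "followup")) {
      r <- radii[s] * if (tp == "followup") 1 + inflation_pct / 100 else 1
      cm <- measure_cylinder_phantom(r, length_mm, spacing_mm, noise_sigma,
                                     seed = seed * 10000L + s * 2L +
                                       (tp == "followup"))
      cm <- cm[cm$chunk_id == 1, ]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0("S", s), timepoint = tp, chunk_id = 1L,
        cm[, c("area_mm2", "misr_mm", "min_diameter_mm", "max_diameter_mm",
               "min_max_ratio", "curvature_per_mm", "torsion_per_mm",
               "perimeter_mm", "circularity")])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# single-chunk atlas for phantom work
mini_atlas <- function(n_branches = 1) {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(branch_id = seq_len(n_branches),
                       branch_name = paste0("tube", seq_len(n_branches)),
                       chunk_id = 1L, chunk_name = "tube"),
            path, row.names = FALSE)
  on.exit(unlink(path))
  load_atlas(path)
}

# full measurement chain on one cylinder phantom
measure_cylinder_phantom <- function(radius_mm, length_mm, spacing_mm,
                                     noise_sigma, seed) {
  spec <- tube_spec("cylinder", radius_mm = radius_mm, length_mm = length_mm,
                    noise_sigma = noise_sigma)
  ph <- make_tube_phantom(spec, spacing_mm, seed = seed)
  mid <- ph$truth[which.min(abs(ph$truth$arclength_mm - length_mm / 2)), ]
  seedvox <- world_to_voxel(ph$volume, matrix(as.numeric(mid[c("x", "y", "z")]), 1))
  mask <- region_grow(ph$volume, seedvox, lower = 50)
  mask <- largest_connected_component(mask)
  mesh <- extract_surface(mask)
  ends <- as.matrix(ph$truth[c(1, nrow(ph$truth)), c("x", "y", "z")])
  # trim endpoints inward so cross-sections stay clear of the end caps
  dirv <- ends[2, ] - ends[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  ends[1, ] <- ends[1, ] + dirv * 2 * radius_mm
  ends[2, ] <- ends[2, ] - dirv * 2 * radius_mm
  cl <- compute_centerline(mask, list(ends))
  cl <- resample_centerline(cl)
  feats <- point_features(mesh, cl)
  chunk_means(feats, mini_atlas(1))
}
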