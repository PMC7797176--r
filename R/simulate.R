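#' Configuration for the synthetic ADNI-like cohort generator
#'
#' The generator emulates the structure of ADNI-style longitudinal data:
#' visits roughly every 6 months with jitter, a long-tailed visit count
#' (mean about 7.3, sd about 4), per-feature observation fractions matching
#' the reference marginals, and diagnoses that progress NC -> MCI -> AD along
#' a monotone latent stage with rare reversions caused by assessment noise.
#'
#' Each subject carries a latent disease stage `z(t) = logistic((t - onset) /
#' rate)`; every continuous marker is an affine function of `z` anchored at
#' the reference mean/sd, with the clinical direction of change (ADAS and
#' ventricles up, MMSE and hippocampus down, intracranial volume flat), a
#' subject-level random intercept, and Gaussian visit noise. Diagnosis is a
#' staged threshold on `z` plus assessment noise; a subject only reverts to
#' an earlier stage if the noisy stage score falls below the stage threshold
#' minus a hysteresis margin, keeping reversions rare.
#'
#' @param n_subjects number of subjects.
#' @param seed integer; drives every random draw (full determinism).
#' @param visit_gap_months integer vector of admissible gaps between
#'   consecutive visits (months); default 4..8, mean 6 with +/-2 jitter.
#' @param n_visits_mean,n_visits_sd target mean and sd of the per-subject
#'   visit count (drawn as 1 + negative binomial).
#' @param missing_rates named vector of per-feature observed fractions in
#'   (0, 1]; names `DX` plus the 22 markers. Defaults to the reference rates.
#' @param missing_mode `"mcar"` (independent Bernoulli per feature per visit)
#'   or `"block"` (whole modalities - cognitive, MRI, each PET tracer, CSF -
#'   observed or missing together per visit).
#' @param noise_sd visit-level marker noise, as a fraction of each marker's
#'   reference sd.
#' @param subject_sd subject-level random-intercept sd, same units.
#' @param stage_slope slope of the marker link in reference-sd units per unit
#'   latent stage.
#' @param onset_mean,onset_sd distribution (months, relative to first visit)
#'   of the latent logistic midpoint.
#' @param rate_meanlog,rate_sdlog log-normal parameters of the logistic time
#'   constant (months).
#' @param dx_noise_sd sd of the assessment noise added to `z` before
#'   thresholding; 0 gives deterministic staging.
#' @param dx_thresholds two thresholds on `z` separating NC/MCI/AD.
#' @param dx_hysteresis reversion margin on the noisy stage score.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 100L, seed = 1L,
                       visit_gap_months = 4:8,
                       n_visits_mean = 7.3, n_visits_sd = 4.0,
                       missing_rates = NULL,
                       missing_mode = c("mcar", "block"),
                       noise_sd = 0.3, subject_sd = 0.6,
                       stage_slope = 2.5,
                       onset_mean = 24, onset_sd = 36,
                       rate_meanlog = log(24), rate_sdlog = 0.4,
                       dx_noise_sd = 0.04,
                       dx_thresholds = c(1 / 3, 2 / 3),
                       dx_hysteresis = 0.05) {
  ref <- .adni_reference()
  if (is.null(missing_rates)) {
    missing_rates <- c(DX = 0.6989, stats::setNames(ref$observed, ref$name))
  }
  stopifnot(all(missing_rates > 0), all(missing_rates <= 1),
            n_visits_mean > 1)
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         visit_gap_months = as.integer(visit_gap_months),
         n_visits_mean = n_visits_mean, n_visits_sd = n_visits_sd,
         missing_rates = missing_rates,
         missing_mode = match.arg(missing_mode),
         noise_sd = noise_sd, subject_sd = subject_sd,
         stage_slope = stage_slope,
         onset_mean = onset_mean, onset_sd = onset_sd,
         rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
         dx_noise_sd = dx_noise_sd, dx_thresholds = dx_thresholds,
         dx_hysteresis = dx_hysteresis),
    class = "sim_config")
}

# modality blocks for block-wise missingness
.modality_blocks <- function() {
  ref <- .adni_reference()$name
  list(cognitive = ref[1:10],
       mri = ref[11:17],
       av45 = "AV45", fdg = "FDG",
       csf = c("ABETA", "TAU", "PTAU"))
}

# negative binomial shifted by 1, parameterized to hit (mean, sd)
.draw_n_visits <- function(cfg) {
  mu <- cfg$n_visits_mean - 1
  v <- cfg$n_visits_sd^2
  if (v <= mu) return(1L + stats::rpois(1L, mu))
  size <- mu^2 / (v - mu)
  1L + stats::rnbinom(1L, size = size, mu = mu)
}

#' Simulate one subject
#'
#' Draws from the current RNG state (or from `seed` if given) so that
#' [simulate_cohort()] can generate subjects sequentially under one seed.
#'
#' @param cfg a [sim_config()]; @param subject_id identifier;
#' @param seed optional integer for a standalone deterministic draw.
#' @return list with `trajectory` (a `subject_trajectory` on the monthly
#'   grid) and `truth` (latent stage, complete pre-missingness feature
#'   matrix and true diagnosis sequence at the visit months).
#' @export
simulate_subject <- function(cfg, subject_id = "s1", seed = NULL) {
  if (!is.null(seed))
    return(.with_seed(seed, simulate_subject(cfg, subject_id)))
  ref <- .adni_reference()
  n_visits <- .draw_n_visits(cfg)
  gaps <- sample(cfg$visit_gap_months, max(0L, n_visits - 1L), replace = TRUE)
  months <- cumsum(c(0L, gaps))

  onset <- stats::rnorm(1L, cfg$onset_mean, cfg$onset_sd)
  rate <- stats::rlnorm(1L, cfg$rate_meanlog, cfg$rate_sdlog)
  z <- stats::plogis((months - onset) / rate)

  b <- stats::rnorm(.n_cont, 0, cfg$subject_sd)        # subject intercepts
  eps <- matrix(stats::rnorm(n_visits * .n_cont, 0, cfg$noise_sd),
                n_visits, .n_cont)
  g <- matrix(0, n_visits, .n_cont)
  for (j in seq_len(.n_cont)) {
    g[, j] <- ref$mean[j] + ref$sd[j] *
      (ref$direction[j] * cfg$stage_slope * (z - 0.5) + b[j] + eps[, j])
  }
  colnames(g) <- ref$name

  # staged diagnosis with reversion hysteresis
  zn <- z + stats::rnorm(n_visits, 0, cfg$dx_noise_sd)
  th <- cfg$dx_thresholds
  stage <- integer(n_visits)
  prev <- NA_integer_
  for (t in seq_len(n_visits)) {
    raw <- 1L + (zn[t] >= th[1L]) + (zn[t] >= th[2L])
    if (!is.na(prev) && raw < prev &&
        zn[t] >= th[prev - 1L] - cfg$dx_hysteresis) {
      raw <- prev                                     # reversion suppressed
    }
    stage[t] <- raw
    prev <- raw
  }
  dx <- dx_levels()[stage]

  # per-feature missingness
  obs <- matrix(FALSE, n_visits, 1L + .n_cont)
  colnames(obs) <- c("DX", ref$name)
  rates <- cfg$missing_rates[colnames(obs)]
  if (cfg$missing_mode == "mcar") {
    obs[] <- matrix(stats::runif(length(obs)), n_visits) <=
      matrix(rates, n_visits, ncol(obs), byrow = TRUE)
  } else {
    obs[, "DX"] <- stats::runif(n_visits) <= rates["DX"]
    for (blk in .modality_blocks()) {
      keep <- stats::runif(n_visits) <= mean(rates[blk])
      obs[, blk] <- keep
    }
  }
  if (!any(obs)) obs[1L, "DX"] <- TRUE                # never fully empty

  visits <- data.frame(month = months,
                       DX = ifelse(obs[, "DX"], dx, NA_character_),
                       ifelse(obs[, -1L, drop = FALSE], g, NA_real_),
                       check.names = FALSE)
  traj <- build_monthly_grid(visits, adni_schema(), resolution = 1L,
                             subject_id = subject_id)
  truth <- list(subject_id = as.character(subject_id), months = months,
                z = z, values = g, dx = dx, onset = onset, rate = rate)
  list(trajectory = traj, truth = truth)
}

#' Simulate a full cohort
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (an `ad_cohort`) and `truth` (one ground-truth
#'   record per subject, keyed by subject ID).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sprintf("S%04d", seq_len(cfg$n_subjects))
  out <- .with_seed(cfg$seed, lapply(ids, function(id)
    simulate_subject(cfg, subject_id = id)))
  list(cohort = cohort(lapply(out, `[[`, "trajectory")),
       truth = stats::setNames(lapply(out, `[[`, "truth"), ids))
}
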