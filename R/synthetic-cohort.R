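#' Synthetic cohort specification
#'
#' Defaults mirror the study design being emulated: 26 female and 20 male
#' subjects, 6 judges scoring twice (sessions three weeks apart), and
#' per-region volume variability that is independent normal around the
#' gender preset.
#'
#' @param n_female,n_male subjects per stratum (defaults 26 and 20).
#' @param cv per-region coefficient of variation of volumes (default 0.08).
#' @param n_judges number of judges (default 6).
#' @param n_sessions scoring sessions (default 2).
#' @param target_r target test-retest Pearson correlation per judge
#'   (default 0.7).
#' @param score_mean,score_sd latent attractiveness distribution on the
#'   1-10 scale (defaults 7.0 and 1.0).
#' @param judge_bias_sd between-judge systematic bias SD (default 0.3).
#' @param seed integer RNG seed.
#' @param n_theta,ring_mm mesh resolution forwarded to [head_spec()]
#'   (cohort default is coarser than the single-head default to keep a
#'   46-subject run cheap).
#' @return `vc_cohortspec`.
#' @export
cohort_spec <- function(n_female = 26L, n_male = 20L, cv = 0.08,
                        n_judges = 6L, n_sessions = 2L, target_r = 0.7,
                        score_mean = 7.0, score_sd = 1.0, judge_bias_sd = 0.3,
                        seed = 1L, n_theta = 36L, ring_mm = 5) {
  stopifnot(n_female >= 0L, n_male >= 0L, cv >= 0,
            target_r >= -1, target_r <= 1, n_judges >= 1L, n_sessions >= 1L)
  structure(list(
    n_female = as.integer(n_female), n_male = as.integer(n_male), cv = cv,
    n_judges = as.integer(n_judges), n_sessions = as.integer(n_sessions),
    target_r = target_r, score_mean = score_mean, score_sd = score_sd,
    judge_bias_sd = judge_bias_sd, seed = as.integer(seed),
    n_theta = as.integer(n_theta), ring_mm = ring_mm
  ), class = "vc_cohortspec")
}

#' Gender preset target distributions
#'
#' The female preset uses the published female shares (self-consistent with
#' the published female mean volumes); the male preset uses the shares
#' recomputed from the published male mean volumes, since the printed male
#' malar/maxillary percentages contradict their own volumes.
#'
#' @param gender `"female"` or `"male"`.
#' @return list with `shares` (percent, sums to 100) and `total_mm3`.
#' @export
gender_preset <- function(gender = c("female", "male")) {
  gender <- match.arg(gender)
  ref <- normative_reference(gender, variant = "volume_consistent")
  list(shares = ref$shares, total_mm3 = sum(ref$mean_volumes),
       mean_volumes = ref$mean_volumes)
}

#' Generate a synthetic cohort of heads
#'
#' Per subject, the four region volumes are drawn independently from
#' `Normal(preset_mean, cv * preset_mean)` truncated at 3 sigma and at
#' zero; a head is calibrated (closed loop through the real measurement
#' pipeline) to the drawn distribution and rescaled to the drawn total.
#' Deterministic under the spec's seed.
#'
#' @param cspec `vc_cohortspec`.
#' @param keep_meshes store each subject's mesh/landmarks in the result
#'   (default `TRUE`; set `FALSE` to save memory when only the table is
#'   needed).
#' @param calibrate_tol_pp per-slab calibration tolerance (default 0.5).
#' @return list with `table` (data.frame: subject_id, gender, drawn true
#'   volumes `true_v_*`, measured volumes `v_*`) and `subjects` (named list
#'   with `spec`, and if kept, `mesh` + `landmarks`).
#' @export
generate_cohort <- function(cspec, keep_meshes = TRUE, calibrate_tol_pp = 0.5) {
  stopifnot(inherits(cspec, "vc_cohortspec"))
  set.seed(cspec$seed)
  genders <- c(rep("female", cspec$n_female), rep("male", cspec$n_male))
  n <- length(genders)
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- vector("list", n)
  names(subjects) <- ids
  rows <- vector("list", n)
  regions <- c("malar", "maxillary", "mandibular", "chin")
  for (i in seq_len(n)) {
    g <- genders[i]
    preset <- gender_preset(g)
    mu <- preset$mean_volumes[regions]
    sdv <- cspec$cv * mu
    draw <- stats::rnorm(4L, mu, sdv)
    draw <- pmin(pmax(draw, mu - 3 * sdv), mu + 3 * sdv)
    draw <- pmax(draw, 0)
    names(draw) <- regions
    target_shares <- 100 * draw / sum(draw)
    spec <- head_spec(g, n_theta = cspec$n_theta, ring_mm = cspec$ring_mm,
                      seed = cspec$seed)
    spec <- calibrate_to_distribution(spec, target_shares,
                                      tol_pp = calibrate_tol_pp)
    spec <- scale_to_total(spec, sum(draw))
    head <- generate_head(spec)
    prof <- measure_mesh(head$mesh, head$landmarks)
    subjects[[i]] <- c(
      list(spec = spec),
      if (keep_meshes) list(mesh = head$mesh, landmarks = head$landmarks)
    )
    rows[[i]] <- data.frame(
      subject_id = ids[i], gender = g,
      true_v_malar = draw[["malar"]], true_v_maxillary = draw[["maxillary"]],
      true_v_mandibular = draw[["mandibular"]], true_v_chin = draw[["chin"]],
      v_malar = prof$v_malar, v_maxillary = prof$v_maxillary,
      v_mandibular = prof$v_mandibular, v_chin = prof$v_chin
    )
  }
  list(table = do.call(rbind, rows), subjects = subjects)
}

#' Generate synthetic jury scores
#'
#' Latent attractiveness per subject is normal
#' (`score_mean`, `score_sd`); each judge adds a fixed bias and each
#' (judge, session) observation adds session noise whose variance is
#' chosen analytically so the expected test-retest Pearson correlation
#' across subjects equals `target_r`
#' (`sd_noise = score_sd * sqrt(1/r - 1)`; zero for `r = 1`, so session 2
#' then duplicates session 1 exactly). Scores are rounded to the nearest
#' half point and clipped to [1, 10]. Deterministic under the spec's seed.
#'
#' @param cspec `vc_cohortspec`.
#' @param subject_ids character vector of subject ids.
#' @return `vc_scores` data.frame, plus attribute `latent` (named true
#'   attractiveness per subject).
#' @export
generate_jury_scores <- function(cspec, subject_ids) {
  stopifnot(inherits(cspec, "vc_cohortspec"))
  n <- length(subject_ids)
  set.seed(cspec$seed + 104729L)  # offset stream from the mesh draws
  latent <- stats::rnorm(n, cspec$score_mean, cspec$score_sd)
  bias <- stats::rnorm(cspec$n_judges, 0, cspec$judge_bias_sd)
  r <- cspec$target_r
  sd_noise <- if (r >= 1) 0 else if (r <= 0) {
    cspec$score_sd * 1e3
  } else {
    cspec$score_sd * sqrt(1 / r - 1)
  }
  rows <- list()
  for (j in seq_len(cspec$n_judges)) {
    # session noise: with target r = 1 both sessions see the identical value
    noise1 <- stats::rnorm(n, 0, sd_noise)
    for (s in seq_len(cspec$n_sessions)) {
      noise <- if (s == 1L || sd_noise == 0) noise1 else stats::rnorm(n, 0, sd_noise)
      raw <- latent + bias[j] + noise
      score <- pmin(pmax(round_half_away(raw * 2, 0) / 2, 1), 10)
      rows[[length(rows) + 1L]] <- data.frame(
        judge_id = sprintf("J%d", j), session = s,
        subject_id = subject_ids, score = score
      )
    }
  }
  out <- jury_scores(do.call(rbind, rows))
  attr(out, "latent") <- stats::setNames(latent, subject_ids)
  out
}
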