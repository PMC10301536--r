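#' Volume profile of the four facial slabs
#'
#' The core statistic: the four slab volumes (mm^3), their total, the
#' percentage share of each slab in the lower two-thirds, and the
#' maxilla/mandible volume ratio.
#'
#' @param v_malar,v_maxillary,v_mandibular,v_chin volumes in mm^3 (>= 0).
#' @return `vc_profile`: list with the volumes, `total`, unrounded shares
#'   (`share_malar`, ...) in percent, and `mm_ratio`.
#' @export
volume_profile <- function(v_malar, v_maxillary, v_mandibular, v_chin) {
  v <- c(malar = v_malar, maxillary = v_maxillary,
         mandibular = v_mandibular, chin = v_chin)
  if (any(v < 0) || any(!is.finite(v))) {
    stop("volume_profile(): volumes must be finite and >= 0")
  }
  total <- sum(v)
  shares <- percentage_distribution(v, decimals = NULL)
  structure(list(
    v_malar = v[["malar"]], v_maxillary = v[["maxillary"]],
    v_mandibular = v[["mandibular"]], v_chin = v[["chin"]],
    total = total,
    share_malar = shares[["malar"]], share_maxillary = shares[["maxillary"]],
    share_mandibular = shares[["mandibular"]], share_chin = shares[["chin"]],
    mm_ratio = if (v[["mandibular"]] > 0) v[["maxillary"]] / v[["mandibular"]] else NA_real_
  ), class = "vc_profile")
}

#' @export
print.vc_profile <- function(x, ...) {
  cat("<volume profile>\n")
  for (r in c("malar", "maxillary", "mandibular", "chin")) {
    cat(sprintf("  %-10s %10.0f mm^3  (%s%%)\n", r, x[[paste0("v_", r)]],
                format(round_half_away(x[[paste0("share_", r)]], 1), nsmall = 1)))
  }
  cat(sprintf("  total      %10.0f mm^3\n", x$total))
  cat(sprintf("  maxilla/mandible ratio: %.2f\n", x$mm_ratio))
  invisible(x)
}

#' Percentage distribution of slab volumes
#'
#' `share_i = 100 * v_i / sum(v)`. Shares are reported rounded
#' half-away-from-zero to `decimals` places (default 1, the study's printed
#' precision); pass `decimals = NULL` for unrounded values.
#'
#' @param v numeric vector of volumes (mm^3), total > 0.
#' @param decimals integer or `NULL`.
#' @return named numeric vector of shares in percent.
#' @export
percentage_distribution <- function(v, decimals = 1) {
  vv <- as.numeric(v)
  names(vv) <- names(v)
  if (any(vv < 0)) stop("percentage_distribution(): negative volume")
  total <- sum(vv)
  if (total <= 0) stop("percentage_distribution(): total volume is zero")
  s <- 100 * vv / total
  if (is.null(decimals)) s else round_half_away(s, decimals)
}

#' Maxilla/mandible volume ratio
#'
#' @param v_maxillary,v_mandibular volumes in mm^3; mandibular must be > 0.
#' @param decimals rounding (half-away-from-zero), default 2; `NULL` for raw.
#' @export
maxillomandibular_ratio <- function(v_maxillary, v_mandibular, decimals = 2) {
  if (v_mandibular <= 0) stop("maxillomandibular_ratio(): mandibular volume must be > 0")
  r <- v_maxillary / v_mandibular
  if (is.null(decimals)) r else round_half_away(r, decimals)
}

#' Round half away from zero
#'
#' Commercial rounding (0.05 -> 0.1, -0.05 -> -0.1), matching printed
#' percentages; base `round()` rounds half to even.
#'
#' @param x numeric.
#' @param decimals integer >= 0.
#' @export
round_half_away <- function(x, decimals = 0) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Jury score tables
#'
#' Long-format score table with one row per (judge, session, subject):
#' columns `judge_id`, `session`, `subject_id`, `score`. Scores must lie in
#' [1, 10]; every subject must be scored by every judge in session 1.
#'
#' @param df data.frame with the four columns above.
#' @return validated `vc_scores` (a data.frame).
#' @export
jury_scores <- function(df) {
  need <- c("judge_id", "session", "subject_id", "score")
  if (!all(need %in% names(df))) {
    stop("jury_scores(): need columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$score <- as.numeric(df$score)
  df$session <- as.integer(df$session)
  if (any(df$score < 1 | df$score > 10 | !is.finite(df$score))) {
    stop("jury_scores(): scores must be finite and within [1, 10]")
  }
  s1 <- df[df$session == 1L, ]
  tab <- table(s1$subject_id, s1$judge_id)
  if (nrow(tab) > 0L && any(tab == 0L)) {
    stop("jury_scores(): some subjects unscored by some judge in session 1")
  }
  structure(df, class = c("vc_scores", "data.frame"))
}

#' Select the most attractive subjects
#'
#' A subject is selected iff the mean over all available (judge, session)
#' scores is greater than or equal to the cutoff (inclusive threshold;
#' default 8.5 on the 1-10 Phillips scale).
#'
#' @param scores `vc_scores` (or conforming data.frame).
#' @param cutoff inclusive mean-score threshold, default 8.5.
#' @return character vector of selected subject ids (in first-seen order).
#' @export
select_attractive <- function(scores, cutoff = 8.5) {
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0L) return(character(0))
  ids <- unique(as.character(scores$subject_id))
  means <- tapply(scores$score, as.character(scores$subject_id), mean)
  if (anyNA(means[ids])) {
    stop("select_attractive(): subject(s) with no scores: ",
         paste(ids[is.na(means[ids])], collapse = ", "))
  }
  ids[means[ids] >= cutoff]
}

#' Mean aesthetic score per subject
#' @param scores `vc_scores`.
#' @return named numeric vector (subject id -> mean score over all judges
#'   and sessions).
#' @export
mean_scores <- function(scores) {
  scores <- as.data.frame(scores)
  tapply(scores$score, as.character(scores$subject_id), mean)
}

#' Judge test-retest repeatability
#'
#' Pearson product-moment correlation between each judge's session-1 and
#' session-2 scores across subjects, with the two-sided p-value, plus the
#' cohort-level mean r over judges. Judges with zero variance in either
#' session are flagged undefined and excluded from the mean with a warning.
#'
#' @param scores `vc_scores` with sessions 1 and 2.
#' @return list with `per_judge` (data.frame: judge_id, n, r, p) and
#'   `mean_r`.
#' @export
judge_repeatability <- function(scores) {
  scores <- as.data.frame(scores)
  judges <- unique(as.character(scores$judge_id))
  rows <- lapply(judges, function(j) {
    s1 <- scores[scores$judge_id == j & scores$session == 1L, ]
    s2 <- scores[scores$judge_id == j & scores$session == 2L, ]
    common <- intersect(s1$subject_id, s2$subject_id)
    x <- s1$score[match(common, s1$subject_id)]
    y <- s2$score[match(common, s2$subject_id)]
    if (length(common) < 3L) {
      stop(sprintf("judge_repeatability(): judge %s has %d paired subjects (need >= 3)",
                   j, length(common)))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("judge %s: zero score variance; r undefined, excluded from mean", j))
      return(data.frame(judge_id = j, n = length(common),
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(judge_id = j, n = length(common),
               r = unname(ct$estimate), p = ct$p.value)
  })
  per_judge <- do.call(rbind, rows)
  list(per_judge = per_judge, mean_r = mean(per_judge$r, na.rm = TRUE))
}

#' Shapiro-Wilk normality check
#'
#' Royston's (AS R94) approximation of the Shapiro-Wilk W statistic and its
#' p-value, as implemented in `stats::shapiro.test()`.
#'
#' @param values numeric, 3 <= n <= 5000, non-zero variance.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("normality_check(): need 3 <= n <= 5000, got ", n)
  }
  if (stats::sd(values) == 0) {
    stop("normality_check(): zero variance; W undefined")
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Gender-stratified cohort summary
#'
#' Per gender: arithmetic mean of each slab volume, percentage shares
#' computed from the mean volumes (not the mean of per-subject shares),
#' the maxilla/mandible ratio of the mean volumes, and the subject count.
#'
#' @param cohort data.frame with columns `subject_id`, `gender`
#'   (`"female"`/`"male"`), `v_malar`, `v_maxillary`, `v_mandibular`,
#'   `v_chin` (mm^3).
#' @return list keyed by gender; each entry holds `n`, `mean_volumes`,
#'   `shares` (unrounded percent), `mm_ratio`.
#' @export
cohort_summary <- function(cohort) {
  need <- c("subject_id", "gender", "v_malar", "v_maxillary",
            "v_mandibular", "v_chin")
  if (!all(need %in% names(cohort))) {
    stop("cohort_summary(): need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cohort$subject_id)) {
    stop("cohort_summary(): duplicate subject ids")
  }
  bad <- setdiff(unique(cohort$gender), c("female", "male"))
  if (length(bad) > 0L) {
    stop("cohort_summary(): unknown gender label(s): ",
         paste(bad, collapse = ", "), " (expected female/male)")
  }
  out <- list()
  for (g in c("female", "male")) {
    sub <- cohort[cohort$gender == g, ]
    if (nrow(sub) == 0L) {
      warning("cohort_summary(): no subjects for gender ", g, "; stratum omitted")
      next
    }
    mv <- c(malar = mean(sub$v_malar), maxillary = mean(sub$v_maxillary),
            mandibular = mean(sub$v_mandibular), chin = mean(sub$v_chin))
    out[[g]] <- list(
      n = nrow(sub),
      mean_volumes = mv,
      shares = percentage_distribution(mv, decimals = NULL),
      mm_ratio = maxillomandibular_ratio(mv[["maxillary"]], mv[["mandibular"]],
                                         decimals = NULL)
    )
  }
  out
}

#' Normative reference distributions
#'
#' Gender-specific reference shares of the four facial slabs, embedded from
#' the package's versioned JSON resource. The printed male malar and
#' maxillary percentages are internally inconsistent with the male mean
#' volumes they accompany (computed 36.5% and 28.0% vs printed 37% and
#' 26%); both variants are shipped, the printed one carrying
#' `inconsistent_shares` flags. The female set is self-consistent.
#'
#' @param gender `"female"` or `"male"`.
#' @param variant `"printed"` (verbatim published shares) or
#'   `"volume_consistent"` (shares recomputed from the published mean
#'   volumes).
#' @return `vc_reference`: list with `gender`, `shares` (named percent),
#'   `mean_volumes` (mm^3), `source`, `flags`.
#' @export
normative_reference <- function(gender = c("female", "male"),
                                variant = c("printed", "volume_consistent")) {
  gender <- match.arg(gender)
  variant <- match.arg(variant)
  refs <- normative_reference_table()
  entry <- refs[[gender]]
  shares <- if (variant == "printed") entry$printed_shares else
    percentage_distribution(unlist(entry$mean_volumes), decimals = NULL)
  structure(list(
    gender = gender,
    shares = unlist(shares),
    mean_volumes = unlist(entry$mean_volumes),
    source = paste0(refs$source, " [", variant, "]"),
    flags = if (variant == "printed") unlist(entry$flags) else character(0)
  ), class = "vc_reference")
}

normative_reference_table <- function() {
  path <- system.file("extdata", "normative_references.json",
                      package = "volcephalo")
  if (!nzchar(path)) {
    # fall back for non-installed use (e.g. sourcing during development)
    path <- file.path("inst", "extdata", "normative_references.json")
  }
  jsonlite::read_json(path)
}

#' Compare a subject's profile to a normative reference
#'
#' Per-region signed deviation in percentage points (subject share minus
#' reference share) and the volume change (mm^3) that would equalise each
#' region's share at constant total (`delta_v_i = -deviation_i/100 * total`;
#' applying one region's change alters the total, so the changes are
#' reported per region independently, not as a joint prescription).
#'
#' @param profile `vc_profile`.
#' @param ref `vc_reference` from [normative_reference()].
#' @return data.frame: region, subject_share, reference_share,
#'   deviation_pp, equalizing_volume_change_mm3.
#' @export
compare_to_reference <- function(profile, ref) {
  stopifnot(inherits(profile, "vc_profile"), inherits(ref, "vc_reference"))
  regions <- c("malar", "maxillary", "mandibular", "chin")
  subj <- vapply(regions, function(r) profile[[paste0("share_", r)]], 0)
  refs <- ref$shares[regions]
  dev <- subj - refs
  data.frame(
    region = regions,
    subject_share = unname(subj),
    reference_share = unname(refs),
    deviation_pp = unname(dev),
    equalizing_volume_change_mm3 = unname(-dev / 100 * profile$total),
    row.names = NULL
  )
}
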