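# published gender mean volumes (mm^3): the package's embedded references
female_vols <- c(malar = 283005, maxillary = 212433, mandibular = 202279,
                 chin = 34340)
male_vols <- c(malar = 300436, maxillary = 230526, mandibular = 242905,
               chin = 49444)

test_that("percentage distribution reproduces the published female shares", {
  expect_equal(unname(percentage_distribution(female_vols)),
               c(38.7, 29.0, 27.6, 4.7))
  expect_equal(unname(percentage_distribution(c(1, 1, 1, 1))),
               c(25, 25, 25, 25))
  # male volumes: the self-consistent shares (the published malar/maxillary
  # percentages disagree with these volumes; chin and mandibular agree)
  expect_equal(unname(percentage_distribution(male_vols)),
               c(36.5, 28.0, 29.5, 6.0))
  expect_equal(unname(round_half_away(percentage_distribution(male_vols, NULL))),
               c(36, 28, 30, 6))
  expect_error(percentage_distribution(c(0, 0, 0, 0)), "total")
  # unrounded shares always sum to 100
  set.seed(2)
  for (k in 1:20) {
    v <- stats::runif(4, 0, 1e6)
    expect_equal(sum(percentage_distribution(v, decimals = NULL)), 100,
                 tolerance = 1e-9)
  }
})

test_that("maxillomandibular ratio matches the published 1.05", {
  expect_equal(maxillomandibular_ratio(212433, 202279), 1.05)
  expect_equal(maxillomandibular_ratio(5, 5), 1.00)
  expect_equal(maxillomandibular_ratio(230526, 242905), 0.95)
  expect_error(maxillomandibular_ratio(1, 0), "> 0")
})

test_that("rounding is half-away-from-zero at the printed precision", {
  expect_equal(round_half_away(0.05, 1), 0.1)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(2.345, 2), 2.35)
  expect_equal(round_half_away(26.5, 0), 27)
})

test_that("jury selection uses an inclusive cutoff and is monotone", {
  df <- data.frame(
    judge_id = "J1", session = 1L,
    subject_id = c("a", "b", "c"),
    score = c(8.7, 8.4, 8.5)
  )
  sc <- jury_scores(df)
  expect_equal(select_attractive(sc, 8.5), c("a", "c"))
  expect_equal(select_attractive(sc[0, ], 8.5), character(0))

  # 6 judges x 2 sessions all exactly at the cutoff: selected
  full <- expand.grid(judge_id = paste0("J", 1:6), session = 1:2,
                      subject_id = "s1", stringsAsFactors = FALSE)
  full$score <- 8.5
  expect_equal(select_attractive(jury_scores(full), 8.5), "s1")

  # monotone: raising the cutoff never adds subjects
  set.seed(4)
  big <- expand.grid(judge_id = paste0("J", 1:6), session = 1:2,
                     subject_id = sprintf("s%02d", 1:30),
                     stringsAsFactors = FALSE)
  big$score <- pmin(pmax(round(stats::rnorm(nrow(big), 7, 1.2) * 2) / 2, 1), 10)
  bs <- jury_scores(big)
  prev <- select_attractive(bs, 6)
  for (cut in c(7, 8, 8.5, 9, 9.5)) {
    cur <- select_attractive(bs, cut)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("judge repeatability: exact, reversed, and hand-computed correlations", {
  mk <- function(s1, s2) jury_scores(data.frame(
    judge_id = "J1",
    session = rep(1:2, each = length(s1)),
    subject_id = rep(sprintf("s%d", seq_along(s1)), 2),
    score = c(s1, s2)
  ))
  r_of <- function(sc) judge_repeatability(sc)$per_judge$r

  expect_equal(r_of(mk(c(8, 9, 7, 6), c(8, 9, 7, 6))), 1.0)
  expect_equal(r_of(mk(c(8, 9, 7, 6), 11 - c(8, 9, 7, 6)) ), -1.0)
  # hand-computed Pearson r for (8,9,7,6) vs (7.5,9,7,6.5)
  expect_equal(r_of(mk(c(8, 9, 7, 6), c(7.5, 9, 7, 6.5))), 0.956183,
               tolerance = 1e-3)

  # symmetry in sessions and invariance to affine rescaling
  a <- c(8, 9, 7, 6, 8.5); b <- c(7.5, 9, 7, 6.5, 8)
  expect_equal(r_of(mk(a, b)), r_of(mk(b, a)), tolerance = 1e-12)
  expect_equal(r_of(mk(a, pmin(0.5 * b + 2, 10))), r_of(mk(a, b)),
               tolerance = 1e-12)

  # zero variance: undefined, excluded with warning
  two <- rbind(
    data.frame(judge_id = "J1", session = rep(1:2, each = 4),
               subject_id = rep(paste0("s", 1:4), 2), score = c(a[1:4], b[1:4])),
    data.frame(judge_id = "J2", session = rep(1:2, each = 4),
               subject_id = rep(paste0("s", 1:4), 2), score = rep(8, 8))
  )
  expect_warning(jr <- judge_repeatability(jury_scores(two)), "zero")
  expect_true(is.na(jr$per_judge$r[jr$per_judge$judge_id == "J2"]))
  expect_equal(jr$mean_r, jr$per_judge$r[jr$per_judge$judge_id == "J1"])
})

test_that("Shapiro-Wilk check matches a reference implementation and behaves under normality", {
  # W for this sample frozen from an independent reference implementation
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195)
  res <- normality_check(x)
  expect_equal(res$W, 0.908049, tolerance = 1e-3)

  expect_error(normality_check(rep(1, 10)), "variance")
  expect_error(normality_check(c(1, 2)), "n")

  # 26 normal draws: p > 0.05 in at least 90% of 100 seeded repetitions
  set.seed(123)
  hits <- mean(replicate(100, normality_check(stats::rnorm(26))$p > 0.05))
  expect_gte(hits, 0.9)
})

test_that("gender summary derives shares from mean volumes and is idempotent", {
  one <- data.frame(subject_id = "f1", gender = "female",
                    v_malar = female_vols[["malar"]],
                    v_maxillary = female_vols[["maxillary"]],
                    v_mandibular = female_vols[["mandibular"]],
                    v_chin = female_vols[["chin"]])
  expect_warning(s <- cohort_summary(one), "male")
  expect_equal(unname(round_half_away(s$female$shares, 1)),
               c(38.7, 29.0, 27.6, 4.7))
  expect_equal(round_half_away(s$female$mm_ratio, 2), 1.05)

  two <- rbind(one, transform(one, subject_id = "f2"))
  expect_warning(s2 <- cohort_summary(two), "male")
  expect_equal(s2$female$mean_volumes, s$female$mean_volumes)
  expect_equal(s2$female$n, 2L)

  expect_error(cohort_summary(transform(one, gender = "other")), "unknown gender")
})

test_that("reference comparison reports signed deviations and equalising volumes", {
  ref <- normative_reference("female", "printed")
  prof <- volume_profile(female_vols[["malar"]], female_vols[["maxillary"]],
                         female_vols[["mandibular"]], female_vols[["chin"]])
  cmp <- compare_to_reference(prof, ref)
  expect_equal(cmp$deviation_pp, rep(0, 4), tolerance = 0.05)

  # shift 2 pp from malar to mandibular at fixed total
  total <- sum(female_vols)
  sh <- c(36.65887492, 29.01864199, 29.63159153, 4.69089156)
  shifted <- volume_profile(sh[1] / 100 * total, sh[2] / 100 * total,
                            sh[3] / 100 * total, sh[4] / 100 * total)
  ref_vc <- normative_reference("female", "volume_consistent")
  cmp2 <- compare_to_reference(shifted, ref_vc)
  expect_equal(cmp2$deviation_pp, c(-2, 0, 2, 0), tolerance = 1e-6)
  expect_equal(cmp2$equalizing_volume_change_mm3[1], 0.02 * total,
               tolerance = 1e-6)

  # printed male reference carries its inconsistency flags
  mref <- normative_reference("male", "printed")
  expect_true(length(mref$flags) >= 2)
  expect_match(paste(mref$flags, collapse = " "), "maxillary")
})
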