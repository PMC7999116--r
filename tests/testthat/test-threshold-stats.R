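# Subgroup machinery, classical tests, Games-Howell, ROC/Youden logic.

# small hand-built slice dataset: 2 patients x 25 valid slabs
make_delta <- function(values, invalid = integer(0)) {
  regions <- rep(c("nasopharynx", "oropharynx", "hypopharynx"),
                 c(5, 9, 11))
  d <- data.frame(slab = 1:25, region = regions,
                  area_pre_mm2 = 100, area_post_mm2 = 100 + values,
                  delta_area_pct = values, valid = TRUE)
  d$valid[invalid] <- FALSE
  d$delta_area_pct[invalid] <- NA
  attr(d, "delta_volume_pct") <- mean(values)
  class(d) <- c("ua_delta", "data.frame")
  d
}

make_records <- function(pids, mx, md) {
  do.call(rbind, lapply(seq_along(pids), function(i) {
    data.frame(patient = pids[i], segment = c("maxilla", "mandible"),
               tx = 0, ty = c(mx[i], md[i]), tz = 0, pitch = 0, roll = 0,
               yaw = 0, ap = c(mx[i], md[i]), rms = 0, icp_iterations = 0)
  }))
}

toy_dataset <- function(mx = c(3, 7), md = c(2, 6),
                        groups = c(A = "MAMS", B = "MMA"),
                        deltas = NULL) {
  pids <- names(groups)
  if (is.null(deltas))
    deltas <- stats::setNames(lapply(seq_along(pids), function(i)
      make_delta(rep(10 * i, 25))), pids)
  build_slice_dataset(deltas, make_records(pids, mx, md),
                      stats::setNames(groups, pids))
}

test_that("slice dataset assembles one row per valid slab", {
  ds <- toy_dataset()
  expect_equal(nrow(ds$slices), 50L)
  expect_equal(attr(ds, "exclusions"), 0L)
  cnt <- table(ds$slices$region[ds$slices$patient == "A"])
  expect_equal(as.integer(cnt[c("nasopharynx", "oropharynx", "hypopharynx")]),
               c(5L, 9L, 11L))
})

test_that("invalid slabs are omitted but counted", {
  deltas <- list(A = make_delta(rep(5, 25), invalid = 3L),
                 B = make_delta(rep(5, 25)))
  ds <- build_slice_dataset(deltas, make_records(c("A", "B"), c(1, 2),
                                                 c(1, 2)),
                            c(A = "MAMS", B = "MMA"))
  expect_equal(nrow(ds$slices), 49L)
  expect_equal(attr(ds, "exclusions"), 1L)
})

test_that("a patient without a segment record is an error", {
  recs <- make_records(c("A", "B"), c(1, 2), c(1, 2))
  recs <- recs[!(recs$patient == "B" & recs$segment == "mandible"), ]
  expect_error(build_slice_dataset(list(A = make_delta(rep(1, 25)),
                                        B = make_delta(rep(1, 25))),
                                   recs, c(A = "MAMS", B = "MMA")),
               "missing a displacement record")
})

test_that("subgroup membership matches a hand enumeration", {
  groups <- c(P1 = "MAMS", P2 = "MMA", P3 = "MMA", P4 = "MMA")
  ds <- toy_dataset(mx = c(3, 2, 5, 8), md = c(-2, 1, 6, 4),
                    groups = groups)
  sp <- subgroup_split(ds, "maxilla", cut = 5)
  expect_setequal(unique(sp$MAMS$patient), "P1")
  expect_setequal(unique(sp$MMA_below$patient), "P2")
  expect_setequal(unique(sp$MMA_at_or_above$patient), c("P3", "P4"))
  # boundary AP exactly 5.0 belongs to the ">= 5" subgroup
  expect_true("P3" %in% sp$MMA_at_or_above$patient)
  sp_md <- subgroup_split(ds, "mandible", cut = 5)
  expect_setequal(unique(sp_md$MMA_at_or_above$patient), "P3")
})

test_that("empty subgroups are flagged with a warning", {
  ds <- toy_dataset(mx = c(3, 2), md = c(1, 1))
  expect_warning(sp <- subgroup_split(ds, "maxilla", cut = 5),
                 "empty subgroup")
  expect_equal(attr(sp, "empty"), "MMA_at_or_above")
})

test_that("one-way ANOVA matches the textbook formula and lm()", {
  g <- list(c(1.1, 2.3, 0.8, 1.9), c(2.0, 3.5, 2.8), c(5.1, 4.2, 6.0, 5.5))
  res <- anova_oneway(g)
  df <- data.frame(y = unlist(g),
                   grp = rep(letters[1:3], lengths(g)))
  ref <- anova(lm(y ~ grp, data = df))
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # identical groups: F = 0, p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res0 <- anova_oneway(same)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "zero within-group")
})

test_that("ANOVA null rejection rate is calibrated", {
  set.seed(314)
  rej <- mean(replicate(2000, {
    anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Games-Howell: identical groups give p near 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- games_howell(g)
  expect_true(all(res$p > 0.999))
  expect_true(all(abs(res$diff) < 1e-12))
})

test_that("Games-Howell matches an independent reference implementation", {
  # p values frozen from pingouin.pairwise_gameshowell on this fixture
  a <- c(12.1, 14.3, 11.8, 13.5, 12.9, 14.1, 13.0, 12.4)
  b <- c(16.2, 19.8, 14.9, 21.3, 18.4, 17.6, 20.1)
  c_ <- c(11.0, 25.0, 18.5, 30.2, 8.9, 22.4, 15.7, 27.3, 19.9)
  res <- games_howell(list(a = a, b = b, c = c_))
  ref_p <- c(0.0012072095, 0.0496593415, 0.8185710528)
  ref_diff <- c(-5.3160714286, -6.8652777778, -1.5492063492)
  ref_df <- c(7.6661173289, 8.2869242418, 9.9687933574)
  expect_equal(res$p, ref_p, tolerance = 1e-3)
  expect_equal(res$diff, ref_diff, tolerance = 1e-9)
  expect_equal(res$df, ref_df, tolerance = 1e-6)
})

test_that("Games-Howell approaches Tukey HSD with equal variances and n", {
  # the limit holds when the per-group variances agree; realise it exactly
  # by giving each group the same centred residuals under shifted means
  set.seed(21)
  base <- as.numeric(scale(rnorm(60)))
  g <- lapply(c(0, 0.4, 0.8), function(m) base + m)
  names(g) <- c("g1", "g2", "g3")
  res <- games_howell(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), each = 60))
  tk <- TukeyHSD(aov(y ~ grp, data = df))$grp
  # match pairs by name; agreement within 0.01 absolute on each p
  key <- paste(res$group2, res$group1, sep = "-")
  expect_lt(max(abs(res$p - tk[key, "p adj"])), 0.01)
})

test_that("Games-Howell rejects tiny groups", {
  expect_error(games_howell(list(a = c(1, 2), b = c(1, 2, 3))), "n >= 3")
})

test_that("Mann-Whitney exact p equals full enumeration for n = 5 + 5", {
  x <- c(1.2, 3.4, 2.2, 5.6, 0.3)
  y <- c(2.9, 7.1, 4.4, 6.0, 3.9)
  res <- mann_whitney(x, y)
  expect_true(res$exact)
  # enumerate all C(10,5) assignments of the pooled ranks
  pooled <- rank(c(x, y))
  combos <- combn(10, 5)
  u_obs <- sum(pooled[1:5]) - 5 * 6 / 2
  u_all <- apply(combos, 2, function(idx) sum(pooled[idx]) - 15)
  mu <- 5 * 5 / 2
  p_enum <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  expect_equal(res$p, p_enum, tolerance = 1e-12)
  expect_equal(res$U, u_obs)
})

test_that("Mann-Whitney on identical samples does not reject", {
  x <- c(1, 2, 3, 4, 5)
  expect_gt(mann_whitney(x, x)$p, 0.9)
})

test_that("Mann-Whitney detects a 2-sigma shift (power > 0.9)", {
  set.seed(77)
  rej <- mean(replicate(500, {
    mann_whitney(rnorm(30), rnorm(30, 2))$p < 0.05
  }))
  expect_gt(rej, 0.9)
})

test_that("perfectly separated scores give AUC 1 with a midpoint threshold", {
  r <- roc_from_scores(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$primary$threshold, 6.5)
  expect_equal(r$primary$J, 1)
})

test_that("AUC equals U / (n_pos * n_neg) on arbitrary data", {
  set.seed(8)
  for (i in 1:20) {
    scores <- sample(rep(round(runif(6, 0, 10), 1), each = 3))
    labels <- runif(18) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_from_scores(scores, labels)
    W <- suppressWarnings(stats::wilcox.test(scores[labels],
                                             scores[!labels]))$statistic
    expect_equal(r$auc, unname(W) / (sum(labels) * sum(!labels)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(12)
  scores <- rnorm(60)
  labels <- runif(60) < stats::plogis(2 * scores)
  if (any(labels) && !all(labels)) {
    r <- roc_from_scores(scores, labels)
    pr <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                              quiet = TRUE, direction = "<"))
    expect_equal(r$auc, as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("label permutation centres AUC on one half", {
  set.seed(123)
  scores <- runif(40, 0, 10)
  labels <- rep(c(TRUE, FALSE), 20)
  aucs <- replicate(500, roc_from_scores(scores, sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("single-class inputs are rejected with class counts", {
  expect_error(roc_from_scores(1:4, rep(TRUE, 4)), "0 negative")
})

test_that("roc_threshold scores slices by their patient's segment AP", {
  ds <- toy_dataset(mx = c(3, 7), md = c(2, 6),
                    deltas = list(A = make_delta(rep(0, 25)),
                                  B = make_delta(rep(60, 25))))
  r <- roc_threshold(ds, "maxilla", cutoff_pct = 50)
  expect_equal(r$auc, 1)
  expect_equal(r$primary$threshold, 5)   # midpoint of 3 and 7
  expect_equal(r$n_pos, 25)
  expect_equal(r$n_neg, 25)
})

test_that("strictly unimodal J has no secondary peaks", {
  set.seed(31)
  scores <- c(rnorm(60, 3), rnorm(60, 8))
  labels <- rep(c(FALSE, TRUE), each = 60)
  r <- roc_from_scores(scores, labels)
  pk <- youden_peaks(r, peak_window = 0.02)
  expect_equal(nrow(pk$secondaries), 0L)
})

test_that("a constructed dual peak reports both thresholds", {
  # patients at APs 1.0, 1.8, 4.8, 5.6 with slice counts engineered so J
  # peaks at the 1.4 and 5.2 midpoints
  scores <- c(rep(1.0, 10), rep(1.8, 10), rep(4.8, 10), rep(5.6, 10))
  labels <- c(rep(FALSE, 10),                       # 1.0: all negative
              rep(TRUE, 6), rep(FALSE, 4),          # 1.8: mostly positive
              rep(FALSE, 8), rep(TRUE, 2),          # 4.8: mostly negative
              rep(TRUE, 10))                        # 5.6: all positive
  r <- roc_from_scores(scores, labels)
  pk <- youden_peaks(r, peak_window = 0.2)
  all_thr <- c(pk$primary$threshold, pk$secondaries$threshold)
  expect_true(any(abs(all_thr - 1.4) < 1e-9))
  expect_true(any(abs(all_thr - 5.2) < 1e-9))
  # the larger-J peak is primary
  expect_equal(pk$primary$J, max(r$points$J))
})

test_that("ties in J resolve to the smaller displacement", {
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  r <- roc_from_scores(scores, labels)
  # J = 1 at both the 2.5 midpoint only; construct an explicit tie instead
  scores2 <- c(1, 2, 3, 4, 5, 6)
  labels2 <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  r2 <- roc_from_scores(scores2, labels2)
  jmax <- max(r2$points$J)
  tied <- r2$points$threshold[r2$points$J == jmax]
  expect_equal(r2$primary$threshold, min(tied))
})

test_that("logistic ROC collapses to the univariate one when a segment is irrelevant", {
  set.seed(55)
  n <- 40
  mx <- runif(n, 0, 10); md <- runif(n, 0, 10)
  groups <- stats::setNames(rep(c("MMA", "MAMS"), n / 2),
                            sprintf("P%02d", 1:n))
  deltas <- stats::setNames(lapply(1:n, function(i) {
    p <- stats::plogis(1.2 * (mx[i] - 5))
    make_delta(ifelse(runif(25) < p, 80, 0))
  }), names(groups))
  ds <- build_slice_dataset(deltas, make_records(names(groups), mx, md),
                            groups)
  multi <- logistic_combined_roc(ds, cutoff_pct = 50)
  uni <- roc_threshold(ds, "maxilla", cutoff_pct = 50)
  expect_equal(multi$auc, uni$auc, tolerance = 0.01)
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(66)
  n <- 1000
  mx <- runif(n, -2, 10); md <- runif(n, -6, 10)
  eta <- -3 + 0.6 * mx + 0.35 * md
  y <- rbinom(n, 1, stats::plogis(eta))
  ds <- list(slices = data.frame(patient = as.character(1:n),
                                 maxilla_ap = mx, mandible_ap = md,
                                 delta_area_pct = ifelse(y == 1, 100, 0)))
  r <- logistic_combined_roc(ds, cutoff_pct = 50)
  expect_lt(abs(r$coefficients["maxilla_ap"] - 0.6) / 0.6, 0.15)
  expect_lt(abs(r$coefficients["mandible_ap"] - 0.35) / 0.35, 0.15)
  expect_false(r$separation)
})

test_that("separable data yield AUC 1 and a separation flag", {
  n <- 30
  mx <- c(runif(n / 2, 0, 3), runif(n / 2, 7, 10))
  ds <- list(slices = data.frame(patient = as.character(1:n),
                                 maxilla_ap = mx, mandible_ap = 0,
                                 delta_area_pct = rep(c(0, 100),
                                                      each = n / 2)))
  r <- logistic_combined_roc(ds, cutoff_pct = 50)
  expect_true(r$separation)
  expect_equal(r$auc, 1)
})

test_that("report tables recompute subgroup statistics faithfully", {
  groups <- c(P1 = "MAMS", P2 = "MMA", P3 = "MMA", P4 = "MMA")
  mx <- c(3, 2, 5, 8); md <- c(-2, 1, 6, 4)
  ds <- toy_dataset(mx = mx, md = md, groups = groups)
  rp <- summarize_reports(ds)
  row <- rp$displacement[rp$displacement$subgroup == "MMA" &
                           rp$displacement$segment == "maxilla", ]
  expect_equal(row$median, median(mx[2:4]))
  expect_equal(row$iqr, IQR(mx[2:4]))
  expect_equal(row$n, 3)
  # 18 threshold cells when all 18 ROCs are supplied
  ds2 <- toy_dataset(mx = c(3, 7), md = c(2, 6),
                     deltas = list(A = make_delta(rep(0, 25)),
                                   B = make_delta(rep(150, 25))))
  thr <- run_threshold_analysis(ds2)
  rp2 <- summarize_reports(ds2, thr$rocs)
  expect_equal(nrow(rp2$thresholds), 18L)
})

test_that("an empty subgroup yields an NA row plus warning", {
  ds <- toy_dataset(mx = c(3, 2), md = c(1, 1))
  expect_warning(rp <- summarize_reports(ds), "empty subgroup")
  row <- rp$displacement[rp$displacement$subgroup == "MMA-MX>=5" &
                           rp$displacement$segment == "maxilla", ]
  expect_equal(row$n, 0)
  expect_true(is.na(row$mean))
})
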