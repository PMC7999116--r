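# Subgroup comparisons (ANOVA, Games-Howell, Mann-Whitney) and the
# ROC / Youden-index displacement-threshold analysis.

#' Assemble the long slice dataset
#'
#' Joins per-case delta tables with the per-patient bone-displacement
#' records into one long table with a row per valid slab (invalid slabs are
#' omitted but counted in the `exclusions` attribute).
#'
#' @param cohort_deltas named list of `ua_delta` tables, one per patient.
#' @param displacement_records `data.frame` of stacked
#'   [compute_bone_displacement()] rows covering, for every patient, both
#'   the maxilla and the mandible.
#' @param groups named character vector mapping patient id to surgical group
#'   (`"MMA"` or `"MAMS"`).
#' @return list of class `ua_slice_dataset`: `slices` (patient, group,
#'   maxilla_ap, mandible_ap, slab, region, delta_area_pct), `cases`
#'   (patient, group, maxilla_ap, mandible_ap, delta_volume_pct) and an
#'   `exclusions` attribute.
#' @export
build_slice_dataset <- function(cohort_deltas, displacement_records,
                                groups) {
  recs <- as.data.frame(displacement_records)
  slices <- list()
  cases <- list()
  excluded <- 0L
  for (pid in names(cohort_deltas)) {
    d <- cohort_deltas[[pid]]
    ap <- vapply(c("maxilla", "mandible"), function(seg) {
      row <- recs[recs$patient == pid & recs$segment == seg, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("patient ", pid, " is missing a displacement record for the ",
             seg)
      row$ap
    }, numeric(1))
    ok <- d$valid
    excluded <- excluded + sum(!ok)
    slices[[pid]] <- data.frame(
      patient = pid, group = unname(groups[pid]),
      maxilla_ap = ap[["maxilla"]], mandible_ap = ap[["mandible"]],
      slab = d$slab[ok], region = d$region[ok],
      delta_area_pct = d$delta_area_pct[ok],
      stringsAsFactors = FALSE)
    cases[[pid]] <- data.frame(
      patient = pid, group = unname(groups[pid]),
      maxilla_ap = ap[["maxilla"]], mandible_ap = ap[["mandible"]],
      delta_volume_pct = attr(d, "delta_volume_pct"),
      stringsAsFactors = FALSE)
  }
  out <- list(slices = do.call(rbind, c(slices, make.row.names = FALSE)),
              cases = do.call(rbind, c(cases, make.row.names = FALSE)))
  attr(out, "exclusions") <- excluded
  class(out) <- "ua_slice_dataset"
  out
}

#' @export
print.ua_slice_dataset <- function(x, ...) {
  cat(sprintf("<ua_slice_dataset> %d slices from %d patients (%d excluded)\n",
              nrow(x$slices), nrow(x$cases), attr(x, "exclusions")))
  invisible(x)
}

segment_ap_column <- function(segment) {
  segment <- match.arg(segment, c("maxilla", "mandible"))
  paste0(segment, "_ap")
}

#' Split slices into the surgical comparison subgroups
#'
#' For a bone segment, returns the three slice sets compared in the
#' subgroup analysis: all MAMS slices, MMA slices from patients with the
#' segment's AP displacement below the cut, and MMA slices at or above it
#' (the boundary value belongs to the ">= cut" subgroup).
#'
#' @param ds a `ua_slice_dataset`.
#' @param segment `"maxilla"` or `"mandible"`.
#' @param cut AP displacement cut in mm (default 5).
#' @param region optional region filter.
#' @return named list `MAMS`, `MMA_below`, `MMA_at_or_above` of slice
#'   data.frames; empty subgroups are flagged via the `empty` attribute.
#' @export
subgroup_split <- function(ds, segment, cut = 5.0, region = NULL) {
  col <- segment_ap_column(segment)
  s <- ds$slices
  if (!is.null(region)) s <- s[s$region == region, , drop = FALSE]
  out <- list(
    MAMS = s[s$group == "MAMS", , drop = FALSE],
    MMA_below = s[s$group == "MMA" & s[[col]] < cut, , drop = FALSE],
    MMA_at_or_above = s[s$group == "MMA" & s[[col]] >= cut, , drop = FALSE])
  empty <- names(out)[vapply(out, nrow, integer(1)) == 0L]
  if (length(empty))
    warning("empty subgroup(s): ", paste(empty, collapse = ", "))
  attr(out, "empty") <- empty
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way F test computed from the between/within
#' sum-of-squares decomposition.
#'
#' @param groups list (>= 2) of numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0)
    stop("zero within-group variance in all groups; F is undefined")
  F_ <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F_, p = stats::pf(F_, k - 1, N - k, lower.tail = FALSE),
       df_between = k - 1, df_within = N - k)
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons robust to unequal variances and sample sizes:
#' `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with Welch-Satterthwaite
#' degrees of freedom; the p value comes from the studentized-range
#' distribution with `q = t * sqrt(2)` and `k` = number of groups.
#' Confidence intervals use the corresponding studentized-range quantile.
#'
#' @param groups named list (>= 2) of numeric vectors, each of length >= 3.
#' @param conf.level confidence level for the intervals.
#' @return `data.frame`: `group1`, `group2`, `diff`, `se`, `df`, `t`, `p`,
#'   `conf.low`, `conf.high`.
#' @export
games_howell <- function(groups, conf.level = 0.95) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 3L))
    stop("Games-Howell requires n >= 3 in every group")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    se <- sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    diff <- unname(m[i] - m[j])
    t_ <- abs(diff) / se
    p <- stats::ptukey(t_ * sqrt(2), nmeans = k, df = unname(df),
                       lower.tail = FALSE)
    qcrit <- stats::qtukey(conf.level, nmeans = k, df = unname(df)) / sqrt(2)
    c(diff = diff, se = unname(se), df = unname(df), t = unname(t_),
      p = unname(p), conf.low = unname(diff - qcrit * se),
      conf.high = unname(diff + qcrit * se))
  })
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             t(out), stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample Mann-Whitney test
#'
#' Two-tailed; exact p when both samples are small (min n <= 8) and
#' tie-free, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic for `x`) and `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' ROC analysis of the displacement threshold
#'
#' Unit of analysis is the slice: a slice is positive when its area change
#' meets the cutoff (`delta_area_pct >= cutoff_pct`), and its score is the
#' AP displacement of the chosen bone segment of its patient (repeated
#' across that patient's slices). Candidate thresholds are midpoints of
#' consecutive sorted unique scores; a slice is called positive when its
#' score is at or above the threshold. AUC is the trapezoidal area, which
#' equals the Mann-Whitney U statistic scaled by `1 / (n_pos * n_neg)`.
#'
#' @param ds a `ua_slice_dataset`.
#' @param segment `"maxilla"` or `"mandible"` (score source).
#' @param region pharyngeal subregion to analyse, or `NULL` for all slices.
#' @param cutoff_pct positivity cutoff on the area change (30, 50 or 100 in
#'   the standard analysis).
#' @param group restrict to one surgical group (`"MMA"`/`"MAMS"`); default
#'   pools all patients.
#' @param patient_average average slices within patient before the ROC
#'   (sensitivity-analysis mode; default off, matching the slice-level
#'   design).
#' @return object of class `ua_roc`: list with `points` (threshold, sens,
#'   spec, J), `auc`, `n_pos`, `n_neg`, `primary`, `secondaries`, plus the
#'   analysis descriptors.
#' @export
roc_threshold <- function(ds, segment, region = NULL, cutoff_pct = 50,
                          group = NULL, patient_average = FALSE) {
  col <- segment_ap_column(segment)
  s <- ds$slices
  if (!is.null(region)) s <- s[s$region == region, , drop = FALSE]
  if (!is.null(group)) s <- s[s$group == group, , drop = FALSE]
  if (patient_average) {
    agg <- stats::aggregate(delta_area_pct ~ patient, data = s, FUN = mean)
    ap <- s[!duplicated(s$patient), c("patient", col)]
    s <- merge(agg, ap, by = "patient")
  }
  labels <- s$delta_area_pct >= cutoff_pct
  scores <- s[[col]]
  roc_from_scores(scores, labels, segment = segment, region = region,
                  cutoff_pct = cutoff_pct)
}

# Core ROC construction from scores and binary labels.
roc_from_scores <- function(scores, labels, segment = NA, region = NA,
                            cutoff_pct = NA, separation = FALSE) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes; have ", n_pos, " positive and ",
         n_neg, " negative slices")
  u <- sort(unique(scores))
  thr <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else u
  sens <- vapply(thr, function(t_) mean(scores[labels] >= t_), numeric(1))
  spec <- vapply(thr, function(t_) mean(scores[!labels] < t_), numeric(1))
  J <- sens + spec - 1

  # trapezoidal AUC over the full curve (extreme operating points included)
  all_thr <- c(-Inf, thr, Inf)
  tpr <- vapply(all_thr, function(t_) mean(scores[labels] >= t_), numeric(1))
  fpr <- vapply(all_thr, function(t_) mean(scores[!labels] >= t_), numeric(1))
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)

  roc <- structure(list(
    points = data.frame(threshold = thr, sens = sens, spec = spec, J = J),
    auc = auc, n_pos = n_pos, n_neg = n_neg,
    segment = segment, region = if (is.null(region)) "all" else region,
    cutoff_pct = cutoff_pct, separation = separation),
    class = "ua_roc")
  peaks <- youden_peaks(roc)
  roc$primary <- peaks$primary
  roc$secondaries <- peaks$secondaries
  roc
}

#' @export
print.ua_roc <- function(x, ...) {
  cat(sprintf(
    "<ua_roc> %s / %s / +%s%%: AUC %.3f, threshold %s (J = %.3f), %d+/%d-\n",
    x$segment, x$region, format(x$cutoff_pct), x$auc,
    format_threshold(x), max(x$points$J), x$n_pos, x$n_neg))
  invisible(x)
}

#' Primary and secondary Youden-index peaks
#'
#' The primary threshold maximises `J = sens + spec - 1` (ties broken
#' toward the smaller displacement, the clinically conservative choice).
#' Secondary thresholds are other local maxima of J over the candidate
#' thresholds whose J lies within `peak_window` of the maximum - the
#' dual-peak pattern that signals a possible double threshold.
#'
#' @param roc a `ua_roc`.
#' @param peak_window J tolerance below the maximum for reporting a
#'   secondary peak (default 0.05).
#' @return list with `primary` (list `threshold`, `J`) and `secondaries`
#'   (data.frame `threshold`, `J`, possibly empty).
#' @export
youden_peaks <- function(roc, peak_window = 0.05) {
  pts <- roc$points[order(roc$points$threshold), ]
  J <- pts$J
  thr <- pts$threshold
  jmax <- max(J)
  primary_i <- which(J == jmax)[1]          # smallest threshold on ties

  # local maxima over the candidate grid (plateaus collapse to their start)
  n <- length(J)
  is_peak <- rep(FALSE, n)
  for (i in seq_len(n)) {
    left <- if (i > 1) J[i - 1] else -Inf
    right <- if (i < n) J[i + 1] else -Inf
    is_peak[i] <- J[i] >= left && J[i] >= right &&
      !(i > 1 && J[i] == J[i - 1])
  }
  sec <- which(is_peak & J >= jmax - peak_window)
  sec <- setdiff(sec, primary_i)
  list(primary = list(threshold = thr[primary_i], J = jmax),
       secondaries = data.frame(threshold = thr[sec], J = J[sec]))
}

# "(secondary) primary" presentation used in the threshold report
format_threshold <- function(roc, digits = 1) {
  p <- format(round(roc$primary$threshold, digits), nsmall = digits)
  if (nrow(roc$secondaries) == 0L) return(p)
  s <- paste(sprintf("(%s)", format(round(roc$secondaries$threshold, digits),
                                    nsmall = digits)), collapse = " ")
  paste(s, p)
}

#' Multivariate ROC from a combined-displacement logistic model
#'
#' Fits a binomial logistic regression of slice positivity on the maxillary
#' and mandibular AP displacements and computes the ROC on the fitted
#' probabilities. Complete separation is flagged; the ROC is still computed
#' on the (separating) fitted score.
#'
#' @param ds a `ua_slice_dataset`.
#' @param region pharyngeal subregion, or `NULL` for all slices.
#' @param cutoff_pct positivity cutoff (default 30, the cutoff whose
#'   positive-to-negative slice ratio is closest to 1).
#' @return a `ua_roc` with extra fields `coefficients` and `separation`.
#' @export
logistic_combined_roc <- function(ds, region = NULL, cutoff_pct = 30) {
  s <- ds$slices
  if (!is.null(region)) s <- s[s$region == region, , drop = FALSE]
  s$label <- as.integer(s$delta_area_pct >= cutoff_pct)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ maxilla_ap + mandible_ap, data = s,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  roc <- roc_from_scores(stats::fitted(fit), s$label == 1L,
                         segment = "combined", region = region,
                         cutoff_pct = cutoff_pct, separation = sep)
  roc$coefficients <- stats::coef(fit)
  roc
}

#' Summary report bundle
#'
#' Builds the three standard report tables: descriptive statistics of the
#' AP displacements by subgroup; descriptive statistics of the slice area
#' changes by region and subgroup; and the threshold table (primary and
#' secondary thresholds, Youden J, AUC) for every segment x cutoff x
#' region combination present in `rocs`.
#'
#' @param ds a `ua_slice_dataset`.
#' @param rocs list of `ua_roc` objects (e.g. from [run_threshold_analysis()]).
#' @param cut subgroup AP cut in mm.
#' @return list of class `ua_reports` with `displacement` (per subgroup and
#'   segment: n, max, min, mean, sd, median, iqr), `delta_area` (per
#'   subgroup and region: mean, sd, min, max, n_patients) and `thresholds`.
#' @export
summarize_reports <- function(ds, rocs = list(), cut = 5.0) {
  cases <- ds$cases
  subgroups <- list(
    MAMS = cases$group == "MAMS",
    MMA = cases$group == "MMA",
    `MMA-MX<5` = cases$group == "MMA" & cases$maxilla_ap < cut,
    `MMA-MX>=5` = cases$group == "MMA" & cases$maxilla_ap >= cut,
    `MMA-MD<5` = cases$group == "MMA" & cases$mandible_ap < cut,
    `MMA-MD>=5` = cases$group == "MMA" & cases$mandible_ap >= cut)

  stat_row <- function(x) {
    if (length(x) == 0L)
      return(c(n = 0, max = NA, min = NA, mean = NA, sd = NA,
               median = NA, iqr = NA))
    c(n = length(x), max = max(x), min = min(x), mean = mean(x),
      sd = stats::sd(x), median = stats::median(x), iqr = stats::IQR(x))
  }
  disp <- do.call(rbind, lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]]
    if (!any(sel))
      warning("empty subgroup '", nm, "' in the displacement table")
    rbind(
      data.frame(subgroup = nm, segment = "maxilla",
                 t(stat_row(cases$maxilla_ap[sel]))),
      data.frame(subgroup = nm, segment = "mandible",
                 t(stat_row(cases$mandible_ap[sel]))))
  }))

  slices <- ds$slices
  da <- do.call(rbind, lapply(names(subgroups), function(nm) {
    pids <- cases$patient[subgroups[[nm]]]
    ss <- slices[slices$patient %in% pids, , drop = FALSE]
    do.call(rbind, lapply(names(REGION_COUNTS), function(rg) {
      x <- ss$delta_area_pct[ss$region == rg]
      data.frame(subgroup = nm, region = rg,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 n_patients = length(pids))
    }))
  }))

  thr <- do.call(rbind, lapply(rocs, function(r) {
    data.frame(segment = r$segment, cutoff_pct = r$cutoff_pct,
               region = r$region,
               threshold_mm = r$primary$threshold,
               threshold_label = format_threshold(r),
               youden = r$primary$J, auc = r$auc,
               n_pos = r$n_pos, n_neg = r$n_neg,
               stringsAsFactors = FALSE)
  }))

  structure(list(displacement = disp, delta_area = da, thresholds = thr),
            class = "ua_reports")
}
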