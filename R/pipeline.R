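# Orchestration: configuration, cohort simulation and analysis, report
# output, and the reference-table verifier.

#' Pipeline configuration
#'
#' Central defaults for a full cohort run. The `segmentation_hounsfield`
#' block records, for provenance only, the CT segmentation windows the
#' source models came from (hard tissue +646.19 (+/- 24.57) to +1000 HU;
#' airway -1000 to 299.39 (+/- 17.2) HU); nothing in the pipeline consumes
#' it.
#'
#' @param pixel_mm raster step for projected areas (mm).
#' @param icp [icp_params()] used for airway alignment (kept lighter than
#'   the module defaults: with a landmark initialisation the refinement
#'   converges in a few iterations and does not need 5000 samples).
#' @param roc_cutoffs area-change cutoffs (percent) for the ROC analysis.
#' @param subgroup_cut AP displacement cut (mm) between minor and major
#'   repositioning.
#' @param seed master seed.
#' @param segment_icp refine segment fits with ICP when segment meshes are
#'   available (landmark-only by default).
#' @return list of class `ua_config`.
#' @export
ua_config <- function(pixel_mm = 0.1,
                      icp = icp_params(max_iterations = 25L,
                                       tolerance = 1e-4,
                                       samples = 1200L),
                      roc_cutoffs = c(30, 50, 100),
                      subgroup_cut = 5.0,
                      seed = 1L,
                      segment_icp = FALSE) {
  stopifnot(pixel_mm > 0, all(roc_cutoffs > 0))
  structure(list(
    pixel_mm = pixel_mm, icp = icp, roc_cutoffs = roc_cutoffs,
    subgroup_cut = subgroup_cut, seed = as.integer(seed),
    segment_icp = segment_icp,
    segmentation_hounsfield = list(
      hard_tissue = c(646.19, 1000), hard_tissue_sd = 24.57,
      airway = c(-1000, 299.39), airway_sd = 17.2)),
    class = "ua_config")
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  icp <- do.call(icp_params, y$icp %||% list())
  keep <- setdiff(names(formals(ua_config)), "icp")
  args <- y[intersect(names(y), keep)]
  do.call(ua_config, c(args, list(icp = icp)))
}

#' @rdname read_config_yaml
#' @param config a [ua_config()].
#' @export
write_config_yaml <- function(config, path) {
  out <- unclass(config)
  out$icp <- unclass(out$icp)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one case
#'
#' Registration (bone displacement for both segments, airway alignment)
#' followed by the slab metrics.
#'
#' @param case a `ua_case` (or equivalent list with `pre` / `post`).
#' @param config a [ua_config()].
#' @return list with `displacement` (two-row data.frame) and `delta`
#'   (`ua_delta`).
#' @export
analyze_case <- function(case, config = ua_config()) {
  disp <- rbind(
    compute_bone_displacement(case$pre, case$post, "maxilla",
                              icp = config$segment_icp, params = config$icp),
    compute_bone_displacement(case$pre, case$post, "mandible",
                              icp = config$segment_icp, params = config$icp))
  aligned <- align_airway_models(case$pre$meshes$airway,
                                 case$post$meshes$airway,
                                 case$pre$landmarks$airway,
                                 case$post$landmarks$airway,
                                 params = config$icp)
  delta <- case_metrics(case$pre$meshes$airway, aligned,
                        pixel = config$pixel_mm)
  list(displacement = disp, delta = delta,
       alignment_rms = attr(aligned, "rms"))
}

#' Run the threshold ROC battery
#'
#' One ROC per segment x cutoff x region (2 x 3 x 3 = 18 analyses by
#' default), plus the combined-displacement logistic ROC per region at the
#' cutoff whose class balance supports it.
#'
#' @param ds a `ua_slice_dataset`.
#' @param cutoffs area-change cutoffs (percent).
#' @param logistic_cutoff cutoff for the multivariate logistic ROC.
#' @return list with `rocs` (list of `ua_roc`) and `logistic` (list of
#'   per-region `ua_roc`).
#' @export
run_threshold_analysis <- function(ds, cutoffs = c(30, 50, 100),
                                   logistic_cutoff = 30) {
  rocs <- list()
  for (seg in c("maxilla", "mandible"))
    for (co in cutoffs)
      for (rg in names(REGION_COUNTS)) {
        key <- paste(seg, co, rg, sep = "_")
        rocs[[key]] <- tryCatch(
          roc_threshold(ds, seg, region = rg, cutoff_pct = co),
          error = function(e) {
            warning("ROC ", key, " skipped: ", conditionMessage(e))
            NULL
          })
      }
  rocs <- Filter(Negate(is.null), rocs)
  logistic <- lapply(stats::setNames(nm = names(REGION_COUNTS)),
                     function(rg) tryCatch(
                       logistic_combined_roc(ds, region = rg,
                                             cutoff_pct = logistic_cutoff),
                       error = function(e) NULL))
  list(rocs = rocs, logistic = Filter(Negate(is.null), logistic))
}

#' Analyse a full cohort
#'
#' Runs every case through registration and slab metrics, assembles the
#' slice dataset, and produces the subgroup statistics (ANOVA +
#' Games-Howell per segment and region, Mann-Whitney on the volume deltas)
#' and the ROC threshold battery. A case that fails is skipped with a
#' warning and listed in `failures`; the run continues.
#'
#' @param cohort a `ua_cohort` (or a directory written by [write_cohort()]).
#' @param config a [ua_config()].
#' @return list of class `ua_analysis`: `dataset`, `records`, `deltas`,
#'   `anova`, `games_howell`, `mann_whitney`, `rocs`, `logistic`,
#'   `reports`, `failures`.
#' @export
analyze_cohort <- function(cohort, config = ua_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  deltas <- list()
  records <- list()
  failures <- character(0)
  for (pid in names(cohort$cases)) {
    res <- tryCatch(analyze_case(cohort$cases[[pid]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("case ", pid, " failed: ", conditionMessage(res))
      failures <- c(failures, pid)
      next
    }
    deltas[[pid]] <- res$delta
    records[[pid]] <- res$displacement
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  groups <- stats::setNames(cohort$manifest$group, cohort$manifest$patient)
  ds <- build_slice_dataset(deltas, records, groups)

  cut <- config$subgroup_cut
  anova_res <- list(); gh_res <- list()
  for (seg in c("maxilla", "mandible"))
    for (rg in names(REGION_COUNTS)) {
      grp <- subgroup_split(ds, seg, cut = cut, region = rg)
      grp <- grp[vapply(grp, nrow, integer(1)) >= 3L]
      key <- paste(seg, rg, sep = "_")
      if (length(grp) >= 2L) {
        vals <- lapply(grp, `[[`, "delta_area_pct")
        anova_res[[key]] <- tryCatch(anova_oneway(vals),
                                     error = function(e) NULL)
        gh_res[[key]] <- tryCatch(games_howell(vals),
                                  error = function(e) NULL)
      }
    }

  mw_res <- list()
  for (seg in c("maxilla", "mandible")) {
    col <- segment_ap_column(seg)
    cases <- ds$cases
    mams <- cases$delta_volume_pct[cases$group == "MAMS"]
    for (side in c("below", "at_or_above")) {
      sel <- cases$group == "MMA" &
        (if (side == "below") cases[[col]] < cut else cases[[col]] >= cut)
      mma <- cases$delta_volume_pct[sel]
      key <- paste(seg, side, sep = "_")
      mw_res[[key]] <- if (length(mma) >= 1L && length(mams) >= 1L)
        mann_whitney(mams, mma) else NULL
    }
  }

  thr <- run_threshold_analysis(ds, cutoffs = config$roc_cutoffs)
  reports <- summarize_reports(ds, thr$rocs, cut = cut)
  structure(list(dataset = ds, records = records, deltas = deltas,
                 anova = anova_res, games_howell = gh_res,
                 mann_whitney = mw_res, rocs = thr$rocs,
                 logistic = thr$logistic, reports = reports,
                 failures = failures, config = config),
            class = "ua_analysis")
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Unreadable cases are skipped with a warning so one corrupt file does not
#' abort a cohort run.
#'
#' @param dir cohort directory.
#' @return a `ua_cohort` (without ground truth).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cases <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient[i]
    cdir <- file.path(dir, pid)
    cs <- tryCatch({
      pre_lm <- read_case_landmarks(file.path(cdir, "landmarks_pre.json"))
      post_lm <- read_case_landmarks(file.path(cdir, "landmarks_post.json"))
      list(pre = list(patient = pid, group = manifest$group[i],
                      landmarks = pre_lm,
                      meshes = list(airway = read_stl(
                        file.path(cdir, "airway_pre.stl")))),
           post = list(patient = pid, group = manifest$group[i],
                       landmarks = post_lm,
                       meshes = list(airway = read_stl(
                         file.path(cdir, "airway_post.stl")))))
    }, error = function(e) {
      warning("case ", pid, " unreadable, skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(cs)) cases[[pid]] <- cs
  }
  structure(list(cases = cases,
                 manifest = manifest[manifest$patient %in% names(cases), ],
                 seed = NA_integer_),
            class = "ua_cohort")
}

#' Write the report bundle as CSV/JSON
#'
#' @param analysis a `ua_analysis` from [analyze_cohort()].
#' @param dir output directory.
#' @export
write_reports <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- analysis$reports
  utils::write.csv(rp$displacement,
                   file.path(dir, "table_displacement.csv"),
                   row.names = FALSE)
  utils::write.csv(rp$delta_area, file.path(dir, "table_delta_area.csv"),
                   row.names = FALSE)
  utils::write.csv(rp$thresholds, file.path(dir, "table_thresholds.csv"),
                   row.names = FALSE)
  for (key in names(analysis$rocs)) {
    r <- analysis$rocs[[key]]
    utils::write.csv(r$points,
                     file.path(dir, paste0("roc_", key, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(analysis$records, file.path(dir, "displacements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(failures = analysis$failures,
         exclusions = attr(analysis$dataset, "exclusions")),
    file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Recompute the packaged reference threshold table checks
#'
#' Recomputes, from the packaged reference table of ROC threshold points
#' (segment x cutoff x region) and from a freshly generated synthetic
#' model, the structural quantities the method fixes: the mean of the six
#' 50% thresholds, the range of the maxillary threshold column, and the
#' 25-slab / 5-9-11 partition layout.
#'
#' @param fixture path to the reference CSV; defaults to the packaged one.
#' @return `data.frame` of class `ua_verification`: `check`, `value`,
#'   `expected`, `pass`.
#' @export
verify_targets <- function(fixture = NULL) {
  if (is.null(fixture))
    fixture <- system.file("extdata", "roc_threshold_reference.csv",
                           package = "uamorph")
  if (!nzchar(fixture) || !file.exists(fixture))
    stop("reference threshold table not found",
         if (!is.null(fixture) && nzchar(fixture)) paste0(": ", fixture))
  ref <- utils::read.csv(fixture, stringsAsFactors = FALSE)
  needed <- c("segment", "cutoff_pct", "region", "threshold_mm")
  if (!all(needed %in% names(ref)))
    stop("reference table lacks columns: ",
         paste(setdiff(needed, names(ref)), collapse = ", "))

  mean50 <- round(mean(ref$threshold_mm[ref$cutoff_pct == 50]), 2)
  mx <- ref$threshold_mm[ref$segment == "maxilla"]
  mesh <- generate_airway(airway_profile(n_theta = 24L, n_rings = 25L),
                          seed = 1L)
  part <- partition_airway(mesh)
  counts <- table(factor(part$region, levels = names(REGION_COUNTS)))

  out <- data.frame(
    check = c("mean 50% threshold (mm)",
              "maxilla threshold min (mm)", "maxilla threshold max (mm)",
              "partition slab count", "nasopharynx slabs",
              "oropharynx slabs", "hypopharynx slabs"),
    value = c(mean50, min(mx), max(mx), nrow(part),
              counts[["nasopharynx"]], counts[["oropharynx"]],
              counts[["hypopharynx"]]),
    expected = c(5.53, 4.8, 7.0, 25, 5, 9, 11))
  out$pass <- abs(out$value - out$expected) < 1e-9
  class(out) <- c("ua_verification", "data.frame")
  out
}
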