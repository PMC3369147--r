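## Cohort orchestration: synthetic cohort -> per-read 2D measures ->
## reader/read averaging -> 3D coverage -> group descriptives, reliability
## and the measure-by-coverage regression grid.

measure_names <- c("extrusion_index", "crossover_ratio", "acetabular_angle",
                   "acetabular_index", "lcea", "posterior_wall_distance")
coverage_names <- c("TC", "Ant", "Post", "ALC", "AMC", "PLC", "PMC")

#' Run the full analysis on a synthetic cohort
#'
#' Generates the cohort, computes the six radiographic measures for every
#' reader/read, averages them to one value per subject, runs the 3D
#' coverage pipeline per subject, and assembles group descriptives with
#' pooled-variance t-tests, intra-/inter-observer ICCs and the regression
#' grid of each 2D measure against each coverage outcome (pooled groups).
#'
#' @param spec a `cohort_spec`.
#' @param include_3d run the 3D coverage chain (set `FALSE` for fast
#'   landmark-only simulations; coverage columns and the regression grid
#'   are then omitted).
#' @param rim_samples rim sampling density for the coverage chain.
#' @param progress print per-subject progress lines.
#' @return object of class `cohort_result`: list with `subjects` (tibble of
#'   averaged measures and coverage per subject), `measures_by_read`,
#'   `descriptives`, `icc_table`, `regressions`, and the `spec`.
#' @export
run_cohort <- function(spec, include_3d = TRUE, rim_samples = 512,
                       progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_controls == 0 || spec$n_patients == 0)
    warning("one group is empty: group comparisons are skipped and the ",
            "regression grid uses the remaining subjects only")
  cohort <- generate_cohort(spec, include_mesh = include_3d)

  ## 2D measures for every reader/read
  per_read <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    reads <- cohort$landmarks[[i]]
    dplyr::bind_cols(
      tibble::tibble(subject = cohort$subject[i], group = cohort$group[i],
                     reader = reads$reader, read = reads$read),
      dplyr::bind_rows(lapply(reads$landmarks, measure_radiograph)))
  }))

  ## reader/read averaging to a single value per subject
  avg <- per_read |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(measure_names),
                                   ~ mean(.x, na.rm = TRUE)),
                     crossover_present = any(is.finite(.data$crossover_ratio)),
                     .groups = "drop") |>
    dplyr::mutate(crossover_ratio = ifelse(is.nan(.data$crossover_ratio),
                                           NA_real_, .data$crossover_ratio))

  ## 3D coverage per subject
  if (include_3d) {
    covs <- lapply(seq_len(nrow(cohort)), function(i) {
      if (progress)
        message(sprintf("[coverage] subject %d/%d (%s)", i, nrow(cohort),
                        cohort$group[i]))
      hc <- tryCatch(
        head_coverage(cohort$mesh[[i]], cohort$rim[[i]],
                      rim_samples = rim_samples),
        error = function(e)
          stop(sprintf("subject %d, stage head_coverage: %s", i,
                       conditionMessage(e))))
      r <- hc$report
      setNames(r$percent[match(c("TC", "Ant", "Post", "AL", "AM", "PL", "PM"),
                               r$region)], coverage_names)
    })
    cov_tbl <- dplyr::bind_cols(subject = cohort$subject,
                                tibble::as_tibble(do.call(rbind, covs)))
    subjects <- dplyr::left_join(avg, cov_tbl, by = "subject")
  } else subjects <- avg

  subjects <- dplyr::left_join(
    subjects,
    dplyr::select(cohort, "subject", "crossover_expected", "expected_tc",
                  "true_version"),
    by = "subject")

  res <- structure(list(subjects = subjects, measures_by_read = per_read,
                        spec = spec), class = "cohort_result")
  res$descriptives <- cohort_descriptives(res)
  res$icc_table <- cohort_icc_table(res)
  if (include_3d) res$regressions <- cohort_regressions(res)
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d controls, %d patients\n",
              sum(x$subjects$group == "control"),
              sum(x$subjects$group == "patient")))
  print(as.data.frame(x$descriptives), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Group descriptives and t-tests for the averaged 2D measures
#'
#' One row per measure with group means and SDs and the pooled-variance
#' two-sided p-value.  The crossover ratio is reported as `NA` for a group
#' in which no subject shows a crossover sign, and the group comparison is
#' skipped when either group has none.
#'
#' @param result a `cohort_result`.
#' @return tibble.
#' @export
cohort_descriptives <- function(result) {
  s <- result$subjects
  rows <- lapply(measure_names, function(m) {
    a <- s[[m]][s$group == "control"]
    b <- s[[m]][s$group == "patient"]
    if (m == "crossover_ratio") {
      ## mirror the reporting convention: not quantified for a group
      ## without any crossover sign
      if (!any(is.finite(a))) a <- numeric(0)
      if (!any(is.finite(b))) b <- numeric(0)
    }
    ok_t <- sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2
    tt <- if (ok_t) student_t(a, b) else NULL
    tibble::tibble(
      measure = m,
      control_mean = if (length(a)) mean(a, na.rm = TRUE) else NA_real_,
      control_sd = if (length(a)) sd(a[is.finite(a)]) else NA_real_,
      patient_mean = if (length(b)) mean(b, na.rm = TRUE) else NA_real_,
      patient_sd = if (length(b)) sd(b[is.finite(b)]) else NA_real_,
      t = if (ok_t) tt$t else NA_real_,
      p = if (ok_t) tt$p_two_sided else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Intra- and inter-observer ICC table
#'
#' Per measure: intra-observer ICC per reader (read 1 vs read 2) and
#' inter-observer ICC per read (reader 1 vs reader 2), each ICC(2,1).
#' The crossover ratio uses the retroversion (patient) group only, and
#' only subjects with the crossover present in every involved cell.
#'
#' @param result a `cohort_result`.
#' @return tibble with columns `measure`, `intra_reader1`, `intra_reader2`,
#'   `inter_read1`, `inter_read2` (NA where undefined or not estimable).
#' @export
cohort_icc_table <- function(result) {
  pr <- result$measures_by_read
  spec <- result$spec
  get_matrix <- function(m, fix, fix_val, vary) {
    d <- pr[pr[[fix]] == fix_val, c("subject", "group", vary, m)]
    if (m == "crossover_ratio") d <- d[d$group == "patient", ]
    w <- tidyr::pivot_wider(d, id_cols = "subject",
                            names_from = dplyr::all_of(vary),
                            values_from = dplyr::all_of(m))
    mat <- as.matrix(w[, -1])
    mat[complete.cases(mat), , drop = FALSE]
  }
  safe_icc <- function(mat) {
    if (nrow(mat) < 5 || ncol(mat) < 2) return(NA_real_)
    tryCatch(icc(mat)$icc, error = function(e) NA_real_)
  }
  rows <- lapply(measure_names, function(m) {
    out <- list(measure = m)
    for (r in seq_len(spec$n_readers))
      out[[paste0("intra_reader", r)]] <-
        safe_icc(get_matrix(m, "reader", r, "read"))
    for (t in seq_len(spec$n_reads))
      out[[paste0("inter_read", t)]] <-
        safe_icc(get_matrix(m, "read", t, "reader"))
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Regression grid: 2D measures against 3D coverage
#'
#' Simple linear regression of each coverage outcome on each averaged 2D
#' measure, control and patient groups pooled, with the Pearson r and
#' two-sided p per cell.
#'
#' @param result a `cohort_result` run with `include_3d = TRUE`.
#' @return tibble with one row per (measure, coverage) pair: `r`, `slope`,
#'   `p`, `n`, `significant` (p < 0.05).
#' @export
cohort_regressions <- function(result) {
  s <- result$subjects
  if (!all(coverage_names %in% names(s)))
    stop("run_cohort(include_3d = TRUE) is required for the regression grid")
  grid <- tidyr::expand_grid(measure = measure_names,
                             coverage = coverage_names)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$measure[i]; cv <- grid$coverage[i]
    x <- s[[m]]; y <- s[[cv]]
    ok <- sum(is.finite(x) & is.finite(y)) >= 3 &&
      sd(x[is.finite(x) & is.finite(y)]) > 0
    fit <- if (ok) simple_regression(x, y) else NULL
    tibble::tibble(measure = m, coverage = cv,
                   r = if (ok) fit$pearson_r else NA_real_,
                   slope = if (ok) fit$slope else NA_real_,
                   p = if (ok) fit$p else NA_real_,
                   n = if (ok) fit$n else NA_integer_)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = is.finite(.data$p) & .data$p < 0.05)
}

#' @export
tidy.cohort_result <- function(x, ...) x$descriptives

#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(n_controls = sum(x$subjects$group == "control"),
                 n_patients = sum(x$subjects$group == "patient"),
                 n_readers = x$spec$n_readers, n_reads = x$spec$n_reads,
                 has_3d = "TC" %in% names(x$subjects))
}

#' Write cohort reports to a directory
#'
#' Emits `table1.csv` (group descriptives), `table2.csv` (ICCs),
#' `table3.csv` (regression grid, when present), `subjects.csv`, and a
#' scatter plot of the posterior wall distance against posterior coverage
#' with its regression line (`figure_pwd_post.pdf`).
#'
#' @param result a `cohort_result`.
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
render_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(result$descriptives, "table1.csv")
  wr(result$icc_table, "table2.csv")
  has_3d <- !is.null(result$regressions)
  if (has_3d) wr(result$regressions, "table3.csv")
  else warning("no 3D coverage in this result: table3 omitted")
  wr(result$subjects, "subjects.csv")
  if (has_3d) {
    path <- file.path(out_dir, "figure_pwd_post.pdf")
    grDevices::pdf(path, width = 6, height = 5)
    print(plot_pwd_regression(result))
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}
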