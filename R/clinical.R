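#' Scheduled visit days of the trial design
#'
#' Eight scheduled assessments between day 1 (baseline) and day 169
#' (week 24, the final efficacy visit).
#'
#' @return integer vector of visit days.
#' @export
defaultVisitSchedule <- function() c(1L, 15L, 29L, 57L, 85L, 113L, 141L, 169L)

#' Last observation carried forward over scheduled visits
#'
#' Completes each patient's trajectory over the full visit schedule: a visit
#' with a missing value takes the most recent observed value. Baseline must
#' be observed. Filled cells are flagged in the `imputed` column.
#'
#' @param visits data.frame `patient_id`, `visit_day`, `mrss` (further value
#'   columns are preserved for observed rows, `NA` for filled rows).
#' @param schedule visit days to complete over (default
#'   [defaultVisitSchedule()]).
#' @return data.frame with one row per patient x scheduled visit: original
#'   columns plus `visit` (index) and `imputed`.
#' @export
applyLocf <- function(visits, schedule = defaultVisitSchedule()) {
  need <- c("patient_id", "visit_day", "mrss")
  .stopIfNot(all(need %in% names(visits)),
             "visits needs patient_id, visit_day, mrss")
  out <- lapply(unique(visits$patient_id), function(pid) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    v <- v[order(v$visit_day), , drop = FALSE]
    base <- v$mrss[v$visit_day == schedule[1L]]
    if (length(base) == 0L || is.na(base[1L]))
      stop("patient ", pid, " has no baseline value")
    res <- data.frame(patient_id = pid, visit = seq_along(schedule),
                      visit_day = schedule, stringsAsFactors = FALSE)
    idx <- match(schedule, v$visit_day)
    res$mrss <- v$mrss[idx]
    res$imputed <- is.na(res$mrss)
    for (i in seq_along(schedule)[-1L])
      if (is.na(res$mrss[i])) res$mrss[i] <- res$mrss[i - 1L]
    res
  })
  do.call(rbind, out)
}

#' Classify a patient as improver by relative mRSS change
#'
#' An improver shows a decrease in mRSS of at least 30 % at the final
#' (post-LOCF) visit relative to baseline. The 30 % boundary is inclusive.
#'
#' @param baseline baseline mRSS (> 0).
#' @param final final-visit mRSS (post-LOCF).
#' @param threshold relative-decrease threshold (default 0.30).
#' @return list `relative_change` ((baseline - final)/baseline) and
#'   `improver` (logical).
#' @export
classifyImprover <- function(baseline, final, threshold = 0.30) {
  .stopIfNot(is.finite(baseline) && baseline > 0,
             "baseline mRSS must be positive")
  .stopIfNot(is.finite(final), "final mRSS must be present")
  rel <- (baseline - final) / baseline
  list(relative_change = rel, improver = rel >= threshold - 1e-12)
}

#' Improver calls for a whole cohort
#'
#' Applies LOCF to the visit table and classifies every patient by the
#' relative mRSS change between baseline and the final scheduled visit.
#'
#' @param visits long-format visit data.frame (`patient_id`, `visit_day`,
#'   `mrss`).
#' @param schedule scheduled visit days.
#' @param threshold relative-decrease threshold (default 0.30).
#' @return data.frame `patient_id`, `baseline`, `final`, `relative_change`,
#'   `improver`.
#' @export
classifyImprovers <- function(visits, schedule = defaultVisitSchedule(),
                              threshold = 0.30) {
  filled <- applyLocf(visits, schedule)
  out <- lapply(unique(filled$patient_id), function(pid) {
    v <- filled[filled$patient_id == pid, ]
    cl <- classifyImprover(v$mrss[1L], v$mrss[nrow(v)], threshold)
    data.frame(patient_id = pid, baseline = v$mrss[1L],
               final = v$mrss[nrow(v)],
               relative_change = cl$relative_change,
               improver = cl$improver, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample t test from summary statistics
#'
#' Student t from per-group mean, SD and n — the form needed when only the
#' published summary table is available. Pooled-variance by default
#' (`df = n1 + n2 - 2`); Welch with Satterthwaite df as an option.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param pooled pooled-variance (default) or Welch.
#' @return list `t`, `df`, `p`, `flag` (`"degenerate"` when both SDs are 0).
#' @export
summaryTwoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE) {
  .stopIfNot(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  .stopIfNot(sd1 >= 0 && sd2 >= 0, "standard deviations must be >= 0")
  diff <- mean1 - mean2
  if (sd1 == 0 && sd2 == 0) {
    if (abs(diff) < .Machine$double.eps^0.5)
      return(list(t = 0, df = n1 + n2 - 2, p = 1, flag = "degenerate"))
    return(list(t = sign(diff) * Inf, df = n1 + n2 - 2,
                p = .Machine$double.xmin, flag = "degenerate"))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- diff / se
  list(t = t, df = df, p = .tPvalue(t, df), flag = "")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7). A table with a zero margin carries no information; p = 1 with a
#' flag.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups, columns =
#'   outcome: `matrix(c(a, c, b, d), 2)`.
#' @return list `p`, `flag`.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  .stopIfNot(all(cells >= 0) && all(cells == round(cells)),
             "cell counts must be non-negative integers")
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(p = 1, flag = "zero margin"))
  list(p = stats::fisher.test(tab)$p.value, flag = "")
}

#' Wilcoxon signed-rank test with exact tied-rank enumeration
#'
#' Zero differences are dropped (classical policy) and tied absolute
#' differences receive midranks. For n <= `exactMax` nonzero differences the
#' two-sided p is exact: the null distribution of the positive-rank sum over
#' all 2^n sign assignments, computed by dynamic programming over doubled
#' ranks. Larger n uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param diffs numeric vector of paired differences.
#' @param exactMax largest n for the exact distribution (default 25).
#' @return list `W` (positive-rank sum), `n` (nonzero differences), `p`,
#'   `method`, `n_zeros_dropped`.
#' @export
wilcoxonSignedRank <- function(diffs, exactMax = 25L) {
  .stopIfNot(is.numeric(diffs) && length(diffs) > 0, "numeric diffs required")
  nz <- diffs[diffs != 0]
  nZeros <- length(diffs) - length(nz)
  if (length(nz) == 0L) stop("no information: all differences are zero")
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= exactMax) {
    r2 <- as.integer(round(2 * r))       # midranks become integers
    total <- sum(r2)
    counts <- c(1, rep(0, total))        # counts[w+1] = #assignments with sum w
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    pLower <- sum(counts[seq_len(w2 + 1L)]) / 2^n
    pUpper <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(pLower, pUpper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tiesTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tiesTab^3 - tiesTab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = W, n = n, p = p, method = method, n_zeros_dropped = nZeros)
}

#' Pool per-arm means into an overall mean
#'
#' Size-weighted mean of arm-level means — the aggregation used when only
#' published per-arm summaries are available.
#'
#' @param means numeric vector of arm means.
#' @param ns integer vector of arm sizes.
#' @return pooled mean.
#' @export
poolArmMeans <- function(means, ns) {
  .stopIfNot(length(means) == length(ns) && all(ns > 0),
             "means and positive sizes must align")
  sum(means * ns) / sum(ns)
}

#' Baseline characteristics summary
#'
#' Per-arm and pooled summaries of a patient table: mean +/- SD and
#' median (range) for numeric variables, count (%) for logical/categorical
#' variables.
#'
#' @param patients data.frame with `patient_id`, `arm` and covariate columns.
#' @param numericVars,categoricalVars variable names to summarize; defaults
#'   to automatic detection by column type.
#' @return list of data.frames `numeric` (arm, variable, n, mean, sd, median,
#'   min, max) and `categorical` (arm, variable, level, count, percent),
#'   each including a pooled `"all"` arm.
#' @export
cohortSummary <- function(patients, numericVars = NULL,
                          categoricalVars = NULL) {
  .stopIfNot(nrow(patients) >= 1L, "at least one patient required")
  skip <- c("patient_id", "arm", "baseline_sample", "post_sample")
  vars <- setdiff(names(patients), skip)
  if (is.null(numericVars))
    numericVars <- vars[vapply(patients[vars], is.numeric, logical(1))]
  if (is.null(categoricalVars))
    categoricalVars <- setdiff(vars, numericVars)
  arms <- c(split(patients, patients$arm), list(all = patients))
  num <- do.call(rbind, lapply(names(arms), function(a) {
    df <- arms[[a]]
    do.call(rbind, lapply(numericVars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      data.frame(arm = a, variable = v, n = length(x),
                 mean = mean(x), sd = stats::sd(x),
                 median = stats::median(x),
                 min = suppressWarnings(min(x)),
                 max = suppressWarnings(max(x)),
                 stringsAsFactors = FALSE)
    }))
  }))
  cat_ <- do.call(rbind, lapply(names(arms), function(a) {
    df <- arms[[a]]
    do.call(rbind, lapply(categoricalVars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      tab <- table(as.character(x))
      data.frame(arm = a, variable = v, level = names(tab),
                 count = as.integer(tab),
                 percent = 100 * as.integer(tab) / length(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(numeric = num, categorical = cat_)
}
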