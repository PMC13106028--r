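#' Phenotyping parameters
#'
#' Bundles every constant used by the eligibility filters, the cleaning
#' rules and the two weight-loss (WL) classifiers. Defaults encode the
#' operational WL definition: a loss of at least 5% of body weight per
#' 12 months (or between study visits) that is not fully regained, or a
#' final BMI below 20 kg/m^2.
#'
#' @param wl_fraction_threshold annualized loss fraction that qualifies a
#'   window (or visit pair) as weight loss. Default 0.05 (5% per year).
#' @param low_bmi_threshold final BMI below this (kg/m^2) is called WL
#'   regardless of trajectory. Default 20.
#' @param slope_p_threshold two-sided p-value below which a fitted window
#'   slope is taken to explain a significant amount of weight variance.
#'   Default 0.05.
#' @param min_window_points minimum records in a window for a slope fit
#'   ("more than two data points"). Default 3.
#' @param lookback_months how far before the last record windows reach.
#'   Default 60.
#' @param window_span_months nominal window width in months. Default 12.
#' @param window_step_months step between window starts. Default 3.
#' @param min_end_before_months windows stop this many months before the
#'   last record; the last two windows shrink to 9 and 6 months. Default 6.
#' @param min_weight_kg records below this weight are implausible. Default 20.
#' @param min_bmi records below this BMI are implausible. Default 10.
#' @param iqr_multiplier per-participant outlier fence in interquartile
#'   ranges beyond the quartiles. Default 3.
#' @param min_age,max_age eligibility age window (max applies in ICD mode).
#'   Defaults 40 and 85.
#' @param min_pack_years smoking exposure floor for spirometric mode.
#'   Default 10.
#' @param max_fev1_fvc FEV1/FVC ratio below this defines airflow
#'   obstruction. Default 0.7.
#' @param icd_prefixes ICD-10 code prefixes defining COPD in EHR mode.
#' @return object of class \code{pheno_params}.
#' @export
pheno_params <- function(wl_fraction_threshold = 0.05,
                         low_bmi_threshold = 20,
                         slope_p_threshold = 0.05,
                         min_window_points = 3,
                         lookback_months = 60,
                         window_span_months = 12,
                         window_step_months = 3,
                         min_end_before_months = 6,
                         min_weight_kg = 20,
                         min_bmi = 10,
                         iqr_multiplier = 3,
                         min_age = 40,
                         max_age = 85,
                         min_pack_years = 10,
                         max_fev1_fvc = 0.7,
                         icd_prefixes = c("J41", "J42", "J43", "J44")) {
  p <- list(
    wl_fraction_threshold = wl_fraction_threshold,
    low_bmi_threshold = low_bmi_threshold,
    slope_p_threshold = slope_p_threshold,
    min_window_points = min_window_points,
    lookback_months = lookback_months,
    window_span_months = window_span_months,
    window_step_months = window_step_months,
    min_end_before_months = min_end_before_months,
    min_weight_kg = min_weight_kg,
    min_bmi = min_bmi,
    iqr_multiplier = iqr_multiplier,
    min_age = min_age,
    max_age = max_age,
    min_pack_years = min_pack_years,
    max_fev1_fvc = max_fev1_fvc,
    icd_prefixes = icd_prefixes
  )
  num <- vapply(p[setdiff(names(p), "icd_prefixes")], is.numeric, logical(1))
  if (!all(num)) stop("pheno_params: all thresholds must be numeric")
  if (any(unlist(p[setdiff(names(p), "icd_prefixes")]) <= 0))
    stop("pheno_params: all thresholds must be positive")
  structure(p, class = "pheno_params")
}

#' Assess COPD eligibility for one participant
#'
#' Spirometric mode (study-visit cohorts): eligible iff age > 40, FEV1/FVC
#' strictly below 0.7, and pack-years >= 10 — or, when pack-years are
#' unavailable and \code{allow_smoker_flag} is set, a positive ever-smoker
#' flag. ICD mode (EHR cohorts): eligible iff 40 <= age <= 85, any ICD-10
#' code starting with J41–J44, and a positive smoking history.
#'
#' Missing required fields yield an explicit \code{"indeterminate"} status
#' rather than silent exclusion.
#'
#' @param record list or one-row data.frame with fields \code{age},
#'   \code{fev1_fvc}, \code{pack_years}, \code{icd_codes} (comma- or
#'   semicolon-separated string or character vector), \code{smoker_flag}.
#' @param params a \code{\link{pheno_params}} object.
#' @param mode \code{"spirometric"} or \code{"icd"}.
#' @param allow_smoker_flag in spirometric mode, accept an ever-smoker flag
#'   in place of pack-years (used for cohorts without quantitative smoking
#'   histories). Default FALSE.
#' @return list with \code{eligible} (TRUE/FALSE/NA), \code{status}
#'   (\code{"eligible"}, \code{"ineligible"}, \code{"indeterminate"}) and
#'   \code{reason}.
#' @export
assess_eligibility <- function(record, params = pheno_params(),
                               mode = c("spirometric", "icd"),
                               allow_smoker_flag = FALSE) {
  mode <- match.arg(mode)
  record <- as.list(record)
  get <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0) return(NA)
    v
  }
  out <- function(eligible, status, reason)
    list(eligible = eligible, status = status, reason = reason)
  age <- get("age")
  if (is.na(age)) return(out(NA, "indeterminate", "missing age"))

  if (mode == "spirometric") {
    ratio <- get("fev1_fvc")
    if (is.na(ratio))
      return(out(NA, "indeterminate", "missing fev1_fvc"))
    py <- get("pack_years")
    smoker <- get("smoker_flag")
    if (is.na(py) && !(allow_smoker_flag && !is.na(smoker)))
      return(out(NA, "indeterminate", "missing pack_years"))
    if (!(age > params$min_age))
      return(out(FALSE, "ineligible", "age <= minimum"))
    if (!(ratio < params$max_fev1_fvc))
      return(out(FALSE, "ineligible", "fev1_fvc not < threshold"))
    smoke_ok <- if (!is.na(py)) py >= params$min_pack_years
      else isTRUE(as.logical(smoker))
    if (!smoke_ok)
      return(out(FALSE, "ineligible", "insufficient smoking exposure"))
    return(out(TRUE, "eligible", "age, obstruction and smoking criteria met"))
  }

  # icd mode
  codes <- get("icd_codes")
  if (length(codes) == 1 && is.character(codes))
    codes <- strsplit(codes, "[,;[:space:]]+")[[1]]
  smoker <- get("smoker_flag")
  if (all(is.na(codes)))
    return(out(NA, "indeterminate", "missing icd_codes"))
  if (is.na(smoker))
    return(out(NA, "indeterminate", "missing smoker_flag"))
  if (!(age >= params$min_age && age <= params$max_age))
    return(out(FALSE, "ineligible", "age outside window"))
  hit <- any(vapply(params$icd_prefixes,
                    function(p) any(startsWith(codes, p)), logical(1)))
  if (!hit) return(out(FALSE, "ineligible", "no qualifying ICD code"))
  if (!isTRUE(as.logical(smoker)))
    return(out(FALSE, "ineligible", "no smoking history"))
  out(TRUE, "eligible", "age, ICD and smoking criteria met")
}

#' Clean a weight series
#'
#' Two-stage cleaning of one participant's longitudinal weights: first
#' remove physiologically implausible records (weight < 20 kg or
#' BMI < 10 kg/m^2), then in a single pass remove weights more than three
#' interquartile ranges above the 75th or below the 25th percentile, with
#' quartiles computed per participant over the post-implausible weights.
#' The IQR pass is deliberately not iterated to a fixpoint.
#'
#' @param series data.frame with columns \code{time_days},
#'   \code{weight_kg} and optionally \code{bmi}, one participant, sorted
#'   by time (sorted on entry if not).
#' @param params a \code{\link{pheno_params}} object.
#' @return list with \code{series} (cleaned data.frame, possibly 0 rows)
#'   and \code{report}: counts removed by rule (\code{low_weight},
#'   \code{low_bmi}, \code{iqr_outlier}), \code{retained}, and a
#'   \code{reasons} character vector aligned with the input rows
#'   (\code{"kept"} or the removal rule).
#' @export
clean_series <- function(series, params = pheno_params()) {
  stopifnot(is.data.frame(series), nrow(series) >= 1,
            all(c("time_days", "weight_kg") %in% names(series)))
  series <- series[order(series$time_days), , drop = FALSE]
  n <- nrow(series)
  reasons <- rep("kept", n)
  bmi <- if ("bmi" %in% names(series)) series$bmi else rep(NA_real_, n)

  low_w <- series$weight_kg < params$min_weight_kg
  low_b <- !is.na(bmi) & bmi < params$min_bmi & !low_w
  reasons[low_w] <- "low_weight"
  reasons[low_b] <- "low_bmi"

  keep <- reasons == "kept"
  w <- series$weight_kg[keep]
  if (length(w) > 0) {
    q <- quantile(w, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    hi <- q[2] + params$iqr_multiplier * iqr
    lo <- q[1] - params$iqr_multiplier * iqr
    out <- keep & (series$weight_kg > hi | series$weight_kg < lo)
    reasons[out] <- "iqr_outlier"
  }

  kept <- reasons == "kept"
  report <- list(
    low_weight = sum(reasons == "low_weight"),
    low_bmi = sum(reasons == "low_bmi"),
    iqr_outlier = sum(reasons == "iqr_outlier"),
    retained = sum(kept),
    input = n,
    reasons = reasons
  )
  stopifnot(report$low_weight + report$low_bmi + report$iqr_outlier +
              report$retained == n)
  list(series = series[kept, , drop = FALSE], report = report)
}

#' Enumerate sliding windows over the last five years of a weight series
#'
#' Windows are anchored to the most recent record. Starts run from 60
#' months before the last record down to 12 in 3-month steps (17 windows);
#' each window ends 12 months after its start but never closer than 6
#' months before the last record, so the last two windows span only 9 and
#' 6 months. Intervals are half-open \code{(start_before, end_before]} in
#' months-before-last coordinates: a record at exactly \code{start_before}
#' months is excluded, one at exactly \code{end_before} months included.
#'
#' @param series cleaned data.frame for one participant (used only for the
#'   anchor time of the most recent record).
#' @param params a \code{\link{pheno_params}} object.
#' @return data.frame with one row per window: \code{start_before},
#'   \code{end_before}, \code{span_months}.
#' @export
enumerate_windows <- function(series, params = pheno_params()) {
  stopifnot(nrow(series) >= 1)
  starts <- seq(params$lookback_months, params$window_span_months,
                by = -params$window_step_months)
  ends <- pmax(starts - params$window_span_months,
               params$min_end_before_months)
  data.frame(start_before = starts, end_before = ends,
             span_months = starts - ends)
}

# indices of records falling in a window, months-before-last coordinates,
# half-open (start_before, end_before]
.window_indices <- function(series, window) {
  t_last <- max(series$time_days)
  mb <- days_to_months(t_last - series$time_days)
  which(mb < window$start_before & mb >= window$end_before)
}

#' Fit an ordinary least-squares slope to the weights inside one window
#'
#' Regresses weight (kg) on time (months) over the records inside the
#' window. Windows with fewer than \code{min_window_points} records, or
#' whose records all share a single day, are skipped. The slope p-value is
#' the two-sided t-test of slope = 0 (identical to the simple-regression
#' F-test of explained variance); perfectly collinear points have zero
#' residual variance and are assigned p = 0, since the variance-explained
#' criterion is then trivially met. The annualized loss fraction is
#' \code{(-slope * 12) / ref_weight} with \code{ref_weight} the mean
#' observed in-window weight.
#'
#' @param series cleaned one-participant data.frame.
#' @param window one row of \code{\link{enumerate_windows}} output.
#' @param params a \code{\link{pheno_params}} object.
#' @return list of class \code{slope_fit} with \code{skipped},
#'   \code{reason}, and when fitted: \code{n_points}, \code{slope} (kg per
#'   month), \code{intercept}, \code{slope_p}, \code{ref_weight},
#'   \code{annualized_loss_fraction}, \code{max_weight}, plus the window.
#' @export
fit_window_slope <- function(series, window, params = pheno_params()) {
  idx <- .window_indices(series, window)
  skip <- function(reason)
    structure(list(skipped = TRUE, reason = reason, window = window,
                   n_points = length(idx)), class = "slope_fit")
  if (length(idx) < params$min_window_points)
    return(skip("fewer than min_window_points records"))
  w <- series$weight_kg[idx]
  tm <- days_to_months(series$time_days[idx])
  if (length(unique(series$time_days[idx])) < 2)
    return(skip("zero time variance"))

  fit <- lm(w ~ tm)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  df <- length(w) - 2
  sxx <- sum((tm - mean(tm))^2)
  if (df <= 0 || rss <= .Machine$double.eps * sum(w^2)) {
    slope_p <- 0  # collinear points: variance fully explained
  } else {
    se <- sqrt(rss / df / sxx)
    slope_p <- 2 * pt(abs(slope) / se, df = df, lower.tail = FALSE)
  }
  ref <- mean(w)
  structure(list(
    skipped = FALSE, reason = NA_character_, window = window,
    n_points = length(idx), slope = slope, intercept = intercept,
    slope_p = slope_p, ref_weight = ref,
    annualized_loss_fraction = (-slope * params$window_span_months) / ref,
    max_weight = max(w)
  ), class = "slope_fit")
}

#' EHR sliding-window weight-loss classifier
#'
#' Applies the 12-month sliding-window algorithm to one cleaned weight
#' series. A window is a WL window iff its slope fit exists, the slope is
#' negative, the slope p-value is below 0.05 and the annualized loss
#' fraction is at least 5% of body weight per 12 months. The participant
#' is a case iff at least one WL window exists \emph{and} the maximum
#' observed weight across all WL windows exceeds the final recorded
#' weight, \emph{or} the last available BMI is below 20 kg/m^2. The
#' \code{basis} field records which rule fired; \code{low_bmi} is reported
#' only when no window confirmed the loss.
#'
#' @param series cleaned data.frame for one participant with columns
#'   \code{time_days}, \code{weight_kg}, optionally \code{bmi}.
#' @param params a \code{\link{pheno_params}} object.
#' @param height_m optional height in metres, used to derive the final
#'   BMI when no BMI column is present.
#' @return list of class \code{phenotype_call}: \code{status}
#'   (\code{"case"}, \code{"control"} or \code{"indeterminate"}),
#'   \code{basis} (\code{"slope_window"}, \code{"low_bmi"}, \code{"none"}),
#'   \code{wl_window} (row index into the window table, or NA),
#'   \code{max_wl_window_weight}, \code{final_weight}, \code{final_bmi},
#'   \code{n_wl_windows}.
#' @export
classify_ehr <- function(series, params = pheno_params(), height_m = NULL) {
  if (is.null(series) || nrow(series) == 0) {
    return(structure(list(status = "indeterminate", basis = "none",
                          wl_window = NA_integer_,
                          max_wl_window_weight = NA_real_,
                          final_weight = NA_real_, final_bmi = NA_real_,
                          n_wl_windows = 0L), class = "phenotype_call"))
  }
  series <- series[order(series$time_days), , drop = FALSE]
  # restrict to the lookback horizon before the most recent record
  t_last <- max(series$time_days)
  series <- series[days_to_months(t_last - series$time_days) <
                     params$lookback_months, , drop = FALSE]

  final_weight <- series$weight_kg[nrow(series)]
  final_bmi <- NA_real_
  if ("bmi" %in% names(series)) {
    b <- series$bmi[!is.na(series$bmi)]
    if (length(b) > 0) final_bmi <- b[length(b)]
  }
  if (is.na(final_bmi) && !is.null(height_m) && !is.na(height_m))
    final_bmi <- final_weight / height_m^2

  windows <- enumerate_windows(series, params)
  wl_idx <- integer(0)
  wl_max <- -Inf
  for (i in seq_len(nrow(windows))) {
    sf <- fit_window_slope(series, windows[i, ], params)
    if (sf$skipped) next
    if (sf$slope < 0 && sf$slope_p < params$slope_p_threshold &&
        sf$annualized_loss_fraction >= params$wl_fraction_threshold) {
      wl_idx <- c(wl_idx, i)
      wl_max <- max(wl_max, sf$max_weight)
    }
  }

  window_case <- length(wl_idx) > 0 && wl_max > final_weight
  bmi_case <- !is.na(final_bmi) && final_bmi < params$low_bmi_threshold
  status <- if (window_case || bmi_case) "case" else "control"
  basis <- if (window_case) "slope_window"
           else if (bmi_case) "low_bmi"
           else "none"
  structure(list(
    status = status, basis = basis,
    wl_window = if (length(wl_idx)) wl_idx[1] else NA_integer_,
    max_wl_window_weight = if (length(wl_idx)) wl_max else NA_real_,
    final_weight = final_weight, final_bmi = final_bmi,
    n_wl_windows = length(wl_idx)
  ), class = "phenotype_call")
}

#' Visit-based weight-loss classifier
#'
#' For study-visit cohorts: a loss event occurs at a consecutive visit
#' pair (i, i+1) iff the relative drop (w_i - w_{i+1}) / w_i is at least
#' 5%; the event is regained iff any subsequent visit weight (including
#' the last) reaches the pre-loss weight w_i (ties count as regained, and
#' the participant is reclassified as a control for that event). A
#' participant is a case iff at least one non-regained loss event exists
#' or the final-visit BMI is below 20 kg/m^2.
#'
#' @inheritParams classify_ehr
#' @return a \code{phenotype_call} list, \code{basis} one of
#'   \code{"visit_loss"}, \code{"low_bmi"}, \code{"none"}.
#' @export
classify_visits <- function(series, params = pheno_params(),
                            height_m = NULL) {
  if (is.null(series) || nrow(series) < 2) {
    return(structure(list(status = "indeterminate", basis = "none",
                          wl_window = NA_integer_,
                          max_wl_window_weight = NA_real_,
                          final_weight = if (!is.null(series) && nrow(series))
                            series$weight_kg[nrow(series)] else NA_real_,
                          final_bmi = NA_real_, n_wl_windows = 0L),
                     class = "phenotype_call"))
  }
  series <- series[order(series$time_days), , drop = FALSE]
  w <- series$weight_kg
  n <- length(w)
  final_weight <- w[n]
  final_bmi <- NA_real_
  if ("bmi" %in% names(series)) {
    b <- series$bmi[!is.na(series$bmi)]
    if (length(b) > 0) final_bmi <- b[length(b)]
  }
  if (is.na(final_bmi) && !is.null(height_m) && !is.na(height_m))
    final_bmi <- final_weight / height_m^2

  loss_event <- FALSE
  for (i in seq_len(n - 1)) {
    drop_frac <- (w[i] - w[i + 1]) / w[i]
    if (drop_frac >= params$wl_fraction_threshold) {
      regained <- any(w[(i + 1):n] >= w[i])
      if (!regained) { loss_event <- TRUE; break }
    }
  }
  bmi_case <- !is.na(final_bmi) && final_bmi < params$low_bmi_threshold
  status <- if (loss_event || bmi_case) "case" else "control"
  basis <- if (loss_event) "visit_loss" else if (bmi_case) "low_bmi" else "none"
  structure(list(status = status, basis = basis, wl_window = NA_integer_,
                 max_wl_window_weight = NA_real_,
                 final_weight = final_weight, final_bmi = final_bmi,
                 n_wl_windows = 0L), class = "phenotype_call")
}

#' Phenotype a whole cohort from a long weights table
#'
#' Applies cleaning and the chosen classifier to every participant in a
#' long-format weights table.
#'
#' @param weights data.frame with columns \code{participant_id},
#'   \code{time_days}, \code{weight_kg}, optionally \code{bmi}.
#' @param params a \code{\link{pheno_params}} object.
#' @param mode \code{"ehr"} (clean + sliding windows) or \code{"visits"}
#'   (consecutive-pair rule; no cleaning, visit data are curated).
#' @param heights optional named numeric vector of heights (m) by
#'   participant id, used for BMI fallback.
#' @return list with \code{calls}: data.frame (participant_id, status,
#'   basis, final_weight, final_bmi) and \code{cleaning}: data.frame of
#'   per-participant removal counts (ehr mode only).
#' @export
phenotype_cohort <- function(weights, params = pheno_params(),
                             mode = c("ehr", "visits"), heights = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("participant_id", "time_days", "weight_kg") %in%
                  names(weights)))
  ids <- unique(weights$participant_id)
  calls <- vector("list", length(ids))
  cleaning <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    s <- weights[weights$participant_id == id, , drop = FALSE]
    h <- if (!is.null(heights)) unname(heights[as.character(id)]) else NULL
    if (mode == "ehr") {
      cl <- clean_series(s, params)
      cleaning[[k]] <- data.frame(
        participant_id = id, low_weight = cl$report$low_weight,
        low_bmi = cl$report$low_bmi, iqr_outlier = cl$report$iqr_outlier,
        retained = cl$report$retained)
      call <- classify_ehr(cl$series, params, height_m = h)
    } else {
      call <- classify_visits(s, params, height_m = h)
    }
    calls[[k]] <- data.frame(
      participant_id = id, status = call$status, basis = call$basis,
      final_weight = call$final_weight, final_bmi = call$final_bmi)
  }
  list(calls = do.call(rbind, calls),
       cleaning = if (mode == "ehr") do.call(rbind, cleaning) else NULL)
}
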