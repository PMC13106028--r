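#' Published per-cohort participant counts
#'
#' Loads the bundled table of published participant and weight-loss
#' counts for the eight contributing COPD cohorts (seven study-visit
#' cohorts plus the EHR cohort), at both whole-cohort ("ALL") and
#' self-identified-race stratum granularity, together with flags marking
#' membership of each row in the three meta-analysis designs: the
#' cosmopolitan design (all cohorts analysed without stratification), the
#' Black/African-American design, and the non-Hispanic-white design.
#'
#' @param path optional path to an alternative counts TSV with the same
#'   header (study, stratum, n, n_wl, in_cosmo, in_baa, in_nhw).
#' @return data.frame of counts.
#' @export
cohort_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_counts.tsv", package = "copdwl")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Cohort accounting report
#'
#' Reproduces the arithmetic behind the study-design totals: the
#' cosmopolitan total is the sum over whole cohorts; the
#' Black/African-American and non-Hispanic-white totals sum the strata
#' (or whole cohorts, for racially homogeneous studies) assigned to each
#' design; per-cohort weight-loss percentages are n_wl / n on the
#' whole-cohort rows.
#'
#' @param counts a counts data.frame from \code{\link{cohort_counts}}.
#' @return list with \code{cosmo_total}, \code{baa_total},
#'   \code{nhw_total}, and \code{wl_pct}: data.frame (study, n, n_wl,
#'   wl_pct) for cohorts with WL counts. Zero rows give an empty report.
#' @export
cohort_accounting <- function(counts = cohort_counts()) {
  if (nrow(counts) == 0)
    return(list(cosmo_total = 0L, baa_total = 0L, nhw_total = 0L,
                wl_pct = data.frame(study = character(0))))
  all_rows <- counts[counts$stratum == "ALL" & !is.na(counts$n_wl), ,
                     drop = FALSE]
  list(
    cosmo_total = sum(counts$n[counts$in_cosmo]),
    baa_total = sum(counts$n[counts$in_baa]),
    nhw_total = sum(counts$n[counts$in_nhw]),
    wl_pct = data.frame(study = all_rows$study, n = all_rows$n,
                        n_wl = all_rows$n_wl,
                        wl_pct = round(100 * all_rows$n_wl / all_rows$n))
  )
}
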