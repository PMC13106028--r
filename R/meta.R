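#' Harmonize per-cohort association tables for meta-analysis
#'
#' Matches variants across studies on chromosome, position and the
#' \emph{unordered} ref/alt allele pair. When a study reports the pair in
#' the opposite orientation to the first study that contributed the
#' variant, its effect is sign-flipped and its allele fraction replaced
#' by 1 - AAF. Any chromosome:position observed with more than one
#' distinct allele pair in any study is removed entirely (multivalent
#' sites), and variants present in fewer than \code{min_studies} studies
#' are dropped. No strand flipping is attempted: all inputs are assumed
#' to share the same (hg38) sequencing convention.
#'
#' @param study_results named list of \code{assoc_result} data.frames,
#'   names = cohort labels.
#' @param study_order character vector fixing the study order for the
#'   direction strings; defaults to \code{names(study_results)}.
#' @param min_studies minimum number of contributing studies per variant.
#'   Default 2.
#' @return long data.frame (study, chrom, pos, ref, alt, id, n, aaf,
#'   beta, se, p) in reference orientation, with removal counts in
#'   \code{attr(, "log")}.
#' @export
harmonize <- function(study_results, study_order = names(study_results),
                      min_studies = 2) {
  stopifnot(length(study_results) >= 1, !is.null(names(study_results)))
  long <- list()
  for (s in names(study_results)) {
    t <- study_results[[s]]
    if ("converged" %in% names(t)) t <- t[t$converged, , drop = FALSE]
    if (any(duplicated(t$id)))
      stop(sprintf("harmonize: duplicate variant '%s' in study '%s'",
                   t$id[duplicated(t$id)][1], s))
    long[[s]] <- data.frame(study = s, t[, c("chrom", "pos", "ref", "alt",
                                             "n", "aaf", "beta", "se", "p")],
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL

  site <- paste(long$chrom, long$pos, sep = ":")
  pair_key <- paste(site,
                    ifelse(long$ref < long$alt,
                           paste(long$ref, long$alt, sep = "/"),
                           paste(long$alt, long$ref, sep = "/")))
  # multivalent: a site carrying more than one distinct unordered pair
  pairs_at_site <- tapply(pair_key, site, function(k) length(unique(k)))
  multivalent_sites <- names(pairs_at_site)[pairs_at_site > 1]
  n_multi <- sum(site %in% multivalent_sites)
  keep <- !(site %in% multivalent_sites)
  long <- long[keep, , drop = FALSE]
  pair_key <- pair_key[keep]

  # reference orientation: the first contributing study's ref/alt
  first <- !duplicated(pair_key)
  ref_orient <- data.frame(key = pair_key[first],
                           ref = long$ref[first], alt = long$alt[first],
                           stringsAsFactors = FALSE)
  m <- match(pair_key, ref_orient$key)
  flipped <- long$ref != ref_orient$ref[m]
  long$beta[flipped] <- -long$beta[flipped]
  long$aaf[flipped] <- 1 - long$aaf[flipped]
  long$ref <- ref_orient$ref[m]
  long$alt <- ref_orient$alt[m]
  long$id <- paste(long$chrom, long$pos, long$ref, long$alt, sep = ":")

  counts <- table(long$id)
  dropped_single <- sum(counts < min_studies)
  long <- long[long$id %in% names(counts)[counts >= min_studies], ,
               drop = FALSE]
  long$study <- factor(long$study, levels = study_order)
  rownames(long) <- NULL
  attr(long, "log") <- list(multivalent_rows_removed = n_multi,
                            variants_dropped_single_study = dropped_single,
                            flipped_rows = sum(flipped))
  long
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' METAL-style effect-size scheme: with weights w_i = 1/se_i^2, the
#' pooled effect is sum(w b)/sum(w) with standard error sum(w)^(-1/2) and
#' a two-sided normal p-value. Heterogeneity is summarised by Cochran's
#' Q = sum(w (b - b_meta)^2), its chi-square p-value on k-1 degrees of
#' freedom, and I^2 = max(0, (Q - (k-1))/Q) * 100 (0 when Q = 0). The
#' direction string has one character per configured study: '+' for a
#' positive effect, '-' negative, '?' when the study did not contribute.
#'
#' @param aligned output of \code{\link{harmonize}}.
#' @param study_order character vector of study labels in direction-string
#'   order; defaults to the factor levels of \code{aligned$study}.
#' @return data.frame of class \code{meta_result}: id, chrom, pos, ref,
#'   alt, k, total_n, min_aaf, max_aaf, beta, se, or_, l95, u95, p,
#'   direction, q, het_df, i2, het_p.
#' @export
fixed_effects_meta <- function(aligned,
                               study_order = levels(aligned$study)) {
  stopifnot(all(is.finite(aligned$beta)), all(aligned$se > 0))
  zcrit <- 1.959964
  ids <- unique(aligned$id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    t <- aligned[aligned$id == ids[i], , drop = FALSE]
    k <- nrow(t)
    w <- 1 / t$se^2
    beta <- sum(w * t$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    q <- sum(w * (t$beta - beta)^2)
    het_df <- k - 1
    het_p <- if (het_df > 0) pchisq(q, het_df, lower.tail = FALSE)
             else NA_real_
    i2 <- if (q > 0) max(0, (q - het_df) / q) * 100 else 0
    dir <- vapply(study_order, function(s) {
      b <- t$beta[as.character(t$study) == s]
      if (length(b) == 0) "?" else if (b > 0) "+" else "-"
    }, character(1))
    res[[i]] <- data.frame(
      id = ids[i], chrom = t$chrom[1], pos = t$pos[1],
      ref = t$ref[1], alt = t$alt[1], k = k, total_n = sum(t$n),
      min_aaf = min(t$aaf), max_aaf = max(t$aaf),
      beta = beta, se = se, or_ = exp(beta),
      l95 = exp(beta - zcrit * se), u95 = exp(beta + zcrit * se),
      p = 2 * pnorm(abs(beta / se), lower.tail = FALSE),
      direction = paste(dir, collapse = ""),
      q = q, het_df = het_df, i2 = i2, het_p = het_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  chrnum <- suppressWarnings(as.integer(sub("^chr", "", out$chrom)))
  out <- out[order(chrnum, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Run a complete meta-analysis from per-cohort tables
#'
#' Convenience wrapper: harmonize then pool.
#'
#' @inheritParams harmonize
#' @return a \code{meta_result} data.frame.
#' @export
run_meta <- function(study_results, study_order = names(study_results),
                     min_studies = 2) {
  aligned <- harmonize(study_results, study_order, min_studies)
  fixed_effects_meta(aligned, study_order)
}

#' Write meta-analysis results in a METAL-like TSV layout
#'
#' Header: ID REF ALT TOTAL_N MIN_FREQ MAX_FREQ BETA SE OR L95 U95 P
#' DIRECTION HET_Q HET_ISQ HET_DF HET_P.
#'
#' @param results a \code{meta_result} data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_meta <- function(results, path) {
  out <- data.frame(ID = results$id, REF = results$ref, ALT = results$alt,
                    TOTAL_N = results$total_n, MIN_FREQ = results$min_aaf,
                    MAX_FREQ = results$max_aaf, BETA = results$beta,
                    SE = results$se, OR = results$or_, L95 = results$l95,
                    U95 = results$u95, P = results$p,
                    DIRECTION = results$direction, HET_Q = results$q,
                    HET_ISQ = results$i2, HET_DF = results$het_df,
                    HET_P = results$het_p)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
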