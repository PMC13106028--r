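#' Collapse rare variants in a gene mask into a per-participant burden
#'
#' Member variants with in-sample minor-allele fraction strictly below
#' \code{maf_max} contribute to the burden. Dosages are oriented to count
#' minor alleles (flipped to 2 - dosage when the alternate allele is the
#' major one), then summed per participant over qualifying members. The
#' gene MAC is the sum of the qualifying members' minor-allele counts.
#'
#' @param block a \code{genotype_block} with allele statistics.
#' @param mask data.frame (gene, variant_id) restricted to one gene, or a
#'   character vector of member variant ids.
#' @param maf_max minor-allele fraction cut-off, strict. Default 0.01.
#' @return list with \code{score} (named numeric per participant),
#'   \code{mac}, \code{n_variants} (qualifying members), \code{skipped}
#'   and \code{reason}; skipped genes have zero qualifying members.
#' @export
build_burden <- function(block, mask, maf_max = 0.01) {
  ids <- if (is.data.frame(mask)) mask$variant_id else mask
  j <- match(ids, block$variants$id)
  j <- j[!is.na(j)]
  if (length(j) == 0)
    return(list(skipped = TRUE, reason = "no members in block",
                n_variants = 0L))
  aaf <- block$variants$aaf[j]
  maf <- pmin(aaf, 1 - aaf)
  j <- j[!is.na(maf) & maf < maf_max]
  if (length(j) == 0)
    return(list(skipped = TRUE, reason = "no members below MAF cut-off",
                n_variants = 0L))
  d <- block$dosage[, j, drop = FALSE]
  flip <- block$variants$aaf[j] > 0.5
  d[, flip] <- 2 - d[, flip]
  score <- rowSums(d, na.rm = TRUE)
  names(score) <- block$participants
  list(skipped = FALSE, reason = NA_character_,
       score = score, mac = sum(block$variants$mac[j]),
       n_variants = length(j))
}

#' Gene-level burden test
#'
#' Logistic regression of case/control status on the per-participant
#' burden score plus age, sex and five ancestry principal components,
#' with a Wald test of the burden coefficient. A burden-only analysis:
#' no variance-component (kernel) or omnibus combination is performed.
#'
#' @param burden output of \code{\link{build_burden}} (not skipped).
#' @param phenotype data.frame (participant_id, status).
#' @param covariates data.frame (participant_id, age, sex, pc1..pc5).
#' @param gene gene label carried into the result.
#' @param mask_class annotation class label (e.g. "LoF_plus").
#' @return one-row data.frame: gene, mask_class, mac, n_variants, beta,
#'   se, or_, p, converged — or NULL when the burden has zero variance.
#' @export
burden_test <- function(burden, phenotype, covariates, gene = NA_character_,
                        mask_class = "LoF_plus") {
  if (isTRUE(burden$skipped)) return(NULL)
  status <- phenotype$status
  if (is.character(status)) status <- as.integer(status == "case")
  names(status) <- phenotype$participant_id
  ids <- intersect(names(burden$score),
                   intersect(phenotype$participant_id,
                             covariates$participant_id))
  y <- status[ids]
  b <- burden$score[ids]
  if (stats::var(b) == 0) return(NULL)  # zero-variance burden: skip
  cov <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  df <- data.frame(y = y, b = b, cov[, c("age", "sex", paste0("pc", 1:5))])
  fit <- tryCatch(
    suppressWarnings(glm(y ~ b + age + sex + pc1 + pc2 + pc3 + pc4 + pc5,
                         data = df, family = binomial(),
                         control = stats::glm.control(epsilon = 1e-12,
                                                      maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || is.na(coef(fit)["b"])) {
    return(data.frame(gene = gene, mask_class = mask_class,
                      mac = burden$mac, n_variants = burden$n_variants,
                      beta = NA_real_, se = NA_real_, or_ = NA_real_,
                      p = NA_real_, converged = FALSE))
  }
  beta <- unname(coef(fit)["b"])
  se <- sqrt(diag(.wald_vcov(fit)))[["b"]]
  converged <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15 && se < 100
  data.frame(gene = gene, mask_class = mask_class, mac = burden$mac,
             n_variants = burden$n_variants, beta = beta, se = se,
             or_ = exp(beta), p = 2 * pnorm(abs(beta / se),
                                            lower.tail = FALSE),
             converged = converged)
}

#' Run burden tests for every gene in a mask table
#'
#' @param block a \code{genotype_block} with allele statistics.
#' @param masks data.frame (gene, variant_id).
#' @param phenotype,covariates as in \code{\link{burden_test}}.
#' @param maf_max minor-allele fraction cut-off. Default 0.01.
#' @param mask_class annotation class label.
#' @return data.frame with one row per testable gene; skipped genes are
#'   listed in \code{attr(, "skipped")} with reasons.
#' @export
run_gene_tests <- function(block, masks, phenotype, covariates,
                           maf_max = 0.01, mask_class = "LoF_plus") {
  genes <- unique(masks$gene)
  res <- list()
  skipped <- list()
  for (g in genes) {
    bu <- build_burden(block, masks[masks$gene == g, , drop = FALSE],
                       maf_max)
    if (isTRUE(bu$skipped)) {
      skipped[[g]] <- bu$reason
      next
    }
    r <- burden_test(bu, phenotype, covariates, gene = g,
                     mask_class = mask_class)
    if (is.null(r)) skipped[[g]] <- "zero-variance burden"
    else res[[g]] <- r
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(gene = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Combine per-study gene p-values with Fisher's method
#'
#' chi2 = -2 * sum(log(p_i)) is referred to a chi-square distribution
#' with 2k degrees of freedom (k = number of studies). The direction
#' string is built from the per-study burden effect signs.
#'
#' @param p numeric vector of per-study p-values, all in (0, 1].
#' @param beta_sign optional numeric vector of per-study burden effects
#'   (only signs are used) for the direction string.
#' @return list: \code{chi2}, \code{df} (= 2k), \code{p_combined},
#'   \code{direction}.
#' @export
fisher_combine <- function(p, beta_sign = NULL) {
  if (length(p) < 1) stop("fisher_combine: need at least one p-value")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("fisher_combine: p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  direction <- if (is.null(beta_sign)) NA_character_ else
    paste(ifelse(is.na(beta_sign), "?",
                 ifelse(beta_sign > 0, "+", "-")), collapse = "")
  list(chi2 = chi2, df = df,
       p_combined = pchisq(chi2, df, lower.tail = FALSE),
       direction = direction)
}

#' Combine gene-level results across studies
#'
#' Joins per-study gene test tables on gene symbol and applies
#' \code{\link{fisher_combine}} to genes tested in every study.
#'
#' @param study_results named list of \code{\link{run_gene_tests}}
#'   outputs, names = study labels.
#' @return data.frame: gene, one p and MAC column per study, chi2, df,
#'   p_combined, direction.
#' @export
combine_gene_results <- function(study_results) {
  stopifnot(length(study_results) >= 1, !is.null(names(study_results)))
  genes <- Reduce(intersect, lapply(study_results, function(t) t$gene))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    ps <- vapply(study_results,
                 function(t) t$p[t$gene == g][1], numeric(1))
    betas <- vapply(study_results,
                    function(t) t$beta[t$gene == g][1], numeric(1))
    macs <- vapply(study_results,
                   function(t) t$mac[t$gene == g][1], numeric(1))
    if (any(is.na(ps))) next
    fc <- fisher_combine(ps, betas)
    row <- data.frame(gene = g, t(setNames(ps, paste0("p_", names(ps)))),
                      t(setNames(macs, paste0("mac_", names(macs)))),
                      chi2 = fc$chi2, df = fc$df,
                      p_combined = fc$p_combined,
                      direction = fc$direction, stringsAsFactors = FALSE)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0))
  rownames(out) <- NULL
  out
}

#' Gene-level significance threshold and hit table
#'
#' Bonferroni correction for a fixed number of independent gene tests:
#' threshold = alpha / n_tests (0.05 / 20000 = 2.5e-6 by default).
#'
#' @param results data.frame with columns \code{gene} and a p-value
#'   column (\code{p} or \code{p_combined}).
#' @param n_tests assumed number of independent gene tests. Default 20000.
#' @param alpha family-wise error rate. Default 0.05.
#' @return list: \code{threshold}, \code{hits} (rows below threshold).
#' @export
gene_significance <- function(results, n_tests = 20000, alpha = 0.05) {
  threshold <- alpha / n_tests
  pcol <- if ("p_combined" %in% names(results)) "p_combined" else "p"
  hits <- if (nrow(results) == 0) results
          else results[!is.na(results[[pcol]]) &
                         results[[pcol]] < threshold, , drop = FALSE]
  list(threshold = threshold, hits = hits)
}
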