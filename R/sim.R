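#' Simulation configuration
#'
#' Defines the multi-cohort synthetic study: cohort sizes and record
#' styles, the target case fraction, the genotype panel (allele-frequency
#' spectrum and planted causal effects), covariate effects on the
#' weight-loss liability, trajectory noise, weight-loss episode rates,
#' regain behaviour, and contamination rates for the cleaning rules.
#'
#' Defaults emulate the structure of the study cohorts: visit-based
#' arms with 2--8 visits spaced months-to-years apart, EHR-style arms with
#' irregular timestamps over 6 years, roughly 45% prevalence of weight
#' loss, episodes of 5--15% of body weight per year, and occasional
#' implausible or outlying records.
#'
#' @param n_participants participants per cohort (scalar or one per cohort).
#' @param n_cohorts number of cohorts.
#' @param visit_style per-cohort style, \code{"visit_based"} or
#'   \code{"ehr_style"} (recycled).
#' @param case_fraction_target target fraction of true WL cases, in (0,1).
#' @param n_variants number of biallelic variants.
#' @param aaf_spectrum alternate-allele fractions in (0, 0.5], recycled
#'   across variants.
#' @param planted_effects data.frame with columns \code{variant} (index)
#'   and \code{beta} (log odds ratio per alt allele); NULL for none.
#' @param covariate_effects named list of log-odds effects:
#'   \code{age} (per year, centred at 65), \code{sex} (male vs female),
#'   \code{pc} (length-5 vector for the ancestry PCs).
#' @param trajectory_noise_sd measurement noise on each weight record, kg.
#' @param wl_episode_rate_range annualized loss rate range for injected
#'   episodes, fraction of body weight per year.
#' @param regain_fraction probability that an injected loss episode is
#'   fully regained (such participants are true controls unless their
#'   final BMI is low).
#' @param low_bmi_case_fraction fraction of true cases expressed as a
#'   low final BMI (< 20) rather than a detectable loss episode.
#' @param contamination_rates named vector of per-participant
#'   probabilities for \code{low_weight}, \code{low_bmi} and
#'   \code{outlier} contaminant records.
#' @param ehr_records_per_year mean Poisson intensity of EHR timestamps.
#' @param seed integer seed; a fixed seed reproduces the study exactly.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_participants = 500,
                       n_cohorts = 2,
                       visit_style = c("visit_based", "ehr_style"),
                       case_fraction_target = 0.45,
                       n_variants = 50,
                       aaf_spectrum = c(0.3, 0.2, 0.1, 0.05, 0.005),
                       planted_effects = NULL,
                       covariate_effects = list(age = 0.02, sex = 0.25,
                                                pc = rep(0, 5)),
                       trajectory_noise_sd = 0.5,
                       wl_episode_rate_range = c(0.05, 0.15),
                       regain_fraction = 0.25,
                       low_bmi_case_fraction = 0.1,
                       contamination_rates = c(low_weight = 0.02,
                                               low_bmi = 0.01,
                                               outlier = 0.02),
                       ehr_records_per_year = 12,
                       seed = 1L) {
  if (any(n_participants <= 0) || n_cohorts <= 0 || n_variants <= 0)
    stop("sim_config: sizes must be positive")
  if (case_fraction_target <= 0 || case_fraction_target >= 1)
    stop("sim_config: case_fraction_target must be in (0,1)")
  if (length(aaf_spectrum) == 0 || any(aaf_spectrum < 0) ||
      any(aaf_spectrum > 0.5))
    stop("sim_config: aaf_spectrum values must lie in [0, 0.5]")
  if (any(wl_episode_rate_range < 0) ||
      wl_episode_rate_range[1] > wl_episode_rate_range[2])
    stop("sim_config: wl_episode_rate_range must be an increasing range")
  if (regain_fraction < 0 || regain_fraction > 1 ||
      any(contamination_rates < 0) || any(contamination_rates > 1))
    stop("sim_config: probabilities must lie in [0,1]")
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("variant", "beta") %in% names(planted_effects)))
    if (any(planted_effects$variant < 1 |
            planted_effects$variant > n_variants))
      stop("sim_config: planted_effects reference invalid variant indices")
  }
  structure(list(
    n_participants = rep_len(n_participants, n_cohorts),
    n_cohorts = n_cohorts,
    visit_style = rep_len(visit_style, n_cohorts),
    case_fraction_target = case_fraction_target,
    n_variants = n_variants,
    aaf_spectrum = aaf_spectrum,
    planted_effects = planted_effects,
    covariate_effects = covariate_effects,
    trajectory_noise_sd = trajectory_noise_sd,
    wl_episode_rate_range = wl_episode_rate_range,
    regain_fraction = regain_fraction,
    low_bmi_case_fraction = low_bmi_case_fraction,
    contamination_rates = contamination_rates,
    ehr_records_per_year = ehr_records_per_year,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic per-stage substreams from the global seed:
# stage k uses seed * 7 + k (kept below 2^31)
.stage_seed <- function(config, k) (config$seed %% 100000000L) * 7L + k

#' Simulate a biallelic genotype block
#'
#' Draws per-variant dosages as independent Binomial(2, AAF) across
#' participants (Hardy-Weinberg, no relatedness), with AAFs recycled from
#' the configured spectrum. Variant coordinates are synthetic hg38-style
#' positions spread over autosomes.
#'
#' @param config a \code{\link{sim_config}}.
#' @param participants character vector of participant ids.
#' @param seed optional integer overriding the config-derived substream.
#' @param panel optional variant panel from \code{\link{variant_panel}};
#'   cohorts of one study must share the panel so that meta-analysis can
#'   match variants on position and allele pair.
#' @return a \code{genotype_block} (see \code{\link{genotype_block}}) with
#'   allele statistics computed.
#' @export
simulate_genotypes <- function(config, participants, seed = NULL,
                               panel = NULL) {
  n <- length(participants)
  if (n <= 0) stop("simulate_genotypes: need a positive number of participants")
  if (is.null(panel)) panel <- variant_panel(config)
  set.seed(seed %||% .stage_seed(config, 1L))
  m <- nrow(panel)
  dosage <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) dosage[, j] <- rbinom(n, 2L, panel$true_aaf[j])
  colnames(dosage) <- panel$id
  rownames(dosage) <- participants
  compute_allele_stats(genotype_block(panel, participants, dosage))
}

#' Build the shared variant panel for a simulated study
#'
#' Draws the variant definitions (synthetic hg38-style coordinates,
#' ref/alt alleles, target AAFs recycled from the spectrum) once from the
#' config's panel substream, so that every cohort of the study carries
#' the same variants.
#'
#' @param config a \code{\link{sim_config}}.
#' @return variant data.frame (chrom, pos, ref, alt, true_aaf, id).
#' @export
variant_panel <- function(config) {
  set.seed(.stage_seed(config, 99L))
  m <- config$n_variants
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  panel <- data.frame(
    chrom = paste0("chr", rep_len(1:22, m)),
    pos = 10000L + 100L * seq_len(m),
    ref = ref, alt = unname(alt),
    true_aaf = rep_len(config$aaf_spectrum, m),
    stringsAsFactors = FALSE)
  panel$id <- paste(panel$chrom, panel$pos, panel$ref, panel$alt,
                    sep = ":")
  panel
}

#' Simulate covariates for one cohort
#'
#' Ages ~ Normal(67, 8) truncated to 42--88; sex ~ Bernoulli(0.55) (1 =
#' male); five ancestry PCs ~ Normal(0,1); pack-years ~ Normal(42, 20)
#' truncated at 10; FEV1/FVC ~ Uniform(0.3, 0.69); a qualifying ICD code
#' and positive smoking flag for every participant (the generator emits
#' participants already meeting COPD eligibility).
#'
#' @inheritParams simulate_genotypes
#' @param cohort cohort label.
#' @return data.frame (participant_id, age, sex, pc1..pc5, pack_years,
#'   fev1_fvc, icd_codes, smoker_flag, cohort).
#' @export
simulate_covariates <- function(config, participants, cohort = "cohort1",
                                seed = NULL) {
  set.seed(seed %||% .stage_seed(config, 2L))
  n <- length(participants)
  age <- pmin(pmax(rnorm(n, 67, 8), 42), 88)
  sex <- rbinom(n, 1, 0.55)
  pcs <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  pack_years <- pmax(rnorm(n, 42, 20), 10)
  fev1_fvc <- runif(n, 0.30, 0.69)
  data.frame(participant_id = participants, age = age, sex = sex, pcs,
             pack_years = pack_years, fev1_fvc = fev1_fvc,
             icd_codes = "J44.9", smoker_flag = 1L,
             cohort = cohort, stringsAsFactors = FALSE)
}

#' Simulate the true weight-loss phenotype
#'
#' Draws the true WL label from a logistic model: logit P(WL) = b0 +
#' sum(beta_g * dosage) + covariate terms (age centred at 65, sex, PCs).
#' The intercept b0 is calibrated by bisection so that the \emph{expected}
#' case fraction over the realized linear predictors equals the target;
#' with n >= 2000 the realized fraction lands within 0.02 of target.
#'
#' @param genotypes a \code{genotype_block}.
#' @param covariates covariate data.frame aligned with the block's
#'   participants.
#' @param config a \code{\link{sim_config}}.
#' @param seed optional substream override.
#' @return truth data.frame (participant_id, wl_true, liability) with the
#'   calibrated intercept in \code{attr(, "b0")} and per-variant true
#'   log-ORs in \code{attr(, "true_beta")}.
#' @export
simulate_phenotype <- function(genotypes, covariates, config, seed = NULL) {
  stopifnot(identical(genotypes$participants, covariates$participant_id))
  set.seed(seed %||% .stage_seed(config, 3L))
  n <- length(genotypes$participants)
  true_beta <- rep(0, config$n_variants)
  if (!is.null(config$planted_effects))
    true_beta[config$planted_effects$variant] <- config$planted_effects$beta

  eta <- as.vector(genotypes$dosage %*% true_beta)
  ce <- config$covariate_effects
  eta <- eta + ce$age * (covariates$age - 65) + ce$sex * covariates$sex +
    as.vector(as.matrix(covariates[paste0("pc", 1:5)]) %*% ce$pc)

  target <- config$case_fraction_target
  f <- function(b0) mean(plogis(b0 + eta)) - target
  lo <- -20; hi <- 20
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  b0 <- (lo + hi) / 2
  p <- plogis(b0 + eta)
  wl <- rbinom(n, 1, p)
  truth <- data.frame(participant_id = genotypes$participants,
                      wl_true = wl, liability = b0 + eta,
                      stringsAsFactors = FALSE)
  attr(truth, "b0") <- b0
  attr(truth, "true_beta") <- true_beta
  truth
}

# piecewise-linear weight trajectory evaluated at day offsets `t_days`
# (0 = first record). Episode: plateau at baseline until onset, linear
# loss at `rate` (fraction of baseline per year) for `dur_days`, then
# plateau (regain = FALSE) or linear return to baseline over the same
# duration (regain = TRUE).
.trajectory_weight <- function(t_days, baseline, onset_day, rate, dur_days,
                               regain, drift_per_year = 0) {
  loss_per_day <- rate * baseline / 365.25
  end_day <- onset_day + dur_days
  w <- baseline + drift_per_year * baseline / 365.25 * t_days
  in_loss <- t_days > onset_day & t_days <= end_day
  after <- t_days > end_day
  w[in_loss] <- baseline - loss_per_day * (t_days[in_loss] - onset_day)
  low <- baseline - loss_per_day * dur_days
  if (regain) {
    # full regain overshoots baseline by 2% (weight cycling), so that a
    # regained control's final weight clears the episode maximum even
    # under measurement noise
    target <- baseline * 1.02
    reg_end <- end_day + dur_days
    reg <- after & t_days <= reg_end
    w[reg] <- low + (target - low) * (t_days[reg] - end_day) / dur_days
    w[t_days > reg_end] <- target
  } else {
    w[after] <- low
  }
  w
}

#' Simulate weight trajectories consistent with the truth labels
#'
#' Builds per-participant piecewise-linear weight trajectories: true cases
#' carry a loss episode at an annualized rate drawn from the configured
#' range (placed so that it falls inside the sliding-window lookback and
#' is not regained), or — for a configured fraction — a flat trajectory
#' ending at BMI < 20; true controls drift at under 2% of body weight per
#' year, a \code{regain_fraction} of them after a fully regained loss
#' episode. Visit-based cohorts get 2--8 visits including baseline and
#' final; EHR-style cohorts get Poisson-process timestamps over at least
#' 60 months. Gaussian measurement noise is added to every record; height
#' is fixed per participant and BMI = weight / height^2.
#'
#' @param truth output of \code{\link{simulate_phenotype}}.
#' @param config a \code{\link{sim_config}}.
#' @param style \code{"visit_based"} or \code{"ehr_style"}.
#' @param seed optional substream override.
#' @return list with \code{weights} (long data.frame: participant_id,
#'   time_days, weight_kg, bmi) and \code{truth} augmented with episode
#'   parameters (onset/rate/regained), \code{height_m}, \code{baseline_kg}
#'   and \code{low_bmi_case}.
#' @export
simulate_trajectories <- function(truth, config,
                                  style = c("ehr_style", "visit_based"),
                                  seed = NULL) {
  style <- match.arg(style)
  set.seed(seed %||% .stage_seed(config, 4L))
  n <- nrow(truth)
  span_days <- round(months_to_days(72))  # 6 years of history

  height <- rnorm(n, 1.70, 0.09)
  # baseline BMI ~ N(27, 3.5), floored at 22.5 so that control drift and
  # regained episodes cannot end below the low-BMI threshold (truth labels
  # follow the EHR-algorithm semantics: controls must finish at BMI >= 20)
  baseline <- pmax(rnorm(n, 27, 3.5), 22.5) * height^2
  low_bmi_case <- truth$wl_true == 1 &
    runif(n) < config$low_bmi_case_fraction
  # low-BMI cases: thin, flat trajectory ending under the BMI threshold
  baseline[low_bmi_case] <- runif(sum(low_bmi_case), 17, 19.4) *
    height[low_bmi_case]^2

  rate <- onset <- dur <- rep(NA_real_, n)
  regained <- rep(NA, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (style == "ehr_style") {
      n_rec <- max(rpois(1, config$ehr_records_per_year * 6), 2)
      t_days <- sort(sample.int(span_days, min(n_rec, span_days)))
      t_days <- c(0L, t_days[t_days > 0])
      t_days[length(t_days)] <- span_days
    } else {
      n_vis <- sample(2:8, 1)
      inner <- sort(sample.int(span_days - 1, max(n_vis - 2, 0)))
      t_days <- unique(c(0L, inner, span_days))
    }

    is_case <- truth$wl_true[i] == 1
    if (is_case && !low_bmi_case[i]) {
      rate[i] <- runif(1, config$wl_episode_rate_range[1],
                       config$wl_episode_rate_range[2])
      dur[i] <- months_to_days(runif(1, 18, 24))
      # episode ends 8-26 months before the last record: inside the
      # lookback, clear of the 6-month stopping rule
      end_before <- months_to_days(runif(1, 8, 26))
      onset[i] <- span_days - end_before - dur[i]
      regained[i] <- FALSE
      w <- .trajectory_weight(t_days, baseline[i], onset[i], rate[i],
                              dur[i], regain = FALSE)
    } else if (is_case) {           # low-BMI case: flat, thin
      w <- rep(baseline[i], length(t_days))
    } else if (runif(1) < config$regain_fraction) {
      rate[i] <- runif(1, config$wl_episode_rate_range[1],
                       config$wl_episode_rate_range[2])
      dur[i] <- months_to_days(runif(1, 12, 18))
      onset[i] <- span_days * runif(1, 0.15, 0.4)
      regained[i] <- TRUE
      w <- .trajectory_weight(t_days, baseline[i], onset[i], rate[i],
                              dur[i], regain = TRUE)
    } else {
      drift <- runif(1, -0.015, 0.015)  # |slope| < 2%/yr
      w <- .trajectory_weight(t_days, baseline[i], 0, 0, 0,
                              regain = FALSE, drift_per_year = drift)
    }
    w <- w + rnorm(length(t_days), 0, config$trajectory_noise_sd)
    rows[[i]] <- data.frame(participant_id = truth$participant_id[i],
                            time_days = as.integer(round(t_days)),
                            weight_kg = w, bmi = w / height[i]^2,
                            stringsAsFactors = FALSE)
  }
  truth$height_m <- height
  truth$baseline_kg <- baseline
  truth$low_bmi_case <- low_bmi_case
  truth$episode_rate <- rate
  truth$episode_onset_day <- onset
  truth$episode_duration_days <- dur
  truth$episode_regained <- regained
  list(weights = do.call(rbind, rows), truth = truth)
}

#' Inject contaminant records
#'
#' With the configured per-participant probabilities, inserts records that
#' the cleaning rules must remove: implausibly low weights (< 20 kg),
#' records implying BMI < 10, and gross outliers beyond three
#' interquartile ranges of the participant's clean weights. Contaminants
#' are tagged in the \code{contaminant_tag} column so cleaning recall is
#' measurable.
#'
#' @param weights long weights data.frame from
#'   \code{\link{simulate_trajectories}}.
#' @param truth truth data.frame carrying \code{height_m}.
#' @param config a \code{\link{sim_config}}.
#' @param seed optional substream override.
#' @return weights data.frame with a \code{contaminant_tag} column
#'   (\code{""} for genuine records).
#' @export
contaminate <- function(weights, truth, config, seed = NULL) {
  set.seed(seed %||% .stage_seed(config, 5L))
  rates <- config$contamination_rates
  if (!"contaminant_tag" %in% names(weights))
    weights$contaminant_tag <- ""
  if (all(rates == 0)) return(weights)
  extra <- list()
  heights <- setNames(truth$height_m, truth$participant_id)
  for (id in unique(weights$participant_id)) {
    s <- weights[weights$participant_id == id, , drop = FALSE]
    h <- unname(heights[as.character(id)])
    tmax <- max(s$time_days)
    mk <- function(w, tag) {
      t0 <- sample.int(max(tmax, 1), 1)
      data.frame(participant_id = id, time_days = t0, weight_kg = w,
                 bmi = w / h^2, contaminant_tag = tag,
                 stringsAsFactors = FALSE)
    }
    if (runif(1) < rates[["low_weight"]])
      extra[[length(extra) + 1]] <- mk(runif(1, 5, 19.5), "low_weight")
    if (runif(1) < rates[["low_bmi"]])
      extra[[length(extra) + 1]] <-
        mk(runif(1, 5, 9.5) * h^2, "low_bmi")
    if (runif(1) < rates[["outlier"]]) {
      q <- quantile(s$weight_kg, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      extra[[length(extra) + 1]] <-
        mk(q[2] + 3 * iqr + runif(1, 5, 30), "outlier")
    }
  }
  out <- rbind(weights, do.call(rbind, extra))
  out <- out[order(out$participant_id, out$time_days), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group rare variants into synthetic gene masks
#'
#' Assigns every variant with true AAF below \code{maf_max} to a gene,
#' \code{per_gene} consecutive rare variants per gene, emulating a
#' loss-of-function-plus annotation group file.
#'
#' @param block a \code{genotype_block}.
#' @param maf_max rare-variant frequency cut-off. Default 0.01.
#' @param per_gene members per synthetic gene. Default 4.
#' @return data.frame (gene, variant_id).
#' @export
make_gene_masks <- function(block, maf_max = 0.01, per_gene = 4) {
  rare <- which(block$variants$true_aaf < maf_max)
  if (length(rare) == 0) return(data.frame(gene = character(0),
                                           variant_id = character(0)))
  gene <- paste0("GENE", ceiling(seq_along(rare) / per_gene))
  data.frame(gene = gene, variant_id = block$variants$id[rare],
             stringsAsFactors = FALSE)
}

#' Simulate a complete multi-cohort study
#'
#' Runs the full generative model for every cohort: genotypes,
#' covariates, truth labels, trajectories and contamination, plus a shared
#' rare-variant gene mask table.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with one element per cohort (\code{genotypes},
#'   \code{covariates}, \code{truth}, \code{weights}, \code{style},
#'   \code{name}) and an attribute-free top-level \code{masks} table.
#' @export
simulate_study <- function(config) {
  cohorts <- vector("list", config$n_cohorts)
  masks <- NULL
  panel <- variant_panel(config)
  for (c in seq_len(config$n_cohorts)) {
    name <- paste0("cohort", c)
    base <- .stage_seed(config, 10L * c)
    ids <- sprintf("%s_P%05d", name, seq_len(config$n_participants[c]))
    geno <- simulate_genotypes(config, ids, seed = base + 1L,
                               panel = panel)
    cov <- simulate_covariates(config, ids, cohort = name, seed = base + 2L)
    truth <- simulate_phenotype(geno, cov, config, seed = base + 3L)
    traj <- simulate_trajectories(truth, config,
                                  style = config$visit_style[c],
                                  seed = base + 4L)
    weights <- contaminate(traj$weights, traj$truth, config,
                           seed = base + 5L)
    if (is.null(masks)) masks <- make_gene_masks(geno)
    cohorts[[c]] <- list(name = name, style = config$visit_style[c],
                         genotypes = geno, covariates = cov,
                         truth = traj$truth, weights = weights)
  }
  list(cohorts = cohorts, masks = masks, config = config)
}

#' Write one simulated cohort to disk
#'
#' Emits the plain-text interchange files every downstream stage reads:
#' \code{weights.tsv}, \code{covariates.tsv}, \code{genotypes.vcf} (VCF
#' 4.2 with GT), \code{groups.txt} (one gene per line) and
#' \code{truth.tsv}.
#'
#' @param cohort one element of \code{simulate_study()$cohorts}.
#' @param masks gene mask table for the group file.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(weights = file.path(dir, "weights.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             vcf = file.path(dir, "genotypes.vcf"),
             groups = file.path(dir, "groups.txt"),
             truth = file.path(dir, "truth.tsv"))
  write.table(cohort$weights, paths["weights"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cohort$covariates, paths["covariates"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_vcf(cohort$genotypes, paths["vcf"])
  write_group_file(masks, paths["groups"])
  write.table(cohort$truth, paths["truth"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paths)
}
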