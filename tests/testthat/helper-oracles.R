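# Independent reference implementations used as oracles. These stay
# deliberately separate from the package's code paths: logistic fits use
# a textbook Newton-Raphson, window slopes use closed-form moment sums
# with an F-test via r^2, and the chi-square survival function for even
# degrees of freedom uses the finite Poisson sum.

# Newton-Raphson maximum-likelihood logistic regression
nr_logistic <- function(X, y, max_iter = 200, tol = 1e-12) {
  X <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    g <- crossprod(X, y - p)
    step <- solve(H, g)
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- b / se
  list(beta = unname(b), se = unname(se),
       p = unname(2 * pnorm(abs(z), lower.tail = FALSE)))
}

# brute-force inverse-variance fixed-effects pooling with explicit loops
brute_meta <- function(betas, ses) {
  k <- length(betas)
  sw <- 0; swb <- 0
  for (i in seq_len(k)) {
    w <- 1 / ses[i]^2
    sw <- sw + w
    swb <- swb + w * betas[i]
  }
  bm <- swb / sw
  q <- 0
  for (i in seq_len(k)) q <- q + (betas[i] - bm)^2 / ses[i]^2
  sem <- sqrt(1 / sw)
  list(beta = bm, se = sem,
       p = 2 * pnorm(abs(bm / sem), lower.tail = FALSE),
       q = q,
       het_p = if (k > 1) pchisq(q, k - 1, lower.tail = FALSE) else NA,
       i2 = if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0)
}

# chi-square upper tail for even df via the finite Poisson series:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!   (df = 2k)
chisq_sf_even_df <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  h <- x / 2
  terms <- vapply(0:(k - 1), function(j) exp(-h + j * log(h) - lgamma(j + 1)),
                  numeric(1))
  if (x == 0) 1 else sum(terms)
}

# brute-force EHR weight-loss classifier: explicit loop over the 17
# windows, closed-form OLS via moment sums, F-test through r^2
brute_classify_ehr <- function(series, wl_thr = 0.05, p_thr = 0.05,
                               bmi_thr = 20) {
  dpm <- 30.4375
  series <- series[order(series$time_days), , drop = FALSE]
  t_last <- max(series$time_days)
  mb <- (t_last - series$time_days) / dpm
  series <- series[mb < 60, , drop = FALSE]
  mb <- mb[mb < 60]
  final_w <- series$weight_kg[nrow(series)]
  final_bmi <- NA_real_
  if ("bmi" %in% names(series)) {
    b <- series$bmi[!is.na(series$bmi)]
    if (length(b)) final_bmi <- b[length(b)]
  }
  wl_max <- -Inf
  any_wl <- FALSE
  for (start in seq(60, 12, by = -3)) {
    end <- max(start - 12, 6)
    idx <- which(mb < start & mb >= end)
    if (length(idx) < 3) next
    x <- series$time_days[idx] / dpm
    y <- series$weight_kg[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    sst <- sum((y - mean(y))^2)
    ssr <- slope^2 * sxx
    n <- length(idx)
    if (sst - ssr <= .Machine$double.eps * sst || sst == 0) {
      pval <- 0
    } else {
      r2 <- ssr / sst
      f <- r2 * (n - 2) / (1 - r2)
      pval <- pf(f, 1, n - 2, lower.tail = FALSE)
    }
    alf <- (-slope * 12) / mean(y)
    if (slope < 0 && pval < p_thr && alf >= wl_thr) {
      any_wl <- TRUE
      wl_max <- max(wl_max, max(y))
    }
  }
  if ((any_wl && wl_max > final_w) ||
      (!is.na(final_bmi) && final_bmi < bmi_thr)) "case" else "control"
}

# random weight series with a mix of flat, drifting and episodic shapes;
# used for oracle-equivalence sweeps
random_series <- function(n_min = 5, n_max = 40) {
  n <- sample(n_min:n_max, 1)
  t <- sort(sample.int(2200, n))
  shape <- sample(c("flat", "drift", "loss", "walk"), 1)
  base <- runif(1, 55, 95)
  w <- switch(shape,
    flat = rep(base, n),
    drift = base * (1 + runif(1, -0.05, 0.05) * t / 365.25),
    loss = {
      onset <- runif(1, 0.2, 0.6) * max(t)
      rate <- runif(1, 0.02, 0.2)
      pmax(base - rate * base / 365.25 * pmax(t - onset, 0), 30)
    },
    walk = base + cumsum(rnorm(n, 0, 1.5)))
  w <- pmax(w + rnorm(n, 0, runif(1, 0, 1)), 25)
  h <- runif(1, 1.5, 1.95)
  data.frame(participant_id = "px", time_days = t, weight_kg = w,
             bmi = w / h^2)
}

# noiseless piecewise trajectory whose in-window annualized loss
# fraction (relative to the window mean) is exactly `alf`
sharpness_series <- function(alf, mean_w = 80) {
  dpm <- 30.4375
  m <- c(1, 5, 9)                     # months after first record
  t <- round(m * dpm)
  mm <- t / dpm
  slope <- -alf * mean_w / 12
  w <- mean_w + slope * (mm - mean(mm))
  final_t <- round(60 * dpm)
  rbind(
    data.frame(participant_id = "s", time_days = t, weight_kg = w,
               bmi = w / 1.8^2),
    data.frame(participant_id = "s", time_days = final_t, weight_kg = 70,
               bmi = 70 / 1.8^2))
}
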