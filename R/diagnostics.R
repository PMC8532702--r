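#' Goodness-of-fit quantities
#'
#' Population predictions (random effects at zero), individual predictions
#' (at the empirical Bayes estimates), conditional weighted residuals
#' (FOCE-linearized, so approximately standard normal under the true model)
#' and time after dose for every observation of a converged fit.
#'
#' @param fit A `pk_fit` object.
#' @return Data frame with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `cwres`. Records with non-finite predictions are flagged in
#'   `attr(, "n_excluded")` and dropped.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  fl <- fit$flat
  res <- foce_eval(fl, fit$structure, fit$theta, fit$omega2, fit$sigma2,
                   want_diag = TRUE)
  ids <- rep(vapply(fl$subjects, function(s) s$id, fl$subjects[[1]]$id),
             diff(fl$obs_ptr))
  tad <- numeric(length(fl$obs_time))
  for (i in seq_along(fl$subjects)) {
    o <- (fl$obs_ptr[i] + 1):fl$obs_ptr[i + 1]
    dt <- fl$dose_time[(fl$dose_ptr[i] + 1):fl$dose_ptr[i + 1]]
    tad[o] <- vapply(fl$obs_time[o],
                     function(t) t - max(dt[dt <= t], -Inf), 0)
  }
  out <- data.frame(id = ids, time = fl$obs_time, tad = tad, dv = fl$obs_y,
                    pred = res$pred, ipred = res$ipred, cwres = res$cwres)
  ok <- is.finite(out$pred) & is.finite(out$ipred) & is.finite(out$cwres)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    warning(n_excluded, " record(s) with non-finite diagnostics excluded")
  out <- out[ok, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits each replicate, and reports
#' per-parameter medians and percentile 95% confidence intervals over the
#' successful replicates (converged with finite relative standard errors).
#'
#' @param data Event data frame or `pk_subjects` list.
#' @param structure A [model_structure()].
#' @param n_replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   usual choice, smaller values keep exploratory runs fast).
#' @param seed RNG seed for the resampling indices.
#' @param inits,control Passed to [fit_popmodel()] for each replicate.
#' @return List with `summary` (data frame: parameter, median, ci_lo,
#'   ci_hi), `estimates` (replicate-by-parameter matrix), `success_rate`
#'   and the resample `indices`.
#' @export
pk_bootstrap <- function(data, structure = model_structure(),
                         n_replicates = 1000, seed = NULL, inits = NULL,
                         control = list()) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  subjects <- as_subjects(data)
  n <- length(subjects)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                nrow = n_replicates)
  est <- vector("list", n_replicates)
  success <- logical(n_replicates)
  for (b in seq_len(n_replicates)) {
    boot_sub <- subjects[idx[b, ]]
    for (j in seq_along(boot_sub)) boot_sub[[j]]$id <- j
    class(boot_sub) <- "pk_subjects"
    ft <- tryCatch(
      suppressWarnings(fit_popmodel(boot_sub, structure, inits = inits,
                                    control = control)),
      error = function(e) NULL)
    if (!is.null(ft)) {
      est[[b]] <- coef(ft)
      # finite RSEs required only when the Hessian is computed
      success[b] <- ft$converged &&
        (isFALSE(control$hessian) || all(is.finite(ft$rse)))
    }
  }
  done <- !vapply(est, is.null, TRUE)
  mat <- do.call(rbind, est[done & success])
  success_rate <- mean(success)
  if (success_rate < 0.5)
    warning(sprintf("bootstrap success rate %.1f%% is below 50%%",
                    100 * success_rate))
  summ <- if (!is.null(mat) && nrow(mat) > 0) {
    data.frame(parameter = colnames(mat),
               median = apply(mat, 2, median),
               ci_lo = apply(mat, 2, quantile, 0.025),
               ci_hi = apply(mat, 2, quantile, 0.975),
               row.names = NULL)
  } else {
    data.frame(parameter = character(), median = numeric(),
               ci_lo = numeric(), ci_hi = numeric())
  }
  list(summary = summ, estimates = mat, success_rate = success_rate,
       indices = idx)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate datasets on the original design from the fitted
#' model, normalizes observed and simulated concentrations by the ratio of
#' the bin-median population prediction to the record's population
#' prediction, and compares observed percentiles with the simulation
#' confidence bands in equal-count bins of time after dose.
#'
#' @param fit A `pk_fit` object.
#' @param n_sim Number of simulated replicate datasets (default 1000).
#' @param bins Number of equal-count bins on time after dose (default 8).
#' @param seed RNG seed for the simulations.
#' @param ci Width of the simulated confidence interval (default 0.90).
#' @return Data frame with one row per (bin, percentile): bin bounds,
#'   observed percentile value and the simulated CI; the fraction of
#'   observed percentile points inside their CI is in
#'   `attr(, "coverage")`.
#' @export
pc_vpc <- function(fit, n_sim = 1000, bins = 8, seed = NULL, ci = 0.90) {
  stopifnot(inherits(fit, "pk_fit"), n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  fl <- fit$flat
  g <- gof(fit)
  nobs <- length(fl$obs_y)
  pred <- g$pred
  usable <- pred > 0
  if (any(!usable))
    warning(sum(!usable), " record(s) with zero population prediction ",
            "excluded from the VPC")

  tv <- typical_values(fit$theta, fit$structure, fl$covs)
  nsub <- length(fl$subjects)
  sims <- matrix(NA_real_, n_sim, nobs)
  for (r in seq_len(n_sim)) {
    e1 <- rnorm(nsub, 0, sqrt(fit$omega2[1]))
    e2 <- rnorm(nsub, 0, sqrt(fit$omega2[2]))
    for (i in seq_len(nsub)) {
      o <- (fl$obs_ptr[i] + 1):fl$obs_ptr[i + 1]
      d <- (fl$dose_ptr[i] + 1):fl$dose_ptr[i + 1]
      f <- cpp_conc(fl$obs_time[o], fl$dose_time[d], fl$dose_amt[d],
                    fl$dose_dur[d], tv$cl[i] * exp(e1[i]),
                    tv$vc[i] * exp(e2[i]), tv$q[i], tv$vp[i])
      sims[r, o] <- f * (1 + rnorm(length(o), 0, sqrt(fit$sigma2)))
    }
  }

  tad <- g$tad
  # deterministic equal-count bin edges on time after dose
  edges <- unique(quantile(tad[usable], probs = seq(0, 1, length.out = bins + 1),
                           type = 1))
  bin_id <- cut(tad, edges, include.lowest = TRUE, labels = FALSE)
  probs <- c(0.05, 0.5, 0.95)
  alpha <- (1 - ci) / 2
  rows <- list()
  cover <- 0L
  total <- 0L
  for (b in seq_len(length(edges) - 1)) {
    sel <- which(bin_id == b & usable)
    if (!length(sel)) next
    pc_fac <- median(pred[sel]) / pred[sel]
    obs_pc <- g$dv[sel] * pc_fac
    obs_q <- quantile(obs_pc, probs)
    sim_q <- t(apply(sims[, sel, drop = FALSE], 1, function(x)
      quantile(x * pc_fac, probs)))
    for (j in seq_along(probs)) {
      lo <- quantile(sim_q[, j], alpha)
      hi <- quantile(sim_q[, j], 1 - alpha)
      inside <- obs_q[j] >= lo & obs_q[j] <= hi
      cover <- cover + inside
      total <- total + 1L
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, tad_lo = edges[b], tad_hi = edges[b + 1],
        n = length(sel), percentile = 100 * probs[j],
        observed = unname(obs_q[j]), sim_lo = unname(lo),
        sim_hi = unname(hi), inside = inside)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "coverage") <- cover / total
  out
}
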