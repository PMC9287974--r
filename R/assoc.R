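# Association analyses: group comparisons of DMP burden (Welch t),
# purity-vs-DMP correlation (Pearson), and Cox proportional-hazards
# regression of relapse interval against DMP count.

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided.
#' Groups with fewer than two observations yield an explicit
#' not-computable result (never a number), mirroring the convention that
#' significance cannot be calculated against single-sample groups.
#'
#' @param x,y Numeric vectors.
#' @param label_x,label_y Optional group labels carried into the result.
#' @return List of class `group_comparison`: `computable`, group `n`,
#'   `mean`, `variance`, `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y, label_x = "x", label_y = "y") {
  base <- list(labels = c(label_x, label_y),
               n = c(length(x), length(y)),
               mean = c(mean(x), mean(y)),
               variance = c(stats::var(x), stats::var(y)))
  if (length(x) < 2 || length(y) < 2) {
    res <- c(base, list(computable = FALSE, t = NA_real_, df = NA_real_,
                        p_value = NA_real_,
                        reason = "group with fewer than 2 observations"))
    class(res) <- "group_comparison"
    return(res)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  res <- c(base, list(computable = TRUE, t = unname(tt$statistic),
                      df = unname(tt$parameter),
                      p_value = tt$p.value))
  class(res) <- "group_comparison"
  res
}

#' Pearson correlation with t-based p-value
#'
#' Sample correlation with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom. Zero variance in either vector yields an
#' undefined-result marker.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `defined`, `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(defined = FALSE, r = NA_real_, p_value = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(defined = TRUE, r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Association between purity difference and DMP burden
#'
#' Spatial mode correlates each patient's purity spread (max - min over
#' biopsies) with its DMP count; temporal mode uses the absolute
#' primary/relapse purity difference. Patients with missing purity are
#' dropped with a warning.
#'
#' @param dmp_counts Named numeric vector, patient id -> DMP count.
#' @param sheet Sample sheet with `purity` filled for the relevant
#'   samples.
#' @param mode `"spatial"` or `"temporal"`.
#' @return As [pearson_correlation()], plus the per-patient `data`
#'   actually correlated.
#' @export
purity_dmp_association <- function(dmp_counts, sheet,
                                   mode = c("spatial", "temporal")) {
  mode <- match.arg(mode)
  xs <- vapply(names(dmp_counts), function(pid) {
    rows <- sheet[sheet$patient_id == pid, ]
    if (mode == "spatial") {
      p <- rows$purity[rows$role == "spatial"]
      if (length(p) < 2 || anyNA(p)) return(NA_real_)
      max(p) - min(p)
    } else {
      pp <- rows$purity[rows$role == "primary"]
      pr <- rows$purity[rows$role %in% c("relapse", "metastasis")]
      if (length(pp) != 1 || length(pr) < 1 || is.na(pp) || anyNA(pr))
        return(NA_real_)
      abs(pr[1] - pp)
    }
  }, numeric(1))
  drop <- is.na(xs)
  if (any(drop))
    warning("dropping ", sum(drop), " patient(s) with missing purity: ",
            paste(names(dmp_counts)[drop], collapse = ", "))
  res <- pearson_correlation(xs[!drop], as.numeric(dmp_counts[!drop]))
  res$data <- data.frame(patient_id = names(dmp_counts)[!drop],
                         purity_difference = unname(xs[!drop]),
                         dmp_count = as.numeric(dmp_counts[!drop]),
                         stringsAsFactors = FALSE)
  res
}

# Breslow log partial likelihood, score and information for a univariate
# Cox model. Subjects sorted by time once; risk sets accumulate from the
# largest time down, with all subjects tied at a time entering the risk
# set before any of their events are scored.
.cox_quantities <- function(beta_hat, time, x, event) {
  ord <- order(-time)
  time <- time[ord]; x <- x[ord]; event <- event[ord]
  eta <- beta_hat * x
  w <- exp(eta)
  s0 <- cumsum(w)
  s1 <- cumsum(w * x)
  s2 <- cumsum(w * x^2)
  # last index of each tied block = full risk set for that time
  block_end <- cumsum(rle(time)$lengths)
  end_of <- rep(block_end, rle(time)$lengths)
  ll <- 0; score <- 0; info <- 0
  ev <- which(event == 1)
  for (i in ev) {
    k <- end_of[i]
    ll <- ll + eta[i] - log(s0[k])
    score <- score + x[i] - s1[k] / s0[k]
    info <- info + s2[k] / s0[k] - (s1[k] / s0[k])^2
  }
  list(loglik = ll, score = score, info = info)
}

#' Cox regression of relapse interval on DMP count
#'
#' Univariate Cox proportional-hazards fit with Breslow tie handling,
#' maximised by Newton-Raphson from 0 (convergence when the absolute
#' score drops below 1e-9, at most 50 iterations; step halving when a
#' step would decrease the partial likelihood). Time to relapse is the
#' outcome, the DMP count the covariate, and by default every patient is
#' an event (all relapsed); a censoring vector is accepted for
#' generality. The covariate is standardised internally (the score
#' criterion applies on the standardised scale) and the estimate and
#' standard error are mapped back, an exact reparameterisation.
#'
#' @param intervals Positive times to relapse (days).
#' @param dmp_counts Per-patient DMP counts (same order).
#' @param events Optional 0/1 event indicators (default all 1).
#' @param log1p_transform If `TRUE`, uses `log1p(dmp_counts)` as the
#'   covariate.
#' @return List of class `cox_fit`: `identifiable`, `coefficient`,
#'   `standard_error`, `wald_z`, `p_value` (two-sided),
#'   `log_partial_likelihood`, `log_partial_likelihood_null`,
#'   `n`, `n_events`, `iterations`, `converged`.
#' @export
cox_relapse_vs_dmps <- function(intervals, dmp_counts, events = NULL,
                                log1p_transform = FALSE) {
  stopifnot(length(intervals) == length(dmp_counts), all(intervals > 0))
  if (is.null(events)) events <- rep(1L, length(intervals))
  stopifnot(length(events) == length(intervals), all(events %in% c(0, 1)))
  x <- if (log1p_transform) log1p(dmp_counts) else as.numeric(dmp_counts)
  if (stats::var(x[events == 1]) == 0 || stats::var(x) == 0) {
    return(structure(list(identifiable = FALSE, coefficient = NA_real_,
                          standard_error = NA_real_, wald_z = NA_real_,
                          p_value = NA_real_,
                          log_partial_likelihood = NA_real_,
                          log_partial_likelihood_null = NA_real_,
                          n = length(x), n_events = sum(events),
                          iterations = 0L, converged = FALSE,
                          reason = "zero-variance covariate"),
                     class = "cox_fit"))
  }
  x_scale <- stats::sd(x)
  xc <- (x - mean(x)) / x_scale
  beta_hat <- 0
  q <- .cox_quantities(beta_hat, intervals, xc, events)
  ll_null <- q$loglik
  iter <- 0L
  converged <- abs(q$score) < 1e-9
  while (!converged && iter < 50L) {
    iter <- iter + 1L
    step <- q$score / q$info
    new_beta <- beta_hat + step
    q_new <- .cox_quantities(new_beta, intervals, xc, events)
    # halve only on decreases beyond floating-point noise in the loglik
    noise <- 1e-11 * (abs(q$loglik) + 1)
    halvings <- 0L
    while (q_new$loglik < q$loglik - noise && halvings < 30L) {
      step <- step / 2
      new_beta <- beta_hat + step
      q_new <- .cox_quantities(new_beta, intervals, xc, events)
      halvings <- halvings + 1L
    }
    beta_hat <- new_beta
    q <- q_new
    converged <- abs(q$score) < 1e-9
  }
  if (!converged)
    stop("Cox fit did not converge in 50 iterations (score = ",
         format(q$score), ", beta = ", format(beta_hat), ")")
  se <- 1 / sqrt(q$info)
  z <- beta_hat / se
  structure(list(identifiable = TRUE, coefficient = beta_hat / x_scale,
                 standard_error = se / x_scale, wald_z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 log_partial_likelihood = q$loglik,
                 log_partial_likelihood_null = ll_null,
                 n = length(x), n_events = sum(events),
                 iterations = iter, converged = TRUE),
            class = "cox_fit")
}
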