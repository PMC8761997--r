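#' Random-effects meta-analysis with REML between-study variance
#'
#' Pools per-study effect sizes under the random-effects model
#' `y_i ~ N(mu, se_i^2 + tau2)`.  The between-study variance `tau2` is
#' estimated by restricted maximum likelihood using the standard iterative
#' scheme (weights `w_i = 1/(se_i^2 + tau2)`, update
#' `tau2 <- sum(w^2 ((y - mu)^2 - se^2)) / sum(w^2) + 1/sum(w)`), floored at
#' zero, to tolerance `tol` within `max_iter` iterations.  The pooled effect
#' is the inverse-variance weighted mean at the converged `tau2`; Cochran's
#' Q uses fixed-effect weights with `k - 1` degrees of freedom.
#'
#' @param effects Numeric vector of per-study effect sizes (>= 2 studies).
#' @param ses Positive standard errors, same length.
#' @param tol Convergence tolerance on tau2 (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return List: pooled_effect, pooled_se, p, tau2, Q, p_Q, k, iterations.
#' @export
meta_random_effects <- function(effects, ses, tol = 1e-8, max_iter = 100L) {
  k <- length(effects)
  if (k < 2L) stop("need at least 2 studies", call. = FALSE)
  if (length(ses) != k || any(ses <= 0)) {
    stop("standard errors must be positive and match effects",
         call. = FALSE)
  }
  v <- ses^2
  # fixed-effect quantities and Cochran's Q
  w_fe <- 1 / v
  mu_fe <- sum(w_fe * effects) / sum(w_fe)
  Q <- sum(w_fe * (effects - mu_fe)^2)
  p_Q <- stats::pchisq(Q, df = k - 1L, lower.tail = FALSE)

  # REML iteration, started from the DerSimonian-Laird estimate
  tau2 <- max(0, (Q - (k - 1)) /
                (sum(w_fe) - sum(w_fe^2) / sum(w_fe)))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * effects) / sum(w)
    tau2_new <- sum(w^2 * ((effects - mu)^2 - v)) / sum(w^2) + 1 / sum(w)
    tau2_new <- max(0, tau2_new)
    trace <- c(trace, tau2_new)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    stop("REML iteration did not converge; tau2 trace: ",
         paste(signif(utils::tail(trace, 10), 6), collapse = ", "),
         call. = FALSE)
  }
  w <- 1 / (v + tau2)
  pooled <- sum(w * effects) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  z <- pooled / pooled_se
  list(pooled_effect = pooled, pooled_se = pooled_se,
       p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, Q = Q, p_Q = p_Q,
       k = k, iterations = length(trace))
}

#' Restricted log-likelihood of the random-effects model
#'
#' Exposed so that independent maximizers (grid search, `optimize()`) can
#' cross-check the REML iteration.
#'
#' @param tau2 Candidate between-study variance (>= 0).
#' @param effects,ses Study effects and standard errors.
#' @return The restricted log-likelihood at `tau2`.
#' @export
reml_loglik <- function(tau2, effects, ses) {
  v <- ses^2 + tau2
  w <- 1 / v
  mu <- sum(w * effects) / sum(w)
  -0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (effects - mu)^2))
}
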