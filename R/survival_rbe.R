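# Clonogenic survival processing, linear-quadratic fitting with
# uncertainties, isoeffect-dose solving and RBE estimation with
# delta-method error propagation.

#' Surviving fractions from colony counts
#'
#' Converts well-level colony counts into condition-level surviving
#' fractions. Within each run, the plating efficiency (PE) is the mean
#' colony-per-seeded-cell ratio of that run's 0 Gy control wells; each
#' well's surviving fraction is `(colonies / seeded) / PE`, so SF at
#' 0 Gy is 1 by construction per run. Conditions are then summarised by
#' their mean SF and a standard deviation.
#'
#' @param records Data frame of colony counts as produced by
#'   [generate_colony_counts()] (columns `mode`, `position`, `dose`,
#'   `run`, `well`, `seeded`, `colonies`).
#' @param sd_method How the condition-level SD is computed: `"pooled"`
#'   (default) takes the sample SD across all wells of the condition,
#'   pooled over runs, which keeps the uncertainty estimate
#'   well-determined when only two runs exist; `"runs"` first averages
#'   wells within each run and takes mean and SD across the run means.
#' @return A data frame of class `survival_observations` with columns
#'   `mode`, `position`, `dose`, `sf`, `sd`, `n` (replicates behind the
#'   SD), `zero_wells` (number of wells with zero colonies, retained
#'   in the mean but flagged) and `log_pe_var` (sampling variance of
#'   the condition's log plating efficiency — an error component shared
#'   by all doses of the condition, propagated by [fit_lq()]).
#' @examples
#' d <- experiment_design(seed = 11)
#' obs <- surviving_fractions(generate_colony_counts(d, lq_truth(0.26, 0.05)))
#' subset(obs, mode == "PBS" & position == 1)
#' @export
surviving_fractions <- function(records, sd_method = c("pooled", "runs")) {
  sd_method <- match.arg(sd_method)
  need <- c("mode", "position", "dose", "run", "seeded", "colonies")
  if (!all(need %in% names(records))) {
    stop_config("records must contain columns: ", paste(need, collapse = ", "))
  }
  records$cond <- label_condition(records$mode, records$position)
  out <- do.call(rbind, lapply(split(records, records$cond), function(cc) {
    do.call(rbind, lapply(split(cc, cc$run), function(rr) {
      ctrl <- rr[rr$dose == 0, ]
      if (!nrow(ctrl)) stop_config("run ", rr$run[1], " of condition ",
                                   rr$cond[1], " lacks 0 Gy controls")
      pe <- mean(ctrl$colonies / ctrl$seeded)
      if (pe <= 0) stop_config("zero control colonies in run ", rr$run[1],
                               " of condition ", rr$cond[1])
      rr$sf_well <- (rr$colonies / rr$seeded) / pe
      rr
    }))
  }))
  # Sampling variance of the log plating efficiency per condition: the
  # PE estimate is shared by every well of its run, so its error is a
  # common (fully correlated) component of all surviving fractions of
  # that condition. Recorded so fit_lq() can propagate it.
  pe_var <- vapply(split(records, records$cond), function(cc) {
    v_runs <- vapply(split(cc, cc$run), function(rr) {
      ratio <- rr$colonies[rr$dose == 0] / rr$seeded[rr$dose == 0]
      if (length(ratio) < 2) return(NA_real_)
      (stats::var(ratio) / length(ratio)) / mean(ratio)^2
    }, numeric(1))
    mean(v_runs) / length(v_runs)
  }, numeric(1))
  agg <- lapply(split(out, list(out$cond, out$dose), drop = TRUE),
                function(g) {
    by_run <- vapply(split(g$sf_well, g$run), mean, numeric(1))
    if (sd_method == "pooled") {
      s <- stats::sd(g$sf_well)
      n <- nrow(g)
    } else {
      s <- if (length(by_run) > 1) stats::sd(by_run) else NA_real_
      n <- length(by_run)
    }
    data.frame(mode = g$mode[1], position = g$position[1], dose = g$dose[1],
               sf = mean(by_run), sd = s, n = n,
               zero_wells = sum(g$colonies == 0),
               log_pe_var = unname(pe_var[g$cond[1]]))
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$mode, agg$position, agg$dose), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("survival_observations", "data.frame")
  agg
}

#' Construct survival observations directly
#'
#' For survival data already summarised as mean surviving fractions with
#' standard deviations (e.g. digitised or externally measured curves).
#'
#' @param dose Doses in Gy.
#' @param sf Mean surviving fractions (0 to 1.5; noise above 1 is
#'   tolerated at low dose).
#' @param sd Standard deviations (optional).
#' @param n Replicates per point.
#' @param mode,position Labels.
#' @return A `survival_observations` data frame.
#' @export
survival_observations <- function(dose, sf, sd = NA_real_, n = 1L,
                                  mode = "test", position = NA) {
  assert_number(dose, "dose", lower = 0)
  assert_number(sf, "sf")
  if (any(sf < 0 | sf > 1.5)) {
    stop_config("'sf' must lie in [0, 1.5]")
  }
  out <- data.frame(mode = mode, position = position, dose = dose,
                    sf = sf, sd = sd, n = n, zero_wells = 0L,
                    log_pe_var = 0)
  class(out) <- c("survival_observations", "data.frame")
  out
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of S(D) = exp(-alpha D - beta D^2) to survival
#' observations. The default works on the log-survival scale, where the
#' model is linear in (alpha, beta): y = -log(SF) = alpha D + beta D^2
#' with no intercept. Points are weighted by the inverse variance of
#' y derived from the replicate SDs (`se(y) = (sd/sqrt(n)) / SF`); when
#' any SD is missing or zero (e.g. the 0 Gy anchor, exact by
#' construction), unit weights are used for all points. If the
#' observations carry a `log_pe_var` column (see
#' [surviving_fractions()]), that shared plating-efficiency error is
#' added as a fully correlated off-diagonal component of the error
#' covariance and the fit becomes generalized least squares — without
#' it the parameter uncertainties of clonogenic data are
#' underestimated, because the PE error shifts the whole curve
#' coherently. Parameter standard errors come from the (generalized)
#' normal equations — treated as known-variance weights when
#' inverse-variance weighting is active, and scaled by the residual
#' variance otherwise. alpha and beta are constrained to be
#' non-negative (active-set clamping at the boundary).
#' `scale = "linear"` instead minimises untransformed-scale squared
#' residuals via Gauss-Newton with diagonal weights.
#'
#' @param observations A `survival_observations` data frame (at least 3
#'   distinct dose levels including doses > 0).
#' @param scale `"log"` (default) or `"linear"` fitting scale.
#' @param label Curve label carried into reports.
#' @return An object of class `lq_fit`: list with `alpha`, `beta`,
#'   `se_alpha`, `se_beta`, `cov_alpha_beta`, `r_squared` (computed on
#'   the fitting scale), `scale`, `label`, `n_points`.
#' @examples
#' obs <- survival_observations(c(0, 1, 3, 5),
#'                              exp(-(0.26 * c(0, 1, 3, 5) +
#'                                    0.05 * c(0, 1, 3, 5)^2)))
#' fit_lq(obs)   # recovers alpha = 0.26, beta = 0.05
#' @export
fit_lq <- function(observations, scale = c("log", "linear"), label = NULL) {
  scale <- match.arg(scale)
  obs <- as.data.frame(observations)
  if (length(unique(obs$dose)) < 3 || !any(obs$dose > 0)) {
    stop_config("need at least 3 distinct dose levels including doses > 0")
  }
  label <- label %||%
    label_condition(as.character(obs$mode[1]), as.character(obs$position[1]))
  if (any(obs$sf <= 0)) {
    stop_config("zero surviving fractions cannot be fitted; ",
                "remove or re-measure flagged wells")
  }
  fitted_pts <- obs[obs$dose > 0, , drop = FALSE]
  X <- cbind(fitted_pts$dose, fitted_pts$dose^2)
  y <- -log(fitted_pts$sf)
  se_y <- (fitted_pts$sd / sqrt(fitted_pts$n)) / fitted_pts$sf
  weighted <- all(is.finite(se_y)) && all(se_y > 0)
  # shared plating-efficiency error: a fully correlated component of
  # every log surviving fraction of the condition (see
  # surviving_fractions()); enters the error covariance off-diagonally
  pe_var <- if ("log_pe_var" %in% names(fitted_pts)) {
    fitted_pts$log_pe_var[1]
  } else 0
  if (!is.finite(pe_var)) pe_var <- 0
  w <- if (weighted) 1 / (se_y^2 + pe_var) else rep(1, nrow(fitted_pts))

  solve_gls <- function(X, y, W) {
    XtW <- t(X) %*% W
    xtx <- XtW %*% X
    coef <- drop(solve(xtx, XtW %*% y))
    # non-negativity: clamp and refit on the remaining column
    for (j in 1:2) {
      if (coef[j] < 0) {
        k <- 3 - j
        ck <- drop(X[, k] %*% W %*% y) / drop(X[, k] %*% W %*% X[, k])
        coef <- c(0, 0)
        coef[k] <- max(ck, 0)
      }
    }
    list(coef = coef, xtx_inv = solve(xtx))
  }

  if (scale == "log") {
    W <- if (weighted) {
      solve(diag(se_y^2, nrow(X)) + pe_var)
    } else {
      diag(nrow(X))
    }
    fit <- solve_gls(X, y, W)
    resid <- y - drop(X %*% fit$coef)
    dof <- max(nrow(X) - sum(fit$coef > 0), 1)
    s2 <- drop(t(resid) %*% W %*% resid) / dof
    vcov <- if (weighted) fit$xtx_inv else s2 * fit$xtx_inv
    tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
    r2 <- 1 - sum(w * resid^2) / tss
  } else {
    # Gauss-Newton on S(D) = exp(-aD - bD^2), started from the log fit
    coef <- solve_gls(X, y, diag(w, nrow(X)))$coef
    s_obs <- fitted_pts$sf
    for (it in 1:50) {
      s_hat <- exp(-drop(X %*% coef))
      J <- -X * s_hat
      r <- s_obs - s_hat
      delta <- tryCatch(drop(solve(t(J * w) %*% J, t(J * w) %*% r)),
                        error = function(e) NULL)
      if (is.null(delta)) stop_config("LQ fit failed to converge: singular ",
                                      "Jacobian at iteration ", it)
      coef <- pmax(coef + delta, 0)
      if (max(abs(delta)) < 1e-12) break
    }
    if (it == 50 && max(abs(delta)) >= 1e-8) {
      stop_config("LQ fit failed to converge after 50 Gauss-Newton steps; ",
                  "last step ", signif(max(abs(delta)), 3))
    }
    s_hat <- exp(-drop(X %*% coef))
    J <- -X * s_hat
    resid <- s_obs - s_hat
    dof <- max(nrow(X) - sum(coef > 0), 1)
    s2 <- sum(w * resid^2) / dof
    xtx_inv <- solve(t(J * w) %*% J)
    vcov <- if (weighted) xtx_inv else s2 * xtx_inv
    tss <- sum(w * (s_obs - stats::weighted.mean(s_obs, w))^2)
    r2 <- 1 - sum(w * resid^2) / tss
    fit <- list(coef = coef)
  }

  structure(
    list(alpha = fit$coef[1], beta = fit$coef[2],
         se_alpha = sqrt(vcov[1, 1]), se_beta = sqrt(vcov[2, 2]),
         cov_alpha_beta = vcov[1, 2], r_squared = r2,
         scale = scale, label = label, n_points = nrow(fitted_pts)),
    class = "lq_fit"
  )
}

#' Construct an LQ fit from known parameters
#'
#' Wraps externally estimated linear-quadratic parameters (for example a
#' published alpha/beta table) in the same `lq_fit` structure produced
#' by [fit_lq()], so they can feed [isoeffect_dose()] and
#' [compute_rbe()]. The alpha-beta covariance defaults to 0 because
#' published tables rarely report it.
#'
#' @param alpha,beta LQ parameters (Gy^-1, Gy^-2), non-negative, not
#'   both zero.
#' @param se_alpha,se_beta Standard errors (default 0).
#' @param cov_alpha_beta Covariance of the estimates (default 0).
#' @param r_squared Goodness of fit if known.
#' @param label Curve label.
#' @return An `lq_fit` object.
#' @examples
#' lq_fit(0.17, 0.03, label = "Co60")
#' @export
lq_fit <- function(alpha, beta, se_alpha = 0, se_beta = 0,
                   cov_alpha_beta = 0, r_squared = NA_real_, label = "") {
  assert_number(alpha, "alpha", lower = 0)
  assert_number(beta, "beta", lower = 0)
  assert_number(se_alpha, "se_alpha", lower = 0)
  assert_number(se_beta, "se_beta", lower = 0)
  if (alpha == 0 && beta == 0) stop_config("alpha and beta cannot both be zero")
  v <- matrix(c(se_alpha^2, cov_alpha_beta, cov_alpha_beta, se_beta^2), 2)
  if (min(eigen(v, only.values = TRUE)$values) < -1e-12) {
    stop_config("covariance matrix must be positive semidefinite")
  }
  structure(
    list(alpha = alpha, beta = beta, se_alpha = se_alpha, se_beta = se_beta,
         cov_alpha_beta = cov_alpha_beta, r_squared = r_squared,
         scale = "external", label = label, n_points = NA_integer_),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("LQ fit [%s]: alpha = %.4g +- %.3g Gy^-1, beta = %.4g +- %.3g Gy^-2",
              x$label, x$alpha, x$se_alpha, x$beta, x$se_beta))
  if (is.finite(x$r_squared)) cat(sprintf(", R^2 = %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Isoeffective dose at a survival level
#'
#' Solves exp(-alpha D - beta D^2) = S for the positive dose:
#' `D = (-alpha + sqrt(alpha^2 + 4 beta log(1/S))) / (2 beta)`, reducing
#' to `log(1/S)/alpha` when beta = 0.
#'
#' @param fit An `lq_fit`.
#' @param survival_level Target surviving fraction, in (0, 1).
#' @return Dose in Gy.
#' @examples
#' isoeffect_dose(lq_fit(log(2), 0), 0.5)        # 1 Gy
#' isoeffect_dose(lq_fit(0.17, 0.03), 0.5)       # ~2.75 Gy
#' @export
isoeffect_dose <- function(fit, survival_level) {
  stopifnot(inherits(fit, "lq_fit"))
  assert_number(survival_level, "survival_level")
  if (survival_level <= 0 || survival_level >= 1) {
    stop_config("'survival_level' must lie strictly in (0, 1)")
  }
  a <- fit$alpha; b <- fit$beta
  if (a == 0 && b == 0) stop_config("degenerate fit: alpha = beta = 0")
  eff <- log(1 / survival_level)
  if (b == 0) return(eff / a)
  (-a + sqrt(a^2 + 4 * b * eff)) / (2 * b)
}

# Gradient of the isoeffect dose in (alpha, beta); beta = 0 handled by
# the analytic limit.
isoeffect_grad <- function(alpha, beta, eff) {
  if (beta == 0) {
    return(c(-eff / alpha^2, -eff^2 / alpha^3))
  }
  q <- sqrt(alpha^2 + 4 * beta * eff)
  d <- (q - alpha) / (2 * beta)
  c((alpha / q - 1) / (2 * beta),
    eff / (beta * q) - d / beta)
}

#' Relative biological effectiveness at a survival level
#'
#' RBE = D_ref(S) / D_test(S): the ratio of the reference-radiation dose
#' to the test-radiation dose producing the same surviving fraction S,
#' both solved from the fitted LQ parameters. The standard error is
#' propagated to first order (delta method) through both isoeffect
#' doses, using each fit's alpha-beta covariance and treating the two
#' fits as independent.
#'
#' @param reference An `lq_fit` for the reference radiation (e.g. Co-60
#'   gamma rays).
#' @param test An `lq_fit` for the test radiation.
#' @param survival_level Surviving fraction at which the comparison is
#'   made (default 0.5).
#' @return An `rbe_estimate`: list with `rbe`, `se`, `survival_level`,
#'   `reference`, `test`, `iso_dose_ref`, `iso_dose_test`.
#' @examples
#' co <- lq_fit(0.17, 0.03, 3.25e-2, 9.99e-3, label = "Co60")
#' pbs1 <- lq_fit(0.26, 0.05, 1.13e-3, 2.77e-2, label = "PBS1")
#' compute_rbe(co, pbs1)   # ~1.41 at 50% survival
#' @export
compute_rbe <- function(reference, test, survival_level = 0.5) {
  stopifnot(inherits(reference, "lq_fit"), inherits(test, "lq_fit"))
  d_ref <- isoeffect_dose(reference, survival_level)
  d_test <- isoeffect_dose(test, survival_level)
  rbe <- d_ref / d_test
  eff <- log(1 / survival_level)
  var_d <- function(fit) {
    g <- isoeffect_grad(fit$alpha, fit$beta, eff)
    v <- matrix(c(fit$se_alpha^2, fit$cov_alpha_beta,
                  fit$cov_alpha_beta, fit$se_beta^2), 2)
    drop(t(g) %*% v %*% g)
  }
  rel_var <- var_d(reference) / d_ref^2 + var_d(test) / d_test^2
  structure(
    list(rbe = rbe, se = rbe * sqrt(rel_var),
         survival_level = survival_level,
         reference = reference$label, test = test$label,
         iso_dose_ref = d_ref, iso_dose_test = d_test),
    class = "rbe_estimate"
  )
}

#' @export
print.rbe_estimate <- function(x, ...) {
  cat(sprintf(
    "RBE_%d%% [%s vs %s]: %.3f +- %.3f  (iso doses %.3f / %.3f Gy)\n",
    round(100 * x$survival_level), x$test, x$reference, x$rbe, x$se,
    x$iso_dose_ref, x$iso_dose_test))
  invisible(x)
}
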