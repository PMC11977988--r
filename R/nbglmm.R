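#' Maximum likelihood for the NB2 random-intercept model
#'
#' Fits `y_ij | b_i ~ NB2(mu_ij, alpha)`, `log mu_ij = x_ij' beta + b_i`,
#' `b_i ~ N(0, sigma_b^2)`, by maximising the marginal likelihood with the
#' random intercept integrated out per group by adaptive Gauss-Hermite
#' quadrature. The optimiser is quasi-Newton (PORT, via [stats::nlminb()])
#' on `(beta, log alpha, log sigma_b)` with starting values from a Poisson
#' GLM for `beta`, `alpha = 1` and `sigma_b = 0.5`; convergence tolerance is
#' `reltol` on the relative log-likelihood change. `log sigma_b` is bounded
#' below (sigma_b ~ 1e-3) so the fit degrades gracefully to a plain NB
#' regression when the data carry no between-group variance.
#'
#' @param y Non-negative integer response vector.
#' @param X Model matrix (must include an intercept column).
#' @param group Group (participant) identifier vector, one per row.
#' @param nodes Number of quadrature nodes (default 11, minimum 9 for the
#'   accuracy the pipeline relies on; estimates are stable from 9 up).
#' @param reltol Relative convergence tolerance (default 1e-6).
#' @param start Optional full start vector `c(beta, log_alpha, log_sigma)`.
#' @param sigma_fixed Optional fixed value for `sigma_b` instead of
#'   estimating it; `0` pins the random intercept out of the model, reducing
#'   the fit to a plain NB regression.
#' @return List with elements `beta`, `se`, `vcov`, `alpha`, `sigma_b`,
#'   `loglik`, `converged`, `n_obs`, `n_groups`, `nodes`.
#' @export
nbglmm_ml <- function(y, X, group, nodes = 11, reltol = 1e-6, start = NULL,
                      sigma_fixed = NULL) {
  stopifnot(length(y) == nrow(X), length(group) == length(y))
  if (anyNA(y)) stop("nbglmm_ml: response has missing values")
  if (all(y == 0)) stop("nbglmm_ml: response is all zero")
  p <- ncol(X)
  ord <- order(match(group, unique(group)))
  y <- as.numeric(y[ord])
  X <- X[ord, , drop = FALSE]
  group <- group[ord]
  r <- rle(as.character(group))
  gend <- cumsum(r$lengths)
  gstart <- gend - r$lengths + 1L

  gh <- pracma::gaussHermite(nodes)
  gh_logw <- log(gh$w) + gh$x^2

  if (is.null(start)) {
    b0 <- suppressWarnings(glm.fit(X, y, family = poisson())$coefficients)
    b0[is.na(b0)] <- 0
    start <- c(b0, 0, log(0.5))
  }
  lower <- c(rep(-Inf, p), -10, -7)
  upper <- c(rep(Inf, p), 10, 3)
  if (!is.null(sigma_fixed)) {
    ls_fix <- max(log(max(sigma_fixed, 0)), -7)
    lower[p + 2] <- upper[p + 2] <- ls_fix
    start[p + 2] <- ls_fix
  }

  fn <- function(par) {
    v <- nbglmm_nll_cpp(y, X, gstart - 1L, gend - 1L, par[seq_len(p)],
                        par[p + 1], par[p + 2], gh$x, gh_logw)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- nlminb(start, fn, lower = lower, upper = upper,
                control = list(rel.tol = reltol, iter.max = 500,
                               eval.max = 2000))

  par <- opt$par
  H <- tryCatch(optimHess(par, fn), error = function(e) NULL)
  vc <- matrix(NA_real_, p + 2, p + 2)
  ok <- FALSE
  if (!is.null(H)) {
    vi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vi) && all(is.finite(diag(vi)[seq_len(p)])) &&
        all(diag(vi)[seq_len(p)] > 0)) {
      vc <- vi
      ok <- TRUE
    } else {
      # variance parameters at a boundary make H singular; invert the
      # fixed-effect block conditional on them
      at_bound <- c(rep(FALSE, p), abs(par[p + 1:2] - lower[p + 1:2]) < 1e-6 |
                      abs(par[p + 1:2] - upper[p + 1:2]) < 1e-6)
      idx <- which(!at_bound)
      vi <- tryCatch(solve(H[idx, idx, drop = FALSE]), error = function(e) NULL)
      if (!is.null(vi) && all(diag(vi)[seq_len(p)] > 0)) {
        vc[idx, idx] <- vi
        ok <- TRUE
      }
    }
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- c(colnames(X), "log_alpha", "log_sigma")
  beta <- setNames(par[seq_len(p)], colnames(X))

  list(beta = beta, se = se[seq_len(p)], vcov = vc,
       alpha = exp(par[p + 1]), sigma_b = exp(par[p + 2]),
       loglik = -opt$objective,
       converged = opt$convergence == 0 && ok,
       n_obs = length(y), n_groups = length(gstart), nodes = nodes)
}

#' Fit the transition-effect NB mixed model to an analysis panel
#'
#' Fits a mixed-effects negative binomial regression with a random intercept
#' per participant to the panel's person-days. The fixed effects are an
#' intercept and the pre/post indicator, optionally plus six weekday
#' contrasts (reference = the panel's modal transition weekday, so the post
#' effect is interpretable at the weekday upgrades typically happen on).
#' Outcomes are rounded to the nearest non-negative integer for the count
#' likelihood. The rate ratio is `exp(beta_post)` with a 95% Wald interval
#' on the log scale; no interval is reported when the fit did not converge.
#'
#' @param panel An analysis panel from [build_panels()] or
#'   [simulate_panel()].
#' @param outcome `"exercise_minutes"` or `"active_calories"`.
#' @param adjust_weekday Add weekday contrasts? (default `FALSE`).
#' @param stratum `"overall"`, `"female"` or `"male"`.
#' @param nodes Quadrature nodes (default 11).
#' @param reltol Convergence tolerance.
#' @return Object of class `nb_glmm` (see [as_model_result()] for the tidy
#'   one-row form).
#' @export
fit_nb_glmm <- function(panel, outcome = c("exercise_minutes", "active_calories"),
                        adjust_weekday = FALSE,
                        stratum = c("overall", "female", "male"),
                        nodes = 11, reltol = 1e-6) {
  outcome <- match.arg(outcome)
  stratum <- match.arg(stratum)
  d <- panel
  if (stratum != "overall") d <- filter(d, .data$sex == stratum)
  if (nrow(d) == 0) stop(sprintf("fit_nb_glmm: empty panel for stratum '%s'", stratum))
  y <- pmax(0, round(d[[outcome]]))
  if (anyNA(y)) stop(sprintf("fit_nb_glmm: outcome '%s' has missing values", outcome))
  if (all(y == 0)) stop("fit_nb_glmm: outcome is all zero")

  if (adjust_weekday) {
    ref <- names(sort(table(as.character(d$transition_weekday)),
                      decreasing = TRUE))[1]
    wd <- factor(as.character(d$weekday),
                 levels = c(ref, setdiff(.weekday_levels, ref)))
    wd <- droplevels(wd)
    X <- model.matrix(~ post + weekday, data = tibble::tibble(post = d$post,
                                                              weekday = wd))
  } else {
    X <- model.matrix(~ post, data = tibble::tibble(post = d$post))
  }

  fit <- nbglmm_ml(y, X, d$participant_id, nodes = nodes, reltol = reltol)
  b1 <- fit$beta[["post"]]
  se1 <- fit$se[["post"]]
  z <- qnorm(0.975)
  structure(list(
    rate_ratio = exp(b1),
    ci_low = if (fit$converged) exp(b1 - z * se1) else NA_real_,
    ci_high = if (fit$converged) exp(b1 + z * se1) else NA_real_,
    beta = fit$beta, se = fit$se, vcov = fit$vcov,
    alpha = fit$alpha, sigma_b = fit$sigma_b, loglik = fit$loglik,
    converged = fit$converged,
    n_participants = fit$n_groups, n_days = fit$n_obs,
    outcome = outcome, adjusted = adjust_weekday, stratum = stratum,
    label = if (nrow(d)) as.character(d$label[1]) else NA_character_,
    window_type = if (nrow(d)) as.character(d$window_type[1]) else NA_character_,
    nodes = nodes
  ), class = "nb_glmm")
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf("NB mixed model (%s, %s, %s, %s)\n", x$label, x$window_type,
              x$outcome, x$stratum))
  cat(sprintf("  RR = %.3f (95%% CI %.3f, %.3f)%s\n", x$rate_ratio,
              x$ci_low, x$ci_high,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  alpha = %.3f, sigma_b = %.3f, logLik = %.2f, n = %d participants / %d days\n",
              x$alpha, x$sigma_b, x$loglik, x$n_participants, x$n_days))
  invisible(x)
}

#' Tidy one-row summary of a fitted model
#'
#' @param fit An `nb_glmm` object.
#' @return One-row tibble with label, window, outcome, stratum, adjustment,
#'   sample sizes, `rr`, `ci_low`, `ci_high`, full-precision `log_rr` and
#'   `se_log_rr`, dispersion, random-intercept SD, log-likelihood and the
#'   convergence flag.
#' @export
as_model_result <- function(fit) {
  stopifnot(inherits(fit, "nb_glmm"))
  tibble::tibble(
    label = fit$label, window_type = fit$window_type, outcome = fit$outcome,
    stratum = fit$stratum, adjusted = fit$adjusted,
    n_participants = fit$n_participants, n_days = fit$n_days,
    rr = fit$rate_ratio, ci_low = fit$ci_low, ci_high = fit$ci_high,
    log_rr = unname(fit$beta[["post"]]), se_log_rr = unname(fit$se[["post"]]),
    alpha = fit$alpha, sigma_b = fit$sigma_b, loglik = fit$loglik,
    converged = fit$converged
  )
}
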