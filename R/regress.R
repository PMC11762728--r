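#' Compress unit-interval responses away from the boundary
#'
#' Band-level mean diversification rates can be exactly 0 (bands holding
#' only monospecific genera), which the beta likelihood cannot accommodate.
#' When any response sits on the boundary, the whole vector is compressed
#' by the usual `(y * (n - 1) + 0.5) / n` transformation; otherwise it is
#' returned untouched.
#'
#' @param y Numeric vector in `[0, 1]`.
#' @return Vector strictly inside `(0, 1)`.
#' @export
compress_unit_interval <- function(y) {
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  n <- length(y)
  if (any(y <= 0 | y >= 1)) (y * (n - 1) + 0.5) / n else y
}

# Beta log-likelihood, mean-precision parameterization:
# shapes mu*phi and (1-mu)*phi, logit link on mu, constant phi.
.beta_loglik <- function(par, X, y) {
  p <- ncol(X)
  eta <- as.numeric(X %*% par[seq_len(p)])
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  phi <- exp(par[p + 1L])
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

.beta_score <- function(par, X, y) {
  p <- ncol(X)
  eta <- as.numeric(X %*% par[seq_len(p)])
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  phi <- exp(par[p + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  d_beta <- as.numeric(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  d_phi <- sum(mu * (ystar - mustar) + log1p(-y) -
                 digamma((1 - mu) * phi) + digamma(phi))
  c(d_beta, d_phi * phi)  # chain rule for log(phi)
}

#' Beta regression by maximum likelihood
#'
#' Fits a beta regression with logit mean link and constant precision
#' `phi` (mean-precision parameterization: density shape parameters
#' `mu * phi` and `(1 - mu) * phi`). Mean coefficients are initialized
#' from least squares on the logit-transformed response and `phi` by
#' method of moments; the likelihood is maximized by BFGS with analytic
#' score, followed by Newton polishing until the Newton decrement (the
#' projected log-likelihood gain of one more step) drops below `grad_tol`.
#'
#' @param formula Model formula, e.g. `div_elev ~ bio1 + I(bio1^2)`.
#' @param data Data frame holding the variables.
#' @param grad_tol Convergence tolerance on the Newton decrement
#'   (log-likelihood units). Default `1e-8`.
#' @param maxit Maximum BFGS iterations (plus up to 50 Newton polish
#'   steps).
#' @return A `beta_fit` object: `coefficients`, `phi`, `se` (Wald, from
#'   the observed information, including `log(phi)`), `vcov`, `logLik`,
#'   `pseudo_r2`, `n`, `k` (number of free parameters incl. `phi`),
#'   `fitted`, `linear_predictor`, `terms`, `converged`, `iterations`.
#' @references Ferrari, S. & Cribari-Neto, F. (2004) Beta regression for
#'   modelling rates and proportions. J. Applied Statistics 31, 799-815.
#' @export
beta_fit <- function(formula, data, grad_tol = 1e-8, maxit = 500) {
  mf <- stats::model.frame(formula, data)
  y0 <- stats::model.response(mf)
  if (any(y0 < 0 | y0 > 1))
    stop("beta regression responses must lie in [0, 1] before compression")
  y <- compress_unit_interval(y0)
  Xraw <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(Xraw)
  if (n <= p + 1L) stop("need n > number of parameters")

  # standardize non-intercept columns for a well-conditioned optimization
  # (estimates and covariance are mapped back to the raw scale below)
  has_int <- colnames(Xraw)[1L] == "(Intercept)"
  ctr <- rep(0, p); scl <- rep(1, p)
  X <- Xraw
  if (has_int && p > 1L) {
    for (j in 2:p) {
      ctr[j] <- mean(Xraw[, j])
      s <- stats::sd(Xraw[, j])
      scl[j] <- if (is.finite(s) && s > 0) s else 1
      X[, j] <- (Xraw[, j] - ctr[j]) / scl[j]
    }
  }

  # init: OLS on logit(y); phi by method of moments via the delta method
  ystar <- stats::qlogis(y)
  ols <- stats::lm.fit(X, ystar)
  beta0 <- ols$coefficients
  mu0 <- stats::plogis(as.numeric(X %*% beta0))
  sig2 <- sum(ols$residuals^2) / max(1, n - p)
  var_y <- pmax(sig2 * (mu0 * (1 - mu0))^2, 1e-10)
  phi0 <- max(mean(mu0 * (1 - mu0) / var_y - 1), 1)

  # log(phi) is bounded above: a degenerate (zero-dispersion) response
  # drives phi to infinity, where the likelihood is unbounded
  log_phi_max <- 30
  par0 <- c(beta0, min(log(phi0), log_phi_max - 1))
  opt <- stats::optim(par0, fn = .beta_loglik, gr = .beta_score,
                      X = X, y = y, method = "L-BFGS-B",
                      lower = rep(-Inf, p + 1L),
                      upper = c(rep(Inf, p), log_phi_max),
                      control = list(fnscale = -1, maxit = maxit,
                                     factr = 10))
  par <- opt$par
  iter <- opt$counts[["function"]]
  at_boundary <- par[p + 1L] >= log_phi_max - 1e-6
  # Newton polish on the analytic score; convergence is judged by the
  # Newton decrement (projected log-likelihood gain), which is invariant
  # to the scale of the parameters and of phi.
  decr <- Inf
  if (!at_boundary) {
    for (it in seq_len(50L)) {
      sc <- .beta_score(par, X, y)
      H <- stats::optimHess(par, .beta_loglik, .beta_score, X = X, y = y)
      step <- tryCatch(solve(H, sc), error = function(e) NULL)
      if (is.null(step)) break
      decr <- abs(sum(sc * step)) / 2
      if (!is.finite(decr) || decr < grad_tol) break
      # step-halve while the likelihood would drop or leave the domain
      cur <- .beta_loglik(par, X, y)
      h <- 1
      repeat {
        cand <- .beta_loglik(par - h * step, X, y)
        if (is.finite(cand) && cand >= cur - 1e-12) break
        h <- h / 2
        if (h <= 1e-4) break
      }
      par <- par - h * step
      if (par[p + 1L] >= log_phi_max) {
        par[p + 1L] <- log_phi_max
        at_boundary <- TRUE
        iter <- iter + 1L
        break
      }
      iter <- iter + 1L
    }
  }
  converged <- at_boundary || (is.finite(decr) && decr < grad_tol)
  if (!converged && decr > 1e-4)
    stop("beta_fit did not converge: Newton decrement = ",
         signif(decr, 3), " after ", iter, " iterations")

  H <- stats::optimHess(par, .beta_loglik, .beta_score, X = X, y = y)
  vc_std <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, p + 1L, p + 1L))
  # map standardized-scale estimates/covariance back to the raw scale:
  # beta_raw = T beta_std with T the affine de-standardization
  Tm <- diag(p + 1L)
  if (has_int && p > 1L) {
    for (j in 2:p) {
      Tm[j, j] <- 1 / scl[j]
      Tm[1L, j] <- -ctr[j] / scl[j]
    }
  }
  par_raw <- as.numeric(Tm %*% par)
  vc <- Tm %*% vc_std %*% t(Tm)
  coefs <- stats::setNames(par_raw[seq_len(p)], colnames(Xraw))
  eta <- as.numeric(X %*% par[seq_len(p)])
  ll <- .beta_loglik(par, X, y)
  fit <- list(
    coefficients = coefs,
    phi = exp(par[p + 1L]),
    se = stats::setNames(sqrt(pmax(diag(vc), 0)),
                         c(colnames(X), "log_phi")),
    vcov = vc,
    logLik = ll,
    n = n, k = p + 1L,
    linear_predictor = eta,
    fitted = stats::plogis(eta),
    y = y,
    terms = colnames(X),
    family = "beta",
    converged = converged,
    iterations = iter
  )
  class(fit) <- "beta_fit"
  fit$pseudo_r2 <- pseudo_r2(fit, y)
  fit
}

#' Ferrari-Cribari-Neto pseudo-R2
#'
#' Squared Pearson correlation between the linear predictor and the
#' link-transformed (logit) observed response.
#'
#' @param fit A `beta_fit` object.
#' @param y Observed responses in `(0, 1)`; defaults to the responses the
#'   model was fitted to (after boundary compression).
#' @return Value in `[0, 1]`, or `NA` when either vector has zero
#'   variance.
#' @export
pseudo_r2 <- function(fit, y = fit$y) {
  eta <- fit$linear_predictor
  if (length(eta) != length(y)) stop("fit and y are dimensionally inconsistent")
  if (stats::sd(eta) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(eta, stats::qlogis(y))^2
}

# Continuous extension of the Poisson log-likelihood: lgamma(y + 1)
# replaces log(y!), so the quasi-likelihood fit on continuous ages still
# carries a well-defined likelihood for LR tests and AICc.
.pois_loglik_cont <- function(y, mu) {
  sum(y * log(mu) - mu - lgamma(y + 1))
}

#' Identity-link GLM with Poisson variance
#'
#' Fits mean genus age (or any nonnegative response) against predictors by
#' iteratively reweighted least squares with Poisson variance and identity
#' link, so coefficients live on the response (Ma) scale. Continuous
#' responses are handled by quasi-likelihood scoring with the Poisson
#' deviance extended continuously; `rounding = TRUE` instead rounds the
#' response to integers for a strict Poisson likelihood.
#'
#' @param formula Model formula, e.g. `age_elev ~ bio1 + I(bio1^2)`.
#' @param data Data frame holding the variables.
#' @param rounding Round the response to integers before fitting.
#' @return A `glm_fit` object: `coefficients`, `se`, `p_values`,
#'   `deviance`, `null_deviance`, `logLik` (continuous-Poisson),
#'   `aic`, `aicc`, `kl_r2` (`1 - deviance/null deviance`, the
#'   Kullback-Leibler-divergence-based R2 for GLMs; 0 by convention for a
#'   saturated-null tie), `n`, `k`, `fitted`, `terms`.
#' @export
glm_fit <- function(formula, data, rounding = FALSE) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("responses must be nonnegative")
  if (rounding) y <- round(y)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need n > number of parameters")

  start <- stats::lm.fit(X, y)$coefficients
  if (any(as.numeric(X %*% start) <= 0))
    start <- c(max(mean(y), 1e-3), rep(0, p - 1L))
  dat <- data.frame(.y = y, X[, -1L, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(
    paste(".y ~", if (p > 1L)
      paste(sprintf("`%s`", colnames(X)[-1L]), collapse = " + ") else "1"))
  g <- tryCatch(
    stats::glm(fml, data = dat,
               family = stats::quasi(link = "identity", variance = "mu"),
               start = start,
               control = stats::glm.control(maxit = 100)),
    error = function(e)
      stop("identity-link Poisson-variance fit failed (fitted mean likely ",
           "driven <= 0): ", conditionMessage(e), call. = FALSE))
  mu <- stats::fitted(g)
  if (any(mu <= 0))
    warning("constrained step: some fitted means are <= 0; ",
            "likelihood quantities are unreliable", call. = FALSE)
  sm <- summary(g)
  ll <- .pois_loglik_cont(y, pmax(mu, .Machine$double.eps))
  dev <- g$deviance
  ndev <- g$null.deviance
  kl_r2 <- if (ndev <= .Machine$double.eps^0.5) 0 else
    max(0, min(1, 1 - dev / ndev))
  fit <- list(
    coefficients = stats::setNames(stats::coef(g), colnames(X)),
    se = stats::setNames(sm$coefficients[, "Std. Error"], colnames(X)),
    p_values = stats::setNames(sm$coefficients[, 4L], colnames(X)),
    deviance = dev,
    null_deviance = ndev,
    logLik = ll,
    aic = -2 * ll + 2 * p,
    aicc = aicc(ll, p, n),
    kl_r2 = kl_r2,
    n = n, k = p,
    fitted = as.numeric(mu),
    y = y,
    terms = colnames(X),
    family = "poisson_identity",
    glm = g
  )
  class(fit) <- "glm_fit"
  fit
}

#' Stationary point of a quadratic linear predictor
#'
#' For a fitted term pair `beta1 * x + beta2 * x^2`, the stationary point
#' is `-beta1 / (2 * beta2)`: a maximum (hump) when `beta2 < 0`, a minimum
#' (U shape) when `beta2 > 0`. Used to locate the temperature at which a
#' hump-shaped genus-age curve peaks.
#'
#' @param beta1 Coefficient on the linear term, or a `beta_fit`/`glm_fit`
#'   object (then `term` selects the predictor).
#' @param beta2 Coefficient on the squared term (ignored when `beta1` is a
#'   fit object).
#' @param term Predictor name when extracting from a fit; its square must
#'   appear as `I(term^2)` or `term^2` among the fit terms.
#' @return List with `x` (the stationary point) and `type`
#'   (`"maximum"`/`"minimum"`).
#' @export
quadratic_vertex <- function(beta1, beta2 = NULL, term = NULL) {
  if (is.list(beta1) && !is.null(beta1$coefficients)) {
    fit <- beta1
    if (is.null(term)) stop("supply 'term' when passing a fit object")
    sq <- intersect(c(sprintf("I(%s^2)", term), sprintf("%s^2", term)),
                    names(fit$coefficients))
    if (!term %in% names(fit$coefficients) || length(sq) == 0L)
      stop("fit does not contain terms '", term, "' and its square")
    beta2 <- fit$coefficients[[sq[1L]]]
    beta1 <- fit$coefficients[[term]]
  }
  if (is.null(beta2) || beta2 == 0) stop("no vertex: quadratic coefficient is 0")
  list(x = -beta1 / (2 * beta2),
       type = if (beta2 < 0) "maximum" else "minimum")
}

#' Likelihood-ratio test of nested fits
#'
#' Compares two fits of the same family on the same data, requiring the
#' smaller model's terms to be a subset of the larger's. The statistic is
#' `2 * (logL_large - logL_small)` on a chi-squared distribution with
#' df equal to the difference in parameter counts; the AICc difference
#' (small minus large) is reported alongside.
#'
#' @param fit_small,fit_large `beta_fit` or `glm_fit` objects.
#' @return List with `statistic`, `df`, `p`, `delta_aicc`, `preferred`
#'   (by lower AICc).
#' @export
lr_test <- function(fit_small, fit_large) {
  if (!all(fit_small$terms %in% fit_large$terms))
    stop("models are not nested: terms ",
         paste(setdiff(fit_small$terms, fit_large$terms), collapse = ", "),
         " absent from the larger model")
  if (fit_small$n != fit_large$n)
    stop("models were fitted to different numbers of observations")
  stat <- 2 * (fit_large$logLik - fit_small$logLik)
  df <- fit_large$k - fit_small$k
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  a_small <- aicc(fit_small$logLik, fit_small$k, fit_small$n)
  a_large <- aicc(fit_large$logLik, fit_large$k, fit_large$n)
  list(statistic = stat, df = df, p = p,
       delta_aicc = a_small - a_large,
       preferred = if (a_large < a_small) "large" else "small")
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`; the small-sample
#' correction vanishes as `n` grows.
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (`n > k + 1`).
#' @return AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Parse a model-specification string
#'
#' Turns config strings like `"div_elev ~ bio1 + bio1^2"` into an R
#' formula with protected polynomial terms (`I(bio1^2)`).
#'
#' @param spec Character model specification.
#' @return A formula.
#' @export
parse_model_spec <- function(spec) {
  protected <- gsub("(\\w+)\\^([0-9]+)", "I(\\1^\\2)", spec)
  stats::as.formula(protected, env = baseenv())
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta regression (logit link, constant precision)\n")
  print(data.frame(estimate = x$coefficients,
                   se = x$se[seq_along(x$coefficients)]))
  cat(sprintf("phi = %.3f | logLik = %.3f | pseudo-R2 = %.3f | n = %d\n",
              x$phi, x$logLik, x$pseudo_r2, x$n))
  invisible(x)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM, Poisson variance, identity link\n")
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_values))
  cat(sprintf("deviance = %.3f (null %.3f) | KL-R2 = %.3f | AICc = %.2f | n = %d\n",
              x$deviance, x$null_deviance, x$kl_r2, x$aicc, x$n))
  invisible(x)
}
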