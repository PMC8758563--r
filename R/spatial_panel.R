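# ---- panel assembly ----------------------------------------------------

# Build stacked (time-major) response and regressor matrices from a
# formula + long data frame, aligned with the weight-matrix labels.
.build_panel <- function(formula, data, W, index = c("unit", "year")) {
  w <- .as_w(W)
  labels <- if (inherits(W, "spatial_weights")) W$labels
            else rownames(w)
  if (!all(index %in% names(data)))
    stop("index columns not found: ", paste(index, collapse = ", "))
  un <- as.character(data[[index[1]]]); yr <- data[[index[2]]]
  if (is.null(labels)) labels <- sort(unique(un))
  if (!all(unique(un) %in% labels))
    stop("units in data not present in weight matrix")
  years <- sort(unique(yr))
  n <- length(labels); Tn <- length(years)
  if (nrow(data) != n * Tn) stop("unbalanced panel: need one row per unit-year")
  o <- order(match(yr, years), match(un, labels))   # time-major
  d <- data[o, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, d)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  list(y = y, X = X, w = w, labels = labels, years = years,
       n = n, T = Tn)
}

# Stable interval for the spatial coefficient from the eigenvalues of W
# (degenerate all-zero W gets the conventional (-1, 1)).
.rho_interval <- function(ev) {
  c(if (min(ev) < 0) 1 / min(ev) else -1,
    if (max(ev) > 0) 1 / max(ev) else 1)
}

# Apply W per time period to a stacked (time-major) vector or matrix.
.wlag <- function(v, w, n, Tn) {
  if (is.matrix(v)) {
    out <- v
    for (t in seq_len(Tn)) {
      idx <- (t - 1L) * n + seq_len(n)
      out[idx, ] <- w %*% v[idx, , drop = FALSE]
    }
    out
  } else {
    out <- numeric(length(v))
    for (t in seq_len(Tn)) {
      idx <- (t - 1L) * n + seq_len(n)
      out[idx] <- drop(w %*% v[idx])
    }
    out
  }
}

# Within transformation of a stacked vector/matrix.
.within <- function(v, n, Tn, effects) {
  if (effects %in% c("none", "random")) return(v)
  M <- matrix(if (is.matrix(v)) v[, 1] else v, n, Tn)
  tr1 <- function(col) {
    M <- matrix(col, n, Tn)
    out <- switch(effects,
      time = sweep(M, 2, colMeans(M)),
      individual = sweep(M, 1, rowMeans(M)),
      twoway = sweep(sweep(M, 2, colMeans(M)), 1, rowMeans(M)) +
               mean(M))
    as.vector(out)
  }
  if (is.matrix(v)) apply(v, 2, tr1) else tr1(v)
}

# ---- maximum-likelihood spatial panel fits ------------------------------

#' Fit a spatial panel model by maximum likelihood
#'
#' Fits pooled OLS, the spatial lag model (SLM), spatial error model (SEM)
#' or spatial Durbin model (SDM, regressors X and WX) on a balanced panel,
#' with fixed effects removed by the within transformation (time,
#' individual or two-way demeaning) or, for \code{model = "ols"}, a
#' Swamy-Arora random-effects GLS. The spatial coefficient is found by
#' concentrated log-likelihood over its stable interval, with the
#' log-determinant evaluated exactly through the eigenvalues of W (one
#' cross-section is small). Standard errors come from the numerical
#' Hessian of the full log-likelihood.
#'
#' @param formula model formula, e.g. \code{eff ~ Pgdp + Urb + Med}.
#' @param data long data frame, one row per unit-year.
#' @param W spatial weights (row-standardised recommended).
#' @param index names of the unit and time columns.
#' @param model \code{"sdm"}, \code{"slm"}, \code{"sem"} or \code{"ols"}.
#' @param effects \code{"time"}, \code{"individual"}, \code{"twoway"},
#'   \code{"none"} or \code{"random"} (random only with
#'   \code{model = "ols"}).
#' @return object of class \code{spfit} with coefficients, \code{rho} (or
#'   \code{lambda_err}), \code{sigma2}, \code{loglik}, \code{r2} (squared
#'   correlation of fitted and observed), full-parameter \code{vcov}, and
#'   the usual accessor methods.
#' @export
fit_spatial_panel <- function(formula, data, W,
                              index = c("unit", "year"),
                              model = c("sdm", "slm", "sem", "ols"),
                              effects = c("time", "individual", "twoway",
                                          "none", "random")) {
  model <- match.arg(model); effects <- match.arg(effects)
  if (effects == "random" && model != "ols")
    stop("random effects are supported for model = \"ols\" only")
  pb <- .build_panel(formula, data, W, index)
  n <- pb$n; Tn <- pb$T; N <- n * Tn
  w <- pb$w
  Xraw <- pb$X
  Z <- if (model == "sdm") {
    WX <- .wlag(Xraw, w, n, Tn)
    colnames(WX) <- paste0("W.", colnames(Xraw))
    cbind(Xraw, WX)
  } else Xraw
  y <- .within(pb$y, n, Tn, effects)
  Z <- .within(Z, n, Tn, effects)
  if (effects %in% c("none", "random"))
    Z <- cbind(`(Intercept)` = 1, Z)
  k <- ncol(Z)
  if (qr(Z)$rank < k) stop("singular regressor matrix")

  ev <- eigen(w, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8)
    warning("complex eigenvalues of W; using real parts in log-determinant")
  ev <- Re(ev)
  iv <- .rho_interval(ev)
  lo <- iv[1] + 1e-6; hi <- iv[2] - 1e-6
  # Transformation-based likelihood for the within-demeaned system: time
  # (cross-section) demeaning removes the unit-eigenvalue direction of a
  # row-stochastic W, so its log(1 - rho) term is dropped and the
  # effective sample shrinks to (n-1) units; unit demeaning removes one
  # period. Without these corrections the time-effects ML estimate of the
  # spatial coefficient is biased at n = 31.
  row_std <- any(w != 0) && all(abs(rowSums(w) - 1) < 1e-10)
  drop_unit_ev <- effects %in% c("time", "twoway") && row_std
  ldm <- switch(effects, individual = Tn - 1L, twoway = Tn - 1L, Tn)
  Nstar <- switch(effects,
                  time = (n - 1L * drop_unit_ev) * Tn,
                  individual = n * (Tn - 1L),
                  twoway = (n - 1L * drop_unit_ev) * (Tn - 1L),
                  N)
  ldet <- function(r) ldm * (sum(log(1 - r * ev)) -
                               if (drop_unit_ev) log(1 - r) else 0)
  df_fe <- switch(effects, time = Tn, individual = n,
                  twoway = n + Tn - 1L, 0L)

  out <- list(model = model, effects = effects, call = match.call(),
              n = n, T = Tn, k = k, W = w, y = y, Z = Z,
              xnames = colnames(Xraw))

  if (model == "ols" && effects == "random") {
    return(.fit_re_gls(pb, out))
  }

  if (model == "ols") {
    fit <- stats::lm.fit(Z, y)
    e <- fit$residuals
    s2 <- sum(e^2) / N
    out$beta <- stats::setNames(fit$coefficients, colnames(Z))
    out$sigma2 <- s2
    out$loglik <- -N / 2 * (log(2 * pi * s2) + 1)
    out$loglik_lsdv <- out$loglik
    out$fitted <- drop(Z %*% fit$coefficients)
    out$residuals <- e
    V <- s2 * N / (N - k - df_fe) * solve(crossprod(Z))
    dimnames(V) <- list(colnames(Z), colnames(Z))
    out$vcov <- V
  } else if (model %in% c("slm", "sdm")) {
    Wy <- .wlag(pb$y, w, n, Tn)
    Wy <- .within(Wy, n, Tn, effects)
    ZtZi <- solve(crossprod(Z))
    b0 <- ZtZi %*% crossprod(Z, y);  e0 <- y - Z %*% b0
    bd <- ZtZi %*% crossprod(Z, Wy); ed <- Wy - Z %*% bd
    cll <- function(rho) {
      e <- e0 - rho * ed
      -Nstar / 2 * log(sum(e^2) / Nstar) + ldet(rho)
    }
    if (sum(ed^2) < 1e-20 * max(sum(e0^2), 1)) {
      rho <- 0                        # W (or its lag) degenerate: OLS
    } else {
      op <- stats::optimize(cll, c(lo, hi), maximum = TRUE,
                            tol = .Machine$double.eps^0.5)
      rho <- op$maximum
      if (min(rho - lo, hi - rho) < 1e-4)
        warning("spatial coefficient at search boundary; ",
                "estimates may not have converged")
    }
    beta <- drop(b0 - rho * bd)
    e <- drop(e0 - rho * ed)
    s2 <- sum(e^2) / Nstar
    ll <- function(p) {      # p = (rho, beta, sigma2)
      r <- p[1]; b <- p[2:(k + 1)]; s <- p[k + 2]
      if (s <= 0 || r <= lo || r >= hi) return(-Inf)
      ee <- y - r * Wy - Z %*% b
      -Nstar / 2 * log(2 * pi * s) + ldet(r) - sum(ee^2) / (2 * s)
    }
    par <- c(rho, beta, s2)
    H <- stats::optimHess(par, ll)
    V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
    nm <- c("rho", colnames(Z), "sigma2")
    dimnames(V) <- list(nm, nm)
    out$rho <- rho
    out$beta <- stats::setNames(beta, colnames(Z))
    out$sigma2 <- s2
    out$loglik <- -Nstar / 2 * log(2 * pi * s2) + ldet(rho) - Nstar / 2
    out$loglik_lsdv <- -N / 2 * (log(2 * pi * sum(e^2) / N) + 1) +
      Tn * sum(log(1 - rho * ev))
    out$fitted <- drop(rho * Wy + Z %*% beta)
    out$residuals <- e
    out$vcov <- V
  } else {                            # SEM
    Wy_ <- .wlag(pb$y, w, n, Tn)
    WZraw <- .wlag(if (effects %in% c("none", "random"))
                     Z[, -1, drop = FALSE] else Z, w, n, Tn)
    Wy_ <- .within(Wy_, n, Tn, effects)
    WZ <- .within(WZraw, n, Tn, effects)
    if (effects %in% c("none", "random")) {
      # intercept spatially lagged is the row-sum vector (1 for
      # row-standardised W)
      Wi <- .wlag(rep(1, N), w, n, Tn)
      WZ <- cbind(Wi, WZ)
    }
    cfit <- function(lam) {
      ys <- y - lam * Wy_
      Zs <- Z - lam * WZ
      b <- solve(crossprod(Zs), crossprod(Zs, ys))
      e <- ys - Zs %*% b
      list(b = drop(b), e = drop(e), s2 = sum(e^2) / N)
    }
    cll <- function(lam) {
      f <- cfit(lam)
      -Nstar / 2 * log(sum(f$e^2) / Nstar) + ldet(lam)
    }
    if (all(w == 0)) {
      lam <- 0
    } else {
      op <- stats::optimize(cll, c(lo, hi), maximum = TRUE,
                            tol = .Machine$double.eps^0.5)
      lam <- op$maximum
      if (min(lam - lo, hi - lam) < 1e-4)
        warning("spatial coefficient at search boundary; ",
                "estimates may not have converged")
    }
    f <- cfit(lam)
    # W commutes with the within transforms used here, so lagging the
    # transformed residual equals transforming the lagged one
    ll <- function(p) {     # p = (lambda, beta, sigma2)
      l <- p[1]; b <- p[2:(k + 1)]; s <- p[k + 2]
      if (s <= 0 || l <= lo || l >= hi) return(-Inf)
      eb <- drop(y - Z %*% b)
      ee <- eb - l * .wlag(eb, w, n, Tn)
      -Nstar / 2 * log(2 * pi * s) + ldet(l) - sum(ee^2) / (2 * s)
    }
    s2 <- sum(f$e^2) / Nstar
    par <- c(lam, f$b, s2)
    H <- stats::optimHess(par, ll)
    V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
    nm <- c("lambda", colnames(Z), "sigma2")
    dimnames(V) <- list(nm, nm)
    out$lambda_err <- lam
    out$beta <- stats::setNames(f$b, colnames(Z))
    out$sigma2 <- s2
    out$loglik <- -Nstar / 2 * log(2 * pi * s2) + ldet(lam) - Nstar / 2
    out$loglik_lsdv <- -N / 2 * (log(2 * pi * sum(f$e^2) / N) + 1) +
      Tn * sum(log(1 - lam * ev))
    out$fitted <- drop(Z %*% f$b)
    out$residuals <- drop(y - out$fitted)
    out$vcov <- V
  }
  if (!is.finite(out$loglik)) stop("non-finite likelihood")
  # R2: squared correlation of observed and fitted on the raw scale, with
  # the concentrated fixed effects recovered from the residual means —
  # comparable across fixed-effect variants, unlike the within-scale fit
  Zr <- if (model == "sdm") {
    WXr <- .wlag(Xraw, w, n, Tn); cbind(Xraw, WXr)
  } else Xraw
  if (effects %in% c("none", "random")) Zr <- cbind(1, Zr)
  part <- drop(Zr %*% out$beta)
  if (!is.null(out$rho)) part <- part + out$rho * .wlag(pb$y, w, n, Tn)
  r0 <- matrix(pb$y - part, n, Tn)
  fe <- switch(effects,
               time = matrix(colMeans(r0), n, Tn, byrow = TRUE),
               individual = matrix(rowMeans(r0), n, Tn),
               twoway = outer(rowMeans(r0), colMeans(r0), "+") - mean(r0),
               matrix(0, n, Tn))
  out$fitted_raw <- part + as.vector(fe)
  out$r2 <- stats::cor(out$fitted_raw, pb$y)^2
  out$r2_within <- stats::cor(out$fitted, y)^2
  # the LSDV log-likelihood is the profile likelihood of the raw data
  # with the fixed effects concentrated out, hence comparable across
  # effect patterns once the effect count is penalised
  out$df_fe <- df_fe
  npar <- k + out$df_fe + 2L -
    (is.null(out$rho) && is.null(out$lambda_err))
  out$bic <- -2 * out$loglik_lsdv + log(N) * npar
  if (model == "sdm") {
    kx <- length(out$xnames)
    out$theta_durbin <- out$beta[paste0("W.", out$xnames)]
    out$beta_main <- out$beta[out$xnames]
  }
  class(out) <- "spfit"
  out
}

# Swamy-Arora random-effects GLS for the non-spatial panel.
.fit_re_gls <- function(pb, out) {
  n <- pb$n; Tn <- pb$T; N <- n * Tn
  Xw <- .within(pb$X, n, Tn, "individual")
  yw <- .within(pb$y, n, Tn, "individual")
  fw <- stats::lm.fit(Xw, yw)
  s2e <- sum(fw$residuals^2) / (N - n - ncol(Xw))
  # between regression on unit means
  Mx <- apply(pb$X, 2, function(col) rowMeans(matrix(col, n, Tn)))
  my <- rowMeans(matrix(pb$y, n, Tn))
  fb <- stats::lm.fit(cbind(1, Mx), my)
  s2b <- sum(fb$residuals^2) / max(n - ncol(Mx) - 1, 1)
  s2u <- max(s2b - s2e / Tn, 0)
  th <- 1 - sqrt(s2e / (s2e + Tn * s2u))
  qd <- function(col) {
    M <- matrix(col, n, Tn)
    as.vector(M - th * rowMeans(M))
  }
  Zq <- cbind(`(Intercept)` = qd(rep(1, N)), apply(pb$X, 2, qd))
  yq <- qd(pb$y)
  fit <- stats::lm.fit(Zq, yq)
  e <- fit$residuals
  s2 <- sum(e^2) / (N - ncol(Zq))
  V <- s2 * solve(crossprod(Zq))
  dimnames(V) <- list(colnames(Zq), colnames(Zq))
  out$model <- "ols"; out$effects <- "random"
  out$beta <- stats::setNames(fit$coefficients, colnames(Zq))
  out$sigma2 <- s2
  out$loglik <- NA_real_           # GLS, not ML; not comparable via LR
  out$fitted <- drop(Zq %*% fit$coefficients)
  out$residuals <- e
  out$vcov <- V
  out$r2 <- stats::cor(out$fitted, yq)^2
  out$variance_components <- c(idiosyncratic = s2e, individual = s2u)
  class(out) <- "spfit"
  out
}

# ---- spfit methods ------------------------------------------------------

#' @export
print.spfit <- function(x, ...) {
  hdr <- switch(x$model,
                ols = "Panel OLS", slm = "Spatial lag panel (ML)",
                sem = "Spatial error panel (ML)",
                sdm = "Spatial Durbin panel (ML)")
  cat(hdr, "- effects:", x$effects, "\n")
  if (!is.null(x$rho)) cat(sprintf("rho = %.4f  ", x$rho))
  if (!is.null(x$lambda_err)) cat(sprintf("lambda = %.4f  ", x$lambda_err))
  cat(sprintf("sigma2 = %.4g  logLik = %.3f  R2 = %.4f\n",
              x$sigma2, x$loglik, x$r2))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.spfit <- function(object, ...) {
  c(if (!is.null(object$rho)) c(rho = object$rho),
    if (!is.null(object$lambda_err)) c(lambda = object$lambda_err),
    object$beta)
}

#' @export
vcov.spfit <- function(object, ...) object$vcov

#' @export
logLik.spfit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + 2 -
                 is.null(object$rho) - is.null(object$lambda_err) + 1,
            class = "logLik")
}

#' @export
residuals.spfit <- function(object, ...) object$residuals

#' @export
fitted.spfit <- function(object, ...) object$fitted

#' @export
predict.spfit <- function(object, ...) {
  # reduced-form prediction on the estimation sample: for lag models the
  # simultaneity is solved out, (I - rho W)^{-1} Z beta per period
  if (is.null(object$rho)) return(object$fitted)
  n <- object$n; Tn <- object$T
  A <- solve(diag(n) - object$rho * object$W)
  xb <- drop(object$Z %*% object$beta)
  out <- numeric(n * Tn)
  for (t in seq_len(Tn)) {
    idx <- (t - 1L) * n + seq_len(n)
    out[idx] <- drop(A %*% xb[idx])
  }
  out
}

#' @export
summary.spfit <- function(object, ...) {
  cf <- coef.spfit(object)
  nm <- names(cf)
  se <- sqrt(diag(object$vcov))[nm]
  z <- cf / se
  tab <- cbind(Estimate = cf, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(fit = object, coefficients = tab),
            class = "summary.spfit")
}

#' @export
print.summary.spfit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
plot.spfit <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "Fitted",
                 ylab = "Residuals",
                 main = paste("Residuals vs fitted -", toupper(x$model)),
                 ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# ---- diagnostics --------------------------------------------------------

#' Harris-Tzavalis panel unit-root test
#'
#' Pooled (within) AR(1) estimate on a short balanced panel with the
#' fixed-T bias correction: under the unit-root null the demeaned within
#' estimator converges to 1 - 3/(T+1), where T is the number of
#' transitions per unit, with known variance, giving a standard normal
#' z-statistic as the number of units grows. Rejection (small p) favours
#' stationarity.
#'
#' @param Y n x T matrix of a variable (units in rows, time in columns),
#'   balanced, at least 3 time points.
#' @param demean subtract unit means (the fixed-effects variant used for
#'   short panels); \code{FALSE} gives the no-intercept variant.
#' @return list with \code{statistic} (the pooled AR(1) estimate),
#'   \code{z}, \code{p}, \code{T} (transitions) and \code{n}.
#' @export
ht_unit_root <- function(Y, demean = TRUE) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("unbalanced panel: missing values present")
  L <- ncol(Y); n <- nrow(Y)
  if (L < 3L) stop("need at least 3 time points per unit")
  Tt <- L - 1L                       # transitions
  y0 <- Y[, 1:(L - 1), drop = FALSE]
  y1 <- Y[, 2:L, drop = FALSE]
  if (demean) {
    y0 <- y0 - rowMeans(y0)
    y1 <- y1 - rowMeans(y1)
  }
  rho <- sum(y0 * y1) / sum(y0^2)
  if (demean) {
    mu <- 1 - 3 / (Tt + 1)
    v <- 3 * (17 * Tt^2 - 20 * Tt + 17) / (5 * (Tt - 1) * (Tt + 1)^3)
  } else {
    mu <- 1
    v <- 2 / (Tt * (Tt + 1))
  }
  z <- sqrt(n) * (rho - mu) / sqrt(v)
  list(statistic = rho, z = z, p = stats::pnorm(z), T = Tt, n = n)
}

#' Lagrange-multiplier diagnostics for spatial dependence
#'
#' Classical and robust LM score tests for an omitted spatial lag and an
#' omitted spatial error term, computed from (within-transformed) pooled
#' OLS residuals with the panel weight structure I_T (x) W. Each statistic
#' is asymptotically chi-squared with 1 degree of freedom under the null
#' of no spatial dependence.
#'
#' @inheritParams fit_spatial_panel
#' @return data frame with columns \code{test}, \code{statistic},
#'   \code{p}, for LM-error, LM-lag and their robust variants.
#' @export
lm_diagnostics <- function(formula, data, W, index = c("unit", "year"),
                           effects = c("none", "time", "individual",
                                       "twoway")) {
  effects <- match.arg(effects)
  pb <- .build_panel(formula, data, W, index)
  n <- pb$n; Tn <- pb$T; N <- n * Tn
  w <- pb$w
  y <- .within(pb$y, n, Tn, effects)
  Z <- .within(pb$X, n, Tn, effects)
  if (effects == "none") Z <- cbind(`(Intercept)` = 1, Z)
  if (qr(Z)$rank < ncol(Z)) stop("singular regressor matrix")
  fit <- stats::lm.fit(Z, y)
  e <- fit$residuals
  s2 <- sum(e^2) / N
  Wy <- .wlag(y, w, n, Tn)
  We <- .wlag(e, w, n, Tn)
  dy <- sum(e * Wy) / s2
  de <- sum(e * We) / s2
  Tw <- Tn * (sum(w * w) + sum(w * t(w)))
  xb <- drop(Z %*% fit$coefficients)
  Wxb <- .wlag(xb, w, n, Tn)
  Mwxb <- Wxb - Z %*% solve(crossprod(Z), crossprod(Z, Wxb))
  J <- sum(Mwxb^2) / s2 + Tw
  lm_lag <- dy^2 / J
  lm_err <- de^2 / Tw
  r_lag <- (dy - de)^2 / (J - Tw)
  r_err <- (de - (Tw / J) * dy)^2 / (Tw * (1 - Tw / J))
  st <- c(`LM-error` = lm_err, `LM-lag` = lm_lag,
          `Robust LM-error` = r_err, `Robust LM-lag` = r_lag)
  data.frame(test = names(st), statistic = unname(st),
             p = stats::pchisq(unname(st), df = 1, lower.tail = FALSE))
}

#' Hausman test between two panel estimators
#'
#' Quadratic form in the difference of the common coefficient subset,
#' weighted by the difference of covariance matrices (Moore-Penrose
#' pseudo-inverse fallback when that difference is not positive definite).
#' Under the null that both estimators are consistent (random effects
#' uncorrelated with regressors) the statistic is chi-squared with
#' degrees of freedom equal to the rank of the weighting matrix.
#'
#' @param fit_fe,fit_re \code{spfit} objects sharing coefficient names
#'   (the intercept and spatial terms are excluded automatically).
#' @param common_sigma evaluate both covariance matrices at the efficient
#'   (second) estimator's error variance, which guarantees a positive
#'   definite difference (default \code{TRUE}).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
hausman_test <- function(fit_fe, fit_re, common_sigma = TRUE) {
  drop_nm <- c("(Intercept)", "rho", "lambda", "sigma2")
  nm <- setdiff(intersect(names(fit_fe$beta), names(fit_re$beta)), drop_nm)
  if (!length(nm)) stop("no common coefficients to compare")
  q <- fit_fe$beta[nm] - fit_re$beta[nm]
  V1 <- fit_fe$vcov[nm, nm, drop = FALSE]
  V2 <- fit_re$vcov[nm, nm, drop = FALSE]
  if (common_sigma && !is.null(fit_fe$sigma2) &&
      !is.null(fit_re$sigma2)) {
    V1 <- V1 * fit_re$sigma2 / fit_fe$sigma2
  }
  V <- V1 - V2
  Vi <- tryCatch({
    ch <- chol(V); chol2inv(ch)
  }, error = function(e) {
    message("Hausman: covariance difference not positive definite; ",
            "using pseudo-inverse")
    MASS::ginv(V)
  })
  stat <- drop(t(q) %*% Vi %*% q)
  df <- qr(V)$rank
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' LR and Wald tests of SDM degeneracy
#'
#' Whether the spatial Durbin model collapses to the spatial lag model
#' (all Durbin coefficients zero) or to the spatial error model (the
#' common-factor restriction theta + rho beta = 0). LR statistics use the
#' nested maximised likelihoods; Wald statistics use the SDM parameter
#' covariance (delta method for the common-factor restriction). All are
#' chi-squared with k (number of covariates) degrees of freedom.
#'
#' @param fit_sdm,fit_sem,fit_slm fitted \code{spfit} objects on the same
#'   sample with the same effects.
#' @return data frame with rows LR/Wald x SEM/SAR.
#' @export
lr_wald_degeneracy <- function(fit_sdm, fit_sem, fit_slm) {
  stopifnot(fit_sdm$model == "sdm", fit_sem$model == "sem",
            fit_slm$model == "slm")
  kx <- length(fit_sdm$xnames)
  lr_sem <- 2 * (fit_sdm$loglik - fit_sem$loglik)
  lr_sar <- 2 * (fit_sdm$loglik - fit_slm$loglik)
  if (min(lr_sem, lr_sar) < -1e-6)
    stop("negative LR statistic: restricted fit exceeded the full model, ",
         "estimation did not converge")
  lr_sem <- max(lr_sem, 0); lr_sar <- max(lr_sar, 0)
  bn <- fit_sdm$xnames; tn <- paste0("W.", bn)
  th <- fit_sdm$beta[tn]; be <- fit_sdm$beta[bn]; rho <- fit_sdm$rho
  V <- fit_sdm$vcov
  # Wald vs SAR: theta = 0
  Vtt <- V[tn, tn, drop = FALSE]
  w_sar <- drop(t(th) %*% solve(Vtt, th))
  # Wald vs SEM: g = theta + rho * beta = 0
  g <- th + rho * be
  pnm <- c("rho", bn, tn)
  G <- cbind(be, rho * diag(kx), diag(kx))
  Vg <- G %*% V[pnm, pnm] %*% t(G)
  w_sem <- drop(t(g) %*% solve(Vg, g))
  st <- c(`LR vs SEM` = lr_sem, `LR vs SAR` = lr_sar,
          `Wald vs SEM` = w_sem, `Wald vs SAR` = w_sar)
  data.frame(test = names(st), statistic = unname(st), df = kx,
             p = stats::pchisq(unname(st), kx, lower.tail = FALSE))
}

# ---- effect decomposition ----------------------------------------------

#' Direct, indirect and total effects of the SDM covariates
#'
#' Under the spatial Durbin model the marginal-effect matrix of covariate
#' k is \eqn{S_k = (I - \rho W)^{-1} (I \beta_k + W \theta_k)}. The direct
#' effect is the average diagonal element, the total effect the average
#' row sum, and the indirect (spillover) effect their difference.
#' Inference simulates parameter draws from the estimated sampling
#' distribution of (rho, beta, theta) and summarises the induced effect
#' distribution.
#'
#' @param fit a fitted SDM (or SLM, where theta = 0) \code{spfit}.
#' @param n_draws number of parameter draws for the simulated standard
#'   errors (0 for point estimates only).
#' @param seed integer seed for the draws.
#' @return object of class \code{effect_decomposition}: a data frame of
#'   point estimates with simulated standard errors, z and p per
#'   covariate and effect type.
#' @export
decompose_effects <- function(fit, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "spfit"))
  if (is.null(fit$rho)) stop("effect decomposition needs a lag-type model")
  w <- fit$W; n <- nrow(w)
  bn <- fit$xnames; kx <- length(bn)
  tn <- paste0("W.", bn)
  has_theta <- fit$model == "sdm"
  ev <- Re(eigen(w, only.values = TRUE)$values)
  iv <- .rho_interval(ev); lo <- iv[1]; hi <- iv[2]
  if (fit$rho <= lo || fit$rho >= hi)
    stop("rho outside the stable interval")
  point <- function(rho, beta, theta) {
    A <- solve(diag(n) - rho * w)
    t(vapply(seq_len(kx), function(j) {
      Sk <- A %*% (diag(beta[j], n) + theta[j] * w)
      direct <- mean(diag(Sk))
      total <- mean(rowSums(Sk))
      c(direct = direct, indirect = total - direct, total = total)
    }, numeric(3)))
  }
  th <- if (has_theta) fit$beta[tn] else stats::setNames(rep(0, kx), tn)
  est <- point(fit$rho, fit$beta[bn], th)
  rownames(est) <- bn
  draws <- NULL
  if (n_draws > 0) {
    if (!is.null(seed)) set.seed(seed)
    pnm <- c("rho", bn, if (has_theta) tn)
    mu <- c(fit$rho, fit$beta[bn], if (has_theta) fit$beta[tn])
    V <- fit$vcov[pnm, pnm]
    V <- (V + t(V)) / 2
    P <- MASS::mvrnorm(n_draws, mu, V)
    keep <- P[, 1] > lo & P[, 1] < hi
    P <- P[keep, , drop = FALSE]
    draws <- array(NA_real_, c(nrow(P), kx, 3),
                   dimnames = list(NULL, bn,
                                   c("direct", "indirect", "total")))
    for (d in seq_len(nrow(P))) {
      td <- if (has_theta) P[d, 1 + kx + seq_len(kx)] else rep(0, kx)
      draws[d, , ] <- point(P[d, 1], P[d, 1 + seq_len(kx)], td)
    }
  }
  tab <- do.call(rbind, lapply(c("direct", "indirect", "total"),
    function(ef) {
      v <- est[, ef]
      if (!is.null(draws)) {
        sd <- apply(draws[, , ef, drop = FALSE], 2, stats::sd)
        z <- v / sd
        p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      } else sd <- z <- p <- rep(NA_real_, kx)
      data.frame(variable = bn, effect = ef, estimate = v, sd = sd,
                 z = z, p = p)
    }))
  rownames(tab) <- NULL
  structure(list(table = tab, estimates = est, draws = draws,
                 rho = fit$rho, n_draws = n_draws, seed = seed),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, digits = 4, ...) {
  cat("SDM effect decomposition (rho =", round(x$rho, 4), ")\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$sd <- round(tab$sd, digits)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("variable", "effect", "estimate", "sd", "p")])
  invisible(x)
}

# ---- model selection ----------------------------------------------------

#' Diagnostic-driven spatial model selection
#'
#' Runs the full decision tree on a balanced panel: (1) Harris-Tzavalis
#' stationarity test per covariate; (2) LM tests on pooled OLS residuals
#' — if neither the lag nor the error alternative is significant, plain
#' OLS is retained; (3) Hausman test of fixed vs random effects; (4) SDM
#' fitted with time, individual and two-way fixed effects, the variant
#' with the highest squared correlation of fitted and observed retained;
#' (5) LR and Wald degeneracy tests of SDM against SEM and SLM — if
#' either restriction is not rejected, the corresponding restricted model
#' is chosen.
#'
#' @inheritParams fit_spatial_panel
#' @param alpha significance level used throughout (default 0.05).
#' @param fe_criterion how to choose among the fixed-effect variants:
#'   \code{"bic"} (default; profile-likelihood BIC counting the
#'   concentrated effects) or \code{"r2"} (highest squared correlation of
#'   observed and fitted, the published comparator, which cannot penalise
#'   the extra effect parameters).
#' @return object of class \code{model_selection}: chosen \code{model} and
#'   \code{effects}, the chosen \code{fit}, and a \code{diagnostics} list
#'   with the HT table, LM table, Hausman result, per-effects R2/BIC and
#'   the LR/Wald table.
#' @export
select_model <- function(formula, data, W, index = c("unit", "year"),
                         alpha = 0.05, fe_criterion = c("bic", "r2")) {
  fe_criterion <- match.arg(fe_criterion)
  pb <- .build_panel(formula, data, W, index)
  diag_list <- list()
  # 1. stationarity of each covariate
  ht <- do.call(rbind, lapply(colnames(pb$X), function(v) {
    r <- ht_unit_root(matrix(pb$X[, v], pb$n, pb$T), demean = TRUE)
    data.frame(variable = v, statistic = r$statistic, z = r$z, p = r$p)
  }))
  diag_list$ht <- ht
  diag_list$stationary <- all(ht$p < alpha)
  # 2. LM tests on pooled OLS
  lmt <- lm_diagnostics(formula, data, W, index, effects = "none")
  diag_list$lm <- lmt
  p_lag <- lmt$p[lmt$test == "LM-lag"]
  p_err <- lmt$p[lmt$test == "LM-error"]
  if (p_lag >= alpha && p_err >= alpha) {
    fit <- fit_spatial_panel(formula, data, W, index, model = "ols",
                             effects = "none")
    return(structure(list(model = "ols", effects = "none", fit = fit,
                          diagnostics = diag_list, alpha = alpha),
                     class = "model_selection"))
  }
  # 3. fixed vs random effects
  fe <- fit_spatial_panel(formula, data, W, index, "ols", "individual")
  re <- fit_spatial_panel(formula, data, W, index, "ols", "random")
  hm <- hausman_test(fe, re)
  diag_list$hausman <- hm
  use_fe <- hm$p < alpha
  # 4. fixed-effect variant by R2 of the SDM fit
  cand <- c("time", "individual", "twoway")
  fits <- lapply(cand, function(ef)
    fit_spatial_panel(formula, data, W, index, "sdm", ef))
  names(fits) <- cand
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  diag_list$r2_by_effects <- r2
  diag_list$bic_by_effects <- bic
  eff <- if (fe_criterion == "bic") cand[which.min(bic)]
         else cand[which.max(r2)]
  diag_list$fixed_effects_preferred <- use_fe
  fit_sdm <- fits[[eff]]
  # 5. degeneracy tests
  fit_sem <- fit_spatial_panel(formula, data, W, index, "sem", eff)
  fit_slm <- fit_spatial_panel(formula, data, W, index, "slm", eff)
  lw <- lr_wald_degeneracy(fit_sdm, fit_sem, fit_slm)
  diag_list$lr_wald <- lw
  rej_sem <- lw$p[lw$test == "LR vs SEM"] < alpha
  rej_sar <- lw$p[lw$test == "LR vs SAR"] < alpha
  if (rej_sem && rej_sar) {
    model <- "sdm"; fit <- fit_sdm
  } else if (!rej_sar && rej_sem) {
    model <- "slm"; fit <- fit_slm
  } else if (!rej_sem && rej_sar) {
    model <- "sem"; fit <- fit_sem
  } else {
    model <- if (fit_sem$loglik >= fit_slm$loglik) "sem" else "slm"
    fit <- if (model == "sem") fit_sem else fit_slm
  }
  structure(list(model = model, effects = eff, fit = fit,
                 diagnostics = diag_list, alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (alpha =", x$alpha, ")\n")
  cat("  stationary covariates:", x$diagnostics$stationary, "\n")
  if (!is.null(x$diagnostics$hausman))
    cat(sprintf("  Hausman: %.2f (p = %.4g)\n",
                x$diagnostics$hausman$statistic, x$diagnostics$hausman$p))
  if (!is.null(x$diagnostics$r2_by_effects)) {
    r2 <- x$diagnostics$r2_by_effects
    cat("  R2 by effects:",
        paste(sprintf("%s %.4f", names(r2), r2), collapse = ", "), "\n")
  }
  cat("  chosen:", toupper(x$model), "with", x$effects, "effects\n")
  invisible(x)
}
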