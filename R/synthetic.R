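#' Specification of a synthetic production-frontier panel
#'
#' The generator emulates the health-production input-output system: a
#' constant-returns log-linear (Cobb-Douglas) frontier in m inputs, one
#' primary desirable output (additional desirable outputs are monotone
#' transforms), and undesirable outputs proportional to realised activity.
#' A designated subset of units has zero inefficiency (true frontier
#' members); the rest are radially inflated copies of frontier units'
#' input mixes, so each non-frontier unit's true efficiency exp(-v) is
#' well defined in the DEA metric itself and is returned for recovery
#' testing. Half-normal inefficiency is the standard choice in the
#' efficiency literature.
#'
#' @param n_units,n_years panel dimensions (defaults 31 and 11, the
#'   province-year study design).
#' @param m,s,q numbers of inputs, desirable and undesirable outputs
#'   (defaults 4, 1, 2 per the health input-output system).
#' @param elasticities positive input elasticities, normalised to sum 1
#'   (constant returns).
#' @param ineff_scale scale of the half-normal inefficiency draw (on the
#'   log scale; default 0.3).
#' @param n_frontier number of zero-inefficiency units per year.
#' @param bad_coupling factors linking undesirable outputs to activity
#'   (length q, recycled).
#' @param input_spread lognormal sigma of the input mix dispersion.
#' @param bad_noise lognormal sigma of noise on the undesirable outputs
#'   (default 0 keeps the frontier guarantees exact).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return object of class \code{frontier_spec}.
#' @export
frontier_spec <- function(n_units = 31, n_years = 11, m = 4, s = 1, q = 2,
                          elasticities = NULL, ineff_scale = 0.3,
                          n_frontier = max(2, round(n_units / 4)),
                          bad_coupling = c(0.5, 0.2),
                          input_spread = 0.3, bad_noise = 0,
                          seed = 1) {
  if (is.null(elasticities)) elasticities <- rep(1 / m, m)
  if (any(elasticities <= 0)) stop("elasticities must be positive")
  elasticities <- elasticities / sum(elasticities)
  if (ineff_scale < 0 || input_spread < 0 || bad_noise < 0)
    stop("scales must be nonnegative")
  if (n_units < m + s + q + 1)
    warning("fewer units than inputs+outputs+1: ",
            "frontier discrimination will be poor")
  structure(list(n_units = n_units, n_years = n_years, m = m, s = s,
                 q = q, elasticities = elasticities,
                 ineff_scale = ineff_scale, n_frontier = n_frontier,
                 bad_coupling = rep_len(bad_coupling, q),
                 input_spread = input_spread, bad_noise = bad_noise,
                 seed = seed),
            class = "frontier_spec")
}

#' Generate a DEA panel with a known frontier
#'
#' @param spec a \code{\link{frontier_spec}}.
#' @return list with \code{panel} (a \code{\link{dea_panel}}) and
#'   \code{true_efficiency} (units x years matrix, 1 for frontier
#'   members).
#' @export
generate_frontier_panel <- function(spec) {
  stopifnot(inherits(spec, "frontier_spec"))
  set.seed(spec$seed)
  n <- spec$n_units; nT <- spec$n_years
  m <- spec$m; s <- spec$s; q <- spec$q
  units <- sprintf("U%02d", seq_len(n))
  years <- seq_len(nT)
  X <- array(NA_real_, c(m, n, nT))
  Y <- array(NA_real_, c(s, n, nT))
  U <- if (q) array(NA_real_, c(q, n, nT)) else NULL
  eff <- matrix(NA_real_, n, nT, dimnames = list(units, years))
  alpha <- spec$elasticities
  fr <- seq_len(spec$n_frontier)
  for (t in seq_len(nT)) {
    # frontier units: free input mixes on the CRS Cobb-Douglas surface
    xf <- matrix(exp(stats::rnorm(m * spec$n_frontier,
                                  sd = spec$input_spread)),
                 m, spec$n_frontier) *
          matrix(exp(stats::rnorm(spec$n_frontier, sd = 0.4)),
                 m, spec$n_frontier, byrow = TRUE)
    yf <- apply(xf, 2, function(xx) prod(xx^alpha))
    x <- matrix(NA_real_, m, n); ystar <- numeric(n)
    x[, fr] <- xf; ystar[fr] <- yf
    v <- numeric(n)
    others <- setdiff(seq_len(n), fr)
    v[others] <- abs(stats::rnorm(length(others), sd = spec$ineff_scale))
    # non-frontier units: scaled copies of a frontier unit's mix, inputs
    # radially inflated by exp(v) so true efficiency is exp(-v)
    for (j in others) {
      b <- sample(fr, 1L)
      cscale <- exp(stats::rnorm(1, sd = 0.4))
      x[, j] <- cscale * exp(v[j]) * xf[, b]
      ystar[j] <- cscale * yf[b]
    }
    yall <- matrix(NA_real_, s, n)
    yall[1, ] <- ystar
    if (s > 1) for (r in 2:s)
      yall[r, ] <- ystar^(0.8 + 0.4 * (r - 1) / (s - 1))  # monotone companions
    ubad <- NULL
    if (q) {
      ubad <- matrix(NA_real_, q, n)
      for (p in seq_len(q)) {
        noise <- if (spec$bad_noise > 0)
          exp(stats::rnorm(n, sd = spec$bad_noise)) else 1
        ubad[p, ] <- spec$bad_coupling[p] * ystar * noise
      }
    }
    X[, , t] <- x; Y[, , t] <- yall
    if (q) U[, , t] <- ubad
    eff[, t] <- exp(-v)
  }
  panel <- dea_panel(X, Y, U, units = units, years = years)
  list(panel = panel, true_efficiency = eff)
}

#' Specification of a spatial Durbin data-generating process
#'
#' @param W spatial weights (row-standardised).
#' @param n_years number of periods.
#' @param rho spatial autoregressive coefficient, strictly inside the
#'   stable interval of W.
#' @param beta covariate coefficients (length k).
#' @param theta_durbin coefficients on the spatially lagged covariates
#'   (length k; zeros give an SLM process).
#' @param effects fixed-effect pattern baked into the process:
#'   \code{"time"}, \code{"individual"}, \code{"twoway"} or \code{"none"}.
#' @param sigma disturbance standard deviation.
#' @param fe_scale standard deviation of the drawn fixed effects.
#' @param seed integer seed.
#' @return object of class \code{sdm_spec}.
#' @export
sdm_spec <- function(W, n_years = 11, rho = 0.4,
                     beta = c(0.5, -0.3, 0.2, 0.8, -0.5, 0.1),
                     theta_durbin = c(0.2, 0.1, -0.15, 0, 0.25, -0.1),
                     effects = c("time", "individual", "twoway", "none"),
                     sigma = 0.5, fe_scale = 0.5, seed = 1) {
  effects <- match.arg(effects)
  w <- .as_w(W)
  ev <- Re(eigen(w, only.values = TRUE)$values)
  iv <- .rho_interval(ev); lo <- iv[1]; hi <- iv[2]
  if (rho <= lo || rho >= hi)
    stop("rho outside the stable interval (", round(lo, 3), ", ",
         round(hi, 3), ")")
  if (length(theta_durbin) != length(beta))
    stop("beta and theta_durbin must have equal length")
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(W = w,
                 labels = if (inherits(W, "spatial_weights")) W$labels
                          else rownames(w),
                 n_years = n_years, rho = rho, beta = beta,
                 theta_durbin = theta_durbin, effects = effects,
                 sigma = sigma, fe_scale = fe_scale, seed = seed),
            class = "sdm_spec")
}

#' Generate a panel from a spatial Durbin process
#'
#' Per period, \eqn{y_t = (I - \rho W)^{-1} (X_t \beta + W X_t \theta +
#' fixed effects + \epsilon_t)}; covariates are iid standard normal.
#'
#' @param spec an \code{\link{sdm_spec}}.
#' @return list with \code{data} (long data frame: unit, year, y, x1..xk),
#'   \code{truth} (the spec parameters) and \code{fixed_effects}.
#' @export
generate_sdm_panel <- function(spec) {
  stopifnot(inherits(spec, "sdm_spec"))
  set.seed(spec$seed)
  w <- spec$W; n <- nrow(w); Tn <- spec$n_years
  k <- length(spec$beta)
  labels <- if (!is.null(spec$labels)) spec$labels
            else sprintf("U%02d", seq_len(n))
  A <- solve(diag(n) - spec$rho * w)
  fe_i <- if (spec$effects %in% c("individual", "twoway"))
    stats::rnorm(n, sd = spec$fe_scale) else rep(0, n)
  fe_t <- if (spec$effects %in% c("time", "twoway"))
    stats::rnorm(Tn, sd = spec$fe_scale) else rep(0, Tn)
  rows <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    X <- matrix(stats::rnorm(n * k), n, k)
    eps <- if (spec$sigma > 0) stats::rnorm(n, sd = spec$sigma)
           else rep(0, n)
    rhs <- X %*% spec$beta + w %*% X %*% spec$theta_durbin +
           fe_i + fe_t[t] + eps
    yt <- drop(A %*% rhs)
    rows[[t]] <- data.frame(unit = labels, year = t, y = yt,
                            X, check.names = FALSE)
  }
  d <- do.call(rbind, rows)
  names(d)[-(1:3)] <- paste0("x", seq_len(k))
  rownames(d) <- NULL
  list(data = d,
       truth = spec[c("rho", "beta", "theta_durbin", "sigma",
                      "effects")],
       fixed_effects = list(individual = fe_i, time = fe_t))
}

#' Packaged province-level efficiency fixture
#'
#' The 31-unit by 11-year grid of published super-efficiency scores
#' (2009-2019) with region labels and the printed per-row max/min/mean
#' columns, at 3-decimal precision. This is the only real-data object in
#' the package; it drives the regional-aggregation cross-checks and lets
#' the spatial stages run without the unavailable yearbook inputs.
#'
#' @return an \code{\link{efficiency_table}} with regions; the printed
#'   row summaries are in \code{attr(x, "printed_summaries")}.
#' @export
fixture_table3 <- function() {
  path <- system.file("extdata", "table3_efficiency.csv",
                      package = "effspace")
  d <- utils::read.csv(path, check.names = FALSE)
  yr <- grep("^y[0-9]{4}$", names(d), value = TRUE)
  s <- as.matrix(d[, yr])
  dimnames(s) <- list(d$unit, sub("^y", "", yr))
  tab <- efficiency_table(s, regions = stats::setNames(d$region, d$unit))
  attr(tab, "printed_summaries") <-
    data.frame(unit = d$unit, max = d$max, min = d$min, mean = d$mean)
  tab
}
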