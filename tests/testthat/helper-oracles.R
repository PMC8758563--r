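# Independent oracles and instance generators used across the suite.

# Random positive DEA cross-section: m inputs, s goods, q bads, n units.
random_instance <- function(n = 8, m = 2, s = 1, q = 1) {
  list(x = matrix(stats::runif(m * n, 0.5, 2), m),
       y = matrix(stats::runif(s * n, 0.5, 2), s),
       u = if (q) matrix(stats::runif(q * n, 0.5, 2), q) else NULL)
}

# Brute-force EBM oracle: for fixed reference intensities lambda the radial
# factors have closed-form optima (theta at its lower bound; the
# denominator is nondecreasing in phi, so phi at its upper bound), leaving
# a low-dimensional minimisation over lambda solved by dense grid search
# plus Nelder-Mead refinement. Independent of the LP path.
oracle_ebm <- function(x, y, u, k, params, super = TRUE,
                       fix_theta = FALSE, fix_phi = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(u)) u <- as.matrix(u)
  n <- ncol(x); m <- nrow(x); s <- nrow(y)
  q <- if (is.null(u)) 0L else nrow(u)
  ref <- if (super) setdiff(seq_len(n), k) else seq_len(n)
  ein <- params$epsilon_in; eout <- params$epsilon_out
  wi <- params$w_in; wr <- params$w_out; wp <- params$w_bad
  fval <- function(lam) {
    lam <- pmax(lam, 0)
    rx <- drop(x[, ref, drop = FALSE] %*% lam) / x[, k]
    ry <- drop(y[, ref, drop = FALSE] %*% lam) / y[, k]
    ru <- if (q) drop(u[, ref, drop = FALSE] %*% lam) / u[, k] else NULL
    th_lo <- max(rx)
    phi_hi <- min(ry)
    phi_lo <- if (q) max(ru) else 0
    th <- if (fix_theta) 1 else th_lo
    if (fix_theta && th_lo > 1 + 1e-9) return(Inf)
    phi <- if (fix_phi) 1 else phi_hi
    if (fix_phi && (phi_lo > 1 + 1e-9 || phi_hi < 1 - 1e-9)) return(Inf)
    if (!fix_phi && phi_lo > phi_hi + 1e-12) return(Inf)
    if (phi <= 1e-12) return(Inf)
    num <- th - ein * sum(wi * (th - rx))
    den <- phi + eout * (sum(wr * (ry - phi)) +
                         if (q) sum(wp * (phi - ru)) else 0)
    if (den <= 1e-12) return(Inf)
    num / den
  }
  nl <- length(ref)
  grid <- seq(0, 3, by = 0.25)
  pts <- as.matrix(do.call(expand.grid, rep(list(grid), nl)))
  vals <- apply(pts, 1, fval)
  best <- Inf
  ord <- order(vals)[seq_len(min(12, length(vals)))]
  for (i in ord) {
    if (!is.finite(vals[i])) next
    if (nl == 1L) {
      lohi <- c(max(pts[i, 1] - 0.3, 0), pts[i, 1] + 0.3)
      op <- stats::optimize(function(l) fval(l), lohi,
                            tol = 1e-12)
      best <- min(best, op$objective)
    } else {
      op <- stats::optim(pts[i, ], fval, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-12))
      op2 <- stats::optim(op$par, fval, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-12))
      best <- min(best, op$value, op2$value)
    }
  }
  if (!is.finite(best)) NA_real_ else best
}

# Double-loop Moran's I, the textbook formula evaluated naively.
oracle_moran <- function(x, w) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  n * num / (sum(w) * sum(z^2))
}

# Long-format panel data frame from a spatial weights object and a DGP.
iid_panel <- function(W, Tn = 11, k = 6,
                      beta = c(0.5, -0.3, 0.2, 0.8, -0.5, 0.1),
                      sd = 1) {
  labels <- W$labels
  d <- expand.grid(unit = labels, year = seq_len(Tn),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  X <- matrix(stats::rnorm(nrow(d) * k), nrow(d))
  d <- data.frame(d, X)
  names(d)[-(1:2)] <- paste0("x", seq_len(k))
  d$y <- drop(X %*% beta) + stats::rnorm(nrow(d), sd = sd)
  d
}

fml6 <- y ~ x1 + x2 + x3 + x4 + x5 + x6
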