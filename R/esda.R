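.as_w <- function(W) {
  if (inherits(W, "spatial_weights")) W$w else as.matrix(W)
}

#' Global Moran's I
#'
#' Cross-product spatial autocorrelation statistic
#' \deqn{I = n \sum_i\sum_j W_{ij}(x_i-\bar x)(x_j-\bar x) /
#'       (\sum_i\sum_j W_{ij} \cdot \sum_i (x_i-\bar x)^2),}
#' with expectation \eqn{-1/(n-1)} under spatial randomness.
#'
#' @param x per-unit values (length n >= 3, non-constant).
#' @param W spatial weights (\code{\link{spatial_weights}} or matrix),
#'   typically row-standardised.
#' @return object of class \code{moran} with fields \code{I},
#'   \code{expected}, \code{n}.
#' @export
global_morans_i <- function(x, W) {
  w <- .as_w(W)
  n <- length(x)
  if (n < 3L) stop("need at least 3 units")
  if (nrow(w) != n) stop("weight matrix does not match x")
  z <- x - mean(x)
  if (sum(z^2) < .Machine$double.eps * n)
    stop("degenerate variance: x is constant")
  s0 <- sum(w)
  I <- n * drop(crossprod(z, w %*% z)) / (s0 * sum(z^2))
  structure(list(I = I, expected = -1 / (n - 1), n = n, method = "none"),
            class = "moran")
}

#' Inference for global Moran's I
#'
#' \code{method = "normal"} standardises I with the randomisation
#' (permutation-moment) variance; \code{method = "permutation"} draws
#' random relabellings and reports the pseudo p-value
#' \eqn{(1 + \#\{I_{perm} \ge I_{obs}\})/(n_{perm}+1)} (one-sided
#' \code{"greater"} by default; \code{"less"} and \code{"two.sided"} use
#' the corresponding tail counts). The analytic z-score is reported in
#' both modes.
#'
#' @inheritParams global_morans_i
#' @param method \code{"permutation"} (default) or \code{"normal"}.
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return a \code{moran} object with \code{z}, \code{p} and, for
#'   permutation inference, \code{perm} (the permuted statistics),
#'   \code{n_perm} and \code{seed}.
#' @export
moran_inference <- function(x, W, method = c("permutation", "normal"),
                            alternative = c("greater", "less",
                                            "two.sided"),
                            n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  w <- .as_w(W)
  res <- global_morans_i(x, W)
  n <- res$n
  z <- x - mean(x)
  s0 <- sum(w)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
           b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
          ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
  res$z <- (res$I - EI) / sqrt(varI)
  res$method <- method
  res$alternative <- alternative
  if (method == "normal") {
    res$p <- switch(alternative,
                    greater = stats::pnorm(res$z, lower.tail = FALSE),
                    less = stats::pnorm(res$z),
                    two.sided = 2 * stats::pnorm(abs(res$z),
                                                 lower.tail = FALSE))
  } else {
    if (n_perm < 99) stop("use at least 99 permutations")
    if (!is.null(seed)) set.seed(seed)
    zc <- z; ss <- sum(zc^2)
    Ip <- replicate(n_perm, {
      zp <- sample(zc)
      n * drop(crossprod(zp, w %*% zp)) / (s0 * ss)
    })
    res$perm <- Ip
    res$n_perm <- n_perm
    res$seed <- seed
    res$p <- switch(alternative,
      greater = (1 + sum(Ip >= res$I)) / (n_perm + 1),
      less = (1 + sum(Ip <= res$I)) / (n_perm + 1),
      two.sided = (1 + sum(abs(Ip - EI) >= abs(res$I - EI))) /
                  (n_perm + 1))
  }
  res
}

#' @export
print.moran <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected, x$n))
  if (!is.null(x$z)) cat(sprintf("  z = %.3f", x$z))
  if (!is.null(x$p))
    cat(sprintf(", p = %.4g [%s, %s]", x$p, x$method, x$alternative))
  cat("\n")
  invisible(x)
}

#' Local Moran scatter quadrants
#'
#' Classifies every unit by the sign of its own deviation from the mean
#' and the sign of its spatial lag's deviation: HH (high surrounded by
#' high), LH (low surrounded by high), LL, HL. Exact zero deviations are
#' assigned to the low side by the documented tie rule.
#'
#' @inheritParams global_morans_i
#' @param W row-standardised weights.
#' @return data frame with per-unit columns \code{value}, \code{lag},
#'   \code{local_i} (local Moran contribution) and \code{quadrant}.
#' @export
local_moran_quadrants <- function(x, W) {
  w <- .as_w(W)
  n <- length(x)
  z <- x - mean(x)
  if (sum(z^2) < .Machine$double.eps * n)
    stop("degenerate variance: x is constant")
  lag <- drop(w %*% x)
  lz <- lag - mean(x)
  hi <- z > 0; lhi <- lz > 0          # ties (exact zero) fall to "L"
  quadrant <- ifelse(hi & lhi, "HH",
              ifelse(!hi & lhi, "LH",
              ifelse(!hi & !lhi, "LL", "HL")))
  m2 <- sum(z^2) / n
  out <- data.frame(unit = if (!is.null(names(x))) names(x)
                           else rownames(w),
                    value = x, lag = lag, local_i = z * lz / m2,
                    quadrant = quadrant)
  rownames(out) <- NULL
  out
}

#' Getis-Ord Gi* hot-spot statistic
#'
#' Share form: \eqn{G_i^* = \sum_j W_{ij} x_j / \sum_j x_j} with
#' self-inclusive weights (the star variant). With \code{star = FALSE}
#' the plain Gi (self-exclusive) is computed. \code{standardized = TRUE}
#' additionally returns the usual z-score form.
#'
#' @param x positive per-unit values.
#' @param W base spatial weights (zero diagonal); for the star variant a
#'   unit self-weight is added before row standardisation.
#' @param star include the unit itself in its neighbourhood.
#' @param standardize_rows row-standardise the (self-inclusive) weights
#'   before computing the share (default \code{TRUE}).
#' @return data frame with columns \code{unit}, \code{gi} and \code{z}.
#' @export
getis_ord_gstar <- function(x, W, star = TRUE, standardize_rows = TRUE) {
  w <- .as_w(W)
  n <- length(x)
  if (sum(x) == 0) stop("sum of x must be nonzero")
  wb <- w
  if (star) diag(wb) <- diag(wb) + ifelse(diag(wb) > 0, 0, 1)
  if (standardize_rows) wb <- row_standardize(wb)$w
  gi <- drop(wb %*% x) / sum(x)
  xb <- mean(x); s <- sqrt(mean(x^2) - xb^2)
  wi <- rowSums(wb); w2 <- rowSums(wb^2)
  denom <- s * sqrt(pmax((n * w2 - wi^2) / (n - 1), 0))
  zi <- ifelse(denom > 0, (drop(wb %*% x) - xb * wi) / denom, NA_real_)
  lab <- names(x)
  if (is.null(lab)) lab <- rownames(w)
  if (is.null(lab)) lab <- paste0("U", seq_len(n))
  data.frame(unit = lab, gi = gi, z = zi)
}
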