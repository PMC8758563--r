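#' Non-oriented radial super-efficiency score (direct formulation)
#'
#' Minimises theta/phi subject to the reference-technology constraints
#' (inputs within theta times the unit's inputs, desirable outputs at least
#' phi times, undesirable outputs at most phi times), with the evaluated
#' unit excluded from the reference set when \code{super = TRUE}. Built as
#' its own inequality LP (by constant-returns homogeneity phi is pinned at
#' 1), independent of the general EBM solver; the two agree whenever the
#' EBM epsilons are zero. Constant returns to scale only.
#'
#' @inheritParams solve_ebm_super
#' @return list with \code{gamma}, \code{theta}, \code{phi},
#'   \code{lambda}, \code{feasible}.
#' @export
solve_radial_super <- function(x, y, u = NULL, k, super = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(u)) u <- as.matrix(u)
  n <- ncol(x); m <- nrow(x); s <- nrow(y)
  q <- if (is.null(u)) 0L else nrow(u)
  ref <- if (super) setdiff(seq_len(n), k) else seq_len(n)
  nl <- length(ref)
  nv <- 1L + nl                       # Theta, Lambda (Phi pinned at 1)
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  for (i in seq_len(m)) {             # sum L x_ij - Theta x_ik <= 0
    A1 <- rbind(A1, c(-x[i, k], x[i, ref])); b1 <- c(b1, 0)
  }
  for (r in seq_len(s)) {             # sum L y_rj >= y_rk
    A2 <- rbind(A2, c(0, y[r, ref])); b2 <- c(b2, y[r, k])
  }
  if (q) for (p in seq_len(q)) {      # sum L u_pj <= u_pk
    A1 <- rbind(A1, c(0, u[p, ref])); b1 <- c(b1, u[p, k])
  }
  sol <- .lp_solve(c(1, numeric(nl)), A1 = A1, b1 = b1,
                   A2 = A2, b2 = b2)
  if (sol$status != 1L)
    return(list(feasible = FALSE, gamma = NA_real_))
  lam <- numeric(n); lam[ref] <- sol$x[-1]
  list(feasible = TRUE, gamma = unname(sol$value),
       theta = unname(sol$x[1]), phi = 1, lambda = lam)
}

#' Non-oriented slack-based measure (SBM) super-efficiency score
#'
#' The pure slack-based limit of the EBM family: radial factors fixed at 1,
#' the score is the ratio of one minus the weighted input-slack shares to
#' one plus the weighted output-slack shares (desirable and undesirable).
#' Built directly from the slack formulation via its own Charnes-Cooper
#' transform, independent of the general EBM solver; the two agree for the
#' theta = epsilon = 1 configuration.
#'
#' @inheritParams solve_ebm_super
#' @param w_in,w_out,w_bad slack weights; default uniform (1/m on inputs,
#'   1/(s+q) across all outputs).
#' @return list with \code{gamma}, slack vectors, \code{lambda},
#'   \code{feasible}.
#' @export
solve_sbm_super <- function(x, y, u = NULL, k, super = TRUE,
                            w_in = NULL, w_out = NULL, w_bad = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(u)) u <- as.matrix(u)
  n <- ncol(x); m <- nrow(x); s <- nrow(y)
  q <- if (is.null(u)) 0L else nrow(u)
  if (is.null(w_in)) w_in <- rep(1 / m, m)
  if (is.null(w_out)) w_out <- rep(1 / (s + q), s)
  if (is.null(w_bad)) w_bad <- rep(1 / (s + q), q)
  ref <- if (super) setdiff(seq_len(n), k) else seq_len(n)
  nl <- length(ref)
  # variables: t, Lambda (nl), Sin (m), Sout (s), Sbad (q)
  nv <- 1L + nl + m + s + q
  iT <- 1L; iL <- 1L + seq_len(nl); iSi <- 1L + nl + seq_len(m)
  iSo <- 1L + nl + m + seq_len(s)
  iSb <- if (q) 1L + nl + m + s + seq_len(q) else integer(0)
  obj <- numeric(nv); obj[iT] <- 1; obj[iSi] <- -w_in / x[, k]
  A3 <- NULL; b3 <- NULL
  nr <- numeric(nv); nr[iT] <- 1; nr[iSo] <- w_out / y[, k]
  if (q) nr[iSb] <- w_bad / u[, k]
  A3 <- rbind(A3, nr); b3 <- 1
  for (i in seq_len(m)) { r <- numeric(nv)
    r[iL] <- x[i, ref]; r[iSi[i]] <- 1; r[iT] <- -x[i, k]
    A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  for (r0 in seq_len(s)) { r <- numeric(nv)
    r[iL] <- y[r0, ref]; r[iSo[r0]] <- -1; r[iT] <- -y[r0, k]
    A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  if (q) for (p in seq_len(q)) { r <- numeric(nv)
    r[iL] <- u[p, ref]; r[iSb[p]] <- 1; r[iT] <- -u[p, k]
    A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  sol <- .lp_solve_eq(obj, A3, b3)
  if (sol$status != 1L || sol$x[iT] < 1e-12)
    return(list(feasible = FALSE, gamma = NA_real_))
  tt <- sol$x[iT]
  lam <- numeric(n); lam[ref] <- sol$x[iL] / tt
  list(feasible = TRUE, gamma = unname(sol$value),
       slack_in = unname(sol$x[iSi] / tt),
       slack_out = unname(sol$x[iSo] / tt),
       slack_bad = if (q) unname(sol$x[iSb] / tt) else numeric(0),
       lambda = lam)
}
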