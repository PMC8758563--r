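#' Parameters of the epsilon-based measure (EBM) model
#'
#' The EBM objective blends a radial contraction/expansion pair
#' (theta, phi) with weighted non-radial slacks. \code{epsilon_in} and
#' \code{epsilon_out} in \code{[0, 1]} set the non-radial share on the
#' input and output side; the weights are nonnegative and normalised
#' (input weights sum to 1; desirable and undesirable output weights sum
#' to 1 jointly).
#'
#' @param epsilon_in,epsilon_out non-radial share on each side, in [0, 1].
#' @param w_in input weights, length m, sum 1.
#' @param w_out desirable-output weights, length s.
#' @param w_bad undesirable-output weights, length q (may be empty);
#'   \code{sum(w_out) + sum(w_bad)} must be 1.
#' @param rts returns to scale: \code{"crs"} or \code{"vrs"}.
#' @return object of class \code{ebm_params}.
#' @export
ebm_params <- function(epsilon_in, epsilon_out = epsilon_in, w_in, w_out,
                       w_bad = numeric(0), rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  chk01 <- function(e, nm) if (!is.finite(e) || e < 0 || e > 1)
    stop(nm, " must lie in [0, 1]")
  chk01(epsilon_in, "epsilon_in"); chk01(epsilon_out, "epsilon_out")
  if (any(w_in < 0) || any(w_out < 0) || any(w_bad < 0))
    stop("weights must be nonnegative")
  if (abs(sum(w_in) - 1) > 1e-8) stop("input weights must sum to 1")
  if (abs(sum(w_out) + sum(w_bad) - 1) > 1e-8)
    stop("output weights (desirable + undesirable) must sum to 1")
  structure(list(epsilon_in = epsilon_in, epsilon_out = epsilon_out,
                 w_in = w_in, w_out = w_out, w_bad = w_bad, rts = rts),
            class = "ebm_params")
}

# Tone-Tsutsui diversity of two positive series: mean absolute deviation of
# the log ratios, relative to their range. Zero for proportional series;
# at most 1/2.
.diversity <- function(a, b) {
  cj <- log(a / b)
  rng <- max(cj) - min(cj)
  if (rng < 1e-12) return(0)
  mean(abs(cj - mean(cj))) / rng
}

# Affinity matrix of the rows of A (variables x units): S = 1 - 2D.
.affinity_matrix <- function(A) {
  m <- nrow(A)
  S <- diag(1, m)
  if (m > 1L)
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m)
      S[a, b] <- S[b, a] <- 1 - 2 * .diversity(A[a, ], A[b, ])
  S
}

# Principal eigenpair of a nonnegative symmetric affinity matrix; the
# Perron eigenvector is normalised to sum 1 (made nonnegative by sign fix).
.affinity_eps <- function(A) {
  m <- nrow(A)
  if (m == 1L) return(list(eps = 0, w = 1))
  S <- .affinity_matrix(A)
  e <- eigen(S, symmetric = TRUE)
  w <- e$vectors[, 1]
  if (sum(w) < 0) w <- -w
  w <- pmax(w, 0); w <- w / sum(w)
  eps <- (m - e$values[1]) / (m - 1)
  list(eps = min(max(eps, 0), 1), w = w)
}

#' Data-driven epsilon and weights for the EBM model
#'
#' Implements the affinity/diversity procedure of the EBM's originators:
#' pairwise affinity of the (log-ratio) profiles of the input series yields
#' an affinity matrix whose principal eigenvector gives the input weights
#' and whose principal eigenvalue gives the diversity-based epsilon;
#' likewise on the output side, where desirable and undesirable outputs
#' form one block. With a single series on a side the non-radial part is
#' empty and epsilon is 0 by convention.
#'
#' @param x input matrix (m x n), strictly positive.
#' @param y desirable output matrix (s x n).
#' @param u undesirable output matrix (q x n) or \code{NULL}.
#' @param rts returns to scale for the resulting parameter set.
#' @param common_epsilon when \code{TRUE} (default) a single epsilon — the
#'   mean of the input- and output-side diversity values — is used on both
#'   sides, matching the single-epsilon formulation of the scoring model.
#' @return an \code{\link{ebm_params}} object.
#' @export
determine_epsilon_weights <- function(x, y, u = NULL,
                                      rts = c("crs", "vrs"),
                                      common_epsilon = TRUE) {
  rts <- match.arg(rts)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(u)) u <- as.matrix(u)
  if (ncol(x) < 2L) stop("need at least two units")
  if (any(x <= 0) || any(y <= 0) || (!is.null(u) && any(u <= 0)))
    stop("positive data required")
  ein <- .affinity_eps(x)
  O <- rbind(y, u)
  eout <- .affinity_eps(O)
  s <- nrow(y)
  e_in <- ein$eps; e_out <- eout$eps
  if (common_epsilon) e_in <- e_out <- mean(c(ein$eps, eout$eps))
  ebm_params(epsilon_in = e_in, epsilon_out = e_out,
             w_in = ein$w,
             w_out = eout$w[seq_len(s)],
             w_bad = if (nrow(O) > s) eout$w[(s + 1):nrow(O)]
                     else numeric(0),
             rts = rts)
}

# --- LP core -----------------------------------------------------------

# Solve the linearised (Charnes-Cooper) EBM program for unit k.
# Variables, in order: Theta, Phi, t, Lambda_j (over reference set),
# Sin (m), Sout (s), Sbad (q). All nonnegative. Constraint senses are
# equalities: the slack variables carry the inequality content.
.solve_ebm_lp <- function(x, y, u, k, params, super = TRUE,
                          fix_theta = FALSE, fix_phi = FALSE) {
  m <- nrow(x); s <- nrow(y); q <- if (is.null(u)) 0L else nrow(u)
  n <- ncol(x)
  ref <- if (super) setdiff(seq_len(n), k) else seq_len(n)
  nl <- length(ref)
  vrs <- params$rts == "vrs"
  use_t <- vrs || fix_theta || fix_phi
  nv <- 3L + nl + m + s + q
  iTh <- 1L; iPh <- 2L; iT <- 3L
  iL <- 3L + seq_len(nl)
  iSin <- 3L + nl + seq_len(m)
  iSout <- 3L + nl + m + seq_len(s)
  iSbad <- if (q) 3L + nl + m + s + seq_len(q) else integer(0)

  obj <- numeric(nv)
  obj[iTh] <- 1
  obj[iSin] <- -params$epsilon_in * params$w_in / x[, k]

  A3 <- NULL; b3 <- NULL
  row <- function(...) { r <- numeric(nv); v <- list(...)
    for (i in seq(1, length(v), by = 2)) r[v[[i]]] <- v[[i + 1]]; r }
  # normalisation: Phi + eps_out * (sum w_r Sout_r / y_rk + sum w_p Sbad_p / u_pk) = 1
  nr <- numeric(nv); nr[iPh] <- 1
  nr[iSout] <- params$epsilon_out * params$w_out / y[, k]
  if (q) nr[iSbad] <- params$epsilon_out * params$w_bad / u[, k]
  A3 <- rbind(A3, nr); b3 <- c(b3, 1)
  for (i in seq_len(m)) {    # sum L x_ij + Sin_i - Theta x_ik = 0
    r <- numeric(nv); r[iL] <- x[i, ref]; r[iSin[i]] <- 1
    r[iTh] <- -x[i, k]; A3 <- rbind(A3, r); b3 <- c(b3, 0)
  }
  for (r0 in seq_len(s)) {   # sum L y_rj - Sout_r - Phi y_rk = 0
    r <- numeric(nv); r[iL] <- y[r0, ref]; r[iSout[r0]] <- -1
    r[iPh] <- -y[r0, k]; A3 <- rbind(A3, r); b3 <- c(b3, 0)
  }
  if (q) for (p in seq_len(q)) {  # sum L u_pj + Sbad_p - Phi u_pk = 0
    r <- numeric(nv); r[iL] <- u[p, ref]; r[iSbad[p]] <- 1
    r[iPh] <- -u[p, k]; A3 <- rbind(A3, r); b3 <- c(b3, 0)
  }
  if (vrs) { r <- numeric(nv); r[iL] <- 1; r[iT] <- -1
             A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  if (fix_theta) { r <- numeric(nv); r[iTh] <- 1; r[iT] <- -1
                   A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  if (fix_phi) { r <- numeric(nv); r[iPh] <- 1; r[iT] <- -1
                 A3 <- rbind(A3, r); b3 <- c(b3, 0) }
  if (!use_t) { r <- numeric(nv); r[iT] <- 1   # pin unused t at 0
                A3 <- rbind(A3, r); b3 <- c(b3, 0) }

  sol <- .lp_solve_eq(obj, A3, b3)
  if (sol$status != 1L)
    return(list(feasible = FALSE, status = sol$status, gamma = NA_real_))
  v <- sol$x
  tt <- if (use_t) v[iT] else 1
  if (use_t && tt < 1e-12)
    return(list(feasible = FALSE, status = 0L, gamma = NA_real_))
  lam <- numeric(n); lam[ref] <- v[iL] / tt
  list(feasible = TRUE, status = 1L,
       gamma = unname(sol$value),
       theta = unname(v[iTh] / tt), phi = unname(v[iPh] / tt),
       slack_in = unname(v[iSin] / tt), slack_out = unname(v[iSout] / tt),
       slack_bad = if (q) unname(v[iSbad] / tt) else numeric(0),
       lambda = lam)
}

#' Solve the (super-efficiency) EBM program for one unit
#'
#' Minimises the ratio of the radial input factor theta net of weighted
#' input slacks to the radial output factor phi augmented by weighted
#' desirable- and undesirable-output slacks, over reference sets that
#' exclude the evaluated unit when \code{super = TRUE}. Undesirable
#' outputs enter the reference constraints scaled by phi and reduced by
#' their own slack. The fractional program is linearised exactly
#' (Charnes-Cooper); scores above 1 rank units on the frontier. With
#' \code{form = "radial"} both epsilons are 0 (pure radial model); with
#' \code{form = "sbm"} theta and phi are fixed at 1 and epsilon at 1
#' (pure slack-based model).
#'
#' @param x,y,u cross-section matrices (variables x units); \code{u} may
#'   be \code{NULL}.
#' @param k evaluated unit (column index).
#' @param params an \code{\link{ebm_params}}; defaults to uniform weights
#'   and the data-driven epsilon of
#'   \code{\link{determine_epsilon_weights}}.
#' @param super exclude unit k from its own reference set.
#' @param form \code{"ebm"}, \code{"radial"} or \code{"sbm"}.
#' @return list of class \code{ebm_result}: \code{gamma} (the score),
#'   \code{theta}, \code{phi}, slack vectors, reference intensities
#'   \code{lambda}, and \code{feasible}. Infeasible programs (a known
#'   super-efficiency pathology) return \code{feasible = FALSE} and an
#'   \code{NA} score, never a fabricated value.
#' @export
solve_ebm_super <- function(x, y, u = NULL, k, params = NULL,
                            super = TRUE,
                            form = c("ebm", "radial", "sbm")) {
  form <- match.arg(form)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(u)) u <- as.matrix(u)
  if (any(x <= 0) || any(y <= 0) || (!is.null(u) && any(u <= 0)))
    stop("positive data required")
  if (is.null(params)) params <- determine_epsilon_weights(x, y, u)
  if (form == "radial")
    params <- ebm_params(0, 0, params$w_in, params$w_out, params$w_bad,
                         rts = params$rts)
  if (form == "sbm")
    params <- ebm_params(1, 1, params$w_in, params$w_out, params$w_bad,
                         rts = params$rts)
  res <- .solve_ebm_lp(x, y, u, k, params,
                       super = super,
                       fix_theta = form == "sbm",
                       fix_phi = form == "sbm")
  res$unit <- k; res$form <- form; res$params <- params
  class(res) <- "ebm_result"
  res
}

#' @export
print.ebm_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("EBM result (unit %s): infeasible program (status %d)\n",
                as.character(x$unit), x$status))
  } else {
    cat(sprintf("EBM result (unit %s, %s): gamma* = %.6f (theta %.4f, phi %.4f)\n",
                as.character(x$unit), x$form, x$gamma, x$theta, x$phi))
  }
  invisible(x)
}

#' Score a full panel, one frontier per calendar year
#'
#' Applies the (super-efficiency) EBM model cross-sectionally: each year's
#' units are scored against that year's frontier. Parameters may be fixed
#' or determined per year from the data (\code{params = "auto"}).
#'
#' @param panel a \code{\link{dea_panel}}.
#' @param params \code{"auto"} (affinity/diversity per year) or a fixed
#'   \code{\link{ebm_params}}.
#' @param super use super-efficiency (reference set excludes the unit).
#' @param form model form passed to \code{\link{solve_ebm_super}}.
#' @param regions optional region scheme for the resulting table.
#' @return an \code{\link{efficiency_table}}; infeasible cells are
#'   \code{NA} with a diagnostic attribute \code{"infeasible"} listing
#'   them.
#' @export
score_panel <- function(panel, params = "auto", super = TRUE,
                        form = "ebm", regions = NULL) {
  stopifnot(inherits(panel, "dea_panel"))
  n <- length(panel$units); nT <- length(panel$years)
  sc <- matrix(NA_real_, n, nT,
               dimnames = list(panel$units, as.character(panel$years)))
  infeas <- character(0)
  par_used <- vector("list", nT)
  for (ti in seq_len(nT)) {
    cs <- panel_year(panel, panel$years[ti])
    p <- if (identical(params, "auto"))
      determine_epsilon_weights(cs$x, cs$y, cs$u) else params
    par_used[[ti]] <- p
    for (k in seq_len(n)) {
      r <- solve_ebm_super(cs$x, cs$y, cs$u, k, params = p, super = super,
                           form = form)
      if (r$feasible) sc[k, ti] <- r$gamma
      else infeas <- c(infeas,
                       paste0(panel$units[k], ":", panel$years[ti]))
    }
  }
  tab <- efficiency_table(sc, regions = regions)
  attr(tab, "infeasible") <- infeas
  names(par_used) <- as.character(panel$years)
  attr(tab, "params") <- par_used
  tab
}

#' Scale efficiency from CRS and VRS scores
#'
#' SE = TE / PTE, where TE is the constant-returns score and PTE the
#' variable-returns score of the same unit on the same cross-section,
#' both computed without the super-efficiency exclusion so that
#' TE <= PTE holds by construction.
#'
#' @param te_crs,te_vrs positive scores (scalars, vectors or matrices of
#'   equal shape).
#' @return SE, same shape as the inputs.
#' @export
decompose_efficiency <- function(te_crs, te_vrs) {
  if (any(te_crs <= 0, na.rm = TRUE) || any(te_vrs <= 0, na.rm = TRUE))
    stop("scores must be > 0")
  te_crs / te_vrs
}

#' Full TE/PTE/SE decomposition of a panel
#'
#' Scores the panel under standard (non-super) CRS and VRS EBM models and
#' returns the efficiency table with TE, PTE and SE = TE/PTE companions.
#'
#' @param panel a \code{\link{dea_panel}}.
#' @param params \code{"auto"} or a fixed \code{\link{ebm_params}} (its
#'   \code{rts} field is overridden per run).
#' @param regions optional region scheme.
#' @return an \code{\link{efficiency_table}} whose main grid is the CRS
#'   (TE) score with \code{te}, \code{pte}, \code{se} companions.
#' @export
efficiency_decomposition <- function(panel, params = "auto",
                                     regions = NULL) {
  stopifnot(inherits(panel, "dea_panel"))
  with_rts <- function(p, rts) {
    if (identical(p, "auto")) return(p)
    ebm_params(p$epsilon_in, p$epsilon_out, p$w_in, p$w_out, p$w_bad, rts)
  }
  te_tab <- score_panel(panel, with_rts(params, "crs"), super = FALSE,
                        regions = regions)
  vrs_params <- if (identical(params, "auto")) {
    # reuse the per-year auto parameters from the CRS run, switched to VRS
    NULL
  } else with_rts(params, "vrs")
  pte <- matrix(NA_real_, length(panel$units), length(panel$years),
                dimnames = dimnames(te_tab$scores))
  for (ti in seq_along(panel$years)) {
    cs <- panel_year(panel, panel$years[ti])
    p <- if (is.null(vrs_params)) {
      pa <- attr(te_tab, "params")[[ti]]
      ebm_params(pa$epsilon_in, pa$epsilon_out, pa$w_in, pa$w_out,
                 pa$w_bad, "vrs")
    } else vrs_params
    for (k in seq_along(panel$units)) {
      r <- solve_ebm_super(cs$x, cs$y, cs$u, k, params = p, super = FALSE)
      if (r$feasible) pte[k, ti] <- r$gamma
    }
  }
  te <- te_tab$scores
  efficiency_table(te, regions = regions, te = te, pte = pte,
                   se = decompose_efficiency(te, pte))
}
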