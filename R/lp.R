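# Dense two-phase primal simplex for the small equality-form LPs behind
# the DEA programs:  min c'x  s.t.  A x = b,  x >= 0.
# Bland's anti-cycling rule throughout; tolerances sized for the
# unit-scaled Charnes-Cooper programs (tens of variables, ~10 rows).
# Returns list(status, x, value); status 1 = optimal, -1 = infeasible,
# 3 = unbounded, 0 = iteration limit.
.lp_solve_eq <- function(obj, A, b, tol = 1e-9, maxit = NULL) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  if (is.null(maxit)) maxit <- 200L * (n + m)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  ntot <- n + m                        # decision vars + artificials
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  pivot <- function(tab, pr, pc) {
    piv <- tab[pr, pc]
    tab[pr, ] <- tab[pr, ] / piv
    other <- setdiff(seq_len(nrow(tab)), pr)
    tab[other, ] <- tab[other, ] - outer(tab[other, pc], tab[pr, ])
    tab
  }
  run <- function(tab, basis, cost, allowed) {
    # canonical reduced-cost row for the current basis
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = 0L, tab = tab, basis = basis))
      cb <- cost[basis]
      red <- cost[seq_len(ntot)] -
        drop(crossprod(tab[, seq_len(ntot), drop = FALSE], cb))
      enter <- 0L
      for (j in allowed) {             # Bland: first improving index
        if (j %in% basis) next
        if (red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L)
        return(list(status = 1L, tab = tab, basis = basis))
      col <- tab[, enter]
      rhs <- tab[, ntot + 1L]
      cand <- which(col > tol)
      if (!length(cand))
        return(list(status = 3L, tab = tab, basis = basis))
      ratio <- rhs[cand] / col[cand]
      best <- min(ratio)
      sel <- cand[ratio <= best + tol]
      leave <- sel[which.min(basis[sel])]   # Bland tie-break
      tab <- pivot(tab, leave, enter)
      basis[leave] <- enter
    }
  }
  # phase 1: minimise the artificial sum
  cost1 <- c(numeric(n), rep(1, m))
  r1 <- run(tab, basis, cost1, seq_len(ntot))
  if (r1$status != 1L) return(list(status = r1$status, x = NULL,
                                   value = NA_real_))
  tab <- r1$tab; basis <- r1$basis
  phase1 <- sum(tab[basis > n, ntot + 1L])
  if (phase1 > 1e-7) return(list(status = -1L, x = NULL,
                                 value = NA_real_))
  # drive surviving artificials out of the basis (or drop redundant rows)
  keep <- rep(TRUE, m)
  for (i in which(basis > n)) {
    row <- tab[i, seq_len(n)]
    j <- which(abs(row) > tol)[1]
    if (is.na(j)) keep[i] <- FALSE else {
      tab <- pivot(tab, i, j); basis[i] <- j
    }
  }
  if (!all(keep)) {
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
  }
  # phase 2
  cost2 <- c(obj, rep(0, m))
  r2 <- run(tab, basis, cost2, seq_len(n))
  if (r2$status != 1L) return(list(status = r2$status, x = NULL,
                                   value = NA_real_))
  x <- numeric(n)
  x[r2$basis] <- r2$tab[, ntot + 1L]
  list(status = 1L, x = x, value = sum(obj * x))
}

# Convenience wrapper with inequality rows:
#   A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0 — slack/surplus columns are
# appended internally.
.lp_solve <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                      A3 = NULL, b3 = NULL, tol = 1e-9) {
  n <- length(obj)
  m1 <- if (is.null(A1)) 0L else nrow(A1)
  m2 <- if (is.null(A2)) 0L else nrow(A2)
  m3 <- if (is.null(A3)) 0L else nrow(A3)
  A <- rbind(
    if (m1) cbind(A1, diag(m1), matrix(0, m1, m2)),
    if (m2) cbind(A2, matrix(0, m2, m1), -diag(m2)),
    if (m3) cbind(A3, matrix(0, m3, m1 + m2)))
  b <- c(b1, b2, b3)
  r <- .lp_solve_eq(c(obj, numeric(m1 + m2)), A, b, tol = tol)
  if (r$status == 1L) r$x <- r$x[seq_len(n)]
  r
}
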