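## Dense two-phase revised simplex for
##   max c'x  s.t.  Aeq x = beq,  Ain x <= bin,  x >= 0
##
## Written for the small, dense LPs this package builds (tens of variables):
## pruning requires a *vertex* (basic) optimum, and KKT differentiation
## requires exact basis duals, so a simplex with a deterministic pivot rule
## is the right tool -- interior-point solutions would land in the relative
## interior of optimal faces and break both.
##
## Pivoting: Dantzig rule with a fixed index tie-break, switching to Bland's
## rule after an iteration threshold to guarantee termination on degenerate
## problems.  All arithmetic is dense base-R; the basis system is re-solved
## from scratch each iteration, trading speed for numerical freshness.

simplex_solve <- function(cvec, Aeq = NULL, beq = NULL, Ain = NULL,
                          bin = NULL, tol = 1e-9, max_iter = 10000L) {
  n <- length(cvec)
  Aeq <- if (is.null(Aeq)) matrix(0, 0L, n) else as.matrix(Aeq)
  Ain <- if (is.null(Ain)) matrix(0, 0L, n) else as.matrix(Ain)
  beq <- as.numeric(beq %||% numeric(0))
  bin <- as.numeric(bin %||% numeric(0))
  me <- nrow(Aeq); mi <- nrow(Ain); m <- me + mi

  ## augmented columns: structural | slack (one per inequality)
  A <- rbind(cbind(Aeq, matrix(0, me, mi)),
             cbind(Ain, diag(1, mi)))
  b <- c(beq, bin)
  ## orient all rows to b >= 0 (track sign to restore duals)
  sgn <- ifelse(b < 0, -1, 1)
  A <- A * sgn
  b <- b * sgn
  ntot <- n + mi

  ## phase 1: artificial basis
  Aph <- cbind(A, diag(1, m))
  basis <- ntot + seq_len(m)
  x <- c(rep(0, ntot), b)
  cph <- c(rep(0, ntot), rep(-1, m))
  r1 <- simplex_iterate(Aph, b, cph, basis, tol, max_iter,
                        forbid = integer(0))
  if (r1$status != "optimal" || r1$objective < -1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible"))
  basis <- r1$basis
  ## drive any residual artificials out of the (degenerate) basis
  art <- which(basis > ntot)
  drop_rows <- integer(0)
  for (k in art) {
    row <- k
    B <- Aph[, basis, drop = FALSE]
    ## row k of B^-1 A over real columns; pick any nonzero pivot
    e <- numeric(m); e[row] <- 1
    yrow <- tryCatch(solve(t(B), e), error = function(err) NULL)
    if (is.null(yrow)) next
    piv <- drop(crossprod(yrow, Aph[, seq_len(ntot), drop = FALSE]))
    piv[basis[basis <= ntot]] <- 0
    j <- which(abs(piv) > 1e-7)
    if (length(j)) basis[k] <- j[[1L]] else drop_rows <- c(drop_rows, k)
  }
  keep <- setdiff(seq_len(m), drop_rows)  # redundant rows (rank-deficient)
  A2 <- A[keep, , drop = FALSE]
  b2 <- b[keep]
  basis2 <- basis[keep]
  stopifnot(all(basis2 <= ntot))

  ## phase 2
  c2 <- c(cvec, rep(0, mi))
  r2 <- simplex_iterate(A2, b2, c2, basis2, tol, max_iter,
                        forbid = integer(0))
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  if (r2$status != "optimal") return(list(status = r2$status))

  xfull <- r2$x
  ## duals on kept rows; redundant rows get dual 0
  y <- numeric(m)
  y[keep] <- r2$y
  y <- y * sgn                          # restore original row orientation
  x <- xfull[seq_len(n)]
  slack <- xfull[n + seq_len(mi)]
  list(status = "optimal",
       x = x,
       objective = sum(cvec * x),
       y_eq = if (me) y[seq_len(me)] else numeric(0),
       y_in = if (mi) y[me + seq_len(mi)] else numeric(0),
       slack_in = slack,
       reduced_costs = r2$reduced[seq_len(n)],
       basis = r2$basis,
       n_slack = mi,
       dropped_rows = setdiff(seq_len(m), keep))
}

## core iteration on  max c'x, A x = b, x >= 0  from a feasible basis
simplex_iterate <- function(A, b, cvec, basis, tol, max_iter, forbid) {
  m <- nrow(A); ntot <- ncol(A)
  bland_after <- 500L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "iteration_limit"))
    B <- A[, basis, drop = FALSE]
    xB <- solve(B, b)
    y <- solve(t(B), cvec[basis])
    reduced <- cvec - drop(crossprod(A, y))
    reduced[basis] <- 0
    cand <- which(reduced > tol)
    cand <- setdiff(cand, forbid)
    if (!length(cand)) {
      x <- numeric(ntot)
      x[basis] <- xB
      return(list(status = "optimal", x = x, basis = basis, y = y,
                  reduced = reduced, objective = sum(cvec[basis] * xB)))
    }
    j <- if (iter > bland_after) min(cand) else cand[which.max(reduced[cand])]
    d <- solve(B, A[, j])
    pos <- which(d > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- xB[pos] / d[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol * max(1, abs(rmin))]
    ## leave by smallest basis index among ties (deterministic, anti-cycling)
    leave <- ties[which.min(basis[ties])]
    basis[leave] <- j
  }
}
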