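#' Homogenize a pruned inhomogeneous problem with a slack variable
#'
#' Splits the pruned stoichiometric matrix into free columns `S1` and fixed
#' columns `S2`: the reactions held at known values -- the active fixed
#' (maintenance-like) fluxes *and*, by default, the objective reaction at
#' its optimal value.  Their aggregate contribution `w = S2 v2` becomes one
#' extra column paired with a slack coordinate `vbar`, giving the cone
#' `{x : [S1 | w] x = 0, x >= 0}`.  At `vbar = 1` points of the cone are
#' exactly the solutions of the original inhomogeneous problem that attain
#' the optimal objective-to-fixed-flux ratio; its extreme rays with
#' `vbar > 0` are the optimal flux modes.
#'
#' Folding the objective is what makes the modes *optimal*: a mode with a
#' lower objective-per-maintenance ratio cannot reach `vbar = 1`.  With
#' `fold_objective = FALSE` and no fixed fluxes the system degrades to the
#' plain flux cone `FC(S)` whose support-minimal rays are the classical
#' elementary flux modes.
#'
#' Inactive inhomogeneous constraints (possible under
#' `fixed_flux_mode = "at-least"`) are relaxed to homogeneous, i.e. their
#' reactions stay free columns.
#'
#' @param pruned a [prune()] result.
#' @param fold_objective fold the objective reaction at its optimal value
#'   into the fixed block (default `TRUE`).
#' @param tol_act activity tolerance for one-sided fixed fluxes.
#' @return An object of class `"homogenized_system"`: matrix `A` (rows =
#'   metabolites, columns = free reactions then `vbar`), `free_rxns`,
#'   `folded` (data frame reaction/value), `has_vbar`, and the reference
#'   point `x_ref` (free fluxes of the pruned optimum, with `vbar = 1`).
#' @export
homogenize <- function(pruned, fold_objective = TRUE, tol_act = 1e-6) {
  model <- pruned$model
  lp <- pruned$lp
  sol <- pruned$solution
  v <- reaction_fluxes(lp, sol)
  mets <- names(model$metabolites)
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry

  fixed <- character(0)
  for (f in model$fixed_fluxes) {
    cval <- resolve_value(f$value, lp$params)
    act <- lp$fixed_flux_mode == "equality" ||
      abs(v[[f$reaction_id]] - cval) <= tol_act * max(1, cval)
    if (act) fixed <- c(fixed, f$reaction_id)
  }
  obj <- model$objective_reaction
  if (fold_objective && obj %in% fixed)
    stop("objective reaction carries a fixed flux; cannot fold it twice",
         call. = FALSE)
  folded_ids <- if (fold_objective) c(fixed, obj) else fixed
  folded_vals <- v[folded_ids]
  free <- setdiff(rxns, folded_ids)

  if (length(folded_ids)) {
    w <- S[, folded_ids, drop = FALSE] %*% folded_vals
    A <- cbind(S[, free, drop = FALSE], `vbar__` = drop(w))
    x_ref <- c(v[free], `vbar__` = 1)
    has_vbar <- TRUE
  } else {
    A <- S[, free, drop = FALSE]
    x_ref <- v[free]
    has_vbar <- FALSE
  }
  res <- max(abs(A %*% x_ref))
  if (res > 1e-6 * max(1, max(abs(x_ref))))
    stop("homogenization inconsistency: reference solution violates ",
         "A x = 0 by ", format(res), call. = FALSE)
  structure(list(A = A, free_rxns = free,
                 folded = data.frame(reaction = folded_ids,
                                     value = unname(folded_vals),
                                     stringsAsFactors = FALSE),
                 has_vbar = has_vbar, x_ref = x_ref,
                 objective_reaction = obj,
                 fold_objective = fold_objective),
            class = "homogenized_system")
}

#' @export
print.homogenized_system <- function(x, ...) {
  cat("homogenized_system: ", nrow(x$A), " metabolites x ",
      length(x$free_rxns), " free reactions",
      if (x$has_vbar) " + vbar", "; folded: ",
      toString(x$folded$reaction), "\n", sep = "")
  invisible(x)
}

#' Extreme rays of a pointed cone by Double Description
#'
#' Enumerates the extreme rays of `{x : A x = 0, x >= 0}` with the
#' incremental Double Description method in its null-space form: the
#' null-space basis of `A` is pivoted so that `d` coordinate constraints
#' are satisfied by construction (a simplicial starting cone), and the
#' remaining nonnegativity constraints are inserted one at a time --
#' descending number of nonzeros in the corresponding columns of `A`, a
#' standard heuristic against intermediate ray blow-up.  At each insertion,
#' rays on the violating side are discarded and adjacent ray pairs with
#' opposite signs are combined; adjacency uses the algebraic rank test on
#' the constraints tight at both rays.  Output is deterministic:
#' rays are normalized to unit 1-norm and ordered lexicographically by
#' support.
#'
#' @param A constraint matrix (equalities).
#' @param tol numerical tolerance for sign classification and rank tests.
#' @return A matrix with one column per extreme ray (possibly 0 columns).
#' @export
double_description <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  qa <- qr(A, LAPACK = TRUE)
  rank <- qr_rank(qa)
  d <- n - rank
  if (d == 0L)
    return(matrix(numeric(0), n, 0, dimnames = list(colnames(A), NULL)))
  N <- nullspace_basis(A, rank)

  ## pivot rows making the top block invertible -> simplicial start
  qn <- qr(t(N), LAPACK = TRUE)
  piv_rows <- qn$pivot[seq_len(d)]
  R <- N %*% solve(N[piv_rows, , drop = FALSE])   # R[piv_rows, ] == I
  rays <- lapply(seq_len(d), function(j) R[, j])

  rest <- setdiff(seq_len(n), piv_rows)
  nnz <- colSums(abs(A) > tol)
  rest <- rest[order(-nnz[rest], rest)]
  processed <- piv_rows

  for (i in rest) {
    vals <- vapply(rays, `[[`, numeric(1), i)
    scales <- vapply(rays, function(r) max(abs(r)), numeric(1))
    cls <- ifelse(vals > tol * scales, 1L, ifelse(vals < -tol * scales,
                                                  -1L, 0L))
    keep <- rays[cls >= 0L]
    pos <- which(cls == 1L); neg <- which(cls == -1L)
    for (p in pos) for (q in neg) {
      if (!rays_adjacent(rays[[p]], rays[[q]], A, processed, n, tol)) next
      newr <- vals[p] * rays[[q]] - vals[q] * rays[[p]]
      newr[i] <- 0                                  # exact by construction
      newr <- newr / max(abs(newr))
      keep[[length(keep) + 1L]] <- newr
    }
    processed <- c(processed, i)
    rays <- keep
  }

  if (!length(rays))
    return(matrix(numeric(0), n, 0, dimnames = list(colnames(A), NULL)))
  M <- vapply(rays, function(r) {
    r[abs(r) <= tol * max(abs(r))] <- 0
    r / sum(abs(r))
  }, numeric(n))
  M <- matrix(M, nrow = n, dimnames = list(colnames(A), NULL))
  supp_key <- apply(M > 0, 2, function(s)
    paste(sprintf("%05d", which(s)), collapse = ","))
  M[, order(supp_key), drop = FALSE]
}

qr_rank <- function(qrd, tol = 1e-9) {
  dR <- abs(diag(qr.R(qrd)))
  if (!length(dR)) return(0L)
  sum(dR > tol * max(dR, 1))
}

nullspace_basis <- function(A, rank = NULL) {
  n <- ncol(A)
  qa <- qr(t(A), LAPACK = TRUE)      # QR of A' : null space = trailing Q cols
  if (is.null(rank)) rank <- qr_rank(qa)
  Q <- qr.Q(qa, complete = TRUE)
  Q[, seq.int(rank + 1L, n), drop = FALSE]
}

## algebraic adjacency: rays r,s (both satisfying A x = 0 and x_i >= 0 on
## processed coordinates) are adjacent iff the constraints tight at both --
## A plus the unit rows of their common zero coordinates -- have rank n - 2
rays_adjacent <- function(r, s, A, processed, n, tol) {
  zr <- abs(r) <= tol * max(abs(r))
  zs <- abs(s) <= tol * max(abs(s))
  common <- intersect(processed[zr[processed] & zs[processed]], processed)
  if (length(common) == 0L && nrow(A) == 0L) return(n == 2L)
  E <- matrix(0, length(common), n)
  E[cbind(seq_along(common), common)] <- 1
  D <- rbind(A, E)
  qr_rank(qr(D, LAPACK = TRUE)) == n - 2L
}

#' Brute-force support-minimal mode enumeration (test oracle)
#'
#' Enumerates candidate supports in increasing cardinality; a subset of
#' columns is a mode support iff the null space of the restricted matrix is
#' one-dimensional with a strictly sign-definite generator and no recorded
#' smaller support is contained in it.  Exponential in the column count --
#' an independent oracle for [double_description()] on small instances, not
#' an algorithm.
#'
#' @param A constraint matrix.
#' @param max_cols refuse instances wider than this (default 14).
#' @param tol numerical tolerance.
#' @return Matrix of modes (one column each, unit 1-norm, lexicographic
#'   support order), as from [double_description()].
#' @export
brute_force_modes <- function(A, max_cols = 14L, tol = 1e-9) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n > max_cols)
    stop("brute_force_modes: ", n, " columns exceeds max_cols = ", max_cols,
         call. = FALSE)
  supports <- list()
  modes <- list()
  for (k in seq_len(n)) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      if (any(vapply(supports, function(s) all(s %in% S), logical(1))))
        next
      As <- A[, S, drop = FALSE]
      qrd <- qr(t(As), LAPACK = TRUE)
      if (qr_rank(qrd) != k - 1L) next
      Ns <- nullspace_basis(As)
      if (ncol(Ns) != 1L) next
      g <- drop(Ns)
      if (all(g > tol) || all(g < -tol)) {
        v <- numeric(n)
        v[S] <- abs(g)
        supports[[length(supports) + 1L]] <- S
        modes[[length(modes) + 1L]] <- v / sum(v)
      }
    }
  }
  if (!length(modes))
    return(matrix(numeric(0), n, 0, dimnames = list(colnames(A), NULL)))
  M <- matrix(unlist(modes), nrow = n, dimnames = list(colnames(A), NULL))
  supp_key <- apply(M > 0, 2, function(s)
    paste(sprintf("%05d", which(s)), collapse = ","))
  M[, order(supp_key), drop = FALSE]
}

#' Optimal flux modes of a homogenized system
#'
#' Runs [double_description()] on the homogenized matrix and keeps the
#' extreme rays with a positive slack component, rescaled to `vbar = 1`
#' (the optimality normalization).  Rays with `vbar = 0` -- modes that
#' cannot meet the fixed fluxes -- are discarded but counted in the
#' `n_vbar_zero` attribute.  For a purely homogeneous system all rays are
#' returned as elementary flux modes at unit 1-norm.
#'
#' @param hs a [homogenize()] result.
#' @param tol_zero threshold for a positive slack component.
#' @return A list of class `"flux_mode_set"`: `modes` (matrix, one column
#'   per mode over `free_rxns` [+ `vbar`]), `has_vbar`, `n_vbar_zero`.
#' @export
ofms <- function(hs, tol_zero = 1e-6) {
  rays <- double_description(hs$A)
  if (!hs$has_vbar) {
    return(structure(list(modes = rays, has_vbar = FALSE, n_vbar_zero = 0L,
                          free_rxns = hs$free_rxns),
                     class = "flux_mode_set"))
  }
  vb <- rays[nrow(rays), ]
  sel <- vb > tol_zero
  if (!any(sel))
    stop("infeasible homogenization: no extreme ray with vbar > 0 ",
         "(contradicts pruned feasibility)", call. = FALSE)
  modes <- rays[, sel, drop = FALSE]
  modes <- sweep(modes, 2, modes[nrow(modes), ], `/`)
  structure(list(modes = modes, has_vbar = TRUE,
                 n_vbar_zero = sum(!sel), free_rxns = hs$free_rxns),
            class = "flux_mode_set")
}

#' @export
print.flux_mode_set <- function(x, ...) {
  cat("flux_mode_set: ", ncol(x$modes),
      if (x$has_vbar) " OFMs (vbar = 1)" else " EFMs (|.|_1 = 1)",
      if (x$n_vbar_zero) paste0("; ", x$n_vbar_zero, " vbar=0 rays dropped"),
      "\n", sep = "")
  invisible(x)
}

#' Decompose the pruned optimum into flux mode weights
#'
#' Solves the nonnegative least squares problem `min ||R lambda - x*||`
#' where `R` stacks the mode vectors columnwise and `x*` is the pruned
#' optimum over the free reactions (with the `vbar` coordinate equal to 1).
#' At a genuine optimum the residual is numerically zero, the weights of a
#' `vbar`-normalized system sum to one, and at most `K` (the number of
#' enzyme pool constraints) weights are positive.
#'
#' @param hs a [homogenize()] result.
#' @param fm a [ofms()] result on `hs`.
#' @param K number of enzymatic pool constraints (for the usage bound).
#' @param tol_zero weight activity threshold.
#' @param tol_residual relative residual bound.
#' @return A list of class `"ofm_decomposition"`: `lambda`, `residual`,
#'   `n_active`, `K`.
#' @export
decompose <- function(hs, fm, K, tol_zero = 1e-6, tol_residual = 1e-8) {
  R <- fm$modes
  target <- hs$x_ref
  if (ncol(R) == 0L) stop("no modes to decompose into", call. = FALSE)
  fit <- pracma::lsqnonneg(R, target)
  lambda <- stats::setNames(fit$x, colnames(R) %||%
                              paste0("ofm", seq_len(ncol(R))))
  resid <- max(abs(R %*% lambda - target))
  if (resid > tol_residual * max(1, max(abs(target))))
    stop("decomposition failure: residual ", format(resid),
         " (missed mode or wrong active set)", call. = FALSE)
  if (fm$has_vbar && abs(sum(lambda) - 1) > 1e-8)
    stop("decomposition failure: weights sum to ", format(sum(lambda)),
         ", expected 1", call. = FALSE)
  n_active <- sum(lambda > tol_zero)
  if (n_active > K)
    stop("decomposition failure: ", n_active, " active modes exceed the ",
         "enzymatic constraint count K = ", K, call. = FALSE)
  names(lambda) <- paste0("ofm", seq_along(lambda))
  structure(list(lambda = lambda, residual = resid, n_active = n_active,
                 K = K, modes = fm$modes, has_vbar = fm$has_vbar,
                 free_rxns = fm$free_rxns),
            class = "ofm_decomposition")
}

#' @export
print.ofm_decomposition <- function(x, ...) {
  cat("ofm_decomposition: ", length(x$lambda), " modes, ", x$n_active,
      " active (K = ", x$K, "), residual ", format(x$residual), "\n",
      sep = "")
  print(round(x$lambda, 6))
  invisible(x)
}

#' Differentiate OFM usage with respect to parameters
#'
#' The weights solve `R(p) lambda(p) = x*(p)` where both the optimal
#' solution `x*` and the mode matrix `R` depend on the parameters: kinetic
#' and capacity parameters move the optimal objective `z*`, which enters
#' the homogenized fixed column `w` and therefore rescales every mode.
#' Differentiating gives
#' \deqn{R_{sub} \frac{d\lambda}{dp} = \frac{dx^*_{sub}}{dp} -
#'   \frac{dR_{sub}}{dp} \lambda}
#' with `dR/dp` recovered per mode from its support system
#' `A_S r = -w`, `dw/dp = S_obj dz*/dp`.  The row subset `sub` always
#' contains the `vbar` (weight-sum) row -- making the conservation
#' `sum(dlambda) = 0` exact -- and is completed greedily by maximal
#' orthogonal pivots for conditioning.
#'
#' Fixed-flux parameters change the cone itself in a way the mode matching
#' does not cover and are rejected.
#'
#' @param dec an [decompose()] result (with `vbar`).
#' @param hs the [homogenize()] result it came from.
#' @param pruned the [prune()] result.
#' @param sens a [kkt_differentiate()] result on the pruned LP covering all
#'   flux variables.
#' @param param_names parameters to differentiate (default: all in `sens`).
#' @param params named numeric registry (for scaled coefficients).
#' @param tol_zero weight activity threshold for scaled output.
#' @return A list of class `"ofm_sensitivity"`: `raw` (#modes x #params,
#'   `dlambda/dp`) and `scaled` (`(p/lambda) dlambda/dp`, `NA` where
#'   `lambda <= tol_zero`).
#' @export
ofm_sensitivity <- function(dec, hs, pruned, sens, param_names = NULL,
                            params = NULL, tol_zero = 1e-6) {
  if (!dec$has_vbar)
    stop("ofm_sensitivity requires a vbar-normalized decomposition ",
         "(fold_objective = TRUE)", call. = FALSE)
  lp <- pruned$lp
  if (is.null(param_names)) param_names <- sens$params
  if (is.null(params)) params <- lp$params
  fixed_pars <- unique(lp$param_dep$param[
    grepl("^fix__", lp$param_dep$row)])
  bad <- intersect(param_names, fixed_pars)
  if (length(bad))
    stop("fixed-flux parameter(s) ", toString(bad), " alter the cone; ",
         "their OFM-usage sensitivity is unsupported", call. = FALSE)

  ## reaction-level sensitivities: sum per-isozyme flux variable rows
  rxn_sens <- function(rxn)
    colSums(sens$raw[lp$rxn_vars[[rxn]], param_names, drop = FALSE])
  free <- dec$free_rxns
  dv_free <- matrix(0, length(free), length(param_names),
                    dimnames = list(free, param_names))
  for (rx in free) dv_free[rx, ] <- rxn_sens(rx)
  dz <- rxn_sens(hs$objective_reaction)

  ## dR/dp per mode: support system A_S r = -w, dw/dp = S_obj dz/dp
  A <- hs$A
  nfree <- length(free)
  w <- A[, ncol(A)]
  S_obj <- {
    r <- pruned$model$reactions[[hs$objective_reaction]]
    s <- stats::setNames(numeric(nrow(A)), rownames(A))
    s[names(r$stoichiometry)] <- r$stoichiometry
    s
  }
  nm <- ncol(dec$modes)
  dR <- array(0, dim = c(nfree + 1L, nm, length(param_names)),
              dimnames = list(c(free, "vbar__"), NULL, param_names))
  for (k in seq_len(nm)) {
    mode_k <- dec$modes[, k]
    supp <- which(mode_k[seq_len(nfree)] > tol_zero)
    As <- A[, supp, drop = FALSE]
    qs <- qr(As)
    for (j in seq_along(param_names)) {
      dw <- S_obj * dz[[j]]
      dr <- qr.coef(qs, -dw)
      dR[supp, k, j] <- dr
    }
  }

  ## row selection: vbar row first (exact conservation), then greedy
  ## max-orthogonal-pivot over the mode-space row vectors
  Rstack <- rbind(dec$modes[seq_len(nfree), , drop = FALSE],
                  vbar__ = rep(1, nm))
  rownames(Rstack) <- c(free, "vbar__")
  sel <- nfree + 1L
  basis <- matrix(Rstack[sel, ] / sqrt(sum(Rstack[sel, ]^2)), ncol = 1)
  while (length(sel) < nm) {
    resid <- Rstack - (Rstack %*% basis) %*% t(basis)
    resid[sel, ] <- 0
    norms <- sqrt(rowSums(resid^2))
    pick <- which.max(norms)
    if (norms[pick] < 1e-12)
      stop("mode matrix row selection failed: rows are rank-deficient",
           call. = FALSE)
    sel <- c(sel, pick)
    newb <- resid[pick, ] / norms[pick]
    basis <- cbind(basis, newb)
  }
  R_sub <- Rstack[sel, , drop = FALSE]
  kap <- kappa(R_sub, exact = TRUE)
  if (kap > 1e10)
    stop("ill-conditioned mode submatrix (condition number ",
         format(kap), ")", call. = FALSE)

  dv_stack <- rbind(dv_free, vbar__ = rep(0, length(param_names)))
  rhs <- dv_stack[sel, , drop = FALSE]
  for (j in seq_along(param_names)) {
    dRj <- matrix(dR[, , j], nrow = nfree + 1L)
    rhs[, j] <- rhs[, j] - dRj[sel, , drop = FALSE] %*% dec$lambda
  }
  dlambda <- solve(R_sub, rhs)
  dimnames(dlambda) <- list(names(dec$lambda), param_names)

  scaled <- sweep(dlambda, 2, params[param_names], `*`) /
    ifelse(dec$lambda > tol_zero, dec$lambda, NA)
  dimnames(scaled) <- dimnames(dlambda)
  structure(list(raw = dlambda, scaled = scaled, lambda = dec$lambda,
                 params = param_names),
            class = "ofm_sensitivity")
}

#' @export
print.ofm_sensitivity <- function(x, ...) {
  cat("ofm_sensitivity: ", nrow(x$raw), " modes x ", ncol(x$raw),
      " parameters\n", sep = "")
  invisible(x)
}

#' Finite-difference oracle for OFM usage
#'
#' Re-solves the pruned model at perturbed parameters, re-homogenizes,
#' re-enumerates the OFMs (matching them to the baseline modes by support)
#' and re-decomposes, then takes the central difference of the weights.
#' Independent cross-check for [ofm_sensitivity()].
#'
#' @param pruned a [prune()] result.
#' @param dec the baseline [decompose()] result.
#' @param param_names parameters to perturb.
#' @param rel_step relative step (default 1e-3).
#' @param fold_objective passed to [homogenize()].
#' @return Matrix #modes x #params of central-difference `dlambda/dp`.
#' @export
ofm_fd_oracle <- function(pruned, dec, param_names, rel_step = 1e-3,
                          fold_objective = TRUE) {
  params <- pruned$lp$params
  nfree <- length(dec$free_rxns)
  base_supp <- apply(dec$modes[seq_len(nfree), , drop = FALSE] > 1e-6, 2,
                     function(s) paste(dec$free_rxns[s], collapse = ","))
  lambda_at <- function(p) {
    lp <- build_lp(pruned$model, p,
                   fixed_flux_mode = pruned$lp$fixed_flux_mode)
    sol <- solve_lp(lp)
    if (sol$status != "optimal") return(NULL)
    pr <- pruned
    pr$lp <- lp; pr$solution <- sol
    hs <- homogenize(pr, fold_objective = fold_objective)
    fm <- ofms(hs)
    d <- decompose(hs, fm, K = dec$K)
    supp <- apply(d$modes[seq_len(nfree), , drop = FALSE] > 1e-6, 2,
                  function(s) paste(dec$free_rxns[s], collapse = ","))
    idx <- match(base_supp, supp)
    if (anyNA(idx)) return(NULL)
    unname(d$lambda[idx])
  }
  out <- matrix(NA_real_, length(dec$lambda), length(param_names),
                dimnames = list(names(dec$lambda), param_names))
  for (pn in param_names) {
    h <- rel_step * params[[pn]]
    up <- params; up[[pn]] <- params[[pn]] + h
    dn <- params; dn[[pn]] <- params[[pn]] - h
    lu <- lambda_at(up); ld <- lambda_at(dn)
    if (is.null(lu) || is.null(ld)) {
      warning("OFM finite difference failed for '", pn, "'", call. = FALSE)
      next
    }
    out[, pn] <- (lu - ld) / (2 * h)
  }
  out
}

#' Export flux modes / OFM sensitivities as TSV
#'
#' `write_modes_tsv()` writes one row per (mode, reaction) with positive
#' flux; `write_ofm_sensitivity_tsv()` writes
#' `mode_id  parameter  dlambda_dparam  scaled`.
#'
#' @param fm a [ofms()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modes_tsv <- function(fm, path) {
  rn <- rownames(fm$modes)
  rows <- do.call(rbind, lapply(seq_len(ncol(fm$modes)), function(k) {
    v <- fm$modes[, k]
    sel <- v > 0
    data.frame(mode_id = paste0("ofm", k), reaction = rn[sel],
               flux = unname(v[sel]), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_modes_tsv
#' @param osens an [ofm_sensitivity()] result.
#' @export
write_ofm_sensitivity_tsv <- function(osens, path) {
  df <- data.frame(
    mode_id = rep(rownames(osens$raw), times = ncol(osens$raw)),
    parameter = rep(colnames(osens$raw), each = nrow(osens$raw)),
    dlambda_dparam = as.vector(osens$raw),
    scaled = as.vector(osens$scaled))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
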