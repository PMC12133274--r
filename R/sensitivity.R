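#' Detect the active constraint set at a vertex optimum
#'
#' Collects all equality rows, the inequality rows fulfilled with equality
#' (slack below `tol_act`, relative to the right-hand side), and the
#' variables sitting at their zero bound.  At a vertex at least as many
#' constraints as variables must be active; fewer indicates a non-vertex
#' (interior-point-like) solution and is an error.  An active inequality
#' whose dual is also (near) zero violates strict complementarity -- the
#' derivative there is only one-sided -- and triggers a warning.
#'
#' @param lp a [build_lp()] result.
#' @param sol an optimal [solve_lp()] solution.
#' @param tol_act activity tolerance.
#' @return A list of class `"active_set"`: `eq_rows`, `active_in`,
#'   `active_bounds` (variable ids at zero), `weak` (active rows failing
#'   strict complementarity).
#' @export
detect_active_set <- function(lp, sol, tol_act = 1e-6) {
  stopifnot(sol$status == "optimal")
  in_ids <- rownames(lp$Ain)
  slack <- sol$slack_in
  active_in <- in_ids[abs(slack) <= tol_act * pmax(1, abs(lp$bin))]
  weak <- active_in[abs(sol$duals_in[active_in]) <= tol_act]
  if (length(weak))
    warning("strict complementarity fails for active row(s): ",
            toString(weak), "; derivatives may be one-sided",
            call. = FALSE)
  active_bounds <- names(sol$primal)[sol$primal <= tol_act]
  n_active <- nrow(lp$Aeq) + length(active_in) + length(active_bounds)
  if (n_active < ncol(lp$Aeq))
    stop("non-vertex solution: ", n_active, " active constraints for ",
         ncol(lp$Aeq), " variables", call. = FALSE)
  structure(list(eq_rows = rownames(lp$Aeq), active_in = active_in,
                 active_bounds = active_bounds, weak = weak,
                 tol_act = tol_act),
            class = "active_set")
}

## Assemble the active system M x = b, eliminate redundant rows by pivoted
## QR, and return a square invertible M of size n = #variables.
active_system <- function(lp, active, tol_rank = 1e-9) {
  n <- ncol(lp$Aeq)
  Mb <- lp$Aeq
  bb <- lp$beq
  if (length(active$active_in)) {
    Mb <- rbind(Mb, lp$Ain[active$active_in, , drop = FALSE])
    bb <- c(bb, lp$bin[active$active_in])
  }
  if (length(active$active_bounds)) {
    B <- matrix(0, length(active$active_bounds), n,
                dimnames = list(paste0("bnd__", active$active_bounds),
                                colnames(lp$Aeq)))
    B[cbind(seq_len(nrow(B)),
            match(active$active_bounds, colnames(lp$Aeq)))] <- 1
    Mb <- rbind(Mb, B)
    bb <- c(bb, stats::setNames(rep(0, nrow(B)), rownames(B)))
  }
  ## rank-revealing selection of n independent rows (columns of t(Mb))
  qrd <- qr(t(Mb), tol = tol_rank, LAPACK = TRUE)
  rank <- sum(abs(diag(qr.R(qrd))) >
                tol_rank * max(abs(diag(qr.R(qrd))), 1))
  if (rank < n)
    stop("active constraint matrix is rank-deficient (rank ", rank,
         " < ", n, " variables); run verify_unique() -- the optimum is ",
         "likely non-unique", call. = FALSE)
  sel <- sort(qrd$pivot[seq_len(n)])
  dropped <- rownames(Mb)[-sel]
  list(M = Mb[sel, , drop = FALSE], b = bb[sel], dropped = dropped,
       all_rows = rownames(Mb))
}

#' Implicit sensitivities by KKT differentiation
#'
#' At a unique vertex optimum the active constraints `M x = b(p)` (with `M`
#' entries depending on parameters through the recorded partials) and
#' stationarity `c - M'y = 0` determine the solution map implicitly.
#' Differentiating both gives, for each parameter `p_j`,
#' \deqn{M \frac{\partial x}{\partial p_j} =
#'   \frac{\partial b}{\partial p_j} - \frac{\partial M}{\partial p_j} x}
#' solved for all parameters with a single factorization of `M`.  Redundant
#' active rows (e.g. conserved-moiety steady-state rows) are removed first
#' by rank-revealing QR; rank deficiency beyond redundancy signals a
#' non-unique optimum and is an error.  Parameters that touch only inactive
#' rows get exactly-zero columns.
#'
#' @param lp a [build_lp()] result.
#' @param sol an optimal [solve_lp()] solution.
#' @param active a [detect_active_set()] result (computed if missing).
#' @param param_names parameters to differentiate against (default: every
#'   parameter with a recorded dependence).
#' @return An object of class `"sensitivity_matrix"`: `raw` is the
#'   (#variables x #parameters) matrix of derivatives, `scaled` is `NULL`
#'   until [control_coefficients()] fills it in.
#' @export
kkt_differentiate <- function(lp, sol, active = NULL, param_names = NULL) {
  if (is.null(active)) active <- detect_active_set(lp, sol)
  if (is.null(param_names))
    param_names <- sort(unique(lp$param_dep$param), method = "radix")
  sys <- active_system(lp, active)
  M <- sys$M
  n <- ncol(M)
  x <- sol$primal[colnames(M)]
  dep <- lp$param_dep
  dep_dropped <- dep$row %in% sys$dropped
  if (any(dep_dropped))
    warning("parameter-dependent active row(s) dropped as redundant: ",
            toString(unique(dep$row[dep_dropped])), call. = FALSE)

  rhs <- matrix(0, n, length(param_names),
                dimnames = list(rownames(M), param_names))
  for (j in seq_along(param_names)) {
    dj <- dep[dep$param == param_names[j] & dep$row %in% rownames(M), ,
              drop = FALSE]
    if (!nrow(dj)) next
    for (k in seq_len(nrow(dj))) {
      ri <- match(dj$row[k], rownames(M))
      if (is.na(dj$col[k])) {              # right-hand-side dependence
        rhs[ri, j] <- rhs[ri, j] + dj$partial[k]
      } else {                             # matrix-entry dependence
        ci <- match(dj$col[k], colnames(M))
        rhs[ri, j] <- rhs[ri, j] - dj$partial[k] * x[ci]
      }
    }
  }
  touched <- param_names %in% dep$param[dep$row %in% rownames(M)]
  dx <- matrix(0, n, length(param_names),
               dimnames = list(colnames(M), param_names))
  ## one factorization, applied per column: results are bitwise identical
  ## whether parameters are differentiated singly or in batch
  qrd <- qr(M)
  for (j in which(touched)) dx[, j] <- solve(qrd, rhs[, j])

  structure(list(raw = dx, scaled = NULL,
                 vars = colnames(M), params = param_names,
                 metadata = list(tol_act = active$tol_act,
                                 dropped_rows = sys$dropped,
                                 active_fingerprint =
                                   paste(sys$all_rows, collapse = "|"))),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("sensitivity_matrix: ", length(x$vars), " variables x ",
      length(x$params), " parameters",
      if (!is.null(x$scaled)) " (scaled available)", "\n", sep = "")
  invisible(x)
}

#' Scaled sensitivities (control coefficients)
#'
#' The control coefficient of variable `x_i` with respect to parameter
#' `p_j` is the log-log response `(p_j / x_i) * dx_i/dp_j`.  Entries for
#' variables with `|x_i| <= tol_zero` are undefined and set to `NA` (not
#' zero); a zero raw sensitivity gives a zero coefficient wherever defined.
#'
#' @param sens a [kkt_differentiate()] (or [finite_difference_oracle()])
#'   result.
#' @param sol the solution the sensitivities were computed at.
#' @param params named numeric parameter registry.
#' @param tol_zero threshold below which a variable counts as zero.
#' @return `sens` with the `scaled` matrix filled in.
#' @export
control_coefficients <- function(sens, sol, params, tol_zero = 1e-6) {
  if (length(sens$params) == 0L) {
    sens$scaled <- sens$raw
    return(sens)
  }
  x <- sol$primal[sens$vars]
  p <- params[sens$params]
  scaled <- sweep(sens$raw, 2, p, `*`) / ifelse(abs(x) > tol_zero, x, NA)
  dimnames(scaled) <- dimnames(sens$raw)
  sens$scaled <- scaled
  sens
}

#' Central finite-difference sensitivities (oracle)
#'
#' Re-solves the model at `p * (1 + rel_step)` and `p * (1 - rel_step)` for
#' each named parameter and takes the central difference slope
#' `(x(p+h) - x(p-h)) / (2h)`.  Intended as the independent cross-check for
#' [kkt_differentiate()]: it shares no code path with the implicit route
#' beyond the LP solver itself.  Meant to be run on a *pruned* model; no
#' re-pruning happens between perturbations.
#'
#' @param model the (pruned) [ec_model()].
#' @param params named numeric parameter registry.
#' @param param_names parameters to perturb (default: all referenced).
#' @param rel_step relative perturbation (default 1e-3, i.e. 0.1 percent).
#' @param fixed_flux_mode passed to [build_lp()].
#' @return A `"sensitivity_matrix"` whose `raw` columns are the finite
#'   difference slopes; a perturbed problem that fails to solve yields an
#'   `NA` column with a warning.
#' @export
finite_difference_oracle <- function(model, params, param_names = NULL,
                                     rel_step = 1e-3,
                                     fixed_flux_mode = "equality") {
  if (!is.numeric(rel_step) || rel_step <= 0)
    stop("rel_step must be > 0", call. = FALSE)
  if (is.null(param_names)) param_names <- referenced_params(model)
  param_names <- sort(param_names, method = "radix")
  solve_at <- function(p) {
    lp <- build_lp(model, p, fixed_flux_mode = fixed_flux_mode)
    sol <- solve_lp(lp)
    if (sol$status != "optimal") return(NULL)
    sol$primal
  }
  base_lp <- build_lp(model, params, fixed_flux_mode = fixed_flux_mode)
  vars <- colnames(base_lp$Aeq)
  out <- matrix(NA_real_, length(vars), length(param_names),
                dimnames = list(vars, param_names))
  for (pn in param_names) {
    h <- rel_step * params[[pn]]
    up <- params; up[[pn]] <- params[[pn]] + h
    dn <- params; dn[[pn]] <- params[[pn]] - h
    xu <- solve_at(up); xd <- solve_at(dn)
    if (is.null(xu) || is.null(xd)) {
      warning("perturbed problem infeasible for parameter '", pn,
              "'; entry flagged missing", call. = FALSE)
      next
    }
    out[, pn] <- (xu[vars] - xd[vars]) / (2 * h)
  }
  structure(list(raw = out, scaled = NULL, vars = vars,
                 params = param_names,
                 metadata = list(rel_step = rel_step, method = "central_fd")),
            class = "sensitivity_matrix")
}

#' Export sensitivities as TSV
#'
#' Long format `variable  parameter  dvalue_dparam  scaled`, plus a JSON
#' metadata sidecar (`<path base>_meta.json`).
#'
#' @param sens a `"sensitivity_matrix"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_tsv <- function(sens, path) {
  df <- data.frame(
    variable = rep(sens$vars, times = length(sens$params)),
    parameter = rep(sens$params, each = length(sens$vars)),
    dvalue_dparam = as.vector(sens$raw),
    scaled = if (!is.null(sens$scaled)) as.vector(sens$scaled) else NA_real_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sens$metadata,
                       paste0(sub("\\.tsv$", "", path), "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
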