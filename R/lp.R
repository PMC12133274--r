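#' Build the parametric ecFBA linear program
#'
#' Assembles the enzyme-constrained FBA problem
#' \deqn{\max v_r \ \mathrm{s.t.}\ Sv = 0,\ v \ge 0,\ v_i = k_{cat,i} e_i,\
#'   \sum_{i \in R_k} w_i e_i \le E_k,\ v_j = c_j\ (j \in R_f)}
#' as explicit dense equality/inequality blocks over flux variables (one per
#' reaction, or one per isozyme when a reaction has several) and enzyme
#' concentration variables (one per gene product used by any isozyme).
#' Pool rows weight enzyme concentrations by gene-product molar mass, so
#' capacities are in mg/gDCW.  Fixed fluxes are encoded as equality rows by
#' default, or as one-sided `>= c_j` rows with
#' `fixed_flux_mode = "at-least"`.
#'
#' Every matrix or right-hand-side entry that depends on a named parameter
#' is recorded in `param_dep` together with the partial derivative of the
#' entry with respect to the parameter; this is the hook used by
#' [kkt_differentiate()].
#'
#' @param model a validated, reversible-split [ec_model()].
#' @param params named numeric vector resolving every parameter reference in
#'   the model.
#' @param fixed_flux_mode `"equality"` (lb = ub = c_j) or `"at-least"`
#'   (v_j >= c_j).
#' @return An object of class `"parametric_lp"`: variable and row tables,
#'   the equality block (`Aeq`, `beq`), the inequality block (`Ain`,
#'   `bin`, rows oriented as `g.x <= h`), objective vector `cvec`,
#'   and the `param_dep` data frame.
#' @export
build_lp <- function(model, params = NULL,
                     fixed_flux_mode = c("equality", "at-least")) {
  fixed_flux_mode <- match.arg(fixed_flux_mode)
  assert_valid(model, params)

  ## ---- variables ----
  var_id <- character(0); var_kind <- character(0)
  var_rxn <- character(0); var_gp <- character(0)
  rxn_vars <- list()                     # reaction id -> flux var ids
  usages <- list()                       # gp id -> list(var, n, kcat, kpar)
  for (r in model$reactions) {
    n_iso <- length(r$isozymes)
    ids <- if (n_iso > 1L) paste0(r$id, "__iso", seq_len(n_iso)) else r$id
    rxn_vars[[r$id]] <- ids
    var_id <- c(var_id, ids)
    var_kind <- c(var_kind, rep("flux", length(ids)))
    var_rxn <- c(var_rxn, rep(r$id, length(ids)))
    var_gp <- c(var_gp, rep(NA_character_, length(ids)))
    if (n_iso > 0L) {
      for (k in seq_len(n_iso)) {
        iso <- r$isozymes[[k]]
        if (is.null(iso$kcat_forward))
          stop("reaction '", r$id, "': isozyme without kcat_forward after ",
               "splitting", call. = FALSE)
        kc <- resolve_value(iso$kcat_forward, params)
        if (kc <= 0)
          stop("reaction '", r$id, "': nonpositive kcat", call. = FALSE)
        kpar <- param_name(iso$kcat_forward)
        for (g in names(iso$subunit_counts)) {
          usages[[g]] <- c(usages[[g]], list(list(
            var = ids[[k]], n = iso$subunit_counts[[g]],
            kcat = kc, kpar = kpar)))
        }
      }
    }
  }
  enz_gps <- sort(names(usages) %||% character(0), method = "radix")
  evar <- if (length(enz_gps)) paste0("e__", enz_gps) else character(0)
  var_id <- c(var_id, evar)
  var_kind <- c(var_kind, rep("enzyme", length(evar)))
  var_rxn <- c(var_rxn, rep(NA_character_, length(evar)))
  var_gp <- c(var_gp, enz_gps)
  nv <- length(var_id)
  vidx <- stats::setNames(seq_len(nv), var_id)

  dep <- list()
  add_dep <- function(row, col, par, partial) {
    if (!is.na(par))
      dep[[length(dep) + 1L]] <<- data.frame(
        row = row, col = col, param = par, partial = partial,
        stringsAsFactors = FALSE)
  }

  ## ---- equality block ----
  eq_rows <- list(); eq_rhs <- numeric(0); eq_id <- character(0)
  eq_kind <- character(0)
  push_eq <- function(coef, rhs, id, kind) {
    eq_rows[[length(eq_rows) + 1L]] <<- coef
    eq_rhs[[length(eq_rhs) + 1L]] <<- rhs
    eq_id[[length(eq_id) + 1L]] <<- id
    eq_kind[[length(eq_kind) + 1L]] <<- kind
  }

  for (m in model$metabolites) {
    coef <- numeric(nv)
    for (r in model$reactions) {
      s <- unname(r$stoichiometry[m$id])
      if (!is.na(s))
        coef[vidx[rxn_vars[[r$id]]]] <- coef[vidx[rxn_vars[[r$id]]]] + s
    }
    push_eq(coef, 0, paste0("ss__", m$id), "steady_state")
  }

  for (g in enz_gps) {
    us <- usages[[g]]
    coef <- numeric(nv)
    rid <- paste0("cpl__", g)
    if (length(us) == 1L) {
      ## canonical two-nonzero form: v - (kcat/n) e = 0
      u <- us[[1L]]
      coef[vidx[[u$var]]] <- 1
      coef[vidx[[paste0("e__", g)]]] <- -u$kcat / u$n
      add_dep(rid, paste0("e__", g), u$kpar %||% NA_character_, -1 / u$n)
    } else {
      ## shared gene product: sum_u (n_u/kcat_u) v_u - e = 0
      for (u in us) {
        j <- vidx[[u$var]]
        coef[j] <- coef[j] + u$n / u$kcat
        add_dep(rid, u$var, u$kpar %||% NA_character_, -u$n / u$kcat^2)
      }
      coef[vidx[[paste0("e__", g)]]] <- -1
    }
    push_eq(coef, 0, rid, "coupling")
  }

  if (fixed_flux_mode == "equality") {
    for (f in model$fixed_fluxes) {
      coef <- numeric(nv)
      coef[vidx[rxn_vars[[f$reaction_id]]]] <- 1
      val <- resolve_value(f$value, params)
      rid <- paste0("fix__", f$reaction_id)
      add_dep(rid, NA_character_, param_name(f$value), 1)
      push_eq(coef, val, rid, "fixed_flux")
    }
  }

  ## ---- inequality block (g.x <= h) ----
  in_rows <- list(); in_rhs <- numeric(0); in_id <- character(0)
  in_kind <- character(0)
  push_in <- function(coef, rhs, id, kind) {
    in_rows[[length(in_rows) + 1L]] <<- coef
    in_rhs[[length(in_rhs) + 1L]] <<- rhs
    in_id[[length(in_id) + 1L]] <<- id
    in_kind[[length(in_kind) + 1L]] <<- kind
  }

  for (p in model$pools) {
    coef <- numeric(nv)
    mem <- intersect(p$members, enz_gps)
    for (g in mem)
      coef[vidx[[paste0("e__", g)]]] <- model$gene_products[[g]]$molar_mass
    rid <- paste0("pool__", p$id)
    add_dep(rid, NA_character_, param_name(p$capacity), 1)
    push_in(coef, resolve_value(p$capacity, params), rid, "pool")
  }

  fixed_ids <- names(model$fixed_fluxes)
  for (r in model$reactions) {
    ub <- resolve_value(r$upper_bound, params)
    if (is.finite(ub) && !(r$id %in% fixed_ids &&
                           fixed_flux_mode == "equality")) {
      coef <- numeric(nv)
      coef[vidx[rxn_vars[[r$id]]]] <- 1
      rid <- paste0("ub__", r$id)
      add_dep(rid, NA_character_, param_name(r$upper_bound), 1)
      push_in(coef, ub, rid, "upper_bound")
    }
    lb <- resolve_value(r$lower_bound, params)
    if (lb > 0 && !(r$id %in% fixed_ids && fixed_flux_mode == "equality")) {
      coef <- numeric(nv)
      coef[vidx[rxn_vars[[r$id]]]] <- -1
      rid <- paste0("lb__", r$id)
      add_dep(rid, NA_character_, param_name(r$lower_bound), -1)
      push_in(coef, -lb, rid, "lower_bound")
    }
  }
  if (fixed_flux_mode == "at-least") {
    for (f in model$fixed_fluxes) {
      coef <- numeric(nv)
      coef[vidx[rxn_vars[[f$reaction_id]]]] <- -1
      rid <- paste0("fix__", f$reaction_id)
      add_dep(rid, NA_character_, param_name(f$value), -1)
      push_in(coef, -resolve_value(f$value, params), rid, "fixed_flux")
    }
  }

  Aeq <- do.call(rbind, eq_rows)
  Ain <- if (length(in_rows)) do.call(rbind, in_rows) else
    matrix(0, 0L, nv)
  dimnames(Aeq) <- list(eq_id, var_id)
  dimnames(Ain) <- list(in_id, var_id)

  cvec <- numeric(nv)
  cvec[vidx[rxn_vars[[model$objective_reaction]]]] <- 1
  names(cvec) <- var_id

  param_dep <- if (length(dep)) do.call(rbind, dep) else
    data.frame(row = character(0), col = character(0),
               param = character(0), partial = numeric(0),
               stringsAsFactors = FALSE)

  structure(list(
    var_table = data.frame(id = var_id, kind = var_kind, reaction = var_rxn,
                           gene_product = var_gp, stringsAsFactors = FALSE),
    row_table = data.frame(id = c(eq_id, in_id),
                           kind = c(eq_kind, in_kind),
                           block = c(rep("eq", length(eq_id)),
                                     rep("in", length(in_id))),
                           stringsAsFactors = FALSE),
    Aeq = Aeq, beq = stats::setNames(eq_rhs, eq_id),
    Ain = Ain, bin = stats::setNames(in_rhs, in_id),
    cvec = cvec,
    param_dep = param_dep,
    params = params,
    objective_reaction = model$objective_reaction,
    rxn_vars = rxn_vars,
    n_pools = length(model$pools),
    fixed_flux_mode = fixed_flux_mode,
    model_id = model$id
  ), class = "parametric_lp")
}

#' @export
print.parametric_lp <- function(x, ...) {
  cat("parametric_lp '", x$model_id, "': ", nrow(x$var_table),
      " variables (", sum(x$var_table$kind == "flux"), " flux, ",
      sum(x$var_table$kind == "enzyme"), " enzyme), ",
      nrow(x$Aeq), " equality rows, ", nrow(x$Ain), " inequality rows, ",
      nrow(x$param_dep), " parameter dependences\n", sep = "")
  invisible(x)
}

#' Solve a parametric ecFBA LP
#'
#' Solves the LP with the package's deterministic two-phase simplex.  The
#' returned optimum is always a vertex (basic) solution with exact basis
#' duals: active `<=`-rows carry nonnegative duals, equality duals are
#' unrestricted.  Infeasibility and unboundedness are reported in `status`,
#' never as errors.
#'
#' @param lp a [build_lp()] result.
#' @param tol_feas solver feasibility tolerance.
#' @return An object of class `"ec_solution"`: `status`, named `primal`,
#'   `duals_eq`, `duals_in`, `reduced_costs`, `objective_value`.
#' @export
solve_lp <- function(lp, tol_feas = 1e-9) {
  res <- simplex_solve(lp$cvec, lp$Aeq, lp$beq, lp$Ain, lp$bin,
                       tol = tol_feas)
  if (res$status != "optimal")
    return(structure(list(status = res$status, primal = NULL,
                          objective_value = NA_real_),
                     class = "ec_solution"))
  structure(list(
    status = "optimal",
    primal = stats::setNames(res$x, colnames(lp$Aeq)),
    duals_eq = stats::setNames(res$y_eq, rownames(lp$Aeq)),
    duals_in = stats::setNames(res$y_in, rownames(lp$Ain)),
    slack_in = stats::setNames(res$slack_in, rownames(lp$Ain)),
    reduced_costs = stats::setNames(res$reduced_costs, colnames(lp$Aeq)),
    objective_value = res$objective
  ), class = "ec_solution")
}

#' @export
print.ec_solution <- function(x, ...) {
  cat("ec_solution: status =", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Reaction fluxes of a solution
#'
#' Aggregates per-isozyme flux variables back to reaction fluxes.
#'
#' @param lp a [build_lp()] result.
#' @param sol an optimal [solve_lp()] solution.
#' @return Named numeric vector, reaction id -> flux.
#' @export
reaction_fluxes <- function(lp, sol) {
  vapply(lp$rxn_vars, function(v) sum(sol$primal[v]), numeric(1))
}

#' Flux variability analysis at the optimum
#'
#' Fixes the objective at its optimal value (as an equality row) and
#' minimizes/maximizes each variable in turn.  A pruned model with a unique
#' optimum yields zero-width ranges for every variable; this is the
#' operational uniqueness probe used by [verify_unique()].
#'
#' @param lp a [build_lp()] result.
#' @param sol an optimal [solve_lp()] solution.
#' @param vars variable ids to scan (default: all).
#' @param tol_feas solver tolerance.
#' @return data frame with columns `id`, `min`, `max`.
#' @export
fva_at_optimum <- function(lp, sol, vars = NULL, tol_feas = 1e-9) {
  stopifnot(sol$status == "optimal")
  if (is.null(vars)) vars <- colnames(lp$Aeq)
  Aeq <- rbind(lp$Aeq, objective = lp$cvec)
  beq <- c(lp$beq, objective = sol$objective_value)
  nv <- ncol(Aeq)
  vidx <- match(vars, colnames(lp$Aeq))
  lo <- hi <- numeric(length(vars))
  for (k in seq_along(vars)) {
    obj <- numeric(nv); obj[vidx[k]] <- 1
    rmax <- simplex_solve(obj, Aeq, beq, lp$Ain, lp$bin, tol = tol_feas)
    rmin <- simplex_solve(-obj, Aeq, beq, lp$Ain, lp$bin, tol = tol_feas)
    hi[k] <- if (rmax$status == "optimal") rmax$objective else
      if (rmax$status == "unbounded") Inf else NA_real_
    lo[k] <- if (rmin$status == "optimal") -rmin$objective else
      if (rmin$status == "unbounded") -Inf else NA_real_
  }
  data.frame(id = vars, min = lo, max = hi, stringsAsFactors = FALSE)
}

#' Export a solution as TSV
#'
#' Writes `variable  kind  value  reduced_cost` and, alongside it, a duals
#' table `row  kind  dual`.
#'
#' @param lp a [build_lp()] result.
#' @param sol an optimal solution.
#' @param path output TSV path; the duals table goes to
#'   `<path base>_duals.tsv`.
#' @return `path`, invisibly.
#' @export
write_solution_tsv <- function(lp, sol, path) {
  stopifnot(sol$status == "optimal")
  df <- data.frame(variable = lp$var_table$id, kind = lp$var_table$kind,
                   value = unname(sol$primal[lp$var_table$id]),
                   reduced_cost = unname(sol$reduced_costs[lp$var_table$id]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  duals <- data.frame(
    row = c(names(sol$duals_eq), names(sol$duals_in)),
    kind = lp$row_table$kind[match(c(names(sol$duals_eq),
                                     names(sol$duals_in)),
                                   lp$row_table$id)],
    dual = c(unname(sol$duals_eq), unname(sol$duals_in)))
  dpath <- paste0(sub("\\.tsv$", "", path), "_duals.tsv")
  utils::write.table(duals, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
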