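#' Run the full differentiation pipeline
#'
#' Chains solve -> prune -> uniqueness gate -> KKT sensitivities ->
#' homogenize -> OFM enumeration -> decomposition -> OFM sensitivities,
#' optionally writing every artifact (TSV/JSON plus a reproducibility
#' manifest) to a directory.
#'
#' @param model a validated [ec_model()] (will be reversible-split if
#'   needed).
#' @param params named numeric parameter registry.
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param tol_zero,tol_act,tol_feas activity / active-set / solver
#'   tolerances.
#' @param fixed_flux_mode passed to [build_lp()].
#' @param force proceed past a failed uniqueness gate (derivatives are then
#'   undefined; for diagnostics only).
#' @return A list with every intermediate object: `lp`, `solution`,
#'   `pruned`, `unique`, `sensitivity`, `homogenized`, `modes`,
#'   `decomposition`, `ofm_sensitivity`.
#' @export
run_pipeline <- function(model, params, out_dir = NULL, tol_zero = 1e-6,
                         tol_act = 1e-6, tol_feas = 1e-9,
                         fixed_flux_mode = "equality", force = FALSE) {
  if (any(vapply(model$reactions, function(r)
    is.numeric(r$lower_bound) && r$lower_bound < 0, logical(1))))
    model <- split_reversible(model)
  lp <- build_lp(model, params, fixed_flux_mode = fixed_flux_mode)
  sol <- solve_lp(lp, tol_feas = tol_feas)
  if (sol$status != "optimal")
    stop("pipeline: model is ", sol$status, call. = FALSE)
  pruned <- prune(model, sol, lp, tol_zero = tol_zero)
  uq <- verify_unique(pruned, tol = max(tol_zero, 1e-6))
  if (!isTRUE(as.logical(uq)) && !force)
    stop("verify_unique failed: pruned optimum is not unique (max FVA ",
         "width ", format(attr(uq, "max_width")), "); derivatives are ",
         "undefined", call. = FALSE)
  active <- detect_active_set(pruned$lp, pruned$solution, tol_act = tol_act)
  sens <- kkt_differentiate(pruned$lp, pruned$solution, active)
  sens <- control_coefficients(sens, pruned$solution, params,
                               tol_zero = tol_zero)
  hs <- homogenize(pruned, tol_act = tol_act)
  fm <- ofms(hs, tol_zero = tol_zero)
  dec <- decompose(hs, fm, K = pruned$lp$n_pools, tol_zero = tol_zero)
  kin <- setdiff(sens$params, unique(pruned$lp$param_dep$param[
    grepl("^fix__", pruned$lp$param_dep$row)]))
  osens <- if (length(kin))
    ofm_sensitivity(dec, hs, pruned, sens, param_names = kin,
                    params = params, tol_zero = tol_zero) else NULL

  res <- list(lp = lp, solution = sol, pruned = pruned, unique = uq,
              sensitivity = sens, homogenized = hs, modes = fm,
              decomposition = dec, ofm_sensitivity = osens,
              config = list(tol_zero = tol_zero, tol_act = tol_act,
                            tol_feas = tol_feas,
                            fixed_flux_mode = fixed_flux_mode))
  if (!is.null(out_dir)) write_pipeline_outputs(res, model, params, out_dir)
  res
}

write_pipeline_outputs <- function(res, model, params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  save_ec_model(model, fp("model.json"))
  jsonlite::write_json(as.list(params), fp("params.json"),
                       auto_unbox = TRUE, digits = NA)
  write_solution_tsv(res$pruned$lp, res$pruned$solution, fp("solution.tsv"))
  save_ec_model(res$pruned$model, fp("pruned_model.json"))
  write_index_map_tsv(res$pruned, fp("index_map.tsv"))
  write_sensitivity_tsv(res$sensitivity, fp("sensitivity.tsv"))
  write_modes_tsv(res$modes, fp("ofms.tsv"))
  utils::write.table(
    data.frame(mode_id = names(res$decomposition$lambda),
               lambda = unname(res$decomposition$lambda)),
    fp("ofm_weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$ofm_sensitivity))
    write_ofm_sensitivity_tsv(res$ofm_sensitivity, fp("ofm_sensitivity.tsv"))
  manifest <- list(
    package = "ofmdiff",
    version = as.character(utils::packageVersion("ofmdiff")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = res$config,
    input_hashes = list(
      model = unname(tools::md5sum(fp("model.json"))),
      params = unname(tools::md5sum(fp("params.json")))),
    objective = res$solution$objective_value,
    n_ofms = length(res$decomposition$lambda))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
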