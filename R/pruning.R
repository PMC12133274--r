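#' Prune inactive reactions and enzymes from an optimal solution
#'
#' Deletes every reaction (or isozyme) whose flux, and every enzyme whose
#' concentration, is below `tol_zero` times the largest flux magnitude in
#' the reference optimum, then drops orphaned gene products, empty pools and
#' unused metabolites.  Retained backward copies of split reversible
#' reactions are recorded in `flipped`.  The pruned model's optimum is
#' provably unique (all its reactions carry strictly positive flux and an
#' enzyme cost), which is the precondition for implicit differentiation.
#'
#' The pruned LP is re-solved to obtain a vertex solution with duals for the
#' reduced variable set; if its objective deviates from the original by more
#' than `1e-6` relative, pruning is inconsistent (tolerance too aggressive,
#' or a non-vertex input solution) and an error is raised.
#'
#' @param model the (reversible-split) [ec_model()] that `sol` solves.
#' @param sol optimal [solve_lp()] solution of `lp`.
#' @param lp the [build_lp()] result `sol` was obtained from.
#' @param tol_zero relative activity threshold.
#' @return A list of class `"pruned_model"`: `model` (reduced
#'   [ec_model()]), `index_map` (named character, pruned id -> original id),
#'   `flipped` (character), `lp` (LP of the pruned model), `solution`
#'   (vertex optimum of the pruned LP).
#' @export
prune <- function(model, sol, lp, tol_zero = 1e-6) {
  stopifnot(sol$status == "optimal")
  fluxes <- sol$primal[lp$var_table$id[lp$var_table$kind == "flux"]]
  scale <- max(abs(fluxes))
  if (scale <= 0) stop("cannot prune an all-zero optimum", call. = FALSE)
  thr <- tol_zero * scale

  keep_rxns <- list()
  index_map <- character(0)
  flipped <- character(0)
  fixed_ids <- names(model$fixed_fluxes)
  for (r in model$reactions) {
    vids <- lp$rxn_vars[[r$id]]
    v <- sol$primal[vids]
    if (r$id %in% fixed_ids || sum(v) > thr) {
      rr <- r
      if (length(r$isozymes) > 1L) {
        rr$isozymes <- r$isozymes[v > thr]
        if (length(rr$isozymes) == 0L) rr$isozymes <- r$isozymes[which.max(v)]
      }
      keep_rxns[[length(keep_rxns) + 1L]] <- rr
      orig <- r$backward_of %||% r$split_of %||% r$id
      index_map[[r$id]] <- orig
      if (!is.null(r$backward_of)) flipped <- c(flipped, r$id)
    }
  }
  kept_ids <- vapply(keep_rxns, `[[`, character(1), "id")
  if (!(model$objective_reaction %in% kept_ids))
    stop("pruning inconsistency: objective reaction pruned away",
         call. = FALSE)

  evars <- lp$var_table[lp$var_table$kind == "enzyme", ]
  active_gp <- evars$gene_product[sol$primal[evars$id] > thr]
  ## a gene product survives only if active and still used by a kept isozyme
  used_gp <- unique(unlist(lapply(keep_rxns, function(r)
    unlist(lapply(r$isozymes, function(i) names(i$subunit_counts))))))
  keep_gp <- intersect(active_gp, used_gp)
  if (!setequal(used_gp, keep_gp))
    stop("pruning inconsistency: kept reaction uses a pruned enzyme",
         call. = FALSE)

  keep_mets <- unique(unlist(lapply(keep_rxns, function(r)
    names(r$stoichiometry))))
  pools <- list()
  for (p in model$pools) {
    mem <- intersect(p$members, keep_gp)
    if (length(mem))
      pools[[length(pools) + 1L]] <- enzyme_pool(p$id, mem, p$capacity)
  }
  pm <- ec_model(
    metabolites = unname(model$metabolites[keep_mets]),
    reactions = keep_rxns,
    gene_products = unname(model$gene_products[keep_gp]),
    pools = pools,
    fixed_fluxes = unname(model$fixed_fluxes),
    objective_reaction = model$objective_reaction,
    id = paste0(model$id, "_pruned"))

  plp <- build_lp(pm, lp$params, fixed_flux_mode = lp$fixed_flux_mode)
  psol <- solve_lp(plp)
  if (psol$status != "optimal")
    stop("pruning inconsistency: pruned model is ", psol$status,
         call. = FALSE)
  dev <- abs(psol$objective_value - sol$objective_value)
  if (dev > 1e-6 * max(1, abs(sol$objective_value)))
    stop("pruning inconsistency: objective drop ", format(dev),
         " (tol_zero too aggressive or non-vertex input solution)",
         call. = FALSE)

  structure(list(model = pm, index_map = index_map, flipped = flipped,
                 lp = plp, solution = psol, tol_zero = tol_zero),
            class = "pruned_model")
}

#' @export
print.pruned_model <- function(x, ...) {
  cat("pruned_model: ", length(x$model$reactions), " reactions, ",
      length(x$model$gene_products), " enzymes (",
      length(x$flipped), " flipped)\n", sep = "")
  invisible(x)
}

#' Check uniqueness of a pruned optimum
#'
#' Runs flux variability analysis with the objective fixed at its optimal
#' value; the optimum is unique iff every variable's range has zero width.
#' This is the operational gate before implicit differentiation: the
#' derivative of the solution map is only defined at a unique optimum.
#'
#' @param pruned a [prune()] result (or any list with `lp` and `solution`).
#' @param tol maximum admissible FVA range width.
#' @return Logical; the FVA table is attached as attribute `"fva"` and the
#'   largest width as `"max_width"`.
#' @export
verify_unique <- function(pruned, tol = 1e-6) {
  fva <- fva_at_optimum(pruned$lp, pruned$solution)
  width <- fva$max - fva$min
  ok <- all(is.finite(width)) && max(width) <= tol
  structure(ok, fva = fva, max_width = max(width))
}

#' Write the pruned-model index map as TSV
#'
#' Columns `pruned_id  original_id  flipped`.
#'
#' @param pruned a [prune()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index_map_tsv <- function(pruned, path) {
  df <- data.frame(pruned_id = names(pruned$index_map),
                   original_id = unname(pruned$index_map),
                   flipped = names(pruned$index_map) %in% pruned$flipped)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
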