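#' Construct an enzyme-constrained metabolic model
#'
#' An `ec_model` is the native container for an enzyme-constrained
#' genome-scale metabolic model (ecGSMM): a stoichiometric network plus, per
#' reaction, one or more isozymes coupling flux to enzyme concentration
#' through a turnover number (`v = kcat * e`), gene products with molar
#' masses, enzyme pools with capacities (`sum of w_g * e_g <= E_k`), and
#' optional fixed (inhomogeneous) fluxes such as ATP maintenance.
#'
#' Components are plain lists keyed by id.  Numeric fields that the
#' sensitivity machinery can differentiate against (kcats, capacities,
#' fixed-flux values, bounds) may be [param_ref()] handles instead of
#' scalars.
#'
#' @param metabolites list of [metabolite()]s.
#' @param reactions list of [reaction()]s.
#' @param gene_products list of [gene_product()]s.
#' @param pools list of [enzyme_pool()]s.
#' @param fixed_fluxes list of [fixed_flux()]es.
#' @param objective_reaction id of the objective reaction; if `NULL`, the
#'   unique reaction with nonzero `objective_coefficient` is used.
#' @param id optional model id.
#' @return An object of class `"ec_model"`, with components stored in
#'   canonical (lexicographic, objective-last) order.
#' @seealso [validate_model()], [split_reversible()], [load_ec_model()]
#' @export
ec_model <- function(metabolites = list(), reactions = list(),
                     gene_products = list(), pools = list(),
                     fixed_fluxes = list(), objective_reaction = NULL,
                     id = "model") {
  m <- structure(list(
    id = id,
    metabolites = named_by_id(metabolites),
    reactions = named_by_id(reactions),
    gene_products = named_by_id(gene_products),
    pools = named_by_id(pools),
    fixed_fluxes = named_by_id(fixed_fluxes, key = "reaction_id"),
    objective_reaction = objective_reaction
  ), class = "ec_model")
  if (is.null(m$objective_reaction)) {
    obj <- vapply(m$reactions, function(r) r$objective_coefficient != 0,
                  logical(1))
    if (sum(obj) == 1L) m$objective_reaction <- names(m$reactions)[obj]
  }
  canonical_order(m)
}

named_by_id <- function(x, key = "id") {
  if (length(x) == 0L) return(structure(list(), names = character(0)))
  names(x) <- vapply(x, function(e) e[[key]], character(1))
  x
}

## lexicographic by id (radix sort: locale-independent), objective last
canonical_order <- function(model) {
  srt <- function(x) x[sort(names(x), method = "radix")]
  model$metabolites <- srt(model$metabolites)
  model$gene_products <- srt(model$gene_products)
  model$pools <- srt(model$pools)
  model$fixed_fluxes <- srt(model$fixed_fluxes)
  model$reactions <- srt(model$reactions)
  obj <- model$objective_reaction
  if (!is.null(obj) && obj %in% names(model$reactions)) {
    ord <- c(setdiff(names(model$reactions), obj), obj)
    model$reactions <- model$reactions[ord]
  }
  model
}

#' @rdname ec_model
#' @param compartment optional compartment id.
#' @export
metabolite <- function(id, compartment = NULL)
  list(id = id, compartment = compartment)

#' @rdname ec_model
#' @param molar_mass molar mass of the gene product, mg/mmol.
#' @export
gene_product <- function(id, molar_mass)
  list(id = id, molar_mass = molar_mass)

#' @rdname ec_model
#' @param subunit_counts named integer vector (gene-product id -> copies per
#'   complex).
#' @param kcat_forward,kcat_reverse turnover numbers, 1/h; scalar or
#'   [param_ref()]; `kcat_reverse` may be `NULL` for irreversible catalysis.
#' @export
isozyme <- function(subunit_counts, kcat_forward = NULL, kcat_reverse = NULL)
  list(subunit_counts = subunit_counts, kcat_forward = kcat_forward,
       kcat_reverse = kcat_reverse)

#' @rdname ec_model
#' @param stoichiometry named numeric vector (metabolite id -> signed
#'   coefficient); negative = consumed.
#' @param lower_bound,upper_bound flux bounds, mmol/gDCW/h; scalar or
#'   [param_ref()].
#' @param isozymes list of [isozyme()]s; empty = no enzyme cost.
#' @param objective_coefficient scalar; exactly one reaction in a model may
#'   have a nonzero value.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = Inf,
                     isozymes = list(), objective_coefficient = 0)
  list(id = id, stoichiometry = stoichiometry, lower_bound = lower_bound,
       upper_bound = upper_bound, isozymes = isozymes,
       objective_coefficient = objective_coefficient)

#' @rdname ec_model
#' @param members character vector of gene-product ids in the pool.
#' @param capacity pool capacity E_k, mg/gDCW; scalar or [param_ref()].
#' @export
enzyme_pool <- function(id, members, capacity)
  list(id = id, members = members, capacity = capacity)

#' @rdname ec_model
#' @param reaction_id id of the constrained reaction.
#' @param value fixed flux value c_j > 0, mmol/gDCW/h; scalar or
#'   [param_ref()].
#' @export
fixed_flux <- function(reaction_id, value)
  list(reaction_id = reaction_id, value = value)

#' @export
print.ec_model <- function(x, ...) {
  cat("ec_model '", x$id, "': ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ", length(x$gene_products),
      " gene products, ", length(x$pools), " pools, ",
      length(x$fixed_fluxes), " fixed fluxes\n", sep = "")
  cat("objective:", x$objective_reaction %||% "<none>", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an ec_model
#'
#' Checks referential integrity (every metabolite, gene product and reaction
#' referenced by id exists), bound consistency, positivity of molar masses
#' and capacities, and the single-objective convention.  Enzyme-free
#' *internal* (metabolic) reactions are reported as warnings, not errors:
#' the uniqueness guarantee for pruned models assumes every metabolic
#' reaction carries an enzyme cost, so cost-free internal reactions weaken
#' that premise (exchange reactions, which involve a single metabolite, are
#' conventionally cost-free and not flagged).
#'
#' @param model an [ec_model()].
#' @param params optional named numeric vector; when given, parameter
#'   references are checked to resolve and resolved values are checked
#'   (capacity > 0, fixed flux > 0, bounds ordered).
#' @return A list of class `"ec_validation"` with character vectors
#'   `errors` and `warnings`.
#' @export
validate_model <- function(model, params = NULL) {
  errs <- character(0); warns <- character(0)
  err <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)
  wrn <- function(...) warns[[length(warns) + 1L]] <<- paste0(...)

  mets <- names(model$metabolites)
  gps <- names(model$gene_products)
  rxns <- names(model$reactions)
  if (anyDuplicated(mets)) err("duplicated metabolite ids")
  if (anyDuplicated(rxns)) err("duplicated reaction ids")

  maybe_resolve <- function(x) {
    if (is_param_ref(x) && is.null(params)) return(NA_real_)
    tryCatch(resolve_value(x, params), error = function(e) {
      err(conditionMessage(e)); NA_real_
    })
  }

  for (g in model$gene_products) {
    mm <- g$molar_mass
    if (!is.numeric(mm) || mm <= 0)
      err("gene product '", g$id, "': molar_mass must be > 0")
  }

  n_obj <- 0L
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoichiometry), mets)
    if (length(bad))
      err("reaction '", r$id, "': unknown metabolite(s) ", toString(bad))
    if (any(r$stoichiometry == 0))
      err("reaction '", r$id, "': zero stoichiometric coefficient")
    lb <- maybe_resolve(r$lower_bound); ub <- maybe_resolve(r$upper_bound)
    if (!is.na(lb) && !is.na(ub) && lb > ub)
      err("reaction '", r$id, "': lower_bound > upper_bound")
    if (r$objective_coefficient != 0) n_obj <- n_obj + 1L
    for (iso in r$isozymes) {
      if (length(iso$subunit_counts) == 0L)
        err("reaction '", r$id, "': isozyme with empty subunit_counts")
      if (is.null(iso$kcat_forward) && is.null(iso$kcat_reverse))
        err("reaction '", r$id, "': isozyme with no kcat")
      bad <- setdiff(names(iso$subunit_counts), gps)
      if (length(bad))
        err("reaction '", r$id, "': unknown gene product(s) ", toString(bad))
      if (any(iso$subunit_counts <= 0))
        err("reaction '", r$id, "': nonpositive subunit count")
    }
    internal <- sum(r$stoichiometry < 0) > 0 && sum(r$stoichiometry > 0) > 0
    if (length(r$isozymes) == 0L) {
      if (internal)
        wrn("reaction '", r$id, "': internal reaction without enzyme cost ",
            "(weakens the uniqueness guarantee of pruned models)")
      else
        wrn("reaction '", r$id, "': cost-free exchange reaction ",
            "(conventional, but outside the uniqueness premise)")
    }
  }

  obj <- model$objective_reaction
  if (is.null(obj)) {
    err("no objective reaction declared")
  } else if (!(obj %in% rxns)) {
    err("objective reaction '", obj, "' not in model")
  }
  if (n_obj > 1L) err("more than one reaction has objective_coefficient != 0")

  for (p in model$pools) {
    if (length(p$members) == 0L) err("pool '", p$id, "': no members")
    bad <- setdiff(p$members, gps)
    if (length(bad))
      err("pool '", p$id, "': unknown gene product(s) ", toString(bad))
    cap <- maybe_resolve(p$capacity)
    if (!is.na(cap) && cap <= 0) err("pool '", p$id, "': capacity must be > 0")
  }

  for (f in model$fixed_fluxes) {
    if (!(f$reaction_id %in% rxns))
      err("fixed flux: unknown reaction '", f$reaction_id, "'")
    v <- maybe_resolve(f$value)
    if (!is.na(v) && v <= 0)
      err("fixed flux '", f$reaction_id, "': value must be > 0")
  }

  structure(list(errors = errs, warnings = warns, valid = length(errs) == 0L),
            class = "ec_validation")
}

#' @export
print.ec_validation <- function(x, ...) {
  cat("ec_model validation:", if (x$valid) "OK" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Stop unless a model validates cleanly
#' @inheritParams validate_model
#' @return The model, invisibly.
#' @export
assert_valid <- function(model, params = NULL) {
  rep <- validate_model(model, params)
  if (!rep$valid)
    stop("model validation failed:\n  ",
         paste(rep$errors, collapse = "\n  "), call. = FALSE)
  invisible(model)
}

#' Split reversible reactions into forward/backward irreversible pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' (bounds `[0, ub]`, forward kcats) and a backward copy with negated
#' stoichiometry (bounds `[0, |lb|]`, the reverse kcats as its forward
#' kcats).  The flux cone of the split model is pointed (`v >= 0`), the
#' precondition for elementary/optimal flux mode enumeration.  A reversible
#' enzymatic reaction lacking `kcat_reverse` yields a cost-free backward
#' copy and a warning.  Parameter-valued bounds on reversible reactions are
#' not supported (the split would need `|lb|` of an unresolved value).
#'
#' @param model an [ec_model()].
#' @param suffixes character(2), suffixes for the forward and backward copy
#'   ids.
#' @return The split [ec_model()]; idempotent on already-irreversible
#'   models.
#' @export
split_reversible <- function(model, suffixes = c("_fwd", "_bwd")) {
  out <- list()
  fixed_ids <- names(model$fixed_fluxes)
  for (r in model$reactions) {
    lb <- r$lower_bound
    if (is_param_ref(lb))
      stop("reaction '", r$id, "': parameter-valued lower bound cannot be ",
           "split; resolve it first", call. = FALSE)
    if (lb >= 0) { out[[length(out) + 1L]] <- r; next }
    if (r$id %in% fixed_ids)
      stop("reaction '", r$id, "': fixed-flux reaction must be irreversible",
           call. = FALSE)
    fwd <- r
    fwd$id <- paste0(r$id, suffixes[1L])
    fwd$split_of <- r$id
    fwd$lower_bound <- 0
    fwd$isozymes <- lapply(r$isozymes, function(iso) {
      iso$kcat_reverse <- NULL; iso
    })
    bwd <- r
    bwd$id <- paste0(r$id, suffixes[2L])
    bwd$backward_of <- r$id
    bwd$stoichiometry <- -r$stoichiometry
    bwd$lower_bound <- 0
    bwd$upper_bound <- abs(lb)
    bwd$objective_coefficient <- 0
    bwd$isozymes <- list()
    for (iso in r$isozymes) {
      if (is.null(iso$kcat_reverse)) {
        warning("reaction '", r$id, "': no kcat_reverse; backward copy '",
                bwd$id, "' has no enzyme cost", call. = FALSE)
      } else {
        bwd$isozymes[[length(bwd$isozymes) + 1L]] <-
          isozyme(iso$subunit_counts, kcat_forward = iso$kcat_reverse)
      }
    }
    out[[length(out) + 1L]] <- fwd
    out[[length(out) + 1L]] <- bwd
  }
  obj <- model$objective_reaction
  new_ids <- vapply(out, `[[`, character(1), "id")
  if (!is.null(obj) && !(obj %in% new_ids))
    obj <- paste0(obj, suffixes[1L])
  ec_model(metabolites = unname(model$metabolites), reactions = out,
           gene_products = unname(model$gene_products),
           pools = unname(model$pools),
           fixed_fluxes = unname(model$fixed_fluxes),
           objective_reaction = obj, id = model$id)
}

## ---- native JSON schema ---------------------------------------------------

val_to_json <- function(x) {
  if (is_param_ref(x)) list(param = x$param) else x
}

val_from_json <- function(x) {
  if (is.list(x) && identical(names(x), "param")) param_ref(x$param) else x
}

#' Read and write the native JSON model format
#'
#' The native schema has top-level keys `metabolites`, `reactions`, `genes`,
#' `pools`, `fixed_fluxes` and `objective`; any differentiable scalar may be
#' written as a parameter reference `{"param": "<name>"}`.  A JSON-Schema
#' document describing the format ships at
#' `system.file("extdata", "ecmodel.schema.json", package = "ofmdiff")`.
#'
#' @param path file path.
#' @param format `"native-json"` or `"cobra-json"` (read-only COBRA import,
#'   see [read_cobra_json()]).
#' @param ... passed on to [read_cobra_json()] for COBRA input.
#' @return `load_ec_model()` returns a validated [ec_model()];
#'   `save_ec_model()` returns `path` invisibly.
#' @export
load_ec_model <- function(path, format = c("native-json", "cobra-json"), ...) {
  format <- match.arg(format)
  if (format == "cobra-json") return(read_cobra_json(path, ...))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- lapply(j$metabolites, function(m)
    metabolite(m$id, m$compartment %||% NULL))
  gps <- lapply(j$genes, function(g) gene_product(g$id, g$molar_mass))
  rxns <- lapply(j$reactions, function(r) {
    stoich <- unlist(r$stoichiometry)
    isos <- lapply(r$isozymes %||% list(), function(i)
      isozyme(unlist(i$subunit_counts),
              kcat_forward = val_from_json(i$kcat_forward),
              kcat_reverse = val_from_json(i$kcat_reverse)))
    ub <- val_from_json(r$upper_bound %||% Inf)
    if (is.character(ub)) ub <- as.numeric(ub)  # "Inf" round-trip
    reaction(r$id, stoich,
             lower_bound = val_from_json(r$lower_bound %||% 0),
             upper_bound = ub,
             isozymes = isos,
             objective_coefficient = r$objective_coefficient %||% 0)
  })
  pools <- lapply(j$pools %||% list(), function(p)
    enzyme_pool(p$id, unlist(p$members), val_from_json(p$capacity)))
  ffs <- lapply(j$fixed_fluxes %||% list(), function(f)
    fixed_flux(f$reaction_id, val_from_json(f$value)))
  m <- ec_model(metabolites = mets, reactions = rxns, gene_products = gps,
                pools = pools, fixed_fluxes = ffs,
                objective_reaction = j$objective %||% NULL,
                id = j$id %||% "model")
  assert_valid(m)
  m
}

#' @rdname load_ec_model
#' @param model an [ec_model()].
#' @export
save_ec_model <- function(model, path) {
  rxns <- lapply(unname(model$reactions), function(r) {
    isos <- lapply(r$isozymes, function(i) list(
      subunit_counts = as.list(i$subunit_counts),
      kcat_forward = val_to_json(i$kcat_forward),
      kcat_reverse = val_to_json(i$kcat_reverse)))
    ub <- r$upper_bound
    if (is.numeric(ub) && is.infinite(ub)) ub <- "Inf"
    list(id = r$id, stoichiometry = as.list(r$stoichiometry),
         lower_bound = val_to_json(r$lower_bound),
         upper_bound = val_to_json(ub),
         isozymes = isos,
         objective_coefficient = r$objective_coefficient)
  })
  j <- list(
    id = model$id,
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, compartment = m$compartment)),
    reactions = rxns,
    genes = lapply(unname(model$gene_products), function(g)
      list(id = g$id, molar_mass = g$molar_mass)),
    pools = lapply(unname(model$pools), function(p)
      list(id = p$id, members = as.list(p$members),
           capacity = val_to_json(p$capacity))),
    fixed_fluxes = lapply(unname(model$fixed_fluxes), function(f)
      list(reaction_id = f$reaction_id, value = val_to_json(f$value))),
    objective = model$objective_reaction
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

## ---- COBRA JSON import ----------------------------------------------------

#' Import a COBRA-style JSON model (best effort)
#'
#' Reads genome-scale models in the JSON layout emitted by standard COBRA
#' toolchains and maps them onto the native enzyme-constrained
#' representation.  Gene-reaction rules are mapped to isozymes: OR branches
#' become separate isozymes, AND conjunctions one complex with unit subunit
#' counts (unless `subunit_counts` overrides them).  COBRA models carry no
#' kinetics, so isozymes are only created for reactions with an entry in
#' `kcats`; other reactions import cost-free, with a warning summarising the
#' count.  Annotation fields are ignored.
#'
#' @param path file path to a COBRA JSON model.
#' @param kcats optional named numeric vector or named list, reaction id ->
#'   kcat (1/h), or reaction id -> list(forward=, reverse=).
#' @param molar_masses optional named numeric vector, gene id -> molar mass
#'   (mg/mmol); genes missing from it get `default_molar_mass`.
#' @param pools optional list of [enzyme_pool()]s to attach.
#' @param default_molar_mass fallback molar mass, mg/mmol.
#' @return A validated [ec_model()].
#' @export
read_cobra_json <- function(path, kcats = NULL, molar_masses = NULL,
                            pools = list(), default_molar_mass = 40) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- lapply(j$metabolites, function(m)
    metabolite(m$id, m$compartment %||% NULL))
  gps <- lapply(j$genes, function(g) {
    mm <- if (!is.null(molar_masses) && g$id %in% names(molar_masses))
      as.numeric(molar_masses[[g$id]]) else default_molar_mass
    gene_product(g$id, mm)
  })
  n_costfree <- 0L
  rxns <- lapply(j$reactions, function(r) {
    stoich <- unlist(r$metabolites)
    gpr <- r$gene_reaction_rule %||% ""
    isos <- list()
    kc <- if (!is.null(kcats) && r$id %in% names(kcats)) kcats[[r$id]] else NULL
    if (nzchar(gpr) && !is.null(kc)) {
      kf <- if (is.list(kc)) kc$forward else as.numeric(kc)
      kr <- if (is.list(kc)) kc$reverse else NULL
      isos <- lapply(parse_gpr(gpr), function(genes) {
        counts <- rep(1L, length(genes)); names(counts) <- genes
        isozyme(counts, kcat_forward = kf, kcat_reverse = kr)
      })
    } else if (nzchar(gpr)) {
      n_costfree <<- n_costfree + 1L
    }
    reaction(r$id, stoich,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% Inf,
             isozymes = isos,
             objective_coefficient = r$objective_coefficient %||% 0)
  })
  if (n_costfree > 0L)
    warning(n_costfree, " reaction(s) with a gene-reaction rule but no kcat ",
            "imported without enzyme cost", call. = FALSE)
  m <- ec_model(metabolites = mets, reactions = rxns, gene_products = gps,
                pools = pools, id = j$id %||% "cobra_model")
  assert_valid(m)
  m
}

## "g1 and g2 or g3" -> list(c("g1","g2"), "g3"); parentheses supported for
## the common (A and B) or (C and D) layouts by recursive descent
parse_gpr <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  toks <- toks[!(tolower(toks) %in% character(0))]
  pos <- 1L
  parse_or <- function() {
    terms <- list(parse_and())
    while (pos <= length(toks) && tolower(toks[pos]) == "or") {
      pos <<- pos + 1L
      terms[[length(terms) + 1L]] <- parse_and()
    }
    unlist(lapply(terms, identity), recursive = FALSE)
  }
  parse_and <- function() {
    branches <- parse_atom()
    while (pos <= length(toks) && tolower(toks[pos]) == "and") {
      pos <<- pos + 1L
      rhs <- parse_atom()
      branches <- unlist(lapply(branches, function(b)
        lapply(rhs, function(r) c(b, r))), recursive = FALSE)
    }
    branches
  }
  parse_atom <- function() {
    if (toks[pos] == "(") {
      pos <<- pos + 1L
      inner <- parse_or()
      if (pos > length(toks) || toks[pos] != ")")
        stop("unbalanced parentheses in gene-reaction rule", call. = FALSE)
      pos <<- pos + 1L
      inner
    } else {
      g <- toks[pos]; pos <<- pos + 1L
      list(g)
    }
  }
  out <- parse_or()
  lapply(out, function(g) sort(unique(unlist(g)), method = "radix"))
}
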