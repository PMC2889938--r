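# Reaction-table-driven mass-action kinetic model of the IKK-IkB-NF-kB module:
# YAML loader with structural validation, rate-function compiler with
# nuclear/cytoplasmic volume bookkeeping, moiety accounting, and SBML export.

REACTION_TYPES <- c("association", "dissociation", "transport", "synthesis", "degradation")

#' Load and validate a kinetic model definition
#'
#' Reads a YAML model file (species, reactions, volume ratio `kv`, conserved
#' moieties). The bundled default (used when `path` is `NULL`) defines the
#' NF-kB module with 24 species and 72 reactions: free NF-kB (cytoplasm,
#' nucleus); IkB alpha/beta/epsilon each as cytoplasmic protein, nuclear
#' protein and transcript; IkB:NF-kB complexes in both compartments per
#' isoform; clamped IKK; and IKK:IkB and IKK:IkB:NF-kB complexes per isoform.
#'
#' Reaction arities by type: association 2 reactants -> 1 product (one
#' compartment); dissociation 1 -> 2, or 1 -> 1 for catabolic release (one
#' part of the complex is proteolysed, the survivor released); transport
#' 1 -> 1 across compartments; synthesis 0 -> 1 with an optional template
#' modifier; degradation 1 -> 0 with an optional catalyst modifier.
#'
#' Declared moieties are verified at load time: the compartment-volume-weighted
#' member vector must lie in the left null space of the effective stoichiometry.
#'
#' @param path Path to a YAML model file, or `NULL` for the bundled default.
#' @return An object of class `kinetic_model`.
#' @export
load_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nfkb_module.yaml", package = "nfkblink")
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || is.null(cfg$reactions) || is.null(cfg$kv)) {
    stop("model config needs 'species', 'reactions' and 'kv'", call. = FALSE)
  }
  kv <- as.numeric(cfg$kv)
  if (!is.finite(kv) || kv <= 0) stop("kv must be a positive number", call. = FALSE)

  species <- do.call(rbind, lapply(seq_along(cfg$species), function(i) {
    s <- cfg$species[[i]]
    for (f in c("name", "compartment", "init")) {
      if (is.null(s[[f]])) stop("species entry ", i, " lacks '", f, "'", call. = FALSE)
    }
    if (!s$compartment %in% c("cytoplasm", "nucleus")) {
      stop("species ", s$name, ": compartment must be cytoplasm or nucleus", call. = FALSE)
    }
    if (s$init < 0) stop("species ", s$name, ": negative initial amount", call. = FALSE)
    data.frame(name = s$name, compartment = s$compartment,
               init = as.numeric(s$init), clamped = isTRUE(s$clamped),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(species$name)) stop("duplicate species name(s)", call. = FALSE)

  comp_of <- stats::setNames(species$compartment, species$name)
  reactions <- lapply(seq_along(cfg$reactions), function(i) {
    r <- cfg$reactions[[i]]
    where <- paste0("reaction ", i)
    if (is.null(r$type) || !r$type %in% REACTION_TYPES) {
      stop(where, ": unknown or missing type", call. = FALSE)
    }
    rx <- list(type = r$type,
               reactants = as.character(unlist(r$reactants)),
               products = as.character(unlist(r$products)),
               modifiers = as.character(unlist(r$modifiers)),
               k = as.numeric(r$k), note = if (is.null(r$note)) "" else r$note)
    if (!is.finite(rx$k) || rx$k <= 0) stop(where, ": rate constant must be > 0", call. = FALSE)
    all_sp <- c(rx$reactants, rx$products, rx$modifiers)
    unknown <- setdiff(all_sp, species$name)
    if (length(unknown)) stop(where, ": unknown species ", paste(unknown, collapse = ", "),
                              call. = FALSE)
    nr <- length(rx$reactants); np <- length(rx$products); nm <- length(rx$modifiers)
    ok <- switch(rx$type,
      association  = nr == 2 && np == 1 && nm == 0 &&
        length(unique(comp_of[c(rx$reactants, rx$products)])) == 1,
      dissociation = nr == 1 && np %in% 1:2 && nm == 0 &&
        length(unique(comp_of[c(rx$reactants, rx$products)])) == 1,
      transport    = nr == 1 && np == 1 && nm == 0 &&
        comp_of[rx$reactants] != comp_of[rx$products],
      synthesis    = nr == 0 && np == 1 && nm <= 1,
      degradation  = nr == 1 && np == 0 && nm <= 1)
    if (!ok) stop(where, " (", rx$type, "): arity or compartment violation", call. = FALSE)
    rx
  })

  used <- unique(unlist(lapply(reactions, function(r) c(r$reactants, r$products, r$modifiers))))
  orphan <- setdiff(species$name[!species$clamped], used)
  if (length(orphan)) {
    stop("species participate in no reaction and are not clamped: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  moieties <- lapply(cfg$moieties, function(m) {
    if (is.null(m$name) || is.null(m$members)) stop("moiety needs 'name' and 'members'", call. = FALSE)
    w <- unlist(m$members)
    unknown <- setdiff(names(w), species$name)
    if (length(unknown)) stop("moiety ", m$name, ": unknown species ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    list(name = m$name, weights = w)
  })

  model <- structure(list(species = species, reactions = reactions, kv = kv,
                          moieties = moieties, path = path),
                     class = "kinetic_model")
  # verify declared moieties against the effective stoichiometry
  Neff <- effective_stoichiometry(model)
  for (m in moieties) {
    w <- moiety_weight_vector(model, m)
    resid <- max(abs(as.numeric(w %*% Neff)))
    if (resid > 1e-9 * max(1, max(abs(w)))) {
      stop("declared moiety '", m$name, "' is not conserved by the stoichiometry (|w'N| = ",
           signif(resid, 3), ")", call. = FALSE)
    }
  }
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", nrow(x$species), " species, ", length(x$reactions),
      " reactions, kv = ", x$kv, ", ", length(x$moieties), " declared moiety(ies)\n",
      sep = "")
  invisible(x)
}

# Volume-weighted member vector of a moiety (full species length): weight as
# declared, times kv for nuclear members, so the weighted concentration sum is
# proportional to the total amount.
moiety_weight_vector <- function(model, moiety) {
  w <- stats::setNames(numeric(nrow(model$species)), model$species$name)
  w[names(moiety$weights)] <- moiety$weights
  nuc <- model$species$compartment == "nucleus"
  w[nuc] <- w[nuc] * model$kv
  w
}

# Effective stoichiometry matrix (species x reactions) on concentration scale:
# entry (s, r) is d[concentration of s]/dt per unit reaction flux, including
# the volume factor for cross-compartment transport (flux defined in the
# source compartment's concentration units; the receiving side is scaled by
# the volume ratio so that amounts balance).
effective_stoichiometry <- function(model) {
  sp <- model$species$name
  comp <- stats::setNames(model$species$compartment, sp)
  kv <- model$kv
  N <- matrix(0, length(sp), length(model$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in r$reactants) N[s, j] <- N[s, j] - 1
    for (s in r$products) {
      f <- 1
      if (r$type == "transport") {
        src <- comp[r$reactants]
        dst <- comp[s]
        f <- if (src == "cytoplasm" && dst == "nucleus") 1 / kv else kv
      }
      N[s, j] <- N[s, j] + f
    }
  }
  N
}

#' Compile a kinetic model into a mass-action rate function
#'
#' Each reaction contributes flux `k * prod(reactant concentrations) *
#' prod(modifier concentrations)`; cross-compartment transport is scaled by
#' the nuclear/cytoplasmic volume ratio on the receiving side so that
#' volume-weighted moiety totals are conserved. Clamped species take their
#' value from the input profile and their derivatives are forced to zero.
#'
#' @param model A `kinetic_model`.
#' @return List with `derivs(t, state, input_fun)` returning d(state)/dt,
#'   `flux(t, state, input_fun)` returning per-reaction fluxes, the effective
#'   stoichiometry matrix `N`, and index bookkeeping.
#' @export
compile_rates <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sp <- model$species$name
  n <- length(sp)
  N <- effective_stoichiometry(model)
  idx <- function(x) match(x, sp)
  # reactant/modifier index vectors; 0 means absent (maps to a padded 1)
  pick <- function(v, slot) {
    vapply(model$reactions, function(r) {
      z <- r[[v]]
      if (length(z) >= slot) idx(z[slot]) else 0L
    }, 0L)
  }
  i1 <- pick("reactants", 1); i2 <- pick("reactants", 2); im <- pick("modifiers", 1)
  kvec <- vapply(model$reactions, `[[`, 0, "k")
  clamped <- which(model$species$clamped)
  flux <- function(t, state, input_fun) {
    if (length(clamped)) state[clamped] <- input_fun(t)
    padded <- c(1, state)
    kvec * padded[i1 + 1] * padded[i2 + 1] * padded[im + 1]
  }
  derivs <- function(t, state, input_fun) {
    v <- flux(t, state, input_fun)
    d <- as.numeric(N %*% v)
    if (length(clamped)) d[clamped] <- 0
    d
  }
  list(derivs = derivs, flux = flux, N = N, clamped = clamped, species = sp)
}

#' Export a kinetic model as SBML Level 3 (mass-action kinetic laws)
#'
#' Writes a minimal SBML Level 3 Version 2 document: two compartments
#' (cytoplasm of size 1, nucleus of size `kv`), species with initial
#' concentrations (clamped species become boundary conditions), and one
#' reaction per table row whose kinetic law is the mass-action flux in
#' substance/time units (`k * product of reactant and modifier concentrations
#' * source-compartment volume`). Import is out of scope.
#'
#' @param model A `kinetic_model`.
#' @param path Output path for the `.sbml`/`.xml` file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  comp_of <- stats::setNames(model$species$compartment, model$species$name)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "nfkb_module",
                             timeUnits = "hour")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cytoplasm", size = "1",
                      spatialDimensions = "3", constant = "true")
  xml2::xml_add_child(lc, "compartment", id = "nucleus",
                      size = as.character(model$kv),
                      spatialDimensions = "3", constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    xml2::xml_add_child(ls, "species", id = s$name, compartment = s$compartment,
                        initialConcentration = as.character(s$init),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (s$clamped) "true" else "false",
                        constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    rid <- sprintf("r%02d_%s", j, r$type)
    rx <- xml2::xml_add_child(lr, "reaction", id = rid, reversible = "false")
    if (length(r$reactants)) {
      n1 <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in r$reactants) {
        xml2::xml_add_child(n1, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
      }
    }
    if (length(r$products)) {
      n2 <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in r$products) {
        xml2::xml_add_child(n2, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
      }
    }
    if (length(r$modifiers)) {
      n3 <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in r$modifiers) {
        xml2::xml_add_child(n3, "modifierSpeciesReference", species = s)
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    apply_node <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(apply_node, "times")
    cn <- xml2::xml_add_child(apply_node, "cn", type = "real")
    xml2::xml_set_text(cn, as.character(r$k))
    src_comp <- if (length(r$reactants)) unname(comp_of[r$reactants[1]]) else {
      unname(comp_of[r$products[1]])
    }
    for (s in c(r$reactants, r$modifiers)) {
      ci <- xml2::xml_add_child(apply_node, "ci"); xml2::xml_set_text(ci, s)
    }
    ci <- xml2::xml_add_child(apply_node, "ci"); xml2::xml_set_text(ci, src_comp)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
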