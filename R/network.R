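# Reaction networks of the Prx decamer oxidation/dissociation cycle and of
# the free-dimer redox cycle, with degeneracy-scaled ("statistical factor")
# rate constants.

SMALL_SPECIES <- c("H2O2", "H2O")

.subunits_of <- function(id) {
  if (grepl("^Dec__", id)) 10L else if (grepl("^Prx_", id)) 2L else 0L
}

#' Construct a reaction network
#'
#' Low-level constructor; most users build networks with
#' [enumerate_network()], [dimer_cycle_reactions()] or [decamerise_model()].
#'
#' @param species Data frame with columns `id` (unique species identifiers)
#'   and `role` (one of `"decamer"`, `"dimer"`, `"small"`, `"redox"`,
#'   `"assay"`).
#' @param reactions List of reactions; each reaction is a list with elements
#'   `id`, `kind`, `rate_ref` (name of the base rate constant), `factor`
#'   (positive integer statistical factor), `reactants` and `products`
#'   (named numeric stoichiometry vectors).
#' @param mode Optional enumeration mode tag.
#' @return An object of class `prx_network`.
#' @export
reaction_network <- function(species, reactions, mode = NULL) {
  stopifnot(is.data.frame(species), all(c("id", "role") %in% names(species)))
  if (anyDuplicated(species$id))
    stop("species identifiers must be unique", call. = FALSE)
  ids <- species$id
  for (r in reactions) {
    miss <- setdiff(c(names(r$reactants), names(r$products)), ids)
    if (length(miss))
      stop("reaction ", r$id, " references unknown species: ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (!is.numeric(r$factor) || r$factor < 1)
      stop("reaction ", r$id, " has statistical factor < 1", call. = FALSE)
    sub_in <- sum(vapply(names(r$reactants), .subunits_of, 0L) * r$reactants)
    sub_out <- sum(vapply(names(r$products), .subunits_of, 0L) * r$products)
    if (sub_in != sub_out)
      stop("reaction ", r$id, " does not conserve Prx subunits (",
           sub_in, " -> ", sub_out, ")", call. = FALSE)
  }
  structure(list(species = species, reactions = reactions, mode = mode),
            class = "prx_network")
}

#' @export
print.prx_network <- function(x, ...) {
  kinds <- table(vapply(x$reactions, `[[`, "", "kind"))
  cat("<prx_network>", nrow(x$species), "species,",
      length(x$reactions), "reactions",
      if (!is.null(x$mode)) paste0("(mode: ", x$mode, ")"), "\n")
  cat("  reactions by kind:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.mk_species <- function(ids, roles) data.frame(id = ids, role = roles,
                                               stringsAsFactors = FALSE)

.rxn <- function(id, kind, rate_ref, factor, reactants, products) {
  list(id = id, kind = kind, rate_ref = rate_ref, factor = as.integer(factor),
       reactants = reactants, products = products)
}

# Dissociation products (5 canonical dimer labels) of a decamer config.
.dissociation_products <- function(cfg) {
  labs <- vapply(1:5, function(d) {
    pair <- sort(cfg[c(2L * d - 1L, 2L * d)])
    paste(site_states()[pair], collapse = "_")
  }, "")
  tab <- table(labs)
  out <- as.numeric(tab)
  names(out) <- paste0("Prx_", names(tab))
  out
}

#' Enumerate the symmetry-reduced Prx decamer oxidation/dissociation network
#'
#' Builds the reaction network of decamer peroxidase activity and
#' disulphide-driven dissociation over canonical (symmetry-reduced) decamer
#' configurations.  In `"single_SS"` mode, decamers carry sites in
#' \{SH, SOH\} plus configurations with exactly one disulphide bridge; a
#' bridged decamer undergoes no further oxidation and dissociates
#' irreversibly into its five dimers in a single step.  In
#' `"multi_SS_one_per_dimer"` mode up to one bridge may form on each dimer
#' unit (at most five in total), sulfenilation continues on bridged species,
#' and every bridged configuration has its own single-step dissociation.
#'
#' Rate-constant references: sulfenilation `k_SOH_decamer`, condensation
#' `k_SS_condensation`, dissociation `k_diss_oxidised`.  Each reaction's
#' `factor` is the number of degenerate microscopic transitions collated by
#' the symmetry reduction.
#'
#' @param mode `"single_SS"` or `"multi_SS_one_per_dimer"`.
#' @param include_small_molecules Include H2O2/H2O in sulfenilation
#'   stoichiometry (and in the species table).
#' @return A `prx_network`.
#' @export
enumerate_network <- function(mode = c("single_SS", "multi_SS_one_per_dimer"),
                              include_small_molecules = TRUE) {
  mode <- match.arg(mode)
  # raw configurations, states 1=SH 2=SOH 3=SS
  if (mode == "single_SS") {
    base <- as.matrix(expand.grid(rep(list(1:2), 10)))
    with_ss <- do.call(rbind, lapply(1:10, function(pos) {
      m <- as.matrix(expand.grid(rep(list(1:2), 9)))
      out <- matrix(0L, nrow(m), 10)
      out[, -pos] <- m
      out[, pos] <- 3L
      out
    }))
    raw <- rbind(base, with_ss)
  } else {
    dimer_states <- as.matrix(expand.grid(1:3, 1:3))
    dimer_states <- dimer_states[rowSums(dimer_states == 3) <= 1, , drop = FALSE]
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(dimer_states))), 5)))
    raw <- matrix(0L, nrow(idx), 10)
    for (d in 1:5) raw[, c(2 * d - 1, 2 * d)] <- dimer_states[idx[, d], ]
  }
  keys <- .canonical_keys(raw)
  ukeys <- sort(unique(keys))
  cfgs <- lapply(ukeys, .key_to_cfg)
  dec_ids <- vapply(cfgs, .decamer_id, "")

  reactions <- list()
  dimer_ids <- character(0)
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    id <- dec_ids[i]
    nss <- sum(cfg == 3L)
    # sulfenilation SH -> SOH
    if (mode == "multi_SS_one_per_dimer" || nss == 0L) {
      sh <- which(cfg == 1L)
      if (length(sh)) {
        prods <- vapply(sh, function(s) {
          s2 <- cfg; s2[s] <- 2L
          .decamer_id(.canonical_cfg(s2))
        }, "")
        tab <- table(prods)
        for (p in names(tab)) {
          re <- c(stats::setNames(1, id),
                  if (include_small_molecules) c(H2O2 = 1))
          pr <- c(stats::setNames(1, p),
                  if (include_small_molecules) c(H2O = 1))
          reactions[[length(reactions) + 1L]] <- .rxn(
            paste0("sulf_", i, "_", match(p, dec_ids)), "sulfenilation",
            "k_SOH_decamer", tab[[p]], re, pr)
        }
      }
    }
    # condensation SOH -> SS (at most one bridge per dimer)
    if (mode == "multi_SS_one_per_dimer" || nss == 0L) {
      soh <- which(cfg == 2L)
      soh <- soh[vapply(soh, function(s) {
        d <- ceiling(s / 2)
        !any(cfg[c(2 * d - 1, 2 * d)] == 3L)
      }, TRUE)]
      if (length(soh)) {
        prods <- vapply(soh, function(s) {
          s2 <- cfg; s2[s] <- 3L
          .decamer_id(.canonical_cfg(s2))
        }, "")
        tab <- table(prods)
        for (p in names(tab)) {
          reactions[[length(reactions) + 1L]] <- .rxn(
            paste0("cond_", i, "_", match(p, dec_ids)), "condensation",
            "k_SS_condensation", tab[[p]],
            stats::setNames(1, id), stats::setNames(1, p))
        }
      }
    }
    # single-step irreversible dissociation of bridged decamers
    if (nss >= 1L) {
      pr <- .dissociation_products(cfg)
      dimer_ids <- union(dimer_ids, names(pr))
      reactions[[length(reactions) + 1L]] <- .rxn(
        paste0("diss_", i), "decamer_dissociation", "k_diss_oxidised", 1,
        stats::setNames(1, id), pr)
    }
  }
  species <- rbind(
    .mk_species(dec_ids, "decamer"),
    .mk_species(sort(dimer_ids), "dimer"),
    if (include_small_molecules) .mk_species(SMALL_SPECIES, "small"))
  reaction_network(species, reactions, mode = mode)
}

#' Species/reaction counts of a network under a counting convention
#'
#' The total species list of the stand-alone single-bridge decamer network
#' comprises the canonical decamer configurations, the five dimer species
#' released by dissociation, and H2O2/H2O.  The `"boundary_excluded"`
#' convention (default) excludes the network's boundary species -- the fully
#' reduced decamer, which the association equilibrium supplies, and the
#' clamped H2O2/H2O pool -- and reproduces the headline totals of the
#' single-bridge network (133 species, 270 reactions).  `"all"` counts every
#' species; `"decamers_only"` counts only decamer configurations.
#'
#' @param network A `prx_network`.
#' @param convention One of `"boundary_excluded"`, `"all"`, `"decamers_only"`.
#' @return List with elements `species` and `reactions`.
#' @export
network_counts <- function(network,
                           convention = c("boundary_excluded", "all",
                                          "decamers_only")) {
  convention <- match.arg(convention)
  ids <- network$species$id
  n_sp <- switch(convention,
    all = length(ids),
    decamers_only = sum(network$species$role == "decamer"),
    boundary_excluded = {
      reduced <- .decamer_id(rep(1L, 10))
      length(setdiff(ids, c(reduced, SMALL_SPECIES)))
    })
  list(species = n_sp, reactions = length(network$reactions))
}

# Collated transitions of free dimers: one reaction per canonical parent
# and product, with the mirror-symmetry statistical factor.
.dimer_transitions <- function(labels, from, to, kind, rate_ref,
                               extra_react = NULL, extra_prod = NULL,
                               allowed = function(lab) TRUE) {
  f <- .state_index(from); t_ <- .state_index(to)
  out <- list()
  for (lab in labels) {
    if (!allowed(lab)) next
    cfg <- sort(.state_index(unlist(strsplit(lab, "_"))))
    sites <- which(cfg == f)
    if (!length(sites)) next
    prods <- vapply(sites, function(s) {
      s2 <- cfg; s2[s] <- t_
      paste(site_states()[sort(s2)], collapse = "_")
    }, "")
    tab <- table(prods)
    for (p in names(tab)) {
      re <- c(stats::setNames(1, paste0("Prx_", lab)), extra_react)
      pr <- c(stats::setNames(1, paste0("Prx_", p)), extra_prod)
      out[[length(out) + 1L]] <- .rxn(
        paste0(kind, "_", lab, "_to_", p), kind, rate_ref, tab[[p]], re, pr)
    }
  }
  out
}

#' Reaction network of the free Prx dimer redox cycle
#'
#' Emits the free-dimer reactions over all canonical dimer species:
#' sulfenilation (SH -> SOH, consuming H2O2), condensation (SOH -> SS),
#' optionally reduction of disulphide sites by thioredoxin, and optionally
#' sulfinilation of SOH sites with sulfiredoxin-mediated reversal.  Each
#' reaction carries its mirror-symmetry statistical factor (e.g. oxidation
#' of SH_SH has factor 2).
#'
#' @param include_sulfinilation Include SOOH chemistry (`k_sulfinilation`,
#'   `k_srx`).
#' @param include_trx Include `Prx_SS + Trx_red -> Prx_SH + Trx_ox` steps
#'   (`k_trx_red`).
#' @param sulfenilation_ref Rate-constant reference for dimer sulfenilation;
#'   `"k_SOH_dimer"` for the mixed-activity model, `"k_SOH_decamer"` to give
#'   dimers full decamer-level activity (the full-activity dimer-only
#'   variant).
#' @param include_small_molecules Include H2O2/H2O stoichiometry.
#' @return A `prx_network`.
#' @export
dimer_cycle_reactions <- function(include_sulfinilation = FALSE,
                                  include_trx = FALSE,
                                  sulfenilation_ref = "k_SOH_dimer",
                                  include_small_molecules = TRUE) {
  states <- if (include_sulfinilation) c("SH", "SOH", "SS", "SOOH")
            else c("SH", "SOH", "SS")
  labels <- .dimer_species(states)
  smr <- if (include_small_molecules) c(H2O2 = 1) else NULL
  smp <- if (include_small_molecules) c(H2O = 1) else NULL
  reactions <- c(
    .dimer_transitions(labels, "SH", "SOH", "sulfenilation",
                       sulfenilation_ref, smr, smp),
    .dimer_transitions(labels, "SOH", "SS", "condensation",
                       "k_SS_condensation"))
  if (include_trx)
    reactions <- c(reactions, .dimer_transitions(
      labels, "SS", "SH", "trx_reduction", "k_trx_red",
      c(Trx_red = 1), c(Trx_ox = 1)))
  if (include_sulfinilation)
    reactions <- c(reactions,
      .dimer_transitions(labels, "SOH", "SOOH", "sulfinilation",
                         "k_sulfinilation", smr, smp),
      .dimer_transitions(labels, "SOOH", "SOH", "srx_reduction", "k_srx"))
  species <- rbind(
    .mk_species(paste0("Prx_", labels), "dimer"),
    if (include_small_molecules) .mk_species(SMALL_SPECIES, "small"),
    if (include_trx) .mk_species(c("Trx_red", "Trx_ox"), "redox"))
  reaction_network(species, reactions)
}

#' Merge two reaction networks
#'
#' Species are united by identifier; reactions are concatenated (duplicate
#' reaction ids in `b` are dropped).
#' @param a,b `prx_network` objects.
#' @return A `prx_network`.
#' @export
merge_networks <- function(a, b) {
  sp <- rbind(a$species, b$species[!b$species$id %in% a$species$id, ])
  ids_a <- vapply(a$reactions, `[[`, "", "id")
  keep <- vapply(b$reactions, function(r) !r$id %in% ids_a, TRUE)
  reaction_network(sp, c(a$reactions, b$reactions[keep]),
                   mode = a$mode %||% b$mode)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Splice the decamerisation cycle into a dimer-level model
#'
#' Extends a free-dimer network with (i) reversible association of five
#' reduced dimers into the fully reduced decamer (`kon`/`koff`), and
#' (ii) the symmetry-reduced decamer oxidation/dissociation network of
#' [enumerate_network()].  Dimer sulfenilation reactions in the input are
#' re-pointed at `k_SOH_dimer`, so that dimers run at the 100-fold lower
#' activity while decamer sulfenilation uses `k_SOH_decamer`.
#'
#' @param dimer_network A `prx_network` containing the fully reduced dimer
#'   `Prx_SH_SH` and sulfenilation reactions.
#' @param params Kinetic parameters (used for validation only; rate values
#'   are resolved at simulation time).
#' @param mode Enumeration mode passed to [enumerate_network()].
#' @return A `prx_network` for the mixed-activity dimer-decamer model.
#' @export
decamerise_model <- function(dimer_network, params = kinetic_parameters(),
                             mode = "single_SS") {
  if (!"Prx_SH_SH" %in% dimer_network$species$id)
    stop("the dimer network must contain the fully reduced dimer Prx_SH_SH",
         call. = FALSE)
  kinds <- vapply(dimer_network$reactions, `[[`, "", "kind")
  if (!any(kinds == "sulfenilation"))
    stop("the dimer network must contain sulfenilation reactions",
         call. = FALSE)
  net <- dimer_network
  net$reactions <- lapply(net$reactions, function(r) {
    if (r$kind == "sulfenilation") r$rate_ref <- "k_SOH_dimer"
    r
  })
  dec0 <- .decamer_id(rep(1L, 10))
  assoc <- list(
    .rxn("assoc_reduced", "decamer_association", "kon", 1,
         c(Prx_SH_SH = 5), stats::setNames(1, dec0)),
    .rxn("diss_reduced", "decamer_dissociation", "koff", 1,
         stats::setNames(1, dec0), c(Prx_SH_SH = 5)))
  incl_sm <- "H2O2" %in% net$species$id
  dec_net <- enumerate_network(mode, include_small_molecules = incl_sm)
  core <- reaction_network(
    rbind(net$species,
          dec_net$species[!dec_net$species$id %in% net$species$id, ]),
    c(net$reactions, assoc), mode = mode)
  merge_networks(core, dec_net)
}

#' Write a plain-text reaction listing
#'
#' One reaction per line in the form
#' `"k_ref x factor: reactants -> products"`.
#'
#' @param network A `prx_network`.
#' @param path Output file; omit to return the lines invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_reaction_listing <- function(network, path = NULL) {
  side <- function(v) paste(
    ifelse(v > 1, paste0(v, " "), ""), names(v), sep = "", collapse = " + ")
  lines <- vapply(network$reactions, function(r) {
    sprintf("%s x%d: %s -> %s", r$rate_ref, r$factor,
            side(r$reactants), side(r$products))
  }, "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
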