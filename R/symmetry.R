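# Site states, canonical dimers and the symmetry-reduced decamer.
#
# A 2-Cys Prx dimer carries two catalytic sites; each site is in one of four
# oxidation states: reduced thiol (SH), sulfenic acid (SOH), disulphide
# bridge (SS) or sulfinic acid (SOOH).  A decamer is a ring of five dimers.
# Decamer configurations are identified up to the symmetry group generated by
# the five ring rotations, the planar reflection (ring reversal) and the
# mirror swap of the two sites within each dimer; the canonical
# representative of an orbit is its lexicographically smallest member under
# the site-state priority SH > SOH > SS > SOOH.

.prx_env <- new.env(parent = emptyenv())

#' Site oxidation states of a peroxiredoxin catalytic site
#'
#' @return Character vector `c("SH", "SOH", "SS", "SOOH")` in priority order
#'   (reduced, sulfenic, disulphide-bridged, sulfinic).
#' @export
site_states <- function() c("SH", "SOH", "SS", "SOOH")

.state_index <- function(x) {
  i <- match(x, site_states())
  if (anyNA(i)) {
    bad <- unique(x[is.na(i)])
    stop("unknown site state(s): ", paste(sQuote(bad), collapse = ", "),
         "; valid states are ", paste(site_states(), collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Canonical form of a Prx dimer
#'
#' Orders the two site states of a dimer so that the left-hand site has the
#' higher priority (SH > SOH > SS > SOOH).  Because the two sites of a free
#' dimer are related by mirror symmetry, the canonical form identifies
#' `(a, b)` with `(b, a)`.
#'
#' @param a,b Site states (see [site_states()]).
#' @return Character vector of length 2, the ordered `(left, right)` pair.
#' @examples
#' canonical_dimer("SOH", "SH")   # c("SH", "SOH")
#' @export
canonical_dimer <- function(a, b) {
  i <- .state_index(c(a, b))
  site_states()[sort(i)]
}

#' Label of a canonical dimer species
#'
#' @inheritParams canonical_dimer
#' @return A string such as `"SH_SOH"`.
#' @export
dimer_label <- function(a, b) paste(canonical_dimer(a, b), collapse = "_")

# All canonical dimer labels over a set of allowed site states.
.dimer_species <- function(states = c("SH", "SOH", "SS")) {
  idx <- .state_index(states)
  out <- character(0)
  for (i in idx) for (j in idx) if (i <= j)
    out <- c(out, paste(site_states()[c(i, j)], collapse = "_"))
  unique(out)
}

# --- the symmetry group --------------------------------------------------

# Permutations of the 10 site positions; dimers are the pairs
# (1,2),(3,4),(5,6),(7,8),(9,10).  The group is the closure of one ring
# rotation, the ring reversal and the five within-dimer swaps (order 320).
.decamer_group <- function() {
  if (!is.null(.prx_env$group)) return(.prx_env$group)
  rot <- c(3:10, 1:2)
  rev_ <- c(9, 10, 7, 8, 5, 6, 3, 4, 1, 2)
  swaps <- lapply(1:5, function(i) {
    p <- 1:10
    a <- 2L * i - 1L
    p[c(a, a + 1L)] <- c(a + 1L, a)
    p
  })
  gens <- c(list(rot, rev_), swaps)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  elems <- list(1:10)
  assign(key(1:10), TRUE, envir = seen)
  frontier <- elems
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) for (g in gens) {
      q <- g[p]
      k <- key(q)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        elems[[length(elems) + 1L]] <- q
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    frontier <- nxt
  }
  .prx_env$group <- do.call(rbind, elems)
  .prx_env$group
}

# Integer key of a configuration (base-4 over the 10 sites, states 1..4).
.cfg_key <- function(s) sum((s - 1L) * 4L^(9:0))

# Canonical representative (integer vector, states 1..4) of one configuration.
.canonical_cfg <- function(s) {
  g <- .decamer_group()
  imgs <- matrix(s[t(g)], nrow = nrow(g), byrow = TRUE)
  keys <- (imgs - 1) %*% (4^(9:0))
  imgs[which.min(keys), ]
}

# Vectorised canonical keys for a matrix of configurations (rows), states 1..4.
.canonical_keys <- function(mat) {
  g <- .decamer_group()
  pow <- 4^(9:0)
  best <- rep(Inf, nrow(mat))
  for (r in seq_len(nrow(g))) {
    k <- (mat[, g[r, ], drop = FALSE] - 1) %*% pow
    best <- pmin(best, k)
  }
  as.vector(best)
}

# Decode an integer key back to a configuration (states 1..4).
.key_to_cfg <- function(key) {
  s <- integer(10)
  for (i in 10:1) {
    s[i] <- key %% 4
    key <- key %/% 4
  }
  as.integer(s + 1L)
}

# --- decamer API ---------------------------------------------------------

.ring_to_sites <- function(ring) {
  if (is.character(ring) && length(ring) == 10L) {
    sites <- ring
  } else if (is.character(ring) && length(ring) == 5L) {
    parts <- strsplit(ring, "_", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("dimer labels must have the form 'STATE_STATE', e.g. 'SH_SOH'",
           call. = FALSE)
    sites <- unlist(parts)
  } else if (is.matrix(ring) && all(dim(ring) == c(5L, 2L))) {
    sites <- as.vector(t(ring))
  } else {
    stop("a decamer ring must be 5 dimer labels, 10 site states, or a 5x2 ",
         "matrix of site states; the decamer geometry is fixed at 5 dimers",
         call. = FALSE)
  }
  sites
}

#' Canonical form of a Prx decamer configuration
#'
#' Reduces a ring of five dimers to the canonical representative of its orbit
#' under the decamer symmetry group (5 rotations x ring reversal x per-dimer
#' mirror swap, order 320).  Canonicalisation is idempotent and constant on
#' orbits.  Sulfinic (SOOH) sites are rejected: hyperoxidation of decamers is
#' structurally excluded from the model.
#'
#' @param ring Either a character vector of 5 dimer labels (`"SH_SOH"`), a
#'   character vector of the 10 site states in ring order, or a 5x2 matrix of
#'   site states.
#' @return An object of class `prx_decamer`: a list with elements `sites`
#'   (length-10 canonical site vector), `ring` (5 canonical dimer labels),
#'   `id` (deterministic species identifier) and `canonical = TRUE`.
#' @examples
#' canonical_decamer(rep("SH_SH", 5))
#' @export
canonical_decamer <- function(ring) {
  sites <- .ring_to_sites(ring)
  idx <- .state_index(sites)
  if (any(idx == 4L))
    stop("SOOH sites cannot occur inside a decamer ",
         "(decamer sulfinilation is excluded)", call. = FALSE)
  can <- .canonical_cfg(idx)
  .decamer_from_cfg(can)
}

.decamer_from_cfg <- function(cfg) {
  sites <- site_states()[cfg]
  ring <- vapply(1:5, function(d) paste(sites[c(2 * d - 1, 2 * d)],
                                        collapse = "_"), "")
  structure(list(sites = sites, ring = ring,
                 id = paste0("Dec__", paste(ring, collapse = "__")),
                 canonical = TRUE),
            class = "prx_decamer")
}

#' @export
print.prx_decamer <- function(x, ...) {
  cat("<prx_decamer> ", paste(x$ring, collapse = " | "), "\n", sep = "")
  invisible(x)
}

# Species id for a canonical configuration given as integer vector.
.decamer_id <- function(cfg) .decamer_from_cfg(cfg)$id

.decamer_id_to_cfg <- function(id) {
  body <- sub("^Dec__", "", id)
  .state_index(unlist(strsplit(body, "__|_")))
}

#' Statistical factor of a site-level transition
#'
#' Counts the degenerate microscopic transitions that are collated into one
#' reaction when species are reduced to canonical form: the number of
#' single-site changes `from -> to` applicable to the canonical
#' representative of `parent` that yield a product in the orbit of
#' `product`.  For the first oxidation of the fully reduced decamer this is
#' 10; for the fully reduced free dimer it is 2.
#'
#' @param parent A `prx_decamer`, a decamer ring (as for
#'   [canonical_decamer()]), or a dimer label / length-2 site vector.
#' @param from,to Site states of the single-site change.
#' @param product Optional product (same forms as `parent`) selecting one
#'   product orbit when the transition can yield several.
#' @return A named integer vector of statistical factors, one per distinct
#'   canonical product (a single unnamed integer when `product` is given).
#' @export
orbit_degeneracy <- function(parent, from, to, product = NULL) {
  f <- .state_index(from); t_ <- .state_index(to)
  if (length(f) != 1L || length(t_) != 1L || f == t_)
    stop("the transition must be a single-site change between two distinct ",
         "states", call. = FALSE)
  is_dimer <- (is.character(parent) && length(parent) == 2L) ||
    (is.character(parent) && length(parent) == 1L && grepl("^[A-Z]+_[A-Z]+$", parent))
  if (inherits(parent, "prx_decamer")) {
    cfg <- .state_index(parent$sites)
  } else if (is_dimer) {
    lab <- if (length(parent) == 2L) parent else unlist(strsplit(parent, "_"))
    cfg <- sort(.state_index(lab))
  } else {
    cfg <- .state_index(.ring_to_sites(parent))
    cfg <- .canonical_cfg(cfg)
  }
  sites_from <- which(cfg == f)
  if (!length(sites_from))
    stop("transition not applicable: parent has no site in state ",
         sQuote(site_states()[f]), call. = FALSE)
  if (length(cfg) == 2L) {
    # free dimer: mirror symmetry only
    prods <- vapply(sites_from, function(i) {
      s2 <- cfg; s2[i] <- t_
      paste(site_states()[sort(s2)], collapse = "_")
    }, "")
  } else {
    prods <- vapply(sites_from, function(i) {
      s2 <- cfg; s2[i] <- t_
      .decamer_id(.canonical_cfg(s2))
    }, "")
  }
  tab <- table(prods)
  out <- as.integer(tab)
  names(out) <- names(tab)
  if (!is.null(product)) {
    pid <- if (inherits(product, "prx_decamer")) product$id
      else if (length(cfg) == 2L) {
        lab <- if (length(product) == 2L) product else unlist(strsplit(product, "_"))
        paste(site_states()[sort(.state_index(lab))], collapse = "_")
      } else canonical_decamer(product)$id
    if (!pid %in% names(out))
      stop("transition not applicable: no microscopic ", from, " -> ", to,
           " change of the parent yields the orbit of ", pid, call. = FALSE)
    out <- unname(out[[pid]])
  }
  out
}

# --- brute-force orbit oracle (independent code path, used by tests) -----

# Partition raw site assignments into orbits by breadth-first expansion
# under the group generators, without any lexicographic canonicalisation.
# `states` is either a vector of state indices (the full product space is
# used) or an explicit configuration matrix (rows = configurations).
.orbit_partition <- function(states = 1:2) {
  grid <- if (is.matrix(states)) states
          else as.matrix(expand.grid(rep(list(states), 10)))
  keys <- (grid - 1) %*% (4^(9:0))
  key_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(as.character(k), FALSE, envir = key_set)
  gens <- list(c(3:10, 1:2), c(9, 10, 7, 8, 5, 6, 3, 4, 1, 2))
  for (i in 1:5) {
    p <- 1:10; a <- 2L * i - 1L; p[c(a, a + 1L)] <- c(a + 1L, a)
    gens[[length(gens) + 1L]] <- p
  }
  orbits <- list()
  for (r in seq_len(nrow(grid))) {
    k0 <- as.character(keys[r])
    if (get(k0, envir = key_set)) next
    # expand the orbit of grid[r, ]
    frontier <- list(grid[r, ])
    assign(k0, TRUE, envir = key_set)
    members <- c(keys[r])
    while (length(frontier)) {
      nxt <- list()
      for (s in frontier) for (g in gens) {
        q <- s[g]
        kq <- sum((q - 1) * 4^(9:0))
        ck <- as.character(kq)
        if (!get(ck, envir = key_set)) {
          assign(ck, TRUE, envir = key_set)
          members <- c(members, kq)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
      frontier <- nxt
    }
    orbits[[length(orbits) + 1L]] <- members
  }
  orbits
}
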