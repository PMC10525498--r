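# Shared, lazily built objects reused across test files (enumeration and
# assay simulations are deterministic, so caching is safe).

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- force(expr)
  .test_cache[[name]]
}

net_single <- function() cached("net_single", enumerate_network("single_SS"))
net_multi <- function() cached("net_multi",
                               enumerate_network("multi_SS_one_per_dimer"))

default_params <- function() kinetic_parameters()

reduced_decamer_id <- function() canonical_decamer(rep("SH_SH", 5))$id

# Minimal association/dissociation-only network (5 reduced dimers <-> the
# reduced decamer).
assoc_only_network <- function() cached("assoc_net", {
  dec0 <- reduced_decamer_id()
  reaction_network(
    data.frame(id = c("Prx_SH_SH", dec0), role = c("dimer", "decamer")),
    list(
      list(id = "assoc", kind = "decamer_association", rate_ref = "kon",
           factor = 1L, reactants = c(Prx_SH_SH = 5),
           products = stats::setNames(1, dec0)),
      list(id = "diss", kind = "decamer_dissociation", rate_ref = "koff",
           factor = 1L, reactants = stats::setNames(1, dec0),
           products = c(Prx_SH_SH = 5))))
})

# A random decamer ring (5 dimer labels) over {SH, SOH} plus optionally one
# or more SS sites (at most one per dimer).
random_ring <- function(allow_ss = TRUE) {
  sites <- sample(c("SH", "SOH"), 10, replace = TRUE)
  if (allow_ss && stats::runif(1) < 0.7) {
    n_ss <- sample(1:3, 1)
    dimers <- sample(1:5, n_ss)
    for (d in dimers) sites[2 * d - sample(0:1, 1)] <- "SS"
  }
  sites
}

# Apply a random symmetry operation to a length-10 site vector.
random_symmetry <- function(sites) {
  k <- sample(0:4, 1)
  if (k > 0) sites <- sites[c((2 * k + 1):10, 1:(2 * k))]
  if (stats::runif(1) < 0.5) sites <- sites[c(9, 10, 7, 8, 5, 6, 3, 4, 1, 2)]
  for (d in 1:5) if (stats::runif(1) < 0.5) {
    a <- 2 * d - 1
    sites[c(a, a + 1)] <- sites[c(a + 1, a)]
  }
  sites
}
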