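# Empirical verification harnesses for the structural theorems:
#  - every NFU node is frozen in every attractor;
#  - the network is robust to an initial-state perturbation of any
#    non-source NFD node;
#  - with no feedback loop at all, every attractor is a fixed point.
# The theorems hold for arbitrary update functions, so each harness draws
# random networks with uniformly random truth tables and checks every
# initial state exhaustively; any violation is an implementation bug.

new_theorem_report <- function(property, n_networks, states, violations) {
  structure(list(property = property, n_networks = n_networks,
                 states_per_network = states, violations = violations,
                 passed = nrow(violations) == 0L),
            class = "theorem_report")
}

#' @export
print.theorem_report <- function(x, ...) {
  cat(sprintf("Property check '%s': %d networks, %s initial states each\n",
              x$property, x$n_networks, x$states_per_network))
  if (x$passed) {
    cat("  0 violations\n")
  } else {
    cat(" ", nrow(x$violations), "violation(s); first:\n")
    print(utils::head(x$violations, 3L))
  }
  invisible(x)
}

random_ensemble <- function(i, seeds, n_nodes, n_edges, acyclic) {
  net <- generate_random_network(n_nodes, n_edges, acyclic = acyclic,
                                 seed = seeds[2L * i - 1L])
  random_boolean_functions(net, seed = seeds[2L * i])
}

#' Verify that NFU nodes freeze, over a random ensemble
#'
#' Draws `n_networks` random Boolean networks (uniform random digraph,
#' fair-coin truth tables), enumerates all `2^N` initial states of each, and
#' checks that every no-FBL-in-upstream node holds a constant value in every
#' attractor. Expected: zero violations.
#'
#' @param n_networks ensemble size.
#' @param n_nodes,n_edges network size (defaults 8 and 14).
#' @param seed master seed; all sub-seeds derive from it.
#' @param acyclic generate acyclic networks only (then every node is NFU and
#'   every attractor must be a fixed point).
#' @return A `theorem_report`; `passed` is `TRUE` iff no violation.
#' @export
verify_nfu_frozen <- function(n_networks = 200L, n_nodes = 8L, n_edges = 14L,
                              seed = 1L, acyclic = FALSE) {
  seeds <- derive_seeds(seed, 2L * n_networks)
  viol <- list()
  for (i in seq_len(n_networks)) {
    bn <- random_ensemble(i, seeds, n_nodes, n_edges, acyclic)
    cls <- classify_nodes(bn$net)
    nfu <- cls$node[cls$is_nfu]
    if (length(nfu) == 0L) next
    ex <- attractors_exhaustive(bn)
    for (att in ex$attractors) {
      for (v in nfu) {
        if (!is_frozen(att, v)) {
          viol[[length(viol) + 1L]] <- data.frame(
            network = i, seed = seeds[2L * i - 1L], node = v,
            state = apply(att$states, 1L, paste, collapse = "")[1L])
        }
      }
    }
  }
  new_theorem_report("NFU nodes frozen", n_networks, "exhaustive",
                     do.call(rbind, viol) %||%
                       data.frame(network = integer(), seed = integer(),
                                  node = character(), state = character()))
}

#' Verify robustness to perturbations of non-source NFD nodes
#'
#' Over the same random ensemble, checks for every non-source
#' no-FBL-in-downstream node `v` and every initial state `s` that the
#' trajectories from `s` and from `s` with `v` flipped converge to equivalent
#' attractors. Uses the full transition table: two states converge to
#' equivalent attractors iff they map to the same attractor of the
#' functional graph. Expected: zero violations.
#'
#' @inheritParams verify_nfu_frozen
#' @return A `theorem_report`.
#' @export
verify_nfd_robust <- function(n_networks = 200L, n_nodes = 8L, n_edges = 14L,
                              seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_networks)
  viol <- list()
  for (i in seq_len(n_networks)) {
    bn <- random_ensemble(i, seeds, n_nodes, n_edges, acyclic = FALSE)
    cls <- classify_nodes(bn$net)
    targets <- cls$node[cls$is_nfd & !cls$is_source]
    if (length(targets) == 0L) next
    ex <- attractors_exhaustive(bn)
    n <- length(bn$nodes)
    codes <- 0:(2L^n - 1L)
    for (v in targets) {
      mask <- 2L^(n - match(v, bn$nodes))
      bad <- which(ex$attid[codes + 1L] != ex$attid[bitwXor(codes, mask) + 1L])
      for (s in bad) {
        viol[[length(viol) + 1L]] <- data.frame(
          network = i, seed = seeds[2L * i - 1L], node = v,
          state = paste(decode_states(codes[s], bn$nodes), collapse = ""))
      }
    }
  }
  new_theorem_report("robust to non-source NFD perturbations", n_networks,
                     "exhaustive",
                     do.call(rbind, viol) %||%
                       data.frame(network = integer(), seed = integer(),
                                  node = character(), state = character()))
}

#' Verify that acyclic networks only have fixed-point attractors
#'
#' Over an ensemble of random acyclic Boolean networks, checks that the
#' attractor from every initial state has period 1 (with no feedback loop
#' every node is NFU, so the whole state freezes).
#'
#' @inheritParams verify_nfu_frozen
#' @return A `theorem_report`.
#' @export
verify_acyclic_fixed_points <- function(n_networks = 200L, n_nodes = 8L,
                                        n_edges = 14L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_networks)
  viol <- list()
  for (i in seq_len(n_networks)) {
    bn <- random_ensemble(i, seeds, n_nodes, n_edges, acyclic = TRUE)
    ex <- attractors_exhaustive(bn)
    for (att in ex$attractors) {
      if (att$period != 1L) {
        viol[[length(viol) + 1L]] <- data.frame(
          network = i, seed = seeds[2L * i - 1L], node = NA_character_,
          state = apply(att$states, 1L, paste, collapse = "")[1L])
      }
    }
  }
  new_theorem_report("acyclic networks reach fixed points", n_networks,
                     "exhaustive",
                     do.call(rbind, viol) %||%
                       data.frame(network = integer(), seed = integer(),
                                  node = character(), state = character()))
}
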