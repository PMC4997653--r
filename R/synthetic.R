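# Random-network and random-function generators. Everything is
# bit-reproducible under a fixed seed and leaves the caller's RNG alone.

#' Generate a uniformly random directed network
#'
#' Samples `n_edges` distinct ordered pairs uniformly from all admissible
#' pairs. With `acyclic = TRUE`, pairs are restricted to those respecting a
#' random topological order, so the result is guaranteed to be a DAG (and
#' every node is both NFU and NFD).
#'
#' @param n_nodes,n_edges network size.
#' @param allow_self_loops permit edges `(v, v)` (default `FALSE`).
#' @param acyclic restrict to a DAG (default `FALSE`); incompatible with
#'   self-loops.
#' @param seed integer seed; identical seeds give identical networks.
#' @param node_names optional identifiers (default `"n01", "n02", ...`,
#'   zero-padded so lexicographic order is generation order).
#' @return A [directed_network].
#' @export
generate_random_network <- function(n_nodes, n_edges, allow_self_loops = FALSE,
                                    acyclic = FALSE, seed = NULL,
                                    node_names = NULL) {
  stopifnot(n_nodes >= 1L, n_edges >= 0L)
  if (acyclic && allow_self_loops) stop("an acyclic network cannot have self-loops")
  nodes <- node_names %||%
    sprintf(paste0("n%0", max(2L, nchar(n_nodes)), "d"), seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes, !anyDuplicated(nodes))
  max_m <- if (acyclic) n_nodes * (n_nodes - 1L) / 2L else
    n_nodes * (n_nodes - 1L) + if (allow_self_loops) n_nodes else 0L
  if (n_edges > max_m) {
    stop("infeasible edge count: ", n_edges, " > ", max_m, " admissible pairs")
  }
  with_seed(seed, {
    if (acyclic) {
      ord <- sample(n_nodes)  # random topological order
      cand <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
      from <- ord[cand[, 1L]]
      to <- ord[cand[, 2L]]
    } else {
      cand <- expand.grid(from = seq_len(n_nodes), to = seq_len(n_nodes))
      keep <- allow_self_loops | cand$from != cand$to
      from <- cand$from[keep]
      to <- cand$to[keep]
    }
    pick <- sample.int(length(from), n_edges)
    directed_network(cbind(nodes[from[pick]], nodes[to[pick]]), nodes = nodes)
  })
}

#' Attach uniformly random update functions to a network
#'
#' Every non-source node gets a truth table over its inputs (sorted by node
#' identifier) with each of the `2^k` output bits drawn by a fair coin;
#' source nodes get none (their state is held).
#'
#' @param net a [directed_network].
#' @param seed integer seed.
#' @return A [boolean_network].
#' @export
random_boolean_functions <- function(net, seed = NULL) {
  indeg <- in_degrees(net)
  non_src <- net$nodes[indeg > 0L]
  with_seed(seed, {
    fns <- lapply(non_src, function(v) {
      ins <- sort(unique(net$edges$from[net$edges$to == v]))
      list(inputs = ins,
           outputs = sample(0:1, 2L^length(ins), replace = TRUE))
    })
    names(fns) <- non_src
    boolean_network(net, fns)
  })
}

#' Degree-preserving random rewiring
#'
#' Performs `n_swaps` successful double-edge swaps: two edges `(a, b)` and
#' `(c, d)` become `(a, d)` and `(c, b)` provided neither replacement edge
#' already exists and no new self-loop is created. Every node keeps its exact
#' in-degree and out-degree, which is the null model used to ask whether an
#' observed classification/annotation association is a degree artifact.
#' Edge signs travel with the tail: `(a, d)` inherits the sign of `(a, b)`.
#'
#' @param net a [directed_network] with at least 2 edges.
#' @param n_swaps number of successful swaps (default `10 * n_edges`, a
#'   standard mixing heuristic). Failed attempts are skipped; a cap of
#'   `100 * n_swaps` attempts guards against pathological inputs.
#' @param seed integer seed.
#' @return A rewired [directed_network] over the same node set.
#' @export
rewire_preserving_degrees <- function(net, n_swaps = NULL, seed = NULL) {
  m <- n_edges(net)
  if (m < 2L) stop("rewiring needs at least 2 edges")
  n_swaps <- n_swaps %||% (10L * m)
  if (n_swaps == 0L) return(net)
  from <- net$edges$from
  to <- net$edges$to
  sgn <- net$edges$sign
  have <- new.env(parent = emptyenv())
  for (k in paste(from, to, sep = "\r")) have[[k]] <- TRUE
  with_seed(seed, {
    done <- 0L
    attempts <- 0L
    max_attempts <- 100L * n_swaps
    while (done < n_swaps && attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      a <- from[i]; b <- to[i]; c_ <- from[j]; d <- to[j]
      if (a == d || c_ == b) next            # would create a self-loop
      k1 <- paste(a, d, sep = "\r"); k2 <- paste(c_, b, sep = "\r")
      if (!is.null(have[[k1]]) || !is.null(have[[k2]])) next
      rm(list = paste(c(a, c_), c(b, d), sep = "\r"), envir = have)
      have[[k1]] <- TRUE; have[[k2]] <- TRUE
      to[i] <- d; to[j] <- b
      done <- done + 1L
    }
    if (done < n_swaps) {
      warning("only ", done, " of ", n_swaps, " swaps succeeded within the attempt cap")
    }
  })
  directed_network(cbind(from, to), nodes = net$nodes, sign = sgn)
}

#' Fixed five-node example network
#'
#' Nodes `a..e`, edges `a->b, b->c, c->b, c->d, d->e`: one two-node feedback
#' loop (`b`, `c`) fed by a source (`a`) and draining into a chain
#' (`d`, `e`). Classification: `a` is the only NFU node, `d` and `e` the NFD
#' nodes, `b` and `c` neither.
#'
#' @return A [directed_network].
#' @export
toy_network_t1 <- function() {
  directed_network(cbind(c("a", "b", "c", "c", "d"),
                         c("b", "c", "b", "d", "e")))
}
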