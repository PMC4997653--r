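#' Flip one node of an initial state
#'
#' An initial-state perturbation: the returned state differs from `s` exactly
#' at node `v` (the bit is negated).
#'
#' @param bn a [boolean_network] (fixes the node order).
#' @param s a network state.
#' @param v node identifier to flip.
#' @return The perturbed state.
#' @export
perturb_initial <- function(bn, s, v) {
  s <- as_state(bn, s)
  if (!v %in% bn$nodes) stop("unknown node: ", v)
  s[[v]] <- 1L - s[[v]]
  s
}

#' Robustness against one initial-state perturbation
#'
#' Runs the trajectories from `s0` and from `s0` with node `v` flipped; the
#' network is robust against the perturbation iff the two attractors are
#' equivalent (equal period, same cycle up to a time offset).
#'
#' @param bn a [boolean_network].
#' @param s0 initial state.
#' @param v node whose initial value is flipped.
#' @return List of class `robustness_result`: `node`, `state` (the initial
#'   state), `robust`, `attractor_original`, `attractor_perturbed`.
#' @export
is_robust <- function(bn, s0, v) {
  s0 <- as_state(bn, s0)
  a1 <- find_attractor(bn, s0)
  a2 <- find_attractor(bn, perturb_initial(bn, s0, v))
  structure(list(node = v, state = s0,
                 robust = attractors_equivalent(a1, a2),
                 attractor_original = a1, attractor_perturbed = a2),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Perturbation of node '%s' in state %s: %s\n", x$node,
              paste(x$state, collapse = ""),
              if (x$robust) "robust" else "sensitive"))
  invisible(x)
}

# --- perturbation-sustainable probability -----------------------------------

#' Probability that a perturbation is sustained through one path
#'
#' For a downstream path `v_x u_1 ... u_L` of its first node, the sustaining
#' probability is the product of the reciprocal in-degrees of `u_1 .. u_L`
#' when some `u_i` is FBL-involved (each input of a node is assumed an
#' equally likely carrier of a flip, so a flip propagates across an edge into
#' `u_i` with probability `1/d_in(u_i)`), and 0 otherwise: a perturbation
#' that never touches a feedback loop dies out and cannot change the
#' attractor.
#'
#' @param net a [directed_network].
#' @param p character vector of node identifiers, the path `v_x, u_1 .. u_L`
#'   (`L >= 1`); consecutive pairs must be edges and no node may repeat
#'   except that the last may equal the first (a feedback loop).
#' @return A probability in `[0, 1]`.
#' @examples
#' path_probability(toy_network_t1(), c("a", "b"))  # 0.5
#' @export
path_probability <- function(net, p) {
  p <- as.character(p)
  if (length(p) < 2L) stop("a path has length >= 1 (two or more nodes)")
  if (!all(p %in% net$nodes)) {
    stop("unknown node(s): ", paste(setdiff(p, net$nodes), collapse = ", "))
  }
  ekey <- paste(net$edges$from, net$edges$to, sep = "\r")
  steps <- paste(p[-length(p)], p[-1L], sep = "\r")
  if (!all(steps %in% ekey)) stop("not a path: some consecutive pair is not an edge")
  inner <- if (p[1L] == p[length(p)]) p[-length(p)] else p
  if (anyDuplicated(inner)) stop("not a simple path: repeated node")
  us <- p[-1L]
  if (!any(us %in% fbl_nodes(net))) return(0)
  d <- in_degrees(net)[us]
  prod(1 / d)
}

#' Perturbation-sustainable probability of every node
#'
#' For each node `v`, the maximum over all downstream paths of `v` of the
#' path-sustaining probability ([path_probability()]): the probability that a
#' state perturbation of `v` survives long enough to enter a feedback loop,
#' where it can be sustained indefinitely. NFD nodes score exactly 0.
#'
#' Computed exactly as a shortest-path problem: each edge `(a, b)` carries
#' weight `log d_in(b)`, so a path's weight is the negative log of its
#' probability; the best path may stop at the first FBL-involved node it
#' meets (further factors are `<= 1`). With nonnegative weights an optimal
#' walk is automatically simple, so a multi-source Dijkstra pass gives the
#' exact maximum in near-linear time.
#'
#' @param net a [directed_network].
#' @return Named numeric vector over all nodes, values in `[0, 1]`.
#' @examples
#' gamma_scores(toy_network_t1())
#' @export
gamma_scores <- function(net) {
  zero <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  fb <- fbl_nodes(net)
  if (length(fb) == 0L || n_edges(net) == 0L) return(zero)
  indeg <- in_degrees(net)
  w <- log(indeg[net$edges$to])  # every edge target has in-degree >= 1
  stopifnot(all(is.finite(w)))
  g <- as_igraph(net)
  g <- igraph::add_vertices(g, 1L, name = "..sink..")
  sink <- length(net$nodes) + 1L
  g <- igraph::add_edges(g, as.vector(rbind(match(fb, net$nodes), sink)))
  # h[u] = min cost of a path u -> ... -> (FBL-involved node), 0 if u is one
  h <- igraph::distances(g, v = "..sink..", to = net$nodes, mode = "in",
                         weights = c(unname(w), numeric(length(fb))))[1L, ]
  # gamma(v) = exp(-min over out-edges (v,u) of [log d_in(u) + h(u)]);
  # the explicit first step keeps a cycle member from scoring via an empty path
  vals <- unname(w) + h[net$edges$to]
  best <- tapply(vals, factor(net$edges$from, levels = net$nodes), min)
  gam <- exp(-as.numeric(best))
  gam[is.na(gam)] <- 0  # nodes with no outgoing edge
  stats::setNames(gam, net$nodes)
}

#' Perturbation-sustainable probability by literal path enumeration (oracle)
#'
#' Same contract as [gamma_scores()] for one node, computed by enumerating
#' every simple downstream path and maximizing [path_probability()] over
#' them. Exponential; guarded to small networks.
#'
#' @param net a [directed_network] with at most `max_nodes` nodes.
#' @param v node identifier.
#' @param max_nodes size guard (default 12).
#' @return A probability in `[0, 1]`.
#' @export
gamma_bruteforce <- function(net, v, max_nodes = 12L) {
  n <- n_nodes(net)
  if (n > max_nodes) {
    stop("network too large for path enumeration (", n, " > ", max_nodes, " nodes)")
  }
  if (!v %in% net$nodes) stop("unknown node: ", v)
  fb <- net$nodes %in% fbl_nodes(net)
  indeg <- in_degrees(net)
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  adj <- lapply(seq_len(n), function(i) ti[fi == i])
  v0 <- match(v, net$nodes)
  best <- 0
  onpath <- logical(n)
  rec <- function(cur, prob, hit_fbl) {
    for (nb in adj[[cur]]) {
      if (onpath[nb] && nb != v0) next
      closing <- nb == v0
      p2 <- prob / indeg[nb]
      h2 <- hit_fbl || fb[nb]
      if (h2 && p2 > best) best <<- p2
      if (!closing) {
        onpath[nb] <<- TRUE
        rec(nb, p2, h2)
        onpath[nb] <<- FALSE
      }
    }
  }
  onpath[v0] <- TRUE
  rec(v0, 1, FALSE)
  unname(best)
}
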