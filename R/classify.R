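#' Classify nodes by feedback loops in their upstream and downstream paths
#'
#' A node is *no-FBL-in-upstream* (NFU) if no upstream path of it contains an
#' FBL-involved node, and *no-FBL-in-downstream* (NFD) if no downstream path
#' does. A node lying on a cycle is neither (its own loop is both an upstream
#' and a downstream path of it). NFU nodes are exactly the nodes not reachable
#' from any FBL-involved node; NFD nodes are those from which no FBL-involved
#' node is reachable — two multi-source traversals, so the classification
#' scales linearly in the network size.
#'
#' @param net a [directed_network].
#' @return A data frame of class `node_classification` with columns `node`,
#'   `is_source` (in-degree zero), `on_fbl`, `is_nfu`, `is_nfd`.
#' @examples
#' cls <- classify_nodes(toy_network_t1())
#' cls$node[cls$is_nfu]  # "a"
#' @export
classify_nodes <- function(net) {
  fb <- fbl_nodes(net)
  down_of_fbl <- reach_from_set(net, fb, "out")  # nodes with an FBL upstream (or on one)
  up_of_fbl <- reach_from_set(net, fb, "in")     # nodes with an FBL downstream (or on one)
  out <- data.frame(
    node = net$nodes,
    is_source = unname(in_degrees(net) == 0L),
    on_fbl = net$nodes %in% fb,
    is_nfu = !net$nodes %in% down_of_fbl,
    is_nfd = !net$nodes %in% up_of_fbl,
    stringsAsFactors = FALSE)
  class(out) <- c("node_classification", "data.frame")
  out
}

#' @export
print.node_classification <- function(x, ...) {
  cat("Node classification:", nrow(x), "nodes\n")
  cat(sprintf("  sources %d | on FBL %d | NFU %d | NFD %d | neither NFU nor NFD %d\n",
              sum(x$is_source), sum(x$on_fbl), sum(x$is_nfu), sum(x$is_nfd),
              sum(!x$is_nfu & !x$is_nfd)))
  NextMethod()
}

#' Write a node classification as TSV
#'
#' Columns `node`, `is_source`, `on_fbl`, `is_nfu`, `is_nfd`, boolean cells
#' written as `1`/`0`.
#'
#' @param cls a `node_classification` (see [classify_nodes()]).
#' @param path output file.
#' @param header optional `#`-prefixed comment lines.
#' @export
write_classification <- function(cls, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("node\tis_source\ton_fbl\tis_nfu\tis_nfd", con)
  writeLines(paste(cls$node, as.integer(cls$is_source), as.integer(cls$on_fbl),
                   as.integer(cls$is_nfu), as.integer(cls$is_nfd), sep = "\t"),
             con)
  invisible(path)
}

# --- literal-definition oracle ----------------------------------------------

# Enumerate, by depth-first search over `adj`, every node that appears as an
# intermediate u_i of some simple path ending (upstream) or starting
# (downstream) at v; the path may close back at v (then v itself is a u_i).
visited_path_nodes <- function(adj, v, n) {
  seen <- logical(n)      # nodes that occurred as some u_i
  onpath <- logical(n)
  rec <- function(cur) {
    for (nb in adj[[cur]]) {
      if (nb == v) seen[v] <<- TRUE      # closing FBL: v is u_1 of that path
      if (onpath[nb] || nb == v) next
      seen[nb] <<- TRUE
      onpath[nb] <<- TRUE
      rec(nb)
      onpath[nb] <<- FALSE
    }
  }
  onpath[v] <- TRUE
  rec(v)
  which(seen)
}

# Is there a simple directed cycle through v? (literal path-based check)
on_cycle_bruteforce <- function(adj, v, n) {
  found <- FALSE
  onpath <- logical(n)
  rec <- function(cur) {
    if (found) return()
    for (nb in adj[[cur]]) {
      if (nb == v) { found <<- TRUE; return() }
      if (onpath[nb]) next
      onpath[nb] <<- TRUE
      rec(nb)
      onpath[nb] <<- FALSE
    }
  }
  onpath[v] <- TRUE
  rec(v)
  found
}

#' Node classification by literal path enumeration (test oracle)
#'
#' Same contract as [classify_nodes()], computed directly from the
#' definitions: FBL involvement by searching for a simple cycle through each
#' node, and NFU/NFD by enumerating every simple upstream/downstream path and
#' checking its intermediate nodes. Exponential; guarded to small networks.
#'
#' @param net a [directed_network] with at most `max_nodes` nodes.
#' @param max_nodes size guard (default 12).
#' @return A `node_classification` data frame.
#' @export
classify_nodes_bruteforce <- function(net, max_nodes = 12L) {
  n <- n_nodes(net)
  if (n > max_nodes) {
    stop("network too large for path enumeration (", n, " > ", max_nodes, " nodes)")
  }
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  adj_out <- lapply(seq_len(n), function(i) ti[fi == i])
  adj_in <- lapply(seq_len(n), function(i) fi[ti == i])
  on_fbl <- vapply(seq_len(n), function(v) on_cycle_bruteforce(adj_out, v, n), logical(1))
  is_nfu <- vapply(seq_len(n), function(v) {
    !any(on_fbl[visited_path_nodes(adj_in, v, n)])
  }, logical(1))
  is_nfd <- vapply(seq_len(n), function(v) {
    !any(on_fbl[visited_path_nodes(adj_out, v, n)])
  }, logical(1))
  out <- data.frame(node = net$nodes,
                    is_source = unname(in_degrees(net) == 0L),
                    on_fbl = on_fbl, is_nfu = is_nfu, is_nfd = is_nfd,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_classification", "data.frame")
  out
}
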