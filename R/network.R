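#' Construct a directed network
#'
#' The structural substrate for all analyses in this package: a set of node
#' identifiers (opaque, case-sensitive strings) plus a set of directed edges,
#' each optionally carrying an interaction sign. Edges follow set semantics:
#' duplicates are dropped (with a message giving the count); self-loops are
#' permitted and count as length-1 feedback loops.
#'
#' @param edges two-column character matrix or data frame (`from`, `to`).
#' @param nodes optional character vector of node identifiers; the union with
#'   all edge endpoints is used. Isolated nodes are kept.
#' @param sign optional character vector, one of `"positive"`, `"negative"`,
#'   `"unknown"` per edge (recycled if length 1). Signs are carried through
#'   I/O and rewiring but never enter classification or scoring.
#' @return An object of class `directed_network` with components `nodes`
#'   (sorted character vector) and `edges` (data frame `from`, `to`, `sign`).
#' @examples
#' net <- directed_network(cbind(c("a", "b"), c("b", "c")))
#' net
#' @export
directed_network <- function(edges, nodes = NULL, sign = NULL) {
  if (is.null(dim(edges))) {
    if (length(edges) == 0L) {
      edges <- matrix(character(), ncol = 2L)
    } else {
      stop("`edges` must be a two-column matrix or data frame")
    }
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` must have two columns (from, to)")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (is.null(sign)) sign <- rep("unknown", length(from))
  sign <- rep_len(as.character(sign), length(from))
  bad <- !sign %in% c("positive", "negative", "unknown")
  if (any(bad)) stop("invalid edge sign(s): ", paste(unique(sign[bad]), collapse = ", "))
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) dropped")
    from <- from[!dup]; to <- to[!dup]; sign <- sign[!dup]
  }
  nodes <- sort(unique(c(as.character(nodes %||% character()), from, to)))
  structure(
    list(nodes = nodes,
         edges = data.frame(from = from, to = to, sign = sign,
                            stringsAsFactors = FALSE)),
    class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  nf <- fbl_nodes(x)
  cat("  sources:", sum(in_degrees(x) == 0L),
      " FBL-involved nodes:", length(nf), "\n")
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

# igraph view of the network (signs are not carried; they never enter the math)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = TRUE, vertices = net$nodes)
}

#' Read a directed network from a plain-text edge list
#'
#' Two dialects are supported. `two_column`: one edge per line,
#' `source target`, whitespace- or tab-separated. `sif`: three fields,
#' `source interaction target`, with the interaction word mapped to an edge
#' sign through `sign_map`. Lines beginning with `#` and blank lines are
#' ignored. Duplicate edges are dropped with a message.
#'
#' @param path file to read.
#' @param dialect `"two_column"` (default) or `"sif"`.
#' @param sign_map named character vector mapping interaction words to signs;
#'   interactions absent from the map become `"unknown"`.
#' @return A [directed_network].
#' @export
read_edge_list <- function(path, dialect = c("two_column", "sif"),
                           sign_map = c(activates = "positive", "+" = "positive",
                                        inhibits = "negative", "-" = "negative")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in file: ", path)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  want <- if (dialect == "two_column") 2L else 3L
  nf <- lengths(parts)
  if (any(nf != want)) {
    bad <- idx[which(nf != want)[1L]]
    stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                 bad, path, want, nf[which(nf != want)[1L]]))
  }
  m <- do.call(rbind, parts)
  if (dialect == "two_column") {
    directed_network(m)
  } else {
    sg <- unname(sign_map[m[, 2L]])
    sg[is.na(sg)] <- "unknown"
    directed_network(m[, c(1L, 3L), drop = FALSE], sign = sg)
  }
}

#' Write a network as a plain-text edge list
#'
#' @param net a [directed_network].
#' @param path output file.
#' @param dialect `"two_column"` or `"sif"` (signs written as
#'   `activates`/`inhibits`/`unknown`).
#' @param header optional character vector of comment lines (written
#'   `#`-prefixed before the edges).
#' @export
write_edge_list <- function(net, path, dialect = c("two_column", "sif"),
                            header = NULL) {
  dialect <- match.arg(dialect)
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (dialect == "two_column") {
    writeLines(paste(net$edges$from, net$edges$to, sep = "\t"), con)
  } else {
    word <- c(positive = "activates", negative = "inhibits",
              unknown = "unknown")[net$edges$sign]
    writeLines(paste(net$edges$from, word, net$edges$to, sep = "\t"), con)
  }
  invisible(path)
}

#' In-degrees of all nodes
#'
#' The in-degree of a node is its number of input nodes; a self-loop
#' contributes one.
#'
#' @param net a [directed_network].
#' @return Named integer vector over all nodes.
#' @export
in_degrees <- function(net) {
  d <- table(factor(net$edges$to, levels = net$nodes))
  stats::setNames(as.integer(d), net$nodes)
}

#' Nodes involved in at least one feedback loop
#'
#' A feedback loop (FBL) is a directed path whose first and last nodes
#' coincide; self-loops are length-1 FBLs. A node is FBL-involved iff it
#' belongs to a strongly connected component of size >= 2 or carries a
#' self-loop.
#'
#' @param net a [directed_network].
#' @return Character vector of FBL-involved nodes (sorted).
#' @export
fbl_nodes <- function(net) {
  if (n_edges(net) == 0L) return(character())
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize >= 2L)
  on_scc <- net$nodes[comp$membership %in% big]
  self <- net$edges$from[net$edges$from == net$edges$to]
  sort(unique(c(on_scc, self)))
}

# All nodes reachable from `set` (inclusive of `set`) following `mode`
# ("out" = downstream, "in" = upstream). Multi-source BFS via a virtual root.
reach_from_set <- function(net, set, mode) {
  if (length(set) == 0L) return(character())
  g <- as_igraph(net)
  g <- igraph::add_vertices(g, 1L, name = "..virtual..")
  root <- length(net$nodes) + 1L
  tgt <- match(set, net$nodes)
  if (mode == "out") {
    g <- igraph::add_edges(g, as.vector(rbind(root, tgt)))
  } else {
    g <- igraph::add_edges(g, as.vector(rbind(tgt, root)))
  }
  got <- igraph::subcomponent(g, "..virtual..", mode = mode)
  setdiff(names(got), "..virtual..")
}

#' Nodes upstream or downstream of a node
#'
#' All nodes `w != v` connected to `v` by a directed path (from `w` to `v`
#' for `upstream`, from `v` to `w` for `downstream`). `v` itself is included
#' only when it lies on a cycle through itself (it then starts and ends an
#' FBL, which is both an upstream and a downstream path of it).
#'
#' @param net a [directed_network].
#' @param v a node identifier.
#' @param direction `"upstream"` or `"downstream"`.
#' @return Character vector of node identifiers (sorted).
#' @export
reachable <- function(net, v, direction = c("upstream", "downstream")) {
  direction <- match.arg(direction)
  if (!v %in% net$nodes) stop("unknown node: ", v)
  g <- as_igraph(net)
  mode <- if (direction == "upstream") "in" else "out"
  got <- names(igraph::subcomponent(g, v, mode = mode))
  got <- setdiff(got, v)
  if (v %in% fbl_nodes(net)) got <- c(got, v)
  sort(got)
}
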