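#' Build a synchronous Boolean network
#'
#' Couples a directed network with one Boolean update function per non-source
#' node. At every discrete time step all nodes update simultaneously:
#' `v(t+1) = f_v(inputs of v at time t)`. Source nodes (in-degree zero) have
#' no update function; their state is held at its initial value for all time.
#'
#' @param net a [directed_network].
#' @param functions named list over the non-source nodes; each element is a
#'   list with `inputs` (character vector, the node's input nodes in the
#'   order the truth table is indexed by) and `outputs` (vector of `2^k`
#'   bits, or a `2^k`-character `"0"/"1"` string). The table is indexed by
#'   the input tuple read as a binary number, most significant bit = first
#'   input.
#' @return An object of class `boolean_network`: the network, the node order
#'   (sorted node identifiers; all states use this order), and the validated
#'   function tables.
#' @examples
#' net <- directed_network(cbind(c("a", "b"), c("b", "a")))
#' bn <- boolean_network(net, list(
#'   a = list(inputs = "b", outputs = c(1, 0)),   # negation
#'   b = list(inputs = "a", outputs = c(1, 0))))
#' step_state(bn, c(0, 0))
#' @export
boolean_network <- function(net, functions) {
  nodes <- net$nodes
  indeg <- in_degrees(net)
  sources <- nodes[indeg == 0L]
  non_src <- setdiff(nodes, sources)
  missing <- setdiff(non_src, names(functions))
  if (length(missing)) {
    stop("missing update function(s) for non-source node(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(functions), non_src)
  if (length(extra)) {
    stop("update function(s) given for source or unknown node(s): ",
         paste(extra, collapse = ", "))
  }
  fns <- vector("list", length(nodes))
  names(fns) <- nodes
  for (v in non_src) {
    f <- functions[[v]]
    ins <- as.character(f$inputs)
    true_ins <- sort(unique(net$edges$from[net$edges$to == v]))
    if (!setequal(ins, true_ins) || length(ins) != length(true_ins)) {
      stop("inputs recorded for node '", v, "' do not match its input nodes")
    }
    out <- f$outputs
    if (is.character(out) && length(out) == 1L) {
      out <- as.integer(strsplit(out, "")[[1L]])
    }
    out <- as.integer(out)
    if (length(out) != 2L^length(ins) || anyNA(out) || !all(out %in% 0:1)) {
      stop("truth table for node '", v, "' must be 2^", length(ins), " bits")
    }
    fns[[v]] <- list(
      inputs = ins,
      in_pos = match(ins, nodes),
      weights = 2L^(rev(seq_along(ins)) - 1L),  # MSB = first input
      outputs = out)
  }
  structure(list(net = net, nodes = nodes, is_source = nodes %in% sources,
                 functions = fns),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Synchronous Boolean network:", length(x$nodes), "nodes (",
      sum(x$is_source), "source, held constant )\n")
  invisible(x)
}

# Coerce/validate a state vector against the network's node order.
as_state <- function(bn, s) {
  if (is.character(s) && length(s) == 1L) s <- as.integer(strsplit(s, "")[[1L]])
  s <- as.integer(s)
  if (length(s) != length(bn$nodes)) {
    stop("state length ", length(s), " does not match node count ",
         length(bn$nodes))
  }
  if (anyNA(s) || !all(s %in% 0:1)) stop("state entries must be 0 or 1")
  names(s) <- bn$nodes
  s
}

state_string <- function(s) paste(s, collapse = "")

#' One synchronous update step
#'
#' Every non-source node reads the current values of its inputs and takes the
#' corresponding truth-table bit; every source node keeps its value.
#'
#' @param bn a [boolean_network].
#' @param s state: 0/1 vector in the network's node order (or a `"0"/"1"`
#'   string).
#' @return The successor state (named 0/1 integer vector).
#' @export
step_state <- function(bn, s) {
  s <- as_state(bn, s)
  ns <- s
  for (j in which(!bn$is_source)) {
    f <- bn$functions[[j]]
    ns[[j]] <- f$outputs[sum(s[f$in_pos] * f$weights) + 1L]
  }
  ns
}

new_attractor <- function(states, transient = NA_integer_) {
  ss <- apply(states, 1L, paste, collapse = "")
  k <- which(ss == min(ss))[1L]
  rot <- c(seq(k, length(ss)), seq_len(k - 1L))
  structure(list(transient = transient, period = nrow(states),
                 states = states, canonical = paste(ss[rot], collapse = "|")),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("Attractor: period", x$period,
      if (!is.na(x$transient)) paste("| transient", x$transient), "\n")
  ss <- apply(x$states, 1L, paste, collapse = "")
  cat(" ", paste(ss, collapse = " -> "), "-> ...\n")
  invisible(x)
}

#' Trajectory and attractor from one initial state
#'
#' Iterates [step_state()] from `s0`, recording first-visit times, until a
#' state repeats. The repeated suffix is the attractor (fixed point if its
#' period is 1, limit cycle otherwise); the steps before entering it are the
#' transient.
#'
#' @param bn a [boolean_network].
#' @param s0 initial state.
#' @return An object of class `attractor`: `transient`, `period`, `states`
#'   (period x N 0/1 matrix in trajectory order, columns named by node), and
#'   `canonical` (the cycle rotated to start at its lexicographically
#'   smallest state, serialized — the identity used for equivalence).
#' @export
find_attractor <- function(bn, s0) {
  s <- as_state(bn, s0)
  seen <- new.env(parent = emptyenv())
  traj <- list()
  t <- 0L
  repeat {
    key <- state_string(s)
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cycle <- traj[seq(hit + 1L, t)]
      states <- do.call(rbind, cycle)
      colnames(states) <- bn$nodes
      return(new_attractor(states, transient = hit))
    }
    seen[[key]] <- t
    traj[[t + 1L]] <- s
    s <- step_state(bn, s)
    t <- t + 1L
  }
}

#' Simulate a fixed-length trajectory
#'
#' @param bn a [boolean_network].
#' @param s0 initial state.
#' @param n_steps number of update steps.
#' @return `(n_steps + 1) x N` 0/1 matrix, rows `t = 0 .. n_steps`.
#' @export
trajectory <- function(bn, s0, n_steps) {
  s <- as_state(bn, s0)
  out <- matrix(NA_integer_, nrow = n_steps + 1L, ncol = length(s),
                dimnames = list(NULL, bn$nodes))
  out[1L, ] <- s
  for (t in seq_len(n_steps)) {
    s <- step_state(bn, s)
    out[t + 1L, ] <- s
  }
  out
}

#' Are two attractors equivalent?
#'
#' Equivalent means equal period and state sequences that coincide up to a
#' cyclic time offset — i.e., identical canonical forms.
#'
#' @param a,b `attractor` objects over the same node order.
#' @return Logical.
#' @export
attractors_equivalent <- function(a, b) {
  a$period == b$period && identical(a$canonical, b$canonical)
}

#' Is a node subset frozen in an attractor?
#'
#' A subset is frozen when every one of its nodes holds one constant value
#' across all states of the attractor cycle (always true for fixed points).
#'
#' @param att an `attractor`.
#' @param subset character vector of node identifiers.
#' @return Logical.
#' @export
is_frozen <- function(att, subset) {
  unknown <- setdiff(subset, colnames(att$states))
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (length(subset) == 0L) return(TRUE)
  cols <- att$states[, subset, drop = FALSE]
  all(apply(cols, 2L, function(x) all(x == x[1L])))
}

# --- exhaustive enumeration over all 2^N initial states ---------------------

# Full synchronous transition map as a 0-based integer code vector:
# state code = bits in node order read as binary, MSB = first node.
transition_table <- function(bn) {
  n <- length(bn$nodes)
  if (n > 30L) stop("state space too large to tabulate")
  codes <- 0:(2L^n - 1L)
  bit_of <- function(pos) bitwAnd(bitwShiftR(codes, n - pos), 1L)
  nxt <- integer(length(codes))
  for (j in seq_len(n)) {
    if (bn$is_source[j]) {
      b <- bit_of(j)
    } else {
      f <- bn$functions[[j]]
      idx <- integer(length(codes))
      for (a in seq_along(f$in_pos)) {
        idx <- idx + bit_of(f$in_pos[a]) * f$weights[a]
      }
      b <- f$outputs[idx + 1L]
    }
    nxt <- nxt + b * 2L^(n - j)
  }
  nxt
}

# Label every state of a functional graph with its attractor id.
# Returns attid (per state, 1-based) and the list of cycles (0-based codes,
# in transition order).
attractor_map <- function(nxt) {
  n <- length(nxt)
  attid <- integer(n)
  onpath <- logical(n)
  cycles <- list()
  path <- integer(64L)
  for (s0 in seq_len(n)) {
    if (attid[s0] > 0L) next
    cur <- s0
    len <- 0L
    while (attid[cur] == 0L && !onpath[cur]) {
      onpath[cur] <- TRUE
      len <- len + 1L
      if (len > length(path)) path <- c(path, integer(length(path)))
      path[len] <- cur
      cur <- nxt[cur] + 1L
    }
    if (attid[cur] > 0L) {
      id <- attid[cur]
    } else {
      # new cycle: from the first occurrence of cur on the path to its end
      k <- which(path[seq_len(len)] == cur)
      cycles[[length(cycles) + 1L]] <- path[seq(k, len)] - 1L
      id <- length(cycles)
    }
    idxs <- path[seq_len(len)]
    attid[idxs] <- id
    onpath[idxs] <- FALSE
  }
  list(attid = attid, cycles = cycles)
}

decode_states <- function(codes, nodes) {
  n <- length(nodes)
  m <- vapply(seq_len(n),
              function(j) bitwAnd(bitwShiftR(codes, n - j), 1L),
              integer(length(codes)))
  m <- matrix(m, nrow = length(codes), ncol = n, dimnames = list(NULL, nodes))
  m
}

#' All attractors of a Boolean network
#'
#' Enumerates every one of the `2^N` initial states (so `N` is capped),
#' tabulates the full synchronous transition map, and extracts the distinct
#' attractors with their basin sizes. Attractors are deduplicated by
#' canonical form; basin sizes sum to `2^N`.
#'
#' @param bn a [boolean_network].
#' @param max_nodes cap on `N` (default 20).
#' @return List with `attractors` (list of `attractor` objects), `basin_sizes`
#'   (integer vector, aligned), and `attid` (attractor index of each state
#'   code `0 .. 2^N - 1`).
#' @export
attractors_exhaustive <- function(bn, max_nodes = 20L) {
  n <- length(bn$nodes)
  if (n > max_nodes) {
    stop("network has ", n, " nodes ( > ", max_nodes,
         " ); exhaustive enumeration is infeasible — sample initial states instead")
  }
  nxt <- transition_table(bn)
  am <- attractor_map(nxt)
  atts <- lapply(am$cycles, function(cy) {
    new_attractor(decode_states(cy, bn$nodes))
  })
  list(attractors = atts,
       basin_sizes = tabulate(am$attid, nbins = length(atts)),
       attid = am$attid)
}

# --- Boolean function file I/O ----------------------------------------------

#' Read Boolean update functions from a TSV file
#'
#' Format, one non-source node per line:
#' `node<TAB>input1,input2,...<TAB>bits`, where `bits` is the
#' `2^k`-character 0/1 truth table indexed by the input tuple read as a
#' binary number, most significant bit = first listed input. `#` lines are
#' comments.
#'
#' @param path file to read.
#' @param net the [directed_network] the functions belong to.
#' @return A [boolean_network].
#' @export
read_boolean_functions <- function(path, net) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fns <- list()
  for (i in keep) {
    parts <- strsplit(trimws(lines[i]), "\t")[[1L]]
    if (length(parts) != 3L) {
      stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields", i, path))
    }
    fns[[parts[1L]]] <- list(inputs = strsplit(parts[2L], ",")[[1L]],
                             outputs = parts[3L])
  }
  boolean_network(net, fns)
}

#' Write Boolean update functions to a TSV file
#'
#' Inverse of [read_boolean_functions()]; the bit-indexing contract is stated
#' in the file header.
#'
#' @param bn a [boolean_network].
#' @param path output file.
#' @export
write_boolean_functions <- function(bn, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# node<TAB>inputs (comma-separated)<TAB>truth table bits",
               "# bits indexed by the input tuple read as binary, MSB = first input"),
             con)
  for (v in bn$nodes[!bn$is_source]) {
    f <- bn$functions[[v]]
    writeLines(paste(v, paste(f$inputs, collapse = ","),
                     paste(f$outputs, collapse = ""), sep = "\t"), con)
  }
  invisible(path)
}
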