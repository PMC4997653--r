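# Annotation-based group analyses: do functionally important genes
# (essential / disease / drug-target lists) avoid the NFD class, and does a
# high perturbation-sustainable probability enrich for them?

#' Load gene annotation lists
#'
#' Each file holds one gene identifier per line (`#` lines ignored);
#' duplicates are dropped. Categories may overlap.
#'
#' @param paths named character vector or list, category name -> file path
#'   (e.g. `c(essential = "ess.txt", disease = "dis.txt")`).
#' @return Named list of character sets, class `gene_annotation`.
#' @export
load_annotations <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("`paths` must be named by category")
  }
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("annotation file not found: ", p)
    x <- trimws(readLines(p, warn = FALSE))
    unique(x[x != "" & !startsWith(x, "#")])
  })
  structure(out, class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("Gene annotation:", length(x), "categories\n")
  for (nm in names(x)) cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Compare an annotation's prevalence in the NFD vs non-NFD group
#'
#' Splits the network's nodes into the NFD group and its complement, counts
#' annotated genes in each, and tests the two proportions against each other
#' (two-sided). Annotated genes absent from the network are ignored (a
#' message reports how many).
#'
#' @param cls a `node_classification` (see [classify_nodes()]).
#' @param ann a `gene_annotation`.
#' @param category which annotation category to use.
#' @param test `"z"` for the two-proportion z-test (via
#'   [stats::prop.test()] without continuity correction, whose chi-squared
#'   statistic is the squared z), or `"fisher"` for Fisher's exact test.
#' @return List of class `group_comparison`: group sizes, annotated counts,
#'   proportions, and `p_value`.
#' @export
compare_groups <- function(cls, ann, category, test = c("z", "fisher")) {
  test <- match.arg(test)
  if (!category %in% names(ann)) stop("unknown annotation category: ", category)
  genes <- cls$node
  members <- ann[[category]]
  dropped <- sum(!members %in% genes)
  if (dropped > 0L) {
    message(dropped, " annotated gene(s) not in the network were ignored")
  }
  members <- intersect(members, genes)
  nfd <- cls$is_nfd
  n1 <- sum(nfd); n2 <- sum(!nfd)
  if (n1 == 0L || n2 == 0L) stop("empty group: NFD split is degenerate")
  k1 <- sum(genes[nfd] %in% members)
  k2 <- sum(genes[!nfd] %in% members)
  p_value <- if (test == "z") {
    if (k1 + k2 == 0L || k1 + k2 == n1 + n2) 1 else
      suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                        correct = FALSE)$p.value)
  } else {
    stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L))$p.value
  }
  structure(list(category = category, test = test,
                 n_nfd = n1, n_non_nfd = n2, k_nfd = k1, k_non_nfd = k2,
                 prop_nfd = k1 / n1, prop_non_nfd = k2 / n2,
                 p_value = p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("'%s' genes | NFD group: %d/%d = %.3f | non-NFD: %d/%d = %.3f | p = %.3g\n",
              x$category, x$k_nfd, x$n_nfd, x$prop_nfd,
              x$k_non_nfd, x$n_non_nfd, x$prop_non_nfd, x$p_value))
  invisible(x)
}

#' Annotation proportions among high-sustainability candidates
#'
#' For each threshold `beta`, the candidate set is the genes whose
#' perturbation-sustainable probability is at least `beta`; the curve gives
#' the candidate count and, per category, the annotated proportion within
#' it. The candidate count is non-increasing in `beta`.
#'
#' @param scores named numeric vector from [gamma_scores()].
#' @param ann a `gene_annotation`.
#' @param betas ascending thresholds in `[0, 1]`; default: the sorted
#'   distinct observed scores (optionally truncated at `max_beta`).
#' @param max_beta optional upper truncation for the default grid.
#' @return Data frame of class `sweep_curve`: `beta`, `n_candidates`, one
#'   proportion column per category (`NA` when the candidate set is empty).
#' @export
threshold_sweep <- function(scores, ann, betas = NULL, max_beta = NULL) {
  if (is.null(betas)) {
    betas <- sort(unique(unname(scores)))
    if (!is.null(max_beta)) betas <- betas[betas <= max_beta]
  }
  if (any(betas < 0 | betas > 1)) stop("thresholds must lie in [0, 1]")
  if (is.unsorted(betas)) stop("`betas` must be ascending")
  rows <- lapply(betas, function(b) {
    cand <- names(scores)[scores >= b]
    props <- vapply(ann, function(set) {
      if (length(cand) == 0L) NA_real_ else mean(cand %in% set)
    }, numeric(1))
    c(beta = b, n_candidates = length(cand), props)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("sweep_curve", "data.frame")
  out
}

#' Rewired-network null distribution of the NFD group difference
#'
#' Generates `n_random` degree-preserving rewirings of the network,
#' reclassifies each, and recomputes the annotated-proportion difference
#' (non-NFD minus NFD) per category, keeping annotations fixed to the nodes.
#' The observed difference's empirical percentile among the replicates says
#' whether the real network's association exceeds what degree structure
#' alone produces.
#'
#' @param net a [directed_network].
#' @param ann a `gene_annotation`.
#' @param n_random number of rewired replicates.
#' @param seed master seed.
#' @param n_swaps swaps per replicate (default `10 * n_edges`).
#' @return List of class `rewired_control`: `null` (data frame `replicate`,
#'   `category`, `diff`; `diff` is `NA` when a replicate's rewiring left one
#'   group empty), `observed` (per-category difference in the real
#'   network), `percentile` (fraction of replicates with `diff` below the
#'   observed, per category; `NA` when `n_random = 0`).
#' @export
rewired_control <- function(net, ann, n_random, seed = NULL, n_swaps = NULL) {
  obs_cls <- classify_nodes(net)
  observed <- vapply(names(ann), function(cat) {
    g <- suppressMessages(compare_groups(obs_cls, ann, cat))
    g$prop_non_nfd - g$prop_nfd
  }, numeric(1))
  seeds <- if (n_random > 0L) derive_seeds(seed, n_random) else integer()
  rows <- list()
  for (i in seq_len(n_random)) {
    rw <- rewire_preserving_degrees(net, n_swaps = n_swaps, seed = seeds[i])
    cls <- classify_nodes(rw)
    for (cat in names(ann)) {
      # a replicate may lose every cycle, degenerating the split; record NA
      d <- tryCatch(
        {
          g <- suppressMessages(compare_groups(cls, ann, cat))
          g$prop_non_nfd - g$prop_nfd
        },
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, category = cat, diff = d, stringsAsFactors = FALSE)
    }
  }
  null <- do.call(rbind, rows) %||%
    data.frame(replicate = integer(), category = character(), diff = numeric())
  percentile <- vapply(names(ann), function(cat) {
    d <- null$diff[null$category == cat & !is.na(null$diff)]
    if (length(d) == 0L) NA_real_ else mean(d < observed[[cat]])
  }, numeric(1))
  structure(list(null = null, observed = observed, percentile = percentile,
                 n_random = n_random),
            class = "rewired_control")
}

#' @export
print.rewired_control <- function(x, ...) {
  cat("Degree-preserving rewired control:", x$n_random, "replicates\n")
  for (cat in names(x$observed)) {
    cat(sprintf("  %s: observed diff %.3f, percentile %.3f\n",
                cat, x$observed[[cat]], x$percentile[[cat]]))
  }
  invisible(x)
}
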