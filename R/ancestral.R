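#' Ancestral gene-order types by parsimony
#'
#' Assigns a gene-order type to every node of a time tree by parsimony
#' over the observed tip types. \code{method = "fitch"} is unordered
#' (unit-cost) parsimony; \code{method = "sankoff"} minimizes total cost
#' under a supplied cost matrix (typically a pairwise RS matrix, see
#' [rs_matrix()]), with the cost of changing from parent state s to child
#' state t read as \code{costs[t, s]} (type t scored against reference s).
#' Both are computed exactly by dynamic programming over the tree.
#'
#' The root state can be forced to the type observed at a designated
#' outgroup tip (the outgroup-rooted convention for ancestral gene
#' orders); otherwise the cheapest root state is chosen. During top-down
#' resolution, ties are broken toward the parent's state, then toward the
#' lowest type id.
#'
#' @param tree a [time_tree()] with every tip mapped.
#' @param method \code{"fitch"} or \code{"sankoff"}.
#' @param costs square cost matrix with type ids as dimnames; required
#'   for \code{"sankoff"} and it must cover all observed types. Ignored
#'   for \code{"fitch"}.
#' @param outgroup optional tip label whose observed type the root is
#'   forced to.
#' @return The \code{time_tree} with \code{node_types} filled: a named
#'   integer vector over all nodes (ape numbering, tips first), with
#'   attribute \code{parsimony_cost} (the minimum total cost conditional
#'   on the root constraint).
#' @export
infer_ancestral_types <- function(tree, method = c("fitch", "sankoff"),
                                  costs = NULL, outgroup = NULL) {
  method <- match.arg(method)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  types <- tree$tip_types
  if (any(is.na(types))) {
    stop("unmapped tips: ",
         paste(phy$tip.label[is.na(types)], collapse = ", "))
  }
  states <- sort(unique(as.integer(types)))
  S <- length(states)
  if (method == "sankoff") {
    if (is.null(costs)) stop("sankoff requires a cost matrix")
    miss <- setdiff(as.character(states), rownames(costs))
    if (length(miss) > 0) {
      stop("cost matrix does not cover types: ", paste(miss, collapse = ", "))
    }
    cost <- costs[as.character(states), as.character(states), drop = FALSE]
    cost <- matrix(as.numeric(cost), S, S,
                   dimnames = list(as.character(states),
                                   as.character(states)))
  } else {
    cost <- matrix(1, S, S); diag(cost) <- 0
    dimnames(cost) <- list(as.character(states), as.character(states))
  }
  # cost of parent state s -> child state t is cost[t, s]
  down <- matrix(Inf, nn, S)       # min cost of subtree given node state
  tipidx <- match(as.integer(types[phy$tip.label]), states)
  for (i in seq_len(ntip)) down[i, ] <- ifelse(seq_len(S) == tipidx[i], 0, Inf)
  down[(ntip + 1):nn, ] <- 0
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    # add min over child state t of cost[t, s] + down[ch, t], per s
    inc <- apply(cost + down[ch, ], 2, min)   # cost[t, s] varies over rows t
    down[p, ] <- down[p, ] + inc
  }
  root <- ntip + 1L
  assign <- rep(NA_integer_, nn)
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label) stop("unknown outgroup tip: ", outgroup)
    root_state <- match(as.integer(types[outgroup]), states)
  } else {
    root_state <- which.min(down[root, ])     # lowest type id on ties
  }
  assign[root] <- root_state
  for (k in rev(seq_len(nrow(po)))) {        # preorder
    p <- po[k, 1]; ch <- po[k, 2]
    s <- assign[p]
    tot <- cost[, s] + down[ch, ]
    best <- min(tot)
    cand <- which(tot <= best + 1e-9)
    assign[ch] <- if (s %in% cand) s else cand[1]
  }
  out <- states[assign]
  names(out) <- c(phy$tip.label, as.character((ntip + 1):nn))
  total <- down[root, root_state]
  attr(out, "parsimony_cost") <- total
  tree$node_types <- out
  tree
}

#' Minimum parsimony cost by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every assignment of states to internal
#' nodes and returns the minimum total cost, optionally conditional on a
#' fixed root state. Exponential; intended for small trees in validation.
#'
#' @inheritParams infer_ancestral_types
#' @param root_state optional forced root type id.
#' @return list: \code{cost} (minimum total), \code{assignment} (one
#'   optimal named vector over all nodes).
#' @export
exhaustive_parsimony <- function(tree, costs = NULL, root_state = NULL) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  types <- as.integer(tree$tip_types[phy$tip.label])
  states <- sort(unique(types))
  S <- length(states)
  if (is.null(costs)) {
    costs <- matrix(1, S, S); diag(costs) <- 0
    dimnames(costs) <- list(as.character(states), as.character(states))
  }
  edge <- phy$edge
  internal <- (ntip + 1):nn
  best <- Inf; best_assign <- NULL
  grid <- rep(list(states), length(internal))
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    full <- c(types, as.integer(combos[r, ]))
    if (!is.null(root_state) && full[ntip + 1] != root_state) next
    tot <- 0
    for (k in seq_len(nrow(edge))) {
      s <- full[edge[k, 1]]; t <- full[edge[k, 2]]
      tot <- tot + costs[as.character(t), as.character(s)]
    }
    if (tot < best) { best <- tot; best_assign <- full }
  }
  names(best_assign) <- c(phy$tip.label, as.character(internal))
  list(cost = best, assignment = best_assign)
}
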