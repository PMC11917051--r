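#' Time-calibrated tree with tip gene-order types
#'
#' Couples an ultrametric \code{ape::phylo} (branch lengths in Myr) with a
#' tip-to-type map and optional per-tip taxon labels. Node ages are
#' measured back from the present (tips at 0).
#'
#' @param phylo rooted \code{phylo} with branch lengths in Myr.
#' @param tip_types named integer vector: type id per tip label. Every
#'   tip must be mapped unless listed in \code{exclude}.
#' @param taxon optional named character vector: taxon (e.g. family) per
#'   tip label.
#' @param exclude tips deliberately left unmapped (they are dropped).
#' @return Object of class \code{time_tree}: list with \code{phylo},
#'   \code{tip_types}, \code{taxon}, \code{node_types} (filled by
#'   [infer_ancestral_types()]).
#' @export
time_tree <- function(phylo, tip_types, taxon = NULL, exclude = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape 'phylo' tree")
  if (!is.null(exclude) && length(exclude) > 0) {
    phylo <- ape::drop.tip(phylo, exclude)
  }
  unmapped <- setdiff(phylo$tip.label, names(tip_types))
  if (length(unmapped) > 0) {
    stop("unmapped tips: ", paste(unmapped, collapse = ", "))
  }
  structure(list(phylo = phylo,
                 tip_types = tip_types[phylo$tip.label],
                 taxon = if (is.null(taxon)) NULL else taxon[phylo$tip.label],
                 node_types = NULL),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree> %d tips, root age %.2f Myr, %d types%s\n",
              ape::Ntip(x$phylo), max(node_ages(x)),
              length(unique(x$tip_types)),
              if (is.null(x$node_types)) "" else ", ancestral types inferred"))
  invisible(x)
}

#' Node ages of a time tree
#'
#' @param tree a \code{time_tree} or \code{phylo}.
#' @return Numeric vector of ages (Myr before present) indexed by ape node
#'   number (tips first).
#' @export
node_ages <- function(tree) {
  phy <- if (inherits(tree, "time_tree")) tree$phylo else tree
  d <- ape::node.depth.edgelength(phy)
  round(max(d) - d, 9)
}

# taxon label per node: a tip's own taxon; for internal nodes the shared
# taxon of all descendant tips, else "ancestral"
node_taxa <- function(tree) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  out <- rep("ancestral", nn)
  if (is.null(tree$taxon)) return(out)
  out[seq_len(ntip)] <- tree$taxon[phy$tip.label]
  po <- ape::reorder.phylo(phy, "postorder")$edge
  acc <- vector("list", nn)
  for (i in seq_len(ntip)) acc[[i]] <- out[i]
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1]; ch <- po[k, 2]
    acc[[p]] <- unique(c(acc[[p]], acc[[ch]]))
  }
  for (v in (ntip + 1):nn) {
    if (length(acc[[v]]) == 1) out[v] <- acc[[v]]
  }
  out
}

#' Prune and graft taxa on a time tree
#'
#' Pruning removes all tips of the named taxa (or the named tips) with
#' branch fusion, preserving the ages of remaining nodes. Grafting
#' attaches new tips at stated ages: each row of \code{graft} gives the
#' new tip \code{label}, the existing \code{attach_to} tip or node label,
#' the \code{attach_age} (Myr) at which the new branch splits off the
#' edge above \code{attach_to}, and optionally \code{taxon} and
#' \code{type}.
#'
#' @param tree a \code{time_tree}.
#' @param prune character vector of taxa or tip labels to remove.
#' @param graft optional data.frame (see above).
#' @return The edited \code{time_tree}.
#' @export
edit_tree <- function(tree, prune = NULL, graft = NULL) {
  phy <- tree$phylo
  tip_types <- tree$tip_types
  taxon <- tree$taxon
  if (!is.null(graft) && nrow(graft) > 0) {
    for (i in seq_len(nrow(graft))) {
      g <- graft[i, ]
      if (!g$attach_to %in% phy$tip.label) {
        stop("unknown taxon or tip: ", g$attach_to)
      }
      w <- match(g$attach_to, phy$tip.label)
      ages <- node_ages(phy)
      parent <- phy$edge[phy$edge[, 2] == w, 1]
      if (g$attach_age >= ages[parent] || g$attach_age <= ages[w]) {
        stop(sprintf("attach_age %.2f outside the edge above '%s'",
                     g$attach_age, g$attach_to))
      }
      sub <- ape::read.tree(text = sprintf("(%s:%f);", g$label, g$attach_age))
      phy <- ape::bind.tree(phy, sub, where = w,
                            position = g$attach_age - ages[w])
      tip_types[g$label] <- if ("type" %in% names(g)) g$type else NA_integer_
      if (!is.null(taxon)) {
        taxon[g$label] <- if ("taxon" %in% names(g)) g$taxon else NA_character_
      }
    }
  }
  if (!is.null(prune) && length(prune) > 0) {
    by_taxon <- if (is.null(taxon)) character(0) else
      phy$tip.label[taxon[phy$tip.label] %in% prune]
    by_label <- intersect(prune, phy$tip.label)
    drop <- union(by_taxon, by_label)
    unknown <- setdiff(prune, union(prune[prune %in% taxon], by_label))
    if (length(unknown) > 0) stop("unknown taxon or tip: ", unknown[1])
    if (length(drop) >= ape::Ntip(phy)) stop("cannot prune every tip")
    phy <- ape::drop.tip(phy, drop)
  }
  time_tree(phy, tip_types, taxon)
}

#' Read a time tree from newick plus a tip-map CSV
#'
#' The tip map has columns \code{tip}, \code{type_id} and optionally
#' \code{taxon}.
#'
#' @param newick_path newick file (branch lengths in Myr).
#' @param tipmap_path CSV path.
#' @return A \code{time_tree}.
#' @export
read_time_tree <- function(newick_path, tipmap_path) {
  phy <- ape::read.tree(newick_path)
  tm <- utils::read.csv(tipmap_path, stringsAsFactors = FALSE)
  time_tree(phy,
            tip_types = stats::setNames(as.integer(tm$type_id), tm$tip),
            taxon = if ("taxon" %in% names(tm)) {
              stats::setNames(tm$taxon, tm$tip)
            } else NULL)
}

#' @rdname read_time_tree
#' @param tree a \code{time_tree}.
#' @param dir output directory.
#' @param stem file-name stem.
#' @export
write_time_tree <- function(tree, dir, stem = "timetree") {
  nwk <- file.path(dir, paste0(stem, ".nwk"))
  csv <- file.path(dir, paste0(stem, "_tips.csv"))
  ape::write.tree(tree$phylo, nwk)
  tm <- data.frame(tip = tree$phylo$tip.label,
                   type_id = as.integer(tree$tip_types),
                   stringsAsFactors = FALSE)
  if (!is.null(tree$taxon)) tm$taxon <- tree$taxon[tm$tip]
  utils::write.csv(tm, csv, row.names = FALSE)
  invisible(c(newick = nwk, tipmap = csv))
}
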