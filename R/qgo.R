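#' Aligned-scheme (breakpoint-partitioned) rearrangement events
#'
#' The aligned scheme scores each gene directly from a homology alignment
#' of gene orders. The circular genome is first divided into two intervals
#' at predefined breakpoints (see [split_intervals()]); genes within each
#' interval are then aligned against the reference's columns and each gene
#' is classified as one of:
#' \describe{
#'   \item{unchanged}{same interval, same relative order, same strand;}
#'   \item{transposed}{interval changed, or relative order within the
#'     interval changed;}
#'   \item{inverted}{strand changed;}
#'   \item{transposed+inverted}{both;}
#'   \item{duplicated}{query gene with no reference column (gained copy);}
#'   \item{lost}{reference column with no query gene (reported on the
#'     reference token).}
#' }
#' "Relative order changed" is decided conservatively: a matched gene is
#' order-changed unless it belongs to \emph{every} maximum-length
#' increasing subsequence of reference ranks (taken in query order within
#' its interval). This marks both sides of a block swap as transposed and
#' makes the classification symmetric in query and reference for
#' content-equal orders.
#'
#' @name qgo
NULL

#' Event-class weights for the aligned scheme
#'
#' @param transposition,inversion,duplication,loss positive weights per
#'   event class. A \code{transposed+inverted} gene scores
#'   \code{transposition + inversion}.
#' @return Named numeric vector.
#' @export
event_weights <- function(transposition = 1, inversion = 1,
                          duplication = 1, loss = 1) {
  w <- c(transposition = transposition, inversion = inversion,
         duplication = duplication, loss = loss)
  if (any(w <= 0)) stop("all event weights must be > 0")
  w
}

# membership of each element of a sequence of distinct numbers in
# some / every maximum-length increasing subsequence (O(n^2))
lis_membership <- function(a) {
  n <- length(a)
  if (n == 0) return(list(some = logical(0), every = logical(0)))
  f <- rep(1L, n); g <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a[j] < a[i] && f[j] + 1L > f[i]) f[i] <- f[j] + 1L
    }
  }
  for (i in rev(seq_len(n))) {
    for (j in if (i < n) (i + 1L):n else integer(0)) {
      if (a[j] > a[i] && g[j] + 1L > g[i]) g[i] <- g[j] + 1L
    }
  }
  L <- max(f)
  some <- (f + g - 1L) == L
  every <- some & vapply(seq_len(n), function(i) {
    some[i] && sum(some & f == f[i]) == 1L
  }, logical(1))
  list(some = some, every = every)
}

# interval label per gene index for a canonical order
interval_labels <- function(order, breakpoints) {
  iv <- split_intervals(order, breakpoints)
  lab <- character(length(order))
  lab[iv$A] <- "A"; lab[iv$B] <- "B"
  # positions in linear reading order A then B
  pos <- integer(length(order))
  pos[c(iv$A, iv$B)] <- seq_along(pos)
  list(label = lab, pos = pos, linear = c(iv$A, iv$B))
}

# pairwise alignment of query genes onto reference columns.
# Copies of a token are paired within the same interval first, then across
# intervals, by nearest relative rank; ties favour the earliest reference
# column. Returns matched/gained rows per query gene plus lost ref columns.
align_pair <- function(query, reference, breakpoints = default_breakpoints()) {
  if (!query$canonical) query <- canonicalize(query)
  if (!reference$canonical) reference <- canonicalize(reference)
  qi <- interval_labels(query, breakpoints)
  ri <- interval_labels(reference, breakpoints)
  nq <- length(query); nr <- length(reference)
  q_rel <- qi$pos / nq
  r_rel <- ri$pos / nr
  match_col <- rep(NA_integer_, nq)
  r_free <- rep(TRUE, nr)
  pair_up <- function(q_idx, r_idx) {
    # greedy nearest-relative-rank matching, earliest ref column on ties
    while (length(q_idx) > 0 && length(r_idx) > 0) {
      d <- outer(q_rel[q_idx], r_rel[r_idx], function(a, b) abs(a - b))
      best <- which(d == min(d), arr.ind = TRUE)
      best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
      match_col[q_idx[best[1]]] <<- r_idx[best[2]]
      r_free[r_idx[best[2]]] <<- FALSE
      q_idx <- q_idx[-best[1]]; r_idx <- r_idx[-best[2]]
    }
  }
  for (tok in unique(query$token)) {
    for (ivl in c("A", "B")) {               # same-interval pass
      pair_up(which(query$token == tok & qi$label == ivl &
                      is.na(match_col)),
              which(reference$token == tok & ri$label == ivl & r_free))
    }
  }
  for (tok in unique(query$token)) {          # cross-interval pass
    pair_up(which(query$token == tok & is.na(match_col)),
            which(reference$token == tok & r_free))
  }
  genes <- data.frame(
    q_idx = seq_len(nq), token = query$token, copy = query$copy,
    strand_q = query$strand, interval_q = qi$label, pos_q = qi$pos,
    ref_col = match_col,
    interval_r = ifelse(is.na(match_col), NA, ri$label[match_col]),
    ref_pos = ifelse(is.na(match_col), NA, ri$pos[match_col]),
    strand_r = ifelse(is.na(match_col), NA, reference$strand[match_col]),
    stringsAsFactors = FALSE)
  lost <- data.frame(
    ref_col = which(r_free), token = reference$token[r_free],
    copy = reference$copy[r_free], strand_r = reference$strand[r_free],
    interval_r = ri$label[r_free], stringsAsFactors = FALSE)
  list(genes = genes, lost = lost, query = query, reference = reference)
}

#' Classify per-gene rearrangement events under the aligned scheme
#'
#' @param query,reference [gene_order()] objects.
#' @param alignment optional precomputed pair alignment (from
#'   [qgo_align()] or internal); computed automatically when \code{NULL}.
#' @param weights [event_weights()].
#' @param breakpoints passed to [split_intervals()].
#' @return data.frame with one row per query gene plus one row per lost
#'   reference column: \code{token}, \code{copy}, \code{event},
#'   \code{score}. Attribute \code{rs} carries the summed score.
#' @export
qgo_gene_events <- function(query, reference, alignment = NULL,
                            weights = event_weights(),
                            breakpoints = default_breakpoints()) {
  if (is.null(alignment)) {
    alignment <- align_pair(query, reference, breakpoints)
  }
  g <- alignment$genes
  matched <- !is.na(g$ref_col)
  interval_moved <- matched & (g$interval_q != g$interval_r)
  order_moved <- rep(FALSE, nrow(g))
  for (ivl in c("A", "B")) {
    idx <- which(matched & !interval_moved & g$interval_q == ivl)
    if (length(idx) < 2) next
    idx <- idx[order(g$pos_q[idx])]
    memb <- lis_membership(g$ref_pos[idx])
    order_moved[idx[!memb$every]] <- TRUE
  }
  transposed <- interval_moved | order_moved
  inverted <- matched & (g$strand_q != g$strand_r)
  event <- rep("unchanged", nrow(g))
  event[transposed] <- "transposed"
  event[inverted & !transposed] <- "inverted"
  event[inverted & transposed] <- "transposed+inverted"
  event[!matched] <- "duplicated"
  score <- numeric(nrow(g))
  score[event == "transposed"] <- weights[["transposition"]]
  score[event == "inverted"] <- weights[["inversion"]]
  score[event == "transposed+inverted"] <-
    weights[["transposition"]] + weights[["inversion"]]
  score[event == "duplicated"] <- weights[["duplication"]]
  out <- data.frame(token = g$token, copy = g$copy, event = event,
                    score = score, stringsAsFactors = FALSE)
  if (nrow(alignment$lost) > 0) {
    out <- rbind(out, data.frame(
      token = alignment$lost$token, copy = alignment$lost$copy,
      event = "lost", score = weights[["loss"]], stringsAsFactors = FALSE))
  }
  attr(out, "rs") <- sum(out$score)
  out
}

#' @rdname qgo_gene_events
#' @return \code{qgo_rs}: the summed event score of the comparison.
#' @export
qgo_rs <- function(query, reference, weights = event_weights(),
                   breakpoints = default_breakpoints()) {
  sum(qgo_gene_events(query, reference, weights = weights,
                      breakpoints = breakpoints)$score)
}

#' Interval alignment of all types against a reference
#'
#' Aligns every type's genes, within each breakpoint-delimited interval,
#' onto the columns of a reference type. With \code{manual} supplied the
#' table is validated (every gene of every type assigned to exactly one
#' column) and used verbatim; otherwise the automatic aligner of
#' [qgo_gene_events()] assigns each gene to the reference column with the
#' same token and nearest relative rank, earliest reference column winning
#' ties. Gained copies receive gap-column labels \code{gain.<k>}.
#'
#' @param types list of \code{rearrangement_type} (see [dedupe_types()]).
#' @param breakpoints see [split_intervals()].
#' @param reference_id type id of the reference; default the first type.
#' @param manual optional manual alignment table, a data.frame with
#'   columns \code{type_id}, \code{interval}, \code{column}, \code{token},
#'   \code{strand}, \code{copy_index} (the TSV layout of
#'   [read_alignment()]).
#' @return Object of class \code{qgo_alignment}: list with \code{table}
#'   (the long-format alignment), \code{reference_id}, \code{breakpoints},
#'   \code{pairs} (per-type pair alignments, \code{NULL} when manual).
#' @export
qgo_align <- function(types, breakpoints = default_breakpoints(),
                      reference_id = types[[1]]$type_id, manual = NULL) {
  ids <- vapply(types, function(t) t$type_id, integer(1))
  ref <- types[[match(reference_id, ids)]]$order
  if (!is.null(manual)) {
    validate_manual_alignment(manual, types)
    return(structure(list(table = manual, reference_id = reference_id,
                          breakpoints = breakpoints, pairs = NULL),
                     class = "qgo_alignment"))
  }
  rows <- list()
  pairs <- list()
  for (t in types) {
    pa <- align_pair(t$order, ref, breakpoints)
    pairs[[as.character(t$type_id)]] <- pa
    g <- pa$genes
    gain_k <- cumsum(is.na(g$ref_col))
    col <- ifelse(is.na(g$ref_col),
                  paste0("gain.", gain_k),
                  paste0(g$interval_r, g$ref_pos))
    rows[[length(rows) + 1L]] <- data.frame(
      type_id = t$type_id, interval = g$interval_q, column = col,
      token = g$token, strand = ifelse(g$strand_q < 0, "-", "+"),
      copy_index = g$copy, stringsAsFactors = FALSE)[order(g$pos_q), ]
  }
  structure(list(table = do.call(rbind, rows), reference_id = reference_id,
                 breakpoints = breakpoints, pairs = pairs),
            class = "qgo_alignment")
}

validate_manual_alignment <- function(manual, types) {
  need <- c("type_id", "interval", "column", "token", "strand", "copy_index")
  if (!all(need %in% names(manual))) {
    stop("alignment-incomplete: manual table lacks columns ",
         paste(setdiff(need, names(manual)), collapse = ", "))
  }
  for (t in types) {
    sub <- manual[manual$type_id == t$type_id, ]
    have <- paste(sub$token, sub$copy_index)
    want <- paste(t$order$token, t$order$copy)
    miss <- setdiff(want, have)
    if (length(miss) > 0) {
      stop(sprintf("alignment-incomplete: type %d gene %s not assigned",
                   t$type_id, miss[1]))
    }
    if (anyDuplicated(have)) {
      dup <- have[duplicated(have)][1]
      stop(sprintf("alignment-incomplete: type %d gene %s assigned twice",
                   t$type_id, dup))
    }
  }
  invisible(TRUE)
}

#' Read and write interval-alignment tables
#'
#' TSV with columns \code{type_id}, \code{interval}, \code{column},
#' \code{token}, \code{strand}, \code{copy_index} - the offline stand-in
#' for a manually curated interval alignment.
#'
#' @param path file path.
#' @export
read_alignment <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_alignment
#' @param alignment a \code{qgo_alignment} or its \code{table}.
#' @export
write_alignment <- function(alignment, path) {
  tab <- if (inherits(alignment, "qgo_alignment")) alignment$table else alignment
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
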