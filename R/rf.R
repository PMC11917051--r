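#' Accumulate per-gene rearrangement frequency (RF) over a dataset
#'
#' RF of a gene token is the per-gene rearrangement score summed over the
#' gene rearrangement types of a dataset, relative to a chosen reference
#' type. By default each type contributes once regardless of how many
#' samples carry it (the convention behind dataset-wide RF tables over
#' deduplicated types); \code{per_sample = TRUE} weights each type by its
#' member count instead. Scores from all copies of a token are pooled
#' under that token; under the aligned scheme, lost genes contribute to
#' the reference token's RF.
#'
#' @param types list of \code{rearrangement_type} (see [dedupe_types()]).
#' @param reference_id type id of the reference type (it must be in
#'   \code{types}); the reference contributes zero.
#' @param scheme \code{"qmgr"} (alignment-free neighbor scheme) or
#'   \code{"qgo"} (breakpoint-partitioned aligned scheme).
#' @param weights [event_weights()], aligned scheme only.
#' @param breakpoints see [split_intervals()], aligned scheme only.
#' @param per_sample weight types by member count.
#' @param by_taxon optional character rank (\code{"family"},
#'   \code{"genus"}, \code{"species"}): also return a long per-taxon
#'   breakdown computed by filtering types carrying each taxon.
#' @return data.frame \code{token}, \code{rf}, sorted by decreasing RF;
#'   with \code{by_taxon}, attribute \code{per_taxon} holds the long
#'   breakdown (\code{taxon}, \code{token}, \code{rf}).
#' @export
accumulate_rf <- function(types, reference_id, scheme = c("qmgr", "qgo"),
                          weights = event_weights(),
                          breakpoints = default_breakpoints(),
                          per_sample = FALSE, by_taxon = NULL) {
  scheme <- match.arg(scheme)
  ids <- vapply(types, function(t) t$type_id, integer(1))
  if (!reference_id %in% ids) stop("reference type not present in types")
  ref <- types[[match(reference_id, ids)]]$order
  per_type <- lapply(types, function(t) {
    sc <- switch(scheme,
      qmgr = {
        s <- qmgr_gene_scores(t$order, ref)
        data.frame(token = s$token, score = s$score)
      },
      qgo = {
        e <- qgo_gene_events(t$order, ref, weights = weights,
                             breakpoints = breakpoints)
        data.frame(token = e$token, score = e$score)
      })
    w <- if (per_sample) t$count else 1L
    sc$score <- sc$score * w
    sc
  })
  pool <- function(idx) {
    all_sc <- do.call(rbind, per_type[idx])
    agg <- stats::aggregate(score ~ token, all_sc, sum)
    tokens <- setdiff(mito_vocabulary(), "extra")
    rf <- stats::setNames(rep(0, length(tokens)), tokens)
    known <- agg$token %in% tokens
    rf[agg$token[known]] <- agg$score[known]
    if (any(!known)) rf <- c(rf, stats::setNames(agg$score[!known],
                                                 agg$token[!known]))
    out <- data.frame(token = names(rf), rf = as.numeric(rf),
                      stringsAsFactors = FALSE)
    out[order(-out$rf, out$token), ]
  }
  res <- pool(seq_along(types))
  rownames(res) <- NULL
  if (!is.null(by_taxon)) {
    taxa <- unique(unlist(lapply(types, function(t) {
      if (is.null(t$taxa) || !by_taxon %in% names(t$taxa)) NULL
      else t$taxa[[by_taxon]]
    })))
    per_taxon <- do.call(rbind, lapply(taxa, function(tx) {
      idx <- which(vapply(types, function(t) {
        !is.null(t$taxa) && by_taxon %in% names(t$taxa) &&
          tx %in% t$taxa[[by_taxon]]
      }, logical(1)))
      cbind(taxon = tx, pool(idx))
    }))
    attr(res, "per_taxon") <- per_taxon
  }
  res
}

#' All-vs-all rearrangement score matrix across types
#'
#' Entry (i, j) is the rearrangement score of type i measured against type
#' j as reference, under the chosen scheme. The diagonal is zero; under
#' the neighbor scheme the matrix is symmetric whenever gene content is
#' equal.
#'
#' @inheritParams accumulate_rf
#' @return Square numeric matrix of class \code{rs_matrix} with type ids
#'   as dimnames.
#' @export
rs_matrix <- function(types, scheme = c("qmgr", "qgo"),
                      weights = event_weights(),
                      breakpoints = default_breakpoints()) {
  scheme <- match.arg(scheme)
  if (length(types) == 0) stop("at least one type required")
  ids <- vapply(types, function(t) t$type_id, integer(1))
  n <- length(types)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      m[i, j] <- switch(scheme,
        qmgr = qmgr_rs(types[[i]]$order, types[[j]]$order),
        qgo = qgo_rs(types[[i]]$order, types[[j]]$order,
                     weights = weights, breakpoints = breakpoints))
    }
  }
  class(m) <- c("rs_matrix", class(m))
  m
}

#' Write RF tables and RS matrices as CSV
#'
#' @param x an RF table (data.frame) or \code{rs_matrix}.
#' @param path file path.
#' @export
write_rf_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rf_table
#' @export
write_rs_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}
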