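#' Neighbor-scheme (alignment-free) rearrangement scores
#'
#' The alignment-free scheme quantifies rearrangement per gene by
#' accumulating changes in its two nearest neighbors: for each gene of the
#' query, the score is the number of its two strand-signed adjacencies
#' (predecessor and successor around the circle) that are absent from the
#' reference's adjacency set (0, 1 or 2). Adjacencies are compared by
#' signed token, ignoring copy index, so duplicated copies are scored
#' against every placement of that token in the reference. A gene with no
#' counterpart in the reference necessarily scores 2.
#'
#' The per-genome rearrangement score (RS) is the sum of the per-gene
#' scores; for gene content-equal orders it is symmetric in query and
#' reference.
#'
#' @param query,reference [gene_order()] objects (canonicalized
#'   internally).
#' @return \code{qmgr_gene_scores}: data.frame with columns \code{token},
#'   \code{copy}, \code{strand}, \code{score} (0-2) and a coarse
#'   \code{event} classification (\code{unchanged}, \code{inverted},
#'   \code{duplicated}, \code{transposed}).
#' @export
qmgr_gene_scores <- function(query, reference) {
  if (!query$canonical) query <- canonicalize(query)
  if (!reference$canonical) reference <- canonicalize(reference)
  ref_keys <- unique(adjacencies(reference)$key)
  st <- signed_tokens(query)
  n <- length(query)
  prv <- if (n == 1L) 1L else c(n, seq_len(n - 1L))
  nxt <- if (n == 1L) 1L else c(2:n, 1L)
  pred_key <- paste0(st[prv], ">", st)
  succ_key <- paste0(st, ">", st[nxt])
  score <- as.integer(!(pred_key %in% ref_keys)) +
    as.integer(!(succ_key %in% ref_keys))
  ref_signed <- signed_tokens(reference)
  ref_counts <- table(reference$token)
  qry_counts <- table(query$token)
  event <- rep("unchanged", n)
  moved <- score > 0
  event[moved] <- "transposed"
  extra <- qry_counts[query$token] > ifelse(
    query$token %in% names(ref_counts), ref_counts[query$token], 0L)
  event[moved & extra] <- "duplicated"
  inv <- !(st %in% ref_signed) & (query$token %in% reference$token)
  event[moved & inv] <- "inverted"
  data.frame(token = query$token, copy = query$copy, strand = query$strand,
             score = score, event = event, stringsAsFactors = FALSE)
}

#' @rdname qmgr_gene_scores
#' @return \code{qmgr_rs}: a single non-negative number, the genome
#'   rearrangement score.
#' @export
qmgr_rs <- function(query, reference) {
  sum(qmgr_gene_scores(query, reference)$score)
}
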