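#' Circular, strand-aware gene orders
#'
#' A \code{gene_order} represents the gene arrangement of one mitogenome as
#' a circular, strand-signed sequence of gene labels. Repeated copies of a
#' token are distinguished by a copy index assigned in encounter order from
#' the anchor during canonicalization. Two orders are considered equal when
#' their canonical serializations (see [format.gene_order()]) are identical;
#' by construction this makes equality invariant to rotation and to full
#' reflection with strand flip.
#'
#' @param tokens character vector of signed tokens in clockwise order, e.g.
#'   \code{c("trnF", "rrnS", "-trnQ", "CR", "CR.2")}. A leading \code{"-"}
#'   marks the minus strand; a \code{".n"} suffix is an explicit copy index
#'   (recomputed at canonicalization).
#' @param sample_id free-text sample identifier.
#' @param taxon optional character vector \code{c(family, genus, species)}.
#' @return An object of class \code{gene_order} with fields
#'   \code{token}, \code{strand} (+1/-1), \code{copy}, \code{sample_id},
#'   \code{taxon} and a \code{canonical} flag.
#' @export
gene_order <- function(tokens, sample_id = "", taxon = NULL) {
  if (length(tokens) == 0) stop("empty-order: a gene order must be non-empty")
  strand <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  tok <- sub("^-", "", tokens)
  copy <- rep(1L, length(tok))
  has_copy <- grepl("\\.[0-9]+$", tok)
  copy[has_copy] <- as.integer(sub("^.*\\.", "", tok[has_copy]))
  tok[has_copy] <- sub("\\.[0-9]+$", "", tok[has_copy])
  known <- tok %in% mito_vocabulary()
  structure(
    list(token = tok, strand = strand, copy = copy,
         sample_id = sample_id, taxon = taxon,
         unknown = unique(tok[!known]), canonical = FALSE),
    class = "gene_order")
}

#' @export
length.gene_order <- function(x) length(x$token)

# signed token strings without copy suffix
signed_tokens <- function(x) {
  paste0(ifelse(x$strand < 0, "-", ""), x$token)
}

#' Serialize a gene order
#'
#' One-line string form: comma-separated tokens, \code{"-"} prefix for the
#' minus strand, \code{".n"} suffix for copy index greater than 1, e.g.
#' \code{"trnF,rrnS,...,trnT,-trnP,CR,CR.2"}. [parse_gene_order()]
#' round-trips exactly.
#'
#' @param x a \code{gene_order}.
#' @param ... unused.
#' @return A single string.
#' @export
format.gene_order <- function(x, ...) paste(format_tokens(x), collapse = ",")

format_tokens <- function(x) {
  paste0(ifelse(x$strand < 0, "-", ""), x$token,
         ifelse(x$copy > 1L, paste0(".", x$copy), ""))
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%d labels%s)\n%s\n", x$sample_id, length(x),
              if (x$canonical) ", canonical" else "", format(x)))
  invisible(x)
}

#' @rdname format.gene_order
#' @param string serialized gene-order string.
#' @param sample_id,taxon passed to [gene_order()].
#' @export
parse_gene_order <- function(string, sample_id = "", taxon = NULL) {
  go <- gene_order(strsplit(trimws(string), ",", fixed = TRUE)[[1]],
                   sample_id = sample_id, taxon = taxon)
  go$canonical <- identical(format(go), format(canonicalize(go)))
  go
}

rotate_order <- function(x, k) {
  n <- length(x)
  if (n == 0 || k %% n == 0) return(x)
  idx <- c((k + 1):n, 1:k)
  x$token <- x$token[idx]; x$strand <- x$strand[idx]; x$copy <- x$copy[idx]
  x
}

reflect_order <- function(x) {
  idx <- rev(seq_along(x$token))
  x$token <- x$token[idx]
  x$strand <- -x$strand[idx]
  x$copy <- x$copy[idx]
  x
}

assign_copies <- function(x) {
  x$copy <- stats::ave(seq_along(x$token), x$token, FUN = seq_along)
  x$copy <- as.integer(x$copy)
  x
}

# serialization of every rotation starting at an occurrence of `anchor`,
# copies re-assigned per rotation; returns the lexicographically smallest
best_rotation <- function(x, anchor) {
  starts <- which(x$token == anchor)
  best <- NULL; best_str <- NULL
  for (s in starts) {
    cand <- assign_copies(rotate_order(x, s - 1L))
    str <- paste(format_tokens(cand), collapse = ",")
    if (is.null(best_str) || str < best_str) { best <- cand; best_str <- str }
  }
  list(order = best, string = best_str)
}

#' Canonicalize a circular gene order
#'
#' Produces the unique representative of a gene order's equivalence class
#' under rotation and reflection-with-strand-flip. The reading direction is
#' chosen so that the majority of protein-coding genes lie on the plus
#' strand (a tie falls back to the lexicographically smaller serialization).
#' The linearization starts at the anchor gene: \code{trnF}, falling back to
#' \code{rrnS}, then to the lexicographically smallest token. Copy indices
#' are assigned in encounter order from the anchor. Idempotent.
#'
#' @param order a [gene_order()].
#' @return A canonical \code{gene_order}.
#' @export
canonicalize <- function(order) {
  if (!inherits(order, "gene_order")) stop("not a gene_order")
  if (length(order) == 0) stop("empty-order: a gene order must be non-empty")
  pcg <- order$token %in% mito_pcgs()
  n_plus <- sum(order$strand[pcg] > 0)
  n_minus <- sum(order$strand[pcg] < 0)
  anchor_of <- function(x) {
    for (a in c("trnF", "rrnS")) if (a %in% x$token) return(a)
    min(x$token)
  }
  pick <- function(x) best_rotation(x, anchor_of(x))
  if (n_minus > n_plus) {
    res <- pick(reflect_order(order))
  } else if (n_plus > n_minus) {
    res <- pick(order)
  } else {
    # no protein-coding majority: prefer the orientation with fewer
    # minus-strand genes overall, then the smaller serialization
    fwd <- pick(order); rev <- pick(reflect_order(order))
    key <- function(r) c(sum(r$order$strand < 0), 0)
    res <- if (key(rev)[1] < key(fwd)[1] ||
               (key(rev)[1] == key(fwd)[1] && rev$string < fwd$string)) {
      rev
    } else fwd
  }
  out <- res$order
  out$canonical <- TRUE
  out
}

#' Clockwise adjacency set of a canonical gene order
#'
#' One ordered, strand-signed pair per gene: each gene paired with its
#' clockwise successor around the circle. A single-gene circle yields the
#' degenerate self-adjacency. The neighbor-scheme rearrangement metrics
#' compare these pairs (by signed token, ignoring copy index) against a
#' reference.
#'
#' @param order a canonical [gene_order()].
#' @return A data.frame of class \code{adjacency_set} with columns
#'   \code{from}, \code{from_copy}, \code{to}, \code{to_copy}, \code{key}
#'   (the signed \code{"from>to"} comparison key).
#' @export
adjacencies <- function(order) {
  if (!order$canonical) order <- canonicalize(order)
  st <- signed_tokens(order)
  nxt <- c(seq_len(length(order))[-1], 1L)
  out <- data.frame(
    from = st, from_copy = order$copy,
    to = st[nxt], to_copy = order$copy[nxt],
    key = paste0(st, ">", st[nxt]),
    stringsAsFactors = FALSE)
  class(out) <- c("adjacency_set", "data.frame")
  out
}

#' Deduplicate gene orders into rearrangement types
#'
#' Partitions samples into gene rearrangement types by exact equality of
#' canonical gene orders. Type ids are assigned by descending member count,
#' ties broken by first appearance in the input.
#'
#' @param orders list of [gene_order()] objects (canonicalized internally).
#' @return A list of \code{rearrangement_type} objects, each with fields
#'   \code{type_id}, \code{order} (the canonical order), \code{members}
#'   (sample ids), \code{taxa} (unique taxon triples, as a data.frame),
#'   \code{count}. See [type_table()] for a tabular summary.
#' @export
dedupe_types <- function(orders) {
  if (length(orders) == 0) return(list())
  orders <- lapply(orders, function(o) if (o$canonical) o else canonicalize(o))
  keys <- vapply(orders, format, character(1))
  first_seen <- match(unique(keys), keys)
  counts <- as.vector(table(keys)[unique(keys)])
  ord <- order(-counts, first_seen)
  uk <- unique(keys)[ord]
  lapply(seq_along(uk), function(i) {
    idx <- which(keys == uk[i])
    taxa <- unique(do.call(rbind, lapply(orders[idx], function(o) {
      if (is.null(o$taxon)) return(NULL)
      as.data.frame(as.list(stats::setNames(
        o$taxon, c("family", "genus", "species")[seq_along(o$taxon)])))
    })))
    structure(
      list(type_id = i, order = orders[[idx[1]]],
           members = vapply(orders[idx], function(o) o$sample_id, character(1)),
           taxa = taxa, count = length(idx)),
      class = "rearrangement_type")
  })
}

#' @export
print.rearrangement_type <- function(x, ...) {
  cat(sprintf("<rearrangement_type %d> n=%d\n%s\n", x$type_id, x$count,
              format(x$order)))
  invisible(x)
}

#' Summary table of rearrangement types
#'
#' @param types list returned by [dedupe_types()].
#' @return data.frame with columns \code{type_id}, \code{count},
#'   \code{n_genes}, \code{order}.
#' @export
type_table <- function(types) {
  data.frame(
    type_id = vapply(types, function(t) t$type_id, integer(1)),
    count = vapply(types, function(t) t$count, integer(1)),
    n_genes = vapply(types, function(t) length(t$order), integer(1)),
    order = vapply(types, function(t) format(t$order), character(1)),
    stringsAsFactors = FALSE)
}

#' Default breakpoints dividing the circle into two intervals
#'
#' The circular genome is cut at two junctions chosen after the widely
#' accepted replication/transcription organisation: between the control
#' region and \code{trnF}, and between \code{trnN} and \code{OL} inside the
#' WANCY tRNA cluster. Each breakpoint is an unsigned token pair
#' \code{c(left, right)}: the cut falls between an occurrence of
#' \code{left} immediately followed by \code{right}.
#'
#' @return List of two character(2) vectors.
#' @export
default_breakpoints <- function() {
  list(c("CR", "trnF"), c("trnN", "OL"))
}

# resolve one breakpoint to a cut position: cut after position i.
# Falls back to "after first `left`", then "before first `right`".
resolve_breakpoint <- function(order, bp) {
  n <- length(order)
  tok <- order$token
  nxt <- if (n == 1L) 1L else c(2:n, 1L)
  hit <- which(tok == bp[1] & tok[nxt] == bp[2])
  if (length(hit) > 0) return(list(cut_after = hit[1], fallback = NA_character_))
  if (bp[1] %in% tok) {
    return(list(cut_after = which(tok == bp[1])[1],
                fallback = sprintf("after first '%s'", bp[1])))
  }
  if (bp[2] %in% tok) {
    i <- which(tok == bp[2])[1]
    return(list(cut_after = if (i == 1L) n else i - 1L,
                fallback = sprintf("before first '%s'", bp[2])))
  }
  stop(sprintf("breakpoint-not-found: neither '%s' nor '%s' present in %s",
               bp[1], bp[2], order$sample_id))
}

#' Split a circular order into two linear intervals at two breakpoints
#'
#' @param order canonical [gene_order()].
#' @param breakpoints list of two \code{c(left, right)} unsigned token
#'   pairs; defaults to [default_breakpoints()]. When an exact junction is
#'   absent the cut falls back to "after the first \code{left}", then
#'   "before the first \code{right}"; the fallback used is reported in the
#'   \code{fallback} attribute.
#' @return List with elements \code{A} and \code{B}: integer index vectors
#'   into the order (interval A starts at the gene following the first
#'   cut), plus attribute \code{fallback}. The concatenation \code{c(A, B)}
#'   is a rotation of the circular order; adjacent cuts give one empty
#'   interval.
#' @export
split_intervals <- function(order, breakpoints = default_breakpoints()) {
  if (!order$canonical) order <- canonicalize(order)
  n <- length(order)
  r1 <- resolve_breakpoint(order, breakpoints[[1]])
  r2 <- resolve_breakpoint(order, breakpoints[[2]])
  c1 <- r1$cut_after; c2 <- r2$cut_after
  circ <- function(from, to) {       # indices strictly after `from` up to `to`
    if (from < to) return((from + 1L):to)
    c(if (from < n) (from + 1L):n else integer(0), seq_len(to))
  }
  out <- if (c1 == c2) {
    list(A = integer(0), B = circ(c1, c1))   # adjacent cuts: one empty interval
  } else {
    list(A = circ(c1, c2), B = circ(c2, c1))
  }
  attr(out, "fallback") <- c(r1$fallback, r2$fallback)
  out
}

#' Read and write gene-order string files
#'
#' Plain-text format: one sample per line, \code{sample_id<TAB>order
#' string}; optional third and later tab fields carry the taxon triple.
#'
#' @param path file path.
#' @return \code{read_gene_orders}: list of [gene_order()].
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    taxon <- if (length(f) > 2) f[3:min(5, length(f))] else NULL
    parse_gene_order(f[2], sample_id = f[1], taxon = taxon)
  })
}

#' @rdname read_gene_orders
#' @param orders list of [gene_order()].
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(orders, function(o) {
    taxon <- if (is.null(o$taxon)) character(0) else o$taxon
    paste(c(o$sample_id, format(o), taxon), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
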