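# Independent oracles and fixture builders shared across tests.

# Brute-force neighbor-scheme RS: for every gene of the query circle,
# scan the reference circle directly for each of its two signed neighbor
# pairs. Deliberately avoids the package's adjacency-set machinery.
brute_qmgr_rs <- function(query_tokens, ref_tokens) {
  strip_copy <- function(v) sub("\\.[0-9]+$", "", v)
  q <- strip_copy(query_tokens)
  r <- strip_copy(ref_tokens)
  nq <- length(q); nr <- length(r)
  pair_in_ref <- function(a, b) {
    for (i in seq_len(nr)) {
      j <- if (i == nr) 1L else i + 1L
      if (r[i] == a && r[j] == b) return(TRUE)
    }
    FALSE
  }
  total <- 0L
  for (i in seq_len(nq)) {
    p <- if (i == 1L) nq else i - 1L
    s <- if (i == nq) 1L else i + 1L
    total <- total + (!pair_in_ref(q[p], q[i])) + (!pair_in_ref(q[i], q[s]))
  }
  as.integer(total)
}

# all circular arrangements of the given distinct labels, as token vectors
# (first label fixed: rotations are equivalent)
all_circular_orders <- function(labels) {
  if (length(labels) == 1) return(list(labels))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  lapply(perms(labels[-1]), function(p) c(labels[1], p))
}

# map simulated tip orders onto types and return the tree ready for
# ancestral inference, together with the types
sim_to_time_tree <- function(sim) {
  types <- dedupe_types(sim$tip_orders)
  keys <- vapply(types, function(t) format(t$order), character(1))
  tip_type <- vapply(sim$tip_orders, function(o) {
    types[[match(format(o), keys)]]$type_id
  }, integer(1))
  names(tip_type) <- vapply(sim$tip_orders, function(o) o$sample_id,
                            character(1))
  tt <- sim$tree
  tt$tip_types <- tip_type[tt$phylo$tip.label]
  list(tree = tt, types = types, keys = keys)
}

# random rooted tree with n tips and unit-ish branch lengths
random_tip_tree <- function(n) {
  phy <- ape::rcoal(n)
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}
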