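#' Configuration for gene-order evolution simulations
#'
#' Defines the study conditions a simulated dataset emulates: a
#' multi-family clade of the stated root age whose tip gene orders arise
#' from the vertebrate ground pattern by stochastic rearrangement events
#' along the tree. Event classes and default rates follow the
#' qualitative structure of real amphibian mitogenomes: translocations
#' most common, control-region duplication prominent, inversions and
#' losses rare.
#'
#' @param n_families number of family clades.
#' @param tips_per_family integer range \code{c(min, max)} of tips drawn
#'   per family.
#' @param root_age crown age of the whole clade in Myr.
#' @param rates named events/lineage/Myr rates for classes
#'   \code{translocation}, \code{inversion}, \code{duplication},
#'   \code{cr_duplication}, \code{loss}.
#' @param loss_guard never delete the last copy of a canonical gene
#'   (default on).
#' @param event_max_age when set, events only occur at ages at or below
#'   this value (Myr), concentrating change toward the present.
#' @param seed integer; fixes the full output stream of
#'   [simulate_tree()] and [simulate_events()].
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 6, tips_per_family = c(2, 6),
                       root_age = 170,
                       rates = c(translocation = 2e-3, inversion = 2e-4,
                                 duplication = 5e-4, cr_duplication = 1e-3,
                                 loss = 2e-4),
                       loss_guard = TRUE, event_max_age = NULL, seed = 1) {
  if (any(rates < 0)) stop("rates must be >= 0")
  if (root_age <= 0) stop("root_age must be > 0")
  if (length(tips_per_family) != 2 || tips_per_family[1] < 1 ||
      tips_per_family[2] < tips_per_family[1]) {
    stop("impossible tip counts: tips_per_family must be c(min, max), min >= 1")
  }
  need <- c("translocation", "inversion", "duplication", "cr_duplication",
            "loss")
  if (!all(need %in% names(rates))) {
    stop("rates must name all classes: ", paste(need, collapse = ", "))
  }
  structure(list(n_families = n_families, tips_per_family = tips_per_family,
                 root_age = root_age, rates = rates[need],
                 loss_guard = loss_guard, event_max_age = event_max_age,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- internal ultrametric tree construction -------------------------------

# sequential coalescence of `nodes` (list of list(age, label, children))
# at the given ascending ages; returns the single root node
coalesce_at <- function(nodes, ages) {
  for (t in ages) {
    pick <- sample.int(length(nodes), 2)
    merged <- list(age = t, label = NULL,
                   children = nodes[pick])
    nodes <- c(nodes[-pick], list(merged))
  }
  nodes[[1]]
}

node_to_newick <- function(node, parent_age = NULL) {
  if (length(node$children) == 0) {
    s <- node$label
  } else {
    s <- paste0("(", paste(vapply(node$children, node_to_newick, character(1),
                                  parent_age = node$age), collapse = ","),
                ")")
  }
  if (is.null(parent_age)) paste0(s, ";")
  else paste0(s, ":", format(parent_age - node$age, digits = 10,
                             scientific = FALSE))
}

#' Simulate an ultrametric multi-family time tree
#'
#' Builds a random ultrametric tree by explicit coalescence: a family
#' backbone whose join ages lie in the deep part of the tree (the oldest
#' join exactly at the root age), and within each family a crown tree
#' coalescing below a family crown age drawn from the shallow part.
#' Family clades are therefore monophyletic and labeled; tips are named
#' \code{Fam<i>_t<j>}. Reproducible from \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @return A [time_tree()] with \code{taxon} set to the family of each
#'   tip and \code{tip_types} unset (\code{NA}) until gene orders are
#'   simulated and deduplicated.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_families
  tpf <- seq(config$tips_per_family[1], config$tips_per_family[2])
  m <- if (length(tpf) == 1) rep(tpf, nf) else sample(tpf, nf, replace = TRUE)
  fams <- sprintf("Fam%02d", seq_len(nf))
  fam_nodes <- lapply(seq_len(nf), function(i) {
    crown <- stats::runif(1, 0.15, 0.45) * config$root_age
    tips <- lapply(seq_len(m[i]), function(j) {
      list(age = 0, label = sprintf("%s_t%d", fams[i], j), children = list())
    })
    if (m[i] == 1) return(tips[[1]])
    ages <- sort(stats::runif(m[i] - 1, 0.02 * config$root_age, crown))
    ages[m[i] - 1] <- crown
    coalesce_at(tips, ages)
  })
  if (nf == 1) {
    root <- fam_nodes[[1]]
  } else {
    back <- sort(stats::runif(nf - 1, 0.55, 0.98)) * config$root_age
    back[nf - 1] <- config$root_age
    root <- coalesce_at(fam_nodes, back)
  }
  phy <- ape::read.tree(text = node_to_newick(root))
  taxon <- stats::setNames(sub("_t[0-9]+$", "", phy$tip.label),
                           phy$tip.label)
  tt <- time_tree(phy,
                  tip_types = stats::setNames(
                    rep(NA_integer_, length(phy$tip.label)), phy$tip.label),
                  taxon = taxon)
  tt$config <- config
  tt
}

# --- event mechanics -------------------------------------------------------

# pure application of one recorded event to a signed-token vector;
# shared by the simulator and the replayer so logs replay bit-exactly
apply_rearrangement <- function(v, class, src, dest, len) {
  n <- length(v)
  switch(class,
    translocation = {
      g <- v[src]
      v <- v[-src]
      append(v, g, after = dest)
    },
    inversion = {
      idx <- ((src - 1L + seq_len(len) - 1L) %% n) + 1L
      flipped <- rev(ifelse(startsWith(v[idx], "-"),
                            sub("^-", "", v[idx]),
                            paste0("-", v[idx])))
      v[idx] <- flipped
      v
    },
    duplication = ,
    cr_duplication = append(v, v[src], after = dest),
    loss = v[-src],
    stop("unknown event class: ", class))
}

base_token <- function(v) sub("^-", "", v)

# draw one event of `class` on state v; returns NULL for a no-op
draw_event <- function(v, class, loss_guard) {
  n <- length(v)
  if (class == "translocation") {
    src <- sample.int(n, 1)
    dest <- sample(setdiff(0:(n - 1L), src - 1L), 1)
    list(src = src, dest = dest, len = NA_integer_, token = v[src])
  } else if (class == "inversion") {
    src <- sample.int(n, 1)
    len <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    idx <- ((src - 1L + seq_len(len) - 1L) %% n) + 1L
    list(src = src, dest = NA_integer_, len = len,
         token = paste(v[idx], collapse = "+"))
  } else if (class %in% c("duplication", "cr_duplication")) {
    cand <- if (class == "cr_duplication") which(base_token(v) == "CR")
            else seq_len(n)
    if (length(cand) == 0) return(NULL)
    src <- if (length(cand) == 1) cand else sample(cand, 1)
    tandem <- stats::runif(1) < 0.5
    dest <- if (tandem) src else sample(0:n, 1)
    list(src = src, dest = dest, len = NA_integer_, token = v[src])
  } else if (class == "loss") {
    cand <- if (loss_guard) {
      which(stats::ave(seq_len(n), base_token(v), FUN = length) >= 2)
    } else seq_len(n)
    if (length(cand) == 0) return(NULL)
    src <- if (length(cand) == 1) cand else sample(cand, 1)
    list(src = src, dest = NA_integer_, len = NA_integer_, token = v[src])
  }
}

#' Simulate rearrangement events along a tree
#'
#' Draws events of each class as independent Poisson processes along
#' every branch (rates in events/lineage/Myr from the config), mutates
#' the circular gene order at each event in age order from the root
#' pattern, and emits the final order at every node. Only applied events
#' are logged (an event with no eligible site, e.g. a guarded loss on a
#' duplicate-free genome, is a silent no-op), so replaying the log from
#' the root pattern reproduces every tip order exactly (see
#' [replay_events()]).
#'
#' @param tree a [simulate_tree()] result.
#' @param config the same [sim_config()].
#' @param root_order starting circular order; default the vertebrate
#'   ground pattern.
#' @return list of class \code{sim_result}: \code{tip_orders} (list of
#'   canonical [gene_order()]), \code{node_orders} (canonical order
#'   string per ape node id: ground-truth internal states),
#'   \code{log} (the event log data.frame: \code{branch} = child node id,
#'   \code{age}, \code{class}, \code{token}, \code{src}, \code{dest},
#'   \code{len}), \code{tree}, \code{config},
#'   \code{tip_event_counts} (events on the root-to-tip path).
#' @export
simulate_events <- function(tree, config = tree$config,
                            root_order = vertebrate_order()) {
  set.seed(config$seed + 1L)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  ages <- node_ages(phy)
  root_v <- format_tokens(root_order)
  root_v <- sub("\\.[0-9]+$", "", root_v)       # copies re-derived at tips
  states <- vector("list", nn)
  states[[ntip + 1L]] <- root_v
  n_events <- integer(nn)
  log_rows <- list()
  edges <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in rev(seq_len(nrow(edges)))) {        # preorder
    p <- edges[k, 1]; ch <- edges[k, 2]
    v <- states[[p]]
    a_old <- ages[p]; a_new <- ages[ch]
    cnt <- 0L
    evs <- list()
    for (class in names(config$rates)) {
      lambda <- config$rates[[class]] * (a_old - a_new)
      nev <- if (lambda > 0) stats::rpois(1, lambda) else 0L
      if (nev > 0) {
        times <- stats::runif(nev, a_new, a_old)
        if (!is.null(config$event_max_age)) {
          times <- times[times <= config$event_max_age]
        }
        for (t in times) evs[[length(evs) + 1L]] <- list(age = t, class = class)
      }
    }
    if (length(evs) > 0) {
      ord <- order(-vapply(evs, function(e) e$age, numeric(1)))
      for (e in evs[ord]) {
        drawn <- draw_event(v, e$class, config$loss_guard)
        if (is.null(drawn)) next
        v <- apply_rearrangement(v, e$class, drawn$src, drawn$dest, drawn$len)
        cnt <- cnt + 1L
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          branch = ch, age = e$age, class = e$class, token = drawn$token,
          src = drawn$src, dest = if (is.na(drawn$dest)) NA_integer_
                                  else drawn$dest,
          len = drawn$len, stringsAsFactors = FALSE)
      }
    }
    states[[ch]] <- v
    n_events[ch] <- n_events[p] + cnt
  }
  tip_orders <- lapply(seq_len(ntip), function(i) {
    fam <- if (is.null(tree$taxon)) NA_character_ else
      tree$taxon[phy$tip.label[i]]
    canonicalize(gene_order(
      states[[i]], sample_id = phy$tip.label[i],
      taxon = c(fam, paste0(fam, "gen"),
                paste(paste0(fam, "gen"), phy$tip.label[i]))))
  })
  node_strings <- vapply(seq_len(nn), function(v) {
    format(canonicalize(gene_order(states[[v]], sample_id = "node")))
  }, character(1))
  log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(branch = integer(0), age = numeric(0), class = character(0),
               token = character(0), src = integer(0), dest = integer(0),
               len = integer(0), stringsAsFactors = FALSE)
  structure(list(tip_orders = tip_orders, node_orders = node_strings,
                 log = log, tree = tree, config = config,
                 tip_event_counts = n_events[seq_len(ntip)]),
            class = "sim_result")
}

#' Replay an event log from the root pattern
#'
#' Mechanically re-applies the logged events along the tree (preorder,
#' oldest first within each branch) and returns the resulting canonical
#' order string per node. Replaying a [simulate_events()] log reproduces
#' its \code{node_orders} exactly.
#'
#' @param log event-log data.frame (see [simulate_events()]).
#' @param tree the [time_tree()] the log was simulated on.
#' @param root_order starting order; default the vertebrate pattern.
#' @return Character vector of canonical order strings per ape node id.
#' @export
replay_events <- function(log, tree, root_order = vertebrate_order()) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root_v <- sub("\\.[0-9]+$", "", format_tokens(root_order))
  states <- vector("list", nn)
  states[[ntip + 1L]] <- root_v
  edges <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in rev(seq_len(nrow(edges)))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    v <- states[[p]]
    br <- log[log$branch == ch, , drop = FALSE]
    if (nrow(br) > 0) {
      br <- br[order(-br$age), , drop = FALSE]
      for (r in seq_len(nrow(br))) {
        v <- apply_rearrangement(v, br$class[r], br$src[r], br$dest[r],
                                 br$len[r])
      }
    }
    states[[ch]] <- v
  }
  vapply(seq_len(nn), function(v) {
    format(canonicalize(gene_order(states[[v]], sample_id = "node")))
  }, character(1))
}

#' Write a simulated dataset to disk
#'
#' Emits the plain-text files every other module reads: gene-order
#' strings, tip-map CSV, newick tree, taxonomy checklist CSV, and
#' (optionally) a per-gene feature TSV with synthetic coordinates so the
#' annotation-ingest path can be exercised end to end. In the feature
#' TSV the control region is deliberately left unannotated: its span
#' remains as an intergenic gap for [detect_control_regions()] to
#' rediscover.
#'
#' @param sim a [simulate_events()] result.
#' @param dir output directory (created if absent).
#' @param features also write the per-gene TSV.
#' @return Named vector of written paths.
#' @export
emit_dataset <- function(sim, dir, features = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  orders_path <- file.path(dir, "gene_orders.tsv")
  write_gene_orders(sim$tip_orders, orders_path)
  types <- dedupe_types(sim$tip_orders)
  keys <- vapply(types, function(t) format(t$order), character(1))
  tip_type <- vapply(sim$tip_orders, function(o) {
    types[[match(format(o), keys)]]$type_id
  }, integer(1))
  names(tip_type) <- vapply(sim$tip_orders, function(o) o$sample_id,
                            character(1))
  tt <- sim$tree; tt$tip_types <- tip_type[tt$phylo$tip.label]
  paths <- write_time_tree(tt, dir, "timetree")
  fams <- sort(unique(tt$taxon))
  checklist <- data.frame(
    family = fams, genus = paste0(fams, "gen"),
    species_count = as.integer(table(tt$taxon)[fams]) + 3L,
    stringsAsFactors = FALSE)
  checklist_path <- file.path(dir, "checklist.csv")
  write_checklist(checklist, checklist_path)
  out <- c(orders = orders_path, paths, checklist = checklist_path)
  if (features) {
    feat_path <- file.path(dir, "features.tsv")
    write_synthetic_features(sim$tip_orders, feat_path)
    out <- c(out, features = feat_path)
  }
  out
}

# plausible per-token feature lengths (bp) for synthetic coordinates
token_lengths <- function() {
  c(nad1 = 957, nad2 = 1035, nad3 = 349, nad4 = 1378, nad4l = 297,
    nad5 = 1821, nad6 = 519, cox1 = 1551, cox2 = 684, cox3 = 784,
    atp6 = 684, atp8 = 165, cob = 1140, rrnS = 930, rrnL = 1600,
    OL = 35, CR = 1200, extra = 100)
}

#' @rdname emit_dataset
#' @param orders list of canonical [gene_order()].
#' @param path output TSV path.
#' @export
write_synthetic_features <- function(orders, path) {
  lens <- token_lengths()
  rows <- lapply(orders, function(o) {
    L <- ifelse(o$token %in% names(lens), lens[o$token],
                ifelse(o$token %in% mito_trnas(), 70L, 100L))
    spacer <- 2L
    is_cr <- o$token == "CR"
    n <- length(o$token)
    prv <- c(n, seq_len(n - 1L)); nxt <- c(seq_len(n)[-1], 1L)
    # an isolated CR is left as a bare gap for detection to rediscover;
    # tandem CR copies stay annotated (one merged gap cannot encode two)
    bare_cr <- is_cr & !is_cr[prv] & !is_cr[nxt]
    start <- cumsum(c(1L, L[-length(L)] + spacer))
    data.frame(sample_id = o$sample_id, raw_name = o$token,
               start = as.integer(start), end = as.integer(start + L - 1L),
               strand = ifelse(o$strand < 0, "-", "+"),
               feature_class = ifelse(o$token %in% mito_trnas(), "tRNA",
                 ifelse(o$token %in% mito_rrnas(), "rRNA",
                   ifelse(o$token == "CR", "D-loop",
                     ifelse(o$token == "OL", "origin", "gene")))),
               anticodon = NA_character_,
               genome_length = as.integer(start[length(start)] +
                                            L[length(L)] - 1L + spacer),
               keep = !bare_cr,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$keep, setdiff(names(tab), "keep")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Planted-type dataset mirroring a large curated collection
#'
#' Builds a dataset of \code{n_samples} gene orders drawn from exactly
#' \code{n_types} distinct planted canonical orders, for testing that
#' type deduplication recovers the planted partition. The first three
#' planted orders are the three ground patterns (vertebrate, Caudata,
#' Neobatrachian) with member counts matching their empirical prevalence
#' shares; remaining types are derived from the ground patterns by short
#' random event chains, re-drawn until canonically distinct.
#'
#' @param n_samples total number of samples (default 1777).
#' @param n_types number of distinct planted orders (default 88).
#' @param seed RNG seed.
#' @return list: \code{orders} (list of [gene_order()]),
#'   \code{planted} (canonical strings of the planted orders),
#'   \code{counts} (samples per planted order).
#' @export
planted_type_dataset <- function(n_samples = 1777, n_types = 88, seed = 1) {
  if (n_types < 3 || n_samples < n_types) {
    stop("need n_types >= 3 and n_samples >= n_types")
  }
  set.seed(seed)
  bases <- list(vertebrate_order(), caudata_order(), neobatrachia_order())
  planted <- vapply(bases, format, character(1))
  while (length(planted) < n_types) {
    base <- bases[[sample.int(3, 1)]]
    v <- sub("\\.[0-9]+$", "", format_tokens(base))
    for (k in seq_len(sample(1:3, 1))) {
      class <- sample(c("translocation", "duplication", "inversion",
                        "cr_duplication"), 1,
                      prob = c(0.5, 0.2, 0.1, 0.2))
      drawn <- draw_event(v, class, loss_guard = TRUE)
      if (is.null(drawn)) next
      v <- apply_rearrangement(v, class, drawn$src, drawn$dest, drawn$len)
    }
    key <- format(canonicalize(gene_order(v)))
    if (!key %in% planted) planted <- c(planted, key)
  }
  # member counts: empirical shares for the three ground patterns,
  # the remainder spread over the derived types
  counts <- integer(n_types)
  shares <- c(162, 415, 756)
  counts[1:3] <- pmax(1L, round(shares / sum(shares) * n_samples * 0.75))
  rest <- n_samples - sum(counts[1:3])
  k <- n_types - 3L
  counts[4:n_types] <- rest %/% k
  extra <- rest - sum(counts[4:n_types])
  if (extra > 0) counts[3 + seq_len(extra)] <- counts[3 + seq_len(extra)] + 1L
  orders <- list()
  s <- 0L
  for (i in seq_len(n_types)) {
    for (j in seq_len(counts[i])) {
      s <- s + 1L
      orders[[s]] <- parse_gene_order(planted[i],
                                      sample_id = sprintf("S%04d", s))
    }
  }
  list(orders = orders, planted = planted, counts = counts)
}

#' Synthetic checklist-reconciliation scenario
#'
#' Deterministically constructs a taxonomy checklist with the stated
#' totals (families, genera, species) and a sample table whose cleaned
#' names cover exactly the stated numbers of families, genera and
#' species, with a handful of qualifier-carrying names routed per the
#' reconciliation rules. Used to exercise the coverage arithmetic on a
#' dataset of realistic shape.
#'
#' @param n_samples total samples (default 1777).
#' @param checklist_totals named vector \code{c(families, genera,
#'   species)} of checklist size (defaults 77, 569, 8689).
#' @param covered named vector \code{c(families, genera, species)}
#'   covered by the samples (defaults 65, 244, 710).
#' @return list: \code{checklist}, \code{samples}.
#' @export
coverage_scenario <- function(n_samples = 1777,
                              checklist_totals = c(families = 77,
                                                   genera = 569,
                                                   species = 8689),
                              covered = c(families = 65, genera = 244,
                                          species = 710)) {
  nf <- checklist_totals[["families"]]
  ng <- checklist_totals[["genera"]]
  ns <- checklist_totals[["species"]]
  gpf <- rep(ng %/% nf, nf)
  gpf[seq_len(ng %% nf)] <- gpf[seq_len(ng %% nf)] + 1L
  fam <- rep(sprintf("Fam%02d", seq_len(nf)), gpf)
  gen <- sprintf("Genus%03d", seq_len(ng))
  spc <- rep(ns %/% ng, ng)
  spc[seq_len(ns %% ng)] <- spc[seq_len(ns %% ng)] + 1L
  checklist <- data.frame(family = fam, genus = gen, species_count = spc,
                          stringsAsFactors = FALSE)
  cf <- covered[["families"]]; cg <- covered[["genera"]]
  cs <- covered[["species"]]
  # pick cg genera spread over exactly the first cf families
  base <- cg %/% cf; extra <- cg %% cf
  take <- rep(base, cf); take[seq_len(extra)] <- take[seq_len(extra)] + 1L
  if (any(take > gpf[seq_len(cf)])) stop("covered genera exceed checklist")
  gidx <- unlist(lapply(seq_len(cf), function(i) {
    which(checklist$family == sprintf("Fam%02d", i))[seq_len(take[i])]
  }))
  # cs species over the cg covered genera
  sbase <- cs %/% cg; sextra <- cs %% cg
  nsp <- rep(sbase, cg); nsp[seq_len(sextra)] <- nsp[seq_len(sextra)] + 1L
  if (any(nsp > checklist$species_count[gidx])) {
    stop("covered species exceed checklist counts")
  }
  species <- unlist(lapply(seq_along(gidx), function(i) {
    paste(checklist$genus[gidx[i]], sprintf("species%02d", seq_len(nsp[i])))
  }))
  n_qual <- 7L                                   # qualifier-bearing samples
  n_named <- n_samples - n_qual
  organisms <- c(species,
                 species[((seq_len(n_named - length(species)) - 1L) %%
                            length(species)) + 1L])
  qual <- c(paste(checklist$genus[gidx[1]], "cf. species01"),
            paste(checklist$genus[gidx[2]], "sp. 2"),
            paste(checklist$genus[gidx[3]], "sp."),
            paste(checklist$genus[gidx[4]], "cf. species02"),
            paste(checklist$genus[gidx[5]], "aff. species01"),
            paste(checklist$genus[gidx[6]], "aff. species02"),
            paste(checklist$genus[gidx[7]], "species01 x species02"))
  organisms <- c(organisms, qual)
  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                        organism = organisms, stringsAsFactors = FALSE)
  list(checklist = checklist, samples = samples)
}
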