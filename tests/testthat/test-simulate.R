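test_that("simulated trees are ultrametric, family-labeled, reproducible", {
  cfg <- sim_config(n_families = 2, tips_per_family = c(2, 2), seed = 5)
  tt <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tt$phylo), 4L)
  ages <- node_ages(tt$phylo)
  expect_true(all(abs(ages[seq_len(4)]) < 1e-6))       # tips at the present
  expect_equal(max(ages), 170, tolerance = 1e-6)
  expect_setequal(unique(tt$taxon), c("Fam01", "Fam02"))
  # family monophyly
  for (fam in unique(tt$taxon)) {
    tips <- names(tt$taxon)[tt$taxon == fam]
    if (length(tips) > 1) expect_true(ape::is.monophyletic(tt$phylo, tips))
  }
  # same seed, same newick
  tt2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(tt2$phylo), ape::write.tree(tt$phylo))
  expect_error(sim_config(tips_per_family = c(0, 2)), "impossible tip counts")
})

test_that("node ages stay within the sliced range of the root age", {
  cfg <- sim_config(n_families = 5, tips_per_family = c(2, 5),
                    root_age = 170, seed = 6)
  tt <- simulate_tree(cfg)
  ages <- node_ages(tt$phylo)
  expect_true(all(ages <= 34 * 5 + 1e-6))
  expect_true(all(ages >= 0))
})

test_that("zero rates leave every tip at the root pattern", {
  cfg <- sim_config(n_families = 3, tips_per_family = c(2, 3),
                    rates = c(translocation = 0, inversion = 0,
                              duplication = 0, cr_duplication = 0, loss = 0),
                    seed = 7)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  expect_equal(nrow(sim$log), 0L)
  keys <- vapply(sim$tip_orders, format, character(1))
  expect_true(all(keys == format(vertebrate_order())))
  expect_length(dedupe_types(sim$tip_orders), 1L)
})

test_that("replaying the event log reproduces every node order exactly", {
  for (seed in c(11, 12, 13)) {
    cfg <- sim_config(n_families = 3, tips_per_family = c(2, 4),
                      rates = c(translocation = 8e-3, inversion = 8e-4,
                                duplication = 2e-3, cr_duplication = 4e-3,
                                loss = 8e-4), seed = seed)
    tt <- simulate_tree(cfg)
    sim <- simulate_events(tt, cfg)
    expect_identical(replay_events(sim$log, tt), sim$node_orders)
    ages <- node_ages(tt$phylo)
    if (nrow(sim$log) > 0) {
      # event ages lie within their branch's span
      parent <- integer(length(ages))
      parent[tt$phylo$edge[, 2]] <- tt$phylo$edge[, 1]
      expect_true(all(sim$log$age >= ages[sim$log$branch] - 1e-9))
      expect_true(all(sim$log$age <= ages[parent[sim$log$branch]] + 1e-9))
    }
  }
})

test_that("a clade-restricted CR duplication marks only that clade", {
  cfg <- sim_config(n_families = 2, tips_per_family = c(3, 3),
                    rates = c(translocation = 0, inversion = 0,
                              duplication = 0, cr_duplication = 0, loss = 0),
                    seed = 17)
  tt <- simulate_tree(cfg)
  sim <- simulate_events(tt, cfg)
  # plant a CR duplication on the stem of Fam01 by replaying an edited log
  fam1 <- names(tt$taxon)[tt$taxon == "Fam01"]
  stem <- ape::getMRCA(tt$phylo, fam1)
  v <- mgorder:::format_tokens(vertebrate_order())
  cr <- which(v == "CR")
  log <- data.frame(branch = stem, age = max(node_ages(tt$phylo)) / 2,
                    class = "cr_duplication", token = "CR",
                    src = cr, dest = cr, len = NA_integer_,
                    stringsAsFactors = FALSE)
  nodes <- replay_events(log, tt)
  ntip <- ape::Ntip(tt$phylo)
  in_clade <- vapply(seq_len(ntip), function(i) tt$taxon[i] == "Fam01",
                     logical(1))
  n_cr <- vapply(seq_len(ntip), function(i) {
    sum(parse_gene_order(nodes[i])$token == "CR")
  }, integer(1))
  expect_true(all(n_cr[match(fam1, tt$phylo$tip.label)] == 2L))
  expect_true(all(n_cr[-match(fam1, tt$phylo$tip.label)] == 1L))
})

test_that("the loss guard protects the last copy of every gene", {
  cfg <- sim_config(n_families = 3, tips_per_family = c(3, 4),
                    rates = c(translocation = 0, inversion = 0,
                              duplication = 4e-3, cr_duplication = 4e-3,
                              loss = 2e-2), seed = 23)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  for (o in sim$tip_orders) {
    expect_true(all(mito_required_genes() %in% o$token))
  }
})

test_that("event-class counts reflect the configured rate ratio", {
  cfg <- sim_config(n_families = 6, tips_per_family = c(4, 6),
                    rates = c(translocation = 2e-2, inversion = 2e-3,
                              duplication = 0, cr_duplication = 0, loss = 0),
                    seed = 29)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  n_tr <- sum(sim$log$class == "translocation")
  n_inv <- sum(sim$log$class == "inversion")
  expect_gt(n_tr, 0)
  # inversion share ~1/11 of events; allow generous binomial error
  p <- n_inv / (n_tr + n_inv)
  expect_lt(p, 0.25)
})

test_that("emitted datasets round-trip through the readers", {
  cfg <- sim_config(n_families = 3, tips_per_family = c(2, 3),
                    rates = c(translocation = 6e-3, inversion = 6e-4,
                              duplication = 1.5e-3, cr_duplication = 3e-3,
                              loss = 0), seed = 37)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  dir <- tempfile(); dir.create(dir)
  paths <- emit_dataset(sim, dir, features = TRUE)
  back <- read_gene_orders(paths["orders"])
  expect_identical(vapply(back, format, character(1)),
                   vapply(sim$tip_orders, format, character(1)))
  tt <- read_time_tree(paths["newick"], paths["tipmap"])
  expect_setequal(tt$phylo$tip.label, sim$tree$phylo$tip.label)
  checklist <- read_checklist(paths["checklist"])
  expect_true(all(unique(sim$tree$taxon) %in% checklist$family))
  # the per-gene TSV regenerates identical canonical orders, with the
  # control regions rediscovered from their gaps
  feats <- parse_features(paths["features"], "tsv")
  gl <- utils::read.delim(paths["features"])
  for (sid in unique(feats$sample_id)) {
    f <- feats[feats$sample_id == sid, ]
    res <- order_from_features(f, gl$genome_length[gl$sample_id == sid][1],
                               min_gap = 250)
    orig <- sim$tip_orders[[match(
      sid, vapply(sim$tip_orders, function(o) o$sample_id, character(1)))]]
    expect_identical(format(res$order), format(orig))
  }
})

test_that("tip RS tracks the number of events on the root-to-tip path", {
  set.seed(41)
  ev <- c(); rs <- c()
  ref <- vertebrate_order()
  for (r in 1:40) {
    cfg <- sim_config(n_families = 3, tips_per_family = c(2, 3),
                      seed = 4100 + r)
    sim <- simulate_events(simulate_tree(cfg), cfg)
    rs <- c(rs, vapply(sim$tip_orders, function(o) qmgr_rs(o, ref),
                       numeric(1)))
    ev <- c(ev, sim$tip_event_counts)
  }
  expect_gt(stats::cor(ev, rs, method = "spearman"), 0.8)
})
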