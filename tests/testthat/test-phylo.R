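test_that("a uniform tip state propagates to every internal node", {
  phy <- random_tip_tree(6)
  tt <- time_tree(phy, stats::setNames(rep(1L, 6), phy$tip.label))
  fit <- infer_ancestral_types(tt, "fitch")
  expect_true(all(fit$node_types == 1L))
  expect_equal(attr(fit$node_types, "parsimony_cost"), 0)
})

test_that("a balanced 4-tip split resolves to the outgroup state", {
  phy <- ape::read.tree(text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,og:3);")
  tt <- time_tree(phy, c(t1 = 1L, t2 = 1L, t3 = 2L, t4 = 2L, og = 1L))
  fit <- infer_ancestral_types(tt, "fitch", outgroup = "og")
  root <- ape::Ntip(phy) + 1L
  expect_equal(unname(fit$node_types[root]), 1L)
  ex <- exhaustive_parsimony(tt, root_state = 1L)
  expect_equal(attr(fit$node_types, "parsimony_cost"), ex$cost)
})

test_that("Fitch and Sankoff match exhaustive minimization on small trees", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    phy <- random_tip_tree(n)
    types <- sample.int(3, n, replace = TRUE)
    tt <- time_tree(phy, stats::setNames(types, phy$tip.label))
    og <- sample(phy$tip.label, 1)
    fit <- infer_ancestral_types(tt, "fitch", outgroup = og)
    ex <- exhaustive_parsimony(tt, root_state = types[match(og, phy$tip.label)])
    expect_equal(attr(fit$node_types, "parsimony_cost"), ex$cost)
    S <- sort(unique(types))
    cm <- matrix(stats::runif(length(S)^2, 0.5, 4), length(S))
    diag(cm) <- 0
    dimnames(cm) <- list(S, S)
    fit2 <- infer_ancestral_types(tt, "sankoff", costs = cm, outgroup = og)
    ex2 <- exhaustive_parsimony(tt, costs = cm,
                                root_state = types[match(og, phy$tip.label)])
    expect_equal(attr(fit2$node_types, "parsimony_cost"), ex2$cost)
  }
})

test_that("Sankoff with unit costs equals the Fitch change count", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    phy <- random_tip_tree(n)
    types <- sample.int(3, n, replace = TRUE)
    tt <- time_tree(phy, stats::setNames(types, phy$tip.label))
    S <- sort(unique(types))
    unit <- matrix(1, length(S), length(S)); diag(unit) <- 0
    dimnames(unit) <- list(S, S)
    f <- infer_ancestral_types(tt, "fitch")
    s <- infer_ancestral_types(tt, "sankoff", costs = unit)
    expect_equal(attr(f$node_types, "parsimony_cost"),
                 attr(s$node_types, "parsimony_cost"))
  }
})

test_that("unit-cost minimum change counts agree with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    phy <- random_tip_tree(n)
    types <- sample.int(3, n, replace = TRUE)
    tt <- time_tree(phy, stats::setNames(types, phy$tip.label))
    fit <- infer_ancestral_types(tt, "fitch")
    dat <- phangorn::phyDat(matrix(as.character(types), ncol = 1,
                                   dimnames = list(phy$tip.label, NULL)),
                            type = "USER", levels = as.character(1:3))
    expect_equal(unname(attr(fit$node_types, "parsimony_cost")),
                 as.numeric(phangorn::fitch(phy, dat)))
  }
})

test_that("unmapped tips are reported by name", {
  phy <- random_tip_tree(4)
  tt <- time_tree(phy, stats::setNames(c(1L, NA, 2L, NA), phy$tip.label))
  expect_error(infer_ancestral_types(tt), "unmapped tips: t2, t4")
  expect_error(time_tree(phy, c(t1 = 1L)), "unmapped tips")
})

test_that("pruning preserves ages and grafting is invertible", {
  cfg <- sim_config(n_families = 4, tips_per_family = c(2, 3), seed = 12)
  tt <- simulate_tree(cfg)
  before <- ape::Ntip(tt$phylo)
  fams <- unique(tt$taxon)
  pruned <- edit_tree(tt, prune = fams[1])
  expect_false(any(pruned$taxon %in% fams[1]))
  expect_lt(ape::Ntip(pruned$phylo), before)
  # branch fusion: every surviving node keeps an age the tree already had
  a0 <- node_ages(tt$phylo); a1 <- node_ages(pruned$phylo)
  expect_true(all(abs(a1[seq_len(ape::Ntip(pruned$phylo))]) < 1e-6))
  expect_true(all(vapply(a1, function(a) any(abs(a0 - a) < 1e-6),
                         logical(1))))
  # empty edit: identical tree
  same <- edit_tree(tt)
  expect_identical(ape::write.tree(same$phylo), ape::write.tree(tt$phylo))
  # graft then prune the same tip restores the original
  g <- data.frame(label = "extra_tip", attach_to = tt$phylo$tip.label[2],
                  attach_age = 4, taxon = "FamX", type = 1L,
                  stringsAsFactors = FALSE)
  round <- edit_tree(edit_tree(tt, graft = g), prune = "extra_tip")
  expect_equal(sort(round$phylo$tip.label), sort(tt$phylo$tip.label))
  expect_equal(sort(node_ages(round$phylo)), sort(node_ages(tt$phylo)),
               tolerance = 1e-6)
  expect_error(edit_tree(tt, prune = "NoSuchFamily"), "unknown taxon")
})

test_that("interval totals land in the slice containing the node age", {
  phy <- ape::read.tree(text = "((t1:5,t2:5):7,t3:12);")
  tt <- time_tree(phy, c(t1 = 1L, t2 = 2L, t3 = 1L))
  fit <- infer_ancestral_types(tt, "fitch")
  rs <- c("1" = 0, "2" = 6)
  sl <- slice_and_accumulate(fit, rs, width = 5)
  a <- sl[sl$taxon == "all", ]
  # the type-2 tip sits at age 0 -> slice [0,5); every other node is type 1
  expect_equal(a$total_rs[a$interval_start == 5], 6)
  expect_equal(sum(a$total_rs), 6)
  expect_equal(a$cumulative_rs[a$interval_start == 5], max(a$cumulative_rs))
  # an internal node of RS 6 at age 12 lands in the [10, 15) slice
  phy2 <- ape::read.tree(text = "((t1:12,t2:12):3,t3:15);")
  tt2 <- time_tree(phy2, c(t1 = 2L, t2 = 2L, t3 = 1L))
  fit2 <- infer_ancestral_types(tt2, "fitch")
  sl2 <- slice_and_accumulate(fit2, rs, width = 5, include_tips = FALSE)
  a2 <- sl2[sl2$taxon == "all", ]
  expect_equal(a2$total_rs[a2$interval_start == 15], 6)
  expect_equal(sum(a2$total_rs), 6)
  expect_true(all(diff(a2$cumulative_rs) >= 0))
})

test_that("cumulative curves are non-decreasing and partition-additive", {
  cfg <- sim_config(n_families = 4, tips_per_family = c(2, 4),
                    rates = c(translocation = 6e-3, inversion = 6e-4,
                              duplication = 1.5e-3, cr_duplication = 3e-3,
                              loss = 6e-4), seed = 21)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  st <- sim_to_time_tree(sim)
  fit <- infer_ancestral_types(st$tree, "fitch")
  m <- rs_matrix(st$types, "qmgr")
  ref_id <- st$types[[1]]$type_id
  sl <- slice_and_accumulate(fit, m, reference_id = ref_id, width = 5,
                             n_intervals = 34)
  for (g in unique(sl$taxon)) {
    expect_true(all(diff(sl$cumulative_rs[sl$taxon == g]) >= 0))
  }
  allr <- sl[sl$taxon == "all", ]
  parts <- sl[sl$taxon != "all", ]
  by_int <- tapply(parts$total_rs, parts$interval_start, sum)
  expect_equal(as.numeric(by_int[as.character(allr$interval_start)]),
               allr$total_rs)
  expect_equal(max(allr$cumulative_rs), sum(allr$total_rs))
})

test_that("all-reference assignments give an all-zero series", {
  phy <- random_tip_tree(5)
  tt <- time_tree(phy, stats::setNames(rep(3L, 5), phy$tip.label))
  fit <- infer_ancestral_types(tt)
  sl <- slice_and_accumulate(fit, c("3" = 0), width = 5)
  expect_true(all(sl$total_rs == 0))
  expect_true(all(sl$cumulative_rs == 0))
})

test_that("branch-delta mode charges changes to the child's slice", {
  phy <- ape::read.tree(text = "((t1:5,t2:5):7,t3:12);")
  tt <- time_tree(phy, c(t1 = 1L, t2 = 2L, t3 = 1L))
  fit <- infer_ancestral_types(tt, "fitch")
  m <- matrix(c(0, 6, 6, 0), 2, dimnames = list(1:2, 1:2))
  sl <- slice_and_accumulate(fit, m, width = 5, mode = "branch")
  a <- sl[sl$taxon == "all", ]
  expect_equal(sum(a$total_rs), 6)             # one change, on t2's branch
  expect_equal(a$total_rs[a$interval_start == 5], 6)
})

test_that("time trees round-trip through newick plus tip map", {
  cfg <- sim_config(n_families = 3, tips_per_family = c(2, 3), seed = 31)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  st <- sim_to_time_tree(sim)
  dir <- tempfile(); dir.create(dir)
  paths <- write_time_tree(st$tree, dir)
  back <- read_time_tree(paths["newick"], paths["tipmap"])
  expect_equal(sort(back$phylo$tip.label), sort(st$tree$phylo$tip.label))
  expect_identical(back$tip_types[st$tree$phylo$tip.label],
                   st$tree$tip_types)
  expect_equal(max(node_ages(back)), max(node_ages(st$tree)),
               tolerance = 1e-6)
})
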