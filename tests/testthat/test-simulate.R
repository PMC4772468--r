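test_that("branch simulation honors degenerate rate settings", {
  still <- simulate_branch(c(0, 1, 5), list(b = 0, d = 0, i = 0), 10)
  expect_equal(still$state, c(0L, 1L, 5L))
  expect_equal(still$births + still$deletions + still$innovations,
               rep(0L, 3))

  set.seed(1)
  grow <- simulate_branch(rep(2L, 500), list(b = 0.4, d = 0, i = 0), 3)
  expect_true(all(grow$state >= 2))       # monotone paths without deletion
  expect_true(all(grow$deletions == 0L))
})

test_that("single-branch mean matches the linear birth-death closed form", {
  set.seed(2)
  b <- 0.2; d <- 0.1; t <- 5; k0 <- 2; n <- 1e4
  s <- simulate_branch(rep(k0, n), list(b = b, d = d, i = 0), t)
  expected <- k0 * exp((b - d) * t)      # 3.2974
  mc_se <- sd(s$state) / sqrt(n)
  expect_lt(abs(mean(s$state) - expected), 3 * mc_se)
})

test_that("event logs conserve flux along every path", {
  set.seed(3)
  tr <- fixture_tree()
  cl <- uniform_classes(tr)
  sim <- simulate_family(tr, cl, list(all = rate_spec("B_I_D", c(0.2, 0.15))),
                         root_state = 2, seed = 9)
  tv <- famflux:::tree_traversal(tr, cl)
  for (e in seq_len(nrow(tv$edge))) {
    par <- tv$edge[e, 1]; ch <- tv$edge[e, 2]
    row <- sim$events[sim$events$branch == ch, ]
    expect_equal(sim$node_states[ch] - sim$node_states[par],
                 row$births + row$innovations - row$deletions)
  }
})

test_that("simulated datasets are reproducible and family-substream stable", {
  tr <- fixture_tree()
  cl <- uniform_classes(tr)
  cfg <- list(YS = list(n = 5, rates = list(all = rate_spec("L_I", 0.1)),
                        root_state = 1),
              AG = list(n = 3, rates = list(all = rate_spec("L", 0.2)),
                        root_state = 2))
  a <- simulate_dataset(tr, cl, cfg, seed = 4)
  b <- simulate_dataset(tr, cl, cfg, seed = 4)
  expect_identical(a$tip_states, b$tip_states)
  expect_equal(length(a$category), 8)
  expect_equal(as.integer(table(a$truth$category)[c("AG", "YS")]),
               c(3L, 5L) * ape::Ntip(tr))

  ## adding families to a later category never changes earlier draws
  cfg2 <- cfg
  cfg2$AG$n <- 6
  c_ <- simulate_dataset(tr, cl, cfg2, seed = 4)
  ys <- grep("^YS", rownames(a$tip_states), value = TRUE)
  expect_identical(a$tip_states[ys, ], c_$tip_states[ys, ])
})

test_that("category with zero rates keeps the root state everywhere", {
  tr <- fixture_tree()
  cl <- uniform_classes(tr)
  sim <- simulate_dataset(tr, cl,
    list(AutS = list(n = 4, rates = list(all = rate_spec("L", 0)),
                     root_state = 1)), seed = 5)
  expect_true(all(sim$tip_states == 1L))
})

test_that("observation emulation respects SEs, masks, and detection", {
  tr <- fixture_tree()
  cl <- uniform_classes(tr)
  sim <- simulate_dataset(tr, cl,
    list(AG = list(n = 3, rates = list(all = rate_spec("L", 0)),
                   root_state = 2)), seed = 6)
  ## SE = 0: observed means equal truth exactly
  obs0 <- emulate_observations(sim, modes = c(AG = "qpcr"), qpcr_se = 0,
                               seed = 8)
  expect_true(all(obs0$obs_type == "qpcr"))
  expect_equal(obs0$mean, rep(2, nrow(obs0)))

  ## fully masked: all rows missing, no numeric leakage
  obsm <- emulate_observations(sim, modes = c(AG = "qpcr"),
    mask = list(list(categories = "AG", taxa = tr$tip.label)), seed = 8)
  expect_true(all(obsm$obs_type == "missing"))
  expect_true(all(is.na(obsm$mean)) && all(is.na(obsm$se)) &&
              all(is.na(obsm$n_unique)))

  ## sampling check: empirical mean of the qPCR noise is centred on truth
  set.seed(9)
  draws <- replicate(2000, {
    o <- emulate_observations(sim, modes = c(AG = "qpcr"), qpcr_se = 0.2,
                              seed = sample.int(1e6, 1))
    o$mean[1]
  })
  expect_lt(abs(mean(draws) - 2), 3 * sd(draws) / sqrt(length(draws)) + 0.01)
})

test_that("the study fixture has the declared shape and satisfies invariants", {
  fx <- study_fixture(1, n_families = c(AutS = 40, AutM = 16, YS = 16, AG = 8))
  expect_equal(ape::Ntip(fx$tree), 17)
  expect_setequal(unique(fx$observations$category),
                  c("AutS", "AutM", "YS", "AG"))
  ## autosomal data only at human/chimp/rhesus; other macaques missing
  aut <- fx$observations[fx$observations$category %in% c("AutS", "AutM"), ]
  masked <- aut[!aut$taxon %in% c("Homo_sapiens", "Pan_troglodytes",
                                  "M_mulatta"), ]
  expect_true(all(masked$obs_type == "missing"))
  expect_true(all(is.na(masked$mean)))
  ## Y families observed at every leaf
  ys <- fx$observations[fx$observations$category == "YS", ]
  expect_setequal(unique(ys$taxon), fx$tree$tip.label)
  expect_true(all(ys$obs_type == "sequence-count"))
  ag <- fx$observations[fx$observations$category == "AG", ]
  expect_true(all(ag$obs_type %in% c("qpcr", "missing")))
  ses <- ag$se[!is.na(ag$se)]
  expect_true(all(ses >= 0.05 & ses <= 0.5))
  ## table invariants: every (family, taxon) profiled, weights in [0, 1]
  expect_s3_class(fx$table, "gene_family_table")
  expect_equal(dim(fx$table$profiles)[2], 17)
  expect_true(all(fx$table$profiles >= 0 & fx$table$profiles <= 1))
  expect_true(all(apply(fx$table$profiles, c(2, 3), max) > 0))
  ## identical seed reproduces the fixture
  fy <- study_fixture(1, n_families = c(AutS = 40, AutM = 16, YS = 16, AG = 8))
  expect_identical(fx$observations, fy$observations)
})

test_that("fixtures serialize to plain-text files with provenance", {
  fx <- study_fixture(2, n_families = c(AutS = 5, AutM = 3, YS = 2, AG = 2))
  prefix <- file.path(withr::local_tempdir(), "run1")
  paths <- write_fixture(fx, prefix)
  expect_true(all(file.exists(paths)))
  back <- parse_newick(readLines(paths[1]))
  expect_setequal(back$tip.label, fx$tree$tip.label)
  obs <- read.delim(paths[3])
  expect_equal(nrow(obs), nrow(fx$observations))
  prov <- jsonlite::read_json(paths[6])
  expect_equal(prov$seed, 2)
})
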