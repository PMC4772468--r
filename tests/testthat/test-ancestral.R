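test_that("ancestral marginals normalize and honor zero-branch identities", {
  n_max <- 4
  tr <- parse_newick("(A:0,B:0);")
  cl <- uniform_classes(tr)
  fit <- manual_fit("L", list(all = rate_spec("L", 0.3)),
                    root_prior("L", n_max))
  profs <- point_profiles(tr, c(2, 2), n_max)
  post <- ancestral_marginals(fit, tr, cl, profs)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)))
  root <- famflux:::root_node(tr)
  expect_equal(unname(post[root, "2"]), 1)   # zero branches force the parent
})

test_that("marginals match brute-force joint enumeration on small trees", {
  set.seed(33)
  for (rep in 1:8) {
    n_leaves <- sample(3:5, 1)
    n_max <- sample(2:4, 1)
    tr <- random_small_tree(n_leaves)
    cl <- uniform_classes(tr)
    form <- sample(model_forms(), 1)
    rs <- random_rates(form)
    prior <- root_prior(form, n_max)
    profs <- point_profiles(tr, sample(0:n_max, n_leaves, replace = TRUE),
                            n_max)
    fit <- manual_fit(form, list(all = rs), prior)
    bf <- brute_tree_posterior(tr, cl, list(all = rs), profs, prior)
    post <- suppressWarnings(ancestral_marginals(fit, tr, cl, profs))
    expect_lt(max(abs(post[bf$internal, ] - bf$post[bf$internal, ])), 1e-10)
  }
})

test_that("MAP states take the argmax with ties broken toward smaller states", {
  post <- structure(rbind(c(0.2, 0.5, 0.3), c(0, 0, 1), c(0.5, 0.5, 0)),
                    dimnames = list(1:3, 0:2), class = "ancestral_posterior")
  m <- map_states(post)
  expect_equal(as.integer(unname(m)), c(1L, 2L, 0L))
  expect_equal(unname(attr(m, "ties")), c(FALSE, FALSE, TRUE))
})

test_that("expected events vanish on zero branches and for zero rates", {
  n_max <- 3
  tr <- parse_newick("(A:0,B:1);")
  cl <- uniform_classes(tr)
  fit <- manual_fit("BD", list(all = rate_spec("BD", c(0.4, 0))),
                    root_prior("BD", n_max))
  profs <- point_profiles(tr, c(2, 2), n_max)
  e0 <- expected_branch_events(fit, tr, cl, profs, "A", "deletion")
  expect_equal(e0$expectation, 0)
  ed <- expected_branch_events(fit, tr, cl, profs, "B", "deletion")
  expect_equal(ed$expectation, 0)  # d = 0
  expect_warning(
    ei <- expected_branch_events(fit, tr, cl, profs, "B", "innovation"),
    "innovation rate is 0")
  expect_equal(ei$expectation, 0)
})

test_that("analytic event expectations match rejection-sampled stochastic mapping", {
  set.seed(71)
  tr <- parse_newick("(A:1.2,B:0.7);")
  cl <- uniform_classes(tr)
  n_max <- 12
  for (rep in 1:6) {
    form <- sample(c("B_I_D", "BD", "L_I"), 1)
    rs <- random_rates(form)
    ## root prior restricted to small states so acceptance stays workable
    prior <- numeric(n_max + 1)
    lo <- if (famflux:::form_has_innovation(form)) 0 else 1
    prior[(lo:3) + 1] <- 1 / length(lo:3)
    tips <- sample(0:3, 2, replace = TRUE)
    profs <- point_profiles(tr, tips, n_max)
    fit <- manual_fit(form, list(all = rs), prior)
    type <- sample(c("birth", "deletion", "innovation"), 1)
    ana <- suppressWarnings(
      expected_branch_events(fit, tr, cl, profs, "A", type))$expectation
    root <- sample(0:n_max, 3e5, replace = TRUE, prob = prior)
    sA <- simulate_branch(root, rs, 1.2)
    sB <- simulate_branch(root, rs, 0.7)
    acc <- sA$state == tips[1] & sB$state == tips[2]
    cnt <- switch(type, birth = sA$births, deletion = sA$deletions,
                  innovation = sA$innovations)[acc]
    n_acc <- length(cnt)
    ## Poisson floor keeps the SE estimate sane when events are rare
    se_eff <- sqrt((stats::var(cnt) + ana + 1e-12) / n_acc)
    expect_lt(abs(ana - mean(cnt)), 3 * se_eff)
    expect_gt(n_acc, 1e3)
  }
})

test_that("flux conservation: expected births minus deletions track state change", {
  ## sum over both branches of E[births - deletions | data] equals
  ## E[tip states | data] - 2 E[root | data] on a two-leaf tree
  set.seed(72)
  tr <- parse_newick("(A:0.9,B:1.4);")
  cl <- uniform_classes(tr)
  n_max <- 14
  rs <- rate_spec("BD", c(0.3, 0.2))
  prior <- numeric(n_max + 1); prior[2:4] <- 1 / 3
  profs <- point_profiles(tr, c(2, 3), n_max)
  fit <- manual_fit("BD", list(all = rs), prior)
  net <- 0
  for (br in c("A", "B")) {
    net <- net +
      expected_branch_events(fit, tr, cl, profs, br, "birth")$expectation -
      expected_branch_events(fit, tr, cl, profs, br, "deletion")$expectation
  }
  post <- ancestral_marginals(fit, tr, cl, profs)
  root <- famflux:::root_node(tr)
  e_root <- sum(as.numeric(colnames(post)) * post[root, ])
  expect_equal(net, (2 + 3) - 2 * e_root, tolerance = 1e-8)
})

test_that("model averaging is a convex combination of per-model expectations", {
  fx <- study_fixture(21, n_families = c(AutS = 0, AutM = 0, YS = 0, AG = 4))
  red <- enumerate_model_space(forms = c("L", "BD"), het_options = FALSE,
                               partitions = "AutS|AutM|YS|AG")
  ## AG-only table: restrict the partition to the one available category
  red <- lapply(red, function(m) {
    m$blocks <- Filter(function(b) "AG" %in% b$categories, m$blocks)
    m$k <- sum(vapply(m$blocks, function(b) {
      famflux:::form_n_par(b$form) * (if (b$het) 2L else 1L)
    }, integer(1)))
    m
  })
  red <- red[!duplicated(vapply(red, function(m) m$blocks[[1]]$form,
                                character(1)))]
  for (j in seq_along(red)) red[[j]]$model_id <- j
  sc <- fit_model_space(fx$table, fx$tree, fx$classes, models = red)
  fams <- table_families(fx$table, "AG")
  rhesus_branch <- "M_mulatta"
  per_model <- vapply(seq_len(nrow(sc)), function(r) {
    fits <- model_block_fits(sc, sc$model_id[r])
    sum(vapply(fams, function(f) {
      expected_branch_events(fits[[1]], fx$tree, fx$classes,
                             profiles_of_family(fx$table, f),
                             rhesus_branch, "deletion")$expectation
    }, numeric(1)))
  }, numeric(1))
  avg <- model_averaged_events(sc, fx$table, fx$tree, fx$classes, fams,
                               rhesus_branch, "deletion")
  expect_gte(avg, min(per_model) - 1e-9)
  expect_lte(avg, max(per_model) + 1e-9)
  expect_equal(avg, sum(sc$weight * per_model), tolerance = 1e-8)
})

test_that("presence-call metrics count the confusion table", {
  ref <- c(n1 = TRUE, n2 = TRUE, n3 = FALSE, n4 = FALSE)
  calls <- c(n1 = TRUE, n2 = FALSE, n3 = FALSE, n4 = TRUE)
  m <- presence_call_metrics(calls, ref)
  expect_equal(m[c("tp", "fn", "tn", "fp")], list(tp = 1, fn = 1, tn = 1, fp = 1))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)

  perfect <- presence_call_metrics(ref, ref)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  allp <- presence_call_metrics(c(a = TRUE, b = TRUE), c(a = TRUE, b = TRUE))
  expect_true(is.na(allp$specificity))

  chr <- presence_call_metrics(c(a = "present", b = "absent"),
                               c(a = "present", b = "present"))
  expect_equal(chr$tp, 1); expect_equal(chr$fn, 1)
  expect_error(presence_call_metrics(c(a = TRUE), c(b = TRUE)), "same keys")
})

test_that("presence references load from two-column TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node\tstate", "n1\tpresent", "n2\tabsent", "n3\tP"), path)
  ref <- read_presence_tsv(path)
  expect_equal(ref, c(n1 = TRUE, n2 = FALSE, n3 = TRUE))
})
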