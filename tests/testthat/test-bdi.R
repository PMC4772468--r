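test_that("rate matrices have copy-proportional tridiagonal structure", {
  Q <- build_rate_matrix(rate_spec("L", 1), 2)
  expect_equal(unname(Q), rbind(c(0, 0, 0), c(1, -2, 1), c(0, 2, -2)))

  Qi <- build_rate_matrix(list(b = 1, d = 1, i = 0.5), 2)
  expect_equal(unname(Qi[1, ]), c(-0.5, 0.5, 0))

  Qbd <- build_rate_matrix(rate_spec("BD", c(2, 1)), 3)
  expect_equal(Qbd["1", "2"], 2)
  expect_equal(Qbd["2", "3"], 4)
  expect_equal(Qbd["3", "2"], 3)
  expect_equal(Qbd["3", "3"], -3)
  expect_true(all(abs(rowSums(Qbd)) < 1e-12))
  expect_error(build_rate_matrix(list(b = -1, d = 1, i = 0), 2), "non-negative")
})

test_that("model forms tie parameters as declared", {
  expect_equal(rate_spec("L", 0.3)[c("b", "d", "i")],
               list(b = 0.3, d = 0.3, i = 0))
  expect_equal(rate_spec("L_I", 0.3)[c("b", "d", "i")],
               list(b = 0.3, d = 0.3, i = 0.3))
  expect_equal(rate_spec("B_I_D", c(0.4, 0.1))[c("b", "d", "i")],
               list(b = 0.4, d = 0.1, i = 0.4))
  expect_equal(rate_spec("L_indI", c(0.2, 0.05))[c("b", "d", "i")],
               list(b = 0.2, d = 0.2, i = 0.05))
  expect_error(rate_spec("BD", 0.3), "free parameter")
})

test_that("transition matrices: identity at t = 0, stochastic rows, closed form", {
  Q <- build_rate_matrix(rate_spec("BD", c(0.4, 0.2)), 5)
  expect_equal(transition_matrix(Q, 0), diag(6))
  P5 <- transition_matrix(Q, 5)
  expect_lt(max(abs(rowSums(P5) - 1)), 1e-10)
  expect_true(all(P5 >= 0 & P5 <= 1))
  ## two-state chain: P00(t) = (d + i e^{-(i+d)t}) / (i + d)
  Q2 <- build_rate_matrix(list(b = 0, d = 1, i = 1), 1)
  expect_equal(transition_matrix(Q2, log(2))[1, 1], 0.625, tolerance = 1e-10)
  expect_error(transition_matrix(Q, -1), "finite")
})

test_that("Chapman-Kolmogorov holds for random generators", {
  set.seed(21)
  for (rep in 1:5) {
    rs <- random_rates()
    Q <- build_rate_matrix(rs, 6)
    t1 <- runif(1, 0.1, 3); t2 <- runif(1, 0.1, 3)
    lhs <- transition_matrix(Q, t1 + t2)
    rhs <- transition_matrix(Q, t1) %*% transition_matrix(Q, t2)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("state 0 is absorbing without innovation and mass drifts to it", {
  Q <- build_rate_matrix(rate_spec("L", 0.5), 4)
  P <- transition_matrix(Q, 2)
  expect_equal(unname(P[1, -1]), rep(0, 4))
  ## limiting distribution at zero: extinction mass grows with t
  p_ext <- vapply(c(1, 10, 100, 1000),
                  function(t) transition_matrix(Q, t)[2, 1], numeric(1))
  expect_true(all(diff(p_ext) > 0))
  expect_gt(p_ext[4], 0.97)
})

test_that("likelihood is invariant to rate/time rescaling", {
  set.seed(22)
  tr <- random_small_tree(4)
  cl <- uniform_classes(tr)
  profs <- point_profiles(tr, c(1, 2, 0, 1), 3)
  rs <- rate_spec("B_I_D", c(0.3, 0.6))
  ll1 <- family_log_likelihood(tr, cl, list(all = rs), profs)
  c_ <- 3.7
  tr2 <- tr; tr2$edge.length <- tr$edge.length / c_
  rs2 <- rate_spec("B_I_D", c(0.3, 0.6) * c_)
  ll2 <- family_log_likelihood(tr2, cl, list(all = rs2), profs)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(23)
  for (rep in 1:12) {
    n_leaves <- sample(2:5, 1)
    n_max <- sample(2:4, 1)
    tr <- random_small_tree(n_leaves)
    cl <- uniform_classes(tr)
    form <- sample(model_forms(), 1)
    rs <- random_rates(form)
    prior <- root_prior(form, n_max)
    profs <- point_profiles(tr, sample(0:n_max, n_leaves, replace = TRUE), n_max)
    bf <- brute_tree_posterior(tr, cl, list(all = rs), profs, prior)
    ll <- family_log_likelihood(tr, cl, list(all = rs), profs, prior = prior)
    if (is.finite(bf$loglik)) {
      expect_equal(ll, bf$loglik, tolerance = 1e-10)
    } else {
      expect_equal(ll, -Inf)
    }
  }
})

test_that("pruning handles uncertain tips and lineage classes against the oracle", {
  set.seed(24)
  tr <- parse_newick("((a:0.6,b:1.1):0.7,(c:0.4,d:0.9):1.3);")
  cl <- assign_clade_class(tr, c("a", "b"), "fast", "slow")
  n_max <- 3
  for (rep in 1:5) {
    rates <- list(fast = random_rates("BD"), slow = random_rates("BD"))
    prior <- root_prior("BD", n_max)
    profs <- list(a = qpcr_profile(2, 0.4, n_max), b = missing_profile(n_max),
                  c = sequence_min_profile(1, n_max), d = count_profile(2, n_max))
    bf <- brute_tree_posterior(tr, cl, rates, profs, prior)
    ll <- family_log_likelihood(tr, cl, rates, profs, prior = prior)
    expect_equal(ll, bf$loglik, tolerance = 1e-10)
  }
})

test_that("degenerate pruning cases: zero branches and all-missing tips", {
  ## two-leaf tree with zero branches and point-mass tips at state 1,
  ## uniform root prior over {1, 2}: likelihood = 1/2
  tr <- parse_newick("(A:0,B:0);")
  cl <- uniform_classes(tr)
  rs <- rate_spec("L", 0.4)
  prior <- c(0, 0.5, 0.5)
  profs <- point_profiles(tr, c(1, 1), 2)
  ll <- family_log_likelihood(tr, cl, list(all = rs), profs, prior = prior)
  expect_equal(ll, log(0.5), tolerance = 1e-12)
  ## all tips missing: likelihood 1 under any normalized prior
  tr2 <- parse_newick("((A:1,B:2):1,C:3);")
  cl2 <- uniform_classes(tr2)
  profs2 <- setNames(lapply(1:3, function(i) missing_profile(4)), tr2$tip.label)
  ll2 <- family_log_likelihood(tr2, cl2, list(all = rate_spec("L_I", 0.3)), profs2)
  expect_equal(ll2, 0, tolerance = 1e-10)
})
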