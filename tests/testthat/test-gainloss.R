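test_that("transition matrix has the closed form and its limits", {
  expect_equal(transition_matrix(0.7, 0.3, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_matrix(0, 0, 5), diag(2), ignore_attr = TRUE)
  # long-time limit: rows converge to the stationary distribution
  P <- transition_matrix(0.7, 0.3, 1e6)
  expect_equal(unname(P[1, ]), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(unname(P[2, ]), c(0.3, 0.7), tolerance = 1e-12)
  expect_error(transition_matrix(1, 1, -1), "negative")

  # matches the matrix exponential (scaled-and-squared series) on random
  # rates and times
  set.seed(5)
  expm_oracle <- function(Q, t) {
    s <- max(0L, ceiling(log2(max(1e-12, sum(abs(Q * t))))))
    A <- Q * t / 2^s
    E <- diag(2); term <- diag(2)
    for (k in 1:40) { term <- term %*% A / k; E <- E + term }
    for (i in seq_len(s)) E <- E %*% E
    E
  }
  for (i in 1:100) {
    g <- rexp(1); l <- rexp(1); t <- rexp(1)
    Q <- matrix(c(-g, l, g, -l), 2, 2)
    expect_equal(unname(transition_matrix(g, l, t)), expm_oracle(Q, t),
                 tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration, including uncertain tips", {
  set.seed(11)
  for (i in 1:30) {
    tr <- random_tree(sample(3:7, 1))
    labs <- tr$label[tr$event == "leaf"]
    states <- setNames(sample(c(0L, 1L, 2L), length(labs), replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)), labs)
    g <- rexp(1); l <- rexp(1)
    rootp <- c(0.4, 0.6)
    expect_equal(pruning_loglik(tr, states, g, l, root_prior = rootp),
                 brute_loglik(tr, states, g, l, rootp), tolerance = 1e-9)
  }
})

test_that("degenerate likelihoods match closed forms", {
  one <- read_nhx("(a:0.5)r;")
  # a single observed-absent tip under a gain-free chain started absent
  expect_equal(pruning_loglik(one, c(a = 0L), g = 0, l = 1,
                              root_prior = c(1, 0)), 0)
  # total missingness carries no information
  tr <- tiny_tree()
  states <- setNames(rep(2L, 4), c("a", "b", "c", "d"))
  expect_equal(pruning_loglik(tr, states, 0.7, 0.4), 0)
})

test_that("marginals match enumeration and respect observed tips", {
  set.seed(13)
  for (i in 1:10) {
    tr <- random_tree(sample(3:6, 1))
    labs <- tr$label[tr$event == "leaf"]
    states <- setNames(sample(0:1, length(labs), replace = TRUE), labs)
    g <- rexp(1); l <- rexp(1)
    rootp <- c(0.5, 0.5)
    mp <- marginal_posteriors(tr, states, g, l, root_prior = rootp)
    for (nd in sample(tr$node, 3)) {
      expect_equal(unname(mp[1, as.character(nd)]),
                   brute_marginal(tr, states, g, l, rootp, nd),
                   tolerance = 1e-9)
    }
    tips <- tr$node[tr$event == "leaf"]
    expect_equal(unname(mp[1, as.character(tips)]),
                 unname(states[tr$label[match(tips, tr$node)]]))
  }
})

test_that("a symmetric tree with symmetric rates gives a 0.5 root marginal", {
  tr <- read_nhx("(a:0.4,b:0.4)r;")
  mp <- marginal_posteriors(tr, c(a = 1L, b = 0L), g = 1, l = 1,
                            root_prior = "stationary")
  expect_equal(unname(mp[1, "1"]), 0.5, tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting at stationarity", {
  # same 3-tip unrooted tree rooted on two different edges
  t1 <- read_nhx("((a:0.3,b:0.5)x:0.2,c:0.6)r;")
  t2 <- read_nhx("((a:0.3,c:0.8)x:0.2,b:0.3)r;") # same path lengths a-b, a-c, b-c
  g <- 0.8; l <- 0.5
  for (pat in list(c(a = 1L, b = 0L, c = 1L), c(a = 0L, b = 0L, c = 1L))) {
    expect_equal(pruning_loglik(t1, pat, g, l, root_prior = "stationary"),
                 pruning_loglik(t2, pat, g, l, root_prior = "stationary"),
                 tolerance = 1e-9)
  }
})

test_that("prior-only MCMC recovers the exponential-mixture prior quantiles", {
  tr <- tiny_tree()
  states <- matrix(2L, 1, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  fit <- mcmc_sample(states, tr, n_iter = 40000, tuning_iter = 1000,
                     tuning_interval = 200, thin = 10, seed = 4,
                     use_likelihood = FALSE)
  # marginal prior P(g <= x) = x / (1 + x): median 1, quartiles 1/3 and 3
  qs <- quantile(fit$samples$g, c(0.25, 0.5, 0.75))
  expect_equal(unname(qs[2]), 1, tolerance = 0.25)
  expect_equal(unname(qs[1]), 1 / 3, tolerance = 0.3)
  expect_equal(unname(qs[3]), 3, tolerance = 0.35)
})

test_that("MCMC is deterministic under a fixed seed and reports diagnostics", {
  tr <- tiny_tree()
  set.seed(99)
  states <- matrix(sample(0:1, 40, replace = TRUE), 10, 4,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  f1 <- mcmc_sample(states, tr, n_iter = 1000, tuning_iter = 200,
                    tuning_interval = 100, thin = 5, seed = 21)
  f2 <- mcmc_sample(states, tr, n_iter = 1000, tuning_iter = 200,
                    tuning_interval = 100, thin = 5, seed = 21)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$ancestral, f2$ancestral)
  expect_true(all(is.finite(f1$ess)))
  expect_true(all(f1$acceptance > 0.1 & f1$acceptance < 0.7))
})

test_that("posterior credible intervals cover the simulating rates", {
  # matched two-state simulation at (g, l) = (2, 1)
  tr <- tiny_tree()
  tips <- c("a", "b", "c", "d")
  sim_matrix <- function(n_loci, g, l) {
    kids <- iesevo:::tree_children(tr)
    out <- matrix(0L, n_loci, length(tips), dimnames = list(NULL, tips))
    for (c in seq_len(n_loci)) {
      st <- setNames(integer(nrow(tr)), tr$node)
      root <- iesevo:::tree_root(tr)
      st[as.character(root)] <- rbinom(1, 1, g / (g + l))
      for (v in rev(iesevo:::tree_postorder(tr))) {
        if (v == root) next
        p <- tr$parent[tr$node == v]
        P <- transition_matrix(g, l, tr$length[tr$node == v])
        st[as.character(v)] <- rbinom(1, 1, P[st[[as.character(p)]] + 1, 2])
      }
      leaves <- tr$node[tr$event == "leaf"]
      v <- st[as.character(leaves)]
      names(v) <- tr$label[match(leaves, tr$node)]
      out[c, ] <- v[tips]
    }
    out
  }
  set.seed(31)
  cover_g <- cover_l <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    m <- sim_matrix(80, 2, 1)
    fit <- mcmc_sample(m, tr, n_iter = 3000, tuning_iter = 400,
                       tuning_interval = 100, thin = 5, seed = 100 + r)
    ci_g <- quantile(fit$samples$g, c(0.025, 0.975))
    ci_l <- quantile(fit$samples$l, c(0.025, 0.975))
    cover_g <- cover_g + (ci_g[1] <= 2 && 2 <= ci_g[2])
    cover_l <- cover_l + (ci_l[1] <= 1 && 1 <= ci_l[2])
  }
  expect_gte(cover_g / n_rep, 0.9)
  expect_gte(cover_l / n_rep, 0.9)
})
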