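## Two-rate presence/absence continuous-time Markov model on a fixed
## (gene) tree: one gain rate g (absent -> present) and one loss rate l
## (present -> absent) shared by all loci of a family, with priors
## g, l ~ Exp(alpha) and hyperprior alpha ~ Exp(1).  The likelihood is
## computed by Felsenstein pruning (compiled); ancestral marginals by the
## standard two-pass up/down algorithm; the posterior is sampled by
## Metropolis-within-Gibbs (exact conjugate Gibbs for alpha).

#' Transition probabilities of the two-state gain/loss chain
#'
#' @param g,l gain and loss rates (>= 0)
#' @param t elapsed branch length (>= 0)
#' @return 2x2 matrix, rows/cols ordered (absent, present)
#' @export
transition_matrix <- function(g, l, t) {
  if (t < 0) stop("negative branch length")
  tot <- g + l
  if (tot == 0) return(diag(2))
  e <- exp(-tot * t)
  p01 <- g / tot * (1 - e)
  p10 <- l / tot * (1 - e)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2, 2,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

## flatten a node table into the arrays the compiled pruning expects
tree_arrays <- function(tree) {
  n <- nrow(tree)
  kids <- tree_children(tree)
  child1 <- child2 <- rep(-1L, n)
  for (v in tree$node) {
    ch <- kids[[as.character(v)]]
    i <- match(v, tree$node)
    if (length(ch) == 2L) {
      child1[i] <- match(ch[1], tree$node) - 1L
      child2[i] <- match(ch[2], tree$node) - 1L
    } else if (length(ch) != 0L) {
      stop("tree must be binary")
    }
  }
  brlen <- ifelse(is.na(tree$parent), 0, tree$length)
  post <- match(tree_postorder(tree), tree$node) - 1L
  root <- match(tree_root(tree), tree$node) - 1L
  list(child1 = child1, child2 = child2, brlen = as.numeric(brlen),
       postorder = post, root = root)
}

## loci x nodes state matrix (codes 0/1/2; -1 on internal columns) from a
## loci x tips matrix whose colnames are tip labels
state_matrix <- function(tree, tip_states) {
  if (is.null(dim(tip_states))) tip_states <- matrix(tip_states, nrow = 1,
    dimnames = list(NULL, names(tip_states)))
  tips <- tree_tips(tree)
  labs <- tree$label[match(tips, tree$node)]
  if (!all(labs %in% colnames(tip_states))) {
    stop("unlabeled tip: tip states missing for ",
         paste(setdiff(labs, colnames(tip_states)), collapse = ", "))
  }
  m <- matrix(-1L, nrow = nrow(tip_states), ncol = nrow(tree))
  m[, match(tips, tree$node)] <- as.integer(tip_states[, labs, drop = FALSE])
  m
}

## "ml" profiles the root state per locus: the likelihood is maximized
## over root present/absent instead of averaged under a prior, which
## keeps ancestral loci from being re-explained as parallel recent gains
## near the root (and vice versa).  Handled in the wrappers below.
## root prior as an nloci x 2 (or recyclable 1 x 2) matrix.  "empirical"
## gives every locus a prior equal to its own smoothed tip prevalence
## (Laplace (k + 0.5) / (n + 1)), an empirical-Bayes choice that keeps
## deep ancestral loci from being re-explained as parallel recent gains.
root_prior_mat <- function(root_prior, g, l, m = NULL) {
  if (is.numeric(root_prior)) {
    if (is.matrix(root_prior)) {
      return(root_prior / rowSums(root_prior))
    }
    return(matrix(root_prior / sum(root_prior), 1L, 2L))
  }
  switch(root_prior,
         stationary = matrix(if (g + l == 0) c(0.5, 0.5) else
           c(l, g) / (g + l), 1L, 2L),
         uniform = matrix(0.5, 1L, 2L),
         empirical = {
           stopifnot(!is.null(m))
           known <- m >= 0L & m != 2L
           k <- rowSums(m == 1L & known)
           n <- rowSums(known)
           p <- (k + 0.5) / (n + 1)
           cbind(1 - p, p)
         },
         stop("unknown root prior: ", root_prior))
}

#' Pruning log-likelihood of a presence/absence matrix
#'
#' Tips coded 0 (absent), 1 (present) or 2 (uncertain; partial likelihood
#' (1,1), i.e. missing data).
#'
#' @param tree node table
#' @param tip_states loci x tips matrix (colnames = tip labels), or a
#'   named vector for a single locus
#' @param g,l gain and loss rates
#' @param root_prior "stationary", "uniform", "empirical" (per-locus
#'   smoothed tip prevalence), "ml" (per-locus profile-maximum-likelihood
#'   root state), a length-2 numeric, or an nloci x 2 matrix
#' @param per_locus return the per-locus vector instead of the sum
#' @return total log-likelihood (or per-locus vector)
#' @export
pruning_loglik <- function(tree, tip_states, g, l,
                           root_prior = "stationary", per_locus = FALSE) {
  if (sum(tree$event == "leaf") == 1L) {
    # pendant chain: root -> ... -> single tip
    m <- state_matrix(tree, tip_states)
    tipcol <- match(tree$node[tree$event == "leaf"], tree$node)
    P <- diag(2)
    v <- tree$node[tree$event == "leaf"]
    while (!is.na(tree$parent[tree$node == v])) {
      P <- transition_matrix(g, l, tree$length[tree$node == v]) %*% P
      v <- tree$parent[tree$node == v]
    }
    rp <- root_prior_mat(root_prior, g, l, m)
    if (nrow(rp) == 1L) rp <- rp[rep(1L, nrow(m)), , drop = FALSE]
    ll <- vapply(seq_len(nrow(m)), function(c) {
      e <- switch(as.character(m[c, tipcol]),
                  "0" = c(1, 0), "1" = c(0, 1), c(1, 1))
      log(sum(rp[c, ] * (P %*% e)))
    }, numeric(1))
    return(if (per_locus) ll else sum(ll))
  }
  ar <- tree_arrays(tree)
  m <- state_matrix(tree, tip_states)
  ll <- loglik_engine(ar, m, g, l, root_prior)
  if (per_locus) ll else sum(ll)
}

## per-locus log-likelihood under any root-prior rule, including the
## profile-ML rule
loglik_engine <- function(ar, m, g, l, root_prior) {
  if (identical(root_prior, "ml")) {
    ll0 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                              ar$root, m, g, l, matrix(c(1, 0), 1L, 2L))
    ll1 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                              ar$root, m, g, l, matrix(c(0, 1), 1L, 2L))
    return(pmax(ll0, ll1))
  }
  rp <- root_prior_mat(root_prior, g, l, m)
  pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                     ar$root, m, g, l, rp)
}

## root-prior matrix actually used for marginals (resolves "ml" to the
## per-locus one-hot argmax)
resolve_root_prior <- function(ar, m, g, l, root_prior) {
  if (identical(root_prior, "ml")) {
    ll0 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                              ar$root, m, g, l, matrix(c(1, 0), 1L, 2L))
    ll1 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                              ar$root, m, g, l, matrix(c(0, 1), 1L, 2L))
    pick <- as.integer(ll1 > ll0)
    return(cbind(1 - pick, pick))
  }
  root_prior_mat(root_prior, g, l, m)
}

#' Marginal ancestral posteriors of IES presence
#'
#' @inheritParams pruning_loglik
#' @return loci x nodes matrix of P(present); columns named by node id
#' @export
marginal_posteriors <- function(tree, tip_states, g, l,
                                root_prior = "stationary") {
  ar <- tree_arrays(tree)
  m <- state_matrix(tree, tip_states)
  rp <- resolve_root_prior(ar, m, g, l, root_prior)
  post <- marginal_posteriors_cpp(ar$child1, ar$child2, ar$brlen,
                                  ar$postorder, ar$root, m, g, l, rp)
  colnames(post) <- tree$node
  post
}

#' Sample the gain/loss posterior by MCMC
#'
#' Metropolis-within-Gibbs over (g, l, alpha): multiplicative log-normal
#' proposals for the rates, whose scales are tuned towards a 20-50%
#' acceptance rate during an initial tuning phase only, and an exact
#' conjugate Gibbs draw for alpha (Gamma(3, g + l + 1)).  Ancestral
#' posteriors are averaged over the retained samples.
#'
#' @param tip_states loci x tips presence matrix (0/1/2)
#' @param tree node table
#' @param n_iter sampling iterations (default 5e5)
#' @param tuning_iter iterations of the tuning phase (default 1e4)
#' @param tuning_interval proposal-scale update interval (default 1e3)
#' @param seed integer seed
#' @param thin keep every `thin`-th sample (default 50)
#' @param burnin_frac fraction of `n_iter` discarded (default 0.1)
#' @param root_prior see [pruning_loglik()]
#' @param use_likelihood set FALSE for a prior-only run
#' @param weights per-row (site-pattern) likelihood weights; rows of
#'   `tip_states` may represent collapsed identical patterns (e.g. the
#'   all-absent pattern of the many well-aligned TA sites that carry no
#'   IES in any species), in which case the weight is the pattern count
#' @return list: `samples` (data.frame g, l, alpha, loglik), `ancestral`
#'   (posterior-mean loci x nodes matrix), `acceptance`, `ess`, `rhat`,
#'   `diagnostic_ok`
#' @export
mcmc_sample <- function(tip_states, tree, n_iter = 500000L,
                        tuning_iter = 10000L, tuning_interval = 1000L,
                        seed = 1L, thin = 50L, burnin_frac = 0.1,
                        root_prior = "stationary", use_likelihood = TRUE,
                        weights = NULL) {
  set.seed(as.integer(seed))
  ar <- tree_arrays(tree)
  m <- state_matrix(tree, tip_states)
  w <- if (is.null(weights)) rep(1, nrow(m)) else as.numeric(weights)
  stopifnot(length(w) == nrow(m))
  sampled_root <- identical(root_prior, "sampled")
  rho <- 0.5
  loglik_fun <- function(g, l, rho_cur = rho) {
    if (!use_likelihood) return(0)
    if (sampled_root) {
      ll0 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                                ar$root, m, g, l, matrix(c(1, 0), 1L, 2L))
      ll1 <- pruning_loglik_cpp(ar$child1, ar$child2, ar$brlen, ar$postorder,
                                ar$root, m, g, l, matrix(c(0, 1), 1L, 2L))
      mx <- pmax(ll0, ll1)
      return(sum(w * (mx + log((1 - rho_cur) * exp(ll0 - mx) +
                                 rho_cur * exp(ll1 - mx)))))
    }
    sum(w * loglik_engine(ar, m, g, l, root_prior))
  }
  g <- 0.5; l <- 0.5; alpha <- 1
  ll <- loglik_fun(g, l)
  if (!is.finite(ll)) {
    for (try in 1:20) {
      g <- rexp(1); l <- rexp(1)
      ll <- loglik_fun(g, l)
      if (is.finite(ll)) break
    }
    if (!is.finite(ll)) {
      stop("cannot initialize the sampler: non-finite starting likelihood")
    }
  }
  sd_g <- 0.5; sd_l <- 0.5
  acc <- c(g = 0L, l = 0L)
  prop <- c(g = 0L, l = 0L)
  # one sweep: MH on g, MH on l (multiplicative proposals with the
  # Jacobian term new/cur), exact Gibbs on alpha
  do_iter <- function() {
    newg <- g * exp(rnorm(1, 0, sd_g))
    newll <- loglik_fun(newg, l)
    logr <- newll - ll - alpha * (newg - g) + log(newg / g)
    prop["g"] <<- prop["g"] + 1L
    if (is.finite(logr) && log(runif(1)) < logr) {
      acc["g"] <<- acc["g"] + 1L; g <<- newg; ll <<- newll
    }
    newl <- l * exp(rnorm(1, 0, sd_l))
    newll <- loglik_fun(g, newl)
    logr <- newll - ll - alpha * (newl - l) + log(newl / l)
    prop["l"] <<- prop["l"] + 1L
    if (is.finite(logr) && log(runif(1)) < logr) {
      acc["l"] <<- acc["l"] + 1L; l <<- newl; ll <<- newll
    }
    if (sampled_root) {
      # logit random-walk on the root-occupancy probability, Unif(0,1) prior
      lo <- log(rho / (1 - rho)) + rnorm(1, 0, 0.5)
      newrho <- 1 / (1 + exp(-lo))
      newll <- loglik_fun(g, l, newrho)
      jac <- log(newrho * (1 - newrho)) - log(rho * (1 - rho))
      if (is.finite(newll) && log(runif(1)) < newll - ll + jac) {
        rho <<- newrho; ll <<- newll
      }
    }
    alpha <<- rgamma(1, shape = 3, rate = g + l + 1)
  }
  keep_g <- keep_l <- keep_a <- keep_ll <- numeric(0)
  anc_sum <- NULL
  n_anc <- 0L
  burn <- floor(burnin_frac * n_iter)
  # tuning phase (discarded)
  if (tuning_iter > 0) {
    acc[] <- 0L; prop[] <- 0L
    for (i in seq_len(tuning_iter)) {
      do_iter()
      if (i %% tuning_interval == 0L) {
        r_g <- acc["g"] / max(prop["g"], 1L)
        r_l <- acc["l"] / max(prop["l"], 1L)
        if (r_g < 0.20) sd_g <- sd_g * 0.7 else if (r_g > 0.50) sd_g <- sd_g * 1.4
        if (r_l < 0.20) sd_l <- sd_l * 0.7 else if (r_l > 0.50) sd_l <- sd_l * 1.4
        acc[] <- 0L; prop[] <- 0L
      }
    }
  }
  acc[] <- 0L; prop[] <- 0L
  for (i in seq_len(n_iter)) {
    do_iter()
    if (i > burn && i %% thin == 0L) {
      keep_g <- c(keep_g, g); keep_l <- c(keep_l, l)
      keep_a <- c(keep_a, alpha); keep_ll <- c(keep_ll, ll)
      if (use_likelihood) {
        rp <- if (sampled_root) matrix(c(1 - rho, rho), 1L, 2L) else
          resolve_root_prior(ar, m, g, l, root_prior)
        anc <- marginal_posteriors_cpp(ar$child1, ar$child2, ar$brlen,
                                       ar$postorder, ar$root, m, g, l, rp)
        anc_sum <- if (is.null(anc_sum)) anc else anc_sum + anc
        n_anc <- n_anc + 1L
      }
    }
  }
  samples <- data.frame(g = keep_g, l = keep_l, alpha = keep_a,
                        loglik = keep_ll)
  ancestral <- if (!is.null(anc_sum)) {
    a <- anc_sum / n_anc
    colnames(a) <- tree$node
    a
  }
  ess <- vapply(samples[c("g", "l")], ess_acf, numeric(1))
  rhat <- vapply(samples[c("g", "l")], split_rhat, numeric(1))
  zero_var <- any(vapply(samples[c("g", "l")], sd, numeric(1)) == 0)
  diagnostic_ok <- !zero_var && all(is.finite(rhat)) && all(rhat < 1.2)
  if (zero_var) warning("zero-variance chain: sampler did not move")
  list(samples = samples, ancestral = ancestral,
       acceptance = acc / pmax(prop, 1L),
       proposal_sd = c(g = sd_g, l = sd_l),
       ess = ess, rhat = rhat, diagnostic_ok = diagnostic_ok)
}

## effective sample size from the autocorrelation function, truncated at
## the first negative estimate
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

## split-Rhat of a single chain (first half vs second half)
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 5 || sd(x) == 0) return(NA_real_)
  h <- list(x[seq_len(n)], x[n + seq_len(n)])
  W <- mean(vapply(h, stats::var, numeric(1)))
  B <- n * stats::var(vapply(h, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}
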