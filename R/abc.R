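#' Uniform prior specification for the selection-inference parameters
#'
#' @param s bounds for the selection coefficient (default c(-0.01, 0.2))
#' @param T_adaptive bounds for the selection onset in generations before
#'   present (default c(1, 1686)); sampled continuously, rounded to integer
#'   generations at simulation time
#' @param p0 bounds for the initial allele frequency (default c(0, 1))
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(s = c(-0.01, 0.2), T_adaptive = c(1, 1686),
                       p0 = c(0, 1)) {
  b <- list(s = s, T_adaptive = T_adaptive, p0 = p0)
  for (nm in names(b))
    if (length(b[[nm]]) != 2L || b[[nm]][1] > b[[nm]][2])
      stop(nm, " bounds must be (low, high) with low <= high")
  structure(b, class = "prior_spec")
}

#' Sample parameter triplets from the prior
#'
#' @param priors prior_spec
#' @param n number of draws
#' @param seed RNG seed
#' @return n x 3 matrix with columns s, T_adaptive, p0.
#' @export
sample_prior <- function(priors, n, seed = 1) {
  stopifnot(inherits(priors, "prior_spec"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- sapply(priors, function(b) stats::runif(n, b[1], b[2]))
  if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(priors)))
  colnames(m) <- c("s", "T_adaptive", "p0")
  m
}

# reflect values into [lo, hi] (preserves the support after perturbation)
reflect_into <- function(x, lo, hi) {
  if (hi == lo) return(rep(lo, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Sequential (adaptive population Monte Carlo) approximate Bayesian
#' computation
#'
#' Likelihood-free inference of (s, T_adaptive, p0) from observed
#' end-of-simulation allele frequencies. The algorithm initializes a
#' population of particles from the prior, then repeatedly: keeps the
#' `alpha_keep` fraction with the smallest distance to the observation,
#' resamples and perturbs them with a component-wise Gaussian kernel whose
#' variance is twice the weighted empirical variance of the kept particles
#' (reflected at the prior bounds), simulates the refreshed particles, and
#' recomputes importance weights. It stops when the proportion of newly
#' proposed particles that improve on the previous tolerance falls below
#' `p_accmin`.
#'
#' @param simulator function(theta, seed) where `theta` is an n x 3 matrix
#'   (columns s, T_adaptive, p0) returning an n x 5 matrix of summary
#'   frequencies (columns CEU, CHB, JPT, KHV, CDX);
#'   see \code{\link{make_wf_simulator}}
#' @param observed numeric vector of 5 observed frequencies
#' @param priors prior_spec
#' @param n_particles population size (>= 100; default 2000)
#' @param alpha_keep fraction of particles kept each iteration (default 0.5)
#' @param p_accmin stopping threshold on the acceptance proportion
#'   (default 0.05)
#' @param seed RNG seed controlling the full run
#' @param max_iter hard cap on iterations (default 60)
#' @param normalize_distance divide each summary's residual by the standard
#'   deviation of that summary among initial prior simulations
#'   (default FALSE: plain Euclidean distance)
#' @return list of class `abc_posterior`: `particles` (kept n_alpha x 3),
#'   `weights` (normalized), `distances`, `acceptance_trace`, `eps_trace`,
#'   `n_simulations`, `priors`, `seed`.
#' @export
abc_sequential <- function(simulator, observed, priors,
                           n_particles = 2000, alpha_keep = 0.5,
                           p_accmin = 0.05, seed = 1, max_iter = 60,
                           normalize_distance = FALSE) {
  stopifnot(inherits(priors, "prior_spec"))
  if (any(observed < 0 | observed > 1)) stop("observed frequencies in [0, 1]")
  if (n_particles < 100) stop("n_particles must be >= 100")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lo <- vapply(priors, `[`, numeric(1), 1L)
  hi <- vapply(priors, `[`, numeric(1), 2L)
  n_keep <- floor(alpha_keep * n_particles)
  if (n_keep < 2) stop("alpha_keep too small for the particle count")
  sim_seed <- function() sample.int(2^31 - 2, 1L)
  dist_to_obs <- function(X, scale) {
    R <- sweep(X, 2L, observed)
    if (!is.null(scale)) R <- sweep(R, 2L, scale, "/")
    d <- sqrt(rowSums(R^2))
    d[!is.finite(d)] <- Inf
    d
  }
  theta <- sample_prior(priors, n_particles, seed = sim_seed())
  X <- simulator(theta, seed = sim_seed())
  scale <- NULL
  if (normalize_distance) {
    scale <- pmax(apply(X, 2L, stats::sd), 1e-9)
  }
  d <- dist_to_obs(X, scale)
  ord <- order(d)[seq_len(n_keep)]
  theta <- theta[ord, , drop = FALSE]
  d <- d[ord]
  w <- rep(1 / n_keep, n_keep)
  eps <- max(d)
  acc_trace <- numeric(0)
  eps_trace <- eps
  n_sim <- n_particles
  n_new <- n_particles - n_keep
  for (it in seq_len(max_iter)) {
    wv <- pmax(weighted_var(theta, w), 1e-12)
    sd_k <- sqrt(2 * wv)
    parents <- sample.int(n_keep, n_new, replace = TRUE, prob = w)
    prop <- theta[parents, , drop = FALSE] +
      matrix(stats::rnorm(n_new * 3L), n_new) %*% diag(sd_k)
    for (c3 in 1:3) prop[, c3] <- reflect_into(prop[, c3], lo[c3], hi[c3])
    Xn <- simulator(prop, seed = sim_seed())
    dn <- dist_to_obs(Xn, scale)
    n_sim <- n_sim + n_new
    # importance weights: uniform prior over the kernel mixture density
    wn <- numeric(n_new)
    for (c3 in 1:3) {
      # accumulate the log kernel per component into a matrix new x kept
      if (c3 == 1L)
        logK <- matrix(0, n_new, n_keep)
      logK <- logK + stats::dnorm(outer(prop[, c3], theta[, c3], "-"),
                                  sd = sd_k[c3], log = TRUE)
    }
    mix <- as.numeric(exp(logK) %*% w)
    wn <- ifelse(mix > 0, 1 / mix, 0)
    p_acc <- mean(dn < eps)
    pool_theta <- rbind(theta, prop)
    pool_d <- c(d, dn)
    pool_w <- c(w, wn)
    ord <- order(pool_d)[seq_len(n_keep)]
    theta <- pool_theta[ord, , drop = FALSE]
    d <- pool_d[ord]
    w <- pool_w[ord]
    if (sum(w) <= 0) w <- rep(1, n_keep)
    w <- w / sum(w)
    eps <- max(d)
    acc_trace <- c(acc_trace, p_acc)
    eps_trace <- c(eps_trace, eps)
    if (p_acc < p_accmin) break
  }
  colnames(theta) <- c("s", "T_adaptive", "p0")
  structure(list(particles = theta, weights = w, distances = d,
                 acceptance_trace = acc_trace, eps_trace = eps_trace,
                 n_simulations = n_sim, priors = priors, seed = seed),
            class = "abc_posterior")
}

weighted_var <- function(theta, w) {
  w <- w / sum(w)
  mu <- colSums(theta * w)
  colSums(sweep(theta, 2L, mu)^2 * w)
}

#' Build a batch simulator closure for ABC over the demographic model
#'
#' @param model demographic_model
#' @param regime selection_regime template (dominance and selected
#'   lineages); per-particle s and T_adaptive come from the ABC proposals
#' @return function(theta, seed) -> n x 5 end-frequency matrix, with
#'   T_adaptive rounded to integer generations.
#' @export
make_wf_simulator <- function(model, regime = selection_regime()) {
  force(model); force(regime)
  function(theta, seed = 1) {
    wf_simulate_batch(model,
                      s = theta[, 1L],
                      T_adaptive = round(theta[, 2L]),
                      p0 = theta[, 3L],
                      regime = regime, seed = seed)
  }
}

#' Weighted quantiles by inverse cumulative-weight CDF
#'
#' @param x numeric values
#' @param w non-negative weights
#' @param probs probabilities
#' @return numeric vector: for each p, the smallest x whose cumulative
#'   normalized weight reaches p.
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Posterior point estimates and credible intervals
#'
#' Weighted median and equal-tailed weighted quantile interval per
#' parameter.
#'
#' @param posterior abc_posterior
#' @param level credible level (default 0.95)
#' @return data.frame: parameter, point (weighted median), lower, upper.
#' @export
posterior_summary <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "abc_posterior"))
  th <- posterior$particles
  if (nrow(unique(th)) < 2L) {
    pt <- th[1L, ]
    return(data.frame(parameter = colnames(th), point = as.numeric(pt),
                      lower = as.numeric(pt), upper = as.numeric(pt),
                      stringsAsFactors = FALSE))
  }
  a <- (1 - level) / 2
  out <- lapply(colnames(th), function(nm) {
    q <- weighted_quantile(th[, nm], posterior$weights, c(0.5, a, 1 - a))
    data.frame(parameter = nm, point = q[1], lower = q[2], upper = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Weighted correlation between selection strength and onset time
#'
#' Among retained ABC particles, stronger selection trades off against a
#' more recent onset (older, weaker selection can yield the same end
#' frequencies), so this correlation is expected to be negative.
#'
#' @param posterior abc_posterior (or any list with `particles`, `weights`)
#' @return weighted Pearson correlation of s and T_adaptive.
#' @export
joint_dependence <- function(posterior) {
  th <- posterior$particles
  if (nrow(th) < 3L) stop("need at least 3 particles")
  w <- posterior$weights / sum(posterior$weights)
  mu <- colSums(th * w)
  xc <- th[, "s"] - mu["s"]
  yc <- th[, "T_adaptive"] - mu["T_adaptive"]
  vx <- sum(w * xc^2); vy <- sum(w * yc^2)
  if (vx == 0 || vy == 0) stop("zero variance in retained particles")
  sum(w * xc * yc) / sqrt(vx * vy)
}
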