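# Shared fixtures: small in-code data builders and independent oracles.

# One simulated peak under the generative cis model (psi = 0.5, delta = 0
# unless stated), returned in the shape fit_joint_model() expects.
sim_one_peak <- function(n = 10, depth = 500, pi = 0.5, phi = 0.1,
                         theta = 0.02, psi = 0.5, delta = 0,
                         allelic_fraction = 0.2, g = NULL) {
  if (is.null(g)) g <- sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  m <- (2 - g) * (1 - pi) + g * pi
  y <- rnbinom(n, size = 1 / phi, mu = depth * m)
  het <- which(g == 1)
  d <- rbinom(length(het), y[het], allelic_fraction)
  p_raw <- pi * (1 - psi) / (pi * (1 - psi) + (1 - pi) * psi)
  p_eff <- p_raw * (1 - 2 * delta) + delta
  a <- caqtlkit:::rbetabinom(length(het), d, p_eff, theta)
  keep <- d > 0
  list(y = y, g = g,
       al = data.table::data.table(sample = het[keep],
                                   ref_count = (d - a)[keep],
                                   alt_count = a[keep]))
}

# Independent R implementation of the penalized joint objective used as a
# grid/optim oracle (never calls package internals).
oracle_objective <- function(y, s, g, a_alt, d_tot, pi, psi, delta, lambda,
                             phi, theta, psi_prior = 10, delta_prior = 19) {
  m <- (2 - g) * (1 - pi) + g * pi
  mu <- pmax(s * lambda * m, 1e-12)
  ll <- sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  if (length(a_alt)) {
    p <- pi * (1 - psi) / (pi * (1 - psi) + (1 - pi) * psi)
    pp <- min(max(p * (1 - 2 * delta) + delta, 1e-10), 1 - 1e-10)
    al <- pp / theta; be <- (1 - pp) / theta
    ll <- ll + sum(lchoose(d_tot, a_alt) +
                   lbeta(a_alt + al, d_tot - a_alt + be) - lbeta(al, be))
    ll <- ll + (psi_prior - 1) * (log(psi) + log(1 - psi)) +
      (delta_prior - 1) * log(1 - delta)
  }
  ll
}

# profile the oracle objective over nuisances at fixed (pi, psi)
oracle_profile <- function(y, s, g, a_alt, d_tot, pi, psi) {
  f <- function(par) {
    -oracle_objective(y, s, g, a_alt, d_tot, pi, psi,
                      delta = par[3], lambda = exp(par[1]),
                      phi = exp(par[2]), theta = exp(par[4]))
  }
  fit <- optim(c(log(mean(y) + 0.5), log(0.1), 0.01, log(0.1)), f,
               method = "L-BFGS-B",
               lower = c(-10, log(1e-4), 0, log(1e-6)),
               upper = c(20, log(50), 0.45, log(50)))
  -fit$value
}

# exhaustive pi x psi grid oracle (step 0.01): maximizes the same penalized
# objective by brute force, profiling the remaining nuisances with optim.
# The NB component depends only on pi, the BB component on (pi, psi), so the
# two inner optimizations are split for speed.
oracle_grid_max <- function(y, s, g, a_alt, d_tot, step = 0.01,
                            psi_prior = 10, delta_prior = 19) {
  pis <- seq(0.01, 0.99, by = step)
  nb_of <- vapply(pis, function(pi) {
    m <- (2 - g) * (1 - pi) + g * pi
    f <- function(par)
      -sum(dnbinom(y, size = 1 / exp(par[2]),
                   mu = pmax(s * exp(par[1]) * m, 1e-12), log = TRUE))
    -optim(c(log(mean(y) + 0.5), log(0.1)), f, method = "L-BFGS-B",
           lower = c(-10, log(1e-4)), upper = c(20, log(50)))$value
  }, 0)
  if (!length(a_alt)) return(max(nb_of))
  psis <- seq(0.01, 0.99, by = step)
  bb_star <- function(pi, psi) {
    p <- pi * (1 - psi) / (pi * (1 - psi) + (1 - pi) * psi)
    f <- function(par) {
      delta <- par[1]; theta <- exp(par[2])
      pp <- min(max(p * (1 - 2 * delta) + delta, 1e-10), 1 - 1e-10)
      al <- pp / theta; be <- (1 - pp) / theta
      -(sum(lchoose(d_tot, a_alt) + lbeta(a_alt + al, d_tot - a_alt + be) -
            lbeta(al, be)) + (delta_prior - 1) * log(1 - delta))
    }
    v <- -optim(c(0.01, log(0.1)), f, method = "L-BFGS-B",
                lower = c(0, log(1e-6)), upper = c(0.45, log(50)))$value
    v + (psi_prior - 1) * (log(psi) + log(1 - psi))
  }
  best <- -Inf
  for (i in seq_along(pis)) for (j in seq_along(psis)) {
    tot <- nb_of[i] + bb_star(pis[i], psis[j])
    if (tot > best) best <- tot
  }
  best
}

# tiny genotype cohort with explicit dosage matrix
make_genotypes <- function(dosage, pos = NULL, chrom = "chr1",
                           peak_id = NULL) {
  n_v <- ncol(dosage)
  pos <- pos %||% seq(1000L, by = 1000L, length.out = n_v)
  ids <- colnames(dosage) %||% sprintf("v%03d", seq_len(n_v))
  colnames(dosage) <- ids
  samples <- rownames(dosage) %||% sprintf("S%02d", seq_len(nrow(dosage)))
  rownames(dosage) <- samples
  variants <- data.table::data.table(
    variant_id = ids, chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "G", maf = colMeans(dosage) / 2,
    peak_id = peak_id %||% rep(NA_character_, n_v))
  structure(list(variants = variants, dosage = dosage,
                 sample_ids = samples),
            class = "cohort_genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_peaks = 60L, n_variants = 180L,
             n_cells_per_sample = 250L, n_coaccess_modules = 4L, ...)
}
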