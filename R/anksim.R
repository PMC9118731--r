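# Coupled-oscillator stand-in for temperature-dependent dynamics
#
# Each ankyrin repeat is one site displaced along the domain's long axis
# (the paper's own reduction of repeat-stack flexibility to one major axis).
# Sites are tethered by an on-site spring (the internally rigid helix
# bundle), coupled by soft nearest-neighbour links (the hairpin connectors),
# and charged sites interact through a screened-Coulomb repulsion.
#
# Charge destabilizes a repeat in this model through its effective site
# stiffness, k_i = k_intra * (1 - softness * q_i^2) (clamped at a floor):
# a dense like-charge cluster inside a repeat lowers the restoring stiffness
# of its internal packing. In one dimension the *inter*-repeat screened
# repulsion alone cannot destabilize (its pair curvature is positive), so it
# is kept as the anharmonic coupling while the within-repeat charge density
# carries the destabilization. Absolute fluctuation values are model units;
# only orderings (charged vs uncharged, warmer vs cooler, mutant vs wild
# type) are meaningful.

#' Build a charged oscillator chain
#'
#' @param n number of repeats (default 7, a ~230-residue domain / 33).
#' @param masses per-site effective mass (recycled).
#' @param k_intra on-site spring constant before charge softening.
#' @param k_link inter-repeat link spring (must not exceed `k_intra`).
#' @param charges per-site net charge in e; default for `n = 7` places the
#'   acidic clusters on repeats 3-6 (hairpins of ANK3/4, alpha-2 cluster of
#'   ANK4, tail of ANK5/6), `c(0, 0, -2, -3, -2, -1, 0)`; otherwise zeros.
#' @param softness stiffness reduction per squared unit charge (see above).
#' @param friction Langevin damping.
#' @param d0 lattice spacing between repeat centres (model length units).
#' @param lambda screening length of the inter-repeat repulsion.
#' @param kc Coulomb prefactor (model units).
#' @param site_form `"harmonic"` or `"soft"` (Gaussian well of width
#'   `x_scale`, softening at large excursions).
#' @param x_scale width of the soft site well.
#' @param temperature_scale kBT in model units per kelvin; the default puts
#'   kBT = 1 at 310.15 K (37 C).
#' @return object of class `OscillatorChain`; `positions` holds the relaxed
#'   (zero-force) displacements, velocities start at zero.
#' @export
build_chain <- function(n = 7, masses = 1, k_intra = 100, k_link = 5,
                        charges = NULL, softness = 0.04, friction = 1,
                        d0 = 8, lambda = 8, kc = 50,
                        site_form = c("harmonic", "soft"), x_scale = 0.3,
                        temperature_scale = 1 / 310.15) {
  site_form <- match.arg(site_form)
  if (n < 1) stop("n must be >= 1")
  if (k_intra < 0 || k_link < 0) stop("spring constants must be >= 0")
  if (k_link > k_intra) stop("k_link must not exceed k_intra")
  if (softness < 0) stop("softness must be >= 0")
  if (is.null(charges)) {
    charges <- if (n == 7) c(0, 0, -2, -3, -2, -1, 0) else rep(0, n)
  }
  if (length(charges) != n) stop("charges must have length n")
  masses <- rep_len(masses, n)
  k_site <- pmax(k_intra * (1 - softness * charges^2), 0.2 * k_intra)
  chain <- structure(
    list(n = n, masses = masses, k_intra = k_intra, k_link = k_link,
         k_site = k_site, charges = charges, softness = softness,
         friction = friction, d0 = d0, lambda = lambda, kc = kc,
         site_form = site_form, x_scale = x_scale,
         temperature_scale = temperature_scale,
         positions = rep(0, n), velocities = rep(0, n)),
    class = "OscillatorChain")
  chain$positions <- relax_chain(chain)
  chain
}

#' @export
print.OscillatorChain <- function(x, ...) {
  cat("OscillatorChain: n =", x$n, "\n")
  cat("  k_site:", paste(signif(x$k_site, 4), collapse = " "), "\n")
  cat("  charges:", paste(x$charges, collapse = " "), "\n")
  invisible(x)
}

chain_potential <- function(chain, x) {
  u <- if (chain$site_form == "soft") {
    sum(0.5 * chain$k_site * chain$x_scale^2 *
          (1 - exp(-(x / chain$x_scale)^2)))
  } else {
    sum(0.5 * chain$k_site * x^2)
  }
  if (chain$n > 1) {
    u <- u + sum(0.5 * chain$k_link * diff(x)^2)
  }
  ch <- which(chain$charges != 0)
  if (length(ch) >= 2) {
    for (a in seq_along(ch)[-length(ch)]) {
      for (b in seq.int(a + 1, length(ch))) {
        i <- ch[a]; j <- ch[b]
        r <- max(chain$d0 * (j - i) + x[j] - x[i], 0.05 * chain$d0)
        u <- u + chain$kc * chain$charges[i] * chain$charges[j] *
          exp(-r / chain$lambda) / r
      }
    }
  }
  u
}

relax_chain <- function(chain) {
  if (all(chain$charges == 0)) return(rep(0, chain$n))
  res <- stats::optim(rep(0, chain$n), function(x) chain_potential(chain, x),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  res$par
}

#' Linearized normal-mode angular frequencies
#'
#' Frequencies of the mass-weighted Hessian of the full potential at the
#' chain's relaxed configuration (finite differences).
#'
#' @param chain an `OscillatorChain`.
#' @return angular frequencies, ascending.
#' @export
normal_modes <- function(chain) {
  n <- chain$n
  x0 <- chain$positions
  h <- 1e-5
  hess <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      xi <- x0; xi[i] <- xi[i] + h; xi[j] <- xi[j] + h
      xj <- x0; xj[i] <- xj[i] + h; xj[j] <- xj[j] - h
      xk <- x0; xk[i] <- xk[i] - h; xk[j] <- xk[j] + h
      xl <- x0; xl[i] <- xl[i] - h; xl[j] <- xl[j] - h
      hess[i, j] <- hess[j, i] <-
        (chain_potential(chain, xi) - chain_potential(chain, xj) -
           chain_potential(chain, xk) + chain_potential(chain, xl)) / (4 * h^2)
    }
  }
  mw <- hess / sqrt(outer(chain$masses, chain$masses))
  sqrt(pmax(eigen(mw, symmetric = TRUE)$values, 0))
}

#' Simulate the chain with Langevin dynamics
#'
#' BAOAB splitting with Gaussian thermal kicks; the random stream is a
#' counter-free generator keyed by `seed`, so identical inputs give
#' bit-identical trajectories. At zero temperature the chain stays at its
#' relaxed configuration.
#'
#' @param chain an `OscillatorChain`.
#' @param temperature kelvin; kBT in model units is
#'   `temperature * chain$temperature_scale`.
#' @param steps integration steps (>= 1).
#' @param dt time step; must satisfy `dt <= 0.1 / omega_max` for the
#'   stiffest site.
#' @param seed integer seed for the thermal noise.
#' @param record_every keep every k-th sample.
#' @return object of class `Trajectory`: `displacements` (samples x n
#'   matrix), `dt`, `temperature`, `seed`, `record_every` and the chain.
#' @export
simulate_chain <- function(chain, temperature, steps, dt = 0.005, seed = 1,
                           record_every = 10L) {
  if (steps < 1) stop("steps must be >= 1")
  omega_max <- sqrt(max(chain$k_site + 2 * chain$k_link) / min(chain$masses))
  if (dt > 0.1 / omega_max) {
    stop(sprintf("dt = %g unstable for the stiffest site; use dt <= %.4g",
                 dt, 0.1 / omega_max))
  }
  kBT <- temperature * chain$temperature_scale
  disp <- langevin_chain(
    chain$positions, chain$velocities, chain$masses, chain$k_site,
    chain$x_scale, if (chain$site_form == "soft") 1L else 0L, chain$k_link,
    chain$charges, chain$d0, chain$lambda, chain$kc, chain$friction, kBT,
    as.integer(steps), dt, as.integer(record_every), as.numeric(seed))
  structure(list(displacements = disp, dt = dt, temperature = temperature,
                 seed = seed, record_every = record_every, chain = chain),
            class = "Trajectory")
}

#' Per-repeat root-mean-square fluctuation
#'
#' RMSF about each site's own trajectory mean, over post-burn-in samples.
#'
#' @param trajectory a `Trajectory`.
#' @param burn_in fraction of samples discarded from the start.
#' @return object of class `RMSFProfile`: `values` (per repeat, model length
#'   units) and `temperature`.
#' @export
rmsf_profile <- function(trajectory, burn_in = 0.2) {
  d <- trajectory$displacements
  from <- floor(nrow(d) * burn_in) + 1
  if (nrow(d) - from + 1 < 100) {
    stop("need >= 100 post-burn-in samples (have ", nrow(d) - from + 1, ")")
  }
  d <- d[from:nrow(d), , drop = FALSE]
  vals <- apply(d, 2, function(x) sqrt(mean((x - mean(x))^2)))
  structure(list(values = vals, temperature = trajectory$temperature),
            class = "RMSFProfile")
}

#' Change the charge of one repeat
#'
#' Returns a copy of the chain with the charge replaced; effective site
#' stiffness and the relaxed configuration are recomputed, everything else
#' is untouched.
#'
#' @param chain an `OscillatorChain`.
#' @param repeat_index 1-based site index.
#' @param new_charge charge in e.
#' @return a new `OscillatorChain`.
#' @export
mutate_charge <- function(chain, repeat_index, new_charge) {
  if (repeat_index < 1 || repeat_index > chain$n) {
    stop("repeat_index out of range 1..", chain$n)
  }
  chain$charges[repeat_index] <- new_charge
  chain$k_site <- pmax(chain$k_intra * (1 - chain$softness * chain$charges^2),
                       0.2 * chain$k_intra)
  chain$positions <- relax_chain(chain)
  chain
}

#' Seed-averaged RMSF comparison across temperatures
#'
#' Runs matched-seed simulations of a chain at several temperatures and
#' returns the per-repeat RMSF averaged over seeds.
#'
#' @param chain an `OscillatorChain`.
#' @param temperatures kelvin.
#' @param seeds integer vector of seeds.
#' @param steps,dt,record_every,burn_in passed to [simulate_chain()] /
#'   [rmsf_profile()].
#' @return matrix (temperature x repeat) of mean RMSF, rownames the
#'   temperatures.
#' @export
rmsf_by_temperature <- function(chain, temperatures, seeds = 1:10,
                                steps = 2e5, dt = 0.005, record_every = 10L,
                                burn_in = 0.2) {
  out <- matrix(0, length(temperatures), chain$n,
                dimnames = list(as.character(temperatures), NULL))
  for (ti in seq_along(temperatures)) {
    acc <- rep(0, chain$n)
    for (s in seeds) {
      tr <- simulate_chain(chain, temperatures[ti], steps, dt, seed = s,
                           record_every = record_every)
      acc <- acc + rmsf_profile(tr, burn_in)$values
    }
    out[ti, ] <- acc / length(seeds)
  }
  out
}
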