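# Population metaheuristics over a box [lower, upper]^dim (WOA, PSO, GSA)
# or over bit strings (GA, ACO). All minimize, all track the best-so-far
# fitness per iteration (elitism: curves are non-increasing by
# construction), and all draw their randomness from one seeded stream.

# One whale position update with explicit draws; split out so the branch
# algebra is unit-testable with fixed random numbers.
# p >= 0.5: logarithmic-spiral move around the best solution,
#   z' = e^(b k) cos(2 pi k) |z* - z| + z*.
# p < 0.5: A = 2 a r1 - a and C = 2 r2, drawn per dimension as in the
#   reference WOA implementation; dimensions with |A| < 1 encircle the best
#   (z* - A |C o (z* - z)|), dimensions with |A| >= 1 explore toward the
#   random agent z_rand. With scalar draws this reduces exactly to the
#   all-or-nothing per-agent branch.
woa_update <- function(z, zstar, zrand, a, b, p, k, r1, r2) {
  if (p >= 0.5) {
    fstar <- abs(zstar - z)
    exp(b * k) * cos(2 * pi * k) * fstar + zstar
  } else {
    A <- 2 * a * r1 - a
    C <- 2 * r2
    ifelse(abs(A) < 1,
           zstar - A * abs(C * (zstar - z)),
           zrand - A * abs(C * (zrand - z)))
  }
}

#' Whale Optimization Algorithm over a continuous box
#'
#' Canonical WOA: each agent either spirals around the incumbent best
#' (probability 1/2) or, depending on the coefficient `|A|` with
#' `a` decreasing linearly from 2 to 0 across iterations, encircles the
#' best or explores toward a random agent. The incumbent is updated
#' greedily, so the returned convergence curve is non-increasing.
#'
#' @param fn objective to minimize, `fn(position) -> scalar`.
#' @param dim problem dimension.
#' @param pop population size; `iters` iterations.
#' @param iters number of iterations.
#' @param lower,upper box bounds (scalars).
#' @param b logarithmic spiral constant (default 1).
#' @param seed integer seed.
#' @return list with `best_position`, `best_fitness`, `curve`
#'   (length `iters`), `evaluations`.
#' @export
woa_optimize <- function(fn, dim, pop = 30L, iters = 200L, lower = 0,
                         upper = 1, b = 1, seed = 1L) {
  if (pop < 2L) stop("population must be >= 2")
  if (iters < 1L) stop("iterations must be >= 1")
  with_seed(seed, {
    Z <- matrix(runif(pop * dim, lower, upper), pop, dim)
    fit <- apply(Z, 1, fn)
    bi <- which.min(fit)
    best <- Z[bi, ]; best_fit <- fit[bi]
    curve <- numeric(iters)
    nev <- pop
    for (u in seq_len(iters)) {
      a <- if (iters == 1L) 0 else 2 * (1 - (u - 1) / (iters - 1))
      for (i in seq_len(pop)) {
        j <- sample(setdiff(seq_len(pop), i), 1)
        z <- woa_update(Z[i, ], best, Z[j, ], a, b,
                        p = runif(1), k = runif(1, -1, 1),
                        r1 = runif(dim), r2 = runif(dim))
        z <- pmin(pmax(z, lower), upper)
        f <- fn(z)
        nev <- nev + 1
        Z[i, ] <- z; fit[i] <- f
        if (f < best_fit) { best_fit <- f; best <- z }
      }
      curve[u] <- best_fit
    }
    list(best_position = best, best_fitness = best_fit, curve = curve,
         evaluations = nev)
  })
}

#' Particle swarm optimization (gbest topology) over a continuous box
#' @inheritParams woa_optimize
#' @param c1,c2 cognitive and social factors (default 2); `w` inertia
#'   weight (default 0.9).
#' @param w inertia weight.
#' @export
pso_optimize <- function(fn, dim, pop = 30L, iters = 200L, lower = 0,
                         upper = 1, c1 = 2, c2 = 2, w = 0.9, seed = 1L) {
  with_seed(seed, {
    X <- matrix(runif(pop * dim, lower, upper), pop, dim)
    vmax <- (upper - lower) * 0.2
    V <- matrix(runif(pop * dim, -vmax, vmax), pop, dim)
    fit <- apply(X, 1, fn)
    P <- X; pfit <- fit
    bi <- which.min(fit); g <- X[bi, ]; gfit <- fit[bi]
    curve <- numeric(iters)
    for (u in seq_len(iters)) {
      for (i in seq_len(pop)) {
        V[i, ] <- w * V[i, ] +
          c1 * runif(dim) * (P[i, ] - X[i, ]) +
          c2 * runif(dim) * (g - X[i, ])
        V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
        X[i, ] <- pmin(pmax(X[i, ] + V[i, ], lower), upper)
        f <- fn(X[i, ])
        if (f < pfit[i]) { pfit[i] <- f; P[i, ] <- X[i, ] }
        if (f < gfit) { gfit <- f; g <- X[i, ] }
      }
      curve[u] <- gfit
    }
    list(best_position = g, best_fitness = gfit, curve = curve,
         evaluations = pop * (iters + 1))
  })
}

#' Gravitational search algorithm over a continuous box
#' @inheritParams woa_optimize
#' @param G0 initial gravitational constant; `alpha` decay exponent.
#' @param alpha decay exponent of the gravitational constant.
#' @export
gsa_optimize <- function(fn, dim, pop = 30L, iters = 200L, lower = 0,
                         upper = 1, G0 = 100, alpha = 20, seed = 1L) {
  with_seed(seed, {
    X <- matrix(runif(pop * dim, lower, upper), pop, dim)
    V <- matrix(0, pop, dim)
    fit <- apply(X, 1, fn)
    bi <- which.min(fit); best <- X[bi, ]; best_fit <- fit[bi]
    curve <- numeric(iters)
    for (u in seq_len(iters)) {
      G <- G0 * exp(-alpha * (u - 1) / iters)
      fbest <- min(fit); fworst <- max(fit)
      m <- if (fworst > fbest) (fworst - fit) / (fworst - fbest)
           else rep(1, pop)
      M <- m / sum(m)
      kbest <- max(2L, round(pop * (1 - (u - 1) / iters)))
      elite <- order(fit)[seq_len(kbest)]
      for (i in seq_len(pop)) {
        acc <- numeric(dim)
        for (j in elite) {
          if (j == i) next
          diffv <- X[j, ] - X[i, ]
          R <- sqrt(sum(diffv^2))
          acc <- acc + runif(1) * G * M[j] * diffv / (R + 1e-12)
        }
        V[i, ] <- runif(dim) * V[i, ] + acc
        X[i, ] <- pmin(pmax(X[i, ] + V[i, ], lower), upper)
        f <- fn(X[i, ])
        fit[i] <- f
        if (f < best_fit) { best_fit <- f; best <- X[i, ] }
      }
      curve[u] <- best_fit
    }
    list(best_position = best, best_fitness = best_fit, curve = curve,
         evaluations = pop * (iters + 1))
  })
}

#' Genetic algorithm over bit strings
#' @inheritParams woa_optimize
#' @param fn objective over 0/1 vectors.
#' @param cr crossover rate; `mr` bit-flip mutation rate; `ts` tournament
#'   size.
#' @param mr mutation rate.
#' @param ts tournament size.
#' @export
ga_optimize <- function(fn, dim, pop = 30L, iters = 200L, cr = 0.8,
                        mr = 0.01, ts = 3L, seed = 1L) {
  with_seed(seed, {
    X <- matrix(as.integer(runif(pop * dim) > 0.5), pop, dim)
    fit <- apply(X, 1, fn)
    bi <- which.min(fit); best <- X[bi, ]; best_fit <- fit[bi]
    curve <- numeric(iters)
    tournament <- function() {
      cand <- sample(pop, ts, replace = TRUE)
      cand[which.min(fit[cand])]
    }
    for (u in seq_len(iters)) {
      XN <- X
      XN[1, ] <- best # elitism
      for (i in seq(2L, pop)) {
        p1 <- X[tournament(), ]; p2 <- X[tournament(), ]
        child <- p1
        if (runif(1) < cr && dim > 1) {
          cut <- sample(dim - 1L, 1)
          child <- c(p1[seq_len(cut)], p2[seq(cut + 1L, dim)])
        }
        flip <- runif(dim) < mr
        child[flip] <- 1L - child[flip]
        XN[i, ] <- child
      }
      X <- XN
      fit <- apply(X, 1, fn)
      bi <- which.min(fit)
      if (fit[bi] < best_fit) { best_fit <- fit[bi]; best <- X[bi, ] }
      curve[u] <- best_fit
    }
    list(best_position = best, best_fitness = best_fit, curve = curve,
         evaluations = pop * (iters + 1))
  })
}

#' Ant colony optimization over bit strings
#'
#' Per-bit pheromone trails for states 0 and 1; ants sample each bit from
#' the pheromone/heuristic product, trails evaporate at rate `rho`, and the
#' iteration best plus the global best deposit reinforcement proportional
#' to solution quality.
#'
#' @inheritParams ga_optimize
#' @param tau initial pheromone; `eta` heuristic desirability;
#'   `alpha`,`beta` pheromone/heuristic exponents; `rho` evaporation rate.
#' @param eta heuristic desirability.
#' @param alpha pheromone exponent.
#' @param beta heuristic exponent.
#' @param rho pheromone evaporation coefficient.
#' @export
aco_optimize <- function(fn, dim, pop = 30L, iters = 200L, tau = 1,
                         eta = 1, alpha = 1, beta = 0.1, rho = 0.2,
                         seed = 1L) {
  with_seed(seed, {
    tau1 <- rep(tau, dim); tau0 <- rep(tau, dim)
    best <- NULL; best_fit <- Inf
    curve <- numeric(iters)
    for (u in seq_len(iters)) {
      w1 <- tau1^alpha * eta^beta
      w0 <- tau0^alpha * eta^beta
      p1 <- w1 / (w1 + w0)
      it_best <- NULL; it_fit <- Inf
      for (i in seq_len(pop)) {
        bits <- as.integer(runif(dim) < p1)
        f <- fn(bits)
        if (f < it_fit) { it_fit <- f; it_best <- bits }
        if (f < best_fit) { best_fit <- f; best <- bits }
      }
      tau1 <- (1 - rho) * tau1
      tau0 <- (1 - rho) * tau0
      for (sol in list(it_best, best)) {
        dep <- 1 / (1 + pmax(0, if (identical(sol, best)) best_fit else it_fit))
        tau1[sol == 1L] <- tau1[sol == 1L] + dep
        tau0[sol == 0L] <- tau0[sol == 0L] + dep
      }
      curve[u] <- best_fit
    }
    list(best_position = best, best_fitness = best_fit, curve = curve,
         evaluations = pop * iters)
  })
}
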