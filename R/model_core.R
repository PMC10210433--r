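# Deterministic core of the lifecycle: found -> clonal growth -> pairwise
# transfer -> public goods / survival -> plasmid loss -> mutation -> global
# dispersal.  In the infinite-population limit a generation is an expectation
# over the multinomial distribution of founder compositions, with mass-action
# transfer inside each (infinitely large) patch.

# All compositions of n over k classes, as an integer matrix (one row per
# composition).  Plain stars-and-bars recursion; k <= 6 here.
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(as.integer(n), 1L, 1L))
  out <- vector("list", n + 1L)
  for (n1 in 0:n) {
    sub <- .compositions(n - n1, k - 1L)
    out[[n1 + 1L]] <- cbind(rep.int(as.integer(n1), nrow(sub)), sub)
  }
  do.call(rbind, out)
}

#' Enumerate founder compositions of a patch
#'
#' Lists every way `N` founder cells can be drawn from the genotypes present
#' in the population, together with its multinomial probability.  Genotypes at
#' frequency zero are excluded from the enumeration (their compositions have
#' zero weight), which keeps the computation exact while shrinking the state
#' space — e.g. three active genotypes and `N = 20` give
#' `choose(22, 2) = 231` compositions.
#'
#' @param state a [coop_state()].
#' @param params a [coop_params()] (supplies `N`).
#' @return An object of class `patch_compositions`: a list with `counts`
#'   (integer matrix, one row per composition, columns the six genotypes) and
#'   `weight` (multinomial probabilities, summing to 1).
#' @examples
#' st <- seed_state(p_coop = 0.5)
#' pc <- enumerate_patch_compositions(st, coop_params(2, 0.5, 0.1, 1, 0.1, 0.1))
#' cbind(pc$counts[, 1:2], weight = pc$weight)  # binomial 1/4, 1/2, 1/4
#' @export
enumerate_patch_compositions <- function(state, params) {
  params <- .as_params(params)
  x <- unclass(coop_state(state))
  N <- params$N
  act <- which(x > 0)
  cm <- .compositions(N, length(act))
  counts <- matrix(0L, nrow(cm), 6L, dimnames = list(NULL, GENOTYPES))
  counts[, act] <- cm
  lw <- lgamma(N + 1) - rowSums(lgamma(cm + 1)) + cm %*% log(x[act])
  structure(list(counts = counts, weight = as.vector(exp(lw)), N = N),
            class = "patch_compositions")
}

#' @export
print.patch_compositions <- function(x, ...) {
  cat(sprintf("%d founder compositions of N = %d (weights sum to %.12f)\n",
              nrow(x$counts), x$N, sum(x$weight)))
  invisible(x)
}

#' Within-patch horizontal transfer
#'
#' Mass-action transfer in the large-patch limit: each cell pairs with a
#' uniformly chosen patch member, and a plasmid-free cell acquires its
#' partner's plasmid with probability `beta`.  Plasmid bearers never change
#' plasmid (incompatibility), chromosomes are untouched, and newly infected
#' cells do not retransmit within the generation.  Converted cells acquire
#' each plasmid type in proportion to that type's patch frequency.
#'
#' @param patch_freqs numeric vector of 6 within-patch genotype frequencies
#'   (simplex).
#' @param beta transfer probability per pairing.
#' @return Post-transfer patch frequencies (named numeric, length 6).
#' @examples
#' f <- setNames(c(0.5, 0.5, 0, 0, 0, 0), genotype_names())
#' within_patch_transfer(f, beta = 1)  # free 0.25, coopP 0.75
#' @export
within_patch_transfer <- function(patch_freqs, beta) {
  if (length(patch_freqs) != 6L || any(patch_freqs < 0) ||
      abs(sum(patch_freqs) - 1) > 1e-9)
    stop("patch_freqs must be 6 non-negative frequencies summing to 1")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  f <- as.numeric(patch_freqs)
  fC <- f[2] + f[5]
  fD <- f[3] + f[6]
  P <- fC + fD
  out <- f
  for (i0 in c(1L, 4L)) {           # the two chromosomal backgrounds
    f0 <- f[i0]
    out[i0] <- f0 * (1 - beta * P)
    out[i0 + 1L] <- f[i0 + 1L] + beta * f0 * fC
    out[i0 + 2L] <- f[i0 + 2L] + beta * f0 * fD
  }
  setNames(out, GENOTYPES)
}

#' Genotype fitness
#'
#' `w = 1 + B * coop_fraction - C_G * [cooperator] - C_C * [plasmid bearer]`.
#' The public-good benefit depends only on the fraction of the patch carrying
#' a cooperation gene after transfer; the production cost `C_G` is paid once
#' even when the gene is carried redundantly on chromosome and plasmid.
#'
#' @param g genotype names or indices (vectorised).
#' @param coop_fraction fraction of patch members carrying a cooperation gene
#'   post-transfer, in `[0, 1]`.
#' @param params a [coop_params()].
#' @return Numeric vector of fitnesses (all positive under valid parameters).
#' @examples
#' p <- coop_params(20, 0.95, 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' fitness("coop:none", coop_fraction = 1, p)      # 1 + B - C_G = 2.335
#' fitness("noncoop:defP", coop_fraction = 0, p)   # 1 - C_C = 0.8
#' @export
fitness <- function(g, coop_fraction, params) {
  params <- .as_params(params)
  if (any(coop_fraction < 0 | coop_fraction > 1))
    stop("coop_fraction must be in [0, 1]")
  g <- as_genotype(g)
  w <- 1 + params$B * coop_fraction -
    params$C_G * is_cooperator(g) - params$C_C * has_plasmid(g)
  if (any(w <= 0))
    stop("parameter combination gives non-positive fitness")
  w
}

#' Segregation loss
#'
#' Moves a fraction `s` of every plasmid-bearing genotype to its plasmid-free
#' counterpart on the same chromosomal background.
#'
#' @param state a [coop_state()].
#' @param s loss probability per generation.
#' @return The post-loss [coop_state()].
#' @export
apply_loss <- function(state, s) {
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  x <- unclass(coop_state(state))
  for (i0 in c(1L, 4L)) {
    lost <- s * (x[i0 + 1L] + x[i0 + 2L])
    x[i0] <- x[i0] + lost
    x[i0 + 1L] <- x[i0 + 1L] * (1 - s)
    x[i0 + 2L] <- x[i0 + 2L] * (1 - s)
  }
  coop_state(x)
}

#' Loss-of-function mutation of the cooperator plasmid
#'
#' A fraction `mu` of each cooperator-plasmid genotype becomes the matching
#' defector-plasmid genotype.  There is no chromosomal mutation in the model.
#'
#' @param state a [coop_state()].
#' @param mu mutation probability per generation.
#' @return The post-mutation [coop_state()].
#' @export
apply_mutation <- function(state, mu) {
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  x <- unclass(coop_state(state))
  for (i0 in c(1L, 4L)) {
    d <- mu * x[i0 + 1L]
    x[i0 + 1L] <- x[i0 + 1L] - d
    x[i0 + 2L] <- x[i0 + 2L] + d
  }
  coop_state(x)
}

# Frequencies below this are clamped to zero (and the state renormalised):
# they are far below any biologically meaningful deterministic frequency and
# would otherwise accumulate rounding noise in long iterations.
.FREQ_CLAMP <- 1e-15

.clamp_state <- function(x) {
  if (any(x > 0 & x < .FREQ_CLAMP)) x[x < .FREQ_CLAMP] <- 0
  x / sum(x)
}

#' Advance one generation
#'
#' One full lifecycle generation of the deterministic recursion: expectation
#' over [enumerate_patch_compositions()] of the post-transfer,
#' fitness-weighted genotype output of each patch (normalised by the
#' population mean fitness), followed by [apply_loss()], [apply_mutation()]
#' and global dispersal (complete mixing, which requires no further
#' operation).  Frequencies below 1e-15 are clamped to zero.
#'
#' @param state a [coop_state()].
#' @param params a [coop_params()].
#' @param compiled use the compiled step (default); `compiled = FALSE` runs
#'   the reference implementation composed from the exported lifecycle
#'   operations.  Both paths agree to machine precision.
#' @return The next-generation [coop_state()], with the population mean
#'   fitness of the survival episode in attribute `"mean_fitness"`.
#' @examples
#' p <- coop_params(20, 0.95, 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' generation_step(seed_state(p_coop = 1e-3), p)
#' @export
generation_step <- function(state, params, compiled = TRUE) {
  params <- .as_params(params)
  x <- unclass(coop_state(state))
  if (compiled) {
    res <- cpp_generation_step(x, params$N, params$beta, params$s, params$B,
                               params$C_G, params$C_C, params$mu)
    out <- coop_state(res$state)
    attr(out, "mean_fitness") <- res$mean_fitness
    return(out)
  }
  pc <- enumerate_patch_compositions(x, params)
  contrib <- numeric(6)
  wbar <- 0
  for (i in seq_along(pc$weight)) {
    f <- pc$counts[i, ] / params$N        # clonal growth: exact 1/N shares
    g <- within_patch_transfer(f, params$beta)
    cf <- min(max(sum(g[is_cooperator(1:6)]), 0), 1)  # guard rounding
    w <- fitness(1:6, cf, params)
    contrib <- contrib + pc$weight[i] * g * w
    wbar <- wbar + pc$weight[i] * sum(g * w)
  }
  if (wbar <= 0) stop("non-positive population mean fitness")
  nxt <- apply_mutation(apply_loss(coop_state(contrib / wbar), params$s),
                        params$mu)
  out <- coop_state(.clamp_state(unclass(nxt)))
  attr(out, "mean_fitness") <- wbar
  out
}

#' Run the recursion for a fixed number of generations
#'
#' @param state a starting [coop_state()].
#' @param params a [coop_params()].
#' @param generations number of generations to iterate.
#' @return A data frame of class `coop_trajectory` with columns `generation`
#'   (0-indexed), one column per genotype, and `mean_fitness` (the mean
#'   fitness of the survival episode leading into each row; `NA` for
#'   generation 0).
#' @examples
#' p <- coop_params(20, 0.95, 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' traj <- run_recursion(seed_state(p_coop = 1e-3, p_def = 1e-3), p, 50)
#' tail(traj, 2)
#' @export
run_recursion <- function(state, params, generations) {
  params <- .as_params(params)
  if (generations < 0) stop("generations must be >= 0")
  x <- unclass(coop_state(state))
  m <- cpp_run_recursion(x, params$N, params$beta, params$s, params$B,
                         params$C_G, params$C_C, params$mu,
                         as.integer(generations))
  out <- data.frame(generation = 0:generations, m)
  names(out) <- c("generation", GENOTYPES, "mean_fitness")
  attr(out, "params") <- params
  class(out) <- c("coop_trajectory", "data.frame")
  out
}
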