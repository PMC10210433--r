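# Stochastic individual-based simulator of the identical lifecycle, used as
# the Monte-Carlo oracle for the deterministic recursion and for the
# enumeration-based relatedness expression.  Differences from the recursion
# are purely finite-size: a finite number of patches, finite patch size at
# pairing time (cells pair by a uniform random perfect matching rather than
# mass action), and multinomial sampling of founders.

#' Configuration for the individual-based simulation
#'
#' @param params a [coop_params()].
#' @param n_patches number of patches (>= 1).
#' @param patch_size cells per patch at pairing time.  Must be even, at least
#'   `2 * N`, and a multiple of `N` so clonal growth gives every founder
#'   lineage an exact `1/N` share.  Default: the smallest multiple of `N`
#'   that is even and at least `max(2 * N, 64)`.
#' @param generations generations to simulate.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param state0 initial [coop_state()] from which founders are drawn
#'   (default: cooperator and defector plasmids at `1e-3` each on a
#'   noncooperative chromosome).
#' @return An object of class `ibs_config`.
#' @export
ibs_config <- function(params, n_patches = 2000, patch_size = NULL,
                       generations = 100, seed,
                       state0 = seed_state(p_coop = 1e-3, p_def = 1e-3)) {
  params <- .as_params(params)
  if (missing(seed)) stop("an integer seed is required for reproducibility")
  N <- params$N
  if (is.null(patch_size)) {
    k <- max(2, ceiling(64 / N))
    if ((k * N) %% 2 == 1) k <- k + 1
    patch_size <- k * N
  }
  if (n_patches < 1) stop("n_patches must be >= 1")
  if (patch_size %% 2 != 0) stop("patch_size must be even (cells pair up)")
  if (patch_size < 2 * N) stop("patch_size must be at least 2 * N")
  if (patch_size %% N != 0)
    stop("patch_size must be a multiple of N (exact founder-lineage shares)")
  if (generations < 1) stop("generations must be >= 1")
  structure(
    list(params = params, n_patches = as.integer(n_patches),
         patch_size = as.integer(patch_size),
         generations = as.integer(generations),
         seed = as.integer(seed), state0 = coop_state(state0)),
    class = "ibs_config"
  )
}

#' Empirical plasmid relatedness from post-transfer lineage counts
#'
#' The simulation counterpart of [plasmid_relatedness()]: every founder
#' plasmid is a distinct lineage whose copies (the founder's clonal
#' descendants plus any cells infected during the transfer round) are counted
#' per patch after transfer.  The estimator is the copy-weighted mean
#' own-lineage patch share,
#' `sum(copies^2 / patch_size) / sum(copies)` —
#' for a random plasmid copy, the expected fraction of its patch occupied by
#' copies of the same lineage at the moment of social action.  With `beta = 0`
#' every lineage holds exactly a `1/N` share, recovering chromosomal
#' relatedness.
#'
#' @param lineage_counts integer vector of post-transfer copy counts, one
#'   entry per plasmid lineage per patch.
#' @param patch_size cells per patch at pairing time.
#' @return The relatedness estimate, or `NA` (with a warning) when there are
#'   no plasmid copies.
#' @export
estimate_relatedness <- function(lineage_counts, patch_size) {
  if (length(lineage_counts) == 0 || sum(lineage_counts) == 0) {
    warning("no plasmid copies: relatedness estimate undefined")
    return(NA_real_)
  }
  if (any(lineage_counts < 0) || any(lineage_counts > patch_size))
    stop("lineage counts must lie in [0, patch_size]")
  sum(lineage_counts^2 / patch_size) / sum(lineage_counts)
}

#' Run the individual-based simulation
#'
#' Per generation: the founder pool is randomly partitioned into patches of
#' `N`; each patch grows clonally to `patch_size` cells in exact
#' founder-lineage proportions; cells are paired by a uniform random perfect
#' matching within the patch and a plasmid-free cell acquires its partner's
#' plasmid with probability `beta` (bearer/bearer and free/free pairs are
#' unchanged — incompatibility); fitness is computed per cell from the patch
#' fraction of cooperators; the next founder pool is drawn by
#' fitness-proportional multinomial sampling of `n_patches * N` cells from
#' the whole population (survival plus global dispersal in one draw); each
#' plasmid-bearing founder then loses its plasmid with probability `s`, and
#' cooperator plasmids mutate to defectors with probability `mu`.
#'
#' @param config an [ibs_config()].
#' @return An object of class `ibs_output`: list with `trajectory` (data
#'   frame: `generation`, one frequency and one `se_` column per genotype,
#'   `mean_fitness`), `relatedness_hat` (data frame: `generation`, `R_hat`,
#'   estimated by [estimate_relatedness()] from the transfer round of each
#'   generation), `config` and `seed_used`.
#' @examples
#' p <- coop_params(4, 0.9, 0.1, B = 1, C_G = 0.1, C_C = 0.05)
#' out <- run_ibs(ibs_config(p, n_patches = 200, generations = 10, seed = 1))
#' tail(out$trajectory, 2)
#' @export
run_ibs <- function(config) {
  if (!inherits(config, "ibs_config")) stop("config must be an ibs_config")
  p <- config$params
  N <- p$N
  np <- config$n_patches
  M <- config$patch_size
  G <- config$generations
  copies <- M %/% N
  nF <- np * N
  ncell <- np * M
  patch <- rep(seq_len(np), each = M)
  odd <- seq.int(1L, ncell, by = 2L)
  even <- odd + 1L

  set.seed(config$seed)
  founders <- sample.int(6L, nF, replace = TRUE,
                         prob = unclass(config$state0))

  freq <- matrix(NA_real_, G + 1L, 6L)
  se <- matrix(NA_real_, G + 1L, 6L)
  wbar <- rep(NA_real_, G + 1L)
  rhat <- rep(NA_real_, G)
  rec <- function(row, f) {
    fr <- tabulate(f, 6L) / nF
    freq[row, ] <<- fr
    se[row, ] <<- sqrt(fr * (1 - fr) / nF)
  }
  rec(1L, founders)

  for (t in seq_len(G)) {
    # dispersal: random partition of the pool into patches of N
    founders <- founders[sample.int(nF)]
    plasF <- (founders - 1L) %% 3L
    lin <- integer(nF)
    carrF <- plasF > 0L
    lin[carrF] <- seq_len(sum(carrF))

    # clonal growth to exact 1/N lineage shares
    g <- rep(founders, each = copies)
    l <- rep(lin, each = copies)

    # uniform random perfect matching within each patch
    ord <- order(patch, runif(ncell))
    g <- g[ord]; l <- l[ord]

    pa <- (g[odd] - 1L) %% 3L
    pb <- (g[even] - 1L) %% 3L
    u <- runif(length(odd))
    ca <- pa == 0L & pb > 0L & u < p$beta      # first of pair converts
    cb <- pb == 0L & pa > 0L & u < p$beta      # second converts
    ia <- odd[ca]; ib <- even[ca]
    g[ia] <- g[ia] + pb[ca]; l[ia] <- l[ib]
    ia <- even[cb]; ib <- odd[cb]
    g[ia] <- g[ia] + pa[cb]; l[ia] <- l[ib]

    # empirical relatedness from post-transfer lineage counts
    pl <- (g - 1L) %% 3L
    carr <- pl > 0L
    if (any(carr)) {
      key <- (patch[carr] - 1) * (nF + 1) + l[carr]
      cnt <- rle(sort(key))$lengths
      rhat[t] <- estimate_relatedness(cnt, M)
    }

    # public goods and survival
    coop <- g > 3L | pl == 1L
    cfrac <- tabulate(patch[coop], np) / M
    w <- 1 + p$B * cfrac[patch] - p$C_G * coop - p$C_C * (pl > 0L)
    wbar[t + 1L] <- mean(w)

    # survival + dispersal: fitness-proportional multinomial founder draw
    founders <- g[sample.int(ncell, nF, replace = TRUE, prob = w)]

    # segregation loss, then loss-of-function mutation, on founders
    plf <- (founders - 1L) %% 3L
    lose <- plf > 0L & runif(nF) < p$s
    founders[lose] <- founders[lose] - plf[lose]
    mut <- (founders - 1L) %% 3L == 1L & runif(nF) < p$mu
    founders[mut] <- founders[mut] + 1L

    rec(t + 1L, founders)
  }

  traj <- data.frame(generation = 0:G, freq, se, mean_fitness = wbar)
  names(traj) <- c("generation", GENOTYPES, paste0("se_", GENOTYPES),
                   "mean_fitness")
  structure(
    list(trajectory = traj,
         relatedness_hat = data.frame(generation = seq_len(G) - 1L,
                                      R_hat = rhat),
         config = config, seed_used = config$seed),
    class = "ibs_output"
  )
}

#' @export
print.ibs_output <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Individual-based run: %d patches x %d cells, %d generations, seed %d\n",
    cfg$n_patches, cfg$patch_size, cfg$generations, x$seed_used))
  last <- x$trajectory[nrow(x$trajectory), ]
  pt <- last[["noncoop:coopP"]] + last[["noncoop:defP"]] +
    last[["coop:coopP"]] + last[["coop:defP"]]
  cat(sprintf("final p_total = %.4f\n", pt))
  invisible(x)
}
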