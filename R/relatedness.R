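# Whole-group relatedness at the chromosomal and plasmid loci.
#
# Chromosomal relatedness in this island-structured lifecycle is 1/N: a focal
# founder's lineage makes up exactly 1/N of its patch at the time of social
# action.  A plasmid lineage additionally spreads horizontally: if its patch
# contains a fraction f0 of plasmid-free cells, every plasmid lineage present
# is amplified by the factor T = 1 + beta * f0 during the transfer round
# (conversions are allocated in proportion to type frequency, so the factor
# is type-blind).  Plasmid relatedness is defined as the copy-weighted
# expected patch share of a focal plasmid lineage at the moment of social
# action,
#
#   R_plas = E[T^2] / (N * E[T]),
#
# the expectation running over the multinomial distribution of the focal
# founder's N - 1 patch co-founders.  This is the quantity whose Hamilton
# threshold R_plas * B > C_G exactly separates cooperator- from
# defector-plasmid success in the recursion (see the methods vignette for the
# derivation), and it reduces to 1/N when beta = 0 and at plasmid fixation.

#' Chromosomal whole-group relatedness
#'
#' In a population of patches founded by `N` independent cells, a focal
#' founder's lineage is exactly `1/N` of its patch when social interactions
#' occur, so whole-group relatedness at any chromosomal locus is `1/N`.
#'
#' @param N founder cells per patch (>= 1).
#' @return `1/N`.
#' @examples
#' chromosome_relatedness(20)  # 0.05
#' @export
chromosome_relatedness <- function(N) {
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  1 / N
}

#' Plasmid whole-group relatedness
#'
#' Computes relatedness at the plasmid locus by exact enumeration over the
#' multinomial founder compositions of a focal plasmid-bearing cell's
#' `N - 1` patch co-founders.  With `f0` the pre-transfer patch frequency of
#' plasmid-free cells, every plasmid lineage in the patch is amplified by
#' `T = 1 + beta * f0` in the transfer round, and
#' `R_plas = E[T^2] / (N * E[T])`: the copy-weighted expected fraction of the
#' patch occupied by the focal lineage's copies at the moment the public good
#' is produced.  Transfer is type-blind, so `R_plas` depends on the plasmid
#' frequencies only through their total `p_C + p_D`; both are accepted so a
#' state's marginals can be passed through unchanged.
#'
#' Limits: `R_plas = 1/N` exactly when `beta = 0` (the plasmid is transmitted
#' like a chromosomal locus) and when `p_C + p_D = 1` (no free cells — at
#' fixation transfer stops and plasmid relatedness equals chromosomal
#' relatedness); `R_plas` rises towards `(1 + beta (N-1)/N)/N` as plasmids
#' become rare; and `1/N <= R_plas <= 1` always.
#'
#' @param p_C population frequency of the cooperator plasmid.
#' @param p_D population frequency of the defector plasmid.
#' @param N founder cells per patch.
#' @param beta transfer probability per pairing.
#' @return An object of class `relatedness_result`: list with `R_plas`,
#'   `R_chrom = 1/N`, `ratio = R_plas/R_chrom`, `p_total_post` (global
#'   post-transfer plasmid frequency), the inputs, and `defined = TRUE`.
#' @examples
#' plasmid_relatedness(0.01, 0, N = 6, beta = 0.6)  # rare plasmid: high R
#' plasmid_relatedness(0.7, 0.3, N = 6, beta = 0.6) # fixation: ratio 1
#' @export
plasmid_relatedness <- function(p_C, p_D, N, beta) {
  if (p_C < 0 || p_D < 0 || p_C + p_D > 1 + 1e-12)
    stop("p_C and p_D must be non-negative with p_C + p_D <= 1")
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  p_total <- min(p_C + p_D, 1)

  if (N == 1) {
    ET <- 1; ET2 <- 1; R <- 1
  } else {
    # enumerate compositions (n_C, n_D, n_free) of the N - 1 co-founders
    cm <- .compositions(N - 1L, 3L)
    pr <- c(p_C, p_D, 1 - p_total)
    act <- pr > 0
    keep <- rowSums(cm[, !act, drop = FALSE]) == 0L
    cm <- cm[keep, , drop = FALSE]
    lw <- lgamma(N) - rowSums(lgamma(cm + 1))
    lw <- lw + as.vector(cm[, act, drop = FALSE] %*% log(pr[act]))
    w <- exp(lw)
    f0 <- cm[, 3] / N                 # patch frequency of free cells
    Tk <- 1 + beta * f0               # lineage amplification by transfer
    ET <- sum(w * Tk)
    ET2 <- sum(w * Tk^2)
    R <- ET2 / (N * ET)
  }

  structure(
    list(R_plas = R,
         R_chrom = 1 / N,
         ratio = R * N,
         p_total_post = p_total * (1 + realized_transfer_rate(beta, N, p_total)),
         p_C = p_C, p_D = p_D, N = as.integer(N), beta = beta,
         defined = TRUE),
    class = "relatedness_result"
  )
}

#' @export
print.relatedness_result <- function(x, ...) {
  if (!x$defined) {
    cat("Plasmid relatedness: undefined (plasmids absent)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Plasmid relatedness at p_C = %g, p_D = %g (N = %d, beta = %g):\n",
    x$p_C, x$p_D, x$N, x$beta))
  cat(sprintf("  R_plas = %.6f, R_chrom = %.6f, ratio = %.4f\n",
              x$R_plas, x$R_chrom, x$ratio))
  invisible(x)
}

#' Realized plasmid transfer rate
#'
#' The effective per-plasmid transmission opportunity: the probability that a
#' free/bearer pairing transmits (`beta`) times the local availability of
#' plasmid-free cells, `((N - 1)/N) * (1 - p_total)`.  It is the same for
#' cooperator and defector plasmids (shared origin of replication) and falls
#' to zero at plasmid fixation.
#'
#' @param beta transfer probability per pairing.
#' @param N founder cells per patch.
#' @param p_total total population frequency of plasmids (both types).
#' @return `beta * ((N - 1)/N) * (1 - p_total)` (vectorised over `p_total`).
#' @examples
#' realized_transfer_rate(0.95, 4, 0)  # 0.7125
#' realized_transfer_rate(0.95, 4, 1)  # 0: no free cells
#' @export
realized_transfer_rate <- function(beta, N, p_total) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  if (any(p_total < 0 | p_total > 1)) stop("p_total must be in [0, 1]")
  beta * ((N - 1) / N) * (1 - p_total)
}

#' Relatedness evaluated at a population state
#'
#' Extracts the plasmid marginals of a full six-genotype state and delegates
#' to [plasmid_relatedness()] (relatedness at the plasmid locus does not
#' depend on the chromosomal background under this lifecycle).  When the
#' total plasmid frequency is below `1e-6` the result is flagged undefined —
#' there are no plasmids whose relatedness could be measured.
#'
#' @param state a [coop_state()].
#' @param params a [coop_params()].
#' @return A `relatedness_result`; `defined = FALSE` (with `NA` values) when
#'   plasmids are absent.
#' @export
relatedness_at_state <- function(state, params) {
  params <- .as_params(params)
  m <- plasmid_marginals(state)
  if (m[["p_total"]] < 1e-6) {
    return(structure(
      list(R_plas = NA_real_, R_chrom = 1 / params$N, ratio = NA_real_,
           p_total_post = m[["p_total"]],
           p_C = m[["p_C"]], p_D = m[["p_D"]],
           N = params$N, beta = params$beta, defined = FALSE),
      class = "relatedness_result"
    ))
  }
  plasmid_relatedness(m[["p_C"]], m[["p_D"]], params$N, params$beta)
}
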