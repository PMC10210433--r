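# Equilibrium, invasion and parameter-sweep analyses built on the recursion.

# Cells whose equilibrium sits within this margin of the Hamilton boundary
# R_plas * B = C_G are flagged near-boundary: selection between cooperator
# and defector plasmids is vanishingly weak there, convergence is slow and
# the 0/1 classification is not meaningful.
.BOUNDARY_MARGIN <- 1e-3

# Plasmid frequencies below this are treated as "plasmids absent" when
# classifying equilibria (matches the undefined regions of the phase
# diagrams).
.PLASMID_PRESENT <- 1e-6

#' Iterate the recursion to equilibrium
#'
#' Repeats [generation_step()] until the L-infinity change in genotype
#' frequencies stays below `tol` for 50 consecutive generations, or `max_gen`
#' is reached.  Non-convergence is flagged, never an error.
#'
#' @param state0 starting [coop_state()].
#' @param params a [coop_params()].
#' @param tol convergence tolerance on the per-generation L-infinity
#'   frequency change (default `1e-10`).
#' @param max_gen generation cap (default `2e5`).
#' @param consecutive generations the change must stay below `tol`
#'   (default 50).
#' @return An `equilibrium_summary`: list with `state_star`, `p_total_star`,
#'   `cooperativeness_star` (`NA` when plasmids are absent),
#'   `cooperator_freq_star`, `R_plas_star` (`NA` when undefined), `R_chrom`,
#'   `generations_run`, `converged`, `max_delta` and `params`.
#' @examples
#' p <- coop_params(20, 0.95, 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' iterate_to_equilibrium(seed_state(p_coop = 1e-3, p_def = 1e-3), p)
#' @export
iterate_to_equilibrium <- function(state0, params, tol = 1e-10,
                                   max_gen = 2e5, consecutive = 50L) {
  params <- .as_params(params)
  if (tol <= 0) stop("tol must be positive")
  x <- unclass(coop_state(state0))
  res <- cpp_iterate(x, params$N, params$beta, params$s, params$B,
                     params$C_G, params$C_C, params$mu,
                     tol, as.integer(max_gen), as.integer(consecutive))
  st <- coop_state(res$state)
  rel <- relatedness_at_state(st, params)
  out <- structure(
    list(state_star = st,
         p_total_star = plasmid_marginals(st)[["p_total"]],
         cooperativeness_star = NA_real_,
         cooperator_freq_star = NA_real_,
         R_plas_star = if (rel$defined) rel$R_plas else NA_real_,
         R_chrom = 1 / params$N,
         generations_run = res$generations,
         converged = res$converged,
         max_delta = res$max_delta,
         params = params),
    class = "equilibrium_summary"
  )
  classify_equilibrium(out)
}

#' Classify an equilibrium
#'
#' Fills in plasmid cooperativeness (the proportion of plasmids carrying the
#' cooperation gene, `p_C*/(p_C* + p_D*)`, undefined when plasmids are
#' absent) and the cooperator frequency (cooperativeness times total plasmid
#' frequency — the population-level amount of plasmid-borne cooperation).
#'
#' @param summary an `equilibrium_summary`.
#' @return The summary with `cooperativeness_star` and
#'   `cooperator_freq_star` set.
#' @export
classify_equilibrium <- function(summary) {
  if (!inherits(summary, "equilibrium_summary"))
    stop("summary must be an equilibrium_summary")
  m <- plasmid_marginals(summary$state_star)
  if (m[["p_total"]] >= .PLASMID_PRESENT) {
    summary$cooperativeness_star <- m[["p_C"]] / m[["p_total"]]
    summary$cooperator_freq_star <- summary$cooperativeness_star * m[["p_total"]]
  } else {
    summary$cooperativeness_star <- NA_real_
    summary$cooperator_freq_star <- 0
  }
  summary
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf("Equilibrium after %d generations (%s, max delta %.3g):\n",
              x$generations_run,
              if (x$converged) "converged" else "NOT converged",
              x$max_delta))
  cat(sprintf("  p_total* = %.6f, cooperativeness* = %s, cooperator freq* = %.6f\n",
              x$p_total_star,
              if (is.na(x$cooperativeness_star)) "undefined"
              else sprintf("%.6f", x$cooperativeness_star),
              x$cooperator_freq_star))
  cat(sprintf("  R_plas* = %s, R_chrom = %.6f\n",
              if (is.na(x$R_plas_star)) "undefined"
              else sprintf("%.6f", x$R_plas_star),
              x$R_chrom))
  invisible(x)
}

#' Hamilton's rule check at equilibrium
#'
#' Returns `TRUE` when `R_plas* x B > C_G` (strict inequality), the condition
#' under which cooperation is favoured at the plasmid locus.  Over a
#' parameter sweep this predicts equilibrium plasmid cooperativeness: 1 where
#' the condition holds, 0 where it fails.
#'
#' @param summary a converged `equilibrium_summary` with defined `R_plas_star`.
#' @param params a [coop_params()].
#' @return Logical scalar, with attribute `"near_boundary"` set when
#'   `|R_plas* x B - C_G| < 1e-3`.
#' @export
hamilton_check <- function(summary, params) {
  params <- .as_params(params)
  if (!inherits(summary, "equilibrium_summary"))
    stop("summary must be an equilibrium_summary")
  if (is.na(summary$R_plas_star))
    stop("R_plas_star is undefined (plasmids absent at equilibrium)")
  margin <- summary$R_plas_star * params$B - params$C_G
  out <- margin > 0
  attr(out, "near_boundary") <- abs(margin) < .BOUNDARY_MARGIN
  out
}

#' Invasion growth factor of a rare genotype
#'
#' Seeds `invader` at frequency `eps` into a resident population, runs the
#' recursion, and returns the geometric-mean per-generation growth factor of
#' the invader over the generations during which its frequency stays below
#' `10 * eps` (the linear regime).  Values above 1 mean invasion.
#'
#' @param resident a [coop_state()], normally an equilibrium of the dynamics
#'   without the invader.
#' @param invader genotype to introduce (name, shorthand such as `"P_COOP"`,
#'   or index; see [as_genotype()]).
#' @param params a [coop_params()].
#' @param eps seeding frequency (default `1e-6`).
#' @param generations generations to run (default 200).
#' @return The geometric-mean growth factor (numeric scalar).
#' @examples
#' p <- coop_params(20, 0.95, 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' invasion_test(seed_state(), "P_COOP", p)  # > 1: cooperator plasmid invades
#' @export
invasion_test <- function(resident, invader, params, eps = 1e-6,
                          generations = 200L) {
  params <- .as_params(params)
  if (eps <= 0 || eps >= 0.1) stop("eps must be in (0, 0.1)")
  g <- as_genotype(invader)
  if (length(g) != 1L) stop("invader must be a single genotype")
  x <- unclass(coop_state(resident))
  if (x[g] > eps) stop("invader already present above eps in the resident")
  x <- x * (1 - eps)
  x[g] <- x[g] + eps
  traj <- run_recursion(coop_state(x), params, generations)
  freq <- traj[[GENOTYPES[g]]]
  ratios <- numeric(0)
  for (t in seq_len(nrow(traj) - 1L)) {
    if (freq[t] <= 0 || freq[t] >= 10 * eps) break
    ratios <- c(ratios, freq[t + 1L] / freq[t])
  }
  if (length(ratios) == 0L) return(if (freq[2] <= 0) 0 else NA_real_)
  exp(mean(log(pmax(ratios, .Machine$double.xmin))))
}

#' Sweep the transfer/loss parameter plane
#'
#' Runs the standard protocol at every point of a `beta` x `s` grid: seed
#' cooperator and defector plasmids at `seed_freq` each in a population with
#' a noncooperative chromosome, iterate to equilibrium, classify, and
#' evaluate plasmid relatedness at the equilibrium.  Optionally each
#' equilibrium is challenged by re-invasion of whichever plasmid type is
#' absent, to distinguish maintenance from mere invasion.
#'
#' @param params a [coop_params()]; its `beta` and `s` are replaced cell by
#'   cell.
#' @param beta_grid,s_grid numeric grids in `[0, 1]` (default 21 points each).
#' @param seed_freq initial frequency of each plasmid type (default `1e-3`).
#' @param tol,max_gen convergence control, as in [iterate_to_equilibrium()].
#' @param challenge run re-invasion tests of absent plasmid types
#'   (default `TRUE`).
#' @return A data frame of class `coop_sweep` with one row per cell and
#'   columns `beta`, `s`, `p_total`, `cooperativeness`, `cooperator_freq`,
#'   `R_plas`, `R_chrom`, `converged`, `flag` (`"ok"`, `"near-boundary"`,
#'   `"not-converged"` and/or `"unstable"`).  The fixed parameters are kept
#'   in `attr(, "params")`.
#' @examples
#' p <- coop_params(20, 0.5, 0.5, B = 1.435, C_G = 0.1, C_C = 0.2)
#' sw <- sweep_equilibria(p, beta_grid = c(0, 0.5, 1), s_grid = c(0, 0.3))
#' sw
#' @export
sweep_equilibria <- function(params,
                             beta_grid = seq(0, 1, length.out = 21),
                             s_grid = seq(0, 1, length.out = 21),
                             seed_freq = 1e-3, tol = 1e-10, max_gen = 2e5,
                             challenge = TRUE) {
  params <- .as_params(params)
  if (any(beta_grid < 0 | beta_grid > 1) || any(s_grid < 0 | s_grid > 1))
    stop("grids must lie within [0, 1]")
  state0 <- seed_state(p_coop = seed_freq, p_def = seed_freq)
  grid <- expand.grid(beta = beta_grid, s = s_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  out <- data.frame(beta = grid$beta, s = grid$s,
                    p_total = NA_real_, cooperativeness = NA_real_,
                    cooperator_freq = NA_real_, R_plas = NA_real_,
                    R_chrom = 1 / params$N, converged = NA,
                    flag = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$beta <- grid$beta[i]
    p_i$s <- grid$s[i]
    eq <- iterate_to_equilibrium(state0, p_i, tol = tol, max_gen = max_gen)
    flags <- character(0)
    if (!eq$converged) flags <- c(flags, "not-converged")
    if (!is.na(eq$R_plas_star)) {
      hc <- hamilton_check(eq, p_i)
      if (attr(hc, "near_boundary")) flags <- c(flags, "near-boundary")
    }
    if (challenge && eq$converged) {
      m <- plasmid_marginals(eq$state_star)
      for (type in c("P_COOP", "P_DEF")) {
        present <- if (type == "P_COOP") m[["p_C"]] else m[["p_D"]]
        if (present < .PLASMID_PRESENT) {
          gf <- invasion_test(eq$state_star, type, p_i, eps = 1e-6,
                              generations = 200L)
          if (!is.na(gf) && gf > 1 + 1e-9) flags <- c(flags, "unstable")
        }
      }
    }
    out$p_total[i] <- eq$p_total_star
    out$cooperativeness[i] <- eq$cooperativeness_star
    out$cooperator_freq[i] <- eq$cooperator_freq_star
    out$R_plas[i] <- eq$R_plas_star
    out$converged[i] <- eq$converged
    out$flag[i] <- if (length(flags)) paste(flags, collapse = ";") else "ok"
  }
  attr(out, "params") <- params
  class(out) <- c("coop_sweep", "data.frame")
  out
}

#' Per-capita plasmid growth factor along a frequency gradient
#'
#' Evaluates the one-generation per-capita growth factor of the total plasmid
#' frequency at each starting frequency in `p_grid` (all other conditions
#' fixed).  Selection on plasmids in this model is negatively
#' frequency-dependent: the more common plasmids are, the fewer free cells
#' remain to infect, so the returned profile is non-increasing.
#'
#' @param params a [coop_params()].
#' @param p_grid starting total plasmid frequencies, strictly inside (0, 1).
#' @param coop_share fraction of the seeded plasmids that are cooperators
#'   (default 0: pure defector plasmids, isolating the transfer/loss/cost
#'   forces).
#' @return Data frame with columns `p_total` and `growth_factor`.
#' @examples
#' p <- coop_params(20, 0.95, 0.1, B = 1.435, C_G = 0.1, C_C = 0.2)
#' prof <- frequency_dependence_profile(p, p_grid = c(0.05, 0.5, 0.95))
#' all(diff(prof$growth_factor) <= 0)
#' @export
frequency_dependence_profile <- function(params, p_grid, coop_share = 0) {
  params <- .as_params(params)
  if (any(p_grid <= 0 | p_grid >= 1)) stop("p_grid must lie strictly in (0, 1)")
  if (coop_share < 0 || coop_share > 1) stop("coop_share must be in [0, 1]")
  gf <- vapply(p_grid, function(p) {
    st <- seed_state(p_coop = p * coop_share, p_def = p * (1 - coop_share))
    nxt <- generation_step(st, params)
    plasmid_marginals(nxt)[["p_total"]] / p
  }, numeric(1))
  data.frame(p_total = p_grid, growth_factor = gf)
}
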