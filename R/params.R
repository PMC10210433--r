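#' Model parameters
#'
#' Lifecycle rates and costs of the patch-structured model of plasmid- and
#' chromosome-encoded public-goods cooperation.  Each generation the
#' population is divided into patches founded by `N` independent cells that
#' grow clonally; cells pair at random within the patch and a plasmid-free
#' cell acquires its partner's plasmid with probability `beta` (transfer is
#' blocked if the recipient already carries a plasmid — incompatibility);
#' cooperators produce a public good at cost `C_G` generating a benefit `B`
#' shared among all patch members; plasmid carriage costs `C_C`; bearers lose
#' their plasmid with probability `s`; cooperator plasmids mutate to defector
#' plasmids with probability `mu`; finally everyone disperses globally.
#'
#' @param N integer, founder cells per patch (>= 1).  Chromosomal whole-group
#'   relatedness is `1/N`.
#' @param beta plasmid transfer probability per pairing, in `[0, 1]`.
#' @param s plasmid (segregation) loss probability per generation, in `[0, 1]`.
#' @param B public-good benefit, shared over the whole patch (>= 0,
#'   dimensionless fitness units).
#' @param C_G cost of public-goods production, in `[0, 1)`.  Paid once even
#'   under redundant (chromosome + plasmid) carriage.
#' @param C_C cost of plasmid carriage, in `[0, 1)`.
#' @param mu cooperator-to-defector plasmid loss-of-function mutation
#'   probability per generation, in `[0, 1]`; default 0.
#' @return An object of class `coop_params`.
#' @examples
#' coop_params(N = 20, beta = 0.95, s = 0.3, B = 1.435, C_G = 0.1, C_C = 0.2)
#' @export
coop_params <- function(N, beta, s, B, C_G, C_C, mu = 0) {
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N))
    stop("N must be a single integer >= 1")
  chk01 <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(name, " must be a single value in [0, 1], got ", format(x))
  }
  chk01(beta, "beta"); chk01(s, "s"); chk01(mu, "mu")
  if (length(B) != 1 || is.na(B) || B < 0) stop("B must be a single value >= 0")
  if (length(C_G) != 1 || is.na(C_G) || C_G < 0 || C_G >= 1)
    stop("C_G must be in [0, 1)")
  if (length(C_C) != 1 || is.na(C_C) || C_C < 0 || C_C >= 1)
    stop("C_C must be in [0, 1)")
  if (1 - C_G - C_C <= 0)
    stop("baseline fitness 1 - C_G - C_C must be positive ",
         "(every genotype must have positive fitness in every patch)")
  structure(
    list(N = as.integer(N), beta = beta, s = s, B = B,
         C_G = C_G, C_C = C_C, mu = mu),
    class = "coop_params"
  )
}

#' @export
print.coop_params <- function(x, ...) {
  cat(sprintf(
    "Model parameters: N = %d, beta = %g, s = %g, B = %g, C_G = %g, C_C = %g, mu = %g\n",
    x$N, x$beta, x$s, x$B, x$C_G, x$C_C, x$mu))
  invisible(x)
}

#' @export
format.coop_params <- function(x, ...) {
  sprintf("N=%d beta=%g s=%g B=%g C_G=%g C_C=%g mu=%g",
          x$N, x$beta, x$s, x$B, x$C_G, x$C_C, x$mu)
}

.as_params <- function(params) {
  if (!inherits(params, "coop_params"))
    stop("params must be a coop_params object; see coop_params()")
  params
}
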