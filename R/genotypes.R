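# Genotype space: haploid cells carry a chromosomal cooperation allele
# (coop / noncoop) and at most one plasmid (none / coopP / defP).  Plasmid
# incompatibility means a bearer can never acquire a second plasmid, so the
# state space is exactly these six genotypes.
#
# Internal coding: genotype index g in 1..6 with
#   chromosome = (g - 1) %/% 3   (0 = noncoop, 1 = coop)
#   plasmid    = (g - 1) %%  3   (0 = none, 1 = coopP, 2 = defP)

GENOTYPES <- c("noncoop:none", "noncoop:coopP", "noncoop:defP",
               "coop:none", "coop:coopP", "coop:defP")

.chrom_of   <- function(g) (g - 1L) %/% 3L
.plasmid_of <- function(g) (g - 1L) %% 3L

#' Genotype table
#'
#' The six haploid genotypes of the model: a chromosomal background
#' (`noncoop` or `coop`) combined with plasmid state (`none`, cooperator
#' plasmid `coopP`, or defector plasmid `defP`).  A cell carries at most one
#' plasmid (incompatibility).
#'
#' @return A data frame with one row per genotype and columns `genotype`,
#'   `chromosome`, `plasmid`, `cooperator` (carries a cooperation gene on
#'   chromosome or plasmid) and `carrier` (bears any plasmid).
#' @examples
#' genotype_table()
#' @export
genotype_table <- function() {
  g <- seq_along(GENOTYPES)
  data.frame(
    genotype   = GENOTYPES,
    chromosome = c("noncoop", "coop")[.chrom_of(g) + 1L],
    plasmid    = c("none", "coopP", "defP")[.plasmid_of(g) + 1L],
    cooperator = is_cooperator(GENOTYPES),
    carrier    = has_plasmid(GENOTYPES),
    stringsAsFactors = FALSE
  )
}

#' @rdname genotype_table
#' @export
genotype_names <- function() GENOTYPES

#' Resolve genotypes to internal indices
#'
#' Accepts genotype names (`"noncoop:coopP"`), bare plasmid shorthands
#' (`"coopP"`, `"defP"`, `"P_COOP"`, `"P_DEF"` — taken on the noncooperative
#' chromosomal background), or integer indices 1..6.
#'
#' @param g genotype specification (character or integer vector).
#' @return Integer vector of genotype indices.
#' @export
as_genotype <- function(g) {
  if (is.numeric(g)) {
    g <- as.integer(g)
    if (any(g < 1L | g > 6L)) stop("genotype index must be in 1..6")
    return(g)
  }
  shorthand <- c(P_COOP = "noncoop:coopP", P_DEF = "noncoop:defP",
                 coopP = "noncoop:coopP", defP = "noncoop:defP",
                 free = "noncoop:none")
  g <- ifelse(g %in% names(shorthand), shorthand[g], g)
  idx <- match(g, GENOTYPES)
  if (anyNA(idx)) {
    stop("unknown genotype(s): ", paste(g[is.na(idx)], collapse = ", "),
         "; valid names are ", paste(GENOTYPES, collapse = ", "))
  }
  idx
}

#' Genotype predicates
#'
#' `is_cooperator()` is TRUE for genotypes carrying a cooperation gene on the
#' chromosome or the plasmid (or both — redundant carriage still produces the
#' public good once).  `has_plasmid()` is TRUE for plasmid bearers.
#'
#' @param g genotype names or indices (see [as_genotype()]).
#' @return Logical vector.
#' @export
is_cooperator <- function(g) {
  g <- as_genotype(g)
  .chrom_of(g) == 1L | .plasmid_of(g) == 1L
}

#' @rdname is_cooperator
#' @export
has_plasmid <- function(g) {
  g <- as_genotype(g)
  .plasmid_of(g) > 0L
}

#' Population state
#'
#' A population state is the vector of global genotype frequencies on the
#' 6-simplex.  Frequencies must be non-negative and sum to 1 within 1e-12.
#'
#' @param freq numeric vector of length 6 (optionally named with genotype
#'   names, in any order).
#' @return A named numeric vector of class `coop_state`, ordered as
#'   [genotype_names()].
#' @examples
#' coop_state(c(0.9, 0.05, 0.05, 0, 0, 0))
#' @export
coop_state <- function(freq) {
  if (length(freq) != 6L) stop("a population state has exactly 6 genotype frequencies")
  if (!is.null(names(freq))) {
    idx <- match(GENOTYPES, names(freq))
    if (anyNA(idx)) stop("state names must be the genotype names; see genotype_names()")
    freq <- freq[idx]
  }
  freq <- as.numeric(freq)
  if (any(freq < 0)) stop("genotype frequencies must be non-negative")
  if (abs(sum(freq) - 1) > 1e-12) {
    stop("genotype frequencies must sum to 1 (|sum - 1| = ",
         format(abs(sum(freq) - 1)), ")")
  }
  structure(setNames(freq, GENOTYPES), class = "coop_state")
}

#' @export
print.coop_state <- function(x, ...) {
  cat("Population state (genotype frequencies):\n")
  print(round(unclass(x), 6))
  m <- plasmid_marginals(x)
  cat(sprintf("p_C = %.6g, p_D = %.6g, p_total = %.6g\n",
              m[["p_C"]], m[["p_D"]], m[["p_total"]]))
  invisible(x)
}

#' Build a state from marginal frequencies
#'
#' Constructs a population state in which plasmid carriage and the chromosomal
#' cooperation allele are distributed independently — the natural seeding for
#' invasion and sweep protocols.
#'
#' @param p_coop frequency of the cooperator plasmid.
#' @param p_def frequency of the defector plasmid.
#' @param chrom_coop frequency of the chromosomal cooperation allele.
#' @return A [coop_state()].
#' @examples
#' seed_state(p_coop = 1e-3, p_def = 1e-3)
#' @export
seed_state <- function(p_coop = 0, p_def = 0, chrom_coop = 0) {
  if (p_coop < 0 || p_def < 0 || chrom_coop < 0 || chrom_coop > 1)
    stop("marginal frequencies must be in [0, 1]")
  if (p_coop + p_def > 1) stop("p_coop + p_def must not exceed 1")
  plas <- c(1 - p_coop - p_def, p_coop, p_def)
  coop_state(c((1 - chrom_coop) * plas, chrom_coop * plas))
}

#' Plasmid marginals of a state
#'
#' @param state a [coop_state()].
#' @return Named numeric vector with `p_C` (cooperator-plasmid frequency),
#'   `p_D` (defector-plasmid frequency), `p_total` and `chrom_coop`
#'   (chromosomal cooperation allele frequency).
#' @export
plasmid_marginals <- function(state) {
  x <- unname(unclass(coop_state(state)))
  c(p_C = x[2] + x[5],
    p_D = x[3] + x[6],
    p_total = x[2] + x[3] + x[5] + x[6],
    chrom_coop = x[4] + x[5] + x[6])
}
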