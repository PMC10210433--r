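# Figure builders.  Each plot_* function returns a ggplot object;
# figure_scripts() regenerates the standard set from result CSVs.

#' Relatedness-ratio curves
#'
#' Plots plasmid relatedness relative to chromosomal relatedness
#' (`R_plas / R_chrom`) as a function of cooperator-plasmid frequency.
#' Exactly one of `N`, `beta`, `p_D` may be a vector, giving one curve per
#' value.  All curves decrease monotonically and reach 1 at plasmid
#' fixation.
#'
#' @param N founder numbers (scalar or vector).
#' @param beta transfer probabilities (scalar or vector).
#' @param p_D defector-plasmid frequencies (scalar or vector).
#' @param p_grid cooperator-plasmid frequency grid.
#' @return A ggplot object.
#' @examples
#' plot_relatedness_ratio(N = c(2, 6, 20), beta = 0.6)
#' @export
plot_relatedness_ratio <- function(N = 6, beta = 0.6, p_D = 0,
                                   p_grid = seq(0.001, 0.999, length.out = 120)) {
  lens <- c(N = length(N), beta = length(beta), p_D = length(p_D))
  if (sum(lens > 1) > 1)
    stop("only one of N, beta, p_D may be a vector")
  vary <- if (any(lens > 1)) names(lens)[lens > 1] else "N"
  cases <- expand.grid(N = N, beta = beta, p_D = p_D,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    ci <- cases[i, ]
    pg <- p_grid[p_grid + ci$p_D <= 1]
    ratio <- vapply(pg, function(p)
      plasmid_relatedness(p, ci$p_D, ci$N, ci$beta)$ratio, numeric(1))
    data.frame(p_C = pg, ratio = ratio,
               curve = paste0(vary, " = ", ci[[vary]]))
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$p_C, y = .data$ratio,
                                     colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "cooperator plasmid frequency (p_C)",
                  y = "R_plas / R_chrom", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Realized transfer-rate curves
#'
#' The effective per-plasmid transmission opportunity
#' `beta * ((N-1)/N) * (1 - p_total)` against total plasmid frequency, one
#' curve per `(beta, N)` case.  Every curve decreases linearly to 0 at
#' plasmid fixation.
#'
#' @param cases data frame with columns `beta` and `N`.
#' @param p_grid total plasmid frequency grid.
#' @return A ggplot object.
#' @examples
#' plot_transfer_rate(data.frame(beta = c(0.95, 0.95, 0.6), N = c(4, 2, 4)))
#' @export
plot_transfer_rate <- function(cases,
                               p_grid = seq(0, 1, length.out = 101)) {
  if (!all(c("beta", "N") %in% names(cases)) || nrow(cases) == 0)
    stop("cases must be a non-empty data frame with columns beta and N")
  rows <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    data.frame(p_total = p_grid,
               rate = realized_transfer_rate(cases$beta[i], cases$N[i], p_grid),
               curve = sprintf("beta = %g, N = %d", cases$beta[i],
                               as.integer(cases$N[i])))
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$p_total, y = .data$rate,
                                     colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "total plasmid frequency",
                  y = "realized transfer rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Four-panel equilibrium phase diagram
#'
#' Heatmaps of equilibrium plasmid relatedness, cooperativeness, total
#' plasmid frequency and cooperator frequency over the `(beta, s)` plane of a
#' sweep.  Cells where plasmids are absent (relatedness and cooperativeness
#' undefined) are left blank.
#'
#' @param sweep a `coop_sweep` data frame (from [sweep_equilibria()] or
#'   [read_results()]).
#' @return A ggplot object (facets = the four panels).
#' @export
plot_sweep <- function(sweep) {
  need <- c("beta", "s", "R_plas", "cooperativeness", "p_total",
            "cooperator_freq")
  miss <- setdiff(need, names(sweep))
  if (length(miss)) stop("sweep is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(sweep) == 0) stop("sweep is empty")
  panels <- c(R_plas = "plasmid relatedness",
              cooperativeness = "plasmid cooperativeness",
              p_total = "plasmid frequency",
              cooperator_freq = "cooperator frequency")
  rows <- do.call(rbind, lapply(names(panels), function(v) {
    data.frame(beta = sweep$beta, s = sweep$s, value = sweep[[v]],
               panel = factor(panels[[v]], levels = unname(panels)))
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$s,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, nrow = 2, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "transfer probability (beta)",
                  y = "loss probability (s)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Genotype-frequency trajectory plot
#'
#' @param traj a `coop_trajectory` data frame (from [run_recursion()],
#'   [run_ibs()]'s `$trajectory`, or [read_results()]).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  miss <- setdiff(c("generation", GENOTYPES), names(traj))
  if (length(miss)) stop("trajectory is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(traj) == 0) stop("trajectory is empty")
  rows <- do.call(rbind, lapply(GENOTYPES, function(g) {
    data.frame(generation = traj$generation, frequency = traj[[g]],
               genotype = g)
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$generation,
                                     y = .data$frequency,
                                     colour = .data$genotype)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "generation", y = "frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Regenerate the standard figures from result CSVs
#'
#' Writes PDF figures into `out_dir`: relatedness-ratio curves and realized
#' transfer-rate curves (computed directly from the package's calculators),
#' the four-panel equilibrium phase diagram from `sweep_csv`, and, when
#' given, a trajectory plot from `trajectory_csv`.
#'
#' @param sweep_csv path to a sweep CSV written by [write_results()].
#' @param out_dir output directory (created if needed).
#' @param trajectory_csv optional path to a trajectory CSV.
#' @return Character vector of the files written, invisibly.
#' @export
figure_scripts <- function(sweep_csv, out_dir, trajectory_csv = NULL) {
  sweep <- read_results(sweep_csv)
  if (nrow(sweep) == 0) stop("sweep CSV is empty: ", sweep_csv)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  save_pdf <- function(plot, name, width = 7, height = 5) {
    f <- file.path(out_dir, name)
    grDevices::pdf(f, width = width, height = height)
    on.exit(grDevices::dev.off())
    print(plot)
    f
  }
  written <- c(
    save_pdf(plot_relatedness_ratio(N = c(2, 6, 20), beta = 0.6),
             "relatedness_ratio.pdf"),
    save_pdf(plot_transfer_rate(
      data.frame(beta = c(0.95, 0.95, 0.6), N = c(4, 2, 4))),
      "transfer_rate.pdf"),
    save_pdf(plot_sweep(sweep), "sweep_panels.pdf", width = 8, height = 6)
  )
  if (!is.null(trajectory_csv)) {
    traj <- read_results(trajectory_csv)
    written <- c(written, save_pdf(plot_trajectory(traj), "trajectory.pdf"))
  }
  message("wrote ", length(written), " figure(s) to ", out_dir)
  invisible(written)
}
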