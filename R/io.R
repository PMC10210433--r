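# Configuration files and CSV output.  Configs are flat key = value files in
# JSON or TOML; results are comma-separated UTF-8 CSVs with '#'-prefixed
# metadata lines (full parameter set and package version) before the header,
# so any output file is reproducible from its own header.

.PARAM_KEYS <- c("N", "beta", "s", "B", "C_G", "C_C", "mu")
.RUN_KEYS <- c("p_coop0", "p_def0", "chrom_coop0", "generations", "tol",
               "max_gen", "n_patches", "patch_size", "seed")

# Minimal reader for flat TOML (key = value lines; comments; bare numbers,
# booleans and quoted strings).  No TOML parser is available among the
# package's dependencies and configs here never need nesting.
.read_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (any(grepl("^\\[", lines)))
    stop("only flat key = value TOML is supported (no [tables])")
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse TOML line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("cannot parse TOML value for '", key, "': ", val)
        num
      }
  }
  out
}

#' Load a run configuration
#'
#' Reads a flat JSON or TOML file with the model parameters (`N`, `beta`,
#' `s`, `B`, `C_G`, `C_C`, optional `mu`) and optional run controls
#' (`p_coop0`, `p_def0`, `chrom_coop0`, `generations`, `tol`, `max_gen`,
#' `n_patches`, `patch_size`, `seed`).  Unknown keys are rejected with a
#' spelling suggestion; missing or out-of-range required fields produce the
#' validation errors of [coop_params()].  Defaults are filled (`mu = 0`,
#' plasmid seeds `1e-3`) and the resolved configuration is echoed to the
#' message stream.
#'
#' @param path path to a `.json` or `.toml` file.
#' @param quiet suppress the echo of the resolved configuration.
#' @return A list of class `run_config` with elements `params`
#'   (a [coop_params()]) and the run-control fields.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.toml$", path, ignore.case = TRUE)) {
    .read_flat_toml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop("config must be a flat table of key = value pairs")

  known <- c(.PARAM_KEYS, .RUN_KEYS)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- adist(k, known, ignore.case = TRUE)
      if (min(d) <= 2) sprintf(" (did you mean '%s'?)", known[which.min(d)])
      else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0("'", unknown, "'", hints, collapse = ", "))
  }
  missing_req <- setdiff(setdiff(.PARAM_KEYS, "mu"), names(raw))
  if (length(missing_req))
    stop("config is missing required field(s): ",
         paste(missing_req, collapse = ", "))

  params <- coop_params(N = raw$N, beta = raw$beta, s = raw$s, B = raw$B,
                        C_G = raw$C_G, C_C = raw$C_C,
                        mu = if (is.null(raw$mu)) 0 else raw$mu)
  defaults <- list(p_coop0 = 1e-3, p_def0 = 1e-3, chrom_coop0 = 0,
                   generations = 100, tol = 1e-10, max_gen = 2e5,
                   n_patches = 2000, patch_size = NULL, seed = NULL)
  cfg <- c(list(params = params),
           lapply(setNames(nm = .RUN_KEYS), function(k)
             if (!is.null(raw[[k]])) raw[[k]] else defaults[[k]]))
  class(cfg) <- "run_config"
  if (!quiet) {
    message("config ", path, ": ", format(params),
            sprintf(" | seeds p_C=%g p_D=%g chrom=%g",
                    cfg$p_coop0, cfg$p_def0, cfg$chrom_coop0))
  }
  cfg
}

.format_cell <- function(v) {
  if (is.double(v)) {
    vapply(v, function(z)
      if (is.na(z)) "NA" else sprintf("%.17g", z),
      character(1))
  } else {
    as.character(v)
  }
}

#' Write results to CSV
#'
#' Writes any of the package's tabular results (trajectories, sweeps,
#' relatedness tables) as a comma-separated UTF-8 file with '#'-prefixed
#' metadata lines (package version and, when available, the full parameter
#' set) before the header row.  Doubles are written with 17 significant
#' digits so a round-trip through [read_results()] is exact to better than
#' 1e-15 relative error.
#'
#' @param x a data frame (possibly classed, e.g. a `coop_sweep` or
#'   `coop_trajectory`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (!is.data.frame(x)) stop("x must be a data frame")
  meta <- sprintf("# plasmidcoop %s", as.character(packageVersion("plasmidcoop")))
  pars <- attr(x, "params")
  if (!is.null(pars)) meta <- c(meta, paste0("# params: ", format(pars)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  df <- as.data.frame(x)
  out <- as.data.frame(lapply(df, .format_cell), check.names = FALSE,
                       stringsAsFactors = FALSE,
                       col.names = names(df))
  if (nrow(df) == 0) {
    writeLines(paste0('"', names(df), '"', collapse = ","), con)
  } else {
    write.table(out, con, sep = ",", row.names = FALSE, qmethod = "double")
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path path to the CSV.
#' @return A data frame; captured '#' metadata lines are kept in
#'   `attr(, "metadata")`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  out <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  attr(out, "metadata") <- meta
  out
}
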