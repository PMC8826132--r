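## One-call orchestration over the scope x filter analysis grid:
## (global, low-latitude) x (>=3, >=5 samples) x (raw, window-standardized),
## with group comparisons and both variance-partitioning methods, plus a
## provenance manifest reconciling row counts.

#' Analysis configuration
#'
#' Bundles and validates the knobs of [run_full_analysis()].
#'
#' @param min_samples Integer vector of per-tooth inclusion thresholds to run
#'   (default `c(3, 5)`).
#' @param scopes Subset of `c("global", "low_latitude")`.
#' @param latitude_cutoff_deg Absolute-latitude cutoff for the low-latitude
#'   scope (default 37).
#' @param groupings Grouping variables for the range tables, subset of
#'   `c("diet", "body_size")`.
#' @param window_size Sliding-window width in samples (default 5).
#' @param window_aggregate,window_across_teeth Aggregation choices passed to
#'   [standardized_ranges()].
#' @param bin_width Range-bin width in permil (default 1).
#' @param variance_methods Subset of `c("mom", "reml")`.
#' @param variance_min_tooth_samples Per-tooth threshold for variance
#'   partitioning (default 5).
#' @param min_individuals_per_species,species_level_only,lump_table Passed to
#'   [species_niche()] (the lump table is also applied in variance
#'   partitioning).
#' @param adjust Multiplicity adjustment for Dunn's adjusted column.
#' @param seed Optional integer recorded in the manifest (the analyses
#'   themselves are deterministic).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(min_samples = c(3, 5),
                            scopes = c("global", "low_latitude"),
                            latitude_cutoff_deg = 37,
                            groupings = "diet",
                            window_size = 5,
                            window_aggregate = "mean",
                            window_across_teeth = "mean",
                            bin_width = 1,
                            variance_methods = c("mom", "reml"),
                            variance_min_tooth_samples = 5,
                            min_individuals_per_species = 3,
                            species_level_only = TRUE,
                            lump_table = NULL,
                            adjust = "holm",
                            seed = NULL) {
  scopes <- match.arg(scopes, c("global", "low_latitude"), several.ok = TRUE)
  groupings <- match.arg(groupings, c("diet", "body_size"),
                         several.ok = TRUE)
  variance_methods <- match.arg(variance_methods, c("mom", "reml"),
                                several.ok = TRUE)
  if (!length(min_samples) || any(min_samples < 1))
    stop("min_samples must contain integers >= 1", call. = FALSE)
  if (latitude_cutoff_deg <= 0 || window_size < 1 || bin_width <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(min_samples = as.integer(min_samples), scopes = scopes,
                 latitude_cutoff_deg = latitude_cutoff_deg,
                 groupings = groupings, window_size = as.integer(window_size),
                 window_aggregate = window_aggregate,
                 window_across_teeth = window_across_teeth,
                 bin_width = bin_width, variance_methods = variance_methods,
                 variance_min_tooth_samples =
                   as.integer(variance_min_tooth_samples),
                 min_individuals_per_species =
                   as.integer(min_individuals_per_species),
                 species_level_only = isTRUE(species_level_only),
                 lump_table = lump_table, adjust = adjust, seed = seed),
            class = "analysis_config")
}

#' Run the full dietary-specialization analysis grid
#'
#' For every scope (global / below the latitude cutoff) and every minimum
#' samples-per-tooth threshold, computes individual summaries, the species
#' niche / III table with per-diet averages, raw and window-standardized
#' range-bin tables, group range tables with Kruskal-Wallis and Dunn tests,
#' and nested variance partitioning under each requested method. A manifest
#' reconciles row counts (loaded = analysed + excluded per reason) and records
#' the configuration.
#'
#' @param x Serial-sample `data.frame` or a path to a CSV/TSV readable by
#'   [read_isoserial()].
#' @param config An [analysis_config()] object.
#' @param quiet Suppress per-stage messages.
#' @return An object of class `isoniche_results`: list with `analyses` (one
#'   entry per scope x threshold, named e.g. `"global_min3"`) and `manifest`.
#'   Each analysis entry carries `summaries`, `niche`, `iii_by_diet`, `bins`,
#'   `standardized`, `standardized_bins`, `range_tables`, `varcomp`.
#' @export
run_full_analysis <- function(x, config = analysis_config(), quiet = TRUE) {
  if (!inherits(config, "analysis_config"))
    stop("config must come from analysis_config()", call. = FALSE)
  if (is.character(x) && length(x) == 1L) x <- read_isoserial(x, quiet = quiet)
  x <- .check_isoserial(x)
  if (!nrow(x)) stop("empty input table", call. = FALSE)
  n_loaded <- nrow(x)

  analyses <- list()
  manifest_rows <- list()
  for (scope in config$scopes) {
    xs <- if (scope == "low_latitude")
      filter_latitude(x, config$latitude_cutoff_deg, quiet = quiet) else x
    if (!nrow(xs))
      stop("scope '", scope, "': latitude filter removed all rows",
           call. = FALSE)
    for (k in config$min_samples) {
      key <- sprintf("%s_min%d", scope, k)
      xf <- filter_min_samples(xs, k)
      if (!nrow(xf))
        stop("scope '", scope, "', min_samples=", k,
             ": minimum-samples filter removed all rows", call. = FALSE)
      summ <- individual_summaries(xf)
      niche <- tryCatch(
        species_niche(xf,
                      min_individuals = config$min_individuals_per_species,
                      species_level_only = config$species_level_only,
                      lump_table = config$lump_table, quiet = TRUE),
        error = function(e) NULL)
      iii_diet <- if (!is.null(niche) && nrow(niche))
        tryCatch(suppressWarnings(mean_iii_by_diet(niche)),
                 error = function(e) NULL) else NULL
      bins <- bin_individual_ranges(summ$range, summ$diet,
                                    width = config$bin_width)
      std <- standardized_ranges(xf, width = config$window_size,
                                 aggregate = config$window_aggregate,
                                 across_teeth = config$window_across_teeth,
                                 quiet = TRUE)
      std_bins <- if (nrow(std))
        bin_individual_ranges(std$standardized_range, std$diet,
                              width = config$bin_width) else NULL
      range_tables <- list()
      for (grp in config$groupings) {
        range_tables[[grp]] <- tryCatch(
          range_group_table(summ, by = grp),
          error = function(e) structure(list(error = conditionMessage(e)),
                                        class = "analysis_failure"))
      }
      vc <- list()
      for (m in config$variance_methods) {
        vc[[m]] <- tryCatch(
          nested_varcomp(xf, method = m,
                         min_tooth_samples = config$variance_min_tooth_samples,
                         lump_table = config$lump_table),
          error = function(e) structure(list(error = conditionMessage(e)),
                                        class = "analysis_failure"))
      }
      analyses[[key]] <- list(scope = scope, min_samples = k,
                              summaries = summ, niche = niche,
                              iii_by_diet = iii_diet, bins = bins,
                              standardized = std,
                              standardized_bins = std_bins,
                              range_tables = range_tables, varcomp = vc)
      failures <- c(
        names(range_tables)[vapply(range_tables, inherits, logical(1),
                                   "analysis_failure")],
        names(vc)[vapply(vc, inherits, logical(1), "analysis_failure")])
      manifest_rows[[key]] <- list(
        scope = scope, min_samples = k,
        n_rows_scope = nrow(xs), n_rows_analysed = nrow(xf),
        n_rows_excluded_min_samples = nrow(xs) - nrow(xf),
        n_individuals = length(unique(xf$individual_id)),
        n_taxa_iii = if (is.null(niche)) 0L else nrow(niche),
        failures = if (length(failures)) failures else character())
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("isoniche")),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "lump_table")]),
    n_rows_loaded = n_loaded,
    n_individuals_loaded = length(unique(x$individual_id)),
    n_rows_excluded_latitude =
      if ("low_latitude" %in% config$scopes)
        n_loaded - nrow(filter_latitude(x, config$latitude_cutoff_deg,
                                        quiet = TRUE)) else 0L,
    analyses = manifest_rows)
  structure(list(analyses = analyses, manifest = manifest),
            class = "isoniche_results")
}

#' @export
print.isoniche_results <- function(x, ...) {
  cat("Dietary-specialization analysis bundle\n")
  cat(sprintf("  input: %d rows, %d individuals\n",
              x$manifest$n_rows_loaded, x$manifest$n_individuals_loaded))
  for (key in names(x$analyses)) {
    a <- x$analyses[[key]]
    cat(sprintf("  [%s] %d individuals, %d III taxa",
                key, nrow(a$summaries),
                if (is.null(a$niche)) 0L else nrow(a$niche)))
    fails <- x$manifest$analyses[[key]]$failures
    if (length(fails)) cat("  (failed: ", paste(fails, collapse = ", "), ")",
                           sep = "")
    cat("\n")
  }
  invisible(x)
}

.fmt_num_df <- function(df, digits = 4) {
  for (cl in names(df))
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], digits = digits, format = "f")
  df
}

#' Write an analysis bundle to CSV and JSON
#'
#' Emits per-analysis CSV tables (`species_niche.csv`, `bin_table.csv`,
#' `range_table.csv`, `group_tests.csv`, `window_ranges.csv`,
#' `variance_partition.csv`, `individual_summaries.csv`) with numeric columns
#' fixed at 4 decimals and rows in a locale-independent sort order, plus a
#' full-precision `results.json` and `manifest.json`. Re-running on the same
#' input produces byte-identical files.
#'
#' @param results An `isoniche_results` object from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "isoniche_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  collect <- function(field, extract = identity) {
    rows <- lapply(names(results$analyses), function(key) {
      a <- results$analyses[[key]]
      tab <- extract(a)
      if (is.null(tab) || !NROW(tab)) return(NULL)
      cbind(data.frame(scope = a$scope, min_samples = a$min_samples,
                       stringsAsFactors = FALSE), tab)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  wr <- function(tab, file) {
    if (is.null(tab)) return(invisible(NULL))
    rownames(tab) <- NULL
    utils::write.csv(.fmt_num_df(tab), file.path(dir, file),
                     row.names = FALSE, na = "")
  }
  wr(collect("summaries", function(a) a$summaries), "individual_summaries.csv")
  wr(collect("niche", function(a) a$niche), "species_niche.csv")
  wr(collect("bins", function(a) {
    raw <- if (!is.null(a$bins)) cbind(kind = "raw", a$bins) else NULL
    std <- if (!is.null(a$standardized_bins))
      cbind(kind = "standardized", a$standardized_bins) else NULL
    rbind(raw, std)
  }), "bin_table.csv")
  wr(collect("range", function(a) {
    rows <- lapply(names(a$range_tables), function(grp) {
      rt <- a$range_tables[[grp]]
      if (inherits(rt, "analysis_failure")) return(NULL)
      cbind(grouping = grp, rt$group_stats)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else NULL
  }), "range_table.csv")
  wr(collect("tests", function(a) {
    rows <- lapply(names(a$range_tables), function(grp) {
      rt <- a$range_tables[[grp]]
      if (inherits(rt, "analysis_failure") || is.null(rt$kw)) return(NULL)
      data.frame(grouping = grp,
                 group_a = rt$pairwise$group_a, group_b = rt$pairwise$group_b,
                 H = rt$kw$statistic, df = rt$kw$df, p_kw = rt$kw$p.value,
                 z = rt$pairwise$z, p_value = rt$pairwise$p_value,
                 p_adjusted = rt$pairwise$p_adjusted,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else NULL
  }), "group_tests.csv")
  wr(collect("std", function(a) a$standardized), "window_ranges.csv")
  wr(collect("vc", function(a) {
    rows <- lapply(names(a$varcomp), function(m) {
      v <- a$varcomp[[m]]
      if (inherits(v, "analysis_failure")) return(NULL)
      data.frame(method = m,
                 sigma2_species = v$components[["species"]],
                 sigma2_individual = v$components[["individual"]],
                 sigma2_within = v$components[["within"]],
                 p_species = v$proportions[["species"]],
                 p_individual = v$proportions[["individual"]],
                 p_within = v$proportions[["within"]],
                 a = v$design$a, B = v$design$B, N = v$design$N,
                 truncated = v$flags[["truncated"]],
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows) else NULL
  }), "variance_partition.csv")
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
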