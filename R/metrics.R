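## Per-individual niche summaries, the isotopic individuality index (III),
## range bins and group summary tables.

#' Per-individual d13C summaries
#'
#' Computes the minimum, maximum, range, mean and sample standard deviation of
#' each individual's serial d13C values, pooling samples across teeth when an
#' individual was sampled on more than one tooth. The standard deviation uses
#' the n-1 denominator and is `NA` for singletons (flagged in `sd_defined`).
#'
#' @param x Serial-sample `data.frame` (canonical columns).
#' @return A `data.frame` with one row per individual: `individual_id`,
#'   `taxon`, `diet`, `latitude`, `body_mass_kg`, `n_samples`, `min`, `max`,
#'   `range`, `mean`, `sd`, `sd_defined`.
#' @export
individual_summaries <- function(x) {
  x <- .check_isoserial(x)
  x <- x[is.finite(x$d13c), , drop = FALSE]
  if (!nrow(x)) stop("no finite d13C samples to summarize", call. = FALSE)
  ids <- unique(x$individual_id)
  sp <- split(seq_len(nrow(x)), factor(x$individual_id, levels = ids))
  one <- function(ix) {
    v <- x$d13c[ix]
    data.frame(
      individual_id = x$individual_id[ix[1L]],
      taxon = x$taxon[ix[1L]],
      diet = x$diet[ix[1L]],
      latitude = x$latitude[ix[1L]],
      body_mass_kg = x$body_mass_kg[ix[1L]],
      n_samples = length(v),
      min = min(v), max = max(v), range = max(v) - min(v),
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      sd_defined = length(v) > 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(sp, one))
  rownames(out) <- NULL
  out
}

## internal: decide whether a taxon name looks species-level (binomial with a
## real epithet, not an open-nomenclature placeholder)
.is_species_level <- function(taxon) {
  toks <- strsplit(trimws(taxon), "\\s+")
  vapply(toks, function(tk) {
    length(tk) >= 2L &&
      !grepl("^(sp|spp|cf|aff|indet|gen)\\.?$", tolower(tk[2L]))
  }, logical(1))
}

#' Species niche breadth and the isotopic individuality index
#'
#' For each taxon, computes the species total d13C range (max minus min over
#' all serial samples of the taxon's qualifying individuals), the average
#' individual range, and the isotopic individuality index
#' III = average individual range / species total range. III near 0 means
#' individuals are specialized relative to the species niche; near 1, each
#' individual spans the species niche.
#'
#' Input should already be filtered to qualifying individuals (e.g. via
#' [filter_min_samples()]). Genus-only records (taxon names that are not
#' binomials) are excluded by default; supply `lump_table` to rename taxa
#' first, e.g. to lump genus-level records with a congener.
#'
#' @param x Serial-sample `data.frame` of qualifying individuals.
#' @param min_individuals Minimum number of individuals a taxon needs for its
#'   III to be reported (default 3).
#' @param species_level_only Drop taxa whose name is not species-level.
#' @param lump_table Optional `data.frame` with columns `from`, `to` renaming
#'   taxa before grouping.
#' @param quiet Suppress messages about excluded taxa.
#' @return A `data.frame` with one row per taxon: `taxon`, `diet`,
#'   `n_individuals`, `species_total_range`, `avg_individual_range`, `iii`,
#'   `iii_defined` (`FALSE` when the species total range is zero, in which
#'   case `iii` is `NA`).
#' @export
species_niche <- function(x, min_individuals = 3, species_level_only = TRUE,
                          lump_table = NULL, quiet = FALSE) {
  x <- .check_isoserial(x)
  if (!nrow(x)) stop("empty sample table", call. = FALSE)
  if (!is.null(lump_table)) {
    stopifnot(is.data.frame(lump_table),
              all(c("from", "to") %in% names(lump_table)))
    m <- match(x$taxon, lump_table$from)
    x$taxon[!is.na(m)] <- lump_table$to[m[!is.na(m)]]
  }
  if (species_level_only) {
    drop <- !.is_species_level(x$taxon)
    n_drop <- length(unique(x$taxon[drop]))
    if (n_drop && !quiet)
      message("excluded ", n_drop, " genus-level (non-binomial) tax",
              if (n_drop == 1L) "on" else "a", " from III")
    x <- x[!drop, , drop = FALSE]
    if (!nrow(x)) stop("no species-level taxa left", call. = FALSE)
  }
  summ <- individual_summaries(x)
  taxa <- unique(summ$taxon)
  rows <- lapply(taxa, function(tx) {
    si <- summ[summ$taxon == tx, , drop = FALSE]
    v <- x$d13c[x$taxon == tx]
    total <- max(v) - min(v)
    avg <- mean(si$range)
    data.frame(taxon = tx, diet = si$diet[1L], n_individuals = nrow(si),
               species_total_range = total, avg_individual_range = avg,
               iii = if (total > 0) avg / total else NA_real_,
               iii_defined = total > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$n_individuals >= min_individuals
  if (any(!keep) && !quiet)
    message("excluded ", sum(!keep), " taxa with fewer than ",
            min_individuals, " individuals")
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$diet, out$taxon, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average III per dietary category
#'
#' Unweighted mean and standard deviation of the isotopic individuality index
#' over species within each dietary category.
#'
#' @param niche Output of [species_niche()].
#' @return A `data.frame` with `diet`, `mean_iii`, `sd_iii`, `n_species`.
#'   Diets with no species are omitted with a warning.
#' @export
mean_iii_by_diet <- function(niche) {
  stopifnot(is.data.frame(niche), all(c("diet", "iii") %in% names(niche)))
  niche <- niche[!is.na(niche$iii), , drop = FALSE]
  if (!nrow(niche)) stop("no taxa with a defined III", call. = FALSE)
  sp <- split(niche$iii, factor(niche$diet, levels = .DIET_LEVELS))
  empty <- names(sp)[vapply(sp, length, integer(1)) == 0L]
  if (length(empty))
    warning("no species in diet group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  sp <- sp[vapply(sp, length, integer(1)) > 0L]
  out <- data.frame(
    diet = names(sp),
    mean_iii = vapply(sp, mean, numeric(1)),
    sd_iii = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                    numeric(1)),
    n_species = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Bin individual ranges into fixed-width permil bins
#'
#' Right-closed bins of width `width` permil: `(0, 1]`, `(1, 2]`, ... The
#' handful of individuals with an exactly zero range (possible with few
#' samples) are counted in the first bin rather than dropped.
#'
#' @param range Numeric vector of individual d13C ranges (>= 0), e.g. the
#'   `range` column of [individual_summaries()] or the `standardized_range`
#'   column of [standardized_ranges()].
#' @param group Optional grouping vector (e.g. diet) recycled against
#'   `range`; by default a single group `"all"`.
#' @param width Bin width in permil (> 0), default 1.
#' @return A long `data.frame` with `group`, `bin_lo`, `bin_hi`, `n`, `prop`,
#'   `cum_prop`; every group carries the full shared set of bins and its
#'   proportions sum to 1.
#' @export
bin_individual_ranges <- function(range, group = NULL, width = 1) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a single positive number", call. = FALSE)
  range <- as.numeric(range)
  if (any(!is.finite(range)) || any(range < 0))
    stop("ranges must be finite and non-negative", call. = FALSE)
  if (!length(range)) stop("no ranges to bin", call. = FALSE)
  if (is.null(group)) group <- "all"
  group <- rep_len(as.character(group), length(range))
  ## right-closed: value w*k goes to bin k; small fuzz guards fp noise in
  ## differences; exact zeros are forced into the first bin
  idx <- pmax(1L, as.integer(ceiling(range / width - 1e-9)))
  nbin <- max(idx)
  glev <- unique(group)
  rows <- lapply(glev, function(g) {
    cnt <- tabulate(idx[group == g], nbins = nbin)
    prop <- cnt / sum(cnt)
    data.frame(group = g, bin_lo = width * (seq_len(nbin) - 1L),
               bin_hi = width * seq_len(nbin), n = cnt, prop = prop,
               cum_prop = cumsum(prop), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of ranges at or below a threshold
#'
#' Cumulative-bin convenience: the share of individuals whose d13C range is
#' less than or equal to `threshold` permil.
#'
#' @param range Numeric vector of ranges.
#' @param threshold Threshold in permil.
#' @return A single proportion in `[0, 1]`.
#' @export
prop_range_at_most <- function(range, threshold) {
  range <- as.numeric(range)
  if (!length(range)) stop("no ranges supplied", call. = FALSE)
  mean(range <= threshold + 1e-9)
}

#' Group summary table of individual ranges with rank tests
#'
#' Mean, standard deviation and count of individual d13C ranges per group
#' (dietary category or body-size class), with a Kruskal-Wallis test across
#' groups and Dunn's pairwise post hoc comparisons (unadjusted and
#' Holm-adjusted p-values side by side).
#'
#' @param summ Output of [individual_summaries()] (or any `data.frame` with a
#'   `range` column and the grouping column).
#' @param by Grouping column name, `"diet"` (default) or `"body_size"`; the
#'   latter is derived from `body_mass_kg` via [body_size_category()] if not
#'   already present, and individuals of unknown size are excluded.
#' @param tests Run the rank tests (requires >= 2 groups and >= 2 distinct
#'   values overall).
#' @return An object of class `range_table`: a list with `group_stats`
#'   (`data.frame` of group, mean, sd, n), `kw` ([kruskal_wallis()] result or
#'   `NULL`), `pairwise` ([dunn_test()] result or `NULL`) and `by`.
#' @export
range_group_table <- function(summ, by = "diet", tests = TRUE) {
  stopifnot(is.data.frame(summ), "range" %in% names(summ))
  if (by == "body_size" && !"body_size" %in% names(summ)) {
    summ$body_size <- body_size_category(summ$body_mass_kg)
    summ <- summ[summ$body_size != "unknown", , drop = FALSE]
  }
  if (!by %in% names(summ)) stop("grouping column not found: ", by,
                                 call. = FALSE)
  summ <- summ[!is.na(summ[[by]]), , drop = FALSE]
  sp <- split(summ$range, summ[[by]])
  sp <- sp[vapply(sp, length, integer(1)) > 0L]
  if (length(sp) < 2L)
    stop("need at least 2 non-empty groups, got ", length(sp), call. = FALSE)
  stats_df <- data.frame(
    group = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(stats_df) <- NULL
  kw <- pw <- NULL
  if (tests) {
    values <- unlist(sp, use.names = FALSE)
    groups <- rep(names(sp), vapply(sp, length, integer(1)))
    kw <- kruskal_wallis(values, groups)
    pw <- dunn_test(values, groups)
  }
  structure(list(group_stats = stats_df, kw = kw, pairwise = pw, by = by),
            class = "range_table")
}

#' @export
print.range_table <- function(x, digits = 4, ...) {
  cat("Individual d13C ranges by", x$by, "\n")
  print(format(x$group_stats, digits = digits), row.names = FALSE)
  if (!is.null(x$kw)) {
    cat(sprintf("\nKruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
                x$kw$statistic, x$kw$df, x$kw$p.value))
    cat("Dunn pairwise comparisons:\n")
    print(format(x$pairwise, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
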