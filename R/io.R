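## Reading, validation and filtering of flat serial-sample tables.
##
## Canonical schema: one row per enamel serial sample, columns
##   individual_id, taxon, diet, latitude, body_mass_kg, tooth_id,
##   position_mm, d13c, source
## Missing values are empty fields. `diet` is the closed set
## browser / grazer / mixed_feeder.

.ISOSERIAL_COLUMNS <- c("individual_id", "taxon", "diet", "latitude",
                        "body_mass_kg", "tooth_id", "position_mm",
                        "d13c", "source")
.ISOSERIAL_NUMERIC <- c("latitude", "body_mass_kg", "position_mm", "d13c")
.ISOSERIAL_MANDATORY <- c("individual_id", "taxon", "diet", "d13c")
.DIET_LEVELS <- c("browser", "grazer", "mixed_feeder")

## d13C values outside this band are flagged as implausible for tooth enamel
## carbonate (terrestrial herbivores span roughly -20 to +3 permil VPDB).
.D13C_PLAUSIBLE <- c(-25, 10)

#' Default column-name aliases for serial-sample tables
#'
#' Maps each canonical column name to the header spellings accepted by
#' [read_isoserial()]. Comparison is case-insensitive. Extend or replace
#' entries to adapt to a particular source table.
#'
#' @return Named list; names are canonical columns, values are character
#'   vectors of accepted headers.
#' @export
isoserial_aliases <- function() {
  list(
    individual_id = c("individual_id", "individual", "specimen", "specimen_id",
                      "specimen_no"),
    taxon         = c("taxon", "species", "taxon_name"),
    diet          = c("diet", "dietary_category", "diet_category"),
    latitude      = c("latitude", "lat", "latitude_deg", "site_latitude"),
    body_mass_kg  = c("body_mass_kg", "mass_kg", "body_mass", "mass"),
    tooth_id      = c("tooth_id", "tooth", "tooth_no"),
    position_mm   = c("position_mm", "position", "distance_mm",
                      "distance_from_root_mm", "dist_from_root"),
    d13c          = c("d13c", "d13c_permil", "d13c_enamel", "delta13c",
                      "d13c_vpdb"),
    source        = c("source", "reference", "publication")
  )
}

.normalize_diet <- function(x) {
  out <- tolower(trimws(x))
  gsub("[ -]+", "_", out)
}

#' Read a serial-sample table
#'
#' Reads a CSV/TSV table with one row per enamel serial sample, maps column
#' headers through an alias table, coerces numeric columns, normalizes diet
#' labels, drops rows without a d13C value (with a message reporting the
#' count), and de-duplicates repeated (individual, tooth, position) keys
#' keeping the first occurrence.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator; default guesses `"\t"` for `.tsv`/`.txt`
#'   extensions and `","` otherwise.
#' @param aliases Alias table as produced by [isoserial_aliases()].
#' @param quiet Suppress informational messages.
#' @return A `data.frame` with the canonical columns (see [isoserial_aliases()]
#'   for names), one row per retained serial sample. Attributes
#'   `n_dropped_missing_d13c` and `n_dropped_duplicates` record row removals.
#' @seealso [validate_isoserial()], [write_isoserial()]
#' @export
read_isoserial <- function(path, sep = NULL,
                           aliases = isoserial_aliases(),
                           quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "", check.names = FALSE,
                           blank.lines.skip = FALSE)
  names(raw) <- tolower(trimws(names(raw)))

  ## map headers to canonical names through the alias table
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in .ISOSERIAL_COLUMNS) {
    hit <- intersect(tolower(aliases[[canon]]), names(raw))
    out[[canon]] <- if (length(hit)) raw[[hit[1L]]] else NA_character_
  }
  present <- vapply(.ISOSERIAL_COLUMNS, function(cl) {
    length(intersect(tolower(aliases[[cl]]), names(raw))) > 0L
  }, logical(1))
  missing_mand <- .ISOSERIAL_MANDATORY[!present[.ISOSERIAL_MANDATORY]]
  if (length(missing_mand))
    stop("missing mandatory column(s): ", paste(missing_mand, collapse = ", "),
         call. = FALSE)

  ## numeric coercion with row-level errors (line number = row + header line)
  for (cl in .ISOSERIAL_NUMERIC) {
    chr <- out[[cl]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & is.na(num))
    if (length(bad))
      stop(sprintf("unparseable numeric in column '%s' at line(s) %s", cl,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    out[[cl]] <- num
  }

  out$diet <- .normalize_diet(out$diet)
  bad_diet <- setdiff(stats::na.omit(unique(out$diet)), .DIET_LEVELS)
  if (length(bad_diet))
    stop("unknown diet categories: ", paste(bad_diet, collapse = ", "),
         "; expected one of ", paste(.DIET_LEVELS, collapse = ", "),
         call. = FALSE)

  ## drop rows without a d13C value (e.g. metadata or summary-only rows)
  drop_d13c <- is.na(out$d13c)
  n_drop <- sum(drop_d13c)
  out <- out[!drop_d13c, , drop = FALSE]
  if (n_drop && !quiet)
    message("dropped ", n_drop, " row(s) without a d13C value")

  ## duplicate (individual, tooth, position) keys: keep first, warn
  haspos <- !is.na(out$position_mm)
  key <- paste(out$individual_id, out$tooth_id, out$position_mm, sep = "\r")
  dup <- haspos & duplicated(key) & key %in% key[haspos]
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, tooth, position) row(s) ",
            "removed (first occurrence kept)", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }

  oob <- which(out$d13c < .D13C_PLAUSIBLE[1] | out$d13c > .D13C_PLAUSIBLE[2])
  if (length(oob))
    warning(length(oob), " d13C value(s) outside the plausible range [",
            .D13C_PLAUSIBLE[1], ", ", .D13C_PLAUSIBLE[2], "] permil",
            call. = FALSE)

  rownames(out) <- NULL
  attr(out, "n_dropped_missing_d13c") <- n_drop
  attr(out, "n_dropped_duplicates") <- sum(dup)
  out
}

#' Write a serial-sample table in canonical CSV form
#'
#' @param x Serial-sample `data.frame` with the canonical columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isoserial <- function(x, path) {
  x <- .check_isoserial(x)
  utils::write.csv(x[, .ISOSERIAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

## internal: assert canonical columns present, return canonical ordering
.check_isoserial <- function(x) {
  if (!is.data.frame(x)) stop("expected a data.frame", call. = FALSE)
  miss <- setdiff(.ISOSERIAL_COLUMNS, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x
}

#' Validate a serial-sample table
#'
#' Structural and plausibility checks: mandatory fields present, d13C finite
#' and within the plausible enamel band (-25 to +10 permil), diet labels in
#' the closed category set, duplicate sample keys, missing positions and
#' latitudes. Issues are counted, not raised.
#'
#' @param x Serial-sample `data.frame` (canonical columns).
#' @return An object of class `isoserial_validation`: a list with row/
#'   individual/taxon counts, per-issue counts in `$issues`, and `$ok`
#'   (`TRUE` when no issue was found).
#' @export
validate_isoserial <- function(x) {
  x <- .check_isoserial(x)
  issues <- list()
  issues$missing_individual_id <- sum(is.na(x$individual_id))
  issues$missing_taxon <- sum(is.na(x$taxon))
  issues$missing_diet <- sum(is.na(x$diet))
  issues$unknown_diet <- sum(!is.na(x$diet) & !x$diet %in% .DIET_LEVELS)
  issues$missing_d13c <- sum(is.na(x$d13c))
  issues$nonfinite_d13c <- sum(!is.na(x$d13c) & !is.finite(x$d13c))
  issues$d13c_out_of_range <- sum(!is.na(x$d13c) &
                                    (x$d13c < .D13C_PLAUSIBLE[1] |
                                       x$d13c > .D13C_PLAUSIBLE[2]))
  haspos <- !is.na(x$position_mm)
  key <- paste(x$individual_id, x$tooth_id, x$position_mm, sep = "\r")
  issues$duplicate_sample_keys <- sum(haspos & duplicated(key))
  issues$negative_position <- sum(haspos & x$position_mm < 0)
  issues$nonpositive_mass <- sum(!is.na(x$body_mass_kg) & x$body_mass_kg <= 0)

  out <- list(
    n_rows = nrow(x),
    n_individuals = length(unique(x$individual_id)),
    n_taxa = length(unique(x$taxon)),
    n_missing_position = sum(!haspos),
    n_missing_latitude = length(unique(x$individual_id[is.na(x$latitude)])),
    diet_counts = table(factor(x$diet, levels = .DIET_LEVELS)),
    issues = issues,
    ok = all(unlist(issues) == 0L)
  )
  class(out) <- "isoserial_validation"
  out
}

#' @export
print.isoserial_validation <- function(x, ...) {
  cat("Serial-sample table validation\n")
  cat(sprintf("  rows: %d  individuals: %d  taxa: %d\n",
              x$n_rows, x$n_individuals, x$n_taxa))
  cat(sprintf("  missing positions: %d rows; missing latitude: %d individuals\n",
              x$n_missing_position, x$n_missing_latitude))
  cat("  diet counts:", paste(names(x$diet_counts), as.integer(x$diet_counts),
                              sep = "=", collapse = "  "), "\n")
  bad <- x$issues[unlist(x$issues) > 0L]
  if (length(bad)) {
    cat("  issues:\n")
    for (nm in names(bad)) cat(sprintf("    %s: %d\n", nm, bad[[nm]]))
  } else cat("  no issues found\n")
  invisible(x)
}

## internal: per-(individual, tooth) sample counts; samples from teeth with
## unknown tooth_id are pooled as one unnamed tooth per individual
.tooth_counts <- function(x) {
  tooth <- ifelse(is.na(x$tooth_id), "", x$tooth_id)
  key <- paste(x$individual_id, tooth, sep = "\r")
  cnt <- table(key)
  data.frame(individual_id = sub("\r.*$", "", names(cnt)),
             tooth_key = names(cnt),
             n = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Filter individuals by minimum serial samples per tooth
#'
#' An individual is retained when at least one of its teeth carries `k` or
#' more serial samples. All of a retained individual's samples are kept (so
#' that summaries pool samples across teeth), unless
#' `drop_nonqualifying_teeth = TRUE`, in which case samples from teeth with
#' fewer than `k` samples are removed as well (the rule used for variance
#' partitioning). Row order is preserved.
#'
#' @param x Serial-sample `data.frame`.
#' @param k Minimum number of serial samples per tooth (>= 1).
#' @param drop_nonqualifying_teeth Also drop samples from teeth below the
#'   threshold within retained individuals.
#' @return The filtered `data.frame`.
#' @export
filter_min_samples <- function(x, k, drop_nonqualifying_teeth = FALSE) {
  x <- .check_isoserial(x)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("k must be a single integer >= 1", call. = FALSE)
  k <- as.integer(k)
  tc <- .tooth_counts(x)
  ok_ind <- unique(tc$individual_id[tc$n >= k])
  keep <- x$individual_id %in% ok_ind
  if (drop_nonqualifying_teeth) {
    tooth <- ifelse(is.na(x$tooth_id), "", x$tooth_id)
    key <- paste(x$individual_id, tooth, sep = "\r")
    ok_tooth <- tc$tooth_key[tc$n >= k]
    keep <- keep & key %in% ok_tooth
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter individuals by absolute site latitude
#'
#' Retains individuals collected strictly below `cutoff_deg` degrees of
#' absolute latitude (both hemispheres). Individuals with unknown latitude are
#' dropped, with a message reporting the count.
#'
#' @param x Serial-sample `data.frame`.
#' @param cutoff_deg Positive latitude cutoff in degrees (default 37, below
#'   which C4 warm-season grasses and C3 browse are isotopically distinct).
#' @param quiet Suppress the dropped-individuals message.
#' @return The filtered `data.frame`.
#' @export
filter_latitude <- function(x, cutoff_deg = 37, quiet = FALSE) {
  x <- .check_isoserial(x)
  if (!is.numeric(cutoff_deg) || length(cutoff_deg) != 1L || cutoff_deg <= 0)
    stop("cutoff_deg must be a single positive number", call. = FALSE)
  miss <- is.na(x$latitude)
  n_miss <- length(unique(x$individual_id[miss]))
  if (n_miss && !quiet)
    message("dropped ", n_miss, " individual(s) with unknown latitude")
  out <- x[!miss & abs(x$latitude) < cutoff_deg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Body-size category from mass
#'
#' Half-open intervals: small `[0, 100)` kg, medium `[100, 350)` kg, large
#' `[350, Inf)` kg. Missing mass maps to `"unknown"` (excluded from size
#' analyses).
#'
#' @param mass_kg Numeric vector of body masses in kg (> 0 where known).
#' @param cutoffs Increasing pair of cutoffs in kg.
#' @return Character vector in `c("small", "medium", "large", "unknown")`.
#' @examples
#' body_size_category(c(99.9, 100, 350, NA))
#' @export
body_size_category <- function(mass_kg, cutoffs = c(100, 350)) {
  if (length(cutoffs) != 2L || !is.numeric(cutoffs) || any(cutoffs <= 0) ||
      diff(cutoffs) <= 0)
    stop("cutoffs must be an increasing pair of positive masses",
         call. = FALSE)
  if (any(!is.na(mass_kg) & mass_kg <= 0))
    stop("body mass must be positive where known", call. = FALSE)
  out <- rep("unknown", length(mass_kg))
  out[!is.na(mass_kg) & mass_kg < cutoffs[1]] <- "small"
  out[!is.na(mass_kg) & mass_kg >= cutoffs[1] & mass_kg < cutoffs[2]] <- "medium"
  out[!is.na(mass_kg) & mass_kg >= cutoffs[2]] <- "large"
  out
}
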