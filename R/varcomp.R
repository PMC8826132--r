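## Nested variance partitioning of d13C across three scales:
## between species, between individuals within species, within individuals.
##
## Two estimators are provided. The method-of-moments route is the classical
## two-level nested ANOVA for unbalanced data: with a species, b_i individuals
## in species i, n_ij serial samples in individual (i,j), n_i. = sum_j n_ij and
## N = sum n_i., the expected mean squares are
##   E[MS_within]     = s2_w
##   E[MS_individual] = s2_w + n0  * s2_I
##   E[MS_species]    = s2_w + n0' * s2_I + nb0 * s2_S
## with design coefficients
##   n0  = (N - sum_i (sum_j n_ij^2) / n_i.) / (sum_i b_i - a)
##   n0' = (sum_i (sum_j n_ij^2) / n_i. - (sum_ij n_ij^2) / N) / (a - 1)
##   nb0 = (N - sum_i n_i.^2 / N) / (a - 1)
## In a balanced design (b individuals of n samples each) these collapse to
## (n, n, b*n). The REML route fits the intercept-only nested random-effects
## model y_ijk = mu + S_i + I_ij + e_ijk by restricted maximum likelihood.

#' Fit nested variance components of d13C
#'
#' Partitions the variance of serial d13C values across species, individuals
#' within species, and serial samples within individuals, either by
#' method-of-moments nested ANOVA for unbalanced data (`method = "mom"`) or by
#' REML for the nested random-effects model (`method = "reml"`, fitted with
#' \pkg{nlme} and extracted with [ape::varcomp()]).
#'
#' Only serial samples from teeth with at least `min_tooth_samples` samples
#' enter the fit (default 5). Negative method-of-moments components are
#' truncated to zero and flagged; REML components are non-negative by
#' construction.
#'
#' @param x Serial-sample `data.frame` (canonical columns), or any
#'   `data.frame` carrying the three columns named below.
#' @param method `"mom"` or `"reml"`.
#' @param min_tooth_samples Per-tooth inclusion threshold; set to 1 (or 0) to
#'   use all samples. Applied only when `x` has a `tooth_id` column.
#' @param lump_table Optional `data.frame` with columns `from`, `to` renaming
#'   taxa before grouping (e.g. lumping genus-level records with a congener).
#' @param value,species,individual Column names of the response and the two
#'   nesting factors.
#' @return An object of class `nested_varcomp`: a list with
#'   \describe{
#'     \item{components}{named vector `c(species, individual, within)` of
#'       variance components (permil^2);}
#'     \item{proportions}{components divided by their sum (`NA` with
#'       `flags["undefined"]` when all components are zero);}
#'     \item{anova}{for `"mom"`, the nested ANOVA table (df, SS, MS);}
#'     \item{coefficients}{for `"mom"`, the expected-mean-square multipliers
#'       `c(n0, n0_prime, nb0)`;}
#'     \item{design}{list with `a` (species), `B` (individuals), `N`
#'       (samples);}
#'     \item{flags}{logical `c(truncated, undefined)`;}
#'     \item{method, call}{bookkeeping.}
#'   }
#' @seealso [variance_proportions()]
#' @examples
#' sim <- simulate_isoserial(sim_params(seed = 1))
#' fit <- nested_varcomp(sim$samples, method = "mom", min_tooth_samples = 1)
#' fit
#' coef(fit)
#' @export
nested_varcomp <- function(x, method = c("mom", "reml"),
                           min_tooth_samples = 5, lump_table = NULL,
                           value = "d13c", species = "taxon",
                           individual = "individual_id") {
  method <- match.arg(method)
  cl <- match.call()
  stopifnot(is.data.frame(x))
  need <- c(value, species, individual)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(lump_table)) {
    stopifnot(all(c("from", "to") %in% names(lump_table)))
    m <- match(x[[species]], lump_table$from)
    x[[species]][!is.na(m)] <- lump_table$to[m[!is.na(m)]]
  }
  if (min_tooth_samples > 1 && "tooth_id" %in% names(x) &&
      all(.ISOSERIAL_COLUMNS %in% names(x)))
    x <- filter_min_samples(x, min_tooth_samples,
                            drop_nonqualifying_teeth = TRUE)
  dd <- data.frame(y = as.numeric(x[[value]]),
                   sp = as.character(x[[species]]),
                   ind = as.character(x[[individual]]),
                   stringsAsFactors = FALSE)
  dd <- dd[is.finite(dd$y), , drop = FALSE]
  ## preconditions on the nesting structure
  a <- length(unique(dd$sp))
  if (a < 2L) stop("need at least 2 species, got ", a, call. = FALSE)
  ind_key <- paste(dd$sp, dd$ind, sep = "\r")
  b_i <- tapply(ind_key, dd$sp, function(k) length(unique(k)))
  if (!any(b_i >= 2L))
    stop("need at least one species with >= 2 individuals", call. = FALSE)
  n_ind <- table(ind_key)
  if (!any(n_ind >= 2L))
    stop("need at least one individual with >= 2 serial samples",
         call. = FALSE)

  out <- switch(method,
                mom = .varcomp_mom(dd),
                reml = .varcomp_reml(dd))
  out$design <- list(a = a, B = length(unique(ind_key)), N = nrow(dd))
  out$method <- method
  out$call <- cl
  class(out) <- "nested_varcomp"
  out
}

## method-of-moments engine; dd has columns y, sp, ind
.varcomp_mom <- function(dd) {
  sp_f <- factor(dd$sp, levels = unique(dd$sp))
  ind_f <- factor(paste(dd$sp, dd$ind, sep = "\r"),
                  levels = unique(paste(dd$sp, dd$ind, sep = "\r")))
  N <- nrow(dd)
  a <- nlevels(sp_f)
  grand <- mean(dd$y)

  ## group sizes
  n_ij <- as.vector(table(ind_f))                   # per individual
  sp_of_ind <- dd$sp[match(levels(ind_f), paste(dd$sp, dd$ind, sep = "\r"))]
  n_i <- as.vector(tapply(n_ij, factor(sp_of_ind, levels = levels(sp_f)), sum))
  b_i <- as.vector(tapply(rep(1L, nlevels(ind_f)),
                          factor(sp_of_ind, levels = levels(sp_f)), sum))
  B <- sum(b_i)

  ## means and sums of squares
  m_ind <- tapply(dd$y, ind_f, mean)
  m_sp <- tapply(dd$y, sp_f, mean)
  ss_within <- sum((dd$y - m_ind[ind_f])^2)
  ss_ind <- sum(n_ij * (m_ind - m_sp[factor(sp_of_ind,
                                            levels = levels(sp_f))])^2)
  ss_sp <- sum(n_i * (m_sp - grand)^2)

  df_sp <- a - 1L
  df_ind <- B - a
  df_within <- N - B
  ms_sp <- ss_sp / df_sp
  ms_ind <- if (df_ind > 0) ss_ind / df_ind else NA_real_
  ms_within <- if (df_within > 0) ss_within / df_within else NA_real_

  ## unbalanced-design expected-mean-square coefficients
  sumsq_by_sp <- tapply(n_ij^2, factor(sp_of_ind, levels = levels(sp_f)), sum)
  A1 <- sum(sumsq_by_sp / n_i)       # sum_i (sum_j n_ij^2) / n_i.
  A2 <- sum(n_ij^2) / N              # (sum_ij n_ij^2) / N
  n0 <- (N - A1) / df_ind
  n0p <- (A1 - A2) / df_sp
  nb0 <- (N - sum(n_i^2) / N) / df_sp

  s2_w <- ms_within
  s2_i <- (ms_ind - ms_within) / n0
  s2_s <- (ms_sp - s2_w - n0p * s2_i) / nb0
  raw <- c(species = s2_s, individual = s2_i, within = s2_w)
  truncated <- any(raw < 0, na.rm = TRUE)
  comp <- pmax(raw, 0)

  undefined <- sum(comp) <= 0
  props <- if (undefined) stats::setNames(rep(NA_real_, 3), names(comp))
           else comp / sum(comp)

  anova_tab <- data.frame(
    source = c("species", "individual_within_species", "within_individual"),
    df = c(df_sp, df_ind, df_within),
    SS = c(ss_sp, ss_ind, ss_within),
    MS = c(ms_sp, ms_ind, ms_within),
    stringsAsFactors = FALSE
  )
  list(components = comp, components_raw = raw, proportions = props,
       anova = anova_tab,
       coefficients = c(n0 = n0, n0_prime = n0p, nb0 = nb0),
       flags = c(truncated = truncated, undefined = undefined))
}

## REML engine via nlme::lme with ape::varcomp extraction
.varcomp_reml <- function(dd) {
  dd$sp <- factor(dd$sp)
  dd$ind <- factor(paste(dd$sp, dd$ind, sep = "/"))
  ## degenerate case: every individual internally constant makes the full
  ## model singular (zero residual variance); collapse to individual means
  ## and fit the remaining one-level model
  within_ss <- tapply(dd$y, dd$ind, function(v) sum((v - mean(v))^2))
  if (all(within_ss == 0)) {
    md <- data.frame(y = as.vector(tapply(dd$y, dd$ind, mean)),
                     sp = factor(dd$sp[match(levels(dd$ind), dd$ind)]))
    fit <- nlme::lme(y ~ 1, random = ~ 1 | sp, data = md)
    vc <- nlme::VarCorr(fit)
    comp <- c(species = as.numeric(vc["(Intercept)", "Variance"]),
              individual = as.numeric(vc["Residual", "Variance"]),
              within = 0)
    props <- comp / sum(comp)
    return(list(components = comp, components_raw = comp,
                proportions = props, anova = NULL, coefficients = NULL,
                flags = c(truncated = FALSE, undefined = FALSE)))
  }
  fit <- tryCatch(
    nlme::lme(y ~ 1, random = ~ 1 | sp / ind, data = dd,
              control = nlme::lmeControl(tolerance = 1e-8,
                                         maxIter = 200, msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) stop("REML fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  vc <- ape::varcomp(fit)  # ordered outermost (species) to within
  comp <- c(species = unname(vc[1]), individual = unname(vc[2]),
            within = unname(vc[3]))
  undefined <- sum(comp) <= 0
  props <- if (undefined) stats::setNames(rep(NA_real_, 3), names(comp))
           else comp / sum(comp)
  list(components = comp, components_raw = comp, proportions = props,
       anova = NULL, coefficients = NULL,
       flags = c(truncated = FALSE, undefined = undefined))
}

#' @export
print.nested_varcomp <- function(x, digits = 4, ...) {
  cat("Nested variance components (", x$method, ")\n", sep = "")
  cat(sprintf("  design: %d species, %d individuals, %d serial samples\n",
              x$design$a, x$design$B, x$design$N))
  tab <- rbind(`variance (permil^2)` = x$components,
               proportion = x$proportions)
  print(round(tab, digits))
  if (isTRUE(x$flags["truncated"]))
    cat("  note: negative moment estimate(s) truncated to zero\n")
  if (isTRUE(x$flags["undefined"]))
    cat("  note: all components zero; proportions undefined\n")
  invisible(x)
}

#' @export
summary.nested_varcomp <- function(object, ...) {
  print(object)
  if (!is.null(object$anova)) {
    cat("\nNested ANOVA table:\n")
    print(format(object$anova, digits = 6), row.names = FALSE)
    cat("Expected-MS coefficients: ",
        paste(names(object$coefficients),
              signif(object$coefficients, 6), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.nested_varcomp <- function(object, ...) object$components

#' Proportions from variance components
#'
#' @param components Non-negative numeric vector of variance components
#'   (any length).
#' @return Components divided by their sum; all-zero input returns `NA`s with
#'   a warning.
#' @examples
#' variance_proportions(c(1, 1, 2))
#' @export
variance_proportions <- function(components) {
  if (any(!is.finite(components)) || any(components < 0))
    stop("components must be finite and non-negative", call. = FALSE)
  s <- sum(components)
  if (s <= 0) {
    warning("all components zero; proportions undefined", call. = FALSE)
    return(rep(NA_real_, length(components)))
  }
  components / s
}
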