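# Fixture builders and independent oracles shared across test files.

# Build a canonical serial-sample data.frame from per-individual value lists.
# `values` is a named list: individual_id -> numeric d13c vector.
make_samples <- function(values,
                         taxon = "Taxon test",
                         diet = "grazer",
                         latitude = 10,
                         body_mass_kg = 200,
                         tooth = NULL,
                         positions = NULL) {
  rows <- lapply(names(values), function(id) {
    v <- values[[id]]
    n <- length(v)
    data.frame(
      individual_id = id,
      taxon = if (length(taxon) > 1) taxon[[id]] else taxon,
      diet = if (length(diet) > 1) diet[[id]] else diet,
      latitude = if (length(latitude) > 1) latitude[[id]] else latitude,
      body_mass_kg = if (length(body_mass_kg) > 1) body_mass_kg[[id]]
                     else body_mass_kg,
      tooth_id = if (is.null(tooth)) paste0(id, "_t1") else tooth,
      position_mm = if (is.null(positions)) 2 * seq_len(n)
                    else positions[[id]],
      d13c = v,
      source = "fixture",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Random canonical table for property tests (structure varies with the seed).
random_samples <- function(seed) {
  set.seed(seed)
  n_ind <- sample(4:9, 1)
  vals <- lapply(seq_len(n_ind), function(i)
    round(rnorm(sample(1:8, 1), mean = -8, sd = 2), 3))
  names(vals) <- sprintf("ind%02d", seq_len(n_ind))
  diets <- sample(c("browser", "grazer", "mixed_feeder"), n_ind,
                  replace = TRUE)
  names(diets) <- names(vals)
  lats <- sample(c(NA, round(runif(3, -60, 60), 1)), n_ind, replace = TRUE)
  names(lats) <- names(vals)
  make_samples(vals, diet = as.list(diets), latitude = as.list(lats),
               taxon = as.list(setNames(
                 sprintf("Genus%d species%d", seq_len(n_ind) %% 3 + 1,
                         seq_len(n_ind) %% 3 + 1), names(vals))))
}

# Independent nested-ANOVA oracle: naive double loops over all samples,
# coefficients from direct evaluation of the defining sums. Never shares code
# with the package implementation.
oracle_nested_anova <- function(y, sp, ind) {
  sp <- as.character(sp)
  ind <- paste(sp, as.character(ind))
  species <- unique(sp)
  a <- length(species)
  N <- length(y)
  grand <- mean(y)

  ss_sp <- 0; ss_ind <- 0; ss_w <- 0
  B <- 0
  sum_nij2_over_ni <- 0; sum_nij2 <- 0; sum_ni2 <- 0
  for (s in species) {
    ys <- y[sp == s]
    ni <- length(ys)
    ms <- mean(ys)
    ss_sp <- ss_sp + ni * (ms - grand)^2
    inds <- unique(ind[sp == s])
    B <- B + length(inds)
    nij2 <- 0
    for (i in inds) {
      yi <- y[ind == i]
      mi <- mean(yi)
      ss_ind <- ss_ind + length(yi) * (mi - ms)^2
      for (v in yi) ss_w <- ss_w + (v - mi)^2
      nij2 <- nij2 + length(yi)^2
    }
    sum_nij2_over_ni <- sum_nij2_over_ni + nij2 / ni
    sum_nij2 <- sum_nij2 + nij2
    sum_ni2 <- sum_ni2 + ni^2
  }
  df <- c(sp = a - 1, ind = B - a, w = N - B)
  ms <- c(ss_sp, ss_ind, ss_w) / df
  n0 <- (N - sum_nij2_over_ni) / df[["ind"]]
  n0p <- (sum_nij2_over_ni - sum_nij2 / N) / df[["sp"]]
  nb0 <- (N - sum_ni2 / N) / df[["sp"]]
  s2w <- ms[[3]]
  s2i <- (ms[[2]] - ms[[3]]) / n0
  s2s <- (ms[[1]] - s2w - n0p * s2i) / nb0
  list(SS = c(sp = ss_sp, ind = ss_ind, w = ss_w), df = df, MS = ms,
       coef = c(n0 = n0, n0_prime = n0p, nb0 = nb0),
       components = c(species = s2s, individual = s2i, within = s2w))
}

# Independent tie-corrected Kruskal-Wallis oracle from explicit rank
# arithmetic (formula coded separately from the package path).
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}
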