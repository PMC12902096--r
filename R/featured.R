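## Cutoff-based habitat-featured family classification, association
## statistics (Pearson chi-square + Cramer's V with bootstrap CI), species
## membership profiling and PCA ordination of the presence-absence matrix.

#' Per-family presence fractions by habitat
#'
#' Computes, for each gene family, the fraction of saltwater species and the
#' fraction of freshwater species carrying it. Outgroup species are ignored.
#'
#' @param pam a `presence_absence_matrix` (species x families).
#' @param meta a `species_metadata` table covering the matrix species.
#' @return data frame with columns family_id, frac_salt, frac_fresh.
#' @export
habitat_fractions <- function(pam, meta) {
  stopifnot(inherits(pam, "presence_absence_matrix"))
  hab <- meta$habitat[match(rownames(pam$values), meta$species_id)]
  if (anyNA(hab)) stop("species missing from metadata: ",
                       paste(rownames(pam$values)[is.na(hab)], collapse = ", "))
  salt <- pam$values[hab == "saltwater", , drop = FALSE]
  fresh <- pam$values[hab == "freshwater", , drop = FALSE]
  if (nrow(salt) == 0 || nrow(fresh) == 0)
    stop("at least one saltwater and one freshwater species required")
  data.frame(family_id = colnames(pam$values),
             frac_salt = colMeans(salt),
             frac_fresh = colMeans(fresh),
             row.names = NULL)
}

#' Classify habitat-featured gene families at a presence cutoff
#'
#' A family is saltwater-featured if it is present in over `cutoff` of the
#' saltwater species AND absent in over `cutoff` of the freshwater species
#' (i.e. `frac_salt > cutoff` and `1 - frac_fresh > cutoff`); freshwater-
#' featured by the mirrored rule. Inequalities are strict ("over").
#'
#' @param fracs output of [habitat_fractions()].
#' @param cutoff presence/absence cutoff in (0.5, 1]; default 0.6.
#' @return a `featured_family_set` with disjoint `salt_featured` and
#'   `fresh_featured` id sets.
#' @export
classify_featured <- function(fracs, cutoff = 0.6) {
  if (cutoff <= 0.5 || cutoff > 1) stop("cutoff must be in (0.5, 1]")
  salt <- fracs$frac_salt > cutoff & (1 - fracs$frac_fresh) > cutoff
  fresh <- fracs$frac_fresh > cutoff & (1 - fracs$frac_salt) > cutoff
  structure(list(cutoff = cutoff,
                 salt_featured = fracs$family_id[salt],
                 fresh_featured = fracs$family_id[fresh]),
            class = "featured_family_set")
}

#' @export
print.featured_family_set <- function(x, ...) {
  cat(sprintf(
    "featured_family_set (cutoff %.2f): %d total (saltwater %d, freshwater %d)\n",
    x$cutoff, length(x$salt_featured) + length(x$fresh_featured),
    length(x$salt_featured), length(x$fresh_featured)))
  invisible(x)
}

#' Habitat x presence association test over featured families
#'
#' Pools presence calls of all featured families into one 2x2 table of
#' habitat (saltwater/freshwater species) x presence (1/0), tests it with
#' Pearson's chi-square (df = 1, no continuity correction unless requested),
#' and reports Cramer's V = sqrt(chi2 / (N * min(r-1, c-1))) with a seeded
#' percentile-bootstrap 95% CI obtained by resampling species within habitat.
#'
#' @param pam presence-absence matrix.
#' @param meta species metadata.
#' @param featured a `featured_family_set`.
#' @param bootstrap_reps bootstrap resamples for the CI of V.
#' @param seed RNG seed for the bootstrap.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @param table optional user-supplied 2x2 table overriding the default
#'   aggregation.
#' @return an `association_result` with fields chi2, df, p_value, cramers_v,
#'   v_ci95 and table.
#' @export
association_test <- function(pam, meta, featured, bootstrap_reps = 200L,
                             seed = 1L, correct = FALSE, table = NULL) {
  fams <- c(featured$salt_featured, featured$fresh_featured)
  if (is.null(table)) {
    if (!length(fams)) stop("featured sets are empty in aggregate")
    tab <- pooled_presence_table(pam, meta, fams)
  } else {
    tab <- as.matrix(table)
    stopifnot(all(dim(tab) == c(2L, 2L)))
  }
  res <- chi2_cramers_v(tab, correct = correct)

  ci <- c(NA_real_, NA_real_)
  if (is.null(table) && bootstrap_reps > 0) {
    hab <- meta$habitat[match(rownames(pam$values), meta$species_id)]
    salt_idx <- which(hab == "saltwater")
    fresh_idx <- which(hab == "freshwater")
    set.seed(derive_seed(seed, "bootstrap"))
    vs <- numeric(bootstrap_reps)
    sub <- pam$values[, fams, drop = FALSE]
    for (b in seq_len(bootstrap_reps)) {
      rs <- c(sample(salt_idx, length(salt_idx), replace = TRUE),
              sample(fresh_idx, length(fresh_idx), replace = TRUE))
      m <- sub[rs, , drop = FALSE]
      ns <- length(salt_idx)
      a <- sum(m[seq_len(ns), ]); b2 <- ns * ncol(m) - a
      c2 <- sum(m[-seq_len(ns), ]); d <- length(fresh_idx) * ncol(m) - c2
      tb <- matrix(c(a, b2, c2, d), 2, byrow = TRUE)
      vs[b] <- tryCatch(chi2_cramers_v(tb, correct = correct)$cramers_v,
                        error = function(e) NA_real_)
    }
    ci <- unname(quantile(vs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(chi2 = res$chi2, df = res$df, p_value = res$p,
                 cramers_v = res$cramers_v, v_ci95 = ci, table = tab,
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "association_result")
}

pooled_presence_table <- function(pam, meta, fams) {
  hab <- meta$habitat[match(rownames(pam$values), meta$species_id)]
  sub <- pam$values[, fams, drop = FALSE]
  salt <- sub[hab == "saltwater", , drop = FALSE]
  fresh <- sub[hab == "freshwater", , drop = FALSE]
  tab <- matrix(c(sum(salt), length(salt) - sum(salt),
                  sum(fresh), length(fresh) - sum(fresh)),
                nrow = 2, byrow = TRUE,
                dimnames = list(habitat = c("saltwater", "freshwater"),
                                presence = c("present", "absent")))
  tab
}

chi2_cramers_v <- function(tab, correct = FALSE) {
  n <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / n
  if (any(exp_tab == 0))
    stop("zero expected cell count; use an exact test (not implemented)")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1)))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "Pearson's chi-square (df=%d) = %.1f, P = %.3g, Cramer's V = %.2f, 95%% CI = [%.2f, %.2f]\n",
    x$df, x$chi2, x$p_value, x$cramers_v, x$v_ci95[1], x$v_ci95[2]))
  invisible(x)
}

#' PCA ordination of species over (featured) gene families
#'
#' Column-mean-centered PCA by singular value decomposition; no scaling or
#' other transformation is applied to the binary data.
#'
#' @param pam presence-absence matrix (optionally restricted to featured
#'   families).
#' @param n_components number of components to return.
#' @return an `ordination_result` with `scores` (species x component) and
#'   `explained_fraction`.
#' @export
pca_species <- function(pam, n_components = 2L) {
  x <- pam$values
  if (nrow(x) < 2) stop("at least 2 species required")
  if (n_components > min(dim(x))) stop("n_components exceeds matrix rank bound")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evar <- pc$sdev^2
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained_fraction = (evar / sum(evar))[seq_len(n_components)]),
            class = "ordination_result")
}

#' Count featured families carried by one species
#'
#' @param pam presence-absence matrix.
#' @param featured a `featured_family_set`.
#' @param species_id one species id present in the matrix.
#' @return list with `salt_housed`, `salt_total`, `fresh_housed`,
#'   `fresh_total`.
#' @export
membership_profile <- function(pam, featured, species_id) {
  if (!species_id %in% rownames(pam$values))
    stop("unknown species id: ", species_id)
  row <- pam$values[species_id, ]
  list(salt_housed = sum(row[featured$salt_featured]),
       salt_total = length(featured$salt_featured),
       fresh_housed = sum(row[featured$fresh_featured]),
       fresh_total = length(featured$fresh_featured))
}
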