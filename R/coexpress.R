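## Cross-species metagene aggregation and weighted co-expression modules:
## soft-thresholded |correlation| adjacency, topological overlap, average-
## linkage clustering with a static branch cut, module eigengenes, and
## module-trait association.

#' Aggregate gene expression into orthogroup metagenes
#'
#' A metagene's level in a sample is the sum of the expression of all member
#' genes of that orthogroup in the sample's species. Only orthogroups shared
#' by every contributing species are retained; samples are concatenated
#' across species.
#'
#' @param exprs list of `expression_matrix`, one per species.
#' @param gmap a `gene_map` (gene_id, species_id, orthogroup_id).
#' @return a `metagene_matrix` with `values` (orthogroups x samples) and
#'   `provenance` (member-gene counts per species).
#' @export
aggregate_metagenes <- function(exprs, gmap) {
  stopifnot(length(exprs) >= 1)
  all_samples <- unlist(lapply(exprs, function(e) colnames(e$values)))
  if (anyDuplicated(all_samples))
    stop("duplicate sample ids across species matrices")
  per_species <- lapply(exprs, function(e) {
    sp <- e$species_tag
    gm <- gmap[gmap$species_id == sp, ]
    gm <- gm[gm$gene_id %in% rownames(e$values), ]
    if (!nrow(gm)) stop("no mapped genes for species ", sp)
    ogs <- sort(unique(gm$orthogroup_id))
    agg <- rowsum(e$values[gm$gene_id, , drop = FALSE], gm$orthogroup_id)
    list(values = agg[ogs, , drop = FALSE],
         ngenes = table(gm$orthogroup_id)[ogs])
  })
  shared <- Reduce(intersect, lapply(per_species, function(p) rownames(p$values)))
  dropped <- setdiff(unique(gmap$orthogroup_id),
                     c(shared, character(0)))
  if (length(dropped))
    warning(length(dropped), " orthogroup(s) not shared by all species dropped")
  vals <- do.call(cbind, lapply(per_species, function(p)
    p$values[shared, , drop = FALSE]))
  prov <- do.call(cbind, lapply(per_species, function(p)
    as.integer(p$ngenes[shared])))
  colnames(prov) <- vapply(exprs, function(e) e$species_tag, character(1))
  rownames(prov) <- shared
  structure(list(values = vals, provenance = prov),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d orthogroups x %d samples (%d species)\n",
              nrow(x$values), ncol(x$values), ncol(x$provenance)))
  invisible(x)
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power beta, connectivity k_i = sum_{j != i}
#' |cor(x_i, x_j)|^beta is computed, k is binned, and log10(frequency) is
#' regressed on log10(mean k); the signed fit index is -sign(slope) * R^2.
#' The smallest power whose index exceeds `r2_min` is chosen; if none
#' qualifies the power maximizing the index is returned with a flag.
#'
#' @param mm a `metagene_matrix`.
#' @param power_grid integer candidate powers.
#' @param r2_min minimum signed fit index (default 0.9).
#' @param n_bins connectivity histogram bins.
#' @return list with `power`, `fit_table` (power, r2_signed, mean_k), and
#'   `reached_r2_min` flag.
#' @export
pick_soft_threshold <- function(mm, power_grid = c(1:10, 12L, 14L, 16L, 18L, 20L),
                                r2_min = 0.9, n_bins = 10L) {
  x <- mm$values
  if (ncol(x) < 4) stop("at least 4 samples required")
  keep <- apply(x, 1L, sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant metagene row(s) removed")
    x <- x[keep, , drop = FALSE]
  }
  cc <- abs(cor(t(x)))
  diag(cc) <- 0
  fit <- data.frame(power = power_grid, r2_signed = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(power_grid)) {
    k <- rowSums(cc^power_grid[i])
    fit$mean_k[i] <- mean(k)
    sf <- scale_free_fit(k, n_bins)
    fit$r2_signed[i] <- sf$r2_signed
    fit$slope[i] <- sf$slope
  }
  ok <- which(!is.na(fit$r2_signed) & fit$r2_signed > r2_min)
  if (length(ok)) {
    power <- power_grid[ok[1L]]
    reached <- TRUE
  } else if (all(is.na(fit$r2_signed))) {
    power <- power_grid[1L]
    reached <- FALSE
    sa_log("degenerate scale-free fit (no variation in connectivity); ",
           "falling back to power ", power)
  } else {
    power <- power_grid[which.max(fit$r2_signed)]
    reached <- FALSE
    sa_log("no power reached signed R^2 > ", r2_min,
           "; using maximizer ", power)
  }
  list(power = power, fit_table = fit, reached_r2_min = reached)
}

scale_free_fit <- function(k, n_bins) {
  if (sd(k) == 0) return(list(r2_signed = NA_real_, slope = NA_real_))
  bins <- cut(k, n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tabulate(bins, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(keep) < 3) return(list(r2_signed = NA_real_, slope = NA_real_))
  f <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(f)$r.squared
  slope <- unname(coef(f)[2L])
  list(r2_signed = -sign(slope) * r2, slope = slope)
}

#' Weighted network adjacency from metagene profiles
#'
#' Unsigned adjacency |cor|^power by default; the signed variant maps
#' correlation through (1 + cor)/2 before raising to the power.
#'
#' @param mm a `metagene_matrix`.
#' @param power soft-threshold power.
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
adjacency_matrix <- function(mm, power, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  cc <- cor(t(mm$values))
  a <- if (type == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, with k_i the connectivity excluding the diagonal; TOM_ii = 1.
#'
#' @param adjacency symmetric matrix in [0, 1] with unit diagonal.
#' @return the TOM, symmetric in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM with
#' a static branch cut; clusters smaller than `min_size` are assigned to the
#' unclustered "grey" label. Non-grey modules are labeled "M1", "M2", ... in
#' decreasing size order (ties by first member) so labels are deterministic.
#'
#' @param tom topological overlap matrix.
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @return named character vector of module labels per orthogroup.
#' @export
detect_modules <- function(tom, min_size = 30L, cut_height = 0.99) {
  if (min_size < 2) stop("min_size must be >= 2")
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", length(raw))
  names(labels) <- rownames(tom)
  if (length(keep)) {
    first_member <- vapply(keep, function(cl)
      which(raw == as.integer(cl))[1L], integer(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (m in seq_along(ord))
      labels[raw == as.integer(ord[m])] <- paste0("M", m)
  }
  labels
}

#' Module eigengenes
#'
#' Per module, the first principal component over the standardized member
#' rows, sign-oriented so its correlation with the module's mean profile is
#' positive; a size-1 module's eigengene is its standardized row.
#'
#' @param mm a `metagene_matrix`.
#' @param labels module labels from [detect_modules()] ("grey" is skipped).
#' @return matrix modules x samples of eigengene values.
#' @export
module_eigengene <- function(mm, labels) {
  mods <- setdiff(sort(unique(labels)), "grey")
  if (!length(mods)) stop("no non-grey modules")
  eg <- matrix(NA_real_, length(mods), ncol(mm$values),
               dimnames = list(mods, colnames(mm$values)))
  for (m in mods) {
    rows <- mm$values[names(labels)[labels == m], , drop = FALSE]
    z <- t(scale(t(rows)))           # standardize each metagene over samples
    z[is.na(z)] <- 0                 # constant rows contribute nothing
    if (nrow(z) == 1L) {
      e <- as.numeric(z)
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1L]
    }
    mp <- colMeans(rows)
    if (sd(mp) > 0 && cor(e, mp) < 0) e <- -e
    # unit-SD scaling: a module of identical rows yields exactly the
    # standardized common profile
    if (sd(e) > 0) e <- as.numeric(scale(e))
    eg[m, ] <- e
  }
  eg
}

#' Module-trait correlations with significance flags
#'
#' Pearson correlation of each module eigengene with each trait; two-sided p
#' from the Student-t transform with n - 2 df. A (module, trait) pair is
#' significant iff |r| >= r_min and p <= p_max (both inclusive). Constant
#' traits give undefined r and are flagged not significant.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits a `sample_traits` table aligned with the samples.
#' @param r_min minimum |r| (default 0.75).
#' @param p_max maximum p (default 0.005).
#' @return data frame (module, trait, r, p, significant).
#' @export
module_trait <- function(eigengenes, traits, r_min = 0.75, p_max = 0.005) {
  idx <- match(colnames(eigengenes), traits$sample_id)
  if (anyNA(idx)) stop("eigengene samples missing from trait table")
  tr <- traits[idx, c("severity", "duration", "damage", "mem25_specific")]
  out <- list()
  n <- ncol(eigengenes)
  for (m in rownames(eigengenes)) for (tname in names(tr)) {
    tv <- as.numeric(tr[[tname]])
    if (sd(tv) == 0 || sd(eigengenes[m, ]) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        module = m, trait = tname, r = NA_real_, p = NA_real_,
        significant = FALSE)
      next
    }
    r <- cor(eigengenes[m, ], tv)
    p <- cor_p_value(r, n)
    out[[length(out) + 1L]] <- data.frame(
      module = m, trait = tname, r = r, p = p,
      significant = abs(r) >= r_min & p <= p_max)
  }
  do.call(rbind, out)
}

# two-sided p from the exact Student-t transform of a Pearson r
cor_p_value <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}

#' Run the whole co-expression stage
#'
#' Aggregates metagenes, picks the soft threshold, builds the TOM, detects
#' modules, computes eigengenes and module-trait associations.
#'
#' @param exprs list of `expression_matrix`.
#' @param gmap gene map.
#' @param traits sample traits.
#' @param config an [analysis_config()].
#' @return a `module_set` list (mm, power, labels, eigengenes, trait_table).
#' @export
coexpression_modules <- function(exprs, gmap, traits,
                                 config = analysis_config()) {
  mm <- aggregate_metagenes(exprs, gmap)
  st <- pick_soft_threshold(mm, config$soft_power_grid,
                            config$scale_free_r2_min)
  adj <- adjacency_matrix(mm, st$power)
  tom <- tom_similarity(adj)
  labels <- detect_modules(tom, config$module_min_size,
                           config$module_cut_height)
  eg <- module_eigengene(mm, labels)
  tt <- module_trait(eg, traits, config$module_trait_r_min,
                     config$module_trait_p_max)
  structure(list(mm = mm, power = st$power, fit_table = st$fit_table,
                 labels = labels, eigengenes = eg, trait_table = tt),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  nmod <- length(setdiff(unique(x$labels), "grey"))
  nsig <- sum(x$trait_table$significant)
  cat(sprintf(
    "module_set: %d modules (power %d), %d significant module-trait pairs\n",
    nmod, x$power, nsig))
  invisible(x)
}
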