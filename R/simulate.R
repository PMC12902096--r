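## Synthetic-data generators with planted ground truth.
##
## Each generator draws from its own substream seed (derive_seed) so the
## generators can be called in any combination without perturbing each other.

#' Simulate a presence-absence study with planted habitat-featured families
#'
#' Background families are present with probability `p_bg` in every species.
#' Planted saltwater families are present with probability `p_hi` in
#' saltwater species and `p_lo` in freshwater species; planted freshwater
#' families mirror this. Present entries receive a copy number of
#' 1 + Poisson(`copy_lambda`), so presence always implies at least one copy.
#'
#' @param n_salt,n_fresh numbers of saltwater and freshwater species.
#' @param n_families total number of gene families.
#' @param n_planted_salt,n_planted_fresh numbers of planted habitat-featured
#'   families of each class.
#' @param p_hi presence probability in the favored habitat.
#' @param p_lo presence probability in the disfavored habitat.
#' @param p_bg background presence probability.
#' @param copy_lambda Poisson mean of extra gene copies when present.
#' @param seed integer root seed (substream derived internally).
#' @return list with `counts` (orthogroup_counts), `meta` (species_metadata)
#'   and `truth` (planted ids).
#' @export
simulate_presence_absence <- function(n_salt = 16L, n_fresh = 24L,
                                      n_families = 2000L,
                                      n_planted_salt = 15L,
                                      n_planted_fresh = 15L,
                                      p_hi = 0.9, p_lo = 0.05, p_bg = 0.3,
                                      copy_lambda = 1.0, seed = 1L) {
  if (n_salt < 1 || n_fresh < 1 || n_families < 1)
    stop("dimensions must be positive")
  if (n_planted_salt + n_planted_fresh > n_families)
    stop("planted families exceed n_families")
  for (p in c(p_hi, p_lo, p_bg))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (p_lo >= p_hi) stop("require p_lo < p_hi")

  set.seed(derive_seed(seed, "pam"))
  species <- c(sprintf("salt_sp%02d", seq_len(n_salt)),
               sprintf("fresh_sp%02d", seq_len(n_fresh)))
  habitat <- rep(c("saltwater", "freshwater"), c(n_salt, n_fresh))
  fam <- sprintf("OG%07d", seq_len(n_families))
  planted_salt <- fam[seq_len(n_planted_salt)]
  planted_fresh <- fam[n_planted_salt + seq_len(n_planted_fresh)]

  pres <- matrix(0L, n_families, n_salt + n_fresh,
                 dimnames = list(fam, species))
  is_salt <- habitat == "saltwater"
  pmat <- matrix(p_bg, n_families, length(species))
  pmat[match(planted_salt, fam), is_salt] <- p_hi
  pmat[match(planted_salt, fam), !is_salt] <- p_lo
  pmat[match(planted_fresh, fam), !is_salt] <- p_hi
  pmat[match(planted_fresh, fam), is_salt] <- p_lo
  pres[] <- rbinom(length(pmat), 1L, as.vector(pmat))
  copies <- pres
  npres <- sum(pres)
  copies[pres == 1L] <- 1L + rpois(npres, copy_lambda)

  list(
    counts = orthogroup_counts(copies),
    meta = species_metadata(species, habitat),
    truth = list(planted_salt_families = planted_salt,
                 planted_fresh_families = planted_fresh)
  )
}

#' Simulate a two-species stress-course expression study with planted modules
#'
#' Emulates a 2 species x 2 salinities x 2 timepoints x `samples_per_cell`
#' design (24 samples at the default 3 replicates). Planted modules follow a
#' one-factor model: metagene value = loading * standardized trait + noise,
#' shifted to nonnegative abundances. Each metagene is realized as 1-3 member
#' genes per species whose values sum to the metagene value, so orthogroup
#' aggregation is exercised.
#'
#' @param n_metagenes number of shared orthogroups (metagenes).
#' @param samples_per_cell replicates per design cell.
#' @param module_specs list of lists with fields `size`, `trait`
#'   (one of "severity", "duration", "damage", "mem25_specific", or the
#'   derived alias "fresh_specific" = 1 - mem25_specific, which plants a
#'   module expressed in the freshwater species) and `loading` in (0, 1].
#' @param noise_sd residual standard deviation of the factor model.
#' @param seed integer root seed.
#' @return list with `exprs` (two expression_matrix), `gmap`, `traits`,
#'   and `truth$planted_modules` (module id -> metagene ids + trait).
#' @export
simulate_expression <- function(n_metagenes = 300L, samples_per_cell = 3L,
                                module_specs = list(
                                  list(size = 40L, trait = "severity",       loading = 0.9),
                                  list(size = 40L, trait = "duration",       loading = 0.9),
                                  list(size = 40L, trait = "fresh_specific", loading = 0.9)),
                                noise_sd = 0.3, seed = 7L) {
  if (!length(module_specs)) stop("module_specs must be nonempty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sizes <- vapply(module_specs, function(m) as.integer(m$size), integer(1))
  if (sum(sizes) > n_metagenes) stop("module sizes exceed n_metagenes")
  loadings <- vapply(module_specs, function(m) m$loading, numeric(1))
  if (any(loadings <= 0 | loadings > 1)) stop("loadings must be in (0, 1]")

  set.seed(derive_seed(seed, "expression"))
  species <- c("MEM25", "FACHB9")
  design <- expand.grid(rep = seq_len(samples_per_cell),
                        time = c(24, 72), salinity = c(10, 40),
                        species = species, stringsAsFactors = FALSE)
  n_s <- nrow(design)
  sample_id <- sprintf("%s_s%02d_t%02d_r%d", design$species, design$salinity,
                       design$time, design$rep)
  # MEM25 is the euryhaline/saltwater-preferring focal species: damage = 1
  # away from preferred salinity.
  damage <- ifelse(design$species == "MEM25",
                   as.integer(design$salinity == 10),
                   as.integer(design$salinity == 40))
  traits <- sample_traits(data.frame(
    sample_id = sample_id, severity = design$salinity,
    duration = design$time, damage = damage,
    mem25_specific = as.integer(design$species == "MEM25")))

  trait_factor <- function(name) {
    v <- if (name == "fresh_specific") 1 - traits$mem25_specific
         else traits[[name]]
    as.numeric(scale(v))
  }
  # column of the trait table that carries the planted signal (for scoring)
  trait_column <- function(name)
    if (name == "fresh_specific") "mem25_specific" else name

  og <- sprintf("OG%07d", seq_len(n_metagenes))
  meta_vals <- matrix(rnorm(n_metagenes * n_s, sd = noise_sd), n_metagenes,
                      n_s, dimnames = list(og, sample_id))
  planted <- list()
  idx0 <- 0L
  for (k in seq_along(module_specs)) {
    spec <- module_specs[[k]]
    rows <- idx0 + seq_len(spec$size)
    f <- trait_factor(spec$trait)
    meta_vals[rows, ] <- meta_vals[rows, ] +
      matrix(rep(spec$loading * f, each = spec$size), spec$size, n_s)
    planted[[paste0("planted", k)]] <- list(metagenes = og[rows],
                                            trait = spec$trait,
                                            trait_column = trait_column(spec$trait))
    idx0 <- idx0 + spec$size
  }
  # shift to nonnegative abundances; correlations downstream are
  # shift-invariant so planted structure is preserved
  meta_vals <- meta_vals - min(meta_vals) + 0.1

  # realize metagenes as member genes per species (1-3 copies, value split)
  exprs <- list(); gm <- list()
  for (sp in species) {
    cols <- which(design$species == sp)
    ncopy <- sample(1:3, n_metagenes, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
    total_genes <- sum(ncopy)
    gvals <- matrix(0, total_genes, length(cols))
    gids <- character(total_genes)
    row <- 1L
    for (i in seq_len(n_metagenes)) {
      k <- ncopy[i]
      w <- runif(k, 0.2, 1); w <- w / sum(w)
      for (j in seq_len(k)) {
        gvals[row, ] <- w[j] * meta_vals[i, cols]
        gids[row] <- sprintf("%s_g%05d_%d", sp, i, j)
        row <- row + 1L
      }
    }
    rownames(gvals) <- gids
    colnames(gvals) <- sample_id[cols]
    exprs[[sp]] <- expression_matrix(gvals, sp)
    gm[[sp]] <- data.frame(gene_id = gids, species_id = sp,
                           orthogroup_id = rep(og, ncopy))
  }

  list(exprs = exprs,
       gmap = gene_map(do.call(rbind, gm)),
       traits = traits,
       truth = list(planted_modules = planted))
}

#' Simulate a metabolite abundance comparison with planted fold changes
#'
#' Differentially abundant (DA) metabolites get a true log2 fold change drawn
#' uniformly from `true_log2fc_range` with a random sign; replicate noise is
#' lognormal with coefficient of variation `cv_noise`.
#'
#' @param n_metab total metabolites.
#' @param n_da number of planted DA metabolites.
#' @param true_log2fc_range (lower, upper) bounds of |true log2FC|.
#' @param replicates replicates per condition.
#' @param cv_noise replicate coefficient of variation (0 = noiseless).
#' @param seed integer root seed.
#' @return list with `mm` (metabolite_matrix with conditions "control" and
#'   "treated") and `truth$planted_da` (data frame metabolite_id, true_log2fc).
#' @export
simulate_metabolites <- function(n_metab = 451L, n_da = 150L,
                                 true_log2fc_range = c(1.2, 4),
                                 replicates = 3L, cv_noise = 0.1,
                                 seed = 3L) {
  if (n_da > n_metab) stop("n_da must be <= n_metab")
  if (replicates < 2) stop("replicates must be >= 2")
  if (true_log2fc_range[1] > true_log2fc_range[2])
    stop("invalid true_log2fc_range ordering")
  set.seed(derive_seed(seed, "metabolites"))
  ids <- sprintf("metab%04d", seq_len(n_metab))
  base <- rlnorm(n_metab, meanlog = 8, sdlog = 1)
  lfc <- numeric(n_metab)
  if (n_da > 0) {
    da_idx <- seq_len(n_da)
    lfc[da_idx] <- sample(c(-1, 1), n_da, replace = TRUE) *
      runif(n_da, true_log2fc_range[1], true_log2fc_range[2])
  }
  sdlog <- sqrt(log(1 + cv_noise^2))
  n_samp <- 2L * replicates
  vals <- matrix(0, n_metab, n_samp)
  mu <- cbind(matrix(base, n_metab, replicates),
              matrix(base * 2^lfc, n_metab, replicates))
  vals[] <- mu * matrix(rlnorm(n_metab * n_samp, -sdlog^2 / 2, sdlog),
                        n_metab, n_samp)
  colnames(vals) <- c(sprintf("control_r%d", seq_len(replicates)),
                      sprintf("treated_r%d", seq_len(replicates)))
  rownames(vals) <- ids
  cond <- rep(c("control", "treated"), each = replicates)
  truth <- if (n_da > 0)
    data.frame(metabolite_id = ids[seq_len(n_da)],
               true_log2fc = lfc[seq_len(n_da)])
  else data.frame(metabolite_id = character(0), true_log2fc = numeric(0))
  list(mm = metabolite_matrix(vals, cond),
       truth = list(planted_da = truth))
}
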