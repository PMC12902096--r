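## Metabolite differential abundance, transcript-metabolite correlation
## networks on log2 fold-change profiles, rule-based salt-sensitive candidate
## triage, and GWAS summary-statistic helpers.

#' Metabolite differential abundance between two conditions
#'
#' log2FC = log2(mean(group_b) / mean(group_a)); p from a two-sided Welch
#' t-test on log2 abundances. A metabolite is significant iff
#' |log2FC| >= `da_log2fc_min` AND p <= `da_p_max` (both inclusive).
#'
#' @param mm a `metabolite_matrix`.
#' @param group_a,group_b condition labels (reference first).
#' @param config an [analysis_config()] (fields da_log2fc_min, da_p_max).
#' @return data frame (metabolite_id, log2fc, p, significant).
#' @export
metabolite_da <- function(mm, group_a = "control", group_b = "treated",
                          config = analysis_config()) {
  ia <- which(mm$condition == group_a)
  ib <- which(mm$condition == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("at least 2 replicates per group required")
  if (any(mm$values <= 0)) stop("nonpositive abundances: log undefined")
  a <- mm$values[, ia, drop = FALSE]
  b <- mm$values[, ib, drop = FALSE]
  lfc <- log2(rowMeans(b) / rowMeans(a))
  la <- log2(a); lb <- log2(b)
  p <- vapply(seq_len(nrow(mm$values)), function(i) {
    if (sd(la[i, ]) == 0 && sd(lb[i, ]) == 0) {
      if (mean(la[i, ]) == mean(lb[i, ])) 1 else 0
    } else t.test(lb[i, ], la[i, ])$p.value
  }, numeric(1))
  data.frame(metabolite_id = rownames(mm$values), log2fc = lfc, p = p,
             significant = abs(lfc) >= config$da_log2fc_min &
               p <= config$da_p_max,
             row.names = NULL)
}

#' Transcript-metabolite correlation network on log2FC profiles
#'
#' Pearson correlation between each orthogroup's and each metabolite's log2
#' fold-change vector over shared conditions; p from the Student-t transform.
#' An edge is retained iff PCC > `pcc_min` and p < `pccp_max` (both strict,
#' so strong negative correlations are excluded); set `two_sided = TRUE` to
#' filter on |PCC| instead.
#'
#' @param gene_profiles numeric matrix, orthogroups x conditions, of log2FC.
#' @param metab_profiles numeric matrix, metabolites x conditions, of log2FC.
#' @param config an [analysis_config()] (fields pcc_min, pccp_max).
#' @param two_sided filter on |PCC| rather than PCC.
#' @return data frame (orthogroup_id, metabolite_id, pcc, p) sorted by
#'   descending pcc.
#' @export
transcript_metabolite_network <- function(gene_profiles, metab_profiles,
                                          config = analysis_config(),
                                          two_sided = FALSE) {
  shared <- intersect(colnames(gene_profiles), colnames(metab_profiles))
  if (length(shared) < 3) stop("at least 3 shared conditions required")
  g <- gene_profiles[, shared, drop = FALSE]
  m <- metab_profiles[, shared, drop = FALSE]
  g_const <- apply(g, 1L, sd) == 0
  m_const <- apply(m, 1L, sd) == 0
  if (any(g_const) || any(m_const))
    warning(sum(g_const) + sum(m_const), " constant profile(s) skipped")
  g <- g[!g_const, , drop = FALSE]
  m <- m[!m_const, , drop = FALSE]
  cc <- cor(t(g), t(m))
  n <- length(shared)
  pass <- if (two_sided) abs(cc) > config$pcc_min else cc > config$pcc_min
  idx <- which(pass, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(orthogroup_id = character(0),
                      metabolite_id = character(0),
                      pcc = numeric(0), p = numeric(0)))
  pcc <- cc[idx]
  p <- vapply(pcc, cor_p_value, numeric(1), n = n)
  keep <- p < config$pccp_max
  out <- data.frame(orthogroup_id = rownames(g)[idx[, 1L]],
                    metabolite_id = rownames(m)[idx[, 2L]],
                    pcc = pcc, p = p)[keep, , drop = FALSE]
  out <- out[order(-out$pcc), ]
  rownames(out) <- NULL
  out
}

#' Rule-based triage of salt-sensitive candidate orthogroups
#'
#' Three selection strategies over cross-species expression contrasts,
#' module annotations and gene copy numbers (MEM25 is the focal euryhaline
#' species, FACHB-9 and allies the freshwater comparators):
#' \itemize{
#'   \item Strategy 1: mean expression higher in the freshwater species than
#'     in the focal species, AND the orthogroup's module is freshwater-
#'     associated AND not focal-specific.
#'   \item Strategy 2: expression lower under high salinity than low salinity
#'     in the focal species, AND module saltwater-associated AND
#'     focal-specific.
#'   \item Strategy 3: gene copy number higher in a majority (or on average,
#'     see `expansion_comparator`) of freshwater species than in the focal
#'     species, AND module freshwater-associated AND not focal-specific.
#' }
#'
#' @param expr_summary data frame with columns orthogroup_id,
#'   expr_focal (mean expression in the focal species),
#'   expr_fresh (mean expression in the freshwater species),
#'   expr_focal_high, expr_focal_low (focal-species means under high/low
#'   salinity).
#' @param module_annotation data frame with columns orthogroup_id, module,
#'   fresh_associated, salt_associated, focal_specific (logical; "grey"
#'   modules must carry FALSE annotations).
#' @param counts an `orthogroup_counts` table.
#' @param meta species metadata identifying habitats.
#' @param focal_species focal species id in `counts`.
#' @param expansion_comparator `"majority"` (default) or `"mean"` copy-number
#'   comparison for strategy 3.
#' @return data frame (orthogroup_id, strategy, plus evidence columns).
#' @export
triage_candidates <- function(expr_summary, module_annotation, counts, meta,
                              focal_species,
                              expansion_comparator = c("majority", "mean")) {
  expansion_comparator <- match.arg(expansion_comparator)
  req <- c("orthogroup_id", "module", "fresh_associated", "salt_associated",
           "focal_specific")
  miss <- setdiff(req, names(module_annotation))
  if (length(miss))
    stop("missing module annotation column(s): ", paste(miss, collapse = ", "))
  ann <- module_annotation[match(expr_summary$orthogroup_id,
                                 module_annotation$orthogroup_id), ]
  if (anyNA(ann$module))
    stop("module annotation missing for some orthogroups")

  # strategy 3 evidence: copy-number expansion in freshwater species
  fresh_sp <- meta$species_id[meta$habitat == "freshwater"]
  fresh_sp <- intersect(fresh_sp, colnames(counts$counts))
  og_idx <- match(expr_summary$orthogroup_id, rownames(counts$counts))
  focal_copy <- counts$counts[og_idx, focal_species]
  fresh_counts <- counts$counts[og_idx, fresh_sp, drop = FALSE]
  expanded <- if (expansion_comparator == "majority")
    rowMeans(fresh_counts > focal_copy) > 0.5
  else rowMeans(fresh_counts) > focal_copy

  s1 <- expr_summary$expr_fresh > expr_summary$expr_focal &
    ann$fresh_associated & !ann$focal_specific
  s2 <- expr_summary$expr_focal_high < expr_summary$expr_focal_low &
    ann$salt_associated & ann$focal_specific
  s3 <- expanded & ann$fresh_associated & !ann$focal_specific

  ev <- data.frame(orthogroup_id = expr_summary$orthogroup_id,
                   module = ann$module,
                   expr_focal = expr_summary$expr_focal,
                   expr_fresh = expr_summary$expr_fresh,
                   expr_focal_high = expr_summary$expr_focal_high,
                   expr_focal_low = expr_summary$expr_focal_low,
                   focal_copy = focal_copy,
                   fresh_expanded = expanded)
  out <- rbind(
    if (any(s1)) cbind(strategy = 1L, ev[s1, ]),
    if (any(s2)) cbind(strategy = 2L, ev[s2, ]),
    if (any(s3)) cbind(strategy = 3L, ev[s3, ]))
  if (is.null(out))
    out <- cbind(strategy = integer(0), ev[0, ])
  rownames(out) <- NULL
  out
}

#' Wald summary statistics from an effect estimate
#'
#' t = beta / se; two-sided p from Student's t with `df` degrees of freedom;
#' 95% CI = beta -/+ t_crit(0.975, df) * se.
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param df degrees of freedom (>= 1).
#' @return an `association_summary` list (beta, se, df, t, p, ci95).
#' @export
wald_stats <- function(beta, se, df) {
  if (se <= 0) stop("se must be > 0")
  if (df < 1) stop("df must be >= 1")
  t <- beta / se
  p <- 2 * pt(-abs(t), df = df)
  crit <- qt(0.975, df = df)
  structure(list(beta = beta, se = se, df = df, t = t, p = p,
                 ci95 = c(beta - crit * se, beta + crit * se)),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat(sprintf(
    "beta = %.5g +/- %.4g, t(%d) = %.3f, P = %.3g, 95%% CI [%.5g, %.5g]\n",
    x$beta, x$se, x$df, x$t, x$p, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Multiple-testing adjustment helpers
#'
#' @param p vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh"` (Benjamini-Hochberg step-up).
#' @param m_override optional number of tests overriding `length(p)`.
#' @return adjusted p-values.
#' @export
multiple_testing <- function(p, method = c("bonferroni", "bh"),
                             m_override = NULL) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- m_override %||% length(p)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni", n = n)
}

#' Bonferroni significance threshold alpha / m
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @export
bonferroni_threshold <- function(alpha, m) alpha / m
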