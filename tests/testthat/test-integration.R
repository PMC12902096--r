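test_that("metabolite differential abundance applies the inclusive rule", {
  # identical groups: log2FC 0, not significant
  v <- matrix(c(10, 11, 9, 10, 11, 9), nrow = 1)
  rownames(v) <- "m1"; colnames(v) <- paste0("s", 1:6)
  mm <- metabolite_matrix(v, rep(c("control", "treated"), each = 3))
  da <- metabolite_da(mm)
  expect_equal(da$log2fc, 0, tolerance = 1e-12)
  expect_false(da$significant)

  # log2FC exactly 1 with tiny p -> significant (inclusive ">= 1")
  a <- c(10, 10.001, 9.999)
  v2 <- rbind(m1 = c(a, 2 * a))
  colnames(v2) <- paste0("s", 1:6)
  mm2 <- metabolite_matrix(v2, rep(c("control", "treated"), each = 3))
  da2 <- metabolite_da(mm2)
  expect_equal(da2$log2fc, 1, tolerance = 1e-12)
  expect_lte(da2$p, 0.05)
  expect_true(da2$significant)
  # boundary on p: a config with p_max equal to the observed p keeps it
  da3 <- metabolite_da(mm2, config = analysis_config(da_p_max = da2$p))
  expect_true(da3$significant)
  # but |log2FC| just under 1 is excluded
  v4 <- rbind(m1 = c(a, 1.99 * a))
  colnames(v4) <- paste0("s", 1:6)
  da4 <- metabolite_da(metabolite_matrix(v4, rep(c("control", "treated"),
                                                 each = 3)))
  expect_false(da4$significant)
})

test_that("planted differential abundance is recovered with high sensitivity", {
  mb <- simulate_metabolites(seed = 3)
  da <- metabolite_da(mb$mm)
  hits <- da$metabolite_id[da$significant]
  sens <- mean(mb$truth$planted_da$metabolite_id %in% hits)
  expect_gte(sens, 0.9)
  # recovered signs agree with the planted fold changes
  sub <- merge(da, mb$truth$planted_da, by = "metabolite_id")
  expect_true(all(sign(sub$log2fc) == sign(sub$true_log2fc)))
})

test_that("transcript-metabolite edges keep strong positive correlations only", {
  g <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), g3 = c(1, 1, 2, 5))
  m <- rbind(m1 = c(1, 2, 3, 4), m2 = c(2, 4, 6, 8.1))
  colnames(g) <- colnames(m) <- paste0("c", 1:4)
  edges <- transcript_metabolite_network(g, m)
  # identical vectors correlate at 1 and survive the strict cutoffs
  e11 <- edges[edges$orthogroup_id == "g1" & edges$metabolite_id == "m1", ]
  expect_equal(e11$pcc, 1, tolerance = 1e-12)
  # perfect anticorrelation (g2 vs m1) is excluded by the one-sided rule
  expect_false(any(edges$orthogroup_id == "g2"))
  # ... but kept when filtering on |PCC|
  edges2 <- transcript_metabolite_network(g, m, two_sided = TRUE)
  expect_true(any(edges2$orthogroup_id == "g2" & edges2$metabolite_id == "m1"))
  # edges sorted by descending correlation
  expect_true(all(diff(edges$pcc) <= 1e-12))

  # constant profiles are skipped with a warning
  gc <- rbind(g, gc = c(2, 2, 2, 2))
  expect_warning(transcript_metabolite_network(gc, m), "constant")
  expect_error(transcript_metabolite_network(g[, 1:2], m[, 1:2]),
               "3 shared conditions")
})

test_that("the network equals brute-force all-pairs filtering on random profiles", {
  set.seed(77)
  g <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:8)))
  m <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("m%02d", 1:20), paste0("c", 1:8)))
  # plant some strong positive pairs
  for (i in 1:5) g[i, ] <- m[i, ] + rnorm(8, sd = 0.05)
  cfg <- analysis_config(pcc_min = 0.5, pccp_max = 0.05)
  edges <- transcript_metabolite_network(g, m, cfg)
  # independent oracle: cor.test per pair
  expected <- character(0)
  for (i in rownames(g)) for (j in rownames(m)) {
    ct <- cor.test(g[i, ], m[j, ])
    if (ct$estimate > 0.5 && ct$p.value < 0.05)
      expected <- c(expected, paste(i, j))
  }
  got <- paste(edges$orthogroup_id, edges$metabolite_id)
  expect_setequal(got, expected)
})

test_that("triage strategies evaluate their full conjunctions", {
  ogs <- c("OG1", "OG2", "OG3", "OG4")
  es <- data.frame(orthogroup_id = ogs,
                   expr_focal = c(2, 2, 10, 5),
                   expr_fresh = c(10, 10, 2, 5),
                   expr_focal_high = c(1, 5, 2, 9),
                   expr_focal_low = c(2, 3, 8, 9))
  ann <- data.frame(orthogroup_id = ogs,
                    module = c("M1", "grey", "M2", "M1"),
                    fresh_associated = c(TRUE, FALSE, FALSE, TRUE),
                    salt_associated = c(FALSE, FALSE, TRUE, FALSE),
                    focal_specific = c(FALSE, FALSE, TRUE, FALSE))
  counts <- orthogroup_counts(matrix(
    c(1L, 3L, 3L,    # OG1 expanded in both freshwater species
      1L, 1L, 1L,
      2L, 1L, 1L,
      1L, 2L, 0L),   # OG4: expanded in only one of two
    4, 3, byrow = TRUE,
    dimnames = list(ogs, c("MEM25", "F1", "F2"))))
  meta <- species_metadata(c("MEM25", "F1", "F2"),
                           c("saltwater", "freshwater", "freshwater"))
  tri <- triage_candidates(es, ann, counts, meta, focal_species = "MEM25")
  # OG1: higher in freshwater + fresh module + not focal-specific -> s1;
  # also majority-expanded -> s3
  expect_setequal(tri$strategy[tri$orthogroup_id == "OG1"], c(1L, 3L))
  # OG2 meets the expression contrast but sits in a grey module
  expect_false("OG2" %in% tri$orthogroup_id)
  # OG3: lower at high salinity + salt module + focal-specific -> s2
  expect_identical(tri$strategy[tri$orthogroup_id == "OG3"], 2L)
  # OG4: expanded in only 1 of 2 freshwater species, no majority -> no s3
  expect_false(3L %in% tri$strategy[tri$orthogroup_id == "OG4"])
  # but OG4 qualifies for s1 (10 > 5 is FALSE here: 5 == 5) -> absent
  expect_false("OG4" %in% tri$orthogroup_id)

  expect_error(triage_candidates(es, ann[, -3], counts, meta, "MEM25"),
               "annotation")
})

test_that("triage matches brute force and shrinks when annotations are removed", {
  set.seed(55)
  n <- 50
  ogs <- sprintf("OG%02d", 1:n)
  es <- data.frame(orthogroup_id = ogs,
                   expr_focal = runif(n, 0, 10),
                   expr_fresh = runif(n, 0, 10),
                   expr_focal_high = runif(n, 0, 10),
                   expr_focal_low = runif(n, 0, 10))
  ann <- data.frame(orthogroup_id = ogs,
                    module = sample(c("M1", "M2", "grey"), n, TRUE),
                    fresh_associated = sample(c(TRUE, FALSE), n, TRUE),
                    salt_associated = sample(c(TRUE, FALSE), n, TRUE),
                    focal_specific = sample(c(TRUE, FALSE), n, TRUE))
  cm <- matrix(rpois(n * 5, 1.2), n, 5,
               dimnames = list(ogs, c("MEM25", paste0("F", 1:4))))
  counts <- orthogroup_counts(cm)
  meta <- species_metadata(colnames(cm),
                           c("saltwater", rep("freshwater", 4)))
  tri <- triage_candidates(es, ann, counts, meta, "MEM25")

  # independent conjunction-by-conjunction evaluation
  for (i in seq_len(n)) {
    exp1 <- es$expr_fresh[i] > es$expr_focal[i] && ann$fresh_associated[i] &&
      !ann$focal_specific[i]
    exp2 <- es$expr_focal_high[i] < es$expr_focal_low[i] &&
      ann$salt_associated[i] && ann$focal_specific[i]
    exp3 <- mean(cm[i, 2:5] > cm[i, 1]) > 0.5 && ann$fresh_associated[i] &&
      !ann$focal_specific[i]
    hit <- tri$strategy[tri$orthogroup_id == ogs[i]]
    expect_identical(1L %in% hit, exp1, label = paste("s1", ogs[i]))
    expect_identical(2L %in% hit, exp2, label = paste("s2", ogs[i]))
    expect_identical(3L %in% hit, exp3, label = paste("s3", ogs[i]))
  }

  # monotonicity: clearing one module annotation can only shrink the set
  ann2 <- ann
  ann2$fresh_associated <- FALSE
  tri2 <- triage_candidates(es, ann2, counts, meta, "MEM25")
  key <- function(d) paste(d$orthogroup_id, d$strategy)
  expect_true(all(key(tri2) %in% key(tri)))
})

test_that("Wald arithmetic is exact and its CI always covers beta", {
  ws <- wald_stats(-0.01618, 0.002495, 196)
  expect_equal(ws$t, -0.01618 / 0.002495, tolerance = 1e-12)
  expect_equal(ws$t, -6.483, tolerance = 0.005)
  expect_lt(ws$p, 1e-8)
  expect_lt(ws$ci95[1], -0.01618); expect_gt(ws$ci95[2], -0.01618)

  w0 <- wald_stats(0, 1, 10)
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)

  set.seed(8)
  for (i in 1:20) {
    b <- rnorm(1); s <- runif(1, 0.1, 2); d <- sample(3:200, 1)
    w <- wald_stats(b, s, d)
    expect_equal(w$t, b / s, tolerance = 1e-12)
    expect_true(w$ci95[1] <= b && b <= w$ci95[2])
    # p symmetric in the sign of beta
    expect_equal(w$p, wald_stats(-b, s, d)$p, tolerance = 1e-12)
  }
  expect_error(wald_stats(1, 0, 10), "se")
})

test_that("multiple-testing helpers match the standard definitions", {
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_equal(multiple_testing(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(multiple_testing(0.04, "bonferroni"), 0.04)
  expect_equal(multiple_testing(c(0.01, 0.4), "bonferroni"),
               pmin(1, c(0.02, 0.8)))
  expect_equal(multiple_testing(0.01, "bonferroni", m_override = 50), 0.5)
  expect_error(multiple_testing(c(0.5, 1.2), "bh"), "0, 1")
})
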