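test_that("habitat fractions count presence per habitat, excluding outgroups", {
  m <- matrix(0L, 12, 3, dimnames = list(
    c(sprintf("s%d", 1:5), sprintf("f%d", 1:5), "out1", "out2"),
    c("OG1", "OG2", "OG3")))
  m[1:4, "OG1"] <- 1L; m[6, "OG1"] <- 1L       # 4/5 salt, 1/5 fresh
  m[11:12, "OG3"] <- 1L                         # outgroups only
  meta <- species_metadata(rownames(m),
                           rep(c("saltwater", "freshwater", "outgroup"),
                               c(5, 5, 2)))
  fr <- habitat_fractions(presence_absence_matrix(m), meta)
  expect_equal(fr$frac_salt[fr$family_id == "OG1"], 0.8)
  expect_equal(fr$frac_fresh[fr$family_id == "OG1"], 0.2)
  expect_equal(fr$frac_salt[fr$family_id == "OG2"], 0)
  expect_equal(fr$frac_fresh[fr$family_id == "OG2"], 0)
  # outgroup presence is invisible to the fractions
  expect_equal(fr$frac_salt[fr$family_id == "OG3"], 0)

  # random matrix matches a brute-force per-cell count
  rp <- random_pam(4, 6, 20, seed = 11)
  fr2 <- habitat_fractions(rp$pam, rp$meta)
  hab <- rp$meta$habitat[match(rownames(rp$pam$values), rp$meta$species_id)]
  for (j in seq_len(20)) {
    expect_equal(fr2$frac_salt[j],
                 sum(rp$pam$values[hab == "saltwater", j]) / 4)
    expect_equal(fr2$frac_fresh[j],
                 sum(rp$pam$values[hab == "freshwater", j]) / 6)
  }

  meta_bad <- species_metadata(rownames(m), rep("saltwater", 12))
  expect_error(habitat_fractions(presence_absence_matrix(m), meta_bad),
               "freshwater")
})

test_that("featured classification follows the strict over-cutoff rule", {
  fr <- data.frame(family_id = c("a", "b"),
                   frac_salt = c(0.8, 0.6), frac_fresh = c(0.2, 0.4))
  feat <- classify_featured(fr, 0.6)
  expect_identical(feat$salt_featured, "a")       # (0.8, 0.2) qualifies
  expect_false("b" %in% feat$salt_featured)        # 0.6 is not "over" 0.6
  expect_length(feat$fresh_featured, 0)
  expect_error(classify_featured(fr, 0.5), "cutoff")
})

test_that("featured classification matches brute force, swaps under label swap, and is monotone", {
  set.seed(101)
  fr <- data.frame(family_id = sprintf("F%03d", 1:500),
                   frac_salt = runif(500), frac_fresh = runif(500))
  cutoff <- 0.6
  feat <- classify_featured(fr, cutoff)
  # independent rule evaluation, row by row
  for (i in seq_len(500)) {
    in_salt <- fr$frac_salt[i] > cutoff && (1 - fr$frac_fresh[i]) > cutoff
    in_fresh <- fr$frac_fresh[i] > cutoff && (1 - fr$frac_salt[i]) > cutoff
    expect_identical(fr$family_id[i] %in% feat$salt_featured, in_salt)
    expect_identical(fr$family_id[i] %in% feat$fresh_featured, in_fresh)
  }
  expect_length(intersect(feat$salt_featured, feat$fresh_featured), 0)

  # habitat-label swap maps salt <-> fresh exactly
  swapped <- classify_featured(
    data.frame(family_id = fr$family_id, frac_salt = fr$frac_fresh,
               frac_fresh = fr$frac_salt), cutoff)
  expect_identical(sort(swapped$salt_featured), sort(feat$fresh_featured))
  expect_identical(sort(swapped$fresh_featured), sort(feat$salt_featured))

  # raising the cutoff never enlarges either set
  prev <- classify_featured(fr, 0.55)
  for (c in c(0.6, 0.7, 0.8, 0.9)) {
    cur <- classify_featured(fr, c)
    expect_true(all(cur$salt_featured %in% prev$salt_featured))
    expect_true(all(cur$fresh_featured %in% prev$fresh_featured))
    prev <- cur
  }
})

test_that("chi-square and Cramer's V follow the closed 2x2 form", {
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  res <- saltadapt:::chi2_cramers_v(tab)
  expect_equal(res$chi2, 18.0, tolerance = 1e-12)
  expect_equal(res$cramers_v, 0.6, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # identical rows -> independence
  res0 <- saltadapt:::chi2_cramers_v(matrix(c(7, 3, 7, 3), 2, byrow = TRUE))
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$cramers_v, 0, tolerance = 1e-12)

  # swapping habitat rows changes nothing
  resw <- saltadapt:::chi2_cramers_v(tab[2:1, ])
  expect_equal(resw$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(resw$cramers_v, res$cramers_v, tolerance = 1e-12)

  expect_error(saltadapt:::chi2_cramers_v(matrix(c(0, 0, 3, 4), 2)),
               "exact test")
})

test_that("association test pools featured presence and bootstraps a CI for V", {
  sim <- simulate_presence_absence(n_salt = 8, n_fresh = 10,
                                   n_families = 200, n_planted_salt = 10,
                                   n_planted_fresh = 10, seed = 2)
  pam <- to_presence_absence(sim$counts)
  fr <- habitat_fractions(pam, sim$meta)
  feat <- classify_featured(fr, 0.6)
  res <- association_test(pam, sim$meta, feat, bootstrap_reps = 100, seed = 4)
  expect_equal(sum(res$table),
               18 * (length(feat$salt_featured) + length(feat$fresh_featured)))
  expect_equal(res$chi2, chi2_2x2_closed_form(res$table), tolerance = 1e-9)
  expect_true(res$v_ci95[1] <= res$v_ci95[2])
  expect_true(all(res$v_ci95 >= 0 & res$v_ci95 <= 1))
  # seeded bootstrap is reproducible
  res2 <- association_test(pam, sim$meta, feat, bootstrap_reps = 100, seed = 4)
  expect_identical(res$v_ci95, res2$v_ci95)
})

test_that("species ordination is centered PCA with nonincreasing explained variance", {
  # exactly one varying family -> PC1 explains everything
  m <- matrix(0L, 4, 3, dimnames = list(paste0("sp", 1:4), paste0("OG", 1:3)))
  m[, 1] <- 1L
  m[1:2, 2] <- 1L
  ord <- pca_species(presence_absence_matrix(m), 2)
  expect_equal(ord$explained_fraction[1], 1, tolerance = 1e-12)

  rp <- random_pam(8, 12, 50, seed = 21)
  ord2 <- pca_species(rp$pam, 5)
  expect_true(all(diff(ord2$explained_fraction) <= 1e-12))
  expect_true(all(ord2$explained_fraction >= 0))
  expect_lte(sum(ord2$explained_fraction), 1 + 1e-12)
  # component variances equal the covariance eigendecomposition
  ev <- eigen(cov(rp$pam$values), symmetric = TRUE)$values
  pcvar <- apply(ord2$scores, 2, var)
  expect_equal(unname(pcvar), ev[1:5], tolerance = 1e-8)

  expect_error(pca_species(presence_absence_matrix(m[1, , drop = FALSE])),
               "2 species")
})

test_that("membership profile counts featured families housed by a species", {
  m <- matrix(0L, 6, 5, dimnames = list(paste0("sp", 1:6), paste0("OG", 1:5)))
  m["sp1", ] <- 1L                                  # carries everything
  m["sp2", c("OG1", "OG4")] <- 1L
  feat <- structure(list(cutoff = 0.6,
                         salt_featured = c("OG1", "OG2"),
                         fresh_featured = c("OG4", "OG5")),
                    class = "featured_family_set")
  pam <- presence_absence_matrix(m)
  p1 <- membership_profile(pam, feat, "sp1")
  expect_equal(p1$salt_housed, 2); expect_equal(p1$fresh_housed, 2)
  p2 <- membership_profile(pam, feat, "sp2")
  expect_equal(p2$salt_housed, 1); expect_equal(p2$fresh_housed, 1)
  p3 <- membership_profile(pam, feat, "sp3")
  expect_equal(p3$salt_housed, 0); expect_equal(p3$fresh_housed, 0)
  expect_equal(p1$salt_total, 2)
  expect_error(membership_profile(pam, feat, "nope"), "unknown species")
})

test_that("featured classification recovers planted families on synthetic data", {
  sim <- simulate_presence_absence(n_salt = 16, n_fresh = 24,
                                   n_families = 2000, n_planted_salt = 15,
                                   n_planted_fresh = 15, p_hi = 0.9,
                                   p_lo = 0.05, p_bg = 0.3, seed = 1)
  pam <- to_presence_absence(sim$counts)
  feat <- classify_featured(habitat_fractions(pam, sim$meta), 0.6)
  found <- c(feat$salt_featured, feat$fresh_featured)
  planted <- c(sim$truth$planted_salt_families,
               sim$truth$planted_fresh_families)
  expect_gte(mean(planted %in% found), 0.8)
  # background families passing the 60% rule by chance are expected at this
  # background presence rate (exact binomial expectation ~13.5 of 1970);
  # the false-discovery proportion stays within that expectation's reach
  expect_lte(mean(!found %in% planted), 0.35)
  # planted direction is classified correctly
  expect_true(all(intersect(sim$truth$planted_salt_families, found) %in%
                    feat$salt_featured))
  expect_true(all(intersect(sim$truth$planted_fresh_families, found) %in%
                    feat$fresh_featured))
})
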