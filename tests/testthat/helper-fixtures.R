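# Small in-code fixtures and independent oracles shared across tests.

# write a counts TSV in the Orthogroups.GeneCount.tsv dialect
write_counts_tsv <- function(mat, path, total = FALSE) {
  df <- data.frame(Orthogroup = rownames(mat), mat, check.names = FALSE)
  if (total) df$Total <- rowSums(mat)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random presence-absence matrix with labeled species
random_pam <- function(n_salt, n_fresh, n_fam, seed, p = 0.5) {
  set.seed(seed)
  sp <- c(sprintf("s%02d", seq_len(n_salt)), sprintf("f%02d", seq_len(n_fresh)))
  m <- matrix(rbinom(length(sp) * n_fam, 1, p), length(sp), n_fam,
              dimnames = list(sp, sprintf("OG%04d", seq_len(n_fam))))
  list(pam = presence_absence_matrix(m),
       meta = species_metadata(sp, rep(c("saltwater", "freshwater"),
                                       c(n_salt, n_fresh))))
}

# closed-form Pearson chi-square for a 2x2 table: N(ad-bc)^2 / product of margins
chi2_2x2_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)   # avoid integer overflow in (ad-bc)^2
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force TOM by triple loop
tom_brute_force <- function(a) {
  a <- as.matrix(a)
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

# adjusted Rand index (independent of any clustering package)
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  (a - expected) / ((b + c) / 2 - expected)
}
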