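# Shared fixtures: tiny cohort builders and exhaustive genotype grids.

# Build a one-sample genotype frame from named genotype strings,
# e.g. mk_geno(rs12913832 = "G/G", rs12203592 = "T/T").
mk_geno <- function(..., sample_id = "S1") {
  g <- empty_genotypes(sample_id)
  calls <- list(...)
  for (r in names(calls)) g[[r]] <- calls[[r]]
  g
}

# The three possible genotypes at a panel SNP, canonical strings.
geno_levels <- function(rsid) {
  p <- panel()
  s <- p[p$rsid == rsid, ]
  c(paste(s$allele1, s$allele1, sep = "/"),
    paste(sort(c(s$allele1, s$allele2)), collapse = "/"),
    paste(s$allele2, s$allele2, sep = "/"))
}

# All complete genotype vectors over the SNPs of one trait
# (3^5 = 243 for eye, 3^6 = 729 for skin), as a genotype frame.
enumerate_trait <- function(trait) {
  rsids <- panel_rsids(trait)
  grid <- do.call(expand.grid,
                  c(setNames(lapply(rsids, geno_levels), rsids),
                    stringsAsFactors = FALSE))
  g <- empty_genotypes(sprintf("V%04d", seq_len(nrow(grid))))
  for (r in rsids) g[[r]] <- grid[[r]]
  g
}

# Random valid cohort with missingness, for round-trip properties.
random_cohort <- function(n, seed, miss = 0.15) {
  set.seed(seed)
  g <- empty_genotypes(sprintf("R%03d", seq_len(n)))
  for (r in panel_rsids()) {
    lv <- geno_levels(r)
    g[[r]] <- ifelse(runif(n) < miss, NA_character_,
                     sample(lv, n, replace = TRUE))
  }
  g
}
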