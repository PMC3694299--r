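# Synthetic population-stratified cohorts. Genotypes are drawn per SNP
# under Hardy-Weinberg proportions (p^2, 2pq, q^2) from per-population
# allele frequencies, independently across SNPs (no LD -- the prediction
# rules treat SNPs independently). Phenotype truth is derived from the
# predictions themselves, with a controlled discordance rate epsilon, so
# that expected error rates are analytically known.

#' Packaged default allele frequencies
#'
#' Synthetic per-population frequencies of the trait-associated allele
#' (`allele1` in [panel()]) used by the simulator when no frequencies are
#' supplied. Plausible magnitudes, not estimates from any cohort.
#'
#' @return Data frame: `population` plus one column per rsID.
#' @export
default_allele_freqs <- function() {
  path <- system.file("extdata", "default_allele_freqs.tsv",
                      package = "plex8", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' @param n_samples Number of samples to draw.
#' @param population_mix Named numeric weights over the population codes
#'   (AA, SA, EA, E, mix); normalized to sum to 1. Defaults to the
#'   published training-set composition (43/27/35/555/143 of 803).
#' @param allele_freqs Data frame as [default_allele_freqs()]: frequency
#'   of the trait-associated allele per population and SNP, each in
#'   \[0, 1\].
#' @param discordance Probability epsilon that a sample's true bin is
#'   replaced by a bin incompatible with its prediction (simulated
#'   prediction error).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return List of class `plex8_config`.
#' @export
cohort_config <- function(n_samples = 1000,
                          population_mix = c(AA = 43, SA = 27, EA = 35,
                                             E = 555, mix = 143) / 803,
                          allele_freqs = default_allele_freqs(),
                          discordance = 0.02,
                          seed = 1L) {
  stopifnot(n_samples >= 1, discordance >= 0, discordance <= 1)
  if (is.null(names(population_mix)) ||
      !all(names(population_mix) %in% POPULATIONS)) {
    stop("population_mix must be named with codes in: ",
         paste(POPULATIONS, collapse = ", "), call. = FALSE)
  }
  if (any(population_mix < 0) || sum(population_mix) <= 0) {
    stop("population_mix weights must be nonnegative and not all zero",
         call. = FALSE)
  }
  need <- c("population", panel_rsids())
  if (!all(need %in% names(allele_freqs))) {
    stop("allele_freqs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  f <- as.matrix(allele_freqs[, panel_rsids()])
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) {
    stop("allele frequencies must be in [0, 1]", call. = FALSE)
  }
  if (!all(names(population_mix) %in% allele_freqs$population)) {
    stop("allele_freqs lacks a row for some population in the mix",
         call. = FALSE)
  }
  cfg <- list(n_samples = as.integer(n_samples),
              population_mix = population_mix / sum(population_mix),
              allele_freqs = allele_freqs,
              discordance = discordance,
              seed = as.integer(seed))
  class(cfg) <- "plex8_config"
  cfg
}

#' Load a cohort configuration from YAML
#'
#' Expected keys: `n_samples`, `discordance`, `seed`, optional
#' `population_mix` (map code -> weight) and `allele_freqs` (map
#' population -> map rsid -> frequency); omitted keys fall back to the
#' [cohort_config()] defaults.
#'
#' @param path YAML file path.
#' @return `plex8_config` list.
#' @export
load_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_samples", "discordance", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$population_mix)) {
    args$population_mix <- unlist(y$population_mix)
  }
  if (!is.null(y$allele_freqs)) {
    af <- do.call(rbind, lapply(names(y$allele_freqs), function(p) {
      row <- as.data.frame(y$allele_freqs[[p]])
      cbind(population = p, row)
    }))
    args$allele_freqs <- af
  }
  do.call(cohort_config, args)
}

hw_genotypes <- function(n, p, a1, a2) {
  # counts of allele1 per diploid sample under HW: Binomial(2, p)
  k <- stats::rbinom(n, 2L, p)
  het <- format_genotype(a1, a2)
  c(paste0(a2, "/", a2), het, paste0(a1, "/", a1))[k + 1L]
}

sample_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  pops <- sample(names(cfg$population_mix), n, replace = TRUE,
                 prob = cfg$population_mix)
  geno <- empty_genotypes(ids)
  p <- panel()
  af <- cfg$allele_freqs
  for (r in panel_rsids()) {
    snp <- p[p$rsid == r, ]
    freq <- af[[r]][match(pops, af$population)]
    geno[[r]] <- vapply(seq_len(n), function(i) {
      hw_genotypes(1L, freq[i], snp$allele1, snp$allele2)
    }, character(1))
  }
  list(genotypes = geno,
       populations = data.frame(sample_id = ids, population = pops,
                                stringsAsFactors = FALSE))
}

#' Draw a genotype cohort
#'
#' Samples `n_samples` individuals: population from the configured mix,
#' then an unordered genotype per SNP under Hardy-Weinberg proportions
#' from that population's allele frequency. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `genotypes` (genotype data frame) and `populations`
#'   (data frame `sample_id`, `population`).
#' @export
sample_cohort <- function(cfg) {
  set.seed(cfg$seed)
  sample_cohort_impl(cfg)
}

pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

assign_phenotypes_impl <- function(cohort, discordance) {
  pred <- predict_cohort(cohort$genotypes, mode = "8plex")
  n <- nrow(pred)
  eye_bin <- character(n)
  skin_bin <- character(n)
  for (i in seq_len(n)) {
    eset <- EYE_COMPAT[[pred$eye_label[i]]]
    sset <- SKIN_COMPAT[[pred$skin_label[i]]]
    eye_bin[i] <- pick1(eset)
    skin_bin[i] <- pick1(sset)
    if (discordance > 0) {
      if (stats::runif(1) < discordance) {
        bad <- setdiff(EYE_BINS, eset)
        if (length(bad)) eye_bin[i] <- pick1(bad)
      }
      if (stats::runif(1) < discordance) {
        bad <- setdiff(SKIN_BINS, sset)
        if (length(bad)) skin_bin[i] <- pick1(bad)
      }
    }
  }
  data.frame(sample_id = pred$sample_id,
             population = cohort$populations$population[
               match(pred$sample_id, cohort$populations$sample_id)],
             eye_bin = eye_bin, skin_bin = skin_bin,
             stringsAsFactors = FALSE)
}

#' Assign phenotype truth to a simulated cohort
#'
#' Runs both predictors on each sample; positive predictions fix the true
#' bin, negative or inconclusive ones draw uniformly from the compatible
#' bins. With probability `discordance` the bin is then replaced by a
#' uniformly drawn *incompatible* bin (no-op for non-calls, whose
#' compatible set is everything).
#'
#' @param cohort Output of [sample_cohort()].
#' @param discordance Discordance rate epsilon in \[0, 1\].
#' @param seed Integer seed, or `NULL` to continue the current RNG
#'   stream.
#' @return Phenotype data frame (`sample_id`, `population`, `eye_bin`,
#'   `skin_bin`).
#' @export
assign_phenotypes <- function(cohort, discordance = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assign_phenotypes_impl(cohort, discordance)
}

#' Simulate a full genotype + phenotype cohort
#'
#' [sample_cohort()] followed by [assign_phenotypes()] under a single
#' seeded RNG stream: identical configs give identical cohorts.
#'
#' @param cfg A [cohort_config()].
#' @return List with `genotypes`, `phenotypes`, `config`.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  cohort <- sample_cohort_impl(cfg)
  pheno <- assign_phenotypes_impl(cohort, cfg$discordance)
  list(genotypes = cohort$genotypes, phenotypes = pheno, config = cfg)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `genotypes.tsv`, `phenotypes.tsv`, a `manifest.yaml` recording
#' the full configuration (including seed and discordance), and
#' optionally `cohort.vcf`. All files round-trip through the package
#' readers.
#'
#' @param cfg A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write a VCF copy of the genotypes?
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_cohort <- function(cfg, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(cfg)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  write_genotype_table(sim$genotypes, paths[["genotypes"]])
  write_phenotype_table(sim$phenotypes, paths[["phenotypes"]])
  af <- cfg$allele_freqs
  manifest <- list(
    n_samples = cfg$n_samples,
    population_mix = as.list(cfg$population_mix),
    discordance = cfg$discordance,
    seed = cfg$seed,
    allele_freqs = stats::setNames(lapply(seq_len(nrow(af)), function(i) {
      as.list(af[i, panel_rsids()])
    }), af$population))
  yaml::write_yaml(manifest, paths[["manifest"]])
  if (vcf) {
    paths <- c(paths, vcf = file.path(dir, "cohort.vcf"))
    write_vcf(sim$genotypes, paths[["vcf"]])
  }
  invisible(paths)
}
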