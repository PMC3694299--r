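#' @importFrom utils read.delim write.table
NULL

# closed vocabularies used throughout
EYE_BINS  <- c("blue", "green", "brown")
SKIN_BINS <- c("light", "medium", "dark")
POPULATIONS <- c("AA", "SA", "EA", "E", "mix")
MISSING_TOKENS <- c("NA", ".", "./.", ".|.", "")

#' Build an empty genotype table
#'
#' The cohort container used throughout the package: one row per sample,
#' a `sample_id` column, and one character column per panel rsID holding a
#' canonical genotype string (`"A/G"`) or `NA` for a missing call.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @return Genotype data frame with all calls missing.
#' @export
empty_genotypes <- function(sample_ids) {
  rsids <- panel_rsids()
  g <- data.frame(sample_id = as.character(sample_ids),
                  stringsAsFactors = FALSE)
  for (r in rsids) g[[r]] <- NA_character_
  g
}

validate_genotypes <- function(geno) {
  if (!is.data.frame(geno) || !"sample_id" %in% names(geno)) {
    stop("genotype table must be a data frame with a 'sample_id' column",
         call. = FALSE)
  }
  extra <- setdiff(names(geno), c("sample_id", panel_rsids()))
  if (length(extra)) {
    stop("unknown rsID column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(geno$sample_id)) {
    stop("duplicated sample_id in genotype table", call. = FALSE)
  }
  invisible(geno)
}

#' Fetch one sample's genotype at one SNP
#' @param geno Genotype data frame.
#' @param sample_id,rsid Identifiers.
#' @return Genotype string or `NA`.
#' @keywords internal
get_genotype <- function(geno, sample_id, rsid) {
  if (!rsid %in% names(geno)) return(NA_character_)
  geno[[rsid]][match(sample_id, geno$sample_id)]
}

#' Read a genotype TSV
#'
#' Expects a tab-separated file with a `sample_id` header column followed by
#' one column per panel rsID. Cells hold genotypes like `A/G` (allele order
#' irrelevant) or a missing token (`NA`, `.`, `./.`). Panel SNPs without a
#' column are returned as missing, with a warning. Non-panel columns are an
#' error. All calls are passed through [normalize_genotype()].
#'
#' @param path Path to the TSV file.
#' @return Genotype data frame (see [empty_genotypes()]).
#' @seealso [write_genotype_table()], [read_vcf()]
#' @export
read_genotype_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (!"sample_id" %in% names(raw)) {
    stop("genotype table ", path, " lacks a 'sample_id' column",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), c("sample_id", panel_rsids()))
  if (length(unknown)) {
    stop("unknown rsID column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(panel_rsids(), names(raw))
  if (length(absent)) {
    warning("panel SNP(s) absent from ", path, ": ",
            paste(absent, collapse = ", "), "; treated as missing",
            call. = FALSE)
  }
  geno <- empty_genotypes(raw$sample_id)
  p <- panel()
  for (r in intersect(panel_rsids(), names(raw))) {
    snp <- p[p$rsid == r, ]
    geno[[r]] <- vapply(seq_len(nrow(raw)), function(i) {
      cell <- trimws(raw[[r]][i])
      if (cell %in% MISSING_TOKENS) return(NA_character_)
      tryCatch(normalize_genotype(cell, snp), error = function(e) {
        stop("invalid genotype '", cell, "' for sample ",
             raw$sample_id[i], " at ", r, ": ", conditionMessage(e),
             call. = FALSE)
      })
    }, character(1))
  }
  validate_genotypes(geno)
}

#' Write a genotype TSV
#'
#' Inverse of [read_genotype_table()]; missing calls are written as `NA`.
#'
#' @param geno Genotype data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(geno, path) {
  validate_genotypes(geno)
  out <- geno[, c("sample_id", intersect(panel_rsids(), names(geno)))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read panel genotypes from a VCF
#'
#' Reads a VCF (v4.2, `GT` genotype field) and extracts the panel sites.
#' Records are matched to the panel primarily by the `ID` column rsID; an
#' optional `pos_map` (data frame with columns `rsid`, `chrom`, `pos`,
#' 1-based coordinates on a declared build) provides a chrom+position
#' fallback for files without rsIDs. Panel SNPs with no matching record,
#' half-calls and `./.` are missing. Phase is ignored.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param pos_map Optional position lookup data frame (see above).
#' @return Genotype data frame, one row per VCF sample.
#' @export
read_vcf <- function(path, pos_map = NULL) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF ", path, " has no GT genotype field",
                        call. = FALSE)
  samples <- colnames(gt)
  if (length(samples) == 0L) stop("VCF ", path, " has no sample columns",
                                  call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(seq_along(rr), function(i) {
    a <- rr$ALT[[i]]
    if (length(a) == 0L) NA_character_ else as.character(a[1])
  }, character(1))
  n_alt <- lengths(rr$ALT)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  idx <- match(panel_rsids(), ids)
  if (!is.null(pos_map)) {
    stopifnot(all(c("rsid", "chrom", "pos") %in% names(pos_map)))
    key_vcf <- paste(chrom, pos)
    key_map <- paste(pos_map$chrom, pos_map$pos)
    for (j in which(is.na(idx))) {
      k <- match(panel_rsids()[j], pos_map$rsid)
      if (!is.na(k)) idx[j] <- match(key_map[k], key_vcf)
    }
  }

  p <- panel()
  geno <- empty_genotypes(samples)
  for (j in seq_along(panel_rsids())) {
    i <- idx[j]
    if (is.na(i)) next
    r <- panel_rsids()[j]
    if (n_alt[i] > 1L) {
      stop("panel site ", r, " in ", path, " is not biallelic",
           call. = FALSE)
    }
    alleles <- c(ref[i], alt[i])  # GT index 0 = REF, 1 = ALT
    snp <- p[p$rsid == r, ]
    geno[[r]] <- vapply(seq_along(samples), function(s) {
      g <- gsub("|", "/", gt[i, s], fixed = TRUE)
      parts <- strsplit(g, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L || any(parts == ".")) return(NA_character_)
      ai <- as.integer(parts) + 1L
      if (any(is.na(ai)) || any(ai < 1L) || any(ai > 2L) ||
          any(is.na(alleles[ai]))) {
        stop("unresolvable GT '", gt[i, s], "' for sample ", samples[s],
             " at ", r, call. = FALSE)
      }
      tryCatch(normalize_genotype(alleles[ai], snp), error = function(e) {
        stop("sample ", samples[s], " at ", r, ": ", conditionMessage(e),
             call. = FALSE)
      })
    }, character(1))
  }
  geno
}

#' Write a minimal VCF v4.2 with panel genotypes
#'
#' Emits one biallelic record per panel SNP (rsID in the ID column,
#' placeholder contig/positions in panel order) with a GT-only FORMAT.
#' The file round-trips through [read_vcf()]. Sites where every sample is
#' missing are written as `./.`.
#'
#' @param geno Genotype data frame.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  validate_genotypes(geno)
  p <- panel()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=plex8",
    "##contig=<ID=panel,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", geno$sample_id), collapse = "\t"))
  rows <- vapply(seq_len(nrow(p)), function(i) {
    r <- p$rsid[i]
    ref <- p$allele2[i]; alt <- p$allele1[i]
    gts <- vapply(geno[[r]], function(g) {
      if (is.na(g)) return("./.")
      a <- split_genotype(g)
      paste(sort(match(a, c(ref, alt)) - 1L), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    paste(c("panel", i * 100L, r, ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phenotype TSV
#'
#' Tab-separated file with columns `sample_id`, `population`, `eye_bin`,
#' `skin_bin`. Bins may be empty/`NA` per row; non-empty tokens are
#' validated against the closed vocabularies (eye: blue/green/brown; skin:
#' light/medium/dark; population: AA/SA/EA/E/mix).
#'
#' @param path Path to the TSV file.
#' @return Data frame of phenotype records.
#' @export
read_phenotype_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("sample_id", "population", "eye_bin", "skin_bin")
  if (!all(need %in% names(raw))) {
    stop("phenotype table ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  clean <- function(x) ifelse(trimws(x) %in% MISSING_TOKENS, NA_character_,
                              trimws(x))
  out <- data.frame(sample_id = raw$sample_id,
                    population = clean(raw$population),
                    eye_bin = clean(raw$eye_bin),
                    skin_bin = clean(raw$skin_bin),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (is.na(out$population[i]) || !out$population[i] %in% POPULATIONS) {
      stop("row ", i, " (", out$sample_id[i], "): unknown population '",
           raw$population[i], "'", call. = FALSE)
    }
    if (!is.na(out$eye_bin[i]) && !out$eye_bin[i] %in% EYE_BINS) {
      stop("row ", i, " (", out$sample_id[i], "): unknown eye bin '",
           out$eye_bin[i], "'", call. = FALSE)
    }
    if (!is.na(out$skin_bin[i]) && !out$skin_bin[i] %in% SKIN_BINS) {
      stop("row ", i, " (", out$sample_id[i], "): unknown skin bin '",
           out$skin_bin[i], "'", call. = FALSE)
    }
  }
  out
}

#' Write a phenotype TSV
#' @param pheno Phenotype data frame (as from [read_phenotype_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pheno, path) {
  write.table(pheno[, c("sample_id", "population", "eye_bin", "skin_bin")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
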