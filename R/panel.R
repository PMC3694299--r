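#' The 8-SNP pigmentation panel
#'
#' Returns the definition of the eight SNPs used by the predictor: dbSNP
#' rsID, gene symbol, the two canonical assay alleles, which trait(s) each
#' SNP informs, and whether the allele pair is strand-ambiguous (C/G or A/T,
#' i.e. identical to its own reverse complement).
#'
#' Five SNPs are used for eye color (rs12913832, rs16891982, rs6119471,
#' rs12203592, rs12896399), six for skin color (rs12913832, rs16891982,
#' rs6119471, rs1426654, rs885479, rs1545397); three are shared.
#'
#' @return A data frame with one row per SNP and columns `rsid`, `gene`,
#'   `allele1`, `allele2`, `used_for_eye`, `used_for_skin`,
#'   `strand_ambiguous`. `allele1` is the trait-associated allele named in
#'   the prediction rules.
#' @examples
#' panel()
#' @export
panel <- function() {
  p <- data.frame(
    rsid = c("rs12913832", "rs1545397", "rs16891982", "rs1426654",
             "rs885479", "rs6119471", "rs12203592", "rs12896399"),
    gene = c("HERC2", "OCA2", "SLC45A2", "SLC24A5",
             "MC1R", "ASIP", "IRF4", "SLC24A4"),
    allele1 = c("G", "T", "G", "A", "A", "G", "T", "T"),
    allele2 = c("A", "A", "C", "G", "G", "C", "C", "G"),
    used_for_eye  = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    used_for_skin = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  p$strand_ambiguous <- unname(comp[p$allele1]) == p$allele2
  p
}

#' Panel rsIDs
#'
#' @param trait `"all"` (default), `"eye"` or `"skin"`: restrict to the SNPs
#'   used for that trait.
#' @return Character vector of rsIDs in panel order.
#' @export
panel_rsids <- function(trait = c("all", "eye", "skin")) {
  trait <- match.arg(trait)
  p <- panel()
  switch(trait,
         all  = p$rsid,
         eye  = p$rsid[p$used_for_eye],
         skin = p$rsid[p$used_for_skin])
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Format an unordered allele pair as a canonical genotype string
#'
#' Alleles are sorted so that `"G/A"` and `"A/G"` produce the same string.
#' @param a1,a2 Single-character alleles.
#' @return Genotype string such as `"A/G"`.
#' @keywords internal
format_genotype <- function(a1, a2) {
  paste(sort(c(a1, a2)), collapse = "/")
}

#' Split a genotype string into its two alleles
#' @param g Genotype string like `"A/G"`, or `NA`.
#' @return Character vector of length 2, or `NULL` for missing.
#' @keywords internal
split_genotype <- function(g) {
  if (is.na(g)) return(NULL)
  strsplit(g, "/", fixed = TRUE)[[1]]
}

#' Normalize a raw genotype call against the panel definition
#'
#' Accepts the call if both alleles belong to the SNP's canonical pair.
#' If they do not, and the SNP is *not* strand-ambiguous, and the
#' base-complemented alleles do belong to the pair, the complemented
#' genotype is accepted with a warning (a likely opposite-strand report).
#' Strand-ambiguous SNPs (C/G or A/T pairs: rs16891982, rs6119471,
#' rs1545397) are never flipped because a strand error there is
#' undetectable from allele labels; out-of-pair alleles at those sites are
#' an error.
#'
#' @param raw Character vector of two alleles (any order), a genotype
#'   string like `"T/C"`, or `NA` for a missing call.
#' @param snp Either an rsID string or a single row of [panel()].
#' @return Canonical genotype string (alleles sorted), or `NA_character_`
#'   for missing input. Idempotent on its own output.
#' @examples
#' normalize_genotype(c("G", "A"), "rs12913832")   # "A/G"
#' suppressWarnings(normalize_genotype("T/C", "rs12913832"))  # flipped to "A/G"
#' @export
normalize_genotype <- function(raw, snp) {
  if (is.character(snp) && length(snp) == 1L) {
    p <- panel()
    i <- match(snp, p$rsid)
    if (is.na(i)) stop("unknown panel rsID: ", snp, call. = FALSE)
    snp <- p[i, ]
  }
  if (length(raw) == 1L && is.na(raw)) return(NA_character_)
  if (length(raw) == 1L) raw <- split_genotype(raw)
  if (length(raw) != 2L) {
    stop("genotype for ", snp$rsid, " must have two alleles", call. = FALSE)
  }
  raw <- toupper(raw)
  if (!all(raw %in% c("A", "C", "G", "T"))) {
    stop("invalid allele(s) '", paste(raw, collapse = "/"), "' at ",
         snp$rsid, call. = FALSE)
  }
  pair <- c(snp$allele1, snp$allele2)
  if (all(raw %in% pair)) return(format_genotype(raw[1], raw[2]))
  flipped <- unname(.complement[raw])
  if (!snp$strand_ambiguous && all(flipped %in% pair)) {
    warning("alleles ", paste(raw, collapse = "/"), " at ", snp$rsid,
            " look like the opposite strand; complemented to ",
            format_genotype(flipped[1], flipped[2]), call. = FALSE)
    return(format_genotype(flipped[1], flipped[2]))
  }
  if (snp$strand_ambiguous && all(flipped %in% pair)) {
    # can only happen for non-symmetric raw pairs at an ambiguous SNP
    stop("alleles ", paste(raw, collapse = "/"), " at strand-ambiguous ",
         snp$rsid, " cannot be reconciled; refusing to strand-flip",
         call. = FALSE)
  }
  stop("alleles ", paste(raw, collapse = "/"),
       " are irreconcilable with panel pair ", snp$allele1, "/",
       snp$allele2, " at ", snp$rsid, call. = FALSE)
}
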