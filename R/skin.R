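# Skin-color elimination predictor. Uses only homozygous genotypes.
#
# Five light markers:  rs12913832 G/G, rs16891982 G/G, rs1426654 A/A,
#                      rs1545397 T/T, rs885479 A/A
# One dark marker:     rs6119471 G/G
#
#   light     : rs12913832 G/G and rs16891982 G/G and rs1426654 A/A
#   not_dark  : at least two of the five light markers
#   not_light : the dark marker, with no lighter-branch rule firing
#   conflict  : a lighter-branch rule and the dark marker both hold
#   inconclusive : nothing holds (e.g. all-heterozygous samples)

SKIN_LABELS <- c("light", "not_dark", "not_light", "conflict",
                 "inconclusive")
SKIN_LIGHT_MARKERS <- c(rs12913832 = "G/G", rs16891982 = "G/G",
                        rs1426654 = "A/A", rs1545397 = "T/T",
                        rs885479 = "A/A")

skin_one <- function(calls) {
  present <- vapply(names(SKIN_LIGHT_MARKERS), function(r) {
    !is.na(calls[[r]]) && calls[[r]] == SKIN_LIGHT_MARKERS[[r]]
  }, logical(1))
  dark <- !is.na(calls$rs6119471) && calls$rs6119471 == "G/G"
  n_light <- sum(present)
  light <- all(present[c("rs12913832", "rs16891982", "rs1426654")])
  lighter <- light || n_light >= 2L
  fired <- names(SKIN_LIGHT_MARKERS)[present]
  if (dark) fired <- c(fired, "rs6119471")
  label <-
    if (lighter && dark) "conflict"
    else if (light) "light"
    else if (n_light >= 2L) "not_dark"
    else if (dark) "not_light"
    else "inconclusive"
  list(label = label, fired = fired, n_light = n_light)
}

#' Predict skin color (homozygote elimination)
#'
#' Classifies each sample as `light`, `not_dark`, `not_light`,
#' `inconclusive` (no homozygous marker present -- possible because the
#' predictor uses only homozygous genotypes) or `conflict` (both a
#' lighter-branch rule and the dark marker rs6119471 G/G hold; no
#' prediction is issued and both signals are reported). Missing genotypes
#' simply fail their conditions.
#'
#' @param geno Genotype data frame (see [read_genotype_table()]).
#' @return Data frame with columns `sample_id`, `skin_label`,
#'   `fired_rules` (semicolon-joined marker rsIDs), `light_marker_count`
#'   (0-5, how many of the five light-associated homozygous genotypes are
#'   present).
#' @examples
#' g <- empty_genotypes("S1")
#' g$rs12913832 <- "G/G"; g$rs16891982 <- "G/G"; g$rs1426654 <- "A/A"
#' predict_skin(g)   # light
#' @export
predict_skin <- function(geno) {
  validate_genotypes(geno)
  res <- lapply(seq_len(nrow(geno)), function(i) skin_one(geno[i, ]))
  data.frame(
    sample_id = geno$sample_id,
    skin_label = vapply(res, `[[`, character(1), "label"),
    fired_rules = vapply(res, function(r) paste(r$fired, collapse = ";"),
                         character(1)),
    light_marker_count = vapply(res, `[[`, integer(1), "n_light"),
    stringsAsFactors = FALSE
  )
}

#' Predict both traits for a cohort
#'
#' Convenience wrapper joining [predict_eye()] and [predict_skin()] output
#' on `sample_id`.
#'
#' @inheritParams predict_eye
#' @return Data frame with both traits' prediction columns.
#' @export
predict_cohort <- function(geno, mode = c("8plex", "7plex")) {
  eye <- predict_eye(geno, mode)
  skin <- predict_skin(geno)
  names(eye)[names(eye) == "fired_rules"] <- "eye_rules"
  names(eye)[names(eye) == "conflict"] <- "eye_conflict"
  names(skin)[names(skin) == "fired_rules"] <- "skin_rules"
  merge(eye, skin, by = "sample_id", sort = FALSE)
}
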