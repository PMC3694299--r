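# Eye-color decision procedure.
#
# Step 1: rs12913832 (HERC2) sets the baseline -- A/A or A/G excludes blue
# ("not_blue"), G/G excludes brown ("not_brown") -- and three auxiliary
# SNPs can refine it to a positive color:
#   brown: rs12913832 in {A/A, A/G} and (rs6119471 G/G or rs16891982 C/C)
#   green: (rs12913832 G/G and rs16891982 C/C) or
#          (rs12913832 A/G and rs12203592 T/T)
#   blue : rs12913832 G/G and rs12203592 T/T
# Step 2 (8-plex only) revisits samples left with a negative label:
#   rs12913832 G/G + rs12896399 T/T -> blue
#   rs12913832 A/A + rs12896399 G/G -> brown
# Heterozygous rs12913832 samples are never touched by step 2.

EYE_LABELS <- c("brown", "green", "blue", "not_blue", "not_brown", "no_call")
EYE_POSITIVE <- c("brown", "green", "blue")

eye_step1_one <- function(b, g16891982, g6119471, g12203592) {
  if (is.na(b)) {
    return(list(label = "no_call", fired = character(0), conflict = FALSE))
  }
  baseline <- if (b == "G/G") "not_brown" else "not_blue"
  fired <- character(0)
  if (b %in% c("A/A", "A/G") &&
      ((!is.na(g6119471) && g6119471 == "G/G") ||
       (!is.na(g16891982) && g16891982 == "C/C"))) {
    fired <- c(fired, "brown")
  }
  if ((b == "G/G" && !is.na(g16891982) && g16891982 == "C/C") ||
      (b == "A/G" && !is.na(g12203592) && g12203592 == "T/T")) {
    fired <- c(fired, "green")
  }
  if (b == "G/G" && !is.na(g12203592) && g12203592 == "T/T") {
    fired <- c(fired, "blue")
  }
  if (length(fired) == 0L) {
    return(list(label = baseline, fired = fired, conflict = FALSE))
  }
  # fixed precedence brown > green > blue; all matches kept in `fired`
  list(label = fired[1], fired = fired, conflict = length(fired) > 1L)
}

#' Predict eye color, step 1 only
#'
#' Applies the first step of the decision procedure to every sample: the
#' rs12913832 baseline (not_blue / not_brown / no_call) refined to brown,
#' green or blue where the auxiliary homozygous genotypes are present.
#' When more than one positive rule matches, the label follows the fixed
#' precedence brown > green > blue, `conflict` is set, and all matching
#' rules are listed in `fired_rules`.
#'
#' @param geno Genotype data frame (see [read_genotype_table()]).
#' @return Data frame with columns `sample_id`, `eye_label`, `eye_step`
#'   (always 1), `fired_rules` (semicolon-joined), `conflict`.
#' @export
predict_eye_step1 <- function(geno) {
  validate_genotypes(geno)
  res <- lapply(seq_len(nrow(geno)), function(i) {
    eye_step1_one(geno$rs12913832[i], geno$rs16891982[i],
                  geno$rs6119471[i], geno$rs12203592[i])
  })
  data.frame(
    sample_id = geno$sample_id,
    eye_label = vapply(res, `[[`, character(1), "label"),
    eye_step = 1L,
    fired_rules = vapply(res, function(r) paste(r$fired, collapse = ";"),
                         character(1)),
    conflict = vapply(res, `[[`, logical(1), "conflict"),
    stringsAsFactors = FALSE
  )
}

#' Predict eye color (two-step 8-plex procedure)
#'
#' Runs step 1 and, in `"8plex"` mode, applies step 2 to samples whose
#' step-1 label is negative: rs12913832 G/G homozygotes with rs12896399
#' T/T are upgraded not_brown -> blue, rs12913832 A/A homozygotes with
#' rs12896399 G/G are upgraded not_blue -> brown. `"7plex"` mode returns
#' the step-1 result unchanged (legacy behavior without rs12896399).
#'
#' @param geno Genotype data frame.
#' @param mode `"8plex"` (default) or `"7plex"`.
#' @return Data frame as [predict_eye_step1()]; `eye_step` is 2 for
#'   samples whose final label was produced by step 2.
#' @examples
#' g <- empty_genotypes("S1")
#' g$rs12913832 <- "G/G"; g$rs12896399 <- "T/T"
#' predict_eye(g)          # blue at step 2
#' @export
predict_eye <- function(geno, mode = c("8plex", "7plex")) {
  mode <- match.arg(mode)
  out <- predict_eye_step1(geno)
  if (mode == "7plex") return(out)
  for (i in seq_len(nrow(out))) {
    if (!out$eye_label[i] %in% c("not_blue", "not_brown")) next
    b <- geno$rs12913832[i]
    s4 <- geno$rs12896399[i]
    if (is.na(b) || is.na(s4)) next
    if (b == "G/G" && s4 == "T/T") {
      out$eye_label[i] <- "blue"
      out$eye_step[i] <- 2L
      out$fired_rules[i] <- "step2_blue"
    } else if (b == "A/A" && s4 == "G/G") {
      out$eye_label[i] <- "brown"
      out$eye_step[i] <- 2L
      out$fired_rules[i] <- "step2_brown"
    }
  }
  out
}
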