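# Rule-based qualitative affinity prediction for SH3 x PRM pairs.
#
# Affinity is categorical -- the mutational evidence behind the rule table
# is class-level (HIGH ~0.3-10 uM, TYPICAL ~20-200 uM, NONE unbound) -- and
# each prediction carries the rules it applied as human-readable rationale.

AFFINITY_BANDS <- list(
  HIGH    = c(0.3, 10),    # measured AGS/Px+P pairs span ~0.3-8 uM
  TYPICAL = c(20, 200),    # canonical class-II SH3/PRM range
  NONE    = c(NA_real_, NA_real_)
)

.downgrade <- function(label) {
  switch(label, HIGH = "TYPICAL", TYPICAL = "NONE", NONE = "NONE")
}

#' Describe a PRM (or PRM variant) for pair prediction
#'
#' A lightweight motif description used by [predict_pair()], convenient for
#' expressing point mutants of a motif (position-2/5 substitutions, anchor
#' proline substitutions) without building a full sequence.
#'
#' @param pos2,pos5 single residue codes at register positions 2 and 5.
#' @param p0_present,p3_present logicals; `FALSE` marks an anchor proline
#'   substituted away (position 0 / position 3).
#' @param prm_class optional explicit class; by default inferred from the
#'   residues (`PX_PLUS_P` when both pos2 and pos5 are K/R, `CLASS_II` when
#'   only pos5 is, otherwise `NONE`). Pass `"CLASS_I"` for the mirror
#'   orientation.
#' @param id identifier used in prediction tables.
#' @return List of class `prm_description`.
#' @examples
#' prm_description(pos2 = "K", pos5 = "R")                 # Px+P motif
#' prm_description(pos2 = "K", pos5 = "R", p3_present = FALSE)  # APC-like
#' @export
prm_description <- function(pos2, pos5, p0_present = TRUE, p3_present = TRUE,
                            prm_class = NULL, id = "prm") {
  pos2 <- toupper(pos2); pos5 <- toupper(pos5)
  if (is.null(prm_class)) {
    prm_class <- if (pos5 %in% c("K", "R")) {
      if (pos2 %in% c("K", "R")) "PX_PLUS_P" else "CLASS_II"
    } else "NONE"
  }
  structure(list(id = id, prm_class = prm_class, pos2 = pos2, pos5 = pos5,
                 p0_present = p0_present, p3_present = p3_present),
            class = "prm_description")
}

#' @export
as_prm_description <- function(x, ...) UseMethod("as_prm_description")

#' @export
as_prm_description.prm_description <- function(x, ...) x

#' @export
as_prm_description.prm_match <- function(x, ...) {
  prm_description(x$pos2_residue, x$pos5_residue,
                  p0_present = TRUE, p3_present = !isTRUE(x$p3_substituted),
                  prm_class = if (x$prm_class == "CLASS_I") "CLASS_I" else NULL,
                  id = x$protein_id)
}

#' Label an SH3 domain with a known class
#'
#' Minimal `sh3_classification` carrying only an id and class label, for
#' building prediction matrices without running the alignment-based
#' classifier.
#'
#' @param id domain identifier.
#' @param sh3_class `"AGS"`, `"CANONICAL"` or `"UNKNOWN"`.
#' @return An object of class `sh3_classification`.
#' @export
sh3_class_label <- function(id, sh3_class) {
  sh3_class <- match.arg(toupper(sh3_class), c("AGS", "CANONICAL", "UNKNOWN"))
  structure(list(id = id, sh3_class = sh3_class), class = "sh3_classification")
}

.sh3_class_of <- function(sh3) {
  if (inherits(sh3, "sh3_classification")) return(sh3$sh3_class)
  if (is.character(sh3) && length(sh3) == 1L) {
    lab <- toupper(sh3)
    if (!(lab %in% c("AGS", "CANONICAL", "UNKNOWN")))
      stop("unknown SH3 class label '", sh3,
           "'; use AGS, CANONICAL or UNKNOWN, or an sh3_classification")
    return(lab)
  }
  stop("sh3 must be an sh3_classification or a class label string")
}

.sh3_id_of <- function(sh3) {
  if (inherits(sh3, "sh3_classification")) sh3$id else as.character(sh3)
}

#' Predict the qualitative affinity class of an SH3 x PRM pair
#'
#' Applies the rule table in fixed order:
#' \describe{
#'   \item{R1}{acidic residue (D/E) at position 5 -> NONE (charge reversal
#'     at the canonical anchor abolishes binding).}
#'   \item{R2}{acidic residue at position 2 paired with an AGS domain ->
#'     NONE (charge reversal inside the acidic pocket).}
#'   \item{R3}{absent anchor proline (position 0 or 3) downgrades the final
#'     label one level per missing anchor (HIGH -> TYPICAL -> NONE).}
#'   \item{R4}{AGS x Px+P -> HIGH; annotated "enhanced" when position 2 is
#'     arginine.}
#'   \item{R5}{AGS x class-II (non-positive position 2) -> TYPICAL.}
#'   \item{R6}{canonical SH3 x (class-II or Px+P) -> TYPICAL.}
#'   \item{R7}{motif of class NONE -> NONE.}
#' }
#' Class-I motifs map to TYPICAL with either SH3 type (canonical-orientation
#' recognition; annotated "untested by direct evidence"), as is the canonical-SH3 x
#' position-2-acidic cell.
#'
#' @param sh3 an `sh3_classification` or one of `"AGS"`, `"CANONICAL"`,
#'   `"UNKNOWN"`.
#' @param prm a `prm_match`, or a [prm_description()].
#' @return List of class `pair_prediction`: `sh3_id`, `prm_id`,
#'   `sh3_class`, `prm_class`, `affinity` (label), `kd_band_uM`,
#'   `modifiers`, `rationale`, `status`.
#' @export
predict_pair <- function(sh3, prm) {
  sh3_class <- .sh3_class_of(sh3)
  if (sh3_class == "UNKNOWN") {
    return(structure(list(
      sh3_id = .sh3_id_of(sh3), prm_id = NA_character_,
      sh3_class = "UNKNOWN", prm_class = NA_character_,
      affinity = NA_character_, kd_band_uM = c(NA_real_, NA_real_),
      modifiers = character(0),
      rationale = "SH3 domain unclassifiable (diagnostic sites unmapped)",
      status = "unclassifiable"), class = "pair_prediction"))
  }
  d <- as_prm_description(prm)
  acidic <- c("D", "E")
  modifiers <- character(0)
  rationale <- character(0)
  label <- NULL

  if (!(d$pos5 %in% c("K", "R")) && d$pos5 %in% acidic) {          # R1
    label <- "NONE"
    modifiers <- c(modifiers, "R1")
    rationale <- c(rationale,
      "R1: acidic residue at position 5 reverses the canonical anchor charge -> no binding")
  } else if (sh3_class == "AGS" && d$pos2 %in% acidic) {           # R2
    label <- "NONE"
    modifiers <- c(modifiers, "R2")
    rationale <- c(rationale,
      "R2: acidic residue at position 2 repelled by the AGS acidic pocket -> no binding")
  } else if (d$prm_class == "CLASS_I") {
    label <- "TYPICAL"
    modifiers <- c(modifiers, "CLASS_I")
    rationale <- c(rationale,
      "class-I motif: canonical-orientation recognition, typical band (untested by direct evidence)")
  } else if (sh3_class == "AGS" && d$prm_class == "PX_PLUS_P") {   # R4
    label <- "HIGH"
    modifiers <- c(modifiers, "R4")
    rationale <- c(rationale,
      "R4: AGS acidic pocket grips the position-2 K/R of the Px+P motif -> high affinity")
    if (d$pos2 == "R") {
      modifiers <- c(modifiers, "enhanced")
      rationale <- c(rationale,
        "enhanced: arginine at position 2 mildly strengthens the interaction")
    }
  } else if (sh3_class == "AGS" && d$prm_class == "CLASS_II") {    # R5
    label <- "TYPICAL"
    modifiers <- c(modifiers, "R5")
    rationale <- c(rationale,
      "R5: class-II motif without a positive position 2 binds AGS in the typical band")
  } else if (sh3_class == "CANONICAL" &&
             d$prm_class %in% c("CLASS_II", "PX_PLUS_P")) {        # R6
    label <- "TYPICAL"
    modifiers <- c(modifiers, "R6")
    rationale <- c(rationale,
      "R6: canonical SH3 binds class-II/Px+P motifs in the typical band")
    if (d$pos2 %in% acidic) {
      modifiers <- c(modifiers, "untested")
      rationale <- c(rationale,
        "position-2 acidic x canonical SH3: cell untested by direct evidence, typical by default")
    }
  } else {                                                          # R7
    label <- "NONE"
    modifiers <- c(modifiers, "R7")
    rationale <- c(rationale, "R7: no canonical PRM class -> no binding")
  }

  if (label != "NONE") {                                            # R3
    for (anchor in c("P0", "P3")[!c(d$p0_present, d$p3_present)]) {
      label <- .downgrade(label)
      modifiers <- c(modifiers, "R3")
      rationale <- c(rationale, paste0(
        "R3: anchor proline ", anchor,
        " substituted -> binding downgraded one level"))
    }
  }

  structure(list(
    sh3_id = .sh3_id_of(sh3), prm_id = d$id,
    sh3_class = sh3_class, prm_class = d$prm_class,
    affinity = label, kd_band_uM = AFFINITY_BANDS[[label]],
    modifiers = modifiers, rationale = rationale, status = "ok"),
    class = "pair_prediction")
}

#' @export
print.pair_prediction <- function(x, ...) {
  cat(sprintf("<pair_prediction> %s x %s: %s [%s]\n", x$sh3_id, x$prm_id,
              x$affinity, paste(x$modifiers, collapse = ",")))
  invisible(x)
}

#' Predict all SH3 x PRM pairs
#'
#' Full cross-product of [predict_pair()] over a set of classified SH3
#' domains and a set of motifs. Per-pair failures (e.g. unclassifiable
#' domains) are reported as row-level `status`, never dropped silently.
#'
#' @param sh3_set list of `sh3_classification` objects (or class labels).
#' @param prm_set list of `prm_match` / [prm_description()] objects.
#' @return data.frame with columns `sh3_id`, `prm_id`, `affinity`,
#'   `band_lo_uM`, `band_hi_uM`, `rules_applied`, `status`.
#' @export
predict_all_pairs <- function(sh3_set, prm_set) {
  empty <- data.frame(sh3_id = character(0), prm_id = character(0),
                      affinity = character(0), band_lo_uM = numeric(0),
                      band_hi_uM = numeric(0), rules_applied = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (length(sh3_set) == 0L || length(prm_set) == 0L) return(empty)
  rows <- list()
  for (s in sh3_set) for (p in prm_set) {
    pr <- predict_pair(s, p)
    rows[[length(rows) + 1L]] <- data.frame(
      sh3_id = pr$sh3_id, prm_id = if (is.na(pr$prm_id) && !is.null(p$id))
        p$id else pr$prm_id,
      affinity = pr$affinity,
      band_lo_uM = pr$kd_band_uM[1L], band_hi_uM = pr$kd_band_uM[2L],
      rules_applied = paste(pr$modifiers, collapse = ";"),
      status = pr$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
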