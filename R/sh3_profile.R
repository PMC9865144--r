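# SH3 RT-loop diagnostic classification.
#
# AGS-type SH3 domains (ASAP/GRAF/SKAP families) replace the groove-center
# aromatic of canonical SH3 domains with a cysteine and carry an acidic
# residue three positions downstream -- the Cxx(D/E) RT-loop signature that
# creates the acidic pocket gripping the position-2 K/R of Px+P motifs.
# Diagnostic positions are located on a query domain by end-gap-free global
# alignment to an annotated reference.

.pkg_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_env$BLOSUM62
}

#' Construct an SH3 domain sequence object
#'
#' A [protein_sequence()] with an SH3-typical length check: domains outside
#' 40-90 residues trigger a warning (they are still accepted, since excised
#' boundaries vary).
#'
#' @inheritParams protein_sequence
#' @return A `protein_sequence` additionally classed `sh3_domain`.
#' @export
sh3_domain <- function(id, residues, numbering_offset = 0L) {
  p <- protein_sequence(id, residues, numbering_offset)
  n <- nchar(p$residues)
  if (n < 40L || n > 90L)
    warning("domain '", id, "' is ", n,
            " residues; typical SH3 domains span 40-90")
  class(p) <- c("sh3_domain", class(p))
  p
}

#' Construct an SH3 reference annotation
#'
#' @param sequence reference SH3 domain sequence (one-letter codes).
#' @param groove_center 1-based index of the groove-center diagnostic site
#'   (cysteine in AGS-type domains, aromatic in canonical ones).
#' @param acidic 1-based index of the acidic diagnostic site; must equal
#'   `groove_center + 3` (the Cxx(D/E) spacing).
#' @param aromatics integer vector of length 4: indices of the conserved
#'   groove aromatic positions.
#' @param numbering_offset offset to biological residue numbers.
#' @param id reference identifier.
#' @return An object of class `sh3_reference`.
#' @export
sh3_reference_annotation <- function(sequence, groove_center, acidic,
                                     aromatics, numbering_offset = 0L,
                                     id = "reference") {
  seq <- protein_sequence(id, sequence, numbering_offset)
  groove_center <- as.integer(groove_center)
  acidic <- as.integer(acidic)
  if (acidic != groove_center + 3L)
    stop("acidic site must be groove-center site + 3 (Cxx(D/E) spacing)")
  aromatics <- as.integer(aromatics)
  if (length(aromatics) != 4L)
    stop("exactly four conserved groove aromatic sites are expected")
  n <- nchar(seq$residues)
  if (any(c(groove_center, acidic, aromatics) > n))
    stop("annotated site index beyond reference length ", n)
  structure(list(seq = seq, groove_center = groove_center, acidic = acidic,
                 aromatics = aromatics), class = "sh3_reference")
}

#' Bundled AGS-type SH3 reference annotation (synthetic model sequence)
#'
#' A constructed SH3-like model sequence standing in for the ASAP1 SH3
#' domain (it is synthetic, not the database sequence), numbered 1087-1147
#' so that the diagnostic cysteine falls at biological residue 1096 and the
#' acidic aspartate at 1099; four groove aromatic positions are annotated
#' (biological 1094, 1122, 1139, 1141). All classifier tests derive their
#' cases from this fixture by mutation.
#'
#' @return An `sh3_reference` object.
#' @export
ags_reference <- function() {
  sh3_reference_annotation(
    sequence = paste0("VTLFVALYDC", "ARDGELSLRK", "GDQVRILSNN",
                      "KSGEWWEAAS", "LTTGQEGLVP", "SNYIFVNSLEK"),
    groove_center = 10L, acidic = 13L, aromatics = c(8L, 36L, 53L, 55L),
    numbering_offset = 1086L, id = "AGS_SH3_reference_synthetic")
}

#' Canonical (SEM5-like) SH3 fixture sequence
#'
#' The bundled AGS reference with the two diagnostic sites swapped to the
#' canonical RT-loop chemistry: aromatic (F) at the groove center and
#' glutamine at the acidic site, mirroring the F/Q pair of a typical
#' class-II-binding SH3 domain. Synthetic fixture.
#'
#' @return An `sh3_domain` object.
#' @export
sem5_like_sh3 <- function() {
  ref <- ags_reference()
  ch <- seq_chars(ref$seq)
  ch[ref$groove_center] <- "F"
  ch[ref$acidic] <- "Q"
  sh3_domain("SEM5_like_synthetic", paste(ch, collapse = ""))
}

#' Read a reference annotation from TSV
#'
#' Expects a single-row TSV with columns `sequence`, `groove_center`,
#' `acidic`, `aromatics` (comma-separated indices) and optionally `offset`.
#'
#' @param path TSV path.
#' @return An `sh3_reference` object.
#' @export
read_reference_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  off <- if ("offset" %in% names(tab)) tab$offset[1L] else 0L
  sh3_reference_annotation(tab$sequence[1L], tab$groove_center[1L],
                           tab$acidic[1L],
                           as.integer(strsplit(tab$aromatics[1L], ",")[[1L]]),
                           numbering_offset = off)
}

# end-gap-free global alignment of query to reference; returns the map from
# reference index -> query index (NA where the reference aligns to a gap or
# falls outside the aligned span)
.align_to_reference <- function(query, ref, gap_open = 11, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query$residues), Biostrings::AAString(ref$seq$residues),
    type = "overlap", substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  map <- rep(NA_integer_, nchar(ref$seq$residues))
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") qi <- qi + 1L
    if (s[k] != "-") {
      si <- si + 1L
      if (p[k] != "-") map[si] <- qi
    }
  }
  list(map = map, score = Biostrings::score(aln))
}

#' Map the diagnostic RT-loop positions of a query SH3 domain
#'
#' Aligns the query to an annotated reference (end-gap-free global pairwise
#' alignment, BLOSUM62, gap open 11 / extend 1) and returns the query
#' indices carrying the reference's groove-center and acidic diagnostic
#' sites, plus the four conserved groove aromatic sites. Alignments scoring
#' below `score_floor_frac` times the reference self-score are declared
#' unalignable (diagnostic mapping must fail loudly on non-SH3 input).
#'
#' @param query an [sh3_domain()] or [protein_sequence()].
#' @param ref an `sh3_reference`, default [ags_reference()].
#' @param score_floor_frac fraction of the reference self-alignment score
#'   below which the query is declared unalignable (default 0.25).
#' @return A list of class `sh3_mapping`: query/reference objects, per-site
#'   query indices (`NA` marks a gap), alignment `score`, and flags.
#' @export
map_diagnostic_positions <- function(query, ref = ags_reference(),
                                     score_floor_frac = 0.25) {
  stopifnot(inherits(query, "protein_sequence"), inherits(ref, "sh3_reference"))
  a <- .align_to_reference(query, ref)
  self <- .align_to_reference(ref$seq, ref)$score
  unalignable <- a$score < score_floor_frac * self
  structure(list(
    query = query, ref = ref,
    groove_center_q = a$map[ref$groove_center],
    acidic_q = a$map[ref$acidic],
    aromatics_q = a$map[ref$aromatics],
    score = a$score, self_score = self,
    unalignable = unalignable), class = "sh3_mapping")
}

#' Classify an SH3 domain as AGS-type or canonical
#'
#' AGS requires cysteine at the mapped groove-center site, D or E at the
#' mapped acidic site, and a spacing of exactly 3 between the two mapped
#' query indices (strict Cxx(D/E); insertions inside the motif disqualify).
#' Histidine is not accepted at the acidic site. `UNKNOWN` is returned when
#' either diagnostic site maps to a gap or the alignment is unalignable.
#'
#' @param mapping an `sh3_mapping` from [map_diagnostic_positions()].
#' @return A list of class `sh3_classification` with the mapped residues,
#'   indices, `sh3_class` (`"AGS"`, `"CANONICAL"` or `"UNKNOWN"`), the
#'   aromatics report of [check_conserved_aromatics()] and alignment score.
#' @export
classify_sh3 <- function(mapping) {
  stopifnot(inherits(mapping, "sh3_mapping"))
  ch <- seq_chars(mapping$query)
  gq <- mapping$groove_center_q
  aq <- mapping$acidic_q
  groove_res <- if (!is.na(gq)) ch[gq] else NA_character_
  acidic_res <- if (!is.na(aq)) ch[aq] else NA_character_
  cls <- if (mapping$unalignable || is.na(gq) || is.na(aq)) {
    "UNKNOWN"
  } else if (identical(groove_res, "C") && acidic_res %in% c("D", "E") &&
             (aq - gq) == 3L) {
    "AGS"
  } else {
    "CANONICAL"
  }
  diagnostic <- if (mapping$unalignable) "unalignable" else
    if (cls == "UNKNOWN") "diagnostic site maps to a gap" else NA_character_
  structure(list(
    id = mapping$query$id,
    groove_center_residue = groove_res, groove_center_index = gq,
    acidic_residue = acidic_res, acidic_index = aq,
    sh3_class = cls,
    aromatics_report = check_conserved_aromatics(mapping),
    score = mapping$score, diagnostic = diagnostic),
    class = "sh3_classification")
}

#' @export
print.sh3_classification <- function(x, ...) {
  cat(sprintf("<sh3_classification> %s: %s (groove %s, acidic %s, %d/4 aromatics)\n",
              x$id, x$sh3_class,
              x$groove_center_residue, x$acidic_residue,
              x$aromatics_report$n_aromatic))
  invisible(x)
}

#' Report the four conserved groove aromatic positions of a query
#'
#' For each annotated aromatic site, reports the mapped query residue and
#' whether it is aromatic (F/Y/W/H). A domain with two or more sites
#' missing or non-aromatic is flagged `"degenerate groove"`.
#'
#' @inheritParams classify_sh3
#' @return List with `residues`, `indices`, `is_aromatic`, `n_aromatic`,
#'   and `flag` (`"degenerate groove"` or `NA`).
#' @export
check_conserved_aromatics <- function(mapping) {
  stopifnot(inherits(mapping, "sh3_mapping"))
  ch <- seq_chars(mapping$query)
  idx <- mapping$aromatics_q
  res <- ifelse(is.na(idx), NA_character_, ch[ifelse(is.na(idx), 1L, idx)])
  is_arom <- !is.na(res) & res %in% c("F", "Y", "W", "H")
  n <- sum(is_arom)
  list(residues = res, indices = idx, is_aromatic = is_arom, n_aromatic = n,
       flag = if (4L - n >= 2L) "degenerate groove" else NA_character_)
}

#' Classify a set of SH3 domains
#'
#' Applies [map_diagnostic_positions()] and [classify_sh3()] to each query.
#'
#' @param queries list of [sh3_domain()]/[protein_sequence()] objects.
#' @param ref reference annotation, default [ags_reference()].
#' @return data.frame with columns `id`, `class`, `groove_center_res`,
#'   `acidic_res`, `aromatics_present`, `score`.
#' @export
classify_sh3_domains <- function(queries, ref = ags_reference()) {
  rows <- lapply(queries, function(q) {
    cl <- classify_sh3(map_diagnostic_positions(q, ref))
    data.frame(id = cl$id, class = cl$sh3_class,
               groove_center_res = cl$groove_center_residue,
               acidic_res = cl$acidic_residue,
               aromatics_present = cl$aromatics_report$n_aromatic,
               score = cl$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
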