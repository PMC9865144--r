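# Position-registered proline-rich motif (PRM) scanners.
#
# Class-II PRMs follow x(-1) P(0) x(1) x(2) P(3) x(4) +(5): the two anchor
# prolines sit at register positions 0 and 3 and the positive residue (K/R)
# at position 5. The atypical high-affinity variant ("Px+P" motif,
# xPx(K/R)Px(K/R)) additionally requires K/R at register position 2, inside
# the PxxP core. Class-I PRMs are the mirror orientation +xxPxxP.

PHI_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "P")

# character class of the 20 standard residues (excludes X, so any window
# containing an unknown residue is voided, not the whole scan)
.aa_class <- function() paste0("[", paste(AA_STANDARD, collapse = ""), "]")

#' Build a PRM position register
#'
#' Maps register positions -2..5 to 1-based indices on the parent sequence.
#' Indices are consecutive; the anchor prolines sit at positions 0 and 3
#' unless the register explicitly represents a P3-substituted variant.
#'
#' @param p0_index 1-based index of the first anchor proline (position 0).
#' @param seq_length length of the parent sequence (bounds check).
#' @param p3_substituted logical; `TRUE` marks a variant register whose
#'   position-3 residue is not proline.
#' @return Named integer vector (names `"-2"` .. `"5"`); position -2 is `NA`
#'   when no preceding residue exists. Class `prm_register`.
#' @export
prm_register <- function(p0_index, seq_length, p3_substituted = FALSE) {
  p0_index <- as.integer(p0_index)
  if (p0_index < 2L || p0_index + 3L > seq_length)
    stop("register with P0 at index ", p0_index,
         " does not fit a sequence of length ", seq_length)
  idx <- c(if (p0_index >= 3L) p0_index - 2L else NA_integer_,
           (p0_index - 1L):(p0_index + 5L))
  idx[idx > seq_length] <- NA_integer_  # positions past the chain end
  names(idx) <- as.character(-2:5)
  structure(idx, p3_substituted = p3_substituted, class = "prm_register")
}

#' @export
print.prm_register <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(v)
  if (isTRUE(attr(x, "p3_substituted"))) cat("(P3-substituted variant)\n")
  invisible(x)
}

#' Convert register indices to biological residue numbers
#'
#' @param register a [prm_register()].
#' @param numbering_offset the parent sequence's numbering offset.
#' @return Named integer vector of biological residue numbers.
#' @export
register_biological_numbers <- function(register, numbering_offset = 0L) {
  register + as.integer(numbering_offset)
}

# internal constructor for a single match
.prm_match <- function(seq, start, prm_class, p3_substituted = FALSE) {
  chars <- seq_chars(seq)
  register <- prm_register(start + 1L, length(chars), p3_substituted)
  pos2 <- chars[register[["2"]]]
  pos5 <- chars[register[["5"]]]
  structure(list(
    protein_id = seq$id,
    start = start,
    end = start + 6L,
    prm_class = prm_class,
    window = substr(seq$residues, start, start + 6L),
    register = register,
    pos2_residue = pos2,
    pos5_residue = pos5,
    pos2_hydrophobic = pos2 %in% PHI_HYDROPHOBIC,
    px_plus_p = pos2 %in% c("K", "R") && pos5 %in% c("K", "R"),
    p3_substituted = p3_substituted
  ), class = "prm_match")
}

#' @export
print.prm_match <- function(x, ...) {
  cat(sprintf("<prm_match> %s %d-%d %s [%s]%s\n", x$protein_id, x$start,
              x$end, x$window, x$prm_class,
              if (isTRUE(x$px_plus_p) && x$prm_class != "PX_PLUS_P")
                " (also Px+P)" else ""))
  invisible(x)
}

# regex-based scan returning match starts; the test-suite oracle re-derives
# these by explicit per-window character checks, so keep this route distinct
.scan_starts <- function(seq, core_pattern) {
  if (nchar(seq$residues) < 7L) return(integer(0))
  hits <- gregexpr(paste0("(?=", core_pattern, ")"), seq$residues,
                   perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

.recheck <- function(window, core_pattern) {
  grepl(paste0("^", core_pattern, "$"), window, perl = TRUE)
}

.scan_generic <- function(seq, core_pattern, prm_class) {
  stopifnot(inherits(seq, "protein_sequence"))
  starts <- .scan_starts(seq, core_pattern)
  out <- lapply(starts, function(s) .prm_match(seq, s, prm_class))
  # every reported window must re-satisfy its defining pattern
  ok <- vapply(out, function(m) .recheck(m$window, core_pattern), logical(1L))
  if (!all(ok)) stop("internal error: reported match fails pattern recheck")
  out
}

#' Scan for class-II proline-rich motifs (xPxxPx+)
#'
#' Reports every 7-residue window matching `x P x x P x (K/R)` where x is any
#' standard residue; windows containing `X` are excluded. All overlapping
#' windows are reported. Matches whose position-2 residue is also K/R carry
#' `px_plus_p = TRUE` (they satisfy the atypical Px+P pattern as well).
#'
#' @param seq a [protein_sequence()].
#' @return List of `prm_match` objects (empty when no window matches).
#' @examples
#' scan_class2(protein_sequence("demo", "GAPAKPARGG"))
#' @export
scan_class2 <- function(seq) {
  x <- .aa_class()
  .scan_generic(seq, paste0(x, "P", x, x, "P", x, "[KR]"), "CLASS_II")
}

#' Scan for class-I proline-rich motifs (+xxPxxP)
#'
#' Reports every 7-residue window matching `(K/R) x x P x x P`. The register
#' is anchored on the two prolines (positions 0 and 3), which places the
#' positive residue at a position conventionally reported as "minus_3"; this
#' anchoring is a package convention for the class-I orientation.
#'
#' @inheritParams scan_class2
#' @return List of `prm_match` objects with class `CLASS_I`.
#' @export
scan_class1 <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  x <- .aa_class()
  core <- paste0("[KR]", x, x, "P", x, x, "P")
  starts <- .scan_starts(seq, core)
  chars <- seq_chars(seq)
  out <- lapply(starts, function(s) {
    # anchor prolines: P0 at window offset +3, P3 at +6
    register <- prm_register(s + 3L, length(chars))
    m <- structure(list(
      protein_id = seq$id, start = s, end = s + 6L, prm_class = "CLASS_I",
      window = substr(seq$residues, s, s + 6L), register = register,
      pos2_residue = chars[register[["2"]]],
      pos5_residue = if (!is.na(register[["5"]]))
        chars[register[["5"]]] else NA_character_,
      pos2_hydrophobic = chars[register[["2"]]] %in% PHI_HYDROPHOBIC,
      px_plus_p = FALSE, p3_substituted = FALSE,
      plus_minus3_residue = chars[s]
    ), class = "prm_match")
    m
  })
  ok <- vapply(out, function(m) .recheck(m$window, core), logical(1L))
  if (!all(ok)) stop("internal error: reported match fails pattern recheck")
  out
}

#' Scan for the atypical Px+P motif (xPx(K/R)Px(K/R))
#'
#' The high-affinity variant of the class-II PRM: K/R at register position 2
#' inside the PxxP core in addition to the canonical K/R at position 5.
#' Every Px+P match also satisfies the class-II pattern, so the result is
#' always a subset of [scan_class2()].
#'
#' @inheritParams scan_class2
#' @return List of `prm_match` objects with class `PX_PLUS_P`.
#' @export
scan_pxplusp <- function(seq) {
  x <- .aa_class()
  .scan_generic(seq, paste0(x, "P", x, "[KR]P", x, "[KR]"), "PX_PLUS_P")
}

#' Classify a single candidate window
#'
#' Returns the most specific canonical class satisfied by the window
#' (`PX_PLUS_P` > `CLASS_II` > `CLASS_I` > `NONE`) together with position-2
#' annotations. Windows of length 8 are interpreted as carrying a leading
#' position -2 residue; length 9 additionally carries one trailing residue;
#' classification always uses the 7-residue core (positions -1..5).
#'
#' In `variant_mode`, a window matching the Px+P/class-II pattern at every
#' position except an absent position-3 proline is annotated
#' `"P3-substituted class-II-like"` (its canonical class remains `NONE`).
#'
#' @param window character scalar of length 7-9.
#' @param variant_mode logical; annotate P3-substituted class-II-like windows.
#' @return List with `prm_class`, `pos2_residue`, `pos2_hydrophobic`,
#'   `p3_present`, and `annotation`.
#' @examples
#' classify_window("APAKPAR")  # PX_PLUS_P
#' classify_window("APAVPAR")  # CLASS_II, hydrophobic position 2
#' classify_window("APAKSAR", variant_mode = TRUE)
#' @export
classify_window <- function(window, variant_mode = FALSE) {
  stopifnot(is.character(window), length(window) == 1L)
  window <- toupper(window)
  n <- nchar(window)
  if (n < 7L || n > 9L)
    stop("window must be 7-9 residues, got ", n)
  core <- if (n == 7L) window else substr(window, 2L, 8L)
  ch <- strsplit(core, "", fixed = TRUE)[[1L]]
  x <- .aa_class()
  is2  <- .recheck(core, paste0(x, "P", x, x, "P", x, "[KR]"))
  ispx <- .recheck(core, paste0(x, "P", x, "[KR]P", x, "[KR]"))
  is1  <- .recheck(core, paste0("[KR]", x, x, "P", x, x, "P"))
  prm_class <- if (ispx) "PX_PLUS_P" else if (is2) "CLASS_II" else
    if (is1) "CLASS_I" else "NONE"
  p3_present <- ch[5L] == "P"
  annotation <- character(0)
  if (variant_mode && prm_class == "NONE") {
    # class-II-like in every respect except the position-3 proline
    like <- .recheck(paste0(substr(core, 1L, 4L), "P", substr(core, 6L, 7L)),
                     paste0(x, "P", x, x, "P", x, "[KR]")) && !p3_present
    if (like) annotation <- "P3-substituted class-II-like"
  }
  list(prm_class = prm_class,
       pos2_residue = ch[4L],
       pos2_hydrophobic = ch[4L] %in% PHI_HYDROPHOBIC,
       p3_present = p3_present,
       annotation = annotation)
}

#' Scan a sequence for PRMs of one or all classes
#'
#' Convenience dispatcher over [scan_class1()], [scan_class2()] and
#' [scan_pxplusp()]. Duplicate (start, class) pairs are removed; overlapping
#' and nested matches are all kept.
#'
#' @inheritParams scan_class2
#' @param prm_class one of `"all"`, `"1"`, `"2"`, `"px+p"`.
#' @return List of `prm_match` objects.
#' @export
scan_prm <- function(seq, prm_class = c("all", "1", "2", "px+p")) {
  prm_class <- match.arg(prm_class)
  out <- switch(prm_class,
    "1" = scan_class1(seq),
    "2" = scan_class2(seq),
    "px+p" = scan_pxplusp(seq),
    all = c(scan_class1(seq), scan_class2(seq), scan_pxplusp(seq)))
  key <- vapply(out, function(m) paste(m$start, m$prm_class), character(1L))
  out[!duplicated(key)]
}

#' Tabulate PRM matches
#'
#' @param matches list of `prm_match` objects (possibly from several
#'   sequences).
#' @return A data.frame with columns `protein_id`, `start`, `end`, `class`,
#'   `window`, `pos2`, `pos5`, `register_json`.
#' @export
prm_match_table <- function(matches) {
  if (length(matches) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      window = character(0), pos2 = character(0),
                      pos5 = character(0), register_json = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    protein_id = vapply(matches, `[[`, character(1L), "protein_id"),
    start = vapply(matches, `[[`, integer(1L), "start"),
    end = vapply(matches, `[[`, integer(1L), "end"),
    class = vapply(matches, `[[`, character(1L), "prm_class"),
    window = vapply(matches, `[[`, character(1L), "window"),
    pos2 = vapply(matches, `[[`, character(1L), "pos2_residue"),
    pos5 = vapply(matches, `[[`, character(1L), "pos5_residue"),
    register_json = vapply(matches, function(m)
      as.character(jsonlite::toJSON(as.list(m$register))), character(1L)),
    stringsAsFactors = FALSE)
}

#' Write PRM matches to TSV or JSON-lines
#'
#' @inheritParams prm_match_table
#' @param path output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_prm_matches <- function(matches, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  tab <- prm_match_table(matches)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(tab)))
      writeLines(as.character(jsonlite::toJSON(as.list(tab[i, ]),
                                               auto_unbox = TRUE)), con)
  }
  invisible(path)
}
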