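# Interface geometry for SH3/peptide complexes: contacts, salt bridges,
# backbone dihedrals / polyproline-II assignment, and structure-derived
# motif registers.

#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records via bio3d after a light format validation
#' pass (malformed records are reported with their line numbers). Hydrogen
#' atoms are dropped; alternate locations are resolved to the highest
#' occupancy (ties broken by first-seen record); insertion codes are kept.
#'
#' @param path PDB file path.
#' @return data.frame of class `atom_table` with columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `element`, `x`, `y`, `z`, `o`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  if (length(rec) == 0L)
    stop("no ATOM/HETATM records in '", path, "'")
  for (i in rec) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (nchar(ln) < 54L || anyNA(coords) || any(!is.finite(coords)))
      stop("malformed ATOM record at line ", i, " of '", path, "'")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  element <- at$elesy
  guess <- toupper(substr(gsub("[0-9']", "", at$elety), 1L, 1L))
  element[is.na(element) | element == ""] <- guess[is.na(element) | element == ""]
  at$element <- element
  at <- at[at$element != "H", , drop = FALSE]
  # altloc: highest occupancy per (chain, resno, insert, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -at$o)  # stable: first seen wins ties
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "|")), , drop = FALSE]
  out <- at[, c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "o")]
  rownames(out) <- NULL
  class(out) <- c("atom_table", "data.frame")
  out
}

.chain_atoms <- function(atoms, chain) {
  sub <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("chain '", chain, "' is empty or absent; complex analyses need ",
         "two populated chains")
  sub
}

#' Compute heavy-atom contacts between two chains
#'
#' All inter-chain heavy-atom pairs with Euclidean distance at or below the
#' cutoff (default 4.5 A, a common literature convention).
#'
#' @param atoms an `atom_table` from [read_structure()].
#' @param chain_a,chain_b chain identifiers (SH3 and peptide by convention).
#' @param cutoff contact distance cutoff in Angstrom.
#' @return data.frame with per-pair atom descriptors and `distance`.
#' @export
compute_contacts <- function(atoms, chain_a, chain_b, cutoff = 4.5) {
  a <- .chain_atoms(atoms, chain_a)
  b <- .chain_atoms(atoms, chain_b)
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resid_a = character(0), elety_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      resid_b = character(0), elety_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  out <- data.frame(
    chain_a = chain_a, resno_a = a$resno[hit[, 1L]],
    resid_a = a$resid[hit[, 1L]], elety_a = a$elety[hit[, 1L]],
    chain_b = chain_b, resno_b = b$resno[hit[, 2L]],
    resid_b = b$resid[hit[, 2L]], elety_b = b$elety[hit[, 2L]],
    distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  out[order(out$resno_a, out$resno_b, out$distance), , drop = FALSE]
}

.SB_BASIC <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.is_basic_n <- function(resid, elety) {
  (resid == "LYS" & elety %in% .SB_BASIC$LYS) |
    (resid == "ARG" & elety %in% .SB_BASIC$ARG)
}
.is_acidic_o <- function(resid, elety) {
  (resid == "ASP" & elety %in% .SB_ACIDIC$ASP) |
    (resid == "GLU" & elety %in% .SB_ACIDIC$GLU)
}

#' Detect inter-chain salt bridges among computed contacts
#'
#' A salt bridge is a Lys NZ or Arg NE/NH1/NH2 nitrogen within `cutoff`
#' (default 4.0 A) of an Asp OD1/OD2 or Glu OE1/OE2 oxygen, in either
#' chain orientation. Histidine is excluded as a donor (protonation state
#' unknown). Pairs are aggregated per residue pair with the minimum N-O
#' distance. Supply contacts computed with a contact cutoff of at least
#' the salt-bridge cutoff so that every bridge is also a contact.
#'
#' @param contacts data.frame from [compute_contacts()].
#' @param cutoff salt-bridge N-O distance cutoff in Angstrom.
#' @return data.frame with `basic_chain`, `basic_resno`, `basic_resid`,
#'   `acidic_chain`, `acidic_resno`, `acidic_resid`, `min_distance`.
#' @export
detect_salt_bridges <- function(contacts, cutoff = 4.0) {
  ab <- .is_basic_n(contacts$resid_a, contacts$elety_a) &
    .is_acidic_o(contacts$resid_b, contacts$elety_b)
  ba <- .is_basic_n(contacts$resid_b, contacts$elety_b) &
    .is_acidic_o(contacts$resid_a, contacts$elety_a)
  keep <- (ab | ba) & contacts$distance <= cutoff
  sub <- contacts[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(basic_chain = character(0), basic_resno = integer(0),
                      basic_resid = character(0), acidic_chain = character(0),
                      acidic_resno = integer(0), acidic_resid = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  flip <- .is_basic_n(sub$resid_b, sub$elety_b)
  out <- data.frame(
    basic_chain = ifelse(flip, sub$chain_b, sub$chain_a),
    basic_resno = ifelse(flip, sub$resno_b, sub$resno_a),
    basic_resid = ifelse(flip, sub$resid_b, sub$resid_a),
    acidic_chain = ifelse(flip, sub$chain_a, sub$chain_b),
    acidic_resno = ifelse(flip, sub$resno_a, sub$resno_b),
    acidic_resid = ifelse(flip, sub$resid_a, sub$resid_b),
    min_distance = sub$distance, stringsAsFactors = FALSE)
  key <- paste(out$basic_chain, out$basic_resno, out$acidic_chain,
               out$acidic_resno, sep = "|")
  agg <- tapply(out$min_distance, key, min)
  out <- out[!duplicated(key), , drop = FALSE]
  out$min_distance <- as.numeric(agg[paste(out$basic_chain, out$basic_resno,
                                           out$acidic_chain, out$acidic_resno,
                                           sep = "|")])
  rownames(out) <- NULL
  out
}

# torsion angle (degrees, (-180, 180]) of four points given as xyz rows
.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi  # IUPAC sign
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Compute backbone phi/psi dihedrals for one chain
#'
#' Standard phi (C(i-1)-N-CA-C) and psi (N-CA-C-N(i+1)) from backbone
#' N/CA/C atoms; residues with missing backbone atoms (and the chain
#' termini, where a neighbour is needed) get `NA` angles, never an error.
#'
#' @param atoms an `atom_table`.
#' @param chain chain identifier.
#' @return data.frame with `resno`, `resid`, `phi`, `psi` (degrees).
#' @export
compute_dihedrals <- function(atoms, chain) {
  sub <- .chain_atoms(atoms, chain)
  resnos <- sort(unique(sub$resno))
  if (length(resnos) < 3L)
    stop("chain '", chain, "' has fewer than 3 residues")
  get_atom <- function(resno, name) {
    row <- sub[sub$resno == resno & sub$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  resid <- character(n)
  for (i in seq_len(n)) {
    r <- resnos[i]
    resid[i] <- sub$resid[sub$resno == r][1L]
    Ni <- get_atom(r, "N"); CAi <- get_atom(r, "CA"); Ci <- get_atom(r, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1L) {
      Cp <- get_atom(resnos[i - 1L], "C")
      if (!is.null(Cp) && resnos[i - 1L] == r - 1L)
        phi[i] <- .dihedral_angle(Cp, Ni, CAi, Ci)
    }
    if (i < n) {
      Nn <- get_atom(resnos[i + 1L], "N")
      if (!is.null(Nn) && resnos[i + 1L] == r + 1L)
        psi[i] <- .dihedral_angle(Ni, CAi, Ci, Nn)
    }
  }
  data.frame(resno = resnos, resid = resid, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

.ang_dist <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Flag residues in polyproline-II conformation
#'
#' A residue is PPII when its (phi, psi) lies within `tol` (angular
#' distance, default 30 degrees) of the canonical PPII backbone
#' (-75, +145). Residues with undefined angles return `NA`.
#'
#' @param dihedrals data.frame with `phi` and `psi` columns (degrees), as
#'   returned by [compute_dihedrals()], or a list with those elements.
#' @param tol angular tolerance in degrees.
#' @param phi0,psi0 centre of the PPII region.
#' @return Logical vector, one element per residue.
#' @export
is_ppii <- function(dihedrals, tol = 30, phi0 = -75, psi0 = 145) {
  phi <- dihedrals$phi
  psi <- dihedrals$psi
  .ang_dist(phi, phi0) <= tol & .ang_dist(psi, psi0) <= tol
}

#' Assign a PRM register from complex coordinates
#'
#' Identifies the two anchor prolines (P0/P3) as the peptide prolines with
#' the largest heavy-atom contact counts to the annotated SH3 groove
#' aromatic residues, then cross-checks against the sequence-derived
#' register from [scan_class2()]. On disagreement a warning is raised and
#' the sequence register wins.
#'
#' @param atoms an `atom_table` of the complex.
#' @param sh3_chain,peptide_chain chain identifiers.
#' @param sh3_annotation list with element `aromatic_resno`: residue
#'   numbers (on `sh3_chain`) of the groove aromatics.
#' @param cutoff contact cutoff in Angstrom passed to [compute_contacts()].
#' @return List with `register` (the winning [prm_register()]),
#'   `structural_anchors` (peptide residue numbers of the two contact-ranked
#'   prolines), `sequence_anchors`, and `mismatch` flag.
#' @export
assign_register_from_structure <- function(atoms, sh3_chain, peptide_chain,
                                           sh3_annotation, cutoff = 4.5) {
  pep <- .chain_atoms(atoms, peptide_chain)
  resnos <- sort(unique(pep$resno))
  resid3 <- vapply(resnos, function(r) pep$resid[pep$resno == r][1L],
                   character(1L))
  pep_seq <- paste(bio3d::aa321(resid3), collapse = "")
  contacts <- compute_contacts(atoms, sh3_chain, peptide_chain,
                               cutoff = cutoff)
  groove <- contacts[contacts$resno_a %in% sh3_annotation$aromatic_resno, ,
                     drop = FALSE]
  pro <- resnos[resid3 == "PRO"]
  counts <- vapply(pro, function(r) sum(groove$resno_b == r), integer(1L))
  if (length(pro) == 0L || all(counts == 0L))
    stop("register unassignable: no peptide proline contacts the ",
         "annotated groove aromatics")
  top <- pro[order(-counts)][seq_len(min(2L, sum(counts > 0L)))]
  struct_anchors <- sort(top)
  struct_p0_index <- match(struct_anchors[1L], resnos)

  pseq <- protein_sequence(paste0("chain_", peptide_chain), pep_seq)
  seq_matches <- scan_class2(pseq)
  if (length(seq_matches) == 0L) {
    warning("no sequence-derived class-II register in peptide chain; ",
            "using the structure-derived anchors")
    return(list(register = prm_register(struct_p0_index, length(resnos)),
                structural_anchors = struct_anchors,
                sequence_anchors = NULL, mismatch = NA))
  }
  seq_p0_index <- seq_matches[[1L]]$register[["0"]]
  seq_anchors <- resnos[c(seq_p0_index, seq_p0_index + 3L)]
  mismatch <- length(struct_anchors) < 2L ||
    !identical(as.integer(struct_anchors), as.integer(seq_anchors))
  if (mismatch)
    warning("structure-derived anchors (", paste(struct_anchors, collapse = ","),
            ") disagree with the sequence-derived register (",
            paste(seq_anchors, collapse = ","), "); sequence register wins")
  list(register = seq_matches[[1L]]$register,
       structural_anchors = struct_anchors,
       sequence_anchors = seq_anchors, mismatch = mismatch)
}

#' Build a full interface report for an SH3/peptide complex
#'
#' Bundles contacts, salt bridges, a pocket summary (per peptide register
#' position, counts of contacts to aromatic-groove vs acidic SH3 residues
#' -- the acidic patch is reported empirically, not from a fixed list),
#' the structure-derived register, and per-residue PPII flags.
#'
#' @inheritParams assign_register_from_structure
#' @param contact_cutoff,salt_bridge_cutoff distance cutoffs in Angstrom.
#' @return List of class `interface_report`.
#' @export
interface_report <- function(atoms, sh3_chain, peptide_chain, sh3_annotation,
                             contact_cutoff = 4.5, salt_bridge_cutoff = 4.0) {
  contacts <- compute_contacts(atoms, sh3_chain, peptide_chain,
                               cutoff = contact_cutoff)
  bridges <- detect_salt_bridges(contacts, cutoff = salt_bridge_cutoff)
  reg <- assign_register_from_structure(atoms, sh3_chain, peptide_chain,
                                        sh3_annotation,
                                        cutoff = contact_cutoff)
  pep <- .chain_atoms(atoms, peptide_chain)
  resnos <- sort(unique(pep$resno))
  dihedrals <- compute_dihedrals(atoms, peptide_chain)
  ppii <- is_ppii(dihedrals)

  positions <- names(reg$register)
  pocket <- data.frame(position = positions,
                       resno = resnos[reg$register],
                       aromatic_contacts = 0L, acidic_contacts = 0L,
                       stringsAsFactors = FALSE)
  arom <- contacts$resno_a %in% sh3_annotation$aromatic_resno |
    contacts$resid_a %in% c("PHE", "TYR", "TRP", "HIS")
  acid <- contacts$resid_a %in% c("ASP", "GLU")
  for (i in seq_along(positions)) {
    r <- pocket$resno[i]
    if (is.na(r)) next
    pocket$aromatic_contacts[i] <- sum(arom & contacts$resno_b == r)
    pocket$acidic_contacts[i] <- sum(acid & contacts$resno_b == r)
  }
  structure(list(contacts = contacts, salt_bridges = bridges,
                 pocket_summary = pocket, structure_register = reg,
                 dihedrals = dihedrals, ppii_flags = ppii),
            class = "interface_report")
}

#' Write an interface report as JSON
#'
#' @param report an `interface_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interface_report <- function(report, path) {
  out <- list(
    contacts = report$contacts,
    salt_bridges = report$salt_bridges,
    pocket_summary = report$pocket_summary,
    register = as.list(report$structure_register$register),
    structural_anchors = report$structure_register$structural_anchors,
    mismatch = report$structure_register$mismatch,
    dihedrals = report$dihedrals,
    ppii_flags = report$ppii_flags)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
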