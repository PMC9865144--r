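# Synthetic-data generators with ground-truth tables.
#
# Every pipeline input (proteomes with planted motifs, annotation tables
# with planted term enrichment, ortholog sets with controlled motif
# conservation, idealized polyproline-II coordinates with pseudo-pocket
# atoms, titration curves) can be generated with known truth, so every
# stage is testable without downloads. A single global seed fans out to
# per-generator streams via [stream_seed()].

# Swiss-Prot-like background amino-acid frequencies (percent); the uniform
# default maximizes test transparency, this table stresses realistic
# false-positive behaviour.
AA_COMPOSITION_SWISSPROT <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)

#' Derive a per-stream seed from a global seed
#'
#' Deterministic fan-out: `(seed * 48271 + stream-index * 104729) mod
#' (2^31 - 1)`, with streams identified by name. Subsets of the generators
#' are therefore reproducible independently of generation order.
#'
#' @param seed global integer seed.
#' @param stream stream name (any string).
#' @return Integer seed.
#' @export
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 104729) %% (2^31 - 1))
}

.sample_background <- function(n, composition) {
  probs <- switch(composition,
                  uniform = stats::setNames(rep(1 / 20, 20), AA_STANDARD),
                  swissprot = AA_COMPOSITION_SWISSPROT[AA_STANDARD] /
                    sum(AA_COMPOSITION_SWISSPROT))
  sample(AA_STANDARD, n, replace = TRUE, prob = probs)
}

# one planted motif window of the requested class; x positions avoid
# P/K/R so the plant carries exactly its intended pattern
.motif_instance <- function(class) {
  x <- function(n = 1L) sample(setdiff(AA_STANDARD, c("P", "K", "R")), n,
                               replace = TRUE)
  pos <- function() sample(c("K", "R"), 1L)
  switch(class,
    PX_PLUS_P = c(x(), "P", x(), pos(), "P", x(), pos()),
    CLASS_II = c(x(), "P", x(), sample(c("A", "V", "L", "I"), 1L), "P",
                 x(), pos()),
    CLASS_I = c(pos(), x(), x(), "P", x(), x(), "P"),
    stop("unknown motif class ", class))
}

.scan_all_classes <- function(seq) {
  c(scan_pxplusp(seq), scan_class2(seq), scan_class1(seq))
}

#' Generate a synthetic proteome with planted PRMs
#'
#' Background residues are drawn i.i.d. from a uniform (default) or
#' Swiss-Prot-like composition; each designated protein carries one motif
#' of its assigned class planted at a recorded position. Proteins are
#' redrawn (bounded retries) until their scanned match set equals the
#' intended plantings, so the truth table is exact: by construction there
#' are no unrecorded spontaneous matches.
#'
#' @param n_proteins number of proteins.
#' @param protein_length residues per protein.
#' @param motif_spec named list of counts per planted class, e.g.
#'   `list(PX_PLUS_P = 12, CLASS_II = 0, CLASS_I = 0)`; the remainder of
#'   the proteome is motif-free.
#' @param seed integer seed (byte-identical output for equal seeds).
#' @param composition `"uniform"` or `"swissprot"`.
#' @return List with `proteome` (list of [protein_sequence()], ids
#'   `SYN0001` ...) and `truth` (data.frame: `protein_id`, `start`, `end`,
#'   `class`, `window`, `planted`).
#' @export
gen_proteome <- function(n_proteins = 50L, protein_length = 200L,
                         motif_spec = list(PX_PLUS_P = 12L, CLASS_II = 0L,
                                           CLASS_I = 0L),
                         seed = 1L,
                         composition = c("uniform", "swissprot")) {
  composition <- match.arg(composition)
  if (protein_length < 9L)
    stop("motif of 7 residues plus flanks is longer than ",
         "the requested sequence length")
  n_motif <- sum(unlist(motif_spec))
  if (n_motif > n_proteins)
    stop("more planted motifs than proteins")
  classes <- rep(names(motif_spec), unlist(motif_spec))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, "proteome"))

  proteome <- vector("list", n_proteins)
  truth_rows <- list()
  for (i in seq_len(n_proteins)) {
    id <- sprintf("SYN%04d", i)
    class_i <- if (i <= n_motif) classes[i] else NA_character_
    for (attempt in 1:100) {
      chars <- .sample_background(protein_length, composition)
      start <- NA_integer_
      if (!is.na(class_i)) {
        start <- sample(2:(protein_length - 7L), 1L)  # room for position -2
        chars[start:(start + 6L)] <- .motif_instance(class_i)
      }
      seq <- protein_sequence(id, paste(chars, collapse = ""))
      found <- .scan_all_classes(seq)
      keys <- unique(vapply(found, function(m)
        paste(m$start, m$prm_class), character(1L)))
      intended <- if (is.na(class_i)) character(0) else {
        k <- paste(start, class_i)
        # a planted Px+P also satisfies the class-II pattern at that start
        if (class_i == "PX_PLUS_P") c(k, paste(start, "CLASS_II")) else k
      }
      if (setequal(keys, intended)) break
      if (attempt == 100L)
        stop("could not generate a clean sequence for ", id)
    }
    proteome[[i]] <- seq
    if (!is.na(class_i)) {
      m <- found[[1L]]
      truth_rows[[id]] <- data.frame(
        protein_id = id, start = start, end = start + 6L, class = class_i,
        window = paste(chars[start:(start + 6L)], collapse = ""),
        planted = TRUE, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), class = character(0), window = character(0),
               planted = logical(0))
  rownames(truth) <- NULL
  names(proteome) <- vapply(proteome, `[[`, character(1L), "id")
  list(proteome = proteome, truth = truth, seed = seed)
}

#' Generate an annotation table with optional planted term enrichment
#'
#' Localization labels are assigned from designated id sets; ontology-like
#' terms are sampled per protein with a base rate, and planted terms with
#' boosted odds among a target set, recording the expected enrichment
#' direction in the truth attribute.
#'
#' @param protein_ids character vector of all proteins to annotate.
#' @param cyto_ids ids labelled cytoplasmic (`"cytoplasm"`); the rest draw
#'   from `other_labels`.
#' @param other_labels non-cytoplasmic localization pool.
#' @param term_spec `NULL`, or a list with `base_rate` (background
#'   annotation probability), `terms` (character vector of term ids),
#'   `planted` (named numeric: term id -> odds multiplier among
#'   `target_ids`), `target_ids`.
#' @param seed integer seed.
#' @return data.frame (`protein_id`, `localization`, `terms`,
#'   `ortholog_set`) with attribute `truth` describing planted enrichment.
#' @export
gen_annotations <- function(protein_ids, cyto_ids = character(0),
                            other_labels = c("nucleus", "membrane",
                                             "secreted"),
                            term_spec = NULL, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, "annotations"))
  if (length(protein_ids) == 0L)
    return(structure(data.frame(protein_id = character(0),
                                localization = character(0),
                                terms = character(0),
                                ortholog_set = character(0)),
                     truth = NULL))
  loc <- ifelse(protein_ids %in% cyto_ids, "cytoplasm",
                sample(other_labels, length(protein_ids), replace = TRUE))
  terms <- rep("", length(protein_ids))
  truth <- NULL
  if (!is.null(term_spec)) {
    if (!is.null(term_spec$base_rate) &&
        (term_spec$base_rate < 0 || term_spec$base_rate > 1))
      stop("base_rate must be in [0, 1]")
    base <- term_spec$base_rate
    assigned <- vector("list", length(protein_ids))
    for (term in term_spec$terms) {
      odds <- if (!is.null(term_spec$planted) &&
                  term %in% names(term_spec$planted))
        term_spec$planted[[term]] else 1
      # boosted membership probability among the target set at the given
      # odds ratio: p1 = odds*p0 / (1 - p0 + odds*p0)
      p1 <- odds * base / (1 - base + odds * base)
      p <- ifelse(protein_ids %in% term_spec$target_ids, p1, base)
      hit <- stats::runif(length(protein_ids)) < p
      for (j in which(hit))
        assigned[[j]] <- c(assigned[[j]], term)
    }
    terms <- vapply(assigned, function(t)
      paste(t, collapse = "|"), character(1L))
    truth <- list(planted_terms = names(term_spec$planted),
                  target_ids = term_spec$target_ids,
                  base_rate = base)
  }
  structure(data.frame(protein_id = protein_ids, localization = loc,
                       terms = terms, ortholog_set = protein_ids,
                       stringsAsFactors = FALSE),
            truth = truth)
}

#' Parse a term map from an annotation table
#'
#' @param annotations data.frame from [gen_annotations()] (or the same
#'   TSV layout, with pipe-separated `terms`).
#' @return Named list: term id -> character vector of protein ids.
#' @export
term_map_from_annotations <- function(annotations) {
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    if (!nzchar(annotations$terms[i])) next
    for (t in strsplit(annotations$terms[i], "|", fixed = TRUE)[[1L]])
      out[[t]] <- c(out[[t]], annotations$protein_id[i])
  }
  out
}

#' Generate ortholog sets with controlled motif conservation
#'
#' Per protein, `k` ortholog sequences with i.i.d. substitutions at the
#' given rate. When the motif is conserved, substitutions avoid the motif
#' window (register positions -1..5); otherwise at least one window
#' position is forcibly mutated in strictly more than 20% of the
#' orthologs, so a 0.8 identity-fraction threshold fails.
#'
#' @param proteome list of [protein_sequence()] (as from [gen_proteome()]).
#' @param truth truth table from [gen_proteome()] (locates motif windows).
#' @param k orthologs per protein (>= 1).
#' @param substitution_rate per-position substitution probability in
#'   `[0, 1]`.
#' @param conserve_motif single logical or named logical vector by protein
#'   id.
#' @param seed integer seed.
#' @return Named list (by protein id) of character vectors of ortholog
#'   sequences.
#' @export
gen_ortholog_sets <- function(proteome, truth, k = 5L,
                              substitution_rate = 0.1,
                              conserve_motif = TRUE, seed = 1L) {
  if (k < 1L) stop("at least one ortholog per protein is required")
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, "orthologs"))
  out <- list()
  for (seq in proteome) {
    id <- seq$id
    chars <- seq_chars(seq)
    conserve <- if (length(conserve_motif) == 1L) conserve_motif else
      isTRUE(conserve_motif[[id]])
    trow <- truth[truth$protein_id == id, , drop = FALSE]
    window <- if (nrow(trow) > 0L)
      trow$start[1L]:(trow$start[1L] + 6L) else integer(0)
    n_mutated <- ceiling(k * 0.4)  # > 20% of orthologs get a motif hit
    orths <- character(k)
    for (j in seq_len(k)) {
      oc <- chars
      sub_at <- which(stats::runif(length(oc)) < substitution_rate)
      if (conserve) sub_at <- setdiff(sub_at, window)
      for (p in sub_at)
        oc[p] <- sample(setdiff(AA_STANDARD, oc[p]), 1L)
      if (!conserve && length(window) > 0L && j <= n_mutated) {
        p <- sample(window, 1L)
        oc[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1L)
      }
      orths[j] <- paste(oc, collapse = "")
    }
    out[[id]] <- orths
  }
  out
}

# ---- coordinate builder ----------------------------------------------------

# place atom D bonded to C with bond length r, angle theta (B-C-D, degrees)
# and dihedral chi (A-B-C-D, degrees) -- the NeRF construction
.place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  # out-of-plane sign chosen so the resulting torsion A-B-C-D equals chi
  # under the IUPAC convention used by compute_dihedrals()
  d_local <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# ideal-geometry backbone (N, CA, C per residue) at constant (phi, psi)
.build_backbone <- function(n_res, phi, psi, omega = 180) {
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7
  coords <- array(NA_real_, dim = c(n_res, 3L, 3L),
                  dimnames = list(NULL, c("N", "CA", "C"), NULL))
  coords[1, "N", ] <- c(0, 0, 0)
  coords[1, "CA", ] <- c(b_NCa, 0, 0)
  th <- a_NCaC * pi / 180
  coords[1, "C", ] <- coords[1, "CA", ] +
    b_CaC * c(-cos(th), sin(th), 0)
  for (i in 2:n_res) {
    coords[i, "N", ] <- .place_atom(coords[i - 1, "N", ],
                                    coords[i - 1, "CA", ],
                                    coords[i - 1, "C", ],
                                    b_CN, a_CaCN, psi)
    coords[i, "CA", ] <- .place_atom(coords[i - 1, "CA", ],
                                     coords[i - 1, "C", ],
                                     coords[i, "N", ],
                                     b_NCa, a_CNCa, omega)
    coords[i, "C", ] <- .place_atom(coords[i - 1, "C", ],
                                    coords[i, "N", ],
                                    coords[i, "CA", ],
                                    b_CaC, a_NCaC, phi)
  }
  coords
}

.cb_position <- function(N, CA, C) {
  .place_atom(N, C, CA, 1.53, 110.5, -122)
}

.AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
             X = "UNK")

#' Generate an idealized SH3/peptide complex fixture
#'
#' Builds the peptide backbone from ideal bond geometry at the requested
#' conformation (polyproline-II: phi = -75, psi = +145; alpha: -60, -45),
#' adds CB atoms and pseudo sidechain tips (NZ for Lys, NH1 for Arg), and
#' emits a pseudo-SH3 chain of marker atoms at planted distances: one
#' aromatic-ring pseudo-atom 3.5 A from each anchor-proline CB (P0 and
#' P3), and acidic carboxylate oxygens 3.2 A from the position-2 and
#' position-5 sidechain nitrogens. The pseudo-pocket is a minimal atom
#' cloud, not a folded domain: the contact, salt-bridge and register logic
#' needs distances, not a fold.
#'
#' @param peptide_seq peptide sequence (one-letter codes); must contain a
#'   scannable class-II motif unless `register_p0` is given.
#' @param register_p0 optional 1-based index of the anchor proline P0 used
#'   for marker placement (defaults to the first [scan_class2()] match;
#'   positions without prolines are rejected).
#' @param conformation `"PPII"` or `"ALPHA"`.
#' @param path output PDB path.
#' @param seed integer seed (reserved for jitter; geometry is currently
#'   deterministic).
#' @return List with `path`, and `truth`: the planted `register`
#'   ([prm_register()]), `phi`/`psi`, `sh3_chain`/`peptide_chain` ids,
#'   `aromatic_resno` (pseudo-SH3 groove residues) and `salt_bridges`
#'   (expected basic/acidic residue pairs).
#' @export
gen_ppii_fixture <- function(peptide_seq, register_p0 = NULL,
                             conformation = c("PPII", "ALPHA"),
                             path = tempfile(fileext = ".pdb"),
                             seed = 1L) {
  conformation <- match.arg(conformation)
  pep <- protein_sequence("peptide", peptide_seq)
  chars <- seq_chars(pep)
  n <- length(chars)
  if (is.null(register_p0)) {
    m <- scan_class2(pep)
    if (length(m) == 0L)
      stop("peptide contains no scannable class-II motif; give register_p0")
    register_p0 <- m[[1L]]$register[["0"]]
  }
  if (chars[register_p0] != "P" || register_p0 + 3L > n ||
      chars[register_p0 + 3L] != "P")
    stop("register inconsistent with sequence: P0/P3 positions must be proline")
  register <- prm_register(register_p0, n)

  angles <- switch(conformation, PPII = c(-75, 145), ALPHA = c(-60, -45))
  bb <- .build_backbone(n, angles[1L], angles[2L])

  atoms <- list()
  add <- function(chain, resno, resid, elety, elesy, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  tip <- rep(list(NULL), n)  # sidechain tip atom per residue, if any
  for (i in seq_len(n)) {
    resid <- .AA1TO3[[chars[i]]]
    add("B", i, resid, "N", "N", bb[i, "N", ])
    add("B", i, resid, "CA", "C", bb[i, "CA", ])
    add("B", i, resid, "C", "C", bb[i, "C", ])
    if (chars[i] != "G") {
      cb <- .cb_position(bb[i, "N", ], bb[i, "CA", ], bb[i, "C", ])
      add("B", i, resid, "CB", "C", cb)
      if (chars[i] %in% c("K", "R")) {
        dir <- cb - bb[i, "CA", ]
        dir <- dir / sqrt(sum(dir^2))
        t <- cb + 2.5 * dir
        nm <- if (chars[i] == "K") "NZ" else "NH1"
        add("B", i, resid, nm, "N", t)
        tip[[i]] <- t
      }
    }
  }

  # pseudo-SH3 chain A: aromatic markers by the anchor-proline CBs,
  # acidic oxygens by the position-2/5 sidechain nitrogens
  cb_of <- function(i) {
    .cb_position(bb[i, "N", ], bb[i, "CA", ], bb[i, "C", ])
  }
  away <- function(i, p) {
    d <- p - bb[i, "CA", ]
    d / sqrt(sum(d^2))
  }
  p0 <- register_p0; p3 <- register_p0 + 3L
  arom_resno <- c(1L, 2L)
  for (j in seq_along(c(p0, p3))) {
    i <- c(p0, p3)[j]
    cb <- cb_of(i)
    add("A", arom_resno[j], "PHE", "CZ", "C", cb + 3.5 * away(i, cb))
  }
  salt <- list()
  acid_resno <- 3L
  for (pos in c("2", "5")) {
    i <- register[[pos]]
    if (!is.na(i) && !is.null(tip[[i]])) {
      resid <- if (pos == "2") "ASP" else "GLU"
      elety <- if (pos == "2") "OD1" else "OE1"
      add("A", acid_resno, resid, elety, "O",
          tip[[i]] + 3.2 * away(i, tip[[i]]))
      salt[[length(salt) + 1L]] <- data.frame(
        basic_resno = i, basic_resid = .AA1TO3[[chars[i]]],
        acidic_resno = acid_resno, acidic_resid = resid,
        stringsAsFactors = FALSE)
      acid_resno <- acid_resno + 1L
    }
  }
  at <- do.call(rbind, atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, elesy = at$elesy,
                   eleno = seq_len(nrow(at)), o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  list(path = path,
       truth = list(register = register, phi = angles[1L], psi = angles[2L],
                    conformation = conformation,
                    sh3_chain = "A", peptide_chain = "B",
                    aromatic_resno = arom_resno,
                    salt_bridges = if (length(salt) > 0L)
                      do.call(rbind, salt) else NULL))
}

#' Generate a complete planted screen dataset
#'
#' Orchestrates [gen_proteome()], [gen_annotations()], a per-residue
#' dihedral table and [gen_ortholog_sets()] into one dataset with nested
#' planted subsets: of `n_motif` Px+P-carrying proteins, `n_cyto` are
#' cytoplasmic, of those `n_ppii` have their motif window in PPII
#' conformation, and of those `n_conserved` have the window conserved
#' across orthologs — so the expected survivor count of the full cascade
#' is `n_conserved`. Per-protein expected filter outcomes are recorded in
#' the truth table.
#'
#' @param n_proteins,n_motif,n_cyto,n_ppii,n_conserved nested counts
#'   (each must not exceed the previous).
#' @param protein_length residues per protein.
#' @param k_orthologs orthologs per protein.
#' @param seed integer seed.
#' @return List with `proteome`, `annotations`, `dihedrals`, `orthologs`,
#'   and `truth` (data.frame with per-protein expected flags `motif`,
#'   `cyto`, `ppii`, `conserved`).
#' @export
gen_screen_dataset <- function(n_proteins = 50L, n_motif = 12L, n_cyto = 8L,
                               n_ppii = 6L, n_conserved = 5L,
                               protein_length = 200L,
                               k_orthologs = 5L, seed = 1L) {
  if (!(n_conserved <= n_ppii && n_ppii <= n_cyto && n_cyto <= n_motif &&
        n_motif <= n_proteins))
    stop("counts must be nested: conserved <= ppii <= cyto <= motif <= total")
  gp <- gen_proteome(n_proteins, protein_length,
                     motif_spec = list(PX_PLUS_P = n_motif), seed = seed)
  ids <- names(gp$proteome)
  motif_ids <- gp$truth$protein_id
  cyto_ids <- motif_ids[seq_len(n_cyto)]
  ppii_ids <- cyto_ids[seq_len(n_ppii)]
  cons_ids <- ppii_ids[seq_len(n_conserved)]

  ann <- gen_annotations(ids, cyto_ids = cyto_ids, seed = seed)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(stream_seed(seed, "dihedrals"))
  dih_rows <- lapply(ids, function(id) {
    phi <- -63 + stats::runif(protein_length, -5, 5)
    psi <- -43 + stats::runif(protein_length, -5, 5)
    if (id %in% ppii_ids) {
      st <- gp$truth$start[gp$truth$protein_id == id][1L]
      win <- st:(st + 6L)
      phi[win] <- -75 + stats::runif(7L, -3, 3)
      psi[win] <- 145 + stats::runif(7L, -3, 3)
    }
    data.frame(protein_id = id, residue = seq_len(protein_length),
               phi = phi, psi = psi, stringsAsFactors = FALSE)
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  dihedrals <- do.call(rbind, dih_rows)

  conserve <- stats::setNames(ids %in% cons_ids, ids)
  orthologs <- gen_ortholog_sets(gp$proteome, gp$truth, k = k_orthologs,
                                 conserve_motif = as.list(conserve),
                                 seed = seed)

  truth <- data.frame(
    protein_id = ids,
    motif = ids %in% motif_ids,
    cyto = ids %in% cyto_ids,
    ppii = ids %in% ppii_ids,
    conserved = ids %in% cons_ids,
    stringsAsFactors = FALSE)
  list(proteome = gp$proteome, annotations = ann, dihedrals = dihedrals,
       orthologs = orthologs, truth = truth, motif_truth = gp$truth,
       seed = seed)
}
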