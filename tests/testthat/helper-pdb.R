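# minimal hand-rolled PDB writer for fixtures built inside tests, kept
# independent of the package's (bio3d-based) structure I/O
write_test_pdb <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    alt <- if (!is.null(atoms$alt)) a$alt else ""
    occ <- if (!is.null(atoms$o)) a$o else 1
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$elety, alt, a$resid, a$chain, a$resno, a$x, a$y, a$z, occ, 0,
      a$element)
  }
  writeLines(c(lines, "END"), path)
  path
}

test_atom <- function(chain, resno, resid, elety, element, x, y, z,
                      alt = "", o = 1) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = element, x = x, y = y, z = z, alt = alt, o = o,
             stringsAsFactors = FALSE)
}

# random peptide carrying one Px+P motif at a known position, flanked by
# residues that cannot extend or duplicate the pattern
random_motif_peptide <- function() {
  flank <- function(n) sample(c("A", "G", "S", "T", "L", "V"), n,
                              replace = TRUE)
  n_pre <- sample(2:4, 1L)
  n_post <- sample(2:4, 1L)
  core <- c("A", "P", sample(c("A", "S", "G"), 1L), sample(c("K", "R"), 1L),
            "P", sample(c("A", "S", "G"), 1L), sample(c("K", "R"), 1L))
  list(seq = paste(c(flank(n_pre), core, flank(n_post)), collapse = ""),
       p0 = n_pre + 2L)
}
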