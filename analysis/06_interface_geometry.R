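#!/usr/bin/env Rscript
# Analyze the idealized SH3/peptide complex fixture: interface contacts,
# the planted salt bridges (position-2 and position-5 basic tips paired
# with the pseudo-pocket acidic oxygens), backbone PPII geometry, and the
# structure-derived motif register.

suppressMessages(library(sh3ags))
dir.create("results", showWarnings = FALSE)

fx <- gen_ppii_fixture("GALPAKPARSG", path = "results/complex_fixture.pdb")
atoms <- read_structure(fx$path)
rep <- interface_report(atoms, "A", "B",
                        list(aromatic_resno = fx$truth$aromatic_resno))
write_interface_report(rep, "results/interface_report.json")
write.table(rep$contacts, "results/contacts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message(sprintf("contacts: %d pairs within 4.5 A", nrow(rep$contacts)))
sb <- rep$salt_bridges
for (i in seq_len(nrow(sb)))
  message(sprintf("salt bridge: %s%d (peptide) -- %s%d (pocket), %.2f A",
                  sb$basic_resid[i], sb$basic_resno[i], sb$acidic_resid[i],
                  sb$acidic_resno[i], sb$min_distance[i]))
interior <- !is.na(rep$dihedrals$phi) & !is.na(rep$dihedrals$psi)
message(sprintf("peptide PPII residues: %d/%d interior",
                sum(rep$ppii_flags[interior]), sum(interior)))
reg <- rep$structure_register
message(sprintf("register: P0 at residue %d, P3 at residue %d (mismatch: %s)",
                reg$register[["0"]], reg$register[["3"]], reg$mismatch))
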