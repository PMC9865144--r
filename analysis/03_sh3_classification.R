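#!/usr/bin/env Rscript
# Classify SH3 domains by their RT-loop diagnostic sites: the bundled
# AGS-type reference, a SEM5-like canonical fixture, and the full panel of
# single-site diagnostic mutants (groove-center C -> F, acidic D -> K),
# which must each flip the AGS call to canonical.

suppressMessages(library(sh3ags))
dir.create("results", showWarnings = FALSE)

ref <- ags_reference()
mutate <- function(idx, to, id) {
  ch <- strsplit(ref$seq$residues, "")[[1L]]
  ch[idx] <- to
  sh3_domain(id, paste(ch, collapse = ""), ref$seq$numbering_offset)
}
domains <- list(
  ref$seq,
  sem5_like_sh3(),
  mutate(ref$groove_center, "F", "groove_center_C_to_F"),
  mutate(ref$acidic, "K", "acidic_D_to_K"),
  mutate(ref$acidic, "E", "acidic_D_to_E"))

tab <- classify_sh3_domains(domains, ref)
write.table(tab, "results/sh3_classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (i in seq_len(nrow(tab)))
  message(sprintf("%-28s %-10s groove=%s acidic=%s aromatics=%d/4",
                  tab$id[i], tab$class[i], tab$groove_center_res[i],
                  tab$acidic_res[i], tab$aromatics_present[i]))
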