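test_that("generated proteomes are deterministic and exactly match their truth", {
  gp1 <- gen_proteome(n_proteins = 20L, motif_spec = list(PX_PLUS_P = 6L),
                      seed = 7)
  gp2 <- gen_proteome(n_proteins = 20L, motif_spec = list(PX_PLUS_P = 6L),
                      seed = 7)
  expect_identical(vapply(gp1$proteome, `[[`, character(1L), "residues"),
                   vapply(gp2$proteome, `[[`, character(1L), "residues"))
  gp3 <- gen_proteome(n_proteins = 20L, motif_spec = list(PX_PLUS_P = 6L),
                      seed = 8)
  expect_false(identical(
    vapply(gp1$proteome, `[[`, character(1L), "residues"),
    vapply(gp3$proteome, `[[`, character(1L), "residues")))

  # scanner output equals the truth table: no hidden positives anywhere
  found <- do.call(rbind, lapply(gp1$proteome, function(s) {
    m <- scan_pxplusp(s)
    if (length(m) == 0L) return(NULL)
    data.frame(protein_id = s$id, start = match_starts(m))
  }))
  expect_equal(nrow(found), 6L)
  expect_setequal(paste(found$protein_id, found$start),
                  paste(gp1$truth$protein_id, gp1$truth$start))
})

test_that("mixed-class plantings are each recovered by their own scanner", {
  gp <- gen_proteome(n_proteins = 15L,
                     motif_spec = list(PX_PLUS_P = 4L, CLASS_II = 3L,
                                       CLASS_I = 2L), seed = 21)
  expect_equal(table(gp$truth$class)[["PX_PLUS_P"]], 4L)
  for (i in seq_len(nrow(gp$truth))) {
    row <- gp$truth[i, ]
    seq <- gp$proteome[[row$protein_id]]
    scanner <- switch(row$class, PX_PLUS_P = scan_pxplusp,
                      CLASS_II = scan_class2, CLASS_I = scan_class1)
    expect_true(row$start %in% match_starts(scanner(seq)))
  }
})

test_that("a proteome with no plantings scans clean", {
  gp <- gen_proteome(n_proteins = 10L, motif_spec = list(PX_PLUS_P = 0L),
                     seed = 3)
  expect_equal(nrow(gp$truth), 0L)
  hits <- sum(vapply(gp$proteome, function(s)
    length(scan_pxplusp(s)) + length(scan_class2(s)) +
      length(scan_class1(s)), integer(1L)))
  expect_equal(hits, 0L)
})

test_that("generator input validation rejects impossible requests", {
  expect_error(gen_proteome(protein_length = 5L), "longer")
  expect_error(gen_proteome(n_proteins = 2L,
                            motif_spec = list(PX_PLUS_P = 5L)), "more planted")
  expect_error(gen_annotations("p1", term_spec = list(base_rate = 1.5,
                                                      terms = "T")),
               "base_rate")
  expect_error(gen_ortholog_sets(list(), data.frame(), k = 0L), "ortholog")
  expect_error(gen_ortholog_sets(list(), data.frame(),
                                 substitution_rate = 2), "rate")
})

test_that("annotation tables mark the designated cytoplasmic proteins", {
  ids <- sprintf("P%02d", 1:10)
  ann <- gen_annotations(ids, cyto_ids = ids[1:4], seed = 2)
  expect_equal(ann$localization[1:4], rep("cytoplasm", 4))
  expect_false(any(ann$localization[5:10] == "cytoplasm"))
  expect_equal(nrow(gen_annotations(character(0))), 0L)
})

test_that("planted term enrichment is recoverable and reads back as a term map", {
  ids <- sprintf("P%03d", 1:200)
  target <- ids[1:40]
  ann <- gen_annotations(ids, term_spec = list(
    base_rate = 0.1, terms = c("T_planted", "T_null"),
    planted = c(T_planted = 5), target_ids = target), seed = 11)
  tm <- term_map_from_annotations(ann)
  res <- hypergeom_enrich(target, ids, tm)
  expect_true(res$passes_thresholds[res$term == "T_planted"])
  expect_gt(res$enrichment_factor[res$term == "T_planted"],
            res$enrichment_factor[res$term == "T_null"])
})

test_that("ortholog sets respect the conservation switch", {
  gp <- gen_proteome(n_proteins = 4L, motif_spec = list(PX_PLUS_P = 4L),
                     seed = 13)
  win_identity <- function(orths, seq, start) {
    idx <- start:(start + 6L)
    src <- substr(seq$residues, start, start + 6L)
    mean(vapply(orths, function(o)
      identical(substr(o, start, start + 6L), src), logical(1L)))
  }
  cons <- gen_ortholog_sets(gp$proteome, gp$truth, k = 5L,
                            substitution_rate = 0.1, conserve_motif = TRUE,
                            seed = 1)
  not <- gen_ortholog_sets(gp$proteome, gp$truth, k = 5L,
                           substitution_rate = 0.1, conserve_motif = FALSE,
                           seed = 1)
  for (id in names(gp$proteome)) {
    st <- gp$truth$start[gp$truth$protein_id == id]
    expect_equal(win_identity(cons[[id]], gp$proteome[[id]], st), 1.0)
    expect_lt(win_identity(not[[id]], gp$proteome[[id]], st), 0.8)
  }
  # zero substitution rate reproduces the source sequences
  zero <- gen_ortholog_sets(gp$proteome, gp$truth, k = 3L,
                            substitution_rate = 0, conserve_motif = TRUE,
                            seed = 1)
  expect_true(all(zero[[1L]] == gp$proteome[[1L]]$residues))
})

test_that("fixture generation is deterministic and validates its register", {
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  gen_ppii_fixture("GALPAKPARSG", path = p1)
  gen_ppii_fixture("GALPAKPARSG", path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(gen_ppii_fixture("GALAAKAARSG"), "scannable")
  expect_error(gen_ppii_fixture("GALPAKPARSG", register_p0 = 2L),
               "inconsistent")
})

test_that("stream seeds are deterministic, distinct, and within integer range", {
  expect_identical(stream_seed(7L, "proteome"), stream_seed(7L, "proteome"))
  expect_false(stream_seed(7L, "proteome") == stream_seed(7L, "orthologs"))
  for (s in c(1L, 1000L, 123456L))
    for (st in c("proteome", "annotations", "dihedrals"))
      expect_lt(stream_seed(s, st), 2^31)
})

test_that("the nested screen dataset encodes its planted counts in the truth", {
  ds <- gen_screen_dataset(n_proteins = 30L, n_motif = 8L, n_cyto = 6L,
                           n_ppii = 4L, n_conserved = 3L, seed = 2)
  expect_equal(colSums(ds$truth[, c("motif", "cyto", "ppii", "conserved")]),
               c(motif = 8, cyto = 6, ppii = 4, conserved = 3))
  # nesting: conserved proteins are ppii, ppii are cyto, cyto carry motifs
  expect_true(all(!ds$truth$conserved | ds$truth$ppii))
  expect_true(all(!ds$truth$ppii | ds$truth$cyto))
  expect_true(all(!ds$truth$cyto | ds$truth$motif))
  expect_error(gen_screen_dataset(n_motif = 2L, n_cyto = 5L), "nested")
})
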