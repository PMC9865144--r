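test_that("the planted cascade yields the truth-table survivors", {
  ds <- gen_screen_dataset(seed = 7)
  res <- run_screen(ds$proteome, ds$annotations, ds$dihedrals, ds$orthologs)
  truth_pass <- ds$truth$protein_id[ds$truth$conserved]
  expect_setequal(res$summary$passing_ids, truth_pass)
  expect_equal(res$summary$final_passes, sum(ds$truth$conserved))
  # audit: eliminated per stage + final passes = motif-positive proteins
  expect_equal(sum(res$summary$eliminated) + res$summary$final_passes,
               res$summary$motif_proteins)
  expect_equal(res$summary$motif_proteins, sum(ds$truth$motif))
})

test_that("every filter subset matches truth and filters are monotone", {
  ds <- gen_screen_dataset(seed = 19)
  all_filters <- c("localization", "ppii", "conservation")
  subsets <- list(character(0), "localization", "ppii", "conservation",
                  c("localization", "ppii"), c("localization", "conservation"),
                  c("ppii", "conservation"), all_filters)
  truth_count <- function(filters) {
    keep <- ds$truth$motif
    if ("localization" %in% filters) keep <- keep & ds$truth$cyto
    if ("ppii" %in% filters) keep <- keep & ds$truth$ppii
    if ("conservation" %in% filters) keep <- keep & ds$truth$conserved
    sum(keep)
  }
  passes <- vapply(subsets, function(f) {
    run_screen(ds$proteome, ds$annotations, ds$dihedrals, ds$orthologs,
               screen_config(filters = f))$summary$final_passes
  }, numeric(1L))
  expect_equal(passes, vapply(subsets, truth_count, numeric(1L)))
  # monotonicity: adding a filter never increases the survivor count
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    if (all(subsets[[i]] %in% subsets[[j]]))
      expect_lte(passes[j], passes[i])
  }
})

test_that("with all filters disabled the screen reduces to the scanner", {
  ds <- gen_screen_dataset(seed = 3)
  res <- run_screen(ds$proteome, ds$annotations, ds$dihedrals, ds$orthologs,
                    screen_config(filters = character(0)))
  scanned <- names(Filter(function(s) length(scan_pxplusp(s)) > 0L,
                          ds$proteome))
  expect_setequal(res$summary$passing_ids, scanned)
  expect_equal(nrow(run_screen(list())$candidates), 0L)
})

test_that("missing annotation data fails closed by default and open on request", {
  gp <- gen_proteome(n_proteins = 3L, motif_spec = list(PX_PLUS_P = 3L),
                     seed = 5)
  ann <- data.frame(protein_id = names(gp$proteome)[1:2],
                    localization = c("cytoplasm", "cytoplasm"),
                    terms = "", ortholog_set = names(gp$proteome)[1:2])
  closed <- run_screen(gp$proteome, ann,
                       config = screen_config(filters = "localization"))
  expect_equal(closed$summary$final_passes, 2L)  # third protein unannotated
  open <- run_screen(gp$proteome, ann,
                     config = screen_config(filters = "localization",
                                            fail_open = TRUE))
  expect_equal(open$summary$final_passes, 3L)
})

test_that("hypergeometric p-values match exact enumeration on a grid", {
  for (N in seq(10, 60, by = 10)) {
    for (K in unique(c(1, N %/% 4, N %/% 2))) {
      for (n in unique(c(2, N %/% 5, N %/% 2))) {
        for (k in 0:min(K, n)) {
          universe <- sprintf("u%02d", 1:N)
          term <- universe[1:K]
          selected <- c(universe[seq_len(k)],
                        setdiff(universe, term)[seq_len(n - k)])
          res <- hypergeom_enrich(selected, universe,
                                  list(T = term))
          expect_equal(res$p, oracle_hyper_tail(k, K, N, n),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("enrichment thresholds and edge cases follow the published criteria", {
  universe <- sprintf("u%03d", 1:100)
  term <- universe[1:10]
  selected <- c(universe[1:5], universe[51:55])   # k=5 of n=10, K=10, N=100
  res <- hypergeom_enrich(selected, universe, list(T1 = term))
  expect_equal(res$enrichment_factor, 5.0)
  expect_equal(res$p, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_true(res$passes_thresholds)

  # degenerate: everything selected and annotated
  all_res <- hypergeom_enrich(universe, universe, list(T = universe))
  expect_equal(all_res$p, 1.0)
  expect_equal(all_res$enrichment_factor, 1.0)
  expect_false(all_res$passes_thresholds)

  # k = 2 fails the minimum count even when p and factor pass
  small <- hypergeom_enrich(universe[1:2], universe, list(T = universe[1:2]))
  expect_lt(small$p, 0.01)
  expect_gt(small$enrichment_factor, 1.5)
  expect_false(small$passes_thresholds)

  # selected must be inside the universe; empty terms are skipped
  expect_error(hypergeom_enrich(c("u001", "zzz"), universe, list(T = term)),
               "zzz")
  expect_equal(nrow(hypergeom_enrich(universe[1:5], universe,
                                     list(T = character(0)))), 0L)
})

test_that("BH q-values are computed and are monotone in p-rank", {
  universe <- sprintf("u%03d", 1:60)
  set.seed(1)
  term_map <- lapply(stats::setNames(1:8, paste0("T", 1:8)),
                     function(i) sample(universe, 12))
  res <- hypergeom_enrich(sample(universe, 15), universe, term_map)
  expect_equal(res$p, sort(res$p))
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("network summaries count components, degrees and cross-class edges", {
  nodes <- c(A1 = "AGS", A2 = "AGS", A3 = "AGS",
             P1 = "PXPLUSP", P2 = "PXPLUSP", P3 = "PXPLUSP",
             P4 = "PXPLUSP", P5 = "PXPLUSP", P6 = "PXPLUSP")
  edges <- data.frame(
    from = c("A1", "A1", "A2", "A2", "A3", "A3"),
    to = c("P1", "P2", "P3", "P4", "P5", "P6"))
  nw <- build_network(edges, nodes)
  expect_equal(nw$cross_class_edges, 6L)
  expect_equal(nw$n_components, 3L)
  expect_equal(unname(nw$degree[c("A1", "P1")]), c(2, 1))

  lonely <- build_network(edges[0, ], nodes)
  expect_equal(lonely$n_components, length(nodes))

  expect_error(build_network(data.frame(from = "A1", to = "GHOST"), nodes),
               "GHOST")
})

test_that("component counts match a union-find oracle on random graphs", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:25, 1L)
    nodes <- stats::setNames(sample(c("AGS", "PXPLUSP"), n, replace = TRUE),
                             paste0("n", seq_len(n)))
    m <- sample(0:(2 * n), 1L)
    edges <- data.frame(from = sample(names(nodes), m, replace = TRUE),
                        to = sample(names(nodes), m, replace = TRUE))
    expect_equal(build_network(edges, nodes)$n_components,
                 oracle_components(names(nodes), edges))
  }
})
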