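# Proteome-wide Px+P candidate screen with a filter cascade
# (localization -> polyproline-II conformation -> ortholog conservation),
# hypergeometric term enrichment, and a simple interaction-network summary.

#' Default screen configuration
#'
#' @param filters character vector, any subset of `"localization"`,
#'   `"ppii"`, `"conservation"` (the motif requirement is intrinsic: only
#'   proteins with at least one Px+P match become candidates).
#' @param cyto_labels localization labels counted as cytoplasmic.
#' @param ppii_tol angular tolerance (degrees) passed to [is_ppii()].
#' @param conservation_threshold minimum fraction of orthologs whose
#'   aligned motif window (register positions -1..5) is identical.
#' @param fail_open logical; `TRUE` lets proteins missing annotation /
#'   dihedral / ortholog data pass the affected filter instead of failing
#'   it (fail-closed is the default policy).
#' @return A named list of settings.
#' @export
screen_config <- function(filters = c("localization", "ppii", "conservation"),
                          cyto_labels = c("cytoplasm", "cytosol"),
                          ppii_tol = 30,
                          conservation_threshold = 0.8,
                          fail_open = FALSE) {
  stopifnot(all(filters %in% c("localization", "ppii", "conservation")))
  list(filters = filters, cyto_labels = cyto_labels, ppii_tol = ppii_tol,
       conservation_threshold = conservation_threshold, fail_open = fail_open)
}

# fraction of orthologs whose residues at the motif window are identical to
# the source window (orthologs are position-aligned, equal-length sequences)
.window_conservation <- function(window_idx, source_chars, orthologs) {
  if (length(orthologs) == 0L) return(NA_real_)
  src <- paste(source_chars[window_idx], collapse = "")
  same <- vapply(orthologs, function(o) {
    oc <- strsplit(o, "", fixed = TRUE)[[1L]]
    if (max(window_idx) > length(oc)) return(FALSE)
    identical(paste(oc[window_idx], collapse = ""), src)
  }, logical(1L))
  mean(same)
}

#' Run the Px+P candidate screen over a proteome
#'
#' Stage 1 scans every protein with [scan_pxplusp()]; proteins with at
#' least one match become candidates. Stage 2 (localization) keeps
#' proteins whose localization labels intersect the configured cytoplasmic
#' set. Stage 3 (ppii) keeps matches whose register residues -1..5 are all
#' in PPII conformation according to the supplied per-residue dihedrals.
#' Stage 4 (conservation) keeps matches whose register window is identical
#' in at least the configured fraction of the protein's orthologs. Every
#' candidate retains all per-stage flags for audit; a protein passes when
#' at least one of its matches passes every enabled filter. Missing data
#' fails the affected filter unless `fail_open` is set.
#'
#' @param proteome list of [protein_sequence()] objects.
#' @param annotations data.frame with columns `protein_id`, `localization`
#'   (pipe-separated labels), optional `terms`, `ortholog_set`.
#' @param dihedrals data.frame with columns `protein_id`, `residue`,
#'   `phi`, `psi`, or `NULL`.
#' @param orthologs named list (by protein id) of character vectors of
#'   ortholog sequences, or `NULL`.
#' @param config a [screen_config()].
#' @return List with `candidates` (data.frame, one row per match, with
#'   per-filter flags and `final_pass`), and `summary` (per-stage
#'   elimination counts).
#' @export
run_screen <- function(proteome, annotations = NULL, dihedrals = NULL,
                       orthologs = NULL, config = screen_config()) {
  if (length(proteome) == 0L)
    return(list(candidates = .empty_candidates(), summary = NULL))
  rows <- list()
  for (seq in proteome) {
    matches <- scan_pxplusp(seq)
    if (length(matches) == 0L) next
    chars <- seq_chars(seq)
    ann <- if (!is.null(annotations))
      annotations[annotations$protein_id == seq$id, , drop = FALSE] else NULL
    has_ann <- !is.null(ann) && nrow(ann) > 0L
    loc_ok <- if (has_ann) {
      labels <- strsplit(ann$localization[1L], "|", fixed = TRUE)[[1L]]
      any(labels %in% config$cyto_labels)
    } else config$fail_open
    dih <- if (!is.null(dihedrals))
      dihedrals[dihedrals$protein_id == seq$id, , drop = FALSE] else NULL
    orth <- if (!is.null(orthologs)) orthologs[[seq$id]] else NULL
    for (m in matches) {
      win <- m$register[as.character(-1:5)]  # -1..5: the 7-residue window
      ppii_ok <- if (!is.null(dih) && nrow(dih) > 0L) {
        sub <- dih[match(win, dih$residue), , drop = FALSE]
        flags <- is_ppii(sub, tol = config$ppii_tol)
        !anyNA(flags) && all(flags)
      } else config$fail_open
      cons <- if (!is.null(orth))
        .window_conservation(win, chars, orth) else NA_real_
      cons_ok <- if (!is.na(cons)) cons >= config$conservation_threshold
        else config$fail_open
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = seq$id, start = m$start, end = m$end,
        window = m$window, motif = TRUE, localization = loc_ok,
        ppii = ppii_ok, conservation_fraction = cons,
        conservation = cons_ok, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(list(candidates = .empty_candidates(), summary = NULL))
  cand <- do.call(rbind, rows)
  enabled <- config$filters
  pass <- rep(TRUE, nrow(cand))
  if ("localization" %in% enabled) pass <- pass & cand$localization
  if ("ppii" %in% enabled) pass <- pass & cand$ppii
  if ("conservation" %in% enabled) pass <- pass & cand$conservation
  cand$final_pass <- pass

  per_protein <- tapply(cand$final_pass, cand$protein_id, any)
  motif_proteins <- unique(cand$protein_id)
  # cascade audit: proteins eliminated at each successive stage
  elim <- c()
  running <- rep(TRUE, nrow(cand))
  for (f in c("localization", "ppii", "conservation")) {
    if (!(f %in% enabled)) next
    before <- tapply(running, cand$protein_id, any)[motif_proteins]
    running <- running & cand[[f]]
    after <- tapply(running, cand$protein_id, any)[motif_proteins]
    elim[f] <- sum(before & !after)
  }
  list(candidates = cand,
       summary = list(motif_proteins = length(motif_proteins),
                      eliminated = elim,
                      final_passes = sum(per_protein),
                      passing_ids = names(per_protein)[per_protein]))
}

.empty_candidates <- function() {
  data.frame(protein_id = character(0), start = integer(0), end = integer(0),
             window = character(0), motif = logical(0),
             localization = logical(0), ppii = logical(0),
             conservation_fraction = numeric(0), conservation = logical(0),
             final_pass = logical(0), stringsAsFactors = FALSE)
}

#' Hypergeometric term-enrichment test
#'
#' For each term, tests whether the selected set is enriched relative to
#' the screened universe using the exact hypergeometric upper tail
#' (`P(X >= k)` with `k` selected-and-annotated out of `n` selected, `K`
#' annotated in a universe of `N`). Benjamini-Hochberg q-values are
#' reported in addition; the pass/fail call uses the three raw thresholds
#' only: p-value below `p_max`, count of at least `min_count`, and
#' enrichment factor `(k/n)/(K/N)` above `min_factor`.
#'
#' @param selected_ids character vector, the selected proteins (must be a
#'   subset of `universe_ids`).
#' @param universe_ids character vector, the screened universe.
#' @param term_map named list: term id -> character vector of annotated
#'   protein ids (terms with no annotated universe member are skipped).
#' @param p_max,min_count,min_factor pass thresholds (defaults 0.01, 3, 1.5).
#' @return data.frame with `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `enrichment_factor`, `passes_thresholds`, ordered by `p`.
#' @export
hypergeom_enrich <- function(selected_ids, universe_ids, term_map,
                             p_max = 0.01, min_count = 3,
                             min_factor = 1.5) {
  selected_ids <- unique(selected_ids)
  universe_ids <- unique(universe_ids)
  if (!all(selected_ids %in% universe_ids))
    stop("selected ids outside the universe: ",
         paste(utils::head(setdiff(selected_ids, universe_ids), 5L),
               collapse = ", "))
  N <- length(universe_ids)
  n <- length(selected_ids)
  rows <- list()
  for (term in names(term_map)) {
    members <- intersect(term_map[[term]], universe_ids)
    K <- length(members)
    if (K == 0L) next
    k <- length(intersect(members, selected_ids))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    ef <- (k / n) / (K / N)
    rows[[term]] <- data.frame(
      term = term, k = k, n = n, K = K, N = N, p = p,
      enrichment_factor = ef,
      passes_thresholds = (p < p_max) && (k >= min_count) &&
        (ef > min_factor),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), enrichment_factor = numeric(0),
                      passes_thresholds = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), c("term", "k", "n", "K", "N", "p", "q",
                             "enrichment_factor", "passes_thresholds")]
  rownames(out) <- NULL
  out
}

#' Summarize an interaction network of SH3-AGS and Px+P proteins
#'
#' Builds an undirected graph from a user-supplied edge list and reports
#' connected components, per-node degree, and the number of cross-class
#' edges between AGS-domain proteins and Px+P-motif proteins.
#'
#' @param edges data.frame with two character columns (`from`, `to`).
#' @param node_classes named character vector mapping every node id to a
#'   class label (e.g. `"AGS"` or `"PXPLUSP"`).
#' @return List with `n_nodes`, `n_edges`, `n_components`,
#'   `component_sizes`, `degree` (named vector), and `cross_class_edges`.
#' @export
build_network <- function(edges, node_classes) {
  nodes <- names(node_classes)
  if (nrow(edges) > 0L) {
    offenders <- setdiff(unique(c(edges[[1L]], edges[[2L]])), nodes)
    if (length(offenders) > 0L)
      stop("edges reference unknown nodes: ",
           paste(offenders, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  cls <- node_classes[igraph::V(g)$name]
  cross <- 0L
  if (nrow(edges) > 0L)
    cross <- sum(node_classes[edges[[1L]]] != node_classes[edges[[2L]]])
  list(n_nodes = length(nodes), n_edges = nrow(edges),
       n_components = comp$no,
       component_sizes = as.integer(comp$csize),
       degree = igraph::degree(g),
       cross_class_edges = as.integer(cross))
}
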