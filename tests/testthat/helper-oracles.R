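# Independent oracles used across the suite. These deliberately take
# different routes from the package implementation (explicit per-window
# character checks instead of regex; log-binomial tail enumeration instead
# of phyper; union-find instead of igraph; bio3d torsions instead of the
# package dihedral math).

STD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# brute-force PRM scanner: tests every 7-residue window character by
# character and returns the 1-based match starts
oracle_scan_starts <- function(residues, prm_class) {
  ch <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  L <- length(ch)
  if (L < 7L) return(integer(0))
  starts <- integer(0)
  for (s in 1:(L - 6L)) {
    w <- ch[s:(s + 6L)]
    if (any(!(w %in% STD_AA))) next
    ok <- switch(prm_class,
      class2  = w[2L] == "P" && w[5L] == "P" && (w[7L] == "K" || w[7L] == "R"),
      pxplusp = w[2L] == "P" && (w[4L] == "K" || w[4L] == "R") &&
        w[5L] == "P" && (w[7L] == "K" || w[7L] == "R"),
      class1  = (w[1L] == "K" || w[1L] == "R") && w[4L] == "P" &&
        w[7L] == "P",
      stop("unknown class"))
    if (ok) starts <- c(starts, s)
  }
  starts
}

# exact hypergeometric upper tail P(X >= k) by direct enumeration of the
# probability mass on log-binomial coefficients
oracle_hyper_tail <- function(k, K, N, n) {
  js <- max(k, 0):min(K, n)
  if (length(js) == 0L || k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# connected-component count via union-find
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (nrow(edges) > 0L) for (r in seq_len(nrow(edges))) {
    a <- find(match(edges[[1L]][r], nodes))
    b <- find(match(edges[[2L]][r], nodes))
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(seq_along(nodes), find, numeric(1L))))
}

# random test sequence with occasional unknown residues
random_sequence <- function(len, x_rate = 0.02) {
  paste(sample(c(STD_AA, "X"), len, replace = TRUE,
               prob = c(rep((1 - x_rate) / 20, 20), x_rate)),
        collapse = "")
}

match_starts <- function(matches) {
  vapply(matches, `[[`, integer(1L), "start")
}
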