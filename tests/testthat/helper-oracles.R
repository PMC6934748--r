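# Independent oracles used to check the implementation by a different
# route: naive per-position summations and exhaustive enumerations.

# Naive nearest-neighbor summation: walks the sequence one doublet at a
# time against the ten published unified values, canonicalising each
# doublet through its reverse complement by string reversal.
oracle_nn <- function(seq) {
  tab <- list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9)
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v <- strsplit(seq, "")[[1]]
  dh <- 0
  ds <- 0
  for (i in seq_len(length(v) - 1)) {
    d <- paste0(v[i], v[i + 1])
    if (is.null(tab[[d]])) {
      d <- paste0(comp[v[i + 1]], comp[v[i]])
    }
    dh <- dh + tab[[d]][1]
    ds <- ds + tab[[d]][2]
  }
  for (b in c(v[1], v[length(v)])) {
    if (b %in% c("G", "C")) {
      dh <- dh + 0.1
      ds <- ds - 2.8
    } else {
      dh <- dh + 2.3
      ds <- ds + 4.1
    }
  }
  c(dH = dh, dS = ds)
}

# Plain character-wise Hamming distance (no missing-data handling).
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Minimum spanning-tree weight by exhaustive enumeration of all
# (n-1)-edge subsets that connect the graph.
oracle_mst_weight <- function(n, edges) {
  # edges: data.frame(i, j, weight) over the complete graph
  best <- Inf
  subsets <- combn(nrow(edges), n - 1)
  for (c_i in seq_len(ncol(subsets))) {
    sel <- edges[subsets[, c_i], ]
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (k in seq_len(nrow(sel))) {
      ri <- find(sel$i[k])
      rj <- find(sel$j[k])
      if (ri != rj) parent[ri] <- rj
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1) {
      best <- min(best, sum(sel$weight))
    }
  }
  best
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small two-species alignment used across tests.
toy_alignment <- function() {
  as_barcode_alignment(tibble::tibble(
    specimen_id = c("a1", "a2", "b1", "b2"),
    species = c("A", "A", "B", "B"),
    #           pos:      012345678
    sequence = c(
      "ATGACGATC",
      "ATGACGATT",
      "ATAACGATC",
      "ATAACGATT"
    )
  ))
}

default_fixture <- function(seed = 1) {
  make_minibarcode_alignment(barcode_spec(seed = seed))
}

default_ranked <- function(aln = default_fixture(),
                           cond = thermo_conditions()) {
  score_and_rank(window_primer_pair(aln), collapse_haplotypes(aln), cond)
}
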