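# Column-wise diagnosis of a two-species alignment: fixed differences,
# shared (plesiomorphic) polymorphisms, substitution type, synonymy, and the
# haplotype minimum spanning network used to visualise them.

.species_pair <- function(aln, species_pair) {
  present <- unique(aln$species)
  if (is.null(species_pair)) {
    species_pair <- setdiff(present, "unknown")
    if (length(species_pair) < 2) species_pair <- present
    species_pair <- species_pair[1:2]
  }
  if (length(species_pair) != 2 || !all(species_pair %in% present)) {
    abort_hrmelt(
      sprintf(
        "both species labels must be present in the alignment (have: %s)",
        paste(present, collapse = ", ")
      ),
      "input_error"
    )
  }
  species_pair
}

# Synonymy of a polymorphic column, holding other sites at each observed
# codon background: synonymous iff no pair of observed codons that differ
# only at this column changes the encoded amino acid.
.site_synonymy <- function(codons, pos_in_codon, code) {
  codons <- unique(codons)
  codons <- codons[!str_detect(codons, "[N-]")]
  if (length(codons) < 2) {
    return(NA)
  }
  comparable <- FALSE
  for (i in seq_len(length(codons) - 1)) {
    for (j in seq(i + 1, length(codons))) {
      ci <- strsplit(codons[i], "", fixed = TRUE)[[1]]
      cj <- strsplit(codons[j], "", fixed = TRUE)[[1]]
      diffs <- which(ci != cj)
      if (identical(diffs, pos_in_codon)) {
        comparable <- TRUE
        if (code[[codons[i]]] != code[[codons[j]]]) {
          return(FALSE)
        }
      }
    }
  }
  if (comparable) TRUE else NA
}

#' Classify alignment columns for a species pair
#'
#' Each column is assigned a category:
#' * `monomorphic` - at most one non-missing state overall;
#' * `fixed_diagnostic` - both species observed, state sets disjoint
#'   (the columns that carry diagnostic power);
#' * `shared_polymorphic` - polymorphic overall with at least one state
#'   observed in both species (a plesiomorphy: contributes within-species
#'   melt variability but no diagnosis);
#' * `private_polymorphic` - polymorphic but only one species has data.
#'
#' `N` and `-` are treated as missing, not as states. Substitution kind is
#' `transition` (A/G or C/T), `transversion`, or `mixed` (three or more
#' states). Synonymy is evaluated by translating every observed codon
#' variant: a site is synonymous iff no pair of observed codons differing
#' only at that site changes the amino acid.
#'
#' @param aln A `barcode_alignment`.
#' @param species_pair Character vector of the two species labels to
#'   compare; defaults to the first two labels in the alignment.
#' @param code_table Genetic code for synonymy calls, see
#'   [translate_codons()].
#' @return A tibble with one row per column: `position` (0-based),
#'   `codon_position` (1/2/3), `category`, `substitution_kind`,
#'   `synonymous`, per-species state strings, and `n_states`.
#' @export
classify_sites <- function(aln, species_pair = NULL, code_table = "standard") {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  species_pair <- .species_pair(aln, species_pair)
  code <- .codon_tables(code_table)
  fo <- frame_offset(aln)
  m <- seq_matrix(aln$sequence)
  len <- ncol(m)
  rows_a <- aln$species == species_pair[1]
  rows_b <- aln$species == species_pair[2]

  per_col <- purrr::map(seq_len(len), function(j) {
    col <- m[, j]
    sa <- setdiff(unique(col[rows_a]), MISSING_STATES)
    sb <- setdiff(unique(col[rows_b]), MISSING_STATES)
    states <- union(sa, sb)
    category <- if (length(states) <= 1) {
      "monomorphic"
    } else if (length(sa) > 0 && length(sb) > 0 &&
      length(intersect(sa, sb)) == 0) {
      "fixed_diagnostic"
    } else if (length(intersect(sa, sb)) > 0) {
      "shared_polymorphic"
    } else {
      "private_polymorphic"
    }
    kind <- if (length(states) < 2) {
      "none"
    } else if (length(states) > 2) {
      "mixed"
    } else if (all(states %in% PURINES) || all(states %in% PYRIMIDINES)) {
      "transition"
    } else {
      "transversion"
    }
    in_frame <- j > fo && j <= fo + 3 * ((len - fo) %/% 3)
    codon_position <- if (in_frame) ((j - fo - 1L) %% 3L) + 1L else NA_integer_
    synonymous <- NA
    if (in_frame && category != "monomorphic") {
      codon_start <- fo + 3 * ((j - fo - 1) %/% 3) + 1
      codons <- apply(
        m[, codon_start:(codon_start + 2), drop = FALSE], 1, paste,
        collapse = ""
      )
      synonymous <- .site_synonymy(codons, codon_position, code)
    }
    tibble(
      position = j - 1L,
      codon_position = codon_position,
      category = category,
      substitution_kind = kind,
      synonymous = synonymous,
      states_a = paste(sort(sa), collapse = ","),
      states_b = paste(sort(sb), collapse = ","),
      n_states = length(states)
    )
  })
  out <- purrr::list_rbind(per_col)
  names(out)[names(out) == "states_a"] <- paste0("states_", species_pair[1])
  names(out)[names(out) == "states_b"] <- paste0("states_", species_pair[2])
  attr(out, "species_pair") <- species_pair
  out
}

#' Write the per-site classification as CSV
#'
#' @param sites Output of [classify_sites()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  readr::write_csv(sites, path)
  invisible(path)
}

#' Between-species divergence of haplotypes
#'
#' Hamming distances (ignoring positions with `N` or gaps in either
#' sequence) over all inter-species haplotype pairs. `mean_between` is the
#' unweighted mean over distinct haplotype pairs -- haplotype frequencies do
#' not enter, matching how divergence between a handful of representative
#' haplotypes is usually quoted. `fixed_count` is the number of columns
#' whose state sets are disjoint between the species.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param species_pair Two species labels; defaults to the two present.
#' @return An object of class `divergence_summary`: list with `matrix`
#'   (distances, species-A haplotypes in rows), `mean_between`,
#'   `fixed_count`, and `species_pair`.
#' @export
pairwise_divergence <- function(haps, species_pair = NULL) {
  if (is.null(species_pair)) {
    species_pair <- unique(haps$species)
  }
  if (length(species_pair) != 2) {
    abort_hrmelt("exactly two species labels are required", "input_error")
  }
  ha <- haps[haps$species == species_pair[1], ]
  hb <- haps[haps$species == species_pair[2], ]
  if (nrow(ha) == 0 || nrow(hb) == 0) {
    abort_hrmelt("both species need at least one haplotype", "input_error")
  }
  if (length(unique(nchar(c(ha$sequence, hb$sequence)))) != 1) {
    abort_hrmelt("haplotype sequences must have equal length", "input_error")
  }
  d <- matrix(0, nrow(ha), nrow(hb),
    dimnames = list(ha$haplotype_id, hb$haplotype_id)
  )
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) {
      d[i, j] <- hamming_distance(ha$sequence[i], hb$sequence[j])
    }
  }
  m <- seq_matrix(c(ha$sequence, hb$sequence))
  fixed_count <- sum(vapply(seq_len(ncol(m)), function(j) {
    sa <- setdiff(unique(m[seq_len(nrow(ha)), j]), MISSING_STATES)
    sb <- setdiff(unique(m[nrow(ha) + seq_len(nrow(hb)), j]), MISSING_STATES)
    length(sa) > 0 && length(sb) > 0 && length(intersect(sa, sb)) == 0
  }, logical(1)))
  structure(
    list(
      matrix = d,
      mean_between = mean(d),
      fixed_count = fixed_count,
      species_pair = species_pair
    ),
    class = "divergence_summary"
  )
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(
    "Between-species divergence (%s vs %s)\n",
    x$species_pair[1], x$species_pair[2]
  ))
  cat(sprintf(
    "  mean Hamming distance over %d haplotype pairs: %.2f\n",
    length(x$matrix), x$mean_between
  ))
  cat(sprintf("  fixed differences: %d\n", x$fixed_count))
  invisible(x)
}

#' @method tidy divergence_summary
#' @export
tidy.divergence_summary <- function(x, ...) {
  as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE)) |>
    setNames(c("haplotype_a", "haplotype_b", "distance"))
}

#' @method glance divergence_summary
#' @export
glance.divergence_summary <- function(x, ...) {
  tibble(
    mean_between = x$mean_between,
    fixed_count = x$fixed_count,
    n_pairs = length(x$matrix)
  )
}

#' Minimum spanning network of haplotypes
#'
#' Kruskal construction on the pairwise Hamming-distance graph, with ties
#' retained: edges are processed in ascending weight classes, and every edge
#' in a class that joins two components (as they stood when the class was
#' entered) is kept -- the first as a tree edge, equal-weight edges joining
#' the same component pair as `alternative` edges. The tree edges form a
#' minimum spanning tree; the alternatives make it a network.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @return Object of class `haplotype_network`: list with `nodes`
#'   (haplotype_id, species, count, `tm_C` placeholder) and `edges`
#'   (from, to, weight, alternative).
#' @export
build_msn <- function(haps) {
  n <- nrow(haps)
  nodes <- tibble(
    haplotype_id = haps$haplotype_id,
    species = haps$species,
    count = haps$count,
    tm_C = NA_real_
  )
  if (n < 2) {
    rlang::warn("single haplotype: degenerate network with no edges",
      class = "hrmelt_degenerate_network"
    )
    return(structure(
      list(nodes = nodes, edges = tibble(
        from = character(), to = character(),
        weight = integer(), alternative = logical()
      )),
      class = "haplotype_network"
    ))
  }
  pairs <- combn(n, 2)
  edges <- tibble(
    i = pairs[1, ], j = pairs[2, ],
    weight = purrr::map2_int(pairs[1, ], pairs[2, ], function(i, j) {
      as.integer(hamming_distance(haps$sequence[i], haps$sequence[j]))
    })
  ) |>
    arrange(.data$weight, .data$i, .data$j)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  kept <- list()
  for (w in unique(edges$weight)) {
    klass <- edges[edges$weight == w, ]
    comp_before <- vapply(seq_len(n), find, integer(1))
    accepted <- klass[comp_before[klass$i] != comp_before[klass$j], ]
    if (nrow(accepted) == 0) next
    accepted$alternative <- FALSE
    for (k in seq_len(nrow(accepted))) {
      ri <- find(accepted$i[k])
      rj <- find(accepted$j[k])
      # retained because it joins different components of the previous
      # weight class; an alternative if an equal-weight path already
      # connects its endpoints
      accepted$alternative[k] <- ri == rj
      if (ri != rj) parent[ri] <- rj
    }
    kept[[length(kept) + 1]] <- accepted
  }
  kept <- purrr::list_rbind(kept)
  structure(
    list(
      nodes = nodes,
      edges = tibble(
        from = haps$haplotype_id[kept$i],
        to = haps$haplotype_id[kept$j],
        weight = kept$weight,
        alternative = kept$alternative
      )
    ),
    class = "haplotype_network"
  )
}

#' Annotate network nodes with melting temperatures
#'
#' @param net A `haplotype_network`.
#' @param tms Named numeric vector, `haplotype_id` -> Tm in deg C (for
#'   example from [score_and_rank()]'s per-haplotype table).
#' @return The network with `nodes$tm_C` filled in.
#' @export
annotate_network_tm <- function(net, tms) {
  idx <- match(net$nodes$haplotype_id, names(tms))
  net$nodes$tm_C <- unname(tms[idx])
  net
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "Haplotype minimum spanning network: %d nodes, %d edges (%d alternative)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$alternative)
  ))
  invisible(x)
}

#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' @method glance haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_alternative = sum(x$edges$alternative),
    tree_weight = sum(x$edges$weight[!x$edges$alternative])
  )
}

#' Export a haplotype network as edge-list CSV and GraphViz DOT
#'
#' @param net A `haplotype_network`.
#' @param csv_path Edge-list CSV path (optional).
#' @param dot_path GraphViz DOT path (optional).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, csv_path = NULL, dot_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(net$edges, csv_path)
  if (!is.null(dot_path)) {
    lab <- sprintf(
      "  \"%s\" [label=\"%s\\n%s (n=%d)\"];",
      net$nodes$haplotype_id, net$nodes$haplotype_id,
      net$nodes$species, net$nodes$count
    )
    edg <- sprintf(
      "  \"%s\" -- \"%s\" [label=%d%s];",
      net$edges$from, net$edges$to, net$edges$weight,
      ifelse(net$edges$alternative, ", style=dashed", "")
    )
    writeLines(c("graph msn {", lab, edg, "}"), dot_path)
  }
  invisible(net)
}
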