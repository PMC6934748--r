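# Mini-amplicon assay design: candidate windows around fixed diagnostic
# sites, primer-pair generation under composition/uniqueness rules, and
# ranking by predicted between-species melting separation.

#' Majority-rule consensus sequence of an alignment
#'
#' Per-column majority base ignoring `N` and gaps; ties break
#' alphabetically. Columns with no data become `N`.
#'
#' @param aln A `barcode_alignment`.
#' @return A single DNA string.
#' @export
consensus_sequence <- function(aln) {
  m <- seq_matrix(aln$sequence)
  paste(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[!col %in% MISSING_STATES]
    if (length(col) == 0) {
      return("N")
    }
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == max(tab)][1]
  }, character(1)), collapse = "")
}

#' Enumerate candidate mini-amplicon windows
#'
#' Every 0-based half-open window `[start, end)` whose length lies in
#' `length_window` and which contains at least one fixed diagnostic site.
#' Windows whose terminal primer-footprint regions (default 18 bp at each
#' end) overlap any polymorphic column are kept but flagged
#' (`clean_primer_sites = FALSE`), since a primer sitting on a polymorphism
#' risks allele-biased amplification.
#'
#' @param aln A `barcode_alignment`.
#' @param sites Site classification from [classify_sites()]; computed from
#'   `aln` if `NULL`.
#' @param length_window Length bounds `(min, max)` in bp; the short-amplicon
#'   regime of roughly 40-106 bp keeps the per-SNP Tm shift large.
#' @param primer_footprint Footprint width checked at each end, bp.
#' @return A tibble: `start`, `end`, `length`, `n_fixed_sites`,
#'   `fixed_positions` (list-column), `clean_primer_sites`.
#' @export
find_candidate_amplicons <- function(aln, sites = NULL,
                                     length_window = c(40, 106),
                                     primer_footprint = 18) {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  if (is.null(sites)) sites <- classify_sites(aln)
  len <- alignment_length(aln)
  fixed_pos <- sites$position[sites$category == "fixed_diagnostic"]
  poly_pos <- sites$position[sites$category != "monomorphic"]
  if (length(fixed_pos) == 0) {
    abort_hrmelt(
      "no fixed diagnostic sites in this alignment: no melt assay can separate the species",
      "design_error"
    )
  }
  min_len <- max(2, length_window[1])
  max_len <- min(length_window[2], len)
  if (min_len > max_len) {
    abort_hrmelt("length window does not fit the alignment", "design_error")
  }
  grid <- expand.grid(
    start = 0:(len - min_len),
    length = min_len:max_len
  )
  grid <- grid[grid$start + grid$length <= len, ]
  out <- tibble(
    start = as.integer(grid$start),
    end = as.integer(grid$start + grid$length),
    length = as.integer(grid$length)
  )
  out$fixed_positions <- purrr::map2(
    out$start, out$end,
    function(s, e) fixed_pos[fixed_pos >= s & fixed_pos < e]
  )
  out$n_fixed_sites <- lengths(out$fixed_positions)
  out <- out[out$n_fixed_sites > 0, ]
  out$clean_primer_sites <- purrr::map2_lgl(
    out$start, out$end,
    function(s, e) {
      fp <- min(primer_footprint, (e - s) %/% 2)
      !any((poly_pos >= s & poly_pos < s + fp) |
        (poly_pos >= e - fp & poly_pos < e))
    }
  )
  arrange(out, desc(.data$n_fixed_sites), .data$length, .data$start)
}

.max_run <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

.gc_fraction <- function(seq) {
  str_count(seq, "[GC]") / nchar(seq)
}

#' Build the primer pair spanning a whole window
#'
#' Convenience constructor: the forward primer is the consensus of the
#' window's first `fwd_len` columns, the reverse primer the reverse
#' complement of its last `rev_len` columns, so the amplicon is exactly the
#' window. No composition rules are applied -- use
#' [generate_primer_pairs()] for constraint-checked enumeration.
#'
#' @param aln A `barcode_alignment`.
#' @param start,end 0-based half-open window on the alignment.
#' @param fwd_len,rev_len Primer lengths in nt.
#' @return A one-row primer-pair tibble (`forward_seq`, `reverse_seq`,
#'   `amplicon_start`, `amplicon_end`, `amplicon_length`).
#' @export
window_primer_pair <- function(aln, start = 0L, end = alignment_length(aln),
                               fwd_len = 18L, rev_len = 18L) {
  cons <- consensus_sequence(aln)
  if (end - start < fwd_len + rev_len) {
    abort_hrmelt("window shorter than combined primer length", "design_error")
  }
  tibble(
    forward_seq = str_sub(cons, start + 1, start + fwd_len),
    reverse_seq = revcomp(str_sub(cons, end - rev_len + 1, end)),
    amplicon_start = as.integer(start),
    amplicon_end = as.integer(end),
    amplicon_length = as.integer(end - start)
  )
}

#' Enumerate primer pairs for an amplicon window
#'
#' Forward primers are anchored at the window start and reverse primers at
#' the window end (so the amplicon equals the window), with lengths in
#' `primer_len`. All forward x reverse combinations that pass the filters
#' are returned. Filters per primer: nearest-neighbor Tm within `tm_band`,
#' GC fraction within `gc_range`, no homopolymer run longer than
#' `max_run`, and -- because a mismatched 3' terminus kills extension --
#' the 3' end must not sit on a polymorphic column.
#'
#' @param aln A `barcode_alignment`.
#' @param window Length-2 integer vector `(start, end)`, 0-based half-open.
#' @param primer_len Primer length bounds, nt.
#' @param tm_band Allowed primer Tm band, deg C.
#' @param gc_range Allowed GC fraction.
#' @param max_run Longest allowed single-base run.
#' @param cond Conditions for primer Tm prediction.
#' @param sites Site classification (computed from `aln` if `NULL`).
#' @return Primer-pair tibble as in [window_primer_pair()] plus per-primer
#'   Tm columns; rejected single primers are attached as the `"rejected"`
#'   attribute with a `reason` column. Warns and returns zero rows if
#'   nothing passes.
#' @export
generate_primer_pairs <- function(aln, window,
                                  primer_len = c(16, 25),
                                  tm_band = c(50, 62),
                                  gc_range = c(0.3, 0.7),
                                  max_run = 4,
                                  cond = thermo_conditions(),
                                  sites = NULL) {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  if (is.null(sites)) sites <- classify_sites(aln)
  poly_pos <- sites$position[sites$category != "monomorphic"]
  start <- window[1]
  end <- window[2]
  if (start < 0 || end > alignment_length(aln) || end - start < sum(primer_len[1] * 2)) {
    abort_hrmelt("invalid window for primer generation", "design_error")
  }
  cons <- consensus_sequence(aln)

  check_primer <- function(seq, three_prime_col, side, len) {
    reason <- NA_character_
    tm <- NA_real_
    if (str_detect(seq, "[^ACGT]")) {
      reason <- "ambiguous_base"
    } else {
      tm <- predict_tm(seq, cond)$tm_C
      if (.max_run(seq) > max_run) {
        reason <- "homopolymer_run"
      } else if (.gc_fraction(seq) < gc_range[1] || .gc_fraction(seq) > gc_range[2]) {
        reason <- "gc_out_of_range"
      } else if (tm < tm_band[1] || tm > tm_band[2]) {
        reason <- "tm_out_of_band"
      } else if (three_prime_col %in% poly_pos) {
        reason <- "three_prime_on_polymorphism"
      }
    }
    tibble(
      side = side, primer_seq = seq, length = len, tm_C = tm,
      pass = is.na(reason), reason = reason
    )
  }

  lens <- primer_len[1]:primer_len[2]
  fwd <- purrr::list_rbind(purrr::map(lens, function(l) {
    check_primer(str_sub(cons, start + 1, start + l),
      three_prime_col = start + l - 1, side = "forward", len = l
    )
  }))
  rev <- purrr::list_rbind(purrr::map(lens, function(l) {
    check_primer(revcomp(str_sub(cons, end - l + 1, end)),
      three_prime_col = end - l, side = "reverse", len = l
    )
  }))
  rejected <- bind_rows(fwd[!fwd$pass, ], rev[!rev$pass, ])
  fwd_ok <- fwd[fwd$pass, ]
  rev_ok <- rev[rev$pass, ]
  if (nrow(fwd_ok) == 0 || nrow(rev_ok) == 0) {
    rlang::warn("no primer pair satisfies the constraints in this window",
      class = "hrmelt_no_primer_warning"
    )
    out <- tibble(
      forward_seq = character(), reverse_seq = character(),
      amplicon_start = integer(), amplicon_end = integer(),
      amplicon_length = integer(), forward_tm_C = double(),
      reverse_tm_C = double()
    )
    attr(out, "rejected") <- rejected
    return(out)
  }
  combos <- expand.grid(f = seq_len(nrow(fwd_ok)), r = seq_len(nrow(rev_ok)))
  out <- tibble(
    forward_seq = fwd_ok$primer_seq[combos$f],
    reverse_seq = rev_ok$primer_seq[combos$r],
    amplicon_start = as.integer(start),
    amplicon_end = as.integer(end),
    amplicon_length = as.integer(end - start),
    forward_tm_C = fwd_ok$tm_C[combos$f],
    reverse_tm_C = rev_ok$tm_C[combos$r]
  )
  attr(out, "rejected") <- rejected
  out
}

#' In-silico PCR: locate a primer pair on a template
#'
#' Finds the forward primer and the reverse complement of the reverse
#' primer on the template with at most `max_mismatches` each; the
#' 3'-terminal base of each primer must match exactly. Returns the spanned
#' amplicon (primer footprints included). `NA` if there is no product;
#' multiple products raise an ambiguity error listing the loci.
#'
#' @param template DNA string.
#' @param pair One-row primer-pair tibble (or list) with `forward_seq` and
#'   `reverse_seq`.
#' @param max_mismatches Per-primer mismatch allowance (3' base exact).
#' @return The amplicon string, or `NA_character_` when no product forms.
#' @export
in_silico_pcr <- function(template, pair, max_mismatches = 2) {
  template <- toupper(template)
  fwd <- toupper(pair$forward_seq[[1]])
  rev <- toupper(pair$reverse_seq[[1]])
  tv <- strsplit(template, "", fixed = TRUE)[[1]]
  if (length(tv) < nchar(fwd) + nchar(rev)) {
    abort_hrmelt("template shorter than combined primer length", "input_error")
  }

  hits <- function(primer, three_prime_at_start) {
    pv <- strsplit(primer, "", fixed = TRUE)[[1]]
    k <- length(pv)
    starts <- seq_len(length(tv) - k + 1)
    keep <- vapply(starts, function(s) {
      mm <- sum(tv[s:(s + k - 1)] != pv)
      three_idx <- if (three_prime_at_start) 1L else k
      mm <= max_mismatches && tv[s + three_idx - 1] == pv[three_idx]
    }, logical(1))
    starts[keep]
  }

  f_hits <- hits(fwd, three_prime_at_start = FALSE)
  r_hits <- hits(revcomp(rev), three_prime_at_start = TRUE)
  products <- expand.grid(f = f_hits, r = r_hits)
  products <- products[products$r + nchar(rev) - 1 >= products$f + nchar(fwd) - 1 &
    products$r >= products$f, , drop = FALSE]
  if (nrow(products) == 0) {
    return(NA_character_)
  }
  if (nrow(products) > 1) {
    abort_hrmelt(
      sprintf(
        "multiple products: forward at {%s}, reverse-site at {%s} (1-based)",
        paste(unique(products$f), collapse = ","),
        paste(unique(products$r), collapse = ",")
      ),
      "ambiguity_error"
    )
  }
  str_sub(template, products$f, products$r + nchar(rev) - 1)
}

#' Score and rank candidate assays by melting separation
#'
#' For each primer pair, the amplicon is excised from every haplotype, its
#' Tm predicted by [predict_tm()], and the candidate scored by
#' `min_between_species_dtm_C`: the minimum over all inter-species
#' haplotype pairs of the absolute Tm difference -- the worst-case
#' separation the assay must still resolve. Candidates are ranked by that
#' score (descending), breaking ties by shorter amplicon then smaller
#' start. Haplotypes whose amplicon contains `N` are skipped with a
#' warning.
#'
#' @param pairs Primer-pair tibble ([generate_primer_pairs()] or
#'   [window_primer_pair()] output, possibly concatenated).
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param cond A [thermo_conditions()] object.
#' @return An `assay_ranking` tibble: the pair columns plus `rank`,
#'   `rank_score`, `min_between_species_dtm_C`, `n_diagnostic_sites`,
#'   `diagnostic_positions` and `per_haplotype_tm` list-columns.
#' @export
score_and_rank <- function(pairs, haps, cond = thermo_conditions()) {
  if (nrow(pairs) == 0) {
    abort_hrmelt("no candidate primer pairs to score", "design_error")
  }
  species <- unique(haps$species)
  if (length(species) < 2) {
    abort_hrmelt("haplotypes must span two species", "input_error")
  }
  m <- seq_matrix(haps$sequence)

  fixed_in <- function(s, e) {
    cols <- (s + 1):e
    keep <- vapply(cols, function(j) {
      sa <- setdiff(unique(m[haps$species == species[1], j]), MISSING_STATES)
      sb <- setdiff(unique(m[haps$species == species[2], j]), MISSING_STATES)
      length(sa) > 0 && length(sb) > 0 && length(intersect(sa, sb)) == 0
    }, logical(1))
    cols[keep] - 1L
  }

  scored <- purrr::list_rbind(purrr::map(seq_len(nrow(pairs)), function(i) {
    s <- pairs$amplicon_start[i]
    e <- pairs$amplicon_end[i]
    amp <- str_sub(haps$sequence, s + 1, e)
    amp <- gsub("-", "", amp, fixed = TRUE)
    usable <- !str_detect(amp, "N")
    if (any(!usable)) {
      rlang::warn(
        sprintf(
          "skipping haplotype(s) with N in amplicon: %s",
          paste(haps$haplotype_id[!usable], collapse = ", ")
        ),
        class = "hrmelt_amplicon_n_warning"
      )
    }
    th <- predict_tm(amp[usable], cond)
    per_hap <- tibble(
      haplotype_id = haps$haplotype_id[usable],
      species = haps$species[usable],
      count = haps$count[usable],
      amplicon = amp[usable],
      n_bp = th$n_bp,
      dH_kcal_mol = th$dH_kcal_mol,
      dS_cal_molK = th$dS_cal_molK,
      tm_C = th$tm_C
    )
    ta <- per_hap$tm_C[per_hap$species == species[1]]
    tb <- per_hap$tm_C[per_hap$species == species[2]]
    min_dtm <- if (length(ta) && length(tb)) {
      min(abs(outer(ta, tb, "-")))
    } else {
      NA_real_
    }
    diag_pos <- fixed_in(s, e)
    tibble(
      pairs[i, ],
      n_diagnostic_sites = length(diag_pos),
      diagnostic_positions = list(diag_pos),
      min_between_species_dtm_C = min_dtm,
      per_haplotype_tm = list(per_hap)
    )
  }))
  scored <- scored |>
    arrange(
      desc(.data$min_between_species_dtm_C),
      .data$amplicon_length, .data$amplicon_start
    ) |>
    mutate(rank = row_number(), rank_score = .data$min_between_species_dtm_C)
  class(scored) <- c("assay_ranking", class(scored))
  attr(scored, "species_pair") <- species[1:2]
  scored
}

#' @method tidy assay_ranking
#' @export
tidy.assay_ranking <- function(x, ...) {
  x |>
    as_tibble() |>
    select("rank", "forward_seq", "reverse_seq", "amplicon_start",
      "amplicon_end", "per_haplotype_tm") |>
    tidyr::unnest("per_haplotype_tm")
}

#' @method glance assay_ranking
#' @export
glance.assay_ranking <- function(x, ...) {
  top <- x[1, ]
  tibble(
    n_candidates = nrow(x),
    best_min_dtm_C = top$min_between_species_dtm_C,
    best_amplicon_length = top$amplicon_length,
    best_n_diagnostic_sites = top$n_diagnostic_sites
  )
}

#' One-call assay design pipeline
#'
#' [find_candidate_amplicons()] -> [generate_primer_pairs()] on the most
#' promising windows -> [score_and_rank()]. Windows that yield no
#' constraint-passing primers fall back to the whole-window pair of
#' [window_primer_pair()] so that every candidate region is still scored.
#'
#' @inheritParams find_candidate_amplicons
#' @inheritParams score_and_rank
#' @param max_windows Cap on the number of candidate windows carried into
#'   primer generation (windows are already ordered best-first).
#' @param ... Passed to [generate_primer_pairs()].
#' @return An `assay_ranking` tibble.
#' @export
design_assays <- function(aln, sites = NULL, length_window = c(40, 106),
                          cond = thermo_conditions(), max_windows = 25, ...) {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  if (is.null(sites)) sites <- classify_sites(aln)
  wins <- find_candidate_amplicons(aln, sites, length_window)
  wins <- head(wins, max_windows)
  haps <- collapse_haplotypes(aln)
  pairs <- purrr::list_rbind(purrr::map(seq_len(nrow(wins)), function(i) {
    p <- suppressWarnings(generate_primer_pairs(
      aln, c(wins$start[i], wins$end[i]),
      cond = cond, sites = sites, ...
    ))
    if (nrow(p) == 0) {
      p <- window_primer_pair(aln, wins$start[i], wins$end[i])
      p$forward_tm_C <- NA_real_
      p$reverse_tm_C <- NA_real_
    }
    p
  }))
  score_and_rank(pairs, haps, cond)
}
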