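# Deterministic synthetic-data generators: mini-barcode alignments with a
# configured diagnostic-site structure, PCR templates embedding a primer
# pair, and high-throughput specimen cohorts with known truth. All
# generators are pure functions of their spec + seed.

.random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
}

.random_codon <- function(gc) {
  repeat {
    cdn <- paste(.random_dna(3, gc), collapse = "")
    if (!cdn %in% c("TAA", "TAG", "TGA")) {
      return(cdn)
    }
  }
}

# Largest-remainder split of n into k parts with geometric weights, so the
# first haplotype is modal, emulating skewed haplotype frequencies.
.split_counts <- function(n, k) {
  w <- 2^(k - seq_len(k))
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  as.integer(base)
}

#' Specification for a synthetic mini-barcode alignment
#'
#' Describes the diagnostic-site structure of a two-species COI-like
#' mini-barcode: an in-frame backbone with `n_fixed_sites` fixed
#' transitions (species-disjoint states, G/C in `gc_bias_species` and A/T
#' in the other, one of them an ATA/ATG codon reading Ile vs Met under the
#' standard code) and `n_shared_sites` shared transitions (polymorphic
#' within a species with a state shared across species). All polymorphic
#' sites sit at third codon positions.
#'
#' @param length_bp Alignment length, bp; multiple of 3, at least 40.
#' @param n_fixed_sites Fixed diagnostic transitions.
#' @param n_shared_sites Shared (plesiomorphic) transitions.
#' @param haplotypes_per_species Haplotypes generated per species.
#' @param n_per_species Specimens per species (alignment record counts).
#' @param species Length-2 character vector of species labels.
#' @param gc_bias_species Which species carries G/C at the fixed sites
#'   (and therefore melts higher).
#' @param gc_content Backbone GC fraction.
#' @param seed RNG seed; the generator is a pure function of spec + seed.
#' @return An object of class `barcode_spec`.
#' @export
#' @examples
#' barcode_spec()
barcode_spec <- function(length_bp = 60, n_fixed_sites = 4,
                         n_shared_sites = 4, haplotypes_per_species = 3,
                         n_per_species = c(43, 22),
                         species = c("marginata", "dolus"),
                         gc_bias_species = species[1],
                         gc_content = 0.35, seed = 1) {
  if (length_bp %% 3 != 0 || length_bp < 40) {
    abort_hrmelt("length_bp must be a multiple of 3 and at least 40",
      "spec_error")
  }
  n_sites <- n_fixed_sites + n_shared_sites
  if (n_sites > length_bp / 3) {
    abort_hrmelt(
      "too few third codon positions for the requested polymorphic sites",
      "spec_error"
    )
  }
  if (length(species) != 2 || anyDuplicated(species)) {
    abort_hrmelt("exactly two distinct species labels required", "spec_error")
  }
  if (!gc_bias_species %in% species) {
    abort_hrmelt("gc_bias_species must be one of the species labels",
      "spec_error")
  }
  if (haplotypes_per_species < 1 || any(n_per_species < haplotypes_per_species)) {
    abort_hrmelt("need at least one specimen per haplotype", "spec_error")
  }
  structure(
    list(
      length_bp = as.integer(length_bp),
      n_fixed_sites = as.integer(n_fixed_sites),
      n_shared_sites = as.integer(n_shared_sites),
      haplotypes_per_species = as.integer(haplotypes_per_species),
      n_per_species = as.integer(n_per_species),
      species = species,
      gc_bias_species = gc_bias_species,
      gc_content = gc_content,
      seed = as.integer(seed)
    ),
    class = "barcode_spec"
  )
}

# Shared-site presence/absence patterns (1 = C-state, 0 = T-state), one
# matrix per species, rows = haplotypes. The default geometry (4 shared
# sites, 3 haplotypes/species) uses a hand-constructed pattern whose 3x3
# inter-species Hamming matrix is {four 5s, five 6s} on top of 4 fixed
# differences (mean 5.56, quoted as 5.6) while every inter-species pair
# stays >= 4 G/C units apart. Other geometries flip sites by the binary
# code of the haplotype index.
.shared_patterns <- function(n_shared, n_hap) {
  if (n_shared == 4 && n_hap == 3) {
    return(list(
      a = rbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)),
      b = rbind(c(0, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0))
    ))
  }
  if (n_shared == 0) {
    z <- matrix(0L, n_hap, 0)
    return(list(a = z, b = z))
  }
  site_owner <- rep(c("a", "b"), length.out = n_shared)
  build <- function(sites) {
    k <- length(sites)
    m <- matrix(0L, n_hap, n_shared)
    if (k == 0 && n_hap > 1) {
      abort_hrmelt(
        "infeasible spec: a species has extra haplotypes but no shared site to vary",
        "spec_error"
      )
    }
    for (h in seq_len(n_hap)[-1]) {
      bits <- as.integer(intToBits(h - 1))[seq_len(k)]
      if (sum(bits) == 0) {
        abort_hrmelt(
          "infeasible spec: more haplotypes than shared-site combinations",
          "spec_error"
        )
      }
      m[h, sites] <- bits
    }
    covered <- colSums(m[, sites, drop = FALSE]) > 0
    if (any(!covered)) {
      abort_hrmelt(
        "infeasible spec: too few haplotypes to vary every shared site",
        "spec_error"
      )
    }
    m
  }
  list(a = build(which(site_owner == "a")), b = build(which(site_owner == "b")))
}

#' Generate a synthetic mini-barcode alignment
#'
#' Builds the alignment described by a [barcode_spec()]: a random in-frame
#' backbone (no stop codons) with the configured fixed and shared
#' transitions placed at distinct third codon positions, expanded to
#' `haplotypes_per_species` haplotypes per species (differing only at
#' shared sites) and to individual specimen records with skewed haplotype
#' frequencies. The first fixed site is realized as an ATA/ATG codon at
#' the third codon (ninth nucleotide) when it fits, so exactly one
#' polymorphic site is non-synonymous under the standard code.
#'
#' @param spec A [barcode_spec()].
#' @return A `barcode_alignment` tibble; the attribute `site_plan` records
#'   where each site was placed.
#' @export
make_minibarcode_alignment <- function(spec) {
  stopifnot(inherits(spec, "barcode_spec"))
  withr::with_seed(spec$seed, {
    n_codons <- spec$length_bp %/% 3
    n_sites <- spec$n_fixed_sites + spec$n_shared_sites

    # interleaved site types (shared first), so the second site -- placed
    # at codon 3, nucleotide 9 -- is fixed whenever both kinds exist
    types <- character(0)
    nf <- spec$n_fixed_sites
    ns <- spec$n_shared_sites
    while (nf + ns > 0) {
      if (ns > 0) {
        types <- c(types, "shared")
        ns <- ns - 1
      }
      if (nf > 0) {
        types <- c(types, "fixed")
        nf <- nf - 1
      }
    }
    if (spec$n_fixed_sites == 4 && spec$n_shared_sites == 4) {
      types <- c(
        "shared", "fixed", "shared", "fixed",
        "shared", "fixed", "fixed", "shared"
      )
    }

    # codon slots: 2 and 3 first (so the Ile/Met site can sit at the ninth
    # nucleotide), the rest spread evenly downstream; assigned to sites in
    # sequence order so site types interleave along the amplicon
    extra <- max(0L, n_sites - 2L)
    pool <- if (extra <= n_codons - 3) {
      seq(4L, n_codons)
    } else {
      setdiff(seq_len(n_codons), c(2L, 3L))
    }
    chosen <- integer(0)
    if (extra > 0) {
      idx <- unique(round(seq(1, length(pool), length.out = extra)))
      while (length(idx) < extra) {
        idx <- sort(union(idx, setdiff(seq_along(pool), idx)[1]))
      }
      chosen <- pool[idx]
    }
    slots <- sort(c(c(2L, 3L)[seq_len(min(2L, n_sites))], chosen))
    # keep a fixed site on codon 3 wherever both kinds exist
    i3 <- which(slots == 3L)
    if (length(i3) == 1 && any(types == "fixed") && types[i3] != "fixed") {
      j <- which(types == "fixed")[1]
      types[c(i3, j)] <- types[c(j, i3)]
    }

    codons <- vapply(seq_len(n_codons), function(i) {
      .random_codon(spec$gc_content)
    }, character(1))

    gc_first <- spec$gc_bias_species == spec$species[1]
    pat <- .shared_patterns(spec$n_shared_sites, spec$haplotypes_per_species)
    if (!gc_first) pat <- list(a = pat$b, b = pat$a)
    n_hap <- spec$haplotypes_per_species

    # per-species haplotype codon matrices, filled site by site
    hap_codons <- list(
      matrix(rep(codons, each = n_hap), nrow = n_hap),
      matrix(rep(codons, each = n_hap), nrow = n_hap)
    )
    shared_idx <- 0
    first_fixed <- TRUE
    plan <- list()
    for (k in seq_len(n_sites)) {
      codon_i <- slots[k]
      if (types[k] == "fixed") {
        if (first_fixed) {
          # Ile/Met codon: G (Met) in the G/C-biased species, A (Ile) in
          # the other
          prefix <- "AT"
          hi <- "G"
          lo <- "A"
          first_fixed <- FALSE
        } else {
          prefix <- paste(.random_dna(2, spec$gc_content), collapse = "")
          hi <- "C"
          lo <- "T"
        }
        gc_sp <- if (gc_first) 1 else 2
        other <- 3 - gc_sp
        hap_codons[[gc_sp]][, codon_i] <- paste0(prefix, hi)
        hap_codons[[other]][, codon_i] <- paste0(prefix, lo)
        plan[[k]] <- tibble(
          position = (codon_i - 1L) * 3L + 2L, type = "fixed",
          codon = codon_i, states = paste0(prefix, hi, "/", prefix, lo)
        )
      } else {
        shared_idx <- shared_idx + 1
        prefix <- paste(.random_dna(2, spec$gc_content), collapse = "")
        for (sp in 1:2) {
          p <- if (sp == 1) pat$a else pat$b
          third <- ifelse(p[, shared_idx] == 1, "C", "T")
          hap_codons[[sp]][, codon_i] <- paste0(prefix, third)
        }
        plan[[k]] <- tibble(
          position = (codon_i - 1L) * 3L + 2L, type = "shared",
          codon = codon_i, states = paste0(prefix, "C/", prefix, "T")
        )
      }
    }

    records <- purrr::list_rbind(purrr::map(1:2, function(sp) {
      seqs <- apply(hap_codons[[sp]], 1, paste, collapse = "")
      counts <- .split_counts(spec$n_per_species[sp], n_hap)
      tibble(
        species = spec$species[sp],
        sequence = rep(seqs, counts)
      )
    }))
    records$specimen_id <- sprintf(
      "%s_%03d", records$species,
      stats::ave(seq_len(nrow(records)), records$species, FUN = seq_along)
    )
    aln <- as_barcode_alignment(
      records[c("specimen_id", "species", "sequence")],
      frame_offset = 0L
    )
    attr(aln, "site_plan") <- purrr::list_rbind(plan)
    aln
  })
}

#' Build a PCR template embedding a primer pair
#'
#' Random flanks + the exact forward primer site + random interior + the
#' exact reverse-complement site, sized so that [in_silico_pcr()] yields an
#' amplicon of exactly `spec$length_bp`.
#'
#' @param spec A [barcode_spec()] (supplies amplicon length, GC content
#'   and seed).
#' @param forward_seq,reverse_seq Primer sequences, both written 5'->3'.
#' @param flank_bp Random flank length on each side.
#' @return A DNA string.
#' @export
make_pcr_template <- function(spec, forward_seq, reverse_seq, flank_bp = 20) {
  stopifnot(inherits(spec, "barcode_spec"))
  interior <- spec$length_bp - nchar(forward_seq) - nchar(reverse_seq)
  if (interior < 0) {
    abort_hrmelt("primers longer than the requested amplicon", "spec_error")
  }
  withr::with_seed(spec$seed, {
    paste0(
      paste(.random_dna(flank_bp, spec$gc_content), collapse = ""),
      toupper(forward_seq),
      paste(.random_dna(interior, spec$gc_content), collapse = ""),
      revcomp(toupper(reverse_seq)),
      paste(.random_dna(flank_bp, spec$gc_content), collapse = "")
    )
  })
}

#' Specification for a synthetic high-throughput cohort
#'
#' Study-scale defaults: 518 specimens of which 279 are males carrying a
#' prior morphology label, failure rate 9/518 (all failures among males),
#' male label-discordance rate 30/279, species proportions matching 296 vs
#' 213 successful assignments, per-specimen melting-peak jitter of 0.15
#' deg C, and per-species reference peaks at 79.4 / 77.0 deg C.
#'
#' @param n_specimens Cohort size.
#' @param n_males Males (the labelled subset).
#' @param species_proportions Named sampling proportions of true species.
#' @param fail_rate Fraction of specimens with failed amplification.
#' @param male_label_discordance_rate Fraction of male prior labels
#'   flipped relative to the true species (label-only: curve simulation
#'   always follows the true species).
#' @param male_only_failures Draw all failures among males.
#' @param noise_sd_fluor Fluorescence noise SD, signal units.
#' @param noise_sd_tm Per-specimen melting-peak jitter SD, deg C.
#' @param reference_tms Named per-species plate-calibrator peak
#'   temperatures, deg C; cohort curves are anchored here.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 518, n_males = 279,
                        species_proportions = c(
                          marginata = 296 / 509,
                          dolus = 213 / 509
                        ),
                        fail_rate = 9 / 518,
                        male_label_discordance_rate = 30 / 279,
                        male_only_failures = TRUE,
                        noise_sd_fluor = 0.02, noise_sd_tm = 0.15,
                        reference_tms = c(marginata = 79.4, dolus = 77.0),
                        seed = 1) {
  if (n_males > n_specimens) {
    abort_hrmelt("n_males cannot exceed n_specimens", "spec_error")
  }
  rates <- c(fail_rate, male_label_discordance_rate)
  if (any(rates < 0 | rates > 1)) {
    abort_hrmelt("rates must lie in [0, 1]", "spec_error")
  }
  if (is.null(names(species_proportions)) || is.null(names(reference_tms)) ||
    !setequal(names(species_proportions), names(reference_tms))) {
    abort_hrmelt(
      "species_proportions and reference_tms must be named consistently",
      "spec_error"
    )
  }
  n_fail <- round(fail_rate * n_specimens)
  if (male_only_failures && n_fail > n_males) {
    abort_hrmelt("more failures requested than males available", "spec_error")
  }
  structure(
    list(
      n_specimens = as.integer(n_specimens),
      n_males = as.integer(n_males),
      species_proportions = species_proportions / sum(species_proportions),
      fail_rate = fail_rate,
      male_label_discordance_rate = male_label_discordance_rate,
      male_only_failures = male_only_failures,
      noise_sd_fluor = noise_sd_fluor,
      noise_sd_tm = noise_sd_tm,
      reference_tms = reference_tms,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a high-throughput specimen cohort
#'
#' Samples true species and a haplotype (frequency-weighted) per specimen,
#' marks exactly `round(fail_rate * n)` specimens as failed amplifications
#' (amplitude-zero curves), assigns prior labels to males with exactly
#' `round(discordance_rate * n_males)` labels flipped, and simulates one
#' melt curve per specimen. Each curve's transition is anchored at the
#' specimen's species reference temperature (the plate-calibrator anchor
#' in `spec$reference_tms`) plus `N(0, noise_sd_tm)` jitter; with
#' `use_haplotype_tm = TRUE` the assay's predicted within-species
#' haplotype Tm offsets (relative to the frequency-weighted species mean)
#' are added as well.
#'
#' @param spec A [cohort_spec()].
#' @param assay A one-row slice of an `assay_ranking` (the assay to
#'   emulate; supplies per-haplotype amplicon thermodynamics).
#' @param cond A [thermo_conditions()].
#' @param use_haplotype_tm Add predicted within-species haplotype Tm
#'   offsets to the anchor (default off: see the package vignette).
#' @return A list with `curves` (long melt-curve tibble) and `metadata`
#'   (`specimen_id`, `sex`, `true_species`, `haplotype_id`, `prior_label`,
#'   `failed`).
#' @export
make_cohort <- function(spec, assay, cond = thermo_conditions(),
                        use_haplotype_tm = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  per_hap <- assay$per_haplotype_tm[[1]]
  sp_names <- names(spec$reference_tms)
  if (!all(sp_names %in% per_hap$species)) {
    abort_hrmelt("assay lacks per-haplotype Tm for both species",
      "spec_error")
  }
  n <- spec$n_specimens
  withr::with_seed(spec$seed, {
    true_species <- sample(sp_names, n,
      replace = TRUE,
      prob = spec$species_proportions[sp_names]
    )
    sex <- rep("female", n)
    sex[sample.int(n, spec$n_males)] <- "male"

    n_fail <- round(spec$fail_rate * n)
    fail_pool <- if (spec$male_only_failures) which(sex == "male") else seq_len(n)
    failed <- rep(FALSE, n)
    failed[sample(fail_pool, n_fail)] <- TRUE

    prior_label <- rep(NA_character_, n)
    males <- which(sex == "male")
    prior_label[males] <- true_species[males]
    n_flip <- round(spec$male_label_discordance_rate * spec$n_males)
    # flips go to males whose amplification succeeds, so the discordance
    # observed in the downstream report matches the configured rate
    flip_pool <- setdiff(males, which(failed))
    if (n_flip > length(flip_pool)) {
      abort_hrmelt("more label flips requested than usable males",
        "spec_error")
    }
    flip <- sample(flip_pool, n_flip)
    prior_label[flip] <- vapply(true_species[flip], function(sp) {
      setdiff(sp_names, sp)[1]
    }, character(1))

    hap_row <- integer(n)
    for (sp in sp_names) {
      rows <- which(per_hap$species == sp)
      idx <- which(true_species == sp)
      hap_row[idx] <- sample(rows, length(idx),
        replace = TRUE,
        prob = per_hap$count[rows]
      )
    }

    centers <- spec$reference_tms[true_species]
    if (use_haplotype_tm) {
      sp_mean <- per_hap |>
        group_by(.data$species) |>
        summarise(
          mean_tm = sum(.data$tm_C * .data$count) / sum(.data$count),
          .groups = "drop"
        )
      offs <- per_hap$tm_C - sp_mean$mean_tm[match(per_hap$species, sp_mean$species)]
      centers <- centers + offs[hap_row]
    }

    grid <- melt_grid()
    t0 <- grid[1]
    jitter <- rnorm(n, 0, spec$noise_sd_tm)
    tm_base <- melting_temperature(
      per_hap$dH_kcal_mol, per_hap$dS_cal_molK, per_hap$n_bp, cond
    )
    # anchor the derivative-peak temperature (what the instrument reports)
    # at center + jitter: see simulate_melt_curve() details
    delta <- vapply(seq_len(nrow(per_hap)), function(r) {
      .peak_offset(
        per_hap$dH_kcal_mol[r], per_hap$dS_cal_molK[r], per_hap$n_bp[r], cond
      )
    }, numeric(1))
    shift <- jitter + centers - (tm_base + delta)[hap_row]
    amplitude <- ifelse(failed, 0, 1)

    # specimens x grid matrix of shifted duplex fractions
    t_eff <- outer(-shift, grid, "+")
    theta <- matrix(0, n, length(grid))
    for (r in seq_len(nrow(per_hap))) {
      idx <- which(hap_row == r)
      if (length(idx) == 0) next
      theta[idx, ] <- .theta_at(
        per_hap$dH_kcal_mol[r], per_hap$dS_cal_molK[r], per_hap$n_bp[r],
        cond, t_eff[idx, , drop = FALSE]
      )
    }
    fmat <- amplitude * theta *
      rep(1 - 0.002 * (grid - t0), each = n) +
      rep(0.05 - 5e-4 * (grid - t0), each = n) +
      matrix(rnorm(n * length(grid), 0, spec$noise_sd_fluor), n)

    ids <- sprintf("sp_%04d", seq_len(n))
    curves <- tibble(
      specimen_id = rep(ids, each = length(grid)),
      temp_C = rep(grid, times = n),
      fluorescence = as.vector(t(fmat))
    )
    metadata <- tibble(
      specimen_id = ids,
      sex = sex,
      true_species = true_species,
      haplotype_id = per_hap$haplotype_id[hap_row],
      prior_label = prior_label,
      failed = failed
    )
    list(curves = curves, metadata = metadata)
  })
}
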