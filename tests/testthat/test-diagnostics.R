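test_that("site categories capture fixed, shared, and monomorphic columns", {
  aln <- toy_alignment()
  sites <- classify_sites(aln, c("A", "B"))
  expect_equal(nrow(sites), alignment_length(aln))
  # categories partition the columns
  expect_equal(
    sum(sites$category == "monomorphic") +
      sum(sites$category != "monomorphic"),
    alignment_length(aln)
  )
  # column 2 (0-based): G in all A, A in all B -> fixed transition
  s2 <- sites[sites$position == 2, ]
  expect_equal(s2$category, "fixed_diagnostic")
  expect_equal(s2$substitution_kind, "transition")
  # column 8: {C,T} in both species -> shared
  expect_equal(sites$category[sites$position == 8], "shared_polymorphic")
})

test_that("a state present in one species and shared with the other is plesiomorphic", {
  aln <- as_barcode_alignment(tibble::tibble(
    specimen_id = c("a1", "a2", "b1"),
    species = c("A", "A", "B"),
    sequence = c("AAA", "GAA", "AAA")
  ))
  sites <- classify_sites(aln, c("A", "B"))
  expect_equal(sites$category[1], "shared_polymorphic")
})

test_that("synonymy is judged from observed codon variants", {
  aln <- toy_alignment()
  sites <- classify_sites(aln, c("A", "B"))
  # ATG vs ATA at the third position of codon 1: Met vs Ile
  expect_false(sites$synonymous[sites$position == 2])
  # ATC vs ATT at codon 3: both Ile
  expect_true(sites$synonymous[sites$position == 8])
  expect_equal(sites$codon_position[sites$position == 2], 3L)
})

test_that("between-species divergence matches a brute-force oracle", {
  # identical single haplotypes
  h0 <- tibble::tibble(
    haplotype_id = c("H1", "H2"), species = c("A", "B"),
    sequence = "ACGTACGT", count = 1L, members = list("a", "b")
  )
  d0 <- pairwise_divergence(h0, c("A", "B"))
  expect_equal(d0$mean_between, 0)
  expect_equal(d0$fixed_count, 0)

  # single pair four substitutions apart
  h4 <- h0
  h4$sequence <- c("ACGTACGT", "TCGAAGGA")
  d4 <- pairwise_divergence(h4, c("A", "B"))
  expect_equal(d4$mean_between, 4)
  expect_equal(d4$fixed_count, 4)

  # default fixture: brute-force mean over the 9 inter-species pairs
  haps <- collapse_haplotypes(default_fixture())
  ha <- haps[haps$species == "marginata", ]
  hb <- haps[haps$species == "dolus", ]
  dists <- as.vector(outer(ha$sequence, hb$sequence,
    Vectorize(oracle_hamming)
  ))
  expect_setequal(unique(dists), c(5, 6))
  expect_equal(sort(table(dists), decreasing = FALSE),
    sort(table(c(rep(5, 4), rep(6, 5)))),
    ignore_attr = TRUE
  )
  dv <- pairwise_divergence(haps, c("marginata", "dolus"))
  expect_equal(dv$mean_between, mean(dists))
  expect_equal(round_half_up(dv$mean_between, 1), 5.6)
})

test_that("divergence fixed count agrees with site classification", {
  for (seed in c(1, 7, 23)) {
    aln <- make_minibarcode_alignment(barcode_spec(seed = seed))
    sites <- classify_sites(aln, c("marginata", "dolus"))
    dv <- pairwise_divergence(collapse_haplotypes(aln), c("marginata", "dolus"))
    expect_equal(dv$fixed_count, sum(sites$category == "fixed_diagnostic"))
  }
})

test_that("divergence is invariant under haplotype reordering", {
  haps <- collapse_haplotypes(default_fixture())
  shuffled <- haps[sample(nrow(haps)), ]
  expect_equal(
    pairwise_divergence(haps, c("marginata", "dolus"))$mean_between,
    pairwise_divergence(shuffled, c("marginata", "dolus"))$mean_between
  )
})

test_that("minimum spanning network handles simple cases", {
  mk <- function(seqs) {
    tibble::tibble(
      haplotype_id = paste0("H", seq_along(seqs)), species = "A",
      sequence = seqs, count = 1L, members = as.list(seq_along(seqs))
    )
  }
  # two haplotypes: the only spanning solution
  n2 <- build_msn(mk(c("AAAA", "ATTA")))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$weight, 2)

  # distances 1,1,2: the weight-2 edge is excluded
  n3 <- build_msn(mk(c("AAA", "AAT", "ATA")))
  expect_equal(sort(n3$edges$weight), c(1, 1))

  # unit square: all four unit edges retained, one closing a cycle
  n4 <- build_msn(mk(c("AA", "AT", "TA", "TT")))
  expect_equal(nrow(n4$edges), 4)
  expect_equal(sum(n4$edges$alternative), 1)
  expect_equal(sum(!n4$edges$alternative), 3)

  expect_warning(build_msn(mk("AAAA")), class = "hrmelt_degenerate_network")
})

test_that("network tree weight is minimal by exhaustive enumeration", {
  withr::local_seed(99)
  for (trial in 1:5) {
    n <- sample(4:6, 1)
    seqs <- replicate(n, random_dna_string(12))
    while (anyDuplicated(seqs)) seqs <- replicate(n, random_dna_string(12))
    haps <- tibble::tibble(
      haplotype_id = paste0("H", 1:n), species = "A",
      sequence = seqs, count = 1L, members = as.list(1:n)
    )
    net <- build_msn(haps)
    pairs <- t(combn(n, 2))
    edges <- data.frame(
      i = pairs[, 1], j = pairs[, 2],
      weight = apply(pairs, 1, function(p) {
        oracle_hamming(seqs[p[1]], seqs[p[2]])
      })
    )
    expect_equal(
      sum(net$edges$weight[!net$edges$alternative]),
      oracle_mst_weight(n, edges)
    )
  }
})

test_that("fixture network spans all six haplotypes", {
  haps <- collapse_haplotypes(default_fixture())
  net <- build_msn(haps)
  expect_equal(nrow(net$nodes), 6)
  # connectivity over all retained edges
  ids <- net$nodes$haplotype_id
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(net$edges))) {
    parent[[find(net$edges$from[k])]] <- find(net$edges$to[k])
  }
  expect_equal(length(unique(vapply(ids, find, character(1)))), 1)

  # Tm annotation flows into the nodes
  ranked <- default_ranked()
  per_hap <- ranked$per_haplotype_tm[[1]]
  net <- annotate_network_tm(net, setNames(per_hap$tm_C, per_hap$haplotype_id))
  expect_true(all(is.finite(net$nodes$tm_C)))
  expect_equal(glance(net)$n_nodes, 6)
})

test_that("site report and network exports are readable text", {
  aln <- default_fixture()
  sites <- classify_sites(aln)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_site_report(sites, csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 60)

  net <- build_msn(collapse_haplotypes(aln))
  ecsv <- withr::local_tempfile(fileext = ".csv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network(net, ecsv, dot)
  expect_equal(
    nrow(readr::read_csv(ecsv, show_col_types = FALSE)),
    nrow(net$edges)
  )
  expect_match(readLines(dot)[1], "graph msn")
})
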