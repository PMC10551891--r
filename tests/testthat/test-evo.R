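test_that("global alignment of identical sequences has identity 1, no gaps", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  al <- global_align(s, s)
  expect_equal(al$identity, 1)
  expect_identical(al$aligned_a, s)
  expect_identical(al$aligned_b, s)
})

test_that("a single-residue deletion gives one gap column", {
  al <- global_align("ACDEFG", "ACDFG")
  expect_equal(nchar(al$aligned_a), 6)
  expect_equal(al$aligned_b, "ACD-FG")
  expect_equal(al$identity, 5 / 6)
})

test_that("non-amino-acid characters other than X are rejected", {
  expect_error(global_align("ACDB", "ACD"), "outside")
  expect_error(global_align("ACD", "AC*D"), "outside")
  al <- global_align("ACXD", "ACXD")  # X accepted
  expect_equal(nchar(al$aligned_a), 4)
})

test_that("alignment equals brute-force enumeration on short sequences", {
  sub <- blosum62_test()
  set.seed(61)
  for (i in 1:25) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1)
    a <- random_sequence(la); b <- random_sequence(lb)
    al <- global_align(a, b)
    expect_equal(al$score, brute_force_score(a, b, sub), tolerance = 1e-9)
    # the reported alignment is real: it reconstructs the inputs and
    # achieves the optimal score, and identity matches its definition
    expect_identical(gsub("-", "", al$aligned_a), a)
    expect_identical(gsub("-", "", al$aligned_b), b)
    expect_equal(score_alignment(al$aligned_a, al$aligned_b, sub), al$score)
    ca <- strsplit(al$aligned_a, "")[[1]]; cb <- strsplit(al$aligned_b, "")[[1]]
    expect_equal(al$identity, sum(ca == cb & ca != "-") / length(ca))
  }
})

test_that("alignment agrees with Biostrings on longer random pairs", {
  sub <- blosum62_test()
  set.seed(62)
  for (i in 1:10) {
    a <- random_sequence(sample(20:80, 1))
    b <- random_sequence(sample(20:80, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sub, gapOpening = 9.5, gapExtension = 0.5,
      type = "global")
    expect_equal(global_align(a, b)$score, Biostrings::score(ref),
                 tolerance = 1e-9)
  }
})

test_that("match_domains keeps the best instance pair above the identity cutoff", {
  dom <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWY"
  prot_a <- as_proteome_df("1.A", paste0("GGGG", dom, "GGGG"))
  prot_b <- as_proteome_df("2.B", paste0("SSSS", dom, "SSSS"))
  da <- data.frame(protein_id = "1.A", domain = "D1", start = 5, end = 44)
  db <- data.frame(protein_id = "2.B", domain = "D1", start = 5, end = 44)
  out <- match_domains("1.A", "2.B", da, db, prot_a, prot_b)
  expect_equal(nrow(out), 1)
  expect_equal(out$identity, 1)
  expect_equal(out$domain, "D1")

  # no shared domain name -> nothing
  db2 <- db; db2$domain <- "D2"
  expect_equal(nrow(match_domains("1.A", "2.B", da, db2, prot_a, prot_b)), 0)
})

test_that("a pair below the identity threshold is dropped", {
  set.seed(63)
  dom_a <- random_sequence(40)
  # ~35% identity: keep 14 of 40 positions, replace the rest
  cs <- strsplit(dom_a, "")[[1]]
  flip <- sample(40, 26)
  cs[flip] <- vapply(cs[flip], function(x)
    sample(setdiff(c("G", "P", "W", "H"), x), 1), character(1))
  dom_b <- paste(cs, collapse = "")
  prot_a <- as_proteome_df("1.A", dom_a)
  prot_b <- as_proteome_df("2.B", dom_b)
  da <- data.frame(protein_id = "1.A", domain = "D1", start = 1, end = 40)
  db <- data.frame(protein_id = "2.B", domain = "D1", start = 1, end = 40)
  ident <- global_align(dom_a, dom_b)$identity
  expect_lt(ident, 0.40)
  expect_equal(nrow(match_domains("1.A", "2.B", da, db, prot_a, prot_b,
                                  min_identity = 0.40)), 0)
  expect_equal(nrow(match_domains("1.A", "2.B", da, db, prot_a, prot_b,
                                  min_identity = ident - 0.01)), 1)
})

test_that("duplicated domain instances resolve to the higher-scoring copy", {
  dom <- "ACDEFGHIKLMNPQRSTVWY"
  set.seed(64)
  cs <- strsplit(dom, "")[[1]]
  cs[sample(20, 8)] <- "G"
  degraded <- paste(cs, collapse = "")
  # protein a carries a degraded copy then a perfect copy
  prot_a <- as_proteome_df("1.A", paste0(degraded, "KKKK", dom))
  prot_b <- as_proteome_df("2.B", dom)
  da <- data.frame(protein_id = c("1.A", "1.A"), domain = "D1",
                   start = c(1, 25), end = c(20, 44))
  db <- data.frame(protein_id = "2.B", domain = "D1", start = 1, end = 20)
  out <- match_domains("1.A", "2.B", da, db, prot_a, prot_b)
  expect_equal(nrow(out), 1)
  expect_equal(out$identity, 1)  # the perfect copy wins
  s_perfect <- global_align(dom, dom)$score
  s_degraded <- global_align(degraded, dom)$score
  expect_equal(out$score, max(s_perfect, s_degraded))
})

test_that("usage ratios count the residues of interest, excluding zero pairs", {
  adp <- data.frame(id_a = c("a1", "a2"), id_b = c("b1", "b2"), domain = "D",
                    aligned_a = c("CACA--MW", "AAAA"),
                    aligned_b = c("CCMMCW--", "ACAA"),
                    score = 1, identity = 1, stringsAsFactors = FALSE)
  out <- usage_ratios(adp, aa_set = c("C", "M"))
  # a1: 2 C + 1 M = 3 vs b1: 3 C + 2 M = 5; a2 has 0 -> excluded
  expect_equal(nrow(out), 1)
  expect_equal(out$count_a, 3)
  expect_equal(out$count_b, 5)
  expect_equal(out$ratio, 3 / 5)
})

test_that("usage ratio is antisymmetric under species swap", {
  cfg <- sim_config(depletion_beta = 0.4, seed = 65)
  os <- make_ortholog_set(cfg, n_pairs = 40)
  aligned <- do.call(rbind, lapply(seq_len(40), function(i)
    match_domains(os$pairs$id_a[i], os$pairs$id_b[i], os$domains_a,
                  os$domains_b, os$proteome_a, os$proteome_b)))
  fwd <- usage_ratios(aligned)
  swapped <- aligned
  names(swapped)[match(c("id_a", "id_b", "aligned_a", "aligned_b"),
                       names(swapped))] <- c("id_b", "id_a", "aligned_b",
                                             "aligned_a")
  rev <- usage_ratios(swapped)
  expect_equal(fwd$ratio, 1 / rev$ratio)
})

test_that("Spearman correlation recovers perfect monotone trends", {
  tab <- data.frame(ratio = seq(2, 0.1, length.out = 20),
                    abundance_ppm = sort(10^runif(20, 0, 4)))
  res <- abundance_usage_correlation(tab)
  expect_equal(res$rho, -1)
  expect_lt(res$p_value, 1e-6)

  expect_error(abundance_usage_correlation(
    data.frame(ratio = rep(1, 10), abundance_ppm = 1:10)), "degenerate")
  expect_error(abundance_usage_correlation(
    data.frame(ratio = 1:2, abundance_ppm = 2:1)), "three")
})

test_that("Spearman rho matches the exact rank-statistic formula", {
  set.seed(66)
  ratio <- rexp(10); ab <- rexp(10)  # continuous: no ties
  res <- abundance_usage_correlation(
    data.frame(ratio = ratio, abundance_ppm = ab))
  d <- rank(ratio) - rank(ab)
  rho_exact <- 1 - 6 * sum(d^2) / (10 * (10^2 - 1))
  expect_equal(res$rho, rho_exact, tolerance = 1e-12)
})

test_that("binning splits rows into balanced, abundance-ordered groups", {
  set.seed(67)
  tab <- data.frame(ratio = runif(600), abundance_ppm = runif(600))
  b <- bin_for_plot(tab, 6)
  expect_equal(b$n, rep(100L, 6))
  expect_true(all(diff(b$abundance_median) > 0))

  tab2 <- data.frame(ratio = runif(601), abundance_ppm = runif(601))
  b2 <- bin_for_plot(tab2, 6)
  expect_equal(sum(b2$n), 601)
  expect_lte(diff(range(b2$n)), 1)

  # planted decreasing trend -> non-increasing bin medians
  n <- 300
  ab <- sort(10^runif(n, 0, 4))
  tab3 <- data.frame(ratio = seq(1.5, 0.5, length.out = n),
                     abundance_ppm = ab)
  b3 <- bin_for_plot(tab3, 6)
  expect_true(all(diff(b3$ratio_median) < 0))
  expect_true(all(b3$ratio_p25 <= b3$ratio_median))
  expect_true(all(b3$ratio_median <= b3$ratio_p75))
})

test_that("significance stars follow the printed thresholds", {
  expect_equal(significance_stars(c(0.005, 0.5, 1e-6, 0.0005, 0.01)),
               c("*", "", "***", "**", ""))
})

test_that("species heatmap table shapes results into aligned matrices", {
  res <- data.frame(query = c("f1", "f1", "f2"),
                    reference = c("human", "fly", "human"),
                    rho = c(-0.3, -0.2, -0.05),
                    p_value = c(1e-7, 0.002, 0.3))
  hm <- species_heatmap_table(res)
  expect_equal(dim(hm$rho), c(2, 2))
  expect_equal(hm$stars["f1", "human"], "***")
  expect_equal(hm$stars["f1", "fly"], "*")
  expect_equal(hm$stars["f2", "human"], "")
  expect_true(is.na(hm$rho["f2", "fly"]))
})

test_that("the full pipeline recovers a planted depletion signal", {
  cfg <- sim_config(depletion_beta = 0.8, seed = 68)
  os <- make_ortholog_set(cfg, n_pairs = 200)
  res <- domain_usage_analysis(os$pairs, os$domains_a, os$domains_b,
                               os$proteome_a, os$proteome_b, os$abundance)
  expect_lt(res$correlation$rho, 0)
  expect_lt(res$correlation$p_value, 0.01)
  expect_lt(res$bins$ratio_median[6], res$bins$ratio_median[1])
})

test_that("complex (non one-to-one) ortholog pairs are excluded", {
  cfg <- sim_config(depletion_beta = 0, seed = 69)
  os <- make_ortholog_set(cfg, n_pairs = 30, n_complex = 10)
  expect_equal(sum(!os$pairs$one_to_one), 10)
  res <- domain_usage_analysis(os$pairs, os$domains_a, os$domains_b,
                               os$proteome_a, os$proteome_b, os$abundance)
  complex_ids <- os$pairs$id_a[!os$pairs$one_to_one]
  expect_false(any(res$table$id_a %in% complex_ids))
})
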