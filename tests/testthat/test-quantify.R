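test_that("contaminant and decoy groups are removed, order preserved", {
  g <- data.frame(group_id = c("1.P1", "CON_k", "REV_x"),
                  members = c("1.P1", "CON_k", "REV_x"),
                  intensity = c(10, 5, 2), stringsAsFactors = FALSE)
  out <- suppressMessages(filter_protein_groups(g))
  expect_equal(out$group_id, "1.P1")

  # a CON_ member buried in a multi-member group also disqualifies the row
  g2 <- data.frame(group_id = c("1.P1", "1.P2"),
                   members = c("1.P1;CON_y", "1.P2;1.P3"),
                   intensity = c(1, 1), stringsAsFactors = FALSE)
  out2 <- suppressMessages(filter_protein_groups(g2))
  expect_equal(out2$group_id, "1.P2")

  expect_equal(nrow(filter_protein_groups(g[0, ])), 0)
  # idempotent
  expect_identical(suppressMessages(filter_protein_groups(out)), out)
})

test_that("planted contaminants are filtered in exact numbers", {
  cfg <- sim_config(n_proteins = 40, seed = 15)
  prot <- make_proteome(cfg)
  ds <- make_abundances(cfg, prot)
  g <- make_protein_groups(cfg, prot, ds, n_contaminants = 6, n_decoys = 4)
  expect_equal(attr(g, "n_planted_bad"), 10)
  out <- suppressMessages(filter_protein_groups(g))
  expect_equal(nrow(out), nrow(g) - 10)
  expect_false(any(grepl("^(CON_|REV_)", out$group_id)))
})

test_that("FDR filter keeps scores at or below threshold and unscored rows", {
  p <- data.frame(protein_id = "x", peptide = "ACDEFK",
                  quantity = 1, fdr_score = c(0.005, 0.01, 0.02))
  out <- suppressMessages(filter_peptides_fdr(p, 0.01))
  expect_equal(out$fdr_score, c(0.005, 0.01))

  p$fdr_score <- NA_real_
  expect_identical(filter_peptides_fdr(p, 0.01), p)

  set.seed(3)
  p2 <- data.frame(protein_id = "x", peptide = "ACDEFK", quantity = 1,
                   fdr_score = runif(1000))
  out2 <- suppressMessages(filter_peptides_fdr(p2, 0.01))
  expect_equal(nrow(out2), sum(p2$fdr_score <= 0.01))
})

test_that("protein-centric abundance divides intensity by observable count", {
  seqs <- c("ACDEFGHILMK", "ACDEFGHILMNPQSTVWYK")  # single observable peptide each
  prot <- as_proteome_df(c("1.P1", "1.P2"), seqs)
  expect_equal(observable_stats(seqs[1])$observable_count, 1L)
  g <- data.frame(group_id = c("1.P1", "1.P2"), members = c("1.P1", "1.P2"),
                  intensity = c(1000, 600), stringsAsFactors = FALSE)
  raw <- protein_centric_abundance(g, prot)
  expect_equal(raw, c("1.P1" = 1000, "1.P2" = 600))

  # linearity
  g2 <- g; g2$intensity <- 2 * g$intensity
  expect_equal(protein_centric_abundance(g2, prot), 2 * raw)

  # unknown group dropped with a message
  g3 <- rbind(g, data.frame(group_id = "9.X", members = "9.X", intensity = 5))
  expect_message(raw3 <- protein_centric_abundance(g3, prot), "no proteome")
  expect_equal(raw3, raw)
})

test_that("multi-member groups resolve to the first mappable member", {
  prot <- as_proteome_df(c("1.P1", "1.P2"),
                         c("ACDEFGHILMK", "ACDEFGHILMNPQSTVWYK"))
  g <- data.frame(group_id = "UNKNOWN", members = "UNKNOWN;1.P2;1.P1",
                  intensity = 500, stringsAsFactors = FALSE)
  raw <- protein_centric_abundance(g, prot)
  expect_equal(names(raw), "1.P2")
})

test_that("peptide-centric abundance normalizes by observable length", {
  # protein made of observable peptides of lengths 10, 20, 30 -> denominator 60
  p10 <- "ACDEFGHILK"
  p20 <- "ACDEFGHILMNPQSTVWYAK"
  p30 <- "ACDEFGHILMNPQSTVWYAACDEFGHILMK"
  prot <- as_proteome_df("1.P1", paste0(p10, p20, p30))
  expect_equal(observable_stats(prot$sequence)$observable_length, 60L)
  peps <- data.frame(protein_id = "1.P1", peptide = c(p10, p20),
                     quantity = c(5, 2), fdr_score = NA_real_)
  raw <- peptide_centric_abundance(peps, prot)
  expect_equal(raw, c("1.P1" = (5 * 10 + 2 * 20) / 60))

  # peptide for an unknown protein is dropped with a message
  peps2 <- rbind(peps, data.frame(protein_id = "9.X", peptide = p10,
                                  quantity = 1, fdr_score = NA_real_))
  expect_message(raw2 <- peptide_centric_abundance(peps2, prot), "unknown")
  expect_equal(raw2, raw)
})

test_that("protein- and peptide-centric pipelines agree on one-peptide proteins", {
  # each protein has exactly one observable peptide covering the whole
  # observable length, and quantity = intensity
  peps <- c("ACDEFGHILM", "WYACDEFGHILMNPQ", "MNPQSTVWYACD")
  prot <- as_proteome_df(sprintf("1.P%d", 1:3), peps)
  ints <- c(100, 250, 40)
  g <- data.frame(group_id = prot$internal_id, members = prot$internal_id,
                  intensity = ints, stringsAsFactors = FALSE)
  pc <- protein_centric_abundance(g, prot)
  pep_tab <- data.frame(protein_id = prot$internal_id, peptide = peps,
                        quantity = ints, fdr_score = NA_real_)
  ppc <- peptide_centric_abundance(pep_tab, prot)
  expect_equal(to_ppm(pc)$ppm, to_ppm(ppc)$ppm)
})

test_that("to_ppm normalizes to 1e6 and is scale invariant", {
  ds <- to_ppm(c(A = 1, B = 3))
  expect_equal(ds$ppm, c(A = 250000, B = 750000))
  expect_equal(to_ppm(c(A = 5))$ppm, c(A = 1e6))
  expect_error(to_ppm(c(A = 0, B = 0)), "no quantified")

  set.seed(9)
  for (i in 1:10) {
    raw <- setNames(rexp(50), sprintf("p%02d", 1:50))
    expect_equal(sum(to_ppm(raw)$ppm), 1e6, tolerance = 1e-9)
    expect_equal(to_ppm(raw * runif(1, 0.001, 1000))$ppm, to_ppm(raw)$ppm)
  }
})

test_that("zero raw values are kept as 0 ppm, distinct from absent", {
  ds <- to_ppm(c(A = 2, B = 0))
  expect_equal(ds$ppm, c(A = 1e6, B = 0))
  expect_true("B" %in% names(ds$ppm))
})

test_that("coverage is the quantified fraction of the proteome", {
  prot <- make_proteome(sim_config(n_proteins = 100, seed = 2))
  ds <- to_ppm(setNames(rep(1, 50), prot$internal_id[1:50]))
  expect_equal(proteome_coverage(ds, prot), 0.5)
  expect_error(proteome_coverage(ds, prot[0, ]), "empty")
})

test_that("abundance datasets survive a TSV + sidecar round trip", {
  cfg <- sim_config(n_proteins = 30, seed = 44)
  ds <- make_abundances(cfg, make_proteome(cfg))
  ds$score <- 4.2; ds$coverage <- 0.9; ds$tissue <- "LIVER"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(ds, path)
  back <- read_abundance(path)
  expect_equal(back$ppm, ds$ppm)
  expect_equal(back$score, 4.2)
  expect_equal(back$tissue, "LIVER")
  expect_equal(back$organism, ds$organism)
})
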