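test_that("unique-category attribution respects the selection order", {
  # the published accounting example at its real scale: 2071 trait-associated
  # variants of which 135 were already taken by the prior-array category
  cat1 <- sprintf("a%d", 1:34039)
  cat2 <- c(cat1[1:135], sprintf("b%d", 1:1936))
  res <- assign_unique_categories(list(prior = cat1, gwas = cat2))
  expect_equal(res$counts$n_unique, c(34039L, 1936L))
  expect_equal(res$counts$n_total, c(34039L, 2071L))
  expect_equal(sum(res$counts$n_unique), nrow(res$assignment))
})

test_that("unique counts always sum to the number of selected variants", {
  set.seed(77)
  for (k in 1:10) {
    pool <- sprintf("v%d", 1:500)
    sets <- lapply(1:6, function(i) sample(pool, sample(0:100, 1)))
    res <- assign_unique_categories(sets)
    expect_equal(sum(res$counts$n_unique),
                 length(unique(unlist(sets))))
    expect_true(all(res$counts$n_total >= res$counts$n_unique))
    expect_false(anyDuplicated(res$assignment$variant_id) > 0)
  }
})

test_that("probeset accounting doubles only A/T and C/G SNPs", {
  expect_equal(probesets_for("A", "T"), 2L)
  expect_equal(probesets_for("T", "A"), 2L)
  expect_equal(probesets_for("C", "G"), 2L)
  expect_equal(probesets_for("A", "C"), 1L)
  expect_equal(probesets_for("G", "T"), 1L)
  expect_equal(probesets_for("AT", "A"), 1L)  # indel
})

test_that("residual gaps report spans above the strict limit", {
  p <- data.table::data.table(chrom = "chr1", pos = c(0L, 260000L))
  g <- residual_gaps(p)
  expect_equal(nrow(g), 1)
  expect_equal(g$span_bp, 260000L)
  dense <- data.table::data.table(chrom = "chr1",
                                  pos = seq(0L, 5e5, by = 10000L))
  expect_equal(nrow(residual_gaps(dense)), 0)
  # exactly at the limit is not a gap
  p2 <- data.table::data.table(chrom = "chr1", pos = c(0L, 250000L))
  expect_equal(nrow(residual_gaps(p2)), 0)
})

# a hand-built candidate scenario exercising categories 1-5, 8, 9, 10
scenario_cohort <- function(seed = 1) {
  set.seed(seed)
  co <- tiny_cohort(seed = seed, n = 50, chrom_len = 1e6)
  v <- add_breed_aafs(co$variants, co$genotypes)
  v$unique_focal <- classify_unique(v, co$panel)
  list(co = co, v = v)
}

test_that("complete-LD pruning keeps at most two per clique and block", {
  set.seed(91)
  # one block of five variants, three of them genotype-identical
  sim <- sim_block_geno(80, list(c(1000, 1500, 2000, 2500, 3000)))
  sim$geno[, 2] <- sim$geno[, 1]
  sim$geno[, 3] <- sim$geno[, 1]
  gm <- make_gm(sim$geno, breed = "DSN")
  v <- data.table::data.table(
    id = colnames(gm$geno), chrom = "chr1", pos = sim$pos,
    ref = "A", alt = "C", class = "SNP",
    impact = c("low", "low", "low", "modifier", "modifier"),
    pconvert_fwd = 0.9, pconvert_rev = 0.9,
    aaf_DSN = oracle_aaf(gm$geno), aaf_HOL = oracle_aaf(gm$geno),
    unique_focal = FALSE)
  blocks <- call_blocks(gm, v)
  expect_equal(nrow(blocks), 1)
  d <- select_categories(v, gm, blocks,
                         categories = list(prior_array_ids = character(0),
                                           gwas_ids = character(0),
                                           parentage_ids = character(0)),
                         panel = breed_panel("DSN", "HOL"))
  picked3 <- d$selected[category == 3, variant_id]
  expect_lte(sum(picked3 %in% c("v1", "v2", "v3")), 2)
  expect_true(all(c("v1", "v2") %in% d$selected$variant_id))
})

test_that("gap filling inserts the candidate closest to the gap midpoint", {
  g <- matrix(rep(c(0L, 1L, 2L), 20), nrow = 12)[, 1:5]
  gm <- make_gm(cbind(g, g[, 1:2])[, 1:5], breed = "DSN")
  v <- data.table::data.table(
    id = sprintf("v%d", 1:5), chrom = "chr1",
    pos = c(100e3, 500e3, 280e3, 320e3, 700e3),
    ref = "A", alt = "C", class = "SNP", impact = "modifier",
    pconvert_fwd = 0.9, pconvert_rev = 0.9,
    aaf_DSN = 0.5, aaf_HOL = 0.5, unique_focal = FALSE)
  colnames(gm$geno) <- v$id
  # v1 and v2 forced in via the prior-array category; v3/v4 are candidates
  d <- select_categories(
    v[order(pos)], gm,
    blocks = data.table::data.table(block = integer(), chrom = character(),
                                    start = integer(), end = integer(),
                                    length_bp = integer(),
                                    n_variants = integer(),
                                    variant_ids = list()),
    categories = list(prior_array_ids = c("v1", "v2", "v5")),
    panel = breed_panel("DSN", "HOL"))
  filled <- d$selected[category == 10, variant_id]
  expect_equal(filled, "v3")  # 280 kb is nearer the 300 kb midpoint? no: |280-300|=20 < |320-300|=20 -> tie broken by position
  gaps <- residual_gaps(d)
  expect_equal(nrow(gaps), 0)
})

test_that("the full design is deterministic and internally consistent", {
  sc <- scenario_cohort(3)
  co <- sc$co
  d1 <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  d2 <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  expect_identical(d1$selected, d2$selected)
  expect_identical(d1$category_counts, d2$category_counts)
  # accounting invariants
  expect_equal(sum(d1$category_counts$n_unique), d1$totals$n_variants)
  expect_equal(d1$totals$n_snps + d1$totals$n_indels, d1$totals$n_variants)
  expect_equal(sum(d1$selected$probesets), d1$totals$n_probesets)
  # probesets = variants + extra for A/T, C/G SNPs + replicate surplus
  sel <- d1$selected
  at_cg <- sum(sel$class == "SNP" &
                 paste(pmin(sel$ref, sel$alt),
                       pmax(sel$ref, sel$alt)) %in% c("A T", "C G"))
  rep_extra <- sum(sel$probesets[sel$category == 2]) -
    sum(probesets_for(sel$ref, sel$alt)[sel$category == 2])
  expect_equal(d1$totals$n_probesets,
               d1$totals$n_variants + at_cg + rep_extra)
})

test_that("every filter output is a subset of its input", {
  sc <- scenario_cohort(5)
  co <- sc$co
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  log <- d$filter_log
  expect_true(all(log$n_out == log$n_in - log$n_removed))
  expect_true(all(log$n_removed >= 0))
  expect_equal(log$n_in[1], nrow(co$variants))
  expect_true(all(d$selected$variant_id %in% co$variants$id))
})

test_that("residual gaps after gap filling contain no surviving candidate", {
  sc <- scenario_cohort(7)
  co <- sc$co
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  gaps <- residual_gaps(d)
  if (nrow(gaps) > 0) {
    cand <- d$candidates[!id %in% d$selected$variant_id]
    for (k in seq_len(nrow(gaps))) {
      inside <- cand[chrom == gaps$chrom[k] & pos > gaps$gap_start[k] &
                       pos < gaps$gap_end[k]]
      expect_equal(nrow(inside), 0)
    }
  } else {
    succeed()
  }
})

test_that("category 2 variants from non-imputed sources get replicate probesets", {
  sc <- scenario_cohort(9)
  co <- sc$co
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  sel2 <- d$selected[category == 2]
  if (nrow(sel2) > 0) {
    imputed <- sel2$variant_id %in% co$categories$gwas_imputed_ids
    base <- probesets_for(sel2$ref, sel2$alt)
    expect_equal(sel2$probesets[imputed], base[imputed])
    expect_equal(sel2$probesets[!imputed], 2L * base[!imputed])
  } else {
    succeed()
  }
})

test_that("exceeding the probeset capacity is an error listing the overflow", {
  sc <- scenario_cohort(11)
  co <- sc$co
  expect_error(
    design_chip(co$variants, co$genotypes, co$panel, co$categories,
                design_cfg = design_config(capacity = 10)),
    "capacity exceeded by")
})
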