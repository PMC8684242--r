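make_calls <- function(calls, conf = NULL, breed = "DSN", animal = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("A%02d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("v%d", seq_len(ncol(calls)))
  }
  if (is.null(conf)) {
    conf <- matrix(0, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  inst <- rownames(calls)
  structure(list(
    calls = calls, conf = conf,
    animal_of = stats::setNames(animal %||% inst, inst),
    breed_of = stats::setNames(rep(breed, length.out = length(inst)), inst),
    batch = stats::setNames(rep(1L, length(inst)), inst),
    failed_variants = character(0)
  ), class = "call_results")
}

test_that("zero-confidence complete calls all pass QC", {
  g <- matrix(sample(0:2, 50, replace = TRUE), nrow = 10)
  cr <- make_calls(g)
  qc <- qc_calls(cr)
  expect_setequal(qc$passed, colnames(cr$calls))
  expect_equal(unname(qc$call_rate), rep(1, 5))
})

test_that("call-rate threshold arithmetic: 94 of 100 calls fail a variant", {
  set.seed(1)
  g <- matrix(0L, nrow = 100, ncol = 2)
  conf <- matrix(0, 100, 2)
  conf[1:6, 1] <- 0.5  # 6 masked -> call rate 0.94
  cr <- make_calls(g, conf)
  qc <- qc_calls(cr)
  expect_equal(qc$passed, "v2")
  expect_equal(unname(qc$call_rate["v1"]), 0.94)
})

test_that("confidence masking happens before the call rate is computed", {
  # all calls present (pre-masking call rate 1) but 10% carry bad
  # confidence: the variant must fail; computing the rate first would pass it
  g <- matrix(1L, nrow = 20, ncol = 1)
  conf <- matrix(0, 20, 1)
  conf[1:2, 1] <- 0.9
  cr <- make_calls(g, conf)
  qc <- qc_calls(cr)
  expect_equal(length(qc$passed), 0)
  expect_equal(unname(qc$call_rate), 0.9)
  expect_true(all(is.na(qc$masked[1:2, 1])))
})

test_that("the call-rate bound is strict by default, inclusive on request", {
  g <- matrix(0L, nrow = 20, ncol = 1)
  conf <- matrix(0, 20, 1)
  conf[1, 1] <- 0.9  # call rate exactly 0.95
  cr <- make_calls(g, conf)
  expect_equal(length(qc_calls(cr)$passed), 0)
  expect_equal(qc_calls(cr, strict = FALSE)$passed, "v1")
})

test_that("confidence exactly at the threshold is kept", {
  g <- matrix(2L, nrow = 4, ncol = 1)
  conf <- matrix(c(0.05, 0.050001, 0, 0), 4, 1)
  qc <- qc_calls(make_calls(g, conf), callrate_threshold = 0.5)
  expect_equal(sum(is.na(qc$masked)), 1)
})

test_that("segregation requires strict MAF above the threshold", {
  g <- cbind(v1 = rep(0L, 50),                    # monomorphic
             v2 = c(1L, rep(0L, 49)),             # MAF 0.01 exactly
             v3 = c(1L, 1L, rep(0L, 48)))         # MAF 0.02
  qc <- qc_calls(make_calls(g))
  expect_equal(segregating_variants(qc, 0.01), "v3")
})

test_that("segregation equals a brute-force tally on random matrices", {
  set.seed(3)
  for (k in 1:10) {
    g <- matrix(sample(c(0:2, NA), 30 * 8, replace = TRUE,
                       prob = c(.5, .2, .2, .1)), 30, 8)
    cr <- make_calls(g)
    qc <- qc_calls(cr, callrate_threshold = 0.5)
    got <- segregating_variants(qc, 0.01)
    want <- character(0)
    for (v in qc$passed) {
      x <- qc$masked[, v]
      x <- x[!is.na(x)]
      aaf <- sum(x) / (2 * length(x))
      if (min(aaf, 1 - aaf) > 0.01) want <- c(want, v)
    }
    expect_setequal(got, want)
  }
})

test_that("concordance of a call set with itself is 100%", {
  set.seed(5)
  g <- matrix(sample(c(0:2, NA), 40, replace = TRUE), nrow = 4)
  cr <- make_calls(g)
  cc <- concordance(cr, cr)
  expect_true(all(cc$per_pair$concordance == 100))
  expect_equal(cc$mean, 100)
})

test_that("one mismatch in ten shared calls gives 90%", {
  a <- matrix(c(rep(0L, 10)), nrow = 1,
              dimnames = list("x", sprintf("v%d", 1:10)))
  b <- a
  b[1, 4] <- 2L
  cc <- concordance(make_calls(a), make_calls(b))
  expect_equal(cc$per_pair$concordance, 90)
  expect_equal(cc$per_pair$n_compared, 10L)
})

test_that("pairs with no comparable calls are undefined and excluded", {
  a <- matrix(c(0L, NA, 1L, NA), nrow = 2,
              dimnames = list(c("x", "y"), c("v1", "v2")))
  b <- matrix(c(0L, NA, 1L, NA), nrow = 2,
              dimnames = list(c("x", "y"), c("v1", "v2")))
  b[2, ] <- NA
  cc <- concordance(make_calls(a), make_calls(b))
  expect_true(is.na(cc$per_pair$concordance[2]))
  expect_equal(cc$n_pairs, 1)
  expect_equal(cc$mean, 100)
})

test_that("category percentages are recomputable and empty rows show NA", {
  counts <- data.table::data.table(
    category = 1:3, label = c("a", "b", "c"),
    n_unique = c(200L, 0L, 50L), n_total = c(220L, 0L, 50L),
    n_called = c(150L, 0L, 49L))
  tab <- format_category_table(counts)
  expect_equal(tab$pct_called, c(75, NA, 98))
  expect_true(is.na(tab$pct_called[2]))  # 0/0 is not 0%
  # recompute from reported counts
  expect_equal(tab$pct_called[c(1, 3)],
               round_half_up(100 * tab$n_called[c(1, 3)] /
                               tab$n_unique[c(1, 3)], 2))
})

test_that("rounding is half-up to two decimals", {
  expect_equal(round_half_up(92.455, 2), 92.46)
  expect_equal(round_half_up(92.454, 2), 92.45)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(100 * 32996 / 34039, 2), 96.94)
  expect_equal(round_half_up(100 * 166563 / 182154, 2), 91.44)
})

test_that("noise-free simulated runs call everything and agree with truth", {
  co <- tiny_cohort(seed = 19, n = 25, chrom_len = 3e5)
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  run <- simulate_chip_run(d, co$genotypes, chip_run_spec(
    base_failure_rate = 0, pconvert_failure_slope = 0,
    rare_allele_cluster_penalty = 0, base_miscall_rate = 0,
    conf_correct = c(0, 0), conf_error = c(0, 0), seed = 4))
  qc <- qc_calls(run)
  # truth has no missing genotypes here, so every variant is called
  expect_setequal(qc$passed, d$selected$variant_id)
  cc <- concordance(run, co$genotypes)
  expect_true(all(cc$per_pair$concordance == 100))
  # and the gap analysis of called variants equals the design's
  called_pos <- d$selected[variant_id %in% qc$passed, .(chrom, pos)]
  expect_identical(residual_gaps(called_pos), residual_gaps(d))
})

test_that("a saturated failure rate leaves nothing callable", {
  co <- tiny_cohort(seed = 23, n = 15, chrom_len = 2e5)
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  run <- simulate_chip_run(d, co$genotypes,
                           chip_run_spec(base_failure_rate = 1, seed = 1))
  expect_equal(length(qc_calls(run)$passed), 0)
})

test_that("per-category evaluation counts are consistent", {
  co <- tiny_cohort(seed = 29, n = 30, chrom_len = 4e5)
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  run <- simulate_chip_run(d, co$genotypes, chip_run_spec(seed = 2))
  rep <- category_table(d, run, focal_breed = "DSN")
  tab <- rep$by_category
  body <- tab[!is.na(tab$category)]
  tot <- tab[is.na(tab$category)]
  expect_equal(sum(body$n_called_focal), tot$n_called_focal)
  expect_equal(sum(body$n_segregating), tot$n_segregating)
  expect_true(all(body$n_segregating <= body$n_called_focal))
  expect_true(all(body$n_called_focal <= body$n_unique))
  expect_equal(sum(rep$totals_by_class$n_selected), d$totals$n_variants)
  # successfully-called-anywhere is a superset of called-in-focal
  expect_true(all(rep$called_focal %in% rep$called_any))
})

test_that("a failed duplicate of a working variant shows complete LD", {
  set.seed(31)
  g <- matrix(rbinom(60, 2, 0.4), nrow = 20, ncol = 3)
  g[, 2] <- g[, 1]
  gm <- make_gm(g, breed = "DSN")
  v <- data.table::data.table(
    id = colnames(gm$geno), chrom = "chr1", pos = c(1000, 1500, 9000),
    ref = "A", alt = "C", class = "SNP")
  d <- fake_design(v)
  fw <- failing_vs_working_ld(d, called_ids = c("v1", "v3"), gm)
  row <- fw$per_variant[fw$per_variant$failed_id == "v2"]
  expect_equal(row$partner_id, "v1")
  expect_equal(row$dprime, 1, tolerance = 1e-7)
  expect_equal(row$r2, 1, tolerance = 1e-7)
})

test_that("no failed variants gives an empty LD summary", {
  v <- data.table::data.table(id = c("v1", "v2"), chrom = "chr1",
                              pos = c(1, 2), ref = "A", alt = "C",
                              class = "SNP")
  g <- matrix(rbinom(20, 2, 0.5), nrow = 10, ncol = 2,
              dimnames = list(sprintf("A%d", 1:10), c("v1", "v2")))
  fw <- failing_vs_working_ld(fake_design(v), c("v1", "v2"), make_gm(g))
  expect_equal(fw$n, 0)
  expect_true(is.na(fw$mean_dprime))
})

test_that("failing-vs-working LD matches a brute-force recomputation", {
  co <- tiny_cohort(seed = 37, n = 30, chrom_len = 3e5)
  d <- design_chip(co$variants, co$genotypes, co$panel, co$categories)
  run <- simulate_chip_run(d, co$genotypes, chip_run_spec(seed = 5))
  called <- qc_calls(run)$passed
  fw <- failing_vs_working_ld(d, called, co$genotypes, breed = "DSN")
  if (fw$n > 0) {
    g <- co$genotypes$geno[co$genotypes$breed_of == "DSN", ]
    blocks <- d$blocks
    sel <- d$selected
    for (k in seq_len(min(5, fw$n))) {
      fid <- fw$per_variant$failed_id[k]
      # brute-force partner search
      blk <- block_assignment(blocks, fid)
      pool <- sel[sel$variant_id %in% called]
      pool_blk <- block_assignment(blocks, pool$variant_id)
      cand <- if (!is.na(blk) && any(pool_blk %in% blk)) {
        pool[pool_blk %in% blk]
      } else {
        pool[pool$chrom == sel$chrom[sel$variant_id == fid]]
      }
      fpos <- sel$pos[sel$variant_id == fid]
      want <- cand$variant_id[which.min(abs(cand$pos - fpos))]
      expect_equal(fw$per_variant$partner_id[k], want)
      st <- dprime_ci(g[, fid], g[, want])
      expect_equal(fw$per_variant$dprime[k], st$dprime)
      expect_equal(fw$per_variant$r2[k], st$r2)
    }
  } else {
    succeed()
  }
})

test_that("MAF histogram bins by 0.05 starting at 0.01", {
  maf <- c(0.005, 0.01, 0.02, 0.049, 0.05, 0.12, 0.49, 0.5)
  h <- maf_histogram(maf)
  expect_equal(h$bin_low[1], 0.01)
  expect_equal(h$bin_high[1], 0.05)
  expect_equal(nrow(h), 10)
  # 0.005 and 0.01 excluded; bins are [low, high): 0.02 and 0.049 in the
  # first bin, 0.05 opens the second; 0.5 closes the last
  expect_equal(h$n[1], 2L)
  expect_equal(h$n[2], 1L)
  expect_equal(h$n[10], 2L)
  expect_equal(sum(h$n), 6L)
})
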