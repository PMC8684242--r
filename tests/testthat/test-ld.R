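test_that("EM equals direct haplotype counting when phase is unambiguous", {
  # no double heterozygote: every genotype pair resolves uniquely
  g1 <- c(0, 0, 2, 2, 1, 1, 0, 2)
  g2 <- c(0, 0, 2, 2, 0, 2, 2, 0)
  fr <- em_haplotype_freqs(g1, g2)
  # direct count: haplotypes per animal are fixed
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(unname(fr["p00"]), 5 / 16, tolerance = 1e-9)
  expect_equal(unname(fr["p11"]), 5 / 16, tolerance = 1e-9)
  expect_equal(unname(fr["p01"]), 3 / 16, tolerance = 1e-9)
  expect_equal(unname(fr["p10"]), 3 / 16, tolerance = 1e-9)
})

test_that("identical loci at AAF 0.5 give perfect LD", {
  g <- c(0, 0, 1, 1, 2, 2, 0, 2, 1, 1)
  st <- dprime_ci(g, g)
  expect_equal(unname(st$freqs), c(0.5, 0, 0, 0.5), tolerance = 1e-8)
  expect_equal(st$dprime, 1, tolerance = 1e-8)
  expect_equal(st$r2, 1, tolerance = 1e-8)
})

test_that("EM matches the fine-grid likelihood oracle on small pairs", {
  set.seed(42)
  for (k in 1:25) {
    pr <- random_pair(sample(10:30, 1))
    st <- dprime_ci(pr$g1, pr$g2)
    if (!st$defined) next
    orc <- oracle_em(pr$g1, pr$g2)
    expect_lt(max(abs(st$freqs - orc)), 1e-4)
    # and the EM likelihood is never below the best grid point
    counts <- pair_counts(pr$g1, pr$g2)
    ll_em <- oracle_loglik(counts, st$freqs[["p11"]], st$pA, st$pB)
    ll_grid <- max(oracle_loglik(
      counts, seq(max(0, st$pA + st$pB - 1), min(st$pA, st$pB),
                  length.out = 101), st$pA, st$pB))
    expect_gte(ll_em, ll_grid - 1e-6)
  }
})

test_that("D' confidence interval equals direct likelihood normalization", {
  # 6-animal toy pair
  g1 <- c(0, 1, 1, 2, 0, 2)
  g2 <- c(0, 1, 2, 2, 0, 1)
  st <- dprime_ci(g1, g2)
  orc <- oracle_ci(g1, g2)
  expect_equal(st$ci_low, orc$ci_low, tolerance = 1e-12)
  expect_equal(st$ci_high, orc$ci_high, tolerance = 1e-12)
  # random pairs
  set.seed(7)
  for (k in 1:20) {
    pr <- random_pair(sample(c(8, 20, 60), 1))
    st <- dprime_ci(pr$g1, pr$g2)
    if (!st$defined) next
    orc <- oracle_ci(pr$g1, pr$g2)
    expect_equal(st$ci_low, orc$ci_low, tolerance = 1e-9)
    expect_equal(st$ci_high, orc$ci_high, tolerance = 1e-9)
  }
})

test_that("perfect-LD pairs with many animals have a high lower bound", {
  set.seed(3)
  pr <- sim_ld_pair(100, 0.4, 0.4, 1)
  st <- dprime_ci(pr$g1, pr$g2)
  expect_gt(st$ci_low, 0.9)
})

test_that("independent common loci rarely reach the strong-LD bound", {
  set.seed(11)
  hits <- 0L
  n_rep <- 20L
  for (k in seq_len(n_rep)) {
    pr <- sim_ld_pair(1000, 0.45, 0.5, 0)
    st <- dprime_ci(pr$g1, pr$g2)
    expect_lt(st$dprime, 0.2)
    if (st$ci_high < 0.85) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 2L)
})

test_that("monomorphic loci are flagged undefined, not NaN-propagated", {
  g1 <- rep(0, 10)
  g2 <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0)
  st <- dprime_ci(g1, g2)
  expect_false(st$defined)
  expect_true(is.na(st$dprime))
  expect_error(em_haplotype_freqs(g1, g2), "monomorphic")
})

test_that("D' and r2 are invariant under allele-label swap at either locus", {
  set.seed(5)
  for (k in 1:10) {
    pr <- random_pair(40)
    a <- dprime_ci(pr$g1, pr$g2)
    b <- dprime_ci(2 - pr$g1, pr$g2)
    cc <- dprime_ci(pr$g1, 2 - pr$g2)
    if (!a$defined) next
    expect_equal(a$dprime, b$dprime, tolerance = 1e-5)
    expect_equal(a$r2, b$r2, tolerance = 1e-5)
    expect_equal(a$dprime, cc$dprime, tolerance = 1e-5)
    expect_equal(a$ci_low, b$ci_low, tolerance = 1e-9)
    expect_equal(a$ci_high, cc$ci_high, tolerance = 1e-9)
  }
})

test_that("r2 never exceeds the square of D'", {
  set.seed(9)
  for (k in 1:40) {
    pr <- random_pair(sample(c(10, 30, 80), 1), maf_min = 0.05)
    st <- dprime_ci(pr$g1, pr$g2)
    if (!st$defined) next
    expect_lte(st$r2, st$dprime^2 + 1e-9)
  }
})

test_that("duplicating every animal fixes the point estimate, never widens the CI", {
  # CI bounds are percentiles of a distribution discretized on a 0.01 grid,
  # so monotone support sharpening is asserted up to one grid step
  step <- 0.01
  set.seed(13)
  for (k in 1:10) {
    pr <- random_pair(30)
    a <- dprime_ci(pr$g1, pr$g2)
    b <- dprime_ci(rep(pr$g1, 2), rep(pr$g2, 2))
    if (!a$defined) next
    expect_equal(a$dprime, b$dprime, tolerance = 1e-6)
    expect_equal(a$r2, b$r2, tolerance = 1e-6)
    expect_gte(b$ci_low, a$ci_low - step - 1e-12)
    expect_lte(b$ci_high, a$ci_high + step + 1e-12)
    expect_lte(b$ci_high - b$ci_low, a$ci_high - a$ci_low + step + 1e-12)
  }
})

test_that("a tight run of perfect-LD SNPs forms a single complete block", {
  set.seed(21)
  sim <- sim_block_geno(100, list(c(1000, 3000, 5000, 7000, 9000)))
  gm <- make_gm(sim$geno)
  v <- data.table::data.table(id = colnames(gm$geno), chrom = "chr1",
                              pos = sim$pos)
  blocks <- call_blocks(gm, v)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_variants, 5L)
  expect_setequal(blocks$variant_ids[[1]], v$id)
})

test_that("blocks never span more than the window", {
  set.seed(22)
  sim <- sim_block_geno(100, list(c(1e3, 2e3, 3e3), c(301e3, 302e3, 303e3)))
  # make the two triplets carry identical genotypes: perfect LD across 300 kb
  sim$geno[, 4:6] <- sim$geno[, 1:3]
  gm <- make_gm(sim$geno)
  v <- data.table::data.table(id = colnames(gm$geno), chrom = "chr1",
                              pos = sim$pos)
  blocks <- call_blocks(gm, v)
  expect_equal(nrow(blocks), 2)
  expect_true(all(blocks$length_bp <= 200e3))
})

test_that("block caller matches the exhaustive-enumeration oracle", {
  set.seed(31)
  for (k in 1:50) {
    n_snp <- sample(4:8, 1)
    pos <- sort(sample.int(50e3, n_snp))
    n_animals <- 60
    layout <- sample(1:3, 1)
    sim <- if (layout == 1) {
      sim_block_geno(n_animals, list(pos))
    } else if (layout == 2) {
      cut <- sample(2:(n_snp - 1), 1)
      sim_block_geno(n_animals, list(pos[1:cut], pos[(cut + 1):n_snp]))
    } else {
      g <- sapply(seq_len(n_snp), function(i)
        rbinom(n_animals, 2, runif(1, 0.1, 0.9)))
      list(geno = g, pos = pos)
    }
    gm <- make_gm(sim$geno)
    v <- data.table::data.table(id = colnames(gm$geno), chrom = "chr1",
                                pos = sim$pos)
    blocks <- call_blocks(gm, v)
    orc <- oracle_blocks(gm$geno, sim$pos)
    expect_equal(nrow(blocks), nrow(orc))
    if (nrow(orc) > 0) {
      got <- lapply(blocks$variant_ids, function(ids) match(ids, v$id))
      want <- lapply(seq_len(nrow(orc)), function(r) orc$i[r]:orc$j[r])
      expect_equal(got, want)
    }
  }
})

test_that("unsorted variant input is rejected", {
  sim <- sim_block_geno(20, list(c(1000, 2000, 3000)))
  gm <- make_gm(sim$geno)
  v <- data.table::data.table(id = colnames(gm$geno), chrom = "chr1",
                              pos = c(3000, 1000, 2000))
  expect_error(call_blocks(gm, v), "sorted")
})

test_that("ld_table reports pairs only within the window", {
  set.seed(41)
  sim <- sim_block_geno(50, list(c(1e3, 5e3), c(400e3, 401e3)))
  gm <- make_gm(sim$geno)
  v <- data.table::data.table(id = colnames(gm$geno), chrom = "chr1",
                              pos = sim$pos)
  tab <- ld_table(gm, v)
  expect_true(all(tab$pos_b - tab$pos_a <= 200e3))
  expect_equal(nrow(tab), 2)  # the two intra-block pairs only
})
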