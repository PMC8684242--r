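# in-code fixtures shared across test files

make_gm <- function(geno, breed = "DSN", conf = NULL, depth = NULL) {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("A%02d", seq_len(nrow(geno)))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("v%d", seq_len(ncol(geno)))
  }
  breed_of <- if (length(breed) == 1) {
    stats::setNames(rep(breed, nrow(geno)), rownames(geno))
  } else {
    stats::setNames(breed, rownames(geno))
  }
  genotype_matrix(geno, breed_of, conf = conf, depth = depth)
}

# two loci with prescribed allele frequencies and D' (positive association),
# genotypes drawn under HWE
sim_ld_pair <- function(n, pA, pB, dprime) {
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- dprime * dmax
  p <- c(`00` = (1 - pA) * (1 - pB) + D, `01` = (1 - pA) * pB - D,
         `10` = pA * (1 - pB) - D, `11` = pA * pB + D)
  hap <- matrix(sample(4, 2 * n, replace = TRUE, prob = p), ncol = 2)
  altA <- matrix(c(0, 0, 1, 1)[hap], ncol = 2)
  altB <- matrix(c(0, 1, 0, 1)[hap], ncol = 2)
  list(g1 = rowSums(altA), g2 = rowSums(altB))
}

# random genotype pair with guaranteed polymorphism at both loci
random_pair <- function(n, maf_min = 0.1) {
  repeat {
    g1 <- rbinom(n, 2, runif(1, maf_min, 1 - maf_min))
    g2 <- rbinom(n, 2, runif(1, maf_min, 1 - maf_min))
    if (length(unique(g1)) > 1 && length(unique(g2)) > 1) {
      return(list(g1 = g1, g2 = g2))
    }
  }
}

# multi-block genotype set: founder-haplotype blocks with free recombination
# between blocks, for block-caller tests
sim_block_geno <- function(n_animals, blocks, founders = 2) {
  # blocks: list of integer vectors of positions
  geno <- NULL
  pos <- integer(0)
  for (b in seq_along(blocks)) {
    m <- length(blocks[[b]])
    pat <- matrix(rbinom(founders * m, 1, 0.5), nrow = founders)
    while (any(apply(pat, 2, function(x) length(unique(x)) == 1))) {
      bad <- which(apply(pat, 2, function(x) length(unique(x)) == 1))
      pat[, bad] <- rbinom(founders * length(bad), 1, 0.5)
    }
    f <- matrix(sample(founders, 2 * n_animals, replace = TRUE), ncol = 2)
    g <- pat[f[, 1], , drop = FALSE] + pat[f[, 2], , drop = FALSE]
    geno <- cbind(geno, g)
    pos <- c(pos, blocks[[b]])
  }
  list(geno = geno, pos = pos)
}

tiny_cohort <- function(seed = 1, n = 40, chrom_len = 5e5, ...) {
  simulate_cohort(cohort_spec(
    breeds = c(DSN = as.integer(n), HOL = as.integer(n)),
    chromosomes = c(chr1 = chrom_len), seed = as.integer(seed), ...))
}

# minimal hand-built chip_design
fake_design <- function(variants, blocks = NULL) {
  v <- data.table::as.data.table(variants)
  if (!"probesets" %in% names(v)) v$probesets <- 1L
  if (!"category" %in% names(v)) v$category <- 1L
  if (!"pconvert_fwd" %in% names(v)) v$pconvert_fwd <- 0.9
  if (!"pconvert_rev" %in% names(v)) v$pconvert_rev <- 0.9
  data.table::setnames(v, "id", "variant_id", skip_absent = TRUE)
  structure(list(
    selected = v,
    category_counts = data.table::data.table(
      category = 1:10,
      label = paste0("cat", 1:10),
      n_unique = c(nrow(v), rep(0L, 9)),
      n_total = c(nrow(v), rep(0L, 9))),
    totals = list(n_variants = nrow(v), n_snps = sum(v$class == "SNP"),
                  n_indels = sum(v$class == "indel"),
                  n_probesets = sum(v$probesets)),
    blocks = blocks %||% data.table::data.table(
      block = integer(), chrom = character(), start = integer(),
      end = integer(), length_bp = integer(), n_variants = integer(),
      variant_ids = list()),
    capacity = 205000
  ), class = "chip_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
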