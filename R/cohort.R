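CONSEQUENCE_POOL <- list(
  modifier = c("intron_variant", "intergenic_variant",
               "upstream_gene_variant", "downstream_gene_variant"),
  low = c("synonymous_variant", "splice_region_variant",
          "3_prime_UTR_variant", "5_prime_UTR_variant"),
  moderate = c("missense_variant", "inframe_deletion", "inframe_insertion"),
  high = c("stop_gained", "splice_donor_variant", "frameshift_variant")
)

#' Synthetic multi-breed cohort specification
#'
#' Parameters of the simulated whole-genome-sequenced cohort the design
#' pipeline is exercised on. Defaults mirror the sequencing study the
#' pipeline is built for: per-animal fold coverage ~ Normal(18.72, 2.44)
#' truncated at 1, consequence-impact class proportions
#' 97.17/2.19/0.60/0.04% (modifier/low/moderate/high), conversion scores
#' concentrated in \[0.6, 1\] with a tail over \[0.3, 0.8\], and
#' block-structured LD from a small pool of founder haplotypes per block
#' with free recombination between blocks.
#'
#' @param breeds named integer vector: animals per breed; the first breed is
#'   the focal breed.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param variant_density expected variants per kb.
#' @param block_length_mean,block_length_min haplotype-block length model
#'   (exponential mean, lower truncation), bp.
#' @param founders_range inclusive range of founder haplotypes per block.
#' @param aaf_shape `c(shape1, shape2)` of the Beta allele-frequency
#'   spectrum targets.
#' @param unique_fraction fraction of variants private to the focal breed.
#' @param depth_mean,depth_sd per-animal fold-coverage distribution.
#' @param impact_proportions probabilities over
#'   (modifier, low, moderate, high); must sum to 1 within 1e-9.
#' @param indel_fraction fraction of variants simulated as indels.
#' @param pconvert_high_weight mixture weight of the near-1 conversion-score
#'   component (the rest is uniform on \[0.3, 0.8\]).
#' @param prior_array_fraction,gwas_fraction,gwas_imputed_share,parentage_n,
#'   empirical_fraction sizes of the simulated category side-lists
#'   (prior-array SNPs, trait-associated variants and their imputed share,
#'   parentage-panel variants, empirically validated probes).
#' @param seed random seed; identical seed and spec give byte-identical
#'   output.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(breeds = c(DSN = 100L, HOL = 100L),
                        chromosomes = c(chr1 = 5e6),
                        variant_density = 1,
                        block_length_mean = 15e3,
                        block_length_min = 1e3,
                        founders_range = c(2L, 4L),
                        aaf_shape = c(0.8, 2.0),
                        unique_fraction = 0.10,
                        depth_mean = 18.72,
                        depth_sd = 2.44,
                        impact_proportions = c(modifier = 0.9717,
                                               low = 0.0219,
                                               moderate = 0.0060,
                                               high = 0.0004),
                        indel_fraction = 0.10,
                        pconvert_high_weight = 0.80,
                        prior_array_fraction = 0.03,
                        gwas_fraction = 0.005,
                        gwas_imputed_share = 0.5,
                        parentage_n = 25L,
                        empirical_fraction = 0.30,
                        seed = 1L) {
  if (is.null(names(breeds)) || any(names(breeds) == "")) {
    stop_field("breeds", "must be a named vector (breed -> n animals)")
  }
  check_positive(breeds, "breeds")
  if (is.null(names(chromosomes)) || any(names(chromosomes) == "")) {
    stop_field("chromosomes", "must be a named vector of lengths")
  }
  check_positive(chromosomes, "chromosomes")
  check_positive(variant_density, "variant_density")
  check_positive(block_length_mean, "block_length_mean")
  check_positive(block_length_min, "block_length_min")
  if (length(founders_range) != 2 || founders_range[1] < 2 ||
      founders_range[2] < founders_range[1]) {
    stop_field("founders_range", "needs lower bound >= 2 and upper >= lower")
  }
  check_positive(aaf_shape, "aaf_shape")
  check_prob(unique_fraction, "unique_fraction")
  check_positive(depth_mean, "depth_mean")
  check_positive(depth_sd, "depth_sd")
  if (length(impact_proportions) != 4 ||
      !setequal(names(impact_proportions), IMPACT_LEVELS)) {
    stop_field("impact_proportions",
               "needs the four named classes modifier/low/moderate/high")
  }
  check_prob(impact_proportions, "impact_proportions")
  if (abs(sum(impact_proportions) - 1) > 1e-9) {
    stop_field("impact_proportions", "must sum to 1 within 1e-9")
  }
  check_prob(indel_fraction, "indel_fraction")
  check_prob(pconvert_high_weight, "pconvert_high_weight")
  check_prob(prior_array_fraction, "prior_array_fraction")
  check_prob(gwas_fraction, "gwas_fraction")
  check_prob(gwas_imputed_share, "gwas_imputed_share")
  check_positive(parentage_n, "parentage_n", strict = FALSE)
  check_prob(empirical_fraction, "empirical_fraction")
  structure(as.list(environment()), class = "cohort_spec")
}

# founder allele patterns for one block x one breed: K founders x m variants,
# entry 1 = founder carries the alt allele. Columns that come up all-zero but
# must be present get a single uniformly drawn carrier founder (rare variants
# then ride on one founder haplotype, as rare alleles do).
draw_patterns <- function(K, p, present) {
  m <- length(p)
  pat <- matrix(rbinom(K * m, 1L, rep(p, each = K)), nrow = K)
  zero <- which(colSums(pat) == 0 & present)
  if (length(zero) > 0) {
    pat[cbind(sample.int(K, length(zero), replace = TRUE), zero)] <- 1L
  }
  pat[, !present] <- 0L
  pat
}

#' Simulate a multi-breed sequenced cohort
#'
#' Generates variants with block-structured LD: each chromosome is
#' partitioned into haplotype blocks; within a block every breed owns a
#' small pool of founder haplotypes (with breed-specific frequencies) from
#' which each animal draws two, independently across blocks (free
#' recombination between blocks, no recombination within). Breed-unique
#' variants carry their alternative allele only on focal-breed founders.
#' Per-variant read depth is the sum of per-animal Poisson draws around each
#' animal's fold coverage. Every variant receives a consequence term drawn
#' to match the impact-class proportions and two per-strand conversion
#' scores.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort`: `variants` (`data.table` incl.
#'   simulation truth columns `block_truth`, `unique_true`,
#'   `target_aaf_<breed>` and category flags), `genotypes` (a
#'   [genotype_matrix()] with per-animal depths), `blocks_truth`,
#'   `categories` (side-lists ready for [select_categories()]), `panel`, and
#'   the echoed `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  breeds <- names(spec$breeds)
  focal <- breeds[1]
  n_per <- as.integer(spec$breeds)
  animal_ids <- unlist(lapply(seq_along(breeds), function(b)
    sprintf("%s_%03d", breeds[b], seq_len(n_per[b]))))
  breed_of <- stats::setNames(rep(breeds, n_per), animal_ids)
  n_animals <- length(animal_ids)

  var_rows <- list()
  geno_cols <- list()
  block_tabs <- list()
  block_counter <- 0L
  for (chr in names(spec$chromosomes)) {
    L <- spec$chromosomes[[chr]]
    # block partition: truncated-exponential lengths tiling the chromosome
    lens <- numeric(0)
    while (sum(lens) < L) {
      lens <- c(lens, pmax(spec$block_length_min,
                           rexp(64, 1 / spec$block_length_mean)))
    }
    starts <- cumsum(c(0, lens))
    starts <- starts[starts < L]
    n_blocks <- length(starts)
    n_var <- rpois(1, spec$variant_density * L / 1000)
    pos <- sort(sample.int(L, min(n_var, L)))
    m <- length(pos)
    block_local <- findInterval(pos, starts)
    blk_ids <- block_counter + seq_len(n_blocks)
    block_tabs[[chr]] <- data.table(
      block_truth = blk_ids, chrom = chr,
      start = as.integer(starts) + 1L,
      end = as.integer(pmin(c(starts[-1], L), L)))
    target_p <- rbeta(m, spec$aaf_shape[1], spec$aaf_shape[2])
    uniq <- runif(m) < spec$unique_fraction
    geno <- matrix(NA_integer_, nrow = n_animals, ncol = m,
                   dimnames = list(animal_ids, NULL))
    target_aaf <- matrix(NA_real_, nrow = m, ncol = length(breeds),
                         dimnames = list(NULL, breeds))
    for (bl in seq_len(n_blocks)) {
      idx <- which(block_local == bl)
      if (length(idx) == 0) next
      K <- if (spec$founders_range[1] == spec$founders_range[2]) {
        spec$founders_range[1]
      } else {
        sample(seq(spec$founders_range[1], spec$founders_range[2]), 1)
      }
      for (b in seq_along(breeds)) {
        is_focal <- breeds[b] == focal
        present <- if (is_focal) rep(TRUE, length(idx)) else !uniq[idx]
        w <- rgamma(K, 1)
        w <- w / sum(w)
        pat <- draw_patterns(K, target_p[idx], present)
        target_aaf[idx, b] <- as.numeric(w %*% pat)
        rows <- which(breed_of == breeds[b])
        f <- matrix(sample.int(K, 2 * length(rows), replace = TRUE,
                               prob = w), ncol = 2)
        geno[rows, idx] <- pat[f[, 1], , drop = FALSE] +
          pat[f[, 2], , drop = FALSE]
      }
    }
    # alleles and variant class
    is_indel <- runif(m) < spec$indel_fraction
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    extra <- sample(bases, m, replace = TRUE)
    ins <- runif(m) < 0.5
    ref_out <- ifelse(is_indel & !ins, paste0(ref, extra), ref)
    alt_out <- ifelse(is_indel & ins, paste0(ref, extra),
                      ifelse(is_indel, ref, alt))
    impact_class <- sample(names(spec$impact_proportions), m, replace = TRUE,
                           prob = spec$impact_proportions)
    consequence <- vapply(impact_class, function(cl)
      sample(CONSEQUENCE_POOL[[cl]], 1), character(1))
    pc <- function(n) {
      hi <- runif(n) < spec$pconvert_high_weight
      ifelse(hi, 1 - 0.4 * rbeta(n, 2, 5), runif(n, 0.3, 0.8))
    }
    vr <- data.table(
      id = sprintf("%s_%d", chr, pos),
      chrom = chr, pos = pos,
      ref = unname(ref_out), alt = unname(alt_out),
      class = variant_class(ref_out, alt_out),
      block_truth = blk_ids[block_local],
      unique_true = uniq,
      consequence = unname(consequence),
      pconvert_fwd = pc(m), pconvert_rev = pc(m)
    )
    for (b in seq_along(breeds)) {
      vr[, (paste0("target_aaf_", breeds[b])) := target_aaf[, b]]
    }
    colnames(geno) <- vr$id
    var_rows[[chr]] <- vr
    geno_cols[[chr]] <- geno
    block_counter <- block_counter + n_blocks
  }
  variants <- data.table::rbindlist(var_rows)
  geno <- do.call(cbind, geno_cols)
  # per-animal fold coverage, then per-variant per-animal Poisson depth
  coverage <- pmax(1, rnorm(n_animals, spec$depth_mean, spec$depth_sd))
  depth <- matrix(rpois(n_animals * ncol(geno), coverage),
                  nrow = n_animals, dimnames = dimnames(geno))
  variants[, total_depth := colSums(depth)]
  variants[, impact := classify_impact(consequence)]

  # category side-lists
  maf_target <- pmin(variants[[paste0("target_aaf_", focal)]],
                     1 - variants[[paste0("target_aaf_", focal)]])
  common_snp <- variants$class == "SNP" & maf_target >= 0.05
  variants[, prior_array := common_snp &
             runif(.N) < spec$prior_array_fraction / max(mean(common_snp),
                                                         1e-9)]
  variants[, gwas := runif(.N) < spec$gwas_fraction]
  variants[, gwas_imputed := gwas & runif(.N) < spec$gwas_imputed_share]
  n_parent <- min(spec$parentage_n, sum(common_snp))
  parent_ids <- sample(variants$id[common_snp], n_parent)
  variants[, parentage := id %in% parent_ids]
  variants[, empirical := runif(.N) < spec$empirical_fraction]

  categories <- list(
    prior_array_ids = variants[prior_array == TRUE, id],
    gwas_ids = variants[gwas == TRUE, id],
    gwas_imputed_ids = variants[gwas_imputed == TRUE, id],
    parentage_ids = variants[parentage == TRUE, id],
    empirical_ids = variants[empirical == TRUE, id]
  )
  structure(list(
    variants = variants,
    genotypes = genotype_matrix(geno, breed_of, depth = depth),
    blocks_truth = data.table::rbindlist(block_tabs),
    categories = categories,
    panel = breed_panel(focal, setdiff(breeds, focal)),
    spec = spec
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d variants on %d chromosome(s), %d animals (%s), seed %d\n",
    nrow(x$variants), length(x$spec$chromosomes),
    nrow(x$genotypes$geno),
    paste(sprintf("%s=%d", names(x$spec$breeds), x$spec$breeds),
          collapse = ", "),
    x$spec$seed))
  invisible(x)
}

#' Write a cohort to VCF plus breed sidecar
#'
#' Writes the simulated cohort as VCFv4.2 (genotypes and per-sample depths,
#' consequence and conversion scores in INFO, simulation parameters echoed
#' in the header) plus the two-column breed table.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param vcf_path,breed_path output paths.
#' @return paths, invisibly.
#' @export
write_cohort <- function(cohort, vcf_path, breed_path) {
  sp <- cohort$spec
  echo <- vapply(names(sp), function(k)
    sprintf("##cohortSpec_%s=%s", k, paste(sp[[k]], collapse = ",")),
    character(1))
  write_vcf(cohort$variants, cohort$genotypes, vcf_path,
            header_extra = unname(echo))
  write_breed_table(cohort$genotypes$breed_of, breed_path)
  invisible(c(vcf_path, breed_path))
}
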