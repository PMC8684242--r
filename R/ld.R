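#' LD engine configuration
#'
#' Thresholds for pairwise LD and confidence-interval haplotype-block
#' calling. Defaults: blocks are sought within 200 kb windows; a pair is in
#' strong LD when the 90% likelihood interval on |D'| has lower bound >= 0.60
#' and upper bound >= 0.85; strong evidence of recombination is an upper
#' bound < 0.90; a candidate span is a block when at least 95% of its
#' informative pairs are in strong LD. Pairs with fewer than 5 animals
#' informative at both loci are excluded. The |D'| likelihood is profiled on
#' a 101-point grid (step 0.01), the usual Haploview-style discretization.
#'
#' @param window maximum block span in bp.
#' @param ci_grid number of grid points on \[0, 1\] for the |D'| likelihood.
#' @param strong_ci_low,strong_ci_high strong-LD bounds on the 90% interval.
#' @param recomb_ci_high upper-bound threshold for strong recombination.
#' @param strong_fraction required fraction of informative pairs in strong LD.
#' @param min_informative minimum animals non-missing at both loci.
#' @param em_tol,em_max_iter EM convergence: max-abs haplotype-frequency
#'   change below `em_tol`, or `em_max_iter` iterations.
#' @return a list of class `ld_config`.
#' @export
ld_config <- function(window = 200e3, ci_grid = 101L,
                      strong_ci_low = 0.60, strong_ci_high = 0.85,
                      recomb_ci_high = 0.90, strong_fraction = 0.95,
                      min_informative = 5L, em_tol = 1e-8,
                      em_max_iter = 1000L) {
  check_positive(window, "window")
  check_positive(ci_grid, "ci_grid")
  for (f in c("strong_ci_low", "strong_ci_high", "recomb_ci_high",
              "strong_fraction")) {
    check_prob(get(f), f)
  }
  structure(as.list(environment()), class = "ld_config")
}

#' EM haplotype frequencies for two biallelic loci
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased
#' genotypes under Hardy-Weinberg equilibrium. Phase is unambiguous except
#' for double heterozygotes, whose cis/trans split is estimated by EM
#' (three starts to avoid boundary stagnation). When no double heterozygote
#' is present the EM solution equals direct haplotype counting.
#'
#' @param g1,g2 integer genotype vectors (0/1/2/`NA`) over the same animals.
#' @param config an [ld_config()].
#' @return named numeric vector `(p00, p01, p10, p11)`; first index is the
#'   allele at the first locus (0 = ref, 1 = alt).
#' @export
em_haplotype_freqs <- function(g1, g2, config = ld_config()) {
  st <- ld_pair_core(as.integer(g1), as.integer(g2),
                     grid_n = config$ci_grid, tol = config$em_tol,
                     max_iter = config$em_max_iter)
  if (!st$defined) {
    stop("LD undefined: a locus is monomorphic (or unobserved) ",
         "among shared non-missing animals")
  }
  st$freqs
}

#' Pairwise D' with likelihood confidence interval
#'
#' EM haplotype frequencies, D, |D'|, r-squared, and a 90% likelihood-based
#' interval on |D'|: the multinomial likelihood of the two-locus genotype
#' table is evaluated on a fixed |D'| grid with allele frequencies held at
#' their sample estimates, normalized to a distribution, and the 5th and
#' 95th percentiles reported.
#'
#' @inheritParams em_haplotype_freqs
#' @return a list of class `ld_stats`: `freqs`, `D`, `dprime`, `r2`,
#'   `ci_low`, `ci_high`, `n_informative`, `defined`.
#' @export
dprime_ci <- function(g1, g2, config = ld_config()) {
  st <- ld_pair_core(as.integer(g1), as.integer(g2),
                     grid_n = config$ci_grid, tol = config$em_tol,
                     max_iter = config$em_max_iter)
  structure(st, class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  if (!x$defined) {
    cat("<ld_stats> undefined (monomorphic locus)\n")
  } else {
    cat(sprintf(
      "<ld_stats> D' = %.3f [90%% CI %.2f-%.2f], r2 = %.3f (n = %d)\n",
      x$dprime, x$ci_low, x$ci_high, x$r2, as.integer(x$n_informative)))
  }
  invisible(x)
}

# genotype submatrix (animals x variants) for one chromosome, position order
chrom_geno <- function(genotypes, variants, chr, breed = "all") {
  v <- as.data.table(variants)[chrom == chr][order(pos)]
  ids <- animals_of_breed(genotypes, breed)
  list(v = v, g = genotypes$geno[ids, v$id, drop = FALSE])
}

#' Pairwise LD table within a window
#'
#' All two-locus statistics for variant pairs whose start positions lie
#' within `config$window` bp of each other, per chromosome.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `id`, `chrom`, `pos`.
#' @param chroms chromosomes to scan (default: all present).
#' @param breed breed whose animals are used (default pooled).
#' @param config an [ld_config()].
#' @return `data.table`: `chrom`, `id_a`, `pos_a`, `id_b`, `pos_b`,
#'   `dprime`, `r2`, `ci_low`, `ci_high`, `n_informative`, `defined`.
#' @export
ld_table <- function(genotypes, variants, chroms = NULL, breed = "all",
                     config = ld_config()) {
  v <- as.data.table(variants)
  chroms <- chroms %||% unique(v$chrom)
  out <- lapply(chroms, function(chr) {
    cg <- chrom_geno(genotypes, v, chr, breed)
    if (nrow(cg$v) < 2) return(NULL)
    tab <- as.data.table(ld_window_core(
      cg$g, as.numeric(cg$v$pos), config$window, config$ci_grid,
      config$em_tol, config$em_max_iter))
    if (nrow(tab) == 0) return(NULL)
    data.table(chrom = chr,
               id_a = cg$v$id[tab$i], pos_a = cg$v$pos[tab$i],
               id_b = cg$v$id[tab$j], pos_b = cg$v$pos[tab$j],
               dprime = tab$dprime, r2 = tab$r2, ci_low = tab$ci_low,
               ci_high = tab$ci_high, n_informative = tab$n_informative,
               defined = tab$defined == 1)
  })
  data.table::rbindlist(out)
}

#' Call confidence-interval haplotype blocks
#'
#' Gabriel-style block calling from unphased genotypes: every pair within
#' the window is classified from its |D'| likelihood interval as strong LD,
#' strong recombination, or non-informative; every candidate span whose
#' informative pairs are in strong LD at the required fraction is
#' enumerated; overlapping candidates are resolved longest-span-first
#' (leftmost on ties), so the returned blocks are non-overlapping with at
#' least two member variants each.
#'
#' @param genotypes a [genotype_matrix()].
#' @param variants variant table with `id`, `chrom`, `pos`. Positions must be
#'   sorted within chromosome; unsorted input is an error.
#' @param chroms chromosomes to scan (default all).
#' @param breed breed whose animals are used (default pooled).
#' @param config an [ld_config()].
#' @return `data.table` of blocks: `block`, `chrom`, `start`, `end`,
#'   `length_bp`, `n_variants`, `variant_ids` (list column, position order).
#' @export
call_blocks <- function(genotypes, variants, chroms = NULL, breed = "all",
                        config = ld_config()) {
  v <- as.data.table(variants)
  if (any(v[, is.unsorted(pos), by = chrom]$V1)) {
    stop("variants must be position-sorted within chromosome")
  }
  chroms <- chroms %||% unique(v$chrom)
  blocks <- lapply(chroms, function(chr) {
    cg <- chrom_geno(genotypes, v, chr, breed)
    if (nrow(cg$v) < 2) return(NULL)
    spans <- as.data.table(gabriel_spans_core(
      cg$g, as.numeric(cg$v$pos), config$window, config$ci_grid,
      config$em_tol, config$em_max_iter, config$strong_ci_low,
      config$strong_ci_high, config$recomb_ci_high,
      config$strong_fraction, config$min_informative))
    if (nrow(spans) == 0) return(NULL)
    chosen <- resolve_spans(spans, cg$v$pos)
    if (nrow(chosen) == 0) return(NULL)
    data.table(
      chrom = chr,
      start = cg$v$pos[chosen$i],
      end = cg$v$pos[chosen$j],
      n_variants = chosen$j - chosen$i + 1L,
      variant_ids = lapply(seq_len(nrow(chosen)),
                           function(k) cg$v$id[chosen$i[k]:chosen$j[k]])
    )
  })
  out <- data.table::rbindlist(blocks)
  if (nrow(out) == 0) {
    return(data.table(block = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      length_bp = integer(), n_variants = integer(),
                      variant_ids = list()))
  }
  setorder(out, chrom, start)
  out[, length_bp := end - start]
  out[, block := .I]
  data.table::setcolorder(out, c("block", "chrom", "start", "end",
                                 "length_bp", "n_variants", "variant_ids"))
  out[]
}

# longest-span-first greedy selection of non-overlapping candidate spans;
# ties broken leftmost, then by member count (larger first)
resolve_spans <- function(spans, pos) {
  spans <- as.data.table(spans)
  spans[, span_bp := pos[j] - pos[i]]
  setorder(spans, -span_bp, i, -j)
  taken <- rep(FALSE, length(pos))
  keep <- logical(nrow(spans))
  for (k in seq_len(nrow(spans))) {
    idx <- spans$i[k]:spans$j[k]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- spans[keep]
  setorder(out, i)
  out
}

#' Map variants to their haplotype block
#'
#' @param blocks output of [call_blocks()].
#' @param variant_ids ids to look up.
#' @return integer vector: block number per variant (`NA` when unblocked).
#' @export
block_assignment <- function(blocks, variant_ids) {
  if (nrow(blocks) == 0) {
    return(rep(NA_integer_, length(variant_ids)))
  }
  map <- blocks[, .(variant_id = unlist(variant_ids)), by = block]
  map$block[match(variant_ids, map$variant_id)]
}

#' Write blocks in PLINK .blocks / .blocks.det format
#'
#' @param blocks output of [call_blocks()].
#' @param prefix output path prefix; writes `<prefix>.blocks` and
#'   `<prefix>.blocks.det`.
#' @return the two paths, invisibly.
#' @export
write_blocks <- function(blocks, prefix) {
  p1 <- paste0(prefix, ".blocks")
  p2 <- paste0(prefix, ".blocks.det")
  writeLines(vapply(blocks$variant_ids, function(ids)
    paste(c("*", ids), collapse = " "), character(1)), p1)
  det <- blocks[, .(
    CHR = chrom, BP1 = start, BP2 = end,
    KB = round((end - start + 1) / 1000, 3),
    NSNPS = n_variants,
    SNPS = vapply(variant_ids, paste, character(1), collapse = "|"))]
  utils::write.table(det, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
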