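#' Chip design configuration
#'
#' Parameters of the ordered ten-category selection. Defaults: probeset
#' budget of a "200 k-class" array (205,000); complete LD means r-squared of
#' 1 within 1e-9 on EM haplotype frequencies, with at most two variants of
#' one complete-LD clique kept per haplotype block; the block-coverage
#' category considers blocks longer than 5 kb, or longer than 1 kb when
#' within 100 kb of a coding gene; gap filling targets inter-variant gaps
#' above 250 kb; trait-associated variants not derived from imputed data are
#' tiled with a replicate probeset factor of 2.
#'
#' @param capacity probeset budget.
#' @param complete_ld_tol complete-LD tolerance on 1 - r2.
#' @param max_complete_ld maximum variants kept per complete-LD clique.
#' @param gap_limit gap-filling threshold in bp.
#' @param block_min_span minimum block span (bp) for block coverage.
#' @param block_alt_min_span relaxed span when near a coding gene.
#' @param gene_window coding-gene proximity window (bp).
#' @param replicate_factor probeset multiplier for non-imputed
#'   trait-associated variants.
#' @param divergence_threshold AAF-difference threshold for the divergence
#'   category (strict).
#' @param maf_priority MAF threshold used in block-representative ranking.
#' @param y_chrom,mt_chrom chromosome names treated as Y and mitochondria.
#' @return a list of class `design_config`.
#' @export
design_config <- function(capacity = 205000,
                          complete_ld_tol = 1e-9,
                          max_complete_ld = 2L,
                          gap_limit = 250e3,
                          block_min_span = 5000,
                          block_alt_min_span = 1000,
                          gene_window = 100e3,
                          replicate_factor = 2L,
                          divergence_threshold = 0.70,
                          maf_priority = 0.05,
                          y_chrom = "Y", mt_chrom = "MT") {
  check_positive(capacity, "capacity")
  check_positive(gap_limit, "gap_limit")
  check_positive(replicate_factor, "replicate_factor")
  check_prob(divergence_threshold, "divergence_threshold")
  structure(as.list(environment()), class = "design_config")
}

#' Probesets needed per variant
#'
#' A/T and C/G SNPs cannot be distinguished by the two-dye labeling
#' chemistry with a single probeset and need a second one; every other SNP
#' and every indel needs one.
#'
#' @param ref,alt allele strings.
#' @return integer vector of probeset counts.
#' @export
probesets_for <- function(ref, alt) {
  cls <- variant_class(ref, alt)
  pair <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  ifelse(cls == "SNP" & pair %in% c("A/T", "C/G"), 2L, 1L)
}

#' Order-respecting unique-category attribution
#'
#' Given the per-category member id sets in selection order, attributes each
#' selected variant to the first category that picked it. The total count of
#' a category includes every selected variant it contains regardless of
#' order; the unique count only the newly added ones, so unique counts sum
#' to the total number of selected variants.
#'
#' @param id_sets ordered named list of character vectors of variant ids.
#' @return list with `assignment` (`data.table`: `variant_id`, `category` =
#'   1-based index of the attributing set) and `counts` (`data.table`:
#'   `category`, `label`, `n_unique`, `n_total`).
#' @export
assign_unique_categories <- function(id_sets) {
  labels <- names(id_sets) %||% paste0("category_", seq_along(id_sets))
  seen <- character(0)
  rows <- vector("list", length(id_sets))
  counts <- data.table(category = seq_along(id_sets), label = labels,
                       n_unique = 0L, n_total = 0L)
  for (k in seq_along(id_sets)) {
    ids <- unique(id_sets[[k]])
    new_ids <- setdiff(ids, seen)
    seen <- c(seen, new_ids)
    rows[[k]] <- if (length(new_ids) > 0) {
      data.table(variant_id = new_ids, category = k)
    } else NULL
    counts$n_unique[k] <- length(new_ids)
  }
  all_selected <- seen
  for (k in seq_along(id_sets)) {
    counts$n_total[k] <- length(intersect(unique(id_sets[[k]]), all_selected))
  }
  list(assignment = data.table::rbindlist(rows), counts = counts)
}

# drop members of complete-LD cliques beyond the per-block cap; returns ids
# to remove. Cliques = connected components of r2 >= 1 - tol edges among the
# given candidate ids inside one haplotype block; the first `max_keep`
# members in position order are kept.
prune_complete_ld <- function(candidate_ids, variants, genotypes, blocks,
                              breed, tol = 1e-9, max_keep = 2L,
                              ld_cfg = ld_config()) {
  if (length(candidate_ids) == 0 || nrow(blocks) == 0) return(character(0))
  v <- as.data.table(variants)[id %in% candidate_ids]
  v[, block := block_assignment(blocks, id)]
  v <- v[!is.na(block)][order(block, pos)]
  if (nrow(v) == 0) return(character(0))
  ids_animals <- animals_of_breed(genotypes, breed)
  g <- genotypes$geno[ids_animals, , drop = FALSE]
  drop <- character(0)
  for (b in unique(v$block)) {
    ids <- v[block == b, id]
    m <- length(ids)
    if (m <= max_keep) next
    parent <- seq_len(m)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        st <- ld_pair_core(g[, ids[i]], g[, ids[j]], ld_cfg$ci_grid,
                           ld_cfg$em_tol, ld_cfg$em_max_iter)
        if (isTRUE(st$defined) && st$r2 >= 1 - tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(m), find, integer(1))
    for (cc in unique(comp)) {
      members <- ids[comp == cc]  # already in position order
      if (length(members) > max_keep) {
        drop <- c(drop, members[-seq_len(max_keep)])
      }
    }
  }
  drop
}

#' Residual gaps between adjacent selected variants
#'
#' Reports every interval between adjacent variants (per chromosome) whose
#' span exceeds the limit. In evaluation mode, pass the positions of the
#' successfully called variants instead of the full design.
#'
#' @param positions a `data.table`/data.frame with `chrom` and `pos`, or a
#'   `chip_design` (its selected variants are used).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, the leading and trailing intervals of each chromosome are
#'   reported too.
#' @param limit minimum gap span in bp (strict).
#' @return `data.table`: `chrom`, `gap_start`, `gap_end`, `span_bp`.
#' @export
residual_gaps <- function(positions, chrom_lengths = NULL, limit = 250e3) {
  if (inherits(positions, "chip_design")) positions <- positions$selected
  p <- as.data.table(positions)[, .(chrom, pos)]
  setorder(p, chrom, pos)
  gaps <- p[, {
    if (.N >= 2) {
      s <- pos[-.N]; e <- pos[-1]
      list(gap_start = s, gap_end = e)
    } else {
      list(gap_start = integer(0), gap_end = integer(0))
    }
  }, by = chrom]
  if (!is.null(chrom_lengths)) {
    ends <- p[, .(first = min(pos), last = max(pos)), by = chrom]
    ends <- ends[chrom %in% names(chrom_lengths)]
    extra <- data.table(
      chrom = rep(ends$chrom, 2),
      gap_start = c(rep(0L, nrow(ends)), ends$last),
      gap_end = c(ends$first, as.integer(chrom_lengths[ends$chrom])))
    gaps <- rbind(gaps, extra)
  }
  gaps[, span_bp := gap_end - gap_start]
  out <- gaps[span_bp > limit]
  setorder(out, chrom, gap_start)
  out[]
}

#' Ordered ten-category variant selection
#'
#' Runs the selection engine over technically suitable candidates:
#' categories are processed in fixed order (1 prior-array informative SNPs,
#' 2 trait-associated, 3 predicted impact, 4 breed-unique, 5 AAF divergence,
#' 6 Y chromosome, 7 mitochondria, 8 parentage panel, 9 haplotype-block
#' coverage, 10 gap filling). A variant already selected is attributed to
#' the earlier category only ("unique") but still counted in later
#' categories' totals. Categories 3 and 4 are jointly pruned so that at most
#' `max_complete_ld` mutually complete-LD variants per haplotype block
#' survive. Category 9 covers blocks not yet represented (span > 5 kb, or
#' > 1 kb near a coding gene), picking one variant per block by descending
#' (empirical evidence, best-strand conversion score, MAF above threshold,
#' focal-vs-divergence-breed AAF difference), ties broken by position then
#' id. Category 10 greedily fills residual inter-variant gaps above the
#' limit: longest gap first, candidate closest to the gap midpoint.
#'
#' @param variants candidate table (all technical filters passed) with
#'   `id`, `chrom`, `pos`, `ref`, `alt`, `class`, `impact`, `pconvert_fwd`,
#'   `pconvert_rev`, `aaf_<breed>` columns and logical `unique_focal`.
#' @param genotypes a [genotype_matrix()] (for complete-LD pruning).
#' @param blocks haplotype blocks from [call_blocks()] built on the same
#'   candidates.
#' @param categories list of category inputs: `prior_array_ids`, `gwas_ids`,
#'   `gwas_imputed_ids`, `parentage_ids`, `empirical_ids`, optional
#'   `mito_ids`, optional `divergence_breed`.
#' @param panel a [breed_panel()].
#' @param config a [design_config()].
#' @param genes optional coding-gene table (`chrom`, `start`, `end`) for the
#'   relaxed block-span clause; when absent only the > 5 kb clause applies.
#' @param ld_cfg an [ld_config()] (for complete-LD pruning).
#' @return an object of class `chip_design`: `selected` (`data.table` with
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `class`, `category`,
#'   `probesets`), `category_counts`, `totals`, `blocks`, `capacity`.
#' @export
select_categories <- function(variants, genotypes, blocks, categories,
                              panel, config = design_config(),
                              genes = NULL, ld_cfg = ld_config()) {
  v <- as.data.table(variants)
  setorder(v, chrom, pos)
  div_breed <- categories$divergence_breed %||% panel$comparison[1]
  empirical <- categories$empirical_ids %||% character(0)

  cat3_ids <- v[impact %in% c("high", "moderate", "low"), id]
  cat4_ids <- v[unique_focal == TRUE, id]
  pruned <- prune_complete_ld(
    union(cat3_ids, cat4_ids), v, genotypes, blocks, panel$focal,
    config$complete_ld_tol, config$max_complete_ld, ld_cfg)
  cat3_ids <- setdiff(cat3_ids, pruned)
  cat4_ids <- setdiff(cat4_ids, pruned)

  divergent <- classify_divergent(v, panel$focal, div_breed,
                                  config$divergence_threshold)
  sets <- list(
    prior_array = v[id %in% categories$prior_array_ids & class == "SNP", id],
    gwas = v[id %in% categories$gwas_ids, id],
    impact = cat3_ids,
    breed_unique = cat4_ids,
    aaf_divergence = v[divergent, id],
    y_chromosome = v[chrom == config$y_chrom, id],
    mitochondria = v[chrom == config$mt_chrom |
                       id %in% (categories$mito_ids %||% character(0)), id],
    parentage = v[id %in% categories$parentage_ids, id]
  )

  # category 9: one representative per still-uncovered eligible block
  covered_by <- function(selected_ids) {
    if (nrow(blocks) == 0) return(integer(0))
    hits <- vapply(blocks$variant_ids, function(ids)
      any(ids %in% selected_ids), logical(1))
    blocks$block[hits]
  }
  selected_18 <- unique(unlist(sets, use.names = FALSE))
  eligible <- blocks$length_bp > config$block_min_span
  if (!is.null(genes) && nrow(blocks) > 0) {
    g <- as.data.table(genes)
    near_gene <- vapply(seq_len(nrow(blocks)), function(k) {
      gg <- g[chrom == blocks$chrom[k]]
      any(gg$start - config$gene_window <= blocks$end[k] &
            gg$end + config$gene_window >= blocks$start[k])
    }, logical(1))
    eligible <- eligible |
      (blocks$length_bp > config$block_alt_min_span & near_gene)
  }
  uncovered <- setdiff(blocks$block[eligible], covered_by(selected_18))
  v[, maf_focal := pmin(aaf_col(v, panel$focal),
                        1 - aaf_col(v, panel$focal))]
  v[, pconvert_best := pmax(pconvert_fwd, pconvert_rev, na.rm = TRUE)]
  v[, aaf_div_gap := abs(aaf_col(v, panel$focal) - aaf_col(v, div_breed))]
  block_of <- block_assignment(blocks, v$id)
  cat9_ids <- character(0)
  for (b in uncovered) {
    cand <- v[which(block_of == b)]
    if (nrow(cand) == 0) next
    cand[, emp := id %in% empirical]
    cand[, maf_ok := !is.na(maf_focal) & maf_focal > config$maf_priority]
    setorder(cand, -emp, -pconvert_best, -maf_ok, -aaf_div_gap, pos, id)
    cat9_ids <- c(cat9_ids, cand$id[1])
  }
  sets$haplotype_blocks <- cat9_ids

  # category 10: greedy gap filling, longest gap first
  selected_19 <- unique(unlist(sets, use.names = FALSE))
  sel_pos <- v[id %in% selected_19, .(chrom, pos)]
  pool <- v[!id %in% selected_19]
  cat10_ids <- character(0)
  repeat {
    gaps <- residual_gaps(sel_pos, limit = config$gap_limit)
    if (nrow(gaps) == 0) break
    setorder(gaps, -span_bp, chrom, gap_start)
    filled <- FALSE
    for (k in seq_len(nrow(gaps))) {
      inside <- pool[chrom == gaps$chrom[k] & pos > gaps$gap_start[k] &
                       pos < gaps$gap_end[k]]
      if (nrow(inside) == 0) next
      mid <- (gaps$gap_start[k] + gaps$gap_end[k]) / 2
      inside[, dist_mid := abs(pos - mid)]
      setorder(inside, dist_mid, pos, id)
      pick <- inside$id[1]
      cat10_ids <- c(cat10_ids, pick)
      sel_pos <- rbind(sel_pos, v[id == pick, .(chrom, pos)])
      pool <- pool[id != pick]
      filled <- TRUE
      break
    }
    if (!filled) break
  }
  sets$gap_filling <- cat10_ids

  res <- assign_unique_categories(sets)
  assignment <- res$assignment
  if (nrow(assignment) == 0) {
    assignment <- data.table(variant_id = character(), category = integer())
  }
  sel <- merge(assignment, v, by.x = "variant_id", by.y = "id",
               sort = FALSE)
  setorder(sel, chrom, pos)
  sel[, probesets := probesets_for(ref, alt)]
  non_imputed_gwas <- setdiff(categories$gwas_ids %||% character(0),
                              categories$gwas_imputed_ids %||% character(0))
  sel[category == 2L & variant_id %in% non_imputed_gwas,
      probesets := probesets * config$replicate_factor]
  counts <- res$counts
  # block-coverage total is the number of blocks covered by the final design
  counts[category == 9L, n_total := length(covered_by(sel$variant_id))]
  totals <- list(
    n_variants = nrow(sel),
    n_snps = sum(sel$class == "SNP"),
    n_indels = sum(sel$class == "indel"),
    n_probesets = sum(sel$probesets)
  )
  if (totals$n_probesets > config$capacity) {
    stop(sprintf("probeset capacity exceeded by %d (%d > %d)",
                 totals$n_probesets - config$capacity, totals$n_probesets,
                 config$capacity))
  }
  structure(list(
    selected = sel[, .(variant_id, chrom, pos, ref, alt, class, category,
                       probesets, pconvert_fwd, pconvert_rev)],
    category_counts = counts,
    totals = totals,
    blocks = blocks,
    pruned_complete_ld = pruned,
    capacity = config$capacity
  ), class = "chip_design")
}

#' @export
print.chip_design <- function(x, ...) {
  cat(sprintf(
    "<chip_design> %d variants (%d SNPs, %d indels), %d probesets (cap %d)\n",
    x$totals$n_variants, x$totals$n_snps, x$totals$n_indels,
    x$totals$n_probesets, x$capacity))
  print(x$category_counts)
  invisible(x)
}

#' Full design pipeline: filters, blocks, selection
#'
#' Convenience orchestration of the whole design: impact classification,
#' per-breed AAFs, breed-unique flags, the four technical filters (with a
#' step-by-step accounting log), haplotype-block calling on the survivors
#' (focal breed), and the ordered ten-category selection.
#'
#' @param variants variant table (e.g. from [simulate_cohort()] or
#'   [read_vcf()]).
#' @param genotypes matching [genotype_matrix()].
#' @param panel a [breed_panel()].
#' @param categories category inputs, as in [select_categories()].
#' @param filter_cfg a [filter_config()].
#' @param design_cfg a [design_config()].
#' @param ld_cfg an [ld_config()].
#' @param n_carriers optional per-chromosome expected-carrier counts for the
#'   depth filter (e.g. `c(Y = 47)`).
#' @param genes optional coding-gene table for the block-coverage category.
#' @param map an [impact_map()] used when impacts are not yet classified.
#' @return a `chip_design` with an additional `filter_log` element
#'   (`data.table`: `step`, `n_in`, `n_removed`, `n_out`).
#' @export
design_chip <- function(variants, genotypes, panel, categories,
                        filter_cfg = filter_config(),
                        design_cfg = design_config(),
                        ld_cfg = ld_config(),
                        n_carriers = integer(), genes = NULL,
                        map = impact_map()) {
  v <- as.data.table(variants)
  if (!"impact" %in% names(v) || all(is.na(v$impact))) {
    v[, impact := classify_impact(consequence, map)]
  }
  v <- add_breed_aafs(v, genotypes)
  v[, unique_focal := classify_unique(v, panel)]
  priority_ids <- unique(c(
    intersect(categories$gwas_ids %||% character(0), v$id),
    v[impact %in% c("high", "moderate", "low"), id],
    v[unique_focal == TRUE, id]))
  log <- list()
  step <- function(name, before, after) {
    data.table(step = name, n_in = nrow(before),
               n_removed = nrow(before) - nrow(after), n_out = nrow(after))
  }
  v1 <- filter_neighborhood(v, filter_cfg, priority_ids)
  log$neighborhood <- step("neighborhood", v, v1)
  v2 <- filter_depth(v1, nrow(genotypes$geno), filter_cfg, n_carriers)
  log$depth <- step("depth", v1, v2)
  v3 <- filter_aaf(v2, panel, filter_cfg,
                   exempt_chroms = c(design_cfg$y_chrom, design_cfg$mt_chrom))
  log$aaf <- step("aaf", v2, v3)
  v4 <- filter_pconvert(v3, filter_cfg)
  log$pconvert <- step("pconvert", v3, v4)
  blocks <- call_blocks(genotypes, v4, breed = panel$focal, config = ld_cfg)
  design <- select_categories(v4, genotypes, blocks, categories, panel,
                              design_cfg, genes = genes, ld_cfg = ld_cfg)
  design$filter_log <- data.table::rbindlist(log)
  design$candidates <- v4
  design
}
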