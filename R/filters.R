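#' Technical-suitability filter configuration
#'
#' Thresholds of the technical filter chain applied before variant
#' selection. Defaults: a variant is discarded when another variant lies
#' closer than 35 bp up- or downstream (20 bp for variants pre-flagged for
#' the high-priority selection categories: trait-associated, predicted
#' impact, breed-unique) since near neighbours interfere with probe
#' hybridization; total read depth across the cohort must reach 10 reads per
#' expected carrier (all animals on autosomes, e.g. 3000 reads for 300
#' animals; males only on Y); the focal-breed AAF must reach 0.05 unless a
#' rescue clause applies; and the in-silico conversion score must reach 0.6
#' on at least one strand.
#'
#' @param neighborhood_bp default interference window (bp).
#' @param neighborhood_bp_priority window for priority-category variants; must
#'   not exceed `neighborhood_bp`.
#' @param min_depth_per_animal required mean reads per expected carrier.
#' @param min_depth_absolute optional absolute total-depth override (e.g.
#'   3000); when set it replaces the per-carrier rule.
#' @param min_aaf_focal AAF threshold in the focal breed.
#' @param rescue_min_aaf_focal focal AAF floor for the rescue clause.
#' @param rescue_breed_aaf AAF a rescue breed must exceed to rescue a variant.
#' @param min_pconvert minimum conversion score (best strand).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(neighborhood_bp = 35,
                          neighborhood_bp_priority = 20,
                          min_depth_per_animal = 10,
                          min_depth_absolute = NULL,
                          min_aaf_focal = 0.05,
                          rescue_min_aaf_focal = 0.01,
                          rescue_breed_aaf = 0.05,
                          min_pconvert = 0.6) {
  check_positive(neighborhood_bp, "neighborhood_bp")
  check_positive(neighborhood_bp_priority, "neighborhood_bp_priority")
  if (neighborhood_bp_priority > neighborhood_bp) {
    stop_field("neighborhood_bp_priority",
               "priority window must not exceed the default window")
  }
  check_positive(min_depth_per_animal, "min_depth_per_animal")
  if (!is.null(min_depth_absolute)) {
    check_positive(min_depth_absolute, "min_depth_absolute")
  }
  check_prob(min_aaf_focal, "min_aaf_focal")
  check_prob(rescue_min_aaf_focal, "rescue_min_aaf_focal")
  check_prob(rescue_breed_aaf, "rescue_breed_aaf")
  check_prob(min_pconvert, "min_pconvert")
  structure(as.list(environment()), class = "filter_config")
}

#' Attach per-breed AAF columns to a variant table
#'
#' Adds one `aaf_<breed>` column per breed (plus the requested extra
#' groupings), computed with [compute_aaf()]. `NA` marks an undefined AAF
#' (no genotyped animal of that breed), never a zero.
#'
#' @param variants variant table with an `id` column.
#' @param genotypes a [genotype_matrix()] covering the same variants.
#' @return the variant table with `aaf_<breed>` columns, invisibly modified
#'   by reference and returned.
#' @export
add_breed_aafs <- function(variants, genotypes) {
  v <- as.data.table(variants)
  for (b in unique(genotypes$breed_of)) {
    aafs <- compute_aaf(genotypes, b)
    v[, (paste0("aaf_", b)) := unname(aafs[v$id])]
  }
  v[]
}

aaf_col <- function(variants, breed) {
  col <- paste0("aaf_", breed)
  if (!col %in% names(variants)) {
    stop("no AAF column for breed '", breed,
         "'; run add_breed_aafs() first")
  }
  variants[[col]]
}

#' Interfering-neighbour filter
#'
#' A variant survives iff no other variant of any kind (surviving or not)
#' lies closer than its window `W` up- or downstream, where `W` is the
#' priority window for variants in `priority_ids` and the default window
#' otherwise. Distances are between variant start positions; a neighbour at
#' exactly `W` bp is tolerated.
#'
#' @param variants position-sorted variant table (`id`, `chrom`, `pos`).
#' @param config a [filter_config()].
#' @param priority_ids ids flagged for the high-priority categories.
#' @return the surviving subset of `variants`.
#' @export
filter_neighborhood <- function(variants, config = filter_config(),
                                priority_ids = character()) {
  v <- as.data.table(variants)
  if (nrow(v) == 0) return(v)
  setorder(v, chrom, pos)
  w <- ifelse(v$id %in% priority_ids,
              config$neighborhood_bp_priority, config$neighborhood_bp)
  d <- v[, {
    gap_prev <- c(Inf, diff(pos))
    gap_next <- c(diff(pos), Inf)
    list(id = id, nearest = pmin(gap_prev, gap_next))
  }, by = chrom]
  keep <- d$nearest >= w
  v[keep]
}

#' Read-depth filter
#'
#' Keeps a variant iff its total read depth across the cohort reaches the
#' threshold: 10 reads (configurable) per expected carrier. Expected
#' carriers default to all animals; for sex chromosomes a per-chromosome
#' carrier count can be supplied (e.g. `c(Y = 47)` when only the males carry
#' a Y). Missing depth fails the filter.
#'
#' @param variants variant table with `chrom` and `total_depth`.
#' @param n_animals number of sequenced animals.
#' @param config a [filter_config()].
#' @param n_carriers optional named vector of expected carriers per
#'   chromosome, overriding `n_animals` on those chromosomes.
#' @return the surviving subset of `variants`.
#' @export
filter_depth <- function(variants, n_animals, config = filter_config(),
                         n_carriers = integer()) {
  v <- as.data.table(variants)
  if (nrow(v) == 0) return(v)
  carriers <- rep(n_animals, nrow(v))
  if (length(n_carriers) > 0) {
    hit <- v$chrom %in% names(n_carriers)
    carriers[hit] <- n_carriers[v$chrom[hit]]
  }
  threshold <- if (!is.null(config$min_depth_absolute)) {
    rep(config$min_depth_absolute, nrow(v))
  } else {
    config$min_depth_per_animal * carriers
  }
  keep <- !is.na(v$total_depth) & v$total_depth >= threshold
  v[keep]
}

#' Focal-breed allele-frequency filter
#'
#' Keeps a variant iff its focal-breed AAF reaches `min_aaf_focal` (default
#' 0.05), OR the rescue clause holds: focal AAF above `rescue_min_aaf_focal`
#' (default 0.01) AND (the variant is focal-unique OR some rescue breed has
#' AAF above `rescue_breed_aaf`). Variants with undefined focal AAF are
#' removed. Chromosomes in `exempt_chroms` (e.g. Y, MT, whose variants enter
#' the design wholesale) bypass the filter.
#'
#' @param variants variant table with `aaf_<breed>` columns (see
#'   [add_breed_aafs()]) and a logical `unique_focal` column (see
#'   [classify_unique()]).
#' @param panel a [breed_panel()].
#' @param config a [filter_config()].
#' @param exempt_chroms chromosomes whose variants always survive.
#' @return the surviving subset of `variants`.
#' @export
filter_aaf <- function(variants, panel, config = filter_config(),
                       exempt_chroms = character()) {
  v <- as.data.table(variants)
  if (nrow(v) == 0) return(v)
  focal <- aaf_col(v, panel$focal)
  uniq <- if ("unique_focal" %in% names(v)) v$unique_focal else
    classify_unique(v, panel)
  rescue_hit <- rep(FALSE, nrow(v))
  for (b in panel$rescue) {
    ab <- aaf_col(v, b)
    rescue_hit <- rescue_hit | (!is.na(ab) & ab > config$rescue_breed_aaf)
  }
  keep <- !is.na(focal) &
    (focal >= config$min_aaf_focal |
       (focal > config$rescue_min_aaf_focal & (uniq | rescue_hit)))
  keep <- keep | v$chrom %in% exempt_chroms
  v[keep]
}

#' Conversion-score filter
#'
#' Keeps a variant iff its in-silico conversion score reaches
#' `min_pconvert` (default 0.6) on at least one strand. Variants with no
#' score on either strand are removed.
#'
#' @param variants variant table with `pconvert_fwd` and `pconvert_rev`.
#' @param config a [filter_config()].
#' @return the surviving subset of `variants`.
#' @export
filter_pconvert <- function(variants, config = filter_config()) {
  v <- as.data.table(variants)
  if (nrow(v) == 0) return(v)
  best <- pmax(v$pconvert_fwd, v$pconvert_rev, na.rm = TRUE)
  best[is.na(v$pconvert_fwd) & is.na(v$pconvert_rev)] <- NA_real_
  keep <- !is.na(best) & best >= config$min_pconvert
  v[keep]
}

#' Breed-unique classification
#'
#' A variant is unique to the focal breed iff it is present there
#' (AAF > 0.01) and absent (AAF = 0) in every comparison breed whose AAF is
#' defined. An undefined comparison AAF (breed not observed) is ignored
#' rather than treated as absence.
#'
#' @param variants variant table with `aaf_<breed>` columns.
#' @param panel a [breed_panel()].
#' @param min_aaf_focal presence threshold in the focal breed (strict).
#' @return logical vector, one flag per variant.
#' @export
classify_unique <- function(variants, panel, min_aaf_focal = 0.01) {
  v <- as.data.table(variants)
  focal <- aaf_col(v, panel$focal)
  absent_everywhere <- rep(TRUE, nrow(v))
  for (b in panel$comparison) {
    ab <- aaf_col(v, b)
    absent_everywhere <- absent_everywhere & (is.na(ab) | ab == 0)
  }
  !is.na(focal) & focal > min_aaf_focal & absent_everywhere
}

#' Allele-frequency divergence classification
#'
#' Flags variants whose AAF difference between two breeds exceeds the
#' threshold (strictly): |AAF_a - AAF_b| > 0.70 by default.
#'
#' @param variants variant table with `aaf_<breed>` columns.
#' @param breed_a,breed_b breed names.
#' @param threshold divergence threshold (strict).
#' @return logical vector, one flag per variant (`FALSE` when either AAF is
#'   undefined).
#' @export
classify_divergent <- function(variants, breed_a, breed_b, threshold = 0.70) {
  v <- as.data.table(variants)
  a <- aaf_col(v, breed_a)
  b <- aaf_col(v, breed_b)
  # strict threshold up to floating-point round-off of the difference
  !is.na(a) & !is.na(b) & abs(a - b) > threshold + 1e-9
}
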