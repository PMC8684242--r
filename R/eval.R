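#' Confidence masking and call-rate QC
#'
#' Masks genotype calls whose confidence exceeds the threshold (confidence
#' is 1 minus the genotype-cluster probability, so 0 is best), then declares
#' a variant successfully called when its post-masking call rate clears the
#' call-rate threshold. Masking is applied before the call rate is computed.
#'
#' @param calls a `call_results` object.
#' @param conf_threshold maximum tolerated confidence (calls strictly above
#'   are set missing).
#' @param callrate_threshold required post-masking call rate.
#' @param strict if `TRUE` (default) the call rate must strictly exceed the
#'   threshold; if `FALSE`, reaching it suffices.
#' @param instances optional instance ids to restrict to (e.g. one breed).
#' @return a list of class `qc_result`: `masked` (calls after masking),
#'   `call_rate` (per variant), `passed` (ids of successfully called
#'   variants).
#' @export
qc_calls <- function(calls, conf_threshold = 0.05,
                     callrate_threshold = 0.95, strict = TRUE,
                     instances = NULL) {
  g <- calls$calls
  cf <- calls$conf
  if (!is.null(instances)) {
    g <- g[instances, , drop = FALSE]
    cf <- cf[instances, , drop = FALSE]
  }
  if (nrow(g) == 0) stop("at least one instance required")
  masked <- g
  if (!is.null(cf)) masked[!is.na(cf) & cf > conf_threshold] <- NA_integer_
  call_rate <- colMeans(!is.na(masked))
  ok <- if (strict) call_rate > callrate_threshold else
    call_rate >= callrate_threshold
  structure(list(masked = masked, call_rate = call_rate,
                 passed = colnames(masked)[ok]), class = "qc_result")
}

#' Variants successfully called in at least one breed
#'
#' Runs [qc_calls()] separately per breed (call-rate denominators use only
#' that breed's instances) and returns the union of passing variants.
#'
#' @inheritParams qc_calls
#' @return character vector of variant ids.
#' @export
called_in_any_breed <- function(calls, conf_threshold = 0.05,
                                callrate_threshold = 0.95, strict = TRUE) {
  ids <- character(0)
  for (b in unique(calls$breed_of)) {
    inst <- names(calls$breed_of)[calls$breed_of == b]
    qc <- qc_calls(calls, conf_threshold, callrate_threshold, strict,
                   instances = inst)
    ids <- union(ids, qc$passed)
  }
  ids
}

#' Segregating variants after QC
#'
#' Successfully called variants that are polymorphic above the MAF
#' threshold (strict) in the target population, computed from the masked
#' calls.
#'
#' @param qc a `qc_result` from [qc_calls()].
#' @param maf_threshold minimum MAF (strict).
#' @return character vector of variant ids.
#' @export
segregating_variants <- function(qc, maf_threshold = 0.01) {
  g <- qc$masked[, qc$passed, drop = FALSE]
  nn <- colSums(!is.na(g))
  aaf <- colSums(g, na.rm = TRUE) / (2 * nn)
  maf <- pmin(aaf, 1 - aaf)
  qc$passed[!is.na(maf) & maf > maf_threshold]
}

#' Concordance between two call sets
#'
#' Per paired instance, the fraction of matching hard genotype calls over
#' the shared variants non-missing in both members; positions missing in
#' either member are excluded. Pairs with zero comparable calls are
#' reported as `NA` and excluded from the mean.
#'
#' @param calls_a,calls_b genotype matrices (instances x variants), or
#'   objects with a `$calls`/`$masked`/`$geno` matrix (`call_results`,
#'   `qc_result`, [genotype_matrix()]).
#' @param pairing two-column data.frame of instance ids (`a`, `b`); by
#'   default, identical rownames are paired.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return a list: `per_pair` (`data.table`: `a`, `b`, `n_compared`,
#'   `concordance` as a percentage), `mean`, `sd`, `n_pairs`.
#' @export
concordance <- function(calls_a, calls_b, pairing = NULL,
                        sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ga <- call_matrix(calls_a)
  gb <- call_matrix(calls_b)
  if (is.null(pairing)) {
    shared <- intersect(rownames(ga), rownames(gb))
    pairing <- data.frame(a = shared, b = shared)
  }
  vars <- intersect(colnames(ga), colnames(gb))
  if (length(vars) == 0) stop("no shared variants between call sets")
  per <- lapply(seq_len(nrow(pairing)), function(k) {
    xa <- ga[pairing$a[k], vars]
    xb <- gb[pairing$b[k], vars]
    ok <- !is.na(xa) & !is.na(xb)
    n <- sum(ok)
    data.table(a = pairing$a[k], b = pairing$b[k], n_compared = n,
               concordance = if (n > 0) 100 * sum(xa[ok] == xb[ok]) / n
               else NA_real_)
  })
  per <- data.table::rbindlist(per)
  vals <- per$concordance[!is.na(per$concordance)]
  s <- if (length(vals) >= 2) {
    if (sd_type == "sample") sd(vals) else
      sqrt(mean((vals - mean(vals))^2))
  } else NA_real_
  list(per_pair = per, mean = mean(vals), sd = s, n_pairs = length(vals))
}

call_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "qc_result")) return(x$masked)
  if (inherits(x, "call_results")) return(x$calls)
  if (inherits(x, "genotype_matrix")) return(x$geno)
  stop("cannot interpret call set")
}

#' Replicate instance pairs of a call set
#'
#' All unordered pairs of instances belonging to the same animal (technical
#' replicates across batches).
#'
#' @param calls a `call_results` object.
#' @return data.frame with columns `a`, `b`.
#' @export
replicate_pairs <- function(calls) {
  out <- list()
  for (a in unique(calls$animal_of)) {
    inst <- names(calls$animal_of)[calls$animal_of == a]
    if (length(inst) >= 2) {
      cmb <- utils::combn(inst, 2)
      out[[a]] <- data.frame(a = cmb[1, ], b = cmb[2, ])
    }
  }
  if (length(out) == 0) return(data.frame(a = character(), b = character()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Percentages for a category count table
#'
#' Adds the report percentages to a table of per-category counts: each
#' count column is expressed as a percentage of the category's unique
#' count, rounded half-up to 2 decimals. Zero denominators give `NA`
#' (printed as an em-dash, not 0%). Reported percentages are exactly
#' recomputable from the reported counts.
#'
#' @param counts `data.table`/data.frame with an `n_unique` column and any
#'   number of `n_*` count columns.
#' @param count_cols count columns to percentage (default: all `n_*` except
#'   `n_unique`/`n_total`).
#' @return the table with added `pct_*` columns.
#' @export
format_category_table <- function(counts, count_cols = NULL) {
  tab <- as.data.table(counts)
  if (is.null(count_cols)) {
    count_cols <- setdiff(grep("^n_", names(tab), value = TRUE),
                          c("n_unique", "n_total"))
  }
  for (cc in count_cols) {
    tab[, (sub("^n_", "pct_", cc)) := pct(get(cc), tab$n_unique)]
  }
  tab[]
}

#' Per-category evaluation table
#'
#' The design's accounting table after a genotyping run: per selection
#' category, the unique and total selected counts, the successfully called
#' unique variants in the focal population and in at least one breed, the
#' segregating unique variants (MAF above threshold in the focal
#' population), and the corresponding percentages of the unique counts. A
#' totals row and a SNP/indel split are included.
#'
#' @param design a `chip_design`.
#' @param calls a `call_results` from the genotyping run.
#' @param focal_breed breed defining the focal population (default: the
#'   most frequent breed among instances).
#' @param conf_threshold,callrate_threshold,strict QC parameters, see
#'   [qc_calls()].
#' @param maf_threshold segregation threshold (strict).
#' @return a list of class `evaluation_report`: `by_category`
#'   (`data.table`), `totals_by_class`, `called_focal`, `called_any`,
#'   `segregating`.
#' @export
category_table <- function(design, calls, focal_breed = NULL,
                           conf_threshold = 0.05,
                           callrate_threshold = 0.95, strict = TRUE,
                           maf_threshold = 0.01) {
  focal_breed <- focal_breed %||%
    names(sort(table(calls$breed_of), decreasing = TRUE))[1]
  inst_focal <- names(calls$breed_of)[calls$breed_of == focal_breed]
  qc_focal <- qc_calls(calls, conf_threshold, callrate_threshold, strict,
                       instances = inst_focal)
  called_any <- called_in_any_breed(calls, conf_threshold,
                                    callrate_threshold, strict)
  seg <- segregating_variants(qc_focal, maf_threshold)
  sel <- design$selected
  counts <- data.table::copy(design$category_counts)
  counts[, n_called_focal := vapply(category, function(k)
    sum(sel$variant_id[sel$category == k] %in% qc_focal$passed),
    integer(1))]
  counts[, n_called_any := vapply(category, function(k)
    sum(sel$variant_id[sel$category == k] %in% called_any), integer(1))]
  counts[, n_segregating := vapply(category, function(k)
    sum(sel$variant_id[sel$category == k] %in% seg), integer(1))]
  total <- data.table(
    category = NA_integer_, label = "total",
    n_unique = sum(counts$n_unique),
    n_total = NA_integer_,
    n_called_focal = sum(counts$n_called_focal),
    n_called_any = sum(counts$n_called_any),
    n_segregating = sum(counts$n_segregating))
  tab <- format_category_table(rbind(counts, total))
  by_class <- sel[, .(
    n_selected = .N,
    n_called_focal = sum(variant_id %in% qc_focal$passed),
    n_called_any = sum(variant_id %in% called_any),
    n_segregating = sum(variant_id %in% seg)
  ), by = class]
  structure(list(
    by_category = tab,
    totals_by_class = by_class,
    called_focal = qc_focal$passed,
    called_any = called_any,
    segregating = seg,
    focal_breed = focal_breed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> focal breed %s\n", x$focal_breed))
  print(x$by_category)
  invisible(x)
}

#' LD between failing and working variants
#'
#' For every selected variant that failed QC, the LD (D' and r-squared)
#' against the nearest successfully called variant in the same haplotype
#' block, falling back to the nearest called variant on the chromosome;
#' summarized as mean and SD. High values indicate that failing variants
#' leave no gap in genetic information.
#'
#' @param design a `chip_design` (with `blocks`).
#' @param called_ids ids of successfully called variants.
#' @param genotypes truth [genotype_matrix()] used for the LD computation.
#' @param breed breed whose animals are used.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @param ld_cfg an [ld_config()].
#' @return a list: `per_variant` (`data.table`: `failed_id`, `partner_id`,
#'   `same_block`, `dprime`, `r2`), `mean_dprime`, `sd_dprime`, `mean_r2`,
#'   `sd_r2`, `n`.
#' @export
failing_vs_working_ld <- function(design, called_ids, genotypes,
                                  breed = "all",
                                  sd_type = c("sample", "population"),
                                  ld_cfg = ld_config()) {
  sd_type <- match.arg(sd_type)
  sel <- design$selected
  failed <- sel[!variant_id %in% called_ids]
  working <- sel[variant_id %in% called_ids]
  empty <- list(per_variant = data.table(), mean_dprime = NA_real_,
                sd_dprime = NA_real_, mean_r2 = NA_real_, sd_r2 = NA_real_,
                n = 0L)
  if (nrow(failed) == 0 || nrow(working) == 0) return(empty)
  blk_failed <- block_assignment(design$blocks, failed$variant_id)
  blk_working <- block_assignment(design$blocks, working$variant_id)
  ids_animals <- animals_of_breed(genotypes, breed)
  g <- genotypes$geno[ids_animals, , drop = FALSE]
  rows <- lapply(seq_len(nrow(failed)), function(k) {
    cand <- working[blk_working %in% blk_failed[k] &
                      !is.na(blk_failed[k])]
    same_block <- nrow(cand) > 0
    if (!same_block) cand <- working[chrom == failed$chrom[k]]
    if (nrow(cand) == 0) return(NULL)
    partner <- cand$variant_id[which.min(abs(cand$pos - failed$pos[k]))]
    st <- ld_pair_core(g[, failed$variant_id[k]], g[, partner],
                       ld_cfg$ci_grid, ld_cfg$em_tol, ld_cfg$em_max_iter)
    if (!isTRUE(st$defined)) return(NULL)
    data.table(failed_id = failed$variant_id[k], partner_id = partner,
               same_block = same_block, dprime = st$dprime, r2 = st$r2)
  })
  per <- data.table::rbindlist(rows)
  if (nrow(per) == 0) return(empty)
  msd <- function(x) {
    if (length(x) >= 2) {
      if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
    } else NA_real_
  }
  list(per_variant = per, mean_dprime = mean(per$dprime),
       sd_dprime = msd(per$dprime), mean_r2 = mean(per$r2),
       sd_r2 = msd(per$r2), n = nrow(per))
}

#' MAF histogram
#'
#' Minor-allele-frequency histogram in bins of 0.05 with the lowest bin
#' starting at 0.01 (frequencies at or below 0.01 are not shown, matching
#' the segregation threshold).
#'
#' @param maf numeric vector of MAFs.
#' @param bin_width bin width.
#' @param min_maf lower edge of the first bin.
#' @return `data.table`: `bin_low`, `bin_high`, `n`.
#' @export
maf_histogram <- function(maf, bin_width = 0.05, min_maf = 0.01) {
  breaks <- c(min_maf, seq(bin_width, 0.5, by = bin_width))
  maf <- maf[!is.na(maf) & maf > min_maf & maf <= 0.5]
  idx <- findInterval(maf, breaks, rightmost.closed = TRUE)
  data.table(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    n = vapply(seq_len(length(breaks) - 1),
               function(k) sum(idx == k), integer(1)))
}
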