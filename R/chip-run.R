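#' Simulated genotyping-run specification
#'
#' Noise model of an array genotyping run on a designed chip. A variant
#' fails assay-wide with probability increasing as its best-strand
#' conversion score falls below 0.8 (failures concentrate at scores
#' 0.6-0.7, as seen on real arrays) plus a rare-allele clustering penalty;
#' individual calls of working variants are corrupted at a base per-call
#' rate plus the same rare-allele penalty (rare alleles form small, unsharp
#' genotype clusters). Call confidences are Beta-distributed: sharply
#' concentrated near 0 for correct calls, diffuse for corrupted ones.
#'
#' @param base_failure_rate assay-wide failure probability floor.
#' @param pconvert_failure_slope extra failure probability per unit of
#'   conversion-score deficit below 0.8.
#' @param rare_allele_cluster_penalty extra failure/miscall probability at
#'   MAF 0, fading linearly to 0 at MAF 0.05.
#' @param base_miscall_rate per-call corruption probability.
#' @param conf_correct,conf_error Beta(shape1, shape2) parameters of call
#'   confidences for correct and corrupted calls; `c(0, 0)` forces exact 0.
#' @param replicate_animals named integer vector: animal id -> total number
#'   of times genotyped (>= 2 adds replicate instances in later batches).
#' @param seed random seed.
#' @return a list of class `chip_run_spec`.
#' @export
chip_run_spec <- function(base_failure_rate = 0.03,
                          pconvert_failure_slope = 0.3,
                          rare_allele_cluster_penalty = 0.05,
                          base_miscall_rate = 0.002,
                          conf_correct = c(0.2, 40),
                          conf_error = c(1.5, 3),
                          replicate_animals = integer(),
                          seed = 1L) {
  check_prob(base_failure_rate, "base_failure_rate")
  check_positive(pconvert_failure_slope, "pconvert_failure_slope",
                 strict = FALSE)
  check_prob(rare_allele_cluster_penalty, "rare_allele_cluster_penalty")
  check_prob(base_miscall_rate, "base_miscall_rate")
  check_positive(conf_correct, "conf_correct", strict = FALSE)
  check_positive(conf_error, "conf_error", strict = FALSE)
  if (length(replicate_animals) > 0 &&
      (is.null(names(replicate_animals)) || any(replicate_animals < 2))) {
    stop_field("replicate_animals",
               "must be a named vector of counts >= 2")
  }
  structure(as.list(environment()), class = "chip_run_spec")
}

rbeta_or_zero <- function(n, shape) {
  if (shape[1] <= 0) rep(0, n) else rbeta(n, shape[1], shape[2])
}

#' Simulate an array genotyping run
#'
#' Produces per-variant x per-instance genotype calls and confidences for
#' the selected variants of a chip design, from the cohort's truth
#' genotypes, under the noise model of [chip_run_spec()]. Replicate animals
#' receive independent call draws in separate batches.
#'
#' @param design a `chip_design`.
#' @param genotypes the truth [genotype_matrix()]; every selected variant
#'   must exist in it (unknown variants are a lookup error).
#' @param run a [chip_run_spec()].
#' @return a list of class `call_results`: `calls` and `conf` matrices
#'   (instances x variants), `animal_of`, `breed_of`, `batch` (named per
#'   instance), and `failed_variants` (assay-wide failures).
#' @export
simulate_chip_run <- function(design, genotypes, run = chip_run_spec()) {
  if (!inherits(design, "chip_design")) stop("design must be a chip_design")
  sel <- design$selected
  missing_ids <- setdiff(sel$variant_id, colnames(genotypes$geno))
  if (length(missing_ids) > 0) {
    stop("design references variant(s) unknown to the genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  bad_rep <- setdiff(names(run$replicate_animals), rownames(genotypes$geno))
  if (length(bad_rep) > 0) {
    stop("replicate list references unknown animal(s): ",
         paste(bad_rep, collapse = ", "))
  }
  set.seed(run$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  animals <- rownames(genotypes$geno)
  inst_animal <- animals
  inst_id <- animals
  inst_batch <- rep(1L, length(animals))
  for (a in names(run$replicate_animals)) {
    k <- run$replicate_animals[[a]]
    inst_animal <- c(inst_animal, rep(a, k - 1))
    inst_id <- c(inst_id, sprintf("%s_rep%d", a, seq(2, k)))
    inst_batch <- c(inst_batch, seq(2, k))
  }
  n_inst <- length(inst_id)
  m <- nrow(sel)
  truth <- genotypes$geno[inst_animal, sel$variant_id, drop = FALSE]
  rownames(truth) <- inst_id

  maf <- compute_maf(genotypes)[sel$variant_id]
  pbest <- if (all(c("pconvert_fwd", "pconvert_rev") %in% names(sel))) {
    pmax(sel$pconvert_fwd, sel$pconvert_rev, na.rm = TRUE)
  } else {
    rep(0.8, m)
  }
  pbest[is.na(pbest)] <- 0.6
  rare_term <- run$rare_allele_cluster_penalty *
    pmax(0, 0.05 - ifelse(is.na(maf), 0, maf)) / 0.05
  p_fail <- pmin(1, run$base_failure_rate +
                   run$pconvert_failure_slope * pmax(0, 0.8 - pbest) +
                   rare_term)
  failed <- runif(m) < p_fail

  miscall_p <- pmin(1, run$base_miscall_rate + rare_term)
  corrupt <- matrix(runif(n_inst * m) <
                      rep(miscall_p, each = n_inst), nrow = n_inst)
  corrupt[is.na(truth)] <- FALSE
  # a corrupted call is a uniformly drawn *different* genotype
  shift <- matrix(sample(1:2, n_inst * m, replace = TRUE), nrow = n_inst)
  calls <- truth
  calls[corrupt] <- (truth[corrupt] + shift[corrupt]) %% 3L
  conf <- matrix(rbeta_or_zero(n_inst * m, run$conf_correct), nrow = n_inst,
                 dimnames = dimnames(truth))
  conf[corrupt] <- rbeta_or_zero(sum(corrupt), run$conf_error)
  calls[, failed] <- NA_integer_
  conf[, failed] <- 1
  structure(list(
    calls = calls, conf = conf,
    animal_of = stats::setNames(inst_animal, inst_id),
    breed_of = stats::setNames(
      unname(genotypes$breed_of[inst_animal]), inst_id),
    batch = stats::setNames(inst_batch, inst_id),
    failed_variants = sel$variant_id[failed]
  ), class = "call_results")
}

#' @export
print.call_results <- function(x, ...) {
  cat(sprintf(
    "<call_results> %d instances x %d variants (%d assay failures)\n",
    nrow(x$calls), ncol(x$calls), length(x$failed_variants)))
  invisible(x)
}
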