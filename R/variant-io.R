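#' Genotype matrix with breed labels
#'
#' Container for hard genotype calls of a multi-breed cohort: an
#' animals-by-variants integer matrix of alternative-allele dosages
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing) plus the breed of every
#' animal and optional per-call confidences and read depths.
#'
#' @param geno integer matrix, animals in rows (rownames = animal ids),
#'   variants in columns (colnames = variant ids); entries 0/1/2/`NA`.
#' @param breed_of named character vector mapping every animal id to a breed.
#' @param conf optional numeric matrix of call confidences in \[0, 1\], same
#'   shape as `geno`.
#' @param depth optional integer matrix of per-animal read depths, same shape.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, breed_of, conf = NULL, depth = NULL) {
  if (!is.matrix(geno)) stop("geno must be a matrix")
  storage.mode(geno) <- "integer"
  if ((nrow(geno) > 0 && is.null(rownames(geno))) ||
      (ncol(geno) > 0 && is.null(colnames(geno)))) {
    stop("geno must have animal ids as rownames and variant ids as colnames")
  }
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad) > 0) stop("genotype codes must be 0, 1, 2 or NA")
  missing_breed <- setdiff(rownames(geno), names(breed_of))
  if (length(missing_breed) > 0) {
    stop("animals without breed assignment: ",
         paste(utils::head(missing_breed, 5), collapse = ", "))
  }
  for (m in list(conf, depth)) {
    if (!is.null(m) && !identical(dim(m), dim(geno))) {
      stop("conf/depth matrices must match geno dimensions")
    }
  }
  if (!is.null(conf) && (min(conf, na.rm = TRUE) < 0 ||
                         max(conf, na.rm = TRUE) > 1)) {
    stop("confidences must lie in [0, 1]")
  }
  structure(
    list(geno = geno, breed_of = breed_of[rownames(geno)], conf = conf,
         depth = depth),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d animals x %d variants; breeds: %s\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%s (%d)", names(table(x$breed_of)),
                            table(x$breed_of)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

animals_of_breed <- function(genotypes, breed) {
  if (identical(breed, "all")) return(rownames(genotypes$geno))
  if (!breed %in% genotypes$breed_of) stop("unknown breed: ", breed)
  names(genotypes$breed_of)[genotypes$breed_of == breed]
}

#' Breed panel: focal breed plus comparison breeds
#'
#' Defines the focal (target) breed of a chip design and the genetically
#' closely related breeds its allele frequencies are compared against for
#' the breed-unique classification.
#'
#' @param focal focal breed name.
#' @param comparison character vector of comparison breed names.
#' @param rescue subset of `comparison` whose frequencies may rescue
#'   low-frequency focal variants in the allele-frequency filter.
#' @return an object of class `breed_panel`.
#' @export
breed_panel <- function(focal, comparison, rescue = comparison) {
  if (focal %in% comparison) stop("focal breed must not be a comparison breed")
  if (!all(rescue %in% comparison)) {
    stop("rescue breeds must be a subset of comparison breeds")
  }
  structure(list(focal = focal, comparison = comparison, rescue = rescue),
            class = "breed_panel")
}

#' Per-breed alternative-allele frequency
#'
#' AAF = alt-allele count / (2 x non-missing animals of the breed). Variants
#' with no non-missing genotype in the breed get `NA` ("undefined"), which is
#' deliberately distinct from 0: the breed-unique rule must distinguish
#' an allele that is absent from one that was never observed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param breed breed name, or `"all"` for the pooled cohort.
#' @return named numeric vector of AAFs (one per variant), `NA` = undefined.
#' @export
compute_aaf <- function(genotypes, breed = "all") {
  ids <- animals_of_breed(genotypes, breed)
  g <- genotypes$geno[ids, , drop = FALSE]
  nn <- colSums(!is.na(g))
  aaf <- colSums(g, na.rm = TRUE) / (2 * nn)
  aaf[nn == 0] <- NA_real_
  aaf
}

#' Per-breed minor-allele frequency
#'
#' MAF = min(AAF, 1 - AAF); undefined (`NA`) where the AAF is undefined.
#'
#' @inheritParams compute_aaf
#' @return named numeric vector of MAFs.
#' @export
compute_maf <- function(genotypes, breed = "all") {
  aaf <- compute_aaf(genotypes, breed)
  pmin(aaf, 1 - aaf)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "indel")
}

# left-aligned minimal representation of a biallelic variant
normalize_variant <- function(ref, alt, pos) {
  for (k in seq_along(ref)) {
    r <- ref[k]; a <- alt[k]; p <- pos[k]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1
    }
    ref[k] <- r; alt[k] <- a; pos[k] <- p
  }
  list(ref = ref, alt = alt, pos = pos)
}

#' Read a breed-membership table
#'
#' Two-column tab-separated file with header `sample<TAB>breed`.
#'
#' @param path file path.
#' @return named character vector mapping sample id to breed.
#' @export
read_breed_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "breed") %in% names(tab))) {
    stop("breed table needs columns 'sample' and 'breed'")
  }
  stats::setNames(tab$breed, tab$sample)
}

#' Write a breed-membership table
#'
#' @param breed_of named character vector (sample -> breed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breed_table <- function(breed_of, path) {
  utils::write.table(
    data.frame(sample = names(breed_of), breed = unname(breed_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort as VCFv4.2
#'
#' Emits plain-text VCFv4.2 with `GT` and per-sample `DP`, carrying the
#' consequence term (`CSQ`) and forward/reverse-strand conversion scores
#' (`PCF`, `PCR`) in INFO. Output is byte-deterministic for identical input.
#'
#' @param variants variant table (`id`, `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `consequence`, `pconvert_fwd`, `pconvert_rev`).
#' @param genotypes a [genotype_matrix()]; per-sample depths are written when
#'   present.
#' @param path output path.
#' @param header_extra optional character vector of extra `##` header lines
#'   (e.g. the echoed simulation parameters).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, header_extra = NULL) {
  v <- as.data.table(variants)
  samples <- rownames(genotypes$geno)
  g <- genotypes$geno[, v$id, drop = FALSE]
  has_dp <- !is.null(genotypes$depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=chipdesign",
    header_extra,
    paste0("##INFO=<ID=CSQ,Number=1,Type=String,",
           "Description=\"Consequence term\">"),
    paste0("##INFO=<ID=PCF,Number=1,Type=Float,",
           "Description=\"Conversion score, forward strand\">"),
    paste0("##INFO=<ID=PCR,Number=1,Type=Float,",
           "Description=\"Conversion score, reverse strand\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- rep("", nrow(v))
  add_info <- function(info, key, val) {
    piece <- ifelse(is.na(val), NA_character_, paste0(key, "=", val))
    ifelse(is.na(piece), info,
           ifelse(info == "", piece, paste0(info, ";", piece)))
  }
  if ("consequence" %in% names(v)) info <- add_info(info, "CSQ", v$consequence)
  for (col in c(PCF = "pconvert_fwd", PCR = "pconvert_rev")) {
    if (col %in% names(v)) {
      key <- names(which(c(PCF = "pconvert_fwd", PCR = "pconvert_rev") == col))
      info <- add_info(info, key, sprintf("%.6g", v[[col]]))
    }
  }
  info[info == ""] <- "."
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(k) {
    gk <- g[, k]
    gt <- ifelse(is.na(gk), "./.", gt_code[gk + 1L])
    if (has_dp) {
      gt <- paste0(gt, ":", genotypes$depth[, v$id[k]])
    }
    paste(c(v$chrom[k], format(v$pos[k], scientific = FALSE, trim = TRUE),
            v$id[k], v$ref[k], v$alt[k], ".", "PASS", info[k],
            if (has_dp) "GT:DP" else "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a biallelic-variant VCF with breed assignments
#'
#' Loads a VCFv4.2 file (via \pkg{vcfR}), drops multiallelic sites with a
#' message, left-aligns indels to their minimal representation, and returns
#' the variant table together with a [genotype_matrix()]. Every VCF sample
#' must appear in `breed_of`; a sample without a breed is a hard error.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param breed_of named character vector (sample -> breed), e.g. from
#'   [read_breed_table()].
#' @return list with elements `variants` (a `data.table`: `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `total_depth`, `consequence`,
#'   `pconvert_fwd`, `pconvert_rev`) and `genotypes`.
#' @export
read_vcf <- function(path, breed_of) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1] %||% character(0)
    geno <- matrix(integer(0), nrow = length(samples), ncol = 0,
                   dimnames = list(samples, character(0)))
    empty <- data.table(id = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), class = character(),
                        total_depth = integer(), consequence = character(),
                        pconvert_fwd = numeric(), pconvert_rev = numeric())
    gm <- if (length(samples) > 0) {
      genotype_matrix(geno, breed_of[samples])
    } else NULL
    return(list(variants = empty, genotypes = gm, n_multiallelic = 0L))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multiallelic site(s) excluded")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  samples <- colnames(vcf@gt)[-1]
  nobreed <- setdiff(samples, names(breed_of))
  if (length(nobreed) > 0) {
    stop("VCF sample(s) without breed assignment: ",
         paste(utils::head(nobreed, 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  dp <- tryCatch(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
    error = function(e) NULL)
  norm <- normalize_variant(fix$REF, fix$ALT, as.integer(fix$POS))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[is.na(ids) | ids == "."], "_",
    norm$pos[is.na(ids) | ids == "."])
  variants <- data.table(
    id = ids,
    chrom = fix$CHROM,
    pos = norm$pos,
    ref = norm$ref,
    alt = norm$alt,
    class = variant_class(norm$ref, norm$alt),
    total_depth = if (is.null(dp)) NA_integer_ else
      as.integer(rowSums(dp, na.rm = TRUE)),
    consequence = extract_info_field(vcf, "CSQ"),
    pconvert_fwd = suppressWarnings(
      as.numeric(extract_info_field(vcf, "PCF"))),
    pconvert_rev = suppressWarnings(
      as.numeric(extract_info_field(vcf, "PCR")))
  )
  geno <- t(code)
  colnames(geno) <- variants$id
  depth <- if (!is.null(dp)) {
    d <- t(dp); colnames(d) <- variants$id; storage.mode(d) <- "integer"; d
  } else NULL
  list(variants = variants,
       genotypes = genotype_matrix(geno, breed_of[samples], depth = depth),
       n_multiallelic = sum(multi))
}

extract_info_field <- function(vcf, key) {
  out <- vcfR::extract.info(vcf, element = key)
  if (is.null(out)) rep(NA_character_, nrow(vcf@fix)) else out
}
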