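IMPACT_LEVELS <- c("modifier", "low", "moderate", "high")

# five normally-"modifier" consequence types promoted to low impact so that
# exonic but non-protein-changing variation competes for chip slots
DEFAULT_LOW_OVERRIDES <- c(
  "coding_sequence_variant", "mature_miRNA_variant", "5_prime_UTR_variant",
  "3_prime_UTR_variant", "non_coding_transcript_exon_variant"
)

#' Consequence-term to impact-class map
#'
#' Loads the bundled VEP-style consequence table (term -> impact) and applies
#' the reclassification overrides: by default five exonic consequence types
#' ("coding sequence variant", "mature miRNA variant", 5'/3' UTR variants and
#' "non-coding transcript exon variant") are promoted from modifier to low
#' impact, reflecting their value on a genotyping array despite not altering
#' the protein.
#'
#' @param path TSV with columns `term` and `impact`; defaults to the table
#'   shipped with the package.
#' @param low_overrides character vector of terms forced to `low` impact.
#' @return an object of class `impact_map` (named character vector,
#'   term -> impact).
#' @export
impact_map <- function(path = system.file("extdata", "consequence_impact.tsv",
                                          package = "chipdesign"),
                       low_overrides = DEFAULT_LOW_OVERRIDES) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("term", "impact") %in% names(tab))) {
    stop("impact table needs columns 'term' and 'impact'")
  }
  if (anyDuplicated(tab$term)) {
    stop("impact table maps a term more than once: ",
         tab$term[duplicated(tab$term)][1])
  }
  if (!all(tab$impact %in% IMPACT_LEVELS)) {
    stop("unknown impact level in table")
  }
  map <- stats::setNames(tab$impact, tab$term)
  map[intersect(low_overrides, names(map))] <- "low"
  map[setdiff(low_overrides, names(map))] <- "low"
  structure(map, class = "impact_map", overrides = low_overrides)
}

#' Classify a variant's impact from its consequence terms
#'
#' Returns the most severe impact class across all of a variant's consequence
#' terms (severity high > moderate > low > modifier), after the map's
#' overrides. Aggregation by maximum severity follows VEP's "most severe
#' consequence" convention; the result is idempotent and independent of term
#' order.
#'
#' @param terms one entry per variant: either a list of character vectors of
#'   consequence terms, or a character vector whose elements are single terms
#'   or `&`-separated term strings as produced by VEP.
#' @param map an [impact_map()].
#' @param unknown `"error"` (default) to fail on a term absent from the map,
#'   or `"modifier"` to classify it as modifier with a warning.
#' @return character vector of impact classes, one per variant.
#' @export
classify_impact <- function(terms, map = impact_map(),
                            unknown = c("error", "modifier")) {
  unknown <- match.arg(unknown)
  if (!is.list(terms)) terms <- strsplit(terms, "&", fixed = TRUE)
  vapply(terms, function(tt) {
    if (length(tt) == 0 || all(is.na(tt))) stop("at least one term required")
    tt <- tt[!is.na(tt)]
    miss <- setdiff(tt, names(map))
    if (length(miss) > 0) {
      if (unknown == "error") {
        stop("unknown consequence term(s): ", paste(miss, collapse = ", "))
      }
      warning("unknown consequence term(s) classified as modifier: ",
              paste(miss, collapse = ", "))
    }
    lev <- unname(map[intersect(tt, names(map))])
    if (length(miss) > 0) lev <- c(lev, "modifier")
    IMPACT_LEVELS[max(match(lev, IMPACT_LEVELS))]
  }, character(1))
}
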