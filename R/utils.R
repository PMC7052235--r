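#' @importFrom rlang .data .env %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols n row_number across rename
#'   distinct pull if_else lag lead case_when anti_join semi_join first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rbeta rbinom rnbinom rnorm rpois runif sd setNames
#'   quantile rexp
#' @importFrom utils head tail
NULL

# The six predictor algorithms consumed as annotation columns.
PREDICTORS <- c(
  "sift", "polyphen2_hvar", "mutation_taster2",
  "mutation_assessor", "fathmm", "fathmm_mkl"
)

CLINVAR_CLASSES <- c(
  "pathogenic", "likely_pathogenic", "uncertain", "conflicting",
  "likely_benign", "benign", "unclassified"
)

# Grades that qualify a variant as a reportable candidate.
QUALIFYING_GRADES <- c("pathogenic", "likely_pathogenic", "predicted_pathogenic")

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used to join variant records with
#' annotations, truth ledgers and call sets.
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Parsimony-based indel normalization without a reference sequence: trim the
# longest shared suffix, then the longest shared prefix keeping >= 1 base,
# shifting pos right by the number of prefix bases removed.
normalize_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    if (is.na(r) || is.na(a) || (nchar(r) == 1L && nchar(a) == 1L)) next
    # suffix trim
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # prefix trim
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a variant by allele-length change
#'
#' @param ref,alt Allele strings.
#' @return One of `"snv"`, `"insertion"`, `"deletion_gt1bp"`, `"other"`.
#' @export
variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "snv",
    nchar(alt) > nchar(ref) ~ "insertion",
    nchar(ref) - nchar(alt) > 1L ~ "deletion_gt1bp",
    TRUE ~ "other"
  )
}

# ---- genotype string helpers -------------------------------------------------

gt_alleles <- function(gt) {
  # returns list of integer allele vectors; NULL-equivalent = integer(0) + NA
  stringr::str_split(gt, "[/|]")
}

#' Count alternate alleles in a genotype string
#'
#' `"0/1"` gives 1, `"1/1"` and hemizygous `"1"` give 2 and 1 respectively;
#' missing genotypes (`"./."`, `"."`, `NA`) give `NA`.
#'
#' @param gt Genotype strings (`/` or `|` separated allele indices).
#' @return Integer vector of alt-allele counts.
#' @export
gt_alt_count <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !stringr::str_detect(gt, "\\.")
  if (any(ok)) {
    out[ok] <- vapply(
      gt_alleles(gt[ok]),
      function(a) sum(as.integer(a) > 0L),
      integer(1)
    )
  }
  out
}

gt_is_missing <- function(gt) is.na(gt) | stringr::str_detect(gt, "\\.")
gt_is_het <- function(gt) {
  ac <- gt_alt_count(gt)
  pl <- gt_ploidy(gt)
  !is.na(ac) & pl == 2L & ac == 1L
}
gt_is_hom_alt <- function(gt) {
  ac <- gt_alt_count(gt)
  pl <- gt_ploidy(gt)
  !is.na(ac) & ac == pl
}
gt_is_hom_ref <- function(gt) {
  ac <- gt_alt_count(gt)
  !is.na(ac) & ac == 0L
}
gt_ploidy <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  out[ok] <- stringr::str_count(gt[ok], "[/|]") + 1L
  out
}
gt_is_phased <- function(gt) !is.na(gt) & stringr::str_detect(gt, "\\|")

# ---- interval helpers --------------------------------------------------------

# Reciprocal-overlap join of two interval tibbles (chrom/start/end, half-open).
# Returns x rows with best-matching y row (suffix .y) and the reciprocal
# overlap fraction; x rows without overlap get NA matches.
reciprocal_overlap <- function(x, y, min_frac = 0.5) {
  if (nrow(x) == 0L) {
    return(mutate(x, match_idx = integer(0), reciprocal = numeric(0)))
  }
  x <- mutate(x, .xi = row_number())
  y <- mutate(y, .yi = row_number())
  j <- inner_join(x, y, by = "chrom", suffix = c("", ".y"),
                  relationship = "many-to-many")
  if (nrow(j) > 0L) {
    j <- j |>
      mutate(
        ov = pmax(0, pmin(.data$end, .data$end.y) - pmax(.data$start, .data$start.y)),
        reciprocal = pmin(
          .data$ov / (.data$end - .data$start),
          .data$ov / (.data$end.y - .data$start.y)
        )
      ) |>
      filter(.data$reciprocal >= min_frac) |>
      group_by(.data$.xi) |>
      dplyr::slice_max(.data$reciprocal, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select(".xi", match_idx = ".yi", "reciprocal")
  } else {
    j <- tibble(.xi = integer(0), match_idx = integer(0), reciprocal = numeric(0))
  }
  x |>
    left_join(j, by = ".xi") |>
    select(-".xi")
}

# TRUE for positions falling inside any interval (half-open 0-based) of `ivs`.
pos_in_intervals <- function(chrom, pos, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(rep(FALSE, length(chrom)))
  out <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(ivs))) {
    out <- out | (chrom == ivs$chrom[i] & pos > ivs$start[i] & pos <= ivs$end[i])
  }
  out
}
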