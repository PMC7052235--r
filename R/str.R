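#' Default tandem-repeat disease-locus panel
#'
#' The 17 repeat-expansion disease loci assessed by default, with curated
#' per-locus repeat-count ranges (normal maximum, optional premutation
#' range, pathogenic minimum). The ranges are shipped defaults drawn from
#' the clinical literature and are user-overridable; they are thresholds for
#' flagging, not diagnostic assertions. AR and FMR1 are X-linked (single
#' allele in males, matched against maternal alleles).
#'
#' @return Tibble: `locus`, `chrom`, `normal_max`, `premut_min`,
#'   `premut_max`, `pathogenic_min`, `x_linked`.
#' @export
str_panel <- function() {
  tibble::tribble(
    ~locus,     ~chrom,  ~normal_max, ~premut_min, ~premut_max, ~pathogenic_min,
    "CBL",      "chr11",  79L,  80L, 100L, 101L,
    "ATN1",     "chr12",  35L,  36L,  47L,  48L,
    "ATXN2",    "chr12",  31L,  32L,  32L,  33L,
    "ATXN3",    "chr14",  44L,  45L,  59L,  60L,
    "JPH3",     "chr16",  28L,  29L,  39L,  40L,
    "CACNA1A",  "chr19",  18L,  19L,  19L,  20L,
    "DMPK",     "chr19",  34L,  35L,  49L,  50L,
    "CSTB",     "chr21",   3L,   4L,  29L,  30L,
    "ATXN10",   "chr22",  32L,  33L, 799L, 800L,
    "ATXN7",    "chr3",   33L,  34L,  36L,  37L,
    "HTT",      "chr4",   26L,  27L,  39L,  40L,
    "PPP2R2B",  "chr5",   32L,  33L,  50L,  51L,
    "ATXN1",    "chr6",   35L,  36L,  38L,  39L,
    "C9ORF72",  "chr9",   23L,  24L,  59L,  60L,
    "FXN",      "chr9",   33L,  34L,  65L,  66L,
    "AR",       "chrX",   34L,  35L,  37L,  38L,
    "FMR1",     "chrX",   44L,  45L, 199L, 200L
  ) |>
    mutate(x_linked = .data$chrom == "chrX")
}

#' Flag repeat genotypes against per-locus pathogenic ranges
#'
#' Classifies each allele of each repeat genotype as `normal`,
#' `premutation` or `pathogenic` (pathogenic lower bound inclusive).
#'
#' @param genotypes Tibble `locus`, `sample_id`, `allele_1`, `allele_2`
#'   (repeat counts; `allele_2` `NA` for hemizygous calls).
#' @param thresholds Locus threshold tibble (default [str_panel()]).
#' @return Long tibble: `locus`, `sample_id`, `allele` (1/2), `repeats`,
#'   `classification`.
#' @export
flag_pathogenic_repeats <- function(genotypes, thresholds = str_panel()) {
  missing <- setdiff(unique(genotypes$locus), thresholds$locus)
  if (length(missing) > 0) {
    stop("no thresholds configured for loci: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), names_to = "allele",
                        names_prefix = "allele_", values_to = "repeats") |>
    filter(!is.na(.data$repeats)) |>
    mutate(allele = as.integer(.data$allele)) |>
    left_join(thresholds, by = "locus") |>
    mutate(classification = case_when(
      .data$repeats >= .data$pathogenic_min ~ "pathogenic",
      !is.na(.data$premut_min) & .data$repeats >= .data$premut_min &
        .data$repeats <= .data$premut_max ~ "premutation",
      TRUE ~ "normal"
    )) |>
    select("locus", "sample_id", "allele", "repeats", "classification")
}

# Best assignment of embryo alleles to parents for one locus.
concordance_one <- function(e, f, m, tolerance = 0) {
  hit <- function(allele, parent) {
    !is.na(allele) && any(abs(parent[!is.na(parent)] - allele) <= tolerance)
  }
  e <- e[!is.na(e)]
  if (length(e) == 1) {
    # hemizygous: matched against maternal alleles only
    return(tibble(allele = 1L, repeats = e,
                  status = if (hit(e, m)) "concordant" else "discordant"))
  }
  a1 <- c(hit(e[1], f), hit(e[2], m))  # allele1 from father, allele2 mother
  a2 <- c(hit(e[1], m), hit(e[2], f))  # swapped
  best <- if (sum(a2) > sum(a1)) a2 else a1
  tibble(allele = c(1L, 2L), repeats = e,
         status = if_else(best, "concordant", "discordant"))
}

#' Parent–embryo tandem-repeat transmission concordance
#'
#' For each locus, labels each embryo allele concordant when its repeat
#' count exactly matches an allele of a distinct parent under one consistent
#' parent-to-allele assignment; of the two possible assignments the one
#' maximizing the concordant count is used. X-linked loci in male embryos
#' carry a single allele matched against the maternal alleles only. Loci
#' with a missing parental genotype are `unassessable`.
#'
#' @param genotypes Repeat genotype tibble (`locus`, `sample_id`,
#'   `allele_1`, `allele_2`).
#' @param pedigree Pedigree tibble.
#' @param embryo_id Embryo sample id.
#' @param tolerance Allowed repeat-count difference (exact = 0, the default).
#' @param panel Locus panel ([str_panel()]), used for X-linkage.
#' @return Tibble: `locus`, `allele`, `repeats`, `status`
#'   (`concordant` / `discordant` / `unassessable`).
#' @export
str_transmission <- function(genotypes, pedigree, embryo_id, tolerance = 0,
                             panel = str_panel()) {
  ids <- parent_ids(pedigree, embryo_id)
  g <- function(sid, locus) {
    row <- filter(genotypes, .data$sample_id == sid, .data$locus == .env$locus)
    if (nrow(row) != 1) return(NULL)
    c(row$allele_1, row$allele_2)
  }
  loci <- genotypes |>
    filter(.data$sample_id == embryo_id) |>
    pull("locus")
  purrr::map_dfr(loci, function(lc) {
    e <- g(embryo_id, lc)
    f <- g(ids$father, lc)
    m <- g(ids$mother, lc)
    e <- e[!is.na(e)]
    if (length(e) == 0) return(tibble())
    x_locus <- lc %in% panel$locus[panel$x_linked]
    male <- identical(ids$sex, "male")
    if (is.null(m) || (!(x_locus && male) && is.null(f))) {
      return(tibble(locus = lc, allele = seq_along(e), repeats = e,
                    status = "unassessable"))
    }
    res <- if (x_locus && male) {
      concordance_one(e[1], NULL, m, tolerance)
    } else {
      concordance_one(e, f, m, tolerance)
    }
    mutate(res, locus = lc) |>
      select("locus", "allele", "repeats", "status")
  })
}
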