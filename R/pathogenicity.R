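#' Grade variants from ClinVar class and review stars
#'
#' ClinVar `pathogenic` / `likely_pathogenic` classes map directly to grades
#' with their review stars carried; `benign` / `likely_benign` map to
#' `benign_like`; `uncertain`, `conflicting` and `unclassified` return
#' `unknown`, making the variant eligible for the stacked prediction filter.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return The input with columns `grade`, `basis`, `stars` added
#'   (prediction-eligible rows graded `unknown`, basis `none`).
#' @export
grade_clinvar <- function(annotations) {
  annotations |>
    mutate(
      grade = case_when(
        .data$clinvar_class == "pathogenic" ~ "pathogenic",
        .data$clinvar_class == "likely_pathogenic" ~ "likely_pathogenic",
        .data$clinvar_class %in% c("benign", "likely_benign") ~ "benign_like",
        TRUE ~ "unknown"
      ),
      basis = if_else(.data$grade == "unknown", "none", "clinvar"),
      stars = if_else(.data$basis == "clinvar", .data$review_stars, NA_integer_)
    )
}

#' Grade unclassified variants with the stacked prediction filter
#'
#' For variants ClinVar leaves unresolved, applies the three-stage prediction
#' conjunction: at least two of the six predictor algorithms call the variant
#' damaging ("more than one"), MPC strictly above 2, and Phred-scaled CADD
#' strictly above 35. Missing predictor verdicts count as not damaging;
#' missing MPC or CADD fails its stage (graded `vus`). Variants already
#' graded by ClinVar are untouched.
#'
#' @param graded Output of [grade_clinvar()].
#' @param min_damaging Predictor consensus threshold (default 2).
#' @param mpc_min,cadd_min Strict score thresholds (defaults 2 and 35).
#' @return The input with `unknown`-grade rows re-graded to
#'   `predicted_pathogenic` (basis `prediction`) or `vus`.
#' @export
grade_prediction <- function(graded, min_damaging = 2, mpc_min = 2,
                             cadd_min = 35) {
  n_damaging <- Reduce(`+`, lapply(PREDICTORS, function(p) {
    as.integer(!is.na(graded[[p]]) & graded[[p]] == "damaging")
  }))
  if (nrow(graded) == 0) n_damaging <- integer(0)
  passes <- n_damaging >= min_damaging &
    !is.na(graded$mpc) & graded$mpc > mpc_min &
    !is.na(graded$cadd_phred) & graded$cadd_phred > cadd_min
  graded |>
    mutate(
      n_damaging = n_damaging,
      basis = if_else(.data$grade == "unknown", "prediction", .data$basis),
      grade = case_when(
        .data$grade != "unknown" ~ .data$grade,
        passes ~ "predicted_pathogenic",
        TRUE ~ "vus"
      )
    )
}

#' Grade an annotation table
#'
#' ClinVar grading first; the prediction stack only for variants ClinVar
#' leaves unresolved (exactly one basis per variant).
#'
#' @inheritParams grade_clinvar
#' @inheritParams grade_prediction
#' @return Annotation tibble with `grade`, `basis`, `stars`, `n_damaging`.
#' @export
grade_variants <- function(annotations, min_damaging = 2, mpc_min = 2,
                           cadd_min = 35) {
  annotations |>
    grade_clinvar() |>
    grade_prediction(min_damaging = min_damaging, mpc_min = mpc_min,
                     cadd_min = cadd_min)
}

#' Screen candidates against an incidental-findings gene list
#'
#' Intersects pathogenic / likely pathogenic findings with a user-supplied
#' incidental-findings gene list (e.g. the ACMG secondary-findings genes) and
#' reports embryo and parental hits separately.
#'
#' @param embryo_candidates Candidate tibble with `gene` and `grade` columns
#'   (embryo findings).
#' @param parent_candidates Tibble of pathogenic variants carried by the
#'   parents, with `gene` and `grade` columns (may be the same table with a
#'   `sample_id` column).
#' @param incidental_genes Character vector of gene symbols.
#' @return A list with `embryo` and `parents` tibbles, or a `notice` string
#'   when the gene list is empty.
#' @export
screen_incidental <- function(embryo_candidates, parent_candidates,
                              incidental_genes) {
  if (length(incidental_genes) == 0) {
    return(list(notice = "incidental-findings gene list empty; section omitted"))
  }
  pick <- function(tbl) {
    filter(tbl, !is.na(.data$gene), .data$gene %in% incidental_genes,
           .data$grade %in% c("pathogenic", "likely_pathogenic"))
  }
  list(embryo = pick(embryo_candidates), parents = pick(parent_candidates))
}
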