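#' Classify parental origin of embryo alternate alleles
#'
#' Labels the embryo's alternate allele at each site by comparing the trio's
#' genotypes: carried by the father only — paternal; mother only — maternal;
#' both parents — ambiguous; neither parent (both confidently called) —
#' de novo. A missing parental genotype yields ambiguous (the allele may
#' still be transmitted); a missing embryo genotype yields `NA` (routed to
#' the expected-but-missing accounting), and embryo reference-only sites
#' yield `"none"`.
#'
#' @param trio Trio-layout tibble (columns `gt_f`, `gt_m`, `gt_e`).
#' @return The input with an `origin` column.
#' @export
classify_transmission <- function(trio) {
  f <- gt_alt_count(trio$gt_f)
  m <- gt_alt_count(trio$gt_m)
  e <- gt_alt_count(trio$gt_e)
  trio |>
    mutate(origin = case_when(
      is.na(e) ~ NA_character_,
      e == 0L ~ "none",
      is.na(f) | is.na(m) ~ "ambiguous",
      f > 0L & m == 0L ~ "paternal",
      m > 0L & f == 0L ~ "maternal",
      f > 0L & m > 0L ~ "ambiguous",
      TRUE ~ "de_novo"
    ))
}

#' Assemble the per-embryo screening table
#'
#' Joins one embryo's trio genotype layout with graded annotations, assigns
#' parental origin, embryo VAF and variant class, and the dbSNP/novel
#' subfilter split. Variants absent from the annotation table get grade
#' `unknown` and subfilter `novel`.
#'
#' @param variants Long variant tibble ([read_trio_vcf()]).
#' @param pedigree Pedigree tibble.
#' @param graded Graded annotation tibble ([grade_variants()]).
#' @param embryo_id Embryo sample id.
#' @return Screening tibble: one row per site with trio calls, `origin`,
#'   `grade`, `subfilter`, `vaf`, `variant_class`.
#' @export
prepare_screen <- function(variants, pedigree, graded, embryo_id) {
  ann_cols <- c("key", "in_dbsnp", "rsid", "clinvar_class", "review_stars",
                "gene", "grade", "basis", "stars", "mpc", "cadd_phred")
  trio_layout(variants, pedigree, embryo_id) |>
    left_join(select(graded, dplyr::all_of(ann_cols)), by = "key") |>
    mutate(
      in_dbsnp = dplyr::coalesce(.data$in_dbsnp, FALSE),
      grade = dplyr::coalesce(.data$grade, "unknown"),
      basis = dplyr::coalesce(.data$basis, "none"),
      subfilter = if_else(.data$in_dbsnp, "dbsnp", "novel")
    ) |>
    classify_transmission() |>
    compute_vaf()
}

#' Infer embryo sex from X heterozygosity
#'
#' Male when the heterozygous fraction over called chrX sites (outside the
#' pseudoautosomal regions) is below `het_max`; requires at least `min_sites`
#' called X sites, otherwise `"unknown"`.
#'
#' @param screen Screening tibble.
#' @param het_max Heterozygosity fraction below which the embryo is male.
#' @param min_sites Minimum number of called X sites.
#' @param par_regions Pseudoautosomal intervals to exclude.
#' @return `"male"`, `"female"` or `"unknown"`.
#' @export
infer_embryo_sex <- function(screen, het_max = 0.1, min_sites = 200,
                             par_regions = NULL) {
  x <- screen |>
    filter(.data$chrom == "chrX",
           !pos_in_intervals(.data$chrom, .data$pos, par_regions),
           !gt_is_missing(.data$gt_e))
  if (nrow(x) < min_sites) return("unknown")
  het_frac <- mean(gt_is_het(x$gt_e))
  if (het_frac < het_max) "male" else "female"
}

resolve_embryo_sex <- function(screen, pedigree, embryo_id, config) {
  sex <- parent_ids(pedigree, embryo_id)$sex
  if (!is.na(sex) && sex %in% c("male", "female")) return(sex)
  infer_embryo_sex(screen, par_regions = config$par_regions)
}

# Evaluate named pass/fail steps, recording the ordered trail.
eval_steps <- function(tbl, steps) {
  pass <- rep(TRUE, nrow(tbl))
  trail <- rep("", nrow(tbl))
  for (nm in names(steps)) {
    s <- steps[[nm]]
    s[is.na(s)] <- FALSE
    trail <- paste0(trail, if_else(trail == "", "", ";"), nm, "=",
                    if_else(s, "pass", "fail"))
    pass <- pass & s
  }
  mutate(tbl, filter_trail = trail, pass = pass)
}

has_embryo_alt <- function(tbl) {
  ac <- gt_alt_count(tbl$gt_e)
  !is.na(ac) & ac > 0L
}

is_x_nonpar <- function(tbl, config) {
  tbl$chrom == "chrX" &
    !pos_in_intervals(tbl$chrom, tbl$pos, config$par_regions)
}

#' Dominant heterozygous filter
#'
#' Retains transmitted (paternal / maternal / ambiguous-origin) alt-bearing
#' embryo calls of qualifying pathogenicity grade at embryo depth >= 10 and
#' genotype quality >= the configured minimum, split into dbSNP and novel
#' subfilters.
#'
#' @param screen Screening tibble ([prepare_screen()]).
#' @param config [screen_config()] list.
#' @param keep_all Return all evaluated rows (with `pass` and `filter_trail`)
#'   instead of only the retained candidates.
#' @return Candidate tibble with `mode = "dominant_het"`.
#' @export
filter_dominant <- function(screen, config = screen_config(), keep_all = FALSE) {
  x <- screen[has_embryo_alt(screen) & !is_x_nonpar(screen, config), ,
              drop = FALSE]
  out <- eval_steps(x, list(
    transmitted = x$origin %in% c("paternal", "maternal", "ambiguous"),
    depth = x$dp_e >= config$depth_min,
    gq = x$gq_e >= config$gq_min,
    grade = x$grade %in% QUALIFYING_GRADES
  )) |>
    mutate(mode = "dominant_het", finding = "affected")
  if (keep_all) out else filter(out, .data$pass)
}

#' Recessive homozygous filter
#'
#' Retains embryo homozygous-alternate records of qualifying grade with one
#' alternate allele from each parent (`finding = "affected"`).
#' Mendelian-impossible homozygotes — a parent confidently homozygous
#' reference — are flagged `"dropout_suspect"` instead of being called.
#' Qualifying heterozygous records are retained separately as
#' `finding = "carrier"` (reported, not disease calls).
#'
#' @inheritParams filter_dominant
#' @return Candidate tibble with `mode = "recessive_hom"` and a `finding`
#'   column (`affected` / `carrier` / `dropout_suspect`).
#' @export
filter_recessive <- function(screen, config = screen_config(), keep_all = FALSE) {
  x <- screen[has_embryo_alt(screen) & !is_x_nonpar(screen, config), ,
              drop = FALSE]
  hom <- gt_is_hom_alt(x$gt_e) & gt_ploidy(x$gt_e) == 2L
  het <- gt_is_het(x$gt_e)
  f_alt <- gt_alt_count(x$gt_f)
  m_alt <- gt_alt_count(x$gt_m)
  parent_dropout <-
    (gt_is_hom_ref(x$gt_f) & !is.na(x$dp_f) & x$dp_f >= config$depth_min) |
    (gt_is_hom_ref(x$gt_m) & !is.na(x$dp_m) & x$dp_m >= config$depth_min)
  out <- eval_steps(x, list(
    depth = x$dp_e >= config$depth_min,
    gq = x$gq_e >= config$gq_min,
    grade = x$grade %in% QUALIFYING_GRADES,
    genotype = hom | het
  )) |>
    mutate(
      mode = "recessive_hom",
      finding = case_when(
        hom & parent_dropout ~ "dropout_suspect",
        hom & f_alt > 0L & m_alt > 0L & !is.na(f_alt) & !is.na(m_alt) ~ "affected",
        hom ~ "dropout_suspect",  # hom-alt without biparental support
        het ~ "carrier",
        TRUE ~ NA_character_
      )
    )
  if (keep_all) out else filter(out, .data$pass)
}

#' X-linked filter
#'
#' Retains chrX (non-pseudoautosomal) qualifying records: hemizygous or
#' homozygous alternate male embryos and homozygous-alternate female embryos
#' are affected; heterozygous females are carriers. With unknown embryo sex,
#' hits are routed to the curation list (`finding = "curation"`).
#'
#' @inheritParams filter_dominant
#' @param embryo_sex `"male"`, `"female"` or `"unknown"`.
#' @return Candidate tibble with `mode = "x_linked"` and `finding`.
#' @export
filter_xlinked <- function(screen, embryo_sex, config = screen_config(),
                           keep_all = FALSE) {
  x <- screen[has_embryo_alt(screen) & is_x_nonpar(screen, config), ,
              drop = FALSE]
  hom <- gt_is_hom_alt(x$gt_e)
  het <- gt_is_het(x$gt_e)
  out <- eval_steps(x, list(
    transmitted = x$origin %in% c("paternal", "maternal", "ambiguous"),
    depth = x$dp_e >= config$depth_min,
    gq = x$gq_e >= config$gq_min,
    grade = x$grade %in% QUALIFYING_GRADES
  )) |>
    mutate(
      mode = "x_linked",
      finding = case_when(
        embryo_sex == "male" ~ "affected",
        embryo_sex == "female" & hom ~ "affected",
        embryo_sex == "female" & het ~ "carrier",
        TRUE ~ "curation"
      )
    )
  if (keep_all) out else filter(out, .data$pass)
}

#' De novo filter (pre-gate)
#'
#' Retains qualifying-grade records whose alternate allele is carried by
#' neither parent. The amplification-artifact gates ([vaf_gate()],
#' [qd_gate()]) are applied downstream.
#'
#' @inheritParams filter_dominant
#' @return Candidate tibble with `mode = "de_novo"`.
#' @export
filter_denovo <- function(screen, config = screen_config(), keep_all = FALSE) {
  x <- screen[has_embryo_alt(screen), , drop = FALSE]
  out <- eval_steps(x, list(
    de_novo = x$origin == "de_novo",
    depth = x$dp_e >= config$depth_min,
    gq = x$gq_e >= config$gq_min,
    grade = x$grade %in% QUALIFYING_GRADES
  )) |>
    mutate(mode = "de_novo", finding = "affected")
  if (keep_all) out else filter(out, .data$pass)
}

#' Failsafe filter
#'
#' Low-specificity, high-sensitivity capture of every alt-bearing embryo call
#' in a clinically actionable gene with read depth above 1, with no genotype
#' quality, grade or VAF requirement — intentionally producing false
#' positives for manual curation.
#'
#' @inheritParams filter_dominant
#' @param actionable_genes Character vector of actionable gene symbols.
#' @return Candidate tibble with `mode = "failsafe"`.
#' @export
filter_failsafe <- function(screen, actionable_genes,
                            config = screen_config(), keep_all = FALSE) {
  x <- screen[has_embryo_alt(screen), , drop = FALSE]
  out <- eval_steps(x, list(
    actionable = !is.na(x$gene) & x$gene %in% actionable_genes,
    depth = x$dp_e >= config$failsafe_depth_min
  )) |>
    mutate(mode = "failsafe", finding = "curation")
  if (keep_all) out else filter(out, .data$pass)
}

#' Compound heterozygote pairing
#'
#' Enumerates all unordered pairs of retained heterozygous hits sharing a
#' gene with opposite parental origin (paternal x maternal, or one inherited
#' plus one retained de novo). Pairs involving an ambiguous-origin hit cannot
#' be phased by parental origin and are emitted with `curation = TRUE`
#' instead of being auto-called.
#'
#' @param het_hits Tibble of retained heterozygous candidates with `key`,
#'   `gene` and `origin` columns (inherited het hits plus gate-surviving
#'   de novo hets).
#' @return Tibble of pairs: `gene`, `key_a`, `key_b`, `origin_a`, `origin_b`,
#'   `curation`.
#' @export
filter_compound_het <- function(het_hits) {
  empty <- tibble(gene = character(0), key_a = character(0),
                  key_b = character(0), origin_a = character(0),
                  origin_b = character(0), curation = logical(0))
  hits <- het_hits |>
    filter(!is.na(.data$gene), gt_is_het(.data$gt_e),
           .data$origin %in% c("paternal", "maternal", "de_novo", "ambiguous")) |>
    distinct(.data$key, .keep_all = TRUE)
  if (nrow(hits) < 2) return(empty)
  out <- hits |>
    group_by(.data$gene) |>
    dplyr::group_split() |>
    purrr::keep(\(g) nrow(g) >= 2) |>
    purrr::map_dfr(function(g) {
      cmb <- utils::combn(seq_len(nrow(g)), 2)
      tibble(
        gene = g$gene[1],
        key_a = g$key[cmb[1, ]], key_b = g$key[cmb[2, ]],
        origin_a = g$origin[cmb[1, ]], origin_b = g$origin[cmb[2, ]]
      )
    })
  if (nrow(out) == 0) return(empty)
  out |>
    mutate(curation = .data$origin_a == "ambiguous" | .data$origin_b == "ambiguous") |>
    filter(.data$curation | .data$origin_a != .data$origin_b)
}

#' Run all inheritance-mode filters for one embryo
#'
#' Applies the six filter workflows and the de novo artifact gates, routes
#' every alt-bearing embryo record into exactly one accounting bucket, and
#' tabulates per-filter survivor counts.
#'
#' @param screen Screening tibble ([prepare_screen()]).
#' @param actionable_genes Actionable gene symbols for the failsafe filter.
#' @param embryo_sex Embryo sex; `NULL` infers from pedigree then X
#'   heterozygosity.
#' @param config [screen_config()].
#' @return A list: `dominant`, `recessive` (affected), `carriers`,
#'   `dropout_suspects`, `xlinked`, `denovo` (gate result), `compound_pairs`,
#'   `failsafe`, `curation`, `rejected`, `survivor_counts`.
#' @export
screen_inheritance <- function(screen, actionable_genes = character(0),
                               embryo_sex = "unknown",
                               config = screen_config()) {
  dom_all <- filter_dominant(screen, config, keep_all = TRUE)
  rec_all <- filter_recessive(screen, config, keep_all = TRUE)
  x_all <- filter_xlinked(screen, embryo_sex, config, keep_all = TRUE)
  dn_all <- filter_denovo(screen, config, keep_all = TRUE)
  fs_all <- filter_failsafe(screen, actionable_genes, config, keep_all = TRUE)

  dominant <- filter(dom_all, .data$pass)
  rec <- filter(rec_all, .data$pass)
  recessive <- filter(rec, .data$finding == "affected")
  carriers <- bind_rows(
    filter(rec, .data$finding == "carrier"),
    filter(x_all, .data$pass, .data$finding == "carrier")
  )
  dropout_suspects <- filter(rec, .data$finding == "dropout_suspect")
  xlinked <- filter(x_all, .data$pass, .data$finding == "affected")
  x_curation <- filter(x_all, .data$pass, .data$finding == "curation")

  denovo <- filter_denovo(screen, config) |>
    vaf_gate(threshold = config$vaf_threshold,
             classes = config$vaf_gate_classes) |>
    qd_gate(threshold = config$qd_threshold)

  het_pool <- bind_rows(
    filter(dominant, gt_is_het(.data$gt_e)),
    filter(denovo$retained, gt_is_het(.data$gt_e))
  )
  compound_pairs <- filter_compound_het(het_pool)

  failsafe <- filter(fs_all, .data$pass)

  accounted <- unique(c(
    dominant$key, recessive$key, carriers$key, dropout_suspects$key,
    xlinked$key, x_curation$key, denovo$retained$key, denovo$rejected$key,
    failsafe$key
  ))
  rejected <- bind_rows(dom_all, rec_all, x_all, dn_all) |>
    filter(!.data$key %in% accounted) |>
    group_by(.data$key) |>
    dplyr::slice(1) |>
    ungroup()

  survivor_counts <- bind_rows(
    survivor_tbl(dom_all, "dominant_het"),
    survivor_tbl(rec_all, "recessive_hom"),
    survivor_tbl(x_all, "x_linked"),
    survivor_tbl(dn_all, "de_novo"),
    survivor_tbl(fs_all, "failsafe"),
    tibble(
      mode = "de_novo", step = c("vaf_gate", "qd_gate"),
      remaining = c(
        nrow(dn_all[dn_all$pass, ]) -
          sum(grepl("^vaf", denovo$rejected$reject_reason)),
        nrow(denovo$retained)
      )
    )
  )

  list(
    dominant = dominant, recessive = recessive, carriers = carriers,
    dropout_suspects = dropout_suspects, xlinked = xlinked,
    denovo = denovo, compound_pairs = compound_pairs, failsafe = failsafe,
    curation = x_curation, rejected = rejected,
    survivor_counts = survivor_counts, embryo_sex = embryo_sex
  )
}

# Successive survivor counts along a filter's trail (Fig. 2-style export).
survivor_tbl <- function(evaluated, mode) {
  if (nrow(evaluated) == 0) {
    return(tibble(mode = mode, step = "input", remaining = 0L))
  }
  steps <- stringr::str_split(evaluated$filter_trail, ";")
  nm <- vapply(stringr::str_split(steps[[1]], "="), `[`, character(1), 1)
  keep <- rep(TRUE, nrow(evaluated))
  out <- tibble(mode = mode, step = "input", remaining = nrow(evaluated))
  for (i in seq_along(nm)) {
    ok <- vapply(steps, function(s) grepl("=pass", s[i], fixed = TRUE), logical(1))
    keep <- keep & ok
    out <- bind_rows(out, tibble(mode = mode, step = nm[i],
                                 remaining = sum(keep)))
  }
  out
}
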