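#' Screen one embryo
#'
#' Runs the full per-embryo pipeline: screening-table assembly, the six
#' inheritance-mode filters with the de novo artifact gates, LoH detection
#' and trio comparison, the expected-but-missing ledger with flanking-SNP
#' rescue, binned trio CNV calling with dosage annotation and the recessive
#' cross-check, and tandem-repeat transmission concordance.
#'
#' @param inputs Input list ([read_family_dir()] or equivalent): `variants`,
#'   `pedigree`, `annotations`, and optionally `tracks`, `str_genotypes`,
#'   `dosage_table`, `actionable_genes`, `incidental_genes`, `sv_calls`.
#' @param embryo_id Embryo sample id.
#' @param config [screen_config()].
#' @return An `embryo_report` list.
#' @export
screen_embryo <- function(inputs, embryo_id, config = screen_config()) {
  graded <- grade_variants(inputs$annotations)
  screen <- prepare_screen(inputs$variants, inputs$pedigree, graded, embryo_id)
  sex <- resolve_embryo_sex(screen, inputs$pedigree, embryo_id, config)
  actionable <- inputs$actionable_genes %||% character(0)

  inh <- screen_inheritance(screen, actionable, sex, config)

  # LoH: embryo segments against informative sites, parents against their own
  ids <- parent_ids(inputs$pedigree, embryo_id)
  emb_seg <- detect_loh_segments(
    embryo_loh_sites(screen), embryo_id,
    config$loh_min_variants, config$loh_min_fraction
  )
  f_seg <- detect_loh_segments(
    parent_loh_sites(inputs$variants, ids$father), ids$father,
    config$loh_min_variants, config$loh_min_fraction
  )
  m_seg <- detect_loh_segments(
    parent_loh_sites(inputs$variants, ids$mother), ids$mother,
    config$loh_min_variants, config$loh_min_fraction
  )
  loh <- trio_call_loh(emb_seg, f_seg, m_seg, config$cnv_reciprocal)

  # recessive homozygotes inside embryo-only LoH are dropout suspects, not
  # disease calls
  emb_only <- filter(loh, .data$label == "embryo_only")
  rec_in_loh <- pos_in_intervals(inh$recessive$chrom, inh$recessive$pos,
                                 emb_only)
  inh$dropout_suspects <- bind_rows(inh$dropout_suspects,
                                    inh$recessive[rec_in_loh, ])
  inh$recessive <- inh$recessive[!rec_in_loh, ]

  ledger <- ledger_expected_missing(screen, loh, config$depth_min) |>
    phase_rescue(screen, config$flank_window)

  # CNV / SV
  cnv <- NULL
  if (!is.null(inputs$tracks)) {
    cnv <- screen_cnvs(inputs, embryo_id, sex, inh, config)
  }
  sv <- NULL
  if (!is.null(inputs$sv_calls) && !is.null(inputs$dosage_table)) {
    sv <- assign_dosage(inputs$sv_calls, inputs$dosage_table)
  }

  str_res <- NULL
  if (!is.null(inputs$str_genotypes)) {
    str_res <- list(
      flags = flag_pathogenic_repeats(inputs$str_genotypes),
      transmission = str_transmission(inputs$str_genotypes, inputs$pedigree,
                                      embryo_id, config$str_tolerance)
    )
  }

  parent_hits <- parental_pathogenic(screen)
  incidental <- screen_incidental(
    bind_rows(inh$dominant, inh$recessive, inh$carriers, inh$xlinked,
              inh$denovo$retained),
    parent_hits,
    inputs$incidental_genes %||% character(0)
  )

  report <- list(
    embryo_id = embryo_id, embryo_sex = sex,
    dominant = inh$dominant, recessive = inh$recessive,
    carriers = inh$carriers, dropout_suspects = inh$dropout_suspects,
    xlinked = inh$xlinked, denovo = inh$denovo,
    compound_pairs = inh$compound_pairs, failsafe = inh$failsafe,
    curation = inh$curation, rejected = inh$rejected,
    loh_segments = loh, ledger = ledger,
    cnv = cnv, sv = sv, str = str_res, incidental = incidental,
    survivor_counts = inh$survivor_counts
  )
  report$summary <- report_counts(report)
  structure(report, class = "embryo_report")
}

# Pathogenic / likely-pathogenic variants carried by either parent.
parental_pathogenic <- function(screen) {
  f_alt <- gt_alt_count(screen$gt_f)
  m_alt <- gt_alt_count(screen$gt_m)
  screen |>
    filter(.data$grade %in% QUALIFYING_GRADES,
           (!is.na(f_alt) & f_alt > 0) | (!is.na(m_alt) & m_alt > 0))
}

screen_cnvs <- function(inputs, embryo_id, sex, inh, config) {
  ids <- parent_ids(inputs$pedigree, embryo_id)
  bins <- bin_depths(inputs$tracks, config$bin_size)
  ped <- inputs$pedigree
  sex_of <- function(id) ped$sex[ped$sample_id == id]
  scored <- score_bins(bins, embryo_id, c(ids$father, ids$mother),
                       sample_sex = sex,
                       control_sexes = c("male", "female"), config = config)
  emb_calls <- call_cnvs(scored, config)
  f_calls <- call_cnvs(
    score_bins(bins, ids$father, ids$mother, "male", "female", config), config
  )
  m_calls <- call_cnvs(
    score_bins(bins, ids$mother, ids$father, "female", "male", config), config
  )
  emb_calls <- trio_cnv_inheritance(emb_calls, f_calls, m_calls,
                                    config$cnv_reciprocal)
  if (!is.null(inputs$dosage_table)) {
    emb_calls <- assign_dosage(emb_calls, inputs$dosage_table)
    het_pool <- bind_rows(
      filter(inh$dominant, gt_is_het(.data$gt_e)),
      filter(inh$carriers, gt_is_het(.data$gt_e))
    )
    compound <- crosscheck_recessive(emb_calls, het_pool)
  } else {
    emb_calls <- mutate(emb_calls, gene = NA_character_,
                        dosage_category = "none", dosage_evidence = "none",
                        route = "none")
    compound <- NULL
  }
  list(bins = scored, calls = emb_calls, father_calls = f_calls,
       mother_calls = m_calls, compound = compound)
}

report_counts <- function(report) {
  cnt <- function(x) if (is.null(x)) 0L else nrow(x)
  tibble(
    category = c("dominant", "recessive_affected", "carriers",
                 "dropout_suspects", "x_linked", "denovo_retained",
                 "denovo_rejected", "compound_pairs", "failsafe",
                 "expected_missing", "loh_segments", "cnv_calls"),
    n = c(cnt(report$dominant), cnt(report$recessive), cnt(report$carriers),
          cnt(report$dropout_suspects), cnt(report$xlinked),
          cnt(report$denovo$retained), cnt(report$denovo$rejected),
          cnt(report$compound_pairs), cnt(report$failsafe),
          cnt(report$ledger), cnt(report$loh_segments),
          cnt(report$cnv$calls))
  )
}

#' Screen every embryo of a family
#'
#' @param inputs Input list or a directory path readable by
#'   [read_family_dir()].
#' @param config [screen_config()].
#' @return A `family_screen` list: `reports` (one `embryo_report` per
#'   embryo), `summary` ([summarize_counts()]).
#' @export
screen_family <- function(inputs, config = screen_config()) {
  if (is.character(inputs)) inputs <- read_family_dir(inputs)
  embryos <- inputs$pedigree$sample_id[inputs$pedigree$role == "embryo"]
  reports <- lapply(embryos, function(e) screen_embryo(inputs, e, config))
  names(reports) <- embryos
  structure(
    list(reports = reports, summary = summarize_counts(reports),
         config = config),
    class = "family_screen"
  )
}

#' Cohort summary counts
#'
#' Per-category mean and standard deviation of the per-embryo report counts
#' (SD is 0 with a single embryo).
#'
#' @param reports List of `embryo_report` objects (or a `family_screen`).
#' @return Tibble `category`, `mean`, `sd`, `n_embryos`.
#' @export
summarize_counts <- function(reports) {
  if (inherits(reports, "family_screen")) reports <- reports$reports
  stopifnot(length(reports) >= 1)
  purrr::map_dfr(reports, function(r) mutate(r$summary,
                                             embryo_id = r$embryo_id)) |>
    group_by(.data$category) |>
    summarise(
      mean = mean(.data$n),
      sd = if (n() > 1) sd(.data$n) else 0,
      n_embryos = n(), .groups = "drop"
    )
}

#' Assign per-condition embryo status
#'
#' For each screened condition (gene + inheritance mode), derives the
#' embryo's status — `affected`, `carrier`, `unaffected`, or `unresolved` —
#' from the report's candidate tables, with the expected-but-missing ledger
#' and its phasing rescue taking precedence when the causal region was
#' unreliable: `carrier_inferred` maps to the carrying status,
#' `noncarrier_inferred` to `unaffected`, and an unrescued entry to
#' `unresolved`.
#'
#' @param report An `embryo_report`.
#' @param conditions Tibble with `gene` and `mode` columns.
#' @return `conditions` with a `status` column.
#' @export
assign_status <- function(report, conditions) {
  in_gene <- function(tbl, g) {
    !is.null(tbl) && nrow(tbl) > 0 && any(!is.na(tbl$gene) & tbl$gene == g)
  }
  status <- character(nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    g <- conditions$gene[i]
    mode <- conditions$mode[i]
    led <- filter(report$ledger, !is.na(.data$gene), .data$gene == g)
    direct <- switch(
      mode,
      dominant_het = if (in_gene(report$dominant, g)) "affected" else NA,
      recessive_hom = if (in_gene(report$recessive, g)) "affected"
        else if (in_gene(filter(report$carriers, .data$mode == "recessive_hom"), g))
          "carrier" else NA,
      x_linked = if (in_gene(report$xlinked, g)) "affected"
        else if (in_gene(filter(report$carriers, .data$mode == "x_linked"), g))
          "carrier" else NA,
      compound_het = {
        pairs <- report$compound_pairs
        n_het <- sum(!is.na(report$dominant$gene) & report$dominant$gene == g &
                       gt_is_het(report$dominant$gt_e))
        if (!is.null(pairs) && nrow(filter(pairs, .data$gene == g,
                                           !.data$curation)) > 0) "affected"
        else if (n_het >= 1) "carrier" else NA
      },
      de_novo = if (in_gene(report$denovo$retained, g)) "affected" else NA
    )
    if (!is.na(direct %||% NA)) {
      status[i] <- direct
    } else if (nrow(led) > 0) {
      rs <- led$rescue_status
      status[i] <- if (all(rs == "noncarrier_inferred")) {
        "unaffected"
      } else if (any(rs == "carrier_inferred")) {
        if (mode %in% c("recessive_hom", "x_linked", "compound_het"))
          "carrier" else "affected"
      } else {
        "unresolved"
      }
    } else if (in_gene(report$dropout_suspects, g)) {
      status[i] <- "unresolved"
    } else {
      status[i] <- "unaffected"
    }
  }
  mutate(conditions, status = status)
}

#' @export
print.embryo_report <- function(x, ...) {
  cat("Embryo screening report:", x$embryo_id, "(", x$embryo_sex, ")\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
print.family_screen <- function(x, ...) {
  cat("Family screen:", length(x$reports), "embryo(s)\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write an embryo report as JSON
#'
#' Machine-readable report (schema version 1): candidate tables, gates,
#' ledger, LoH, CNV calls, STR concordance, summary counts.
#'
#' @param report An `embryo_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema_version = 1,
    embryo_id = report$embryo_id,
    embryo_sex = report$embryo_sex,
    summary = report$summary,
    dominant = report$dominant, recessive = report$recessive,
    carriers = report$carriers, xlinked = report$xlinked,
    denovo_retained = report$denovo$retained,
    denovo_rejected = report$denovo$rejected,
    compound_pairs = report$compound_pairs,
    failsafe = report$failsafe,
    expected_missing = report$ledger,
    loh_segments = report$loh_segments,
    cnv_calls = report$cnv$calls,
    str_transmission = report$str$transmission,
    survivor_counts = report$survivor_counts
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# ---- broom-style methods -----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an embryo report into one candidate table
#'
#' @param x An `embryo_report`.
#' @param ... Unused.
#' @return Tibble of all retained candidates across modes.
#' @export
tidy.embryo_report <- function(x, ...) {
  common <- c("key", "chrom", "pos", "ref", "alt", "gene", "mode",
              "subfilter", "origin", "grade", "vaf", "finding")
  pick <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
    select(tbl, dplyr::any_of(common))
  }
  bind_rows(
    pick(x$dominant), pick(x$recessive), pick(x$carriers), pick(x$xlinked),
    pick(x$denovo$retained), pick(x$failsafe)
  ) |>
    mutate(embryo_id = x$embryo_id)
}

#' One-row summary of an embryo report
#'
#' @param x An `embryo_report`.
#' @param ... Unused.
#' @return One-row tibble of per-category counts.
#' @export
glance.embryo_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "category", values_from = "n") |>
    mutate(embryo_id = x$embryo_id, .before = 1)
}

#' @rdname tidy.embryo_report
#' @export
tidy.family_screen <- function(x, ...) {
  purrr::map_dfr(x$reports, tidy)
}

#' @rdname glance.embryo_report
#' @export
glance.family_screen <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}
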