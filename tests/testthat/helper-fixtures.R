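# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A moderately sized simulated family shared across tests: default genome,
# halved site density, two embryos.
test_family <- function() {
  memo("family", {
    withr::with_seed(101, {
      simulate_family(sim_params(site_density = 1 / 1600, n_embryos = 2))
    })
  })
}

test_family_dir <- function() {
  memo("family_dir", {
    d <- file.path(tempdir(), "es_family")
    emit_family(test_family(), d)
    d
  })
}

test_inputs <- function() {
  memo("inputs", read_family_dir(test_family_dir()))
}

test_screen <- function() {
  memo("screen", screen_family(test_inputs()))
}

# One embryo's screening table (graded + origins), reused by filter tests.
test_screen_tbl <- function() {
  memo("screen_tbl", {
    inp <- test_inputs()
    graded <- grade_variants(inp$annotations)
    prepare_screen(inp$variants, inp$pedigree, graded, "embryo1")
  })
}

# Large parental simulation (>=100,000 SNVs) for substitution-spectrum checks.
test_big_parents <- function() {
  memo("big_parents", {
    withr::with_seed(405, {
      lens <- setNames(rep(2.5e7, 8), paste0("chr", 1:8))
      simulate_parents(sim_params(chrom_lengths = lens,
                                  planted_variants = NULL))
    })
  })
}

# Minimal trio-layout row builder for unit tests of the filters.
trio_row <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                     gt_f = "0/0", gt_m = "0/0", gt_e = "0/1",
                     dp_f = 40L, dp_m = 40L, dp_e = 40L,
                     gq_f = 80, gq_m = 80, gq_e = 80,
                     ad_alt_e = NA_integer_, qd = 25,
                     gene = NA_character_, grade = "pathogenic",
                     in_dbsnp = TRUE, embryo_id = "embryo1") {
  ad_alt_e <- if (is.na(ad_alt_e)) {
    as.integer(round(dp_e * gt_alt_count(gt_e) / pmax(1, gt_ploidy(gt_e))))
  } else {
    ad_alt_e
  }
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    key = variant_key(chrom, pos, ref, alt), qd = qd,
    gt_f = gt_f, ad_ref_f = dp_f, ad_alt_f = 0L, dp_f = dp_f, gq_f = gq_f,
    gt_m = gt_m, ad_ref_m = dp_m, ad_alt_m = 0L, dp_m = dp_m, gq_m = gq_m,
    gt_e = gt_e, ad_ref_e = as.integer(dp_e - ad_alt_e), ad_alt_e = ad_alt_e,
    dp_e = dp_e, gq_e = gq_e,
    embryo_id = embryo_id, in_dbsnp = in_dbsnp, rsid = NA_character_,
    clinvar_class = "unclassified", review_stars = 0L, gene = gene,
    grade = grade, basis = "clinvar", stars = 2L,
    mpc = NA_real_, cadd_phred = NA_real_,
    subfilter = ifelse(in_dbsnp, "dbsnp", "novel")
  ) |>
    classify_transmission() |>
    compute_vaf()
}

trio_rows <- function(...) dplyr::bind_rows(...)

# Annotation-row builder for grading tests.
ann_row <- function(clinvar_class = "unclassified", review_stars = 0L,
                    n_damaging = 0L, mpc = NA_real_, cadd = NA_real_,
                    gene = "G1", pos = 100L, in_dbsnp = TRUE) {
  verdicts <- c(rep("damaging", n_damaging),
                rep("tolerated", 6 - n_damaging))
  out <- tibble::tibble(
    key = variant_key("chr1", pos, "A", "T"), chrom = "chr1",
    pos = as.integer(pos), ref = "A", alt = "T", in_dbsnp = in_dbsnp,
    rsid = NA_character_, clinvar_class = clinvar_class,
    review_stars = as.integer(review_stars), gene = gene
  )
  for (i in seq_along(PREDICTORS)) out[[PREDICTORS[i]]] <- verdicts[i]
  out$mpc <- mpc
  out$cadd_phred <- cadd
  out
}
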