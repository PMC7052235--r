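# Annotation, dosage-table and file emission for simulated families.

# Per-site external-evidence annotations for every site the family's VCF
# will carry. Planted conditions get their specified ClinVar class (or the
# predictor-stack profile); background sites get realistic class, predictor,
# MPC and CADD draws.
simulate_annotations <- function(parents, embryos, params) {
  pv <- params$planted_variants
  sites <- parents$sites |>
    select("chrom", "pos", "ref", "alt", "key", "gene", "planted") |>
    mutate(site_origin = "family")
  extra <- purrr::map_dfr(embryos, function(e) {
    bind_rows(
      e$denovo |>
        mutate(planted_i = if_else(.data$planted, find_planted_denovo(pv),
                                   NA_integer_)) |>
        select("chrom", "pos", "ref", "alt", "key", planted = "planted_i") |>
        mutate(site_origin = "de_novo"),
      e$artifacts |>
        select("chrom", "pos", "ref", "alt", "key") |>
        mutate(planted = NA_integer_, site_origin = "artifact")
    )
  }) |>
    distinct(.data$key, .keep_all = TRUE)
  extra$gene <- locate_gene(extra$chrom, extra$pos, parents$gene_map)
  all <- bind_rows(sites, filter(extra, !.data$key %in% sites$key))
  n <- nrow(all)

  p_db <- dplyr::case_when(
    all$site_origin == "family" ~ params$p_dbsnp_parent,
    all$site_origin == "de_novo" ~ params$p_dbsnp_denovo,
    TRUE ~ params$p_dbsnp_artifact
  )
  in_dbsnp <- runif(n) < p_db
  u <- runif(n)
  pp <- params$p_background_pathogenic
  pl <- params$p_background_likely
  clinvar <- dplyr::case_when(
    in_dbsnp & u < pp ~ "pathogenic",
    in_dbsnp & u < pp + pl ~ "likely_pathogenic",
    u < 0.10 ~ "benign",
    u < 0.25 ~ "likely_benign",
    u < 0.30 ~ "uncertain",
    TRUE ~ "unclassified"
  )
  stars <- dplyr::case_when(
    clinvar %in% c("pathogenic", "likely_pathogenic") ~
      sample(1:2, n, replace = TRUE),
    clinvar %in% c("benign", "likely_benign", "uncertain") ~
      sample(0:2, n, replace = TRUE),
    TRUE ~ 0L
  )
  is_snv <- nchar(all$ref) == 1L & nchar(all$alt) == 1L
  verdicts <- lapply(PREDICTORS, function(p) {
    v <- sample(c("damaging", "tolerated", NA_character_), n, replace = TRUE,
                prob = c(params$predictor_damaging_rate,
                         0.92 - params$predictor_damaging_rate, 0.08))
    v[!is_snv] <- NA_character_   # predictors score substitutions only
    v
  })
  names(verdicts) <- PREDICTORS
  mpc <- round(rlnorm(n, log(0.8), 0.6), 3)
  cadd <- round(rlnorm(n, log(8), 0.8), 2)

  ann <- tibble(
    chrom = all$chrom, pos = as.integer(all$pos), ref = all$ref,
    alt = all$alt, in_dbsnp = in_dbsnp,
    rsid = if_else(in_dbsnp, paste0("rs", 1e6 + seq_len(n)), ""),
    clinvar_class = clinvar, review_stars = as.integer(stars),
    gene = all$gene
  )
  for (p in PREDICTORS) ann[[p]] <- verdicts[[p]]
  ann$mpc <- mpc
  ann$cadd_phred <- cadd

  # background pathogenic evidence is kept out of the planted condition
  # genes so each condition's status is attributable to its planted site
  if (!is.null(pv) && nrow(pv) > 0) {
    bg_in_cond <- !is.na(ann$gene) & ann$gene %in% pv$gene &
      is.na(all$planted)
    ann$clinvar_class[bg_in_cond &
                        ann$clinvar_class %in%
                          c("pathogenic", "likely_pathogenic")] <- "unclassified"
    ann$mpc[bg_in_cond] <- pmin(ann$mpc[bg_in_cond], 1.5)
  }

  # planted overrides
  if (!is.null(pv) && nrow(pv) > 0) {
    idx <- match(all$planted, seq_len(nrow(pv)))
    planted_rows <- which(!is.na(idx))
    for (r in planted_rows) {
      i <- idx[r]
      ann$clinvar_class[r] <- pv$clinvar_class[i]
      ann$review_stars[r] <- pv$review_stars[i]
      ann$gene[r] <- pv$gene[i]
      ann$in_dbsnp[r] <- pv$de_novo[i] || ann$in_dbsnp[r]
      if (isTRUE(pv$predicted[i])) {
        for (p in PREDICTORS[1:3]) ann[[p]][r] <- "damaging"
        for (p in PREDICTORS[4:6]) ann[[p]][r] <- "tolerated"
        ann$mpc[r] <- 2.6
        ann$cadd_phred[r] <- 38
      }
    }
  }
  ann
}

#' Synthetic dosage-sensitivity table
#'
#' A ClinGen-style gene dosage table over the synthetic gene map:
#' haploinsufficiency / triplosensitivity evidence for a handful of genes,
#' including those under the default planted CNVs.
#'
#' @param gene_map Synthetic gene map ([sim_gene_map()]).
#' @return Dosage tibble for [assign_dosage()].
#' @export
sim_dosage_table <- function(gene_map = sim_gene_map()) {
  ev <- tibble::tribble(
    ~gene, ~haploinsufficiency, ~triplosensitivity,
    "PKD1", "sufficient_evidence", "none",
    "SCN1A", "sufficient_evidence", "none",
    "CFTR", "autosomal_recessive_gene", "none",
    "ABL1", "none", "sufficient_evidence",
    "C3G031", "sufficient_evidence", "none",
    "C1G036", "none", "sufficient_evidence",
    "DMD", "sufficient_evidence", "none"
  )
  ev |>
    inner_join(gene_map, by = "gene") |>
    select("gene", "chrom", "start", "end", "haploinsufficiency",
           "triplosensitivity")
}

#' Default actionable-gene list for the synthetic family
#' @return Character vector of gene symbols.
#' @export
sim_actionable_genes <- function() {
  c("ABL1", "PKD1", "SCN1A", "DMD", "BRCA2", "KRT10", "CFTR", "GLA")
}

#' Write a simulated family to disk
#'
#' Emits the inputs the screening pipeline reads: a multi-sample VCF 4.2,
#' per-sample bedGraph depth tracks, pedigree / annotation / tandem-repeat /
#' dosage tables, gene lists, and the ground-truth ledger (variant origins,
#' dropout and CNV regions, per-condition expected statuses). Output is a
#' deterministic function of the family object.
#'
#' @param family [simulate_family()] output.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parents <- family$parents
  params <- family$params
  sites <- parents$sites

  site_tbl <- select(sites, "chrom", "pos", "ref", "alt", "key", "qd")
  extra_sites <- purrr::map_dfr(family$embryos, function(e) {
    bind_rows(
      mutate(select(e$meiosis$denovo, "chrom", "pos", "ref", "alt", "key"),
             qd = e$denovo_calls$qd),
      mutate(select(e$artifacts, "chrom", "pos", "ref", "alt", "key"),
             qd = round(e$artifact_calls$qd, 2))
    )
  }) |>
    distinct(.data$key, .keep_all = TRUE) |>
    filter(!.data$key %in% site_tbl$key)
  all_sites <- bind_rows(site_tbl, extra_sites) |>
    mutate(qd = round(.data$qd, 2))

  # parental filler at embryo-specific sites: confident homozygous reference
  filler <- function(who) {
    hemi <- who == "father" & extra_sites$chrom == "chrX"
    tibble(
      key = extra_sites$key, sample_id = who,
      gt = if_else(hemi, "0", "0|0"),
      ad_ref = as.integer(round(params$mean_depth_parent)), ad_alt = 0L,
      dp = as.integer(round(params$mean_depth_parent)), gq = 60
    )
  }
  embryo_long <- purrr::map_dfr(family$embryos, function(e) {
    bind_rows(e$calls,
              select(e$denovo_calls, -"qd"),
              select(e$artifact_calls, -"qd"))
  })
  long <- bind_rows(parents$calls, filler("father"), filler("mother"),
                    embryo_long) |>
    left_join(all_sites, by = "key") |>
    select("chrom", "pos", "ref", "alt", "key", "qd", "sample_id", "gt",
           "ad_ref", "ad_alt", "dp", "gq")
  samples <- c("father", "mother", names(family$embryos))
  write_trio_vcf(long, file.path(dir, "family.vcf"), samples = samples)

  readr::write_tsv(
    family$pedigree |>
      mutate(parents = if_else(is.na(.data$father_id), "",
                               paste0(.data$father_id, ",", .data$mother_id))) |>
      select(sample = "sample_id", "role", "sex", "parents"),
    file.path(dir, "pedigree.tsv")
  )
  readr::write_tsv(family$annotations, file.path(dir, "annotations.tsv"))
  tracks <- bind_rows(parents$tracks,
                      purrr::map_dfr(family$embryos, "track"))
  for (s in samples) {
    readr::write_tsv(
      tracks |>
        filter(.data$sample_id == s) |>
        select("chrom", "start", "end", "depth"),
      file.path(dir, paste0("depth_", s, ".bedGraph")), col_names = FALSE
    )
  }
  readr::write_tsv(family$str_genotypes, file.path(dir, "str_genotypes.tsv"))
  readr::write_tsv(sim_dosage_table(parents$gene_map),
                   file.path(dir, "dosage_synthetic.tsv"))
  writeLines(sim_actionable_genes(), file.path(dir, "actionable_genes.txt"))
  writeLines("BRCA2", file.path(dir, "incidental_genes.txt"))
  readr::write_tsv(family$truth$variants, file.path(dir, "truth_variants.tsv"))
  write_or_touch <- function(tbl, path) {
    if (!is.null(tbl) && ncol(tbl) > 0) readr::write_tsv(tbl, path)
    else writeLines(character(0), path)
  }
  write_or_touch(family$truth$regions, file.path(dir, "truth_regions.tsv"))
  write_or_touch(family$truth$conditions,
                 file.path(dir, "truth_conditions.tsv"))
  invisible(dir)
}

#' Read a simulated (or equivalently structured) family directory
#'
#' @param dir Directory written by [emit_family()].
#' @return A list of pipeline inputs: `variants`, `pedigree`, `annotations`,
#'   `tracks`, `str_genotypes`, `dosage_table`, `actionable_genes`,
#'   `incidental_genes`.
#' @export
read_family_dir <- function(dir) {
  pedigree <- read_pedigree(file.path(dir, "pedigree.tsv"))
  variants <- read_trio_vcf(file.path(dir, "family.vcf"), pedigree)
  annotations <- read_annotations(file.path(dir, "annotations.tsv"))
  tracks <- purrr::map_dfr(pedigree$sample_id, function(s) {
    read_bedgraph(file.path(dir, paste0("depth_", s, ".bedGraph")), s)
  })
  str_path <- file.path(dir, "str_genotypes.tsv")
  dosage_path <- file.path(dir, "dosage_synthetic.tsv")
  list(
    variants = variants, pedigree = pedigree, annotations = annotations,
    tracks = tracks,
    str_genotypes = if (file.exists(str_path)) {
      readr::read_tsv(str_path, col_types = "ccii")
    } else NULL,
    dosage_table = if (file.exists(dosage_path)) {
      readr::read_tsv(dosage_path, col_types = readr::cols())
    } else NULL,
    actionable_genes = read_gene_list(file.path(dir, "actionable_genes.txt")),
    incidental_genes = read_gene_list(file.path(dir, "incidental_genes.txt"))
  )
}

read_gene_list <- function(path) {
  if (!file.exists(path)) return(character(0))
  x <- readLines(path)
  x[nzchar(x)]
}
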