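#' Read a pedigree table
#'
#' Reads the 4-column pedigree TSV (`sample`, `role`, `sex`, `parents`) where
#' `parents` is `father_id,mother_id` for embryos and empty for parents, and
#' validates it: each embryo must reference exactly one father and one mother
#' present in the table, and the father/mother roles appear at most once.
#'
#' @param path TSV file path.
#' @return A tibble with columns `sample_id`, `role`, `sex`, `father_id`,
#'   `mother_id`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(ped) <- c("sample_id", "role", "sex", "parents")[seq_along(names(ped))]
  validate_pedigree(
    ped |>
      tidyr::separate(
        "parents",
        into = c("father_id", "mother_id"),
        sep = ",", fill = "right"
      ) |>
      mutate(across(c("father_id", "mother_id"), \(x) dplyr::na_if(x, "")))
  )
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("sample_id", "role", "sex") %in% names(ped)))
  if (!all(ped$role %in% c("father", "mother", "embryo"))) {
    stop("pedigree roles must be father/mother/embryo", call. = FALSE)
  }
  if (sum(ped$role == "father") > 1 || sum(ped$role == "mother") > 1) {
    stop("roles father/mother may appear at most once per family", call. = FALSE)
  }
  emb <- filter(ped, .data$role == "embryo")
  parents <- filter(ped, .data$role != "embryo")
  ok <- emb$father_id %in% parents$sample_id[parents$role == "father"] &
    emb$mother_id %in% parents$sample_id[parents$role == "mother"]
  if (nrow(emb) > 0 && !all(ok)) {
    stop("every embryo must reference the family's father and mother",
         call. = FALSE)
  }
  as_tibble(ped)
}

parent_ids <- function(pedigree, embryo_id) {
  row <- filter(pedigree, .data$sample_id == embryo_id, .data$role == "embryo")
  if (nrow(row) != 1) stop("embryo '", embryo_id, "' not in pedigree", call. = FALSE)
  list(father = row$father_id, mother = row$mother_id,
       sex = row$sex)
}

#' Read a multi-sample trio VCF into a long variant table
#'
#' Parses a VCF 4.2 file (FORMAT `GT:AD:DP:GQ`, INFO `QD`) into one row per
#' variant per pedigree sample. Multiallelic rows are decomposed into one
#' biallelic record per alternate allele with allele depths re-indexed
#' (original reference depth kept; other alternate alleles recoded as
#' reference in the genotype). Indel alleles are left-normalized by
#' prefix/suffix parsimony trimming so annotation joins are deterministic.
#' Records whose AD field cannot be parsed are skipped with a warning and
#' counted in the `skipped` attribute.
#'
#' @param vcf_path VCF file (plain text or gzipped).
#' @param pedigree Pedigree tibble from [read_pedigree()]; all its sample ids
#'   must appear in the VCF header.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`, `qd`,
#'   `sample_id`, `gt`, `ad_ref`, `ad_alt`, `dp`, `gq`. Missing genotypes are
#'   preserved as `"./."` / `NA` depths.
#' @export
read_trio_vcf <- function(vcf_path, pedigree) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(pedigree$sample_id, samples)
  if (length(missing) > 0) {
    stop("pedigree samples absent from VCF header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))

  keep_samples <- pedigree$sample_id
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- 0L

  # biallelic fast path (vectorized)
  bi <- which(!multi)
  bi_parts <- list()
  if (length(bi) > 0) {
    ad_bad <- rep(FALSE, length(bi))
    ad_split <- list()
    for (s in keep_samples) {
      m <- stringr::str_split_fixed(ad[bi, s], ",", 2)
      r <- suppressWarnings(as.integer(m[, 1]))
      a <- suppressWarnings(as.integer(m[, 2]))
      # "." fields are missing, not malformed
      present <- !is.na(ad[bi, s]) & !grepl("^[.,]*$", ad[bi, s])
      ad_bad <- ad_bad | (present & (is.na(r) | is.na(a)))
      ad_split[[s]] <- list(r = r, a = a)
    }
    n_skipped <- n_skipped + sum(ad_bad)
    keep <- bi[!ad_bad]
    if (length(keep) > 0) {
      norm <- normalize_alleles(as.integer(fix$POS[keep]), fix$REF[keep],
                                fix$ALT[keep])
      bi_parts <- lapply(keep_samples, function(s) {
        sl <- ad_split[[s]]
        tibble(
          chrom = fix$CHROM[keep], pos = norm$pos,
          ref = norm$ref, alt = norm$alt,
          qd = qd[keep], sample_id = s, gt = unname(gt[keep, s]),
          ad_ref = sl$r[!ad_bad], ad_alt = sl$a[!ad_bad],
          dp = as.integer(dp[keep, s]), gq = as.numeric(gq[keep, s])
        )
      })
    }
  }

  # multiallelic rows: decompose one record per alternate allele
  mu_parts <- list()
  for (i in which(multi)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- lapply(keep_samples, function(s) {
      suppressWarnings(as.integer(strsplit(ad[i, s] %||% NA_character_,
                                           ",", fixed = TRUE)[[1]]))
    })
    bad <- vapply(seq_along(keep_samples), function(j) {
      a <- ad_i[[j]]
      s_raw <- ad[i, keep_samples[j]]
      !is.na(s_raw) && !grepl("^[.,]*$", s_raw) &&
        (length(a) != length(alts) + 1L || anyNA(a))
    }, logical(1))
    if (any(bad)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (k in seq_along(alts)) {
      norm <- normalize_alleles(as.integer(fix$POS[i]), fix$REF[i], alts[k])
      for (j in seq_along(keep_samples)) {
        s <- keep_samples[j]
        a <- ad_i[[j]]
        mu_parts[[length(mu_parts) + 1L]] <- tibble(
          chrom = fix$CHROM[i], pos = norm$pos,
          ref = norm$ref, alt = norm$alt,
          qd = qd[i], sample_id = s, gt = recode_gt(gt[i, s], k),
          ad_ref = if (length(a)) a[1] else NA_integer_,
          ad_alt = if (length(a)) a[k + 1L] else NA_integer_,
          dp = as.integer(dp[i, s]), gq = as.numeric(gq[i, s])
        )
      }
    }
  }

  out <- bind_rows(c(bi_parts, mu_parts)) |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    select("chrom", "pos", "ref", "alt", "key", "qd", dplyr::everything()) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  if (n_skipped > 0) {
    warning(n_skipped, " VCF record(s) skipped (malformed AD)", call. = FALSE)
  }
  attr(out, "skipped") <- n_skipped
  out
}

# Recode a genotype string for the k-th alternate allele of a decomposed
# multiallelic row: allele index k -> 1, everything else -> 0; phase kept.
recode_gt <- function(g, k) {
  if (is.na(g)) return(NA_character_)
  sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
  parts <- strsplit(g, "[/|]")[[1]]
  parts <- vapply(parts, function(p) {
    if (p == ".") "." else if (as.integer(p) == k) "1" else "0"
  }, character(1))
  paste(parts, collapse = sep)
}

#' Write a long variant table as a multi-sample VCF
#'
#' Emits a plain-text VCF 4.2 with FORMAT `GT:AD:DP:GQ` and INFO `QD`,
#' covering exactly the fields the screening pipeline consumes.
#'
#' @param variants Long variant tibble as produced by [read_trio_vcf()].
#' @param path Output file.
#' @param samples Sample column order; defaults to order of appearance.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, path, samples = unique(variants$sample_id)) {
  wide <- variants |>
    mutate(
      fmt = paste(
        dplyr::coalesce(.data$gt, "./."),
        paste0(
          if_else(is.na(.data$ad_ref), ".", as.character(.data$ad_ref)), ",",
          if_else(is.na(.data$ad_alt), ".", as.character(.data$ad_alt))
        ),
        if_else(is.na(.data$dp), ".", as.character(.data$dp)),
        if_else(is.na(.data$gq), ".", as.character(.data$gq)),
        sep = ":"
      )
    ) |>
    select("chrom", "pos", "ref", "alt", "qd", "sample_id", "fmt") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "fmt") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS",
    if_else(is.na(wide$qd), ".", paste0("QD=", wide$qd)),
    "GT:AD:DP:GQ",
    sep = "\t"
  )
  for (s in samples) {
    body <- paste(body, dplyr::coalesce(wide[[s]], "./.:.,.:.:."), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Reads the tab-separated annotation table (declared header) keyed by
#' `chrom`, `pos`, `ref`, `alt`, carrying dbSNP membership, ClinVar class and
#' review stars, gene symbol, the six predictor verdicts, MPC and CADD.
#' Absent predictor columns are treated as missing verdicts. Unknown ClinVar
#' class strings map to `"unclassified"` with a warning; duplicate variant
#' keys and review stars outside 0–4 are fatal.
#'
#' @param tsv_path TSV file path.
#' @return Annotation tibble keyed by `key`.
#' @export
read_annotations <- function(tsv_path) {
  ann <- readr::read_tsv(tsv_path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c",
    in_dbsnp = "l", rsid = "c", clinvar_class = "c", review_stars = "i",
    gene = "c", mpc = "d", cadd_phred = "d", .default = "c"
  ))
  for (p in PREDICTORS) {
    if (!p %in% names(ann)) ann[[p]] <- NA_character_
    ann[[p]] <- dplyr::na_if(ann[[p]], "")
    bad_verdict <- !is.na(ann[[p]]) & !ann[[p]] %in% c("damaging", "tolerated")
    if (any(bad_verdict)) {
      warning("unrecognized ", p, " verdicts treated as missing", call. = FALSE)
      ann[[p]][bad_verdict] <- NA_character_
    }
  }
  ann <- mutate(ann, key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  dup <- ann$key[duplicated(ann$key)]
  if (length(dup) > 0) {
    stop("duplicate annotation keys: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ann$review_stars) | ann$review_stars < 0 | ann$review_stars > 4)) {
    stop("review_stars must be integers in [0, 4]", call. = FALSE)
  }
  unknown <- !ann$clinvar_class %in% CLINVAR_CLASSES
  if (any(unknown)) {
    warning(sum(unknown), " unknown clinvar_class value(s) set to 'unclassified'",
            call. = FALSE)
    ann$clinvar_class[unknown] <- "unclassified"
  }
  select(ann, "key", "chrom", "pos", "ref", "alt", "in_dbsnp", "rsid",
         "clinvar_class", "review_stars", "gene",
         dplyr::all_of(PREDICTORS), "mpc", "cadd_phred")
}

#' Lay out a long variant table as one row per site for one trio
#'
#' Joins the father/mother/embryo calls of one embryo's trio side by side
#' (suffixes `_f`, `_m`, `_e`) for inheritance-mode filtering.
#'
#' @param variants Long variant tibble from [read_trio_vcf()].
#' @param pedigree Pedigree tibble.
#' @param embryo_id Embryo sample id.
#' @return Wide trio tibble keyed by `key`.
#' @export
trio_layout <- function(variants, pedigree, embryo_id) {
  ids <- parent_ids(pedigree, embryo_id)
  site <- variants |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$key, .data$qd)
  pick <- function(id, suffix) {
    variants |>
      filter(.data$sample_id == id) |>
      select("key", "gt", "ad_ref", "ad_alt", "dp", "gq") |>
      rename_with(\(x) paste0(x, suffix), -"key")
  }
  site |>
    left_join(pick(ids$father, "_f"), by = "key") |>
    left_join(pick(ids$mother, "_m"), by = "key") |>
    left_join(pick(embryo_id, "_e"), by = "key") |>
    mutate(embryo_id = embryo_id) |>
    arrange(.data$chrom, .data$pos)
}

#' @importFrom dplyr rename_with
NULL

#' Compare two genotype call sets
#'
#' Computes genotype concordance between two call sets over their shared
#' variant keys, optionally restricted to sites heterozygous in set A (the
#' comparison used to validate sequencing calls against SNP-array
#' genotypes). Genotypes are compared as unordered allele sets.
#'
#' @param set_a,set_b Tibbles with columns `key` and `gt`.
#' @param site_subset `"het_in_a"` (default) restricts to keys heterozygous in
#'   `set_a`; `"all"` uses every shared key.
#' @return A `concordance_summary` list: `sites_compared`, `genotype_matches`,
#'   `concordance`, `mismatches` (tibble of discordant keys).
#' @export
compare_callsets <- function(set_a, set_b, site_subset = c("het_in_a", "all")) {
  site_subset <- match.arg(site_subset)
  a <- distinct(set_a, .data$key, .keep_all = TRUE)
  if (site_subset == "het_in_a") a <- filter(a, gt_is_het(.data$gt))
  j <- inner_join(
    select(a, "key", gt_a = "gt"),
    select(distinct(set_b, .data$key, .keep_all = TRUE), "key", gt_b = "gt"),
    by = "key"
  )
  if (nrow(j) == 0) stop("no shared sites to compare", call. = FALSE)
  norm <- function(g) {
    vapply(strsplit(g, "[/|]"), function(x) paste(sort(x), collapse = "/"),
           character(1))
  }
  j <- mutate(j, match = norm(.data$gt_a) == norm(.data$gt_b))
  structure(
    list(
      sites_compared = nrow(j),
      genotype_matches = sum(j$match),
      concordance = sum(j$match) / nrow(j),
      mismatches = filter(j, !.data$match)
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "Call-set concordance: %d/%d sites (%.2f%%), %d mismatches\n",
    x$genotype_matches, x$sites_compared, 100 * x$concordance,
    nrow(x$mismatches)
  ))
  invisible(x)
}
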