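test_that("transmission classification matches brute force over all 27 trios", {
  gts <- c("0/0", "0/1", "1/1")
  grid <- expand.grid(f = gts, m = gts, e = gts, stringsAsFactors = FALSE)
  x <- purrr::pmap_dfr(grid, function(f, m, e) {
    trio_row(pos = nrow(grid), gt_f = f, gt_m = m, gt_e = e)
  }) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    classify_transmission()
  # independent oracle: count alt alleles directly from the strings
  alt_of <- function(g) sum(strsplit(g, "/")[[1]] == "1")
  oracle <- purrr::pmap_chr(grid, function(f, m, e) {
    ea <- alt_of(e); fa <- alt_of(f); ma <- alt_of(m)
    if (ea == 0) "none"
    else if (fa > 0 && ma == 0) "paternal"
    else if (ma > 0 && fa == 0) "maternal"
    else if (fa > 0 && ma > 0) "ambiguous"
    else "de_novo"
  })
  expect_equal(x$origin, oracle)
  # missing genotypes
  expect_true(is.na(classify_transmission(trio_row(gt_e = "./."))$origin))
  expect_equal(classify_transmission(trio_row(gt_f = "./.", gt_e = "0/1"))$origin,
               "ambiguous")
})

test_that("dominant filter gates on depth, quality, transmission and grade", {
  x <- trio_rows(
    trio_row(pos = 1, gt_f = "0/1", gt_e = "0/1", dp_e = 30L),        # keep
    trio_row(pos = 2, gt_f = "0/1", gt_e = "0/1", dp_e = 8L),         # depth
    trio_row(pos = 3, gt_f = "0/1", gt_e = "0/1", grade = "benign_like"),
    trio_row(pos = 4, gt_e = "0/1"),                                  # de novo
    trio_row(pos = 5, gt_f = "0/1", gt_e = "0/1", gq_e = 10)          # GQ
  )
  out <- filter_dominant(x)
  expect_equal(out$pos, 1L)
  expect_equal(out$mode, "dominant_het")
  expect_equal(out$subfilter, "dbsnp")
  all_rows <- filter_dominant(x, keep_all = TRUE)
  expect_match(dplyr::filter(all_rows, pos == 2)$filter_trail, "depth=fail")
  # boundary: exactly 10 reads passes the >10x threshold reading
  expect_equal(nrow(filter_dominant(trio_row(gt_f = "0/1", gt_e = "0/1",
                                             dp_e = 10L))), 1)
})

test_that("recessive filter separates affected, carriers and dropout suspects", {
  x <- trio_rows(
    trio_row(pos = 1, gt_f = "0/1", gt_m = "0/1", gt_e = "1/1"),
    trio_row(pos = 2, gt_f = "0/1", gt_m = "0/0", gt_e = "1/1", dp_m = 40L),
    trio_row(pos = 3, gt_f = "0/1", gt_m = "0/1", gt_e = "0/1")
  )
  out <- filter_recessive(x)
  expect_equal(dplyr::filter(out, pos == 1)$finding, "affected")
  expect_equal(dplyr::filter(out, pos == 2)$finding, "dropout_suspect")
  expect_equal(dplyr::filter(out, pos == 3)$finding, "carrier")
})

test_that("X-linked filter is sex-aware and never emits autosomes", {
  xv <- trio_rows(
    trio_row(pos = 1, chrom = "chrX", gt_f = "0", gt_m = "0|1", gt_e = "1"),
    trio_row(pos = 2, chrom = "chrX", gt_f = "0", gt_m = "0|1", gt_e = "0/1"),
    trio_row(pos = 3, chrom = "chr2", gt_f = "0/1", gt_e = "0/1")
  )
  male <- filter_xlinked(xv, "male")
  expect_equal(dplyr::filter(male, pos == 1)$finding, "affected")
  expect_false(any(male$chrom != "chrX"))
  fem <- filter_xlinked(xv, "female")
  expect_equal(dplyr::filter(fem, pos == 2)$finding, "carrier")
  unk <- filter_xlinked(xv, "unknown")
  expect_true(all(unk$finding == "curation"))
})

test_that("embryo sex is inferred from X heterozygosity when needed", {
  male_x <- purrr::map_dfr(1:250, function(i) {
    trio_row(pos = i, chrom = "chrX", gt_f = "0", gt_m = "0|1", gt_e = "1")
  })
  expect_equal(infer_embryo_sex(male_x), "male")
  fem_x <- dplyr::mutate(male_x, gt_e = "0/1")
  expect_equal(infer_embryo_sex(fem_x), "female")
  expect_equal(infer_embryo_sex(male_x[1:50, ]), "unknown")
})

test_that("failsafe keeps low-quality actionable hits the strict filters drop", {
  x <- trio_rows(
    trio_row(pos = 1, gt_e = "0/1", dp_e = 2L, gq_e = 3, gene = "ABL1",
             grade = "pathogenic"),
    trio_row(pos = 2, gt_e = "0/1", dp_e = 1L, gene = "ABL1"),   # depth > 1
    trio_row(pos = 3, gt_e = "0/1", dp_e = 50L, gene = "OTHER")
  )
  out <- filter_failsafe(x, actionable_genes = "ABL1")
  expect_equal(out$pos, 1L)
  expect_equal(nrow(filter_dominant(x[1, ])), 0)  # strict filter rejects it
})

test_that("failsafe output is a superset of strict filters on actionable genes", {
  screen <- test_screen_tbl()
  actionable <- test_inputs()$actionable_genes
  fs <- filter_failsafe(screen, actionable)
  strict <- dplyr::bind_rows(
    filter_dominant(screen),
    dplyr::filter(filter_recessive(screen), finding != "dropout_suspect"),
    filter_xlinked(screen, "male"),
    filter_denovo(screen)
  ) |>
    dplyr::filter(!is.na(gene), gene %in% actionable)
  expect_true(all(strict$key %in% fs$key))
  # every strict filter's set respects the depth floor
  expect_true(all(strict$dp_e >= 10))
})

test_that("compound het pairing equals exhaustive enumeration on a random table", {
  withr::with_seed(41, {
    n <- 50
    hits <- purrr::map_dfr(1:n, function(i) {
      trio_row(
        pos = i * 10, gene = sample(paste0("G", 1:8), 1),
        gt_f = sample(c("0/1", "0/0"), 1), gt_m = sample(c("0/1", "0/0"), 1),
        gt_e = "0/1"
      )
    })
  })
  hits <- dplyr::filter(hits, origin != "none")
  out <- filter_compound_het(hits)
  # brute-force all unordered pairs
  oracle <- list()
  for (i in seq_len(nrow(hits) - 1)) {
    for (j in (i + 1):nrow(hits)) {
      if (is.na(hits$gene[i]) || hits$gene[i] != hits$gene[j]) next
      oi <- hits$origin[i]; oj <- hits$origin[j]
      amb <- oi == "ambiguous" | oj == "ambiguous"
      valid <- (!amb && oi != oj &&
                  all(c(oi, oj) %in% c("paternal", "maternal", "de_novo")))
      if (valid || amb) {
        oracle[[length(oracle) + 1]] <-
          paste(sort(c(hits$key[i], hits$key[j])), collapse = "+")
      }
    }
  }
  got <- apply(out[, c("key_a", "key_b")], 1, function(r) {
    paste(sort(r), collapse = "+")
  })
  expect_setequal(got, unlist(oracle))
  # a paternal + maternal pair auto-calls; two same-origin hets never pair
  two <- trio_rows(
    trio_row(pos = 1, gene = "G", gt_f = "0/1", gt_e = "0/1"),
    trio_row(pos = 2, gene = "G", gt_m = "0/1", gt_e = "0/1")
  )
  p <- filter_compound_het(two)
  expect_equal(nrow(p), 1)
  expect_false(p$curation)
  same <- trio_rows(
    trio_row(pos = 1, gene = "G", gt_f = "0/1", gt_e = "0/1"),
    trio_row(pos = 2, gene = "G", gt_f = "0/1", gt_e = "0/1")
  )
  expect_equal(nrow(filter_compound_het(same)), 0)
})

test_that("every alt-bearing embryo record lands in exactly one accounting bucket", {
  screen <- test_screen_tbl()
  inh <- screen_inheritance(screen, test_inputs()$actionable_genes, "male")
  alt_keys <- screen$key[has_embryo_alt(screen)]
  buckets <- c(
    inh$dominant$key, inh$recessive$key, inh$carriers$key,
    inh$dropout_suspects$key, inh$xlinked$key, inh$curation$key,
    inh$denovo$retained$key, inh$denovo$rejected$key, inh$failsafe$key,
    inh$rejected$key
  )
  expect_true(all(alt_keys %in% buckets))
  # survivor counts are monotone non-increasing along each chain
  mono <- inh$survivor_counts |>
    dplyr::group_by(mode) |>
    dplyr::summarise(ok = all(diff(remaining) <= 0))
  expect_true(all(mono$ok))
})

test_that("with no artifacts or dropout, de novo origin equals planted truth", {
  withr::with_seed(202, {
    p <- sim_params(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                    artifact_het_rate = 0, dropout_rate = 0,
                    scale_denovo = FALSE, denovo_rate = 20,
                    planted_variants = NULL, planted_cnvs = NULL,
                    n_embryos = 1)
    fam <- simulate_family(p)
  })
  d <- tempfile()
  emit_family(fam, d)
  inp <- read_family_dir(d)
  graded <- grade_variants(inp$annotations)
  screen <- prepare_screen(inp$variants, inp$pedigree, graded, "embryo1")
  called_dn <- screen$key[!is.na(screen$origin) & screen$origin == "de_novo" &
                            has_embryo_alt(screen)]
  truth_dn <- dplyr::filter(fam$truth$variants, origin == "de_novo")$key
  expect_setequal(called_dn, truth_dn)
  unlink(d, recursive = TRUE)
})
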