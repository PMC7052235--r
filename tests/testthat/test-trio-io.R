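make_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "dad", "mum", "kid", sep = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

tiny_pedigree <- tibble::tibble(
  sample_id = c("dad", "mum", "kid"),
  role = c("father", "mother", "embryo"),
  sex = c("male", "female", "female"),
  father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum")
)

test_that("multiallelic rows decompose with re-indexed allele depths", {
  p <- make_vcf(paste(
    "chr1", 100, ".", "A", "C,T", ".", "PASS", "QD=30", "GT:AD:DP:GQ",
    "1/2:10,5,6:21:99", "0/1:12,8,0:20:80", "0/2:9,0,7:16:70", sep = "\t"
  ))
  v <- read_trio_vcf(p, tiny_pedigree)
  expect_equal(nrow(v), 6)   # 2 records x 3 samples
  dad_c <- dplyr::filter(v, sample_id == "dad", alt == "C")
  dad_t <- dplyr::filter(v, sample_id == "dad", alt == "T")
  expect_equal(c(dad_c$ad_ref, dad_c$ad_alt), c(10L, 5L))
  expect_equal(c(dad_t$ad_ref, dad_t$ad_alt), c(10L, 6L))
  expect_equal(dad_c$gt, "1/0")  # the other alt recodes to reference
  expect_equal(dad_t$gt, "0/1")
  # decomposition preserves total alternate evidence per source row
  expect_equal(
    sum(v$ad_alt[v$sample_id == "dad"]), 5 + 6
  )
})

test_that("missing genotypes are preserved, not dropped", {
  p <- make_vcf(paste(
    "chr1", 200, ".", "G", "A", ".", "PASS", "QD=15", "GT:AD:DP:GQ",
    "0/1:10,10:20:99", "0/0:22,0:22:60", "./.:.,.:.:.", sep = "\t"
  ))
  v <- read_trio_vcf(p, tiny_pedigree)
  kid <- dplyr::filter(v, sample_id == "kid")
  expect_equal(nrow(kid), 1)
  expect_true(gt_is_missing(kid$gt))
})

test_that("indel alleles are parsimony-normalized on read", {
  p <- make_vcf(paste(
    "chr1", 300, ".", "CAGAG", "CAG", ".", "PASS", "QD=18", "GT:AD:DP:GQ",
    "0/1:10,10:20:99", "0/0:20,0:20:60", "0/1:9,9:18:80", sep = "\t"
  ))
  v <- read_trio_vcf(p, tiny_pedigree)
  # CAGAG>CAG: suffix 'AG' trims, then prefix 'C' shifts pos
  expect_equal(unique(v$ref), "CAG")
  expect_equal(unique(v$alt), "C")
  expect_equal(unique(v$pos), 300L)
})

test_that("a pedigree sample missing from the header is fatal", {
  p <- make_vcf(character(0))
  bad_ped <- dplyr::mutate(tiny_pedigree,
                           sample_id = c("dad", "mum", "other_kid"))
  expect_error(read_trio_vcf(p, bad_ped), "absent from VCF header")
})

test_that("a 1,000-record table round-trips through the writer losslessly", {
  withr::with_seed(5, {
    n <- 1000
    pos <- sort(sample.int(1e6, n))
    qd <- round(runif(n, 1, 40), 2)   # QD is a site-level field
    long <- purrr::map_dfr(c("dad", "mum", "kid"), function(s) {
      dp <- sample(10:60, n, replace = TRUE)
      ad_alt <- as.integer(round(dp * sample(c(0, 0.5, 1), n, replace = TRUE)))
      tibble::tibble(
        chrom = "chr1", pos = pos, ref = "A", alt = "G",
        key = variant_key("chr1", pos, "A", "G"),
        qd = qd, sample_id = s,
        gt = dplyr::case_when(ad_alt == 0L ~ "0/0",
                              ad_alt == dp ~ "1/1", TRUE ~ "0/1"),
        ad_ref = as.integer(dp - ad_alt), ad_alt = ad_alt,
        dp = as.integer(dp), gq = as.numeric(sample(20:99, n, replace = TRUE))
      )
    })
  })
  path <- tempfile(fileext = ".vcf")
  write_trio_vcf(long, path, samples = c("dad", "mum", "kid"))
  back <- read_trio_vcf(path, tiny_pedigree)
  sort_cols <- function(x) dplyr::arrange(x, key, sample_id)
  expect_equal(
    sort_cols(back)[names(long)] |> as.data.frame(),
    sort_cols(long) |> as.data.frame(),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("annotation reading enforces stars, keys and predictor columns", {
  ann <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
    in_dbsnp = TRUE, rsid = c("rs1", "rs2"),
    clinvar_class = c("pathogenic", "weirdo"), review_stars = c(3L, 1L),
    gene = c("G1", "G2"), mpc = c(2.5, NA), cadd_phred = c(36, NA)
  )
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(ann, p)
  expect_warning(out <- read_annotations(p), "unknown clinvar_class")
  expect_equal(out$review_stars[1], 3L)
  expect_equal(out$clinvar_class[2], "unclassified")
  # absent predictor columns become missing verdicts
  expect_true(all(is.na(out$sift)))

  dup <- dplyr::bind_rows(ann, ann[1, ])
  readr::write_tsv(dup, p)
  expect_error(read_annotations(p), "chr1:10:A:T")

  bad <- dplyr::mutate(ann, review_stars = c(5L, 1L))
  readr::write_tsv(bad, p)
  expect_error(read_annotations(p), "review_stars")
})

test_that("call-set concordance matches identity, counting and planted-flip cases", {
  a <- tibble::tibble(key = paste0("k", 1:100), gt = "0/1")
  expect_equal(compare_callsets(a, a)$concordance, 1.0)

  b <- a
  b$gt[1] <- "1/1"
  s <- compare_callsets(a, b)
  expect_equal(s$concordance, 0.99)
  expect_equal(s$mismatches$key, "k1")

  # phase / allele order must not count as mismatch
  expect_equal(compare_callsets(
    tibble::tibble(key = "k", gt = "0/1"),
    tibble::tibble(key = "k", gt = "1|0")
  )$concordance, 1.0)

  # planted 0.5% flips on 10,000 sites recover ~0.995
  withr::with_seed(99, {
    big <- tibble::tibble(key = paste0("s", 1:10000), gt = "0/1")
    flipped <- big
    idx <- sample.int(10000, 50)
    flipped$gt[idx] <- "1/1"
  })
  s2 <- compare_callsets(big, flipped)
  expect_equal(s2$concordance, 0.995, tolerance = 0.002)

  expect_error(compare_callsets(
    tibble::tibble(key = "a", gt = "0/1"),
    tibble::tibble(key = "b", gt = "0/1")
  ), "no shared sites")
})
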