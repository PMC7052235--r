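# Deterministic depth tracks: per-1kb intervals at given means.
flat_track <- function(sample_id, depth, len = 2e6, chroms = c("chr1", "chr2"),
                       bin = 1000) {
  purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0, len - bin, by = bin)
    tibble::tibble(sample_id = sample_id, chrom = ch, start = starts,
                   end = starts + bin, depth = depth)
  })
}

scale_region <- function(track, chrom, from, to, factor) {
  dplyr::mutate(track, depth = ifelse(
    chrom == .env$chrom & start >= from & start < to,
    depth * factor, depth
  ))
}

test_that("binning averages with bp weights and normalizes by autosomal median", {
  tr <- tibble::tibble(
    sample_id = "s", chrom = "chr1",
    start = c(0, 5000, 12000), end = c(5000, 12000, 20000),
    depth = c(10, 20, 40)
  )
  b <- bin_depths(tr, 1e4)
  # bin 1: 5kb@10 + 5kb@20 = 15; bin 2: 8kb@40 + 2kb@20 -> (2*20+8*40)/10 = 36
  expect_equal(b$depth, c(15, 36))
  expect_equal(b$norm_depth, b$depth / median(b$depth))
})

test_that("uniform coverage scores to ratio 1 and z near 0; copy arithmetic holds", {
  withr::with_seed(3, {
    tracks <- dplyr::bind_rows(
      flat_track("f", 46) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)),
      flat_track("m", 46) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)),
      flat_track("e", 48) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)) |>
        scale_region("chr1", 1.0e6, 1.2e6, 1.5) |>   # 3 copies: ratio 1.5
        scale_region("chr2", 0.5e6, 0.7e6, 0)        # homozygous deletion
    )
  })
  bins <- bin_depths(tracks, 1e4)
  sc <- score_bins(bins, "e", c("f", "m"))
  normal <- dplyr::filter(sc, chrom == "chr1", start < 1e6)
  expect_equal(mean(normal$ratio), 1, tolerance = 0.05)
  expect_lt(mean(abs(normal$z)), 2)
  three_copy <- dplyr::filter(sc, chrom == "chr1", start >= 1e6, start < 1.2e6)
  expect_equal(mean(three_copy$ratio), 1.5, tolerance = 0.1)
  # 1.5 is below the duplication threshold: not called
  calls <- call_cnvs(sc)
  expect_false(any(calls$chrom == "chr1" & calls$state == "duplication" &
                     calls$start < 1.2e6 & calls$end > 1.0e6))
  # the homozygous deletion is called despite zero embryo depth
  del <- dplyr::filter(calls, chrom == "chr2", state == "deletion")
  expect_equal(nrow(del), 1)
  expect_equal(del$start, 0.5e6)
  expect_equal(del$end, 0.7e6)
  expect_equal(del$mean_ratio, 0)
})

test_that("calls never include flagged bins and merge maximal clean runs", {
  withr::with_seed(4, {
    tracks <- dplyr::bind_rows(
      flat_track("f", 46) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)),
      flat_track("m", 46) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)),
      flat_track("e", 48) |> dplyr::mutate(depth = depth + rnorm(dplyr::n(), 0, 2)) |>
        scale_region("chr1", 1.0e6, 1.12e6, 2.5)     # 12 bins, copy 5
    )
  })
  sc <- score_bins(bin_depths(tracks, 1e4), "e", c("f", "m"))
  calls <- call_cnvs(sc)
  dup <- dplyr::filter(calls, state == "duplication")
  expect_equal(nrow(dup), 1)
  expect_equal(dup$n_bins, 12L)
  expect_equal(c(dup$start, dup$end), c(1.0e6, 1.12e6))
  # no call may overlap a flagged bin
  flagged <- dplyr::filter(sc, qc_flags != "")
  for (i in seq_len(nrow(calls))) {
    expect_false(any(flagged$chrom == calls$chrom[i] &
                       flagged$start < calls$end[i] &
                       flagged$end > calls$start[i]))
  }
  # a degraded control region flags instead of calling
  tracks2 <- dplyr::bind_rows(
    flat_track("f", 46) |> scale_region("chr2", 1e6, 1.2e6, 0.05),
    flat_track("m", 46),
    flat_track("e", 48)
  )
  sc2 <- score_bins(bin_depths(tracks2, 1e4), "e", c("f", "m"))
  reg <- dplyr::filter(sc2, chrom == "chr2", start >= 1e6, start < 1.2e6)
  expect_true(all(grepl("high_control_variation", reg$qc_flags)))
})

test_that("planted CNVs are recovered 6/6 with no false call of 100 kb or more", {
  cnvs <- tibble::tribble(
    ~sample, ~chrom, ~start, ~end, ~copy,
    "embryo1", "chr1", 1.0e6, 1.15e6, 0,
    "embryo1", "chr1", 5.0e6, 5.2e6, 5,
    "embryo1", "chr2", 2.0e6, 2.4e6, 0,
    "embryo1", "chr2", 7.0e6, 7.1e6, 6,
    "embryo1", "chr3", 3.0e6, 3.25e6, 5,
    "embryo1", "chr4", 8.0e6, 8.5e6, 0
  )
  withr::with_seed(55, {
    p <- sim_params(planted_cnvs = cnvs, planted_variants = NULL,
                    n_embryos = 1)
    parents <- simulate_parents(p)
    emb <- simulate_embryo(parents, p, "embryo1", "female")
    mda <- simulate_mda(emb, parents, p)
  })
  tracks <- dplyr::bind_rows(parents$tracks, mda$track)
  sc <- score_bins(bin_depths(tracks, 1e4), "embryo1", c("father", "mother"),
                   "female", c("male", "female"))
  calls <- call_cnvs(sc)
  overlaps <- function(a, b) {
    a$chrom == b$chrom & a$start < b$end & a$end > b$start
  }
  recalled <- vapply(seq_len(nrow(cnvs)), function(i) {
    any(vapply(seq_len(nrow(calls)), function(j) {
      overlaps(calls[j, ], cnvs[i, ]) &&
        calls$state[j] == ifelse(cnvs$copy[i] > 2, "duplication", "deletion")
    }, logical(1)))
  }, logical(1))
  expect_true(all(recalled))
  # no false positive of >= 100 kb
  big <- dplyr::filter(calls, end - start >= 1e5)
  false_big <- vapply(seq_len(nrow(big)), function(j) {
    !any(vapply(seq_len(nrow(cnvs)), function(i) {
      overlaps(big[j, ], cnvs[i, ])
    }, logical(1)))
  }, logical(1))
  expect_equal(sum(false_big), 0)
})

test_that("artifact-free call boundaries match planted CNVs within one bin", {
  cnvs <- tibble::tibble(sample = "embryo1", chrom = "chr2",
                         start = 4.0e6, end = 4.3e6, copy = 5)
  withr::with_seed(66, {
    p <- sim_params(planted_cnvs = cnvs, planted_variants = NULL,
                    n_embryos = 1, wave_sd = 0, depth_size_embryo = 1e4,
                    depth_size_parent = 1e4)
    parents <- simulate_parents(p)
    mda <- simulate_mda(simulate_embryo(parents, p, "embryo1", "female"),
                        parents, p)
  })
  sc <- score_bins(bin_depths(dplyr::bind_rows(parents$tracks, mda$track), 1e4),
                   "embryo1", c("father", "mother"), "female",
                   c("male", "female"))
  dup <- dplyr::filter(call_cnvs(sc), state == "duplication")
  expect_equal(nrow(dup), 1)
  expect_lte(abs(dup$start - 4.0e6), 1e4)
  expect_lte(abs(dup$end - 4.3e6), 1e4)
})

dosage_fixture <- tibble::tibble(
  gene = c("HI1", "TS1", "AR1"),
  chrom = "chr1",
  start = c(1e6, 5e6, 8e6), end = c(1.2e6, 5.2e6, 8.2e6),
  haploinsufficiency = c("sufficient_evidence", "none",
                         "autosomal_recessive_gene"),
  triplosensitivity = c("none", "sufficient_evidence", "none")
)

cnv_call <- function(chrom = "chr1", start = 1e6, end = 1.1e6,
                     state = "deletion") {
  tibble::tibble(sample_id = "e", chrom = chrom, start = start, end = end,
                 state = state, n_bins = 10L, mean_ratio = 0.1, mean_z = -5,
                 mean_depth = 40, mean_ctl_depth = 46)
}

test_that("dosage assignment routes report / recessive-check / none", {
  calls <- dplyr::bind_rows(
    cnv_call(start = 1.0e6, end = 1.1e6, state = "deletion"),
    cnv_call(start = 5.0e6, end = 5.1e6, state = "duplication"),
    cnv_call(start = 8.0e6, end = 8.1e6, state = "deletion"),
    cnv_call(start = 3.0e6, end = 3.1e6, state = "duplication")
  )
  out <- assign_dosage(calls, dosage_fixture)
  expect_equal(out$route, c("report", "report", "recessive_check", "none"))
  expect_equal(out$dosage_category[1:2],
               c("haploinsufficiency", "triplosensitivity"))
  expect_error(assign_dosage(calls, dplyr::mutate(dosage_fixture,
                                                  haploinsufficiency = "yes")),
               "malformed dosage table")
})

test_that("trio CNV inheritance labels by reciprocal same-state overlap", {
  emb <- dplyr::bind_rows(
    cnv_call(start = 1e6, end = 1.2e6, state = "deletion"),
    cnv_call(start = 5e6, end = 5.2e6, state = "duplication"),
    cnv_call(start = 8e6, end = 8.2e6, state = "deletion")
  )
  f <- cnv_call(start = 1.02e6, end = 1.2e6, state = "deletion")
  m <- cnv_call(start = 8e6, end = 8.2e6, state = "duplication")  # state differs
  out <- trio_cnv_inheritance(emb, f, m)
  expect_equal(out$inheritance, c("paternal", "de_novo", "de_novo"))
  # labels match truth exactly on a constructed inherited + de novo set
  both <- trio_cnv_inheritance(emb, f, dplyr::mutate(f, start = 1.0e6))
  expect_equal(both$inheritance[1], "ambiguous")
})

test_that("recessive CNV x SNV cross-check equals exhaustive pairing", {
  withr::with_seed(88, {
    genes <- paste0("G", 1:20)
    cnvs <- purrr::map_dfr(1:15, function(i) {
      g <- sample(genes, 1)
      cnv_call() |>
        dplyr::mutate(gene = g, route = sample(c("recessive_check", "none"), 1),
                      state = sample(c("deletion", "duplication"), 1),
                      inheritance = sample(c("paternal", "maternal",
                                             "de_novo"), 1))
    })
    snvs <- purrr::map_dfr(1:25, function(i) {
      tibble::tibble(key = paste0("k", i), gene = sample(genes, 1),
                     origin = sample(c("paternal", "maternal", "ambiguous"), 1),
                     grade = sample(c("pathogenic", "vus"), 1))
    })
  })
  out <- crosscheck_recessive(cnvs, snvs)
  oracle <- 0L
  for (i in seq_len(nrow(cnvs))) for (j in seq_len(nrow(snvs))) {
    if (cnvs$gene[i] == snvs$gene[j] &&
        (cnvs$state[i] == "deletion" || cnvs$route[i] == "recessive_check") &&
        cnvs$inheritance[i] %in% c("paternal", "maternal") &&
        snvs$origin[j] %in% c("paternal", "maternal") &&
        snvs$grade[j] %in% c("pathogenic", "likely_pathogenic",
                             "predicted_pathogenic") &&
        cnvs$inheritance[i] != snvs$origin[j]) {
      oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(out), oracle)
  # same-parent pairs never pair
  one <- crosscheck_recessive(
    dplyr::mutate(cnv_call(), gene = "G", route = "recessive_check",
                  inheritance = "paternal"),
    tibble::tibble(key = "k", gene = "G", origin = "paternal",
                   grade = "pathogenic")
  )
  expect_equal(nrow(one), 0)
})

test_that("external SV ingestion types map onto dosage logic", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000000\t1100000\tDEL",
               "chr1\t5000000\t5100000\tINV",
               "chr2\t1000\t2000\tCTX",
               "chr3\t1000\t2000\tweird"), p)
  sv <- ingest_sv_calls(p, "external")
  expect_equal(sv$state, c("deletion", "other", "other", "other"))
  expect_equal(sv$type[4], "OTHER")
  ann <- assign_dosage(sv, dosage_fixture)
  expect_equal(ann$route[1], "report")       # DEL over HI gene
  expect_true(all(ann$route[-1] == "none"))  # INV/CTX excluded from dosage
})
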