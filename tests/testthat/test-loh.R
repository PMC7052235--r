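loh_sites <- function(pos, is_loh, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 key = variant_key(chrom, pos, "A", "T"), is_loh = is_loh)
}

test_that("segment emission thresholds are strict at >100 sites and 95%", {
  # exactly 100 consecutive LoH sites: not emitted
  s100 <- loh_sites(1:100 * 1000, rep(TRUE, 100))
  expect_equal(nrow(detect_loh_segments(s100)), 0)
  # 101 sites: emitted
  s101 <- loh_sites(1:101 * 1000, rep(TRUE, 101))
  seg <- detect_loh_segments(s101, "e1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_sites, 101L)
  expect_equal(seg$loh_fraction, 1)
  # a fully heterozygous chromosome yields nothing
  expect_equal(nrow(detect_loh_segments(loh_sites(1:500, rep(FALSE, 500)))), 0)
})

test_that("segments tolerate isolated failures while fraction holds", {
  is_loh <- rep(TRUE, 200)
  is_loh[c(50, 120)] <- FALSE     # 198/200 = 0.99
  seg <- detect_loh_segments(loh_sites(1:200 * 500, is_loh))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_loh, 198L)
  expect_equal(seg$n_sites, 200L)
  # too many failures break the run into sub-threshold pieces
  is_loh2 <- rep(c(TRUE, FALSE), 100)
  expect_equal(nrow(detect_loh_segments(loh_sites(1:200 * 500, is_loh2))), 0)
})

test_that("a planted dropout region is recovered as one embryo-only segment", {
  fam <- test_family()
  e1 <- fam$embryos$embryo1
  skip_if(nrow(e1$dropout_regions) == 0, "no dropout drawn for this seed")
  screen <- test_screen_tbl()
  segs <- detect_loh_segments(embryo_loh_sites(screen), "embryo1")
  labelled <- trio_call_loh(
    segs,
    detect_loh_segments(parent_loh_sites(test_inputs()$variants, "father"),
                        "father"),
    detect_loh_segments(parent_loh_sites(test_inputs()$variants, "mother"),
                        "mother")
  )
  emb_only <- dplyr::filter(labelled, label == "embryo_only")
  for (i in seq_len(nrow(e1$dropout_regions))) {
    d <- e1$dropout_regions[i, ]
    hit <- dplyr::filter(emb_only, chrom == d$chrom,
                         end > d$start, start < d$end)
    expect_gte(nrow(hit), 1)
    covered <- sum(pmin(hit$end, d$end) - pmax(hit$start, d$start))
    expect_gte(covered / (d$end - d$start), 0.9)
  }
})

test_that("trio LoH labelling follows reciprocal overlap", {
  e <- tibble::tibble(chrom = "chr1", start = c(0, 5e6), end = c(1e6, 6e6),
                      n_sites = 500L, n_loh = 500L, loh_fraction = 1,
                      sample_id = "e")
  f <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, n_sites = 500L,
                      n_loh = 500L, loh_fraction = 1, sample_id = "f")
  m <- f[0, ]
  out <- trio_call_loh(e, f, m)
  expect_equal(out$label, c("shared_parental", "embryo_only"))
})

test_that("expected-but-missing ledger assigns reasons and conserves variants", {
  x <- trio_rows(
    trio_row(pos = 1, gt_f = "0|1", gt_e = "0/1", dp_e = 30L),   # called
    trio_row(pos = 2, gt_f = "0|1", gt_e = "0/1", dp_e = 4L),    # low cov
    trio_row(pos = 3, gt_m = "0|1", gt_e = "./.", dp_e = NA)     # uncalled
  )
  led <- ledger_expected_missing(x, NULL, depth_min = 10)
  expect_setequal(led$pos, c(2L, 3L))
  expect_equal(dplyr::filter(led, pos == 2)$reason, "low_coverage")
  expect_equal(dplyr::filter(led, pos == 3)$reason, "uncalled")
  expect_equal(dplyr::filter(led, pos == 3)$expected_from, "maternal")
  # inside an embryo-only LoH segment the reason is loh
  segs <- tibble::tibble(chrom = "chr1", start = 0, end = 5000,
                         label = "embryo_only")
  led2 <- ledger_expected_missing(x, segs, depth_min = 10)
  expect_true(all(led2$reason[led2$pos %in% c(2, 3)] == "loh"))
  # conservation on the simulated family: every parental pathogenic variant
  # is either an adequately covered embryo call or a ledger entry
  screen <- test_screen_tbl()
  led3 <- ledger_expected_missing(screen, NULL, 10)
  par_path <- parental_pathogenic(screen)
  called <- par_path$key[!gt_is_missing(par_path$gt_e) &
                           !is.na(par_path$dp_e) & par_path$dp_e >= 10]
  expect_setequal(par_path$key, union(called, led3$key))
})

# Construct a phased trio neighbourhood around a missing variant.
rescue_fixture <- function(transmit_hap = 1L, variant_hap = 1L,
                           flank_haps = c(1L, 1L)) {
  hap_gt <- function(h) if (h == 1L) "1|0" else "0|1"
  flank <- function(pos, hap) {
    # father het (alt on haplotype `hap`), mother hom-ref, embryo shows
    # whether the alt haplotype arrived
    got_alt <- hap == transmit_hap
    trio_row(pos = pos, gt_f = hap_gt(hap), gt_m = "0|0",
             gt_e = if (got_alt) "0/1" else "0/0", dp_e = 40L)
  }
  entry_row <- trio_row(pos = 5000, gt_f = hap_gt(variant_hap), gt_m = "0|0",
                        gt_e = "./.", dp_e = 2L)
  screen <- trio_rows(flank(1000, flank_haps[1]), entry_row,
                      flank(9000, flank_haps[2]))
  led <- ledger_expected_missing(screen, NULL, 10)
  phase_rescue(led, screen)
}

test_that("flanking-SNP rescue infers carrier status only from agreeing flanks", {
  # variant on transmitted haplotype, informative flanks both sides
  out <- rescue_fixture(transmit_hap = 1L, variant_hap = 1L)
  expect_equal(out$rescue_status, "carrier_inferred")
  out2 <- rescue_fixture(transmit_hap = 2L, variant_hap = 1L)
  expect_equal(out2$rescue_status, "noncarrier_inferred")
})

test_that("rescue accuracy is perfect without in-window recombination", {
  withr::with_seed(77, {
    res <- purrr::map_chr(1:200, function(i) {
      th <- sample(1:2, 1); vh <- sample(1:2, 1)
      out <- rescue_fixture(transmit_hap = th, variant_hap = vh)
      expected <- if (th == vh) "carrier_inferred" else "noncarrier_inferred"
      paste(out$rescue_status, expected, sep = "=")
    })
  })
  split_ok <- vapply(strsplit(res, "="), function(p) p[1] == p[2], logical(1))
  expect_true(all(split_ok))
})

test_that("discordant flanks (recombination) are never mis-assigned", {
  # a crossover between the flanks makes them disagree
  f1 <- trio_row(pos = 1000, gt_f = "1|0", gt_m = "0|0", gt_e = "0/1",
                 dp_e = 40L)  # hap1 transmitted here
  entry <- trio_row(pos = 5000, gt_f = "1|0", gt_m = "0|0", gt_e = "./.",
                    dp_e = 2L)
  f2 <- trio_row(pos = 9000, gt_f = "1|0", gt_m = "0|0", gt_e = "0/0",
                 dp_e = 40L)  # hap2 transmitted here
  screen <- trio_rows(f1, entry, f2)
  out <- phase_rescue(ledger_expected_missing(screen, NULL, 10), screen)
  expect_equal(out$rescue_status, "unresolved")
  # single usable flank: also unresolved
  out2 <- phase_rescue(
    ledger_expected_missing(trio_rows(f1, entry), NULL, 10),
    trio_rows(f1, entry)
  )
  expect_equal(out2$rescue_status, "unresolved")
})
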