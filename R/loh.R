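#' Sites informative for embryo loss-of-heterozygosity
#'
#' The LoH site universe for an embryo: sites where the parents carry
#' different genotypes (so the embryo is expected heterozygous on at least
#' one parental configuration). A site is LoH-consistent when the embryo is
#' called homozygous or missing.
#'
#' @param screen Screening tibble ([prepare_screen()]).
#' @return Tibble `chrom`, `pos`, `key`, `is_loh`, ordered by position.
#' @export
embryo_loh_sites <- function(screen) {
  norm_gt <- function(g) {
    vapply(strsplit(dplyr::coalesce(g, "."), "[/|]"),
           function(x) paste(sort(x), collapse = "/"), character(1))
  }
  screen |>
    filter(!gt_is_missing(.data$gt_f), !gt_is_missing(.data$gt_m),
           norm_gt(.data$gt_f) != norm_gt(.data$gt_m)) |>
    mutate(is_loh = !gt_is_het(.data$gt_e)) |>
    select("chrom", "pos", "key", "is_loh") |>
    arrange(.data$chrom, .data$pos)
}

#' Sites informative for parental loss of heterozygosity
#'
#' For a genomic-DNA parent the LoH signal is runs of homozygosity over the
#' family's variant sites at which the parent has a call.
#'
#' @param variants Long variant tibble.
#' @param sample_id Parent sample id.
#' @return Tibble `chrom`, `pos`, `key`, `is_loh`.
#' @export
parent_loh_sites <- function(variants, sample_id) {
  variants |>
    filter(.data$sample_id == .env$sample_id, !gt_is_missing(.data$gt)) |>
    mutate(is_loh = !gt_is_het(.data$gt)) |>
    select("chrom", "pos", "key", "is_loh") |>
    arrange(.data$chrom, .data$pos)
}

#' Detect loss-of-heterozygosity segments
#'
#' Finds maximal runs of LoH-consistent sites: consecutive LoH runs are
#' merged across interrupting non-LoH sites while the merged segment's LoH
#' fraction stays at or above `min_fraction` (smallest interruptions merged
#' first), and segments are emitted when they span strictly more than
#' `min_variants` sites at `loh_fraction >= min_fraction`. Segment bounds are
#' reported as 0-based half-open intervals anchored on LoH sites.
#'
#' @param sites Tibble from [embryo_loh_sites()] / [parent_loh_sites()]:
#'   `chrom`, `pos`, `is_loh`.
#' @param sample_id Label attached to the output.
#' @param min_variants Strict lower bound on sites per segment.
#' @param min_fraction Minimum LoH-consistent fraction.
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_sites`, `n_loh`,
#'   `loh_fraction`, `sample_id`.
#' @export
detect_loh_segments <- function(sites, sample_id = NA_character_,
                                min_variants = 100, min_fraction = 0.95) {
  out <- sites |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ loh_segments_chrom(.x, min_fraction)) |>
    ungroup()
  out |>
    filter(.data$n_sites > min_variants, .data$loh_fraction >= min_fraction) |>
    mutate(sample_id = sample_id) |>
    select("chrom", "start", "end", "n_sites", "n_loh", "loh_fraction",
           "sample_id")
}

# Greedy agglomerative run merging on one chromosome. Runs of consecutive
# is_loh sites are merged across the smallest gaps first while the pooled
# fraction holds; this keeps emitted segments maximal under the thresholds.
loh_segments_chrom <- function(x, min_fraction) {
  r <- rle(x$is_loh)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(
    first = starts[r$values], last = ends[r$values],
    n_loh = r$lengths[r$values]
  )
  if (nrow(runs) == 0) {
    return(tibble(start = numeric(0), end = numeric(0), n_sites = integer(0),
                  n_loh = integer(0), loh_fraction = numeric(0)))
  }
  runs$n_sites <- runs$n_loh
  repeat {
    if (nrow(runs) < 2) break
    gap <- runs$first[-1] - runs$last[-nrow(runs)] - 1L
    merged_sites <- runs$last[-1] - runs$first[-nrow(runs)] + 1L
    merged_loh <- runs$n_loh[-1] + runs$n_loh[-nrow(runs)]
    frac <- merged_loh / merged_sites
    ok <- which(frac >= min_fraction)
    if (length(ok) == 0) break
    i <- ok[which.min(gap[ok])]
    runs$last[i] <- runs$last[i + 1]
    runs$n_loh[i] <- merged_loh[i]
    runs$n_sites[i] <- merged_sites[i]
    runs <- runs[-(i + 1), ]
  }
  tibble(
    start = x$pos[runs$first] - 1,
    end = as.numeric(x$pos[runs$last]),
    n_sites = as.integer(runs$n_sites),
    n_loh = as.integer(runs$n_loh),
    loh_fraction = runs$n_loh / runs$n_sites
  )
}

#' Trio-compare LoH segments
#'
#' Labels embryo LoH segments `shared_parental` when they reciprocally
#' overlap a parental LoH segment by at least `min_reciprocal` (likely
#' inherited homozygosity), otherwise `embryo_only` (likely amplification
#' dropout).
#'
#' @param embryo_segments,father_segments,mother_segments Segment tibbles
#'   from [detect_loh_segments()].
#' @param min_reciprocal Reciprocal overlap fraction.
#' @return `embryo_segments` with a `label` column.
#' @export
trio_call_loh <- function(embryo_segments, father_segments, mother_segments,
                          min_reciprocal = 0.5) {
  parental <- bind_rows(father_segments, mother_segments)
  hit <- reciprocal_overlap(embryo_segments, parental, min_reciprocal)
  embryo_segments |>
    mutate(label = if_else(is.na(hit$match_idx), "embryo_only",
                           "shared_parental"))
}

#' Ledger of expected-but-missing parental pathogenic variants
#'
#' One entry per pathogenic / predicted-pathogenic variant carried by either
#' parent whose embryo call is absent, missing or below the depth threshold,
#' with the reason: `loh` when inside an embryo-only LoH segment,
#' `low_coverage` when called but under-covered, else `uncalled`.
#'
#' @param screen Screening tibble.
#' @param embryo_loh Labelled embryo LoH segments ([trio_call_loh()]); only
#'   `embryo_only` segments (or all, if unlabelled) define the `loh` reason.
#' @param depth_min Embryo depth threshold.
#' @return Tibble of `MissingExpectedVariant` records: `key`, `chrom`, `pos`,
#'   `gene`, `grade`, `expected_from`, `reason`, plus the trio call columns.
#' @export
ledger_expected_missing <- function(screen, embryo_loh = NULL, depth_min = 10) {
  loh_ivs <- embryo_loh
  if (!is.null(loh_ivs) && "label" %in% names(loh_ivs)) {
    loh_ivs <- filter(loh_ivs, .data$label == "embryo_only")
  }
  f_alt <- gt_alt_count(screen$gt_f)
  m_alt <- gt_alt_count(screen$gt_m)
  parental <- screen |>
    mutate(
      f_carries = !is.na(f_alt) & f_alt > 0L,
      m_carries = !is.na(m_alt) & m_alt > 0L
    ) |>
    filter(.data$grade %in% QUALIFYING_GRADES,
           .data$f_carries | .data$m_carries)
  in_loh <- pos_in_intervals(parental$chrom, parental$pos, loh_ivs)
  # inside an embryo-only LoH segment one haplotype's evidence is gone, so
  # the call is unreliable even when present at depth — ledgered for rescue
  missing_call <- gt_is_missing(parental$gt_e) |
    is.na(parental$dp_e) | parental$dp_e < depth_min | in_loh
  parental |>
    filter(missing_call) |>
    mutate(
      expected_from = case_when(
        .data$f_carries & .data$m_carries ~ "either",
        .data$f_carries ~ "paternal",
        TRUE ~ "maternal"
      ),
      reason = case_when(
        pos_in_intervals(.data$chrom, .data$pos, loh_ivs) ~ "loh",
        !gt_is_missing(.data$gt_e) & !is.na(.data$dp_e) &
          .data$dp_e < depth_min ~ "low_coverage",
        TRUE ~ "uncalled"
      ),
      rescue_status = "unresolved"
    ) |>
    select("key", "chrom", "pos", "ref", "alt", "gene", "grade",
           "expected_from", "reason", "rescue_status",
           dplyr::starts_with("gt_"), dplyr::starts_with("dp_"))
}

#' Phase-rescue expected-but-missing variants from flanking SNPs
#'
#' For each ledger entry, locates the nearest informative flanking SNP on
#' each side within `window` — a site where the carrier parent is phased
#' heterozygous, the other parent is homozygous, and the embryo call reveals
#' which parental haplotype was transmitted — and infers carrier status only
#' when both flanks agree: both indicate the variant-bearing haplotype gives
#' `carrier_inferred`, both the other haplotype `noncarrier_inferred`;
#' discordant flanks (recombination between them), a single usable flank, or
#' no flank in-window stay `unresolved`. No imputation is attempted.
#'
#' Requires phased parental genotypes (`|`-separated, haplotype order
#' consistent along each chromosome, as the synthetic generator emits).
#'
#' @param ledger Output of [ledger_expected_missing()].
#' @param screen Screening tibble with phased parental genotypes.
#' @param window Maximum flank distance in bp.
#' @return The ledger with `rescue_status` and flank keys filled in.
#' @export
phase_rescue <- function(ledger, screen, window = 1e6) {
  if (nrow(ledger) == 0) {
    return(mutate(ledger, flank_left = character(0), flank_right = character(0)))
  }
  out <- ledger |>
    mutate(flank_left = NA_character_, flank_right = NA_character_)
  for (i in seq_len(nrow(out))) {
    side <- if (out$expected_from[i] == "maternal") "m" else "f"
    # 'either' defaults to the paternal haplotype context; with both parents
    # carrying, single-parent phasing cannot separate the two contributions.
    if (out$expected_from[i] == "either") {
      next
    }
    res <- rescue_one(out[i, ], screen, side, window)
    out$rescue_status[i] <- res$status
    out$flank_left[i] <- res$left
    out$flank_right[i] <- res$right
  }
  out
}

rescue_one <- function(entry, screen, side, window) {
  gt_p <- paste0("gt_", side)
  gt_o <- paste0("gt_", if (side == "f") "m" else "f")
  unresolved <- list(status = "unresolved", left = NA_character_,
                     right = NA_character_)
  # which haplotype of the carrier parent bears the variant
  pgt <- screen[[gt_p]][screen$key == entry$key]
  if (length(pgt) != 1 || !gt_is_phased(pgt)) return(unresolved)
  phap <- as.integer(strsplit(pgt, "|", fixed = TRUE)[[1]])
  if (sum(phap == 1L) != 1L) return(unresolved)
  variant_hap <- which(phap == 1L)

  cand <- screen |>
    filter(.data$chrom == entry$chrom,
           abs(.data$pos - entry$pos) <= window,
           .data$key != entry$key) |>
    mutate(dist = abs(.data$pos - entry$pos)) |>
    arrange(.data$dist)
  informative <- gt_is_phased(cand[[gt_p]]) & gt_is_het(cand[[gt_p]]) &
    !gt_is_missing(cand[[gt_o]]) & !gt_is_het(cand[[gt_o]]) &
    !gt_is_missing(cand$gt_e)
  cand <- cand[informative, , drop = FALSE]
  if (nrow(cand) == 0) return(unresolved)

  transmitted_hap <- function(row) {
    ph <- as.integer(strsplit(row[[gt_p]], "|", fixed = TRUE)[[1]])
    other_allele <- gt_alt_count(row[[gt_o]])
    other_allele <- if (other_allele > 0L) 1L else 0L
    e_alt <- gt_alt_count(row$gt_e)
    from_p <- e_alt - other_allele
    if (is.na(from_p) || !from_p %in% c(0L, 1L)) return(NA_integer_)
    hap <- which(ph == from_p)
    if (length(hap) != 1L) return(NA_integer_)
    hap
  }
  flank_call <- function(sub) {
    for (j in seq_len(nrow(sub))) {
      h <- transmitted_hap(sub[j, ])
      if (!is.na(h)) return(list(hap = h, key = sub$key[j]))
    }
    NULL
  }
  left <- flank_call(filter(cand, .data$pos < entry$pos))
  right <- flank_call(filter(cand, .data$pos > entry$pos))
  if (is.null(left) || is.null(right)) return(unresolved)
  status <- if (left$hap == right$hap) {
    if (left$hap == variant_hap) "carrier_inferred" else "noncarrier_inferred"
  } else {
    "unresolved"
  }
  list(status = status, left = left$key, right = right$key)
}
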