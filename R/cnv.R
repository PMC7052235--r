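#' Read a bedGraph depth track
#'
#' @param path bedGraph file (`chrom start end depth`, 0-based half-open).
#' @param sample_id Label attached to the rows.
#' @return Tibble `sample_id`, `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path, sample_id) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                  col_types = "cnnd", comment = "#") |>
    mutate(sample_id = sample_id) |>
    select("sample_id", dplyr::everything())
}

#' Bin depth tracks into fixed-width windows
#'
#' Averages per-interval coverage into windows of `bin_size` (10 kb by
#' default) per sample, then normalizes each sample by its autosomal median
#' bin depth so copy ratios are scale-free.
#'
#' @param tracks Long depth tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `depth`), e.g. from [read_bedgraph()].
#' @param bin_size Window width in bp.
#' @return Tibble `sample_id`, `chrom`, `start`, `end`, `depth` (mean raw),
#'   `norm_depth`.
#' @export
bin_depths <- function(tracks, bin_size = 1e4) {
  # split intervals at bin boundaries, then average with bp weights
  pieces <- tracks |>
    mutate(
      bin_first = floor(.data$start / bin_size),
      bin_last = floor((.data$end - 1) / bin_size)
    )
  simple <- filter(pieces, .data$bin_first == .data$bin_last)
  spanning <- filter(pieces, .data$bin_first != .data$bin_last)
  if (nrow(spanning) > 0) {
    spanning <- spanning |>
      mutate(bin = purrr::map2(.data$bin_first, .data$bin_last, seq)) |>
      tidyr::unnest("bin") |>
      mutate(
        start = pmax(.data$start, .data$bin * bin_size),
        end = pmin(.data$end, (.data$bin + 1) * bin_size)
      )
  }
  bind_rows(mutate(simple, bin = .data$bin_first), spanning) |>
    group_by(.data$sample_id, .data$chrom, .data$bin) |>
    summarise(
      depth = sum(.data$depth * (.data$end - .data$start)) /
        sum(.data$end - .data$start),
      .groups = "drop"
    ) |>
    mutate(start = .data$bin * bin_size, end = (.data$bin + 1) * bin_size) |>
    group_by(.data$sample_id) |>
    mutate(norm_depth = .data$depth /
             median(.data$depth[.data$chrom != "chrX"])) |>
    ungroup() |>
    select("sample_id", "chrom", "start", "end", "depth", "norm_depth") |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Score depth bins against parental controls
#'
#' Computes, for one target sample against one or two control samples, the
#' per-bin copy ratio (target normalized depth over mean control normalized
#' depth, corrected for the sex-chromosome expectation) and a Z-score of the
#' target bin against the controls' genome-wide normalized-depth
#' distribution, and sets the four QC flags: `high_control_variation` (the
#' controls disagree at the bin), `low_control_depth`, `low_z_score`
#' (|z| below `z_min` — deviation within noise), and `within_regional_iqr`
#' (target depth inside the interquartile range of the surrounding window).
#'
#' @param bins Binned depth tibble ([bin_depths()]) containing target and
#'   control samples.
#' @param sample Target sample id (embryo, or a parent scored against the
#'   other parent).
#' @param controls Control sample ids.
#' @param sample_sex `"male"`/`"female"`/`"unknown"`; with `control_sexes`,
#'   sets the expected chrX ratio.
#' @param control_sexes Character vector matching `controls`.
#' @param config [screen_config()] (z, CV, depth and IQR-window settings).
#' @return One row per bin: depths, `ratio`, `z`, `qc_flags` (semicolon
#'   string, `""` when clean).
#' @export
score_bins <- function(bins, sample, controls,
                       sample_sex = "unknown", control_sexes = NULL,
                       config = screen_config()) {
  tgt <- bins |>
    filter(.data$sample_id == sample) |>
    select("chrom", "start", "end", "depth", "norm_depth")
  ctl <- bins |>
    filter(.data$sample_id %in% controls) |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(
      ctl_norm = mean(.data$norm_depth),
      ctl_sd = if (n() > 1) sd(.data$norm_depth) else 0,
      ctl_depth = mean(.data$depth),
      .groups = "drop"
    )
  x <- inner_join(tgt, ctl, by = c("chrom", "start", "end")) |>
    arrange(.data$chrom, .data$start)

  # genome-wide control reference distribution (autosomal bins)
  ctl_auto <- bins |>
    filter(.data$sample_id %in% controls, .data$chrom != "chrX")
  ref_mean <- mean(ctl_auto$norm_depth)
  ref_sd <- sd(ctl_auto$norm_depth)

  # expected copy ratio on chrX given sexes (autosomes: 1)
  expected_x <- expected_x_ratio(sample_sex, control_sexes %||%
                                   rep("unknown", length(controls)))
  x <- x |>
    mutate(
      expected = if_else(.data$chrom == "chrX", expected_x, 1),
      ratio = if_else(.data$ctl_norm > 0,
                      (.data$norm_depth / .data$ctl_norm) / .data$expected,
                      NA_real_),
      z = if (ref_sd > 0) (.data$norm_depth / .data$expected - ref_mean) / ref_sd
          else NA_real_,
      candidate = !is.na(.data$ratio) & !is.na(.data$z) &
        ((.data$ratio > config$cnv_dup_ratio & .data$z > 0) |
           (.data$ratio < config$cnv_del_ratio & .data$z < 0))
    ) |>
    group_by(.data$chrom) |>
    mutate(
      # regional IQR of the surrounding window, from background (non-
      # candidate) bins only, so a broad genuine CNV does not flag itself
      reg_lo = roll_quantile(.data$depth, !.data$candidate,
                             config$cnv_iqr_window, 0.25),
      reg_hi = roll_quantile(.data$depth, !.data$candidate,
                             config$cnv_iqr_window, 0.75)
    ) |>
    ungroup()
  cv <- if_else(x$ctl_norm > 0, x$ctl_sd / x$ctl_norm, Inf)
  flags <- paste0(
    if_else(cv > config$cnv_control_cv_max, "high_control_variation;", ""),
    if_else(is.na(x$ctl_depth) | x$ctl_depth < config$cnv_control_depth_min,
            "low_control_depth;", ""),
    if_else(is.na(x$z) | abs(x$z) < config$cnv_z_min, "low_z_score;", ""),
    if_else(!is.na(x$reg_lo) & x$depth >= x$reg_lo & x$depth <= x$reg_hi,
            "within_regional_iqr;", "")
  )
  x |>
    mutate(qc_flags = sub(";$", "", flags), sample_id = sample) |>
    select("sample_id", "chrom", "start", "end", "depth", "norm_depth",
           "ctl_depth", "ratio", "z", "qc_flags")
}

expected_x_ratio <- function(sample_sex, control_sexes) {
  copies <- function(sex) switch(sex, male = 1, female = 2, 1.5)
  copies(sample_sex) / mean(vapply(control_sexes, copies, numeric(1)))
}

# Rolling two-sided quantile over +/- w positions, restricted to bins with
# keep = TRUE; NA when fewer than 10 usable bins fall in the window.
roll_quantile <- function(x, keep, w, p) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    v <- x[lo:hi][keep[lo:hi]]
    v <- v[!is.na(v)]
    if (length(v) < 10) return(NA_real_)
    quantile(v, p, names = FALSE)
  }, numeric(1))
}

#' Call CNVs from scored bins
#'
#' Merges maximal runs of consecutive qualifying bins — duplications at
#' ratio strictly above 2.0 with positive Z, deletions at ratio strictly
#' below 0.5 with negative Z, in both cases with an empty QC-flag set — and
#' keeps calls whose mean raw target depth exceeds `min_depth`. Runs are
#' split at any non-qualifying or flagged bin (no gap tolerance).
#'
#' @param scored Output of [score_bins()].
#' @param config [screen_config()].
#' @return Tibble of calls: `chrom`, `start`, `end`, `state`, `n_bins`,
#'   `mean_ratio`, `mean_z`, `mean_depth`, `sample_id`.
#' @export
call_cnvs <- function(scored, config = screen_config()) {
  x <- scored |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      state = case_when(
        .data$qc_flags != "" | is.na(.data$ratio) | is.na(.data$z) ~ "none",
        .data$ratio > config$cnv_dup_ratio & .data$z > 0 ~ "duplication",
        .data$ratio < config$cnv_del_ratio & .data$z < 0 ~ "deletion",
        TRUE ~ "none"
      )
    ) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(
      .data$state != dplyr::lag(.data$state, default = "") |
        .data$start != dplyr::lag(.data$end, default = -1)
    )) |>
    ungroup()
  x |>
    filter(.data$state != "none") |>
    group_by(.data$sample_id, .data$chrom, .data$run, .data$state) |>
    summarise(
      start = min(.data$start), end = max(.data$end), n_bins = n(),
      mean_ratio = mean(.data$ratio), mean_z = mean(.data$z),
      mean_depth = mean(.data$depth),
      mean_ctl_depth = mean(.data$ctl_depth), .groups = "drop"
    ) |>
    # depth QC on the controls: the region must be reliably sequenceable
    # (an embryo homozygous deletion is, by construction, depth-poor)
    filter(.data$mean_ctl_depth > config$cnv_min_depth) |>
    select("sample_id", "chrom", "start", "end", "state", "n_bins",
           "mean_ratio", "mean_z", "mean_depth", "mean_ctl_depth") |>
    arrange(.data$chrom, .data$start)
}

#' Annotate CNV calls with dosage-sensitivity categories
#'
#' Intersects calls with a gene-interval dosage table (ClinGen-style) and
#' assigns: deletions over a sufficient-evidence haploinsufficiency gene and
#' duplications over a sufficient-evidence triplosensitivity gene are
#' reportable; genes with autosomal-recessive evidence route the call to the
#' recessive SNV/indel cross-check instead of auto-reporting.
#'
#' @param calls CNV call tibble ([call_cnvs()]) or SV interval tibble with a
#'   `state` column (`duplication`/`deletion`).
#' @param dosage_table Tibble `gene`, `chrom`, `start`, `end`,
#'   `haploinsufficiency`, `triplosensitivity` (values
#'   `sufficient_evidence`, `autosomal_recessive_gene`, `none`).
#' @return Calls with `gene`, `dosage_category`, `dosage_evidence`, `route`
#'   (`report` / `recessive_check` / `none`); calls spanning several dosage
#'   genes emit one row per gene.
#' @export
assign_dosage <- function(calls, dosage_table) {
  required <- c("gene", "chrom", "start", "end", "haploinsufficiency",
                "triplosensitivity")
  if (!all(required %in% names(dosage_table)) ||
      anyNA(dosage_table$start) || anyNA(dosage_table$end)) {
    stop("malformed dosage table", call. = FALSE)
  }
  bad <- !(dosage_table$haploinsufficiency %in%
             c("sufficient_evidence", "autosomal_recessive_gene", "none")) |
    !(dosage_table$triplosensitivity %in%
        c("sufficient_evidence", "autosomal_recessive_gene", "none"))
  if (any(bad)) stop("malformed dosage table evidence values", call. = FALSE)
  if (nrow(calls) == 0) {
    return(mutate(calls, gene = character(0), dosage_category = character(0),
                  dosage_evidence = character(0), route = character(0)))
  }
  hits <- calls |>
    mutate(.ci = row_number()) |>
    inner_join(dosage_table, by = "chrom", suffix = c("", ".g"),
               relationship = "many-to-many") |>
    filter(.data$start < .data$end.g, .data$start.g < .data$end) |>
    mutate(
      dosage_category = case_when(
        .data$state == "deletion" &
          .data$haploinsufficiency != "none" ~ "haploinsufficiency",
        .data$state == "duplication" &
          .data$triplosensitivity != "none" ~ "triplosensitivity",
        TRUE ~ "none"
      ),
      dosage_evidence = case_when(
        .data$dosage_category == "haploinsufficiency" ~ .data$haploinsufficiency,
        .data$dosage_category == "triplosensitivity" ~ .data$triplosensitivity,
        TRUE ~ "none"
      ),
      route = case_when(
        .data$dosage_evidence == "sufficient_evidence" ~ "report",
        .data$dosage_evidence == "autosomal_recessive_gene" ~ "recessive_check",
        TRUE ~ "none"
      )
    ) |>
    select(dplyr::all_of(c(names(calls), ".ci", "gene", "dosage_category",
                           "dosage_evidence", "route")))
  no_hit <- calls |>
    mutate(.ci = row_number()) |>
    anti_join(hits, by = ".ci") |>
    mutate(gene = NA_character_, dosage_category = "none",
           dosage_evidence = "none", route = "none")
  bind_rows(hits, no_hit) |>
    arrange(.data$.ci) |>
    select(-".ci")
}

#' Trio CNV inheritance
#'
#' Labels each embryo CNV call by comparing it with the parents' calls
#' (computed with the same pipeline, each parent scored against the other):
#' a same-state call overlapping reciprocally by at least `min_reciprocal`
#' in one parent gives that parent; in both parents, `ambiguous`; in
#' neither, `de_novo`.
#'
#' @param embryo_calls,father_calls,mother_calls CNV call tibbles.
#' @param min_reciprocal Reciprocal overlap fraction.
#' @return `embryo_calls` with an `inheritance` column.
#' @export
trio_cnv_inheritance <- function(embryo_calls, father_calls, mother_calls,
                                 min_reciprocal = 0.5) {
  match_parent <- function(calls, parent_calls) {
    if (nrow(calls) == 0) return(logical(0))
    out <- rep(FALSE, nrow(calls))
    for (st in unique(calls$state)) {
      idx <- which(calls$state == st)
      pc <- filter(parent_calls, .data$state == st)
      hit <- reciprocal_overlap(calls[idx, ], pc, min_reciprocal)
      out[idx] <- !is.na(hit$match_idx)
    }
    out
  }
  pat <- match_parent(embryo_calls, father_calls)
  mat <- match_parent(embryo_calls, mother_calls)
  embryo_calls |>
    mutate(inheritance = case_when(
      pat & mat ~ "ambiguous",
      pat ~ "paternal",
      mat ~ "maternal",
      TRUE ~ "de_novo"
    ))
}

#' Cross-check recessive-routed CNVs against recessive SNV/indel hits
#'
#' Pairs a deletion (or recessive-routed dosage CNV) inherited from one
#' parent with a pathogenic or predicted-pathogenic heterozygous SNV/indel
#' of the same gene inherited from the other parent — a candidate compound
#' loss emitted for curation.
#'
#' @param cnv_calls Dosage-annotated, inheritance-labelled CNV calls.
#' @param het_candidates Heterozygous candidate tibble with `gene`, `origin`,
#'   `grade`, `key`.
#' @return Tibble of compound findings: gene, CNV interval and state, CNV
#'   parent, SNV key and parent.
#' @export
crosscheck_recessive <- function(cnv_calls, het_candidates) {
  cnv <- cnv_calls |>
    filter(!is.na(.data$gene),
           .data$state == "deletion" | .data$route == "recessive_check",
           .data$inheritance %in% c("paternal", "maternal"))
  snv <- het_candidates |>
    filter(!is.na(.data$gene), .data$grade %in% QUALIFYING_GRADES,
           .data$origin %in% c("paternal", "maternal"))
  if (nrow(cnv) == 0 || nrow(snv) == 0) {
    return(tibble(gene = character(0), cnv_chrom = character(0),
                  cnv_start = numeric(0), cnv_end = numeric(0),
                  cnv_state = character(0), cnv_parent = character(0),
                  snv_key = character(0), snv_parent = character(0)))
  }
  inner_join(
    select(cnv, "gene", cnv_chrom = "chrom", cnv_start = "start",
           cnv_end = "end", cnv_state = "state", cnv_parent = "inheritance"),
    select(snv, "gene", snv_key = "key", snv_parent = "origin"),
    by = "gene", relationship = "many-to-many"
  ) |>
    filter(.data$cnv_parent != .data$snv_parent)
}

#' Ingest external structural-variant calls
#'
#' Reads a BED-like interval file of externally discovered SVs
#' (`chrom start end type`, 0-based half-open; types DEL, DUP, INV, ITX,
#' CTX), maps DEL/DUP onto the CNV dosage logic and leaves other types
#' annotated but outside dosage logic.
#'
#' @param path Interval file.
#' @param source Tag recorded in the `source` column.
#' @return SV tibble with `state` (`deletion`/`duplication`/`other`) and
#'   `type`.
#' @export
ingest_sv_calls <- function(path, source) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "type"),
                  col_types = "cnnc", comment = "#") |>
    mutate(
      type = toupper(.data$type),
      type = if_else(.data$type %in% c("DEL", "DUP", "INV", "ITX", "CTX"),
                     .data$type, "OTHER"),
      state = case_when(
        .data$type == "DEL" ~ "deletion",
        .data$type == "DUP" ~ "duplication",
        TRUE ~ "other"
      ),
      source = source
    )
}

#' Write CNV calls as BED
#'
#' @param calls CNV call tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path) {
  readr::write_tsv(
    calls |>
      mutate(name = paste0(.data$state, "_ratio", round(.data$mean_ratio, 2))) |>
      select("chrom", "start", "end", "name"),
    path, col_names = FALSE
  )
  invisible(path)
}
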