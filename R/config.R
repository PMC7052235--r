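#' Screening configuration
#'
#' Collects every tunable threshold of the screening pipeline in one list.
#' Defaults follow the published workflow: strict filters require embryo depth
#' of at least 10 reads, the failsafe requires more than 1 read and drops the
#' genotype-quality requirement, the de novo variant-allele-fraction gate
#' rejects below 0.35, and the quality-by-depth gate (novel subfilters only)
#' requires QD strictly above 12.
#'
#' @param depth_min Minimum embryo read depth for the strict filters
#'   (">10x coverage", implemented as `>= 10` reads).
#' @param gq_min Minimum genotype quality for the strict filters. The failsafe
#'   filter is defined by omitting this requirement; the published workflow
#'   does not print its GQ cutoff, so a conventional Q20 is the default.
#' @param failsafe_depth_min Minimum embryo depth for the failsafe filter
#'   ("read depth >1", implemented as `>= 2` reads).
#' @param vaf_threshold De novo candidates with VAF strictly below this are
#'   rejected as amplification artifacts.
#' @param vaf_gate_classes Variant classes subject to the VAF gate. Defaults to
#'   all classes; restrict to `"snv"` to exempt longer deletions.
#' @param qd_threshold Quality-by-depth must strictly exceed this for novel
#'   (non-dbSNP) de novo candidates.
#' @param loh_min_variants A loss-of-heterozygosity segment must span strictly
#'   more than this many informative sites.
#' @param loh_min_fraction Minimum fraction of sites in a segment that are
#'   LoH-consistent.
#' @param flank_window Maximum distance (bp) to search for an informative
#'   flanking SNP when phasing expected-but-missing variants.
#' @param bin_size Width (bp) of the read-depth bins for CNV calling.
#' @param cnv_dup_ratio,cnv_del_ratio Copy-ratio thresholds for duplication
#'   (`> 2.0`) and deletion (`< 0.5`) calls.
#' @param cnv_min_depth Minimum mean raw embryo depth over a CNV call.
#' @param cnv_z_min Bins with `|z|` below this carry the low-Z-score QC flag.
#' @param cnv_control_cv_max Bins where the controls' normalized depths have a
#'   coefficient of variation above this carry the high-control-variation flag.
#' @param cnv_control_depth_min Bins with mean raw control depth below this
#'   carry the low-control-depth flag.
#' @param cnv_iqr_window Half-width, in bins, of the regional window for the
#'   within-regional-IQR flag.
#' @param cnv_reciprocal Reciprocal-overlap fraction for trio CNV / LoH
#'   comparisons.
#' @param str_tolerance Allowed repeat-count difference still called
#'   concordant (exact transmission = 0).
#' @param par_regions Tibble (`chrom`, `start`, `end`; 0-based half-open) of
#'   pseudoautosomal regions to treat as autosomal. Empty by default; use
#'   [grch37_par()] for GRCh37 data.
#' @return A named list with class `screen_config`.
#' @export
screen_config <- function(depth_min = 10,
                          gq_min = 20,
                          failsafe_depth_min = 2,
                          vaf_threshold = 0.35,
                          vaf_gate_classes = c("snv", "insertion",
                                               "deletion_gt1bp", "other"),
                          qd_threshold = 12,
                          loh_min_variants = 100,
                          loh_min_fraction = 0.95,
                          flank_window = 1e6,
                          bin_size = 1e4,
                          cnv_dup_ratio = 2.0,
                          cnv_del_ratio = 0.5,
                          cnv_min_depth = 5,
                          cnv_z_min = 1.96,
                          cnv_control_cv_max = 0.5,
                          cnv_control_depth_min = 10,
                          cnv_iqr_window = 50,
                          cnv_reciprocal = 0.5,
                          str_tolerance = 0,
                          par_regions = NULL) {
  cfg <- list(
    depth_min = depth_min, gq_min = gq_min,
    failsafe_depth_min = failsafe_depth_min,
    vaf_threshold = vaf_threshold, vaf_gate_classes = vaf_gate_classes,
    qd_threshold = qd_threshold,
    loh_min_variants = loh_min_variants, loh_min_fraction = loh_min_fraction,
    flank_window = flank_window,
    bin_size = bin_size,
    cnv_dup_ratio = cnv_dup_ratio, cnv_del_ratio = cnv_del_ratio,
    cnv_min_depth = cnv_min_depth, cnv_z_min = cnv_z_min,
    cnv_control_cv_max = cnv_control_cv_max,
    cnv_control_depth_min = cnv_control_depth_min,
    cnv_iqr_window = cnv_iqr_window, cnv_reciprocal = cnv_reciprocal,
    str_tolerance = str_tolerance,
    par_regions = par_regions %||%
      tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  )
  structure(cfg, class = "screen_config")
}

#' Read a screening configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults. File paths for
#' pipeline inputs (vcf, pedigree, annotations, depth tracks, gene lists) may
#' be carried under an `inputs:` mapping and are returned in `$inputs`.
#'
#' @param path YAML file.
#' @return A `screen_config` list, possibly with an `inputs` element.
#' @export
read_screen_config <- function(path) {
  y <- yaml::read_yaml(path)
  inputs <- y$inputs
  y$inputs <- NULL
  known <- names(formals(screen_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(y$par_regions)) {
    y$par_regions <- as_tibble(y$par_regions)
  }
  cfg <- do.call(screen_config, y)
  cfg$inputs <- inputs
  cfg
}

#' GRCh37 chrX pseudoautosomal regions
#'
#' Coordinates (0-based half-open) of PAR1 and PAR2 on GRCh37 chromosome X,
#' for use as `par_regions` when screening GRCh37-aligned data.
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
grch37_par <- function() {
  tibble(
    chrom = c("chrX", "chrX"),
    start = c(60000, 154931043),
    end = c(2699520, 155260560)
  )
}
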