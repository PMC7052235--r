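#' Simulation parameters for the synthetic trio generator
#'
#' Defaults emulate the sequencing conditions the screening pipeline
#' assumes: a miniature genome (four 10 Mb autosomes plus a 10 Mb chrX),
#' parental germline heterozygosity, Mendelian transmission with
#' recombination, de novo point mutations (74 per full-genome equivalent,
#' scaled to the miniature genome by default), and multiple-displacement-
#' amplification artifacts — allele-dropout regions, false heterozygotes
#' with VAF mode 0.26 on support 0.08–0.34, and coverage degradation
#' reproducing an 87.5% (embryo) versus 96.4% (parent) genome fraction at
#' 20x. Depths are negative-binomial (parents: mean 46, size 8; embryos:
#' mean 48, size 3.65 under 100 kb lognormal amplification waves,
#' sdlog 0.2).
#'
#' @param chrom_lengths Named vector of contig lengths.
#' @param site_density Family variant sites per bp.
#' @param p_alt_hap Per-haplotype alternate-allele probability at a site.
#' @param p_indel Fraction of sites that are short indels.
#' @param tstv_target Expected transition/transversion ratio of SNVs.
#' @param mean_depth_parent,depth_size_parent Parent depth NB mean and size.
#' @param mean_depth_embryo,depth_size_embryo Embryo depth NB mean and size.
#' @param wave_sd,wave_region Lognormal sdlog and width (bp) of regional
#'   embryo amplification waves.
#' @param denovo_rate Expected de novo SNVs per full genome equivalent.
#' @param scale_denovo Scale `denovo_rate` by simulated/full genome size.
#' @param genome_full Full genome size used for scaling.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param dropout_rate Expected allele-dropout regions per embryo genome.
#' @param dropout_min_length,dropout_max_length Dropout region length range
#'   (uniform).
#' @param artifact_het_rate False-heterozygote artifacts per bp.
#' @param artifact_vaf Scaled-beta parameters of the artifact VAF
#'   distribution (`shape1`, `shape2`, `lo`, `hi`; mode 0.26 at defaults).
#' @param p_dbsnp_parent,p_dbsnp_denovo,p_dbsnp_artifact dbSNP membership
#'   probabilities by site origin.
#' @param p_background_pathogenic,p_background_likely Background ClinVar
#'   pathogenic / likely-pathogenic rates among catalogued parental sites.
#' @param predictor_damaging_rate Background per-predictor damaging rate.
#' @param n_embryos Number of embryos; sexes recycle `embryo_sexes`.
#' @param embryo_sexes Sexes assigned to embryos in order.
#' @param str_discord_rate Per-allele probability of a repeat-count slip in
#'   embryo tandem-repeat calls.
#' @param planted_variants Planted condition table
#'   ([default_planted_variants()]).
#' @param planted_cnvs Planted CNV table ([default_planted_cnvs()]).
#' @param track_bin Depth-track resolution (bp).
#' @return A `sim_params` list.
#' @export
sim_params <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7,
                                         chr4 = 1e7, chrX = 1e7),
                       site_density = 1 / 800,
                       p_alt_hap = 0.35,
                       p_indel = 0.05,
                       tstv_target = 2.081,
                       mean_depth_parent = 46, depth_size_parent = 8,
                       mean_depth_embryo = 48, depth_size_embryo = 3.65,
                       wave_sd = 0.2, wave_region = 5e4,
                       denovo_rate = 74, scale_denovo = TRUE,
                       genome_full = 3.1e9,
                       crossover_rate = 1,
                       dropout_rate = 3,
                       dropout_min_length = 5e5, dropout_max_length = 3e6,
                       artifact_het_rate = 5e-5,
                       artifact_vaf = list(shape1 = 10, shape2 = 5,
                                           lo = 0.08, hi = 0.34),
                       p_dbsnp_parent = 0.98, p_dbsnp_denovo = 0.1,
                       p_dbsnp_artifact = 0.02,
                       p_background_pathogenic = 5e-5,
                       p_background_likely = 1e-4,
                       predictor_damaging_rate = 0.08,
                       n_embryos = 3,
                       embryo_sexes = c("male", "female"),
                       str_discord_rate = 0.1,
                       planted_variants = default_planted_variants(),
                       planted_cnvs = default_planted_cnvs(),
                       track_bin = 1e3) {
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

#' Synthetic gene map
#'
#' Tiles each chromosome with 150 kb genes every 200 kb. A handful of slots
#' carry real gene symbols so planted conditions, the actionable-gene list
#' and the dosage table have recognisable names; all coordinates are
#' synthetic.
#'
#' @param chrom_lengths Contig lengths.
#' @return Tibble `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
sim_gene_map <- function(chrom_lengths = sim_params()$chrom_lengths) {
  map <- purrr::imap_dfr(as.list(chrom_lengths), function(len, chrom) {
    starts <- seq(0, len - 2e5, by = 2e5)
    tibble(
      chrom = chrom, start = starts, end = starts + 1.5e5,
      gene = sprintf("%sG%03d", toupper(sub("chr", "C", chrom)),
                     seq_along(starts))
    )
  })
  named <- c(
    KRT10 = "C1G010", PKD1 = "C1G025",
    CFTR = "C2G010", SCN1A = "C2G025",
    BRCA2 = "C3G010",
    ABL1 = "C4G010",
    GLA = "CXG025", DMD = "CXG040"
  )
  for (i in seq_along(named)) {
    map$gene[map$gene == named[i]] <- names(named)[i]
  }
  select(map, "gene", "chrom", "start", "end")
}

#' Default planted disease conditions
#'
#' One condition per major inheritance mode, in the synthetic gene map's
#' named genes: a paternal dominant SNV, a biparental recessive 3 bp
#' deletion, a maternal dominant insertion, a maternal X-linked SNV, a
#' predicted-pathogenic (predictor-graded) paternal SNV, a compound-
#' heterozygous pair, and a catalogued de novo SNV planted in the first
#' embryo with VAF 0.63 and QD 20.9.
#'
#' @return Planted-variant specification tibble.
#' @export
default_planted_variants <- function() {
  tibble::tribble(
    ~gene, ~mode, ~offset, ~ref, ~alt, ~clinvar_class, ~review_stars,
    ~father_gt, ~mother_gt, ~predicted, ~de_novo, ~embryos,
    "KRT10", "dominant_het", 5e4, "C", "T", "pathogenic", 2L,
    "0|1", "0|0", FALSE, FALSE, NA,
    "CFTR", "recessive_hom", 5e4, "CTTT", "C", "pathogenic", 2L,
    "0|1", "0|1", FALSE, FALSE, NA,
    "BRCA2", "dominant_het", 5e4, "A", "ATG", "likely_pathogenic", 1L,
    "0|0", "0|1", FALSE, FALSE, NA,
    "GLA", "x_linked", 5e4, "G", "A", "pathogenic", 2L,
    "0", "0|1", FALSE, FALSE, NA,
    "PKD1", "dominant_het", 5e4, "G", "C", "unclassified", 0L,
    "0|1", "0|0", TRUE, FALSE, NA,
    "SCN1A", "compound_het", 3e4, "T", "A", "pathogenic", 1L,
    "0|1", "0|0", FALSE, FALSE, NA,
    "SCN1A", "compound_het", 9e4, "G", "T", "pathogenic", 1L,
    "0|0", "0|1", FALSE, FALSE, NA,
    "ABL1", "de_novo", 5e4, "A", "G", "pathogenic", 2L,
    "0|0", "0|0", FALSE, TRUE, "embryo1"
  )
}

#' Default planted copy-number variants
#'
#' Two de novo depth events in the first embryo: a homozygous (copy 0)
#' 300 kb deletion and a copy 5 400 kb duplication, both large enough for
#' 10 kb binned calling.
#'
#' @return Tibble `sample`, `chrom`, `start`, `end`, `copy`.
#' @export
default_planted_cnvs <- function() {
  tibble::tribble(
    ~sample, ~chrom, ~start, ~end, ~copy,
    "embryo1", "chr3", 6.0e6, 6.3e6, 0,
    "embryo1", "chr1", 7.0e6, 7.4e6, 5
  )
}

# Draw alt alleles with the configured Ts/Tv spectrum.
draw_alleles <- function(n, params) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_indel <- runif(n) < params$p_indel
  p_ts <- params$tstv_target / (1 + params$tstv_target)
  is_ts <- runif(n) < p_ts
  alt <- character(n)
  for (i in seq_len(n)) {
    if (is_indel[i]) next
    alt[i] <- if (is_ts[i]) {
      transition[[ref[i]]]
    } else {
      sample(setdiff(bases, c(ref[i], transition[[ref[i]]])), 1)
    }
  }
  if (any(is_indel)) {
    idx <- which(is_indel)
    ins <- runif(length(idx)) < 0.5
    unit <- vapply(seq_along(idx), function(j) {
      paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    }, character(1))
    ref[idx][ins] <- ref[idx][ins]
    alt[idx][ins] <- paste0(ref[idx][ins], unit[ins])
    ref[idx][!ins] <- paste0(ref[idx][!ins], unit[!ins])
    alt[idx][!ins] <- substr(ref[idx][!ins], 1, 1)
  }
  tibble(ref = ref, alt = alt)
}

#' Simulate the parental genomes
#'
#' Places family variant sites at the configured density, draws the four
#' phased parental haplotypes (the father carries a single X), applies the
#' planted-variant parental genotypes, and samples each parent's genotype
#' calls (negative-binomial depth, binomial allele depths at heterozygous
#' sites with success probability 0.5) and depth track.
#'
#' @param params [sim_params()].
#' @return A `sim_parents` list: `sites` (haplotype table), `calls` (long
#'   call tibble for `father`/`mother`), `tracks`, `gene_map`, `params`.
#' @export
simulate_parents <- function(params = sim_params()) {
  gene_map <- sim_gene_map(params$chrom_lengths)
  sites <- purrr::imap_dfr(as.list(params$chrom_lengths), function(len, chrom) {
    n <- round(len * params$site_density)
    pos <- sort(sample.int(len - 10L, n))
    al <- draw_alleles(n, params)
    tibble(chrom = chrom, pos = pos, ref = al$ref, alt = al$alt)
  }) |>
    mutate(
      f1 = rbinom(n(), 1, params$p_alt_hap),
      f2 = if_else(.data$chrom == "chrX", NA_integer_,
                   rbinom(n(), 1, params$p_alt_hap)),
      m1 = rbinom(n(), 1, params$p_alt_hap),
      m2 = rbinom(n(), 1, params$p_alt_hap),
      planted = NA_integer_
    )

  # planted conditions overwrite the haplotypes of a site inside their gene
  pv <- params$planted_variants
  if (!is.null(pv) && nrow(pv) > 0) {
    pv <- pv |>
      left_join(gene_map, by = "gene") |>
      mutate(pos = .data$start + .data$offset)
    if (anyNA(pv$start)) {
      stop("planted variant gene(s) absent from gene map", call. = FALSE)
    }
    gt_to_hap <- function(gt) {
      a <- as.integer(strsplit(gt, "|", fixed = TRUE)[[1]])
      if (length(a) == 1) c(a, NA_integer_) else a
    }
    # de novo specs are planted at meiosis, not in the parental germline
    planted_rows <- purrr::map_dfr(which(!pv$de_novo), function(i) {
      fh <- gt_to_hap(pv$father_gt[i])
      mh <- gt_to_hap(pv$mother_gt[i])
      tibble(
        chrom = pv$chrom[i], pos = as.integer(pv$pos[i]),
        ref = pv$ref[i], alt = pv$alt[i],
        f1 = fh[1], f2 = fh[2], m1 = mh[1], m2 = mh[2],
        planted = i
      )
    })
    sites <- sites |>
      filter(!paste(.data$chrom, .data$pos) %in%
               paste(planted_rows$chrom, planted_rows$pos)) |>
      bind_rows(planted_rows) |>
      arrange(.data$chrom, .data$pos)
  }

  # keep sites variant in the family (any alt on any haplotype)
  any_alt <- rowSums(cbind(sites$f1, sites$f2, sites$m1, sites$m2),
                     na.rm = TRUE) > 0
  sites <- sites[any_alt | !is.na(sites$planted), , drop = FALSE] |>
    mutate(
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      qd = pmax(1, rnorm(n(), 25, 5))
    )
  sites$gene <- locate_gene(sites$chrom, sites$pos, gene_map)

  calls <- bind_rows(
    parent_calls(sites, "father", params),
    parent_calls(sites, "mother", params)
  )
  tracks <- bind_rows(
    parent_track(params, "father"),
    parent_track(params, "mother")
  )
  structure(
    list(sites = sites, calls = calls, tracks = tracks,
         gene_map = gene_map, params = params),
    class = "sim_parents"
  )
}

locate_gene <- function(chrom, pos, gene_map) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(gene_map))) {
    hit <- chrom == gene_map$chrom[i] & pos > gene_map$start[i] &
      pos <= gene_map$end[i]
    out[hit] <- gene_map$gene[i]
  }
  out
}

# Genotype calls (phased GT, AD, DP, GQ) for one parent over all sites.
parent_calls <- function(sites, who, params) {
  h1 <- if (who == "father") sites$f1 else sites$m1
  h2 <- if (who == "father") sites$f2 else sites$m2
  n <- nrow(sites)
  dp <- rnbinom(n, size = params$depth_size_parent,
                mu = params$mean_depth_parent)
  hemi <- is.na(h2)
  gt <- if_else(hemi, as.character(h1), paste0(h1, "|", h2))
  n_alt <- ifelse(hemi, h1, h1 + h2)
  ploidy <- ifelse(hemi, 1L, 2L)
  ad_alt <- integer(n)
  het <- n_alt == 1L & ploidy == 2L
  ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  ad_alt[n_alt == ploidy & n_alt > 0] <- dp[n_alt == ploidy & n_alt > 0]
  gq <- pmin(99L, pmax(0L, as.integer(round(dp * 2 + rnorm(n, 0, 5)))))
  tibble(
    key = sites$key, sample_id = who, gt = gt,
    ad_ref = as.integer(dp - ad_alt), ad_alt = as.integer(ad_alt),
    dp = as.integer(dp), gq = as.numeric(gq)
  )
}

parent_track <- function(params, who, cnvs = NULL) {
  purrr::imap_dfr(as.list(params$chrom_lengths), function(len, chrom) {
    starts <- seq(0, len - params$track_bin, by = params$track_bin)
    mu <- rep(params$mean_depth_parent, length(starts))
    tibble(sample_id = who, chrom = chrom, start = starts,
           end = starts + params$track_bin,
           depth = rnbinom(length(starts), size = params$depth_size_parent,
                           mu = mu))
  })
}

#' Simulate one embryo's inherited genome
#'
#' Transmits one haplotype per parent per chromosome with Poisson-distributed
#' crossovers, honours forced transmissions of planted variants (by flipping
#' the transmitted haplotype labelling of the whole chromosome, preserving
#' the crossover structure), and plants Poisson-distributed de novo SNVs at
#' genomic allele fraction 0.5. Male embryos receive no paternal X.
#'
#' @param parents [simulate_parents()] output.
#' @param params [sim_params()].
#' @param embryo_id Sample id.
#' @param sex `"male"` or `"female"`.
#' @return A `sim_embryo` list: `transmission` (per-site transmitted
#'   alleles), `denovo` (planted de novo site table), `breakpoints`, `sex`.
#' @export
simulate_embryo <- function(parents, params = parents$params,
                            embryo_id = "embryo1", sex = "female") {
  sites <- parents$sites
  pv <- params$planted_variants
  chroms <- names(params$chrom_lengths)

  draw_crossovers <- function(len) {
    k <- rpois(1, params$crossover_rate)
    list(bp = sort(runif(k, 0, len)), start = sample(1:2, 1))
  }
  pick_hap <- function(cx, pos) {
    1L + (cx$start - 1L + findInterval(pos, cx$bp)) %% 2L
  }

  transmission <- list()
  breakpoints <- list()
  for (chrom in chroms) {
    idx <- which(sites$chrom == chrom)
    s <- sites[idx, ]
    len <- params$chrom_lengths[[chrom]]
    is_x <- chrom == "chrX"
    # paternal
    if (is_x && sex == "male") {
      pat <- rep(NA_integer_, nrow(s))
      pat_hap <- rep(NA_integer_, nrow(s))
    } else if (is_x) {
      pat <- s$f1
      pat_hap <- rep(1L, nrow(s))
    } else {
      f_cx <- draw_crossovers(len)
      breakpoints[[paste0(chrom, "_pat")]] <- f_cx$bp
      pat_hap <- pick_hap(f_cx, s$pos)
      pat <- if_else(pat_hap == 1L, s$f1, s$f2)
    }
    m_cx <- draw_crossovers(len)
    breakpoints[[paste0(chrom, "_mat")]] <- m_cx$bp
    mat_hap <- pick_hap(m_cx, s$pos)
    mat <- if_else(mat_hap == 1L, s$m1, s$m2)

    # forced transmission for planted variants on this chromosome: flip the
    # whole chromosome's transmitted-haplotype labelling (preserves the
    # crossover structure and flank/variant phase consistency)
    planted_here <- which(!is.na(s$planted))
    for (j in planted_here) {
      i <- s$planted[j]
      if (embryo_limited(pv, i, embryo_id)) next
      want_f <- forced_allele(pv, i, "father")
      want_m <- forced_allele(pv, i, "mother")
      if (!is.na(want_f) && !(is_x && sex == "male")) {
        if (pat[j] != want_f) {
          if (is_x) {
            stop("planted variant '", pv$gene[i],
                 "': father X cannot transmit the requested allele",
                 call. = FALSE)
          }
          pat_hap <- 3L - pat_hap
          pat <- if_else(pat_hap == 1L, s$f1, s$f2)
          if (pat[j] != want_f) {
            stop("planted variant '", pv$gene[i],
                 "': father genotype cannot transmit the requested allele",
                 call. = FALSE)
          }
        }
      }
      if (!is.na(want_m)) {
        if (mat[j] != want_m) {
          mat_hap <- 3L - mat_hap
          mat <- if_else(mat_hap == 1L, s$m1, s$m2)
          if (mat[j] != want_m) {
            stop("planted variant '", pv$gene[i],
                 "': mother genotype cannot transmit the requested allele",
                 call. = FALSE)
          }
        }
      }
    }
    transmission[[chrom]] <- tibble(
      key = s$key, pat = pat, mat = mat,
      pat_hap = pat_hap, mat_hap = mat_hap
    )
  }
  transmission <- bind_rows(transmission)

  # de novo SNVs
  lens <- params$chrom_lengths
  rate <- params$denovo_rate *
    if (params$scale_denovo) sum(lens) / params$genome_full else 1
  n_dn <- rpois(1, rate)
  dn_chrom <- sample(names(lens), n_dn, replace = TRUE,
                     prob = lens / sum(lens))
  dn <- tibble(
    chrom = dn_chrom,
    pos = vapply(dn_chrom, function(ch) sample.int(lens[[ch]] - 10L, 1),
                 integer(1)),
    hap = sample(c("pat", "mat"), n_dn, replace = TRUE)
  )
  al <- draw_alleles_snv(n_dn, params)
  dn <- bind_cols(dn, al) |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
           planted = FALSE) |>
    filter(!.data$key %in% sites$key)

  # planted de novo conditions
  if (!is.null(pv) && any(pv$de_novo)) {
    gm <- parents$gene_map
    for (i in which(pv$de_novo)) {
      if (embryo_limited(pv, i, embryo_id)) next
      g <- gm[gm$gene == pv$gene[i], ]
      dn <- bind_rows(dn, tibble(
        chrom = g$chrom, pos = as.integer(g$start + pv$offset[i]),
        hap = "mat", ref = pv$ref[i], alt = pv$alt[i],
        key = variant_key(g$chrom, g$start + pv$offset[i], pv$ref[i],
                          pv$alt[i]),
        planted = TRUE
      ))
    }
  }

  structure(
    list(embryo_id = embryo_id, sex = sex, transmission = transmission,
         denovo = dn, breakpoints = breakpoints, params = params),
    class = "sim_embryo"
  )
}

# TRUE when a planted row is restricted to other embryos.
embryo_limited <- function(pv, i, embryo_id) {
  !is.na(pv$embryos[i]) &&
    !embryo_id %in% strsplit(pv$embryos[i], ",", fixed = TRUE)[[1]]
}

# Desired transmitted allele for a planted variant. An explicit
# transmit_father/transmit_mother spec ("alt"/"ref") forces the allele and
# is validated against the parental genotype; otherwise homozygous parents
# transmit their only allele and heterozygous carriers transmit at random.
forced_allele <- function(pv, i, who) {
  gt_col <- paste0(who, "_gt")
  tr_col <- paste0("transmit_", who)
  a <- as.integer(strsplit(pv[[gt_col]][i], "|", fixed = TRUE)[[1]])
  want <- if (tr_col %in% names(pv)) pv[[tr_col]][i] else NA_character_
  if (!is.na(want)) {
    allele <- if (want == "alt") 1L else 0L
    if (!allele %in% a) {
      stop("planted variant '", pv$gene[i], "': ", who,
           " genotype ", pv[[gt_col]][i], " cannot transmit the requested '",
           want, "' allele", call. = FALSE)
    }
    return(allele)
  }
  if (all(a == 0L)) return(NA_integer_)
  if (all(a == 1L)) return(1L)
  NA_integer_
}

draw_alleles_snv <- function(n, params) {
  p <- params
  p$p_indel <- 0
  draw_alleles(n, p)
}

#' Apply the amplification model to an embryo
#'
#' Converts the embryo's true genome into VCF-ready calls under the
#' multiple-displacement-amplification model: allele-dropout regions erase
#' one parental haplotype's evidence (heterozygotes appear homozygous for
#' the remaining allele), false heterozygotes appear at new positions with
#' VAFs from the scaled-beta artifact distribution (mode 0.26), true
#' heterozygous allele depths are binomial at 0.5, and the depth track is
#' degraded by regional amplification waves so about 87.5% of the genome
#' reaches 20x. Planted copy-number events scale depth by copy/2; calls at
#' zero depth are missing.
#'
#' @param embryo [simulate_embryo()] output.
#' @param parents [simulate_parents()] output.
#' @param params [sim_params()].
#' @return A `sim_mda` list: `calls` (long call tibble), `track`,
#'   `dropout_regions`, `artifacts`, `denovo_calls`, plus per-site truth.
#' @export
simulate_mda <- function(embryo, parents, params = parents$params) {
  sites <- parents$sites
  tr <- embryo$transmission
  stopifnot(identical(sites$key, tr$key))
  lens <- params$chrom_lengths

  # dropout regions
  n_do <- rpois(1, params$dropout_rate)
  do_chrom <- sample(names(lens), n_do, replace = TRUE,
                     prob = lens / sum(lens))
  do_len <- runif(n_do, params$dropout_min_length, params$dropout_max_length)
  # clamp to half the chromosome on miniature genomes
  do_len <- pmin(do_len, vapply(do_chrom, function(ch) lens[[ch]] / 2,
                                numeric(1)))
  do_start <- vapply(seq_len(n_do), function(i) {
    runif(1, 0, lens[[do_chrom[i]]] - do_len[i])
  }, numeric(1))
  dropout <- tibble(
    chrom = do_chrom, start = do_start, end = do_start + do_len,
    dropped_hap = sample(c("pat", "mat"), n_do, replace = TRUE)
  )

  # regional amplification waves + planted CNV copy scaling
  waves <- purrr::imap_dfr(as.list(lens), function(len, chrom) {
    starts <- seq(0, len - params$wave_region, by = params$wave_region)
    tibble(chrom = chrom, start = starts, end = starts + params$wave_region,
           mult = rlnorm(length(starts), -params$wave_sd^2 / 2,
                         params$wave_sd))
  })
  cnvs <- params$planted_cnvs
  cnvs <- if (is.null(cnvs)) tibble() else
    filter(cnvs, .data$sample == embryo$embryo_id)
  mult_at <- function(chrom, pos) {
    wi <- match(
      paste(chrom, floor(pos / params$wave_region)),
      paste(waves$chrom, floor(waves$start / params$wave_region))
    )
    m <- waves$mult[wi]
    if (nrow(cnvs) > 0) {
      for (i in seq_len(nrow(cnvs))) {
        hit <- chrom == cnvs$chrom[i] & pos > cnvs$start[i] &
          pos <= cnvs$end[i]
        m[hit] <- m[hit] * cnvs$copy[i] / 2
      }
    }
    m
  }

  # --- true sites -----------------------------------------------------------
  n <- nrow(sites)
  in_dropout <- rep(FALSE, n)
  dropped_side <- rep(NA_character_, n)
  if (nrow(dropout) > 0) {
    for (i in seq_len(nrow(dropout))) {
      hit <- sites$chrom == dropout$chrom[i] & sites$pos > dropout$start[i] &
        sites$pos <= dropout$end[i]
      in_dropout <- in_dropout | hit
      dropped_side[hit] <- dropout$dropped_hap[i]
    }
  }
  pat <- tr$pat
  mat <- tr$mat
  hemi <- is.na(pat)   # male X: maternal only
  drop_pat <- in_dropout & !is.na(dropped_side) & dropped_side == "pat" & !hemi
  drop_mat <- in_dropout & !is.na(dropped_side) & dropped_side == "mat"
  obs_pat <- ifelse(drop_pat | hemi, NA_integer_, pat)
  obs_mat <- ifelse(drop_mat, NA_integer_, mat)
  n_left <- (!is.na(obs_pat)) + (!is.na(obs_mat))
  one_left <- dplyr::coalesce(obs_pat, obs_mat)

  dp <- rnbinom(n, size = params$depth_size_embryo,
                mu = params$mean_depth_embryo * mult_at(sites$chrom, sites$pos))
  erased <- n_left == 0L | dp == 0L
  het <- !erased & n_left == 2L & obs_pat != obs_mat
  true_gt <- dplyr::case_when(
    erased & hemi ~ ".",
    erased ~ "./.",
    n_left == 1L & hemi ~ as.character(one_left),
    n_left == 1L ~ paste0(one_left, "/", one_left),   # dropout: apparent hom
    het ~ "0/1",
    TRUE ~ paste0(obs_pat, "/", obs_mat)
  )
  ad_alt <- integer(n)
  ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  all_alt <- !erased & !het &
    ((n_left == 1L & one_left == 1L) |
       (n_left == 2L & obs_pat == 1L & obs_mat == 1L))
  all_alt[is.na(all_alt)] <- FALSE
  ad_alt[all_alt] <- dp[all_alt]
  gq <- pmin(99L, pmax(0L, as.integer(round(dp * 2 + rnorm(n, 0, 5)))))
  calls <- tibble(
    key = sites$key, sample_id = embryo$embryo_id, gt = true_gt,
    ad_ref = as.integer(dp - ad_alt), ad_alt = as.integer(ad_alt),
    dp = as.integer(dp), gq = as.numeric(gq)
  )

  # --- de novo sites --------------------------------------------------------
  dn <- embryo$denovo
  dn_dp <- rnbinom(nrow(dn), size = params$depth_size_embryo,
                   mu = params$mean_depth_embryo * mult_at(dn$chrom, dn$pos))
  dn_ad <- integer(nrow(dn))
  dn_gt <- character(nrow(dn))
  for (i in seq_len(nrow(dn))) {
    if (dn$planted[i]) {
      dn_dp[i] <- max(dn_dp[i], 21L)
      dn_ad[i] <- as.integer(round(0.63 * dn_dp[i]))
    } else {
      dn_ad[i] <- rbinom(1, dn_dp[i], 0.5)
    }
    male_x <- dn$chrom[i] == "chrX" && embryo$sex == "male"
    dn_gt[i] <- if (male_x) "1" else "0/1"
  }
  denovo_calls <- tibble(
    key = dn$key, sample_id = embryo$embryo_id, gt = dn_gt,
    ad_ref = as.integer(dn_dp - dn_ad), ad_alt = as.integer(dn_ad),
    dp = as.integer(dn_dp),
    gq = pmin(99, pmax(0, round(dn_dp * 2 + rnorm(nrow(dn), 0, 5)))),
    qd = if_else(dn$planted, 20.9,
                 pmax(1, rnorm(nrow(dn), 25, 5)))
  )

  # --- artifact false heterozygotes ----------------------------------------
  n_art <- rpois(1, params$artifact_het_rate * sum(lens))
  art_chrom <- sample(names(lens), n_art, replace = TRUE,
                      prob = lens / sum(lens))
  art <- tibble(
    chrom = art_chrom,
    pos = vapply(art_chrom, function(ch) sample.int(lens[[ch]] - 10L, 1),
                 integer(1))
  )
  al <- draw_alleles_snv(n_art, params)
  av <- params$artifact_vaf
  art <- bind_cols(art, al) |>
    mutate(
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      vaf_true = av$lo + (av$hi - av$lo) * rbeta(n(), av$shape1, av$shape2)
    ) |>
    filter(!.data$key %in% c(sites$key, dn$key)) |>
    distinct(.data$key, .keep_all = TRUE)
  art_dp <- pmax(2L, rnbinom(nrow(art), size = params$depth_size_embryo,
                             mu = params$mean_depth_embryo *
                               mult_at(art$chrom, art$pos)))
  art_ad <- pmax(1L, as.integer(round(art$vaf_true * art_dp)))
  artifact_calls <- tibble(
    key = art$key, sample_id = embryo$embryo_id, gt = "0/1",
    ad_ref = as.integer(art_dp - art_ad), ad_alt = art_ad,
    dp = as.integer(art_dp),
    gq = round(runif(nrow(art), 5, 60)),
    qd = pmax(0.5, rgamma(nrow(art), shape = 2, scale = 3.5))
  )

  # --- depth track ----------------------------------------------------------
  track <- purrr::imap_dfr(as.list(lens), function(len, chrom) {
    starts <- seq(0, len - params$track_bin, by = params$track_bin)
    tibble(sample_id = embryo$embryo_id, chrom = chrom, start = starts,
           end = starts + params$track_bin,
           depth = rnbinom(length(starts), size = params$depth_size_embryo,
                           mu = params$mean_depth_embryo *
                             mult_at(chrom, starts + params$track_bin / 2)))
  })

  structure(
    list(
      embryo_id = embryo$embryo_id, sex = embryo$sex,
      calls = calls, denovo_calls = denovo_calls,
      artifact_calls = artifact_calls,
      denovo = dn, artifacts = art,
      dropout_regions = dropout, track = track,
      in_dropout = in_dropout, true_gt = true_gt
    ),
    class = "sim_mda"
  )
}

#' Simulate a complete family
#'
#' Parents, `n_embryos` embryos through meiosis and the amplification model,
#' tandem-repeat genotypes, and the assembled ground-truth ledger.
#'
#' @param params [sim_params()].
#' @return A `sim_family` list with `parents`, `embryos` (list of `sim_mda`
#'   results), `pedigree`, `str_genotypes`, `truth` (list of `variants`,
#'   `regions`, `conditions`) and `params`.
#' @export
simulate_family <- function(params = sim_params()) {
  parents <- simulate_parents(params)
  sexes <- rep(params$embryo_sexes, length.out = params$n_embryos)
  embryos <- list()
  for (i in seq_len(params$n_embryos)) {
    eid <- paste0("embryo", i)
    emb <- simulate_embryo(parents, params, eid, sexes[i])
    embryos[[eid]] <- simulate_mda(emb, parents, params)
    embryos[[eid]]$meiosis <- emb
  }
  pedigree <- tibble(
    sample_id = c("father", "mother", names(embryos)),
    role = c("father", "mother", rep("embryo", length(embryos))),
    sex = c("male", "female", sexes),
    father_id = c(NA, NA, rep("father", length(embryos))),
    mother_id = c(NA, NA, rep("mother", length(embryos)))
  )
  str_genotypes <- simulate_str(params, pedigree)
  annotations <- simulate_annotations(parents, embryos, params)
  truth <- assemble_truth(parents, embryos, params)
  structure(
    list(parents = parents, embryos = embryos, pedigree = pedigree,
         str_genotypes = str_genotypes, annotations = annotations,
         truth = truth, params = params),
    class = "sim_family"
  )
}

simulate_str <- function(params, pedigree) {
  panel <- str_panel()
  draw <- function() {
    vapply(seq_len(nrow(panel)), function(i) {
      sample.int(max(panel$normal_max[i] - 4L, 2L), 1) + 4L
    }, integer(1))
  }
  f1 <- draw(); f2 <- draw(); m1 <- draw(); m2 <- draw()
  out <- list(
    tibble(locus = panel$locus, sample_id = "father",
           allele_1 = if_else(panel$x_linked, f1, f1),
           allele_2 = if_else(panel$x_linked, NA_integer_, f2)),
    tibble(locus = panel$locus, sample_id = "mother",
           allele_1 = m1, allele_2 = m2)
  )
  emb <- filter(pedigree, .data$role == "embryo")
  for (i in seq_len(nrow(emb))) {
    from_f <- if_else(runif(nrow(panel)) < 0.5, f1, f2)
    from_f[panel$x_linked] <- f1[panel$x_linked]
    from_m <- if_else(runif(nrow(panel)) < 0.5, m1, m2)
    slip <- function(x) {
      s <- runif(length(x)) < params$str_discord_rate
      x + if_else(s, sample(c(-2L, -1L, 1L, 2L), length(x), replace = TRUE),
                  0L)
    }
    male <- emb$sex[i] == "male"
    a1 <- slip(from_f)
    a2 <- slip(from_m)
    out[[length(out) + 1]] <- tibble(
      locus = panel$locus, sample_id = emb$sample_id[i],
      allele_1 = if_else(panel$x_linked & male, slip(from_m), a1),
      allele_2 = if_else(panel$x_linked & male, NA_integer_, a2)
    )
  }
  bind_rows(out)
}

assemble_truth <- function(parents, embryos, params) {
  sites <- parents$sites
  pv <- params$planted_variants
  variants <- purrr::imap_dfr(embryos, function(e, eid) {
    tr <- e$meiosis$transmission
    pat <- tr$pat; mat <- tr$mat
    origin <- case_when(
      dplyr::coalesce(pat, 0L) == 1L & dplyr::coalesce(mat, 0L) == 1L ~ "both",
      dplyr::coalesce(pat, 0L) == 1L ~ "paternal",
      dplyr::coalesce(mat, 0L) == 1L ~ "maternal",
      TRUE ~ "none"
    )
    bind_rows(
      tibble(key = sites$key, embryo_id = eid, origin = origin,
             true_gt = e$true_gt, dp = e$calls$dp, in_dropout = e$in_dropout,
             planted_idx = sites$planted),
      tibble(key = e$denovo$key, embryo_id = eid, origin = "de_novo",
             true_gt = e$denovo_calls$gt, dp = e$denovo_calls$dp,
             in_dropout = FALSE,
             planted_idx = if_else(e$denovo$planted,
                                   find_planted_denovo(pv), NA_integer_)),
      tibble(key = e$artifacts$key, embryo_id = eid, origin = "artifact",
             true_gt = "0/0", dp = e$artifact_calls$dp, in_dropout = FALSE,
             planted_idx = NA_integer_)
    )
  })
  regions <- bind_rows(
    purrr::imap_dfr(embryos, function(e, eid) {
      mutate(e$dropout_regions, sample_id = eid, type = "dropout",
             detail = .data$dropped_hap) |>
        select("sample_id", "type", "chrom", "start", "end", "detail")
    }),
    if (!is.null(params$planted_cnvs) && nrow(params$planted_cnvs) > 0) {
      params$planted_cnvs |>
        mutate(type = "cnv", detail = paste0("copy", .data$copy)) |>
        select(sample_id = "sample", "type", "chrom", "start", "end", "detail")
    }
  )
  conditions <- truth_conditions(parents, embryos, params, variants)
  list(variants = variants, regions = regions, conditions = conditions)
}

find_planted_denovo <- function(pv) {
  if (is.null(pv)) return(NA_integer_)
  idx <- which(pv$de_novo)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

# Expected per-embryo status for every planted condition, from true genotypes.
truth_conditions <- function(parents, embryos, params, variants) {
  pv <- params$planted_variants
  if (is.null(pv) || nrow(pv) == 0) return(tibble())
  gm <- parents$gene_map
  pv <- pv |>
    left_join(gm, by = "gene") |>
    mutate(pos = .data$start + .data$offset,
           key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  purrr::imap_dfr(embryos, function(e, eid) {
    purrr::map_dfr(unique(pv$gene), function(g) {
      rows <- filter(pv, .data$gene == g)
      mode <- rows$mode[1]
      tgt <- variants |>
        filter(.data$embryo_id == eid, .data$key %in% rows$key)
      n_alt <- sum(gt_alt_count(tgt$true_gt), na.rm = TRUE)
      # empty tgt (condition not planted in this embryo) is trivially covered
      covered <- all(!gt_is_missing(tgt$true_gt)) &&
        all(!tgt$in_dropout) && all(tgt$dp >= 10)
      status <- switch(
        mode,
        dominant_het = if (n_alt >= 1) "affected" else "unaffected",
        recessive_hom = dplyr::case_when(
          n_alt >= 2 ~ "affected", n_alt == 1 ~ "carrier",
          TRUE ~ "unaffected"),
        x_linked = {
          male <- e$sex == "male"
          if (male) {
            if (n_alt >= 1) "affected" else "unaffected"
          } else {
            dplyr::case_when(n_alt >= 2 ~ "affected", n_alt == 1 ~ "carrier",
                             TRUE ~ "unaffected")
          }
        },
        compound_het = {
          per_site <- gt_alt_count(tgt$true_gt) > 0
          if (nrow(tgt) == nrow(rows) && all(per_site)) "affected"
          else if (any(per_site)) "carrier" else "unaffected"
        },
        de_novo = if (nrow(tgt) > 0 && n_alt >= 1) "affected" else "unaffected"
      )
      tibble(embryo_id = eid, gene = g, mode = mode,
             keys = paste(rows$key, collapse = ","),
             expected_status = status, covered = covered)
    })
  })
}
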