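#' Compute embryo variant allele fractions
#'
#' VAF = alternate-supporting reads / total reads at the site, from the
#' embryo's AD and DP fields; undefined (NA) at zero depth. Also records the
#' variant class (amplification artifacts affect substitutions and longer
#' deletions differently).
#'
#' @param candidates Tibble with `ad_alt_e`, `dp_e`, `ref`, `alt` columns
#'   (trio layout).
#' @return The input with `vaf` and `variant_class` columns.
#' @export
compute_vaf <- function(candidates) {
  candidates |>
    mutate(
      vaf = if_else(!is.na(.data$dp_e) & .data$dp_e > 0,
                    .data$ad_alt_e / .data$dp_e, NA_real_),
      variant_class = variant_class(.data$ref, .data$alt)
    )
}

as_gate_result <- function(x) {
  if (inherits(x, "gate_result")) return(x)
  structure(
    list(retained = x, rejected = mutate(x[0, ], reject_reason = character(0))),
    class = "gate_result"
  )
}

gate_apply <- function(x, reject, reason) {
  g <- as_gate_result(x)
  newly <- mutate(g$retained[reject, , drop = FALSE], reject_reason = reason)
  structure(
    list(
      retained = g$retained[!reject, , drop = FALSE],
      rejected = bind_rows(g$rejected, newly)
    ),
    class = "gate_result"
  )
}

#' Variant-allele-fraction gate for de novo candidates
#'
#' Rejects de novo candidates whose embryo VAF is strictly below the
#' threshold — the signature of multiple-displacement-amplification false
#' heterozygotes, whose VAFs peak near 0.26 — keeping the rejected list for
#' the failsafe/curation path. Missing VAF rejects with reason
#' `"vaf_missing"`. By default all variant classes are gated; restrict
#' `classes` to exempt, e.g., longer deletions.
#'
#' @param candidates Candidate tibble carrying `vaf` and `variant_class`
#'   (see [compute_vaf()]), or a previous gate result to compose gates.
#' @param threshold Rejection bound; VAF `>= threshold` is retained.
#' @param classes Variant classes the gate applies to.
#' @return A `gate_result`: list of `retained` and `rejected` tibbles
#'   (rejected rows carry `reject_reason`).
#' @export
vaf_gate <- function(candidates, threshold = 0.35,
                     classes = c("snv", "insertion", "deletion_gt1bp", "other")) {
  g <- as_gate_result(candidates)
  x <- g$retained
  gated <- x$variant_class %in% classes
  g <- gate_apply(g, gated & is.na(x$vaf), "vaf_missing")
  x2 <- g$retained
  low2 <- x2$variant_class %in% classes & !is.na(x2$vaf) & x2$vaf < threshold
  gate_apply(g, low2, sprintf("vaf_below_%.2f", threshold))
}

#' Quality-by-depth gate for novel de novo candidates
#'
#' Rejects candidates whose site QD is not strictly above the threshold.
#' Applied only to the non-dbSNP (novel) subfilter — transmitted and
#' catalogued variants are not QD-gated. Missing QD rejects with reason
#' `"qd_missing"`.
#'
#' @param candidates Candidate tibble with `qd` and `subfilter` columns, or a
#'   gate result.
#' @param threshold Strict lower bound (retained iff `qd > threshold`).
#' @param subfilters Subfilters the gate applies to (default `"novel"`).
#' @return A `gate_result` (see [vaf_gate()]).
#' @export
qd_gate <- function(candidates, threshold = 12, subfilters = "novel") {
  g <- as_gate_result(candidates)
  x <- g$retained
  gated <- if ("subfilter" %in% names(x)) x$subfilter %in% subfilters else
    rep(TRUE, nrow(x))
  g <- gate_apply(g, gated & is.na(x$qd), "qd_missing")
  x2 <- g$retained
  gated2 <- if ("subfilter" %in% names(x2)) x2$subfilter %in% subfilters else
    rep(TRUE, nrow(x2))
  gate_apply(g, gated2 & !is.na(x2$qd) & x2$qd <= threshold,
             sprintf("qd_le_%g", threshold))
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Gate result: %d retained, %d rejected\n",
              nrow(x$retained), nrow(x$rejected)))
  if (nrow(x$rejected) > 0) {
    print(dplyr::count(x$rejected, .data$reject_reason))
  }
  invisible(x)
}

#' Per-sample VAF histogram counts
#'
#' Bins VAF values into fixed-width bins (default 0.02), the representation
#' used to locate the artifact VAF mode.
#'
#' @param vaf Numeric VAF values in \[0, 1\].
#' @param binwidth Bin width.
#' @return Tibble with `bin_mid` and `count`, one row per non-empty bin.
#' @export
vaf_histogram <- function(vaf, binwidth = 0.02) {
  vaf <- vaf[!is.na(vaf)]
  bin <- floor(vaf / binwidth + 0.5)   # bins centred on multiples of binwidth
  tibble(bin_mid = sort(unique(bin)) * binwidth) |>
    mutate(count = as.integer(table(factor(bin, levels = sort(unique(bin)))))) |>
    arrange(.data$bin_mid)
}

#' Mode of a VAF distribution from its histogram
#'
#' @inheritParams vaf_histogram
#' @return The midpoint of the most populated bin.
#' @export
vaf_mode <- function(vaf, binwidth = 0.02) {
  h <- vaf_histogram(vaf, binwidth)
  h$bin_mid[which.max(h$count)]
}
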