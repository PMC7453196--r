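#' Mutation copy number from VAF, purity and copy number
#'
#' The mutation copy number \eqn{n_{mut}} is the product of the cancer cell
#' fraction and the number of mutated chromosomal copies (multiplicity). It is
#' obtained by inverting the expected-VAF relation:
#' \deqn{n_{mut} = VAF \cdot \frac{\rho\,CN_t + (1-\rho)\,CN_n}{\rho}.}
#'
#' @param vaf Observed variant allele frequency in \[0, 1\] (vectorised).
#' @param purity Tumour purity \eqn{\rho} in (0, 1].
#' @param cn_tumour,cn_normal Total tumour / normal copy number at the locus.
#' @return Mutation copy number (non-negative, may exceed 1).
#' @examples
#' mutation_copy_number(0.5, 1, 2, 2)    # 1: clonal het in a pure diploid
#' mutation_copy_number(0.25, 0.5, 2, 2) # 1: clonal het at 50% purity
#' @export
mutation_copy_number <- function(vaf, purity, cn_tumour = 2, cn_normal = 2) {
  if (any(purity <= 0 | purity > 1, na.rm = TRUE)) {
    abort_input("`purity` must lie in (0, 1]")
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) {
    abort_input("`vaf` must lie in [0, 1]")
  }
  vaf * (purity * cn_tumour + (1 - purity) * cn_normal) / purity
}

# CCF plausibility policy: values in (1, 1.5] are clipped to 1 and flagged
# `capped`; values > 1.5 are flagged `implausible` and excluded from
# clustering. Low-depth cells (< 10 reads) are flagged but kept.
CCF_CAP_LIMIT <- 1.5
LOW_DEPTH <- 10L

#' Multiplicity and CCF of a single SNV by binomial maximum likelihood
#'
#' Chooses the number of mutated copies \eqn{m} among `1..cn_major` that
#' maximises the binomial likelihood of the observed alt count given the VAF
#' expected for a clonal mutation on \eqn{m} copies, then converts the
#' mutation copy number to a CCF estimate `ccf = n_mut / m`. CCF values in
#' (1, 1.5] are capped at 1 (`capped = TRUE`); values above 1.5 are flagged
#' implausible.
#'
#' @param alt,depth Mutant read count and total depth (vectorised; depth > 0).
#' @param purity Sample purity in (0, 1].
#' @param cn_tumour Total tumour copy number at the locus.
#' @param cn_major Major allele copy number; the multiplicity search upper
#'   bound (an SNV cannot occupy more copies than the major allele).
#' @param cn_normal Normal-cell copy number (2 on autosomes).
#' @return Tibble with columns `multiplicity`, `mutation_cn`, `ccf`, `capped`,
#'   `implausible`.
#' @examples
#' assign_multiplicity(30, 60, 1, 2, 1)  # m = 1, ccf = 1
#' assign_multiplicity(28, 40, 1, 3, 2)  # m = 2, ccf capped to 1
#' @export
assign_multiplicity <- function(alt, depth, purity, cn_tumour, cn_major,
                                cn_normal = 2) {
  n <- length(alt)
  stopifnot(length(depth) == n)
  if (any(depth <= 0)) abort_input("`depth` must be positive; flag zero-depth cells upstream")
  if (any(alt > depth)) abort_input("`alt` cannot exceed `depth`")
  if (any(cn_major < 1)) abort_input("`cn_major` must be >= 1")
  purity <- rep_len(purity, n)
  cn_tumour <- rep_len(cn_tumour, n)
  cn_major <- as.integer(rep_len(cn_major, n))
  cn_normal <- rep_len(cn_normal, n)
  m_best <- integer(n)
  ll_best <- rep(-Inf, n)
  for (m in seq_len(max(cn_major))) {
    active <- m <= cn_major
    p <- expected_vaf(rep(1, sum(active)), pmin(m, cn_tumour[active]),
                      purity[active], cn_tumour[active], cn_normal[active])
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll <- dbinom(alt[active], depth[active], p, log = TRUE)
    better <- ll > ll_best[active]
    idx <- which(active)[better]
    m_best[idx] <- m
    ll_best[idx] <- ll[better]
  }
  n_mut <- mutation_copy_number(alt / depth, purity, cn_tumour, cn_normal)
  ccf_raw <- n_mut / m_best
  tibble(
    multiplicity = m_best,
    mutation_cn = n_mut,
    ccf = ifelse(ccf_raw > CCF_CAP_LIMIT, NA_real_, pmin(ccf_raw, 1)),
    capped = ccf_raw > 1 & ccf_raw <= CCF_CAP_LIMIT,
    implausible = ccf_raw > CCF_CAP_LIMIT
  )
}

#' Per-SNV, per-sample CCF matrix from reads, segments and purities
#'
#' Looks up the allele-specific copy-number segment covering each SNV in each
#' sample, assigns multiplicity by binomial maximum likelihood and converts
#' the VAF to a CCF. Cells without a covering segment are flagged
#' `missing_cn`; zero-depth cells are flagged `zero_depth`; cells with fewer
#' than 10 reads are flagged `low_depth` but retained.
#'
#' @param reads Long SNV read tibble (`snv_id`, `chrom`, `pos`, `sample_id`,
#'   `alt_count`, `depth`), e.g. from [simulate_reads()] or [read_snv_table()].
#' @param segments Copy-number segments (`sample_id`, `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`), 0-based half-open.
#' @param purities Tibble (`sample_id`, `purity`).
#' @param cn_normal Normal copy number (2; autosomes only by default).
#' @return A `ccf_matrix` tibble: one row per SNV x sample with `vaf`,
#'   `cn_major`, `cn_minor`, `cn_tumour`, `purity`, `multiplicity`,
#'   `mutation_cn`, `ccf` and logical flags `capped`, `implausible`,
#'   `missing_cn`, `zero_depth`, `low_depth`.
#' @export
compute_ccf <- function(reads, segments, purities, cn_normal = 2) {
  check_reads(reads)
  missing_p <- setdiff(unique(reads$sample_id), purities$sample_id)
  if (length(missing_p) > 0) {
    abort_input("no purity for sample(s): %s", paste(missing_p, collapse = ", "))
  }
  segs <- as_tibble(segments) %>%
    mutate(cn_tumour = .data$major_cn + .data$minor_cn)
  x <- reads %>%
    left_join(purities %>% select(all_of(c("sample_id", "purity"))),
              by = "sample_id") %>%
    mutate(pos0 = .data$pos - 1L) %>%
    left_join(segs, by = join_by("sample_id", "chrom",
                                 between(x$pos0, y$start, y$end, bounds = "[)")))
  finish_ccf(x, cn_normal)
}

#' CCF assuming diploid loci (copy-number-free targeted data)
#'
#' For targeted sequencing without reliable copy-number calls, restrict the
#' input to loci known (or assumed) diploid and estimate CCF with
#' \eqn{CN_t = CN_n = 2} and multiplicity 1, so `ccf = 2 vaf / purity`.
#' Purity can come from [estimate_purity_from_vaf_peak()].
#'
#' @inheritParams compute_ccf
#' @param purities Tibble (`sample_id`, `purity`), or a single number applied
#'   to every sample.
#' @return A `ccf_matrix` tibble as in [compute_ccf()] (no cell can be
#'   `missing_cn`).
#' @export
ccf_assuming_diploid <- function(reads, purities) {
  check_reads(reads)
  if (is.numeric(purities) && length(purities) == 1) {
    purities <- tibble(sample_id = unique(reads$sample_id), purity = purities)
  }
  x <- reads %>%
    left_join(purities %>% select(all_of(c("sample_id", "purity"))),
              by = "sample_id") %>%
    mutate(major_cn = 1L, minor_cn = 1L, cn_tumour = 2L)
  finish_ccf(x, cn_normal = 2)
}

# shared tail of the two CCF constructors: flags + multiplicity + class
finish_ccf <- function(x, cn_normal) {
  x <- x %>%
    mutate(
      missing_cn = is.na(.data$cn_tumour),
      zero_depth = .data$depth == 0,
      low_depth = .data$depth > 0 & .data$depth < LOW_DEPTH,
      vaf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
      multiplicity = NA_integer_, mutation_cn = NA_real_, ccf = NA_real_,
      capped = FALSE, implausible = FALSE
    )
  ok <- !x$missing_cn & !x$zero_depth
  if (any(ok)) {
    est <- assign_multiplicity(x$alt_count[ok], x$depth[ok], x$purity[ok],
                               x$cn_tumour[ok], x$major_cn[ok], cn_normal)
    x$multiplicity[ok] <- est$multiplicity
    x$mutation_cn[ok] <- est$mutation_cn
    x$ccf[ok] <- est$ccf
    x$capped[ok] <- est$capped
    x$implausible[ok] <- est$implausible
  }
  out <- x %>%
    select(all_of(c("snv_id", "chrom", "pos", "sample_id", "alt_count",
                    "depth", "vaf", "cn_major" = "major_cn",
                    "cn_minor" = "minor_cn", "cn_tumour", "purity",
                    "multiplicity", "mutation_cn", "ccf", "capped",
                    "implausible", "missing_cn", "zero_depth", "low_depth")))
  class(out) <- c("ccf_matrix", class(out))
  out
}

check_reads <- function(reads) {
  need <- c("snv_id", "sample_id", "alt_count", "depth")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols) > 0) {
    abort_input("reads table is missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(reads) == 0) abort_input("reads table is empty")
  if (any(reads$alt_count > reads$depth)) {
    abort_input("alt_count exceeds depth for some rows")
  }
  invisible(reads)
}

#' Estimate tumour purity from the clonal VAF peak
#'
#' For copy-number-free targeted data restricted to diploid loci, the clonal
#' mutations form the VAF peak at \eqn{\rho/2}. A Gaussian kernel density
#' (Silverman's bandwidth, 512-point grid over \[0, 1\]) is fitted to the VAFs,
#' strict local maxima are located, the peak at the highest VAF is taken as
#' the clonal set, and purity is estimated as twice that VAF (capped at 1).
#'
#' @param vafs Numeric VAF values in \[0, 1\].
#' @param min_n Minimum number of values required (default 10).
#' @return Purity estimate in (0, 1].
#' @examples
#' estimate_purity_from_vaf_peak(rnorm(200, 0.35, 0.02))  # about 0.7
#' @export
estimate_purity_from_vaf_peak <- function(vafs, min_n = 10) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_n) {
    abort_input("need at least %d VAF values, got %d", min_n, length(vafs))
  }
  if (all(vafs == 0)) abort_input("all VAFs are zero; cannot locate a clonal peak")
  d <- density(vafs, bw = "nrd0", n = 512, from = 0, to = 1)
  y <- d$y
  # strict local maxima; ripples in the near-zero tail are not peaks
  is_peak <- c(FALSE, y[2:511] > y[1:510] & y[2:511] > y[3:512], FALSE) &
    y >= 0.01 * max(y)
  if (!any(is_peak)) {
    # monotone density: the boundary maximum is the only candidate
    peak_x <- d$x[which.max(y)]
  } else {
    peak_x <- max(d$x[is_peak])
  }
  min(1, 2 * peak_x)
}
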