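#' Keep only SNVs with identical copy-number status across samples
#'
#' Apparent presence/absence differences between samples can be manufactured
#' by copy-number aberrations rather than true clonal structure. This filter
#' keeps an SNV only if the allele-specific copy-number pair
#' (`major_cn`, `minor_cn`) at its locus is identical in every sample; SNVs
#' whose locus is uncovered by a segment in any sample are removed as
#' `ambiguous-cn`, and differing pairs as `cna-discordant`.
#'
#' @param reads SNV read tibble with `snv_id`, `chrom`, `pos`.
#' @param segments Per-sample copy-number segments (0-based half-open).
#' @param samples Character vector of sample ids that must all agree; default
#'   every sample present in `reads`.
#' @return Tibble (`snv_id`, `keep`, `reason`) with one row per SNV; `reason`
#'   is `NA` for kept SNVs, else `cna-discordant` or `ambiguous-cn`.
#' @export
cna_consistent_loci <- function(reads, segments, samples = NULL) {
  samples <- samples %||% unique(reads$sample_id)
  loci <- reads %>% distinct(.data$snv_id, .data$chrom, .data$pos)
  segs <- as_tibble(segments) %>% filter(.data$sample_id %in% samples)
  hits <- loci %>%
    tidyr::crossing(sample_id = samples) %>%
    mutate(pos0 = .data$pos - 1L) %>%
    left_join(segs, by = join_by("sample_id", "chrom",
                                 between(x$pos0, y$start, y$end, bounds = "[)")))
  hits %>%
    group_by(.data$snv_id) %>%
    summarise(
      n_covered = sum(!is.na(.data$major_cn)),
      n_states = n_distinct(paste(.data$major_cn, .data$minor_cn)),
      .groups = "drop"
    ) %>%
    mutate(
      reason = case_when(
        n_covered < length(samples) ~ "ambiguous-cn",
        n_states > 1 ~ "cna-discordant",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    ) %>%
    select(all_of(c("snv_id", "keep", "reason")))
}

#' Remove SNVs whose heterogeneity is explainable by copy number
#'
#' An SNV that appears lost in one sample but present in others is only
#' evidence of clonal heterogeneity if copy number cannot explain the loss.
#' This filter removes an SNV when, in a sample where it is effectively absent
#' (CCF < `absence_ccf` and at most `absence_alt` supporting reads), the locus
#' shows loss of heterozygosity or any total copy-number decrease relative to
#' every SNV-bearing sample — eliminating pseudo-heterogeneity before
#' clustering. The test is deliberately conservative: any CN explanation for
#' the loss disqualifies the SNV.
#'
#' @param ccf A `ccf_matrix` from [compute_ccf()] (needs `cn_major`,
#'   `cn_minor`, `cn_tumour` columns).
#' @param absence_ccf,absence_alt Absence thresholds: CCF below `absence_ccf`
#'   (default 0.05) with `alt_count` at or below `absence_alt` (default 1).
#' @return List with `ccf` (rows of removed SNVs dropped, class kept) and
#'   `report`, a tibble (`snv_id`, `keep`, `reason`) where `reason` is
#'   `loh-explains-loss` for removed SNVs.
#' @export
filter_pseudo_heterogeneity <- function(ccf, absence_ccf = 0.05,
                                        absence_alt = 1L) {
  stopifnot(inherits(ccf, "ccf_matrix"))
  per_cell <- ccf %>%
    mutate(
      absent = !.data$missing_cn & !.data$zero_depth &
        !is.na(.data$ccf) & .data$ccf < absence_ccf &
        .data$alt_count <= absence_alt,
      bearing = !.data$missing_cn & !.data$zero_depth & !.data$absent
    )
  verdict <- per_cell %>%
    group_by(.data$snv_id) %>%
    summarise(
      remove = any(.data$absent) && any(.data$bearing) &&
        cn_explains_loss(.data$absent, .data$bearing,
                         .data$cn_tumour, .data$cn_minor),
      .groups = "drop"
    )
  report <- verdict %>%
    mutate(keep = !.data$remove,
           reason = ifelse(.data$remove, "loh-explains-loss", NA_character_)) %>%
    select(all_of(c("snv_id", "keep", "reason")))
  kept <- ccf %>% semi_join(report %>% filter(.data$keep), by = "snv_id")
  class(kept) <- class(ccf)
  list(ccf = kept, report = report)
}

# TRUE if some absent sample has lower total CN than every bearing sample, or
# LOH (minor 0) while every bearing sample retains both alleles
cn_explains_loss <- function(absent, bearing, cn_tumour, cn_minor) {
  ab_cn <- cn_tumour[absent]
  ab_minor <- cn_minor[absent]
  be_cn <- cn_tumour[bearing]
  be_minor <- cn_minor[bearing]
  any(ab_cn < min(be_cn), na.rm = TRUE) ||
    any(ab_minor == 0 & all(be_minor > 0), na.rm = TRUE)
}
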