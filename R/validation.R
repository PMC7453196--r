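#' Call SNVs validated by an orthogonal capture experiment
#'
#' Applies the orthogonal-validation criteria to deep targeted resequencing of
#' SNVs first called in a discovery (e.g. WGS) experiment: a cell is excluded
#' when capture coverage is below `min_cov` (default 30x), otherwise the SNV
#' is *validated somatic* in that sample when supported by at least `min_alt`
#' alternate reads (default 2). The validation rate divides validated cells by
#' validated plus not-validated cells — low-coverage cells are excluded from
#' the denominator. When the capture table lacks a queried position entirely,
#' it is excluded with status `low-coverage-excluded`.
#'
#' @param wgs_calls Tibble of discovery calls: `snv_id` plus optionally
#'   `cluster_id` (rates are then also reported per cluster) and `sample_id`
#'   (restricting which cells are queried; otherwise all capture cells for
#'   the SNV are used).
#' @param capture_reads Tibble (`snv_id`, `sample_id`, `alt_count`, `depth`)
#'   from the validation experiment.
#' @param min_alt Minimum alternate reads to validate (default 2).
#' @param min_cov Minimum capture coverage; below it the cell is excluded
#'   (default 30).
#' @return List with `table` (per SNV x sample: `status` in
#'   validated / not-validated / low-coverage-excluded), `rate` (overall),
#'   and `rates_by_cluster` (tibble, if `cluster_id` was supplied).
#' @examples
#' validate_somatic(
#'   tibble::tibble(snv_id = "s1"),
#'   tibble::tibble(snv_id = "s1", sample_id = "A", alt_count = 2, depth = 40)
#' )$rate  # 1
#' @export
validate_somatic <- function(wgs_calls, capture_reads, min_alt = 2,
                             min_cov = 30) {
  wgs_calls <- as_tibble(wgs_calls)
  capture_reads <- as_tibble(capture_reads)
  keys <- intersect(c("snv_id", "sample_id"), names(wgs_calls))
  cells <- wgs_calls %>%
    left_join(capture_reads, by = keys)
  tab <- cells %>%
    mutate(status = case_when(
      is.na(.data$depth) | .data$depth < min_cov ~ "low-coverage-excluded",
      .data$alt_count >= min_alt ~ "validated",
      TRUE ~ "not-validated"
    ))
  assessed <- tab %>% filter(.data$status != "low-coverage-excluded")
  rate <- if (nrow(assessed) == 0) NA_real_ else {
    mean(assessed$status == "validated")
  }
  out <- list(table = tab, rate = rate)
  if ("cluster_id" %in% names(tab)) {
    out$rates_by_cluster <- assessed %>%
      group_by(.data$cluster_id) %>%
      summarise(n_validated = sum(.data$status == "validated"),
                n_assessed = n(),
                rate = .data$n_validated / .data$n_assessed,
                .groups = "drop")
  }
  out
}

#' Detect discovery SNVs in an independent (e.g. archival primary) sample
#'
#' A mutation is called detected when supported by at least `min_alt` reads
#' reporting the alternative allele (default 2).
#'
#' @param targeted_reads Tibble with `snv_id` and `alt_count` (per sample row
#'   if `sample_id` is present).
#' @param min_alt Minimum supporting reads (default 2).
#' @return The input with a logical `detected` column added.
#' @export
detect_in_primary <- function(targeted_reads, min_alt = 2) {
  as_tibble(targeted_reads) %>%
    mutate(detected = .data$alt_count >= min_alt)
}
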