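# File conventions (declared in every header we write):
#   * SNV positions are 1-based (VCF convention) in all inputs and outputs.
#   * Copy-number segments are 0-based half-open [start, end) (BED convention).
# Coordinate shifts happen only inside the segment-overlap joins.

#' Read a per-sample SNV read-count table
#'
#' Two dialects are supported. `format = "tsv"` reads the pipeline's wide
#' table: columns `chrom`, `pos` (1-based), `ref`, `alt`, then one
#' `<sample>_alt` and `<sample>_depth` pair per sample (comment lines start
#' with `#`). `format = "vcf"` reads a VCF with per-sample `AD`
#' (ref,alt allelic depths) or `AD` + `DP` FORMAT fields via the vcfR
#' package. Rows violating `0 <= alt <= depth` or duplicating a
#' (chrom, pos, alt) key are rejected with their positions named.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return Long tibble: `snv_id`, `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `alt_count`, `depth`.
#' @export
read_snv_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_snv_vcf(path))
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(wide))) {
    abort_input("TSV must have columns %s plus <sample>_alt/<sample>_depth",
                paste(need, collapse = ", "))
  }
  alt_cols <- grep("_alt$", setdiff(names(wide), "alt"), value = TRUE)
  samples <- sub("_alt$", "", alt_cols)
  if (length(samples) == 0 ||
      !all(paste0(samples, "_depth") %in% names(wide))) {
    abort_input("missing per-sample <sample>_alt / <sample>_depth column pairs")
  }
  wide <- wide %>% mutate(chrom = as.character(.data$chrom))
  key <- paste(wide$chrom, wide$pos, wide$alt)
  if (anyDuplicated(key)) {
    abort_input("duplicate SNV keys at rows: %s",
                paste(which(duplicated(key)), collapse = ", "))
  }
  long <- wide %>%
    rename(ref_allele = "ref", alt_allele = "alt") %>%
    mutate(snv_id = sprintf("snv%06d", row_number())) %>%
    tidyr::pivot_longer(cols = all_of(c(paste0(samples, "_alt"),
                                        paste0(samples, "_depth"))),
                        names_to = c("sample_id", ".value"),
                        names_pattern = "(.*)_(alt|depth)$") %>%
    rename(alt_count = "alt", ref = "ref_allele", alt = "alt_allele") %>%
    select(all_of(c("snv_id", "chrom", "pos", "ref", "alt", "sample_id",
                    "alt_count", "depth")))
  validate_read_rows(long, path)
}

read_snv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_input("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) abort_input("VCF lacks the per-sample AD FORMAT field")
  samples <- colnames(ad)
  ref_d <- apply(ad, 2, function(x) as.integer(sub(",.*", "", x)))
  # AD is "ref,alt[,...]"; take the first ALT depth
  alt_d <- apply(ad, 2, function(x) {
    as.integer(vapply(strsplit(x, ","), function(p) p[2], character(1)))
  })
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  depth <- if (!is.null(dp) && !all(is.na(dp))) dp else ref_d + alt_d
  long <- purrr::map_dfr(seq_along(samples), function(j) {
    tibble(snv_id = sprintf("snv%06d", seq_len(nrow(fix))),
           chrom = fix$CHROM, pos = as.integer(fix$POS),
           ref = fix$REF, alt = fix$ALT, sample_id = samples[j],
           alt_count = alt_d[, j], depth = as.integer(depth[, j]))
  })
  validate_read_rows(long, path)
}

validate_read_rows <- function(long, path) {
  bad <- which(is.na(long$alt_count) | is.na(long$depth) |
                 long$alt_count < 0 | long$alt_count > long$depth)
  if (length(bad) > 0) {
    abort_input("%s: %d malformed count cell(s), e.g. %s:%s in %s",
                path, length(bad), long$chrom[bad[1]], long$pos[bad[1]],
                long$sample_id[bad[1]])
  }
  long
}

#' Write the pipeline's wide SNV read-count TSV
#'
#' @param reads Long read tibble as produced by [simulate_reads()] or
#'   [read_snv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(reads, path) {
  wide <- reads %>%
    tidyr::pivot_wider(id_cols = all_of(c("snv_id", "chrom", "pos", "ref", "alt")),
                       names_from = "sample_id",
                       values_from = all_of(c("alt_count", "depth"))) %>%
    select(-all_of("snv_id"))
  names(wide) <- sub("^alt_count_(.*)$", "\\1_alt", names(wide))
  names(wide) <- sub("^depth_(.*)$", "\\1_depth", names(wide))
  writeLines("# SNV read counts; pos is 1-based", path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' BED-like TSV with columns `sample_id`, `chrom`, `start`, `end` (0-based
#' half-open), `major_cn`, `minor_cn`; `#` lines are comments.
#'
#' @param path Input file.
#' @return Segment tibble.
#' @export
read_copy_number_segments <- function(path) {
  segs <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(chrom = readr::col_character()))
  need <- c("sample_id", "chrom", "start", "end", "major_cn", "minor_cn")
  if (!all(need %in% names(segs))) {
    abort_input("segment TSV must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(segs$major_cn < segs$minor_cn) || any(segs$minor_cn < 0)) {
    abort_input("segments must satisfy major_cn >= minor_cn >= 0")
  }
  segs
}

#' Read per-sample purity (and optional ploidy)
#'
#' TSV with columns `sample_id`, `purity` and optionally `ploidy`.
#'
#' @param path Input file.
#' @return Purity tibble.
#' @export
read_sample_purity <- function(path) {
  p <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("sample_id", "purity") %in% names(p))) {
    abort_input("purity TSV must have columns sample_id, purity")
  }
  if (any(p$purity <= 0 | p$purity > 1)) {
    abort_input("purities must lie in (0, 1]")
  }
  p
}

#' Write cluster assignments as TSV
#'
#' One row per SNV with its cluster and the cluster's per-sample CCF
#' locations (`ccf_<sample>` columns).
#'
#' @param clusters A `clone_clusters`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_assignments <- function(clusters, path) {
  stopifnot(inherits(clusters, "clone_clusters"))
  locw <- clusters$locations %>%
    tidyr::pivot_wider(id_cols = "cluster_id", names_from = "sample_id",
                       values_from = "ccf", names_prefix = "ccf_")
  out <- clusters$assignments %>% left_join(locw, by = "cluster_id")
  writeLines("# SNV cluster assignments; cluster CCF locations per sample", path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
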