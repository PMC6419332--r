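# Discordant-SNV characterization: HC/LC confidence stratification with the
# PR/GR enrichment ratios, depth histograms, and reference-allele base
# composition.

#' Confidence regions from intervals or a BED file
#'
#' High-confidence (HC) regions are held as a normalized (reduced, sorted)
#' GRanges; membership of a position is deterministic interval lookup with
#' BED's half-open convention, i.e. position p is HC iff p lies in
#' \[start, end) of some interval.
#'
#' @param seq_name,start,end equal-length vectors describing 0-based
#'   half-open intervals.
#' @return a \code{confidence_regions} object.
#' @export
confidence_regions <- function(seq_name = character(0),
                               start = integer(0), end = integer(0)) {
  gr <- GenomicRanges::GRanges(
    seq_name, IRanges::IRanges(start = as.integer(start) + 1L,
                               end = as.integer(end)))
  structure(list(gr = GenomicRanges::reduce(gr)),
            class = "confidence_regions")
}

#' @rdname confidence_regions
#' @param path BED3 file (0-based half-open).
#' @export
read_confidence_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("seq_name", "start", "end")[1:3],
                           select = 1:3, colClasses = list(character = 1))
  if (nrow(bed) == 0L) return(confidence_regions())
  confidence_regions(bed$seq_name, bed$start, bed$end)
}

#' Write confidence regions as BED3
#' @param regions a \code{confidence_regions}.
#' @param path output path.
#' @export
write_confidence_bed <- function(regions, path) {
  gr <- regions$gr
  data.table::fwrite(
    data.table::data.table(as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr) - 1L,
                           GenomicRanges::end(gr)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Partition SNVs into high- and low-confidence rosters
#'
#' An SNV is HC iff its position lies in a high-confidence interval; the HC
#' and LC rosters partition the input exactly.
#'
#' @param snvs SNV data.table.
#' @param regions a \code{confidence_regions} on the same assembly.
#' @return list with \code{hc}, \code{lc} (data.tables) and the logical
#'   membership vector \code{is_hc}.
#' @export
stratify <- function(snvs, regions) {
  stopifnot(inherits(regions, "confidence_regions"))
  if (nrow(snvs) == 0L)
    return(list(hc = snvs, lc = snvs, is_hc = logical(0)))
  pts <- GenomicRanges::GRanges(
    snvs$seq_name, IRanges::IRanges(snvs$pos + 1L, snvs$pos + 1L))
  is_hc <- GenomicRanges::countOverlaps(pts, regions$gr) > 0L
  list(hc = snvs[is_hc], lc = snvs[!is_hc], is_hc = is_hc)
}

#' LC-vs-HC discordance enrichment ratios (PR and GR)
#'
#' PR compares how often position-discordant SNVs fall in low-confidence
#' regions relative to all converted SNVs:
#' \code{PR = (lc_pd/lc_all) / (hc_pd/hc_all)}, and GR is the same ratio for
#' genotype-discordant SNVs. Both are reported with their log2 values; a
#' zero count anywhere makes the affected ratio NA (undefined sentinel).
#'
#' @param counts list or vector with \code{hc_all}, \code{lc_all},
#'   \code{hc_pd}, \code{lc_pd}, \code{hc_gd}, \code{lc_gd}.
#' @return list \code{pr}, \code{gr}, \code{log2_pr}, \code{log2_gr}.
#' @export
discordance_ratios <- function(counts) {
  cn <- as.list(counts)
  ratio <- function(lc_d, hc_d) {
    if (cn$lc_all <= 0 || cn$hc_all <= 0 || hc_d <= 0 || lc_d < 0)
      return(NA_real_)
    (lc_d / cn$lc_all) / (hc_d / cn$hc_all)
  }
  pr <- ratio(cn$lc_pd, cn$hc_pd)
  gr <- ratio(cn$lc_gd, cn$hc_gd)
  list(pr = pr, gr = gr,
       log2_pr = if (is.na(pr) || pr <= 0) NA_real_ else log2(pr),
       log2_gr = if (is.na(gr) || gr <= 0) NA_real_ else log2(gr))
}

#' Depth frequency tables for SNV rosters
#'
#' One frequency row per depth 0..max_depth plus an overflow bin and a
#' missing-depth bin; column sums equal roster sizes.
#'
#' @param rosters named list of SNV data.tables.
#' @param max_depth bin ceiling.
#' @return data.table with a \code{depth} label column and one count column
#'   per roster.
#' @export
depth_histogram <- function(rosters, max_depth = 60L) {
  labs <- c(as.character(0:max_depth), "overflow", "missing")
  out <- data.table::data.table(depth = labs)
  for (nm in names(rosters)) {
    d <- rosters[[nm]]$depth
    cnt <- integer(length(labs))
    if (length(d)) {
      miss <- is.na(d)
      over <- !miss & d > max_depth
      inb <- !miss & !over
      cnt[seq_len(max_depth + 1L)] <- tabulate(d[inb] + 1L, max_depth + 1L)
      cnt[max_depth + 2L] <- sum(over)
      cnt[max_depth + 3L] <- sum(miss)
    }
    out[[nm]] <- cnt
  }
  out
}

#' Reference-allele base composition of a roster
#'
#' Percentages of A/T/G/C among the (target-side) reference alleles of a
#' roster, with the combined G+C percentage; parts sum to 100.
#'
#' @param roster non-empty SNV data.table.
#' @return list \code{pct_a}, \code{pct_t}, \code{pct_g}, \code{pct_c},
#'   \code{pct_gc}, \code{n}.
#' @export
base_composition <- function(roster) {
  if (nrow(roster) == 0L)
    stop("base composition undefined for an empty roster")
  n <- nrow(roster)
  p <- function(b) 100 * sum(roster$ref == b) / n
  out <- list(pct_a = p("A"), pct_t = p("T"), pct_g = p("G"), pct_c = p("C"))
  out$pct_gc <- out$pct_g + out$pct_c
  out$n <- n
  out
}

#' Characterize the discordant SNVs of a comparison
#'
#' Bundles HC/LC stratified counts and PR/GR ratios, depth histograms for the
#' converted, unconverted, PD and GD rosters, and separate base compositions
#' for the PD and GD rosters (NULL when a roster is empty).
#'
#' @param report a \code{match_report} from \code{\link{run_comparison}}.
#' @param regions \code{confidence_regions} on the target assembly.
#' @param max_depth histogram bin ceiling.
#' @return a \code{characterization} list.
#' @export
characterize <- function(report, regions, max_depth = 60L) {
  stopifnot(inherits(report, "match_report"))
  conv <- report$converted %||% stop("report lacks the converted roster; ",
                                     "use run_comparison()")
  s_all <- stratify(conv, regions)
  s_pd <- stratify(report$pd_roster, regions)
  s_gd <- stratify(report$gd_roster, regions)
  counts <- list(hc_all = nrow(s_all$hc), lc_all = nrow(s_all$lc),
                 hc_pd = nrow(s_pd$hc), lc_pd = nrow(s_pd$lc),
                 hc_gd = nrow(s_gd$hc), lc_gd = nrow(s_gd$lc))
  rosters <- list(converted = conv,
                  unconverted = report$unconverted %||% empty_snvs(),
                  position_discordant = report$pd_roster,
                  genotype_discordant = report$gd_roster)
  structure(list(
    stratified_counts = counts,
    ratios = discordance_ratios(counts),
    depth_histogram = depth_histogram(rosters, max_depth),
    composition_pd = if (nrow(report$pd_roster))
      base_composition(report$pd_roster) else NULL,
    composition_gd = if (nrow(report$gd_roster))
      base_composition(report$gd_roster) else NULL),
    class = "characterization")
}

#' Serialize / restore a characterization bundle
#'
#' The bundle round-trips losslessly through a single JSON document (full
#' numeric precision).
#'
#' @param bundle a \code{characterization}.
#' @param path JSON file path.
#' @export
write_characterization <- function(bundle, path) {
  x <- unclass(bundle)
  x$depth_histogram <- as.data.frame(x$depth_histogram)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_characterization
#' @export
read_characterization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$depth_histogram <- data.table::as.data.table(x$depth_histogram)
  null_if_empty <- function(v) if (is.null(v) || length(v) == 0L) NULL else v
  x$composition_pd <- null_if_empty(x$composition_pd)
  x$composition_gd <- null_if_empty(x$composition_gd)
  x$ratios <- lapply(stats::setNames(nm = c("pr", "gr", "log2_pr", "log2_gr")),
                     function(k) if (is.null(x$ratios[[k]])) NA_real_
                                 else x$ratios[[k]])
  structure(x, class = "characterization")
}
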