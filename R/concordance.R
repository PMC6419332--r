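# Call-set concordance: conversion rate, matching of converted vs directly
# called SNVs, and the PD/GD discordance statistics.

#' Conversion rate
#'
#' Percentage of a call set's SNVs that successfully lifted to the other
#' assembly: \code{100 * n_converted / n_source_total}.
#'
#' @param n_converted number of successfully converted SNVs.
#' @param n_source_total number of SNVs in the source call set.
#' @return percentage in \[0, 100\].
#' @export
conversion_rate <- function(n_converted, n_source_total) {
  if (n_source_total <= 0) stop("conversion rate undefined: no source SNVs")
  if (n_converted < 0 || n_converted > n_source_total)
    stop("n_converted must lie in [0, n_source_total]")
  100 * n_converted / n_source_total
}

#' Match converted SNVs against directly-called SNVs
#'
#' Classifies every converted SNV against the call set obtained directly on
#' the target assembly. The match key is (seq_name, pos, ref); genotypes are
#' compared as unordered diploid allele multisets (phase-insensitive):
#' \itemize{
#'   \item concordant: a direct SNV at the same key with the same allele
#'     multiset;
#'   \item genotype-discordant (GD): key matches but the alt allele or the
#'     genotype differs;
#'   \item position-discordant (PD): no direct SNV at that key.
#' }
#' PDR and GDR are PD and GD as percentages of the converted SNVs, and the
#' log2 PD/GD ratio summarises their balance (NA when either count is zero).
#'
#' @param converted converted SNV table on target coordinates, sorted.
#' @param direct directly-called SNV table on the same assembly, sorted.
#' @param alt_mismatch_class how a matched position+ref with a different alt
#'   allele is classified: \code{"genotype"} (default) or \code{"position"}.
#' @return a \code{match_report}: counts, rates (percent), and PD/GD rosters.
#' @export
match_callsets <- function(converted, direct,
                           alt_mismatch_class = c("genotype", "position")) {
  alt_mismatch_class <- match.arg(alt_mismatch_class)
  assert_sorted(converted, "converted call set")
  assert_sorted(direct, "direct call set")
  converted <- data.table::as.data.table(converted)
  direct <- data.table::as.data.table(direct)

  n_conv <- nrow(converted)
  if (n_conv == 0L) {
    rep <- list(n_converted = 0L, n_concordant = 0L,
                n_position_discordant = 0L, n_genotype_discordant = 0L,
                pdr_pct = 0, gdr_pct = 0, pd_to_gd_log2_ratio = NA_real_,
                pd_roster = empty_snvs(), gd_roster = empty_snvs(),
                classes = character(0))
    class(rep) <- "match_report"
    return(rep)
  }
  conv <- data.table::copy(converted)
  conv[, alleles := genotype_alleles(ref, alt, gt)]
  conv[, cid := .I]
  dir2 <- direct[, .(seq_name, pos, ref,
                     d_alt = alt, d_alleles = genotype_alleles(ref, alt, gt))]
  # a position may hold several direct records (multi-allelic splits):
  # classify each converted SNV against the best match at its key
  m <- dir2[conv, on = c("seq_name", "pos", "ref"), allow.cartesian = TRUE]
  per <- m[, .(any_key = any(!is.na(d_alleles)),
               any_alt = any(!is.na(d_alt) & d_alt == alt),
               any_conc = any(!is.na(d_alleles) & d_alleles == alleles)),
           by = cid]
  data.table::setorder(per, cid)
  cls <- if (alt_mismatch_class == "genotype") {
    data.table::fifelse(per$any_conc, "concordant",
      data.table::fifelse(per$any_key, "genotype_discordant",
                          "position_discordant"))
  } else {
    data.table::fifelse(per$any_conc, "concordant",
      data.table::fifelse(per$any_alt, "genotype_discordant",
                          "position_discordant"))
  }
  n_pd <- sum(cls == "position_discordant")
  n_gd <- sum(cls == "genotype_discordant")
  rep <- list(
    n_converted = n_conv,
    n_concordant = n_conv - n_pd - n_gd,
    n_position_discordant = n_pd,
    n_genotype_discordant = n_gd,
    pdr_pct = 100 * n_pd / n_conv,
    gdr_pct = 100 * n_gd / n_conv,
    pd_to_gd_log2_ratio = if (n_pd > 0 && n_gd > 0) log2(n_pd / n_gd)
                          else NA_real_,
    pd_roster = converted[cls == "position_discordant"],
    gd_roster = converted[cls == "genotype_discordant"],
    classes = cls)
  class(rep) <- "match_report"
  rep
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  if (!is.null(x$n_source_total))
    cat(sprintf("  source SNVs:     %d\n", x$n_source_total))
  cat(sprintf("  converted:       %d\n", x$n_converted))
  if (!is.null(x$conversion_rate_pct))
    cat(sprintf("  conversion rate: %.2f%%\n", x$conversion_rate_pct))
  cat(sprintf("  concordant:      %d\n", x$n_concordant))
  cat(sprintf("  position disc.:  %d (PDR %.2f%%)\n",
              x$n_position_discordant, x$pdr_pct))
  cat(sprintf("  genotype disc.:  %d (GDR %.2f%%)\n",
              x$n_genotype_discordant, x$gdr_pct))
  if (is.finite(x$pd_to_gd_log2_ratio %||% NA))
    cat(sprintf("  log2(PD/GD):     %.3f\n", x$pd_to_gd_log2_ratio))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one direction of the cross-assembly comparison
#'
#' Composes SNV filtering, liftover and call-set matching for one conversion
#' direction: the source call set is lifted through the chains onto the
#' target assembly and compared with the call set obtained directly there.
#' Running both directions is two independent invocations with the roles and
#' chain direction swapped.
#'
#' @param source_vcf call set on the source assembly.
#' @param direct_target_vcf call set obtained directly on the target assembly.
#' @param chains chain set or chain file path (source -> target).
#' @param target_fasta target assembly FASTA.
#' @param on_ref_mismatch,alt_mismatch_class flags passed through.
#' @return a \code{match_report} additionally carrying \code{n_source_total},
#'   \code{conversion_rate_pct}, the conversion \code{tally}, the
#'   \code{converted} and \code{unconverted} rosters and the direct-set
#'   filter tally.
#' @export
run_comparison <- function(source_vcf, direct_target_vcf, chains,
                           target_fasta,
                           on_ref_mismatch = c("reject", "keep"),
                           alt_mismatch_class = c("genotype", "position")) {
  lifted <- lift_callset(source_vcf, chains, target_fasta,
                         on_ref_mismatch = match.arg(on_ref_mismatch))
  direct <- filter_snvs(direct_target_vcf)
  rep <- match_callsets(lifted$converted, direct$snvs,
                        alt_mismatch_class = match.arg(alt_mismatch_class))
  rep$n_source_total <- unname(lifted$tally["n_input"])
  rep$conversion_rate_pct <- conversion_rate(rep$n_converted,
                                             rep$n_source_total)
  rep$tally <- lifted$tally
  rep$converted <- lifted$converted
  rep$unconverted <- lifted$rejects
  rep$direct_filter_tally <- direct$tally
  rep$filter_tally <- lifted$filter_tally
  rep
}
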