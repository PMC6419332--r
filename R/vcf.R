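# VCF reading (via vcfR), SNV-only filtering, and deterministic VCF writing.
#
# Internal SNV tables are data.tables with columns
#   seq_name, pos (0-based), ref, alt, gt, depth
# VCF itself is 1-based; the +-1 conversion happens only here, at the I/O
# boundary.

#' Read a VCF and keep only biallelic SNVs
#'
#' Parses a single-sample VCF and reduces it to biallelic single-nucleotide
#' substitutions. Indels, symbolic/structural alleles and records with a
#' missing genotype are removed. Multi-allelic records are split into
#' per-alt-allele records, each keeping the sample's dosage of that alt
#' (dosage 1 -> het 0/1, dosage 2 -> hom 1/1); split alleles the sample does
#' not carry, and split alleles that are not single bases, are dropped.
#' Duplicate positions within the set keep the first record after sorting.
#'
#' @param path path to a VCF file.
#' @return list with \code{snvs} (sorted SNV data.table) and \code{tally}
#'   (named integer vector of removal classes).
#' @export
filter_snvs <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  tally <- c(input_records = 0L, kept_snvs = 0L, indel = 0L, symbolic = 0L,
             missing_genotype = 0L, multiallelic_records = 0L,
             non_snv_allele_dropped = 0L, zero_dosage_dropped = 0L,
             duplicate_position_dropped = 0L)
  if (is.null(fix) || nrow(fix) == 0L)
    return(list(snvs = empty_snvs(), tally = tally))
  tally["input_records"] <- nrow(fix)
  gt <- tryCatch(vcfR::extract.gt(vcf, "GT")[, 1L],
                 error = function(e) rep(NA_character_, nrow(fix)))
  dp <- tryCatch(suppressWarnings(
    vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)[, 1L]),
    error = function(e) rep(NA_real_, nrow(fix)))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  missing_gt <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  symbolic <- grepl("[<>\\[\\]*]", alt, perl = TRUE)
  multi <- !missing_gt & !symbolic & grepl(",", alt, fixed = TRUE)
  snv_ok <- !missing_gt & !symbolic & !multi &
    nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES & alt %in% BASES
  indel <- !missing_gt & !symbolic & !multi & !snv_ok
  tally["missing_genotype"] <- sum(missing_gt)
  tally["symbolic"] <- sum(symbolic & !missing_gt)
  tally["indel"] <- sum(indel)
  tally["multiallelic_records"] <- sum(multi)

  snvs <- data.table::data.table(
    seq_name = fix[snv_ok, "CHROM"],
    pos = as.integer(fix[snv_ok, "POS"]) - 1L,
    ref = ref[snv_ok], alt = alt[snv_ok], gt = gt[snv_ok],
    depth = as.integer(dp[snv_ok]), rec = which(snv_ok))

  if (any(multi)) {
    parts <- vector("list", sum(multi))
    for (j in seq_along(which(multi))) {
      i <- which(multi)[j]
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      idx <- suppressWarnings(
        as.integer(strsplit(gsub("\\|", "/", gt[i]), "/", fixed = TRUE)[[1]]))
      if (anyNA(idx)) {
        tally["missing_genotype"] <- tally["missing_genotype"] + 1L
        next
      }
      keep_alt <- character(0); keep_gt <- character(0)
      for (k in seq_along(alts)) {
        if (!(nchar(ref[i]) == 1L && nchar(alts[k]) == 1L &&
              ref[i] %in% BASES && alts[k] %in% BASES)) {
          tally["non_snv_allele_dropped"] <-
            tally["non_snv_allele_dropped"] + 1L
          next
        }
        dose <- sum(idx == k)
        if (dose == 0L) {
          tally["zero_dosage_dropped"] <- tally["zero_dosage_dropped"] + 1L
          next
        }
        keep_alt <- c(keep_alt, alts[k])
        keep_gt <- c(keep_gt, if (dose >= 2L) "1/1" else "0/1")
      }
      if (length(keep_alt))
        parts[[j]] <- data.table::data.table(
          seq_name = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]) - 1L,
          ref = ref[i], alt = keep_alt, gt = keep_gt,
          depth = as.integer(dp[i]), rec = i)
    }
    snvs <- data.table::rbindlist(
      c(list(snvs), parts[!vapply(parts, is.null, logical(1))]))
  }
  if (nrow(snvs) == 0L) return(list(snvs = empty_snvs(), tally = tally))
  data.table::setorder(snvs, seq_name, pos, rec)
  # two distinct input records at the same position: keep the first record
  # (split rows of one multi-allelic record all survive)
  snvs[, first_rec := min(rec), by = .(seq_name, pos)]
  dup <- snvs$rec != snvs$first_rec
  tally["duplicate_position_dropped"] <- sum(dup)
  snvs <- snvs[!dup][, c("rec", "first_rec") := NULL]
  tally["kept_snvs"] <- nrow(snvs)
  list(snvs = snvs, tally = tally)
}

empty_snvs <- function() {
  data.table::data.table(seq_name = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         gt = character(0), depth = integer(0))
}

#' Write an SNV table as a VCF file
#'
#' Emits a minimal, deterministic single-sample VCF v4.2 (no timestamps, so
#' identical inputs give byte-identical output). Internal 0-based positions
#' are converted to VCF's 1-based POS on output.
#'
#' @param snvs SNV data.table (\code{seq_name}, 0-based \code{pos},
#'   \code{ref}, \code{alt}, \code{gt}, \code{depth}).
#' @param path output path.
#' @param contig_sizes named integer vector of contig lengths for the header.
#' @param info optional per-record INFO strings (default ".").
#' @param sample sample column name.
#' @return \code{path}, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, contig_sizes, info = NULL,
                          sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_sizes),
                   as.integer(contig_sizes)),
           "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Pre-liftover coordinate (name:pos1)\">",
           "##INFO=<ID=CHAIN,Number=1,Type=Integer,Description=\"Chain id used for liftover\">",
           "##INFO=<ID=LIFT_STATUS,Number=1,Type=String,Description=\"Liftover rejection status\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  if (nrow(snvs)) {
    if (is.null(info)) info <- rep(".", nrow(snvs))
    dpf <- ifelse(is.na(snvs$depth), ".", as.character(snvs$depth))
    body <- paste(snvs$seq_name, snvs$pos + 1L, ".", snvs$ref, snvs$alt,
                  ".", "PASS", info, "GT:DP",
                  paste0(snvs$gt, ":", dpf), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Contig lengths declared in a VCF header (named integer; empty if none).
vcf_contig_sizes <- function(path) {
  meta <- readLines(path, n = 500L)
  meta <- meta[startsWith(meta, "##contig")]
  ids <- sub('.*ID=([^,>]+).*', "\\1", meta)
  len <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", meta)))
  keep <- !is.na(len)
  stats::setNames(len[keep], ids[keep])
}
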