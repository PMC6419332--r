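# Small shared helpers: nucleotide complements, genotype algebra, sortedness.

BASES <- c("A", "C", "G", "T")

#' Complement single-nucleotide alleles
#'
#' Vectorised complement for one-base alleles (A<->T, C<->G). Used when a
#' variant lifts across an inverted alignment block: both alleles must be
#' reverse-complemented, which for a single base is its complement.
#'
#' @param x character vector of single bases in \code{A,C,G,T}.
#' @return character vector of complemented bases.
#' @export
complement_base <- function(x) {
  out <- c(A = "T", C = "G", G = "C", T = "A")[x]
  if (anyNA(out)) stop("complement_base: non-ACGT allele: ",
                       paste(unique(x[is.na(out)]), collapse = ","))
  unname(out)
}

# Canonical unordered diploid allele multiset, e.g. ref="A", alt="G",
# gt="1|0" -> "A/G". Phase separators are ignored on purpose: callers differ
# in phasing and zygosity is what concordance compares.
genotype_alleles <- function(ref, alt, gt) {
  idx <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  mapply(function(r, a, i) {
    i <- suppressWarnings(as.integer(i))
    if (anyNA(i)) return(NA_character_)
    al <- c(r, a)[i + 1L]
    paste(sort(al), collapse = "/")
  }, ref, alt, idx, USE.NAMES = FALSE)
}

# TRUE iff an SNV table is sorted by (seq_name, pos).
is_sorted_snvs <- function(snvs) {
  if (nrow(snvs) < 2L) return(TRUE)
  !is.unsorted(order(snvs$seq_name, snvs$pos))  &&
    identical(order(snvs$seq_name, snvs$pos), seq_len(nrow(snvs)))
}

assert_sorted <- function(snvs, what) {
  if (!is_sorted_snvs(snvs))
    stop(what, " must be sorted by (seq_name, pos)")
  invisible(TRUE)
}

# Named character vector of sequences -> base at 0-based positions.
seq_base_at <- function(seqs, name, pos) {
  if (!all(name %in% names(seqs)))
    stop("sequence accessor missing sequence(s): ",
         paste(setdiff(unique(name), names(seqs)), collapse = ","))
  substring(seqs[name], pos + 1L, pos + 1L)
}

# Load a FASTA into a plain named character vector (upper case).
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
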