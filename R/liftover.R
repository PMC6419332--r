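# Coordinate liftover: block index construction, point mapping, and
# allele-aware lifting of SNV call sets.

LIFT_STATUSES <- c("converted", "unmapped_no_chain", "unmapped_in_gap",
                   "rejected_ref_mismatch", "rejected_multimap")

#' Build a queryable coordinate index from a chain set
#'
#' Flattens every chain into absolute-coordinate alignment blocks and keys
#' them for interval search, so point queries cost O(log n) via binary
#' search rather than a linear walk over all blocks.
#'
#' @param chain_set a \code{chain_set} from \code{\link{parse_chain}}.
#' @return a \code{chain_index} holding the block table and per-chain spans.
#' @export
build_chain_index <- function(chain_set) {
  stopifnot(inherits(chain_set, "chain_set"))
  tabs <- lapply(chain_set$chains, function(ch) {
    src_off <- ch$src_start +
      c(0L, cumsum(ch$blocks$size + ch$blocks$src_gap))[seq_len(nrow(ch$blocks))]
    tgt_off <- ch$tgt_start +
      c(0L, cumsum(ch$blocks$size + ch$blocks$tgt_gap))[seq_len(nrow(ch$blocks))]
    data.table::data.table(
      src_name = ch$src_name,
      start = src_off, end = src_off + ch$blocks$size - 1L,  # closed interval
      tgt_name = ch$tgt_name, tgt_size = ch$tgt_size,
      strand = ch$tgt_strand, tgt_local_start = tgt_off,
      score = ch$score, chain_id = ch$chain_id)
  })
  blocks <- data.table::rbindlist(tabs)
  spans <- data.table::rbindlist(lapply(chain_set$chains, function(ch)
    data.table::data.table(src_name = ch$src_name, start = ch$src_start,
                           end = ch$src_end - 1L)))
  if (nrow(blocks)) {
    data.table::setkey(blocks, src_name, start, end)
    data.table::setkey(spans, src_name, start, end)
  }
  structure(list(blocks = blocks, spans = spans,
                 source_sizes = chain_set$source_sizes,
                 target_sizes = chain_set$target_sizes),
            class = "chain_index")
}

#' Map source-assembly positions to the target assembly
#'
#' Vectorised point liftover. Each query resolves to exactly one of:
#' \code{converted} (a covering aligned block; multiple covering chains are
#' resolved by taking the highest-score chain), \code{unmapped_in_gap}
#' (inside a chain's span but in an alignment gap), \code{unmapped_no_chain}
#' (no chain covers the position or the sequence is unknown), or
#' \code{rejected_multimap} (distinct equal-top-score chains disagree on the
#' target). All failure modes are statuses, never errors.
#'
#' Chain target coordinates are strand-local; for a '-' block the plus-strand
#' coordinate is \code{tgt_size - 1 - local}.
#'
#' @param index a \code{chain_index}.
#' @param seq_name,pos equal-length vectors of sequence names and 0-based
#'   positions.
#' @return data.table with one row per query: \code{status},
#'   \code{tgt_name}, \code{tgt_pos} (0-based, plus strand), \code{strand},
#'   \code{chain_id}.
#' @export
map_position <- function(index, seq_name, pos) {
  stopifnot(inherits(index, "chain_index"), length(seq_name) == length(pos))
  n <- length(pos)
  out <- data.table::data.table(
    status = rep("unmapped_no_chain", n),
    tgt_name = NA_character_, tgt_pos = NA_integer_,
    strand = NA_character_, chain_id = NA_integer_)
  if (n == 0L || nrow(index$blocks) == 0L) return(out)
  q <- data.table::data.table(src_name = seq_name,
                              start = as.integer(pos),
                              end = as.integer(pos), qid = seq_len(n))
  data.table::setkey(q, src_name, start, end)
  hits <- data.table::foverlaps(q, index$blocks, type = "within",
                                nomatch = NULL)
  if (nrow(hits)) {
    # foverlaps prefixes clashing query columns with "i.": query pos is i.start
    local <- hits$tgt_local_start + (hits$i.start - hits$start)
    hits[, tgt_pos := data.table::fifelse(strand == "+", local,
                                          tgt_size - 1L - local)]
    hits[, top := score == max(score), by = qid]
    best <- hits[top == TRUE]
    uni <- unique(best, by = c("qid", "tgt_name", "tgt_pos", "strand"))
    ntab <- uni[, .N, by = qid]
    single <- ntab[N == 1L, qid]
    multim <- ntab[N > 1L, qid]
    pick <- uni[qid %in% single]
    out[pick$qid, `:=`(status = "converted", tgt_name = pick$tgt_name,
                       tgt_pos = pick$tgt_pos, strand = pick$strand,
                       chain_id = pick$chain_id)]
    if (length(multim)) out[multim, status := "rejected_multimap"]
  }
  unresolved <- which(out$status == "unmapped_no_chain")
  if (length(unresolved) && nrow(index$spans)) {
    q2 <- q[qid %in% unresolved]
    sp <- data.table::foverlaps(q2, index$spans, type = "within",
                                nomatch = NULL)
    if (nrow(sp)) out[unique(sp$qid), status := "unmapped_in_gap"]
  }
  out
}

#' Lift SNVs to a target assembly with allele checks
#'
#' Maps each SNV's position with \code{\link{map_position}}; on a '-' strand
#' block ref and alt are complemented (reverse complement of a single base).
#' The lifted ref is then compared with the target assembly base at the
#' mapped position: a mismatch is rejected by default
#' (\code{on_ref_mismatch = "reject"}, mirroring Picard LiftoverVcf) or kept
#' with \code{"keep"}. The genotype string is carried through unchanged, so
#' zygosity and phase separators survive liftover.
#'
#' @param index a \code{chain_index}.
#' @param snvs SNV data.table (see \code{\link{filter_snvs}}).
#' @param target_seqs named character vector of target assembly sequences
#'   (e.g. from \code{read_genome}); a mapped sequence name absent from it is
#'   a hard error, since that means inconsistent inputs.
#' @param on_ref_mismatch \code{"reject"} or \code{"keep"}.
#' @return the input table with added columns \code{status}, \code{tgt_name},
#'   \code{tgt_pos}, \code{strand}, \code{chain_id}, \code{lifted_ref},
#'   \code{lifted_alt}.
#' @export
lift_snvs <- function(index, snvs, target_seqs,
                      on_ref_mismatch = c("reject", "keep")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  res <- map_position(index, snvs$seq_name, snvs$pos)
  out <- cbind(data.table::as.data.table(snvs), res)
  out[, `:=`(lifted_ref = NA_character_, lifted_alt = NA_character_)]
  conv <- out$status == "converted"
  if (any(conv)) {
    missing_seq <- setdiff(unique(out$tgt_name[conv]), names(target_seqs))
    if (length(missing_seq))
      stop("target sequence accessor is missing: ",
           paste(missing_seq, collapse = ","))
    minus <- conv & out$strand == "-"
    out[conv, `:=`(lifted_ref = ref, lifted_alt = alt)]
    if (any(minus))
      out[minus, `:=`(lifted_ref = complement_base(ref),
                      lifted_alt = complement_base(alt))]
    tbase <- seq_base_at(target_seqs, out$tgt_name[conv], out$tgt_pos[conv])
    bad <- which(conv)[tbase != out$lifted_ref[conv]]
    if (length(bad) && on_ref_mismatch == "reject") {
      out[bad, `:=`(status = "rejected_ref_mismatch",
                    lifted_ref = NA_character_, lifted_alt = NA_character_)]
    }
  }
  out
}

#' Lift a whole call set and write converted/reject VCFs
#'
#' Reads a VCF, filters it to biallelic SNVs, lifts every SNV, and writes a
#' coordinate-sorted converted VCF on the target assembly (with INFO tags
#' recording the source coordinate and chain id) plus a rejects VCF annotated
#' with each record's rejection status. The conversion tally partitions the
#' input exactly: \code{n_input = n_converted + sum(rejects by reason)}.
#'
#' A direction mismatch (chains whose target sizes disagree with the target
#' FASTA, or whose source sizes disagree with the VCF's contig headers) is a
#' hard error.
#'
#' @param vcf_in path to the source call set.
#' @param chains a \code{chain_set} or path to a chain file (source = the
#'   assembly of \code{vcf_in}).
#' @param target_fasta path to the target assembly FASTA.
#' @param vcf_converted_out,rejects_out optional output VCF paths.
#' @param on_ref_mismatch passed to \code{\link{lift_snvs}}.
#' @return list with \code{tally} (named counts incl. per-reason rejects),
#'   \code{converted} (SNV table on target coordinates, sorted),
#'   \code{rejects} (source-coordinate table with status), and
#'   \code{filter_tally}.
#' @export
lift_callset <- function(vcf_in, chains, target_fasta,
                         vcf_converted_out = NULL, rejects_out = NULL,
                         on_ref_mismatch = c("reject", "keep")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  if (!inherits(chains, "chain_set")) chains <- parse_chain(chains)
  target_seqs <- read_genome(target_fasta)
  tl <- nchar(target_seqs)
  shared <- intersect(names(tl), names(chains$target_sizes))
  if (length(shared) == 0L ||
      any(tl[shared] != chains$target_sizes[shared]))
    stop("chain direction mismatch: chain target sizes disagree with the ",
         "target FASTA")
  csz <- vcf_contig_sizes(vcf_in)
  sh2 <- intersect(names(csz), names(chains$source_sizes))
  if (length(sh2) && any(csz[sh2] != chains$source_sizes[sh2]))
    stop("chain direction mismatch: chain source sizes disagree with the ",
         "input VCF contigs")

  fl <- filter_snvs(vcf_in)
  index <- build_chain_index(chains)
  lifted <- lift_snvs(index, fl$snvs, target_seqs, on_ref_mismatch)

  conv <- lifted[status == "converted",
                 .(seq_name = tgt_name, pos = tgt_pos,
                   ref = lifted_ref, alt = lifted_alt, gt, depth,
                   src_name = seq_name, src_pos = pos, chain_id, strand)]
  data.table::setorder(conv, seq_name, pos)
  rej <- lifted[status != "converted"]

  tally <- c(n_input = nrow(lifted), n_converted = nrow(conv),
             stats::setNames(
               vapply(setdiff(LIFT_STATUSES, "converted"),
                      function(s) sum(rej$status == s), integer(1)),
               paste0("n_", setdiff(LIFT_STATUSES, "converted"))))

  if (!is.null(vcf_converted_out)) {
    info <- sprintf("SRC=%s:%d;CHAIN=%d", conv$src_name, conv$src_pos + 1L,
                    conv$chain_id)
    write_snv_vcf(conv, vcf_converted_out, tl, info = info)
  }
  if (!is.null(rejects_out)) {
    src_sizes <- chains$source_sizes
    if (length(csz)) src_sizes <- csz
    write_snv_vcf(rej[, .(seq_name, pos, ref, alt, gt, depth)],
                  rejects_out, src_sizes,
                  info = paste0("LIFT_STATUS=", rej$status))
  }
  list(tally = tally, converted = conv, rejects = rej,
       filter_tally = fl$tally)
}
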