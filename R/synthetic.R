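# Synthetic fixture generator: assembly pairs related by a known edit script,
# consistent chain files in both directions, diploid SNV call sets with
# injected discordances, confidence-region BEDs, and a per-variant truth
# ledger. Every statistic the pipeline computes has an exact or closed-form
# expected value on these fixtures.

#' Random DNA sequence with a given GC fraction
#' @param n length in bases.
#' @param gc expected G+C fraction.
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.42) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Vectorised uniform draw over the three non-reference bases.
random_alt <- function(ref) {
  off <- sample.int(3L, base::length(ref), replace = TRUE)
  BASES[(match(ref, BASES) - 1L + off) %% 4L + 1L]
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Edit script specification for an assembly pair
#'
#' Describes how the target assembly differs from the source: deletions
#' (source bases absent from the target), insertions (target bases absent
#' from the source) and inversions (segments reverse-complemented in the
#' target). Edits are placed non-overlapping on the source with at least
#' 50 bp of untouched sequence between and around them.
#'
#' @param n_deletions,n_insertions,n_inversions edit counts.
#' @param deletion_length,insertion_length,inversion_length length ranges
#'   (min, max) in bases.
#' @param seed RNG seed used when the pair is generated.
#' @return an \code{edit_spec} list.
#' @export
edit_spec <- function(n_deletions = 0L, deletion_length = c(200L, 800L),
                      n_insertions = 0L, insertion_length = c(200L, 800L),
                      n_inversions = 0L, inversion_length = c(500L, 1500L),
                      seed = 1L) {
  structure(list(n_deletions = n_deletions,
                 deletion_length = deletion_length,
                 n_insertions = n_insertions,
                 insertion_length = insertion_length,
                 n_inversions = n_inversions,
                 inversion_length = inversion_length,
                 seed = seed), class = "edit_spec")
}

# Build chains from a base-level map (0-based target position per source
# base, NA where unmapped) and its strand vector. Colinear '+' runs form one
# gapped chain; each inverted run becomes its own '-' chain, which is how
# real chain files represent inversions.
chains_from_map <- function(map0, strand, src_name, src_size,
                            tgt_name, tgt_size, first_id = 1L) {
  idx <- which(!is.na(map0))
  if (length(idx) == 0L)
    return(new_chain_set(list(),
                         stats::setNames(src_size, src_name),
                         stats::setNames(tgt_size, tgt_name)))
  m <- map0[idx]; st <- strand[idx]
  k <- length(idx)
  newrun <- c(TRUE, diff(idx) != 1L | st[-1] != st[-k] |
                diff(m) != ifelse(st[-1] == "+", 1L, -1L))
  run_id <- cumsum(newrun)
  runs <- data.table::data.table(
    src_start = idx[newrun] - 1L,
    len = as.integer(tabulate(run_id)),
    strand = st[newrun],
    tgt_first = m[newrun])
  chains <- list()
  cid <- first_id
  plus <- runs[strand == "+"]
  if (nrow(plus)) {
    np <- nrow(plus)
    src_gap <- c(plus$src_start[-1] - (plus$src_start[-np] + plus$len[-np]),
                 0L)
    tgt_gap <- c(plus$tgt_first[-1] - (plus$tgt_first[-np] + plus$len[-np]),
                 0L)
    if (any(src_gap < 0L) || any(tgt_gap < 0L))
      stop("internal error: non-colinear '+' runs")
    chains[[length(chains) + 1L]] <- list(
      score = 100 * sum(plus$len),
      src_name = src_name, src_size = src_size, src_strand = "+",
      src_start = plus$src_start[1],
      src_end = plus$src_start[np] + plus$len[np],
      tgt_name = tgt_name, tgt_size = tgt_size, tgt_strand = "+",
      tgt_start = plus$tgt_first[1],
      tgt_end = plus$tgt_first[np] + plus$len[np],
      blocks = data.table::data.table(size = plus$len, src_gap = src_gap,
                                      tgt_gap = tgt_gap),
      chain_id = cid)
    cid <- cid + 1L
  }
  minus <- runs[strand == "-"]
  for (i in seq_len(nrow(minus))) {
    hi <- minus$tgt_first[i]          # first source base maps to highest tgt
    len <- minus$len[i]
    lo <- hi - len + 1L
    chains[[length(chains) + 1L]] <- list(
      score = 10 * len,
      src_name = src_name, src_size = src_size, src_strand = "+",
      src_start = minus$src_start[i], src_end = minus$src_start[i] + len,
      tgt_name = tgt_name, tgt_size = tgt_size, tgt_strand = "-",
      tgt_start = tgt_size - (hi + 1L), tgt_end = tgt_size - lo,
      blocks = data.table::data.table(size = len, src_gap = 0L,
                                      tgt_gap = 0L),
      chain_id = cid)
    cid <- cid + 1L
  }
  new_chain_set(chains, stats::setNames(src_size, src_name),
                stats::setNames(tgt_size, tgt_name))
}

#' Generate a related assembly pair with ground truth
#'
#' Builds a random source sequence, applies the edit script to obtain the
#' target assembly, and derives (a) a base-level truth map giving, for every
#' source base, its 0-based target coordinate and strand or a deleted
#' marker, and (b) UCSC chain sets in both directions that are consistent
#' with that map by construction. A fixed seed gives byte-identical output.
#'
#' @param length source genome length in bases (>= 1000).
#' @param gc GC fraction of the simulated genome.
#' @param edits an \code{\link{edit_spec}}.
#' @param seq_name sequence name used on both assemblies.
#' @return an \code{assembly_pair}: sequences, truth maps in both
#'   directions, strand vectors, both chain sets and the realized edit table.
#' @export
generate_assembly_pair <- function(length, gc = 0.42, edits = edit_spec(),
                                   seq_name = "chr1") {
  stopifnot(length >= 1000L)
  set.seed(edits$seed)
  rlen <- function(n, range) {       # safe against length-1 ranges
    if (n == 0L) return(integer(0))
    cand <- seq(range[1], range[2])
    cand[sample.int(base::length(cand), n, replace = TRUE)]
  }
  etab <- data.table::data.table(
    type = rep(c("deletion", "insertion", "inversion"),
               c(edits$n_deletions, edits$n_insertions, edits$n_inversions)),
    len = c(rlen(edits$n_deletions, edits$deletion_length),
            rlen(edits$n_insertions, edits$insertion_length),
            rlen(edits$n_inversions, edits$inversion_length)))
  k <- nrow(etab)
  margin <- 50L
  if (k > 0L) {
    etab <- etab[sample(k)]
    etab[, src_len := ifelse(type == "insertion", 0L, len)]
    slack <- length - sum(etab$src_len) - (k + 1L) * margin
    if (slack < 0L) stop("infeasible edit spec: edits do not fit in ",
                         length, " bases")
    gaps <- as.integer(stats::rmultinom(1L, slack, rep(1, k + 1L)))
    starts <- integer(k); cur <- 0L
    for (i in seq_len(k)) {
      cur <- cur + gaps[i] + margin
      starts[i] <- cur
      cur <- cur + etab$src_len[i]
    }
    etab[, src_start := starts]
  } else {
    etab[, `:=`(src_len = integer(0), src_start = integer(0))]
  }

  src <- random_dna(length, gc)
  src_map <- integer(length); src_strand <- rep("+", length)
  chunks <- list(); tpos <- 0L; spos <- 0L   # 0-based cursors
  add_colinear <- function(from, to) {       # [from, to) on source
    n <- to - from
    if (n <= 0L) return(invisible())
    src_map[(from + 1L):to] <<- tpos + 0L:(n - 1L)
    chunks[[base::length(chunks) + 1L]] <<- substring(src, from + 1L, to)
    tpos <<- tpos + n
  }
  for (i in seq_len(k)) {
    a <- etab$src_start[i]
    add_colinear(spos, a)
    if (etab$type[i] == "deletion") {
      src_map[(a + 1L):(a + etab$len[i])] <- NA_integer_
      spos <- a + etab$len[i]
    } else if (etab$type[i] == "insertion") {
      chunks[[base::length(chunks) + 1L]] <- random_dna(etab$len[i], gc)
      tpos <- tpos + etab$len[i]
      spos <- a
    } else {                                 # inversion
      n <- etab$len[i]
      chunks[[base::length(chunks) + 1L]] <-
        revcomp(substring(src, a + 1L, a + n))
      src_map[(a + 1L):(a + n)] <- tpos + (n - 1L):0L
      src_strand[(a + 1L):(a + n)] <- "-"
      tpos <- tpos + n
      spos <- a + n
    }
  }
  add_colinear(spos, length)
  tgt <- paste(unlist(chunks), collapse = "")
  tgt_len <- nchar(tgt)
  stopifnot(tgt_len == tpos)

  tgt_map <- rep(NA_integer_, tgt_len); tgt_strand <- rep(NA_character_,
                                                          tgt_len)
  mapped <- which(!is.na(src_map))
  tgt_map[src_map[mapped] + 1L] <- mapped - 1L
  tgt_strand[src_map[mapped] + 1L] <- src_strand[mapped]
  tgt_strand[is.na(tgt_strand)] <- "+"

  chain_fwd <- chains_from_map(src_map, src_strand, seq_name, length,
                               seq_name, tgt_len)
  chain_rev <- chains_from_map(tgt_map, tgt_strand, seq_name, tgt_len,
                               seq_name, length)
  structure(list(seq_name = seq_name, gc = gc,
                 source_seq = stats::setNames(src, seq_name),
                 target_seq = stats::setNames(tgt, seq_name),
                 src_map = src_map, src_strand = src_strand,
                 tgt_map = tgt_map, tgt_strand = tgt_strand,
                 chain_fwd = chain_fwd, chain_rev = chain_rev,
                 edits = etab, edit_seed = edits$seed),
            class = "assembly_pair")
}

#' Expected liftover status for every source base of a pair
#'
#' The generator's own base-level oracle: "converted" where the truth map is
#' defined, otherwise "unmapped_in_gap" inside some chain's source span and
#' "unmapped_no_chain" outside all spans.
#'
#' @param pair an \code{assembly_pair}.
#' @param direction \code{"fwd"} (source base statuses) or \code{"rev"}.
#' @return character vector, one status per base.
#' @export
truth_status <- function(pair, direction = c("fwd", "rev")) {
  direction <- match.arg(direction)
  map0 <- if (direction == "fwd") pair$src_map else pair$tgt_map
  cs <- if (direction == "fwd") pair$chain_fwd else pair$chain_rev
  st <- rep("unmapped_no_chain", base::length(map0))
  for (ch in cs$chains)
    st[(ch$src_start + 1L):ch$src_end] <- "unmapped_in_gap"
  st[!is.na(map0)] <- "converted"
  st
}

#' Injected-discordance specification
#'
#' Controls which truths the direct target call set violates: how many
#' converted variants it omits (position discordant), how many it alters in
#' zygosity (genotype discordant), how strongly injected discordances are
#' enriched in low-confidence regions (per-position LC weight), and how much
#' the depths of unconvertible/discordant variants are scaled down.
#'
#' @param n_position_discordant,n_genotype_discordant injected counts.
#' @param lc_enrichment relative probability (>= 1) of drawing an injected
#'   discordance from an LC position versus an HC position.
#' @param depth_shift multiplicative depth reduction for unconvertible and
#'   discordant variants.
#' @param seed RNG seed for the call-set simulation.
#' @return a \code{discordance_spec} list.
#' @export
discordance_spec <- function(n_position_discordant = 0L,
                             n_genotype_discordant = 0L,
                             lc_enrichment = 1, depth_shift = 0.2,
                             seed = 1L) {
  stopifnot(lc_enrichment >= 1, depth_shift > 0)
  structure(list(n_position_discordant = n_position_discordant,
                 n_genotype_discordant = n_genotype_discordant,
                 lc_enrichment = lc_enrichment, depth_shift = depth_shift,
                 seed = seed), class = "discordance_spec")
}

#' Simulate diploid call sets on an assembly pair
#'
#' Draws a source-assembly call set and derives the direct target-assembly
#' call set as the truth-mapped projection of the convertible variants,
#' minus the injected position-discordant omissions and with the injected
#' genotype-discordant zygosity flips. Per-variant depths follow a negative
#' binomial (mean \code{depth_mean}), scaled by \code{depth_shift} for
#' unconvertible and discordant variants. HC regions are drawn as random
#' windows covering \code{hc_coverage} of each assembly, and injected
#' discordances are drawn with per-position weight \code{lc_enrichment} in
#' LC regions, so the expected PR/GR enrichment ratio equals
#' \code{lc_enrichment} exactly. Discordant variants' reference alleles are
#' drawn from \code{gc_bias_discordant}; all other variants use the genome's
#' background base probabilities. Every injected fact is recorded in the
#' ledger.
#'
#' @param pair an \code{assembly_pair}.
#' @param n_variants total variants in the source call set.
#' @param gc_bias_discordant named draw probabilities (A,T,G,C) for
#'   discordant reference alleles; default combined G+C of 0.52 against the
#'   genome's 0.42 background.
#' @param spec a \code{\link{discordance_spec}}.
#' @param n_unconvertible source variants deliberately placed in deleted
#'   (unmappable) regions.
#' @param n_target_private extra direct-set variants placed in
#'   target-inserted regions, hence unconvertible in the reverse direction.
#' @param hc_coverage fraction of each assembly covered by HC regions.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @return a \code{truth_bundle}: the pair, both call sets, both HC region
#'   sets, the per-variant ledger and all parameters.
#' @export
simulate_callsets <- function(pair, n_variants,
                              gc_bias_discordant = c(A = 0.24, T = 0.24,
                                                     G = 0.26, C = 0.26),
                              spec = discordance_spec(),
                              n_unconvertible = 0L, n_target_private = 0L,
                              hc_coverage = 0.7, depth_mean = 30,
                              depth_size = 8) {
  stopifnot(inherits(pair, "assembly_pair"),
            abs(sum(gc_bias_discordant) - 1) < 1e-9)
  set.seed(spec$seed)
  n_pd <- spec$n_position_discordant
  n_gd <- spec$n_genotype_discordant
  n_bg <- n_variants - n_pd - n_gd - n_unconvertible
  if (n_bg < 0L) stop("injected counts exceed n_variants")

  L <- base::length(pair$src_map)
  Lt <- base::length(pair$tgt_map)
  src_bases <- strsplit(pair$source_seq, "", fixed = TRUE)[[1]]
  convertible <- !is.na(pair$src_map)
  if (n_pd + n_gd + n_bg > sum(convertible))
    stop("more convertible variants requested than convertible positions")
  if (n_unconvertible > sum(!convertible))
    stop("n_unconvertible exceeds deleted positions")

  # HC regions as random windows covering ~hc_coverage of each assembly
  win <- 1000L
  draw_hc <- function(Lx) {
    nw <- ceiling(Lx / win)
    flags <- rep(FALSE, nw)
    flags[sample.int(nw, round(hc_coverage * nw))] <- TRUE
    flags
  }
  hc_win_tgt <- draw_hc(Lt)
  hc_win_src <- draw_hc(L)
  hc_of_tgt <- function(p) hc_win_tgt[p %/% win + 1L]
  regions_from_flags <- function(flags, Lx) {
    sel <- which(flags)
    if (!base::length(sel))
      return(confidence_regions())
    confidence_regions(rep(pair$seq_name, base::length(sel)),
                       (sel - 1L) * win, pmin(sel * win, Lx))
  }

  # position pools keyed by base; convertible pools split by target-side HC
  conv_pos <- which(convertible) - 1L                     # 0-based
  conv_hc <- hc_of_tgt(pair$src_map[conv_pos + 1L])
  del_pos <- which(!convertible) - 1L
  pool <- new.env(parent = emptyenv())
  for (b in BASES) {
    cb <- conv_pos[src_bases[conv_pos + 1L] == b]
    hb <- conv_hc[src_bases[conv_pos + 1L] == b]
    assign(paste0("hc_", b), cb[hb], envir = pool)
    assign(paste0("lc_", b), cb[!hb], envir = pool)
    assign(paste0("del_", b), del_pos[src_bases[del_pos + 1L] == b],
           envir = pool)
  }
  take <- function(key, n) {
    v <- get(key, envir = pool)
    if (n > base::length(v))
      stop("not enough candidate positions in pool ", key)
    sel <- if (n == 0L) integer(0) else v[sample.int(base::length(v), n)]
    assign(key, setdiff(v, sel), envir = pool)
    sel
  }

  bg_prob <- stats::setNames(
    c((1 - pair$gc) / 2, (1 - pair$gc) / 2, pair$gc / 2, pair$gc / 2),
    c("A", "T", "G", "C"))
  draw_class_positions <- function(n, probs, weight_lc) {
    if (n == 0L) return(integer(0))
    cnt <- as.integer(stats::rmultinom(1L, n, probs[c("A", "T", "G", "C")]))
    out <- integer(0)
    for (j in seq_along(BASES_ATGC)) {
      b <- BASES_ATGC[j]
      nb <- cnt[j]
      if (nb == 0L) next
      n_lc_pool <- base::length(get(paste0("lc_", b), envir = pool))
      n_hc_pool <- base::length(get(paste0("hc_", b), envir = pool))
      p_lc <- weight_lc * n_lc_pool / (weight_lc * n_lc_pool + n_hc_pool)
      k_lc <- stats::rbinom(1L, nb, p_lc)
      out <- c(out, take(paste0("lc_", b), k_lc),
               take(paste0("hc_", b), nb - k_lc))
    }
    out
  }

  disc_pos <- draw_class_positions(n_pd + n_gd, gc_bias_discordant,
                                   spec$lc_enrichment)
  bg_pos <- draw_class_positions(n_bg, bg_prob, 1)
  unconv_cnt <- as.integer(stats::rmultinom(1L, n_unconvertible,
                                            bg_prob[c("A", "T", "G", "C")]))
  unconv_pos <- integer(0)
  for (j in seq_along(BASES_ATGC)) {
    key <- paste0("del_", BASES_ATGC[j])
    avail <- base::length(get(key, envir = pool))
    if (unconv_cnt[j] > avail)   # fall back across bases if a pool is short
      stop("not enough deleted positions with base ", BASES_ATGC[j])
    unconv_pos <- c(unconv_pos, take(key, unconv_cnt[j]))
  }

  disc_pos <- disc_pos[sample.int(base::length(disc_pos))]
  pd_pos <- disc_pos[seq_len(n_pd)]
  gd_pos <- if (n_gd > 0L) disc_pos[n_pd + seq_len(n_gd)] else integer(0)

  cls <- c(rep("position_discordant", n_pd),
           rep("genotype_discordant", n_gd),
           rep("concordant", n_bg),
           rep("unconvertible", n_unconvertible))
  pos <- c(pd_pos, gd_pos, bg_pos, unconv_pos)
  n_all <- base::length(pos)
  ref <- src_bases[pos + 1L]
  alt <- random_alt(ref)
  gt <- sample(c("0/1", "1/1"), n_all, replace = TRUE, prob = c(2, 1) / 3)
  shifted <- cls != "concordant"
  depth <- stats::rnbinom(n_all, size = depth_size,
                          mu = ifelse(shifted,
                                      depth_mean * spec$depth_shift,
                                      depth_mean))

  src_set <- data.table::data.table(
    variant_id = seq_len(n_all), seq_name = pair$seq_name, pos = pos,
    ref = ref, alt = alt, gt = gt, depth = depth, class = cls)
  # truth-map projection
  src_set[, tgt_pos := pair$src_map[pos + 1L]]
  src_set[, strand := pair$src_strand[pos + 1L]]
  src_set[class == "unconvertible", `:=`(tgt_pos = NA_integer_,
                                         strand = NA_character_)]
  src_set[, expected_status := ifelse(class == "unconvertible",
                                      truth_status(pair)[pos + 1L],
                                      "converted")]
  src_set[, hc := ifelse(is.na(tgt_pos), NA, hc_of_tgt(tgt_pos))]
  data.table::setorder(src_set, pos)

  # direct target call set: projection minus PD, with GD zygosity flips
  proj <- src_set[class %in% c("concordant", "genotype_discordant")]
  direct <- data.table::data.table(
    variant_id = proj$variant_id, seq_name = pair$seq_name,
    pos = proj$tgt_pos,
    ref = ifelse(proj$strand == "-", complement_base(proj$ref), proj$ref),
    alt = ifelse(proj$strand == "-", complement_base(proj$alt), proj$alt),
    gt = ifelse(proj$class == "genotype_discordant",
                ifelse(proj$gt == "0/1", "1/1", "0/1"), proj$gt),
    depth = stats::rnbinom(nrow(proj), size = depth_size, mu = depth_mean),
    class = proj$class)
  if (n_target_private > 0L) {
    ins_pos <- which(is.na(pair$tgt_map)) - 1L
    if (n_target_private > base::length(ins_pos))
      stop("n_target_private exceeds target-inserted positions")
    tp <- sort(ins_pos[sample.int(base::length(ins_pos), n_target_private)])
    tp_ref <- seq_base_at(pair$target_seq, rep(pair$seq_name,
                                               n_target_private), tp)
    direct <- rbind(direct, data.table::data.table(
      variant_id = n_all + seq_len(n_target_private),
      seq_name = pair$seq_name, pos = tp,
      ref = tp_ref,
      alt = random_alt(tp_ref),
      gt = sample(c("0/1", "1/1"), n_target_private, replace = TRUE,
                  prob = c(2, 1) / 3),
      depth = stats::rnbinom(n_target_private, size = depth_size,
                             mu = depth_mean * spec$depth_shift),
      class = "target_private"))
  }
  data.table::setorder(direct, pos)

  ledger <- rbind(
    src_set[, .(variant_id, assembly = "source", pos, ref, alt, gt, depth,
                class, expected_status, tgt_pos, strand, hc)],
    direct[class == "target_private",
           .(variant_id, assembly = "target", pos, ref, alt, gt, depth,
             class, expected_status = "unmapped", tgt_pos = NA_integer_,
             strand = NA_character_, hc = NA)])

  structure(list(
    pair = pair,
    snvs_source = src_set[, .(seq_name, pos, ref, alt, gt, depth)],
    snvs_target = direct[, .(seq_name, pos, ref, alt, gt, depth)],
    hc_source = regions_from_flags(hc_win_src, L),
    hc_target = regions_from_flags(hc_win_tgt, Lt),
    ledger = ledger,
    params = list(n_variants = n_variants, n_pd = n_pd, n_gd = n_gd,
                  n_unconvertible = n_unconvertible,
                  n_target_private = n_target_private,
                  lc_enrichment = spec$lc_enrichment,
                  depth_shift = spec$depth_shift,
                  hc_coverage = hc_coverage, depth_mean = depth_mean,
                  depth_size = depth_size,
                  gc_bias_discordant = gc_bias_discordant,
                  seed = spec$seed, edit_seed = pair$edit_seed)),
    class = "truth_bundle")
}

BASES_ATGC <- c("A", "T", "G", "C")

#' Write a truth bundle to disk as a fixture tree
#'
#' Writes both assemblies (FASTA), both chain files, both call sets (VCF
#' v4.2, sorted, with GT:DP), both HC BEDs, the tab-separated truth ledger
#' and a YAML manifest holding every generator parameter and seed. All
#' writers are deterministic, so the same bundle always produces
#' byte-identical files.
#'
#' @param bundle a \code{truth_bundle}.
#' @param dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  pair <- bundle$pair
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(pair$source_seq), p("source.fa"), width = 70L)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(pair$target_seq), p("target.fa"), width = 70L)
  write_chain(pair$chain_fwd, p("fwd.chain"))
  write_chain(pair$chain_rev, p("rev.chain"))
  write_snv_vcf(bundle$snvs_source, p("source.vcf"),
                stats::setNames(nchar(pair$source_seq), pair$seq_name))
  write_snv_vcf(bundle$snvs_target, p("target_direct.vcf"),
                stats::setNames(nchar(pair$target_seq), pair$seq_name))
  write_confidence_bed(bundle$hc_source, p("hc_source.bed"))
  write_confidence_bed(bundle$hc_target, p("hc_target.bed"))
  data.table::fwrite(bundle$ledger, p("ledger.tsv"), sep = "\t")
  manifest <- c(list(files = list(
    source_fasta = "source.fa", target_fasta = "target.fa",
    chain_fwd = "fwd.chain", chain_rev = "rev.chain",
    vcf_source = "source.vcf", vcf_target_direct = "target_direct.vcf",
    hc_bed_source = "hc_source.bed", hc_bed_target = "hc_target.bed",
    ledger = "ledger.tsv")), bundle$params)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(manifest)
}
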