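# UCSC chain file parsing, validation and writing.
#
# Coordinate conventions (UCSC): all intervals are 0-based, half-open. The
# chain header is
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
# followed by alignment-block lines "size dt dq" and a bare final "size".
# The t-side strand is always '+'; the q-side coordinates are STRAND-LOCAL,
# i.e. for qStrand '-' they count from the far end of the sequence.
#
# IMPORTANT direction note: this package follows liftOver usage, where the
# chain's t-side is the lift SOURCE assembly and the q-side the lift TARGET.
# Everywhere below "source" means t-side and "target" means q-side.

new_chain_set <- function(chains, source_sizes, target_sizes) {
  structure(list(chains = chains,
                 source_sizes = source_sizes,
                 target_sizes = target_sizes),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("<chain_set> ", length(x$chains), " chain(s); source: ",
      paste(names(x$source_sizes), collapse = ","),
      "; target: ", paste(names(x$target_sizes), collapse = ","), "\n",
      sep = "")
  invisible(x)
}

#' Parse a UCSC chain file
#'
#' Reads chain-format text into a \code{chain_set}: a list of chains, each
#' holding its header fields and an ordered table of alignment blocks
#' (\code{size}, \code{src_gap}, \code{tgt_gap}). Block arithmetic is
#' validated against the header spans: the sizes plus source-side gaps must
#' sum to \code{src_end - src_start}, and sizes plus target-side gaps to
#' \code{tgt_end - tgt_start}; a mismatch raises an error naming the chain id.
#'
#' The chain's t-side is interpreted as the lift source and the q-side as the
#' lift target, matching how liftOver consumes chains.
#'
#' @param input path to a chain file, or a character vector of chain-format
#'   lines.
#' @return a \code{chain_set} object.
#' @export
parse_chain <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input) else unlist(strsplit(input, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chains <- list()
  src_sizes <- integer(0)
  tgt_sizes <- integer(0)
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) != 13L)
      stop("malformed chain header at line ", i, ": ", lines[i])
    hd <- list(score = as.numeric(f[2]),
               src_name = f[3], src_size = as.integer(f[4]),
               src_strand = f[5],
               src_start = as.integer(f[6]), src_end = as.integer(f[7]),
               tgt_name = f[8], tgt_size = as.integer(f[9]),
               tgt_strand = f[10],
               tgt_start = as.integer(f[11]), tgt_end = as.integer(f[12]),
               chain_id = as.integer(f[13]))
    if (hd$src_strand != "+")
      stop("chain ", hd$chain_id, ": source (t-side) strand must be '+'")
    if (!hd$tgt_strand %in% c("+", "-"))
      stop("chain ", hd$chain_id, ": bad target strand '", hd$tgt_strand, "'")
    i <- i + 1L
    sizes <- integer(0); sgap <- integer(0); tgap <- integer(0)
    repeat {
      if (i > length(lines))
        stop("chain ", hd$chain_id, ": truncated block list")
      b <- suppressWarnings(as.integer(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(b)) stop("chain ", hd$chain_id, ": malformed block line: ",
                         lines[i])
      i <- i + 1L
      if (length(b) == 1L) {           # final block, no trailing gaps
        sizes <- c(sizes, b[1]); sgap <- c(sgap, 0L); tgap <- c(tgap, 0L)
        break
      }
      if (length(b) != 3L)
        stop("chain ", hd$chain_id, ": block lines must have 1 or 3 fields")
      sizes <- c(sizes, b[1]); sgap <- c(sgap, b[2]); tgap <- c(tgap, b[3])
    }
    if (any(sizes < 1L) || any(sgap < 0L) || any(tgap < 0L))
      stop("chain ", hd$chain_id, ": block sizes must be >=1 and gaps >=0")
    if (sum(sizes) + sum(sgap) != hd$src_end - hd$src_start)
      stop("chain ", hd$chain_id,
           ": block arithmetic mismatch on source side (",
           sum(sizes) + sum(sgap), " vs span ",
           hd$src_end - hd$src_start, ")")
    if (sum(sizes) + sum(tgap) != hd$tgt_end - hd$tgt_start)
      stop("chain ", hd$chain_id,
           ": block arithmetic mismatch on target side (",
           sum(sizes) + sum(tgap), " vs span ",
           hd$tgt_end - hd$tgt_start, ")")
    hd$blocks <- data.table::data.table(size = sizes, src_gap = sgap,
                                        tgt_gap = tgap)
    chains[[length(chains) + 1L]] <- hd
    src_sizes[hd$src_name] <- hd$src_size
    tgt_sizes[hd$tgt_name] <- hd$tgt_size
  }
  new_chain_set(chains, src_sizes, tgt_sizes)
}

#' Write a chain set in UCSC chain format
#'
#' Inverse of \code{\link{parse_chain}}: emits one header plus block lines per
#' chain, blank-line separated. Output is deterministic (no timestamps), so a
#' written file re-parses field-for-field.
#'
#' @param chain_set a \code{chain_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_chain <- function(chain_set, path) {
  stopifnot(inherits(chain_set, "chain_set"))
  out <- character(0)
  for (ch in chain_set$chains) {
    hdr <- paste("chain", format(ch$score, scientific = FALSE, trim = TRUE),
                 ch$src_name, ch$src_size, ch$src_strand,
                 ch$src_start, ch$src_end,
                 ch$tgt_name, ch$tgt_size, ch$tgt_strand,
                 ch$tgt_start, ch$tgt_end, ch$chain_id)
    nb <- nrow(ch$blocks)
    body <- character(nb)
    if (nb > 1L)
      body[seq_len(nb - 1L)] <- paste(ch$blocks$size[-nb],
                                      ch$blocks$src_gap[-nb],
                                      ch$blocks$tgt_gap[-nb])
    body[nb] <- as.character(ch$blocks$size[nb])
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}
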